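# Combined pathway enthalpies (kJ/mol) for vitamin B3: SETPT = IP+PDE,
# SPLET = PA+ETE, BASE = IP+PDE-BDE as printed; last row attributed to
# the criticized literature study.
molecule_id,site_id,medium,unit,SETPT,SPLET,BASE,IPH_ref
UB3LYP/6-311G(d.p),COOH,gas,kJ/mol,1758.6,1758.6,1321.5,1321.5
ROB3LYP/6-311G(d.p),COOH,gas,kJ/mol,1765.1,1765.1,1321.5,1321.5
UB3LYP/6-311++G(d.p),COOH,gas,kJ/mol,1760.4,1760.4,1321.8,1321.8
ROB3LYP/6-311++G(d.p),COOH,gas,kJ/mol,1767.1,1767.1,1321.8,1321.8
UB3LYP/6-311G(d.p),COOH,water,kJ/mol,602.8,602.8,166.5,166.5
ROB3LYP/6-311G(d.p),COOH,water,kJ/mol,609.2,609.2,166.5,166.5
UB3LYP/6-311++G(d.p),COOH,water,kJ/mol,604.0,604.0,166.8,166.8
ROB3LYP/6-311++G(d.p),COOH,water,kJ/mol,610.7,610.7,166.8,166.8
B3LYP-lit/6-311G(d.p),COOH,water,kJ/mol,1761,627,1320,166.5
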