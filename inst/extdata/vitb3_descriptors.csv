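# Reaction enthalpies (kJ/mol) for vitamin B3 (nicotinic acid) in gas and
# water, own UB3LYP/ROB3LYP calculations at two basis sets, plus the row
# attributed to the criticized literature study (declared aqueous there).
# molecule_id encodes method/basis; IPH_ref is the per-protocol H-atom
# ionization enthalpy (continuum-solvent protocol for water rows).
molecule_id,site_id,medium,unit,BDE,IP,PDE,PA,ETE,IPH_ref
UB3LYP/6-311G(d.p),COOH,gas,kJ/mol,437.1,879.9,878.7,1432.5,326.1,1321.5
ROB3LYP/6-311G(d.p),COOH,gas,kJ/mol,443.6,884.3,880.8,1432.5,332.6,1321.5
UB3LYP/6-311++G(d.p),COOH,gas,kJ/mol,438.6,891.8,868.6,1397.4,363.0,1321.8
ROB3LYP/6-311++G(d.p),COOH,gas,kJ/mol,445.3,896.1,870.9,1397.4,369.6,1321.8
UB3LYP/6-311G(d.p),COOH,water,kJ/mol,436.3,584.2,18.6,154.2,448.6,166.5
ROB3LYP/6-311G(d.p),COOH,water,kJ/mol,442.7,588.5,20.7,154.2,455.1,166.5
UB3LYP/6-311++G(d.p),COOH,water,kJ/mol,437.2,595.1,8.9,117.8,486.2,166.8
ROB3LYP/6-311++G(d.p),COOH,water,kJ/mol,443.9,599.5,11.2,117.8,492.9,166.8
B3LYP-lit/6-311G(d.p),COOH,water,kJ/mol,441,892,869,149,478,166.5
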