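# Reported combined scavenging enthalpies (kJ/mol) for five dietary
# vitamins, declared as aqueous-phase M05-2X/M06-2X averages.
# SETPT = IP+PDE, SPLET = PA+ETE, BASE = IP+PDE-BDE as printed;
# IPH_ref is the water-phase H-atom ionization enthalpy reference.
molecule_id,site_id,medium,unit,SETPT,SPLET,BASE,IPH_ref
vitaminA,,water,kJ/mol,1742.0+/-2.0,532.0+/-1.0,1386.0,155.6
vitaminB1,,water,kJ/mol,1750.5+/-0.5,611.5+/-1.5,1315.5,155.6
vitaminB3,,water,kJ/mol,1790.5+/-1.5,658.0+/-2.0,1309.0,155.6
vitaminB6,,water,kJ/mol,1655.0+/-1.0,537.0+/-0.0,1294.5,155.6
vitaminC,,water,kJ/mol,1611.5+/-1.5,495.0+/-2.0,1293.0,155.6
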