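# Reported reaction enthalpies (kcal/mol) for the food colorant peonidin
# at B3LYP/6-31+G(d,p) (IEF-PCM for water), with the reported combined
# sums and the per-medium H-atom ionization enthalpy reference.
molecule_id,site_id,medium,unit,BDE,IP,PDE,PA,ETE,SETPT,SPLET,IPH_ref
peonidin,,gas,kcal/mol,81.50,235.37,159.88,-120.49,515.74,395.25,395.25,314.7
peonidin,,water,kcal/mol,78.92,138.36,254.51,-88.96,483.38,392.87,394.42,32.8
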