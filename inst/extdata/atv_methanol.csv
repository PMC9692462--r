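# Reported reaction enthalpies (kcal/mol) for atorvastatin (ATV) and its
# ortho- and para-hydroxy metabolites in methanol, B3LYP/6-31+G(d,p).
# IP is printed once per molecule (it is a molecule-level property).
# BASE is the printed IP+PDE-BDE offset; IPH_ref the methanol reference.
molecule_id,Position,medium,unit,BDE,IP,PDE,SETPT,PA,ETE,SPLET,BASE,IPH_ref
ATV,1-OH,methanol,kcal/mol,91.4,107.0,22.4,129.4,23.8,105.7,129.4,38.1,38.1
ATV,2-OH,methanol,kcal/mol,104.2,,35.3,142.3,46.7,95.6,142.3,38.1,38.1
ATV,3-OH,methanol,kcal/mol,105.2,,36.3,143.2,61.5,81.8,143.2,38.1,38.1
ATV,4-NH,methanol,kcal/mol,90.2,,21.3,128.3,44.4,83.9,128.3,38.1,38.1
o-ATV,1-OH,methanol,kcal/mol,91.2,106.9,22.4,129.3,23.8,105.5,129.3,38.1,38.1
o-ATV,2-OH,methanol,kcal/mol,104.2,,35.4,142.3,46.8,95.5,142.3,38.1,38.1
o-ATV,3-OH,methanol,kcal/mol,105.1,,36.3,143.2,61.5,81.7,143.2,38.1,38.1
o-ATV,4-NH,methanol,kcal/mol,89.3,,20.5,127.4,49.0,78.4,127.4,38.1,38.1
o-ATV,5-OH,methanol,kcal/mol,77.5,,8.7,115.6,34.4,81.2,115.6,38.1,38.1
p-ATV,1-OH,methanol,kcal/mol,90.7,106.2,22.6,128.8,23.8,105.0,128.8,38.1,38.1
p-ATV,2-OH,methanol,kcal/mol,104.2,,36.0,142.2,46.8,95.4,142.2,38.1,38.1
p-ATV,3-OH,methanol,kcal/mol,105.1,,37.0,143.2,58.2,85.0,143.2,38.1,38.1
p-ATV,4-NH,methanol,kcal/mol,85.5,,17.4,123.6,43.8,79.0,123.6,38.1,38.1
p-ATV,5-OH,methanol,kcal/mol,77.4,,9.2,115.4,37.9,77.5,115.4,38.1,38.1
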