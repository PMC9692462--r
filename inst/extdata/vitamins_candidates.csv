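# Candidate media for inference on the vitamins table: H-atom ionization
# enthalpy (kJ/mol) averaged over the M05-2X and M06-2X functionals at
# 6-311++G(d,p), as printed alongside the reported table.
medium,iph_kj
water,155.6
gas,1312.6
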