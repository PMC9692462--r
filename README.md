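# radaudit

Consistency audits for free-radical-scavenging thermochemistry.

## The problem

An antioxidant AXH can neutralize a free radical R• three ways:

* **HAT** — direct H-atom transfer, `AXH + R• → AX• + RH`, characterized
  by the bond dissociation enthalpy
  `BDE = H(AX•) + H(H•) − H(AXH)`;
* **SET-PT** — electron transfer then proton transfer:
  `IP = H(AXH•⁺) + H(e⁻) − H(AXH)`, then
  `PDE = H(AX•) + H(H⁺) − H(AXH•⁺)`;
* **SPLET** — proton loss then electron transfer:
  `PA = H(AX⁻) + H(H⁺) − H(AXH)`, then
  `ETE = H(AX•) + H(e⁻) − H(AX⁻)`.

Because the two two-step routes share reactants and products, and because
all five descriptors are balanced reactions over one species set, Hess's
law forces two exact identities on any correctly computed table:

```
T1:  IP + PDE = PA + ETE
T2:  IP + PDE − BDE = PA + ETE − BDE = IP_H  > 0
```

where `IP_H = H(H⁺) + H(e⁻) − H(H•)` is the ionization enthalpy of the
hydrogen atom in the same medium — identical for **every** molecule and
H-donation site in that medium. Published descriptor tables violate these
identities surprisingly often (unit mix-ups, gas-phase numbers labeled
aqueous, transcription slips), and any mechanistic conclusion drawn from
such a table is void. `radaudit` computes the descriptors from species
enthalpies, evaluates `IP_H` for gas and five common solvents from a
built-in reference catalog, and audits reported tables against both
identities with rounding-aware tolerances and failure diagnoses. It never
ranks mechanisms: the identities themselves show that SET-PT vs SPLET
cannot be adjudicated from the antioxidant's descriptors alone.

## Worked example

Audit a published table of combined pathway enthalpies for five dietary
vitamins, declared as aqueous-phase values (kJ/mol):

```r
library(radaudit)
v    <- read_descriptor_table(radaudit_example("vitamins_aqueous.csv"))
cand <- read.csv(radaudit_example("vitamins_candidates.csv"),
                 comment.char = "#")
audit_table(v, audit_config(printed_decimals = 1), candidates = cand)
#> audit report: 5 rows, 17 findings ( 12 fail / 5 pass / 0 indeterminate )
#> inferred media: water -> gas
#> failures:
#>    scope row molecule_id ... check              residual unit   ...
#>      row   1    vitaminA     T1                   1210.0 kJ/mol
#>      ...
#>  dataset  NA        <NA>     T2_site_invariance     93.0 kJ/mol
#>  dataset  NA        <NA>     medium_inference        3.6 kJ/mol
```

Reading the report: every row fails T1 — the two pathway sums differ by
1116–1210 kJ/mol where they must be equal, so the table cannot be
internally consistent. The `IP + PDE − BDE` offsets (which should all
equal the aqueous `IP_H` ≈ 155.6 kJ/mol) spread over 93 kJ/mol and sit
within 3.6 kJ/mol of the **gas-phase** `IP_H` ≈ 1312.6 kJ/mol, so the
audit diagnoses `medium_mismatch_suspected`: the ionization-side numbers
were most likely computed in gas and mislabeled aqueous.

Other entry points:

```r
iph("B3LYP", "6-311++G(d,p)", "water")       # 164.85 kJ/mol
identity_basis(canonical_reaction_system())  # the two identities, exactly
generate_consistent(5, 3, "water", seed = 42)   # synthetic fixtures
inject_violation(tbl, "unit_mixup", rows = 2)   # labeled faults
```

A CLI wrapper ships under `inst/cli/radaudit` with subcommands `convert`,
`iph`, `descriptors`, `identities`, `audit`, `simulate`.

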