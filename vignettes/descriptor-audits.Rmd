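---
title: "Auditing antioxidant descriptor tables with exact Hess's-law identities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing antioxidant descriptor tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radaudit)
```

## The model

Five reaction enthalpies characterize how an antioxidant AXH donates a
hydrogen atom: BDE (direct transfer), IP and PDE (electron transfer then
proton transfer), PA and ETE (proton loss then electron transfer). Each
is a balanced reaction over the species set {AXH, AX•, AX⁻, AXH•⁺, H•,
H⁺, e⁻}, so each is a row of an integer stoichiometric matrix. The left
null space of that matrix is the set of linear identities that any
correctly computed table must satisfy *exactly* — not approximately, and
at any level of theory, because they are arithmetic consequences of the
definitions, not physics that a better functional could change. For the
canonical system the space is two-dimensional and is spanned by

* **T1**: IP + PDE − PA − ETE = 0 (both two-step routes share reactants
  and products), and
* **T2**: IP + PDE − BDE − IP\_H = 0, where
  IP\_H = H(H⁺) + H(e⁻) − H(H•) is the hydrogen atom's ionization
  enthalpy in the same medium.

`identity_basis()` discovers these by exact integer elimination
(fraction-free row reduction; floats appear only when residuals of
measured values are evaluated), so the engine generalizes to extended
species sets — add the scavenged radical's species and the same machinery
derives the corresponding identities without new code.

T2 has an important corollary: IP + PDE − BDE is the *same positive
number* for every molecule and every H-donation site in one medium. A
descriptor table whose offsets scatter is internally inconsistent no
matter what reference value one believes in.

The same relations hold verbatim for Gibbs energies; the quantity kind is
a dataset-level tag, not a separate code path.

## Reference data and IP\_H

The catalog ships gas-phase enthalpies of the proton (6.140 kJ/mol) and
electron (3.135 kJ/mol), H-atom enthalpies per functional/basis (B3LYP,
PBE0, M062x, M052x over the Pople families, all at 298.15 K with the
universal 0.002361 hartree thermal correction), and PCM solvation
enthalpies of H⁺/e⁻/H• for benzene, toluene, ethanol, methanol and
water. A solvated reference-particle enthalpy is assembled as gas value
plus solvation term. Three numerical conventions are fixed once:
1 hartree = 2625.49964 kJ/mol, 1 kcal = 4.184 kJ (thermochemical),
1 eV = 96.48533 kJ/mol; all internal arithmetic is in kJ/mol with
conversion only at boundaries.

Basis names normalize before lookup: star notation expands
(`6-311G**` → `6-311G(d,p)`), extra polarization shells collapse (they do
not move the one-electron reference values), and within a Pople family
the non-diffuse variant maps onto the singly-diffuse one. The catalog is
overridable from JSON (`read_catalog()`), and every entry must carry a
provenance string — auditable reference data is the point of the tool.

Two deliberate accommodations:

* An alternative proton hydration enthalpy (−1022 kJ/mol instead of
  −1058.9) ships as a selectable variant, because descriptor differences
  of tens of kJ/mol between publications can stem from this choice alone.
* Aqueous IP\_H values obtained by computing the H-atom directly inside
  the continuum solvent differ by ~2 kJ/mol from the
  gas-value-plus-solvation chain. The audit therefore accepts per-dataset
  (and per-row) IP\_H overrides rather than guessing a reconciliation.

A read-only annex carries Koopmans (negative HOMO) estimates of IP\_H
for display only: they are off by 3–5 eV in gas and ~12 eV in polar
solvents, which is why no computation here uses orbital energies.

## Tolerances

Printed tables round. The default tolerance for a residual assembled
from k independently rounded printed terms is k · 0.5 · 10^−d at d
printed decimals: a T1 residual re-added from four one-decimal step
descriptors gets 0.2; one formed from two reported one-decimal sums gets
0.1. Comparisons are inclusive at the boundary. An absolute mode
(kJ/mol, converted with the table's unit) serves synthetic data.

T1 compares the two pathway *totals*. When a table prints both the
addends and the total of a pathway, the printed total is taken as the
table's claim (k = 1 rounded term) and a separate transcription check
compares it against the re-added components; `prefer = "components"`
restores pure re-addition. This split matters in practice: one shipped
reference table contains a row whose printed proton-affinity/ETE addends
disagree with their own printed total by 0.8 kcal/mol while the total,
the offset column and every cross-check are self-consistent — a
transcription typo in an addend cell, which is exactly what the
transcription finding (and not a theorem violation) should say.

T2 is tested in two tiers. Site-invariance — all IP+PDE−BDE offsets in
one medium agree — is strict and reference-free (residual: the spread;
verdict: maximal deviation from the median against the k-term
tolerance). The comparison against a *reference* IP\_H is loose by
default (5 kJ/mol) because of the protocol dependence noted above. The
reference resolves in order: config override, per-row reference column,
catalog lookup for the declared medium and method.

## Diagnoses

Failures carry a best-effort cause:

* `unit_mixup_suspected` — the T1 residual collapses under tolerance
  after rescaling one side by 4.184 (kcal values in a kJ column or vice
  versa);
* `medium_mismatch_suspected` — the dataset's median offset sits closer
  to a *different* medium's IP\_H than to the declared one.
  `infer_medium()` asserts a match only when the deviation is below half
  the smallest gap between candidate IP\_H values (at B3LYP/6-311++G(d,p)
  the water and methanol values are only 0.3 kJ/mol apart, so with the
  full six-medium candidate set a match needs sub-0.15 kJ/mol agreement;
  with a water-vs-gas candidate pair the gap is ~1157 kJ/mol and
  inference is essentially certain);
* `gross_inconsistency` — neither simple repair explains the residual.

## The synthetic generator

`generate_consistent()` draws descriptor targets uniformly inside the
windows spanned by published antioxidant tables — BDE in [300, 500]
kJ/mol, molecule-level IP in [500, 900] kJ/mol, PA in [50, 700] kJ/mol —
and solves for species enthalpies (parent enthalpy near −2·10⁶ kJ/mol;
the absolute scale cancels in every descriptor) that reproduce them
exactly through the same reference-particle chain the auditor uses. PDE
and ETE then follow from the identities. It emulates table *structure*
and error classes, not electronic-structure physics: no conformer
ensembles, no solvent-model noise, no correlated errors between species.
A green audit on generated data therefore establishes that the checks
are algebraically sound and correctly calibrated to rounding — not that
they would catch every failure mode of a real quantum-chemistry
workflow. All entry points take explicit seeds and restore global RNG
state; the same seed gives identical tables.

`inject_violation()` plants labeled faults: a T1 offset (PDE shifted),
a T2 offset (PDE and ETE shifted alike, so T1 stays intact), a unit
mix-up (SPLET-side cells times 4.184), a medium mislabel (declared
medium only), or a transcription error (reported total corrupted). The
truth labels let sensitivity/specificity be measured exactly; the test
suite requires 100% detection at twice the tolerance and zero false
positives on clean tables across 50 seeds.

## Numerical and design choices

* Exact integer arithmetic for identity discovery; basis vectors are
  primitive-integer, lexicographically ordered by support, positive
  leading coefficient — deterministic and testable output.
* Rounding for display mimics table printing: half away from zero with a
  1e-9 relative guard against binary-representation artifacts.
* IP attaches to the molecule, not the site; `fill_molecule_ip()` fans a
  once-printed IP out to site rows.
* Uncertainty cells (`a±b`, ASCII `a+/-b`) parse as mean and half-range;
  audits use the mean and carry the half-range alongside.
* Malformed cells become absent values with warnings — never zeros — and
  absent inputs yield `indeterminate` verdicts, not passes.
* Dataset-level checks group rows by declared medium, since T2's
  constancy only holds within one medium.

## Known limitations

* The shipped reference tables contain their own last-digit
  inconsistencies (a duplicated PBE0 row; one kJ cell disagreeing with
  its kcal companion by 0.1): the package reproduces the consistent
  chain and the test suite documents the misprints rather than matching
  them.
* Solvents are reducible to three solvation enthalpies; media that are
  not (explicit microsolvation, mixtures) are out of scope.
* The tool audits consistency; it deliberately refuses to rank HAT vs
  SET-PT vs SPLET, because the identities prove the combined two-step
  enthalpies are always equal and always exceed BDE — settling the
  competition requires the radical's thermochemistry and kinetics, which
  are outside a descriptor table.
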