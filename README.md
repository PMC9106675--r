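# ppidrugg

Structure-based druggability assessment of protein–protein interaction
(PPI) interfaces.

PPI interfaces are flat, extended and hydrophobic, and for decades they
were written off as undruggable. Whether a *particular* interface can bind
a drug-like small molecule is nonetheless a quantitative question: seed
the candidate region with a ligand, measure the pocket it sits in, and
score it. `ppidrugg` is an R implementation of that workflow for
structural bioinformaticians and early-discovery computational chemists:

* **Curation** — read PDB files, resolve alternate locations by
  occupancy, keep only the inhibitor-bound chain, strip solvent and
  heteroatoms (`read_pdb()`, `select_chain()`, `strip_non_protein()`,
  `extract_ligand()`).
* **Superposition** — pose a reference ligand into apo or
  peptide/protein-bound structures via global sequence alignment
  (Needleman–Wunsch, affine gaps, BLOSUM62) and Kabsch Cα fitting
  (`global_align()`, `kabsch()`, `superpose_on_reference()`).
* **Pocket descriptors** — a deterministic grid/ray-casting engine
  computes the number of site points *n*, the enclosure factor
  *e* ∈ [0, 1] (fraction of 162 icosphere ray directions blocked by
  protein within 10 Å) and the hydrophilicity factor *p* (scaled
  polar-contact fraction of the pocket lining), or reports **ND** — no
  site detected — on flat interfaces (`detect_site()`).
* **Scoring and classification** — the druggability score

  ```
  Dscore = 0.094 * sqrt(n) + 0.60 * e − 0.324 * p
  ```

  with the four-class PPI scheme (≥ 1.0 very druggable; ≥ 0.75
  druggable; ≥ 0.5 moderately druggable; otherwise difficult, ND
  included) and Halgren's original three-class scheme
  (`dscore()`, `classify_ppi()`, `classify_halgren()`), plus per-target
  aggregation, percent-reduction arithmetic for apo/holo comparisons,
  correlations and pIC50 handling.
* **Drug-likeness** — Lipinski rule-of-five violation counts, the
  relaxed one-violation rule **Ro5-1**, the QED desirability score
  (published ADS parameters; unweighted or canonical weights) and the
  Rule-of-Four profile of PPI inhibitors, with per-target audits
  (`ro5_violations()`, `qed_score()`, `audit_set()`).
* **Synthetic fixtures** — generators for slab structures with cavities
  of controlled radius, depth, rim and polar lining, apo/holo pairs with
  tunable pocket closure, per-target descriptor distributions and
  property tables with planted rule violations, so the entire pipeline is
  testable offline (`make_cavity_structure()`, `make_apo_holo_pair()`,
  `make_descriptor_table()`, `make_property_table()`).
* **Pipeline** — a manifest-driven end-to-end run with per-structure
  failure isolation and table/JSON rendering (`ppi_run()`,
  `render_tables()`). A thin command-line wrapper ships in
  `inst/scripts/ppidrugg.R`.

## Worked example

Build a synthetic interface with a 4 Å × 4 Å pocket whose lining is half
polar, detect the site and classify it; then do the same for a flat,
ZipA-like slab:

```r
library(ppidrugg)

cav  <- make_cavity_structure(cavity_spec(radius = 4, depth = 4, polar_fraction = 0.5))
cav$structure
#> <ppi_structure> 2441 heavy atoms, 1 chain(s) [A], 2435 residue(s), 6 hetero atom(s)

site <- detect_site(cav$structure, cav$ligand)
site
#> <site_descriptors> n = 143 site points, e = 0.636, p = 0.706 (Dscore 1.277)
classify_ppi(dscore(site$n, site$e, site$p))
#> [1] "very druggable"

flat <- make_cavity_structure(cavity_spec(radius = 4, depth = 0))
detect_site(flat$structure, flat$ligand)
#> <site_descriptors> ND (no site detected)
```

The pocket holds 143 grid points, is moderately buried (64% of ray
directions blocked) and mildly polar, scoring 1.28 — a very druggable
site; the flat slab has no pocket at all and would classify as a
difficult target.

Emulate the published 12-target dataset (320 structures) from its
per-target descriptor medians, aggregate and classify:

```r
rec <- emulate_reference_dataset(seed = 1)
s   <- aggregate_target(rec)
ov  <- s[s$form == "overall", ]
ov$class <- classify_ppi(round(ov$median_dscore, 2))
head(ov[order(-ov$median_dscore),
        c("target", "n_structures", "median_dscore", "median_n", "class")], 5)
#>  target n_structures median_dscore median_n          class
#>    DCN1           10          1.21       98 very druggable
#>    HDM2           87          1.00       54 very druggable
#>   Bcl-2           26          0.94       46      druggable
#>    XDM2           11          0.93       49      druggable
#>  Bcl-xL           24          0.90       46      druggable
```

Audit a property table with a planted Lipinski-violation profile
(30% clean, 35% one violation, …):

```r
tab <- make_property_table(200, c(0.30, 0.35, 0.20, 0.10, 0.05), seed = 1)
audit_set(tab)
#>   group   n n_ro5 pct_ro5 n_qed pct_qed n_ro5_minus_1 pct_ro5_minus_1
#> 1   all 200    60      30    64      32           130              65
```

Exactly 30% of molecules pass the strict rule of five and 65% pass the
relaxed Ro5-1 — the planted profile, recovered by the audit.

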