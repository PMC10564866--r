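# repgut

Analysis of immunoglobulin heavy-chain (IGH) repertoires from paired gut
mucosal and peripheral blood samples of two donor groups — individuals
treated early (eART) versus late (lART) in HIV-1 infection. The package
implements the full bulk-repertoire pipeline as reusable, tested
functions, plus a synthetic repertoire generator that provides ground
truth for every stage:

* paired-end amplicon merging (≥10 nt overlap, min length 300, terminal
  Q20 trimming);
* germline V/J assignment by affine Smith–Waterman (match +1, mismatch
  −2, gap −5/−2) with Karlin–Altschul E-values
  (*E = K·m·n·e^(−λS)*, λ = 1.3327, K = 0.621), isotype calling, and
  CDR-H3 extraction between the Cys104 anchor and the W-G-x-G motif;
* quality filters: stop codon, V E-value > 10⁻³, missing W-G-x-G,
  germline alignment start > 9;
* somatic hypermutation counting over the full aligned V region;
* 99%-identity dereplication (greedy, CD-HIT-style);
* clonal families: same V and J gene, same CDR-H3 length, ≥ 0.8 CDR-H3
  amino-acid identity, single linkage;
* single-nucleotide mutation networks (edges = one non-indel
  difference), with GraphML/edge-list export;
* repertoire feature statistics: per-parameter 2×2 Fisher exact tests,
  Welch *t*, Pearson correlation matrices, Benjamini–Hochberg control,
  volcano tables, IgA/IgG ratios;
* gut↔blood clone sharing: identical V and J genes plus ≥ 90% CDR-H3
  amino-acid identity at equal length;
* reactivity metrics: ELISA AUC and cumulative AUC
  (log₁₀(ΣAUC + 1)), robust microarray Z-scores, and the
  polyreactivity index with the strict PI > 0.21 classification.

The repository is organised as an analysis workflow: numbered drivers
under `analysis/` narrate the study over simulated data and write their
tables under `results/`, while all computation lives in the package
(`R/`, `src/`) where the tests exercise it.

## Worked example

```r
library(repgut)

cfg <- sim_config(seed = 42, n_clones = 120)   # defaults = study conditions
sim <- simulate_repertoire(cfg)
ref <- load_germline_reference("builtin")

rearr <- annotate_rearrangements(
  data.frame(id = sim$truth$sequence_id, sequence = sim$truth$sequence,
             duplicate_count = sim$truth$duplicate_count), ref)
qc    <- apply_qc(rearr)
derep <- dereplicate_99(qc$pass)
fams  <- infer_clonal_families(derep)

nrow(fams)
sharing_frequency_test(33, 99, 6, 101)$p       # published sharing table
fisher_exact_2x2(12, 87, 1, 100)               # polyreactive subset
```

Running the drivers in order (`Rscript analysis/01_simulate_repertoire.R`
… `08_validation.R`) prints, among others:

```
simulated 480 clones, 2103 unique members (948 gut / 1155 blood)
sharing rate eART 6.7%, lART 35.8% (configured 4.9 / 33.3)
merged 2103/2103 pairs (0 overlap failures, 0 too short after trimming)
annotated 2103 sequences; 2082 passed QC, 21 rejected
V-call concordance with simulation truth: 100.00%
dereplicated 2082 -> 2035 unique sequences
484 clonal families; network: 2035 vertices, 0 edges, 2035 components
eART: 8/120 gut clones found in blood (6.7%)
lART: 43/120 gut clones found in blood (35.8%)
simulated lART vs eART sharing: 35.8% vs 6.7%, Fisher p = 2.83e-08
published sharing table 33/99 vs 6/101:  p = 6.93e-07
published polyreactive table 12/99 vs 1/101: p = 0.0012
clean limit (n = 3505 members): ARI 1.000, V/J exact 100.0%, mutation counts exact 100.0%
mutation-mean recovery: max relative error 1.37% over 8 strata
sharing recovery: eART 4.66% (configured 4.9), lART 33.14% (configured 33.3), exact in all replicates: TRUE
null rejection at alpha 0.05: Welch 0.052, Fisher 0.047
```

The sharing comparison recovers the configured group difference, and the
two published 2×2 tables reproduce their printed p-values (p < 0.0001
and p = 0.0012). The mutation means per group/compartment printed by
stage 03 track the configured stratum targets (20.5–22.0 gut,
18.4–19.8 blood).

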