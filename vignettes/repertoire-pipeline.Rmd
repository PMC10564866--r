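---
title: "Methods: gut and blood B-cell repertoire analysis with repgut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut and blood B-cell repertoire analysis with repgut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

repgut analyses immunoglobulin heavy-chain (IGH) repertoires sampled from
two body compartments (gut mucosa and peripheral blood) of two donor
groups - individuals who started antiretroviral therapy early (eART)
versus late (lART) in HIV-1 infection. The pipeline takes paired-end
amplicon reads (or pre-merged sequences), assigns germline V and J
segments and the isotype, extracts the CDR-H3, counts somatic
hypermutation (SHM), removes low-quality rearrangements, collapses
near-duplicate reads, groups sequences into clonal families, builds
single-nucleotide mutation networks, compares repertoire features between
groups, detects gut-derived clones inside the blood repertoire, and
scores antibody polyreactivity from ELISA and protein-microarray
readouts.

Because no public sequencing data accompany the study design this
package targets, every stage is validated against a synthetic repertoire
generator (`simulate_repertoire()`) whose defaults encode the study
conditions, and the package's empirical claims are exactly the ones its
tests and `scripts/acceptance.R` compute.

# The generative model

A repertoire is a set of clonal lineages. For each (group, compartment)
the generator draws `n_clones` clones; each clone has:

* a V and a J allele drawn uniformly from the packaged toy germline set
  (8 V alleles in 4 families, 4 J alleles, IGA/IGG constant segments);
* a random productive junction of 3-20 codons (no stop codons - the
  sequenced material is expressed antibody mRNA from sorted B cells);
* an isotype drawn from the compartment mix. The gut mix is 36% IgA vs
  22% IgG (renormalized to 0.62/0.38), the memory-compartment
  composition the analysis assumes; the blood mix is not pinned down by
  the study conditions and defaults to 0.5/0.5 as the package's choice;
* a polyreactivity flag with group-dependent probability (eART 0.188,
  lART 0.313);
* for gut clones, a probability of also seeding the blood (eART 0.049,
  lART 0.333). Blood members of a shared clone carry a junction variant
  with at most 10% amino-acid divergence, the limit at which the
  sharing rule still applies.

Members of a clone carry Poisson-distributed V-region substitution
loads whose means are the per-stratum study values:

| stratum | eART | lART |
|---|---|---|
| gut IgA | 20.5 | 21.4 |
| gut IgG | 22.0 | 21.9 |
| blood IgA | 18.4 | 19.8 |
| blood IgG | 19.8 | 18.9 |

Mutation positions are uniform over the V region excluding the anchor
cysteine codon, and a fraction of each member's load comes from a
clone-shared pool, giving lineage structure. Mutated bases that would
create an in-frame stop codon are resampled (functional selection: an
expressed memory B cell cannot carry a nonsense V region); the mutation
*count* is unaffected. The model is substitution-only - the network
stage defines edges by single non-indel differences, and indels are out
of scope throughout.

Junctions are rejection-sampled to be below 70% amino-acid identity to
any other clone in the same (V gene, J gene, length) bucket. This makes
the generative partition identifiable by the 0.8 clonal-family rule and
the 0.9 sharing rule: without it, rare junction collisions would make
"exact recovery" an ill-posed target. Clone sizes (per-member duplicate
counts) follow a discrete power law with exponent 2.5 by default; the
study reports narrowed and broad expansions without stating a law, so
the exponent is a modelling choice, not a claim about the data.

What the simulator does *not* emulate: insertion/deletion sequencing
errors, chimeric amplicons, primer artefacts, allele-level germline
polymorphism beyond the toy set, light chains, and the true clone-size
law of the biological repertoires. Passing the clean-limit tests
therefore demonstrates algorithmic correctness of each stage under the
stated model, not numerical parity with the original figures.

# Stage conventions and parameters

**Merging.** Reads overlap by at least 10 nt (`min_overlap`); the
overlap offset maximizes matches subject to a 25% mismatch cap; within
the overlap the higher-quality base wins (tie: forward read) and gets
the maximum of the two qualities. Terminal bases under Q20 are trimmed
from both ends, and merged sequences under 300 nt are dropped
(`merge_params()`). The merge replaces an external assembler with a
maximal-matching overlap rule; parity with any particular assembler is
not claimed, only the exact round trip on error-free simulated pairs.

**Alignment and E-values.** All segment assignment uses affine-gap
Smith-Waterman with match +1, mismatch -2, gap open -5, gap extend -2
(a gap of length $k$ costs $5+2k$). E-values follow Karlin-Altschul
statistics $E = K m n e^{-\lambda S}$ with the standard ungapped
parameters for this scheme over uniform base composition,
$\lambda = 1.3327$ (the root of $0.25e^{\lambda}+0.75e^{-2\lambda}=1$)
and $K = 0.621$; $m$ is the query length and $n$ the summed V-reference
length. Any calibrated monotone transform of the score preserves the
behaviour of the E-value filter; fixing the scheme makes the threshold
reproducible. The default call floor is a bit score of 20. At this
search space that floor sits at $E \approx 1$, i.e. at the random-hit
noise peak, so a shuffled query may still receive a nominal V call -
it is then removed by the E-value QC filter ($E > 10^{-3}$), which is
the filter that actually defines membership in the repertoire.

**CDR-H3 convention.** The CDR-H3 runs from the codon after the
V-anchored Cys104 to the codon before the J-anchored tryptophan of the
W-G-x-G motif - anchors excluded. The choice is convention-stable for
"same CDR-H3 length" groupings; an anchor-inclusive convention would
shift every length by two but change no grouping.

**Mutation counting.** V mutations are mismatches over the V alignment
*extended ungapped to the germline ends* where the query covers them.
A purely local count would silently drop substitutions in the first or
last positions of the V (the local optimum trims terminal mismatches),
which would bias the count low by up to ~1 mutation at SHM 20; with
the extension the clean-limit recovery of planted counts is exact.
Query N positions never count as mutations. The frequency is per 100
aligned V nucleotides and is independent of duplicate counts.

**QC.** A record is rejected iff it is unproductive (stop codon in the
V-anchored frame through the motif), has V E-value above $10^{-3}$,
lacks an intact W-G-x-G motif, or its V alignment starts after germline
position 9. All triggered flags are recorded. Note that under heavy SHM
the subject-start filter has a genuine ~0.5-1% false-rejection rate on
simulated data: a cluster of mutations in the first V codons makes the
optimal local alignment start past position 9. This is inherent to the
filter as stated, and the clean-limit experiment reports the pass
fraction alongside the exactness measures.

**Dereplication (99%).** Greedy incremental clustering in decreasing
(duplicate count, length, id) order; a record joins the first cluster
whose seed it matches at >= 99% global identity, defined as
matches / alignment length of a Needleman-Wunsch alignment under match
+1, mismatch -1, gap -2 with diagonal-preferring traceback. The
production path uses a banded decision ("identity at least t?") whose
band width is derived from the threshold - any alignment reaching
identity $t$ has at most $(1-t)(|a|+|b|)$ gap columns, so the band is
sound - with borderline accepts confirmed by the exact DP. Tests compare
the whole clustering against a naive greedy oracle.

**Clonal families.** Sequences are bucketed by (V gene, J gene, CDR-H3
amino-acid length) with allele suffixes stripped (SHM routinely obscures
allele identity), then single-linkage connected components under CDR-H3
identity >= 0.8. The 0.8 figure is read as a *similarity* cutoff: a
distance reading would merge near-unrelated junctions, contradicting
the purpose of the rule. Single linkage implements the transitive
"grouping" semantics. Family ids are content hashes of the sorted
member ids, so output is order-invariant.

**Networks.** Vertices are unique sequences sized by duplicate count;
edges connect equal-length pairs at Hamming distance exactly 1. The
implementation scans length groups with early-exit comparisons and is
tested against the all-pairs brute force.

**Sharing.** A gut monoclonal matches a blood NGS record iff V gene and
J gene are identical, CDR-H3 lengths are equal, and CDR-H3 amino-acid
identity is >= 0.90. Length equality is required because homology
between different-length junctions is undefined without an indel model,
and clonal relatives share junction length. Isotype is deliberately not
part of the rule - shared clones appear under both IgA and IgG.

**Statistics.** Categorical repertoire parameters use the two-sided
Fisher exact test with the probability-at-most-observed rule, computed
exactly in log space from the hypergeometric mass function; continuous
parameters use Welch's t (Satterthwaite degrees of freedom). The
volcano significance flag is the *unadjusted* p < 0.05, matching how
such panels are usually displayed, with Benjamini-Hochberg adjusted
values reported alongside rather than instead. Correlation matrices
report pairwise Pearson r and p over pairwise-complete observations,
BH-adjusted p-values, and the largest raw p passing BH at q = 0.05.
CDR3 charge is (#R + #K) - (#D + #E); histidine is excluded (neutral-pH
convention).

**Reactivity.** ELISA curves are integrated by the trapezoid rule over
log10 concentration with negative ODs clamped at zero; the cumulative
AUC is $\log_{10}(\sum \text{AUC} + 1)$, the +1 offset pinning the
zero-binding antibody at 0 (the handling of zero AUC is not otherwise
specified). Microarray Z-scores are robust per-array scores
$(x - \text{median})/(1.4826\,\text{MAD})$ after averaging duplicate
spots; the polyreactivity index is the fraction of proteins whose
diagonal deviation $\sigma_i = (Z_{test,i} - Z_{ref,i})/\sqrt 2$
exceeds 2, with the strict classification rule PI > 0.21. The PI
functional form is a declared reconstruction of a score defined in
proprietary software: it preserves the scale (PI in [0,1]) and the
printed threshold semantics, but numerical parity with the original
scoring software is not claimed.

# Validation experiments and problem sizes

The packaged experiments (also driven by `analysis/08_validation.R`)
pin the pipeline to its generative truth at the following sizes, chosen
so the full suite completes in minutes on a single core:

* **Clean limit** (`run_clean_limit_experiment`): 200 clones per
  (group, compartment), SHM mean 20, error-free reads; ~3,500 members.
  Asserts lossless merging, exact V/J calls, exact junctions, exact
  mutation counts, and adjusted Rand index 1 between inferred families
  and true clones.
* **SHM recovery** (`run_shm_recovery_experiment`): 2,900 clones per
  (group, compartment) with a heavier-tailed clone-size law (exponent
  2.3) so that each of the eight strata carries at least 10,000
  duplicate-weighted sequences - the per-sequence mean the study
  reports is a duplicate-weighted mean over unique sequences. Recovered
  stratum means land within 5% of the configured targets (observed
  maximum relative error ~1.5%).
* **Sharing recovery** (`run_sharing_recovery_experiment`): 50
  replicate simulations, 100 gut-clone mAbs per group each, at the
  configured sharing fractions 0.049/0.333. The matcher recovers
  exactly the truly shared clones in every replicate; recovered
  frequencies are checked against the binomial sampling band around the
  configured fractions. Residual deviation at this scale is generative
  binomial noise, not matcher error.
* **Calibration** (`run_calibration_experiment`): 1,000 null
  replicates. Welch rejects within the 3-SE binomial band of 0.05;
  Fisher, being exact and discrete, is conservative - it must not
  exceed the nominal level but may fall below it, which the test
  encodes (large per-group counts keep the discreteness mild).

# Known limitations

* The toy germline set is synthetic; real-data parity (IMGT alleles, D
  segments, allele-level calls) is out of scope. D segments are not
  assigned - the clonal rule needs only V, J and CDR-H3.
* The merge stage is not an assembler-parity reimplementation; its
  contract is the clean-limit round trip and the stated thresholds.
* Light chains enter only through pre-annotated single-cell tables in
  the feature panel; they are never aligned.
* The subject-start QC filter interacts with dense 5' SHM as noted
  above; on real data the same trade-off applies to the original
  filter.
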