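---
title: "Methods: the segmentation test on evolutionary-rate rankings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the segmentation test on evolutionary-rate rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gssa)
```

## The model and its assumptions

The package detects functional modules — sets of genes sharing an annotation —
whose members are not spread evenly across a genome-wide ranking of an
evolutionary variable but skewed toward one extreme. The variables are the
outputs of a free-ratio branch codon model: per-gene, per-branch dS, dN,
ω = dN/dS, and Δω = ω − ω of the ancestral branch. The test itself is purely
rank-based: once genes are ordered, the values play no further role, so no
distributional assumption is made about the rates beyond exchangeability of
genes under the null.

The procedure runs in five stages:

1. **Rank** all genes of the genome by the chosen variable, highest first.
2. **Annotate** each gene with its functional terms (a gene may carry many).
3. **Partition** the ranked list at P evenly spaced cuts,
   `cut_k = ⌊k·N/(P+1)⌋`, k = 1..P.
4. **Test** each (term, partition) pair with a two-tailed Fisher's exact test
   on the 2×2 table of term/non-term genes above/below the cut.
5. **Correct** all C×P p-values of the run jointly with Benjamini–Hochberg,
   and classify each term from its minimum q-value: SH if over-represented
   above its best cut, SL if below, NS if no partition reaches the 5% tier.

The joint C×P family is deliberate: partitions of one term are strongly
dependent, and correcting them together with all other terms reproduces the
published protocol exactly. The family size actually used (after any cut
de-duplication) is logged by `run_pipeline()` because it is the least obvious
reproducibility-critical quantity.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_partitions` | 30 | cuts | 20–50 partitions give near-optimal sensitivity for genome-scale lists; 30 is the published setting. |
| `min_set_size` | 15 | genes | terms smaller than 15 genes (counted against the ranked universe of the run) are too unstable for a 2×2 exact test at these FDR tiers. |
| `level_window` | none (2–8 typical for mammal GO, 2–12 for insects) | DAG levels | removes near-root terms that are trivially huge and leaf terms that fail the size rule anyway. |
| `fdr_tiers` | 0.001, 0.05 | FDR | the strict and loose significance tiers reported as `**` and `*`. |
| saturation rules | `primates` 0.064/0.030, `rodents` 0.256/0.122, `primates_rodents` 1/0.5 | dS, dN subst./site | exclusive upper bounds beyond which rate estimates are considered saturated; a record is excluded when **either** bound is reached (conservative reading of an ambiguous exclusion clause). |
| `min_aln_bp` | 100 | bp | alignments shorter than 100 bp give unreliable rate estimates. |

## Numerical conventions

- **Two-sided Fisher p**: minimum-likelihood convention — the sum of
  hypergeometric point probabilities not exceeding that of the observed
  table, with the customary `1 + 1e-7` relative tolerance guarding
  floating-point ties. This matches `stats::fisher.test`, against which the
  implementation is verified to `1e-12` over every 2×2 table with total ≤ 40.
- **Odds ratio**: the sample odds ratio `ad/bc` with `0/0 → 1`, `x/0 → ∞`
  (reported, not used for inference).
- **Ranking ties**: stable descending sort with a lexicographic gene-id
  tie-break, recorded in the `ranked_list`, so runs are byte-reproducible
  across platforms.
- **dS = 0**: ω is undefined and left missing (not ∞); such genes are
  excluded from ω and Δω rankings and counted. Free-ratio estimates with
  dS = 0 are numerically unstable and no published rule covers them.
- **Best partition ties**: lowest q, then lowest partition index.
- **Duplicate cuts**: under the enforced precondition N ≥ P+1 the floor
  formula cannot produce duplicates; the collapse rule exists as a defensive
  contract only.
- **GO level**: shortest-path depth from the root, root = level 1
  (`level(t) = 1 + min(level(parents))`). Whether the original annotation
  tooling used shortest or longest paths is not recoverable; the window
  bounds are configuration, only the convention is fixed, and it is stated
  here so users can reproduce any window.
- **"Contributing genes"**: the fraction of a term's genes on the enriched
  side of the *first* significant partition. The notion is not formally
  defined in the literature this implements; this operational definition
  reproduces how the quantity is described alongside published summaries.

## The synthetic world

`simulate_rates()` emulates a genome-scale free-ratio run on a mammal-like
branch: dS ~ Gamma(shape 3, rate 30) (mean 0.1) and dN ~ Gamma(shape 1.5,
rate 75) (mean 0.02), independently per gene, with an independently drawn
ancestral branch so Δω is exercised. ω = dN/dS is then right-skewed and
mostly below 1, as in real purifying-selection-dominated genomes. dS shape 3
keeps 1/dS square-integrable, so the sample standard deviation of ω — the
unit in which planted effects are expressed — is stable. These defaults were
chosen once, before any calibration was run, and are not tuned.

What the generator does **not** emulate: correlation between dS and dN along
a gene (they are independent here), gene-length effects on estimation noise,
phylogenetic correlation between branches, and annotation structure (terms
are random draws unless planted). A green test on this world therefore
establishes the statistical behaviour of the ranking-and-segmentation
machinery, not the biological fidelity of any particular rate table.

`plant_modules()` shifts the ranking variable of a module's genes by
`effect × sd(background)` — upward for SH, downward for SL — which is the
minimal mechanism producing the rank skew the test detects, keeping ground
truth unambiguous. Shifts act on the named variable and dependent columns
are recomputed (shifting ω rescales dN = ω·dS, etc.) so tables stay
internally consistent. Downward shifts are clamped at 0 for non-negative
variables, leaving those genes tied at the bottom of the ranking — the
extreme the test should find. Negative-control terms are drawn at random
with sizes matched to the planted-size distribution, so size is not a
confound in recovery reports.

## Calibration and what the tests establish

`false_positive_scan()` permutes the gene↔annotation assignment with a
uniformly random gene-label bijection — preserving every term's size and the
overlap structure between terms, the closest reading of "randomizing the
original assignment" — and reruns the full analysis per replicate. On 5,000
genes, 100 terms of sizes 20–1,400 and 200 replicates, the overall fraction
of (term, replicate) pairs called significant at 5% FDR is ≈ 0.02–0.03%,
two orders of magnitude below the 5% tier and well below the 0.5% bound
reported for the published 10,000-replicate experiment: under the global
null, Fisher discreteness plus the joint BH family make the procedure
strongly conservative, regardless of term size and of the shape of the rate
distribution (verified with gamma, lognormal and uniform backgrounds).

## Design choices where the design was open

- **Partition placement** is unspecified beyond "P partitions along the
  list"; evenly spaced rank cuts are the simplest scheme consistent with the
  numbered-partition presentation and the segmentation-test lineage.
- **Saturation AND/OR**: the printed exclusion clause joins the dS and dN
  bounds with "and"; excluding when either bound is met is the conservative
  reading and is what ships.
- **Randomization null**: a gene-label bijection, not per-term resampling
  (which would destroy term overlap).
- **Classification partition**: verdicts use the best (minimum-q) partition;
  the first significant partition is recorded alongside, so either
  convention in published summaries can be reconstructed.
- **Reversal symmetry** of SH/SL holds exactly when (P+1) divides N, because
  only then is the floor cut grid mirror-symmetric; for general N the
  reversed run's cuts are offset by one rank and q-values may differ in the
  last decimal places. Tests pin the exact symmetry at N = 31k.
- **DAG input** is a child→parent edge list rather than full OBO parsing;
  full relationship typing is out of scope.

## Known limitations

- **Term-level FDP under strong signal.** BH over the joint C×P family
  controls the FDR of *tests*, not of *terms*. A genuinely shifted term
  contributes up to P ≈ 30 near-zero p-values, which raises the BH step-up
  threshold; every null term then has ~30 correlated partition tests as
  chances to cross it, and the per-term minimum-q selection is itself
  uncorrected. Consequently, when a large fraction of the family carries
  real signal (as in planted-module power grids with matched controls), the
  term-level false-discovery proportion is measured at ≈ 8–12% despite the
  5% test-level tier. In realistic genome-wide runs, where significant terms
  are a modest fraction of 1,000+ terms, the inflation is correspondingly
  smaller; under the global null the procedure is strongly conservative (see
  calibration above). Users comparing few, strongly contrasted gene sets
  should interpret borderline 5%-tier calls cautiously or tighten to the
  0.1% tier.
- A single test family per run: the package does not attempt cross-run
  (multi-species, multi-variable) joint correction; the summary matrix is
  descriptive.
- PSG flags are consumed, not computed; the Welch t-test comparing PSG
  counts between SH and SL modules inherits whatever upstream calling
  produced the flags.
- The generator's independence assumptions mean power estimates transfer to
  real data only qualitatively.
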