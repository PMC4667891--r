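---
title: "Mutation signatures from independent features: model and methods"
author: "featsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation signatures from independent features: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featsig)
```

## The model

A somatic substitution is described by a vector of L discrete *mutation
features* `m = (m1, ..., mL)`: the substitution type (six values after
pyrimidine normalization: C>A, C>G, C>T, T>A, T>C, T>G), the flanking
bases at offsets −n…−1 and +1…+n (four values each), and optionally the
transcription strand (+/−). `buildFeatureSpace(nFlank, includeStrand)`
fixes this feature order and the per-feature cardinalities
`M = (M1, ..., ML)`.

Each of K latent mutational processes ("signatures") is a set of
per-feature probability vectors `F_k = (f_k1, ..., f_kL)`, and each sample
i carries membership proportions `q_i` on the K-simplex. A mutation in
sample i is generated by drawing its process `z ~ Multinomial(q_i)` and
then every feature independently, `Pr(x_l = m | z = k) = f_klm`. The
independence assumption is the point: it reduces the per-signature
parameter count from `prod(M) - 1` (the unconstrained "full model", which
the package also fits as the single-meta-feature special case) to
`sum(M - 1)` — 18 instead of 3,071 for substitution ± 2 flanks + strand —
in exact analogy to a position weight matrix for binding motifs. It cannot
represent within-signature dependencies between features (e.g. "C>A at
ApC**G** but C>T at TpC**A**" as *one* process); such structure surfaces
instead as additional signatures.

### Pyrimidine normalization and the strand feature

Substitutions are recorded with the original base fixed to C or T: when
the reference base is a purine, ref/alt are complemented and the context
reverse-complemented (`flipped`). With the strand feature enabled, a
mutation inside a gene gets "+" when the normalized (pyrimidine) base lies
on the coding/untranscribed strand and "−" on the template strand, i.e.
gene strand XOR flip. Intergenic mutations are dropped in this mode, as
are mutations covered by genes on both strands — the annotation cannot say
which transcription direction applies, so we prefer a documented DROP over
an arbitrary choice.

### The background signature

Genome composition (e.g. CpG depletion) would otherwise leak into the
estimated signatures. `backgroundFromSequences()` builds a fixed
full-dimensional component F₀ from the (2n+1)-mer composition of
user-supplied sequence: windows are tallied after pyrimidine
normalization of the central base (flipping any strand label in the
process), the three alternate bases are assumed equally likely given each
central base, and frequencies are normalized to a distribution. When
strand is tracked, the strand share comes from the per-orientation k-mer
tallies themselves; the package takes arbitrary sequences (an exome
BED × FASTA, or synthetic genomes) rather than bundling a reference.
`uniformBackground()` is a neutral built-in. During fitting F₀ is mixture
component 0: its pattern distribution is never updated, only its
membership weight.

## Estimation

With `g_im` the count of pattern m in sample i, EM alternates:

* E step — responsibilities
  `theta_ikm = q_ik Pr(m|k) / sum_k' q_ik' Pr(m|k')`;
* M step — `f_klp` proportional to the responsibility-weighted count of
  feature value p *summed over samples and patterns*, and `q_ik`
  proportional to the weighted count per sample. (The sum over samples in
  the f-update is the standard complete-data maximum-likelihood step.)

Implementation notes, all asserted by tests:

* **Restarts.** The likelihood is multimodal; `fitSignatures()` runs
  `nRestarts = 10` random restarts (memberships and signature vectors from
  symmetric Dirichlet(1)) and keeps the best, with the whole restart
  sequence driven by one seed.
* **Convergence.** Relative log-likelihood improvement below `tol = 1e-8`
  or `maxIter = 10000`. The plain-EM trace is non-decreasing by
  construction; non-convergence is flagged in metadata, not an error.
* **Acceleration.** `accelerate = TRUE` applies a SQUAREM-style squared
  extrapolation of the parameter vector (two EM steps, extrapolate with
  step length −|r|/|v|, one stabilizing EM step) with a monotonicity
  safeguard: whenever the extrapolated likelihood falls below the plain
  two-step value, the plain step is taken. Extrapolated parameters are
  clamped at 1e-10 and renormalized per block. Accelerated and plain runs
  agree on the final log-likelihood to well under 1e-6 on fixed-seed
  instances.
* **Degenerate cases.** A component receiving (numerically) zero total
  responsibility is re-initialized with a warning; samples that carry no
  mutations get uniform memberships (they contribute nothing to the
  likelihood); responsibilities are computed from products of per-feature
  probabilities, which for L ≤ 13 cannot underflow meaningfully, and no
  pseudo-counts are added unless requested (`pseudocount`).
* **Label switching.** Fits are returned unordered; every comparison
  (bootstrap replicates, down-sampling refits, truth in simulations) goes
  through `matchSignatures()` — greedy maximal cosine matching by default,
  exact permutation assignment (K ≤ 8) by flag.

## Uncertainty and model selection

`bootstrapSE()` implements the non-parametric bootstrap: mutations are
resampled with replacement within each sample (J_i preserved, a
multinomial draw on the sample's empirical pattern distribution), the
model is refitted warm-started at the original estimates, components are
matched back by cosine, and SEs are the across-replicate standard
deviations. The default is B = 100 replicates.

`kSelectionReport()` fits a range of K and reports log-likelihood, mean
bootstrap SE and the largest off-diagonal Pearson correlation between
membership columns. Strongly correlated memberships combined with similar
signatures indicate one process split in two. The report deliberately
never picks K: the selection strategy is manual (likelihood high, SEs low,
no duplicated-signature pair), and no quantitative thresholds are imposed
because none are established.

`mergeSignatures()` pools fits from several cohorts and clusters their
signatures by single linkage on the Frobenius distance
`sqrt(sum((F1 - F2)^2))` of the parameter matrices, merging chains whose
linkage distance is strictly below the 0.6 threshold. The distance is on
the square-root (metric) scale, which is what makes the printed threshold
behave like a distance. The consensus of a cluster is the
mutation-count-weighted average of the members' per-feature vectors,
renormalized per feature — a package choice, since no consensus rule is
canonical.

## The simulator

`simulateCatalog()` draws from exactly the generative model above:
memberships from Dirichlet(alpha), process labels per mutation, features
per process (equivalently, patterns from the expanded product
distribution), optionally a fixed-weight background component. True
signatures can be supplied or drawn with per-feature Dirichlet
concentration `gamma / M_l` (`gamma` around 0.3 gives sharp,
well-separated signatures; large `gamma` approaches uniform).
`simulateGenome()`, `simulateAnnotation()` and
`simulateMutationPositions()` additionally generate a random reference,
strand-annotated gene intervals, and mutation *position* records whose
extracted patterns follow a planted signature mixture — so the whole
extraction path (FASTA context lookup, pyrimidine normalization, strand
assignment) is testable end to end without any external data.

What the simulator does *not* emulate: real genomes are compositionally
biased, mutation rates vary along the genome, signatures co-occur with
correlated activities, and real catalogs contain artifacts and non-SNV
events. Passing recovery tests therefore demonstrate correctness of the
estimator under its own model, not robustness to model misspecification.

`downsampleCatalog()` retains `round(r * total)` mutations uniformly
*without replacement* (a multivariate hypergeometric draw over catalog
cells); sampling without replacement is the natural reading of "keep r% of
the data" and is verified against a record-level resampling oracle.
`downsamplingExperiment()` refits on each down-sampled catalog from fresh
random restarts (warm-starting at the gold fit would mask exactly the
instability the experiment measures) and reports matched cosine
similarities to the gold-standard fit.

## Numerical and design choices

* Pattern encoding is mixed-radix with the substitution varying slowest,
  then flanks −n…+n, then strand; 1-based throughout. All serialized
  files are label-keyed (`"AA[C>A]TG,+"`), never integer codes, so the
  internal order is free to change.
* Simplex validation tolerance is 1e-6; expanded signatures sum to 1
  within 1e-9.
* Logo box heights use `1 + 0.5 * log2(sum(f^2))` — one minus half the
  order-2 Rényi entropy in bits, 0 for uniform-over-4 and 1 for a point
  mass. The logarithm base is configurable (`base =`), but base 2 is the
  default because it is the only base for which the endpoints take these
  clean values.
* Chromosome names are matched exactly (no "chr" aliasing); reference
  mismatches are dropped and tallied by default and fatal under
  `strict = TRUE`.
* Merging ties: signatures at exactly the threshold distance do *not*
  merge; cluster order and member order are lexicographic in
  (group, signature), making the output independent of input order.

## Problem sizes in the shipped tests

The test suite works at desk scale, chosen so the full suite runs in
about half a minute while each property still has power: brute-force EM
oracles on I ≤ 5 samples and ≤ 200 mutations over the 96-pattern space;
recovery of K = 3 well-separated signatures (pairwise cosine < 0.5) from
I = 30 samples × 500 mutations across 20 seeded replicates; a
down-sampling experiment on a 2-signature ±2+strand catalog of ~14,700
mutations over 26 samples with 20 repetitions per ratio; bootstraps at
B = 50 where distributional behaviour is asserted and B = 100 kept as the
interface default.

## Limitations

Single-base substitutions only (no indels, doublets or structural
variants); no mutation-opportunity weighting beyond the fixed background
component; maximum-likelihood point estimates (no posterior over K or
signatures); the independence assumption itself, which trades
within-signature feature dependence for stability and readability.
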