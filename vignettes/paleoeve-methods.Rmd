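---
title: "Authenticating and dating ancient endogenous viral elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating and dating ancient endogenous viral elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Endogenous viral elements (EVEs) are remnants of ancient viruses fixed in
host germlines. When the *same* insertion is found at the *same* genomic
position in many species — orthology, established through the conserved
order of flanking host genes (synteny) — the insertion must predate their
common ancestor. The age of the most recent common ancestor (MRCA) of all
carrier species is then a lower bound on the insertion age, and a
node-calibrated molecular clock applied to the element sequences themselves
can push the element's own ancestry even deeper. Because such elements are
typically dead (no selection), their divergence should match that of the
surrounding noncoding DNA; testing that assumption is part of
authentication.

`paleoeve` implements this whole chain of reasoning as testable components:

1. **synthetic genomes** with known ground truth (insertion branch, ages,
   losses, lesions) to validate everything end to end;
2. **translated homology search** (tBLASTn-style) with Karlin–Altschul
   statistics and annotation of inactivating mutations;
3. **synteny-anchored presence calling** between flanking landmark genes;
4. **alignment utilities** (MAF slicing/stitching, profile merging,
   trimming, p-distances);
5. **node-calibrated Bayesian dating** (GTR+Γ pruning likelihood,
   Metropolis–Hastings MCMC, HPD/ESS summaries);
6. **a neutrality test** against resampled noncoding null regions;
7. **a pipeline** tying the stages together reproducibly.

# The synthetic-data generator

The generator emulates a mammalian locus carrying two paralogous
integrations of a large DNA virus (a *Maverick*/Polinton-like element):

* A calibrated, ultrametric 12-taxon host tree (`default_host_newick()`)
  with ten placental-like carriers (crown age 102 My), a marsupial-like and
  a monotreme-like outgroup (splits at 172 and 187 My) — TimeTree-style
  ages.
* An ancestral locus: three landmark protein-coding genes on each side,
  intergenic spacers (default 6 kb, a conservative mammalian intergenic
  scale), and the element itself: nine core genes (polymerase POLB at
  1,053 aa, integrase, ATPase, protease, minor/major capsid and four
  accessory genes) between terminal inverted repeats.
* Neutral decay at 0.0027 substitutions/site/My — the pangenomic mammal
  rate — under GTR+Γ4 (mammal-like exchangeabilities, base frequencies
  A/T 0.295, C/G 0.205, shape α = 1), with lognormal per-branch rate
  multipliers (default σ = 0.1, mild lineage effects) and indels at 0.1
  events per substitution with geometric lengths (mean 3 nt).
* **Pre-insertion constraint.** Until the insertion age the element was a
  functional viral genome: its genes evolve like the landmark genes
  (rate scale 0.15, no indels). Neutral decay — substitutions, indels,
  the stops and frameshifts the annotation later recovers — starts at the
  insertion. Without this the deep pre-insertion history would shred
  reading frames far beyond what detectable real elements show.
* Landmark (host) genes evolve at 0.15× the neutral rate throughout,
  emulating purifying selection; indel placement is weighted by the same
  per-site scale, so constrained features are spared indels as well as
  substitutions.
* Gene codons are drawn from the sense codons weighted by the stationary
  base frequencies, so coding and noncoding regions share base
  composition and the neutrality test compares like with like.
* Lineage losses excise the element (flanks joined) independently per
  carrier with a configurable probability.

Every stochastic step derives its own seed from one explicit global seed
(`derive_seed()`), so a dataset is byte-identical under a fixed seed and no
hidden global RNG state leaks between stages.

What the generator does *not* emulate: chromosome-scale context,
transposition/copy-number dynamics, selection on element genes after
insertion, rearrangements, and assembly artifacts. Passing tests therefore
demonstrate correctness of the analysis machinery under the stated model,
not robustness to assembly error or complex real-genome structure.

# Translated homology search

Protein probes are searched against all six reading frames (stops translate
to `*`, fuzzy codons to `X`) under BLOSUM45 with affine gaps (open 14,
extend 2) — the standard choice for distant homology. The engine is
seed-and-extend: word-size-2 neighborhood seeds (score ≥ 11), two-hit
seeding on a diagonal within 40 positions, ungapped X-drop extension
(X = 20), and a windowed gapped Smith–Waterman around anchors that reach
half the reporting score cutoff, with the window grown while the alignment
touches its boundary. Nested or mostly-overlapping lower-scoring alignments
are culled.

Two deliberate design points:

* **Small-input exactness.** Seeding is a sensitivity heuristic that only
  pays off on large subjects. For frames whose dynamic-programming area is
  below `exhaustive_area` (default 250k cells) the engine runs the exact
  full Smith–Waterman instead. Word-2/threshold-11 seeding provably cannot
  reproduce every optimum of *random* weak alignments (an optimal alignment
  need not contain any word pair scoring ≥ 11); on planted-homology
  inputs — the regime seeding is designed for — the seeded path matches the
  exact search, and the tests assert both properties separately.
* **Stops are signal.** `*` in a translated frame is scored by the
  matrix's `*` column (−5 against every residue) but never forbidden: in
  degraded elements in-frame stops are exactly what we want inside
  alignments, where the annotation step reads them off.

E-values follow Karlin–Altschul, `E = K m n exp(−λS)`, with λ solved
exactly from the ungapped equation under Robinson–Robinson backgrounds and
the gapped regime approximated by configurable constants (λ scaled by 0.9,
K = 0.05); every E-value is labelled with its regime. The exact lattice
computation of ungapped K (and island statistics for gapped K) is out of
scope; since E enters only through thresholds spanning orders of magnitude,
a constant-factor K is adequate and is documented as such.

**Inactivating mutations.** Premature stops are reported at the
forward-strand start of their codon, read directly off HSP subject
translations. Frameshifts are inferred between chained HSPs in different
frames; the breakpoint is refined by a codon-resolution changepoint scan:
the probe↔codon correspondence is anchored on aligned pairs *outside* the
junction zone (local alignments overshoot junctions by tens of codons) and
each candidate breakpoint is scored as upstream-frame codon scores before
it plus downstream-frame scores after it, leftmost maximum on ties. The
breakpoint is identifiable only to codon resolution; the constructed test
cases (`plant_frameshift_case()`) therefore plant lesions whose disrupted
and junction codons both mismatch the probe, making the planted coordinate
the unique optimum.

# Synteny and presence calls

Orthologous regions are anchored by the innermost located landmark genes
(pad 0 by default); with a single-sided anchor the region extends by
3 × 1,053 nt (the assumed ancestral polymerase length). Presence requires
at least one core-protein hit group at E < 1e−5 inside the region (a
stricter two-probe mode is available); **absent is only called when both
innermost landmarks were located and the intervening region searched** —
otherwise the call is ambiguous, so assembly gaps cannot masquerade as
loss. An alignment-based second method (non-gap coverage of the element's
columns, the synthetic stand-in for a whole-genome-alignment screen) is
compared against the hit-based calls; discordances are reported, never
reconciled. On degraded copies the expected direction is alignment-present
/ hits-absent, the classic signature of divergence beyond BLAST's reach.

# Calibrated Bayesian dating

The dating model fixes the topology: each locus contributes a clade
mirroring the host tree restricted to its carriers (orthologous insertions
track host phylogeny), joined at a root representing the element ancestor
(the paralogue split). Topology search is out of scope. The likelihood is
Felsenstein pruning under GTR+Γ4 (pattern-compressed, rescaled, in C++);
TVM — the model selected for the real data by information criteria — nests
inside GTR. Protein-mode dating is supported through
`empirical_model()` with a user-supplied 20-state exchangeability matrix;
no third-party matrix is bundled.

Priors: normal calibrations on clade ages (means at host divergence times;
the synthetic experiments use sd = 2 My); uncalibrated node ages flat
within their ordering constraints; root age uniform between the oldest
calibration mean and 500 My; clock rate lognormal with median 0.003
substitutions/site/My and log-sd 1 (diffuse); GTR exchangeabilities
exponential(1) with GT fixed at 1; frequencies flat on the simplex; Γ
shape lognormal(0, 1.5); relaxed-clock branch multipliers lognormal with
mean 1 and fixed σ.

Moves: node-age uniform slides within (oldest child, parent) bounds,
reflected root-age slides, multiplicative scales on rate/shape/
exchangeabilities, frequency transfers, and branch-multiplier scales.
Step sizes auto-tune toward ~30% acceptance during burn-in (capped, then
frozen); bounded-uniform age slides need no tuning. Summaries report the
posterior mean, median, shortest 95% HPD (which by construction contains
at least 95% of post-burn-in samples) and ESS via the initial positive
autocorrelation sequence. An antithetic (negatively autocorrelated) trace
is *not* penalized by this estimator — that is the statistically correct
behavior, since such traces estimate means better than iid draws.

**Desk-scale settings.** The validation experiments run two loci × ten
carriers with 600-site markers and chains of 12k–20k proposals sampled
every 15–20 (burn-in 25%) — the package's own choice of problem size for
routine validation; real analyses should scale the chain up by orders of
magnitude (production relaxed-clock runs conventionally use 10⁷–10⁸
generations sampled every few thousand) and check ESS > 200 as usual. The age-recovery experiment simulates under the strict clock it
fits, the standard model-matched design for verifying coverage; the
relaxed clock is exercised separately. Calibrations in these experiments
sit at the true host ages, so crown-age coverage is largely prior-driven —
by design: it verifies that calibrated dating is internally consistent,
while root-age and rate recovery are data-driven checks.

**A deliberate model mismatch in the end-to-end simulation.** The locus
generator evolves the element's pre-insertion stem under purifying
constraint (the virus was functional until insertion), while the dating
model — like real analyses — assumes a single clock rate over the whole
element tree including that stem. The pipeline's root (paralogue-split)
age estimate on such data is therefore a systematic *underestimate* of
the generator's nominal split age; this mirrors the instability of deep
root estimates on real data, where nucleotide- and protein-based
estimates of the same node can differ twofold. Model-matched root
recovery is validated separately with `simulate_dating_alignment()`,
which simulates directly under the fitted clock. The minimum insertion
ages (carrier crown nodes) are insensitive to this: they are anchored by
host calibrations and post-insertion data.

# The neutrality test

Pairwise p-distances (observed proportion of differing nucleotides,
pairwise deletion, ambiguity codes excluded — this artifact's declared
convention) are computed within the element region and within 100
noncoding null regions of identical length sampled uniformly from the
locus outside annotated features (overlap among null windows allowed).
The one-tailed statistic is `D+ = sup_t (F_eve − F_null)` for the
alternative "element distances stochastically smaller" — the purifying-
constraint signature; the direction is configurable.

Distances within a region are strongly dependent (all pairs share the
species tree), so the classical pooled-sample KS p-value is not
calibrated here. `neutrality_test()` therefore refers the element's
statistic to the empirical distribution of the same statistic computed
for each null region against the pool of nulls *not overlapping it*
(region-label permutation; the non-overlap rule keeps the element, which
never overlaps a null window, exchangeable with the nulls). The classical
asymptotic p-value is still reported for reference, and
`ks_test_one_tailed()` provides asymptotic, Monte-Carlo permutation and
exact-enumeration variants for iid-sample use.

piRNA-cluster overlap is a plain half-open interval intersection
(touching boundaries do not overlap).

# Numerical and engineering choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  human-readable reports (BLAST convention).
* Alignment trimming is deterministic gap-fraction filtering (default
  0.8) with a retained column map, replacing heuristic method selection.
* Traceback tie-breaking in the aligners prefers diagonal, then up (gap
  in subject), then left, making results deterministic.
* Pattern compression and per-node rescaling keep the pruning likelihood
  exact on deep trees; categories are combined by log-sum-exp.
* MAF rows keep their own-strand coordinates; clipping recomputes starts
  by counting removed non-gap characters, valid for either strand.

# Known limitations

* The search engine implements single-HSP Karlin–Altschul statistics only
  (no sum statistics, no composition adjustment); very fragmented homology
  below the single-HSP threshold goes undetected — mirroring the real
  phenomenon that highly diverged copies are found by whole-genome
  alignment but not by BLAST.
* Exhaustive mode reports one best alignment per frame.
* The region-permutation p-value has resolution 1/(n_null + 1).
* The dating model fixes the topology and assumes a single partition; it
  does not infer trees, select models, or run coupled chains.
* Synthetic genomes do not model assembly gaps, rearrangements or
  segmental duplication; ambiguity handling for those cases is exercised
  only through constructed unit tests.
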