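---
title: "phagekit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagekit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagekit)
```

phagekit implements the computational side of a lytic-phage
characterization study: pan-genome phylogenomics of a small cluster of
related phage genomes, kinetic parameter estimation from titer assays, and
statistical evaluation of phage–antibiotic combinations from plate-reader
OD~590~ kill curves. Every analysis stage has a matching synthetic-data
generator so that the whole pipeline can be exercised, and its estimators
validated against retained ground truth, at desk scale. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data do and do not establish
about behavior on real data.

## Pan-genome phylogenomics

### Ortholog clustering

`cluster_orthologs()` groups the proteins of a set of phage proteomes into
ortholog families. Large ortholog pipelines built on BLAST plus Markov
clustering (OrthoMCL-style, typically run at an e-value cutoff of 1e-5 and
an inflation of 1.5) are the field standard for this step; phagekit uses a
deterministic desk-scale formulation with no external binaries: all
candidate protein pairs are aligned globally (Needleman–Wunsch, match +2,
mismatch −1, linear gap penalty 2), an edge connects two proteins whose

* identity — defined as matches divided by **all** alignment columns, gap
  columns included in the denominator, because identity definitions vary
  and this one is the most conservative — reaches `min_identity`
  (default 0.5), and whose
* coverage — doubly-aligned columns over the length of the shorter
  sequence — reaches `min_coverage` (default 0.5),

and families are the connected components of that graph (single linkage,
the default) or greedily grown cliques in input order (`complete`).
Equal-length pairs are scored column-wise without gaps (at identities near
the threshold the linear-gap optimum of an equal-length pair is the
ungapped alignment); unequal-length pairs go through the full dynamic
program. A 6-mer prefilter — only pairs sharing at least one exact
6-peptide are aligned — cuts the all-vs-all cost the way
greedy-incremental clusterers do; at the default thresholds a pair with no
shared 6-mer has effectively no chance of reaching 50% identity, and the
filter can be disabled (`prefilter = FALSE`) for exhaustive alignment.
Family ids are assigned in order of each family's first gene, so the
output is deterministic given the input order and invariant, up to family
relabelling, under permutation of the genomes.

`pangenome_summary()` reports the total number of distinct families, the
*single-copy core* (families with copy number exactly 1 in every genome),
per-genome *singletons*, and pairwise shared-family counts. Where a
genome holds paralogs, singletons are counted as families, not genes —
the matrix is explicit about copy number, so either reading can be
recomputed.

### Distance trees and the co-grouping consensus

The presence/absence dendrogram follows the classic recipe: reduce the
family × genome matrix to presence/absence, compute the Jaccard distance
`d(i,j) = 1 − |F_i ∩ F_j| / |F_i ∪ F_j|` for every genome pair
(`jaccard_distances()`), and reconstruct a tree with neighbor joining.
`neighbor_joining()` is the Saitou–Nei agglomeration with the standard
Q-criterion. Two details are pinned down for determinism and
non-additive inputs:

* ties in Q are broken by the lowest (i, j) index pair;
* a negative branch length (possible on non-additive matrices such as
  Jaccard distances) is clamped to zero and the deficit moved to its
  sister branch, preserving path lengths through the joined pair.

On additive matrices the reconstruction is exact — topology and branch
lengths — which the test suite verifies against randomly generated trees
and against an independent implementation (`ape::nj`).

The consensus procedure summarizes the `core_gene_trees()` — one NJ tree
per single-copy core family, built from pairwise amino-acid p-distances
(fraction of mismatched aligned positions; a Poisson correction
`−log(1−p)` is available behind a flag, unnecessary for the synthetic
data, which contain no indels). For every pair of genomes,
`cogrouping_consensus()` counts the gene trees in which the pair forms a
**cherry** — two leaves attached to the same internal node of the unrooted
topology. "Grouping together" admits several readings for non-cherry
nestings; the cherry is the only unambiguous pairing notion on small
unrooted trees, so it is the definition used here. Counts convert to
dissimilarities via the minimal monotone map `1 − count/n_trees` (the
transform is an argument, so a user who prefers, say, a log transform can
supply one), and a final neighbor joining yields the consensus tree.
Binary fingerprint matrices (e.g. repetitive-element PCR band patterns
scored strain × band) flow through exactly the same
`jaccard_distances()` + `neighbor_joining()` path.

### The pan-genome generator

`simulate_pangenome()` produces proteomes with retained truth labels by
evolving gene content along a guide tree: `n_core` families are born at
the root and inherited by every genome; accessory families arise on each
branch (Poisson, mean `gain_rate` per branch) and are lost on each
downstream branch with probability `loss_rate`; each genome additionally
receives private singleton families (Poisson, mean `n_singletons_mean`).
Sequences evolve by i.i.d. per-site substitution to a uniformly chosen
different residue with per-branch probability `divergence`; there are no
indels, which keeps identity arithmetic exact and lets the estimator
tests use column identity as their oracle. Protein lengths are drawn as
30 + a negative-binomial spread around `prot_len` (default 200 aa),
mimicking the broad ORF length distribution of real phage genomes.

The defaults emulate a six-genome T4-like cluster: `n_core = 111`,
`gain_rate = 16`, `loss_rate = 0.1`, `n_singletons_mean = 65`,
`divergence = 0.1` on a balanced three-cherry guide tree. Together these
give ≈630–660 distinct families with per-genome singleton counts in the
dozens — the regime reported for real *Tevenvirinae* clusters. At the
default divergence the expected within-family identity across the tree
diameter stays near 0.6, comfortably above the clustering threshold; the
generator warns when a requested divergence pushes that expectation below
0.5, because families then become unrecoverable *by design*.

What the synthetic data do not capture: real ortholog structure includes
domain shuffling, fragmented ORF calls, paralogous expansions and indels.
A perfect adjusted-Rand recovery on the generator therefore validates the
graph machinery and thresholds, not the clusterer's robustness to those
real-data pathologies — for real proteomes the thresholds are exposed
precisely so users can tighten or relax them.

## Growth/kill curves and synergy statistics

### The mechanistic generator

`simulate_growth_kill()` integrates, per treatment arm, a deterministic
compartment model (per ml): susceptible cells S, m sequential infected
stages I₁..I_m, phage-resistant cells R, and free phage P, with

* logistic growth `g = r (1 − N/K)` of S and R, where
  `N = S + ΣI + R` (infected cells stop dividing but occupy the niche);
* mass-action adsorption `δ·S·P` into I₁ and Erlang-staged lysis — stage
  transit at rate `m/τ`, so the latent period has mean `τ` and shape `m`
  (default 5; a smooth, ODE-friendly stand-in for a hard delay) — each
  lysis releasing `β` phage;
* a fraction `μ` of susceptible divisions yielding phage-resistant
  daughters;
* Hill-type antibiotic kill `a(c) = emax·c^h/(ec50^h + c^h)` in one of
  two mechanistic modes (below);
* observation `OD = α·N + od0`, with multiplicative Gaussian noise of
  s.d. `sigma` (default 0.01, plate-reader-like) per replicate reading.

Defaults describe a carbapenemase-producing *A. baumannii*-like host and a
T4-like phage: `r = 1.4`/h, `K = 1e9` cells/ml, `β = 39`, `τ = 0.5` h (the
one-step-growth values), inoculum `n0 = 2.5e8` cfu/ml, `α = 5e-10`
OD·ml/cell and `od0 = 0.03` so an untreated culture saturates at OD ≈ 0.53.
The adsorption constant defaults to `δ = 1e-8` ml/h. That value is chosen
deliberately below what the adsorption *assay* implies (99% adsorption in
12 min at 1e7 cfu/ml corresponds to ≈2.3e-6 ml/h): at assay-implied rates
the phage-crash phase of the full infection model becomes stiff on the
20-min observation grid, and the slower constant keeps the prescribed
fixed-step integration accurate while preserving every qualitative regime
(crash within hours at high MOI, delayed crash at MOI 1e-6 around 3–5 h).
The adsorption-assay generator (`simulate_adsorption()`) is parameterized
independently and reproduces the 12-min/99% kinetics exactly.

**Antibiotic modes.** The two modes encode the mechanistic difference
between cell-wall/replication drugs and membrane-active drugs:

* `"dividing"` (meropenem- or ciprofloxacin-like): the per-capita kill
  rate is `a(c)·max(g, 0)/r` on S and R — proportional to the current
  division rate. A culture near carrying capacity divides little and is
  barely touched (single-drug arms change end-OD almost not at all, only
  slowing growth), while a sparse, exponentially regrowing subpopulation
  feels the full rate. This is the package's stand-in for the empirical
  pattern that single antibiotics leave end-OD unchanged yet combinations
  suppress resistant regrowth; the mechanism of that suppression in real
  cultures is an open question, and this formulation is a modeling choice,
  not a claim about the biology.
* `"all"` (colistin-like): `a(c)` applies to S, R and all infected
  stages regardless of division.

Default pharmacodynamic anchors sit at MIC-like values for the three
drugs of the combination study: meropenem `ec50 = 32` mg/l
(`emax = 1.25`/h, h = 2, dividing), ciprofloxacin `ec50 = 0.09` mg/l
(`emax = 1.0`/h, h = 1, dividing), colistin `ec50 = 2` mg/l
(`emax = 1.2`/h, h = 2, all). With `emax` below `r`, no single drug
sterilizes — matching the observation the synergy analysis starts from.

**Resistant regrowth.** The default mutation probability is `μ = 0`: in a
deterministic model any `μ ≳ 1e-9` regrows to carrying capacity within
16 h after an early crash, so regrowth is a scenario switch rather than a
default. The regrowth analyses set `μ = 2e-7`, which reproduces the
phage-decline-then-regrowth pattern and its suppression by a co-applied
dividing-mode drug.

**Integration.** The model is integrated with a deterministic fixed-step
classical Runge–Kutta (RK4) at `substeps = 100` internal steps per 20-min
output interval (12-s steps). The phage-crash phase makes the system
locally stiff — at coarser substeps (e.g. dt/20) the susceptible
compartment oscillates unstably — and at dt/100 the solution agrees with
an adaptive reference integration (`deSolve::lsoda` at rtol 1e-10) to
better than 3e-6 OD across all tested regimes; the test suite asserts
1e-3. Compartment densities are clamped at zero after each substep (the
true solution decays exponentially; the clamp removes integrator
undershoot). Two bookkeeping integrals (cumulative lysed cells, cumulative
adsorbed phage) make the conservation identity
`P = P₀ + β·lysed − adsorbed` (exact when `μ = 0` and no drug is present)
assertable to integrator tolerance.

### Suppression metrics and tests

Two per-replicate metrics summarize each arm: the OD at the final time
point (**end-OD**) and the **trapezoid AUC**
`Σ_i (f(t_i)+f(t_{i+1}))/2 · Δt` over the measured intervals, with `Δt`
carried as the exact rational 1/3 h for the standard 20-min grid — the
customary "0.33 h" is display rounding, and using it would bias every AUC
by 1%. For a 49-point assay the sum runs over the 48 observed intervals;
formulations that index a 49th interval implicitly reference a 50th,
never-measured point and are not self-consistent, so phagekit integrates
over measured points only.

`one_tailed_ttest()` tests whether a combination suppresses more strongly
than its comparator: alternative *treated mean < baseline mean*,
one-sided, Welch unequal-variance by default (the pooled-variance Student
variant sits behind `var_equal = TRUE`), with the conventional star map
(*p* < 0.05 `*`, < 0.01 `**`, < 0.001 `***`). When both arms are exactly
constant with equal means the statistic is undefined; the convention
`t = 0, p = 0.5` applies and the result is flagged degenerate. No
multiple-testing correction is applied across a combination grid — each
cell is reported as its own test, as is conventional for these assay
panels; `stats::p.adjust` composes trivially downstream if a user wants
family-wise control.

`evaluate_combinations()` implements both baseline conventions in use:
`phage_alone` compares each combination against the phage-only arm at the
same MOI; `best_single` against whichever single-agent arm (phage at the
same MOI, or drug at the same concentration) shows the lower mean of the
metric under test. Both are exposed because combination studies use both,
sometimes in different figures of the same paper; the choice is an
argument, never hard-coded.

The type-I behavior of the full path (generator noise → metric →
Welch test → star call) is property-tested: on arms with identical
dynamics the star rate at α = 0.05 stays at or below ~6%. Detection power
is validated on a fixed large-effect scenario — combination end-OD mean
0.10 versus best-single 0.45 under 1% multiplicative noise with n = 3 —
defined at the level of arm means rather than by tuning ODE parameters to
land on those values.

## Titer-assay kinetics

`simulate_one_step()` renders the one-step growth experiment: a plateau at
`titer0` before the latent period and a logistic rise to `β·titer0`
afterwards (rise s.d. 1 min), observed as triplicate Poisson plaque
counts at the classic schedule (every 5 min to 30 min, then every 10 min
to 120 min) with a plating dilution such that expected counts are ~100.
`burst_size()` estimates the burst as the ratio of the last-k to first-k
plateau means (k = 3; the assay convention reads "begin and end of the
experiment", and k is configurable) per replicate, reported mean ± s.d.
across replicates — the titer-ratio reading, which is what plateau data
identify. `latent_period()` reports the first *sampled* time at which the
mean titer exceeds `rise_factor` (default 2) times the initial plateau:
an explicit, tunable rule standing in for reading the inflection off the
curve, reported at the sampling resolution with no interpolation.

`simulate_adsorption()` draws duplicate Poisson counts around
`p0·exp(−k·cells·t)` sampled every 3 min; defaults place the 1%-free
crossing exactly at 12 min for a host density of 1e7 cfu/ml.
`adsorption_profile()` reports the free fraction per sampled time, `t99`
(first sampled time under 1% free — again at sampling resolution), and
`k_hat`, the least-squares slope of log free-fraction over time points
with positive counts, in 1/min. Recovery tests show the estimator lands
within 10% of truth in ~100/100 noisy assays at the default count scale.

`host_range_summary()` is deliberately plain arithmetic — per strain
class, the count and percentage of strains with zones of clearing
(undiluted spot) and with productive lysis (individual plaques on
titration, the accepted indicator that clearing reflects replication
rather than lysis from without) — with half-up integer rounding to match
how such percentages are conventionally printed.

## Genome-record statistics

`genome_record_stats()` parses a GenBank flat file directly (none of the
installed R stack reads GenBank offline) and reports sequence length, GC
content — computed as (G+C)/(A+C+G+T) over the ORIGIN sequence with
ambiguity codes excluded from numerator *and* denominator, rounded
half-up to 2 decimals — and the counts of `CDS` and `tRNA` feature keys.
It counts features already present in a record; it does not predict
genes. The bundled `synthetic_phage_record.gb` is a small synthetic
record (generated, not a real deposit — the name says so) whose expected
statistics were frozen from an independent parser.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit integer seed; pipeline
configurations carry one master seed from which each stage derives child
seeds via the documented linear map `derive_seed()` (multiplier 48271
modulo 2³¹−1), so partial re-runs reproduce and two stages never share a
stream. Identical seeds give bit-identical outputs, including CSV/TSV
artifacts.

The committed studies use desk-scale problem sizes chosen to estimate
their rates tightly enough for the stated bounds: 100 random trees for NJ
exactness, 100 consensus experiments of 111 gene trees at 20% topology
noise, 200 one-step assays and 100 adsorption assays for estimator
recovery, 10,000 null replicates for test size and 500 for power, and the
full default six-genome pan-genome (~1,200 proteins) for clustering
recovery.

## Known limitations

* The growth/kill model is well-mixed and deterministic with observation
  noise only: no spatial structure or biofilms, no pharmacokinetics, no
  demographic stochasticity (a Gillespie engine is out of scope), and no
  phage-resistance cost. The resistant-subpopulation formulation of
  regrowth, and the division-coupled kill mode, are modeling stand-ins
  for mechanisms the underlying experiments do not resolve.
* Ortholog clustering is alignment-identity-based: no profile/HMM remote
  homology, no synteny, no nucleotide-level comparison. On deeply
  diverged real proteomes it will fragment families that BLAST+MCL
  pipelines hold together; thresholds are exposed for that reason.
* Core-gene trees are built from pairwise p-distances, not from a
  multiple sequence alignment with model-based inference; with indels and
  rate heterogeneity on real data, per-gene topologies will be noisier
  than the synthetic benchmark suggests — which is precisely the
  situation the co-grouping consensus is designed to average over.
* OD is mapped linearly to cell density; real OD–cfu relations flatten at
  high density and are strain-dependent.
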