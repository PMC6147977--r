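# phagekit

Computational characterization of lytic bacteriophages, built for studies
that pair a newly isolated phage (e.g. a T4-like *Acinetobacter
baumannii* myovirus) with multi-drug-resistant clinical isolates. The
package covers the three analysis tracks such studies run:

1. **Pan-genome phylogenomics** — cluster phage proteomes into ortholog
   families; summarize the pan-genome (total / single-copy core /
   singleton families); build the presence/absence dendrogram from
   Jaccard distances, `d(i,j) = 1 − |F_i ∩ F_j| / |F_i ∪ F_j|`, with
   neighbor joining; and condense the per-gene trees of all single-copy
   core families into a **co-grouping consensus**: count, for each genome
   pair, the gene trees in which the pair are sisters (a cherry), map
   counts to distances via `1 − count/n_trees`, and re-run neighbor
   joining. Binary fingerprint (band presence) matrices flow through the
   same Jaccard + NJ path.
2. **Phage kinetics** — burst size (post-/pre-burst plateau titer ratio),
   latent period, adsorption profiles (free fraction, t99, first-order
   rate from the log-linear slope), and host-range summaries from spot
   assays.
3. **Phage–antibiotic synergy** — per-replicate end-OD and trapezoid AUC,
   `Σ_i (f(t_i)+f(t_{i+1}))/2 · Δt` with Δt = 1/3 h on the standard
   49-point, 16-h OD₅₉₀ grid, compared arm-against-baseline with
   one-tailed Welch t-tests and conventional star calls, under either the
   phage-alone or the best-single-agent baseline rule.

A mechanistic synthetic-data generator (logistic growth, mass-action
adsorption, Erlang-staged lysis, Hill-type antibiotic kill, emergent
phage-resistant subpopulations; tree-structured gene gain/loss for
proteomes; Poisson plaque counts for titer assays) makes every stage
testable against retained ground truth. See
`vignettes/phagekit-methods.Rmd` for the models, defaults, and numerical
choices.

## Worked example

Simulate a six-genome phage cluster, recover its pan-genome, and build
both trees:

```r
library(phagekit)
res <- run_phylogenomics(list(phylogenomics = list(seed = 20260920)),
                         "results/phylogenomics")
```

```
phylogenomics: 6 genomes, 1227 genes
phylogenomics: 638 families (111 single-copy core)
```

The 638 distinct families split into 111 single-copy core families
(present exactly once in every genome, the input to the consensus) and
per-genome singletons in the dozens (`res$summary$singletons`); the
co-grouping consensus over the 111 core-gene trees reproduces the
generating topology (`rf_distance(res$consensus$tree,
default_guide_tree())` is 0). Artifacts — family matrix TSV, Jaccard
distance TSV, Newick trees, JSON summary — land under
`results/phylogenomics/`.

Kinetics, from noisy simulated titer assays:

```r
os <- simulate_one_step(beta = 39, tau_latent = 30, seed = 20260920)
burst_size(os); latent_period(os)
ad <- simulate_adsorption(seed = 20260920)
adsorption_profile(ad)[c("t99", "k_hat")]
```

```
burst size: 39.3 +- 1.2 phage/cell | latent period: 30 min
t99: 12 min | fitted rate 0.3864 /min (truth 0.3838, error 0.7%)
```

i.e. the estimators read back the simulated burst size (39), the 30-min
latent period at the 5-min sampling resolution, and the adsorption rate
set so 99% of particles adsorb by 12 min.

Synergy, on a resistant-regrowth scenario (phage-resistance mutation rate
2e-7; phage MOI 1 with or without meropenem 32 mg/l):

```
regrowth scenario end-OD: untreated 0.531 | phage alone 0.518 |
  meropenem alone 0.531 | combination 0.032
  metric          baseline mean_combo mean_baseline  p_one_sided stars
1  endOD AB04|moi=1|none=0 0.03165548     0.5182848 4.614205e-06   ***
2    AUC AB04|moi=1|none=0 0.59471348     2.0254438 4.654985e-07   ***
```

Phage alone crashes the culture and then resistant cells regrow to the
untreated level by 16 h; neither single agent moves the end-OD, but the
combination holds it at background — detected at `***` on both metrics
against the best single agent.

The numbered drivers under `analysis/` run these studies end to end
(`Rscript analysis/01_pangenome_phylogenomics.R`, etc.) and write their
tables under `results/`.

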