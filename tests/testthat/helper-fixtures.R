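# shared fixtures and independent oracles, built in code at test time

# random unrooted binary tree with positive branch lengths (additive case)
rand_additive_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

# standard 49-point 16-h assay grid
assay_times <- function() seq(0, 16, by = 1 / 3)

# od_series replicates around a noise-free template curve, multiplicative noise
noisy_series <- function(template, tr, n_reps = 3, sigma = 0.01) {
  lapply(seq_len(n_reps), function(r) {
    od_series(assay_times(), pmax(template * (1 + sigma * stats::rnorm(length(template))), 0),
              treatment = tr, replicate = r)
  })
}

# template OD curve on the assay grid: grows logistically, optionally crashes
# towards `end` mid-assay; only the end value matters to the endOD metric
template_curve <- function(end, start = 0.15, peak = 0.5) {
  t <- assay_times()
  up <- start + (peak - start) / (1 + exp(-(t - 3)))
  if (end >= peak) return(start + (end - start) / (1 + exp(-(t - 3))))
  up - (peak - end) / (1 + exp(-(t - 8)))
}

# tiny proteome set with a known family structure: `n_fam` families shared by
# all genomes (identical copies), plus `n_priv` private genes per genome
toy_genome_set <- function(genome_ids = c("GA", "GB"), n_fam = 10, n_priv = 0,
                           len = 60, seed = 1) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  fams <- vapply(seq_len(n_fam), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
  genomes <- list(); truth <- character(0)
  for (g in genome_ids) {
    ids <- sprintf("%s_f%02d", g, seq_len(n_fam))
    seqs <- stats::setNames(fams, ids)
    truth <- c(truth, stats::setNames(sprintf("fam%02d", seq_len(n_fam)), ids))
    if (n_priv > 0) {
      pids <- sprintf("%s_p%02d", g, seq_len(n_priv))
      priv <- vapply(seq_len(n_priv), function(i)
        paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
      seqs <- c(seqs, stats::setNames(priv, pids))
      truth <- c(truth, stats::setNames(paste0("priv_", pids), pids))
    }
    genomes[[g]] <- seqs
  }
  phage_genome_set(genomes, truth = truth)
}

# brute-force pan-genome summary by explicit set enumeration
brute_pangenome_summary <- function(counts) {
  fams <- rownames(counts); genomes <- colnames(counts)
  sets <- lapply(genomes, function(g) fams[counts[, g] > 0])
  names(sets) <- genomes
  core <- 0L
  for (f in fams) if (all(vapply(genomes, function(g) counts[f, g] == 1L, logical(1))))
    core <- core + 1L
  singles <- vapply(genomes, function(g) {
    n <- 0L
    for (f in sets[[g]])
      if (!any(vapply(setdiff(genomes, g), function(h) f %in% sets[[h]], logical(1))))
        n <- n + 1L
    n
  }, integer(1))
  shared <- matrix(0L, length(genomes), length(genomes),
                   dimnames = list(genomes, genomes))
  for (a in genomes) for (b in genomes)
    shared[a, b] <- length(intersect(sets[[a]], sets[[b]]))
  list(total = length(fams), core = core, singletons = singles,
       shared_pairs = shared)
}

# brute-force Robinson-Foulds by bipartition set comparison
rf_oracle <- function(a, b) {
  splits_of <- function(tree) {
    tr <- ape::unroot(tree)
    n_tip <- length(tr$tip.label)
    anchor <- sort(tr$tip.label)[1L]
    out <- character(0)
    for (e in seq_len(nrow(tr$edge))) {
      child <- tr$edge[e, 2L]
      if (child <= n_tip) next  # pendant edges are shared trivially
      tips <- ape::extract.clade(tr, child)$tip.label
      side <- if (anchor %in% tips) tips else setdiff(tr$tip.label, tips)
      out <- c(out, paste(sort(side), collapse = "|"))
    }
    unique(out)
  }
  sa <- splits_of(a); sb <- splits_of(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# Welch t statistic, degrees of freedom, and one-sided p, written out in full
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = stats::pt(t, df))
}
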