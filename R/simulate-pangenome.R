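AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default six-genome guide tree
#'
#' A balanced unrooted six-leaf topology of three cherries, used as the true
#' genealogy by [simulate_pangenome()] and in consensus-recovery studies.
#'
#' @param labels Tip labels; default `G1`..`G6`.
#' @return An `ape` "phylo" object.
#' @export
default_guide_tree <- function(labels = paste0("G", 1:6)) {
  stopifnot(length(labels) == 6L)
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,(E:0.1,F:0.1):0.05);")
  tr$tip.label <- labels
  tr
}

#' A set of phage proteomes with retained truth labels
#'
#' @param genomes Named list; each element a named character vector of
#'   amino-acid sequences (names are gene ids, unique within a genome).
#' @param truth Named character vector mapping gene id to true family label
#'   (for generator output), or `NULL` for real data.
#' @return An object of class `"phage_genome_set"`.
#' @export
phage_genome_set <- function(genomes, truth = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1L, !is.null(names(genomes)))
  for (g in names(genomes)) {
    seqs <- genomes[[g]]
    if (length(seqs)) {
      if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop(sprintf("genome '%s': gene ids must be unique and named", g),
             call. = FALSE)
      if (any(nchar(seqs) == 0))
        stop(sprintf("genome '%s': empty sequence", g), call. = FALSE)
      bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
      if (any(bad))
        stop(sprintf("genome '%s': invalid amino-acid residues in %s", g,
                     paste(names(seqs)[bad], collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(genomes = genomes, truth = truth),
            class = "phage_genome_set")
}

#' @export
print.phage_genome_set <- function(x, ...) {
  cat(sprintf("<phage_genome_set> %d genomes: %s\n", length(x$genomes),
              paste(sprintf("%s (%d genes)", names(x$genomes),
                            lengths(x$genomes)), collapse = ", ")))
  invisible(x)
}

#' Simulate a phage pan-genome along a guide tree
#'
#' Generates proteomes for the tip genomes of `params$guide_tree` with a
#' core/accessory/singleton structure: `n_core` single-copy families present
#' in every genome (diverged copies of a common ancestral protein),
#' accessory families gained along branches (Poisson with mean `gain_rate`
#' per branch) and lost on downstream branches with probability
#' `loss_rate`, and private singleton families per genome (Poisson with
#' mean `n_singletons_mean`).  Sequences evolve by i.i.d. per-site
#' substitution with per-branch probability `divergence` to a uniformly
#' chosen different residue; no indels, so within-family sequences share
#' their length.
#'
#' True family labels are retained in the `truth` field for evaluating
#' ortholog clustering.  If the divergence across the tree diameter pushes
#' expected within-family identity below 0.5 (the default clustering
#' threshold) a warning is raised: families become unrecoverable by design.
#'
#' @param params A [gene_evolution_params()].
#' @return A [phage_genome_set()] with truth labels.
#' @export
simulate_pangenome <- function(params) {
  stopifnot(inherits(params, "gene_evolution_params"))
  tree <- params$guide_tree
  set.seed(params$seed)

  n_tip <- length(tree$tip.label)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge  # parent, child; root first
  root <- setdiff(edges[, 1L], edges[, 2L])[1L]

  # expected identity across the tree diameter under the substitution model
  diam <- max(edge_path_lengths(tree))
  exp_ident <- (1 - params$divergence)^diam +
    (1 - (1 - params$divergence)^diam) / length(AA_ALPHABET)
  if (exp_ident < 0.5)
    warning("divergence so high that within-family identity falls below the ",
            "default clustering threshold (0.5); families may be unrecoverable",
            call. = FALSE)

  rand_seq <- function(len) sample.int(20L, len, replace = TRUE)
  genomes <- stats::setNames(vector("list", n_tip), tree$tip.label)
  for (g in seq_len(n_tip)) genomes[[g]] <- list()
  truth <- character(0)

  draw_len <- function() 30L + stats::rnbinom(1L, mu = max(params$prot_len - 30, 1),
                                              size = 3)

  # drop a family's ancestral sequence down the subtree rooted at `node`
  propagate <- function(node, seq, family, subject_to_loss) {
    if (node <= n_tip) {
      genomes[[node]][[length(genomes[[node]]) + 1L]] <<- list(family = family,
                                                               seq = seq)
      return(invisible(NULL))
    }
    for (e in which(edges[, 1L] == node)) {
      if (subject_to_loss && stats::runif(1L) < params$loss_rate) next
      propagate(edges[e, 2L], mutate_seq(seq, params$divergence), family,
                subject_to_loss)
    }
  }

  # core families: ancestor at root, inherited everywhere (no loss)
  for (f in seq_len(params$n_core))
    propagate(root, rand_seq(draw_len()), sprintf("core%03d", f), FALSE)

  # accessory families: born at the child node of a branch, lost downstream
  fam_counter <- 0L
  for (e in seq_len(nrow(edges))) {
    for (gained in seq_len(stats::rpois(1L, params$gain_rate))) {
      fam_counter <- fam_counter + 1L
      propagate(edges[e, 2L], rand_seq(draw_len()),
                sprintf("acc%04d", fam_counter), TRUE)
    }
  }

  # private singletons
  for (g in seq_len(n_tip)) {
    for (s in seq_len(stats::rpois(1L, params$n_singletons_mean))) {
      genomes[[g]][[length(genomes[[g]]) + 1L]] <-
        list(family = sprintf("sing_%s_%03d", tree$tip.label[g], s),
             seq = rand_seq(draw_len()))
    }
  }

  out <- stats::setNames(vector("list", n_tip), tree$tip.label)
  for (g in seq_len(n_tip)) {
    entries <- genomes[[g]]
    ids <- sprintf("%s_g%04d", tree$tip.label[g], seq_along(entries))
    seqs <- vapply(entries, function(x) paste(AA_ALPHABET[x$seq], collapse = ""),
                   character(1))
    fams <- vapply(entries, function(x) x$family, character(1))
    out[[g]] <- stats::setNames(seqs, ids)
    truth <- c(truth, stats::setNames(fams, ids))
  }
  phage_genome_set(out, truth = truth)
}

# substitute each site independently with probability `p` to a uniformly
# chosen different residue (integer-coded sequence)
mutate_seq <- function(seq, p) {
  if (p == 0) return(seq)
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    seq[hit] <- ((seq[hit] - 1L + shift) %% 20L) + 1L
  }
  seq
}

# pairwise tip-to-tip path lengths in edge counts
edge_path_lengths <- function(tree) {
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  d <- ape::cophenetic.phylo(t1)
  d[upper.tri(d)]
}

#' Simulate gene trees as noisy copies of a guide topology
#'
#' Each simulated tree is the guide topology with probability
#' `1 - noise_prob`, and otherwise a random nearest-neighbour-interchange
#' (NNI) rearrangement of it, emulating the tree-to-tree variation of
#' single-gene phylogenies around a dominant species history.  Branch
#' lengths are discarded (cladograms).
#'
#' @param guide_tree An `ape` "phylo" with `>= 4` tips.
#' @param n Number of gene trees.
#' @param noise_prob Probability that a tree is an NNI rearrangement.
#' @param seed Integer seed.
#' @return List of "phylo" cladograms.
#' @export
simulate_gene_trees <- function(guide_tree, n = 111L, noise_prob = 0.2,
                                seed = 1L) {
  stopifnot(inherits(guide_tree, "phylo"), length(guide_tree$tip.label) >= 4L)
  if (noise_prob < 0 || noise_prob > 1)
    stop("'noise_prob' must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  guide <- ape::unroot(guide_tree)
  guide$edge.length <- NULL
  lapply(seq_len(n), function(i) {
    if (stats::runif(1L) < noise_prob) phangorn::rNNI(guide, 1L) else guide
  })
}
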