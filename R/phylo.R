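#' Jaccard distances between genomes from a gene-family matrix
#'
#' Reduces copy numbers to presence/absence and computes, for every genome
#' pair, `d = 1 - |shared families| / |union of families|`.  Two genomes
#' with identical family sets are at distance 0; genomes sharing nothing
#' are at distance 1.  A pair of genomes that both have empty family sets
#' is assigned distance 0 with a warning.
#'
#' @param matrix A `gene_family_matrix` from [cluster_orthologs()] or a bare
#'   family x genome count (or presence) matrix with at least 2 genomes.
#' @return Symmetric labeled distance matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
jaccard_distances <- function(matrix) {
  counts <- if (inherits(matrix, "gene_family_matrix")) matrix$counts
            else as.matrix(matrix)
  if (ncol(counts) < 2L) stop("need >= 2 genomes", call. = FALSE)
  pres <- counts > 0
  inter <- crossprod(pres * 1)
  sizes <- colSums(pres)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  if (any(union == 0)) {
    warning("genome pair(s) with two empty family sets: distance defined 0",
            call. = FALSE)
    d[union == 0] <- 0
  }
  diag(d) <- 0
  d
}

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA/NaN/Inf entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The agglomerative algorithm of Saitou and Nei with the standard
#' Q-criterion `Q(i,j) = (r-2) d(i,j) - R_i - R_j`.  Deterministic
#' tie-break: among minimal-Q pairs the one with the lowest (i, j) index
#' pair is joined.  A negative branch length arising from a non-additive
#' matrix is clamped to zero and the deficit moved to its sister branch, so
#' path lengths through the joined pair are preserved.
#'
#' On an additive matrix the reconstruction is exact (topology and branch
#' lengths of the generating tree).
#'
#' @param d Symmetric distance matrix (labeled) or `dist`, `>= 3` taxa.
#' @return An unrooted `ape` "phylo" tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 taxa", call. = FALSE)
  # each active node carries a Newick fragment
  frag <- sprintf("'%s'", rownames(d))
  frag <- ifelse(grepl("^[A-Za-z0-9_.]+$", rownames(d)), rownames(d), frag)

  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest index pair among minimal Q entries
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(d) <- colnames(d) <- NULL
  }
  # closed-form three-point resolution
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmt(la), frag[2L], fmt(lb),
                 frag[3L], fmt(lc))
  ape::read.tree(text = txt)
}

#' Per-family p-distance between two aligned or unaligned proteins
#'
#' Fraction of mismatched aligned positions.  Equal-length sequences are
#' compared site by site (the generator produces no indels); unequal
#' lengths are globally aligned first and gap columns excluded.  A Poisson
#' correction `-log(1 - p)` is available for multiple hits.
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @param correction `"none"` or `"poisson"`.
#' @return The distance (>= 0).
#' @export
p_distance <- function(a, b, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    p <- mean(ca != cb)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = aa_substitution_matrix(), gapOpening = 0,
      gapExtension = 2)
    ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    both <- ca != "-" & cb != "-"
    p <- if (any(both)) mean(ca[both] != cb[both]) else 1
  }
  if (correction == "poisson") {
    if (p >= 1) stop("p-distance 1: Poisson correction undefined", call. = FALSE)
    -log(1 - p)
  } else p
}

#' Neighbor-joining trees of all single-copy core gene families
#'
#' For every family present exactly once in each genome, computes the
#' pairwise p-distance matrix of its member proteins and reconstructs a
#' neighbor-joining tree, one per family.
#'
#' @param matrix A `gene_family_matrix` (with membership and gene-genome
#'   mapping, as produced by [cluster_orthologs()]).
#' @param genomes The [phage_genome_set()] the matrix was built from.
#' @param correction Passed to [p_distance()].
#' @return Named list of unrooted "phylo" trees (tips = genome ids); empty
#'   with a warning when there are no single-copy core families.
#' @export
core_gene_trees <- function(matrix, genomes, correction = "none") {
  stopifnot(inherits(matrix, "gene_family_matrix"),
            inherits(genomes, "phage_genome_set"))
  if (ncol(matrix$counts) < 3L) stop("need >= 3 genomes", call. = FALSE)
  core <- rownames(matrix$counts)[apply(matrix$counts, 1L, function(x) all(x == 1L))]
  if (!length(core)) {
    warning("no single-copy core families", call. = FALSE)
    return(list())
  }
  # gene ids may be globally unique or genome-prefixed
  tab <- gene_table(genomes)
  seq_of <- stats::setNames(tab$seq, tab$id)
  trees <- lapply(core, function(fam) {
    ids <- matrix$membership[[fam]]
    gnm <- matrix$gene_genome[ids]
    seqs <- stats::setNames(seq_of[ids], gnm)
    k <- length(seqs)
    d <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]],
                                         correction = correction)
    neighbor_joining(d)
  })
  stats::setNames(trees, core)
}

#' Cherry (sister-pair) leaf pairs of an unrooted tree
#'
#' @param tree An `ape` "phylo".
#' @return Two-column character matrix of leaf-label pairs that are mutual
#'   sisters (attached to the same internal node) in the unrooted tree.
#' @export
cherry_pairs <- function(tree) {
  tr <- ape::unroot(tree)
  n_tip <- length(tr$tip.label)
  tip_edges <- tr$edge[tr$edge[, 2L] <= n_tip, , drop = FALSE]
  out <- list()
  for (parent in unique(tip_edges[, 1L])) {
    tips <- tip_edges[tip_edges[, 1L] == parent, 2L]
    if (length(tips) >= 2L) {
      prs <- utils::combn(sort(tr$tip.label[tips]), 2L)
      for (c_i in seq_len(ncol(prs)))
        out[[length(out) + 1L]] <- prs[, c_i]
    }
  }
  if (!length(out)) return(matrix(character(0), ncol = 2L))
  do.call(rbind, out)
}

#' Co-grouping consensus of a set of gene trees
#'
#' Counts, for every pair of taxa, in how many input trees the pair forms a
#' cherry (mutual sisters in the unrooted topology), converts the counts to
#' a dissimilarity with `transform` (default `1 - count/n_trees`), and
#' reconstructs a neighbor-joining consensus tree from that matrix.
#'
#' @param trees List of "phylo" trees sharing an identical leaf set of
#'   `>= 4` taxa.
#' @param transform Function of `(counts, n_trees)` returning the distance
#'   matrix entries; must be monotone decreasing in the counts.
#' @return List with `counts` (symmetric integer co-grouping matrix,
#'   `n_trees` attribute), and `tree`, the NJ consensus.
#' @export
cogrouping_consensus <- function(trees, transform = function(counts, n) 1 - counts / n) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  labels <- sort(trees[[1L]]$tip.label)
  if (length(labels) < 4L) stop("need >= 4 taxa", call. = FALSE)
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(labels, labels))
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labels))
      stop("all trees must share an identical leaf set", call. = FALSE)
    ch <- cherry_pairs(tr)
    for (r in seq_len(nrow(ch))) {
      counts[ch[r, 1L], ch[r, 2L]] <- counts[ch[r, 1L], ch[r, 2L]] + 1L
      counts[ch[r, 2L], ch[r, 1L]] <- counts[ch[r, 2L], ch[r, 1L]] + 1L
    }
  }
  n_trees <- length(trees)
  d <- transform(counts, n_trees)
  diag(d) <- 0
  tree <- neighbor_joining(d)
  attr(counts, "n_trees") <- n_trees
  list(counts = counts, tree = tree)
}

#' Robinson-Foulds distance between two unrooted topologies
#'
#' Symmetric bipartition distance; 0 if and only if the unrooted topologies
#' are identical.
#'
#' @param a,b "phylo" trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees must share the same leaf set", call. = FALSE)
  as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
}

#' Newick and distance-matrix file I/O
#'
#' Newick files are written unrooted with branch lengths at 9 significant
#' digits; distance matrices as square TSV with a header row and a leading
#' label column.
#'
#' @param tree A "phylo" object.
#' @param d Labeled square distance matrix.
#' @param path File path.
#' @return Readers return the parsed object; writers the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 9)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname write_newick
#' @export
write_distance_tsv <- function(d, path) {
  d <- validate_distance_matrix(d)
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1L, drop = FALSE])
  rownames(d) <- df$label
  validate_distance_matrix(d)
}
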