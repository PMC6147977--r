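#' Ortholog clustering parameters
#'
#' Thresholds of the identity/coverage graph used by [cluster_orthologs()].
#' Identity is defined as matches divided by alignment columns (gap columns
#' count in the denominator) under a global alignment with a linear gap
#' penalty; coverage is the fraction of the shorter sequence aligned
#' against a residue of the other.
#'
#' @param min_identity Minimum pairwise identity in `[0, 1]`; default 0.5.
#' @param min_coverage Minimum aligned fraction of the shorter sequence;
#'   default 0.5.
#' @param linkage `"single"` (families = connected components) or
#'   `"complete"` (greedy cliques in input order).
#' @param prefilter Skip alignments between sequences sharing no exact
#'   6-mer (an index-based speedup in the spirit of greedy-incremental
#'   clusterers; pairs this skips essentially never reach the default
#'   identity threshold).  Disable for exhaustive all-vs-all alignment.
#' @return An object of class `"clustering_params"`.
#' @export
clustering_params <- function(min_identity = 0.5, min_coverage = 0.5,
                              linkage = c("single", "complete"),
                              prefilter = TRUE) {
  linkage <- match.arg(linkage)
  if (min_identity < 0 || min_identity > 1)
    stop("'min_identity' must be in [0, 1]", call. = FALSE)
  if (min_coverage < 0 || min_coverage > 1)
    stop("'min_coverage' must be in [0, 1]", call. = FALSE)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 linkage = linkage, prefilter = isTRUE(prefilter)),
            class = "clustering_params")
}

aa_substitution_matrix <- function() {
  mat <- matrix(-1, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(mat) <- 2
  mat
}

#' Global pairwise identity and coverage between proteins
#'
#' Aligns each sequence of `patterns` globally against `subject`
#' (Needleman-Wunsch, match +2 / mismatch -1, linear gap penalty 2) and
#' returns identity = matches / alignment columns (gaps in the denominator)
#' and coverage = doubly-aligned columns / length of the shorter sequence.
#' In a pairwise global alignment no column is gap-gap, so the number of
#' doubly-aligned columns is `len(a) + len(b) - columns`.
#'
#' @param patterns Character vector of amino-acid sequences.
#' @param subject Single amino-acid sequence.
#' @return Data frame with columns `identity`, `coverage`.
#' @export
protein_identity <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = aa_substitution_matrix(),
    gapOpening = 0, gapExtension = 2)
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  la <- nchar(patterns); lb <- nchar(subject)
  both <- la + lb - cols
  data.frame(identity = matches / cols, coverage = both / pmin(la, lb))
}

# gene table of a phage_genome_set: one row per gene with a globally unique id
gene_table <- function(genomes) {
  stopifnot(inherits(genomes, "phage_genome_set"))
  rows <- lapply(names(genomes$genomes), function(g) {
    seqs <- genomes$genomes[[g]]
    if (!length(seqs)) return(NULL)
    data.frame(genome = g, gene = names(seqs), seq = unname(seqs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("genome set contains no genes", call. = FALSE)
  tab$id <- if (anyDuplicated(tab$gene)) paste(tab$genome, tab$gene, sep = "|")
            else tab$gene
  tab
}

# ungapped column identity of two equal-length sequences (split into chars)
sitewise_identity <- function(ca, cb) sum(ca == cb) / length(ca)

# indices of sequence pairs sharing at least one exact k-mer
kmer_candidate_pairs <- function(seqs, k = 6L) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  idx <- rep(seq_along(seqs), lengths(kmers))
  by_kmer <- split(idx, unlist(kmers))
  pairs <- unlist(lapply(by_kmer, function(v) {
    if (length(v) < 2L) return(NULL)
    combn(sort(v), 2L)
  }))
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(matrix(pairs, ncol = 2L, byrow = TRUE))
}

#' Cluster proteomes into ortholog families
#'
#' Builds the gene-family (ortholog) table of a genome set: all candidate
#' gene pairs are aligned globally ([protein_identity()]), an edge connects
#' two genes when identity and coverage reach the thresholds of `params`,
#' and families are the connected components of the resulting graph
#' (`linkage = "single"`) or greedily grown cliques in input order
#' (`linkage = "complete"`).  Deterministic given input order; family ids
#' are assigned in order of each family's first gene.
#'
#' @param genomes A [phage_genome_set()] with at least one genome.
#' @param params A [clustering_params()].
#' @return A `gene_family_matrix`: list with `counts` (family x genome
#'   copy-number matrix), `membership` (named list family -> gene ids) and
#'   `gene_genome` (named vector gene id -> genome).
#' @export
cluster_orthologs <- function(genomes, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  tab <- gene_table(genomes)
  n <- nrow(tab)

  cand <- if (params$prefilter) kmer_candidate_pairs(tab$seq)
          else t(utils::combn(n, 2L))
  # a pair can only reach the identity threshold if the shorter sequence is
  # long enough relative to the longer (matches <= min len, columns >= max len)
  if (nrow(cand)) {
    la <- nchar(tab$seq[cand[, 1L]]); lb <- nchar(tab$seq[cand[, 2L]])
    cand <- cand[pmin(la, lb) / pmax(la, lb) >= params$min_identity, ,
                 drop = FALSE]
  }

  edges <- matrix(integer(0), ncol = 2L)
  if (nrow(cand)) {
    keep <- logical(nrow(cand))
    lens <- nchar(tab$seq)
    eq <- which(lens[cand[, 1L]] == lens[cand[, 2L]])
    if (length(eq)) {
      # equal-length pairs: the linear-gap global alignment of a
      # near-identical pair is the ungapped one; score columns directly
      chars <- strsplit(tab$seq, "", fixed = TRUE)
      ident <- vapply(eq, function(r)
        sitewise_identity(chars[[cand[r, 1L]]], chars[[cand[r, 2L]]]),
        numeric(1))
      keep[eq] <- ident >= params$min_identity  # coverage is 1 ungapped
    }
    ne <- setdiff(seq_len(nrow(cand)), eq)
    for (j in unique(cand[ne, 2L])) {
      rows <- ne[cand[ne, 2L] == j]
      res <- protein_identity(tab$seq[cand[rows, 1L]], tab$seq[j])
      keep[rows] <- res$identity >= params$min_identity &
        res$coverage >= params$min_coverage
    }
    edges <- cand[keep, , drop = FALSE]
  }

  fam_of <- integer(n)
  if (params$linkage == "single") {
    gr <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2L), directed = FALSE)
    gr <- gr + igraph::vertices(setdiff(as.character(seq_len(n)),
                                        igraph::V(gr)$name))
    comp <- igraph::components(gr)$membership
    fam_of <- comp[as.character(seq_len(n))]
  } else {
    # greedy cliques: a gene joins the first family whose every member it
    # matches at threshold
    neighbors <- vector("list", n)
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      neighbors[[a]] <- c(neighbors[[a]], b)
      neighbors[[b]] <- c(neighbors[[b]], a)
    }
    families <- list()
    for (i in seq_len(n)) {
      placed <- FALSE
      for (f in seq_along(families)) {
        if (all(families[[f]] %in% neighbors[[i]])) {
          families[[f]] <- c(families[[f]], i); placed <- TRUE; break
        }
      }
      if (!placed) families[[length(families) + 1L]] <- i
    }
    for (f in seq_along(families)) fam_of[families[[f]]] <- f
  }

  # relabel families in order of first appearance
  first <- vapply(split(seq_len(n), fam_of), min, integer(1))
  ord <- order(first)
  relabel <- integer(length(ord)); relabel[as.integer(names(first))[ord]] <- seq_along(ord)
  fam_of <- relabel[fam_of]
  fam_ids <- sprintf("fam%04d", seq_len(max(fam_of)))

  genome_ids <- names(genomes$genomes)
  counts <- matrix(0L, nrow = length(fam_ids), ncol = length(genome_ids),
                   dimnames = list(fam_ids, genome_ids))
  for (i in seq_len(n))
    counts[fam_of[i], tab$genome[i]] <- counts[fam_of[i], tab$genome[i]] + 1L
  membership <- lapply(split(tab$id, fam_ids[fam_of]), sort)
  membership <- membership[fam_ids]

  structure(list(counts = counts, membership = membership,
                 gene_genome = stats::setNames(tab$genome, tab$id)),
            class = "gene_family_matrix")
}

#' @export
print.gene_family_matrix <- function(x, ...) {
  cat(sprintf("<gene_family_matrix> %d families x %d genomes (%d genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Pan-genome summary of a gene-family matrix
#'
#' @param matrix A `gene_family_matrix` from [cluster_orthologs()] (or a
#'   bare family x genome count matrix).
#' @return List with `total` distinct families, `core` (single-copy core:
#'   copy number exactly 1 in every genome), `singletons` (named per-genome
#'   counts of families present in that genome only; families, not genes),
#'   and `shared_pairs` (symmetric genome x genome matrix of shared-family
#'   counts).
#' @export
pangenome_summary <- function(matrix) {
  counts <- if (inherits(matrix, "gene_family_matrix")) matrix$counts else as.matrix(matrix)
  if (!nrow(counts)) stop("empty family matrix", call. = FALSE)
  pres <- counts > 0
  core <- sum(apply(counts, 1L, function(x) all(x == 1L)))
  n_genomes_per_fam <- rowSums(pres)
  singletons <- vapply(seq_len(ncol(counts)), function(j)
    sum(pres[, j] & n_genomes_per_fam == 1L), integer(1))
  names(singletons) <- colnames(counts)
  shared <- crossprod(pres * 1L)
  list(total = nrow(counts), core = core, singletons = singletons,
       shared_pairs = shared)
}

#' Best-hit identity histogram between two proteomes
#'
#' For each gene of proteome `a`, finds its best-hit identity among the
#' genes of proteome `b` (0 when no hit reaches `min_coverage`; ties broken
#' by the lexicographically first gene id) and bins the identities.  Bins
#' are half-open `[lo, hi)` with the top bin closed, plus an underflow
#' class for genes below the lowest break.
#'
#' @param genome_a,genome_b Named character vectors of amino-acid sequences.
#' @param bins Strictly increasing identity breaks in `[0, 1]`; default
#'   `c(0.5, 0.7, 0.8, 0.9, 0.95, 1)`.
#' @param params A [clustering_params()] supplying `min_coverage`.
#' @return List with `counts` (named integer vector, underflow class first),
#'   `best_identity` (per gene of `a`), `best_hit` (gene ids in `b`).
#' @export
identity_bins <- function(genome_a, genome_b,
                          bins = c(0.5, 0.7, 0.8, 0.9, 0.95, 1),
                          params = clustering_params()) {
  if (!length(genome_a)) stop("empty proteome 'genome_a'", call. = FALSE)
  if (is.unsorted(bins, strictly = TRUE) || any(bins < 0) || any(bins > 1))
    stop("'bins' must be strictly increasing within [0, 1]", call. = FALSE)
  best <- stats::setNames(numeric(length(genome_a)), names(genome_a))
  hit <- stats::setNames(rep(NA_character_, length(genome_a)), names(genome_a))
  if (length(genome_b)) {
    ord_b <- order(names(genome_b))
    b_seqs <- genome_b[ord_b]
    b_chars <- strsplit(unname(b_seqs), "", fixed = TRUE)
    b_lens <- nchar(b_seqs)
    for (i in seq_along(genome_a)) {
      a_chars <- strsplit(genome_a[[i]], "", fixed = TRUE)[[1L]]
      ident <- numeric(length(b_seqs))
      eq <- which(b_lens == length(a_chars))
      if (length(eq))
        ident[eq] <- vapply(eq, function(j) sitewise_identity(a_chars, b_chars[[j]]),
                            numeric(1))
      ne <- setdiff(seq_along(b_seqs), eq)
      if (length(ne)) {
        res <- protein_identity(unname(b_seqs[ne]), genome_a[[i]])
        res$identity[res$coverage < params$min_coverage] <- 0
        ident[ne] <- res$identity
      }
      j <- which.max(ident)  # first index on ties = lexicographic id
      if (length(j) && ident[j] > 0) {
        best[i] <- ident[j]
        hit[i] <- names(b_seqs)[j]
      }
    }
  }
  k <- length(bins)
  labels <- sprintf("<%g", bins[1L])
  if (k > 1L) {
    labels <- c(labels, sprintf("[%g,%g)", bins[-k], bins[-1L]))
    labels[length(labels)] <- sprintf("[%g,%g]", bins[k - 1L], bins[k])
  }
  # half-open [lo, hi) bins with the top bin closed: the +Inf upper break
  # folds identities at exactly bins[k] into the top bin
  cuts <- cut(best, breaks = c(-Inf, bins[-k], Inf), right = FALSE)
  counts <- as.integer(table(cuts))
  names(counts) <- labels
  list(counts = counts, best_identity = best, best_hit = hit)
}

#' Adjusted Rand index of recovered families against truth labels
#'
#' @param matrix A `gene_family_matrix`.
#' @param truth Named character vector gene id -> true family (e.g. the
#'   `truth` field of a simulated [phage_genome_set()]).
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
family_recovery_ari <- function(matrix, truth) {
  stopifnot(inherits(matrix, "gene_family_matrix"))
  fam <- rep(names(matrix$membership), lengths(matrix$membership))
  names(fam) <- unlist(matrix$membership)
  common <- intersect(names(fam), names(truth))
  if (!length(common)) stop("no gene ids shared with truth labels", call. = FALSE)
  mclust::adjustedRandIndex(fam[common], truth[common])
}

#' Read / write proteome FASTA files
#'
#' One FASTA per genome; headers are `genome|gene` with a third `|family`
#' field carrying truth labels when available.  On reading, the genome id
#' is taken from the header prefix when headers contain `|`, else from the
#' file name.
#'
#' @param paths FASTA file paths (reader) .
#' @param genomes A [phage_genome_set()] (writer).
#' @param dir Output directory; created if needed.
#' @return `read_proteomes`: a [phage_genome_set()] (with truth labels when
#'   present in headers). `write_proteomes`: the file paths, invisibly.
#' @export
read_proteomes <- function(paths) {
  genomes <- list(); truth <- character(0)
  for (p in paths) {
    set <- Biostrings::readAAStringSet(p)
    if (!length(set)) stop(sprintf("'%s': empty FASTA", p), call. = FALSE)
    headers <- names(set)
    parts <- strsplit(headers, "|", fixed = TRUE)
    if (all(lengths(parts) >= 2L)) {
      gids <- vapply(parts, `[`, character(1), 1L)
      gene <- vapply(parts, `[`, character(1), 2L)
      fams <- vapply(parts, function(x) if (length(x) >= 3L) x[3L] else NA_character_,
                     character(1))
    } else {
      gids <- rep(sub("\\.(fa|fasta|faa)$", "", basename(p)), length(set))
      gene <- headers
      fams <- rep(NA_character_, length(set))
    }
    for (g in unique(gids)) {
      sel <- gids == g
      seqs <- stats::setNames(as.character(set[sel]), gene[sel])
      genomes[[g]] <- c(genomes[[g]], seqs)
      if (!all(is.na(fams[sel])))
        truth <- c(truth, stats::setNames(fams[sel], gene[sel]))
    }
  }
  phage_genome_set(genomes, truth = if (length(truth)) truth else NULL)
}

#' @rdname read_proteomes
#' @export
write_proteomes <- function(genomes, dir) {
  stopifnot(inherits(genomes, "phage_genome_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (g in names(genomes$genomes)) {
    seqs <- genomes$genomes[[g]]
    headers <- if (!is.null(genomes$truth))
      paste(g, names(seqs), genomes$truth[names(seqs)], sep = "|")
    else paste(g, names(seqs), sep = "|")
    set <- Biostrings::AAStringSet(stats::setNames(unname(seqs), headers))
    path <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(set, path, width = 70L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write / read a gene-family matrix as TSV
#'
#' The count matrix goes to `<path>` (families x genomes, first column
#' `family`); membership to `<path_membership>` as two columns
#' `family`, `gene`.
#'
#' @param matrix A `gene_family_matrix`.
#' @param path Count-matrix TSV path.
#' @param path_membership Membership TSV path (default: `path` with
#'   `_membership` inserted).
#' @return The paths, invisibly (writer); a `gene_family_matrix` (reader;
#'   `gene_genome` is reconstructed only when gene ids carry a `genome|`
#'   prefix).
#' @export
write_family_matrix <- function(matrix, path,
                                path_membership = sub("(\\.tsv)?$", "_membership.tsv",
                                                      path)[1L]) {
  stopifnot(inherits(matrix, "gene_family_matrix"))
  df <- data.frame(family = rownames(matrix$counts), matrix$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mem <- data.frame(family = rep(names(matrix$membership),
                                 lengths(matrix$membership)),
                    gene = unlist(matrix$membership), stringsAsFactors = FALSE)
  utils::write.table(mem, path_membership, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, path_membership))
}

#' @rdname write_family_matrix
#' @export
read_family_matrix <- function(path,
                               path_membership = sub("(\\.tsv)?$", "_membership.tsv",
                                                     path)[1L]) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$family
  storage.mode(counts) <- "integer"
  membership <- NULL
  gene_genome <- NULL
  if (file.exists(path_membership)) {
    mem <- utils::read.table(path_membership, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    membership <- split(mem$gene, mem$family)[rownames(counts)]
    has_prefix <- grepl("|", mem$gene, fixed = TRUE)
    if (all(has_prefix))
      gene_genome <- stats::setNames(vapply(strsplit(mem$gene, "|", fixed = TRUE),
                                            `[`, character(1), 1L), mem$gene)
  }
  structure(list(counts = counts, membership = membership,
                 gene_genome = gene_genome),
            class = "gene_family_matrix")
}
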