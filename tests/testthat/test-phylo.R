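test_that("Jaccard distances follow the shared/union set arithmetic", {
  m <- cbind(A = c(1, 1, 1, 0), B = c(1, 1, 1, 0), C = c(0, 0, 0, 1))
  d <- jaccard_distances(m)
  expect_equal(d["A", "B"], 0)           # identical sets
  expect_equal(d["A", "C"], 1)           # disjoint non-empty sets
  m2 <- cbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))
  expect_equal(jaccard_distances(m2)["A", "B"], 0.5)  # {1,2,3} vs {2,3,4}
  # empty vs empty pair is defined 0 with a warning
  m3 <- cbind(A = c(0, 0), B = c(0, 0), C = c(1, 1))
  expect_warning(d3 <- jaccard_distances(m3), "empty")
  expect_equal(d3["A", "B"], 0)
})

test_that("Jaccard distance satisfies the triangle inequality", {
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rbinom(30 * 5, 1, 0.5), 30, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
    m[1, ] <- 1  # avoid empty sets
    d <- jaccard_distances(m)
    for (a in 1:5) for (b in 1:5) for (cc in 1:5)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
  }
})

test_that("neighbor joining is exact on additive matrices", {
  for (i in 1:30) {
    tr <- rand_additive_tree(sample(5:8, 1), seed = 100 + i)
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(rf_distance(nj, tr), 0L)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)] - d)),
              1e-9)
  }
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(d)
  lens <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("neighbor joining agrees topologically with an independent implementation", {
  set.seed(53)
  for (i in 1:15) {
    m <- matrix(rbinom(40 * 6, 1, 0.5), 40, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
    m[1, ] <- 1
    d <- jaccard_distances(m)
    expect_equal(rf_distance(neighbor_joining(d), ape::nj(as.dist(d))), 0L)
  }
})

test_that("degenerate distance inputs are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), "symmetric")
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3[1, 2] <- d3[2, 1] <- NaN
  expect_error(neighbor_joining(d3), "NA/NaN")
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"), c("a", "b")))),
               ">= 3 taxa")
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister", {
  # a strongly non-additive matrix known to produce a negative estimate
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 5.9  # push one cherry branch negative
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length >= 0))
})

test_that("core-gene trees reduce to NJ of each family's p-distance matrix", {
  pg <- simulate_pangenome(gene_evolution_params(
    guide_tree = default_guide_tree(), n_core = 5, gain_rate = 0,
    n_singletons_mean = 0, divergence = 0.08, seed = 19))
  fams <- cluster_orthologs(pg)
  trees <- core_gene_trees(fams, pg)
  expect_length(trees, 5L)
  # definition check on the first family
  fam <- names(trees)[1]
  ids <- fams$membership[[fam]]
  gnm <- fams$gene_genome[ids]
  seqs <- stats::setNames(unlist(unname(pg$genomes))[ids], gnm)
  k <- length(seqs)
  d <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]])
  expect_equal(rf_distance(trees[[fam]], neighbor_joining(d)), 0L)
})

test_that("identical sequences across genomes give a star tree of zero lengths", {
  gs <- toy_genome_set(paste0("G", 1:4), n_fam = 3)
  fams <- cluster_orthologs(gs)
  trees <- core_gene_trees(fams, gs)
  for (tr in trees) expect_equal(max(tr$edge.length), 0)
})

test_that("gene trees simulated on a known genealogy mostly recover it", {
  guide <- default_guide_tree()
  pg <- simulate_pangenome(gene_evolution_params(
    guide_tree = guide, n_core = 30, gain_rate = 0, n_singletons_mean = 0,
    divergence = 0.12, seed = 29))
  fams <- cluster_orthologs(pg)
  trees <- core_gene_trees(fams, pg)
  rfs <- vapply(trees, function(tr) rf_distance(tr, guide), integer(1))
  expect_gt(mean(rfs == 0), 0.5)
})

test_that("p-distance handles unequal lengths and the Poisson correction", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAC"), 0.25)
  expect_equal(p_distance("AAAA", "AAAC", correction = "poisson"),
               -log(0.75))
  # gap columns are excluded from the comparison
  expect_lte(p_distance("AAAAAA", "AAAA"), 0.5)
  expect_error(p_distance("AA", "CC", correction = "poisson"), "undefined")
})

test_that("cherries of an unrooted tree are its mutually-sister leaf pairs", {
  tr <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  ch <- cherry_pairs(tr)
  expect_equal(nrow(ch), 3L)
  expect_setequal(apply(ch, 1, paste, collapse = "-"),
                  c("A-B", "C-D", "E-F"))
  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")  # caterpillar
  ch6 <- cherry_pairs(cat6)
  # unrooted caterpillar has exactly two cherries: the two end pairs
  expect_setequal(apply(ch6, 1, paste, collapse = "-"), c("A-B", "E-F"))
})

test_that("identical input trees dominate the co-grouping counts and consensus", {
  guide <- default_guide_tree()
  trees <- rep(list(guide), 50)
  cons <- cogrouping_consensus(trees)
  ch <- cherry_pairs(guide)
  for (r in seq_len(nrow(ch)))
    expect_equal(cons$counts[ch[r, 1], ch[r, 2]], 50L)
  expect_equal(sum(cons$counts > 0), 2L * nrow(ch))
  expect_equal(rf_distance(cons$tree, guide), 0L)
})

test_that("a cherry present in all 111 trees becomes a zero-distance sister pair", {
  guide <- default_guide_tree(paste0("P", 1:6))
  trees <- simulate_gene_trees(guide, 111, noise_prob = 0, seed = 2)
  cons <- cogrouping_consensus(trees)
  ch <- cherry_pairs(guide)
  d <- 1 - cons$counts / 111
  expect_equal(d[ch[1, 1], ch[1, 2]], 0)
  cons_ch <- apply(cherry_pairs(cons$tree), 1, paste, collapse = "-")
  expect_true(paste(ch[1, ], collapse = "-") %in% cons_ch)
})

test_that("the consensus is invariant to tree order and leaf relabelling", {
  guide <- default_guide_tree()
  trees <- simulate_gene_trees(guide, 40, noise_prob = 0.3, seed = 9)
  c1 <- cogrouping_consensus(trees)
  set.seed(1)
  c2 <- cogrouping_consensus(sample(trees))
  expect_identical(c1$counts, c2$counts)
  expect_equal(rf_distance(c1$tree, c2$tree), 0L)
  # relabel leaves consistently
  perm <- stats::setNames(paste0("X", 6:1), guide$tip.label)
  trees_rl <- lapply(trees, function(tr) {
    tr$tip.label <- unname(perm[tr$tip.label]); tr
  })
  c3 <- cogrouping_consensus(trees_rl)
  expect_equal(c3$counts[perm[rownames(c1$counts)], perm[colnames(c1$counts)]],
               c1$counts, ignore_attr = TRUE)
})

test_that("trees with mismatched leaf sets are rejected", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(cogrouping_consensus(list(t1, t2)), "identical leaf set")
  expect_error(rf_distance(t1, t2), "same leaf set")
})

test_that("Robinson-Foulds distance equals brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  set.seed(61)
  for (i in 1:15) {
    a <- ape::rtree(7, rooted = FALSE)
    b <- ape::rtree(7, rooted = FALSE)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_distance(a, b), rf_oracle(a, b))
  }
})

test_that("Newick and distance-matrix files round-trip", {
  tr <- rand_additive_tree(6, seed = 77)
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(rf_distance(tr, back), 0L)
  d <- ape::cophenetic.phylo(tr)
  p2 <- tempfile(fileext = ".tsv")
  write_distance_tsv(d, p2)
  expect_equal(read_distance_tsv(p2), d, tolerance = 1e-12)
})

test_that("binary fingerprint matrices flow through the same distance/tree path", {
  # ERIC-PCR style band presence matrix: strains x bands
  set.seed(83)
  bands <- matrix(rbinom(25 * 8, 1, 0.5), 25, 8,
                  dimnames = list(NULL, paste0("AB", sprintf("%02d", 1:8))))
  bands[1, ] <- 1
  d <- jaccard_distances(bands)
  expect_true(all(d >= 0 & d <= 1))
  tree <- neighbor_joining(d)
  expect_setequal(tree$tip.label, colnames(bands))
})
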