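test_that("two identical proteomes cluster into all single-copy core families", {
  gs <- toy_genome_set(c("GA", "GB"), n_fam = 10)
  fams <- cluster_orthologs(gs)
  expect_equal(nrow(fams$counts), 10L)
  expect_true(all(fams$counts == 1L))
  s <- pangenome_summary(fams)
  expect_equal(s$core, 10L)
  expect_equal(unname(s$singletons), c(0L, 0L))
})

test_that("mutually dissimilar genes each form their own singleton family", {
  gs <- toy_genome_set("GA", n_fam = 0, n_priv = 8, seed = 5)
  fams <- cluster_orthologs(gs)
  expect_equal(nrow(fams$counts), 8L)
  s <- pangenome_summary(fams)
  expect_equal(unname(s$singletons), 8L)
})

test_that("families partition the gene universe", {
  pg <- simulate_pangenome(gene_evolution_params(n_core = 20, gain_rate = 4,
                                                 n_singletons_mean = 6,
                                                 seed = 3))
  fams <- cluster_orthologs(pg)
  genes <- unlist(fams$membership)
  expect_equal(sort(unname(genes)), sort(names(pg$truth)))
  expect_false(anyDuplicated(genes) > 0)
  # column sums equal per-genome gene counts
  expect_equal(unname(colSums(fams$counts)),
               unname(lengths(pg$genomes)[colnames(fams$counts)]))
})

test_that("raising the identity threshold never decreases the family count", {
  pg <- simulate_pangenome(gene_evolution_params(n_core = 15, gain_rate = 3,
                                                 n_singletons_mean = 4,
                                                 divergence = 0.15, seed = 8))
  n_fams <- vapply(c(0.4, 0.6, 0.8, 0.95), function(th)
    nrow(cluster_orthologs(pg, clustering_params(min_identity = th))$counts),
    numeric(1))
  expect_true(all(diff(n_fams) >= 0))
})

test_that("clustering is invariant under genome input permutation", {
  pg <- simulate_pangenome(gene_evolution_params(n_core = 12, gain_rate = 3,
                                                 n_singletons_mean = 3,
                                                 seed = 21))
  perm <- phage_genome_set(rev(pg$genomes), truth = pg$truth)
  f1 <- cluster_orthologs(pg)
  f2 <- cluster_orthologs(perm)
  part <- function(f) sort(unname(vapply(f$membership, function(g)
    paste(sort(g), collapse = ","), character(1))))
  expect_identical(part(f1), part(f2))
})

test_that("ortholog recovery on a scaled synthetic pan-genome is near perfect", {
  pg <- simulate_pangenome(gene_evolution_params(n_core = 30, gain_rate = 6,
                                                 n_singletons_mean = 10,
                                                 divergence = 0.1, seed = 13))
  fams <- cluster_orthologs(pg)
  expect_gte(family_recovery_ari(fams, pg$truth), 0.95)
})

test_that("pan-genome summary equals brute-force set enumeration", {
  m <- matrix(1L, 10, 6, dimnames = list(sprintf("f%02d", 1:10),
                                         sprintf("g%d", 1:6)))
  s <- pangenome_summary(m)
  expect_equal(s$total, 10L)
  expect_equal(s$core, 10L)
  expect_true(all(s$singletons == 0L))

  m2 <- m; m2["f01", ] <- c(1L, 0L, 0L, 0L, 0L, 0L)
  s2 <- pangenome_summary(m2)
  expect_equal(unname(s2$singletons["g1"]), 1L)

  set.seed(17)
  for (i in 1:5) {
    r <- matrix(rpois(50 * 4, 0.6), 50, 4,
                dimnames = list(sprintf("f%02d", 1:50), sprintf("g%d", 1:4)))
    r <- r[rowSums(r) > 0, , drop = FALSE]
    expect_equal(pangenome_summary(r)[c("total", "core", "singletons", "shared_pairs")],
                 brute_pangenome_summary(r)[c("total", "core", "singletons", "shared_pairs")])
  }
})

test_that("identity bins place self-comparisons on top and empty targets below", {
  gs <- toy_genome_set("GA", n_fam = 6, seed = 2)
  prot <- gs$genomes$GA
  self <- identity_bins(prot, prot)
  expect_equal(unname(self$counts[length(self$counts)]), 6L)
  expect_equal(sum(self$counts), 6L)

  none <- identity_bins(prot, character(0))
  expect_equal(unname(none$counts[1L]), 6L)
  expect_error(identity_bins(character(0), prot), "empty proteome")
  expect_error(identity_bins(prot, prot, bins = c(0.5, 0.4)), "increasing")
})

test_that("identity histogram matches a direct per-pair identity oracle", {
  # pairs at controlled divergence: mutate each family copy independently
  set.seed(23)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  n <- 20; len <- 150
  a <- character(n); b <- character(n)
  for (i in 1:n) {
    anc <- sample(aa, len, replace = TRUE)
    d <- runif(1, 0, 0.45)
    flip <- function(x) {
      hit <- runif(len) < d / 2
      x[hit] <- sample(aa, sum(hit), replace = TRUE)
      x
    }
    a[i] <- paste(flip(anc), collapse = "")
    b[i] <- paste(flip(anc), collapse = "")
  }
  names(a) <- sprintf("a%02d", 1:n); names(b) <- sprintf("b%02d", 1:n)
  res <- identity_bins(a, b)
  # direct oracle: column identity of the true partner (same length, no
  # indels); families are far enough apart that it is the best hit
  direct <- vapply(1:n, function(i) {
    ca <- strsplit(a[[i]], "")[[1]]; cb <- strsplit(b[[i]], "")[[1]]
    mean(ca == cb)
  }, numeric(1))
  expect_equal(unname(res$best_identity), direct, tolerance = 1e-12)
  expect_equal(unname(res$best_hit), names(b))
  oracle_counts <- table(cut(direct, c(-Inf, 0.5, 0.7, 0.8, 0.9, 0.95, Inf),
                             right = FALSE))
  expect_equal(unname(res$counts), as.vector(oracle_counts))
})

test_that("proteome FASTA files round-trip with truth labels", {
  pg <- simulate_pangenome(gene_evolution_params(n_core = 8, gain_rate = 2,
                                                 n_singletons_mean = 2, seed = 6))
  dir <- tempfile(); dir.create(dir)
  write_proteomes(pg, dir)
  back <- read_proteomes(list.files(dir, full.names = TRUE))
  expect_setequal(names(back$genomes), names(pg$genomes))
  for (g in names(pg$genomes))
    expect_equal(back$genomes[[g]][names(pg$genomes[[g]])], pg$genomes[[g]])
  expect_equal(back$truth[names(pg$truth)], pg$truth)
})

test_that("family matrix TSV round-trips", {
  gs <- toy_genome_set(c("GA", "GB"), n_fam = 5, n_priv = 2)
  fams <- cluster_orthologs(gs)
  path <- tempfile(fileext = ".tsv")
  write_family_matrix(fams, path)
  back <- read_family_matrix(path)
  expect_equal(back$counts, fams$counts)
  expect_equal(back$membership, fams$membership)
})
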