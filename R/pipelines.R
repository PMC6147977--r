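#' Read a pipeline configuration file
#'
#' A single YAML file with optional `phylogenomics:` and `synergy:` sections
#' and a top-level `seed`.  Arguments passed directly to [run_phylogenomics()]
#' or [run_synergy()] override config values.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' not found", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

config_section <- function(config, section) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  stopifnot(is.list(config))
  out <- if (!is.null(config[[section]])) config[[section]] else config
  if (is.null(out$seed)) out$seed <- config$seed
  if (is.null(out$seed)) out$seed <- 1L
  out
}

#' Run the pan-genome phylogenomics workflow
#'
#' Chains the full analysis: obtain proteomes (from FASTA files named in
#' the config, or from the synthetic pan-genome generator), cluster
#' orthologs, summarize the pan-genome, build the presence/absence Jaccard
#' neighbor-joining dendrogram, reconstruct all single-copy core-gene
#' trees, and derive the co-grouping consensus tree.  All artifacts are
#' written deterministically under `out_dir`.
#'
#' Config keys (section `phylogenomics:` of a YAML file, or a flat list):
#' `proteomes` (character vector of FASTA paths) or `synthetic` (named list
#' of [gene_evolution_params()] arguments), `seed`, and optional
#' `min_identity`, `min_coverage`.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the in-memory objects (`genomes`,
#'   `families`, `summary`, `jaccard`, `tree`, `gene_trees`, `consensus`)
#'   and the written `paths`.
#' @export
run_phylogenomics <- function(config, out_dir = "phylogenomics_out") {
  cfg <- config_section(config, "phylogenomics")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(cfg$proteomes)) {
    genomes <- read_proteomes(cfg$proteomes)
  } else {
    syn <- if (is.null(cfg$synthetic)) list() else cfg$synthetic
    syn$seed <- derive_seed(cfg$seed, 1L)
    genomes <- simulate_pangenome(do.call(gene_evolution_params, syn))
  }
  message(sprintf("phylogenomics: %d genomes, %d genes",
                  length(genomes$genomes), sum(lengths(genomes$genomes))))

  cp <- clustering_params(
    min_identity = if (is.null(cfg$min_identity)) 0.5 else cfg$min_identity,
    min_coverage = if (is.null(cfg$min_coverage)) 0.5 else cfg$min_coverage)
  fams <- cluster_orthologs(genomes, cp)
  summ <- pangenome_summary(fams)
  message(sprintf("phylogenomics: %d families (%d single-copy core)",
                  summ$total, summ$core))

  d <- jaccard_distances(fams)
  tree <- neighbor_joining(d)
  gene_trees <- core_gene_trees(fams, genomes)
  consensus <- if (length(gene_trees) && ncol(fams$counts) >= 4L)
    cogrouping_consensus(gene_trees) else NULL

  paths <- c(
    family_matrix = file.path(out_dir, "family_matrix.tsv"),
    jaccard = file.path(out_dir, "jaccard_distances.tsv"),
    nj_tree = file.path(out_dir, "presence_absence_nj.nwk"),
    summary = file.path(out_dir, "summary.json"))
  write_family_matrix(fams, paths[["family_matrix"]])
  write_distance_tsv(d, paths[["jaccard"]])
  write_newick(tree, paths[["nj_tree"]])
  if (!is.null(consensus)) {
    paths["cogrouping"] <- file.path(out_dir, "cogrouping_counts.tsv")
    paths["consensus"] <- file.path(out_dir, "consensus_nj.nwk")
    utils::write.table(
      data.frame(label = rownames(consensus$counts), consensus$counts,
                 check.names = FALSE),
      paths[["cogrouping"]], sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(consensus$tree, paths[["consensus"]])
  }
  summary_json <- list(
    n_genomes = length(genomes$genomes),
    total_families = summ$total, core_families = summ$core,
    singletons = as.list(summ$singletons),
    n_core_gene_trees = length(gene_trees),
    presence_absence_tree = ape::write.tree(tree),
    consensus_tree = if (!is.null(consensus)) ape::write.tree(consensus$tree)
                     else NULL)
  jsonlite::write_json(summary_json, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genomes = genomes, families = fams, summary = summ,
                 jaccard = d, tree = tree, gene_trees = gene_trees,
                 consensus = consensus, paths = paths))
}

#' Run the phage-antibiotic synergy workflow
#'
#' Loads a plate-reader CSV or simulates a treatment grid with
#' [simulate_growth_kill()], computes end-OD and AUC per replicate and arm,
#' and tests every phage+antibiotic combination with
#' [evaluate_combinations()].  Artifacts: a per-arm metric table and a tidy
#' results CSV (one row per combination x metric).
#'
#' Config keys (section `synergy:`): `plate_csv` (path) or `scenario`, a
#' list with `strain`, `mois`, `antibiotics` (named list antibiotic ->
#' concentration vector), and optional [growth_kill_params()] overrides
#' under `params`; plus `seed`, `baseline_rule`, `n_reps`, `duration`.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with `experiment` (the od_series list),
#'   `arm_metrics` (data frame), `results` (data frame), `paths`.
#' @export
run_synergy <- function(config, out_dir = "synergy_out") {
  cfg <- config_section(config, "synergy")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  baseline_rule <- if (is.null(cfg$baseline_rule)) "phage_alone" else cfg$baseline_rule

  if (!is.null(cfg$plate_csv)) {
    experiment <- read_plate_csv(cfg$plate_csv)
  } else {
    sc <- cfg$scenario
    if (is.null(sc)) stop("synergy config needs 'plate_csv' or 'scenario'",
                          call. = FALSE)
    strain <- if (is.null(sc$strain)) "AB01" else sc$strain
    mois <- if (is.null(sc$mois)) 10^-c(1, 3, 5, 7) else as.numeric(sc$mois)
    abx <- if (is.null(sc$antibiotics))
      list(meropenem = c(16, 32, 64, 128, 256)) else sc$antibiotics
    pars <- do.call(growth_kill_params,
                    if (is.null(sc$params)) list() else sc$params)
    treatments <- list(treatment(strain))
    for (moi in mois) treatments <- c(treatments, list(treatment(strain, moi = moi)))
    for (ab in names(abx)) for (conc in abx[[ab]])
      treatments <- c(treatments, list(treatment(strain, antibiotic = ab,
                                                 concentration = conc)))
    for (moi in mois) for (ab in names(abx)) for (conc in abx[[ab]])
      treatments <- c(treatments, list(treatment(strain, moi = moi,
                                                 antibiotic = ab,
                                                 concentration = conc)))
    experiment <- simulate_growth_kill(
      pars, treatments,
      duration = if (is.null(cfg$duration)) 16 else cfg$duration,
      n_reps = if (is.null(cfg$n_reps)) 3L else cfg$n_reps,
      seed = derive_seed(cfg$seed, 2L))
  }
  message(sprintf("synergy: %d series over %d arms", length(experiment),
                  nrow(arm_table(experiment))))

  arm_metrics <- do.call(rbind, lapply(experiment, function(s) {
    tr <- s$treatment
    data.frame(strain = tr$strain_id, moi = tr$moi, antibiotic = tr$antibiotic,
               conc_mg_l = tr$concentration, replicate = s$replicate,
               end_od = end_od(s), auc = auc_trapezoid(s),
               stringsAsFactors = FALSE)
  }))
  results <- evaluate_combinations(experiment, baseline_rule = baseline_rule)
  if (!nrow(results))
    warning("no phage+antibiotic combination arms found", call. = FALSE)

  paths <- c(plate = file.path(out_dir, "plate_od590.csv"),
             arms = file.path(out_dir, "arm_metrics.csv"),
             results = file.path(out_dir, "synergy_results.csv"))
  write_plate_csv(experiment, paths[["plate"]])
  utils::write.csv(arm_metrics, paths[["arms"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(results, paths[["results"]], row.names = FALSE, quote = FALSE)
  invisible(list(experiment = experiment, arm_metrics = arm_metrics,
                 results = results, paths = paths))
}
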