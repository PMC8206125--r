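# File-to-file pipeline stages. Each stage_*() function is a thin,
# deterministic wrapper over the package's in-memory API: it reads the
# declared inputs, runs one analysis stage, and writes headered text tables.
# Rerunning a stage with an identical configuration and seed produces
# byte-identical primary outputs. The inst/cli/locusnet.R script dispatches
# to these functions from the shell.

#' Simulation stage: write a full synthetic study to a directory
#'
#' @param config A [sim_config()] or a path to a YAML file with its fields.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
stage_simulate <- function(config, outdir) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(sim_config, y)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  panels <- plant_disease_sets(sim$truth, sim$ref)
  deg <- simulate_deg_study(sim$truth)
  p <- function(f) file.path(outdir, f)
  write_expression(sim$ref, p("ref_expr.tsv"), config)
  write_expression(sim$test, p("test_expr.tsv"), config)
  write_tsv(sim$covariates, p("covariates.tsv"), config)
  write_gmt(panels$disease, p("panels_disease.gmt"))
  write_gmt(panels$control, p("panels_control.gmt"))
  write_tsv(deg$method_a, p("deg_a.tsv"), config)
  write_tsv(deg$method_b, p("deg_b.tsv"), config)
  write_tsv(deg$homology, p("homology.tsv"), config)
  writeLines(sim$truth$interval_genes, p("interval_genes.txt"))
  truth <- list(
    true_partition = as.list(sim$truth$true_partition),
    true_loadings = as.list(round(sim$truth$true_loadings, 10)),
    interval_genes = sim$truth$interval_genes,
    interval_weak = sim$truth$interval_weak,
    planted_disease_members = panels$planted,
    deg_truth = as.list(deg$deg_truth[deg$deg_truth != 0]))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list.files(outdir, full.names = TRUE))
}

#' Preprocessing stage: filter, outlier removal, residualization
#'
#' @param expr_path Expression TSV (genes x samples).
#' @param covariates_path Covariate TSV (or NULL to skip residualization).
#' @param out Output TSV for the analysis-ready matrix.
#' @param log_path Optional JSON log of removed genes/samples and design
#'   columns.
#' @param max_missing_fraction,z_cut See [preprocess_expression()].
#' @return Invisibly, `out`.
#' @export
stage_preprocess <- function(expr_path, covariates_path, out,
                             log_path = NULL, max_missing_fraction = 0.5,
                             z_cut = -2.5) {
  expr <- read_expression(expr_path)
  cov <- if (!is.null(covariates_path)) read_covariates(covariates_path)
  res <- preprocess_expression(expr, cov, max_missing_fraction, z_cut)
  cfg <- list(max_missing_fraction = max_missing_fraction, z_cut = z_cut)
  write_expression(res, out, cfg)
  if (!is.null(log_path)) {
    plog <- attr(res, "preprocess_log")
    plog$design_columns <- attr(res, "design_columns")
    jsonlite::write_json(plog, log_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Network stage: adjacency, TOM, modules, eigengenes, kME, meta-modules
#'
#' @param expr_path Preprocessed expression TSV.
#' @param outdir Output directory.
#' @param config A [network_config()].
#' @return Invisibly, the [build_network()] result.
#' @export
stage_network <- function(expr_path, outdir, config = network_config()) {
  expr <- read_expression(expr_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- build_network(expr, config)
  p <- function(f) file.path(outdir, f)
  write_tsv(net$sft, p("sft.tsv"), config)
  if (!is.null(net$eigengenes)) {
    write_module_table(net$partition, net$kme, p("modules.tsv"), config)
    eg <- net$eigengenes$eigengenes
    egdf <- data.frame(module = rownames(eg), as.data.frame(eg),
                       check.names = FALSE)
    write_tsv(egdf, p("eigengenes.tsv"), config)
    km <- data.frame(gene = rownames(net$kme$r),
                     as.data.frame(net$kme$r), check.names = FALSE)
    write_tsv(km, p("kme.tsv"), config)
    if (!is.null(net$meta_modules))
      write_tsv(data.frame(module = names(net$meta_modules),
                           meta_module = as.integer(net$meta_modules)),
                p("meta_modules.tsv"), config)
  } else {
    write_module_table(net$partition, NULL, p("modules.tsv"), config)
  }
  if (!is.null(net$dendrogram)) {
    dd <- net$dendrogram
    write_tsv(data.frame(merge1 = dd$merge[, 1], merge2 = dd$merge[, 2],
                         height = dd$height),
              p("dendrogram.tsv"), config)
  }
  invisible(net)
}

#' Preservation stage: Zsummary.pres and Zsummary.qual tables
#'
#' @param ref_path,test_path Expression TSVs.
#' @param modules_path Module table from [stage_network()].
#' @param out Output TSV.
#' @param n_perm Permutations for preservation.
#' @param n_splits,n_perm_qual Splits/permutations for quality (set
#'   `n_splits = 0` to skip the quality analysis).
#' @param seed RNG seed.
#' @param beta Soft-threshold power.
#' @return Invisibly, the combined data frame.
#' @export
stage_preserve <- function(ref_path, test_path, modules_path, out,
                           n_perm = 200, n_splits = 50, n_perm_qual = 30,
                           seed = 1, beta = 8) {
  ref <- read_expression(ref_path)
  test <- read_expression(test_path)
  part <- read_module_table(modules_path)$partition
  pres <- z_summary_pres(ref, test, part, n_perm = n_perm, seed = seed,
                         beta = beta)
  tab <- data.frame(module = pres$module, module_size = pres$module_size,
                    size_used = pres$size_used,
                    z_density = pres$z_density,
                    z_connectivity = pres$z_connectivity,
                    z_summary_pres = pres$z_summary,
                    category_pres = pres$category)
  if (n_splits > 0) {
    qual <- z_summary_qual(ref, part, n_splits = n_splits,
                           n_perm = n_perm_qual, seed = seed, beta = beta)
    tab$z_summary_qual <- qual$z_summary[match(tab$module, qual$module)]
    tab$category_qual <- qual$category[match(tab$module, qual$module)]
  }
  cfg <- list(n_perm = n_perm, n_splits = n_splits, seed = seed, beta = beta)
  write_tsv(tab, out, cfg)
  invisible(tab)
}

#' Prioritization stage: top neighbors, enrichment screen, drivers
#'
#' @param expr_path Preprocessed expression TSV.
#' @param modules_path Module table from [stage_network()].
#' @param interval_path Text file with one interval gene per line.
#' @param disease_gmt,control_gmt Panel GMT paths.
#' @param outdir Output directory.
#' @param rho_cut,alpha,kme_cut,alpha_adj Thresholds.
#' @return Invisibly, the [prioritize_interval()] result.
#' @export
stage_prioritize <- function(expr_path, modules_path, interval_path,
                             disease_gmt, control_gmt, outdir,
                             rho_cut = 0.5, alpha = 0.05, kme_cut = 0.8,
                             alpha_adj = 0.05) {
  expr <- read_expression(expr_path)
  part <- read_module_table(modules_path)$partition
  interval <- readLines(interval_path)
  interval <- interval[nzchar(interval)]
  disease <- read_gmt(disease_gmt)
  control <- read_gmt(control_gmt)
  eg <- module_eigengenes(expr, part)
  res <- prioritize_interval(expr, part, eg$kme, interval, disease, control,
                             rho_cut = rho_cut, alpha = alpha,
                             kme_cut = kme_cut, alpha_adj = alpha_adj)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  cfg <- list(rho_cut = rho_cut, alpha = alpha, kme_cut = kme_cut,
              alpha_adj = alpha_adj)
  nb <- do.call(rbind, lapply(res$neighbor_sets, function(s)
    if (nrow(s$members) > 0)
      data.frame(seed = s$seed, module = s$module, s$members)))
  if (is.null(nb))
    nb <- data.frame(seed = character(0), module = integer(0),
                     gene = character(0), rho = numeric(0), p = numeric(0))
  write_tsv(nb, p("top_neighbors.tsv"), cfg)
  write_tsv(res$hubs, p("hubs.tsv"), cfg)
  write_tsv(res$screen$overlaps, p("overlaps.tsv"), cfg)
  dr <- res$drivers
  drtab <- rbind(
    data.frame(gene = dr$prioritized_seeds, role = "seed",
               stringsAsFactors = FALSE),
    data.frame(gene = dr$partner_drivers, role = "partner",
               stringsAsFactors = FALSE))
  prov <- vapply(drtab$gene, function(g) {
    rows <- dr$provenance[dr$provenance$gene == g, , drop = FALSE]
    if (nrow(rows) == 0) "" else
      paste(sprintf("%s:%s", rows$seed, rows$gene_set), collapse = ",")
  }, "")
  drtab$provenance <- prov
  write_tsv(drtab, p("drivers.tsv"), cfg)
  jsonlite::write_json(
    list(specificity = res$screen$specificity,
         skipped_seeds = res$screen$skipped_seeds),
    p("specificity.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  targets <- network_target_sets(part, interval, res$neighbor_sets, dr)
  jsonlite::write_json(unclass(targets), p("targets.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' DEG-validation stage: consensus, homology filter, three-scale enrichment
#'
#' @param deg_a_path,deg_b_path DEG TSVs from the two methods.
#' @param homology_path Two-column homology TSV.
#' @param targets_path targets.json from [stage_prioritize()].
#' @param expr_path Preprocessed expression TSV supplying the network-gene
#'   universe.
#' @param out Output TSV.
#' @param alpha Nominal threshold.
#' @return Invisibly, the validation data frame.
#' @export
stage_validate_degs <- function(deg_a_path, deg_b_path, homology_path,
                                targets_path, expr_path, out, alpha = 0.05) {
  a <- read_deg_table(deg_a_path)
  b <- read_deg_table(deg_b_path)
  hom <- read_homology(homology_path)
  tg <- jsonlite::read_json(targets_path, simplifyVector = TRUE)
  targets <- structure(list(broad = tg$broad, subnetwork = tg$subnetwork,
                            drivers = tg$drivers),
                       class = "network_target_sets")
  expr <- read_expression(expr_path)
  cons <- consensus_degs(a, b, alpha)
  degs <- map_homologs(cons$gene, hom)
  universe <- intersect(map_homologs(a$gene, hom), rownames(expr))
  tab <- validate_enrichment(degs, targets, universe, alpha)
  write_tsv(tab, out, list(alpha = alpha))
  invisible(tab)
}
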