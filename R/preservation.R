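# Module preservation (reproducibility in an independent test cohort) and
# quality (robustness within the reference cohort) via permutation-
# standardized composites of density and connectivity statistics.
#
# Default statistic roster: four density statistics evaluated in the test
# cohort (mean intramodular signed adjacency, proportion of variance
# explained by the module eigengene, mean sign-aware kME, mean intramodular
# correlation) and three connectivity statistics evaluated between cohorts
# (correlation of intramodular connectivity profiles, of kME profiles, and
# of the vectorized intramodular correlation matrices). Component Z scores
# are summarized by the median within each class; the composite Zsummary is
# the mean of the two medians.

density_stat_names <- c("mean_adj", "prop_var", "mean_kme", "mean_cor")
connectivity_stat_names <- c("cor_kim", "cor_kme", "cor_cor")

# Precompute per-cohort quantities over a fixed gene universe.
pres_prep <- function(expr, universe) {
  x <- expr[universe, , drop = FALSE]
  xs <- row_standardize(x)
  cc <- tcrossprod(xs) / (ncol(x) - 1)
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc) <- 1
  list(std = xs, cor = cc, n_samples = ncol(x))
}

# Module eigengene and kME of a gene set from a prepared cohort.
pres_me_kme <- function(prep, idx) {
  x <- prep$std[idx, , drop = FALSE]
  cp <- crossprod(x)
  eg <- eigen(cp, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  kme <- as.vector(x %*% v1)
  kme <- kme / (sqrt(rowSums(x^2)) * sqrt(sum(v1^2)))
  if (mean(kme) < 0) kme <- -kme
  list(kme = pmin(pmax(kme, -1), 1),
       prop_var = eg$values[1] / sum(pmax(eg$values, 0)))
}

# Per-cohort profile bundle of a gene set: intramodular connectivity, kME,
# vectorized intramodular correlations, plus the density statistics of the
# set in that cohort.
pres_profiles <- function(prep, idx, beta) {
  cc <- prep$cor[idx, idx]
  ut <- upper.tri(cc)
  aa <- ((1 + cc) / 2)^beta
  mk <- pres_me_kme(prep, idx)
  list(kim = rowSums(aa) - 1, kme = mk$kme, corvec = cc[ut],
       density = c(mean_adj = mean(aa[ut]), prop_var = mk$prop_var,
                   mean_kme = mean(mk$kme), mean_cor = mean(cc[ut])))
}

# Full 7-statistic vector: density of `idx_test` in the test cohort, and
# connectivity agreement between the reference profiles (`ref_prof`,
# computed on the observed module) and the test profiles of `idx_test`.
# Under the label-permutation null, idx_test is a random gene set while the
# reference side keeps the observed module, mimicking a random permutation
# of module assignments in the test network.
pres_stats <- function(prep_test, ref_prof, idx_test, beta) {
  tp <- pres_profiles(prep_test, idx_test, beta)
  c(tp$density,
    cor_kim = stats::cor(ref_prof$kim, tp$kim),
    cor_kme = stats::cor(ref_prof$kme, tp$kme),
    cor_cor = stats::cor(ref_prof$corvec, tp$corvec))
}

#' Preservation/quality statistics of one module
#'
#' Computes the density statistics of a module in `expr` and, when a paired
#' reference is given, the cross-cohort connectivity statistics.
#'
#' @param expr Genes x samples matrix (the "test" side).
#' @param partition Named integer vector of module labels.
#' @param module Module label to evaluate (at least 3 genes present).
#' @param ref_expr Optional paired reference matrix; when NULL, `expr` is
#'   used as its own reference (connectivity statistics are then 1).
#' @param beta Soft-threshold power used for the adjacency-based statistics.
#' @return Named numeric vector of the 7 statistics.
#' @export
module_stats <- function(expr, partition, module, ref_expr = NULL, beta = 8) {
  genes <- names(partition)[partition == module]
  genes <- intersect(genes, rownames(expr))
  if (!is.null(ref_expr)) genes <- intersect(genes, rownames(ref_expr))
  if (length(genes) < 3) stop("module must have at least 3 genes present")
  if (is.null(ref_expr)) ref_expr <- expr
  prep_t <- pres_prep(expr, genes)
  prep_r <- pres_prep(ref_expr, genes)
  ref_prof <- pres_profiles(prep_r, seq_along(genes), beta)
  pres_stats(prep_t, ref_prof, seq_along(genes), beta)
}

pres_composite <- function(obs, null_mat, warn_prefix = "") {
  mu <- colMeans(null_mat)
  sdv <- apply(null_mat, 2, stats::sd)
  z <- (obs - mu) / sdv
  degenerate <- !is.finite(z)
  if (any(degenerate)) {
    warning(warn_prefix, "dropping statistic(s) with zero permutation sd: ",
            paste(names(obs)[degenerate], collapse = ", "))
  }
  zd <- z[density_stat_names][is.finite(z[density_stat_names])]
  zc <- z[connectivity_stat_names][is.finite(z[connectivity_stat_names])]
  z_density <- stats::median(zd)
  z_connectivity <- stats::median(zc)
  c(z_density = z_density, z_connectivity = z_connectivity,
    z_summary = (z_density + z_connectivity) / 2)
}

#' Classify a Zsummary score
#'
#' Z < 2: no evidence; 2 <= Z <= 10: moderate evidence; Z > 10: strong
#' evidence. The boundaries use the closed-interval convention on the
#' moderate side.
#'
#' @param z Finite numeric (vectorized).
#' @return Character vector in {"none", "moderate", "strong"}.
#' @export
classify_preservation <- function(z) {
  if (any(!is.finite(z))) stop("non-finite Zsummary")
  ifelse(z < 2, "none", ifelse(z <= 10, "moderate", "strong"))
}

#' Permutation-standardized module preservation (Zsummary.pres)
#'
#' For each named module, observed density statistics are computed in the
#' test cohort and connectivity statistics between cohorts; the null is
#' built by drawing random gene sets of the same size from the union of
#' assigned genes (background excluded), mimicking a random permutation of
#' module labels over the test network. Each statistic is standardized as
#' Z = (obs - mean_perm)/sd_perm; Zsummary is the mean of the density and
#' connectivity Z medians. Modules larger than `max_module_size` are reduced
#' once by seeded random subsampling.
#'
#' @param ref_expr,test_expr Genes x samples matrices sharing gene ids.
#' @param partition Named integer vector from the reference network.
#' @param n_perm Number of permutations (default 200).
#' @param max_module_size Subsampling cap (default 1000).
#' @param seed RNG seed.
#' @param beta Soft-threshold power for adjacency statistics.
#' @return Data frame: module, module_size, size_used, z_density,
#'   z_connectivity, z_summary, category, n_permutations.
#' @export
z_summary_pres <- function(ref_expr, test_expr, partition, n_perm = 200,
                           max_module_size = 1000, seed = 1, beta = 8) {
  assert_expr_matrix(ref_expr, "ref_expr")
  assert_expr_matrix(test_expr, "test_expr")
  if (n_perm < 2) stop("n_perm must be at least 2")
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  labs <- sort(unique(partition[partition > 0]))
  if (length(labs) == 0) stop("no named modules to evaluate")
  with_seed(seed, {
    # sorted gene sets make the permutation stream independent of the
    # caller's gene ordering, so Zsummary is exactly reproducible
    mod_genes <- list()
    for (q in labs) {
      mem <- sort(intersect(names(partition)[partition == q], common))
      full <- sum(partition == q)
      if (length(mem) < 0.5 * full)
        stop("gene overlap between cohorts covers < 50% of module ", q)
      if (length(mem) > max_module_size)
        mem <- sort(sample(mem, max_module_size))
      mod_genes[[as.character(q)]] <- mem
    }
    universe <- sort(intersect(names(partition)[partition > 0], common))
    prep_r <- pres_prep(ref_expr, universe)
    prep_t <- pres_prep(test_expr, universe)
    uidx <- stats::setNames(seq_along(universe), universe)

    rows <- list()
    for (q in names(mod_genes)) {
      idx <- uidx[mod_genes[[q]]]
      ref_prof <- pres_profiles(prep_r, idx, beta)
      obs <- pres_stats(prep_t, ref_prof, idx, beta)
      null_mat <- t(vapply(seq_len(n_perm), function(b) {
        ridx <- sample(length(universe), length(idx))
        pres_stats(prep_t, ref_prof, ridx, beta)
      }, obs))
      comp <- pres_composite(obs, null_mat,
                             warn_prefix = paste0("module ", q, ": "))
      rows[[q]] <- data.frame(module = as.integer(q),
                              module_size = sum(partition == as.integer(q)),
                              size_used = length(idx),
                              z_density = comp["z_density"],
                              z_connectivity = comp["z_connectivity"],
                              z_summary = comp["z_summary"],
                              category = classify_preservation(
                                comp["z_summary"]),
                              n_permutations = n_perm,
                              row.names = NULL)
    }
    do.call(rbind, rows)
  })
}

#' Module quality by repeated random splits (Zsummary.qual)
#'
#' Applies the preservation composite to repeated random half-splits of the
#' reference cohort (half A acting as reference, half B as test; the larger
#' half takes the extra sample when the count is odd), and averages the
#' resulting Zsummary over splits. Categories use the same thresholds as
#' preservation.
#'
#' @param ref_expr Reference genes x samples matrix (>= 20 samples).
#' @param partition Named integer vector.
#' @param n_splits Number of random splits (default 200).
#' @param n_perm Permutations per split used to standardize the composite.
#' @param max_module_size Subsampling cap.
#' @param seed RNG seed.
#' @param beta Soft-threshold power.
#' @return Data frame: module, module_size, size_used, z_density,
#'   z_connectivity, z_summary, category, n_splits.
#' @export
z_summary_qual <- function(ref_expr, partition, n_splits = 200, n_perm = 30,
                           max_module_size = 1000, seed = 1, beta = 8) {
  assert_expr_matrix(ref_expr, "ref_expr")
  if (n_splits < 1) stop("n_splits must be at least 1")
  if (ncol(ref_expr) < 20) stop("need at least 20 samples for quality splits")
  labs <- sort(unique(partition[partition > 0]))
  if (length(labs) == 0) stop("no named modules to evaluate")
  with_seed(seed, {
    mod_genes <- list()
    for (q in labs) {
      mem <- sort(intersect(names(partition)[partition == q],
                            rownames(ref_expr)))
      if (length(mem) < 3) stop("module ", q, " has fewer than 3 genes")
      if (length(mem) > max_module_size)
        mem <- sort(sample(mem, max_module_size))
      mod_genes[[as.character(q)]] <- mem
    }
    universe <- sort(intersect(names(partition)[partition > 0],
                               rownames(ref_expr)))
    uidx <- stats::setNames(seq_along(universe), universe)
    ns <- ncol(ref_expr)
    n_b <- ns %/% 2                      # test half; larger half is reference
    acc <- matrix(0, length(mod_genes), 3,
                  dimnames = list(names(mod_genes),
                                  c("z_density", "z_connectivity",
                                    "z_summary")))
    for (s in seq_len(n_splits)) {
      test_idx <- sample(ns, n_b)
      prep_r <- pres_prep(ref_expr[, -test_idx, drop = FALSE], universe)
      prep_t <- pres_prep(ref_expr[, test_idx, drop = FALSE], universe)
      for (q in names(mod_genes)) {
        idx <- uidx[mod_genes[[q]]]
        ref_prof <- pres_profiles(prep_r, idx, beta)
        obs <- pres_stats(prep_t, ref_prof, idx, beta)
        null_mat <- t(vapply(seq_len(n_perm), function(b) {
          ridx <- sample(length(universe), length(idx))
          pres_stats(prep_t, ref_prof, ridx, beta)
        }, obs))
        comp <- suppressWarnings(pres_composite(obs, null_mat))
        acc[q, ] <- acc[q, ] + comp
      }
    }
    acc <- acc / n_splits
    data.frame(module = as.integer(names(mod_genes)),
               module_size = vapply(names(mod_genes), function(q)
                 sum(partition == as.integer(q)), 0L),
               size_used = lengths(mod_genes),
               z_density = acc[, "z_density"],
               z_connectivity = acc[, "z_connectivity"],
               z_summary = acc[, "z_summary"],
               category = classify_preservation(acc[, "z_summary"]),
               n_splits = n_splits, row.names = NULL)
  })
}
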