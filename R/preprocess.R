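# Preprocessing: missingness/variance filters, sample-network outlier
# detection, and covariate residualization. Input is assumed to be
# normalized, log2-scale expression (genes x samples); no count-level
# normalization is performed here.

#' Filter genes and samples by missingness, then zero-variance genes
#'
#' Iteratively removes genes and then samples whose fraction of missing
#' entries exceeds `max_missing_fraction` (default 0.5) until stable, then
#' removes genes with zero variance. Counts removed at each step are attached
#' as the `"filter_log"` attribute and reported via `message()`.
#'
#' @param expr Genes x samples matrix (may contain NA).
#' @param max_missing_fraction Maximum tolerated missing fraction.
#' @return The filtered matrix (no missing-row/column offenders, no
#'   zero-variance genes among fully-observed values).
#' @export
filter_genes_samples <- function(expr, max_missing_fraction = 0.5) {
  assert_expr_matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  log_steps <- list()
  repeat {
    g_miss <- rowMeans(is.na(expr))
    drop_g <- g_miss > max_missing_fraction
    if (any(drop_g)) {
      log_steps <- c(log_steps, list(list(step = "genes_missing",
                                          removed = sum(drop_g))))
      expr <- expr[!drop_g, , drop = FALSE]
      if (nrow(expr) == 0) stop("all genes removed by missingness filter")
    }
    s_miss <- colMeans(is.na(expr))
    drop_s <- s_miss > max_missing_fraction
    if (any(drop_s)) {
      log_steps <- c(log_steps, list(list(step = "samples_missing",
                                          removed = sum(drop_s))))
      expr <- expr[, !drop_s, drop = FALSE]
      if (ncol(expr) < 2) stop("fewer than 2 samples remain after filtering")
    }
    if (!any(drop_g) && !any(drop_s)) break
  }
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  drop_v <- !is.finite(v) | v == 0
  if (any(drop_v)) {
    log_steps <- c(log_steps, list(list(step = "genes_zero_variance",
                                        removed = sum(drop_v))))
    expr <- expr[!drop_v, , drop = FALSE]
    if (nrow(expr) == 0) stop("all genes removed by variance filter")
  }
  for (s in log_steps)
    message("filter: removed ", s$removed, " (", s$step, ")")
  attr(expr, "filter_log") <- log_steps
  expr
}

#' Detect outlier samples by standardized sample-network connectivity
#'
#' Builds the sample-sample correlation network A = (1 + cor)/2, computes
#' each sample's connectivity k (column sums minus the self term),
#' standardizes it (Z.k), and flags samples with Z.k below `z_cut`
#' (default -2.5). One pass, no iteration.
#'
#' @param expr Genes x samples matrix (complete cases used).
#' @param z_cut Standardized connectivity cut (negative).
#' @return Character vector of flagged sample ids (possibly empty), with the
#'   Z.k vector attached as attribute `"z_k"`.
#' @export
detect_outlier_samples <- function(expr, z_cut = -2.5) {
  assert_expr_matrix(expr)
  if (ncol(expr) < 10) stop("need at least 10 samples for outlier detection")
  cc <- stats::cor(expr, use = "pairwise.complete.obs")
  a <- (1 + cc) / 2
  k <- colSums(a) - 1
  z <- (k - mean(k)) / stats::sd(k)
  flagged <- colnames(expr)[z < z_cut]
  attr(flagged, "z_k") <- stats::setNames(z, colnames(expr))
  flagged
}

# Build the covariate design matrix: categoricals one-hot with the reference
# level dropped, continuous covariates centered. The death classification is
# treated as an unordered categorical (the Hardy scale is not
# interval-valued); age accepts numeric years or bracket strings like
# "60-69", which are mapped to decade midpoints.
covariate_design <- function(cov, sample_ids) {
  rownames(cov) <- cov$sample_id
  missing <- setdiff(sample_ids, cov$sample_id)
  if (length(missing) > 0)
    stop("covariate rows missing for samples: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cov <- cov[sample_ids, , drop = FALSE]
  if (anyNA(cov)) stop("missing covariate values for retained samples")
  parts <- list()
  for (nm in setdiff(names(cov), "sample_id")) {
    v <- cov[[nm]]
    if (nm == "age" && is.character(v)) {
      lo <- suppressWarnings(as.numeric(sub("-.*", "", v)))
      hi <- suppressWarnings(as.numeric(sub(".*-", "", v)))
      if (anyNA(lo) || anyNA(hi)) stop("unparseable age brackets")
      v <- (lo + hi) / 2
    }
    if (nm %in% c("age", "pmi")) v <- as.numeric(v)
    if (nm == "death_class") v <- factor(v)
    if (is.numeric(v)) {
      parts[[nm]] <- matrix(v - mean(v), ncol = 1,
                            dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        parts[[nm]] <- matrix(0, length(v), 0)
      } else {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, "_", levels(f)[-1])
        parts[[nm]] <- mm
      }
    }
  }
  x <- cbind(intercept = 1, do.call(cbind, parts))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  x
}

#' Remove covariate-mediated variance by per-gene least squares
#'
#' Regresses each gene on the covariate design (sex, age, death
#' classification, postmortem interval, batch — whichever columns are
#' present) and returns the residuals with each gene's grand mean added
#' back. Residuals are exactly orthogonal to every design column, so the
#' operation is idempotent.
#'
#' @param expr Genes x samples matrix without missing values.
#' @param cov Covariate data frame with a `sample_id` column.
#' @return Residualized matrix of the same shape, with the design column
#'   names attached as attribute `"design_columns"`.
#' @export
residualize <- function(expr, cov) {
  assert_expr_matrix(expr)
  if (anyNA(expr)) stop("residualize requires a complete matrix; filter first")
  x <- covariate_design(cov, colnames(expr))
  qx <- qr(x)
  # residuals for all genes at once: t(resid) = Y' - X (X'X)^-1 X' Y'
  yt <- t(expr)
  res <- yt - x %*% qr.coef(qx, yt)
  out <- t(res) + rowMeans(expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "design_columns") <- colnames(x)
  out
}

#' One-call preprocessing: filter, outlier removal, residualization
#'
#' Applies [filter_genes_samples()], [detect_outlier_samples()] (outliers
#' removed before residualization by default), and [residualize()] when a
#' covariate table is supplied.
#'
#' @param expr Raw genes x samples matrix (log2 scale).
#' @param cov Optional covariate data frame.
#' @param max_missing_fraction Missingness threshold.
#' @param z_cut Outlier cut on standardized sample connectivity.
#' @param outliers_before_residualization Order of the two steps.
#' @return The analysis-ready matrix, with a `"preprocess_log"` attribute.
#' @export
preprocess_expression <- function(expr, cov = NULL,
                                  max_missing_fraction = 0.5, z_cut = -2.5,
                                  outliers_before_residualization = TRUE) {
  expr <- filter_genes_samples(expr, max_missing_fraction)
  flog <- attr(expr, "filter_log")
  out_ids <- character(0)
  do_outliers <- function(e) {
    ids <- if (ncol(e) >= 10) detect_outlier_samples(e, z_cut) else character(0)
    out_ids <<- as.character(ids)
    if (length(ids) > 0) e[, !colnames(e) %in% ids, drop = FALSE] else e
  }
  if (outliers_before_residualization) expr <- do_outliers(expr)
  if (!is.null(cov)) expr <- residualize(expr, cov)
  if (!outliers_before_residualization) expr <- do_outliers(expr)
  attr(expr, "preprocess_log") <- list(filter = flog,
                                       outliers_removed = out_ids)
  expr
}
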