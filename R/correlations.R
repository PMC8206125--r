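# Three correlation contracts are used deliberately in this pipeline:
# network similarity uses the robust biweight midcorrelation, eigengene-based
# connectivity (kME) uses Pearson, and top-neighbor screening uses Spearman.

# Tukey biweight midweights of one vector: u = (x - med)/(9 MAD),
# w = (1 - u^2)^2 on |u| < 1, else 0. Returns the weighted, median-centered
# vector, or NULL when MAD is zero (caller falls back to mean-centering).
bicor_prep <- function(x) {
  med <- stats::median(x)
  mad_x <- stats::median(abs(x - med))
  if (mad_x == 0) return(NULL)
  u <- (x - med) / (9 * mad_x)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation in which each observation is weighted by its Tukey
#' biweight relative to the median and the median absolute deviation, damping
#' the influence of outlying samples. When a vector has zero MAD (more than
#' half its values tied), the function falls back to the Pearson correlation
#' for that pair with a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 4 samples).
#' @return A correlation in \[-1, 1\].
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.6 * x + rnorm(50)
#' bicor(x, y)
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("bicor needs at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop("bicor does not accept missing values")
  xg <- bicor_prep(x)
  yg <- bicor_prep(y)
  if (is.null(xg) || is.null(yg)) {
    warning("zero median absolute deviation; falling back to Pearson")
    return(stats::cor(x, y))
  }
  sum(xg * yg) / sqrt(sum(xg^2) * sum(yg^2))
}

#' Biweight midcorrelation matrix of a gene expression matrix
#'
#' Computes all pairwise biweight midcorrelations between the rows (genes) of
#' an expression matrix. Rows with zero median absolute deviation fall back
#' to Pearson-style mean-centering (with a single warning naming the count).
#'
#' @param expr Numeric genes x samples matrix with at least 4 samples.
#' @return A symmetric genes x genes correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(expr) {
  assert_expr_matrix(expr)
  if (ncol(expr) < 4) stop("bicor needs at least 4 samples")
  n <- nrow(expr)
  g <- matrix(0, n, ncol(expr), dimnames = dimnames(expr))
  fallback <- 0L
  for (i in seq_len(n)) {
    gi <- bicor_prep(expr[i, ])
    if (is.null(gi)) {
      fallback <- fallback + 1L
      gi <- expr[i, ] - mean(expr[i, ])
    }
    g[i, ] <- gi
  }
  if (fallback > 0)
    warning(fallback, " gene(s) had zero MAD; Pearson fallback used for them")
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- Inf
  g <- g / nrm
  cc <- tcrossprod(g)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

# Two-sided p-value for a correlation r at sample size n via the
# t = r * sqrt((n-2)/(1-r^2)) transform. Vectorized.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df, lower.tail = FALSE)
}

# Spearman rho of a seed vector against rows of a matrix, with two-sided
# t-approximation p-values. Ties handled by midranks.
spearman_vs_rows <- function(seed_vec, mat) {
  n <- length(seed_vec)
  rs <- rank(seed_vec)
  rm_ <- t(apply(mat, 1, rank))
  rs <- (rs - mean(rs)) / stats::sd(rs)
  rmc <- rm_ - rowMeans(rm_)
  sdr <- sqrt(rowSums(rmc^2) / (n - 1))
  sdr[sdr == 0] <- Inf
  rho <- unname(as.vector((rmc %*% rs) / (n - 1)) / sdr)
  rho <- pmin(pmax(rho, -1), 1)
  list(rho = rho, p = cor_pvalue(rho, n))
}
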