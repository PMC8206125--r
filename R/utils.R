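#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Writers stamp outputs with the
# package version and a short hash of the generating configuration so that
# any table can be traced back to the exact settings that produced it.

#' Short deterministic hash of a configuration object
#'
#' Serializes the object to a canonical character form and applies a 32-bit
#' FNV-1a hash. Used to stamp output files; not cryptographic.
#'
#' @param x Any R object (typically a list of parameters).
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, give.attr = FALSE,
                                              digits.d = 15)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(low8, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    # h * 16777619 mod 2^32, split into 16-bit halves to avoid overflow
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

ln_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("locusnet"))
  sprintf("# locusnet %s config=%s", ver,
          if (is.null(config)) "none" else config_hash(config))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`
# (Mersenne-Twister + Inversion), restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

assert_expr_matrix <- function(expr, what = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(what, " must be a numeric genes x samples matrix", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop(what, " has duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop(what, " has duplicated sample ids", call. = FALSE)
  invisible(expr)
}

# Standardize rows (genes) to mean 0, sd 1 (denominator n-1). Constant rows
# are mapped to all-zero with a warning from callers that care.
row_standardize <- function(x) {
  m <- rowMeans(x)
  x <- x - m
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1))
  s[s == 0] <- Inf
  x / s
}

# Format a numeric for deterministic text output: fixed significant digits,
# plain "NA" for missing. Used by all writers so reruns are byte-identical.
fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
}
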