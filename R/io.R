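# Readers and writers for every external file the pipeline touches, with
# strict validation. Gene identifiers are treated as opaque case-sensitive
# strings throughout; any symbol/accession mapping is the caller's job.
# All writers emit a single header comment line carrying the package version
# and a hash of the generating configuration.

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe Optional explicit background gene list.
#' @param provenance Character vector of free-text source labels, recycled
#'   across sets.
#' @return A list of class `"gene_set_collection"` with elements `sets`,
#'   `universe`, `provenance`.
#' @export
gene_set_collection <- function(sets, universe = NULL, provenance = "") {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    s <- as.character(s)
    if (length(s) == 0) stop("empty gene set")
    unique(s)
  })
  if (!is.null(universe)) universe <- unique(as.character(universe))
  provenance <- rep_len(as.character(provenance), length(sets))
  names(provenance) <- names(sets)
  structure(list(sets = sets, universe = universe, provenance = provenance),
            class = "gene_set_collection")
}

split_tsv_lines <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: genes in rows, first column the gene id, header row of sample
#' ids. GCT: standard v1.2 with the two-line header (v1.3 metadata layouts
#' are rejected). Empty cells and "NA" become missing values; missing entries
#' are never silently coerced to numbers.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @return Numeric genes x samples matrix with ids preserved in file order.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#\\s*locusnet", lines)]
  if (format == "gct") {
    if (length(lines) < 3) stop("GCT file too short")
    if (!identical(lines[1], "#1.2")) {
      if (grepl("^#1\\.3", lines[1]))
        stop("GCT v1.3 is not supported; use v1.2")
      stop("not a GCT v1.2 file (first line must be '#1.2')")
    }
    dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
    body <- lines[-(1:2)]
    mat <- parse_expression_body(body, first_data_col = 3L, path = path,
                                 line_offset = 2L)
    if (nrow(mat) != dims[1] || ncol(mat) != dims[2])
      stop(sprintf(
        "GCT header declares %d x %d but file contains %d x %d",
        dims[1], dims[2], nrow(mat), ncol(mat)))
    mat
  } else {
    parse_expression_body(lines, first_data_col = 2L, path = path,
                          line_offset = 0L)
  }
}

parse_expression_body <- function(body, first_data_col, path, line_offset) {
  if (length(body) < 2) stop("expression file has no data rows: ", path)
  fields <- split_tsv_lines(body)
  header <- fields[[1]]
  sample_ids <- header[first_data_col:length(header)]
  n_col <- length(header)
  rows <- fields[-1]
  widths <- lengths(rows)
  bad <- which(widths != n_col)
  if (length(bad) > 0)
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1] + 1L + line_offset, n_col, widths[bad[1]]))
  gene_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- vapply(rows, function(r) {
    v <- r[first_data_col:n_col]
    v[v == "" | v == "NA"] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !is.na(v)))
      stop("non-numeric expression value '",
           v[which(is.na(out) & !is.na(v))[1]], "' for gene ", r[1L])
    out
  }, numeric(length(sample_ids)))
  mat <- t(vals)
  dimnames(mat) <- list(gene_ids, sample_ids)
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @param config Optional configuration object hashed into the header line.
#' @param digits Significant digits written.
#' @export
write_expression <- function(expr, path, config = NULL, digits = 10) {
  assert_expr_matrix(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ln_header(config), con)
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i)
    paste(c(rownames(expr)[i], fmt_num(expr[i, ], digits)), collapse = "\t"),
    "")
  writeLines(body, con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated members. The
#' description is retained as provenance. Duplicate members within a line are
#' deduplicated with a warning; duplicate set names or empty member lists are
#' errors.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- split_tsv_lines(lines)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  prov <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), 0L))
  if (ndup > 0)
    warning(ndup, " duplicated member(s) within GMT lines were deduplicated")
  sets <- lapply(sets, unique)
  names(sets) <- nm
  gene_set_collection(sets, provenance = prov)
}

#' Write a gene-set collection to GMT
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$provenance[[nm]], gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a module-assignment table
#'
#' Tab-separated columns: gene, module label, kME to its own module, kME
#' p-value; sorted by module label then descending kME. Unassigned genes get
#' the label "unassigned" and empty kME fields. Re-reading with
#' [read_module_table()] reproduces the partition exactly.
#'
#' @param partition Named integer vector (gene -> module label, 0 =
#'   unassigned).
#' @param kme kME result from [module_eigengenes()], or NULL.
#' @param path Output path.
#' @param config Optional configuration hashed into the header.
#' @export
write_module_table <- function(partition, kme, path, config = NULL) {
  genes <- names(partition)
  lab <- ifelse(partition == 0, "unassigned", as.character(partition))
  own_r <- rep(NA_real_, length(genes))
  own_p <- rep(NA_real_, length(genes))
  if (!is.null(kme)) {
    for (i in seq_along(genes)) {
      if (partition[i] > 0) {
        mcol <- as.character(partition[i])
        if (!mcol %in% colnames(kme$r))
          stop("gene ", genes[i], " has no kME entry for its module ", mcol)
        own_r[i] <- kme$r[genes[i], mcol]
        own_p[i] <- kme$p[genes[i], mcol]
      }
    }
  }
  ord <- order(partition == 0, partition, -ifelse(is.na(own_r), -Inf, own_r),
               genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ln_header(config), con)
  writeLines("gene\tmodule\tkme\tkme_p", con)
  body <- paste(genes[ord], lab[ord],
                ifelse(is.na(own_r[ord]), "", fmt_num(own_r[ord])),
                ifelse(is.na(own_p[ord]), "", fmt_num(own_p[ord])),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a module-assignment table back into a partition
#' @param path Path written by [write_module_table()].
#' @return List with `partition` (named integer vector) and `table` (the full
#'   data frame).
#' @export
read_module_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  lab <- ifelse(df$module == "unassigned", 0L, suppressWarnings(
    as.integer(df$module)))
  if (anyNA(lab)) stop("unparseable module labels in ", path)
  partition <- stats::setNames(lab, df$gene)
  list(partition = partition, table = df)
}

#' Read a two-column homology table, enforcing a one-to-one mapping
#'
#' Rows whose source gene maps to more than one target (or vice versa) are
#' dropped before use, with the count reported, so that enrichment universes
#' stay well defined. Duplicate identical pairs are collapsed.
#'
#' @param path TSV with columns source, target (header required).
#' @return Data frame with columns `source`, `target`.
#' @export
read_homology <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("homology table needs two columns")
  names(df)[1:2] <- c("source", "target")
  validate_homology(df[, 1:2])
}

#' @rdname read_homology
#' @param pairs Data frame with columns source, target.
#' @export
validate_homology <- function(pairs) {
  pairs <- unique(pairs[, c("source", "target")])
  multi_s <- pairs$source %in% pairs$source[duplicated(pairs$source)]
  multi_t <- pairs$target %in% pairs$target[duplicated(pairs$target)]
  drop <- multi_s | multi_t
  if (any(drop))
    message("dropped ", sum(drop),
            " homology pair(s) with one-to-many mappings")
  pairs[!drop, , drop = FALSE]
}

#' Read a differential-expression table
#'
#' Expected tab-separated columns: gene, log2fc, pvalue, method. Validates
#' that p-values lie in \[0, 1\], fold changes are finite and gene symbols are
#' non-empty.
#'
#' @param path File path.
#' @return Data frame with columns `gene`, `log2fc`, `pvalue`, `method`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(df)))
    stop("DEG table must have columns gene, log2fc, pvalue")
  if (!"method" %in% names(df)) df$method <- ""
  if (any(!nzchar(df$gene))) stop("empty gene symbol in DEG table")
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc in DEG table")
  if (any(df$pvalue < 0 | df$pvalue > 1 | is.na(df$pvalue)))
    stop("p-values outside [0, 1] in DEG table")
  df[, c("gene", "log2fc", "pvalue", "method")]
}

#' Write a generic data frame as a headered TSV
#' @param df Data frame.
#' @param path Output path.
#' @param config Optional configuration hashed into the header.
#' @param digits Significant digits for numeric columns.
#' @export
write_tsv <- function(df, path, config = NULL, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ln_header(config), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col)
    if (is.numeric(col)) fmt_num(col, digits) else as.character(col))
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a sample covariate table
#'
#' @param path TSV with columns sample_id, sex, age, death_class, pmi, batch.
#' @return Data frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("covariate table must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in covariates")
  df
}
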