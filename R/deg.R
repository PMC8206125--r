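# Proof-of-concept validation: intersect two differential-expression tables
# into consensus DEGs, translate them through a one-to-one homology table,
# and test enrichment of network-derived target sets at three scales of
# interconnectedness (broad interval-module network, top-neighbor
# subnetwork, prioritized drivers).

#' Consensus differentially expressed genes from two methods
#'
#' A gene is a consensus DEG when both tables call it at p < `alpha` and
#' (by default) the fold-change signs agree. The direction label is
#' retained.
#'
#' @param a,b DEG data frames (columns gene, log2fc, pvalue; same gene
#'   namespace). Duplicated genes within a table are an error.
#' @param alpha Nominal significance threshold (default 0.05).
#' @param require_sign_concordance Drop genes whose fold changes disagree in
#'   sign between methods (default TRUE).
#' @return Data frame: gene, direction ("up"/"down"), log2fc_a, log2fc_b.
#' @export
consensus_degs <- function(a, b, alpha = 0.05,
                           require_sign_concordance = TRUE) {
  for (tab in list(a, b))
    if (anyDuplicated(tab$gene))
      stop("duplicated gene within a DEG table: ",
           tab$gene[duplicated(tab$gene)][1])
  common <- intersect(a$gene, b$gene)
  a <- a[match(common, a$gene), ]
  b <- b[match(common, b$gene), ]
  keep <- a$pvalue < alpha & b$pvalue < alpha
  if (require_sign_concordance)
    keep <- keep & (sign(a$log2fc) == sign(b$log2fc)) & a$log2fc != 0
  out <- data.frame(gene = common[keep],
                    direction = ifelse(a$log2fc[keep] > 0, "up", "down"),
                    log2fc_a = a$log2fc[keep], log2fc_b = b$log2fc[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Translate genes through a validated one-to-one homology table
#'
#' @param genes Character vector in the source namespace.
#' @param table Homology data frame (columns source, target), already
#'   one-to-one (see [validate_homology()]).
#' @return Character vector of translated genes; unmapped inputs are dropped
#'   and their count attached as attribute `"n_dropped"` (also reported via
#'   `message()`).
#' @export
map_homologs <- function(genes, table) {
  idx <- match(genes, table$source)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message("map_homologs: dropped ", dropped, " gene(s) without homologs")
  out <- table$target[idx[!is.na(idx)]]
  attr(out, "n_dropped") <- dropped
  out
}

#' Network target sets at three scales of interconnectedness
#'
#' Broad: all genes in modules harboring interval genes; subnetwork: union
#' of top-neighbor sets plus their seeds; drivers: the prioritized driver
#' genes. Drivers are contained in the subnetwork, and the subnetwork in
#' the broad set plus the interval genes.
#'
#' @param partition Named integer vector.
#' @param interval_genes Locus genes.
#' @param neighbor_sets List of [top_neighbors()] results.
#' @param drivers A `"driver_set"` from [assemble_drivers()].
#' @return List of class `"network_target_sets"`: `broad`, `subnetwork`,
#'   `drivers`.
#' @export
network_target_sets <- function(partition, interval_genes, neighbor_sets,
                                drivers) {
  imods <- interval_modules(partition, interval_genes)
  broad <- sort(unique(names(partition)[partition %in%
                                          as.integer(names(imods))]))
  sub <- sort(unique(c(unlist(lapply(neighbor_sets,
                                     function(s) s$members$gene)),
                       vapply(neighbor_sets, function(s) s$seed, ""))))
  structure(list(broad = broad, subnetwork = sub,
                 drivers = drivers$genes),
            class = "network_target_sets")
}

#' Test DEG enrichment of network targets at three scales
#'
#' One exact hypergeometric upper-tail test per scale against the supplied
#' universe (typically the homology-filtered network genes). No multiplicity
#' correction is applied across the three scales unless `adjust = TRUE`.
#'
#' @param degs Consensus DEG gene list (target namespace).
#' @param targets A [network_target_sets()] object.
#' @param universe Background gene list.
#' @param alpha Significance threshold.
#' @param adjust Apply Benjamini-Hochberg across the three scales.
#' @return Data frame with one row per scale: scale, overlap and test
#'   columns, significant.
#' @export
validate_enrichment <- function(degs, targets, universe, alpha = 0.05,
                                adjust = FALSE) {
  rows <- list()
  for (scale in c("broad", "subnetwork", "drivers")) {
    tg <- targets[[scale]]
    if (length(intersect(tg, universe)) == 0) {
      warning("empty target set at scale '", scale, "'; skipped")
      next
    }
    res <- hypergeom_overlap(degs, tg, universe)
    rows[[scale]] <- cbind(data.frame(scale = scale,
                                      stringsAsFactors = FALSE), res)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust) bh_adjust(out$p_raw) else out$p_raw
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
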