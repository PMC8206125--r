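# Guilt-by-association prioritization: locate the modules harboring interval
# genes, call hubs by kME, extract intramodular top neighbors by Spearman
# hard-thresholding, screen the neighbors against disease and control
# gene-set panels with exact hypergeometric tests and Benjamini-Hochberg
# correction, and assemble the prioritized driver set.

#' Modules harboring interval genes
#'
#' @param partition Named integer vector of module labels (0 = unassigned).
#' @param interval_genes Character vector of locus genes.
#' @return Named list: module label -> interval genes it contains (the
#'   unassigned label is excluded). Interval genes absent from the partition
#'   are reported via `message()` and attached as attribute `"absent"`.
#' @export
interval_modules <- function(partition, interval_genes) {
  absent <- setdiff(interval_genes, names(partition))
  if (length(absent) > 0)
    message("interval genes absent from partition: ",
            paste(absent, collapse = ", "))
  present <- intersect(interval_genes, names(partition))
  labs <- partition[present]
  if (all(labs == 0))
    stop("no interval gene is assigned to any module")
  keep <- labs > 0
  out <- split(present[keep], labs[keep])
  attr(out, "absent") <- absent
  attr(out, "unassigned") <- present[!keep]
  out
}

#' Call hub status of interval genes by own-module kME
#'
#' A hub is an interval gene with kME to its own module above `kme_cut` and
#' a significant correlation p-value; interval genes whose own-module kME is
#' not significant (p >= alpha) are flagged as low-connectivity and excluded
#' from seed eligibility downstream.
#'
#' @param kme kME list (`r`, `p`) from [module_eigengenes()].
#' @param partition Named integer vector.
#' @param interval_genes Locus genes (assigned ones are evaluated).
#' @param kme_cut Hub threshold on kME (default 0.8).
#' @param alpha Significance threshold on the kME p-value.
#' @return Data frame: gene, module, kme, p, hub, low_connectivity.
#' @export
call_hubs <- function(kme, partition, interval_genes, kme_cut = 0.8,
                      alpha = 0.05) {
  genes <- intersect(interval_genes, names(partition))
  genes <- genes[partition[genes] > 0]
  rows <- lapply(genes, function(g) {
    mod <- as.character(partition[g])
    if (!g %in% rownames(kme$r) || !mod %in% colnames(kme$r))
      stop("no kME entry for gene ", g, " and module ", mod)
    r <- kme$r[g, mod]
    p <- kme$p[g, mod]
    data.frame(gene = g, module = as.integer(mod), kme = r, p = p,
               hub = (r > kme_cut) && (p < alpha),
               low_connectivity = p >= alpha)
  })
  do.call(rbind, rows)
}

#' Intramodular top neighbors of a seed gene
#'
#' Spearman correlation (midranks, two-sided t-approximation p-values)
#' between the seed and every other gene in its module; neighbors are the
#' genes with rho >= `rho_cut` and p < `alpha`.
#'
#' @param expr Genes x samples matrix.
#' @param partition Named integer vector.
#' @param seed_gene Seed (must be assigned to a named module).
#' @param rho_cut Correlation threshold (default 0.5).
#' @param alpha Significance threshold.
#' @return List of class `"top_neighbor_set"`: `seed`, `module`, `members`
#'   (data frame gene, rho, p).
#' @export
top_neighbors <- function(expr, partition, seed_gene, rho_cut = 0.5,
                          alpha = 0.05) {
  if (!seed_gene %in% names(partition) || partition[seed_gene] == 0)
    stop("seed '", seed_gene, "' is not assigned to a named module")
  mod <- partition[seed_gene]
  others <- setdiff(names(partition)[partition == mod], seed_gene)
  others <- intersect(others, rownames(expr))
  sp <- spearman_vs_rows(expr[seed_gene, ], expr[others, , drop = FALSE])
  keep <- sp$rho >= rho_cut & sp$p < alpha
  members <- data.frame(gene = others[keep], rho = sp$rho[keep],
                        p = sp$p[keep], stringsAsFactors = FALSE)
  members <- members[order(-members$rho, members$gene), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(seed = seed_gene, module = as.integer(mod),
                 members = members),
            class = "top_neighbor_set")
}

#' Exact upper-tail hypergeometric overlap test
#'
#' Both gene lists are intersected with the universe before testing; the
#' p-value is the exact upper tail P(X >= overlap) of the hypergeometric
#' distribution (no normal approximation).
#'
#' @param neighbors Query gene list (e.g. a seed's top neighbors).
#' @param gene_set Annotation gene list.
#' @param universe Background gene list (non-empty after intersection).
#' @return One-row data frame: overlap_count, universe_size,
#'   set_size_in_universe, neighbors_in_universe, expected, p_raw.
#' @export
hypergeom_overlap <- function(neighbors, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  nb <- intersect(unique(neighbors), universe)
  gs <- intersect(unique(gene_set), universe)
  n_u <- length(universe)
  k <- length(gs)
  n <- length(nb)
  q <- length(intersect(nb, gs))
  if (q > min(k, n)) stop("overlap exceeds min(set, neighbors): impossible")
  p <- stats::phyper(q - 1, k, n_u - k, n, lower.tail = FALSE)
  data.frame(overlap_count = q, universe_size = n_u,
             set_size_in_universe = k, neighbors_in_universe = n,
             expected = n * k / n_u, p_raw = p)
}

#' Benjamini-Hochberg adjustment within families
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param family Optional grouping vector; the step-up correction is applied
#'   within each family separately.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Screen top-neighbor sets against disease and control panels
#'
#' Runs every seed x gene-set hypergeometric test, adjusts p-values by
#' Benjamini-Hochberg within the disease family and within the control
#' family separately, and summarizes specificity as the fraction of
#' significant tests in each family. Seeds with empty neighbor sets are
#' skipped (and listed in the summary).
#'
#' @param neighbor_sets List of [top_neighbors()] results.
#' @param disease,control [gene_set_collection()]s.
#' @param universe Background gene list (typically all genes in the final
#'   network).
#' @param alpha_adj Significance threshold on adjusted p-values.
#' @return List with `overlaps` (data frame: seed, gene_set, family, plus
#'   [hypergeom_overlap()] columns, p_adjusted, significant) and
#'   `specificity` (per-family tested/significant counts and fractions).
#' @export
enrichment_screen <- function(neighbor_sets, disease, control, universe,
                              alpha_adj = 0.05) {
  nonempty <- Filter(function(s) nrow(s$members) > 0, neighbor_sets)
  skipped <- vapply(Filter(function(s) nrow(s$members) == 0, neighbor_sets),
                    function(s) s$seed, "")
  if (length(nonempty) == 0) stop("no seed has a non-empty neighbor set")
  if (length(skipped) > 0)
    message("seeds with empty neighbor sets skipped: ",
            paste(skipped, collapse = ", "))
  run_family <- function(gsc, family) {
    rows <- list()
    for (s in nonempty) {
      for (nm in names(gsc$sets)) {
        res <- hypergeom_overlap(s$members$gene, gsc$sets[[nm]], universe)
        rows[[length(rows) + 1]] <-
          cbind(data.frame(seed = s$seed, gene_set = nm, family = family,
                           stringsAsFactors = FALSE), res)
      }
    }
    do.call(rbind, rows)
  }
  tab <- rbind(run_family(disease, "disease"), run_family(control, "control"))
  tab$p_adjusted <- bh_adjust(tab$p_raw, tab$family)
  tab$significant <- tab$p_adjusted < alpha_adj
  spec <- do.call(rbind, lapply(split(tab, tab$family), function(d)
    data.frame(family = d$family[1], n_tests = nrow(d),
               n_significant = sum(d$significant),
               fraction_significant = mean(d$significant))))
  rownames(spec) <- NULL
  list(overlaps = tab, specificity = spec, skipped_seeds = skipped)
}

#' Assemble the prioritized driver set
#'
#' Prioritized seeds are those with at least one significant disease-set
#' overlap; partner drivers are the union, over significant (seed, set)
#' pairs, of the seed's top neighbors that belong to the overlapping disease
#' set, reported with per-gene provenance.
#'
#' @param screen Result of [enrichment_screen()].
#' @param neighbor_sets List of [top_neighbors()] results.
#' @param disease The disease [gene_set_collection()].
#' @param hubs Optional [call_hubs()] table used to flag hub seeds.
#' @return List of class `"driver_set"`: `prioritized_seeds`,
#'   `partner_drivers`, `hub_seeds`, `provenance` (data frame gene, seed,
#'   gene_set), `genes` (union of seeds and partners).
#' @export
assemble_drivers <- function(screen, neighbor_sets, disease, hubs = NULL) {
  tab <- screen$overlaps
  sig <- tab[tab$family == "disease" & tab$significant, , drop = FALSE]
  sig <- sig[order(sig$seed, sig$gene_set), , drop = FALSE]
  by_seed <- stats::setNames(
    lapply(neighbor_sets, function(s) s$members$gene),
    vapply(neighbor_sets, function(s) s$seed, ""))
  prov <- list()
  for (i in seq_len(nrow(sig))) {
    hit <- intersect(by_seed[[sig$seed[i]]],
                     disease$sets[[sig$gene_set[i]]])
    if (length(hit) > 0)
      prov[[length(prov) + 1]] <- data.frame(gene = sort(hit),
                                             seed = sig$seed[i],
                                             gene_set = sig$gene_set[i],
                                             stringsAsFactors = FALSE)
  }
  prov <- if (length(prov) > 0) do.call(rbind, prov) else
    data.frame(gene = character(0), seed = character(0),
               gene_set = character(0))
  seeds <- sort(unique(sig$seed))
  partners <- sort(setdiff(unique(prov$gene), seeds))
  hub_seeds <- if (!is.null(hubs))
    sort(intersect(seeds, hubs$gene[hubs$hub])) else character(0)
  structure(list(prioritized_seeds = seeds, partner_drivers = partners,
                 hub_seeds = hub_seeds, provenance = prov,
                 genes = sort(union(seeds, partners))),
            class = "driver_set")
}

#' Run the whole prioritization stage
#'
#' Convenience wrapper: interval-module lookup, hub calling, seed
#' eligibility (low-connectivity interval genes are excluded before neighbor
#' extraction), top-neighbor extraction, enrichment screen, and driver
#' assembly.
#'
#' @param expr Genes x samples matrix.
#' @param partition Named integer vector.
#' @param kme kME list from [module_eigengenes()].
#' @param interval_genes Locus genes.
#' @param disease,control [gene_set_collection()]s.
#' @param universe Background; defaults to all genes in `expr`.
#' @param rho_cut,alpha,kme_cut,alpha_adj Thresholds.
#' @return List with `interval_modules`, `hubs`, `eligible_seeds`,
#'   `neighbor_sets`, `screen`, `drivers`.
#' @export
prioritize_interval <- function(expr, partition, kme, interval_genes,
                                disease, control,
                                universe = rownames(expr), rho_cut = 0.5,
                                alpha = 0.05, kme_cut = 0.8,
                                alpha_adj = 0.05) {
  imods <- interval_modules(partition, interval_genes)
  hubs <- call_hubs(kme, partition, interval_genes, kme_cut, alpha)
  eligible <- hubs$gene[!hubs$low_connectivity]
  neighbor_sets <- lapply(eligible, function(g)
    top_neighbors(expr, partition, g, rho_cut, alpha))
  screen <- enrichment_screen(neighbor_sets, disease, control, universe,
                              alpha_adj)
  drivers <- assemble_drivers(screen, neighbor_sets, disease, hubs)
  list(interval_modules = imods, hubs = hubs, eligible_seeds = eligible,
       neighbor_sets = neighbor_sets, screen = screen, drivers = drivers)
}
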