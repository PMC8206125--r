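# Signed weighted co-expression network construction and modular
# decomposition: bicor -> soft-threshold adjacency -> topological overlap ->
# average-linkage clustering -> dynamic hybrid-style two-phase tree cut ->
# module eigengenes / kME -> merging of close modules -> meta-modules.

#' Network construction configuration
#'
#' @param beta Soft-threshold power (positive integer); NULL means pick via
#'   [pick_soft_power()].
#' @param sft_target_r2 Scale-free-topology fit threshold for power
#'   selection.
#' @param min_module_size Smallest allowed module.
#' @param deep_split Integer 0-4; larger values split more aggressively.
#' @param merge_cut_height Eigengene-dissimilarity height below which modules
#'   are merged (0.2 corresponds to eigengene correlation 0.8).
#' @param bicor_max_p_outliers Reserved for capping bicor outlier weighting;
#'   the default 1.0 applies no cap.
#' @param meta_module_cut_height Eigengene-dissimilarity height defining
#'   meta-modules.
#' @param cut_height_frac Fraction of the dendrogram height range used for
#'   the static cut that bounds branch search.
#' @return List of class `"network_config"`.
#' @export
network_config <- function(beta = NULL, sft_target_r2 = 0.8,
                           min_module_size = 30, deep_split = 2,
                           merge_cut_height = 0.2,
                           bicor_max_p_outliers = 1.0,
                           meta_module_cut_height = 0.5,
                           cut_height_frac = 0.99) {
  if (!is.null(beta) && beta < 1) stop("beta must be >= 1")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  if (merge_cut_height <= 0 || merge_cut_height > 1)
    stop("merge_cut_height must be in (0, 1]")
  if (meta_module_cut_height <= 0 || meta_module_cut_height > 1)
    stop("meta_module_cut_height must be in (0, 1]")
  structure(list(beta = beta, sft_target_r2 = sft_target_r2,
                 min_module_size = min_module_size, deep_split = deep_split,
                 merge_cut_height = merge_cut_height,
                 bicor_max_p_outliers = bicor_max_p_outliers,
                 meta_module_cut_height = meta_module_cut_height,
                 cut_height_frac = cut_height_frac),
            class = "network_config")
}

#' Signed soft-threshold adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta, so perfect negative correlation maps to 0
#' rather than to a strong edge; the diagonal is forced to 1.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param beta Soft-threshold power.
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(corr, beta) {
  if (any(abs(corr) > 1 + 1e-12)) stop("correlations outside [-1, 1]")
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + pmin(pmax(corr, -1), 1)) / 2)^beta
  diag(a) <- 1
  a
}

# Connectivity: row sums of adjacency minus the self term.
connectivity <- function(adj) rowSums(adj) - diag(adj)

#' Scan candidate soft-threshold powers for scale-free topology fit
#'
#' For each candidate power, computes whole-network connectivities, bins
#' log10(k) into equal-width bins, regresses log10(mean frequency) on
#' log10(mean k) per bin, and reports the signed fit index
#' -sign(slope) * R^2 together with connectivity summaries.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate powers (at least 2).
#' @param n_bins Number of histogram bins.
#' @param corr Optional precomputed correlation matrix (bicor by default).
#' @return Data frame: power, signed_r2, mean_k, median_k, max_k.
#' @export
sft_scan <- function(expr, powers = c(1:10, seq(12, 20, 2)), n_bins = 10,
                     corr = NULL) {
  if (length(powers) < 2) stop("need at least 2 candidate powers")
  if (is.null(corr)) corr <- bicor_matrix(expr)
  sim <- (1 + corr) / 2
  diag(sim) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(sim^b)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, signed_r2 = fit, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  do.call(rbind, rows)
}

# Signed R^2 of the log-log degree-distribution fit; NA when degenerate.
# Connectivities are binned into equal-width bins on the raw k scale (the
# standard convention for this fit index), then log10(frequency) is
# regressed on log10(mean k) over the occupied bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Pick the lowest power reaching the scale-free fit target
#'
#' Returns the lowest candidate power whose signed R^2 reaches
#' `target_r2`; if none does, returns the power with the maximal signed R^2
#' with a warning.
#'
#' @param sft Data frame from [sft_scan()].
#' @param target_r2 Fit threshold (default 0.8).
#' @return The selected power (scalar).
#' @export
pick_soft_power <- function(sft, target_r2 = 0.8) {
  ok <- which(!is.na(sft$signed_r2) & sft$signed_r2 >= target_r2)
  if (length(ok) > 0) return(sft$power[min(ok)])
  warning("no candidate power reaches signed R^2 >= ", target_r2,
          "; returning the best-fitting power")
  sft$power[which.max(sft$signed_r2)]
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj over u != i, j; the diagonal is 1. Computed with
#' matrix products.
#'
#' @param adj Adjacency matrix (symmetric, unit diagonal, entries in 0..1).
#' @return TOM matrix; `1 - tom()` is the clustering dissimilarity.
#' @export
tom_similarity <- function(adj) {
  if (any(adj < 0) || any(adj > 1)) stop("adjacency entries must be in [0,1]")
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  l <- a %*% a            # includes no self terms since diag(a) = 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  if (any(denom <= 0)) stop("internal error: non-positive TOM denominator")
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# ---------------------------------------------------------------------------
# Dynamic hybrid-style two-phase tree cut.
#
# Phase 1 (branch identification): candidate modules are the maximal
# dendrogram branches that (i) have at least min_module_size leaves,
# (ii) are separated from the rest of the tree by a height gap — the branch
# merges into its parent at least `gap_min` above its own top — and
# (iii) are tight: the mean dissimilarity among members is smaller than the
# mean dissimilarity to non-members by at least `tight_min`. Both thresholds
# are absolute on the TOM-dissimilarity scale and roughly halve per
# deep_split step, so larger values split more aggressively. Because side
# branches attach densely along a large cluster's spine and erode its local
# height gap, extraction is iterated: once the distinct branches of a round
# are removed, the remaining genes are re-clustered and searched again,
# until no distinct branch remains.
#
# Phase 2 (straggler assignment): every remaining gene is assigned to the
# nearest candidate by average dissimilarity, provided it is closer to that
# candidate than to the unassigned background and within the candidate's
# assignment radius (a high quantile of the members' own average
# intra-cluster dissimilarity). Genes failing both go to "unassigned".
# ---------------------------------------------------------------------------

ds_gap_min <- c(0.006, 0.003, 0.0015, 0.0008, 0.0004)
ds_tight_min <- c(0.10, 0.05, 0.03, 0.015, 0.0075)

# One round of branch identification on a dissimilarity submatrix.
# Returns a list of character vectors (member gene ids) plus diagnostics.
find_branches <- function(dtom, min_size, gap_min, tight_min, h_cut_frac) {
  n <- nrow(dtom)
  if (n < min_size)
    return(list(modules = list(), info = NULL, hc = NULL))
  hc <- stats::hclust(stats::as.dist(dtom), method = "average")
  h <- hc$height
  rng <- max(h) - min(h)
  if (rng <= 0) return(list(modules = list(), info = NULL, hc = hc))
  h_cut <- min(h) + h_cut_frac * rng
  m <- hc$merge
  n_nodes <- nrow(m)
  size <- integer(n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  leaves <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    s <- 0L
    lv <- integer(0)
    for (child in m[i, ]) {
      if (child < 0) {
        s <- s + 1L
        lv <- c(lv, -child)
      } else {
        s <- s + size[child]
        parent[child] <- i
        lv <- c(lv, leaves[[child]])
      }
    }
    size[i] <- s
    leaves[[i]] <- lv
  }
  parent_h <- ifelse(is.na(parent), max(h) + rng, h[parent])
  gap <- parent_h - h
  distinct <- size >= min_size & gap >= gap_min & h <= h_cut
  cand <- which(distinct)
  if (length(cand) == 0)
    return(list(modules = list(), info = NULL, hc = hc))
  maximal <- vapply(cand, function(nd) {
    p <- parent[nd]
    while (!is.na(p)) {
      if (distinct[p]) return(FALSE)
      p <- parent[p]
    }
    TRUE
  }, TRUE)
  cand <- cand[maximal]
  modules <- list()
  info <- data.frame()
  for (nd in cand) {
    idx <- leaves[[nd]]
    intra <- mean(dtom[idx, idx][upper.tri(diag(length(idx)))])
    extra <- if (length(idx) < n) mean(dtom[idx, -idx]) else NA_real_
    kept <- is.na(extra) || (extra - intra >= tight_min)
    info <- rbind(info, data.frame(size = length(idx), height = h[nd],
                                   gap = gap[nd], intra = intra,
                                   extra = extra, kept = kept))
    if (kept) modules[[length(modules) + 1]] <- rownames(dtom)[idx]
  }
  list(modules = modules, info = info, hc = hc)
}

#' Cluster a TOM dissimilarity and cut the dendrogram into modules
#'
#' Average-linkage hierarchical clustering followed by a two-phase dynamic
#' hybrid-style cut (branch identification by height-gap and tightness
#' criteria modulated by `deep_split`, then nearest-cluster assignment of
#' leftover genes). One label, 0 / "unassigned", is reserved for genes that
#' cannot be assigned unequivocally. Module labels are stable integers
#' ordered by decreasing module size.
#'
#' @param dtom Symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - tom_similarity(adj)`).
#' @param config A [network_config()].
#' @param max_rounds Maximum number of extract-and-recluster rounds.
#' @return List with `partition` (named integer vector, 0 = unassigned),
#'   `dendrogram` (the hclust object of the full gene set), and `cut_info`
#'   (per-candidate diagnostics across rounds).
#' @export
cluster_and_cut <- function(dtom, config = network_config(), max_rounds = 10) {
  if (!isTRUE(all.equal(dtom, t(dtom), tolerance = 1e-8)))
    stop("dtom must be symmetric")
  if (any(abs(diag(dtom)) > 1e-8)) stop("dtom must have zero diagonal")
  genes <- rownames(dtom)
  n <- length(genes)
  min_size <- config$min_module_size
  part <- stats::setNames(integer(n), genes)
  if (n < min_size)
    return(list(partition = part, dendrogram = NULL, cut_info = NULL))
  gap_min <- ds_gap_min[config$deep_split + 1]
  tight_min <- ds_tight_min[config$deep_split + 1]

  modules <- list()
  info <- data.frame()
  remaining <- genes
  hc_full <- NULL
  for (round in seq_len(max_rounds)) {
    res <- find_branches(dtom[remaining, remaining, drop = FALSE], min_size,
                         gap_min, tight_min, config$cut_height_frac)
    if (round == 1) hc_full <- res$hc
    if (!is.null(res$info) && nrow(res$info) > 0)
      info <- rbind(info, cbind(round = round, res$info))
    if (length(res$modules) == 0) break
    modules <- c(modules, res$modules)
    remaining <- setdiff(remaining, unlist(res$modules))
    if (length(remaining) < min_size) break
  }

  if (length(modules) > 0) {
    for (q in seq_along(modules)) part[modules[[q]]] <- q
    # phase 2: nearest-candidate assignment of stragglers
    unl <- which(part == 0)
    if (length(unl) > 0) {
      dmod <- vapply(modules, function(mem)
        rowMeans(dtom[unl, mem, drop = FALSE]), numeric(length(unl)))
      dmod <- matrix(dmod, nrow = length(unl))
      radius <- vapply(modules, function(mem) {
        intra_avg <- rowMeans(dtom[mem, mem, drop = FALSE]) *
          length(mem) / (length(mem) - 1)
        as.numeric(stats::quantile(intra_avg, 0.95))
      }, 0)
      d_bg <- rowMeans(dtom[unl, unl, drop = FALSE])
      best <- max.col(-dmod, ties.method = "first")
      d_best <- dmod[cbind(seq_along(unl), best)]
      take <- d_best < d_bg & d_best <= radius[best]
      part[unl[take]] <- best[take]
    }
    part <- relabel_by_size(part, min_size)
  }
  list(partition = part, dendrogram = hc_full, cut_info = info)
}

# Renumber module labels 1..K by decreasing size; modules that fell below
# min_size (e.g. after merging elsewhere) become unassigned.
relabel_by_size <- function(part, min_size = 0) {
  tab <- table(part[part > 0])
  keep <- names(tab)[tab >= min_size]
  small <- setdiff(names(tab), keep)
  if (length(small) > 0) part[as.character(part) %in% small] <- 0L
  tab <- tab[keep]
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  map <- stats::setNames(seq_along(ord), ord)
  new <- part
  pos <- part > 0
  new[pos] <- as.integer(map[as.character(part[pos])])
  new
}

#' Module eigengenes, variance explained, and kME
#'
#' Each module's eigengene is the first right-singular vector of its
#' row-standardized member submatrix (unit norm across samples), with the
#' sign chosen so the mean correlation with member genes is non-negative.
#' kME is the Pearson correlation between every gene and every module
#' eigengene, with two-sided p-values from the t transform.
#'
#' @param expr Genes x samples matrix.
#' @param partition Named integer vector (0 = unassigned).
#' @return List with `eigengenes` (modules x samples, rownames are module
#'   labels), `prop_var` (named vector), and `kme` (list of matrices `r` and
#'   `p`, genes x modules).
#' @export
module_eigengenes <- function(expr, partition) {
  assert_expr_matrix(expr)
  bad <- setdiff(names(partition), rownames(expr))
  if (length(bad) > 0)
    stop("partition references genes absent from expr: ",
         paste(utils::head(bad, 5), collapse = ", "))
  labs <- sort(unique(partition[partition > 0]))
  if (length(labs) == 0) stop("no named modules in partition")
  ns <- ncol(expr)
  me <- matrix(0, length(labs), ns,
               dimnames = list(as.character(labs), colnames(expr)))
  pv <- stats::setNames(numeric(length(labs)), as.character(labs))
  for (j in seq_along(labs)) {
    mem <- names(partition)[partition == labs[j]]
    x <- row_standardize(expr[mem, , drop = FALSE])
    if (length(mem) == 1) {
      v <- as.numeric(x)
      me[j, ] <- v / sqrt(sum(v^2))
      pv[j] <- 1
      next
    }
    cp <- crossprod(x)            # samples x samples
    eg <- eigen(cp, symmetric = TRUE)
    v1 <- eg$vectors[, 1]
    if (mean(x %*% v1) < 0) v1 <- -v1
    me[j, ] <- v1
    pv[j] <- eg$values[1] / sum(pmax(eg$values, 0))
  }
  # kME as exact Pearson correlation of every gene with every eigengene,
  # then sign alignment: mean kME of a module's own members must be >= 0
  xs <- row_standardize(expr)
  mec <- me - rowMeans(me)
  mes <- sqrt(rowSums(mec^2))
  kr <- (xs %*% t(mec)) / (sqrt(rowSums(xs^2)) %o% mes)
  for (j in seq_along(labs)) {
    mem <- names(partition)[partition == labs[j]]
    if (mean(kr[mem, j]) < 0) {
      me[j, ] <- -me[j, ]
      kr[, j] <- -kr[, j]
    }
  }
  kr <- pmin(pmax(kr, -1), 1)
  kp <- matrix(cor_pvalue(kr, ns), nrow(kr), ncol(kr),
               dimnames = dimnames(kr))
  list(eigengenes = me, prop_var = pv, kme = list(r = kr, p = kp))
}

#' Merge modules with strongly correlated eigengenes
#'
#' Clusters module eigengenes by average linkage on 1 - cor(ME), merges all
#' modules within branches below `merge_cut_height` (0.2 corresponds to
#' eigengene correlation 0.8), recomputes eigengenes, and iterates until no
#' eigengene pair correlates above the implied threshold (at most `max_iter`
#' rounds). The unassigned label never merges.
#'
#' @param expr Genes x samples matrix.
#' @param partition Named integer vector.
#' @param merge_cut_height Dissimilarity cut height.
#' @param max_iter Maximum merge rounds.
#' @return List with `partition` (relabeled by size) and `eigengenes` (the
#'   [module_eigengenes()] result for the final partition).
#' @export
merge_close_modules <- function(expr, partition, merge_cut_height = 0.2,
                                max_iter = 10) {
  stopifnot(any(partition > 0))
  r_thresh <- 1 - merge_cut_height
  for (it in seq_len(max_iter)) {
    eg <- module_eigengenes(expr, partition)
    k <- nrow(eg$eigengenes)
    if (k < 2) break
    cc <- stats::cor(t(eg$eigengenes))
    d <- 1 - cc
    hcme <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hcme, h = merge_cut_height)
    off <- cc[upper.tri(cc)]
    if (max(grp) == k && max(off) <= r_thresh) break
    if (max(grp) == k) {
      # no branch below the cut but a pair still exceeds the correlation
      # threshold: merge the closest pair directly
      pair <- which(cc == max(off) & upper.tri(cc), arr.ind = TRUE)[1, ]
      grp[pair[2]] <- grp[pair[1]]
    }
    old_labels <- as.integer(rownames(eg$eigengenes))
    map <- stats::setNames(grp, old_labels)
    pos <- partition > 0
    partition[pos] <- as.integer(map[as.character(partition[pos])])
  }
  partition <- relabel_by_size(partition)
  list(partition = partition,
       eigengenes = module_eigengenes(expr, partition))
}

#' Group modules into meta-modules
#'
#' Average-linkage clustering of module eigengenes on 1 - cor(ME); branches
#' below `cut_height` form meta-modules (singletons allowed). Only positive
#' correlation brings modules together, since anticorrelated eigengenes have
#' dissimilarity above 1.
#'
#' @param eigengenes Modules x samples eigengene matrix.
#' @param cut_height Dissimilarity cut (default 0.5).
#' @return Named integer vector module label -> meta-module id.
#' @export
meta_modules <- function(eigengenes, cut_height = 0.5) {
  if (nrow(eigengenes) < 2)
    stop("need at least 2 modules for meta-module analysis")
  d <- 1 - stats::cor(t(eigengenes))
  hcme <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hcme, h = cut_height)
}

#' Run the full network stage on a preprocessed matrix
#'
#' Convenience wrapper: bicor, power selection (unless fixed), adjacency,
#' TOM, clustering and cutting, eigengenes/kME, module merging, and
#' meta-modules.
#'
#' @param expr Preprocessed genes x samples matrix.
#' @param config A [network_config()].
#' @param powers Candidate powers for the scale-free scan.
#' @return List with `sft`, `beta`, `partition`, `eigengenes`, `kme`,
#'   `meta_modules`, `dendrogram`, `cut_info`.
#' @export
build_network <- function(expr, config = network_config(),
                          powers = c(1:10, seq(12, 20, 2))) {
  corr <- bicor_matrix(expr)
  sft <- sft_scan(expr, powers = powers, corr = corr)
  beta <- if (is.null(config$beta))
    pick_soft_power(sft, config$sft_target_r2) else config$beta
  adj <- signed_adjacency(corr, beta)
  tom <- tom_similarity(adj)
  cut <- cluster_and_cut(1 - tom, config)
  if (all(cut$partition == 0)) {
    return(list(sft = sft, beta = beta, partition = cut$partition,
                eigengenes = NULL, kme = NULL, meta_modules = NULL,
                dendrogram = cut$dendrogram, cut_info = cut$cut_info))
  }
  merged <- merge_close_modules(expr, cut$partition, config$merge_cut_height)
  eg <- merged$eigengenes
  mm <- if (nrow(eg$eigengenes) >= 2)
    meta_modules(eg$eigengenes, config$meta_module_cut_height) else NULL
  list(sft = sft, beta = beta, partition = merged$partition,
       eigengenes = eg, kme = eg$kme, meta_modules = mm,
       dendrogram = cut$dendrogram, cut_info = cut$cut_info)
}
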