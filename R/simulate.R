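# Synthetic cohorts with planted ground truth. The generator emulates the
# statistical structure the downstream analysis assumes: modular expression
# (gene = loading * module eigengene + noise) on the log2 scale, a background
# of unassigned pure-noise genes, interval genes distributed across modules
# (a few deliberately peripheral, mirroring low-abundance locus genes),
# nuisance covariates with linear effects, a replicate cohort sharing the
# module structure with independent samples, gene-set panels enriched in
# specific seed neighborhoods, and a two-group negative-binomial
# differential-expression study with effects planted on interval genes and a
# fraction of their module partners.

#' Simulation configuration
#'
#' Assembles and validates the parameter set that defines a synthetic study.
#' The defaults describe a desk-scale cohort: 2,000 genes in 5 modules of
#' sizes 400/300/200/150/100 plus 850 background genes, 100 reference and 30
#' test samples, gene loadings uniform on (0.5, 0.9), and 21 interval genes
#' of which 16 are well-connected module members, 4 are peripheral
#' (low-loading) module members and 1 is background.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_ref,n_samples_test Samples in the reference / test cohort.
#' @param module_sizes Integer vector of planted module sizes (including the
#'   interval genes placed in each module).
#' @param loading_range Length-2 vector, the uniform range for gene loadings
#'   (target gene-eigengene correlations) in \[0, 1\].
#' @param weak_loading_range Uniform range for the peripheral interval genes.
#' @param n_interval_genes Number of interval (locus) genes.
#' @param interval_placement Named integer vector mapping interval gene name
#'   to module index, with 0 meaning background. Defaults distribute the 21
#'   genes over the 5 modules (6/5/4/3/2) with one background placement.
#' @param interval_weak Names of interval genes drawn with weak loadings.
#' @param covariate_effect_size Standard deviation of per-gene covariate
#'   coefficients (standardized effect units); 0 disables nuisance effects.
#' @param disease_set_specs List of disease-set specs, each a list with
#'   elements `size`, `enrichment_fraction` and `target` (an interval gene).
#' @param control_set_specs List of control-set specs, each a list with `size`.
#' @param deg_spec List with `n_per_group`, `dispersion`, `lfc_on_interval`,
#'   `partner_fraction`, `lfc_on_partners`, `homology_coverage`.
#' @param seed Integer RNG seed (Mersenne-Twister; fixed seed gives
#'   bit-identical output).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_ref = 100,
                       n_samples_test = 30,
                       module_sizes = c(400, 300, 200, 150, 100),
                       loading_range = c(0.5, 0.9),
                       weak_loading_range = c(0.03, 0.15),
                       n_interval_genes = 21,
                       interval_placement = NULL,
                       interval_weak = NULL,
                       covariate_effect_size = 0.5,
                       disease_set_specs = NULL,
                       control_set_specs = NULL,
                       deg_spec = NULL,
                       seed = 1) {
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (any(loading_range < 0) || any(loading_range > 1) ||
      diff(loading_range) < 0)
    stop("loading_range must be an increasing pair within [0, 1]")
  iv_names <- sprintf("IVG%02d", seq_len(n_interval_genes))
  if (is.null(interval_placement)) {
    k <- length(module_sizes)
    counts <- c(6, 5, 4, 3, 2)[seq_len(min(5, k))]
    counts <- counts[counts > 0]
    placement <- rep(seq_along(counts), counts)
    placement <- placement[seq_len(min(length(placement),
                                       n_interval_genes - 1))]
    interval_placement <- c(placement,
                            rep(0, n_interval_genes - length(placement)))
    names(interval_placement) <- iv_names
  }
  if (is.null(names(interval_placement)))
    names(interval_placement) <- iv_names[seq_along(interval_placement)]
  if (any(interval_placement > length(module_sizes)) ||
      any(interval_placement < 0))
    stop("interval_placement references a module index out of range")
  if (is.null(interval_weak)) {
    assigned <- names(interval_placement)[interval_placement > 0]
    # one peripheral gene per module, up to four, taken from the tail of the
    # default placement so each weak gene sits in a different module
    interval_weak <- character(0)
    for (m in unique(interval_placement[assigned])) {
      mem <- assigned[interval_placement[assigned] == m]
      if (length(mem) > 1 && length(interval_weak) < 4)
        interval_weak <- c(interval_weak, mem[length(mem)])
    }
  }
  if (is.null(disease_set_specs)) {
    strong <- setdiff(names(interval_placement)[interval_placement > 0],
                      interval_weak)
    mods <- interval_placement[strong]
    # three enriched sets target strong seeds in three distinct modules;
    # three further disease sets are unenriched (as many as seeds allow)
    targets <- utils::head(strong[!duplicated(mods)], 3)
    nulls <- strong[c(2, 4, 6)]
    nulls <- nulls[!is.na(nulls)]
    disease_set_specs <- c(
      lapply(targets, function(tg)
        list(size = 40, enrichment_fraction = 0.5, target = tg)),
      lapply(nulls, function(tg)
        list(size = 40, enrichment_fraction = 0, target = tg)))
  }
  if (is.null(control_set_specs))
    control_set_specs <- lapply(c(40, 40, 40, 250),
                                function(s) list(size = s))
  for (sp in disease_set_specs)
    if (sp$enrichment_fraction < 0 || sp$enrichment_fraction > 1)
      stop("enrichment_fraction must be in [0, 1]")
  if (is.null(deg_spec))
    deg_spec <- list(n_per_group = 5, dispersion = 0.05,
                     lfc_on_interval = -1, partner_fraction = 0.3,
                     lfc_on_partners = -0.75, homology_coverage = 0.95)
  cfg <- list(n_genes = n_genes, n_samples_ref = n_samples_ref,
              n_samples_test = n_samples_test, module_sizes = module_sizes,
              loading_range = loading_range,
              weak_loading_range = weak_loading_range,
              background_fraction = 1 - sum(module_sizes) / n_genes,
              n_interval_genes = n_interval_genes,
              interval_placement = interval_placement,
              interval_weak = interval_weak,
              covariate_effect_size = covariate_effect_size,
              disease_set_specs = disease_set_specs,
              control_set_specs = control_set_specs,
              deg_spec = deg_spec, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Draw one cohort's expression given memberships/loadings: ME profiles are
# standard normal across samples, gene i in module q is
# r_i * ME_q + sqrt(1 - r_i^2) * eps_i; background genes are pure noise.
draw_cohort <- function(labels, loadings, baseline, n_samples, sample_prefix) {
  n <- length(labels)
  k <- max(labels)
  me <- matrix(stats::rnorm(k * n_samples), k, n_samples,
               dimnames = list(paste0("ME", seq_len(k)),
                               paste0(sample_prefix, seq_len(n_samples))))
  eps <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  x <- matrix(0, n, n_samples,
              dimnames = list(names(labels), colnames(me)))
  in_mod <- labels > 0
  x[in_mod, ] <- loadings[in_mod] * me[labels[in_mod], , drop = FALSE] +
    sqrt(1 - loadings[in_mod]^2) * eps[in_mod, , drop = FALSE]
  x[!in_mod, ] <- eps[!in_mod, , drop = FALSE]
  x <- x + baseline
  list(expr = x, eigengenes = me)
}

#' Simulate a reference and a replicate test cohort with planted modules
#'
#' Generates log2-scale expression for a reference cohort (with nuisance
#' covariate effects) and an independent test cohort that reuses the same
#' gene-module memberships and loadings but freshly drawn module eigengenes
#' and noise — shared structure, independent samples. Returns the full
#' planted truth needed to benchmark every downstream stage.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `ref` and `test` (genes x samples matrices),
#'   `covariates` (data frame for the reference samples: sample_id, sex, age,
#'   death_class, pmi, batch), and `truth` (list: `true_partition` named
#'   integer vector with 0 = background, `true_loadings`,
#'   `true_eigengenes_ref`, `true_eigengenes_test`, `interval_genes`,
#'   `interval_weak`, `covariate_coefs`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    sizes <- config$module_sizes
    k <- length(sizes)
    iv <- names(config$interval_placement)
    # memberships: interval genes occupy their placed modules first, the
    # remaining slots are filled with ordinary genes, the rest is background
    labels <- integer(n)
    gene_ids <- character(n)
    iv_mods <- config$interval_placement
    ord_needed <- n - length(iv)
    ord_ids <- sprintf("G%04d", seq_len(ord_needed))
    pos <- 1L
    idx <- 1L
    for (q in seq_len(k)) {
      iv_here <- iv[iv_mods == q]
      n_ord <- sizes[q] - length(iv_here)
      if (n_ord < 0) stop("module ", q, " too small for its interval genes")
      ids <- c(iv_here, ord_ids[idx:(idx + n_ord - 1)])
      idx <- idx + n_ord
      gene_ids[pos:(pos + sizes[q] - 1)] <- ids
      labels[pos:(pos + sizes[q] - 1)] <- q
      pos <- pos + sizes[q]
    }
    bg_iv <- iv[iv_mods == 0]
    bg_ids <- c(bg_iv, ord_ids[idx:ord_needed])
    gene_ids[pos:n] <- bg_ids[seq_len(n - pos + 1)]
    names(labels) <- gene_ids
    loadings <- stats::setNames(numeric(n), gene_ids)
    in_mod <- labels > 0
    loadings[in_mod] <- stats::runif(sum(in_mod), config$loading_range[1],
                                     config$loading_range[2])
    weak <- intersect(config$interval_weak, gene_ids[in_mod])
    loadings[weak] <- stats::runif(length(weak),
                                   config$weak_loading_range[1],
                                   config$weak_loading_range[2])
    # seeds targeted by enriched disease sets are well-connected by design
    # (prioritization targets are the strongly connected interval genes), so
    # their true neighborhoods always support the requested enrichment
    targets <- unique(vapply(
      Filter(function(sp) sp$enrichment_fraction > 0,
             config$disease_set_specs),
      function(sp) sp$target, ""))
    targets <- intersect(targets, gene_ids[in_mod])
    hi <- max(config$loading_range[2], 0.9)
    loadings[targets] <- stats::runif(length(targets), 0.75, hi)
    baseline <- stats::setNames(stats::runif(n, 2, 12), gene_ids)

    ref <- draw_cohort(labels, loadings, baseline, config$n_samples_ref, "R")
    test <- draw_cohort(labels, loadings, baseline, config$n_samples_test, "T")

    # nuisance covariates on the reference cohort, as linear offsets with
    # per-gene coefficients ~ N(0, effect^2) on standardized covariates
    ns <- config$n_samples_ref
    cov <- data.frame(
      sample_id = colnames(ref$expr),
      sex = sample(c("F", "M"), ns, replace = TRUE),
      age = round(stats::runif(ns, 20, 79)),
      death_class = sample(0:4, ns, replace = TRUE),
      pmi = round(stats::runif(ns, 60, 1200)),
      batch = sample(c("b1", "b2"), ns, replace = TRUE),
      stringsAsFactors = FALSE)
    ces <- config$covariate_effect_size
    coefs <- NULL
    if (ces > 0) {
      design <- cbind(sex = as.numeric(cov$sex == "M"),
                      age = as.numeric(scale(cov$age)),
                      batch = as.numeric(cov$batch == "b2"))
      coefs <- matrix(stats::rnorm(n * ncol(design), 0, ces), n, ncol(design),
                      dimnames = list(gene_ids, colnames(design)))
      ref$expr <- ref$expr + coefs %*% t(design)
    }

    truth <- list(true_partition = labels,
                  true_loadings = loadings,
                  true_eigengenes_ref = ref$eigengenes,
                  true_eigengenes_test = test$eigengenes,
                  interval_genes = iv,
                  interval_weak = config$interval_weak,
                  covariate_coefs = coefs,
                  config = config)
    list(ref = ref$expr, test = test$expr, covariates = cov, truth = truth)
  })
}

# True guilt-by-association neighborhood of a seed: module co-members whose
# population correlation with the seed (r_seed * r_j) clears the screening
# threshold. These are the genes that will be the seed's top neighbors.
true_neighborhood <- function(truth, seed_gene, rho_cut = 0.5) {
  lab <- truth$true_partition
  if (!seed_gene %in% names(lab) || lab[seed_gene] == 0)
    stop("seed '", seed_gene, "' is not assigned to a module")
  mod <- lab[seed_gene]
  mem <- setdiff(names(lab)[lab == mod], seed_gene)
  r <- truth$true_loadings
  mem[r[seed_gene] * r[mem] >= rho_cut]
}

#' Plant disease and control gene-set panels with known enrichment
#'
#' Each disease set draws `enrichment_fraction` of its members uniformly from
#' the target seed's true high-loading module co-members (the genes destined
#' to be its top neighbors) and the remainder uniformly from all other genes;
#' control sets are drawn uniformly at random. No set contains its target
#' seed.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param expr Expression matrix supplying the gene universe.
#' @param specs,control_specs Disease / control set specs (see [sim_config()]).
#' @param seed RNG seed.
#' @param rho_cut Screening correlation threshold defining the neighborhood.
#' @return A list with `disease` and `control` [gene_set_collection()]s and
#'   `planted`, the per-disease-set list of members drawn from the target
#'   neighborhood.
#' @export
plant_disease_sets <- function(truth, expr, specs = truth$config$disease_set_specs,
                               control_specs = truth$config$control_set_specs,
                               seed = truth$config$seed + 1,
                               rho_cut = 0.5) {
  genes <- rownames(expr)
  with_seed(seed, {
    disease <- list()
    planted <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      nm <- sprintf("disease_%02d", i)
      nbh <- true_neighborhood(truth, sp$target, rho_cut)
      n_enr <- round(sp$size * sp$enrichment_fraction)
      if (n_enr > length(nbh))
        stop("requested enrichment (", n_enr, ") exceeds neighborhood size (",
             length(nbh), ") for seed ", sp$target)
      enr <- if (n_enr > 0) sample(nbh, n_enr) else character(0)
      pool <- setdiff(genes, c(enr, sp$target))
      members <- c(enr, sample(pool, sp$size - n_enr))
      disease[[nm]] <- members
      planted[[nm]] <- enr
    }
    control <- list()
    for (i in seq_along(control_specs)) {
      nm <- sprintf("control_%02d", i)
      control[[nm]] <- sample(genes, control_specs[[i]]$size)
    }
    list(
      disease = gene_set_collection(disease,
                                    provenance = rep("synthetic planted panel",
                                                     length(disease))),
      control = gene_set_collection(control,
                                    provenance = rep("synthetic random panel",
                                                     length(control))),
      planted = planted)
  })
}

#' Simulate a two-group negative-binomial differential-expression study
#'
#' Generates counts for a wild-type and a mutant group; interval genes get a
#' planted log2 fold change (default -1, halved dosage), and a random
#' fraction of each interval gene's true module co-members get a partner
#' effect. Two genuinely different tests produce the two DEG tables: a Welch
#' t-test on log2(count + 1) and a Wald test from a moment-matched
#' negative-binomial fit with a common dispersion. A homology table maps a
#' configurable fraction of the source-namespace genes to the cohort
#' namespace, to exercise homology filtering.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param deg_spec See [sim_config()].
#' @param seed RNG seed.
#' @return A list with `method_a` and `method_b` (data frames: gene, log2fc,
#'   pvalue, method), `homology` (data frame: source, target), and
#'   `deg_truth` (named vector of true log2 fold changes, cohort namespace).
#' @export
simulate_deg_study <- function(truth, deg_spec = truth$config$deg_spec,
                               seed = truth$config$seed + 2) {
  if (deg_spec$n_per_group < 3) stop("need at least 3 samples per group")
  if (deg_spec$dispersion <= 0) stop("dispersion must be positive")
  with_seed(seed, {
    lab <- truth$true_partition
    genes <- names(lab)
    n <- length(genes)
    lfc <- stats::setNames(numeric(n), genes)
    iv <- truth$interval_genes
    lfc[iv] <- deg_spec$lfc_on_interval
    partners <- character(0)
    for (g in iv[lab[iv] > 0]) {
      partners <- union(partners, setdiff(names(lab)[lab == lab[g]], iv))
    }
    hit <- sample(partners, round(length(partners) * deg_spec$partner_fraction))
    lfc[hit] <- deg_spec$lfc_on_partners

    m <- deg_spec$n_per_group
    mu_wt <- 2^stats::runif(n, 5, 12)
    mu_mut <- mu_wt * 2^lfc
    size <- 1 / deg_spec$dispersion
    wt <- matrix(stats::rnbinom(n * m, mu = rep(mu_wt, m), size = size), n, m)
    mut <- matrix(stats::rnbinom(n * m, mu = rep(mu_mut, m), size = size), n, m)
    rownames(wt) <- rownames(mut) <- genes

    # method A: Welch t-test on log2(count + 1)
    la <- log2(wt + 1); lb <- log2(mut + 1)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
    se <- sqrt(va / m + vb / m)
    se[se == 0] <- Inf
    tstat <- (mb - ma) / se
    df <- (va / m + vb / m)^2 /
      pmax((va / m)^2 / (m - 1) + (vb / m)^2 / (m - 1), .Machine$double.eps)
    p_a <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    lfc_a <- mb - ma

    # method B: Wald test from a moment-matched NB fit; per-gene method-of-
    # moments dispersions are noisy at small n, so a common (median)
    # dispersion across genes is used
    m1 <- rowMeans(wt); m2 <- rowMeans(mut)
    v1 <- apply(wt, 1, stats::var); v2 <- apply(mut, 1, stats::var)
    phi_g <- c((v1 - m1) / m1^2, (v2 - m2) / m2^2)
    phi <- max(stats::median(phi_g[is.finite(phi_g)], na.rm = TRUE), 1e-8)
    m1c <- pmax(m1, 0.5); m2c <- pmax(m2, 0.5)
    se_w <- sqrt((1 / m1c + phi) / m + (1 / m2c + phi) / m)
    z <- (log(m2c) - log(m1c)) / se_w
    p_b <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    lfc_b <- log2(m2c / m1c)

    # homology: the study is reported in a source ("m_") namespace; a random
    # subset of genes has a one-to-one mapping to the cohort namespace
    covered <- sort(sample(genes, round(n * deg_spec$homology_coverage)))
    homology <- data.frame(source = paste0("m_", covered), target = covered,
                           stringsAsFactors = FALSE)

    src <- paste0("m_", genes)
    list(method_a = data.frame(gene = src, log2fc = lfc_a, pvalue = p_a,
                               method = "welch_log2", stringsAsFactors = FALSE,
                               row.names = NULL),
         method_b = data.frame(gene = src, log2fc = lfc_b, pvalue = p_b,
                               method = "nb_wald", stringsAsFactors = FALSE,
                               row.names = NULL),
         homology = homology,
         deg_truth = lfc)
  })
}
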