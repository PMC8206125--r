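test_that("the factor model produces the planted gene-eigengene geometry", {
  # a loading of exactly 1 reproduces the eigengene; a loading of 0 is noise
  cfg <- sim_config(n_genes = 600, module_sizes = c(120),
                    n_samples_ref = 100, n_samples_test = 10,
                    loading_range = c(1, 1), covariate_effect_size = 0,
                    interval_placement = stats::setNames(
                      c(1, rep(0, 20)), sprintf("IVG%02d", 1:21)),
                    interval_weak = character(0), seed = 3)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  me <- sim$truth$true_eigengenes_ref["ME1", ]
  g <- names(lab)[lab == 1][5]
  centred <- sim$ref[g, ] - mean(sim$ref[g, ])
  expect_equal(max(abs(centred - (me - mean(me)))), 0, tolerance = 1e-10)

  # background genes: mean |cor| with the eigengene stays below 0.1 at n=100
  bg <- names(lab)[lab == 0][1:479]
  cors <- abs(cor(t(sim$ref[bg, ]), me))
  expect_lt(mean(cors), 0.1)
})

test_that("a planted loading is recovered empirically at large n", {
  cfg <- sim_config(n_genes = 80, module_sizes = c(40),
                    n_samples_ref = 1000, n_samples_test = 10,
                    loading_range = c(0.7, 0.7), covariate_effect_size = 0,
                    interval_placement = stats::setNames(
                      c(1, rep(0, 20)), sprintf("IVG%02d", 1:21)),
                    interval_weak = character(0), seed = 4)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  me <- sim$truth$true_eigengenes_ref["ME1", ]
  # ordinary module members only: interval genes may carry special loadings
  mem <- setdiff(names(lab)[lab == 1], sim$truth$interval_genes)
  r_hat <- cor(t(sim$ref[mem, ]), me)
  expect_true(all(abs(r_hat - 0.7) < 0.05))
})

test_that("pairwise correlation converges to the loading product", {
  cfg <- sim_config(n_genes = 100, module_sizes = c(60),
                    n_samples_ref = 2000, n_samples_test = 10,
                    covariate_effect_size = 0,
                    interval_placement = stats::setNames(
                      c(1, rep(0, 20)), sprintf("IVG%02d", 1:21)),
                    seed = 5)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  r <- sim$truth$true_loadings
  mem <- names(lab)[lab == 1]
  set.seed(1)
  pairs <- replicate(60, sample(mem, 2))
  for (j in seq_len(ncol(pairs))) {
    gi <- pairs[1, j]; gj <- pairs[2, j]
    expect_lt(abs(cor(sim$ref[gi, ], sim$ref[gj, ]) - r[gi] * r[gj]), 0.03 * 3)
  }
  obs <- apply(pairs, 2, function(p) cor(sim$ref[p[1], ], sim$ref[p[2], ]))
  expt <- apply(pairs, 2, function(p) r[p[1]] * r[p[2]])
  expect_lt(mean(abs(obs - expt)), 0.03)
})

test_that("a fixed seed gives bit-identical cohorts; covariates are removable", {
  cfg <- sim_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ref, b$ref)
  expect_identical(a$test, b$test)
  expect_identical(a$covariates, b$covariates)

  # residualization restores the gene-eigengene correlation structure of a
  # matched no-covariate simulation
  cfg1 <- sim_config(covariate_effect_size = 1, seed = 8)
  cfg0 <- sim_config(covariate_effect_size = 0, seed = 8)
  s1 <- simulate_cohort(cfg1)
  s0 <- simulate_cohort(cfg0)
  resid <- residualize(s1$ref, s1$covariates)
  lab <- s1$truth$true_partition
  me <- s1$truth$true_eigengenes_ref
  set.seed(1)
  mem <- sample(names(lab)[lab > 0], 200)
  k1 <- vapply(mem, function(g) cor(resid[g, ], me[lab[g], ]), 0)
  k0 <- vapply(mem, function(g) cor(s0$ref[g, ], me[lab[g], ]), 0)
  expect_lt(mean(abs(k1 - k0)), 0.05)
})

test_that("planted disease sets follow their enrichment specification", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_cohort(cfg)
  panels <- plant_disease_sets(sim$truth, sim$ref)
  specs <- cfg$disease_set_specs
  lab <- sim$truth$true_partition
  for (i in seq_along(specs)) {
    nm <- sprintf("disease_%02d", i)
    members <- panels$disease$sets[[nm]]
    expect_length(members, specs[[i]]$size)
    expect_false(specs[[i]]$target %in% members)
    planted <- panels$planted[[nm]]
    expect_length(planted, round(specs[[i]]$size *
                                   specs[[i]]$enrichment_fraction))
    # planted members really are module co-members of the target seed
    if (length(planted) > 0)
      expect_true(all(lab[planted] == lab[specs[[i]]$target]))
  }
  # enrichment exceeding the neighborhood errors
  bad <- list(list(size = 5000, enrichment_fraction = 1,
                   target = specs[[1]]$target))
  expect_error(plant_disease_sets(sim$truth, sim$ref, specs = bad),
               "exceeds neighborhood")
})

test_that("expected module overlap of an enriched set matches linearity", {
  # size 40, enrichment 0.5, module 200, genome 2000:
  # E[overlap with the module] ~= 20 + 20 * (200/2000) = 22
  overlaps <- numeric(200)
  cfg <- sim_config(seed = 1)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  target <- Find(function(s) s$enrichment_fraction == 0.5,
                 cfg$disease_set_specs)$target
  stopifnot(lab[target] == 1)  # module 1 has 400 genes in the default config
  spec <- list(list(size = 40, enrichment_fraction = 0.5, target = target))
  for (rep in seq_len(200)) {
    p <- plant_disease_sets(sim$truth, sim$ref, specs = spec,
                            control_specs = list(), seed = rep)
    overlaps[rep] <- sum(lab[p$disease$sets$disease_01] == lab[target])
  }
  expected <- 20 + 20 * (400 / 2000)   # module size 400 here
  expect_lt(abs(mean(overlaps) - expected), 1.5)
})

test_that("the DEG study plants dosage effects and calibrated nulls", {
  # interval genes at log2FC -1: mutant/wild-type mean count ratio ~ 0.5,
  # averaged over 200 planted genes
  lab <- stats::setNames(rep(c(1L, 0L), c(400, 600)), sprintf("g%04d", 1:1000))
  truth <- list(true_partition = lab,
                interval_genes = names(lab)[1:200],
                config = sim_config(seed = 1))
  deg <- simulate_deg_study(truth, deg_spec = list(
    n_per_group = 50, dispersion = 0.05, lfc_on_interval = -1,
    partner_fraction = 0, lfc_on_partners = 0, homology_coverage = 1),
    seed = 11)
  ratio <- 2^deg$method_a$log2fc[1:200]
  expect_lt(abs(mean(ratio) - 0.5), 0.05)

  # null genes have ~uniform p-values: rejection at 0.05 close to nominal
  null_idx <- 301:1000
  deg5 <- simulate_deg_study(truth, deg_spec = list(
    n_per_group = 5, dispersion = 0.05, lfc_on_interval = -1,
    partner_fraction = 0, lfc_on_partners = 0, homology_coverage = 1),
    seed = 12)
  fr_a <- mean(deg5$method_a$pvalue[null_idx] < 0.05)
  fr_b <- mean(deg5$method_b$pvalue[null_idx] < 0.05)
  expect_lt(abs(fr_a - 0.05), 0.025)
  expect_lt(abs(fr_b - 0.05), 0.035)

  # homology covers the requested fraction, one-to-one
  cfg <- sim_config(seed = 13)
  sim <- simulate_cohort(cfg)
  d <- simulate_deg_study(sim$truth)
  expect_equal(nrow(d$homology), round(0.95 * cfg$n_genes))
  expect_false(anyDuplicated(d$homology$source) > 0)
  expect_error(simulate_deg_study(sim$truth, deg_spec = modifyList(
    cfg$deg_spec, list(dispersion = 0))), "dispersion")
  expect_error(simulate_deg_study(sim$truth, deg_spec = modifyList(
    cfg$deg_spec, list(n_per_group = 2))), "at least 3")
})
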