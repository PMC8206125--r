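test_that("interval modules mirror the locus distribution of the partition", {
  # 21 locus genes spread over 7 modules with counts (1,4,1,6,1,3,5)
  counts <- c(1, 4, 1, 6, 1, 3, 5)
  iv <- sprintf("IVG%02d", 1:21)
  part <- stats::setNames(c(rep(seq_along(counts), counts),
                            rep(c(3L, 0L), c(40, 40))),
                          c(iv, sprintf("G%03d", 1:80)))
  im <- interval_modules(part, iv)
  expect_length(im, 7)
  expect_equal(unname(lengths(im)[as.character(1:7)]), counts)
  # an unassigned interval gene does not create an interval module
  part2 <- part
  part2["IVG01"] <- 0L
  im2 <- interval_modules(part2, iv)
  expect_false("1" %in% names(im2))
  expect_identical(attr(im2, "unassigned"), "IVG01")
  # all interval genes in one module
  part3 <- stats::setNames(rep(1L, 21), iv)
  expect_length(interval_modules(part3, iv)[["1"]], 21)
  expect_error(interval_modules(stats::setNames(0L, "IVG01"), "IVG01"),
               "no interval gene")
})

test_that("hub calls require both the kME and significance thresholds", {
  genes <- c("hub1", "mid1", "low1")
  r <- matrix(c(0.84, 0.9, 0.11), 3, 1,
              dimnames = list(genes, "1"))
  p <- matrix(c(8.33e-30, 0.2, 0.25), 3, 1, dimnames = list(genes, "1"))
  part <- stats::setNames(rep(1L, 3), genes)
  hubs <- call_hubs(list(r = r, p = p), part, genes)
  expect_true(hubs$hub[hubs$gene == "hub1"])
  expect_false(hubs$hub[hubs$gene == "mid1"])   # kME high but p fails
  expect_false(hubs$hub[hubs$gene == "low1"])
  expect_true(hubs$low_connectivity[hubs$gene == "low1"])
  expect_false(hubs$low_connectivity[hubs$gene == "hub1"])
})

test_that("top neighbors are intramodular, thresholded, and symmetric", {
  cfg <- small_config(seed = 11)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  expr <- sim$ref
  seeds <- names(lab)[lab == 1][1:2]
  tn <- top_neighbors(expr, lab, seeds[1])
  expect_s3_class(tn, "top_neighbor_set")
  expect_true(all(lab[tn$members$gene] == lab[seeds[1]]))
  expect_false(seeds[1] %in% tn$members$gene)
  expect_true(all(tn$members$rho >= 0.5 & tn$members$p < 0.05))
  # symmetry: mutual membership for two co-module seeds above threshold
  tn2 <- top_neighbors(expr, lab, seeds[2])
  if (seeds[2] %in% tn$members$gene)
    expect_true(seeds[1] %in% tn2$members$gene)
  # a gene outside the module never appears, however correlated
  expect_true(all(tn$members$gene %in% names(lab)[lab == 1]))
  expect_error(top_neighbors(expr, lab, names(lab)[lab == 0][1]),
               "not assigned")
  # an uncorrelated seed yields an empty set: plant a flat noise gene
  expr_flat <- rbind(expr, seedx = rnorm(ncol(expr)))
  lab_flat <- c(lab, seedx = 1L)
  tn3 <- top_neighbors(expr_flat, lab_flat, "seedx")
  expect_equal(nrow(tn3$members), 0)
})

test_that("hypergeometric overlap is exact", {
  # N=10, K=5, n=4, q=4 -> C(5,4)/C(10,4) = 5/210
  uni <- paste0("u", 1:10)
  res <- hypergeom_overlap(uni[1:4], uni[1:5], uni)
  expect_equal(res$p_raw, 5 / 210, tolerance = 1e-15)
  # enumeration oracle agrees
  expect_equal(res$p_raw, hyper_upper_enum(10, 5, 4, 4), tolerance = 1e-12)
  # q = 0 -> upper tail from zero is 1
  res0 <- hypergeom_overlap(uni[6:9], uni[1:5], uni[c(1:5, 6:9)])
  expect_lte(abs(res0$p_raw - 1), 1e-15)
  expect_error(hypergeom_overlap(character(0), uni[1:2], character(0)),
               "empty universe")
  # intersection with the universe happens before testing
  res2 <- hypergeom_overlap(c(uni[1:4], "offworld"), uni[1:5], uni)
  expect_equal(res2$neighbors_in_universe, 4)
})

test_that("BH adjustment follows the step-up procedure within families", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  fam <- c("a", "a", "b")
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), fam),
               c(0.02, 0.02, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("the enrichment screen finds planted sets with specificity", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  expr <- residualize(sim$ref, sim$covariates)
  panels <- plant_disease_sets(sim$truth, sim$ref)
  eg <- module_eigengenes(expr, lab)
  res <- prioritize_interval(expr, lab, eg$kme, sim$truth$interval_genes,
                             panels$disease, panels$control)
  planted_targets <- vapply(Filter(function(s) s$enrichment_fraction > 0,
                                   cfg$disease_set_specs),
                            function(s) s$target, "")
  expect_true(all(planted_targets %in% res$drivers$prioritized_seeds))
  spec <- res$screen$specificity
  ctrl <- spec$fraction_significant[spec$family == "control"]
  dis <- spec$fraction_significant[spec$family == "disease"]
  expect_lte(ctrl, 0.10)
  expect_gt(dis, ctrl)
  # seed eligibility implements the low-connectivity exclusion exactly:
  # eligible seeds are the assigned interval genes with significant own-
  # module kME, and every excluded gene fails that significance test
  hubs <- res$hubs
  expect_setequal(res$eligible_seeds, hubs$gene[!hubs$low_connectivity])
  expect_true(all(hubs$p[hubs$low_connectivity] >= 0.05))
  excluded <- setdiff(hubs$gene, res$eligible_seeds)
  expect_true(all(excluded %in% hubs$gene[hubs$p >= 0.05]))
  # drivers: provenance genes always belong to both the neighbor set and set
  prov <- res$drivers$provenance
  for (i in seq_len(min(nrow(prov), 20))) {
    s <- Find(function(x) x$seed == prov$seed[i], res$neighbor_sets)
    expect_true(prov$gene[i] %in% s$members$gene)
    expect_true(prov$gene[i] %in% panels$disease$sets[[prov$gene_set[i]]])
  }
})

test_that("driver assembly is a pure function of significant overlaps", {
  ns <- list(structure(list(seed = "s1", module = 1L,
                            members = data.frame(gene = c("g1", "g2", "g3"),
                                                 rho = c(0.9, 0.8, 0.7),
                                                 p = rep(1e-6, 3))),
                       class = "top_neighbor_set"))
  disease <- gene_set_collection(list(dz = c("g1", "g2", "far")))
  screen_sig <- list(overlaps = data.frame(
    seed = "s1", gene_set = "dz", family = "disease", significant = TRUE))
  dr <- assemble_drivers(screen_sig, ns, disease)
  expect_identical(dr$prioritized_seeds, "s1")
  expect_identical(dr$partner_drivers, c("g1", "g2"))
  expect_identical(dr$genes, c("g1", "g2", "s1"))
  # no significant test -> empty driver set
  screen_null <- list(overlaps = data.frame(
    seed = "s1", gene_set = "dz", family = "disease", significant = FALSE))
  dr0 <- assemble_drivers(screen_null, ns, disease)
  expect_length(dr0$genes, 0)
  # invariance to row order of the overlap table
  screen2 <- list(overlaps = screen_sig$overlaps[
    rev(seq_len(nrow(screen_sig$overlaps))), ])
  expect_identical(assemble_drivers(screen2, ns, disease)$genes, dr$genes)
})
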