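test_that("signed adjacency maps correlations as the formula dictates", {
  corr <- matrix(c(1, 1, -1, 0,
                   1, 1, 0, 0.5,
                   -1, 0, 1, 0,
                   0, 0.5, 0, 1), 4, 4)
  dimnames(corr) <- list(paste0("g", 1:4), paste0("g", 1:4))
  a <- signed_adjacency(corr, beta = 8)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  expect_equal(a["g1", "g4"], 0.5^8)   # = 0.00390625
  expect_equal(diag(a), stats::setNames(rep(1, 4), rownames(corr)))
  expect_error(signed_adjacency(corr * 1.5, 8), "outside")

  # monotone in corr; increasing beta never increases off-diagonals
  set.seed(1)
  cc <- cor(matrix(rnorm(200), 20, 10))
  a4 <- signed_adjacency(cc, 4)
  a8 <- signed_adjacency(cc, 8)
  off <- upper.tri(cc)
  expect_true(all(a8[off] <= a4[off] + 1e-15))
  ord <- order(cc[off])
  expect_true(all(diff(a8[off][ord]) >= -1e-15))
})

test_that("power selection takes the lowest power reaching the target", {
  sft <- data.frame(power = c(2, 4, 6, 8, 10),
                    signed_r2 = c(0.2, 0.55, 0.78, 0.83, 0.86))
  expect_equal(pick_soft_power(sft, 0.8), 8)
  sft$signed_r2 <- c(0.2, 0.4, 0.5, 0.6, 0.7)
  expect_warning(p <- pick_soft_power(sft, 0.8), "best-fitting")
  expect_equal(p, 10)
  expect_error(sft_scan(matrix(1, 2, 4), powers = 5), "at least 2")
})

test_that("the default synthetic cohort reaches the scale-free target", {
  sim <- simulate_cohort(sim_config(seed = 21))
  expr <- residualize(sim$ref, sim$covariates)
  sft <- sft_scan(expr)
  beta <- pick_soft_power(sft)
  expect_lte(beta, 12)
  expect_gte(sft$signed_r2[sft$power == beta], 0.8)
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  # 3 genes, all off-diagonal adjacencies 0.5:
  # l_12 = 0.25, k = 1 -> TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tt <- tom_similarity(a)
  expect_equal(tt["g1", "g2"], 0.5, tolerance = 1e-15)
  expect_equal(diag(tt), stats::setNames(rep(1, 3), rownames(a)))

  # zero adjacency stays zero
  z <- diag(3); dimnames(z) <- dimnames(a)
  expect_equal(tom_similarity(z)[upper.tri(z)], rep(0, 3))

  # random adjacency equals the O(n^3) oracle elementwise
  adj <- random_adjacency(50, seed = 7)
  expect_lt(max(abs(tom_similarity(adj) - tom_oracle(adj))), 1e-12)

  # entries stay in [0, 1] on random valid inputs
  for (s in 1:5) {
    adj <- random_adjacency(40, seed = 100 + s)
    tt <- tom_similarity(adj)
    expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
  }
})

test_that("eigengenes match a full-decomposition oracle", {
  set.seed(8)
  expr <- matrix(rnorm(30 * 25), 30, 25,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:25)))
  part <- stats::setNames(rep(1L, 30), rownames(expr))
  eg <- module_eigengenes(expr, part)
  xs <- t(scale(t(expr)))
  sv <- svd(xs)
  v1 <- sv$v[, 1]
  if (mean(xs %*% v1) < 0) v1 <- -v1
  expect_lt(max(abs(eg$eigengenes["1", ] - v1)), 1e-10)
  expect_equal(unname(eg$prop_var["1"]), sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-10)
  kme_oracle <- cor(t(expr), v1)[, 1]
  expect_lt(max(abs(eg$kme$r[, "1"] - kme_oracle)), 1e-10)

  # identical genes: rank-1 module, prop_var 1, ME = the common profile
  common <- rnorm(25)
  expr2 <- matrix(rep(common, each = 10), 10, 25,
                  dimnames = list(paste0("h", 1:10), paste0("s", 1:25)))
  eg2 <- module_eigengenes(expr2, stats::setNames(rep(1L, 10),
                                                  rownames(expr2)))
  expect_equal(unname(eg2$prop_var["1"]), 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg2$eigengenes["1", ], common)), 1, tolerance = 1e-12)

  # kME of a gene identical to its ME is 1 with a vanishing p-value
  cfg <- small_config(seed = 3)
  sim <- simulate_cohort(cfg)
  lab <- sim$truth$true_partition
  eg3 <- module_eigengenes(sim$ref, lab)
  g_top <- names(which.max(eg3$kme$r[names(lab)[lab == 1], "1"]))
  expect_lt(eg3$kme$p[g_top, "1"], 1e-10)
})

test_that("kME p-values are uniform under the null", {
  set.seed(9)
  n <- 100
  me <- rnorm(n)
  nulls <- matrix(rnorm(5000 * n), 5000, n)
  r <- as.vector(cor(t(nulls), me))
  p <- locusnet:::cor_pvalue(r, n)
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.03)
})

test_that("cluster_and_cut honors the minimum module size", {
  adj <- random_adjacency(20, seed = 3)
  cut <- cluster_and_cut(1 - adj, network_config(min_module_size = 30))
  expect_true(all(cut$partition == 0))
})

test_that("close modules merge, orthogonal modules do not", {
  set.seed(10)
  n <- 60
  me_a <- rnorm(n)
  me_c <- rnorm(n)   # independent of me_a
  mk <- function(me, k) t(sapply(seq_len(k),
                                 function(i) 0.9 * me + 0.436 * rnorm(n)))
  expr <- rbind(mk(me_a, 30), mk(me_a, 30), mk(me_c, 30))
  dimnames(expr) <- list(sprintf("g%03d", 1:90), sprintf("s%02d", 1:n))
  part <- stats::setNames(rep(c(1L, 2L, 3L), each = 30), rownames(expr))
  merged <- merge_close_modules(expr, part)
  lab <- merged$partition
  # the two artificially split halves end up together, away from module C
  expect_equal(length(unique(lab[1:60])), 1)
  expect_false(lab[1] == lab[61])
  expect_equal(max(merged$partition), 2)
})

test_that("chained eigengene correlations merge exactly as far as they reach", {
  # r(A,B) = r(B,C) = 0.85, r(A,C) = 0.5: average linkage joins one close
  # pair at height 0.15; the merged pair's recomputed eigengene correlates
  # (0.85 + 0.5)/sqrt(2 + 2 * 0.85) ~= 0.70 < 0.8 with the third module, so
  # the chain stops at two modules
  chain_expr <- function(r_ac, seed) {
    set.seed(seed)
    n <- 400
    sig <- matrix(c(1, 0.85, r_ac,
                    0.85, 1, 0.85,
                    r_ac, 0.85, 1), 3, 3)
    mes <- matrix(rnorm(3 * n), n, 3) %*% chol(sig)
    mk <- function(me, k) t(sapply(seq_len(k),
                                   function(i) 0.95 * me + 0.312 * rnorm(n)))
    expr <- rbind(mk(mes[, 1], 25), mk(mes[, 2], 25), mk(mes[, 3], 25))
    dimnames(expr) <- list(sprintf("g%03d", 1:75), sprintf("s%03d", 1:n))
    expr
  }
  part <- stats::setNames(rep(c(1L, 2L, 3L), each = 25),
                          sprintf("g%03d", 1:75))
  merged <- merge_close_modules(chain_expr(0.5, seed = 11), part)
  expect_equal(max(merged$partition), 2)
  # with r(A,C) = 0.75 the merged pair's eigengene clears 0.8 against the
  # remaining module, and iteration collapses the chain to one module
  merged2 <- merge_close_modules(chain_expr(0.75, seed = 12), part)
  expect_equal(max(merged2$partition), 1)
})

test_that("meta-modules group positively correlated eigengenes", {
  # dissimilarity 1 - cor: cor 0.7 -> 0.3 (below 0.5, same meta-module);
  # cor -0.2 -> 1.2 (separate)
  set.seed(12)
  n <- 2000
  base <- rnorm(n)
  me1 <- base + 0.55 * rnorm(n)
  me2 <- base + 0.55 * rnorm(n)          # cor(me1, me2) ~ 0.7
  me3 <- rnorm(n) - 0.45 * base          # mildly anticorrelated with base
  eg <- rbind("1" = me1, "2" = me2, "3" = me3)
  mm <- meta_modules(eg, cut_height = 0.5)
  expect_equal(mm[["1"]], mm[["2"]])
  expect_false(mm[["3"]] == mm[["1"]])
  expect_error(meta_modules(eg[1, , drop = FALSE]), "at least 2")
})

test_that("meta-module recovery matches a two-group eigengene design", {
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 300
    base1 <- rnorm(n); base2 <- rnorm(n)
    mk_me <- function(b) sqrt(0.6) * b + sqrt(0.4) * rnorm(n)
    eg <- rbind("1" = mk_me(base1), "2" = mk_me(base1),
                "3" = mk_me(base2), "4" = mk_me(base2))
    mm <- meta_modules(eg, 0.5)
    ok <- mm[["1"]] == mm[["2"]] && mm[["3"]] == mm[["4"]] &&
      mm[["1"]] != mm[["3"]]
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("the full network stage is deterministic given the input", {
  sim <- simulate_cohort(small_config(seed = 6))
  a <- build_network(sim$ref, network_config(beta = 6))
  b <- build_network(sim$ref, network_config(beta = 6))
  expect_identical(a$partition, b$partition)
  expect_identical(a$eigengenes$eigengenes, b$eigengenes$eigengenes)
})
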