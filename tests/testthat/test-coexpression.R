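test_that("scale-free fit index behaves on constructed degree sequences", {
  # multiplicities proportional to k^-2 give an approximate power law
  k <- 1:50
  degrees <- rep(k, times = round(1000 * k^-2))
  expect_gt(scale_free_fit_index(degrees), 0.9)
  # degrees engineered so occupied log-log bins lie on an exact line
  expect_error(scale_free_fit_index(rep(3, 100)), "degenerate")
})

test_that("perfect power-law bins give R squared of 1", {
  # two occupied bins always fit exactly; use a 3-bin exact construction
  set.seed(1)
  # construct degrees so that bin means and frequencies obey freq = C*k^-1
  degrees <- c(rep(1, 100), rep(10, 10), rep(100, 1))
  r2 <- suppressWarnings(scale_free_fit_index(degrees, n_bins = 100L))
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("adjacency matches the definition and a brute-force loop", {
  set.seed(7)
  x <- matrix(rnorm(30 * 20), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  a <- adjacency_matrix(x, 2L)
  expect_true(all(diag(a) == 0))
  expect_true(all(a >= 0 & a <= 1))
  for (i in sample(30, 5)) for (j in sample(30, 5)) {
    if (i == j) next
    expect_equal(a[i, j], abs(cor(x[i, ], x[j, ]))^2, tolerance = 1e-10)
  }
  x[3, ] <- 5
  expect_error(adjacency_matrix(x, 2L), "zero-variance gene: g3")
})

test_that("topological overlap matches the formula and the triple loop", {
  # isolated pair with full adjacency
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(topological_overlap(a)[1, 2], 1)
  # fully connected triangle
  a3 <- matrix(1, 3, 3); diag(a3) <- 0
  expect_equal(topological_overlap(a3)[1, 2], 1)
  # all-zero adjacency
  z <- matrix(0, 4, 4)
  expect_true(all(topological_overlap(z)[upper.tri(z)] == 0))
  # oracle equivalence on random instances
  set.seed(5)
  for (rep in 1:3) {
    n <- sample(10:40, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-10)
  }
})

test_that("module eigengene is the first right singular vector", {
  set.seed(9)
  x <- matrix(rnorm(300), nrow = 15,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:20)))
  eg <- module_eigengene(x, paste0("g", 1:10))
  expect_equal(sum(eg^2), 1, tolerance = 1e-9)
  z <- t(scale(t(x[1:10, ])))
  v1 <- svd(z)$v[, 1]
  expect_equal(abs(cor(eg, v1)), 1, tolerance = 1e-9)
  # identical profiles: eigengene is the standardized shared profile
  xx <- x
  for (i in 2:5) xx[i, ] <- xx[1, ]
  eg2 <- module_eigengene(xx, paste0("g", 1:5))
  prof <- scale(xx[1, ])[, 1]
  expect_equal(abs(cor(eg2, prof)), 1, tolerance = 1e-9)
  expect_gt(cor(eg2, prof), 0)  # positive orientation
  # single-gene module
  eg3 <- module_eigengene(x, "g7")
  expect_equal(abs(cor(eg3, x[7, ])), 1, tolerance = 1e-9)
  expect_error(module_eigengene(x, character(0)), "empty")
})

test_that("eigengene explains at least as much variance as any member", {
  set.seed(21)
  x <- matrix(rnorm(40 * 25), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:25)))
  for (rep in 1:10) {
    members <- sample(rownames(x), 8)
    z <- t(scale(t(x[members, ])))
    eg <- module_eigengene(x, members)
    ev_eigen <- sum((z %*% eg)^2)
    for (m in members) {
      surrogate <- scale(x[m, ])[, 1]
      surrogate <- surrogate / sqrt(sum(surrogate^2))
      expect_gte(ev_eigen + 1e-9, sum((z %*% surrogate)^2))
    }
  }
})

test_that("two noiseless factor blocks are split perfectly", {
  set.seed(13)
  f1 <- rnorm(30); f2 <- rnorm(30)
  lam <- runif(80, 0.5, 1)
  x <- rbind(lam[1:40] %o% f1, lam[41:80] %o% f2)
  dimnames(x) <- list(paste0("g", 1:80), paste0("s", 1:30))
  mods <- detect_modules(x, power = 6L, min_size = 10L)
  truth <- rep(c("A", "B"), each = 40)
  expect_equal(adjusted_rand(mods$assignment, truth), 1)
  expect_identical(sort(unname(unique(mods$assignment))), c("M1", "M2"))
})

test_that("pure noise yields essentially no modules", {
  aris <- numeric(10)
  for (r in 1:10) {
    set.seed(300 + r)
    x <- matrix(rnorm(100 * 40), nrow = 100,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:40)))
    mods <- detect_modules(x, power = 6L, min_size = 30L)
    aris[r] <- adjusted_rand(mods$assignment, rep("bg", 100))
  }
  # adjusted Rand vs the all-background labeling; 1 when nothing is called
  expect_gte(mean(aris >= 0.9), 0.9)
})

test_that("module detection recovers the planted cohort structure", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  sft <- pick_soft_threshold(co$expression, powers = 1:12)
  expect_true(sft$chosen_power %in% 1:12)
  # reported fit indices are recomputable from reported connectivities
  i <- which(sft$report$power == sft$chosen_power)
  expect_equal(sft$report$fit_index[i],
               scale_free_fit_index(sft$connectivities[[i]]),
               tolerance = 1e-12)
  mods <- detect_modules(co$expression, sft$chosen_power, min_size = 15L)
  ari <- adjusted_rand(mods$assignment,
                       co$truth$module_of_gene[names(mods$assignment)])
  expect_gte(ari, 0.9)
  # eigengene rows are unit norm
  expect_equal(rowSums(mods$eigengenes^2),
               rep(1, nrow(mods$eigengenes)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("module assignment is invariant under gene permutation", {
  cfg <- small_config(seed = 5L)
  co <- generate_cohort(cfg)
  x <- co$expression
  set.seed(1)
  perm <- sample(nrow(x))
  m1 <- detect_modules(x, 6L, min_size = 15L)
  m2 <- detect_modules(x[perm, ], 6L, min_size = 15L)
  expect_equal(adjusted_rand(m1$assignment[rownames(x)],
                             m2$assignment[rownames(x)]), 1)
})

test_that("module-trait correlation matches the Student asymptotic formula", {
  # r = 0.5, n = 47 gives t = 3.873, p = 3.44e-4
  r <- 0.5; n <- 47
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t, 3.873, tolerance = 1e-3)
  expect_equal(2 * pt(-t, n - 2), 3.44e-4, tolerance = 1e-2)
  # a trait equal to an eigengene correlates perfectly
  cfg <- small_config()
  co <- generate_cohort(cfg)
  mods <- detect_modules(co$expression, 6L, min_size = 15L)
  tr <- data.frame(sample_id = colnames(co$expression),
                   self = mods$eigengenes[1, ])
  mt <- module_trait_correlation(mods, tr)
  row <- mt[mt$module == rownames(mods$eigengenes)[1], ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_lt(row$p, 1e-100)
  expect_error(
    module_trait_correlation(mods, data.frame(
      sample_id = colnames(co$expression), flat = 1)),
    "constant trait: flat")
})

test_that("planted trait-module coupling is recovered at the target r", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  ami <- co$meta$sample_id[co$meta$group == "AMI"]
  mods <- detect_modules(co$expression[, ami], 6L, min_size = 15L)
  mt <- module_trait_correlation(mods, co$traits)
  mapping <- match_modules(mods$assignment, co$truth$module_of_gene)
  linked <- mapping[[co$truth$trait_module_links[["infarct_size"]]]]
  row <- mt[mt$module == linked & mt$trait == "infarct_size", ]
  expect_lt(abs(abs(row$r) - 0.6), 0.15)
  expect_lt(row$p_adj, 0.05)
})

test_that("shuffled traits rarely reach significance", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  ami <- co$meta$sample_id[co$meta$group == "AMI"]
  mods <- detect_modules(co$expression[, ami], 6L, min_size = 15L)
  set.seed(99)
  traits <- setdiff(colnames(co$traits), "sample_id")
  hits <- matrix(FALSE, 200, length(traits), dimnames = list(NULL, traits))
  for (r in 1:200) {
    tr <- co$traits
    tr$sample_id <- sample(tr$sample_id)
    mt <- module_trait_correlation(mods, tr)
    for (tn in traits)
      hits[r, tn] <- any(mt$p_adj[mt$trait == tn] < 0.05)
  }
  # BH is calibrated per trait family
  for (tn in traits) expect_lte(mean(hits[, tn]), 0.10)
})
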