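test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$traits, b$traits)
  expect_identical(a$functional, b$functional)
  expect_identical(a$truth$module_of_gene, b$truth$module_of_gene)
})

test_that("cohort layout and invariants match the configuration", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  expect_identical(dim(co$expression), c(300L, 67L))
  expect_identical(sum(co$meta$group == "AMI"), 47L)
  expect_identical(sum(co$meta$subgroup == "Small"), 23L)
  expect_identical(sum(co$meta$subgroup == "Large"), 24L)
  expect_true(all(co$meta$subgroup[co$meta$group == "control"] == "none"))
  expect_identical(nrow(co$traits), 47L)
  sizes <- table(co$truth$module_of_gene)
  expect_identical(as.integer(sizes[paste0("M", 1:5)]),
                   cfg$module_sizes + 1L)  # planted TF included
  expect_error(synthetic_config(n_small = 10L),
               "n_small \\+ n_large")
  expect_error(synthetic_config(
    trait_couplings = data.frame(trait = "t", module = 1L, r = 1.2)),
    "\\|r\\| < 1")
})

test_that("with no group shift, module-factor group tests are null-uniform", {
  cfg <- synthetic_config(n_genes = 30L, module_sizes = rep(3L, 5L),
                          group_shift = rep(0, 5L),
                          subgroup_shift = rep(0, 5L))
  pvals <- numeric(200)
  for (r in 1:200) {
    cfg$seed <- r
    co <- generate_cohort(cfg)
    f <- co$truth$factors[1L, ]
    ami <- co$meta$group == "AMI"
    pvals[r] <- welch_t(f[ami], f[!ami])$p
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted modules are internally co-expressed above background", {
  cfg <- synthetic_config(n_genes = 300L, n_modules = 1L,
                          module_sizes = 50L, loading_range = c(0.6, 0.9),
                          group_shift = 0, subgroup_shift = 0,
                          trait_couplings = data.frame(
                            trait = "infarct_size", module = 1L, r = 0.6),
                          seed = 1L)
  co <- generate_cohort(cfg)
  members <- names(co$truth$module_of_gene)[
    co$truth$module_of_gene == "M1" &
      !startsWith(names(co$truth$module_of_gene), "TF")]
  bg <- names(co$truth$module_of_gene)[
    co$truth$module_of_gene == "background"]
  cw <- abs(cor(t(co$expression[members, ])))
  within <- mean(cw[upper.tri(cw)])
  cb <- abs(cor(t(co$expression[members, ]), t(co$expression[bg, ])))
  expect_gt(within - mean(cb), 0.2)
})

test_that("same-module gene covariance equals the product of loadings", {
  cfg <- synthetic_config(n_genes = 20L, n_modules = 1L, module_sizes = 10L,
                          n_ami = 2500L, n_ctrl = 2500L,
                          n_small = 1250L, n_large = 1250L,
                          group_shift = 0, subgroup_shift = 0,
                          trait_couplings = data.frame(
                            trait = "infarct_size", module = 1L, r = 0.6),
                          n_tfs = 1L, seed = 3L)
  co <- generate_cohort(cfg)
  members <- names(co$truth$module_of_gene)[
    co$truth$module_of_gene == "M1" &
      !startsWith(names(co$truth$module_of_gene), "TF")]
  # expression is scaled by 2, so covariances scale by 4
  cv <- cov(t(co$expression[members, ])) / 4
  lam <- co$truth$loadings[members]
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(abs(cv[i, j] - lam[i] * lam[j]), 0.05)
  }
})

test_that("planted TF-target mutual information beats TF-background", {
  diffs <- numeric(50)
  for (r in 1:50) {
    cfg <- synthetic_config(n_genes = 60L, n_modules = 1L,
                            module_sizes = 20L, n_tfs = 1L,
                            targets_per_tf = 20L,
                            group_shift = 0, subgroup_shift = 0,
                            trait_couplings = data.frame(
                              trait = "infarct_size", module = 1L, r = 0.6),
                            seed = 100L + r)
    co <- generate_cohort(cfg)
    tf <- co$expression["TF01", ]
    tg <- co$truth$targets_of_tf[["TF01"]]
    bg <- names(co$truth$module_of_gene)[
      co$truth$module_of_gene == "background"][1:20]
    mi_t <- mean(vapply(tg, function(g)
      mutual_information(tf, co$expression[g, ]), numeric(1)))
    mi_b <- mean(vapply(bg, function(g)
      mutual_information(tf, co$expression[g, ]), numeric(1)))
    diffs[r] <- mi_t - mi_b
  }
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("perturbation database plants reversers and is deterministic", {
  cfg <- small_config(n_drugs = 10L, n_reversers = 0L)
  sig <- structure(list(up = paste0("G", sprintf("%05d", 1:20)),
                        down = paste0("G", sprintf("%05d", 21:30))),
                   class = "signature")
  genes <- paste0("G", sprintf("%05d", 1:300))
  a <- generate_perturbation_db(cfg, sig, genes)
  b <- generate_perturbation_db(cfg, sig, genes)
  expect_identical(a$db, b$db)
  expect_length(a$reversers, 0L)
  # null database: scores centered near zero
  conn <- connectivity_scores(sig, a$db)
  expect_lt(abs(median(conn$c)), 0.25)

  # an overwhelming reverser gain forces every up-gene below every other
  cfg2 <- small_config(n_drugs = 5L, n_reversers = 1L, reverser_gain = 50)
  d <- generate_perturbation_db(cfg2, sig, genes)
  z <- as.numeric(d$db[d$db$drug == d$reversers, genes])
  expect_true(all(rank(z)[match(sig$up, genes)] <= length(sig$up)))
  expect_error(
    generate_perturbation_db(small_config(n_drugs = 2L, n_reversers = 5L),
                             sig, genes),
    "n_reversers")
})
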