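test_that("GBLUP and rrBLUP produce equivalent GEBVs", {
  cfg <- single_stage_cfg(n = 120, m = 300, seed = 31)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  f1 <- gblup_fit(bl, list(G = GA))
  f2 <- rrblup_fit(bl, dat$geno)
  expect_gt(cor(f1$gebv, f2$gebv[names(f1$gebv)]), 0.999)
  # marker effects reproduce the GEBVs
  W <- sweep(dat$geno$dosages, 2, 2 * dat$geno$allele_freq)
  expect_gt(cor(drop(W %*% f2$marker_effects), f2$gebv), 0.999999)
})

test_that("unphenotyped genotypes are predicted through the covariance", {
  cfg <- single_stage_cfg(n = 150, m = 300, h2 = 0.8, seed = 32)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  train <- dat$geno$ids[1:100]
  fit <- gblup_fit(bl[train], list(G = GA))
  test <- setdiff(dat$geno$ids, train)
  expect_true(all(test %in% names(fit$gebv)))
  pa <- cor(fit$gebv[test], dat$true$breeding_values[test, "TRS"])
  expect_gt(pa, 0.5)

  # an individual with zero covariance to training shrinks to the mean (0)
  ids2 <- c(train, "stranger")
  K2 <- unclass(GA)[ids2[1:100], ids2[1:100]]
  K2 <- rbind(cbind(K2, 0), 0)
  K2[101, 101] <- 1
  dimnames(K2) <- list(ids2, ids2)
  f0 <- gblup_fit(bl[train], list(G = rel_matrix(K2, "G_A")))
  expect_lt(abs(f0$gebv["stranger"]), 1e-8)
})

test_that("noise-free additive signal is recovered almost perfectly", {
  cfg <- single_stage_cfg(n = 300, m = 1000, n_chr = 5, h2 = 0.99,
                          resid = 0.01, seed = 33)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  fit <- gblup_fit(bl, list(G = GA))
  expect_gt(cor(fit$gebv, dat$true$breeding_values[names(fit$gebv), "TRS"]), 0.99)
})

test_that("dominance variance stays small when the trait is purely additive", {
  pas <- replicate(5, {
    seed <- sample.int(1e4, 1)
    cfg <- single_stage_cfg(n = 150, m = 300, seed = seed)
    dat <- simulate_dataset(cfg)
    bl <- stage_blues(dat)
    GA <- build_grm(dat$geno, "additive")
    GD <- build_grm(dat$geno, "dominance")
    f <- gblup_fit(bl, list(G = GA, D = GD))
    unname(f$varcomps["D"] / f$varcomps["G"])
  })
  expect_lt(mean(pas), 0.15)
})

test_that("Bayesian sampler bookkeeping and determinism hold", {
  cfg <- single_stage_cfg(n = 80, m = 120, seed = 34)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  f1 <- bayes_fit(bl, dat$geno, "BRR", n_iter = 1200, burn_in = 200,
                  thin = 5, seed = 7)
  expect_equal(f1$n_retained, (1200 - 200) / 5)
  f2 <- bayes_fit(bl, dat$geno, "BRR", n_iter = 1200, burn_in = 200,
                  thin = 5, seed = 7)
  expect_identical(f1$chains$varE, f2$chains$varE)
  expect_identical(f1$gebv, f2$gebv)
  expect_error(bayes_fit(bl, dat$geno, "BRR", n_iter = 100, burn_in = 200),
               "n_iter")
})

test_that("every Bayesian prior tracks the ridge solution on dense signal", {
  cfg <- single_stage_cfg(n = 150, m = 250, seed = 35)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  fr <- rrblup_fit(bl, dat$geno)
  for (m in c("BRR", "BL", "BayesA", "BayesB", "BayesC")) {
    fb <- bayes_fit(bl, dat$geno, m, n_iter = 2000, burn_in = 500,
                    thin = 5, seed = 7)
    expect_gt(cor(fb$gebv, fr$gebv[names(fb$gebv)]), 0.95)
  }
})

test_that("Bayesian chains pass a split-half convergence check", {
  cfg <- single_stage_cfg(n = 100, m = 150, seed = 36)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  fb <- bayes_fit(bl, dat$geno, "BRR", n_iter = 4000, burn_in = 1000,
                  thin = 2, seed = 8)
  ch <- fb$chains$varE
  half <- length(ch) %/% 2
  rhat <- function(a, b) {
    mw <- mean(c(var(a), var(b)))
    mb <- var(c(mean(a), mean(b))) * length(a)
    sqrt((mw * (length(a) - 1) / length(a) + mb / length(a)) / mw)
  }
  expect_lt(rhat(ch[1:half], ch[(half + 1):(2 * half)]), 1.1)
})

test_that("RKHS kernel limits behave as specified", {
  cfg <- single_stage_cfg(n = 80, m = 150, seed = 37)
  dat <- simulate_dataset(cfg)
  # tiny bandwidth: kernel degenerates to all-ones
  expect_error(rkhs_kernel(dat$geno, bandwidth = 1e-8), "degenerate")
  # huge bandwidth: kernel approaches identity, unphenotyped ids shrink to 0
  K <- rkhs_kernel(dat$geno, bandwidth = 50)
  off <- unclass(K)[upper.tri(K)]
  expect_lt(max(abs(off)), 0.05)
  bl <- stage_blues(dat)
  train <- dat$geno$ids[1:60]
  fk <- rkhs_fit(bl[train], dat$geno, bandwidth = 50, n_iter = 600,
                 burn_in = 100, seed = 2)
  test <- setdiff(dat$geno$ids, train)
  expect_lt(max(abs(fk$gebv[test])), 0.1 * sd(bl))
})

test_that("RKHS prediction is competitive with GBLUP on additive data", {
  cfg <- single_stage_cfg(n = 200, m = 400, seed = 38)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  train <- dat$geno$ids[1:150]
  test <- setdiff(dat$geno$ids, train)
  tb <- dat$true$breeding_values[test, "TRS"]
  pa_g <- cor(gblup_fit(bl[train], list(G = GA))$gebv[test], tb)
  fk <- rkhs_fit(bl[train], dat$geno, n_iter = 2000, burn_in = 500, seed = 3)
  pa_k <- cor(fk$gebv[test], tb)
  expect_lt(abs(pa_k - pa_g), 0.15)
})

test_that("ML adapters learn a noiseless linear marker signal", {
  cfg <- single_stage_cfg(n = 400, m = 60, n_chr = 2, seed = 39)
  G <- simulate_genotypes(cfg)
  W <- G$dosages
  beta <- c(2, -1.5, 1, 0.8, -1.2)
  y <- setNames(drop(W[, seq(5, 45, by = 10)] %*% beta), G$ids)
  train <- G$ids[1:320]; test <- setdiff(G$ids, train)
  for (m in c("random_forest", "svr_radial")) {
    f <- ml_fit(y[train], G, m, seed = 5)
    expect_gt(cor(f$gebv[test], y[test]), 0.8)
  }
  # RF seed determinism
  f1 <- ml_fit(y[train], G, "random_forest", seed = 9)
  f2 <- ml_fit(y[train], G, "random_forest", seed = 9)
  expect_identical(f1$gebv, f2$gebv)
  # constant response rejected
  expect_error(ml_fit(setNames(rep(1, length(train)), train), G, "random_forest"),
               "constant")
})

test_that("association scan pins an exact marker signal and flags monomorphs", {
  cfg <- single_stage_cfg(n = 120, m = 200, seed = 40)
  G <- simulate_genotypes(cfg)
  y <- setNames(G$dosages[, 57] * 1.0, G$ids)
  sc <- gwas_scan(y, G, K = NULL)
  expect_equal(which.min(sc$results$p), 57L)

  d <- G$dosages; d[, 1] <- 2
  Gm <- genotype_matrix(d, chrom = G$chrom, pos = G$pos)
  y2 <- setNames(rnorm(120), Gm$ids)
  sc2 <- gwas_scan(y2, Gm, K = NULL)
  expect_equal(sc2$results$p[1], 1)
})

test_that("fixed-SNP GBLUP falls back cleanly and blocks leaky scans", {
  cfg <- single_stage_cfg(n = 100, m = 150, seed = 41)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  # empty selection: identical to the plain GBLUP
  sc <- gwas_scan(bl, dat$geno, K = GA, p_threshold = 1e-12)
  expect_length(sc$selected, 0)
  expect_message(fgs <- gs_with_fixed_snps(bl, list(G = GA), sc, dat$geno),
                 "falling back")
  fpl <- gblup_fit(bl, list(G = GA))
  expect_equal(fgs$gebv, fpl$gebv, tolerance = 1e-10)

  # a scan computed on ids outside the training set is rejected
  train <- dat$geno$ids[1:70]
  sc_full <- gwas_scan(bl, dat$geno, K = GA, p_threshold = 0.05)
  if (length(sc_full$selected)) {
    expect_error(gs_with_fixed_snps(bl[train], list(G = GA), sc_full, dat$geno),
                 "training")
    expect_s3_class(gs_with_fixed_snps(bl[train], list(G = GA), sc_full,
                                       dat$geno, allow_full_data_scan = TRUE),
                    "gebv_fit")
  }
})

test_that("predictions are invariant to genotype ordering", {
  cfg <- single_stage_cfg(n = 90, m = 150, seed = 42)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  f1 <- gblup_fit(bl, list(G = GA))
  perm <- sample(length(bl))
  f2 <- gblup_fit(bl[perm], list(G = GA))
  expect_equal(f1$gebv[names(f1$gebv)], f2$gebv[names(f1$gebv)], tolerance = 1e-6)
})
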