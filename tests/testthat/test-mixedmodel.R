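test_that("REML on balanced one-way data equals the ANOVA oracle on all paths", {
  set.seed(21)
  ng <- 15; nr <- 4
  g <- rep(sprintf("g%02d", 1:ng), each = nr)
  u <- rnorm(ng, 0, 2)
  y <- 10 + u[as.integer(factor(g))] + rnorm(ng * nr, 0, 1.3)
  df <- data.frame(genotype = g, y = y)
  m <- tapply(y, g, mean)
  msb <- nr * var(m)
  msw <- sum((y - m[g])^2) / (ng * nr - ng)
  sg_anova <- (msb - msw) / nr

  for (meth in c("spectral", "ai", "em")) {
    fit <- reml_fit(df, "y", random = rterm("G", "genotype"),
                    method = meth, tol = 1e-10, max_iter = 500)
    expect_equal(unname(fit$varcomps["G"]), sg_anova, tolerance = 1e-5)
    expect_equal(unname(fit$varcomps["resid"]), msw, tolerance = 1e-5)
  }
})

test_that("spectral, AI and EM agree on likelihood and BLUPs with a kernel", {
  cfg <- single_stage_cfg(n = 80, m = 150, seed = 22)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  df <- data.frame(genotype = names(bl), y = unname(bl))
  fs <- reml_fit(df, "y", random = rterm("g", "genotype", K = GA), method = "spectral")
  fa <- reml_fit(df, "y", random = rterm("g", "genotype", K = GA),
                 method = "ai", tol = 1e-9)
  expect_equal(fs$varcomps, fa$varcomps, tolerance = 1e-3)
  expect_equal(fs$loglik, fa$loglik, tolerance = 1e-5)
  expect_gt(cor(fs$blups$g, fa$blups$g[names(fs$blups$g)]), 0.99999)
})

test_that("REML log-likelihood is non-decreasing across EM iterations", {
  cfg <- single_stage_cfg(n = 60, m = 120, seed = 23)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  GD <- build_grm(dat$geno, "dominance")
  df <- data.frame(genotype = names(bl), y = unname(bl))
  fit <- reml_fit(df, "y",
                  random = list(rterm("G", "genotype", K = GA),
                                rterm("D", "genotype", K = GD)),
                  method = "em", max_iter = 40, tol = 1e-12)
  expect_true(all(diff(fit$ll_path) > -1e-8))
})

test_that("adding a kernel never decreases the training REML log-likelihood", {
  cfg <- single_stage_cfg(n = 100, m = 200, seed = 24)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  GA <- build_grm(dat$geno, "additive")
  GD <- build_grm(dat$geno, "dominance")
  hk <- hadamard_kernels(GA, GD)
  f1 <- gblup_fit(bl, list(G = GA))
  f2 <- gblup_fit(bl, list(G = GA, D = GD))
  f4 <- gblup_fit(bl, list(G = GA, D = GD, GG = hk$G_AA, GD = hk$G_AD))
  expect_gte(f2$loglik, f1$loglik - 1e-3)
  expect_gte(f4$loglik, f2$loglik - 1e-3)
})

test_that("degenerate zero-residual data pins the residual at its floor", {
  g <- rep(letters[1:10], each = 3)
  consts <- seq(1, 10)
  y <- consts[as.integer(factor(g))]
  fit <- reml_fit(data.frame(genotype = g, y = y), "y",
                  random = rterm("G", "genotype"), method = "ai")
  expect_lt(fit$varcomps["resid"] / fit$varcomps["G"], 1e-4)
  blup <- fit$blups$G + fit$beta[1]
  expect_equal(unname(blup[letters[1:10]]), consts, tolerance = 0.05)
})

test_that("BLUEs equal raw means on balanced noise-free data and resist env shifts", {
  cfg <- sim_config(n_genotypes = 40, n_markers = 60, n_chromosomes = 2,
                    var_env = 0, var_rep = 0, var_crop = 0, var_env_crop = 0,
                    var_ge = 0, var_gc = 0, var_gce = 0, var_resid = 0,
                    stage_plan = list(list(stage = 2, n_env = 2, crops = "P",
                                           n_reps = 2, soils = c("H", "L"), frac = 1)),
                    seed = 25)
  dat <- simulate_dataset(cfg)
  tt <- dat$trials
  bl <- compute_blues(tt, "TRS")
  raw <- tapply(tt$TRS, tt$genotype, mean)
  expect_equal(bl$blue, as.vector(raw[bl$genotype]), tolerance = 1e-6)

  # unbalanced design with a shifted environment: only half the genotypes
  # appear in the shifted environment, so their raw means are biased while
  # the mixed model recovers the environmental deviation
  half <- unique(tt$genotype)[1:20]
  tt2 <- tt[!(tt$env == tt$env[1] & !tt$genotype %in% half), ]
  tt2$TRS[tt2$env == tt2$env[1]] <- tt2$TRS[tt2$env == tt2$env[1]] + 10
  bl2 <- compute_blues(tt2, "TRS")
  raw2 <- tapply(tt2$TRS, tt2$genotype, mean)
  truth <- raw[bl2$genotype]   # unshifted adjusted means
  mae_blue <- mean(abs(scale(bl2$blue, scale = FALSE) - scale(truth, scale = FALSE)))
  mae_raw <- mean(abs(scale(as.vector(raw2[bl2$genotype]), scale = FALSE) -
                        scale(truth, scale = FALSE)))
  expect_lt(mae_blue, mae_raw)

  # row-permutation invariance
  perm <- sample(nrow(tt))
  bl3 <- compute_blues(tt[perm, ], "TRS")
  expect_equal(bl3$blue, bl$blue, tolerance = 1e-8)
})

test_that("genotypes seen in a single record still receive a BLUE", {
  cfg <- sim_config(n_genotypes = 30, n_markers = 40, n_chromosomes = 2,
                    stage_plan = list(list(stage = 2, n_env = 2, crops = "P",
                                           n_reps = 1, soils = c("H", "L"), frac = 1)),
                    seed = 26)
  dat <- simulate_dataset(cfg)
  tt <- dat$trials
  solo <- unique(tt$genotype)[1]
  tt <- tt[!(tt$genotype == solo & tt$env == tt$env[nrow(tt)]), ]
  bl <- compute_blues(tt, "TRS")
  expect_true(solo %in% bl$genotype)
  expect_true(is.finite(bl$blue[bl$genotype == solo]))
})

test_that("harmonic means count environments, crops, cells and records", {
  tt <- data.frame(genotype = c("a", "a", "a", "b"),
                   env = c("e1", "e2", "e3", "e1"),
                   crop = "P", rep = 1)
  hm <- harmonic_means(tt)
  expect_equal(hm$nE, 2 / (1 / 3 + 1 / 1))   # counts 3 and 1 -> harmonic 1.5
  expect_equal(hm$nC, 1)
  expect_equal(hm$nECr, 1.5)

  # balanced table: harmonic equals arithmetic counts
  tt2 <- expand.grid(genotype = c("a", "b"), env = c("e1", "e2", "e3"),
                     crop = c("P", "R1"), rep = 1:2, stringsAsFactors = FALSE)
  hm2 <- harmonic_means(tt2)
  expect_equal(hm2$nE, 3); expect_equal(hm2$nC, 2)
  expect_equal(hm2$nEC, 6); expect_equal(hm2$nECr, 12)
})

test_that("Holland heritability arithmetic and monotonicity hold", {
  hm <- structure(list(nE = 2, nC = 2, nEC = 4, nECr = 8),
                  class = "harmonic_means")
  vc <- c(G = 2, GE = 2, GC = 2, GCE = 4, resid = 8)
  expect_equal(holland_h2(vc, hm), 1 / 3)
  expect_equal(holland_h2(c(G = 5, resid = 0), hm), 1)
  expect_equal(holland_h2(c(G = 0, GE = 1, resid = 1), hm), 0)
  expect_error(holland_h2(c(G = 0, resid = 0), hm), "undefined")

  # increasing sigma2_G raises H2; increasing any other component lowers it
  base <- holland_h2(vc, hm)
  expect_gt(holland_h2(replace(vc, "G", 3), hm), base)
  for (nm in c("GE", "GC", "GCE", "resid"))
    expect_lt(holland_h2(replace(vc, nm, vc[nm] * 2), hm), base)
})

test_that("narrow-sense heritability recovers the simulated value", {
  cfg <- single_stage_cfg(n = 400, m = 600, h2 = 0.6, seed = 27)
  dat <- simulate_dataset(cfg)
  GA <- build_grm(dat$geno, "additive")
  est <- narrow_h2(dat$trials, "TRS", GA)
  expect_lt(abs(est$h2 - 0.6), 0.1)

  # pure-noise trait: estimate collapses toward zero
  tt <- dat$trials
  set.seed(27)
  tt$TRS <- rnorm(nrow(tt))
  expect_lt(narrow_h2(tt, "TRS", GA)$h2, 0.12)
})

test_that("pedigree and marker heritabilities agree on pedigree-free panels", {
  cfg <- single_stage_cfg(n = 300, m = 500, h2 = 0.5, seed = 28)
  dat <- simulate_dataset(cfg)
  GA <- build_grm(dat$geno, "additive")
  hm <- narrow_h2(dat$trials, "TRS", GA)
  expect_warning(narrow_h2(dat$trials, "TRS",
                           rel_matrix(diag(300), "K", ids = dat$geno$ids)),
                 "additive")
  expect_true(hm$h2 > 0.3 && hm$h2 < 0.7)
})
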