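test_that("k-fold splits partition the ids deterministically", {
  ids <- sprintf("g%02d", 1:10)
  folds <- kfold_split(ids, k = 5, seed = 1)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), ids)

  ids2 <- sprintf("g%02d", 1:23)
  f2 <- kfold_split(ids2, k = 5, seed = 2)
  expect_setequal(unlist(f2), ids2)
  expect_lte(diff(range(lengths(f2))), 1)
  expect_equal(sum(lengths(f2)), 23)   # disjoint partition

  expect_identical(kfold_split(ids2, 5, seed = 7), kfold_split(ids2, 5, seed = 7))
  expect_false(identical(kfold_split(ids2, 5, seed = 7), kfold_split(ids2, 5, seed = 8)))
  expect_error(kfold_split(ids, k = 1), "at least 2")
  expect_error(kfold_split(ids, k = 11), "exceed")
})

test_that("predictive ability is a guarded Pearson correlation", {
  x <- setNames(rnorm(50), paste0("g", 1:50))
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(x, -x), -1)
  set.seed(4)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(predictive_ability(a, b)), 0.1)
  expect_error(predictive_ability(rep(1, 10), rnorm(10)), "constant")
  expect_error(predictive_ability(1:2, 2:1), "at least 3")
  # name matching reorders pairs
  y <- setNames(as.numeric(1:5), paste0("g", 1:5))
  expect_equal(predictive_ability(y, rev(y)), 1)
})

test_that("coincidence indices count tail overlap with stable ties", {
  y <- setNames(as.numeric(1:10), paste0("g", 1:10))
  expect_equal(coincidence_index(y, y, 0.2, "top"), 1)
  expect_equal(coincidence_index(y, y, 0.2, "bottom"), 1)
  # predicted top-2 disjoint from observed top-2
  pred <- y; pred[c("g9", "g10")] <- c(-1, -2)
  expect_equal(coincidence_index(pred, y, 0.2, "top"), 0)
  # random-ranking null mean equals the selection fraction
  set.seed(5)
  tci <- replicate(2000, coincidence_index(sample(100), 1:100, 0.2, "top"))
  expect_lt(abs(mean(tci) - 0.2), 0.03)
})

test_that("k-fold GBLUP validation recovers strong signal and is reproducible", {
  cfg <- single_stage_cfg(n = 150, m = 300, h2 = 0.95, resid = 0.05, seed = 61)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  data <- list(blues = data.frame(genotype = names(bl), stage = 2,
                                  TRS = unname(bl)),
               geno = dat$geno)
  sch <- cv_scheme("kfold", k = 5, seed = 3)
  ev <- run_scheme(sch, gs_model("gblup"), "TRS", data)
  expect_equal(nrow(ev$per_fold), 5)
  expect_gt(ev$pa, 0.7)
  expect_true(ev$tci >= 0 && ev$tci <= 1)
  ev2 <- run_scheme(sch, gs_model("gblup"), "TRS", data)
  expect_equal(ev$pa, ev2$pa)
})

test_that("cross-stage validation guards against genotype overlap leakage", {
  cfg <- single_stage_cfg(n = 120, m = 250, h2 = 0.8, seed = 62)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  ids <- names(bl)
  blues <- rbind(
    data.frame(genotype = ids, stage = 2, TRS = unname(bl)),
    data.frame(genotype = ids[81:120], stage = 5, TRS = unname(bl[81:120])))
  data <- list(blues = blues, geno = dat$geno)
  sch <- cv_scheme("cross_stage", train = list(stage = 2), test = list(stage = 5))
  # every stage-5 genotype also sits in stage 2: strict scheme has no test set
  expect_error(run_scheme(sch, gs_model("gblup"), "TRS", data), "overlap")
  sch2 <- cv_scheme("cross_stage", train = list(stage = 2),
                    test = list(stage = 5), keep_overlap = TRUE)
  ev <- run_scheme(sch2, gs_model("gblup"), "TRS", data)
  expect_gt(ev$pa, 0.9)   # overlap makes it quasi-training performance

  # disjoint training: train on first 80, test the rest
  blues3 <- rbind(
    data.frame(genotype = ids[1:80], stage = 2, TRS = unname(bl[1:80])),
    data.frame(genotype = ids[81:120], stage = 5, TRS = unname(bl[81:120])))
  ev3 <- run_scheme(sch, gs_model("gblup"), "TRS",
                    list(blues = blues3, geno = dat$geno))
  expect_true(is.finite(ev3$pa))
  expect_error(run_scheme(cv_scheme("cross_stage", train = list(stage = 3),
                                    test = list(stage = 5)),
                          gs_model("gblup"), "TRS",
                          list(blues = blues3, geno = dat$geno)),
               "no rows")
})

test_that("cross-stage prediction of unrelated genotypes carries no information", {
  cfg <- single_stage_cfg(n = 150, m = 300, ld_block_size = 1, seed = 63)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  ids <- names(bl)
  # independently simulated founders: genotypes unrelated to training
  blues <- rbind(
    data.frame(genotype = ids[1:100], stage = 2, TRS = unname(bl[1:100])),
    data.frame(genotype = ids[101:150], stage = 5, TRS = unname(bl[101:150])))
  sch <- cv_scheme("cross_stage", train = list(stage = 2), test = list(stage = 5))
  ev <- run_scheme(sch, gs_model("gblup"), "TRS",
                   list(blues = blues, geno = dat$geno))
  expect_lt(abs(ev$pa), 0.35)
})

test_that("marker-density sweep counts are monotone and evaluation runs per threshold", {
  cfg <- sim_config(n_genotypes = 120, n_markers = 400, n_chromosomes = 4,
                    ld_block_size = 10, h2_additive = 0.6,
                    var_dominance_frac = 0, var_epistasis_frac = 0,
                    stage_plan = list(list(stage = 2, n_env = 1, crops = "P",
                                           n_reps = 1, soils = "L", frac = 1)),
                    var_env = 0, var_rep = 0, var_crop = 0, var_env_crop = 0,
                    var_ge = 0, var_gc = 0, var_gce = 0, var_resid = 0.4,
                    seed = 64)
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  data <- list(blues = data.frame(genotype = names(bl), stage = 2,
                                  TRS = unname(bl)),
               geno = dat$geno)
  sweep_tbl <- marker_density_sweep(data, "TRS", gs_model("gblup"),
                                    cv_scheme("kfold", k = 3, seed = 5),
                                    thresholds = c(0.1, 0.3, 0.99))
  expect_equal(nrow(sweep_tbl), 3)
  expect_true(all(diff(sweep_tbl$n_markers) >= 0))
  expect_true(all(is.finite(sweep_tbl$pa)))
})

test_that("the Hk kernel route builds the single-step matrix from the pedigree", {
  cfg <- single_stage_cfg(n = 100, m = 200, h2 = 0.7, seed = 65)
  cfg$genotyped_frac <- 0.8
  dat <- simulate_dataset(cfg)
  bl <- stage_blues(dat)
  data <- list(blues = data.frame(genotype = names(bl), stage = 2,
                                  TRS = unname(bl)),
               geno = dat$geno, ped = dat$ped)
  ev <- run_scheme(cv_scheme("kfold", k = 3, seed = 6),
                   gs_model("gblup", kernels = c("G", "Hk")), "TRS", data)
  expect_true(is.finite(ev$pa))
})
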