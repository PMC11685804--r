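test_that("marker filters apply missing-rate and MAF thresholds in order", {
  d <- matrix(0, 10, 3, dimnames = list(paste0("g", 1:10), c("m1", "m2", "m3")))
  d[, 1] <- c(rep(NA, 3), rep(2, 7))               # 30% missing
  d[, 2] <- c(1, rep(0, 9))                        # MAF 0.05
  d[, 3] <- rep(c(0, 1, 2, 1, 0), 2)               # clean, MAF 0.4
  G <- toy_panel(d)
  out <- filter_markers(G, max_missing = 0.2, min_maf = 0.1)
  expect_equal(out$marker_ids, "m3")
  # all passing -> identity
  Gok <- toy_panel(d[, 3, drop = FALSE])
  expect_identical(filter_markers(Gok)$dosages, Gok$dosages)
  # nothing passing -> explicit empty-panel error
  expect_error(filter_markers(toy_panel(d[, 1:2]), 0.2, 0.1), "empty panel")
})

test_that("mean imputation fills missing calls without moving column means", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2, dimnames = list(letters[1:3], c("m1", "m2")))
  G <- impute_mean(toy_panel(d))
  expect_equal(unname(G$dosages[3, 1]), 1)
  expect_false(anyNA(G$dosages))
  expect_equal(colMeans(G$dosages), colMeans(d, na.rm = TRUE), ignore_attr = TRUE)
  # complete matrix is untouched
  expect_identical(impute_mean(G)$dosages, G$dosages)
  # entirely missing marker is an error
  d2 <- d; d2[, 2] <- NA
  expect_error(impute_mean(toy_panel(d2)), "entirely missing")
})

test_that("complete-LD deduplication keeps one representative per r2=1 group", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0)
  d <- cbind(m1 = x, m2 = x, m3 = x, m4 = 2 - x, m5 = c(0, 0, 1, 2, 2, 1, 0, 1))
  G <- toy_panel(d)
  out <- dedup_complete_ld(G)
  expect_equal(out$marker_ids, c("m1", "m5"))    # m2, m3 identical; m4 reflected
  # no perfect pairs -> identity
  out2 <- dedup_complete_ld(out)
  expect_identical(out2$marker_ids, out$marker_ids)
})

test_that("greedy LD pruning respects the threshold and is monotone in it", {
  set.seed(42)
  x <- rbinom(200, 2, 0.5)
  flip <- function(p) ifelse(runif(200) < p, sample(0:2, 200, TRUE), x)
  d <- cbind(m1 = x, m2 = flip(0.35))
  r2 <- pairwise_r2(d)[1, 2]
  G <- toy_panel(d)
  expect_equal(ncol(ld_prune(G, r2_threshold = r2 - 0.05)$dosages), 1L)
  expect_equal(ncol(ld_prune(G, r2_threshold = r2 + 0.05)$dosages), 2L)

  cfg <- sim_config(n_genotypes = 200, n_markers = 300, n_chromosomes = 3,
                    ld_block_size = 15, seed = 11)
  Gp <- simulate_genotypes(cfg)
  ths <- c(0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8, 0.99)
  counts <- vapply(ths, function(t) ncol(ld_prune(Gp, t)$dosages), 0L)
  expect_true(all(diff(counts) >= 0))
  # full threshold with no perfect duplicates keeps everything
  Gd <- dedup_complete_ld(Gp)
  expect_equal(ncol(ld_prune(Gd, 1.0)$dosages), ncol(Gd$dosages))
  # dedup then prune at 0.99 is idempotent
  Gq <- ld_prune(Gd, 0.99)
  expect_identical(ld_prune(Gq, 0.99)$marker_ids, Gq$marker_ids)
})

test_that("heterozygosity is the fraction of dosage-1 calls", {
  d <- rbind(a = c(0, 1, 2, 1), b = c(0, 0, 2, 2), c = c(1, 1, 1, 1))
  het <- heterozygosity(toy_panel(d))
  expect_equal(unname(het), c(0.5, 0, 1))
})

test_that("VanRaden additive GRM matches the hand-computed single-marker case", {
  G <- toy_panel(matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "m")))
  GA <- build_grm(G, "additive")
  expect_equal(unclass(GA),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
               ignore_attr = TRUE)
  # identical individuals share diagonal and off-diagonal entries
  G2 <- toy_panel(rbind(a = c(0, 2, 1, 1), b = c(0, 2, 1, 1),
                        c = c(2, 0, 1, 0)))
  GA2 <- unclass(build_grm(G2, "additive"))
  expect_equal(GA2[1, 2], GA2[1, 1])
  expect_equal(GA2[1, 2], GA2[2, 2])
})

test_that("GRM diagonals behave as expected under Hardy-Weinberg sampling", {
  cfg <- sim_config(n_genotypes = 1000, n_markers = 2000, n_chromosomes = 4,
                    ld_block_size = 1, seed = 12)
  G <- simulate_genotypes(cfg)
  GA <- build_grm(G, "additive")
  expect_gt(mean(diag(GA)), 0.95)
  expect_lt(mean(diag(GA)), 1.05)
  # additive and dominance relationships are near-orthogonal
  GD <- build_grm(G, "dominance")
  up <- upper.tri(GA)
  expect_lt(abs(cor(unclass(GA)[up], unclass(GD)[up])), 0.1)
})

test_that("monomorphic markers are excluded from GRMs with a warning", {
  d <- cbind(m1 = c(0, 1, 2, 1), m2 = c(2, 2, 2, 2))
  expect_warning(GA <- build_grm(toy_panel(d), "additive"), "monomorphic")
  expect_equal(dim(GA), c(4L, 4L))
})

test_that("tabular A matrix reproduces textbook relationships", {
  # two unrelated founders
  p0 <- pedigree(c("x", "y"), c(NA, NA), c(NA, NA))
  expect_equal(unclass(amatrix(p0)), diag(2), ignore_attr = TRUE)

  # full sibs related 0.5; parent-offspring 0.5; selfed-sib offspring 1.25
  ped <- pedigree(c("f1", "f2", "s1", "s2", "x"),
                  c(NA, NA, "f1", "f1", "s1"),
                  c(NA, NA, "f2", "f2", "s2"))
  A <- unclass(amatrix(ped))
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["f1", "s1"], 0.5)
  expect_equal(A["x", "x"], 1.25)

  # out-of-order input is auto-sorted; a cycle is rejected
  ped2 <- pedigree(c("kid", "pa", "ma"), c("pa", NA, NA), c("ma", NA, NA))
  expect_equal(ped2$id[3], "kid")
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)), "cycle")
})

test_that("tabular A agrees with gene-dropping Monte Carlo on a random pedigree", {
  cfg <- sim_config(n_genotypes = 30, n_markers = 10, n_chromosomes = 1, seed = 13)
  ped <- simulate_pedigree(cfg)
  A <- amatrix(ped)
  set.seed(13)
  Amc <- gene_drop_amatrix(ped, n_rep = 2e4)
  expect_lt(max(abs(unclass(A) - unclass(Amc))), 0.03)
})

test_that("single-step H matrix collapses to its limiting cases", {
  cfg <- single_stage_cfg(n = 60, m = 120, seed = 14)
  G <- simulate_genotypes(cfg)
  GA <- build_grm(G, "additive")
  ped <- pedigree(G$ids, rep(NA, 60), rep(NA, 60))
  A <- amatrix(ped)

  expect_equal(unclass(hmatrix(A, GA, genotyped = G$ids, tau_blend = 0)),
               unclass(GA), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(hmatrix(A, GA, genotyped = character(0))),
               unclass(A), tolerance = 1e-8, ignore_attr = TRUE)
  sub <- G$ids[1:20]
  A22 <- rel_matrix(unclass(A)[sub, sub], "G_A")
  expect_equal(unclass(hmatrix(A, A22, genotyped = sub, tau_blend = 0)),
               unclass(A), tolerance = 1e-8, ignore_attr = TRUE)
  # partially genotyped H stays symmetric PSD
  H <- hmatrix(A, GA, genotyped = G$ids[1:30], tau_blend = 0.05)
  expect_lt(max(abs(unclass(H) - t(unclass(H)))), 1e-10)
  expect_gt(min(eigen(unclass(H), symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("Hadamard kernels square/cross the inputs and stay PSD", {
  GA <- rel_matrix(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))), "G_A")
  GD <- rel_matrix(diag(2), "G_D", ids = c("a", "b"))
  hk <- hadamard_kernels(GA, GD, rescale = FALSE)
  expect_equal(unclass(hk$G_AA), matrix(c(1, 0.25, 0.25, 1), 2),
               ignore_attr = TRUE)
  expect_equal(unclass(hk$G_AD), diag(2), ignore_attr = TRUE)

  cfg <- single_stage_cfg(n = 80, m = 150, seed = 15)
  G <- simulate_genotypes(cfg)
  hk2 <- hadamard_kernels(build_grm(G, "additive"), build_grm(G, "dominance"))
  for (K in hk2) {
    expect_gt(min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_equal(mean(diag(K)), 1, tolerance = 1e-10)
  }
  # id mismatch is an error
  GD2 <- rel_matrix(diag(2), "G_D", ids = c("a", "zz"))
  expect_error(hadamard_kernels(GA, GD2), "same ids")
})
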