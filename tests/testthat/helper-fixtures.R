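# Shared fixtures: small single-stage simulation configs and panels.

# one unreplicated single-environment stage: phenotype = genotype + residual
single_stage_cfg <- function(n = 200, m = 400, n_chr = 4, h2 = 0.5,
                             resid = NULL, seed = 1, ...) {
  if (is.null(resid)) resid <- 1 - h2
  sim_config(n_genotypes = n, n_markers = m, n_chromosomes = n_chr,
             h2_additive = h2, var_dominance_frac = 0, var_epistasis_frac = 0,
             stage_plan = list(list(stage = 2, n_env = 1, crops = "P",
                                    n_reps = 1, soils = "L", frac = 1)),
             var_env = 0, var_rep = 0, var_crop = 0, var_env_crop = 0,
             var_ge = 0, var_gc = 0, var_gce = 0, var_resid = resid,
             seed = seed, ...)
}

# named per-genotype phenotype vector from a single-stage trial table
stage_blues <- function(dat, trait = "TRS") {
  tt <- dat$trials
  stats::setNames(tapply(tt[[trait]], tt$genotype, mean)[dat$geno$ids],
                  dat$geno$ids)
}

# tiny deterministic dosage panel
toy_panel <- function(d, ...) genotype_matrix(as.matrix(d), ...)

# brute-force pairwise r^2 between dosage columns
pairwise_r2 <- function(d) {
  suppressWarnings(stats::cor(d))^2
}
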