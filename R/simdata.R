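#' Configuration for the staged-trial simulator
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate a
#' staged clonal sugarcane breeding program: 567 genotypes funnelled through
#' four selection stages, plant-cane and two ratoon crops on heavy and light
#' soils, and a dense biallelic SNP panel with block-wise linkage
#' disequilibrium. Four latent traits (TRS, NS, SW, Fiber) are simulated from
#' marker effects; cane yield and sugar yield are the deterministic products
#' `CY = NS * SW` and `SY = CY * TRS / 1000` (TRS in kg/Mg, yields in Mg/ha).
#'
#' @param n_genotypes number of genotypes.
#' @param n_markers number of biallelic SNPs (split across chromosomes, the
#'   remainder going to the first ones).
#' @param n_chromosomes number of chromosomes.
#' @param ld_block_size markers per LD block; within a block gametic alleles
#'   follow an AR(1) latent haplotype signal so r^2 decays with distance.
#' @param ld_decay AR(1) correlation between adjacent markers within a block.
#' @param maf_range allele-frequency bounds `(min, max)`, a subset of (0, 0.5].
#' @param missing_rate fraction of dosage calls set missing (MCAR).
#' @param h2_additive named additive variance fraction per latent trait.
#' @param var_dominance_frac,var_epistasis_frac dominance / additive-additive
#'   epistatic variance fractions (recycled across traits).
#' @param trait_genetic_corr 4x4 genetic correlation among the latent traits
#'   (TRS, NS, SW, Fiber); symmetric, unit diagonal, positive semi-definite.
#' @param trait_means,trait_sds natural-scale mean and genetic SD per latent
#'   trait (TRS kg/Mg, NS thousand stalks/ha, SW kg, Fiber %).
#' @param n_qtl number of causal markers per trait (`Inf` = all markers).
#' @param stage_plan list of stages, each a list with `stage`, `n_env`,
#'   `crops`, `n_reps`, `soils` (per environment), `frac` (fraction of
#'   genotypes entering; non-increasing).
#' @param selection_trait trait whose phenotypic mean ranks genotypes for
#'   advancement between stages.
#' @param var_env,var_rep,var_crop,var_env_crop,var_ge,var_gc,var_gce,var_resid
#'   non-genetic variance components on the standardized latent-trait scale.
#' @param founder_frac fraction of individuals that are pedigree founders.
#' @param genotyped_frac fraction of individuals flagged genotyped.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 567, n_markers = 20451, n_chromosomes = 10,
                       ld_block_size = 20, ld_decay = 0.9,
                       maf_range = c(0.1, 0.5), missing_rate = 0,
                       h2_additive = c(TRS = 0.45, NS = 0.30, SW = 0.45, Fiber = 0.35),
                       var_dominance_frac = 0.05, var_epistasis_frac = 0.05,
                       trait_genetic_corr = NULL,
                       trait_means = c(TRS = 100, NS = 100, SW = 1, Fiber = 11),
                       trait_sds = c(TRS = 8, NS = 15, SW = 0.12, Fiber = 1.5),
                       n_qtl = Inf,
                       stage_plan = default_stage_plan(),
                       selection_trait = "SY",
                       var_env = 1, var_rep = 0.1, var_crop = 0.3,
                       var_env_crop = 0.2, var_ge = 0.2, var_gc = 0.1,
                       var_gce = 0.1, var_resid = 1,
                       founder_frac = 0.15, genotyped_frac = 1,
                       seed = 1L) {
  traits <- c("TRS", "NS", "SW", "Fiber")
  if (n_genotypes < 1 || n_markers < 1 || n_chromosomes < 1)
    stop("n_genotypes, n_markers and n_chromosomes must be positive")
  if (n_markers < n_chromosomes)
    stop("n_markers must be at least n_chromosomes")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5] with min <= max")
  h2_additive <- rep_len(h2_additive, 4); names(h2_additive) <- traits
  var_dominance_frac <- rep_len(var_dominance_frac, 4); names(var_dominance_frac) <- traits
  var_epistasis_frac <- rep_len(var_epistasis_frac, 4); names(var_epistasis_frac) <- traits
  fr <- h2_additive + var_dominance_frac + var_epistasis_frac
  if (any(h2_additive < 0 | h2_additive > 1) || any(var_dominance_frac < 0) ||
      any(var_epistasis_frac < 0) || any(fr > 1))
    stop("variance fractions must lie in [0,1] with additive+dominance+epistasis <= 1")
  if (is.null(trait_genetic_corr)) {
    # mildly structured default: NS-SW trade-off, near-independent otherwise
    trait_genetic_corr <- diag(4)
    trait_genetic_corr[2, 3] <- trait_genetic_corr[3, 2] <- -0.32
    dimnames(trait_genetic_corr) <- list(traits, traits)
  }
  if (!isTRUE(all.equal(trait_genetic_corr, t(trait_genetic_corr))) ||
      any(abs(diag(trait_genetic_corr) - 1) > 1e-8))
    stop("trait_genetic_corr must be symmetric with unit diagonal")
  if (min(eigen(trait_genetic_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("trait_genetic_corr must be positive semi-definite")
  fracs <- vapply(stage_plan, `[[`, 0, "frac")
  if (any(fracs > 1) || any(fracs <= 0)) stop("stage fractions must lie in (0, 1]")
  if (any(diff(fracs) > 1e-12)) stop("stage fractions must be non-increasing (selection funnel)")
  cfg <- list(n_genotypes = as.integer(n_genotypes), n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
              maf_range = maf_range, missing_rate = missing_rate,
              h2_additive = h2_additive, var_dominance_frac = var_dominance_frac,
              var_epistasis_frac = var_epistasis_frac,
              trait_genetic_corr = trait_genetic_corr,
              trait_means = trait_means, trait_sds = trait_sds, n_qtl = n_qtl,
              stage_plan = stage_plan, selection_trait = selection_trait,
              var_env = var_env, var_rep = var_rep, var_crop = var_crop,
              var_env_crop = var_env_crop, var_ge = var_ge, var_gc = var_gc,
              var_gce = var_gce, var_resid = var_resid,
              founder_frac = founder_frac, genotyped_frac = genotyped_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default selection-funnel stage plan
#'
#' Four stages mirroring a staged variety-development program: environment
#' counts 2/8/7/14, replications 1/2/2/3, three crop types (plant cane and
#' two ratoons), heavy/light soils split across environments, and a
#' truncation-selection funnel. Entry fractions are free parameters of the
#' simulator; the defaults give a realistic 1 : 0.5 : 0.25 : 0.1 funnel.
#'
#' @param fracs fractions of genotypes entering stages 2-5.
#' @return list of stage descriptors for [sim_config()].
#' @export
default_stage_plan <- function(fracs = c(1, 0.5, 0.25, 0.1)) {
  n_env <- c(2L, 8L, 7L, 14L)
  n_reps <- c(1L, 2L, 2L, 3L)
  lapply(1:4, function(i) {
    soils <- rep(c("H", "L"), length.out = n_env[i])
    list(stage = i + 1L, n_env = n_env[i], crops = c("P", "R1", "R2"),
         n_reps = n_reps[i], soils = soils, frac = fracs[i])
  })
}

#' Simulate a genotype dosage panel with block LD
#'
#' Two gametes per individual are drawn from a Gaussian-copula AR(1) latent
#' haplotype process: within each LD block the latent signal has correlation
#' `ld_decay^distance`, blocks and chromosomes are independent, and the
#' latent signal is thresholded at the marker's allele frequency (drawn
#' uniformly from `maf_range`). Dosage = sum of the two gametes, so every
#' marker is in Hardy-Weinberg proportion. Missing calls are injected
#' completely at random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genotypes; m <- config$n_markers
  nchr <- config$n_chromosomes
  # markers split across chromosomes, remainder on the first ones
  sizes <- rep(m %/% nchr, nchr) + (seq_len(nchr) <= m %% nchr)
  chrom <- rep(seq_len(nchr), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(p)
  gam <- function() {
    z <- matrix(0, n, m)
    phi <- config$ld_decay
    for (j in seq_len(m)) {
      newblock <- within[j] == 1L || (within[j] - 1L) %% config$ld_block_size == 0L
      e <- stats::rnorm(n)
      z[, j] <- if (newblock || config$ld_block_size == 1L) e
                else phi * z[, j - 1L] + sqrt(1 - phi^2) * e
    }
    sweep(z, 2L, thr, `<`) * 1
  }
  d <- gam() + gam()
  if (config$missing_rate > 0) {
    nm <- round(config$missing_rate * length(d))
    d[sample.int(length(d), nm)] <- NA
  }
  genotype_matrix(d, ids = sprintf("g%04d", seq_len(n)),
                  marker_ids = sprintf("c%02d_m%05d", chrom, within),
                  chrom = chrom, pos = within * 1e4)
}

#' Simulate a pedigree with founders and crosses
#'
#' A founder set (fraction `founder_frac`) with unknown parents, followed by
#' crosses whose sire and dam are drawn from earlier individuals, so the
#' pedigree is topologically ordered by construction. A fraction
#' `genotyped_frac` of individuals is flagged genotyped (for the single-step
#' H matrix).
#'
#' @param config a [sim_config()].
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genotypes < 4) stop("n_genotypes must be at least 4 for a pedigree")
  set.seed(config$seed + 1L)
  n <- config$n_genotypes
  nf <- max(4L, round(config$founder_frac * n))
  id <- sprintf("g%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1L):n) {
    par <- sample.int(i - 1L, 2L)
    sire[i] <- id[par[1L]]; dam[i] <- id[par[2L]]
  }
  genotyped <- stats::runif(n) < config$genotyped_frac
  pedigree(id, sire, dam, genotyped = genotyped)
}

#' Simulate latent genetic values for the trait set
#'
#' Draws additive, dominance and pairwise additive-by-additive epistatic
#' marker effects for the four latent traits (TRS, NS, SW, Fiber) with the
#' configured genetic correlations (on the additive effects), scales each
#' component to its target variance fraction on the standardized scale, and
#' maps to natural scales via `trait_means + trait_sds * latent`. The
#' compound traits are then `CY = NS * SW` and `SY = CY * TRS / 1000` at the
#' genotypic level. The non-additive remainder of the products is assigned to
#' the epistatic column, so `total = bv + dom + epi` holds exactly for all
#' six traits.
#'
#' @param G a complete (or mean-imputed) [genotype_matrix()].
#' @param config a [sim_config()].
#' @return list of class `true_values` with matrices `breeding_values`,
#'   `dominance_deviations`, `epistatic_deviations`, `total_genotypic`
#'   (genotypes x 6 traits, natural scales) and `latent` (standardized).
#' @export
simulate_trait_set <- function(G, config) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  d <- .imputed_dosages(G)
  n <- nrow(d); m <- ncol(d)
  traits <- c("TRS", "NS", "SW", "Fiber")
  Sg <- config$trait_genetic_corr
  ev <- eigen(Sg, symmetric = TRUE)
  Lg <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4) %*% t(ev$vectors)

  nq <- min(config$n_qtl, m)
  qtl <- if (nq == m) seq_len(m) else sort(sample.int(m, nq))
  W <- scale(d[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  H <- scale((d[, qtl, drop = FALSE] == 1) * 1, center = TRUE, scale = FALSE)

  scale_to <- function(x, v) {
    s <- stats::sd(x)
    if (s < 1e-12 || v <= 0) return(rep(0, length(x)))
    (x - mean(x)) / s * sqrt(v)
  }
  # correlated additive effects across traits
  alpha <- matrix(stats::rnorm(nq * 4), nq, 4) %*% t(Lg)
  A <- W %*% alpha
  lat_add <- vapply(1:4, function(t) scale_to(A[, t], config$h2_additive[t]), numeric(n))
  # dominance effects (independent across traits)
  delta <- matrix(stats::rnorm(nq * 4), nq, 4)
  D <- H %*% delta
  lat_dom <- vapply(1:4, function(t) scale_to(D[, t], config$var_dominance_frac[t]), numeric(n))
  # pairwise additive-by-additive epistasis on random marker pairs
  npair <- min(200L, max(1L, nq %/% 2L))
  i1 <- sample(seq_len(nq), npair, replace = nq < npair)
  i2 <- sample(seq_len(nq), npair, replace = nq < npair)
  E <- (W[, i1, drop = FALSE] * W[, i2, drop = FALSE]) %*%
       matrix(stats::rnorm(npair * 4), npair, 4)
  lat_epi <- vapply(1:4, function(t) scale_to(E[, t], config$var_epistasis_frac[t]), numeric(n))
  colnames(lat_add) <- colnames(lat_dom) <- colnames(lat_epi) <- traits

  nat <- function(lat) sweep(sweep(lat, 2L, config$trait_sds[traits], `*`), 2L,
                             config$trait_means[traits], `+`)
  tot_lat <- lat_add + lat_dom + lat_epi
  all6 <- c(traits, "CY", "SY")
  mk <- function() matrix(0, n, 6, dimnames = list(G$ids, all6))
  bv <- dom <- epi <- tot <- mk()
  nat_add <- nat(lat_add)
  nat_tot <- nat(tot_lat)
  bv[, traits] <- sweep(lat_add, 2L, config$trait_sds[traits], `*`)
  dom[, traits] <- sweep(lat_dom, 2L, config$trait_sds[traits], `*`)
  epi[, traits] <- sweep(lat_epi, 2L, config$trait_sds[traits], `*`)
  tot[, traits] <- sweep(nat_tot, 2L, config$trait_means[traits])  # centered totals
  # compound traits on natural scales
  cy_tot <- nat_tot[, "NS"] * nat_tot[, "SW"]
  sy_tot <- cy_tot * nat_tot[, "TRS"] / 1000
  cy_add <- nat_add[, "NS"] * nat_add[, "SW"]
  sy_add <- cy_add * nat_add[, "TRS"] / 1000
  bv[, "CY"] <- cy_add - mean(cy_add); bv[, "SY"] <- sy_add - mean(sy_add)
  tot[, "CY"] <- cy_tot - mean(cy_tot); tot[, "SY"] <- sy_tot - mean(sy_tot)
  epi[, "CY"] <- tot[, "CY"] - bv[, "CY"]; epi[, "SY"] <- tot[, "SY"] - bv[, "SY"]
  out <- list(breeding_values = bv, dominance_deviations = dom,
              epistatic_deviations = epi, total_genotypic = tot,
              latent = tot_lat,
              natural_total = cbind(nat_tot, CY = cy_tot, SY = sy_tot),
              ids = G$ids, config = config)
  class(out) <- "true_values"
  out
}

#' @export
print.true_values <- function(x, ...) {
  cat(sprintf("true_values: %d genotypes x %d traits\n", nrow(x$total_genotypic),
              ncol(x$total_genotypic)))
  cat("realized genotypic variance (natural scale):\n")
  print(round(apply(x$total_genotypic, 2, stats::var), 4))
  invisible(x)
}

#' Simulate multi-stage trial phenotype records
#'
#' Builds one record per genotype x environment x crop x replicate cell of
#' each stage in the plan. Measured traits (TRS, NS, SW, Fiber) follow the
#' trial model: genotypic value plus environment, replicate-within-
#' environment, crop, environment-by-crop, genotype-by-environment,
#' genotype-by-crop and genotype-by-crop-by-environment effects plus a plot
#' residual, each with its configured variance (drawn on the standardized
#' scale and mapped through the trait's SD). The compound records are the
#' products of the measured records, `CY = NS * SW` and `SY = CY * TRS /
#' 1000`, exactly as such traits are derived from field measurements. Between
#' stages, genotypes are advanced by truncation on the previous stage's
#' phenotypic mean of `selection_trait`.
#'
#' @param true a [simulate_trait_set()] result.
#' @param config a [sim_config()].
#' @return a `data.frame` (class `trial_table`) with columns `genotype`,
#'   `stage`, `location`, `year`, `env`, `crop`, `soil`, `rep` and the six
#'   trait columns.
#' @export
simulate_trials <- function(true, config) {
  stopifnot(inherits(true, "true_values"), inherits(config, "sim_config"))
  if (!length(config$stage_plan)) stop("stage_plan must be non-empty")
  set.seed(config$seed + 3L)
  traits <- c("TRS", "NS", "SW", "Fiber")
  ids <- true$ids
  n <- length(ids)
  lat_tot <- sweep(true$total_genotypic[, traits, drop = FALSE], 2L,
                   config$trait_sds[traits], `/`)  # standardized genotypic values
  records <- list()
  current <- ids
  prev_mean <- NULL
  for (sp in config$stage_plan) {
    n_keep <- max(1L, round(sp$frac * n))
    if (!is.null(prev_mean)) {
      ranked <- names(sort(prev_mean, decreasing = TRUE))
      ranked <- ranked[ranked %in% current]
      current <- ranked[seq_len(min(n_keep, length(ranked)))]
    } else {
      current <- ids[seq_len(min(n_keep, n))]
    }
    envs <- sprintf("S%d_E%02d", sp$stage, seq_len(sp$n_env))
    grid <- expand.grid(genotype = current, env = envs, crop = sp$crops,
                        rep = seq_len(sp$n_reps), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$stage <- sp$stage
    grid$soil <- sp$soils[match(grid$env, envs)]
    grid$location <- grid$env
    grid$year <- 1L
    gi <- match(grid$genotype, ids)
    # shared design effects per trait
    ph <- matrix(0, nrow(grid), 4, dimnames = list(NULL, traits))
    for (t in seq_along(traits)) {
      eff_e <- stats::rnorm(length(envs), 0, sqrt(config$var_env))
      eff_r <- stats::rnorm(length(envs) * sp$n_reps, 0, sqrt(config$var_rep))
      eff_c <- stats::rnorm(length(sp$crops), 0, sqrt(config$var_crop))
      eff_ec <- stats::rnorm(length(envs) * length(sp$crops), 0, sqrt(config$var_env_crop))
      ge <- matrix(stats::rnorm(n * length(envs), 0, sqrt(config$var_ge)), n)
      gc <- matrix(stats::rnorm(n * length(sp$crops), 0, sqrt(config$var_gc)), n)
      gce <- array(stats::rnorm(n * length(envs) * length(sp$crops), 0,
                                sqrt(config$var_gce)), c(n, length(envs), length(sp$crops)))
      ei <- match(grid$env, envs); ci <- match(grid$crop, sp$crops)
      ph[, t] <- lat_tot[gi, t] + eff_e[ei] +
        eff_r[(ei - 1L) * sp$n_reps + grid$rep] + eff_c[ci] +
        eff_ec[(ei - 1L) * length(sp$crops) + ci] +
        ge[cbind(gi, ei)] + gc[cbind(gi, ci)] + gce[cbind(gi, ei, ci)] +
        stats::rnorm(nrow(grid), 0, sqrt(config$var_resid))
    }
    nat <- sweep(sweep(ph, 2L, config$trait_sds[traits], `*`), 2L,
                 config$trait_means[traits], `+`)
    grid$TRS <- nat[, "TRS"]; grid$NS <- nat[, "NS"]
    grid$SW <- nat[, "SW"]; grid$Fiber <- nat[, "Fiber"]
    grid$CY <- grid$NS * grid$SW
    grid$SY <- grid$CY * grid$TRS / 1000
    records[[length(records) + 1L]] <- grid
    pm <- tapply(grid[[config$selection_trait]], grid$genotype, mean)
    prev_mean <- pm
  }
  out <- do.call(rbind, records)
  out <- out[, c("genotype", "stage", "location", "year", "env", "crop", "soil",
                 "rep", "TRS", "NS", "SW", "CY", "SY", "Fiber")]
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate a complete staged-trial dataset
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_pedigree()],
#' [simulate_trait_set()] and [simulate_trials()] from one configuration.
#'
#' @param config a [sim_config()].
#' @return list with elements `geno`, `ped`, `true`, `trials` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  ped <- simulate_pedigree(config)
  true <- simulate_trait_set(geno, config)
  trials <- simulate_trials(true, config)
  list(geno = geno, ped = ped, true = true, trials = trials, config = config)
}
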