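# Model presets for multi-environment trial analysis.
#
# The trial table is long format with columns: genotype, stage, location,
# year, crop, soil, rep and one column per trait. "Environment" is the
# location x year combination. Terms whose factor has fewer than two observed
# levels (e.g. crop in a single-crop subset, rep in an unreplicated stage)
# are dropped automatically.

.add_env_column <- function(table) {
  if (is.null(table$env)) {
    if (is.null(table$location)) stop("table needs 'env' or 'location' (+ optional 'year') columns")
    table$env <- if (is.null(table$year)) as.character(table$location)
                 else paste(table$location, table$year, sep = "_")
  }
  table$env <- as.character(table$env)
  table
}

# random-term lists for the two presets; genotype fixed for BLUEs, random for H2
.eq1_random_terms <- function(table, include_genotype) {
  nlev <- function(cols) {
    v <- do.call(paste, c(lapply(cols, function(cc) as.character(table[[cc]])), list(sep = ":")))
    length(unique(v))
  }
  has <- function(col) !is.null(table[[col]]) && length(unique(table[[col]])) > 1L
  terms <- list()
  if (has("env")) terms <- c(terms, list(rterm("E", "env")))
  if (has("env") && has("rep") && nlev(c("env", "rep")) > nlev("env"))
    terms <- c(terms, list(rterm("R", c("env", "rep"))))
  if (has("crop")) {
    terms <- c(terms, list(rterm("C", "crop")))
    if (has("env")) terms <- c(terms, list(rterm("EC", c("env", "crop"))))
  }
  if (include_genotype) terms <- c(terms, list(rterm("G", "genotype")))
  if (has("crop")) terms <- c(terms, list(rterm("GC", c("genotype", "crop"))))
  if (has("env")) terms <- c(terms, list(rterm("GE", c("genotype", "env"))))
  if (has("crop") && has("env")) terms <- c(terms, list(rterm("GCE", c("genotype", "crop", "env"))))
  terms
}

#' Adjusted genotype means (BLUEs) from multi-environment trial data
#'
#' Fits the standard trial mixed model with genotype as a fixed effect and
#' environment (location x year), replicate within environment, crop type and
#' all their interactions with genotype as random effects, then returns one
#' adjusted mean (best linear unbiased estimate) with standard error per
#' genotype. Terms not identifiable in the given table (single crop, no
#' replication, single environment) are dropped automatically, so the same
#' preset serves combined and stratified (per-crop, per-soil) subsets.
#'
#' @param table trial data frame (long format; see package docs).
#' @param trait name of the trait column.
#' @param ... passed to [reml_fit()] (e.g. `method`, `tol`).
#' @return data.frame with columns `genotype`, `blue`, `se`, plus the
#'   underlying `remlfit` as attribute `"fit"`.
#' @export
compute_blues <- function(table, trait, ...) {
  table <- .add_env_column(table)
  if (is.null(table$genotype)) stop("table must have a 'genotype' column")
  table$genotype <- as.character(table$genotype)
  if (is.null(table[[trait]])) stop(sprintf("trait '%s' not found", trait))
  if (all(is.na(table[[trait]]))) stop(sprintf("trait '%s' is entirely missing", trait))
  random <- .eq1_random_terms(table, include_genotype = FALSE)
  gl <- sort(unique(table$genotype))
  if (!length(random)) {
    # no identifiable non-genetic terms: BLUE is the raw genotype mean
    mu <- tapply(table[[trait]], table$genotype, mean, na.rm = TRUE)[gl]
    sdv <- stats::sd(table[[trait]], na.rm = TRUE)
    out <- data.frame(genotype = gl, blue = as.numeric(mu),
                      se = rep(sdv, length(gl)), stringsAsFactors = FALSE)
    return(out)
  }
  fit <- reml_fit(table, trait, fixed = "genotype", random = random, ...)
  # adjusted mean = intercept + genotype effect (reference level's effect = 0)
  bn <- names(fit$beta)
  L <- matrix(0, length(gl), length(bn), dimnames = list(gl, bn))
  L[, "(Intercept)"] <- 1
  for (g in gl) {
    cn <- paste0("genotype", g)
    if (cn %in% bn) L[g, cn] <- 1
  }
  blue <- drop(L %*% fit$beta)
  se <- sqrt(pmax(rowSums((L %*% fit$beta_cov) * L), 0))
  out <- data.frame(genotype = gl, blue = as.numeric(blue), se = as.numeric(se),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Harmonic means of per-genotype replication counts
#'
#' For each genotype the number of distinct environments, crop types,
#' environment x crop cells, and total records is counted; the harmonic mean
#' of each count across genotypes is returned. These are the effective
#' replication numbers that scale the interaction and residual variances in
#' the Holland broad-sense heritability.
#'
#' @param table trial data frame.
#' @return list of class `harmonic_means` with elements `nE`, `nC`, `nEC`,
#'   `nECr`.
#' @export
harmonic_means <- function(table) {
  table <- .add_env_column(table)
  if (is.null(table$genotype)) stop("table must have a 'genotype' column")
  g <- as.character(table$genotype)
  crop <- if (is.null(table$crop)) rep("all", nrow(table)) else as.character(table$crop)
  hm <- function(x) length(x) / sum(1 / x)
  cnt <- function(v) tapply(v, g, function(z) length(unique(z)))
  out <- list(nE = hm(cnt(table$env)),
              nC = hm(cnt(crop)),
              nEC = hm(cnt(paste(table$env, crop))),
              nECr = hm(as.numeric(table(g))))
  class(out) <- "harmonic_means"
  out
}

#' @export
print.harmonic_means <- function(x, ...) {
  cat(sprintf("harmonic means: nE = %.2f, nC = %.2f, nEC = %.2f, nECr = %.2f\n",
              x$nE, x$nC, x$nEC, x$nECr))
  invisible(x)
}

#' Holland broad-sense heritability
#'
#' `H^2 = s2_G / (s2_G + s2_GE/nE + s2_GC/nC + s2_GEC/nEC + s2_e/nECr)`,
#' where the interaction and residual variances are divided by the harmonic
#' means of the per-genotype replication counts. Components absent from
#' `varcomps` (e.g. `GC` in a single-crop subset) contribute zero.
#'
#' @param varcomps named variance components; must contain `G` and `resid`,
#'   optionally `GE`, `GC`, `GCE`.
#' @param hm a [harmonic_means()] object.
#' @return heritability in `[0, 1]`.
#' @export
holland_h2 <- function(varcomps, hm) {
  stopifnot(inherits(hm, "harmonic_means"))
  if (!all(c("G", "resid") %in% names(varcomps)))
    stop("varcomps must contain at least 'G' and 'resid'")
  gv <- function(nm) if (nm %in% names(varcomps)) unname(varcomps[nm]) else 0
  denom <- gv("G") + gv("GE") / hm$nE + gv("GC") / hm$nC +
           gv("GCE") / hm$nEC + gv("resid") / hm$nECr
  if (denom <= 0) stop("all variance components are zero; heritability undefined")
  gv("G") / denom
}

#' Broad-sense heritability of a trial table
#'
#' Convenience wrapper: fits the trial mixed model with genotype (and all
#' other terms) random, and plugs the variance components and harmonic means
#' into [holland_h2()].
#'
#' @param table trial data frame.
#' @param trait trait column name.
#' @param ... passed to [reml_fit()].
#' @return list with `H2`, `varcomps`, `harmonic_means` and the `remlfit`.
#' @export
broad_sense_h2 <- function(table, trait, ...) {
  table <- .add_env_column(table)
  random <- .eq1_random_terms(table, include_genotype = TRUE)
  if (!any(vapply(random, function(t) t$name == "G", TRUE)))
    random <- c(random, list(rterm("G", "genotype")))
  fit <- reml_fit(table, trait, fixed = NULL, random = random, ...)
  hm <- harmonic_means(table[!is.na(table[[trait]]), , drop = FALSE])
  list(H2 = holland_h2(fit$varcomps, hm), varcomps = fit$varcomps,
       harmonic_means = hm, fit = fit)
}

#' Narrow-sense heritability under a relationship matrix
#'
#' Fits `y = mu + g + e` with `g ~ N(0, K s2_A)` on plot-level records
#' (`basis = "plot"`) or on per-genotype means (`basis = "entry"`), using the
#' exact single-kernel spectral REML, and returns
#' `h2 = s2_A / (s2_A + s2_e)`. With a pedigree `A` matrix this is the
#' pedigree narrow-sense heritability; with a VanRaden `G_A` it is the
#' marker-based (genomic) heritability.
#'
#' @param table trial data frame (or any data frame with `genotype` and the
#'   trait column).
#' @param trait trait column name.
#' @param K a [rel_matrix()] of kind `A` or `G_A`.
#' @param basis `"plot"` (records) or `"entry"` (genotype means).
#' @return list with `h2`, `varcomps` and the `remlfit`.
#' @export
narrow_h2 <- function(table, trait, K, basis = c("plot", "entry")) {
  basis <- match.arg(basis)
  stopifnot(inherits(K, "rel_matrix"))
  if (!attr(K, "kind") %in% c("A", "G_A"))
    warning("narrow-sense heritability expects an additive (A or G_A) matrix")
  df <- data.frame(genotype = as.character(table$genotype),
                   y = table[[trait]], stringsAsFactors = FALSE)
  df <- df[!is.na(df$y), , drop = FALSE]
  if (basis == "entry") {
    mu <- tapply(df$y, df$genotype, mean)
    df <- data.frame(genotype = names(mu), y = as.numeric(mu),
                     stringsAsFactors = FALSE)
  }
  if (!all(df$genotype %in% rel_ids(K)))
    stop("all genotypes must be present in K")
  fit <- reml_fit(df, "y", fixed = NULL,
                  random = rterm("A", "genotype", K = K), method = "spectral")
  h2 <- unname(fit$varcomps["A"] / sum(fit$varcomps))
  list(h2 = h2, varcomps = fit$varcomps, fit = fit)
}
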