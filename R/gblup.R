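# Whole-genome prediction models returning `gebv_fit` objects.

.as_blues_vector <- function(blues) {
  if (is.data.frame(blues)) {
    if (!all(c("genotype", "blue") %in% names(blues)))
      stop("blues data frame must have 'genotype' and 'blue' columns")
    blues <- stats::setNames(blues$blue, blues$genotype)
  }
  if (is.null(names(blues))) stop("blues must be named by genotype id")
  blues[!is.na(blues)]
}

new_gebv_fit <- function(label, gebv, train_ids, varcomps = NULL, blups = NULL,
                         beta = NULL, marker_effects = NULL, gebv_sd = NULL,
                         loglik = NA_real_, extra = list()) {
  out <- c(list(model_label = label, gebv = gebv, train_ids = train_ids,
                varcomps = varcomps, blups = blups, beta = beta,
                marker_effects = marker_effects, gebv_sd = gebv_sd,
                loglik = loglik), extra)
  class(out) <- "gebv_fit"
  out
}

#' @export
print.gebv_fit <- function(x, ...) {
  cat(sprintf("gebv_fit [%s]: %d genotypes (%d in training)\n",
              x$model_label, length(x$gebv), length(x$train_ids)))
  if (!is.null(x$varcomps)) {
    cat("variance components:\n"); print(round(x$varcomps, 4))
  }
  invisible(x)
}

#' @export
predict.gebv_fit <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$gebv)
  miss <- setdiff(ids, names(object$gebv))
  if (length(miss)) stop(sprintf("no prediction for id(s): %s",
                                 paste(utils::head(miss, 5L), collapse = ", ")))
  object$gebv[ids]
}

#' @export
coef.gebv_fit <- function(object, ...) {
  if (!is.null(object$marker_effects)) object$marker_effects else object$beta
}

#' Extended GBLUP with multiple relationship kernels
#'
#' Fits `y = X b + sum_k u_k + e` on per-genotype adjusted means, with one
#' random effect per relationship kernel (`u_k ~ N(0, K_k s2_k)`), estimating
#' the variance components by REML. Kernel labels follow the extended-GBLUP
#' family: `G` (additive), `D` (dominance), `GG` (additive-additive), `GD`
#' (additive-dominance), `Hk` (single-step H). Optional fixed covariates
#' (e.g. genome-wide heterozygosity) are centered and absorbed as fixed
#' effects. The GEBV of every genotype in the kernels' id universe —
#' including unphenotyped ones, predicted through the covariance — is the sum
#' of its kernel BLUPs plus the contribution of any `genetic_covariates`
#' (used for GWAS-selected fixed SNPs).
#'
#' @param blues named numeric vector of adjusted means (or a data frame with
#'   `genotype` and `blue` columns); names must appear in the kernel ids.
#' @param kernels a [rel_matrix()] or named list of them, all over the same
#'   ids.
#' @param fixed_covariates optional matrix/data.frame of nuisance covariates
#'   (rows named by genotype id).
#' @param genetic_covariates optional matrix of covariates whose fitted
#'   contribution counts as genetic value (e.g. selected SNP dosages).
#' @param ... passed to [reml_fit()].
#' @return a `gebv_fit` with elements `gebv`, per-kernel `blups`, `varcomps`,
#'   `beta`, `loglik`.
#' @export
gblup_fit <- function(blues, kernels, fixed_covariates = NULL,
                      genetic_covariates = NULL, ...) {
  blues <- .as_blues_vector(blues)
  if (inherits(kernels, "rel_matrix")) kernels <- list(G = kernels)
  if (!length(kernels)) stop("at least one kernel is required")
  if (is.null(names(kernels)) || anyDuplicated(names(kernels)))
    stop("kernels must have unique labels")
  ids <- rel_ids(kernels[[1L]])
  for (nm in names(kernels)) {
    k <- kernels[[nm]]
    if (!inherits(k, "rel_matrix")) stop("each kernel must be a rel_matrix")
    if (!identical(rel_ids(k), ids)) stop("all kernels must share the same ids in the same order")
    ev_min <- min(eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-6 * mean(diag(k)))
      stop(sprintf("kernel '%s' is not positive semi-definite", nm))
  }
  train <- intersect(names(blues), ids)
  if (length(train) < 3L) stop("fewer than 3 phenotyped genotypes match the kernel ids")
  df <- data.frame(genotype = train, y = unname(blues[train]),
                   stringsAsFactors = FALSE)
  fixed <- NULL
  add_covs <- function(covs, prefix) {
    if (is.null(covs)) return(character(0))
    covs <- as.matrix(covs)
    if (is.null(rownames(covs))) stop("covariates must have genotype ids as row names")
    if (!all(train %in% rownames(covs))) stop("covariates must cover all training ids")
    cn <- paste0(prefix, seq_len(ncol(covs)))
    for (i in seq_along(cn)) df[[cn[i]]] <<- covs[train, i] - mean(covs[ids[ids %in% rownames(covs)], i])
    cn
  }
  fixed <- c(add_covs(fixed_covariates, "cov_"), add_covs(genetic_covariates, "snp_"))
  if (!length(fixed)) fixed <- NULL
  random <- lapply(names(kernels), function(nm) rterm(nm, "genotype", K = kernels[[nm]]))
  fit <- reml_fit(df, "y", fixed = fixed, random = random, ...)
  gebv <- Reduce(`+`, fit$blups)
  if (!is.null(genetic_covariates)) {
    gc <- as.matrix(genetic_covariates)
    common <- intersect(ids, rownames(gc))
    contrib <- stats::setNames(rep(0, length(ids)), ids)
    bsnp <- fit$beta[grep("^snp_", names(fit$beta))]
    if (length(bsnp)) {
      gcc <- sweep(gc[common, , drop = FALSE], 2L, colMeans(gc[common, , drop = FALSE]))
      contrib[common] <- drop(gcc[, seq_along(bsnp), drop = FALSE] %*% bsnp)
    }
    gebv <- gebv + contrib[names(gebv)]
  }
  label <- paste(names(kernels), collapse = "+")
  if (!is.null(genetic_covariates)) label <- paste0(label, "+S")
  if (!is.null(fixed_covariates)) label <- paste0(label, "+H")
  new_gebv_fit(label, gebv, train, varcomps = fit$varcomps, blups = fit$blups,
               beta = fit$beta, loglik = fit$loglik,
               extra = list(remlfit = fit))
}

#' Ridge-regression BLUP on marker effects
#'
#' Estimates the marker-effect variance by exact REML on the equivalent
#' kernel model (`K = W W' / sum(2 p q)` with `W` the 2p-centered dosages),
#' then backsolves the ridge marker effects
#' `a = (s2_A / c) W' V^{-1} (y - X b)`; the GEBV of any genotyped individual
#' is `w' a`. Numerically identical to additive GBLUP by the standard
#' equivalence.
#'
#' @param blues named vector (or data frame) of adjusted means.
#' @param G a complete [genotype_matrix()] covering training and prediction
#'   ids.
#' @return a `gebv_fit` with `marker_effects`.
#' @export
rrblup_fit <- function(blues, G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$dosages) < 1L) stop("no markers available")
  blues <- .as_blues_vector(blues)
  d <- .imputed_dosages(G)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(d, 2L, 2 * p)
  cc <- sum(2 * p * (1 - p))
  train <- intersect(names(blues), G$ids)
  if (length(train) < 3L) stop("fewer than 3 phenotyped genotypes in the panel")
  Wt <- W[train, , drop = FALSE]
  K <- rel_matrix(tcrossprod(W) / cc, "G_A", ids = G$ids)
  df <- data.frame(genotype = train, y = unname(blues[train]),
                   stringsAsFactors = FALSE)
  fit <- reml_fit(df, "y", random = rterm("G", "genotype", K = K),
                  method = "spectral")
  sg <- fit$varcomps["G"]; se <- fit$varcomps["resid"]
  Vt <- (sg / cc) * tcrossprod(Wt) + diag(se, length(train))
  r <- unname(blues[train]) - fit$beta[1L]
  alpha <- drop((sg / cc) * crossprod(Wt, solve(Vt, r)))
  gebv <- stats::setNames(drop(W %*% alpha), G$ids)
  new_gebv_fit("rrBLUP", gebv, train,
               varcomps = c(marker = unname(sg) / cc, resid = unname(se)),
               beta = fit$beta, marker_effects = stats::setNames(alpha, colnames(d)),
               loglik = fit$loglik)
}

#' GBLUP with GWAS-selected SNPs as fixed effects
#'
#' Appends the dosages of the markers selected by a mixed-linear-model
#' association scan as fixed covariates of an extended GBLUP ("G+S" model).
#' The GEBV is the fixed marker contribution plus the kernel BLUPs. To avoid
#' information leakage the scan must have been computed on training
#' genotypes only; a scan that used other ids is rejected unless
#' `allow_full_data_scan = TRUE`.
#'
#' @param blues named vector (or data frame) of adjusted means.
#' @param kernels kernel list as in [gblup_fit()].
#' @param scan a [gwas_scan()] result.
#' @param G the [genotype_matrix()] supplying the selected SNP dosages.
#' @param allow_full_data_scan permit a scan computed on non-training ids.
#' @param ... passed to [gblup_fit()].
#' @return a `gebv_fit`; with an empty selection, the plain GBLUP fit (a
#'   message notes the fallback).
#' @export
gs_with_fixed_snps <- function(blues, kernels, scan, G,
                               allow_full_data_scan = FALSE, ...) {
  stopifnot(inherits(scan, "gwas_scan"), inherits(G, "genotype_matrix"))
  blues <- .as_blues_vector(blues)
  if (!allow_full_data_scan && !all(scan$train_ids %in% names(blues)))
    stop("scan was computed on ids outside the training set; ",
         "rerun the scan on training folds only (or set allow_full_data_scan = TRUE)")
  if (!length(scan$selected)) {
    message("no markers passed the scan threshold; falling back to plain GBLUP")
    return(gblup_fit(blues, kernels, ...))
  }
  d <- .imputed_dosages(G)
  S <- d[, scan$selected, drop = FALSE]
  # prune a rank-deficient selected set
  qrS <- qr(scale(S, scale = FALSE))
  if (qrS$rank < ncol(S)) {
    keep <- qrS$pivot[seq_len(qrS$rank)]
    warning(sprintf("%d selected SNP(s) aliased and dropped", ncol(S) - length(keep)))
    S <- S[, keep, drop = FALSE]
  }
  gblup_fit(blues, kernels, genetic_covariates = S, ...)
}

#' Gaussian-kernel matrix on genomic distance
#'
#' `K = exp(-h * D2)` where `D2` is the matrix of mean squared Euclidean
#' distances between dosage profiles, rescaled to mean 1 over off-diagonal
#' entries.
#'
#' @param G a [genotype_matrix()].
#' @param bandwidth positive rate `h`.
#' @return a [rel_matrix()] of kind `K`.
#' @export
rkhs_kernel <- function(G, bandwidth = 1) {
  stopifnot(inherits(G, "genotype_matrix"), bandwidth > 0)
  d <- .imputed_dosages(G)
  D2 <- as.matrix(stats::dist(d))^2 / ncol(d)
  off <- D2[upper.tri(D2)]
  if (mean(off) > 0) D2 <- D2 / mean(off)
  K <- exp(-bandwidth * D2)
  if (min(K) > 1 - 1e-6)
    stop("degenerate kernel (all entries ~1); increase the bandwidth")
  rel_matrix(K, "K", ids = G$ids)
}
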