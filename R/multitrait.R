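# Multi-trait genomic prediction with a Kronecker-structured genetic
# covariance: vec(A) ~ N(0, Sigma (x) K) and residuals R (x) I with R
# diagonal. Traits are standardized to unit variance internally and
# back-transformed on output (yield and quality traits live on very
# different natural scales).

.align_K <- function(Y, K) {
  ids <- rownames(Y)
  if (is.null(ids)) stop("Y must have genotype ids as row names")
  if (!all(ids %in% rel_ids(K))) stop("K must cover all ids of Y")
  unclass(K)[ids, ids]
}

new_mtgs_fit <- function(method, Sigma, R, mu, gebv_matrix, converged = TRUE,
                         loglik = NA_real_, extra = list()) {
  out <- c(list(method = method, Sigma = Sigma, R = R, mu = mu,
                gebv_matrix = gebv_matrix, converged = converged,
                loglik = loglik), extra)
  class(out) <- "mtgs_fit"
  out
}

#' @export
print.mtgs_fit <- function(x, ...) {
  t <- ncol(x$gebv_matrix)
  cat(sprintf("mtgs_fit [%s]: %d genotypes x %d traits, %s\n", x$method,
              nrow(x$gebv_matrix), t,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat("genetic correlations:\n")
  print(round(stats::cov2cor(x$Sigma), 3))
  invisible(x)
}

# BLUP of all genotype x trait genetic values given observed cells,
# on the standardized scale. Yc centered; obs = !is.na(Yc).
.mt_blup <- function(Yc, Kn, Sigma, Rdiag) {
  n <- nrow(Yc); t <- ncol(Yc)
  obs <- which(!is.na(as.vector(Yc)))           # trait-major (column stacking)
  Gfull <- kronecker(Sigma, Kn)
  Voo <- Gfull[obs, obs, drop = FALSE] +
    diag(rep(Rdiag, each = n)[obs], length(obs))
  a <- Gfull[, obs, drop = FALSE] %*% solve(Voo, as.vector(Yc)[obs])
  matrix(a, n, t, dimnames = dimnames(Yc))
}

# observed-cell log-likelihood (standardized scale, means already removed)
.mt_loglik <- function(Yc, Kn, Sigma, Rdiag) {
  n <- nrow(Yc)
  obs <- which(!is.na(as.vector(Yc)))
  Voo <- kronecker(Sigma, Kn)[obs, obs, drop = FALSE] +
    diag(rep(Rdiag, each = n)[obs], length(obs))
  ch <- chol(Voo + diag(1e-10, length(obs)))
  yv <- as.vector(Yc)[obs]
  z <- backsolve(ch, yv, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# complete-data REML EM in the eigenbasis of the mean-projected kernel
.mt_em <- function(Yt, dv, Sigma, Rdiag, tol, max_iter) {
  nb <- nrow(Yt); t <- ncol(Yt)
  dv <- pmax(dv, 1e-10)
  ll_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Ssum <- matrix(0, t, t); Rsum <- numeric(t); ll <- 0
    for (i in seq_len(nb)) {
      Si <- dv[i] * Sigma
      Ci <- Si + diag(Rdiag, t)
      Cinv <- solve(Ci)
      yi <- Yt[i, ]
      mi <- drop(Si %*% Cinv %*% yi)
      Pi <- Si - Si %*% Cinv %*% Si
      Ssum <- Ssum + (tcrossprod(mi) + Pi) / dv[i]
      ri <- yi - mi
      Rsum <- Rsum + ri^2 + diag(Pi)
      ll <- ll - 0.5 * (t * log(2 * pi) +
                        as.numeric(determinant(Ci, logarithm = TRUE)$modulus) +
                        drop(crossprod(yi, Cinv %*% yi)))
    }
    Sigma_new <- (Ssum + t(Ssum)) / (2 * nb)
    ev <- eigen(Sigma_new, symmetric = TRUE)
    if (min(ev$values) < 0)      # repair to the PSD cone
      Sigma_new <- ev$vectors %*% diag(pmax(ev$values, 1e-10), t) %*% t(ev$vectors)
    Rdiag_new <- pmax(Rsum / nb, 1e-10)
    done <- abs(ll - ll_old) < tol * (1 + abs(ll))
    Sigma <- Sigma_new; Rdiag <- Rdiag_new; ll_old <- ll
    if (done) { converged <- TRUE; break }
  }
  list(Sigma = Sigma, Rdiag = Rdiag, loglik = ll_old, converged = converged,
       n_iter = iter)
}

#' Multivariate GBLUP with unstructured genetic covariance
#'
#' Fits `y = mu + Z a + e` jointly over traits with
#' `a ~ MVN(0, Sigma (x) K)` (`Sigma` unstructured) and
#' `e ~ MVN(0, R (x) I)` (`R` diagonal), by REML expectation-maximization in
#' the eigenbasis of the kernel after projecting out the trait means.
#' Missing cells (e.g. a trait hidden in the validation set) are handled by
#' an outer loop that re-imputes them with their conditional expectation
#' under the current parameters; predictions for every genotype x trait cell
#' are the BLUPs at the final estimates. With a single trait the model *is*
#' single-trait GBLUP and is delegated to the exact spectral REML.
#'
#' @param Y genotypes x traits matrix of adjusted means with ids as row
#'   names; `NA` marks unobserved cells.
#' @param K additive [rel_matrix()] covering the ids.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations (per outer imputation pass).
#' @param max_outer maximum imputation passes when cells are missing.
#' @return an `mtgs_fit` with `Sigma`, diagonal `R`, trait means `mu`, and
#'   `gebv_matrix` of genetic-value predictions (natural scale, centered).
#' @export
mvgblup_fit <- function(Y, K, tol = 1e-6, max_iter = 500L, max_outer = 25L) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("t", seq_len(ncol(Y)))
  t <- ncol(Y)
  if (any(rowSums(!is.na(Y)) == 0)) stop("every genotype must have at least one observed trait")
  Kn <- .align_K(Y, K)
  n <- nrow(Y)
  if (t == 1L) {
    df <- data.frame(genotype = rownames(Y), y = Y[, 1L], stringsAsFactors = FALSE)
    Kr <- rel_matrix(Kn, "K", ids = rownames(Y))
    fit <- reml_fit(df, "y", random = rterm("g", "genotype", K = Kr),
                    method = "spectral")
    gm <- matrix(fit$blups$g[rownames(Y)], n, 1L, dimnames = dimnames(Y))
    return(new_mtgs_fit("MVGBLUP", matrix(fit$varcomps["g"], 1, 1,
                                          dimnames = list(colnames(Y), colnames(Y))),
                        matrix(fit$varcomps["resid"], 1, 1,
                               dimnames = list(colnames(Y), colnames(Y))),
                        stats::setNames(fit$beta[1L], colnames(Y)), gm,
                        loglik = fit$loglik,
                        extra = list(singletrait = fit)))
  }
  sds <- apply(Y, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds <= 0)) stop("each trait needs variation among observed values")
  Ys <- sweep(Y, 2L, sds, `/`)
  mu <- colMeans(Ys, na.rm = TRUE)
  Yc <- sweep(Ys, 2L, mu)
  miss <- is.na(Yc)

  # mean-projection contrast basis and kernel eigen-decomposition (once)
  qr1 <- qr(matrix(1, n, 1L))
  Tb <- qr.Q(qr1, complete = TRUE)[, -1L, drop = FALSE]   # n x (n-1), T'1 = 0
  ei <- eigen(crossprod(Tb, Kn %*% Tb), symmetric = TRUE)
  dv <- pmax(ei$values, 0)
  Ut <- Tb %*% ei$vectors                                  # n x (n-1) orthonormal

  Sigma <- diag(0.5, t); Rdiag <- rep(0.5, t)
  Yfill <- Yc; Yfill[miss] <- 0
  converged <- FALSE
  outer_n <- if (any(miss)) max_outer else 1L
  for (outer in seq_len(outer_n)) {
    em <- .mt_em(crossprod(Ut, Yfill), dv, Sigma, Rdiag,
                 tol = tol, max_iter = max_iter)
    Sigma <- em$Sigma; Rdiag <- em$Rdiag; converged <- em$converged
    if (!any(miss)) break
    a <- .mt_blup(Yc, Kn, Sigma, Rdiag)
    old <- Yfill[miss]
    Yfill[miss] <- a[miss]
    if (max(abs(Yfill[miss] - old)) < 1e-5) break
  }
  a <- .mt_blup(Yc, Kn, Sigma, Rdiag)
  ll <- .mt_loglik(Yc, Kn, Sigma, Rdiag)

  Dn <- diag(sds, t)
  Sig_nat <- Dn %*% Sigma %*% Dn
  dimnames(Sig_nat) <- list(colnames(Y), colnames(Y))
  R_nat <- diag(Rdiag * sds^2, t)
  dimnames(R_nat) <- dimnames(Sig_nat)
  gm <- sweep(a, 2L, sds, `*`)
  new_mtgs_fit("MVGBLUP", Sig_nat, R_nat,
               stats::setNames(mu * sds, colnames(Y)), gm,
               converged = converged, loglik = ll,
               extra = list(Sigma_std = Sigma, R_std = Rdiag))
}

#' Bayesian multi-trait model (Gibbs sampler)
#'
#' Same Kronecker model as [mvgblup_fit()], sampled by Gibbs: genetic values
#' in the kernel eigenbasis (jointly across traits via simultaneous
#' diagonalization of `Sigma` in the residual metric), an inverse-Wishart
#' update for the unstructured `Sigma`, scaled-inverse-chi-squared updates
#' for the diagonal residual variances, and data augmentation for missing
#' cells. Priors are weak: `Sigma ~ IW(t + 2, 0.5 I)` and residual df 5 on
#' the standardized scale.
#'
#' @inheritParams mvgblup_fit
#' @param n_iter,burn_in,thin MCMC settings (defaults 12000 / 2000 / 5).
#' @param seed RNG seed (chains are reproducible).
#' @return an `mtgs_fit` with posterior means and `n_retained`.
#' @export
bmtm_fit <- function(Y, K, n_iter = 12000L, burn_in = 2000L, thin = 5L,
                     seed = 1L) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("t", seq_len(ncol(Y)))
  stopifnot(n_iter > burn_in)
  t <- ncol(Y); n <- nrow(Y)
  Kn <- .align_K(Y, K)
  sds <- apply(Y, 2L, stats::sd, na.rm = TRUE)
  Ys <- sweep(Y, 2L, sds, `/`)
  miss <- is.na(Ys)
  n_obs <- colSums(!miss)
  if (any(n_obs < 3L)) stop("each trait needs at least 3 observed values")

  ei <- eigen(Kn, symmetric = TRUE)
  dv <- pmax(ei$values, 1e-10)
  U <- ei$vectors

  df0 <- t + 2; S0 <- diag(0.5, t) * (df0 - t - 1 + 1)  # weak IW prior scale
  dfe <- 5; Se0 <- 0.5 * (dfe + 2)
  Sigma <- diag(0.5, t); Rdiag <- rep(0.5, t)
  mu <- colMeans(Ys, na.rm = TRUE)
  A <- matrix(0, n, t)
  Yfill <- Ys
  for (j in seq_len(t)) Yfill[miss[, j], j] <- mu[j]

  keep_n <- (n_iter - burn_in) %/% thin
  A_sum <- matrix(0, n, t); Sig_sum <- matrix(0, t, t)
  R_sum <- numeric(t); mu_sum <- numeric(t)
  chain_sig11 <- numeric(keep_n)
  kept <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    # --- genetic values ---
    rsq <- sqrt(Rdiag)
    M <- Sigma / tcrossprod(rsq)
    em <- eigen(M, symmetric = TRUE)
    lam <- pmax(em$values, 1e-12)
    Q <- em$vectors
    Yc <- sweep(Yfill, 2L, mu)
    Yt <- crossprod(U, Yc)                       # n x t
    Z <- sweep(Yt, 2L, rsq, `/`) %*% Q
    Lam <- 1 + outer(1 / dv, 1 / lam)            # n x t
    At <- ((Z / Lam) + matrix(stats::rnorm(n * t), n, t) / sqrt(Lam)) %*%
      t(Q * rsq)                                 # rows: R^{1/2} Q applied
    A <- U %*% At
    # --- missing-cell augmentation ---
    if (any(miss)) {
      for (j in seq_len(t)) {
        mj <- miss[, j]
        if (any(mj))
          Yfill[mj, j] <- mu[j] + A[mj, j] + stats::rnorm(sum(mj), 0, rsq[j])
      }
    }
    # --- trait means (observed cells only) ---
    for (j in seq_len(t)) {
      oj <- !miss[, j]
      mu[j] <- mean(Ys[oj, j] - A[oj, j]) + stats::rnorm(1L) * rsq[j] / sqrt(n_obs[j])
    }
    # --- genetic covariance (inverse-Wishart) ---
    Sc <- crossprod(At / sqrt(dv))               # sum a_i a_i' / d_i
    Wi <- stats::rWishart(1L, df0 + n, solve(S0 + Sc))[, , 1L]
    Sigma <- solve(Wi)
    Sigma <- (Sigma + t(Sigma)) / 2
    # --- residual variances (observed cells) ---
    for (j in seq_len(t)) {
      oj <- !miss[, j]
      ss <- sum((Ys[oj, j] - mu[j] - A[oj, j])^2)
      Rdiag[j] <- (Se0 + ss) / stats::rchisq(1L, dfe + n_obs[j])
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      A_sum <- A_sum + A; Sig_sum <- Sig_sum + Sigma
      R_sum <- R_sum + Rdiag; mu_sum <- mu_sum + mu
      chain_sig11[kept] <- Sigma[1L, 1L]
    }
  }
  Dn <- diag(sds, t)
  Sig_nat <- Dn %*% (Sig_sum / kept) %*% Dn
  dimnames(Sig_nat) <- list(colnames(Y), colnames(Y))
  R_nat <- diag((R_sum / kept) * sds^2, t); dimnames(R_nat) <- dimnames(Sig_nat)
  gm <- sweep(A_sum / kept, 2L, sds, `*`)
  dimnames(gm) <- dimnames(Y)
  new_mtgs_fit("BMTM", Sig_nat, R_nat,
               stats::setNames((mu_sum / kept) * sds, colnames(Y)), gm,
               extra = list(n_retained = kept,
                            chains = list(sigma11 = chain_sig11),
                            mcmc = c(n_iter = n_iter, burn_in = burn_in, thin = thin)))
}

#' Predict a trait hidden in the validation set from correlated traits
#'
#' Emulates multi-trait genomic selection of a compound target trait: the
#' target's phenotype is masked for the validation genotypes while the
#' chosen secondary (correlated) traits remain observed there; the selected
#' multi-trait model then predicts the masked cells using genomic
#' relationships plus the secondary phenotypes. A single-trait GBLUP
#' baseline (trained on the same training genotypes, target only) is
#' computed alongside for comparison.
#'
#' @param Y genotypes x traits matrix of adjusted means (ids as row names).
#' @param K additive [rel_matrix()].
#' @param target name of the trait to predict.
#' @param secondary character vector of secondary trait names observed in
#'   validation (empty degenerates to single-trait prediction, with a
#'   message).
#' @param validation_ids genotypes whose target phenotype is hidden.
#' @param method `"mvgblup"` or `"bmtm"`.
#' @param ... passed to the chosen fitter.
#' @return list of class `hidden_trait_pred` with `predictions` (named,
#'   validation ids), `baseline` (single-trait GBLUP predictions), and the
#'   underlying `fit`.
#' @export
predict_hidden_trait <- function(Y, K, target, secondary, validation_ids,
                                 method = c("mvgblup", "bmtm"), ...) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (!target %in% colnames(Y)) stop(sprintf("target trait '%s' not in Y", target))
  secondary <- setdiff(intersect(secondary, colnames(Y)), target)
  validation_ids <- intersect(validation_ids, rownames(Y))
  if (!length(validation_ids)) stop("no validation ids present in Y")
  train_ids <- setdiff(rownames(Y)[!is.na(Y[, target])], validation_ids)
  if (length(train_ids) < 3L) stop("too few training genotypes with the target observed")

  base_fit <- gblup_fit(Y[train_ids, target],
                        list(G = rel_matrix(unclass(K)[rownames(Y), rownames(Y)],
                                            attr(K, "kind"), ids = rownames(Y))))
  baseline <- base_fit$gebv[validation_ids]

  if (!length(secondary)) {
    message("no secondary traits supplied; returning single-trait predictions")
    return(structure(list(predictions = baseline, baseline = baseline,
                          fit = base_fit, target = target,
                          secondary = character(0),
                          validation_ids = validation_ids),
                     class = "hidden_trait_pred"))
  }
  Ym <- Y[, c(target, secondary), drop = FALSE]
  Ym[validation_ids, target] <- NA
  fit <- if (method == "mvgblup") mvgblup_fit(Ym, K, ...)
         else bmtm_fit(Ym, K, ...)
  preds <- fit$gebv_matrix[validation_ids, target]
  structure(list(predictions = preds, baseline = baseline, fit = fit,
                 target = target, secondary = secondary,
                 validation_ids = validation_ids),
            class = "hidden_trait_pred")
}

#' @export
print.hidden_trait_pred <- function(x, ...) {
  cat(sprintf("hidden-trait prediction of %s from {%s} for %d validation genotypes\n",
              x$target, paste(x$secondary, collapse = ", "),
              length(x$validation_ids)))
  invisible(x)
}
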