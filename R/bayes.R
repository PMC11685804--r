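#' Bayesian whole-genome regression (the Bayesian alphabet)
#'
#' Single-site Gibbs samplers for five marker-effect priors: `BRR` (common
#' normal marker variance), `BayesA` (marker-specific scaled-inverse-chi^2
#' variances), `BayesB`/`BayesC` (spike-and-slab with inclusion probability
#' `pi` under a beta prior), and `BL` (Bayesian lasso; double-exponential
#' prior via the exponential scale mixture). Hyper-parameters follow the
#' usual convention: all variance priors have 5 degrees of freedom with
#' scales set so each term's prior explains half the phenotypic variance;
#' `pi` has a Beta(5, 5) prior (mean 0.5). Chains are reproducible from
#' `seed` (R's RNG drives the compiled sampler). The GEBV is the posterior
#' mean of `W a` over the retained draws, for every genotype in the panel
#' (training or not); the retained-draw count is
#' `(n_iter - burn_in) / thin`.
#'
#' @param blues named vector (or data frame) of adjusted means.
#' @param G a [genotype_matrix()] covering training and prediction ids.
#' @param method one of `"BRR"`, `"BL"`, `"BayesA"`, `"BayesB"`, `"BayesC"`.
#' @param n_iter,burn_in,thin MCMC settings (defaults 12000 / 2000 / 5).
#' @param seed RNG seed.
#' @param R2 prior proportion of variance attributed to markers.
#' @param df0,dfe prior degrees of freedom for marker and residual variances.
#' @param pi_a,pi_b beta prior for the inclusion probability.
#' @return a `gebv_fit` with posterior-mean `gebv`, `gebv_sd`,
#'   `marker_effects`, retained chains (`chains`) and `n_retained`.
#' @export
bayes_fit <- function(blues, G, method = c("BRR", "BL", "BayesA", "BayesB", "BayesC"),
                      n_iter = 12000L, burn_in = 2000L, thin = 5L, seed = 1L,
                      R2 = 0.5, df0 = 5, dfe = 5, pi_a = 5, pi_b = 5) {
  method <- match.arg(method)
  stopifnot(inherits(G, "genotype_matrix"), n_iter > burn_in)
  blues <- .as_blues_vector(blues)
  train <- intersect(names(blues), G$ids)
  if (length(train) < 3L) stop("fewer than 3 phenotyped genotypes in the panel")
  d <- .imputed_dosages(G)
  W <- scale(d, center = TRUE, scale = FALSE)
  keep <- apply(W, 2L, function(x) stats::sd(x) > 0)
  W <- W[, keep, drop = FALSE]
  set.seed(seed)
  res <- .wgr_gibbs(W[train, , drop = FALSE], unname(blues[train]), W, method,
                    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                    R2, df0, dfe, pi_a, pi_b)
  gebv <- stats::setNames(drop(res$g_mean), G$ids)
  new_gebv_fit(method, gebv, train,
               varcomps = c(marker = mean(res$chain_varB), resid = mean(res$chain_varE)),
               beta = c(mu = res$mu),
               marker_effects = stats::setNames(drop(res$beta), colnames(W)),
               gebv_sd = stats::setNames(drop(res$g_sd), G$ids),
               extra = list(n_retained = res$n_retained,
                            chains = list(varE = drop(res$chain_varE),
                                          varB = drop(res$chain_varB),
                                          pi = drop(res$chain_pi)),
                            mcmc = c(n_iter = n_iter, burn_in = burn_in, thin = thin)))
}

#' Reproducing kernel Hilbert space regression
#'
#' A Gaussian kernel on mean-scaled squared Euclidean genomic distance
#' ([rkhs_kernel()]) fitted as a single-kernel Bayesian GBLUP by Gibbs
#' sampling in the kernel's eigenbasis. Unphenotyped genotypes are predicted
#' per draw through the kernel covariance, so the reported GEBV is their
#' posterior-mean genetic value.
#'
#' @inheritParams bayes_fit
#' @param bandwidth Gaussian kernel rate `h` (on distance rescaled to mean
#'   1); `"auto"` uses 1.
#' @return a `gebv_fit`.
#' @export
rkhs_fit <- function(blues, G, bandwidth = 1, n_iter = 12000L, burn_in = 2000L,
                     thin = 5L, seed = 1L, R2 = 0.5, df0 = 5, dfe = 5) {
  stopifnot(inherits(G, "genotype_matrix"), n_iter > burn_in)
  if (identical(bandwidth, "auto")) bandwidth <- 1
  blues <- .as_blues_vector(blues)
  K <- rkhs_kernel(G, bandwidth)
  train <- intersect(names(blues), G$ids)
  if (length(train) < 3L) stop("fewer than 3 phenotyped genotypes in the panel")
  y <- unname(blues[train])
  n <- length(y)
  Ktt <- unclass(K)[train, train]
  ei <- eigen(Ktt, symmetric = TRUE)
  dv <- pmax(ei$values, 1e-10)
  U <- ei$vectors
  other <- setdiff(G$ids, train)
  Pnew <- if (length(other))
    unclass(K)[other, train, drop = FALSE] %*% U %*% diag(1 / dv, n) else NULL

  vary <- stats::var(y)
  S0u <- vary * R2 * (df0 + 2)
  Se0 <- vary * (1 - R2) * (dfe + 2)
  su <- vary * R2; se <- vary * (1 - R2)
  mu <- mean(y); s <- rep(0, n)
  keep_n <- (n_iter - burn_in) %/% thin
  u_sum <- rep(0, n); unew_sum <- if (length(other)) rep(0, length(other)) else NULL
  chain_ve <- chain_vu <- numeric(keep_n)
  kept <- 0L
  set.seed(seed)
  yt <- drop(crossprod(U, y))
  for (it in seq_len(n_iter)) {
    # eigen-coordinates of the genetic values
    prec <- 1 / se + 1 / (su * dv)
    m1 <- (yt - drop(crossprod(U, rep(mu, n)))) / se / prec
    s <- m1 + stats::rnorm(n) / sqrt(prec)
    u <- drop(U %*% s)
    mu <- mean(y - u) + stats::rnorm(1L) * sqrt(se / n)
    su <- (S0u + sum(s^2 / dv)) / stats::rchisq(1L, df0 + n)
    se <- (Se0 + sum((y - mu - u)^2)) / stats::rchisq(1L, dfe + n)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      u_sum <- u_sum + u
      if (length(other)) unew_sum <- unew_sum + drop(Pnew %*% s)
      chain_ve[kept] <- se; chain_vu[kept] <- su
    }
  }
  gebv <- stats::setNames(rep(NA_real_, length(G$ids)), G$ids)
  gebv[train] <- u_sum / kept
  if (length(other)) gebv[other] <- unew_sum / kept
  new_gebv_fit("RKHS", gebv, train,
               varcomps = c(kernel = mean(chain_vu), resid = mean(chain_ve)),
               beta = c(mu = mu),
               extra = list(n_retained = kept, bandwidth = bandwidth,
                            chains = list(varE = chain_ve, varU = chain_vu)))
}

#' Machine-learning regression adapters (random forest, radial SVM)
#'
#' Trains `randomForest` or an epsilon-regression SVM with radial kernel on
#' the (imputed) marker dosages of the phenotyped genotypes and predicts all
#' genotypes in the panel. These are the standard non-parametric baselines of
#' genomic prediction benchmarking.
#'
#' @param blues named vector (or data frame) of adjusted means.
#' @param G a [genotype_matrix()].
#' @param method `"random_forest"` or `"svr_radial"`.
#' @param hyper named list of hyper-parameters forwarded to the backend
#'   (e.g. `ntree`, `mtry`; `cost`, `gamma`, `epsilon`).
#' @param seed RNG seed (makes the random forest reproducible).
#' @return a `gebv_fit` whose `gebv` are the model predictions.
#' @export
ml_fit <- function(blues, G, method = c("random_forest", "svr_radial"),
                   hyper = list(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(G, "genotype_matrix"))
  blues <- .as_blues_vector(blues)
  train <- intersect(names(blues), G$ids)
  if (length(train) < 3L) stop("fewer than 3 phenotyped genotypes in the panel")
  y <- unname(blues[train])
  if (stats::sd(y) == 0) stop("constant response; predictive ability undefined")
  d <- .imputed_dosages(G)
  set.seed(seed)
  if (method == "random_forest") {
    args <- c(list(x = d[train, , drop = FALSE], y = y), hyper)
    if (is.null(args$ntree)) args$ntree <- 500L
    mod <- do.call(randomForest::randomForest, args)
    pred <- stats::predict(mod, d)
  } else {
    args <- c(list(x = d[train, , drop = FALSE], y = y, kernel = "radial",
                   type = "eps-regression"), hyper)
    mod <- do.call(e1071::svm, args)
    pred <- stats::predict(mod, d)
  }
  gebv <- stats::setNames(as.numeric(pred), G$ids)
  new_gebv_fit(if (method == "random_forest") "RF" else "SVM", gebv, train,
               extra = list(model = mod))
}

#' Mixed-linear-model association scan
#'
#' Single-locus MLM: each marker is tested as a fixed effect in
#' `y = mu + x b + u + e` with a polygenic term `u ~ N(0, K s2_g)`. Variance
#' components are estimated once on the null (markerless) model by exact
#' spectral REML, and every marker receives a generalized-least-squares Wald
#' test in the whitened data (the usual population-parameters-previously-
#' determined approximation). With `K = NULL` the scan is ordinary
#' regression. Monomorphic markers receive `p = 1` by convention.
#'
#' @param blues named vector (or data frame) of adjusted means.
#' @param G a [genotype_matrix()].
#' @param K optional polygenic [rel_matrix()].
#' @param p_threshold markers with `p <` this enter the selected set
#'   (default 0.001).
#' @return an object of class `gwas_scan`: data frame `results`
#'   (`marker`, `chrom`, `pos`, `effect`, `se`, `p`), `selected` marker ids,
#'   `train_ids`, `threshold`.
#' @export
gwas_scan <- function(blues, G, K = NULL, p_threshold = 0.001) {
  stopifnot(inherits(G, "genotype_matrix"))
  blues <- .as_blues_vector(blues)
  train <- intersect(names(blues), G$ids)
  if (length(train) < 5L) stop("too few phenotyped genotypes for a scan")
  y <- unname(blues[train])
  d <- .imputed_dosages(G)
  M <- scale(d[train, , drop = FALSE], center = TRUE, scale = FALSE)
  n <- length(y)
  if (!is.null(K)) {
    stopifnot(inherits(K, "rel_matrix"))
    df <- data.frame(genotype = train, y = y, stringsAsFactors = FALSE)
    null_fit <- reml_fit(df, "y", random = rterm("g", "genotype", K = K),
                         method = "spectral")
    sg <- null_fit$varcomps["g"]; se <- null_fit$varcomps["resid"]
    ei <- eigen(unclass(K)[train, train], symmetric = TRUE)
    wts <- 1 / sqrt(pmax(sg * ei$values + se, 1e-12))
    Tm <- wts * t(ei$vectors)              # V^{-1/2}
    yt <- drop(Tm %*% y); Xt <- drop(Tm %*% rep(1, n)); Mt <- Tm %*% M
  } else {
    yt <- y; Xt <- rep(1, n); Mt <- M
  }
  # residualize intercept out of response and markers
  px <- sum(Xt^2)
  yr <- yt - Xt * sum(Xt * yt) / px
  Mr <- Mt - outer(Xt, drop(crossprod(Mt, Xt)) / px)
  sxx <- colSums(Mr^2)
  sxy <- drop(crossprod(Mr, yr))
  mono <- sxx < 1e-10
  bhat <- ifelse(mono, 0, sxy / pmax(sxx, 1e-12))
  dfres <- n - 2L
  rss <- pmax(sum(yr^2) - bhat^2 * sxx, 1e-12)
  s2 <- rss / dfres
  sevec <- sqrt(s2 / pmax(sxx, 1e-12))
  tval <- ifelse(mono, 0, bhat / sevec)
  pval <- ifelse(mono, 1, 2 * stats::pt(-abs(tval), dfres))
  res <- data.frame(marker = G$marker_ids, chrom = G$chrom, pos = G$pos,
                    effect = bhat, se = sevec, p = pval,
                    stringsAsFactors = FALSE)
  out <- list(results = res,
              selected = res$marker[res$p < p_threshold],
              train_ids = train, threshold = p_threshold,
              polygenic = !is.null(K))
  class(out) <- "gwas_scan"
  out
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d markers on %d genotypes (%s), %d selected at p < %g\n",
              nrow(x$results), length(x$train_ids),
              if (x$polygenic) "MLM" else "plain regression",
              length(x$selected), x$threshold))
  invisible(x)
}
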