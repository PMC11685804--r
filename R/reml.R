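#' Random term specification
#'
#' Describes one random term of a Gaussian mixed model: the data column(s)
#' whose interaction defines the incidence factor, and optionally a known
#' covariance structure ([rel_matrix()]) among its levels. With `K = NULL`
#' the levels are i.i.d. (identity covariance).
#'
#' @param name label used for the variance component.
#' @param factors character vector of data column names; their interaction
#'   defines the term's levels.
#' @param K optional [rel_matrix()] whose row names enumerate the levels.
#' @return an object of class `rterm`.
#' @export
rterm <- function(name, factors, K = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.character(factors))
  if (!is.null(K) && !inherits(K, "rel_matrix")) stop("K must be a rel_matrix or NULL")
  structure(list(name = name, factors = factors, K = K), class = "rterm")
}

# Assemble design: returns list(y, X, terms, dropped, n); each term carries
# its incidence in the prior eigenbasis (see below)
.build_mm_design <- function(data, response, fixed, random) {
  y <- data[[response]]
  if (is.null(y)) stop(sprintf("response '%s' not found in data", response))
  keep <- !is.na(y)
  if (!any(keep)) stop(sprintf("trait '%s' is entirely missing", response))
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  n <- length(y)

  if (is.null(fixed) || !length(fixed)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    df <- data
    for (f in fixed) {
      if (is.null(df[[f]])) stop(sprintf("fixed term '%s' not found in data", f))
      if (is.character(df[[f]]) || is.logical(df[[f]])) df[[f]] <- factor(df[[f]])
    }
    fml <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
    X <- stats::model.matrix(fml, df)
  }
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  # K-structured terms are reparameterized in the eigenbasis of K restricted
  # to its range: u = U s with s ~ N(0, sigma^2 D), which is exact (u lies in
  # range(K) almost surely) and keeps the mixed-model equations diagonal in
  # the prior, avoiding the ill-conditioned inversion of near-singular GRMs.
  terms <- lapply(random, function(tm) {
    stopifnot(inherits(tm, "rterm"))
    for (f in tm$factors)
      if (is.null(data[[f]])) stop(sprintf("random term '%s': column '%s' not found", tm$name, f))
    fval <- if (length(tm$factors) == 1L) as.character(data[[tm$factors]])
            else do.call(paste, c(lapply(tm$factors, function(f) as.character(data[[f]])), sep = ":"))
    if (is.null(tm$K)) {
      levels <- sort(unique(fval))
      Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(fval, levels), x = 1,
                                dims = c(n, length(levels)))
      return(list(name = tm$name, Z = Z, d = NULL, U = NULL, logdetK = 0,
                  levels = levels, q = length(levels)))
    }
    levels <- rel_ids(tm$K)
    if (!all(fval %in% levels))
      stop(sprintf("random term '%s': levels missing from its covariance matrix", tm$name))
    ei <- eigen(unclass(tm$K), symmetric = TRUE)
    keepv <- ei$values > max(ei$values) * 1e-10
    if (!any(keepv)) stop(sprintf("covariance of term '%s' is numerically zero", tm$name))
    dv <- ei$values[keepv]
    U <- ei$vectors[, keepv, drop = FALSE]
    Zi <- Matrix::sparseMatrix(i = seq_len(n), j = match(fval, levels), x = 1,
                               dims = c(n, length(levels)))
    Zt <- as.matrix(Zi %*% U)
    list(name = tm$name, Z = Zt, d = dv, U = U, logdetK = sum(log(dv)),
         levels = levels, q = length(dv))
  })
  list(y = y, X = X, terms = terms, dropped = dropped, n = n)
}

# Exact REML for a single random term via spectral decomposition (EMMA-style).
# Z is the incidence in the term's eigenbasis (n x q), d the prior eigen-
# variances (NULL for an identity covariance), U the basis (levels x q).
.spectral_reml <- function(y, X, Z, d = NULL, U = NULL) {
  n <- length(y); p <- ncol(X)
  Zm <- as.matrix(Z)
  M <- if (is.null(d)) tcrossprod(Zm) else Zm %*% (d * t(Zm))
  M <- (M + t(M)) / 2
  Qx <- qr.Q(qr(X))
  # project M onto the orthogonal complement of X, shift X-span to zero
  QtM <- crossprod(Qx, M)
  A <- M - Qx %*% QtM - t(QtM) %*% t(Qx) + Qx %*% (QtM %*% Qx) %*% t(Qx)
  A <- A + diag(n) - tcrossprod(Qx)
  A <- (A + t(A)) / 2
  ei <- eigen(A, symmetric = TRUE)
  idx <- seq_len(n - p)
  xi <- pmax(ei$values[idx] - 1, 0)
  Up <- ei$vectors[, idx, drop = FALSE]
  eta2 <- as.numeric(crossprod(Up, y))^2

  logdetXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  nconst <- (n - p) * log(2 * pi) + (n - p) + logdetXtX
  neg2 <- function(logd) {
    d <- exp(logd)
    sg <- sum(eta2 / (xi + d)) / (n - p)
    (n - p) * log(sg) + sum(log(xi + d)) + nconst
  }
  # coarse grid then local refinement of log(delta)
  grid <- seq(-18, 18, length.out = 61)
  vals <- vapply(grid, neg2, 0)
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(neg2, c(lo, hi), tol = 1e-10)
  delta <- exp(opt$minimum)
  sg <- sum(eta2 / (xi + delta)) / (n - p)
  se <- delta * sg

  # full-space quantities at the optimum
  ef <- eigen(M, symmetric = TRUE)
  dv <- pmax(ef$values, 0)
  w <- 1 / (sg * dv + se)
  Uf <- ef$vectors
  Vinv <- Uf %*% (w * t(Uf))
  XtVi <- crossprod(X, Vinv)
  bcov <- solve(XtVi %*% X)
  beta <- drop(bcov %*% (XtVi %*% y))
  r <- y - drop(X %*% beta)
  Vir <- drop(Vinv %*% r)
  s <- as.numeric(Matrix::crossprod(Z, Vir))
  u <- if (is.null(d)) sg * s else sg * as.numeric(U %*% (d * s))
  loglik <- -0.5 * neg2(opt$minimum)
  list(sg = sg, se = se, beta = beta, beta_cov = bcov, u = u, loglik = loglik,
       Vinv = Vinv, resid_mean = r, delta = delta)
}

#' Fit a Gaussian mixed model by REML
#'
#' Restricted maximum likelihood for models
#' `y = X b + sum_i Z_i u_i + e`, `u_i ~ N(0, sigma^2_i K_i)`,
#' `e ~ N(0, sigma^2_e I)`, with known (possibly identity) covariance
#' structures `K_i`. Variance components are estimated by EM-REML with
#' optional average-information (AI) acceleration on the mixed-model
#' equations; models with a single random term use an exact profiled REML via
#' a one-time spectral decomposition (`method = "spectral"`, the `"auto"`
#' default for such models). Fixed-effect rank deficiencies are resolved by
#' dropping aliased columns (treatment contrasts, first level as reference);
#' the dropped columns are reported in the fit.
#'
#' @param data data frame with the response, factor and covariate columns.
#' @param response name of the response column.
#' @param fixed character vector of fixed-term column names (intercept always
#'   included); `NULL` for intercept only.
#' @param random list of [rterm()] specifications.
#' @param method `"auto"`, `"ai"`, `"em"` or `"spectral"`.
#' @param tol relative convergence tolerance on the REML log-likelihood.
#' @param max_iter maximum number of iterations.
#' @param verbose print the likelihood path.
#' @return an object of class `remlfit` with elements `varcomps` (named,
#'   residual last), `beta`, `beta_cov`, `blups` (named list of per-level
#'   effect vectors), `loglik`, `converged`, `n_iter`, `method`, `n`, `p`.
#' @export
reml_fit <- function(data, response, fixed = NULL, random,
                     method = c("auto", "ai", "em", "spectral"),
                     tol = 1e-6, max_iter = 200L, verbose = FALSE) {
  method <- match.arg(method)
  if (inherits(random, "rterm")) random <- list(random)
  if (!length(random)) stop("at least one random term is required")
  des <- .build_mm_design(data, response, fixed, random)
  y <- des$y; X <- des$X; terms <- des$terms
  n <- des$n; p <- ncol(X); r <- length(terms)
  if (n <= p) stop("no residual degrees of freedom")
  if (method == "auto") method <- if (r == 1L) "spectral" else "ai"
  if (method == "spectral" && r > 1L)
    stop("spectral method only supports a single random term")

  tnames <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(tnames)) stop("random term names must be unique")

  if (method == "spectral") {
    tm <- terms[[1L]]
    fit <- .spectral_reml(y, X, tm$Z, tm$d, tm$U)
    vc <- c(fit$sg, fit$se); names(vc) <- c(tm$name, "resid")
    blups <- list(stats::setNames(fit$u, tm$levels)); names(blups) <- tm$name
    out <- list(varcomps = vc, beta = stats::setNames(fit$beta, colnames(X)),
                beta_cov = fit$beta_cov, blups = blups, loglik = fit$loglik,
                converged = TRUE, n_iter = NA_integer_, method = "spectral",
                n = n, p = p, dropped_fixed = des$dropped,
                term_levels = stats::setNames(lapply(terms, `[[`, "levels"), tnames))
    class(out) <- "remlfit"
    return(out)
  }

  ## ---- MME-based EM / AI ----
  Zall <- do.call(cbind, lapply(terms, `[[`, "Z"))
  q <- vapply(terms, `[[`, 0L, "q"); Q <- sum(q)
  off <- p + c(0L, cumsum(q))[seq_len(r)]      # block starts (0-based after fixed)
  blk <- lapply(seq_len(r), function(i) off[i] + seq_len(q[i]))
  W <- cbind(X, as.matrix(Zall))
  Cbase <- crossprod(W)                         # (p+Q)^2 dense
  rhs <- drop(crossprod(W, y))
  yty <- sum(y^2)
  vy <- stats::var(y)
  flo <- 1e-8 * vy
  logdetKsum <- sum(vapply(terms, `[[`, 0, "logdetK"))

  dinv <- lapply(terms, function(tm) if (is.null(tm$d)) rep(1, tm$q) else 1 / tm$d)

  eval_theta <- function(theta) {
    th <- theta[seq_len(r)]; te <- theta[r + 1L]
    C <- Cbase
    for (i in seq_len(r)) {
      ix <- blk[[i]]
      diag(C)[ix] <- diag(Cbase)[ix] + (te / th[i]) * dinv[[i]]
    }
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) { diag(C) <- diag(C) + 1e-8 * max(diag(C)); ch <- chol(C) }
    Ci <- chol2inv(ch)
    sol <- drop(Ci %*% rhs)
    sse <- max(yty - sum(sol * rhs), 1e-12)
    logdetCfull <- 2 * sum(log(diag(ch))) - (p + Q) * log(te)
    neg2 <- n * log(te) + sum(q * log(th)) + logdetKsum + logdetCfull + sse / te +
      (n - p) * log(2 * pi)
    list(Ci = Ci, sol = sol, sse = sse, loglik = -0.5 * neg2, theta = theta)
  }

  em_step <- function(st) {
    theta <- st$theta; te <- theta[r + 1L]
    new <- theta
    for (i in seq_len(r)) {
      ix <- blk[[i]]
      u <- st$sol[ix]
      quad <- sum(u^2 * dinv[[i]])
      tr <- sum(diag(st$Ci)[ix] * dinv[[i]])
      new[i] <- (quad + te * tr) / q[i]
    }
    new[r + 1L] <- st$sse / (n - p)
    pmax(new, flo)
  }

  ai_step <- function(st) {
    theta <- st$theta; th <- theta[seq_len(r)]; te <- theta[r + 1L]
    b <- st$sol[seq_len(p)]
    ehat <- y - drop(W %*% st$sol)
    Py <- ehat / te
    Fm <- matrix(0, n, r + 1L)
    trPV <- numeric(r + 1L)
    for (i in seq_len(r)) {
      ix <- blk[[i]]
      Ztp <- as.numeric(Matrix::crossprod(terms[[i]]$Z, Py))
      Fm[, i] <- as.numeric(terms[[i]]$Z %*% (Ztp / dinv[[i]]))
      tr <- sum(diag(st$Ci)[ix] * dinv[[i]])
      trPV[i] <- (q[i] - (te / th[i]) * tr) / th[i]
    }
    Fm[, r + 1L] <- Py
    trPV[r + 1L] <- ((n - p) - sum(trPV[seq_len(r)] * th)) / te
    SOL <- st$Ci %*% crossprod(W, Fm)
    PF <- (Fm - W %*% SOL) / te
    AI <- 0.5 * crossprod(Fm, as.matrix(PF))
    score <- -0.5 * (trPV - drop(crossprod(Fm, Py)))
    # components pinned at the boundary with an inward-pointing gradient are
    # held fixed; the AI update runs on the active set only
    active <- theta > 2 * flo | score > 0
    active[r + 1L] <- TRUE
    if (!any(active)) return(NULL)
    delta <- tryCatch(
      solve(AI[active, active, drop = FALSE] + diag(1e-10, sum(active)),
            score[active]),
      error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    out <- theta
    out[active] <- out[active] + drop(delta)
    pmax(out, flo)
  }

  # multi-kernel genetic models have flat, highly collinear likelihood
  # ridges; warm-starting from the exact single-kernel optimum of the first
  # K-structured term keeps the fit on the right branch (and makes the fit
  # of a nested model a lower bound, up to the small mass on the extra terms)
  theta <- rep(vy / (r + 1), r + 1L)
  warm <- FALSE
  kidx <- which(!vapply(terms, function(tm) is.null(tm$d), TRUE))
  if (length(kidx) && r > 1L && method == "ai") {
    tm1 <- terms[[kidx[1L]]]
    ws <- tryCatch(.spectral_reml(y, X, tm1$Z, tm1$d, tm1$U), error = function(e) NULL)
    if (!is.null(ws) && is.finite(ws$loglik)) {
      theta[] <- 1e-6 * ws$sg
      theta[kidx[1L]] <- ws$sg
      theta[r + 1L] <- max(ws$se, 1e-3 * vy)
      theta <- pmax(theta, flo)
      warm <- TRUE
    }
  }
  st <- eval_theta(theta)
  ll_path <- st$loglik
  converged <- FALSE; iter <- 0L
  min_iter <- if (method == "ai") (if (warm) 2L else 4L) else 1L
  while (iter < max_iter) {
    iter <- iter + 1L
    use_ai <- method == "ai" && (warm || iter > 2L)
    theta_new <- if (use_ai) ai_step(st) else em_step(st)
    if (is.null(theta_new)) theta_new <- em_step(st)
    st_new <- eval_theta(theta_new)
    if (use_ai && st_new$loglik < st$loglik - 1e-8) {
      # AI overshoot: halve toward current, fall back to EM if still worse
      for (h in 1:4) {
        theta_new <- (theta_new + st$theta) / 2
        st_new <- eval_theta(theta_new)
        if (st_new$loglik >= st$loglik - 1e-8) break
      }
      if (st_new$loglik < st$loglik - 1e-8) {
        theta_new <- em_step(st); st_new <- eval_theta(theta_new)
      }
    }
    # components collapsing to the boundary decay geometrically under EM;
    # snap them to the floor once they are negligible (AI mode only, so the
    # pure-EM path keeps its strict monotone ascent)
    tiny <- method == "ai" & st_new$theta < 1e-5 * vy & st_new$theta < st$theta
    if (any(tiny[seq_len(r)])) {
      th2 <- st_new$theta; th2[seq_len(r)][tiny[seq_len(r)]] <- flo
      st2 <- eval_theta(th2)
      if (st2$loglik >= st_new$loglik - 1e-6 * (1 + abs(st_new$loglik))) st_new <- st2
    }
    done <- abs(st_new$loglik - st$loglik) < tol * (1 + abs(st$loglik)) &&
            iter >= min_iter
    if (verbose) message(sprintf("iter %3d  logLik %.6f", iter, st_new$loglik))
    st <- st_new
    ll_path <- c(ll_path, st$loglik)
    if (done) { converged <- TRUE; break }
  }

  blups <- lapply(seq_len(r), function(i) {
    s <- st$sol[blk[[i]]]
    if (is.null(terms[[i]]$U)) stats::setNames(s, terms[[i]]$levels)
    else stats::setNames(as.numeric(terms[[i]]$U %*% s), terms[[i]]$levels)
  })
  names(blups) <- tnames
  vc <- c(st$theta); names(vc) <- c(tnames, "resid")
  te <- st$theta[r + 1L]
  out <- list(varcomps = vc,
              beta = stats::setNames(st$sol[seq_len(p)], colnames(X)),
              beta_cov = te * st$Ci[seq_len(p), seq_len(p), drop = FALSE],
              blups = blups, loglik = st$loglik, converged = converged,
              n_iter = iter, method = method, n = n, p = p,
              ll_path = ll_path, dropped_fixed = des$dropped,
              term_levels = stats::setNames(lapply(terms, `[[`, "levels"), tnames))
  class(out) <- "remlfit"
  out
}

#' @export
print.remlfit <- function(x, ...) {
  cat(sprintf("REML fit (%s): n = %d, logLik = %.3f, %s\n", x$method, x$n,
              x$loglik, if (x$converged) "converged" else "NOT converged"))
  cat("variance components:\n")
  print(round(x$varcomps, 6))
  invisible(x)
}

#' @export
summary.remlfit <- function(object, ...) {
  se <- sqrt(diag(object$beta_cov))
  structure(list(varcomps = object$varcomps,
                 fixef = data.frame(estimate = object$beta, se = se),
                 loglik = object$loglik, converged = object$converged,
                 n_iter = object$n_iter, method = object$method),
            class = "summary.remlfit")
}

#' @export
print.summary.remlfit <- function(x, ...) {
  cat(sprintf("REML fit (%s), logLik = %.3f\n", x$method, x$loglik))
  cat("\nVariance components:\n"); print(round(x$varcomps, 6))
  cat("\nFixed effects:\n"); print(round(x$fixef, 4))
  invisible(x)
}

#' @export
coef.remlfit <- function(object, ...) object$beta

#' @export
logLik.remlfit <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomps) + length(object$beta),
            class = "logLik")
}
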