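# Validation schemes and metrics: k-fold and cross-stage prediction,
# predictive ability (PA), and top/bottom coincidence indices (TCI/BCI).

#' Random k-fold partition of genotype ids
#'
#' Seed-deterministic disjoint folds whose union is the id set and whose
#' sizes differ by at most one.
#'
#' @param ids character vector of ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of `k` id vectors.
#' @export
kfold_split <- function(ids, k = 5L, seed = 1L) {
  ids <- as.character(ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(ids)) stop("k cannot exceed the number of ids")
  set.seed(seed)
  split(sample(ids), rep_len(seq_len(k), length(ids)))
}

#' Predictive ability
#'
#' Pearson correlation between predicted genetic values (GEBVs) and observed
#' adjusted means (BLUEs), matched by name when both vectors are named.
#'
#' @param gebv,blues numeric vectors (named by genotype id, or equal-length).
#' @return Pearson correlation.
#' @export
predictive_ability <- function(gebv, blues) {
  if (!is.null(names(gebv)) && !is.null(names(blues))) {
    common <- intersect(names(gebv), names(blues))
    gebv <- gebv[common]; blues <- blues[common]
  }
  ok <- !is.na(gebv) & !is.na(blues)
  gebv <- gebv[ok]; blues <- blues[ok]
  if (length(gebv) < 3L) stop("need at least 3 paired values")
  if (stats::sd(gebv) == 0 || stats::sd(blues) == 0)
    stop("constant vector; predictive ability undefined")
  stats::cor(gebv, blues)
}

#' Top / bottom coincidence index
#'
#' Fraction of the observed top (or bottom) `fraction` of genotypes that is
#' recovered in the predicted top (or bottom) tail of the same size,
#' `|intersection| / ceiling(n * fraction)`. Ties are broken by stable id
#' order (position in the input).
#'
#' @param gebv,blues numeric vectors named by genotype id (or equal length).
#' @param fraction tail size as a fraction of `n` (default 0.2).
#' @param side `"top"` or `"bottom"`.
#' @return coincidence in `[0, 1]`.
#' @export
coincidence_index <- function(gebv, blues, fraction = 0.2,
                              side = c("top", "bottom")) {
  side <- match.arg(side)
  if (!is.null(names(gebv)) && !is.null(names(blues))) {
    common <- intersect(names(gebv), names(blues))
    gebv <- gebv[common]; blues <- blues[common]
  } else if (length(gebv) == length(blues)) {
    names(gebv) <- names(blues) <- seq_along(gebv)
  }
  ok <- !is.na(gebv) & !is.na(blues)
  gebv <- gebv[ok]; blues <- blues[ok]
  n <- length(gebv)
  nsel <- ceiling(n * fraction)
  if (nsel < 1L) stop("n * fraction must be at least 1")
  if (stats::sd(gebv) == 0 || stats::sd(blues) == 0)
    stop("constant vector; coincidence undefined")
  pick <- function(x) {
    o <- order(x, decreasing = (side == "top"), method = "radix")
    names(x)[o[seq_len(nsel)]]
  }
  length(intersect(pick(gebv), pick(blues))) / nsel
}

#' Validation scheme descriptor
#'
#' @param kind `"kfold"` or `"cross_stage"`.
#' @param k number of folds (kfold).
#' @param seed RNG seed for fold assignment.
#' @param train,test selector lists for cross-stage schemes; each may give
#'   `stage` and optionally `crop` and/or `soil` values to filter the BLUE
#'   table on (e.g. `list(stage = 2, crop = "P", soil = "L")`).
#' @param keep_overlap keep genotypes present in both stages in the *test*
#'   set too (default `FALSE`: they are retained in training only, the
#'   leakage-safe choice).
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("kfold", "cross_stage"), k = 5L, seed = 1L,
                      train = NULL, test = NULL, keep_overlap = FALSE) {
  kind <- match.arg(kind)
  if (kind == "cross_stage" && (is.null(train) || is.null(test)))
    stop("cross_stage schemes need 'train' and 'test' selectors")
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed),
                 train = train, test = test, keep_overlap = keep_overlap),
            class = "cv_scheme")
}

#' Prediction model descriptor
#'
#' @param method one of `"gblup"`, `"rrblup"`, `"bayes"`, `"rkhs"`, `"rf"`,
#'   `"svm"`, `"gs_fixed"`.
#' @param kernels kernel labels for GBLUP-type models, from
#'   `{"G", "D", "GG", "GD", "Hk"}`.
#' @param use_heterozygosity include genome-wide heterozygosity as a fixed
#'   covariate.
#' @param ... method options (`bayes_method`, `n_iter`, `burn_in`, `thin`,
#'   `bandwidth`, `p_threshold`, `hyper`, ...).
#' @return list of class `gs_model`.
#' @export
gs_model <- function(method = c("gblup", "rrblup", "bayes", "rkhs", "rf",
                                "svm", "gs_fixed"),
                     kernels = "G", use_heterozygosity = FALSE, ...) {
  method <- match.arg(method)
  structure(list(method = method, kernels = kernels,
                 use_heterozygosity = use_heterozygosity, options = list(...)),
            class = "gs_model")
}

# build the kernel list a model needs, from precomputed components
.model_kernels <- function(model, comp) {
  ks <- list()
  for (lab in model$kernels) {
    ks[[lab]] <- switch(lab,
      G = comp$G_A, D = comp$G_D, GG = comp$G_AA, GD = comp$G_AD,
      Hk = comp$H,
      stop(sprintf("unknown kernel label '%s'", lab)))
    if (is.null(ks[[lab]])) stop(sprintf("kernel '%s' not available (pedigree needed for Hk?)", lab))
  }
  ks
}

# compute relationship components once per data bundle
.precompute_components <- function(geno, ped = NULL, tau_blend = 0.05) {
  Gi <- if (anyNA(geno$dosages)) impute_mean(geno) else geno
  G_A <- build_grm(Gi, "additive")
  G_D <- build_grm(Gi, "dominance")
  had <- hadamard_kernels(G_A, G_D)
  H <- NULL
  if (!is.null(ped)) {
    A <- amatrix(ped)
    gids <- intersect(ped$id[ped$genotyped], Gi$ids)
    Hfull <- hmatrix(A, G_A, genotyped = gids, tau_blend = tau_blend)
    H <- rel_matrix(unclass(Hfull)[Gi$ids, Gi$ids], "H", ids = Gi$ids)
  }
  list(geno = Gi, G_A = G_A, G_D = G_D, G_AA = had$G_AA, G_AD = had$G_AD, H = H,
       het = heterozygosity(Gi))
}

# fit one model on training blues, return GEBVs for all panel ids.
# All training-data-dependent preprocessing (the association scan for
# gs_fixed) is fitted on the training ids only.
.fit_predict <- function(model, train_blues, comp, seed = 1L) {
  op <- model$options
  hc <- if (model$use_heterozygosity)
    matrix(comp$het, ncol = 1L, dimnames = list(names(comp$het), "het")) else NULL
  switch(model$method,
    gblup = gblup_fit(train_blues, .model_kernels(model, comp),
                      fixed_covariates = hc)$gebv,
    rrblup = rrblup_fit(train_blues, comp$geno)$gebv,
    bayes = do.call(bayes_fit, c(list(blues = train_blues, G = comp$geno,
                                      method = op$bayes_method %||% "BRR",
                                      seed = seed),
                                 op[setdiff(names(op), "bayes_method")]))$gebv,
    rkhs = do.call(rkhs_fit, c(list(blues = train_blues, G = comp$geno,
                                    seed = seed), op))$gebv,
    rf = ml_fit(train_blues, comp$geno, "random_forest",
                hyper = op$hyper %||% list(), seed = seed)$gebv,
    svm = ml_fit(train_blues, comp$geno, "svr_radial",
                 hyper = op$hyper %||% list(), seed = seed)$gebv,
    gs_fixed = {
      scan <- gwas_scan(train_blues, comp$geno, K = comp$G_A,
                        p_threshold = op$p_threshold %||% 0.001)
      suppressMessages(
        gs_with_fixed_snps(train_blues, .model_kernels(model, comp), scan,
                           comp$geno)$gebv)
    },
    stop("unknown model method"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.select_rows <- function(blues_table, sel) {
  keep <- rep(TRUE, nrow(blues_table))
  for (f in intersect(names(sel), c("stage", "crop", "soil")))
    keep <- keep & blues_table[[f]] %in% sel[[f]]
  keep
}

#' Run a validation scheme for one model and trait
#'
#' For k-fold schemes the genotypes of the (single-stage) BLUE table are
#' partitioned with [kfold_split()]; the model is fitted on k-1 folds and
#' predicts the held-out fold, and PA/TCI/BCI are computed per fold and
#' averaged. For cross-stage schemes the model is trained on the BLUEs of
#' the training selector's genotypes and predicts the test selector's
#' genotypes from genomic data alone; genotypes present in both subsets are
#' kept in training only unless the scheme says otherwise.
#'
#' @param scheme a [cv_scheme()].
#' @param model a [gs_model()].
#' @param trait trait name (a column of `data$blues`).
#' @param data list with `blues` (data frame: `genotype`, optionally `stage`,
#'   `crop`, `soil`, plus trait columns), `geno` (a [genotype_matrix()]) and
#'   optionally `ped` (a [pedigree()], needed for the `Hk` kernel).
#' @param fraction tail fraction for the coincidence indices (default 0.2).
#' @return an `EvaluationResult`-style list of class `gs_eval`: `per_fold`
#'   data frame and the means `pa`, `tci`, `bci`.
#' @export
run_scheme <- function(scheme, model, trait, data, fraction = 0.2) {
  stopifnot(inherits(scheme, "cv_scheme"), inherits(model, "gs_model"))
  bt <- data$blues
  if (is.null(bt[[trait]])) stop(sprintf("trait '%s' not in the BLUE table", trait))
  comp <- data$comp %||% .precompute_components(data$geno, data$ped)
  label <- paste0(model$method,
                  if (model$method %in% c("gblup", "gs_fixed"))
                    paste0("[", paste(model$kernels, collapse = "+"), "]") else "")
  if (scheme$kind == "kfold") {
    ids <- unique(bt$genotype[!is.na(bt[[trait]])])
    ids <- intersect(ids, data$geno$ids)
    blues <- stats::setNames(bt[[trait]][match(ids, bt$genotype)], ids)
    folds <- kfold_split(ids, scheme$k, scheme$seed)
    rows <- lapply(seq_along(folds), function(i) {
      test <- folds[[i]]
      train <- setdiff(ids, test)
      gebv <- .fit_predict(model, blues[train], comp, seed = scheme$seed + i)
      data.frame(fold = i,
                 pa = predictive_ability(gebv[test], blues[test]),
                 tci = coincidence_index(gebv[test], blues[test], fraction, "top"),
                 bci = coincidence_index(gebv[test], blues[test], fraction, "bottom"))
    })
  } else {
    tr <- bt[.select_rows(bt, scheme$train), , drop = FALSE]
    te <- bt[.select_rows(bt, scheme$test), , drop = FALSE]
    if (!nrow(tr)) stop("training selector matched no rows")
    if (!nrow(te)) stop("test selector matched no rows")
    train_ids <- intersect(unique(tr$genotype[!is.na(tr[[trait]])]), data$geno$ids)
    test_ids <- intersect(unique(te$genotype[!is.na(te[[trait]])]), data$geno$ids)
    overlap <- intersect(train_ids, test_ids)
    if (length(overlap) && !scheme$keep_overlap)
      test_ids <- setdiff(test_ids, overlap)
    if (length(test_ids) < 3L) stop("fewer than 3 test genotypes after overlap handling")
    train_blues <- stats::setNames(tr[[trait]][match(train_ids, tr$genotype)], train_ids)
    test_blues <- stats::setNames(te[[trait]][match(test_ids, te$genotype)], test_ids)
    gebv <- .fit_predict(model, train_blues, comp, seed = scheme$seed)
    rows <- list(data.frame(
      fold = 1L,
      pa = predictive_ability(gebv[test_ids], test_blues),
      tci = coincidence_index(gebv[test_ids], test_blues, fraction, "top"),
      bci = coincidence_index(gebv[test_ids], test_blues, fraction, "bottom")))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(model_label = label, trait = trait, scheme = scheme$kind,
                 per_fold = per_fold,
                 pa = mean(per_fold$pa), tci = mean(per_fold$tci),
                 bci = mean(per_fold$bci)),
            class = "gs_eval")
}

#' @export
print.gs_eval <- function(x, ...) {
  cat(sprintf("%s | %s | %s: PA = %.3f, TCI = %.3f, BCI = %.3f (%d fold%s)\n",
              x$model_label, x$trait, x$scheme, x$pa, x$tci, x$bci,
              nrow(x$per_fold), if (nrow(x$per_fold) == 1L) "" else "s"))
  invisible(x)
}

#' Marker-density sweep over LD-pruning thresholds
#'
#' For each r^2 threshold the panel is pruned with [ld_prune()] (on genotype
#' data only, once per threshold), relationship kernels are rebuilt, and the
#' given validation scheme is run for every model; PA and surviving marker
#' counts are tabulated. The default thresholds are the eight LD filter
#' schemes commonly used for density studies, plus the full panel.
#'
#' @param data data bundle as in [run_scheme()].
#' @param trait trait name.
#' @param models list of [gs_model()]s (or a single one).
#' @param scheme a [cv_scheme()].
#' @param thresholds r^2 thresholds.
#' @param ... passed to [run_scheme()].
#' @return data frame with columns `threshold`, `n_markers`, `model`, `pa`,
#'   `tci`, `bci`.
#' @export
marker_density_sweep <- function(data, trait, models, scheme,
                                 thresholds = c(0.1, 0.15, 0.2, 0.3, 0.4,
                                                0.6, 0.8, 0.99), ...) {
  if (inherits(models, "gs_model")) models <- list(models)
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  out <- list()
  for (th in thresholds) {
    Gp <- ld_prune(data$geno, th)
    dat <- list(blues = data$blues, geno = Gp, ped = data$ped)
    for (mod in models) {
      ev <- run_scheme(scheme, mod, trait, dat, ...)
      out[[length(out) + 1L]] <- data.frame(
        threshold = th, n_markers = ncol(Gp$dosages), model = ev$model_label,
        pa = ev$pa, tci = ev$tci, bci = ev$bci)
    }
  }
  do.call(rbind, out)
}
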