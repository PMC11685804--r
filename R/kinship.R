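#' Pedigree
#'
#' Three-column pedigree (individual, sire, dam) with unknown parents coded
#' `NA` (or `0`/`""` on input), plus a logical `genotyped` flag used by the
#' single-step H matrix. Rows are topologically sorted so parents precede
#' offspring; a cycle is an error.
#'
#' @param id,sire,dam character vectors of equal length.
#' @param genotyped logical flag per individual (default all `TRUE`).
#' @param sort_topologically reorder so parents precede offspring
#'   (default `TRUE`); if `FALSE`, an out-of-order pedigree is an error.
#' @return a `data.frame` of class `pedigree` with columns
#'   `id`, `sire`, `dam`, `genotyped`.
#' @export
pedigree <- function(id, sire, dam, genotyped = TRUE, sort_topologically = TRUE) {
  id <- as.character(id)
  clean <- function(x) { x <- as.character(x); x[x %in% c("0", "", "NA")] <- NA; x }
  sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  unknown_parent <- function(p) !is.na(p) & !(p %in% id)
  if (any(unknown_parent(sire)) || any(unknown_parent(dam)))
    stop("parent not present in the pedigree id column")
  genotyped <- rep_len(as.logical(genotyped), length(id))
  ped <- data.frame(id = id, sire = sire, dam = dam, genotyped = genotyped,
                    stringsAsFactors = FALSE)
  ord <- .ped_toposort(ped)
  if (is.null(ord)) stop("pedigree contains a cycle")
  if (!identical(ord, seq_along(id))) {
    if (!sort_topologically) stop("individual listed before its parents; set sort_topologically = TRUE")
    ped <- ped[ord, , drop = FALSE]
    rownames(ped) <- NULL
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; NULL on cycle
.ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    queue <- sort(queue)           # stable: keep input order among ready nodes
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != n) return(NULL)
  out
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("pedigree: %d individuals (%d founders), %d genotyped\n",
              nrow(x), founders, sum(x$genotyped)))
  invisible(x)
}

#' Relationship matrix
#'
#' A symmetric kinship-style covariance structure among genotypes, tagged by
#' kind: `A` (pedigree numerator), `G_A` (VanRaden additive GRM), `G_D`
#' (Vitezica dominance GRM), `G_AA`/`G_AD` (Hadamard epistatic kernels),
#' `H` (single-step hybrid) or `K` (generic, e.g. a Gaussian RKHS kernel).
#'
#' @param values symmetric numeric matrix with genotype ids as dimnames.
#' @param kind one of `"A"`, `"G_A"`, `"G_D"`, `"G_AA"`, `"G_AD"`, `"H"`, `"K"`.
#' @param ids genotype labels, defaulting to `rownames(values)`.
#' @return a numeric matrix of class `rel_matrix` with a `kind` attribute.
#' @export
rel_matrix <- function(values, kind = "K", ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(values)))
  if (max(abs(values - t(values))) > 1e-8) stop("relationship matrix must be symmetric")
  values <- (values + t(values)) / 2
  kind <- match.arg(kind, c("A", "G_A", "G_D", "G_AA", "G_AD", "H", "K"))
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix [%s]: %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

rel_ids <- function(K) rownames(K)

#' Genomic relationship matrices (VanRaden additive, Vitezica dominance)
#'
#' Additive: markers are centered by twice the observed allele frequency,
#' `W = M - 2p`, and `G_A = W W' / sum(2 p (1 - p))`. Dominance: the
#' breeding-model dominance coding per marker is `-2p^2` (dosage 0),
#' `2 p (1 - p)` (dosage 1) and `-2 (1 - p)^2` (dosage 2), scaled by
#' `sum((2 p (1 - p))^2)`. Allele frequencies are recomputed on the (mean-
#' imputed) panel. Monomorphic markers carry no information and are excluded
#' with a warning.
#'
#' @param G a complete (imputed) [genotype_matrix()].
#' @param kind `"additive"` or `"dominance"`.
#' @return a [rel_matrix()] of kind `G_A` or `G_D`.
#' @export
build_grm <- function(G, kind = c("additive", "dominance")) {
  stopifnot(inherits(G, "genotype_matrix"))
  kind <- match.arg(kind)
  d <- G$dosages
  if (anyNA(d)) stop("genotype matrix contains missing calls; impute_mean() first")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sprintf("%d monomorphic marker(s) excluded from the GRM", sum(!poly)))
    d <- d[, poly, drop = FALSE]; p <- p[poly]
  }
  if (!length(p)) stop("no polymorphic markers left to build a GRM")
  q <- 1 - p
  if (kind == "additive") {
    W <- sweep(d, 2L, 2 * p)
    K <- tcrossprod(W) / sum(2 * p * q)
    return(rel_matrix(K, "G_A", ids = G$ids))
  }
  # Vitezica dominance coding
  P0 <- matrix(-2 * p^2, nrow(d), ncol(d), byrow = TRUE)
  P1 <- matrix(2 * p * q, nrow(d), ncol(d), byrow = TRUE)
  P2 <- matrix(-2 * q^2, nrow(d), ncol(d), byrow = TRUE)
  # fractional (imputed) dosages: linear interpolation between the three codes
  lo <- pmax(0, 1 - abs(d - 1))          # weight on the heterozygote code
  w0 <- pmax(0, 1 - d) ; w2 <- pmax(0, d - 1)
  WD <- w0 * P0 + lo * P1 + w2 * P2
  K <- tcrossprod(WD) / sum((2 * p * q)^2)
  rel_matrix(K, "G_D", ids = G$ids)
}

#' Pedigree numerator relationship matrix (Henderson tabular method)
#'
#' `a_ii = 1 + 0.5 a(sire_i, dam_i)`; `a_ij = 0.5 (a(j, sire_i) + a(j, dam_i))`
#' for `j` earlier in the (topologically sorted) pedigree; founders have
#' diagonal 1 and zero relationship to all earlier individuals.
#'
#' @param ped a [pedigree()].
#' @return a [rel_matrix()] of kind `A`.
#' @export
amatrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else rep(0, i - 1L)) +
                   (if (!is.na(d)) A[j, d] else rep(0, i - 1L)))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  rel_matrix(A, "A", ids = ped$id)
}

#' Monte Carlo A matrix by gene dropping
#'
#' Independent check of [amatrix()]: founder alleles are labelled uniquely and
#' dropped through the pedigree with Mendelian sampling in `n_rep` replicates;
#' the additive relationship is estimated as twice the average probability of
#' identity by descent between random alleles of the two individuals.
#'
#' @param ped a [pedigree()].
#' @param n_rep number of gene-dropping replicates.
#' @return a [rel_matrix()] of kind `A` (Monte Carlo estimate).
#' @export
gene_drop_amatrix <- function(ped, n_rep = 1e5) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  a1 <- matrix(0L, n_rep, n); a2 <- matrix(0L, n_rep, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      a_s <- rep.int(next_allele, n_rep); next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      a_s <- ifelse(pick, a1[, s], a2[, s])
    }
    if (is.na(d)) {
      a_d <- rep.int(next_allele, n_rep); next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      a_d <- ifelse(pick, a1[, d], a2[, d])
    }
    a1[, i] <- a_s; a2[, i] <- a_d
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
           (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
    A[i, j] <- A[j, i] <- 2 * mean(ibd) / 4
  }
  rel_matrix(A, "A", ids = ped$id)
}

#' Single-step hybrid relationship matrix (H)
#'
#' Combines pedigree relationships `A` over all individuals with a genomic
#' matrix `G` over the genotyped subset. With individuals partitioned into
#' non-genotyped (1) and genotyped (2):
#' `H22 = G* = (1 - tau_blend) G + tau_blend A22`,
#' `H12 = A12 A22^{-1} G*`, and
#' `H11 = A11 + A12 A22^{-1} (G* - A22) A22^{-1} A21`.
#' Blending keeps `G*` invertible and propagates pedigree information.
#'
#' @param A pedigree [rel_matrix()] over all individuals.
#' @param G genomic [rel_matrix()] over the genotyped individuals.
#' @param genotyped ids of the genotyped subset (default: the ids of `G`).
#' @param tau_blend blending weight on `A22` in `G*` (default 0.05).
#' @return a [rel_matrix()] of kind `H` over the ids of `A`.
#' @export
hmatrix <- function(A, G, genotyped = rel_ids(G), tau_blend = 0.05) {
  stopifnot(inherits(A, "rel_matrix"), inherits(G, "rel_matrix"),
            tau_blend >= 0, tau_blend <= 1)
  ids <- rel_ids(A)
  genotyped <- as.character(genotyped)
  if (!all(genotyped %in% ids)) stop("genotyped ids must be a subset of the ids of A")
  if (!all(genotyped %in% rel_ids(G))) stop("G must cover all genotyped ids")
  if (!length(genotyped)) return(rel_matrix(unclass(A), "H", ids = ids))
  i2 <- match(genotyped, ids); i1 <- setdiff(seq_along(ids), i2)
  A22 <- A[i2, i2, drop = FALSE]
  Gs <- (1 - tau_blend) * G[genotyped, genotyped, drop = FALSE] + tau_blend * A22
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  H[i2, i2] <- Gs
  if (length(i1)) {
    A22i <- tryCatch(solve(A22), error = function(e)
      stop("A22 is singular; consider blending (tau_blend > 0) or pruning the pedigree"))
    A12 <- A[i1, i2, drop = FALSE]
    B <- A12 %*% A22i                       # A12 A22^-1
    H[i1, i2] <- B %*% Gs
    H[i2, i1] <- t(H[i1, i2])
    H[i1, i1] <- A[i1, i1] + B %*% (Gs - A22) %*% t(B)
  }
  rel_matrix(H, "H", ids = ids)
}

#' Hadamard epistatic kernels
#'
#' Element-wise products of the additive and dominance GRMs give the
#' additive-by-additive (`G_AA = G_A o G_A`) and additive-by-dominance
#' (`G_AD = G_A o G_D`) covariance kernels; both are positive semi-definite
#' by the Schur product theorem. By default each kernel is rescaled so its
#' mean diagonal equals 1, keeping variance components comparable across
#' kernels.
#'
#' @param G_A additive [rel_matrix()].
#' @param G_D dominance [rel_matrix()].
#' @param rescale rescale each product to mean diagonal 1 (default `TRUE`).
#' @return list with elements `G_AA` and `G_AD`.
#' @export
hadamard_kernels <- function(G_A, G_D, rescale = TRUE) {
  stopifnot(inherits(G_A, "rel_matrix"), inherits(G_D, "rel_matrix"))
  if (!identical(rel_ids(G_A), rel_ids(G_D)))
    stop("G_A and G_D must be over the same ids in the same order")
  GAA <- unclass(G_A) * unclass(G_A)
  GAD <- unclass(G_A) * unclass(G_D)
  if (rescale) {
    GAA <- GAA / mean(diag(GAA))
    if (mean(diag(GAD)) > 0) GAD <- GAD / mean(diag(GAD))
  }
  list(G_AA = rel_matrix(GAA, "G_AA", ids = rel_ids(G_A)),
       G_AD = rel_matrix(GAD, "G_AD", ids = rel_ids(G_A)))
}
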