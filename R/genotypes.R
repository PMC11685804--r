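#' Genotype dosage matrix
#'
#' Container for a panel of biallelic markers scored as alternate-allele
#' dosages \{0, 1, 2\} on a set of genotypes (clones). Missing calls are
#' stored as `NA`. A marker map (chromosome, position) is carried along so
#' LD-based operations can work within chromosomes.
#'
#' @param dosages numeric matrix, genotypes in rows and markers in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param ids genotype labels; defaults to `rownames(dosages)`.
#' @param marker_ids marker labels; defaults to `colnames(dosages)`.
#' @param chrom integer/character chromosome per marker; defaults to a single
#'   chromosome.
#' @param pos numeric map position per marker; defaults to the column index.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `ids`, `marker_ids`, `chrom`, `pos` and `allele_freq` (the
#'   alternate-allele frequency computed from non-missing calls).
#' @export
genotype_matrix <- function(dosages, ids = rownames(dosages),
                            marker_ids = colnames(dosages),
                            chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (n < 1L || m < 1L) stop("dosages must have at least one genotype and one marker")
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(m))
  ids <- as.character(ids); marker_ids <- as.character(marker_ids)
  if (anyDuplicated(ids)) stop("genotype ids must be unique")
  if (length(ids) != n) stop("ids length does not match number of rows")
  if (length(marker_ids) != m) stop("marker_ids length does not match number of columns")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stop("dosage entries must lie in [0, 2] ({0, 1, 2} for raw calls) or be NA")
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m)
  if (length(chrom) != m || length(pos) != m) stop("marker map length must equal number of markers")
  dimnames(dosages) <- list(ids, marker_ids)
  obj <- list(dosages = dosages, ids = ids, marker_ids = marker_ids,
              chrom = chrom, pos = as.numeric(pos),
              allele_freq = colMeans(dosages, na.rm = TRUE) / 2)
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d genotypes x %d markers (%d chromosome%s), %.1f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$dosages

# subset markers by logical/integer index, preserving map
subset_markers <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE], ids = G$ids,
                  marker_ids = G$marker_ids[keep],
                  chrom = G$chrom[keep], pos = G$pos[keep])
}

#' Filter markers on missing rate and minor allele frequency
#'
#' Retains markers whose missing-call fraction is at most `max_missing` and
#' whose minor allele frequency (computed on non-missing calls) is at least
#' `min_maf`. Marker order is preserved. The defaults are the conventional
#' panel filters (missing <= 20%, MAF >= 10%).
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximum tolerated fraction of missing calls per marker.
#' @param min_maf minimum minor allele frequency.
#' @return the filtered `genotype_matrix`.
#' @export
filter_markers <- function(G, max_missing = 0.2, min_maf = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(G$dosages))
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing marker
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) stop("no markers survive the missing-rate/MAF filters (empty panel)")
  subset_markers(G, keep)
}

#' Replace missing dosages by the marker mean
#'
#' Mean imputation per marker: each missing call is replaced by the mean
#' dosage of the non-missing calls at that marker, leaving column means
#' unchanged.
#'
#' @param G a [genotype_matrix()].
#' @return a complete `genotype_matrix` (fractional dosages allowed downstream).
#' @export
impute_mean <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (!anyNA(d)) return(G)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("marker(s) entirely missing; filter before imputation")
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  out <- G
  out$dosages <- d
  out$allele_freq <- colMeans(d) / 2
  out
}

# imputed dosage matrix, imputing on the fly when needed
.imputed_dosages <- function(G) {
  if (anyNA(G$dosages)) impute_mean(G)$dosages else G$dosages
}

#' Collapse markers in complete linkage disequilibrium
#'
#' Among any group of markers whose pairwise squared correlation (on mean-
#' imputed dosages) equals 1, only the first marker in map order is retained.
#' r^2 = 1 means the standardized dosage vectors are identical up to sign, so
#' the groups are found exactly by hashing the sign-canonicalized standardized
#' columns rather than by an m x m correlation matrix.
#'
#' @param G a [genotype_matrix()].
#' @return the deduplicated `genotype_matrix`.
#' @export
dedup_complete_ld <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- .imputed_dosages(G)
  z <- scale(d)                       # center + unit sd; constant cols -> NaN
  keep <- rep(TRUE, ncol(d))
  ok <- which(apply(is.finite(z), 2L, all))
  if (length(ok) > 1L) {
    zz <- z[, ok, drop = FALSE]
    # canonical sign: first non-zero entry positive
    sgn <- apply(zz, 2L, function(v) { i <- which(abs(v) > 1e-12)[1L]; if (is.na(i)) 1 else sign(v[i]) })
    zz <- sweep(zz, 2L, sgn, `*`)
    key <- apply(round(zz, 9L), 2L, paste, collapse = ",")
    keep[ok[duplicated(key)]] <- FALSE
  }
  subset_markers(G, keep)
}

#' Greedy LD pruning in map order
#'
#' Deterministic single pass along each chromosome in map order: a marker is
#' kept if and only if its squared correlation with every previously kept
#' marker on the same chromosome within a trailing window is below
#' `r2_threshold`. Correlations are composite (dosage-based), computed on
#' mean-imputed dosages.
#'
#' @param G a [genotype_matrix()].
#' @param r2_threshold markers at r^2 >= this value with a kept marker are
#'   removed; must lie in (0, 1].
#' @param window number of previously kept markers compared against.
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(G, r2_threshold, window = 50L) {
  stopifnot(inherits(G, "genotype_matrix"),
            r2_threshold > 0, r2_threshold <= 1)
  d <- .imputed_dosages(G)
  z <- scale(d)
  nn <- nrow(d) - 1
  keep <- logical(ncol(d))
  for (ch in unique(G$chrom)) {
    cols <- which(G$chrom == ch)
    cols <- cols[order(G$pos[cols])]
    kept <- integer(0)
    for (j in cols) {
      if (!all(is.finite(z[, j]))) { keep[j] <- TRUE; kept <- c(kept, j); next }
      recent <- utils::tail(kept, window)
      recent <- recent[apply(is.finite(z[, recent, drop = FALSE]), 2L, all)]
      if (length(recent)) {
        r2 <- (crossprod(z[, recent, drop = FALSE], z[, j]) / nn)^2
        if (any(r2 >= r2_threshold)) next
      }
      keep[j] <- TRUE
      kept <- c(kept, j)
    }
  }
  subset_markers(G, keep)
}

#' Genome-wide heterozygosity per genotype
#'
#' Fraction of markers scored as heterozygous (dosage exactly 1) for each
#' genotype; missing calls are skipped. Used as a fixed covariate in extended
#' GBLUP models.
#'
#' @param G a [genotype_matrix()].
#' @return named numeric vector in `[0, 1]`.
#' @export
heterozygosity <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  het <- rowMeans(G$dosages == 1, na.rm = TRUE)
  names(het) <- G$ids
  het
}
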