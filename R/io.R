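# Readers and writers for the plain-text interchange formats:
# dosage TSV (rows = genotypes, header = marker ids), minimal unphased VCF,
# 3-column pedigree CSV (0 = unknown parent), trial-table CSV, and labelled
# TSV for relationship matrices.

#' Write / read a genotype dosage TSV
#'
#' Tab-separated file with genotype ids in the first column and one column
#' per marker; missing calls are written as `NA`. The marker map is stored in
#' two header comment lines (`#chrom`, `#pos`).
#'
#' @param G a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chrom\t", paste(G$chrom, collapse = "\t")), con)
  writeLines(paste0("#pos\t", paste(G$pos, collapse = "\t")), con)
  writeLines(paste(c("id", G$marker_ids), collapse = "\t"), con)
  utils::write.table(cbind(id = G$ids, as.data.frame(G$dosages)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  hdr <- readLines(path, n = 3L)
  chrom <- strsplit(hdr[1L], "\t")[[1]][-1L]
  pos <- as.numeric(strsplit(hdr[2L], "\t")[[1]][-1L])
  dat <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  d <- as.matrix(dat[, -1L, drop = FALSE])
  rownames(d) <- dat[[1L]]
  genotype_matrix(d, chrom = chrom, pos = pos)
}

#' Write / read genotypes as minimal VCF
#'
#' Writes an unphased GT-only VCF v4.2 (REF=A, ALT=T placeholders; dosage 0
#' -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`). Reading uses the
#' `vcfR` parser and converts GT back to alternate-allele dosage.
#'
#' @param G a [genotype_matrix()] with integer dosages.
#' @param path file path.
#' @return `write_vcf` returns `path` invisibly; `read_vcf` a
#'   [genotype_matrix()].
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (any(!is.na(d) & d != round(d)))
    stop("VCF export requires raw integer dosages (not imputed values)")
  gt <- matrix("./.", ncol(d), nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  ok <- which(!is.na(t(d)))
  gt[ok] <- codes[t(d)[ok] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$ids), collapse = "\t")), con)
  body <- cbind(G$chrom, format(G$pos, scientific = FALSE, trim = TRUE),
                G$marker_ids, "A", "T", ".", "PASS", ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x != "./." & x != ".|."
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), 0)
    out
  }
  d <- t(apply(gt, 1L, count_alt))
  colnames(d) <- colnames(gt)
  fx <- vcfR::getFIX(v)
  genotype_matrix(t(d), ids = colnames(gt), marker_ids = fx[, "ID"],
                  chrom = fx[, "CHROM"], pos = as.numeric(fx[, "POS"]))
}

#' Write / read a pedigree CSV
#'
#' Three columns `id, sire, dam` with `0` for unknown parents, plus a
#' `genotyped` flag column.
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @return `write_pedigree_csv` returns `path` invisibly; `read_pedigree_csv`
#'   a [pedigree()].
#' @export
write_pedigree_csv <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  genotyped <- if ("genotyped" %in% names(df)) as.logical(df$genotyped) else TRUE
  pedigree(df$id, df$sire, df$dam, genotyped = genotyped)
}

#' Write a trial table or relationship matrix
#'
#' @param x a `trial_table` data frame or [rel_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$genotype <- as.character(out$genotype)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @rdname write_trials_csv
#' @export
write_rel_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "rel_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind\t", attr(x, "kind")), con)
  utils::write.table(cbind(id = rownames(x), as.data.frame(unclass(x))), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_rel_matrix_tsv <- function(path) {
  kind <- sub("^#kind\t", "", readLines(path, n = 1L))
  dat <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(dat[, -1L, drop = FALSE])
  rownames(m) <- dat[[1L]]
  rel_matrix(m, kind = kind)
}
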