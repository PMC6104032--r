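#' Genotype matrix container
#'
#' Holds biallelic SNP calls for a panel of lines as allele dosages.
#' Dosage coding: 0 and 2 are the two homozygotes (0 = first allele label
#' listed for the marker, 2 = second), 1 is heterozygous, `NA` is missing.
#' Inbred wheat panels are expected to sit almost entirely in \{0, 2\}.
#'
#' @param calls integer matrix, lines in rows and markers in columns, with
#'   dimnames giving line and marker identifiers. Values in \{0, 1, 2, NA\}.
#' @param alleles character matrix with one row per marker (rownames matching
#'   the marker ids of `calls`) and two columns giving the allele labels
#'   mapped to dosage 0 and dosage 2.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, alleles) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  # empty dimensions legitimately carry NULL dimnames in R
  if ((nrow(calls) > 0L && is.null(rownames(calls))) ||
      (ncol(calls) > 0L && is.null(colnames(calls))))
    stop("`calls` must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate line ids in genotype matrix")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids in genotype matrix")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != 2L)
    stop("`alleles` must have two columns")
  if (is.null(rownames(alleles)))
    stop("`alleles` must have marker ids as rownames")
  if (!setequal(rownames(alleles), colnames(calls)))
    stop("allele table and call matrix disagree on marker ids")
  alleles <- alleles[colnames(calls), , drop = FALSE]
  if (any(alleles[, 1L] == alleles[, 2L]))
    stop("the two allele labels of a marker must be distinct")
  colnames(alleles) <- c("a0", "a2")
  structure(list(calls = calls, alleles = alleles), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d lines x %d markers (%.1f%% missing, %.2f%% heterozygous)\n",
    nrow(x$calls), ncol(x$calls),
    100 * mean(is.na(x$calls)),
    100 * het_rate(x)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Line and marker identifiers of a genotype matrix
#' @param G a `geno_matrix`
#' @return character vector of ids.
#' @export
line_ids <- function(G) rownames(G$calls)

#' @rdname line_ids
#' @export
marker_ids <- function(G) colnames(G$calls)

#' Subset a genotype matrix by lines and/or markers
#'
#' @param G a `geno_matrix`
#' @param lines,markers character or index vectors; `NULL` keeps all.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(G, lines = NULL, markers = NULL) {
  calls <- G$calls
  if (!is.null(lines)) calls <- calls[lines, , drop = FALSE]
  if (!is.null(markers)) calls <- calls[, markers, drop = FALSE]
  geno_matrix(calls, G$alleles[colnames(calls), , drop = FALSE])
}

#' Per-marker alternate-allele frequency
#'
#' Frequency of the dosage-2 allele among non-missing calls,
#' counting heterozygotes as half.
#' @param G a `geno_matrix`
#' @return named numeric vector over markers.
#' @export
allele_freq <- function(G) colMeans(G$calls, na.rm = TRUE) / 2

#' Minor allele frequency per marker
#' @param G a `geno_matrix`
#' @return named numeric vector over markers; `NaN` where all calls missing.
#' @export
maf <- function(G) {
  p <- allele_freq(G)
  pmin(p, 1 - p)
}

#' Panel-wide heterozygous call rate
#' @param G a `geno_matrix`
#' @return fraction of non-missing calls equal to 1.
#' @export
het_rate <- function(G) {
  nm <- !is.na(G$calls)
  if (!any(nm)) return(NaN)
  sum(G$calls == 1L, na.rm = TRUE) / sum(nm)
}

# dosage -> allele-letter string for fully homozygous calls; NA otherwise
call_to_allele <- function(dosage, alleles) {
  out <- rep(NA_character_, length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- alleles[1L]
  out[!is.na(dosage) & dosage == 2L] <- alleles[2L]
  out
}
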