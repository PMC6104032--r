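#' Wheat chromosome labels in canonical order
#'
#' Bread wheat's 21 chromosomes ordered 1A, 1B, 1D, 2A, ..., 7D. The position
#' of a label in this vector is the chromosome index used in haplotype-block
#' names (1 = 1A, 2 = 1B, ..., 21 = 7D).
#' @return character vector of length 21.
#' @export
wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 3), c("A", "B", "D"))
}

#' Chromosome label to numeric index
#' @param chrom character vector of labels present in `levels`
#' @param levels ordered chromosome labels (default [wheat_chromosomes()])
#' @return integer index vector.
#' @export
chrom_index <- function(chrom, levels = wheat_chromosomes()) {
  i <- match(chrom, levels)
  if (anyNA(i))
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  i
}

#' Genetic map container
#'
#' A validated, deterministically ordered marker map. Markers are sorted by
#' chromosome index, then centimorgan position, then marker id (the
#' lexicographic tie-break fixes the order of co-located markers, which
#' matters because only the first of a co-located group enters haplotype
#' construction).
#'
#' @param marker character marker ids (unique)
#' @param chrom chromosome labels
#' @param cM numeric genetic positions, `>= 0`
#' @param chrom_levels ordered chromosome labels defining the index
#' @return data.frame of class `genetic_map` with columns
#'   `marker`, `chrom`, `cM`, `chrom_idx`.
#' @export
genetic_map <- function(marker, chrom, cM, chrom_levels = wheat_chromosomes()) {
  marker <- as.character(marker)
  if (anyDuplicated(marker))
    stop("duplicate marker id(s) in genetic map")
  cM <- as.numeric(cM)
  if (anyNA(cM) || any(cM < 0))
    stop("cM positions must be non-negative and non-missing")
  idx <- chrom_index(as.character(chrom), chrom_levels)
  m <- data.frame(marker = marker, chrom = as.character(chrom),
                  cM = cM, chrom_idx = idx, stringsAsFactors = FALSE)
  m <- m[order(m$chrom_idx, m$cM, m$marker), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "chrom_levels") <- chrom_levels
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Restrict a map to a set of markers, preserving order
#' @param map a `genetic_map`
#' @param markers marker ids to keep
#' @return a `genetic_map`.
#' @export
subset_map <- function(map, markers) {
  keep <- map[map$marker %in% markers, , drop = FALSE]
  genetic_map(keep$marker, keep$chrom, keep$cM, attr(map, "chrom_levels"))
}
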