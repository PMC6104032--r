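#' Marker and line quality-control parameters
#'
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param hwe_p_min Hardy-Weinberg exact-test p-value cutoff (default 0.001)
#' @param individual_missing_max maximum per-line missing fraction
#'   (default 0.75; lines above it are removed before marker filters)
#' @param hwe_mode `"skip_inbred"` (default) disables the HWE filter when the
#'   panel heterozygous call rate is below `inbred_het_max` — a panel of
#'   selfed lines violates HWE at every marker, so a literal filter would
#'   empty it; `"apply"` always applies the exact test
#' @param inbred_het_max het-rate threshold that auto-engages the skip
#' @param ld_window maximum pairwise marker distance (cM) evaluated for LD
#'   and spanned by a block (default 5)
#' @return object of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.05, hwe_p_min = 0.001,
                      individual_missing_max = 0.75,
                      hwe_mode = c("skip_inbred", "apply"),
                      inbred_het_max = 0.02,
                      ld_window = 5) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            hwe_p_min >= 0, hwe_p_min <= 1,
            individual_missing_max > 0, individual_missing_max <= 1,
            ld_window > 0)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 individual_missing_max = individual_missing_max,
                 hwe_mode = hwe_mode, inbred_het_max = inbred_het_max,
                 ld_window = ld_window),
            class = "qc_params")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditioning on observed allele counts, summing the
#' probability of all heterozygote counts no more probable than the observed
#' one.
#' @param n0,n1,n2 counts of the two homozygotes and the heterozygote class
#'   (`n1` heterozygotes)
#' @return p-value.
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  rare <- 2 * min(n0, n2) + n1   # rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probabilities of each possible heterozygote count
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n1)
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' Quality-control filter for a genotype panel
#'
#' Applied in order: (1) lines with more than `individual_missing_max`
#' missing calls are removed; (2) markers with minor allele frequency below
#' `maf_min` are removed; (3) markers failing the Hardy-Weinberg exact test
#' at `hwe_p_min` are removed when the HWE filter is engaged; (4) markers
#' sharing a genetic position keep only the first in map order. Markers
#' absent from the map are reported and excluded.
#'
#' @param G a `geno_matrix`
#' @param map a `genetic_map`
#' @param params a [qc_params()]
#' @return list with `geno` (filtered `geno_matrix`), `map` (matching
#'   filtered map) and `report` (data.frame `entity`, `id`, `reason`,
#'   `value`, `threshold`).
#' @export
qc_filter <- function(G, map, params = qc_params()) {
  report <- list()
  note <- function(entity, id, reason, value, threshold) {
    report[[length(report) + 1L]] <<- data.frame(
      entity = entity, id = id, reason = reason,
      value = value, threshold = threshold, stringsAsFactors = FALSE)
  }
  miss_line <- rowMeans(is.na(G$calls))
  drop_lines <- miss_line > params$individual_missing_max
  for (i in which(drop_lines))
    note("line", line_ids(G)[i], "missing_fraction", miss_line[i],
         params$individual_missing_max)
  if (any(drop_lines))
    G <- subset_geno(G, lines = !drop_lines)
  if (nrow(G$calls) == 0L) stop("all lines removed by missing-data filter")

  unmapped <- setdiff(marker_ids(G), map$marker)
  for (m in unmapped) note("marker", m, "not_in_map", NA_real_, NA_real_)
  keep <- setdiff(marker_ids(G), unmapped)
  G <- subset_geno(G, markers = keep)

  mafs <- maf(G)
  low <- is.na(mafs) | mafs < params$maf_min
  for (j in which(low))
    note("marker", marker_ids(G)[j], "maf", mafs[j], params$maf_min)
  if (all(low))
    stop("quality control removed every marker: empty panel")
  G <- subset_geno(G, markers = !low)

  hwe_engaged <- params$hwe_mode == "apply" ||
    (is.finite(het_rate(G)) && het_rate(G) >= params$inbred_het_max)
  if (hwe_engaged && ncol(G$calls)) {
    p <- apply(G$calls, 2L, function(d) {
      hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                     sum(d == 2L, na.rm = TRUE))
    })
    fail <- p < params$hwe_p_min
    for (j in which(fail))
      note("marker", marker_ids(G)[j], "hwe", p[j], params$hwe_p_min)
    if (all(fail))
      stop("quality control removed every marker: empty panel")
    G <- subset_geno(G, markers = !fail)
  }

  fmap <- subset_map(map, marker_ids(G))
  dup <- duplicated(fmap[, c("chrom", "cM")])
  for (m in fmap$marker[dup])
    note("marker", m, "co_located", NA_real_, NA_real_)
  fmap <- subset_map(fmap, fmap$marker[!dup])
  G <- subset_geno(G, markers = fmap$marker)

  if (ncol(G$calls) == 0L)
    stop("quality control removed every marker: empty panel")
  list(geno = G, map = fmap,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(entity = character(), id = character(),
                    reason = character(), value = numeric(),
                    threshold = numeric(), stringsAsFactors = FALSE))
}
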