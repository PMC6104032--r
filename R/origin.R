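#' Parent-of-origin A/B/H classification for one cross
#'
#' Classifies each (line, marker) call of a cross against its three parents.
#' A marker is informative when all three parents are homozygous, the two
#' elites carry the same allele, and the exotic differs. At informative
#' markers a line call equal to the exotic homozygote is coded `B` (exotic
#' origin), equal to the elite homozygote `A` (elite origin), heterozygous
#' `H`; missing calls stay missing. Non-informative markers — any parent
#' heterozygous or missing, elites disagreeing, or exotic matching the
#' elites — are coded `U` (unidentified origin) for every line of the cross.
#'
#' @param G `geno_matrix` holding the derived lines
#' @param registry a [cross_registry()]
#' @param cross_id cross to classify
#' @param parent_geno `geno_matrix` holding the parents (defaults to `G`)
#' @return character matrix (class `origin_matrix`) of codes
#'   `A`/`B`/`H`/`U`/`NA`, lines of the cross in rows, shared markers in
#'   columns; attribute `cross_id`.
#' @export
classify_abh <- function(G, registry, cross_id, parent_geno = G) {
  par <- cross_parents(registry, cross_id)
  absent <- setdiff(par, line_ids(parent_geno))
  if (length(absent))
    stop("parent genotype(s) absent: ", paste(absent, collapse = ", "))
  lines <- intersect(line_ids(G), cross_lines(registry, cross_id))
  if (!length(lines)) stop("no lines of cross ", cross_id, " in panel")
  mks <- intersect(marker_ids(G), marker_ids(parent_geno))
  ex <- parent_geno$calls[par[["exotic"]], mks]
  e1 <- parent_geno$calls[par[["elite1"]], mks]
  e2 <- parent_geno$calls[par[["elite2"]], mks]
  informative <- !is.na(ex) & !is.na(e1) & !is.na(e2) &
    ex != 1L & e1 != 1L & e2 != 1L & e1 == e2 & ex != e1
  calls <- G$calls[lines, mks, drop = FALSE]
  out <- matrix(NA_character_, length(lines), length(mks),
                dimnames = list(lines, mks))
  for (j in seq_along(mks)) {
    if (!informative[j]) { out[, j] <- "U"; next }
    d <- calls[, j]
    cj <- rep(NA_character_, length(d))
    cj[!is.na(d) & d == ex[j]] <- "B"
    cj[!is.na(d) & d == e1[j]] <- "A"
    cj[!is.na(d) & d == 1L] <- "H"
    out[, j] <- cj
  }
  structure(out, cross_id = cross_id, class = c("origin_matrix", "matrix"))
}

#' A/B/H classification for every registered cross
#'
#' Runs [classify_abh()] per cross and stacks the results over the shared
#' marker set.
#' @inheritParams classify_abh
#' @return an `origin_matrix` covering all registered lines present in `G`.
#' @export
classify_abh_all <- function(G, registry, parent_geno = G) {
  parts <- lapply(registry$crosses$cross_id, function(cid) {
    if (!length(intersect(line_ids(G), cross_lines(registry, cid))))
      return(NULL)
    classify_abh(G, registry, cid, parent_geno)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("no registered lines found in panel")
  mks <- Reduce(intersect, lapply(parts, colnames))
  out <- do.call(rbind, lapply(parts, function(p) p[, mks, drop = FALSE]))
  structure(out, class = c("origin_matrix", "matrix"))
}

#' Summarize exotic/elite genome contribution from an origin matrix
#'
#' Emits raw fractions of A/B/H/U/missing (denominator: all classified
#' markers) and renormalized fractions among the origin-informative codes
#' \{A, B, H\}. The exotic-contribution estimate counts a heterozygous call
#' as half exotic: `exotic_est = B + H/2` and `elite_est = A + H/2` on the
#' renormalized scale. Lines with no informative marker get `NA` estimates.
#'
#' @param origin an `origin_matrix` (possibly stacked over crosses)
#' @param map optional `genetic_map` for per-chromosome summaries
#' @param registry optional `cross_registry` for per-cross summaries
#' @return list of class `contribution_summary` with `per_line`,
#'   `per_chrom` (if `map` given), `per_cross` (if `registry` given) and
#'   `panel` (a one-row data.frame of panel means).
#' @export
summarize_contribution <- function(origin, map = NULL, registry = NULL) {
  frac_row <- function(m) {
    tot <- ncol(m) * nrow(m) / nrow(m)  # markers per line
    cnt <- function(code) rowSums(m == code, na.rm = TRUE)
    nA <- cnt("A"); nB <- cnt("B"); nH <- cnt("H"); nU <- cnt("U")
    nMiss <- rowSums(is.na(m))
    nc <- nA + nB + nH
    data.frame(
      n_markers = ncol(m),
      frac_A = nA / ncol(m), frac_B = nB / ncol(m), frac_H = nH / ncol(m),
      frac_U = nU / ncol(m), frac_missing = nMiss / ncol(m),
      classified_frac = nc / ncol(m),
      renorm_A = ifelse(nc > 0, nA / nc, NA_real_),
      renorm_B = ifelse(nc > 0, nB / nc, NA_real_),
      renorm_H = ifelse(nc > 0, nH / nc, NA_real_),
      exotic_est = ifelse(nc > 0, (nB + nH / 2) / nc, NA_real_),
      elite_est = ifelse(nc > 0, (nA + nH / 2) / nc, NA_real_))
  }
  per_line <- cbind(data.frame(line = rownames(origin),
                               stringsAsFactors = FALSE), frac_row(origin))
  rownames(per_line) <- NULL
  panel_means <- colMeans(per_line[, -1L], na.rm = TRUE)
  panel <- as.data.frame(t(panel_means))
  out <- list(per_line = per_line, panel = panel)
  if (!is.null(map)) {
    mks <- intersect(colnames(origin), map$marker)
    chrom <- map$chrom[match(mks, map$marker)]
    out$per_chrom <- do.call(rbind, lapply(split(mks, chrom), function(mm) {
      sub <- origin[, mm, drop = FALSE]
      cbind(data.frame(chrom = map$chrom[match(mm[1], map$marker)],
                       stringsAsFactors = FALSE),
            as.data.frame(t(colMeans(frac_row(sub), na.rm = TRUE))))
    }))
    rownames(out$per_chrom) <- NULL
  }
  if (!is.null(registry)) {
    cid <- registry$membership$cross_id[match(per_line$line,
                                              registry$membership$line)]
    byc <- split(seq_len(nrow(per_line)), cid)
    out$per_cross <- do.call(rbind, lapply(names(byc), function(cc) {
      cbind(data.frame(cross_id = cc, n_lines = length(byc[[cc]]),
                       stringsAsFactors = FALSE),
            as.data.frame(t(colMeans(per_line[byc[[cc]], -1L], na.rm = TRUE))))
    }))
    rownames(out$per_cross) <- NULL
  }
  class(out) <- "contribution_summary"
  out
}

#' @export
print.contribution_summary <- function(x, ...) {
  p <- x$panel
  cat(sprintf(paste0(
    "contribution_summary over %d lines:\n",
    "  raw: A %.1f%%  B %.1f%%  H %.1f%%  U %.1f%%  missing %.1f%%\n",
    "  renormalized: exotic %.1f%%  elite %.1f%%\n"),
    nrow(x$per_line), 100 * p$frac_A, 100 * p$frac_B, 100 * p$frac_H,
    100 * p$frac_U, 100 * p$frac_missing,
    100 * p$exotic_est, 100 * p$elite_est))
  invisible(x)
}

#' Identify exotic-specific haplotype blocks
#'
#' A block found on the derived-line panel is exotic-specific when at least
#' one of its observed haplotype classes is present in the exotic parent
#' panel and absent from every elite parent (`rule = "presence"`); with
#' `rule = "majority"` the test is applied to the block's most frequent
#' class only. Presence in a panel means at least one assigned line carries
#' the class.
#'
#' @param blocks blocks from [find_blocks()] on the derived-line panel
#' @param G_pbl,G_exotic,G_elite genotype panels of derived lines, exotic
#'   parents and elite parents (all containing the block markers)
#' @param rule specificity rule (see above)
#' @return list with `flags` (named logical over blocks), `blocks` (the
#'   exotic-specific subset), `imprint_fraction` (specific / total), and
#'   `detail` (per block, the exotic-private classes found).
#' @export
exotic_specific_blocks <- function(blocks, G_pbl, G_exotic, G_elite,
                                   rule = c("presence", "majority")) {
  rule <- match.arg(rule)
  if (nrow(G_elite$calls) == 0L)
    stop("empty elite panel: exotic specificity undefined")
  flags <- logical(length(blocks))
  detail <- vector("list", length(blocks))
  nm <- vapply(blocks, `[[`, "", "name")
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    pbl_classes <- names(assign_classes(b, G_pbl)$class_freq)
    if (rule == "majority" && length(pbl_classes))
      pbl_classes <- pbl_classes[1L]
    exo <- names(assign_classes(b, G_exotic)$class_freq)
    eli <- names(assign_classes(b, G_elite)$class_freq)
    private <- intersect(pbl_classes, setdiff(exo, eli))
    flags[k] <- length(private) > 0L
    detail[[k]] <- private
  }
  names(flags) <- names(detail) <- nm
  out_blocks <- blocks[flags]
  class(out_blocks) <- "hap_block_list"
  list(flags = flags, blocks = out_blocks,
       imprint_fraction = if (length(blocks)) mean(flags) else NA_real_,
       detail = detail)
}

#' Compare two haplotype-block maps
#'
#' For each block of panel `a`, lists the blocks of panel `b` whose cM
#' intervals intersect on the same chromosome, with shared-marker counts,
#' plus per-panel count and mean-span summaries.
#'
#' @param blocks_a,blocks_b two block sets on the same genetic map
#' @return list with `overlaps` (data.frame: `a_name`, `b_name`, `chrom`,
#'   `a_span`, `b_span`, `overlap_cM`, `shared_markers`) and `summary`
#'   (per-panel block count and mean span).
#' @export
compare_block_maps <- function(blocks_a, blocks_b) {
  rows <- list()
  for (a in blocks_a) {
    for (b in blocks_b) {
      if (a$chrom != b$chrom) next
      lo <- max(a$start_cM, b$start_cM); hi <- min(a$end_cM, b$end_cM)
      if (lo > hi) next
      rows[[length(rows) + 1L]] <- data.frame(
        a_name = a$name, b_name = b$name, chrom = a$chrom,
        a_span = a$span, b_span = b$span, overlap_cM = hi - lo,
        shared_markers = length(intersect(a$markers, b$markers)),
        stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_name = character(), b_name = character(), chrom = character(),
               a_span = numeric(), b_span = numeric(), overlap_cM = numeric(),
               shared_markers = integer(), stringsAsFactors = FALSE)
  span <- function(bl) vapply(bl, `[[`, 1, "span")
  summary <- data.frame(
    panel = c("a", "b"),
    n_blocks = c(length(blocks_a), length(blocks_b)),
    mean_span = c(if (length(blocks_a)) mean(span(blocks_a)) else NA_real_,
                  if (length(blocks_b)) mean(span(blocks_b)) else NA_real_))
  list(overlaps = overlaps, summary = summary)
}
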