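#' Haplotype-block construction by the confidence-interval D-prime rule
#'
#' Evaluates every marker pair within `ld_window` cM, classifies each pair
#' as strong LD / strong recombination / inconclusive from the D-prime
#' confidence bounds, and accepts a run of consecutive markers as a block
#' when at least 95% of its informative (non-inconclusive) pairs are in
#' strong LD. Accepted candidates are ranked by marker count (ties: cM span,
#' then leftmost) and taken greedily without overlap. Blocks are named
#' `HB<chromosome index>.<rank>` with ranks incrementing left to right along
#' each chromosome (1 = 1A, 2 = 1B, ..., 21 = 7D). Singleton markers form no
#' block.
#'
#' @param G a QC-filtered `geno_matrix` (see [qc_filter()])
#' @param map the matching filtered `genetic_map`
#' @param params a [qc_params()] (supplies `ld_window`)
#' @param strong_frac_min minimum fraction of informative pairs in strong LD
#'   (default 0.95)
#' @param ... passed to [dprime_ci()] (CI bounds, recombination bound)
#' @return list of blocks (class `hap_block_list`); each block is a list
#'   with `name`, `chrom`, `chrom_idx`, `markers`, `start_cM`, `end_cM`,
#'   `span`, `assignments` (named per-line class strings, `NA` for
#'   heterozygous/missing lines) and `class_freq` (named frequencies over
#'   assigned lines).
#' @export
find_blocks <- function(G, map, params = qc_params(), strong_frac_min = 0.95,
                        ...) {
  if (ncol(G$calls) == 0L) {
    out <- list(); class(out) <- "hap_block_list"; return(out)
  }
  stopifnot(all(map$marker %in% marker_ids(G)))
  blocks <- list()
  for (ci in unique(map$chrom_idx)) {
    cm <- map[map$chrom_idx == ci, , drop = FALSE]
    mk <- cm$marker; pos <- cm$cM
    nm <- length(mk)
    if (nm < 2L) next
    # classify pairs within the window (upper triangle only)
    cls <- matrix(NA_character_, nm, nm)
    for (i in seq_len(nm - 1L)) {
      for (j in (i + 1L):nm) {
        if (pos[j] - pos[i] > params$ld_window) break
        cls[i, j] <- pair_ld(G, mk[i], mk[j], ...)$classification
      }
    }
    # candidate intervals: spans within the window
    cand <- list()
    for (i in seq_len(nm - 1L)) {
      for (j in (i + 1L):nm) {
        if (pos[j] - pos[i] > params$ld_window) break
        sub <- cls[i:j, i:j]
        pc <- sub[upper.tri(sub)]
        n_strong <- sum(pc == "strong_LD", na.rm = TRUE)
        n_inf <- n_strong + sum(pc == "strong_recombination", na.rm = TRUE)
        if (n_inf >= 1L && n_strong / n_inf >= strong_frac_min)
          cand[[length(cand) + 1L]] <-
            list(i = i, j = j, size = j - i + 1L, span = pos[j] - pos[i])
      }
    }
    if (!length(cand)) next
    ord <- order(-vapply(cand, `[[`, 1L, "size"),
                 -vapply(cand, `[[`, 1, "span"),
                 vapply(cand, `[[`, 1L, "i"))
    taken <- rep(FALSE, nm)
    chosen <- list()
    for (k in ord) {
      cc <- cand[[k]]
      if (any(taken[cc$i:cc$j])) next
      taken[cc$i:cc$j] <- TRUE
      chosen[[length(chosen) + 1L]] <- cc
    }
    chosen <- chosen[order(vapply(chosen, `[[`, 1L, "i"))]
    for (r in seq_along(chosen)) {
      cc <- chosen[[r]]
      b <- list(name = sprintf("HB%d.%d", ci, r),
                chrom = cm$chrom[1L], chrom_idx = ci,
                markers = mk[cc$i:cc$j],
                start_cM = pos[cc$i], end_cM = pos[cc$j], span = cc$span)
      ac <- assign_classes(b, G)
      b$assignments <- ac$assignments
      b$class_freq <- ac$class_freq
      class(b) <- "hap_block"
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  class(blocks) <- "hap_block_list"
  blocks
}

#' @export
print.hap_block <- function(x, ...) {
  cat(sprintf("%s (%s, %.2f-%.2f cM, %d markers): %s\n", x$name, x$chrom,
              x$start_cM, x$end_cM, length(x$markers),
              paste(sprintf("%s %.1f%%", names(x$class_freq),
                            100 * x$class_freq), collapse = ", ")))
  invisible(x)
}

#' @export
print.hap_block_list <- function(x, ...) {
  cat(sprintf("hap_block_list: %d blocks on %d chromosome(s)\n", length(x),
              length(unique(vapply(x, `[[`, 1L, "chrom_idx")))))
  for (b in head(x, 10L)) print(b)
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

#' Assign per-line haplotype classes for a block
#'
#' A line fully homozygous at every member marker gets the allele string of
#' its haplotype (e.g. `"GT"`); lines heterozygous or missing at any member
#' marker get `NA`. Class frequencies are computed over assigned lines.
#'
#' @param block a block (needs `markers`) from [find_blocks()], or a list
#'   with a `markers` field
#' @param G a `geno_matrix` containing the member markers
#' @return list with `assignments` (named character vector over lines) and
#'   `class_freq` (named numeric, sums to 1 over assigned lines).
#' @export
assign_classes <- function(block, G) {
  mks <- block$markers
  absent <- setdiff(mks, marker_ids(G))
  if (length(absent))
    stop("block marker(s) absent from panel: ", paste(absent, collapse = ", "))
  letters_mat <- vapply(mks, function(m)
    call_to_allele(G$calls[, m], G$alleles[m, ]), character(nrow(G$calls)))
  if (is.null(dim(letters_mat)))
    letters_mat <- matrix(letters_mat, nrow = 1L)
  cls <- apply(letters_mat, 1L, function(r)
    if (anyNA(r)) NA_character_ else paste(r, collapse = ""))
  names(cls) <- line_ids(G)
  tab <- table(cls[!is.na(cls)])
  freq <- if (length(tab)) as.numeric(tab) / sum(tab) else numeric(0)
  names(freq) <- names(tab)
  freq <- sort(freq, decreasing = TRUE)
  list(assignments = cls, class_freq = freq)
}

#' Multi-allelic D-prime between two haplotype blocks
#'
#' Treats each block as a multi-allelic locus (alleles = haplotype classes)
#' and returns the frequency-weighted average of the absolute two-by-two
#' D-prime over all class pairs: sum over i, j of p_i q_j |D'_ij|, where
#' each D'_ij collapses the joint class table to class-i-vs-rest by
#' class-j-vs-rest. Values near 1 indicate no effective recombination
#' between the blocks.
#'
#' @param blockA,blockB blocks on the same chromosome
#' @param G a `geno_matrix`; lines assigned in both blocks are used
#' @return value in [0, 1], or `NA` when either block shows fewer than two
#'   classes among the jointly assigned lines (degenerate).
#' @export
multiallelic_dprime <- function(blockA, blockB, G) {
  a <- assign_classes(blockA, G)$assignments
  b <- assign_classes(blockB, G)$assignments
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  ca <- sort(unique(a)); cb <- sort(unique(b))
  if (length(ca) < 2L || length(cb) < 2L) return(NA_real_)
  n <- length(a)
  joint <- table(factor(a, ca), factor(b, cb)) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  total <- 0
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      pij <- joint[i, j]
      D <- pij - pa[i] * pb[j]
      Dmax <- if (D >= 0) min(pa[i] * (1 - pb[j]), (1 - pa[i]) * pb[j]) else
        min(pa[i] * pb[j], (1 - pa[i]) * (1 - pb[j]))
      if (Dmax > 0)
        total <- total + pa[i] * pb[j] * min(1, abs(D) / Dmax)
    }
  }
  as.numeric(total)
}
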