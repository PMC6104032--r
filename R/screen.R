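#' Per-class trait profiles for haplotype blocks
#'
#' Arithmetic class means per trait-environment cell, the class frequency
#' among assigned lines, and the difference against the best other class
#' (positive = this class leads). Classes with fewer than `min_n` lines in
#' a cell are reported but flagged low-support, and are excluded from the
#' "best other class" comparison so that one or two outlier lines cannot
#' mask or fake a difference.
#'
#' @param blocks a `hap_block_list`
#' @param G panel `geno_matrix`
#' @param traits a [trait_table()]
#' @param min_n low-support threshold (default 3)
#' @return data.frame of class `class_profiles`: `block`, `class`,
#'   `freq_pct`, `trait`, `env`, `mean`, `n`, `diff_vs_best_other`,
#'   `diff_vs_ref` / `se_vs_ref` (difference against the block's most
#'   frequent class and its standard error), `low_support`.
#' @export
class_profiles <- function(blocks, G, traits, min_n = 3L) {
  cells <- unique(traits[, c("trait", "env")])
  rows <- list()
  for (b in blocks) {
    ac <- assign_classes(b, G)
    cls <- ac$assignments
    for (r in seq_len(nrow(cells))) {
      tr <- cells$trait[r]; ev <- cells$env[r]
      tt <- traits[traits$trait == tr & traits$env == ev, ]
      val <- setNames(tt$value, tt$line)[names(cls)]
      ok <- !is.na(cls) & !is.na(val)
      if (!any(ok)) next
      mu <- tapply(val[ok], cls[ok], mean)
      nn <- tapply(val[ok], cls[ok], length)
      s2 <- tapply(val[ok], cls[ok], var)
      supported <- names(nn)[nn >= min_n]
      ref <- names(ac$class_freq)[1L]   # most frequent class
      for (cl in names(ac$class_freq)) {
        if (!cl %in% names(mu)) next
        others <- mu[setdiff(supported, cl)]
        se_ref <- if (cl != ref && ref %in% names(mu) &&
                      !is.na(s2[[cl]]) && !is.na(s2[[ref]]))
          sqrt(s2[[cl]] / nn[[cl]] + s2[[ref]] / nn[[ref]]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          block = b$name, class = cl,
          freq_pct = 100 * ac$class_freq[[cl]],
          trait = tr, env = ev,
          mean = as.numeric(mu[[cl]]), n = as.integer(nn[[cl]]),
          diff_vs_best_other = if (length(others))
            as.numeric(mu[[cl]] - max(others)) else NA_real_,
          diff_vs_ref = if (cl != ref && ref %in% names(mu))
            as.numeric(mu[[cl]] - mu[[ref]]) else NA_real_,
          se_vs_ref = as.numeric(se_ref),
          low_support = nn[[cl]] < min_n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(), class = character(), freq_pct = numeric(),
               trait = character(), env = character(), mean = numeric(),
               n = integer(), diff_vs_best_other = numeric(),
               diff_vs_ref = numeric(), se_vs_ref = numeric(),
               low_support = logical(), stringsAsFactors = FALSE)
  class(out) <- c("class_profiles", "data.frame")
  out
}

#' Screen for rare favorable haplotypes
#'
#' A (block, class) pair is a candidate when: the class is rare (frequency
#' at or below `rare_max`); the block is significant for the target trait
#' in at least `min_instances` environments of the scan; the block is not
#' significant for the confounder trait (days to heading by default —
#' blocks whose apparent stress advantage works through earliness are
#' excluded); the class leads the trait mean in at least one significant
#' environment; and no environment shows a penalty. A penalty is declared
#' when the class mean falls below the block's reference (most frequent)
#' class by more than `penalty_tol` trait standard deviations AND the
#' deficit is distinguishable from sampling noise (two standard errors of
#' the class-mean difference) — raw class means at modest carrier counts
#' would otherwise flag spurious penalties.
#' Candidates are ranked by favorable-instance count, then best p-value,
#' then the observed favorable margin over the reference class.
#'
#' @param profiles output of [class_profiles()]
#' @param scan an `association_scan` from [scan_features()] covering the
#'   target and confounder traits
#' @param traits the [trait_table()] (supplies per-environment trait SDs
#'   for the penalty tolerance)
#' @param target_trait trait the candidate must help
#' @param confounder_trait phenology trait whose association disqualifies a
#'   block (default `"days_to_heading"`); its scan must be present
#' @param rare_max rarity threshold on class frequency (default 0.15)
#' @param min_instances minimum significant environments (default 1)
#' @param penalty_tol penalty tolerance in trait SDs (default 0.25)
#' @param exotic_flags optional named logical from
#'   [exotic_specific_blocks()] attached as provenance
#' @return data.frame of class `rare_screen`, ranked; zero rows when
#'   nothing qualifies.
#' @export
screen_rare_favorable <- function(profiles, scan, traits, target_trait,
                                  confounder_trait = "days_to_heading",
                                  rare_max = 0.15, min_instances = 1L,
                                  penalty_tol = 0.25, exotic_flags = NULL) {
  if (!any(scan$trait == confounder_trait))
    stop("scan results for confounder trait '", confounder_trait,
         "' are required")
  empty <- data.frame(block = character(), class = character(),
                      freq_pct = numeric(), n_favorable = integer(),
                      n_significant = integer(), best_p = numeric(),
                      margin = numeric(),
                      favorable_envs = character(), penalty_envs = character(),
                      exotic_specific = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("rare_screen", "data.frame")
  tgt <- scan[scan$trait == target_trait, , drop = FALSE]
  if (!nrow(tgt)) return(empty)
  conf_blocks <- unique(scan$feature[scan$trait == confounder_trait &
                                       scan$significant])
  sds <- tapply(traits$value[traits$trait == target_trait],
                traits$env[traits$trait == target_trait], sd, na.rm = TRUE)
  pr <- profiles[profiles$trait == target_trait, , drop = FALSE]
  out <- list()
  for (key in unique(paste(pr$block, pr$class, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1L]]
    bn <- parts[1L]; cl <- parts[2L]
    sub <- pr[pr$block == bn & pr$class == cl, , drop = FALSE]
    freq <- sub$freq_pct[1L] / 100
    if (freq > rare_max) next
    if (any(sub$low_support)) next   # too few carriers to characterize
    if (bn %in% conf_blocks) next
    sig <- tgt[tgt$feature == bn & tgt$significant, , drop = FALSE]
    if (nrow(sig) < min_instances) next
    fav <- character(0); pen <- character(0)
    for (r in seq_len(nrow(sub))) {
      ev <- sub$env[r]; d <- sub$diff_vs_best_other[r]
      tol <- penalty_tol * (if (ev %in% names(sds)) sds[[ev]] else
        sd(traits$value[traits$trait == target_trait], na.rm = TRUE))
      dref <- sub$diff_vs_ref[r]; seref <- sub$se_vs_ref[r]
      if (!is.na(dref) && dref < -tol &&
          (is.na(seref) || dref < -2 * seref)) pen <- c(pen, ev)
      if (!is.na(d) && d > 0 && ev %in% sig$env) fav <- c(fav, ev)
    }
    if (!length(fav) || length(pen)) next
    margin <- suppressWarnings(max(sub$diff_vs_ref[sub$env %in% fav],
                                   na.rm = TRUE))
    if (!is.finite(margin)) margin <- 0
    out[[length(out) + 1L]] <- data.frame(
      block = bn, class = cl, freq_pct = sub$freq_pct[1L],
      n_favorable = length(fav), n_significant = nrow(sig),
      best_p = min(sig$p), margin = margin,
      favorable_envs = paste(fav, collapse = ";"),
      penalty_envs = "",
      exotic_specific = if (!is.null(exotic_flags) && bn %in% names(exotic_flags))
        exotic_flags[[bn]] else NA,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$n_favorable, res$best_p, -res$margin, res$block),
             , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("rare_screen", "data.frame")
  res
}

#' Significance consistency matrix
#'
#' Features in rows, (trait, environment) instances in columns, cells
#' marked where the scan calls the association significant; row sums count
#' a feature's significant instances across the design.
#'
#' @param scan an `association_scan`
#' @return list of class `consistency_matrix`: `matrix` (logical), and
#'   `row_sums`.
#' @export
consistency_matrix <- function(scan) {
  if (!nrow(scan)) stop("empty scan results")
  inst <- unique(paste(scan$trait, scan$env, sep = "/"))
  feats <- unique(scan$feature)
  m <- matrix(FALSE, length(feats), length(inst),
              dimnames = list(feats, inst))
  key <- paste(scan$trait, scan$env, sep = "/")
  for (r in seq_len(nrow(scan)))
    if (isTRUE(scan$significant[r]))
      m[scan$feature[r], key[r]] <- TRUE
  structure(list(matrix = m, row_sums = rowSums(m)),
            class = "consistency_matrix")
}

#' @export
print.consistency_matrix <- function(x, ...) {
  cat(sprintf("consistency_matrix: %d features x %d instances, %d significant cells\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  top <- sort(x$row_sums, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  top features:",
        paste(sprintf("%s (%d)", names(head(top, 5L)), head(top, 5L)),
              collapse = ", "), "\n")
  invisible(x)
}
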