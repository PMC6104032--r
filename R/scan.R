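#' Empirical significance threshold from a p-value distribution
#'
#' The bottom `percentile` percent of the supplied p-values (default 0.1,
#' i.e. the 0.001 quantile, taken as the smallest order statistic covering
#' that mass). A fixed threshold (for instance 0.001 for yield traits or
#' 0.0001 for disease traits) can be configured in [scan_features()]
#' instead.
#'
#' @param pvalues numeric vector of p-values
#' @param percentile bottom percentile, in percent (default 0.1)
#' @return the threshold p-value.
#' @export
empirical_threshold <- function(pvalues, percentile = 0.1) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values supplied")
  need <- ceiling(100 / percentile)
  if (length(pvalues) < need)
    warning("fewer than ", need, " tests: the ", percentile,
            " percentile threshold is coarse")
  as.numeric(quantile(pvalues, percentile / 100, type = 1, names = FALSE))
}

#' Quantile-quantile deviation flags and genomic inflation factor
#'
#' Compares observed p-values with uniform expectation. A feature deviates
#' when its observed p-value falls below the lower 95% pointwise band of
#' the corresponding uniform order statistic (Beta(i, n - i + 1)); in the
#' two-condition significance rule a feature must both pass the threshold
#' and deviate here. Also returns the genomic inflation factor lambda
#' (median chi-square ratio).
#'
#' @param pvalues numeric p-values (at least 20)
#' @return list: `deviates` (logical, input order), `lambda`, and `table`
#'   (sorted expected/observed quantiles with the band, plot-ready).
#' @export
qq_deviation <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  n <- length(p)
  if (n < 20L) stop("qq_deviation needs at least 20 tests")
  ord <- order(p)
  ranks <- integer(n); ranks[ord] <- seq_len(n)
  band_low <- qbeta(0.05, ranks, n - ranks + 1)
  dev <- p < band_low
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
  i <- seq_len(n)
  tab <- data.frame(expected = i / (n + 1), observed = p[ord],
                    band_low = qbeta(0.05, i, n - i + 1))
  out <- rep(NA, length(pvalues))
  out[ok] <- dev
  list(deviates = out, lambda = as.numeric(lambda), table = tab)
}

#' Haplotype-block / SNP association scan across traits and environments
#'
#' For each (trait, environment) cell: aligns the phenotype to the panel,
#' picks the number of PC covariates by BIC, fits the null mixed model
#' (kinship random effect) by REML, then tests every feature by P3D
#' generalized least squares. Significance follows the two-condition rule:
#' p at or below the scan threshold (empirical bottom-percentile by
#' default, or a fixed per-trait value) AND deviation from the uniform
#' quantiles in the QQ sense.
#'
#' Features are tested against a leave-one-chromosome-out (LOCO) kinship by
#' default: the tested feature's chromosome is excluded from the
#' relationship matrix so that the polygenic correction cannot absorb the
#' tested effect (proximal contamination). Set `loco = FALSE` to use the
#' single global kinship everywhere. PC covariates are always selected
#' against the global kinship.
#'
#' @param features a `hap_block_list` from [find_blocks()], or a character
#'   vector of marker ids for single-SNP tests
#' @param G panel `geno_matrix`
#' @param traits a [trait_table()]
#' @param map `genetic_map`; required for LOCO (locates each feature's
#'   chromosome)
#' @param loco use leave-one-chromosome-out kinship (default TRUE when a
#'   map is supplied)
#' @param k_max maximum number of PC covariates considered (default 5)
#' @param threshold `NULL` for the empirical bottom-percentile threshold, a
#'   single number, or a named numeric vector by trait (e.g.
#'   `c(yield = 1e-3, rust = 1e-4)`)
#' @param percentile bottom percentile for the empirical threshold
#' @param pool_below rare-class pooling threshold for block designs
#' @return data.frame of class `association_scan`: one row per
#'   feature x trait x environment with `p`, `df`, `n_used`, `effects`
#'   (class:effect pairs), `threshold`, `qq_deviates`, `significant`;
#'   attribute `lambda` holds the per-scan genomic inflation factors.
#' @export
scan_features <- function(features, G, traits, map = NULL,
                          loco = !is.null(map), k_max = 5L,
                          threshold = NULL, percentile = 0.1,
                          pool_below = 0.01) {
  if (loco && is.null(map))
    stop("LOCO testing needs a genetic map")
  is_blocks <- inherits(features, "hap_block_list") ||
    (is.list(features) && length(features) && !is.character(features))
  feat_chrom <- if (!loco) NULL else if (is_blocks) {
    as.character(vapply(features, `[[`, 1L, "chrom_idx"))
  } else {
    as.character(map$chrom_idx[match(features, map$marker)])
  }
  cells <- unique(traits[, c("trait", "env")])
  all_lines <- line_ids(G)
  rows <- list()
  lambdas <- c()
  panel_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(cells))) {
    tr <- cells$trait[r]; ev <- cells$env[r]
    tt <- traits[traits$trait == tr & traits$env == ev, ]
    y_all <- setNames(tt$value, tt$line)[all_lines]
    use <- !is.na(y_all)
    lines <- all_lines[use]
    y <- y_all[use]
    # kinship and eigendecompositions depend only on the line subset
    key <- paste(lines, collapse = "\r")
    cache_id <- as.character(sum(utf8ToInt(substr(key, 1, 10000))) +
                               nchar(key))
    panel <- if (!is.null(panel_cache[[cache_id]]) &&
                 identical(panel_cache[[cache_id]]$lines, lines)) {
      panel_cache[[cache_id]]
    } else {
      Gs <- subset_geno(G, lines = lines)
      Ks <- if (loco) kinship_loco(Gs, map) else list(all = kinship(Gs))
      eigs <- lapply(Ks, eigen, symmetric = TRUE)
      p <- list(lines = lines, Gs = Gs, Ks = Ks, eigs = eigs)
      panel_cache[[cache_id]] <- p
      p
    }
    Gs <- panel$Gs
    k_opt <- select_pcs_bic(y, Gs, panel$Ks$all, k_max = k_max,
                            eig = panel$eigs$all)$k_opt
    X <- cbind(`(Intercept)` = rep(1, length(y)),
               pca_covariates(Gs, k_opt))
    fits <- lapply(names(panel$Ks), function(nm)
      fit_null_mlm(y, X, panel$Ks[[nm]], eig = panel$eigs[[nm]]))
    names(fits) <- names(panel$Ks)
    res <- list()
    for (k in seq_along(features)) {
      knm <- if (loco && feat_chrom[k] %in% names(fits)) feat_chrom[k] else "all"
      fit <- fits[[knm]]
      Kk <- panel$Ks[[knm]]
      if (is_blocks) {
        b <- features[[k]]
        D <- block_design(b, Gs, pool_below = pool_below)
        t1 <- test_feature(fit, Kk, D)
        eff <- if (length(t1$effects))
          paste(sprintf("%s:%.6g", sub("^class_", "", names(t1$effects)),
                        t1$effects), collapse = ";") else ""
        fid <- b$name
      } else {
        m <- features[k]
        D <- matrix(as.numeric(Gs$calls[, m]), ncol = 1L,
                    dimnames = list(lines, m))
        t1 <- test_feature(fit, Kk, D)
        eff <- if (length(t1$effects))
          sprintf("%s:%.6g", m, t1$effects[1L]) else ""
        fid <- m
      }
      res[[length(res) + 1L]] <- data.frame(
        feature = fid, trait = tr, env = ev, p = t1$p, df = t1$df,
        n_used = t1$n_used, effects = eff, degenerate = t1$degenerate,
        stringsAsFactors = FALSE)
    }
    scan <- do.call(rbind, res)
    thr <- if (is.null(threshold)) {
      empirical_threshold(scan$p[!scan$degenerate], percentile)
    } else if (length(threshold) > 1L || !is.null(names(threshold))) {
      if (!tr %in% names(threshold))
        stop("no threshold configured for trait ", tr)
      threshold[[tr]]
    } else threshold
    scan$threshold <- thr
    if (sum(!scan$degenerate) >= 20L) {
      qq <- qq_deviation(ifelse(scan$degenerate, NA, scan$p))
      scan$qq_deviates <- !is.na(qq$deviates) & qq$deviates
      lambdas[paste(tr, ev, sep = "/")] <- qq$lambda
    } else {
      scan$qq_deviates <- TRUE   # too few tests for a band; threshold rules
      lambdas[paste(tr, ev, sep = "/")] <- NA_real_
    }
    scan$significant <- !scan$degenerate & scan$p <= thr & scan$qq_deviates
    rows[[length(rows) + 1L]] <- scan
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lambda") <- lambdas
  class(out) <- c("association_scan", "data.frame")
  out
}
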