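#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic markers
#' from unphased diploid dosages. All genotype configurations except the
#' double heterozygote are phase-known and counted directly; double
#' heterozygotes are split between the coupling and repulsion phases by EM.
#' Allele "A"/"B" denote the dosage-0 allele at the first/second locus.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) over the same lines; lines missing
#'   either call are dropped
#' @param tol convergence tolerance on the frequency change (default 1e-8)
#' @param max_iter maximum EM iterations (default 1000)
#' @return list with `freqs` (named: `p_AB`, `p_Ab`, `p_aB`, `p_ab`),
#'   `n_gametes`, `converged`, and `low_information` (TRUE when every
#'   informative line is a double heterozygote, leaving the phase split
#'   undetermined by the data).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 1L) stop("no pairwise-complete lines")
  # phase-known gamete counts
  cnt <- function(a, b) sum(g1 == a & g2 == b)
  k_AB <- 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0)
  k_Ab <- 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2)
  k_aB <- 2 * cnt(2, 0) + cnt(1, 0) + cnt(2, 1)
  k_ab <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)
  n_dh <- cnt(1, 1)
  tot <- 2 * n
  p <- rep(0.25, 4)
  converged <- TRUE
  if (n_dh == 0L) {
    p <- c(k_AB, k_Ab, k_aB, k_ab) / tot
  } else {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      num <- p[1] * p[4]
      den <- num + p[2] * p[3]
      w <- if (den > 0) num / den else 0.5
      p_new <- c(k_AB + w * n_dh, k_Ab + (1 - w) * n_dh,
                 k_aB + (1 - w) * n_dh, k_ab + w * n_dh) / tot
      if (max(abs(p_new - p)) < tol) { p <- p_new; converged <- TRUE; break }
      p <- p_new
    }
  }
  list(freqs = setNames(p, c("p_AB", "p_Ab", "p_aB", "p_ab")),
       n_gametes = tot, converged = converged,
       low_information = n_dh > 0 && (k_AB + k_Ab + k_aB + k_ab) == 0)
}

#' D-prime with profile-likelihood confidence bounds
#'
#' Computes D, D-prime and a 95% confidence interval from the profile
#' multinomial likelihood over a grid of D-prime values (allele frequencies
#' held at their estimates, sign of D fixed), with bounds at the 5th and
#' 95th percentiles of the normalized likelihood mass. Pairs are classified
#' Gabriel-style: strong LD when the upper bound exceeds `strong_high` and
#' the lower bound exceeds `strong_low`; strong recombination when the upper
#' bound falls below `recomb_bound`; otherwise inconclusive.
#'
#' @param freqs haplotype frequencies as returned by [em_haplotype_freqs()]
#' @param n_gametes number of gametes behind the estimate
#' @param strong_low,strong_high strong-LD bounds on the CI (defaults 0.70
#'   and 0.98)
#' @param recomb_bound strong-recombination bound on the upper CI
#'   (default 0.90)
#' @param grid_points D-prime grid density (default 101)
#' @return list of class `pair_ld`: `D`, `dprime`, `ci_low`, `ci_high`,
#'   `classification` (one of `"strong_LD"`, `"strong_recombination"`,
#'   `"inconclusive"`, or `"degenerate"` for a monomorphic pair),
#'   `n_gametes`, `freqs`.
#' @export
dprime_ci <- function(freqs, n_gametes, strong_low = 0.70, strong_high = 0.98,
                      recomb_bound = 0.90, grid_points = 101L) {
  if (n_gametes < 2) stop("need at least 2 gametes")
  p <- as.numeric(freqs)
  if (abs(sum(p) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  D <- p[1] - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  out <- list(D = D, dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              classification = "degenerate", n_gametes = n_gametes,
              freqs = setNames(p, c("p_AB", "p_Ab", "p_aB", "p_ab")))
  class(out) <- "pair_ld"
  if (Dmax <= 0) return(out)
  out$dprime <- min(1, abs(D) / Dmax)
  grid <- seq(0, 1, length.out = grid_points)
  counts <- n_gametes * p
  s <- if (D >= 0) 1 else -1
  Di <- s * grid * Dmax
  f <- rbind(pA * pB + Di, pA * (1 - pB) - Di,
             (1 - pA) * pB - Di, (1 - pA) * (1 - pB) + Di)
  f[f < 0] <- 0
  lf <- log(f)
  lf[f == 0] <- 0
  ll <- colSums(counts * lf)
  ll[colSums(f == 0 & counts > 1e-9) > 0] <- -Inf
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  out$ci_low <- grid[which(cw >= 0.05)[1L]]
  out$ci_high <- grid[which(cw >= 0.95)[1L]]
  out$classification <-
    if (out$ci_high > strong_high && out$ci_low > strong_low) "strong_LD"
    else if (out$ci_high < recomb_bound) "strong_recombination"
    else "inconclusive"
  out
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("pair_ld: D' = %.3f [%.2f, %.2f] (%s, %d gametes)\n",
              x$dprime, x$ci_low, x$ci_high, x$classification, x$n_gametes))
  invisible(x)
}

# EM + CI for one marker pair of a panel
pair_ld <- function(G, m1, m2, ...) {
  em <- em_haplotype_freqs(G$calls[, m1], G$calls[, m2])
  dprime_ci(em$freqs, em$n_gametes, ...)
}
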