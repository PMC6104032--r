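#' Genomic relationship (kinship) matrix
#'
#' VanRaden centered-dosage cross-product: missing calls are imputed to the
#' marker mean (for this computation only), dosages are centered at twice
#' the allele frequency, and K = WW' / (2 sum p(1-p)). The diagonal is
#' approximately 1 + f for inbreeding coefficient f.
#'
#' @param G a `geno_matrix` with at least 2 markers
#' @return n x n symmetric positive semi-definite matrix with line ids as
#'   dimnames.
#' @export
kinship <- function(G) {
  X <- impute_marker_mean(G)
  if (ncol(X) < 2L) stop("kinship needs at least 2 markers")
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: kinship undefined")
  W <- sweep(X, 2L, 2 * p)
  K <- tcrossprod(W) / denom
  (K + t(K)) / 2
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome, the VanRaden kinship computed from all markers NOT
#' on that chromosome. Used by the association scan so that the tested
#' feature's own chromosome does not contribute to the polygenic
#' correction (proximal contamination would otherwise absorb part of the
#' tested effect). Computed by subtracting per-chromosome cross-products
#' from the global one, so the cost is one pass over the markers.
#'
#' @param G a `geno_matrix`
#' @param map a `genetic_map` covering the markers of `G`
#' @return named list of kinship matrices, one per chromosome index
#'   present in `map`, plus the global matrix under `"all"`.
#' @export
kinship_loco <- function(G, map) {
  X <- impute_marker_mean(G)
  if (ncol(X) < 2L) stop("kinship needs at least 2 markers")
  p <- colMeans(X) / 2
  W <- sweep(X, 2L, 2 * p)
  d_all <- 2 * sum(p * (1 - p))
  if (d_all <= 0) stop("all markers monomorphic: kinship undefined")
  C_all <- tcrossprod(W)
  chroms <- unique(map$chrom_idx)
  out <- list(all = (C_all + t(C_all)) / (2 * d_all))
  for (ci in chroms) {
    mk <- intersect(map$marker[map$chrom_idx == ci], colnames(W))
    if (!length(mk)) { out[[as.character(ci)]] <- out$all; next }
    Wc <- W[, mk, drop = FALSE]
    dc <- 2 * sum(p[mk] * (1 - p[mk]))
    if (d_all - dc <= 0) { out[[as.character(ci)]] <- out$all; next }
    Kc <- (C_all - tcrossprod(Wc)) / (d_all - dc)
    out[[as.character(ci)]] <- (Kc + t(Kc)) / 2
  }
  out
}

# dosage matrix with missing imputed to the marker mean
impute_marker_mean <- function(G) {
  X <- G$calls
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2L]]
  X
}

#' Principal-component covariates for population structure
#'
#' PCA of the mean-imputed, centered dosage matrix. Column signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param G a `geno_matrix`
#' @param k number of components (`k = 0` gives a zero-column matrix; must
#'   be `< n` lines)
#' @return n x k score matrix with line ids as rownames.
#' @export
pca_covariates <- function(G, k) {
  n <- nrow(G$calls)
  if (k >= n) stop("k must be smaller than the number of lines")
  if (k == 0L)
    return(matrix(numeric(0), n, 0L, dimnames = list(line_ids(G), NULL)))
  X <- impute_marker_mean(G)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  rownames(scores) <- line_ids(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# spectral profile likelihood of the variance ratio lambda = sg2/se2.
# Returns the ML or REML log-likelihood maximized analytically over the
# scale, for fixed lambda, after rotation by the eigenvectors of K.
mlm_profile <- function(log_lambda, Uy, UX, d, reml = FALSE) {
  lambda <- exp(log_lambda)
  w <- lambda * d + 1
  sw <- 1 / sqrt(w)
  Xw <- UX * sw
  yw <- Uy * sw
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  n <- length(yw); p <- ncol(UX)
  if (rss < 1e-300) return(list(ll = Inf, beta = beta, rss = rss))
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                    2 * sum(log(abs(diag(qr.R(qr_x))))) + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  }
  list(ll = ll, beta = beta, rss = rss, s2 = s2)
}

#' Fit the null mixed linear model
#'
#' Random-effect covariance proportional to the kinship matrix, estimated by
#' the spectral reparameterization: one eigendecomposition of K, then
#' one-dimensional optimization of the variance ratio with O(n) likelihood
#' evaluations. Both ML (for BIC comparisons across fixed-effect
#' structures) and REML (for testing) variance components are returned.
#'
#' @param y numeric trait vector (no missing values)
#' @param X fixed-effect design matrix (full rank, including intercept)
#' @param K kinship matrix aligned with `y`
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`
#' @return object of class `mlm_fit`: variance components (`sigma_g2`,
#'   `sigma_e2` from REML; `_ml` variants), `lambda` (REML ratio), log
#'   likelihoods, `beta`, `h2`, and the rotation (`U`, `d`) for reuse.
#' @export
fit_null_mlm <- function(y, X, K, eig = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y) || any(!is.finite(y))) stop("trait vector must be finite")
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Uy <- crossprod(U, y)
  UX <- crossprod(U, X)
  # degenerate: (near-)constant residuals under OLS
  ols_res <- qr.resid(qr(X), y)
  if (var(ols_res) < 1e-12 || sd(y) < 1e-12) {
    fit <- list(sigma_g2 = 0, sigma_e2 = 0, sigma_g2_ml = 0, sigma_e2_ml = 0,
                lambda = 0, loglik_ml = NA_real_, loglik_reml = NA_real_,
                beta = qr.coef(qr(X), y), h2 = NA_real_,
                U = U, d = d, X = X, y = y, degenerate = TRUE)
    class(fit) <- "mlm_fit"
    return(fit)
  }
  solve_one <- function(reml) {
    f <- function(ll) -mlm_profile(ll, Uy, UX, d, reml)$ll
    opt <- optimize(f, interval = c(-12, 12), tol = 1e-8)
    # compare against the boundaries (lambda -> 0 or very large)
    cand <- c(opt$minimum, -12, 12)
    vals <- vapply(cand, f, numeric(1))
    ll_opt <- cand[which.min(vals)]
    prof <- mlm_profile(ll_opt, Uy, UX, d, reml)
    lambda <- if (ll_opt <= -12 + 1e-9) 0 else exp(ll_opt)
    se2 <- prof$s2
    list(lambda = lambda, sigma_e2 = se2, sigma_g2 = lambda * se2,
         ll = prof$ll, beta = prof$beta)
  }
  ml <- solve_one(FALSE)
  reml <- solve_one(TRUE)
  fit <- list(sigma_g2 = reml$sigma_g2, sigma_e2 = reml$sigma_e2,
              sigma_g2_ml = ml$sigma_g2, sigma_e2_ml = ml$sigma_e2,
              lambda = reml$lambda,
              loglik_ml = ml$ll, loglik_reml = reml$ll,
              beta = reml$beta,
              h2 = reml$sigma_g2 / (reml$sigma_g2 + reml$sigma_e2),
              U = U, d = d, X = X, y = y, degenerate = FALSE)
  class(fit) <- "mlm_fit"
  fit
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("mlm_fit: sigma_g2 = %.4g, sigma_e2 = %.4g (REML), h2 = %.3f, n = %d\n",
              x$sigma_g2, x$sigma_e2, x$h2, length(x$y)))
  invisible(x)
}

#' @export
summary.mlm_fit <- function(object, ...) {
  cat("Mixed linear model (spectral reparameterization)\n")
  cat(sprintf("  n = %d lines, %d fixed effect(s)\n",
              length(object$y), ncol(object$X)))
  cat(sprintf("  REML: sigma_g2 = %.5g, sigma_e2 = %.5g, lambda = %.4g, h2 = %.3f\n",
              object$sigma_g2, object$sigma_e2, object$lambda, object$h2))
  cat(sprintf("  ML:   sigma_g2 = %.5g, sigma_e2 = %.5g, logLik = %.4f\n",
              object$sigma_g2_ml, object$sigma_e2_ml, object$loglik_ml))
  invisible(object)
}

#' Select the number of PC covariates by BIC
#'
#' Fits the null mixed model by maximum likelihood for k = 0..k_max
#' principal components and returns the k minimizing
#' BIC = -2 logL + n_params log(n), counting fixed effects plus the two
#' variance components. Ties break toward smaller k.
#'
#' @param y trait vector (finite)
#' @param G `geno_matrix` aligned with `y`
#' @param K kinship matrix
#' @param k_max largest number of components considered
#' @param eig optional precomputed eigendecomposition of `K`
#' @return list with `k_opt` and the `bic` vector (named by k).
#' @export
select_pcs_bic <- function(y, G, K, k_max = 5L, eig = NULL) {
  if (anyNA(y) || any(!is.finite(y))) stop("trait vector must be finite")
  n <- length(y)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  pcs <- pca_covariates(G, k_max)
  bic <- vapply(0:k_max, function(k) {
    X <- cbind(`(Intercept)` = rep(1, n),
               pcs[, seq_len(k), drop = FALSE])
    fit <- fit_null_mlm(y, X, K, eig = eig)
    if (is.na(fit$loglik_ml)) return(Inf)
    -2 * fit$loglik_ml + (k + 1 + 2) * log(n)
  }, numeric(1))
  names(bic) <- 0:k_max
  list(k_opt = as.integer(names(bic)[which.min(bic)]), bic = bic)
}

#' Build the dummy design for a haplotype block
#'
#' Classes are dummy-coded against the most frequent class as reference;
#' classes rarer than `pool_below` (frequency among assigned lines) are
#' pooled into `"rare_other"` before coding to avoid rank deficiency.
#'
#' @param block a block from [find_blocks()]
#' @param G panel `geno_matrix`
#' @param pool_below pooling threshold (default 0.01)
#' @return design matrix with line-id rownames and `NA` rows for
#'   unassigned lines, or `NULL` when fewer than two classes are observed.
#' @export
block_design <- function(block, G, pool_below = 0.01) {
  ac <- assign_classes(block, G)
  cls <- ac$assignments
  freq <- ac$class_freq
  if (length(freq) < 2L) return(NULL)
  rare <- names(freq)[freq < pool_below]
  if (length(rare))
    cls[cls %in% rare] <- "rare_other"
  lv <- names(sort(table(cls[!is.na(cls)]), decreasing = TRUE))
  if (length(lv) < 2L) return(NULL)
  f <- factor(cls, levels = lv)
  D <- matrix(NA_real_, length(cls), length(lv) - 1L,
              dimnames = list(names(cls), paste0("class_", lv[-1L])))
  ok <- !is.na(f)
  D[ok, ] <- stats::model.matrix(~f[ok])[, -1L, drop = FALSE]
  attr(D, "reference") <- lv[1L]
  D
}

#' Test one feature in the fitted mixed model (P3D)
#'
#' Generalized least squares with the null model's REML variance components
#' held fixed (P3D/EMMAX style): the phenotypic covariance
#' V = sigma_g2 K + sigma_e2 I is built once, lines missing the feature are
#' dropped for this test only, and the feature columns are tested jointly
#' by an F test against the null design. Per-class effects are reported
#' relative to the reference class.
#'
#' @param fit an `mlm_fit` from [fit_null_mlm()]
#' @param K kinship matrix used for the fit
#' @param feature_design design matrix from [block_design()] (or a single
#'   dosage column for a SNP test), `NA` rows allowed; `NULL` is treated as
#'   a degenerate feature
#' @return list: `p`, `df`, `F`, `effects` (named numeric), `n_used`,
#'   `degenerate`.
#' @export
test_feature <- function(fit, K, feature_design) {
  if (is.null(feature_design))
    return(list(p = 1, df = 0L, F = NA_real_, effects = numeric(0),
                n_used = 0L, degenerate = TRUE))
  Fd <- as.matrix(feature_design)
  n <- length(fit$y)
  ok <- rowSums(is.na(Fd)) == 0L
  if (sum(ok) < ncol(fit$X) + ncol(Fd) + 1L)
    return(list(p = 1, df = ncol(Fd), F = NA_real_, effects = numeric(0),
                n_used = sum(ok), degenerate = TRUE))
  sg <- fit$sigma_g2; se <- fit$sigma_e2
  if (sg + se < 1e-10) { sg <- 0; se <- 1 }
  V <- sg * K + diag(se, n)
  Vs <- V[ok, ok, drop = FALSE]
  R <- chol(Vs)
  wh <- function(M) backsolve(R, M, transpose = TRUE)
  yw <- wh(fit$y[ok])
  X0 <- wh(fit$X[ok, , drop = FALSE])
  Fw <- wh(Fd[ok, , drop = FALSE])
  # drop feature columns collinear with the whitened null design
  qf <- qr(cbind(X0, Fw))
  keep_rank <- qf$rank - qr(X0)$rank
  if (keep_rank < 1L)
    return(list(p = 1, df = 0L, F = NA_real_, effects = numeric(0),
                n_used = sum(ok), degenerate = TRUE))
  fit0 <- lm.fit(X0, yw)
  fit1 <- lm.fit(cbind(X0, Fw), yw)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df1 <- keep_rank
  df2 <- sum(ok) - fit1$rank
  if (df2 < 1L || rss1 <= 0)
    return(list(p = 1, df = df1, F = NA_real_, effects = numeric(0),
                n_used = sum(ok), degenerate = TRUE))
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  eff <- fit1$coefficients[-(seq_len(ncol(X0)))]
  names(eff) <- colnames(Fd)
  list(p = as.numeric(p), df = df1, F = as.numeric(Fstat),
       effects = eff[!is.na(eff)], n_used = sum(ok), degenerate = FALSE)
}
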