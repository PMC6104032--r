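# a small structured panel reused across the MLM tests (memoized in helper)

test_that("kinship is PSD, marker-order invariant and duplicates lines faithfully", {
  pop <- gwas_pop()
  G <- pop$geno
  K <- kinship(G)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_identical(rownames(K), line_ids(G))
  # marker order invariance
  K2 <- kinship(subset_geno(G, markers = rev(marker_ids(G))))
  expect_equal(K, K2, tolerance = 1e-12)
  # a duplicated line: off-diagonal equals the diagonal for the pair
  calls <- G$calls[c(1, 1, 2:10), ]
  rownames(calls) <- c("dupA", "dupB", rownames(calls)[-(1:2)])
  Gd <- geno_matrix(calls, G$alleles)
  Kd <- kinship(Gd)
  expect_equal(Kd["dupA", "dupB"], Kd["dupA", "dupA"], tolerance = 1e-12)
  expect_error(kinship(subset_geno(G, markers = 1)), "at least 2")
  # unrelated founders: off-diagonals near zero
  cfgf <- sim_config(n_chromosomes = 2, n_markers_per_chr = 400,
                     n_exotic_founders = 20, exotic_divergence = 0.5,
                     elite_divergence = 0.4)
  cfgf$seed <- 7L
  Kf <- kinship(subset_geno(simulate_founders(cfgf),
                            lines = paste0("EX", 1:20)))
  off <- Kf[upper.tri(Kf)]
  # unrelated lines: off-diagonals sit at the sample-centering bias
  # -diag/(n-1), i.e. near zero relative to the (inbred, ~2) diagonal
  bias <- -mean(diag(Kf)) / (nrow(Kf) - 1)
  expect_lt(abs(mean(off) - bias), 0.02)
  expect_lt(mean(abs(off - bias)), 0.05 * mean(diag(Kf)))
})

test_that("PC covariates are orthogonal, sign-fixed and separate subpopulations", {
  pop <- gwas_pop()
  G <- pop$geno
  S <- pca_covariates(G, 3)
  expect_identical(dim(S), c(nrow(G$calls), 3L))
  cp <- crossprod(S)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  # variance explained non-increasing
  v <- apply(S, 2, var)
  expect_true(all(diff(v) <= 1e-9))
  expect_identical(ncol(pca_covariates(G, 0)), 0L)
  expect_error(pca_covariates(G, nrow(G$calls)), "smaller")
  # two diverged founder pools separate on PC1
  cfg2 <- sim_config(n_chromosomes = 2, n_markers_per_chr = 300,
                     n_elite_founders = 15, n_exotic_founders = 15,
                     elite_divergence = 0.05, exotic_divergence = 0.45)
  cfg2$seed <- 31L
  Gf <- simulate_founders(cfg2)
  p1 <- pca_covariates(Gf, 1)[, 1]
  grp <- grepl("^EL", line_ids(Gf))
  # silhouette-style separation: all elites on one side of the midpoint
  mid <- (mean(p1[grp]) + mean(p1[!grp])) / 2
  expect_true(all(p1[grp] < mid) || all(p1[grp] > mid))
})

test_that("null MLM with identity kinship reduces to ordinary least squares", {
  set.seed(5)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 1) + rnorm(n)
  K <- diag(n)
  fit <- fit_null_mlm(y, X, K)
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta[, 1]), unname(ols$coefficients),
               tolerance = 1e-6)
  # sigma_g2 + sigma_e2 equals the OLS residual variance (ML scale)
  expect_equal(fit$sigma_g2_ml + fit$sigma_e2_ml,
               sum(ols$residuals^2) / n, tolerance = 1e-5)
  # constant y handled without division errors
  fc <- fit_null_mlm(rep(3, n), matrix(1, n, 1), K)
  expect_identical(c(fc$sigma_g2, fc$sigma_e2), c(0, 0))
  expect_error(fit_null_mlm(c(rep(1, n - 1), NA), X, K), "finite")
  expect_error(fit_null_mlm(rnorm(n), cbind(X, X[, 2]), K), "rank")
})

test_that("REML recovers planted variance components", {
  pop <- gwas_pop()
  K <- kinship(pop$geno)
  n <- nrow(K)
  ed <- eigen(K, symmetric = TRUE)
  set.seed(42)
  h2_hat <- replicate(12, {
    u <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * rnorm(n))
    y <- as.numeric(u + rnorm(n))    # sigma_g2 = sigma_e2 = 1 on the K scale
    f <- fit_null_mlm(y, matrix(1, n, 1), K, eig = ed)
    f$sigma_g2 / (f$sigma_g2 + f$sigma_e2)
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.15)
})

test_that("BIC selects no PCs for unstructured traits and PCs for PC-driven ones", {
  pop <- gwas_pop()
  G <- pop$geno
  K <- kinship(G)
  eig <- eigen(K, symmetric = TRUE)
  set.seed(77)
  k0 <- replicate(20, {
    y <- rnorm(nrow(K))
    select_pcs_bic(y, G, K, k_max = 3, eig = eig)$k_opt
  })
  expect_gte(mean(k0 == 0), 0.9)
  # trait = PC1 + small noise
  p1 <- pca_covariates(G, 1)[, 1]
  y1 <- p1 + rnorm(length(p1), 0, 0.1 * sd(p1))
  expect_gte(select_pcs_bic(y1, G, K, k_max = 3, eig = eig)$k_opt, 1)
  expect_identical(select_pcs_bic(y1, G, K, k_max = 0, eig = eig)$k_opt, 0L)
})

test_that("P3D block test equals one-way ANOVA under identity kinship", {
  set.seed(9)
  n <- 120
  cls <- factor(sample(c("aa", "bb", "cc"), n, TRUE, prob = c(.5, .3, .2)))
  y <- rnorm(n) + 0.4 * (cls == "bb")
  K <- diag(n)
  rownames(K) <- colnames(K) <- paste0("L", 1:n)
  names(y) <- rownames(K)
  fit <- fit_null_mlm(y, matrix(1, n, 1), K)
  D <- stats::model.matrix(~cls)[, -1, drop = FALSE]
  rownames(D) <- names(y)
  t1 <- test_feature(fit, K, D)
  p_aov <- anova(lm(y ~ cls))[1, "Pr(>F)"]
  expect_equal(t1$p, p_aov, tolerance = 1e-9)
  expect_identical(t1$df, 2L)
  # per-class effects relative to the reference equal the OLS coefficients
  eff_ols <- coef(lm(y ~ cls))[-1]
  expect_equal(unname(t1$effects), unname(eff_ols), tolerance = 1e-9)
  # degenerate feature: one observed class
  expect_identical(test_feature(fit, K, NULL)$p, 1)
})

test_that("permutation type-I error is nominal and power rises with effect size", {
  pop <- gwas_pop()
  G <- pop$geno
  K <- kinship(G)
  eig <- eigen(K, symmetric = TRUE)
  qc <- qc_filter(G, pop$map, qc_params())
  bl <- find_blocks(qc$geno, qc$map)
  b <- bl[[which.max(vapply(bl, function(x) length(x$class_freq), 1L))]]
  D <- block_design(b, G)
  set.seed(61)
  y0 <- rnorm(nrow(K))
  hits <- replicate(200, {
    yp <- sample(y0)
    fit <- fit_null_mlm(yp, matrix(1, length(yp), 1), K, eig = eig)
    test_feature(fit, K, D)$p <= 0.05
  })
  # binomial 99% CI around 0.05 with 200 draws
  expect_lt(abs(mean(hits) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200) + 1e-9)
  # monotone power in effect size, paired noise draws
  cls <- assign_classes(b, G)$assignments
  target <- names(sort(table(cls), decreasing = TRUE))[2]
  carrier <- !is.na(cls) & cls == target
  set.seed(62)
  pow <- vapply(c(0.3, 0.8, 1.6), function(eff) {
    mean(replicate(15, {
      y <- rnorm(length(carrier)) + eff * carrier
      fit <- fit_null_mlm(y, matrix(1, length(y), 1), K, eig = eig)
      test_feature(fit, K, D)$p <= 0.01
    }))
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})

test_that("empirical threshold takes the bottom percentile order statistic", {
  set.seed(3)
  p <- runif(1000)
  expect_identical(empirical_threshold(p, 0.1), min(p))
  expect_warning(empirical_threshold(runif(50), 0.1), "coarse")
  expect_error(empirical_threshold(numeric(0)), "no p-values")
  p1 <- rep(1, 1000)
  expect_identical(empirical_threshold(p1, 0.1), 1)
})

test_that("QQ deviation flags planted signals, not uniform noise", {
  set.seed(8)
  pu <- runif(500)
  qq <- qq_deviation(pu)
  expect_lte(mean(qq$deviates), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_lt(abs(qq$lambda - 1), 0.15)
  # one strong signal among nulls is flagged
  ps <- c(1e-8, runif(199))
  qq2 <- qq_deviation(ps)
  expect_true(qq2$deviates[1])
  expect_error(qq_deviation(runif(10)), "at least 20")
})

test_that("scan output is invariant to line order and matches across modes", {
  pop <- gwas_pop()
  qc <- qc_filter(pop$geno, pop$map, qc_params())
  bl <- find_blocks(qc$geno, qc$map)
  set.seed(12)
  traits <- trait_table(data.frame(line = line_ids(qc$geno), trait = "t",
                                   env = "e",
                                   value = rnorm(nrow(qc$geno$calls))))
  s1 <- scan_features(bl, qc$geno, traits, map = qc$map, threshold = 0.01)
  perm <- sample(nrow(qc$geno$calls))
  s2 <- scan_features(bl, subset_geno(qc$geno, lines = perm), traits,
                      map = qc$map, threshold = 0.01)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
  # SNP mode runs and produces one row per marker
  mks <- marker_ids(qc$geno)[1:25]
  s3 <- scan_features(mks, qc$geno, traits, map = qc$map, threshold = 0.01)
  expect_identical(nrow(s3), 25L)
  expect_true(all(s3$df %in% c(0L, 1L)))
})
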