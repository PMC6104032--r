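test_that("qc_filter applies thresholds in the documented order", {
  # 20 lines; m1 fine, m2 has MAF 0.04 equivalent (1 minor allele of 25
  # after the high-missing line is dropped), m3 co-located with m1
  calls <- cbind(m1 = c(rep(0L, 10), rep(2L, 10)),
                 m2 = c(2L, rep(0L, 19)),
                 m3 = c(rep(0L, 10), rep(2L, 10)))
  calls[1, ] <- NA   # line 1: 100% missing -> dropped first
  G <- make_geno(calls)
  map <- genetic_map(c("m1", "m2", "m3"), rep("1A", 3), c(0, 5, 0))
  out <- qc_filter(G, map, qc_params(maf_min = 0.05))
  expect_false("L01" %in% line_ids(out$geno))
  expect_false("m2" %in% marker_ids(out$geno))   # MAF 1/38 < 0.05
  expect_false("m3" %in% marker_ids(out$geno))   # co-located, second in order
  expect_true("m1" %in% marker_ids(out$geno))
  expect_setequal(unique(out$report$reason[out$report$id == "m2"]), "maf")
  expect_true(any(out$report$reason == "co_located"))
  # all markers removed -> explicit error
  Gbad <- make_geno(matrix(0L, 10, 2))
  expect_error(qc_filter(Gbad, make_map(Gbad)), "empty panel")
})

test_that("HWE filter engages only when requested or panel is outbred", {
  # m1: extreme heterozygote excess; m2: perfect Hardy-Weinberg proportions
  calls <- cbind(m1 = rep(1L, 60), m2 = c(rep(0L, 15), rep(1L, 30), rep(2L, 15)))
  G <- make_geno(calls)
  map <- make_map(G)
  out_skip <- qc_filter(G, map, qc_params(maf_min = 0, hwe_mode = "skip_inbred",
                                          inbred_het_max = 0.9))
  expect_true("m1" %in% marker_ids(out_skip$geno))
  out_apply <- qc_filter(G, map, qc_params(maf_min = 0, hwe_mode = "apply"))
  expect_false("m1" %in% marker_ids(out_apply$geno))
  expect_true("m2" %in% marker_ids(out_apply$geno))
})

test_that("Hardy-Weinberg exact test behaves like the exact reference", {
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-20)
  # large balanced case agrees with the chi-square approximation
  p_exact <- hwe_exact_test(300, 350, 150)
  o <- c(300, 350, 150); n <- sum(o)
  p_all <- (2 * 300 + 350) / (2 * n)
  e <- n * c(p_all^2, 2 * p_all * (1 - p_all), (1 - p_all)^2)
  p_chi <- pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  expect_lt(abs(p_exact - p_chi), 0.02)
})

test_that("EM haplotype frequencies equal direct counting on phase-known data", {
  g1 <- c(rep(0L, 50), rep(2L, 50)); g2 <- g1
  em <- em_haplotype_freqs(g1, g2)
  expect_equal(unname(em$freqs), c(0.5, 0, 0, 0.5))
  expect_false(em$low_information)
  # 90:10:10:90 homozygote mix
  g1 <- c(rep(0L, 100), rep(2L, 100))
  g2 <- c(rep(0L, 90), rep(2L, 10), rep(0L, 10), rep(2L, 90))
  em2 <- em_haplotype_freqs(g1, g2)
  expect_equal(unname(em2$freqs), c(0.45, 0.05, 0.05, 0.45))
  # random inbred panels: EM equals direct haplotype counting exactly
  set.seed(31)
  for (i in 1:10) {
    h1 <- rbinom(80, 1, 0.5); h2 <- ifelse(runif(80) < 0.8, h1, 1 - h1)
    emr <- em_haplotype_freqs(2L * h1, 2L * h2)
    direct <- table(factor(paste0(h1, h2), c("00", "01", "10", "11"))) / 80
    expect_equal(unname(emr$freqs), as.numeric(direct))
  }
  # a panel of only double heterozygotes is flagged low-information
  em3 <- em_haplotype_freqs(rep(1L, 40), rep(1L, 40))
  expect_true(em3$low_information)
  expect_equal(em3$freqs[["p_AB"]] + em3$freqs[["p_ab"]], 0.5, tolerance = 1e-6)
})

test_that("D-prime point estimates and CI classification follow the rule", {
  pl <- dprime_ci(c(0.5, 0, 0, 0.5), 200)
  expect_equal(pl$dprime, 1)
  expect_identical(pl$classification, "strong_LD")
  # closed form: D = 0.2, Dmax = 0.25 -> D' = 0.8
  pl2 <- dprime_ci(c(0.45, 0.05, 0.05, 0.45), 400)
  expect_equal(pl2$dprime, 0.8)
  # tiny n: D' = 1 but CI too wide to call strong LD
  pl3 <- dprime_ci(c(0.5, 0, 0, 0.5), 4)
  expect_equal(pl3$dprime, 1)
  expect_identical(pl3$classification, "inconclusive")
  expect_lt(pl3$ci_low, 0.7)
  # monomorphic pair is a degenerate signal
  expect_identical(dprime_ci(c(1, 0, 0, 0), 100)$classification, "degenerate")
  expect_true(dprime_ci(c(0.25, 0.25, 0.25, 0.25), 500)$ci_high < 0.9)
})

test_that("find_blocks matches the exhaustive-interval oracle on small maps", {
  set.seed(41)
  for (rep in 1:4) {
    n <- 80
    # build 5-6 markers with mixed LD structure
    h <- rbinom(n, 1, 0.5)
    calls <- cbind(2L * h, 2L * h,                        # perfect LD pair
                   2L * ifelse(runif(n) < 0.9, h, 1 - h), # strong-ish
                   2L * rbinom(n, 1, 0.5),                # independent
                   2L * rbinom(n, 1, 0.4))
    G <- make_geno(calls)
    map <- make_map(G, spacing = 1.5)
    got <- find_blocks(G, map)
    want <- brute_force_blocks(G, map)
    expect_identical(lapply(got, `[[`, "markers"), want)
  }
})

test_that("blocks respect the LD window and name markers left to right", {
  h <- rbinom(100, 1, 0.5)
  G <- make_geno(cbind(2L * h, 2L * h))
  # two perfectly correlated markers 8 cM apart with a 5 cM window
  map <- genetic_map(marker_ids(G), c("1A", "1A"), c(0, 8))
  expect_length(find_blocks(G, map), 0)
  # same pair within the window forms one 2-marker block named HB1.1
  map2 <- genetic_map(marker_ids(G), c("1A", "1A"), c(0, 3))
  bl <- find_blocks(G, map2)
  expect_length(bl, 1)
  expect_identical(bl[[1]]$name, "HB1.1")
  # chromosome index drives the name prefix: 1B -> HB2.x
  map3 <- genetic_map(marker_ids(G), c("1B", "1B"), c(0, 3))
  expect_identical(find_blocks(G, map3)[[1]]$name, "HB2.1")
})

test_that("block construction is invariant to line order and marker renaming", {
  G <- make_ld_panel(seed = 5)
  map <- make_map(G)
  b1 <- find_blocks(G, map)
  perm <- sample(nrow(G$calls))
  G2 <- subset_geno(G, lines = perm)
  b2 <- find_blocks(G2, map)
  expect_identical(lapply(b1, `[[`, "markers"), lapply(b2, `[[`, "markers"))
  expect_identical(lapply(b1, `[[`, "class_freq"), lapply(b2, `[[`, "class_freq"))
  # renaming markers (order kept) changes ids only
  new_names <- paste0("z", marker_ids(G))
  calls3 <- G$calls; colnames(calls3) <- new_names
  al3 <- G$alleles; rownames(al3) <- new_names
  G3 <- geno_matrix(calls3, al3)
  map3 <- genetic_map(new_names, map$chrom, map$cM)
  b3 <- find_blocks(G3, map3)
  expect_identical(lapply(b3, function(b) sub("^z", "", b$markers)),
                   lapply(b1, `[[`, "markers"))
})

test_that("every filtered marker lands in at most one block", {
  pop <- simulate_topcross(local({
    cfg <- sim_config(n_chromosomes = 2, n_markers_per_chr = 40,
                      n_crosses = 4, n_lines_per_cross = 25)
    cfg$seed <- 77L
    cfg
  }))
  qc <- qc_filter(pop$geno, pop$map, qc_params())
  bl <- find_blocks(qc$geno, qc$map)
  members <- unlist(lapply(bl, `[[`, "markers"))
  expect_identical(anyDuplicated(members), 0L)
  expect_true(all(members %in% marker_ids(qc$geno)))
})

test_that("class assignment maps homozygous allele strings and drops hets", {
  calls <- cbind(m1 = c(0L, 2L, 1L, 0L), m2 = c(2L, 2L, 2L, NA))
  al <- matrix(c("A", "C", "G", "T"), 2, 2, dimnames = list(c("m1", "m2"), NULL))
  G <- make_geno(calls, al)
  ac <- assign_classes(list(markers = c("m1", "m2")), G)
  expect_identical(unname(ac$assignments), c("AT", "GT", NA, NA))
  expect_equal(sum(ac$class_freq), 1)
  expect_equal(ac$class_freq[["AT"]], 0.5)
})

test_that("multi-allelic D-prime reduces to the biallelic case and detects independence", {
  G <- make_ld_panel(seed = 8)
  map <- make_map(G)
  bl <- find_blocks(G, map)
  b <- bl[[1]]
  expect_equal(multiallelic_dprime(b, b, G), 1)
  # two-class x two-class equals |D'| from the biallelic collapse
  h1 <- rbinom(400, 1, 0.5)
  h2 <- ifelse(runif(400) < 0.85, h1, rbinom(400, 1, 0.5))
  Gp <- make_geno(cbind(2L * h1, 2L * h2))
  bA <- list(markers = marker_ids(Gp)[1]); bB <- list(markers = marker_ids(Gp)[2])
  em <- em_haplotype_freqs(Gp$calls[, 1], Gp$calls[, 2])
  expect_equal(multiallelic_dprime(bA, bB, Gp),
               dprime_ci(em$freqs, em$n_gametes)$dprime, tolerance = 1e-9)
  # independently shuffled labels decorrelate the blocks
  set.seed(9)
  calls_sh <- cbind(Gp$calls[, 1], sample(Gp$calls[, 2]))
  G_sh <- make_geno(calls_sh)
  expect_lt(multiallelic_dprime(list(markers = marker_ids(G_sh)[1]),
                                list(markers = marker_ids(G_sh)[2]), G_sh), 0.1)
})

test_that("elite panels yield fewer, longer blocks than exotic panels", {
  # mosaic founders: narrow elite ancestry with long shared segments vs a
  # broader exotic pool with short segments
  cfg <- sim_config(n_chromosomes = 2, n_markers_per_chr = 150,
                    n_elite_founders = 25, n_exotic_founders = 25,
                    elite_divergence = 0.08, exotic_divergence = 0.35,
                    founder_structure = "mosaic",
                    n_elite_ancestors = 3, n_exotic_ancestors = 8,
                    elite_segment_cM = 30, exotic_segment_cM = 8)
  cfg$seed <- 55L
  map <- sim_genetic_map(cfg)
  F <- simulate_founders(cfg, map)
  panel_blocks <- function(ids) {
    q <- qc_filter(subset_geno(F, lines = ids), map, qc_params())
    find_blocks(q$geno, q$map)
  }
  be <- panel_blocks(paste0("EL", 1:25))
  bx <- panel_blocks(paste0("EX", 1:25))
  cmp <- compare_block_maps(be, bx)
  expect_lt(cmp$summary$n_blocks[1], cmp$summary$n_blocks[2])
  expect_gt(cmp$summary$mean_span[1], cmp$summary$mean_span[2])
})
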