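# fixture builders and independent oracles shared across test files

# genotype matrix from a plain integer matrix; marker/line names generated
make_geno <- function(calls, alleles = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("m%02d", seq_len(ncol(calls)))
  if (is.null(alleles)) {
    alleles <- matrix(rep(c("A", "T"), each = ncol(calls)), ncol = 2)
    rownames(alleles) <- colnames(calls)
  }
  geno_matrix(calls, alleles)
}

# evenly spaced single-chromosome map for a genotype panel
make_map <- function(G, chrom = "1A", spacing = 1) {
  mk <- marker_ids(G)
  genetic_map(mk, rep(chrom, length(mk)), (seq_along(mk) - 1) * spacing)
}

# an inbred panel with two haplotype groups in perfect LD plus noise markers
make_ld_panel <- function(n_group1 = 60, n_group2 = 40, seed = 1) {
  set.seed(seed)
  n <- n_group1 + n_group2
  g <- rbind(matrix(0L, n_group1, 3), matrix(2L, n_group2, 3))
  noise <- matrix(2L * rbinom(n * 2, 1, 0.5), n, 2)
  make_geno(cbind(g, noise))
}

# independent brute-force reimplementation of the block rule for tiny maps:
# enumerate every interval, apply the 95% informative-pair rule, greedy
# non-overlap by (size desc, span desc, leftmost)
brute_force_blocks <- function(G, map, window = 5, strong_min = 0.95, ...) {
  mk <- map$marker; pos <- map$cM; nm <- length(mk)
  pair_class <- function(i, j) {
    em <- em_haplotype_freqs(G$calls[, mk[i]], G$calls[, mk[j]])
    dprime_ci(em$freqs, em$n_gametes, ...)$classification
  }
  cand <- list()
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (j <= i || pos[j] - pos[i] > window) next
    cls <- c()
    for (a in i:(j - 1)) for (b in (a + 1):j) cls <- c(cls, pair_class(a, b))
    inf <- sum(cls %in% c("strong_LD", "strong_recombination"))
    if (inf >= 1 && sum(cls == "strong_LD") / inf >= strong_min)
      cand[[length(cand) + 1]] <- list(i = i, j = j, size = j - i + 1,
                                       span = pos[j] - pos[i])
  }
  if (!length(cand)) return(list())
  ord <- order(-sapply(cand, `[[`, "size"), -sapply(cand, `[[`, "span"),
               sapply(cand, `[[`, "i"))
  taken <- rep(FALSE, nm); out <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (any(taken[cc$i:cc$j])) next
    taken[cc$i:cc$j] <- TRUE
    out[[length(out) + 1]] <- mk[cc$i:cc$j]
  }
  out[order(sapply(out, function(m) match(m[1], mk)))]
}

# memoized small structured topcross panel shared by the MLM tests
.gwas_pop_cache <- new.env(parent = emptyenv())
gwas_pop <- function() {
  if (is.null(.gwas_pop_cache$pop)) {
    cfg <- sim_config(n_chromosomes = 3, n_markers_per_chr = 40,
                      n_crosses = 6, n_lines_per_cross = 25)
    cfg$seed <- 101L
    .gwas_pop_cache$pop <- simulate_topcross(cfg)
  }
  .gwas_pop_cache$pop
}

# one end-to-end recovery replicate: full default genome, 300 lines
# as 30 crosses x 10, a tight 3-marker exotic-private haplotype implanted in
# 4 of 10 exotics (expected carrier frequency 10%), heat-only yield effect
# of one total phenotypic SD, irrigated environment effect-free,
# days-to-heading unassociated
planted_rep <- function(seed, full_screen = FALSE) {
  scfg <- sim_config(n_crosses = 30, n_lines_per_cross = 10)
  scfg$seed <- seed
  map <- sim_genetic_map(scfg)
  founders <- simulate_founders(scfg, map)
  mks <- introhap:::pick_block_markers(map, chrom_idx = 6L, n = 3L, window = 5)
  imp <- implant_haplotype(founders, mks, paste0("EX", 1:4))
  pop <- simulate_topcross_population(imp$founders, map, scfg)
  residual_sd <- 500
  polygenic_var <- (0.3 * residual_sd)^2
  total_sd <- sqrt(residual_sd^2 + 2 * polygenic_var)
  spec <- qtl_spec(
    rbind(data.frame(trait = "grain_yield", env = c("heat", "irrigated"),
                     mean = c(3000, 6000)),
          data.frame(trait = "days_to_heading", env = "irrigated", mean = 80)),
    qtl = list(list(markers = mks, class = imp$class, effect = total_sd,
                    trait = "grain_yield", envs = "heat")),
    polygenic_var = polygenic_var, residual_var = residual_sd^2)
  traits <- simulate_phenotypes(pop, spec, seed = seed)
  G <- pop$geno
  hy <- traits[traits$trait == "grain_yield" & traits$env == "heat", ]
  y <- setNames(hy$value, hy$line)[line_ids(G)]
  ci <- map$chrom_idx[match(mks[1], map$marker)]
  Gk <- subset_geno(G, markers = setdiff(marker_ids(G),
                                         map$marker[map$chrom_idx == ci]))
  K <- kinship(Gk)
  eig <- eigen(K, symmetric = TRUE)
  fit <- fit_null_mlm(y, matrix(1, length(y), 1), K, eig = eig)
  p_focal <- test_feature(fit, K, block_design(list(markers = mks), G))$p
  out <- list(p_focal = p_focal, markers = mks, class = imp$class)
  if (!full_screen) return(out)
  qc <- qc_filter(G, map, qc_params())
  blocks <- find_blocks(qc$geno, qc$map)
  scan <- scan_features(blocks, qc$geno, traits, map = qc$map,
                        threshold = 0.001)
  prof <- class_profiles(blocks, qc$geno, traits)
  exo <- exotic_specific_blocks(
    blocks, qc$geno,
    subset_geno(imp$founders, lines = paste0("EX", 1:10)),
    subset_geno(imp$founders, lines = paste0("EL", 1:7)))
  cand <- screen_rare_favorable(prof, scan, traits, "grain_yield",
                                exotic_flags = exo$flags)
  focal <- Filter(function(b) any(mks %in% b$markers), blocks)
  out$focal_exospec <- length(focal) > 0 &&
    any(exo$flags[vapply(focal, `[[`, "", "name")])
  # recovery: the top candidate's block contains planted markers and its
  # class, restricted to those markers, is the planted allele string
  out$screen_hit <- FALSE
  out$penalty_free <- NA
  if (nrow(cand)) {
    top <- Filter(function(b) b$name == cand$block[1], blocks)[[1]]
    shared <- intersect(top$markers, mks)
    if (length(shared)) {
      pos_top <- match(shared, top$markers)
      pos_q <- match(shared, mks)
      cls_top <- strsplit(cand$class[1], "")[[1]][pos_top]
      cls_q <- strsplit(imp$class, "")[[1]][pos_q]
      out$screen_hit <- identical(cls_top, cls_q)
      out$penalty_free <- cand$penalty_envs[1] == ""
    }
  }
  out
}
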