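#' Simulation configuration for the topcross breeding scheme
#'
#' Defines the genome, the founder pools and the crossing/selfing plan used
#' by the forward simulator. Defaults emulate a wheat pre-breeding panel:
#' 21 chromosomes, ~2,000 mapped SNPs, a narrow elite pool with long shared
#' haplotypes, diverse exotic accessions, and three-way crosses
#' exotic/elite1//elite2 selfed four generations to TC1F5.
#'
#' @param n_chromosomes number of chromosomes (default 21)
#' @param chr_length_cM genetic length per chromosome, cM (recycled)
#' @param n_markers_per_chr markers per chromosome (recycled)
#' @param n_elite_founders,n_exotic_founders founder pool sizes
#' @param elite_divergence probability that a pair of elite founders differs
#'   at a marker; small values create the long shared elite haplotypes seen
#'   in elite breeding pools
#' @param exotic_divergence probability that an elite and an exotic founder
#'   differ at a marker (must exceed `elite_divergence / 2`)
#' @param selfing_generations number of selfing generations after the
#'   topcross F1 (default 4: TC1F1 through TC1F5)
#' @param n_crosses number of three-way crosses
#' @param n_lines_per_cross derived inbred lines per cross
#' @param missing_rate fraction of calls masked to missing in derived lines
#' @param parent_het_rate fraction of founder loci made heterozygous
#'   (default 0: founders fully inbred); nonzero values exercise the
#'   unidentified-origin path of the A/B/H classifier
#' @param founder_structure `"iid"` (default): founder alleles independent
#'   across markers, so pairwise difference rates are exactly the
#'   configured divergences; `"mosaic"`: founders are segmental mosaics of
#'   a small pool of ancestral haplotypes, which creates linkage structure
#'   within the founder panels (long shared haplotypes in the narrow elite
#'   pool, shorter ones among exotics) at approximately the configured
#'   divergences
#' @param n_elite_ancestors,n_exotic_ancestors ancestral-haplotype pool
#'   sizes for the mosaic mode
#' @param elite_segment_cM,exotic_segment_cM mean mosaic segment lengths
#' @param seed root random seed; all child streams derive from it
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 21,
                       chr_length_cM = 150,
                       n_markers_per_chr = 95,
                       n_elite_founders = 7,
                       n_exotic_founders = 10,
                       elite_divergence = 0.05,
                       exotic_divergence = 0.30,
                       selfing_generations = 4,
                       n_crosses = 10,
                       n_lines_per_cross = 30,
                       missing_rate = 0,
                       parent_het_rate = 0,
                       founder_structure = c("iid", "mosaic"),
                       n_elite_ancestors = 3,
                       n_exotic_ancestors = 12,
                       elite_segment_cM = 25,
                       exotic_segment_cM = 10,
                       seed = 1L) {
  founder_structure <- match.arg(founder_structure)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chr_length_cM = rep_len(as.numeric(chr_length_cM), n_chromosomes),
              n_markers_per_chr = rep_len(as.integer(n_markers_per_chr),
                                          n_chromosomes),
              n_elite_founders = as.integer(n_elite_founders),
              n_exotic_founders = as.integer(n_exotic_founders),
              elite_divergence = elite_divergence,
              exotic_divergence = exotic_divergence,
              selfing_generations = as.integer(selfing_generations),
              n_crosses = as.integer(n_crosses),
              n_lines_per_cross = as.integer(n_lines_per_cross),
              missing_rate = missing_rate,
              parent_het_rate = parent_het_rate,
              founder_structure = founder_structure,
              n_elite_ancestors = as.integer(n_elite_ancestors),
              n_exotic_ancestors = as.integer(n_exotic_ancestors),
              elite_segment_cM = elite_segment_cM,
              exotic_segment_cM = exotic_segment_cM,
              seed = as.integer(seed))
  if (cfg$n_chromosomes < 1 || cfg$n_chromosomes > 21)
    stop("n_chromosomes must be in 1..21")
  if (any(cfg$chr_length_cM <= 0)) stop("chromosome lengths must be > 0")
  if (any(cfg$n_markers_per_chr < 1)) stop("need at least one marker per chromosome")
  if (cfg$elite_divergence < 0 || cfg$elite_divergence > 1 ||
      cfg$exotic_divergence < 0 || cfg$exotic_divergence > 1)
    stop("divergences must lie in [0, 1]")
  if (cfg$elite_divergence > 0.5)
    stop("elite_divergence above 0.5 is not representable by independent founder draws")
  if (cfg$selfing_generations < 0) stop("selfing_generations must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic child seed derived from the root; stays below 2^31 - 1
child_seed <- function(root, ...) {
  s <- as.numeric(root) %% 2147483647
  for (k in c(...)) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

#' Genetic map for a simulation configuration
#'
#' Marker positions are drawn uniformly on each chromosome (then sorted),
#' reproducibly from the configuration seed.
#' @param config a [sim_config()]
#' @return a [genetic_map()].
#' @export
sim_genetic_map <- function(config) {
  set.seed(child_seed(config$seed, 11))
  chroms <- wheat_chromosomes()[seq_len(config$n_chromosomes)]
  parts <- lapply(seq_len(config$n_chromosomes), function(c) {
    n <- config$n_markers_per_chr[c]
    pos <- sort(round(runif(n, 0, config$chr_length_cM[c]), 3))
    data.frame(marker = sprintf("m%02d_%04d", c, seq_len(n)),
               chrom = chroms[c], cM = pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  genetic_map(df$marker, df$chrom, df$cM)
}

#' Simulate founder genotypes
#'
#' Elite founders are independent perturbations of a shared elite consensus
#' haplotype, so any elite pair differs at a marker with probability equal to
#' `elite_divergence`; exotic founders are perturbed such that an
#' elite-exotic pair differs with probability `exotic_divergence`. Founders
#' are fully homozygous unless `parent_het_rate > 0`.
#'
#' @param config a [sim_config()]
#' @param map optional precomputed [sim_genetic_map()] for the same config
#' @return a [geno_matrix()] of `n_elite_founders + n_exotic_founders`
#'   founders (line ids `EL1..`, `EX1..`).
#' @export
simulate_founders <- function(config, map = sim_genetic_map(config)) {
  M <- nrow(map)
  if (M == 0) stop("configuration yields zero markers")
  set.seed(child_seed(config$seed, 23))
  # flip probability giving the requested pairwise elite difference rate
  de <- config$elite_divergence
  f <- (1 - sqrt(1 - 2 * de)) / 2
  dx <- config$exotic_divergence
  px <- if (f < 0.5) (dx - f) / (1 - 2 * f) else 0.5
  if (px < 0 || px > 1)
    stop("exotic_divergence incompatible with elite_divergence")
  nucs <- c("A", "C", "G", "T")
  a0 <- sample(nucs, M, replace = TRUE)
  a2 <- vapply(a0, function(a) sample(setdiff(nucs, a), 1L), character(1))
  alleles <- cbind(a0, a2)
  rownames(alleles) <- map$marker
  ne <- config$n_elite_founders; nx <- config$n_exotic_founders
  ids <- c(paste0("EL", seq_len(ne)), paste0("EX", seq_len(nx)))
  # founder haplotypes as 0/1 allele indices; consensus is all-0
  hap <- matrix(0L, ne + nx, M, dimnames = list(ids, map$marker))
  if (config$founder_structure == "iid") {
    for (i in seq_len(ne))
      hap[i, ] <- as.integer(runif(M) < f)
    for (i in seq_len(nx))
      hap[ne + i, ] <- as.integer(runif(M) < px)
  } else {
    # mosaic mode: founders are segmental mosaics of ancestral haplotypes.
    # Two founders of a pool of A ancestors share an ancestor at a locus
    # with probability 1/A, so ancestral flip rates are scaled up to keep
    # the pairwise founder divergence approximately at the configured value.
    scale_up <- function(d, A) min(0.5, d / max(1e-12, 1 - 1 / A))
    fe_anc <- (1 - sqrt(pmax(0, 1 - 2 * scale_up(de, config$n_elite_ancestors)))) / 2
    px_anc <- if (fe_anc < 0.5) (dx - fe_anc) / (1 - 2 * fe_anc) else 0.5
    px_anc <- min(max(px_anc, 0), 1)
    anc_e <- matrix(as.integer(runif(config$n_elite_ancestors * M) < fe_anc),
                    config$n_elite_ancestors, M)
    anc_x <- matrix(as.integer(runif(config$n_exotic_ancestors * M) < px_anc),
                    config$n_exotic_ancestors, M)
    layout <- map_layout(map)
    mosaic <- function(anc, seg_len) {
      out <- integer(M)
      for (chr in layout) {
        pos <- chr$pos
        len <- max(pos)
        brk <- sort(runif(rpois(1L, len / seg_len), 0, len))
        src <- sample.int(nrow(anc), length(brk) + 1L, replace = TRUE)
        seg <- findInterval(pos, brk) + 1L
        out[chr$i] <- anc[cbind(src[seg], chr$i)]
      }
      out
    }
    for (i in seq_len(ne)) hap[i, ] <- mosaic(anc_e, config$elite_segment_cM)
    for (i in seq_len(nx)) hap[ne + i, ] <- mosaic(anc_x, config$exotic_segment_cM)
  }
  calls <- 2L * hap
  if (config$parent_het_rate > 0) {
    hets <- matrix(runif(length(calls)) < config$parent_het_rate, nrow(calls))
    calls[hets] <- 1L
  }
  geno_matrix(calls, alleles)
}

# internal plant representation: two chromatids, each with per-marker
# allele index (0/1) and ancestry origin code (1 = exotic, 2 = elite1,
# 3 = elite2)
plant <- function(a1, o1, a2, o2) list(a = cbind(a1, a2), o = cbind(o1, o2))

# chromosome layout helper: start/end marker indices and positions per chrom
map_layout <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom_idx)
  lapply(idx, function(i) list(i = i, pos = map$cM[i]))
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean `length / 100`
#' (Haldane model, no interference), crossover positions uniform on the cM
#' scale. The returned gamete carries recombined allele indices and ancestry
#' labels.
#'
#' @param genome a plant as built internally (two chromatids with allele and
#'   origin vectors over all mapped markers)
#' @param layout chromosome layout from the map (internal helper); markers
#'   outside the map are a caller error
#' @return list with `a` (allele index) and `o` (origin code) vectors.
#' @keywords internal
meiosis <- function(genome, layout) {
  M <- nrow(genome$a)
  a <- integer(M); o <- integer(M)
  xo_pos <- vector("list", length(layout))
  for (k in seq_along(layout)) {
    chr <- layout[[k]]
    len <- max(chr$pos)
    nxo <- rpois(1L, len / 100)
    start <- sample(c(1L, 2L), 1L)
    if (nxo == 0L) {
      pick <- rep(start, length(chr$i))
      xo_pos[[k]] <- numeric(0)
    } else {
      xo <- sort(runif(nxo, 0, len))
      seg <- findInterval(chr$pos, xo)
      pick <- 1L + (start - 1L + seg) %% 2L
      xo_pos[[k]] <- xo
    }
    ii <- chr$i
    a[ii] <- ifelse(pick == 1L, genome$a[ii, 1L], genome$a[ii, 2L])
    o[ii] <- ifelse(pick == 1L, genome$o[ii, 1L], genome$o[ii, 2L])
  }
  list(a = a, o = o, xo = xo_pos)
}

#' Simulate a topcross pre-breeding population with ancestry truth
#'
#' For each cross, an F1 (exotic x elite1) is crossed to elite2, and the
#' topcross F1 is selfed `selfing_generations` times by single-seed descent.
#' Every line records, per marker and chromatid, which founder role (exotic,
#' elite1, elite2) the segment descends from. Under no selection the expected
#' exotic genome fraction is 25%.
#'
#' @param founders founder `geno_matrix` from [simulate_founders()]
#' @param map the matching [sim_genetic_map()]
#' @param config the [sim_config()]
#' @param crosses optional data.frame (`cross_id`, `exotic`, `elite1`,
#'   `elite2`); by default crosses cycle deterministically through the pools
#' @return object of class `topcross_pop`: list with `geno` (lines
#'   `geno_matrix`), `truth` (list of two integer matrices `o1`, `o2`, codes
#'   1 = exotic, 2 = elite1, 3 = elite2), `registry` (a [cross_registry()]),
#'   `founders`, `map`, `config`.
#' @export
simulate_topcross_population <- function(founders, map, config, crosses = NULL) {
  if (is.null(crosses)) {
    ne <- config$n_elite_founders; nx <- config$n_exotic_founders
    i <- seq_len(config$n_crosses) - 1L
    crosses <- data.frame(
      cross_id = sprintf("C%02d", i + 1L),
      exotic = paste0("EX", (i %% nx) + 1L),
      elite1 = paste0("EL", (i %% ne) + 1L),
      elite2 = paste0("EL", ((i + 1L) %% ne) + 1L),
      stringsAsFactors = FALSE)
  }
  pids <- unique(unlist(crosses[, c("exotic", "elite1", "elite2")]))
  missing_parents <- setdiff(pids, line_ids(founders))
  if (length(missing_parents))
    stop("unknown parent id(s): ", paste(missing_parents, collapse = ", "))
  layout <- map_layout(map)
  M <- nrow(map)
  n_lines <- config$n_crosses * config$n_lines_per_cross
  calls <- matrix(NA_integer_, n_lines, M)
  o1 <- matrix(NA_integer_, n_lines, M)
  o2 <- matrix(NA_integer_, n_lines, M)
  ids <- character(n_lines)
  member <- data.frame(line = character(n_lines), cross_id = character(n_lines),
                       stringsAsFactors = FALSE)
  # founder chromatid pairs (possibly heterozygous if parent_het_rate > 0)
  fhap <- function(id) {
    d <- founders$calls[id, ]
    h1 <- as.integer(d >= 1L)          # het -> 1/0 split
    h2 <- as.integer(d == 2L)
    list(h1 = h1, h2 = h2)
  }
  row <- 0L
  for (ci in seq_len(nrow(crosses))) {
    ex <- fhap(crosses$exotic[ci])
    e1 <- fhap(crosses$elite1[ci])
    e2 <- fhap(crosses$elite2[ci])
    for (li in seq_len(config$n_lines_per_cross)) {
      set.seed(child_seed(config$seed, 37, ci, li))
      f1 <- plant(ex$h1, rep(1L, M), e1$h1, rep(2L, M))
      g_f1 <- meiosis(f1, layout)
      g_e2 <- meiosis(plant(e2$h1, rep(3L, M), e2$h2, rep(3L, M)), layout)
      pl <- plant(g_f1$a, g_f1$o, g_e2$a, g_e2$o)
      for (g in seq_len(config$selfing_generations)) {
        gam1 <- meiosis(pl, layout)
        gam2 <- meiosis(pl, layout)
        pl <- plant(gam1$a, gam1$o, gam2$a, gam2$o)
      }
      row <- row + 1L
      d <- pl$a[, 1L] + pl$a[, 2L]
      if (config$missing_rate > 0)
        d[runif(M) < config$missing_rate] <- NA_integer_
      calls[row, ] <- d
      o1[row, ] <- pl$o[, 1L]
      o2[row, ] <- pl$o[, 2L]
      ids[row] <- sprintf("PBL_%s_%03d", crosses$cross_id[ci], li)
      member$line[row] <- ids[row]
      member$cross_id[row] <- crosses$cross_id[ci]
    }
  }
  dimnames(calls) <- list(ids, map$marker)
  dimnames(o1) <- dimnames(o2) <- list(ids, map$marker)
  structure(list(geno = geno_matrix(calls, founders$alleles[map$marker, ]),
                 truth = list(o1 = o1, o2 = o2),
                 registry = cross_registry(crosses, member),
                 founders = founders, map = map, config = config),
            class = "topcross_pop")
}

#' @export
print.topcross_pop <- function(x, ...) {
  cat(sprintf("topcross_pop: %d lines from %d crosses, %d markers, g = %d selfings\n",
              nrow(x$geno$calls), nrow(x$registry$crosses),
              ncol(x$geno$calls), x$config$selfing_generations))
  invisible(x)
}

#' One-call simulation of map, founders and population
#' @param config a [sim_config()]
#' @return a `topcross_pop` (with `map` and `founders` attached).
#' @export
simulate_topcross <- function(config) {
  map <- sim_genetic_map(config)
  founders <- simulate_founders(config, map)
  simulate_topcross_population(founders, map, config)
}

#' Per-line ancestry-truth origin fractions
#'
#' Fraction of chromatid-marker slots descending from each founder role.
#' @param pop a `topcross_pop`
#' @return data.frame with columns `line`, `exotic`, `elite1`, `elite2`.
#' @export
truth_fractions <- function(pop) {
  both <- cbind(pop$truth$o1, pop$truth$o2)
  data.frame(line = rownames(pop$truth$o1),
             exotic = rowMeans(both == 1L),
             elite1 = rowMeans(both == 2L),
             elite2 = rowMeans(both == 3L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' QTL specification for phenotype simulation
#'
#' @param env_means data.frame (`trait`, `env`, `mean`): one row per
#'   trait-environment cell of the design, in trait units
#' @param qtl list of QTL; each a list with `markers` (character), `class`
#'   (allele string carried, e.g. `"GT"`), `effect` (trait units), `trait`,
#'   and `envs` (environments where the effect is active)
#' @param polygenic_var variance of the kinship-structured polygenic term
#' @param residual_var residual variance
#' @return object of class `qtl_spec`.
#' @export
qtl_spec <- function(env_means, qtl = list(), polygenic_var = 0,
                     residual_var = 1) {
  if (!all(c("trait", "env", "mean") %in% names(env_means)))
    stop("env_means needs columns trait, env, mean")
  if (polygenic_var < 0 || residual_var < 0) stop("variances must be >= 0")
  for (q in qtl) {
    if (!all(c("markers", "class", "effect", "trait", "envs") %in% names(q)))
      stop("each QTL needs markers, class, effect, trait, envs")
    bad <- setdiff(q$envs, env_means$env[env_means$trait == q$trait])
    if (length(bad))
      stop("QTL active in unknown environment(s): ", paste(bad, collapse = ", "))
  }
  structure(list(env_means = env_means, qtl = qtl,
                 polygenic_var = polygenic_var, residual_var = residual_var),
            class = "qtl_spec")
}

# TRUE for lines homozygous for `class` across `markers`
carries_class <- function(G, markers, class) {
  absent <- setdiff(markers, marker_ids(G))
  if (length(absent))
    stop("QTL references absent marker(s): ", paste(absent, collapse = ", "))
  sub <- G$calls[, markers, drop = FALSE]
  al <- G$alleles[markers, , drop = FALSE]
  want <- strsplit(class, "")[[1L]]
  if (length(want) != length(markers))
    stop("class string length must equal number of QTL markers")
  ok <- rep(TRUE, nrow(sub))
  for (j in seq_along(markers)) {
    a <- call_to_allele(sub[, j], al[j, ])
    ok <- ok & !is.na(a) & a == want[j]
  }
  ok
}

#' Simulate multi-environment phenotypes with planted haplotype QTL
#'
#' Each record is environment mean + the sum of active QTL effects for
#' carried haplotype classes + a kinship-structured polygenic term (shared
#' across environments within a trait) + independent Gaussian residual.
#'
#' @param pop a `topcross_pop` (or any object with a `geno` field)
#' @param spec a [qtl_spec()]
#' @param seed random seed
#' @return a [trait_table()].
#' @export
simulate_phenotypes <- function(pop, spec, seed = 1L) {
  G <- if (inherits(pop, "geno_matrix")) pop else pop$geno
  set.seed(child_seed(seed, 53))
  n <- nrow(G$calls)
  lines <- line_ids(G)
  traits <- unique(spec$env_means$trait)
  u <- matrix(0, n, length(traits), dimnames = list(lines, traits))
  if (spec$polygenic_var > 0) {
    K <- kinship(G)
    ed <- eigen(K, symmetric = TRUE)
    Lh <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), n)
    for (t in seq_along(traits))
      u[, t] <- sqrt(spec$polygenic_var) * (Lh %*% rnorm(n))
  }
  carrier <- lapply(spec$qtl, function(q) carries_class(G, q$markers, q$class))
  out <- list()
  for (r in seq_len(nrow(spec$env_means))) {
    tr <- spec$env_means$trait[r]; ev <- spec$env_means$env[r]
    val <- rep(spec$env_means$mean[r], n) + u[, tr]
    for (k in seq_along(spec$qtl)) {
      q <- spec$qtl[[k]]
      if (q$trait == tr && ev %in% q$envs)
        val <- val + q$effect * carrier[[k]]
    }
    if (spec$residual_var > 0)
      val <- val + rnorm(n, 0, sqrt(spec$residual_var))
    out[[r]] <- data.frame(line = lines, trait = tr, env = ev, value = val,
                           stringsAsFactors = FALSE)
  }
  trait_table(do.call(rbind, out))
}

#' Truncation selection on a trait
#'
#' Retains the top fraction of lines by trait value (averaged over the
#' selected environments) and subsets the ancestry truth and registry
#' accordingly. Emulates phenotypic bulk selection during line advancement.
#'
#' @param pop a `topcross_pop`
#' @param traits a [trait_table()] covering all lines of `pop`
#' @param trait trait name to select on
#' @param retained_fraction fraction in (0, 1] to keep
#' @param env optional environment label(s); default all environments
#' @return a `topcross_pop` restricted to the selected lines.
#' @export
apply_selection <- function(pop, traits, trait, retained_fraction, env = NULL) {
  if (retained_fraction <= 0 || retained_fraction > 1)
    stop("retained_fraction must be in (0, 1]")
  tt <- traits[traits$trait == trait, , drop = FALSE]
  if (!is.null(env)) tt <- tt[tt$env %in% env, , drop = FALSE]
  score <- tapply(tt$value, tt$line, mean, na.rm = TRUE)
  lines <- line_ids(pop$geno)
  if (!all(lines %in% names(score)))
    stop("trait '", trait, "' missing for some lines")
  s <- score[lines]
  n_keep <- max(1L, as.integer(round(retained_fraction * length(lines))))
  keep <- lines[order(-s, lines)][seq_len(n_keep)]
  keep <- lines[lines %in% keep]   # preserve original order
  out <- pop
  out$geno <- subset_geno(pop$geno, lines = keep)
  out$truth <- list(o1 = pop$truth$o1[keep, , drop = FALSE],
                    o2 = pop$truth$o2[keep, , drop = FALSE])
  mem <- pop$registry$membership
  out$registry <- cross_registry(pop$registry$crosses,
                                 mem[mem$line %in% keep, , drop = FALSE])
  out
}
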