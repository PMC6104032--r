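#' Implant a private haplotype into selected founders
#'
#' Overwrites founder calls at the given markers: carrier founders become
#' homozygous for the alternate (dosage-2) allele, every other founder
#' homozygous for the reference allele. Used to plant a guaranteed
#' exotic-private haplotype whose carrier frequency among derived lines is
#' 0.25 times the fraction of crosses with a carrier exotic parent.
#'
#' @param founders founder `geno_matrix`
#' @param markers marker ids to overwrite
#' @param carriers founder ids made homozygous carriers
#' @return list: `founders` (modified), `class` (the carrier allele string,
#'   usable in a [qtl_spec()]).
#' @export
implant_haplotype <- function(founders, markers, carriers) {
  absent <- setdiff(markers, marker_ids(founders))
  if (length(absent)) stop("unknown marker(s): ", paste(absent, collapse = ", "))
  absent <- setdiff(carriers, line_ids(founders))
  if (length(absent)) stop("unknown founder(s): ", paste(absent, collapse = ", "))
  founders$calls[, markers] <- 0L
  founders$calls[carriers, markers] <- 2L
  list(founders = founders,
       class = paste(founders$alleles[markers, 2L], collapse = ""))
}

#' Pipeline run configuration
#'
#' Either simulator-backed (`sim` given) or file-backed (`paths` given:
#' `genotypes`, `format`, `map`, `phenotypes`, `crosses`, `membership`,
#' optionally `parent_genotypes`). The configuration is validated before
#' any compute and echoed verbatim into the run directory.
#'
#' @param sim a [sim_config()] (simulator-backed runs)
#' @param paths named list of input files (file-backed runs)
#' @param qc a [qc_params()]
#' @param qtl a [qtl_spec()] for simulated phenotypes, or `NULL` for a
#'   default demo specification (planted heat-specific yield QTL on an
#'   exotic-private haplotype, neutral days-to-heading)
#' @param gwas list: `k_max`, `threshold` (NULL/number/named-by-trait),
#'   `percentile`, `pool_below`
#' @param screen list: `target_trait`, `confounder_trait`, `rare_max`,
#'   `min_instances`, `penalty_tol`
#' @param seed root seed for every stochastic stage
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), paths = NULL,
                       qc = qc_params(), qtl = NULL,
                       gwas = list(), screen = list(), seed = 1L) {
  gwas <- modifyList(list(k_max = 5L, threshold = NULL, percentile = 0.1,
                          pool_below = 0.01), gwas)
  screen <- modifyList(list(target_trait = "grain_yield",
                            confounder_trait = "days_to_heading",
                            rare_max = 0.15, min_instances = 1L,
                            penalty_tol = 0.25), screen)
  if (!is.null(paths)) {
    need <- c("genotypes", "map", "phenotypes", "crosses", "membership")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths must include: ", paste(miss, collapse = ", "))
    gone <- unlist(paths[intersect(names(paths), c(need, "parent_genotypes"))])
    gone <- gone[!file.exists(gone)]
    if (length(gone))
      stop("input file(s) not found: ", paste(gone, collapse = ", "))
  } else if (!inherits(sim, "sim_config")) {
    stop("either a sim_config or input paths must be supplied")
  }
  structure(list(sim = sim, paths = paths, qc = qc, qtl = qtl,
                 gwas = gwas, screen = screen, seed = as.integer(seed)),
            class = "run_config")
}

# demo phenotype model: one exotic-private rare haplotype with a
# heat-specific yield effect and no irrigated penalty; days_to_heading
# left unassociated. effect_sd is in units of the total non-QTL phenotypic
# SD: residual_var + 2 * polygenic_var, the factor 2 being the kinship
# diagonal of fully inbred lines.
demo_qtl_spec <- function(markers, class, effect_sd = 1, residual_sd = 500) {
  env_means <- rbind(
    data.frame(trait = "grain_yield", env = c("heat", "drought", "irrigated"),
               mean = c(3000, 2500, 6000)),
    data.frame(trait = "days_to_heading", env = "irrigated", mean = 80))
  polygenic_var <- (0.3 * residual_sd)^2
  total_sd <- sqrt(residual_sd^2 + 2 * polygenic_var)
  qtl_spec(env_means,
           qtl = list(list(markers = markers, class = class,
                           effect = effect_sd * total_sd,
                           trait = "grain_yield", envs = "heat")),
           polygenic_var = polygenic_var,
           residual_var = residual_sd^2)
}

# pick the tightest run of n adjacent markers (within window cM) on a
# chromosome: a physically compact planted block minimizes recombinant
# haplotypes among derived lines, as in real small haplotype blocks
pick_block_markers <- function(map, chrom_idx = 1L, n = 3L, window = 5) {
  cm <- map[map$chrom_idx == chrom_idx, , drop = FALSE]
  if (nrow(cm) < n)
    stop("chromosome ", chrom_idx, " has fewer than ", n, " markers")
  spans <- cm$cM[n:nrow(cm)] - cm$cM[seq_len(nrow(cm) - n + 1L)]
  best <- which.min(spans)
  if (spans[best] > window)
    stop("no run of ", n, " markers within ", window, " cM on chromosome ",
         chrom_idx)
  cm$marker[best:(best + n - 1L)]
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  attr(res, ".elapsed") <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: simulate (or load) inputs; marker QC;
#' haplotype-block construction; parent-of-origin tracing and
#' exotic-specific block identification; mixed-model association scan;
#' rare-favorable-haplotype screen. All tables are written as TSV/CSV into
#' `out_dir` together with a JSON manifest (seed, stage timings, output
#' checksums, package version). Reruns with the same configuration and
#' seed are bit-identical.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created; existing files overwritten)
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- clock("inputs", {
    if (!is.null(config$paths)) {
      p <- config$paths
      fmt <- if (is.null(p$format)) "hapmap" else p$format
      G <- read_genotypes(p$genotypes, fmt)
      list(geno = G,
           map = read_map(p$map),
           traits = read_phenotypes(p$phenotypes),
           registry = read_crosses(p$crosses, p$membership),
           parents = if (!is.null(p$parent_genotypes))
             read_genotypes(p$parent_genotypes, fmt) else G,
           truth = NULL)
    } else {
      cfg <- config$sim
      cfg$seed <- config$seed
      map <- sim_genetic_map(cfg)
      founders <- simulate_founders(cfg, map)
      qtl <- config$qtl
      if (is.null(qtl)) {
        mks <- pick_block_markers(map, chrom_idx = min(6L, cfg$n_chromosomes),
                                  n = 3L, window = config$qc$ld_window)
        carriers <- paste0("EX", seq_len(max(1L,
          round(0.4 * cfg$n_exotic_founders))))
        imp <- implant_haplotype(founders, mks, carriers)
        founders <- imp$founders
        qtl <- demo_qtl_spec(mks, imp$class)
      }
      pop <- simulate_topcross_population(founders, map, cfg)
      traits <- simulate_phenotypes(pop, qtl, seed = config$seed)
      list(geno = pop$geno, map = map, traits = traits,
           registry = pop$registry, parents = founders, truth = pop$truth)
    }
  })
  write_genotypes(inputs$geno, file.path(out_dir, "genotypes.hmp.txt"),
                  inputs$map)
  write_map(inputs$map, file.path(out_dir, "map.tsv"))
  write_phenotypes(inputs$traits, file.path(out_dir, "phenotypes.csv"))
  write_crosses(inputs$registry, file.path(out_dir, "crosses.csv"),
                file.path(out_dir, "membership.csv"))

  qc <- clock("qc", qc_filter(inputs$geno, inputs$map, config$qc))
  write.table(qc$report, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  blocks <- clock("blocks", find_blocks(qc$geno, qc$map, config$qc))
  write_blocks(blocks, file.path(out_dir, "blocks.tsv"))

  trace <- clock("trace", {
    origin <- classify_abh_all(inputs$geno, inputs$registry, inputs$parents)
    summ <- summarize_contribution(origin, inputs$map, inputs$registry)
    pid <- line_ids(inputs$parents)
    exo_ids <- intersect(unique(inputs$registry$crosses$exotic), pid)
    eli_ids <- intersect(unique(unlist(
      inputs$registry$crosses[, c("elite1", "elite2")])), pid)
    spec <- exotic_specific_blocks(
      blocks, qc$geno,
      subset_geno(inputs$parents, lines = exo_ids),
      subset_geno(inputs$parents, lines = eli_ids))
    list(origin = origin, summary = summ, exotic_specific = spec)
  })
  write.table(trace$summary$per_line,
              file.path(out_dir, "contribution_per_line.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(trace$summary$panel, file.path(out_dir, "contribution_panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(trace$origin)),
                   file.path(out_dir, "origin_matrix.csv"))

  scan <- clock("gwas", scan_features(
    blocks, qc$geno, inputs$traits, map = qc$map,
    k_max = config$gwas$k_max, threshold = config$gwas$threshold,
    percentile = config$gwas$percentile,
    pool_below = config$gwas$pool_below))
  write_associations(scan, file.path(out_dir, "associations.tsv"))

  screened <- clock("screen", {
    profiles <- class_profiles(blocks, qc$geno, inputs$traits)
    sc <- config$screen
    cands <- screen_rare_favorable(
      profiles, scan, inputs$traits, sc$target_trait,
      confounder_trait = sc$confounder_trait, rare_max = sc$rare_max,
      min_instances = sc$min_instances, penalty_tol = sc$penalty_tol,
      exotic_flags = trace$exotic_specific$flags)
    cm <- consistency_matrix(scan)
    list(profiles = profiles, candidates = cands, consistency = cm)
  })
  write.table(screened$profiles, file.path(out_dir, "class_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(screened$candidates, file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cm_df <- data.frame(feature = rownames(screened$consistency$matrix),
                      ifelse(screened$consistency$matrix, "*", ""),
                      n_significant = screened$consistency$row_sums,
                      check.names = FALSE)
  write.table(cm_df, file.path(out_dir, "consistency_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("introhap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    timings_sec = as.list(timings),
    n_lines = nrow(inputs$geno$calls),
    n_markers_input = ncol(inputs$geno$calls),
    n_markers_qc = ncol(qc$geno$calls),
    n_blocks = length(blocks),
    exotic_imprint_fraction = trace$exotic_specific$imprint_fraction,
    panel_exotic_est = trace$summary$panel$exotic_est,
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(inputs = inputs, qc = qc, blocks = blocks, trace = trace,
                 scan = scan, screen = screened, manifest = manifest))
}
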