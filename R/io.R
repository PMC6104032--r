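#' Phenotype table
#'
#' Replicate-mean trait values per line, trait and environment.
#'
#' @param df data.frame with columns `line`, `trait`, `env`, `value`
#' @return validated data.frame of class `trait_table`.
#' @export
trait_table <- function(df) {
  need <- c("line", "trait", "env", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$line <- as.character(df$line)
  df$trait <- as.character(df$trait)
  df$env <- as.character(df$env)
  df$value <- as.numeric(df$value)
  key <- paste(df$line, df$trait, df$env, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, trait, environment) record(s), e.g. ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  if (any(is.infinite(df$value)))
    stop("phenotype values must be finite or missing")
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Cross registry
#'
#' Maps each three-way cross to its exotic, elite1 and elite2 parents and
#' each derived line to its cross.
#'
#' @param crosses data.frame with columns `cross_id`, `exotic`, `elite1`, `elite2`
#' @param membership data.frame with columns `line`, `cross_id`
#' @return object of class `cross_registry`.
#' @export
cross_registry <- function(crosses, membership) {
  needc <- c("cross_id", "exotic", "elite1", "elite2")
  if (!all(needc %in% names(crosses)))
    stop("cross table needs columns: ", paste(needc, collapse = ", "))
  crosses <- data.frame(lapply(crosses[, needc], as.character),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(crosses$cross_id))
    stop("duplicate cross_id in cross table")
  if (!all(c("line", "cross_id") %in% names(membership)))
    stop("membership table needs columns: line, cross_id")
  membership <- data.frame(line = as.character(membership$line),
                           cross_id = as.character(membership$cross_id),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(membership$line))
    stop("a line may belong to exactly one cross; duplicated: ",
         membership$line[duplicated(membership$line)][1L])
  unknown <- setdiff(membership$cross_id, crosses$cross_id)
  if (length(unknown))
    stop("membership references unknown cross_id: ", unknown[1L])
  structure(list(crosses = crosses, membership = membership),
            class = "cross_registry")
}

#' Lines belonging to a cross
#' @param registry a `cross_registry`
#' @param cross_id cross identifier
#' @return character vector of line ids.
#' @export
cross_lines <- function(registry, cross_id) {
  registry$membership$line[registry$membership$cross_id == cross_id]
}

#' Parent ids of a cross
#' @param registry a `cross_registry`
#' @param cross_id cross identifier
#' @return named character vector (exotic, elite1, elite2).
#' @export
cross_parents <- function(registry, cross_id) {
  row <- registry$crosses[registry$crosses$cross_id == cross_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown cross_id: ", cross_id)
  c(exotic = row$exotic, elite1 = row$elite1, elite2 = row$elite2)
}

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `"hapmap"` is a HapMap-style TSV with columns
#' `rs`, `alleles` (e.g. `"A/T"`), `chrom`, `pos`, then one column per line
#' holding two-letter calls (`AA`, `AT`, ...), single-letter IUPAC codes, or
#' `NN`/`N`/`--` for missing. `"vcf"` is VCF 4.x, GT field only, read via the
#' vcfR package; `./.` maps to missing, `0/0`/`0/1`/`1/1` to dosages 0/1/2.
#'
#' @param path input file
#' @param format `"hapmap"` or `"vcf"`
#' @param multiallelic for VCF, `"error"` (default) rejects records with more
#'   than one ALT allele, `"skip"` drops them with a warning.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("hapmap", "vcf"),
                           multiallelic = c("error", "skip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         hapmap = read_hapmap(path),
         vcf = read_vcf(path, match.arg(multiallelic)))
}

read_hapmap <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("rs", "alleles")
  if (!all(need %in% names(df)))
    stop("malformed hapmap header at line 1: need columns 'rs' and 'alleles'")
  if (anyDuplicated(df$rs))
    stop("duplicate marker id in hapmap file: ", df$rs[duplicated(df$rs)][1L])
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  if (any(lengths(al) != 2L))
    stop("malformed alleles field at line ", which(lengths(al) != 2L)[1L] + 1L)
  alleles <- do.call(rbind, al)
  rownames(alleles) <- df$rs
  line_cols <- setdiff(names(df), c("rs", "alleles", "chrom", "pos"))
  if (!length(line_cols)) stop("hapmap file has no line columns")
  calls <- matrix(NA_integer_, length(line_cols), nrow(df),
                  dimnames = list(line_cols, df$rs))
  for (j in seq_len(nrow(df))) {
    a0 <- alleles[j, 1L]; a2 <- alleles[j, 2L]
    raw <- toupper(as.character(df[j, line_cols]))
    raw[raw %in% c("NN", "N", "--", "", "NA")] <- NA
    two <- !is.na(raw) & nchar(raw) == 2L
    one <- !is.na(raw) & nchar(raw) == 1L
    d <- rep(NA_integer_, length(raw))
    if (any(two)) {
      l1 <- substr(raw[two], 1L, 1L); l2 <- substr(raw[two], 2L, 2L)
      d[two] <- ifelse(l1 == a0 & l2 == a0, 0L,
                ifelse(l1 == a2 & l2 == a2, 2L,
                ifelse((l1 == a0 & l2 == a2) | (l1 == a2 & l2 == a0), 1L,
                       NA_integer_)))
      if (anyNA(d[two]))
        stop("call inconsistent with alleles ", a0, "/", a2,
             " for marker ", df$rs[j])
    }
    if (any(one)) {
      s <- raw[one]
      d1 <- rep(NA_integer_, length(s))
      d1[s == a0] <- 0L
      d1[s == a2] <- 2L
      hh <- s %in% names(iupac_het)
      if (any(hh)) {
        pair <- iupac_het[s[hh]]
        ok <- pair == paste0(a0, a2) | pair == paste0(a2, a0) |
          vapply(pair, function(p) {
            setequal(strsplit(p, "")[[1L]], c(a0, a2))
          }, logical(1L))
        if (!all(ok))
          stop("IUPAC call inconsistent with alleles for marker ", df$rs[j])
        d1[hh] <- 1L
      }
      if (anyNA(d1))
        stop("unrecognized call for marker ", df$rs[j])
      d[one] <- d1
    }
    calls[, j] <- d
  }
  geno_matrix(calls, alleles)
}

read_vcf <- function(path, multiallelic) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic VCF record(s), first at ",
           fix[multi, "CHROM"][1L], ":", fix[multi, "POS"][1L])
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  if (anyDuplicated(ids))
    stop("duplicate marker id in VCF: ", ids[duplicated(ids)][1L])
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d <- matrix(NA_integer_, nrow(gt), ncol(gt))
  d[gt %in% "0/0"] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% "1/1"] <- 2L
  calls <- t(d)
  dimnames(calls) <- list(colnames(gt), ids)
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  rownames(alleles) <- ids
  geno_matrix(calls, alleles)
}

#' Write a genotype matrix as HapMap-style TSV
#'
#' @param G a `geno_matrix`
#' @param path output file
#' @param map optional `genetic_map` supplying `chrom`/`pos` columns
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, map = NULL) {
  mk <- marker_ids(G)
  al <- G$alleles
  chrom <- pos <- rep(NA, length(mk))
  if (!is.null(map)) {
    i <- match(mk, map$marker)
    chrom <- map$chrom[i]; pos <- map$cM[i]
  }
  cells <- matrix("NN", length(mk), nrow(G$calls))
  for (j in seq_along(mk)) {
    d <- G$calls[, j]
    s <- rep("NN", length(d))
    s[!is.na(d) & d == 0L] <- strrep(al[j, 1L], 2L)
    s[!is.na(d) & d == 2L] <- strrep(al[j, 2L], 2L)
    s[!is.na(d) & d == 1L] <- paste0(al[j, 1L], al[j, 2L])
    cells[j, ] <- s
  }
  out <- data.frame(rs = mk, alleles = paste(al[, 1L], al[, 2L], sep = "/"),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c("rs", "alleles", "chrom", "pos", line_ids(G))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' TSV with header `marker`, `chrom`, `cM`.
#' @param path input file
#' @param chrom_levels ordered chromosome labels (default wheat 1A..7D)
#' @return a [genetic_map()].
#' @export
read_map <- function(path, chrom_levels = wheat_chromosomes()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% names(df)))
    stop("malformed map header at line 1: need columns ",
         paste(need, collapse = ", "))
  genetic_map(df$marker, df$chrom, df$cM, chrom_levels)
}

#' @rdname read_map
#' @param map a `genetic_map` to write
#' @export
write_map <- function(map, path) {
  write.table(map[, c("marker", "chrom", "cM")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header `line`, `trait`, `env`, `value`.
#' @param path input file
#' @return a [trait_table()].
#' @export
read_phenotypes <- function(path) {
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_phenotypes
#' @param traits a `trait_table` to write
#' @export
write_phenotypes <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cross registry
#'
#' @param crosses_path CSV with header `cross_id`, `exotic`, `elite1`, `elite2`
#' @param membership_path CSV with header `line`, `cross_id`
#' @return a [cross_registry()].
#' @export
read_crosses <- function(crosses_path, membership_path) {
  cross_registry(utils::read.csv(crosses_path, stringsAsFactors = FALSE),
                 utils::read.csv(membership_path, stringsAsFactors = FALSE))
}

#' @rdname read_crosses
#' @param registry a `cross_registry` to write
#' @export
write_crosses <- function(registry, crosses_path, membership_path) {
  utils::write.csv(registry$crosses, crosses_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(registry$membership, membership_path, row.names = FALSE,
                   quote = FALSE)
  invisible(crosses_path)
}

#' Write haplotype blocks as TSV
#'
#' One row per block: `chrom`, `start_cM`, `end_cM`, `name`, `n_markers`,
#' `markers` (semicolon-joined, map order), `classes`
#' (`class:frequency` pairs, semicolon-joined).
#'
#' @param blocks list of haplotype blocks from [find_blocks()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    data.frame(chrom = b$chrom, start_cM = b$start_cM, end_cM = b$end_cM,
               name = b$name, n_markers = length(b$markers),
               markers = paste(b$markers, collapse = ";"),
               classes = paste(sprintf("%s:%.10g", names(b$class_freq),
                                       b$class_freq), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start_cM = numeric(), end_cM = numeric(),
               name = character(), n_markers = integer(), markers = character(),
               classes = character(), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association scan result table as TSV
#'
#' Columns: `feature`, `trait`, `env`, `p`, `df`, `effects` (per-class effect
#' estimates as `class:effect` pairs), `significant`, `qq_deviates`.
#'
#' @param results data.frame from [scan_features()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_associations <- function(results, path) {
  cols <- c("feature", "trait", "env", "p", "df", "effects",
            "significant", "qq_deviates")
  if (!nrow(results)) {
    results <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                      cols), stringsAsFactors = FALSE)
  } else {
    missing_cols <- setdiff(cols, names(results))
    for (m in missing_cols) results[[m]] <- NA
    results <- results[, cols]
  }
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
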