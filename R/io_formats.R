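## Readers and writers for the standard formats the simulator touches:
## phased VCF, Oxford haps/sample, genetic-map text, PLINK PED/MAP, and a
## versioned population snapshot.

#' Read a phased VCF into a haplotype panel
#'
#' Accepts biallelic SNP records whose GT fields are all phased (`"|"`).
#' One haplotype row is produced per sample haplotype, in deterministic
#' order: sample order x (hap0, hap1). Allele 1 codes the record's ALT.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @return a `haplotype_panel` with REF/ALT letters kept as locus metadata.
#' @export
read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  bad_alt <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(bad_alt))
    stop("multi-allelic record at ", fix[which(bad_alt)[1L], "CHROM"], ":",
         fix[which(bad_alt)[1L], "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  slash <- grepl("/", gt, fixed = TRUE)
  if (any(slash)) {
    rec <- arrayInd(which(slash)[1L], dim(gt))
    stop("unphased genotype at ", fix[rec[1L], "CHROM"], ":",
         fix[rec[1L], "POS"], " sample ", colnames(gt)[rec[2L]])
  }
  if (any(grepl(".", gt, fixed = TRUE)))
    stop("missing allele ('.') in GT field; the panel must be fully phased and called")
  L <- nrow(gt); S <- ncol(gt)
  a0 <- substr(gt, 1L, 1L); a1 <- substr(gt, 3L, 3L)
  if (!all(c(a0, a1) %in% c("0", "1")))
    stop("GT alleles must be 0 or 1 (biallelic panel)")
  haps <- matrix(0L, nrow = 2L * S, ncol = L)
  haps[2L * seq_len(S) - 1L, ] <- t(matrix(as.integer(a0), L, S))
  haps[2L * seq_len(S), ]      <- t(matrix(as.integer(a1), L, S))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("snp%d", which(is.na(ids) | ids == "."))
  loci <- locus_table(ids, fix[, "CHROM"], as.integer(fix[, "POS"]))
  loci$ref <- fix[, "REF"]; loci$alt <- fix[, "ALT"]
  haplotype_panel(haps, loci, colnames(gt))
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a `haplotype_panel`.
#' @param path output path (plain text).
#' @export
write_phased_vcf <- function(panel, path) {
  loci <- panel$loci
  ref <- if (!is.null(loci$ref)) loci$ref else rep("A", nrow(loci))
  alt <- if (!is.null(loci$alt)) loci$alt else rep("G", nrow(loci))
  S <- length(panel$sample_ids)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=fwdgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  h <- panel$haps
  for (j in seq_len(nrow(loci))) {
    gts <- paste0(h[2L * seq_len(S) - 1L, j], "|", h[2L * seq_len(S), j])
    writeLines(paste(c(loci$chrom[j], loci$pos_bp[j], loci$name[j], ref[j],
                       alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read Oxford .haps/.sample files into a haplotype panel
#'
#' Expects one `.haps` row per SNP (`chrom id pos a0 a1` then 2N 0/1 alleles)
#' and a standard `.sample` file with its two header lines.
#'
#' @param haps_path path to the `.haps` file.
#' @param sample_path path to the `.sample` file.
#' @return a `haplotype_panel`.
#' @export
read_oxford_haps <- function(haps_path, sample_path) {
  smp <- utils::read.table(sample_path, header = FALSE, skip = 2L,
                           stringsAsFactors = FALSE)
  ids <- as.character(smp[[2L]])
  tab <- utils::read.table(haps_path, header = FALSE, stringsAsFactors = FALSE)
  L <- nrow(tab)
  if (ncol(tab) != 5L + 2L * length(ids))
    stop(".haps rows carry ", ncol(tab) - 5L, " alleles but .sample lists ",
         length(ids), " individuals (need ", 2L * length(ids), ")")
  am <- as.matrix(tab[, -(1:5), drop = FALSE])
  if (!all(am %in% c(0, 1))) stop(".haps alleles must be 0 or 1")
  haps <- t(am); storage.mode(haps) <- "integer"
  dimnames(haps) <- NULL
  loci <- locus_table(as.character(tab[[2L]]), as.character(tab[[1L]]),
                      as.integer(tab[[3L]]))
  loci$ref <- as.character(tab[[4L]]); loci$alt <- as.character(tab[[5L]])
  haplotype_panel(haps, loci, ids)
}

#' Write a haplotype panel as Oxford .haps/.sample files
#' @param panel a `haplotype_panel`.
#' @param prefix output path prefix (`<prefix>.haps`, `<prefix>.sample`).
#' @export
write_oxford_haps <- function(panel, prefix) {
  loci <- panel$loci
  ref <- if (!is.null(loci$ref)) loci$ref else rep("A", nrow(loci))
  alt <- if (!is.null(loci$alt)) loci$alt else rep("G", nrow(loci))
  rows <- cbind(loci$chrom, loci$name, loci$pos_bp, ref, alt, t(panel$haps))
  utils::write.table(rows, paste0(prefix, ".haps"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- panel$sample_ids
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(ids, ids, "0")), paste0(prefix, ".sample"))
  invisible(prefix)
}

## Genetic map ---------------------------------------------------------------

#' Read a fine-scale genetic map
#'
#' Whitespace-delimited, three columns (`pos_bp rate_cM_per_Mb cumulative_cM`,
#' one chromosome per file) or four (`chrom` first). A header row is detected
#' by a non-numeric first token and skipped.
#'
#' @param path path to the map file.
#' @param chrom chromosome label used when the file has no chrom column;
#'   `NA` means "applies to any chromosome".
#' @return a `genetic_map`: data.frame with columns `chrom`, `pos_bp`,
#'   `rate_cM_per_Mb`, `cumulative_cM`.
#' @export
read_genetic_map <- function(path, chrom = NA_character_) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1L]]
  has_header <- suppressWarnings(is.na(as.numeric(first[length(first)])))
  tab <- utils::read.table(path, header = FALSE, skip = as.integer(has_header),
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 3L) {
    map <- data.frame(chrom = chrom, pos_bp = as.numeric(tab[[1L]]),
                      rate_cM_per_Mb = as.numeric(tab[[2L]]),
                      cumulative_cM = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 4L) {
    map <- data.frame(chrom = as.character(tab[[1L]]), pos_bp = as.numeric(tab[[2L]]),
                      rate_cM_per_Mb = as.numeric(tab[[3L]]),
                      cumulative_cM = as.numeric(tab[[4L]]),
                      stringsAsFactors = FALSE)
  } else stop("genetic map needs 3 or 4 columns")
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  for (ch in unique(map$chrom)) {
    sub <- map[is.na(map$chrom) | map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0) || any(diff(sub$cumulative_cM) < 0))
      stop("genetic map must be monotone in pos_bp and cumulative_cM")
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Assign cumulative genetic positions to panel loci
#'
#' Interpolates cumulative cM linearly in physical position between flanking
#' map rows; loci outside the map range are extrapolated with the nearest
#' row's local rate. With `map = NULL` a physical map is used instead, at a
#' constant recombination rate of 0.01 per Mbp (1 cM/Mb), i.e.
#' `cM = pos_bp * 1e-8 * 100`.
#'
#' @param panel a `haplotype_panel` (or a `population`).
#' @param map a `genetic_map` from [read_genetic_map()], or `NULL`.
#' @return the input object with its locus table's `cm` column filled.
#' @export
assign_cm <- function(panel, map = NULL) {
  loci <- panel$loci
  if (is.null(map)) {
    loci$cm <- loci$pos_bp * 1e-8 * 100
  } else {
    validate_genetic_map(map)
    cm <- numeric(nrow(loci))
    for (ch in unique(loci$chrom)) {
      sub <- map[is.na(map$chrom) | map$chrom == ch, ]
      if (nrow(sub) == 0L) stop("genetic map does not cover chromosome ", ch)
      sel <- which(loci$chrom == ch)
      cm[sel] <- interp_cm(loci$pos_bp[sel], sub)
    }
    loci$cm <- cm
  }
  panel$loci <- loci
  panel
}

interp_cm <- function(pos, map) {
  if (nrow(map) == 1L)
    return(map$cumulative_cM + (pos - map$pos_bp) * map$rate_cM_per_Mb * 1e-6)
  out <- stats::approx(map$pos_bp, map$cumulative_cM, xout = pos,
                       rule = 1, ties = "ordered")$y
  below <- pos < map$pos_bp[1L]
  above <- pos > map$pos_bp[nrow(map)]
  out[below] <- map$cumulative_cM[1L] -
    (map$pos_bp[1L] - pos[below]) * map$rate_cM_per_Mb[1L] * 1e-6
  out[above] <- map$cumulative_cM[nrow(map)] +
    (pos[above] - map$pos_bp[nrow(map)]) * map$rate_cM_per_Mb[nrow(map)] * 1e-6
  out
}

## PLINK PED/MAP and covariates ---------------------------------------------

#' Write a sample as PLINK PED/MAP text files
#'
#' PED columns are FID IID PAT MAT SEX PHENO followed by two alleles per
#' locus coded 1/2 (1 = reference/0, 2 = alternate/1). Phenotype is coded
#' 2 = affected, 1 = unaffected, -9 = unknown. MAP columns are chrom, marker
#' name, cM and bp position.
#'
#' @param sample a `gwas_sample` (see the sampling functions).
#' @param prefix output prefix (`<prefix>.ped`, `<prefix>.map`).
#' @export
write_ped_map <- function(sample, prefix) {
  ind <- sample$ind
  h <- sample$haps + 1L                     # 0/1 -> 1/2
  n <- nrow(ind)
  a0 <- h[2L * seq_len(n) - 1L, , drop = FALSE]
  a1 <- h[2L * seq_len(n), , drop = FALSE]
  geno <- matrix("", n, 2L * ncol(h))
  geno[, seq(1L, 2L * ncol(h), by = 2L)] <- as.character(a0)
  geno[, seq(2L, 2L * ncol(h), by = 2L)] <- as.character(a1)
  pheno <- ifelse(is.na(ind$pheno), -9L, ifelse(ind$pheno, 2L, 1L))
  ped <- cbind(ind$fid, ind$iid, ind$pat, ind$mat, ind$sex, pheno, geno)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  loci <- sample$loci
  cm <- ifelse(is.na(loci$cm), 0, loci$cm)
  utils::write.table(cbind(loci$chrom, loci$name, cm, loci$pos_bp),
                     paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write per-individual covariates (environment, ancestry) as TSV
#' @param sample a `gwas_sample`.
#' @param path output path.
#' @export
write_covariate_tsv <- function(sample, path) {
  utils::write.table(
    data.frame(IID = sample$ind$iid, env = sample$ind$env,
               ancestry = sample$ind$ancestry),
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

## Snapshot ------------------------------------------------------------------

SNAPSHOT_VERSION <- 1L

#' Save / load a population snapshot
#'
#' A single-file container carrying an explicit format-version field; the
#' round trip is bit-exact, including the generation counter and the stored
#' RNG state.
#'
#' @param pop a `population`.
#' @param path snapshot path.
#' @return `read_population_snapshot` returns the `population`.
#' @export
write_population_snapshot <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  saveRDS(list(format = "fwdgwas_snapshot", version = SNAPSHOT_VERSION,
               population = pop), path)
  invisible(path)
}

#' @rdname write_population_snapshot
#' @export
read_population_snapshot <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fwdgwas_snapshot"))
    stop("not a fwdgwas population snapshot: ", path)
  if (x$version > SNAPSHOT_VERSION)
    stop("snapshot version ", x$version, " is newer than this package supports")
  x$population
}
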