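## Core containers -----------------------------------------------------------

#' Construct a locus table
#'
#' Marker metadata shared by haplotype panels and populations. Alleles are
#' coded 0/1 throughout the package, with 1 the alternate allele of the input
#' panel; original allele letters, if known, are carried as metadata columns.
#'
#' @param name character vector of marker identifiers.
#' @param chrom chromosome labels (character or coercible).
#' @param pos_bp 1-based physical positions in bp; strictly increasing within
#'   each chromosome.
#' @param cm cumulative genetic positions in centimorgans; non-decreasing
#'   within each chromosome. May be `NA` until a map is assigned (see
#'   [assign_cm()]).
#' @return a `data.frame` with columns `name`, `chrom`, `pos_bp`, `cm`.
#' @export
locus_table <- function(name, chrom, pos_bp, cm = NA_real_) {
  loci <- data.frame(
    name = as.character(name), chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp), cm = as.numeric(cm),
    stringsAsFactors = FALSE
  )
  validate_loci(loci)
  loci
}

validate_loci <- function(loci) {
  stopifnot(all(c("name", "chrom", "pos_bp", "cm") %in% names(loci)))
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, ]
    if (nrow(sub) > 1L) {
      if (any(diff(sub$pos_bp) <= 0))
        stop("pos_bp must be strictly increasing within chromosome ", ch)
      cms <- sub$cm[!is.na(sub$cm)]
      if (length(cms) == nrow(sub) && any(diff(cms) < 0))
        stop("cm must be non-decreasing within chromosome ", ch)
    }
  }
  invisible(loci)
}

#' Construct a phased haplotype panel
#'
#' The seed of every simulation: an H x L binary matrix of phased haplotypes
#' (H haplotypes, L loci) plus per-locus metadata. Consecutive haplotype rows
#' (1,2), (3,4), ... pair into diploid source individuals.
#'
#' @param haps integer/numeric matrix with entries in \{0, 1\}; one row per
#'   haplotype, one column per locus.
#' @param loci a locus table (see [locus_table()]) with `nrow(loci) == ncol(haps)`.
#' @param sample_ids optional character vector of length `nrow(haps)/2` naming
#'   the diploid source individuals.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, loci, sample_ids = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (!all(haps %in% c(0L, 1L))) stop("haplotype entries must be 0 or 1")
  validate_loci(loci)
  if (ncol(haps) != nrow(loci))
    stop("panel has ", ncol(haps), " columns but ", nrow(loci), " loci")
  if (is.null(sample_ids)) {
    if (nrow(haps) %% 2L != 0L)
      stop("odd number of haplotypes with no explicit pairing")
    sample_ids <- sprintf("ind%d", seq_len(nrow(haps) %/% 2L))
  } else if (length(sample_ids) * 2L != nrow(haps)) {
    stop("sample_ids must pair consecutive haplotype rows (length H/2)")
  }
  structure(list(haps = haps, loci = loci, sample_ids = as.character(sample_ids)),
            class = "haplotype_panel")
}

#' @method print haplotype_panel
#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$haps), " haplotypes x ", nrow(x$loci),
      " loci (", length(unique(x$loci$chrom)), " chromosome(s))\n", sep = "")
  invisible(x)
}

#' @method dim haplotype_panel
#' @export
dim.haplotype_panel <- function(x) dim(x$haps)

## Population ----------------------------------------------------------------

new_subpop <- function(haps, sex, ancestry, affected = NULL, env = NULL) {
  n <- nrow(haps) %/% 2L
  if (is.null(affected)) affected <- rep(NA, n)
  if (is.null(env)) env <- rep(NA_real_, n)
  list(haps = haps, sex = sex, ancestry = ancestry,
       affected = affected, env = env)
}

#' Construct / initialize a diploid population from haplotype panels
#'
#' Each source individual of a panel (two consecutive haplotype rows) becomes
#' `copies` diploid individuals carrying those two phased haplotypes. Sexes
#' alternate male/female in construction order so both sexes always exist;
#' ancestry is initialized to `ancestry` (default 0) and becomes meaningful
#' only after an admixture setup assigns distinct values per subpopulation.
#'
#' @param panel a `haplotype_panel`, or a list of panels sharing one locus
#'   table — one subpopulation is created per panel.
#' @param copies integer >= 1; number of identical copies per source individual.
#' @param ancestry scalar or per-panel vector of initial ancestry values in
#'   \[0, 1\].
#' @return an object of class `population` with fields `loci`, `subpops`,
#'   `generation` (= 0) and `rng_state`.
#' @export
initialize_population <- function(panel, copies = 1L, ancestry = 0) {
  panels <- if (inherits(panel, "haplotype_panel")) list(panel) else panel
  stopifnot(length(panels) >= 1L, copies >= 1L)
  loci <- panels[[1L]]$loci
  ancestry <- rep_len(ancestry, length(panels))
  subpops <- vector("list", length(panels))
  for (k in seq_along(panels)) {
    p <- panels[[k]]
    if (!identical(p$loci$name, loci$name))
      stop("all panels must share one locus list")
    H <- nrow(p$haps)
    if (H %% 2L != 0L) stop("odd number of haplotypes with no explicit pairing")
    n_src <- H %/% 2L
    idx <- rep(seq_len(n_src), each = copies)       # source individual per child
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haps <- p$haps[rows, , drop = FALSE]
    n <- n_src * copies
    sex <- rep_len(c(1L, 2L), n)                    # 1 = male, 2 = female
    subpops[[k]] <- new_subpop(haps, sex, rep(ancestry[k], n))
  }
  structure(list(loci = loci, subpops = subpops, generation = 0L,
                 rng_state = NULL),
            class = "population")
}

#' @method print population
#' @export
print.population <- function(x, ...) {
  sizes <- vapply(x$subpops, function(s) nrow(s$haps) %/% 2L, integer(1))
  cat("<population> generation ", x$generation, "; ",
      length(sizes), " subpop(s) of size ", paste(sizes, collapse = ", "),
      "; ", nrow(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Number of diploid individuals
#' @param pop a `population`.
#' @param subpop optional subpopulation index; default totals all.
#' @export
pop_size <- function(pop, subpop = NULL) {
  sizes <- vapply(pop$subpops, function(s) nrow(s$haps) %/% 2L, integer(1))
  if (is.null(subpop)) sum(sizes) else sizes[subpop]
}

## pooled 2N x L haplotype matrix
pop_haps <- function(pop, subpop = NULL) {
  if (!is.null(subpop)) return(pop$subpops[[subpop]]$haps)
  do.call(rbind, lapply(pop$subpops, `[[`, "haps"))
}

## per-individual field pooled over subpops
pop_field <- function(pop, field) {
  unlist(lapply(pop$subpops, `[[`, field), use.names = FALSE)
}

#' Alternate-allele frequency at a locus
#'
#' Count of allele 1 divided by 2N over the chosen scope.
#'
#' @param pop a `population`.
#' @param locus_index locus index (1-based column).
#' @param subpop optional subpopulation index; default pools all.
#' @return frequency in \[0, 1\].
#' @export
allele_frequency <- function(pop, locus_index, subpop = NULL) {
  stopifnot(locus_index >= 1L, locus_index <= nrow(pop$loci))
  h <- pop_haps(pop, subpop)
  if (nrow(h) == 0L) stop("cannot compute allele frequency of an empty population")
  mean(h[, locus_index])
}

#' Subset a haplotype panel by region, frequency or name
#'
#' Filters compose: a locus is kept iff it passes every filter supplied.
#' Locus order is preserved and haplotype rows are untouched. The region
#' filter is a closed interval on 1-based physical positions (both ends
#' inclusive). The MAF filter keeps loci with minor-allele frequency greater
#' than or equal to `maf_min`.
#'
#' @param panel a `haplotype_panel`.
#' @param region optional `list(chrom, start_bp, end_bp)` (or length-3 vector).
#' @param maf_min optional minimum minor-allele frequency.
#' @param keep_names optional character vector of marker names to keep.
#' @param max_markers optional cap: keep the first `max_markers` surviving loci.
#' @return a `haplotype_panel` (possibly with zero loci, with a warning).
#' @export
select_markers <- function(panel, region = NULL, maf_min = NULL,
                           keep_names = NULL, max_markers = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- rep(TRUE, nrow(panel$loci))
  if (!is.null(region)) {
    region <- as.list(region)
    keep <- keep & panel$loci$chrom == as.character(region[[1L]]) &
      panel$loci$pos_bp >= as.numeric(region[[2L]]) &
      panel$loci$pos_bp <= as.numeric(region[[3L]])
  }
  if (!is.null(maf_min)) {
    p <- colMeans(panel$haps)
    keep <- keep & pmin(p, 1 - p) >= maf_min
  }
  if (!is.null(keep_names)) keep <- keep & panel$loci$name %in% keep_names
  idx <- which(keep)
  if (!is.null(max_markers)) idx <- utils::head(idx, max_markers)
  if (length(idx) == 0L) warning("no markers survive the requested filters")
  haplotype_panel(panel$haps[, idx, drop = FALSE],
                  panel$loci[idx, , drop = FALSE],
                  panel$sample_ids)
}

#' Extract the current population as a haplotype panel
#'
#' @param pop a `population`.
#' @param subpop optional subpopulation index; default pools all.
#' @return a `haplotype_panel` over the population's loci.
#' @export
as_panel <- function(pop, subpop = NULL) {
  haplotype_panel(pop_haps(pop, subpop), pop$loci)
}
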