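## Synthetic haplotype-panel generator. Produces panels with the two
## statistical properties the simulator relies on from real reference
## panels — block-wise LD (high within-block D') and a floor on the
## minor-allele-frequency spectrum at kb-scale marker spacing — via a
## mosaic-of-blocks construction, so every other module builds and tests
## without any download.

#' Specification of a synthetic haplotype panel
#'
#' Loci are partitioned into haplotype blocks of geometric mean length
#' `block_len`; each block carries `n_block_haps` founder haplotypes with
#' frequencies drawn once from a symmetric Dirichlet(1); every output
#' haplotype is an independent chain of founder choices across blocks. The
#' genetic map places `hotspot_rate` on between-block intervals and
#' `background_rate` within blocks. Defaults emulate a dense reference
#' panel: ~1.8 kb mean marker spacing and a 0.05 MAF floor.
#'
#' @param n_haplotypes even number of haplotypes H.
#' @param n_loci number of markers L.
#' @param block_len mean loci per haplotype block.
#' @param n_block_haps distinct founder haplotypes per block (>= 2).
#' @param maf_min minor-allele-frequency floor, in (0, 0.5].
#' @param spacing_bp mean inter-marker distance (bp).
#' @param hotspot_rate,background_rate cM/Mb for between-block and
#'   within-block intervals.
#' @param chrom chromosome label.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @export
synthetic_panel_spec <- function(n_haplotypes = 200L, n_loci = 200L,
                                 block_len = 10, n_block_haps = 6L,
                                 maf_min = 0.05, spacing_bp = 1810,
                                 hotspot_rate = 10, background_rate = 0.05,
                                 chrom = "1", seed = 1L) {
  stopifnot(n_haplotypes %% 2L == 0L, n_block_haps >= 2L,
            maf_min > 0, maf_min <= 0.5, n_loci >= 1L)
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_loci = as.integer(n_loci), block_len = block_len,
                 n_block_haps = as.integer(n_block_haps), maf_min = maf_min,
                 spacing_bp = spacing_bp, hotspot_rate = hotspot_rate,
                 background_rate = background_rate, chrom = as.character(chrom),
                 seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

#' Generate a synthetic haplotype panel and matching genetic map
#'
#' Per-locus founder alleles are resampled (bounded retries) until the
#' realized panel MAF is at least `maf_min` at every locus, so the MAF floor
#' holds exactly in the delivered panel. Founder choice is independent
#' across blocks, so between-block loci are independent in expectation
#' while within-block loci share the block's founder mosaic (high |D'|).
#'
#' @param spec a [synthetic_panel_spec()].
#' @return list with elements `panel` (a `haplotype_panel`, cM assigned)
#'   and `map` (a `genetic_map`).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  L <- spec$n_loci; H <- spec$n_haplotypes; K <- spec$n_block_haps
  ## geometric block lengths (mean block_len)
  lens <- integer(0)
  while (sum(lens) < L)
    lens <- c(lens, 1L + stats::rgeom(max(8L, L), 1 / spec$block_len))
  cum <- cumsum(lens)
  n_blocks <- which(cum >= L)[1L]
  lens <- lens[seq_len(n_blocks)]
  lens[n_blocks] <- lens[n_blocks] - (cum[n_blocks] - L)
  lens <- lens[lens > 0L]; n_blocks <- length(lens)
  block_of <- rep(seq_len(n_blocks), lens)

  ## positions: exponential gaps with mean spacing_bp (>= 1 bp)
  gaps <- pmax(1, round(stats::rexp(L, 1 / spec$spacing_bp)))
  pos <- cumsum(c(10000, gaps[-1L]))

  haps <- matrix(0L, H, L)
  max_retry <- 2000L
  for (b in seq_len(n_blocks)) {
    fr <- stats::rexp(K); fr <- fr / sum(fr)          # Dirichlet(1) block freqs
    z <- sample.int(K, H, replace = TRUE, prob = fr)  # founder per output hap
    counts <- tabulate(z, K)
    cols <- which(block_of == b)
    for (j in cols) {
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        a <- stats::rbinom(K, 1L, 0.5)
        p <- sum(counts * a) / H
        if (min(p, 1 - p) >= spec$maf_min) { ok <- TRUE; break }
      }
      if (!ok)
        stop("MAF constraint infeasible: could not place a locus with MAF >= ",
             spec$maf_min, " using ", K, " founder haplotypes")
      haps[, j] <- a[z]
    }
  }

  ## genetic map: hotspot rate on block-boundary intervals
  boundary <- c(FALSE, diff(block_of) != 0L)              # interval before locus j
  rate <- ifelse(boundary, spec$hotspot_rate, spec$background_rate)
  cm <- numeric(L)
  cm[1L] <- pos[1L] * spec$background_rate * 1e-6
  if (L > 1L)
    cm[2:L] <- cm[1L] + cumsum(diff(pos) * rate[2:L] * 1e-6)
  map <- data.frame(chrom = spec$chrom, pos_bp = pos,
                    rate_cM_per_Mb = c(rate[-1L], spec$background_rate),
                    cumulative_cM = cm, stringsAsFactors = FALSE)
  map <- validate_genetic_map(map)

  loci <- locus_table(sprintf("snp%d", seq_len(L)), spec$chrom, pos, cm)
  loci$block <- block_of
  panel <- haplotype_panel(haps, loci)
  list(panel = panel, map = map)
}
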