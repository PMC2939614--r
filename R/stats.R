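## Population and sample statistics: allele frequencies, LD (D, D', r2) and
## distance-decay profiles, FST, haplotype diversity, harmonic-mean
## effective size, and allele-based chi-square association tests.

as_hap_matrix <- function(x) {
  if (inherits(x, "population")) pop_haps(x)
  else if (inherits(x, "haplotype_panel")) x$haps
  else if (inherits(x, "gwas_sample")) x$haps
  else as.matrix(x)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Haplotype frequencies are counted directly (no EM needed with phase
#' known). `D = p11 - p1 q1`; `D' = D / Dmax` with
#' `Dmax = min(p1 q0, p0 q1)` for `D > 0` and `min(p1 q1, p0 q0)`
#' otherwise; `r2 = D^2 / (p1 p0 q1 q0)`. A monomorphic locus yields a
#' flagged (`defined = FALSE`) result rather than an error.
#'
#' @param x a `population`, `haplotype_panel`, `gwas_sample` or binary matrix.
#' @param l1,l2 locus indices.
#' @return an `ld_stats` list: `D`, `Dprime`, `r2`, `defined`.
#' @export
ld_pair <- function(x, l1, l2) {
  h <- as_hap_matrix(x)
  p1 <- mean(h[, l1]); q1 <- mean(h[, l2])
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1))
    return(structure(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                          defined = FALSE), class = "ld_stats"))
  p11 <- mean(h[, l1] * h[, l2])
  D <- p11 - p1 * q1
  dmax <- if (D > 0) min(p1 * (1 - q1), (1 - p1) * q1)
          else min(p1 * q1, (1 - p1) * (1 - q1))
  Dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
  structure(list(D = D, Dprime = Dprime, r2 = r2, defined = TRUE),
            class = "ld_stats")
}

#' Mean LD as a function of marker distance
#'
#' All same-chromosome pairs closer than `max_dist_bp` are assigned to
#' half-open distance bins `[k bin, (k+1) bin)` and the arithmetic mean of
#' `r2` and `|D'|` is reported per bin; monomorphic loci are excluded and
#' empty bins reported as `NA`.
#'
#' @param x a `population`, `haplotype_panel` or binary matrix (with `loci`
#'   supplied for plain matrices).
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp bin width in bp (default 10 kb).
#' @param loci locus table; taken from `x` when available.
#' @return data.frame: `bin_start`, `bin_end`, `n_pairs`, `mean_r2`,
#'   `mean_absDprime`.
#' @export
ld_decay_profile <- function(x, max_dist_bp, bin_bp = 10000, loci = NULL) {
  h <- as_hap_matrix(x)
  if (is.null(loci)) loci <- x$loci
  p <- colMeans(h)
  poly <- which(p > 0 & p < 1)
  n_bins <- ceiling(max_dist_bp / bin_bp)
  sums_r2 <- sums_dp <- counts <- numeric(n_bins)
  H <- nrow(h)
  for (ch in unique(loci$chrom)) {
    idx <- intersect(which(loci$chrom == ch), poly)
    if (length(idx) < 2L) next
    hp <- h[, idx, drop = FALSE]
    pj <- p[idx]
    p11 <- crossprod(hp) / H
    Dm <- p11 - outer(pj, pj)
    denom <- outer(pj * (1 - pj), pj * (1 - pj))
    r2m <- Dm^2 / denom
    dmax_pos <- pmin(outer(pj, 1 - pj), outer(1 - pj, pj))
    dmax_neg <- pmin(outer(pj, pj), outer(1 - pj, 1 - pj))
    dpm <- abs(Dm / ifelse(Dm > 0, dmax_pos, dmax_neg))
    dpm[Dm == 0] <- 0
    dist <- abs(outer(loci$pos_bp[idx], loci$pos_bp[idx], "-"))
    ut <- upper.tri(dist)
    keep <- ut & dist < max_dist_bp
    b <- dist[keep] %/% bin_bp + 1L
    sums_r2 <- sums_r2 + vapply(seq_len(n_bins), function(k)
      sum(r2m[keep][b == k]), numeric(1))
    sums_dp <- sums_dp + vapply(seq_len(n_bins), function(k)
      sum(dpm[keep][b == k]), numeric(1))
    counts <- counts + tabulate(b, n_bins)
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_bp,
             bin_end = seq_len(n_bins) * bin_bp,
             n_pairs = counts,
             mean_r2 = ifelse(counts > 0, sums_r2 / counts, NA_real_),
             mean_absDprime = ifelse(counts > 0, sums_dp / counts, NA_real_))
}

#' Fixation index between subpopulations
#'
#' Default `method = "nei"` is the classic fixation-index / Gst form: the
#' ratio of summed (sample-size weighted) between-subpopulation variance of
#' allele frequencies to summed `pbar (1 - pbar)`, a ratio of sums across
#' loci. It is exactly 0 for duplicated subpopulations and exactly 1 for
#' subpopulations fixed for opposite alleles. `method = "wc"` is the
#' Weir-Cockerham (1984) theta with its finite-sample corrections
#' (slightly negative for identical subpopulations by design). Loci
#' monomorphic across all subpopulations are skipped; if all are, `NA` is
#' returned with a warning.
#'
#' @param pop a `population` with >= 2 subpopulations.
#' @param loci optional locus indices (default all).
#' @param method `"nei"` or `"wc"`.
#' @return the multi-locus FST estimate.
#' @export
fst <- function(pop, loci = NULL, method = c("nei", "wc")) {
  method <- match.arg(method)
  r <- length(pop$subpops)
  if (r < 2L) stop("fst requires at least two subpopulations")
  if (is.null(loci)) loci <- seq_len(nrow(pop$loci))
  n <- vapply(pop$subpops, function(s) length(s$sex), numeric(1))
  P <- vapply(pop$subpops, function(s) colMeans(s$haps)[loci],
              numeric(length(loci)))          # loci x subpops
  P <- matrix(P, nrow = length(loci))
  wts <- n / sum(n)
  pbar <- as.vector(P %*% wts)
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) {
    warning("all loci monomorphic across subpopulations; FST undefined")
    return(NA_real_)
  }
  P <- P[poly, , drop = FALSE]; pbar <- pbar[poly]
  if (method == "nei") {
    num <- as.vector(((P - pbar)^2) %*% wts)
    sum(num) / sum(pbar * (1 - pbar))
  } else {
    ## observed heterozygote frequencies per subpop
    Hm <- vapply(seq_len(r), function(k) {
      sp <- pop$subpops[[k]]
      odd <- 2L * seq_len(length(sp$sex)) - 1L
      g <- sp$haps[odd, loci, drop = FALSE] + sp$haps[odd + 1L, loci, drop = FALSE]
      colMeans(g == 1L)
    }, numeric(length(loci)))
    Hm <- matrix(Hm, ncol = r)[poly, , drop = FALSE]
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    a_s <- b_s <- c_s <- 0
    for (l in seq_len(nrow(P))) {
      p <- P[l, ]; pb <- sum(n * p) / sum(n)
      s2 <- sum(n * (p - pb)^2) / ((r - 1) * nbar)
      hb <- sum(n * Hm[l, ]) / sum(n)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pb * (1 - pb) - (r - 1) / r * s2 - hb / 4))
      b <- nbar / (nbar - 1) *
        (pb * (1 - pb) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hb)
      cc <- hb / 2
      a_s <- a_s + a; b_s <- b_s + b; c_s <- c_s + cc
    }
    a_s / (a_s + b_s + c_s)
  }
}

#' Haplotype diversity over a locus window
#'
#' Exact counting over all 2N haplotypes restricted to the window.
#'
#' @param pop a `population` (or panel / matrix).
#' @param window integer vector of locus indices.
#' @return list with `n_distinct` and `top_freq` (frequency of the most
#'   common haplotype).
#' @export
haplotype_summary <- function(pop, window) {
  h <- as_hap_matrix(pop)[, window, drop = FALSE]
  key <- apply(h, 1L, paste0, collapse = "")
  tab <- table(key)
  list(n_distinct = length(tab), top_freq = max(tab) / length(key))
}

#' Harmonic-mean effective population size
#'
#' `Ne = T / sum(1 / N_t)` over the supplied per-generation sizes. For an
#' expansion schedule, pass generations 0..T-1 (excluding the final census),
#' e.g. `harmonic_ne(head(size_schedule(dem), -1))`.
#'
#' @param sizes integer vector of per-generation diploid sizes (all >= 1).
#' @export
harmonic_ne <- function(sizes) {
  if (length(sizes) == 0L) stop("empty size list")
  if (any(sizes < 1)) stop("sizes must be >= 1")
  length(sizes) / sum(1 / sizes)
}

#' Allele-based chi-square test of case-control association
#'
#' Counts alleles (two per individual) in cases and controls at one locus,
#' forms the 2 x 2 table and applies Pearson's chi-square without continuity
#' correction (1 df). A zero margin yields `chi2 = 0`, `p = 1`, flagged.
#'
#' @param case_sample,control_sample `gwas_sample`s (or binary hap matrices).
#' @param locus locus index.
#' @return list: `chi2`, `p`, `defined`.
#' @export
chi2_allele_test <- function(case_sample, control_sample, locus) {
  hc <- as_hap_matrix(case_sample); hu <- as_hap_matrix(control_sample)
  a <- sum(hc[, locus]); b <- nrow(hc) - a        # cases: alt, ref
  c_ <- sum(hu[, locus]); d <- nrow(hu) - c_      # controls
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    return(list(chi2 = 0, p = 1, defined = FALSE))
  chi2 <- n * (a * d - b * c_)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       defined = TRUE)
}

#' Genome scan of allele-based chi-square tests
#'
#' @param case_sample,control_sample `gwas_sample`s sharing one locus table.
#' @return data.frame: chrom, pos_bp, name, chi2, p, neg_log10_p per locus.
#' @export
association_scan <- function(case_sample, control_sample) {
  loci <- case_sample$loci
  res <- lapply(seq_len(nrow(loci)), function(l)
    chi2_allele_test(case_sample, control_sample, l))
  data.frame(chrom = loci$chrom, pos_bp = loci$pos_bp, name = loci$name,
             chi2 = vapply(res, `[[`, numeric(1), "chi2"),
             p = vapply(res, `[[`, numeric(1), "p"),
             neg_log10_p = -log10(vapply(res, `[[`, numeric(1), "p")),
             stringsAsFactors = FALSE)
}
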