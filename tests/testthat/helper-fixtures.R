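## Small fixtures built in code, shared across test files.

## panel from an explicit H x L matrix; positions default to 1 kb spacing,
## genetic positions from the constant physical map (0.01 per Mbp)
tiny_panel <- function(haps, pos = NULL, chrom = "1", names = NULL) {
  haps <- as.matrix(haps)
  L <- ncol(haps)
  if (is.null(pos)) pos <- 1000L * seq_len(L)
  if (is.null(names)) names <- sprintf("m%d", seq_len(L))
  panel <- haplotype_panel(haps, locus_table(names, chrom, pos))
  assign_cm(panel, NULL)
}

## diploid population with a single subpop from a hap matrix
tiny_pop <- function(haps, ...) initialize_population(tiny_panel(haps, ...))

## population with one locus and an exact allele count: n individuals,
## `alt` alternate alleles placed deterministically
one_locus_pop <- function(n, alt) {
  h <- matrix(0L, 2L * n, 1L)
  if (alt > 0) h[seq_len(alt), 1L] <- 1L
  tiny_pop(h)
}

## all-heterozygote single-locus population (exact HWE(0.5) offspring)
het_pop <- function(n) {
  h <- matrix(0L, 2L * n, 1L)
  h[seq(1L, 2L * n, by = 2L), 1L] <- 1L
  tiny_pop(h)
}

## two loci with a chosen recombination fraction r (Haldane inverse)
two_locus_panel <- function(haps, r) {
  d_cm <- -50 * log(1 - 2 * r)             # cM giving recomb fraction r
  haplotype_panel(as.matrix(haps),
                  locus_table(c("a", "b"), "1", c(1000L, 2000L),
                              cm = c(0, d_cm)))
}

## write a 2-sample, 3-site phased VCF fixture; returns the path
write_vcf_fixture <- function(path, gts = c("0|1", "1|1", "0|0",
                                            "1|0", "0|0", "0|1")) {
  m <- matrix(gts, nrow = 3L)               # sites x samples
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("2", "100", "rs1", "A", "G", ".", "PASS", ".", "GT", m[1, ]), collapse = "\t"),
    paste(c("2", "200", "rs2", "C", "T", ".", "PASS", ".", "GT", m[2, ]), collapse = "\t"),
    paste(c("2", "300", "rs3", "G", "A", ".", "PASS", ".", "GT", m[3, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}
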