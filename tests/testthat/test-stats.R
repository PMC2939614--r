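test_that("ld_pair matches hand-computed D, D' and r2", {
  ## haplotypes 11 and 00 at 50/50
  h <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 0L))
  ld <- ld_pair(h, 1, 2)
  expect_equal(ld$D, 0.25)
  expect_equal(ld$Dprime, 1)
  expect_equal(ld$r2, 1)
  ## independent loci: all four haplotypes equally frequent
  h2 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  ld2 <- ld_pair(h2, 1, 2)
  expect_equal(ld2$D, 0)
  expect_equal(ld2$r2, 0)
  ## a locus with itself
  ld3 <- ld_pair(h2, 1, 1)
  expect_equal(ld3$Dprime, 1)
  expect_equal(ld3$r2, 1)
  ## monomorphic input is flagged, not an error
  ld4 <- ld_pair(cbind(rep(0L, 4), c(0L, 1L, 0L, 1L)), 1, 2)
  expect_false(ld4$defined)
})

test_that("r2 never exceeds |D'| (property over random haplotype tables)", {
  set.seed(30)
  for (rep in 1:50) {
    h <- matrix(rbinom(80, 1, runif(1, 0.2, 0.8)), 40, 2)
    ld <- ld_pair(h, 1, 2)
    if (!ld$defined) next
    expect_lte(ld$r2, abs(ld$Dprime) + 1e-12)
    expect_lte(abs(ld$Dprime), 1 + 1e-12)
    expect_gte(ld$r2, 0)
  }
})

test_that("ld_decay_profile bins pairs half-open by distance", {
  set.seed(36)
  h <- matrix(rbinom(150, 1, 0.5), 50, 3)
  h[, 2] <- h[, 1]                             # perfect LD pair at 5 kb
  panel <- haplotype_panel(h, locus_table(letters[1:3], "1",
                                          c(1000L, 6000L, 11000L)))
  prof <- ld_decay_profile(panel, max_dist_bp = 30000)
  ## (a,b) and (b,c) at 5 kb -> bin 1; (a,c) at exactly 10 kb -> bin 2
  expect_equal(prof$n_pairs, c(2L, 1L, 0L))
  expect_gte(prof$mean_r2[1], 0.5)             # contains the r2 = 1 pair
  expect_equal(prof$bin_start[2], 10000)       # half-open boundary convention
  expect_true(is.na(prof$mean_r2[3]))          # empty bin reported missing
})

test_that("fst identities: duplicated subpops give 0, fixed differences 1", {
  set.seed(31)
  h <- matrix(rbinom(200, 1, 0.4), 40, 5)
  p <- tiny_panel(h)
  dup <- initialize_population(list(p, p))
  expect_lt(abs(fst(dup)), 1e-12)
  ## opposite fixation at all loci
  pa <- tiny_panel(matrix(1L, 20, 5)); pb <- tiny_panel(matrix(0L, 20, 5))
  fixed <- initialize_population(list(pa, pb))
  expect_equal(fst(fixed), 1)
  ## all-monomorphic populations are flagged undefined
  mono <- initialize_population(list(pb, pb))
  expect_warning(res <- fst(mono), "monomorphic")
  expect_true(is.na(res))
})

test_that("fst is invariant to subpop order and allele relabeling", {
  set.seed(32)
  h1 <- matrix(rbinom(300, 1, 0.3), 30, 10)
  h2 <- matrix(rbinom(300, 1, 0.6), 30, 10)
  pop <- initialize_population(list(tiny_panel(h1), tiny_panel(h2)))
  rev_pop <- initialize_population(list(tiny_panel(h2), tiny_panel(h1)))
  expect_equal(fst(pop), fst(rev_pop))
  ## flip alleles at loci 2 and 5
  flip <- function(h) { h[, c(2, 5)] <- 1L - h[, c(2, 5)]; h }
  flipped <- initialize_population(list(tiny_panel(flip(h1)),
                                        tiny_panel(flip(h2))))
  expect_equal(fst(pop), fst(flipped))
  expect_equal(fst(pop, method = "wc"), fst(flipped, method = "wc"))
})

test_that("Weir-Cockerham theta matches an independent transcription", {
  ## two subpops of 10 individuals, printed allele counts 12/20 and 4/20
  h1 <- matrix(0L, 20, 1); h1[1:12, 1] <- 1L
  h2 <- matrix(0L, 20, 1); h2[1:4, 1] <- 1L
  pop <- initialize_population(list(tiny_panel(h1), tiny_panel(h2)))
  ## textbook WC84 formulas, written out independently
  wc_oracle <- function(n, p, hobs) {
    r <- length(n); nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * hobs) / sum(n)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  }
  hob <- function(h) {
    g <- h[seq(1, nrow(h), 2), 1] + h[seq(2, nrow(h), 2), 1]
    mean(g == 1)
  }
  expected <- wc_oracle(c(10, 10), c(0.6, 0.2), c(hob(h1), hob(h2)))
  expect_equal(fst(pop, method = "wc"), expected)
})

test_that("haplotype_summary counts distinct haplotypes exactly", {
  h <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 1L))
  res <- haplotype_summary(h, 1:2)
  expect_equal(res$n_distinct, 3L)
  expect_equal(res$top_freq, 0.5)
  same <- haplotype_summary(matrix(1L, 8, 3), 1:3)
  expect_equal(same$n_distinct, 1L)
  expect_equal(same$top_freq, 1)
  uniq <- haplotype_summary(diag(6L), 1:6)
  expect_equal(uniq$n_distinct, 6L)
  expect_equal(uniq$top_freq, 1 / 6)
})

test_that("harmonic Ne matches constants and the AM-HM inequality", {
  expect_equal(harmonic_ne(rep(100, 7)), 100)
  expect_error(harmonic_ne(integer(0)), "empty")
  set.seed(33)
  for (r in 1:20) {
    sizes <- sample(1:1000, 30, replace = TRUE)
    expect_lte(harmonic_ne(sizes), mean(sizes) + 1e-9)
  }
  ## exponential expansion 993 -> 100,000 over 500 generations
  s <- size_schedule(demographic_model(993, 100000, 500, "exponential"))
  expect_equal(harmonic_ne(head(s, -1)), 4603, tolerance = 0.001)
  ## the linear schedule's harmonic mean is far larger (~21,000)
  sl <- size_schedule(demographic_model(993, 100000, 500, "linear"))
  expect_gt(harmonic_ne(head(sl, -1)), 20000)
})

test_that("allele-count chi-square matches the shortcut formula", {
  case_h <- matrix(0L, 100, 1); case_h[1:30, 1] <- 1L   # 30 alt / 70 ref
  ctrl_h <- matrix(0L, 100, 1); ctrl_h[1:10, 1] <- 1L   # 10 alt / 90 ref
  res <- chi2_allele_test(case_h, ctrl_h, 1)
  expect_equal(res$chi2, 12.5)
  expect_equal(res$p, pchisq(12.5, 1, lower.tail = FALSE))
  ## identical counts give chi2 = 0, p = 1
  same <- chi2_allele_test(case_h, case_h, 1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  ## equivalence with the textbook formula on random tables
  set.seed(34)
  for (r in 1:25) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    ch <- matrix(c(rep(1L, a), rep(0L, 60 - a)), ncol = 1)
    cu <- matrix(c(rep(1L, b), rep(0L, 60 - b)), ncol = 1)
    got <- chi2_allele_test(ch, cu, 1)$chi2
    tab <- rbind(c(a, 60 - a), c(b, 60 - b))
    want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(got, unname(want))
  }
  ## zero margin flagged with p = 1
  zero <- chi2_allele_test(matrix(0L, 10, 1), matrix(0L, 10, 1), 1)
  expect_false(zero$defined)
  expect_equal(zero$p, 1)
})

test_that("association_scan emits one row per locus with -log10 p", {
  set.seed(35)
  h <- matrix(rbinom(400, 1, 0.5), 40, 10)
  pop <- tiny_pop(h)
  pop$subpops[[1]]$affected <- rep(c(TRUE, FALSE), 10)
  s <- draw_case_control_direct(pop, 10, 10)
  cases <- s$ind$pheno
  rows <- as.vector(rbind(2 * which(cases) - 1, 2 * which(cases)))
  crows <- as.vector(rbind(2 * which(!cases) - 1, 2 * which(!cases)))
  scan <- association_scan(
    fwdgwas:::new_gwas_sample(s$loci, s$ind[cases, ], s$haps[rows, ]),
    fwdgwas:::new_gwas_sample(s$loci, s$ind[!cases, ], s$haps[crows, ]))
  expect_equal(nrow(scan), 10L)
  expect_equal(scan$neg_log10_p, -log10(scan$p))
})
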