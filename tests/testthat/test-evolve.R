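test_that("size_schedule pins endpoints and matches closed forms", {
  dem <- demographic_model(993, 100000, 500, "linear")
  s <- size_schedule(dem)
  expect_equal(s[1], 993L)
  expect_equal(s[2], 1191L)                 # round(993 + 198.014)
  expect_equal(s[501], 100000L)
  expect_equal(length(s), 501L)
  se <- size_schedule(demographic_model(993, 100000, 500, "exponential"))
  expect_equal(se[1], 993L); expect_equal(se[501], 100000L)
  expect_true(all(diff(se) >= 0))
  sc <- size_schedule(demographic_model(50, 50, 10, "constant"))
  expect_true(all(sc == 50L))
  expect_error(demographic_model(10, 20, 0), "T = 0")
})

test_that("scale_config magnifies forces and shrinks the schedule", {
  dem <- demographic_model(1000, 50000, 500, "linear")
  sel <- selection_model(3L, fitness_triple(1, 0.996, 0.994))
  cfg <- evolution_config(dem, mu = 1e-8, selection = sel, lam = 1)
  expect_identical(scale_config(cfg), cfg)              # lambda = 1 identity
  cfg2 <- evolution_config(dem, mu = 1e-8, selection = sel, lam = 2)
  s2 <- scale_config(cfg2)
  sizes <- size_schedule(s2$demographic)
  expect_equal(length(sizes) - 1L, 250L)                # T/lambda
  expect_equal(sizes[length(sizes)], 25000L)            # NT/lambda
  expect_equal(s2$mu, 2e-8)
  expect_equal(s2$recomb_scale, 2)
  expect_equal(s2$lam, 1)
  w <- unclass(s2$selection$triples[[1]])
  expect_equal(unname(w[2]), 0.992)                     # 1 + 2 (0.996 - 1)
  expect_equal(unname(w[3]), 0.988)
  ## fitness deviations that scale below zero are clipped with a warning
  cfg3 <- evolution_config(dem, selection = selection_model(1L, fitness_triple(1, 0.9, 0.5)),
                           lam = 5)
  expect_warning(s3 <- scale_config(cfg3), "clipped")
  expect_equal(unname(unclass(s3$selection$triples[[1]])[3]), 0)
})

test_that("interval probabilities follow Haldane with free inter-chromosome recombination", {
  loci <- locus_table(c("a", "b", "c", "d"), c("1", "1", "1", "2"),
                      c(100L, 200L, 300L, 50L), cm = c(0, 0, 10, 0))
  r <- interval_recomb_probs(loci)
  expect_equal(r[1], 0)                                  # zero cM
  expect_equal(r[2], 0.5 * (1 - exp(-0.2)))              # 10 cM
  expect_equal(r[3], 0.5)                                # chromosome boundary
  ## scaling multiplies the probability and caps at 0.5
  r5 <- interval_recomb_probs(loci, scale = 5)
  expect_equal(r5[2], min(0.5, 5 * r[2]))
  expect_equal(r5[1], 0)
})

test_that("recombine_gamete performs standard meiosis", {
  h0 <- c(0L, 0L, 0L); h1 <- c(1L, 1L, 1L)
  set.seed(1)
  ## no recombination: gamete is an intact parental haplotype, each ~1/2
  picks <- replicate(200, sum(recombine_gamete(h0, h1, c(0, 0))))
  expect_true(all(picks %in% c(0L, 3L)))
  expect_gt(mean(picks == 0), 0.35); expect_lt(mean(picks == 0), 0.65)
  ## homozygous parent: gamete equals the haplotype regardless of r
  hom <- replicate(20, recombine_gamete(c(1L, 0L), c(1L, 0L), 0.5))
  expect_true(all(hom == c(1L, 0L)))
  ## double heterozygote in coupling at r = 0.2: recombinant fraction ~ 0.2
  set.seed(42)
  n <- 20000
  pop <- tiny_pop(rbind(c(1L, 1L), c(0L, 0L)))
  gam <- fwdgwas:::make_gametes(pop$subpops[[1]]$haps, rep(1L, n), 0.2)
  recomb <- gam[, 1] != gam[, 2]
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(recomb) - 0.2), 3 * se)
})

test_that("mutation flips sites at the configured rate", {
  expect_identical(mutate_haplotype(c(0L, 1L), 0), c(0L, 1L))
  expect_identical(mutate_haplotype(c(0L, 1L), 1), c(1L, 0L))
  set.seed(8)
  flips <- replicate(60, sum(mutate_haplotype(rep(0L, 1e4), 0.01)))
  expect_lt(abs(mean(flips) - 100), 3 * sqrt(99 / 60))   # Binomial(1e4, .01)
})

test_that("genotype fitness is the product over selected loci", {
  h0 <- c(1L, 1L); h1 <- c(0L, 1L)      # het at locus 1, alt-hom at locus 2
  expect_equal(genotype_fitness(h0, h1, NULL), 1)
  sel1 <- selection_model(1L, fitness_triple(1, 0.996, 0.994))
  expect_equal(genotype_fitness(h0, h1, sel1), 0.996)
  sel2 <- selection_model(c(1L, 2L),
                          list(fitness_triple(1, 0.996, 0.994),
                               fitness_triple(1, 1.001, 1.005)))
  expect_equal(genotype_fitness(h0, h1, sel2), 0.996 * 1.005)
})

test_that("neutral parent choice is uniform and ancestry averages", {
  set.seed(3)
  sexes <- rep(c(1L, 2L), 5)
  pr <- fwdgwas:::sample_parents(20000, sexes, rep(1, 10))
  counts <- tabulate(pr$fathers, 10)[sexes == 1L]
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  ## child ancestry is the parental mean
  pop <- tiny_pop(matrix(0L, 4, 2))
  pop$subpops[[1]]$ancestry <- c(0, 1)
  kid <- random_mating_generation(pop, 50, mu = 0)
  expect_true(all(kid$subpops[[1]]$ancestry %in% c(0, 0.5, 1)))
  pop$subpops[[1]]$ancestry <- c(1, 0)   # one male (anc 1), one female (anc 0)
  kid <- random_mating_generation(pop, 50, mu = 0)
  expect_true(all(kid$subpops[[1]]$ancestry == 0.5))
})

test_that("one round of random mating restores Hardy-Weinberg proportions", {
  set.seed(12)
  n <- 5000
  h <- matrix(rbinom(2 * n, 1, 0.35), 2 * n, 1)
  pop <- tiny_pop(h)
  off <- random_mating_generation(pop, n, mu = 0)
  hapo <- off$subpops[[1]]$haps
  g <- hapo[seq(1, 2 * n, 2), 1] + hapo[seq(2, 2 * n, 2), 1]
  p <- mean(h)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((tabulate(g + 1L, 3L) - expected)^2 / expected)
  expect_gt(stats::pchisq(chi2, df = 2, lower.tail = FALSE), 0.001)
})

test_that("stepping-stone and gene-flow migration move the right counts", {
  h <- matrix(0L, 200, 2)
  p1 <- tiny_panel(h); p2 <- tiny_panel(h)
  pop <- initialize_population(list(p1, p2), ancestry = c(0, 1))
  ## m = 0 is the identity
  same <- migrate(pop, migration_model("stepping_stone", m = 0))
  expect_identical(same$subpops, pop$subpops)
  ## two-deme stepping stone with m = 0.5: each deme becomes half-and-half
  set.seed(4)
  mig <- migrate(pop, migration_model("stepping_stone", m = 0.5))
  expect_equal(mean(mig$subpops[[1]]$ancestry), 0.5)
  expect_equal(mean(mig$subpops[[2]]$ancestry), 0.5)
  expect_equal(length(mig$subpops[[1]]$sex), 100L)
  ## gene flow: round(p N_sink) migrants replace sink individuals
  gf <- migrate(pop, migration_model("gene_flow", p = 0.05, source = 2, sink = 1))
  expect_equal(sum(gf$subpops[[1]]$ancestry == 1), 5L)
  expect_equal(length(gf$subpops[[1]]$sex), 100L)
  expect_equal(length(gf$subpops[[2]]$sex), 100L)
})

test_that("assortative-mating admixture conserves mean ancestry", {
  set.seed(9)
  h <- matrix(rbinom(400, 1, 0.5), 200, 2)
  pop <- tiny_pop(h)
  pop$subpops[[1]]$ancestry <- rep(c(1, 0), each = 50)
  adm <- admixture_config(assort_within = 0.8, threshold = 0.5)
  means <- replicate(60, {
    kid <- admixture_generation(pop, adm, 100, mu = 0)
    mean(kid$subpops[[1]]$ancestry)
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 4 * se + 1e-3)
  ## degenerate configs
  pop0 <- pop; pop0$subpops[[1]]$ancestry <- rep(0, 100)
  kid0 <- admixture_generation(pop0, adm, 50, mu = 0)
  expect_true(all(kid0$subpops[[1]]$ancestry == 0))
})

test_that("evolve is deterministic, respects T = 0, and logs sizes", {
  gen <- generate_panel(synthetic_panel_spec(n_haplotypes = 60, n_loci = 30,
                                             seed = 5))
  pop <- initialize_population(gen$panel)
  cfg0 <- evolution_config(demographic_model(30, 30, 0), seed = 1)
  res0 <- evolve(pop, cfg0)
  expect_identical(res0$population$subpops, pop$subpops)
  expect_equal(res0$population$generation, 0L)
  cfg <- evolution_config(demographic_model(30, 120, 15), mu = 1e-4,
                          seed = 99, summary_every = 5,
                          watched_loci = c(1L, 7L))
  r1 <- evolve(pop, cfg)
  r2 <- evolve(pop, cfg)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$log, r2$log)
  expect_equal(pop_size(r1$population), 120L)
  expect_true(all(c("freq_1", "freq_7") %in% names(r1$log)))
  expect_equal(r1$log$size[r1$log$generation == 15], 120L)
})
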