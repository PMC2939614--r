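test_that("selection_response matches hand-computed values", {
  expect_equal(selection_response(0.3, fitness_triple(1, 1, 1)), 0.3)
  ## recessive lethal at x = 0.5: 0.25 / 0.75 = 1/3
  expect_equal(selection_response(0.5, fitness_triple(1, 1, 0)), 1 / 3)
  ## slow positive sweep fitnesses, x = 0.0588 (hand-evaluated formula)
  expect_equal(selection_response(0.0588, fitness_triple(1, 1.02, 1.03)),
               0.059872, tolerance = 1e-5)
  ## closed-form oracle on a grid
  f <- fitness_triple(1, 0.98, 0.95)
  for (x in c(0, 0.1, 0.7, 1)) {
    wbar <- x^2 * 0.95 + 2 * x * (1 - x) * 0.98 + (1 - x)^2
    expect_equal(selection_response(x, f), (x^2 * 0.95 + x * (1 - x) * 0.98) / wbar)
  }
  expect_error(selection_response(0.5, fitness_triple(0, 0, 0)), "mean fitness")
})

test_that("the backward kernel inverts the selection response", {
  triples <- list(fitness_triple(1, 1, 1),
                  fitness_triple(1, 1.02, 1.03),
                  fitness_triple(1, 0.996, 0.994),
                  fitness_triple(1, 1.05, 1.11),
                  fitness_triple(1, 1.2, 0.9))
  xs <- seq(0.01, 0.99, by = 0.07)
  for (f in triples) {
    inv <- inverse_selection_response(xs, f)
    expect_lt(max(abs(selection_response(inv, f) - xs)), 1e-10)
  }
  ## neutral inverse is the identity
  expect_equal(inverse_selection_response(0.37, fitness_triple(1, 1, 1)),
               0.37, tolerance = 1e-10)
})

test_that("marginal fitness of a multiplicative model factorizes", {
  own <- fitness_triple(1, 0.996, 0.994)
  other <- fitness_triple(1, 1.001, 1.005)
  sel1 <- selection_model(4L, own)
  m1 <- marginal_fitness(sel1, freqs = 0.3, locus = 4L)
  expect_equal(unclass(m1), unclass(own))
  sel2 <- selection_model(c(4L, 9L), list(own, other))
  ## oracle: exhaustive 9-genotype enumeration of E[w | g1]
  q2 <- 0.2
  hw <- c((1 - q2)^2, 2 * q2 * (1 - q2), q2^2)
  oracle <- vapply(0:2, function(g1) {
    sum(vapply(0:2, function(g2)
      hw[g2 + 1] * unclass(own)[g1 + 1] * unclass(other)[g2 + 1], numeric(1)))
  }, numeric(1))
  m2 <- marginal_fitness(sel2, freqs = c(0.3, q2), locus = 4L)
  expect_equal(unname(unclass(m2)), oracle)
  ## proportional to the locus's own triple
  expect_equal(unname(unclass(m2) / unclass(own)),
               rep((unclass(m2) / unclass(own))[[1]], 3))
  ## other locus fixed: exact product with that genotype's fitness
  mfix <- marginal_fitness(sel2, freqs = c(0.3, 1), locus = 4L)
  expect_equal(unname(unclass(mfix)), unname(unclass(own)) * 1.005)
  ## normalized form keeps the locus's own scale
  mn <- marginal_fitness(sel2, freqs = c(0.3, q2), locus = 4L, normalize = TRUE)
  expect_equal(unclass(mn), unclass(own))
  ## linked selected loci are rejected when locus metadata is available
  loci <- locus_table(letters[1:9], rep("1", 9), 1:9 * 1000L)
  expect_error(marginal_fitness(sel2, c(0.3, 0.2), 4L, loci = loci), "unlinked")
})

test_that("forward trajectories accept, restart and hit the deterministic limit", {
  sizes <- rep(500L, 21)
  set.seed(1)
  tr <- simulate_forward_trajectory(0.3, fitness_triple(1, 1, 1), sizes)
  expect_equal(tr$attempts, 1)                    # range [0,1] accepts at once
  expect_equal(nrow(tr$freqs), 21L)
  expect_true(all(tr$freqs >= 0 & tr$freqs <= 1))
  ## deterministic limit reproduces iterated selection response
  f <- fitness_triple(1, 1.02, 1.03)
  trd <- simulate_forward_trajectory(0.0588, f, rep(1000L, 11),
                                     deterministic = TRUE)
  x <- 0.0588
  for (t in 1:10) x <- selection_response(x, f)
  expect_equal(trd$freqs[11], x)
  ## infeasible range errors with a feasibility report
  set.seed(2)
  err <- tryCatch(
    simulate_forward_trajectory(0.01, fitness_triple(1, 1, 1), rep(50L, 6),
                                x_range = c(0.99, 1), max_attempts = 20),
    trajectory_infeasible = function(e) e)
  expect_s3_class(err, "trajectory_infeasible")
  expect_match(conditionMessage(err), "average ending frequency")
})

test_that("backward trajectories terminate at loss and bound the origin", {
  set.seed(3)
  sizes <- rep(50L, 41)
  tr <- simulate_backward_trajectory(1 / 100, fitness_triple(1, 1, 1), sizes)
  expect_true(tr$origin_gen >= 0)
  expect_equal(tr$freqs[tr$origin_gen + 1], 0)
  expect_true(all(tr$freqs[(tr$origin_gen + 2):41] >= 0))
  ## a rare neutral allele is typically lost within a few back-steps
  expect_gt(tr$origin_gen, 41 - 1 - 25)
  ## strong selection from high frequency gives a finite origin distribution
  set.seed(4)
  trs <- simulate_backward_trajectory(0.99, fitness_triple(1, 1.05, 1.11),
                                      rep(500L, 501), max_attempts = 200)
  age <- 500 - trs$origin_gen
  expect_gt(age, 20); expect_lt(age, 500)         # order of magnitude only
  ## max_origin_gen bounds the age
  set.seed(5)
  trb <- simulate_backward_trajectory(0.5, fitness_triple(1, 1.05, 1.11),
                                      rep(200L, 301), max_origin_gen = 150,
                                      max_attempts = 500)
  expect_lte(301 - 1 - trb$origin_gen, 150)
})

test_that("controlled mating hits allele-count quotas exactly", {
  set.seed(6)
  n <- 500
  h <- matrix(rbinom(2 * n * 2, 1, c(0.3, 0.6)), 2 * n, 2, byrow = TRUE)
  pop <- tiny_pop(h)
  ## one controlled locus at 5%
  res <- controlled_offspring_generation(pop, loci = 1L, target_counts = 50L,
                                         target_size = n)
  expect_equal(sum(res$subpops[[1]]$haps[, 1]), 50L)
  expect_equal(res$generation, 1L)
  expect_equal(pop_size(res), n)
  ## two controlled loci with independent quotas, both exact
  res2 <- controlled_offspring_generation(pop, loci = c(1L, 2L),
                                          target_counts = c(280L, 610L),
                                          target_size = n)
  expect_equal(sum(res2$subpops[[1]]$haps[, 1]), 280L)
  expect_equal(sum(res2$subpops[[1]]$haps[, 2]), 610L)
  ## infeasible quota names the locus
  absent <- tiny_pop(matrix(0L, 20, 2))
  expect_error(controlled_offspring_generation(absent, 2L, 5L),
               "locus 2.*absent")
})

test_that("trajectory TSV files round-trip frequencies", {
  set.seed(7)
  tr <- simulate_forward_trajectory(0.4, fitness_triple(1, 1, 1), rep(100L, 11))
  tr$loci <- 3L
  path <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  back <- read_trajectory_tsv(path)
  expect_equal(as.vector(back$freqs), as.vector(tr$freqs))
  expect_equal(back$loci, 3L)
})
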