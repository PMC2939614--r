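## Pre-simulation of disease-allele frequency trajectories (forward and
## backward in time) and the controlled mating scheme that forces the
## population to follow them at the controlled loci.

#' Deterministic one-generation response to viability selection
#'
#' For alternate-allele frequency `x` and fitnesses `(w11, w12, w22)` of the
#' genotypes with 0, 1, 2 alternate copies, the next-generation frequency is
#' `x' = (x^2 w22 + x (1 - x) w12) / wbar` with
#' `wbar = x^2 w22 + 2 x (1 - x) w12 + (1 - x)^2 w11`.
#' A neutral triple is the identity.
#'
#' @param x frequency (vectorized) in \[0, 1\].
#' @param f a [fitness_triple()].
#' @export
selection_response <- function(x, f) {
  w <- unname(unclass(f))
  wbar <- x^2 * w[3L] + 2 * x * (1 - x) * w[2L] + (1 - x)^2 * w[1L]
  if (any(wbar == 0)) stop("mean fitness is 0; selection response undefined")
  (x^2 * w[3L] + x * (1 - x) * w[2L]) / wbar
}

#' Invert the deterministic selection response
#'
#' Finds `x` with `selection_response(x, f) = y` by monotone bisection on
#' \[0, 1\]. Used as the transition kernel of backward trajectory
#' simulation ("invert deterministic selection, then binomial").
#'
#' @param y target frequency in \[0, 1\].
#' @param f a [fitness_triple()].
#' @param tol bisection tolerance.
#' @export
inverse_selection_response <- function(y, f, tol = 1e-12) {
  vapply(y, function(yy) {
    if (yy <= 0) return(0)
    if (yy >= 1) return(1)
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (selection_response(mid, f) < yy) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Marginal fitness of one locus in a multiplicative multilocus model
#'
#' The expectation of multilocus fitness over Hardy-Weinberg genotype
#' distributions at the other loci, conditioned on the genotype at `locus`.
#' For a multiplicative model this is the locus's own triple times a
#' genotype-independent constant (the mean fitness contributed by the other
#' loci). With `normalize = TRUE` the constant is divided out so the triple
#' keeps its own scale.
#'
#' Controlled loci must be unlinked; if `loci` metadata is supplied, selected
#' loci sharing a chromosome raise an error.
#'
#' @param sel a [selection_model()].
#' @param freqs alternate-allele frequencies at the model's loci (same order).
#' @param locus the locus (index into `sel$loci`'s values) to marginalize to.
#' @param loci optional locus table for the linkage check.
#' @param normalize divide out the genotype-independent constant.
#' @return a [fitness_triple()].
#' @export
marginal_fitness <- function(sel, freqs, locus, loci = NULL, normalize = FALSE) {
  k <- match(locus, sel$loci)
  if (is.na(k)) stop("locus ", locus, " is not in the selection model")
  if (!is.null(loci)) {
    ch <- loci$chrom[sel$loci]
    if (anyDuplicated(ch))
      stop("controlled/selected loci must be unlinked (one per chromosome)")
  }
  own <- unclass(sel$triples[[k]])
  const <- 1
  for (j in seq_along(sel$loci)) {
    if (j == k) next
    x <- freqs[j]
    w <- unclass(sel$triples[[j]])
    const <- const * ((1 - x)^2 * w[1L] + 2 * x * (1 - x) * w[2L] + x^2 * w[3L])
  }
  m <- own * const
  if (normalize) m <- m / const
  fitness_triple(m[1L], m[2L], m[3L])
}

trajectory_obj <- function(freqs, origin_gen, attempts) {
  freqs <- as.matrix(freqs)
  structure(list(freqs = freqs, origin_gen = origin_gen, attempts = attempts,
                 loci = NULL),
            class = "trajectory")
}

#' @method print trajectory
#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", ncol(x$freqs), " locus/loci over ",
      nrow(x$freqs) - 1L, " generations; origin at ",
      paste(x$origin_gen, collapse = ", "), "; accepted after ",
      x$attempts, " attempt(s)\n", sep = "")
  invisible(x)
}

traj_error <- function(msg, report) {
  stop(structure(class = c("trajectory_infeasible", "error", "condition"),
                 list(message = paste0(msg, " (", report, ")"), call = NULL,
                      report = report)))
}

#' Simulate a disease-allele frequency trajectory forward in time
#'
#' Starting from `x0` (the allele frequency in the initial population), each
#' generation applies the deterministic selection response and then binomial
#' sampling of `2 N_t` alleles. The whole path is re-drawn from scratch until
#' the present-day frequency lands in `x_range`; if `max_attempts` paths all
#' miss, an error of class `trajectory_infeasible` reports the average ending
#' frequency so the selection parameters can be adjusted.
#'
#' @param x0 starting frequency (> 0).
#' @param f a [fitness_triple()] (use [marginal_fitness()] for multilocus
#'   models).
#' @param sizes diploid size schedule, generations 0..T (see
#'   [size_schedule()]).
#' @param x_range length-2 acceptance interval for the frequency at
#'   generation T.
#' @param max_attempts maximum number of path restarts.
#' @param deterministic skip the binomial step (infinite-population limit).
#' @return a `trajectory` whose `freqs` has `T + 1` rows.
#' @export
simulate_forward_trajectory <- function(x0, f, sizes, x_range = c(0, 1),
                                        max_attempts = 1000L,
                                        deterministic = FALSE) {
  stopifnot(x0 > 0, x0 <= 1, length(x_range) == 2L)
  T <- length(sizes) - 1L
  endings <- numeric(0)
  for (att in seq_len(max_attempts)) {
    x <- numeric(T + 1L)
    x[1L] <- x0
    for (t in seq_len(T)) {
      p <- selection_response(x[t], f)
      x[t + 1L] <- if (deterministic) p else
        stats::rbinom(1L, 2L * sizes[t + 1L], p) / (2L * sizes[t + 1L])
    }
    endings <- c(endings, x[T + 1L])
    if (x[T + 1L] >= x_range[1L] && x[T + 1L] <= x_range[2L])
      return(trajectory_obj(x, origin_gen = 0L, attempts = att))
  }
  traj_error("no forward trajectory reached the target frequency range",
             sprintf("average ending frequency %.4f over %d attempts",
                     mean(endings), max_attempts))
}

#' Simulate a disease-allele frequency trajectory backward in time
#'
#' For a recent mutant: steps back from the present-day frequency `x_T` by
#' inverting the deterministic selection response and binomially resampling
#' `2 N_{t-1}` alleles, until the allele is lost; the generation at which the
#' frequency hits 0 is recorded as the origin. Paths that absorb at 1, or
#' whose origin lies more than `max_origin_gen` generations before present,
#' are re-drawn. On exhaustion the error reports the mean trajectory length.
#'
#' @param x_T present-day frequency (> 0).
#' @param f a [fitness_triple()].
#' @param sizes diploid size schedule, generations 0..T.
#' @param max_origin_gen maximum allele age in generations (default T).
#' @param max_attempts maximum number of path restarts.
#' @return a `trajectory` with zeros before `origin_gen`.
#' @export
simulate_backward_trajectory <- function(x_T, f, sizes,
                                         max_origin_gen = length(sizes) - 1L,
                                         max_attempts = 1000L) {
  stopifnot(x_T > 0, x_T <= 1)
  T <- length(sizes) - 1L
  lengths_seen <- numeric(0)
  for (att in seq_len(max_attempts)) {
    x <- numeric(T + 1L)
    x[T + 1L] <- x_T
    origin <- NA_integer_
    ok <- TRUE
    for (t in T:1) {
      inv <- inverse_selection_response(x[t + 1L], f)
      xp <- stats::rbinom(1L, 2L * sizes[t], inv) / (2L * sizes[t])
      if (xp >= 1) { ok <- FALSE; break }          # absorbed at 1: restart
      x[t] <- xp
      if (xp == 0) { origin <- t - 1L; break }
    }
    if (!ok) next
    if (is.na(origin)) { lengths_seen <- c(lengths_seen, T); next }
    lengths_seen <- c(lengths_seen, T - origin)
    if (T - origin > max_origin_gen) next
    return(trajectory_obj(x, origin_gen = origin, attempts = att))
  }
  traj_error("no backward trajectory reached loss within the allowed age",
             sprintf("mean trajectory length %.1f generations over %d attempts",
                     mean(lengths_seen), max_attempts))
}

#' Combine single-locus trajectories for controlled evolution
#'
#' @param trajs list of `trajectory` objects of equal length.
#' @param loci integer indices of the controlled loci, one per trajectory.
#' @return a `trajectory` with one frequency column per controlled locus.
#' @export
combine_trajectories <- function(trajs, loci) {
  stopifnot(length(trajs) == length(loci))
  tr <- trajectory_obj(do.call(cbind, lapply(trajs, `[[`, "freqs")),
                       origin_gen = vapply(trajs, `[[`, integer(1), "origin_gen"),
                       attempts = sum(vapply(trajs, `[[`, numeric(1), "attempts")))
  tr$loci <- as.integer(loci)
  tr
}

#' Write / read a trajectory as TSV (generation, locus, frequency)
#' @param traj a `trajectory`.
#' @param path file path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  k <- ncol(traj$freqs)
  loci <- if (is.null(traj$loci)) seq_len(k) else traj$loci
  df <- data.frame(
    generation = rep(0:(nrow(traj$freqs) - 1L), k),
    locus = rep(loci, each = nrow(traj$freqs)),
    frequency = as.vector(traj$freqs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  loci <- sort(unique(df$locus))
  freqs <- vapply(loci, function(l) df$frequency[df$locus == l],
                  numeric(sum(df$locus == loci[1L])))
  tr <- trajectory_obj(freqs, origin_gen = rep(NA_integer_, length(loci)),
                       attempts = NA)
  tr$loci <- as.integer(loci)
  tr
}

#' One generation of trajectory-controlled mating
#'
#' Offspring are produced by the usual fitness-weighted random mating and
#' accepted or rejected so that the offspring generation carries exactly
#' `target_counts[l]` copies of allele 1 at every controlled locus `l`.
#' An offspring with allele counts `c_l` is accepted iff for every
#' controlled locus `c_l` does not exceed the remaining quota and the quota
#' left after accepting it can still be met by the remaining slots
#' (`quota - c_l <= 2 * (slots - 1)`).
#'
#' @param pop a `population` with a single subpopulation.
#' @param loci integer indices of the controlled loci.
#' @param target_counts target allele-1 counts, one per controlled locus
#'   (typically `round(2 N_t x_t)`).
#' @param sel optional [selection_model()].
#' @param probs per-interval recombination probabilities.
#' @param mu per-locus mutation rate.
#' @param target_size offspring generation size (diploids); defaults to the
#'   current size.
#' @param max_tries_mult error out after `max_tries_mult * target_size`
#'   candidate offspring.
#' @return the next-generation `population` with exact controlled counts.
#' @export
controlled_offspring_generation <- function(pop, loci, target_counts,
                                            sel = NULL, probs = NULL, mu = 0,
                                            target_size = NULL,
                                            max_tries_mult = 2000L) {
  if (length(pop$subpops) != 1L)
    stop("controlled mating requires a single subpopulation")
  if (is.null(probs)) probs <- interval_recomb_probs(pop$loci)
  sp <- pop$subpops[[1L]]
  n <- if (is.null(target_size)) length(sp$sex) else as.integer(target_size)
  loci <- as.integer(loci)
  quota <- as.integer(target_counts)
  stopifnot(length(quota) == length(loci), all(quota >= 0L), all(quota <= 2L * n))
  ## feasibility: the parental pool must segregate compatibly at each locus
  odd <- 2L * seq_along(sp$sex) - 1L
  for (k in seq_along(loci)) {
    g <- sp$haps[odd, loci[k]] + sp$haps[odd + 1L, loci[k]]
    if (quota[k] > 0L && all(g == 0L))
      stop("quota infeasible at locus ", loci[k], ": allele 1 absent in parents")
    if (quota[k] < 2L * n && all(g == 2L))
      stop("quota infeasible at locus ", loci[k], ": allele 1 fixed in parents")
  }
  w <- subpop_fitness(sp$haps, sel)
  slots <- n
  acc_F <- matrix(0L, n, ncol(sp$haps))
  acc_M <- matrix(0L, n, ncol(sp$haps))
  acc_anc <- numeric(n)
  tries <- 0L
  max_tries <- max_tries_mult * n
  batch <- max(64L, n)
  while (slots > 0L) {
    if (tries >= max_tries)
      stop("controlled mating exceeded ", max_tries, " candidate offspring; ",
           "quota remaining at controlled loci: ",
           paste(quota, collapse = ", "))
    b <- min(batch, max_tries - tries)
    pr <- sample_parents(b, sp$sex, w)
    gamF <- make_gametes(sp$haps, pr$fathers, probs, mu)
    gamM <- make_gametes(sp$haps, pr$mothers, probs, mu)
    cnt <- gamF[, loci, drop = FALSE] + gamM[, loci, drop = FALSE]
    anc <- (sp$ancestry[pr$fathers] + sp$ancestry[pr$mothers]) / 2
    for (i in seq_len(b)) {
      tries <- tries + 1L
      ci <- cnt[i, ]
      if (all(ci <= quota) && all(quota - ci <= 2L * (slots - 1L))) {
        j <- n - slots + 1L
        acc_F[j, ] <- gamF[i, ]
        acc_M[j, ] <- gamM[i, ]
        acc_anc[j] <- anc[i]
        quota <- quota - ci
        slots <- slots - 1L
        if (slots == 0L) break
      }
    }
  }
  haps <- matrix(0L, 2L * n, ncol(sp$haps))
  haps[2L * seq_len(n) - 1L, ] <- acc_F
  haps[2L * seq_len(n), ] <- acc_M
  pop$subpops[[1L]] <- new_subpop(haps, stats::rbinom(n, 1L, 0.5) + 1L, acc_anc)
  pop$generation <- pop$generation + 1L
  pop
}
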