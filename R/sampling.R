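## Draw analysis-ready samples from an evolved population: random,
## case-control (direct or rejection) and affected-offspring trios.
## Sample draws never mutate the source population.

new_gwas_sample <- function(loci, ind, haps) {
  structure(list(loci = loci, ind = ind, haps = haps), class = "gwas_sample")
}

#' @method print gwas_sample
#' @export
print.gwas_sample <- function(x, ...) {
  cat("<gwas_sample> ", nrow(x$ind), " individuals (",
      sum(x$ind$pheno %in% TRUE), " affected) x ", nrow(x$loci), " loci\n",
      sep = "")
  invisible(x)
}

## build singleton-family sample rows from pooled population indices
singleton_sample <- function(pop, idx) {
  haps_all <- pop_haps(pop)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  n <- length(idx)
  ind <- data.frame(
    fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
    pat = rep("0", n), mat = rep("0", n),
    sex = pop_field(pop, "sex")[idx],
    pheno = pop_field(pop, "affected")[idx],
    env = pop_field(pop, "env")[idx],
    ancestry = pop_field(pop, "ancestry")[idx],
    stringsAsFactors = FALSE)
  new_gwas_sample(pop$loci, ind, haps_all[rows, , drop = FALSE])
}

#' Draw a uniform random sample of individuals
#'
#' @param pop a `population` (pooled over subpopulations).
#' @param n sample size; uniform without replacement.
#' @return a `gwas_sample` of singleton families.
#' @export
draw_random_sample <- function(pop, n) {
  N <- pop_size(pop)
  if (n > N) stop("requested ", n, " individuals from a population of ", N)
  singleton_sample(pop, sample.int(N, n))
}

#' Draw cases and controls directly from the population
#'
#' Uniform without replacement within the affected and unaffected strata;
#' requires [assign_affection()] to have been run.
#'
#' @param pop a `population` with affection status set.
#' @param n_cases,n_controls stratum sizes.
#' @return a `gwas_sample`; phenotype TRUE for cases.
#' @export
draw_case_control_direct <- function(pop, n_cases, n_controls) {
  aff <- pop_field(pop, "affected")
  if (anyNA(aff)) stop("affection status not assigned; run assign_affection()")
  cases <- which(aff); controls <- which(!aff)
  if (length(cases) < n_cases || length(controls) < n_controls)
    stop("population holds ", length(cases), " cases and ", length(controls),
         " controls; need ", n_cases, "/", n_controls,
         " (consider draw_case_control_rejection)")
  idx <- c(cases[sample.int(length(cases), n_cases)],
           controls[sample.int(length(controls), n_controls)])
  singleton_sample(pop, idx)
}

## produce `b` offspring from `b` freshly drawn uniform parent pairs;
## returns haplotypes, genotype fields needed by the model, and metadata
offspring_batch <- function(haps, sex_pool, anc_pool, b, probs, mu) {
  N <- length(sex_pool)
  fa <- sample.int(N, b, replace = TRUE)
  mo <- sample.int(N, b, replace = TRUE)
  gamF <- make_gametes(haps, fa, probs, mu)
  gamM <- make_gametes(haps, mo, probs, mu)
  list(fa = fa, mo = mo, gamF = gamF, gamM = gamM,
       anc = (anc_pool[fa] + anc_pool[mo]) / 2)
}

offspring_penetrance <- function(model, gamF, gamM, anc) {
  b <- nrow(gamF)
  if (inherits(model, "logistic_disease_model")) {
    g1 <- gamF[, model$loci[1L]] + gamM[, model$loci[1L]]
    g2 <- gamF[, model$loci[2L]] + gamM[, model$loci[2L]]
    env <- as.integer(stats::runif(b) < model$env_p)
    list(p = penetrance(model, g1, g2, env), env = env)
  } else if (inherits(model, c("single_locus_logistic_model",
                               "genotype_table_model"))) {
    g <- gamF[, model$locus] + gamM[, model$locus]
    list(p = penetrance(model, g), env = rep(NA_real_, b))
  } else if (inherits(model, "ancestry_linear_model")) {
    list(p = penetrance(model, anc), env = rep(NA_real_, b))
  } else stop("unknown disease model class")
}

#' Rejection-sample a case-control panel of simulated offspring
#'
#' Repeatedly draws a fresh uniform parent pair from the population, produces
#' one offspring by standard transmission, assigns affection from the
#' penetrance model, and files the offspring under the first unfilled quota
#' matching its status, until both quotas are full. Suited to rare diseases
#' where the population itself holds too few affected individuals.
#'
#' @param pop a `population`.
#' @param n_cases,n_controls quotas (honored exactly).
#' @param model a disease model object.
#' @param mu per-locus mutation rate for transmission (default 0).
#' @param max_draws error out (reporting achieved counts) after this many
#'   candidate offspring; guards against near-impossible quotas.
#' @return a `gwas_sample` of unrelated simulated offspring.
#' @export
draw_case_control_rejection <- function(pop, n_cases, n_controls, model,
                                        mu = 0,
                                        max_draws = 2000L * (n_cases + n_controls)) {
  probs <- if (nrow(pop$loci) > 1L) interval_recomb_probs(pop$loci) else numeric(0)
  haps <- pop_haps(pop)
  sex_pool <- pop_field(pop, "sex"); anc_pool <- pop_field(pop, "ancestry")
  n_tot <- n_cases + n_controls
  kept <- matrix(0L, 2L * n_tot, ncol(haps))
  pheno <- logical(n_tot); envs <- numeric(n_tot); ancs <- numeric(n_tot)
  got_case <- 0L; got_ctrl <- 0L; filled <- 0L; draws <- 0L
  while (got_case < n_cases || got_ctrl < n_controls) {
    if (draws >= max_draws)
      stop("rejection sampling exhausted ", max_draws, " offspring with ",
           got_case, "/", n_cases, " cases and ", got_ctrl, "/", n_controls,
           " controls collected")
    b <- min(max(256L, n_tot), max_draws - draws)
    off <- offspring_batch(haps, sex_pool, anc_pool, b, probs, mu)
    pen <- offspring_penetrance(model, off$gamF, off$gamM, off$anc)
    affected <- stats::runif(b) < pen$p
    draws <- draws + b
    for (i in seq_len(b)) {
      take <- if (affected[i]) got_case < n_cases else got_ctrl < n_controls
      if (!take) next
      filled <- filled + 1L
      kept[2L * filled - 1L, ] <- off$gamF[i, ]
      kept[2L * filled, ] <- off$gamM[i, ]
      pheno[filled] <- affected[i]; envs[filled] <- pen$env[i]
      ancs[filled] <- off$anc[i]
      if (affected[i]) got_case <- got_case + 1L else got_ctrl <- got_ctrl + 1L
      if (got_case == n_cases && got_ctrl == n_controls) break
    }
  }
  ind <- data.frame(
    fid = sprintf("F%d", seq_len(n_tot)), iid = sprintf("I%d", seq_len(n_tot)),
    pat = "0", mat = "0", sex = sample(c(1L, 2L), n_tot, replace = TRUE),
    pheno = pheno, env = envs, ancestry = ancs, stringsAsFactors = FALSE)
  new_gwas_sample(pop$loci, ind, kept)
}

#' Rejection-sample affected-offspring trio families
#'
#' Repeatedly draws a uniform parent pair (with replacement across trios),
#' produces one offspring, and keeps the trio iff the offspring is affected
#' under the penetrance model. Family IDs are sequential; each family's rows
#' are father, mother, affected child.
#'
#' @param pop a `population`.
#' @param n_trios number of trios to collect (honored exactly).
#' @param model a disease model object.
#' @param mu per-locus mutation rate for transmission (default 0).
#' @param max_draws cap on candidate offspring; exceeding it errors with the
#'   achieved count.
#' @return a `gwas_sample` with 3 individuals per family.
#' @export
draw_trios_rejection <- function(pop, n_trios, model, mu = 0,
                                 max_draws = 2000L * n_trios) {
  probs <- if (nrow(pop$loci) > 1L) interval_recomb_probs(pop$loci) else numeric(0)
  haps <- pop_haps(pop)
  sex_pool <- pop_field(pop, "sex"); anc_pool <- pop_field(pop, "ancestry")
  L <- ncol(haps)
  kept <- matrix(0L, 6L * n_trios, L)   # fa0 fa1 mo0 mo1 ch0 ch1 per family
  envs <- numeric(n_trios); ancs_ch <- numeric(n_trios)
  fa_idx <- integer(n_trios); mo_idx <- integer(n_trios)
  got <- 0L; draws <- 0L
  while (got < n_trios) {
    if (draws >= max_draws)
      stop("trio rejection sampling exhausted ", max_draws,
           " offspring with ", got, "/", n_trios, " trios collected")
    b <- min(max(256L, n_trios), max_draws - draws)
    off <- offspring_batch(haps, sex_pool, anc_pool, b, probs, mu)
    pen <- offspring_penetrance(model, off$gamF, off$gamM, off$anc)
    affected <- stats::runif(b) < pen$p
    draws <- draws + b
    for (i in which(affected)) {
      got <- got + 1L
      r <- 6L * (got - 1L)
      kept[r + 1L:2L, ] <- haps[c(2L * off$fa[i] - 1L, 2L * off$fa[i]), ]
      kept[r + 3L:4L, ] <- haps[c(2L * off$mo[i] - 1L, 2L * off$mo[i]), ]
      kept[r + 5L, ] <- off$gamF[i, ]
      kept[r + 6L, ] <- off$gamM[i, ]
      envs[got] <- pen$env[i]; ancs_ch[got] <- off$anc[i]
      fa_idx[got] <- off$fa[i]; mo_idx[got] <- off$mo[i]
      if (got == n_trios) break
    }
  }
  fam <- rep(seq_len(n_trios), each = 3L)
  role <- rep(c("father", "mother", "child"), n_trios)
  anc_all <- pop_field(pop, "ancestry")
  ind <- data.frame(
    fid = sprintf("F%d", fam),
    iid = sprintf("I%d_%d", fam, rep(1:3, n_trios)),
    pat = ifelse(role == "child", sprintf("I%d_1", fam), "0"),
    mat = ifelse(role == "child", sprintf("I%d_2", fam), "0"),
    sex = ifelse(role == "father", 1L, ifelse(role == "mother", 2L,
                 sample(c(1L, 2L), 3L * n_trios, replace = TRUE))),
    pheno = ifelse(role == "child", TRUE, NA),
    env = ifelse(role == "child", rep(envs, each = 3L), NA_real_),
    ancestry = ifelse(role == "child", rep(ancs_ch, each = 3L),
                      ifelse(role == "father", rep(anc_all[fa_idx], each = 3L),
                             rep(anc_all[mo_idx], each = 3L))),
    stringsAsFactors = FALSE)
  new_gwas_sample(pop$loci, ind, kept)
}
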