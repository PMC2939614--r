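## Penetrance models, prevalence calibration, and affection assignment.

expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Two-locus logistic disease model with GxG and GxE interactions
#'
#' Penetrance is
#' `expit(alpha + beta1 g1 + beta2 g2 + beta3 g1 g2 + gamma1 g1 e + gamma2 g2 e)`
#' where `g1`, `g2` are the disease-allele counts at the two unlinked loci
#' and `e` is a binary environmental factor with `P(e = 1) = env_p`.
#'
#' @param alpha intercept.
#' @param beta1,beta2 main effects of the two disease-allele counts.
#' @param beta3 gene-gene interaction coefficient.
#' @param gamma1,gamma2 gene-environment interaction coefficients.
#' @param env_p probability that the environmental factor equals 1.
#' @param loci length-2 integer vector of locus indices.
#' @export
logistic_disease_model <- function(alpha, beta1, beta2, beta3 = 0,
                                   gamma1 = 0, gamma2 = 0, env_p = 0.5,
                                   loci = c(1L, 2L)) {
  stopifnot(env_p >= 0, env_p <= 1, length(loci) == 2L)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 gamma1 = gamma1, gamma2 = gamma2, env_p = env_p,
                 loci = as.integer(loci)),
            class = c("logistic_disease_model", "disease_model"))
}

#' Two-locus logistic model with the half-effect constraint
#'
#' Constructor variant enforcing `beta1 = beta2 / 2` and
#' `gamma1 = gamma2 / 2` (the first locus has half the effect of the
#' second); supplying violating values is an error.
#'
#' @inheritParams logistic_disease_model
#' @export
logistic_disease_model_paired <- function(alpha, beta2, gamma2 = 0, beta3 = 0,
                                          env_p = 0.5, loci = c(1L, 2L),
                                          beta1 = beta2 / 2,
                                          gamma1 = gamma2 / 2) {
  if (!isTRUE(all.equal(beta1, beta2 / 2)) ||
      !isTRUE(all.equal(gamma1, gamma2 / 2)))
    stop("this constructor requires beta1 = beta2/2 and gamma1 = gamma2/2")
  logistic_disease_model(alpha, beta1, beta2, beta3, gamma1, gamma2,
                         env_p, loci)
}

#' Single-locus logistic penetrance model
#'
#' `logit(P(affected)) = intercept + slope * g`, `g` the disease-allele
#' count at `locus`.
#'
#' @param intercept,slope logistic coefficients.
#' @param locus locus index.
#' @export
single_locus_logistic_model <- function(intercept, slope, locus = 1L) {
  structure(list(intercept = intercept, slope = slope, locus = as.integer(locus)),
            class = c("single_locus_logistic_model", "disease_model"))
}

#' Ancestry-linear penetrance model
#'
#' `P(affected) = base + slope * ancestry`, clipped to \[0, 1\]. The default
#' `0.05 + ancestry / 6` makes individuals with full migrant ancestry about
#' 4.3 times as susceptible as natives without any marker being causal.
#'
#' @param base baseline penetrance at ancestry 0.
#' @param slope increase in penetrance per unit ancestry.
#' @export
ancestry_linear_model <- function(base = 0.05, slope = 1 / 6) {
  structure(list(base = base, slope = slope),
            class = c("ancestry_linear_model", "disease_model"))
}

#' Genotype-table penetrance model
#'
#' Directly specifies `Pr(affected | genotype)` for the three genotypes at
#' one locus (0, 1, 2 copies of the disease allele), with no functional-form
#' constraint.
#'
#' @param penetrances length-3 vector of probabilities.
#' @param locus locus index.
#' @export
genotype_table_model <- function(penetrances, locus = 1L) {
  stopifnot(length(penetrances) == 3L,
            all(penetrances >= 0), all(penetrances <= 1))
  structure(list(penetrances = penetrances, locus = as.integer(locus)),
            class = c("genotype_table_model", "disease_model"))
}

#' @export
penetrance.genotype_table_model <- function(model, g, ...) {
  model$penetrances[g + 1L]
}

#' Penetrance of a disease model
#'
#' Probability of being affected given genotype (and environment or
#' ancestry, depending on the model). All methods are vectorized.
#'
#' @param model a disease model object.
#' @param ... model-specific arguments: `g1`, `g2`, `env` for
#'   [logistic_disease_model()]; `g` for [single_locus_logistic_model()];
#'   `ancestry` for [ancestry_linear_model()].
#' @return probabilities in \[0, 1\].
#' @export
penetrance <- function(model, ...) UseMethod("penetrance")

#' @export
penetrance.logistic_disease_model <- function(model, g1, g2, env, ...) {
  if (missing(env) || is.null(env))
    stop("the gene-environment model requires the environmental state 'env'")
  expit(model$alpha + model$beta1 * g1 + model$beta2 * g2 +
          model$beta3 * g1 * g2 + model$gamma1 * g1 * env +
          model$gamma2 * g2 * env)
}

#' @export
penetrance.single_locus_logistic_model <- function(model, g, ...) {
  expit(model$intercept + model$slope * g)
}

#' @export
penetrance.ancestry_linear_model <- function(model, ancestry, ...) {
  pmin(1, pmax(0, model$base + model$slope * ancestry))
}

hwe_probs <- function(x) c((1 - x)^2, 2 * x * (1 - x), x^2)

## exact prevalence of a two-locus GxE model by 3 x 3 x 2 enumeration,
## assuming HWE and independence across the unlinked loci
enumerate_prevalence <- function(model, q1, q2) {
  p1 <- hwe_probs(q1); p2 <- hwe_probs(q2)
  pe <- c(1 - model$env_p, model$env_p)
  tot <- 0
  for (g1 in 0:2) for (g2 in 0:2) for (e in 0:1)
    tot <- tot + p1[g1 + 1L] * p2[g2 + 1L] * pe[e + 1L] *
      penetrance(model, g1, g2, e)
  tot
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' With the effect coefficients fixed, finds `alpha` such that the exact
#' prevalence — the expectation of penetrance over the 3 x 3 x 2
#' genotype-environment classes under HWE at the supplied disease-allele
#' frequencies — equals `target_prevalence`. Prevalence is monotone in
#' `alpha`, so bisection converges; the result satisfies
#' `|prevalence - target| < 1e-10`.
#'
#' @param model a [logistic_disease_model()] (its `alpha` is ignored).
#' @param dpa_freqs length-2 vector of disease-allele frequencies `(q1, q2)`.
#' @param target_prevalence target population fraction affected, in (0, 1).
#' @return the calibrated intercept `alpha`.
#' @export
calibrate_intercept <- function(model, dpa_freqs, target_prevalence) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target prevalence must be in (0, 1)")
  q1 <- dpa_freqs[1L]; q2 <- dpa_freqs[2L]
  fn <- function(a) {
    m <- model; m$alpha <- a
    enumerate_prevalence(m, q1, q2) - target_prevalence
  }
  lo <- logit(target_prevalence) - 50; hi <- logit(target_prevalence) + 50
  while (hi - lo > 1e-14 || abs(fn((lo + hi) / 2)) >= 1e-10) {
    mid <- (lo + hi) / 2
    if (fn(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(1, abs(lo))) break
  }
  (lo + hi) / 2
}

#' Assign affection status to every individual
#'
#' Draws any environmental state required by the model, evaluates penetrance
#' per individual, and sets `affected` by an independent Bernoulli draw.
#' Environmental states are stored for covariate export.
#'
#' @param pop a `population`.
#' @param model a disease model object.
#' @return the `population` with `affected` (and `env`) fields set.
#' @export
assign_affection <- function(pop, model) {
  pop$subpops <- lapply(pop$subpops, function(sp) {
    n <- length(sp$sex)
    pen <- penetrance_subpop(model, sp, pop$loci)
    sp$env <- pen$env
    sp$affected <- stats::runif(n) < pen$p
    sp
  })
  pop
}

## per-subpop penetrance + environment draw
penetrance_subpop <- function(model, sp, loci) {
  n <- length(sp$sex)
  odd <- 2L * seq_len(n) - 1L
  if (inherits(model, "logistic_disease_model")) {
    g1 <- sp$haps[odd, model$loci[1L]] + sp$haps[odd + 1L, model$loci[1L]]
    g2 <- sp$haps[odd, model$loci[2L]] + sp$haps[odd + 1L, model$loci[2L]]
    env <- as.integer(stats::runif(n) < model$env_p)
    list(p = penetrance(model, g1, g2, env), env = env)
  } else if (inherits(model, c("single_locus_logistic_model",
                               "genotype_table_model"))) {
    g <- sp$haps[odd, model$locus] + sp$haps[odd + 1L, model$locus]
    list(p = penetrance(model, g), env = rep(NA_real_, n))
  } else if (inherits(model, "ancestry_linear_model")) {
    list(p = penetrance(model, sp$ancestry), env = rep(NA_real_, n))
  } else stop("unknown disease model class")
}
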