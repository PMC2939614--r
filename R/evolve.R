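## Forward-time engine: demography, lambda-scaling, transmission with
## map-based recombination and symmetric mutation, fitness-weighted mating,
## migration, and admixture with ancestry tracking.

round_half_up <- function(x) floor(x + 0.5)

fw_log <- function(...) {
  if (isTRUE(getOption("fwdgwas.verbose", FALSE))) message(...)
}

## Configuration objects -----------------------------------------------------

#' Demographic model
#'
#' Population-size history from `N0` to `NT` diploids over `T` generations.
#' The linear schedule adds the same number of individuals each generation
#' (expanding faster at first, which preserves more founder diversity and
#' yields a larger harmonic-mean effective size than exponential growth);
#' the exponential schedule multiplies by a constant factor.
#'
#' @param N0 initial diploid size (>= 1).
#' @param NT final diploid size (>= 1).
#' @param T number of generations (>= 0).
#' @param schedule one of `"linear"`, `"exponential"`, `"constant"`.
#' @param sizes optional explicit integer schedule of length `T + 1`;
#'   overrides `schedule` (used internally by [scale_config()]).
#' @export
demographic_model <- function(N0, NT = N0, T, schedule = c("linear", "exponential", "constant"),
                              sizes = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(N0 >= 1, NT >= 1, T >= 0)
  if (T == 0 && N0 != NT && is.null(sizes))
    stop("T = 0 with N0 != NT is inconsistent")
  structure(list(N0 = as.integer(N0), NT = as.integer(NT), T = as.integer(T),
                 schedule = schedule, sizes = sizes),
            class = "demographic_model")
}

#' Per-generation population sizes for a demographic model
#'
#' Linear: `N_t = round(N0 + t (NT - N0) / T)`; exponential:
#' `N_t = round(N0 (NT/N0)^(t/T))`. Endpoints are exact by construction.
#'
#' @param dem a [demographic_model()].
#' @return integer vector of length `T + 1` (generations 0..T).
#' @export
size_schedule <- function(dem) {
  if (!is.null(dem$sizes)) return(as.integer(dem$sizes))
  T <- dem$T
  if (T == 0L) return(dem$N0)
  t <- 0:T
  n <- switch(dem$schedule,
    linear      = round(dem$N0 + t * (dem$NT - dem$N0) / T),
    exponential = round(dem$N0 * (dem$NT / dem$N0)^(t / T)),
    constant    = rep(dem$N0, T + 1L))
  n[1L] <- dem$N0; n[T + 1L] <- dem$NT
  as.integer(n)
}

#' Relative fitness of the three genotypes at a biallelic locus
#'
#' `w11`, `w12`, `w22` are the fitnesses of genotypes carrying 0, 1 and 2
#' copies of the selected (alternate) allele.
#'
#' @param w11,w12,w22 non-negative relative fitnesses.
#' @export
fitness_triple <- function(w11, w12, w22) {
  w <- c(w11 = unname(w11), w12 = unname(w12), w22 = unname(w22))
  if (any(w < 0)) stop("fitness values must be non-negative")
  structure(w, class = "fitness_triple")
}

#' Multiplicative multilocus selection model
#'
#' @param loci integer locus indices (distinct).
#' @param triples list of [fitness_triple()]s, one per locus; a single triple
#'   is recycled.
#' @export
selection_model <- function(loci, triples) {
  if (inherits(triples, "fitness_triple")) triples <- list(triples)
  triples <- rep_len(triples, length(loci))
  if (anyDuplicated(loci)) stop("selection loci must be distinct")
  structure(list(loci = as.integer(loci), triples = triples),
            class = "selection_model")
}

#' Migration model
#'
#' `stepping_stone`: each generation, `round(m * N_i)` uniformly chosen
#' individuals move from each subpopulation to each adjacent one on a 1-D
#' chain, reciprocally and simultaneously from the pre-migration state.
#' `gene_flow` (continuous gene-flow admixture model): each generation,
#' `round(p * N_sink)` uniformly chosen sink individuals are replaced by
#' copies sampled (with replacement) from the source, so migrants make up
#' fraction `p` of the post-migration sink.
#'
#' @param kind `"stepping_stone"` or `"gene_flow"`.
#' @param m per-generation migration fraction (stepping stone).
#' @param p per-generation gene-flow fraction.
#' @param source,sink subpopulation indices (gene flow).
#' @param duration number of generations the model applies (default: all).
#' @export
migration_model <- function(kind = c("stepping_stone", "gene_flow"),
                            m = 0, p = 0, source = 1L, sink = 2L,
                            duration = Inf) {
  kind <- match.arg(kind)
  stopifnot(m >= 0, m <= 1, p >= 0, p <= 1)
  structure(list(kind = kind, m = m, p = p, source = as.integer(source),
                 sink = as.integer(sink), duration = duration),
            class = "migration_model")
}

#' Assortative-mating admixture configuration
#'
#' Individuals are split into two groups at the ancestry `threshold`; a
#' fraction `assort_within` of matings draws both parents from one group
#' (the group of a uniformly chosen index parent), the rest from the whole
#' population.
#'
#' @param assort_within fraction of matings constrained within ancestry group.
#' @param threshold ancestry cut separating the groups.
#' @param subpop subpopulation the scheme applies to.
#' @export
admixture_config <- function(assort_within = 0.8, threshold = 0.5, subpop = 1L) {
  stopifnot(assort_within >= 0, assort_within <= 1)
  structure(list(assort_within = assort_within, threshold = threshold,
                 subpop = as.integer(subpop)),
            class = "admixture_config")
}

#' Full evolution configuration
#'
#' Demography plus genetic forces plus the scaling factor lambda; together
#' with a seed this fully determines a run.
#'
#' @param demographic a [demographic_model()].
#' @param mu per-locus per-generation symmetric mutation rate.
#' @param selection optional [selection_model()].
#' @param migration optional [migration_model()].
#' @param admixture optional [admixture_config()].
#' @param lam scaling factor lambda >= 1 (see [scale_config()]).
#' @param seed optional integer seed set at the start of [evolve()].
#' @param summary_every generations between logged summaries.
#' @param watched_loci locus indices whose frequencies the summary log tracks.
#' @param recomb_scale internal multiplier on per-interval recombination
#'   probabilities (set by [scale_config()]).
#' @export
evolution_config <- function(demographic, mu = 1e-8, selection = NULL,
                             migration = NULL, admixture = NULL, lam = 1,
                             seed = NULL, summary_every = 10L,
                             watched_loci = integer(0), recomb_scale = 1) {
  stopifnot(mu >= 0, mu <= 1, lam >= 1)
  structure(list(demographic = demographic, mu = mu, selection = selection,
                 migration = migration, admixture = admixture, lam = lam,
                 seed = seed, summary_every = as.integer(summary_every),
                 watched_loci = as.integer(watched_loci),
                 recomb_scale = recomb_scale),
            class = "evolution_config")
}

#' Rewrite a configuration for lambda-scaled execution
#'
#' A scaled run evolves a population of size `N/lambda` for `T/lambda`
#' generations with all forces magnified by lambda: mutation rate
#' `lambda * mu`, per-interval recombination probability
#' `min(lambda * r, 0.5)`, and fitness deviations `w' = 1 + lambda (w - 1)`
#' (clipped at 0 with a warning). The diffusion argument behind this shortcut
#' holds only for weak additive forces; callers should refuse large lambda
#' with strongly non-additive fitness (the CLI does).
#'
#' @param cfg an [evolution_config()].
#' @return an executable [evolution_config()] with `lam = 1`.
#' @export
scale_config <- function(cfg) {
  lam <- cfg$lam
  if (lam == 1) return(cfg)
  full <- size_schedule(cfg$demographic)
  T <- length(full) - 1L
  Ts <- max(1L, round_half_up(T / lam))
  sizes <- vapply(0:Ts, function(t) {
    idx <- min(round_half_up(t * lam), T)
    max(1L, as.integer(round_half_up(full[idx + 1L] / lam)))
  }, integer(1))
  dem <- demographic_model(sizes[1L], sizes[Ts + 1L], Ts, sizes = sizes)
  sel <- cfg$selection
  if (!is.null(sel)) {
    sel$triples <- lapply(sel$triples, function(w) {
      w2 <- 1 + lam * (unclass(w) - 1)
      if (any(w2 < 0)) {
        warning("scaled fitness below 0 clipped to 0")
        w2 <- pmax(w2, 0)
      }
      fitness_triple(w2[1L], w2[2L], w2[3L])
    })
  }
  evolution_config(dem, mu = min(1, lam * cfg$mu), selection = sel,
                   migration = cfg$migration, admixture = cfg$admixture,
                   lam = 1, seed = cfg$seed, summary_every = cfg$summary_every,
                   watched_loci = cfg$watched_loci, recomb_scale = lam)
}

## Transmission --------------------------------------------------------------

#' Per-interval recombination probabilities from genetic positions
#'
#' Haldane's map function converts the cM distance between adjacent loci into
#' a recombination fraction `r = 0.5 (1 - exp(-2 d))`, `d` in Morgans;
#' chromosome boundaries recombine freely (`r = 0.5`). An optional scale
#' multiplies the probabilities (not distances), capped at 0.5.
#'
#' @param loci a locus table with `chrom` and non-`NA` `cm`.
#' @param scale probability multiplier (lambda scaling).
#' @return numeric vector of length `nrow(loci) - 1`.
#' @export
interval_recomb_probs <- function(loci, scale = 1) {
  L <- nrow(loci)
  if (L < 2L) return(numeric(0))
  if (anyNA(loci$cm))
    stop("loci lack genetic positions; call assign_cm() first")
  d <- diff(loci$cm) / 100                       # Morgans
  r <- 0.5 * (1 - exp(-2 * d))
  r <- pmin(0.5, scale * r)
  r[loci$chrom[-1L] != loci$chrom[-L]] <- 0.5    # free between chromosomes
  r
}

#' Form one gamete by meiosis
#'
#' Starts from a fair-coin choice of parental haplotype and switches source
#' haplotype at interval `i` with probability `probs[i]`.
#'
#' @param hap0,hap1 the parent's two haplotypes (binary vectors).
#' @param probs per-interval recombination probabilities, length `L - 1`.
#' @return a binary gamete vector of length `L`.
#' @export
recombine_gamete <- function(hap0, hap1, probs) {
  L <- length(hap0)
  s <- stats::rbinom(1L, 1L, 0.5)
  if (L > 1L) {
    sw <- stats::runif(L - 1L) < probs
    s <- (s + cumsum(c(0L, sw))) %% 2L
  }
  ifelse(s == 0L, hap0, hap1)
}

#' Mutate a haplotype under the symmetric diallelic model
#'
#' Each site flips 0 <-> 1 independently with probability `mu`.
#'
#' @param hap binary vector.
#' @param mu per-site mutation probability.
#' @export
mutate_haplotype <- function(hap, mu) {
  if (mu <= 0) return(hap)
  flip <- stats::runif(length(hap)) < mu
  hap[flip] <- 1L - hap[flip]
  hap
}

## vectorized meiosis: one gamete per entry of `parents` (individual indices
## into haps rows 2i-1, 2i); returns n x L integer matrix
make_gametes <- function(haps, parents, probs, mu = 0) {
  L <- ncol(haps)
  n <- length(parents)
  A <- haps[2L * parents - 1L, , drop = FALSE]
  B <- haps[2L * parents, , drop = FALSE]
  cur <- stats::rbinom(n, 1L, 0.5)
  S <- matrix(0L, n, L)
  S[, 1L] <- cur
  if (L > 1L) {
    sw <- matrix(stats::runif(n * (L - 1L)), n, L - 1L) <
      matrix(probs, n, L - 1L, byrow = TRUE)
    for (j in 2:L) {
      cur <- (cur + sw[, j - 1L]) %% 2L
      S[, j] <- cur
    }
  }
  g <- A * (1L - S) + B * S
  if (mu > 0) {
    nf <- stats::rbinom(1L, n * L, mu)
    if (nf > 0L) {
      idx <- sample.int(n * L, nf)
      g[idx] <- 1L - g[idx]
    }
  }
  g
}

## Fitness -------------------------------------------------------------------

#' Relative fitness of a diploid genotype under a multilocus model
#'
#' Multiplicative across selected loci: the product of the fitness-triple
#' entries matching the individual's alternate-allele counts.
#'
#' @param hap0,hap1 the individual's haplotypes.
#' @param sel a [selection_model()] or `NULL` (fitness 1).
#' @export
genotype_fitness <- function(hap0, hap1, sel) {
  if (is.null(sel)) return(1)
  w <- 1
  for (k in seq_along(sel$loci)) {
    g <- hap0[sel$loci[k]] + hap1[sel$loci[k]]
    w <- w * unname(unclass(sel$triples[[k]]))[g + 1L]
  }
  w
}

## per-individual fitness vector for a 2n x L haplotype matrix
subpop_fitness <- function(haps, sel) {
  n <- nrow(haps) %/% 2L
  if (is.null(sel)) return(rep(1, n))
  w <- rep(1, n)
  odd <- 2L * seq_len(n) - 1L
  for (k in seq_along(sel$loci)) {
    l <- sel$loci[k]
    g <- haps[odd, l] + haps[odd + 1L, l]
    w <- w * unname(unclass(sel$triples[[k]]))[g + 1L]
  }
  w
}

## fitness-weighted parent index sampling, father/mother by sex where possible
sample_parents <- function(n, sex, w) {
  draw <- function(pool) {
    if (length(pool) == 0L) return(NULL)
    wp <- w[pool]
    if (all(wp == 0)) stop("all candidate parents have fitness 0")
    pool[sample.int(length(pool), n, replace = TRUE, prob = wp)]
  }
  males <- which(sex == 1L); females <- which(sex == 2L)
  fa <- draw(males); mo <- draw(females)
  if (is.null(fa) || is.null(mo)) {
    warning("subpopulation lacks one sex; mating ignores sex this generation")
    all <- seq_along(sex)
    fa <- draw(all); mo <- draw(all)
  }
  list(fathers = fa, mothers = mo)
}

## Mating --------------------------------------------------------------------

#' One generation of fitness-weighted random mating
#'
#' For each offspring a father and a mother are drawn independently within
#' the subpopulation with probability proportional to fitness (with
#' replacement); the child receives one recombined and mutated gamete from
#' each, a fair-coin sex, and the mean of the parental ancestries.
#'
#' @param pop a `population`.
#' @param target_sizes integer vector of next-generation sizes per subpop.
#' @param sel optional [selection_model()].
#' @param probs per-interval recombination probabilities
#'   (see [interval_recomb_probs()]).
#' @param mu per-locus mutation rate.
#' @return the next-generation `population`.
#' @export
random_mating_generation <- function(pop, target_sizes, sel = NULL,
                                     probs = NULL, mu = 0) {
  if (is.null(probs)) probs <- interval_recomb_probs(pop$loci)
  target_sizes <- rep_len(as.integer(target_sizes), length(pop$subpops))
  if (any(target_sizes < 1L)) stop("target subpopulation sizes must be >= 1")
  pop$subpops <- lapply(seq_along(pop$subpops), function(k) {
    breed_subpop(pop$subpops[[k]], target_sizes[k], sel, probs, mu)
  })
  pop$generation <- pop$generation + 1L
  pop
}

breed_subpop <- function(sp, n, sel, probs, mu,
                         fathers = NULL, mothers = NULL) {
  if (is.null(fathers)) {
    w <- subpop_fitness(sp$haps, sel)
    pr <- sample_parents(n, sp$sex, w)
    fathers <- pr$fathers; mothers <- pr$mothers
  }
  gamF <- make_gametes(sp$haps, fathers, probs, mu)
  gamM <- make_gametes(sp$haps, mothers, probs, mu)
  haps <- matrix(0L, 2L * n, ncol(sp$haps))
  haps[2L * seq_len(n) - 1L, ] <- gamF
  haps[2L * seq_len(n), ] <- gamM
  new_subpop(haps,
             sex = stats::rbinom(n, 1L, 0.5) + 1L,
             ancestry = (sp$ancestry[fathers] + sp$ancestry[mothers]) / 2)
}

#' One generation of assortative mating during admixture
#'
#' With probability `assort_within` both parents are drawn (fitness-weighted)
#' from the ancestry group of a uniformly drawn index parent (ancestry `>=`
#' threshold vs `<` threshold); otherwise both are drawn from the whole
#' subpopulation. Child ancestry is the parental mean, so mating alone never
#' changes the subpopulation's expected mean ancestry.
#'
#' @param pop a `population`.
#' @param adm an [admixture_config()].
#' @param target_size next-generation size of the admixing subpopulation.
#' @param probs per-interval recombination probabilities.
#' @param mu per-locus mutation rate.
#' @param sel optional [selection_model()].
#' @export
admixture_generation <- function(pop, adm, target_size, probs = NULL, mu = 0,
                                 sel = NULL) {
  if (is.null(probs)) probs <- interval_recomb_probs(pop$loci)
  k <- adm$subpop
  sp <- pop$subpops[[k]]
  n <- as.integer(target_size)
  w <- subpop_fitness(sp$haps, sel)
  hi <- which(sp$ancestry >= adm$threshold)
  lo <- which(sp$ancestry < adm$threshold)
  if (length(hi) == 0L || length(lo) == 0L) {
    fw_log("one ancestry group empty; all matings population-wide")
    within <- rep(FALSE, n)
  } else {
    within <- stats::runif(n) < adm$assort_within
  }
  fathers <- integer(n); mothers <- integer(n)
  all_idx <- seq_along(sp$sex)
  draw_w <- function(pool, size) {
    pool[sample.int(length(pool), size, replace = TRUE, prob = w[pool])]
  }
  n_out <- sum(!within)
  if (n_out > 0L) {
    fathers[!within] <- draw_w(all_idx, n_out)
    mothers[!within] <- draw_w(all_idx, n_out)
  }
  n_in <- sum(within)
  if (n_in > 0L) {
    idx_parent <- all_idx[sample.int(length(all_idx), n_in, replace = TRUE)]
    grp_hi <- sp$ancestry[idx_parent] >= adm$threshold
    for (g in c(TRUE, FALSE)) {
      sel_i <- which(within)[grp_hi == g]
      if (length(sel_i) == 0L) next
      pool <- if (g) hi else lo
      fathers[sel_i] <- draw_w(pool, length(sel_i))
      mothers[sel_i] <- draw_w(pool, length(sel_i))
    }
  }
  pop$subpops[[k]] <- breed_subpop(sp, n, sel, probs, mu,
                                   fathers = fathers, mothers = mothers)
  pop
}

## Migration -----------------------------------------------------------------

#' Apply one generation of migration
#'
#' See [migration_model()] for the two schemes. Stepping-stone moves are
#' executed simultaneously from a frozen pre-migration state; counts are
#' rounded to nearest, so `m * N < 0.5` yields zero migrants that generation.
#'
#' @param pop a `population` with at least two subpopulations.
#' @param mig a [migration_model()].
#' @return the migrated `population`.
#' @export
migrate <- function(pop, mig) {
  r <- length(pop$subpops)
  if (r < 2L) stop("migration requires at least two subpopulations")
  if (mig$kind == "stepping_stone") {
    if (mig$m == 0) return(pop)
    sizes <- vapply(pop$subpops, function(s) length(s$sex), integer(1))
    ## choose outgoing individuals per deme, split among neighbours
    outgoing <- vector("list", r)   # outgoing[[i]][[j]]: indices i -> j
    for (i in seq_len(r)) {
      nb <- intersect(c(i - 1L, i + 1L), seq_len(r))
      cnt <- round_half_up(mig$m * sizes[i])
      if (cnt < 1L) {
        fw_log("subpop ", i, ": m*N < 0.5, no migrants this generation")
        outgoing[[i]] <- stats::setNames(rep(list(integer(0)), length(nb)), nb)
        next
      }
      total <- min(cnt * length(nb), sizes[i])
      picks <- sample.int(sizes[i], total)
      grp <- rep_len(seq_along(nb), length(picks))
      outgoing[[i]] <- stats::setNames(
        lapply(seq_along(nb), function(k) picks[grp == k]), nb)
    }
    old <- pop$subpops
    pop$subpops <- lapply(seq_len(r), function(i) {
      leave <- unlist(outgoing[[i]], use.names = FALSE)
      stay <- setdiff(seq_len(sizes[i]), leave)
      parts <- list(subpop_subset(old[[i]], stay))
      for (j in seq_len(r)) {
        inc <- outgoing[[j]][[as.character(i)]]
        if (!is.null(inc) && length(inc) > 0L)
          parts <- c(parts, list(subpop_subset(old[[j]], inc)))
      }
      do.call(subpop_bind, parts)
    })
  } else {                                   # gene_flow
    if (mig$p == 0) return(pop)
    src <- pop$subpops[[mig$source]]
    snk <- pop$subpops[[mig$sink]]
    n_sink <- length(snk$sex)
    cnt <- round_half_up(mig$p * n_sink)
    if (cnt < 1L) return(pop)
    mig_idx <- sample.int(length(src$sex), cnt, replace = TRUE)
    out_idx <- sample.int(n_sink, cnt)
    keep <- setdiff(seq_len(n_sink), out_idx)
    pop$subpops[[mig$sink]] <- subpop_bind(subpop_subset(snk, keep),
                                           subpop_subset(src, mig_idx))
  }
  pop
}

subpop_subset <- function(sp, idx) {
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  new_subpop(sp$haps[rows, , drop = FALSE], sp$sex[idx], sp$ancestry[idx],
             sp$affected[idx], sp$env[idx])
}

subpop_bind <- function(...) {
  parts <- list(...)
  new_subpop(do.call(rbind, lapply(parts, `[[`, "haps")),
             unlist(lapply(parts, `[[`, "sex")),
             unlist(lapply(parts, `[[`, "ancestry")),
             unlist(lapply(parts, `[[`, "affected")),
             unlist(lapply(parts, `[[`, "env")))
}

## Evolution driver ----------------------------------------------------------

#' Evolve a population forward in time
#'
#' Runs the configured number of generations, each chaining migration and
#' (controlled, assortative or random) mating, and logs periodic summaries.
#' Fully reproducible from the configuration seed.
#'
#' @param pop the initial `population` (generation 0).
#' @param cfg an [evolution_config()]; if `cfg$lam > 1` it is passed through
#'   [scale_config()] first.
#' @param controlled optional trajectory control: a `trajectory` object
#'   (see [simulate_forward_trajectory()]) whose rows index generations
#'   0..T and whose `loci` name the controlled loci. Requires a single
#'   subpopulation.
#' @return a list with elements `population` and `log` (a data.frame with
#'   one row per logged generation and subpopulation: generation, subpop,
#'   size, and the frequency of each watched locus).
#' @export
evolve <- function(pop, cfg, controlled = NULL) {
  stopifnot(inherits(pop, "population"), inherits(cfg, "evolution_config"))
  if (cfg$lam > 1) cfg <- scale_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  schedule <- size_schedule(cfg$demographic)
  T <- length(schedule) - 1L
  probs <- if (nrow(pop$loci) > 1L)
    interval_recomb_probs(pop$loci, cfg$recomb_scale) else numeric(0)
  nsub <- length(pop$subpops)
  shares <- vapply(pop$subpops, function(s) length(s$sex), integer(1))
  shares <- shares / sum(shares)
  if (!is.null(controlled) && nsub > 1L)
    stop("trajectory-controlled mating requires a single subpopulation")
  watch <- cfg$watched_loci
  log_rows <- list()
  log_gen <- function(p, t) {
    for (k in seq_len(nsub)) {
      row <- data.frame(generation = p$generation, subpop = k,
                        size = length(p$subpops[[k]]$sex))
      for (l in watch)
        row[[paste0("freq_", l)]] <- allele_frequency(p, l, k)
      log_rows[[length(log_rows) + 1L]] <<- row
    }
  }
  log_gen(pop, 0L)
  for (t in seq_len(T)) {
    targets <- round_half_up(schedule[t + 1L] * shares)
    targets[1L] <- schedule[t + 1L] - sum(targets[-1L])
    if (any(targets < 1L)) stop("scheduled subpopulation size fell below 1")
    if (!is.null(cfg$migration) && nsub > 1L && t <= cfg$migration$duration)
      pop <- migrate(pop, cfg$migration)
    if (!is.null(controlled)) {
      counts <- round_half_up(2 * targets[1L] * controlled$freqs[t + 1L, ])
      pop <- controlled_offspring_generation(pop, controlled$loci, counts,
                                             sel = cfg$selection, probs = probs,
                                             mu = cfg$mu, target_size = targets[1L])
    } else if (!is.null(cfg$admixture)) {
      k <- cfg$admixture$subpop
      pop <- admixture_generation(pop, cfg$admixture, targets[k], probs,
                                  cfg$mu, cfg$selection)
      for (j in setdiff(seq_len(nsub), k))
        pop$subpops[[j]] <- breed_subpop(pop$subpops[[j]], targets[j],
                                         cfg$selection, probs, cfg$mu)
      pop$generation <- pop$generation + 1L
    } else {
      pop <- random_mating_generation(pop, targets, cfg$selection, probs, cfg$mu)
    }
    if (t %% cfg$summary_every == 0L || t == T) log_gen(pop, t)
    if (t %% 100L == 0L) fw_log("generation ", t, "/", T)
  }
  pop$rng_state <- .Random.seed
  list(population = pop, log = do.call(rbind, log_rows))
}

#' Write an evolution summary log as TSV
#' @param log the `log` component returned by [evolve()].
#' @param path output path.
#' @export
write_summary_tsv <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
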