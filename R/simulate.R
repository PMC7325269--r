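#' Configuration for coalescent simulations
#'
#' Describes a haploid (mtDNA-style) Kingman coalescent: `n_tips` sampled
#' lineages coalesce backward in time with pairwise rate 1/N per generation,
#' where N may follow a piecewise-constant schedule.  Mutations accumulate on
#' branches as independent Poisson processes with mean
#' `branch_years / years_per_mutation`.
#'
#' @param n_tips number of sampled lineages (>= 2).
#' @param Ne effective population size: a single positive number, or a data
#'   frame with columns `start_gen` (epoch start, generations before present,
#'   first row 0, non-decreasing) and `N` (positive sizes), most recent epoch
#'   first.
#' @param years_per_mutation whole-molecule rate scalar (default the human
#'   mtDNA value; `Inf` switches mutation off).
#' @param generation_time_years years per generation.
#' @param reps replicate count for experiments.
#' @param seed optional integer seed; fixes the whole output stream.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_tips = 10, Ne = 1000, years_per_mutation = 4651,
                       generation_time_years = 20, reps = 1, seed = NULL) {
  if (is.numeric(Ne) && length(Ne) == 1L)
    Ne <- data.frame(start_gen = 0, N = Ne)
  stopifnot(is.data.frame(Ne), all(c("start_gen", "N") %in% names(Ne)),
            nrow(Ne) >= 1, Ne$start_gen[1] == 0, !is.unsorted(Ne$start_gen),
            all(Ne$N > 0), n_tips >= 2, years_per_mutation > 0,
            generation_time_years > 0, reps >= 1)
  structure(list(n_tips = as.integer(n_tips), Ne = Ne,
                 years_per_mutation = years_per_mutation,
                 generation_time_years = generation_time_years,
                 reps = as.integer(reps), seed = seed),
            class = "sim_config")
}

# waiting time (generations) to the next coalescence of i lineages starting
# at time t, under the piecewise-constant size schedule
.coal_wait <- function(t, i, sched) {
  target <- stats::rexp(1)
  pair_rate <- i * (i - 1) / 2
  repeat {
    k <- findInterval(t, sched$start_gen)
    rate <- pair_rate / sched$N[k]
    bound <- if (k < nrow(sched)) sched$start_gen[k + 1] else Inf
    dt <- target / rate
    if (t + dt <= bound) return(t + dt)
    target <- target - (bound - t) * rate
    t <- bound
  }
}

#' Simulate a Kingman coalescent tree with Poisson mutations
#'
#' Draws inter-coalescence waiting times exponentially with rate
#' `i(i-1)/2 / N(t)` per generation (haploid scaling), joins uniformly chosen
#' lineage pairs, and sprinkles Poisson mutations on each branch with mean
#' `branch_duration_years / years_per_mutation`.
#'
#' @param config a [sim_config()].
#' @return a list with `tree` (a [mutation_tree()] whose branch lengths are
#'   the simulated mutation counts) and `tmrca_years` /
#'   `tmrca_generations` (the true root age).
#' @examples
#' sim <- simulate_kingman_tree(sim_config(n_tips = 5, seed = 1))
#' sim$tmrca_years
#' @export
simulate_kingman_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_tips
  ypg <- config$generation_time_years
  ypm <- config$years_per_mutation
  frag <- paste0("t", seq_len(n))
  height <- numeric(n)
  t <- 0
  while (length(frag) > 1L) {
    i <- length(frag)
    t <- .coal_wait(t, i, config$Ne)
    pick <- sample.int(i, 2L)
    muts <- stats::rpois(2L, (t - height[pick]) * ypg / ypm)
    joined <- sprintf("(%s:%d,%s:%d)", frag[pick[1]], muts[1],
                      frag[pick[2]], muts[2])
    frag <- c(frag[-pick], joined)
    height <- c(height[-pick], t)
  }
  tree <- read_mutation_tree(paste0(frag, ";"))
  list(tree = tree, tmrca_years = t * ypg, tmrca_generations = t)
}

#' Simulate a star phylogeny with Poisson mutation counts
#'
#' All `n` lineages radiate independently from the root; each tip branch
#' carries a Poisson-distributed mutation count with the given mean.
#'
#' @param n number of tips (>= 2).
#' @param mean_mutations expected mutations per lineage (>= 0).
#' @param seed optional integer seed.
#' @return a [mutation_tree()].
#' @export
simulate_star_tree <- function(n, mean_mutations, seed = NULL) {
  stopifnot(n >= 2, mean_mutations >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(n, mean_mutations)
  nwk <- paste0("(", paste0("t", seq_len(n), ":", counts, collapse = ","),
                ");")
  read_mutation_tree(nwk)
}

#' Parameter-recovery experiment for the age estimators
#'
#' Simulates replicate coalescent trees, decomposes each into coalescent
#' periods, and estimates the root age twice in exact arithmetic: unscaled
#' (every period factor 1, the plain modified-rho age) and scaled (the
#' time-dependent factors).  Reports, for each estimator, the mean estimate,
#' bias and RMSE against the true simulated TMRCA, and the empirical coverage
#' of the 95% Poisson-kiloyear interval.
#'
#' @param config a [sim_config()]; `reps` should be at least 100 for stable
#'   summaries.
#' @return an object of class `recovery_experiment`: a list with `summary`
#'   (one row per estimator), `replicates` (per-replicate ages), and the
#'   config.
#' @export
recovery_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$reps < 2) stop("recovery experiments need at least 2 replicates")
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg1 <- config
  cfg1$seed <- NULL  # stream already seeded; replicates must differ
  rate <- rate_model(config$years_per_mutation, rounding = "exact")
  res <- vapply(seq_len(config$reps), function(r) {
    sim <- simulate_kingman_tree(cfg1)
    tab <- decompose_periods(sim$tree)
    unscaled <- rho_age(tab, rate, scaling = "none")
    scaled <- rho_age(tab, rate, scaling = "period")
    cover <- function(fit) {
      ci <- poisson_kyr_uncertainty(fit$age_years)
      as.numeric(sim$tmrca_years >= ci["ci95_low"] &
                 sim$tmrca_years <= ci["ci95_high"])
    }
    c(true = sim$tmrca_years, unscaled = unscaled$age_years,
      scaled = scaled$age_years,
      cover_unscaled = cover(unscaled), cover_scaled = cover(scaled))
  }, numeric(5))
  res <- as.data.frame(t(res))
  summary <- data.frame(
    estimator = c("unscaled", "scaled"),
    mean_age = c(mean(res$unscaled), mean(res$scaled)),
    mean_true = mean(res$true),
    bias = c(mean(res$unscaled - res$true), mean(res$scaled - res$true)),
    rmse = c(sqrt(mean((res$unscaled - res$true)^2)),
             sqrt(mean((res$scaled - res$true)^2))),
    coverage = c(mean(res$cover_unscaled), mean(res$cover_scaled)),
    se_mean = c(stats::sd(res$unscaled), stats::sd(res$scaled)) /
      sqrt(config$reps))
  structure(list(summary = summary, replicates = res, config = config),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates, n = %d tips\n",
              x$config$reps, x$config$n_tips))
  cat(sprintf("mean true TMRCA: %.0f years\n\n", x$summary$mean_true[1]))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
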