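#' Individual-based model configuration
#'
#' Run parameters of the stochastic simulator. The defaults are the
#' published full-scale setting: a well-mixed population of 1000, 1000
#' groups of `N` drawn per generation (so each individual plays about
#' `groups * N / pop_size = 7` games), 100 tournament reproduction bouts
#' per generation, per-offspring mutation probability 0.1 with a uniform
#' step of half-width `epsilon = 0.005` applied to both traits (`q`
#' directly, the cost in the transformed coordinate `u = c_A^alpha`), and
#' 1.5e5 generations. `init_c = NULL` means "start at the central singular
#' point cost `k/2^(1/alpha)`", resolved when the population is built.
#'
#' @param pop_size population size.
#' @param groups_per_generation groups sampled per generation.
#' @param bouts tournament reproduction comparisons per generation.
#' @param mutation_prob probability that an offspring mutates (both traits).
#' @param epsilon mutation step half-width.
#' @param generations number of generations to run.
#' @param seed integer RNG seed, or `NULL` to leave the RNG stream alone.
#' @param init_q initial (monomorphic) probability of playing A.
#' @param init_c initial cost, or `NULL` for the singular-point cost.
#' @param record_every record a trajectory row every this many generations.
#' @return object of class `ibm_config`.
#' @seealso [desk_scale()] for the reduced setting used by the test suite.
#' @export
ibm_config <- function(pop_size = 1000, groups_per_generation = 1000,
                       bouts = 100, mutation_prob = 0.1, epsilon = 0.005,
                       generations = 150000, seed = NULL,
                       init_q = 0.5, init_c = NULL, record_every = 100) {
  stopifnot(pop_size >= 2, groups_per_generation >= 1, bouts >= 0,
            mutation_prob >= 0, mutation_prob <= 1, epsilon >= 0,
            generations >= 0, record_every >= 1)
  check_prob(init_q, "init_q")
  structure(list(pop_size = as.integer(pop_size),
                 groups_per_generation = as.integer(groups_per_generation),
                 bouts = as.integer(bouts),
                 mutation_prob = mutation_prob, epsilon = epsilon,
                 generations = as.integer(generations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 init_q = init_q, init_c = init_c,
                 record_every = as.integer(record_every)),
            class = "ibm_config")
}

#' Desk-scale variant of an IBM configuration
#'
#' Shrinks a configuration to the reduced setting used for testing:
#' population 300, 300 groups and 30 bouts per generation (preserving the
#' full-scale ratios of about 7 games per individual and 10% generational
#' turnover), 2e4 generations. Full scale remains available by not calling
#' this.
#'
#' @param cfg an [ibm_config()].
#' @param generations override for the run length.
#' @export
desk_scale <- function(cfg = ibm_config(), generations = 20000L) {
  cfg$pop_size <- 300L
  cfg$groups_per_generation <- 300L
  cfg$bouts <- 30L
  cfg$generations <- as.integer(generations)
  cfg
}

resolve_init_c <- function(cfg, g) {
  t <- g$trade_off
  c0 <- if (is.null(cfg$init_c)) t$k / 2^(1 / t$alpha) else cfg$init_c
  if (c0 < 0 || c0 > t$k)
    stop(sprintf("init_c = %g outside [0, k] = [0, %g]", c0, t$k), call. = FALSE)
  c0
}

#' Build the initial (monomorphic) population
#'
#' Everyone starts at `{init_q, init_c}` with zero fitness and zero games
#' played; trait variance is exactly zero. If the configuration carries a
#' seed it is applied here, so two populations built from the same config
#' are identical.
#'
#' @param cfg an [ibm_config()].
#' @param g a [game_spec()].
#' @return object of class `population_state` with per-individual vectors
#'   `q`, `c_A`, `fitness`, `games` and a `generation` counter.
#' @export
initialize_population <- function(cfg, g) {
  stopifnot(inherits(cfg, "ibm_config"), inherits(g, "game_spec"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$pop_size
  c0 <- resolve_init_c(cfg, g)
  structure(list(q = rep(cfg$init_q, n), c_A = rep(c0, n),
                 fitness = rep(0, n), games = rep(0L, n),
                 generation = 0L),
            class = "population_state")
}

#' One generation of group play
#'
#' Samples `groups_per_generation` groups of `N` distinct individuals, lets
#' each member draw its subtask by an independent Bernoulli(`q`), pays each
#' member its sharing-model benefit share minus the cost of the subtask it
#' actually performed, and realises fitness as accumulated payoff divided by
#' games played. Individuals that never got sampled keep fitness exactly 0.
#'
#' @param state a `population_state`.
#' @param g a [game_spec()].
#' @param cfg an [ibm_config()].
#' @param check_conservation also track the largest deviation between a
#'   realised group's summed benefit payments and `expected_payout` (a
#'   vector indexed by A-count 0..N supplied by the caller); stored in
#'   `attr(, "max_conservation_dev")`.
#' @param expected_payout see above; defaults to the model's own totals.
#' @return the updated `population_state`.
#' @export
play_generation <- function(state, g, cfg,
                            check_conservation = FALSE,
                            expected_payout = group_payout_totals(g)) {
  stopifnot(inherits(state, "population_state"), inherits(g, "game_spec"))
  s <- share_tables(g)
  cB <- complementary_cost(state$c_A, g$trade_off)
  res <- cpp_play_generation(state$q, state$c_A, cB, s$A, s$B,
                             g$N, cfg$groups_per_generation,
                             check_conservation, expected_payout)
  state$fitness <- res$fitness
  state$games <- res$games
  state$generation <- state$generation + 1L
  attr(state, "max_conservation_dev") <-
    if (check_conservation) res$max_conservation_dev else NULL
  state
}

#' Total benefit actually paid to a realised group
#'
#' The summed benefit payments to a group with `i` A-players, as a vector
#' over `i = 0..N`: `beta(i)` in model I; in model II, with the analytic
#' convention of dropping the factor 1/2, interior compositions pay out
#' `2*beta(i)` (each subgroup receives the whole benefit) and the pure
#' compositions `beta(i)`; with `half_factor = TRUE` these halve.
#'
#' @param g a [game_spec()].
#' @export
group_payout_totals <- function(g) {
  stopifnot(inherits(g, "game_spec"))
  N <- g$N
  vapply(0:N, function(i) {
    a <- if (i >= 1) i * individual_share(i, "A", g) else 0
    b <- if (i <= N - 1) (N - i) * individual_share(i, "B", g) else 0
    a + b
  }, numeric(1))
}

#' Tournament reproduction with mutation
#'
#' Repeats `bouts` times: two distinct individuals are drawn uniformly, the
#' one with lower realised fitness is replaced by an offspring of the other
#' (ties decided by a fair coin). The offspring copies the parent's traits;
#' with probability `mutation_prob` both traits mutate in one event:
#' `q' ~ U[q - eps, q + eps]` clamped to `[0, 1]`, and the cost moves
#' uniformly in the transformed coordinate `u = c_A^alpha`,
#' `u' ~ U[u - eps, u + eps]` clamped to `[0, k^alpha]`, then mapped back.
#' Offspring fitness and game counters start at zero, and replacements are
#' serial, so later bouts see earlier ones.
#'
#' @inheritParams play_generation
#' @export
reproduce_and_mutate <- function(state, cfg, g) {
  stopifnot(inherits(state, "population_state"), inherits(cfg, "ibm_config"))
  t <- g$trade_off
  cB <- complementary_cost(state$c_A, t)
  res <- cpp_reproduce(state$q, state$c_A, cB, state$fitness, state$games,
                       cfg$bouts, cfg$mutation_prob, cfg$epsilon,
                       t$k, t$alpha)
  state$q <- res$q
  state$c_A <- res$c_A
  state$fitness <- res$fitness
  state$games <- res$games
  state
}

#' Run the individual-based simulation
#'
#' The full generational loop: reset fitness, play all groups, realise
#' fitness, reproduce with mutation; repeated `generations` times from a
#' monomorphic start, recording summary rows (trait means/variances, mean
#' realised fitness, and the masses and centroids of the two `q`-clusters
#' split at 1/2) at generation 0, every `record_every` generations and at
#' the end. The returned trajectory carries the final population and a
#' branching verdict from [detect_branching()].
#'
#' @param cfg an [ibm_config()]; its `seed` (if any) is applied before the
#'   run, making trajectories bit-identical under a fixed seed.
#' @param g a [game_spec()].
#' @param check_conservation track per-group payout conservation (slightly
#'   slower); the largest deviation ends up in `$max_conservation_dev`.
#' @return object of class `trajectory`: `records` (data.frame), `final`
#'   (population state), `verdict`, `cfg`, `game`.
#' @export
run_simulation <- function(cfg, g, check_conservation = FALSE) {
  stopifnot(inherits(cfg, "ibm_config"), inherits(g, "game_spec"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- g$trade_off
  n <- cfg$pop_size
  c0 <- resolve_init_c(cfg, g)
  q <- rep(cfg$init_q, n)
  cA <- rep(c0, n)
  cB <- complementary_cost(cA, t)
  s <- share_tables(g)
  res <- cpp_run(q, cA, cB, s$A, s$B, g$N,
                 cfg$groups_per_generation, cfg$bouts,
                 cfg$mutation_prob, cfg$epsilon, t$k, t$alpha,
                 cfg$generations, cfg$record_every,
                 check_conservation, group_payout_totals(g))
  rec <- as.data.frame(res$records)
  names(rec) <- c("generation", "mean_q", "var_q", "mean_c", "var_c",
                  "mean_fitness", "frac_low", "mean_q_low", "mean_q_high",
                  "mean_c_low", "mean_c_high")
  final <- structure(list(q = res$q, c_A = res$c_A, fitness = res$fitness,
                          games = res$games,
                          generation = cfg$generations),
                     class = "population_state")
  traj <- structure(list(records = rec, final = final, cfg = cfg, game = g,
                         max_conservation_dev =
                           if (check_conservation) res$max_conservation_dev else NULL),
                    class = "trajectory")
  traj$verdict <- detect_branching(traj)
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d generations, pop %d: outcome '%s'\n",
              x$cfg$generations, x$cfg$pop_size, x$verdict$outcome))
  invisible(x)
}

classify_snapshot <- function(q, mass_min, lo, hi) {
  n <- length(q)
  if (n == 0) stop("empty population", call. = FALSE)
  low <- q < 0.5
  nlow <- sum(low)
  nhigh <- n - nlow
  branched <- nlow / n >= mass_min && nhigh / n >= mass_min &&
    nlow > 0 && nhigh > 0 &&
    mean(q[low]) < lo && mean(q[!low]) > hi
  near_pure <- (nhigh / n >= 1 - mass_min && nhigh > 0 && mean(q[!low]) > hi) ||
    (nlow / n >= 1 - mass_min && nlow > 0 && mean(q[low]) < lo)
  if (branched) "branched" else if (near_pure) "near_pure" else "undecided"
}

#' Classify a population as branched, near-pure or undecided
#'
#' Operationalises the three visual outcome classes of the simulation
#' study. A snapshot is *branched* when splitting at `q = 1/2` leaves at
#' least `mass_min` of the population on each side with cluster means below
#' `lo` and above `hi` respectively; *near-pure* when at least
#' `1 - mass_min` of the population sits on one side with its mean beyond
#' the corresponding threshold; otherwise *undecided* (typically still
#' spread around the start). For a [run_simulation()] trajectory, the
#' branched verdict must additionally be sustained over the last
#' `persistence` recorded rows. The thresholds are invented operational
#' cutoffs (the original classification was visual) and are reported with
#' every verdict.
#'
#' @param x a `population_state`, a bare numeric vector of `q` values, or a
#'   `trajectory`.
#' @param mass_min minimum cluster mass fraction.
#' @param lo,hi centroid thresholds for the low-`q` and high-`q` clusters.
#' @param persistence recorded snapshots over which branching must hold
#'   (trajectories only).
#' @return list of class `branching_verdict`: `outcome`, logical
#'   `branched`, `onset_generation` (trajectories; `NA` if never), and the
#'   thresholds used.
#' @export
detect_branching <- function(x, mass_min = 0.2, lo = 0.25, hi = 0.75,
                             persistence = 10) {
  thr <- list(mass_min = mass_min, lo = lo, hi = hi)
  if (inherits(x, "trajectory")) {
    rec <- x$records
    row_branched <- with(rec,
      frac_low >= mass_min & (1 - frac_low) >= mass_min &
        !is.na(mean_q_low) & !is.na(mean_q_high) &
        mean_q_low < lo & mean_q_high > hi)
    m <- nrow(rec)
    tail_ok <- if (m >= persistence)
      all(row_branched[(m - persistence + 1):m]) else FALSE
    outcome <- classify_snapshot(x$final$q, mass_min, lo, hi)
    branched <- outcome == "branched" && tail_ok
    if (outcome == "branched" && !tail_ok) outcome <- "undecided"
    onset <- NA_real_
    if (branched) {
      # first recorded generation from which branching held to the end
      runlen <- rev(cumprod(rev(row_branched)))
      onset <- rec$generation[which(runlen == 1)[1]]
    }
    return(structure(c(list(outcome = outcome, branched = branched,
                            onset_generation = onset, persistence = persistence),
                       thr),
                     class = "branching_verdict"))
  }
  q <- if (inherits(x, "population_state")) x$q else as.numeric(x)
  outcome <- classify_snapshot(q, mass_min, lo, hi)
  structure(c(list(outcome = outcome, branched = outcome == "branched",
                   onset_generation = NA_real_), thr),
            class = "branching_verdict")
}

#' @export
print.branching_verdict <- function(x, ...) {
  cat(sprintf("<branching_verdict> %s (mass >= %g, centroids < %g / > %g)\n",
              x$outcome, x$mass_min, x$lo, x$hi))
  invisible(x)
}
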