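#' Branching-frequency sweep over the (k, alpha) plane
#'
#' For every `(k, alpha)` cell, runs `replicates` seeded simulations
#' started at the central singular point `x* = {1/2, k/2^(1/alpha)}` and
#' tallies the [detect_branching()] outcomes (branched / near-pure /
#' undecided, which always sum to `replicates`). Where `alpha < 1`, the
#' analytic convergence-stability threshold [critical_k()] is attached for
#' overlay: below it the central point is a branching attractor. Per-run
#' seeds are derived deterministically from `seed_base`, so a sweep is
#' bit-identical under a fixed base.
#'
#' @param k_values,alpha_values positive numeric vectors spanning the grid.
#' @param g_base a [game_spec()] supplying `N`, benefit and sharing model
#'   (its own trade-off is replaced cell by cell).
#' @param cfg an [ibm_config()] giving the per-run scale; its `init_q`,
#'   `init_c` and `seed` are overridden.
#' @param replicates runs per cell.
#' @param seed_base integer base for the deterministic per-run seeds.
#' @return data.frame (class `sweep_result`) with one row per cell:
#'   `k`, `alpha`, `branched`, `near_pure`, `undecided`, `replicates`,
#'   `critical_k`. Per-run failures are recorded in the `failures`
#'   attribute, never fatal.
#' @export
branching_sweep <- function(k_values, alpha_values, g_base,
                            cfg = desk_scale(), replicates = 10,
                            seed_base = 1L) {
  stopifnot(inherits(g_base, "game_spec"), all(k_values > 0),
            all(alpha_values > 0), replicates >= 1)
  cells <- expand.grid(k = k_values, alpha = alpha_values,
                       KEEP.OUT.ATTRS = FALSE)
  failures <- character(0)
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    k <- cells$k[ci]; a <- cells$alpha[ci]
    g <- game_spec(N = g_base$N, benefit = g_base$benefit,
                   sharing = g_base$sharing, trade_off = trade_off(k, a),
                   half_factor = g_base$half_factor)
    tally <- c(branched = 0L, near_pure = 0L, undecided = 0L)
    for (r in seq_len(replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- as.integer((seed_base + 7919 * (ci - 1L) + r) %% .Machine$integer.max)
      cfg_r$init_q <- 0.5
      cfg_r$init_c <- NULL  # singular-point start
      res <- tryCatch(run_simulation(cfg_r, g), error = function(e) e)
      if (inherits(res, "error")) {
        failures <<- c(failures,
                       sprintf("cell (k=%g, alpha=%g) rep %d: %s", k, a, r,
                               conditionMessage(res)))
        tally["undecided"] <- tally["undecided"] + 1L
      } else {
        tally[res$verdict$outcome] <- tally[res$verdict$outcome] + 1L
      }
    }
    ck <- if (a < 1) critical_k(a, g) else NA_real_
    data.frame(k = k, alpha = a, branched = tally[["branched"]],
               near_pure = tally[["near_pure"]],
               undecided = tally[["undecided"]],
               replicates = replicates, critical_k = ck)
  })
  res <- do.call(rbind, out)
  attr(res, "failures") <- failures
  class(res) <- c("sweep_result", class(res))
  res
}

#' Basin-of-attraction grid over initial conditions
#'
#' One (scaled-down) run per starting point `{q0, c0}` on a grid (default
#' 11 x 11 over `[0,1] x [0,k]`), recording the outcome of each. With the
#' branching-regime parameter set, the boundary between the
#' corner-converging and branching outcomes brackets the analytic unstable
#' roots of `G + H` in `q`.
#'
#' @param g a [game_spec()].
#' @param cfg an [ibm_config()] (its `init_q`, `init_c`, `seed` are set per
#'   start point).
#' @param q0,c0 grid coordinates; `c0 = NULL` means 11 equally spaced
#'   values on `[0, k]`.
#' @param seed_base deterministic per-cell seed base.
#' @return data.frame with one row per start point: `q0`, `c0`, `outcome`,
#'   `final_mean_q`.
#' @export
initial_condition_grid <- function(g, cfg = desk_scale(),
                                   q0 = seq(0, 1, length.out = 11),
                                   c0 = NULL, seed_base = 1L) {
  stopifnot(inherits(g, "game_spec"))
  if (is.null(c0)) c0 <- seq(0, g$trade_off$k, length.out = 11)
  grid <- expand.grid(q0 = q0, c0 = c0, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(ci) {
    cfg_r <- cfg
    cfg_r$init_q <- grid$q0[ci]
    cfg_r$init_c <- grid$c0[ci]
    cfg_r$seed <- as.integer((seed_base + 104729 * ci) %% .Machine$integer.max)
    tr <- run_simulation(cfg_r, g)
    data.frame(q0 = grid$q0[ci], c0 = grid$c0[ci],
               outcome = tr$verdict$outcome,
               final_mean_q = mean(tr$final$q))
  })
  do.call(rbind, rows)
}

#' Shifted-Gaussian benefit table
#'
#' The symmetric Gaussian benefit evaluated with its maximum displaced by
#' `shift` and tabulated over `i = 0..N`; the device used to probe how
#' benefit asymmetry affects branching (the original study does not print
#' its asymmetric functional forms, so an explicit table is the honest
#' representation).
#'
#' @param shift displacement of the benefit maximum (in units of `i`).
#' @param N group size.
#' @param base a `benefit_gaussian` supplying amplitude/sigma/mu.
#' @export
shifted_benefit_table <- function(shift, N = 7,
                                  base = benefit_gaussian()) {
  b <- benefit_gaussian(base$amplitude, base$sigma, base$mu + shift,
                        conventional = base$conventional)
  benefit_table(beta_values(b, N))
}

#' Asymmetric-benefit runs
#'
#' Runs the simulator from the symmetric game's singular point under
#' benefit tables whose maximum is displaced by each value of
#' `asymmetry`, and reports final cluster masses. The qualitative
#' expectation: mild asymmetry still branches but with unequal cluster
#' masses leaning to the favoured task; strong asymmetry collapses the
#' population onto a single near-pure strategy.
#'
#' @param asymmetry numeric vector of benefit-maximum shifts (0 reproduces
#'   a symmetric single cell).
#' @param g a symmetric-benefit [game_spec()] supplying everything else.
#' @param cfg an [ibm_config()].
#' @param replicates runs per asymmetry level.
#' @param seed_base deterministic seed base.
#' @return data.frame with one row per (level, replicate): `asymmetry`,
#'   `replicate`, `outcome`, `frac_low`, `frac_high`, `final_mean_q`.
#' @export
asymmetric_benefit_experiment <- function(asymmetry, g, cfg = desk_scale(),
                                          replicates = 3, seed_base = 1L) {
  stopifnot(inherits(g, "game_spec"))
  init_c <- g$trade_off$k / 2^(1 / g$trade_off$alpha)
  rows <- list()
  for (li in seq_along(asymmetry)) {
    ben <- if (asymmetry[li] == 0) g$benefit else
      shifted_benefit_table(asymmetry[li], g$N,
                            if (inherits(g$benefit, "benefit_gaussian"))
                              g$benefit else benefit_gaussian())
    g_a <- game_spec(N = g$N, benefit = ben, sharing = g$sharing,
                     trade_off = g$trade_off, half_factor = g$half_factor)
    for (r in seq_len(replicates)) {
      cfg_r <- cfg
      cfg_r$init_q <- 0.5
      cfg_r$init_c <- init_c
      cfg_r$seed <- as.integer((seed_base + 31 * li + r) %% .Machine$integer.max)
      tr <- run_simulation(cfg_r, g_a)
      fl <- mean(tr$final$q < 0.5)
      rows[[length(rows) + 1L]] <-
        data.frame(asymmetry = asymmetry[li], replicate = r,
                   outcome = tr$verdict$outcome,
                   frac_low = fl, frac_high = 1 - fl,
                   final_mean_q = mean(tr$final$q))
    }
  }
  do.call(rbind, rows)
}
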