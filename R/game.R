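#' Gaussian group-benefit function
#'
#' Total benefit of a group in which `i` of the `N` members perform subtask A:
#' `beta(i) = amplitude / (sigma * sqrt(2*pi)) * exp(-(i - mu)^2 / (2*sigma)^2)`.
#' Note the denominator `(2*sigma)^2` — this is the form used by the
#' simulation study (amplitude 30, `sigma = 5`, `mu = 3.5`), which for `N = 7`
#' is symmetric about `i = 3.5` and peaks where the subtask ratio is closest
#' to 1. Set `conventional = TRUE` for the textbook Gaussian denominator
#' `2*sigma^2` instead.
#'
#' @param amplitude positive scale factor.
#' @param sigma positive width parameter.
#' @param mu location of the maximum (may be half-integer).
#' @param conventional use `2*sigma^2` in the exponent denominator.
#' @return A `benefit_spec` object.
#' @export
benefit_gaussian <- function(amplitude = 30, sigma = 5, mu = 3.5,
                             conventional = FALSE) {
  stopifnot(is.numeric(amplitude), amplitude > 0,
            is.numeric(sigma), sigma > 0, is.numeric(mu))
  structure(list(kind = "gaussian", amplitude = amplitude, sigma = sigma,
                 mu = mu, conventional = isTRUE(conventional)),
            class = c("benefit_gaussian", "benefit_spec"))
}

#' Tabulated group-benefit function
#'
#' An explicit benefit table `beta(0), ..., beta(N)` for a group of size `N`.
#' Symmetry is detected, never assumed, so asymmetric tables are allowed
#' (they are what the asymmetric-benefit experiment feeds in); analytical
#' results that require a symmetric benefit refuse to run on them.
#'
#' @param beta numeric vector of `N + 1` nonnegative values, `beta[i + 1]`
#'   being the group total when `i` members play A.
#' @export
benefit_table <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) >= 3, all(is.finite(beta)),
            all(beta >= 0))
  structure(list(kind = "table", table = as.numeric(beta)),
            class = c("benefit_table", "benefit_spec"))
}

# beta(0..N) as a plain vector
beta_values <- function(benefit, N) {
  if (inherits(benefit, "benefit_gaussian")) {
    i <- 0:N
    denom <- if (benefit$conventional) 2 * benefit$sigma^2 else (2 * benefit$sigma)^2
    benefit$amplitude / (benefit$sigma * sqrt(2 * pi)) *
      exp(-(i - benefit$mu)^2 / denom)
  } else {
    if (length(benefit$table) != N + 1L)
      stop(sprintf("benefit table has %d entries but N = %d needs %d",
                   length(benefit$table), N, N + 1L), call. = FALSE)
    benefit$table
  }
}

#' Group game specification
#'
#' Bundles everything that defines one instance of the collective-task game:
#' the group size `N`, the benefit function, the benefit-sharing model and
#' the cost trade-off. Sharing model "I" divides the group benefit `beta(i)`
#' equally among all `N` members (a common good nobody can be excluded
#' from); model "II" divides it between the two task subgroups and then
#' equally within each, so the scarcer subtask earns a higher share. The
#' analytical treatment drops model II's extra factor 1/2 as a pure
#' rescaling; `half_factor = TRUE` restores it (sensitivity checks only).
#'
#' @param N integer group size, at least 2.
#' @param benefit a `benefit_spec`, by default the Gaussian used throughout
#'   the simulation study.
#' @param sharing `"I"` or `"II"`.
#' @param trade_off a [trade_off()].
#' @param half_factor keep model II's factor 1/2 (default `FALSE`).
#' @return A `game_spec` object; field `symmetric` records whether
#'   `beta(i) = beta(N - i)` holds to 1e-12 relative tolerance.
#' @examples
#' g <- game_spec(N = 7, sharing = "I", trade_off = trade_off(0.25, 0.15))
#' benefit_total(3, g)
#' @export
game_spec <- function(N = 7, benefit = benefit_gaussian(),
                      sharing = c("I", "II"),
                      trade_off = divlabsim::trade_off(0.25, 0.15),
                      half_factor = FALSE) {
  sharing <- match.arg(sharing)
  stopifnot(inherits(benefit, "benefit_spec"), inherits(trade_off, "trade_off"))
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  beta <- beta_values(benefit, N)
  sym <- all(abs(beta - rev(beta)) <= 1e-12 * max(abs(beta), 1))
  structure(list(N = N, benefit = benefit, beta = beta, sharing = sharing,
                 trade_off = trade_off, half_factor = isTRUE(half_factor),
                 symmetric = sym),
            class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("<game_spec> N = %d, sharing model %s, %s benefit (%s), k = %g, alpha = %g\n",
              x$N, x$sharing, x$benefit$kind,
              if (x$symmetric) "symmetric" else "asymmetric",
              x$trade_off$k, x$trade_off$alpha))
  invisible(x)
}

#' Two-trait strategy
#'
#' The heritable phenotype: `q`, the probability of choosing subtask A, and
#' `c_A`, the additional cost assigned to it (its B cost follows from the
#' trade-off). Mutants and residents are just different `strategy` values.
#'
#' @param q probability in `[0, 1]`.
#' @param c_A nonnegative cost (validated against `k` by the operations that
#'   receive a game).
#' @export
strategy <- function(q, c_A) {
  check_prob(q)
  stopifnot(is.numeric(c_A), length(c_A) == 1L, is.finite(c_A), c_A >= 0,
            length(q) == 1L)
  structure(list(q = as.numeric(q), c_A = as.numeric(c_A)), class = "strategy")
}

#' Total group benefit
#'
#' `beta(i)` for a realised group with `i` A-players among all `N` members.
#'
#' @param i integer count of A-players in the full group, `0..N`.
#' @param g a [game_spec()].
#' @export
benefit_total <- function(i, g) {
  stopifnot(inherits(g, "game_spec"))
  if (any(i != floor(i)) || any(i < 0) || any(i > g$N))
    stop(sprintf("'i' must be an integer in 0..%d", g$N), call. = FALSE)
  g$beta[i + 1L]
}

#' Per-member benefit share
#'
#' The benefit paid to one member of a realised group with `i` A-players (in
#' the full group). Model I pays `beta(i)/N` to everyone; model II pays
#' `beta(i)/i` per A-player and `beta(i)/(N-i)` per B-player (times 1/2 iff
#' `half_factor`). An A-share requires `i >= 1`, a B-share `i <= N - 1`.
#'
#' @param i A-player count in the full group.
#' @param role `"A"` or `"B"`.
#' @param g a [game_spec()].
#' @export
individual_share <- function(i, role = c("A", "B"), g) {
  role <- match.arg(role)
  stopifnot(inherits(g, "game_spec"))
  if (i != floor(i) || i < 0 || i > g$N)
    stop(sprintf("'i' must be an integer in 0..%d", g$N), call. = FALSE)
  if (role == "A" && i < 1)
    stop("an A-share requires at least one A-player (i >= 1)", call. = FALSE)
  if (role == "B" && i > g$N - 1)
    stop("a B-share requires at least one B-player (i <= N-1)", call. = FALSE)
  b <- g$beta[i + 1L]
  s <- if (g$sharing == "I") {
    b / g$N
  } else {
    half <- if (g$half_factor) 0.5 else 1
    if (role == "A") half * b / i else half * b / (g$N - i)
  }
  s
}

# share lookup tables indexed by full-group A-count 0..N; undefined
# (i, role) pairs are 0 and never paid
share_tables <- function(g) {
  N <- g$N
  sA <- numeric(N + 1)
  sB <- numeric(N + 1)
  for (i in 1:N) sA[i + 1L] <- individual_share(i, "A", g)
  for (i in 0:(N - 1)) sB[i + 1L] <- individual_share(i, "B", g)
  list(A = sA, B = sB)
}

#' Benefit advantage of playing A
#'
#' `Delta_b(i) = b_A(i + 1) - b_B(i)`: the benefit gain of a focal individual
#' choosing A rather than B when `i` of the OTHER `N - 1` group members play
#' A. For a symmetric benefit it is antisymmetric:
#' `Delta_b(i) = -Delta_b(N - 1 - i)`.
#'
#' @param i A-player count among the other `N - 1` members, `0..N-1`.
#' @param g a [game_spec()].
#' @export
benefit_advantage <- function(i, g) {
  stopifnot(inherits(g, "game_spec"))
  if (any(i != floor(i)) || any(i < 0) || any(i > g$N - 1))
    stop(sprintf("'i' must be an integer in 0..%d (others in the group)", g$N - 1),
         call. = FALSE)
  vapply(i, function(ii) {
    individual_share(ii + 1L, "A", g) - individual_share(ii, "B", g)
  }, numeric(1))
}

#' Group-composition distribution seen by a focal individual
#'
#' Probability that `i` of the other `N - 1` group members play A when the
#' population mean A-propensity is `q_bar`: the binomial pmf
#' `C(N-1, i) q_bar^i (1 - q_bar)^(N-1-i)` for `i = 0..N-1`. Satisfies the
#' mirror identity `f[i](q) = f[N-1-i](1 - q)`.
#'
#' @param q_bar population mean probability of playing A.
#' @param g a [game_spec()].
#' @return numeric vector of length `N` (index `i + 1` holds composition `i`).
#' @export
group_composition_pmf <- function(q_bar, g) {
  stopifnot(inherits(g, "game_spec"), length(q_bar) == 1L)
  check_prob(q_bar, "q_bar")
  stats::dbinom(0:(g$N - 1L), g$N - 1L, q_bar)
}

#' Expected payoffs of the two roles
#'
#' Expected payoff of a focal individual conditional on playing A or B, in a
#' population with mean A-propensity `q_bar`, for an individual whose A cost
#' is `c_A`:
#' `w_A = sum_i f[i](q_bar) b_A(i + 1) - c_A` and
#' `w_B = sum_i f[i](q_bar) b_B(i) - c_B(c_A)`.
#'
#' @inheritParams group_composition_pmf
#' @param c_A the focal individual's A cost in `[0, k]`.
#' @return named numeric vector `c(w_A =, w_B =)`.
#' @export
expected_role_payoffs <- function(q_bar, c_A, g) {
  stopifnot(inherits(g, "game_spec"))
  check_cost_domain(c_A, g$trade_off)
  f <- group_composition_pmf(q_bar, g)
  idx <- 0:(g$N - 1L)
  bA <- vapply(idx + 1L, individual_share, numeric(1), role = "A", g = g)
  bB <- vapply(idx, individual_share, numeric(1), role = "B", g = g)
  c(w_A = sum(f * bA) - c_A,
    w_B = sum(f * bB) - complementary_cost(c_A, g$trade_off))
}

#' Expected payoff of a strategy
#'
#' `w_bar(q, c_A, q_bar) = q w_A(q_bar, c_A) + (1 - q) w_B(q_bar, c_A)`:
#' the focal individual's expected payoff per game given the resident mean
#' A-propensity `q_bar`.
#'
#' @param s a [strategy()].
#' @inheritParams expected_role_payoffs
#' @export
mean_payoff <- function(s, q_bar, g) {
  stopifnot(inherits(s, "strategy"))
  w <- expected_role_payoffs(q_bar, s$c_A, g)
  unname(s$q * w["w_A"] + (1 - s$q) * w["w_B"])
}

#' Invasion fitness of a rare mutant
#'
#' `W(x', x) = w_bar(q', c_A', q) - w_bar(q, c_A, q)`: the payoff advantage
#' of a rare mutant strategy `x'` in a monomorphic resident-`x` population
#' (the mutant is too rare to shift the resident composition). Zero exactly
#' when mutant equals resident, and linear in the mutant's `q'`.
#'
#' @param mutant,resident [strategy()] values.
#' @param g a [game_spec()].
#' @export
invasion_fitness <- function(mutant, resident, g) {
  stopifnot(inherits(mutant, "strategy"), inherits(resident, "strategy"))
  mean_payoff(mutant, resident$q, g) - mean_payoff(resident, resident$q, g)
}
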