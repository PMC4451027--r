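#' Expected benefit advantage of playing A
#'
#' `G(q) = sum_{i=0}^{N-1} f[i](q) Delta_b(i)`: the benefit side of the
#' selection gradient in `q`. For a symmetric benefit `G` is antisymmetric
#' about 1/2 (`G(1/2) = 0` in both sharing models) and `G(q) > 0` for
#' `q < 1/2`. Vectorised in `q`.
#'
#' @param q population mean probability of playing A, in `[0, 1]`.
#' @param g a [game_spec()].
#' @export
benefit_gradient_term <- function(q, g) {
  stopifnot(inherits(g, "game_spec"))
  check_prob(q)
  db <- benefit_advantage(0:(g$N - 1L), g)
  vapply(q, function(qq) sum(group_composition_pmf(qq, g) * db), numeric(1))
}

#' Selection gradient at a resident strategy
#'
#' The gradient of invasion fitness with respect to the mutant traits,
#' evaluated at mutant = resident `x`:
#' `dW/dq' = w_A(q, c_A) - w_B(q, c_A)` and
#' `dW/dc' = -(q + (1 - q) dc_B/dc_A)`, i.e. minus the slope of the mean
#' cost. At the corners `c_A = 0` or `c_A = k` the trade-off curve has a
#' zero-or-infinite slope for `alpha != 1`, so the `c` component may be
#' `+-Inf` there; the result then carries `attr(, "corner") = TRUE` and
#' should be read as the one-sided direction in the locally natural cost
#' coordinate (`c_A` near the all-A corner, `c_B` near the all-B corner).
#'
#' @param x a [strategy()].
#' @param g a [game_spec()].
#' @return named vector `c(dW_dq =, dW_dc =)`.
#' @export
selection_gradient <- function(x, g) {
  stopifnot(inherits(x, "strategy"), inherits(g, "game_spec"))
  t <- g$trade_off
  check_cost_domain(x$c_A, t)
  w <- expected_role_payoffs(x$q, x$c_A, g)
  cB <- complementary_cost(x$c_A, t)
  corner <- x$c_A == 0 || cB == 0
  # slope of the trade-off curve, dc_B/dc_A = -(c_A/c_B)^(alpha - 1)
  s <- if (alpha_is_one(t)) -1 else {
    if (x$c_A == 0) {
      if (t$alpha < 1) -Inf else 0
    } else if (cB == 0) {
      if (t$alpha < 1) 0 else -Inf
    } else {
      -exp((t$alpha - 1) * (log(x$c_A) - log(cB)))
    }
  }
  # at q = 1 the (1-q) term vanishes even against an infinite slope (Eq. 31
  # logic: the pure-A resident feels only its own -1 cost direction)
  dW_dc <- -(x$q + if (x$q < 1) (1 - x$q) * s else 0)
  out <- c(dW_dq = unname(w["w_A"] - w["w_B"]), dW_dc = dW_dc)
  attr(out, "corner") <- corner
  out
}

singular_point <- function(q, c_A, kind, residual = 0, note = NULL) {
  structure(list(strategy = strategy(q, c_A), kind = kind,
                 residual = residual, note = note),
            class = "singular_point")
}

#' @export
print.singular_point <- function(x, ...) {
  cat(sprintf("<singular_point> %s: q = %.6g, c_A = %.6g (|G+H| = %.2e)\n",
              x$kind, x$strategy$q, x$strategy$c_A, x$residual))
  invisible(x)
}

#' Locate the singular points of trait evolution
#'
#' Finds all interior roots of `G(q) + H(q) = 0`, the condition for the
#' selection gradient to vanish once the cost trait sits on its optimal
#' curve. The scan evaluates `G + H` on a uniform grid (default 1e4
#' intervals, using the finite endpoint limits of `H` at `q = 0, 1`),
#' brackets every sign change and polishes each root by bisection. Each
#' interior root is paired with its optimal cost `c_A(q)`; the central point
#' `q = 1/2` is always present for a symmetric benefit, and non-central
#' roots come in mirror pairs `(q, 1 - q)`. The two pure corner states
#' `x^(0) = {0, k}` and `x^(1) = {1, 0}` are returned as boundary points
#' annotated with their invasion verdicts. For `alpha = 1` the interior
#' singular point is replaced by a neutral line at `q = 1/2` (the cost trait
#' does not affect the mean cost there) and no root search is run.
#'
#' @param g a [game_spec()] with a symmetric benefit (asymmetric benefits
#'   are refused: the `G + H` antisymmetry the search relies on needs
#'   `beta(i) = beta(N - i)`).
#' @param grid_n number of scan intervals on `[0, 1]`.
#' @param tol bisection tolerance on `q`.
#' @return list of class `singular_set` with elements `interior` (list of
#'   `singular_point`), `boundary` (the annotated corner states), and `game`.
#' @export
find_singular_points <- function(g, grid_n = 1e4, tol = 1e-10) {
  stopifnot(inherits(g, "game_spec"))
  if (!g$symmetric)
    stop("find_singular_points() needs a symmetric benefit (beta(i) = beta(N-i)): ",
         "the root structure and the q <-> 1-q pairing rely on it. ",
         "Use selection_gradient() directly for asymmetric benefits.",
         call. = FALSE)
  t <- g$trade_off
  boundary <- list(
    x0 = structure(list(strategy = strategy(0, t$k), kind = "boundary_pure",
                        verdict = pure_state_invasibility("all_B", g)),
                   class = "singular_point"),
    x1 = structure(list(strategy = strategy(1, 0), kind = "boundary_pure",
                        verdict = pure_state_invasibility("all_A", g)),
                   class = "singular_point"))
  if (alpha_is_one(t)) {
    interior <- list(singular_point(0.5, t$k / 2, kind = "neutral_line",
      note = "alpha = 1: c_A is neutral at q = 1/2; singular line, not a point"))
    return(structure(list(interior = interior, boundary = boundary, game = g),
                     class = "singular_set"))
  }
  db <- benefit_advantage(0:(g$N - 1L), g)
  gh <- function(q) {
    if (q <= 0) return(sum(group_composition_pmf(0, g) * db) + cost_gradient_limit(0, t))
    if (q >= 1) return(sum(group_composition_pmf(1, g) * db) + cost_gradient_limit(1, t))
    sum(group_composition_pmf(q, g) * db) + cost_gradient_term(q, t)
  }
  qs <- seq(0, 1, length.out = grid_n + 1L)
  v <- vapply(qs, gh, numeric(1))
  roots <- numeric(0)
  fails <- character(0)
  zero_at <- abs(v) < 1e-13
  roots <- c(roots, qs[zero_at & qs > 0 & qs < 1])
  for (j in seq_len(grid_n)) {
    if (zero_at[j] || zero_at[j + 1L]) next
    if (sign(v[j]) * sign(v[j + 1L]) < 0) {
      r <- tryCatch(
        stats::uniroot(gh, c(qs[j], qs[j + 1L]), tol = tol)$root,
        error = function(e) NA_real_)
      if (is.na(r)) {
        fails <- c(fails, sprintf("no convergence in [%.6g, %.6g]", qs[j], qs[j + 1L]))
      } else roots <- c(roots, r)
    }
  }
  roots <- sort(unique(roots))
  # merge near-duplicates from adjacent brackets
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  interior <- lapply(roots, function(r) {
    kind <- if (abs(r - 0.5) <= 1e-8) "central" else "unstable_pair_member"
    q <- if (kind == "central") 0.5 else r
    singular_point(q, optimal_cost(q, t)$c_A, kind, residual = abs(gh(q)))
  })
  if (!any(vapply(interior, function(p) p$kind == "central", logical(1))))
    fails <- c(fails, "central root q = 1/2 not recovered by the scan")
  structure(list(interior = interior, boundary = boundary, game = g,
                 solver_failures = fails),
            class = "singular_set")
}

#' @export
print.singular_set <- function(x, ...) {
  cat(sprintf("<singular_set> %d interior point(s):\n", length(x$interior)))
  for (p in x$interior) print(p)
  for (b in x$boundary)
    cat(sprintf("  boundary %s: q = %g, c_A = %g, invasible = %s\n",
                b$verdict$state, b$strategy$q, b$strategy$c_A,
                b$verdict$invasible))
  invisible(x)
}

#' Slope of the role-payoff difference at the central singular point
#'
#' `Delta_w(1/2) = 2^{-(N-3)} sum_i C(N-1, i) i Delta_b(i)`: the derivative
#' of `w_A - w_B` with respect to the resident mean `q`, evaluated at the
#' central singular point of a symmetric-benefit game. Negative in both
#' sharing models whenever the benefit has its single maximum in the middle;
#' it is the quantity that sets the convergence-stability threshold.
#'
#' @param g a [game_spec()] with symmetric benefit.
#' @export
delta_w <- function(g) {
  stopifnot(inherits(g, "game_spec"))
  if (!g$symmetric)
    stop("delta_w() requires a symmetric benefit", call. = FALSE)
  i <- 0:(g$N - 1L)
  sum(choose(g$N - 1L, i) * i * benefit_advantage(i, g)) / 2^(g$N - 3L)
}

#' General slope of the role-payoff difference
#'
#' The same derivative as [delta_w()] but at an arbitrary resident `q` in
#' (0, 1): `sum_i C(N-1,i) q^(i-1) (1-q)^(N-2-i) [i - (N-1) q] Delta_b(i)`.
#' At `q = 1/2` it reduces to [delta_w()] for a symmetric benefit (the
#' simplification the closed form is derived from).
#'
#' @param q resident mean in (0, 1).
#' @param g a [game_spec()].
#' @export
delta_w_general <- function(q, g) {
  stopifnot(inherits(g, "game_spec"), length(q) == 1L, q > 0, q < 1)
  i <- 0:(g$N - 1L)
  sum(choose(g$N - 1L, i) * q^(i - 1) * (1 - q)^(g$N - 2L - i) *
        (i - (g$N - 1L) * q) * benefit_advantage(i, g))
}

#' Convergence / branching classification of a singular point
#'
#' For the central singular point `x* = {1/2, k/2^(1/alpha)}` of a
#' symmetric-benefit game with `alpha != 1`, builds the Jacobian of the
#' selection gradient,
#' `J = [[Delta_w(1/2), -2], [-2, (alpha-1)/c_A*]]`, and the mutant Hessian
#' `H = [[0, -2], [-2, (alpha-1)/c_A*]]`. `H` is always indefinite (its
#' determinant is `-4 - ...` at most, and the zero diagonal with nonzero
#' off-diagonal forces mixed-sign eigenvalues), so the central point is a
#' branching point whenever evolution converges to it. Convergence
#' (negative-definite `J`) reduces to the single criterion
#' `Delta_w(1/2) * 2^(1/alpha) * (alpha - 1) / 4 > k`, which can hold only
#' for `alpha < 1`. For `alpha >= 1` both matrices are indefinite and
#' convergence depends on the mutational covariance, which this package does
#' not model; the report says so rather than guessing. Non-central points
#' get a numeric-Jacobian fallback (central finite differences of the
#' selection gradient) with a caveat flag.
#'
#' @param p a `singular_point` from [find_singular_points()].
#' @param g the [game_spec()] it was located in.
#' @return list of class `stability_report`.
#' @export
stability_report <- function(p, g) {
  stopifnot(inherits(p, "singular_point"), inherits(g, "game_spec"))
  t <- g$trade_off
  if (alpha_is_one(t) || p$kind == "neutral_line") {
    return(structure(list(kind = "neutral_line", jacobian = NULL,
      hessian = NULL, convergence_stable = NA, branching_point = NA,
      note = paste("alpha = 1: singular line at q = 1/2, cost trait neutral;",
                   "no Jacobian classification")),
      class = "stability_report"))
  }
  if (p$kind == "central") {
    if (!g$symmetric) stop("central-point classification needs a symmetric benefit",
                           call. = FALSE)
    dw <- delta_w(g)
    cstar <- t$k / 2^(1 / t$alpha)
    J <- matrix(c(dw, -2, -2, (t$alpha - 1) / cstar), 2, 2, byrow = TRUE)
    H <- matrix(c(0, -2, -2, (t$alpha - 1) / cstar), 2, 2, byrow = TRUE)
    lhs <- dw * 2^(1 / t$alpha) * (t$alpha - 1) / 4
    conv <- (t$alpha < 1) && (lhs > t$k)
    note <- if (t$alpha >= 1)
      paste("alpha >= 1: J is indefinite; convergence depends on the",
            "covariance matrix of mutations, which is not modelled here")
    structure(list(kind = "central", jacobian = J, hessian = H,
                   delta_w = dw, criterion_lhs = lhs,
                   convergence_stable = conv,
                   branching_point = TRUE,  # H indefinite by construction
                   indefinite_cases = note, caveat = NULL),
              class = "stability_report")
  } else {
    # numeric fallback: Jacobian of the gradient field g(x) = dW(x'|x)/dx'
    x0 <- c(p$strategy$q, p$strategy$c_A)
    h <- 1e-6
    grad_at <- function(z) {
      z <- pmin(pmax(z, c(0, 0)), c(1, t$k))
      unname(selection_gradient(strategy(z[1], z[2]), g))
    }
    J <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      J[, j] <- (grad_at(x0 + e) - grad_at(x0 - e)) / (2 * h)
    }
    ev <- eigen(J, only.values = TRUE)$values
    structure(list(kind = p$kind, jacobian = J, hessian = NULL,
                   eigenvalues = ev,
                   convergence_stable = all(Re(ev) < 0),
                   branching_point = NA,
                   caveat = "numeric Jacobian at a non-central point; treat as approximate"),
              class = "stability_report")
  }
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s: convergence_stable = %s, branching_point = %s\n",
              x$kind, x$convergence_stable, x$branching_point))
  if (!is.null(x$criterion_lhs))
    cat(sprintf("  criterion lhs = %.4g (must exceed k)\n", x$criterion_lhs))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Critical cost ceiling for convergence-stable branching
#'
#' The value `Delta_w(1/2) * 2^(1/alpha) * (alpha - 1) / 4`: the central
#' singular point is convergence stable (and therefore, being a branching
#' point, an attractor where the population splits) exactly when `k` is
#' below this threshold. Defined for `0 < alpha < 1` only (the criterion is
#' never satisfiable otherwise) and independent of the game's own `k`.
#'
#' @param alpha trade-off exponent in (0, 1).
#' @param g a [game_spec()] with symmetric benefit (its trade-off exponent
#'   is ignored; only `N`, benefit and sharing enter through `Delta_w`).
#' @export
critical_k <- function(alpha, g) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0 || alpha >= 1)
    stop("critical_k() is defined for 0 < alpha < 1 only", call. = FALSE)
  delta_w(g) * 2^(1 / alpha) * (alpha - 1) / 4
}

#' Can a mixed strategy invade a pure resident population?
#'
#' Linearised invasion analysis at the cost-free pure corners. At
#' `x^(1) = {1, 0}` (everyone plays A at zero cost) a rare mutant with
#' `q' < 1` gains `-(G(1) + k)` per unit of `1 - q'`, so invasion requires
#' `margin = G(1) + k < 0`; at `x^(0) = {0, k}` (everyone plays B, whose
#' cost `c_B = 0`) it requires `G(0) - k > 0`. Model II makes the corner
#' margins far more invasible than model I because the first deviant is
#' paid the whole scarce-role share.
#'
#' @param state `"all_A"` or `"all_B"`.
#' @param g a [game_spec()].
#' @return list of class `invasion_verdict`: `state`, `margin`, `invasible`.
#' @export
pure_state_invasibility <- function(state = c("all_A", "all_B"), g) {
  state <- match.arg(state)
  stopifnot(inherits(g, "game_spec"))
  k <- g$trade_off$k
  if (state == "all_A") {
    margin <- benefit_advantage(g$N - 1L, g) + k   # G(1) + k
    invasible <- margin < 0
  } else {
    margin <- benefit_advantage(0L, g) - k         # G(0) - k
    invasible <- margin > 0
  }
  structure(list(state = state, margin = unname(margin), invasible = invasible),
            class = "invasion_verdict")
}

#' @export
print.invasion_verdict <- function(x, ...) {
  cat(sprintf("<invasion_verdict> %s: margin = %.4g, invasible = %s\n",
              x$state, x$margin, x$invasible))
  invisible(x)
}
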