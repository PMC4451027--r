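#' Power-law cost trade-off between the two subtasks
#'
#' An individual that lowers its cost for subtask A necessarily raises its
#' cost for subtask B: the two additional costs are tied to the constraint
#' surface `c_A^alpha + c_B^alpha = k^alpha`. `k` is the maximal additional
#' cost (in payoff units, on top of a basic cost scaled to zero) and `alpha`
#' is the shape exponent: `alpha < 1` makes the trade-off curve convex so
#' generalists (mixed strategists) pay more on average than specialists,
#' `alpha > 1` makes it concave, and `alpha = 1` is the neutral linear case.
#'
#' @param k positive real, maximal additional cost.
#' @param alpha positive real, trade-off shape exponent.
#' @return An object of class `trade_off` with fields `k` and `alpha`.
#' @examples
#' t <- trade_off(k = 0.25, alpha = 0.15)
#' complementary_cost(0.1, t)
#' @export
trade_off <- function(k, alpha) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single finite positive number", call. = FALSE)
  structure(list(k = as.numeric(k), alpha = as.numeric(alpha)),
            class = "trade_off")
}

#' @export
print.trade_off <- function(x, ...) {
  cat(sprintf("<trade_off> c_A^%g + c_B^%g = %g^%g  (%s)\n",
              x$alpha, x$alpha, x$k, x$alpha, cost_regime(x)$label))
  invisible(x)
}

# exact comparison band for "alpha equals 1"; alpha = 1 is its own regime,
# not the limit of the alpha != 1 formulas
.ALPHA_ONE_TOL <- 1e-12

alpha_is_one <- function(t) abs(t$alpha - 1) <= .ALPHA_ONE_TOL

#' Cost-regime classification of a trade-off
#'
#' Labels the optimisation regime implied by the exponent: an interior cost
#' optimum for `alpha < 1`, a corner optimum for `alpha > 1`, and a neutral
#' line (cost does not affect the mean) at `q = 1/2` for `alpha = 1`. `theta`
#' is the sign index used by the endpoint limits of the cost gradient term:
#' +1 for `alpha < 1`, 0 for `alpha = 1`, -1 for `alpha > 1`.
#'
#' @param t a [trade_off()].
#' @return list with `label` and integer `theta`.
#' @export
cost_regime <- function(t) {
  stopifnot(inherits(t, "trade_off"))
  if (alpha_is_one(t)) {
    list(label = "neutral_line", theta = 0L)
  } else if (t$alpha < 1) {
    list(label = "interior_optimum", theta = 1L)
  } else {
    list(label = "corner_optimum", theta = -1L)
  }
}

check_cost_domain <- function(c_A, t) {
  if (!is.numeric(c_A) || any(!is.finite(c_A)))
    stop("'c_A' must be finite numeric", call. = FALSE)
  if (any(c_A < 0 | c_A > t$k))
    stop(sprintf("'c_A' must lie in [0, k] = [0, %g]", t$k), call. = FALSE)
}

check_prob <- function(q, name = "q") {
  if (!is.numeric(q) || any(!is.finite(q)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (any(q < 0 | q > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
}

#' Complementary cost on the trade-off curve
#'
#' Given the cost `c_A` chosen for subtask A, returns the cost of subtask B
#' forced by the constraint: `c_B = (k^alpha - c_A^alpha)^(1/alpha)`.
#' Evaluated on the rescaled variable `(c_A/k)^alpha` so extreme exponents do
#' not overflow. Vectorised in `c_A`.
#'
#' @param c_A numeric in `[0, k]`.
#' @param t a [trade_off()].
#' @return `c_B` in `[0, k]`.
#' @export
complementary_cost <- function(c_A, t) {
  stopifnot(inherits(t, "trade_off"))
  check_cost_domain(c_A, t)
  u <- (c_A / t$k)^t$alpha           # in [0, 1]
  t$k * (1 - u)^(1 / t$alpha)
}

#' Mean additional cost of a mixed strategist
#'
#' Average per-game cost of an individual that plays A with probability `q`
#' at cost `c_A` and B otherwise at the complementary cost:
#' `q * c_A + (1 - q) * c_B(c_A)`.
#'
#' @param q probability of choosing subtask A.
#' @param c_A cost assigned to subtask A, in `[0, k]`.
#' @param t a [trade_off()].
#' @export
mean_cost <- function(q, c_A, t) {
  stopifnot(inherits(t, "trade_off"))
  check_prob(q)
  check_cost_domain(c_A, t)
  q * c_A + (1 - q) * complementary_cost(c_A, t)
}

# interior extremum of the mean cost for alpha != 1:
#   c_A = k * [ (q/(1-q))^(alpha/(1-alpha)) + 1 ]^(-1/alpha)
# computed through logs so q near 0/1 and extreme alpha stay finite
cost_extremum <- function(q, t) {
  a <- t$alpha
  if (q <= 0) return(t$k)
  if (q >= 1) return(0)
  logr <- log(q) - log1p(-q)
  logB <- (a / (1 - a)) * logr
  if (logB > 0) {
    log1pB <- logB + log1p(exp(-logB))
  } else {
    log1pB <- log1p(exp(logB))
  }
  t$k * exp(-log1pB / a)
}

#' Cost-minimising specialisation for a given task preference
#'
#' Minimises the mean additional cost over `c_A` in `[0, k]` at fixed `q`.
#' For `alpha < 1` the optimum is interior and moves continuously from `k`
#' (pure-B specialist) at `q = 0` to `0` at `q = 1`; for `alpha > 1` it sits
#' at a corner, jumping from `k` to `0` as `q` crosses 1/2; for `alpha = 1`
#' the corner rule holds for `q != 1/2` and every `c_A` is equally good at
#' `q = 1/2`. At the `q = 1/2` tie (`alpha >= 1`) the function returns
#' `c_A = k` deterministically and sets `degenerate = TRUE`.
#'
#' @param q probability of choosing subtask A, scalar in `[0, 1]`.
#' @param t a [trade_off()].
#' @return list with `c_A`, `regime` (see [cost_regime()]), and logical
#'   `degenerate` flagging the tie/neutral case.
#' @export
optimal_cost <- function(q, t) {
  stopifnot(inherits(t, "trade_off"), length(q) == 1L)
  check_prob(q)
  reg <- cost_regime(t)
  tie <- abs(q - 0.5) <= 1e-12
  if (reg$label == "interior_optimum") {
    return(list(c_A = cost_extremum(q, t), regime = reg, degenerate = FALSE))
  }
  # alpha >= 1: end points, tie at q = 1/2
  c_A <- if (tie) t$k else if (q < 0.5) t$k else 0
  list(c_A = c_A, regime = reg, degenerate = tie)
}

#' Cost contribution to the selection gradient
#'
#' `H(q) = -d/dq [ mean cost along the optimal-cost curve ]`, in closed form
#' `k * [(q/(1-q))^(1/(1-alpha)) - 1] * [(q/(1-q))^(alpha/(1-alpha)) + 1]^(-1/alpha)`
#' for `alpha != 1`; identically zero for `alpha = 1`. Antisymmetric about
#' `q = 1/2`, strictly increasing for `alpha < 1` and decreasing for
#' `alpha > 1`, with finite endpoint limits `-theta*k` (q -> 0) and
#' `+theta*k` (q -> 1); use [cost_gradient_limit()] for those. Evaluated in
#' log space so large `(q/(1-q))` powers do not overflow. Vectorised in `q`.
#'
#' @param q probability strictly inside (0, 1).
#' @param t a [trade_off()].
#' @export
cost_gradient_term <- function(q, t) {
  stopifnot(inherits(t, "trade_off"))
  check_prob(q)
  if (any(q == 0 | q == 1))
    stop("H(q) is defined on the open interval (0,1); use cost_gradient_limit() at the endpoints",
         call. = FALSE)
  if (alpha_is_one(t)) return(rep(0, length(q)))
  a <- t$alpha
  logr <- log(q) - log1p(-q)
  logA <- logr / (1 - a)
  logB <- (a / (1 - a)) * logr
  log1pB <- ifelse(logB > 0, logB + log1p(exp(-logB)), log1p(exp(logB)))
  # H = k * (A - 1) * (B + 1)^(-1/a), split so both factors stay in range
  t$k * (exp(logA - log1pB / a) - exp(-log1pB / a))
}

#' Endpoint limits of the cost gradient term
#'
#' `H(q) -> -theta*k` as `q -> 0` and `+theta*k` as `q -> 1`, with `theta`
#' from [cost_regime()].
#'
#' @param at endpoint, 0 or 1.
#' @param t a [trade_off()].
#' @export
cost_gradient_limit <- function(at, t) {
  stopifnot(inherits(t, "trade_off"), at %in% c(0, 1))
  th <- cost_regime(t)$theta
  if (at == 0) -th * t$k else th * t$k
}
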