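# Selection gradients, singular points, invasion and branching classification.

test_that("benefit gradient G has its frozen values and antisymmetry", {
  g1 <- paper_game("I")
  g2 <- paper_game("II")
  expect_equal(benefit_gradient_term(0.5, g1), 0, tolerance = 1e-12)
  expect_equal(benefit_gradient_term(0.5, g2), 0, tolerance = 1e-12)
  expect_equal(benefit_gradient_term(0.0154, g1), 0.0181872723183,
               tolerance = 1e-10)
  expect_equal(benefit_gradient_term(1, g1), -0.0187071414128, tolerance = 1e-10)
  q <- seq(0, 1, by = 0.05)
  for (g in list(g1, g2)) {
    G <- benefit_gradient_term(q, g)
    expect_equal(G, -rev(G), tolerance = 1e-12)
    expect_true(all(G[q < 0.5] > 0))
  }
})

test_that("selection gradient vanishes at the centre and matches finite differences", {
  g <- paper_game("I")
  t <- g$trade_off
  xs <- strategy(0.5, optimal_cost(0.5, t)$c_A)
  expect_equal(as.numeric(selection_gradient(xs, g)), c(0, 0), tolerance = 1e-10)
  # all-A corner: dW/dq' = G(1) + k, flagged as a corner
  sg <- selection_gradient(strategy(1, 0), g)
  expect_equal(sg[["dW_dq"]], 0.231292858587, tolerance = 1e-10)
  expect_true(attr(sg, "corner"))
  # agreement with central finite differences of invasion fitness
  set.seed(5)
  h <- 1e-6
  for (rep in 1:50) {
    model <- sample(c("I", "II"), 1)
    gg <- paper_game(model, k = runif(1, 0.1, 1), alpha = runif(1, 0.2, 2.5))
    kk <- gg$trade_off$k
    x <- strategy(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95) * kk)
    sg <- selection_gradient(x, gg)
    fd_q <- (invasion_fitness(strategy(x$q + h, x$c_A), x, gg) -
             invasion_fitness(strategy(x$q - h, x$c_A), x, gg)) / (2 * h)
    fd_c <- (invasion_fitness(strategy(x$q, x$c_A + h), x, gg) -
             invasion_fitness(strategy(x$q, x$c_A - h), x, gg)) / (2 * h)
    expect_equal(sg[["dW_dq"]], fd_q, tolerance = 1e-5)
    expect_equal(sg[["dW_dc"]], fd_c, tolerance = 1e-5)
  }
})

test_that("corner gradients point the way the trade-off shape dictates", {
  # weak trade-off: raising c_A off 0 is strongly favoured for q < 1
  sg <- selection_gradient(strategy(0.7, 0), paper_game("I", alpha = 0.15))
  expect_identical(sg[["dW_dc"]], Inf)
  # strong trade-off: the corner is locally cost-optimal
  sg <- selection_gradient(strategy(0.7, 0), paper_game("I", alpha = 1.5))
  expect_equal(sg[["dW_dc"]], -0.7)
})

test_that("singular points: unique central root for strong trade-offs", {
  for (k in c(0.1, 0.25, 1)) {
    for (a in c(1.2, 1.5, 2)) {
      sp <- find_singular_points(paper_game("I", k = k, alpha = a))
      expect_length(sp$interior, 1)
      expect_identical(sp$interior[[1]]$kind, "central")
      expect_lt(abs(sp$interior[[1]]$strategy$q - 0.5), 1e-6)
    }
  }
  # alpha = 1 is reported as a neutral line, not searched
  sp <- find_singular_points(paper_game("I", alpha = 1))
  expect_identical(sp$interior[[1]]$kind, "neutral_line")
})

test_that("singular points: the unstable pair of the weak trade-off", {
  sp <- find_singular_points(paper_game("I"))
  q <- sort(vapply(sp$interior, function(p) p$strategy$q, numeric(1)))
  expect_length(q, 3)
  # frozen root locations (independent oracle: dense-grid sign scan + uniroot
  # on direct binomial sums and the closed-form H)
  expect_equal(q, c(0.0153621506725, 0.5, 0.984637849327), tolerance = 1e-5)
  expect_lt(abs(q[3] - (1 - q[1])), 1e-6)      # mirror pair
  for (p in sp$interior) {
    expect_lte(p$residual, 1e-8)
    # the paired cost re-solves the c-component of the gradient
    sg <- selection_gradient(p$strategy, paper_game("I"))
    expect_lt(abs(sg[["dW_dc"]]), 1e-8)
    expect_lt(abs(sg[["dW_dq"]]), 1e-8)
  }
  # boundary corners are annotated with invasion verdicts
  expect_false(sp$boundary$x1$verdict$invasible)
  expect_false(sp$boundary$x0$verdict$invasible)
})

test_that("find_singular_points refuses asymmetric benefits with an explanation", {
  g <- game_spec(N = 4, benefit = benefit_table(c(0, 1, 2, 3, 4)),
                 sharing = "I", trade_off = trade_off(0.25, 0.5))
  expect_error(find_singular_points(g), "symmetric")
  expect_error(delta_w(g), "symmetric")
})

test_that("delta_w matches its frozen values and the general form", {
  g1 <- paper_game("I")
  g2 <- paper_game("II")
  expect_equal(delta_w(g1), -0.0393438805061, tolerance = 1e-10)
  expect_equal(delta_w(g2), -2.5375789059, tolerance = 1e-8)
  expect_lt(delta_w(g1), 0)
  expect_lt(delta_w(g2), 0)
  # the closed form at q = 1/2 equals the general derivative
  expect_equal(delta_w(g1), delta_w_general(0.5, g1), tolerance = 1e-10)
  expect_equal(delta_w(g2), delta_w_general(0.5, g2), tolerance = 1e-10)
  # and for the tiny table game too
  expect_equal(delta_w(tiny_game()), delta_w_general(0.5, tiny_game()),
               tolerance = 1e-10)
})

test_that("stability report classifies the central point", {
  g <- paper_game("I")
  sp <- find_singular_points(g)
  ctr <- Filter(function(p) p$kind == "central", sp$interior)[[1]]
  rep <- stability_report(ctr, g)
  expect_identical(rep$hessian[1, 1], 0)
  expect_identical(rep$hessian[1, 2], -2)
  expect_identical(rep$hessian[2, 1], -2)
  expect_identical(rep$jacobian[1, 2], -2)
  expect_equal(rep$criterion_lhs, 0.849381435334, tolerance = 1e-8)
  expect_true(rep$convergence_stable)   # 0.849 > k = 0.25
  expect_true(rep$branching_point)
  # strong trade-off: never convergence stable, covariance caveat reported
  g15 <- paper_game("I", alpha = 1.5)
  ctr15 <- find_singular_points(g15)$interior[[1]]
  rep15 <- stability_report(ctr15, g15)
  expect_false(rep15$convergence_stable)
  expect_true(rep15$branching_point)
  expect_match(rep15$indefinite_cases, "covariance")
  # k above the threshold: branching point but not convergence stable
  gk <- paper_game("I", k = 1.2)
  ctrk <- Filter(function(p) p$kind == "central",
                 find_singular_points(gk)$interior)[[1]]
  repk <- stability_report(ctrk, gk)
  expect_false(repk$convergence_stable)
  # alpha = 1: neutral line, no Jacobian
  rep1 <- stability_report(find_singular_points(paper_game("I", alpha = 1))$interior[[1]],
                           paper_game("I", alpha = 1))
  expect_identical(rep1$kind, "neutral_line")
  expect_null(rep1$jacobian)
})

test_that("non-central points get a flagged numeric Jacobian and are unstable", {
  g <- paper_game("I")
  sp <- find_singular_points(g)
  lo <- sp$interior[[1]]
  expect_identical(lo$kind, "unstable_pair_member")
  rep <- stability_report(lo, g)
  expect_match(rep$caveat, "numeric")
  expect_false(rep$convergence_stable)
})

test_that("critical_k has its frozen value, ordering and limit", {
  g1 <- paper_game("I")
  g2 <- paper_game("II")
  expect_equal(critical_k(0.15, g1), 0.849381435334, tolerance = 1e-8)
  # model II's threshold dominates model I's at equal alpha and benefit
  for (a in c(0.1, 0.15, 0.3, 0.6, 0.9))
    expect_gt(critical_k(a, g2), critical_k(a, g1))
  expect_lt(critical_k(0.999, g1), 1e-2)   # vanishes as alpha -> 1
  expect_gt(critical_k(0.15, g1), 0)
  expect_error(critical_k(1.5, g1), "0 < alpha < 1")
})

test_that("pure-state invasibility margins per sharing model", {
  g1 <- paper_game("I")
  g2 <- paper_game("II")
  vA1 <- pure_state_invasibility("all_A", g1)
  expect_equal(vA1$margin, 0.231292858587, tolerance = 1e-10)
  expect_false(vA1$invasible)
  vA2 <- pure_state_invasibility("all_A", g2)
  expect_equal(vA2$margin, -1.6961038875, tolerance = 1e-8)
  expect_true(vA2$invasible)
  # symmetric benefit: the all-B verdict mirrors all-A
  for (g in list(g1, g2)) {
    vA <- pure_state_invasibility("all_A", g)
    vB <- pure_state_invasibility("all_B", g)
    expect_equal(vB$margin, -vA$margin, tolerance = 1e-12)
    expect_identical(vA$invasible, vB$invasible)
  }
})
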