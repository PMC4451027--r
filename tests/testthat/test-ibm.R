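# Individual-based simulator: determinism, payoffs, mutation, branching.

test_that("initialisation is monomorphic, zeroed and seed-deterministic", {
  g <- paper_game("I")
  cfg <- ibm_config(pop_size = 50, seed = 3)
  st <- initialize_population(cfg, g)
  expect_identical(st$q, rep(0.5, 50))
  expect_equal(var(st$q), 0)
  expect_identical(st$c_A, rep(0.25 / 2^(1 / 0.15), 50))
  expect_identical(st$fitness, rep(0, 50))
  expect_identical(initialize_population(cfg, g), st)
  cfg$init_c <- 0.3
  expect_error(initialize_population(cfg, g), "outside")
})

test_that("a monomorphic all-A population earns beta(N)/N exactly", {
  g <- paper_game("I")
  cfg <- ibm_config(pop_size = 100, groups_per_generation = 100, bouts = 0,
                    mutation_prob = 0, generations = 0, seed = 1,
                    init_q = 1, init_c = 0)
  st <- play_generation(initialize_population(cfg, g), g, cfg)
  played <- st$games > 0
  expect_true(any(played))
  # identical payoff every game; averaging j copies only perturbs by an ulp
  expect_equal(st$fitness[played],
               rep(benefit_total(7, g) / 7, sum(played)), tolerance = 1e-14)
  expect_true(all(st$fitness[!played] == 0))
})

test_that("per-group payout conservation holds in logged runs of both models", {
  for (model in c("I", "II")) {
    g <- paper_game(model)
    cfg <- desk_scale(ibm_config(seed = 8), generations = 200)
    tr <- run_simulation(cfg, g, check_conservation = TRUE)
    expect_lt(tr$max_conservation_dev, 1e-12)
  }
})

test_that("fixed seeds give bit-identical trajectories", {
  g <- paper_game("I")
  cfg <- desk_scale(ibm_config(seed = 21), generations = 500)
  tr1 <- run_simulation(cfg, g)
  tr2 <- run_simulation(cfg, g)
  expect_identical(tr1$records, tr2$records)
  expect_identical(tr1$final$q, tr2$final$q)
  expect_identical(tr1$final$c_A, tr2$final$c_A)
})

test_that("zero generations returns only the initial state", {
  g <- paper_game("I")
  tr <- run_simulation(ibm_config(pop_size = 40, generations = 0, seed = 1), g)
  expect_identical(nrow(tr$records), 1L)
  expect_identical(tr$records$generation, 0)
  expect_identical(tr$records$var_q, 0)
})

test_that("mutation respects its brackets and the eps = 0 contract", {
  set.seed(4)
  n <- 200
  k <- 0.25; a <- 0.5
  # eps = 0: offspring exactly identical to parents
  q <- runif(n); cA <- runif(n) * k
  cB <- complementary_cost(cA, trade_off(k, a))
  res <- divlabsim:::cpp_reproduce(q, cA, cB, rep(1, n), rep(1L, n),
                                   bouts = 100, mut_prob = 1, eps = 0,
                                   k = k, alpha = a)
  expect_true(all(res$q %in% q))
  expect_true(all(res$c_A %in% cA))
  # parent at c_A = 0: a single mutation step stays in [0, eps^(1/alpha)]
  # (single bouts, so no compounding through serial replacement)
  eps <- 0.005
  stepped <- replicate(300, {
    res <- divlabsim:::cpp_reproduce(rep(0.5, n), rep(0, n), rep(k, n),
                                     rep(1, n), rep(1L, n),
                                     bouts = 1, mut_prob = 1, eps = eps,
                                     k = k, alpha = a)
    max(res$c_A)
  })
  expect_true(all(stepped >= 0 & stepped <= eps^(1 / a) + 1e-12))
  expect_gt(max(stepped), 0)
  # q clamped to [0, 1]
  res <- divlabsim:::cpp_reproduce(rep(0.999, n), rep(0.1, n), rep(0.15, n),
                                   rep(1, n), rep(1L, n),
                                   bouts = 500, mut_prob = 1, eps = eps,
                                   k = k, alpha = a)
  expect_true(all(res$q >= 0 & res$q <= 1))
  # population size is untouched by reproduction
  expect_length(res$q, n)
})

test_that("neutral drift keeps the expected composition (martingale)", {
  set.seed(99)
  fr <- replicate(400, {
    n <- 60
    q <- c(rep(0.2, 30), rep(0.8, 30))
    res <- divlabsim:::cpp_reproduce(q, rep(0.1, n), rep(0.1, n),
                                     rep(1, n), rep(1L, n),
                                     bouts = 20, mut_prob = 0, eps = 0.005,
                                     k = 0.25, alpha = 0.5)
    mean(res$q > 0.5)
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se)
})

test_that("monomorphic realised fitness matches the analytic expected payoff", {
  # mutation off; mean over participants across >= 200 generations within 3 SE
  cases <- list(list(model = "I", k = 0.25, a = 0.15, q0 = 0.5),
                list(model = "II", k = 0.25, a = 0.15, q0 = 0.5),
                list(model = "I", k = 0.5, a = 1.5, q0 = 0.3))
  for (cs in cases) {
    t <- trade_off(cs$k, cs$a)
    g <- paper_game(cs$model, k = cs$k, alpha = cs$a)
    c0 <- optimal_cost(cs$q0, t)$c_A
    cfg <- ibm_config(pop_size = 300, groups_per_generation = 300, bouts = 0,
                      mutation_prob = 0, generations = 0, seed = 11,
                      init_q = cs$q0, init_c = c0)
    st <- initialize_population(cfg, g)
    m <- replicate(250, {
      s2 <- play_generation(st, g, cfg)
      mean(s2$fitness[s2$games > 0])
    })
    pred <- mean_payoff(strategy(cs$q0, c0), cs$q0, g)
    expect_lt(abs(mean(m) - pred), 3 * sd(m) / sqrt(length(m)))
  }
})

test_that("branching detector classifies constructed populations", {
  bi <- make_fixtures("bimodal_population", seed = 1)
  expect_identical(detect_branching(bi)$outcome, "branched")
  expect_identical(detect_branching(rep(0.5, 40))$outcome, "undecided")
  expect_identical(detect_branching(runif(40, 0.95, 1))$outcome, "near_pure")
  expect_identical(detect_branching(c(0.02, rep(0.98, 39)))$outcome, "near_pure")
  expect_error(detect_branching(numeric(0)), "empty")
  # fixture determinism
  expect_identical(make_fixtures("bimodal_population", seed = 1), bi)
})

test_that("branching occurs at full scale in the convergent-branching regime", {
  # k = 0.25, alpha = 0.15, model I is convergence stable + branching point;
  # pop 1000 x 1e5 generations is the smallest scale we found that branches
  # reliably (pop 300 does not branch on desk timescales; see the vignette)
  outcomes <- character(0)
  for (s in 1:3) {
    tr <- heavy_run(paste0("branch", s), 0.25, 0.15, "I", seed = s)
    outcomes <- c(outcomes, tr$verdict$outcome)
    if (tr$verdict$outcome == "branched") {
      r <- tr$records[nrow(tr$records), ]
      # clusters near q = 0 and 1 with specialised costs
      expect_lt(r$mean_q_low, 0.05)
      expect_gt(r$mean_q_high, 0.95)
      expect_gt(r$mean_c_low, 0.8 * 0.25)   # B specialists pay c_A ~ k
      expect_lt(r$mean_c_high, 0.05 * 0.25) # A specialists pay c_A ~ 0
      expect_false(is.na(tr$verdict$onset_generation))
    }
  }
  expect_gte(sum(outcomes == "branched"), 2)
})

test_that("no branching without convergence stability (alpha = 1.5)", {
  outcomes <- vapply(1:2, function(s)
    heavy_run(paste0("nob", s), 0.25, 1.5, "I", seed = s)$verdict$outcome,
    character(1))
  expect_true(all(outcomes != "branched"))
  # outcome class (1): population collapses onto one pure corner
  expect_true(all(outcomes == "near_pure"))
})

test_that("corner starts remain in the corner basins", {
  g <- paper_game("I")
  k <- g$trade_off$k
  cfg <- desk_scale(ibm_config(), generations = 3000)
  cfg$seed <- 17; cfg$init_q <- 0.999; cfg$init_c <- 0
  hi <- run_simulation(cfg, g)
  expect_gt(mean(hi$final$q), 0.9)
  cfg$seed <- 18; cfg$init_q <- 0.001; cfg$init_c <- k
  lo <- run_simulation(cfg, g)
  expect_lt(mean(lo$final$q), 0.1)
})
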