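# Shared fixtures, built in code.

paper_trade_off <- function(k = 0.25, alpha = 0.15) trade_off(k, alpha)

# the simulation study's game: N = 7, Gaussian benefit 30/5/3.5
paper_game <- function(sharing = "I", k = 0.25, alpha = 0.15, ...) {
  game_spec(N = 7, benefit = benefit_gaussian(30, 5, 3.5),
            sharing = sharing, trade_off = trade_off(k, alpha), ...)
}

tiny_game <- function() make_fixtures("tiny_game")

# independent benefit table for oracles: plain arithmetic, no package calls
oracle_beta <- function(i) 30 / (5 * sqrt(2 * pi)) * exp(-(i - 3.5)^2 / (2 * 5)^2)

# full-scale runs take ~30 s each; share them across test files
.heavy <- new.env(parent = emptyenv())
heavy_run <- function(key, k, alpha, sharing, seed, generations = 1e5) {
  if (is.null(.heavy[[key]])) {
    g <- game_spec(N = 7, benefit = benefit_gaussian(30, 5, 3.5),
                   sharing = sharing, trade_off = trade_off(k, alpha))
    .heavy[[key]] <- run_simulation(
      ibm_config(seed = seed, generations = generations), g)
  }
  .heavy[[key]]
}
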