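# JSON configuration: one flat schema shared by all subcommands, with
# per-subcommand sections ("ibm", "sweep", "grid"). Unknown keys are
# rejected, defaults are applied and logged.

.config_defaults <- list(
  model = "I", N = 7L, k = 0.25, alpha = 0.15, half_factor = FALSE,
  benefit = list(kind = "gaussian", amplitude = 30, sigma = 5, mu = 3.5,
                 conventional = FALSE))

.ibm_defaults <- list(pop_size = 1000L, groups_per_generation = 1000L,
                      bouts = 100L, mutation_prob = 0.1, epsilon = 0.005,
                      generations = 150000L, seed = NULL, init_q = 0.5,
                      init_c = NULL, record_every = 100L)

check_known_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s) at %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

fill_defaults <- function(x, defaults, path, quiet) {
  for (nm in names(defaults)) {
    if (is.null(x[[nm]]) && !is.null(defaults[[nm]])) {
      x[[nm]] <- defaults[[nm]]
      if (!quiet) message(sprintf("config: %s.%s defaulted to %s", path, nm,
                                  paste(format(unlist(defaults[[nm]])),
                                        collapse = ",")))
    }
  }
  x
}

#' Load and validate a JSON run configuration
#'
#' Reads a JSON file describing a game (`model`, `N`, `k`, `alpha`,
#' `benefit`, `half_factor`) and, optionally, `ibm`, `sweep` and `grid`
#' sections for the drivers. Missing fields are filled from the documented
#' defaults (the published parameter set) and each applied default is
#' logged as a message; unknown keys raise a validation error naming the
#' offending field path.
#'
#' @param path JSON file path.
#' @param quiet suppress default-logging messages.
#' @return list of class `run_config` with elements `game`
#'   ([game_spec()]), `ibm` ([ibm_config()]), optional `sweep` and `grid`
#'   lists, and `resolved` (the fully resolved raw configuration, suitable
#'   for [dump_config()]).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("cannot parse %s as JSON: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  check_known_keys(raw, c(names(.config_defaults), "ibm", "sweep", "grid"),
                   "<top level>")
  raw <- fill_defaults(raw, .config_defaults, "game", quiet)
  check_known_keys(raw$benefit,
                   c("kind", "amplitude", "sigma", "mu", "conventional", "table"),
                   "benefit")
  if (identical(raw$benefit$kind, "gaussian"))
    raw$benefit <- fill_defaults(raw$benefit, .config_defaults$benefit,
                                 "benefit", quiet)
  if (!raw$model %in% c("I", "II"))
    stop("config field 'model' must be \"I\" or \"II\"", call. = FALSE)
  if (!is.numeric(raw$alpha) || raw$alpha <= 0)
    stop("config field 'alpha' must be a positive number", call. = FALSE)
  if (!is.numeric(raw$k) || raw$k <= 0)
    stop("config field 'k' must be a positive number", call. = FALSE)
  benefit <- switch(raw$benefit$kind,
    gaussian = benefit_gaussian(raw$benefit$amplitude, raw$benefit$sigma,
                                raw$benefit$mu,
                                isTRUE(raw$benefit$conventional)),
    table = benefit_table(raw$benefit$table),
    stop("config field 'benefit.kind' must be \"gaussian\" or \"table\"",
         call. = FALSE))
  game <- game_spec(N = raw$N, benefit = benefit, sharing = raw$model,
                    trade_off = trade_off(raw$k, raw$alpha),
                    half_factor = isTRUE(raw$half_factor))
  ibm_raw <- if (is.null(raw$ibm)) list() else raw$ibm
  check_known_keys(ibm_raw, names(.ibm_defaults), "ibm")
  ibm_raw <- fill_defaults(ibm_raw, .ibm_defaults, "ibm", quiet)
  ibm <- ibm_config(pop_size = ibm_raw$pop_size,
                    groups_per_generation = ibm_raw$groups_per_generation,
                    bouts = ibm_raw$bouts,
                    mutation_prob = ibm_raw$mutation_prob,
                    epsilon = ibm_raw$epsilon,
                    generations = ibm_raw$generations,
                    seed = ibm_raw$seed, init_q = ibm_raw$init_q,
                    init_c = ibm_raw$init_c,
                    record_every = ibm_raw$record_every)
  if (!is.null(raw$sweep))
    check_known_keys(raw$sweep,
                     c("k_values", "alpha_values", "replicates", "seed_base"),
                     "sweep")
  if (!is.null(raw$grid))
    check_known_keys(raw$grid, c("q0", "c0", "seed_base"), "grid")
  resolved <- raw
  resolved$ibm <- ibm_raw
  structure(list(game = game, ibm = ibm, sweep = raw$sweep, grid = raw$grid,
                 resolved = resolved),
            class = "run_config")
}

#' Write a resolved configuration back to JSON
#'
#' `load_config(dump_config(cfg, path))` reproduces `cfg` exactly: the dump
#' contains every default already applied.
#'
#' @param cfg a `run_config` from [load_config()].
#' @param path output JSON path.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(cfg$resolved, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write driver outputs with a reproducibility manifest
#'
#' Writes each element of `results` into `out_dir` — data.frames as CSV,
#' everything else as JSON — then writes `manifest.json` last, recording
#' the resolved configuration, package version, seed(s), timestamps and an
#' MD5 checksum per file. An existing manifest in `out_dir` makes the call
#' refuse unless `force = TRUE`.
#'
#' @param results named list of data.frames and/or lists.
#' @param manifest list of run metadata merged into the manifest.
#' @param out_dir output directory (created if missing).
#' @param force overwrite a directory that already holds a manifest.
#' @return invisibly, the manifest list (including the file inventory).
#' @export
write_outputs <- function(results, manifest = list(), out_dir,
                          force = FALSE) {
  stopifnot(is.list(results))
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list", call. = FALSE)
  man_path <- file.path(out_dir, "manifest.json")
  if (file.exists(man_path) && !force)
    stop(sprintf("%s already contains a manifest; use force = TRUE to overwrite",
                 out_dir), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
    }
    files <- c(files, p)
  }
  inventory <- data.frame(file = basename(files),
                          md5 = unname(tools::md5sum(files)),
                          stringsAsFactors = FALSE)
  man <- c(manifest,
           list(package = "divlabsim",
                version = as.character(utils::packageVersion("divlabsim")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                files = inventory))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(man)
}

#' Deterministic small fixtures for tests and examples
#'
#' @param kind one of `"bimodal_population"` (40 individuals, 20 near
#'   `q = 0.02` and 20 near `q = 0.98`, costs specialised accordingly),
#'   `"monomorphic_population"` (40 individuals at the singular point of
#'   the tiny game), `"benefit_table"` (the 5-point symmetric table
#'   `c(0, 1, 2, 1, 0)`), `"tiny_game"` (N = 3, table benefit
#'   `c(1, 2, 2, 1)`, model I, `k = 0.25`, `alpha = 0.5`).
#' @param seed deterministic seed for the jittered fixtures.
#' @export
make_fixtures <- function(kind = c("bimodal_population",
                                   "monomorphic_population",
                                   "benefit_table", "tiny_game"),
                          seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    bimodal_population = {
      q <- c(stats::runif(20, 0, 0.04), stats::runif(20, 0.96, 1))
      c_A <- c(stats::runif(20, 0.22, 0.25), stats::runif(20, 0, 0.03))
      structure(list(q = q, c_A = c_A, fitness = rep(0, 40),
                     games = rep(0L, 40), generation = 0L),
                class = "population_state")
    },
    monomorphic_population = {
      g <- make_fixtures("tiny_game")
      c0 <- g$trade_off$k / 2^(1 / g$trade_off$alpha)
      structure(list(q = rep(0.5, 40), c_A = rep(c0, 40),
                     fitness = rep(0, 40), games = rep(0L, 40),
                     generation = 0L),
                class = "population_state")
    },
    benefit_table = benefit_table(c(0, 1, 2, 1, 0)),
    tiny_game = game_spec(N = 3, benefit = benefit_table(c(1, 2, 2, 1)),
                          sharing = "I", trade_off = trade_off(0.25, 0.5))
  )
}
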