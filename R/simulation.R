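# Whole-run orchestration: seeded execution of the generation loop, outcome
# measures, replicate batches with reproducible seed derivation, and CSV
# export of trajectories.

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards,
# so runs are deterministic without clobbering the session RNG stream.
with_run_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-group outcome measures for one generation
#'
#' Computes the principal outcome measures: the arithmetic mean of social
#' learning reliance and of parochialism in each group, the mean group and
#' population pay-offs, the frequency of each learning strategy within each
#' group, and the group sizes.
#'
#' @param population An evaluated `population` (see [init_population()]).
#' @return A data frame with one row per group and columns `generation`,
#'   `group`, `group_size`, `mean_reliance`, `mean_parochialism`,
#'   `mean_payoff`, `freq_UT`, `freq_CT`, `freq_PT`, `mean_payoff_pop`.
#' @examples
#' set.seed(1)
#' summarize_population(init_population(model_params(N = 20, generations = 0)))
#' @export
summarize_population <- function(population) {
  stopifnot(is.data.frame(population))
  if (anyNA(population$payoff))
    stop("population has unevaluated agents (NA pay-offs)", call. = FALSE)
  gen <- attr(population, "generation", exact = TRUE)
  if (is.null(gen)) gen <- NA_integer_
  pop_pay <- mean(population$payoff)
  rows <- lapply(c(0L, 1L), function(g) {
    members <- population[population$group == g, , drop = FALSE]
    if (nrow(members) == 0L)
      stop("group ", g, " is empty; populations must keep both groups ",
           "non-empty", call. = FALSE)
    data.frame(
      generation = gen, group = g, group_size = nrow(members),
      mean_reliance = mean(members$reliance),
      mean_parochialism = mean(members$parochialism),
      mean_payoff = mean(members$payoff),
      freq_UT = mean(members$strategy == "UT"),
      freq_CT = mean(members$strategy == "CT"),
      freq_PT = mean(members$strategy == "PT"),
      mean_payoff_pop = pop_pay
    )
  })
  do.call(rbind, rows)
}

#' Run one seeded simulation
#'
#' Initializes the founder generation and applies the four-stage generation
#' step `params$generations` times, recording the per-group outcome measures
#' after initialization and after every step. The full trajectory is a pure
#' function of `params` (including its seed): identical parameters always
#' reproduce identical results. The caller's RNG state is left untouched.
#'
#' @param params A [model_params()] object.
#' @param engine `"cpp"` (default) runs the compiled generation loop;
#'   `"r"` runs the pure-R reference engine built from [step_generation()].
#'   The two engines implement the identical procedure and are
#'   distributionally equivalent, but consume the RNG stream in different
#'   orders, so trait-by-trait results for one seed differ.
#' @return An object of class `"sim_run"`: a list with elements `params`,
#'   `seed`, `trajectory` (data frame, one row per generation x group, of
#'   length `2 * (generations + 1)` rows), `final` (the last generation's
#'   summary rows) and `final_population`.
#' @examples
#' res <- run(model_params(N = 60, generations = 20, seed = 7))
#' res$final
#' @export
run <- function(params, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "model_params"))
  engine <- match.arg(engine)
  out <- with_run_seed(params$seed, {
    if (engine == "cpp") run_engine_cpp(params) else run_engine_r(params)
  })
  structure(list(params = params, seed = params$seed, engine = engine,
                 trajectory = out$trajectory, final = out$final,
                 final_population = out$final_population),
            class = "sim_run")
}

run_engine_cpp <- function(params) {
  codes <- match(params$allowed_strategies, strategy_levels) - 1L
  raw <- sim_run_cpp(
    N = params$N, p = params$p, delta_theta = params$delta_theta,
    e = params$e, sigma = params$sigma, d = params$d,
    n_targets = params$n_targets, mu_cont = params$mu_cont,
    delta_mut = params$delta_mut, mu_strat = params$mu_strat,
    allowed_codes = codes,
    paroch_evolvable = params$parochialism_evolvable,
    reliance_evolvable = params$reliance_evolvable,
    marker_reassign = params$marker_inheritance == "reassign",
    T = params$generations
  )
  trajectory <- as.data.frame(raw$trajectory)
  trajectory$generation <- as.integer(trajectory$generation)
  trajectory$group <- as.integer(trajectory$group)
  trajectory$group_size <- as.integer(trajectory$group_size)
  fp <- raw$final
  final_population <- new_population(data.frame(
    group = fp$group, marker = fp$marker,
    parochialism = fp$parochialism, reliance = fp$reliance,
    strategy = strategy_levels[fp$strategy_code + 1L],
    trait_x = fp$trait_x, trait_y = fp$trait_y, payoff = fp$payoff,
    stringsAsFactors = FALSE
  ), generation = params$generations)
  list(trajectory = trajectory,
       final = trajectory[trajectory$generation == params$generations, ,
                          drop = FALSE],
       final_population = final_population)
}

run_engine_r <- function(params) {
  pop <- init_population(params)
  summaries <- vector("list", params$generations + 1L)
  summaries[[1L]] <- summarize_population(pop)
  for (t in seq_len(params$generations)) {
    pop <- step_generation(pop, params)
    summaries[[t + 1L]] <- summarize_population(pop)
  }
  trajectory <- do.call(rbind, summaries)
  rownames(trajectory) <- NULL
  list(trajectory = trajectory,
       final = trajectory[trajectory$generation == params$generations, ,
                          drop = FALSE],
       final_population = pop)
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> N = %d, T = %d, seed = %d, engine = %s\n",
              x$params$N, x$params$generations, x$seed, x$engine))
  cat("final generation:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' Derive the seed of replicate `r` from a base seed
#'
#' Replicate `r` (1-based) of a batch with base seed `b` always runs with
#' seed `(b + r - 1) mod (2^31 - 1)`: a documented, deterministic derivation,
#' so any replicate reproduces identically whether executed alone, inside a
#' batch, or in parallel.
#'
#' @param base_seed Integer base seed.
#' @param r Replicate index (1-based), vectorized.
#' @return Integer vector of derived seeds.
#' @export
replicate_seed <- function(base_seed, r) {
  as.integer((as.double(base_seed) + r - 1) %% .Machine$integer.max)
}

#' Run independent replicates of one parameter combination
#'
#' Executes `n_reps` runs whose seeds are derived from `base_seed` via
#' [replicate_seed()]; replicate `r`'s result depends only on `(base_seed,
#' r)`, never on batch composition or execution order.
#'
#' @param params A [model_params()] object (its own `seed` is ignored).
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed for the batch.
#' @param engine Passed to [run()].
#' @return A list of `sim_run` objects of length `n_reps`.
#' @examples
#' reps <- run_replicates(model_params(N = 60, generations = 10), 3, 99)
#' sapply(reps, function(r) r$final$mean_reliance[1])
#' @export
run_replicates <- function(params, n_reps, base_seed, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "model_params"), n_reps >= 1)
  engine <- match.arg(engine)
  lapply(seq_len(n_reps), function(r) {
    run(update_params(params, seed = replicate_seed(base_seed, r)), engine)
  })
}

#' Extract a run's trajectory as a tidy data frame
#'
#' One row per generation x group, with run metadata columns (`seed` and any
#' extras supplied) prepended, ready for CSV export or row-binding across
#' replicates.
#'
#' @param result A `sim_run` object.
#' @param ... Named scalar metadata columns to prepend (e.g. replicate index).
#' @return A data frame.
#' @export
trajectory_df <- function(result, ...) {
  stopifnot(inherits(result, "sim_run"))
  meta <- list(...)
  out <- result$trajectory
  base <- data.frame(seed = result$seed)
  if (length(meta) > 0L) base <- cbind(base, as.data.frame(meta))
  cbind(base[rep(1L, nrow(out)), , drop = FALSE], out, row.names = NULL)
}

#' Write a run's trajectory to CSV
#'
#' @param result A `sim_run` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  utils::write.csv(trajectory_df(result), path, row.names = FALSE)
  invisible(path)
}
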