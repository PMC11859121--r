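# Experiment presets mirroring the principal result regimes, and the
# parameter-sweep runner producing tidy long-format tables.

#' Construct a parameter-sweep specification
#'
#' A sweep evaluates the Cartesian product of the `grid` values applied on
#' top of `base_params`, with `n_reps` seeded replicates per combination.
#'
#' @param base_params A [model_params()] object.
#' @param grid Named list mapping `model_params` field names to value
#'   vectors. An empty list runs `base_params` alone.
#' @param n_reps Replicates per combination.
#' @param base_seed Integer base seed; combination `c`, replicate `r` runs
#'   with seed `sweep_seed(base_seed, c, r)`.
#' @return An object of class `"sweep_spec"`.
#' @examples
#' spec <- sweep_spec(model_params(N = 60, generations = 10),
#'                    grid = list(sigma = c(0.1, 0.5)), n_reps = 2)
#' spec
#' @export
sweep_spec <- function(base_params, grid = list(), n_reps = 20,
                       base_seed = 1L) {
  stopifnot(inherits(base_params, "model_params"), n_reps >= 1)
  if (length(grid) > 0L) {
    if (is.null(names(grid)) || any(names(grid) == ""))
      stop("all `grid` entries must be named", call. = FALSE)
    bad <- setdiff(names(grid), names(unclass(base_params)))
    if (length(bad) > 0L)
      stop("grid keys must name model parameters; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(base_params = base_params, grid = grid,
                 n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

sweep_combinations <- function(spec) {
  if (length(spec$grid) == 0L)
    return(data.frame(.combo = 1L))
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  combos$.combo <- seq_len(nrow(combos))
  combos
}

#' @export
print.sweep_spec <- function(x, ...) {
  n_combo <- nrow(sweep_combinations(x))
  cat("<sweep_spec>\n")
  if (length(x$grid) > 0L)
    for (key in names(x$grid))
      cat(sprintf("  %s: %s\n", key, paste(signif(x$grid[[key]], 4),
                                           collapse = ", ")))
  cat(sprintf("  %d combination(s) x %d replicate(s) = %d runs (base seed %d)\n",
              n_combo, x$n_reps, n_combo * x$n_reps, x$base_seed))
  invisible(x)
}

#' Derive the seed for one sweep run
#'
#' Combination `c`, replicate `r` of a sweep with base seed `b` always runs
#' with seed `(b + 10007 * (c - 1) + r - 1) mod (2^31 - 1)`. The stride
#' keeps the replicate seeds of distinct combinations disjoint for any
#' `n_reps <= 10007`.
#'
#' @param base_seed Integer base seed.
#' @param combo Combination index (1-based).
#' @param r Replicate index (1-based).
#' @return Integer seed.
#' @export
sweep_seed <- function(base_seed, combo, r) {
  as.integer((as.double(base_seed) + 10007 * (combo - 1) + (r - 1)) %%
               .Machine$integer.max)
}

#' Named experiment presets for the principal result regimes
#'
#' Returns a ready-to-run [sweep_spec()] reproducing, at desk scale, one of
#' the model's qualitative result regimes:
#' \describe{
#'   \item{`baseline_sigma`}{one effective group (`delta_theta = 0`),
#'     unbiased transmission only, parochialism off; sweeps the
#'     individual-learning error `sigma`. Reliance on social learning rises
#'     with `sigma`.}
#'   \item{`diversity_collapse`}{two groups with diverging optima,
#'     parochialism off; sweeps `delta_theta` x `sigma`. Unbiased social
#'     learning is increasingly selected against as the optima separate.}
#'   \item{`parochial_rescue`}{parochialism evolvable; sweeps `delta_theta`
#'     x marker reliability `e`. Reliable markers restore selection for
#'     social learning in diverse populations.}
#'   \item{`group_size`}{the rescue scenario at fully reliable markers
#'     (`e = 1`), sweeping majority share `p` x `delta_theta`; majority
#'     groups capitalize on parochial social learning more than minorities.}
#'   \item{`conformist_competition`}{strategies `{UT, CT}` compete;
#'     sweeps `delta_theta` x `e` with parochialism evolvable.}
#'   \item{`payoff_competition`}{strategies `{UT, PT}` compete; same grid.
#'     At intermediate `e` the two groups can settle at different reliance
#'     equilibria.}
#'   \item{`three_way`}{all of `{UT, CT, PT}` compete; same grid.}
#' }
#'
#' Preset grids are deliberately coarse (a few values per axis, `n_reps`
#' replicates) so a full preset runs on a desktop in minutes; pass a denser
#' grid or more replicates through the arguments for closer aggregation.
#'
#' @param name Preset name (see above).
#' @param n_reps Replicates per combination (default 20).
#' @param base_seed Integer base seed.
#' @param N,generations Population size and run length for the preset's base
#'   parameters.
#' @return A [sweep_spec()].
#' @examples
#' preset("baseline_sigma", n_reps = 2, N = 60, generations = 10)
#' @export
preset <- function(name, n_reps = 20, base_seed = 1L, N = 300,
                   generations = 800) {
  presets <- c("baseline_sigma", "diversity_collapse", "parochial_rescue",
               "group_size", "conformist_competition", "payoff_competition",
               "three_way")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset; valid names: ", paste(presets, collapse = ", "),
         call. = FALSE)
  dtheta_grid <- c(0, pi / 4, pi / 2, 3 * pi / 4, pi)
  e_grid <- c(0, 0.25, 0.5, 0.75, 1)
  base <- model_params(N = N, generations = generations, p = 0.5,
                       delta_theta = 0, e = 1, sigma = 0.5,
                       allowed_strategies = "UT",
                       parochialism_evolvable = FALSE)
  spec <- switch(
    name,
    baseline_sigma = sweep_spec(
      base, grid = list(sigma = c(0.02, 0.1, 0.25, 0.5, 1)),
      n_reps = n_reps, base_seed = base_seed),
    diversity_collapse = sweep_spec(
      base, grid = list(delta_theta = dtheta_grid, sigma = c(0.25, 0.5)),
      n_reps = n_reps, base_seed = base_seed),
    parochial_rescue = sweep_spec(
      update_params(base, parochialism_evolvable = TRUE),
      grid = list(delta_theta = dtheta_grid, e = c(0, 0.5, 1)),
      n_reps = n_reps, base_seed = base_seed),
    group_size = sweep_spec(
      update_params(base, parochialism_evolvable = TRUE, e = 1),
      grid = list(delta_theta = dtheta_grid, p = c(0.5, 0.65, 0.75, 0.9)),
      n_reps = n_reps, base_seed = base_seed),
    conformist_competition = sweep_spec(
      update_params(base, parochialism_evolvable = TRUE,
                    allowed_strategies = c("UT", "CT")),
      grid = list(delta_theta = dtheta_grid, e = e_grid),
      n_reps = n_reps, base_seed = base_seed),
    payoff_competition = sweep_spec(
      update_params(base, parochialism_evolvable = TRUE,
                    allowed_strategies = c("UT", "PT")),
      grid = list(delta_theta = dtheta_grid, e = e_grid),
      n_reps = n_reps, base_seed = base_seed),
    three_way = sweep_spec(
      update_params(base, parochialism_evolvable = TRUE,
                    allowed_strategies = c("UT", "CT", "PT")),
      grid = list(delta_theta = dtheta_grid, e = e_grid),
      n_reps = n_reps, base_seed = base_seed)
  )
  spec
}

#' Execute a parameter sweep
#'
#' Runs every grid combination x replicate and collects the final-generation
#' outcome measures into one long-format table: one row per (combination x
#' replicate x group). Seeds follow [sweep_seed()], so results are identical
#' whatever the execution order or worker count.
#'
#' @param spec A [sweep_spec()] (e.g. from [preset()]).
#' @param workers Number of parallel workers (forked via
#'   [parallel::mclapply()]; `1` runs serially).
#' @param engine Passed to [run()].
#' @param quiet Suppress per-combination progress messages.
#' @return A data frame of class `"sweep_result"` with the varied parameter
#'   columns, `combo`, `replicate`, `seed`, `group`, `group_size`,
#'   `mean_reliance`, `mean_parochialism`, `mean_payoff`, `freq_UT`,
#'   `freq_CT`, `freq_PT`, `mean_payoff_pop`.
#' @examples
#' spec <- sweep_spec(model_params(N = 60, generations = 10),
#'                    grid = list(sigma = c(0.1, 0.5)), n_reps = 2)
#' res <- run_sweep(spec, quiet = TRUE)
#' nrow(res)  # 2 combos x 2 reps x 2 groups = 8 rows
#' @export
run_sweep <- function(spec, workers = 1L, engine = c("cpp", "r"),
                      quiet = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  engine <- match.arg(engine)
  combos <- sweep_combinations(spec)
  jobs <- expand.grid(.combo = combos$.combo, .rep = seq_len(spec$n_reps),
                      KEEP.OUT.ATTRS = FALSE)
  if (!quiet)
    message(sprintf("sweep: %d combination(s) x %d replicate(s) = %d runs",
                    nrow(combos), spec$n_reps, nrow(jobs)))
  run_one <- function(j) {
    combo_id <- jobs$.combo[j]
    r <- jobs$.rep[j]
    seed <- sweep_seed(spec$base_seed, combo_id, r)
    overrides <- as.list(combos[combos$.combo == combo_id,
                                setdiff(names(combos), ".combo"),
                                drop = FALSE])
    params <- do.call(update_params,
                      c(list(spec$base_params), overrides, list(seed = seed)))
    res <- tryCatch(
      run(params, engine = engine),
      error = function(err) stop(sprintf(
        "sweep run failed at combination %d, replicate %d (seed %d): %s",
        combo_id, r, seed, conditionMessage(err)), call. = FALSE))
    fin <- res$final
    meta <- data.frame(combo = combo_id, replicate = r, seed = seed)
    if (length(overrides) > 0L)
      meta <- cbind(as.data.frame(overrides, stringsAsFactors = FALSE), meta)
    cbind(meta[rep(1L, nrow(fin)), , drop = FALSE],
          fin[, setdiff(names(fin), "generation"), drop = FALSE],
          row.names = NULL)
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(jobs)), function(j) {
      if (!quiet && jobs$.rep[j] == spec$n_reps)
        message(sprintf("  combination %d/%d done", jobs$.combo[j],
                        nrow(combos)))
      run_one(j)
    })
  }
  failed <- vapply(rows, inherits, logical(1), what = "try-error")
  if (any(failed)) stop(rows[[which(failed)[1]]], call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$combo, out$replicate, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
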