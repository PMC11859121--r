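#' Model parameters for a parochial social learning simulation
#'
#' Bundles and validates the full parameter set governing one simulation run.
#' The population holds `N` agents split into two intermixed groups; group 0
#' receives `round(N * p)` agents and group 1 the remainder, and these counts
#' are held constant over all generations.
#'
#' @param N Population size (total agents; both groups must round to a
#'   non-empty size).
#' @param p Proportion of the population in group 0, in (0, 1).
#' @param delta_theta Angular separation of the two group optima on the unit
#'   circle, in radians, restricted to `[0, pi]` (aligned through opposed).
#' @param e Marker reliability in `[0, 1]`: the probability that an agent
#'   receives the identity marker matching its group; otherwise the marker is
#'   drawn from the population marker frequencies (`p` for marker 0).
#' @param sigma Individual-learning error: per-axis standard deviation of the
#'   isotropic bivariate normal draw around the learner's own group optimum,
#'   in units of the unit-circle radius. Must be non-negative.
#' @param d Selection intensity: denominator of the Gaussian fitness kernel
#'   `exp(-dist^2 / d)`. Smaller values punish trait-optimum distance more
#'   severely. Must be positive.
#' @param n_targets Number of agents from the parent generation each learner
#'   initially observes (sampled without replacement), at most `N`.
#' @param mu_cont Mutation probability for the continuous traits (reliance and
#'   parochialism), in `[0, 1]`. Note this is the probability of *mutating*;
#'   faithful inheritance happens with probability `1 - mu_cont`.
#' @param delta_mut Standard deviation of the zero-mean normal mutation added
#'   to a continuous trait when it mutates; results are truncated to `[0, 1]`.
#' @param mu_strat Strategy mutation probability in `[0, 1]`: with this
#'   probability the offspring draws a strategy uniformly from
#'   `allowed_strategies` (the parent's own strategy included in the draw).
#' @param allowed_strategies Character vector, a non-empty subset of
#'   `c("UT", "CT", "PT")` that must contain `"UT"` (every simulation starts
#'   from pure unbiased transmission).
#' @param parochialism_evolvable Logical; if `FALSE` parochialism is fixed at
#'   0 in every generation.
#' @param reliance_evolvable Logical; if `FALSE` reliance on social learning
#'   is clamped to 0 with mutation disabled (the individual-learning-only
#'   control used for pay-off comparisons).
#' @param marker_inheritance Either `"reassign"` (default; offspring markers
#'   are re-drawn at birth via the `e` rule applied to the offspring's group,
#'   keeping the marker-group correlation at `e` in every generation) or
#'   `"inherit"` (offspring copy the parent's marker verbatim).
#' @param generations Number of generation steps `T` to simulate after
#'   initialization (non-negative; 0 records only the founder generation).
#' @param seed Integer seed controlling all randomness of the run.
#'
#' @return An object of class `"model_params"` (a validated named list).
#' @examples
#' params <- model_params(N = 100, sigma = 0.5, generations = 50, seed = 1)
#' params$delta_theta
#' @seealso [run()], [preset()]
#' @export
model_params <- function(N = 500,
                         p = 0.5,
                         delta_theta = 0,
                         e = 1,
                         sigma = 0.5,
                         d = 1,
                         n_targets = 5,
                         mu_cont = 0.1,
                         delta_mut = 0.05,
                         mu_strat = 0.05,
                         allowed_strategies = "UT",
                         parochialism_evolvable = FALSE,
                         reliance_evolvable = TRUE,
                         marker_inheritance = c("reassign", "inherit"),
                         generations = 1000,
                         seed = 1L) {
  marker_inheritance <- match.arg(marker_inheritance)
  check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                           lo_open = FALSE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
    ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
    if (!ok)
      stop(sprintf("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
                   if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"), call. = FALSE)
    x
  }
  N <- as.integer(check_scalar(N, "N", 2))
  p <- check_scalar(p, "p", 0, 1, TRUE, TRUE)
  delta_theta <- check_scalar(delta_theta, "delta_theta", 0, pi)
  e <- check_scalar(e, "e", 0, 1)
  sigma <- check_scalar(sigma, "sigma", 0)
  d <- check_scalar(d, "d", 0, lo_open = TRUE)
  n_targets <- as.integer(check_scalar(n_targets, "n_targets", 1))
  mu_cont <- check_scalar(mu_cont, "mu_cont", 0, 1)
  delta_mut <- check_scalar(delta_mut, "delta_mut", 0)
  mu_strat <- check_scalar(mu_strat, "mu_strat", 0, 1)
  generations <- as.integer(check_scalar(generations, "generations", 0))
  seed <- as.integer(check_scalar(seed, "seed",
                                  -.Machine$integer.max, .Machine$integer.max))

  n0 <- as.integer(round(N * p))
  if (n0 < 1L || N - n0 < 1L)
    stop("both groups must be non-empty: round(N * p) and N - round(N * p) ",
         "must be at least 1", call. = FALSE)
  if (n_targets > N)
    stop("`n_targets` cannot exceed the population size `N`", call. = FALSE)

  allowed_strategies <- unique(as.character(allowed_strategies))
  if (length(allowed_strategies) == 0L ||
      !all(allowed_strategies %in% c("UT", "CT", "PT")))
    stop("`allowed_strategies` must be a non-empty subset of ",
         "c(\"UT\", \"CT\", \"PT\")", call. = FALSE)
  if (!"UT" %in% allowed_strategies)
    stop("`allowed_strategies` must contain \"UT\": every run starts from ",
         "pure unbiased transmission", call. = FALSE)

  stopifnot(is.logical(parochialism_evolvable), length(parochialism_evolvable) == 1L,
            is.logical(reliance_evolvable), length(reliance_evolvable) == 1L)

  structure(list(
    N = N, p = p, delta_theta = delta_theta, e = e, sigma = sigma, d = d,
    n_targets = n_targets, mu_cont = mu_cont, delta_mut = delta_mut,
    mu_strat = mu_strat, allowed_strategies = allowed_strategies,
    parochialism_evolvable = parochialism_evolvable,
    reliance_evolvable = reliance_evolvable,
    marker_inheritance = marker_inheritance,
    generations = generations, seed = seed
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  N = %d (group 0: %d, group 1: %d), generations = %d, seed = %d\n",
              x$N, round(x$N * x$p), x$N - round(x$N * x$p),
              x$generations, x$seed))
  cat(sprintf("  delta_theta = %.4g, e = %.3g, sigma = %.3g, d = %.3g, n_targets = %d\n",
              x$delta_theta, x$e, x$sigma, x$d, x$n_targets))
  cat(sprintf("  mutation: mu_cont = %.3g (sd %.3g), mu_strat = %.3g\n",
              x$mu_cont, x$delta_mut, x$mu_strat))
  cat(sprintf("  strategies: {%s}; parochialism %s; reliance %s; markers %s\n",
              paste(x$allowed_strategies, collapse = ", "),
              if (x$parochialism_evolvable) "evolvable" else "fixed at 0",
              if (x$reliance_evolvable) "evolvable" else "clamped to 0",
              if (x$marker_inheritance == "reassign")
                "re-assigned at birth" else "inherited"))
  invisible(x)
}

#' Modify a subset of model parameters
#'
#' Returns a new `model_params` object with the named fields replaced and all
#' validation re-run. Used by the sweep runner to apply grid values.
#'
#' @param params A `model_params` object.
#' @param ... Named replacement values (names must be `model_params` fields).
#' @return A new `model_params` object.
#' @examples
#' base <- model_params(N = 100, generations = 10)
#' update_params(base, sigma = 0.8, seed = 42)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  changes <- list(...)
  if (length(changes) == 0L) return(params)
  if (is.null(names(changes)) || any(names(changes) == ""))
    stop("all replacement values must be named", call. = FALSE)
  bad <- setdiff(names(changes), names(unclass(params)))
  if (length(bad) > 0L)
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  fields <- unclass(params)
  fields[names(changes)] <- changes
  do.call(model_params, fields)
}
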