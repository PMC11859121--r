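# Stateless mathematical primitives: optimum placement, the Gaussian fitness
# kernel, individual-learning draws, the social-learning selection rules, and
# trait blending. These are the reference implementations; the compiled
# simulation core mirrors them.

# Coerce a length-2 numeric or an n x 2 matrix to an n x 2 matrix of points.
as_points <- function(x, name = deparse(substitute(x))) {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2L)
    x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 2L)
    stop(sprintf("`%s` must be a length-2 numeric vector or an n x 2 matrix",
                 name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite coordinates", name), call. = FALSE)
  colnames(x) <- c("x", "y")
  x
}

#' Group-specific adaptive optimum on the unit circle
#'
#' The two groups' optimal trait values sit on the unit circle, symmetric
#' about the positive x-axis and subtending angle `delta_theta`: group 0 at
#' polar angle `+delta_theta / 2`, group 1 at `-delta_theta / 2`. At
#' `delta_theta = 0` the optima coincide at (1, 0); at `delta_theta = pi`
#' they are antipodal.
#'
#' @param group Integer vector of group labels in `{0, 1}`.
#' @param delta_theta Angular separation in radians, in `[0, pi]`.
#' @return An `n x 2` matrix of optimum coordinates (columns `x`, `y`), one
#'   row per element of `group`.
#' @examples
#' optimum_position(c(0, 1), pi / 2)
#' @export
optimum_position <- function(group, delta_theta) {
  if (!all(group %in% c(0, 1)))
    stop("`group` must contain only 0 and 1", call. = FALSE)
  if (!is.numeric(delta_theta) || length(delta_theta) != 1L ||
      !is.finite(delta_theta) || delta_theta < 0 || delta_theta > pi)
    stop("`delta_theta` must be a single value in [0, pi]", call. = FALSE)
  ang <- ifelse(group == 0, delta_theta / 2, -delta_theta / 2)
  cbind(x = cos(ang), y = sin(ang))
}

#' Gaussian pay-off of a behavioural trait
#'
#' Pay-off declines with the Euclidean distance between an agent's adopted
#' trait and its group optimum: `exp(-||trait - optimum||^2 / d)`. The
#' denominator `d` controls the intensity of selection; the pay-off is 1 at
#' the optimum and strictly positive everywhere.
#'
#' @param trait,optimum Length-2 numeric vectors or `n x 2` matrices of
#'   trait-space points (recycled row-wise if one has a single row).
#' @param d Selection intensity, a single positive number.
#' @return Numeric vector of pay-offs in `(0, 1]`.
#' @examples
#' gaussian_payoff(c(1, 0), c(1, 0), d = 1)        # 1 at the optimum
#' gaussian_payoff(c(0, 0), c(1, 0), d = 1)        # exp(-1)
#' @export
gaussian_payoff <- function(trait, optimum, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("`d` must be a single positive number", call. = FALSE)
  trait <- as_points(trait)
  optimum <- as_points(optimum)
  if (nrow(trait) != nrow(optimum)) {
    if (nrow(optimum) == 1L) optimum <- optimum[rep(1L, nrow(trait)), , drop = FALSE]
    else if (nrow(trait) == 1L) trait <- trait[rep(1L, nrow(optimum)), , drop = FALSE]
    else stop("`trait` and `optimum` have incompatible numbers of rows",
              call. = FALSE)
  }
  as.vector(exp(-((trait[, 1] - optimum[, 1])^2 +
                    (trait[, 2] - optimum[, 2])^2) / d))
}

#' Individual trial-and-error learning draw
#'
#' Draws trait values from an isotropic bivariate normal distribution centred
#' on the learner's own group optimum, with per-axis standard deviation
#' `sigma` (the individual-learning error). `sigma = 0` returns the optimum
#' exactly.
#'
#' @param optimum A length-2 numeric vector or an `n x 2` matrix of centres
#'   (a single centre is recycled for all `n` draws).
#' @param sigma Per-axis standard deviation, non-negative.
#' @param n Number of draws (defaults to the number of centres supplied).
#' @return An `n x 2` matrix of sampled trait points.
#' @examples
#' set.seed(1)
#' individual_learning_draw(c(1, 0), sigma = 0.3, n = 5)
#' @export
individual_learning_draw <- function(optimum, sigma, n = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  optimum <- as_points(optimum)
  if (is.null(n)) n <- nrow(optimum)
  n <- as.integer(n)
  if (nrow(optimum) == 1L) optimum <- optimum[rep(1L, n), , drop = FALSE]
  if (nrow(optimum) != n)
    stop("`n` must match the number of centres supplied", call. = FALSE)
  cbind(x = as.vector(optimum[, 1]) + stats::rnorm(n, 0, sigma),
        y = as.vector(optimum[, 2]) + stats::rnorm(n, 0, sigma))
}

#' Blend socially and individually learned trait values
#'
#' The trait an agent ultimately adopts is the convex combination of its
#' socially and individually acquired values, weighted per axis by its
#' reliance on social learning `s`:
#' `trait = s * social + (1 - s) * individual`.
#'
#' @param social,individual Length-2 numeric vectors or `n x 2` matrices.
#' @param reliance Social-learning weight(s) in `[0, 1]` (scalar or length
#'   `n`).
#' @return An `n x 2` matrix of blended trait points.
#' @examples
#' blend_traits(c(1, 0), c(0, 0), reliance = 0.5)  # midpoint (0.5, 0)
#' @export
blend_traits <- function(social, individual, reliance) {
  social <- as_points(social)
  individual <- as_points(individual)
  if (nrow(social) != nrow(individual))
    stop("`social` and `individual` must have the same number of rows",
         call. = FALSE)
  if (!is.numeric(reliance) || any(!is.finite(reliance)) ||
      any(reliance < 0) || any(reliance > 1))
    stop("`reliance` must lie in [0, 1]", call. = FALSE)
  cbind(x = as.vector(reliance * social[, 1] +
                        (1 - reliance) * individual[, 1]),
        y = as.vector(reliance * social[, 2] +
                        (1 - reliance) * individual[, 2]))
}

#' Select a socially learned trait value from a set of targets
#'
#' Applies one of the three social learning strategies to a non-empty set of
#' surviving targets:
#' \describe{
#'   \item{UT (unbiased transmission)}{copy a uniformly random target.}
#'   \item{CT (conformist transmission)}{adopt the marginal (componentwise)
#'     median of the targets' traits; for even counts, the per-axis mean of
#'     the two central values. The result need not coincide with any single
#'     target.}
#'   \item{PT (pay-off-biased transmission)}{copy the target with the highest
#'     pay-off, ties broken uniformly at random.}
#' }
#'
#' Callers must route empty target sets to pure individual learning before
#' calling; an empty set here is a contract violation.
#'
#' @param strategy One of `"UT"`, `"CT"`, `"PT"`.
#' @param targets A data frame with numeric columns `trait_x`, `trait_y` and
#'   (for PT) `payoff`; one row per surviving target.
#' @return A length-2 named numeric vector `c(x, y)`.
#' @examples
#' targets <- data.frame(trait_x = c(0, 1, 2), trait_y = c(1, 0, 2),
#'                       payoff = c(0.5, 0.9, 0.7))
#' select_social_trait("CT", targets)  # marginal median (1, 1)
#' select_social_trait("PT", targets)  # trait of the payoff-0.9 target
#' @export
select_social_trait <- function(strategy, targets) {
  strategy <- match.arg(strategy, c("UT", "CT", "PT"))
  if (!is.data.frame(targets) || nrow(targets) == 0L)
    stop("`targets` must be a non-empty data frame; empty target sets must ",
         "fall back to individual learning before reaching this point",
         call. = FALSE)
  if (strategy == "UT") {
    i <- sample.int(nrow(targets), 1L)
    c(x = targets$trait_x[i], y = targets$trait_y[i])
  } else if (strategy == "CT") {
    c(x = stats::median(targets$trait_x), y = stats::median(targets$trait_y))
  } else {
    best <- which(targets$payoff == max(targets$payoff))
    i <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    c(x = targets$trait_x[i], y = targets$trait_y[i])
  }
}
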