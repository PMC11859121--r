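# Per-generation demographic and learning procedures: initialization,
# pay-off-proportional reproduction with mutation, model choice with
# parochial filtering, and the learning stage. These pure-R functions are the
# reference engine; run(engine = "cpp") executes the same procedure compiled.

strategy_levels <- c("UT", "CT", "PT")

#' Assign an identity marker given group membership
#'
#' With probability `e` the agent receives the marker matching its group
#' (markers are reliable cues); otherwise the marker is drawn from the
#' population marker frequencies — marker 0 with probability `p`, marker 1
#' with probability `1 - p` — keeping overall marker frequencies consistent
#' across reliability conditions. Hence
#' `P(marker == group | group = 0) = e + (1 - e) * p`.
#'
#' @param group Integer vector of group labels in `{0, 1}`.
#' @param e Marker reliability in `[0, 1]`.
#' @param p Proportion of the population in group 0 (the marker-0 frequency).
#' @return Integer vector of markers, same length as `group`.
#' @examples
#' set.seed(1)
#' table(assign_marker(rep(0L, 1000), e = 0.5, p = 0.5))
#' @export
assign_marker <- function(group, e, p) {
  if (!all(group %in% c(0, 1))) stop("`group` must contain only 0 and 1",
                                     call. = FALSE)
  stopifnot(e >= 0, e <= 1, p >= 0, p <= 1)
  n <- length(group)
  faithful <- stats::runif(n) < e
  random_marker <- ifelse(stats::runif(n) < p, 0L, 1L)
  as.integer(ifelse(faithful, group, random_marker))
}

#' Select a parent by pay-off-proportional rejection sampling
#'
#' A candidate is drawn uniformly from the group and reproduces with
#' probability `payoff / max(payoffs)`; the draw repeats until acceptance.
#' The stationary selection probability of member `i` is
#' `w_i / sum(w)`, i.e. exact pay-off-proportional selection.
#'
#' @param payoffs Numeric vector of strictly positive pay-offs for one
#'   group's parent generation.
#' @return The integer index of the selected parent.
#' @examples
#' set.seed(1)
#' table(replicate(1000, select_parent(c(1, 0.5))))  # approx 2:1
#' @export
select_parent <- function(payoffs) {
  k <- length(payoffs)
  if (k == 0L) stop("cannot select a parent from an empty group", call. = FALSE)
  if (any(!is.finite(payoffs)) || any(payoffs <= 0))
    stop("all pay-offs must be finite and strictly positive", call. = FALSE)
  if (k == 1L) return(1L)
  wmax <- max(payoffs)
  repeat {
    j <- sample.int(k, 1L)
    if (stats::runif(1) * wmax < payoffs[j]) return(j)
  }
}

#' Mutate a continuous heritable trait
#'
#' With probability `1 - mu_cont` the value is inherited faithfully;
#' otherwise a zero-mean normal perturbation with standard deviation
#' `delta_mut` is added and the result truncated to remain in `[0, 1]`.
#' Vectorized over `values`.
#'
#' @param values Numeric vector of trait values in `[0, 1]`.
#' @param mu_cont Mutation probability in `[0, 1]`.
#' @param delta_mut Mutation standard deviation, non-negative.
#' @return Numeric vector of offspring trait values in `[0, 1]`.
#' @export
mutate_continuous <- function(values, mu_cont, delta_mut) {
  stopifnot(all(values >= 0), all(values <= 1),
            mu_cont >= 0, mu_cont <= 1, delta_mut >= 0)
  n <- length(values)
  hit <- stats::runif(n) < mu_cont
  if (any(hit))
    values[hit] <- values[hit] + stats::rnorm(sum(hit), 0, delta_mut)
  pmin(pmax(values, 0), 1)
}

#' Inherit a social learning strategy with mutation
#'
#' With probability `1 - mu_strat` the offspring keeps the parent's strategy;
#' otherwise it adopts a strategy uniformly at random from the allowed set
#' (which includes the parent's own strategy, so a "mutation" may reproduce
#' it). Vectorized over `parent_strategy`.
#'
#' @param parent_strategy Character vector of parent strategies, each in
#'   `allowed`.
#' @param mu_strat Strategy mutation probability in `[0, 1]`.
#' @param allowed Non-empty character vector of allowed strategies.
#' @return Character vector of offspring strategies.
#' @export
inherit_strategy <- function(parent_strategy, mu_strat, allowed) {
  if (length(allowed) == 0L)
    stop("`allowed` must be a non-empty strategy set", call. = FALSE)
  stopifnot(all(parent_strategy %in% allowed), mu_strat >= 0, mu_strat <= 1)
  n <- length(parent_strategy)
  hit <- stats::runif(n) < mu_strat
  if (any(hit))
    parent_strategy[hit] <- allowed[sample.int(length(allowed), sum(hit),
                                               replace = TRUE)]
  parent_strategy
}

new_population <- function(df, generation) {
  attr(df, "generation") <- as.integer(generation)
  class(df) <- c("population", "data.frame")
  df
}

#' Initialize the founder generation
#'
#' Creates a population of `round(N * p)` group-0 agents and the remainder in
#' group 1 (deterministic counts, constant thereafter). All founders are
#' non-parochial pure individual learners: reliance 0, parochialism 0,
#' strategy UT. Markers are assigned via [assign_marker()], traits drawn by
#' [individual_learning_draw()] around each agent's own optimum, and pay-offs
#' computed immediately.
#'
#' @param params A [model_params()] object.
#' @return A `population`: a data frame with one row per agent and columns
#'   `group`, `marker`, `parochialism`, `reliance`, `strategy`, `trait_x`,
#'   `trait_y`, `payoff`, carrying a `generation` attribute (0).
#' @examples
#' set.seed(1)
#' pop <- init_population(model_params(N = 10, generations = 0))
#' head(pop)
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n0 <- as.integer(round(params$N * params$p))
  group <- c(rep(0L, n0), rep(1L, params$N - n0))
  marker <- assign_marker(group, params$e, params$p)
  opt <- optimum_position(group, params$delta_theta)
  trait <- individual_learning_draw(opt, params$sigma)
  payoff <- gaussian_payoff(trait, opt, params$d)
  new_population(data.frame(
    group = group, marker = marker,
    parochialism = 0, reliance = 0, strategy = "UT",
    trait_x = trait[, 1], trait_y = trait[, 2], payoff = payoff,
    stringsAsFactors = FALSE
  ), generation = 0L)
}

#' Produce the next generation by pay-off-proportional reproduction
#'
#' Each group produces a number of offspring equal to its current size, so
#' both the population size and the relative group sizes stay constant. Every
#' offspring has one parent, selected from its own group via
#' [select_parent()]. The offspring copies its parent's group; its marker is
#' re-assigned at birth via the `e` rule (or copied verbatim when
#' `marker_inheritance = "inherit"`); reliance and parochialism pass through
#' [mutate_continuous()] (parochialism only when `parochialism_evolvable`,
#' reliance only when `reliance_evolvable`); the strategy passes through
#' [inherit_strategy()]. Traits and pay-offs are left unset (`NA`) until the
#' learning stage.
#'
#' @param parents A `population` with computed pay-offs.
#' @param params A [model_params()] object.
#' @return A `population` of unevaluated offspring with a `parent_index`
#'   column giving each offspring's parent row in `parents`.
#' @export
reproduce <- function(parents, params) {
  stopifnot(inherits(params, "model_params"), is.data.frame(parents))
  parent_index <- integer(nrow(parents))
  for (g in c(0L, 1L)) {
    idx <- which(parents$group == g)
    w <- parents$payoff[idx]
    parent_index[idx] <- idx[vapply(idx, function(i) select_parent(w),
                                    integer(1))]
  }
  group <- parents$group  # offspring slots mirror parental group layout
  marker <- if (params$marker_inheritance == "reassign")
    assign_marker(group, params$e, params$p)
  else
    parents$marker[parent_index]
  reliance <- parents$reliance[parent_index]
  if (params$reliance_evolvable)
    reliance <- mutate_continuous(reliance, params$mu_cont, params$delta_mut)
  parochialism <- parents$parochialism[parent_index]
  if (params$parochialism_evolvable)
    parochialism <- mutate_continuous(parochialism, params$mu_cont,
                                      params$delta_mut)
  strategy <- inherit_strategy(parents$strategy[parent_index],
                               params$mu_strat, params$allowed_strategies)
  new_population(data.frame(
    group = group, marker = marker,
    parochialism = parochialism, reliance = reliance, strategy = strategy,
    trait_x = NA_real_, trait_y = NA_real_, payoff = NA_real_,
    parent_index = parent_index, stringsAsFactors = FALSE
  ), generation = attr(parents, "generation", exact = TRUE) + 1L)
}

#' Sample and parochially filter learning targets
#'
#' The focal agent observes `n_targets` agents sampled uniformly without
#' replacement from the entire parent generation (both groups), then excludes
#' each target that does not display its own marker independently with
#' probability equal to its parochialism. Same-marker targets are always
#' retained. A highly parochial agent may be left with zero targets, in which
#' case it must rely exclusively on individual learning.
#'
#' @param focal A single-row data frame (or list) with fields `marker` and
#'   `parochialism`.
#' @param parents The parent `population`.
#' @param params A [model_params()] object.
#' @return Integer vector of retained row indices into `parents` (possibly
#'   empty).
#' @export
choose_and_filter_targets <- function(focal, parents, params) {
  n_avail <- nrow(parents)
  if (params$n_targets > n_avail)
    stop("`n_targets` exceeds the parent generation size", call. = FALSE)
  cand <- sample.int(n_avail, params$n_targets)
  unlike <- parents$marker[cand] != focal$marker
  drop <- unlike
  if (any(unlike))
    drop[unlike] <- stats::runif(sum(unlike)) < focal$parochialism
  cand[!drop]
}

#' Acquire a trait value through social and individual learning
#'
#' If the surviving target set is empty the agent relies exclusively on
#' individual learning and its trait is the [individual_learning_draw()]
#' alone. Otherwise the socially selected value ([select_social_trait()]
#' applied with the focal agent's strategy) is blended with an individual
#' draw via [blend_traits()], weighted by the agent's reliance.
#'
#' @param focal A single-row data frame (or list) with fields `group`,
#'   `reliance`, `strategy`.
#' @param targets Data frame of surviving targets (possibly 0 rows), with
#'   columns `trait_x`, `trait_y`, `payoff`.
#' @param params A [model_params()] object.
#' @return A length-2 named numeric vector `c(x, y)`: the adopted trait.
#' @export
learn <- function(focal, targets, params) {
  opt <- optimum_position(focal$group, params$delta_theta)
  indiv <- individual_learning_draw(opt, params$sigma)[1L, ]
  if (is.null(targets) || nrow(targets) == 0L)
    return(indiv)
  social <- select_social_trait(focal$strategy, targets)
  blend_traits(social, indiv, focal$reliance)[1L, ]
}

#' Advance a population by one full generation (reference engine)
#'
#' Runs the four per-generation stages in order: (1) reproduction via
#' [reproduce()], (2) model choice via [choose_and_filter_targets()],
#' (3) learning via [learn()], and (4) pay-off acquisition via
#' [gaussian_payoff()] against each agent's own group optimum. The parent
#' generation is not referenced afterwards.
#'
#' This is the pure-R reference implementation used for testing and small
#' populations; [run()] defaults to the compiled engine, which executes the
#' identical procedure.
#'
#' @param parents A fully evaluated `population` (traits and pay-offs set).
#' @param params A [model_params()] object.
#' @return The evaluated offspring `population`.
#' @export
step_generation <- function(parents, params) {
  offspring <- reproduce(parents, params)
  n <- nrow(offspring)
  traits <- matrix(NA_real_, n, 2L)
  # plain vectors avoid repeated data-frame row extraction in the agent loop
  p_trait_x <- parents$trait_x
  p_trait_y <- parents$trait_y
  p_payoff <- parents$payoff
  for (i in seq_len(n)) {
    focal <- list(group = offspring$group[i], marker = offspring$marker[i],
                  parochialism = offspring$parochialism[i],
                  reliance = offspring$reliance[i],
                  strategy = offspring$strategy[i])
    keep <- choose_and_filter_targets(focal, parents, params)
    targets <- data.frame(trait_x = p_trait_x[keep],
                          trait_y = p_trait_y[keep],
                          payoff = p_payoff[keep])
    traits[i, ] <- learn(focal, targets, params)
  }
  offspring$trait_x <- traits[, 1]
  offspring$trait_y <- traits[, 2]
  opt <- optimum_position(offspring$group, params$delta_theta)
  offspring$payoff <- gaussian_payoff(traits, opt, params$d)
  offspring$parent_index <- NULL
  offspring
}
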