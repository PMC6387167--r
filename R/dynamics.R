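#' Action selection parameters
#'
#' Weights of the log-linear action selection function. Two features are
#' registered: \code{f1}, the (negated) exact goal distance on a reachable
#' state graph, and \code{f2}, the (negated) count of unsatisfied goal
#' predicates, a cheap landmark-style surrogate. When no state graph is
#' supplied to the selection function, \code{f1} falls back to \code{f2}'s
#' value; when the goal is unreachable from a successor state, \code{f1}
#' falls back to \code{f2}'s value minus \code{unreachable_penalty}, keeping
#' the support positive so deviations from the optimal sequence stay
#' possible.
#'
#' @param lambda1,lambda2 Feature weights (defaults 1; the influence of each
#'   heuristic is a free modelling choice).
#' @param unreachable_penalty Large constant subtracted from the fallback
#'   feature value for unreachable goals.
#' @param hazard_mode Passed to [termination_prob()].
#' @return Object of class \code{ccbm_params}.
#' @export
selection_params <- function(lambda1 = 1, lambda2 = 1, unreachable_penalty = 100,
                             hazard_mode = c("printed", "standard")) {
  stopifnot(is.finite(lambda1), is.finite(lambda2))
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 unreachable_penalty = unreachable_penalty,
                 hazard_mode = match.arg(hazard_mode)),
            class = "ccbm_params")
}

#' Goal prior
#'
#' Uniform, or informed: the target goal receives \code{factor} times the
#' weight of each other goal before normalisation (so with g goals in total
#' and the default factor 2, the target's prior mass is 2/(g+1)).
#'
#' @param problem A \code{ccbm_problem}.
#' @param mode \code{"uniform"} or \code{"informed"}.
#' @param target Goal name or index (required for informed mode).
#' @param factor Relative weight of the target goal.
#' @return Named probability vector over the problem's goals.
#' @export
goal_prior <- function(problem, mode = c("uniform", "informed"), target = NULL,
                       factor = 2) {
  mode <- match.arg(mode)
  gn <- names(problem$goals)
  stopifnot(length(gn) > 0L)
  w <- stats::setNames(rep(1, length(gn)), gn)
  if (mode == "informed") {
    if (is.null(target)) stop("informed priors need a target goal", call. = FALSE)
    w[resolve_goal(problem, target)] <- factor
  }
  w / sum(w)
}

#' CCBM state tuple
#'
#' The structured filter state: current action \code{a} (ground action
#' index), termination flag \code{d}, goal \code{g} (goal index), world
#' state \code{s}, start time \code{u} of the current action and current
#' time \code{v} (the discrete window index).
#'
#' @param a,d,g,s,u,v Components as above.
#' @return Object of class \code{ccbm_state}.
#' @export
ccbm_state <- function(a, d, g, s, u, v) {
  stopifnot(u <= v)
  structure(list(a = as.integer(a), d = isTRUE(d), g = as.integer(g),
                 s = s, u = as.integer(u), v = as.integer(v)),
            class = "ccbm_state")
}

#' Action execution model
#'
#' Deterministic world update: if the previous action terminated, the newly
#' selected action's effect is applied; otherwise the world is unchanged.
#' All probability mass is 0/1.
#'
#' @param problem Grounded problem.
#' @param prev_world Named logical world state.
#' @param action Ground action index.
#' @param terminated Termination flag d.
#' @return The successor world state.
#' @export
action_execution <- function(problem, prev_world, action, terminated) {
  problem <- ensure_ground(problem)
  if (!terminated) return(prev_world)
  apply_action(prev_world, problem$ground$actions[[action]])
}

#' Action start time model
#'
#' @param terminated Termination flag d.
#' @param prev_start Previous start time u.
#' @param now Current time v.
#' @return \code{now} if terminated, else \code{prev_start}.
#' @export
start_time_update <- function(terminated, prev_start, now) {
  stopifnot(prev_start <= now)
  if (terminated) now else prev_start
}

#' Goal persistence model
#'
#' Once selected (at t = 0, from the goal prior) the goal never changes.
#'
#' @param prev_goal Previous goal index.
#' @return The same goal index.
#' @export
goal_persistence <- function(prev_goal) prev_goal

# feature matrix for candidate actions (rows) in world `state` toward `goal`
selection_features <- function(problem, cand, goal, state, params, graph = NULL) {
  f2 <- vapply(cand, function(ai) {
    s2 <- apply_action(state, problem$ground$actions[[ai]], check = FALSE)
    -as.numeric(unsatisfied_goal_predicates(problem, s2, goal))
  }, numeric(1))
  if (is.null(graph)) {
    f1 <- f2
  } else {
    f1 <- vapply(seq_along(cand), function(i) {
      s2 <- apply_action(state, problem$ground$actions[[cand[i]]], check = FALSE)
      d <- goal_distance(problem, s2, goal, graph)
      if (is.finite(d)) -d else f2[i] - params$unreachable_penalty
    }, numeric(1))
  }
  cbind(f1 = f1, f2 = f2)
}

#' Action selection distribution
#'
#' The log-linear (softmax) distribution over actions applicable in the
#' previous world state:
#' \deqn{\gamma(a) \propto \exp(\lambda_1 f_1(a) + \lambda_2 f_2(a))}
#' where the features are evaluated on the successor state a(s). Support is
#' exactly the applicable actions. This is the d = true branch of the action
#' selection model; when the previous action has not terminated it is kept
#' with probability 1 and this function is not consulted.
#'
#' @param problem Grounded problem.
#' @param goal Goal name or index.
#' @param prev_world World state in which the new action is selected.
#' @param params \code{ccbm_params}.
#' @param graph Optional \code{ccbm_state_graph} enabling the exact goal
#'   distance feature.
#' @param prev_action Previous ground action index (part of the model
#'   signature; unused by the two default features).
#' @return List with \code{actions} (ground action indices) and \code{prob}.
#' @export
action_selection_dist <- function(problem, goal, prev_world, params,
                                  graph = NULL, prev_action = NULL) {
  problem <- ensure_ground(problem)
  goal <- resolve_goal(problem, goal)
  cand <- applicable_actions(problem, prev_world)
  if (length(cand) == 0L)
    stop("dead end: no applicable action (add an always-applicable action)", call. = FALSE)
  feats <- selection_features(problem, cand, goal, prev_world, params, graph)
  score <- params$lambda1 * feats[, "f1"] + params$lambda2 * feats[, "f2"]
  score <- score - max(score)  # softmax stability & shift invariance
  p <- exp(score); p <- p / sum(p)
  list(actions = cand, prob = unname(p))
}

#' Initial CCBM state distribution
#'
#' At t = 1 the goal is drawn from the prior, the first action is selected
#' from the initial world state by the action selection function, its effect
#' is applied, and the start time is set to 1.
#'
#' @param problem Grounded problem.
#' @param goal Goal index for this trajectory.
#' @param params \code{ccbm_params}.
#' @param graph Optional state graph.
#' @return List of \code{ccbm_state} and matching \code{prob}.
#' @export
initial_state_dist <- function(problem, goal, params, graph = NULL) {
  problem <- ensure_ground(problem)
  sel <- action_selection_dist(problem, goal, problem$ground$s0, params, graph)
  states <- lapply(sel$actions, function(ai)
    ccbm_state(a = ai, d = TRUE, g = resolve_goal(problem, goal),
               s = apply_action(problem$ground$s0, problem$ground$actions[[ai]]),
               u = 1L, v = 1L))
  list(states = states, prob = sel$prob)
}

#' Sample one CCBM transition
#'
#' Composes the five sub-models in dependency order: draw the termination
#' flag from the duration hazard, persist the goal, select (or keep) the
#' action, execute its effect, and update the start time.
#'
#' @param problem Grounded problem.
#' @param state Current \code{ccbm_state}.
#' @param params \code{ccbm_params}.
#' @param durations \code{ccbm_durations}.
#' @param graph Optional state graph.
#' @param seed Optional integer seed for reproducibility.
#' @return The successor \code{ccbm_state} at time v + 1.
#' @export
sample_transition <- function(problem, state, params, durations, graph = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  problem <- ensure_ground(problem)
  now <- state$v + 1L
  h <- termination_prob(durations, state$a, state$u, state$v, now,
                        mode = params$hazard_mode)
  d <- stats::runif(1) < h
  g <- goal_persistence(state$g)
  if (d) {
    sel <- action_selection_dist(problem, g, state$s, params, graph,
                                 prev_action = state$a)
    a <- sel$actions[sample.int(length(sel$actions), 1L, prob = sel$prob)]
  } else {
    a <- state$a
  }
  s <- action_execution(problem, state$s, a, d)
  u <- start_time_update(d, state$u, now)
  ccbm_state(a = a, d = d, g = g, s = s, u = u, v = now)
}

#' Log-probability of one CCBM transition
#'
#' Sum of the five sub-model log terms; \code{-Inf} for causally impossible
#' transitions (goal change, world change without termination, inapplicable
#' action, inconsistent start time or clock).
#'
#' @param problem Grounded problem.
#' @param prev,next_state Consecutive \code{ccbm_state}s.
#' @param params \code{ccbm_params}.
#' @param durations \code{ccbm_durations}.
#' @param graph Optional state graph.
#' @return Log-probability.
#' @export
transition_logprob <- function(problem, prev, next_state, params, durations,
                               graph = NULL) {
  problem <- ensure_ground(problem)
  if (next_state$v != prev$v + 1L) return(-Inf)
  if (next_state$g != prev$g) return(-Inf)
  h <- termination_prob(durations, prev$a, prev$u, prev$v, next_state$v,
                        mode = params$hazard_mode)
  if (next_state$d) {
    if (h <= 0) return(-Inf)
    sel <- action_selection_dist(problem, prev$g, prev$s, params, graph,
                                 prev_action = prev$a)
    i <- match(next_state$a, sel$actions)
    if (is.na(i)) return(-Inf)
    expected_s <- apply_action(prev$s, problem$ground$actions[[next_state$a]],
                               check = FALSE)
    if (!identical(unname(next_state$s), unname(expected_s))) return(-Inf)
    if (next_state$u != next_state$v) return(-Inf)
    log(h) + log(sel$prob[i])
  } else {
    if (h >= 1) return(-Inf)
    if (next_state$a != prev$a) return(-Inf)
    if (!identical(unname(next_state$s), unname(prev$s))) return(-Inf)
    if (next_state$u != prev$u) return(-Inf)
    log1p(-h)
  }
}
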