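# Independent brute-force oracles.  They enumerate complete trajectories /
# state paths and sum their probabilities directly, sharing none of the
# filters' recursion code.

# all one-step successors of a ccbm_state with their probabilities,
# composed from the primitive sub-models
oracle_successors <- function(problem, state, params, durations, graph = NULL) {
  now <- state$v + 1L
  h <- termination_prob(durations, state$a, state$u, state$v, now,
                        mode = params$hazard_mode)
  out <- list()
  if (h < 1) {
    out[[1]] <- list(state = ccbm_state(state$a, FALSE, state$g, state$s,
                                        state$u, now),
                     prob = 1 - h)
  }
  if (h > 0) {
    sel <- action_selection_dist(problem, state$g, state$s, params, graph,
                                 prev_action = state$a)
    for (i in seq_along(sel$actions)) {
      ai <- sel$actions[i]
      s2 <- apply_action(state$s, problem$ground$actions[[ai]])
      out[[length(out) + 1L]] <- list(
        state = ccbm_state(ai, TRUE, state$g, s2, now, now),
        prob = h * sel$prob[i])
    }
  }
  out
}

# filtered class/goal marginals at every step by exhaustive enumeration of
# all trajectory prefixes, each weighted by process probability times the
# observation likelihood of every step it covers
oracle_filter <- function(problem, params, durations, lik, prior, graph = NULL) {
  classes <- sort(unique(problem$ground$action_class))
  goals <- names(problem$goals)
  T_len <- nrow(lik)
  cm <- matrix(0, T_len, length(classes), dimnames = list(NULL, classes))
  gm <- matrix(0, T_len, length(goals), dimnames = list(NULL, goals))
  # trajectories as lists of (state, weight); grown step by step
  trajs <- list()
  for (gi in which(prior > 0)) {
    init <- initial_state_dist(problem, gi, params, graph)
    for (i in seq_along(init$states)) {
      st <- init$states[[i]]
      w <- prior[gi] * init$prob[i] *
        lik[1, problem$ground$action_class[st$a]]
      trajs[[length(trajs) + 1L]] <- list(state = st, weight = w)
    }
  }
  tot <- sum(vapply(trajs, `[[`, numeric(1), "weight"))
  for (tr in trajs) {
    cl <- problem$ground$action_class[tr$state$a]
    cm[1, cl] <- cm[1, cl] + tr$weight / tot
    gm[1, goals[tr$state$g]] <- gm[1, goals[tr$state$g]] + tr$weight / tot
  }
  for (t in seq_len(T_len)[-1]) {
    nxt <- list()
    for (tr in trajs) {
      if (tr$weight == 0) next
      for (succ in oracle_successors(problem, tr$state, params, durations, graph)) {
        w <- tr$weight * succ$prob *
          lik[t, problem$ground$action_class[succ$state$a]]
        nxt[[length(nxt) + 1L]] <- list(state = succ$state, weight = w)
      }
    }
    trajs <- nxt
    tot <- sum(vapply(trajs, `[[`, numeric(1), "weight"))
    for (tr in trajs) {
      cl <- problem$ground$action_class[tr$state$a]
      cm[t, cl] <- cm[t, cl] + tr$weight / tot
      gm[t, goals[tr$state$g]] <- gm[t, goals[tr$state$g]] + tr$weight / tot
    }
  }
  list(class_marginal = cm, goal_marginal = gm)
}

# exhaustive path-sum filtering for a class HMM
oracle_hmm_filter <- function(spec, lik) {
  K <- length(spec$states)
  T_len <- nrow(lik)
  post <- matrix(0, T_len, K, dimnames = list(NULL, spec$states))
  for (t in seq_len(T_len)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), t)))
    w <- apply(paths, 1, function(path) {
      p <- spec$prior[path[1]] * lik[1, spec$states[path[1]]]
      if (t >= 2) for (s in 2:t) {
        p <- p * spec$transition[path[s - 1], path[s]] * lik[s, spec$states[path[s]]]
      }
      p
    })
    for (k in seq_len(K)) post[t, k] <- sum(w[paths[, t] == k])
    post[t, ] <- post[t, ] / sum(post[t, ])
  }
  post
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
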