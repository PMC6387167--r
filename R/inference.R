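# Bayesian filtering over the structured CCBM state space.
#
# The filter state is (action a, goal g, world state s, elapsed time e),
# where e = v - u collapses the unbounded start-time variable to the elapsed
# time since the current action started, capped at `elapsed_cap` (the hazard
# is then evaluated at the cap).  When every action has a geometric duration
# the hazard is constant in e and the cap degenerates to 1.

new_state_registry <- function(problem) {
  env <- new.env(parent = emptyenv())
  reg <- list(env = env, states = list())
  reg
}

# returns list(reg, sid)
registry_add <- function(reg, state) {
  k <- state_key(state)
  sid <- get0(k, envir = reg$env, inherits = FALSE)
  if (is.null(sid)) {
    reg$states[[length(reg$states) + 1L]] <- state
    sid <- length(reg$states)
    assign(k, sid, envir = reg$env)
  }
  list(reg = reg, sid = sid)
}

check_lik <- function(problem, lik) {
  stopifnot(is.matrix(lik), !is.null(colnames(lik)))
  need <- unique(problem$ground$action_class)
  missing <- setdiff(need, colnames(lik))
  if (length(missing))
    stop(sprintf("likelihood matrix lacks class column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

check_prior <- function(problem, prior) {
  gn <- names(problem$goals)
  stopifnot(!is.null(names(prior)), all(names(prior) %in% gn))
  full <- stats::setNames(rep(0, length(gn)), gn)
  full[names(prior)] <- prior
  if (abs(sum(full) - 1) > 1e-9) stop("goal prior must sum to 1", call. = FALSE)
  full
}

posterior_skeleton <- function(problem, T_len) {
  classes <- sort(unique(problem$ground$action_class))
  goals <- names(problem$goals)
  list(class_marginal = matrix(0, T_len, length(classes), dimnames = list(NULL, classes)),
       goal_marginal = matrix(0, T_len, length(goals), dimnames = list(NULL, goals)))
}

#' Exact forward filter over the CCBM state space
#'
#' Deterministic forward recursion: predict with the structured transition
#' model (duration hazard, goal persistence, log-linear action selection,
#' deterministic effects), update by weighting each state with the observed
#' action-class distribution, renormalise.
#'
#' @param problem Grounded \code{ccbm_problem}.
#' @param params \code{ccbm_params}.
#' @param durations \code{ccbm_durations}.
#' @param lik Matrix (time steps x action classes) of observation weights,
#'   e.g. from [class_distribution()].
#' @param prior Named goal prior (see [goal_prior()]); goals with zero mass
#'   are excluded from the hypothesis space.
#' @param graph Optional state graph enabling the exact goal-distance
#'   feature.
#' @param elapsed_cap Maximum tracked elapsed time (bounds the state space).
#' @param max_support Abort (condition class \code{ccbm_cap_error},
#'   suggesting [particle_filter()]) if the filtered support exceeds this.
#' @param prune Drop support states whose posterior weight falls below this
#'   threshold after each update (then renormalise).  The default 1e-12
#'   introduces error far below the filter's 1e-9 verification tolerance
#'   while keeping the support tractable; set 0 for the fully exact
#'   recursion.
#' @return Object of class \code{ccbm_posterior} with per-step class and
#'   goal marginals and the final-step support.
#' @export
exact_filter <- function(problem, params, durations, lik, prior, graph = NULL,
                         elapsed_cap = 30L, max_support = 2e5, prune = 1e-12) {
  problem <- ensure_ground(problem)
  check_lik(problem, lik)
  prior <- check_prior(problem, prior)
  if (all(durations$memoryless)) elapsed_cap <- 1L
  T_len <- nrow(lik)
  classes_of <- problem$ground$action_class
  out <- posterior_skeleton(problem, T_len)

  reg <- new_state_registry(problem)
  hmemo <- new.env(parent = emptyenv())
  selmemo <- new.env(parent = emptyenv())

  hazard <- function(a, e) {
    k <- paste(a, e)
    v <- get0(k, envir = hmemo, inherits = FALSE)
    if (is.null(v)) {
      v <- termination_prob(durations, a, 0L, e, e + 1L, mode = params$hazard_mode)
      assign(k, v, envir = hmemo)
    }
    v
  }
  selection <- function(g, sid) {
    k <- paste(g, sid)
    v <- get0(k, envir = selmemo, inherits = FALSE)
    if (is.null(v)) {
      s <- reg$states[[sid]]
      sel <- action_selection_dist(problem, g, s, params, graph)
      succ <- integer(length(sel$actions))
      for (i in seq_along(sel$actions)) {
        s2 <- apply_action(s, problem$ground$actions[[sel$actions[i]]], check = FALSE)
        r <- registry_add(reg, s2); reg <<- r$reg; succ[i] <- r$sid
      }
      v <- list(actions = sel$actions, prob = sel$prob, succ = succ)
      assign(k, v, envir = selmemo)
    }
    v
  }
  aggregate_rows <- function(a, g, sid, e, w) {
    key <- paste(a, g, sid, e, sep = "|")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "|", fixed = TRUE)
    m <- matrix(as.integer(unlist(parts)), ncol = 4L, byrow = TRUE)
    ord <- order(m[, 1], m[, 2], m[, 3], m[, 4])  # deterministic support order
    list(a = m[ord, 1], g = m[ord, 2], sid = m[ord, 3], e = m[ord, 4],
         w = as.numeric(agg)[ord])
  }
  record <- function(t, sup) {
    cm <- rowsum(sup$w, classes_of[sup$a])
    out$class_marginal[t, rownames(cm)] <<- as.numeric(cm)
    gm <- rowsum(sup$w, names(problem$goals)[sup$g])
    out$goal_marginal[t, rownames(gm)] <<- as.numeric(gm)
  }

  # t = 1
  a <- integer(0); g <- integer(0); sid <- integer(0); e <- integer(0); w <- numeric(0)
  for (gi in which(prior > 0)) {
    init <- initial_state_dist(problem, gi, params, graph)
    for (i in seq_along(init$states)) {
      st <- init$states[[i]]
      r <- registry_add(reg, st$s); reg <- r$reg
      a <- c(a, st$a); g <- c(g, gi); sid <- c(sid, r$sid); e <- c(e, 0L)
      w <- c(w, prior[gi] * init$prob[i])
    }
  }
  sup <- aggregate_rows(a, g, sid, e, w)
  sup$w <- sup$w * lik[1, classes_of[sup$a]]
  if (sum(sup$w) <= 0)
    stop("observation degeneracy at step 1: all state weights are zero", call. = FALSE)
  sup$w <- sup$w / sum(sup$w)
  record(1L, sup)

  for (t in seq_len(T_len)[-1]) {
    hk <- paste(sup$a, sup$e)
    uk <- unique(hk)
    hv <- vapply(strsplit(uk, " ", fixed = TRUE), function(p)
      hazard(as.integer(p[1]), as.integer(p[2])), numeric(1))
    h <- hv[match(hk, uk)]
    # continue branch
    keep <- sup$w * (1 - h) > 0
    parts_a <- list(sup$a[keep]); parts_g <- list(sup$g[keep])
    parts_sid <- list(sup$sid[keep]); parts_e <- list(pmin(sup$e[keep] + 1L, elapsed_cap))
    parts_w <- list((sup$w * (1 - h))[keep])
    # termination branch: states sharing (g, sid) share the successor law
    tw <- sup$w * h
    ti <- which(tw > 0)
    if (length(ti)) {
      gk <- paste(sup$g[ti], sup$sid[ti])
      wsum <- rowsum(tw[ti], gk)
      for (j in seq_len(nrow(wsum))) {
        parts <- strsplit(rownames(wsum)[j], " ", fixed = TRUE)[[1]]
        gi <- as.integer(parts[1]); si <- as.integer(parts[2])
        sel <- selection(gi, si)
        k <- length(sel$actions)
        parts_a[[length(parts_a) + 1L]] <- sel$actions
        parts_g[[length(parts_g) + 1L]] <- rep(gi, k)
        parts_sid[[length(parts_sid) + 1L]] <- sel$succ
        parts_e[[length(parts_e) + 1L]] <- rep(0L, k)
        parts_w[[length(parts_w) + 1L]] <- wsum[j] * sel$prob
      }
    }
    sup <- aggregate_rows(unlist(parts_a), unlist(parts_g), unlist(parts_sid),
                          unlist(parts_e), unlist(parts_w))
    if (length(sup$a) > max_support) {
      cond <- structure(class = c("ccbm_cap_error", "error", "condition"),
                        list(message = sprintf(
                          "filter support exceeded %d at step %d; use particle_filter()",
                          max_support, t), call = sys.call(-1)))
      stop(cond)
    }
    sup$w <- sup$w * lik[t, classes_of[sup$a]]
    if (sum(sup$w) <= 0)
      stop(sprintf("observation degeneracy at step %d: all state weights are zero", t),
           call. = FALSE)
    sup$w <- sup$w / sum(sup$w)
    if (prune > 0 && any(sup$w < prune)) {
      keep <- sup$w >= prune
      sup <- lapply(sup, `[`, keep)
      sup$w <- sup$w / sum(sup$w)
    }
    record(t, sup)
  }

  structure(list(class_marginal = out$class_marginal,
                 goal_marginal = out$goal_marginal,
                 classes = colnames(out$class_marginal),
                 goals = colnames(out$goal_marginal),
                 method = "exact", support = sup),
            class = "ccbm_posterior")
}

#' Particle filter over the CCBM state space
#'
#' Sequential importance resampling with systematic resampling when the
#' effective sample size drops below \code{ess_frac * n}.  Reproducible
#' under a fixed seed; converges to [exact_filter()] marginals as
#' \code{n_particles} grows.
#'
#' @inheritParams exact_filter
#' @param n_particles Number of particles (>= 1).
#' @param seed Optional integer seed.
#' @param ess_frac Resampling threshold as a fraction of \code{n_particles}.
#' @return Object of class \code{ccbm_posterior}.
#' @export
particle_filter <- function(problem, params, durations, lik, prior,
                            n_particles = 1000L, seed = NULL, graph = NULL,
                            elapsed_cap = 30L, ess_frac = 0.5) {
  stopifnot(n_particles >= 1L)
  if (!is.null(seed)) set.seed(seed)
  problem <- ensure_ground(problem)
  check_lik(problem, lik)
  prior <- check_prior(problem, prior)
  if (all(durations$memoryless)) elapsed_cap <- 1L
  T_len <- nrow(lik)
  classes_of <- problem$ground$action_class
  out <- posterior_skeleton(problem, T_len)
  n <- as.integer(n_particles)

  reg <- new_state_registry(problem)
  selmemo <- new.env(parent = emptyenv())
  hmemo <- new.env(parent = emptyenv())
  hazard <- function(a, e) {
    k <- paste(a, e)
    v <- get0(k, envir = hmemo, inherits = FALSE)
    if (is.null(v)) {
      v <- termination_prob(durations, a, 0L, e, e + 1L, mode = params$hazard_mode)
      assign(k, v, envir = hmemo)
    }
    v
  }
  selection <- function(g, sid) {
    k <- paste(g, sid)
    v <- get0(k, envir = selmemo, inherits = FALSE)
    if (is.null(v)) {
      s <- reg$states[[sid]]
      sel <- action_selection_dist(problem, g, s, params, graph)
      succ <- integer(length(sel$actions))
      for (i in seq_along(sel$actions)) {
        s2 <- apply_action(s, problem$ground$actions[[sel$actions[i]]], check = FALSE)
        r <- registry_add(reg, s2); reg <<- r$reg; succ[i] <- r$sid
      }
      v <- list(actions = sel$actions, prob = sel$prob, succ = succ)
      assign(k, v, envir = selmemo)
    }
    v
  }
  record <- function(t, pa, pg, w) {
    cm <- rowsum(w, classes_of[pa])
    out$class_marginal[t, rownames(cm)] <<- as.numeric(cm)
    gm <- rowsum(w, names(problem$goals)[pg])
    out$goal_marginal[t, rownames(gm)] <<- as.numeric(gm)
  }
  systematic_resample <- function(w) {
    cw <- cumsum(w) / sum(w)
    pts <- (stats::runif(1) + seq_len(n) - 1) / n
    pmin(findInterval(pts, cw) + 1L, n)
  }

  # init (t = 1)
  gidx <- which(prior > 0)
  pg <- gidx[sample.int(length(gidx), n, replace = TRUE, prob = prior[gidx])]
  pa <- integer(n); psid <- integer(n); pe <- integer(n)
  for (gi in unique(pg)) {
    sel <- action_selection_dist(problem, gi, problem$ground$s0, params, graph)
    succ <- integer(length(sel$actions))
    for (i in seq_along(sel$actions)) {
      s2 <- apply_action(problem$ground$s0, problem$ground$actions[[sel$actions[i]]],
                         check = FALSE)
      r <- registry_add(reg, s2); reg <- r$reg; succ[i] <- r$sid
    }
    rows <- which(pg == gi)
    pick <- sample.int(length(sel$actions), length(rows), replace = TRUE, prob = sel$prob)
    pa[rows] <- sel$actions[pick]; psid[rows] <- succ[pick]
  }
  w <- lik[1, classes_of[pa]]
  if (sum(w) <= 0) stop("particle degeneracy at step 1: all weights zero", call. = FALSE)
  w <- w / sum(w)
  record(1L, pa, pg, w)
  if (1 / sum(w^2) < ess_frac * n) {
    idx <- systematic_resample(w)
    pa <- pa[idx]; pg <- pg[idx]; psid <- psid[idx]; pe <- pe[idx]
    w <- rep(1 / n, n)
  }

  for (t in seq_len(T_len)[-1]) {
    h <- vapply(seq_len(n), function(i) hazard(pa[i], pe[i]), numeric(1))
    term <- stats::runif(n) < h
    pe[!term] <- pmin(pe[!term] + 1L, elapsed_cap)
    if (any(term)) {
      grp <- paste(pg[term], psid[term])
      for (k in unique(grp)) {
        parts <- strsplit(k, " ", fixed = TRUE)[[1]]
        sel <- selection(as.integer(parts[1]), as.integer(parts[2]))
        rows <- which(term)[grp == k]
        pick <- sample.int(length(sel$actions), length(rows), replace = TRUE,
                           prob = sel$prob)
        pa[rows] <- sel$actions[pick]; psid[rows] <- sel$succ[pick]
        pe[rows] <- 0L
      }
    }
    w <- w * lik[t, classes_of[pa]]
    if (sum(w) <= 0)
      stop(sprintf("particle degeneracy at step %d: all weights zero", t), call. = FALSE)
    w <- w / sum(w)
    record(t, pa, pg, w)
    if (1 / sum(w^2) < ess_frac * n) {
      idx <- systematic_resample(w)
      pa <- pa[idx]; pg <- pg[idx]; psid <- psid[idx]; pe <- pe[idx]
      w <- rep(1 / n, n)
    }
  }

  structure(list(class_marginal = out$class_marginal,
                 goal_marginal = out$goal_marginal,
                 classes = colnames(out$class_marginal),
                 goals = colnames(out$goal_marginal),
                 method = "particle", n_particles = n),
            class = "ccbm_posterior")
}

#' @export
print.ccbm_posterior <- function(x, ...) {
  cat("ccbm_posterior (", x$method, "): ", nrow(x$class_marginal), " steps, ",
      length(x$classes), " classes, ", length(x$goals), " goals\n", sep = "")
  invisible(x)
}

#' Decode the action-class sequence from a posterior
#'
#' Per-step argmax over the class marginal; ties are broken by alphabetical
#' class order.
#'
#' @param posterior A \code{ccbm_posterior} (class columns are stored in
#'   alphabetical order).
#' @return Character vector of class labels, one per step.
#' @export
decode_actions <- function(posterior) {
  cm <- posterior$class_marginal[, sort(colnames(posterior$class_marginal)), drop = FALSE]
  colnames(cm)[max.col(cm, ties.method = "first")]
}

goal_modes <- function(posterior) {
  gm <- posterior$goal_marginal
  colnames(gm)[max.col(gm, ties.method = "first")]
}

#' Multiple-goals estimate
#'
#' Collects every goal that is the posterior mode at one or more time steps
#' and scores it against the true goal set:
#' performance = |est intersect truth| / |est|.
#'
#' @param posterior A \code{ccbm_posterior}.
#' @param truth Character vector of true goal names.
#' @return Object of class \code{ccbm_goal_estimate} with \code{est},
#'   \code{truth} and \code{performance}.
#' @export
multigoal_estimate <- function(posterior, truth) {
  est <- unique(goal_modes(posterior))
  if (length(est) == 0L) stop("empty goal estimate", call. = FALSE)
  structure(list(est = est, truth = truth,
                 performance = length(intersect(est, truth)) / length(est)),
            class = "ccbm_goal_estimate")
}

#' @export
print.ccbm_goal_estimate <- function(x, ...) {
  cat("goal estimate {", paste(x$est, collapse = ", "), "} vs truth {",
      paste(x$truth, collapse = ", "), "}: performance ", format(x$performance), "\n",
      sep = "")
  invisible(x)
}

#' Pooled-goal recognition decision
#'
#' Under the pooled strategy each distinct set of true goals is subsumed as
#' one composite recognisable goal.  A run is recognised when the goal
#' posterior mode at the final step equals the true composite goal and has
#' held for the last \code{k} steps.
#'
#' @param posterior A \code{ccbm_posterior} over composite goal targets.
#' @param truth Name of the true composite goal.
#' @param k Persistence window (default 1: final step only).
#' @return Logical scalar.
#' @export
pooled_goal_recognised <- function(posterior, truth, k = 1L) {
  modes <- goal_modes(posterior)
  T_len <- length(modes)
  k <- min(k, T_len)
  all(modes[(T_len - k + 1L):T_len] == truth)
}

#' Collapse a goal posterior onto goal pools
#'
#' Sums per-step goal marginal mass within each pool (e.g. mapping meal
#' goals onto healthy/unhealthy meal/drink pools).
#'
#' @param posterior A \code{ccbm_posterior}.
#' @param pool_map Named character vector mapping goal name -> pool label.
#' @return A \code{ccbm_posterior} whose goal marginal is over pools.
#' @export
pool_posterior <- function(posterior, pool_map) {
  gm <- posterior$goal_marginal
  keep <- colnames(gm) %in% names(pool_map)
  gm <- gm[, keep, drop = FALSE]
  pools <- sort(unique(unname(pool_map[colnames(gm)])))
  out <- matrix(0, nrow(gm), length(pools), dimnames = list(NULL, pools))
  for (j in seq_len(ncol(gm))) {
    p <- pool_map[[colnames(gm)[j]]]
    out[, p] <- out[, p] + gm[, j]
  }
  rs <- rowSums(out)
  out <- out / ifelse(rs > 0, rs, 1)
  res <- posterior
  res$goal_marginal <- out
  res$goals <- pools
  res
}
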