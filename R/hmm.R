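#' Estimate an HMM over action classes by counting
#'
#' Transitions are relative frequencies of observed label bigrams,
#' transition(i, j) = count(i -> j) / count(i -> .); classes never left in
#' the data (observed only at sequence ends) receive a self-loop of 1.
#' Priors are proportional to state occurrence counts.  Optional add-alpha
#' smoothing (default 0: raw counting).
#'
#' @param sequences List of character label sequences (or a single vector).
#' @param states Character vector of states; defaults to the sorted classes
#'   observed in the data.
#' @param alpha Additive smoothing for transition counts.
#' @return Object of class \code{ccbm_hmm} with \code{states},
#'   \code{transition} (row-stochastic matrix) and \code{prior}.
#' @export
estimate_transitions <- function(sequences, states = NULL, alpha = 0) {
  if (!is.list(sequences)) sequences <- list(sequences)
  labels <- unlist(sequences)
  if (length(labels) == 0L) stop("empty annotation input", call. = FALSE)
  if (is.null(states)) states <- sort(unique(labels))
  stopifnot(all(labels %in% states))
  K <- length(states)
  counts <- matrix(alpha, K, K, dimnames = list(states, states))
  occ <- stats::setNames(rep(0, K), states)
  for (seq in sequences) {
    occ[names(table(seq))] <- occ[names(table(seq))] + as.numeric(table(seq))
    if (length(seq) >= 2L) {
      for (i in seq_len(length(seq) - 1L))
        counts[seq[i], seq[i + 1L]] <- counts[seq[i], seq[i + 1L]] + 1
    }
  }
  trans <- counts
  for (i in seq_len(K)) {
    rs <- sum(counts[i, ])
    if (rs > 0) trans[i, ] <- counts[i, ] / rs
    else { trans[i, ] <- 0; trans[i, i] <- 1 }  # empty-row rule: self-loop
  }
  prior <- if (sum(occ) > 0) occ / sum(occ) else rep(1 / K, K)
  structure(list(states = states, transition = trans, prior = prior),
            class = "ccbm_hmm")
}

#' @export
print.ccbm_hmm <- function(x, ...) {
  cat("ccbm_hmm with", length(x$states), "states:",
      paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

#' Forward filter for a class-level HMM
#'
#' Standard normalised forward recursion.
#'
#' @param spec A \code{ccbm_hmm}.
#' @param lik Matrix (time steps x classes) of observation likelihoods whose
#'   columns cover the spec's states.
#' @return Matrix (time steps x states) of filtered posteriors.
#' @export
hmm_filter <- function(spec, lik) {
  stopifnot(inherits(spec, "ccbm_hmm"))
  missing <- setdiff(spec$states, colnames(lik))
  if (length(missing))
    stop(sprintf("likelihoods lack state column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  L <- lik[, spec$states, drop = FALSE]
  T_len <- nrow(L)
  post <- matrix(0, T_len, length(spec$states), dimnames = list(NULL, spec$states))
  f <- spec$prior * L[1, ]
  if (sum(f) <= 0) stop("degeneracy at step 1: all likelihoods zero", call. = FALSE)
  post[1, ] <- f / sum(f)
  for (t in seq_len(T_len)[-1]) {
    f <- as.numeric(post[t - 1L, ] %*% spec$transition) * L[t, ]
    if (sum(f) <= 0)
      stop(sprintf("degeneracy at step %d: all likelihoods zero", t), call. = FALSE)
    post[t, ] <- f / sum(f)
  }
  post
}

#' Build a joint HMM for goal recognition
#'
#' Combines one per-goal sub-model through a common start state whose
#' outgoing transitions are the goal prior times the sub-model's normalised
#' state priors.  Joint states are (action class, goal) tuples; there are no
#' transitions between different goals' blocks, so the goal posterior is
#' obtained by block marginalisation.
#'
#' @param specs Named list of \code{ccbm_hmm} sub-models, one per goal.
#' @param prior Named goal prior over (a subset of) the sub-model names;
#'   defaults to uniform.
#' @return Object of class \code{ccbm_joint_hmm}.
#' @export
build_joint_hmm <- function(specs, prior = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1L, !is.null(names(specs)))
  goals <- names(specs)
  if (is.null(prior)) prior <- stats::setNames(rep(1 / length(goals), length(goals)), goals)
  stopifnot(all(goals %in% names(prior)))
  prior <- prior[goals] / sum(prior[goals])
  state_goal <- character(0); state_class <- character(0)
  start <- numeric(0)
  blocks <- list()
  for (g in goals) {
    sp <- specs[[g]]
    if (length(sp$states) == 0L) stop(sprintf("empty sub-model for goal '%s'", g), call. = FALSE)
    state_goal <- c(state_goal, rep(g, length(sp$states)))
    state_class <- c(state_class, sp$states)
    start <- c(start, prior[[g]] * sp$prior / sum(sp$prior))
    blocks[[g]] <- sp$transition
  }
  n <- length(state_goal)
  trans <- matrix(0, n, n)
  off <- 0L
  for (g in goals) {
    k <- length(specs[[g]]$states)
    trans[(off + 1L):(off + k), (off + 1L):(off + k)] <- blocks[[g]]
    off <- off + k
  }
  structure(list(goals = goals, state_goal = state_goal, state_class = state_class,
                 start = start, transition = trans, goal_prior = prior),
            class = "ccbm_joint_hmm")
}

#' Per-step goal posterior of a joint HMM
#'
#' Forward-filters the joint (class, goal) chain and marginalises the
#' per-step mass within each goal block.
#'
#' @param joint A \code{ccbm_joint_hmm}.
#' @param lik Matrix (time steps x classes) of observation likelihoods.
#' @return Matrix (time steps x goals) of goal posteriors.
#' @export
joint_goal_posterior <- function(joint, lik) {
  stopifnot(inherits(joint, "ccbm_joint_hmm"))
  missing <- setdiff(unique(joint$state_class), colnames(lik))
  if (length(missing))
    stop(sprintf("likelihoods lack class column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  T_len <- nrow(lik)
  L <- lik[, joint$state_class, drop = FALSE]
  post <- matrix(0, T_len, length(joint$goals), dimnames = list(NULL, joint$goals))
  f <- joint$start * L[1, ]
  if (sum(f) <= 0) stop("degeneracy at step 1", call. = FALSE)
  f <- f / sum(f)
  post[1, ] <- as.numeric(rowsum(f, joint$state_goal)[joint$goals, ])
  for (t in seq_len(T_len)[-1]) {
    f <- as.numeric(f %*% joint$transition) * L[t, ]
    if (sum(f) <= 0) stop(sprintf("degeneracy at step %d", t), call. = FALSE)
    f <- f / sum(f)
    post[t, ] <- as.numeric(rowsum(f, joint$state_goal)[joint$goals, ])
  }
  post
}

#' Wrap an HMM goal posterior as a \code{ccbm_posterior}
#'
#' Lets HMM goal-recognition output flow through [multigoal_estimate()],
#' [pooled_goal_recognised()] and [pool_posterior()].
#'
#' @param goal_marginal Matrix (time steps x goals).
#' @param class_marginal Optional matrix (time steps x classes).
#' @return Object of class \code{ccbm_posterior}.
#' @export
as_ccbm_posterior <- function(goal_marginal, class_marginal = NULL) {
  if (is.null(class_marginal))
    class_marginal <- matrix(1, nrow(goal_marginal), 1, dimnames = list(NULL, "unknown"))
  structure(list(class_marginal = class_marginal, goal_marginal = goal_marginal,
                 classes = colnames(class_marginal), goals = colnames(goal_marginal),
                 method = "hmm"),
            class = "ccbm_posterior")
}

#' Serialise an HMM as CSV matrices
#'
#' @param spec A \code{ccbm_hmm}.
#' @param path Base path; writes \code{<path>_transition.csv} and
#'   \code{<path>_prior.csv}.
#' @export
write_hmm <- function(spec, path) {
  utils::write.csv(as.data.frame(spec$transition),
                   paste0(path, "_transition.csv"), row.names = TRUE)
  utils::write.csv(data.frame(state = spec$states, prior = as.numeric(spec$prior)),
                   paste0(path, "_prior.csv"), row.names = FALSE)
  invisible(path)
}
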