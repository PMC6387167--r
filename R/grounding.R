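#' Ground a parsed problem
#'
#' Substitutes every type-compatible combination of declared objects into the
#' predicate schemas and action templates, producing the finite ground
#' predicate set P and ground action set A.  Grounding is deterministic and
#' duplicate free: predicates follow schema declaration order then
#' lexicographic argument order; actions follow template declaration order
#' then lexicographic argument order.  Equality constraints in preconditions
#' (\code{(= ?x ?y)} / \code{(not (= ?x ?y))}) are resolved statically and
#' incompatible bindings are dropped.
#'
#' @param problem A \code{ccbm_problem} from [parse_problem()].
#' @return The problem with a \code{$ground} component: \code{pred_keys}
#'   (character vector naming P), \code{actions} (list of ground actions with
#'   precompiled precondition/effect indices), \code{s0} (the initial world
#'   state as a named logical vector over P) and \code{action_class} (the
#'   class label, i.e. template name, per ground action).
#' @export
ground_problem <- function(problem) {
  stopifnot(inherits(problem, "ccbm_problem"))
  types <- problem$types
  objects <- problem$objects

  objects_of_type <- function(ty) {
    obs <- names(objects)[vapply(objects, function(t) type_is_a(types, t, ty), logical(1))]
    sort(obs)
  }

  # lexicographic cartesian product (first column most significant)
  cart <- function(cols) {
    if (length(cols) == 0L) return(matrix(character(0), nrow = 1L, ncol = 0L))
    if (any(lengths(cols) == 0L)) return(matrix(character(0), nrow = 0L, ncol = length(cols)))
    grid <- expand.grid(rev(cols), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    as.matrix(grid[, rev(seq_along(cols)), drop = FALSE])
  }

  # ground predicates
  pred_keys <- character(0)
  for (pn in names(problem$predicates)) {
    argm <- cart(lapply(problem$predicates[[pn]], objects_of_type))
    for (i in seq_len(nrow(argm))) pred_keys <- c(pred_keys, atom_key(pn, argm[i, ]))
  }
  pred_index <- stats::setNames(seq_along(pred_keys), pred_keys)

  lit_index <- function(lit, binding) {
    args <- vapply(lit$args, function(a) if (startsWith(a, "?")) binding[[a]] else a, character(1))
    key <- atom_key(lit$pred, args)
    idx <- pred_index[[key]]
    if (is.null(idx)) stop(sprintf("ground atom %s not in predicate set", key), call. = FALSE)
    idx
  }

  actions <- list()
  for (tpl in problem$templates) {
    argm <- cart(lapply(tpl$params$type, objects_of_type))
    for (i in seq_len(nrow(argm))) {
      args <- argm[i, ]
      binding <- stats::setNames(as.list(args), tpl$params$var)
      # static equality filtering
      ok <- TRUE
      for (eq in tpl$precond$equalities) {
        val <- function(a) if (startsWith(a, "?")) binding[[a]] else a
        equal <- identical(val(eq$args[1]), val(eq$args[2]))
        if (equal != eq$positive) { ok <- FALSE; break }
      }
      if (!ok) next
      pre_pos <- integer(0); pre_neg <- integer(0)
      for (lit in tpl$precond$lits) {
        idx <- lit_index(lit, binding)
        if (lit$positive) pre_pos <- c(pre_pos, idx) else pre_neg <- c(pre_neg, idx)
      }
      add <- integer(0); del <- integer(0)
      for (lit in tpl$effect) {
        idx <- lit_index(lit, binding)
        if (lit$positive) add <- c(add, idx) else del <- c(del, idx)
      }
      actions[[length(actions) + 1L]] <- list(
        name = atom_key(tpl$name, args), template = tpl$name, args = args,
        class = tpl$name, pre_pos = unique(pre_pos), pre_neg = unique(pre_neg),
        add = unique(add), del = unique(del),
        duration = tpl$duration, observation = tpl$observation)
    }
  }

  s0 <- stats::setNames(rep(FALSE, length(pred_keys)), pred_keys)
  for (atom in problem$init) s0[[atom_key(atom$pred, atom$args)]] <- TRUE

  goal_lits <- lapply(problem$goals, function(lits) {
    list(idx = vapply(lits, function(l) pred_index[[atom_key(l$pred, l$args)]], integer(1)),
         value = vapply(lits, function(l) l$positive, logical(1)))
  })

  problem$ground <- list(pred_keys = pred_keys, pred_index = pred_index,
                         actions = actions,
                         action_names = vapply(actions, `[[`, character(1), "name"),
                         action_class = vapply(actions, `[[`, character(1), "class"),
                         s0 = s0, goal_lits = goal_lits)
  problem
}

ensure_ground <- function(problem) {
  if (is.null(problem$ground)) ground_problem(problem) else problem
}

resolve_goal <- function(problem, goal) {
  gn <- names(problem$goals)
  if (is.numeric(goal)) {
    stopifnot(goal >= 1, goal <= length(gn))
    return(as.integer(goal))
  }
  idx <- match(goal, gn)
  if (is.na(idx)) stop(sprintf("unknown goal '%s'", goal), call. = FALSE)
  idx
}

#' Test applicability of a ground action
#'
#' @param state Named logical world state over the ground predicate set.
#' @param action A ground action entry from \code{problem$ground$actions}.
#' @return Logical scalar.
#' @export
action_applicable <- function(state, action) {
  all(state[action$pre_pos]) && !any(state[action$pre_neg])
}

#' Apply a ground action's effect to a world state
#'
#' Delete atoms are applied first, then add atoms, so a conflicting
#' add+delete of the same atom resolves to add (the common PDDL rule).
#' The input state is not modified.
#'
#' @inheritParams action_applicable
#' @param check If \code{TRUE} (default), raise an error when the action's
#'   precondition does not hold in \code{state}.
#' @return The successor world state.
#' @export
apply_action <- function(state, action, check = TRUE) {
  if (check && !action_applicable(state, action))
    stop(sprintf("action %s is not applicable in this state", action$name), call. = FALSE)
  state[action$del] <- FALSE
  state[action$add] <- TRUE
  state
}

state_key <- function(state) paste(as.integer(state), collapse = "")

applicable_actions <- function(problem, state) {
  acts <- problem$ground$actions
  which(vapply(acts, function(a) action_applicable(state, a), logical(1)))
}

#' Breadth-first closure of the reachable state space
#'
#' Expands all world states reachable from the initial state by any action
#' sequence, deduplicating states by equality and labelling edges with the
#' generating action.  Expansion order is deterministic (FIFO over states,
#' actions in grounding order), so the graph is identical across runs.
#'
#' @param problem A grounded \code{ccbm_problem}.
#' @param max_states Abort cleanly when more than this many states have been
#'   discovered.  The error condition (class \code{ccbm_cap_error}) carries
#'   the partial graph and the unexpanded frontier.
#' @return An object of class \code{ccbm_state_graph}: \code{states} (list of
#'   world states), \code{keys}, \code{edges} (data.frame from/to/action) and
#'   a per-goal distance cache used by [goal_distance()].
#' @export
reachable_states <- function(problem, max_states = 1e6) {
  problem <- ensure_ground(problem)
  s0 <- problem$ground$s0
  states <- list(s0)
  keys <- state_key(s0)
  key2id <- new.env(parent = emptyenv())
  assign(keys, 1L, envir = key2id)
  from <- integer(0); to <- integer(0); edge_action <- integer(0)
  queue <- 1L
  qpos <- 1L
  while (qpos <= length(queue)) {
    sid <- queue[qpos]; qpos <- qpos + 1L
    s <- states[[sid]]
    for (ai in applicable_actions(problem, s)) {
      s2 <- apply_action(s, problem$ground$actions[[ai]], check = FALSE)
      k2 <- state_key(s2)
      id2 <- get0(k2, envir = key2id, inherits = FALSE)
      if (is.null(id2)) {
        if (length(states) + 1L > max_states) {
          graph <- new_state_graph(problem, states, keys,
                                   data.frame(from = from, to = to, action = edge_action),
                                   complete = FALSE)
          cond <- structure(
            class = c("ccbm_cap_error", "error", "condition"),
            list(message = sprintf("state cap %d exceeded; partial graph attached", max_states),
                 call = sys.call(-1), graph = graph, frontier = queue[qpos:length(queue)]))
          stop(cond)
        }
        states[[length(states) + 1L]] <- s2
        id2 <- length(states)
        assign(k2, id2, envir = key2id)
        keys <- c(keys, k2)
        queue <- c(queue, id2)
      }
      from <- c(from, sid); to <- c(to, id2); edge_action <- c(edge_action, ai)
    }
  }
  new_state_graph(problem, states, keys,
                  data.frame(from = from, to = to, action = edge_action),
                  complete = TRUE)
}

new_state_graph <- function(problem, states, keys, edges, complete) {
  key2id <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) assign(keys[i], i, envir = key2id)
  structure(list(states = states, keys = keys, key2id = key2id, edges = edges,
                 complete = complete, dist_cache = new.env(parent = emptyenv())),
            class = "ccbm_state_graph")
}

#' @export
print.ccbm_state_graph <- function(x, ...) {
  cat("ccbm_state_graph:", length(x$states), "states,", nrow(x$edges), "edges",
      if (!x$complete) "(partial)" else "", "\n")
  invisible(x)
}

graph_state_id <- function(graph, state) {
  id <- get0(state_key(state), envir = graph$key2id, inherits = FALSE)
  if (is.null(id)) stop("state not present in the state graph", call. = FALSE)
  id
}

goal_holds <- function(problem, state, goal) {
  gi <- resolve_goal(problem, goal)
  gl <- problem$ground$goal_lits[[gi]]
  length(gl$idx) == 0L || all(state[gl$idx] == gl$value)
}

# distances (in actions) from every graph state to the nearest goal state;
# Inf where unreachable.  Memoised per goal on the graph object.
goal_distance_map <- function(problem, graph, goal) {
  gi <- resolve_goal(problem, goal)
  key <- as.character(gi)
  cached <- get0(key, envir = graph$dist_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  n <- length(graph$states)
  dist <- rep(Inf, n)
  in_goal <- vapply(graph$states, function(s) goal_holds(problem, s, gi), logical(1))
  dist[in_goal] <- 0
  # reverse adjacency
  radj <- split(graph$edges$from, graph$edges$to)
  queue <- which(in_goal)
  qpos <- 1L
  while (qpos <= length(queue)) {
    v <- queue[qpos]; qpos <- qpos + 1L
    for (u in radj[[as.character(v)]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  assign(key, dist, envir = graph$dist_cache)
  dist
}

#' Shortest goal distance of a world state
#'
#' Length of the shortest action sequence from \code{state} to any state
#' satisfying the named goal, computed on a reachable-state graph.  Returns
#' \code{Inf} when no goal state is reachable.
#'
#' @param problem A grounded \code{ccbm_problem}.
#' @param state Named logical world state (must be a node of \code{graph}).
#' @param goal Goal name or index.
#' @param graph A \code{ccbm_state_graph} from [reachable_states()].
#' @return Non-negative count, or \code{Inf}.
#' @export
goal_distance <- function(problem, state, goal, graph) {
  problem <- ensure_ground(problem)
  id <- graph_state_id(graph, state)
  goal_distance_map(problem, graph, goal)[id]
}

#' Count unsatisfied goal predicates
#'
#' The landmark-style surrogate for goal distance: the number of atoms in the
#' goal specification whose required value differs from the state's value.
#'
#' @inheritParams goal_distance
#' @return Non-negative count (0 for an empty goal specification).
#' @export
unsatisfied_goal_predicates <- function(problem, state, goal) {
  problem <- ensure_ground(problem)
  gi <- resolve_goal(problem, goal)
  gl <- problem$ground$goal_lits[[gi]]
  if (length(gl$idx) == 0L) return(0L)
  sum(state[gl$idx] != gl$value)
}

#' Enumerate valid plans to a goal
#'
#' Depth-first enumeration of action sequences from the initial state to the
#' goal set.  Every returned plan replays validly from s0.  Actions whose
#' effect leaves the state unchanged (e.g. the always-applicable "unknown"
#' action) are excluded by default so the plan set stays finite; cycles
#' through distinct states are permitted up to \code{max_length}.
#'
#' @param problem A grounded \code{ccbm_problem}.
#' @param goal Goal name or index.
#' @param max_length Maximum plan length.
#' @param max_plans Truncate enumeration after this many plans (the result's
#'   \code{truncated} flag is then \code{TRUE}).
#' @param allow_noop Include state-preserving actions in plans.
#' @return List with \code{plans} (list of integer action-index vectors),
#'   \code{count} and \code{truncated}.
#' @export
enumerate_plans <- function(problem, goal, max_length = 20L, max_plans = 1e5,
                            allow_noop = FALSE) {
  problem <- ensure_ground(problem)
  gi <- resolve_goal(problem, goal)
  plans <- list()
  truncated <- FALSE
  rec <- function(state, prefix) {
    if (truncated) return(invisible(NULL))
    if (goal_holds(problem, state, gi)) {
      if (length(plans) >= max_plans) { truncated <<- TRUE; return(invisible(NULL)) }
      plans[[length(plans) + 1L]] <<- prefix
      return(invisible(NULL))  # minimal plans: stop at first goal hit along a branch
    }
    if (length(prefix) >= max_length) return(invisible(NULL))
    for (ai in applicable_actions(problem, state)) {
      s2 <- apply_action(state, problem$ground$actions[[ai]], check = FALSE)
      if (!allow_noop && identical(unname(s2), unname(state))) next
      rec(s2, c(prefix, ai))
    }
  }
  rec(problem$ground$s0, integer(0))
  list(plans = plans, count = length(plans), truncated = truncated)
}

#' Replay-check a plan
#'
#' @param problem Grounded problem.
#' @param plan Integer vector of action indices.
#' @param goal Optional goal the final state must satisfy.
#' @return \code{TRUE} if each action is applicable in sequence from s0 (and
#'   the final state satisfies \code{goal} when given), else \code{FALSE}.
#' @export
validate_plan <- function(problem, plan, goal = NULL) {
  problem <- ensure_ground(problem)
  s <- problem$ground$s0
  for (ai in plan) {
    act <- problem$ground$actions[[ai]]
    if (!action_applicable(s, act)) return(FALSE)
    s <- apply_action(s, act, check = FALSE)
  }
  if (!is.null(goal)) return(goal_holds(problem, s, goal))
  TRUE
}

#' Write a grounding report
#'
#' Tab-separated text: action name, class, arguments.
#'
#' @param problem Grounded problem.
#' @param path Output file path.
#' @export
write_grounding_report <- function(problem, path) {
  problem <- ensure_ground(problem)
  rows <- vapply(problem$ground$actions, function(a)
    paste(a$name, a$class, paste(a$args, collapse = " "), sep = "\t"), character(1))
  writeLines(c("action\tclass\targuments", rows), path)
  invisible(path)
}
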