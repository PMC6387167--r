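# Synthetic kitchen corpus: forward-simulates goal-directed meal-preparation
# runs from the CCBM dynamics and emits noisy sensor channels plus ground
# truth annotation, mirroring a 15-run corpus with per-run goal sets.

#' The eight action classes
#' @export
kitchen_classes <- c("clean", "drink", "eat", "get", "move", "prepare", "put", "unknown")

#' The full meal/drink object set of the cooking ontology
#' @export
kitchen_meals_all <- c("chicken", "coffee", "cookies", "juice", "pasta", "potato",
                       "readymeal", "rice", "salad", "snack", "tea", "toast",
                       "water", "other")

kitchen_drinks <- c("coffee", "tea", "juice", "water")
kitchen_unhealthy <- c("coffee", "toast", "readymeal", "cookies")

#' Health pool of a meal
#'
#' Coffee, toast, ready meals and cookies are classed unhealthy; everything
#' else healthy.  Crossed with meal vs drink this yields the four pooled
#' health goals.
#'
#' @param meal Meal name(s).
#' @return Character pool label(s), e.g. \code{"healthy-meal"}.
#' @export
kitchen_health_pool <- function(meal) {
  health <- ifelse(meal %in% kitchen_unhealthy, "unhealthy", "healthy")
  kind <- ifelse(meal %in% kitchen_drinks, "drink", "meal")
  paste(health, kind, sep = "-")
}

composite_goal_name <- function(meals) {
  if (length(meals) == 1L) meals else paste(sort(meals), collapse = "+")
}

#' Build the kitchen planning problem
#'
#' Generates (and parses) the causal-model source for the cooking domain:
#' move/get/put/prepare/eat/drink/clean/unknown templates over items
#' \{ingredients, tools\}, locations \{kitchen, study\} and the supplied
#' meal list.  One named goal is declared per meal (meal consumed, kitchen
#' cleaned); multi-meal goal sets are declared as composite conjunction
#' goals named \code{"a+b"}.
#'
#' @param meals Meals/drinks to instantiate (subset of
#'   [kitchen_meals_all]; default a small tractable pair).
#' @param goal_sets Optional list of character vectors; each multi-meal set
#'   adds a composite goal.
#' @return A grounded \code{ccbm_problem}.
#' @export
build_kitchen_problem <- function(meals = c("pasta", "coffee"), goal_sets = list()) {
  stopifnot(all(meals %in% kitchen_meals_all), length(meals) >= 1L)
  drinks <- intersect(meals, kitchen_drinks)
  src <- c(
    "(:types location - object item - object meal - object)",
    paste0("(:objects kitchen - location study - location ",
           "ingredients - item tools - item ",
           paste(sort(meals), "- meal", collapse = " "), ")"),
    "(:predicates (at ?l - location) (taken ?i - item ?m - meal)",
    "  (prepared ?m - meal) (consumed ?m - meal) (drinkable ?m - meal) (cleaned))",
    "(:action move :parameters (?from - location ?to - location)",
    "  :duration (geometric 0.4)",
    "  :precondition (and (at ?from) (not (= ?from ?to)))",
    "  :effect (and (not (at ?from)) (at ?to)) :observation move)",
    "(:action get :parameters (?i - item ?m - meal)",
    "  :duration (geometric 0.4)",
    "  :precondition (and (at kitchen) (not (taken ?i ?m)) (not (prepared ?m)))",
    "  :effect (taken ?i ?m) :observation get)",
    "(:action put :parameters (?i - item ?m - meal)",
    "  :duration (geometric 0.4)",
    "  :precondition (and (at kitchen) (taken ?i ?m) (prepared ?m))",
    "  :effect (not (taken ?i ?m)) :observation put)",
    "(:action prepare :parameters (?m - meal)",
    "  :duration (geometric 0.3)",
    "  :precondition (and (at kitchen) (taken ingredients ?m) (taken tools ?m)",
    "                     (not (prepared ?m)))",
    "  :effect (prepared ?m) :observation prepare)",
    "(:action eat :parameters (?m - meal)",
    "  :duration (geometric 0.3)",
    "  :precondition (and (prepared ?m) (not (drinkable ?m)) (not (consumed ?m)))",
    "  :effect (consumed ?m) :observation eat)",
    "(:action drink :parameters (?m - meal)",
    "  :duration (geometric 0.3)",
    "  :precondition (and (prepared ?m) (drinkable ?m) (not (consumed ?m)))",
    "  :effect (consumed ?m) :observation drink)",
    "(:action clean :parameters () :duration (geometric 0.4)",
    "  :precondition (at kitchen) :effect (cleaned) :observation clean)",
    "(:action unknown :parameters () :duration (geometric 0.5)",
    "  :precondition (and) :effect (and) :observation unknown)",
    paste0("(:init (at kitchen)",
           if (length(drinks)) paste0(" ", paste0("(drinkable ", sort(drinks), ")", collapse = " ")),
           ")")
  )
  for (m in sort(meals))
    src <- c(src, sprintf("(:goal %s (and (consumed %s) (cleaned)))", m, m))
  for (gs in goal_sets) {
    if (length(gs) <= 1L) next
    stopifnot(all(gs %in% meals))
    nm <- composite_goal_name(gs)
    atoms <- paste0("(consumed ", sort(gs), ")", collapse = " ")
    src <- c(src, sprintf("(:goal %s (and %s (cleaned)))", nm, atoms))
  }
  ground_problem(parse_problem(paste(src, collapse = "\n")))
}

kitchen_binary_channels <- c("fridge", "kettle", "cupboard_tl", "cupboard_tr",
                             "cupboard_sink", "drawer_mid", "drawer_bot",
                             "movement", "water_hot", "water_cold")
kitchen_cont_channels <- c("temperature", "humidity")

default_emission_map <- function() {
  list(clean = c("water_hot", "water_cold"),
       drink = "kettle",
       eat = "cupboard_sink",
       get = c("fridge", "cupboard_tl"),
       move = "movement",
       prepare = "cupboard_tr",
       put = c("drawer_mid", "drawer_bot"),
       unknown = character(0))
}

#' Kitchen scenario configuration
#'
#' Bundles the kitchen problem, selection parameters, duration models,
#' reachable state graph, per-class sensor emission map and corpus layout.
#' The emission map encodes the usual sensor rationale (getting raises the
#' fridge/cupboard channels, preparing drives temperature/humidity drift,
#' cleaning raises water flow, moving toggles the movement sensor); all
#' values are configuration, not claims about any particular hardware.
#'
#' @param meals Meals instantiated in the problem.
#' @param run_goal_sets List of per-run true goal sets (character vectors of
#'   meals); defaults to a 15-run layout over \code{meals} whose first run
#'   is a multi-goal run covering every meal.
#' @param noise Emission noise in [0, 1]: binary channels fire with
#'   probability 1 - noise when their class is active and noise otherwise
#'   (0.5 is fully uninformative, 0 deterministic); continuous channel
#'   jitter scales linearly in it.
#' @param length_bound Maximum simulated steps per run.
#' @param ticks_per_step Raw sensor rows emitted per simulated step.
#' @param ms_per_tick Milliseconds between raw rows.
#' @param lambda1,lambda2 Action-selection weights of the simulated actor.
#'   The generator default sharpens the goal-distance feature (lambda1 = 3)
#'   so that roughly half of the simulated actions lie on a minimal plan,
#'   matching the deviation rate visible in real cooking runs (executed
#'   sequences about twice the minimal plan length); lambda1 = 1 produces
#'   actors that routinely cook other meals than their goal's.
#' @param use_graph Precompute the reachable graph (exact goal-distance
#'   feature f1); recommended for goal-directed simulation.
#' @param coords Also emit x/y/z person coordinates from per-location
#'   Gaussians.
#' @param complete_first_run Reseed the first run (bounded retries) until it
#'   contains all eight action classes.
#' @return Object of class \code{ccbm_scenario}.
#' @export
kitchen_scenario <- function(meals = c("pasta", "coffee"), run_goal_sets = NULL,
                             noise = 0.05, length_bound = 100L,
                             ticks_per_step = 2L, ms_per_tick = 400,
                             lambda1 = 3, lambda2 = 1, use_graph = TRUE,
                             coords = FALSE, complete_first_run = TRUE) {
  if (is.null(run_goal_sets)) {
    singles <- as.list(rep(sort(meals), length.out = 14L))
    run_goal_sets <- c(list(sort(meals)), singles)  # 15 runs, first multi-goal
  }
  problem <- build_kitchen_problem(meals, goal_sets = run_goal_sets)
  graph <- if (use_graph) reachable_states(problem) else NULL
  pool_map <- stats::setNames(kitchen_health_pool(sort(meals)), sort(meals))
  structure(list(meals = sort(meals), problem = problem, graph = graph,
                 params = selection_params(lambda1, lambda2),
                 durations = duration_model(problem),
                 emission = default_emission_map(),
                 run_goal_sets = run_goal_sets, noise = noise,
                 length_bound = as.integer(length_bound),
                 ticks_per_step = as.integer(ticks_per_step),
                 ms_per_tick = ms_per_tick, coords = coords,
                 complete_first_run = complete_first_run,
                 pool_map = pool_map),
            class = "ccbm_scenario")
}

#' @export
print.ccbm_scenario <- function(x, ...) {
  cat("ccbm_scenario:", length(x$meals), "meals,",
      length(x$problem$ground$actions), "ground actions,",
      length(x$problem$goals), "goals, noise", x$noise, "\n")
  invisible(x)
}

emit_ticks <- function(config, class, world, n_ticks) {
  noise <- config$noise
  active <- config$emission[[class]]
  out <- list()
  for (ch in kitchen_binary_channels) {
    p <- if (ch %in% active) 1 - noise else noise
    out[[ch]] <- stats::rbinom(n_ticks, 1L, p)
  }
  prep <- as.numeric(class == "prepare")
  out$temperature <- 20 + 5 * prep + stats::rnorm(n_ticks, 0, 10 * noise)
  out$humidity <- 50 + 10 * prep + stats::rnorm(n_ticks, 0, 20 * noise)
  if (config$coords) {
    in_study <- isTRUE(world[["(at study)"]])
    mu <- if (in_study) c(5, 4, 0) else c(1, 1, 0)
    out$x <- stats::rnorm(n_ticks, mu[1], 0.3 + noise)
    out$y <- stats::rnorm(n_ticks, mu[2], 0.3 + noise)
    out$z <- stats::rnorm(n_ticks, mu[3], 0.1 + noise)
  }
  as.data.frame(out)
}

#' Simulate one goal-directed kitchen run
#'
#' Samples a trajectory from the CCBM dynamics until the goal set is reached
#' (or errors at the length bound), then emits per-tick sensor readings from
#' the class emission map.  Reproducible under the seed.
#'
#' @param config A \code{ccbm_scenario}.
#' @param goals Character vector of the run's true meals (a declared goal or
#'   composite goal of the problem).
#' @param seed Integer seed.
#' @return Object of class \code{ccbm_run}: \code{steps} (per-step action,
#'   class), \code{windows} (per-step features + label, ready for
#'   [train_observation_model()]), \code{raw} (per-tick wide sensor table),
#'   \code{annotation} (t_ms, label), \code{plan}, \code{goal},
#'   \code{goal_set}.
#' @export
simulate_run <- function(config, goals, seed = 1L) {
  stopifnot(inherits(config, "ccbm_scenario"))
  goal <- composite_goal_name(goals)
  problem <- config$problem
  gi <- resolve_goal(problem, goal)  # errors on undeclared goal
  seed <- as.integer(seed)
  set.seed(seed)

  init <- initial_state_dist(problem, gi, config$params, config$graph)
  pick <- sample.int(length(init$states), 1L, prob = init$prob)
  state <- init$states[[pick]]
  states <- list(state)
  done <- goal_holds(problem, state$s, gi)
  while (!done) {
    if (state$v >= config$length_bound)
      stop(sprintf("goal '%s' not reached within %d steps", goal, config$length_bound),
           call. = FALSE)
    state <- sample_transition(problem, state, config$params, config$durations,
                               config$graph)
    states[[length(states) + 1L]] <- state
    done <- goal_holds(problem, state$s, gi)
  }
  acts <- vapply(states, function(st) st$a, integer(1))
  dflag <- vapply(states, function(st) st$d, logical(1))
  action_names <- problem$ground$action_names[acts]
  classes <- problem$ground$action_class[acts]
  T_len <- length(acts)

  # per-tick emission, per-step feature = max over the step's ticks
  tick_feats <- vector("list", T_len)
  for (t in seq_len(T_len))
    tick_feats[[t]] <- emit_ticks(config, classes[t], states[[t]]$s,
                                  config$ticks_per_step)
  raw <- do.call(rbind, tick_feats)
  raw <- cbind(data.frame(t_ms = (seq_len(nrow(raw)) - 1L) * config$ms_per_tick + 1),
               raw)
  step_feats <- do.call(rbind, lapply(tick_feats, function(df)
    as.data.frame(lapply(df, max))))
  windows <- cbind(step_feats, data.frame(label = classes, stringsAsFactors = FALSE))

  # annotation: label start times at action-change ticks
  change <- which(dflag)
  ann <- data.frame(t_ms = (change - 1L) * config$ticks_per_step * config$ms_per_tick + 1,
                    label = action_names[change], stringsAsFactors = FALSE)
  plan <- acts[dflag]

  structure(list(steps = data.frame(t = seq_len(T_len), action = action_names,
                                    class = classes, stringsAsFactors = FALSE),
                 windows = windows, raw = raw, annotation = ann,
                 plan = plan, goal = goal, goal_set = sort(goals), seed = seed),
            class = "ccbm_run")
}

#' @export
print.ccbm_run <- function(x, ...) {
  cat("ccbm_run: goal", x$goal, "-", nrow(x$steps), "steps,",
      length(x$plan), "actions\n")
  invisible(x)
}

#' Generate a synthetic corpus
#'
#' Simulates \code{n_runs} runs with the configured per-run goal sets
#' (recycled as needed) and per-run seeds derived from \code{seed}.
#'
#' @param config A \code{ccbm_scenario}.
#' @param n_runs Number of runs (default 15).
#' @param seed Integer base seed.
#' @return Object of class \code{ccbm_corpus}: \code{runs} (list of
#'   \code{ccbm_run}) and \code{manifest} (per-run goals and lengths).
#' @export
generate_corpus <- function(config, n_runs = 15L, seed = 1L) {
  stopifnot(n_runs >= 1L)
  seed <- as.integer(seed)
  sets <- rep(config$run_goal_sets, length.out = n_runs)
  runs <- vector("list", n_runs)
  # The first run emulates the corpus' exploratory long run (the one
  # containing all action classes): it is simulated with the softer
  # selection weights (lambda1 = 1) and reseeded (bounded, deterministic)
  # until every class occurs.
  cfg1 <- config
  cfg1$params <- selection_params(1, 1)
  for (i in seq_len(n_runs)) {
    run_seed <- (seed + i * 7919L) %% .Machine$integer.max
    if (i == 1L && config$complete_first_run) {
      runs[[1L]] <- simulate_run(cfg1, sets[[1L]], seed = run_seed)
      tries <- 0L
      while (length(unique(runs[[1L]]$windows$label)) < length(kitchen_classes) &&
             tries < 50L) {
        tries <- tries + 1L
        run_seed <- (run_seed + 104729L) %% .Machine$integer.max
        runs[[1L]] <- simulate_run(cfg1, sets[[1L]], seed = run_seed)
      }
    } else {
      runs[[i]] <- simulate_run(config, sets[[i]], seed = run_seed)
    }
  }
  manifest <- data.frame(
    run = seq_len(n_runs),
    goal = vapply(runs, `[[`, character(1), "goal"),
    goals = vapply(runs, function(r) paste(r$goal_set, collapse = ";"), character(1)),
    length = vapply(runs, function(r) nrow(r$steps), integer(1)),
    n_actions = vapply(runs, function(r) length(r$plan), integer(1)),
    seed = vapply(runs, `[[`, integer(1), "seed"))
  structure(list(runs = runs, manifest = manifest, config = config),
            class = "ccbm_corpus")
}

#' @export
print.ccbm_corpus <- function(x, ...) {
  cat("ccbm_corpus:", length(x$runs), "runs\n")
  print(x$manifest[c("run", "goal", "length", "n_actions")])
  invisible(x)
}

#' Write a corpus to disk
#'
#' Per run directory: \code{sensors.csv} (per-tick wide table),
#' \code{annotation.csv}, \code{truth.json}; plus a corpus
#' \code{manifest.json}.
#'
#' @param corpus A \code{ccbm_corpus}.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(corpus$runs)) {
    rd <- file.path(dir, sprintf("run%02d", i))
    dir.create(rd, showWarnings = FALSE)
    run <- corpus$runs[[i]]
    utils::write.csv(run$raw, file.path(rd, "sensors.csv"), row.names = FALSE)
    utils::write.csv(run$annotation, file.path(rd, "annotation.csv"), row.names = FALSE)
    jsonlite::write_json(list(goal = run$goal, goal_set = run$goal_set,
                              plan = run$plan, seed = run$seed),
                         file.path(rd, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
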