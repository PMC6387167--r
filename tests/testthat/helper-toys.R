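# Toy domains and model bundles shared across the test files.

toy_toggle <- function() {
  ground_problem(parse_problem("
    (:types thing - object)
    (:objects lamp - thing)
    (:predicates (on ?t - thing))
    (:action switch-on :parameters (?t - thing)
      :precondition (not (on ?t)) :effect (on ?t))
    (:action switch-off :parameters (?t - thing)
      :precondition (on ?t) :effect (not (on ?t)))
    (:init )
    (:goal lit (and (on lamp)))
  "))
}

toy_move <- function() {
  ground_problem(parse_problem("
    (:types location - object)
    (:objects kitchen - location study - location)
    (:predicates (at ?l - location))
    (:action move :parameters (?from - location ?to - location)
      :duration (normal 30 5)
      :precondition (and (at ?from) (not (= ?from ?to)))
      :effect (and (not (at ?from)) (at ?to)) :observation move)
    (:init (at kitchen))
    (:goal instudy (and (at study)))
  "))
}

# two order-independent actions both required by the goal
toy_pair <- function() {
  ground_problem(parse_problem("
    (:types step - object)
    (:objects s1 - step s2 - step)
    (:predicates (done ?s - step))
    (:action doit :parameters (?s - step)
      :precondition (not (done ?s)) :effect (done ?s))
    (:init )
    (:goal both (and (done s1) (done s2)))
  "))
}

# linear chain: a then b reaches the goal
toy_chain <- function() {
  ground_problem(parse_problem("
    (:types t - object)
    (:objects x - t)
    (:predicates (p1 ?v - t) (p2 ?v - t))
    (:action a :parameters (?v - t)
      :precondition (not (p1 ?v)) :effect (p1 ?v))
    (:action b :parameters (?v - t)
      :precondition (and (p1 ?v) (not (p2 ?v))) :effect (p2 ?v))
    (:init )
    (:goal end (and (p1 x) (p2 x)))
  "))
}

# small non-memoryless model for filter tests: uniform durations,
# always-applicable wait action keeps the support alive
toy_filter_model <- function() {
  problem <- ground_problem(parse_problem("
    (:types t - object)
    (:objects x - t)
    (:predicates (p ?v - t) (q ?v - t))
    (:action doa :parameters (?v - t) :duration (uniform 0 4)
      :precondition (not (p ?v)) :effect (p ?v) :observation doa)
    (:action dob :parameters (?v - t) :duration (uniform 0 4)
      :precondition (and (p ?v) (not (q ?v))) :effect (q ?v) :observation dob)
    (:action wait :parameters () :duration (uniform 0 3)
      :precondition (and) :effect (and) :observation wait)
    (:init )
    (:goal pq (and (p x) (q x)))
    (:goal ponly (and (p x)))
  "))
  list(problem = problem,
       params = selection_params(),
       durations = duration_model(problem),
       classes = sort(unique(problem$ground$action_class)))
}

uniform_lik <- function(T_len, classes) {
  matrix(1 / length(classes), T_len, length(classes),
         dimnames = list(NULL, classes))
}

uniform_goal_prior <- function(problem) {
  gn <- names(problem$goals)
  stats::setNames(rep(1 / length(gn), length(gn)), gn)
}

# small fixed kitchen bundle reused by several files (built once per session)
kitchen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- kitchen_scenario()
      corp <- generate_corpus(sc, n_runs = 15, seed = 2)
      om <- suppressWarnings(train_observation_model(
        lapply(corp$runs, `[[`, "windows"),
        observation_spec("optimistic"), classes = kitchen_classes))
      cache <<- list(scenario = sc, corpus = corp, om = om)
    }
    cache
  }
})
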