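test_that("action execution, start time and goal persistence have 0/1 mass", {
  p <- toy_move()
  mv <- match("(move kitchen study)", p$ground$action_names)
  s <- p$ground$s0
  # not terminated: world unchanged with probability 1
  expect_identical(action_execution(p, s, mv, terminated = FALSE), s)
  # terminated: effect applied with probability 1
  s2 <- action_execution(p, s, mv, terminated = TRUE)
  expect_true(s2[["(at study)"]])
  # effect-free action on termination: same state
  pn <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action idle :parameters () :effect (and))(:init (p x))"))
  expect_identical(action_execution(pn, pn$ground$s0, 1L, TRUE), pn$ground$s0)
  # terminated action must be applicable
  back <- match("(move study kitchen)", p$ground$action_names)
  expect_error(action_execution(p, s, back, TRUE), "not applicable")

  expect_equal(start_time_update(TRUE, 3, 7), 7)
  expect_equal(start_time_update(FALSE, 3, 7), 3)
  expect_equal(start_time_update(TRUE, 5, 5), 5)
  expect_equal(start_time_update(FALSE, 5, 5), 5)

  expect_equal(goal_persistence(2L), 2L)
})

test_that("termination_prob evaluates the printed hazard form", {
  m <- toy_filter_model()
  # uniform(0, 10): (F(5) - F(4)) / (1 - F(5)) = 0.1 / 0.5 = 0.2
  pu <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action a :parameters () :duration (uniform 0 10) :effect (p x))(:init )"))
  du <- duration_model(pu)
  expect_equal(termination_prob(du, 1L, 0, 4, 5), 0.2)
  # standard-hazard mode: 0.1 / 0.6
  expect_equal(termination_prob(du, 1L, 0, 4, 5, mode = "standard"), 0.1 / 0.6)
  # no duration mass yet -> 0
  pz <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action a :parameters () :duration (uniform 5 10) :effect (p x))(:init )"))
  expect_equal(termination_prob(duration_model(pz), 1L, 0, 1, 2), 0)
  # exhausted CDF -> certain termination by the clip rule
  expect_equal(termination_prob(du, 1L, 0, 10, 11), 1)
})

test_that("geometric durations are memoryless in both hazard modes", {
  pg <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action a :parameters () :duration (geometric 0.3) :effect (p x))(:init )"))
  dg <- duration_model(pg)
  printed <- vapply(1:8, function(e) termination_prob(dg, 1L, 0, e, e + 1), numeric(1))
  standard <- vapply(1:8, function(e)
    termination_prob(dg, 1L, 0, e, e + 1, mode = "standard"), numeric(1))
  expect_equal(printed, rep(0.3 / 0.7, 8))
  expect_equal(standard, rep(0.3, 8))
})

test_that("empirical durations use the sample CDF", {
  pe <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action a :parameters () :duration (empirical gaps) :effect (p x))(:init )"))
  de <- duration_model(pe, empirical = list(gaps = c(2, 2, 4, 8)))
  # F(2) = 0.5, F(3) = 0.5, F(4) = 0.75
  expect_equal(termination_prob(de, 1L, 0, 3, 4), (0.75 - 0.5) / (1 - 0.75))
  expect_error(duration_model(pe), "no empirical duration samples")
})

test_that("action selection is the softmax of the weighted features", {
  m <- toy_filter_model()
  p <- m$problem
  # all weights zero -> uniform over the applicable actions
  sel0 <- action_selection_dist(p, "pq", p$ground$s0, selection_params(0, 0))
  expect_equal(sel0$prob, rep(1 / length(sel0$actions), length(sel0$actions)))
  # applicable support only: dob requires p
  expect_setequal(p$ground$action_names[sel0$actions], c("(doa x)", "(wait)"))

  # feature sums 0 and ln 3 -> probabilities 0.25 / 0.75:
  # doa reduces the unsatisfied count by 1, wait does not, so with
  # lambda2 = ln 3 the odds are exp(ln 3) : 1
  sel <- action_selection_dist(p, "pq", p$ground$s0, selection_params(0, log(3)))
  prob <- stats::setNames(sel$prob, p$ground$action_names[sel$actions])
  expect_equal(unname(prob["(doa x)"]), 0.75)
  expect_equal(unname(prob["(wait)"]), 0.25)
})

test_that("gamma is invariant to constant feature shifts", {
  # an extra goal atom that no action can change adds 1 to every
  # candidate's unsatisfied count: the softmax must not move
  p1 <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t) (q ?v - t))
    (:action a :parameters () :precondition (not (p x)) :effect (p x))
    (:action w :parameters () :effect (and))
    (:init )(:goal g (and (p x)))"))
  p2 <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t) (q ?v - t))
    (:action a :parameters () :precondition (not (p x)) :effect (p x))
    (:action w :parameters () :effect (and))
    (:init )(:goal g (and (p x) (q x)))"))
  s1 <- action_selection_dist(p1, "g", p1$ground$s0, selection_params(0, 1.3))
  s2 <- action_selection_dist(p2, "g", p2$ground$s0, selection_params(0, 1.3))
  expect_equal(s1$prob, s2$prob, tolerance = 1e-12)
})

test_that("larger lambda1 concentrates mass on the goal-closest action", {
  m <- toy_filter_model()  # s0 offers doa (distance 1 after) and wait (2)
  g <- reachable_states(m$problem)
  probs <- vapply(c(0.5, 1, 2), function(l1) {
    sel <- action_selection_dist(m$problem, "pq", m$problem$ground$s0,
                                 selection_params(l1, 0), g)
    best <- which(m$problem$ground$action_names[sel$actions] == "(doa x)")
    sel$prob[best]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("dead ends raise an explicit error", {
  pd <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p ?v - t))
    (:action a :parameters () :precondition (not (p x)) :effect (p x))
    (:init (p x))(:goal g (and (p x)))"))
  expect_error(action_selection_dist(pd, "g", pd$ground$s0, selection_params()),
               "dead end")
})

test_that("goal priors are normalised; informed mode gives 2/(g+1)", {
  m <- toy_filter_model()
  pu <- goal_prior(m$problem)
  expect_equal(unname(pu), c(0.5, 0.5))
  pi4 <- goal_prior(kitchen_fixture()$scenario$problem, "informed", target = "pasta")
  g <- length(pi4)
  expect_equal(unname(pi4[["pasta"]]), 2 / (g + 1))
  expect_equal(sum(pi4), 1)
  expect_true(all(pi4[names(pi4) != "pasta"] == pi4[[which(names(pi4) != "pasta")[1]]]))
})

test_that("transition_logprob normalises over enumerable successors", {
  m <- toy_filter_model()
  p <- m$problem
  init <- initial_state_dist(p, "pq", m$params)
  st <- init$states[[1]]
  succ <- oracle_successors(p, st, m$params, m$durations)
  # every oracle successor's probability matches transition_logprob, and
  # the masses sum to one
  total <- 0
  for (sc in succ) {
    lp <- transition_logprob(p, st, sc$state, m$params, m$durations)
    expect_equal(exp(lp), sc$prob, tolerance = 1e-12)
    total <- total + exp(lp)
  }
  expect_equal(total, 1, tolerance = 1e-9)
  # causally impossible transitions get -Inf: world changed while d = FALSE
  bad <- sc$state
  bad$d <- FALSE
  expect_identical(transition_logprob(p, st, bad, m$params, m$durations), -Inf)
  # goal switch is impossible
  bad2 <- succ[[1]]$state
  bad2$g <- 2L
  expect_identical(transition_logprob(p, st, bad2, m$params, m$durations), -Inf)
})

test_that("sampled transitions match the analytic sub-model products", {
  m <- toy_filter_model()
  p <- m$problem
  init <- initial_state_dist(p, "pq", m$params)
  st <- init$states[[which.max(init$prob)]]
  succ <- oracle_successors(p, st, m$params, m$durations)
  keys <- vapply(succ, function(sc)
    paste(sc$state$a, sc$state$d, paste(as.integer(sc$state$s), collapse = "")),
    character(1))
  set.seed(99)
  n <- 10000
  draws <- table(vapply(seq_len(n), function(i) {
    nx <- sample_transition(p, st, m$params, m$durations)
    paste(nx$a, nx$d, paste(as.integer(nx$s), collapse = ""))
  }, character(1)))
  for (j in seq_along(succ)) {
    phat <- if (keys[j] %in% names(draws)) draws[[keys[j]]] / n else 0
    se <- sqrt(succ[[j]]$prob * (1 - succ[[j]]$prob) / n)
    expect_lt(abs(phat - succ[[j]]$prob), 3 * se + 1e-9)
  }
})

test_that("the goal component never changes along sampled trajectories", {
  m <- toy_filter_model()
  init <- initial_state_dist(m$problem, "ponly", m$params)
  set.seed(5)
  for (rep in 1:25) {
    st <- init$states[[sample.int(length(init$states), 1, prob = init$prob)]]
    for (t in 1:10) {
      st <- sample_transition(m$problem, st, m$params, m$durations)
      expect_identical(st$g, resolve_goal(m$problem, "ponly"))
    }
  }
})
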