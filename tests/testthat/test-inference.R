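# lik matrix with mass concentrated on one class per step
concentrated_lik <- function(labels, classes, floor = 0.01) {
  L <- matrix(floor, length(labels), length(classes),
              dimnames = list(NULL, classes))
  for (t in seq_along(labels)) L[t, labels[t]] <- 1 - floor * (length(classes) - 1)
  L
}

test_that("exact_filter equals the brute-force trajectory oracle", {
  m <- toy_filter_model()
  prior <- uniform_goal_prior(m$problem)
  set.seed(42)
  for (rep in 1:3) {
    L <- matrix(stats::runif(3 * length(m$classes), 0.2, 1), 3,
                dimnames = list(NULL, m$classes))
    post <- exact_filter(m$problem, m$params, m$durations, L, prior, prune = 0)
    ora <- oracle_filter(m$problem, m$params, m$durations, L, prior)
    expect_equal(post$class_marginal, ora$class_marginal, tolerance = 1e-9)
    expect_equal(post$goal_marginal, ora$goal_marginal, tolerance = 1e-9)
  }
})

test_that("uninformative observations leave the prior process untouched", {
  m <- toy_filter_model()
  prior <- uniform_goal_prior(m$problem)
  L <- uniform_lik(4, m$classes)
  post <- exact_filter(m$problem, m$params, m$durations, L, prior, prune = 0)
  ora <- oracle_filter(m$problem, m$params, m$durations,
                       matrix(1, 4, length(m$classes),
                              dimnames = list(NULL, m$classes)),
                       prior)
  expect_equal(post$class_marginal, ora$class_marginal, tolerance = 1e-9)
  # goal marginal at t = 1 equals the prior under a flat likelihood
  expect_equal(post$goal_marginal[1, ], prior, tolerance = 1e-12)
})

test_that("uninformative filtering matches seeded forward sampling", {
  m <- toy_filter_model()
  prior <- uniform_goal_prior(m$problem)
  T_len <- 4
  post <- exact_filter(m$problem, m$params, m$durations,
                       uniform_lik(T_len, m$classes), prior, prune = 0)
  set.seed(7)
  n <- 4000
  freq <- matrix(0, T_len, length(m$classes),
                 dimnames = list(NULL, m$classes))
  gidx <- seq_along(prior)
  for (i in seq_len(n)) {
    g <- sample(gidx, 1, prob = prior)
    init <- initial_state_dist(m$problem, g, m$params)
    st <- init$states[[sample.int(length(init$states), 1, prob = init$prob)]]
    cl <- m$problem$ground$action_class[st$a]
    freq[1, cl] <- freq[1, cl] + 1
    for (t in 2:T_len) {
      st <- sample_transition(m$problem, st, m$params, m$durations)
      cl <- m$problem$ground$action_class[st$a]
      freq[t, cl] <- freq[t, cl] + 1
    }
  }
  freq <- freq / n
  se <- sqrt(post$class_marginal * (1 - post$class_marginal) / n)
  expect_true(all(abs(freq - post$class_marginal) < 3 * se + 1e-9))
})

test_that("noise-free observations recover the simulated labels", {
  fix <- kitchen_fixture()
  sc <- fix$scenario
  run <- simulate_run(sc, "pasta", seed = 11)
  L <- concentrated_lik(run$windows$label, kitchen_classes, floor = 1e-4)
  prior <- uniform_goal_prior(sc$problem)
  post <- exact_filter(sc$problem, sc$params, sc$durations, L, prior,
                       graph = sc$graph)
  expect_identical(decode_actions(post), run$windows$label)
})

test_that("a single particle under deterministic dynamics collapses to the trajectory", {
  # chain with certain termination and a single applicable action at each step
  p <- ground_problem(parse_problem("
    (:types t - object)(:objects x - t)(:predicates (p1 ?v - t) (p2 ?v - t))
    (:action a :parameters (?v - t) :duration (uniform 0 1)
      :precondition (not (p1 ?v)) :effect (p1 ?v) :observation a)
    (:action b :parameters (?v - t) :duration (uniform 0 1)
      :precondition (and (p1 ?v) (not (p2 ?v))) :effect (p2 ?v) :observation b)
    (:action done :parameters () :duration (uniform 0 1)
      :precondition (and (p1 x) (p2 x)) :effect (and) :observation done)
    (:init )(:goal g (and (p1 x) (p2 x)))"))
  durs <- duration_model(p)
  classes <- sort(unique(p$ground$action_class))
  L <- concentrated_lik(c("a", "b", "done"), classes)
  prior <- stats::setNames(1, "g")
  post <- particle_filter(p, selection_params(), durs, L, prior,
                          n_particles = 1, seed = 3)
  expect_identical(decode_actions(post), c("a", "b", "done"))
})

test_that("the particle filter is reproducible and converges to the exact filter", {
  m <- toy_filter_model()
  prior <- uniform_goal_prior(m$problem)
  set.seed(1)
  T_len <- 6
  L <- matrix(stats::runif(T_len * length(m$classes), 0.2, 1), T_len,
              dimnames = list(NULL, m$classes))
  exact <- exact_filter(m$problem, m$params, m$durations, L, prior, prune = 0)

  # bitwise determinism under a fixed seed
  p1 <- particle_filter(m$problem, m$params, m$durations, L, prior,
                        n_particles = 500, seed = 77)
  p2 <- particle_filter(m$problem, m$params, m$durations, L, prior,
                        n_particles = 500, seed = 77)
  expect_identical(p1$class_marginal, p2$class_marginal)
  expect_identical(p1$goal_marginal, p2$goal_marginal)

  # total variation decreases with n (monotone trend over 5 seeds)
  mean_tv <- vapply(c(100, 1000, 10000), function(n) {
    mean(vapply(1:5, function(s) {
      pf <- particle_filter(m$problem, m$params, m$durations, L, prior,
                            n_particles = n, seed = s)
      mean(vapply(seq_len(T_len), function(t)
        total_variation(pf$class_marginal[t, ], exact$class_marginal[t, ]),
        numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_tv) < 0))
  expect_lt(mean_tv[3], 0.02)
})

test_that("degenerate observations raise an error naming the step", {
  m <- toy_filter_model()
  prior <- uniform_goal_prior(m$problem)
  L <- uniform_lik(3, m$classes)
  L[2, ] <- 0
  expect_error(
    exact_filter(m$problem, m$params, m$durations, L, prior),
    "step 2")
  expect_error(
    particle_filter(m$problem, m$params, m$durations, L, prior,
                    n_particles = 50, seed = 1),
    "step 2")
})

test_that("decode_actions breaks ties alphabetically", {
  post <- structure(list(
    class_marginal = matrix(c(0.5, 0.5, 0, 0.2, 0.2, 0.6), 2, byrow = TRUE,
                            dimnames = list(NULL, c("clean", "move", "eat"))),
    goal_marginal = matrix(1, 2, 1, dimnames = list(NULL, "g")),
    classes = c("clean", "move", "eat"), goals = "g", method = "exact"),
    class = "ccbm_posterior")
  expect_identical(decode_actions(post), c("clean", "eat"))
})

test_that("multigoal_estimate implements the set-overlap performance", {
  mk <- function(modes, goals) {
    gm <- matrix(0, length(modes), length(goals), dimnames = list(NULL, goals))
    for (t in seq_along(modes)) gm[t, modes[t]] <- 1
    structure(list(class_marginal = matrix(1, length(modes), 1,
                                           dimnames = list(NULL, "unknown")),
                   goal_marginal = gm, classes = "unknown", goals = goals,
                   method = "exact"),
              class = "ccbm_posterior")
  }
  goals <- c("coffee", "pasta", "tea")
  expect_equal(multigoal_estimate(mk(rep("pasta", 3), goals), "pasta")$performance, 1.0)
  expect_equal(multigoal_estimate(mk(c("pasta", "coffee", "pasta"), goals),
                                  "pasta")$performance, 0.5)
  expect_equal(multigoal_estimate(mk(rep("tea", 2), goals),
                                  c("pasta", "coffee"))$performance, 0.0)

  # pooled decision: mode must end on the true composite and hold k steps
  expect_true(pooled_goal_recognised(mk(rep("pasta", 3), goals), "pasta"))
  expect_false(pooled_goal_recognised(mk(c("pasta", "tea", "coffee"), goals), "pasta"))
  expect_false(pooled_goal_recognised(mk(c("pasta", "coffee", "pasta"), goals),
                                      "pasta", k = 3))
  expect_true(pooled_goal_recognised(mk(c("coffee", "pasta", "pasta"), goals),
                                     "pasta", k = 2))
})

test_that("pool_posterior collapses goal mass onto pools", {
  gm <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list(NULL, c("pasta", "tea", "coffee")))
  post <- as_ccbm_posterior(gm)
  pooled <- pool_posterior(post, c(pasta = "healthy", tea = "healthy", coffee = "unhealthy"))
  expect_equal(unname(pooled$goal_marginal[1, "healthy"]), 0.8)
  expect_equal(unname(pooled$goal_marginal[1, "unhealthy"]), 0.2)
})

test_that("informed priors with factor 2 give exact 2/(g+1) mass at t = 0", {
  sc <- kitchen_fixture()$scenario
  gn <- names(sc$problem$goals)
  prior <- goal_prior(sc$problem, "informed", target = "pasta")
  expect_equal(unname(prior[["pasta"]]), 2 / (length(gn) + 1))
  # the first filtering step under a flat likelihood reproduces the prior
  classes <- sort(unique(sc$problem$ground$action_class))
  post <- exact_filter(sc$problem, sc$params, sc$durations,
                       uniform_lik(1, classes), prior, graph = sc$graph)
  expect_equal(post$goal_marginal[1, ], prior, tolerance = 1e-12)
})
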