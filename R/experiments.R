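#' Classification accuracy with per-class breakdown
#'
#' Accuracy = sum over classes of correctly recognised instances, divided by
#' the total number of instances; the per-class correct counts and the full
#' confusion table are retained.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Object of class \code{ccbm_accuracy} with \code{value},
#'   \code{per_class}, \code{n} and \code{confusion}.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and true label sequences differ in length", call. = FALSE)
  classes <- sort(unique(c(predicted, truth)))
  conf <- table(factor(truth, classes), factor(predicted, classes))
  per_class <- stats::setNames(diag(conf), classes)
  structure(list(value = sum(per_class) / length(truth), per_class = per_class,
                 n = length(truth), confusion = conf),
            class = "ccbm_accuracy")
}

#' @export
print.ccbm_accuracy <- function(x, ...) {
  cat("accuracy:", format(x$value), "on", x$n, "instances\n")
  invisible(x)
}

#' Exhaustive feature-subset sweep
#'
#' Evaluates \code{evaluate(subset)} for every one of the 2^n subsets of
#' \code{features} (the empty subset included: a majority-class predictor in
#' the default backends) and derives, for each feature, the mean accuracy of
#' all subsets containing it versus all subsets without it, plus the best
#' subset (ties: highest accuracy, then smallest subset, then lexicographic
#' feature order).
#'
#' @param features Character vector of feature names (>= 1).
#' @param evaluate Function(character subset) -> accuracy in [0, 1]; must be
#'   pure given any seed it uses.
#' @return Object of class \code{ccbm_feature_sweep}: \code{results}
#'   (subset, size, accuracy), \code{feature_means} (with/without means per
#'   feature) and \code{best}.
#' @export
feature_sweep <- function(features, evaluate) {
  n <- length(features)
  stopifnot(n >= 1L)
  n_subsets <- as.integer(2^n)
  acc <- numeric(n_subsets)
  member <- matrix(FALSE, n_subsets, n, dimnames = list(NULL, features))
  subset_label <- character(n_subsets)
  for (m in seq_len(n_subsets) - 1L) {
    sel <- features[bitwAnd(m, 2L^(seq_len(n) - 1L)) > 0L]
    member[m + 1L, sel] <- TRUE
    subset_label[m + 1L] <- paste(sel, collapse = ";")
    acc[m + 1L] <- evaluate(sel)
  }
  feature_means <- data.frame(
    feature = features,
    with_mean = vapply(seq_len(n), function(j) mean(acc[member[, j]]), numeric(1)),
    without_mean = vapply(seq_len(n), function(j) mean(acc[!member[, j]]), numeric(1)))
  size <- rowSums(member)
  ord <- order(-acc, size, subset_label)
  best <- list(subset = strsplit(subset_label[ord[1]], ";", fixed = TRUE)[[1]],
               accuracy = acc[ord[1]])
  structure(list(results = data.frame(subset = subset_label, size = size,
                                      accuracy = acc),
                 feature_means = feature_means, best = best,
                 n_subsets = n_subsets),
            class = "ccbm_feature_sweep")
}

#' @export
print.ccbm_feature_sweep <- function(x, ...) {
  cat("feature sweep over", x$n_subsets, "subsets; best:",
      paste(x$best$subset, collapse = ", "), "->", format(x$best$accuracy), "\n")
  invisible(x)
}

#' Leave-one-out cross validation over runs
#'
#' @param runs List of runs (>= 2).
#' @param evaluate Function(train_runs, test_run) -> accuracy.
#' @return List with \code{mean} and \code{per_run} accuracies.
#' @export
loocv <- function(runs, evaluate) {
  stopifnot(length(runs) >= 2L)
  per_run <- vapply(seq_along(runs), function(i)
    evaluate(runs[-i], runs[[i]]), numeric(1))
  list(mean = mean(per_run), per_run = per_run)
}

#' Factorial design cells
#'
#' The activity-recognition design crosses algorithm (DT; HMM and CCBM each
#' in general and specialised flavour) with the observation-model protocol,
#' the DT lacking the system-model factor: 10 cells.  The goal-recognition
#' design crosses algorithm (HMM/CCBM) x goal target (meal/healthy) x
#' strategy (multiple/pooled) x prior (informed/uninformed): 16 cells.
#'
#' @param design \code{"ar"} or \code{"gr"}.
#' @return Data.frame with one row per cell.
#' @export
factorial_cells <- function(design = c("ar", "gr")) {
  design <- match.arg(design)
  if (design == "ar") {
    cells <- rbind(
      expand.grid(algorithm = "dt", system = NA_character_,
                  om = c("optimistic", "pessimistic"),
                  stringsAsFactors = FALSE),
      expand.grid(algorithm = c("hmm", "ccbm"), system = c("general", "specialised"),
                  om = c("optimistic", "pessimistic"), stringsAsFactors = FALSE))
    cells$cell <- ifelse(is.na(cells$system), paste(cells$algorithm, cells$om, sep = "."),
                         paste(cells$algorithm, cells$system, cells$om, sep = "."))
  } else {
    cells <- expand.grid(algorithm = c("hmm", "ccbm"), target = c("meal", "healthy"),
                         strategy = c("multiple", "pooled"),
                         prior = c("uninformed", "informed"),
                         stringsAsFactors = FALSE)
    cells$cell <- with(cells, paste(algorithm, target, strategy, prior, sep = "."))
  }
  cells
}

# class likelihood matrix for a run under a trained observation model
run_likelihood <- function(om, run) class_distribution(om, run$windows[om$features])

corpus_observation_models <- function(corpus, protocols = c("optimistic", "pessimistic")) {
  window_sets <- lapply(corpus$runs, `[[`, "windows")
  out <- list()
  for (p in protocols)
    out[[p]] <- suppressWarnings(train_observation_model(
      window_sets, observation_spec(protocol = p), classes = kitchen_classes))
  out
}

ccbm_run_posterior <- function(corpus, run, prior, filter = c("exact", "particle"),
                               n_particles = 500L, seed = 1L, om = NULL) {
  filter <- match.arg(filter)
  cfg <- corpus$config
  lik <- run_likelihood(om, run)
  if (filter == "exact")
    exact_filter(cfg$problem, cfg$params, cfg$durations, lik, prior, graph = cfg$graph)
  else
    particle_filter(cfg$problem, cfg$params, cfg$durations, lik, prior,
                    n_particles = n_particles, seed = seed, graph = cfg$graph)
}

#' Factorial activity-recognition experiment
#'
#' Evaluates the 10 AR cells on a corpus: the raw decision tree, general and
#' specialised HMMs (transition counts from all runs vs the test run's own
#' annotation) and general and specialised CCBM filters (uniform goal prior
#' vs prior mass restricted to the run's true goal), each under the
#' optimistic and pessimistic observation protocols.
#'
#' @param corpus A \code{ccbm_corpus}.
#' @param filter \code{"exact"} or \code{"particle"} for the CCBM cells.
#' @param n_particles,seed Particle-filter controls.
#' @return Object of class \code{ccbm_factorial}: \code{cells} and
#'   \code{results} (one row per cell x run with its accuracy).
#' @export
factorial_ar <- function(corpus, filter = c("exact", "particle"),
                         n_particles = 500L, seed = 1L) {
  filter <- match.arg(filter)
  cells <- factorial_cells("ar")
  oms <- corpus_observation_models(corpus)
  cfg <- corpus$config
  gn <- names(cfg$problem$goals)
  labels <- lapply(corpus$runs, function(r) r$windows$label)
  hmm_general <- estimate_transitions(labels, states = kitchen_classes)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    om <- oms[[cell$om]]
    for (ri in seq_along(corpus$runs)) {
      run <- corpus$runs[[ri]]
      truth <- run$windows$label
      pred <- if (cell$algorithm == "dt") {
        lik <- run_likelihood(om, run)
        colnames(lik)[max.col(lik, ties.method = "first")]
      } else if (cell$algorithm == "hmm") {
        spec <- if (cell$system == "general") hmm_general
                else estimate_transitions(list(truth), states = kitchen_classes)
        post <- hmm_filter(spec, run_likelihood(om, run))
        colnames(post)[max.col(post, ties.method = "first")]
      } else {
        prior <- if (cell$system == "general") {
          stats::setNames(rep(1 / length(gn), length(gn)), gn)
        } else {
          stats::setNames(as.numeric(gn == run$goal), gn)
        }
        post <- ccbm_run_posterior(corpus, run, prior, filter = filter,
                                   n_particles = n_particles,
                                   seed = seed + ri, om = om)
        decode_actions(post)
      }
      rows[[length(rows) + 1L]] <- data.frame(cell = cell$cell, run = ri,
                                              accuracy = accuracy(pred, truth)$value)
    }
  }
  structure(list(design = "ar", cells = cells, results = do.call(rbind, rows)),
            class = "ccbm_factorial")
}

#' Factorial goal-recognition experiment
#'
#' Evaluates the 16 GR cells.  The meal target reasons over per-meal goals;
#' the healthy target collapses them onto the four health pools.  The
#' multiple-goals strategy collects every goal recognised at least once and
#' scores |est n truth| / |est| per run; the pooled strategy treats each
#' distinct true goal set as one composite goal and counts runs whose final
#' posterior mode is the correct composite.  Informed priors give each of
#' the run's true goals twice the mass of the others.
#'
#' @inheritParams factorial_ar
#' @param om_protocol Observation protocol used for all cells.
#' @return Object of class \code{ccbm_factorial}; multiple-strategy rows
#'   carry the per-run performance, pooled rows a 0/1 recognition flag.
#' @export
factorial_gr <- function(corpus, filter = c("exact", "particle"),
                         n_particles = 500L, seed = 1L,
                         om_protocol = "pessimistic") {
  filter <- match.arg(filter)
  cells <- factorial_cells("gr")
  cfg <- corpus$config
  om <- corpus_observation_models(corpus, om_protocol)[[om_protocol]]
  meals <- cfg$meals
  gn <- names(cfg$problem$goals)
  composite <- setdiff(gn, meals)
  labels <- lapply(corpus$runs, function(r) r$windows$label)

  prior_for <- function(goal_names, informed_targets = NULL) {
    w <- stats::setNames(rep(1, length(goal_names)), goal_names)
    if (!is.null(informed_targets)) w[informed_targets] <- 2
    w / sum(w)
  }
  hmm_submodels <- function(goal_names, truth_of_run) {
    specs <- list()
    for (g in goal_names) {
      in_runs <- which(vapply(seq_along(corpus$runs), function(ri)
        g %in% truth_of_run[[ri]], logical(1)))
      if (length(in_runs) == 0L) next
      specs[[g]] <- estimate_transitions(labels[in_runs])
    }
    specs
  }

  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (cell$strategy == "multiple") {
      goal_space <- meals
      truth_of_run <- lapply(corpus$runs, `[[`, "goal_set")
    } else {
      goal_space <- unique(vapply(corpus$runs, `[[`, character(1), "goal"))
      truth_of_run <- lapply(corpus$runs, function(r) r$goal)
    }
    if (cell$algorithm == "hmm") submodels <- hmm_submodels(goal_space, truth_of_run)
    for (ri in seq_along(corpus$runs)) {
      run <- corpus$runs[[ri]]
      truth <- truth_of_run[[ri]]
      informed <- if (cell$prior == "informed") truth else NULL
      post <- if (cell$algorithm == "hmm") {
        prior <- prior_for(names(submodels), intersect(informed, names(submodels)))
        joint <- build_joint_hmm(submodels, prior)
        as_ccbm_posterior(joint_goal_posterior(joint, run_likelihood(om, run)))
      } else {
        w <- stats::setNames(rep(0, length(gn)), gn)
        w[goal_space] <- 1
        if (!is.null(informed)) w[informed] <- 2
        ccbm_run_posterior(corpus, run, w / sum(w), filter = filter,
                           n_particles = n_particles, seed = seed + ri, om = om)
      }
      if (cell$target == "healthy") {
        pool_of <- function(g) {
          parts <- strsplit(g, "+", fixed = TRUE)[[1]]
          paste(sort(unique(kitchen_health_pool(parts))), collapse = "+")
        }
        pm <- stats::setNames(vapply(post$goals, pool_of, character(1)), post$goals)
        post <- pool_posterior(post, pm)
        truth <- unique(vapply(truth, pool_of, character(1)))
      }
      value <- if (cell$strategy == "multiple") {
        multigoal_estimate(post, truth)$performance
      } else {
        as.numeric(pooled_goal_recognised(post, truth))
      }
      rows[[length(rows) + 1L]] <- data.frame(cell = cell$cell, run = ri, value = value)
    }
  }
  structure(list(design = "gr", cells = cells, results = do.call(rbind, rows)),
            class = "ccbm_factorial")
}

#' @export
print.ccbm_factorial <- function(x, ...) {
  cat("ccbm_factorial (", x$design, "): ", nrow(x$cells), " cells\n", sep = "")
  agg <- stats::aggregate(x$results[[3]], by = list(cell = x$results$cell), FUN = mean)
  names(agg)[2] <- "mean"
  print(agg)
  invisible(x)
}

#' Paired comparison of two cells
#'
#' Wilcoxon signed-rank test on paired per-run values.  When every pair is
#' tied the test is degenerate; a statistic of 0 and p-value of 1 are
#' returned with a note.
#'
#' @param a,b Equal-length numeric vectors of per-run results.
#' @return List with \code{statistic}, \code{p.value} and optional
#'   \code{note}.
#' @export
paired_compare <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (all(a == b))
    return(list(statistic = 0, p.value = 1, note = "all pairs tied"))
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
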