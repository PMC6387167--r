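#' Observation model specification
#'
#' @param protocol \code{"optimistic"} (train = test corpus) or
#'   \code{"pessimistic"} (train on the designated first run only).
#' @param features Optional character vector restricting the sensor columns
#'   used; \code{NULL} uses all columns.
#' @param alpha Laplace smoothing added to each class count in leaves
#'   (default 1).
#' @param max_depth,min_split Tree growth limits (defaults: unlimited depth,
#'   split nodes with at least 2 rows).
#' @return Object of class \code{ccbm_om_spec}.
#' @export
observation_spec <- function(protocol = c("optimistic", "pessimistic"),
                             features = NULL, alpha = 1,
                             max_depth = Inf, min_split = 2L) {
  structure(list(protocol = match.arg(protocol), features = features,
                 alpha = alpha, max_depth = max_depth, min_split = min_split),
            class = "ccbm_om_spec")
}

# Gini impurity from integer class counts (exact, order independent)
gini_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Deterministic CART: Gini criterion, thresholds at midpoints of consecutive
# distinct sorted values, ties broken by feature (column) order then smallest
# threshold.  All statistics are computed from class counts, so the fitted
# tree is invariant to row permutation.
fit_tree <- function(X, y, classes, max_depth = Inf, min_split = 2L) {
  X <- as.data.frame(X)
  y <- factor(as.character(y), levels = classes)
  stopifnot(!anyNA(y))
  build <- function(idx, depth) {
    counts <- table(y[idx])
    node_gini <- gini_from_counts(counts)
    if (length(idx) < min_split || depth >= max_depth || node_gini == 0)
      return(list(leaf = TRUE, counts = counts))
    best <- NULL
    for (f in names(X)) {
      v <- X[[f]][idx]
      ord <- order(v)
      vs <- v[ord]; ys <- y[idx][ord]
      distinct <- which(diff(vs) > 0)
      if (length(distinct) == 0L) next
      # cumulative class counts along the sorted order
      onehot <- outer(as.integer(ys), seq_along(classes), `==`) * 1L
      cum <- apply(onehot, 2, cumsum)
      total <- counts
      for (cut in distinct) {
        left <- cum[cut, ]
        right <- as.numeric(total) - left
        nl <- sum(left); nr <- sum(right)
        imp <- (nl * gini_from_counts(left) + nr * gini_from_counts(right)) / length(idx)
        gain <- node_gini - imp
        thr <- (vs[cut] + vs[cut + 1L]) / 2
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12))
          best <- list(feature = f, threshold = thr, gain = gain)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, counts = counts))
    go_left <- X[[best$feature]][idx] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = build(idx[go_left], depth + 1L),
         right = build(idx[!go_left], depth + 1L))
  }
  build(seq_along(y), 0L)
}

tree_route <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
  }
  node$counts
}

#' Train the decision-tree observation model
#'
#' Fits a deterministic CART classifier mapping windowed sensor vectors to
#' action-class distributions.  Under the optimistic protocol the model is
#' trained on all supplied runs (and later tested on the same corpus); under
#' the pessimistic protocol it is trained on the first run only.
#'
#' @param runs List of data.frames, one per run, each holding the sensor
#'   feature columns plus a \code{label} column with the action class.
#' @param spec A \code{ccbm_om_spec}.
#' @param classes Character vector of all action classes the model must emit
#'   (classes absent from the training data receive the smoothed floor
#'   probability; a warning records them).
#' @return Object of class \code{ccbm_om}.
#' @export
train_observation_model <- function(runs, spec = observation_spec(),
                                    classes = NULL) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  train <- if (spec$protocol == "pessimistic") runs[[1L]] else do.call(rbind, runs)
  stopifnot("label" %in% names(train))
  feats <- spec$features
  if (is.null(feats)) feats <- setdiff(names(train), "label")
  missing <- setdiff(feats, names(train))
  if (length(missing))
    stop(sprintf("feature(s) not in training data: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(unlist(lapply(runs, function(r) r$label))))
  absent <- setdiff(classes, unique(train$label))
  if (length(absent))
    warning(sprintf("class(es) absent from training data (floor mass only): %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  tree <- if (length(feats) == 0L) {
    list(leaf = TRUE, counts = table(factor(train$label, levels = classes)))
  } else {
    fit_tree(train[feats], train$label, classes,
             max_depth = spec$max_depth, min_split = spec$min_split)
  }
  structure(list(tree = tree, features = feats, classes = classes,
                 alpha = spec$alpha, spec = spec, absent = absent),
            class = "ccbm_om")
}

#' Per-step class distribution of the observation model
#'
#' Routes feature vectors through the fitted tree and returns Laplace
#' smoothed leaf class frequencies: (count + alpha) / (n + alpha * K).
#' A pure function of its inputs.
#'
#' @param model A \code{ccbm_om}.
#' @param features Data.frame (one row per time step) or single named vector
#'   covering the model's feature subset.
#' @return Matrix (steps x classes) of probabilities, rows summing to 1.
#' @export
class_distribution <- function(model, features) {
  stopifnot(inherits(model, "ccbm_om"))
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  missing <- setdiff(model$features, names(features))
  if (length(missing))
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  K <- length(model$classes)
  out <- matrix(NA_real_, nrow(features), K, dimnames = list(NULL, model$classes))
  for (i in seq_len(nrow(features))) {
    counts <- tree_route(model$tree, features[i, , drop = FALSE])
    out[i, ] <- (as.numeric(counts) + model$alpha) / (sum(counts) + model$alpha * K)
  }
  out
}

#' Likelihood weight of a CCBM state under an observed class distribution
#'
#' The observation likelihood factorises into an action term and an
#' environment term, P(Z|A) * P(W|S).  The action term is the observed
#' distribution's mass on the state's action class; the environment term
#' defaults to 1 (uninformative) because the learned model emits only action
#' class distributions, but a user-supplied hook may score the world state.
#'
#' @param dist Named probability vector over action classes (one row of
#'   [class_distribution()]).
#' @param class Action class of the state's current action.
#' @param env_likelihood Optional function(world_state) returning P(W|S);
#'   ignored when \code{world} is NULL.
#' @param world Optional world state passed to \code{env_likelihood}.
#' @return Non-negative likelihood weight.
#' @export
state_weight <- function(dist, class, env_likelihood = NULL, world = NULL) {
  if (!class %in% names(dist))
    stop(sprintf("class '%s' missing from distribution", class), call. = FALSE)
  z <- dist[[class]]
  w <- 1
  if (!is.null(env_likelihood) && !is.null(world)) w <- env_likelihood(world)
  z * w
}

#' Serialise / load an observation model as structured text
#'
#' @param model A \code{ccbm_om}.
#' @param path File path (JSON).
#' @export
write_observation_model <- function(model, path) {
  ser <- function(node) {
    if (node$leaf) list(leaf = TRUE, counts = as.list(node$counts))
    else list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
              left = ser(node$left), right = ser(node$right))
  }
  jsonlite::write_json(list(features = model$features, classes = model$classes,
                            alpha = model$alpha, tree = ser(model$tree)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observation_model
#' @export
read_observation_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(node) {
    if (isTRUE(node$leaf)) {
      counts <- unlist(node$counts)
      list(leaf = TRUE,
           counts = stats::setNames(as.numeric(counts), names(counts)))
    } else {
      list(leaf = FALSE, feature = node$feature, threshold = as.numeric(node$threshold),
           left = de(node$left), right = de(node$right))
    }
  }
  structure(list(tree = de(obj$tree), features = unlist(obj$features),
                 classes = unlist(obj$classes), alpha = as.numeric(obj$alpha),
                 spec = NULL, absent = character(0)),
            class = "ccbm_om")
}

#' Per-class precision/recall report
#'
#' @param model A \code{ccbm_om}.
#' @param windows Data.frame with feature columns and a \code{label} column.
#' @param path Optional CSV output path.
#' @return Data.frame with class, precision, recall, support.
#' @export
observation_report <- function(model, windows, path = NULL) {
  dist <- class_distribution(model, windows[model$features])
  pred <- model$classes[max.col(dist, ties.method = "first")]
  truth <- windows$label
  rows <- lapply(model$classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    data.frame(class = cl,
               precision = if (sum(pred == cl)) tp / sum(pred == cl) else NA_real_,
               recall = if (sum(truth == cl)) tp / sum(truth == cl) else NA_real_,
               support = sum(truth == cl))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
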