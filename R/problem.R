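#' Parse a causal-model description
#'
#' Reads the package's PDDL-like dialect: a sequence of top-level
#' s-expressions declaring a type hierarchy, typed objects, predicate
#' schemas, action templates and initial/goal states.  Supported sections:
#' \code{(:types child - parent ...)}, \code{(:objects name - type ...)},
#' \code{(:predicates (name ?v - type ...) ...)},
#' \code{(:action name :parameters ... :duration ... :precondition ...
#' :effect ... :observation name)}, \code{(:init atom ...)} and
#' \code{(:goal name (and atom ...))}.  Preconditions are conjunctions of
#' possibly negated predicate atoms plus \code{(= ?x ?y)} equality atoms;
#' effects are conjunctions of add/delete atoms.  Unknown clause keywords
#' are rejected.
#'
#' @param text Character scalar holding the model source.
#' @return An object of class \code{ccbm_problem} with the type hierarchy,
#'   objects, predicate schemas, action templates, initial state atoms and
#'   the named goal list.  Call [ground_problem()] to obtain ground actions
#'   and predicates.
#' @seealso [read_problem()] to parse from a file.
#' @export
parse_problem <- function(text) {
  forms <- read_sexprs(text)
  types <- c(object = NA_character_)
  objects <- character(0)
  predicates <- list()
  templates <- list()
  init <- list()
  goals <- list()

  for (form in forms) {
    if (!is.list(form) || length(form) == 0L || !is_atom(form[[1]]))
      stop(sprintf("line %s: expected a section form", form_line(form)), call. = FALSE)
    head <- form[[1]]
    body <- form[-1]
    switch(head,
      ":types" = {
        pairs <- parse_dashed_list(body, form_line(form))
        for (i in seq_len(nrow(pairs))) types[[pairs$name[i]]] <- pairs$parent[i]
      },
      ":objects" = {
        pairs <- parse_dashed_list(body, form_line(form))
        for (i in seq_len(nrow(pairs))) objects[[pairs$name[i]]] <- pairs$parent[i]
      },
      ":predicates" = {
        for (p in body) {
          if (!is.list(p) || !is_atom(p[[1]]))
            stop(sprintf("line %s: malformed predicate schema", form_line(form)), call. = FALSE)
          vars <- parse_typed_vars(p[-1], form_line(p))
          predicates[[p[[1]]]] <- vars$type
        }
      },
      ":action" = {
        templates[[length(templates) + 1L]] <- parse_action(form)
      },
      ":init" = {
        for (a in body) init[[length(init) + 1L]] <- parse_ground_atom(a)
      },
      ":goal" = {
        if (length(body) != 2L || !is_atom(body[[1]]))
          stop(sprintf("line %s: :goal expects a name and a formula", form_line(form)), call. = FALSE)
        goals[[body[[1]]]] <- parse_literal_conjunction(body[[2]], allow_equality = FALSE)$lits
      },
      stop(sprintf("line %s: unknown section '%s'", form_line(form), head), call. = FALSE)
    )
  }

  check_type_forest(types)
  for (ob in names(objects)) {
    if (!objects[[ob]] %in% names(types))
      stop(sprintf("object '%s' has undeclared type '%s'", ob, objects[[ob]]), call. = FALSE)
  }
  for (pn in names(predicates)) {
    for (ty in predicates[[pn]]) {
      if (!ty %in% names(types))
        stop(sprintf("predicate '%s' uses undeclared type '%s'", pn, ty), call. = FALSE)
    }
  }
  for (tpl in templates) validate_template(tpl, predicates)
  for (atom in init) validate_ground_atom(atom, predicates, objects)
  for (gn in names(goals)) {
    for (lit in goals[[gn]]) validate_ground_atom(lit, predicates, objects)
  }

  structure(list(types = types, objects = objects, predicates = predicates,
                 templates = templates, init = init, goals = goals),
            class = "ccbm_problem")
}

#' @rdname parse_problem
#' @param path Path to a UTF-8 model file.
#' @export
read_problem <- function(path) {
  parse_problem(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                      collapse = "\n"))
}

#' @export
print.ccbm_problem <- function(x, ...) {
  cat("ccbm_problem:",
      length(x$templates), "action templates,",
      length(x$objects), "objects,",
      length(x$predicates), "predicate schemas,",
      length(x$goals), "goals\n")
  if (!is.null(x$ground))
    cat("  grounded:", length(x$ground$actions), "actions,",
        length(x$ground$pred_keys), "predicates\n")
  invisible(x)
}

# --- section helpers ---------------------------------------------------------

# "name name - parent name - parent" lists (PDDL style: names may share a dash)
parse_dashed_list <- function(items, line) {
  if (any(!vapply(items, is_atom, logical(1))))
    stop(sprintf("line %s: expected flat 'name - parent' list", line), call. = FALSE)
  items <- unlist(items)
  name <- character(0); parent <- character(0)
  pending <- character(0)
  i <- 1L
  while (i <= length(items)) {
    if (items[i] == "-") {
      if (i == length(items) || length(pending) == 0L)
        stop(sprintf("line %s: dangling '-'", line), call. = FALSE)
      name <- c(name, pending); parent <- c(parent, rep(items[i + 1L], length(pending)))
      pending <- character(0)
      i <- i + 2L
    } else {
      pending <- c(pending, items[i])
      i <- i + 1L
    }
  }
  if (length(pending) > 0L)
    stop(sprintf("line %s: names without a type: %s", line,
                 paste(pending, collapse = ", ")), call. = FALSE)
  data.frame(name = name, parent = parent, stringsAsFactors = FALSE)
}

parse_typed_vars <- function(items, line) {
  pairs <- parse_dashed_list(items, line)
  if (!all(startsWith(pairs$name, "?")))
    stop(sprintf("line %s: variables must start with '?'", line), call. = FALSE)
  data.frame(var = pairs$name, type = pairs$parent, stringsAsFactors = FALSE)
}

parse_atom_form <- function(form) {
  if (!is.list(form) || length(form) == 0L || !all(vapply(form, is_atom, logical(1))))
    stop(sprintf("line %s: malformed atom", form_line(form)), call. = FALSE)
  list(pred = form[[1]], args = as.character(unlist(form[-1])))
}

parse_ground_atom <- function(form) {
  a <- parse_atom_form(form)
  a$positive <- TRUE
  a
}

# A literal is atom | (not atom) | (= ?x ?y) | (not (= ?x ?y)).
parse_literal <- function(form, allow_equality) {
  if (!is.list(form)) stop("malformed literal", call. = FALSE)
  positive <- TRUE
  if (is_atom(form[[1]]) && form[[1]] == "not") {
    if (length(form) != 2L)
      stop(sprintf("line %s: (not ...) takes one argument", form_line(form)), call. = FALSE)
    positive <- FALSE
    form <- form[[2]]
  }
  a <- parse_atom_form(form)
  if (a$pred == "=") {
    if (!allow_equality)
      stop("equality atoms are only allowed in preconditions", call. = FALSE)
    if (length(a$args) != 2L) stop("(= ...) takes two arguments", call. = FALSE)
  }
  a$positive <- positive
  a
}

# Conjunction: single literal or (and lit ...).
parse_literal_conjunction <- function(form, allow_equality) {
  lits <- list(); eqs <- list()
  push <- function(lit) {
    if (lit$pred == "=") eqs[[length(eqs) + 1L]] <<- lit
    else lits[[length(lits) + 1L]] <<- lit
  }
  if (is.list(form) && length(form) > 0L && is_atom(form[[1]]) && form[[1]] == "and") {
    for (sub in form[-1]) push(parse_literal(sub, allow_equality))
  } else {
    push(parse_literal(form, allow_equality))
  }
  list(lits = lits, equalities = eqs)
}

parse_action <- function(form) {
  line <- form_line(form)
  if (length(form) < 2L || !is_atom(form[[2]]))
    stop(sprintf("line %s: :action needs a name", line), call. = FALSE)
  name <- form[[2]]
  rest <- form[-(1:2)]
  allowed <- c(":parameters", ":precondition", ":effect", ":duration", ":observation")
  fields <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[[i]]
    if (!is_atom(key) || !key %in% allowed)
      stop(sprintf("line %s: unknown action clause '%s'", line,
                   if (is_atom(key)) key else "<form>"), call. = FALSE)
    if (i == length(rest))
      stop(sprintf("line %s: clause '%s' missing its value", line, key), call. = FALSE)
    fields[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  params <- if (is.null(fields[[":parameters"]])) {
    data.frame(var = character(0), type = character(0), stringsAsFactors = FALSE)
  } else parse_typed_vars(fields[[":parameters"]], line)
  precond <- if (is.null(fields[[":precondition"]])) list(lits = list(), equalities = list())
             else parse_literal_conjunction(fields[[":precondition"]], allow_equality = TRUE)
  effect <- if (is.null(fields[[":effect"]])) list(lits = list())
            else parse_literal_conjunction(fields[[":effect"]], allow_equality = FALSE)
  duration <- parse_duration(fields[[":duration"]], line)
  observation <- fields[[":observation"]]
  if (!is.null(observation) && !is_atom(observation))
    stop(sprintf("line %s: :observation expects an identifier", line), call. = FALSE)
  list(name = name, params = params, precond = precond,
       effect = effect$lits, duration = duration,
       observation = if (is.null(observation)) name else observation)
}

# :duration (normal MEAN SD | empirical NAME | geometric P | uniform A B)
parse_duration <- function(form, line) {
  if (is.null(form)) return(list(family = "geometric", p = 0.5))
  if (!is.list(form) || !is_atom(form[[1]]))
    stop(sprintf("line %s: malformed :duration", line), call. = FALSE)
  fam <- form[[1]]
  num <- function(k) {
    v <- suppressWarnings(as.numeric(form[[k]]))
    if (is.na(v)) stop(sprintf("line %s: non-numeric duration parameter", line), call. = FALSE)
    v
  }
  switch(fam,
    normal = { stopifnot(length(form) == 3L); list(family = "normal", mean = num(2), sd = num(3)) },
    geometric = { stopifnot(length(form) == 2L); list(family = "geometric", p = num(2)) },
    uniform = { stopifnot(length(form) == 3L); list(family = "uniform", a = num(2), b = num(3)) },
    empirical = { stopifnot(length(form) == 2L); list(family = "empirical", source = form[[2]]) },
    stop(sprintf("line %s: unknown duration family '%s'", line, fam), call. = FALSE)
  )
}

# --- validation --------------------------------------------------------------

check_type_forest <- function(types) {
  for (ty in names(types)) {
    seen <- character(0)
    cur <- ty
    while (!is.na(types[[cur]])) {
      if (cur %in% seen) stop(sprintf("type cycle involving '%s'", ty), call. = FALSE)
      seen <- c(seen, cur)
      parent <- types[[cur]]
      if (!parent %in% names(types))
        stop(sprintf("type '%s' has undeclared parent '%s'", cur, parent), call. = FALSE)
      cur <- parent
    }
    if (cur != "object")
      stop(sprintf("type '%s' does not descend from 'object'", ty), call. = FALSE)
  }
  invisible(TRUE)
}

type_is_a <- function(types, ty, ancestor) {
  while (TRUE) {
    if (ty == ancestor) return(TRUE)
    parent <- types[[ty]]
    if (is.na(parent)) return(FALSE)
    ty <- parent
  }
}

validate_template <- function(tpl, predicates) {
  vars <- tpl$params$var
  check_lit <- function(lit, where) {
    if (lit$pred == "=") {
      bad <- setdiff(lit$args[startsWith(lit$args, "?")], vars)
      if (length(bad)) stop(sprintf("action '%s': unbound variable %s", tpl$name, bad[1]), call. = FALSE)
      return(invisible(TRUE))
    }
    if (!lit$pred %in% names(predicates))
      stop(sprintf("action '%s' %s: undeclared predicate '%s'", tpl$name, where, lit$pred), call. = FALSE)
    if (length(lit$args) != length(predicates[[lit$pred]]))
      stop(sprintf("action '%s' %s: arity mismatch for '%s'", tpl$name, where, lit$pred), call. = FALSE)
    bad <- setdiff(lit$args[startsWith(lit$args, "?")], vars)
    if (length(bad))
      stop(sprintf("action '%s' %s: unbound variable %s", tpl$name, where, bad[1]), call. = FALSE)
    invisible(TRUE)
  }
  for (lit in tpl$precond$lits) check_lit(lit, "precondition")
  for (lit in tpl$precond$equalities) check_lit(lit, "precondition")
  for (lit in tpl$effect) check_lit(lit, "effect")
  invisible(TRUE)
}

validate_ground_atom <- function(atom, predicates, objects) {
  if (!atom$pred %in% names(predicates))
    stop(sprintf("undeclared predicate '%s'", atom$pred), call. = FALSE)
  if (length(atom$args) != length(predicates[[atom$pred]]))
    stop(sprintf("arity mismatch for '%s'", atom$pred), call. = FALSE)
  bad <- setdiff(atom$args, names(objects))
  if (length(bad))
    stop(sprintf("undeclared object '%s' in atom (%s ...)", bad[1], atom$pred), call. = FALSE)
  invisible(TRUE)
}

atom_key <- function(pred, args) {
  if (length(args) == 0L) sprintf("(%s)", pred)
  else sprintf("(%s %s)", pred, paste(args, collapse = " "))
}
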