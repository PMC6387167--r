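# Minimal s-expression reader for the causal-model dialect.
# Atoms are bare symbols (case preserved); ';' starts a comment to end of line.

ccbm_syntax_error <- function(msg, line, col) {
  stop(sprintf("syntax error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

# Tokenise into parens and atoms, tracking line/column for error reporting.
tokenize_sexpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0); types <- character(0); lines <- integer(0); cols <- integer(0)
  line <- 1L; col <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    col <- col + 1L
    if (ch == "\n") { line <- line + 1L; col <- 0L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == ";") { # comment to end of line
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "(" || ch == ")") {
      toks <- c(toks, ch); types <- c(types, if (ch == "(") "lparen" else "rparen")
      lines <- c(lines, line); cols <- c(cols, col)
      i <- i + 1L; next
    }
    # atom: run until whitespace, paren, or comment
    start <- i; startcol <- col
    while (i <= n && !(chars[i] %in% c(" ", "\t", "\r", "\n", "(", ")", ";"))) i <- i + 1L
    col <- col + (i - start - 1L)
    toks <- c(toks, paste(chars[start:(i - 1L)], collapse = ""))
    types <- c(types, "atom"); lines <- c(lines, line); cols <- c(cols, startcol)
  }
  list(token = toks, type = types, line = lines, col = cols)
}

# Parse all top-level forms into nested lists of character atoms.
# Each list node carries attributes "line"/"col" of its opening paren.
read_sexprs <- function(text) {
  tk <- tokenize_sexpr(text)
  pos <- 1L
  ntok <- length(tk$token)
  read_form <- function() {
    if (pos > ntok) ccbm_syntax_error("unexpected end of input", tk$line[ntok], tk$col[ntok])
    ty <- tk$type[pos]
    if (ty == "atom") {
      v <- tk$token[pos]
      pos <<- pos + 1L
      return(v)
    }
    if (ty == "rparen") ccbm_syntax_error("unexpected ')'", tk$line[pos], tk$col[pos])
    # lparen
    ln <- tk$line[pos]; cl <- tk$col[pos]
    pos <<- pos + 1L
    out <- list()
    repeat {
      if (pos > ntok) ccbm_syntax_error("unbalanced '(': missing ')'", ln, cl)
      if (tk$type[pos] == "rparen") { pos <<- pos + 1L; break }
      out[[length(out) + 1L]] <- read_form()
    }
    attr(out, "line") <- ln
    attr(out, "col") <- cl
    out
  }
  forms <- list()
  while (pos <= ntok) forms[[length(forms) + 1L]] <- read_form()
  forms
}

form_line <- function(form) {
  ln <- attr(form, "line")
  if (is.null(ln)) NA_integer_ else ln
}

is_atom <- function(x) is.character(x) && length(x) == 1L
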