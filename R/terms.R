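#' Candidate basis terms
#'
#' A term is one entry of the candidate-function library: a scalar-valued
#' function of the measured state vector `y` and (optionally) the input
#' vector `u`. Supported kinds are the constant `1`, monomials in states
#' and inputs, `sin`/`cos` of a single state, rational terms
#' (a monomial divided by a monomial), and arbitrary custom expressions
#' built from `+ - * / ^ sin cos abs`.
#'
#' Exponent maps are named integer vectors: names are state (or input)
#' indices, values are positive integer powers, e.g. `c("1" = 2, "2" = 1)`
#' for `y1^2*y2`.
#'
#' @param kind one of `"constant"`, `"monomial"`, `"input_monomial"`,
#'   `"trig_sin"`, `"trig_cos"`, `"rational"`, `"custom"`.
#' @param ypow,upow exponent maps for states / inputs (numerator).
#' @param den_ypow,den_upow exponent maps of the denominator (rational
#'   terms only).
#' @param expr for `kind = "custom"`, the expression as a string or an
#'   unevaluated R call; only whitelisted arithmetic is accepted.
#' @return an object of class `odisco_term`.
#' @examples
#' t1 <- term_spec("monomial", ypow = c("1" = 1, "2" = 1))
#' term_to_string(t1)            # "y1*y2"
#' eval_term(t1, y = c(2, 3))    # 6
#' @export
term_spec <- function(kind, ypow = integer(), upow = integer(),
                      den_ypow = integer(), den_upow = integer(),
                      expr = NULL) {
  kind <- match.arg(kind, c("constant", "monomial", "input_monomial",
                            "trig_sin", "trig_cos", "rational", "custom"))
  norm_pow <- function(p, what) {
    if (length(p) == 0) return(integer())
    if (is.null(names(p)) || any(names(p) == ""))
      stop("exponent map for ", what, " must be named by index", call. = FALSE)
    p <- p[p != 0]
    if (length(p) == 0) return(integer())
    idx <- suppressWarnings(as.integer(names(p)))
    if (any(is.na(idx)) || any(idx < 1))
      stop("exponent map names must be positive integer indices", call. = FALSE)
    if (any(p < 0) || any(p != round(p)))
      stop("exponents must be positive integers", call. = FALSE)
    p <- as.integer(p)[order(idx)]
    names(p) <- sort(idx)
    p
  }
  ypow <- norm_pow(ypow, "states")
  upow <- norm_pow(upow, "inputs")
  den_ypow <- norm_pow(den_ypow, "denominator states")
  den_upow <- norm_pow(den_upow, "denominator inputs")
  if (kind %in% c("trig_sin", "trig_cos")) {
    if (length(ypow) != 1 || ypow[[1]] != 1L)
      stop("trig terms take a single state with power 1", call. = FALSE)
  }
  if (kind == "rational" && length(den_ypow) + length(den_upow) == 0)
    stop("rational term needs a denominator", call. = FALSE)
  if (kind == "custom") {
    if (is.character(expr)) expr <- .parse_custom_expr(expr)
    if (!is.language(expr) && !is.numeric(expr))
      stop("custom term needs an expression", call. = FALSE)
    .check_custom_expr(expr)
  }
  structure(list(kind = kind, ypow = ypow, upow = upow,
                 den_ypow = den_ypow, den_upow = den_upow, expr = expr),
            class = "odisco_term")
}

# Allowed AST for custom expressions: arithmetic, sin/cos/abs, y<i>/u<i>
# symbols and numeric literals. Everything else is rejected so a label can
# never smuggle in arbitrary code.
.custom_funs <- c("+", "-", "*", "/", "^", "(", "sin", "cos", "abs")

.parse_custom_expr <- function(s) {
  e <- tryCatch(parse(text = s, keep.source = FALSE),
                error = function(err) stop("cannot parse term '", s, "': ",
                                           conditionMessage(err), call. = FALSE))
  if (length(e) != 1) stop("term '", s, "' is not a single expression", call. = FALSE)
  e[[1]]
}

.check_custom_expr <- function(e) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    if (!grepl("^(y[0-9]+|u[0-9]*)$", as.character(e)))
      stop("symbol '", as.character(e), "' not allowed in a term", call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .custom_funs)
      stop("function '", fn, "' not allowed in a term", call. = FALSE)
    for (i in seq_along(e)[-1]) .check_custom_expr(e[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported construct in term expression", call. = FALSE)
}

.pow_prod <- function(pow, v) {
  out <- 1
  for (i in seq_along(pow)) {
    idx <- as.integer(names(pow)[i])
    if (idx > length(v)) stop("term refers to index ", idx,
                              " beyond vector of length ", length(v), call. = FALSE)
    out <- out * v[[idx]]^pow[[i]]
  }
  out
}

#' Evaluate a basis term at one point
#'
#' @param term an `odisco_term`.
#' @param y numeric state-measurement vector.
#' @param u numeric input vector (may be empty).
#' @return a scalar.
#' @export
eval_term <- function(term, y, u = numeric()) {
  stopifnot(inherits(term, "odisco_term"))
  switch(term$kind,
    constant = 1,
    monomial = ,
    input_monomial = .pow_prod(term$ypow, y) * .pow_prod(term$upow, u),
    trig_sin = sin(y[[as.integer(names(term$ypow))]]),
    trig_cos = cos(y[[as.integer(names(term$ypow))]]),
    rational = {
      den <- .pow_prod(term$den_ypow, y) * .pow_prod(term$den_upow, u)
      if (any(den == 0))
        stop("division by zero evaluating term '", term_to_string(term), "'",
             call. = FALSE)
      .pow_prod(term$ypow, y) * .pow_prod(term$upow, u) / den
    },
    custom = {
      env <- new.env(parent = baseenv())
      for (i in seq_along(y)) assign(paste0("y", i), y[[i]], envir = env)
      if (length(u)) {
        assign("u", u[[1]], envir = env)
        for (i in seq_along(u)) assign(paste0("u", i), u[[i]], envir = env)
      }
      eval(term$expr, env)
    })
}

# Vectorised evaluation over all samples: Y is N x n, U is N x p (or NULL).
# Returns a length-N vector. Used by the batch pipeline.
.eval_term_batch <- function(term, Y, U = NULL) {
  n <- ncol(Y); N <- nrow(Y)
  pows <- function(pow, M, lab) {
    out <- rep.int(1, N)
    for (i in seq_along(pow)) {
      idx <- as.integer(names(pow)[i])
      if (is.null(M) || idx > ncol(M))
        stop("term refers to ", lab, " index ", idx, " not present in data",
             call. = FALSE)
      out <- out * M[, idx]^pow[[i]]
    }
    out
  }
  switch(term$kind,
    constant = rep.int(1, N),
    monomial = ,
    input_monomial = pows(term$ypow, Y, "state") * pows(term$upow, U, "input"),
    trig_sin = sin(Y[, as.integer(names(term$ypow))]),
    trig_cos = cos(Y[, as.integer(names(term$ypow))]),
    rational = {
      den <- pows(term$den_ypow, Y, "state") * pows(term$den_upow, U, "input")
      if (any(den == 0))
        stop("division by zero evaluating term '", term_to_string(term), "'",
             call. = FALSE)
      pows(term$ypow, Y, "state") * pows(term$upow, U, "input") / den
    },
    custom = {
      env <- new.env(parent = baseenv())
      for (i in seq_len(n)) assign(paste0("y", i), Y[, i], envir = env)
      if (!is.null(U) && ncol(U) > 0) {
        assign("u", U[, 1], envir = env)
        for (i in seq_len(ncol(U))) assign(paste0("u", i), U[, i], envir = env)
      }
      v <- eval(term$expr, env)
      if (length(v) == 1) v <- rep.int(v, N)
      v
    })
}

.mono_string <- function(ypow, upow) {
  parts <- character()
  for (i in seq_along(ypow)) {
    idx <- names(ypow)[i]; p <- ypow[[i]]
    parts <- c(parts, if (p == 1) paste0("y", idx) else paste0("y", idx, "^", p))
  }
  for (i in seq_along(upow)) {
    idx <- as.integer(names(upow)[i]); p <- upow[[i]]
    base <- if (idx == 1) "u" else paste0("u", idx)
    parts <- c(parts, if (p == 1) base else paste0(base, "^", p))
  }
  if (length(parts) == 0) "1" else paste(parts, collapse = "*")
}

#' Canonical label of a basis term
#'
#' Labels are stable across runs and round-trip through [parse_term()].
#'
#' @param term an `odisco_term`.
#' @return a string such as `"y1*y2"`, `"sin(y1)"` or `"(y3/y1)^2"`.
#' @export
term_to_string <- function(term) {
  stopifnot(inherits(term, "odisco_term"))
  switch(term$kind,
    constant = "1",
    monomial = ,
    input_monomial = .mono_string(term$ypow, term$upow),
    trig_sin = paste0("sin(y", names(term$ypow), ")"),
    trig_cos = paste0("cos(y", names(term$ypow), ")"),
    rational = {
      # simple y_i^p / y_j^p case gets the compact (yi/yj)^p form
      if (length(term$ypow) == 1 && length(term$upow) == 0 &&
          length(term$den_ypow) == 1 && length(term$den_upow) == 0 &&
          term$ypow[[1]] == term$den_ypow[[1]]) {
        p <- term$ypow[[1]]
        core <- paste0("(y", names(term$ypow), "/y", names(term$den_ypow), ")")
        if (p == 1) core else paste0(core, "^", p)
      } else {
        num <- .mono_string(term$ypow, term$upow)
        den <- .mono_string(term$den_ypow, term$den_upow)
        if (grepl("*", den, fixed = TRUE)) den <- paste0("(", den, ")")
        paste0(num, "/", den)
      }
    },
    custom = paste(deparse(term$expr, width.cutoff = 500), collapse = ""))
}

.parse_monomial_factors <- function(s) {
  # returns list(ypow, upow) or NULL if s is not a plain monomial
  facs <- strsplit(s, "*", fixed = TRUE)[[1]]
  facs <- trimws(facs)
  ypow <- integer(); upow <- integer()
  for (f in facs) {
    m <- regmatches(f, regexec("^(y([0-9]+)|u([0-9]*))(\\^([0-9]+))?$", f))[[1]]
    if (length(m) == 0) return(NULL)
    p <- if (m[6] == "") 1L else as.integer(m[6])
    if (startsWith(m[2], "y")) {
      idx <- m[3]
      ypow[idx] <- (if (idx %in% names(ypow)) ypow[[idx]] else 0L) + p
    } else {
      idx <- if (m[4] == "") "1" else m[4]
      upow[idx] <- (if (idx %in% names(upow)) upow[[idx]] else 0L) + p
    }
  }
  list(ypow = ypow, upow = upow)
}

#' Parse a term label
#'
#' Inverse of [term_to_string()]: recognises the constant, monomial,
#' trigonometric and rational label forms; any other expression over the
#' allowed grammar becomes a custom term.
#'
#' @param label expression string.
#' @return an `odisco_term`.
#' @examples
#' parse_term("y1^2*y2")
#' parse_term("(y3/y1)^2")
#' @export
parse_term <- function(label) {
  s <- gsub(" ", "", label)
  if (s == "1") return(term_spec("constant"))
  m <- regmatches(s, regexec("^(sin|cos)\\(y([0-9]+)\\)$", s))[[1]]
  if (length(m)) {
    pw <- stats::setNames(1L, m[3])
    return(term_spec(if (m[2] == "sin") "trig_sin" else "trig_cos", ypow = pw))
  }
  m <- regmatches(s, regexec("^\\(y([0-9]+)/y([0-9]+)\\)(\\^([0-9]+))?$", s))[[1]]
  if (length(m)) {
    p <- if (m[5] == "") 1L else as.integer(m[5])
    return(term_spec("rational", ypow = stats::setNames(p, m[2]),
                     den_ypow = stats::setNames(p, m[3])))
  }
  mono <- .parse_monomial_factors(s)
  if (!is.null(mono)) {
    kind <- if (length(mono$ypow) == 0 && length(mono$upow) > 0)
      "input_monomial" else "monomial"
    if (length(mono$ypow) + length(mono$upow) == 0) kind <- "constant"
    return(term_spec(kind, ypow = mono$ypow, upow = mono$upow))
  }
  # num/den with monomial halves
  if (grepl("/", s, fixed = TRUE)) {
    halves <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(halves) == 2) {
      den_s <- gsub("^\\(|\\)$", "", halves[2])
      num <- .parse_monomial_factors(halves[1])
      den <- .parse_monomial_factors(den_s)
      if (!is.null(num) && !is.null(den))
        return(term_spec("rational", ypow = num$ypow, upow = num$upow,
                         den_ypow = den$ypow, den_upow = den$upow))
    }
  }
  term_spec("custom", expr = s)
}

#' @export
print.odisco_term <- function(x, ...) {
  cat("<term> ", term_to_string(x), "  [", x$kind, "]\n", sep = "")
  invisible(x)
}
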