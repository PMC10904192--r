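#' Candidate-function library specification
#'
#' A library places basis terms into the structured regressor matrix
#' \eqn{\Psi(y, u)} (n_states rows, r columns): each parameter index
#' \eqn{1..r} owns exactly one (state row, term) pair, and entry
#' \eqn{\Psi[j, i]} is the value of term i when it is attached to state
#' equation j (zero elsewhere). In `block_diagonal` mode every state row
#' carries the same ordered term list in a contiguous column block, the
#' layout used by the generic discovery libraries; `structured` mode
#' allows arbitrary placements for systems whose structure is partially
#' known.
#'
#' @param n_states number of state equations (rows of Psi).
#' @param n_inputs number of exogenous inputs.
#' @param placement list of triples `list(row =, index =, term =)` where
#'   `term` is an `odisco_term` or a label string.
#' @param mode `"block_diagonal"` or `"structured"`.
#' @return an object of class `odisco_library` with fields `n_states`,
#'   `n_inputs`, `mode`, `r`, `row`, `index`, `terms`, `labels`.
#' @export
library_spec <- function(n_states, n_inputs = 0, placement,
                         mode = c("block_diagonal", "structured")) {
  mode <- match.arg(mode)
  stopifnot(n_states >= 1, n_inputs >= 0)
  r <- length(placement)
  if (r < 1) stop("placement must contain at least one term", call. = FALSE)
  row <- integer(r); index <- integer(r); terms <- vector("list", r)
  for (i in seq_len(r)) {
    p <- placement[[i]]
    row[i] <- as.integer(p$row)
    index[i] <- as.integer(p$index)
    tm <- if (!is.null(p$term)) p$term else parse_term(p$label)
    if (is.character(tm)) tm <- parse_term(tm)
    if (!inherits(tm, "odisco_term")) stop("invalid term in placement ", i)
    terms[[i]] <- tm
  }
  if (any(row < 1) || any(row > n_states))
    stop("placement rows must lie in 1..n_states", call. = FALSE)
  if (!identical(sort(index), seq_len(r)))
    stop("parameter indices must be exactly 1..r, each used once", call. = FALSE)
  ord <- order(index)
  row <- row[ord]; terms <- terms[ord]; index <- seq_len(r)
  if (mode == "block_diagonal") {
    # each state's indices must form one contiguous block, blocks in row order
    for (j in unique(row)) {
      idx <- which(row == j)
      if (any(diff(idx) != 1))
        stop("block_diagonal mode requires contiguous parameter blocks per state",
             call. = FALSE)
    }
    if (is.unsorted(row))
      stop("block_diagonal mode requires blocks ordered by state row", call. = FALSE)
  }
  structure(list(n_states = as.integer(n_states),
                 n_inputs = as.integer(n_inputs),
                 mode = mode, r = r, row = row, index = index,
                 terms = terms,
                 labels = vapply(terms, term_to_string, character(1))),
            class = "odisco_library")
}

#' @export
print.odisco_library <- function(x, ...) {
  cat("<library> ", x$n_states, " states, ", x$n_inputs, " inputs, r = ", x$r,
      " (", x$mode, ")\n", sep = "")
  for (j in seq_len(x$n_states)) {
    i <- which(x$row == j)
    cat("  eq ", j, ": ", paste0("th", x$index[i], ":", x$labels[i],
                                 collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

# ordered per-block term list shared by all generated libraries:
# constant; pure powers then mixed monomials per total degree; sin; cos;
# input powers. A fixed order keeps parameter indices reproducible.
.block_terms <- function(n_states, n_inputs, degree, include_constant,
                         include_trig, include_input_terms) {
  terms <- list()
  if (include_constant) terms <- c(terms, list(term_spec("constant")))
  tuples_of_degree <- function(d) {
    # non-decreasing index tuples of length d over 1..n_states, lex order
    out <- list()
    rec <- function(prefix, start) {
      if (length(prefix) == d) { out[[length(out) + 1]] <<- prefix; return() }
      for (i in start:n_states) rec(c(prefix, i), i)
    }
    rec(integer(), 1L)
    out
  }
  for (d in seq_len(degree)) {
    tl <- tuples_of_degree(d)
    pure <- Filter(function(tp) length(unique(tp)) == 1, tl)
    mixed <- Filter(function(tp) length(unique(tp)) > 1, tl)
    for (tp in c(pure, mixed)) {
      pw <- table(tp)
      terms <- c(terms, list(term_spec("monomial",
                                       ypow = stats::setNames(as.integer(pw),
                                                              names(pw)))))
    }
  }
  if (include_trig) {
    for (i in seq_len(n_states))
      terms <- c(terms, list(term_spec("trig_sin",
                                       ypow = stats::setNames(1L, i))))
    for (i in seq_len(n_states))
      terms <- c(terms, list(term_spec("trig_cos",
                                       ypow = stats::setNames(1L, i))))
  }
  if (include_input_terms && n_inputs > 0) {
    for (i in seq_len(n_inputs))
      for (p in seq_len(min(degree, 2L)))
        terms <- c(terms, list(term_spec("input_monomial",
                                         upow = stats::setNames(p, i))))
  }
  terms
}

#' Generate a block-diagonal polynomial library
#'
#' Every state equation receives the same ordered candidate list: an
#' optional constant, all state monomials up to `degree` (linear terms in
#' ascending state index, then pure powers, then mixed products in
#' lexicographic order), optional `sin`/`cos` of each state, and optional
#' input powers `u, u^2`. The order is fixed so that parameter indices
#' are stable across runs.
#'
#' @param n_states,n_inputs dimensions of the measured system.
#' @param degree maximal total monomial degree (>= 1; degrees above 2 must
#'   be enabled explicitly via `allow_high_degree`).
#' @param include_constant include the constant term 1 in each block.
#' @param include_trig include `sin(yi)`, `cos(yi)` terms.
#' @param include_input_terms include input powers (requires `n_inputs > 0`).
#' @param allow_high_degree permit `degree > 2`.
#' @return an `odisco_library` in block-diagonal mode.
#' @examples
#' lib <- make_polynomial_library(3, degree = 2)  # r = 30
#' lib$r
#' @export
make_polynomial_library <- function(n_states, n_inputs = 0, degree = 2,
                                    include_constant = TRUE,
                                    include_trig = FALSE,
                                    include_input_terms = n_inputs > 0,
                                    allow_high_degree = FALSE) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  if (n_states < 1 || n_inputs < 0) stop("counts must be non-negative", call. = FALSE)
  if (degree > 2 && !allow_high_degree)
    stop("degree > 2 must be enabled explicitly (allow_high_degree = TRUE)",
         call. = FALSE)
  blk <- .block_terms(n_states, n_inputs, degree, include_constant,
                      include_trig, include_input_terms)
  placement <- list(); idx <- 0L
  for (j in seq_len(n_states)) {
    for (tm in blk) {
      idx <- idx + 1L
      placement[[idx]] <- list(row = j, index = idx, term = tm)
    }
  }
  library_spec(n_states, n_inputs, placement, mode = "block_diagonal")
}

#' Assemble the structured regressor matrix
#'
#' Evaluates every placed term at a single measurement point and returns
#' the n_states x r matrix \eqn{\Psi(y, u)}; entries not owned by a
#' placement are zero (block-diagonal sparsity in `block_diagonal` mode).
#'
#' @param lib an `odisco_library`.
#' @param y numeric vector of length `n_states`.
#' @param u numeric vector of length `n_inputs`.
#' @return numeric matrix, `n_states` x `r`.
#' @export
build_psi <- function(lib, y, u = numeric()) {
  stopifnot(inherits(lib, "odisco_library"))
  if (length(y) != lib$n_states)
    stop("y has length ", length(y), ", expected ", lib$n_states, call. = FALSE)
  if (length(u) != lib$n_inputs)
    stop("u has length ", length(u), ", expected ", lib$n_inputs, call. = FALSE)
  P <- matrix(0, lib$n_states, lib$r)
  for (i in seq_len(lib$r))
    P[lib$row[i], i] <- eval_term(lib$terms[[i]], y, u)
  P
}

# batch term values: N x r matrix with column i holding term i evaluated
# at every sample. Shared by run_discovery and excitation_gramian.
.term_values <- function(lib, Y, U = NULL) {
  V <- matrix(0, nrow(Y), lib$r)
  for (i in seq_len(lib$r))
    V[, i] <- .eval_term_batch(lib$terms[[i]], Y, U)
  V
}

#' Libraries used by the bundled benchmark studies
#'
#' Returns the candidate library each benchmark study pairs with its
#' simulator: generic block-diagonal quadratic libraries for the
#' mass-spring-damper (r = 10), Lorenz (r = 30), Lotka-Volterra (r = 20)
#' and linear control (r = 14, with input terms) systems; the Van der Pol
#' library adds the cubic term `y1^2*y2` to each block (r = 12); the
#' Roessler library is structured with linear terms in rows 1-2 and the
#' full 10-term quadratic block in row 3 (r = 16); the magnetic-levitation
#' library is the 5-term structured layout with the rational term
#' `(y3/y1)^2` (r = 5).
#'
#' @param name one of `"msd"`, `"lorenz"`, `"rossler"`, `"lotka_volterra"`,
#'   `"van_der_pol"`, `"linear_control"`, `"maglev"`.
#' @return an `odisco_library`.
#' @export
benchmark_library <- function(name) {
  name <- match.arg(name, c("msd", "lorenz", "rossler", "lotka_volterra",
                            "van_der_pol", "linear_control", "maglev"))
  quad10 <- c("1", "y1", "y2", "y3", "y1^2", "y2^2", "y3^2",
              "y1*y2", "y1*y3", "y2*y3")
  switch(name,
    msd = make_polynomial_library(2, degree = 2, include_constant = FALSE),
    lorenz = make_polynomial_library(3, degree = 2),
    lotka_volterra = make_polynomial_library(2, degree = 2),
    linear_control = make_polynomial_library(2, n_inputs = 1, degree = 2,
                                             include_constant = FALSE,
                                             include_input_terms = TRUE),
    van_der_pol = {
      labs <- c("y1", "y2", "y1^2", "y2^2", "y1*y2", "y1^2*y2")
      placement <- list(); idx <- 0L
      for (j in 1:2) for (lb in labs) {
        idx <- idx + 1L
        placement[[idx]] <- list(row = j, index = idx, label = lb)
      }
      library_spec(2, 0, placement, mode = "block_diagonal")
    },
    rossler = {
      placement <- list(); idx <- 0L
      for (j in 1:2) for (lb in c("y1", "y2", "y3")) {
        idx <- idx + 1L
        placement[[idx]] <- list(row = j, index = idx, label = lb)
      }
      for (lb in quad10) {
        idx <- idx + 1L
        placement[[idx]] <- list(row = 3L, index = idx, label = lb)
      }
      library_spec(3, 0, placement, mode = "structured")
    },
    maglev = {
      placement <- list(
        list(row = 1L, index = 1L, label = "y2"),
        list(row = 2L, index = 2L, label = "1"),
        list(row = 2L, index = 3L, label = "(y3/y1)^2"),
        list(row = 3L, index = 4L, label = "y3"),
        list(row = 3L, index = 5L, label = "u"))
      library_spec(3, 1, placement, mode = "structured")
    })
}

#' Build a library from a short textual specification
#'
#' Accepts either a benchmark name (see [benchmark_library()]) or a
#' generator string of the form `"poly<d>[_const][_trig][_input<p>]"`,
#' e.g. `"poly2_const"` for the full quadratic library with constant.
#'
#' @param spec specification string.
#' @param n_states,n_inputs dimensions (generator strings only).
#' @return an `odisco_library`.
#' @export
library_from_string <- function(spec, n_states = NULL, n_inputs = 0) {
  bench <- c("msd", "lorenz", "rossler", "lotka_volterra", "van_der_pol",
             "linear_control", "maglev")
  if (spec %in% bench) return(benchmark_library(spec))
  m <- regmatches(spec, regexec(
    "^poly([0-9]+)(_const)?(_trig)?(_input)?$", spec))[[1]]
  if (length(m) == 0)
    stop("unknown library specification '", spec, "'", call. = FALSE)
  if (is.null(n_states))
    stop("n_states is required for generator library '", spec, "'", call. = FALSE)
  make_polynomial_library(n_states, n_inputs,
                          degree = as.integer(m[2]),
                          include_constant = m[3] != "",
                          include_trig = m[4] != "",
                          include_input_terms = m[5] != "" && n_inputs > 0)
}

#' Build a library from a configuration list
#'
#' The list holds `n_states`, `n_inputs`, and either a `generator` block
#' (`degree`, `constant`, `trig`, `input_terms`) or an explicit
#' `placement` list of `{row, index, label}` entries plus `mode`.
#'
#' @param x a named list, typically read from a YAML/JSON config file.
#' @return an `odisco_library`.
#' @export
library_from_config <- function(x) {
  .check_keys(x, c("n_states", "n_inputs", "mode", "generator", "placement",
                   "name"), "library")
  if (!is.null(x$name)) return(benchmark_library(x$name))
  n <- x$n_states %||% stop("library config needs n_states", call. = FALSE)
  p <- x$n_inputs %||% 0
  if (!is.null(x$generator)) {
    g <- x$generator
    .check_keys(g, c("degree", "constant", "trig", "input_terms",
                     "allow_high_degree"), "library.generator")
    return(make_polynomial_library(n, p,
      degree = g$degree %||% 2,
      include_constant = isTRUE(g$constant %||% TRUE),
      include_trig = isTRUE(g$trig),
      include_input_terms = isTRUE(g$input_terms %||% (p > 0)),
      allow_high_degree = isTRUE(g$allow_high_degree)))
  }
  if (is.null(x$placement))
    stop("library config needs a generator or a placement list", call. = FALSE)
  library_spec(n, p, x$placement, mode = x$mode %||% "block_diagonal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
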