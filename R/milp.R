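# Solver-agnostic mixed-integer linear model container.  Builders assemble
# variables and constraint rows (sparse index/coefficient pairs), and
# backends or the LP/MPS writers consume the finished object.

#' Construct a MILP model
#'
#' @param var_names Character vector of variable names (unique).
#' @param lb,ub Numeric bounds per variable (`ub` may be `Inf`).
#' @param vtype Character per variable: `"C"` continuous, `"I"` integer,
#'   `"B"` binary.
#' @param obj Numeric objective coefficients (minimised).
#' @param constraints List of rows, each
#'   `list(ind =, val =, sense =, rhs =, name =)` with `sense` one of
#'   `"<="`, `"="`, `">="` and `ind` 1-based variable indices.
#' @param formulation Free-form tag recorded on the model.
#' @return An object of class `milp_model`.
#' @export
milp_model <- function(var_names, lb, ub, vtype, obj, constraints,
                       formulation = "custom") {
  n <- length(var_names)
  stopifnot(!anyDuplicated(var_names),
            length(lb) == n, length(ub) == n, length(vtype) == n,
            length(obj) == n, all(vtype %in% c("C", "I", "B")),
            all(is.finite(obj)))
  for (ct in constraints) {
    stopifnot(length(ct$ind) == length(ct$val),
              all(ct$ind >= 1L & ct$ind <= n),
              ct$sense %in% c("<=", "=", ">="))
  }
  structure(list(var_names = var_names, lb = as.numeric(lb),
                 ub = as.numeric(ub), vtype = vtype, obj = as.numeric(obj),
                 constraints = constraints, formulation = formulation),
            class = "milp_model")
}

#' @export
print.milp_model <- function(x, ...) {
  cat(sprintf("MILP model [%s]: %d variables (%d int/bin), %d constraints\n",
              x$formulation, length(x$var_names),
              sum(x$vtype != "C"), length(x$constraints)))
  invisible(x)
}

#' Number of variables / constraints
#' @param model A `milp_model`.
#' @return Integer count.
#' @export
n_variables <- function(model) length(model$var_names)

#' @rdname n_variables
#' @export
n_constraints <- function(model) length(model$constraints)

# Dense constraint matrix plus row sense/rhs; used by the pure-R backend and
# by tests.  Models in this package are small enough for dense algebra.
constraint_matrix <- function(model) {
  n <- length(model$var_names)
  m <- length(model$constraints)
  A <- matrix(0, m, n)
  sense <- character(m); rhs <- numeric(m)
  for (r in seq_len(m)) {
    ct <- model$constraints[[r]]
    A[r, ct$ind] <- ct$val
    sense[r] <- ct$sense; rhs[r] <- ct$rhs
  }
  list(A = A, sense = sense, rhs = rhs)
}

# Evaluate all constraint rows at a (named or plain) solution vector.
constraint_violations <- function(model, x, tol = 1e-6) {
  bad <- character(0)
  for (ct in model$constraints) {
    lhs <- sum(ct$val * x[ct$ind])
    ok <- switch(ct$sense,
                 "<=" = lhs <= ct$rhs + tol,
                 ">=" = lhs >= ct$rhs - tol,
                 "="  = abs(lhs - ct$rhs) <= tol)
    if (!ok) bad <- c(bad, ct$name %||% "<unnamed>")
  }
  bad
}

lp_num <- function(x) formatC(x, format = "g", digits = 15)

lp_terms <- function(ind, val, names) {
  parts <- character(length(ind))
  for (q in seq_along(ind)) {
    v <- val[q]
    parts[q] <- sprintf("%s %s %s", if (v < 0) "-" else "+",
                        lp_num(abs(v)), names[ind[q]])
  }
  sub("^\\+ ", "", paste(parts, collapse = " "))
}

#' Export a model in CPLEX LP text format
#'
#' @param model A `milp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- model$var_names
  wl <- function(...) writeLines(sprintf(...), con)
  wl("\\ %s formulation, %d vars, %d rows", model$formulation,
     length(nm), length(model$constraints))
  wl("Minimize")
  nz <- which(model$obj != 0)
  objstr <- if (length(nz)) lp_terms(nz, model$obj[nz], nm) else
    sprintf("0 %s", nm[1])
  wl(" obj: %s", objstr)
  wl("Subject To")
  for (r in seq_along(model$constraints)) {
    ct <- model$constraints[[r]]
    wl(" %s: %s %s %s", ct$name %||% sprintf("c%d", r),
       lp_terms(ct$ind, ct$val, nm),
       ct$sense, lp_num(ct$rhs))
  }
  wl("Bounds")
  for (q in seq_along(nm)) {
    u <- if (is.finite(model$ub[q])) lp_num(model$ub[q]) else "+inf"
    wl(" %s <= %s <= %s", lp_num(model$lb[q]), nm[q], u)
  }
  gen <- nm[model$vtype == "I"]; bin <- nm[model$vtype == "B"]
  if (length(gen)) { wl("General"); wl(" %s", paste(gen, collapse = " ")) }
  if (length(bin)) { wl("Binary"); wl(" %s", paste(bin, collapse = " ")) }
  wl("End")
  invisible(path)
}

#' Export a model in free MPS text format
#'
#' @inheritParams write_lp
#' @return `path`, invisibly.
#' @export
write_mps <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  nm <- model$var_names
  rown <- vapply(seq_along(model$constraints), function(r)
    model$constraints[[r]]$name %||% sprintf("c%d", r), character(1))
  wl("NAME %s", model$formulation)
  wl("ROWS")
  wl(" N obj")
  for (r in seq_along(model$constraints))
    wl(" %s %s", c("<=" = "L", "=" = "E", ">=" = "G")[
      model$constraints[[r]]$sense], rown[r])
  # column-major entries; integer columns wrapped in MARKER lines
  entries <- vector("list", length(nm))
  for (q in which(model$obj != 0))
    entries[[q]] <- c(entries[[q]], sprintf("obj %s", lp_num(model$obj[q])))
  for (r in seq_along(model$constraints)) {
    ct <- model$constraints[[r]]
    for (q in seq_along(ct$ind))
      entries[[ct$ind[q]]] <- c(entries[[ct$ind[q]]],
                                sprintf("%s %s", rown[r], lp_num(ct$val[q])))
  }
  wl("COLUMNS")
  intcols <- model$vtype != "C"
  in_int <- FALSE
  for (q in seq_along(nm)) {
    if (intcols[q] && !in_int) {
      wl(" MARKER 'MARKER' 'INTORG'"); in_int <- TRUE
    } else if (!intcols[q] && in_int) {
      wl(" MARKER 'MARKER' 'INTEND'"); in_int <- FALSE
    }
    for (e in entries[[q]]) wl(" %s %s", nm[q], e)
  }
  if (in_int) wl(" MARKER 'MARKER' 'INTEND'")
  wl("RHS")
  for (r in seq_along(model$constraints))
    if (model$constraints[[r]]$rhs != 0)
      wl(" rhs %s %s", rown[r], lp_num(model$constraints[[r]]$rhs))
  wl("BOUNDS")
  for (q in seq_along(nm)) {
    if (model$lb[q] != 0) wl(" LO bnd %s %s", nm[q], lp_num(model$lb[q]))
    if (is.finite(model$ub[q])) wl(" UP bnd %s %s", nm[q], lp_num(model$ub[q]))
  }
  wl("ENDATA")
  invisible(path)
}
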