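# Solver backends behind one surface.  "highs" drives the HiGHS
# branch-and-cut engine through SciPy's milp() interface in a python
# subprocess (model and solution exchanged as JSON); "bb" is a pure-R
# branch-and-bound over boot::simplex LP relaxations, intended for small
# models and for cross-backend agreement checks.

#' Solve a MILP model
#'
#' @param model A [milp_model()].
#' @param backend `"highs"` (default; SciPy/HiGHS via the `python` on PATH)
#'   or `"bb"` (pure-R branch-and-bound, small models only).
#' @param mip_gap Relative optimality gap requested from the backend
#'   (default 0: prove optimality).
#' @param time_limit Optional wall-clock limit in seconds.
#' @param verbose Print backend chatter.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"limit"`), `objective`, `values` (named vector), and `backend`.
#' @export
solve_milp <- function(model,
                       backend = getOption("casevac.solver", "highs"),
                       mip_gap = 0, time_limit = NULL, verbose = FALSE) {
  backend <- match.arg(backend, c("highs", "bb"))
  res <- switch(backend,
                highs = solve_milp_highs(model, mip_gap, time_limit, verbose),
                bb = solve_milp_bb(model))
  res$backend <- backend
  if (res$status == "optimal") {
    names(res$values) <- model$var_names
    # clean residual fractional noise on integer variables
    intv <- model$vtype != "C"
    res$values[intv] <- round(res$values[intv])
    res$objective <- sum(model$obj * res$values)
  }
  res
}

find_python <- function() {
  cand <- getOption("casevac.python", Sys.getenv("CASEVAC_PYTHON", ""))
  if (nzchar(cand)) return(cand)
  for (p in c("python", "python3")) {
    fp <- Sys.which(p)
    if (nzchar(fp)) return(fp)
  }
  stop("no python interpreter found on PATH; the 'highs' backend needs one ",
       "with scipy installed (or use backend = 'bb' for small models)",
       call. = FALSE)
}

solve_milp_highs <- function(model, mip_gap, time_limit, verbose) {
  helper <- system.file("python", "milp_solve.py", package = "casevac")
  if (!nzchar(helper)) stop("bundled solver helper not found", call. = FALSE)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  m <- length(model$constraints)
  rlb <- numeric(m); rub <- numeric(m)
  for (r in seq_len(m)) {
    ct <- model$constraints[[r]]
    rows <- c(rows, rep.int(r - 1L, length(ct$ind)))
    cols <- c(cols, ct$ind - 1L)
    vals <- c(vals, ct$val)
    rlb[r] <- switch(ct$sense, "<=" = -Inf, ct$rhs)
    rub[r] <- switch(ct$sense, ">=" = Inf, ct$rhs)
  }
  payload <- list(
    n = length(model$var_names),
    obj = model$obj,
    lb = model$lb, ub = model$ub,
    integrality = as.integer(model$vtype != "C"),
    A = list(row = rows, col = cols, val = vals, m = m),
    row_lb = rlb, row_ub = rub,
    mip_gap = mip_gap,
    time_limit = if (is.null(time_limit)) -1 else time_limit)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # JSON cannot carry Inf; encode as very large sentinels decoded in python
  payload$ub <- pmin(payload$ub, 1e30)
  payload$row_lb <- pmax(payload$row_lb, -1e30)
  payload$row_ub <- pmin(payload$row_ub, 1e30)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(find_python(), c(helper, fin, fout),
                                  stdout = if (verbose) "" else TRUE,
                                  stderr = if (verbose) "" else TRUE))
  if (!file.exists(fout) || !file.size(fout))
    stop("solver backend failed: ",
         paste(utils::head(out, 20), collapse = "\n"), call. = FALSE)
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  list(status = res$status,
       objective = if (res$status == "optimal") res$objective else NA_real_,
       values = if (res$status == "optimal") as.numeric(res$x) else NULL)
}

# ---- pure-R branch and bound ------------------------------------------------

# LP relaxation via boot::simplex with extra bound rows.  Returns
# list(status, objective, x).  boot::simplex is dense and pure R; adequate
# for the small models this backend is meant for.
solve_lp_boot <- function(obj, A, sense, rhs, lb, ub, maxit = 2000) {
  n <- length(obj)
  # shift to y = x - lb so that all variables are >= 0
  shift <- lb
  rhs <- rhs - as.numeric(A %*% shift)
  A1 <- NULL; b1 <- numeric(0)   # <=
  A2 <- NULL; b2 <- numeric(0)   # >=
  A3 <- NULL; b3 <- numeric(0)   # =
  add <- function(mat, row) if (is.null(mat)) matrix(row, 1) else rbind(mat, row)
  for (r in seq_along(sense)) {
    row <- A[r, ]; b <- rhs[r]
    if (b < 0 && sense[r] != "=") { row <- -row; b <- -b
      sense[r] <- if (sense[r] == "<=") ">=" else "<=" }
    if (sense[r] == "<=") { A1 <- add(A1, row); b1 <- c(b1, b) }
    else if (sense[r] == ">=") { A2 <- add(A2, row); b2 <- c(b2, b) }
    else {
      if (b < 0) { row <- -row; b <- -b }
      A3 <- add(A3, row); b3 <- c(b3, b)
    }
  }
  for (q in seq_len(n)) {
    if (is.finite(ub[q])) {
      row <- numeric(n); row[q] <- 1
      A1 <- add(A1, row); b1 <- c(b1, ub[q] - shift[q])
    }
  }
  if (is.null(A1)) { # boot::simplex mishandles instances without <= rows
    A1 <- matrix(0, 1, n); A1[1, 1] <- 1; b1 <- 1e12
  }
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1,
                  A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                  maxi = FALSE, n.iter = maxit, eps = 1e-10),
    error = function(e) NULL)
  if (is.null(res)) return(list(status = "error"))
  if (res$solved == -1) return(list(status = "infeasible"))
  if (res$solved != 1) return(list(status = "limit"))
  x <- as.numeric(res$soln) + shift
  list(status = "optimal", objective = sum(obj * x), x = x)
}

solve_milp_bb <- function(model, int_tol = 1e-6, node_limit = 20000L) {
  cm <- constraint_matrix(model)
  intv <- which(model$vtype != "C")
  best <- list(objective = Inf, x = NULL)
  nodes <- list(list(lb = model$lb, ub = model$ub))
  explored <- 0L
  while (length(nodes)) {
    node <- nodes[[length(nodes)]]; nodes[[length(nodes)]] <- NULL
    explored <- explored + 1L
    if (explored > node_limit)
      stop("branch-and-bound node limit exceeded; use the 'highs' backend",
           call. = FALSE)
    rel <- solve_lp_boot(model$obj, cm$A, cm$sense, cm$rhs, node$lb, node$ub)
    if (rel$status == "error")
      stop("LP relaxation failed in the pure-R backend", call. = FALSE)
    if (rel$status != "optimal") next
    if (rel$objective >= best$objective - 1e-9) next
    frac <- abs(rel$x[intv] - round(rel$x[intv]))
    if (!length(intv) || max(frac) <= int_tol) {
      x <- rel$x
      x[intv] <- round(x[intv])
      best <- list(objective = sum(model$obj * x), x = x)
      next
    }
    br <- intv[which.max(frac)]
    v <- rel$x[br]
    dn <- node; dn$ub[br] <- floor(v)
    up <- node; up$lb[br] <- ceiling(v)
    nodes <- c(nodes, list(dn, up))
  }
  if (is.null(best$x)) return(list(status = "infeasible",
                                   objective = NA_real_, values = NULL))
  list(status = "optimal", objective = best$objective, values = best$x)
}
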