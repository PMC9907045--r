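## LP backend abstraction.  Every flux computation in the package goes
## through lp_batch(): a list of problems
##   list(c = <numeric n>, lb = <numeric n>, ub = <numeric n>,
##        maximize = <logical>)
## all sharing one steady-state matrix S (A x = 0), solved either by the
## built-in simplex ("simplex") or by SciPy's HiGHS via one python
## subprocess per batch ("scipy").  Batching matters only for "scipy",
## where the subprocess startup dominates.

lp_solvers <- c("simplex", "scipy")

default_solver <- function() getOption("gemvuln.solver", "simplex")

lp_batch <- function(S, problems, solver = default_solver()) {
  solver <- match.arg(solver, lp_solvers)
  if (!length(problems)) return(list())
  if (solver == "simplex") {
    A <- as.matrix(S)
    b <- numeric(nrow(A))
    lapply(problems, function(p)
      simplex_solve(p$c, A, b, p$lb, p$ub, maximize = isTRUE(p$maximize)))
  } else {
    lp_batch_scipy(S, problems)
  }
}

lp_batch_scipy <- function(S, problems) {
  script <- system.file("python", "lp_batch.py", package = "gemvuln")
  if (script == "") stop("lp_batch.py not found in installed package")
  tri <- Matrix::summary(methods::as(S, "TsparseMatrix"))
  payload <- list(
    m = nrow(S), n = ncol(S),
    Ai = as.integer(tri$i - 1L), Aj = as.integer(tri$j - 1L),
    Ax = as.numeric(tri$x),
    problems = lapply(problems, function(p)
      list(c = as.numeric(p$c), lb = as.numeric(p$lb),
           ub = as.numeric(p$ub), maximize = isTRUE(p$maximize))))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout))
    stop("scipy LP backend failed (exit status ", status, ")")
  res <- jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(res, function(r)
    list(status = r$status,
         objective = if (is.null(r$objective)) NA_real_ else as.numeric(r$objective),
         x = if (is.null(r$x)) NULL else as.numeric(unlist(r$x))))
}

## TRUE if the scipy backend can run in this environment.
scipy_available <- function() {
  if (!nzchar(Sys.which("python"))) return(FALSE)
  ok <- tryCatch(system2("python", c("-c", shQuote("import scipy.optimize")),
                         stdout = FALSE, stderr = FALSE) == 0,
                 error = function(e) FALSE)
  isTRUE(ok)
}
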