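#' Default gamma grid for sweeps
#'
#' A grid dense enough to show the plateau of the dead set on \[0, 1)
#' and the jumps at the endpoints: 0, 0.1, ..., 0.9, 0.95, 0.99, 1.
#' @export
default_gamma_grid <- function() c(seq(0, 0.9, by = 0.1), 0.95, 0.99, 1)

#' Vulnerability sets across a grid of growth fractions
#'
#' Computes the flux-dependent baseline (raw bounds) and, for every
#' gamma in `gammas`, the growth-dependent sets.  The per-reaction
#' knockout LPs do not depend on gamma, so they are solved once and
#' shared across the whole grid.
#'
#' @inheritParams growth_dependent_sets
#' @param gammas numeric vector of growth fractions in \[0, 1\].
#' @return an object of class `gamma_sweep`: list with `gammas`,
#'   `baseline` (a `vulnerability_report` with `gamma = NA`),
#'   `reports` (one `vulnerability_report` per gamma), `sizes` (a
#'   data.frame of set sizes, baseline row first) and `mu_max`.
#' @export
run_sweep <- function(model, gammas = default_gamma_grid(),
                      solver = default_solver(), epsilon = 1e-6,
                      include_boundary = FALSE) {
  stopifnot(inherits(model, "cbm"))
  if (!length(gammas)) stop("gammas must be a non-empty vector in [0,1]")
  if (any(gammas < 0 | gammas > 1)) stop("gammas must lie in [0,1]")
  gammas <- sort(unique(as.numeric(gammas)))
  growths <- knockout_growth_all(model, solver = solver)
  baseline <- flux_dependent_sets(model, solver = solver, epsilon = epsilon,
                                  include_boundary = include_boundary,
                                  growths = growths)
  mu <- max_growth(model, gamma = 1, solver = solver,
                   epsilon = epsilon)$mu_max
  reports <- lapply(gammas, function(g) {
    ctx <- structure(list(mu_max = mu, gamma = g, flux = NULL),
                     class = "growth_context")
    growth_dependent_sets(model, ctx, solver = solver, epsilon = epsilon,
                          include_boundary = include_boundary,
                          growths = growths)
  })
  names(reports) <- sprintf("%g", gammas)
  sizes <- do.call(rbind, c(list(sweep_sizes_row(baseline, model)),
                            lapply(reports, sweep_sizes_row, model = model)))
  rownames(sizes) <- NULL
  structure(list(gammas = gammas, baseline = baseline, reports = reports,
                 sizes = sizes, mu_max = mu), class = "gamma_sweep")
}

## One summary row; the redundancy column |R - ER - DR| is always
## derived from the membership lists, never counted independently.
sweep_sizes_row <- function(report, model) {
  redundancy <- length(setdiff(model$reactions,
                               union(report$essential,
                                     report$partition$dead)))
  data.frame(
    gamma = if (is.na(report$gamma)) NA_real_ else report$gamma,
    level = if (is.na(report$gamma)) "flux-dependent" else "growth-dependent",
    NR = length(report$partition$non_reversible),
    RR = length(report$partition$reversible),
    DR = length(report$partition$dead),
    CP = length(report$chokepoints),
    DEM = length(report$dead_end_metabolites),
    ER = length(report$essential),
    blocked = length(report$blocked),
    redundancy = redundancy,
    stringsAsFactors = FALSE)
}

#' @method print gamma_sweep
#' @export
print.gamma_sweep <- function(x, ...) {
  cat("Gamma sweep over", length(x$gammas), "growth fractions",
      sprintf("(mu_max = %g)\n", x$mu_max))
  print(x$sizes, row.names = FALSE)
  invisible(x)
}
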