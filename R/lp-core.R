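#' Maximal growth rate (FBA)
#'
#' Solves the flux balance problem max v\[r_g\] subject to S v = 0 and
#' L <= v <= U, returning the optimum mu_max together with the gamma
#' fraction to be used by downstream growth-dependent analyses.
#'
#' @param model a `cbm` model with its objective reaction set.
#' @param gamma growth fraction in \[0, 1\] recorded in the returned
#'   context (used by [fva()] and [growth_dependent_sets()]).
#' @param solver LP backend, `"simplex"` (built-in) or `"scipy"`.
#' @param epsilon zero tolerance on fluxes; a maximal growth below
#'   `epsilon` is treated as zero growth.
#' @return an object of class `growth_context` with fields `mu_max`,
#'   `gamma`, and `flux` (one optimal flux vector).
#' @export
max_growth <- function(model, gamma = 1, solver = default_solver(),
                       epsilon = 1e-6) {
  stopifnot(inherits(model, "cbm"))
  if (is.na(model$objective))
    stop("model has no growth objective; use set_objective()")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0,1]")
  c_obj <- as.numeric(model$reactions == model$objective)
  res <- lp_batch(model$S, list(list(c = c_obj, lb = model$lower,
                                     ub = model$upper, maximize = TRUE)),
                  solver)[[1]]
  if (res$status == "infeasible")
    stop("model is infeasible: flux bounds admit no steady state")
  if (res$status == "unbounded")
    stop("growth is unbounded: an exchange reaction lacks a finite bound")
  mu <- res$objective
  if (abs(mu) < epsilon) mu <- 0
  structure(list(mu_max = mu, gamma = gamma, flux = res$x),
            class = "growth_context")
}

#' @method print growth_context
#' @export
print.growth_context <- function(x, ...) {
  cat(sprintf("Growth context: mu_max = %g, gamma = %g\n", x$mu_max, x$gamma))
  invisible(x)
}

#' Maximal growth after a single reaction knockout
#'
#' Solves the FBA problem with the additional constraint v\[r\] = 0
#' (implemented by pinning both flux bounds of r to zero).  An
#' infeasible knockout problem is reported as such, since essentiality
#' counts infeasibility as loss of growth.
#'
#' @inheritParams max_growth
#' @param r reaction identifier to knock out.
#' @return a list with `status` (`"optimal"` or `"infeasible"`) and
#'   `growth` (the optimum, `NA` if infeasible).
#' @export
knockout_growth <- function(model, r, solver = default_solver()) {
  check_reaction(model, r)
  knockout_growth_all(model, r, solver = solver)[[r]]
}

## Knockout growths for several reactions in one LP batch.  Returns a
## named list of list(status=, growth=).  The LPs do not depend on
## gamma, so growth-dependent essential sets at every gamma can be read
## off one batch.
knockout_growth_all <- function(model, reactions = model$reactions,
                                solver = default_solver()) {
  stopifnot(inherits(model, "cbm"))
  if (is.na(model$objective))
    stop("model has no growth objective; use set_objective()")
  for (r in reactions) check_reaction(model, r)
  c_obj <- as.numeric(model$reactions == model$objective)
  probs <- lapply(reactions, function(r) {
    lb <- model$lower; ub <- model$upper
    i <- match(r, model$reactions)
    if (lb[i] > 0 || ub[i] < 0) {
      ## 0 outside [L,U]: the knockout LP is trivially infeasible
      lb[i] <- 1; ub[i] <- 0   # flagged; solver reports infeasible
    } else lb[i] <- ub[i] <- 0
    list(c = c_obj, lb = lb, ub = ub, maximize = TRUE)
  })
  ## bounds lb>ub are rejected by the backends up-front, so pre-mark them
  res <- vector("list", length(reactions))
  names(res) <- reactions
  solvable <- vapply(probs, function(p) all(p$lb <= p$ub), logical(1))
  if (any(solvable)) {
    sols <- lp_batch(model$S, probs[solvable], solver)
    res[solvable] <- lapply(sols, function(s)
      if (s$status == "optimal") list(status = "optimal", growth = s$objective)
      else list(status = "infeasible", growth = NA_real_))
  }
  res[!solvable] <- list(list(status = "infeasible", growth = NA_real_))
  res
}

#' Flux variability analysis with a growth floor
#'
#' For every reaction r, computes the minimum and maximum of v\[r\]
#' subject to S v = 0, L <= v <= U and the growth floor
#' gamma * mu_max <= v\[r_g\].  At gamma = 0 (or when mu_max = 0) the
#' floor is vacuous and the result equals the blocked-reaction LPs.
#' Bounds with absolute value below `epsilon` are snapped to exactly 0
#' before any classification.
#'
#' @inheritParams max_growth
#' @param ctx a `growth_context` from [max_growth()] on the same model
#'   (carries mu_max and gamma).
#' @return a [flux_bounds()] object tagged with the gamma used.
#' @export
fva <- function(model, ctx, solver = default_solver(), epsilon = 1e-6) {
  stopifnot(inherits(model, "cbm"), inherits(ctx, "growth_context"))
  if (ctx$gamma < 0 || ctx$gamma > 1) stop("gamma must be in [0,1]")
  lb <- model$lower; ub <- model$upper
  gi <- match(model$objective, model$reactions)
  if (ctx$mu_max > 0) {
    if (ctx$gamma > 0)
      lb[gi] <- max(lb[gi], ctx$gamma * ctx$mu_max)
  } else if (ctx$gamma > 0) {
    warning("mu_max is numerically zero; gamma floor has no effect ",
            "(treating as gamma = 0)")
  }
  n <- length(model$reactions)
  probs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    ci <- as.numeric(seq_len(n) == i)
    probs[[2L * i - 1L]] <- list(c = ci, lb = lb, ub = ub, maximize = FALSE)
    probs[[2L * i]] <- list(c = ci, lb = lb, ub = ub, maximize = TRUE)
  }
  sols <- lp_batch(model$S, probs, solver)
  bad <- vapply(sols, function(s) s$status != "optimal", logical(1))
  if (any(bad))
    stop("FVA subproblem not optimal (status: ",
         sols[[which(bad)[1]]]$status,
         "); this indicates solver tolerance trouble")
  lo <- vapply(seq_len(n), function(i) sols[[2L * i - 1L]]$objective, 0)
  hi <- vapply(seq_len(n), function(i) sols[[2L * i]]$objective, 0)
  lo[abs(lo) < epsilon] <- 0
  hi[abs(hi) < epsilon] <- 0
  swap <- lo > hi
  if (any(swap)) { tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp }
  names(lo) <- names(hi) <- model$reactions
  flux_bounds(lo, hi, gamma = ctx$gamma)
}
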