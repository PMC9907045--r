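#' Construct a constraint-based metabolic model
#'
#' A constraint-based model is the tuple \{R, M, S, L, U\}: a set of
#' reactions R, a set of metabolites M, the |M| x |R| stoichiometric
#' matrix S, and per-reaction lower/upper flux bounds L and U (in
#' mmol gDW^-1 h^-1).  Negative entries of S mark reactants, positive
#' entries mark products.  One reaction may be designated as the growth
#' (biomass) objective r_g; its lower bound is assumed non-negative and
#' is clamped to 0 with a warning if it is not.
#'
#' @param S stoichiometric matrix, metabolites in rows, reactions in
#'   columns; coerced to a sparse `Matrix::dgCMatrix`.  Row and column
#'   names are used as identifiers when `metabolites`/`reactions` are
#'   not given.
#' @param lower,upper numeric flux bound vectors, one entry per reaction.
#' @param reactions,metabolites character identifier vectors; must be
#'   unique.
#' @param objective identifier of the growth reaction, or `NA` if the
#'   model has no objective (yet).
#' @param boundary character vector of metabolite ids flagged as
#'   external/boundary; these have no enforced mass balance and are by
#'   default excluded from chokepoint and dead-end computations.
#' @param orphaned character vector of reaction ids whose stoichiometry
#'   was emptied by metabolite removal (kept so that R stays stable).
#' @return an object of class `cbm`.
#' @examples
#' S <- matrix(c(1, -1), nrow = 1,
#'             dimnames = list("A", c("ex_A", "rg")))
#' m <- cbm(S, lower = c(0, 0), upper = c(10, 1000), objective = "rg")
#' max_growth(m)$mu_max
#' @export
cbm <- function(S, lower, upper, reactions = colnames(S),
                metabolites = rownames(S), objective = NA_character_,
                boundary = character(), orphaned = character()) {
  S <- methods::as(methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(reactions)) reactions <- sprintf("r%d", seq_len(ncol(S)))
  if (is.null(metabolites)) metabolites <- sprintf("m%d", seq_len(nrow(S)))
  reactions <- as.character(reactions)
  metabolites <- as.character(metabolites)
  if (anyDuplicated(reactions)) stop("duplicate reaction identifiers")
  if (anyDuplicated(metabolites)) stop("duplicate metabolite identifiers")
  if (length(reactions) != ncol(S)) stop("length(reactions) != ncol(S)")
  if (length(metabolites) != nrow(S)) stop("length(metabolites) != nrow(S)")
  if (length(lower) != ncol(S) || length(upper) != ncol(S))
    stop("flux bound vectors must have one entry per reaction")
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(lower > upper + 1e-12)) {
    bad <- reactions[lower > upper + 1e-12]
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  dimnames(S) <- list(metabolites, reactions)
  names(lower) <- names(upper) <- reactions
  if (!is.na(objective)) {
    if (!objective %in% reactions)
      stop("objective reaction not in model: ", objective)
    if (lower[objective] < 0) {
      warning("lower bound of growth reaction ", objective,
              " is negative; clamping to 0")
      lower[objective] <- 0
    }
  }
  boundary <- intersect(as.character(boundary), metabolites)
  structure(list(reactions = reactions, metabolites = metabolites,
                 S = S, lower = lower, upper = upper,
                 objective = as.character(objective),
                 boundary = boundary,
                 orphaned = intersect(as.character(orphaned), reactions)),
            class = "cbm")
}

#' @method print cbm
#' @export
print.cbm <- function(x, ...) {
  cat("Constraint-based model:", length(x$reactions), "reactions,",
      length(x$metabolites), "metabolites\n")
  cat("  objective:",
      if (is.na(x$objective)) "<unset>" else x$objective, "\n")
  if (length(x$boundary))
    cat("  boundary metabolites:", length(x$boundary), "\n")
  if (length(x$orphaned))
    cat("  orphaned reactions:", length(x$orphaned), "\n")
  invisible(x)
}

#' @export
dim.cbm <- function(x) dim(x$S)

#' Set the growth objective of a model
#'
#' @param model a `cbm` model.
#' @param reaction reaction identifier to use as growth objective.
#' @return the model with the objective set (and `L[r_g]` clamped to be
#'   non-negative, with a warning, if needed).
#' @export
set_objective <- function(model, reaction) {
  stopifnot(inherits(model, "cbm"))
  check_reaction(model, reaction)
  model$objective <- reaction
  if (model$lower[reaction] < 0) {
    warning("lower bound of growth reaction ", reaction,
            " is negative; clamping to 0")
    model$lower[reaction] <- 0
  }
  model
}

check_reaction <- function(model, r) {
  if (!is.character(r) || length(r) != 1L || !r %in% model$reactions)
    stop("unknown reaction: ", r)
  invisible(r)
}

check_metabolite <- function(model, m) {
  if (!is.character(m) || length(m) != 1L || !m %in% model$metabolites)
    stop("unknown metabolite: ", m)
  invisible(m)
}

## Non-boundary metabolites considered for chokepoint/DEM computation.
internal_metabolites <- function(model, include_boundary = FALSE) {
  if (include_boundary) model$metabolites
  else setdiff(model$metabolites, model$boundary)
}

#' Structural producers and consumers of a metabolite
#'
#' Topology-only accessors: the producers of a metabolite m are the
#' reactions with a positive stoichiometric entry for m, the consumers
#' those with a negative entry.  Flux bounds are ignored; see
#' [star_producers()] for the flux-aware variants.
#'
#' @param model a `cbm` model.
#' @param m metabolite identifier.
#' @return character vector of reaction ids.
#' @export
structural_producers <- function(model, m) {
  check_metabolite(model, m)
  row <- model$S[m, ]
  model$reactions[row > 0]
}

#' @rdname structural_producers
#' @export
structural_consumers <- function(model, m) {
  check_metabolite(model, m)
  row <- model$S[m, ]
  model$reactions[row < 0]
}

#' Per-reaction flux bounds, possibly FVA-derived
#'
#' A light container for a pair of per-reaction bound vectors; when the
#' bounds come from FVA at a growth fraction gamma, that gamma is
#' recorded.
#'
#' @param lower,upper numeric vectors of equal length; `lower <= upper`
#'   within `tol`.
#' @param gamma optional growth fraction in \[0, 1\] that produced the
#'   bounds, or `NA` for raw bounds.
#' @param tol numeric tolerance for the `lower <= upper` check.
#' @return an object of class `flux_bounds`.
#' @export
flux_bounds <- function(lower, upper, gamma = NA_real_, tol = 1e-6) {
  if (length(lower) != length(upper)) stop("bound vectors differ in length")
  if (any(lower > upper + tol)) stop("lower bound exceeds upper bound")
  if (!is.na(gamma) && (gamma < 0 || gamma > 1)) stop("gamma must be in [0,1]")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 gamma = gamma), class = "flux_bounds")
}

#' @method print flux_bounds
#' @export
print.flux_bounds <- function(x, ...) {
  cat("Flux bounds for", length(x$lower), "reactions",
      if (!is.na(x$gamma)) sprintf("(FVA, gamma = %g)", x$gamma) else "(raw)",
      "\n")
  invisible(x)
}

#' Replace the flux bounds of a model
#'
#' Returns a copy of the model with L and U replaced by the given
#' bounds, e.g. the FVA-derived bounds lb_gamma/ub_gamma, producing the
#' growth-constrained model \{R, M, S, lb_gamma, ub_gamma\}.  The input
#' model is not modified.
#'
#' @param model a `cbm` model.
#' @param bounds a [flux_bounds()] object whose length matches the
#'   number of reactions.
#' @return a new `cbm` model.
#' @export
apply_bounds <- function(model, bounds) {
  stopifnot(inherits(model, "cbm"), inherits(bounds, "flux_bounds"))
  n <- length(model$reactions)
  if (length(bounds$lower) != n)
    stop("bounds dimension (", length(bounds$lower),
         ") does not match number of reactions (", n, ")")
  out <- model
  out$lower[] <- pmin(bounds$lower, bounds$upper)
  out$upper[] <- bounds$upper
  ## clamp again: an FVA floor can pin the objective above 0, never below
  if (!is.na(out$objective) && out$lower[out$objective] < 0 &&
      model$lower[model$objective] >= 0)
    out$lower[out$objective] <- max(out$lower[out$objective], 0)
  out
}
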