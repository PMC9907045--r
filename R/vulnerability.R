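## Flux-dependent star-set masks over all (metabolite, reaction) pairs.
## A reaction with U > eps can run forwards, one with L < -eps can run
## backwards; reactants and products follow from the sign of S in the
## allowed directions.  Returns logical sparse matrices (as dgCMatrix
## patterns via triplets) for "m is reactant of r" and "m is product
## of r".
star_masks <- function(model, epsilon = 1e-6) {
  tri <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
  fwd <- model$upper[tri$j] > epsilon    # reaction can run forwards
  bwd <- model$lower[tri$j] < -epsilon   # reaction can run backwards
  neg <- tri$x < 0
  pos <- tri$x > 0
  reactant <- (neg & fwd) | (pos & bwd)
  product <- (pos & fwd) | (neg & bwd)
  list(i = tri$i, j = tri$j, reactant = reactant, product = product)
}

#' Flux-dependent reactant/product and producer/consumer sets
#'
#' The star-sets account for both flux directions a reaction's bounds
#' allow: a metabolite with negative stoichiometry is a reactant when
#' the upper bound is positive, and also a product when the lower bound
#' is negative (the reaction can run in reverse).  Strict sign tests use
#' the tolerance `epsilon`.  A dead reaction (L = U = 0) has empty
#' star-sets.
#'
#' `star_consumers(m)` is the set of reactions having m among their
#' star-reactants; `star_producers(m)` the set having m among their
#' star-products.
#'
#' @param model a `cbm` model.
#' @param r reaction identifier.
#' @param m metabolite identifier.
#' @param epsilon strictness tolerance for sign tests on bounds.
#' @return character vector of metabolite ids (`star_reactants`,
#'   `star_products`) or reaction ids (`star_consumers`,
#'   `star_producers`).
#' @export
star_reactants <- function(model, r, epsilon = 1e-6) {
  check_reaction(model, r)
  j <- match(r, model$reactions)
  sm <- star_masks(model, epsilon)
  sel <- sm$j == j & sm$reactant
  model$metabolites[sm$i[sel]]
}

#' @rdname star_reactants
#' @export
star_products <- function(model, r, epsilon = 1e-6) {
  check_reaction(model, r)
  j <- match(r, model$reactions)
  sm <- star_masks(model, epsilon)
  sel <- sm$j == j & sm$product
  model$metabolites[sm$i[sel]]
}

#' @rdname star_reactants
#' @export
star_consumers <- function(model, m, epsilon = 1e-6) {
  check_metabolite(model, m)
  i <- match(m, model$metabolites)
  sm <- star_masks(model, epsilon)
  sel <- sm$i == i & sm$reactant
  sort(model$reactions[sm$j[sel]])
}

#' @rdname star_reactants
#' @export
star_producers <- function(model, m, epsilon = 1e-6) {
  check_metabolite(model, m)
  i <- match(m, model$metabolites)
  sm <- star_masks(model, epsilon)
  sel <- sm$i == i & sm$product
  sort(model$reactions[sm$j[sel]])
}

#' Chokepoint reactions
#'
#' A chokepoint is a reaction that is the unique producer or the unique
#' consumer of some metabolite.  The flux-dependent variant (default)
#' uses the star-sets, so reversibility and dead bounds are taken into
#' account; the structural variant uses only the sign pattern of the
#' stoichiometric matrix.  Boundary metabolites are excluded unless
#' `include_boundary = TRUE`, since their mass balance is not enforced.
#'
#' @inheritParams star_reactants
#' @param structural if `TRUE`, use topology-only producer/consumer sets.
#' @param include_boundary include boundary metabolites in the search.
#' @return sorted character vector of chokepoint reaction ids.
#' @export
chokepoints <- function(model, epsilon = 1e-6, structural = FALSE,
                        include_boundary = FALSE) {
  stopifnot(inherits(model, "cbm"))
  mets <- internal_metabolites(model, include_boundary)
  if (!length(mets)) return(character())
  mi <- match(mets, model$metabolites)
  if (structural) {
    tri <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
    cons <- tri$x < 0; prod <- tri$x > 0
    ii <- tri$i; jj <- tri$j
  } else {
    sm <- star_masks(model, epsilon)
    cons <- sm$reactant; prod <- sm$product
    ii <- sm$i; jj <- sm$j
  }
  cp <- integer()
  for (k in mi) {
    cj <- unique(jj[ii == k & cons])
    pj <- unique(jj[ii == k & prod])
    if (length(cj) == 1L) cp <- c(cp, cj)
    if (length(pj) == 1L) cp <- c(cp, pj)
  }
  sort(unique(model$reactions[cp]))
}

#' Dead-end metabolites
#'
#' A dead-end metabolite has no producer or no consumer, so its amount
#' can only drift in one direction.  The flux-dependent variant
#' (default) uses star-sets; the structural variant uses the sign
#' pattern of S only.
#'
#' @inheritParams chokepoints
#' @return sorted character vector of metabolite ids.
#' @export
dead_end_metabolites <- function(model, epsilon = 1e-6, structural = FALSE,
                                 include_boundary = FALSE) {
  stopifnot(inherits(model, "cbm"))
  mets <- internal_metabolites(model, include_boundary)
  if (!length(mets)) return(character())
  mi <- match(mets, model$metabolites)
  if (structural) {
    tri <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
    cons <- tri$x < 0; prod <- tri$x > 0
    ii <- tri$i
  } else {
    sm <- star_masks(model, epsilon)
    cons <- sm$reactant; prod <- sm$product
    ii <- sm$i
  }
  has_cons <- mi %in% ii[cons]
  has_prod <- mi %in% ii[prod]
  sort(mets[!(has_cons & has_prod)])
}

#' Partition reactions into dead, reversible and non-reversible
#'
#' A reaction is dead if both bounds are (numerically) zero, reversible
#' if its lower bound is negative and its upper bound positive, and
#' non-reversible otherwise.  The three sets always partition R.
#'
#' @inheritParams star_reactants
#' @return an object of class `reaction_partition`: a list with sorted
#'   character fields `dead`, `reversible`, `non_reversible`.
#' @export
classify_reactions <- function(model, epsilon = 1e-6) {
  stopifnot(inherits(model, "cbm"))
  lo <- model$lower; hi <- model$upper
  dead <- abs(lo) <= epsilon & abs(hi) <= epsilon
  rev <- !dead & lo < -epsilon & hi > epsilon
  structure(list(dead = sort(model$reactions[dead]),
                 reversible = sort(model$reactions[rev]),
                 non_reversible = sort(model$reactions[!dead & !rev])),
            class = "reaction_partition")
}

#' @method print reaction_partition
#' @export
print.reaction_partition <- function(x, ...) {
  cat(sprintf("Reaction partition: %d dead, %d reversible, %d non-reversible\n",
              length(x$dead), length(x$reversible), length(x$non_reversible)))
  invisible(x)
}

#' Essential reactions
#'
#' A reaction is essential if pinning its flux to zero makes the
#' maximal growth zero (or the LP infeasible).  Computed by one
#' knockout LP per reaction.
#'
#' @inheritParams max_growth
#' @return sorted character vector of essential reaction ids.
#' @export
essential_reactions <- function(model, solver = default_solver(),
                                epsilon = 1e-6) {
  g <- knockout_growth_all(model, solver = solver)
  ess <- vapply(g, function(x)
    x$status == "infeasible" || x$growth <= epsilon, logical(1))
  sort(names(g)[ess])
}

## Shared helper: growth-dependent essential set from precomputed
## knockout growths.  Strictly-below test with relative tolerance, so
## gamma = 0 yields the empty set on any feasible model (growth is
## never negative), and knockouts that keep exactly gamma*mu_max are
## not essential.
essential_from_growths <- function(growths, mu_max, gamma,
                                   epsilon_rel = 1e-6) {
  thr <- gamma * mu_max
  ess <- vapply(growths, function(x)
    x$status == "infeasible" || x$growth < thr * (1 - epsilon_rel) -
      .Machine$double.eps, logical(1))
  sort(names(growths)[ess])
}

#' Growth-dependent essential reactions
#'
#' A reaction is essential at growth fraction gamma if its knockout
#' caps the maximal growth strictly below gamma * mu_max (or makes the
#' LP infeasible).  At gamma = 1 this is the set of reactions essential
#' for optimal growth (EROG); at gamma = 0 the set is empty for any
#' feasible model.
#'
#' @inheritParams fva
#' @param epsilon_rel relative tolerance on the strict comparison
#'   against gamma * mu_max.
#' @return sorted character vector of reaction ids.
#' @export
growth_dependent_essential <- function(model, ctx, solver = default_solver(),
                                       epsilon_rel = 1e-6) {
  stopifnot(inherits(ctx, "growth_context"))
  g <- knockout_growth_all(model, solver = solver)
  essential_from_growths(g, ctx$mu_max, ctx$gamma, epsilon_rel)
}

#' Blocked reactions
#'
#' A reaction is blocked if its flux is zero at every steady state,
#' i.e. both its minimum and maximum feasible fluxes under S v = 0 and
#' the raw bounds are zero.  This equals the dead set of the
#' growth-constrained model at gamma = 0.
#'
#' @inheritParams max_growth
#' @return sorted character vector of reaction ids.
#' @export
blocked_reactions <- function(model, solver = default_solver(),
                              epsilon = 1e-6) {
  stopifnot(inherits(model, "cbm"))
  ctx <- structure(list(mu_max = 0, gamma = 0, flux = NULL),
                   class = "growth_context")
  fb <- fva(model, ctx, solver = solver, epsilon = epsilon)
  blocked <- abs(fb$lower) <= epsilon & abs(fb$upper) <= epsilon
  sort(model$reactions[blocked])
}

#' Full growth-dependent vulnerability report
#'
#' Runs FVA at the gamma carried by `ctx`, replaces the model's bounds
#' by the FVA bounds, and computes the dead/reversible/non-reversible
#' partition, chokepoints and dead-end metabolites of the constrained
#' model, together with the growth-dependent essential set and the
#' blocked set.
#'
#' @inheritParams fva
#' @param include_boundary include boundary metabolites in
#'   chokepoint/DEM computation.
#' @param growths optional precomputed result of the per-reaction
#'   knockout LPs (they do not depend on gamma); used by [run_sweep()]
#'   to avoid recomputation.
#' @return an object of class `vulnerability_report` with fields
#'   `chokepoints`, `dead_end_metabolites`, `essential`, `blocked`,
#'   `partition`, `gamma`, `mu_max`, `fva_bounds`.
#' @export
growth_dependent_sets <- function(model, ctx, solver = default_solver(),
                                  epsilon = 1e-6, include_boundary = FALSE,
                                  growths = NULL) {
  stopifnot(inherits(model, "cbm"), inherits(ctx, "growth_context"))
  fb <- fva(model, ctx, solver = solver, epsilon = epsilon)
  constrained <- apply_bounds(model, fb)
  if (is.null(growths))
    growths <- knockout_growth_all(model, solver = solver)
  ess <- essential_from_growths(growths, ctx$mu_max, ctx$gamma)
  part <- classify_reactions(constrained, epsilon)
  blocked <- if (ctx$gamma == 0) part$dead
             else blocked_reactions(model, solver = solver, epsilon = epsilon)
  structure(list(
    chokepoints = chokepoints(constrained, epsilon,
                              include_boundary = include_boundary),
    dead_end_metabolites = dead_end_metabolites(
      constrained, epsilon, include_boundary = include_boundary),
    essential = ess,
    blocked = blocked,
    partition = part,
    gamma = ctx$gamma,
    mu_max = ctx$mu_max,
    fva_bounds = fb), class = "vulnerability_report")
}

#' @method print vulnerability_report
#' @export
print.vulnerability_report <- function(x, ...) {
  lev <- if (is.na(x$gamma)) "flux-dependent (raw bounds)"
         else sprintf("growth-dependent, gamma = %g", x$gamma)
  cat("Vulnerability report [", lev, "]\n", sep = "")
  cat(sprintf("  chokepoints: %d | dead-end metabolites: %d | essential: %d\n",
              length(x$chokepoints), length(x$dead_end_metabolites),
              length(x$essential)))
  cat(sprintf("  dead: %d | reversible: %d | non-reversible: %d | blocked: %d\n",
              length(x$partition$dead), length(x$partition$reversible),
              length(x$partition$non_reversible), length(x$blocked)))
  invisible(x)
}

#' Flux-dependent vulnerability report on the raw bounds
#'
#' The pre-FVA baseline: star-set chokepoints, dead-end metabolites,
#' the DR/RR/NR partition of the raw bounds, the essential set of
#' Def. "knockout kills growth", and the blocked set.
#'
#' @inheritParams growth_dependent_sets
#' @return a `vulnerability_report` with `gamma = NA`.
#' @export
flux_dependent_sets <- function(model, solver = default_solver(),
                                epsilon = 1e-6, include_boundary = FALSE,
                                growths = NULL) {
  stopifnot(inherits(model, "cbm"))
  if (!length(model$reactions))
    return(structure(list(
      chokepoints = character(), dead_end_metabolites = character(),
      essential = character(), blocked = character(),
      partition = classify_reactions(model, epsilon),
      gamma = NA_real_, mu_max = NA_real_, fva_bounds = NULL),
      class = "vulnerability_report"))
  if (is.null(growths))
    growths <- knockout_growth_all(model, solver = solver)
  ess <- vapply(growths, function(x)
    x$status == "infeasible" || x$growth <= epsilon, logical(1))
  structure(list(
    chokepoints = chokepoints(model, epsilon,
                              include_boundary = include_boundary),
    dead_end_metabolites = dead_end_metabolites(
      model, epsilon, include_boundary = include_boundary),
    essential = sort(names(growths)[ess]),
    blocked = blocked_reactions(model, solver = solver, epsilon = epsilon),
    partition = classify_reactions(model, epsilon),
    gamma = NA_real_,
    mu_max = NA_real_,
    fva_bounds = NULL), class = "vulnerability_report")
}

#' Remove dead-end metabolites from a model
#'
#' Iteratively deletes structural dead-end metabolites (no producing or
#' no consuming reaction in the sign pattern of S) and their
#' stoichiometric rows until none remain; removing a metabolite can
#' orphan reactions and expose new dead ends, so the deletion runs to a
#' fixpoint.  Reactions whose reactant and product sets become empty
#' are kept (so the reaction set R stays comparable across models) but
#' recorded in the model's `orphaned` field.
#'
#' @inheritParams chokepoints
#' @return a new `cbm` model without the removed rows; the ids of the
#'   removed metabolites are in `attr(, "removed_metabolites")`.
#' @export
remove_dead_end_metabolites <- function(model, include_boundary = FALSE) {
  stopifnot(inherits(model, "cbm"))
  removed <- character()
  orphaned <- model$orphaned
  cur <- model
  repeat {
    dem <- dead_end_metabolites(cur, structural = TRUE,
                                include_boundary = include_boundary)
    if (!length(dem)) break
    removed <- c(removed, dem)
    ## any reaction touching a dead-end metabolite is blocked (its flux
    ## would change the dead end's amount), so its stoichiometry is
    ## emptied; the reaction itself is kept and flagged, which is what
    ## lets the removal cascade (a metabolite whose only consumer was
    ## such a reaction becomes a dead end on the next pass)
    touched <- cur$reactions[Matrix::colSums(
      abs(cur$S[dem, , drop = FALSE])) > 0]
    keep <- setdiff(cur$metabolites, dem)
    cur$S <- cur$S[keep, , drop = FALSE]
    if (length(touched) && nrow(cur$S))
      cur$S[, touched] <- matrix(0, nrow(cur$S), length(touched))
    cur$metabolites <- keep
    cur$boundary <- intersect(cur$boundary, keep)
    orphaned <- union(orphaned, touched)
  }
  cur$orphaned <- sort(orphaned)
  attr(cur, "removed_metabolites") <- removed
  cur
}
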