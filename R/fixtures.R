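#' Specification for a synthetic test network
#'
#' Describes a small mass-balanceable network: exchange inputs feeding
#' one or more parallel internal pathways into a biomass precursor
#' consumed by the growth reaction.  Optional planted features: a
#' produced-but-never-consumed metabolite (dead end), a reaction with
#' both bounds zero (dead), and reversible internal links.  Generation
#' is deterministic given `seed`.
#'
#' @param n_metabolites,n_reactions minimum numbers of metabolites and
#'   reactions; the generator pads with extra pathway segments and
#'   redundant parallel edges to reach them exactly.
#' @param reversible_fraction fraction of internal pathway reactions
#'   given reversible bounds (-1000, 1000).
#' @param n_parallel_paths number of parallel exchange-to-biomass
#'   routes; more paths mean more redundancy (a larger set of non-dead,
#'   non-essential reactions).
#' @param include_dem plant a dead-end metabolite (produced, never
#'   consumed), whose producing reaction is then blocked.
#' @param include_dead plant a reaction with L = U = 0.
#' @param path_capacities optional numeric vector (recycled to
#'   `n_parallel_paths`) of exchange upper bounds; defaults to random
#'   integers in 1..10.
#' @param seed integer random seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_metabolites = 6, n_reactions = 8,
                         reversible_fraction = 0.25,
                         n_parallel_paths = 2, include_dem = FALSE,
                         include_dead = FALSE, path_capacities = NULL,
                         seed = 1L) {
  stopifnot(n_metabolites >= 2, n_parallel_paths >= 1,
            reversible_fraction >= 0, reversible_fraction <= 1)
  ## minimal structure: per path one exchange + one terminal reaction,
  ## plus the growth reaction
  min_rx <- 2L * n_parallel_paths + 1L + include_dem + include_dead
  if (n_reactions < min_rx)
    stop("n_reactions too small: need at least ", min_rx,
         " for ", n_parallel_paths, " path(s) and planted features")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 reversible_fraction = reversible_fraction,
                 n_parallel_paths = as.integer(n_parallel_paths),
                 include_dem = isTRUE(include_dem),
                 include_dead = isTRUE(include_dead),
                 path_capacities = path_capacities,
                 seed = as.integer(seed)), class = "fixture_spec")
}

## run expr with a locally-seeded RNG, restoring global state
with_fixture_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic constraint-based model
#'
#' Builds the network described by a [fixture_spec()]: feasibility is
#' guaranteed by construction (the exchange-to-biomass paths are laid
#' down first; redundant edges and planted features are added after and
#' cannot break mass balance).  Stoichiometric weights are 1 or 2.
#'
#' @param spec a [fixture_spec()].
#' @return a `cbm` model with objective `"rg"`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    npath <- spec$n_parallel_paths
    caps <- spec$path_capacities
    if (is.null(caps)) caps <- sample(1:10, npath, replace = TRUE)
    caps <- rep_len(caps, npath)

    n_extra <- spec$include_dem + spec$include_dead
    ## metabolites: biomass precursor + path chains (+ planted DEM)
    n_chain_met <- spec$n_metabolites - 1L - spec$include_dem
    if (n_chain_met < npath)
      stop("n_metabolites too small for ", npath, " path(s)")
    ## distribute chain metabolites over paths (each path >= 1)
    per_path <- rep(n_chain_met %/% npath, npath)
    rem <- n_chain_met %% npath
    if (rem > 0) per_path[seq_len(rem)] <- per_path[seq_len(rem)] + 1L

    mets <- "mB"
    rx <- list()   # each: list(id, consume, produce, lb, ub, w)
    add_rx <- function(id, consume, produce, lb, ub, w = 1) {
      rx[[length(rx) + 1L]] <<- list(id = id, consume = consume,
                                     produce = produce, lb = lb, ub = ub,
                                     w = w)
    }
    chain_mets <- list()
    for (p in seq_len(npath)) {
      ms <- sprintf("m%d_%d", p, seq_len(per_path[p]))
      chain_mets[[p]] <- ms
      mets <- c(mets, ms)
      add_rx(sprintf("ex%d", p), NULL, ms[1], 0, caps[p])
      if (per_path[p] > 1)
        for (k in seq_len(per_path[p] - 1L))
          add_rx(sprintf("p%d_%d", p, k), ms[k], ms[k + 1], 0, DEFAULT_BOUND)
      add_rx(sprintf("b%d", p), ms[per_path[p]], "mB", 0, DEFAULT_BOUND)
    }
    add_rx("rg", "mB", NULL, 0, DEFAULT_BOUND)
    if (spec$include_dem) {
      mets <- c(mets, "m_dem")
      src <- chain_mets[[1]][1]
      add_rx("r_dem", src, "m_dem", 0, DEFAULT_BOUND)
    }
    if (spec$include_dead) {
      src <- chain_mets[[1]][1]
      dst <- if (npath > 1) chain_mets[[2]][1] else "mB"
      add_rx("r_dead", src, dst, 0, 0)
    }
    ## pad with redundant forward edges along random paths
    k <- 0L
    while (length(rx) < spec$n_reactions) {
      k <- k + 1L
      p <- sample(npath, 1)
      ms <- c(chain_mets[[p]], "mB")
      i <- if (length(ms) > 1) sample(length(ms) - 1L, 1) else 1L
      add_rx(sprintf("dup%d", k), ms[i], ms[min(i + 1L, length(ms))],
             0, DEFAULT_BOUND, w = sample(1:2, 1))
    }
    ## reversible marking of internal (non-exchange, non-growth,
    ## non-planted) reactions
    ids <- vapply(rx, `[[`, "", "id")
    internal <- grepl("^(p|b|dup)", ids)
    n_rev <- round(spec$reversible_fraction * sum(internal))
    if (n_rev > 0) {
      pick <- sample(which(internal), n_rev)
      for (i in pick) rx[[i]]$lb <- -DEFAULT_BOUND
    }

    S <- matrix(0, length(mets), length(rx),
                dimnames = list(mets, ids))
    for (i in seq_along(rx)) {
      if (!is.null(rx[[i]]$consume)) S[rx[[i]]$consume, i] <- -1
      if (!is.null(rx[[i]]$produce)) S[rx[[i]]$produce, i] <- rx[[i]]$w
    }
    cbm(S, vapply(rx, `[[`, 0, "lb"), vapply(rx, `[[`, 0, "ub"),
        objective = "rg")
  })
}

#' Hand-built nets mirroring the worked examples
#'
#' Two small networks with the properties used throughout the worked
#' examples of the underlying method:
#'
#' * `net1` (10 reactions, 7 metabolites): a linear trunk `ex -> ma ->
#'   mb` where `r2` is the sole consumer of `ma` (hence a chokepoint)
#'   and essential; an optimal 2-for-1 branch `r3, r4, r7: me -> 2 mf`
#'   competing with a lossier branch `r5, r6`, so `r3`, `r4` are
#'   essential for optimal growth but not essential; and a metabolite
#'   `mg` that is produced but never consumed (a dead-end).
#' * `net2` (8 reactions, 5 metabolites): reversible reactions `r3`,
#'   `r4`, a dead reaction `r7`, and a blocked reaction `r6` consuming
#'   the dead-end `md`.  At gamma = 1 reactions `r2, r3, r5, r6, r7`
#'   are dead, `r4` turns non-reversible and becomes the sole consumer
#'   of `ma`/sole producer of `mc` (a growth-dependent chokepoint),
#'   while the chokepoint `r3` of the raw model drops out.
#'
#' @return named list of two `cbm` models, `net1` and `net2`.
#' @export
figure_like_nets <- function() {
  ## net1: ma..mg, r1..r9 + rg
  mets1 <- c("ma", "mb", "mc", "md", "me", "mf", "mg")
  rx1 <- c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg")
  S1 <- matrix(0, 7, 10, dimnames = list(mets1, rx1))
  S1["ma", "r1"] <- 1                       # r1: -> ma (exchange, cap 10)
  S1["ma", "r2"] <- -1; S1["mb", "r2"] <- 1 # r2: ma -> mb
  S1["mb", "r3"] <- -1; S1["mc", "r3"] <- 1 # r3: mb -> mc  (optimal branch)
  S1["mc", "r4"] <- -1; S1["me", "r4"] <- 1 # r4: mc -> me
  S1["mb", "r5"] <- -1; S1["md", "r5"] <- 1 # r5: mb -> md  (lossy branch)
  S1["md", "r6"] <- -1; S1["mf", "r6"] <- 1 # r6: md -> mf
  S1["me", "r7"] <- -1; S1["mf", "r7"] <- 2 # r7: me -> 2 mf
  S1["mc", "r8"] <- -1; S1["mg", "r8"] <- 1 # r8: mc -> mg  (mg: dead end)
  S1["mf", "r9"] <- -1                      # r9: mf ->     (export)
  S1["mb", "rg"] <- -1; S1["mf", "rg"] <- -1 # rg: mb + mf -> growth
  lb1 <- rep(0, 10); ub1 <- rep(DEFAULT_BOUND, 10)
  ub1[1] <- 10
  net1 <- cbm(S1, lb1, ub1, objective = "rg")

  ## net2: ma..me, r1..r7 + rg
  mets2 <- c("ma", "mb", "mc", "md", "me")
  rx2 <- c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "rg")
  S2 <- matrix(0, 5, 8, dimnames = list(mets2, rx2))
  S2["ma", "r1"] <- 1                        # r1: -> ma (exchange, cap 10)
  S2["ma", "r2"] <- -2; S2["mb", "r2"] <- 1  # r2: 2 ma -> mb (lossy)
  S2["mb", "r3"] <- -1; S2["mc", "r3"] <- 1  # r3: mb <-> mc (reversible)
  S2["ma", "r4"] <- -1; S2["mc", "r4"] <- 1  # r4: ma <-> mc (reversible)
  S2["mc", "r5"] <- -1                       # r5: mc ->     (export)
  S2["md", "r6"] <- -1; S2["me", "r6"] <- 1  # r6: md -> me (md: dead end)
  S2["me", "r7"] <- -1; S2["ma", "r7"] <- 1  # r7: me -> ma (dead bounds)
  S2["mc", "rg"] <- -1                       # rg: mc -> growth
  lb2 <- c(0, 0, -DEFAULT_BOUND, -DEFAULT_BOUND, 0, 0, 0, 0)
  ub2 <- c(10, DEFAULT_BOUND, DEFAULT_BOUND, DEFAULT_BOUND,
           DEFAULT_BOUND, DEFAULT_BOUND, 0, DEFAULT_BOUND)
  net2 <- cbm(S2, lb2, ub2, objective = "rg")
  list(net1 = net1, net2 = net2)
}

#' Brute-force vulnerability oracle
#'
#' Independent re-computation of every vulnerability set on a small
#' model by literal evaluation of the definitions: star-sets by an
#' explicit double loop over all (metabolite, reaction) pairs,
#' chokepoints and dead-end metabolites by direct uniqueness/emptiness
#' tests, FVA by one LP pair per reaction and essentiality by
#' exhaustive single knockouts, all solved with a second LP backend
#' (SciPy/HiGHS by default).  Intentionally naive; refuses models with
#' more than 20 reactions.
#'
#' @inheritParams growth_dependent_sets
#' @param gamma growth fraction in \[0, 1\].
#' @param solver LP backend for the oracle; keep it different from the
#'   backend under test.
#' @return a `vulnerability_report`, comparable field by field with
#'   [growth_dependent_sets()] output.
#' @export
brute_force_sets <- function(model, gamma, solver = "scipy",
                             epsilon = 1e-6, include_boundary = FALSE) {
  stopifnot(inherits(model, "cbm"))
  if (length(model$reactions) > 20)
    stop("brute-force oracle refuses models with more than 20 reactions")
  if (length(model$reactions) == 0)
    return(structure(list(chokepoints = character(),
                          dead_end_metabolites = character(),
                          essential = character(), blocked = character(),
                          partition = structure(
                            list(dead = character(), reversible = character(),
                                 non_reversible = character()),
                            class = "reaction_partition"),
                          gamma = gamma, mu_max = 0, fva_bounds = NULL),
                     class = "vulnerability_report"))
  S <- as.matrix(model$S)
  n <- length(model$reactions); m <- length(model$metabolites)
  ## one LP per definition; transport batched per group so the
  ## subprocess backend is launched a handful of times, not per LP
  solve_group <- function(probs) lp_batch(model$S, probs, solver)
  cg <- as.numeric(model$reactions == model$objective)
  r0 <- solve_group(list(list(c = cg, lb = model$lower, ub = model$upper,
                              maximize = TRUE)))[[1]]
  if (r0$status != "optimal") stop("oracle: base model not optimal")
  mu <- if (abs(r0$objective) < epsilon) 0 else r0$objective

  ## remaining LPs (FVA pairs with the gamma floor, knockouts, blocked
  ## pairs) are independent of each other once mu is known, so they go
  ## into a single batch: one LP per definition, one transport call
  lb <- model$lower; ub <- model$upper
  if (gamma > 0 && mu > 0) {
    gi <- which(cg > 0)
    lb[gi] <- max(lb[gi], gamma * mu)
  }
  fva_probs <- list()
  for (i in seq_len(n)) {
    ci <- as.numeric(seq_len(n) == i)
    fva_probs <- c(fva_probs,
                   list(list(c = ci, lb = lb, ub = ub, maximize = FALSE),
                        list(c = ci, lb = lb, ub = ub, maximize = TRUE)))
  }
  ko_probs <- list(); ko_idx <- integer()
  pre_essential <- logical(n)
  for (j in seq_len(n)) {
    klb <- model$lower; kub <- model$upper
    if (klb[j] > 0 || kub[j] < 0) {
      pre_essential[j] <- TRUE   # v[r] = 0 infeasible outright
    } else {
      klb[j] <- kub[j] <- 0
      ko_probs <- c(ko_probs, list(list(c = cg, lb = klb, ub = kub,
                                        maximize = TRUE)))
      ko_idx <- c(ko_idx, j)
    }
  }
  bl_probs <- list()
  for (i in seq_len(n)) {
    ci <- as.numeric(seq_len(n) == i)
    bl_probs <- c(bl_probs,
                  list(list(c = ci, lb = model$lower, ub = model$upper,
                            maximize = FALSE),
                       list(c = ci, lb = model$lower, ub = model$upper,
                            maximize = TRUE)))
  }
  sol <- solve_group(c(fva_probs, ko_probs, bl_probs))
  fva_sol <- sol[seq_along(fva_probs)]
  ko_sol <- sol[length(fva_probs) + seq_along(ko_probs)]
  bl_sol <- sol[length(fva_probs) + length(ko_probs) + seq_along(bl_probs)]

  lo <- numeric(n); hi <- numeric(n)
  for (i in seq_len(n)) {
    a <- fva_sol[[2L * i - 1L]]; b <- fva_sol[[2L * i]]
    if (a$status != "optimal" || b$status != "optimal")
      stop("oracle: FVA subproblem not optimal")
    lo[i] <- a$objective; hi[i] <- b$objective
  }
  lo[abs(lo) < epsilon] <- 0; hi[abs(hi) < epsilon] <- 0

  ## classification by literal definition on the FVA bounds
  dead <- abs(lo) <= epsilon & abs(hi) <= epsilon
  rev <- lo < -epsilon & hi > epsilon & !dead
  nonrev <- !dead & !rev

  ## star-sets of the FVA-constrained model by double loop
  is_reactant <- matrix(FALSE, m, n)
  is_product <- matrix(FALSE, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- S[i, j]
    if (s < 0 && hi[j] > epsilon) is_reactant[i, j] <- TRUE
    if (s > 0 && lo[j] < -epsilon) is_reactant[i, j] <- TRUE
    if (s > 0 && hi[j] > epsilon) is_product[i, j] <- TRUE
    if (s < 0 && lo[j] < -epsilon) is_product[i, j] <- TRUE
  }
  mets <- internal_metabolites(model, include_boundary)
  cp <- character(); dem <- character()
  for (mid in mets) {
    i <- match(mid, model$metabolites)
    consumers <- which(is_reactant[i, ])
    producers <- which(is_product[i, ])
    if (length(consumers) == 1) cp <- c(cp, model$reactions[consumers])
    if (length(producers) == 1) cp <- c(cp, model$reactions[producers])
    if (length(consumers) == 0 || length(producers) == 0)
      dem <- c(dem, mid)
  }

  ## essentiality by exhaustive single knockouts against raw bounds
  ess <- model$reactions[pre_essential]
  for (k in seq_along(ko_idx)) {
    kr <- ko_sol[[k]]
    if (kr$status != "optimal" ||
        kr$objective < gamma * mu * (1 - 1e-6) - .Machine$double.eps)
      ess <- c(ess, model$reactions[ko_idx[k]])
  }

  ## blocked: FVA at gamma = 0
  blo <- vapply(seq_len(n), function(i) bl_sol[[2L * i - 1L]]$objective, 0)
  bhi <- vapply(seq_len(n), function(i) bl_sol[[2L * i]]$objective, 0)
  blocked <- abs(blo) <= epsilon & abs(bhi) <= epsilon

  structure(list(
    chokepoints = sort(unique(cp)),
    dead_end_metabolites = sort(dem),
    essential = sort(ess),
    blocked = sort(model$reactions[blocked]),
    partition = structure(list(
      dead = sort(model$reactions[dead]),
      reversible = sort(model$reactions[rev]),
      non_reversible = sort(model$reactions[nonrev])),
      class = "reaction_partition"),
    gamma = gamma, mu_max = mu,
    fva_bounds = flux_bounds(stats::setNames(lo, model$reactions),
                             stats::setNames(hi, model$reactions),
                             gamma = gamma)),
    class = "vulnerability_report")
}
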