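make_simple <- function(lb, ub) {
  # r: A -> 2B with the given bounds, plus feeder/drain so nothing is
  # trivially empty
  S <- matrix(c(1, 0, -1, 2, 0, -1), 2, 3,
              dimnames = list(c("A", "B"), c("exA", "r", "exB")))
  cbm(S, c(0, lb, 0), c(1000, ub, 1000))
}

test_that("star reactant/product sets follow the bound-aware formula", {
  m_fwd <- make_simple(0, 1000)     # irreversible A -> 2B
  expect_identical(star_reactants(m_fwd, "r"), "A")
  expect_identical(star_products(m_fwd, "r"), "B")

  m_rev <- make_simple(-1000, 1000) # reversible: both sides both roles
  expect_setequal(star_reactants(m_rev, "r"), c("A", "B"))
  expect_setequal(star_products(m_rev, "r"), c("A", "B"))

  m_dead <- make_simple(0, 0)       # dead: empty star-sets
  expect_length(star_reactants(m_dead, "r"), 0)
  expect_length(star_products(m_dead, "r"), 0)

  m_bwd <- make_simple(-1000, 0)    # backwards only: roles swapped
  expect_identical(star_reactants(m_bwd, "r"), "B")
  expect_identical(star_products(m_bwd, "r"), "A")
})

test_that("star consumer/producer sets invert the star maps", {
  # brute-force agreement over random fixtures
  for (seed in c(3, 8)) {
    fx <- random_fixture(seed)
    for (met in fx$metabolites) {
      cons <- Filter(function(r) met %in% star_reactants(fx, r),
                     fx$reactions)
      prod <- Filter(function(r) met %in% star_products(fx, r),
                     fx$reactions)
      expect_setequal(star_consumers(fx, met), cons)
      expect_setequal(star_producers(fx, met), prod)
    }
  }
  expect_error(star_consumers(random_fixture(3), "nope"),
               "unknown metabolite")
})

test_that("chokepoints are unique star-consumers or star-producers", {
  nets <- figure_like_nets()
  # r2 is the sole consumer of ma in net1
  expect_identical(star_consumers(nets$net1, "ma"), "r2")
  expect_true("r2" %in% chokepoints(nets$net1))
  # two producers and two consumers -> no chokepoint from that metabolite
  S <- matrix(c(1, 1, -1, -1), 1, 4,
              dimnames = list("A", c("p1", "p2", "c1", "c2")))
  m <- cbm(S, rep(0, 4), rep(10, 4))
  expect_length(chokepoints(m), 0)
  # a reversible reaction that is sole producer AND sole consumer counts once
  S2 <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("rv", "other")))
  m2 <- cbm(S2, c(-10, 0), c(10, 0))   # other is dead
  expect_identical(chokepoints(m2), "rv")
})

test_that("dead-end metabolites have an empty star side", {
  nets <- figure_like_nets()
  expect_true("mg" %in% dead_end_metabolites(nets$net1))
  # reversible partner reaction keeps a metabolite out of the DEM set
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rv")))
  m <- cbm(S, c(0, -10), c(10, 10))
  expect_length(dead_end_metabolites(m), 0)
  # metabolite touched only by dead reactions is a DEM (both sides empty)
  m_dead <- cbm(S, c(0, 0), c(0, 0))
  expect_identical(dead_end_metabolites(m_dead), "A")
})

test_that("classify_reactions partitions R by the bound signs", {
  S <- matrix(1, 1, 4, dimnames = list("A", paste0("r", 1:4)))
  m <- cbm(S, c(0, -1000, -1000, 0), c(0, 1000, 0, 1000))
  p <- classify_reactions(m)
  expect_identical(p$dead, "r1")
  expect_identical(p$reversible, "r2")
  expect_setequal(p$non_reversible, c("r3", "r4"))
  # partition law on random fixtures and their FVA-updated versions
  for (seed in c(2, 9)) {
    fx <- random_fixture(seed)
    for (mod in list(fx, apply_bounds(fx, fva(fx, max_growth(fx))))) {
      q <- classify_reactions(mod)
      all_ids <- c(q$dead, q$reversible, q$non_reversible)
      expect_identical(sort(all_ids), sort(mod$reactions))
      expect_identical(anyDuplicated(all_ids), 0L)
    }
  }
})

test_that("essential_reactions flags every cut of the only route", {
  # unique path: ex -> A -> B -> rg; everything essential
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("A", "B"), c("ex", "conv", "rg")))
  m <- cbm(S, rep(0, 3), c(5, 1000, 1000), objective = "rg")
  expect_setequal(essential_reactions(m), c("ex", "conv", "rg"))
  # redundant parallel path -> exchanges not essential
  expect_setequal(essential_reactions(parallel_paths_34()), "rg")
})

test_that("growth-dependent essentiality moves with gamma", {
  fx <- parallel_paths_34()
  mu <- max_growth(fx)$mu_max        # 7
  path3 <- c("ex1", "b1"); path4 <- c("ex2", "b2")
  # frozen from exhaustive knockout LPs (both backends agree):
  # gamma=0: empty; gamma=3/7: none of the path reactions;
  # gamma=4/7: only the capacity-4 path; gamma=1: both paths
  expect_length(growth_dependent_essential(fx, ctx_at(mu, 0)), 0)
  er_37 <- growth_dependent_essential(fx, ctx_at(mu, 3 / 7))
  expect_length(intersect(er_37, c(path3, path4)), 0)
  er_47 <- growth_dependent_essential(fx, ctx_at(mu, 4 / 7))
  expect_setequal(intersect(er_47, c(path3, path4)), path4)
  er_1 <- growth_dependent_essential(fx, ctx_at(mu, 1))
  expect_true(all(c(path3, path4) %in% er_1))
})

test_that("blocked_reactions equals the dead set at gamma = 0", {
  for (seed in c(1, 5)) {
    fx <- random_fixture(seed)
    bl <- blocked_reactions(fx)
    rep0 <- growth_dependent_sets(fx, ctx_at(max_growth(fx)$mu_max, 0))
    expect_identical(bl, rep0$partition$dead)
  }
  # open chain with no dead ends: nothing blocked
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rg")))
  m <- cbm(S, c(0, 0), c(10, 1000), objective = "rg")
  expect_length(blocked_reactions(m), 0)
})

test_that("growth_dependent_sets reproduces the chokepoint hand-offs", {
  n2 <- figure_like_nets()$net2
  rep1 <- growth_dependent_sets(n2, max_growth(n2, gamma = 1))
  # flux-dependent chokepoint r3 goes dead at gamma=1 and drops out;
  # reversible r4 becomes sole consumer of ma / producer of mc
  expect_true("r3" %in% chokepoints(n2))
  expect_false("r4" %in% chokepoints(n2))
  expect_false("r3" %in% rep1$chokepoints)
  expect_true("r4" %in% rep1$chokepoints)
  expect_true("r4" %in% rep1$partition$non_reversible)
  # report invariants
  expect_length(intersect(rep1$chokepoints, rep1$partition$dead), 0)
  expect_length(intersect(rep1$essential, rep1$blocked), 0)
})

test_that("remove_dead_end_metabolites cascades to a fixpoint", {
  # chain A -> B -> C with C produced-never-consumed: two passes
  S <- matrix(c(1, 0, 0, -1, 1, 0, 0, -1, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("ex", "r1", "r2")))
  m <- cbm(S, rep(0, 3), rep(10, 3))
  pruned <- remove_dead_end_metabolites(m)
  expect_setequal(attr(pruned, "removed_metabolites"), c("B", "C", "A"))
  expect_setequal(pruned$orphaned, c("ex", "r1", "r2"))
  expect_identical(pruned$reactions, m$reactions)  # R stays stable

  # model without DEMs comes back unchanged
  S2 <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rg")))
  m2 <- cbm(S2, c(0, 0), c(10, 10))
  out <- remove_dead_end_metabolites(m2)
  expect_identical(out$metabolites, "A")
  expect_length(attr(out, "removed_metabolites"), 0)
})

test_that("dead reactions are never chokepoints nor DEM partners", {
  for (seed in c(3, 12)) {
    fx <- random_fixture(seed)
    rep1 <- growth_dependent_sets(fx, max_growth(fx, gamma = 1))
    expect_length(intersect(rep1$chokepoints, rep1$partition$dead), 0)
    upd <- apply_bounds(fx, rep1$fva_bounds)
    for (r in rep1$partition$dead) {
      expect_length(star_reactants(upd, r), 0)
      expect_length(star_products(upd, r), 0)
    }
  }
})
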