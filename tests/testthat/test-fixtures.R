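test_that("fixture generation is deterministic and honours its spec", {
  sp <- fixture_spec(n_metabolites = 8, n_reactions = 12,
                     n_parallel_paths = 2, include_dem = TRUE,
                     include_dead = TRUE, seed = 11)
  a <- make_fixture(sp); b <- make_fixture(sp)
  expect_identical(as.matrix(a$S), as.matrix(b$S))
  expect_identical(a$lower, b$lower)
  expect_identical(a$upper, b$upper)
  expect_identical(dim(a), c(8L, 12L))
  expect_identical(a$objective, "rg")
  expect_identical(unname(a$lower["rg"]), 0)
  expect_gt(max_growth(a)$mu_max, 0)

  # planted structures are always detected
  expect_true("m_dem" %in% dead_end_metabolites(a))
  expect_true("r_dead" %in% classify_reactions(a)$dead)
  expect_true("r_dem" %in% blocked_reactions(a))
  for (g in c(0, 0.5, 1)) {
    rep_g <- growth_dependent_sets(a, ctx_at(max_growth(a)$mu_max, g))
    expect_true("r_dead" %in% rep_g$partition$dead)
  }

  expect_error(fixture_spec(n_reactions = 2, n_parallel_paths = 2),
               "n_reactions too small")
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_fixture(fixture_spec(seed = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("figure-like nets satisfy their stated memberships", {
  nets <- figure_like_nets()
  n1 <- nets$net1
  expect_identical(dim(n1), c(7L, 10L))
  expect_true(all(c("r1", "r2") %in% essential_reactions(n1)))
  erog <- growth_dependent_essential(n1, max_growth(n1, gamma = 1))
  expect_true(all(c("r1", "r2", "r3", "r4") %in% erog))
  expect_true("mg" %in% dead_end_metabolites(n1))

  n2 <- nets$net2
  expect_identical(dim(n2), c(5L, 8L))
  p <- classify_reactions(n2)
  expect_identical(p$reversible, c("r3", "r4"))
  expect_identical(p$dead, "r7")
  expect_true("r6" %in% blocked_reactions(n2))
})

test_that("the brute-force oracle handles the degenerate cases", {
  empty <- cbm(matrix(0, 0, 0), numeric(), numeric())
  out <- brute_force_sets(empty, gamma = 0, solver = "simplex")
  expect_length(out$chokepoints, 0)
  expect_length(out$essential, 0)
  expect_length(out$partition$dead, 0)

  big <- make_fixture(fixture_spec(n_metabolites = 20, n_reactions = 25,
                                   n_parallel_paths = 2, seed = 1))
  expect_error(brute_force_sets(big, 0), "refuses")
})

test_that("oracle equals the implementation on sampled fixtures", {
  # the full 20-fixture x 2-backend comparison lives in the acceptance
  # suite; here one fixture per structural feature, both backends
  for (seed in c(1, 4)) {
    fx <- random_fixture(seed)
    mu <- max_growth(fx)$mu_max
    for (g in c(0, 1)) {
      own <- growth_dependent_sets(fx, ctx_at(mu, g))
      bf <- brute_force_sets(fx, g, solver = "simplex")
      expect_same_report(own, bf)
    }
  }
})
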