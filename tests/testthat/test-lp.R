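test_that("max_growth solves simple FBA problems", {
  # import-limited chain: ex -> A (cap 10), rg: A ->
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rg")))
  m <- cbm(S, c(0, 0), c(10, 1000), objective = "rg")
  expect_equal(max_growth(m)$mu_max, 10)

  # growth reaction pinned to zero
  m0 <- cbm(S, c(0, 0), c(10, 0), objective = "rg")
  expect_equal(max_growth(m0)$mu_max, 0)

  # two parallel paths with capacities 3 and 4 -> mu_max = 7
  expect_equal(max_growth(parallel_paths_34())$mu_max, 7)

  expect_error(max_growth(cbm(S, c(0, 0), c(10, 1000))),
               "no growth objective")
})

test_that("infeasible and unbounded models raise dedicated errors", {
  # A must be consumed at >= 5 but can only be produced at <= 1
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rg")))
  m_inf <- cbm(S, c(0, 5), c(1, 1000), objective = "rg")
  expect_error(max_growth(m_inf), "infeasible")

  # growth with no exchange cap at all (infinite bounds)
  m_unb <- cbm(S, c(0, 0), c(Inf, Inf), objective = "rg")
  expect_error(max_growth(m_unb), "unbounded")
})

test_that("knockout_growth pins a reaction to zero", {
  fx <- parallel_paths_34()
  # cutting one of two redundant paths leaves the other's capacity
  expect_equal(knockout_growth(fx, "ex1")$growth, 4)  # ex1 caps the 3-path
  expect_equal(knockout_growth(fx, "ex2")$growth, 3)
  expect_equal(knockout_growth(fx, "rg")$growth, 0)
  expect_error(knockout_growth(fx, "nope"), "unknown reaction")

  # knockout of a blocked reaction leaves mu_max unchanged
  fx2 <- make_fixture(fixture_spec(n_metabolites = 6, n_reactions = 9,
                                   include_dem = TRUE, seed = 4,
                                   reversible_fraction = 0))
  bl <- blocked_reactions(fx2)
  expect_true("r_dem" %in% bl)
  mu <- max_growth(fx2)$mu_max
  expect_equal(knockout_growth(fx2, "r_dem")$growth, mu)
})

test_that("fva honours the growth floor and snaps near-zero bounds", {
  nets <- figure_like_nets()
  n2 <- nets$net2
  ctx0 <- ctx_at(max_growth(n2)$mu_max, 0)
  fb0 <- fva(n2, ctx0)
  # r6 consumes the dead-end md: pinned to zero even at gamma = 0
  i <- match("r6", n2$reactions)
  expect_identical(fb0$lower[i], 0)
  expect_identical(fb0$upper[i], 0)
  expect_true(all(fb0$lower <= fb0$upper))

  # gamma = 1 floor: the objective interval collapses to mu_max
  mu <- max_growth(n2)$mu_max
  fb1 <- fva(n2, ctx_at(mu, 1))
  gi <- match("rg", n2$reactions)
  expect_equal(fb1$lower[gi], mu, tolerance = 1e-6)
  expect_equal(fb1$upper[gi], mu, tolerance = 1e-6)
})

test_that("FVA intervals nest as gamma grows (containment property)", {
  for (seed in c(1, 6)) {
    fx <- random_fixture(seed)
    mu <- max_growth(fx)$mu_max
    gammas <- c(0, 0.3, 0.8, 1)
    fbs <- lapply(gammas, function(g) fva(fx, ctx_at(mu, g)))
    for (k in 2:length(fbs)) {
      expect_true(all(fbs[[k]]$lower >= fbs[[k - 1]]$lower - 1e-6),
                  label = sprintf("seed %d lower nesting %g in %g",
                                  seed, gammas[k], gammas[k - 1]))
      expect_true(all(fbs[[k]]$upper <= fbs[[k - 1]]$upper + 1e-6),
                  label = sprintf("seed %d upper nesting", seed))
    }
  }
})

test_that("a zero-growth model makes the gamma floor vacuous", {
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3,
              dimnames = list(c("A", "B"), c("ex", "conv", "rg")))
  m <- cbm(S, c(0, 0, 0), c(10, 0, 1000), objective = "rg")  # conv dead
  ctx <- max_growth(m)
  expect_equal(ctx$mu_max, 0)
  expect_warning(fb1 <- fva(m, ctx_at(0, 0.5)), "numerically zero")
  fb0 <- fva(m, ctx_at(0, 0))
  expect_equal(fb1$lower, fb0$lower)
  expect_equal(fb1$upper, fb0$upper)
})

test_that("re-solving FBA on FVA-updated bounds certifies the floor", {
  fx <- random_fixture(7)
  mu <- max_growth(fx)$mu_max
  for (g in c(0.5, 1)) {
    upd <- apply_bounds(fx, fva(fx, ctx_at(mu, g)))
    expect_gte(max_growth(upd)$mu_max, g * mu - 1e-6)
  }
})

test_that("both LP backends agree on growth and knockout values", {
  fx <- parallel_paths_34()
  expect_equal(max_growth(fx, solver = "scipy")$mu_max,
               max_growth(fx, solver = "simplex")$mu_max, tolerance = 1e-7)
  expect_equal(knockout_growth(fx, "ex2", solver = "scipy")$growth,
               3, tolerance = 1e-7)
})
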