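test_that("cbm enforces its invariants", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("ex", "rg")))
  expect_error(cbm(S, c(0, 5), c(10, 0)), "lower bound exceeds")
  expect_error(cbm(S, c(0, 0), c(10, 10), reactions = c("r", "r"),
                   metabolites = "A"), "duplicate reaction")
  expect_warning(m <- cbm(S, c(0, -5), c(10, 10), objective = "rg"),
                 "clamping")
  expect_identical(unname(m$lower["rg"]), 0)
  expect_error(cbm(S, c(0, 0), c(10, 10), objective = "nope"),
               "objective reaction not in model")
})

test_that("structural producer/consumer sets match a brute-force scan", {
  set.seed(42)
  for (rep in 1:5) {
    S <- matrix(0, 6, 8)
    nz <- sample(length(S), 14)
    S[nz] <- sample(c(-2, -1, 1, 2), 14, replace = TRUE)
    dimnames(S) <- list(paste0("m", 1:6), paste0("r", 1:8))
    m <- cbm(S, rep(-10, 8), rep(10, 8))
    for (met in m$metabolites) {
      expect_setequal(structural_producers(m, met),
                      colnames(S)[S[met, ] > 0])
      expect_setequal(structural_consumers(m, met),
                      colnames(S)[S[met, ] < 0])
      # disjoint unless a reaction carries both signs for one metabolite
      expect_length(intersect(structural_producers(m, met),
                              structural_consumers(m, met)), 0)
    }
  }
  expect_error(structural_producers(make_fixture(fixture_spec(seed = 1)),
                                    "no_such_met"), "unknown metabolite")
})

test_that("apply_bounds replaces bounds without touching the original", {
  fx <- random_fixture(2)
  ident <- apply_bounds(fx, flux_bounds(fx$lower, fx$upper))
  expect_identical(ident$lower, fx$lower)
  expect_identical(ident$upper, fx$upper)
  expect_error(apply_bounds(fx, flux_bounds(0, 1)), "dimension")

  ctx <- max_growth(fx)
  fb <- fva(fx, ctx)
  upd <- apply_bounds(fx, fb)
  # never widens relative to the raw bounds (FVA interval containment)
  expect_true(all(upd$lower >= fx$lower - 1e-6))
  expect_true(all(upd$upper <= fx$upper + 1e-6))
  # original untouched
  expect_identical(fx$lower, make_fixture(fixture_spec(
    n_metabolites = 6 + 2 %% 3, n_reactions = 9 + 2 %% 4,
    reversible_fraction = 0.5, n_parallel_paths = 1,
    include_dem = FALSE, include_dead = FALSE, seed = 2))$lower)

  # pinning one reaction to zero makes it dead downstream
  fb0 <- flux_bounds(replace(fx$lower, 2, 0), replace(fx$upper, 2, 0))
  expect_true(fx$reactions[2] %in%
                classify_reactions(apply_bounds(fx, fb0))$dead)
})

test_that("flux_bounds validates its inputs", {
  expect_error(flux_bounds(c(0, 1), 0), "differ in length")
  expect_error(flux_bounds(1, 0), "exceeds")
  expect_error(flux_bounds(0, 1, gamma = 2), "gamma")
  fb <- flux_bounds(c(0, -1), c(1, 1), gamma = 0.5)
  expect_identical(fb$gamma, 0.5)
})
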