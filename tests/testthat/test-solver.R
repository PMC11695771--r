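test_that("micromodel feasibility matches the closed form at fixed mu", {
  m <- make_analytic_micromodel(k_eff = 1, uptake_cap = 10)
  f <- feasible_at(m, 0.5)
  expect_true(f$feasible)
  expect_equal(unname(f$flux["uptake"]), 1, tolerance = 1e-6)  # mu k/(k-mu)
  expect_false(feasible_at(m, 0.95)$feasible)                  # v_up = 19 > 10
  expect_true(feasible_at(m, 0)$feasible)
})

test_that("bisection matches the closed-form mu_max over a (k, cap) grid", {
  for (k in c(0.5, 2, 10)) {
    for (cap in c(0.5, 2, 10)) {
      r <- maximize_growth(make_analytic_micromodel(k, cap),
                           solve_options(mu_hi = min(k, cap) + 0.1))
      expect_equal(r$mu_max, micromodel_mu_max(k, cap), tolerance = 3e-6)
    }
  }
  r0 <- maximize_growth(make_analytic_micromodel(1, 0))
  expect_equal(r0$mu_max, 0)
})

test_that("bisection iteration count respects the log2 bound", {
  opts <- solve_options(mu_hi = 2, bisect_tol = 1e-6)
  r <- maximize_growth(make_analytic_micromodel(1, 10), opts)
  bound <- ceiling(log2((opts$mu_hi - opts$mu_lo) / opts$bisect_tol)) + 2
  expect_lte(r$iterations, bound)
})

test_that("parsimonious solution is feasible, minimal and kills free cycles", {
  m <- make_analytic_micromodel(1, 10)
  ## add a free reversible cycle through two extra reactions
  m <- add_species(m, "x_c", "c")
  m <- add_reaction(m, me_reaction("cyc1", "metabolic", list(M_c = -1, x_c = 1),
                                   -Inf, Inf))
  m <- add_reaction(m, me_reaction("cyc2", "metabolic", list(x_c = -1, M_c = 1),
                                   -Inf, Inf))
  r <- maximize_growth(m)
  v <- parsimonious_solution(m, r$mu_max)
  lp <- assemble_lp(m, r$mu_max)
  expect_lte(max(abs(as.numeric(lp$A %*% v))), 1e-6)
  expect_true(all(v >= lp$lb - 1e-7 & v <= lp$ub + 1e-7))
  expect_equal(unname(v["cyc1"]), 0, tolerance = 1e-8)
  expect_equal(unname(v["cyc2"]), 0, tolerance = 1e-8)
  expect_equal(unname(v["uptake"]),
               r$mu_max * 1 / (1 - r$mu_max), tolerance = 1e-3)
})

test_that("optimize_at_mu enforces the growth bound and optimizes on top", {
  m <- make_analytic_micromodel(1, 10)
  v <- optimize_at_mu(m, 0.5, c(biomass = 1))
  ## the biomass lower bound is raised to mu ...
  expect_gte(unname(v["biomass"]), 0.5 - 1e-9)
  ## ... and maximizing biomass at fixed mu reaches cap * (1 - mu/k)
  expect_equal(unname(v["biomass"]), 10 * (1 - 0.5), tolerance = 1e-6)
  ## an all-zero objective still returns a feasible vector
  v0 <- optimize_at_mu(m, 0.5, c(biomass = 0))
  lp <- assemble_lp(m, 0.5)
  expect_lte(max(abs(as.numeric(lp$A %*% v0))), 1e-7)
  expect_error(optimize_at_mu(m, 0.95, c(biomass = 1)), "infeasible")
})

test_that("grid oracle and bisection agree on the micromodel", {
  m <- make_analytic_micromodel(1, 10)
  g <- brute_force_mu_max(m, delta = 1e-3)
  expect_equal(g, 10 / 11, tolerance = 1.5e-3)
  r <- maximize_growth(m)
  expect_lte(abs(r$mu_max - g), 1e-3)
})
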