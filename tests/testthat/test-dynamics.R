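test_that("a plasmid-free noncooperative population converges to itself", {
  eq <- iterate_to_equilibrium(seed_state(), fig_params())
  expect_true(eq$converged)
  expect_lte(eq$generations_run, 51)
  expect_equal(unname(unclass(eq$state_star)[1]), 1)
  expect_equal(eq$cooperator_freq_star, 0)
  expect_true(is.na(eq$cooperativeness_star))
  expect_true(is.na(eq$R_plas_star))
})

test_that("without loss an invading plasmid sweeps to fixation", {
  p <- coop_params(20, beta = 0.9, s = 0, B = 1.435, C_G = 0.1, C_C = 0.2)
  eq <- iterate_to_equilibrium(seed_state(p_def = 1e-3), p)
  expect_true(eq$converged)
  expect_equal(eq$p_total_star, 1, tolerance = 1e-8)
  # at fixation plasmid relatedness equals chromosomal relatedness
  expect_equal(eq$R_plas_star, 0.05, tolerance = 1e-9)
})

test_that("without transfer any lossy plasmid goes extinct", {
  p <- coop_params(20, beta = 0, s = 0.1, B = 1.435, C_G = 0.1, C_C = 0.2)
  eq <- iterate_to_equilibrium(seed_state(p_coop = 0.3, p_def = 0.3), p)
  expect_true(eq$converged)
  expect_equal(eq$p_total_star, 0)
})

test_that("classification computes cooperativeness and the product rule", {
  p <- fig_params()
  eq <- iterate_to_equilibrium(seed_state(p_coop = 1e-3, p_def = 1e-3), p)
  expect_true(eq$converged)
  expect_equal(eq$cooperator_freq_star,
               eq$cooperativeness_star * eq$p_total_star, tolerance = 1e-12)
  # cooperative cell of the phase diagram: all plasmids end up cooperative
  expect_equal(eq$cooperativeness_star, 1, tolerance = 1e-6)
  expect_gt(eq$R_plas_star * p$B, p$C_G)
  expect_true(hamilton_check(eq, p))
})

test_that("hamilton_check applies the strict threshold R_plas x B > C_G", {
  p <- fig_params()
  fake <- function(R) {
    structure(list(state_star = seed_state(p_coop = 0.2),
                   R_plas_star = R, converged = TRUE),
              class = "equilibrium_summary")
  }
  expect_false(hamilton_check(fake(0.05), p))   # 0.07175 < 0.1
  expect_true(hamilton_check(fake(0.1), p))     # 0.1435  > 0.1
  boundary <- hamilton_check(fake(0.1 / 1.435), p)
  expect_false(boundary)                        # strict inequality
  expect_true(attr(boundary, "near_boundary"))
  expect_error(hamilton_check(fake(NA_real_), p), "undefined")
})

test_that("invasion growth factors separate spreading from doomed plasmids", {
  # transfer off: only loss and carriage cost act
  p_noinv <- coop_params(20, beta = 0, s = 0.2, B = 1.435, C_G = 0.1, C_C = 0.2)
  expect_lt(invasion_test(seed_state(), "P_DEF", p_noinv), 1)
  # cooperator plasmid invades the noncooperative resident (high beta)
  p <- fig_params()
  gf <- invasion_test(seed_state(), "P_COOP", p, eps = 1e-6)
  expect_gt(gf, 1)
  # the rare-invader growth factor is invariant to eps in the linear regime
  gf2 <- invasion_test(seed_state(), "P_COOP", p, eps = 1e-8)
  expect_equal(gf, gf2, tolerance = 1e-4)
  # defectors cannot re-invade the cooperative equilibrium here
  eq <- iterate_to_equilibrium(seed_state(p_coop = 1e-3), p)
  expect_lt(invasion_test(eq$state_star, "P_DEF", p), 1)
  expect_error(invasion_test(seed_state(p_coop = 0.5), "P_COOP", p),
               "already present")
})

test_that("identical inputs give bit-identical equilibria", {
  p <- fig_params(s = 0.25)
  st <- seed_state(p_coop = 1e-3, p_def = 1e-3)
  a <- iterate_to_equilibrium(st, p)
  b <- iterate_to_equilibrium(st, p)
  expect_identical(unclass(a$state_star), unclass(b$state_star))
  expect_identical(a$generations_run, b$generations_run)
})

test_that("a small sweep reproduces the fixation and extinction laws", {
  p <- fig_params()
  sw <- sweep_equilibria(p, beta_grid = c(0, 0.5, 0.95),
                         s_grid = c(0, 0.15, 0.5))
  expect_s3_class(sw, "coop_sweep")
  expect_equal(nrow(sw), 9)
  expect_true(all(sw$converged))
  # s = 0: every invaded cell reaches plasmid fixation
  invaded <- sw$s == 0 & sw$p_total > 1e-6
  expect_true(any(invaded))
  expect_true(all(abs(sw$p_total[invaded] - 1) < 1e-8))
  # beta = 0 with s > 0: plasmid-free equilibria
  expect_true(all(sw$p_total[sw$beta == 0 & sw$s > 0] == 0))
  # cooperativeness defined only where plasmids persist
  expect_true(all(is.na(sw$cooperativeness[sw$p_total < 1e-6])))
})

test_that("chromosomal cooperation fixes when B/N exceeds C_G, plasmids or not", {
  p <- coop_params(10, beta = 0.6, s = 0.2, B = 1.435, C_G = 0.1, C_C = 0.2)
  expect_gt(p$B / p$N, p$C_G)
  eq <- iterate_to_equilibrium(
    seed_state(p_coop = 0.05, p_def = 0.05, chrom_coop = 0.1), p)
  expect_true(eq$converged)
  expect_equal(plasmid_marginals(eq$state_star)[["chrom_coop"]], 1,
               tolerance = 1e-6)
})

test_that("plasmid selection is negatively frequency-dependent", {
  p <- coop_params(20, beta = 0.95, s = 0.1, B = 1.435, C_G = 0.1, C_C = 0.2)
  prof <- frequency_dependence_profile(p, seq(0.02, 0.98, by = 0.04))
  expect_true(all(diff(prof$growth_factor) <= 1e-12))
  # near fixation with s > 0 the plasmid must decline (loss, no free cells)
  expect_lt(tail(prof$growth_factor, 1), 1)
  # the rare end enjoys the greatest transfer opportunity
  expect_equal(which.max(prof$growth_factor), 1L)
  expect_error(frequency_dependence_profile(p, c(0, 0.5)), "strictly")
})
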