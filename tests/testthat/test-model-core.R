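test_that("patch composition enumeration reproduces multinomial weights", {
  p2 <- coop_params(2, 0.5, 0.1, 1, 0.1, 0.1)
  # N = 1: single-genotype patches with weight = genotype frequency
  st <- coop_state(c(0.3, 0.3, 0.4, 0, 0, 0))
  pc <- enumerate_patch_compositions(st, coop_params(1, 0.5, 0.1, 1, 0.1, 0.1))
  expect_equal(nrow(pc$counts), 3)
  expect_equal(sort(pc$weight), sort(c(0.3, 0.3, 0.4)))
  # N = 2, two genotypes at 0.5: binomial 1/4, 1/2, 1/4
  pc2 <- enumerate_patch_compositions(seed_state(p_coop = 0.5), p2)
  expect_equal(nrow(pc2$counts), 3)
  w <- pc2$weight[order(pc2$counts[, "noncoop:coopP"])]
  expect_equal(w, c(0.25, 0.5, 0.25))
  # N = 20, 3 active genotypes: stars and bars, C(22, 2) = 231 compositions
  pc3 <- enumerate_patch_compositions(
    seed_state(p_coop = 0.1, p_def = 0.2),
    coop_params(20, 0.5, 0.1, 1, 0.1, 0.1))
  expect_equal(nrow(pc3$counts), choose(22, 2))
  expect_equal(sum(pc3$weight), 1, tolerance = 1e-12)
  expect_true(all(rowSums(pc3$counts) == 20))
  expect_error(enumerate_patch_compositions(st, coop_params(0, 0.5, 0.1, 1, 0.1, 0.1)))
})

test_that("enumeration weights match a multinomial Monte-Carlo oracle", {
  set.seed(42)
  st <- random_state(zero = c(4, 6))
  p <- coop_params(5, 0.5, 0.1, 1, 0.1, 0.1)
  pc <- enumerate_patch_compositions(st, p)
  draws <- rmultinom(20000, 5, unclass(st))
  key_draws <- apply(draws, 2, paste, collapse = "/")
  key_enum <- apply(t(pc$counts), 2, paste, collapse = "/")
  emp <- table(factor(key_draws, levels = key_enum)) / 20000
  expect_equal(as.numeric(emp), pc$weight, tolerance = 0.02)
})

test_that("within-patch transfer follows mass action and respects incompatibility", {
  # beta = 0: identity
  f <- c(0.2, 0.3, 0.1, 0.15, 0.15, 0.1)
  expect_equal(unname(within_patch_transfer(f, 0)), f)
  # no plasmid-free cells: identity (bearers cannot acquire a second plasmid)
  g <- c(0, 0.5, 0.2, 0, 0.2, 0.1)
  expect_equal(unname(within_patch_transfer(g, 0.9)), g)
  # beta = 1, free 0.5 / coopP 0.5: free halves, coopP picks up the rest
  h <- within_patch_transfer(c(0.5, 0.5, 0, 0, 0, 0), 1)
  expect_equal(unname(h[1:2]), c(0.25, 0.75))
  # conversions split between plasmid types in proportion to their frequency,
  # chromosome backgrounds untouched, simplex preserved
  out <- within_patch_transfer(f, 0.8)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(sum(out[1:3]), sum(f[1:3]))  # chromosomal marginal
  gain_C <- (out[2] - f[2]) + (out[5] - f[5])
  gain_D <- (out[3] - f[3]) + (out[6] - f[6])
  fC <- f[2] + f[5]; fD <- f[3] + f[6]
  expect_equal(unname(gain_C / gain_D), fC / fD)
})

test_that("fitness combines shared benefit with production and carriage costs", {
  p <- fig_params()
  expect_equal(fitness("noncoop:none", 0, p), 1)
  expect_equal(fitness("coop:none", 1, p), 1 + 1.435 - 0.1)  # 2.335
  expect_equal(fitness("noncoop:defP", 0, p), 0.8)
  # redundancy: chromosome + plasmid cooperator pays C_G once
  expect_equal(fitness("coop:coopP", 1, p), 1 + 1.435 - 0.1 - 0.2)
  expect_error(fitness("coop:none", 1.5, p), "coop_fraction")
  # the guard against non-positive fitness (unreachable through validated
  # parameters, which enforce 1 - C_G - C_C > 0)
  bad <- fig_params()
  bad$C_G <- 0.7; bad$C_C <- 0.5
  expect_error(fitness("coop:defP", 0, bad), "non-positive")
})

test_that("segregation loss and mutation move mass along the right edges", {
  st <- coop_state(c(0.6, 0.4, 0, 0, 0, 0))
  expect_equal(unclass(apply_loss(st, 0)), unclass(st))
  out <- apply_loss(st, 0.25)
  expect_equal(unname(out[1:2]), c(0.7, 0.3))
  # s = 1: all plasmids gone, chromosome marginals unchanged
  st2 <- random_state()
  gone <- apply_loss(st2, 1)
  expect_equal(unname(gone[c(2, 3, 5, 6)]), rep(0, 4))
  expect_equal(sum(gone[1:3]), sum(st2[1:3]))

  expect_equal(unclass(apply_mutation(st2, 0)), unclass(st2))
  mut <- apply_mutation(coop_state(c(0.8, 0.2, 0, 0, 0, 0)), 0.1)
  expect_equal(unname(mut[2:3]), c(0.18, 0.02))
  allmut <- apply_mutation(st2, 1)
  expect_equal(unname(allmut[c(2, 5)]), c(0, 0))
})

test_that("an all-noncooperative plasmid-free population is a fixed point", {
  p <- fig_params()
  st <- seed_state()
  expect_equal(as.numeric(generation_step(st, p)), as.numeric(st),
               tolerance = 1e-14)
})

test_that("without transfer a costly plasmid strictly declines", {
  p <- coop_params(20, beta = 0, s = 0.1, B = 1.435, C_G = 0.1, C_C = 0.2)
  traj <- run_recursion(seed_state(p_def = 0.2), p, 20)
  pt <- traj_p_total(traj)
  expect_true(all(diff(pt) < 0))
})

test_that("compiled and reference generation steps agree to machine precision", {
  set.seed(7)
  for (i in 1:25) {
    st <- random_state(zero = sample(0:6, sample(0:3, 1)))
    p <- random_params(max_N = 6)
    a <- generation_step(st, p, compiled = TRUE)
    b <- generation_step(st, p, compiled = FALSE)
    expect_equal(unclass(a), unclass(b), tolerance = 1e-13)
    expect_equal(attr(a, "mean_fitness"), attr(b, "mean_fitness"),
                 tolerance = 1e-13)
  }
})

test_that("every operation maps the simplex to itself", {
  set.seed(11)
  for (i in 1:400) {
    st <- random_state(zero = sample(0:6, sample(0:4, 1)))
    p <- random_params()
    expect_lt(abs(sum(generation_step(st, p)) - 1), 1e-12)
    expect_lt(abs(sum(within_patch_transfer(unclass(st), p$beta)) - 1), 1e-12)
    expect_lt(abs(sum(apply_loss(st, p$s)) - 1), 1e-12)
    expect_lt(abs(sum(apply_mutation(st, p$mu)) - 1), 1e-12)
  }
})

test_that("chromosomal cooperation cannot arise de novo (closure)", {
  set.seed(3)
  for (i in 1:20) {
    st <- random_state(zero = 4:6)  # no chromosomal cooperators
    p <- random_params()
    traj <- run_recursion(st, p, 30)
    chrom <- traj[["coop:none"]] + traj[["coop:coopP"]] + traj[["coop:defP"]]
    expect_true(all(chrom == 0))
  }
})

test_that("with B = 0, C_G = 0 plasmid dynamics ignore the chromosome", {
  p <- coop_params(6, beta = 0.7, s = 0.2, B = 0, C_G = 0, C_C = 0.15)
  st1 <- seed_state(p_coop = 0.2, p_def = 0.1, chrom_coop = 0)
  st2 <- seed_state(p_coop = 0.2, p_def = 0.1, chrom_coop = 0.6)
  t1 <- run_recursion(st1, p, 25)
  t2 <- run_recursion(st2, p, 25)
  expect_equal(traj_p_total(t1), traj_p_total(t2), tolerance = 1e-12)
})

test_that("trajectories include generation 0 and record mean fitness", {
  p <- fig_params()
  traj <- run_recursion(seed_state(p_coop = 0.01), p, 10)
  expect_equal(nrow(traj), 11)
  expect_equal(traj$generation, 0:10)
  expect_true(is.na(traj$mean_fitness[1]))
  expect_true(all(traj$mean_fitness[-1] > 0))
})
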