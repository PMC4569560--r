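## Stochastic bond formation/breakage, the molecule ledger, and bond loads.

test_that("forced P = 1 bonding is capped by partner availability", {
  ## TC face with 3.0 molecules facing a PMN face with 2.0: exactly 2 bonds
  pl <- planar_setup(n = 1, face_area = 1e-12, gap = 0.05e-6,
                     icam = 3e12, lfa = 2e12, mac = 0)
  set.seed(1)
  res <- forced_bonding_run(pl$tc, pl$pmn, pl$ledger,
                            list(lfa_type()), ref_env())
  expect_equal(res$n_bonds, 2)
  expect_equal(unname(res$ledger$pmn[1, "LFA1"]), 0)
  expect_equal(unname(res$ledger$tc[1, "ICAM1"]), 1)
})

test_that("fractional molecules: 8.3 on a face yields 8 + Bernoulli(0.3)", {
  env <- ref_env()
  counts <- vapply(1:2000, function(sd) {
    pl <- planar_setup(n = 1, face_area = 1e-12, gap = 0.05e-6,
                       icam = 8.3e12, lfa = 100e12, mac = 0)
    set.seed(sd)
    forced_bonding_run(pl$tc, pl$pmn, pl$ledger, list(lfa_type()),
                       env)$n_bonds
  }, 0)
  expect_true(all(counts %in% c(8, 9)))
  ## mean ~ 8.3 within 3 sigma of the Bernoulli(0.3) component
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(mean(counts) - 8.3), 3 * se)
})

test_that("one-step expected bond count matches sum of n * P", {
  ## one-to-one opposing planar pairs, moderate probabilities, 200+ seeds
  env <- ref_env(dt = 3e-7)
  p <- lfa_type()
  build <- function() planar_setup(n = 8, face_area = 2.5e-13,
                                   gap = 0.05e-6, icam = 13e12,
                                   lfa = 45e12, mac = 0)
  pl <- build()
  pairs <- gated_face_pairs(pl$tc, pl$pmn, 2 * p$lambda)
  expect_equal(nrow(pairs), 8)  # pitch keeps diagonals outside the gate
  ## independent expectation oracle: corrected kon from first principles
  kb <- 1.380649e-23; T <- 310.15
  kon_loc <- 3000 * 11.25 * exp(-1e-3 * (pairs$d - 5e-8)^2 / (2 * kb * T))
  kon_glob <- (8 * 11.25) * 3000 *
    exp(-1e-3 * (5e-8 - 5e-8)^2 / (2 * kb * T))
  kon_corr <- kon_loc * kon_glob / mean(kon_loc)
  P <- 1 - exp(-kon_corr * env$dt)
  ## 3 full draws at P plus the fractional draw at 0.25 P per face:
  ## expected count per face = (3 + 0.25) P
  expected <- sum((3 + 0.25) * P)
  var1 <- sum(3 * P * (1 - P) + 0.25 * P * (1 - 0.25 * P))
  n_seed <- 300
  counts <- vapply(seq_len(n_seed), function(sd) {
    pl <- build()
    set.seed(sd)
    nrow(formation_step(pairs, pl$tc, pl$pmn, pl$ledger, list(p),
                        env)$bonds)
  }, 0)
  se <- sqrt(var1 / n_seed)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("breakage is binomial and restores availability", {
  env <- ref_env(dt = 1e-3)
  p <- lfa_type()
  ## zero rate: everything survives
  pl <- planar_setup(n = 8, icam = 20e12, lfa = 45e12, mac = 0)
  set.seed(5)
  res <- forced_bonding_run(pl$tc, pl$pmn, pl$ledger, list(p), env)
  keep <- breakage_step(res$bonds, pl$tc, pl$pmn, res$ledger, list(p),
                        env, forced_p = 0)
  expect_equal(nrow(keep$bonds), res$n_bonds)
  ## forced P = 0.25 on ~1000 bonds: survivors within 3 sigma binomial
  pl2 <- planar_setup(n = 10, face_area = 1e-11, gap = 0.05e-6,
                      icam = 10e12, lfa = 100e12, mac = 0)
  set.seed(6)
  res2 <- forced_bonding_run(pl2$tc, pl2$pmn, pl2$ledger, list(p), env)
  expect_equal(res2$n_bonds, 1000)
  set.seed(7)
  surv <- breakage_step(res2$bonds, pl2$tc, pl2$pmn, res2$ledger, list(p),
                        env, forced_p = 0.25)
  expect_lt(abs(nrow(surv$bonds) - 750), 3 * sqrt(1000 * 0.25 * 0.75))
  ## broken bonds returned their molecules
  expect_equal(ledger_conservation_error(surv$ledger, surv$bonds, list(p)),
               0, tolerance = 1e-9)
})

test_that("molecules are conserved over 1000 form/break cycles", {
  ## gap slightly past lambda so both formation and breakage are active
  env <- ref_env(dt = 0.5)
  types <- list(lfa_type(), mac_type())
  pl <- planar_setup(n = 8, face_area = 2.5e-13, gap = 0.054e-6)
  pairs <- gated_face_pairs(pl$tc, pl$pmn, 0.1e-6)
  ledger <- pl$ledger
  bonds <- empty_bonds(); bonds$d_form <- numeric(0)
  set.seed(11)
  worst <- 0
  for (step in 1:1000) {
    br <- breakage_step(bonds, pl$tc, pl$pmn, ledger, types, env)
    bonds <- br$bonds; ledger <- br$ledger
    fr <- formation_step(pairs, pl$tc, pl$pmn, ledger, types, env,
                         time = step)
    ledger <- fr$ledger
    bonds <- rbind(bonds, fr$bonds)
    worst <- max(worst, ledger_conservation_error(ledger, bonds, types))
  }
  expect_lt(worst, 1e-9)
  expect_true(all(ledger$tc >= 0) && all(ledger$pmn >= 0))
  ## the churn actually exercised both processes
  expect_gt(nrow(bonds), 0)
})

test_that("a TC molecule cannot be double-booked across bond types", {
  ## one TC species against two PMN species, 1.0 ICAM per face:
  ## total bonds across both types is at most one per TC face
  pl <- planar_setup(n = 8, face_area = 1e-12, gap = 0.05e-6,
                     icam = 1e12, lfa = 45e12, mac = 5e12)
  set.seed(2)
  res <- forced_bonding_run(pl$tc, pl$pmn, pl$ledger,
                            list(lfa_type(), mac_type()), ref_env())
  expect_equal(res$n_bonds, 8)
  per_face <- table(res$bonds$tc_face)
  expect_true(all(per_face <= 1))
})

test_that("bond loads: rest length, Hookean magnitude, symmetry", {
  env <- ref_env(eps_mv = 0)
  p <- lfa_type()
  mkbond <- function(n) data.frame(tc_face = seq_len(n), pmn_face = seq_len(n),
                                   type = p$name, t_form = 0,
                                   tc_used = 1, pmn_used = 1)
  ## at the equilibrium length: zero force
  tc <- point_faces(c(0, 0.05e-6, 0), "tc")
  pm <- point_faces(c(0, 0, 0), "pmn")
  bl <- bond_loads(mkbond(1), tc, pm, list(p), env)
  expect_equal(bl$F, c(0, 0, 0))
  ## 50 nm stretch at s = 2e-3 N/m: |f| = 1.0e-10 N, pulling the TC down
  tc2 <- point_faces(c(0, 0.10e-6, 0), "tc")
  bl2 <- bond_loads(mkbond(1), tc2, pm, list(p), env)
  expect_equal(bl2$force, 1e-10)
  expect_equal(bl2$F, c(0, -1e-10, 0))
  ## compression pushes apart
  tc3 <- point_faces(c(0, 0.02e-6, 0), "tc")
  expect_gt(bond_loads(mkbond(1), tc3, pm, list(p), env)$F[2], 0)
  ## mirror-symmetric bonds about the centroid axis: zero net torque
  tc4 <- point_faces(rbind(c(1e-6, 0.1e-6, 0), c(-1e-6, 0.1e-6, 0)), "tc")
  pm4 <- point_faces(rbind(c(1e-6, 0, 0), c(-1e-6, 0, 0)), "pmn")
  bl4 <- bond_loads(mkbond(2), tc4, pm4, list(p), env)
  expect_equal(bl4$T, c(0, 0, 0), tolerance = 1e-25)
})

test_that("formation draws are reproducible for a fixed seed", {
  pl <- planar_setup()
  env <- ref_env(dt = 1e-5)
  pairs <- gated_face_pairs(pl$tc, pl$pmn, 0.1e-6)
  run <- function() {
    set.seed(99)
    formation_step(pairs, pl$tc, pl$pmn, pl$ledger,
                   list(lfa_type(), mac_type()), env)$bonds
  }
  expect_identical(run(), run())
})
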