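test_that("ensemble J-factors follow the Boltzmann closed forms", {
  e1 <- ensemble_jfactor(list(fake_state(0)))
  expect_equal(e1$J, 1)
  expect_equal(unname(e1$fractions), 1)

  e2 <- ensemble_jfactor(list(fake_state(0, twist = 30),
                              fake_state(log(2), twist = 38)))
  expect_equal(unname(e2$fractions), c(2 / 3, 1 / 3), tolerance = 1e-12)

  oris <- rep(c("A1", "A2", "P1", "P2"), each = 2)
  fams <- rep(c("F1", "F2"), 4)
  e8 <- ensemble_jfactor(Map(function(o, f, tw) fake_state(1.5, o, f, tw),
                             oris, fams, 30 + seq_len(8)))
  expect_equal(unname(e8$fractions), rep(1 / 8, 8), tolerance = 1e-12)
  expect_equal(e8$J, 8 * exp(-1.5), tolerance = 1e-12)
})

test_that("fractions normalize and J ignores infeasible states", {
  s_bad <- fake_state(0.2, "P1", twist = 50)
  s_bad$feasible <- FALSE
  states <- list(fake_state(0.7, twist = 31), fake_state(2.1, twist = 39),
                 s_bad)
  e <- ensemble_jfactor(states)
  expect_equal(sum(e$fractions), 1, tolerance = 1e-12)
  expect_equal(e$J, exp(-0.7) + exp(-2.1), tolerance = 1e-12)
  expect_equal(e$n_excluded, 1L)
  # zero feasible states: J = 0, fractions undefined
  e0 <- ensemble_jfactor(list(s_bad))
  expect_equal(e0$J, 0)

  # a constant energy offset rescales J without moving the fractions
  shifted <- lapply(states[1:2], function(s) { s$psi <- s$psi + 1.3; s })
  e_sh <- ensemble_jfactor(shifted)
  expect_equal(e_sh$J, e$J * exp(-1.3), tolerance = 1e-12)
  expect_equal(e_sh$fractions, e$fractions, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("extrema detection handles monotone, peaked, and periodic input", {
  mono <- data.frame(spacing = 1:6, J = 1:6)
  expect_equal(nrow(find_extrema(mono)), 0L)

  tri <- data.frame(spacing = 1:5, J = c(1, 2, 5, 2, 1))
  ex <- find_extrema(tri)
  expect_equal(ex$spacing, 3)
  expect_equal(ex$type, "max")

  hr <- 10.9
  spg <- seq(100, 130, 0.5)
  ex2 <- find_extrema(data.frame(spacing = spg,
                                 J = 2 + cos(2 * pi * spg / hr)))
  expect_true(all(abs(diff(ex2$spacing) - hr / 2) <= 0.5))
  # ties break to the smaller spacing
  flat <- data.frame(spacing = 1:5, J = c(0, 1, 1, 0, 0))
  expect_equal(find_extrema(flat)$spacing[1], 2)
})

test_that("twisted-WLC phasing is periodic and vanishes without torsion", {
  hr <- 10.48
  # the phasing modulation recurs one helical repeat later (up to the slow
  # growth of the twist variance with contour length)
  f1 <- wlc_jfactor(300, hr = hr) / wlc_jfactor(300, hr = hr,
                                                torsional_c = 0)
  f2 <- wlc_jfactor(300 + hr, hr = hr) /
    wlc_jfactor(300 + hr, hr = hr, torsional_c = 0)
  expect_equal(f1, f2, tolerance = 0.05)
  # and its peaks are spaced by exactly one repeat
  lb0 <- seq(295, 320, 0.02)
  mod0 <- wlc_jfactor(lb0, hr = hr) / wlc_jfactor(lb0, hr = hr,
                                                  torsional_c = 0)
  pk <- lb0[which(diff(sign(diff(mod0))) == -2) + 1]
  expect_equal(diff(pk)[1], hr, tolerance = 1e-2)

  lb <- seq(290, 312, 0.5)
  mod <- wlc_jfactor(lb) / wlc_jfactor(lb, torsional_c = 0)
  expect_gt(max(mod), 1.2)        # oscillates with torsion on
  expect_lt(min(mod), 0.8)
  expect_equal(wlc_jfactor(lb, torsional_c = 0),
               112.04 / 465^3 * (lb * 3.4 / 465)^(-5) *
                 exp(-14.055 / (lb * 3.4 / 465) +
                       0.246 * lb * 3.4 / 465) * 1e27 / 6.02214e23,
               tolerance = 1e-12)
  expect_error(wlc_jfactor(80), "100 bp")
})

test_that("the closure envelope matches a brute-force Monte-Carlo estimate", {
  # independent discrete-chain sampling of the same wormlike-chain model
  j_mc <- mc_ring_closure(400, 46.5, n_chains = 1.2e6, seed = 42)
  j_cf <- wlc_jfactor(400, 46.5, torsional_c = 0)
  expect_lt(abs(log(j_mc / j_cf)), log(2))   # within a factor of two
})
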