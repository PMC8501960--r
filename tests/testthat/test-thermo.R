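test_that("repression-level ratios and the J transform are exact", {
  expect_equal(repression_level(1000, 200), 5)
  expect_error(repression_level(0, 10), "positive")
  expect_equal(normalized_rl(10, 2), 5)
  expect_equal(normalized_rl(7, 7), 1)

  expect_equal(jloop_from_rl(9, 5, 100), 100)
  expect_equal(jloop_from_rl(5, 5, 100), 0)
  expect_error(jloop_from_rl(9, 1, 100), "undefined")
  # exact round trip
  rl <- c(2.3, 5, 17.8, 140)
  expect_equal(rl_from_jloop(jloop_from_rl(rl, 5, 100), 5, 100), rl,
               tolerance = 1e-14)
})

test_that("the twist penalty is periodic with the quoted magnitude", {
  expect_equal(twist_penalty(144, 11, 144, 0.5, 144), 0)
  expect_equal(twist_penalty(144 + 11, 11, 144, 0.5, 144), 0)
  expect_equal(twist_penalty(144 - 2 * 11, 11, 144, 0.5, 144), 0)
  # half-register cost, hand arithmetic:
  # C pi^2 / (2 L kBT) with C = 0.44e-19 erg cm, L = 138 * 3.4e-8 cm
  dg <- twist_penalty(144.03 + 11.07 / 2, 11.07, 144.03, 0.44, 138)
  expect_equal(dg, 0.44e-19 * pi^2 / (2 * 138 * 3.4e-8 * 4.1e-14),
               tolerance = 1e-12)
  expect_equal(dg, 1.13, tolerance = 0.005)
})

test_that("the RL model obeys its limiting forms", {
  p <- list(hr = 11, c_app = 0.5, k_max = 0, k_nsl = 0, sp_optimal = 144)
  expect_equal(rl_model(seq(130, 150, 2), p, rl_noloop = 5),
               rep(5, 11), tolerance = 1e-12)
  p2 <- list(hr = 11, c_app = 0.5, k_max = 20, k_nsl = 2, sp_optimal = 144)
  expect_equal(rl_model(144, p2, rl_noloop = 5), 5 + 4 * 22,
               tolerance = 1e-12)
  # infinitely stiff torsion: only the register spacing keeps the loop
  p3 <- list(hr = 11, c_app = 1e7, k_max = 20, k_nsl = 2, sp_optimal = 144)
  off <- rl_model(c(140, 149), p3, rl_noloop = 5)
  expect_equal(off, rep(5 + 4 * 2, 2), tolerance = 1e-6)
  expect_equal(rl_model(144, p3, rl_noloop = 5), 5 + 4 * 22,
               tolerance = 1e-12)
})

test_that("model-implied J commutes with the RL transform", {
  p <- list(hr = 11.07, c_app = 0.44, k_max = 33.56, k_nsl = 1.2,
            sp_optimal = 144.03)
  sp <- seq(131.5, 146.5, 0.25)
  rl <- rl_model(sp, p, rl_noloop = 5)
  j_direct <- 100 * (p$k_nsl + p$k_max *
                       exp(-twist_penalty(sp, p$hr, p$sp_optimal, p$c_app,
                                          sp)))
  expect_equal(jloop_from_rl(rl, 5, 100), j_direct, tolerance = 1e-9)
})

test_that("noiseless synthetic data are refit to numerical precision", {
  for (cond in c("ns_tale", "sp_tale", "sp_tale_nhp6a", "ns_tale_nhp6a")) {
    truth <- series1_params(cond)
    d <- generate_rl_dataset(truth, series = 1, noise = 0, rl_noloop = 5,
                             condition = cond)
    f <- fit_series1(d, rl_noloop = 5)
    est <- coef(f)[names(unlist(truth))]
    nonzero <- unlist(truth) != 0
    expect_lt(max(abs(est[nonzero] - unlist(truth)[nonzero]) /
                    unlist(truth)[nonzero]), 1e-4)
    if (any(!nonzero)) expect_lt(max(abs(est[!nonzero])), 1e-4)
  }
})

test_that("series-2 fitting recovers its three parameters with hr fixed", {
  truth <- series2_params("sp_tale")
  d <- generate_rl_dataset(truth, series = 2, noise = 0, rl_noloop = 5,
                           hr = 10.96)
  f <- fit_series2(d, hr = 10.96, rl_noloop = 5)
  expect_lt(max(abs(coef(f)[names(unlist(truth))] - unlist(truth)) /
                  unlist(truth)), 1e-4)
  # and with modest noise the recovery stays in range
  dn <- generate_rl_dataset(truth, series = 2, noise = 0.1, rl_noloop = 5,
                            hr = 10.96, seed = 77)
  fn <- fit_series2(dn, hr = 10.96, rl_noloop = 5)
  expect_lt(abs(coef(fn)[["k_smax"]] - truth$k_smax) / truth$k_smax, 0.35)
})

test_that("fits are invariant to row order", {
  truth <- series1_params("sp_tale")
  d <- generate_rl_dataset(truth, series = 1, noise = 0.08, rl_noloop = 5,
                           seed = 31)
  f1 <- fit_series1(d, rl_noloop = 5)
  set.seed(9)
  d2 <- d[sample(nrow(d)), ]
  attr(d2, "rl_noloop") <- 5
  f2 <- fit_series1(d2, rl_noloop = 5)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("boundary estimates report one-sided confidence intervals", {
  truth <- series1_params("ns_tale")   # k_nsl at the zero boundary
  d <- generate_rl_dataset(truth, series = 1, noise = 0.05, rl_noloop = 5,
                           seed = 12)
  f <- fit_series1(d, rl_noloop = 5)
  if (coef(f)[["k_nsl"]] < 1e-8)
    expect_equal(unname(f$ci["k_nsl", "lower"]), 0)
  expect_true(all(c("hr", "c_app", "k_max", "k_nsl", "sp_optimal") %in%
                    names(coef(f))))
})
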