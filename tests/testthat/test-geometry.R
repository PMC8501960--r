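test_that("step transform handles identity, pure twist, and pure roll", {
  expect_equal(step_transform(rep(0, 6)), diag(4))

  M <- step_transform(c(0, 0, 36, 0, 0, 3.4))
  expect_equal(M[1:3, 1:3], aa_rot(c(0, 0, 1), 36), tolerance = 1e-12)
  expect_equal(M[1:3, 4], c(0, 0, 3.4), tolerance = 1e-12)

  # 90-degree roll: successor normal perpendicular to predecessor normal,
  # rotation matches an independently coded axis-angle composition
  M <- step_transform(c(0, 0, 0, 0, 0, 0) + c(0, 90, 0, 0, 0, 0))
  expect_equal(M[1:3, 1:3], aa_rot(c(0, 1, 0), 90), tolerance = 1e-12)
  expect_lt(abs(sum(M[1:3, 3] * c(0, 0, 1))), 1e-12)

  # tilt rotates about the short axis
  M <- step_transform(c(25, 0, 0, 0, 0, 0))
  expect_equal(M[1:3, 1:3], aa_rot(c(1, 0, 0), 25), tolerance = 1e-12)

  expect_error(step_transform(c(NA, 0, 0, 0, 0, 0)), "non-finite")
})

test_that("a closed helical register returns to the start orientation", {
  steps <- matrix(rep(c(0, 0, 360 / 10.9, 0, 0, 3.4), 109),
                  ncol = 6, byrow = TRUE)
  fr <- build_chain(bp_frame(), steps)
  expect_equal(dim(fr)[3], 110L)
  expect_equal(fr[1:3, 4, 110], c(0, 0, 109 * 3.4), tolerance = 1e-9)
  expect_equal(fr[1:3, 1:3, 110], diag(3), tolerance = 1e-9)
})

test_that("build_chain and extract_steps are mutually inverse", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    steps <- cbind(rnorm(n, 0, 8), rnorm(n, 0, 8), rnorm(n, 34, 8),
                   rnorm(n, 0, 0.6), rnorm(n, 0, 0.6), rnorm(n, 3.4, 0.5))
    fr <- build_chain(bp_frame(), steps)
    expect_lt(max(abs(extract_steps(fr) - steps)), 1e-8)
  }
  # two identical frames give the all-zero step
  fr2 <- array(rep(diag(4), 2), c(4, 4, 2))
  expect_equal(unname(extract_steps(fr2)[1, ]), rep(0, 6))
  # ideal 10.48 bp/turn helix
  fr3 <- build_chain(bp_frame(),
                     matrix(rep(c(0, 0, 360 / 10.48, 0, 0, 3.4), 5),
                            ncol = 6, byrow = TRUE))
  st3 <- extract_steps(fr3)
  expect_equal(unname(st3[, "twist"]), rep(360 / 10.48, 5), tolerance = 1e-10)
  expect_equal(unname(st3[, "rise"]), rep(3.4, 5), tolerance = 1e-10)
  expect_lt(max(abs(st3[, c("tilt", "roll", "shift", "slide")])), 1e-10)
})

test_that("chains compose associatively when built in halves", {
  set.seed(3)
  n <- 30
  steps <- cbind(rnorm(n, 0, 5), rnorm(n, 0, 5), rnorm(n, 33, 5),
                 rnorm(n, 0, .4), rnorm(n, 0, .4), rnorm(n, 3.4, .3))
  whole <- build_chain(bp_frame(), steps)
  half1 <- build_chain(bp_frame(), steps[1:15, ])
  half2 <- build_chain(half1[, , 16], steps[16:30, ])
  expect_equal(whole[, , 31], half2[, , 16], tolerance = 1e-10)
})

test_that("strand reversal negates tilt and shift and is an involution", {
  set.seed(5)
  n <- 25
  steps <- cbind(rnorm(n, 0, 6), rnorm(n, 0, 6), rnorm(n, 34, 5),
                 rnorm(n, 0, .5), rnorm(n, 0, .5), rnorm(n, 3.4, .3))
  colnames(steps) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  rv <- reverse_steps(steps)
  expect_equal(unname(rv[, "tilt"]), unname(-rev(steps[, "tilt"])),
               tolerance = 1e-9)
  expect_equal(unname(rv[, "shift"]), unname(-rev(steps[, "shift"])),
               tolerance = 1e-9)
  expect_equal(unname(rv[, c("roll", "twist", "slide", "rise")]),
               unname(steps[rev(seq_len(n)), c("roll", "twist", "slide",
                                               "rise")]),
               tolerance = 1e-9)
  expect_equal(reverse_steps(rv), steps, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("invalid frames and malformed steps are rejected", {
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(extract_steps(array(c(diag(4), bad), c(4, 4, 2))),
               "orthonormal")
  expect_error(as_step_matrix(matrix(1, 2, 5)), "6 columns")
  expect_error(bp_frame(orientation = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1),
                                             3, 3)), "left-handed")
})
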