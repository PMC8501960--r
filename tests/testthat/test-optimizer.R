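test_that("a rest-register boundary optimizes to zero energy", {
  n_bp <- 41
  b <- loop_boundary(bp_frame(), rest_end_frame(n_bp, ff10))
  seed <- dna_chain(bp_frame(), rest_chain_steps(n_bp - 1, ff10))
  s <- optimize_loop(seed, b, ff10)
  expect_true(s$feasible)
  expect_lt(s$psi, 1e-6)
  expect_true(s$monotone)
})

test_that("a pure torsional offset is shared equally across free steps", {
  n_bp <- 61
  end <- rest_end_frame(n_bp, ff10) %*% step_transform(c(0, 0, 10, 0, 0, 0))
  b <- loop_boundary(bp_frame(), end)
  seed <- dna_chain(bp_frame(), rest_chain_steps(n_bp - 1, ff10))
  s <- optimize_loop(seed, b, ff10)
  kt <- force_constants(ff10)[["twist"]]
  analytic <- 0.5 * kt * (10 * pi / 180)^2 / (n_bp - 1)
  expect_true(s$feasible)
  expect_equal(s$psi, analytic, tolerance = 1e-3)
  # the optimal twist offset is uniform
  tw <- s$chain$steps[, "twist"]
  expect_lt(diff(range(tw)), 0.02)
})

test_that("a planar U-turn matches the uniform-arc elastic-rod energy", {
  fix <- uturn_fixture(61, ff10)
  s <- optimize_loop(fix$seed, fix$boundary, ff10)
  kb <- force_constants(ff10)[["tilt"]]
  analytic <- 0.5 * kb * pi^2 / fix$n_steps
  expect_true(s$feasible)
  expect_equal(s$psi, analytic, tolerance = 0.05)
})

test_that("frozen segments are bit-identical through optimization", {
  bd <- make_toy_boundary(30, 50, "A1")
  s <- optimize_loop(seed_configuration(bd, 66, "F1", ff_std), bd, ff_std,
                     family = "F1")
  fp <- idealized_tale_footprint()
  sf <- insert_protein(s, fp, position = 22, ramp_steps = 4, ff = ff_std)
  expect_identical(unname(sf$chain$steps[22:36, ]), unname(fp$steps))
  expect_true(all(sf$chain$labels[22:36] == "frozen:tale_ideal"))
  # and a further optimization leaves them untouched
  s2 <- optimize_loop(sf$chain, bd, ff_std, family = "F1")
  expect_identical(unname(s2$chain$steps[22:36, ]), unname(fp$steps))
  expect_gt(sf$psi, s$psi)   # straight stiff insert strains a bent loop
})

test_that("ramped insertion agrees with direct frozen optimization", {
  bd <- make_toy_boundary(30, 50, "A1")
  dn <- optimize_loop(seed_configuration(bd, 70, "F1", ff_std), bd, ff_std,
                      family = "F1")
  fp <- idealized_tale_footprint()
  ramped <- insert_protein(dn, fp, position = 25, ramp_steps = 5,
                           ff = ff_std)
  st <- dn$chain$steps; st[25:39, ] <- fp$steps
  lab <- dn$chain$labels; lab[25:39] <- "frozen:tale_ideal"
  direct <- optimize_loop(dna_chain(dn$chain$first, st, lab), bd, ff_std,
                          family = "F1")
  expect_true(ramped$feasible && direct$feasible)
  expect_lt(abs(ramped$psi - direct$psi), 0.1)
})

test_that("growing a loop matches de-novo seeding at the target length", {
  bd <- make_toy_boundary(30, 50, "A1")
  s66 <- optimize_loop(seed_configuration(bd, 66, "F1", ff_std), bd,
                       ff_std, family = "F1")
  grown <- grow_loop(s66, 70, ff_std)
  denovo <- optimize_loop(seed_configuration(bd, 70, "F1", ff_std), bd,
                          ff_std, family = "F1")
  expect_true(grown$feasible)
  expect_equal(nrow(grown$chain$steps), 69L)
  expect_lt(abs(grown$psi - denovo$psi), 0.1)
  # growing a rest-state chain while the boundary advances by rest steps
  # costs nothing
  b0 <- loop_boundary(bp_frame(), rest_end_frame(31, ff10))
  s0 <- optimize_loop(dna_chain(bp_frame(), rest_chain_steps(30, ff10)),
                      b0, ff10)
  b1 <- loop_boundary(bp_frame(), rest_end_frame(33, ff10))
  g0 <- grow_loop(s0, 33, ff10, boundary = b1)
  expect_lt(g0$psi, 1e-6)
})

test_that("the two family seeds reach distinct optima under strain", {
  bd <- make_toy_boundary(30, 50, "A1")
  # a strained spacing (between registers)
  s1 <- optimize_loop(seed_configuration(bd, 73, "F1", ff_std), bd, ff_std,
                      family = "F1")
  s2 <- optimize_loop(seed_configuration(bd, 73, "F2", ff_std), bd, ff_std,
                      family = "F2")
  d <- s1$chain$steps - s2$chain$steps
  distinct <- sqrt(mean(d[, 1:3]^2)) > 0.5 ||
    sqrt(mean(d[, 4:6]^2)) > 0.05
  expect_true(distinct)
  expect_equal(length(dedup_states(list(s1, s2))), 2L)
  # a state is its own duplicate
  expect_equal(length(dedup_states(list(s1, s1))), 1L)
})

test_that("mirror-imaging a configuration flips its chirality measure", {
  bd <- make_toy_boundary(30, 50, "A1")
  s <- optimize_loop(seed_configuration(bd, 73, "F1", ff_std), bd, ff_std,
                     family = "F1")
  wr <- classify_loop(s)$chirality
  orig <- chain_origins(s$chain)
  mirrored <- orig; mirrored[, 2] <- -mirrored[, 2]
  expect_equal(polyline_writhe(mirrored), -wr, tolerance = 1e-9)
})

test_that("steric screening passes rods and circles but fails hairpins", {
  expect_true(steric_clear(dna_chain(bp_frame(), rest_chain_steps(139,
                                                                  ff_std))))
  # 140-bp circle: diameter ~ 151 A exceeds the 18-A cutoff
  circ <- rest_chain_steps(139, ff_std)
  circ[, "roll"] <- 360 / 139
  expect_true(steric_clear(dna_chain(bp_frame(), circ)))
  # tight hairpin: antiparallel strands ~4 A apart
  arm <- rest_chain_steps(20, ff_std)
  turn <- rbind(c(0, 178, 34, 0, 0, 3.4), c(0, 2, 34, 0, 0, 3.4))
  colnames(turn) <- colnames(arm)
  expect_false(steric_clear(dna_chain(bp_frame(), rbind(arm, turn, arm))))
})

test_that("infeasible seeds and bad footprint placements error", {
  bd <- make_toy_boundary(30, 500, "A1")   # far beyond a 20-bp contour
  expect_error(seed_configuration(bd, 20, "F1", ff_std), "infeasible")
  bd2 <- make_toy_boundary(30, 50, "A1")
  s <- optimize_loop(seed_configuration(bd2, 66, "F1", ff_std), bd2,
                     ff_std, family = "F1")
  expect_error(insert_protein(s, idealized_tale_footprint(), position = 60,
                              ff = ff_std), "fit")
})
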