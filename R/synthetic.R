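# Synthetic inputs: reporter-style repression datasets, idealized protein
# footprints, and toy repressor boundary geometries.  Everything the
# downstream modules consume can be generated here, so the full pipeline
# runs without any external structure or measurement files.

#' Generate a synthetic repression dataset
#'
#' Draws replicate repression levels around the thermodynamic model curve
#' (Gaussian noise on RL, by default 10% of the model value, matching the
#' scale of reporter-assay error bars) and reports the per-spacing mean,
#' standard deviation and replicate count.  The seed fully determines the
#' output.
#'
#' @param params generating parameters ([series1_params()] /
#'   [series2_params()] style list).
#' @param series 1 or 2.
#' @param spacings spacing grid in bp; defaults to the experimental grids
#'   (131.5-146.5 for series 1, 85.5-100.5 for series 2, 1-bp increments).
#' @param rl_noloop no-loop repression baseline.
#' @param noise relative noise level (sd as a fraction of RL); 0 gives the
#'   model exactly.
#' @param replicates independent colonies per spacing.
#' @param hr helical repeat for series 2 (fixed there).
#' @param seed RNG seed.
#' @param condition label stored with the dataset.
#' @return `data.frame` of class `rl_data` with columns `series`,
#'   `condition`, `spacing`, `RL`, `sd`, `n`; attributes `rl_noloop` and
#'   `series`.
#' @export
generate_rl_dataset <- function(params, series = 1, spacings = NULL,
                                rl_noloop = 5, noise = 0.1, replicates = 6,
                                hr = NULL, seed = 20210903L,
                                condition = "synthetic") {
  stopifnot(noise >= 0, replicates >= 1)
  if (is.null(spacings))
    spacings <- if (series == 1) seq(131.5, 146.5, 1) else seq(85.5, 100.5, 1)
  mu <- rl_model(spacings, params, rl_noloop, series = series, hr = hr)
  set.seed(as.integer(seed))
  rl <- numeric(length(mu)); sdv <- numeric(length(mu))
  for (i in seq_along(mu)) {
    reps <- mu[i] + rnorm(replicates, 0, noise * mu[i])
    reps <- pmax(reps, 1e-6)
    rl[i] <- mean(reps)
    sdv[i] <- if (replicates > 1) sd(reps) else 0
  }
  if (noise == 0) { rl <- mu; sdv <- rep(0, length(mu)) }
  out <- data.frame(series = series, condition = condition,
                    spacing = spacings, RL = rl, sd = sdv, n = replicates,
                    stringsAsFactors = FALSE)
  attr(out, "rl_noloop") <- rl_noloop
  attr(out, "series") <- series
  class(out) <- c("rl_data", "data.frame")
  out
}

#' Idealized TALE footprint
#'
#' A straight, 16-bp rigid segment with the ~11.5 bp/turn repeat of
#' TALE-bound DNA: twist 360/11.5 deg per step, rise 3.4 A, all other
#' parameters zero.  Models the stiffening hypothesis -- the footprint
#' itself is unbent but deformation inside it is forbidden.
#'
#' @param length_bp footprint length (bp).
#' @param bp_per_turn helical repeat of the protein-bound segment.
#' @return a [protein_footprint()].
#' @export
idealized_tale_footprint <- function(length_bp = 16, bp_per_turn = 11.5) {
  n <- length_bp - 1
  steps <- cbind(tilt = 0, roll = 0, twist = rep(360 / bp_per_turn, n),
                 shift = 0, slide = 0, rise = 3.4)
  protein_footprint("tale_ideal", steps, "forward")
}

#' Idealized Nhp6A (HMGB) footprint
#'
#' A 10-bp segment reproducing the two signature deformations of
#' minor-groove HMG-box binding: a net ~90 degree kink between the entry
#' and exit helix axes, distributed as roll over the three central steps
#' (which carry no twist, so the roll axes stay parallel and the bend adds
#' exactly), and net undertwisting relative to protein-free DNA.
#'
#' @param orientation `"forward"` or `"reverse"`; the reverse footprint is
#'   the exact convention-consistent parameter reversal.
#' @param kink_deg total inter-axis bend (degrees).
#' @param flank_twist twist (degrees) on the non-kinked steps.
#' @return a [protein_footprint()] of 10 bp (9 steps).
#' @export
idealized_nhp6a_footprint <- function(orientation = "forward",
                                      kink_deg = 90, flank_twist = 360 / 10.5) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  n <- 9
  steps <- cbind(tilt = 0, roll = 0, twist = rep(flank_twist, n),
                 shift = 0, slide = 0, rise = 3.4)
  kink_idx <- 4:6
  steps[kink_idx, "roll"] <- kink_deg / 3
  steps[kink_idx, "twist"] <- 0
  if (orientation == "reverse") steps <- reverse_steps(steps)
  protein_footprint(paste0("nhp6a_ideal_", orientation), steps, orientation)
}

#' Toy V-shaped repressor boundary
#'
#' A stand-in for repressor-bound operator frames: two end frames in a
#' plane, separated along x, with the helix axes tilted apart by an
#' opening angle; the far frame is turned 180 degrees so that a smooth
#' U-shaped loop connects them.  The four orientation variants are
#' generated by flipping each operator's strand direction
#' (see [boundary_variants()]).
#'
#' @param opening_angle angle (degrees) by which the two helix axes tilt
#'   away from antiparallel.
#' @param separation distance (Angstrom) between the operator frames.
#' @param orientation `"A1"`, `"A2"`, `"P1"`, `"P2"`, or `"all"` for the
#'   named list of all four.
#' @return a [loop_boundary()], or a list of four when
#'   `orientation = "all"`.
#' @export
make_toy_boundary <- function(opening_angle = 30, separation = 50,
                              orientation = "A1") {
  half <- opening_angle / 2
  S <- bp_frame(c(0, 0, 0), rot_y(-half))
  # far frame turned 180 deg about x so its helix axis points back down
  E <- bp_frame(c(separation, 0, 0), rot_y(half) %*% diag(c(1, -1, -1)))
  vars <- boundary_variants(S, E)
  if (identical(orientation, "all")) return(vars)
  vars[[match.arg(orientation, c("A1", "A2", "P1", "P2"))]]
}
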