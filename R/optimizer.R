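# Energy optimization of DNA loops between fixed protein-bound end frames.
#
# The last frame of the chain is driven onto the boundary end frame by a
# quadratic penalty (stiff springs on the end origin and on the Frobenius
# mismatch of the end orientation) whose stiffness is increased over a
# short continuation ladder; feasibility is verified afterwards at
# 0.05 A / 0.05 deg.  Minimization is quasi-Newton (L-BFGS-B) over the
# 6*(n free steps) parameters with gradients from the compiled kernel.

#' Loop boundary: repressor-bound end frames
#'
#' @param start,end 4x4 base-pair frames of the first and last base pair of
#'   the loop (operator termini on the protein assembly).
#' @param orientation one of `"A1"`, `"A2"`, `"P1"`, `"P2"`, the four frame
#'   pairings generated from one repressor geometry by flipping each
#'   operator's 5'->3' direction.
#' @return Object of class `loop_boundary`.
#' @export
loop_boundary <- function(start, end, orientation = "A1") {
  orientation <- match.arg(orientation, c("A1", "A2", "P1", "P2"))
  structure(list(start = as_frame(start), end = as_frame(end),
                 orientation = orientation),
            class = "loop_boundary")
}

#' @export
print.loop_boundary <- function(x, ...) {
  d <- sqrt(sum((frame_origin(x$start) - frame_origin(x$end))^2))
  cat(sprintf("Loop boundary %s: end-to-end separation %.1f A\n",
              x$orientation, d))
  invisible(x)
}

#' Flip a base-pair frame to the opposite strand direction
#'
#' Rotates the frame 180 degrees about its short axis, reversing the
#' apparent 5'->3' direction of the bound operator.
#'
#' @param f 4x4 frame.
#' @return flipped 4x4 frame.
#' @export
flip_frame <- function(f) {
  f <- as_frame(f)
  f %*% diag(c(1, -1, -1, 1))
}

#' The four orientation variants of one repressor geometry
#'
#' @param start,end the reference operator frames.
#' @return named list of four [loop_boundary()] objects (`A1`, `A2`, `P1`,
#'   `P2`), obtained by flipping neither, both, or one of the two frames.
#' @export
boundary_variants <- function(start, end) {
  list(A1 = loop_boundary(start, end, "A1"),
       A2 = loop_boundary(flip_frame(start), flip_frame(end), "A2"),
       P1 = loop_boundary(start, flip_frame(end), "P1"),
       P2 = loop_boundary(flip_frame(start), end, "P2"))
}

#' Protein footprint: a frozen run of step parameters
#'
#' @param name identifier (e.g. a TALE or Nhp6A model label).
#' @param steps (length-1) x 6 step-parameter matrix of the protein-bound
#'   segment; a footprint of `n` bp has `n - 1` steps.
#' @param orientation `"forward"` or `"reverse"`; reversal is the
#'   convention-consistent parameter reversal of [reverse_steps()].
#' @return Object of class `protein_footprint`.
#' @export
protein_footprint <- function(name, steps, orientation = "forward") {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  structure(list(name = name, steps = as_step_matrix(steps),
                 length = nrow(as_step_matrix(steps)) + 1L,
                 orientation = orientation),
            class = "protein_footprint")
}

#' @export
print.protein_footprint <- function(x, ...) {
  cat(sprintf("Protein footprint '%s' (%s): %d bp, net twist %.1f deg\n",
              x$name, x$orientation, x$length, sum(x$steps[, "twist"])))
  invisible(x)
}

default_loop_control <- function() {
  list(ladder = c(10, 1e3, 1e5), maxit = 2000, factr = 1e7,
       pos_tol = 0.05, ang_tol = 0.05, max_extra_rungs = 2)
}

# Core penalized minimization.  Returns updated steps plus diagnostics.
optimize_steps <- function(first, steps, labels, target, ff,
                           control = list()) {
  ctl <- utils::modifyList(default_loop_control(), control)
  k <- force_constants(ff)
  r <- rest_step_internal(ff)
  st <- step_units_internal(as_step_matrix(steps))
  free <- which(labels == "free")
  if (length(free) == 0) stop("no free steps to optimize", call. = FALSE)
  fidx <- as.integer(free - 1L)
  par <- as.numeric(t(st[free, , drop = FALSE]))
  first <- as_frame(first)
  target <- as_frame(target)

  obj_trace <- numeric(0)
  monotone <- TRUE
  ladder <- ctl$ladder
  for (extra in seq_len(ctl$max_extra_rungs))
    ladder <- c(ladder, ladder[length(ladder)] * 10)
  n_rungs_used <- 0
  for (kp in ctl$ladder) {
    res <- run_rung(par, st, fidx, first, target, r, k, kp, ctl)
    monotone <- monotone && res$monotone
    par <- res$par
    obj_trace <- c(obj_trace, res$value)
    n_rungs_used <- n_rungs_used + 1
  }
  # stiffen further only if the end-frame residuals are not yet inside
  # tolerance
  repeat {
    d <- end_residuals(par, st, fidx, first, target, r, k)
    feasible <- d$pos <= ctl$pos_tol && d$ang <= ctl$ang_tol
    if (feasible || n_rungs_used >= length(ladder)) break
    n_rungs_used <- n_rungs_used + 1
    res <- run_rung(par, st, fidx, first, target, r, k,
                    ladder[n_rungs_used], ctl)
    monotone <- monotone && res$monotone
    par <- res$par
    obj_trace <- c(obj_trace, res$value)
  }

  st[free, ] <- matrix(par, ncol = 6, byrow = TRUE)
  out_steps <- step_units_external(st)
  d <- end_residuals(par, st, fidx, first, target, r, k)
  psi <- cpp_loop_objective(par, st, fidx, first, target, r, k,
                            0, 0, FALSE)$elastic
  list(steps = out_steps, psi = psi,
       feasible = d$pos <= ctl$pos_tol && d$ang <= ctl$ang_tol,
       pos_residual = d$pos, ang_residual = d$ang,
       monotone = monotone, objective_trace = obj_trace)
}

run_rung <- function(par, st, fidx, first, target, r, k, kp, ctl) {
  cache <- new.env(parent = emptyenv())
  eval_obj <- function(p) {
    o <- cpp_loop_objective(p, st, fidx, first, target, r, k, kp, kp, TRUE)
    assign("last_par", p, envir = cache)
    assign("last", o, envir = cache)
    o
  }
  fn <- function(p) {
    if (!is.null(cache$last_par) && identical(p, cache$last_par))
      return(cache$last$value)
    eval_obj(p)$value
  }
  gr <- function(p) {
    if (!is.null(cache$last_par) && identical(p, cache$last_par))
      return(cache$last$gradient)
    eval_obj(p)$gradient
  }
  v0 <- cpp_loop_objective(par, st, fidx, first, target, r, k, kp, kp,
                           FALSE)$value
  fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = ctl$maxit, factr = ctl$factr))
  list(par = fit$par, value = fit$value,
       monotone = fit$value <= v0 + 1e-9 * (1 + abs(v0)))
}

end_residuals <- function(par, st, fidx, first, target, r, k) {
  o <- cpp_loop_objective(par, st, fidx, first, target, r, k, 0, 0, FALSE)
  # rot_frobenius^2 = 4 (1 - cos theta) for rotations
  ct <- 1 - o$rot_frobenius^2 / 4
  ang <- acos(pmin(1, pmax(-1, ct))) / DEG2RAD
  list(pos = o$pos_residual, ang = ang)
}

#' Seed configuration for a loop boundary
#'
#' Builds a smooth initial pathway between the boundary frames: origins on
#' a bulged curve whose arc length matches the chain contour, orientations
#' from parallel-transported tangent frames twisted at the rest rate.  The
#' two topological families bulge through opposite sides and carry
#' opposite-signed out-of-plane excursions (opposite initial chirality), so
#' that optimization converges to distinct minima when the loop is
#' strained.
#'
#' @param boundary a [loop_boundary()].
#' @param n_bp number of base pairs in the loop (>= 10).
#' @param family `"F1"` or `"F2"`.
#' @param ff a [force_field()].
#' @return a [dna_chain()] starting exactly at `boundary$start`.
#' @export
seed_configuration <- function(boundary, n_bp, family = "F1", ff) {
  stopifnot(inherits(boundary, "loop_boundary"), n_bp >= 10)
  family <- match.arg(family, c("F1", "F2"))
  sgn <- if (family == "F1") 1 else -1
  S <- boundary$start; E <- boundary$end
  so <- frame_origin(S); eo <- frame_origin(E)
  n_steps <- n_bp - 1
  contour <- n_steps * ff$rest_rise
  d <- sqrt(sum((eo - so)^2))
  if (d > contour)
    stop("infeasible seed: end frames farther apart than the chain contour",
         call. = FALSE)

  u <- if (d > 1e-8) (eo - so) / d else frame_rotation(S)[, 3]
  v <- frame_rotation(S)[, 3]
  b <- v - sum(v * u) * u
  if (sqrt(sum(b^2)) < 1e-6) b <- frame_rotation(S)[, 1] -
      sum(frame_rotation(S)[, 1] * u) * u
  b <- sgn * b / sqrt(sum(b^2))
  cvec <- cross3(u, b)

  tt <- seq(0, 1, length.out = n_bp)
  path_len <- function(A) {
    p <- outer(1 - tt, so) + outer(tt, eo) + A * outer(sin(pi * tt), b) +
      0.15 * A * sgn * outer(sin(2 * pi * tt), cvec)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  if (path_len(0) >= contour * 0.999) {
    A <- 0
  } else {
    hi <- contour            # generous bracket for the bulge amplitude
    while (path_len(hi) < contour) hi <- hi * 2
    A <- stats::uniroot(function(a) path_len(a) - contour, c(0, hi),
                        tol = 1e-6)$root
  }
  p <- outer(1 - tt, so) + outer(tt, eo) + A * outer(sin(pi * tt), b) +
    0.15 * A * sgn * outer(sin(2 * pi * tt), cvec)

  # tangent frames, parallel transported, with rest twist added
  frames <- array(0, dim = c(4, 4, n_bp))
  frames[, , 1] <- unclass(S)
  x_prev <- frame_rotation(S)[, 1]
  z_prev <- frame_rotation(S)[, 3]
  tw <- 360 / ff$hr
  for (kk in 2:n_bp) {
    zi <- p[min(kk + 1, n_bp), ] - p[kk - 1, ]
    zi <- zi / sqrt(sum(zi^2))
    xi <- x_prev - sum(x_prev * zi) * zi
    if (sqrt(sum(xi^2)) < 1e-8) xi <- cross3(c(0, 1, 0), zi)
    xi <- xi / sqrt(sum(xi^2))
    # advance the twist about the local normal
    R <- cbind(xi, cross3(zi, xi), zi)
    R <- R %*% rot_z(tw)
    f <- diag(4); f[1:3, 1:3] <- R; f[1:3, 4] <- p[kk, ]
    frames[, , kk] <- f
    x_prev <- R[, 1]; z_prev <- zi
  }
  dna_chain(S, extract_steps(frames))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimize a loop configuration against its boundary
#'
#' Minimizes the elastic energy of the free steps subject to the last frame
#' matching the boundary end frame (position residual <= 0.05 A,
#' orientation residual <= 0.05 deg).  Frozen steps are never touched.
#' Non-convergence is reported through the `feasible` flag, not an error.
#'
#' @param chain a [dna_chain()] seed (see [seed_configuration()]).
#' @param boundary a [loop_boundary()]; `chain$first` must equal its start
#'   frame.
#' @param ff a [force_field()].
#' @param family optional family label to attach (defaults to the measured
#'   chirality, see [classify_loop()]).
#' @param control optional list overriding the continuation ladder,
#'   `maxit`, and the feasibility tolerances `pos_tol` / `ang_tol`.
#' @return Object of class `loop_state` with the optimized configuration,
#'   total elastic energy `psi` (kBT), feasibility and steric flags.
#' @export
optimize_loop <- function(chain, boundary, ff, family = NULL,
                          control = list()) {
  stopifnot(inherits(chain, "dna_chain"), inherits(boundary, "loop_boundary"))
  res <- optimize_steps(chain$first, chain$steps, chain$labels,
                        boundary$end, ff, control)
  out_chain <- dna_chain(chain$first, res$steps, chain$labels)
  st <- structure(list(boundary = boundary,
                       orientation = boundary$orientation,
                       chain = out_chain, psi = res$psi,
                       feasible = res$feasible,
                       pos_residual = res$pos_residual,
                       ang_residual = res$ang_residual,
                       monotone = res$monotone,
                       objective_trace = res$objective_trace,
                       steric_ok = steric_clear(out_chain),
                       family = family),
                  class = "loop_state")
  if (is.null(family)) st$family <- suppressWarnings(classify_loop(st)$family)
  st
}

#' @export
print.loop_state <- function(x, ...) {
  cat(sprintf(
    "Loop state %s/%s: %d bp, psi = %.3f kBT, %s%s\n",
    x$orientation, x$family, nrow(x$chain$steps) + 1, x$psi,
    if (x$feasible) "closed" else
      sprintf("OPEN (%.3g A / %.3g deg)", x$pos_residual, x$ang_residual),
    if (x$steric_ok) "" else ", steric clash"))
  invisible(x)
}

#' Grow a loop one base pair at a time
#'
#' Inserts base pairs singly (each new residue copies the parameters of an
#' existing free step) and re-optimizes after every insertion under the
#' same end conditions.
#'
#' @param state a [loop_state()].
#' @param target_n desired number of base pairs (>= current).
#' @param ff a [force_field()].
#' @param boundary optional replacement boundary (same orientation) applied
#'   from the first insertion on; used by [jfactor_profile()] when the
#'   operator spacing changes.
#' @param control optimizer control list.
#' @return the re-optimized [loop_state()] at the new length.
#' @export
grow_loop <- function(state, target_n, ff, boundary = NULL,
                      control = list()) {
  stopifnot(inherits(state, "loop_state"))
  if (is.null(boundary)) boundary <- state$boundary
  n_now <- nrow(state$chain$steps) + 1
  if (target_n < n_now) stop("target_n below current length", call. = FALSE)
  chain <- state$chain
  fam <- state$family
  while (n_now < target_n) {
    pos <- insertion_point(chain$labels)
    chain <- dna_chain(chain$first,
                       rbind(chain$steps[seq_len(pos), , drop = FALSE],
                             chain$steps[pos, , drop = FALSE],
                             if (pos < nrow(chain$steps))
                               chain$steps[(pos + 1):nrow(chain$steps), ,
                                           drop = FALSE]),
                       append(chain$labels, "free", after = pos))
    n_now <- n_now + 1
    state <- optimize_loop(chain, boundary, ff, family = fam,
                           control = control)
    chain <- state$chain
  }
  if (n_now == nrow(state$chain$steps) + 1 &&
      !identical(boundary, state$boundary)) {
    state <- optimize_loop(chain, boundary, ff, family = fam,
                           control = control)
  }
  state
}

# middle of the longest contiguous run of free steps
insertion_point <- function(labels) {
  free <- labels == "free"
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  as.integer(floor((starts[best] + ends[best]) / 2))
}

#' Introduce a protein footprint by ramping
#'
#' Gradually deforms the step parameters at the binding site from their
#' current values toward the footprint's fixed values; each increment
#' freezes the partially deformed segment and re-optimizes the rest of the
#' loop.  After the last increment the footprint steps equal
#' `fp$steps` exactly and stay frozen.
#'
#' @param state a [loop_state()].
#' @param fp a [protein_footprint()].
#' @param position 1-based index of the first footprint step within the
#'   chain; the whole footprint must lie on currently free steps.
#' @param ramp_steps number of ramp increments.
#' @param ff a [force_field()].
#' @param control optimizer control list.
#' @return the re-optimized [loop_state()] with the footprint frozen in.
#' @export
insert_protein <- function(state, fp, position, ramp_steps = 5, ff,
                           control = list()) {
  stopifnot(inherits(state, "loop_state"), inherits(fp, "protein_footprint"))
  chain <- state$chain
  nf <- nrow(fp$steps)
  idx <- position:(position + nf - 1)
  if (position < 1 || max(idx) > nrow(chain$steps))
    stop("footprint does not fit inside the chain", call. = FALSE)
  if (any(chain$labels[idx] != "free"))
    stop("footprint overlaps a frozen segment", call. = FALSE)
  start_steps <- chain$steps[idx, , drop = FALSE]
  lab <- chain$labels
  lab[idx] <- paste0("frozen:", fp$name)
  fam <- state$family
  for (s in seq_len(ramp_steps)) {
    frac <- s / ramp_steps
    st <- chain$steps
    st[idx, ] <- (1 - frac) * start_steps + frac * fp$steps
    chain <- dna_chain(chain$first, st, lab)
    state <- optimize_loop(chain, state$boundary, ff, family = fam,
                           control = control)
    chain <- state$chain
  }
  state
}

#' Steric screen for a chain configuration
#'
#' @param x a [dna_chain()], [loop_state()], or an N x 3 matrix of origins.
#' @param cutoff minimum allowed distance (Angstrom) between base-pair
#'   origins; default 18 A, about one duplex diameter.
#' @param window pairs closer than this many steps along the chain are
#'   ignored.
#' @return `TRUE` if no distal pair comes closer than `cutoff`.
#' @export
steric_clear <- function(x, cutoff = 18, window = 10) {
  if (inherits(x, "loop_state")) x <- x$chain
  orig <- if (inherits(x, "dna_chain")) chain_origins(x) else as.matrix(x)
  n <- nrow(orig)
  if (n <= window + 1) return(TRUE)
  D <- as.matrix(dist(orig))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  all(D[sep > window] >= cutoff)
}

#' Writhe-like chirality of a polyline
#'
#' Discrete Gauss double sum over non-adjacent segment pairs; used as the
#' chirality measure that separates the two topological loop families.
#'
#' @param origins N x 3 matrix of base-pair origins.
#' @return signed scalar (positive = right-handed excursion).
#' @export
polyline_writhe <- function(origins) {
  p <- as.matrix(origins)
  n <- nrow(p) - 1
  seg <- p[-1, , drop = FALSE] - p[-(n + 1), , drop = FALSE]
  mid <- (p[-1, , drop = FALSE] + p[-(n + 1), , drop = FALSE]) / 2
  w <- 0
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    r <- sweep(mid[j, , drop = FALSE], 2, mid[i, ])
    d3 <- (rowSums(r^2))^(3 / 2)
    cr <- cbind(seg[i, 2] * seg[j, 3] - seg[i, 3] * seg[j, 2],
                seg[i, 3] * seg[j, 1] - seg[i, 1] * seg[j, 3],
                seg[i, 1] * seg[j, 2] - seg[i, 2] * seg[j, 1])
    w <- w + sum(rowSums(cr * r) / d3)
  }
  w / (2 * pi)
}

#' Classify a loop state by orientation and topological family
#'
#' Orientation is read from the boundary; the family is assigned from the
#' sign of the writhe-like chirality measure (`F1` positive, `F2`
#' negative).  Near-planar loops get the label `"planar"` with a warning.
#'
#' @param state a [loop_state()].
#' @param tol chirality magnitude below which the loop is called planar.
#' @return list with `orientation`, `family` and the `chirality` value.
#' @export
classify_loop <- function(state, tol = 0.05) {
  stopifnot(inherits(state, "loop_state"))
  wr <- polyline_writhe(chain_origins(state$chain))
  fam <- if (abs(wr) < tol) {
    warning("near-planar loop: family ambiguous", call. = FALSE)
    "planar"
  } else if (wr > 0) "F1" else "F2"
  list(orientation = state$orientation, family = fam, chirality = wr)
}

#' Deduplicate a list of loop states
#'
#' States whose step parameters agree within 0.5 degrees RMS (angles) and
#' 0.05 A RMS (translations) are one minimum and are counted once.
#'
#' @param states list of [loop_state()] objects of equal length.
#' @param ang_tol,trans_tol RMS thresholds.
#' @return the list with duplicates removed (first occurrence kept).
#' @export
dedup_states <- function(states, ang_tol = 0.5, trans_tol = 0.05) {
  keep <- rep(TRUE, length(states))
  for (i in seq_along(states)) {
    if (!keep[i]) next
    for (j in seq_along(states)) {
      if (j <= i || !keep[j]) next
      if (states_duplicate(states[[i]], states[[j]], ang_tol, trans_tol))
        keep[j] <- FALSE
    }
  }
  states[keep]
}

states_duplicate <- function(a, b, ang_tol = 0.5, trans_tol = 0.05) {
  sa <- a$chain$steps; sb <- b$chain$steps
  if (nrow(sa) != nrow(sb)) return(FALSE)
  d <- sa - sb
  sqrt(mean(d[, 1:3]^2)) < ang_tol && sqrt(mean(d[, 4:6]^2)) < trans_tol
}
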