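# Harmonic step-level elastic potential for protein-free DNA.
#
# The rest state is an ideal, naturally straight, inextensible double helix:
# all parameters zero except twist (360/n degrees for a helical repeat of n
# bp/turn) and rise (3.4 A).  Deformation scales are quoted as the single
# deformation that raises the energy of one step by kBT/2: 4.1 deg of
# twist, 4.8 deg of bending (applied isotropically to tilt and roll), or
# 0.02 A of translation.  Energies are in units of kBT; conversions to cgs
# use kBT = 4.1e-14 erg at room temperature.

#' Elastic force field for protein-free DNA
#'
#' @param hr helical repeat in bp/turn; the rest twist is `360/hr` degrees.
#' @param delta_twist twist change (degrees) costing kBT/2 on one step.
#' @param delta_bend bending change (degrees) costing kBT/2; applied to
#'   tilt and roll separately (isotropic bending).
#' @param delta_trans translational move (Angstrom) costing kBT/2; applied
#'   to shift, slide and rise and effectively renders the chain
#'   inextensible.
#' @param rest_rise rest rise in Angstrom.
#' @param kBT_erg Boltzmann energy at the working temperature, in erg, used
#'   only for cgs conversions.
#' @return Object of class `force_field`.
#' @examples
#' ff <- force_field(hr = 10.9)
#' implied_moduli(ff)
#' @export
force_field <- function(hr = 10.9, delta_twist = 4.1, delta_bend = 4.8,
                        delta_trans = 0.02, rest_rise = 3.4,
                        kBT_erg = 4.1e-14) {
  vals <- c(hr = hr, delta_twist = delta_twist, delta_bend = delta_bend,
            delta_trans = delta_trans, rest_rise = rest_rise,
            kBT_erg = kBT_erg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all force-field scales must be finite and positive", call. = FALSE)
  structure(as.list(vals), class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(paste0(
    "DNA elastic force field\n",
    "  helical repeat : %.3f bp/turn (rest twist %.3f deg)\n",
    "  kBT/2 scales   : twist %.2f deg, bend %.2f deg, translation %.3f A\n",
    "  rest rise      : %.2f A\n"),
    x$hr, 360 / x$hr, x$delta_twist, x$delta_bend, x$delta_trans,
    x$rest_rise))
  invisible(x)
}

#' Rest-state step of a force field
#' @param ff a [force_field()].
#' @return length-6 step (degrees / Angstrom).
#' @export
rest_step <- function(ff) {
  stopifnot(inherits(ff, "force_field"))
  c(tilt = 0, roll = 0, twist = 360 / ff$hr, shift = 0, slide = 0,
    rise = ff$rest_rise)
}

#' Quadratic force constants implied by a force field
#'
#' Each constant is `kBT / delta^2` so that a lone deformation of `delta`
#' costs exactly kBT/2.  Angular constants are per radian^2, translational
#' per Angstrom^2 (the internal units of the energy kernel).
#'
#' @param ff a [force_field()].
#' @return named numeric vector of 6 constants, in kBT units, ordered as
#'   tilt, roll, twist, shift, slide, rise.
#' @export
force_constants <- function(ff) {
  stopifnot(inherits(ff, "force_field"))
  kb <- 1 / (ff$delta_bend * DEG2RAD)^2
  kt <- 1 / (ff$delta_twist * DEG2RAD)^2
  ks <- 1 / ff$delta_trans^2
  c(tilt = kb, roll = kb, twist = kt, shift = ks, slide = ks, rise = ks)
}

# rest step in internal units (radians / Angstrom)
rest_step_internal <- function(ff) {
  r <- rest_step(ff)
  r[1:3] <- r[1:3] * DEG2RAD
  unname(r)
}

#' Elastic energy of a chain configuration
#'
#' Sum over free (non-frozen) steps of the diagonal quadratic potential;
#' frozen protein-bound steps contribute nothing.
#'
#' @param chain a [dna_chain()] or a bare step matrix (all steps free).
#' @param ff a [force_field()].
#' @return energy in kBT; zero iff every free step is at rest.
#' @export
chain_energy <- function(chain, ff) {
  if (!inherits(chain, "dna_chain")) chain <- dna_chain(bp_frame(), chain)
  k <- force_constants(ff)
  r <- rest_step_internal(ff)
  st <- step_units_internal(chain$steps)
  idx <- free_steps(chain)
  if (length(idx) == 0) return(0)
  dev <- sweep(st[idx, , drop = FALSE], 2, r)
  sum(0.5 * sweep(dev^2, 2, k, `*`))
}

#' Persistence length and torsional modulus implied by a force field
#'
#' Closed forms from the equipartition variances of the harmonic step
#' distribution: each bending degree of freedom fluctuates with variance
#' `delta_bend^2` (radians^2), so the mean squared bend per step is twice
#' that and the persistence length is `P = 2 h / <theta^2>` with h the rest
#' rise; the torsional modulus is `C = kBT h / delta_twist^2` in erg cm.
#'
#' @param ff a [force_field()].
#' @return list with `persistence_nm` and `torsional_erg_cm`.
#' @seealso [mc_moduli()] for the Monte-Carlo estimate of the same two
#'   quantities.
#' @export
implied_moduli <- function(ff) {
  stopifnot(inherits(ff, "force_field"))
  db <- ff$delta_bend * DEG2RAD
  dt <- ff$delta_twist * DEG2RAD
  h_cm <- ff$rest_rise * 1e-8
  list(persistence_nm = 2 * (ff$rest_rise / 10) / (2 * db^2),
       torsional_erg_cm = ff$kBT_erg * h_cm / dt^2)
}

#' Monte-Carlo check of the implied moduli
#'
#' Samples free chains from the harmonic step distribution and measures
#' (i) the exponential decay of the tangent-tangent correlation, giving the
#' persistence length, and (ii) the per-step twist variance, giving the
#' torsional modulus.
#'
#' @param ff a [force_field()].
#' @param n_chains,n_steps Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return list with `persistence_nm`, `torsional_erg_cm` and the raw
#'   tangent correlations.
#' @export
mc_moduli <- function(ff, n_chains = 400, n_steps = 120, seed = 1L) {
  stopifnot(inherits(ff, "force_field"))
  set.seed(seed)
  db <- ff$delta_bend
  dt <- ff$delta_twist
  w0 <- 360 / ff$hr
  corr <- matrix(0, n_chains, n_steps)
  tw2 <- numeric(n_chains)
  for (c in seq_len(n_chains)) {
    steps <- cbind(rnorm(n_steps, 0, db), rnorm(n_steps, 0, db),
                   rnorm(n_steps, w0, dt), 0, 0, ff$rest_rise)
    fr <- build_chain(bp_frame(), steps)
    tang <- t(fr[1:3, 3, ])          # helix normals
    corr[c, ] <- tang[-1, ] %*% tang[1, ]
    tw2[c] <- mean((steps[, 3] - w0)^2)
  }
  cbar <- colMeans(corr)
  n_fit <- max(which(cbar > 0.2))    # fit the early exponential decay
  kfit <- seq_len(n_fit)
  slope <- -sum(kfit * log(cbar[kfit])) / sum(kfit^2)
  p_nm <- (ff$rest_rise / 10) / slope
  c_cgs <- ff$kBT_erg * (ff$rest_rise * 1e-8) / (mean(tw2) * DEG2RAD^2)
  list(persistence_nm = p_nm, torsional_erg_cm = c_cgs,
       tangent_correlation = cbar)
}
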