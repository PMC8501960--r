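# Looping propensities: Boltzmann sums over optimized loop ensembles,
# spacing profiles, and a twisted-wormlike-chain reference curve.

#' J-factor and state fractions of a loop ensemble
#'
#' The relative looping propensity is the sum of Boltzmann factors
#' `exp(-psi_i)` (psi in kBT) over the feasible, sterically clear states;
#' each included state contributes the fraction `exp(-psi_i) / J`.
#' Duplicated minima are counted once (see [dedup_states()]).
#'
#' @param states list of [loop_state()] objects (up to eight: four
#'   orientations times two families).
#' @param dedup drop duplicate minima before summing.
#' @return Object of class `loop_ensemble` with `J`, `fractions`, and the
#'   included states.
#' @examples
#' # two states at 0 and log(2) kBT give fractions 2/3 and 1/3
#' @export
ensemble_jfactor <- function(states, dedup = TRUE) {
  stopifnot(is.list(states))
  if (dedup) states <- dedup_states(states)
  ok <- vapply(states, function(s) isTRUE(s$feasible) && isTRUE(s$steric_ok),
               logical(1))
  inc <- states[ok]
  w <- vapply(inc, function(s) exp(-s$psi), numeric(1))
  J <- sum(w)
  fr <- if (J > 0) w / J else rep(NA_real_, length(w))
  names(fr) <- vapply(inc, function(s) paste0(s$orientation, "_", s$family),
                      character(1))
  structure(list(J = J, fractions = fr, states = inc,
                 n_excluded = sum(!ok)),
            class = "loop_ensemble")
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf("Loop ensemble: J = %.4g (%d states included, %d excluded)\n",
              x$J, length(x$states), x$n_excluded))
  if (length(x$fractions))
    print(round(x$fractions, 3))
  invisible(x)
}

# map a (possibly half-integer) center-to-center spacing onto a chain
# length and a boundary whose end frame absorbs the residual fraction of a
# rest step
spacing_geometry <- function(boundary, spacing, ff) {
  n_bp <- as.integer(floor(spacing)) + 1L
  resid <- spacing - floor(spacing)
  end <- boundary$end
  if (resid > 1e-9) {
    r <- rest_step(ff)
    end <- end %*% step_transform(r * resid)
  }
  list(n_bp = n_bp,
       boundary = loop_boundary(boundary$start, end, boundary$orientation))
}

#' J-factor profile over operator spacings
#'
#' For every spacing the eight states (four boundary orientations times two
#' seeded families) are energy-optimized -- by continuation from the
#' previous spacing via [grow_loop()] -- and summed into a J-factor.
#' Optional protein footprints are ramped in at the first spacing and
#' carried along.  Spacings may be half-integers; the residual half step is
#' absorbed into the boundary end frame.
#'
#' @param boundaries named list of [loop_boundary()] objects as from
#'   [boundary_variants()] or [make_toy_boundary()] with
#'   `orientation = "all"` (all four orientations for the full
#'   eight-state ensemble; a subset is allowed for cheaper profiles).
#' @param spacings strictly increasing numeric spacings (bp).
#' @param ff a [force_field()].
#' @param footprint optional [protein_footprint()] frozen into every state.
#' @param footprint_from_end distance (steps) from the loop end to the last
#'   footprint step; the footprint keeps this offset as the loop grows,
#'   mimicking a binding site at fixed distance from the proximal operator.
#' @param control optimizer control list.
#' @return `data.frame` of class `jprofile`: spacing, J, per-state psi
#'   columns, the dominant state, and the number of feasible states.
#' @export
jfactor_profile <- function(boundaries, spacings, ff, footprint = NULL,
                            footprint_from_end = 20, control = list()) {
  stopifnot(all(diff(spacings) > 0), length(boundaries) >= 1,
            !is.null(names(boundaries)))
  labels <- names(boundaries)
  fams <- c("F1", "F2")
  state_names <- as.vector(outer(labels, fams, paste, sep = "_"))
  cur <- list()

  rows <- vector("list", length(spacings))
  for (si in seq_along(spacings)) {
    sp <- spacings[si]
    psi <- setNames(rep(NA_real_, length(state_names)), state_names)
    states <- list()
    for (ol in labels) {
      geo <- spacing_geometry(boundaries[[ol]], sp, ff)
      fresh_state <- function(fam) {
        seed <- seed_configuration(geo$boundary, geo$n_bp, fam, ff)
        st0 <- optimize_loop(seed, geo$boundary, ff, family = fam,
                             control = control)
        if (!is.null(footprint)) {
          pos <- nrow(st0$chain$steps) - footprint_from_end -
            nrow(footprint$steps) + 1
          st0 <- insert_protein(st0, footprint, pos, ramp_steps = 5, ff,
                                control = control)
        }
        st0
      }
      tmp <- list()
      for (fam in fams) {
        key <- paste0(ol, "_", fam)
        tmp[[fam]] <- tryCatch({
          if (is.null(cur[[key]])) fresh_state(fam)
          else grow_loop(cur[[key]], geo$n_bp, ff, boundary = geo$boundary,
                         control = control)
        }, error = function(e) NULL)
      }
      # when the two family tracks have merged into one basin, try fresh
      # seeds to recover the second topological family at this spacing
      if (!is.null(tmp$F1) && !is.null(tmp$F2) &&
          states_duplicate(tmp$F1, tmp$F2)) {
        for (fam in fams) {
          other <- tmp[[setdiff(fams, fam)]]
          fr <- tryCatch(fresh_state(fam), error = function(e) NULL)
          if (!is.null(fr) && fr$feasible && !states_duplicate(fr, other)) {
            tmp[[fam]] <- fr
            break
          }
        }
      }
      for (fam in fams) {
        key <- paste0(ol, "_", fam)
        if (!is.null(tmp[[fam]])) {
          cur[[key]] <- tmp[[fam]]
          psi[key] <- tmp[[fam]]$psi
          states[[key]] <- tmp[[fam]]
        }
      }
    }
    ens <- ensemble_jfactor(unname(states))
    dom <- if (length(states)) {
      feas <- vapply(states, function(s) s$feasible && s$steric_ok,
                     logical(1))
      pv <- psi[names(states)][feas]
      if (length(pv)) names(states)[feas][which.min(pv)] else NA_character_
    } else NA_character_
    rows[[si]] <- data.frame(spacing = sp, J = ens$J,
                             as.list(setNames(psi, paste0("psi_",
                                                          state_names))),
                             dominant_state = dom,
                             n_feasible = length(ens$states),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("jprofile", "data.frame")
  out
}

#' Local extrema of a J profile
#'
#' Interior points that strictly exceed (maxima) or undercut (minima) both
#' neighbours; on ties the smaller spacing wins.
#'
#' @param profile a `jprofile` data frame, or any data frame with columns
#'   `spacing` and `J`.
#' @return `data.frame` with columns `spacing` and `type` (`"max"`/`"min"`).
#' @export
find_extrema <- function(profile) {
  x <- profile$spacing; y <- profile$J
  stopifnot(length(x) >= 3)
  out <- data.frame(spacing = numeric(0), type = character(0),
                    stringsAsFactors = FALSE)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      out <- rbind(out, data.frame(spacing = x[i], type = "max"))
    } else if (y[i] < y[i - 1] && y[i] <= y[i + 1]) {
      out <- rbind(out, data.frame(spacing = x[i], type = "min"))
    }
  }
  out
}

#' Twisted-wormlike-chain J-factor
#'
#' Shimada-Yamakawa-type cyclization factor for an intrinsically straight
#' wormlike chain, modulated by a Gaussian torsional-phasing factor with
#' period equal to the helical repeat.  The bending envelope is the
#' ring-closure probability density of the chain ends (molar units),
#' `J_b = 1660.6 * (112.04 / P^3) * l^-5 * exp(-14.055 / l + 0.246 * l)`
#' with `l = L / P` (this closed form reproduces a brute-force Monte-Carlo
#' estimate of the end-to-end closure density to a few percent for
#' `l ~ 2-4`; order-one end-orientation alignment factors are not
#' included, consistent with use as a relative reference curve).  The
#' twist factor sums Gaussians of variance `kBT L / C` over integer
#' linking offsets, normalized to average one over a helical period.
#'
#' @param length_bp chain length in bp (>= 100, the domain of the
#'   closed-form approximation).
#' @param persistence_nm persistence length P (nm).
#' @param torsional_c torsional rigidity C (erg cm); `0` disables the
#'   torsional modulation (pure bending envelope).
#' @param hr helical repeat (bp/turn).
#' @param kBT_erg Boltzmann energy in erg.
#' @return J in mol/L; vectorized over `length_bp`.
#' @examples
#' wlc_jfactor(500)   # near the cyclization optimum of mixed-sequence DNA
#' @export
wlc_jfactor <- function(length_bp, persistence_nm = 46.5,
                        torsional_c = 2.4e-19, hr = 10.48,
                        kBT_erg = 4.1e-14) {
  if (any(length_bp < 100))
    stop("closed-form J-factor needs length >= 100 bp", call. = FALSE)
  P <- persistence_nm * 10          # A
  L <- length_bp * 3.4              # A
  l <- L / P
  j_num <- 112.04 / P^3 * l^(-5) * exp(-14.055 / l + 0.246 * l)  # per A^3
  j_m <- j_num * 1e27 / 6.02214e23  # mol/L
  if (torsional_c <= 0) return(j_m)
  sigma2 <- kBT_erg * (L * 1e-8) / torsional_c       # rad^2
  delta <- 2 * pi * (length_bp / hr - round(length_bp / hr))
  m <- -4:4
  ftw <- vapply(seq_along(delta), function(i) {
    sum(exp(-(delta[i] + 2 * pi * m)^2 / (2 * sigma2[i])))
  }, numeric(1)) * 2 * pi / sqrt(2 * pi * sigma2)
  j_m * ftw
}
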