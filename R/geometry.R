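# Rigid base-pair geometry: frames, step transforms, chain reconstruction.
#
# A base-pair frame is a 4x4 homogeneous matrix [R o; 0 1] whose rotation
# columns are the short (minor-groove) axis, long axis and helix normal of
# the base pair, and whose last column holds the origin in Angstrom.  A
# step is described by six rigid-body parameters (tilt, roll, twist in
# degrees; shift, slide, rise in Angstrom) under the mid-step-frame
# (CEHS/3DNA-style) convention: the rotation from frame i to i+1 is
# Rz(w/2 - phi) Ry(Gamma) Rz(w/2 + phi) with Gamma = sqrt(tilt^2 + roll^2)
# and phi = atan2(tilt, roll), and the translation is expressed in the
# half-way frame.  Twist is positive for right-handed DNA.

#' Construct a base-pair frame
#'
#' @param origin numeric length-3 origin in Angstrom.
#' @param orientation 3x3 rotation matrix (orthonormal, determinant +1);
#'   columns are the base-pair short axis, long axis and normal.
#' @return A 4x4 homogeneous transform of class `bp_frame`.
#' @examples
#' bp_frame()                       # identity frame at the origin
#' bp_frame(c(0, 0, 3.4))           # one rise up the helix axis
#' @export
bp_frame <- function(origin = c(0, 0, 0), orientation = diag(3)) {
  stopifnot(length(origin) == 3, is.matrix(orientation),
            all(dim(orientation) == c(3, 3)))
  check_rotation(orientation)
  f <- diag(4)
  f[1:3, 1:3] <- orientation
  f[1:3, 4] <- origin
  class(f) <- c("bp_frame", "matrix")
  f
}

check_rotation <- function(R, tol = 1e-9) {
  if (any(!is.finite(R)))
    stop("frame orientation contains non-finite values", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("frame orientation is not orthonormal", call. = FALSE)
  if (det(R) < 0)
    stop("frame orientation is left-handed (det < 0)", call. = FALSE)
  invisible(TRUE)
}

as_frame <- function(x) {
  x <- unclass(x)
  stopifnot(is.matrix(x), all(dim(x) == c(4, 4)))
  check_rotation(x[1:3, 1:3])
  x
}

frame_origin <- function(f) unclass(f)[1:3, 4]
frame_rotation <- function(f) unclass(f)[1:3, 1:3]

#' Rotation matrices about the z and y axes (degrees)
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(angle) {
  a <- angle * DEG2RAD
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(angle) {
  a <- angle * DEG2RAD
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

step_units_internal <- function(steps) {
  steps <- as_step_matrix(steps)
  steps[, 1:3] <- steps[, 1:3] * DEG2RAD
  steps
}

step_units_external <- function(steps) {
  steps[, 1:3] <- steps[, 1:3] / DEG2RAD
  colnames(steps) <- STEP_COLS
  steps
}

#' Coerce to a step-parameter matrix
#'
#' Step parameters are kept as numeric matrices with columns
#' `tilt, roll, twist` (degrees) and `shift, slide, rise` (Angstrom);
#' a single step may be given as a length-6 vector.
#'
#' @param x vector of 6 values or an n x 6 matrix.
#' @return n x 6 numeric matrix with canonical column names.
#' @export
as_step_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 6)
    stop("step parameters need 6 columns (tilt, roll, twist, shift, slide, rise)",
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite step parameter", call. = FALSE)
  colnames(x) <- STEP_COLS
  x
}

#' Rigid transform generated by one base-pair step
#'
#' Realizes the six rigid-body parameters as a 4x4 homogeneous transform
#' from frame i to frame i+1 under the mid-step-frame convention.  A pure
#' twist rotates about the frame normal; an all-zero step is the identity.
#'
#' @param p length-6 numeric (tilt, roll, twist in degrees; shift, slide,
#'   rise in Angstrom).
#' @return 4x4 homogeneous transform.
#' @examples
#' step_transform(c(0, 0, 36, 0, 0, 3.4))   # ideal B-DNA-like step
#' @export
step_transform <- function(p) {
  p <- as_step_matrix(p)
  if (nrow(p) != 1) stop("step_transform() takes a single step", call. = FALSE)
  cpp_step_matrix(as.numeric(step_units_internal(p)))
}

#' Reconstruct base-pair frames from step parameters
#'
#' @param first 4x4 first base-pair frame (see [bp_frame()]).
#' @param steps n x 6 step-parameter matrix; the chain has n + 1 base pairs.
#' @return 4 x 4 x (n+1) array of frames; slice 1 equals `first`.
#' @seealso [extract_steps()] for the exact inverse.
#' @export
build_chain <- function(first, steps) {
  first <- as_frame(first)
  steps <- step_units_internal(steps)
  if (nrow(steps) < 1) stop("need at least one step", call. = FALSE)
  cpp_chain_frames(first, steps)
}

#' Recover step parameters from a list of frames
#'
#' Exact inverse of [build_chain()] under the same mid-step-frame
#' convention.
#'
#' @param frames 4 x 4 x N array (N >= 2) of valid base-pair frames.
#' @return (N-1) x 6 step-parameter matrix in degrees / Angstrom.
#' @export
extract_steps <- function(frames) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] == 4, dim(frames)[2] == 4)
  if (dim(frames)[3] < 2) stop("need at least two frames", call. = FALSE)
  for (k in seq_len(dim(frames)[3])) check_rotation(frames[1:3, 1:3, k])
  step_units_external(cpp_extract_steps(frames))
}

#' Reverse a duplex segment
#'
#' Returns the step parameters of the same double-helical segment read in
#' the opposite 5'->3' direction: every frame is flipped 180 degrees about
#' its short axis, the order is reversed, and steps are re-extracted.  Under
#' the mid-step-frame convention this negates tilt and shift and preserves
#' roll, twist, slide and rise.
#'
#' @param steps n x 6 step-parameter matrix.
#' @return n x 6 step-parameter matrix of the reversed segment.
#' @export
reverse_steps <- function(steps) {
  steps <- as_step_matrix(steps)
  fr <- build_chain(bp_frame(), steps)
  n <- dim(fr)[3]
  flip <- diag(c(1, -1, -1, 1))
  out <- array(0, dim = c(4, 4, n))
  for (k in seq_len(n)) out[, , k] <- fr[, , n - k + 1] %*% flip
  extract_steps(out)
}

#' DNA chain configuration
#'
#' Bundles a first frame, a step-parameter matrix and per-step labels
#' (`"free"` or `"frozen:<name>"` for protein-bound segments).
#'
#' @param first 4x4 first base-pair frame.
#' @param steps n x 6 step-parameter matrix (n >= 1, so >= 2 base pairs).
#' @param labels character vector of per-step labels; defaults to all free.
#' @return Object of class `dna_chain`.
#' @export
dna_chain <- function(first, steps, labels = NULL) {
  first <- as_frame(first)
  steps <- as_step_matrix(steps)
  if (is.null(labels)) labels <- rep("free", nrow(steps))
  stopifnot(length(labels) == nrow(steps))
  ok <- labels == "free" | startsWith(labels, "frozen")
  if (!all(ok)) stop("labels must be 'free' or 'frozen:<name>'", call. = FALSE)
  structure(list(first = first, steps = steps, labels = labels),
            class = "dna_chain")
}

#' @export
print.dna_chain <- function(x, ...) {
  nfro <- sum(x$labels != "free")
  cat(sprintf("DNA chain: %d bp (%d steps, %d frozen)\n",
              nrow(x$steps) + 1, nrow(x$steps), nfro))
  invisible(x)
}

#' Frames of a chain configuration
#' @param chain a [dna_chain()].
#' @return 4 x 4 x N frame array.
#' @export
chain_frames <- function(chain) {
  stopifnot(inherits(chain, "dna_chain"))
  build_chain(chain$first, chain$steps)
}

chain_origins <- function(chain) {
  fr <- chain_frames(chain)
  t(fr[1:3, 4, ])
}

free_steps <- function(chain) which(chain$labels == "free")
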