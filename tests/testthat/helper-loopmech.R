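# shared fixtures and independent oracles for the test suite

# force field with an integer helical register (clean torsion bookkeeping)
ff10 <- force_field(hr = 10)
ff_std <- force_field(hr = 10.9)

rest_chain_steps <- function(n_steps, ff) {
  m <- matrix(rep(rest_step(ff), n_steps), ncol = 6, byrow = TRUE)
  colnames(m) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  m
}

rest_end_frame <- function(n_bp, ff) {
  build_chain(bp_frame(), rest_chain_steps(n_bp - 1, ff))[, , n_bp]
}

# independent axis-angle rotation composition (oracle for step_transform):
# never calls the package's kernel
aa_rot <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# fabricate a minimal feasible loop state with a given energy (for
# ensemble algebra tests)
fake_state <- function(psi, orientation = "A1", family = "F1", twist = 34) {
  steps <- matrix(c(0, 0, twist, 0, 0, 3.4), 1,
                  dimnames = list(NULL, c("tilt", "roll", "twist",
                                          "shift", "slide", "rise")))
  structure(list(orientation = orientation, family = family,
                 chain = dna_chain(bp_frame(), steps),
                 psi = psi, feasible = TRUE, steric_ok = TRUE),
            class = "loop_state")
}

# planar semicircular U-turn boundary plus a matching arc seed: the end
# frame is transported along the arc with rest-rate twist so that closure
# is twist-neutral; returns list(boundary, seed, n_steps)
uturn_fixture <- function(n_bp, ff) {
  R <- (n_bp - 1) * ff$rest_rise / pi
  tt <- seq(0, pi, length.out = n_bp)
  p <- cbind(R - R * cos(tt), 0, R * sin(tt))
  frames <- array(0, c(4, 4, n_bp))
  frames[, , 1] <- diag(4)
  xp <- c(1, 0, 0)
  w <- 2 * pi / ff$hr
  for (k in 2:n_bp) {
    z <- p[min(k + 1, n_bp), ] - p[k - 1, ]
    z <- z / sqrt(sum(z^2))
    x <- xp - sum(xp * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    Rm <- cbind(x, y, z) %*%
      matrix(c(cos(w), sin(w), 0, -sin(w), cos(w), 0, 0, 0, 1), 3, 3)
    f <- diag(4); f[1:3, 1:3] <- Rm; f[1:3, 4] <- p[k, ]
    frames[, , k] <- f
    xp <- Rm[, 1]
  }
  list(boundary = loop_boundary(bp_frame(), frames[, , n_bp]),
       seed = dna_chain(bp_frame(), extract_steps(frames)),
       n_steps = n_bp - 1)
}

# brute-force Monte-Carlo estimate of the wormlike-chain ring-closure
# density (mol/L): discrete Gaussian-rotation chain, radial shell counts
# log-extrapolated to zero separation.  Independent of the package kernel.
mc_ring_closure <- function(length_bp, p_nm, n_chains = 1.2e6, seg_bp = 10,
                            seed = 42,
                            shell_fracs = c(0.04, 0.06, 0.08, 0.10, 0.12)) {
  set.seed(seed)
  P <- p_nm * 10; h <- 3.4
  nseg <- round(length_bp / seg_bp)
  hseg <- length_bp * h / nseg
  sig <- sqrt(hseg / P)
  n <- n_chains
  r11 <- rep(1, n); r12 <- rep(0, n); r13 <- rep(0, n)
  r21 <- rep(0, n); r22 <- rep(1, n); r23 <- rep(0, n)
  r31 <- rep(0, n); r32 <- rep(0, n); r33 <- rep(1, n)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  for (k in seq_len(nseg)) {
    x <- x + hseg * r13; y <- y + hseg * r23; z <- z + hseg * r33
    tilt <- rnorm(n, 0, sig); roll <- rnorm(n, 0, sig)
    tw <- runif(n, -pi, pi)
    gam <- sqrt(tilt^2 + roll^2); phi <- atan2(tilt, roll)
    a <- tw / 2 - phi; b <- tw / 2 + phi
    ca <- cos(a); sa <- sin(a); cg <- cos(gam); sg <- sin(gam)
    cb <- cos(b); sb <- sin(b)
    m11 <- ca * cg * cb - sa * sb; m12 <- -ca * cg * sb - sa * cb
    m13 <- ca * sg
    m21 <- sa * cg * cb + ca * sb; m22 <- -sa * cg * sb + ca * cb
    m23 <- sa * sg
    m31 <- -sg * cb; m32 <- sg * sb; m33 <- cg
    n11 <- r11 * m11 + r12 * m21 + r13 * m31
    n12 <- r11 * m12 + r12 * m22 + r13 * m32
    n13 <- r11 * m13 + r12 * m23 + r13 * m33
    n21 <- r21 * m11 + r22 * m21 + r23 * m31
    n22 <- r21 * m12 + r22 * m22 + r23 * m32
    n23 <- r21 * m13 + r22 * m23 + r23 * m33
    n31 <- r31 * m11 + r32 * m21 + r33 * m31
    n32 <- r31 * m12 + r32 * m22 + r33 * m32
    n33 <- r31 * m13 + r32 * m23 + r33 * m33
    r11 <- n11; r12 <- n12; r13 <- n13
    r21 <- n21; r22 <- n22; r23 <- n23
    r31 <- n31; r32 <- n32; r33 <- n33
  }
  rho <- sqrt(x^2 + y^2 + z^2)
  L <- length_bp * h
  edges <- L * shell_fracs
  lo <- c(0, edges[-length(edges)])
  Wsh <- mid2 <- cnts <- numeric(length(edges))
  for (i in seq_along(edges)) {
    cnt <- sum(rho >= lo[i] & rho < edges[i])
    vol <- 4 / 3 * pi * (edges[i]^3 - lo[i]^3)
    cnts[i] <- cnt
    Wsh[i] <- cnt / n / vol
    mid2[i] <- (edges[i]^2 + edges[i] * lo[i] + lo[i]^2) / 3
  }
  ok <- cnts >= 20
  fit <- stats::lm(log(Wsh[ok]) ~ mid2[ok])
  exp(unname(coef(fit)[1])) * 1e27 / 6.02214e23
}
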