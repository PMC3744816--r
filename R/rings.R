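# Ring pucker-state geometry.
#
# Rings cannot be built from an acyclic z-matrix alone: the closing bond is
# never placed explicitly, so the ring-internal angles and dihedrals must be
# chosen so that the cycle closes.  Canonical pucker states are therefore
# solved once per (ring, state) as a small geometric least-squares problem
# -- bond lengths held essentially exact, bond angles and the state's target
# torsion pattern soft -- and the resulting internal coordinates are stored
# in the template.  Six-membered rings enumerate the two chairs (alternating
# +/- torsions); five-membered rings use a pseudorotation description,
# torsion_j = tau_m * cos(P + 4*pi*(j-1)/5) on an 18-degree phase grid at
# fixed amplitude.

#' Solve the Cartesian geometry of a closed ring state
#'
#' @param lengths ring bond lengths (Angstrom), bond j connecting atom j to
#'   atom j+1 (cyclically).
#' @param angle_targets target internal angles at each ring atom (degrees).
#' @param torsion_targets target ring torsions; torsion j is the dihedral
#'   (atom j-1, atom j, atom j+1, atom j+2), i.e. about bond j.
#' @param angle_weight,torsion_weight soft-restraint weights (per degree).
#' @param init_z initial out-of-plane displacements (Angstrom), one per
#'   atom; chooses the pucker branch.
#' @return k x 3 coordinate matrix of the solved ring.
#' @keywords internal
solve_ring_fragment <- function(lengths, angle_targets, torsion_targets,
                                angle_weight = 1, torsion_weight = 1,
                                init_z = NULL) {
  k <- length(lengths)
  stopifnot(length(angle_targets) == k, length(torsion_targets) == k)
  R <- mean(lengths) / (2 * sin(pi / k))
  th <- 2 * pi * (seq_len(k) - 1) / k
  if (is.null(init_z)) init_z <- 0.25 * cos(th * k / 2)
  x0 <- cbind(R * cos(th), R * sin(th), init_z)

  nxt <- c(2:k, 1)
  prv <- c(k, 1:(k - 1))
  nxt2 <- nxt[nxt]
  obj <- function(p) {
    xyz <- matrix(p, k, 3)
    d <- sqrt(rowSums((xyz - xyz[nxt, , drop = FALSE])^2))
    ang <- vapply(seq_len(k), function(j)
      vec_angle(xyz[prv[j], ], xyz[j, ], xyz[nxt[j], ]), 0)
    tor <- vapply(seq_len(k), function(j)
      dihedral_xyz(xyz[prv[j], ], xyz[j, ], xyz[nxt[j], ], xyz[nxt2[j], ]), 0)
    sum((2e3 * (d - lengths))^2) +
      sum((angle_weight * (ang - angle_targets))^2) +
      sum((torsion_weight * wrap_angle(tor - torsion_targets))^2)
  }
  fit <- stats::optim(as.vector(x0), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  xyz <- matrix(fit$par, k, 3)
  d <- sqrt(rowSums((xyz - xyz[nxt, , drop = FALSE])^2))
  if (max(abs(d - lengths)) > 5e-3)
    stop("ring state did not close: max bond residual ",
         format(max(abs(d - lengths)), digits = 3), " A")
  xyz
}

# Plain-R signed dihedral used during template construction.
dihedral_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- pracma_cross(b1, b2); c2 <- pracma_cross(b2, b3)
  x <- sum(c1 * c2)
  y <- sum(pracma_cross(c1, c2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# Directions for the two substituents at ring atom j of a solved ring.
# "up" is the side of the local ring normal (consistent around the cycle
# for near-planar and chair rings).
ring_sub_dirs <- function(xyz, j, sub_angle = 109.47) {
  k <- nrow(xyz)
  prv <- if (j == 1) k else j - 1
  nxt <- if (j == k) 1 else j + 1
  e1 <- xyz[prv, ] - xyz[j, ]; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- xyz[nxt, ] - xyz[j, ]; e2 <- e2 / sqrt(sum(e2^2))
  bis <- -(e1 + e2); bis <- bis / sqrt(sum(bis^2))
  nrm <- pracma_cross(e1, e2); nrm <- nrm / sqrt(sum(nrm^2))
  # choose the half-angle so both substituent-to-ring angles ~ sub_angle
  ct <- cos(sub_angle * pi / 180) / sum(bis * e1)
  ct <- min(max(ct, -1), 1)
  h <- acos(ct)
  list(up = cos(h) * bis + sin(h) * nrm,
       down = cos(h) * bis - sin(h) * nrm)
}

# Internal coordinates of one z-matrix row measured on reference coords.
zrow_internals <- function(xyz, name, parent, aref, dref) {
  len <- sqrt(sum((xyz[name, ] - xyz[parent, ])^2))
  ang <- vec_angle(xyz[name, ], xyz[parent, ], xyz[aref, ])
  dih <- dihedral_xyz(xyz[name, ], xyz[parent, ], xyz[aref, ], xyz[dref, ])
  c(length = len, angle = ang, dihedral = dih)
}

# Torsion target pattern for a 5-ring pseudorotation state.
furanose_torsions <- function(P_deg, tau_m = 39) {
  j <- 0:4
  tau_m * cos((P_deg + 144 * j) * pi / 180)
}

# Torsion target pattern for the two chairs of a 6-ring.
chair_torsions <- function(which = c("A", "B"), magnitude = 55) {
  which <- match.arg(which)
  s <- if (which == "A") 1 else -1
  s * magnitude * rep(c(1, -1), 3)
}
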