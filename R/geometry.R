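#' Build a Cartesian conformer from torsion and pucker assignments
#'
#' Places every atom of the template by natural extension from its z-matrix
#' references, keeping all bond lengths and angles fixed and setting the
#' named rotatable-bond dihedrals, trivial-rotor dihedrals and ring
#' pucker-state internal coordinates to the requested values.  Deterministic
#' for identical inputs.
#'
#' @param template a [molecule_template()].
#' @param torsions named numeric vector of torsion angles (degrees; any
#'   convention, wrapped internally to (-180, 180]).  Must assign every
#'   rotatable bond.
#' @param puckers named character vector assigning one canonical state to
#'   every ring (may be empty when the template has no rings).
#' @param trivial optional named numeric vector for trivial rotors
#'   (methyls); defaults to the template's base values.
#' @param check when TRUE (default) verify ring closure against the
#'   template tolerance and error naming the offending ring.
#' @return an object of class `cartesian_conformer`: list with `xyz`
#'   (atoms x 3 matrix, Angstrom, rownames = atom names), `torsion_values`
#'   and `pucker_values`.
#' @export
build_conformer <- function(template, torsions = numeric(), puckers = character(),
                            trivial = NULL, check = TRUE) {
  ens <- list(
    torsions = matrix(wrap_angle(torsions), nrow = 1,
                      dimnames = list(NULL, names(torsions))),
    puckers = matrix(puckers, nrow = 1, dimnames = list(NULL, names(puckers))),
    trivial = if (is.null(trivial)) NULL else
      matrix(wrap_angle(trivial), nrow = 1, dimnames = list(NULL, names(trivial)))
  )
  cube <- ensemble_coords(template, ens)
  xyz <- cube[, , 1]
  rownames(xyz) <- template$zmatrix$name
  conf <- structure(list(xyz = xyz,
                         torsion_values = wrap_angle(torsions)[names(template$rotatable_bonds)],
                         pucker_values = puckers[names(template$rings)]),
                    class = "cartesian_conformer")
  names(conf$torsion_values) <- names(template$rotatable_bonds)
  if (check) check_ring_closure(template, xyz)
  conf
}

check_ring_closure <- function(template, xyz, tol = template$tolerances$ring_closure) {
  for (rn in names(template$rings)) {
    ring <- template$rings[[rn]]
    k <- length(ring$atoms)
    a <- xyz[ring$atoms[1], ]
    b <- xyz[ring$atoms[k], ]
    d <- sqrt(sum((a - b)^2))
    if (abs(d - ring$closure_length) > tol)
      stop("ring ", rn, " failed to close: closure bond ",
           format(d, digits = 4), " A vs expected ",
           format(ring$closure_length, digits = 4), " A")
  }
  invisible(TRUE)
}

# Turn per-conformer assignments into full angle/dihedral matrices and run
# the compiled builder.  `ens` carries matrices `torsions` (n x n_torsion),
# `puckers` (n x n_ring, character state labels) and optionally `trivial`.
ensemble_coords <- function(template, ens) {
  tg <- ensemble_trig(template, ens)
  plan <- template$plan
  nerf_build_cpp(plan$parent, plan$aref, plan$dref, plan$lengths,
                 tg$cA, tg$sA, tg$cD, tg$sD)
}

# the angle/dihedral trig matrices for the compiled builders
ensemble_trig <- function(template, ens) {
  plan <- template$plan
  nt <- if (is.null(ens$torsions)) 0 else nrow(ens$torsions)
  n <- max(nt, if (is.null(ens$puckers)) 1 else nrow(ens$puckers), 1)
  A <- matrix(plan$angles, nrow = n, ncol = length(plan$angles), byrow = TRUE)
  D <- matrix(plan$dihedrals, nrow = n, ncol = length(plan$dihedrals), byrow = TRUE)

  want <- names(plan$torsion_rows)
  have <- colnames(ens$torsions)
  if (length(setdiff(have, want)))
    stop("unknown torsion name(s): ", paste(setdiff(have, want), collapse = ", "))
  if (length(setdiff(want, have)))
    stop("missing torsion assignment(s): ", paste(setdiff(want, have), collapse = ", "))
  for (tn in want) {
    v <- ens$torsions[, tn]
    if (any(!is.finite(v))) stop("non-finite angle for torsion ", tn)
    D[, plan$torsion_rows[[tn]]] <- v
  }
  if (!is.null(ens$trivial)) {
    for (tn in colnames(ens$trivial)) {
      if (!(tn %in% names(plan$trivial_rows)))
        stop("unknown trivial rotor: ", tn)
      D[, plan$trivial_rows[[tn]]] <- ens$trivial[, tn]
    }
  }
  varying <- unique(c(unlist(plan$torsion_rows[have]),
                      if (!is.null(ens$trivial))
                        unlist(plan$trivial_rows[colnames(ens$trivial)])))
  for (rn in names(template$rings)) {
    if (is.null(ens$puckers) || !(rn %in% colnames(ens$puckers)))
      stop("missing pucker assignment for ring ", rn)
    states <- ens$puckers[, rn]
    if (length(states) == 1 && n > 1) states <- rep(states, n)
    geom <- plan$ring_geom[[rn]]
    bad <- setdiff(unique(states), names(geom))
    if (length(bad))
      stop("unknown pucker state(s) for ring ", rn, ": ", paste(bad, collapse = ", "))
    us <- unique(states)
    for (s in us) {
      g <- geom[[s]]
      sel <- which(states == s)
      A[sel, g$rows] <- matrix(g$angle, nrow = length(sel),
                               ncol = length(g$rows), byrow = TRUE)
      D[sel, g$rows_d] <- matrix(g$dihedral, nrow = length(sel),
                                 ncol = length(g$rows_d), byrow = TRUE)
    }
    if (length(us) > 1)
      varying_a <- c(if (exists("varying_a")) varying_a,
                     geom[[us[1]]]$rows)
  }
  if (!exists("varying_a")) varying_a <- integer()
  varying <- unique(c(varying, varying_a))
  # trig: most columns are constant across conformers; evaluate those once
  d2r <- pi / 180
  expand <- function(v) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)
  cA <- expand(cos(A[1, ] * d2r)); sA <- expand(sin(A[1, ] * d2r))
  cD <- expand(cos(D[1, ] * d2r)); sD <- expand(sin(D[1, ] * d2r))
  if (n > 1 && length(varying)) {
    cD[, varying] <- cos(D[, varying] * d2r)
    sD[, varying] <- sin(D[, varying] * d2r)
  }
  if (n > 1 && length(varying_a)) {
    cA[, varying_a] <- cos(A[, varying_a] * d2r)
    sA[, varying_a] <- sin(A[, varying_a] * d2r)
  }
  list(cA = cA, sA = sA, cD = cD, sD = sD)
}

#' Measure a dihedral angle from Cartesian coordinates
#'
#' Signed dihedral in the IUPAC convention, wrapped to (-180, 180].
#'
#' @param x a `cartesian_conformer` or an atoms-by-3 coordinate matrix with
#'   rownames.
#' @param a,b,c,d atom names (or row indices) of the four atoms.
#' @return angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(x, a, b, c, d) {
  xyz <- if (inherits(x, "cartesian_conformer")) x$xyz else x
  atoms <- c(a, b, c, d)
  if (is.character(atoms)) {
    miss <- setdiff(atoms, rownames(xyz))
    if (length(miss)) stop("unknown atom(s): ", paste(miss, collapse = ", "))
    atoms <- match(atoms, rownames(xyz))
  }
  if (length(unique(atoms)) != 4) stop("dihedral requires four distinct atoms")
  p <- xyz[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  c1 <- pracma_cross(b1, b2); c2 <- pracma_cross(b2, b3)
  if (sqrt(sum(c1^2)) < 1e-9 || sqrt(sum(c2^2)) < 1e-9)
    stop("undefined dihedral: collinear reference atoms")
  cube <- array(xyz, dim = c(nrow(xyz), 3, 1))
  wrap_angle(measure_dihedrals_cpp(cube, matrix(atoms - 1L, 1, 4))[1, 1])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Detect steric clashes between non-bonded heavy atoms
#'
#' Scans all heavy-atom pairs separated by at least three bonds (1-2 and
#' 1-3 pairs are never tested) and reports those closer than `min_dist`.
#'
#' @param conformer a `cartesian_conformer`.
#' @param template the [molecule_template()] that built it (supplies the
#'   bond graph and default contact distance).
#' @param min_dist minimum allowed distance in Angstrom; defaults to the
#'   template's `min_contact`.
#' @return data frame with columns `atom_i`, `atom_j`, `distance`, sorted
#'   by distance (possibly zero rows).
#' @export
detect_clashes <- function(conformer, template, min_dist = template$min_contact) {
  if (min_dist <= 0) stop("min_dist must be > 0")
  heavy <- template$plan$heavy
  xyz <- conformer$xyz[heavy, , drop = FALSE]
  sep <- template$bond_sep[heavy, heavy]
  dmat <- as.matrix(stats::dist(xyz))
  keep <- upper.tri(dmat) & sep >= 3 & dmat < min_dist
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(atom_i = rownames(xyz)[idx[, 1]],
                    atom_j = rownames(xyz)[idx[, 2]],
                    distance = dmat[keep][order(dmat[keep])][rank(dmat[idx])],
                    stringsAsFactors = FALSE)
  out$distance <- dmat[idx]
  out[order(out$distance), , drop = FALSE]
}

#' Geometry sanity report against template tolerances
#'
#' Compares every constructed bond length, bond angle and recorded torsion
#' of a conformer against the template's reference values, as
#' Z = |observed - reference| / spread, and flags features with Z strictly
#' greater than the threshold.  This is a template-tolerance self-check in
#' the spirit of crystallographic-database geometry screening.
#'
#' @inheritParams detect_clashes
#' @param z_threshold flag features with Z strictly greater than this
#'   (default 3).
#' @return data frame with columns `feature`, `type`, `observed`,
#'   `reference`, `spread`, `z`, `flagged`.
#' @export
geometry_report <- function(conformer, template, z_threshold = 3) {
  tol <- template$tolerances
  if (any(unlist(tol[c("length_spread", "angle_spread", "torsion_spread")]) <= 0))
    stop("reference spreads must be positive")
  zm <- template$zmatrix
  xyz <- conformer$xyz
  # reference internal coordinates for this conformer's assignment
  ens <- list(torsions = matrix(conformer$torsion_values, nrow = 1,
                                dimnames = list(NULL, names(conformer$torsion_values))),
              puckers = matrix(conformer$pucker_values, nrow = 1,
                               dimnames = list(NULL, names(conformer$pucker_values))))
  ref <- reference_internals(template, ens)
  rows <- list()
  for (k in seq_len(nrow(zm))[-1]) {
    obs <- sqrt(sum((xyz[zm$name[k], ] - xyz[zm$parent[k], ])^2))
    rows[[length(rows) + 1]] <- data.frame(
      feature = paste(zm$name[k], zm$parent[k], sep = "-"), type = "bond",
      observed = obs, reference = zm$length[k], spread = tol$length_spread)
  }
  for (k in seq_len(nrow(zm))) {
    if (k < 3) next
    obs <- vec_angle(xyz[zm$name[k], ], xyz[zm$parent[k], ], xyz[zm$aref[k], ])
    rows[[length(rows) + 1]] <- data.frame(
      feature = paste(zm$name[k], zm$parent[k], zm$aref[k], sep = "-"),
      type = "angle", observed = obs, reference = ref$angles[k],
      spread = tol$angle_spread)
  }
  for (tn in names(template$rotatable_bonds)) {
    q <- template$rotatable_bonds[[tn]]
    obs <- measure_dihedral(conformer, q[1], q[2], q[3], q[4])
    rows[[length(rows) + 1]] <- data.frame(
      feature = tn, type = "torsion", observed = obs,
      reference = conformer$torsion_values[[tn]], spread = tol$torsion_spread)
  }
  out <- do.call(rbind, rows)
  dev <- ifelse(out$type == "bond", abs(out$observed - out$reference),
                circ_dist(out$observed, out$reference))
  out$z <- dev / out$spread
  out$flagged <- out$z > z_threshold
  rownames(out) <- NULL
  out
}

# Reference (assigned) angles/dihedrals per z-matrix row for one conformer.
reference_internals <- function(template, ens) {
  plan <- template$plan
  A <- plan$angles
  D <- plan$dihedrals
  for (tn in colnames(ens$torsions)) D[plan$torsion_rows[[tn]]] <- ens$torsions[, tn]
  for (rn in colnames(ens$puckers)) {
    g <- plan$ring_geom[[rn]][[ens$puckers[, rn]]]
    A[g$rows] <- g$angle
    D[g$rows_d] <- g$dihedral
  }
  list(angles = A, dihedrals = D)
}
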