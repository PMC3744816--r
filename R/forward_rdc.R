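# Residual dipolar couplings from molecular shape.
#
# Weak steric alignment in a compressed gel orients a molecule according
# to its shape anisotropy.  Here each conformer's alignment tensor is the
# traceless gyration tensor of its van-der-Waals surface, evaluated in
# closed form (each heavy atom's sphere surface contributes its exact
# second moment, surface-area weighted) and normalised by the isotropic
# moment; only the tensor's orientation, rhombicity and relative
# anisotropy matter because the per-medium magnitude is always a fitted
# nuisance scale.  Predicted couplings are ensemble averages of b' S b
# over the unit C-H bond vectors, linear in the scale.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20, S = 1.80, P = 1.80)

# deterministic Fibonacci sphere directions (n x 3)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Steric alignment tensor of a conformer
#'
#' @param conformer a `cartesian_conformer`, or an n x 3 coordinate matrix
#'   (treated as a plain point cloud with zero radii).
#' @param template optional [molecule_template()]; when given, the surface
#'   moments are taken over the heavy atoms at van der Waals radii.
#' @return symmetric traceless 3 x 3 tensor: the deviatoric part of the
#'   point-cloud gyration tensor divided by its isotropic moment
#'   (dimensionless; near zero for spherical shapes, order one for
#'   strongly anisotropic ones).  The per-medium magnitude in Hz is always
#'   a fitted nuisance scale.
#' @export
steric_alignment_tensor <- function(conformer, template = NULL) {
  if (inherits(conformer, "cartesian_conformer")) {
    stopifnot(!is.null(template))
    heavy <- template$plan$heavy
    radii <- .vdw_radii[template$zmatrix$element[heavy]]
    cube <- array(conformer$xyz, dim = c(nrow(conformer$xyz), 3, 1))
    # evaluate through the same closed-form surface-moment kernel used for
    # prediction, with a probe pair that is discarded
    w <- radii^2
    xyz <- conformer$xyz[heavy, , drop = FALSE]
    mu <- colSums(w * xyz) / sum(w)
    ctr <- sweep(xyz, 2, mu)
    G <- crossprod(sqrt(w) * ctr) / sum(w) +
      diag(3) * sum(w * radii^2 / 3) / sum(w)
    sv <- svd(ctr)$d
    if (sv[2] < 1e-8 * sv[1])
      stop("degenerate (collinear) geometry: alignment tensor undefined")
  } else {
    pts <- as.matrix(conformer)
    if (nrow(pts) < 4) stop("need at least 4 points for an alignment tensor")
    ctr <- sweep(pts, 2, colMeans(pts))
    G <- crossprod(ctr) / nrow(pts)
    sv <- svd(ctr)$d
    if (sum(ctr^2) / nrow(pts) > 1e-12 && sv[2] < 1e-8 * sv[1])
      stop("degenerate (collinear) geometry: alignment tensor undefined")
  }
  iso <- sum(diag(G))
  S <- G - diag(3) * iso / 3
  if (iso < 1e-12) return(S)
  # scale-invariant: deviatoric over isotropic moment, near zero for a
  # sphere, order one for strongly anisotropic shapes
  S / iso
}

#' Predict residual dipolar couplings from an ensemble
#'
#' D = scale * < b' S b > over conformers, where S is each conformer's
#' steric alignment tensor and b the unit C-H bond vector.
#'
#' @param coords atoms x 3 x n coordinate array (or a single
#'   `cartesian_conformer`).
#' @param template the [molecule_template()].
#' @param pairs data frame with columns `atom_c`, `atom_h` (bonded pairs).
#' @param scale per-medium magnitude (Hz; fitted nuisance, may be
#'   negative).
#' @return numeric vector of predicted couplings (Hz), one per pair.
#' @export
predict_rdc <- function(coords, template, pairs, scale = 1) {
  if (inherits(coords, "cartesian_conformer"))
    coords <- array(coords$xyz, dim = c(nrow(coords$xyz), 3, 1))
  idx <- template$plan$idx
  ic <- idx[pairs$atom_c]; ih <- idx[pairs$atom_h]
  if (any(is.na(ic)) || any(is.na(ih)))
    stop("unknown atom(s) in RDC pairs")
  sep <- template$bond_sep[cbind(ic, ih)]
  if (any(sep != 1))
    stop("RDC pairs must be bonded: ",
         paste(pairs$atom_c[sep != 1], pairs$atom_h[sep != 1],
               collapse = ", "))
  heavy <- template$plan$heavy
  radii <- .vdw_radii[template$zmatrix$element[heavy]]
  proj <- rdc_project_cpp(coords, heavy - 1L, radii, cbind(ic, ih) - 1L)
  scale * colMeans(proj)
}

#' Effective RDC error with angle-dependent model-error inflation
#'
#' The orientation dependence of a dipolar coupling is strongly
#' non-linear, so a fractional model error referenced to the medium's
#' maximal coupling is added in quadrature to the measurement error:
#' e_eff = sqrt(e_exp^2 + (f * D_max)^2).
#'
#' @param error experimental error (Hz, > 0).
#' @param d_max the medium's maximal absolute coupling at the current
#'   scale (Hz).
#' @param f model-error fraction (default 0.1).
#' @return effective error (Hz), always >= `error`.
#' @export
rdc_effective_error <- function(error, d_max, f = 0.1) {
  if (any(error <= 0)) stop("base error must be > 0")
  sqrt(error^2 + (f * d_max)^2)
}
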