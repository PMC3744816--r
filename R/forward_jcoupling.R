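#' Karplus scalar-coupling prediction
#'
#' Evaluates J(theta) = A cos^2(theta) + B cos(theta) + C for a vicinal
#' H-C-C-H dihedral, optionally with Haasnoot-Altona substituent
#' corrections: for each substituent with electronegativity difference
#' `dchi` and orientation sign `s` (+1/-1), a term
#' dchi * (P4 + P5 * cos^2(s * theta + P6 * |dchi|)) is added.
#'
#' @param theta dihedral angle(s), degrees.
#' @param k a Karplus coefficient set: list or one-row data frame with
#'   `A`, `B`, `C` and optionally `P4`, `P5`, `P6` plus `corrections`, a
#'   list of `list(dchi =, sign =)` records (or its JSON encoding).
#' @return coupling constant(s), Hz.
#' @export
karplus_j <- function(theta, k) {
  th <- theta * pi / 180
  J <- k$A * cos(th)^2 + k$B * cos(th) + k$C
  corr <- k$corrections
  if (!is.null(corr) && length(corr) && !all(is.na(corr)) &&
      !identical(corr, "")) {
    if (is.character(corr)) corr <- jsonlite::fromJSON(corr, simplifyVector = FALSE)
    if (!is.null(corr$dchi)) corr <- list(corr)  # single record
    for (cc in corr) {
      J <- J + cc$dchi *
        (k$P4 + k$P5 * cos(cc$sign * th + k$P6 * abs(cc$dchi) * pi / 180)^2)
    }
  }
  J
}

#' Ensemble-averaged scalar coupling
#'
#' Averages the Karplus coupling over the conformers of an ensemble;
#' averaging is always over J values, never over angles.
#'
#' @param thetas per-conformer dihedral angles (degrees) of the coupling's
#'   torsion path.
#' @param k Karplus coefficient set (see [karplus_j()]).
#' @return mean coupling, Hz.
#' @export
ensemble_j <- function(thetas, k) {
  if (!length(thetas)) stop("empty ensemble")
  mean(karplus_j(thetas, k))
}

# default generic 3JHH coefficient set shipped with the fixtures
default_karplus <- function() {
  data.frame(id = "hh3_generic", A = 7.76, B = -1.10, C = 1.40,
             corrections = "", stringsAsFactors = FALSE)
}
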