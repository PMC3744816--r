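#' Spin systems
#'
#' Collapses the template's protons into NOESY spins: each equivalence
#' group (methyl, guanidinium NH2) becomes one spin of multiplicity equal
#' to its member count; remaining protons are singleton spins named by
#' atom.  Exchangeable protons are excluded unless requested (D2O samples
#' observe only non-exchangeable protons).
#'
#' @param template a [molecule_template()].
#' @param exchangeable include exchangeable (N-H) spins.
#' @return object of class `spin_system`: list with `spins` (names),
#'   `members` (atom names per spin), `mult` (multiplicities),
#'   `atom_idx` (coordinate row indices per spin).
#' @export
spin_system <- function(template, exchangeable = FALSE) {
  zm <- template$zmatrix
  protons <- zm$name[zm$element == "H"]
  grouped <- unlist(template$equivalence_groups, use.names = FALSE)
  singles <- setdiff(protons, grouped)
  members <- c(stats::setNames(as.list(singles), singles),
               template$equivalence_groups)
  # template order for determinism
  first_atom <- vapply(members, function(m) match(m[1], zm$name), 0)
  members <- members[order(first_atom)]
  exch <- vapply(members, function(m) any(m %in% template$exchangeable), TRUE)
  if (!exchangeable) members <- members[!exch]
  structure(list(
    spins = names(members),
    members = members,
    mult = vapply(members, length, 0),
    exchangeable = vapply(members, function(m) any(m %in% template$exchangeable), TRUE),
    atom_idx = lapply(members, function(m) match(m, zm$name))),
    class = "spin_system")
}

spin_of <- function(ss, name) {
  hit <- match(name, ss$spins)
  if (!is.na(hit)) return(hit)
  for (i in seq_along(ss$members)) if (name %in% ss$members[[i]]) return(i)
  NA_integer_
}

#' Ensemble-averaged r^-6 interaction sums
#'
#' For every pair of spins, averages r^-6 over the conformers of the
#' ensemble; equivalence groups contribute the sum over member-proton
#' pairs (the per-spin multiplicity normalisation is applied later, in
#' [relaxation_matrix()]).  The diagonal holds intra-group (ordered) pair
#' sums.
#'
#' @param coords conformer coordinates: an atoms x 3 x n array (as from the
#'   internal ensemble builder) or a single `cartesian_conformer`.
#' @param spins a [spin_system()].
#' @param r_floor van-der-Waals contact floor (Angstrom): pair distances
#'   below this — sterically impossible for real protons, but reachable by
#'   an idealised torsional model during libration — are evaluated at the
#'   floor, which keeps the heavy-tailed r^-6 average finite and stable.
#'   0 disables the floor.
#' @return object of class `r6_matrix`: list with `A` (spins x spins,
#'   Angstrom^-6), `mult`, `spins`.
#' @export
ensemble_r6 <- function(coords, spins, r_floor = 1.7) {
  if (inherits(coords, "cartesian_conformer"))
    coords <- array(coords$xyz, dim = c(nrow(coords$xyz), 3, 1))
  atom_idx <- unlist(spins$atom_idx)
  grp_idx <- rep(seq_along(spins$spins), spins$mult)
  res <- r6_pairs_cpp(coords, atom_idx - 1L, grp_idx - 1L,
                      length(spins$spins), r_floor = r_floor)
  if (res$min_r < 0.05) {
    pr <- res$min_pair + 1L
    stop("coincident protons (r = ", format(res$min_r, digits = 3), " A): ",
         paste(spins$members[grp_idx[pr[1]]][[1]][1],
               spins$members[grp_idx[pr[2]]][[1]][1], sep = " / "))
  }
  A <- res$A
  dimnames(A) <- list(spins$spins, spins$spins)
  structure(list(A = A, mult = spins$mult, spins = spins$spins),
            class = "r6_matrix")
}

# (mu0/4pi)^2 * gammaH^4 * hbar^2, in Angstrom^6 s^-2
.dipolar_constant <- (1e-7)^2 * (2.6752218744e8)^4 * (1.054571817e-34)^2 * 1e60

#' Homonuclear dipolar relaxation rate matrix
#'
#' Converts ensemble-averaged r^-6 sums into the NOESY rate matrix for
#' rigid isotropic tumbling with a single correlation time: Lorentzian
#' spectral density J(w) = (2/5) tau_c / (1 + w^2 tau_c^2), cross
#' relaxation proportional to 6J(2w) - J(0) and auto relaxation to
#' J(0) + 3J(w) + 6J(2w), each scaled by the dipolar constant and the
#' pair's r^-6 sum, with multiplicity weighting for collapsed spins and an
#' optional uniform leak rate on the diagonal.
#'
#' @param r6 an `r6_matrix` from [ensemble_r6()], or a plain symmetric
#'   matrix of pair r^-6 values (Angstrom^-6; multiplicities taken as 1).
#' @param tau_c rotational correlation time (seconds, > 0).
#' @param field_mhz proton Larmor frequency (MHz, > 0).
#' @param leak uniform external leak rate added to the diagonal (1/s).
#' @return object of class `relaxation_matrix`: list with `R` (1/s),
#'   `tau_c`, `omega`, `mult`, `spins`.
#' @export
relaxation_matrix <- function(r6, tau_c, field_mhz, leak = 0) {
  if (tau_c <= 0) stop("tau_c must be > 0")
  if (field_mhz <= 0) stop("field_mhz must be > 0")
  if (inherits(r6, "r6_matrix")) {
    A <- r6$A; mult <- r6$mult; spins <- r6$spins
  } else {
    A <- as.matrix(r6)
    mult <- rep(1, nrow(A))
    spins <- rownames(A) %||% paste0("s", seq_len(nrow(A)))
  }
  omega <- 2 * pi * field_mhz * 1e6
  jw <- function(w) 0.4 * tau_c / (1 + (w * tau_c)^2)
  sig_u <- .dipolar_constant / 10 * (6 * jw(2 * omega) - jw(0))
  rho_u <- .dipolar_constant / 10 * (jw(0) + 3 * jw(omega) + 6 * jw(2 * omega))
  n <- nrow(A)
  R <- sig_u * A / mult            # row i divided by n_i
  off_sums <- rowSums(A) - diag(A)
  diag(R) <- (rho_u * (off_sums + diag(A)) + sig_u * diag(A)) / mult + leak
  dimnames(R) <- list(spins, spins)
  structure(list(R = R, tau_c = tau_c, omega = omega, mult = mult,
                 spins = spins), class = "relaxation_matrix")
}

#' Predict NOESY peak heights by diagonalisation
#'
#' Solves the relaxation first-order rate equation dM/dt = -R M over the
#' mixing time and returns the height matrix exp(-R tau_m) for unit
#' one-mole initial magnetisation per spin: entry (i, j) is the
#' cross-peak height at position (i, j); the diagonal holds the surviving
#' diagonal-peak heights.  The multiplicity-weighted rate matrix is
#' similar to a symmetric matrix and is exponentiated by
#' eigendecomposition; a non-symmetrisable user-supplied matrix falls back
#' to scaling-and-squaring with a warning.
#'
#' @param R a [relaxation_matrix()] (or plain square rate matrix, 1/s).
#' @param mixing_time NOESY mixing time (seconds, >= 0).
#' @return spins x spins height matrix.
#' @export
predict_noesy <- function(R, mixing_time) {
  if (mixing_time < 0) stop("mixing_time must be >= 0")
  if (inherits(R, "relaxation_matrix")) {
    mat <- R$R; mult <- R$mult; spins <- R$spins
  } else {
    mat <- as.matrix(R); mult <- rep(1, nrow(mat))
    spins <- rownames(mat) %||% paste0("s", seq_len(nrow(mat)))
  }
  s <- sqrt(mult)
  M <- sweep(sweep(mat, 1, s, "*"), 2, s, "/")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    warning("rate matrix is not symmetrisable; using scaling-and-squaring")
    H <- expm_ss(-mat * mixing_time)
  } else {
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    E <- e$vectors %*% (exp(-e$values * mixing_time) * t(e$vectors))
    H <- sweep(sweep(E, 1, s, "/"), 2, s, "*")
  }
  dimnames(H) <- list(spins, spins)
  H
}

# scaling-and-squaring matrix exponential (Taylor core), fallback only
expm_ss <- function(X, order = 12) {
  nrm <- max(abs(X))
  k <- max(0, ceiling(log2(max(nrm, 1e-300)))) + 1
  Xs <- X / 2^k
  E <- diag(nrow(X))
  term <- diag(nrow(X))
  for (i in seq_len(order)) {
    term <- term %*% Xs / i
    E <- E + term
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}
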