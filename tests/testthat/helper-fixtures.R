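# Shared helpers for the test suite.  Everything is generated in code; no
# stored fixtures.

# cache expensive fixtures once per test run
fixture_env <- new.env(parent = emptyenv())

get_strep <- function() {
  if (is.null(fixture_env$strep)) fixture_env$strep <- streptomycin_template()
  fixture_env$strep
}

get_probe <- function() {
  if (is.null(fixture_env$probe)) fixture_env$probe <- toy_probe_template()
  fixture_env$probe
}

# ground-truth mean torsions of the fixture (primary linkage mode)
strep_mean_torsions <- function() {
  c(phi12 = -75, psi12 = -134, phi23 = -103, psi23 = -81, chi1_S1 = 78,
    chi3_S1 = 128, chi3_R2 = 180, chi2_G3 = 257, chi5_G3 = 315)
}

strep_ground_puckers <- function() c(S1 = "1C4", R2 = "P144", G3 = "4C1")

# a minimal hand-built spin system over arbitrary coordinate rows
fake_spins <- function(names, atom_idx, mult = rep(1, length(names))) {
  structure(list(spins = names,
                 members = stats::setNames(as.list(names), names),
                 mult = mult,
                 exchangeable = rep(FALSE, length(names)),
                 atom_idx = atom_idx),
            class = "spin_system")
}

# coordinates cube from a list of per-conformer coordinate matrices
cube_of <- function(...) {
  mats <- list(...)
  arr <- array(0, dim = c(nrow(mats[[1]]), 3, length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  dimnames(arr) <- list(rownames(mats[[1]]), NULL, NULL)
  arr
}

# independent signed-dihedral oracle: rotate the frame so the central bond
# lies along +z, then compare the azimuths of the two outer atoms
dihedral_oracle <- function(p1, p2, p3, p4) {
  z <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  a <- p1 - p2
  b <- p4 - p3
  phi1 <- atan2(sum(a * y), sum(a * x))
  phi2 <- atan2(sum(b * y), sum(b * x))
  ((phi2 - phi1) * 180 / pi + 540) %% 360 - 180
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# fast fit configuration for unit tests
test_config <- function(...) fit_config(n_ensemble = 120, ...)
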