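# two protons r Angstrom apart, as a coordinate cube
two_spin_cube <- function(...) {
  rs <- c(...)
  mats <- lapply(rs, function(r)
    rbind(a = c(0, 0, 0), b = c(r, 0, 0)))
  do.call(cube_of, mats)
}

test_that("ensemble r^-6 averaging is the plain mean over conformers", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  r6 <- ensemble_r6(two_spin_cube(3), ss)
  expect_equal(r6$A["a", "b"], 3^-6, tolerance = 1e-12)
  expect_equal(r6$A["a", "b"], 1.3717e-3, tolerance = 1e-4)

  r6_2 <- ensemble_r6(two_spin_cube(2, 4), ss)
  expect_equal(r6_2$A["a", "b"], mean(c(2^-6, 4^-6)), tolerance = 1e-12)
  expect_equal(r6_2$A["a", "b"]^(-1 / 6), 2.239, tolerance = 1e-3)
  # permuting conformer order changes nothing
  r6_3 <- ensemble_r6(two_spin_cube(4, 2), ss)
  expect_equal(r6_2$A, r6_3$A)
})

test_that("coincident protons raise a singularity error", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  expect_error(ensemble_r6(two_spin_cube(1e-4), ss), "coincident")
})

test_that("cross-relaxation changes sign at omega tau_c = sqrt(5)/2", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  r6 <- ensemble_r6(two_spin_cube(2.5), ss)
  omega <- 2 * pi * 900e6
  tau_zero <- sqrt(5) / 2 / omega
  R_fast <- relaxation_matrix(r6, tau_zero / 50, 900)
  R_slow <- relaxation_matrix(r6, tau_zero * 50, 900)
  R_zero <- relaxation_matrix(r6, tau_zero, 900)
  # the rate matrix enters as dM/dt = -R M with off-diagonal +sigma, so
  # sigma > 0 (fast tumbling) means a positive entry and vice versa
  expect_gt(R_fast$R[1, 2], 0)
  expect_lt(R_slow$R[1, 2], 0)
  expect_lt(abs(R_zero$R[1, 2]) / abs(R_slow$R[1, 2]), 1e-10)
})

test_that("dipolar rates are linear in the r^-6 sums", {
  A <- matrix(c(0, 2e-3, 2e-3, 0), 2, 2)
  R1 <- relaxation_matrix(A, 0.35e-9, 900)
  R2 <- relaxation_matrix(2 * A, 0.35e-9, 900)
  expect_equal(R2$R, 2 * R1$R, tolerance = 1e-12)
})

test_that("two-spin rates match an independently coded textbook formula", {
  r <- 2.5
  tau <- 0.35e-9
  field <- 900
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  R <- relaxation_matrix(ensemble_r6(two_spin_cube(r), ss), tau, field)
  # independent evaluation: sigma = K/10 r^-6 (6 J(2w) - J(0)),
  # rho = K/10 r^-6 (J(0) + 3 J(w) + 6 J(2w)), J(w) = 0.4 tau/(1+(w tau)^2),
  # K = (mu0/4pi gamma^2 hbar)^2 with CODATA constants
  mu0_4pi <- 1e-7; gam <- 2.6752218744e8; hbar <- 1.054571817e-34
  K <- (mu0_4pi * gam^2 * hbar)^2 * 1e60
  w <- 2 * pi * field * 1e6
  Jf <- function(x) 0.4 * tau / (1 + (x * tau)^2)
  sigma <- K / 10 * r^-6 * (6 * Jf(2 * w) - Jf(0))
  rho <- K / 10 * r^-6 * (Jf(0) + 3 * Jf(w) + 6 * Jf(2 * w))
  expect_equal(R$R[1, 2], sigma, tolerance = 1e-12)
  expect_equal(R$R[1, 1], rho, tolerance = 1e-12)
  expect_error(relaxation_matrix(ensemble_r6(two_spin_cube(r), ss), -1, 900),
               "tau_c")
})

test_that("zero mixing time returns the identity", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  R <- relaxation_matrix(ensemble_r6(two_spin_cube(2.2), ss), 0.5e-9, 600)
  H <- predict_noesy(R, 0)
  expect_equal(unname(H), diag(2), tolerance = 1e-12)
})

test_that("initial-rate cross-peak ratio follows the sixth-power law", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  h <- vapply(c(2.0, 2.5), function(r) {
    R <- relaxation_matrix(ensemble_r6(two_spin_cube(r), ss), 0.35e-9, 900)
    predict_noesy(R, 1e-5)[1, 2]
  }, 0)
  expect_equal(h[1] / h[2], (2.5 / 2.0)^6, tolerance = 1e-3)
  expect_equal((2.5 / 2.0)^6, 3.8147, tolerance = 1e-4)
})

test_that("diagonalisation equals a truncated Taylor series on 4 spins", {
  set.seed(21)
  xyz <- matrix(rnorm(12, sd = 1.5), 4, 3)
  xyz <- xyz * 2.5 / min(dist(xyz))
  ss <- fake_spins(paste0("s", 1:4), as.list(1:4))
  R <- relaxation_matrix(ensemble_r6(cube_of(xyz), ss), 0.4e-9, 700)
  tm <- 0.5
  H <- predict_noesy(R, tm)
  X <- -R$R * tm
  S <- diag(4); term <- diag(4)
  for (k in 1:40) {
    term <- term %*% X / k
    S <- S + term
  }
  expect_equal(unname(H), unname(S), tolerance = 1e-8)
})

test_that("heights respect detailed balance for uniform multiplicities", {
  set.seed(33)
  xyz <- matrix(rnorm(15, sd = 2), 5, 3)
  xyz <- xyz * 2.2 / min(dist(xyz))
  ss <- fake_spins(paste0("s", 1:5), as.list(1:5))
  R <- relaxation_matrix(ensemble_r6(cube_of(xyz), ss), 0.35e-9, 900)
  H <- predict_noesy(R, 0.7)
  expect_lt(max(abs(H - t(H))), 1e-10)
})

test_that("ISPA limit: heights/tau converge to -sigma as tau -> 0", {
  ss <- fake_spins(c("a", "b"), list(1L, 2L))
  R <- relaxation_matrix(ensemble_r6(two_spin_cube(2.5), ss), 0.35e-9, 900)
  tm <- 1e-3
  rate <- predict_noesy(R, tm)[1, 2] / tm
  expect_lt(abs(rate - (-R$R[1, 2])) / abs(R$R[1, 2]), 0.01)
})

test_that("ensemble averaging obeys the Jensen inequality direction", {
  tpl <- get_probe()
  ss <- spin_system(tpl)
  c1 <- build_conformer(tpl, c(t1 = 60), character())
  c2 <- build_conformer(tpl, c(t1 = 180), character())
  cmean <- build_conformer(tpl, c(t1 = 120), character())
  cube <- cube_of(c1$xyz, c2$xyz)
  r6_ens <- ensemble_r6(cube, ss)
  r6_mean <- ensemble_r6(cmean, ss)
  i <- match("H1", ss$spins); j <- match("H2", ss$spins)
  expect_gte(r6_ens$A[i, j], r6_mean$A[i, j])
})

test_that("collapsed equivalence groups keep the multiplicity bookkeeping", {
  # one methyl-like group of 3 protons at ~2.6 A from a lone proton
  xyz <- rbind(h = c(0, 0, 0), m1 = c(2.6, 0, 0), m2 = c(2.6, 1.78, 0),
               m3 = c(2.6, 0.89, 1.54))
  ss <- structure(list(spins = c("h", "Me"),
                       members = list(h = "h", Me = c("m1", "m2", "m3")),
                       mult = c(h = 1, Me = 3),
                       exchangeable = c(FALSE, FALSE),
                       atom_idx = list(1L, 2:4)), class = "spin_system")
  r6 <- ensemble_r6(cube_of(xyz), ss)
  # off-diagonal = pair sum over the three member protons
  want <- sum(apply(xyz[2:4, ], 1, function(p) sum((p - xyz[1, ])^2)^-3))
  expect_equal(r6$A["h", "Me"], want, tolerance = 1e-12)
  R <- relaxation_matrix(r6, 0.35e-9, 900)
  # n_i R_ij = n_j R_ji (group detailed balance)
  expect_equal(1 * R$R["h", "Me"], 3 * R$R["Me", "h"], tolerance = 1e-12)
  H <- predict_noesy(R, 0.3)
  expect_equal(1 * H["h", "Me"], 3 * H["Me", "h"], tolerance = 1e-12)
})
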