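test_that("dihedral construction and measurement agree on a 4-atom chain", {
  tpl <- toy_chain_template(4)
  cf <- build_conformer(tpl, c(t1 = 180), character())
  expect_equal(measure_dihedral(cf, "C1", "C2", "C3", "C4"), 180,
               tolerance = 1e-9)

  # cis geometry minimises the 1-4 distance over all torsions
  d14 <- vapply(seq(-180, 175, by = 5), function(t) {
    cc <- build_conformer(tpl, c(t1 = t), character())
    sqrt(sum((cc$xyz["C1", ] - cc$xyz["C4", ])^2))
  }, 0)
  expect_equal(which.min(d14), which(seq(-180, 175, by = 5) == 0))
})

test_that("measure_dihedral matches an independent frame-based oracle", {
  set.seed(42)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(12, sd = 2), 4, 3,
                  dimnames = list(paste0("a", 1:4), NULL))
    got <- measure_dihedral(xyz, "a1", "a2", "a3", "a4")
    want <- dihedral_oracle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    expect_equal(circ_dist(got, want), 0, tolerance = 1e-6)
  }
})

test_that("mirroring coordinates negates dihedrals", {
  set.seed(7)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3,
                dimnames = list(paste0("a", 1:4), NULL))
  mirrored <- xyz %*% diag(c(1, 1, -1))
  rownames(mirrored) <- rownames(xyz)
  expect_equal(measure_dihedral(mirrored, "a1", "a2", "a3", "a4"),
               -measure_dihedral(xyz, "a1", "a2", "a3", "a4"),
               tolerance = 1e-9)
})

test_that("collinear central atoms give an undefined-dihedral error", {
  xyz <- rbind(a1 = c(0, 0, 0), a2 = c(1, 0, 0), a3 = c(2, 0, 0),
               a4 = c(3, 1, 0))
  expect_error(measure_dihedral(xyz, "a1", "a2", "a3", "a4"), "collinear")
})

test_that("fixture torsions round-trip through construction", {
  tpl <- get_strep()
  tor <- strep_mean_torsions()
  cf <- build_conformer(tpl, tor, strep_ground_puckers())
  for (tn in names(tor)) {
    q <- tpl$rotatable_bonds[[tn]]
    expect_lt(circ_dist(measure_dihedral(cf, q[1], q[2], q[3], q[4]),
                        tor[[tn]]), 1e-3)
  }
  # bond lengths and angles equal template values regardless of torsions
  rep <- geometry_report(cf, tpl)
  expect_lt(max(rep$z), 1e-6)
})

test_that("rigid-body motion leaves dihedrals and clash lists unchanged", {
  tpl <- get_strep()
  cf <- build_conformer(tpl, strep_mean_torsions(), strep_ground_puckers())
  R <- random_rotation(11)
  moved <- cf
  moved$xyz <- sweep(cf$xyz %*% t(R), 2, c(5, -3, 2), "+")
  q <- tpl$rotatable_bonds$psi12
  expect_lt(circ_dist(measure_dihedral(moved, q[1], q[2], q[3], q[4]),
                      measure_dihedral(cf, q[1], q[2], q[3], q[4])), 1e-6)
  canon <- function(cl) cl[order(cl$atom_i, cl$atom_j), ]
  cl1 <- canon(detect_clashes(cf, tpl, min_dist = 3))
  cl2 <- canon(detect_clashes(moved, tpl, min_dist = 3))
  expect_equal(cl1$atom_i, cl2$atom_i)
  expect_equal(cl1$atom_j, cl2$atom_j)
  expect_equal(cl1$distance, cl2$distance, tolerance = 1e-9)
})

test_that("clash detection equals a brute-force pair scan", {
  tpl <- toy_chain_template(10)
  tor <- stats::setNames(c(60, -60, 60, 170, 60, -75, 40),
                         paste0("t", 1:7))
  cf <- build_conformer(tpl, tor, character())
  got <- detect_clashes(cf, tpl, min_dist = 4)
  # brute force double loop over heavy pairs at least 3 bonds apart
  xyz <- cf$xyz
  sep <- tpl$bond_sep
  want <- data.frame()
  for (i in 1:9) for (j in (i + 1):10) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (sep[i, j] >= 3 && d < 4)
      want <- rbind(want, data.frame(i = i, j = j, d = d))
  }
  want <- want[order(want$d), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$distance, want$d, tolerance = 1e-12)
  expect_equal(match(got$atom_i, rownames(xyz)), want$i)
})

test_that("a heavy-atom pair at 2.3 A violates the 2.4 A contact rule", {
  tpl <- toy_chain_template(5)
  # find a torsion pair putting C1 and C5 at exactly 2.3 A
  f <- function(t) {
    cc <- build_conformer(tpl, c(t1 = t, t2 = t), character())
    sqrt(sum((cc$xyz["C1", ] - cc$xyz["C5", ])^2)) - 2.3
  }
  t0 <- uniroot(f, c(0, 90))$root
  cf <- build_conformer(tpl, c(t1 = t0, t2 = t0), character())
  hits <- detect_clashes(cf, tpl, min_dist = 2.4)
  expect_equal(nrow(hits), 1)
  expect_equal(sort(c(hits$atom_i, hits$atom_j)), c("C1", "C5"))
  expect_equal(hits$distance, 2.3, tolerance = 1e-6)
  # widely separated pairs give an empty list
  cf2 <- build_conformer(tpl, c(t1 = 180, t2 = 180), character())
  expect_equal(nrow(detect_clashes(cf2, tpl, min_dist = 2.4)), 0)
})

test_that("geometry report flags only deviations strictly beyond threshold", {
  tpl <- toy_chain_template(5)
  cf <- build_conformer(tpl, c(t1 = 60, t2 = 180), character())
  rep0 <- geometry_report(cf, tpl)
  expect_lt(max(rep0$z), 1e-9)
  expect_false(any(rep0$flagged))

  spread <- tpl$tolerances$length_spread
  stretch <- function(k) {
    cc <- cf
    dir <- cc$xyz["C5", ] - cc$xyz["C4", ]
    dir <- dir / sqrt(sum(dir^2))
    cc$xyz["C5", ] <- cc$xyz["C5", ] + k * spread * dir
    cc
  }
  # displaced by 3 spreads: Z = 3, and the flag rule is strictly greater,
  # so a feature sitting exactly on the threshold is not flagged
  r3 <- geometry_report(stretch(3), tpl)
  row <- r3[r3$feature == "C5-C4", ]
  expect_equal(row$z, 3, tolerance = 1e-6)
  r3b <- geometry_report(stretch(3), tpl, z_threshold = row$z)
  expect_false(r3b[r3b$feature == "C5-C4", "flagged"])
  # 3.5 spreads is flagged
  r35 <- geometry_report(stretch(3.5), tpl)
  expect_true(r35[r35$feature == "C5-C4", "flagged"])
  # zero reference spread is a configuration error
  tpl2 <- tpl
  tpl2$tolerances$length_spread <- 0
  expect_error(geometry_report(cf, tpl2), "spread")
})

test_that("unknown torsions and rings are rejected", {
  tpl <- toy_chain_template(4)
  expect_error(build_conformer(tpl, c(bogus = 10), character()), "unknown torsion")
  expect_error(build_conformer(tpl, numeric(), character()), "missing torsion")
  tpl2 <- get_strep()
  pk <- strep_ground_puckers()
  pk["R2"] <- "P999"
  expect_error(build_conformer(tpl2, strep_mean_torsions(), pk),
               "unknown pucker")
})

test_that("all canonical ring states build and close", {
  tpl <- get_strep()
  tor <- strep_mean_torsions()
  for (rn in names(tpl$rings)) {
    for (st in tpl$rings[[rn]]$states) {
      pk <- strep_ground_puckers()
      pk[rn] <- st
      cf <- build_conformer(tpl, tor, pk)  # closure checked internally
      rep <- geometry_report(cf, tpl)
      expect_lt(max(rep$z), 1e-6)
    }
  }
})

test_that("torsion input accepts [0, 360) and wraps to (-180, 180]", {
  expect_equal(wrap_angle(300), -60)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  tpl <- toy_chain_template(4)
  a <- build_conformer(tpl, c(t1 = 300), character())
  b <- build_conformer(tpl, c(t1 = -60), character())
  expect_equal(a$xyz, b$xyz, tolerance = 1e-12)
  expect_equal(a$torsion_values[["t1"]], -60)
})
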