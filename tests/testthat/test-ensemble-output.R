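test_that("the output ensemble has exactly n clash-free microstates", {
  tpl <- get_strep()
  m <- ground_truth_model()
  out <- emit_microstates(m, tpl, n = 120, seed = 7)
  expect_equal(dim(out$coords)[3], 120)
  expect_equal(nrow(out$ensemble$torsions), 120)
  # every emitted conformer passes an independent clash re-validation
  for (i in seq(1, 120, by = 24)) {
    cf <- structure(list(xyz = out$coords[, , i]), class = "cartesian_conformer")
    expect_equal(nrow(detect_clashes(cf, tpl, min_dist = tpl$min_contact)), 0)
  }
  expect_gt(out$n_rejected, 0)
  expect_lt(out$acceptance_rate, 1)
})

test_that("min_dist = 0 disables trimming and returns the raw draws", {
  tpl <- get_strep()
  m <- ground_truth_model()
  out <- emit_microstates(m, tpl, n = 40, min_dist = 0, seed = 3)
  set.seed(3)
  bs <- sample.int(.Machine$integer.max, 40)
  raw <- sample_ensemble(m, tpl, n = 40, seed = bs[1])
  expect_equal(out$ensemble$torsions, raw$torsions)
  expect_equal(out$n_rejected, 0)
})

test_that("an implausibly large contact distance aborts with advice", {
  tpl <- get_strep()
  m <- ground_truth_model()
  expect_error(emit_microstates(m, tpl, n = 20, min_dist = 3.5, seed = 1),
               "acceptance rate|could not collect")
})

test_that("macrostate output delegates to the enumeration", {
  tpl <- get_strep()
  m <- ground_truth_model()
  out <- emit_macrostates(m, tpl)
  expect_equal(dim(out$coords)[3], 12)
  st <- enumerate_macrostates(m)
  expect_equal(out$occupancy, st$occupancy)
  expect_equal(sum(out$occupancy), 1, tolerance = 1e-9)
  # a fully uni-modal model gives one conformer of occupancy 1
  uni <- dynamic_model(list(bond_model("t1", list(macrostate(1, 0, 5)))),
                       template = get_probe())
  out1 <- emit_macrostates(uni, get_probe())
  expect_equal(dim(out1$coords)[3], 1)
  expect_equal(out1$occupancy, 1)
})

test_that("torsion histograms conserve counts with documented edge rule", {
  set.seed(5)
  a <- runif(100, -180, 180)
  h <- torsion_histogram(a)
  expect_equal(sum(h$count), 100)
  expect_equal(nrow(h), 24)
  expect_equal(h$center, seq(0, 345, by = 15))
  # edges are half-open [centre - w/2, centre + w/2): 7.5 belongs to the
  # bin centred at 15
  h1 <- torsion_histogram(7.5)
  expect_equal(h1$count[h1$center == 15], 1)
  expect_equal(sum(h1$count), 1)
  expect_error(torsion_histogram(a, bin_width = 14), "divide")
})

test_that("binning matches a direct histogram oracle", {
  set.seed(9)
  a <- wrap_angle(170 + rnorm(500, sd = 25))
  h <- torsion_histogram(a, bin_width = 15)
  # oracle: shift by half a bin, wrap to [0, 360), integer-divide
  k <- floor(((a %% 360) + 7.5) %% 360 / 15)
  want <- vapply(0:23, function(b) sum(k == b), 0)
  expect_equal(h$count, want)
})

test_that("geometry queries equal direct vector arithmetic", {
  tpl <- get_strep()
  cf <- build_conformer(tpl, strep_mean_torsions(), strep_ground_puckers())
  g <- measure_geometry(cf, list(c("S1_O2", "R2_O4"),
                                 c("S1_C1", "S1_C2", "S1_C3"),
                                 c("S1_O2", "S1_O2")))
  xyz <- cf$xyz
  expect_equal(g$mean[1], sqrt(sum((xyz["S1_O2", ] - xyz["R2_O4", ])^2)),
               tolerance = 1e-12)
  expect_equal(g$mean[3], 0)
  # three collinear points give an angle of 180 degrees
  cc <- array(rbind(a = c(0, 0, 0), b = c(1, 1, 0), c = c(2, 2, 0)),
              dim = c(3, 3, 1), dimnames = list(c("a", "b", "c"), NULL, NULL))
  g2 <- measure_geometry(cc, list(c("a", "b", "c")))
  expect_equal(g2$mean, 180, tolerance = 1e-6)
  expect_error(measure_geometry(cf, list(c("S1_O2", "NOPE"))), "unknown")
})

test_that("multi-model PDB output round-trips through a standard reader", {
  skip_if_not_installed("bio3d")
  tpl <- get_strep()
  m <- ground_truth_model()
  out <- emit_macrostates(m, tpl)
  path <- tempfile(fileext = ".pdb")
  write_pdb_models(out$coords, tpl, path, occupancy = out$occupancy)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  expect_equal(dim(pdb$xyz)[1], 12)
  n_at <- nrow(tpl$zmatrix)
  for (mdl in c(1, 7)) {
    back <- matrix(pdb$xyz[mdl, ], ncol = 3, byrow = TRUE)
    expect_equal(back, unname(out$coords[, , mdl]), tolerance = 1e-3)
  }
  expect_equal(pdb$atom$o[1], round(out$occupancy[1], 2), tolerance = 0.011)
  expect_setequal(unique(pdb$atom$elesy), c("C", "H", "N", "O"))
})

test_that("gentle trimming does not bias the torsion marginals", {
  tpl <- get_strep()
  m <- ground_truth_model()
  # at a looser contact threshold the clash rate is small, so raw and
  # trimmed marginals agree (two-sample Kolmogorov-Smirnov per bond)
  raw <- emit_microstates(m, tpl, n = 400, min_dist = 0, seed = 21)
  trimmed <- emit_microstates(m, tpl, n = 400, min_dist = 1.7, seed = 21)
  expect_lt(1 - trimmed$acceptance_rate, 0.05)
  for (bn in c("phi12", "psi23", "chi3_R2")) {
    ks <- suppressWarnings(
      stats::ks.test(raw$ensemble$torsions[, bn],
                     trimmed$ensemble$torsions[, bn]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the output bundle writes the standard files", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(1, -65, 10)))),
                     template = tpl)
  sim <- simulate_restraints(
    tpl, m,
    datasets = data.frame(dataset_id = "noesy", mixing_time_s = 0.3,
                          field_mhz = 900, temperature_k = 278,
                          spins = "nonexchangeable", stringsAsFactors = FALSE),
    j_pairs = data.frame(atom1 = "H1", atom2 = "C1", atom3 = "C2",
                         atom4 = "H2"),
    rdc_pairs = data.frame(atom_c = "C1", atom_h = "H1"),
    rdc_scales = c(gel = 10), seed = 2, add_noise = TRUE)
  f <- metropolis_fit(m, tpl, sim$restraints, steps = 30, seed = 1,
                      config = test_config())
  dir <- tempfile()
  write_output_bundle(f, dir, n_microstates = 20, seed = 1,
                      defining_bonds = "t1",
                      queries = list(c("H1", "H4")))
  expect_true(all(file.exists(file.path(dir,
    c("microstates.pdb", "macrostates.pdb", "families.json",
      "torsion_histograms.tsv", "measurements.tsv")))))
  fam <- jsonlite::read_json(file.path(dir, "families.json"),
                             simplifyVector = TRUE)
  expect_equal(sum(fam$families$population), 1, tolerance = 1e-9)
})
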