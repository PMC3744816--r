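# Model selection on noise-free probe data; common random numbers and a
# large generating ensemble make the chi-square surfaces clean enough to
# discriminate variants in a few hundred Metropolis steps.
sel_sim <- function(model, seed = 1,
                    noise = noise_spec(noise_floor = 1e-9)) {
  simulate_restraints(
    get_probe(), model,
    datasets = data.frame(dataset_id = "noesy", mixing_time_s = 0.3,
                          field_mhz = 900, temperature_k = 278,
                          spins = "nonexchangeable", stringsAsFactors = FALSE),
    j_pairs = data.frame(atom1 = "H1", atom2 = "C1", atom3 = "C2",
                         atom4 = "H2"),
    rdc_pairs = data.frame(atom_c = c("C1", "C2", "C3"),
                           atom_h = c("H1", "H2", "H4")),
    rdc_scales = c(gel = 10), tau_c = 0.4e-9, noise = noise,
    n = 20000, seed = seed, add_noise = FALSE)
}

sel_cfg <- fit_config(n_ensemble = 800, common_random = TRUE,
                      anneal = c(5, 0.3))

test_that("modality scan recovers a uni-modal generating model", {
  tpl <- get_probe()
  # a mean far from the classic rotamers, so the lock rule stays inactive
  truth <- dynamic_model(list(bond_model("t1", list(macrostate(1, -100, 10)))),
                         template = tpl)
  sim <- sel_sim(truth, seed = 31)
  res <- modality_scan(truth, tpl, sim$restraints, "t1", steps = 1500,
                       seed = 5, config = sel_cfg)
  expect_equal(length(res$best$macrostates), 1)
  expect_lt(circ_dist(res$best$macrostates[[1]]$mu, -100), 5)
})

test_that("modality scan recovers a well-separated bi-modal model", {
  tpl <- get_probe()
  truth <- dynamic_model(list(bond_model("t1",
                                         list(macrostate(0.6, 60, 8),
                                              macrostate(0.4, -175, 8)))),
                         template = tpl)
  # the tiny four-proton system needs precise data before two modes carry
  # more information than one broad libration; tighter errors provide it
  sim <- sel_sim(truth, seed = 33,
                 noise = noise_spec(noe_fraction = 0.05, rdc_sigma = 0.15,
                                    noise_floor = 1e-9))
  res <- modality_scan(truth, tpl, sim$restraints, "t1", steps = 2500,
                       seed = 6, config = sel_cfg)
  expect_equal(length(res$best$macrostates), 2)
  pis <- sort(vapply(res$best$macrostates, `[[`, 0, "pi"), decreasing = TRUE)
  se <- sqrt(0.6 * 0.4 / 300)
  expect_lt(abs(pis[1] - 0.6), 3 * se + 0.02)
})

test_that("near-degenerate and negligible modes are reduced away", {
  # merging rule: two modes closer than their combined spreads collapse
  bm <- bond_model("x", list(macrostate(0.5, 50, 12),
                             macrostate(0.5, 60, 12)))
  red <- ensemblefit:::reduce_bond(bm, fit_config())
  expect_equal(length(red$macrostates), 1)
  expect_equal(red$macrostates[[1]]$pi, 1)
  expect_lt(circ_dist(red$macrostates[[1]]$mu, 55), 3)
  # occupancy floor prunes a trace mode
  bm2 <- bond_model("x", list(macrostate(0.99, 50, 5),
                              macrostate(0.01, 180, 5)))
  red2 <- ensemblefit:::reduce_bond(bm2, fit_config())
  expect_equal(length(red2$macrostates), 1)
  # rotamer locking snaps means within tolerance
  bm3 <- bond_model("x", list(macrostate(1, 65, 5)))
  lk <- ensemblefit:::lock_rotamers(bm3, fit_config())
  expect_equal(lk$macrostates[[1]]$mu, 60)
  expect_true(lk$macrostates[[1]]$fixed_mu)
  far <- ensemblefit:::lock_rotamers(
    bond_model("x", list(macrostate(1, 100, 5))), fit_config())
  expect_false(far$macrostates[[1]]$fixed_mu)
})

test_that("prochiral assignment recovers the generating labels", {
  tpl <- get_probe()
  # -100 degrees puts H2 and H3 in clearly distinct NOE/J environments
  truth <- dynamic_model(list(bond_model("t1", list(macrostate(1, -100, 10)))),
                         template = tpl)
  sim <- sel_sim(truth, seed = 35)
  res <- assign_prochiral(truth, tpl, sim$restraints, c("H2", "H3"),
                          steps = 0, seed = 4, config = sel_cfg)
  expect_equal(res$assignment, "original")
  expect_lt(res$delta_chi2, 0 + res$fit_swapped$chi2_total)  # bookkeeping
  expect_equal(res$delta_chi2,
               res$fit_swapped$chi2_total - res$fit_original$chi2_total)

  # a swap-symmetric restraint set is flagged undetermined
  rs <- sim$restraints
  keep <- rs$noe$atom_i == "H2" & rs$noe$atom_j == "H3"
  rs$noe <- rs$noe[keep, , drop = FALSE]
  rs$j <- rs$j[0, , drop = FALSE]
  rs$rdc <- rs$rdc[0, , drop = FALSE]
  res2 <- assign_prochiral(truth, tpl, rs, c("H2", "H3"), steps = 0,
                          seed = 4, config = sel_cfg)
  expect_equal(res2$assignment, "undetermined")
  expect_error(assign_prochiral(truth, tpl, sim$restraints, c("H1", "H4")),
               "prochiral")
})

test_that("ring pucker scans recover the generating canonical states", {
  tpl <- get_strep()
  truth <- ground_truth_model()
  sim <- simulate_restraints(tpl, truth, seed = 37, add_noise = FALSE,
                             noise = noise_spec(noise_floor = 1e-9))
  cfg <- fit_config(common_random = TRUE)
  # six-membered ring: the correct chair of the two wins
  res6 <- scan_ring_puckers(truth, tpl, sim$restraints, "G3", steps = 0,
                            seed = 2, config = cfg)
  expect_equal(res6$best_states, "4C1")
  # furanose: the generating grid state wins over the full phase grid
  res5 <- scan_ring_puckers(truth, tpl, sim$restraints, "R2", steps = 0,
                            seed = 2, config = cfg)
  expect_equal(res5$best_states, "P144")
})
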