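# A small single-rotor spin system keeps the fitting tests fast: the toy
# probe template has four protons around one rotatable bond, one NOESY
# dataset, one vicinal coupling and three C-H RDC vectors.
probe_datasets <- function() {
  data.frame(dataset_id = "noesy", mixing_time_s = 0.3, field_mhz = 900,
             temperature_k = 278, spins = "nonexchangeable",
             stringsAsFactors = FALSE)
}

probe_sim <- function(model, seed = 1, add_noise = FALSE, ...) {
  tpl <- get_probe()
  simulate_restraints(
    tpl, model, datasets = probe_datasets(),
    j_pairs = data.frame(atom1 = "H1", atom2 = "C1", atom3 = "C2",
                         atom4 = "H2"),
    rdc_pairs = data.frame(atom_c = c("C1", "C2", "C3"),
                           atom_h = c("H1", "H2", "H4")),
    rdc_scales = c(gel = 10),
    tau_c = 0.4e-9, seed = seed, add_noise = add_noise, ...)
}

probe_model <- function(ms = list(macrostate(1, -65, 12)))
  dynamic_model(list(bond_model("t1", ms)), template = get_probe())

test_that("chi-square is additive, non-negative and zero at exactness", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m)
  rs <- sim$restraints
  # exact predictions give zero
  preds <- list(noe = rs$noe$height, j = rs$j$observed_hz,
                rdc = rs$rdc$observed_hz)
  rep0 <- chi_square(preds, rs)
  expect_equal(rep0$total, 0)
  expect_true(all(rep0$contributions >= 0))
  # one restraint off by exactly its error contributes 1.0
  preds$j <- rs$j$observed_hz + rs$j$error_hz
  rep1 <- chi_square(preds, rs)
  expect_equal(rep1$total, nrow(rs$j), tolerance = 1e-12)
  # per-dataset totals sum to the grand total
  expect_equal(sum(rep1$per_dataset$chi2), rep1$total, tolerance = 1e-9)
  # missing predictions are an error
  preds$noe <- preds$noe[-1]
  expect_error(chi_square(preds, rs), "missing")
})

test_that("the per-restraint summary reproduces printed rounding", {
  # a 309-restraint set whose total chi-square is 194.9 reports 0.6 per
  # restraint at one decimal
  n <- 309
  k <- default_karplus()
  rs <- restraint_set(
    j = data.frame(atom1 = "H1", atom2 = "C1", atom3 = "C2", atom4 = "H2",
                   observed_hz = rep(0, n), error_hz = 1,
                   karplus_id = k$id),
    karplus = k)
  preds <- list(j = rep(sqrt(194.9 / n), n))
  rep <- chi_square(preds, rs)
  expect_equal(rep$total, 194.9, tolerance = 1e-9)
  expect_equal(round(rep$total / rep$n, 1), 0.6)
})

test_that("nuisance scales close exactly on self-generated data", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 8)
  # evaluate with the generating ensemble: scales must come back exactly
  ctx <- ensemblefit:::make_fit_context(tpl, sim$restraints, fit_config())
  pu <- ensemblefit:::forward_ensemble(ctx, m, 0.4e-9,
                                       sim$manifest$ens_seed)
  sc <- ensemblefit:::solve_scales(ctx, pu)
  expect_equal(sc$rdc$gel, 10, tolerance = 1e-6)
  # the NOESY scale is pulled slightly below 1 by sub-floor positions
  # recorded as zero-height no-NOEs; without truncation it is exact
  sim2 <- probe_sim(m, seed = 8, noise = noise_spec(noise_floor = 1e-9))
  ctx2 <- ensemblefit:::make_fit_context(tpl, sim2$restraints, fit_config())
  pu2 <- ensemblefit:::forward_ensemble(ctx2, m, 0.4e-9,
                                        sim2$manifest$ens_seed)
  sc2 <- ensemblefit:::solve_scales(ctx2, pu2)
  expect_equal(sc2$noesy$noesy, 1, tolerance = 1e-6)
})

test_that("tau_c is recovered from noise-free data", {
  tpl <- get_strep()
  m <- ground_truth_model()
  sim <- simulate_restraints(tpl, m, noise = noise_spec(noise_floor = 1e-9),
                             tau_c = 0.6e-9, seed = 4, add_noise = FALSE)
  ctx <- ensemblefit:::make_fit_context(tpl, sim$restraints, fit_config())
  tau <- ensemblefit:::refit_tau(ctx, m, sim$manifest$ens_seed)
  expect_lt(abs(tau - 0.6e-9) / 0.6e-9, 0.01)
})

test_that("a uniform intensity factor moves the scale, not the fit", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 5, add_noise = TRUE)
  rs2 <- sim$restraints
  rs2$noe$height <- 3 * rs2$noe$height
  rs2$noe$error <- 3 * rs2$noe$error
  nu1 <- solve_nuisances(m, tpl, sim$restraints, seed = 6)
  nu2 <- solve_nuisances(m, tpl, rs2, seed = 6)
  expect_equal(nu2$noesy_scales$noesy, 3 * nu1$noesy_scales$noesy,
               tolerance = 1e-9)
  expect_equal(nu2$chi2$total, nu1$chi2$total, tolerance = 1e-9)
})

test_that("identical seeds reproduce identical fits bitwise", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 2, add_noise = TRUE)
  cfg <- test_config()
  f1 <- metropolis_fit(random_start(m, 5), tpl, sim$restraints,
                       steps = 120, seed = 77, config = cfg)
  f2 <- metropolis_fit(random_start(m, 5), tpl, sim$restraints,
                       steps = 120, seed = 77, config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$chi2_total, f2$chi2_total)
  f3 <- metropolis_fit(random_start(m, 5), tpl, sim$restraints,
                       steps = 120, seed = 78, config = cfg)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("the best-so-far trace is monotone non-increasing", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 3, add_noise = TRUE)
  f <- metropolis_fit(random_start(m, 1), tpl, sim$restraints,
                      steps = 200, seed = 10, config = test_config())
  expect_false(is.unsorted(-f$trace$best))
  expect_true(all(f$trace$best <= f$trace$chi2 + 1e-9))
})

test_that("a uni-modal generating model is recovered from a random start", {
  tpl <- get_probe()
  m <- probe_model(list(macrostate(1, -65, 10)))
  # a large generating ensemble makes the data represent the model
  # expectation, so the chi-square of a perfect refit approaches zero
  sim <- probe_sim(m, seed = 7, n = 20000,
                   noise = noise_spec(noise_floor = 1e-9))
  cfg <- fit_config(n_ensemble = 2000, common_random = TRUE)
  f <- metropolis_fit(random_start(m, 3), tpl, sim$restraints,
                      steps = 600, seed = 12, config = cfg)
  expect_lt(f$chi2_total, 0.01 * f$chi2$n)
  expect_lt(circ_dist(f$model$bonds$t1$macrostates[[1]]$mu, -65), 2)
})

test_that("multistart compares the stated fraction of best runs", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 9, add_noise = TRUE)
  cfg <- test_config()
  f <- multistart_fit(m, tpl, sim$restraints, runs = 12, steps = 40,
                      top_fraction = 0.10, seed = 3, config = cfg)
  expect_equal(f$multistart$top_compared, 2)  # ceiling(1.2)
  expect_equal(f$convergence$n_compared, 2)
  expect_equal(nrow(f$runs_summary), 12)
  expect_equal(f$chi2_total, min(f$runs_summary$chi2))
  # a single run is trivially converged
  f1 <- multistart_fit(m, tpl, sim$restraints, runs = 1, steps = 40,
                       seed = 3, config = cfg)
  expect_true(f1$convergence$converged)
})

test_that("top runs agree on the recovered mode means", {
  tpl <- get_probe()
  m <- probe_model(list(macrostate(1, 40, 8)))
  sim <- probe_sim(m, seed = 13, n = 20000,
                   noise = noise_spec(noise_floor = 1e-9))
  cfg <- fit_config(n_ensemble = 500, common_random = TRUE)
  f <- multistart_fit(m, tpl, sim$restraints, runs = 3, steps = 1500,
                      top_fraction = 0.67, seed = 21, config = cfg)
  expect_true(f$convergence$converged)
  expect_true(all(f$convergence$detail$max_dmu < 5))
})

test_that("fitted-model methods expose the standard modelling surface", {
  tpl <- get_probe()
  m <- probe_model()
  sim <- probe_sim(m, seed = 2, add_noise = TRUE)
  f <- metropolis_fit(m, tpl, sim$restraints, steps = 60, seed = 2,
                      config = test_config())
  cf <- coef(f)
  expect_true(all(c("t1.mu1", "t1.sigma1", "t1.pi1", "tau_c_ns") %in% names(cf)))
  p <- predict(f)
  expect_equal(nrow(p), f$chi2$n)
  expect_true(all(c("observed", "predicted", "error", "chi2") %in% names(p)))
  r <- residuals(f)
  expect_equal(length(r), f$chi2$n)
  sims <- simulate(f, nsim = 2, n = 20)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]$torsions), 20)
  s <- summary(f)
  expect_s3_class(s, "summary.ensemble_fit")
  expect_equal(nrow(s$torsions), 1)
  expect_output(print(f), "chi-square|Chi-square")
  # plotting runs headless
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f, which = 1))
})
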