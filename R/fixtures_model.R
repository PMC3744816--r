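#' Noise specification for synthetic restraint generation
#'
#' Defaults follow the measurement-error rules used throughout the
#' package: NOESY cross-peak errors at 40 percent of the measured height,
#' scalar couplings at 1 Hz (Karplus predictive accuracy), RDCs at 1.5 Hz
#' (gel measurement error), and a spectral noise floor below which a
#' cross-peak position is classified as a no-NOE with error noise/3 times
#' the multiplet factor.
#'
#' @param noe_fraction relative NOESY restraint error (the 40 percent rule
#'   covers measurement scatter and prediction error together).
#' @param noe_meas_fraction the share of the NOESY error budget realised
#'   as proportional measurement scatter when simulating (the remainder
#'   represents prediction error, which a self-consistent forward model
#'   does not exhibit).
#' @param j_sigma scalar-coupling noise and restraint error (Hz).
#' @param rdc_sigma RDC noise and restraint error (Hz).
#' @param noise_floor spectral noise height (one-mole-equivalent units);
#'   measurement scatter also has an additive component of a third of this
#'   (the noise standard deviation implied by the three-sigma floor rule).
#' @param nonoe_factor multiplet scaling factor assumed for no-NOE error
#'   conversion.
#' @return list of settings.
#' @export
noise_spec <- function(noe_fraction = 0.40, noe_meas_fraction = 0.5,
                       j_sigma = 1.0, rdc_sigma = 1.5,
                       noise_floor = 1e-4, nonoe_factor = 2) {
  stopifnot(noe_fraction >= 0, noe_meas_fraction >= 0, j_sigma >= 0,
            rdc_sigma >= 0, noise_floor > 0, nonoe_factor >= 1)
  as.list(environment())
}

#' Final fitted dynamic model of the streptomycin-like fixture
#'
#' Encodes the fixture's ground-truth conformational model: a uni-modal
#' S1-R2 linkage (phi12 = -75 +/- 16 deg, psi12 = -134 +/- 22 deg), a
#' bi-modal R2-G3 linkage coupled with the G3 hydroxymethyl rotor into one
#' mode group (primary 62 percent at phi23/psi23/chi5 = -103/-81/315 deg,
#' secondary 38 percent at 103/173/296 deg), a tri-modal gem-diol rotor
#' locked on the classic rotamers with occupancies 0.51/0.45/0.04, a
#' symmetric bi-modal guanidinium rotor at C1, uni-modal chi3_S1 and
#' chi2_G3, and uni-modal ring states (S1 1C4 chair, G3 4C1 chair, R2
#' furanose at pseudorotation grid state P144).
#'
#' @return a [dynamic_model()].
#' @export
ground_truth_model <- function() {
  dynamic_model(
    bonds = list(
      bond_model("phi12", list(macrostate(1, -75, 16))),
      bond_model("psi12", list(macrostate(1, -134, 22))),
      bond_model("phi23", list(macrostate(0.62, -103, 6),
                               macrostate(0.38, 103, 10)),
                 coupling = "link23"),
      bond_model("psi23", list(macrostate(0.62, -81, 12),
                               macrostate(0.38, 173, 25)),
                 coupling = "link23"),
      bond_model("chi5_G3", list(macrostate(0.62, 315, 25),
                                 macrostate(0.38, 296, 25)),
                 coupling = "link23"),
      bond_model("chi1_S1", list(macrostate(0.5, 78, 17),
                                 macrostate(0.5, 162, 17))),
      bond_model("chi3_S1", list(macrostate(1, 128, 27))),
      bond_model("chi3_R2", list(macrostate(0.51, 180, 20, fixed_mu = TRUE),
                                 macrostate(0.45, 300, 20, fixed_mu = TRUE),
                                 macrostate(0.04, 60, 20, fixed_mu = TRUE))),
      bond_model("chi2_G3", list(macrostate(1, 257, 18)))),
    rings = list(ring_model("S1", "1C4", 1),
                 ring_model("R2", "P144", 1),
                 ring_model("G3", "4C1", 1)))
}

#' @rdname simulate_restraints
#' @export
strep_acquisitions <- function() {
  data.frame(dataset_id = c("noesy_d2o", "noesy_h2o"),
             mixing_time_s = c(0.700, 0.600),
             field_mhz = c(900, 600),
             temperature_k = c(278, 278),
             spins = c("nonexchangeable", "all"),
             stringsAsFactors = FALSE)
}

# vicinal ring H-C-C-H coupling paths of the fixture
strep_jpairs <- function() {
  rbind(
    data.frame(atom1 = paste0("S1_H", 1:5), atom2 = paste0("S1_C", 1:5),
               atom3 = paste0("S1_C", 2:6), atom4 = paste0("S1_H", 2:6)),
    data.frame(atom1 = "R2_H1", atom2 = "R2_C1", atom3 = "R2_C2",
               atom4 = "R2_H2"),
    data.frame(atom1 = paste0("G3_H", 1:4), atom2 = paste0("G3_C", 1:4),
               atom3 = paste0("G3_C", 2:5), atom4 = paste0("G3_H", 2:5)))
}

# resolvable one-bond C-H pairs of the fixture
strep_rdc_pairs <- function() {
  rbind(
    data.frame(atom_c = paste0("S1_C", 1:6), atom_h = paste0("S1_H", 1:6)),
    data.frame(atom_c = c("R2_C1", "R2_C2", "R2_C4", "R2_C3p"),
               atom_h = c("R2_H1", "R2_H2", "R2_H4", "R2_H3p")),
    data.frame(atom_c = c(paste0("G3_C", 1:5), "G3_C6", "G3_C6"),
               atom_h = c(paste0("G3_H", 1:5), "G3_H61", "G3_H62")))
}

#' Simulate a synthetic restraint set from a dynamic model
#'
#' Forward-predicts NOESY peak heights (full relaxation matrix at the
#' stated correlation time, field and mixing time), ensemble-averaged
#' scalar couplings and shape-based RDCs from a microstate ensemble
#' sampled from `model`, then adds Gaussian noise per [noise_spec()].
#' Observed cross-peak heights below the noise floor are classified as
#' no-NOEs with the noise/3 error rule.  Fully reproducible given `seed`;
#' when `dir` is given, writes the restraint TSVs plus a manifest of true
#' values (and the generating model/template as JSON).
#'
#' @param template a [molecule_template()].
#' @param model generating [dynamic_model()].
#' @param noise a [noise_spec()].
#' @param datasets NOESY acquisition table (see [strep_acquisitions()]).
#' @param tau_c true rotational correlation time (s).
#' @param rdc_scales named per-medium true alignment magnitudes (Hz).
#' @param j_pairs,rdc_pairs restraint target tables; defaults are the
#'   fixture's ring vicinal couplings and resolvable C-H pairs.
#' @param n microstates in the generating ensemble.
#' @param seed integer seed (drives both the ensemble and the noise).
#' @param add_noise draw Gaussian noise (default TRUE); when FALSE the
#'   observed values equal the forward predictions exactly while the
#'   restraint errors still follow the stated rules.
#' @param dir optional output directory.
#' @return list with `restraints` (a [restraint_set()]) and `manifest`
#'   (true values and bookkeeping).
#' @export
simulate_restraints <- function(template, model, noise = noise_spec(),
                                datasets = strep_acquisitions(),
                                tau_c = 0.6e-9,
                                rdc_scales = c(gel_4.5 = 12, gel_6 = 16),
                                j_pairs = strep_jpairs(),
                                rdc_pairs = strep_rdc_pairs(),
                                n = 300, seed = 1, add_noise = TRUE,
                                dir = NULL) {
  set.seed(seed)
  ens_seed <- sample.int(.Machine$integer.max, 1)
  ens <- sample_ensemble(model, template, n, ens_seed)
  cube <- ensemble_coords(template, ens)
  set.seed(seed + 1)  # noise stream, separate from the ensemble stream

  noe_rows <- list()
  truth_noe <- list()
  for (i in seq_len(nrow(datasets))) {
    id <- datasets$dataset_id[i]
    ss <- spin_system(template, exchangeable = identical(datasets$spins[i], "all"))
    r6 <- ensemble_r6(cube, ss)
    R <- relaxation_matrix(r6, tau_c, datasets$field_mhz[i])
    H <- predict_noesy(R, datasets$mixing_time_s[i])
    ns <- length(ss$spins)
    pair <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
    if (identical(datasets$spins[i], "all")) {
      # the D2O set already covers non-exchangeable pairs
      keep <- ss$exchangeable[pair[, 1]] | ss$exchangeable[pair[, 2]]
      pair <- pair[keep, , drop = FALSE]
    }
    h_true <- H[pair]
    h_obs <- h_true
    if (add_noise) {
      # measurement scatter: additive spectral noise (floor/3, the noise
      # s.d. implied by the three-sigma floor rule) plus the measurement
      # share of the proportional error budget, in quadrature
      sd_meas <- sqrt((noise$noe_meas_fraction * noise$noe_fraction *
                         abs(h_true))^2 + (noise$noise_floor / 3)^2)
      h_obs <- h_true + stats::rnorm(length(h_true)) * sd_meas
    }
    is_noe <- abs(h_obs) >= noise$noise_floor
    noe_rows[[id]] <- data.frame(
      dataset_id = id,
      atom_i = ss$spins[pair[, 1]], atom_j = ss$spins[pair[, 2]],
      height = ifelse(is_noe, h_obs, 0),
      error = ifelse(is_noe,
                     pmax(noe_error(pmax(abs(h_obs), 1e-12),
                                    max(noise$noe_fraction, 1e-6)), 1e-6),
                     nonoe_error(noise$noise_floor, noise$nonoe_factor)),
      kind = ifelse(is_noe, "NOE", "noNOE"),
      stringsAsFactors = FALSE)
    truth_noe[[id]] <- h_true
  }
  noe <- do.call(rbind, c(noe_rows, list(make.row.names = FALSE)))

  kset <- default_karplus()
  idx <- template$plan$idx
  quads <- cbind(idx[j_pairs$atom1], idx[j_pairs$atom2],
                 idx[j_pairs$atom3], idx[j_pairs$atom4]) - 1L
  th <- measure_dihedrals_cpp(cube, quads)
  j_true <- vapply(seq_len(nrow(j_pairs)), function(r)
    mean(karplus_j(th[, r], as.list(kset[1, ]))), 0)
  j_obs <- j_true
  if (add_noise) j_obs <- j_true + stats::rnorm(length(j_true)) * noise$j_sigma
  j <- data.frame(j_pairs,
                  observed_hz = j_obs,
                  error_hz = max(noise$j_sigma, 1.0),
                  karplus_id = kset$id, stringsAsFactors = FALSE)

  u <- predict_rdc(cube, template, rdc_pairs)
  rdc_rows <- list()
  for (m in names(rdc_scales)) {
    d_true <- rdc_scales[[m]] * u
    d_obs <- d_true
    if (add_noise) d_obs <- d_true + stats::rnorm(length(d_true)) * noise$rdc_sigma
    rdc_rows[[m]] <- data.frame(
      medium_id = m, rdc_pairs,
      observed_hz = d_obs,
      error_hz = max(noise$rdc_sigma, 1e-3), stringsAsFactors = FALSE)
  }
  rdc <- do.call(rbind, c(rdc_rows, list(make.row.names = FALSE)))

  rs <- restraint_set(noe = noe, j = j, rdc = rdc, karplus = kset,
                      datasets = datasets, template = template)
  manifest <- list(
    seed = seed, ens_seed = ens_seed, n_microstates = n, tau_c = tau_c,
    rdc_scales = as.list(rdc_scales),
    noise = noise,
    counts = list(
      noe = as.list(table(paste(noe$dataset_id, noe$kind))),
      j = nrow(j), rdc = nrow(rdc)),
    true_noe = lapply(truth_noe, unname),
    true_j = j_true,
    true_rdc_unit = unname(u))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_restraints(rs, dir)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_model_json(model, file.path(dir, "model.json"))
    write_template_json(template, file.path(dir, "template.json"))
  }
  list(restraints = rs, manifest = manifest)
}
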