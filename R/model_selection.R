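# Model selection: bond modality, prochiral assignment, ring puckers.
#
# All three follow the same recipe the refinement itself uses: fit each
# candidate variant against the restraints, then compare chi-squares with
# a parsimony adjustment -- a variant with more macrostates must improve
# the total chi-square by a configurable margin per added parameter, which
# makes the "no change to the dynamic model reduces the chi-square"
# stopping rule operational in the presence of ensemble sampling noise.

.classic_rotamers <- c(60, 180, -60)

# Fit (or evaluate) one candidate, then score it on a common evaluation
# ensemble so that candidate comparisons are paired: with one shared
# ensemble seed the sampling noise cancels out of the chi-square
# differences between variants.
fit_or_eval <- function(model, template, restraints, steps, seed,
                        score_seed, config) {
  fitted <- if (steps > 0)
    metropolis_fit(model, template, restraints, steps = steps, seed = seed,
                   config = config)$model
  else model
  nu <- solve_nuisances(fitted, template, restraints, seed = score_seed,
                        config = config)
  list(model = fitted, chi2_total = nu$chi2$total, chi2 = nu$chi2,
       tau_c = nu$tau_c)
}

n_bond_params <- function(bm) {
  k <- length(bm$macrostates)
  n_mu <- sum(!vapply(bm$macrostates, `[[`, TRUE, "fixed_mu"))
  n_mu + k + (k - 1)  # free means + spreads + free occupancies
}

#' Scan the modality of one rotatable bond
#'
#' Fits uni-, bi- and tri-modal variants of the bond (all other bonds kept
#' at their current model), reduces a fitted variant when two modes merge
#' (circular distance of means below the combined spreads) or a mode's
#' occupancy falls below the floor, locks means that settle within
#' tolerance of a classic rotamer (60, 180, 300 degrees), and returns the
#' variant with the best parsimony-adjusted chi-square.
#'
#' @param model current [dynamic_model()].
#' @param template the [molecule_template()].
#' @param restraints a [restraint_set()].
#' @param bond torsion name to scan.
#' @param modalities candidate mode counts.
#' @param steps Metropolis steps per candidate fit.
#' @param seed integer seed.
#' @param config a [fit_config()].
#' @return list with `best` (the selected [bond_model()]), `model` (full
#'   model with the bond replaced), and `table` (per-variant chi-square,
#'   parameters, adjusted score).
#' @export
modality_scan <- function(model, template, restraints, bond,
                          modalities = 1:3, steps = 2000, seed = 1,
                          config = fit_config()) {
  if (!(bond %in% names(model$bonds))) stop("unknown bond: ", bond)
  if (!is.null(model$bonds[[bond]]$coupling)) {
    n_in_group <- sum(vapply(model$bonds, function(b)
      identical(b$coupling, model$bonds[[bond]]$coupling), TRUE))
    if (n_in_group > 1)
      stop("bond ", bond, " is coupled; scan the coupling group jointly ",
           "by editing the model instead")
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(modalities) + 1)
  score_seed <- seeds[length(seeds)]
  rows <- list(); fits <- list()
  for (i in seq_along(modalities)) {
    k <- modalities[i]
    variant <- model
    variant$bonds[[bond]] <- bond_model(bond, lapply(seq_len(k), function(j)
      macrostate(1 / k, .classic_rotamers[j], 15)))
    f <- fit_or_eval(variant, template, restraints, steps, seeds[i],
                     score_seed, config)
    bm <- reduce_bond(f$model$bonds[[bond]], config)
    f$model$bonds[[bond]] <- bm
    fits[[i]] <- f
    k_eff <- length(bm$macrostates)
    rows[[i]] <- data.frame(modality = k, effective_modality = k_eff,
                            chi2 = f$chi2_total,
                            n_params = n_bond_params(bm))
  }
  tab <- do.call(rbind, rows)
  tab$score <- tab$chi2 + config$parsimony_margin * tab$n_params
  best_i <- which.min(tab$score)
  best <- lock_rotamers(fits[[best_i]]$model$bonds[[bond]], config)
  out_model <- fits[[best_i]]$model
  out_model$bonds[[bond]] <- best
  list(best = best, model = out_model, table = tab)
}

# merge near-degenerate modes and prune negligible occupancies
reduce_bond <- function(bm, config) {
  ms <- bm$macrostates
  changed <- TRUE
  while (changed && length(ms) > 1) {
    changed <- FALSE
    for (i in seq_along(ms)) for (j in seq_along(ms)) {
      if (i >= j) next
      if (circ_dist(ms[[i]]$mu, ms[[j]]$mu) <
          (ms[[i]]$sigma + ms[[j]]$sigma)) {
        w <- c(ms[[i]]$pi, ms[[j]]$pi)
        if (sum(w) == 0) w <- c(1, 1)
        mu <- circ_mean(rep(c(ms[[i]]$mu, ms[[j]]$mu),
                            round(1000 * w / sum(w)) + 1))
        ms[[i]] <- macrostate(sum(c(ms[[i]]$pi, ms[[j]]$pi)), mu,
                              max(ms[[i]]$sigma, ms[[j]]$sigma),
                              ms[[i]]$fixed_mu && ms[[j]]$fixed_mu)
        ms[[j]] <- NULL
        changed <- TRUE
        break
      }
    }
  }
  keep <- vapply(ms, `[[`, 0, "pi") >= config$occupancy_floor
  if (!all(keep) && any(keep)) {
    ms <- ms[keep]
    tot <- sum(vapply(ms, `[[`, 0, "pi"))
    for (k in seq_along(ms)) ms[[k]]$pi <- ms[[k]]$pi / tot
  }
  bond_model(bm$torsion, ms, bm$coupling)
}

lock_rotamers <- function(bm, config) {
  ms <- lapply(bm$macrostates, function(m) {
    d <- circ_dist(m$mu, .classic_rotamers)
    if (min(d) <= config$rotamer_lock_tol) {
      m$mu <- .classic_rotamers[which.min(d)]
      m$fixed_mu <- TRUE
    }
    m
  })
  bond_model(bm$torsion, ms, bm$coupling)
}

#' Determine a prochiral stereo-assignment
#'
#' Runs a full fit under each of the two NMR-degenerate label assignments
#' of a prochiral pair (the restraint labels are swapped) and selects the
#' lower-chi-square combination; a difference below the tie tolerance is
#' flagged undetermined.
#'
#' @inheritParams modality_scan
#' @param pair length-2 character vector of swappable labels; must be
#'   declared in the template's prochiral pairs.
#' @param tie_tol chi-square difference below which the assignment is
#'   reported undetermined.
#' @return list with `assignment` ("original", "swapped" or
#'   "undetermined"), `delta_chi2` (swapped minus original), and the two
#'   fits.
#' @export
assign_prochiral <- function(model, template, restraints, pair,
                             steps = 2000, seed = 1, tie_tol = 2,
                             config = fit_config()) {
  declared <- vapply(template$prochiral_pairs, function(p)
    setequal(p, pair), TRUE)
  if (!any(declared))
    stop("pair not declared prochiral in template: ",
         paste(pair, collapse = "/"))
  swap <- function(x) {
    y <- x
    y[x == pair[1]] <- pair[2]
    y[x == pair[2]] <- pair[1]
    y
  }
  rs2 <- restraints
  rs2$noe$atom_i <- swap(rs2$noe$atom_i)
  rs2$noe$atom_j <- swap(rs2$noe$atom_j)
  for (col in paste0("atom", 1:4)) rs2$j[[col]] <- swap(rs2$j[[col]])
  rs2$rdc$atom_h <- swap(rs2$rdc$atom_h)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  f1 <- fit_or_eval(model, template, restraints, steps, seeds[1], seeds[3],
                    config)
  f2 <- fit_or_eval(model, template, rs2, steps, seeds[2], seeds[3], config)
  d <- f2$chi2_total - f1$chi2_total
  assignment <- if (abs(d) < tie_tol) "undetermined" else
    if (d > 0) "original" else "swapped"
  list(assignment = assignment, delta_chi2 = d,
       fit_original = f1, fit_swapped = f2)
}

#' Scan canonical ring pucker states
#'
#' Fits the model with the ring held in each canonical state (and
#' optionally bi-modal state combinations) and returns the best
#' parsimony-adjusted candidate; candidates within the tie tolerance of
#' the best are reported as degenerate.
#'
#' @inheritParams modality_scan
#' @param ring ring name.
#' @param states candidate states (default: the template's grid).
#' @param bimodal also try two-state combinations (with a free occupancy
#'   fixed at the values given in `bimodal_probs`).
#' @param bimodal_probs occupancies used for two-state candidates.
#' @param tie_tol chi-square window for the degeneracy flag.
#' @return list with `best_states`, `probs`, `model`, `table`,
#'   `degenerate` (other candidates within tolerance).
#' @export
scan_ring_puckers <- function(model, template, restraints, ring,
                              states = template$rings[[ring]]$states,
                              bimodal = FALSE, bimodal_probs = c(0.5, 0.5),
                              steps = 0, seed = 1, tie_tol = 2,
                              config = fit_config()) {
  if (!(ring %in% names(template$rings))) stop("unknown ring: ", ring)
  cands <- lapply(states, function(s) list(states = s, probs = 1))
  if (bimodal && length(states) > 1) {
    cmb <- utils::combn(states, 2)
    for (i in seq_len(ncol(cmb)))
      cands[[length(cands) + 1]] <- list(states = cmb[, i],
                                         probs = bimodal_probs)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(cands) + 1)
  score_seed <- seeds[length(seeds)]
  rows <- list(); fits <- list()
  for (i in seq_along(cands)) {
    variant <- model
    variant$rings[[ring]] <- ring_model(ring, cands[[i]]$states,
                                        cands[[i]]$probs)
    f <- fit_or_eval(variant, template, restraints, steps, seeds[i],
                     score_seed, config)
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      candidate = paste(cands[[i]]$states, collapse = "+"),
      n_states = length(cands[[i]]$states), chi2 = f$chi2_total)
  }
  tab <- do.call(rbind, rows)
  tab$score <- tab$chi2 + config$parsimony_margin * (tab$n_states - 1)
  best_i <- which.min(tab$score)
  deg <- tab$candidate[tab$score <= tab$score[best_i] + tie_tol &
                         seq_len(nrow(tab)) != best_i]
  list(best_states = cands[[best_i]]$states, probs = cands[[best_i]]$probs,
       model = fits[[best_i]]$model, table = tab, degenerate = deg)
}
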