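#' Fit configuration
#'
#' Tunable settings for chi-square evaluation and Metropolis Monte-Carlo
#' refinement.  Defaults: proposal step sizes mu +/- 5 deg, sigma +/- 2
#' deg, occupancy simplex step 0.05; temperature 1 on the chi-square scale
#' (optionally geometric annealing); a fresh 300-microstate ensemble drawn
#' per evaluation (common random numbers available to suppress proposal
#' noise); tau_c refit every 100 steps over a 0.05-5 ns bracket.
#'
#' @param temperature Metropolis temperature on the chi-square scale.
#' @param anneal optional c(T_start, T_end) for geometric annealing.
#' @param step_mu,step_sigma,step_pi proposal step sizes (deg, deg,
#'   occupancy).
#' @param n_ensemble microstates per chi-square evaluation.
#' @param tau_bracket tau_c search bracket in seconds.
#' @param refit_tau_every steps between tau_c refits.
#' @param common_random reuse one ensemble seed for every evaluation of a
#'   run (variance reduction); default FALSE (fresh draw per step).
#' @param sigma_range allowed libration spread range (deg); the upper
#'   bound keeps macrostates librational (a wrapped normal much beyond 45
#'   degrees approaches free rotation and stops being a defined mode).
#' @param rdc_f fractional model error for the RDC angle-dependent error
#'   inflation.
#' @param leak uniform external relaxation leak rate (1/s).
#' @param r6_floor van-der-Waals contact floor for the r^-6 averages
#'   (Angstrom; see [ensemble_r6()]).
#' @param parsimony_margin chi-square improvement required per added
#'   parameter during model selection.
#' @param occupancy_floor modes below this occupancy are pruned during
#'   model selection.
#' @param rotamer_lock_tol lock means within this distance of a classic
#'   rotamer (deg).
#' @param final_polish re-score the best visited states with replicate
#'   ensembles before reporting.
#' @param burnin_fraction fraction of steps run as burn-in on a reduced
#'   ensemble size (`burnin_n` microstates per evaluation) before the
#'   full-size refinement phase; the best state is tracked only over
#'   full-size evaluations.  Default 0 (every step at `n_ensemble`).
#' @param burnin_n microstates per evaluation during burn-in.
#' @param jump_prob probability that a mean-angle move is a global jump
#'   (uniform on the circle) instead of a local step; lets the chain hop
#'   between rotamer basins that a 5-degree random walk cannot cross.
#' @return list of settings.
#' @export
fit_config <- function(temperature = 1, anneal = NULL, step_mu = 5,
                       step_sigma = 2, step_pi = 0.05, n_ensemble = 300,
                       tau_bracket = c(0.05e-9, 5e-9), refit_tau_every = 100,
                       common_random = FALSE, sigma_range = c(0.5, 45),
                       rdc_f = 0.1, leak = 0, r6_floor = 1.7,
                       parsimony_margin = 1,
                       occupancy_floor = 0.02, rotamer_lock_tol = 10,
                       final_polish = TRUE, burnin_fraction = 0,
                       burnin_n = 100, jump_prob = 0.1) {
  as.list(environment())
}

# ---------------------------------------------------------------------
# Prediction context: everything about (template, restraints) that does
# not change during a fit, resolved to integer indices once.
make_fit_context <- function(template, restraints, config = fit_config()) {
  validate_restraints(restraints, template)
  ds <- restraints$datasets
  ss_full <- spin_system(template, exchangeable = TRUE)
  datasets <- list()
  for (i in seq_len(nrow(ds))) {
    id <- ds$dataset_id[i]
    ss <- spin_system(template, exchangeable = identical(ds$spins[i], "all"))
    rows <- which(restraints$noe$dataset_id == id)
    si <- vapply(restraints$noe$atom_i[rows], spin_of, 0L, ss = ss)
    sj <- vapply(restraints$noe$atom_j[rows], spin_of, 0L, ss = ss)
    if (any(is.na(si)) || any(is.na(sj)))
      stop("dataset ", id, ": restraint protons outside the observable spin pool")
    datasets[[id]] <- list(
      id = id, rows = rows, ss = ss,
      sel_full = match(ss$spins, ss_full$spins),
      pair_idx = cbind(si, sj),
      mixing_time = ds$mixing_time_s[i], field_mhz = ds$field_mhz[i],
      omega = 2 * pi * ds$field_mhz[i] * 1e6)
  }
  jq <- NULL; jks <- NULL
  if (nrow(restraints$j)) {
    idx <- template$plan$idx
    jq <- cbind(idx[restraints$j$atom1], idx[restraints$j$atom2],
                idx[restraints$j$atom3], idx[restraints$j$atom4]) - 1L
    jks <- lapply(seq_len(nrow(restraints$j)), function(r) {
      k <- restraints$karplus[restraints$karplus$id ==
                                restraints$j$karplus_id[r], ]
      as.list(k[1, ])
    })
  }
  rp <- NULL; rdc_pair_of <- NULL; rdc_media <- NULL
  if (nrow(restraints$rdc)) {
    idx <- template$plan$idx
    key <- paste(restraints$rdc$atom_c, restraints$rdc$atom_h)
    upairs <- !duplicated(key)
    rp <- cbind(idx[restraints$rdc$atom_c[upairs]],
                idx[restraints$rdc$atom_h[upairs]]) - 1L
    rdc_pair_of <- match(key, key[upairs])
    rdc_media <- unique(restraints$rdc$medium_id)
  }
  heavy <- template$plan$heavy
  empty_im <- function(k) matrix(integer(), 0, k)
  list(template = template, restraints = restraints, config = config,
       datasets = datasets,
       ss_full = ss_full,
       full_atom_idx0 = unlist(ss_full$atom_idx) - 1L,
       full_grp_idx0 = rep(seq_along(ss_full$spins), ss_full$mult) - 1L,
       j_quads0 = jq, j_ksets = jks,
       j_quads0m = if (is.null(jq)) empty_im(4) else jq,
       rdc_pairs0 = rp, rdc_pair_of = rdc_pair_of, rdc_media = rdc_media,
       rdc_pairs0m = if (is.null(rp)) empty_im(2) else rp,
       heavy0 = heavy - 1L,
       radii = unname(.vdw_radii[template$zmatrix$element[heavy]]))
}

# sample an ensemble from the model and run the fused forward kernel:
# relaxation pair sums, coupling dihedrals and RDC projections in one pass
forward_ensemble <- function(ctx, model, tau_c, seed, n = NULL) {
  ens <- sample_ensemble(model, ctx$template, n %||% ctx$config$n_ensemble,
                         seed, validate = FALSE)
  tg <- ensemble_trig(ctx$template, ens)
  plan <- ctx$template$plan
  fw <- forward_cpp(plan$parent, plan$aref, plan$dref, plan$lengths,
                    tg$cA, tg$sA, tg$cD, tg$sD,
                    ctx$full_atom_idx0, ctx$full_grp_idx0,
                    max(length(ctx$ss_full$spins), 1L),
                    ctx$j_quads0m, ctx$heavy0, ctx$radii, ctx$rdc_pairs0m,
                    r_floor = ctx$config$r6_floor)
  # (near-)coincident protons from a pathological proposal make the
  # relaxation rates blow up; the resulting chi-square is huge or
  # non-finite and the Metropolis step simply rejects the move
  noe <- rep(NA_real_, nrow(ctx$restraints$noe))
  r6 <- list()
  for (d in ctx$datasets) {
    A <- fw$A[d$sel_full, d$sel_full]
    r6[[d$id]] <- A
    H <- heights_from_A(A, d$ss$mult, tau_c, d$omega, d$mixing_time,
                        ctx$config$leak)
    noe[d$rows] <- H[d$pair_idx]
  }
  j <- numeric(0)
  if (!is.null(ctx$j_quads0))
    j <- vapply(seq_along(ctx$j_ksets), function(r)
      mean(karplus_j(fw$dih[, r], ctx$j_ksets[[r]])), 0)
  rdc_u <- if (!is.null(ctx$rdc_pairs0))
    fw$rdc_mean[ctx$rdc_pair_of] else numeric(0)
  list(noe = noe, j = j, rdc_u = rdc_u, r6 = r6)
}

# rate matrix + matrix exponential, minimal allocation path
heights_from_A <- function(A, mult, tau_c, omega, mixing_time, leak = 0) {
  jw <- function(w) 0.4 * tau_c / (1 + (w * tau_c)^2)
  sig_u <- .dipolar_constant / 10 * (6 * jw(2 * omega) - jw(0))
  rho_u <- .dipolar_constant / 10 * (jw(0) + 3 * jw(omega) + 6 * jw(2 * omega))
  R <- sig_u * A / mult
  off_sums <- rowSums(A) - diag(A)
  diag(R) <- (rho_u * (off_sums + diag(A)) + sig_u * diag(A)) / mult + leak
  s <- sqrt(mult)
  M <- sweep(sweep(R, 1, s, "*"), 2, s, "/")
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  E <- e$vectors %*% (exp(-e$values * mixing_time) * t(e$vectors))
  sweep(sweep(E, 1, s, "/"), 2, s, "*")
}

# closed-form least-squares nuisance scales given unit predictions
solve_scales <- function(ctx, pu) {
  noe <- ctx$restraints$noe
  noesy <- list()
  for (d in ctx$datasets) {
    rows <- d$rows
    u <- pu$noe[rows]; h <- noe$height[rows]; e <- noe$error[rows]
    den <- sum(u^2 / e^2)
    if (!is.finite(den) || den <= 0)
      stop("degenerate NOESY scale for dataset ", d$id,
           " (all-zero predictions)")
    noesy[[d$id]] <- sum(h * u / e^2) / den
  }
  rdc <- list()
  if (length(pu$rdc_u)) {
    r <- ctx$restraints$rdc
    for (m in ctx$rdc_media) {
      rows <- which(r$medium_id == m)
      u <- pu$rdc_u[rows]; obs <- r$observed_hz[rows]; e <- r$error_hz[rows]
      den <- sum(u^2 / e^2)
      if (!is.finite(den) || den <= 0) stop("degenerate RDC scale for medium ", m)
      s1 <- sum(obs * u / e^2) / den
      ee <- rdc_effective_error(e, max(abs(s1 * u)), ctx$config$rdc_f)
      rdc[[m]] <- sum(obs * u / ee^2) / sum(u^2 / ee^2)
    }
  }
  list(noesy = noesy, rdc = rdc)
}

# chi-square contributions given unit predictions and scales
context_chi2 <- function(ctx, pu, scales) {
  noe <- ctx$restraints$noe
  contrib_noe <- rep(NA_real_, nrow(noe))
  pred_noe <- rep(NA_real_, nrow(noe))
  for (d in ctx$datasets) {
    rows <- d$rows
    pred <- scales$noesy[[d$id]] * pu$noe[rows]
    pred_noe[rows] <- pred
    contrib_noe[rows] <- (pred - noe$height[rows])^2 / noe$error[rows]^2
  }
  jt <- ctx$restraints$j
  contrib_j <- if (nrow(jt)) (pu$j - jt$observed_hz)^2 / jt$error_hz^2 else numeric(0)
  rt <- ctx$restraints$rdc
  contrib_rdc <- numeric(0); pred_rdc <- numeric(0)
  if (nrow(rt)) {
    pred_rdc <- rep(NA_real_, nrow(rt))
    contrib_rdc <- rep(NA_real_, nrow(rt))
    for (m in ctx$rdc_media) {
      rows <- which(rt$medium_id == m)
      pred <- scales$rdc[[m]] * pu$rdc_u[rows]
      ee <- rdc_effective_error(rt$error_hz[rows], max(abs(pred)),
                                ctx$config$rdc_f)
      pred_rdc[rows] <- pred
      contrib_rdc[rows] <- (pred - rt$observed_hz[rows])^2 / ee^2
    }
  }
  groups <- c(if (nrow(noe)) paste(noe$dataset_id, noe$kind),
              if (nrow(jt)) rep("scalar couplings", nrow(jt)),
              if (nrow(rt)) paste("RDC", rt$medium_id))
  contrib <- c(contrib_noe, contrib_j, contrib_rdc)
  chi_square_report(contrib, groups,
                    predictions = list(noe = pred_noe, j = pu$j,
                                       rdc = pred_rdc))
}

#' Chi-square goodness of fit
#'
#' The fit statistic is the sum over restraints of squared
#' prediction-minus-experiment distances divided by squared estimated
#' errors; no-NOEs are scored against an experimental height of zero with
#' their noise-derived errors.  The report groups contributions per
#' dataset (NOE and no-NOE counted separately, scalar couplings together,
#' RDCs per medium).
#'
#' @param predictions list with elements `noe`, `j`, `rdc`: predicted
#'   values aligned with the rows of the corresponding restraint tables
#'   (already on the experimental scale).
#' @param restraints a [restraint_set()].
#' @return object of class `chi_square_report`: list with `total`, `n`,
#'   `per_dataset` (data frame `group`, `n`, `chi2`, `per_restraint`) and
#'   `contributions`.
#' @export
chi_square <- function(predictions, restraints) {
  noe <- restraints$noe; jt <- restraints$j; rt <- restraints$rdc
  if (nrow(noe) && length(predictions$noe) != nrow(noe))
    stop("missing NOE predictions for restraints: ",
         paste(which(is.na(predictions$noe[seq_len(nrow(noe))])), collapse = ","))
  contrib <- c(
    if (nrow(noe)) (predictions$noe - noe$height)^2 / noe$error^2,
    if (nrow(jt)) (predictions$j - jt$observed_hz)^2 / jt$error_hz^2,
    if (nrow(rt)) (predictions$rdc - rt$observed_hz)^2 / rt$error_hz^2)
  if (any(is.na(contrib))) stop("missing prediction(s)")
  groups <- c(if (nrow(noe)) paste(noe$dataset_id, noe$kind),
              if (nrow(jt)) rep("scalar couplings", nrow(jt)),
              if (nrow(rt)) paste("RDC", rt$medium_id))
  chi_square_report(contrib, groups, predictions)
}

chi_square_report <- function(contrib, groups, predictions = NULL) {
  per <- data.frame(group = unique(groups),
                    n = as.vector(table(groups)[unique(groups)]))
  per$chi2 <- vapply(per$group, function(g) sum(contrib[groups == g]), 0)
  per$per_restraint <- per$chi2 / per$n
  structure(list(total = sum(contrib), n = length(contrib),
                 per_dataset = per, contributions = contrib,
                 groups = groups, predictions = predictions),
            class = "chi_square_report")
}

#' @export
print.chi_square_report <- function(x, ...) {
  cat("Chi-square fit summary\n")
  cat(sprintf("  %-24s %5s %10s %14s\n", "Dataset", "n", "Total chi2",
              "chi2/restraint"))
  for (i in seq_len(nrow(x$per_dataset)))
    cat(sprintf("  %-24s %5d %10.1f %14.1f\n", x$per_dataset$group[i],
                x$per_dataset$n[i], x$per_dataset$chi2[i],
                x$per_dataset$per_restraint[i]))
  cat(sprintf("  %-24s %5d %10.1f %14.1f\n", "Total", x$n, x$total,
              x$total / max(x$n, 1)))
  invisible(x)
}

# one full stochastic evaluation: ensemble -> predictions -> scales -> chi2.
# `full = FALSE` skips assembling the grouped report (Monte-Carlo hot path).
eval_model <- function(ctx, model, tau_c, seed, full = TRUE, n = NULL) {
  pu <- forward_ensemble(ctx, model, tau_c, seed, n = n)
  scales <- solve_scales(ctx, pu)
  if (!full) {
    noe <- ctx$restraints$noe
    tot <- 0
    for (d in ctx$datasets) {
      rows <- d$rows
      pred <- scales$noesy[[d$id]] * pu$noe[rows]
      tot <- tot + sum((pred - noe$height[rows])^2 / noe$error[rows]^2)
    }
    jt <- ctx$restraints$j
    if (nrow(jt)) tot <- tot + sum((pu$j - jt$observed_hz)^2 / jt$error_hz^2)
    rt <- ctx$restraints$rdc
    if (nrow(rt)) for (m in ctx$rdc_media) {
      rows <- which(rt$medium_id == m)
      pred <- scales$rdc[[m]] * pu$rdc_u[rows]
      ee <- rdc_effective_error(rt$error_hz[rows], max(abs(pred)),
                                ctx$config$rdc_f)
      tot <- tot + sum((pred - rt$observed_hz[rows])^2 / ee^2)
    }
    return(list(chi2 = tot, scales = scales, pu = pu))
  }
  rep <- context_chi2(ctx, pu, scales)
  list(chi2 = rep$total, report = rep, scales = scales, pu = pu)
}

# refit tau_c by bounded 1-D minimisation of the NOESY chi-square over one
# set of ensemble-averaged r6 matrices (sampled fresh from the model, or
# reused from the caller's most recent evaluation)
refit_tau <- function(ctx, model, seed, r6 = NULL) {
  if (is.null(r6)) r6 <- forward_ensemble(ctx, model, 1e-9, seed)$r6
  noe <- ctx$restraints$noe
  obj <- function(lt) {
    tau <- 10^lt
    tot <- 0
    for (d in ctx$datasets) {
      H <- heights_from_A(r6[[d$id]], d$ss$mult, tau, d$omega,
                          d$mixing_time, ctx$config$leak)
      u <- H[d$pair_idx]
      h <- noe$height[d$rows]; e <- noe$error[d$rows]
      s <- sum(h * u / e^2) / sum(u^2 / e^2)
      tot <- tot + sum((s * u - h)^2 / e^2)
    }
    tot
  }
  br <- log10(ctx$config$tau_bracket)
  10^(stats::optimize(obj, br, tol = 1e-3)$minimum)
}

#' Solve nuisance parameters for a model
#'
#' The per-dataset NOESY intensity scale and per-medium RDC magnitude are
#' linear in the predictions and solved in closed form; the correlation
#' time tau_c is optimised by bounded one-dimensional minimisation of the
#' NOESY chi-square over the configured bracket.  Deterministic given the
#' seed.
#'
#' @param model a [dynamic_model()].
#' @param template the [molecule_template()].
#' @param restraints a [restraint_set()].
#' @param seed ensemble seed.
#' @param config a [fit_config()].
#' @return list with `tau_c` (s), `noesy_scales`, `rdc_scales`, `chi2`
#'   (a `chi_square_report`).
#' @export
solve_nuisances <- function(model, template, restraints, seed = 1,
                            config = fit_config()) {
  ctx <- make_fit_context(template, restraints, config)
  tau <- if (length(ctx$datasets)) refit_tau(ctx, model, seed) else 1e-9
  ev <- eval_model(ctx, model, tau, seed)
  list(tau_c = tau, noesy_scales = ev$scales$noesy,
       rdc_scales = ev$scales$rdc, chi2 = ev$report)
}

# ---------------------------------------------------------------------
# parameter bookkeeping for the Monte-Carlo moves

model_params <- function(model) {
  mu <- list(); sg <- list(); pi_groups <- list()
  for (bn in names(model$bonds)) {
    b <- model$bonds[[bn]]
    for (k in seq_along(b$macrostates)) {
      m <- b$macrostates[[k]]
      if (!m$fixed_mu) mu[[length(mu) + 1]] <- c(bond = bn, mode = k)
      sg[[length(sg) + 1]] <- c(bond = bn, mode = k)
    }
  }
  for (g in coupling_groups(model))
    if (g$n_modes > 1) pi_groups[[g$id]] <- g
  list(mu = mu, sigma = sg, pi_groups = pi_groups)
}

set_group_pi <- function(model, group_id, probs) {
  for (bn in names(model$bonds)) {
    b <- model$bonds[[bn]]
    id <- b$coupling %||% paste0(".solo_", bn)
    if (id == group_id)
      for (k in seq_along(b$macrostates))
        model$bonds[[bn]]$macrostates[[k]]$pi <- probs[k]
  }
  for (rn in names(model$rings)) {
    r <- model$rings[[rn]]
    id <- r$coupling %||% paste0(".solo_", rn)
    if (id == group_id) model$rings[[rn]]$probs <- probs
  }
  model
}

group_pi <- function(model, group_id) {
  for (g in coupling_groups(model)) if (g$id == group_id) return(g$probs)
  stop("no such coupling group: ", group_id)
}

#' Metropolis Monte-Carlo refinement of a dynamic model
#'
#' Minimises the restraint chi-square over the macrostate parameters by a
#' random-walk Metropolis chain: each step perturbs one parameter class
#' (a mean angle, a spread, or an occupancy-simplex move; means flagged
#' `fixed_mu` are never moved), evaluates the chi-square on a freshly
#' sampled microstate ensemble (nuisance scales re-solved in closed form)
#' and accepts with probability min(1, exp(-delta chi2 / T)).  tau_c is
#' refit periodically.  The best visited state is returned; the best-so-far
#' trace is non-increasing by construction.  Bitwise reproducible given
#' `seed`.
#'
#' @param model0 starting [dynamic_model()].
#' @param template the [molecule_template()].
#' @param restraints a [restraint_set()].
#' @param steps Monte-Carlo steps (default 10000).
#' @param seed integer seed.
#' @param config a [fit_config()].
#' @return an object of class `ensemble_fit` (see [multistart_fit()] for
#'   the fields and available methods).
#' @export
metropolis_fit <- function(model0, template, restraints, steps = 10000,
                           seed = 1, config = fit_config(),
                           polish_seeds = NULL) {
  stopifnot(steps >= 1)
  validate_dynamic_model(model0, template)
  ctx <- make_fit_context(template, restraints, config)
  set.seed(seed)
  crn_seed <- sample.int(.Machine$integer.max, 1)
  next_seed <- function() if (config$common_random) crn_seed else
    sample.int(.Machine$integer.max, 1)
  # evaluations reseed the global RNG (reproducible ensembles); the
  # proposal stream must not be disturbed by them
  keep_rng <- function(expr) {
    rs <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", rs, envir = .GlobalEnv))
    expr
  }

  temp_at <- function(step) {
    if (is.null(config$anneal)) return(config$temperature)
    config$anneal[1] * (config$anneal[2] / config$anneal[1])^((step - 1) /
                                                               max(steps - 1, 1))
  }

  cur <- model0
  tau <- if (length(ctx$datasets))
    keep_rng(refit_tau(ctx, cur, next_seed())) else 1e-9
  n_burn <- floor(config$burnin_fraction * steps)
  eval_n <- function(step) if (step <= n_burn) config$burnin_n else NULL
  ev <- keep_rng(eval_model(ctx, cur, tau, next_seed(), full = FALSE,
                            n = eval_n(1)))
  cur_chi2 <- ev$chi2
  cur_ev <- ev
  # best-visited state is tracked over full-size evaluations only
  best <- NULL
  top <- list()
  note_best <- function(chi2, ev) {
    if (is.null(best) || chi2 < best$chi2) {
      best <<- list(model = cur, tau = tau, chi2 = chi2, ev = ev)
      top <<- c(top, list(best))
      if (length(top) > 10) top <<- top[-1]
    }
  }
  if (n_burn == 0) note_best(cur_chi2, ev)
  trace_cur <- numeric(steps)
  trace_best <- numeric(steps)
  n_acc <- 0L

  pars <- model_params(cur)
  n_mu <- length(pars$mu); n_sg <- length(pars$sigma)
  n_pi <- length(pars$pi_groups)
  for (step in seq_len(steps)) {
    pick <- sample.int(n_mu + n_sg + n_pi, 1)
    prop <- cur
    if (pick <= n_mu) {
      p <- pars$mu[[pick]]
      k <- as.integer(p[["mode"]])
      m <- prop$bonds[[p[["bond"]]]]$macrostates[[k]]
      m$mu <- if (stats::runif(1) < config$jump_prob)
        stats::runif(1, -180, 180)  # basin-hopping jump (symmetric kernel)
      else wrap_angle(m$mu + stats::rnorm(1) * config$step_mu)
      prop$bonds[[p[["bond"]]]]$macrostates[[k]] <- m
    } else if (pick <= n_mu + n_sg) {
      p <- pars$sigma[[pick - n_mu]]
      k <- as.integer(p[["mode"]])
      m <- prop$bonds[[p[["bond"]]]]$macrostates[[k]]
      s <- m$sigma + stats::rnorm(1) * config$step_sigma
      lo <- config$sigma_range[1]; hi <- config$sigma_range[2]
      if (s < lo) s <- lo + (lo - s)
      if (s > hi) s <- hi - (s - hi)
      m$sigma <- min(max(s, lo), hi)
      prop$bonds[[p[["bond"]]]]$macrostates[[k]] <- m
    } else {
      gid <- names(pars$pi_groups)[pick - n_mu - n_sg]
      p <- group_pi(cur, gid)
      ij <- sample.int(length(p), 2)
      if (stats::runif(1) < 0.2) {
        # occupancy swap between two modes: the coordinated move that a
        # one-parameter random walk cannot make (mixture label exchange)
        p[ij] <- p[rev(ij)]
      } else {
        d <- stats::runif(1, 0, config$step_pi)
        d <- min(d, p[ij[1]])  # cannot go negative
        p[ij[1]] <- p[ij[1]] - d
        p[ij[2]] <- p[ij[2]] + d
      }
      prop <- set_group_pi(prop, gid, p)
    }
    u <- stats::runif(1)
    ev_p <- keep_rng(tryCatch(
      eval_model(ctx, prop, tau, next_seed(), full = FALSE, n = eval_n(step)),
      error = function(e) list(chi2 = Inf)))
    if (!is.finite(ev_p$chi2)) ev_p$chi2 <- Inf
    if (ev_p$chi2 <= cur_chi2 ||
        u < exp(-(ev_p$chi2 - cur_chi2) / temp_at(step))) {
      cur <- prop
      cur_chi2 <- ev_p$chi2
      cur_ev <- ev_p
      n_acc <- n_acc + 1L
      if (step > n_burn) note_best(cur_chi2, ev_p)
    }
    if (length(ctx$datasets) && step %% config$refit_tau_every == 0) {
      tau <- refit_tau(ctx, cur, next_seed(), r6 = cur_ev$pu$r6)
      ev_c <- keep_rng(eval_model(ctx, cur, tau, next_seed(), full = FALSE,
                                  n = eval_n(step)))
      cur_chi2 <- ev_c$chi2
      cur_ev <- ev_c
      if (step > n_burn) note_best(cur_chi2, ev_c)
    }
    if (step == n_burn && n_burn < steps) {
      # burn-in over: rebase the chain on a full-size evaluation
      ev_c <- keep_rng(eval_model(ctx, cur, tau, next_seed(), full = FALSE))
      cur_chi2 <- ev_c$chi2
      cur_ev <- ev_c
      note_best(cur_chi2, ev_c)
    }
    trace_cur[step] <- cur_chi2
    trace_best[step] <- if (step <= n_burn) NA_real_ else best$chi2
  }
  if (is.null(best)) note_best(cur_chi2, cur_ev)

  # Re-score the best visited states on replicate ensembles: a freshly
  # sampled ensemble per evaluation makes the chi-square a noisy estimate,
  # and taking the raw minimum over ~1e4 evaluations would reward lucky
  # draws rather than good models.  The replicates use ensembles five
  # times the working size because the expected chi-square of a finite
  # ensemble is inflated by the model's conformational variance over n --
  # comparing models at small n would systematically favour artificially
  # sharp ones.  The replicate seeds can be supplied by the caller so that
  # competing runs are compared on identical ensembles.
  if (config$final_polish && length(top) >= 1) {
    seeds <- polish_seeds %||% sample.int(.Machine$integer.max, 3)
    n_polish <- 5L * config$n_ensemble
    rescore <- vapply(top, function(st)
      mean(vapply(seeds, function(s)
        keep_rng(eval_model(ctx, st$model, st$tau, s, full = FALSE,
                            n = n_polish))$chi2,
        0)), 0)
    best <- top[[which.min(rescore)]]
    best$chi2 <- min(rescore)  # replicate-averaged fit quality
    best$chi2_polished <- min(rescore)
  }
  # final grouped report for the returned state
  best$ev <- eval_model(ctx, best$model, best$tau,
                        sample.int(.Machine$integer.max, 1), full = TRUE)

  structure(list(
    model = best$model, tau_c = best$tau,
    noesy_scales = best$ev$scales$noesy, rdc_scales = best$ev$scales$rdc,
    chi2 = best$ev$report, chi2_total = best$chi2,
    seed = seed, steps = steps,
    trace = data.frame(step = seq_len(steps), chi2 = trace_cur,
                       best = trace_best),
    accept_rate = n_acc / steps,
    config = config, template_name = template$name,
    restraints = restraints, template = template),
    class = "ensemble_fit")
}

#' Randomised starting model
#'
#' Keeps the structure of a model (modalities, coupling groups, fixed
#' rotamer locks, ring states) but randomises the free parameters: free
#' means uniform on the circle, spreads uniform in 5-30 degrees,
#' occupancies from a uniform simplex draw.
#'
#' @param model0 structural template [dynamic_model()].
#' @param seed integer seed.
#' @return a [dynamic_model()].
#' @export
random_start <- function(model0, seed) {
  set.seed(seed)
  m <- model0
  for (bn in names(m$bonds)) {
    b <- m$bonds[[bn]]
    for (k in seq_along(b$macrostates)) {
      if (!b$macrostates[[k]]$fixed_mu)
        b$macrostates[[k]]$mu <- stats::runif(1, -180, 180)
      b$macrostates[[k]]$sigma <- stats::runif(1, 5, 30)
    }
    m$bonds[[bn]] <- b
  }
  for (g in coupling_groups(m)) {
    if (g$n_modes > 1) {
      w <- -log(stats::runif(g$n_modes))
      m <- set_group_pi(m, g$id, w / sum(w))
    }
  }
  validate_dynamic_model(m)
  m
}

#' Multistart Metropolis refinement
#'
#' Runs independent seeded Metropolis chains from randomised starting
#' configurations, returns the lowest-chi-square run, and compares the
#' best fraction of runs (default the top 10 percent) to check that the
#' optimisation converged to one set of conformations: macrostate means
#' are compared by circular distance (after nearest-mode alignment) and
#' occupancies by absolute difference, against 10 degree / 0.1 tolerances.
#'
#' @inheritParams metropolis_fit
#' @param runs number of independent runs (default 96).
#' @param top_fraction fraction of best runs compared for convergence.
#' @param randomize_starts draw each run's start with [random_start()]
#'   (otherwise all runs start from `model0`).
#' @param progress print one line per completed run.
#' @return an object of class `ensemble_fit`: the best run's fit, with
#'   `runs_summary` (per-run chi-square and seed) and `convergence` (the
#'   comparison report) attached.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `plot`, `simulate`.
#' @export
multistart_fit <- function(model0, template, restraints, runs = 96,
                           steps = 10000, top_fraction = 0.10, seed = 1,
                           config = fit_config(), randomize_starts = TRUE,
                           progress = FALSE) {
  stopifnot(runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  # shared polish ensembles: run-to-run comparisons are paired
  polish_seeds <- sample.int(.Machine$integer.max, 3)
  fits <- vector("list", runs)
  for (r in seq_len(runs)) {
    start <- if (randomize_starts) random_start(model0, run_seeds[r]) else model0
    fits[[r]] <- metropolis_fit(start, template, restraints, steps = steps,
                                seed = run_seeds[r], config = config,
                                polish_seeds = polish_seeds)
    if (progress)
      cat(sprintf("run %2d/%d: chi2 = %.1f\n", r, runs,
                  fits[[r]]$chi2_total))
  }
  chi2s <- vapply(fits, `[[`, 0, "chi2_total")
  ord <- order(chi2s)
  n_top <- min(max(ceiling(top_fraction * runs), 1), runs)
  conv <- compare_runs(fits[ord[seq_len(n_top)]])
  best <- fits[[ord[1]]]
  best$runs_summary <- data.frame(run = seq_len(runs), seed = run_seeds,
                                  chi2 = chi2s)
  best$convergence <- conv
  best$multistart <- list(runs = runs, top_compared = n_top, seed = seed)
  best
}

# circular-distance comparison of the top runs' macrostate parameters
compare_runs <- function(fits, tol_mu = 10, tol_pi = 0.1) {
  ref <- fits[[1]]$model
  rows <- list()
  for (f in seq_along(fits)[-1]) {
    m <- fits[[f]]$model
    for (bn in names(ref$bonds)) {
      mu_ref <- vapply(ref$bonds[[bn]]$macrostates, `[[`, 0, "mu")
      pi_ref <- vapply(ref$bonds[[bn]]$macrostates, `[[`, 0, "pi")
      mu_f <- vapply(m$bonds[[bn]]$macrostates, `[[`, 0, "mu")
      pi_f <- vapply(m$bonds[[bn]]$macrostates, `[[`, 0, "pi")
      # align modes to the reference by nearest circular distance
      perm <- seq_along(mu_ref)
      if (length(mu_ref) > 1) {
        perms <- all_perms(length(mu_ref))
        cost <- vapply(perms, function(p) sum(circ_dist(mu_f[p], mu_ref)), 0)
        perm <- perms[[which.min(cost)]]
      }
      rows[[length(rows) + 1]] <- data.frame(
        run = f, bond = bn,
        max_dmu = max(circ_dist(mu_f[perm], mu_ref)),
        max_dpi = max(abs(pi_f[perm] - pi_ref)))
    }
  }
  if (!length(rows))
    return(list(converged = TRUE, n_compared = 1,
                detail = data.frame()))
  detail <- do.call(rbind, rows)
  detail$diverged <- detail$max_dmu > tol_mu | detail$max_dpi > tol_pi
  list(converged = !any(detail$diverged), n_compared = length(fits),
       tol_mu = tol_mu, tol_pi = tol_pi, detail = detail)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Fit a dynamic conformational ensemble to NMR restraints
#'
#' The top-level modelling interface: wraps [multistart_fit()] with the
#' standard defaults (96 randomised starts of 10000 Metropolis steps).
#'
#' @inheritParams multistart_fit
#' @param model starting/structural [dynamic_model()]; defaults to
#'   tri-modal free bonds via [initial_model()].
#' @return an `ensemble_fit` object.
#' @export
ensemble_fit <- function(restraints, template, model = initial_model(template),
                         runs = 96, steps = 10000, seed = 1,
                         config = fit_config(), ...) {
  multistart_fit(model, template, restraints, runs = runs, steps = steps,
                 seed = seed, config = config, ...)
}

#' Initial dynamic model for refinement
#'
#' Every rotatable bond starts with the requested modality (default
#' tri-modal with floating means and spreads, the usual first-round
#' configuration), equal occupancies, staggered-rotamer means; rings start
#' in their template default states.
#'
#' @param template a [molecule_template()].
#' @param modality macrostates per bond (1-3).
#' @return a [dynamic_model()].
#' @export
initial_model <- function(template, modality = 3) {
  bonds <- lapply(names(template$rotatable_bonds), function(tn)
    bond_model(tn, lapply(seq_len(modality), function(k)
      macrostate(1 / modality, c(60, 180, -60)[k], 15))))
  rings <- lapply(names(template$rings), function(rn)
    ring_model(rn, template$rings[[rn]]$default, 1))
  dynamic_model(bonds, rings, template)
}
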