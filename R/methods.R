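# S3 methods for fitted ensemble models.

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Dynamic ensemble fit (", x$template_name, ")\n", sep = "")
  cat(sprintf("  %d Metropolis steps, seed %d, acceptance %.2f, tau_c %.2f ns\n",
              x$steps, x$seed, x$accept_rate, x$tau_c * 1e9))
  if (!is.null(x$multistart))
    cat(sprintf("  best of %d runs (top %d compared: %s)\n",
                x$multistart$runs, x$multistart$top_compared,
                if (isTRUE(x$convergence$converged)) "converged" else "DIVERGED"))
  print(x$chi2)
  invisible(x)
}

#' Summarise a fitted dynamic ensemble
#'
#' Produces the per-bond macrostate table (mode, mean angle, libration
#' amplitude, occupancy), the enumerated whole-molecule macrostates and
#' the conformational-family populations on the given defining bonds.
#'
#' @param object an `ensemble_fit`.
#' @param defining_bonds torsions defining conformational families
#'   (default the R2-G3 linkage pair when present).
#' @param ... unused.
#' @export
summary.ensemble_fit <- function(object,
                                 defining_bonds = intersect(c("phi23", "psi23"),
                                                            names(object$model$bonds)),
                                 ...) {
  m <- object$model
  rows <- list()
  for (bn in names(m$bonds)) {
    for (k in seq_along(m$bonds[[bn]]$macrostates)) {
      ms <- m$bonds[[bn]]$macrostates[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        torsion = bn, mode = k, mean_angle = ms$mu,
        libration = ms$sigma, occupancy = ms$pi,
        fixed = ms$fixed_mu)
    }
  }
  tab <- do.call(rbind, rows)
  states <- enumerate_macrostates(m)
  fam <- if (length(defining_bonds))
    cluster_families(states, m, defining_bonds) else NULL
  out <- list(torsions = tab, n_macrostates = nrow(states$modes),
              families = fam, chi2 = object$chi2, tau_c = object$tau_c,
              noesy_scales = object$noesy_scales,
              rdc_scales = object$rdc_scales,
              convergence = object$convergence)
  class(out) <- "summary.ensemble_fit"
  out
}

#' @export
print.summary.ensemble_fit <- function(x, ...) {
  cat("Torsion angle conformational preferences\n")
  cat(sprintf("  %-9s %4s %11s %10s %10s\n", "Torsion", "Mode",
              "Mean angle", "Libration", "Occupancy"))
  for (i in seq_len(nrow(x$torsions)))
    cat(sprintf("  %-9s %4d %10.0f%s %9.0f%s %10.2f\n",
                x$torsions$torsion[i], x$torsions$mode[i],
                x$torsions$mean_angle[i],
                if (x$torsions$fixed[i]) "*" else " ",
                x$torsions$libration[i], "°",
                x$torsions$occupancy[i]))
  cat(sprintf("  (* mean locked at classic rotamer)\n"))
  cat(sprintf("%d whole-molecule macrostates\n", x$n_macrostates))
  if (!is.null(x$families)) {
    for (i in seq_len(nrow(x$families)))
      cat(sprintf("  Family %d: population %.2f (%d macrostates)\n",
                  x$families$family[i], x$families$population[i],
                  x$families$n_members[i]))
  }
  cat(sprintf("tau_c = %.2f ns\n", x$tau_c * 1e9))
  print(x$chi2)
  invisible(x)
}

#' @export
coef.ensemble_fit <- function(object, ...) {
  out <- c()
  for (bn in names(object$model$bonds)) {
    ms <- object$model$bonds[[bn]]$macrostates
    for (k in seq_along(ms)) {
      out[paste0(bn, ".mu", k)] <- ms[[k]]$mu
      out[paste0(bn, ".sigma", k)] <- ms[[k]]$sigma
      out[paste0(bn, ".pi", k)] <- ms[[k]]$pi
    }
  }
  out["tau_c_ns"] <- object$tau_c * 1e9
  for (d in names(object$noesy_scales))
    out[paste0("scale.", d)] <- object$noesy_scales[[d]]
  for (m in names(object$rdc_scales))
    out[paste0("scale.", m)] <- object$rdc_scales[[m]]
  out
}

#' Forward predictions from a fitted model
#'
#' Re-evaluates the forward models (NOESY relaxation matrix, Karplus
#' averages, shape-based RDCs) for the fitted dynamic model against a
#' restraint set, applying the fitted nuisance scales.
#'
#' @param object an `ensemble_fit`.
#' @param newdata a [restraint_set()] (defaults to the training set).
#' @param n ensemble size for the evaluation.
#' @param seed ensemble seed.
#' @param ... unused.
#' @return data frame with one row per restraint: `class`, `group`,
#'   `observed`, `predicted`, `error`, `chi2`.
#' @export
predict.ensemble_fit <- function(object, newdata = NULL, n = NULL,
                                 seed = 1, ...) {
  rs <- newdata %||% object$restraints
  cfg <- object$config
  if (!is.null(n)) cfg$n_ensemble <- n
  ctx <- make_fit_context(object$template, rs, cfg)
  ev <- eval_model(ctx, object$model, object$tau_c, seed)
  rep <- ev$report
  obs <- c(rs$noe$height, rs$j$observed_hz, rs$rdc$observed_hz)
  pred <- c(rep$predictions$noe, rep$predictions$j, rep$predictions$rdc)
  err <- c(rs$noe$error, rs$j$error_hz, rs$rdc$error_hz)
  cls <- c(rep("NOESY", nrow(rs$noe)), rep("J", nrow(rs$j)),
           rep("RDC", nrow(rs$rdc)))
  data.frame(class = cls, group = rep$groups, observed = obs,
             predicted = pred, error = err, chi2 = rep$contributions,
             stringsAsFactors = FALSE)
}

#' @export
fitted.ensemble_fit <- function(object, ...) {
  p <- predict(object, ...)
  p$predicted
}

#' @export
residuals.ensemble_fit <- function(object, type = c("normalized", "raw"), ...) {
  type <- match.arg(type)
  p <- predict(object, ...)
  r <- p$observed - p$predicted
  if (type == "normalized") r / p$error else r
}

#' Simulate microstate ensembles from a fitted model
#'
#' @param object an `ensemble_fit`.
#' @param nsim number of ensembles.
#' @param seed integer seed.
#' @param n microstates per ensemble.
#' @param ... unused.
#' @return list of `torsion_ensemble` objects (length `nsim`).
#' @export
simulate.ensemble_fit <- function(object, nsim = 1, seed = 1, n = 300, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    sample_ensemble(object$model, object$template, n = n, seed = s))
}

#' Diagnostic plots for a fitted ensemble
#'
#' Four base-graphics panels: the best-so-far chi-square trace, observed
#' versus predicted values per restraint class, normalised residuals, and
#' circular torsion histograms of a sampled ensemble for the multimodal
#' bonds.
#'
#' @param x an `ensemble_fit`.
#' @param which subset of panels (1-4).
#' @param ... unused.
#' @export
plot.ensemble_fit <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(length(which) > 2, 2) + c(1, 0),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(x$trace$step, x$trace$best, type = "l", log = "y",
                   xlab = "MC step", ylab = expression(chi^2),
                   main = "best-so-far chi-square")
    graphics::lines(x$trace$step, x$trace$chi2, col = "grey70")
  }
  p <- predict(x)
  if (2 %in% which) {
    graphics::plot(p$observed, p$predicted,
                   col = as.integer(factor(p$class)),
                   xlab = "observed", ylab = "predicted",
                   main = "observed vs predicted")
    graphics::abline(0, 1, lty = 2)
  }
  if (3 %in% which) {
    graphics::plot((p$observed - p$predicted) / p$error,
                   col = as.integer(factor(p$class)), xlab = "restraint",
                   ylab = "(obs - pred)/error", main = "residuals")
    graphics::abline(h = c(-1, 0, 1), lty = c(3, 2, 3))
  }
  if (4 %in% which) {
    ens <- sample_ensemble(x$model, x$template, 1000, seed = 1)
    multi <- names(x$model$bonds)[vapply(x$model$bonds, function(b)
      length(b$macrostates) > 1, TRUE)]
    bn <- if (length(multi)) multi[1] else names(x$model$bonds)[1]
    h <- torsion_histogram(ens$torsions[, bn])
    graphics::barplot(h$count, names.arg = h$center, las = 2,
                      main = paste("torsion histogram:", bn),
                      xlab = "angle (deg)", ylab = "count")
  }
  invisible(x)
}
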