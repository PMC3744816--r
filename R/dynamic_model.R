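#' Torsional macrostate models
#'
#' A dynamic model assigns to every rotatable bond of a template an ordered
#' set of one to three macrostates, each with an occupancy `pi`, a mean
#' torsion `mu` (degrees) and a libration spread `sigma` (degrees, the
#' circular standard deviation of a wrapped normal).  Rings carry
#' probabilistic canonical pucker states in the same way.  Bonds and rings
#' sharing a `coupling` group id select one joint macrostate index per
#' microstate draw (members may differ in `mu`/`sigma` per index but share
#' occupancies).
#'
#' @param pi occupancy in [0, 1].
#' @param mu mean torsion angle (degrees, any convention; wrapped).
#' @param sigma libration spread (degrees, >= 0).
#' @param fixed_mu lock the mean at a classic rotamer during fitting.
#' @return `macrostate` returns a macrostate record.
#' @export
macrostate <- function(pi, mu, sigma, fixed_mu = FALSE) {
  stopifnot(is.finite(pi), is.finite(mu), is.finite(sigma))
  if (pi < 0 || pi > 1) stop("macrostate occupancy must lie in [0, 1]")
  if (sigma < 0) stop("macrostate spread must be >= 0")
  list(pi = pi, mu = wrap_angle(mu), sigma = sigma, fixed_mu = isTRUE(fixed_mu))
}

#' @rdname macrostate
#' @param torsion rotatable-bond (torsion) name.
#' @param macrostates list of [macrostate()] records (1 to 3).
#' @param coupling optional coupling-group id.
#' @export
bond_model <- function(torsion, macrostates, coupling = NULL) {
  structure(list(torsion = torsion, macrostates = macrostates,
                 coupling = coupling), class = "bond_model")
}

#' @rdname macrostate
#' @param ring ring name.
#' @param states character vector of canonical pucker-state labels.
#' @param probs state probabilities (same length as `states`).
#' @export
ring_model <- function(ring, states, probs = rep(1 / length(states), length(states)),
                       coupling = NULL) {
  structure(list(ring = ring, states = states, probs = probs,
                 coupling = coupling), class = "ring_model")
}

#' @rdname macrostate
#' @param bonds list of [bond_model()]s, one per rotatable bond.
#' @param rings list of [ring_model()]s, one per ring.
#' @param template optional [molecule_template()] to validate coverage
#'   against.
#' @return `dynamic_model` returns an object of class `dynamic_model`.
#' @export
dynamic_model <- function(bonds, rings = list(), template = NULL) {
  names(bonds) <- vapply(bonds, `[[`, "", "torsion")
  names(rings) <- vapply(rings, `[[`, "", "ring")
  m <- structure(list(bonds = bonds, rings = rings), class = "dynamic_model")
  validate_dynamic_model(m, template)
  m
}

#' @rdname macrostate
#' @param model a `dynamic_model`.
#' @export
validate_dynamic_model <- function(model, template = NULL) {
  for (b in model$bonds) {
    k <- length(b$macrostates)
    if (k < 1 || k > 3)
      stop("bond ", b$torsion, ": between 1 and 3 macrostates required")
    p <- vapply(b$macrostates, `[[`, 0, "pi")
    if (abs(sum(p) - 1) > 1e-9)
      stop("bond ", b$torsion, ": macrostate probabilities sum to ",
           format(sum(p), digits = 12), ", not 1")
    if (any(vapply(b$macrostates, `[[`, 0, "sigma") < 0))
      stop("bond ", b$torsion, ": negative spread")
  }
  for (r in model$rings) {
    if (length(r$states) != length(r$probs))
      stop("ring ", r$ring, ": states/probs length mismatch")
    if (abs(sum(r$probs) - 1) > 1e-9)
      stop("ring ", r$ring, ": state probabilities do not sum to 1")
  }
  # coupled members must agree in mode count and occupancies
  groups <- coupling_groups(model)
  for (g in groups) {
    ps <- lapply(g$members, function(m) m$probs)
    ns <- lengths(ps)
    if (length(unique(ns)) != 1)
      stop("coupling group ", g$id, ": members differ in macrostate count")
    for (p in ps[-1]) if (max(abs(p - ps[[1]])) > 1e-9)
      stop("coupling group ", g$id, ": members differ in occupancies")
  }
  if (!is.null(template)) {
    want <- names(template$rotatable_bonds)
    have <- names(model$bonds)
    if (!setequal(want, have))
      stop("model bonds do not match template rotatable bonds; missing: ",
           paste(setdiff(want, have), collapse = ", "),
           "; extra: ", paste(setdiff(have, want), collapse = ", "))
    for (r in model$rings) {
      if (!(r$ring %in% names(template$rings)))
        stop("model ring ", r$ring, " not in template")
      bad <- setdiff(r$states, template$rings[[r$ring]]$states)
      if (length(bad))
        stop("ring ", r$ring, ": unknown pucker state(s) ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(model)
}

# Partition bonds and rings into joint-selection groups.  Uncoupled
# entities form singleton groups.  Each member is reduced to
# (name, kind, probs); order is model order, deterministic.
coupling_groups <- function(model) {
  ents <- c(
    lapply(model$bonds, function(b)
      list(name = b$torsion, kind = "bond", coupling = b$coupling,
           probs = vapply(b$macrostates, `[[`, 0, "pi"))),
    lapply(model$rings, function(r)
      list(name = r$ring, kind = "ring", coupling = r$coupling,
           probs = r$probs)))
  ids <- vapply(ents, function(e) e$coupling %||% paste0(".solo_", e$name), "")
  out <- list()
  for (id in unique(ids)) {
    members <- ents[ids == id]
    out[[id]] <- list(id = id, members = members,
                      probs = members[[1]]$probs,
                      n_modes = length(members[[1]]$probs))
  }
  out
}

#' Sample a microstate ensemble from a dynamic model
#'
#' Draws `n` whole-molecule torsion assignments: for each coupling group a
#' macrostate index is selected with its occupancy probabilities (jointly
#' for all group members), then each bond angle is drawn from a wrapped
#' normal with that macrostate's mean and spread.  Ring states follow the
#' group index directly; trivial rotors (methyls) are drawn uniformly.
#' Fully reproducible given `seed`.
#'
#' @param model a [dynamic_model()].
#' @param template the [molecule_template()] (supplies trivial rotors).
#' @param n ensemble size (default 300 microstates).
#' @param seed integer RNG seed.
#' @param validate re-validate the model before sampling (default TRUE;
#'   internal callers that maintain the invariants by construction skip
#'   it).
#' @return an object of class `torsion_ensemble`: list with `torsions`
#'   (n x bonds matrix, degrees), `puckers` (n x rings character matrix),
#'   `trivial` (n x rotors matrix) and `modes` (n x groups index matrix).
#' @export
sample_ensemble <- function(model, template, n = 300, seed = 1,
                            validate = TRUE) {
  stopifnot(n >= 1)
  if (validate) validate_dynamic_model(model, template)
  set.seed(seed)
  groups <- coupling_groups(model)
  modes <- matrix(0L, n, length(groups),
                  dimnames = list(NULL, names(groups)))
  for (gi in seq_along(groups)) {
    p <- groups[[gi]]$probs
    modes[, gi] <- if (length(p) == 1) 1L else
      sample.int(length(p), n, replace = TRUE, prob = p)
  }
  group_of <- function(nm, kind) {
    for (g in groups) for (m in g$members)
      if (m$name == nm && m$kind == kind) return(g$id)
    stop("entity not found: ", nm)
  }
  bonds <- names(model$bonds)
  torsions <- matrix(0, n, length(bonds), dimnames = list(NULL, bonds))
  for (bn in bonds) {
    b <- model$bonds[[bn]]
    k <- modes[, group_of(bn, "bond")]
    mu <- vapply(b$macrostates, `[[`, 0, "mu")[k]
    sg <- vapply(b$macrostates, `[[`, 0, "sigma")[k]
    torsions[, bn] <- wrap_angle(mu + stats::rnorm(n) * sg)
  }
  rings <- names(model$rings)
  puckers <- matrix("", n, length(rings), dimnames = list(NULL, rings))
  for (rn in rings) {
    r <- model$rings[[rn]]
    puckers[, rn] <- r$states[modes[, group_of(rn, "ring")]]
  }
  triv <- names(template$plan$trivial_rows)
  trivial <- matrix(stats::runif(n * length(triv), -180, 180), n, length(triv),
                    dimnames = list(NULL, triv))
  structure(list(torsions = torsions, puckers = puckers, trivial = trivial,
                 modes = modes, n = n),
            class = "torsion_ensemble")
}

#' Enumerate whole-molecule macrostates
#'
#' Forms the Cartesian product of macrostate indices over independent
#' coupling groups (trivial rotors are grouped away; unimodal groups
#' contribute a single state) with occupancy equal to the product of the
#' member probabilities.  Occupancies sum to 1.
#'
#' @param model a [dynamic_model()].
#' @param max_states guard against combinatorial explosion (default 1e6).
#' @return object of class `macrostate_set`: list with `modes` (states x
#'   groups index matrix), `occupancy`, `torsions` (states x bonds matrix of
#'   mode means) and `puckers`.
#' @export
enumerate_macrostates <- function(model, max_states = 1e6) {
  validate_dynamic_model(model)
  groups <- coupling_groups(model)
  sizes <- vapply(groups, `[[`, 0, "n_modes")
  if (prod(sizes) > max_states)
    stop("macrostate enumeration would produce ", prod(sizes),
         " states (limit ", max_states, ")")
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  colnames(grid) <- names(groups)
  occ <- apply(grid, 1, function(k)
    prod(vapply(seq_along(groups), function(gi) groups[[gi]]$probs[k[gi]], 0)))
  group_of <- stats::setNames(
    rep(names(groups), vapply(groups, function(g) length(g$members), 0)),
    unlist(lapply(groups, function(g) vapply(g$members, `[[`, "", "name"))))
  bonds <- names(model$bonds)
  torsions <- matrix(0, nrow(grid), length(bonds),
                     dimnames = list(NULL, bonds))
  for (bn in bonds) {
    mu <- vapply(model$bonds[[bn]]$macrostates, `[[`, 0, "mu")
    torsions[, bn] <- mu[grid[, group_of[[bn]]]]
  }
  rings <- names(model$rings)
  puckers <- matrix("", nrow(grid), length(rings),
                    dimnames = list(NULL, rings))
  for (rn in rings)
    puckers[, rn] <- model$rings[[rn]]$states[grid[, group_of[[rn]]]]
  structure(list(modes = grid, occupancy = occ, torsions = torsions,
                 puckers = puckers), class = "macrostate_set")
}

#' @export
print.macrostate_set <- function(x, ...) {
  cat("Macrostate set:", nrow(x$modes), "whole-molecule macrostates\n")
  cat("  occupancy range:", format(range(x$occupancy), digits = 3), "\n")
  invisible(x)
}

#' Cluster macrostates into conformational families
#'
#' Groups enumerated macrostates by their macrostate index on the coupling
#' groups covering the given defining bonds (e.g. the two glycosidic
#' torsions of a linkage); the family population is the summed occupancy of
#' its members.
#'
#' @param macrostates a `macrostate_set` from [enumerate_macrostates()].
#' @param model the generating [dynamic_model()].
#' @param defining_bonds character vector of torsion names.
#' @return data frame with columns `family`, `population`, `n_members`,
#'   plus a `members` attribute listing member state indices.
#' @export
cluster_families <- function(macrostates, model, defining_bonds) {
  if (length(defining_bonds) == 0) stop("defining_bonds must be non-empty")
  groups <- coupling_groups(model)
  covering <- unique(unlist(lapply(names(groups), function(id) {
    nm <- vapply(groups[[id]]$members, `[[`, "", "name")
    if (any(defining_bonds %in% nm)) id else NULL
  })))
  missing <- setdiff(defining_bonds,
                     unlist(lapply(groups, function(g)
                       vapply(g$members, `[[`, "", "name"))))
  if (length(missing))
    stop("defining bond(s) not in model: ", paste(missing, collapse = ", "))
  key <- apply(macrostates$modes[, covering, drop = FALSE], 1, paste,
               collapse = "/")
  fam <- sort(unique(key))
  pop <- vapply(fam, function(f) sum(macrostates$occupancy[key == f]), 0)
  ord <- order(-pop)
  out <- data.frame(family = seq_along(fam),
                    key = fam[ord], population = pop[ord],
                    n_members = as.vector(table(key)[fam][ord]))
  attr(out, "members") <- lapply(fam[ord], function(f) which(key == f))
  attr(out, "defining_groups") <- covering
  out
}

#' Read and write dynamic-model JSON
#'
#' Lossless round trip of the per-bond macrostate lists, coupling groups
#' and ring states.
#'
#' @param path file path.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path)
  bonds <- lapply(j$bonds, function(b)
    bond_model(b$torsion,
               lapply(b$macrostates, function(m)
                 macrostate(m$pi, m$mu, m$sigma, isTRUE(m$fixed_mu))),
               coupling = b$coupling))
  rings <- lapply(j$rings, function(r)
    ring_model(r$ring, unlist(r$states), unlist(r$probs), coupling = r$coupling))
  dynamic_model(bonds, rings)
}

#' @rdname read_model_json
#' @param model a [dynamic_model()].
#' @export
write_model_json <- function(model, path) {
  out <- list(
    bonds = unname(lapply(model$bonds, function(b)
      list(torsion = b$torsion, coupling = b$coupling,
           macrostates = lapply(b$macrostates, function(m)
             list(pi = m$pi, mu = m$mu, sigma = m$sigma,
                  fixed_mu = m$fixed_mu))))),
    rings = unname(lapply(model$rings, function(r)
      list(ring = r$ring, states = as.list(r$states),
           probs = as.list(r$probs), coupling = r$coupling))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat("Dynamic model:", length(x$bonds), "bonds,", length(x$rings), "rings\n")
  for (b in x$bonds) {
    parts <- vapply(b$macrostates, function(m)
      sprintf("pi=%.2f mu=%.0f sd=%.0f%s", m$pi, m$mu, m$sigma,
              if (m$fixed_mu) "*" else ""), "")
    cat(sprintf("  %-9s %s%s\n", b$torsion, paste(parts, collapse = " | "),
                if (!is.null(b$coupling)) paste0("  [", b$coupling, "]") else ""))
  }
  for (r in x$rings)
    cat(sprintf("  ring %-4s %s\n", r$ring,
                paste(sprintf("%s(%.2f)", r$states, r$probs), collapse = " ")))
  invisible(x)
}
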