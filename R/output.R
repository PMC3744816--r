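#' Emit a clash-trimmed microstate ensemble
#'
#' Samples microstates from the model and removes conformations bringing
#' non-bonded heavy atoms closer than `min_dist`, replacing each rejected
#' draw with a further draw from the same model until exactly `n`
#' acceptable conformers are collected.  Reproducible by seed.
#'
#' @param model a [dynamic_model()].
#' @param template the [molecule_template()].
#' @param n output ensemble size (default 250).
#' @param min_dist clash threshold (Angstrom); 0 disables trimming.
#' @param seed integer seed.
#' @param max_batches safety limit on resampling rounds.
#' @return list with `coords` (atoms x 3 x n array), `ensemble` (the
#'   accepted torsion assignments), `n_rejected`, `acceptance_rate`.
#' @export
emit_microstates <- function(model, template, n = 250,
                             min_dist = template$min_contact, seed = 1,
                             max_batches = 40) {
  set.seed(seed)
  batch_seeds <- sample.int(.Machine$integer.max, max_batches)
  heavy0 <- template$plan$heavy - 1L
  sep <- template$bond_sep[template$plan$heavy, template$plan$heavy]
  excl <- sep < 3
  kept_cubes <- list(); kept_tors <- list(); kept_puck <- list()
  kept_triv <- list()
  n_kept <- 0; n_drawn <- 0; n_rejected <- 0
  for (b in seq_len(max_batches)) {
    ens <- sample_ensemble(model, template, n, batch_seeds[b])
    cube <- ensemble_coords(template, ens)
    ok <- if (min_dist > 0)
      !clash_any_cpp(cube, heavy0, excl, min_dist) else rep(TRUE, n)
    n_drawn <- n_drawn + n
    n_rejected <- n_rejected + sum(!ok)
    take <- which(ok)[seq_len(min(sum(ok), n - n_kept))]
    if (length(take)) {
      kept_cubes[[b]] <- cube[, , take, drop = FALSE]
      kept_tors[[b]] <- ens$torsions[take, , drop = FALSE]
      kept_puck[[b]] <- ens$puckers[take, , drop = FALSE]
      kept_triv[[b]] <- ens$trivial[take, , drop = FALSE]
      n_kept <- n_kept + length(take)
    }
    if (n_kept >= n) break
    if (b >= 3 && (n_drawn - n_rejected) / n_drawn < 0.01)
      stop("microstate acceptance rate below 1%: review the model or ",
           "min_dist (", format(min_dist, digits = 3), " A)")
  }
  if (n_kept < n)
    stop("could not collect ", n, " clash-free microstates in ",
         max_batches, " batches")
  coords <- array(0, dim = c(nrow(template$zmatrix), 3, n),
                  dimnames = list(template$zmatrix$name, NULL, NULL))
  i <- 1
  for (b in seq_along(kept_cubes)) {
    if (is.null(kept_cubes[[b]])) next
    k <- dim(kept_cubes[[b]])[3]
    coords[, , i:(i + k - 1)] <- kept_cubes[[b]]
    i <- i + k
  }
  list(coords = coords,
       ensemble = list(torsions = do.call(rbind, kept_tors),
                       puckers = do.call(rbind, kept_puck),
                       trivial = do.call(rbind, kept_triv)),
       n_rejected = n_rejected,
       acceptance_rate = (n_drawn - n_rejected) / n_drawn)
}

#' Emit mean-state macrostate conformers
#'
#' One conformer per enumerated whole-molecule macrostate, built at the
#' mode mean angles with libration ignored and trivial rotors at their
#' staggered reference; occupancies attached.
#'
#' @param model a [dynamic_model()].
#' @param template the [molecule_template()].
#' @return list with `coords` (atoms x 3 x n_states), `occupancy`,
#'   `macrostates` (the [enumerate_macrostates()] result).
#' @export
emit_macrostates <- function(model, template) {
  states <- enumerate_macrostates(model)
  ens <- list(torsions = states$torsions, puckers = states$puckers,
              trivial = NULL)
  coords <- ensemble_coords(template, ens)
  dimnames(coords) <- list(template$zmatrix$name, NULL, NULL)
  list(coords = coords, occupancy = states$occupancy, macrostates = states)
}

#' Circular torsion histogram
#'
#' Bins angles at fixed intervals around the circle, bin k centred at
#' k * bin_width starting from 0 degrees at north and proceeding
#' clockwise; bin edges are half-open, [centre - w/2, centre + w/2).
#'
#' @param angles angles in degrees (any convention).
#' @param bin_width bin width in degrees; must divide 360.
#' @return data frame with `center` (degrees, 0 to 360 - w) and `count`;
#'   counts sum to `length(angles)`.
#' @export
torsion_histogram <- function(angles, bin_width = 15) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  a <- angles %% 360
  k <- floor(((a + bin_width / 2) %% 360) / bin_width)
  nb <- 360 / bin_width
  counts <- tabulate(k + 1, nbins = nb)
  data.frame(center = (seq_len(nb) - 1) * bin_width, count = counts)
}

#' Measure distances and angles over a conformer set
#'
#' @param coords atoms x 3 x n coordinate array (dimnames on atoms) or a
#'   single `cartesian_conformer`.
#' @param queries list of character vectors: length 2 = distance
#'   (Angstrom), length 3 = angle at the middle atom (degrees), length 4 =
#'   dihedral (degrees).
#' @return data frame with one row per query: `query`, `type`, `mean`
#'   (linear mean for distances/angles, circular mean for dihedrals),
#'   `sd`, `min`, `max`.
#' @export
measure_geometry <- function(coords, queries) {
  if (inherits(coords, "cartesian_conformer"))
    coords <- array(coords$xyz, dim = c(nrow(coords$xyz), 3, 1),
                    dimnames = list(rownames(coords$xyz), NULL, NULL))
  nm <- dimnames(coords)[[1]]
  rows <- lapply(queries, function(q) {
    miss <- setdiff(q, nm)
    if (length(miss)) stop("unknown atom(s): ", paste(miss, collapse = ", "))
    i <- match(q, nm)
    vals <- vapply(seq_len(dim(coords)[3]), function(c) {
      xyz <- coords[, , c]
      if (length(q) == 2) sqrt(sum((xyz[i[1], ] - xyz[i[2], ])^2))
      else if (length(q) == 3) vec_angle(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ])
      else dihedral_xyz(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
    }, 0)
    type <- c("distance", "distance", "angle", "dihedral")[length(q)]
    data.frame(query = paste(q, collapse = "-"), type = type,
               mean = if (type == "dihedral") circ_mean(vals) else mean(vals),
               sd = if (type == "dihedral") circ_sd(vals) else stats::sd(vals),
               min = min(vals), max = max(vals))
  })
  do.call(rbind, rows)
}

#' Write a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformer with populated element columns;
#' the occupancy column records per-model occupancies when supplied
#' (macrostate files), else 1.00.
#'
#' @param coords atoms x 3 x n array with atom names as dimnames.
#' @param template the [molecule_template()] (residues and elements).
#' @param path output file.
#' @param occupancy optional per-model occupancies.
#' @export
write_pdb_models <- function(coords, template, path, occupancy = NULL) {
  zm <- template$zmatrix
  res_id <- match(zm$residue, unique(zm$residue))
  con <- file(path, "w")
  on.exit(close(con))
  n_models <- dim(coords)[3]
  for (m in seq_len(n_models)) {
    occ <- if (is.null(occupancy)) 1 else occupancy[m]
    writeLines(sprintf("MODEL     %4d", m), con)
    for (a in seq_len(nrow(zm))) {
      atom <- sub("^[^_]*_", "", zm$name[a])
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a, substr(atom, 1, 4), substr(zm$residue[a], 1, 3), res_id[a],
        coords[a, 1, m], coords[a, 2, m], coords[a, 3, m], occ, 0,
        zm$element[a]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write the standard output bundle of a fit
#'
#' Emits `microstates.pdb` (clash-trimmed ensemble), `macrostates.pdb`
#' (mean states with occupancies), `families.json`, a 15-degree torsion
#' histogram TSV and optional geometry measurements.
#'
#' @param fit an `ensemble_fit`.
#' @param dir output directory.
#' @param n_microstates ensemble size (default 250).
#' @param seed seed for the output ensemble.
#' @param defining_bonds family-defining torsions.
#' @param queries optional geometry queries (see [measure_geometry()]).
#' @return the directory, invisibly.
#' @export
write_output_bundle <- function(fit, dir, n_microstates = 250, seed = 1,
                                defining_bonds = intersect(c("phi23", "psi23"),
                                                           names(fit$model$bonds)),
                                queries = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- fit$template
  micro <- emit_microstates(fit$model, tpl, n = n_microstates, seed = seed)
  write_pdb_models(micro$coords, tpl, file.path(dir, "microstates.pdb"))
  macro <- emit_macrostates(fit$model, tpl)
  write_pdb_models(macro$coords, tpl, file.path(dir, "macrostates.pdb"),
                   occupancy = macro$occupancy)
  if (length(defining_bonds)) {
    fam <- cluster_families(macro$macrostates, fit$model, defining_bonds)
    jsonlite::write_json(list(defining_bonds = defining_bonds,
                              families = fam),
                         file.path(dir, "families.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  hist_rows <- do.call(rbind, lapply(colnames(micro$ensemble$torsions),
                                     function(bn) {
    h <- torsion_histogram(micro$ensemble$torsions[, bn])
    data.frame(torsion = bn, h)
  }))
  utils::write.table(hist_rows, file.path(dir, "torsion_histograms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(queries)) {
    g <- measure_geometry(micro$coords, queries)
    utils::write.table(g, file.path(dir, "measurements.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
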