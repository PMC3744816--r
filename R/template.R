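#' Molecule templates
#'
#' A molecule template holds everything needed to build Cartesian conformers
#' of a molecule with fixed internal geometry: a z-matrix (construction
#' tree with bond lengths, bond angles and reference dihedrals), the named
#' rotatable bonds, ring definitions with pre-solved canonical pucker-state
#' geometries, NMR equivalence groups, prochiral swap pairs and clash
#' tolerances.  Conformers differ only in the dihedral assignments of
#' rotatable bonds, trivial rotors (e.g. methyls) and ring pucker states.
#'
#' The z-matrix is a data frame with one row per atom, in construction
#' order: `name`, `element`, `residue`, `parent`, `aref`, `dref` (atom
#' names; `NA` where a reference is not needed for the first rows),
#' `length` (Angstrom), `angle`, `dihedral` (degrees), `dih_type` (one of
#' `"root"`, `"fixed"`, `"torsion"`, `"trivial"`, `"ring"`) and `dih_key`
#' (the torsion/trivial-rotor name, or the ring id for ring rows).
#'
#' @param name template name.
#' @param zmatrix z-matrix data frame as described above.
#' @param rotatable_bonds named list; each entry the four atom names
#'   defining a named torsion.
#' @param rings named list; each entry a list with `atoms` (the cycle, in
#'   order), `states` (character vector of canonical pucker-state labels)
#'   and `geom` (per state, a data frame `name`/`angle`/`dihedral` giving
#'   the internal coordinates of the state-dependent z-matrix rows), plus
#'   `closure_length` for the ring-closing bond.
#' @param equivalence_groups named list of atom-name vectors (NMR-equivalent
#'   protons, e.g. a methyl group).
#' @param prochiral_pairs list of length-2 character vectors of swappable
#'   proton (or group) labels.
#' @param exchangeable character vector of exchangeable proton names
#'   (excluded from D2O spin systems).
#' @param min_contact default minimum allowed non-bonded heavy-atom
#'   distance in Angstrom.
#' @param tolerances list of reference spreads and checks:
#'   `length_spread` (Angstrom), `angle_spread`, `torsion_spread` (degrees),
#'   `ring_closure` (Angstrom).
#' @return an object of class `molecule_template`.
#' @export
molecule_template <- function(name, zmatrix, rotatable_bonds = list(),
                              rings = list(), equivalence_groups = list(),
                              prochiral_pairs = list(), exchangeable = character(),
                              min_contact = 2.4, tolerances = list()) {
  tol <- modifyList(list(length_spread = 0.015, angle_spread = 1.5,
                         torsion_spread = 10, ring_closure = 0.05), tolerances)
  tpl <- structure(list(name = name, zmatrix = zmatrix,
                        rotatable_bonds = rotatable_bonds, rings = rings,
                        equivalence_groups = equivalence_groups,
                        prochiral_pairs = prochiral_pairs,
                        exchangeable = exchangeable,
                        min_contact = min_contact, tolerances = tol),
                   class = "molecule_template")
  validate_template(tpl)
  tpl$plan <- build_template_plan(tpl)
  tpl$bonds <- template_bonds(tpl)
  tpl$bond_sep <- bond_separation(tpl)
  tpl
}

validate_template <- function(tpl) {
  zm <- tpl$zmatrix
  need <- c("name", "element", "residue", "parent", "aref", "dref",
            "length", "angle", "dihedral", "dih_type", "dih_key")
  if (!all(need %in% names(zm)))
    stop("z-matrix is missing columns: ", paste(setdiff(need, names(zm)), collapse = ", "))
  if (anyDuplicated(zm$name)) stop("duplicate atom names in z-matrix")
  idx <- stats::setNames(seq_len(nrow(zm)), zm$name)
  # construction order must be connected and acyclic: references point backwards
  for (k in seq_len(nrow(zm))) {
    refs <- c(zm$parent[k], if (k >= 3) zm$aref[k], if (k >= 4) zm$dref[k])
    refs <- refs[!is.na(refs)]
    if (k == 1 && length(refs) > 0) stop("root atom must have no references")
    bad <- refs[!(refs %in% zm$name[seq_len(max(k - 1, 0))])]
    if (length(bad))
      stop("z-matrix row ", k, " (", zm$name[k], ") references atoms not yet placed: ",
           paste(bad, collapse = ", "))
  }
  for (tn in names(tpl$rotatable_bonds)) {
    atoms <- tpl$rotatable_bonds[[tn]]
    if (length(atoms) != 4 || !all(atoms %in% zm$name))
      stop("rotatable bond ", tn, " references unknown atoms")
    if (!(tn %in% zm$dih_key[zm$dih_type == "torsion"]))
      stop("rotatable bond ", tn, " has no torsion row in the z-matrix")
  }
  for (rn in names(tpl$rings)) {
    ring <- tpl$rings[[rn]]
    if (!all(ring$atoms %in% zm$name)) stop("ring ", rn, " references unknown atoms")
    if (length(ring$atoms) < 3) stop("ring ", rn, " is not a cycle")
  }
  for (gn in names(tpl$equivalence_groups)) {
    g <- tpl$equivalence_groups[[gn]]
    if (!all(g %in% zm$name)) stop("equivalence group ", gn, " references unknown atoms")
  }
  if (!is.numeric(tpl$min_contact) || tpl$min_contact <= 0)
    stop("min_contact must be > 0")
  invisible(tpl)
}

# Precompute integer plan consumed by the compiled conformer builder.
build_template_plan <- function(tpl) {
  zm <- tpl$zmatrix
  idx <- stats::setNames(seq_len(nrow(zm)), zm$name)
  to0 <- function(x) ifelse(is.na(x), 0L, as.integer(idx[x]) - 1L)
  torsion_rows <- which(zm$dih_type == "torsion")
  trivial_rows <- which(zm$dih_type == "trivial")
  ring_rows <- lapply(tpl$rings, function(ring) {
    lapply(ring$geom, function(g) {
      r <- as.integer(idx[g$name])
      has_d <- !is.na(g$dihedral)
      list(rows = r, angle = g$angle,
           rows_d = r[has_d], dihedral = g$dihedral[has_d])
    })
  })
  list(parent = to0(zm$parent), aref = to0(zm$aref), dref = to0(zm$dref),
       lengths = zm$length, angles = zm$angle, dihedrals = zm$dihedral,
       torsion_rows = stats::setNames(torsion_rows, zm$dih_key[torsion_rows]),
       trivial_rows = stats::setNames(trivial_rows, zm$dih_key[trivial_rows]),
       ring_geom = ring_rows, idx = idx,
       heavy = which(zm$element != "H"),
       protons = which(zm$element == "H"))
}

# All covalent bonds: the z-matrix tree plus each ring-closing bond.
template_bonds <- function(tpl) {
  zm <- tpl$zmatrix
  idx <- tpl$plan$idx %||% stats::setNames(seq_len(nrow(zm)), zm$name)
  b <- cbind(seq_len(nrow(zm))[-1], idx[zm$parent[-1]])
  for (ring in tpl$rings) {
    k <- length(ring$atoms)
    pairs <- cbind(idx[ring$atoms], idx[ring$atoms[c(2:k, 1)]])
    tree <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    miss <- which(!(paste(pmin(pairs[, 1], pairs[, 2]),
                          pmax(pairs[, 1], pairs[, 2])) %in% tree))
    if (length(miss) != 1)
      stop("ring ", ring$id %||% "?", " does not close the construction tree once")
    b <- rbind(b, pairs[miss, , drop = FALSE])
  }
  unname(b)
}

# Matrix of graph (bond-count) separations between all atoms, via BFS.
bond_separation <- function(tpl) {
  n <- nrow(tpl$zmatrix)
  adj <- vector("list", n)
  for (r in seq_len(nrow(tpl$bonds))) {
    i <- tpl$bonds[r, 1]; j <- tpl$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  sep <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        queue <- c(queue, w)
      }
    }
    sep[s, ] <- d
  }
  sep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.molecule_template <- function(x, ...) {
  cat("Molecule template:", x$name, "\n")
  cat(" ", nrow(x$zmatrix), "atoms (",
      sum(x$zmatrix$element != "H"), "heavy ),",
      length(x$rotatable_bonds), "rotatable bonds,",
      length(x$rings), "rings\n")
  if (length(x$rotatable_bonds))
    cat("  torsions:", paste(names(x$rotatable_bonds), collapse = ", "), "\n")
  if (length(x$rings))
    cat("  rings:", paste(names(x$rings), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write molecule-template JSON
#'
#' Topology files are JSON documents carrying the atom table / z-matrix,
#' rotatable bonds, ring definitions with per-state geometry, equivalence
#' groups, prochiral pairs and tolerances.  The round trip is lossless.
#'
#' @param path file path.
#' @return `read_template_json` returns a `molecule_template`.
#' @export
read_template_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rings <- lapply(j$rings, function(r) {
    r$geom <- lapply(r$geom, as.data.frame)
    r
  })
  molecule_template(name = j$name, zmatrix = as.data.frame(j$zmatrix),
                    rotatable_bonds = lapply(j$rotatable_bonds, unlist),
                    rings = rings,
                    equivalence_groups = lapply(j$equivalence_groups, unlist),
                    prochiral_pairs = lapply(j$prochiral_pairs, unlist),
                    exchangeable = unlist(j$exchangeable) %||% character(),
                    min_contact = j$min_contact,
                    tolerances = j$tolerances)
}

#' @rdname read_template_json
#' @param template a `molecule_template`.
#' @export
write_template_json <- function(template, path) {
  out <- template[c("name", "zmatrix", "rotatable_bonds", "rings",
                    "equivalence_groups", "prochiral_pairs", "exchangeable",
                    "min_contact", "tolerances")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
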