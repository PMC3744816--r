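#' Restraint sets
#'
#' A restraint set bundles the three restraint classes used for dynamic
#' ensemble refinement, each as a data frame:
#' \describe{
#'   \item{noe}{`dataset_id`, `atom_i`, `atom_j` (atom or equivalence-group
#'     names), `height` (one-mole-equivalent peak height, arbitrary units),
#'     `error` (same units), `kind` (`"NOE"` or `"noNOE"`; no-NOEs have
#'     height 0 and a noise-derived error).}
#'   \item{j}{`atom1`..`atom4` (the H-C-C-H torsion path), `observed_hz`,
#'     `error_hz`, `karplus_id`.}
#'   \item{rdc}{`medium_id`, `atom_c`, `atom_h`, `observed_hz`, `error_hz`.}
#' }
#' plus `karplus` (coefficient sets `id`, `A`, `B`, `C` of
#' J = A cos^2 + B cos + C, optional substituent corrections) and
#' `datasets` (per-NOESY-dataset acquisition metadata: `dataset_id`,
#' `mixing_time_s`, `field_mhz`, `temperature_k`, `spins` -- which spin
#' pool is observable, `"nonexchangeable"` for D2O or `"all"` for H2O).
#'
#' @param noe,j,rdc,karplus,datasets data frames as described above (any
#'   may be empty).
#' @param template optional [molecule_template()]; when given, all atom and
#'   group references are validated against it.
#' @return an object of class `restraint_set`.
#' @export
restraint_set <- function(noe = empty_noe(), j = empty_j(), rdc = empty_rdc(),
                          karplus = empty_karplus(), datasets = empty_datasets(),
                          template = NULL) {
  rs <- structure(list(noe = noe, j = j, rdc = rdc, karplus = karplus,
                       datasets = datasets), class = "restraint_set")
  validate_restraints(rs, template)
  rs
}

empty_noe <- function() data.frame(dataset_id = character(), atom_i = character(),
                                   atom_j = character(), height = numeric(),
                                   error = numeric(), kind = character(),
                                   stringsAsFactors = FALSE)
empty_j <- function() data.frame(atom1 = character(), atom2 = character(),
                                 atom3 = character(), atom4 = character(),
                                 observed_hz = numeric(), error_hz = numeric(),
                                 karplus_id = character(), stringsAsFactors = FALSE)
empty_rdc <- function() data.frame(medium_id = character(), atom_c = character(),
                                   atom_h = character(), observed_hz = numeric(),
                                   error_hz = numeric(), stringsAsFactors = FALSE)
empty_karplus <- function() data.frame(id = character(), A = numeric(),
                                       B = numeric(), C = numeric(),
                                       corrections = character(),
                                       stringsAsFactors = FALSE)
empty_datasets <- function() data.frame(dataset_id = character(),
                                        mixing_time_s = numeric(),
                                        field_mhz = numeric(),
                                        temperature_k = numeric(),
                                        spins = character(),
                                        stringsAsFactors = FALSE)

validate_restraints <- function(rs, template = NULL, error_floor = 1e-6) {
  bad_line <- function(tbl, i, msg)
    stop(tbl, " line ", i, ": ", msg, call. = FALSE)
  for (i in seq_len(nrow(rs$noe))) {
    r <- rs$noe[i, ]
    if (!(r$kind %in% c("NOE", "noNOE"))) bad_line("noe", i, "kind must be NOE or noNOE")
    if (r$kind == "noNOE" && r$height != 0) bad_line("noe", i, "no-NOE height must be 0")
    if (!is.finite(r$error) || r$error < error_floor)
      bad_line("noe", i, "non-positive error")
    if (!(r$dataset_id %in% rs$datasets$dataset_id))
      bad_line("noe", i, paste("unknown dataset", r$dataset_id))
  }
  if (nrow(rs$j) && any(rs$j$error_hz <= 0)) {
    i <- which(rs$j$error_hz <= 0)[1]
    bad_line("j", i, "non-positive error")
  }
  if (nrow(rs$j)) {
    miss <- setdiff(rs$j$karplus_id, rs$karplus$id)
    if (length(miss))
      stop("j: unresolved karplus_id(s): ", paste(unique(miss), collapse = ", "))
  }
  if (nrow(rs$rdc) && any(rs$rdc$error_hz <= 0)) {
    i <- which(rs$rdc$error_hz <= 0)[1]
    bad_line("rdc", i, "non-positive error")
  }
  if (!is.null(template)) {
    known <- c(template$zmatrix$name, names(template$equivalence_groups))
    chk <- function(tbl, cols) {
      d <- rs[[tbl]]
      for (col in cols) {
        bad <- which(!(d[[col]] %in% known))
        if (length(bad))
          bad_line(tbl, bad[1], paste("unknown atom/group", d[[col]][bad[1]]))
      }
    }
    chk("noe", c("atom_i", "atom_j"))
    chk("j", paste0("atom", 1:4))
    chk("rdc", c("atom_c", "atom_h"))
  }
  invisible(rs)
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("Restraint set:\n")
  if (nrow(x$noe)) {
    tab <- table(x$noe$dataset_id, x$noe$kind)
    for (d in rownames(tab))
      cat(sprintf("  %-12s %3d NOE  %3d noNOE\n", d,
                  if ("NOE" %in% colnames(tab)) tab[d, "NOE"] else 0,
                  if ("noNOE" %in% colnames(tab)) tab[d, "noNOE"] else 0))
  }
  cat(sprintf("  %d scalar couplings, %d RDCs (%d media)\n", nrow(x$j),
              nrow(x$rdc), length(unique(x$rdc$medium_id))))
  invisible(x)
}

#' Multiplet scaling factors from coupling patterns
#'
#' Peak heights are rescaled to one-mole-proton equivalence at measurement
#' time: each fine-structure component of a multiplet is multiplied by the
#' reciprocal of its relative intensity.  The intensities follow from
#' convolving one 1:1 doublet per coupling (equal couplings merge
#' components), so one coupling gives a doublet with factors `c(2, 2)`, two
#' equal couplings a 1:2:1 triplet with factors `c(4, 2, 4)`, and two
#' unequal couplings a doublet-of-doublets with factors `c(4, 4, 4, 4)`.
#'
#' @param couplings numeric vector of coupling magnitudes (Hz); may be
#'   empty (a singlet).
#' @param tol couplings closer than this merge into one multiplet line.
#' @return numeric vector of per-component scaling factors, in increasing
#'   frequency-offset order.
#' @export
multiplet_scaling_factors <- function(couplings, tol = 1e-6) {
  if (any(couplings < 0)) stop("couplings must be >= 0")
  # positions (offsets) and weights, convolved coupling by coupling
  pos <- 0
  wt <- 1
  for (jc in couplings) {
    pos <- c(pos - jc / 2, pos + jc / 2)
    wt <- c(wt, wt) / 2
  }
  ord <- order(pos)
  pos <- pos[ord]; wt <- wt[ord]
  # merge coincident lines
  mpos <- numeric(); mwt <- numeric()
  for (i in seq_along(pos)) {
    if (length(mpos) && abs(pos[i] - mpos[length(mpos)]) < tol)
      mwt[length(mwt)] <- mwt[length(mwt)] + wt[i]
    else { mpos <- c(mpos, pos[i]); mwt <- c(mwt, wt[i]) }
  }
  1 / mwt
}

#' Default restraint error rules
#'
#' `noe_error` sets the error on a measured NOESY cross-peak at a fraction
#' (default 40 percent) of its height.  `nonoe_error` sets the error on an
#' absent cross-peak to a third of the maximum peak height the noise could
#' conceal, i.e. noise height times the proton's largest multiplet scaling
#' factor, divided by 3 (treating the noise as the top of the most intense
#' multiplet component within three standard deviations).
#'
#' @param height measured peak height (> 0).
#' @param fraction relative error (default 0.40).
#' @return error in the same units as the height.
#' @export
noe_error <- function(height, fraction = 0.40) {
  if (any(height <= 0)) stop("NOE height must be > 0")
  fraction * height
}

#' @rdname noe_error
#' @param noise_height spectral noise height (> 0).
#' @param max_scaling_factor the proton's largest multiplet scaling factor
#'   (>= 1).
#' @export
nonoe_error <- function(noise_height, max_scaling_factor = 1) {
  if (any(noise_height <= 0)) stop("noise height must be > 0")
  if (any(max_scaling_factor < 1)) stop("scaling factor must be >= 1")
  noise_height * max_scaling_factor / 3
}

#' Read and write restraint tables
#'
#' Restraints are stored as UTF-8 TSV files with a header row:
#' `noe.tsv`, `j.tsv`, `rdc.tsv`, `karplus.tsv` and `datasets.tsv` in one
#' directory, with the column schemas of [restraint_set()].  Missing files
#' yield empty tables.  `parse_restraints` validates against the template
#' and reports per-line diagnostics for unknown atoms or non-positive
#' errors.
#'
#' @param dir directory containing the TSV files.
#' @param template optional [molecule_template()] for reference validation.
#' @return a [restraint_set()].
#' @export
parse_restraints <- function(dir, template = NULL) {
  rd <- function(f, empty) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(empty)
    d <- utils::read.delim(p, stringsAsFactors = FALSE)
    need <- names(empty)
    miss <- setdiff(setdiff(need, "corrections"), names(d))
    if (length(miss))
      stop(f, ": missing column(s) ", paste(miss, collapse = ", "))
    if (nrow(d) == 0) empty else d
  }
  karplus <- rd("karplus.tsv", empty_karplus())
  if (is.null(karplus$corrections)) karplus$corrections <- ""
  karplus$corrections[is.na(karplus$corrections)] <- ""
  restraint_set(noe = rd("noe.tsv", empty_noe()),
                j = rd("j.tsv", empty_j()),
                rdc = rd("rdc.tsv", empty_rdc()),
                karplus = karplus,
                datasets = rd("datasets.tsv", empty_datasets()),
                template = template)
}

#' @rdname parse_restraints
#' @param restraints a [restraint_set()].
#' @export
write_restraints <- function(restraints, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(restraints$noe, "noe.tsv")
  wr(restraints$j, "j.tsv")
  wr(restraints$rdc, "rdc.tsv")
  wr(restraints$karplus, "karplus.tsv")
  wr(restraints$datasets, "datasets.tsv")
  invisible(dir)
}
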