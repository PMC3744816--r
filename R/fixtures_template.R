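# Fixture molecule templates.
#
# The flagship fixture is a streptomycin-like topology: streptidine (S1, an
# all-carbon cyclohexane carrying two guanidinium groups and four oxygens),
# streptose (R2, a furanose with a C3' gem-diol and a C-methyl) and
# N-methyl-glucosamine (G3, a pyranose with an N-methyl amine and a
# hydroxymethyl arm), joined by two glycosidic linkages.  Internal geometry
# is idealised (standard sugar/guanidinium fragment values); the nine named
# rotatable bonds, the three rings, the methyl equivalence groups and the
# prochiral pairs follow the real molecule's connectivity.  Hydroxyl
# protons are in fast exchange and are not modelled; N-H protons are
# present and flagged exchangeable.

.ensemblefit_cache <- new.env(parent = emptyenv())

# bond lengths / angles used throughout the fixtures (Angstrom / degrees)
.CC <- 1.53; .CO <- 1.42; .COg <- 1.41; .CN <- 1.47; .CNg <- 1.33
.CH <- 1.09; .NH <- 1.01; .TET <- 109.47; .SP2 <- 120; .COC <- 117

zr <- function(name, element, residue, parent = NA, aref = NA, dref = NA,
               length = 0, angle = 0, dihedral = 0, dih_type = "fixed",
               dih_key = NA_character_) {
  data.frame(name = name, element = element, residue = residue,
             parent = parent, aref = aref, dref = dref, length = length,
             angle = angle, dihedral = dihedral, dih_type = dih_type,
             dih_key = dih_key, stringsAsFactors = FALSE)
}

# place ring substituents on a solved ring fragment; `ang` widens the
# substituent-to-ring-bond angle beyond tetrahedral where sugar geometry
# calls for it
frag_with_subs <- function(xyz, atoms, subs) {
  rownames(xyz) <- atoms
  for (s in subs) {
    j <- match(s$at, atoms)
    dirs <- ring_sub_dirs(xyz[seq_along(atoms), , drop = FALSE], j,
                          sub_angle = s$ang %||% 109.47)
    d <- if (s$side == "up") dirs$up else dirs$down
    xyz <- rbind(xyz, matrix(xyz[s$at, ] + s$len * d, 1, 3,
                             dimnames = list(s$name, NULL)))
  }
  xyz
}

# label a solved 6-ring chair by which of two reference atoms sits above the
# plane of the remaining four
chair_label <- function(xyz, up_idx = 4, down_idx = 1) {
  others <- setdiff(1:6, c(up_idx, down_idx))
  ctr <- colMeans(xyz[others, ])
  n <- pracma_cross(xyz[others[2], ] - xyz[others[1], ],
                    xyz[others[4], ] - xyz[others[1], ])
  n <- n / sqrt(sum(n^2))
  h_up <- sum((xyz[up_idx, ] - ctr) * n)
  if (h_up > 0) "4C1" else "1C4"
}

# extract per-state geometry rows for one ring from its solved fragment
extract_geom <- function(frag, zm, row_names, angle_only) {
  out <- lapply(row_names, function(nm) {
    r <- zm[zm$name == nm, ]
    ic <- zrow_internals(frag, nm, r$parent,
                         if (is.na(r$aref)) r$parent else r$aref,
                         if (is.na(r$dref)) r$parent else r$dref)
    # the third z-matrix row uses only its angle; rows flagged angle-only
    # keep their dihedral driven by a named torsion
    dih <- if (nm %in% angle_only) NA_real_ else ic[["dihedral"]]
    data.frame(name = nm, length = ic[["length"]], angle = ic[["angle"]],
               dihedral = dih, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Streptomycin-like fixture topology
#'
#' Builds (and caches) the three-residue fixture template described above:
#' 75 atoms, nine rotatable bonds (phi12, psi12, phi23, psi23, chi1_S1,
#' chi3_S1, chi3_R2, chi2_G3, chi5_G3), two trivial methyl rotors, three
#' rings (two pyranose-type chairs, one furanose on an 18-degree
#' pseudorotation grid at amplitude 39 degrees), methyl and guanidinium-NH2
#' equivalence groups and prochiral swap pairs.
#'
#' @return a [molecule_template()].
#' @export
streptomycin_template <- function() {
  if (!is.null(.ensemblefit_cache$strep)) return(.ensemblefit_cache$strep)
  tpl <- build_strep_template()
  .ensemblefit_cache$strep <- tpl
  tpl
}

# Substituent face assignments (side of the local ring normal carrying the
# heavy substituent; the geminal H takes the other side).  Chosen so that
# the molecule is stereochemically sensible: streptamine-like S1 has all
# heavy substituents equatorial in its preferred chair, G3 is
# glucosamine-like (ring substituents equatorial, anomeric oxygen axial),
# and the anomeric faces reproduce the close-but-not-clashing inter-residue
# contacts of the parent molecule at the fitted mean conformations.
# widened substituent placement angles (degrees) at crowded centres
.strep_sub_angles <- list(R2_O3 = 116, R2_O2 = 114)

.strep_sides <- list(
  S1 = c(N1 = "down", O2 = "up", N3 = "down", O4 = "up", O5 = "down", O6 = "up"),
  R2 = c(S1_O4 = "down", C5 = "down", O3 = "up", C3p = "down", O2 = "up"),
  G3 = c(R2_O2 = "down", C6 = "down", O4 = "up", O3 = "down", N2 = "up"))

build_strep_template <- function(sides = .strep_sides, r2_phase_offset = 95,
                                 r2_phases = seq(0, 342, by = 18),
                                 sub_angles = .strep_sub_angles) {
  rows <- list(
    # --- S1 streptidine ring ------------------------------------------
    zr("S1_C1", "C", "S1"),
    zr("S1_C2", "C", "S1", "S1_C1", length = .CC),
    zr("S1_C3", "C", "S1", "S1_C2", "S1_C1", length = .CC, angle = 111,
       dih_type = "ring", dih_key = "S1"),
    zr("S1_C4", "C", "S1", "S1_C3", "S1_C2", "S1_C1", .CC, 111, 55,
       "ring", "S1"),
    zr("S1_C5", "C", "S1", "S1_C4", "S1_C3", "S1_C2", .CC, 111, -55,
       "ring", "S1"),
    zr("S1_C6", "C", "S1", "S1_C5", "S1_C4", "S1_C3", .CC, 111, 55,
       "ring", "S1"),
    # ring substituents (axial/equatorial pattern per chair state)
    zr("S1_N1", "N", "S1", "S1_C1", "S1_C2", "S1_C3", .CN, .TET, 60, "ring", "S1"),
    zr("S1_H1", "H", "S1", "S1_C1", "S1_C2", "S1_C3", .CH, .TET, -60, "ring", "S1"),
    zr("S1_O2", "O", "S1", "S1_C2", "S1_C3", "S1_C4", .CO, .TET, -60, "ring", "S1"),
    zr("S1_H2", "H", "S1", "S1_C2", "S1_C3", "S1_C4", .CH, .TET, 60, "ring", "S1"),
    zr("S1_N3", "N", "S1", "S1_C3", "S1_C4", "S1_C5", .CN, .TET, 60, "ring", "S1"),
    zr("S1_H3", "H", "S1", "S1_C3", "S1_C4", "S1_C5", .CH, .TET, -60, "ring", "S1"),
    zr("S1_O4", "O", "S1", "S1_C4", "S1_C5", "S1_C6", .CO, .TET, -60, "ring", "S1"),
    zr("S1_H4", "H", "S1", "S1_C4", "S1_C5", "S1_C6", .CH, .TET, 60, "ring", "S1"),
    zr("S1_O5", "O", "S1", "S1_C5", "S1_C6", "S1_C1", .CO, .TET, 60, "ring", "S1"),
    zr("S1_H5", "H", "S1", "S1_C5", "S1_C6", "S1_C1", .CH, .TET, -60, "ring", "S1"),
    zr("S1_O6", "O", "S1", "S1_C6", "S1_C1", "S1_C2", .CO, .TET, -60, "ring", "S1"),
    zr("S1_H6", "H", "S1", "S1_C6", "S1_C1", "S1_C2", .CH, .TET, 60, "ring", "S1"),
    # guanidinium at N1 (chi1_S1 rotates the whole group)
    zr("S1_C1p", "C", "S1", "S1_N1", "S1_C1", "S1_C6", .CNg, .SP2, 78,
       "torsion", "chi1_S1"),
    zr("S1_HN1", "H", "S1", "S1_N1", "S1_C1", "S1_C1p", .NH, .SP2, 180),
    zr("S1_N11", "N", "S1", "S1_C1p", "S1_N1", "S1_C1", .CNg, .SP2, 0),
    zr("S1_N12", "N", "S1", "S1_C1p", "S1_N1", "S1_N11", .CNg, .SP2, 180),
    zr("S1_HN111", "H", "S1", "S1_N11", "S1_C1p", "S1_N1", .NH, .SP2, 0),
    zr("S1_HN112", "H", "S1", "S1_N11", "S1_C1p", "S1_HN111", .NH, .SP2, 180),
    zr("S1_HN121", "H", "S1", "S1_N12", "S1_C1p", "S1_N1", .NH, .SP2, 0),
    zr("S1_HN122", "H", "S1", "S1_N12", "S1_C1p", "S1_HN121", .NH, .SP2, 180),
    # guanidinium at N3 (chi3_S1)
    zr("S1_C3p", "C", "S1", "S1_N3", "S1_C3", "S1_C2", .CNg, .SP2, 128,
       "torsion", "chi3_S1"),
    zr("S1_HN3", "H", "S1", "S1_N3", "S1_C3", "S1_C3p", .NH, .SP2, 180),
    zr("S1_N31", "N", "S1", "S1_C3p", "S1_N3", "S1_C3", .CNg, .SP2, 0),
    zr("S1_N32", "N", "S1", "S1_C3p", "S1_N3", "S1_N31", .CNg, .SP2, 180),
    zr("S1_HN311", "H", "S1", "S1_N31", "S1_C3p", "S1_N3", .NH, .SP2, 0),
    zr("S1_HN312", "H", "S1", "S1_N31", "S1_C3p", "S1_HN311", .NH, .SP2, 180),
    zr("S1_HN321", "H", "S1", "S1_N32", "S1_C3p", "S1_N3", .NH, .SP2, 0),
    zr("S1_HN322", "H", "S1", "S1_N32", "S1_C3p", "S1_HN321", .NH, .SP2, 180),
    # --- R2 streptose (furanose) --------------------------------------
    zr("R2_C1", "C", "R2", "S1_O4", "S1_C4", "S1_C3", .COg, .COC, -134,
       "torsion", "psi12"),
    zr("R2_O4", "O", "R2", "R2_C1", "S1_O4", "S1_C4", .CO, .TET, -75,
       "torsion", "phi12"),
    zr("R2_C4", "C", "R2", "R2_O4", "R2_C1", "S1_O4", .CO, 109, 120, "ring", "R2"),
    zr("R2_C3", "C", "R2", "R2_C4", "R2_O4", "R2_C1", .CC, 104, -20, "ring", "R2"),
    zr("R2_C2", "C", "R2", "R2_C3", "R2_C4", "R2_O4", .CC, 104, 30, "ring", "R2"),
    zr("R2_H1", "H", "R2", "R2_C1", "R2_O4", "R2_C4", .CH, .TET, 120, "ring", "R2"),
    zr("R2_O2", "O", "R2", "R2_C2", "R2_C3", "R2_C4", .COg, .TET, -120, "ring", "R2"),
    zr("R2_H2", "H", "R2", "R2_C2", "R2_C3", "R2_C4", .CH, .TET, 120, "ring", "R2"),
    zr("R2_O3", "O", "R2", "R2_C3", "R2_C4", "R2_O4", .CO, .TET, 120, "ring", "R2"),
    zr("R2_C3p", "C", "R2", "R2_C3", "R2_C4", "R2_O4", .CC, .TET, -120, "ring", "R2"),
    zr("R2_C5", "C", "R2", "R2_C4", "R2_O4", "R2_C1", .CC, .TET, -120, "ring", "R2"),
    zr("R2_H4", "H", "R2", "R2_C4", "R2_O4", "R2_C1", .CH, .TET, 120, "ring", "R2"),
    # gem-diol group (chi3_R2 rotates O31/O32/H3p together)
    zr("R2_O31", "O", "R2", "R2_C3p", "R2_C3", "R2_C2", .CO, .TET, 180,
       "torsion", "chi3_R2"),
    zr("R2_O32", "O", "R2", "R2_C3p", "R2_C3", "R2_O31", .CO, .TET, 120),
    zr("R2_H3p", "H", "R2", "R2_C3p", "R2_C3", "R2_O31", .CH, .TET, -120),
    # C-methyl (trivial rotor)
    zr("R2_H51", "H", "R2", "R2_C5", "R2_C4", "R2_C3", .CH, .TET, 60,
       "trivial", "me_R2"),
    zr("R2_H52", "H", "R2", "R2_C5", "R2_C4", "R2_H51", .CH, .TET, 120),
    zr("R2_H53", "H", "R2", "R2_C5", "R2_C4", "R2_H51", .CH, .TET, -120),
    # --- G3 N-methyl-glucosamine (pyranose) ---------------------------
    zr("G3_C1", "C", "G3", "R2_O2", "R2_C2", "R2_C1", .COg, .COC, -81,
       "torsion", "psi23"),
    zr("G3_O5", "O", "G3", "G3_C1", "R2_O2", "R2_C2", .CO, .TET, -103,
       "torsion", "phi23"),
    zr("G3_C5", "C", "G3", "G3_O5", "G3_C1", "R2_O2", .CO, 109, 120, "ring", "G3"),
    zr("G3_C4", "C", "G3", "G3_C5", "G3_O5", "G3_C1", .CC, 111, 55, "ring", "G3"),
    zr("G3_C3", "C", "G3", "G3_C4", "G3_C5", "G3_O5", .CC, 111, -55, "ring", "G3"),
    zr("G3_C2", "C", "G3", "G3_C3", "G3_C4", "G3_C5", .CC, 111, 55, "ring", "G3"),
    zr("G3_H1", "H", "G3", "G3_C1", "G3_O5", "G3_C5", .CH, .TET, 120, "ring", "G3"),
    zr("G3_N2", "N", "G3", "G3_C2", "G3_C3", "G3_C4", .CN, .TET, -120, "ring", "G3"),
    zr("G3_H2", "H", "G3", "G3_C2", "G3_C3", "G3_C4", .CH, .TET, 120, "ring", "G3"),
    zr("G3_O3", "O", "G3", "G3_C3", "G3_C4", "G3_C5", .CO, .TET, 120, "ring", "G3"),
    zr("G3_H3", "H", "G3", "G3_C3", "G3_C4", "G3_C5", .CH, .TET, -120, "ring", "G3"),
    zr("G3_O4", "O", "G3", "G3_C4", "G3_C5", "G3_O5", .CO, .TET, -120, "ring", "G3"),
    zr("G3_H4", "H", "G3", "G3_C4", "G3_C5", "G3_O5", .CH, .TET, 120, "ring", "G3"),
    zr("G3_C6", "C", "G3", "G3_C5", "G3_O5", "G3_C1", .CC, .TET, 120, "ring", "G3"),
    zr("G3_H5", "H", "G3", "G3_C5", "G3_O5", "G3_C1", .CH, .TET, -120, "ring", "G3"),
    # N-methyl amine (chi2_G3)
    zr("G3_C2p", "C", "G3", "G3_N2", "G3_C2", "G3_C1", .CN, .TET, -103,
       "torsion", "chi2_G3"),
    zr("G3_HN2", "H", "G3", "G3_N2", "G3_C2", "G3_C2p", .NH, .TET, 120),
    zr("G3_H2p1", "H", "G3", "G3_C2p", "G3_N2", "G3_C2", .CH, .TET, 60,
       "trivial", "me_G3"),
    zr("G3_H2p2", "H", "G3", "G3_C2p", "G3_N2", "G3_H2p1", .CH, .TET, 120),
    zr("G3_H2p3", "H", "G3", "G3_C2p", "G3_N2", "G3_H2p1", .CH, .TET, -120),
    # hydroxymethyl arm (chi5_G3)
    zr("G3_O6", "O", "G3", "G3_C6", "G3_C5", "G3_C4", .CO, 112, -45,
       "torsion", "chi5_G3"),
    zr("G3_H61", "H", "G3", "G3_C6", "G3_C5", "G3_O6", .CH, .TET, 120),
    zr("G3_H62", "H", "G3", "G3_C6", "G3_C5", "G3_O6", .CH, .TET, -120)
  )
  zm <- do.call(rbind, rows)

  # ---- solve ring pucker-state geometries ----------------------------
  flip <- function(s) if (s == "up") "down" else "up"
  pair_subs <- function(at, heavy, hyd, hlen, side)
    list(list(at = at, name = heavy, len = hlen, side = side,
              ang = sub_angles[[heavy]]),
         list(at = at, name = hyd, len = .CH, side = flip(side)))

  s1_atoms <- paste0("S1_C", 1:6)
  ss <- sides$S1
  s1_subs <- c(
    pair_subs("S1_C1", "S1_N1", "S1_H1", .CN, ss[["N1"]]),
    pair_subs("S1_C2", "S1_O2", "S1_H2", .CO, ss[["O2"]]),
    pair_subs("S1_C3", "S1_N3", "S1_H3", .CN, ss[["N3"]]),
    pair_subs("S1_C4", "S1_O4", "S1_H4", .CO, ss[["O4"]]),
    pair_subs("S1_C5", "S1_O5", "S1_H5", .CO, ss[["O5"]]),
    pair_subs("S1_C6", "S1_O6", "S1_H6", .CO, ss[["O6"]]))
  s1_rows <- zm$name[zm$dih_key %in% "S1"]
  s1_geom <- list()
  for (w in c("A", "B")) {
    frag <- solve_ring_fragment(rep(.CC, 6), rep(111, 6), chair_torsions(w),
                                angle_weight = 3, torsion_weight = 0.3,
                                init_z = 0.25 * rep(c(1, -1), 3) * (if (w == "A") 1 else -1))
    lab <- chair_label(frag, up_idx = 4, down_idx = 1)
    frag <- frag_with_subs(frag, s1_atoms, s1_subs)
    s1_geom[[lab]] <- extract_geom(frag, zm, s1_rows, angle_only = character())
  }

  g3_atoms <- c("G3_C1", "G3_O5", "G3_C5", "G3_C4", "G3_C3", "G3_C2")
  gs <- sides$G3
  g3_subs <- c(
    pair_subs("G3_C1", "R2_O2", "G3_H1", .COg, gs[["R2_O2"]]),
    pair_subs("G3_C5", "G3_C6", "G3_H5", .CC, gs[["C6"]]),
    pair_subs("G3_C4", "G3_O4", "G3_H4", .CO, gs[["O4"]]),
    pair_subs("G3_C3", "G3_O3", "G3_H3", .CO, gs[["O3"]]),
    pair_subs("G3_C2", "G3_N2", "G3_H2", .CN, gs[["N2"]]))
  g3_lengths <- c(.CO, .CO, .CC, .CC, .CC, .CC)
  g3_angles <- c(111, 109, 111, 111, 111, 111)
  g3_rows <- zm$name[zm$dih_key %in% "G3"]
  g3_geom <- list()
  for (w in c("A", "B")) {
    frag <- solve_ring_fragment(g3_lengths, g3_angles, chair_torsions(w),
                                angle_weight = 3, torsion_weight = 0.3,
                                init_z = 0.25 * rep(c(1, -1), 3) * (if (w == "A") 1 else -1))
    lab <- chair_label(frag, up_idx = 4, down_idx = 1)
    frag <- frag_with_subs(frag, g3_atoms, g3_subs)
    g3_geom[[lab]] <- extract_geom(frag, zm, g3_rows, angle_only = "G3_O5")
  }

  r2_atoms <- c("R2_C1", "R2_O4", "R2_C4", "R2_C3", "R2_C2")
  rs <- sides$R2
  r2_subs <- c(
    pair_subs("R2_C1", "S1_O4", "R2_H1", .COg, rs[["S1_O4"]]),
    pair_subs("R2_C4", "R2_C5", "R2_H4", .CC, rs[["C5"]]),
    pair_subs("R2_C2", "R2_O2", "R2_H2", .COg, rs[["O2"]]),
    list(list(at = "R2_C3", name = "R2_O3", len = .CO, side = rs[["O3"]],
              ang = sub_angles[["R2_O3"]]),
         list(at = "R2_C3", name = "R2_C3p", len = .CC, side = rs[["C3p"]],
              ang = sub_angles[["R2_C3p"]])))
  r2_lengths <- c(.CO, .CO, .CC, .CC, .CC)
  r2_angles <- c(106, 109, 104, 102, 104)
  r2_rows <- zm$name[zm$dih_key %in% "R2"]
  r2_geom <- list()
  for (P in r2_phases) {
    tt <- furanose_torsions(P + r2_phase_offset, tau_m = 39)
    init_z <- 0.35 * sqrt(2 / 5) *
      cos((P + r2_phase_offset + 144 * (0:4) + 72) * pi / 180)
    frag <- solve_ring_fragment(r2_lengths, r2_angles, tt,
                                angle_weight = 0.5, torsion_weight = 3,
                                init_z = init_z)
    frag <- frag_with_subs(frag, r2_atoms, r2_subs)
    r2_geom[[sprintf("P%03d", P)]] <-
      extract_geom(frag, zm, r2_rows, angle_only = "R2_O4")
  }

  rings <- list(
    S1 = list(atoms = s1_atoms, closure_length = .CC,
              states = names(s1_geom), geom = s1_geom, default = "1C4"),
    R2 = list(atoms = r2_atoms, closure_length = .CC,
              states = names(r2_geom), geom = r2_geom, default = "P144"),
    G3 = list(atoms = g3_atoms, closure_length = .CC,
              states = names(g3_geom), geom = g3_geom, default = "4C1"))

  # patch default-state values into the base z-matrix
  for (rn in names(rings)) {
    g <- rings[[rn]]$geom[[rings[[rn]]$default]]
    for (i in seq_len(nrow(g))) {
      k <- match(g$name[i], zm$name)
      zm$angle[k] <- g$angle[i]
      if (!is.na(g$dihedral[i])) zm$dihedral[k] <- g$dihedral[i]
    }
  }

  rot <- list(
    phi12 = c("R2_O4", "R2_C1", "S1_O4", "S1_C4"),
    psi12 = c("R2_C1", "S1_O4", "S1_C4", "S1_C3"),
    phi23 = c("G3_O5", "G3_C1", "R2_O2", "R2_C2"),
    psi23 = c("G3_C1", "R2_O2", "R2_C2", "R2_C1"),
    chi1_S1 = c("S1_C6", "S1_C1", "S1_N1", "S1_C1p"),
    chi3_S1 = c("S1_C2", "S1_C3", "S1_N3", "S1_C3p"),
    chi3_R2 = c("R2_C2", "R2_C3", "R2_C3p", "R2_O31"),
    chi2_G3 = c("G3_C1", "G3_C2", "G3_N2", "G3_C2p"),
    chi5_G3 = c("G3_C4", "G3_C5", "G3_C6", "G3_O6"))

  eq <- list(
    Me_R2 = c("R2_H51", "R2_H52", "R2_H53"),
    Me_G3 = c("G3_H2p1", "G3_H2p2", "G3_H2p3"),
    HN11 = c("S1_HN111", "S1_HN112"),
    HN12 = c("S1_HN121", "S1_HN122"),
    HN31 = c("S1_HN311", "S1_HN312"),
    HN32 = c("S1_HN321", "S1_HN322"))

  exch <- c("S1_HN1", "S1_HN3", "G3_HN2",
            unlist(eq[c("HN11", "HN12", "HN31", "HN32")], use.names = FALSE))

  molecule_template(
    name = "streptomycin_like_synthetic",
    zmatrix = zm, rotatable_bonds = rot, rings = rings,
    equivalence_groups = eq,
    prochiral_pairs = list(c("G3_H61", "G3_H62"),
                           c("HN11", "HN12"), c("HN31", "HN32")),
    exchangeable = exch, min_contact = 2.4)
}

#' Toy templates for tests and examples
#'
#' `toy_chain_template` is a linear carbon chain with one named torsion per
#' rotatable bond (`t1`, `t2`, ...).  `toy_probe_template` is a minimal
#' H-C-C fragment carrying four protons around one rotatable bond, useful
#' for exercising the forward models and the fitting machinery quickly.
#'
#' @param n number of chain atoms (>= 4).
#' @return a [molecule_template()].
#' @export
toy_chain_template <- function(n = 4) {
  stopifnot(n >= 4)
  rows <- list(zr("C1", "C", "X"),
               zr("C2", "C", "X", "C1", length = .CC),
               zr("C3", "C", "X", "C2", "C1", length = .CC, angle = .TET))
  rot <- list()
  for (k in 4:n) {
    tn <- paste0("t", k - 3)
    rows[[k]] <- zr(paste0("C", k), "C", "X", paste0("C", k - 1),
                    paste0("C", k - 2), paste0("C", k - 3), .CC, .TET, 180,
                    "torsion", tn)
    rot[[tn]] <- paste0("C", (k - 3):k)
  }
  molecule_template(name = paste0("toy_chain_", n),
                    zmatrix = do.call(rbind, rows), rotatable_bonds = rot)
}

#' @rdname toy_chain_template
#' @export
toy_probe_template <- function() {
  rows <- list(
    zr("C1", "C", "X"),
    zr("C2", "C", "X", "C1", length = .CC),
    zr("H1", "H", "X", "C1", "C2", length = .CH, angle = .TET),
    zr("H2", "H", "X", "C2", "C1", "H1", .CH, .TET, 180, "torsion", "t1"),
    zr("H3", "H", "X", "C2", "C1", "H2", .CH, .TET, 120),
    zr("C3", "C", "X", "C2", "C1", "H2", .CC, .TET, -120),
    zr("H4", "H", "X", "C3", "C2", "C1", .CH, .TET, 180))
  molecule_template(name = "toy_probe",
                    zmatrix = do.call(rbind, rows),
                    rotatable_bonds = list(t1 = c("H1", "C1", "C2", "H2")),
                    prochiral_pairs = list(c("H2", "H3")))
}
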