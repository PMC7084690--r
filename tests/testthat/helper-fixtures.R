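# in-code fixtures shared across test files

# shift table with CA (+CB) rows at exactly the random-coil values, so all
# secondary shifts are zero unless perturbed
coil_table <- function(seq1 = "ADGT", start = 1) {
  rc <- random_coil_table()
  aa <- strsplit(seq1, "")[[1]]
  rows <- lapply(seq_along(aa), function(i) {
    r <- rc[rc$residue_type == aa[i], ]
    if (aa[i] == "G")
      data.frame(residue_index = start + i - 1, residue_type = aa[i],
                 atom = "CA", shift_ppm = r$CA)
    else
      data.frame(residue_index = rep(start + i - 1, 2),
                 residue_type = aa[i], atom = c("CA", "CB"),
                 shift_ppm = c(r$CA, r$CB))
  })
  df <- do.call(rbind, rows)
  shift_table(df$residue_index, df$residue_type, df$atom, df$shift_ppm)
}

# amide-only table for CSP tests
amide_table <- function(res, h, n, type = "A") {
  shift_table(rep(res, each = 2), type,
              rep(c("H", "N"), length(res)), as.numeric(rbind(h, n)))
}

# minimal one-residue PDB file; returns the path
write_mini_pdb <- function(path, cryst1 = NULL) {
  lines <- c(
    cryst1,
    sprintf(paste0("ATOM  %5d  %-3s %3s %s%4d    ",
                   "%8.3f%8.3f%8.3f%6.2f%6.2f          %2s"),
            1:3, c("N", "CA", "C"), "ALA", "A", 1,
            c(0, 1.4, 2.4), c(0, 0.5, 1.0), 0, 1, 10, c("N", "C", "C")),
    "END")
  writeLines(lines, path)
  path
}

write_mini_cif <- function(path, with_cell = TRUE) {
  cif <- c(
    "data_mini",
    if (with_cell) c(
      "_cell.length_a 48.300", "_cell.length_b 48.300",
      "_cell.length_c 60.400", "_cell.angle_alpha 90.00",
      "_cell.angle_beta 90.00", "_cell.angle_gamma 120.00",
      "_symmetry.space_group_name_H-M \"P 31 2 1\""),
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    paste("ATOM", 1:3, c("N", "C", "C"), c("N", "CA", "C"), ". ALA A 1",
          1, "?", c(0, 1.4, 2.4), c(0, 0.5, 1.0),
          "0.000 1.00 10.00 ?", 1, "ALA A", c("N", "CA", "C"), 1))
  writeLines(cif, path)
  path
}

parse_identity <- function() list(R = diag(3), t = c(0, 0, 0))

# rigidly move a structure model (rotation about z by theta + translation)
move_model <- function(model, theta = 0, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  model$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, shift, `+`)
  model
}
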