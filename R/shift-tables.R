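#' Per-residue backbone chemical-shift table
#'
#' A `shift_table` holds assigned backbone chemical shifts for one protein
#' state: one row per (residue, atom) with the shift in ppm. It is the
#' substrate of the secondary-shift index ([secondary_shifts()]) and of
#' chemical-shift-perturbation mapping ([csp()]).
#'
#' @param residue_index integer vector of (positive) residue numbers.
#' @param residue_type one-letter amino-acid codes.
#' @param atom atom names, each one of `"H"`, `"N"`, `"CA"`, `"CB"`.
#' @param shift_ppm chemical shifts in ppm.
#'
#' @return A data frame of class `shift_table` with columns
#'   `residue_index`, `residue_type`, `atom`, `shift_ppm`.
#'
#' @details Invariants enforced: residue indices strictly positive; at most
#'   one entry per (residue, atom); glycine rows never carry CB; shifts lie
#'   in \[0, 250\] ppm (values outside that window almost always indicate a
#'   column mix-up in the input file).
#'
#' @examples
#' shift_table(c(2, 2), c("A", "A"), c("CA", "CB"), c(52.5, 19.1))
#' @export
shift_table <- function(residue_index, residue_type, atom, shift_ppm) {
  df <- data.frame(
    residue_index = as.integer(residue_index),
    residue_type  = toupper(as.character(residue_type)),
    atom          = toupper(as.character(atom)),
    shift_ppm     = as.numeric(shift_ppm),
    stringsAsFactors = FALSE
  )
  validate_shift_table(df)
  class(df) <- c("shift_table", "data.frame")
  df
}

validate_shift_table <- function(df) {
  req <- c("residue_index", "residue_type", "atom", "shift_ppm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("shift table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(df$residue_index <= 0) || anyNA(df$residue_index))
    stop("residue_index must be strictly positive")
  bad_atom <- setdiff(unique(df$atom), c("H", "N", "CA", "CB"))
  if (length(bad_atom))
    stop("unsupported atom name(s): ", paste(bad_atom, collapse = ", "))
  key <- paste(df$residue_index, df$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue_index, atom) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  gly_cb <- df$residue_type == "G" & df$atom == "CB"
  if (any(gly_cb))
    stop("glycine cannot carry a CB shift (residue ",
         paste(df$residue_index[gly_cb], collapse = ", "), ")")
  out_of_range <- !is.na(df$shift_ppm) &
    (df$shift_ppm < 0 | df$shift_ppm > 250)
  if (any(out_of_range))
    stop("shift outside [0, 250] ppm at residue ",
         paste(df$residue_index[out_of_range], collapse = ", "),
         " (likely column mix-up)")
  invisible(df)
}

#' Read a delimited chemical-shift table
#'
#' Reads a tab- or comma-delimited text file with header columns
#' `residue_index, residue_type, atom, shift_ppm` (the delimiter is
#' auto-detected from the header line).
#'
#' @param path path to the file.
#' @return a [shift_table()].
#' @export
read_shift_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  shift_table(df$residue_index, df$residue_type, df$atom, df$shift_ppm)
}

#' Write a shift table as tab-delimited text
#'
#' @param x a [shift_table()].
#' @param path output path.
#' @export
write_shift_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 3-letter -> 1-letter lookup used by the NMR-STAR reader and structure code
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Read backbone shifts from an NMR-STAR v3 chemical-shift loop
#'
#' Extracts the four columns needed here (sequence id, residue type, atom
#' id, shift value) from the `_Atom_chem_shift` loop of an NMR-STAR v3
#' file, keeping only H, N, CA and CB rows.
#'
#' @param path path to the NMR-STAR file.
#' @return a [shift_table()].
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path)
  tag_idx <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (!length(tag_idx))
    stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("^\\s*_Atom_chem_shift\\.", "", trimws(lines[tag_idx]))
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  col <- match(need, tags)
  if (anyNA(col))
    stop("chemical-shift loop lacks tag(s): ",
         paste(need[is.na(col)], collapse = ", "))
  body <- lines[seq(max(tag_idx) + 1L, length(lines))]
  stop_at <- grep("^\\s*(stop_|loop_|save_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  body <- trimws(body)
  body <- body[nzchar(body) & !startsWith(body, "#")]
  fields <- strsplit(body, "\\s+")
  fields <- fields[vapply(fields, length, 1L) >= max(col, na.rm = TRUE)]
  m <- do.call(rbind, lapply(fields, function(f) f[col]))
  keep <- toupper(m[, 3]) %in% c("H", "N", "CA", "CB")
  m <- m[keep, , drop = FALSE]
  res3 <- toupper(m[, 2])
  res1 <- ifelse(res3 %in% names(AA3TO1), AA3TO1[res3], res3)
  shift_table(as.integer(m[, 1]), res1, m[, 3], as.numeric(m[, 4]))
}

#' Random-coil reference shifts for CA and CB
#'
#' The default random-coil chemical-shift reference set (Wishart et al.,
#' 1995, J. Biomol. NMR 5:67; DSS-referenced, reduced cysteine). Glycine has
#' no CB. The provenance string travels with the table and is echoed in
#' every secondary-shift output so results remain auditable against the
#' reference choice; supply your own table (same columns, with a
#' `provenance` attribute) to use a different set.
#'
#' @return data frame with columns `residue_type`, `CA`, `CB` and attribute
#'   `provenance`.
#' @export
random_coil_table <- function() {
  df <- data.frame(
    residue_type = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    CA = c(52.5, 56.0, 52.8, 53.1, 58.2, 56.1, 56.6, 45.1, 55.0, 61.3,
           55.1, 56.5, 55.3, 57.9, 63.1, 58.3, 62.1, 57.6, 58.1, 62.3),
    CB = c(19.1, 30.9, 37.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.0,
           42.4, 32.5, 32.6, 39.8, 31.7, 63.8, 69.2, 29.8, 38.8, 32.5),
    stringsAsFactors = FALSE
  )
  attr(df, "provenance") <- "Wishart-1995-random-coil (DSS-referenced)"
  df
}
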