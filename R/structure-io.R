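#' Construct a structure model
#'
#' The coordinate container used throughout the interface analysis: a flat
#' atom table plus optional crystal cell, space group and symmetry
#' operators. [read_structure()] builds one from a PDB or mmCIF file; the
#' synthetic generators build them directly.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`
#'   (3-letter residue name), `elety` (atom name), `element`, `x`, `y`,
#'   `z` (Angstrom); optional `o` (occupancy), `b`, `radius` (explicit
#'   vdW radius, used by [sasa()] in preference to the element lookup).
#' @param cell optional numeric `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees).
#' @param space_group optional Hermann-Mauguin symbol, e.g. `"P 31 2 1"`.
#' @param sym_ops optional list of symmetry operators, each
#'   `list(R = 3x3 matrix, t = length-3 vector)` in fractional
#'   coordinates; when `NULL` and `space_group` is given, operators come
#'   from the built-in table.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, space_group = NULL,
                            sym_ops = NULL) {
  req <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  atoms$is_water <- atoms$resid %in% c("HOH", "WAT", "DOD")
  if (!is.null(cell)) {
    stopifnot(length(cell) == 6, all(cell[1:3] > 0),
              all(cell[4:6] > 0 & cell[4:6] < 180))
  }
  if (is.null(sym_ops) && !is.null(space_group))
    sym_ops <- space_group_ops(space_group)
  structure(list(atoms = atoms, cell = cell, space_group = space_group,
                 sym_ops = sym_ops),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain[!x$atoms$is_water])
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(ch), "chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]\n")
  if (!is.null(x$cell))
    cat(sprintf("  cell a=%.2f b=%.2f c=%.2f al=%.1f be=%.1f ga=%.1f  %s (%d ops)\n",
                x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5],
                x$cell[6], x$space_group %||% "?",
                length(x$sym_ops %||% list())))
  invisible(x)
}

guess_element <- function(elety) {
  # strip leading digits (e.g. "1HB"), element = leading letters of the
  # remainder; two-letter elements in protein files are rare and handled
  # by the explicit list
  nm <- toupper(sub("^[0-9]*", "", elety))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN"),
         two, substr(nm, 1, 1))
}

#' Read a PDB or mmCIF coordinate file
#'
#' Atom records are parsed with bio3d; the crystal cell and space group
#' (CRYST1 record / `_cell` and `_symmetry` items), which bio3d does not
#' expose, are read here. Alternate locations are resolved to the
#' highest-occupancy copy, and waters are flagged (not removed).
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  # rm.alt=FALSE: altlocs are resolved below by occupancy, not by label
  pdb <- if (format == "pdb")
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  else suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                        rm.alt = FALSE))
  at <- pdb$atom
  # altloc resolution: keep the highest-occupancy copy per (chain,res,atom)
  at$o[is.na(at$o)] <- 1
  ord <- order(at$chain, at$resno, at$elety, -at$o)
  at <- at[ord, ]
  at <- at[!duplicated(at[, c("chain", "resno", "elety")]), ]
  at <- at[order(at$chain, at$resno, match(at$elety, unique(at$elety))), ]
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == ""))
    element <- guess_element(at$elety)
  element[is.na(element) | element == ""] <-
    guess_element(at$elety[is.na(element) | element == ""])
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, resid = at$resid,
                      elety = at$elety, element = toupper(element),
                      x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
                      stringsAsFactors = FALSE)
  cellinfo <- if (format == "pdb") read_cell_pdb(path) else read_cell_cif(path)
  structure_model(atoms, cell = cellinfo$cell,
                  space_group = cellinfo$space_group)
}

read_cell_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) return(list(cell = NULL, space_group = NULL))
  cr <- cr[1]
  cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                       substr(cr, 25, 33), substr(cr, 34, 40),
                       substr(cr, 41, 47), substr(cr, 48, 54)))
  sg <- trimws(substr(cr, 56, 66))
  # a 1 A P1 placeholder cell means "no crystal information"
  if (all(cell[1:3] == 1)) return(list(cell = NULL, space_group = NULL))
  list(cell = cell, space_group = sg)
}

read_cell_cif <- function(path) {
  lines <- readLines(path)
  grab <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NA)
    val <- trimws(sub(paste0("^\\s*", tag, "\\s+"), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  a <- suppressWarnings(as.numeric(grab("_cell\\.length_a")))
  if (is.na(a)) return(list(cell = NULL, space_group = NULL))
  cell <- suppressWarnings(as.numeric(c(
    a, grab("_cell\\.length_b"), grab("_cell\\.length_c"),
    grab("_cell\\.angle_alpha"), grab("_cell\\.angle_beta"),
    grab("_cell\\.angle_gamma"))))
  sg <- grab("_symmetry\\.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group\\.name_H-M_alt")
  list(cell = cell, space_group = if (is.na(sg)) NULL else sg)
}

#' Write a structure model as a PDB file
#'
#' Coordinates go through bio3d's PDB writer; when a cell and space group
#' are present a CRYST1 record is prepended so symmetry information
#' round-trips.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  n <- nrow(at)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(at[, c("x", "y", "z")])),
                   type = rep("ATOM", n), resno = at$resno,
                   resid = at$resid, eleno = seq_len(n), elety = at$elety,
                   chain = at$chain, o = at$o, b = at$b,
                   elesy = at$element)
  if (!is.null(model$cell)) {
    cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                  model$cell[1], model$cell[2], model$cell[3],
                  model$cell[4], model$cell[5], model$cell[6],
                  model$space_group %||% "P 1", 1L)
    writeLines(c(cr, readLines(path)), path)
  }
  invisible(path)
}

coords <- function(model, subset = TRUE) {
  as.matrix(model$atoms[subset, c("x", "y", "z")])
}

split_chains <- function(model, drop_water = TRUE) {
  at <- model$atoms
  if (drop_water) at <- at[!at$is_water, , drop = FALSE]
  lapply(split(at, at$chain), function(a)
    structure_model(a, cell = NULL))
}
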