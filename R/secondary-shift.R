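#' Secondary chemical shifts from a shift table
#'
#' Computes the per-residue secondary shifts dCA = obs(CA) - rc(CA) and
#' dCB = obs(CB) - rc(CB) against a random-coil reference, together with
#' the raw secondary-structure index dCA - dCB. A negative index indicates
#' beta-strand character, a positive one alpha-helix. Glycine has no CB;
#' its dCB is defined as 0 so the index reduces to dCA. Residues without a
#' CA shift are kept in the output but marked undefined (NA).
#'
#' @param shifts a [shift_table()] containing CA (and, where the residue
#'   has one, CB) entries.
#' @param reference a random-coil table as returned by
#'   [random_coil_table()] (the default).
#' @return data frame with columns `residue_index`, `residue_type`,
#'   `d_ca`, `d_cb`, `raw_index`; attribute `reference_provenance` records
#'   which random-coil set was used.
#' @export
secondary_shifts <- function(shifts, reference = random_coil_table()) {
  validate_shift_table(shifts)
  cs <- shifts[shifts$atom %in% c("CA", "CB"), , drop = FALSE]
  res <- unique(cs[, c("residue_index", "residue_type")])
  res <- res[order(res$residue_index), , drop = FALSE]
  unknown <- !(res$residue_type %in% reference$residue_type)
  if (any(unknown))
    stop("unknown residue type '",
         paste(unique(res$residue_type[unknown]), collapse = "', '"),
         "' at residue ",
         paste(res$residue_index[unknown], collapse = ", "))
  ref_ca <- stats::setNames(reference$CA, reference$residue_type)
  ref_cb <- stats::setNames(reference$CB, reference$residue_type)
  ca <- cs[cs$atom == "CA", ]
  cb <- cs[cs$atom == "CB", ]
  d_ca <- ca$shift_ppm - ref_ca[ca$residue_type]
  names(d_ca) <- ca$residue_index
  d_cb <- cb$shift_ppm - ref_cb[cb$residue_type]
  names(d_cb) <- cb$residue_index
  out <- data.frame(
    residue_index = res$residue_index,
    residue_type  = res$residue_type,
    d_ca = unname(d_ca[as.character(res$residue_index)]),
    d_cb = unname(d_cb[as.character(res$residue_index)]),
    stringsAsFactors = FALSE
  )
  # Gly convention: no CB exists, index falls back to d_ca alone.
  # Other residues missing CB keep NA d_cb but still get an index from CA
  # only if CB was never assigned; missing CA leaves the index undefined.
  out$d_cb[out$residue_type == "G"] <- 0
  out$d_cb[is.na(out$d_cb)] <- 0
  out$raw_index <- out$d_ca - out$d_cb
  out$raw_index[is.na(out$d_ca)] <- NA_real_
  attr(out, "reference_provenance") <-
    attr(reference, "provenance") %||% "user-supplied"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-residue smoothing of a per-residue index
#'
#' Smooths a per-residue index with the running mean over residues
#' i-1, i, i+1. At chain termini and next to assignment gaps the mean is
#' taken over the window members that exist, so coverage is preserved; a
#' residue with no raw value of its own stays undefined.
#'
#' @param raw numeric vector named by residue index (gaps allowed; NA
#'   entries are treated as missing).
#' @return numeric vector named like `raw`.
#' @export
smooth_index <- function(raw) {
  idx <- as.integer(names(raw))
  if (is.null(names(raw)) || anyNA(idx))
    stop("raw index must be a numeric vector named by residue number")
  val <- stats::setNames(as.numeric(raw), idx)
  out <- rep(NA_real_, length(raw))
  names(out) <- names(raw)
  for (k in seq_along(idx)) {
    if (is.na(val[k])) next
    window <- val[as.character(idx[k] + (-1L:1L))]
    out[k] <- mean(window, na.rm = TRUE)
  }
  out
}

#' Secondary-structure call from a smoothed index
#'
#' Sign rule with a deadband: smoothed index above `+deadband` is helix,
#' below `-deadband` is strand, otherwise coil; residues with no index are
#' undefined. The deadband guards against over-calling structure from
#' noise; the underlying rule is negative = strand, positive = helix.
#'
#' @param smoothed numeric vector named by residue index.
#' @param deadband non-negative half-width in ppm of the coil band
#'   (default 0.7).
#' @return character vector (`"helix"`, `"strand"`, `"coil"`,
#'   `"undefined"`) named like `smoothed`.
#' @export
classify_secondary <- function(smoothed, deadband = 0.7) {
  if (deadband < 0) stop("deadband must be >= 0")
  lab <- ifelse(is.na(smoothed), "undefined",
         ifelse(smoothed >  deadband, "helix",
         ifelse(smoothed < -deadband, "strand", "coil")))
  stats::setNames(lab, names(smoothed))
}

#' Full secondary-shift secondary-structure profile
#'
#' Convenience wrapper chaining [secondary_shifts()], [smooth_index()] and
#' [classify_secondary()] into one per-residue table.
#'
#' @inheritParams secondary_shifts
#' @inheritParams classify_secondary
#' @return data frame with columns `residue_index`, `residue_type`,
#'   `d_ca`, `d_cb`, `raw_index`, `smoothed_index`, `label`.
#' @examples
#' tab <- shift_table(1:3, c("A", "A", "A"), rep("CA", 3), c(55.5, 55.5, 55.5))
#' secondary_structure_profile(tab)
#' @export
secondary_structure_profile <- function(shifts,
                                        reference = random_coil_table(),
                                        deadband = 0.7) {
  prof <- secondary_shifts(shifts, reference)
  raw <- stats::setNames(prof$raw_index, prof$residue_index)
  prof$smoothed_index <- unname(smooth_index(raw))
  prof$label <- unname(classify_secondary(
    stats::setNames(prof$smoothed_index, prof$residue_index), deadband))
  prof
}
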