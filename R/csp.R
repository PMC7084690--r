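#' Amide chemical-shift perturbation between two states
#'
#' For every residue with H and N shifts in both tables, computes the
#' signed differences dH = H(a) - H(b), dN = N(a) - N(b) and the combined
#' amide perturbation
#' \deqn{\Delta\delta_{NH} = \sqrt{(\Delta\delta_H^2 +
#'   (\Delta\delta_N/5)^2)/2}}
#' The 1/5 factor scales the 15N dispersion onto the 1H scale. Signed
#' components are kept for diagnostics; the combined value only uses their
#' squares, so it is symmetric in the two states and non-negative.
#'
#' Residues present (with an amide) in only one state are never silently
#' dropped: they are reported in the `unmatched` attribute.
#'
#' @param state_a,state_b [shift_table()]s containing H and N entries.
#' @return data frame of class `csp_profile` with columns `residue_index`,
#'   `delta_h`, `delta_n`, `delta_nh`; attribute `unmatched` is a list with
#'   the residue indices found only in `a` or only in `b`.
#' @export
csp <- function(state_a, state_b) {
  validate_shift_table(state_a)
  validate_shift_table(state_b)
  amide <- function(tab) {
    h <- tab[tab$atom == "H", ]
    n <- tab[tab$atom == "N", ]
    shared <- intersect(h$residue_index, n$residue_index)
    data.frame(
      residue_index = shared,
      h = h$shift_ppm[match(shared, h$residue_index)],
      n = n$shift_ppm[match(shared, n$residue_index)]
    )
  }
  a <- amide(state_a)
  b <- amide(state_b)
  shared <- intersect(a$residue_index, b$residue_index)
  if (!length(shared))
    stop("no residues share H and N assignments in both states")
  shared <- sort(shared)
  ia <- match(shared, a$residue_index)
  ib <- match(shared, b$residue_index)
  delta_h <- a$h[ia] - b$h[ib]
  delta_n <- a$n[ia] - b$n[ib]
  out <- data.frame(
    residue_index = shared,
    delta_h = delta_h,
    delta_n = delta_n,
    delta_nh = sqrt((delta_h^2 + (delta_n / 5)^2) / 2)
  )
  attr(out, "unmatched") <- list(
    a_only = setdiff(a$residue_index, shared),
    b_only = setdiff(b$residue_index, shared)
  )
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Bin chemical-shift perturbations into significance tiers
#'
#' Tier k is the number of thresholds a residue's combined perturbation
#' strictly exceeds, so tier 0 means below every threshold and the top tier
#' means above all of them. Typical threshold sets are
#' `c(0.25, 0.5, 1.0)` ppm for comparing two protein variants and
#' `c(0.05, 0.1)` ppm for a ligand titration.
#'
#' @param profile a `csp_profile` from [csp()].
#' @param thresholds strictly ascending positive thresholds in ppm.
#' @return `profile` with an integer `tier` column added.
#' @export
tier_csp <- function(profile, thresholds = c(0.25, 0.5, 1.0)) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending and positive")
  profile$tier <- vapply(profile$delta_nh,
                         function(x) sum(x > thresholds), integer(1))
  attr(profile, "thresholds") <- thresholds
  profile
}
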