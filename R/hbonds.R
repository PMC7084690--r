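#' Interchain backbone hydrogen bonds
#'
#' Detects backbone N-H...O=C hydrogen bonds between chains. With amide
#' hydrogens present the criterion is N...O <= `d_max` and the N-H...O
#' angle at the hydrogen >= `angle_min`. Crystal structures at moderate
#' resolution carry no hydrogens, so without an H the criterion falls back
#' to the N...O distance plus a C-O...N angle window of
#' \[`co_angle_range`\] at the carbonyl oxygen, which rejects geometries
#' where the nitrogen approaches the oxygen from behind the carbonyl.
#' Proline, lacking an amide proton, is never a donor. Each donor reports
#' at most one bond (the closest acceptor).
#'
#' @param dimer a [structure_model()] with at least two chains carrying
#'   backbone N and O atoms.
#' @param d_max donor-acceptor N...O cutoff in Angstrom (default 3.5).
#' @param angle_min minimal N-H...O angle in degrees when an amide H
#'   exists (default 120).
#' @param co_angle_range C-O...N angle window in degrees used when no H is
#'   present (default `c(90, 180)`).
#' @return data frame with columns `donor_chain`, `donor_resno`,
#'   `acceptor_chain`, `acceptor_resno`, `distance_no`, `angle`
#'   (the criterion angle actually evaluated); zero rows when no bond
#'   qualifies.
#' @export
backbone_hbonds <- function(dimer, d_max = 3.5, angle_min = 120,
                            co_angle_range = c(90, 180)) {
  at <- dimer$atoms[!dimer$atoms$is_water, , drop = FALSE]
  if (length(unique(at$chain)) < 2)
    stop("need at least two chains for interchain hydrogen bonds")
  don <- at[at$elety == "N" & at$resid != "PRO", , drop = FALSE]
  acc <- at[at$elety == "O", , drop = FALSE]
  carb <- at[at$elety == "C", , drop = FALSE]
  hyd <- at[at$elety %in% c("H", "HN"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(don))) {
    d <- don[i, ]
    cand <- acc[acc$chain != d$chain, , drop = FALSE]
    if (!nrow(cand)) next
    dist <- sqrt((cand$x - d$x)^2 + (cand$y - d$y)^2 + (cand$z - d$z)^2)
    cand <- cand[dist <= d_max, , drop = FALSE]
    dist <- dist[dist <= d_max]
    if (!nrow(cand)) next
    h <- hyd[hyd$chain == d$chain & hyd$resno == d$resno, , drop = FALSE]
    keep <- rep(FALSE, nrow(cand))
    ang <- rep(NA_real_, nrow(cand))
    for (j in seq_len(nrow(cand))) {
      a <- cand[j, ]
      if (nrow(h) == 1) {
        ang[j] <- vec_angle(c(d$x, d$y, d$z) - c(h$x, h$y, h$z),
                            c(a$x, a$y, a$z) - c(h$x, h$y, h$z))
        keep[j] <- ang[j] >= angle_min
      } else {
        cc <- carb[carb$chain == a$chain & carb$resno == a$resno, ,
                   drop = FALSE]
        if (nrow(cc) != 1) next
        ang[j] <- vec_angle(c(cc$x, cc$y, cc$z) - c(a$x, a$y, a$z),
                            c(d$x, d$y, d$z) - c(a$x, a$y, a$z))
        keep[j] <- ang[j] >= co_angle_range[1] & ang[j] <= co_angle_range[2]
      }
    }
    if (!any(keep)) next
    best <- which(keep)[which.min(dist[keep])]
    out[[length(out) + 1L]] <- data.frame(
      donor_chain = d$chain, donor_resno = d$resno,
      acceptor_chain = cand$chain[best], acceptor_resno = cand$resno[best],
      distance_no = dist[best], angle = ang[best],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      acceptor_chain = character(),
                      acceptor_resno = integer(),
                      distance_no = numeric(), angle = numeric()))
  do.call(rbind, out)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Residue-pairing register map of a dimer interface
#'
#' Reduces interchain backbone hydrogen bonds to residue pairs
#' (residue in the first chain, residue in the second chain), regardless
#' of which side donates, deduplicated and sorted.
#'
#' @param dimer a two-chain [structure_model()], or a hydrogen-bond table
#'   from [backbone_hbonds()].
#' @param ... passed to [backbone_hbonds()] when `dimer` is a model.
#' @return data frame with columns `res_a`, `res_b`.
#' @export
register_map <- function(dimer, ...) {
  hb <- if (inherits(dimer, "structure_model"))
    backbone_hbonds(dimer, ...) else dimer
  if (!nrow(hb))
    return(data.frame(res_a = integer(), res_b = integer()))
  chains <- sort(unique(c(hb$donor_chain, hb$acceptor_chain)))
  first <- chains[1]
  res_a <- ifelse(hb$donor_chain == first, hb$donor_resno,
                  hb$acceptor_resno)
  res_b <- ifelse(hb$donor_chain == first, hb$acceptor_resno,
                  hb$donor_resno)
  m <- unique(data.frame(res_a = res_a, res_b = res_b))
  m <- m[order(m$res_a, m$res_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Register shift between two dimer interfaces
#'
#' For an antiparallel pairing, each hydrogen-bonded residue pair (i, j)
#' has pairing centre (i + j) / 2, which is invariant to which strand the
#' residues sit on. The register shift between two interfaces is the
#' difference of the median pairing centres inside a residue window,
#' rounded to the nearest integer. Positive values mean the pairing centre
#' of `map_b` sits closer to the C-terminus than that of `map_a`.
#'
#' @param map_a,map_b register maps from [register_map()].
#' @param window inclusive residue window restricting both maps (default
#'   `c(5, 15)`, the chemokine N-terminal interface).
#' @return integer offset in residues.
#' @export
register_shift <- function(map_a, map_b, window = c(5, 15)) {
  clip <- function(m) m[m$res_a >= window[1] & m$res_a <= window[2] &
                          m$res_b >= window[1] & m$res_b <= window[2], ,
                        drop = FALSE]
  a <- clip(map_a)
  b <- clip(map_b)
  if (!nrow(a) || !nrow(b))
    stop("no register pairs inside the window [", window[1], ", ",
         window[2], "] in both maps")
  centre <- function(m) stats::median((m$res_a + m$res_b) / 2)
  as.integer(round(centre(b) - centre(a)))
}
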