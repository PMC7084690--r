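#' Default chemokine-like secondary-structure topology
#'
#' Per-residue topology string (H = helix, E = strand, C = coil) for a
#' 68-residue CC-chemokine fold: extended N-terminus, three antiparallel
#' strands (24-28, 39-43, 46-51) and a C-terminal helix (56-66).
#'
#' @return character scalar of length-68 topology codes.
#' @export
ccl5_topology <- function() {
  topo <- rep("C", 68)
  topo[24:28] <- "E"
  topo[39:43] <- "E"
  topo[46:51] <- "E"
  topo[56:66] <- "H"
  paste(topo, collapse = "")
}

#' Generate a synthetic chemical-shift table with known topology
#'
#' Builds a shift table whose CA/CB secondary-shift index
#' (dCA - dCB) is drawn around +`effect` ppm in helices, -`effect` ppm in
#' strands and 0 in coil, plus Gaussian noise, on top of the shipped
#' random-coil reference -- so the secondary-structure analysis can be
#' validated against exact truth labels. Amide H/N shifts (around 8.3 /
#' 119 ppm) are included so the same tables feed perturbation mapping.
#'
#' @param topology per-residue topology string over `{H, E, C}`
#'   (default [ccl5_topology()]).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param noise_sd Gaussian noise on the index, ppm (default 0).
#' @param effect class-centre magnitude of the index, ppm (default 3).
#' @param sequence one-letter sequence matching `topology` length
#'   (default: the CCL5 12AAA14 chain, recycled/truncated to fit).
#' @param with_amide also emit H and N rows (default `TRUE`).
#' @return list with `table` (a [shift_table()]), `truth` (character
#'   labels named by residue) and `spec` (the generating parameters).
#' @export
gen_shift_table <- function(topology = ccl5_topology(), seed = 1,
                            noise_sd = 0, effect = 3,
                            sequence = NULL, with_amide = TRUE) {
  topo <- strsplit(topology, "")[[1]]
  stopifnot(all(topo %in% c("H", "E", "C")), noise_sd >= 0)
  n <- length(topo)
  if (is.null(sequence)) {
    base <- strsplit(substr(ccl5_sequence(c("12" = "A", "14" = "A"),
                                          met0 = FALSE), 1, n), "")[[1]]
    aa <- rep(base, length.out = n)
  } else {
    aa <- strsplit(sequence, "")[[1]]
    stopifnot(length(aa) == n)
  }
  set.seed(seed)
  centre <- c(H = effect, E = -effect, C = 0)[topo]
  index <- centre + stats::rnorm(n, 0, noise_sd)
  rc <- random_coil_table()
  ref_ca <- stats::setNames(rc$CA, rc$residue_type)
  ref_cb <- stats::setNames(rc$CB, rc$residue_type)
  rows <- list()
  for (i in seq_len(n)) {
    if (aa[i] == "G") {
      rows[[length(rows) + 1L]] <-
        data.frame(residue_index = i, residue_type = aa[i], atom = "CA",
                   shift_ppm = ref_ca[[aa[i]]] + index[i])
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(residue_index = c(i, i), residue_type = aa[i],
                   atom = c("CA", "CB"),
                   shift_ppm = c(ref_ca[[aa[i]]] + index[i] / 2,
                                 ref_cb[[aa[i]]] - index[i] / 2))
    }
    if (with_amide)
      rows[[length(rows) + 1L]] <-
        data.frame(residue_index = c(i, i), residue_type = aa[i],
                   atom = c("H", "N"),
                   shift_ppm = c(8.3 + stats::rnorm(1, 0, 0.3),
                                 119 + stats::rnorm(1, 0, 3)))
  }
  df <- do.call(rbind, rows)
  truth <- stats::setNames(
    c(H = "helix", E = "strand", C = "coil")[topo], seq_len(n))
  list(table = shift_table(df$residue_index, df$residue_type, df$atom,
                           df$shift_ppm),
       truth = truth,
       spec = list(seed = seed, noise_sd = noise_sd, effect = effect,
                   topology = topology))
}

#' Standard relaxation delay grids
#'
#' The delay lists used by the longitudinal (R1) and transverse (R2)
#' relaxation experiments this package was developed against, in
#' milliseconds.
#'
#' @name delay_grids
#' @return numeric vector of delays in ms.
#' @export
r1_delays_ms <- function() c(5, 10, 20, 40, 80, 150, 300, 600, 800, 1000)

#' @rdname delay_grids
#' @export
r2_delays_ms <- function() c(0, 16.96, 33.92, 50.88, 67.84, 84.8, 101.76,
                             118.72, 135.68, 169.60, 203.52, 237.44)

#' Generate synthetic mono-exponential intensity decays
#'
#' I(t) = I0 exp(-R t) with multiplicative Gaussian noise,
#' I_obs = I(t) (1 + eps), eps ~ N(0, noise_sd). Default delay grids are
#' the standard R1/R2 lists ([r1_delays_ms()], [r2_delays_ms()]).
#'
#' @param rates named or unnamed vector of true rates (1/s), one per
#'   residue; names are residue indices (default `seq_along`).
#' @param seed RNG seed.
#' @param noise_sd fractional noise standard deviation (default 0).
#' @param delays_ms delay grid in ms (default the R2 list when
#'   `kind = "R2"`, the R1 list otherwise).
#' @param kind `"R1"` or `"R2"` (selects the default grid).
#' @param i0 amplitude (default 100).
#' @return list with `decays` (data frame `residue_index`, `delay_s`,
#'   `intensity`) and `truth` (the input rates, named by residue).
#' @export
gen_decays <- function(rates, seed = 1, noise_sd = 0, delays_ms = NULL,
                       kind = c("R2", "R1"), i0 = 100) {
  kind <- match.arg(kind)
  stopifnot(all(rates > 0), noise_sd >= 0)
  if (is.null(delays_ms))
    delays_ms <- if (kind == "R2") r2_delays_ms() else r1_delays_ms()
  if (is.null(names(rates))) names(rates) <- seq_along(rates)
  set.seed(seed)
  t_s <- delays_ms / 1000
  rows <- lapply(names(rates), function(r) {
    ideal <- i0 * exp(-rates[[r]] * t_s)
    data.frame(residue_index = as.integer(r), delay_s = t_s,
               intensity = ideal * (1 + stats::rnorm(length(t_s), 0,
                                                     noise_sd)))
  })
  list(decays = do.call(rbind, rows), truth = rates)
}

# geometric conventions of the idealized antiparallel two-strand fixture;
# fixed in one place so structural tests reproduce bit-for-bit
beta_geometry <- function() {
  list(rise = 3.4,        # A per residue along the strand axis
       strand_sep = 5.1,  # A between the two strand axes
       nco_x = 1.0,       # N/C offset from CA along the strand
       n_y = 0.6,         # N/C offset toward the partner strand
       o_y = 1.6,         # carbonyl O offset when H-bonding (N...O = 2.9)
       o_flip_y = -0.4)   # carbonyl O offset when pointing away
}

#' Generate an idealized antiparallel beta-strand dimer
#'
#' Builds a two-chain backbone-only (N, CA, C, O) model of two
#' antiparallel strands whose interstrand hydrogen-bond ladder realizes a
#' designed residue-pairing register: for every requested pair (i, j),
#' N(i, chain A)...O(j, chain B) and N(j, chain B)...O(i, chain A) sit at
#' 2.9 Angstrom with linear C-O...N geometry, while carbonyls of unpaired
#' residues point away from the interface. All pairs must share the same
#' antiparallel register i + j. Chain B is an exact two-fold image of
#' chain A when the pair set is symmetric.
#'
#' @param pairs list of length-2 integer vectors (residue in A, residue
#'   in B), e.g. `list(c(8, 10), c(10, 8))`.
#' @param residues residue numbers to build (default: the pair range
#'   padded by 3 on each side, floored at 1).
#' @return list with `model` (a two-chain [structure_model()]) and
#'   `truth` (the designed register map as a data frame `res_a`,
#'   `res_b`).
#' @examples
#' gen_beta_dimer(list(c(10, 10)))$truth
#' @export
gen_beta_dimer <- function(pairs, residues = NULL) {
  pm <- do.call(rbind, lapply(pairs, as.integer))
  stopifnot(ncol(pm) == 2, all(pm >= 1))
  K <- unique(rowSums(pm))
  if (length(K) != 1)
    stop("all pairs must share one antiparallel register i + j")
  if (is.null(residues))
    residues <- max(1, min(pm) - 3):(max(pm) + 3)
  if (length(residues) < 4) stop("need at least 4 residues")
  g <- beta_geometry()
  cx <- g$rise * K   # x-coordinate scale centring the register
  o_on_a <- unique(pm[, 1])  # chain A residues whose O faces chain B
  o_on_b <- unique(pm[, 2])
  mk_chain <- function(chain) {
    rows <- lapply(residues, function(i) {
      if (chain == "A") {
        ca <- c(g$rise * i, 0, 0)
        nn <- c(g$rise * i - g$nco_x, g$n_y, 0)
        cc <- c(g$rise * i + g$nco_x, g$n_y, 0)
        oy <- if (i %in% o_on_a) g$o_y else g$o_flip_y
        oo <- c(g$rise * i + g$nco_x, oy, 0)
      } else {
        ca <- c(cx - g$rise * i, g$strand_sep, 0)
        nn <- c(cx - g$rise * i + g$nco_x, g$strand_sep - g$n_y, 0)
        cc <- c(cx - g$rise * i - g$nco_x, g$strand_sep - g$n_y, 0)
        oy <- if (i %in% o_on_b) g$o_y else g$o_flip_y
        oo <- c(cx - g$rise * i - g$nco_x, g$strand_sep - oy, 0)
      }
      xyz <- rbind(nn, ca, cc, oo)
      data.frame(chain = chain, resno = i, resid = "ALA",
                 elety = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  atoms <- rbind(mk_chain("A"), mk_chain("B"))
  truth <- unique(data.frame(res_a = pm[, 1], res_b = pm[, 2]))
  truth <- truth[order(truth$res_a), , drop = FALSE]
  rownames(truth) <- NULL
  list(model = structure_model(atoms), truth = truth)
}

#' Generate a pseudo-atom sphere fixture
#'
#' Spheres with explicit radii at given centres, for validating the
#' surface-area quadrature against closed forms.
#'
#' @param radii numeric vector of sphere radii (Angstrom).
#' @param centers matrix (n x 3) of sphere centres.
#' @param chains chain id per sphere (default all `"A"`).
#' @return a [structure_model()] whose atoms carry an explicit `radius`
#'   column (used by [sasa()] instead of element radii).
#' @export
gen_sphere_fixture <- function(radii, centers, chains = NULL) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(length(radii) == nrow(centers), all(radii > 0))
  n <- length(radii)
  atoms <- data.frame(chain = chains %||% rep("A", n),
                      resno = seq_len(n), resid = "SPH", elety = "X",
                      element = "X",
                      x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      radius = radii, stringsAsFactors = FALSE)
  structure_model(atoms)
}
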