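# Symmetry operator triplets for the space groups supported here, in the
# standard International Tables settings. Keys are Hermann-Mauguin symbols
# with spaces removed.
SPACE_GROUP_TRIPLETS <- list(
  "P1"       = "x,y,z",
  "P21"      = "x,y,z;-x,y+1/2,-z",
  "C2"       = "x,y,z;-x,y,-z;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z",
  "P212121"  = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2",
  "P321"     = "x,y,z;-y,x-y,z;-x+y,-x,z;y,x,-z;x-y,-y,-z;-x,-x+y,-z",
  "P3121"    = paste0("x,y,z;-y,x-y,z+1/3;-x+y,-x,z+2/3;",
                      "y,x,-z;x-y,-y,-z+2/3;-x,-x+y,-z+1/3"),
  "P3221"    = paste0("x,y,z;-y,x-y,z+2/3;-x+y,-x,z+1/3;",
                      "y,x,-z;x-y,-y,-z+1/3;-x,-x+y,-z+2/3"),
  "P6122"    = paste0("x,y,z;x-y,x,z+1/6;-y,x-y,z+1/3;-x,-y,z+1/2;",
                      "-x+y,-x,z+2/3;y,-x+y,z+5/6;-y,-x,-z+5/6;",
                      "-x,-x+y,-z+2/3;-x+y,y,-z+1/2;y,x,-z+1/3;",
                      "x,x-y,-z+1/6;x-y,-y,-z")
)
# aliases for full-symbol spellings
SPACE_GROUP_ALIASES <- c("P1211" = "P21", "C121" = "C2")

normalize_sg <- function(symbol) {
  key <- toupper(gsub("[ ()_]", "", symbol))
  if (key %in% names(SPACE_GROUP_ALIASES)) key <- SPACE_GROUP_ALIASES[[key]]
  key
}

parse_symop <- function(triplet) {
  parts <- strsplit(triplet, ",")[[1]]
  stopifnot(length(parts) == 3)
  ev <- function(expr, x, y, z)
    eval(parse(text = expr), list(x = x, y = y, z = z))
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    t[i] <- ev(parts[i], 0, 0, 0)
    R[i, 1] <- ev(parts[i], 1, 0, 0) - t[i]
    R[i, 2] <- ev(parts[i], 0, 1, 0) - t[i]
    R[i, 3] <- ev(parts[i], 0, 0, 1) - t[i]
  }
  # rotation entries are integers and translations multiples of 1/12 in
  # these settings; rounding removes floating-point residue from eval()
  list(R = round(R), t = round(t * 12) / 12)
}

#' Symmetry operators of a space group
#'
#' Returns the symmetry operators (fractional rotation matrix plus
#' translation) of a supported space group from the built-in table.
#'
#' @param symbol Hermann-Mauguin symbol (spaces and underscores ignored),
#'   e.g. `"P 31 2 1"`.
#' @return list of `list(R, t)` operators; the identity is first.
#' @export
space_group_ops <- function(symbol) {
  key <- normalize_sg(symbol)
  if (!key %in% names(SPACE_GROUP_TRIPLETS))
    stop("unsupported space group '", symbol, "'; supported: ",
         paste(names(SPACE_GROUP_TRIPLETS), collapse = ", "))
  lapply(strsplit(SPACE_GROUP_TRIPLETS[[key]], ";")[[1]], parse_symop)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard PDB convention: a along x, b in the xy plane.
#'
#' @param cell `c(a, b, c, alpha, beta, gamma)` in Angstrom / degrees.
#' @return 3x3 matrix M with cartesian = M %*% fractional.
#' @export
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Unit-cell volume
#'
#' General triclinic formula
#' V = abc * sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g).
#'
#' @inheritParams orthogonalization_matrix
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ang <- cell[4:6] * pi / 180
  cell[1] * cell[2] * cell[3] *
    sqrt(1 - sum(cos(ang)^2) + 2 * prod(cos(ang)))
}

apply_symop_frac <- function(frac, op, shift = c(0, 0, 0)) {
  sweep(frac %*% t(op$R), 2, op$t + shift, `+`)
}

#' Build the crystallographic dimer from a one-molecule asymmetric unit
#'
#' When a protein crystallizes with one molecule per asymmetric unit but
#' packs as a dimer across a crystallographic two-fold, the physiological
#' dimer must be regenerated from the symmetry operators. All symmetry
#' mates within the 3x3x3 block of neighbouring unit cells are generated
#' and the mate making the largest number of heavy-atom contacts (closer
#' than `contact_dist`) with the input molecule is taken as the partner.
#'
#' @param model a [structure_model()] with cell and symmetry operators.
#' @param contact_dist heavy-atom contact cutoff in Angstrom (default 5).
#' @return a two-chain [structure_model()] (chains relabelled A and B,
#'   waters dropped); attribute `contacts` holds the winning contact
#'   count, `operator` the winning (op index, cell shift).
#' @export
build_dimer_from_asu <- function(model, contact_dist = 5) {
  if (is.null(model$cell) || is.null(model$sym_ops))
    stop("need cell and symmetry operators to build a symmetry dimer")
  at <- model$atoms[!model$atoms$is_water, , drop = FALSE]
  M <- orthogonalization_matrix(model$cell)
  Minv <- solve(M)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  frac <- xyz %*% t(Minv)
  heavy <- at$element != "H"
  ref <- xyz[heavy, , drop = FALSE]
  rng <- apply(ref, 2, range)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- list(count = 0L)
  for (k in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[k]]
    identity_op <- all(op$R == diag(3)) && all(op$t == 0)
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[s, ])
      if (identity_op && all(sh == 0)) next
      mate <- apply_symop_frac(frac, op, sh) %*% t(M)
      mh <- mate[heavy, , drop = FALSE]
      # bounding-box prefilter before the pair-distance count
      if (any(apply(mh, 2, min) > rng[2, ] + contact_dist) ||
          any(apply(mh, 2, max) < rng[1, ] - contact_dist)) next
      cnt <- contact_count(ref, mh, contact_dist)
      if (cnt > best$count)
        best <- list(count = cnt, mate = mate, op = k, shift = sh)
    }
  }
  if (best$count == 0L)
    stop("monomeric packing: no symmetry mate within ", contact_dist,
         " A of the asymmetric unit")
  a_atoms <- at
  a_atoms$chain <- "A"
  b_atoms <- at
  b_atoms$chain <- "B"
  b_atoms[, c("x", "y", "z")] <- best$mate
  dimer <- structure_model(rbind(a_atoms, b_atoms))
  attr(dimer, "contacts") <- best$count
  attr(dimer, "operator") <- list(op_index = best$op, cell_shift = best$shift)
  dimer
}

contact_count <- function(a, b, cutoff) {
  # number of inter-set atom pairs closer than cutoff
  n <- 0L
  cut2 <- cutoff^2
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    n <- n + sum(d2 < cut2)
  }
  n
}
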