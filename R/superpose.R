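#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `target` over a selection of paired atoms
#' using the closed-form SVD (Kabsch) solution with reflection
#' correction, and reports the RMSD over the selection. Atoms are paired
#' by residue number and atom name (and chain, when both selections span
#' several chains); by default the selection is the Calpha trace,
#' optionally restricted to a residue range.
#'
#' @param mobile,target [structure_model()]s.
#' @param elety atom name(s) to pair on (default `"CA"`).
#' @param resno optional residue numbers to restrict the selection.
#' @param on_mismatch `"error"` (default) to fail listing atoms present in
#'   only one selection, or `"intersect"` to silently use the shared set.
#' @return list of class `superposition`: `rmsd` (Angstrom), `rotation`
#'   (3x3), `translation` (length 3; transformed = coords %*% t(rotation)
#'   + translation), `n_pairs`, `selection`.
#' @export
superpose <- function(mobile, target, elety = "CA", resno = NULL,
                      on_mismatch = c("error", "intersect")) {
  on_mismatch <- match.arg(on_mismatch)
  pick <- function(model) {
    at <- model$atoms[!model$atoms$is_water, , drop = FALSE]
    at <- at[at$elety %in% elety, , drop = FALSE]
    if (!is.null(resno)) at <- at[at$resno %in% resno, , drop = FALSE]
    multi <- length(unique(at$chain)) > 1
    at$pair_key <- if (multi) paste(at$chain, at$resno, at$elety)
                   else paste(at$resno, at$elety)
    at
  }
  a <- pick(mobile)
  b <- pick(target)
  only_a <- setdiff(a$pair_key, b$pair_key)
  only_b <- setdiff(b$pair_key, a$pair_key)
  if (on_mismatch == "error" && (length(only_a) || length(only_b)))
    stop("selection mismatch; unpaired atoms: ",
         paste(utils::head(c(paste0("mobile:", only_a),
                             paste0("target:", only_b)), 8),
               collapse = ", "))
  shared <- intersect(a$pair_key, b$pair_key)
  if (length(shared) < 3)
    stop("need at least 3 paired atoms, got ", length(shared))
  P <- as.matrix(a[match(shared, a$pair_key), c("x", "y", "z")])
  Q <- as.matrix(b[match(shared, b$pair_key), c("x", "y", "z")])
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))   # H = P'Q; R = V S U' with det correction
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rmsd = rmsd, rotation = R, translation = trans,
                 n_pairs = length(shared),
                 selection = paste0(paste(elety, collapse = "+"),
                                    if (!is.null(resno))
                                      sprintf(" %d-%d", min(resno),
                                              max(resno)) else "")),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: RMSD %.3f A over %d atoms (%s)\n",
              x$rmsd, x$n_pairs, x$selection))
  invisible(x)
}

#' Apply a rigid transformation to a structure model
#'
#' @param model a [structure_model()].
#' @param sp a `superposition` from [superpose()], or a list with
#'   `rotation` and `translation`.
#' @return the model with transformed coordinates.
#' @export
transform_structure <- function(model, sp) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
  model$atoms[, c("x", "y", "z")] <- moved
  model
}
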