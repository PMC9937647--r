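# Relating conformational states to structural states: the four
# conformational-state unit vectors (local frame) are fitted to four
# structural-state helix-axis unit vectors by a rigid rotation (no scaling,
# no reflection) for each of the 24 possible state assignments; the
# assignment with the smallest combined least-squares residual (largest
# 1/LSc) is the best match. The internal geometry of each set is fixed --
# only a global rotation is free.

#' Optimal rigid rotation between two assigned vector sets
#'
#' Orthogonal-Procrustes (Kabsch) solution with the determinant constrained
#' to +1, so chirality is preserved: minimizes `sum || R a_i - b_{pi(i)} ||^2`.
#'
#' @param a,b Matrices of unit row vectors (same number of rows).
#' @param assignment Permutation mapping rows of `a` to rows of `b`
#'   (default identity).
#' @return List with `rotation` (3 x 3, det +1) and `LSc` (combined
#'   least-squares residual).
#' @export
best_rotation <- function(a, b, assignment = seq_len(nrow(a))) {
  a <- as.matrix(a); b <- as.matrix(b)[assignment, , drop = FALSE]
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  H <- t(a) %*% b
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  LSc <- sum((a %*% t(R) - b)^2)
  list(rotation = R, LSc = LSc)
}

#' Match conformational to structural states over all 24 assignments
#'
#' Evaluates [best_rotation()] for every permutation assigning the four
#' conformational states to the four structural states and ranks assignments
#' by `1/LSc` (descending).
#'
#' @param conformational 4 x 3 matrix of unit vectors (rows C1..C4).
#' @param structural 4 x 3 matrix of unit vectors; row names (e.g.
#'   `E_O, E_X, I_O, I_X`) label the ranked assignments.
#' @return Data.frame with one row per assignment: `assignment` (labels of
#'   the structural state matched to C1..C4), `LSc`, `inv_LSc`, `best`
#'   flagging the top-ranked row; attribute `rotation` holds the best
#'   rotation.
#' @export
match_states <- function(conformational, structural) {
  a <- as.matrix(conformational); b <- as.matrix(structural)
  stopifnot(nrow(a) == 4, nrow(b) == 4)
  labels <- rownames(b)
  if (is.null(labels)) labels <- paste0("S", 1:4)
  perms <- all_permutations(4)
  res <- lapply(seq_len(nrow(perms)), function(r) {
    fit <- best_rotation(a, b, assignment = perms[r, ])
    data.frame(assignment = paste(labels[perms[r, ]], collapse = ","),
               LSc = fit$LSc, inv_LSc = 1 / fit$LSc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ord <- order(out$LSc)
  out <- out[ord, ]
  out$best <- seq_len(nrow(out)) == 1
  rownames(out) <- NULL
  attr(out, "rotation") <- best_rotation(a, b, perms[ord[1], ])$rotation
  attr(out, "best_permutation") <- perms[ord[1], ]
  out
}

#' Read a labelled vector set from a data.frame
#'
#' Accepts either Cartesian columns `x, y, z` or spherical columns
#' `theta_deg, phi_deg`; vectors are normalized to unit length.
#'
#' @param df Data.frame with a `label` column plus coordinates.
#' @return Matrix of unit row vectors with `label` rownames.
#' @export
read_vector_set <- function(df) {
  if (all(c("x", "y", "z") %in% names(df))) {
    V <- as.matrix(df[, c("x", "y", "z")])
    V <- V / sqrt(rowSums(V^2))
  } else if (all(c("theta_deg", "phi_deg") %in% names(df))) {
    V <- sph_to_cart(df$theta_deg, df$phi_deg)
  } else {
    stop("vector set needs x/y/z or theta_deg/phi_deg columns")
  }
  rownames(V) <- df$label
  V
}
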