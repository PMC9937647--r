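# Local-frame alignment: every molecule is rotated from the laboratory frame
# into a common local frame defined by its own ordered state means. The local
# x-axis is the C1 mean direction, the x-y plane is the C1-C4 plane, so by
# construction mean phi_1 = 0 and mean theta_1 = theta_4 = 90 degrees. In
# this frame, events of the same state pooled across molecules form a single
# distribution regardless of how each molecule sat on the coverslip.

#' Build the local frame of a molecule from its ordered state means
#'
#' `X = V1/|V1|`, `Y` is the component of `V4` orthogonal to `X`
#' (normalized), `Z = X x Y`.
#'
#' @param model A `state_model` with 4 ordered states, or a 4 x 3 matrix of
#'   ordered state mean vectors.
#' @return Object of class `local_frame`: 3 x 3 matrix with rows X, Y, Z
#'   (unit vectors in lab coordinates, right-handed).
#' @export
build_local_frame <- function(model) {
  V <- if (inherits(model, "state_model")) model$means else as.matrix(model)
  stopifnot(nrow(V) >= 2)
  V1 <- V[1, ]; VM <- V[nrow(V), ]
  X <- unit(V1)
  c1 <- cross3(X, VM)
  if (sqrt(sum(c1^2)) < 1e-9) {
    stop("degenerate frame: C1 and C4 directions are (anti)parallel")
  }
  Y <- unit(cross3(c1, X))
  Z <- unit(cross3(X, Y))
  F <- rbind(X = X, Y = Y, Z = Z)
  class(F) <- c("local_frame", class(F))
  F
}

#' Express orientations in a molecule's local frame
#'
#' `theta = acos(Z . v)` and `phi = atan2(Y . v, X . v)` (the arctangent of
#' the in-plane projection), in degrees; `phi` is reported in (-180, 180].
#'
#' @param v Unit vector (length 3) or matrix of row vectors, lab frame.
#' @param frame A [build_local_frame()] result.
#' @return Data.frame with `theta_deg`, `phi_deg`.
#' @export
to_local <- function(v, frame) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  coords <- v %*% t(unclass(frame))     # columns: X., Y., Z. components
  th <- rad2deg(acos(clamp(coords[, 3], -1, 1)))
  ph <- rad2deg(atan2(coords[, 2], coords[, 1]))
  ph <- ifelse(ph <= -180, ph + 360, ph)
  data.frame(theta_deg = th, phi_deg = ph)
}

#' Direct angle between two state orientations
#' @param v_i,v_j Unit vectors.
#' @return Great-circle angle Omega in degrees, in [0, 180].
#' @export
direct_angle <- function(v_i, v_j) angular_distance(v_i, v_j)

#' Chord displacement of a site under a rotation
#'
#' A rotation by `omega` of a site `radius` away from the pivot moves it by
#' `2 r sin(omega/2)` along the chord: 5 and 10 degrees at 20 Angstrom give
#' 1.7 and 3.5 Angstrom.
#'
#' @param omega_deg Rotation angle, degrees.
#' @param radius Distance of the site from the rotation origin (Angstrom).
#' @return Chord displacement in the unit of `radius`.
#' @export
chord_displacement <- function(omega_deg, radius) {
  stopifnot(all(radius > 0))
  2 * radius * sin(deg2rad(omega_deg) / 2)
}

#' Pool local-frame state distributions across molecules
#'
#' Each molecule contributes its events' local-frame angles per state.
#' Pooling is event-level by default; `per_molecule = TRUE` pools the
#' per-molecule state means instead (molecule-to-molecule variation), and
#' `dwell_weighted` weights contributions by dwell time. Statistics are
#' arithmetic for theta and circular for phi.
#'
#' Because the measured dipole orientation carries a four-fold degeneracy,
#' a molecule's resolved state geometry can be the mirror image of the true
#' one, and the shortest-path indexing then runs backwards: neither the
#' handedness nor the traversal direction is observable from one molecule
#' alone. With `harmonize = TRUE` (default) each molecule is therefore
#' brought into registry with the ensemble before pooling: among the
#' candidate transformations (index reversal, local mirror, in-plane flip,
#' and their combinations), the one whose per-state local means best match
#' the running consensus is applied. This is what makes a "consistently
#' chosen" state sequence across molecules operational.
#'
#' @param molecules List; each element a list with `events` (data.frame
#'   including `theta_deg`, `phi_deg`, `dwell_ms`, `state`) and `frame`
#'   (the molecule's [build_local_frame()]). Events are embedded, rotated
#'   into the local frame, then pooled.
#' @param per_molecule Pool per-molecule means instead of events.
#' @param dwell_weighted Weight events by dwell time (default FALSE).
#' @param harmonize Reconcile per-molecule indexing direction and
#'   handedness against the ensemble consensus (default TRUE).
#' @return Data.frame: `state`, `n`, `theta_mean`, `theta_sd`, `theta_sem`,
#'   `phi_mean`, `phi_sd`, `phi_sem`.
#' @export
pool_ensemble <- function(molecules, per_molecule = FALSE,
                          dwell_weighted = FALSE, harmonize = TRUE) {
  locals <- list()
  for (m in molecules) {
    if (is.null(m$frame)) next
    V <- embed_events(m$events$theta_deg, m$events$phi_deg)
    loc <- to_local(V, m$frame)
    loc$state <- m$events$state
    loc$w <- if (dwell_weighted) m$events$dwell_ms else rep(1, nrow(loc))
    locals[[length(locals) + 1]] <- loc
  }
  if (harmonize && length(locals) > 1) locals <- harmonize_variants(locals)$locals
  samples <- list()
  for (loc in locals) {
    if (per_molecule) {
      loc <- do.call(rbind, lapply(split(loc, loc$state), function(d) {
        data.frame(theta_deg = stats::weighted.mean(d$theta_deg, d$w),
                   phi_deg = circular_mean(d$phi_deg, 360, d$w),
                   state = d$state[1],
                   w = if (dwell_weighted) sum(d$w) else 1)
      }))
    }
    samples[[length(samples) + 1]] <- loc
  }
  all <- do.call(rbind, samples)
  out <- do.call(rbind, lapply(split(all, all$state), function(d) {
    n <- nrow(d)
    w <- d$w / sum(d$w)
    tm <- sum(w * d$theta_deg)
    tsd <- if (n > 1) sqrt(sum(w * (d$theta_deg - tm)^2) * n / (n - 1)) else NA_real_
    pm <- circular_mean(d$phi_deg, 360, d$w)
    psd <- circular_sd(d$phi_deg, 360, d$w)
    data.frame(state = d$state[1], n = n, theta_mean = tm, theta_sd = tsd,
               theta_sem = tsd / sqrt(n), phi_mean = pm, phi_sd = psd,
               phi_sem = psd / sqrt(n))
  }))
  rownames(out) <- NULL
  out
}

# Reconcile per-molecule local-frame data against an ensemble consensus.
# Candidate transforms, expressed directly on local (theta, phi):
#   identity; mirror (theta -> 180 - theta); reversal (relabel i <-> k+1-i,
#   theta -> 180 - theta, phi -> phi_k - phi); and reversal + mirror.
# The reversal formulas follow from rebuilding the frame with V1 and Vk
# exchanged, which rotates the x-axis onto Vk and flips the local z.
# Returns the chosen variant per molecule alongside the transformed data.
harmonize_variants <- function(locals) {
  k <- max(vapply(locals, function(d) max(d$state), numeric(1)))
  # variant "<r><a>": r = relabel states i -> k+1-i (1) or not (0);
  # a = angle op: I (none), T (theta -> 180 - theta), P (in-plane flip
  # phi -> phi_k - phi about the end state), TP (both). The physical index
  # reversal is "1TP"; the mirror-resolved molecule is "0T".
  variant_set <- c("0I", "0T", "0P", "0TP", "1I", "1T", "1P", "1TP")
  apply_variant <- function(d, variant) {
    out <- d
    relabel <- substr(variant, 1, 1) == "1"
    ang <- substring(variant, 2)
    if (relabel) out$state <- k + 1 - d$state
    if (ang %in% c("P", "TP")) {
      phik <- circular_mean(out$phi_deg[out$state == k],
                            360, out$w[out$state == k])
      out$phi_deg <- (phik - out$phi_deg) %% 360
    }
    if (ang %in% c("T", "TP")) out$theta_deg <- 180 - out$theta_deg
    # re-normalize to the frame convention: mean phi of state 1 at zero
    phi1 <- circular_mean(out$phi_deg[out$state == 1], 360,
                          out$w[out$state == 1])
    out$phi_deg <- (out$phi_deg - phi1) %% 360
    out
  }
  state_means <- function(d) {
    V <- embed_events(d$theta_deg, d$phi_deg) * d$w
    t(vapply(seq_len(k), function(s) {
      m <- colSums(V[d$state == s, , drop = FALSE])
      n <- sqrt(sum(m^2))
      if (n < 1e-12) rep(NA_real_, 3) else m / n
    }, numeric(3)))
  }
  variants <- variant_set
  ord <- order(-vapply(locals, nrow, numeric(1)))
  consensus <- state_means(locals[[ord[1]]])
  chosen <- rep("0I", length(locals))
  for (pass in 1:2) {
    acc <- matrix(0, k, 3)
    for (i in ord) {
      d <- locals[[i]]
      best <- "0I"; best_d <- Inf
      for (v in variants) {
        sm <- state_means(apply_variant(d, v))
        ok <- stats::complete.cases(sm) & stats::complete.cases(consensus)
        if (!any(ok)) next
        dist <- sum(angular_distance(sm[ok, , drop = FALSE],
                                     consensus[ok, , drop = FALSE]))
        if (dist < best_d) { best_d <- dist; best <- v }
      }
      chosen[i] <- best
      sm <- state_means(apply_variant(d, best))
      sm[!stats::complete.cases(sm), ] <- 0
      acc <- acc + sm
    }
    consensus <- acc / pmax(sqrt(rowSums(acc^2)), 1e-12)
  }
  list(locals = lapply(seq_along(locals),
                       function(i) apply_variant(locals[[i]], chosen[i])),
       variants = chosen, k = k)
}

#' Reconcile state indexing across molecules
#'
#' The four-fold orientation degeneracy makes the handedness and traversal
#' direction of a single molecule's state sequence unobservable, so the
#' shortest-path indexing of some molecules runs backwards relative to the
#' rest of the ensemble. This function registers every molecule against the
#' ensemble consensus in the local frame and relabels the reversed
#' molecules' event states (`i -> k + 1 - i`), making state identities
#' comparable across molecules — the prerequisite for pooled distributions
#' and for per-state occupancy statistics.
#'
#' @param molecules List; each element a list with `events` (including
#'   `theta_deg`, `phi_deg`, `dwell_ms`, `state`) and `frame`.
#' @return The list with corrected `events$state` and a `variant` field per
#'   molecule (see the variant codes in the source; relabeling variants
#'   start with "1").
#' @export
harmonize_molecules <- function(molecules) {
  usable <- which(vapply(molecules, function(m) !is.null(m$frame), logical(1)))
  if (length(usable) < 2) return(molecules)
  locals <- lapply(molecules[usable], function(m) {
    V <- embed_events(m$events$theta_deg, m$events$phi_deg)
    loc <- to_local(V, m$frame)
    loc$state <- m$events$state
    loc$w <- rep(1, nrow(loc))
    loc
  })
  hv <- harmonize_variants(locals)
  for (j in seq_along(usable)) {
    i <- usable[j]
    molecules[[i]]$variant <- hv$variants[j]
    if (substr(hv$variants[j], 1, 1) == "1") {
      molecules[[i]]$events$state <- hv$k + 1 - molecules[[i]]$events$state
      if (!is.null(molecules[[i]]$model)) {
        md <- molecules[[i]]$model
        rev_idx <- rev(seq_len(md$k))
        md$means <- md$means[rev_idx, , drop = FALSE]
        md$sigma_deg <- md$sigma_deg[rev_idx]
        md$n <- md$n[rev_idx]
        md$assignments <- md$k + 1 - md$assignments
        molecules[[i]]$model <- md
      }
    }
  }
  molecules
}

#' Pairwise direct-angle matrix of a state model
#' @param means k x 3 matrix of state mean unit vectors.
#' @return Symmetric k x k matrix of Omega values (degrees).
#' @export
omega_matrix <- function(means) {
  k <- nrow(means)
  M <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    M[i, j] <- angular_distance(means[i, ], means[j, ])
  }
  M
}
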