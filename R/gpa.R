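# Generalized Procrustes analysis and relative warps.
#
# Full Procrustes superimposition: every configuration is centred, scaled to
# unit centroid size, and rotated to the running consensus; the consensus is
# re-estimated until it stabilizes. Shape variables are the aligned
# coordinates orthogonally projected into the tangent space at the consensus;
# relative warps are their principal components with equal landmark
# weighting (bending-energy exponent 0).

# optimal rotation of unit-size centred X onto C (both k x 2)
optimal_rotation <- function(x, cons, allow_reflection = FALSE) {
  sv <- svd(crossprod(x, cons))
  r <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(r) < 0) {
    u <- sv$u
    u[, 2] <- -u[, 2]
    r <- u %*% t(sv$v)
  }
  r
}

normalize_config <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs < .Machine$double.eps^0.5) {
    stop("degenerate configuration: all landmarks coincide")
  }
  list(conf = m / cs, cs = cs)
}

#' Generalized Procrustes superimposition
#'
#' Iteratively centres, scales to unit centroid size, and rotates all
#' configurations to a running consensus until the consensus changes by less
#' than `tol` (Frobenius norm). Centroid sizes are recorded before scaling.
#' Reflections are disallowed by default (specimens photographed in a common
#' lateral orientation); set `allow_reflection = TRUE` for mixed data.
#'
#' @param shapes A `shape_data` object (>= 2 specimens, equal landmark
#'   counts, no missing landmarks).
#' @param tol Convergence threshold on the consensus update.
#' @param max_iter Iteration cap.
#' @param allow_reflection Permit improper rotations.
#' @return The `shape_data` with `aligned`, `centroid_sizes`, and
#'   `consensus` filled in.
#' @export
gpa <- function(shapes, tol = 1e-10, max_iter = 200, allow_reflection = FALSE) {
  stopifnot(inherits(shapes, "shape_data"))
  n <- dim(shapes$coords)[1]
  k <- dim(shapes$coords)[2]
  if (n < 2) stop("need at least two specimens")
  if (anyNA(shapes$coords)) stop("missing landmarks are not supported")

  norm <- lapply(seq_len(n), function(i) normalize_config(shapes$coords[i, , ]))
  confs <- lapply(norm, `[[`, "conf")
  cs <- vapply(norm, `[[`, numeric(1), "cs")

  consensus <- confs[[1]]
  for (it in seq_len(max_iter)) {
    rotated <- lapply(confs, function(x) {
      x %*% optimal_rotation(x, consensus, allow_reflection)
    })
    new_cons <- Reduce(`+`, rotated) / n
    new_cons <- normalize_config(new_cons)$conf
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  # canonical orientation: consensus on its principal axes (proper rotation
  # only), so the alignment is invariant to a common rigid motion of the
  # raw inputs
  q <- svd(consensus)$v
  if (det(q) < 0) q[, 2] <- -q[, 2]
  cq <- consensus %*% q
  if (cq[which.max(abs(cq[, 1])), 1] < 0) q <- -q
  consensus <- consensus %*% q

  aligned <- array(NA_real_, dim(shapes$coords))
  for (i in seq_len(n)) {
    aligned[i, , ] <- confs[[i]] %*%
      optimal_rotation(confs[[i]], consensus, allow_reflection)
  }
  dimnames(aligned)[[1]] <- shapes$meta$specimen_id
  shapes$aligned <- aligned
  shapes$centroid_sizes <- cs
  shapes$consensus <- consensus
  shapes
}

#' Procrustes distance between two configurations
#'
#' Partial Procrustes distance: both configurations are centred and scaled
#' to unit centroid size, one is optimally rotated onto the other, and the
#' root summed squared difference is returned.
#'
#' @param a,b `k x 2` landmark matrices.
#' @param allow_reflection Permit improper rotations.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  na <- normalize_config(as.matrix(a))$conf
  nb <- normalize_config(as.matrix(b))$conf
  ra <- na %*% optimal_rotation(na, nb, allow_reflection)
  sqrt(sum((ra - nb)^2))
}

# tangent-space coordinates: aligned configs projected orthogonally to the
# consensus direction (vectorized; consensus has unit norm after GPA)
tangent_coords <- function(shapes) {
  n <- dim(shapes$aligned)[1]
  v <- t(vapply(seq_len(n), function(i) as.numeric(shapes$aligned[i, , ]),
                numeric(prod(dim(shapes$aligned)[2:3]))))
  cvec <- as.numeric(shapes$consensus)
  cvec <- cvec / vec_norm(cvec)
  proj <- v %*% cvec
  v - proj %*% t(cvec) + matrix(cvec, n, length(cvec), byrow = TRUE)
}

#' Relative warps (shape principal components)
#'
#' Principal components of the tangent-space shape coordinates about the
#' consensus, with uniform and non-uniform variation analysed together and
#' equal landmark weighting. The default retains seven axes, the number used
#' downstream as shape variables. Each axis is oriented so its
#' largest-magnitude loading is positive.
#'
#' @param shapes A `shape_data` after [gpa()].
#' @param n_keep Number of axes to retain (default 7).
#' @return An object of class `relative_warps`: `scores` (tibble of
#'   specimen metadata plus `RW1..RWn`), `eigenvalues` (all axes),
#'   `variance_fractions` (sum to 1 over all axes), `loadings`, `center`,
#'   and `consensus`.
#' @export
relative_warps <- function(shapes, n_keep = 7) {
  stopifnot(inherits(shapes, "shape_data"))
  if (is.null(shapes$aligned)) stop("run gpa() before relative_warps()")
  tc <- tangent_coords(shapes)
  pc <- prcomp(tc, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  rank_eff <- sum(eig > max(eig) * 1e-12)
  if (n_keep > rank_eff) {
    stop(sprintf("n_keep = %d exceeds the available rank (%d)",
                 n_keep, rank_eff))
  }
  # sign convention: largest |loading| positive per axis
  flips <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    w <- pc$rotation[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flips, `*`)
  pc$x <- sweep(pc$x, 2, flips, `*`)

  scores <- tibble::as_tibble(pc$x[, seq_len(n_keep), drop = FALSE],
                              .name_repair = "minimal")
  names(scores) <- paste0("RW", seq_len(n_keep))
  structure(list(
    scores = dplyr::bind_cols(shapes$meta, scores),
    eigenvalues = eig,
    variance_fractions = eig / sum(eig),
    loadings = pc$rotation,
    center = pc$center,
    n_keep = n_keep,
    consensus = shapes$consensus
  ), class = "relative_warps")
}

#' @export
print.relative_warps <- function(x, ...) {
  cat(sprintf("<relative_warps: %d specimens, %d axes retained (%.1f%% var)>\n",
              nrow(x$scores), x$n_keep,
              100 * sum(x$variance_fractions[seq_len(x$n_keep)])))
  invisible(x)
}
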