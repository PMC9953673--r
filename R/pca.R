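#' Rigid-body superposition of an ensemble
#'
#' Removes translation (centroid to origin) and rotation (Kabsch optimal
#' proper rotation, determinant +1, so mirror images are never matched) of
#' every frame onto a reference. With the default mean-structure reference
#' the alignment is iterated twice: align to the first frame, recompute the
#' mean, realign to it.
#'
#' @param ensemble an [ensemble()] with at least 2 frames.
#' @param reference `"mean_structure"` (default) or `"first_frame"`, or an
#'   explicit `n x 3` coordinate matrix.
#' @return The aligned [ensemble()]; metadata gains `aligned_to` and the
#'   reference coordinates in `reference_structure`.
#' @export
align_frames <- function(ensemble, reference = c("mean_structure", "first_frame")) {
  if (!inherits(ensemble, "ensemble")) stop("need an ensemble")
  explicit <- is.matrix(reference)
  if (length(ensemble$frames) < 2 && !explicit)
    stop("need at least 2 frames to align")
  if (!explicit) reference <- match.arg(reference)
  centre <- function(m) sweep(m, 2, colMeans(m))
  ref <- if (explicit) centre(reference)
         else centre(ensemble$frames[[1]]$chain_coords)
  if (degenerate_reference(ref) && !explicit) {
    warning("degenerate (collinear) reference; falling back to first_frame")
    reference <- "first_frame"
  }
  aligned <- align_to(ensemble, ref)
  if (!explicit && reference == "mean_structure") {
    for (pass in 1:2) {
      ref <- Reduce(`+`, lapply(aligned$frames, function(f) f$chain_coords)) /
        length(aligned$frames)
      if (degenerate_reference(ref)) {
        warning("degenerate (collinear) mean reference; keeping first_frame alignment")
        break
      }
      aligned <- align_to(aligned, centre(ref))
    }
  }
  aligned$metadata$aligned_to <- if (explicit) "explicit" else reference
  aligned$metadata$reference_structure <- ref
  aligned
}

degenerate_reference <- function(ref) {
  sv <- svd(centre_mat(ref))$d
  sv[2] < 1e-8 * max(sv[1], 1e-300)
}

centre_mat <- function(m) sweep(m, 2, colMeans(m))

align_to <- function(ensemble, ref_centred) {
  out <- ensemble
  out$frames <- lapply(ensemble$frames, function(f) {
    m <- centre_mat(f$chain_coords)
    f$chain_coords <- m %*% kabsch_rotation(m, ref_centred)
    f
  })
  out
}

# proper rotation R minimising || m R - ref ||_F for centred coordinates
kabsch_rotation <- function(m, ref) {
  s <- svd(t(m) %*% ref)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Principal component analysis of an aligned ensemble
#'
#' Eigendecomposition of the covariance of the flattened (3N-dimensional)
#' aligned coordinates. Components are orthonormal with non-increasing
#' eigenvalues; the sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param aligned an aligned [ensemble()] (see [align_frames()]) with at
#'   least 3 frames.
#' @param n_components number of components to retain (default all nonzero,
#'   capped at 10).
#' @return Object of class `pca_result`: `mean_structure` (n x 3),
#'   `components` (3N x k), `eigenvalues`, `explained_fraction`,
#'   `projections` (frames x 2: PC1/PC2 scores, Angstrom), `total_variance`.
#' @export
fit_pca <- function(aligned, n_components = 10) {
  if (!inherits(aligned, "ensemble")) stop("need an ensemble")
  nf <- length(aligned$frames)
  if (nf < 3) stop("need at least 3 frames for PCA")
  X <- t(vapply(aligned$frames, function(f) as.numeric(f$chain_coords),
                numeric(3 * aligned$spec$n_residues)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  eig <- sv$d^2 / (nf - 1)
  k <- min(n_components, sum(eig > max(eig[1], 0) * 1e-12), length(eig))
  k <- max(k, 2)
  comp <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {          # deterministic sign convention
    i_max <- which.max(abs(comp[, j]))
    if (comp[i_max, j] < 0) comp[, j] <- -comp[, j]
  }
  scores <- Xc %*% comp
  structure(
    list(mean_structure = matrix(mu, ncol = 3),
         components = comp,
         eigenvalues = eig[seq_len(k)],
         all_eigenvalues = eig,
         explained_fraction = eig[seq_len(k)] / sum(eig),
         projections = scores[, 1:2, drop = FALSE],
         total_variance = sum(eig),
         n_frames = nf),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d frames; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              x$n_frames, 100 * x$explained_fraction[1],
              100 * x$explained_fraction[2]))
  invisible(x)
}

#' Project another ensemble into a fitted component space
#'
#' Used for the control-in-background display: components are fitted on one
#' system and a second system is projected into the same space. Frames of
#' `other` are first superposed onto the PCA mean structure (set
#' `align = FALSE` if they already are).
#'
#' @param pca a `pca_result` from [fit_pca()].
#' @param other an [ensemble()] with the same bead count.
#' @param align superpose `other` onto `pca$mean_structure` first (default
#'   TRUE).
#' @return Numeric matrix, frames x 2 (PC1/PC2 scores).
#' @export
project_onto <- function(pca, other, align = TRUE) {
  if (!inherits(pca, "pca_result")) stop("need a pca_result")
  n <- nrow(pca$mean_structure)
  if (other$spec$n_residues != n)
    stop(sprintf("bead count mismatch: PCA fitted on %d beads, ensemble has %d",
                 n, other$spec$n_residues))
  if (align) other <- align_frames(other, reference = pca$mean_structure)
  X <- t(vapply(other$frames, function(f) as.numeric(f$chain_coords),
                numeric(3 * n)))
  Xc <- sweep(X, 2, as.numeric(pca$mean_structure))
  (Xc %*% pca$components)[, 1:2, drop = FALSE]
}

#' Area of the occupied PC1-PC2 region
#'
#' Convex-hull area of a score cloud; used to compare how much conformational
#' space two conditions occupy in a shared component space.
#'
#' @param scores frames x 2 matrix of PC scores.
#' @return Area in Angstrom^2.
#' @export
pc_area <- function(scores) {
  h <- grDevices::chull(scores[, 1], scores[, 2])
  xy <- scores[h, , drop = FALSE]
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}
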