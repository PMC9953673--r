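#' Radius of gyration of a single frame
#'
#' Root-mean-square distance of the chain beads from their centroid, with
#' uniform bead weights; ions are excluded.
#'
#' @param frame a [frame()] object, or a bare `n x 3` coordinate matrix.
#' @return Rg in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(make_rod(poly_chain("D"))$frames[[1]])
radius_of_gyration <- function(frame) {
  coords <- if (inherits(frame, "frame")) frame$chain_coords else as.matrix(frame)
  if (nrow(coords) < 2) stop("need at least 2 beads")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  centred <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centred^2)))
}

#' End-to-end distance of a single frame
#'
#' @param frame a [frame()] object or coordinate matrix.
#' @return Euclidean distance between the first and last bead, Angstrom.
#' @export
end_to_end <- function(frame) {
  coords <- if (inherits(frame, "frame")) frame$chain_coords else as.matrix(frame)
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}

#' Per-frame Rg time series with summary statistics
#'
#' Computes Rg for every frame in order and attaches the summary used for the
#' violin-style distribution displays: mean, standard deviation and the
#' 5/25/50/75/95% quantiles.
#'
#' @param ensemble an [ensemble()].
#' @return Object of class `rg_series`: list with `values`, `frame_indices`,
#'   `spacing`, `spacing_unit` and `summary`.
#' @export
rg_series <- function(ensemble) {
  if (!inherits(ensemble, "ensemble")) stop("need an ensemble")
  check_chain_whole(ensemble)
  vals <- vapply(ensemble$frames, radius_of_gyration, numeric(1))
  idx <- vapply(ensemble$frames, function(f) f$frame_index, integer(1))
  structure(
    list(values = vals, frame_indices = idx,
         spacing = frame_spacing_of(ensemble),
         spacing_unit = ensemble$metadata$spacing_unit %||% "frame",
         summary = series_summary(vals)),
    class = "rg_series"
  )
}

series_summary <- function(vals) {
  list(mean = mean(vals),
       sd = if (length(vals) > 1) sd(vals) else NA_real_,
       quantiles = quantile(vals, c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE))
}

#' @export
print.rg_series <- function(x, ...) {
  cat(sprintf("<rg_series> %d frames: mean Rg %.2f A (sd %.2f), median %.2f A\n",
              length(x$values), x$summary$mean, x$summary$sd,
              x$summary$quantiles[["50%"]]))
  invisible(x)
}

#' @export
as.data.frame.rg_series <- function(x, ...) {
  data.frame(frame_index = x$frame_indices, rg = x$values)
}

# imported ensembles must hold a whole (unwrapped) chain: any virtual bond
# longer than half the box indicates wrapping the analyses cannot undo
check_chain_whole <- function(ensemble) {
  box <- ensemble$frames[[1]]$box_edge
  for (f in ensemble$frames) {
    b <- diff_rows(f$chain_coords)
    if (any(sqrt(rowSums(b^2)) > box / 2))
      stop("chain appears wrapped across the periodic box (bond > box_edge/2); ",
           "unwrap the trajectory before analysis")
  }
  invisible(TRUE)
}

diff_rows <- function(m) m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
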