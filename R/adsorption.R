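#' Count ions adsorbed on the chain in one frame
#'
#' An ion is adsorbed when its minimum-image centre-to-centre distance to the
#' nearest chain bead is less than or equal to the cutoff (boundary
#' inclusive). The conventional cutoff is 4 Angstrom.
#'
#' @param frame a [frame()].
#' @param cutoff adsorption distance, Angstrom (> 0).
#' @param species_filter `"all"`, `"cations"`, `"anions"`, or an integer
#'   vector of valences to count.
#' @return Integer count.
#' @export
count_adsorbed <- function(frame, cutoff = 4.0, species_filter = "all") {
  stopifnot(cutoff > 0)
  ions <- frame$ions
  if (nrow(ions) == 0) return(0L)
  keep <- ion_filter(ions$valence, species_filter)
  if (!any(keep)) return(0L)
  pos <- as.matrix(ions[keep, c("x", "y", "z")])
  sum(min_image_min_dist(pos, frame$chain_coords, frame$box_edge) <= cutoff)
}

ion_filter <- function(valence, species_filter) {
  if (is.numeric(species_filter)) return(valence %in% species_filter)
  switch(match.arg(species_filter, c("all", "cations", "anions")),
         all = rep(TRUE, length(valence)),
         cations = valence > 0,
         anions = valence < 0)
}

# per-ion minimum over beads of the minimum-image distance
min_image_min_dist <- function(ion_pos, bead_pos, box) {
  dx <- outer(ion_pos[, 1], bead_pos[, 1], "-")
  dy <- outer(ion_pos[, 2], bead_pos[, 2], "-")
  dz <- outer(ion_pos[, 3], bead_pos[, 3], "-")
  dx <- dx - box * round(dx / box)
  dy <- dy - box * round(dy / box)
  dz <- dz - box * round(dz / box)
  r2 <- dx * dx + dy * dy + dz * dz
  sqrt(apply(r2, 1, min))
}

#' Adsorbed-ion statistics for an ensemble
#'
#' Per-frame adsorbed counts, the trajectory mean, and the joint histogram of
#' (Rg, count) used for the two-dimensional compaction-vs-adsorption
#' distributions. The default species filter counts counterions, i.e. ions
#' whose charge sign opposes the chain's net charge; for a neutral chain it
#' falls back to all ions.
#'
#' @param ensemble an [ensemble()].
#' @param cutoff adsorption cutoff, Angstrom.
#' @param species_filter `"counterions"` (default), `"all"`, `"cations"`,
#'   `"anions"`, or integer valences.
#' @param rg_breaks bin width for the Rg axis of the joint histogram,
#'   Angstrom.
#' @return Object of class `adsorption_result`: `cutoff`, `species_filter`,
#'   `per_frame_counts`, `mean_count`, `rg` (per-frame Rg), and `joint_hist`
#'   (counts matrix with `rg_edges` / `count_values`).
#' @export
adsorption_series <- function(ensemble, cutoff = 4.0,
                              species_filter = "counterions", rg_breaks = 1.0) {
  if (!inherits(ensemble, "ensemble")) stop("need an ensemble")
  filt <- species_filter
  if (identical(species_filter, "counterions")) {
    q <- chain_net_charge(ensemble$spec)
    filt <- if (q < 0) "cations" else if (q > 0) "anions" else "all"
  }
  counts <- vapply(ensemble$frames, count_adsorbed, integer(1),
                   cutoff = cutoff, species_filter = filt)
  rg <- vapply(ensemble$frames, radius_of_gyration, numeric(1))
  lo <- floor(min(rg)); hi <- ceiling(max(rg))
  if (hi <= lo) hi <- lo + rg_breaks
  rg_edges <- seq(lo, hi, by = rg_breaks)
  if (rg_edges[length(rg_edges)] < hi) rg_edges <- c(rg_edges, hi)
  count_values <- min(counts):max(counts)
  joint <- table(
    rg_bin = cut(rg, rg_edges, include.lowest = TRUE),
    count = factor(counts, levels = count_values)
  )
  structure(
    list(cutoff = cutoff, species_filter = filt,
         per_frame_counts = counts, mean_count = mean(counts), rg = rg,
         joint_hist = unclass(joint), rg_edges = rg_edges,
         count_values = count_values),
    class = "adsorption_result"
  )
}

#' @export
print.adsorption_result <- function(x, ...) {
  cat(sprintf("<adsorption_result> cutoff %.1f A, %s: mean %.3f ions/frame over %d frames\n",
              x$cutoff, x$species_filter, x$mean_count,
              length(x$per_frame_counts)))
  invisible(x)
}

#' @export
as.data.frame.adsorption_result <- function(x, ...) {
  data.frame(frame = seq_along(x$per_frame_counts),
             count = x$per_frame_counts, rg = x$rg)
}
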