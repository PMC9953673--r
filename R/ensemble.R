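#' Construct a single trajectory frame
#'
#' @param chain_coords numeric matrix, one row per bead, columns x/y/z in
#'   Angstrom.
#' @param ions data frame of ion records with columns `species`, `valence`,
#'   `diameter`, `x`, `y`, `z` (may have zero rows).
#' @param box_edge edge of the cubic periodic box, Angstrom.
#' @param frame_index integer index of the frame along the trajectory.
#' @param frame_spacing trajectory spacing per unit frame index (e.g. sweeps
#'   between stored frames for Monte Carlo data, picoseconds for imported MD).
#' @return An object of class `frame`.
#' @export
frame <- function(chain_coords, ions = empty_ions(), box_edge,
                  frame_index = 1L, frame_spacing = 1) {
  chain_coords <- as.matrix(chain_coords)
  storage.mode(chain_coords) <- "double"
  if (ncol(chain_coords) != 3) stop("chain_coords must have 3 columns")
  if (!all(is.finite(chain_coords))) stop("non-finite chain coordinates")
  ions <- validate_ions(ions)
  if (!is.numeric(box_edge) || length(box_edge) != 1 || !is.finite(box_edge))
    stop("box_edge must be a finite scalar")
  structure(
    list(chain_coords = chain_coords, ions = ions, box_edge = box_edge,
         frame_index = as.integer(frame_index), frame_spacing = frame_spacing),
    class = "frame"
  )
}

#' @rdname frame
#' @export
empty_ions <- function() {
  data.frame(species = character(0), valence = integer(0),
             diameter = numeric(0), x = numeric(0), y = numeric(0),
             z = numeric(0), stringsAsFactors = FALSE)
}

validate_ions <- function(ions) {
  if (is.null(ions)) return(empty_ions())
  required <- c("species", "valence", "diameter", "x", "y", "z")
  if (!all(required %in% names(ions)))
    stop("ion table must have columns: ", paste(required, collapse = ", "))
  if (nrow(ions) > 0) {
    if (any(ions$valence == 0)) stop("ion valence must be nonzero")
    if (any(ions$diameter <= 0)) stop("ion diameter must be positive")
    if (!all(is.finite(ions$x)) || !all(is.finite(ions$y)) || !all(is.finite(ions$z)))
      stop("non-finite ion coordinates")
  }
  ions[required]
}

#' Construct a conformational ensemble
#'
#' An ordered set of frames for one chain, with provenance metadata. All
#' frames must share the box edge and bead count, and frame indices must be
#' strictly increasing.
#'
#' @param spec a [chain_spec()].
#' @param frames list of [frame()] objects.
#' @param salt optional [salt_spec()] describing the ionic conditions.
#' @param metadata named list of provenance entries (generator, seed,
#'   parameters, `spacing_unit` such as "sweep" or "ps").
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(spec, frames, salt = NULL, metadata = list()) {
  if (!inherits(spec, "chain_spec")) stop("spec must be a chain_spec")
  if (length(frames) < 1) stop("an ensemble needs at least one frame")
  n <- spec$n_residues
  box <- frames[[1]]$box_edge
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  for (f in frames) {
    if (!inherits(f, "frame")) stop("frames must be frame objects")
    if (nrow(f$chain_coords) != n)
      stop(sprintf("frame %d has %d beads, chain_spec declares %d",
                   f$frame_index, nrow(f$chain_coords), n))
    if (f$box_edge != box) stop("all frames must share box_edge")
    if (f$box_edge <= 2 * spec$bond_length)
      stop("box_edge must exceed 2 * bond_length")
  }
  if (any(diff(idx) <= 0)) stop("frame_index must be strictly increasing")
  if (is.null(metadata$spacing_unit)) metadata$spacing_unit <- "frame"
  structure(list(spec = spec, salt = salt, frames = frames,
                 metadata = metadata),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d beads, box %g A, source: %s\n",
              length(x$frames), x$spec$n_residues, x$frames[[1]]$box_edge,
              x$metadata$generator %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in an ensemble
#' @param ensemble an [ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Chain coordinates as a 3-d array
#'
#' Stacks all frames into an `n_residues x 3 x n_frames` array; the workhorse
#' layout for the vectorised analyses.
#'
#' @param ensemble an [ensemble()].
#' @return numeric array.
#' @export
coords_array <- function(ensemble) {
  n <- ensemble$spec$n_residues
  f <- length(ensemble$frames)
  a <- array(0, dim = c(n, 3, f))
  for (k in seq_len(f)) a[, , k] <- ensemble$frames[[k]]$chain_coords
  a
}

frame_spacing_of <- function(ensemble) ensemble$frames[[1]]$frame_spacing

# single-frame ensembles come up a lot in the generators
single_frame_ensemble <- function(spec, coords, box_edge, metadata) {
  ensemble(spec,
           list(frame(coords, box_edge = box_edge, frame_index = 1L)),
           metadata = metadata)
}
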