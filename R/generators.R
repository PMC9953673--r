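#' Perfectly straight reference chain
#'
#' Single-frame ensemble with all beads collinear and equally spaced at the
#' bond length: the analytic extended-conformation limit with internal
#' scaling exponent exactly 1.
#'
#' @param spec a [chain_spec()].
#' @return An [ensemble()] with one frame and no ions.
#' @export
#' @examples
#' rod <- make_rod(poly_chain("GS"))
#' radius_of_gyration(rod$frames[[1]])  # b * sqrt((N^2 - 1) / 12)
make_rod <- function(spec) {
  n <- spec$n_residues
  b <- spec$bond_length
  coords <- cbind(b * (seq_len(n) - 1), 0, 0)
  single_frame_ensemble(spec, coords, box_edge = max(4 * b, 2.5 * n * b),
                        metadata = list(generator = "rod"))
}

#' Compact space-filling reference chain
#'
#' Beads laid along a 3-d Hilbert-curve Hamiltonian path through an
#' `n_side^3` cubic lattice with nearest-neighbour steps of one bond length.
#' This is the analytic compact limit: internal distances grow as the cube
#' root of sequence separation, so the fitted scaling exponent is ~1/3.
#'
#' @param n_side lattice edge in sites; must be a power of two in 2..16.
#' @param bond_length lattice spacing, Angstrom.
#' @return Single-frame [ensemble()] of `n_side^3` neutral beads.
#' @export
make_compact <- function(n_side, bond_length = 3.8) {
  if (!(n_side %in% c(2, 4, 8, 16)))
    stop("n_side must be one of 2, 4, 8, 16")
  n <- n_side^3
  xyz <- hilbert3d(n_side)                # lattice coordinates, 0-based
  coords <- xyz * bond_length
  spec <- chain_spec(rep("G", n), bead_charge = 0,
                     bond_length = bond_length, bead_diameter = bond_length)
  single_frame_ensemble(spec, coords,
                        box_edge = max(4 * bond_length, 3 * n_side * bond_length),
                        metadata = list(generator = "compact_hilbert",
                                        n_side = n_side))
}

# 3-d Hilbert curve by Skilling's transpose algorithm: maps the curve index
# 0..n_side^3-1 to lattice coordinates such that consecutive indices are
# nearest neighbours. Returns an n x 3 integer matrix.
hilbert3d <- function(n_side) {
  b <- as.integer(round(log2(n_side)))
  ndim <- 3L
  n <- n_side^3
  out <- matrix(0L, n, 3)
  for (d in 0:(n - 1)) {
    # distribute the 3b bits of d round-robin (MSB first) into X[1..3]
    X <- integer(3)
    bits <- as.integer(intToBits(d))[seq_len(ndim * b)]  # LSB first
    bits <- rev(bits)                                    # MSB first
    for (k in seq_along(bits)) {
      dim_k <- ((k - 1) %% ndim) + 1
      X[dim_k] <- bitwOr(bitwShiftL(X[dim_k], 1), bits[k])
    }
    # Gray decode
    t <- bitwShiftR(X[ndim], 1)
    for (i in ndim:2) X[i] <- bitwXor(X[i], X[i - 1])
    X[1] <- bitwXor(X[1], t)
    # undo excess work
    Q <- 2L
    while (Q != bitwShiftL(1L, b)) {
      P <- Q - 1L
      for (i in ndim:1) {
        if (bitwAnd(X[i], Q) != 0) {
          X[1] <- bitwXor(X[1], P)
        } else {
          t <- bitwAnd(bitwXor(X[1], X[i]), P)
          X[1] <- bitwXor(X[1], t)
          X[i] <- bitwXor(X[i], t)
        }
      }
      Q <- bitwShiftL(Q, 1L)
    }
    out[d + 1, ] <- X
  }
  out
}

#' Freely jointed chain sampler
#'
#' Independent ideal-chain conformations: successive bond vectors are uniform
#' on the sphere with fixed length and no excluded volume, giving the
#' random-coil reference with mean squared internal distance `b^2 * s` and
#' scaling exponent 0.5. Used as the neutral polyGS-like control ensemble.
#'
#' @param spec a [chain_spec()]; only `n_residues` and `bond_length` are used.
#' @param n_frames number of independent conformations.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @return An [ensemble()] with `n_frames` frames and no ions.
#' @export
sample_ideal_chain <- function(spec, n_frames, seed = 1L) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  n <- spec$n_residues
  b <- spec$bond_length
  box <- max(4 * b, 2.5 * n * b)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    steps <- random_unit_vectors(n - 1) * b
    cs <- apply(steps, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    coords <- rbind(c(0, 0, 0), cs)
    frames[[k]] <- frame(coords, box_edge = box, frame_index = k)
  }
  ensemble(spec, frames,
           metadata = list(generator = "ideal_chain", seed = seed,
                           spacing_unit = "frame"))
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Self-avoiding walk sampler (pivot algorithm)
#'
#' Off-lattice self-avoiding configurations with fixed bond lengths: starting
#' from a rod, random pivot moves (uniform axis and angle about a random
#' interior bead, applied to the shorter tail) are accepted when no two
#' non-bonded beads come closer than the bead diameter. Frames are stored
#' after a fixed number of accepted pivots so that successive frames are
#' essentially decorrelated.
#'
#' @param spec a [chain_spec()]; `bead_diameter` is the hard-sphere overlap
#'   distance and must be below `2 * bond_length`.
#' @param n_frames frames to store.
#' @param seed integer seed.
#' @param pivots_per_frame accepted pivots between stored frames (default:
#'   one per residue).
#' @param max_attempts_per_pivot rejection budget before giving up.
#' @return An [ensemble()] with `n_frames` frames and no ions.
#' @export
sample_saw_chain <- function(spec, n_frames, seed = 1L,
                             pivots_per_frame = spec$n_residues,
                             max_attempts_per_pivot = 200L) {
  stopifnot(n_frames >= 1)
  if (spec$bead_diameter >= 2 * spec$bond_length)
    stop("bead_diameter must be below 2 * bond_length for the pivot sampler")
  set.seed(seed)
  n <- spec$n_residues
  b <- spec$bond_length
  d2 <- spec$bead_diameter^2
  box <- max(4 * b, 2.5 * n * b)
  coords <- cbind(b * (seq_len(n) - 1), 0, 0)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    accepted <- 0L
    attempts <- 0L
    budget <- pivots_per_frame * max_attempts_per_pivot
    while (accepted < pivots_per_frame) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("pivot acceptance collapsed; use a smaller bead_diameter")
      p <- sample(2:(n - 1), 1)
      tail_side <- p > n / 2
      idx_mov <- if (tail_side) (p + 1):n else 1:(p - 1)
      rot <- random_rotation()
      moved <- sweep(coords[idx_mov, , drop = FALSE], 2, coords[p, ]) %*% rot
      moved <- sweep(moved, 2, coords[p, ], "+")
      fixed <- coords[-idx_mov, , drop = FALSE]
      if (!saw_overlap(moved, fixed, idx_mov, setdiff(seq_len(n), idx_mov), d2)) {
        coords[idx_mov, ] <- moved
        accepted <- accepted + 1L
      }
    }
    frames[[k]] <- frame(coords, box_edge = box, frame_index = k)
  }
  ensemble(spec, frames,
           metadata = list(generator = "saw_pivot", seed = seed,
                           pivots_per_frame = pivots_per_frame,
                           spacing_unit = "frame"))
}

# any non-bonded pair between the moved and fixed sets closer than sqrt(d2)?
saw_overlap <- function(moved, fixed, idx_mov, idx_fix, d2) {
  dx <- outer(moved[, 1], fixed[, 1], "-")
  dy <- outer(moved[, 2], fixed[, 2], "-")
  dz <- outer(moved[, 3], fixed[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  bonded <- abs(outer(idx_mov, idx_fix, "-")) == 1
  any(r2[!bonded] < d2)
}

random_rotation <- function() {
  axis <- random_unit_vectors(1)[1, ]
  theta <- runif(1, -pi, pi)
  rotation_matrix(axis, theta)
}

rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

#' Autocorrelated observable series with known relaxation time
#'
#' Stationary first-order autoregressive (discretised Ornstein-Uhlenbeck)
#' series: lag-`k` autocorrelation is exactly `exp(-k * spacing / tau)`, so
#' the series provides a ground truth for validating the relaxation-time
#' estimator.
#'
#' @param mean stationary mean.
#' @param variance stationary variance (> 0).
#' @param tau relaxation time in the same units as `spacing`.
#' @param n_points series length.
#' @param spacing index-to-time spacing (default 1).
#' @param seed integer seed.
#' @return Numeric vector with attributes `spacing` and `tau_true`.
#' @export
sample_ou_series <- function(mean, variance, tau, n_points, spacing = 1,
                             seed = 1L) {
  if (!is.numeric(variance) || variance <= 0) stop("variance must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  stopifnot(n_points >= 2)
  set.seed(seed)
  phi <- exp(-spacing / tau)
  innov_sd <- sqrt(variance * (1 - phi^2))
  x <- numeric(n_points)
  x[1] <- rnorm(1, mean, sqrt(variance))
  eps <- rnorm(n_points - 1, 0, innov_sd)
  for (t in 2:n_points) x[t] <- mean + phi * (x[t - 1] - mean) + eps[t - 1]
  attr(x, "spacing") <- spacing
  attr(x, "tau_true") <- tau
  x
}

#' Synthetic proteome generator
#'
#' Random protein sequences with planted homorepeat runs, for exercising the
#' repeat census on data with known ground truth. Each sequence is a random
#' background of the 20 amino acids; with probability `repeat_prob` a single
#' run from `charge_class` is planted at a random position, with run length
#' drawn uniformly from `length_range` and the first class residue (E for DE,
#' K for KR) chosen per position with probability `first_residue_prob`.
#'
#' @param n_proteins number of sequences.
#' @param length protein length in residues.
#' @param charge_class "DE" or "KR".
#' @param repeat_prob probability a protein carries a planted run.
#' @param length_range integer range of planted run lengths.
#' @param first_residue_prob per-position probability of E (or K) within runs.
#' @param seed integer seed.
#' @return Named character vector of sequences; attribute `planted` holds a
#'   data frame of the planted runs.
#' @export
sample_proteome <- function(n_proteins, length = 200,
                            charge_class = c("DE", "KR"),
                            repeat_prob = 0.5, length_range = c(10, 20),
                            first_residue_prob = 0.75, seed = 1L) {
  charge_class <- match.arg(charge_class)
  set.seed(seed)
  pair <- if (charge_class == "DE") c("E", "D") else c("K", "R")
  background <- setdiff(strsplit("ACFGHILMNPQSTVWY", "")[[1]], pair)
  seqs <- character(n_proteins)
  planted <- list()
  for (i in seq_len(n_proteins)) {
    s <- sample(background, length, replace = TRUE)
    if (runif(1) < repeat_prob) {
      run_len <- sample(length_range[1]:length_range[2], 1)
      start <- sample(seq_len(length - run_len + 1), 1)
      run <- ifelse(runif(run_len) < first_residue_prob, pair[1], pair[2])
      s[start:(start + run_len - 1)] <- run
      planted[[base::length(planted) + 1]] <-
        data.frame(protein = i, start = start - 1L, length = run_len)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("synthetic_protein_%04d", seq_len(n_proteins))
  attr(seqs, "planted") <- do.call(rbind, planted)
  seqs
}
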