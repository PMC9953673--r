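# shared fixtures and independent oracles for the test suite

tiny_spec <- function(n = 3, b = 3.8, d = 3.8, charge = 0) {
  chain_spec(rep("G", n), bead_charge = charge, bond_length = b,
             bead_diameter = d)
}

# a small hand-built ensemble with ions, for IO and adsorption tests
toy_ensemble <- function(n_frames = 2, n_beads = 3, n_ions = 2, box = 40,
                         seed = 42) {
  set.seed(seed)
  spec <- tiny_spec(n_beads)
  frames <- lapply(seq_len(n_frames), function(k) {
    coords <- cbind(3.8 * (seq_len(n_beads) - 1) + 10, 10 + k, 10)
    ions <- if (n_ions > 0) {
      data.frame(species = rep(c("NA", "CL"), length.out = n_ions),
                 valence = rep(c(1L, -1L), length.out = n_ions),
                 diameter = rep(c(2.3, 3.6), length.out = n_ions),
                 x = runif(n_ions, 0, box), y = runif(n_ions, 0, box),
                 z = runif(n_ions, 0, box), stringsAsFactors = FALSE)
    } else empty_ions()
    frame(coords, ions, box_edge = box, frame_index = k)
  })
  ensemble(spec, frames, metadata = list(generator = "toy"))
}

# brute-force rms internal distance profile: explicit loops over frames and
# residue pairs, independent of the vectorised implementation
brute_profile <- function(ens) {
  n <- ens$spec$n_residues
  seps <- seq_len(n - 1)
  vals <- numeric(length(seps))
  for (s in seps) {
    acc <- 0; cnt <- 0
    for (f in ens$frames) {
      for (i in seq_len(n - s)) {
        acc <- acc + sum((f$chain_coords[i + s, ] - f$chain_coords[i, ])^2)
        cnt <- cnt + 1
      }
    }
    vals[s] <- sqrt(acc / cnt)
  }
  data.frame(separation = seps, value = vals)
}

# brute-force adsorbed-ion count with explicit 27-image minimum distance
brute_count_adsorbed <- function(fr, cutoff, valences = NULL) {
  ions <- fr$ions
  if (nrow(ions) == 0) return(0L)
  if (!is.null(valences)) ions <- ions[ions$valence %in% valences, ]
  if (nrow(ions) == 0) return(0L)
  box <- fr$box_edge
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * box
  count <- 0L
  for (k in seq_len(nrow(ions))) {
    p <- c(ions$x[k], ions$y[k], ions$z[k])
    dmin <- Inf
    for (b in seq_len(nrow(fr$chain_coords))) {
      for (sh in seq_len(nrow(shifts))) {
        d <- sqrt(sum((p + shifts[sh, ] - fr$chain_coords[b, ])^2))
        if (d < dmin) dmin <- d
      }
    }
    if (dmin <= cutoff) count <- count + 1L
  }
  count
}

# regular-expression oracle for maximal homorepeat runs
regex_repeats <- function(sequence, charge_class, min_length) {
  pat <- if (charge_class == "DE") "[DE]+" else "[KR]+"
  m <- gregexpr(pat, sequence)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), length = integer(0)))
  len <- attr(m, "match.length")
  keep <- len >= min_length
  data.frame(start = as.integer(m[keep]) - 1L, length = len[keep])
}

random_rigid_transform <- function(coords) {
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sweep(coords %*% rot, 2, rnorm(3, sd = 20), "+")
}
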