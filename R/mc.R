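#' Salt specification
#'
#' Ionic conditions for the coarse-grained simulator: 1:1 (Na/Cl-like) or 2:1
#' (Mg/Cl2-like) salt at a molar concentration, plus neutralising counterions
#' for the chain's net charge. A concentration of 0 with a charged chain is
#' the counterion-only ("0 M") condition and requires `neutralize_chain`.
#'
#' @param concentration mol/L, >= 0.
#' @param cation_valence +1 (monovalent, "NA" species) or +2 (divalent,
#'   "MG" species).
#' @param neutralize_chain add counterions cancelling the chain net charge.
#' @param cation_diameter,anion_diameter excluded-volume diameters, Angstrom.
#'   Defaults: 2.3 (monovalent cation), 3.0 (divalent cation), 3.6 (anion).
#' @return Object of class `salt_spec`.
#' @export
#' @examples
#' salt_spec(0.125)                      # 125 mM 1:1 salt
#' salt_spec(0.125, cation_valence = 2)  # 125 mM 2:1 salt
salt_spec <- function(concentration = 0, cation_valence = 1,
                      neutralize_chain = TRUE,
                      cation_diameter = NULL, anion_diameter = 3.6) {
  if (!cation_valence %in% c(1, 2)) stop("cation_valence must be +1 or +2")
  if (concentration < 0) stop("concentration must be >= 0")
  if (is.null(cation_diameter))
    cation_diameter <- if (cation_valence == 2) 3.0 else 2.3
  structure(
    list(concentration = concentration,
         cation_valence = as.integer(cation_valence),
         anion_valence = -1L,
         neutralize_chain = isTRUE(neutralize_chain),
         cation_species = if (cation_valence == 2) "MG" else "NA",
         anion_species = "CL",
         cation_diameter = cation_diameter,
         anion_diameter = anion_diameter),
    class = "salt_spec"
  )
}

#' Monte Carlo run parameters
#'
#' @param n_sweeps total sweeps (one sweep = one attempted move per particle).
#' @param equilibration_sweeps sweeps discarded before sampling; the
#'   displacement step is auto-tuned to 30-50% acceptance during this phase
#'   and frozen afterwards.
#' @param sample_interval sweeps between stored frames.
#' @param max_displacement initial per-particle trial displacement, Angstrom.
#' @param pivot_probability probability that a trial move on a chain bead is
#'   a pivot of the shorter tail rather than a single-bead displacement.
#' @param temperature Kelvin (enters only through the Bjerrum length).
#' @param relative_permittivity dielectric constant of the implicit solvent.
#' @param coulomb_cutoff Coulomb truncation distance, Angstrom; default
#'   `box_edge / 2`, and never allowed to exceed it.
#' @param bond_stiffness harmonic bond constant, kT per Angstrom^2.
#' @param seed integer seed; identical inputs give bit-identical trajectories.
#' @return Object of class `mc_params`.
#' @export
mc_params <- function(n_sweeps = 20000, equilibration_sweeps = 4000,
                      sample_interval = 20, max_displacement = 1.0,
                      pivot_probability = 0.2, temperature = 300,
                      relative_permittivity = 78.5, coulomb_cutoff = NULL,
                      bond_stiffness = 100, seed = 1L) {
  if (n_sweeps <= equilibration_sweeps || equilibration_sweeps < 0)
    stop("need n_sweeps > equilibration_sweeps >= 0")
  if (pivot_probability < 0 || pivot_probability > 1)
    stop("pivot_probability must be in [0, 1]")
  stopifnot(sample_interval >= 1, max_displacement > 0, bond_stiffness > 0)
  structure(
    list(n_sweeps = as.integer(n_sweeps),
         equilibration_sweeps = as.integer(equilibration_sweeps),
         sample_interval = as.integer(sample_interval),
         max_displacement = max_displacement,
         pivot_probability = pivot_probability,
         temperature = temperature,
         relative_permittivity = relative_permittivity,
         coulomb_cutoff = coulomb_cutoff,
         bond_stiffness = bond_stiffness,
         seed = as.integer(seed)),
    class = "mc_params"
  )
}

#' Ion counts for a chain in a box of salt
#'
#' Whole formula units only, never breaking electroneutrality: the salt adds
#' `round(concentration * N_A * V)` units (1 cation + `z` anions for a `z`:1
#' salt); neutralising counterions are cations (for an anionic chain) or
#' anions (for a cationic chain). If the chain charge is not divisible by the
#' cation valence, the remainder is balanced with extra anions.
#'
#' @param spec a [chain_spec()].
#' @param salt a [salt_spec()].
#' @param box_edge cubic box edge, Angstrom.
#' @return list with `n_salt_units`, `n_counter_cations`, `n_counter_anions`,
#'   `n_cations`, `n_anions`, `total_charge` (always 0).
#' @export
#' @examples
#' salt_ion_counts(poly_chain("E"), salt_spec(0.125), box_edge = 75)
salt_ion_counts <- function(spec, salt, box_edge) {
  q_chain <- chain_net_charge(spec)
  if (salt$concentration == 0 && q_chain != 0 && !salt$neutralize_chain)
    stop("a charged chain at 0 M salt requires neutralize_chain = TRUE")
  v_litre <- box_edge^3 * 1e-27
  n_units <- round(salt$concentration * .AVOGADRO * v_litre)
  z <- salt$cation_valence
  n_cc <- 0L; n_ca <- 0L
  if (salt$neutralize_chain && q_chain != 0) {
    if (q_chain < 0) {
      n_cc <- as.integer(ceiling(-q_chain / z))
      n_ca <- as.integer(n_cc * z + q_chain)     # excess balanced by anions
    } else {
      n_ca <- as.integer(q_chain)
    }
  }
  n_cat <- n_units + n_cc
  n_an <- n_units * z + n_ca
  total <- q_chain + n_cat * z - n_an
  if (total != 0) stop("internal consistency error: non-neutral ion assignment")
  list(n_salt_units = n_units, n_counter_cations = n_cc,
       n_counter_anions = n_ca, n_cations = n_cat, n_anions = n_an,
       total_charge = total)
}

#' Coarse-grained explicit-ion polyelectrolyte Monte Carlo
#'
#' Metropolis Monte Carlo of a bead-spring chain plus explicit ions in a
#' cubic periodic box. The energy (in kT) is the sum of harmonic bonds,
#' Weeks-Chandler-Andersen excluded volume between all particle pairs
#' (arithmetic diameter mixing, well depth 1 kT), and pairwise Coulomb
#' `lambda_B z_i z_j / r` truncated at the Coulomb cutoff. Ion pairs and
#' ion-bead pairs use the minimum-image convention; bead-bead pairs use
#' direct distances because the chain is kept whole (its contour may exceed
#' the box). Moves are single-particle displacements and chain pivots; the
#' displacement step is tuned to 30-50% acceptance during equilibration only.
#'
#' @param spec a [chain_spec()].
#' @param salt a [salt_spec()]; ion counts follow [salt_ion_counts()].
#' @param box_edge cubic box edge, Angstrom (default 75).
#' @param params an [mc_params()].
#' @return An [ensemble()] whose metadata records all parameters, the ion
#'   bookkeeping, acceptance rates and the tuned displacement step; frame
#'   spacing is `sample_interval` with spacing unit "sweep".
#' @export
run_cg_simulation <- function(spec, salt = salt_spec(0), box_edge = 75,
                              params = mc_params()) {
  stopifnot(inherits(spec, "chain_spec"), inherits(salt, "salt_spec"),
            inherits(params, "mc_params"))
  rcut <- params$coulomb_cutoff %||% (box_edge / 2)
  if (rcut > box_edge / 2) stop("coulomb_cutoff must not exceed box_edge / 2")
  lambda_b <- bjerrum_length(params$relative_permittivity, params$temperature)
  counts <- salt_ion_counts(spec, salt, box_edge)
  nb <- spec$n_residues
  n_ion <- counts$n_cations + counts$n_anions
  charge <- c(spec$bead_charge,
              rep(salt$cation_valence, counts$n_cations),
              rep(-1, counts$n_anions))
  diam <- c(rep(spec$bead_diameter, nb),
            rep(salt$cation_diameter, counts$n_cations),
            rep(salt$anion_diameter, counts$n_anions))
  if (sum(charge) != 0) stop("internal consistency error: system not neutral")

  set.seed(params$seed)
  coords0 <- initial_configuration(nb, spec$bond_length, diam, box_edge)

  res <- mc_engine(coords0, charge, diam, nb,
                   params$bond_stiffness, spec$bond_length,
                   box_edge, lambda_b, rcut,
                   params$n_sweeps, params$equilibration_sweeps,
                   params$sample_interval, params$max_displacement,
                   params$pivot_probability)

  acc <- c(displacement = res$acc_disp, pivot = res$acc_pivot)
  warn <- !is.na(acc["displacement"]) &&
    (acc["displacement"] < 0.05 || acc["displacement"] > 0.95)
  if (warn)
    warning(sprintf("displacement acceptance %.2f outside (0.05, 0.95) after tuning",
                    acc["displacement"]))

  species <- c(rep(salt$cation_species, counts$n_cations),
               rep(salt$anion_species, counts$n_anions))
  ion_valence <- charge[-seq_len(nb)]
  ion_diam <- diam[-seq_len(nb)]
  nf <- res$n_frames
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    xk <- res$coords[, , k]
    ions <- if (n_ion > 0) {
      data.frame(species = species, valence = as.integer(ion_valence),
                 diameter = ion_diam,
                 x = xk[nb + seq_len(n_ion), 1],
                 y = xk[nb + seq_len(n_ion), 2],
                 z = xk[nb + seq_len(n_ion), 3],
                 stringsAsFactors = FALSE)
    } else empty_ions()
    frames[[k]] <- frame(xk[seq_len(nb), , drop = FALSE], ions,
                         box_edge = box_edge, frame_index = k,
                         frame_spacing = params$sample_interval)
  }
  ensemble(spec, frames, salt = salt,
           metadata = list(
             generator = "cg_monte_carlo", seed = params$seed,
             spacing_unit = "sweep",
             box_edge = box_edge, bjerrum_length = lambda_b,
             coulomb_cutoff = rcut, params = unclass(params),
             ion_counts = counts,
             acceptance = as.list(acc),
             tuned_max_displacement = res$max_disp,
             acceptance_warning = warn))
}

# chain laid out as a serpentine walk on a lattice of the bond length around
# the box centre (self-avoiding by construction, exact bond lengths); ions
# placed uniformly, resampled away from hard overlaps
initial_configuration <- function(nb, bond_length, diam, box_edge) {
  side <- ceiling(nb^(1 / 3))
  grid <- hilbert_free_serpentine(nb, side) * bond_length
  grid <- sweep(grid, 2, colMeans(grid))
  grid <- sweep(grid, 2, rep(box_edge / 2, 3), "+")
  n <- length(diam)
  coords <- matrix(0, n, 3)
  coords[seq_len(nb), ] <- grid
  if (n > nb) {
    for (i in (nb + 1):n) {
      for (try in 1:200) {
        p <- runif(3, 0, box_edge)
        d <- sweep(coords[seq_len(i - 1), , drop = FALSE], 2, p)
        d <- d - box_edge * round(d / box_edge)
        min_sep <- 0.7 * (diam[i] + diam[seq_len(i - 1)]) / 2
        if (all(rowSums(d^2) > min_sep^2)) break
      }
      coords[i, ] <- p
    }
  }
  coords
}

# boustrophedon path on a side^3 lattice, truncated to nb sites; consecutive
# sites are always nearest neighbours
hilbert_free_serpentine <- function(nb, side) {
  out <- matrix(0L, nb, 3)
  i <- 0L
  for (z in 0:(side - 1)) {
    ys <- if (z %% 2 == 0) 0:(side - 1) else (side - 1):0
    for (y in ys) {
      xs <- if ((y + z) %% 2 == 0) 0:(side - 1) else (side - 1):0
      for (x in xs) {
        i <- i + 1L
        if (i > nb) return(out)
        out[i, ] <- c(x, y, z)
      }
    }
  }
  out
}
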