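wca_energy <- function(r, sig) {
  ifelse(r < 2^(1 / 6) * sig,
         4 * ((sig / r)^12 - (sig / r)^6) + 1, 0)
}

test_that("salt ion counts use whole formula units and stay neutral", {
  spec <- poly_chain("E")                     # net charge -30
  c1 <- salt_ion_counts(spec, salt_spec(0.125), box_edge = 75)
  expect_equal(c1$n_salt_units, 32)           # round(0.125 N_A V)
  expect_equal(c1$n_counter_cations, 30)
  expect_equal(c1$total_charge, 0)
  c2 <- salt_ion_counts(spec, salt_spec(0.125, cation_valence = 2), box_edge = 75)
  expect_equal(c2$n_counter_cations, 15)      # 30 / 2
  expect_equal(c2$n_anions, 64)               # 2 per formula unit
  expect_equal(c2$total_charge, 0)
  # non-divisible chain charge balanced with an extra anion
  odd <- chain_spec(rep("D", 31), bead_charge = -1)
  c3 <- salt_ion_counts(odd, salt_spec(0, cation_valence = 2), box_edge = 75)
  expect_equal(c3$n_counter_cations, 16)
  expect_equal(c3$n_counter_anions, 1)
  expect_equal(c3$total_charge, 0)
  # cationic chain neutralised by anions
  c4 <- salt_ion_counts(poly_chain("K"), salt_spec(0), box_edge = 75)
  expect_equal(c4$n_anions, 30)
  expect_error(salt_ion_counts(spec, salt_spec(0, neutralize_chain = FALSE),
                               box_edge = 75), "neutralize_chain")
})

test_that("every generated frame is exactly charge neutral", {
  for (cfg in list(list("E", salt_spec(0)), list("K", salt_spec(0.125)),
                   list("D", salt_spec(0.125, cation_valence = 2)))) {
    ens <- run_cg_simulation(poly_chain(cfg[[1]]), cfg[[2]], box_edge = 75,
                             params = mc_params(n_sweeps = 300,
                                                equilibration_sweeps = 100,
                                                sample_interval = 50, seed = 3))
    for (f in ens$frames)
      expect_identical(sum(f$ions$valence) + sum(ens$spec$bead_charge), 0)
  }
})

test_that("identical parameters give bit-identical trajectories", {
  p <- mc_params(n_sweeps = 2000, equilibration_sweeps = 500,
                 sample_interval = 50, seed = 77)
  a <- run_cg_simulation(poly_chain("E"), salt_spec(0.125), params = p)
  b <- run_cg_simulation(poly_chain("E"), salt_spec(0.125), params = p)
  expect_identical(coords_array(a), coords_array(b))
  expect_identical(a$frames[[5]]$ions, b$frames[[5]]$ions)
  c <- run_cg_simulation(poly_chain("E"), salt_spec(0.125),
                         params = mc_params(n_sweeps = 2000,
                                            equilibration_sweeps = 500,
                                            sample_interval = 50, seed = 78))
  expect_false(identical(coords_array(a), coords_array(c)))
})

test_that("bonds stay within five thermal widths of the rest length", {
  ens <- run_cg_simulation(poly_chain("E"), salt_spec(0),
                           params = mc_params(n_sweeps = 10000,
                                              equilibration_sweeps = 2000,
                                              sample_interval = 25, seed = 5))
  thermal_width <- sqrt(1 / 100)              # sqrt(kT / k), k = 100 kT/A^2
  worst <- 0
  for (f in ens$frames) {
    d <- f$chain_coords[-1, ] - f$chain_coords[-30, ]
    worst <- max(worst, max(abs(sqrt(rowSums(d^2)) - 3.8)))
  }
  expect_lt(worst, 5 * thermal_width)
})

test_that("acceptance is tuned into a healthy band and reported", {
  ens <- run_cg_simulation(poly_chain("E"), salt_spec(0),
                           params = mc_params(n_sweeps = 6000,
                                              equilibration_sweeps = 2000,
                                              sample_interval = 50, seed = 2))
  md <- ens$metadata
  expect_gt(md$acceptance$displacement, 0.05)
  expect_lt(md$acceptance$displacement, 0.95)
  expect_true(md$tuned_max_displacement > 0.01)
  expect_false(md$acceptance_warning)
  expect_equal(md$ion_counts$n_counter_cations, 30)
  expect_error(
    run_cg_simulation(poly_chain("E"), salt_spec(0), box_edge = 75,
                      params = mc_params(coulomb_cutoff = 50)),
    "coulomb_cutoff")
})

test_that("two-bead harmonic toy samples the Boltzmann bond distribution", {
  sp <- chain_spec(c("G", "G"), bead_charge = 0, bond_length = 3.8,
                   bead_diameter = 3.8)
  ens <- run_cg_simulation(sp, salt_spec(0), box_edge = 40,
                           params = mc_params(n_sweeps = 510000,
                                              equilibration_sweeps = 10000,
                                              sample_interval = 5, seed = 12))
  r <- vapply(ens$frames, function(f)
    sqrt(sum((f$chain_coords[2, ] - f$chain_coords[1, ])^2)), numeric(1))
  expect_gte(length(r), 1e5)
  breaks <- c(0, seq(3.55, 4.2, by = 0.05), Inf)
  obs <- table(cut(r, breaks))
  # Boltzmann oracle: p(r) dr ~ r^2 exp(-u(r)) dr by numeric integration
  grid <- seq(3.0, 4.8, by = 1e-4)
  dens <- grid^2 * exp(-(0.5 * 100 * (grid - 3.8)^2 + wca_energy(grid, 3.8)))
  cdf_bin <- function(lo, hi) sum(dens[grid >= lo & grid < hi])
  expected <- vapply(seq_len(length(breaks) - 1), function(i)
    cdf_bin(max(breaks[i], 3.0), min(breaks[i + 1], 4.8)), numeric(1))
  keep <- expected / sum(expected) * length(r) >= 5
  p <- chisq.test(as.numeric(obs[keep]), p = expected[keep] / sum(expected[keep]))$p.value
  expect_gt(p, 0.01)
})

test_that("an isolated +1/-1 pair samples the screened Boltzmann distance law", {
  coords0 <- rbind(c(5, 5, 5), c(9, 5, 5))
  res <- polyion:::mc_engine(coords0, charge = c(1, -1), diam = c(2.3, 3.6),
                             n_beads = 0L, bond_k = 0, bond_r0 = 0,
                             box = 20, lambda_b = 7.1, rcut = 10,
                             n_sweeps = 600000L, equil_sweeps = 5000L,
                             sample_interval = 6L, max_disp = 2.0,
                             pivot_prob = 0)
  x <- res$coords
  d <- x[1, , ] - x[2, , ]
  d <- d - 20 * round(d / 20)
  r <- sqrt(colSums(d^2))
  lim <- 9.5
  breaks <- seq(2.7, lim, by = 0.4)
  obs <- table(cut(r[r >= breaks[1] & r < lim], breaks))
  u <- function(rr) wca_energy(rr, 2.95) + ifelse(rr <= 10, -7.1 / rr, 0)
  grid <- seq(breaks[1], lim, by = 1e-4)
  dens <- grid^2 * exp(-u(grid))
  expected <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(dens[grid >= breaks[i] & grid < breaks[i + 1]]), numeric(1))
  p <- chisq.test(as.numeric(obs), p = expected / sum(expected))$p.value
  expect_gt(p, 0.01)
})

test_that("engine equilibrium matches an independent full-energy Metropolis", {
  # tiny charged system: 6-bead anionic chain + 6 cations in a 30 A box,
  # sampled both by the engine and by a plain R Metropolis that recomputes
  # the total energy from scratch at every step
  nb <- 6; box <- 30; lb <- 7.1; rcut <- 15
  total_energy <- function(x, q, d) {
    n <- nrow(x); u <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- x[i, ] - x[j, ]
      dx <- dx - box * round(dx / box)
      r2 <- sum(dx^2); sig <- (d[i] + d[j]) / 2
      if (r2 < 2^(1 / 3) * sig^2) {
        s6 <- (sig^2 / r2)^3
        u <- u + 4 * (s6^2 - s6) + 1
      }
      if (q[i] * q[j] != 0 && r2 < rcut^2) u <- u + lb * q[i] * q[j] / sqrt(r2)
    }
    for (i in 1:(nb - 1)) {
      r <- sqrt(sum((x[i, ] - x[i + 1, ])^2))
      u <- u + 0.5 * 100 * (r - 3.8)^2
    }
    u
  }
  set.seed(1)
  x0 <- rbind(cbind(3.8 * (0:5) + 8, 12, 12), matrix(runif(18, 5, 25), 6, 3))
  q <- c(rep(-1, 6), rep(1, 6)); d <- c(rep(3.8, 6), rep(2.3, 6))
  set.seed(2)
  res <- polyion:::mc_engine(x0, q, d, 6L, 100, 3.8, box, lb, rcut,
                             50000L, 5000L, 10L, 1.0, 0.25)
  e_engine <- apply(res$coords, 3, total_energy, q = q, d = d)
  set.seed(3)
  x <- x0; e <- total_energy(x, q, d); es <- numeric(0)
  for (sweep in 1:12000) {
    for (m in 1:12) {
      i <- sample(12, 1)
      xn <- x; xn[i, ] <- x[i, ] + runif(3, -0.9, 0.9)
      if (i > nb) xn[i, ] <- xn[i, ] - box * floor(xn[i, ] / box)
      en <- total_energy(xn, q, d)
      if (runif(1) < exp(min(0, e - en))) { x <- xn; e <- en }
    }
    if (sweep > 3000 && sweep %% 9 == 0) es <- c(es, e)
  }
  expect_lt(abs(mean(e_engine) - mean(es)), 0.5)   # kT
  expect_lt(abs(sd(e_engine) - sd(es)), 1.0)
})

test_that("a neutral chain reproduces self-avoiding-walk statistics", {
  sp <- chain_spec(rep("G", 30), bead_charge = 0, bond_length = 3.8,
                   bead_diameter = 3.8)
  mc <- run_cg_simulation(sp, salt_spec(0), box_edge = 75,
                          params = mc_params(n_sweeps = 30000,
                                             equilibration_sweeps = 5000,
                                             sample_interval = 100,
                                             pivot_probability = 0.3, seed = 6))
  rg_mc <- rg_series(mc)$values
  rg_saw <- rg_series(sample_saw_chain(sp, 250, seed = 7))$values
  tt <- t.test(rg_mc, rg_saw)
  expect_gt(tt$p.value, 0.01)
  # scaling exponents agree too
  nu_mc <- flory_exponent(mc)$nu
  nu_saw <- flory_exponent(sample_saw_chain(sp, 400, seed = 8))$nu
  expect_lt(abs(nu_mc - nu_saw), 0.05)
})
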