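test_that("rod geometry matches the collinear closed forms", {
  sp <- poly_chain("D")                      # N = 30, b = 3.8
  rod <- make_rod(sp)
  expect_equal(n_frames(rod), 1)
  f <- rod$frames[[1]]
  expect_equal(radius_of_gyration(f), 3.8 * sqrt((30^2 - 1) / 12),
               tolerance = 1e-12)
  prof <- internal_distance_profile(rod)
  expect_equal(prof$value, 3.8 * prof$separation, tolerance = 1e-12)
  two <- make_rod(tiny_spec(2))
  expect_equal(radius_of_gyration(two$frames[[1]]), 3.8 / 2, tolerance = 1e-12)
})

test_that("hilbert path is a nearest-neighbour Hamiltonian path on the lattice", {
  for (n_side in c(2, 4, 8)) {
    ens <- make_compact(n_side, bond_length = 1)
    xyz <- ens$frames[[1]]$chain_coords
    expect_equal(nrow(xyz), n_side^3)
    # visits every lattice site exactly once
    expect_equal(nrow(unique(as.data.frame(xyz))), n_side^3)
    expect_true(all(xyz >= 0 & xyz <= n_side - 1))
    # consecutive beads are lattice neighbours
    steps <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_equal(steps, rep(1, n_side^3 - 1), tolerance = 1e-12)
  }
  expect_error(make_compact(5), "n_side")
})

test_that("compact space-filling chain scales with exponent ~1/3", {
  fit <- flory_exponent(make_compact(8, 3.8), fit_range = c(4, 64))
  expect_equal(fit$nu, 1 / 3, tolerance = 0.05)
})

test_that("freely jointed chain reproduces ideal-coil statistics", {
  sp <- poly_chain("GS")
  ens <- sample_ideal_chain(sp, n_frames = 2000, seed = 7)
  prof <- internal_distance_profile(ens)
  # E[R^2(s)] = b^2 s: rms distance at s = 9 is 3.8 * 3 = 11.4 A
  expect_equal(prof$value[9], 11.4, tolerance = 0.02 * 11.4)
  # rms end-to-end at s = N-1
  expect_equal(prof$value[29], 3.8 * sqrt(29), tolerance = 0.03 * 3.8 * sqrt(29))
  # mean Rg ~ b sqrt(N/6) for large N
  expect_equal(mean(rg_series(ens)$values), 3.8 * sqrt(30 / 6),
               tolerance = 0.03 * 3.8 * sqrt(30 / 6))
})

test_that("ideal-chain scaling exponent is 0.5 across seeds", {
  nus <- vapply(1:4, function(s) {
    flory_exponent(sample_ideal_chain(poly_chain("GS"), 1500, seed = s))$nu
  }, numeric(1))
  expect_true(all(abs(nus - 0.5) < 0.03))
})

test_that("generators are deterministic under a fixed seed", {
  a <- sample_ideal_chain(tiny_spec(10), 5, seed = 123)
  b <- sample_ideal_chain(tiny_spec(10), 5, seed = 123)
  expect_identical(coords_array(a), coords_array(b))
  a <- sample_saw_chain(tiny_spec(12), 3, seed = 9)
  b <- sample_saw_chain(tiny_spec(12), 3, seed = 9)
  expect_identical(coords_array(a), coords_array(b))
  a <- sample_ou_series(5, 2, 20, 100, seed = 4)
  b <- sample_ou_series(5, 2, 20, 100, seed = 4)
  expect_identical(a, b)
})

test_that("self-avoiding walk respects the hard-core constraint and swells", {
  sp <- poly_chain("D")                       # diameter = bond = 3.8
  saw <- sample_saw_chain(sp, n_frames = 150, seed = 11)
  for (f in saw$frames) {
    d <- as.matrix(dist(f$chain_coords))
    nonbonded <- abs(row(d) - col(d)) > 1
    expect_true(all(d[nonbonded & upper.tri(d)] >= 3.8 - 1e-9))
    # bond lengths are rigid
    bonds <- d[cbind(1:29, 2:30)]
    expect_equal(bonds, rep(3.8, 29), tolerance = 1e-9)
  }
  ideal <- sample_ideal_chain(sp, n_frames = 500, seed = 11)
  expect_gt(mean(rg_series(saw)$values), mean(rg_series(ideal)$values))
})

test_that("SAW scaling exponent sits between ideal coil and rod", {
  sp60 <- chain_spec(rep("G", 60), bead_charge = 0, bond_length = 3.8,
                     bead_diameter = 3.8)
  fit <- flory_exponent(sample_saw_chain(sp60, 800, seed = 3),
                        fit_range = c(2, 30))
  expect_gt(fit$nu, 0.55)
  expect_lt(fit$nu, 0.72)
})

test_that("OU series has the declared mean, variance and lag-1 correlation", {
  tau <- 50
  x <- sample_ou_series(mean = 10, variance = 4, tau = tau, n_points = 50000,
                        seed = 21)
  # standard error of the mean for an OU series ~ sqrt(2 var tau / n)
  se_mean <- sqrt(2 * 4 * tau / 50000)
  expect_lt(abs(mean(x) - 10), 3 * se_mean)
  expect_equal(var(x), 4, tolerance = 0.15)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, exp(-1 / tau), tolerance = 0.01)
  expect_error(sample_ou_series(0, 0, 10, 100), "variance")
  expect_error(sample_ou_series(0, 1, -1, 100), "tau")
})

test_that("synthetic proteome plants recoverable repeats", {
  prot <- sample_proteome(30, length = 120, charge_class = "DE",
                          repeat_prob = 1, length_range = c(12, 15), seed = 5)
  planted <- attr(prot, "planted")
  expect_equal(nrow(planted), 30)
  for (i in seq_len(10)) {
    hits <- find_repeats(prot[[i]], "DE", min_length = 10)
    expect_gte(nrow(hits), 1)
    expect_true(planted$start[planted$protein == i] %in% hits$start)
  }
})
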