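test_that("chain_spec validates its invariants", {
  sp <- chain_spec("DDEE")
  expect_equal(sp$n_residues, 4)
  expect_equal(sp$bead_charge, rep(-1, 4))
  expect_error(chain_spec("D"), "at least 2")
  expect_error(chain_spec("DD", bond_length = 0), "bond_length")
  expect_error(chain_spec("DD", bead_charge = c(1, 2, 3)), "one value per residue")
  expect_equal(poly_chain("K")$bead_charge, rep(1, 30))
  expect_equal(sum(poly_chain("GS")$bead_charge), 0)
})

test_that("ensemble construction enforces frame consistency", {
  sp <- tiny_spec(3)
  f1 <- frame(cbind(0:2 * 3.8, 0, 0), box_edge = 40, frame_index = 1L)
  f_bad <- frame(cbind(0:3 * 3.8, 0, 0), box_edge = 40, frame_index = 2L)
  expect_error(ensemble(sp, list(f1, f_bad)), "beads")
  f2 <- frame(cbind(0:2 * 3.8, 1, 0), box_edge = 40, frame_index = 1L)
  expect_error(ensemble(sp, list(f1, f2)), "strictly increasing")
  expect_error(frame(cbind(c(0, NA), 0, 0), box_edge = 40), "finite")
})

test_that("PDB write/read round-trips frames, beads and ions", {
  ens <- toy_ensemble(n_frames = 2, n_beads = 3, n_ions = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  expect_equal(sum(substr(lines, 1, 6) == "ATOM  "), 6)      # 3 beads x 2 models
  expect_equal(sum(substr(lines, 1, 6) == "HETATM"), 6)      # 3 ions x 2 models
  back <- read_ensemble(path)
  expect_equal(n_frames(back), 2)
  for (k in 1:2) {
    expect_equal(back$frames[[k]]$chain_coords,
                 ens$frames[[k]]$chain_coords, tolerance = 1e-3)
    expect_equal(back$frames[[k]]$ions$valence, ens$frames[[k]]$ions$valence)
    expect_equal(back$frames[[k]]$ions$x, ens$frames[[k]]$ions$x,
                 tolerance = 1e-3)
  }
})

test_that("PDB reader raises structural and parse errors with context", {
  ens <- toy_ensemble(n_frames = 2, n_beads = 3, n_ions = 0)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  lines <- readLines(path)
  # drop one ATOM record from model 2
  atom_idx <- which(substr(lines, 1, 6) == "ATOM  ")
  writeLines(lines[-atom_idx[4]], path)
  expect_error(read_ensemble(path), "structural error")
  # corrupt a coordinate field
  lines2 <- readLines(path)
  lines2[atom_idx[1]] <- sub("10\\.000", "1x.y00", lines2[atom_idx[1]])
  writeLines(lines2, path)
  expect_error(read_ensemble(path), "line")
})

test_that("columnar format round-trips at full precision with metadata", {
  ens <- toy_ensemble(n_frames = 3, n_beads = 4, n_ions = 2)
  path <- withr::local_tempfile(fileext = ".trj")
  write_ensemble(ens, path, format_hint = "columnar")
  back <- read_ensemble(path, format_hint = "columnar")
  expect_equal(n_frames(back), 3)
  expect_equal(back$spec$n_residues, 4)
  expect_equal(back$spec$bond_length, ens$spec$bond_length)
  for (k in 1:3)
    expect_equal(back$frames[[k]]$chain_coords, ens$frames[[k]]$chain_coords,
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$frames[[2]]$ions$species, ens$frames[[2]]$ions$species)
})

test_that("round-trip is identity up to format precision for generator output", {
  specs <- list(tiny_spec(5), tiny_spec(8, b = 2.0, d = 1.5))
  for (i in seq_along(specs)) {
    ens <- sample_ideal_chain(specs[[i]], n_frames = 4, seed = 100 + i)
    for (fmt in c("pdb_multimodel", "columnar")) {
      path <- withr::local_tempfile(fileext = if (fmt == "columnar") ".trj" else ".pdb")
      write_ensemble(ens, path, format_hint = fmt)
      back <- read_ensemble(path, format_hint = fmt)
      expect_equal(n_frames(back), n_frames(ens))
      tol <- if (fmt == "columnar") 1e-9 else 1e-3
      for (k in seq_len(n_frames(ens)))
        expect_equal(back$frames[[k]]$chain_coords, ens$frames[[k]]$chain_coords,
                     tolerance = tol, ignore_attr = TRUE)
    }
  }
})

test_that("FASTA reading uppercases, strips whitespace and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ddee", ">p2", "DD EE", "KKRR"), path)
  seqs <- read_fasta(path)
  expect_equal(unname(seqs), c("DDEE", "DDEEKKRR"))
  expect_equal(names(seqs), c("p1", "p2"))
  writeLines(c(">bad", "DD1EE"), path)
  expect_error(read_fasta(path), "non-alphabetic")
  writeLines(character(0), path)
  expect_warning(empty <- read_fasta(path), "no FASTA records")
  expect_length(empty, 0)
})
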