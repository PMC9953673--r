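# Ensemble input/output: multi-model PDB (one CA bead per residue, ions as
# single-atom HETATM records) and a diffable columnar text format.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- structure(names(.AA3), names = unname(.AA3))

# default recognised ion residue names -> (valence, diameter)
.ION_MAP <- list("NA" = c(1, 2.3), SOD = c(1, 2.3), MG = c(2, 3.0),
                 CL = c(-1, 3.6), CLA = c(-1, 3.6))

#' Read a conformational ensemble from disk
#'
#' Supports the package's two trajectory layouts: multi-model PDB (one
#' CA-named atom per residue, ions as HETATM records recognised by residue
#' name) and the columnar text format written by [write_ensemble()].
#'
#' @param path input file.
#' @param format_hint `"pdb_multimodel"` or `"columnar"`; by default guessed
#'   from the file extension (`.pdb` vs anything else).
#' @param ion_names character vector of residue names treated as ions
#'   (default NA, CL, MG, SOD, CLA).
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path, format_hint = NULL,
                          ion_names = names(.ION_MAP)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format_hint)) {
    format_hint <- if (grepl("\\.pdb$", path, ignore.case = TRUE))
      "pdb_multimodel" else "columnar"
  }
  format_hint <- match.arg(format_hint, c("pdb_multimodel", "columnar"))
  if (format_hint == "pdb_multimodel") read_pdb_ensemble(path, ion_names)
  else read_columnar_ensemble(path)
}

#' Write a conformational ensemble to disk
#'
#' @param ensemble an [ensemble()].
#' @param path output file.
#' @param format_hint `"pdb_multimodel"` (one MODEL per frame, coordinates to
#'   PDB's 3-decimal precision) or `"columnar"` (full double precision).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format_hint = NULL) {
  if (!inherits(ensemble, "ensemble")) stop("need an ensemble")
  if (is.null(format_hint)) {
    format_hint <- if (grepl("\\.pdb$", path, ignore.case = TRUE))
      "pdb_multimodel" else "columnar"
  }
  format_hint <- match.arg(format_hint, c("pdb_multimodel", "columnar"))
  if (format_hint == "pdb_multimodel") write_pdb_ensemble(ensemble, path)
  else write_columnar_ensemble(ensemble, path)
  invisible(path)
}

write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  box <- ensemble$frames[[1]]$box_edge
  spacing <- frame_spacing_of(ensemble)
  unit <- ensemble$metadata$spacing_unit %||% "frame"
  writeLines(c(
    sprintf("REMARK 100 FRAME_SPACING %g %s", spacing, unit),
    sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
            box, box, box)), con)
  labels <- ensemble$spec$residue_labels
  res3 <- unname(.AA3[labels])
  res3[is.na(res3)] <- "UNK"
  for (f in ensemble$frames) {
    writeLines(sprintf("MODEL %8d", f$frame_index), con)
    serial <- 0L
    n <- nrow(f$chain_coords)
    lines <- character(n)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines[i] <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                          serial, " CA", res3[i], i,
                          f$chain_coords[i, 1], f$chain_coords[i, 2],
                          f$chain_coords[i, 3])
    }
    writeLines(lines, con)
    if (nrow(f$ions) > 0) {
      ion_lines <- character(nrow(f$ions))
      for (k in seq_len(nrow(f$ions))) {
        serial <- serial + 1L
        sp <- substr(f$ions$species[k], 1, 3)
        ion_lines[k] <- sprintf("HETATM%5d %-4s %-3s B%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                                serial, sp, sp, k,
                                f$ions$x[k], f$ions$y[k], f$ions$z[k])
      }
      writeLines(ion_lines, con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

read_pdb_ensemble <- function(path, ion_names) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- NA_real_
  spacing <- 1
  unit <- "frame"
  cryst <- which(rec == "CRYST1")
  if (length(cryst)) box <- pdb_num(lines[cryst[1]], 7, 15, cryst[1])
  rem <- grep("^REMARK 100 FRAME_SPACING", lines)
  if (length(rem)) {
    parts <- strsplit(trimws(sub("^REMARK 100 FRAME_SPACING", "", lines[rem[1]])),
                      "\\s+")[[1]]
    spacing <- as.numeric(parts[1])
    if (length(parts) > 1) unit <- parts[2]
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0) {
    model_bounds <- list(seq_along(lines))
    model_ids <- 1L
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("structural error: unbalanced MODEL/ENDMDL records")
    model_bounds <- Map(function(s, e) (s + 1):(e - 1), model_starts, model_ends)
    model_ids <- seq_along(model_starts)
  }
  frames <- vector("list", length(model_bounds))
  labels <- NULL
  n_ref <- NULL
  for (m in seq_along(model_bounds)) {
    idx <- model_bounds[[m]]
    atom_idx <- idx[rec[idx] %in% c("ATOM  ", "HETATM")]
    resname <- trimws(substr(lines[atom_idx], 18, 20))
    atname <- trimws(substr(lines[atom_idx], 13, 16))
    is_ion <- resname %in% ion_names
    is_bead <- !is_ion & atname == "CA"
    bead_lines <- atom_idx[is_bead]
    if (length(bead_lines) == 0)
      stop("structural error: model ", m, " has no CA bead records")
    coords <- t(vapply(bead_lines, function(li) {
      c(pdb_num(lines[li], 31, 38, li), pdb_num(lines[li], 39, 46, li),
        pdb_num(lines[li], 47, 54, li))
    }, numeric(3)))
    if (is.null(n_ref)) {
      n_ref <- nrow(coords)
      labels1 <- unname(.AA1[resname[is_bead]])
      labels1[is.na(labels1)] <- "X"
      labels <- labels1
    } else if (nrow(coords) != n_ref) {
      stop(sprintf("structural error: model %d has %d residues, model 1 has %d",
                   m, nrow(coords), n_ref))
    }
    ion_lines <- atom_idx[is_ion]
    ions <- if (length(ion_lines)) {
      sp <- resname[is_ion]
      vd <- t(vapply(sp, function(s) {
        if (!is.null(.ION_MAP[[s]])) .ION_MAP[[s]] else c(0, 3.0)
      }, numeric(2)))
      bad <- vd[, 1] == 0
      if (any(bad)) stop("unknown ion species with no valence mapping: ",
                         paste(unique(sp[bad]), collapse = ", "))
      data.frame(species = sp, valence = as.integer(vd[, 1]), diameter = vd[, 2],
                 x = vapply(ion_lines, function(li) pdb_num(lines[li], 31, 38, li), numeric(1)),
                 y = vapply(ion_lines, function(li) pdb_num(lines[li], 39, 46, li), numeric(1)),
                 z = vapply(ion_lines, function(li) pdb_num(lines[li], 47, 54, li), numeric(1)),
                 stringsAsFactors = FALSE)
    } else empty_ions()
    if (is.na(box)) box <- max(4, 2 * max(abs(coords)) + 1)
    frames[[m]] <- frame(coords, ions, box_edge = box,
                         frame_index = model_ids[m], frame_spacing = spacing)
  }
  b <- median_bond_length(frames[[1]]$chain_coords)
  spec <- chain_spec(labels, bond_length = b)
  ensemble(spec, frames,
           metadata = list(source = path, generator = "pdb_import",
                           spacing_unit = unit))
}

pdb_num <- function(line, from, to, line_no) {
  v <- suppressWarnings(as.numeric(substr(line, from, to)))
  if (is.na(v))
    stop(sprintf("parse error at line %d: expected a number in columns %d-%d",
                 line_no, from, to))
  v
}

median_bond_length <- function(coords) {
  d <- diff_rows(coords)
  stats::median(sqrt(rowSums(d^2)))
}

write_columnar_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  spec <- ensemble$spec
  writeLines(c(
    "# polyion columnar trajectory v1",
    sprintf("# box_edge %.10g", ensemble$frames[[1]]$box_edge),
    sprintf("# frame_spacing %.10g", frame_spacing_of(ensemble)),
    sprintf("# spacing_unit %s", ensemble$metadata$spacing_unit %||% "frame"),
    sprintf("# n_residues %d", spec$n_residues),
    sprintf("# bond_length %.10g", spec$bond_length),
    sprintf("# bead_diameter %.10g", spec$bead_diameter),
    sprintf("# residue_labels %s", paste(spec$residue_labels, collapse = "")),
    sprintf("# bead_charge %s", paste(spec$bead_charge, collapse = " "))), con)
  writeLines("frame_index kind species valence diameter x y z", con)
  for (f in ensemble$frames) {
    n <- nrow(f$chain_coords)
    writeLines(sprintf("%d bead %s 0 %.10g %.10g %.10g %.10g",
                       f$frame_index, spec$residue_labels,
                       spec$bead_diameter,
                       f$chain_coords[, 1], f$chain_coords[, 2],
                       f$chain_coords[, 3]), con)
    if (nrow(f$ions) > 0)
      writeLines(sprintf("%d ion %s %d %.10g %.10g %.10g %.10g",
                         f$frame_index, f$ions$species, f$ions$valence,
                         f$ions$diameter, f$ions$x, f$ions$y, f$ions$z), con)
  }
}

read_columnar_ensemble <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  get_hdr <- function(key, required = TRUE) {
    hit <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(hit)) {
      if (required) stop("columnar header missing key: ", key)
      return(NULL)
    }
    trimws(sub(paste0("^# ", key, " "), "", hit[1]))
  }
  box <- as.numeric(get_hdr("box_edge"))
  spacing <- as.numeric(get_hdr("frame_spacing"))
  unit <- get_hdr("spacing_unit")
  b <- as.numeric(get_hdr("bond_length"))
  bd <- as.numeric(get_hdr("bead_diameter"))
  labels <- strsplit(get_hdr("residue_labels"), "")[[1]]
  charges <- as.numeric(strsplit(get_hdr("bead_charge"), "\\s+")[[1]])
  tab <- tryCatch(
    read.table(path, header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE, na.strings = character(0)),
    error = function(e) stop("parse error in columnar data section: ",
                             conditionMessage(e))
  )
  needed <- c("frame_index", "kind", "species", "valence", "diameter",
              "x", "y", "z")
  if (!all(needed %in% names(tab)))
    stop("columnar data section must have columns: ",
         paste(needed, collapse = ", "))
  spec <- chain_spec(labels, bead_charge = charges, bond_length = b,
                     bead_diameter = bd)
  frames <- lapply(split(tab, tab$frame_index), function(ft) {
    beads <- ft[ft$kind == "bead", ]
    ions_t <- ft[ft$kind == "ion", ]
    if (nrow(beads) != spec$n_residues)
      stop(sprintf("structural error: frame %d has %d beads, header declares %d",
                   ft$frame_index[1], nrow(beads), spec$n_residues))
    ions <- if (nrow(ions_t)) {
      data.frame(species = ions_t$species, valence = as.integer(ions_t$valence),
                 diameter = ions_t$diameter, x = ions_t$x, y = ions_t$y,
                 z = ions_t$z, stringsAsFactors = FALSE)
    } else empty_ions()
    frame(as.matrix(beads[, c("x", "y", "z")]), ions, box_edge = box,
          frame_index = beads$frame_index[1], frame_spacing = spacing)
  })
  frames <- frames[order(vapply(frames, function(f) f$frame_index, integer(1)))]
  ensemble(spec, unname(frames),
           metadata = list(source = path, generator = "columnar_import",
                           spacing_unit = unit))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and internal whitespace is stripped; order is
#' preserved. Non-alphabetic residues raise a validation error naming the
#' offending characters.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    warning("no FASTA records found in ", path)
    return(character(0))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("\\s+", "", as.character(set)))
  offenders <- unique(unlist(strsplit(gsub("[A-Z]", "", seqs), "")))
  if (length(offenders))
    stop("non-alphabetic characters in sequences: ",
         paste(offenders, collapse = " "))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}
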