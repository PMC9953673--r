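#' Find charged homorepeats in a protein sequence
#'
#' Returns all maximal runs of residues from one charge class (D/E for
#' negatively charged repeats, K/R for positively charged ones) of at least
#' `min_length` residues. Runs are maximal: they cannot be extended on either
#' side within the class; any character outside the class alphabet, including
#' unknown ones, breaks a run.
#'
#' @param sequence character scalar, uppercase amino-acid sequence.
#' @param charge_class `"DE"` or `"KR"`.
#' @param min_length minimum run length (default 10, the conventional
#'   shortest repeat for this census).
#' @return data frame with columns `start` (0-based offset), `length`,
#'   `charge_class`, and per-residue composition counts (`n_first`,
#'   `n_second` for E/D or K/R).
#' @export
#' @examples
#' find_repeats("MEEEEEEEEEEK", "DE")       # one run of 10 E
find_repeats <- function(sequence, charge_class = c("DE", "KR"),
                         min_length = 10) {
  charge_class <- match.arg(charge_class)
  stopifnot(length(sequence) == 1, min_length >= 1)
  alphabet <- strsplit(charge_class, "")[[1]]   # c("D","E") or c("K","R")
  chars <- strsplit(toupper(sequence), "")[[1]]
  member <- chars %in% alphabet
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) {
    return(data.frame(start = integer(0), length = integer(0),
                      charge_class = character(0), n_first = integer(0),
                      n_second = integer(0), stringsAsFactors = FALSE))
  }
  first <- if (charge_class == "DE") "E" else "K"
  second <- if (charge_class == "DE") "D" else "R"
  res <- lapply(which(keep), function(i) {
    run <- chars[starts[i]:ends[i]]
    data.frame(start = starts[i] - 1L, length = r$lengths[i],
               charge_class = charge_class,
               n_first = sum(run == first), n_second = sum(run == second),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cumulative protein-count curve over repeat length thresholds
#'
#' For each length threshold `L` from `min_length` up to the longest observed
#' run, counts proteins whose qualifying runs fall at or below `L`. In the
#' default (`"up_to"`) mode a protein contributes at threshold `L` when its
#' longest maximal run `r` satisfies `min_length <= r <= L`; in `"at_least"`
#' mode it contributes when it has any run of length `>= L`. Each protein is
#' counted at most once per threshold.
#'
#' @param proteome named character vector of sequences (see [read_fasta()]).
#' @param charge_class `"DE"` or `"KR"`.
#' @param min_length shortest repeat considered (default 10).
#' @param mode `"up_to"` (default) or `"at_least"`.
#' @return Object of class `repeat_curve`: data frame `curve` (columns
#'   `threshold`, `n_proteins`), plus `charge_class`, `mode`,
#'   `total_proteins`, and the per-protein longest-run table.
#' @export
cumulative_curve <- function(proteome, charge_class = c("DE", "KR"),
                             min_length = 10, mode = c("up_to", "at_least")) {
  charge_class <- match.arg(charge_class)
  mode <- match.arg(mode)
  if (length(proteome) == 0) {
    warning("empty proteome: returning empty curve")
    return(structure(list(curve = data.frame(threshold = integer(0),
                                             n_proteins = integer(0)),
                          charge_class = charge_class, mode = mode,
                          total_proteins = 0L,
                          longest_runs = integer(0)),
                     class = "repeat_curve"))
  }
  longest <- vapply(proteome, function(s) {
    hits <- find_repeats(s, charge_class, min_length)
    if (nrow(hits) == 0) 0L else as.integer(max(hits$length))
  }, integer(1))
  max_run <- max(longest, min_length)
  thresholds <- min_length:max_run
  counts <- vapply(thresholds, function(L) {
    if (mode == "up_to") sum(longest >= min_length & longest <= L)
    else sum(longest >= L)
  }, numeric(1))
  structure(
    list(curve = data.frame(threshold = thresholds,
                            n_proteins = as.integer(counts)),
         charge_class = charge_class, mode = mode,
         total_proteins = length(proteome), longest_runs = longest),
    class = "repeat_curve"
  )
}

#' @export
print.repeat_curve <- function(x, ...) {
  with_rep <- sum(x$longest_runs > 0)
  cat(sprintf("<repeat_curve> %s (%s mode): %d / %d proteins with runs >= %d\n",
              x$charge_class, x$mode, with_rep, x$total_proteins,
              if (nrow(x$curve)) x$curve$threshold[1] else NA_integer_))
  invisible(x)
}

#' Composition ratio within homorepeat hits
#'
#' Total count of the first class residue divided by the second (E/D for DE
#' repeats, K/R for KR repeats) pooled over all hits. A zero denominator is
#' reported as `Inf` with an `infinite` flag rather than an error, since
#' all-E (or all-K) runs are legitimate.
#'
#' @param hits data frame of hits from [find_repeats()] (possibly
#'   row-bound across proteins).
#' @return list with `ratio`, `n_first`, `n_second`, `infinite`.
#' @export
composition_ratio <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) stop("no hits to summarise")
  n1 <- sum(hits$n_first)
  n2 <- sum(hits$n_second)
  list(ratio = if (n2 == 0) Inf else n1 / n2,
       n_first = n1, n_second = n2, infinite = n2 == 0)
}
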