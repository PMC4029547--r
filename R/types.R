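#' Construct a deletion call set
#'
#' A deletion call is one caller's assertion that a reference span is deleted.
#' The call size is always the interval length (`end - start`).
#'
#' @param contig,start,end interval coordinates (0-based half-open).
#' @param caller caller identifier(s); must be non-empty strings.
#' @param score optional caller-native confidence score.
#' @param ploidy optional genotype/ploidy tag (assembly callers report one).
#' @return a `data.frame` with columns `contig`, `start`, `end`, `size`,
#'   `caller`, `score`, `ploidy`.
#' @examples
#' deletion_calls("chr1", 99, 199, caller = "HC")
#' @export
deletion_calls <- function(contig, start, end, caller,
                           score = NA_real_, ploidy = NA_character_) {
  gi <- gintervals(contig, start, end)
  n <- nrow(gi)
  caller <- rep_len(as.character(caller), n)
  if (anyNA(caller) || any(!nzchar(caller))) {
    stop("every call must carry a non-empty caller identifier", call. = FALSE)
  }
  gi$size <- interval_length(gi)
  gi$caller <- caller
  gi$score <- rep_len(as.numeric(score), n)
  gi$ploidy <- rep_len(as.character(ploidy), n)
  gi
}

empty_calls <- function() {
  deletion_calls(character(), numeric(), numeric(), character())
}

#' Construct a truth (prepared SV) record set
#'
#' Truth records describe the variants injected into a simulated genome, in
#' reference coordinates. Deletions span the deleted bases; insertions are
#' anchored on a single reference base (a length-1 interval) and carry the
#' inserted sequence, whose length is the record's size.
#'
#' @param contig,start,end interval coordinates (0-based half-open).
#' @param sv_type `"DEL"` or `"INS"`.
#' @param inserted_sequence nucleotide string for insertions, `NA` for
#'   deletions.
#' @return a `data.frame` with columns `contig`, `start`, `end`, `sv_type`,
#'   `size`, `inserted_sequence`.
#' @export
truth_records <- function(contig, start, end, sv_type,
                          inserted_sequence = NA_character_) {
  gi <- gintervals(contig, start, end)
  n <- nrow(gi)
  sv_type <- rep_len(as.character(sv_type), n)
  inserted_sequence <- rep_len(as.character(inserted_sequence), n)
  if (!all(sv_type %in% c("DEL", "INS"))) {
    stop("sv_type must be 'DEL' or 'INS'", call. = FALSE)
  }
  is_ins <- sv_type == "INS"
  if (any(is_ins & (is.na(inserted_sequence) | !nzchar(inserted_sequence)))) {
    stop("INS records require an inserted_sequence", call. = FALSE)
  }
  if (any(is_ins & interval_length(gi) != 1)) {
    stop("INS records must anchor on a single base (length-1 interval)", call. = FALSE)
  }
  if (any(!is_ins & !is.na(inserted_sequence))) {
    stop("DEL records must not carry an inserted_sequence", call. = FALSE)
  }
  gi$sv_type <- sv_type
  gi$size <- ifelse(is_ins, nchar(inserted_sequence), interval_length(gi))
  gi$inserted_sequence <- inserted_sequence
  gi
}

empty_truths <- function() {
  truth_records(character(), numeric(), numeric(), character())
}

#' Define a size-bin scheme
#'
#' Bins are half-open `[low, high)` and must tile the evaluated size range
#' without gaps or overlaps. The default edges are log10-spaced, matching the
#' logarithmic size axis on which deletion-calling performance is usually
#' drawn.
#'
#' @param edges increasing numeric vector of bin edges; bin i is
#'   `[edges[i], edges[i+1])`.
#' @return a `data.frame` with columns `low`, `high`.
#' @examples
#' size_bins()  # 1-10, 10-100, ..., 1e5-1e6
#' @export
size_bins <- function(edges = c(1, 10, 100, 1000, 1e4, 1e5, 1e6)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || anyNA(edges)) stop("need at least two bin edges", call. = FALSE)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  if (edges[1] < 1) stop("sizes start at 1 bp; the first edge must be >= 1", call. = FALSE)
  data.frame(low = edges[-length(edges)], high = edges[-1])
}

#' Map sizes to bins
#'
#' @param size numeric vector of SV sizes in bp.
#' @param bins a bin scheme from [size_bins()].
#' @return integer vector of bin row indices; `NA` for sizes outside the
#'   scheme's range.
#' @export
bin_index <- function(size, bins) {
  edges <- c(bins$low, bins$high[nrow(bins)])
  idx <- findInterval(size, edges)
  idx[idx < 1L | idx > nrow(bins)] <- NA_integer_
  idx
}

#' Per-caller, per-size-bin precision priors
#'
#' The merge step resolves duplicated calls by keeping the call whose caller
#' is more precise for calls of that size, as estimated from simulation. This
#' object holds those estimates: one precision value per (caller, size range)
#' pair, plus a default for lookups that miss the table.
#'
#' @param table `data.frame` with columns `caller`, `low`, `high` (half-open
#'   size range, bp) and `precision` in `[0, 1]`.
#' @param default precision assigned to (caller, size) pairs absent from the
#'   table.
#' @return an object of class `precision_profile`.
#' @export
precision_profile <- function(table, default = 0) {
  stopifnot(is.data.frame(table),
            all(c("caller", "low", "high", "precision") %in% names(table)))
  if (nrow(table)) {
    if (any(table$precision < 0 | table$precision > 1)) {
      stop("precision values must lie in [0, 1]", call. = FALSE)
    }
    if (any(table$low < 1) || any(table$low >= table$high)) {
      stop("size ranges must satisfy 1 <= low < high", call. = FALSE)
    }
    for (cl in unique(table$caller)) {
      rows <- table[table$caller == cl, , drop = FALSE]
      rows <- rows[order(rows$low), , drop = FALSE]
      if (nrow(rows) > 1L && any(rows$low[-1] < rows$high[-nrow(rows)])) {
        stop(sprintf("overlapping size ranges for caller '%s': a size must resolve to exactly one bin", cl),
             call. = FALSE)
      }
    }
  }
  if (default < 0 || default > 1) stop("default precision must lie in [0, 1]", call. = FALSE)
  structure(list(table = table, default = default), class = "precision_profile")
}

#' Default precision priors
#'
#' Nominal >0.9 priors for the three bundled caller archetypes over the size
#' ranges where each is known to be strong: an assembly caller (`HC`) below
#' 100 bp, a split-read caller (`Pindel`) from 100 bp to 30 kb, and a
#' read-pair caller (`BD`) above 1 kb. Replace with profiles estimated from
#' your own simulations for production use.
#'
#' @return a [precision_profile()].
#' @export
default_precision_profile <- function() {
  precision_profile(data.frame(
    caller = c("HC", "Pindel", "BD"),
    low = c(1, 100, 1000),
    high = c(101, 30001, 1000001),
    precision = c(0.95, 0.93, 0.91)
  ), default = 0)
}

#' Look up the precision prior of each call
#'
#' @param calls a call set from [deletion_calls()].
#' @param profile a [precision_profile()].
#' @return numeric vector of precision priors in `[0, 1]`, the profile's
#'   default where the (caller, size) pair is not covered.
#' @export
precision_of <- function(calls, profile) {
  stopifnot(inherits(profile, "precision_profile"))
  out <- rep(profile$default, nrow(calls))
  tb <- profile$table
  if (nrow(tb)) {
    for (i in seq_len(nrow(tb))) {
      hit <- calls$caller == tb$caller[i] &
        calls$size >= tb$low[i] & calls$size < tb$high[i]
      out[hit] <- tb$precision[i]
    }
  }
  out
}
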