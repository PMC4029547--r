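#' Per-caller size-range filter specification
#'
#' Each caller is reliable only within a size range; filtering retains, per
#' caller, only calls whose size falls inside a range chosen to keep that
#' caller's precision above 90%.
#'
#' @param caller character vector of caller identifiers.
#' @param min_size,max_size inclusive size bounds in bp, one per caller.
#' @param allow_unlisted if `TRUE`, calls from callers absent from the table
#'   pass unfiltered; if `FALSE` (default) such calls are an error.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(caller, min_size, max_size, allow_unlisted = FALSE) {
  caller <- as.character(caller)
  min_size <- as.numeric(min_size)
  max_size <- as.numeric(max_size)
  stopifnot(length(caller) == length(min_size), length(caller) == length(max_size))
  if (any(min_size < 1)) stop("min_size must be >= 1 bp", call. = FALSE)
  if (any(min_size > max_size)) stop("min_size must be <= max_size", call. = FALSE)
  if (anyDuplicated(caller)) stop("one size range per caller", call. = FALSE)
  structure(list(table = data.frame(caller = caller, min_size = min_size,
                                    max_size = max_size),
                 allow_unlisted = isTRUE(allow_unlisted)),
            class = "filter_spec")
}

#' Default per-caller size ranges
#'
#' Ranges over which each bundled caller archetype keeps >90% precision:
#' the assembly caller `HC` at 1-100 bp, the split-read caller `Pindel` at
#' 100-30,000 bp, and the read-pair caller `BD` at 1,000-1,000,000 bp.
#' Bounds are inclusive and fully configurable via [filter_spec()].
#'
#' @return a `filter_spec`.
#' @export
default_filter_spec <- function() {
  filter_spec(caller = c("HC", "Pindel", "BD"),
              min_size = c(1, 100, 1000),
              max_size = c(100, 30000, 1000000))
}

#' Filter deletion calls to per-caller size ranges
#'
#' Retains exactly the calls whose caller has a range in `spec` and whose size
#' lies within it (inclusive at both ends); input order is preserved.
#'
#' @param calls a deletion call set.
#' @param spec a [filter_spec()].
#' @return the retained subset of `calls`.
#' @export
filter_calls <- function(calls, spec = default_filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!nrow(calls)) return(calls)
  tb <- spec$table
  unknown <- setdiff(unique(calls$caller), tb$caller)
  if (length(unknown) && !spec$allow_unlisted) {
    stop(sprintf("no size range configured for caller(s): %s (set allow_unlisted to pass them through)",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  m <- match(calls$caller, tb$caller)
  keep <- is.na(m) |  # unlisted and allowed
    (calls$size >= tb$min_size[m] & calls$size <= tb$max_size[m])
  calls[keep, , drop = FALSE]
}

#' Reciprocal overlap predicate
#'
#' Two calls are duplicates when they overlap each other by strictly more than
#' `fraction` of their called regions. In the default `"reciprocal"` mode both
#' calls' fractions must exceed the threshold (the BEDTools `-r` idiom); in
#' `"either"` mode one side suffices.
#'
#' @param a,b deletion call sets, paired row-wise (recycled).
#' @param fraction overlap fraction threshold in `(0, 1]`; default 2/3.
#' @param mode `"reciprocal"` (default) or `"either"`.
#' @return logical vector.
#' @examples
#' a <- deletion_calls("c1", 0, 300, "HC")
#' b <- deletion_calls("c1", 100, 400, "BD")
#' mutual_overlap_exceeds(a, b)  # FALSE: overlap 200 is not > 2/3 * 300
#' @export
mutual_overlap_exceeds <- function(a, b, fraction = 2/3,
                                   mode = c("reciprocal", "either")) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  inter <- intersect_size(a[ai, ], b[bi, ])
  fa <- inter > fraction * interval_length(a)[ai]
  fb <- inter > fraction * interval_length(b)[bi]
  if (mode == "reciprocal") fa & fb else fa | fb
}

#' Merge configuration
#'
#' @param overlap_fraction duplicate threshold in `(0, 1]`; default 2/3.
#' @param precision_profile a [precision_profile()] supplying the per-call
#'   precision priors that decide which duplicate survives.
#' @param caller_priority character vector ordering callers for tie-breaks
#'   when two duplicates have equal precision priors.
#' @param mode overlap mode passed to [mutual_overlap_exceeds()].
#' @return a list of class `merge_config`.
#' @export
merge_config <- function(overlap_fraction = 2/3,
                         precision_profile = default_precision_profile(),
                         caller_priority = c("HC", "Pindel", "BD"),
                         mode = c("reciprocal", "either")) {
  mode <- match.arg(mode)
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(inherits(precision_profile, "precision_profile"))
  structure(list(overlap_fraction = overlap_fraction,
                 precision_profile = precision_profile,
                 caller_priority = as.character(caller_priority),
                 mode = mode),
            class = "merge_config")
}

# Canonical total order over calls; makes merging invariant to input order.
canonical_order <- function(calls) {
  order(calls$contig, calls$start, calls$end, calls$caller, calls$size,
        method = "radix")
}

#' Merge call sets, removing duplicated calls by precision priority
#'
#' Pools all call sets, then repeatedly removes, from every pair of calls that
#' satisfy the reciprocal-overlap predicate, the member with the lower
#' precision prior, until no such pair remains. The sweep is fully
#' deterministic: candidate pairs are processed in decreasing order of overlap
#' size (coordinates break ties), and within a pair ties in precision are
#' broken by `caller_priority`, then smaller start, then larger size. The
#' surviving call keeps its original coordinates — duplicates are removed,
#' never averaged.
#'
#' @param callsets a single call set or a list of call sets (one per caller).
#' @param config a [merge_config()].
#' @return the unified call set, sorted by (contig, start, end), with a
#'   `precision` column holding each surviving call's prior.
#' @export
merge_callsets <- function(callsets, config = merge_config()) {
  stopifnot(inherits(config, "merge_config"))
  if (is.data.frame(callsets)) callsets <- list(callsets)
  calls <- do.call(rbind, c(callsets, list(make.row.names = FALSE)))
  if (is.null(calls) || !nrow(calls)) {
    out <- empty_calls()
    out$precision <- numeric()
    return(out)
  }
  calls <- calls[canonical_order(calls), , drop = FALSE]
  rownames(calls) <- NULL
  prec <- precision_of(calls, config$precision_profile)
  prio <- match(calls$caller, config$caller_priority)
  prio[is.na(prio)] <- length(config$caller_priority) + 1L

  pairs <- overlap_pairs(calls, calls)
  pairs <- pairs[pairs$query < pairs$subject, , drop = FALSE]
  if (nrow(pairs)) {
    dup <- mutual_overlap_exceeds(calls[pairs$query, ], calls[pairs$subject, ],
                                  config$overlap_fraction, config$mode)
    pairs <- pairs[dup, , drop = FALSE]
  }
  alive <- rep(TRUE, nrow(calls))
  if (nrow(pairs)) {
    ov <- intersect_size(calls[pairs$query, ], calls[pairs$subject, ])
    # descending overlap, then canonical pair coordinates
    ord <- order(-ov, pairs$query, pairs$subject)
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$query[k]; j <- pairs$subject[k]
      if (!alive[i] || !alive[j]) next
      loser <- pick_loser(i, j, prec, prio, calls)
      alive[loser] <- FALSE
    }
  }
  out <- calls[alive, , drop = FALSE]
  out$precision <- prec[alive]
  out <- out[order(out$contig, out$start, out$end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Which of calls i, j is removed: lower precision prior loses; ties fall to
# caller priority, then larger start (smaller start survives), then smaller
# size (larger size survives), then higher row index.
pick_loser <- function(i, j, prec, prio, calls) {
  if (prec[i] != prec[j]) return(if (prec[i] < prec[j]) i else j)
  if (prio[i] != prio[j]) return(if (prio[i] > prio[j]) i else j)
  if (calls$start[i] != calls$start[j]) {
    return(if (calls$start[i] > calls$start[j]) i else j)
  }
  if (calls$size[i] != calls$size[j]) {
    return(if (calls$size[i] < calls$size[j]) i else j)
  }
  max(i, j)
}
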