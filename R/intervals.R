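#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` (BED convention), the
#' native coordinate system of every function in this package. VCF's 1-based
#' inclusive coordinates are converted at the I/O boundary only.
#'
#' @param contig character vector of contig identifiers.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions.
#' @return a `data.frame` with columns `contig`, `start`, `end`. Zero-length
#'   intervals are rejected: a 1-bp deletion is a length-1 interval.
#' @examples
#' gi <- gintervals("chr1", 0, 100)
#' interval_length(gi)  # 100
#' @export
gintervals <- function(contig, start, end) {
  n <- max(length(contig), length(start), length(end))
  contig <- rep_len(as.character(contig), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (anyNA(contig) || any(!nzchar(contig))) {
    stop("contig identifiers must be non-empty", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end)) stop("coordinates must not be NA", call. = FALSE)
  if (any(start < 0)) stop("start coordinates must be non-negative", call. = FALSE)
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("coordinates must be whole numbers of base pairs", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start (%s) must be < end (%s); zero-length intervals are not allowed",
                 bad[1], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)), call. = FALSE)
  }
  data.frame(contig = contig, start = start, end = end, stringsAsFactors = FALSE)
}

#' Interval lengths in base pairs
#'
#' @param x a data frame with `start` and `end` columns (half-open).
#' @return numeric vector `end - start`.
#' @export
interval_length <- function(x) {
  x$end - x$start
}

#' Size of the intersection of two intervals
#'
#' Vectorised over rows (shorter input recycled). Intervals on different
#' contigs, and disjoint intervals, intersect in 0 bp.
#'
#' @param a,b interval tables as produced by [gintervals()].
#' @return non-negative numeric vector of overlap sizes in bp.
#' @examples
#' intersect_size(gintervals("c1", 0, 101), gintervals("c1", 10, 111))  # 91
#' @export
intersect_size <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov[a$contig[ai] != b$contig[bi]] <- 0
  pmax(ov, 0)
}

#' Size of the union of two intervals
#'
#' `|a| + |b| - |a intersect b|`; for intervals on different contigs this is
#' simply the sum of the two lengths.
#'
#' @inheritParams intersect_size
#' @return positive numeric vector of union sizes in bp.
#' @export
union_size <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  interval_length(a)[ai] + interval_length(b)[bi] - intersect_size(a, b)
}

# Indices of overlapping row pairs between two interval tables, computed per
# contig with an IRanges interval index. Returns a data.frame(query, subject).
overlap_pairs <- function(a, b) {
  out <- list()
  for (ctg in intersect(unique(a$contig), unique(b$contig))) {
    ia <- which(a$contig == ctg)
    ib <- which(b$contig == ctg)
    ra <- IRanges::IRanges(start = as.integer(a$start[ia]) + 1L,
                           end = as.integer(a$end[ia]))
    rb <- IRanges::IRanges(start = as.integer(b$start[ib]) + 1L,
                           end = as.integer(b$end[ib]))
    hits <- IRanges::findOverlaps(ra, rb)
    out[[ctg]] <- data.frame(query = ia[S4Vectors_queryHits(hits)],
                             subject = ib[S4Vectors_subjectHits(hits)])
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Thin indirection so the IRanges accessors resolve whether they live in
# S4Vectors or IRanges across Bioconductor versions.
S4Vectors_queryHits <- function(h) methods::slot(h, "from")
S4Vectors_subjectHits <- function(h) methods::slot(h, "to")
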