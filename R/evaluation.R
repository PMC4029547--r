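#' Evaluation configuration
#'
#' @param margin non-negative margin in bp by which every SV region is
#'   extended on both sides before overlap is scored. The margin tolerates
#'   small breakpoint deviations caused by ambiguous mapping at repeats; 50 bp
#'   is the default used throughout.
#' @param bins size-bin scheme from [size_bins()] over which precision and
#'   recall are stratified.
#' @return a list with class `evaluation_config`.
#' @export
evaluation_config <- function(margin = 50, bins = size_bins()) {
  stop_if_not_scalar_number(margin, "margin")
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  stopifnot(is.data.frame(bins), all(c("low", "high") %in% names(bins)))
  structure(list(margin = margin, bins = bins), class = "evaluation_config")
}

#' Effective region of an SV
#'
#' Extends each interval symmetrically by `margin` bp, clamping at position 0
#' and, when `contig_length` is supplied, at the contig end. A 1-bp deletion
#' with a 50 bp margin has a 101-bp effective region.
#'
#' @param x an interval table ([gintervals()] or any table with `contig`,
#'   `start`, `end`).
#' @param margin non-negative margin in bp.
#' @param contig_length optional contig length(s) in bp for right clamping;
#'   either a single value or a named vector indexed by contig.
#' @return an interval table of the same height.
#' @export
effective_region <- function(x, margin, contig_length = NULL) {
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  start <- pmax(0, x$start - margin)
  end <- x$end + margin
  if (!is.null(contig_length)) {
    len <- if (!is.null(names(contig_length))) {
      unname(contig_length[x$contig])
    } else {
      rep_len(contig_length, nrow(x))
    }
    if (anyNA(len)) stop("contig_length missing for some contigs", call. = FALSE)
    end <- pmin(end, len)
  }
  gintervals(x$contig, start, end)
}

#' Match quality between called and prepared deletions
#'
#' The quality of a (called, prepared) pair is the Jaccard index of their
#' effective regions: `size(a intersect b) / size(a union b)`, a value in
#' `[0, 1]`. It is 1 for identical regions and 0 once the effective regions
#' are disjoint (breakpoints more than `2 * margin` apart for 1-bp events).
#' Vectorised over rows; rows are paired elementwise.
#'
#' @param called deletion call set (or any interval table).
#' @param prepared truth record set; insertion records are rejected, the
#'   metric is defined for deletions only.
#' @param margin margin in bp (default 50).
#' @return numeric vector of qualities in `[0, 1]`.
#' @examples
#' # a 1-bp call 10 bp away from a 1-bp truth, margin 50: q = 91/111
#' q <- call_quality(deletion_calls("c1", 110, 111, "HC"),
#'                   truth_records("c1", 100, 101, "DEL"))
#' round(q, 1)  # 0.8
#' @export
call_quality <- function(called, prepared, margin = 50) {
  if (!is.null(prepared$sv_type) && any(prepared$sv_type != "DEL")) {
    stop("quality is defined for deletion records only; remove INS records first",
         call. = FALSE)
  }
  ea <- effective_region(called, margin)
  eb <- effective_region(prepared, margin)
  intersect_size(ea, eb) / union_size(ea, eb)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in `[0, 1]`; vectorised.
#' @return `2 * p * r / (p + r)`, 0 where `p + r == 0`, `NA` where either
#'   input is `NA`.
#' @export
f_measure <- function(precision, recall) {
  out <- ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall))
  out[is.na(precision) | is.na(recall)] <- NA_real_
  out
}

# Best-match quality for each row of `a` against any row of `b`, both already
# deletion interval tables. Only pairs whose effective regions overlap can
# score q > 0, so an interval index over effective regions finds every
# candidate maximizer; rows with no overlap get exactly 0.
best_quality <- function(a, b, margin) {
  q <- numeric(nrow(a))
  if (!nrow(a) || !nrow(b)) return(q)
  ea <- effective_region(a, margin)
  eb <- effective_region(b, margin)
  pairs <- overlap_pairs(ea, eb)
  if (nrow(pairs)) {
    inter <- intersect_size(ea[pairs$query, ], eb[pairs$subject, ])
    uni <- union_size(ea[pairs$query, ], eb[pairs$subject, ])
    qq <- inter / uni
    agg <- tapply(qq, pairs$query, max)
    q[as.integer(names(agg))] <- as.numeric(agg)
  }
  q
}

#' Size-stratified evaluation of deletion calls against a truth set
#'
#' For every size bin, precision is the mean over called deletions of that
#' size of the best match quality against *any* prepared deletion (matching is
#' independent per call, so one truth may be the best match of several calls),
#' and recall is the mirror image with calls and truths exchanged:
#' \deqn{precision(s) = \sum_{i : called, size(i)=s} \max_j q_{ij} / N(called\ size = s)}
#' \deqn{recall(s) = \sum_{j : prepared, size(j)=s} \max_i q_{ij} / N(prepared\ size = s)}
#' where \eqn{q} is [call_quality()]. Insertion truth records are excluded.
#' Bins with no calls have undefined (`NA`) precision; bins with no prepared
#' deletions have undefined recall.
#'
#' @param calls a deletion call set.
#' @param truths a truth record set (insertions are ignored).
#' @param config an [evaluation_config()].
#' @return a `data.frame` of class `svu_report` with one row per bin and
#'   columns `bin_low`, `bin_high`, `n_called`, `n_prepared`, `precision`,
#'   `recall`, `f_measure`.
#' @export
evaluate_deletions <- function(calls, truths, config = evaluation_config()) {
  stopifnot(inherits(config, "evaluation_config"))
  truths <- truths[truths$sv_type == "DEL", , drop = FALSE]
  bins <- config$bins
  n <- nrow(bins)

  call_bin <- if (nrow(calls)) bin_index(calls$size, bins) else integer()
  truth_bin <- if (nrow(truths)) bin_index(truths$size, bins) else integer()

  q_call <- best_quality(calls, truths, config$margin)   # per call, vs all truths
  q_truth <- best_quality(truths, calls, config$margin)  # per truth, vs all calls

  n_called <- tabulate(call_bin, nbins = n)
  n_prepared <- tabulate(truth_bin, nbins = n)
  sum_by_bin <- function(q, bin) {
    s <- numeric(n)
    keep <- !is.na(bin)
    if (any(keep)) {
      agg <- tapply(q[keep], bin[keep], sum)
      s[as.integer(names(agg))] <- as.numeric(agg)
    }
    s
  }
  precision <- ifelse(n_called > 0, sum_by_bin(q_call, call_bin) / n_called, NA_real_)
  recall <- ifelse(n_prepared > 0, sum_by_bin(q_truth, truth_bin) / n_prepared, NA_real_)

  out <- data.frame(
    bin_low = bins$low, bin_high = bins$high,
    n_called = n_called, n_prepared = n_prepared,
    precision = precision, recall = recall,
    f_measure = f_measure(precision, recall)
  )
  class(out) <- c("svu_report", "data.frame")
  out
}

#' Per-bin precision only
#'
#' Convenience wrapper around [evaluate_deletions()] returning the precision
#' columns.
#' @inheritParams evaluate_deletions
#' @return the report restricted to `bin_low`, `bin_high`, `n_called`,
#'   `precision`.
#' @export
precision_by_size <- function(calls, truths, config = evaluation_config()) {
  evaluate_deletions(calls, truths, config)[, c("bin_low", "bin_high", "n_called", "precision")]
}

#' Per-bin recall only
#'
#' @inheritParams evaluate_deletions
#' @return the report restricted to `bin_low`, `bin_high`, `n_prepared`,
#'   `recall`.
#' @export
recall_by_size <- function(calls, truths, config = evaluation_config()) {
  evaluate_deletions(calls, truths, config)[, c("bin_low", "bin_high", "n_prepared", "recall")]
}

#' @export
print.svu_report <- function(x, ...) {
  cat(sprintf("Deletion-call evaluation over %d size bins\n", nrow(x)))
  df <- as.data.frame(x)
  df$precision <- round(df$precision, 4)
  df$recall <- round(df$recall, 4)
  df$f_measure <- round(df$f_measure, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.svu_report <- function(x, ...) {
  mid <- sqrt(x$bin_low * x$bin_high)
  keep <- !is.na(x$f_measure)
  graphics::matplot(mid, cbind(x$precision, x$recall, x$f_measure),
                    type = "b", pch = c(1, 2, 3), lty = 1:3, log = "x",
                    xlab = "deletion size (bp)", ylab = "score", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("precision", "recall", "F-measure"),
                   pch = c(1, 2, 3), lty = 1:3, col = 1:3, bty = "n")
  invisible(x)
}

#' Write / read an evaluation report as TSV
#'
#' @param report an `svu_report`.
#' @param path output path.
#' @return `path`, invisibly (writer); an `svu_report` (reader).
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("svu_report", "data.frame")
  out
}
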