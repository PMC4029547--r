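#' Caller emulator profile
#'
#' Describes a synthetic caller: per size bin, the probability that a true
#' deletion is emitted (`recall_prob`) and the rate of spurious calls
#' (`fp_per_mb`, false calls per megabase per bin), plus Gaussian jitter on
#' the emitted breakpoint and size. Profiles calibrated to the known per-size
#' behaviour of real caller families (assembly callers strong below 100 bp,
#' split-read callers at 100 bp - 30 kb, read-pair callers above 1 kb) let the
#' filtering/merging/evaluation stack be exercised end-to-end with known
#' ground truth and no external binaries.
#'
#' @param caller caller identifier stamped on emitted calls.
#' @param bins a [size_bins()] scheme.
#' @param recall_prob per-bin emission probability, recycled to `nrow(bins)`.
#' @param fp_per_mb per-bin false-positive rate (calls per Mb), recycled.
#' @param breakpoint_jitter_sd sd (bp) of the Gaussian shift applied to the
#'   emitted start.
#' @param size_jitter_sd sd (bp) of the Gaussian perturbation of the emitted
#'   size (clamped to >= 1).
#' @param seed integer seed; emulation is deterministic under it.
#' @return a list of class `emulator_profile`.
#' @export
emulator_profile <- function(caller, bins = size_bins(), recall_prob = 1,
                             fp_per_mb = 0, breakpoint_jitter_sd = 0,
                             size_jitter_sd = 0, seed = 1L) {
  recall_prob <- rep_len(recall_prob, nrow(bins))
  fp_per_mb <- rep_len(fp_per_mb, nrow(bins))
  stopifnot(nzchar(caller), all(recall_prob >= 0 & recall_prob <= 1),
            all(fp_per_mb >= 0), breakpoint_jitter_sd >= 0, size_jitter_sd >= 0)
  structure(list(caller = caller, bins = bins, recall_prob = recall_prob,
                 fp_per_mb = fp_per_mb,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 size_jitter_sd = size_jitter_sd, seed = as.integer(seed)),
            class = "emulator_profile")
}

#' Emulate a caller's deletion calls from a truth set
#'
#' Each true deletion is emitted with its bin's `recall_prob`; the emitted
#' start is shifted by `round(Normal(0, breakpoint_jitter_sd))` and the size
#' perturbed by `round(Normal(0, size_jitter_sd))`, clamped to >= 1 bp and to
#' the contig. False positives are placed per bin as a Poisson count at
#' `fp_per_mb` over the genome, uniformly positioned, with sizes uniform
#' within the bin. Insertion truths are ignored.
#'
#' @param truths a [truth_records()] table.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param profile an [emulator_profile()].
#' @return a [deletion_calls()] table.
#' @export
emulate_calls <- function(truths, contig_lengths, profile) {
  stopifnot(inherits(profile, "emulator_profile"))
  if (is.null(names(contig_lengths))) {
    stop("contig_lengths must be named by contig", call. = FALSE)
  }
  dels <- truths[truths$sv_type == "DEL", , drop = FALSE]
  bins <- profile$bins
  with_seed(profile$seed, {
    out <- list()
    if (nrow(dels)) {
      b <- bin_index(dels$size, bins)
      p <- ifelse(is.na(b), 0, profile$recall_prob[b])
      emit <- stats::runif(nrow(dels)) < p
      em <- dels[emit, , drop = FALSE]
      if (nrow(em)) {
        clen <- unname(contig_lengths[em$contig])
        start <- em$start + round(stats::rnorm(nrow(em), 0, profile$breakpoint_jitter_sd))
        size <- pmax(1, em$size + round(stats::rnorm(nrow(em), 0, profile$size_jitter_sd)))
        start <- pmax(0, pmin(start, clen - size))
        out$tp <- deletion_calls(em$contig, start, start + size, profile$caller)
      }
    }
    genome_mb <- sum(contig_lengths) / 1e6
    for (i in seq_len(nrow(bins))) {
      n_fp <- stats::rpois(1, profile$fp_per_mb[i] * genome_mb)
      if (n_fp == 0) next
      ctg <- sample(names(contig_lengths), n_fp, replace = TRUE,
                    prob = contig_lengths)
      hi <- min(bins$high[i] - 1, max(contig_lengths))
      size <- floor(stats::runif(n_fp, bins$low[i], hi + 1))
      size <- pmin(size, unname(contig_lengths[ctg]) - 1)
      start <- floor(stats::runif(n_fp, 0, unname(contig_lengths[ctg]) - size))
      out[[paste0("fp", i)]] <- deletion_calls(ctg, start, start + size,
                                               profile$caller)
    }
    if (!length(out)) return(empty_calls())
    calls <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    calls[order(calls$contig, calls$start, calls$end, method = "radix"), ,
          drop = FALSE]
  })
}
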