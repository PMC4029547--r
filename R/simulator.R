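#' Default SV size sampler
#'
#' A synthetic stand-in for the empirical deletion/insertion size spectrum of
#' large resequencing projects: a log-uniform background over
#' `[min_size, max_size]` with excess mass at ~300 bp (Alu-sized events) and
#' ~6,000 bp (LINE-sized events). Supply [empirical_size_sampler()] to use a
#' real size table instead.
#'
#' @param min_size,max_size size range in bp.
#' @param peak_weight total probability mass given to the two repeat-element
#'   peaks (split 2:1 between the Alu and LINE peaks).
#' @return a function `f(n)` returning `n` integer sizes.
#' @export
default_size_sampler <- function(min_size = 1, max_size = 1e6, peak_weight = 0.3) {
  stopifnot(min_size >= 1, min_size < max_size, peak_weight >= 0, peak_weight < 1)
  function(n) {
    comp <- sample(c("bg", "alu", "line"), n, replace = TRUE,
                   prob = c(1 - peak_weight, peak_weight * 2/3, peak_weight * 1/3))
    sz <- numeric(n)
    nbg <- sum(comp == "bg")
    sz[comp == "bg"] <- 10^stats::runif(nbg, log10(min_size), log10(max_size))
    sz[comp == "alu"] <- stats::rnorm(sum(comp == "alu"), 300, 30)
    sz[comp == "line"] <- stats::rnorm(sum(comp == "line"), 6000, 600)
    pmin(pmax(round(sz), min_size), max_size)
  }
}

#' Empirical SV size sampler
#'
#' @param sizes integer vector of observed sizes.
#' @param weights optional sampling weights.
#' @return a function `f(n)` resampling from the table.
#' @export
empirical_size_sampler <- function(sizes, weights = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) > 0, all(sizes >= 1))
  function(n) sample(sizes, n, replace = TRUE, prob = weights)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the benchmarking protocol:
#' 100-bp paired-end reads, insert sizes from Normal(350, 50) (draws shorter
#' than two read lengths are redrawn), a 0.1% per-base substitution error,
#' and depth chosen from the 5/10/20/30x series.
#'
#' @param n_sv number of SVs to inject.
#' @param del_fraction fraction of SVs that are deletions (the rest are
#'   insertions).
#' @param size_sampler function `f(n)` returning SV sizes in bp.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size (fragment-length) normal
#'   parameters in bp.
#' @param error_rate per-base substitution probability in `[0, 1]`.
#' @param depth target mean fold coverage.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_sv = 500, del_fraction = 0.5,
                              size_sampler = default_size_sampler(),
                              read_length = 100, insert_mean = 350,
                              insert_sd = 50, error_rate = 0.001,
                              depth = 30, seed = 1L) {
  stopifnot(n_sv >= 0, del_fraction >= 0, del_fraction <= 1,
            is.function(size_sampler), read_length >= 1,
            insert_mean > 0, insert_sd >= 0,
            error_rate >= 0, error_rate <= 1, depth > 0)
  structure(list(n_sv = n_sv, del_fraction = del_fraction,
                 size_sampler = size_sampler, read_length = read_length,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, depth = depth,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a random reference genome
#'
#' Uniform i.i.d. A/C/G/T sequence, as a stand-in reference for simulation
#' tests.
#'
#' @param lengths named numeric vector of contig lengths (names become contig
#'   names; unnamed vectors get `contig1..n`).
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
random_genome <- function(lengths, seed = 1L) {
  if (is.null(names(lengths))) names(lengths) <- paste0("contig", seq_along(lengths))
  with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Inject deletions and insertions into a reference genome
#'
#' Builds an artificial donor genome by placing `n_sv` non-overlapping SVs at
#' uniformly random positions. Placements that would overlap a previous event
#' (plus a 1-bp guard), cross a contig boundary, or touch an N run are
#' rejected and resampled. Deletions remove their span; insertions add a
#' random A/C/G/T string immediately after a single anchor base. Truth
#' coordinates are reported in *reference* (pre-mutation) space, because calls
#' made against the reference are what the evaluation compares.
#'
#' @param reference named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param config a [simulation_config()].
#' @param max_tries_per_sv rejection budget per SV before giving up.
#' @return a list with `genome` (mutated named character vector) and `truth`
#'   (a [truth_records()] table).
#' @export
inject_svs <- function(reference, config = simulation_config(),
                       max_tries_per_sv = 1000) {
  stopifnot(inherits(config, "simulation_config"), length(reference) > 0)
  contigs <- names(reference)
  if (is.null(contigs)) stop("reference contigs must be named", call. = FALSE)
  clen <- nchar(reference)

  truth <- with_seed(config$seed, {
    n <- config$n_sv
    if (n == 0) {
      empty_truths()
    } else {
      sizes <- config$size_sampler(n)
      is_del <- stats::runif(n) < config$del_fraction
      placed <- vector("list", n)
      occupied <- lapply(contigs, function(x) data.frame(start = numeric(), end = numeric()))
      names(occupied) <- contigs
      for (k in seq_len(n)) {
        span <- if (is_del[k]) sizes[k] else 1  # INS occupies its anchor base
        ok <- FALSE
        for (try in seq_len(max_tries_per_sv)) {
          ctg <- sample(contigs, 1, prob = clen)
          if (clen[ctg] < span + 2) next
          s <- floor(stats::runif(1, 0, clen[ctg] - span))
          e <- s + span
          occ <- occupied[[ctg]]
          # 1-bp guard between events
          if (nrow(occ) && any(pmin(occ$end, e + 1) - pmax(occ$start, s - 1) > 0)) next
          if (grepl("N", substr(reference[[ctg]], s + 1, e), fixed = TRUE)) next
          occupied[[ctg]] <- rbind(occ, data.frame(start = s, end = e))
          placed[[k]] <- list(contig = ctg, start = s, end = e)
          ok <- TRUE
          break
        }
        if (!ok) {
          stop(sprintf("could not place SV %d (size %d) after %d attempts; use fewer or smaller SVs",
                       k, sizes[k], max_tries_per_sv), call. = FALSE)
        }
      }
      ins_seq <- rep(NA_character_, n)
      nins <- sum(!is_del)
      if (nins) {
        ins_seq[!is_del] <- vapply(sizes[!is_del], function(L) {
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
        }, character(1))
      }
      truth_records(
        contig = vapply(placed, `[[`, character(1), "contig"),
        start = vapply(placed, `[[`, numeric(1), "start"),
        end = vapply(placed, `[[`, numeric(1), "end"),
        sv_type = ifelse(is_del, "DEL", "INS"),
        inserted_sequence = ins_seq
      )
    }
  })

  genome <- vapply(contigs, function(ctg) {
    ev <- truth[truth$contig == ctg, , drop = FALSE]
    if (!nrow(ev)) return(reference[[ctg]])
    ev <- ev[order(ev$start), , drop = FALSE]
    seq <- reference[[ctg]]
    pieces <- character(0)
    cursor <- 0  # 0-based position up to which output is emitted
    for (i in seq_len(nrow(ev))) {
      if (ev$sv_type[i] == "DEL") {
        pieces <- c(pieces, substr(seq, cursor + 1, ev$start[i]))
        cursor <- ev$end[i]
      } else {
        # keep through the anchor base, then splice in the insertion
        pieces <- c(pieces, substr(seq, cursor + 1, ev$end[i]), ev$inserted_sequence[i])
        cursor <- ev$end[i]
      }
    }
    pieces <- c(pieces, substr(seq, cursor + 1, nchar(seq)))
    paste(pieces, collapse = "")
  }, character(1))
  names(genome) <- contigs

  list(genome = genome, truth = truth)
}

#' Simulate paired-end reads from a genome
#'
#' Emits `round(depth * genome_length / (2 * read_length))` read pairs.
#' Fragment lengths are drawn from Normal(insert_mean, insert_sd), rounded,
#' and redrawn while shorter than two read lengths; fragment starts are
#' uniform over each contig (contigs chosen proportionally to length). Mates
#' are in FR orientation: read 1 is the fragment's 5' end, read 2 the reverse
#' complement of its 3' end. Each base is substituted with probability
#' `error_rate` by a uniformly chosen *different* base. Base qualities are
#' constant. Read names encode the pair index and the true fragment
#' coordinates.
#'
#' @param genome named character vector of contig sequences.
#' @param config a [simulation_config()].
#' @param out_prefix if non-`NULL`, gzip-compressed FASTQ files
#'   `<prefix>_1.fastq.gz` / `<prefix>_2.fastq.gz` are written.
#' @return invisibly, a list with `read1`, `read2` (character vectors),
#'   `names`, and `fragments` (`data.frame` of contig/start/end per pair).
#'   Contigs shorter than the longest feasible fragment are skipped with a
#'   warning.
#' @export
simulate_reads <- function(genome, config = simulation_config(), out_prefix = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  rl <- config$read_length
  clen <- nchar(genome)
  usable <- clen >= 2 * rl
  if (!all(usable)) {
    warning(sprintf("skipping %d contig(s) shorter than one fragment (%d bp)",
                    sum(!usable), 2 * rl))
    genome <- genome[usable]
    clen <- clen[usable]
  }
  if (!length(genome)) stop("no contig is long enough to carry a fragment", call. = FALSE)
  glen <- sum(clen)
  n_pairs <- round(config$depth * glen / (2 * rl))

  res <- with_seed(config$seed, {
    frag_len <- round(stats::rnorm(n_pairs, config$insert_mean, config$insert_sd))
    bad <- which(frag_len < 2 * rl)
    while (length(bad)) {
      frag_len[bad] <- round(stats::rnorm(length(bad), config$insert_mean, config$insert_sd))
      bad <- bad[frag_len[bad] < 2 * rl]
    }
    ctg_idx <- sample.int(length(genome), n_pairs, replace = TRUE, prob = clen)
    frag_len <- pmin(frag_len, clen[ctg_idx])
    start <- floor(stats::runif(n_pairs, 0, clen[ctg_idx] - frag_len + 1))
    end <- start + frag_len

    read1 <- substring(genome[ctg_idx], start + 1, start + rl)
    read2_fwd <- substring(genome[ctg_idx], end - rl + 1, end)
    read2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(read2_fwd)))

    read1 <- unname(add_substitution_errors(read1, config$error_rate))
    read2 <- unname(add_substitution_errors(read2, config$error_rate))
    list(read1 = read1, read2 = read2,
         fragments = data.frame(contig = names(genome)[ctg_idx],
                                start = start, end = end))
  })
  res$names <- sprintf("pair%07d_%s_%d_%d", seq_len(n_pairs),
                       res$fragments$contig, res$fragments$start,
                       res$fragments$end)
  if (!is.null(out_prefix)) {
    write_fastq_pair(res$read1, res$read2, res$names, out_prefix)
  }
  invisible(res)
}

# Substitute each base with probability `rate` by a uniformly chosen
# different base. Vectorised: reads with k errors receive them in k rounds.
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, rate)
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  while (any(n_err > 0)) {
    idx <- which(n_err > 0)
    pos <- 1L + floor(stats::runif(length(idx)) * rl[idx])
    cur <- substr(reads[idx], pos, pos)
    repl <- vapply(cur, function(b) sample(others[[b]], 1), character(1),
                   USE.NAMES = FALSE)
    substr(reads[idx], pos, pos) <- repl
    n_err[idx] <- n_err[idx] - 1L
  }
  reads
}
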