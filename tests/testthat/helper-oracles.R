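# Brute-force oracles used to cross-check the interval arithmetic, the
# quality/precision/recall metrics, and the merge fixed point. All oracles
# materialise position sets or loop over all pairs; they share no code with
# the implementation paths they verify.

# Positions covered by interval row i of table x, as "contig:pos" strings.
oracle_positions <- function(x, i) {
  if (x$end[i] <= x$start[i]) return(character())
  paste0(x$contig[i], ":", seq(x$start[i], x$end[i] - 1))
}

oracle_intersect <- function(a, b) {
  length(intersect(oracle_positions(a, 1), oracle_positions(b, 1)))
}

oracle_union <- function(a, b) {
  length(union(oracle_positions(a, 1), oracle_positions(b, 1)))
}

oracle_effective <- function(x, margin) {
  data.frame(contig = x$contig, start = pmax(0, x$start - margin),
             end = x$end + margin)
}

oracle_quality <- function(call, truth, margin) {
  ea <- oracle_effective(call, margin)
  eb <- oracle_effective(truth, margin)
  oracle_intersect(ea, eb) / oracle_union(ea, eb)
}

# All-pairs size-stratified precision/recall, looping over every (call, truth)
# pair with the position-set quality.
oracle_evaluate <- function(calls, truths, margin, bins) {
  truths <- truths[truths$sv_type == "DEL", , drop = FALSE]
  qmax_call <- vapply(seq_len(nrow(calls)), function(i) {
    if (!nrow(truths)) return(0)
    max(vapply(seq_len(nrow(truths)), function(j) {
      oracle_quality(calls[i, ], truths[j, ], margin)
    }, numeric(1)))
  }, numeric(1))
  qmax_truth <- vapply(seq_len(nrow(truths)), function(j) {
    if (!nrow(calls)) return(0)
    max(vapply(seq_len(nrow(calls)), function(i) {
      oracle_quality(calls[i, ], truths[j, ], margin)
    }, numeric(1)))
  }, numeric(1))
  in_bin <- function(size, k) size >= bins$low[k] & size < bins$high[k]
  precision <- recall <- rep(NA_real_, nrow(bins))
  for (k in seq_len(nrow(bins))) {
    ci <- which(in_bin(calls$size, k))
    ti <- which(in_bin(truths$size, k))
    if (length(ci)) precision[k] <- mean(qmax_call[ci])
    if (length(ti)) recall[k] <- mean(qmax_truth[ti])
  }
  list(precision = precision, recall = recall)
}

# Merge fixed point: enumerate all duplicate pairs among surviving calls,
# remove the loser of the highest-priority pair, repeat until none remain.
oracle_merge <- function(calls, config) {
  prof <- config$precision_profile
  calls <- calls[order(calls$contig, calls$start, calls$end, calls$caller,
                       calls$size, method = "radix"), , drop = FALSE]
  rownames(calls) <- NULL
  prec <- precision_of(calls, prof)
  prio <- match(calls$caller, config$caller_priority)
  prio[is.na(prio)] <- length(config$caller_priority) + 1L
  alive <- rep(TRUE, nrow(calls))
  repeat {
    idx <- which(alive)
    cand <- NULL
    for (x in seq_along(idx)) {
      for (y in seq_along(idx)) {
        if (y <= x) next
        i <- idx[x]; j <- idx[y]
        inter <- oracle_intersect(calls[i, ], calls[j, ])
        frac_ok <- inter > config$overlap_fraction * (calls$end[i] - calls$start[i]) &&
          inter > config$overlap_fraction * (calls$end[j] - calls$start[j])
        if (frac_ok) cand <- rbind(cand, c(inter, i, j))
      }
    }
    if (is.null(cand)) break
    first <- cand[order(-cand[, 1], cand[, 2], cand[, 3])[1], ]
    i <- first[2]; j <- first[3]
    loser <- if (prec[i] != prec[j]) {
      if (prec[i] < prec[j]) i else j
    } else if (prio[i] != prio[j]) {
      if (prio[i] > prio[j]) i else j
    } else if (calls$start[i] != calls$start[j]) {
      if (calls$start[i] > calls$start[j]) i else j
    } else if (calls$size[i] != calls$size[j]) {
      if (calls$size[i] < calls$size[j]) i else j
    } else max(i, j)
    alive[loser] <- FALSE
  }
  out <- calls[alive, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random fixture generators (coordinates < 1e4 so position-set oracles stay
# cheap).
random_intervals <- function(n, max_coord = 1e4, contigs = c("c1", "c2")) {
  start <- floor(runif(n, 0, max_coord - 1))
  len <- pmax(1, floor(rexp(n, 1 / 50)))
  gintervals(sample(contigs, n, replace = TRUE), start, start + len)
}

random_callset <- function(n, max_coord = 1e4, callers = c("HC", "Pindel", "BD"),
                           contigs = c("c1", "c2")) {
  gi <- random_intervals(n, max_coord, contigs)
  deletion_calls(gi$contig, gi$start, gi$end, sample(callers, n, replace = TRUE))
}

random_truthset <- function(n, max_coord = 1e4, ins_fraction = 0.2,
                            contigs = c("c1", "c2")) {
  gi <- random_intervals(n, max_coord, contigs)
  type <- ifelse(runif(n) < ins_fraction, "INS", "DEL")
  gi$end[type == "INS"] <- gi$start[type == "INS"] + 1
  seqs <- ifelse(type == "INS",
                 vapply(pmax(1, floor(runif(n, 1, 20))),
                        function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                          collapse = ""), character(1)),
                 NA_character_)
  truth_records(gi$contig, gi$start, gi$end, type, inserted_sequence = seqs)
}
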