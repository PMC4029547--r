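#' Read deletion calls from a VCF file
#'
#' Normalizes VCF records to deletion calls in 0-based half-open coordinates.
#' A record is a deletion when its ALT allele is the symbolic `<DEL>`, or when
#' REF is longer than ALT and they share their leading base (the VCF padding
#' convention). The deleted span of a sequence-resolved deletion at `POS` with
#' reference allele of length `L` is `[POS, POS + L - 1)` in 0-based
#' coordinates; for symbolic alleles it is `[POS, END)`. The size comes from
#' `SVLEN` (absolute value) when present, else `len(REF) - len(ALT)` /
#' `END - POS`. Records failing FILTER (other than `PASS` or `.`) are dropped
#' and counted; multi-allelic records are split and non-deletion alleles
#' dropped.
#'
#' @param path VCF file (plain or gzip/bgzip).
#' @param caller caller identifier stamped on all calls.
#' @return a [deletion_calls()] table; the number of FILTER-dropped records is
#'   attached as attribute `n_filtered`.
#' @export
read_deletions_vcf <- function(path, caller) {
  stopifnot(nzchar(caller))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) return(empty_calls())

  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  n_filtered <- sum(!pass)
  fix <- fix[pass, , drop = FALSE]

  recs <- list()
  for (r in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.numeric(fix[r, "POS"]))
    if (is.na(pos) || pos < 1) {
      stop(sprintf("malformed POS in VCF record %d", r), call. = FALSE)
    }
    ref <- fix[r, "REF"]
    info <- fix[r, "INFO"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (identical(alt, "<DEL>")) {
        end1 <- vcf_info_field(info, "END")
        svlen <- vcf_info_field(info, "SVLEN")
        if (is.na(end1) && is.na(svlen)) {
          stop(sprintf("symbolic <DEL> without END or SVLEN in VCF record %d", r),
               call. = FALSE)
        }
        if (is.na(end1)) end1 <- pos + abs(svlen)
        if (end1 < pos) {
          stop(sprintf("END < POS in VCF record %d", r), call. = FALSE)
        }
        size <- if (!is.na(svlen)) abs(svlen) else end1 - pos
        # 1-based (POS, END] == 0-based [POS, END)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = fix[r, "CHROM"], start = pos, end = end1, size = size)
      } else if (grepl("^[ACGTNacgtn]+$", alt) && nchar(ref) > nchar(alt) &&
                 substr(ref, 1, 1) == substr(alt, 1, 1)) {
        svlen <- vcf_info_field(info, "SVLEN")
        size <- if (!is.na(svlen)) abs(svlen) else nchar(ref) - nchar(alt)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = fix[r, "CHROM"], start = pos, end = pos + nchar(ref) - 1,
          size = size)
      }
      # SNVs, insertions, other symbolic alleles: not deletions, skipped
    }
  }
  if (!length(recs)) {
    out <- empty_calls()
  } else {
    df <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    out <- deletion_calls(df$contig, df$start, df$end, caller)
    out$size <- df$size  # SVLEN may disagree with the span; keep the stated size
  }
  attr(out, "n_filtered") <- n_filtered
  out
}

vcf_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) return(NA_real_)
  suppressWarnings(as.numeric(m[2]))
}

#' Read deletion calls from a BED file
#'
#' BED is 0-based half-open. Column 4, when present, is the caller/label and
#' column 5 the score; an explicit `caller` argument overrides column 4.
#'
#' @param path BED/TSV file.
#' @param caller optional caller identifier; required when the file has no
#'   column 4.
#' @return a [deletion_calls()] table.
#' @export
read_deletions_bed <- function(path, caller = NULL) {
  df <- read_bed_table(path)
  if (is.null(df)) {
    if (is.null(caller)) caller <- "unknown"
    return(empty_calls())
  }
  cl <- if (!is.null(caller)) caller else if (ncol(df) >= 4) as.character(df[[4]]) else
    stop("BED file has no caller column; supply `caller`", call. = FALSE)
  score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  validate_bed_coords(df, path)
  deletion_calls(df[[1]], df[[2]], df[[3]], cl, score = score)
}

#' Read a truth BED file
#'
#' Columns: contig, start, end, SV type (`DEL`/`INS`), size, and inserted
#' sequence (`.` for deletions) — the format written by [write_bed()] for
#' truth sets.
#'
#' @param path BED file.
#' @return a [truth_records()] table.
#' @export
read_truth_bed <- function(path) {
  df <- read_bed_table(path)
  if (is.null(df)) return(empty_truths())
  if (ncol(df) < 5) stop("truth BED needs >= 5 columns (type and size)", call. = FALSE)
  validate_bed_coords(df, path)
  ins_seq <- if (ncol(df) >= 6) as.character(df[[6]]) else "."
  ins_seq[ins_seq == "."] <- NA_character_
  truth_records(df[[1]], df[[2]], df[[3]], as.character(df[[4]]),
                inserted_sequence = ins_seq)
}

read_bed_table <- function(path) {
  if (file.size(path) == 0) return(NULL)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (!nrow(df)) return(NULL)
  df[[2]] <- suppressWarnings(as.numeric(df[[2]]))
  df[[3]] <- suppressWarnings(as.numeric(df[[3]]))
  df
}

validate_bed_coords <- function(df, path) {
  bad <- which(is.na(df[[2]]) | is.na(df[[3]]) | df[[2]] < 0 | df[[2]] >= df[[3]])
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates at line %d (need 0 <= start < end)",
                 path, bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' Write calls or truth records as BED
#'
#' Call sets are written as contig/start/end/caller/score; truth sets as
#' contig/start/end/type/size/inserted-sequence. Both round-trip losslessly
#' through [read_deletions_bed()] / [read_truth_bed()].
#'
#' @param x a call set or truth set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (!is.null(x$sv_type)) {
    df <- data.frame(x$contig, format_coord(x$start), format_coord(x$end),
                     x$sv_type, format_coord(x$size),
                     ifelse(is.na(x$inserted_sequence), ".", x$inserted_sequence))
  } else {
    df <- data.frame(x$contig, format_coord(x$start), format_coord(x$end),
                     x$caller, ifelse(is.na(x$score), ".", as.character(x$score)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write / read the unified extended-BED call list
#'
#' The pipeline's output format: a BED-like TSV with columns contig, start
#' (0-based), end, caller, precision prior (3 decimals), size, and ploidy
#' (`.` when absent).
#'
#' @param calls a call set carrying a `precision` column (as returned by
#'   [merge_callsets()]).
#' @param path file path.
#' @return `path` invisibly (writer); a call set with `precision` column
#'   (reader).
#' @export
write_extended_bed <- function(calls, path) {
  prec <- calls$precision %||% rep(NA_real_, nrow(calls))
  df <- data.frame(calls$contig, format_coord(calls$start),
                   format_coord(calls$end), calls$caller,
                   sprintf("%.3f", prec), format_coord(calls$size),
                   ifelse(is.na(calls$ploidy), ".", calls$ploidy))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_extended_bed
#' @export
read_extended_bed <- function(path) {
  df <- read_bed_table(path)
  if (is.null(df)) {
    out <- empty_calls()
    out$precision <- numeric()
    return(out)
  }
  validate_bed_coords(df, path)
  ploidy <- if (ncol(df) >= 7) ifelse(df[[7]] == ".", NA_character_, df[[7]]) else NA_character_
  out <- deletion_calls(df[[1]], df[[2]], df[[3]], df[[4]], ploidy = ploidy)
  out$precision <- suppressWarnings(as.numeric(df[[5]]))
  out
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's working representation
#' (named character vectors) at the boundary.
#'
#' @param path FASTA file.
#' @param x named character vector of sequences.
#' @return named character vector (reader); `path` invisibly (writer).
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Write / read a gzip-compressed FASTQ pair
#'
#' Files `<prefix>_1.fastq.gz` and `<prefix>_2.fastq.gz`; mate order is kept
#' aligned between the two files. Base qualities are written as a constant
#' high quality (`I`, Q40).
#'
#' @param read1,read2 character vectors of mate sequences.
#' @param names read names (without `/1`, `/2` suffixes).
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly (writer); a list with
#'   `read1`, `read2`, `names` (reader).
#' @export
write_fastq_pair <- function(read1, read2, names, prefix) {
  stopifnot(length(read1) == length(read2), length(read1) == length(names))
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (mate in 1:2) {
    reads <- if (mate == 1) read1 else read2
    con <- gzfile(paths[mate], "wb")
    qual <- strrep("I", nchar(reads))
    writeLines(paste0("@", names, "/", mate, "\n", reads, "\n+\n", qual),
               con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(prefix) {
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  parse_one <- function(p) {
    lines <- readLines(gzfile(p))
    if (length(lines) %% 4 != 0) stop(sprintf("%s: truncated FASTQ", p), call. = FALSE)
    list(names = sub("/[12]$", "", sub("^@", "", lines[seq(1, length(lines), 4)])),
         reads = lines[seq(2, length(lines), 4)])
  }
  m1 <- parse_one(paths[1])
  m2 <- parse_one(paths[2])
  if (!identical(m1$names, m2$names)) {
    stop("mate order differs between the two FASTQ files", call. = FALSE)
  }
  list(read1 = m1$reads, read2 = m2$reads, names = m1$names)
}
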