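#' Read an INI-style pipeline configuration file
#'
#' One file configures every stage, with `[section]` headers and `key = value`
#' lines. Values are auto-typed: numbers become numeric, comma-separated
#' values become vectors, `true`/`false` become logical. Section names may
#' carry a qualifier after a colon (e.g. `[emulator:HC]`).
#'
#' @param path config file path.
#' @return a named list of sections, each a named list of values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("config values must appear under a [section]", call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][[key]] <- parse_config_value(val)
    } else {
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    }
  }
  out
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  conv <- function(x) {
    if (tolower(x) %in% c("true", "false")) return(as.logical(toupper(x)))
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) num else x
  }
  parsed <- lapply(parts, conv)
  if (length(parsed) == 1L) parsed[[1]] else unlist(parsed)
}

#' End-to-end pipeline configuration
#'
#' Programmatic equivalent of the INI config: bundles the simulation settings,
#' the emulator profiles standing in for real callers, and the filter / merge
#' / evaluation settings.
#'
#' @param genome_lengths named numeric vector of contig lengths for the
#'   simulated reference (ignored when `reference` is given).
#' @param reference optional named character vector (or FASTA path) to use as
#'   the reference instead of a random genome.
#' @param simulation a [simulation_config()].
#' @param emulators list of [emulator_profile()]s, one per emulated caller.
#' @param filter a [filter_spec()].
#' @param merge a [merge_config()].
#' @param evaluation an [evaluation_config()].
#' @param write_reads if `TRUE`, paired FASTQ is also written (reads are not
#'   needed by the downstream stages, which consume call sets).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_lengths = c(contig1 = 1e6),
                            reference = NULL,
                            simulation = simulation_config(n_sv = 100),
                            emulators = list(emulator_profile("HC")),
                            filter = default_filter_spec(),
                            merge = merge_config(),
                            evaluation = evaluation_config(),
                            write_reads = FALSE) {
  structure(list(genome_lengths = genome_lengths, reference = reference,
                 simulation = simulation, emulators = emulators,
                 filter = filter, merge = merge, evaluation = evaluation,
                 write_reads = isTRUE(write_reads)),
            class = "pipeline_config")
}

#' Run the full pipeline on simulated data
#'
#' Simulates a genome with injected SVs, emulates each configured caller,
#' filters every call set to its caller's trusted size range, merges the
#' filtered sets into a unified deletion list, and evaluates the merged list
#' against the truth. All outputs (truth BED, per-caller BEDs, merged extended
#' BED, evaluation TSV, and a JSON run manifest) are written under `out_dir`;
#' inputs are never mutated. Per-stage seeds are derived from `seed` salted
#' with the stage name, so every stage has its own reproducible stream.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @return a list with `report` (an `svu_report`), `merged` (the unified call
#'   set), `truth`, `calls` (per-caller, post-filter), and `paths`.
#' @export
run_end_to_end <- function(config, out_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage <- "simulate"
  result <- tryCatch({
    reference <- config$reference
    if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
      reference <- read_fasta(reference)
    }
    if (is.null(reference)) {
      reference <- random_genome(config$genome_lengths,
                                 seed = stage_seed(seed, "reference"))
    }
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(seed, "simulate")
    sim <- inject_svs(reference, sim_cfg)
    paths$truth <- file.path(out_dir, "truth.bed")
    write_bed(sim$truth, paths$truth)
    if (config$write_reads) {
      sim_cfg$seed <- stage_seed(seed, "reads")
      paths$fastq <- simulate_reads(sim$genome, sim_cfg,
                                    out_prefix = file.path(out_dir, "reads"))
      paths$genome <- file.path(out_dir, "genome.fa")
      write_fasta(sim$genome, paths$genome)
    }
    contig_lengths <- nchar(reference)

    stage <- "emulate"
    callsets <- lapply(config$emulators, function(prof) {
      prof$seed <- stage_seed(seed, paste0("emulate:", prof$caller))
      calls <- emulate_calls(sim$truth, contig_lengths, prof)
      p <- file.path(out_dir, sprintf("calls_%s.bed", prof$caller))
      write_bed(calls, p)
      paths[[paste0("calls_", prof$caller)]] <<- p
      calls
    })

    stage <- "filter"
    filtered <- lapply(callsets, filter_calls, spec = config$filter)

    stage <- "merge"
    merged <- merge_callsets(filtered, config$merge)
    paths$merged <- file.path(out_dir, "merged.bed")
    write_extended_bed(merged, paths$merged)

    stage <- "evaluate"
    report <- evaluate_deletions(merged, sim$truth, config$evaluation)
    paths$report <- file.path(out_dir, "report.tsv")
    write_report(report, paths$report)

    list(report = report, merged = merged, truth = sim$truth, calls = filtered)
  }, error = function(e) {
    write_manifest(config, seed, paths, out_dir, status = paste0("failed at stage: ", stage))
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  paths$manifest <- write_manifest(config, seed, paths, out_dir, status = "ok")
  result$paths <- paths
  result
}

# JSON run manifest: config snapshot, seeds, output checksums, version, time.
write_manifest <- function(config, seed, paths, out_dir, status) {
  flat <- unlist(paths, use.names = TRUE)
  manifest <- list(
    tool = "svunify",
    version = as.character(utils::packageVersion("svunify")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status,
    seed = seed,
    stage_seeds = list(
      reference = stage_seed(seed, "reference"),
      simulate = stage_seed(seed, "simulate"),
      emulate = vapply(config$emulators, function(p)
        stage_seed(seed, paste0("emulate:", p$caller)), numeric(1))
    ),
    config = config_snapshot(config),
    outputs = lapply(seq_along(flat), function(i) {
      list(path = unname(flat[i]),
           md5 = unname(tools::md5sum(flat[i])))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  path
}

config_snapshot <- function(config) {
  list(
    genome_lengths = as.list(config$genome_lengths),
    simulation = config$simulation[setdiff(names(config$simulation), "size_sampler")],
    emulators = lapply(config$emulators, function(p)
      p[setdiff(names(p), "bins")]),
    filter = config$filter$table,
    merge = list(overlap_fraction = config$merge$overlap_fraction,
                 caller_priority = config$merge$caller_priority,
                 mode = config$merge$mode,
                 precision_profile = config$merge$precision_profile$table,
                 profile_default = config$merge$precision_profile$default),
    evaluation = list(margin = config$evaluation$margin,
                      bins = config$evaluation$bins),
    write_reads = config$write_reads
  )
}
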