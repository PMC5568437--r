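#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis. The configuration is
#' echoed verbatim (as JSON) into every output directory so runs are
#' self-documenting and reproducible.
#'
#' @param theta Conservation threshold for [profile_sequences()].
#' @param min_seed,min_total Poly-Ala detection parameters.
#' @param flank_max Domain flank retained around the outermost runs.
#' @param max_mismatch Araneidae consensus mismatch tolerance.
#' @param strict_ggy If `TRUE`, GGF does not satisfy the MaSp1 GGY criterion.
#' @param motifs Motif labels quantified by [summarize_sequences()].
#' @param format Output table format, `"tsv"` or `"json"`.
#' @param seed Seed for any stochastic step.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(theta = 1 / 3, min_seed = 3L, min_total = 4L,
                       flank_max = 60L, max_mismatch = 3L,
                       strict_ggy = FALSE, motifs = c("GP", "QQ", "GGY"),
                       format = c("tsv", "json"), seed = 1L) {
  stopifnot(theta > 0, theta <= 1, min_seed >= 1, min_total >= min_seed,
            flank_max >= 0, max_mismatch >= 0)
  format <- match.arg(format)
  structure(
    list(theta = theta, min_seed = as.integer(min_seed),
         min_total = as.integer(min_total),
         flank_max = as.integer(flank_max),
         max_mismatch = as.integer(max_mismatch), strict_ggy = strict_ggy,
         motifs = motifs, format = format, seed = as.integer(seed)),
    class = "run_config"
  )
}

start_run <- function(out_dir, config, command) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(list(command = command), unclass(config)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("command: %s\n", command), file = log_path)
  function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
}

load_bounds <- function(metadata) {
  if (is.null(metadata) ||
      !all(c("rep_start", "rep_end") %in% names(metadata))) {
    return(NULL)
  }
  metadata[c("id", "rep_start", "rep_end")]
}

profile_pipeline <- function(seqs, config, metadata = NULL, log = NULL) {
  units <- withCallingHandlers(
    segment_spidroins(seqs, min_seed = config$min_seed,
                      min_total = config$min_total,
                      flank_max = config$flank_max,
                      bounds = load_bounds(metadata)),
    warning = function(w) {
      if (!is.null(log)) log("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  usable <- units |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(any(.data$complete)) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(units$id), unique(usable$id))
  if (length(dropped) > 0 && !is.null(log)) {
    log("warning: skipping %s: no complete repeats",
        paste(dropped, collapse = ", "))
  }
  counts <- if (nrow(usable)) profile_repeats(usable) else
    tibble::tibble(id = character(0), repeat_index = integer(0),
                   repeat_length = integer(0), complete = logical(0),
                   motif = character(0), count = integer(0))
  profiles <- if (nrow(counts)) profile_sequences(counts, theta = config$theta)
    else tibble::tibble(id = character(0), motif = character(0),
                        n_complete_repeats = integer(0),
                        occurrence_fraction = double(0),
                        mean_count_per_repeat = double(0),
                        present = logical(0), conserved = logical(0))
  list(units = units, usable = usable, counts = counts, profiles = profiles)
}

#' Run the profiling pipeline and write per-sequence motif profiles
#'
#' Segments every record, scans complete repeats for catalog motifs, and
#' writes the per-(sequence, motif) profile table (occurrence fraction, mean
#' count per repeat, conserved flag). Records with no poly-Ala run or no
#' complete repeat are skipped and logged.
#'
#' @param fasta Path to the input FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param metadata_path Optional metadata TSV (for per-sequence domain
#'   bounds).
#' @return The profile tibble, invisibly.
#' @export
run_profile <- function(fasta, out_dir, config = run_config(),
                        metadata_path = NULL) {
  log <- start_run(out_dir, config, "profile")
  seqs <- read_fasta(fasta)
  metadata <- if (!is.null(metadata_path)) read_metadata(metadata_path)
  res <- profile_pipeline(seqs, config, metadata, log)
  out <- res$profiles |>
    dplyr::mutate(conserved = as.integer(.data$conserved),
                  present = as.integer(.data$present))
  ext <- if (config$format == "tsv") ".tsv" else ".json"
  write_table(out, file.path(out_dir, paste0("profiles", ext)), config$format)
  log("profiled %d/%d sequences", dplyr::n_distinct(res$profiles$id),
      nrow(seqs))
  invisible(res$profiles)
}

#' Run the classification pipeline
#'
#' Profiles every record and assigns MaSp1 / MaSp2 / intermediate /
#' nonconforming labels. Records skipped as nonrepetitive are reported as
#' nonconforming rather than aborting the run.
#'
#' @inheritParams run_profile
#' @return The classification tibble (`id`, `label`, `evidence`), invisibly.
#' @export
run_classify <- function(fasta, out_dir, config = run_config(),
                         metadata_path = NULL) {
  log <- start_run(out_dir, config, "classify")
  seqs <- read_fasta(fasta)
  metadata <- if (!is.null(metadata_path)) read_metadata(metadata_path)
  res <- profile_pipeline(seqs, config, metadata, log)
  cls <- if (nrow(res$profiles)) {
    classify_spidroins(res$profiles, res$usable,
                       strict_ggy = config$strict_ggy)
  } else {
    tibble::tibble(id = character(0), label = character(0),
                   evidence = character(0))
  }
  missing <- setdiff(seqs$id, cls$id)
  if (length(missing) > 0) {
    cls <- dplyr::bind_rows(cls, tibble::tibble(
      id = missing, label = "nonconforming",
      evidence = "no canonical poly-Ala/Gly-rich architecture"
    ))
  }
  cls <- cls[match(seqs$id, cls$id), ]
  ext <- if (config$format == "tsv") ".tsv" else ".json"
  write_table(cls, file.path(out_dir, paste0("classification", ext)),
              config$format)
  log("classified %d sequences", nrow(cls))
  invisible(cls)
}

#' Run the consensus-match pipeline
#'
#' Reports, for every poly-Ala run of every record, the comparison of its
#' flanks against the extended Araneidae MaSp2 consensus templates.
#'
#' @inheritParams run_profile
#' @return The match tibble, invisibly.
#' @export
run_consensus_match <- function(fasta, out_dir, config = run_config()) {
  log <- start_run(out_dir, config, "consensus-match")
  seqs <- read_fasta(fasta)
  matches <- match_consensus(seqs, max_mismatch = config$max_mismatch,
                             min_seed = config$min_seed,
                             min_total = config$min_total)
  out <- dplyr::mutate(matches,
                       eligible = as.integer(.data$eligible),
                       matched = as.integer(.data$matched))
  ext <- if (config$format == "tsv") ".tsv" else ".json"
  write_table(out, file.path(out_dir, paste0("consensus_match", ext)),
              config$format)
  log("matched %d/%d eligible runs", sum(matches$matched),
      sum(matches$eligible))
  invisible(matches)
}

#' Run the quantification pipeline
#'
#' Writes per-sequence repeat-length and motif-abundance box summaries and,
#' when metadata is given, the grouped-by-web-architecture report. Metadata
#' ids that do not match any sequence produce a logged warning; sequences
#' without metadata are grouped as unknown.
#'
#' @inheritParams run_profile
#' @return A list with `per_sequence` and (possibly `NULL`) `grouped`,
#'   invisibly.
#' @export
run_quantify <- function(fasta, out_dir, config = run_config(),
                         metadata_path = NULL) {
  log <- start_run(out_dir, config, "quantify")
  seqs <- read_fasta(fasta)
  metadata <- if (!is.null(metadata_path)) read_metadata(metadata_path)
  res <- profile_pipeline(seqs, config, metadata, log)
  per_seq <- summarize_sequences(res$counts, motifs = config$motifs)
  flat <- dplyr::select(per_seq, -"outliers")
  ext <- if (config$format == "tsv") ".tsv" else ".json"
  write_table(flat, file.path(out_dir, paste0("per_sequence", ext)),
              config$format)
  grouped <- NULL
  if (!is.null(metadata)) {
    orphans <- setdiff(metadata$id, seqs$id)
    if (length(orphans) > 0) {
      log("warning: metadata ids without sequences: %s",
          paste(orphans, collapse = ", "))
    }
    grouped <- group_by_architecture(per_seq, metadata)
    write_table(
      dplyr::select(grouped, -"medians") |>
        dplyr::mutate(web_architecture = as.character(.data$web_architecture)),
      file.path(out_dir, paste0("grouped", ext)), config$format
    )
  }
  log("quantified %d sequences", dplyr::n_distinct(per_seq$id))
  invisible(list(per_sequence = per_seq, grouped = grouped))
}

#' Run the simulation pipeline
#'
#' Thin wrapper over [simulate_panel()] that also echoes the configuration.
#'
#' @param specs List of [sim_spec()] objects.
#' @param out_dir Output directory.
#' @param seed Panel seed.
#' @return The panel list, invisibly.
#' @export
run_simulate <- function(specs, out_dir, seed = 1L) {
  log <- start_run(out_dir, run_config(seed = seed), "simulate")
  panel <- simulate_panel(specs, seed = seed, out_dir = out_dir)
  log("simulated %d sequences", nrow(panel$sequences))
  invisible(panel)
}
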