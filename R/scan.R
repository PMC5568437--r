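#' Scan a repeat sequence for catalog motifs under precedence rules
#'
#' Assigns non-overlapping motif hits in three left-to-right passes, one per
#' motif class in the catalog's precedence order (default: doublets, then
#' `GGX`, then `GX`). The doublet pass packs `QQ`/`SS` hits greedily within
#' each maximal homopolymer run; the `GGX` pass claims any position whose
#' three residues are all still unassigned; the `GX` pass claims unassigned
#' pairs. Because the doublet pass runs first, a `GGQQ` context yields a
#' single `QQ` hit (the orphaned `GG` matches nothing), extending the
#' QQ-over-GQ rule to `GGQ`. No residue ever belongs to two hits, so summed
#' hit lengths never exceed the repeat length. Ambiguity codes (X/B/Z) never
#' match any motif.
#'
#' @param repeat_seq Single normalized residue string (see
#'   [normalize_residues()]).
#' @param catalog A [motif_catalog()].
#' @return A tibble with one row per hit: `motif`, `start` (0-based position
#'   within `repeat_seq`), `length`; sorted by `start`.
#' @examples
#' scan_motifs("GQQGPGGQGPYGPGAAAAAAAGGYGPGAGQQ")
#' @export
scan_motifs <- function(repeat_seq, catalog = motif_catalog()) {
  stopifnot(is.character(repeat_seq), length(repeat_seq) == 1L)
  chars <- strsplit(repeat_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  assigned <- logical(n)
  motif <- character(0)
  start <- integer(0)

  add_hit <- function(lab, s, len) {
    motif[[length(motif) + 1L]] <<- lab
    start[[length(start) + 1L]] <<- s
    assigned[s:(s + len - 1L)] <<- TRUE
  }

  pass_doublet <- function() {
    for (d in catalog$doublets) {
      res <- substr(d, 1L, 1L)
      r <- rle(chars == res)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      for (k in which(r$values & r$lengths >= 2L)) {
        p <- run_start[k]
        while (p + 1L <= run_end[k]) {
          if (!assigned[p] && !assigned[p + 1L]) {
            add_hit(d, p, 2L)
            p <- p + 2L
          } else {
            p <- p + 1L
          }
        }
      }
    }
  }

  pass_ggx <- function() {
    i <- 1L
    while (i <= n - 2L) {
      if (!assigned[i] && !assigned[i + 1L] && !assigned[i + 2L] &&
          chars[i] == "G" && chars[i + 1L] == "G" &&
          chars[i + 2L] %in% catalog$x_alphabet) {
        add_hit(paste0("GG", chars[i + 2L]), i, 3L)
        i <- i + 3L
      } else {
        i <- i + 1L
      }
    }
  }

  pass_gx <- function() {
    i <- 1L
    while (i <= n - 1L) {
      if (!assigned[i] && !assigned[i + 1L] &&
          chars[i] == "G" && chars[i + 1L] %in% catalog$x_alphabet) {
        add_hit(paste0("G", chars[i + 1L]), i, 2L)
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }

  for (pass in catalog$precedence) {
    switch(pass,
      doublet = pass_doublet(),
      GGX = pass_ggx(),
      GX = pass_gx()
    )
  }

  out <- tibble::tibble(
    motif = motif,
    start = start - 1L,  # report 0-based
    length = nchar(motif)
  )
  dplyr::arrange(out, .data$start)
}

#' Tally motif hits into a per-repeat profile
#'
#' @param hits Tibble of hits from [scan_motifs()] on one repeat.
#' @param repeat_length Length of the repeat in residues (> 0).
#' @param repeat_index 0-based ordinal of the repeat within its sequence.
#' @return A tibble with columns `repeat_index`, `repeat_length`, `motif`,
#'   `count` — one row per motif label observed (absent motifs are implicitly
#'   zero; use [tidyr::complete()] or the sequence-level profiling to
#'   materialize zeros).
#' @export
profile_repeat <- function(hits, repeat_length, repeat_index = 0L) {
  if (repeat_length <= 0L) {
    stop("repeat_length must be positive", call. = FALSE)
  }
  counts <- dplyr::count(hits, .data$motif, name = "count")
  tibble::tibble(
    repeat_index = as.integer(repeat_index),
    repeat_length = as.integer(repeat_length),
    motif = counts$motif,
    count = as.integer(counts$count)
  )
}

#' Scan and profile every repeat unit of every sequence
#'
#' Data-frame-first wrapper: takes the repeat-unit table produced by
#' [segment_spidroins()] and returns one row per (sequence, repeat, motif)
#' with hit counts. Motifs with zero hits in a given repeat are completed
#' with explicit zero rows for every motif label seen anywhere in that
#' sequence, so downstream occurrence fractions are well defined.
#'
#' @param units Tibble with columns `id`, `index`, `sequence`, `complete`
#'   (from [segment_spidroins()]).
#' @param catalog A [motif_catalog()].
#' @return Tibble with columns `id`, `repeat_index`, `repeat_length`,
#'   `complete`, `motif`, `count`.
#' @export
profile_repeats <- function(units, catalog = motif_catalog()) {
  stopifnot(all(c("id", "index", "sequence", "complete") %in% names(units)))
  per_unit <- purrr::pmap(
    list(units$id, units$index, units$sequence, units$complete),
    function(id, index, sequence, complete) {
      hits <- scan_motifs(sequence, catalog)
      counts <- dplyr::count(hits, .data$motif, name = "count")
      tibble::tibble(
        id = id,
        repeat_index = as.integer(index),
        repeat_length = nchar(sequence),
        complete = complete,
        motif = if (nrow(counts)) counts$motif else character(0),
        count = if (nrow(counts)) as.integer(counts$count) else integer(0)
      )
    }
  )
  long <- dplyr::bind_rows(per_unit)
  frame <- units |>
    dplyr::transmute(
      id = .data$id,
      repeat_index = as.integer(.data$index),
      repeat_length = nchar(.data$sequence),
      complete = .data$complete
    )
  labels <- dplyr::distinct(long, .data$id, .data$motif)
  frame |>
    dplyr::inner_join(labels, by = "id", relationship = "many-to-many") |>
    dplyr::left_join(
      long,
      by = c("id", "repeat_index", "repeat_length", "complete", "motif")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$id, .data$repeat_index, .data$motif)
}

#' Conserved-motif profile of a sequence
#'
#' Summarizes per-repeat motif counts into a per-sequence profile over
#' *complete* repeats only: for each motif label, the fraction of complete
#' repeats containing at least one hit (`occurrence_fraction`), the mean hit
#' count per complete repeat, whether the motif is present anywhere
#' (`present`), and whether it is conserved (`occurrence_fraction >= theta`).
#' The default threshold `theta = 1/3` admits a motif recurring once every
#' three repeats while excluding singleton noise.
#'
#' @param repeat_profiles Tibble from [profile_repeats()] (may contain
#'   incomplete repeats; they are dropped here).
#' @param theta Conservation threshold on the occurrence fraction, in (0, 1].
#' @return Tibble with columns `id`, `motif`, `n_complete_repeats`,
#'   `occurrence_fraction`, `mean_count_per_repeat`, `present`, `conserved`.
#' @export
profile_sequences <- function(repeat_profiles, theta = 1 / 3) {
  stopifnot(theta > 0, theta <= 1)
  complete <- dplyr::filter(repeat_profiles, .data$complete)
  bad <- setdiff(unique(repeat_profiles$id), unique(complete$id))
  if (length(bad) > 0) {
    stop("insufficient repeats: no complete repeats for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  complete |>
    dplyr::group_by(.data$id, .data$motif) |>
    dplyr::summarise(
      n_complete_repeats = dplyr::n_distinct(.data$repeat_index),
      occurrence_fraction = mean(.data$count > 0L),
      mean_count_per_repeat = mean(.data$count),
      present = any(.data$count > 0L),
      .groups = "drop"
    ) |>
    dplyr::mutate(conserved = .data$present &
                    .data$occurrence_fraction >= theta) |>
    dplyr::arrange(.data$id, .data$motif)
}

#' Conserved motif set of one profiled sequence
#'
#' @param profiles Tibble from [profile_sequences()].
#' @param id Sequence id to extract (default: the only id present).
#' @return Character vector of conserved motif labels.
#' @export
conserved_set <- function(profiles, id = NULL) {
  if (!is.null(id)) {
    profiles <- dplyr::filter(profiles, .data$id == !!id)
  }
  sort(profiles$motif[profiles$conserved])
}
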