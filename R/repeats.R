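#' Detect poly-alanine runs
#'
#' Seeds are maximal runs of at least `min_seed` contiguous alanines. Two
#' seeds separated by exactly one residue from {G, S, V} are merged into one
#' run, recording the interruption; merging chains across multiple
#' interruptions. Merged runs shorter than `min_total` residues are
#' discarded. By construction every reported run starts and ends with `A` and
#' is at least 75% alanine.
#'
#' @param residues Single normalized residue string.
#' @param min_seed Minimum seed length in contiguous alanines (default 3).
#' @param min_total Minimum total run length after merging (default 4).
#' @return Tibble with one row per run, sorted by position: `start`, `end`
#'   (0-based half-open), `length`, `ala_count`, `interruptions` (list column
#'   of tibbles with `position` (0-based) and `residue`).
#' @examples
#' find_polyala_runs("GGQAAAAAAGGY")
#' find_polyala_runs("AAASAAA")
#' @export
find_polyala_runs <- function(residues, min_seed = 3L, min_total = 4L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  r <- rle(chars == "A")
  seed_end <- cumsum(r$lengths)
  seed_start <- seed_end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_seed
  starts <- seed_start[keep]
  ends <- seed_end[keep]  # 1-based inclusive
  empty <- tibble::tibble(
    start = integer(0), end = integer(0), length = integer(0),
    ala_count = integer(0), interruptions = list()
  )
  if (length(starts) == 0L) {
    return(empty)
  }

  runs <- list()
  cur_start <- starts[1]
  cur_end <- ends[1]
  cur_int <- integer(0)
  flush <- function() {
    runs[[length(runs) + 1L]] <<- list(
      start = cur_start, end = cur_end, interruptions = cur_int
    )
  }
  if (length(starts) > 1L) {
    for (k in 2:length(starts)) {
      gap_len <- starts[k] - cur_end - 1L
      if (gap_len == 1L && chars[cur_end + 1L] %in% c("G", "S", "V")) {
        cur_int <- c(cur_int, cur_end + 1L)
        cur_end <- ends[k]
      } else {
        flush()
        cur_start <- starts[k]
        cur_end <- ends[k]
        cur_int <- integer(0)
      }
    }
  }
  flush()

  out <- purrr::map(runs, function(run) {
    len <- run$end - run$start + 1L
    if (len < min_total) {
      return(NULL)
    }
    tibble::tibble(
      start = run$start - 1L,
      end = run$end,
      length = len,
      ala_count = len - length(run$interruptions),
      interruptions = list(tibble::tibble(
        position = run$interruptions - 1L,
        residue = chars[run$interruptions]
      ))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(out) == 0L) empty else out
}

#' Delimit the repetitive domain of a spidroin record
#'
#' If explicit bounds are supplied they win (`source = "user"`); otherwise
#' the domain extends from `flank_max` residues before the first poly-Ala run
#' to `flank_max` residues after the last, clamped to the sequence
#' (`source = "auto"`).
#'
#' @param residues Normalized residue string of the record.
#' @param runs Tibble from [find_polyala_runs()] on `residues`.
#' @param user_bounds Optional length-2 integer vector, 0-based half-open.
#' @param flank_max Maximum flank retained around the outermost runs.
#' @return One-row tibble: `repetitive_start`, `repetitive_end`, `source`.
#' @export
delimit_repetitive_domain <- function(residues, runs, user_bounds = NULL,
                                      flank_max = 60L) {
  len <- nchar(residues)
  if (!is.null(user_bounds)) {
    stopifnot(length(user_bounds) == 2L)
    rs <- as.integer(user_bounds[1])
    re <- as.integer(user_bounds[2])
    if (rs < 0L || re > len || rs >= re) {
      stop("user bounds [", rs, ", ", re, ") invalid for sequence of length ",
           len, call. = FALSE)
    }
    return(tibble::tibble(repetitive_start = rs, repetitive_end = re,
                          source = "user"))
  }
  if (nrow(runs) == 0L) {
    stop("nonrepetitive input: no poly-Ala runs and no user bounds",
         call. = FALSE)
  }
  tibble::tibble(
    repetitive_start = max(0L, runs$start[1] - as.integer(flank_max)),
    repetitive_end = min(len, runs$end[nrow(runs)] + as.integer(flank_max)),
    source = "auto"
  )
}

#' Segment a repetitive domain into tandem repeat units
#'
#' A repeat boundary is placed at the start of each poly-Ala run, the only
#' anchor conserved across all surveyed taxa: unit *i* spans from run *i*'s
#' start to run *i + 1*'s start. Residues before the first run form a leading
#' partial segment reported with `index = -1` and `complete = FALSE`; the
#' final unit (last run to domain end) is likewise incomplete because the
#' domain ends inside its glycine-rich region. Joining the leading segment
#' and all units reconstructs the domain exactly.
#'
#' @param domain_seq Residue string of the repetitive domain.
#' @param runs Tibble from [find_polyala_runs()] with coordinates relative to
#'   `domain_seq`.
#' @return Tibble with columns `index` (-1 for the leading segment), `start`,
#'   `end` (0-based half-open within the domain), `sequence`, `complete`.
#' @export
segment_repeats <- function(domain_seq, runs) {
  len <- nchar(domain_seq)
  if (nrow(runs) == 0L) {
    return(tibble::tibble(index = 0L, start = 0L, end = len,
                          sequence = domain_seq, complete = FALSE))
  }
  stopifnot(all(runs$start >= 0L), all(runs$end <= len))
  bounds <- c(runs$start, len)
  index <- integer(0); start <- integer(0); end <- integer(0)
  if (runs$start[1] > 0L) {
    index <- -1L; start <- 0L; end <- runs$start[1]
  }
  n_units <- length(bounds) - 1L
  index <- c(index, seq_len(n_units) - 1L)
  start <- c(start, bounds[-length(bounds)])
  end <- c(end, bounds[-1])
  complete <- c(if (runs$start[1] > 0L) FALSE else NULL,
                rep(TRUE, n_units - 1L), FALSE)
  tibble::tibble(
    index = index, start = start, end = end,
    sequence = substring(domain_seq, start + 1L, end),
    complete = complete
  )
}

#' Detect runs, delimit domains, and segment every sequence
#'
#' Data-frame-first wrapper running [find_polyala_runs()],
#' [delimit_repetitive_domain()] and [segment_repeats()] over a sequence
#' table. Records with no poly-Ala run and no user bounds are skipped with a
#' warning (they cannot carry the canonical repeat architecture).
#'
#' @param seqs Tibble with columns `id`, `residues` (from [read_fasta()]).
#' @param min_seed,min_total Poly-Ala detection parameters.
#' @param flank_max Domain flank retained around the outermost runs.
#' @param bounds Optional tibble with columns `id`, `rep_start`, `rep_end`
#'   (1-based inclusive, as in the metadata file) supplying per-sequence
#'   domain bounds.
#' @return Tibble of repeat units: `id`, `index`, `start`, `end` (0-based
#'   half-open, in record coordinates), `sequence`, `complete`,
#'   `n_polyala_runs`, plus domain columns `repetitive_start`,
#'   `repetitive_end`, `domain_source`.
#' @export
segment_spidroins <- function(seqs, min_seed = 3L, min_total = 4L,
                              flank_max = 60L, bounds = NULL) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  out <- purrr::map(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    residues <- seqs$residues[i]
    runs <- find_polyala_runs(residues, min_seed, min_total)
    ub <- NULL
    if (!is.null(bounds) && id %in% bounds$id) {
      row <- bounds[bounds$id == id, ]
      if (!is.na(row$rep_start[1]) && !is.na(row$rep_end[1])) {
        ub <- c(row$rep_start[1] - 1L, row$rep_end[1])  # 1-based incl -> 0-based half-open
      }
    }
    if (nrow(runs) == 0L && is.null(ub)) {
      warning("skipping '", id, "': nonrepetitive (no poly-Ala runs)",
              call. = FALSE)
      return(NULL)
    }
    dom <- delimit_repetitive_domain(residues, runs, user_bounds = ub,
                                     flank_max = flank_max)
    dom_seq <- substring(residues, dom$repetitive_start + 1L,
                         dom$repetitive_end)
    dom_runs <- runs |>
      dplyr::filter(.data$start >= dom$repetitive_start,
                    .data$end <= dom$repetitive_end) |>
      dplyr::mutate(start = .data$start - dom$repetitive_start,
                    end = .data$end - dom$repetitive_start)
    units <- segment_repeats(dom_seq, dom_runs)
    units |>
      dplyr::mutate(
        id = id,
        start = .data$start + dom$repetitive_start,
        end = .data$end + dom$repetitive_start,
        n_polyala_runs = nrow(dom_runs),
        repetitive_start = dom$repetitive_start,
        repetitive_end = dom$repetitive_end,
        domain_source = dom$source
      ) |>
      dplyr::relocate("id")
  })
  dplyr::bind_rows(purrr::compact(out))
}

#' Poly-alanine runs for every sequence
#'
#' @param seqs Tibble with columns `id`, `residues`.
#' @inheritParams segment_spidroins
#' @return Tibble of runs with an `id` column, coordinates in record space.
#' @export
polyala_runs <- function(seqs, min_seed = 3L, min_total = 4L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  purrr::map2(seqs$id, seqs$residues, function(id, residues) {
    runs <- find_polyala_runs(residues, min_seed, min_total)
    if (nrow(runs) == 0L) NULL else dplyr::mutate(runs, id = id, .before = 1L)
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}
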