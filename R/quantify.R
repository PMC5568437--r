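#' Motif abundance as percentage of repeat length
#'
#' The abundance of a motif within one repeat is the fraction of the repeat's
#' residues covered by its hits: `100 * count * motif_length /
#' repeat_length`, with motif lengths of 2 for `GX` and doublets and 3 for
#' `GGX`. Two GP hits in a 47-residue repeat give 8.51%, for example.
#'
#' @param repeat_profiles Tibble from [profile_repeats()] (columns
#'   `repeat_length`, `motif`, `count`).
#' @return The input with an added `percent_of_length` column.
#' @export
motif_abundance <- function(repeat_profiles) {
  if (any(repeat_profiles$repeat_length <= 0L)) {
    stop("repeat_length must be positive", call. = FALSE)
  }
  dplyr::mutate(
    repeat_profiles,
    percent_of_length = 100 * .data$count * motif_length(.data$motif) /
      .data$repeat_length
  )
}

#' Box-plot summary of a numeric vector
#'
#' Median and quartiles by linear interpolation between order statistics
#' (type-7 quantiles); whiskers are the most extreme data values within 1.5
#' interquartile ranges of the box; points beyond the whiskers are outliers.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `n`, `mean`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, `outliers` (list column).
#' @examples
#' box_summary(c(1, 1, 1, 10))
#' @export
box_summary <- function(values) {
  if (length(values) == 0L || any(is.na(values))) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  out <- values[values < lo_fence | values > hi_fence]
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = min(inside),
    whisker_high = max(inside),
    n_outliers = length(out),
    outliers = list(sort(out))
  )
}

#' Per-sequence repeat-length and motif-abundance summaries
#'
#' Pools the complete repeats of each sequence and reports a box summary of
#' repeat lengths (metric `"repeat_length"`) and, for each requested motif, a
#' box summary of its percent-of-repeat-length abundance plus the mean hit
#' count per repeat.
#'
#' @param repeat_profiles Tibble from [profile_repeats()].
#' @param motifs Motif labels to summarize (default: the three MaSp2
#'   diagnostics GP, QQ, GGY).
#' @return Tibble with columns `id`, `metric`, the [box_summary()] columns,
#'   and `mean_count_per_repeat` (`NA` for the repeat-length metric).
#' @export
summarize_sequences <- function(repeat_profiles,
                                motifs = c("GP", "QQ", "GGY")) {
  complete <- dplyr::filter(repeat_profiles, .data$complete)
  if (nrow(complete) == 0L) {
    stop("no complete repeats to summarize", call. = FALSE)
  }
  abun <- motif_abundance(complete)
  per_id <- function(df) {
    lengths <- df |>
      dplyr::distinct(.data$repeat_index, .data$repeat_length)
    len_row <- box_summary(lengths$repeat_length) |>
      dplyr::mutate(metric = "repeat_length", mean_count_per_repeat = NA_real_,
                    .before = 1L)
    motif_rows <- purrr::map(motifs, function(m) {
      sub <- df |> dplyr::filter(.data$motif == m)
      vals <- rep(0, nrow(lengths))
      counts <- rep(0, nrow(lengths))
      if (nrow(sub) > 0L) {
        idx <- match(sub$repeat_index, lengths$repeat_index)
        vals[idx] <- sub$percent_of_length
        counts[idx] <- sub$count
      }
      box_summary(vals) |>
        dplyr::mutate(metric = m, mean_count_per_repeat = mean(counts),
                      .before = 1L)
    })
    dplyr::bind_rows(len_row, motif_rows)
  }
  abun |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ per_id(.x)) |>
    dplyr::ungroup() |>
    dplyr::relocate("id", "metric")
}

#' Group per-sequence summaries by web architecture
#'
#' Joins the metadata's `web_architecture` onto the per-sequence summaries
#' (ids without metadata fall into `"unknown"`) and reports, for each
#' architecture group and metric, the per-sequence medians with their group
#' range. Groups are ordered orb, cobweb, sheet, none, unknown.
#'
#' @param seq_summaries Tibble from [summarize_sequences()].
#' @param metadata Tibble from [read_metadata()], or `NULL`.
#' @return Tibble with columns `web_architecture`, `metric`, `n_sequences`,
#'   `medians` (list column of per-sequence medians), `median_min`,
#'   `median_max`.
#' @export
group_by_architecture <- function(seq_summaries, metadata = NULL) {
  wa <- rep("unknown", nrow(seq_summaries))
  if (!is.null(metadata)) {
    hit <- match(seq_summaries$id, metadata$id)
    known <- !is.na(hit)
    wa[known] <- metadata$web_architecture[hit[known]]
    wa[is.na(wa)] <- "unknown"
  }
  seq_summaries |>
    dplyr::mutate(web_architecture = factor(wa, levels = web_architectures())) |>
    dplyr::group_by(.data$web_architecture, .data$metric) |>
    dplyr::summarise(
      n_sequences = dplyr::n(),
      medians = list(.data$median),
      median_min = min(.data$median),
      median_max = max(.data$median),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$web_architecture, .data$metric)
}
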