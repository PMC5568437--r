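#' Tile plot of conserved motif profiles
#'
#' One tile per (sequence, motif), shaded by occurrence fraction and outlined
#' where the motif passes the conservation threshold — the visual analogue of
#' comparing conserved-motif repertoires across sequences.
#'
#' @param profiles Tibble from [profile_sequences()].
#' @return A ggplot object.
#' @export
plot_motif_profile <- function(profiles) {
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(x = .data$motif, y = .data$id,
                 fill = .data$occurrence_fraction)
  ) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_point(
      data = dplyr::filter(profiles, .data$conserved),
      shape = 1, size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1),
                                 name = "occurrence\nfraction") +
    ggplot2::labs(x = "motif", y = NULL,
                  title = "Conserved motif profiles",
                  subtitle = "circled: conserved (occurrence >= theta)") +
    ggplot2::theme_minimal()
}

#' Box plots of repeat length / motif abundance by sequence
#'
#' Renders the per-sequence box summaries (median, quartiles, whiskers,
#' outlier counts) produced by [summarize_sequences()], optionally colored by
#' web architecture.
#'
#' @param seq_summaries Tibble from [summarize_sequences()].
#' @param metadata Optional tibble from [read_metadata()] supplying
#'   `web_architecture` fill colors.
#' @return A ggplot object.
#' @export
plot_abundance <- function(seq_summaries, metadata = NULL) {
  df <- seq_summaries
  df$web_architecture <- "unknown"
  if (!is.null(metadata)) {
    hit <- match(df$id, metadata$id)
    df$web_architecture[!is.na(hit)] <-
      metadata$web_architecture[hit[!is.na(hit)]]
  }
  df$web_architecture <- factor(df$web_architecture,
                                levels = web_architectures())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, fill = .data$web_architecture)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(orb = "gold", cobweb = "steelblue", sheet = "firebrick",
                 none = "seagreen", unknown = "grey70"),
      drop = FALSE, name = "web architecture"
    ) +
    ggplot2::labs(x = NULL,
                  y = "repeat length (residues) / abundance (% of repeat)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
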