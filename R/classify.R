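#' Superimpose sequence profiles into a consensus motif profile
#'
#' The consensus set is the intersection of the members' conserved motif
#' sets — a motif is consensual only if every member sequence conserves it.
#' The partial map preserves the per-motif fraction of members conserving it,
#' so majority patterns remain visible.
#'
#' @param profiles Tibble from [profile_sequences()] covering one or more
#'   sequence ids.
#' @return An object of class `spidroin_consensus` with members, the
#'   consensus motif set, and the per-motif member fractions. Use
#'   [generics::tidy()] for the per-motif table and [generics::glance()] for
#'   the one-row summary.
#' @export
derive_consensus <- function(profiles) {
  if (nrow(profiles) == 0L) {
    stop("cannot derive a consensus from zero profiles", call. = FALSE)
  }
  members <- unique(profiles$id)
  partial <- profiles |>
    dplyr::filter(.data$conserved) |>
    dplyr::distinct(.data$id, .data$motif) |>
    dplyr::count(.data$motif, name = "n_members") |>
    dplyr::mutate(fraction = .data$n_members / length(members)) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$motif)
  structure(
    list(
      members = members,
      consensus_set = sort(partial$motif[partial$fraction == 1]),
      partial_map = partial
    ),
    class = "spidroin_consensus"
  )
}

#' @export
print.spidroin_consensus <- function(x, ...) {
  cat("<spidroin_consensus> ", length(x$members), " member(s)\n", sep = "")
  cat("  consensus set: {", paste(x$consensus_set, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn derive_consensus Per-motif member fractions as a tibble.
#' @param x A `spidroin_consensus` object.
#' @param ... Unused.
#' @export
tidy.spidroin_consensus <- function(x, ...) {
  dplyr::mutate(x$partial_map, consensus = .data$fraction == 1)
}

#' @describeIn derive_consensus One-row summary (members, consensus size).
#' @export
glance.spidroin_consensus <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    n_consensus_motifs = length(x$consensus_set),
    consensus_motifs = paste(x$consensus_set, collapse = ",")
  )
}

#' Classify one conserved-motif repertoire as MaSp1 / MaSp2 / intermediate
#'
#' Decision rules, applied in order to a sequence with canonical repeat
#' architecture: conserved QQ together with conserved GP is diagnostic for
#' MaSp2; absence of QQ with a conserved GGY (or its GGF substitute, as in
#' *Euprosthenops australis*) indicates MaSp1; conserved QQ without GP is the
#' intermediate repertoire seen in *Tetragnatha*; anything else is
#' intermediate with no diagnostic motifs. Sequences without the canonical
#' poly-Ala / glycine-rich alternation are nonconforming and never receive a
#' MaSp label. Note GP without QQ but with GGY classifies as MaSp1 — the ADF4
#' situation, a proline-rich sequence whose motif repertoire is MaSp1-like.
#'
#' @param conserved Character vector of conserved motif labels.
#' @param architecture_ok Does the sequence show the canonical alternating
#'   poly-Ala / Gly-rich architecture?
#' @param strict_ggy If `TRUE`, only GGY (not GGF) satisfies the MaSp1
#'   criterion.
#' @return A list with `label` and `evidence` (character vector of rule
#'   firings).
#' @export
classify_profile <- function(conserved, architecture_ok, strict_ggy = FALSE) {
  if (!architecture_ok) {
    return(list(label = "nonconforming",
                evidence = "no canonical poly-Ala/Gly-rich architecture"))
  }
  has_qq <- "QQ" %in% conserved
  has_gp <- "GP" %in% conserved
  ggy_like <- c("GGY", if (!strict_ggy) "GGF")
  has_ggy <- any(ggy_like %in% conserved)
  if (has_qq && has_gp) {
    list(label = "MaSp2", evidence = "conserved QQ and GP")
  } else if (!has_qq && has_ggy) {
    list(label = "MaSp1",
         evidence = paste0("no conserved QQ; conserved ",
                           intersect(ggy_like, conserved)[1]))
  } else if (has_qq && !has_gp) {
    list(label = "intermediate", evidence = "conserved QQ without GP")
  } else {
    list(label = "intermediate", evidence = "no diagnostic motifs")
  }
}

#' Classify every profiled sequence
#'
#' Canonical architecture is operationalized as at least two poly-Ala runs
#' and at least one complete tandem repeat. Sequences present in `units` but
#' failing that test are labelled nonconforming even if they were profiled.
#'
#' @param profiles Tibble from [profile_sequences()].
#' @param units Tibble from [segment_spidroins()] (for the architecture
#'   check). Pass `NULL` to assume canonical architecture for all ids.
#' @param strict_ggy See [classify_profile()].
#' @param theta Unused here; conservation is already encoded in `profiles`.
#' @return Tibble with columns `id`, `label`, `evidence`.
#' @export
classify_spidroins <- function(profiles, units = NULL, strict_ggy = FALSE) {
  ids <- unique(profiles$id)
  arch <- rep(TRUE, length(ids))
  names(arch) <- ids
  if (!is.null(units)) {
    ok <- units |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(
        ok = dplyr::first(.data$n_polyala_runs) >= 2L & any(.data$complete),
        .groups = "drop"
      )
    arch[ok$id[!ok$ok]] <- FALSE
  }
  purrr::map(ids, function(one) {
    res <- classify_profile(conserved_set(profiles, one), arch[[one]],
                            strict_ggy = strict_ggy)
    tibble::tibble(id = one, label = res$label,
                   evidence = paste(res$evidence, collapse = "; "))
  }) |>
    dplyr::bind_rows()
}

#' Araneidae MaSp2 consensus flank templates
#'
#' The extended Araneidae MaSp2 consensus wraps each 6-9 residue poly-Ala
#' stretch with a conserved 14-residue upstream flank, `GQQGPGGQGPYGP(G/S)`,
#' and a 10-residue downstream flank, `GGYGPG(A/S)GQQ`; bracketed positions
#' match either residue.
#'
#' @return A list with `upstream` and `downstream`, each a list of allowed
#'   residue sets per position.
#' @export
araneidae_templates <- function() {
  expand <- function(spec) {
    purrr::map(spec, function(p) strsplit(p, "", fixed = TRUE)[[1]])
  }
  list(
    upstream = expand(c("G", "Q", "Q", "G", "P", "G", "G", "Q", "G", "P",
                        "Y", "G", "P", "GS")),
    downstream = expand(c("G", "G", "Y", "G", "P", "G", "AS", "G", "Q", "Q"))
  )
}

#' Instantiate the Araneidae consensus core
#'
#' Builds the explicit consensus string for a given poly-Ala length, with the
#' ambiguous positions fixed (`G` at the upstream G/S position, `A`
#' downstream), e.g. `an_length = 7` gives the 31-residue
#' `GQQGPGGQGPYGPGAAAAAAAGGYGPGAGQQ`.
#'
#' @param an_length Number of alanines in the poly-Ala stretch (6-9).
#' @param upstream_choice,downstream_choice Residue used at the ambiguous
#'   template positions.
#' @return A single residue string of length `24 + an_length`.
#' @export
araneidae_consensus_core <- function(an_length, upstream_choice = "G",
                                     downstream_choice = "A") {
  stopifnot(an_length >= 6L, an_length <= 9L)
  paste0("GQQGPGGQGPYGP", upstream_choice,
         strrep("A", an_length),
         "GGYGPG", downstream_choice, "GQQ")
}

#' Match poly-Ala runs against the extended Araneidae MaSp2 consensus
#'
#' For each poly-Ala run of length 6-9 with at least 14 residues upstream and
#' 10 downstream, the immediately flanking 14-mer and 10-mer are compared
#' position-wise against the consensus templates (see
#' [araneidae_templates()]); a run matches when the total mismatch count is
#' at most `max_mismatch`. Runs failing the length or flank eligibility are
#' reported unmatched with mismatch counts unset.
#'
#' @param domain_seq Residue string (repetitive domain or full record).
#' @param runs Tibble from [find_polyala_runs()] on `domain_seq`.
#' @param max_mismatch Maximum tolerated mismatches across the 24 templated
#'   positions (default 3).
#' @return Tibble with one row per run: `run_start`, `run_end`,
#'   `polyala_length`, `eligible`, `upstream_flank`, `downstream_flank`,
#'   `upstream_mismatches`, `downstream_mismatches`, `matched`.
#' @export
match_araneidae_consensus <- function(domain_seq, runs, max_mismatch = 3L) {
  tmpl <- araneidae_templates()
  n_up <- length(tmpl$upstream)
  n_down <- length(tmpl$downstream)
  len <- nchar(domain_seq)
  count_mismatches <- function(flank, template) {
    chars <- strsplit(flank, "", fixed = TRUE)[[1]]
    sum(!purrr::map2_lgl(chars, template, ~ .x %in% .y))
  }
  purrr::map(seq_len(nrow(runs)), function(k) {
    s <- runs$start[k]
    e <- runs$end[k]
    plen <- runs$length[k]
    eligible <- plen >= 6L && plen <= 9L && s >= n_up && e + n_down <= len
    if (!eligible) {
      return(tibble::tibble(
        run_start = s, run_end = e, polyala_length = plen, eligible = FALSE,
        upstream_flank = NA_character_, downstream_flank = NA_character_,
        upstream_mismatches = NA_integer_, downstream_mismatches = NA_integer_,
        matched = FALSE
      ))
    }
    up <- substring(domain_seq, s - n_up + 1L, s)
    down <- substring(domain_seq, e + 1L, e + n_down)
    up_mm <- count_mismatches(up, tmpl$upstream)
    down_mm <- count_mismatches(down, tmpl$downstream)
    tibble::tibble(
      run_start = s, run_end = e, polyala_length = plen, eligible = TRUE,
      upstream_flank = up, downstream_flank = down,
      upstream_mismatches = up_mm, downstream_mismatches = down_mm,
      matched = (up_mm + down_mm) <= max_mismatch
    )
  }) |>
    dplyr::bind_rows()
}

#' Consensus matching across a sequence table
#'
#' @param seqs Tibble with columns `id`, `residues`.
#' @param max_mismatch See [match_araneidae_consensus()].
#' @param min_seed,min_total Poly-Ala detection parameters.
#' @return Tibble of per-run match reports with an `id` column.
#' @export
match_consensus <- function(seqs, max_mismatch = 3L, min_seed = 3L,
                            min_total = 4L) {
  purrr::map2(seqs$id, seqs$residues, function(id, residues) {
    runs <- find_polyala_runs(residues, min_seed, min_total)
    if (nrow(runs) == 0L) {
      return(NULL)
    }
    match_araneidae_consensus(residues, runs, max_mismatch) |>
      dplyr::mutate(id = id, .before = 1L)
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}
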