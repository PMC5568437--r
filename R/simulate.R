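#' Specification for one synthetic spidroin sequence
#'
#' Describes the generating process for a spidroin-like sequence of
#' `n_repeats` tandem repeats, each an alternation of a poly-alanine run and
#' a glycine-rich region assembled from catalog motifs sampled by weight.
#' Identical specs (including `seed`) always produce identical sequences.
#'
#' @param n_repeats Number of tandem repeats (>= 1). Under the
#'   poly-Ala-anchored segmentation convention the last repeat is reported
#'   incomplete, so `n_repeats` repeats yield `n_repeats - 1` complete units.
#' @param polyala_lengths Candidate poly-Ala lengths: either an unnamed
#'   integer vector sampled uniformly (default `6:9`, the canonical range) or
#'   a named numeric vector of weights over lengths in 4..12.
#' @param interruption_prob Probability that a run carries one interior
#'   G/S/V interruption (applied only when the run is long enough to keep
#'   three alanines on each side, so detection still recovers the planted
#'   boundaries).
#' @param motif_weights Named non-negative weights over motif labels used to
#'   build the Gly-rich regions.
#' @param glyrich_length Target residues of planted motifs per Gly-rich
#'   region (motifs are drawn until their summed length reaches it).
#' @param linker_residues Residues available for the 0-2 spacer positions
#'   between planted motifs.
#' @param substitution_rate Per-residue substitution probability applied to
#'   the finished sequence; ground truth records the pre-noise state.
#' @param seed Integer seed; every random draw for this sequence derives
#'   from it.
#' @param class_label Intended class (`"MaSp1"`, `"MaSp2"`,
#'   `"intermediate"`, or free text).
#' @param web_architecture Planted web architecture for the metadata table.
#' @param species,family Optional metadata strings.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_repeats = 20L,
                     polyala_lengths = 6:9,
                     interruption_prob = 0.1,
                     motif_weights = c(GP = 4, QQ = 2, GGY = 2, GS = 1),
                     glyrich_length = 25L,
                     linker_residues = c("G", "Y", "S"),
                     substitution_rate = 0,
                     seed = 1L,
                     class_label = "custom",
                     web_architecture = "unknown",
                     species = NA_character_,
                     family = NA_character_) {
  if (n_repeats < 1L) {
    stop("n_repeats must be >= 1", call. = FALSE)
  }
  if (is.null(names(motif_weights)) || length(motif_weights) == 0L) {
    stop("motif_weights must be a non-empty named vector", call. = FALSE)
  }
  if (any(!is.finite(motif_weights)) || any(motif_weights < 0) ||
      sum(motif_weights) <= 0) {
    stop("motif_weights must be finite, non-negative, with positive sum",
         call. = FALSE)
  }
  lens <- if (is.null(names(polyala_lengths))) {
    as.integer(polyala_lengths)
  } else {
    as.integer(names(polyala_lengths))
  }
  if (any(lens < 4L) || any(lens > 12L)) {
    stop("polyala_lengths must lie in 4..12", call. = FALSE)
  }
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            interruption_prob >= 0, interruption_prob <= 1)
  structure(
    list(
      n_repeats = as.integer(n_repeats),
      polyala_lengths = polyala_lengths,
      interruption_prob = interruption_prob,
      motif_weights = motif_weights[motif_weights > 0],
      glyrich_length = as.integer(glyrich_length),
      linker_residues = toupper(linker_residues),
      substitution_rate = substitution_rate,
      seed = as.integer(seed),
      class_label = class_label,
      web_architecture = web_architecture,
      species = species,
      family = family
    ),
    class = "sim_spec"
  )
}

#' Canonical MaSp1 / MaSp2 / intermediate generating specs
#'
#' Convenience constructors with the canonical motif repertoires: MaSp1
#' (GGY, GA, GQ; no glutamine doublets, no proline), MaSp2 (GP, QQ, GGY,
#' GS), and the intermediate *Tetragnatha*-like repertoire (QQ and GGX
#' motifs without proline).
#'
#' @param ... Passed to [sim_spec()] to override defaults.
#' @export
masp1_spec <- function(...) {
  args <- list(...)
  defaults <- list(motif_weights = c(GGY = 3, GA = 2, GQ = 2),
                   class_label = "MaSp1")
  do.call(sim_spec, utils::modifyList(defaults, args))
}

#' @rdname masp1_spec
#' @export
masp2_spec <- function(...) {
  args <- list(...)
  defaults <- list(motif_weights = c(GP = 4, QQ = 2, GGY = 2, GS = 1),
                   class_label = "MaSp2")
  do.call(sim_spec, utils::modifyList(defaults, args))
}

#' @rdname masp1_spec
#' @export
intermediate_spec <- function(...) {
  args <- list(...)
  defaults <- list(motif_weights = c(QQ = 2, GGY = 2, GS = 2, GGL = 1),
                   class_label = "intermediate")
  do.call(sim_spec, utils::modifyList(defaults, args))
}

resample <- function(x, size = 1L, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

sample_polyala_length <- function(polyala_lengths) {
  if (is.null(names(polyala_lengths))) {
    resample(as.integer(polyala_lengths))
  } else {
    resample(as.integer(names(polyala_lengths)),
             prob = as.numeric(polyala_lengths))
  }
}

# Linker characters between planted motifs, chosen so that the scanner's
# precedence passes cannot convert or extend a planted motif:
#  - never 'A' (would blur into a poly-Ala run),
#  - never equal to an adjacent Q/S (would extend a doublet context),
#  - never 'G' immediately before a G-initial motif (would convert a planted
#    GX into a GGX hit).
safe_linker <- function(n, linker_residues, prev_char, next_first) {
  pool0 <- setdiff(linker_residues, "A")
  out <- character(n)
  prev <- prev_char
  for (i in seq_len(n)) {
    pool <- pool0
    if (prev %in% c("Q", "S")) pool <- setdiff(pool, prev)
    if (i == n) {
      if (next_first == "G") pool <- setdiff(pool, "G")
      if (next_first %in% c("Q", "S")) pool <- setdiff(pool, next_first)
    }
    if (length(pool) == 0L) {
      return(out[seq_len(i - 1L)])
    }
    out[i] <- resample(pool)
    prev <- out[i]
  }
  out
}

build_glyrich <- function(spec) {
  labels <- names(spec$motif_weights)
  weights <- as.numeric(spec$motif_weights)
  chunks <- character(0)
  planted <- character(0)
  planted_len <- 0L
  prev_char <- "A"  # region always follows a poly-Ala run
  while (planted_len < spec$glyrich_length) {
    m <- resample(labels, prob = weights)
    if (length(chunks) > 0L) {
      link <- safe_linker(resample(0:2), spec$linker_residues, prev_char,
                          substr(m, 1L, 1L))
      if (length(link) > 0L) {
        chunks <- c(chunks, paste(link, collapse = ""))
        prev_char <- link[length(link)]
      }
    }
    if (prev_char == "G" && substr(m, 1L, 1L) == "G") {
      # zero-length linker landed a G next to a G-initial motif: pad with a
      # guaranteed-neutral residue
      pad <- setdiff(spec$linker_residues, c("A", "G"))
      if (length(pad) == 0L) pad <- "Y"
      chunks <- c(chunks, resample(pad))
    }
    chunks <- c(chunks, m)
    prev_char <- substr(m, nchar(m), nchar(m))
    planted <- c(planted, m)
    planted_len <- planted_len + nchar(m)
  }
  list(text = paste(chunks, collapse = ""), planted = planted,
       last_char = prev_char)
}

build_polyala <- function(spec) {
  len <- sample_polyala_length(spec$polyala_lengths)
  chars <- rep("A", len)
  if (len >= 7L && stats::runif(1) < spec$interruption_prob) {
    pos <- resample(4:(len - 3L))
    chars[pos] <- resample(c("G", "S", "V"))
  }
  paste(chars, collapse = "")
}

apply_noise <- function(residues, rate, free_noise = FALSE) {
  if (rate <= 0) {
    return(residues)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  if (!free_noise) {
    aa <- setdiff(aa, "A")  # keep planted poly-Ala boundaries decidable
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- resample(setdiff(aa, chars[i]))
  }
  paste(chars, collapse = "")
}

#' Simulate one spidroin-like sequence with ground truth
#'
#' Emits `n_repeats` units, each a sampled poly-Ala run followed by a
#' Gly-rich region of planted motifs separated by 0-2 linker residues, then
#' applies substitution noise. The ground truth records the pre-noise planted
#' motif counts per repeat, the planted repeat boundaries (the 0-based start
#' of each poly-Ala run), and the intended class label.
#'
#' @param spec A [sim_spec()].
#' @param id Sequence identifier.
#' @param free_noise If `TRUE`, noise substitutions may introduce alanines
#'   (by default they never do, so segmentation truth stays well defined).
#' @return A list with `record` (one-row tibble: `id`, `description`,
#'   `residues`), `truth` (list: `label`, `boundaries`, `counts`), and
#'   `spec`.
#' @export
simulate_spidroin <- function(spec, id = "sim1", free_noise = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    pieces <- character(0)
    boundary <- integer(spec$n_repeats)
    counts <- vector("list", spec$n_repeats)
    pos <- 0L
    for (r in seq_len(spec$n_repeats)) {
      boundary[r] <- pos
      pa <- build_polyala(spec)
      gr <- build_glyrich(spec)
      unit <- paste0(pa, gr$text)
      if (r < spec$n_repeats && gr$last_char == "A") {
        # keep a planted terminal alanine from fusing into the next run
        pad <- setdiff(spec$linker_residues, c("A", "G"))
        if (length(pad) == 0L) pad <- "Y"
        unit <- paste0(unit, resample(pad))
      }
      pieces <- c(pieces, unit)
      pos <- pos + nchar(unit)
      tab <- table(gr$planted)
      counts[[r]] <- tibble::tibble(
        repeat_index = r - 1L,
        motif = names(tab),
        count = as.integer(tab)
      )
    }
    residues <- apply_noise(paste(pieces, collapse = ""),
                            spec$substitution_rate, free_noise)
    list(
      record = tibble::tibble(
        id = id,
        description = paste0("synthetic ", spec$class_label, " spidroin"),
        residues = residues
      ),
      truth = list(
        label = spec$class_label,
        boundaries = tibble::tibble(
          repeat_index = seq_len(spec$n_repeats) - 1L,
          start = boundary
        ),
        counts = dplyr::bind_rows(counts)
      ),
      spec = spec
    )
  })
}

#' Simulate a sequence carrying the Araneidae MaSp2 consensus
#'
#' Every repeat consists of the exact 14-residue upstream template
#' `GQQGPGGQGPYGP(G/S)`, a pure poly-Ala stretch of `an_length` alanines,
#' the exact 10-residue downstream template `GGYGPG(A/S)GQQ`, and a variable
#' spacer of 0-3 GP/QQ motifs; the bracketed template positions are sampled.
#' At zero noise every run therefore matches the consensus at zero
#' mismatches.
#'
#' @param spec A [sim_spec()] (its `n_repeats`, `substitution_rate`, and
#'   `seed` are used).
#' @param an_length Poly-Ala length, 6-9.
#' @inheritParams simulate_spidroin
#' @return As [simulate_spidroin()]; `truth$counts` tallies the variable
#'   spacer motifs only (the fixed templates contribute constant counts).
#' @export
embed_consensus <- function(spec, an_length = 7L, id = "cons1",
                            free_noise = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  if (an_length < 6L || an_length > 9L) {
    stop("an_length must be in 6..9", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    pieces <- character(0)
    boundary <- integer(spec$n_repeats)
    counts <- vector("list", spec$n_repeats)
    pos <- 0L
    for (r in seq_len(spec$n_repeats)) {
      up <- paste0("GQQGPGGQGPYGP", resample(c("G", "S")))
      down <- paste0("GGYGPG", resample(c("A", "S")), "GQQ")
      k <- resample(0:3)
      spacer_motifs <- if (k > 0) resample(c("GP", "QQ"), k) else character(0)
      unit <- paste0(up, strrep("A", an_length), down,
                     paste(spacer_motifs, collapse = ""))
      boundary[r] <- pos + nchar(up)
      pieces <- c(pieces, unit)
      pos <- pos + nchar(unit)
      tab <- table(spacer_motifs)
      counts[[r]] <- tibble::tibble(
        repeat_index = r - 1L,
        motif = if (length(tab)) names(tab) else character(0),
        count = if (length(tab)) as.integer(tab) else integer(0)
      )
    }
    residues <- apply_noise(paste(pieces, collapse = ""),
                            spec$substitution_rate, free_noise)
    list(
      record = tibble::tibble(
        id = id,
        description = "synthetic Araneidae-consensus spidroin",
        residues = residues
      ),
      truth = list(
        label = spec$class_label,
        boundaries = tibble::tibble(
          repeat_index = seq_len(spec$n_repeats) - 1L,
          start = boundary
        ),
        counts = dplyr::bind_rows(counts)
      ),
      spec = spec
    )
  })
}

#' Simulate a panel of spidroin sequences
#'
#' Per-record seeds are derived deterministically from the panel seed, so the
#' same call always yields byte-identical output files.
#'
#' @param specs List of [sim_spec()] objects.
#' @param seed Panel seed.
#' @param ids Optional character vector of record ids (default
#'   `sim001, sim002, ...`). Must be unique.
#' @param out_dir Optional directory; when given, writes `panel.fasta`,
#'   `metadata.tsv`, and `truth.tsv` there.
#' @return A list with `sequences` (tibble of records), `metadata` (tibble:
#'   `id`, `species`, `family`, `spidroin_label`, `web_architecture`), and
#'   `truth` (tibble: `id`, `repeat_index`, `repeat_start`, `motif`,
#'   `count`, `label`).
#' @export
simulate_panel <- function(specs, seed = 1L, ids = NULL, out_dir = NULL) {
  if (length(specs) == 0L) {
    stop("specs must be non-empty", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- sprintf("sim%03d", seq_along(specs))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ids in panel", call. = FALSE)
  }
  sims <- purrr::imap(specs, function(spec, i) {
    derived <- ((as.integer(seed) %% 100000L) * 10007L + i * 7919L) %%
      2147483647L
    spec$seed <- as.integer(derived)
    simulate_spidroin(spec, id = ids[i])
  })
  sequences <- dplyr::bind_rows(purrr::map(sims, "record"))
  metadata <- dplyr::bind_rows(purrr::imap(specs, function(spec, i) {
    tibble::tibble(
      id = ids[i],
      species = spec$species,
      family = spec$family,
      spidroin_label = spec$class_label,
      web_architecture = spec$web_architecture
    )
  }))
  truth <- dplyr::bind_rows(purrr::map(sims, function(sim) {
    sim$truth$counts |>
      dplyr::left_join(sim$truth$boundaries, by = "repeat_index") |>
      dplyr::transmute(
        id = sim$record$id,
        repeat_index = .data$repeat_index,
        repeat_start = .data$start,
        motif = .data$motif,
        count = .data$count,
        label = sim$truth$label
      )
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sequences, file.path(out_dir, "panel.fasta"))
    readr::write_tsv(metadata, file.path(out_dir, "metadata.tsv"),
                     progress = FALSE)
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  list(sequences = sequences, metadata = metadata, truth = truth)
}
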