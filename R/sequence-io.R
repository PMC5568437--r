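#' Normalize an amino-acid string
#'
#' Uppercases, strips whitespace and digits, removes a single trailing stop
#' (`*`) if present, and rejects any remaining character outside A-Z. Internal
#' stops are rejected: a `*` is only tolerated at the very end, where
#' conceptual-translation FASTA files often carry it. Ambiguity codes X/B/Z
#' are retained but never match a motif or a poly-Ala residue downstream.
#'
#' @param residues Character vector of raw sequence strings.
#' @return Character vector of normalized residue strings.
#' @export
normalize_residues <- function(residues) {
  out <- toupper(gsub("[[:space:][:digit:]]", "", residues))
  out <- sub("\\*$", "", out)
  bad <- grepl("[^A-Z]", out)
  if (any(bad)) {
    stop("invalid residue characters in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with one row per entry, in file order: `id` (first
#'   whitespace-delimited token of the header), `description` (remainder of
#'   the header), `residues` (normalized residue string).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 test", "gqqgpg"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)  # byte set: tolerate case/stops, normalize below
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  raw <- as.character(set)
  empty <- !nzchar(raw)
  if (any(empty)) {
    stop("FASTA entry with empty sequence: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    id = unname(ids),
    description = unname(desc),
    residues = unname(normalize_residues(raw))
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id`, `residues`, and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  headers <- seqs$id
  if ("description" %in% names(seqs)) {
    has_desc <- nzchar(seqs$description)
    headers[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Recognized web-architecture categories, in reporting order
#' @export
web_architectures <- function() {
  c("orb", "cobweb", "sheet", "none", "unknown")
}

#' Read a per-sequence metadata table
#'
#' Tab-separated with a header row; must contain an `id` column and may
#' contain `species`, `family`, `spidroin_label`, `web_architecture`, and
#' 1-based inclusive repetitive-domain bounds `rep_start`, `rep_end`.
#' Unrecognized `web_architecture` strings are mapped to `"unknown"` with a
#' warning; missing columns are filled with `NA` (architecture with
#' `"unknown"`).
#'
#' @param path Path to the TSV file.
#' @return A tibble keyed by `id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path, call. = FALSE)
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"id" %in% names(tbl)) {
    stop("metadata is missing the required 'id' column", call. = FALSE)
  }
  if (anyDuplicated(tbl$id)) {
    stop("duplicate ids in metadata: ",
         paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("species", "family", "spidroin_label")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  if (!"web_architecture" %in% names(tbl)) {
    tbl$web_architecture <- "unknown"
  }
  wa <- tolower(trimws(tbl$web_architecture))
  wa[is.na(wa) | !nzchar(wa)] <- "unknown"
  bad <- !wa %in% web_architectures()
  if (any(bad)) {
    warning("unrecognized web_architecture value(s) mapped to 'unknown': ",
            paste(unique(tbl$web_architecture[bad]), collapse = ", "),
            call. = FALSE)
    wa[bad] <- "unknown"
  }
  tbl$web_architecture <- wa
  for (col in c("rep_start", "rep_end")) {
    if (col %in% names(tbl)) tbl[[col]] <- as.integer(tbl[[col]])
  }
  tbl
}

#' Write a result table as TSV or JSON
#'
#' Column order is preserved as given; floating-point values are written with
#' four decimal places so reruns are byte-identical.
#'
#' @param rows A data frame of results (possibly zero rows).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  is_dbl <- vapply(rows, is.double, logical(1))
  rows[is_dbl] <- lapply(rows[is_dbl], function(x) sprintf("%.4f", x))
  if (format == "tsv") {
    readr::write_tsv(rows, path, progress = FALSE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
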