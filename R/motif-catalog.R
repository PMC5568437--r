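#' Motif catalog for spidroin repeat scanning
#'
#' The catalog defines the short amino-acid motifs searched for in each tandem
#' repeat: two-residue `GX` and three-residue `GGX` glycine-led patterns, where
#' `X` is drawn from a restricted alphabet, plus the di-glutamine (`QQ`) and
#' di-serine (`SS`) doublets. Motif classes are mutually exclusive within a
#' repeat and are assigned in precedence order (doublets, then `GGX`, then
#' `GX`) so that no residue is counted twice.
#'
#' @param x_alphabet Character vector of residues allowed as `X` in `GX`/`GGX`.
#'   Must not contain `G` (a `G` in the X position would make `GGG`/`GG`
#'   assignments ambiguous).
#' @param doublets Character vector of homopolymer doublet motifs.
#' @param precedence Character vector ordering the three scan passes; a
#'   permutation of `c("doublet", "GGX", "GX")`.
#' @return An object of class `motif_catalog`.
#' @examples
#' motif_catalog()
#' @export
motif_catalog <- function(x_alphabet = c("A", "S", "Y", "Q", "D", "R", "P", "N", "L", "F"),
                          doublets = c("QQ", "SS"),
                          precedence = c("doublet", "GGX", "GX")) {
  x_alphabet <- toupper(x_alphabet)
  if ("G" %in% x_alphabet) {
    stop("x_alphabet must not contain 'G'", call. = FALSE)
  }
  if (!all(nchar(doublets) == 2L) ||
      !all(substr(doublets, 1L, 1L) == substr(doublets, 2L, 2L))) {
    stop("doublets must be two identical residues, e.g. 'QQ'", call. = FALSE)
  }
  if (!setequal(precedence, c("doublet", "GGX", "GX"))) {
    stop("precedence must be a permutation of c('doublet', 'GGX', 'GX')",
         call. = FALSE)
  }
  structure(
    list(x_alphabet = x_alphabet, doublets = doublets, precedence = precedence),
    class = "motif_catalog"
  )
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("<motif_catalog>\n")
  cat("  GX/GGX with X in {", paste(x$x_alphabet, collapse = ","), "}\n", sep = "")
  cat("  doublets: ", paste(x$doublets, collapse = ", "), "\n", sep = "")
  cat("  precedence: ", paste(x$precedence, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Motif labels and lengths
#'
#' Enumerates every motif label a catalog can emit, with its length in
#' residues (2 for `GX` and doublets, 3 for `GGX`).
#'
#' @param catalog A [motif_catalog()].
#' @return A tibble with columns `motif` and `motif_length`.
#' @export
motif_lengths <- function(catalog = motif_catalog()) {
  tibble::tibble(
    motif = c(catalog$doublets,
              paste0("GG", catalog$x_alphabet),
              paste0("G", catalog$x_alphabet)),
    motif_length = c(rep(2L, length(catalog$doublets)),
                     rep(3L, length(catalog$x_alphabet)),
                     rep(2L, length(catalog$x_alphabet)))
  )
}

#' Length in residues of a motif label
#'
#' @param motif Character vector of motif labels (e.g. `"GP"`, `"GGY"`, `"QQ"`).
#' @return Integer vector of residue lengths.
#' @export
motif_length <- function(motif) {
  nchar(motif)
}
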