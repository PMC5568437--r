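# Independent oracles used by the property tests. These deliberately use a
# different algorithmic route from the package implementation: the scanner
# oracle solves each precedence pass as an explicit optimization (maximum
# number of non-overlapping hits, ties broken toward lexicographically
# earliest start positions) by recursion over candidate placements, and the
# box-plot oracle computes interpolated quantiles and fences from first
# principles.

# Best subset of fixed-width candidate placements: maximize count, then
# prefer lexicographically earliest starts. Returns integer starts.
best_placement <- function(starts, width) {
  if (length(starts) == 0L) {
    return(integer(0))
  }
  rec <- function(i, blocked_until) {
    if (i > length(starts)) {
      return(integer(0))
    }
    s <- starts[i]
    skip <- rec(i + 1L, blocked_until)
    if (s <= blocked_until) {
      return(skip)
    }
    take <- c(s, rec(i + 1L, s + width - 1L))
    if (length(take) >= length(skip)) take else skip
  }
  rec(1L, -1L)
}

oracle_scan_motifs <- function(repeat_seq, catalog = spidromotif::motif_catalog()) {
  chars <- strsplit(repeat_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  assigned <- logical(n)
  hits <- list()
  claim <- function(label, starts, width) {
    for (s in starts) {
      assigned[s:(s + width - 1L)] <<- TRUE
      hits[[length(hits) + 1L]] <<-
        data.frame(motif = label, start = s - 1L, length = width)
    }
  }
  free <- function(s, width) {
    s >= 1L && s + width - 1L <= n && !any(assigned[s:(s + width - 1L)])
  }
  for (pass in catalog$precedence) {
    if (pass == "doublet") {
      for (d in catalog$doublets) {
        res <- substr(d, 1, 1)
        cand <- which(chars == res & c(chars[-1], "") == res)
        cand <- cand[vapply(cand, free, logical(1), width = 2L)]
        claim(d, best_placement(cand, 2L), 2L)
      }
    } else if (pass == "GGX") {
      cand <- which(
        chars == "G" &
          c(chars[-1], "") == "G" &
          c(chars[-(1:2)], "", "") %in% catalog$x_alphabet
      )
      cand <- cand[vapply(cand, free, logical(1), width = 3L)]
      for (s in best_placement(cand, 3L)) {
        claim(paste0("GG", chars[s + 2L]), s, 3L)
      }
    } else {
      cand <- which(chars == "G" & c(chars[-1], "") %in% catalog$x_alphabet)
      cand <- cand[vapply(cand, free, logical(1), width = 2L)]
      for (s in best_placement(cand, 2L)) {
        claim(paste0("G", chars[s + 1L]), s, 2L)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      length = integer(0)))
  }
  out[order(out$start), , drop = FALSE]
}

# Interpolated quantile (type-7 convention) computed from first principles.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  if (lo + 1 >= length(x)) {
    return(x[length(x)])
  }
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

oracle_box <- function(values) {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  med <- oracle_quantile(values, 0.5)
  lo <- q1 - 1.5 * (q3 - q1)
  hi <- q3 + 1.5 * (q3 - q1)
  inside <- values[values >= lo & values <= hi]
  list(median = med, q1 = q1, q3 = q3,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo | values > hi]))
}

# Hand-constructed sequence profile rows (the shape profile_sequences()
# emits) for consensus/classification tests.
make_profile <- function(id, conserved, extra_present = character(0)) {
  motifs <- union(conserved, extra_present)
  tibble::tibble(
    id = id,
    motif = motifs,
    n_complete_repeats = 6L,
    occurrence_fraction = ifelse(motifs %in% conserved, 1, 0.1),
    mean_count_per_repeat = 1,
    present = TRUE,
    conserved = motifs %in% conserved
  )
}

random_protein <- function(n, alphabet = c("G", "A", "P", "Q", "S", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

scan_counts <- function(seq, catalog = spidromotif::motif_catalog()) {
  hits <- spidromotif::scan_motifs(seq, catalog)
  table(hits$motif)
}
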