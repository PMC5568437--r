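#!/usr/bin/env Rscript

# Optional extended suite over published spidroin repetitive-domain
# sequences. These checks need the GenBank entries on local disk (this
# toolkit performs no network access): download the repetitive-domain
# protein sequences for the accessions below into one directory as
# uncompressed FASTA, with each record id equal to its accession (e.g.
# ">U47855 ..."), then run
#
#   Rscript scripts/extended_acceptance.R --fasta-dir <dir> --out <path>
#
# Accessions used: U47855 (A. diadematus ADF4), AM490169 (E. australis
# MaSp2), EF595245 + EU177657 (Latrodectus MaSp2), M37137 (N. clavipes
# MaSp1), M92913 (N. clavipes MaSp2), JX202781 (A. bruennichi MaSp2).

suppressPackageStartupMessages({
  library(spidromotif)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
fasta_dir <- get_arg("--fasta-dir", NULL)
out_path <- get_arg("--out", "results/extended_acceptance.json")
if (is.null(fasta_dir) || !dir.exists(fasta_dir)) {
  stop("supply --fasta-dir pointing at the downloaded accession FASTAs")
}
dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

files <- list.files(fasta_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
seqs <- bind_rows(lapply(files, read_fasta))

results <- list()
put <- function(name, value, n) {
  results[[name]] <<- list(value = value, n = n)
}

have <- function(acc) all(acc %in% seqs$id)

seq_counts <- function(ids) {
  units <- segment_spidroins(seqs[seqs$id %in% ids, ])
  profile_repeats(units)
}

# ADF4: repetitive-region length and complete tandem repeats
if (have("U47855")) {
  adf4 <- seqs[seqs$id == "U47855", ]
  units <- segment_spidroins(adf4)
  put("adf4_repetitive_residues",
      unique(units$repetitive_end - units$repetitive_start), 1L)
  put("adf4_complete_repeats", sum(units$complete), nrow(units))
}

# E. australis MaSp2: median GP percent of repeat length
if (have("AM490169")) {
  s <- summarize_sequences(seq_counts("AM490169"), motifs = "GP")
  put("e_australis_median_gp_percent", s$median[s$metric == "GP"],
      s$n[s$metric == "GP"])
}

# Latrodectus MaSp2 (pooled accessions): GP percent and mean GP per repeat
lat <- intersect(c("EF595245", "EU177657"), seqs$id)
if (length(lat) > 0) {
  counts <- seq_counts(lat) |> mutate(id = "latrodectus_pooled")
  s <- summarize_sequences(counts, motifs = "GP")
  put("latrodectus_median_gp_percent", s$median[s$metric == "GP"],
      s$n[s$metric == "GP"])
  put("latrodectus_mean_gp_per_repeat",
      s$mean_count_per_repeat[s$metric == "GP"], s$n[s$metric == "GP"])
}

# N. clavipes: glutamine content of repeat residues (MaSp1 vs MaSp2)
gln_percent <- function(acc) {
  units <- segment_spidroins(seqs[seqs$id == acc, ]) |> filter(complete)
  res <- paste(units$sequence, collapse = "")
  100 * sum(strsplit(res, "")[[1]] == "Q") / nchar(res)
}
if (have("M37137")) {
  put("n_clavipes_masp1_gln_percent", gln_percent("M37137"), 1L)
}
if (have("M92913")) {
  put("n_clavipes_masp2_gln_percent", gln_percent("M92913"), 1L)
}

# Median MaSp2 repeat lengths
median_len <- function(acc) {
  s <- summarize_sequences(seq_counts(acc), motifs = character(0))
  s$median[s$metric == "repeat_length"]
}
if (have("EF595245")) {
  put("l_hesperus_median_repeat_length", median_len("EF595245"), 1L)
}
if (have("JX202781")) {
  put("a_bruennichi_median_repeat_length", median_len("JX202781"), 1L)
}

jsonlite::write_json(results, out_path, auto_unbox = TRUE, digits = NA)
cat("wrote", out_path, "\n")
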