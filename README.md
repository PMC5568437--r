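# spidromotif

Motif-based analysis of spider dragline silk protein (major ampullate
spidroin, MaSp) repetitive domains.

Dragline silk combines two spidroins, MaSp1 and MaSp2, whose mechanical
properties trace back to a long repetitive core: tandem repeats alternating
a poly-alanine run (β-sheet nanocrystals) with a glycine-rich region (the
amorphous fraction). The glycine-rich regions decompose almost entirely into
very short motifs. `spidromotif` makes that decomposition explicit and
computable, for anyone screening spidroin candidates from cDNA/genomic
surveys or transcriptome assemblies:

* **Segmentation** — detect poly-Ala runs (maximal runs of ≥3 A, merging a
  single G/S/V interruption, minimum length 4), delimit the repetitive
  domain, and cut it into tandem repeat units anchored at each run start.
* **Motif scanning** — count `GX` and `GGX` hits with
  `X ∈ {A,S,Y,Q,D,R,P,N,L,F}`, plus the `QQ`/`SS` doublets, as mutually
  exclusive non-overlapping assignments under precedence
  (doublets > GGX > GX), each pass left-to-right.
* **Profiles and classification** — per-sequence conserved-motif sets
  (motifs recurring in ≥ θ of complete repeats, θ = 1/3 by default),
  cross-sequence consensus profiles by intersection, and the diagnostic
  rules: conserved `QQ` + `GP` ⇒ MaSp2; no `QQ` but `GGY` (or its GGF
  substitute) ⇒ MaSp1; `QQ` without `GP` ⇒ intermediate.
* **Araneidae consensus matching** — for each 6–9-residue poly-Ala run,
  compare the flanking 14-mer / 10-mer against
  `GQQGPGGQGPYGP(G/S) Aₙ GGYGPG(A/S)GQQ` and count mismatches.
* **Quantification** — motif abundance as percent of repeat length
  (`100·count·motif_length/repeat_length`), box-plot summaries
  (interpolated quartiles, 1.5 IQR whiskers), grouped by web architecture
  (orb, cobweb, sheet, none).
* **Simulation** — seeded generator of spidroin-like sequences with planted
  motif composition and ground truth, so the whole pipeline is testable
  offline.

## Worked example

Simulate one MaSp2-like and one MaSp1-like sequence, segment, profile,
classify, and quantify:

```r
library(spidromotif)
library(dplyr)

seqs <- simulate_panel(list(masp2_spec(n_repeats = 8),
                            masp1_spec(n_repeats = 8)), seed = 42)$sequences
units <- segment_spidroins(seqs)              # one row per repeat unit
prof  <- profile_sequences(profile_repeats(units))

classify_spidroins(prof, units)
#> # A tibble: 2 × 3
#>   id     label evidence
#> 1 sim001 MaSp2 conserved QQ and GP
#> 2 sim002 MaSp1 no conserved QQ; conserved GGY

summarize_sequences(profile_repeats(units)) |>
  select(id, metric, n, median, mean_count_per_repeat)
#>   id     metric            n median mean_count_per_repeat
#> 1 sim001 repeat_length     7  46                    NA
#> 2 sim001 GP                7  26.1                  5.86
#> 3 sim001 QQ                7   9.52                 2.29
#> 4 sim001 GGY               7  13.6                  2.14
#> 5 sim002 repeat_length     7  43                    NA
#> 6 sim002 GP                7   0                    0
#> ...
```

`sim001` (the planted MaSp2) conserves GP and QQ with a median GP abundance
of 26.1% of repeat length over its 7 complete repeats; the planted MaSp1
has exactly zero GP and QQ — its repertoire is GGY/GA/GQ. The scanner on
the instantiated Araneidae consensus core (A₇, 31 residues) shows the
precedence rules at work:

```r
scan_motifs(araneidae_consensus_core(7))
#> GQQGPGGQGPYGPGAAAAAAAGGYGPGAGQQ
#> motif: QQ GP GGQ GP GP GA GGY GP GA QQ   (QQ:2, GGQ:1, GGY:1, GP:4, GA:2)
```

Real FASTA input goes through the same verbs (`read_fasta()`,
`segment_spidroins()`, …) or the batch runners `run_profile()`,
`run_classify()`, `run_consensus_match()`, `run_quantify()`, which write
TSVs plus a config echo and run log; a thin CLI over them lives at
`inst/scripts/spidromotif.R`. Plots: `plot_motif_profile()` (profile tiles)
and `plot_abundance()` (box plots colored by web architecture).

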