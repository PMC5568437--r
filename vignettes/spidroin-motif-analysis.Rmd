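---
title: "Motif-based analysis of spidroin tandem repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based analysis of spidroin tandem repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidromotif)
library(dplyr)
```

## The analysis in one paragraph

Dragline silk is spun from two major ampullate spidroins, MaSp1 and MaSp2.
Both are dominated by a long repetitive core: tandem repeats that alternate a
poly-alanine run (the crystalline fraction of the fiber) with a glycine-rich
region built from very short motifs. `spidromotif` treats those motifs as
discrete, explicitly defined units — `GX` and `GGX` with
`X ∈ {A, S, Y, Q, D, R, P, N, L, F}`, plus the `QQ` and `SS` doublets — and
derives everything else from their counts: per-repeat profiles, per-sequence
conserved-motif sets, cross-sequence consensus profiles, a MaSp1/MaSp2
classifier (conserved `QQ` + `GP` ⇒ MaSp2; no `QQ` but `GGY` ⇒ MaSp1),
a matcher for the extended ~32-residue Araneidae MaSp2 consensus
`GQQGPGGQGPYGP(G/S)AₙGGYGPG(A/S)GQQ`, and abundance statistics that can be
grouped by the web architecture each species builds.

## Segmentation model

Poly-alanine runs are detected as maximal runs of at least `min_seed = 3`
contiguous alanines; two seeds separated by exactly one residue from
{G, S, V} are merged (the "occasional interruption" seen in real poly-Ala
stretches), and merged runs shorter than `min_total = 4` residues are
dropped. These defaults accept the canonical 6–9-residue stretches with one
interruption while rejecting `(GA)ₙ` arrays, which are flanking elements in
their own right, not poly-Ala.

Repeat boundaries are placed at the **start** of each poly-Ala run. This is
a convention, not a biological claim: the poly-Ala run is the only anchor
conserved across every taxon the classifier must handle, so it is the only
place a deterministic boundary can go. Two consequences follow:

* residues before the first run form a *leading partial segment*
  (`index = -1`, `complete = FALSE`), and the final unit is always
  incomplete, because a domain ends inside a glycine-rich region without
  announcing where the next repeat would have begun. All statistics use
  complete repeats only.
* published repeat lengths measured under someone else's (unstated) boundary
  convention may differ from ours by a small constant offset. Comparisons
  with published per-accession values should therefore carry a ±2-residue
  tolerance.

The repetitive domain itself is delimited automatically as the span from
`flank_max = 60` residues before the first run to 60 after the last (clamped
to the sequence), or taken verbatim from user-supplied bounds (metadata
columns `rep_start`/`rep_end`, 1-based inclusive). Automatic delimitation is
deliberately generous; terminal domains contain no poly-Ala runs and only
contribute incomplete edge units, which the statistics already exclude.

Coordinates are 0-based and half-open everywhere in the package; the only
1-based values are the `rep_start`/`rep_end` metadata columns, converted on
input.

## Scanning rules and tie-breaks

Motif assignment is three left-to-right passes in precedence order:

1. **doublets** (`QQ`, `SS`): packed greedily inside each maximal
   homopolymer run — `QQQ` yields one hit, `QQQQ` two. Greedy left-to-right
   packing is the simplest deterministic rule and attains the maximum
   possible number of doublets in a run.
2. **GGX**: claimed at any position whose three residues are all still
   unassigned.
3. **GX**: claimed on remaining unassigned pairs.

Precedence makes the classes mutually exclusive: no residue is counted
twice, so the summed length of all hits never exceeds the repeat length.
Because doublets run first, a `GGQQ` context yields `QQ` and nothing else —
the orphaned `GG` matches no motif. This extends the stated QQ-over-GQ rule
to `GGQ`; the pass order is configurable through
`motif_catalog(precedence = ...)` for anyone who wants the opposite
tie-break. Ambiguity codes (X/B/Z) survive normalization but never match a
motif or count as alanine, so uncertain residues can only remove motifs,
never create them.

The scanner runs across the full repeat unit including its poly-Ala run: the
abundance denominator is the repeat length, poly-Ala interiors contain no G
and cannot spawn motifs, and a `GA` hit at the run boundary legitimately
captures the `(GA)ₙ` elements that precede many runs. A property test checks
the scanner against an independent brute-force oracle (per-pass maximization
of non-overlapping placements with earliest-position tie-break) on random
sequences up to length 15.

## Conservation, consensus, classification

A motif is *conserved* in a sequence when it occurs in at least a fraction
`theta` of the complete repeats. The default `theta = 1/3` is chosen to
admit a motif recurring once every three repeats — the lowest recurrence
observed for a profile-positive motif (GP in the sheet-web *E. australis*
MaSp2) — while excluding singletons. It is exposed as a parameter because
by-eye profiling plausibly used a different implicit threshold per sequence.

The consensus profile of a set of sequences is the **intersection** of their
conserved sets (superimposition keeps only what everyone shares); the
per-motif member fractions are retained alongside, so majority-but-not-unanimous
motifs such as GGY in MaSp2 (conserved in four of five reference
repertoires, with GGF replacing it in *E. australis*) remain visible via
`tidy()`.

Classification applies the diagnostic rules in order, on the conserved set
alone: `QQ ∧ GP ⇒ MaSp2`; `¬QQ ∧ GGY-like ⇒ MaSp1` (GGF counts as GGY-like
unless `strict_ggy`); `QQ ∧ ¬GP ⇒ intermediate` (the *Tetragnatha*
pattern); otherwise intermediate with no diagnostic motifs. The ordering
matters: a proline-rich sequence with GP but no QQ (the ADF4 situation)
falls through to MaSp1. The canonical-architecture gate — at least two
poly-Ala runs and one complete repeat — is a precondition; sequences failing
it are nonconforming regardless of motif content.

The Araneidae consensus matcher compares, for each run of length 6–9 with
enough context, the 14-mer immediately upstream against
`GQQGPGGQGPYGP[G/S]` and the 10-mer immediately downstream against
`GGYGPG[A/S]GQQ`, counting position-wise mismatches (bracket positions match
either residue). `max_mismatch` defaults to 3 across the 24 templated
positions — the flanks are strongly conserved but not invariant across
species, and no published mismatch budget exists, so this is a tunable, not
a claim.

## Quantification conventions

Motif abundance in a repeat is
`100 × count × motif_length / repeat_length` — the percentage of the
repeat's residues covered by the motif's hits (lengths 2 for `GX`/doublets,
3 for `GGX`). This reproduces the anchor values: 2 GP per ~47-residue repeat
≈ 8.5%, 4 GP per 31 ≈ 25.8%.

Box summaries use median and quartiles by linear interpolation between order
statistics (the common type-7 default; no published method to match) with
whiskers at the most extreme *attained* values within 1.5 IQR of the box and
everything beyond reported as outliers. Statistics pool repeats within an
accession; where a species has multiple accessions of the same homolog, the
pooled default can be overridden by simply not concatenating the inputs.
Group reports order architectures orb, cobweb, sheet, none, unknown, and
sequences without metadata fall into `unknown` rather than erroring — the
pipeline is meant for survey-style screening where warnings must not abort a
batch.

## What the generator emulates — and what it does not

`sim_spec()` describes a spidroin as: `n_repeats` units, each a poly-Ala run
(length uniform on 6–9 by default; 10% chance of a single interior G/S/V
interruption, placed so three alanines remain on each side) followed by a
glycine-rich region assembled by sampling motifs by weight until their
summed length reaches `glyrich_length = 25` residues, with 0–2 linker
residues from {G, Y, S} between motifs. The canonical repertoires are
`masp1_spec()` (GGY:3, GA:2, GQ:2 — no glutamine doublets, no proline),
`masp2_spec()` (GP:4, QQ:2, GGY:2, GS:1), and `intermediate_spec()` (QQ and
GGX motifs without proline). Substitution noise is applied last, and ground
truth records the pre-noise planted counts and boundaries.

Linker emission is adjacency-guarded: a linker never ends with `G`
immediately before a G-initial motif, never extends a doublet context, and a
motif-final alanine is padded before a following poly-Ala run. Without the
guards, roughly a fifth of planted `GP` motifs would be silently converted
into `GGP` hits by an adjacent linker `G`, and planted counts would stop
being ground truth at all; with them, planted GP/QQ/GGY counts are recovered
exactly at zero noise, so the recovery tests measure the pipeline, not
generator artifacts. The noise alphabet excludes alanine by default (so
planted boundaries stay decidable); `free_noise = TRUE` lifts this for
robustness experiments.

What the generator does **not** emulate: positional grammar within the
glycine-rich region (motifs are i.i.d. by weight; real Araneidae repeats are
highly organized — `embed_consensus()` provides that structured regime
instead), long-range length variation of linkers (real inter-motif spacing
varies enough to preclude alignment; ours is 0–2 residues), codon-level
processes, and concerted evolution among repeats. Passing recovery and
classification tests on synthetic panels therefore demonstrates that the
pipeline measures what was planted — not that real spidroins satisfy the
generator's independence assumptions.

## Determinism and problem sizes

Every stochastic step flows from an integer seed: a `sim_spec` carries its
own seed, and panels derive per-record seeds from the panel seed, so
simulations are reproducible byte-for-byte. The test-suite and acceptance
computations use panels of 5–20 sequences with 10–20 repeats each — large
enough that every conserved motif's occurrence fraction is estimated from
≥9 complete repeats, and small enough that the whole suite runs in well
under a minute on one core.

## Known limitations

* Basal-clade (Hypochilidae/Haplogynae) repeat architectures do not follow
  the poly-Ala/Gly-rich alternation and are deliberately out of scope; they
  will come back as `nonconforming`.
* The boundary-convention offset described above means per-accession repeat
  lengths are comparable only to ±2 residues.
* GP tallies at `GPGXX` junctions depend on the precedence passes; a by-eye
  count may differ by a hit or two in pathological contexts.
* The classifier is a rule system over conserved sets, not a probabilistic
  model: it reports evidence strings, not posterior probabilities.
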