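test_that("simulation specs validate their parameters", {
  expect_error(sim_spec(n_repeats = 0), "n_repeats")
  expect_error(sim_spec(motif_weights = c(GP = 0, QQ = 0)), "positive sum")
  expect_error(sim_spec(motif_weights = c(1, 2)), "named")
  expect_error(sim_spec(polyala_lengths = 2:3), "4..12")
  expect_error(embed_consensus(masp2_spec(), an_length = 12), "6..9")
})

test_that("identical specs give identical sequences; seeds change them", {
  a <- simulate_spidroin(masp2_spec(n_repeats = 10, seed = 5), "x")
  b <- simulate_spidroin(masp2_spec(n_repeats = 10, seed = 5), "x")
  expect_identical(a$record$residues, b$record$residues)
  expect_identical(a$truth$counts, b$truth$counts)
  c <- simulate_spidroin(masp2_spec(n_repeats = 10, seed = 6), "x")
  expect_false(identical(a$record$residues, c$record$residues))
})

test_that("panels are reproducible byte-for-byte", {
  specs <- c(replicate(3, masp1_spec(n_repeats = 8), simplify = FALSE),
             replicate(3, masp2_spec(n_repeats = 8), simplify = FALSE))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_panel(specs, seed = 42, out_dir = d1)
  simulate_panel(specs, seed = 42, out_dir = d2)
  for (f in c("panel.fasta", "metadata.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_error(simulate_panel(specs, ids = rep("x", 6)), "duplicate")
  expect_error(simulate_panel(list()), "non-empty")
})

test_that("planted repeat boundaries are recovered exactly at zero noise", {
  for (seed in c(3, 19, 101)) {
    sim <- simulate_spidroin(masp2_spec(n_repeats = 12, seed = seed), "s")
    units <- segment_spidroins(sim$record)
    expect_equal(units$start[units$index >= 0], sim$truth$boundaries$start)
  }
})

test_that("planted GP/QQ/GGY counts are recovered within 10% at zero noise", {
  for (seed in c(1, 8)) {
    sim <- simulate_spidroin(masp2_spec(n_repeats = 20, seed = seed), "s")
    units <- segment_spidroins(sim$record)
    counts <- profile_repeats(units)
    n_complete <- sum(units$complete)
    obs <- counts |>
      dplyr::filter(.data$complete, .data$motif %in% c("GP", "QQ", "GGY")) |>
      dplyr::group_by(.data$motif) |>
      dplyr::summarise(mean_obs = mean(.data$count), .groups = "drop")
    planted <- sim$truth$counts |>
      dplyr::filter(.data$repeat_index < n_complete,
                    .data$motif %in% c("GP", "QQ", "GGY")) |>
      dplyr::group_by(.data$motif) |>
      dplyr::summarise(mean_planted = sum(.data$count) / n_complete,
                       .groups = "drop")
    cmp <- dplyr::inner_join(obs, planted, by = "motif")
    expect_equal(nrow(cmp), 3L)
    expect_true(all(abs(cmp$mean_obs - cmp$mean_planted) /
                      cmp$mean_planted <= 0.10))
  }
})

test_that("motifs with zero planted weight are recovered at exactly zero", {
  sim <- simulate_spidroin(masp1_spec(n_repeats = 20, seed = 4), "s")
  counts <- profile_repeats(segment_spidroins(sim$record))
  expect_false("GP" %in% counts$motif[counts$count > 0])
  expect_false("QQ" %in% counts$motif[counts$count > 0])
  expect_false(grepl("P", sim$record$residues))
})

test_that("canonical specs classify to their planted labels at zero noise", {
  for (seed in c(2, 9)) {
    for (ctor in list(masp1_spec, masp2_spec, intermediate_spec)) {
      spec <- ctor(n_repeats = 10, seed = seed)
      sim <- simulate_spidroin(spec, "s")
      units <- segment_spidroins(sim$record)
      prof <- profile_sequences(profile_repeats(units))
      cls <- classify_spidroins(prof, units)
      expect_equal(cls$label, spec$class_label)
    }
  }
})

test_that("embedded consensus cores have the expected size and always match", {
  emb <- embed_consensus(masp2_spec(n_repeats = 6, seed = 13), an_length = 7)
  m <- match_consensus(emb$record)
  expect_equal(nrow(m), 6L)
  expect_true(all(m$eligible))
  expect_true(all(m$matched))
  expect_true(all(m$upstream_mismatches + m$downstream_mismatches == 0L))
  # 14 + an + 10 residues of templated core around each run
  expect_true(all(m$run_end - m$run_start == 7L))
  core_len <- 14L + (m$run_end - m$run_start) + 10L
  expect_true(all(core_len == 31L))
})

test_that("consensus match fraction decays with substitution noise", {
  frac <- vapply(c(0, 0.15, 0.5), function(rate) {
    m <- purrr::map(1:4, function(seed) {
      emb <- embed_consensus(
        masp2_spec(n_repeats = 10, seed = seed, substitution_rate = rate),
        an_length = 7
      )
      runs <- find_polyala_runs(emb$record$residues)
      if (nrow(runs) == 0L) {
        return(0)
      }
      mean(match_araneidae_consensus(emb$record$residues, runs)$matched)
    })
    mean(unlist(m))
  }, numeric(1))
  expect_equal(frac[1], 1)
  expect_true(frac[1] >= frac[2])
  expect_true(frac[2] >= frac[3])
})

test_that("noise never introduces alanine unless free_noise is set", {
  # noise is applied after construction, so the same seed yields the same
  # pre-noise sequence: substituted positions are exactly the diffs
  clean <- simulate_spidroin(masp2_spec(n_repeats = 10, seed = 21), "s")
  noisy <- simulate_spidroin(masp2_spec(n_repeats = 10, seed = 21,
                                        substitution_rate = 0.3), "s")
  c1 <- strsplit(clean$record$residues, "")[[1]]
  c2 <- strsplit(noisy$record$residues, "")[[1]]
  changed <- which(c1 != c2)
  expect_gt(length(changed), 0)
  expect_false(any(c2[changed] == "A"))
})
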