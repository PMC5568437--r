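test_that("poly-Ala runs: seeds, single-residue merges, discards", {
  run <- find_polyala_runs("GGQAAAAAAGGY")
  expect_equal(run$start, 3L)
  expect_equal(run$end, 9L)
  expect_equal(run$length, 6L)
  expect_equal(nrow(run$interruptions[[1]]), 0L)

  merged <- find_polyala_runs("AAASAAA")
  expect_equal(c(merged$start, merged$end, merged$length), c(0L, 7L, 7L))
  expect_equal(merged$ala_count, 6L)
  expect_equal(merged$interruptions[[1]]$position, 3L)
  expect_equal(merged$interruptions[[1]]$residue, "S")

  expect_equal(nrow(find_polyala_runs("GGYGPGQQ")), 0L)
  # (GA)n arrays are flanking elements, not poly-Ala runs
  expect_equal(nrow(find_polyala_runs("GAGAGAGAGA")), 0L)
  # merges chain across interruptions and only G/S/V merge
  chained <- find_polyala_runs("AAASAAAVAAA")
  expect_equal(c(chained$start, chained$end), c(0L, 11L))
  expect_equal(nrow(chained$interruptions[[1]]), 2L)
  two <- find_polyala_runs("AAAAPAAAA")
  expect_equal(nrow(two), 2L)
  # seeds below min_seed never merge
  expect_equal(nrow(find_polyala_runs("AAGAA")), 0L)
})

test_that("run invariants hold on random sequences", {
  withr::local_seed(421)
  n_with_runs <- 0L
  for (i in 1:50) {
    chars <- sample(c("A", "G", "S", "V", "Q", "Y"), sample(10:80, 1),
                    replace = TRUE, prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    seq <- paste(chars, collapse = "")
    runs <- find_polyala_runs(seq)
    if (nrow(runs) == 0L) next
    n_with_runs <- n_with_runs + 1L
    chars <- strsplit(seq, "")[[1]]
    expect_true(all(runs$end - runs$start == runs$length))
    expect_true(all(runs$length >= 4L))
    expect_true(all(chars[runs$start + 1L] == "A"))
    expect_true(all(chars[runs$end] == "A"))
    expect_true(all(runs$ala_count / runs$length >= 0.75))
    expect_true(all(diff(runs$start) > 0))
    expect_true(all(runs$start[-1] >= runs$end[-nrow(runs)]))
  }
  expect_gt(n_with_runs, 25L)
})

test_that("domain delimitation honors user bounds, flanks, and errors", {
  seq302 <- strrep("AAAAAAGGYGQGGYGQGGYGQGGYGQGGYGQGGYGQG", 9)
  runs <- find_polyala_runs(seq302)
  dom <- delimit_repetitive_domain(seq302, runs, user_bounds = c(0L, 302L))
  expect_equal(c(dom$repetitive_start, dom$repetitive_end), c(0L, 302L))
  expect_equal(dom$source, "user")

  seq30 <- paste0(strrep("G", 10), "AAAAAA", strrep("G", 14))
  dom_auto <- delimit_repetitive_domain(seq30, find_polyala_runs(seq30))
  expect_equal(c(dom_auto$repetitive_start, dom_auto$repetitive_end),
               c(0L, 30L))
  expect_equal(dom_auto$source, "auto")

  expect_error(
    delimit_repetitive_domain("GGYGPG", find_polyala_runs("GGYGPG")),
    "nonrepetitive"
  )
})

test_that("segmentation follows the poly-Ala anchor convention", {
  seq3 <- "AAAAAAGGYGQAAAAAAGGYGQAAAAAAGGYGQ"
  units <- segment_repeats(seq3, find_polyala_runs(seq3))
  expect_equal(units$start, c(0L, 11L, 22L))
  expect_equal(units$end, c(11L, 22L, 33L))
  expect_equal(units$complete, c(TRUE, TRUE, FALSE))
  expect_equal(units$index, 0:2)

  lead <- "GGYAAAAAAGGY"
  units2 <- segment_repeats(lead, find_polyala_runs(lead))
  expect_equal(units2$index, c(-1L, 0L))
  expect_equal(units2$start, c(0L, 3L))
  expect_equal(units2$end, c(3L, 12L))
  expect_false(any(units2$complete))

  units3 <- segment_repeats("GGYGPGQQ", find_polyala_runs("GGYGPGQQ"))
  expect_equal(nrow(units3), 1L)
  expect_false(units3$complete)
  expect_equal(units3$sequence, "GGYGPGQQ")
})

test_that("segmentation round-trips and counts complete units correctly", {
  withr::local_seed(97)
  for (i in 1:40) {
    n_rep <- sample(1:6, 1)
    seq <- paste(
      c(random_protein(sample(0:8, 1), c("G", "Q", "Y")),
        replicate(n_rep, paste0(strrep("A", sample(4:9, 1)),
                                random_protein(sample(5:20, 1),
                                               c("G", "Q", "Y", "P", "S"))))),
      collapse = ""
    )
    runs <- find_polyala_runs(seq)
    units <- segment_repeats(seq, runs)
    # round trip: leading segment + units reconstruct the domain exactly
    expect_identical(paste(units$sequence, collapse = ""), seq)
    # complete units == runs - 1 when the domain ends in a Gly-rich region
    expect_equal(sum(units$complete), max(0L, nrow(runs) - 1L))
    # each complete unit holds exactly one run, at its start
    for (k in which(units$complete)) {
      inner <- find_polyala_runs(units$sequence[k])
      expect_equal(nrow(inner), 1L)
      expect_equal(inner$start, 0L)
    }
  }
})

test_that("segment_spidroins applies metadata bounds and skips nonrepetitive", {
  seqs <- tibble::tibble(
    id = c("a", "b"),
    residues = c("GGYAAAAAAGGYGQAAAAAAGGYGQ", "GGYGPGQQGGY")
  )
  expect_warning(units <- segment_spidroins(seqs), "nonrepetitive")
  expect_equal(unique(units$id), "a")

  bounds <- tibble::tibble(id = "a", rep_start = 4L, rep_end = 25L)
  res <- suppressWarnings(segment_spidroins(seqs, bounds = bounds))
  expect_equal(unique(res$repetitive_start), 3L)
  expect_equal(unique(res$repetitive_end), 25L)
  expect_equal(unique(res$domain_source), "user")
})
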