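# Conserved repertoires standing in for the five reference MaSp1/MaSp2
# profiles: each member conserves GGY (the universal MaSp1 anchor) plus
# species-specific extras; the MaSp2 members all conserve GP and QQ, with
# GGF replacing GGY in one member.
ref_masp1 <- list(
  LH = c("GGY", "GA", "GQ"), NC = c("GGY", "GA", "GQ", "GGA"),
  AD = c("GP", "GGY", "GS"), AB = c("GGY", "GA"), EA = c("GGY", "GS")
)
ref_masp2 <- list(
  LH = c("GP", "QQ", "GGY", "GS"), NC = c("GP", "QQ", "GGY", "GA"),
  AD = c("GP", "QQ", "GGY"), AB = c("GP", "QQ", "GGY", "GS"),
  EA = c("GP", "QQ", "GGF", "GS")
)

profiles_from <- function(ref) {
  dplyr::bind_rows(purrr::imap(ref, ~ make_profile(.y, .x)))
}

test_that("consensus profiles are the intersection of conserved sets", {
  cons1 <- derive_consensus(profiles_from(ref_masp1))
  expect_equal(cons1$consensus_set, "GGY")

  cons2 <- derive_consensus(profiles_from(ref_masp2))
  expect_true(all(c("GP", "QQ") %in% cons2$consensus_set))
  expect_false("GGY" %in% cons2$consensus_set)
  td <- tidy(cons2)
  expect_equal(td$fraction[td$motif == "GGY"], 4 / 5)

  single <- derive_consensus(make_profile("only", c("GGY", "GA")))
  expect_equal(single$consensus_set, c("GA", "GGY"))

  expect_error(derive_consensus(make_profile("x", "GGY")[0, ]), "zero")
})

test_that("tidy/glance expose the consensus object as tibbles", {
  cons <- derive_consensus(profiles_from(ref_masp2))
  td <- tidy(cons)
  expect_s3_class(td, "tbl_df")
  expect_true(all(td$consensus == (td$fraction == 1)))
  gl <- glance(cons)
  expect_equal(gl$n_members, 5L)
  expect_true(grepl("GP", gl$consensus_motifs))
})

test_that("classification follows the QQ/GP/GGY rule order", {
  lab <- function(set, ...) classify_profile(set, TRUE, ...)$label
  expect_equal(lab(c("GGY", "GA", "GQ")), "MaSp1")
  expect_equal(lab(c("GP", "QQ", "GS", "GGY")), "MaSp2")
  expect_equal(lab(c("QQ", "GGY", "GGL", "GS")), "intermediate")
  # the ADF4 repertoire: proline-rich but MaSp1 by motif criteria
  expect_equal(lab(c("GP", "GGY", "GS")), "MaSp1")
  # GGF substitutes for GGY unless strict
  expect_equal(lab(c("GGF", "GA")), "MaSp1")
  expect_equal(lab(c("GGF", "GA"), strict_ggy = TRUE), "intermediate")
  expect_equal(classify_profile(c("GP", "QQ"), FALSE)$label, "nonconforming")
  expect_equal(lab(character(0)), "intermediate")
  expect_equal(classify_profile(character(0), TRUE)$evidence,
               "no diagnostic motifs")
})

test_that("classification is a pure function of the conserved set", {
  set <- c("GP", "QQ", "GGY", "GS")
  for (i in 1:5) {
    expect_equal(classify_profile(sample(set), TRUE)$label, "MaSp2")
  }
})

test_that("consensus templates have the published flank structure", {
  tmpl <- araneidae_templates()
  expect_length(tmpl$upstream, 14L)
  expect_length(tmpl$downstream, 10L)
  expect_equal(tmpl$upstream[[14]], c("G", "S"))
  expect_equal(tmpl$downstream[[7]], c("A", "S"))
  expect_equal(nchar(araneidae_consensus_core(8)), 32L)
})

test_that("consensus matching counts mismatches and applies eligibility", {
  ctx <- function(core) paste0("GGYGPGQQ", core, "GPGQQGGY")
  clean <- ctx(araneidae_consensus_core(7))
  runs <- find_polyala_runs(clean)
  m <- match_araneidae_consensus(clean, runs)
  expect_true(m$eligible)
  expect_equal(m$upstream_mismatches + m$downstream_mismatches, 0L)
  expect_equal(m$polyala_length, 7L)
  expect_true(m$matched)

  # the S variants of the ambiguous positions also match at 0
  s_var <- ctx(araneidae_consensus_core(6, upstream_choice = "S",
                                        downstream_choice = "S"))
  ms <- match_araneidae_consensus(s_var, find_polyala_runs(s_var))
  expect_equal(ms$upstream_mismatches + ms$downstream_mismatches, 0L)

  # two substitutions in the upstream flank still match at tolerance 3
  mut <- clean
  substr(mut, 9, 9) <- "A"   # G -> A in upstream flank
  substr(mut, 11, 11) <- "A" # Q -> A
  mm <- match_araneidae_consensus(mut, find_polyala_runs(mut))
  expect_equal(mm$upstream_mismatches, 2L)
  expect_true(mm$matched)
  expect_false(match_araneidae_consensus(mut, find_polyala_runs(mut),
                                         max_mismatch = 1L)$matched)

  # a 12-alanine run is outside the 6-9 consensus range
  long_run <- paste0("GQQGPGGQGPYGPG", strrep("A", 12), "GGYGPGAGQQ")
  ml <- match_araneidae_consensus(long_run, find_polyala_runs(long_run))
  expect_false(ml$eligible)
  expect_false(ml$matched)
  expect_true(is.na(ml$upstream_mismatches))

  # insufficient upstream context is ineligible too
  short_ctx <- paste0("AAAAAAA", "GGYGPGAGQQ")
  msx <- match_araneidae_consensus(short_ctx, find_polyala_runs(short_ctx))
  expect_false(msx$eligible)
})

test_that("a zero-mismatch consensus sequence always classifies MaSp2", {
  for (seed in c(2, 17)) {
    emb <- embed_consensus(masp2_spec(n_repeats = 8, seed = seed),
                           an_length = 7, id = "emb")
    units <- segment_spidroins(emb$record)
    prof <- profile_sequences(profile_repeats(units))
    cls <- classify_spidroins(prof, units)
    expect_equal(cls$label, "MaSp2")
    m <- match_consensus(emb$record)
    expect_true(all(m$matched))
  }
})
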