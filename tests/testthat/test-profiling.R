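test_that("accumulation matches the hand-traced single- and two-step cases", {
  a <- benchmark_spec("A")
  one <- cat_accumulate("A", a)
  expect_equal(one$nearMatches, 0)
  expect_equal(one$exactMatches, 1)
  expect_equal(one$bonusTotal, 0)

  # i=0: exact 1, prevMatches 0.6; i=1: near 0.6 with bonus 0.6*0.6
  two <- cat_accumulate("AA", a)
  expect_equal(two$nearMatches, 0.96)
  expect_equal(two$exactMatches, 1)
  expect_equal(two$bonusTotal, 0.6)

  expect_error(cat_accumulate("", a), "non-empty")
  expect_error(cat_accumulate("ACGN", a), "invalid base")
})

test_that("accumulation agrees with the plain-R recurrence oracle on random sequences", {
  set.seed(401)
  for (rep in 1:50) {
    seq <- random_dna(sample(1:8, 1))
    for (spec in cat_benchmarks()) {
      got <- cat_accumulate(seq, spec)
      want <- naive_accumulate(seq, spec$period)
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  }
})

test_that("dna_distance normalizes the accumulated mass", {
  a <- benchmark_spec("A")
  expect_equal(dna_distance(cat_accumulate("AA", a), 2), 1.96 / 2.6)
  zeros <- list(nearMatches = 0, exactMatches = 0, bonusTotal = 0)
  expect_equal(dna_distance(zeros, 10), 0)
  alg <- list(nearMatches = 0, exactMatches = 7, bonusTotal = 3)
  expect_equal(dna_distance(alg, 7), 7 / 10)
  neg <- list(nearMatches = 1, exactMatches = 1, bonusTotal = -5)
  expect_error(dna_distance(neg, 2), "degenerate")
})

test_that("triangle legs follow the cosine-theorem geometry", {
  leg <- triangle_legs(0.6, 0.8)
  expect_equal(leg$cosAlpha, 0.6)
  expect_equal(leg$D, 0.36)
  expect_equal(leg$H, 0.48)
  expect_false(leg$clamped)

  sym <- triangle_legs(0.5, 0.5)  # isoceles on the unit base
  expect_equal(sym$cosAlpha, 1)
  expect_equal(sym$D, 0.5)
  expect_equal(sym$H, 0)

  degen <- triangle_legs(0, 0.7)
  expect_true(degen$degenerate)
  expect_equal(c(degen$D, degen$H), c(0, 0))

  # Pythagorean identity whenever no clamping fired; H never negative
  set.seed(402)
  for (rep in 1:200) {
    leg <- triangle_legs(runif(1, 0.01, 1.5), runif(1, 0.01, 1.5))
    expect_gte(leg$H, 0)
    if (!leg$clamped)
      expect_equal(leg$D^2 + leg$H^2, leg$dnaDistance^2, tolerance = 1e-9)
  }
})

test_that("profiles are deterministic and separate distinct sequences", {
  expect_identical(cat_profile("ACGTACGTAC"), cat_profile("ACGTACGTAC"))

  # a prefix of the A-benchmark is closest to the A-benchmark
  d <- cat_distances("ACGTACGTACGT")
  expect_equal(names(which.max(d)), "A")

  p1 <- cat_profile("AAAAAAAAAA")
  p2 <- cat_profile("ACGTACGTAC")
  expect_false(identical(p1$profile, p2$profile))
})

test_that("the vectorized space pipeline equals per-sequence profiling", {
  consts <- cat_constants()
  bm <- cat_benchmarks()
  periods <- rbind(
    match(strsplit(bm$C$period, "")[[1]], c("A", "C", "G", "T")) - 1L,
    match(strsplit(bm$A$period, "")[[1]], c("A", "C", "G", "T")) - 1L,
    match(strsplit(bm$T$period, "")[[1]], c("A", "C", "G", "T")) - 1L)
  space <- catseq:::cpp_profile_space(3L, periods, consts$baseDistance,
                                      consts$minPoint)
  seqs <- enumerate_space(3)
  expect_equal(nrow(space), 64L)
  for (k in seq_along(seqs)) {
    p <- cat_profile(seqs[k])$profile
    expect_equal(as.numeric(space[k, ]),
                 c(p$C$D, p$C$H, p$A$D, p$A$H, p$T$D, p$T$H),
                 tolerance = 1e-15)
  }
})

test_that("ambiguous bases are rejected by default and score zero when admitted", {
  expect_error(cat_profile("ACNT"), "invalid base 'N' at position 3")
  p <- cat_profile("ACNT", ambiguous = "zero")
  expect_s3_class(p, "cat_profile")
  # an admitted N contributes no match mass: same scores as any non-matching pass
  accN <- cat_accumulate("N", benchmark_spec("A"), ambiguous = "zero")
  expect_equal(accN$nearMatches, 0)
  expect_equal(accN$exactMatches, 0)
})
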