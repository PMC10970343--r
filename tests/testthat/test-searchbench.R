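test_that("space enumeration is complete, ordered and bounded", {
  expect_equal(enumerate_space(1), c("A", "C", "G", "T"))
  s2 <- enumerate_space(2)
  expect_equal(length(s2), 16L)
  expect_equal(s2[1], "AA")
  expect_equal(s2[16], "TT")
  expect_false(is.unsorted(s2))
  expect_equal(anyDuplicated(s2), 0L)
  expect_equal(length(enumerate_space(5)), 1024L)
  expect_error(enumerate_space(14), "streaming")
  expect_error(enumerate_space(0), "between")
})

test_that("collision experiments find only self-matches and are seed-reproducible", {
  tiny <- collision_experiment(1, sample_size = 4, seed = 11)
  expect_equal(tiny$per_query_counts, rep(1L, 4))
  expect_equal(tiny$total_permutations, 4)

  r5 <- collision_experiment(5, sample_size = 100, seed = 12)
  expect_equal(r5$total_permutations, 1024)
  expect_true(all(r5$per_query_counts >= 1L))  # every query matches itself
  expect_equal(r5$average_full_matches, 1)

  again <- collision_experiment(5, sample_size = 100, seed = 12)
  expect_identical(r5, again)
  expect_error(collision_experiment(2, sample_size = 17), "sample_size")
})

test_that("threshold search filters, sorts and honors exhaustive uniqueness", {
  seqs <- enumerate_space(5)
  store <- lapply(seq_along(seqs), function(k) {
    cat_profile(seqs[k], sequence_id = seqs[k])
  })
  query <- store[[137]]
  exact <- profile_search(query, store, min_similarity = 100)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$sequence_id, seqs[137])
  expect_equal(exact$similarity_percent, 100)

  everything <- profile_search(query, store, min_similarity = 0)
  expect_equal(nrow(everything), length(store))
  expect_true(all(diff(everything$similarity_percent) <= 0))

  near <- profile_search(query, store, min_similarity = 99)
  expect_true(all(near$similarity_percent >= 99))
  expect_true(seqs[137] %in% near$sequence_id)
})

test_that("alignment baseline: self-alignment, minimal cases and invariants", {
  s <- "ACGTACGT"
  self <- needleman_wunsch(s, s)
  expect_equal(self$score, nchar(s))
  expect_equal(self$identity_percent, 100)
  expect_equal(self$aligned_a, s)

  expect_equal(needleman_wunsch("A", "T")$score, -1)  # mismatch beats two gaps
  expect_error(needleman_wunsch("", "ACGT"), "non-empty")

  set.seed(405)
  for (rep in 1:25) {
    a <- random_dna(sample(1:12, 1))
    b <- random_dna(sample(1:12, 1))
    al <- needleman_wunsch(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    expect_equal(al$score, needleman_wunsch(b, a)$score)
  }
})

test_that("alignment scores equal exhaustive enumeration and an external aligner", {
  # exhaustive over all pairs of lengths 1..2
  short <- c(enumerate_space(1), enumerate_space(2))
  for (a in short) for (b in short) {
    expect_equal(needleman_wunsch(a, b)$score,
                 brute_force_alignment_score(a, b))
  }

  # seeded pairs up to length 5 against the brute-force oracle
  set.seed(406)
  for (rep in 1:60) {
    a <- random_dna(sample(1:5, 1))
    b <- random_dna(sample(1:5, 1))
    expect_equal(needleman_wunsch(a, b)$score,
                 brute_force_alignment_score(a, b))
  }

  # independent cross-check against Biostrings' global aligner
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(407)
  for (rep in 1:10) {
    a <- random_dna(sample(10:40, 1))
    b <- random_dna(sample(10:40, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(needleman_wunsch(a, b)$score, ref)
  }
})

test_that("KMP search equals sliding-window search and handles overlaps", {
  expect_equal(kmp_search("A", "AAA"), c(0L, 1L, 2L))
  expect_equal(kmp_search("ACG", "TTTT"), integer(0))
  expect_equal(kmp_search("ACAC", "ACACAC"), c(0L, 2L))
  expect_error(kmp_search("", "ACGT"), "non-empty")

  set.seed(408)
  for (rep in 1:1000) {
    pattern <- random_dna(sample(1:5, 1))
    text <- random_dna(sample(1:40, 1))
    expect_equal(kmp_search(pattern, text), naive_find(pattern, text))
  }
})
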