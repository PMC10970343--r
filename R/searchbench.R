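#' Enumerate the complete space of DNA sequences of a given length
#'
#' Yields every sequence over `{A,C,G,T}` of length `n`, exactly once, in
#' lexicographic order with `A < C < G < T`. The whole space is materialized,
#' so lengths are capped at 13 (4^13 = 67,108,864); beyond that the collision
#' harness would need a streaming consumer rather than a vector.
#'
#' @param n Sequence length, 1..13.
#' @return Character vector of 4^n sequences.
#' @examples
#' enumerate_space(1)  # "A" "C" "G" "T"
#' @export
enumerate_space <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n == as.integer(n))
  if (n < 1 || n > 13)
    stop("length must be between 1 and 13; larger spaces must be consumed ",
         "in streaming batches rather than materialized", call. = FALSE)
  cpp_enumerate_space(as.integer(n))
}

#' Collision analysis over an exhaustive sequence space
#'
#' Profiles every one of the 4^n sequences of length `n`, draws
#' `sample_size` query sequences without replacement under `seed`, and for
#' each query counts how many members of the full space compare as a 100%
#' match (every per-benchmark profile distance below `tolerance`). Each
#' query matches at least itself, so an average of exactly 1 means the
#' profiles are collision-free at this length.
#'
#' @param n Sequence length, 1..13.
#' @param sample_size Number of queries, at most 4^n.
#' @param seed Integer seed for the query draw.
#' @param constants A `cat_constants`.
#' @param tolerance Per-benchmark distance below which profiles count as
#'   equal.
#' @return A `cat_collision_report`: `length`, `total_permutations`,
#'   `sample_size`, `seed`, `average_full_matches`, `per_query_counts`,
#'   `tolerance`.
#' @export
collision_experiment <- function(n, sample_size = 1000L, seed = 1L,
                                 constants = cat_constants(),
                                 tolerance = CAT_MATCH_TOLERANCE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n <= 13,
            is.numeric(sample_size), sample_size >= 1)
  total <- 4^n
  if (sample_size > total)
    stop("sample_size exceeds the 4^n space", call. = FALSE)
  bm <- cat_benchmarks()
  periods <- rbind(period_codes(bm$C), period_codes(bm$A), period_codes(bm$T))
  profiles <- cpp_profile_space(as.integer(n), periods, constants$baseDistance,
                                constants$minPoint)
  set.seed(seed)
  queries <- sample.int(total, as.integer(sample_size))
  counts <- cpp_count_full_matches(profiles, queries - 1L, tolerance)
  structure(list(length = as.integer(n), total_permutations = total,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed),
                 average_full_matches = mean(counts),
                 per_query_counts = counts, tolerance = tolerance),
            class = "cat_collision_report")
}

#' @export
print.cat_collision_report <- function(x, ...) {
  cat(sprintf(paste0("<cat_collision_report> length %d: %s permutations, ",
                     "%d queries (seed %d)\n  average 100%%-matches per ",
                     "query: %g\n"),
              x$length, format(x$total_permutations, big.mark = ","),
              x$sample_size, x$seed, x$average_full_matches))
  invisible(x)
}

#' Threshold similarity search over a profile store
#'
#' Compares a query profile against every profile in a store (as produced by
#' [cat_profile()] or loaded with [read_profiles()]) and returns the entries
#' whose percent similarity is at least `min_similarity`, sorted by
#' descending similarity with ties broken by `sequence_id`. Only stored
#' profile numbers are read; no sequence text is needed.
#'
#' @param query A `cat_profile`.
#' @param store List of `cat_profile` objects with matching provenance.
#' @param min_similarity Threshold in percent, 0..100.
#' @return A data.frame with columns `sequence_id` and `similarity_percent`.
#' @export
profile_search <- function(query, store, min_similarity = 100) {
  stopifnot(inherits(query, "cat_profile"), is.list(store),
            is.numeric(min_similarity), min_similarity >= 0,
            min_similarity <= 100)
  if (length(store) == 0L)
    return(data.frame(sequence_id = character(0),
                      similarity_percent = numeric(0)))
  sims <- vapply(store, function(p) {
    compare_profiles(query, p)$similarity_percent
  }, numeric(1))
  ids <- vapply(store, function(p) p$sequence_id, character(1))
  keep <- sims >= min_similarity
  out <- data.frame(sequence_id = ids[keep], similarity_percent = sims[keep])
  out <- out[order(-out$similarity_percent, out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Needleman-Wunsch global alignment (reference baseline)
#'
#' Exact dynamic-programming global alignment with linear gap penalties,
#' used as the accuracy baseline against which the constant-time profile
#' comparison is judged. Traceback is deterministic with tie preference
#' diagonal, then gap in `b`, then gap in `a`.
#'
#' @param a,b DNA sequences (single non-empty strings).
#' @param match,mismatch,gap Scoring scheme (defaults 1, -1, -1).
#' @return A `cat_alignment`: `score`, `aligned_a`, `aligned_b` (gapped,
#'   equal length), `identity_percent`.
#' @examples
#' needleman_wunsch("GATTACA", "GCATGCT")$score
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- normalize_sequence(a, what = "sequence a")
  b <- normalize_sequence(b, what = "sequence b")
  out <- cpp_needleman_wunsch(a, b, match, mismatch, gap)
  structure(out, class = "cat_alignment")
}

#' @export
print.cat_alignment <- function(x, ...) {
  cat(sprintf("<cat_alignment> score %g, identity %.1f%%\n", x$score,
              x$identity_percent))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Knuth-Morris-Pratt substring search (reference baseline)
#'
#' Linear-time exact occurrence search via the classic failure function,
#' used as the exact-match search baseline. Overlapping occurrences are all
#' reported.
#'
#' @param pattern Non-empty pattern string.
#' @param text Text string to scan.
#' @return Integer vector of zero-based start positions, ascending.
#' @examples
#' kmp_search("A", "AAA")  # 0 1 2
#' @export
kmp_search <- function(pattern, text) {
  stopifnot(is.character(pattern), length(pattern) == 1L, is.character(text),
            length(text) == 1L)
  if (!nzchar(pattern)) stop("pattern must be non-empty", call. = FALSE)
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p)
  n <- length(t)
  if (n < m) return(integer(0))
  fail <- integer(m)
  k <- 0L
  if (m > 1L) for (i in 2:m) {
    while (k > 0L && p[k + 1L] != p[i]) k <- fail[k]
    if (p[k + 1L] == p[i]) k <- k + 1L
    fail[i] <- k
  }
  hits <- integer(0)
  q <- 0L
  for (i in seq_len(n)) {
    while (q > 0L && p[q + 1L] != t[i]) q <- fail[q]
    if (p[q + 1L] == t[i]) q <- q + 1L
    if (q == m) {
      hits <- c(hits, i - m)
      q <- fail[q]
    }
  }
  hits
}

#' Timing harness for profile comparison against the alignment baselines
#'
#' Generates seeded random sequence pairs at each requested length and
#' reports the mean wall-clock cost per operation of (a) comparing
#' precomputed CAT profiles, (b) Needleman-Wunsch alignment and (c) KMP
#' search of the first sequence in the second. Profile computation time is
#' reported separately from comparison time, mirroring the intended
#' workflow in which profiles are computed once at upload. Timings are
#' indicative only and are never asserted against reference values.
#'
#' @param lengths Integer vector of sequence lengths.
#' @param algorithms Subset of `c("cat", "nw", "kmp")`.
#' @param seed Integer seed.
#' @param reps Comparison repetitions per measurement for the constant-time
#'   path (single-run operations use 1).
#' @return data.frame with columns `algorithm`, `length`,
#'   `seconds_per_op`.
#' @export
run_benchmark <- function(lengths = c(100L, 1000L),
                          algorithms = c("cat", "nw", "kmp"), seed = 1L,
                          reps = 200L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  for (len in lengths) {
    recs <- generate_fixtures(2L, len, seed = seed + len)
    s1 <- recs$sequence[1]
    s2 <- recs$sequence[2]
    if ("cat" %in% algorithms) {
      p1 <- cat_profile(s1, "s1")
      p2 <- cat_profile(s2, "s2")
      el <- system.time(for (r in seq_len(reps)) compare_profiles(p1, p2))[[3]]
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = "cat", length = len,
                   seconds_per_op = el / reps)
    }
    if ("nw" %in% algorithms) {
      el <- system.time(needleman_wunsch(s1, s2))[[3]]
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = "nw", length = len, seconds_per_op = el)
    }
    if ("kmp" %in% algorithms) {
      pat <- substr(s1, 1L, max(1L, len %/% 10L))
      el <- system.time(kmp_search(pat, s2))[[3]]
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = "kmp", length = len, seconds_per_op = el)
    }
  }
  do.call(rbind, rows)
}
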