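# Independent oracles, written against the method's definitions rather than
# the package internals: scoring by looking at actual neighbor characters in
# the periodic benchmark text, the profile recurrence as a plain R loop,
# alignment scoring by exhaustive enumeration, and substring search by a
# sliding window.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# benchmark character at zero-based position j of the infinite repeat of
# `period`; negative j wraps (the periodic text extends in both directions)
bench_at <- function(period, j) {
  substr(period, (j %% 4) + 1, (j %% 4) + 1)
}

# (exact, near) scores by literal neighbor inspection of the benchmark text
naive_scores <- function(period, i, b, baseDistance = c(0, 0.6, 0.4, 0.6)) {
  adjacent <- baseDistance[2]
  far <- baseDistance[3]
  if (b == bench_at(period, i)) return(c(exact = 1, near = 0))
  if (b == bench_at(period, i - 1) || b == bench_at(period, i + 1))
    return(c(exact = 0, near = adjacent))
  stopifnot(b == bench_at(period, i + 2))  # period is a permutation
  c(exact = 0, near = far)
}

# plain-R transcription of the profile accumulation recurrence
naive_accumulate <- function(seq, period, baseDistance = c(0, 0.6, 0.4, 0.6),
                             minPoint = 0.4) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  near <- 0; exact <- 0; prev <- 0; bonus <- 0; spl <- 0
  for (j in seq_len(n)) {
    s <- naive_scores(period, j - 1, chars[j], baseDistance)
    nm <- s[["near"]]
    em <- s[["exact"]]
    near <- near + nm + prev * nm
    exact <- exact + em + prev * em
    prev <- spl / j + em + nm - minPoint
    bonus <- bonus + if (j == n) 0 else prev
    spl <- spl + prev
  }
  list(nearMatches = near, exactMatches = exact, prevMatches = prev,
       bonusTotal = bonus, sequencePrevLength = spl)
}

# optimal global alignment score by exhaustive exploration of every gapped
# alignment (no dynamic-programming table)
brute_force_alignment_score <- function(a, b, match = 1, mismatch = -1,
                                        gap = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, (if (ca[i] == cb[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# sliding-window exact search, zero-based start positions
naive_find <- function(pattern, text) {
  m <- nchar(pattern)
  n <- nchar(text)
  if (m > n) return(integer(0))
  starts <- 0:(n - m)
  starts[vapply(starts, function(s) {
    substr(text, s + 1, s + m) == pattern
  }, logical(1))]
}
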