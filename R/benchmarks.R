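#' The three constant CAT benchmark sequences
#'
#' The CAT method replaces the data-dependent "favorite sequence" of earlier
#' database heuristics with three constant, infinitely periodic reference
#' sequences named after their leading role: the C-, A- and T-benchmarks, with
#' 4-base periods `AGTC`, `ACGT` and `GTAC` respectively. The periods are
#' chosen so that the A- and T-benchmarks never agree at any position, while
#' the C-benchmark agrees with each of the other two at exactly one position
#' in four. Any DNA sequence can therefore match a given position on at most
#' one of the A/T pair, and profiles measured against the three benchmarks
#' triangulate the sequence's position by trilateration.
#'
#' @param key One of `"C"`, `"A"`, `"T"`.
#' @return `benchmark_spec()` returns a single `cat_benchmark` object (a list
#'   with elements `key` and `period`); `cat_benchmarks()` returns the named
#'   list of all three in leg order C, A, T.
#' @examples
#' benchmark_spec("A")$period  # "ACGT"
#' @export
benchmark_spec <- function(key = c("C", "A", "T")) {
  key <- match.arg(key)
  new_benchmark(key, switch(key, C = "AGTC", A = "ACGT", T = "GTAC"))
}

#' @rdname benchmark_spec
#' @export
cat_benchmarks <- function() {
  list(C = benchmark_spec("C"), A = benchmark_spec("A"), T = benchmark_spec("T"))
}

#' Construct a benchmark from an arbitrary 4-base period
#'
#' Exposed for experimentation; the shipped profiles always use the three
#' constants from [cat_benchmarks()]. The period must be a permutation of
#' `A`, `C`, `G`, `T` so that every base has a unique canonical position.
#'
#' @param key Single-character label for the benchmark.
#' @param period 4-character string, a permutation of the four bases.
#' @return A `cat_benchmark` object.
#' @export
new_benchmark <- function(key, period) {
  stopifnot(is.character(key), length(key) == 1L, is.character(period),
            length(period) == 1L)
  period <- toupper(period)
  chars <- strsplit(period, "")[[1]]
  if (length(chars) != 4L || !setequal(chars, c("A", "C", "G", "T")))
    stop("benchmark period must be a permutation of A, C, G, T, got '",
         period, "'", call. = FALSE)
  structure(list(key = key, period = period), class = "cat_benchmark")
}

#' @export
print.cat_benchmark <- function(x, ...) {
  cat(sprintf("<%s-benchmark> period %s (repeats %s...)\n", x$key, x$period,
              strrep(x$period, 3)))
  invisible(x)
}

#' Scoring constants for profile accumulation
#'
#' `baseDistance` assigns the per-position match weight by circular distance
#' between the observed base's canonical position in the benchmark period and
#' the aligned position: index 0 is the exact slot (near score 0 there; the
#' exact score of 1 is accounted separately), indexes 1 and 3 are the left and
#' right neighbors (0.6 each), index 2 the far neighbor (0.4). `minPoint` is
#' the floor subtracted from the running previous-match term at every
#' position; the default is the smallest nonzero match score.
#'
#' @param baseDistance Numeric vector of 4 near-match weights.
#' @param minPoint Single numeric floor for the previous-match recurrence.
#' @return A `cat_constants` object.
#' @export
cat_constants <- function(baseDistance = c(0, 0.6, 0.4, 0.6), minPoint = 0.4) {
  stopifnot(is.numeric(baseDistance), length(baseDistance) == 4L,
            all(is.finite(baseDistance)), is.numeric(minPoint),
            length(minPoint) == 1L, is.finite(minPoint))
  structure(list(baseDistance = as.numeric(baseDistance),
                 minPoint = as.numeric(minPoint)),
            class = "cat_constants")
}

# Alphabet and integer encoding (lexicographic A<C<G<T, codes 0..3) ----------

CAT_ALPHABET <- c("A", "C", "G", "T")

#' Normalize and validate a DNA sequence
#'
#' Uppercases the input and checks it against the `{A,C,G,T}` alphabet.
#' By default any other character (including `N` and IUPAC ambiguity codes)
#' is an error naming the offending 1-based position; with
#' `ambiguous = "zero"` such characters are admitted and score 0 for both
#' exact and near matches.
#'
#' @param seq Single character string.
#' @param ambiguous `"error"` (default) or `"zero"`.
#' @param what Label used in error messages.
#' @return The normalized uppercase sequence.
#' @export
normalize_sequence <- function(seq, ambiguous = c("error", "zero"),
                               what = "sequence") {
  ambiguous <- match.arg(ambiguous)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop(what, " must be non-empty", call. = FALSE)
  if (ambiguous == "error") {
    bad <- regexpr("[^ACGT]", seq)
    if (bad > 0L)
      stop(sprintf("%s contains invalid base '%s' at position %d", what,
                   substr(seq, bad, bad), bad), call. = FALSE)
  }
  seq
}

# integer codes 0..3; unknown bases (only reachable under ambiguous = "zero")
# become -1, which the accumulator scores as 0/0
encode_sequence <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], CAT_ALPHABET) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

period_codes <- function(spec) {
  match(strsplit(spec$period, "")[[1]], CAT_ALPHABET) - 1L
}

#' Benchmark base at a position
#'
#' The benchmarks are infinite periodic repeats, so the base at zero-based
#' position `i` is `period[i mod 4]`.
#'
#' @param spec A `cat_benchmark`.
#' @param i Zero-based position(s), non-negative integer.
#' @return Character vector of bases, recycled over `i`.
#' @examples
#' benchmark_char(benchmark_spec("A"), 0:7)  # "A" "C" "G" "T" "A" "C" "G" "T"
#' @export
benchmark_char <- function(spec, i) {
  stopifnot(inherits(spec, "cat_benchmark"), is.numeric(i))
  if (any(i < 0)) stop("position must be non-negative", call. = FALSE)
  strsplit(spec$period, "")[[1]][(as.integer(i) %% 4L) + 1L]
}

check_bases <- function(b) {
  if (!all(b %in% CAT_ALPHABET))
    stop("base must be one of A, C, G, T", call. = FALSE)
}

#' Exact and near match scores against a benchmark
#'
#' `exact_match()` scores 1 when the observed base equals the benchmark base
#' at the same position, else 0. `near_match()` scores a mismatching base by
#' the circular distance between its canonical position in the benchmark
#' period and the aligned position: adjacent neighbor 0.6, far neighbor 0.4,
#' and 0 for the exact slot (the exact case carries no near score). Both are
#' vectorized over positions and bases.
#'
#' @param spec A `cat_benchmark`.
#' @param i Zero-based position(s).
#' @param b Base(s), each one of `A`, `C`, `G`, `T`.
#' @param constants A `cat_constants` (near weights).
#' @return Numeric score vector.
#' @examples
#' a <- benchmark_spec("A")
#' near_match(a, 1, "G")  # 0.6 - right-adjacent to the benchmark's C
#' near_match(a, 2, "A")  # 0.4 - far neighbor
#' exact_match(a, 1, "C") # 1
#' @export
exact_match <- function(spec, i, b) {
  stopifnot(inherits(spec, "cat_benchmark"))
  if (any(i < 0)) stop("position must be non-negative", call. = FALSE)
  b <- toupper(b)
  check_bases(b)
  as.numeric(benchmark_char(spec, i) == b)
}

#' @rdname exact_match
#' @export
near_match <- function(spec, i, b, constants = cat_constants()) {
  stopifnot(inherits(spec, "cat_benchmark"), inherits(constants, "cat_constants"))
  if (any(i < 0)) stop("position must be non-negative", call. = FALSE)
  b <- toupper(b)
  check_bases(b)
  canon <- match(b, strsplit(spec$period, "")[[1]]) - 1L
  d <- (canon - (as.integer(i) %% 4L)) %% 4L
  constants$baseDistance[d + 1L]
}
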