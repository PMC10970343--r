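#' Compare two CAT profiles in constant time
#'
#' Stage two of the method: per benchmark leg the Euclidean distance between
#' the stored `(D, H)` coordinates is taken,
#' `resultX = sqrt((D1 - D2)^2 + (H1 - H2)^2)`, and the overall similarity is
#' `1 - (resultC + resultA + resultT) / 3`, reported as a percentage clamped
#' to `[0, 100]` (the raw value is kept for diagnostics; it can go negative
#' for very distant profiles). The computation touches only the six numbers
#' stored in each profile, never the sequences, so its cost is independent of
#' sequence length.
#'
#' Profiles computed under different provenance (benchmark periods, scoring
#' constants or pairing convention) are geometrically incomparable and the
#' function refuses them.
#'
#' @param p,q `cat_profile` objects with identical provenance.
#' @return A `cat_similarity` list: `resultC`, `resultA`, `resultT`,
#'   `similarity_raw`, `similarity_percent`, `full_match` (all three
#'   distances below the `1e-12` equality tolerance).
#' @examples
#' p <- cat_profile("ACGTACGTAC")
#' compare_profiles(p, p)$similarity_percent  # 100
#' @export
compare_profiles <- function(p, q) {
  stopifnot(inherits(p, "cat_profile"), inherits(q, "cat_profile"))
  if (!identical(p$provenance, q$provenance))
    stop(paste("profiles were computed under different provenance (benchmark",
               "periods, scoring constants or pairing) and are not",
               "comparable; recompute one of them"), call. = FALSE)
  res <- vapply(c(C = "C", A = "A", T = "T"), function(k) {
    sqrt((p$profile[[k]]$D - q$profile[[k]]$D)^2 +
         (p$profile[[k]]$H - q$profile[[k]]$H)^2)
  }, numeric(1))
  raw <- 1 - (res[["C"]] + res[["A"]] + res[["T"]]) / 3
  structure(list(resultC = res[["C"]], resultA = res[["A"]],
                 resultT = res[["T"]], similarity_raw = raw,
                 similarity_percent = 100 * min(max(raw, 0), 1),
                 full_match = all(res < CAT_MATCH_TOLERANCE)),
            class = "cat_similarity")
}

#' Compare two DNA sequences through their CAT profiles
#'
#' Convenience composition: computes both profiles with [cat_profile()] and
#' compares them with [compare_profiles()]. Equivalent bit-exactly to the
#' two-step pipeline.
#'
#' @param s1,s2 DNA sequences (single strings).
#' @param constants A `cat_constants` shared by both profiles.
#' @param ambiguous Passed to [normalize_sequence()].
#' @return A `cat_similarity`.
#' @examples
#' compare_sequences("ACGTACGTAC", "ACGTACGTAC")$similarity_percent  # 100
#' @export
compare_sequences <- function(s1, s2, constants = cat_constants(),
                              ambiguous = c("error", "zero")) {
  ambiguous <- match.arg(ambiguous)
  compare_profiles(cat_profile(s1, "s1", constants, ambiguous),
                   cat_profile(s2, "s2", constants, ambiguous))
}

#' @export
print.cat_similarity <- function(x, ...) {
  cat(sprintf("<cat_similarity> %.4f%%\n", x$similarity_percent))
  cat(sprintf("  distances: C %.6g  A %.6g  T %.6g  (raw %.6g)\n",
              x$resultC, x$resultA, x$resultT, x$similarity_raw))
  invisible(x)
}
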