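#' Read DNA sequence records from a FASTA file
#'
#' Parses with Biostrings and validates on top of it: ids must be non-empty
#' and unique within the file, sequences are uppercased, line wrapping is
#' ignored, and every base must be in `{A,C,G,T}` (or, with
#' `ambiguous = "zero"`, other characters are admitted and will score zero
#' during profiling). Structural problems found by a light pre-scan (file
#' not starting with a header, a header with no sequence) are reported with
#' their line number; invalid bases are reported with the record id and
#' 1-based position.
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Passed to [normalize_sequence()].
#' @return data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, ambiguous = c("error", "zero")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop(path, ": empty file, expected FASTA", call. = FALSE)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop(sprintf("%s: line %d: expected FASTA header starting with '>'",
                 path, nonblank[1]), call. = FALSE)
  headers <- which(startsWith(lines, ">"))
  for (h in seq_along(headers)) {
    from <- headers[h] + 1L
    to <- if (h < length(headers)) headers[h + 1L] - 1L else length(lines)
    body <- lines[seq2(from, to)]
    if (sum(nchar(trimws(body))) == 0L)
      stop(sprintf("%s: line %d: header with empty sequence", path,
                   headers[h]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop(path, ": record with empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(path, ": duplicate sequence id '", dup[1], "'", call. = FALSE)
  seqs <- vapply(seq_along(set), function(k) {
    normalize_sequence(as.character(set[[k]]), ambiguous = ambiguous,
                       what = sprintf("record '%s'", ids[k]))
  }, character(1))
  data.frame(id = ids, sequence = seqs)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Write sequence records to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::DNAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate seeded synthetic sequence records
#'
#' Uniform i.i.d. bases over `{A,C,G,T}`, fully reproducible for a given
#' seed; ids are `synth_1`, `synth_2`, ... These synthetic records emulate
#' the random test collections used to exercise profiling and search; they
#' carry no compositional bias, repeats or homology structure.
#'
#' @param n_sequences Number of records, at least 1.
#' @param length Length of every sequence, at least 1.
#' @param seed Integer seed.
#' @return data.frame with columns `id` and `sequence`.
#' @examples
#' generate_fixtures(2, 8, seed = 42)
#' @export
generate_fixtures <- function(n_sequences, length, seed = 1L) {
  stopifnot(is.numeric(n_sequences), n_sequences >= 1, is.numeric(length),
            length >= 1)
  set.seed(seed)
  seqs <- vapply(seq_len(n_sequences), function(k) {
    paste(sample(CAT_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(id = paste0("synth_", seq_len(n_sequences)), sequence = seqs)
}

PROFILE_SCHEMA_VERSION <- 1L

#' Persist and reload CAT profiles as a JSON-lines sidecar
#'
#' One JSON record per line, so stores are appendable and streamable:
#' `{"schema_version": 1, "sequence_id": ..., "length": ..., "profile":
#' {"C": {"D": ..., "H": ...}, "A": ..., "T": ...}, "provenance": ...}`.
#' Numbers are written at full round-trip precision, so
#' `read_profiles(write_profiles(p))` reproduces the in-memory profiles
#' bit-identically and downstream comparisons of reloaded profiles equal
#' in-memory comparisons exactly. All profiles in one file must share
#' provenance; a file whose provenance was altered will be refused by
#' [compare_profiles()] against profiles from the original constants.
#'
#' @param profiles List of `cat_profile` objects (a single profile is
#'   accepted).
#' @param path Sidecar path (conventionally `.jsonl`).
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns a list of `cat_profile` objects.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "cat_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "cat_profile")))
  prov <- profiles[[1]]$provenance
  same <- vapply(profiles, function(p) identical(p$provenance, prov),
                 logical(1))
  if (!all(same))
    stop("profiles with mixed provenance cannot share a sidecar file",
         call. = FALSE)
  lines <- vapply(profiles, function(p) {
    as.character(jsonlite::toJSON(
      list(schema_version = PROFILE_SCHEMA_VERSION,
           sequence_id = p$sequence_id, length = p$length,
           profile = p$profile, provenance = p$provenance),
      auto_unbox = TRUE, digits = I(17)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    rec <- jsonlite::fromJSON(lines[k], simplifyVector = FALSE)
    if (!identical(as.integer(rec$schema_version), PROFILE_SCHEMA_VERSION))
      stop(sprintf("%s: line %d: unsupported profile schema version %s",
                   path, k, format(rec$schema_version)), call. = FALSE)
    legs <- lapply(rec$profile, function(l) {
      list(D = as.numeric(l$D), H = as.numeric(l$H))
    })
    prov <- list(periods = lapply(rec$provenance$periods, as.character),
                 baseDistance = as.numeric(unlist(rec$provenance$baseDistance)),
                 minPoint = as.numeric(rec$provenance$minPoint),
                 pairing = as.character(rec$provenance$pairing))
    structure(list(sequence_id = as.character(rec$sequence_id),
                   length = as.integer(rec$length), profile = legs,
                   provenance = prov),
              class = "cat_profile")
  })
}
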