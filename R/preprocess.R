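#' Trim the 3' adapter from reads
#'
#' Finds, for each read, the leftmost position at which the read's suffix
#' matches the adapter: either the overlap (suffix of the read vs prefix of
#' the adapter) is >= 8 nt and exact, or the full adapter occurs with at
#' most one mismatch. Everything from that position on is removed. Reads
#' with no adapter hit are kept whole; reads that trim to length zero (or
#' empty input reads) are flagged for discard.
#'
#' @param sequences character vector of read sequences.
#' @param qualities parallel vector of Phred+33 quality strings.
#' @param adapter adapter sequence, length >= 8.
#' @return data.frame with columns `sequence`, `quality` (trimmed) and
#'   `discard` (logical).
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACTGGAATTCTC", strrep("I", 28),
#'              "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(sequences, qualities, adapter) {
  if (nchar(adapter) < 8) .stopf("adapter must be >= 8 nt")
  stopifnot(length(sequences) == length(qualities))
  n <- length(sequences)
  if (n == 0L) {
    return(data.frame(sequence = character(0), quality = character(0),
                      discard = logical(0), stringsAsFactors = FALSE))
  }
  len <- nchar(sequences)
  cut <- rep(NA_integer_, n)

  # exact path: leftmost occurrence of the adapter's first 8 bases whose
  # whole read/adapter overlap matches exactly
  probe <- substr(adapter, 1L, 8L)
  alen <- nchar(adapter)
  todo <- which(len >= 8L)
  offset <- rep(0L, n)
  while (length(todo) > 0L) {
    rel <- regexpr(probe, substring(sequences[todo], offset[todo] + 1L),
                   fixed = TRUE)
    hit <- which(rel > 0L)
    if (length(hit) == 0L) break
    i <- todo[hit]
    at <- offset[i] + as.integer(rel[hit])
    ov <- pmin(alen, len[i] - at + 1L)
    ok <- substr(sequences[i], at, at + ov - 1L) == substr(adapter, 1L, ov)
    cut[i[ok]] <- at[ok]
    # re-scan reads where the 8-mer hit but the full overlap mismatched
    again <- i[!ok]
    offset[again] <- at[!ok]
    todo <- again[offset[again] + 8L <= len[again]]
  }

  # tolerant path: full adapter with <= 1 mismatch (may start earlier than
  # the exact hit, e.g. when the mismatch falls in the first 8 bases).
  # Pigeonhole pre-filter: such a hit contains one exact adapter half, so
  # only reads where a half occurs before the exact cut need checking.
  half <- alen %/% 2L
  h1 <- substr(adapter, 1L, half)
  h2 <- substr(adapter, half + 1L, alen)
  p1 <- regexpr(h1, sequences, fixed = TRUE)
  p2 <- regexpr(h2, sequences, fixed = TRUE)
  cand1 <- ifelse(p1 > 0L, as.integer(p1), NA_integer_)
  cand2 <- ifelse(p2 > 0L, as.integer(p2) - half, NA_integer_)
  earliest <- pmin(cand1, cand2, na.rm = TRUE)
  has_room <- which(len >= alen & !is.na(earliest) &
                      (is.na(cut) | earliest < cut))
  if (length(has_room) > 0L) {
    mm <- Biostrings::vmatchPattern(adapter,
                                    Biostrings::DNAStringSet(
                                      sequences[has_room]),
                                    max.mismatch = 1)
    first <- vapply(mm, function(ir) {
      if (length(ir) == 0L) NA_integer_ else min(IRanges::start(ir))
    }, integer(1))
    better <- !is.na(first) & (is.na(cut[has_room]) | first < cut[has_room])
    cut[has_room[better]] <- first[better]
  }

  keep_to <- ifelse(is.na(cut), len, cut - 1L)
  data.frame(
    sequence = substr(sequences, 1L, keep_to),
    quality = substr(qualities, 1L, keep_to),
    discard = keep_to == 0L,
    stringsAsFactors = FALSE)
}

#' Quality-filter reads and collapse to unique tags
#'
#' Drops reads shorter than `min_len` or containing any base below
#' `min_phred` (one score threshold governs both the error null downstream
#' and the read filter here), then collapses survivors by exact sequence.
#' RPTM normalisation uses the retained reads as the library total.
#'
#' @param sequences character vector of (trimmed) read sequences.
#' @param qualities parallel Phred+33 quality strings.
#' @param min_len minimum read length (default 18 nt).
#' @param min_phred minimum per-base Phred score (default 30).
#' @return data.frame of class `unique_reads` with columns `sequence`,
#'   `raw_count`, `rptm`, `min_phred`, ordered by decreasing count then
#'   sequence; attribute `library_total` holds the number of retained reads.
#' @export
filter_and_collapse <- function(sequences, qualities, min_len = 18,
                                min_phred = 30) {
  stopifnot(length(sequences) == length(qualities))
  if (any(nchar(qualities) != nchar(sequences))) {
    .stopf("quality strings must match read lengths")
  }
  minq <- vapply(qualities, function(q) {
    if (nchar(q) == 0L) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
  if (any(minq < 0)) .stopf("malformed quality string (char below '!')")
  keep <- nchar(sequences) >= min_len & minq >= min_phred
  sequences <- sequences[keep]
  minq <- minq[keep]

  total <- length(sequences)
  if (total == 0L) {
    out <- data.frame(sequence = character(0), raw_count = integer(0),
                      rptm = numeric(0), min_phred = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "library_total") <- 0L
    class(out) <- c("unique_reads", "data.frame")
    return(out)
  }
  f <- factor(sequences)
  raw_count <- as.integer(tabulate(f, nbins = nlevels(f)))
  minq_u <- vapply(split(minq, f), min, numeric(1))
  out <- data.frame(sequence = levels(f), raw_count = raw_count,
                    rptm = normalize_rptm(raw_count, total),
                    min_phred = unname(minq_u),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "library_total") <- total
  class(out) <- c("unique_reads", "data.frame")
  out
}

#' Reads-per-ten-million normalisation
#'
#' @param raw_count read count(s).
#' @param library_total total usable sequencing tags in the library (>= 1).
#' @return `raw_count * 1e7 / library_total`.
#' @examples
#' normalize_rptm(7, 3.5e6) # 20
#' @export
normalize_rptm <- function(raw_count, library_total) {
  if (length(library_total) != 1L || library_total < 1) {
    .stopf("library_total must be a single count >= 1")
  }
  raw_count * 1e7 / library_total
}

#' Full preprocessing: trim, filter, collapse
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_and_collapse
#' @return a `unique_reads` data.frame (see [filter_and_collapse()]).
#' @export
preprocess_reads <- function(sequences, qualities,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_len = 18, min_phred = 30) {
  tr <- trim_adapter(sequences, qualities, adapter)
  tr <- tr[!tr$discard, , drop = FALSE]
  filter_and_collapse(tr$sequence, tr$quality, min_len = min_len,
                      min_phred = min_phred)
}
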