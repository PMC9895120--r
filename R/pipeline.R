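#' Process one sample from raw reads to per-sample site calls
#'
#' Convenience composition of the per-sample stages: adapter trimming,
#' quality filtering and collapsing, alignment, cross-mapping correction,
#' pileup and site calling.
#'
#' @param sequences,qualities raw read sequences and Phred+33 qualities
#'   (e.g. from [read_fastq()] or a `sim_sample`).
#' @param ref a `mirna_reference`.
#' @param adapter 3' adapter sequence.
#' @param min_len,min_phred read filtering parameters (defaults 18, 30).
#' @param max_mismatches,max_tail aligner parameters (defaults 2, 3).
#' @param ... further arguments passed to [call_sites()].
#' @return list with `unique_reads`, `alignments` (weighted), `pileup`,
#'   `calls` and `library_total`.
#' @export
process_sample <- function(sequences, qualities, ref,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           min_len = 18, min_phred = 30,
                           max_mismatches = 2, max_tail = 3, ...) {
  if (inherits(sequences, "sim_sample")) {
    qualities <- sequences$qualities
    sequences <- sequences$sequences
  }
  ur <- preprocess_reads(sequences, qualities, adapter = adapter,
                         min_len = min_len, min_phred = min_phred)
  library_total <- attr(ur, "library_total")
  al <- align_to_premirnas(ur, ref, max_mismatches = max_mismatches,
                           max_tail = max_tail)
  al <- cross_map_correct(al)
  pu <- build_pileup(al, ref)
  calls <- if (library_total > 0L) {
    call_sites(pu, library_total, ...)
  } else {
    call_sites_empty()
  }
  list(unique_reads = ur, alignments = al, pileup = pu, calls = calls,
       library_total = library_total)
}

# empty site_calls table (no usable reads in the sample)
call_sites_empty <- function() {
  out <- data.frame(key = character(0), locus = character(0),
                    position = integer(0), ref = character(0),
                    alt = character(0), coverage = numeric(0),
                    level = numeric(0), support_raw = numeric(0),
                    support_rptm = numeric(0), p_value = numeric(0),
                    q_value = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_calls", "data.frame")
  out
}
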