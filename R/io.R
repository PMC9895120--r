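#' Write a reference set to FASTA + GFF3
#'
#' Hairpins go to `hairpins.fa`; mature coordinates to `matures.gff3` in the
#' miRBase dialect (one `miRNA_primary_transcript` per hairpin, `miRNA`
#' features with `Name=` attributes, 1-based inclusive coordinates on the
#' hairpin itself); genomic flanks to `flanks.fa` (entries `<id>|flank5`,
#' `<id>|flank3`); decoys, if any, to `decoys.fa`.
#'
#' @param ref a `mirna_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "mirna_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "hairpins.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$hairpins), fa)

  hp_len <- nchar(ref$hairpins)
  gr_hp <- GenomicRanges::GRanges(
    seqnames = names(ref$hairpins),
    ranges = IRanges::IRanges(1L, unname(hp_len)),
    strand = "+",
    type = "miRNA_primary_transcript",
    Name = names(ref$hairpins),
    ID = names(ref$hairpins))
  gr_mat <- GenomicRanges::GRanges(
    seqnames = ref$matures$pre_mirna_id,
    ranges = IRanges::IRanges(ref$matures$start, ref$matures$end),
    strand = "+",
    type = "miRNA",
    Name = ref$matures$name,
    ID = ref$matures$name)
  gff <- file.path(dir, "matures.gff3")
  rtracklayer::export(c(gr_hp, gr_mat), gff, format = "gff3")

  fl <- c(stats::setNames(ref$flanks$flank5,
                          paste0(ref$flanks$pre_mirna_id, "|flank5")),
          stats::setNames(ref$flanks$flank3,
                          paste0(ref$flanks$pre_mirna_id, "|flank3")))
  flf <- file.path(dir, "flanks.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fl), flf)

  paths <- c(hairpins = fa, gff = gff, flanks = flf)
  if (nrow(ref$decoys) > 0) {
    df <- file.path(dir, "decoys.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(ref$decoys$sequence,
                                               ref$decoys$id)), df)
    paths <- c(paths, decoys = df)
  }
  invisible(paths)
}

#' Read a reference set from FASTA + GFF3
#'
#' Inverse of [write_reference()]. `miRNA` features supply the mature
#' arms; the arm label is taken from a trailing `-5p`/`-3p` in `Name`, or
#' inferred from which hairpin half the interval sits in.
#'
#' @param hairpin_fasta path to the hairpin FASTA.
#' @param gff path to the miRBase-style GFF3.
#' @param flank_fasta optional flank FASTA as written by [write_reference()].
#' @param decoy_fasta optional decoy FASTA.
#' @return a `mirna_reference`.
#' @export
read_reference <- function(hairpin_fasta, gff, flank_fasta = NULL,
                           decoy_fasta = NULL) {
  hp <- Biostrings::readDNAStringSet(hairpin_fasta)
  hairpins <- stats::setNames(as.character(hp), names(hp))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "miRNA"]
  id <- as.character(GenomicRanges::seqnames(gr))
  nm <- as.character(gr$Name)
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  arm <- ifelse(grepl("-5p$", nm), "5p",
                ifelse(grepl("-3p$", nm), "3p",
                       ifelse((st + en) / 2 <= nchar(hairpins[id]) / 2,
                              "5p", "3p")))
  matures <- data.frame(pre_mirna_id = id, name = nm, arm = arm,
                        start = st, end = en, stringsAsFactors = FALSE)

  ids <- names(hairpins)
  flanks <- data.frame(pre_mirna_id = ids,
                       flank5 = strrep("N", 0),
                       flank3 = strrep("N", 0),
                       stringsAsFactors = FALSE)
  if (!is.null(flank_fasta)) {
    fl <- Biostrings::readDNAStringSet(flank_fasta)
    flv <- stats::setNames(as.character(fl), names(fl))
    flanks$flank5 <- unname(flv[paste0(ids, "|flank5")])
    flanks$flank3 <- unname(flv[paste0(ids, "|flank3")])
  }
  decoys <- data.frame(id = character(0), sequence = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(decoy_fasta)) {
    dc <- Biostrings::readDNAStringSet(decoy_fasta)
    decoys <- data.frame(id = names(dc), sequence = as.character(dc),
                         stringsAsFactors = FALSE)
  }
  structure(list(hairpins = hairpins, matures = matures,
                 flanks = flanks, decoys = decoys),
            class = "mirna_reference")
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param x a `sim_sample`, or a character vector of sequences.
#' @param path output path.
#' @param qualities,names required when `x` is a plain character vector.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(x, path, qualities = NULL, names = NULL) {
  if (inherits(x, "sim_sample")) {
    sequences <- x$sequences
    qualities <- x$qualities
    names <- x$names
  } else {
    sequences <- x
  }
  stopifnot(length(sequences) == length(qualities),
            length(sequences) == length(names))
  ss <- Biostrings::DNAStringSet(stats::setNames(sequences, names))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ path.
#' @return list with `sequences`, `qualities`, `names`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  list(sequences = unname(as.character(ss)),
       qualities = unname(as.character(S4Vectors::mcols(ss)$qualities)),
       names = names(ss))
}
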