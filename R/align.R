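#' Align unique reads to pre-miRNA hairpins and decoy loci
#'
#' A deterministic exact-seed, ungapped aligner. Every `seed_len`-mer of a
#' read is looked up in an index of all loci (hairpins plus decoys); each
#' candidate placement is verified by direct comparison. A read may end in
#' an untemplated 3' tail of up to `max_tail` nt: for every placement the
#' split between body mismatches and tail is chosen to minimise
#' `mismatches + tail length`, ties broken in favour of the shorter tail
#' (so a 3' base that happens to match the template is counted as
#' templated body). Tail positions may run past the hairpin 3' end, where
#' they are compared against the genomic 3' flank; decoys carry no flank,
#' so reads overhanging a decoy end are not placed there.
#'
#' Mismatches and tails are reported in RNA letters: template base upper
#' case (T as U), read base lower case (t as u), matching the site-key
#' convention `{hairpin}_{pos}_{REF}_{alt}`.
#'
#' @param reads a `unique_reads` data.frame (see [filter_and_collapse()]),
#'   or any data.frame with `sequence` and `raw_count` columns.
#' @param ref a `mirna_reference`.
#' @param max_mismatches maximum substitutions in the read body (default 2).
#' @param max_tail maximum untemplated 3' tail length (default 3).
#' @param seed_len exact seed length for the index (default 12).
#' @return data.frame of class `mirna_alignments`: one row per placement
#'   with columns `read_idx`, `raw_count`, `locus`, `start`, `body_len`,
#'   `n_mism`, `tail_len`, `mism` and `tail` (strings `pos:REF>alt`
#'   semicolon-joined), `perfect`, `weight` (1 for uniquely placed reads,
#'   uniform over placements otherwise until [cross_map_correct()] runs).
#' @export
align_to_premirnas <- function(reads, ref, max_mismatches = 2,
                               max_tail = 3, seed_len = 12) {
  stopifnot(inherits(ref, "mirna_reference"),
            all(c("sequence", "raw_count") %in% names(reads)))
  loci_seq <- c(ref$hairpins,
                stats::setNames(ref$decoys$sequence, ref$decoys$id))
  is_hairpin <- c(rep(TRUE, length(ref$hairpins)),
                  rep(FALSE, nrow(ref$decoys)))
  flank3 <- stats::setNames(ref$flanks$flank3, ref$flanks$pre_mirna_id)
  loci_len <- nchar(loci_seq)
  loci_ch <- lapply(loci_seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  # seed index: kmer -> matrix of (locus index, 1-based position)
  kk <- lapply(seq_along(loci_seq), function(li) {
    n <- loci_len[li] - seed_len + 1L
    if (n < 1L) return(NULL)
    pos <- seq_len(n)
    data.frame(k = substring(loci_seq[li], pos, pos + seed_len - 1L),
               li = li, pos = pos, stringsAsFactors = FALSE)
  })
  kk <- do.call(rbind, kk)
  kmap <- split(seq_len(nrow(kk)), kk$k)

  seqs <- reads$sequence
  acc <- list()  # per-read vectors of equal-length columns, rbound once
  acc_n <- 0L
  loci_names <- names(loci_seq)
  for (ri in seq_along(seqs)) {
    rd <- seqs[ri]
    L <- nchar(rd)
    if (L < seed_len) next
    offs <- seq_len(L - seed_len + 1L)
    kmers <- substring(rd, offs, offs + seed_len - 1L)
    idx <- kmap[kmers]
    found <- which(!vapply(idx, is.null, logical(1)))
    if (length(found) == 0L) next
    nhit <- lengths(idx[found])
    rows <- unlist(idx[found], use.names = FALSE)
    cand_li <- kk$li[rows]
    cand_st <- kk$pos[rows] - rep.int(offs[found], nhit) + 1L
    keep <- cand_st >= 1L &
      cand_st + (L - max_tail) - 1L <= loci_len[cand_li]
    ckey <- cand_li[keep] * 100000L + cand_st[keep]
    u <- !duplicated(ckey)
    c_li <- cand_li[keep][u]
    c_st <- cand_st[keep][u]
    if (length(c_li) == 0L) next
    rd_ch <- strsplit(rd, "", fixed = TRUE)[[1]]

    o_locus <- character(0); o_start <- integer(0); o_bl <- integer(0)
    o_nm <- integer(0); o_tl <- integer(0)
    o_mism <- character(0); o_tail <- character(0)
    for (ci in seq_along(c_li)) {
      li <- c_li[ci]; st <- c_st[ci]
      llen <- loci_len[li]
      overlap <- min(L, llen - st + 1L)
      mism_vec <- rd_ch[seq_len(overlap)] !=
        loci_ch[[li]][st:(st + overlap - 1L)]
      cm <- cumsum(mism_vec)
      bl_min <- max(1L, L - max_tail)
      bl_max <- overlap
      if (bl_max < bl_min) next
      if (L > overlap) {  # read overhangs the locus 3' end
        if (!is_hairpin[li]) next  # decoy: no flank to compare a tail to
        fl <- flank3[[loci_names[li]]]
        if (is.na(fl) || nchar(fl) < L - overlap) next
      }
      best <- NULL
      for (bl in seq.int(bl_max, bl_min)) {  # descending: shorter tail first
        nm <- cm[bl]
        tl <- L - bl
        if (nm > max_mismatches) next
        sc <- nm + tl
        if (is.null(best) || sc < best$sc) best <- list(bl = bl, nm = nm,
                                                        tl = tl, sc = sc)
      }
      if (is.null(best)) next
      bl <- best$bl
      mism_str <- ""
      if (best$nm > 0L) {
        mp <- which(mism_vec[seq_len(bl)])
        pos <- st + mp - 1L
        refs <- .rna_upper[loci_ch[[li]][pos]]
        alts <- .rna_lower[rd_ch[mp]]
        mism_str <- paste(sprintf("%d:%s>%s", pos, refs, alts),
                          collapse = ";")
      }
      tail_str <- ""
      if (best$tl > 0L) {
        tp <- seq.int(bl + 1L, L)
        pos <- st + tp - 1L
        tmpl <- loci_ch[[li]][pmin(pos, llen)]
        over <- pos > llen
        if (any(over)) {
          fl <- flank3[[loci_names[li]]]
          tmpl[over] <- substring(fl, pos[over] - llen, pos[over] - llen)
        }
        tail_str <- paste(sprintf("%d:%s>%s", pos, .rna_upper[tmpl],
                                  .rna_lower[rd_ch[tp]]), collapse = ";")
      }
      o_locus <- c(o_locus, loci_names[li]); o_start <- c(o_start, st)
      o_bl <- c(o_bl, bl); o_nm <- c(o_nm, best$nm); o_tl <- c(o_tl, best$tl)
      o_mism <- c(o_mism, mism_str); o_tail <- c(o_tail, tail_str)
    }
    if (length(o_locus) > 0L) {
      acc_n <- acc_n + 1L
      acc[[acc_n]] <- list(read_idx = rep.int(ri, length(o_locus)),
                           raw_count = rep.int(reads$raw_count[ri],
                                               length(o_locus)),
                           locus = o_locus, start = o_start,
                           body_len = o_bl, n_mism = o_nm, tail_len = o_tl,
                           mism = o_mism, tail = o_tail)
    }
  }
  if (acc_n == 0L) {
    aln <- data.frame(read_idx = integer(0), raw_count = integer(0),
                      locus = character(0), start = integer(0),
                      body_len = integer(0), n_mism = integer(0),
                      tail_len = integer(0), mism = character(0),
                      tail = character(0), perfect = logical(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
    class(aln) <- c("mirna_alignments", "data.frame")
    return(aln)
  }
  cols <- names(acc[[1]])
  aln <- data.frame(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(acc[seq_len(acc_n)], `[[`, cn), use.names = FALSE)
  }), stringsAsFactors = FALSE)
  aln$perfect <- aln$n_mism == 0L & aln$tail_len == 0L
  aln <- aln[order(aln$read_idx, aln$locus, aln$start), , drop = FALSE]
  rownames(aln) <- NULL
  n_place <- table(aln$read_idx)
  aln$weight <- 1 / as.numeric(n_place[as.character(aln$read_idx)])
  class(aln) <- c("mirna_alignments", "data.frame")
  aln
}

#' Cross-mapping correction of multi-placed reads
#'
#' Iterative proportional allocation: a multi-placed read's weight at each
#' of its loci is set proportional to the current weighted mass of
#' perfectly matching reads at that locus plus a pseudocount, iterating
#' until the largest weight change falls below `tol` (or `max_iter`).
#' Uniquely placed reads keep weight 1, so each read's weights always sum
#' to 1 and total read mass is conserved.
#'
#' @param alignments a `mirna_alignments` data.frame.
#' @param prior optional named numeric: fixed perfect-match read mass per
#'   locus, overriding the mass computed from `alignments`.
#' @param pseudocount added to each locus mass (default 0.5).
#' @param tol convergence tolerance on the max weight change (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return `alignments` with the `weight` column updated.
#' @export
cross_map_correct <- function(alignments, prior = NULL, pseudocount = 0.5,
                              tol = 1e-6, max_iter = 100) {
  if (nrow(alignments) == 0L) return(alignments)
  grp <- as.character(alignments$read_idx)
  n_place <- table(grp)
  multi <- n_place[grp] > 1L
  w <- ifelse(multi, 1 / as.numeric(n_place[grp]), 1)

  locus_mass <- function(w) {
    if (!is.null(prior)) {
      m <- prior[alignments$locus]
      m[is.na(m)] <- 0
      return(unname(m))
    }
    pm <- alignments$perfect
    mass <- tapply(alignments$raw_count[pm] * w[pm],
                   alignments$locus[pm], sum)
    out <- mass[alignments$locus]
    out[is.na(out)] <- 0
    unname(out)
  }

  if (any(multi)) {
    for (it in seq_len(max_iter)) {
      m <- locus_mass(w) + pseudocount
      num <- ifelse(multi, m, 1)
      denom <- tapply(num, grp, sum)[grp]
      w_new <- ifelse(multi, num / as.numeric(denom), 1)
      delta <- max(abs(w_new - w))
      w <- w_new
      if (delta < tol) break
    }
  }
  alignments$weight <- w
  alignments
}

#' Per-site fraction of supporting-read mass mapped to other loci
#'
#' For every mismatch/tail site observed at a locus, the supporting reads
#' are those whose placement at that locus carries the site's alternative
#' base. Their total read mass is `sum(raw_count)` (each read's weights sum
#' to 1 across loci); the fraction attributed elsewhere is
#' `1 - sum(raw_count * weight at this locus) / sum(raw_count)`. Values
#' above 0.5 drive the Pseudo category.
#'
#' @param alignments a weighted `mirna_alignments` data.frame.
#' @return data.frame with `locus`, `position`, `ref`, `alt` (RNA letters)
#'   and `cross_map_fraction`.
#' @export
site_cross_map_fraction <- function(alignments) {
  ev <- .expand_events(alignments)
  if (nrow(ev) == 0L) {
    return(data.frame(locus = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      cross_map_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ev$here <- ev$raw_count * ev$weight
  agg <- stats::aggregate(cbind(here, raw_count) ~
                            locus + position + ref + alt,
                          data = ev, FUN = sum)
  out <- data.frame(locus = agg$locus, position = agg$position,
                    ref = agg$ref, alt = agg$alt,
                    cross_map_fraction = 1 - agg$here / agg$raw_count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# expand the packed mism/tail strings of an alignment table into one row
# per (alignment, event): locus, position, ref, alt, raw_count, weight,
# tail_event (TRUE for untemplated 3' tail bases)
.expand_events <- function(alignments) {
  empty <- data.frame(locus = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      raw_count = numeric(0), weight = numeric(0),
                      tail_event = logical(0), stringsAsFactors = FALSE)
  expand_col <- function(col, is_tail) {
    has <- col != ""
    al <- alignments[has, , drop = FALSE]
    if (nrow(al) == 0L) return(empty)
    pieces <- strsplit(col[has], ";", fixed = TRUE)
    n_ev <- lengths(pieces)
    flat <- unlist(pieces, use.names = FALSE)
    m <- regmatches(flat, regexec("^(\\d+):([ACGU])>([acgu])$", flat))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) .stopf("malformed event string: %s", flat[which(bad)[1]])
    mm <- do.call(rbind, m)
    data.frame(locus = rep(al$locus, n_ev),
               position = as.integer(mm[, 2]),
               ref = mm[, 3], alt = mm[, 4],
               raw_count = rep(al$raw_count, n_ev),
               weight = rep(al$weight, n_ev),
               tail_event = is_tail,
               stringsAsFactors = FALSE)
  }
  if (nrow(alignments) == 0L) return(empty)
  rbind(expand_col(alignments$mism, FALSE),
        expand_col(alignments$tail, TRUE))
}
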