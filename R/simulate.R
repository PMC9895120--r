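#' Sequencing-error model
#'
#' The per-base error rate is tied to a single Phred quality score:
#' `per_base_error = 10^(-phred_q / 10)`, the probability that a sequenced
#' base is wrong, distributed uniformly over the three non-template
#' nucleotides. The same score is emitted as a uniform Phred string for
#' every simulated read, so the downstream quality filter sees exactly the
#' score the error model assumes.
#'
#' `per_base_error` may be overridden, in particular to 0 for noiseless
#' reads that still carry a finite-quality string.
#'
#' @param phred_q integer Phred quality score (default 30, i.e. 0.001).
#' @param per_base_error optional explicit error probability in \[0, 0.25\].
#' @return an object of class `error_model`.
#' @examples
#' error_model(30)$per_base_error # 0.001
#' @export
error_model <- function(phred_q = 30, per_base_error = NULL) {
  if (!is.numeric(phred_q) || length(phred_q) != 1L || phred_q < 2) {
    .stopf("phred_q must be a single quality score >= 2")
  }
  if (is.null(per_base_error)) {
    per_base_error <- 10^(-phred_q / 10)
  }
  if (per_base_error < 0 || per_base_error > 0.25) {
    .stopf("per_base_error must lie in [0, 0.25], got %g", per_base_error)
  }
  structure(
    list(phred_q = as.integer(phred_q), per_base_error = per_base_error),
    class = "error_model"
  )
}

#' Generate a synthetic pre-miRNA reference set
#'
#' Draws random hairpin sequences with one or two annotated mature arms
#' (5p and/or 3p, 20-24 nt, fully inside the hairpin), genomic flanking
#' sequence on both sides, and optional decoy loci. A decoy is a genomic
#' segment that shares a long (>= 18 nt) exact substring with one hairpin
#' but differs by one substitution near the shared window's 5' edge, so a
#' read carrying that substitution maps perfectly to the decoy and
#' imperfectly to the hairpin -- the configuration cross-mapping correction
#' is designed to resolve.
#'
#' @param n_hairpins number of hairpins (>= 1).
#' @param hairpin_len_range length-2 interval of hairpin lengths (>= 50 nt).
#' @param n_decoys number of decoy loci (default 0).
#' @param flank_len genomic flank length on each side (>= 10 nt).
#' @param seed optional integer seed; fixed seed gives byte-identical output.
#' @return an object of class `mirna_reference` with elements
#'   `hairpins` (named character), `matures` (data.frame: pre_mirna_id,
#'   name, arm, start, end; 1-based inclusive), `flanks` (data.frame:
#'   pre_mirna_id, flank5, flank3) and `decoys` (data.frame: id, sequence).
#' @examples
#' ref <- generate_reference(3, c(60, 90), seed = 1)
#' ref$matures
#' @export
generate_reference <- function(n_hairpins,
                               hairpin_len_range = c(60, 110),
                               n_decoys = 0,
                               flank_len = 30,
                               seed = NULL) {
  if (!is.numeric(n_hairpins) || n_hairpins < 1) {
    .stopf("n_hairpins must be >= 1")
  }
  if (length(hairpin_len_range) != 2L ||
      hairpin_len_range[1] > hairpin_len_range[2] ||
      hairpin_len_range[1] < 50) {
    .stopf("hairpin_len_range must be an increasing interval with lengths >= 50")
  }
  if (flank_len < 10) .stopf("flank_len must be >= 10")
  n_hairpins <- as.integer(n_hairpins)

  with_seed(seed, {
    ids <- sprintf("sim-mir-%d", seq_len(n_hairpins))
    hairpins <- character(n_hairpins)
    mat_rows <- vector("list", n_hairpins)
    flank5 <- character(n_hairpins)
    flank3 <- character(n_hairpins)

    for (i in seq_len(n_hairpins)) {
      lens <- seq.int(hairpin_len_range[1], hairpin_len_range[2])
      len <- if (length(lens) == 1L) lens else sample(lens, 1L)
      hp <- paste(sample(.NUCS, len, replace = TRUE), collapse = "")
      # candidate arms; draw everything up front so RNG use is fixed
      s5 <- sample(4:8, 1L)
      l5 <- sample(20:24, 1L)
      e3 <- len - sample(4:8, 1L)
      l3 <- sample(20:24, 1L)
      pick <- sample(c("5p", "3p"), 1L)
      a5 <- c(start = s5, end = s5 + l5 - 1L)
      a3 <- c(start = e3 - l3 + 1L, end = e3)
      both_ok <- len >= 70 && a3["start"] > a5["end"] + 3L
      arms <- if (both_ok) c("5p", "3p") else pick
      rows <- lapply(arms, function(a) {
        iv <- if (a == "5p") a5 else a3
        data.frame(pre_mirna_id = ids[i],
                   name = paste0(ids[i], "-", a),
                   arm = a,
                   start = unname(iv["start"]),
                   end = unname(iv["end"]),
                   stringsAsFactors = FALSE)
      })
      hairpins[i] <- hp
      mat_rows[[i]] <- do.call(rbind, rows)
      flank5[i] <- paste(sample(.NUCS, flank_len, replace = TRUE), collapse = "")
      flank3[i] <- paste(sample(.NUCS, flank_len, replace = TRUE), collapse = "")
    }
    names(hairpins) <- ids

    decoys <- data.frame(id = character(0), sequence = character(0),
                         stringsAsFactors = FALSE)
    if (n_decoys > 0) {
      drows <- vector("list", n_decoys)
      for (j in seq_len(n_decoys)) {
        hi <- sample(n_hairpins, 1L)
        mats <- mat_rows[[hi]]
        w_start <- mats$start[1]
        w_end <- min(w_start + 23L, nchar(hairpins[hi]))
        w_start <- max(1L, w_end - 23L)
        win <- substr(hairpins[hi], w_start, w_end)
        orig <- substr(win, 3L, 3L)
        sub <- sample(setdiff(.NUCS, orig), 1L)
        substr(win, 3L, 3L) <- sub
        pad5 <- paste(sample(.NUCS, 20, replace = TRUE), collapse = "")
        pad3 <- paste(sample(.NUCS, 20, replace = TRUE), collapse = "")
        drows[[j]] <- data.frame(id = sprintf("decoy-%d", j),
                                 sequence = paste0(pad5, win, pad3),
                                 stringsAsFactors = FALSE)
      }
      decoys <- do.call(rbind, drows)
    }

    structure(
      list(hairpins = hairpins,
           matures = do.call(rbind, mat_rows),
           flanks = data.frame(pre_mirna_id = ids, flank5 = flank5,
                               flank3 = flank3, stringsAsFactors = FALSE),
           decoys = decoys),
      class = "mirna_reference"
    )
  })
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("mirna_reference: %d hairpins, %d mature arms, %d decoys\n",
              length(x$hairpins), nrow(x$matures), nrow(x$decoys)))
  invisible(x)
}

# template (DNA) nucleotide at hairpin position p; positions past the hairpin
# 3' end read into the genomic 3' flank
.template_nt <- function(ref, id, pos) {
  len <- nchar(ref$hairpins[[id]])
  if (pos <= len) {
    substr(ref$hairpins[[id]], pos, pos)
  } else {
    fl <- ref$flanks$flank3[ref$flanks$pre_mirna_id == id]
    off <- pos - len
    if (length(fl) != 1L || off > nchar(fl)) {
      .stopf("position %d is beyond hairpin '%s' and its 3' flank", pos, id)
    }
    substr(fl, off, off)
  }
}

#' Specify a planted mutation/editing event
#'
#' One row per event. Positions are 1-based in the hairpin; tail events sit
#' past the mature 3' end (possibly past the hairpin itself, where the
#' template base comes from the genomic 3' flank). `alt_nt` uses the
#' lower-case RNA alphabet of site keys (`a/c/g/u`); `ref_nt` is the
#' upper-case DNA template base and is checked against the reference.
#'
#' @param pre_mirna_id hairpin identifier.
#' @param position 1-based hairpin position of the event.
#' @param ref_nt template nucleotide (A/C/G/T).
#' @param alt_nt planted nucleotide, lower-case RNA (a/c/g/u).
#' @param target_level fraction of covering reads that carry the event.
#' @param kind one of "central", "tail", "five_prime", "snp".
#' @return one-row data.frame; rows may be `rbind`ed into an edit table.
#' @examples
#' edit_spec("sim-mir-1", 9, "A", "g", 0.3, "central")
#' @export
edit_spec <- function(pre_mirna_id, position, ref_nt, alt_nt,
                      target_level, kind = c("central", "tail",
                                             "five_prime", "snp")) {
  kind <- match.arg(kind)
  if (!ref_nt %in% .NUCS) .stopf("ref_nt must be one of A/C/G/T")
  if (!alt_nt %in% c("a", "c", "g", "u")) {
    .stopf("alt_nt must be lower-case RNA (a/c/g/u)")
  }
  if (target_level < 0 || target_level > 1) {
    .stopf("target_level must lie in [0, 1]")
  }
  if (kind == "snp" && target_level != 1) {
    .stopf("kind = 'snp' requires target_level = 1 (homozygous variant)")
  }
  if (.dna_from_rna[[alt_nt]] == ref_nt) {
    .stopf("alt_nt must differ from ref_nt")
  }
  data.frame(pre_mirna_id = pre_mirna_id, position = as.integer(position),
             ref_nt = ref_nt, alt_nt = alt_nt,
             target_level = target_level, kind = kind,
             stringsAsFactors = FALSE)
}

#' Canonical site key for a planted event
#' @keywords internal
.site_key <- function(id, pos, ref_dna, alt_rna) {
  paste(id, pos, .rna_upper[[ref_dna]], alt_rna, sep = "_")
}

.validate_edits <- function(ref, edits) {
  for (k in seq_len(nrow(edits))) {
    e <- edits[k, ]
    if (!e$pre_mirna_id %in% names(ref$hairpins)) {
      .stopf("edit %d references unknown hairpin '%s'", k, e$pre_mirna_id)
    }
    len <- nchar(ref$hairpins[[e$pre_mirna_id]])
    mats <- ref$matures[ref$matures$pre_mirna_id == e$pre_mirna_id, ]
    tmpl <- .template_nt(ref, e$pre_mirna_id, e$position)
    if (tmpl != e$ref_nt) {
      .stopf("edit %d: ref_nt %s does not match template %s at %s:%d",
             k, e$ref_nt, tmpl, e$pre_mirna_id, e$position)
    }
    if (e$kind == "tail") {
      if (!any(e$position > mats$end)) {
        .stopf("edit %d: tail position must lie past a mature 3' end", k)
      }
    } else if (e$position > len) {
      .stopf("edit %d: non-tail position %d outside hairpin (len %d)",
             k, e$position, len)
    }
  }
  invisible(edits)
}

#' Simulate one small RNA-seq sample from a reference set
#'
#' Reads are anchored on the mature arms with geometric 5'/3' end jitter
#' (`P(offset = k) ~ (1 - jitter_prob)^k`, capped at `max_jitter`, random
#' sign), so the pileup reproduces isomiR-like coverage. Each read
#' independently carries each planted event that its body covers with
#' probability `target_level` (always, for SNP events). Tail events
#' truncate the body at `position - 1` and append the untemplated
#' nucleotide. Sequencing errors are then applied per base at
#' `error$per_base_error`, uniformly over the three other nucleotides, and
#' a fixed 3' adapter plus a uniform Phred string are attached.
#'
#' @param ref a `mirna_reference`.
#' @param edits edit table from [edit_spec()] (or NULL).
#' @param depth_per_arm reads generated per mature arm (>= 1).
#' @param error an [error_model()].
#' @param adapter 3' adapter appended to every read (common small-RNA kit
#'   adapter by default); sequenced error-free so trimming is exact.
#' @param jitter_prob,max_jitter geometric end-jitter parameters.
#' @param seed optional integer seed.
#' @return object of class `sim_sample`: `sequences`, `qualities`, `names`
#'   (parallel character vectors, adapter included) and `truth`, a
#'   data.frame with one row per planted event (site key, kind,
#'   target_level, n_covering = reads whose body covers the position,
#'   n_carrying = reads that actually carry it).
#' @examples
#' ref <- generate_reference(1, c(70, 70), seed = 1)
#' s <- simulate_sample(ref, depth_per_arm = 50, seed = 2)
#' length(s$sequences)
#' @export
simulate_sample <- function(ref, edits = NULL, depth_per_arm = 100,
                            error = error_model(),
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            jitter_prob = 0.7, max_jitter = 3,
                            seed = NULL) {
  stopifnot(inherits(ref, "mirna_reference"), inherits(error, "error_model"))
  if (depth_per_arm < 1) .stopf("depth_per_arm must be >= 1")
  if (!is.null(edits) && nrow(edits) > 0) .validate_edits(ref, edits)

  with_seed(seed, {
    mats <- ref$matures
    n_arm <- nrow(mats)
    n_total <- n_arm * depth_per_arm

    hp_id <- rep(mats$pre_mirna_id, each = depth_per_arm)
    hp_len <- nchar(ref$hairpins)[hp_id]
    m_start <- rep(mats$start, each = depth_per_arm)
    m_end <- rep(mats$end, each = depth_per_arm)

    j5 <- pmin(stats::rgeom(n_total, jitter_prob), max_jitter) *
      sample(c(-1L, 1L), n_total, replace = TRUE)
    j3 <- pmin(stats::rgeom(n_total, jitter_prob), max_jitter) *
      sample(c(-1L, 1L), n_total, replace = TRUE)
    start <- pmax(1L, m_start + j5)
    end <- pmin(hp_len, pmax(m_end + j3, start + 1L))
    seqs <- substr(rep(unname(ref$hairpins[hp_id]), 1L), start, end)

    truth <- NULL
    if (!is.null(edits) && nrow(edits) > 0) {
      t_rows <- vector("list", nrow(edits))
      for (k in seq_len(nrow(edits))) {
        e <- edits[k, ]
        alt_dna <- .dna_from_rna[[e$alt_nt]]
        if (e$kind == "tail") {
          idx <- which(hp_id == e$pre_mirna_id & end >= e$position - 1L &
                         start < e$position)
        } else {
          idx <- which(hp_id == e$pre_mirna_id & start <= e$position &
                         end >= e$position)
        }
        carry <- idx[stats::runif(length(idx)) < e$target_level]
        if (e$kind == "tail") {
          # untemplated addition: cut the body back and append the alt base
          seqs[carry] <- paste0(
            substr(seqs[carry], 1L, e$position - start[carry]), alt_dna)
          end[carry] <- e$position - 1L
        } else {
          at <- e$position - start[carry] + 1L
          substr(seqs[carry], at, at) <- alt_dna
        }
        t_rows[[k]] <- data.frame(
          key = .site_key(e$pre_mirna_id, e$position, e$ref_nt, e$alt_nt),
          pre_mirna_id = e$pre_mirna_id, position = e$position,
          ref_nt = e$ref_nt, alt_nt = e$alt_nt, kind = e$kind,
          target_level = e$target_level,
          n_covering = length(idx), n_carrying = length(carry),
          stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, t_rows)
    }

    # per-base sequencing errors over the insert (adapter stays exact)
    if (error$per_base_error > 0) {
      nch <- nchar(seqs)
      flat_read <- rep.int(seq_len(n_total), nch)
      flat_pos <- sequence(nch)
      hit <- which(stats::runif(length(flat_read)) < error$per_base_error)
      if (length(hit) > 0) {
        r <- flat_read[hit]
        p <- flat_pos[hit]
        cur <- substr(seqs[r], p, p)
        # uniform over the three non-current nucleotides
        shift <- sample.int(3L, length(hit), replace = TRUE)
        others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                        G = c("A", "C", "T"), T = c("A", "C", "G"))
        repl <- others[cbind(match(cur, rownames(others)), shift)]
        for (u in seq_along(hit)) {
          substr(seqs[r[u]], p[u], p[u]) <- repl[u]
        }
      }
    }

    qchar <- intToUtf8(error$phred_q + 33L)
    seqs_out <- paste0(seqs, adapter)
    quals <- strrep(qchar, nchar(seqs_out))
    structure(
      list(sequences = seqs_out,
           qualities = quals,
           names = sprintf("read%06d", seq_len(n_total)),
           truth = truth),
      class = "sim_sample"
    )
  })
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("sim_sample: %d reads, %d planted events\n",
              length(x$sequences),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}
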