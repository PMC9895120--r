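#' Build a weighted per-position pileup over hairpins
#'
#' Each aligned base contributes its read's `raw_count * weight` to the
#' counters at its hairpin position; untemplated tail bases contribute at
#' their post-body positions (which may extend up to `max_tail` past the
#' hairpin 3' end). Decoy placements are excluded: they exist to absorb
#' cross-mapping weight, not to be called.
#'
#' @param alignments a weighted `mirna_alignments` data.frame.
#' @param ref a `mirna_reference`.
#' @return object of class `pileup`: `coverage`, a list mapping hairpin id
#'   to a numeric vector of per-position weighted coverage (length
#'   hairpin + 3), and `alts`, a data.frame of weighted alternative-base
#'   counts (`locus`, `position`, `ref`, `alt`, `count`).
#' @export
build_pileup <- function(alignments, ref) {
  stopifnot(inherits(ref, "mirna_reference"))
  hp <- names(ref$hairpins)
  al <- alignments[alignments$locus %in% hp, , drop = FALSE]

  coverage <- lapply(hp, function(id) numeric(nchar(ref$hairpins[[id]]) + 3L))
  names(coverage) <- hp
  if (nrow(al) > 0L) {
    mass <- al$raw_count * al$weight
    for (id in unique(al$locus)) {
      sel <- al$locus == id
      len <- length(coverage[[id]])
      delta <- numeric(len + 1L)
      st <- al$start[sel]
      en <- st + al$body_len[sel] - 1L
      m <- mass[sel]
      for (j in seq_along(st)) {
        delta[st[j]] <- delta[st[j]] + m[j]
        delta[en[j] + 1L] <- delta[en[j] + 1L] - m[j]
      }
      coverage[[id]] <- cumsum(delta[seq_len(len)])
    }
  }

  ev <- .expand_events(al)
  alts <- data.frame(locus = character(0), position = integer(0),
                     ref = character(0), alt = character(0),
                     count = numeric(0), stringsAsFactors = FALSE)
  if (nrow(ev) > 0L) {
    ev$mass <- ev$raw_count * ev$weight
    agg <- stats::aggregate(mass ~ locus + position + ref + alt, data = ev,
                            FUN = sum)
    names(agg)[names(agg) == "mass"] <- "count"
    alts <- agg[order(agg$locus, agg$position, agg$alt), , drop = FALSE]
    rownames(alts) <- NULL
    # tail bases also contribute coverage at their own positions
    tl <- ev[ev$tail_event, , drop = FALSE]
    if (nrow(tl) > 0L) {
      for (j in seq_len(nrow(tl))) {
        coverage[[tl$locus[j]]][tl$position[j]] <-
          coverage[[tl$locus[j]]][tl$position[j]] + tl$mass[j]
      }
    }
  }
  structure(list(coverage = coverage, alts = alts), class = "pileup")
}

#' Upper-tail binomial probability of a sequencing-error pile
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the probability that random
#' sequencing errors alone produce at least `k` alternative bases among
#' `n` covering reads.
#'
#' @param k observed alternative count (integer).
#' @param n coverage (integer).
#' @param p0 per-base error probability toward the alternative.
#' @return numeric vector of upper-tail probabilities.
#' @export
binom_tail <- function(k, n, p0) {
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Call per-sample mutation/editing sites from a pileup
#'
#' Every position/alternative with weighted count > 0 becomes a candidate.
#' Its p-value is the upper-tail probability of at least that many
#' alternative bases under a Binomial(coverage, `p0`) sequencing-error
#' null with `p0 = 10^(-phred_threshold/10)` (optionally split over the
#' three alternatives); weighted counts are rounded half-up to integers
#' for the test. Benjamini-Hochberg correction runs over all candidates in
#' the sample, and a site is significant iff editing level >= `min_level`,
#' normalised support >= `min_support_rptm` reads per ten million, and
#' q-value < `alpha`.
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @param library_total retained sequencing tags in the sample (for RPTM).
#' @param phred_threshold Phred score defining the error null (default 30).
#' @param min_level minimum editing level (default 0.05).
#' @param min_support_rptm minimum support in reads per ten million
#'   (default 10).
#' @param alpha FDR level for the corrected p-value (default 0.05).
#' @param error_split_three if TRUE, use `p0 / 3` (error mass split evenly
#'   over the three alternatives) instead of the conservative `p0`.
#' @return data.frame of class `site_calls`: `key`
#'   (`{hairpin}_{pos}_{REF}_{alt}`), `locus`, `position`, `ref`, `alt`,
#'   `coverage`, `level`, `support_raw`, `support_rptm`, `p_value`,
#'   `q_value`, `significant`.
#' @export
call_sites <- function(pileup, library_total, phred_threshold = 30,
                       min_level = 0.05, min_support_rptm = 10,
                       alpha = 0.05, error_split_three = FALSE) {
  stopifnot(inherits(pileup, "pileup"))
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  if (library_total < 1) .stopf("library_total must be >= 1")
  alts <- pileup$alts[pileup$alts$count > 0, , drop = FALSE]
  if (nrow(alts) == 0L) {
    out <- data.frame(key = character(0), locus = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), coverage = numeric(0),
                      level = numeric(0), support_raw = numeric(0),
                      support_rptm = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("site_calls", "data.frame")
    return(out)
  }
  cov <- mapply(function(l, p) pileup$coverage[[l]][p],
                alts$locus, alts$position)
  p0 <- 10^(-phred_threshold / 10)
  if (error_split_three) p0 <- p0 / 3
  n <- round_half_up(cov)
  k <- round_half_up(alts$count)
  p <- binom_tail(k, n, p0)
  p[k == 0] <- 1
  q <- bh_correct(p)
  level <- alts$count / cov
  rptm <- normalize_rptm(alts$count, library_total)
  out <- data.frame(
    key = paste(alts$locus, alts$position, alts$ref, alts$alt, sep = "_"),
    locus = alts$locus, position = alts$position,
    ref = alts$ref, alt = alts$alt,
    coverage = unname(cov), level = unname(level),
    support_raw = alts$count, support_rptm = rptm,
    p_value = p, q_value = q,
    significant = level >= min_level & rptm >= min_support_rptm & q < alpha,
    stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Combine per-sample site calls across a cohort
#'
#' Takes the union of site keys over samples and retains a site when it is
#' significant in at least `min_frac` of the samples, the threshold being
#' round-half-up of `min_frac * n_samples` (floored at 1 sample). At
#' `n_samples = 131` and `min_frac = 0.10` the threshold is 13 samples.
#'
#' @param calls named list of `site_calls`, one per sample; names are
#'   sample ids and must be unique.
#' @param n_samples cohort size (defaults to `length(calls)`).
#' @param min_frac retention fraction (default 0.10).
#' @return object of class `combined_sites`: `sites`, a data.frame (`key`,
#'   `locus`, `position`, `ref`, `alt`, `n_significant`, `retained`);
#'   `levels`, `support` and `significant`, site-by-sample matrices
#'   (level 0 / support 0 / FALSE where a sample has no candidate); and
#'   `threshold`, `n_samples`.
#' @export
combine_samples <- function(calls, n_samples = length(calls),
                            min_frac = 0.10) {
  if (length(calls) == 0L) .stopf("no samples supplied")
  ids <- names(calls)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    .stopf("calls must be a named list with unique sample ids")
  }
  if (n_samples < 1) .stopf("n_samples must be >= 1")
  threshold <- retention_threshold(n_samples, min_frac)

  allsites <- do.call(rbind, lapply(calls, function(x) {
    x[, c("key", "locus", "position", "ref", "alt"), drop = FALSE]
  }))
  sites <- allsites[!duplicated(allsites$key), , drop = FALSE]
  sites <- sites[order(sites$locus, sites$position, sites$alt), ,
                 drop = FALSE]
  rownames(sites) <- NULL

  nk <- nrow(sites)
  levels_m <- matrix(0, nk, length(ids), dimnames = list(sites$key, ids))
  support_m <- levels_m
  signif_m <- matrix(FALSE, nk, length(ids),
                     dimnames = list(sites$key, ids))
  for (s in ids) {
    cs <- calls[[s]]
    if (nrow(cs) == 0L) next
    ix <- match(cs$key, sites$key)
    levels_m[ix, s] <- cs$level
    support_m[ix, s] <- cs$support_rptm
    signif_m[ix, s] <- cs$significant
  }
  sites$n_significant <- as.integer(rowSums(signif_m))
  sites$retained <- sites$n_significant >= threshold
  structure(list(sites = sites, levels = levels_m, support = support_m,
                 significant = signif_m, threshold = threshold,
                 n_samples = n_samples),
            class = "combined_sites")
}

#' Retention threshold for the fraction-of-samples rule
#'
#' Round-half-up of `min_frac * n_samples`, never below one sample;
#' reproduces the printed 13-of-131 behaviour at the default fraction.
#'
#' @param n_samples cohort size.
#' @param min_frac required fraction of samples (default 0.10).
#' @return integer threshold in samples.
#' @examples
#' retention_threshold(131) # 13
#' @export
retention_threshold <- function(n_samples, min_frac = 0.10) {
  max(1L, as.integer(round_half_up(min_frac * n_samples)))
}

#' @export
print.combined_sites <- function(x, ...) {
  cat(sprintf(
    "combined_sites: %d sites x %d samples, %d retained (threshold %d)\n",
    nrow(x$sites), ncol(x$levels), sum(x$sites$retained), x$threshold))
  invisible(x)
}
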