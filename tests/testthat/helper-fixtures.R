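# Deterministic fixtures built in code, plus independent brute-force
# oracles for the statistical primitives.

# A hand-controlled single-hairpin reference: mature 5p at 6..27, known
# bases at the positions the classification fixture uses, 10-nt flanks.
# Positions:   3 (pre-mature 5'), 8 (decoy-substituted), 10 A, 12 C, 14 T,
#   16 A (SNP), 28 G / 29 C / 30 A (tail templates).
toy_ref <- function(with_decoy = FALSE) {
  ch <- mirledit:::with_seed(424242, sample(c("A", "C", "G", "T"), 60,
                                            replace = TRUE))
  ch[8] <- "T"; ch[10] <- "A"; ch[12] <- "C"; ch[14] <- "T"; ch[16] <- "A"
  ch[28] <- "G"; ch[29] <- "C"; ch[30] <- "A"
  hp <- paste(ch, collapse = "")
  decoys <- data.frame(id = character(0), sequence = character(0),
                       stringsAsFactors = FALSE)
  if (with_decoy) {
    win <- ch[6:29]
    win[3] <- "G"  # hairpin position 8 (T) substituted
    pad <- mirledit:::with_seed(424243,
                                sample(c("A", "C", "G", "T"), 40,
                                       replace = TRUE))
    decoys <- data.frame(
      id = "decoy-1",
      sequence = paste(c(pad[1:20], win, pad[21:40]), collapse = ""),
      stringsAsFactors = FALSE)
  }
  structure(
    list(hairpins = c(hp1 = hp),
         matures = data.frame(pre_mirna_id = "hp1", name = "hp1-5p",
                              arm = "5p", start = 6L, end = 27L,
                              stringsAsFactors = FALSE),
         flanks = data.frame(pre_mirna_id = "hp1",
                             flank5 = "TTTTTTTTTT",
                             flank3 = "ACGTTGCAAC",
                             stringsAsFactors = FALSE),
         decoys = decoys),
    class = "mirna_reference")
}

toy_hairpin_chars <- function(ref = toy_ref()) {
  strsplit(ref$hairpins[[1]], "", fixed = TRUE)[[1]]
}

# minimal unique-read table for the aligner
mk_reads <- function(sequences, raw_count = 1L) {
  data.frame(sequence = sequences,
             raw_count = rep_len(raw_count, length(sequences)),
             stringsAsFactors = FALSE)
}

# hand-made per-sample call table for combine/classify tests
mk_call <- function(key, level, support_rptm = 100, significant = TRUE) {
  f <- parse_site_key(key)
  out <- data.frame(key = key, locus = f$pre_mirna_id,
                    position = f$position, ref = f$ref, alt = f$alt,
                    coverage = 1000, level = level,
                    support_raw = level * 1000,
                    support_rptm = support_rptm,
                    p_value = 1e-10, q_value = 1e-9,
                    significant = significant, stringsAsFactors = FALSE)
  class(out) <- c("site_calls", "data.frame")
  out
}

# --- independent oracles -------------------------------------------------

# midranks computed from scratch (sort-based, no rank())
oracle_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman rho by explicit covariance of midranks
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# all permutations via Heap's algorithm (iterative)
oracle_perms <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  out[1L, ] <- a
  cnt <- 1L
  c_ <- rep(0L, n)
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      cnt <- cnt + 1L
      out[cnt, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# exact two-sided permutation p-value for Spearman
oracle_spearman_p <- function(x, y) {
  obs <- oracle_spearman_rho(x, y)
  P <- oracle_perms(length(y))
  rhos <- apply(P, 1L, function(ix) oracle_spearman_rho(x, y[ix]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Mann-Whitney U by pairwise comparison (greater + half ties)
oracle_u <- function(case, control) {
  sum(outer(case, control, ">")) + 0.5 * sum(outer(case, control, "=="))
}

# exact two-sided p by enumerating all C(n1+n2, n1) group labelings
oracle_mw_p <- function(case, control) {
  pooled <- c(case, control)
  n1 <- length(case)
  u_obs <- oracle_u(case, control)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2L, function(ix) {
    oracle_u(pooled[ix], pooled[-ix])
  })
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# BH by its sorted-minimum definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# binomial upper tail by direct pmf summation
oracle_binom_tail <- function(k, n, p0) {
  if (k > n) return(0)
  sum(stats::dbinom(k:n, n, p0))
}
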