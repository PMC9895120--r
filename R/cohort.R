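#' Benjamini-Hochberg step-up correction
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; NAs are allowed
#'   and stay NA (the family size is the number of non-NA p-values).
#' @return q-values, order-preserving and capped at 1.
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_correct <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    .stopf("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

# all permutations of 1..n as an (n!) x n matrix, lexicographic
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- nrow(sub)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[((i - 1L) * r + 1L):(i * r), ] <-
      cbind(i, matrix(rest[sub], r, n - 1L))
  }
  out
}

#' Spearman correlation of editing level with age
#'
#' Midrank (average-rank) Spearman coefficient. The p-value is exact by
#' full permutation enumeration for n <= 8 and uses the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on n - 2 degrees of freedom
#' otherwise. Zero variance in either vector yields an undefined result
#' (NA rho and p, `undefined = TRUE`) rather than an error.
#'
#' @param levels per-sample editing levels for one site.
#' @param ages matching ages (years), aligned by sample.
#' @return list with `rho`, `p_value`, `n`, `undefined`.
#' @examples
#' spearman_age(c(0.1, 0.4, 0.2, 0.3), c(10, 40, 20, 30))
#' @export
spearman_age <- function(levels, ages) {
  stopifnot(length(levels) == length(ages))
  ok <- !is.na(levels) & !is.na(ages)
  x <- levels[ok]
  y <- ages[ok]
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                undefined = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    P <- .permutations(n)
    # rho for each permutation of the age ranks, shared marginals
    s_obs <- sum(rx * ry)
    s_perm <- matrix(ry[P], nrow(P), n) %*% rx
    mxy <- n * mean(rx) * mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_perm <- (as.numeric(s_perm) - mxy) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1), n = n, undefined = FALSE)
}

# exact null distribution of the case rank sum (midranks, doubled to
# integers) by dynamic programming over the pooled multiset
.mw_exact_p <- function(r2, n1, w2) {
  N <- length(r2)
  S <- sum(r2)
  dp <- matrix(0, n1 + 1L, S + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(n1, N)  # fill top-down so each value is used once
    for (k in seq.int(kmax, 1L)) {
      if (v > 0) {
        dp[k + 1L, (v + 1L):(S + 1L)] <- dp[k + 1L, (v + 1L):(S + 1L)] +
          dp[k, 1L:(S + 1L - v)]
      } else {
        dp[k + 1L, ] <- dp[k + 1L, ] + dp[k, ]
      }
    }
  }
  dist <- dp[n1 + 1L, ]
  total <- sum(dist)
  lo <- sum(dist[seq_len(w2 + 1L)]) / total        # P(W <= w)
  hi <- sum(dist[(w2 + 1L):(S + 1L)]) / total      # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test for case-control differential editing
#'
#' U is computed from pooled midranks. The two-sided p-value is exact
#' (full null distribution of the rank sum over the pooled multiset) when
#' `n_case * n_control <= exact_limit`, and otherwise uses the normal
#' approximation with tie correction and continuity correction. Direction
#' compares group medians: `hyper` when the case median exceeds the
#' control median, `hypo` when it is lower, `tie` otherwise.
#'
#' @param case_levels,control_levels editing levels in the two groups.
#' @param exact_limit switch point for the exact p-value (default 400).
#' @return list with `u_statistic` (for the case group, in
#'   \[0, n_case * n_control\]), `p_value`, `direction`, `n_case`,
#'   `n_control`, `exact`.
#' @examples
#' mannwhitney_site(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
#' @export
mannwhitney_site <- function(case_levels, control_levels,
                             exact_limit = 400) {
  n1 <- length(case_levels)
  n2 <- length(control_levels)
  if (n1 == 0L || n2 == 0L) .stopf("both groups must be non-empty")
  pooled <- c(case_levels, control_levels)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2

  med1 <- stats::median(case_levels)
  med2 <- stats::median(control_levels)
  direction <- if (med1 > med2) "hyper" else if (med1 < med2) "hypo" else "tie"

  if (all(pooled == pooled[1])) {
    return(list(u_statistic = u, p_value = 1, direction = direction,
                n_case = n1, n_control = n2, exact = FALSE))
  }

  exact <- n1 * n2 <= exact_limit
  if (exact) {
    r2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * w))
    p <- .mw_exact_p(r2, n1, w2)
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u_statistic = u, p_value = p, direction = direction,
       n_case = n1, n_control = n2, exact = exact)
}

#' Cohort-level analysis of a site-by-sample editing-level matrix
#'
#' Runs, per site: (i) Spearman correlation of editing level with age
#' within each group, BH-corrected across sites separately per group, and
#' (ii) the Mann-Whitney case-control comparison, reporting both the
#' uncorrected p < 0.05 call and a BH-corrected call. When
#' `subgroup_max_age` is set, samples are first restricted to age strictly
#' below it (e.g. the under-10 subgroup).
#'
#' @param levels site-by-sample matrix of editing levels (rownames = site
#'   keys, colnames = sample ids).
#' @param design data.frame with `sample`, `group` ("case"/"control"),
#'   `age` (years), optionally `region`; must cover all matrix columns.
#' @param subgroup_max_age optional strict upper age bound in years.
#' @param alpha significance level (default 0.05).
#' @return object of class `cohort_results`: `correlation` (group, key,
#'   rho, p_value, q_value, n, significant), `comparison` (key,
#'   u_statistic, p_value, q_value, direction, significant = raw
#'   p < alpha, significant_bh), `n_case`, `n_control`.
#' @export
run_cohort_analysis <- function(levels, design, subgroup_max_age = NULL,
                                alpha = 0.05) {
  stopifnot(is.matrix(levels),
            all(c("sample", "group", "age") %in% names(design)))
  if (anyDuplicated(design$sample)) .stopf("duplicate sample ids in design")
  if (!all(colnames(levels) %in% design$sample)) {
    .stopf("design must cover every matrix column")
  }
  design <- design[match(colnames(levels), design$sample), , drop = FALSE]
  if (!all(design$group %in% c("case", "control"))) {
    .stopf("group must be 'case' or 'control'")
  }
  if (!is.null(subgroup_max_age)) {
    keep <- design$age < subgroup_max_age
    design <- design[keep, , drop = FALSE]
    levels <- levels[, keep, drop = FALSE]
  }
  n_case <- sum(design$group == "case")
  n_control <- sum(design$group == "control")
  if (n_case == 0L || n_control == 0L) {
    .stopf("subgroup filter left an empty group (case %d, control %d)",
           n_case, n_control)
  }
  keys <- rownames(levels)

  corr <- do.call(rbind, lapply(c("case", "control"), function(g) {
    sel <- design$group == g
    res <- lapply(keys, function(k) {
      spearman_age(levels[k, sel], design$age[sel])
    })
    data.frame(group = g, key = keys,
               rho = vapply(res, `[[`, numeric(1), "rho"),
               p_value = vapply(res, `[[`, numeric(1), "p_value"),
               n = vapply(res, `[[`, numeric(1), "n"),
               stringsAsFactors = FALSE)
  }))
  corr$q_value <- NA_real_
  for (g in c("case", "control")) {
    sel <- corr$group == g
    corr$q_value[sel] <- bh_correct(corr$p_value[sel])
  }
  corr$significant <- !is.na(corr$q_value) & corr$q_value < alpha

  cmp_res <- lapply(keys, function(k) {
    mannwhitney_site(levels[k, design$group == "case"],
                     levels[k, design$group == "control"])
  })
  comparison <- data.frame(
    key = keys,
    u_statistic = vapply(cmp_res, `[[`, numeric(1), "u_statistic"),
    p_value = vapply(cmp_res, `[[`, numeric(1), "p_value"),
    direction = vapply(cmp_res, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  comparison$q_value <- bh_correct(comparison$p_value)
  comparison$significant <- comparison$p_value < alpha
  comparison$significant_bh <- comparison$q_value < alpha
  rownames(corr) <- rownames(comparison) <- NULL
  structure(list(correlation = corr, comparison = comparison,
                 n_case = n_case, n_control = n_control),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort_results: %d sites, %d case / %d control samples\n",
    "  age-correlated (BH q < 0.05): %d\n",
    "  differential (raw p < 0.05): %d (%d hyper, %d hypo)\n"),
    nrow(x$comparison), x$n_case, x$n_control,
    sum(x$correlation$significant),
    sum(x$comparison$significant),
    sum(x$comparison$significant & x$comparison$direction == "hyper"),
    sum(x$comparison$significant & x$comparison$direction == "hypo")))
  invisible(x)
}
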