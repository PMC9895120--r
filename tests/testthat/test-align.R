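test_that("exact substrings align uniquely with no events", {
  ref <- toy_ref()
  hp <- ref$hairpins[[1]]
  rd <- substr(hp, 15, 36)
  al <- align_to_premirnas(mk_reads(rd), ref)
  expect_equal(nrow(al), 1)
  expect_equal(al$start, 15L)
  expect_equal(al$n_mism, 0L)
  expect_equal(al$tail_len, 0L)
  expect_true(al$perfect)
  expect_equal(al$weight, 1)
})

test_that("a single substitution is reported at its hairpin position", {
  ref <- toy_ref()
  ch <- toy_hairpin_chars(ref)
  rd <- ch[15:36]
  expect_equal(ch[23], "C")  # toy reference has C at 23
  rd[23 - 15 + 1] <- "A"
  al <- align_to_premirnas(mk_reads(paste(rd, collapse = "")), ref)
  expect_equal(nrow(al), 1)
  expect_equal(al$n_mism, 1L)
  expect_equal(al$mism, "23:C>a")
})

test_that("3' additions become position-coded events against the template", {
  ref <- toy_ref()
  ch <- toy_hairpin_chars(ref)
  # inside the hairpin: body end + disagreeing base at position 36
  rd <- c(ch[15:35], if (ch[36] == "T") "G" else "T")
  al <- align_to_premirnas(mk_reads(paste(rd, collapse = "")), ref)
  expect_equal(nrow(al), 1)
  ev <- mirledit:::.expand_events(al)
  expect_equal(ev$position, 36L)
  expect_equal(ev$ref, mirledit:::.rna_upper[[ch[36]]])
  # past the hairpin end: template comes from the 3' flank (A at flank[1])
  rd2 <- paste0(substr(ref$hairpins[[1]], 40, 60), "C")
  al2 <- align_to_premirnas(mk_reads(rd2), ref)
  expect_equal(al2$tail_len, 1L)
  expect_equal(al2$tail, "61:A>c")
})

test_that("the mismatch/tail split minimises mismatches + tail length", {
  ref <- toy_ref()
  hp <- ref$hairpins[[1]]
  ch <- toy_hairpin_chars(ref)
  # three trailing disagreements cannot all be body mismatches (max 2):
  # the optimal split keeps total mismatches + tail at 3, and the tie is
  # broken in favour of the shortest tail (2 mismatches + 1 tail base)
  rd <- paste0(substr(hp, 30, 57),
               paste(vapply(ch[58:60], function(x) {
                 setdiff(c("A", "C", "G", "T"), x)[1]
               }, ""), collapse = ""))
  al <- align_to_premirnas(mk_reads(rd), ref)
  expect_equal(nrow(al), 1)
  expect_equal(al$n_mism + al$tail_len, 3L)
  expect_equal(al$tail_len, 1L)
  # with only one trailing disagreement past the body, no mismatch is
  # cheaper than a tail, so it stays a body mismatch at max body length
  rd1 <- paste0(substr(hp, 30, 59),
                setdiff(c("A", "C", "G", "T"), ch[60])[1])
  al1 <- align_to_premirnas(mk_reads(rd1), ref)
  expect_equal(al1$n_mism, 1L)
  expect_equal(al1$tail_len, 0L)
})

test_that("alignment output is order-invariant across input read order", {
  ref <- toy_ref(with_decoy = TRUE)
  hp <- ref$hairpins[[1]]
  reads <- c(substr(hp, 6, 29), substr(hp, 10, 33), substr(hp, 20, 45))
  a <- align_to_premirnas(mk_reads(reads), ref)
  b <- align_to_premirnas(mk_reads(rev(reads)), ref)
  a$read_idx <- NULL
  b$read_idx <- NULL
  key <- function(x) do.call(paste, x[order(x$locus, x$start), ])
  expect_setequal(key(a), key(b))
})

test_that("cross-mapping correction reproduces proportional allocation", {
  ref <- toy_ref(with_decoy = TRUE)
  hp <- ref$hairpins[[1]]
  # decoy shares hairpin[6..29] with a substitution at hairpin position 8
  decoy_win <- ref$decoys$sequence[1]
  shared <- substr(decoy_win, 21, 44)  # the 24-nt window
  reads <- mk_reads(c(substr(hp, 6, 29), shared), raw_count = c(90L, 10L))
  al <- align_to_premirnas(reads, ref)
  # both reads place on both loci (one perfect, one 1-mismatch placement)
  expect_equal(nrow(al), 4)
  alw <- cross_map_correct(al, prior = c(hp1 = 90, `decoy-1` = 10))
  w1 <- alw$weight[alw$read_idx == 1 & alw$locus == "hp1"]
  expect_equal(w1, 90.5 / 101, tolerance = 1e-12)

  # symmetric masses stay at 1/2
  sym <- cross_map_correct(al, prior = c(hp1 = 5, `decoy-1` = 5))
  expect_true(all(abs(sym$weight - 0.5) < 1e-12))

  # uniquely placed reads keep weight 1
  uniq <- align_to_premirnas(mk_reads(substr(hp, 35, 58)), ref)
  expect_equal(cross_map_correct(uniq)$weight, 1)
})

test_that("read mass is conserved through cross-mapping correction", {
  ref <- toy_ref(with_decoy = TRUE)
  hp <- ref$hairpins[[1]]
  decoy_win <- substr(ref$decoys$sequence[1], 21, 44)
  reads <- mk_reads(c(substr(hp, 6, 29), decoy_win, substr(hp, 30, 55),
                      substr(hp, 8, 31)),
                    raw_count = c(17L, 40L, 9L, 3L))
  al <- align_to_premirnas(reads, ref)
  alw <- cross_map_correct(al)
  per_read <- tapply(alw$weight, alw$read_idx, sum)
  expect_true(all(abs(per_read - 1) < 1e-9))
  aligned_counts <- reads$raw_count[as.integer(names(per_read))]
  expect_lt(abs(sum(alw$raw_count * alw$weight) - sum(aligned_counts)),
            1e-9)
})

test_that("a decoy-perfect mismatch read loses the hairpin weight vote", {
  ref <- toy_ref(with_decoy = TRUE)
  hp <- ref$hairpins[[1]]
  decoy_win <- substr(ref$decoys$sequence[1], 21, 44)
  # decoy strongly expressed, hairpin weakly
  reads <- mk_reads(c(decoy_win, substr(hp, 6, 29)),
                    raw_count = c(90L, 10L))
  alw <- cross_map_correct(align_to_premirnas(reads, ref))
  w_hp <- alw$weight[alw$read_idx == 1 & alw$locus == "hp1"]
  expect_lt(w_hp, 0.5)
  frac <- site_cross_map_fraction(alw)
  ps <- frac[frac$locus == "hp1" & frac$position == 8, ]
  expect_equal(nrow(ps), 1)
  expect_gt(ps$cross_map_fraction, 0.5)
})
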