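test_that("generated references respect the contract", {
  ref <- generate_reference(1, c(60, 60), seed = 7)
  expect_s3_class(ref, "mirna_reference")
  expect_equal(nchar(ref$hairpins[[1]]), 60)
  expect_gte(nrow(ref$matures), 1)
  expect_true(all(ref$matures$start >= 1))
  expect_true(all(ref$matures$end <= 60))
  expect_true(all(ref$matures$end - ref$matures$start + 1 >= 20))
  expect_true(all(ref$matures$end - ref$matures$start + 1 <= 24))
  expect_false(any(grepl("[^ACGT]", ref$hairpins)))
  expect_false(any(grepl("[^ACGT]", ref$flanks$flank3)))
  expect_error(generate_reference(0, c(60, 60)), "n_hairpins")
  expect_error(generate_reference(1, c(40, 60)), "hairpin_len_range")
})

test_that("reference generation is deterministic under a fixed seed", {
  a <- generate_reference(20, c(60, 110), seed = 1)
  b <- generate_reference(20, c(60, 110), seed = 1)
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "refA")
  d2 <- file.path(tempdir(), "refB")
  write_reference(a, d1)
  write_reference(b, d2)
  fa1 <- readLines(file.path(d1, "hairpins.fa"))
  fa2 <- readLines(file.path(d2, "hairpins.fa"))
  expect_identical(fa1, fa2)
  g1 <- readLines(file.path(d1, "matures.gff3"))
  g2 <- readLines(file.path(d2, "matures.gff3"))
  # drop the date comment lines; features must be byte-identical
  expect_identical(grep("^#", g1, value = TRUE, invert = TRUE),
                   grep("^#", g2, value = TRUE, invert = TRUE))
  cc <- generate_reference(5, c(60, 110), seed = 2)
  aa <- generate_reference(5, c(60, 110), seed = 1)
  expect_false(identical(unname(aa$hairpins), unname(cc$hairpins)))
})

test_that("reference FASTA/GFF3 round-trips through read_reference", {
  ref <- generate_reference(4, c(70, 100), n_decoys = 1, seed = 11)
  d <- file.path(tempdir(), "refRT")
  p <- write_reference(ref, d)
  back <- read_reference(p["hairpins"], p["gff"], p["flanks"], p["decoys"])
  expect_identical(back$hairpins, ref$hairpins)
  expect_identical(back$matures[order(back$matures$name), ],
                   ref$matures[order(ref$matures$name), ],
                   ignore_attr = TRUE)
  expect_identical(back$flanks$flank3, ref$flanks$flank3)
  expect_identical(back$decoys$sequence, ref$decoys$sequence)
})

test_that("noiseless, edit-free reads are exact hairpin substrings", {
  ref <- generate_reference(2, c(70, 90), seed = 3)
  s <- simulate_sample(ref, NULL, depth_per_arm = 100,
                       error = error_model(30, per_base_error = 0),
                       adapter = "TGGAATTCTCGGGTGCCAAGG", seed = 4)
  inserts <- sub("TGGAATTCTCGGGTGCCAAGG.*$", "", s$sequences)
  hit <- vapply(inserts, function(x) {
    any(vapply(ref$hairpins, function(h) grepl(x, h, fixed = TRUE),
               logical(1)))
  }, logical(1))
  expect_true(all(hit))
})

test_that("a level-1 edit is carried by every covering read", {
  ref <- toy_ref()
  ed <- edit_spec("hp1", 10, "A", "g", 1.0, "central")
  s <- simulate_sample(ref, ed, depth_per_arm = 200,
                       error = error_model(30, per_base_error = 0),
                       seed = 5)
  expect_equal(s$truth$n_carrying, s$truth$n_covering)
  expect_gt(s$truth$n_covering, 0)
})

test_that("planted level is recovered within the binomial interval", {
  ref <- toy_ref()
  ed <- edit_spec("hp1", 14, "T", "g", 0.30, "central")
  s <- simulate_sample(ref, ed, depth_per_arm = 2000,
                       error = error_model(30, per_base_error = 0),
                       seed = 11)
  frac <- s$truth$n_carrying / s$truth$n_covering
  expect_lt(abs(frac - 0.30), 0.03)
})

test_that("simulation is byte-reproducible and validates its inputs", {
  ref <- toy_ref()
  ed <- edit_spec("hp1", 10, "A", "g", 0.5, "central")
  s1 <- simulate_sample(ref, ed, depth_per_arm = 50, seed = 9)
  s2 <- simulate_sample(ref, ed, depth_per_arm = 50, seed = 9)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1, f1)
  write_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_sample(ref, edit_spec("nope", 10, "A", "g", 0.5),
                               seed = 1), "unknown hairpin")
  expect_error(edit_spec("hp1", 10, "A", "g", 0.5, "snp"), "target_level")
  expect_error(edit_spec("hp1", 10, "A", "a", 0.5), "differ")
  expect_error(error_model(30, per_base_error = 0.3), "0.25")
  # ref_nt must match the template
  expect_error(simulate_sample(ref, edit_spec("hp1", 10, "C", "u", 0.5),
                               seed = 1), "template")
  # tail positions must lie past a mature 3' end
  expect_error(
    simulate_sample(ref, edit_spec("hp1", 10, "A", "g", 0.5, "tail"),
                    seed = 1), "past a mature")
})

test_that("FASTQ io round-trips sequences and qualities", {
  ref <- toy_ref()
  s <- simulate_sample(ref, NULL, depth_per_arm = 10, seed = 2)
  f <- tempfile(fileext = ".fastq")
  write_fastq(s, f)
  back <- read_fastq(f)
  expect_identical(back$sequences, s$sequences)
  expect_identical(back$qualities, s$qualities)
  expect_identical(back$names, s$names)
})
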