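#' The nine mutation/editing site categories
#'
#' @return character vector of the nine category labels.
#' @export
site_categories <- function() {
  c("3'-A", "3'-U", "3'-Other", "5'", "A-to-I", "C-to-U",
    "Other", "Pseudo", "SNP")
}

#' Parse a site key
#'
#' Splits `{hairpin}_{position}_{REF}_{alt}` into its fields; the hairpin
#' id may itself contain hyphens but not underscores in the final three
#' fields.
#'
#' @param key character vector of site keys.
#' @return data.frame with `pre_mirna_id`, `position`, `ref`, `alt`.
#' @examples
#' parse_site_key("hsa-mir-376a-1_9_A_g")
#' @export
parse_site_key <- function(key) {
  m <- regmatches(key,
                  regexec("^(.*)_(\\d+)_([ACGU])_([acgu])$", key))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) .stopf("unparseable site key: %s", key[which(bad)[1]])
  mm <- do.call(rbind, m)
  data.frame(pre_mirna_id = mm[, 2], position = as.integer(mm[, 3]),
             ref = mm[, 4], alt = mm[, 5], stringsAsFactors = FALSE)
}

# choose the mature arm a hairpin position belongs to: an arm containing
# the position, else the nearest arm
.pick_mature <- function(position, matures) {
  if (nrow(matures) == 0L) .stopf("hairpin has no mature annotation")
  inside <- matures$start <= position & position <= matures$end
  if (any(inside)) return(matures[which(inside)[1], , drop = FALSE])
  d <- pmin(abs(position - matures$start), abs(position - matures$end))
  matures[which.min(d), , drop = FALSE]
}

#' Classify one site into its category
#'
#' Decision order: (1) SNP if `is_snp`; (2) Pseudo if more than half of the
#' supporting-read mass is attributed to another locus by cross-mapping
#' correction; (3) positions past the mature 3' end (up to 5 nt) are 3'-A /
#' 3'-U / 3'-Other by the added nucleotide; (4) positions at or before the
#' mature 5' start are 5'; (5) central sites are A-to-I for A>g, C-to-U for
#' C>u, and Other for everything else.
#'
#' @param key site key `{hairpin}_{pos}_{REF}_{alt}`.
#' @param mature_start,mature_end 1-based mature interval on the hairpin.
#' @param cross_map_fraction fraction of the site's supporting-read mass
#'   mapped to other loci (default 0).
#' @param is_snp result of [match_snp()] (default FALSE).
#' @param max_three_prime how far past the mature 3' end a site may sit
#'   (default 5 nt); farther is a classification error.
#' @return a single category label (see [site_categories()]).
#' @examples
#' classify_site("hsa-mir-376a-1_9_A_g", mature_start = 6, mature_end = 27)
#' @export
classify_site <- function(key, mature_start, mature_end,
                          cross_map_fraction = 0, is_snp = FALSE,
                          max_three_prime = 5) {
  f <- parse_site_key(key)
  pos <- f$position
  if (pos > mature_end + max_three_prime) {
    .stopf("site %s lies %d nt past the mature 3' end (max %d)",
           key, pos - mature_end, max_three_prime)
  }
  if (is_snp) return("SNP")
  if (cross_map_fraction > 0.5) return("Pseudo")
  if (pos > mature_end) {
    return(switch(f$alt, a = "3'-A", u = "3'-U", "3'-Other"))
  }
  if (pos <= mature_start) return("5'")
  if (f$ref == "A" && f$alt == "g") return("A-to-I")
  if (f$ref == "C" && f$alt == "u") return("C-to-U")
  "Other"
}

#' Test whether a site is a known homozygous variant
#'
#' A site matches a variant record iff (i) its genomic position equals the
#' variant's, (ii) reference and alternative alleles agree (strand-aware:
#' alleles are complemented for hairpins on the minus strand), and
#' (iii) its editing level reaches 100% in at least one sample.
#'
#' @param key site key.
#' @param max_level maximum per-sample editing level observed for the site.
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (upper-case DNA) and optionally `id`.
#' @param hairpin_location list/row with `chrom`, `start` (genomic
#'   coordinate of hairpin position 1) and `strand` ("+" or "-"; on "-",
#'   hairpin position p maps to `start - (p - 1)`).
#' @return TRUE iff some variant matches position, alleles and the 100%
#'   level criterion.
#' @export
match_snp <- function(key, max_level, variants, hairpin_location) {
  if (is.null(variants) || nrow(variants) == 0L) return(FALSE)
  if (max_level < 1 - 1e-9) return(FALSE)
  f <- parse_site_key(key)
  ref_dna <- .dna_from_rna[[f$ref]]
  alt_dna <- .dna_from_rna[[f$alt]]
  if (identical(hairpin_location$strand, "-")) {
    gpos <- hairpin_location$start - (f$position - 1L)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_dna <- comp[[ref_dna]]
    alt_dna <- comp[[alt_dna]]
  } else {
    gpos <- hairpin_location$start + (f$position - 1L)
  }
  any(variants$chrom == hairpin_location$chrom &
        variants$pos == gpos &
        variants$ref == ref_dna &
        variants$alt == alt_dna)
}

#' Read a variant table from a VCF subset or TSV
#'
#' Accepts a (possibly header-bearing) VCF with at least CHROM, POS, ID,
#' REF, ALT columns, or a TSV with columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 50L)
  if (any(startsWith(first, "##")) || any(startsWith(first, "#CHROM"))) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                      id = parts[, 3], ref = parts[, 4], alt = parts[, 5],
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"id" %in% names(out)) out$id <- NA_character_
    out <- out[, c("chrom", "pos", "id", "ref", "alt")]
  }
  .check_nucleotides(out$ref, "variant ref allele")
  .check_nucleotides(out$alt, "variant alt allele")
  out
}

#' Flag a site as conserved across species
#'
#' A central editing site (A-to-I or C-to-U) is conserved when at least one
#' record from another species shows the same editing type at the same
#' mature-relative position, so that, counting the human site, at least two
#' species share it. Sites outside the mature miRNA are never conserved.
#'
#' @param category site category.
#' @param mature_rel_pos 1-based position within the mature miRNA (NA when
#'   the site lies outside the mature).
#' @param cross_sites data.frame with `species`, `position`
#'   (mature-relative) and `type` ("A-to-I" or "C-to-U").
#' @return TRUE/FALSE.
#' @export
flag_conserved <- function(category, mature_rel_pos, cross_sites) {
  if (is.null(cross_sites) || nrow(cross_sites) == 0L) return(FALSE)
  if (!category %in% c("A-to-I", "C-to-U")) return(FALSE)
  if (is.na(mature_rel_pos)) return(FALSE)
  any(cross_sites$position == mature_rel_pos &
        cross_sites$type == category)
}

#' Seed-region membership
#'
#' The seed region is mature positions 2-8 (the standard convention for
#' target recognition).
#'
#' @param position 1-based hairpin position.
#' @param mature_start mature 5' start on the hairpin.
#' @return TRUE iff `position - mature_start + 1` lies in \[2, 8\].
#' @examples
#' in_seed(9, 7) # relative position 3
#' @export
in_seed <- function(position, mature_start) {
  rel <- position - mature_start + 1L
  !is.na(rel) & rel >= 2L & rel <= 8L
}

#' Annotate combined sites with categories and flags
#'
#' Applies [classify_site()], [match_snp()], [flag_conserved()] and
#' [in_seed()] to every site of a combined cohort, resolving each site to
#' its nearest mature arm and recording the hairpin nucleotides flanking
#' it.
#'
#' @param combined a `combined_sites` object.
#' @param ref a `mirna_reference`.
#' @param variants optional variant table (see [read_variants()]).
#' @param hairpin_locations optional data.frame mapping `pre_mirna_id` to
#'   genomic `chrom`, `start`, `strand` (required for SNP matching).
#' @param cross_map data.frame from [site_cross_map_fraction()] (optional;
#'   sites absent from it get fraction 0).
#' @param cross_sites optional cross-species editing-site table (see
#'   [flag_conserved()]).
#' @param retained_only annotate only retained sites (default TRUE).
#' @return data.frame of class `site_annotations`: key, position fields,
#'   `category`, `is_snp`, `is_conserved`, `in_seed`, `mature_name`,
#'   `mature_rel_pos`, `context5`, `context3`.
#' @export
classify_sites <- function(combined, ref, variants = NULL,
                           hairpin_locations = NULL, cross_map = NULL,
                           cross_sites = NULL, retained_only = TRUE) {
  stopifnot(inherits(combined, "combined_sites"),
            inherits(ref, "mirna_reference"))
  sites <- combined$sites
  if (retained_only) sites <- sites[sites$retained, , drop = FALSE]
  n <- nrow(sites)
  cm_key <- character(0)
  cm_frac <- numeric(0)
  if (!is.null(cross_map) && nrow(cross_map) > 0L) {
    cm_key <- paste(cross_map$locus, cross_map$position, cross_map$ref,
                    cross_map$alt, sep = "_")
    cm_frac <- cross_map$cross_map_fraction
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sites[i, ]
    mats <- ref$matures[ref$matures$pre_mirna_id == s$locus, , drop = FALSE]
    mat <- .pick_mature(s$position, mats)
    frac <- 0
    j <- match(s$key, cm_key)
    if (!is.na(j)) frac <- cm_frac[j]
    max_level <- max(combined$levels[s$key, ])
    snp <- FALSE
    if (!is.null(variants) && !is.null(hairpin_locations)) {
      loc <- hairpin_locations[
        hairpin_locations$pre_mirna_id == s$locus, , drop = FALSE]
      if (nrow(loc) == 1L) {
        snp <- match_snp(s$key, max_level, variants,
                         list(chrom = loc$chrom, start = loc$start,
                              strand = loc$strand))
      }
    }
    category <- classify_site(s$key, mat$start, mat$end,
                              cross_map_fraction = frac, is_snp = snp)
    rel <- if (s$position >= mat$start && s$position <= mat$end) {
      s$position - mat$start + 1L
    } else {
      NA_integer_
    }
    conserved <- flag_conserved(category, rel, cross_sites)
    hp <- ref$hairpins[[s$locus]]
    ctx5 <- if (s$position >= 2L && s$position <= nchar(hp) + 1L) {
      substr(hp, s$position - 1L, s$position - 1L)
    } else {
      NA_character_
    }
    ctx3 <- if (s$position + 1L <= nchar(hp)) {
      substr(hp, s$position + 1L, s$position + 1L)
    } else {
      NA_character_
    }
    rows[[i]] <- data.frame(
      key = s$key, pre_mirna_id = s$locus, position = s$position,
      ref = s$ref, alt = s$alt, category = category,
      is_snp = snp, is_conserved = conserved,
      in_seed = !is.na(rel) && in_seed(s$position, mat$start),
      mature_name = mat$name, mature_rel_pos = rel,
      context5 = ctx5, context3 = ctx3,
      stringsAsFactors = FALSE)
  }
  out <- if (n == 0L) {
    data.frame(key = character(0), pre_mirna_id = character(0),
               position = integer(0), ref = character(0),
               alt = character(0), category = character(0),
               is_snp = logical(0), is_conserved = logical(0),
               in_seed = logical(0), mature_name = character(0),
               mature_rel_pos = integer(0), context5 = character(0),
               context3 = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("site_annotations", "data.frame")
  out
}

#' Neighbour-nucleotide preference of a site category
#'
#' Tabulates the hairpin nucleotides immediately 5' and 3' of each site of
#' a category (e.g. the U/G context of A-to-I sites or the C/C context of
#' C-to-U sites). Sites whose neighbours fall outside the hairpin are
#' excluded and counted.
#'
#' @param annotations a `site_annotations` data.frame.
#' @param category optional category filter (e.g. "A-to-I").
#' @return list with `counts` and `freqs` (4 x 2 matrices, rows A/C/G/U,
#'   columns `five_prime`/`three_prime`; frequency columns sum to 1) and
#'   `n_excluded`.
#' @export
context_preference <- function(annotations, category = NULL) {
  ann <- annotations
  if (!is.null(category)) {
    ann <- ann[ann$category == category, , drop = FALSE]
  }
  ok <- !is.na(ann$context5) & !is.na(ann$context3)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L) {
    warning(sprintf("%d site(s) excluded: neighbour outside the hairpin",
                    n_excluded), call. = FALSE)
  }
  ann <- ann[ok, , drop = FALSE]
  rna <- c("A", "C", "G", "U")
  counts <- matrix(0L, 4, 2, dimnames = list(rna,
                                             c("five_prime", "three_prime")))
  if (nrow(ann) > 0L) {
    t5 <- table(factor(.rna_upper[ann$context5], levels = rna))
    t3 <- table(factor(.rna_upper[ann$context3], levels = rna))
    counts[, 1] <- as.integer(t5)
    counts[, 2] <- as.integer(t3)
  }
  freqs <- counts
  storage.mode(freqs) <- "double"
  for (j in 1:2) {
    tot <- sum(counts[, j])
    freqs[, j] <- if (tot > 0) counts[, j] / tot else 0
  }
  list(counts = counts, freqs = freqs, n_excluded = n_excluded)
}

#' Category summary of annotated sites
#'
#' @param annotations a `site_annotations` data.frame.
#' @return data.frame with `category`, `n` and `percent` over all nine
#'   categories (zero rows included).
#' @export
category_summary <- function(annotations) {
  tab <- table(factor(annotations$category, levels = site_categories()))
  n <- as.integer(tab)
  data.frame(category = site_categories(), n = n,
             percent = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 9),
             stringsAsFactors = FALSE)
}
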