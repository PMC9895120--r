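#' @keywords internal
"_PACKAGE"

# DNA template letter -> RNA letters used in site keys (REF upper, alt lower)
.rna_upper <- c(A = "A", C = "C", G = "G", T = "U")
.rna_lower <- c(A = "a", C = "c", G = "g", T = "u")
# inverse: RNA (either case) -> DNA template letter
.dna_from_rna <- c(A = "A", C = "C", G = "G", U = "T", T = "T",
                   a = "A", c = "C", g = "G", u = "T", t = "T")

.NUCS <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' `round()` in R rounds half to even; the retention rule and the binomial
#' discretisation of weighted counts both use conventional round-half-up.
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Run an expression with a locally seeded RNG
#'
#' Saves and restores the caller's `.Random.seed` so that simulation helpers
#' are reproducible under a fixed seed without clobbering global RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_nucleotides <- function(x, what) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    .stopf("%s must contain only A/C/G/T (offending entry: %s)",
           what, x[which(bad)[1]])
  }
  invisible(x)
}
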