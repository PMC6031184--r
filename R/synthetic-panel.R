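#' Generate a synthetic amplicon panel
#'
#' Builds a panel of random amplicon sequences with a controlled CpG layout:
#' each amplicon carries exactly `n_cpg` reference CpGs at evenly spaced
#' interior positions (outside the primer footprints) and no other CpG
#' dinucleotide, while the remaining cytosines provide abundant CHH/CHG
#' context for conversion-rate estimation. Useful for tests and for
#' exercising the full simulate/trim/call/QC/titrate pipeline without any
#' genomic reference.
#'
#' @param n_amplicons Number of amplicons (each on its own contig, named
#'   `amp01`, `amp02`, ...).
#' @param amp_len Amplicon length (bp).
#' @param n_cpg Reference CpGs per amplicon.
#' @param fwd_primer_len,rev_primer_len Primer footprints (bp).
#' @param seed RNG seed.
#' @return A `tbs_panel`.
#' @examples
#' pnl <- synthetic_panel(2, amp_len = 250, n_cpg = 4, seed = 1)
#' @export
synthetic_panel <- function(n_amplicons = 7L, amp_len = 300L, n_cpg = 5L,
                            fwd_primer_len = 20L, rev_primer_len = 20L,
                            seed = NULL) {
  stopifnot(n_amplicons >= 0, amp_len >= 50, n_cpg >= 0)
  if (!is.null(seed)) set.seed(seed)
  amps <- vector("list", n_amplicons)
  for (i in seq_len(n_amplicons)) {
    b <- .random_cpg_free(amp_len)
    if (n_cpg > 0) {
      lo <- fwd_primer_len + 5L
      hi <- amp_len - rev_primer_len - 5L
      if (hi - lo < 3L * n_cpg)
        stop("amplicon too short to place ", n_cpg, " CpGs")
      at <- round(seq(lo, hi, length.out = n_cpg))
      b[at] <- "C"
      b[at + 1L] <- "G"
    }
    amps[[i]] <- amplicon(sprintf("amp%02d", i), paste(b, collapse = ""),
                          fwd_primer_len = fwd_primer_len,
                          rev_primer_len = rev_primer_len,
                          len_range = c(50L, 600L))
  }
  panel(amps)
}

# random sequence with no CpG dinucleotide (no G ever follows a C)
.random_cpg_free <- function(len) {
  bases <- c("A", "C", "G", "T")
  b <- sample(bases, len, replace = TRUE)
  for (i in which(b == "G")) {
    if (i > 1L && b[i - 1L] == "C")
      b[i] <- sample(c("A", "T"), 1L)
  }
  b
}
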