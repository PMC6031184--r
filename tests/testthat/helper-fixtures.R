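# small hand-built amplicons for exact-value tests (len_range relaxed so
# short fixtures load without warnings)
tiny_amplicon <- function(seq, name = "tiny", ...) {
  amplicon(name, seq, len_range = c(1L, 600L), ...)
}

# one-row SiteCall constructor for QC fixture tables
site_row <- function(sample, amplicon, pos, context, is_ref_cpg,
                     n_meth, n_unmeth) {
  data.frame(sample = sample, amplicon = amplicon, chrom = amplicon,
             pos = pos, offset = pos, strand = "top", context = context,
             is_reference_cpg = is_ref_cpg, n_meth = n_meth,
             n_unmeth = n_unmeth, coverage = n_meth + n_unmeth,
             meth_fraction = ifelse(n_meth + n_unmeth > 0,
                                    n_meth / (n_meth + n_unmeth), NA_real_),
             stringsAsFactors = FALSE)
}

as_calls <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("tbs_calls", "data.frame")
  df
}

# SAM-style record for constructed alignments (pure-M, 1-based pos)
rec_row <- function(qname, flag, rname, pos, seq, qual) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = 42L, cigar = paste0(nchar(seq), "M"), rnext = "=",
             pnext = 1L, tlen = 0L, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

# per-pair per-position coverage from a record table (for trim invariants)
pair_position_coverage <- function(rec) {
  rec <- rec[nchar(rec$seq) > 0L, , drop = FALSE]
  cov <- list()
  for (i in seq_len(nrow(rec))) {
    k <- paste(rec$qname[i], rec$rname[i])
    pos <- rec$pos[i] + seq_len(nchar(rec$seq[i])) - 1L
    cov[[k]] <- c(cov[[k]], pos)
  }
  vapply(cov, function(p) max(table(p)), numeric(1))
}

# exact hypergeometric moments of the subsampled methylation estimate
hyper_sd_oracle <- function(p, cov, N = 100000L, n_boot = 1000L) {
  m <- round(p * N)
  if (m == 0 || m == N) return(list(sd = 0, se = 0))
  k <- 0:cov
  pr <- stats::dhyper(k, m, N - m, cov)
  mu <- sum(k * pr) / cov
  s2 <- sum(((k / cov) - mu)^2 * pr)
  m4 <- sum(((k / cov) - mu)^4 * pr)
  se_sd <- sqrt((m4 - s2^2 * (n_boot - 3) / (n_boot - 1)) / n_boot) /
    (2 * sqrt(s2))
  list(sd = sqrt(s2), se = se_sd)
}
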