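#' Call per-site methylation from aligned bisulfite reads
#'
#' At every assayed-strand cytosine of the panel (primer-masked positions
#' excluded), read bases at or above `min_baseq` are counted: `C` as
#' methylated, `T` as unmethylated; other bases (sequencing error or SNP)
#' are ignored. Sites are reported with their reference context
#' (CpG/CHG/CHH). In addition, the analysis is not limited to reference
#' CpGs: any non-reference position where at least one read shows a `C`
#' immediately followed by `G` (a read-evidenced CpG, arising from PCR
#' artifacts or SNPs creating CpG sites) is emitted with
#' `is_reference_cpg = FALSE`; at such sites reads showing `CG` count as
#' methylated and reads showing `TG` as unmethylated, and the CpG
#' interpretation supersedes the position's reference context (so a
#' SNP-created CpG does not deflate the CHH conversion denominator).
#' Classification of these sites into artifact versus SNP-CpG is the job of
#' [detect_artifacts()].
#'
#' Input alignments are expected to be overlap-trimmed (see
#' [trim_overlap()]) so a read pair contributes each position at most once.
#'
#' @param x A `tbs_sim`, a records data.frame, or a SAM path.
#' @param pnl The `tbs_panel` the reads are aligned to.
#' @param min_baseq Minimum Phred base quality for a base to be counted.
#' @param sample Sample identifier; defaults to the simulation's sample for
#'   a `tbs_sim` input, otherwise `"sample1"`.
#' @return A `tbs_calls` data.frame keyed by (`sample`, `amplicon`, `pos`):
#'   columns `sample, amplicon, chrom, pos, offset, strand, context,
#'   is_reference_cpg, n_meth, n_unmeth, coverage, meth_fraction`.
#' @export
call_sites <- function(x, pnl, min_baseq = 20L, sample = NULL) {
  stopifnot(inherits(pnl, "tbs_panel"))
  if (inherits(x, "tbs_sim")) {
    if (is.null(sample)) sample <- x$sample
    rec <- x$records
  } else if (is.character(x) && length(x) == 1L) {
    rec <- read_sam(x)$records
  } else rec <- x
  if (is.null(sample)) sample <- "sample1"
  unknown <- setdiff(unique(rec$rname), names(pnl))
  if (length(unknown))
    stop("alignment(s) to unknown amplicon(s): ",
         paste(unknown, collapse = ", "))
  ctx <- enumerate_contexts(pnl)
  out <- lapply(pnl, function(amp)
    .call_amplicon(rec[rec$rname == amp$name, , drop = FALSE], amp,
                   ctx[ctx$amplicon == amp$name, , drop = FALSE],
                   min_baseq, sample))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("tbs_calls", "data.frame")
  out
}

.call_amplicon <- function(rec, amp, ctx, min_baseq, sample) {
  L <- nchar(amp$ref_seq)
  ctx <- ctx[!ctx$in_primer, , drop = FALSE]
  rec <- rec[nchar(rec$seq) > 0L, , drop = FALSE]  # fully trimmed mates
  simple <- grepl("^[0-9]+M$", rec$cigar)
  if (any(!simple))
    warning(sum(!simple), " read(s) with non-M CIGAR ignored in calling")
  rec <- rec[simple, , drop = FALSE]
  n <- nrow(rec)

  M <- matrix(NA_character_, n, L)
  Q <- matrix(NA_integer_, n, L)
  if (n) {
    lens <- nchar(rec$seq)
    rows <- rep.int(seq_len(n), lens)
    cols <- sequence(lens) + rep.int(rec$pos, lens) - 1L
    if (any(cols < 1L | cols > L))
      stop("read extends beyond amplicon '", amp$name, "'")
    ij <- cbind(rows, cols)
    M[ij] <- unlist(strsplit(rec$seq, ""), use.names = FALSE)
    Q[ij] <- utf8ToInt(paste(rec$qual, collapse = "")) - 33L
    M[!is.na(Q) & Q < min_baseq] <- NA_character_
  }
  isC <- !is.na(M) & M == "C"
  isT <- !is.na(M) & M == "T"
  isG <- !is.na(M) & M == "G"

  # read-evidenced CpGs at non-reference-CpG cytosine positions: a C
  # followed by G in a read marks a CpG absent from the reference (PCR
  # artifact, or a SNP in the following base creating a genuine CpG).
  # Only assayed-strand reference cytosines are candidates -- at a genomic
  # T a read C is indistinguishable from a conversion failure.
  novel <- NULL
  if (n && L >= 2L) {
    cg <- colSums(isC[, -L, drop = FALSE] & isG[, -1L, drop = FALSE])
    tg <- colSums(isT[, -L, drop = FALSE] & isG[, -1L, drop = FALSE])
    refcpg_off <- ctx$offset[ctx$is_reference_cpg]
    primer_off <- c(seq_len(amp$fwd_primer_len),
                    seq.int(L - amp$rev_primer_len + 1L, length.out = amp$rev_primer_len))
    ref_c_off <- which(strsplit(working_seq(amp), "")[[1]] == "C")
    cand <- intersect(which(cg >= 1L), ref_c_off)
    cand <- setdiff(cand, c(refcpg_off, primer_off))
    # the CpG interpretation supersedes the reference context at these
    # positions (keys stay unique; a SNP-CpG must not deflate the CHH
    # conversion denominator)
    ctx <- ctx[!ctx$offset %in% cand, , drop = FALSE]
    if (length(cand)) {
      novel <- data.frame(
        sample = sample, amplicon = amp$name, chrom = amp$chrom,
        pos = vapply(cand, function(o) genomic_pos(amp, o), integer(1)),
        offset = cand, strand = amp$strand, context = "CpG",
        is_reference_cpg = FALSE, n_meth = cg[cand], n_unmeth = tg[cand],
        stringsAsFactors = FALSE)
    }
  }

  # reference-context sites (minus any position reinterpreted as novel CpG)
  ref_sites <- if (nrow(ctx)) {
    nm <- colSums(isC[, ctx$offset, drop = FALSE])
    nu <- colSums(isT[, ctx$offset, drop = FALSE])
    data.frame(sample = sample, amplicon = amp$name, chrom = amp$chrom,
               pos = ctx$pos, offset = ctx$offset, strand = amp$strand,
               context = ctx$context, is_reference_cpg = ctx$is_reference_cpg,
               n_meth = nm, n_unmeth = nu, stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(ref_sites, novel)
  if (is.null(out)) return(NULL)
  out$coverage <- out$n_meth + out$n_unmeth
  out$meth_fraction <- ifelse(out$coverage > 0, out$n_meth / out$coverage,
                              NA_real_)
  out
}

#' Bisulfite conversion rate of a sample x amplicon unit
#'
#' The conversion rate is measured on CHH-context cytosines, which are
#' essentially unmethylated in human DNA: a converted CHH cytosine reads T,
#' so `rate = sum(n_unmeth) / sum(coverage)` over the unit's CHH sites.
#'
#' @param calls A `tbs_calls` table.
#' @param sample,amplicon Unit to evaluate.
#' @return The conversion rate (fraction in `[0,1]`).
#' @export
conversion_rate <- function(calls, sample, amplicon) {
  sub <- calls[calls$sample == sample & calls$amplicon == amplicon &
                 calls$context == "CHH", , drop = FALSE]
  tot <- sum(sub$coverage)
  if (!nrow(sub) || tot == 0L)
    stop("conversion rate undefined: no CHH coverage for sample '", sample,
         "' amplicon '", amplicon, "'")
  sum(sub$n_unmeth) / tot
}

# per-unit conversion rates (NA where no CHH coverage)
conversion_rates <- function(calls) {
  units <- unique(calls[, c("sample", "amplicon")])
  units$rate <- mapply(function(s, a) {
    sub <- calls[calls$sample == s & calls$amplicon == a &
                   calls$context == "CHH", ]
    tot <- sum(sub$coverage)
    if (!nrow(sub) || tot == 0L) NA_real_ else sum(sub$n_unmeth) / tot
  }, units$sample, units$amplicon)
  rownames(units) <- NULL
  units
}

#' Write a calls table as TSV
#'
#' Cytosine-report-style export: one row per (sample, amplicon, position)
#' with contexts, counts, coverage and methylation fraction.
#'
#' @param calls A `tbs_calls` table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a calls table written by [write_calls()]
#' @param path TSV path.
#' @return A `tbs_calls` data.frame.
#' @export
read_calls <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("tbs_calls", "data.frame")
  out
}
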