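#' Write aligned reads as SAM
#'
#' Emits a SAM file (with `@SQ` header lines generated from the panel or the
#' simulation's sequence table) from a record table as produced by
#' [simulate_sample()], [read_sam()] or [trim_overlap()].
#'
#' @param x A `tbs_sim`, or a records data.frame with columns
#'   `qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual`.
#' @param path Output SAM path.
#' @param pnl Panel (or a data.frame `name`,`length`) supplying reference
#'   names and lengths for the header; unnecessary for a `tbs_sim`.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(x, path, pnl = NULL) {
  if (inherits(x, "tbs_sim")) {
    si <- x$seqinfo
    rec <- x$records
  } else {
    rec <- x
    si <- if (inherits(pnl, "tbs_panel")) .panel_seqinfo(pnl) else pnl
    if (is.null(si)) stop("'pnl' is required to build the SAM header")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", si$name, si$length),
           "@PG\tID:hamtbs\tPN:hamtbs")
  body <- if (nrow(rec)) {
    # zero-length mates (fully trimmed) cannot be represented; drop them
    rec <- rec[nchar(rec$seq) > 0L, , drop = FALSE]
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq, rec$cigar,
            rec$rnext, rec$pnext, rec$tlen, rec$seq, rec$qual)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into a record table
#'
#' Converts the SAM to a temporary BAM with Rsamtools and scans it back,
#' returning the plain record table used throughout the package. Note BAM
#' conversion sorts by coordinate; pairing is re-established by read name
#' downstream.
#'
#' @param path SAM (or BAM) file.
#' @return A list with `records` (data.frame of SAM columns) and `seqinfo`
#'   (`name`, `length` per reference sequence).
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
  else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                        indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "isize", "seq", "qual"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  rec <- data.frame(
    qname = r$qname, flag = r$flag, rname = as.character(r$rname),
    pos = r$pos, mapq = r$mapq, cigar = r$cigar,
    rnext = ifelse(is.na(r$mrnm) | as.character(r$mrnm) == as.character(r$rname),
                   "=", as.character(r$mrnm)),
    pnext = ifelse(is.na(r$mpos), 0L, r$mpos),
    tlen = ifelse(is.na(r$isize), 0L, r$isize),
    seq = as.character(r$seq), qual = as.character(r$qual),
    stringsAsFactors = FALSE)
  rec$rnext[is.na(r$mrnm)] <- "*"
  list(records = rec,
       seqinfo = data.frame(name = names(hdr), length = unname(hdr),
                            stringsAsFactors = FALSE))
}

#' Write simulated reads as paired FASTQ
#'
#' First mates are written as sequenced (assayed strand); second mates are
#' reverse-complemented back to sequencing orientation, with reversed
#' quality strings.
#'
#' @param sim A `tbs_sim`.
#' @param r1_path,r2_path Output FASTQ paths (R2 ignored for single-end
#'   simulations).
#' @return Invisibly, the paths written.
#' @export
write_fastq <- function(sim, r1_path, r2_path = NULL) {
  stopifnot(inherits(sim, "tbs_sim"))
  rec <- sim$records
  is_r2 <- bitwAnd(rec$flag, 128L) > 0L
  .fq <- function(id, seq, qual, path) {
    writeLines(as.vector(rbind(paste0("@", id), seq, "+", qual)), path)
  }
  r1 <- rec[!is_r2, , drop = FALSE]
  .fq(r1$qname, r1$seq, r1$qual, r1_path)
  if (any(is_r2)) {
    if (is.null(r2_path)) stop("paired simulation needs r2_path")
    r2 <- rec[is_r2, , drop = FALSE]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(r2$seq)))
    rq <- vapply(r2$qual, function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    .fq(r2$qname, rc, rq, r2_path)
  }
  invisible(c(r1_path, r2_path))
}
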