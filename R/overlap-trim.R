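#' Trim overlapping ends of paired reads
#'
#' Amplicons shorter than twice the read length produce paired-end reads
#' whose inner ends overlap, so the same template base would be counted
#' twice — and read ends are the lowest-quality part of a read. For every
#' overlapping pair, the mate with the lower mean base quality over the
#' intersection has its overlapping bases hard-trimmed (on equal means the
#' second mate is trimmed), after which each reference position is covered
#' at most once per pair. Non-overlapping pairs and unpaired reads pass
#' through unchanged; pairs whose CIGAR is not pure `M` (indels/clips) are
#' passed through untrimmed with a warning.
#'
#' @param x A `tbs_sim`, a records data.frame, or a SAM path.
#' @param out Optional SAM path; when given, the trimmed records are also
#'   written there (requires `pnl` unless `x` is a `tbs_sim` or SAM path).
#' @param pnl Panel for the SAM header when writing from a bare data.frame.
#' @return The trimmed object, same class as the input records carrier
#'   (a `tbs_sim` keeps its truth/config; fully trimmed mates are kept as
#'   zero-length records and skipped by [write_sam()]).
#' @export
trim_overlap <- function(x, out = NULL, pnl = NULL) {
  si <- NULL
  if (inherits(x, "tbs_sim")) {
    rec <- x$records
    si <- x$seqinfo
  } else if (is.character(x) && length(x) == 1L) {
    rd <- read_sam(x)
    rec <- rd$records
    si <- rd$seqinfo
  } else rec <- x
  if (inherits(pnl, "tbs_panel")) si <- .panel_seqinfo(pnl)

  trimmed <- .trim_records(rec)
  res <- if (inherits(x, "tbs_sim")) {
    x$records <- trimmed
    x
  } else trimmed
  if (!is.null(out)) {
    if (is.null(si)) stop("need 'pnl' to write SAM output")
    write_sam(trimmed, out, pnl = si)
  }
  res
}

.trim_records <- function(rec) {
  if (!nrow(rec)) return(rec)
  paired <- bitwAnd(rec$flag, 1L) > 0L
  # pair rows by name: first mate then second
  o <- order(rec$qname, bitwAnd(rec$flag, 128L))
  rec <- rec[o, , drop = FALSE]
  idx <- which(paired[o])
  if (!length(idx)) return(rec)
  qn <- rec$qname[idx]
  runs <- rle(qn)
  if (any(runs$lengths != 2L)) {
    warning("unpaired or multiply-mapped paired reads left untrimmed")
    keep <- qn %in% runs$values[runs$lengths == 2L]
    idx <- idx[keep]
  }
  if (!length(idx)) return(rec)
  i1 <- idx[seq(1L, length(idx), by = 2L)]
  i2 <- idx[seq(2L, length(idx), by = 2L)]
  same_ref <- rec$rname[i1] == rec$rname[i2]
  if (any(!same_ref))
    stop("mates aligned to different amplicons: ",
         rec$qname[i1[!same_ref][1]])
  nonempty <- nchar(rec$seq[i1]) > 0L & nchar(rec$seq[i2]) > 0L
  simple <- grepl("^[0-9]+M$", rec$cigar[i1]) &
    grepl("^[0-9]+M$", rec$cigar[i2]) & nonempty
  if (any(!simple & nonempty))
    warning(sum(!simple & nonempty),
            " pair(s) with non-M CIGAR passed through untrimmed")
  i1 <- i1[simple]; i2 <- i2[simple]
  if (!length(i1)) return(rec)

  s1 <- rec$pos[i1]; e1 <- s1 + nchar(rec$seq[i1]) - 1L
  s2 <- rec$pos[i2]; e2 <- s2 + nchar(rec$seq[i2]) - 1L
  ov_s <- pmax(s1, s2); ov_e <- pmin(e1, e2)
  has_ov <- ov_s <= ov_e
  if (!any(has_ov)) return(rec)
  i1 <- i1[has_ov]; i2 <- i2[has_ov]
  s1 <- s1[has_ov]; e1 <- e1[has_ov]; s2 <- s2[has_ov]; e2 <- e2[has_ov]
  ov_s <- ov_s[has_ov]; ov_e <- ov_e[has_ov]

  mq <- function(i, s, qs, qe) {
    # mean Phred over overlap columns [qs, qe] of each read
    vapply(seq_along(i), function(j) {
      mean(utf8ToInt(substr(rec$qual[i[j]], qs[j], qe[j]))) - 33
    }, numeric(1))
  }
  m1 <- mq(i1, s1, ov_s - s1 + 1L, ov_e - s1 + 1L)
  m2 <- mq(i2, s2, ov_s - s2 + 1L, ov_e - s2 + 1L)
  victim_is_2 <- m2 <= m1
  vi <- ifelse(victim_is_2, i2, i1)
  vs <- ifelse(victim_is_2, s2, s1)
  ve <- ifelse(victim_is_2, e2, e1)

  # remainder of the victim after removing the intersection; when the other
  # mate's interval contains the victim's start, keep the right-hand piece,
  # otherwise the left-hand piece (the overlap always sits at one end for
  # same-length amplicon pairs)
  new_s <- ifelse(vs < ov_s, vs, ov_e + 1L)
  new_e <- ifelse(vs < ov_s, ov_s - 1L, ve)
  empty <- new_s > new_e
  keep_from <- ifelse(empty, 1L, new_s - vs + 1L)
  keep_to <- ifelse(empty, 0L, new_e - vs + 1L)
  rec$seq[vi] <- substr(rec$seq[vi], keep_from, keep_to)
  rec$qual[vi] <- substr(rec$qual[vi], keep_from, keep_to)
  rec$pos[vi] <- ifelse(empty, rec$pos[vi], new_s)
  rec$cigar[vi] <- ifelse(empty, "*", paste0(new_e - new_s + 1L, "M"))
  rec
}
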