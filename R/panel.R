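#' Define a single amplicon
#'
#' An amplicon is one targeted bisulfite PCR product: a genomic interval, the
#' bisulfite strand it assays, optional primer footprints at either end, and
#' its reference sequence.
#'
#' Internally all per-base logic runs on the *assayed strand*: for
#' `strand = "bottom"` the working sequence is the reverse complement of
#' `ref_seq`, so cytosine contexts, simulation and calling are always
#' top-strand-like. Offsets into the working sequence are mapped back to
#' 1-based genomic positions when results are reported.
#'
#' @param name Amplicon identifier (unique within a panel).
#' @param ref_seq Upper-case DNA string (`ACGTN`) of the genomic top strand
#'   over `[start, end)`.
#' @param chrom Contig name. Defaults to `name` (amplicon-as-contig
#'   references, the usual layout for targeted bisulfite panels).
#' @param start,end 0-based half-open genomic coordinates. Default `start = 0`.
#' @param strand Assayed bisulfite strand, `"top"` or `"bottom"`.
#' @param fwd_primer_len,rev_primer_len Primer footprint lengths in bases at
#'   the 5' and 3' end of the assayed strand. Bases under a primer footprint
#'   come from synthetic oligos, not template DNA, and are masked from
#'   methylation calling and conversion-rate denominators.
#' @param len_range Length range (bp) outside which a warning is raised;
#'   typical TBS amplicons run 200-450 bp.
#' @return An object of class `tbs_amplicon`.
#' @examples
#' amplicon("amp1", "ACGTACGTAC", len_range = c(1, 600))
#' @export
amplicon <- function(name, ref_seq, chrom = name, start = 0L,
                     end = start + nchar(ref_seq),
                     strand = c("top", "bottom"),
                     fwd_primer_len = 0L, rev_primer_len = 0L,
                     len_range = c(200L, 450L)) {
  strand <- match.arg(strand)
  ref_seq <- toupper(as.character(ref_seq))
  .check_dna(ref_seq)
  len <- nchar(ref_seq)
  start <- as.integer(start); end <- as.integer(end)
  if (end - start != len)
    stop("end - start (", end - start, ") does not match ref_seq length (",
         len, ") for amplicon '", name, "'")
  fwd_primer_len <- as.integer(fwd_primer_len)
  rev_primer_len <- as.integer(rev_primer_len)
  if (fwd_primer_len < 0 || rev_primer_len < 0)
    stop("primer lengths must be non-negative")
  if (fwd_primer_len + rev_primer_len >= len)
    stop("primer footprints cover the whole amplicon '", name, "'")
  if (len < len_range[1] || len > len_range[2])
    warning("amplicon '", name, "' length ", len,
            " bp is outside the typical range [", len_range[1], ", ",
            len_range[2], "] bp")
  structure(
    list(name = as.character(name), chrom = as.character(chrom),
         start = start, end = end, strand = strand,
         fwd_primer_len = fwd_primer_len, rev_primer_len = rev_primer_len,
         ref_seq = ref_seq),
    class = "tbs_amplicon")
}

#' Assemble amplicons into a panel
#'
#' @param ... `tbs_amplicon` objects, or a single list of them.
#' @return An object of class `tbs_panel`: a named list of amplicons.
#' @details Duplicate amplicon names are an error. Overlapping intervals on
#'   the same contig and strand raise a warning (double-assayed bases), never
#'   an error.
#' @export
panel <- function(...) {
  amps <- list(...)
  if (length(amps) == 1L && !inherits(amps[[1]], "tbs_amplicon"))
    amps <- amps[[1]]
  if (!all(vapply(amps, inherits, logical(1), "tbs_amplicon")))
    stop("all panel members must be tbs_amplicon objects")
  nm <- vapply(amps, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate amplicon name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(amps) <- nm
  # warn on same-strand overlap within a contig
  if (length(amps) > 1L) {
    key <- paste(vapply(amps, `[[`, character(1), "chrom"),
                 vapply(amps, `[[`, character(1), "strand"))
    for (k in unique(key[duplicated(key)])) {
      sub <- amps[key == k]
      s <- vapply(sub, `[[`, integer(1), "start")
      e <- vapply(sub, `[[`, integer(1), "end")
      o <- order(s)
      if (any(s[o][-1] < e[o][-length(e)]))
        warning("overlapping amplicons on ", k)
    }
  }
  structure(amps, class = "tbs_panel")
}

#' @export
print.tbs_panel <- function(x, ...) {
  cat("TBS amplicon panel:", length(x), "amplicon(s)\n")
  for (a in x)
    cat(sprintf("  %-12s %s:%d-%d (%s strand, %d bp, primers %d/%d)\n",
                a$name, a$chrom, a$start, a$end, a$strand,
                a$end - a$start, a$fwd_primer_len, a$rev_primer_len))
  invisible(x)
}

#' @export
print.tbs_amplicon <- function(x, ...) {
  cat(sprintf("amplicon %s  %s:%d-%d (%s strand, %d bp)\n",
              x$name, x$chrom, x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

# working (assayed-strand) sequence of an amplicon
working_seq <- function(amp) {
  if (amp$strand == "top") amp$ref_seq
  else as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp$ref_seq)))
}

# 1-based genomic position of a 1-based offset into the working sequence
genomic_pos <- function(amp, offset) {
  if (amp$strand == "top") amp$start + offset else amp$end - offset + 1L
}

.check_dna <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequence contains characters outside ACGTN")
  invisible(TRUE)
}

#' Load an amplicon panel from BED + FASTA
#'
#' @param bed_path BED file of amplicon intervals: 0-based half-open, columns
#'   `chrom start end [name score strand [fwd_primer_len rev_primer_len]]`.
#'   Strand `+` is the top bisulfite strand, `-` the bottom. Primer footprint
#'   lengths default to 0 when absent. When no name column is present the
#'   contig name is used.
#' @param fasta_path Reference FASTA containing every contig referenced by
#'   the BED.
#' @param len_range Passed to [amplicon()].
#' @return A [panel()] with `ref_seq` extracted from the FASTA per interval.
#' @export
load_panel <- function(bed_path, fasta_path, len_range = c(200L, 450L)) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  bed <- tryCatch(
    utils::read.table(bed_path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE,
                      col.names = paste0("V", 1:8), fill = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame()
      else stop(e)
    })
  if (nrow(bed) == 0L) return(panel(list()))
  amps <- vector("list", nrow(bed))
  for (i in seq_len(nrow(bed))) {
    chrom <- as.character(bed$V1[i])
    start <- as.integer(bed$V2[i]); end <- as.integer(bed$V3[i])
    nm <- if (!is.na(bed$V4[i]) && nzchar(bed$V4[i])) as.character(bed$V4[i]) else chrom
    strand <- if (!is.na(bed$V6[i]) && bed$V6[i] == "-") "bottom" else "top"
    fwd <- if (!is.na(bed$V7[i])) as.integer(bed$V7[i]) else 0L
    rev <- if (!is.na(bed$V8[i])) as.integer(bed$V8[i]) else 0L
    if (!chrom %in% names(ref))
      stop("contig '", chrom, "' not found in ", fasta_path)
    ctg <- ref[[chrom]]
    if (is.na(start) || is.na(end) || start < 0 || end > length(ctg) || start >= end)
      stop("interval ", chrom, ":", start, "-", end,
           " falls outside contig (length ", length(ctg), ")")
    amps[[i]] <- amplicon(nm, as.character(ctg[(start + 1L):end]),
                          chrom = chrom, start = start, end = end,
                          strand = strand, fwd_primer_len = fwd,
                          rev_primer_len = rev, len_range = len_range)
  }
  panel(amps)
}

#' Write a panel to BED + FASTA
#'
#' Inverse of [load_panel()]: one FASTA record per contig, one BED row per
#' amplicon (8 columns, primer footprints in columns 7-8).
#'
#' @param pnl A `tbs_panel`.
#' @param bed_path,fasta_path Output paths.
#' @return Invisibly, `pnl`.
#' @export
write_panel <- function(pnl, bed_path, fasta_path) {
  stopifnot(inherits(pnl, "tbs_panel"))
  chroms <- unique(vapply(pnl, `[[`, character(1), "chrom"))
  seqs <- character(0)
  for (ch in chroms) {
    sub <- pnl[vapply(pnl, function(a) a$chrom == ch, logical(1))]
    len <- max(vapply(sub, `[[`, integer(1), "end"))
    ctg <- rep("N", len)
    for (a in sub)
      ctg[(a$start + 1L):a$end] <- strsplit(a$ref_seq, "")[[1]]
    seqs[ch] <- paste(ctg, collapse = "")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  rows <- vapply(pnl, function(a)
    paste(a$chrom, a$start, a$end, a$name, 0L,
          if (a$strand == "top") "+" else "-",
          a$fwd_primer_len, a$rev_primer_len, sep = "\t"), character(1))
  writeLines(rows, bed_path)
  invisible(pnl)
}

#' Enumerate cytosine contexts on the assayed strand
#'
#' Every cytosine of each amplicon's assayed strand is classified by the two
#' following reference bases: `CG` is CpG, `C[ACT]G` is CHG and
#' `C[ACT][ACT]` is CHH. Cytosines too close to the amplicon end to be
#' classified (or followed by `N`) are skipped. CHH sites carry the
#' bisulfite-conversion signal: human CHH cytosines are essentially
#' unmethylated, so any retained `C` there marks a conversion failure.
#'
#' @param pnl A `tbs_panel`.
#' @return A data.frame with one row per classifiable cytosine: `amplicon`,
#'   `chrom`, `pos` (1-based genomic), `offset` (1-based within the assayed
#'   strand), `strand`, `context` (`CpG`/`CHG`/`CHH`), `in_primer`,
#'   `is_reference_cpg`.
#' @export
enumerate_contexts <- function(pnl) {
  stopifnot(inherits(pnl, "tbs_panel"))
  out <- lapply(pnl, function(amp) {
    ws <- working_seq(amp)
    .check_dna(ws)
    b <- strsplit(ws, "")[[1]]
    L <- length(b)
    cpos <- which(b == "C")
    if (!length(cpos))
      return(NULL)
    nxt <- ifelse(cpos < L, b[cpos + 1L], NA_character_)
    nxt2 <- ifelse(cpos < L - 1L, b[cpos + 2L], NA_character_)
    ctx <- rep(NA_character_, length(cpos))
    ctx[!is.na(nxt) & nxt == "G"] <- "CpG"
    hg <- !is.na(nxt) & nxt != "G" & nxt != "N" & !is.na(nxt2) & nxt2 == "G"
    hh <- !is.na(nxt) & nxt != "G" & nxt != "N" &
      !is.na(nxt2) & nxt2 != "G" & nxt2 != "N"
    ctx[hg] <- "CHG"
    ctx[hh] <- "CHH"
    keep <- !is.na(ctx)
    cpos <- cpos[keep]; ctx <- ctx[keep]
    if (!length(cpos)) return(NULL)
    L <- nchar(ws)
    in_primer <- cpos <= amp$fwd_primer_len | cpos > L - amp$rev_primer_len
    data.frame(amplicon = amp$name, chrom = amp$chrom,
               pos = vapply(cpos, function(o) genomic_pos(amp, o), integer(1)),
               offset = cpos, strand = amp$strand, context = ctx,
               in_primer = in_primer, is_reference_cpg = ctx == "CpG",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(amplicon = character(0), chrom = character(0),
                      pos = integer(0), offset = integer(0),
                      strand = character(0), context = character(0),
                      in_primer = logical(0), is_reference_cpg = logical(0))
  rownames(out) <- NULL
  out
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Bisulfite deaminates unmethylated cytosine to uracil (read as T);
#' 5-methylcytosine is protected. The two modes correspond to the two
#' idealised templates: fully unmethylated DNA (every C reads T) and
#' CpG-methylated DNA (only CpG cytosines remain C).
#'
#' @param seq DNA string (`ACGTN`).
#' @param mode `"unmethylated"` or `"cpg_methylated"`.
#' @return The converted sequence.
#' @examples
#' convert_reference("ACGTCAT", "unmethylated")   # "ATGTTAT"
#' convert_reference("ACGTCAT", "cpg_methylated") # "ACGTTAT"
#' @export
convert_reference <- function(seq, mode = c("unmethylated", "cpg_methylated")) {
  mode <- match.arg(mode)
  seq <- toupper(as.character(seq))
  .check_dna(seq)
  if (mode == "unmethylated") gsub("C", "T", seq, fixed = TRUE)
  else gsub("C(?!G)", "T", seq, perl = TRUE)
}

#' Panel capacity and sequencer loading arithmetic
#'
#' The loading factor of a multiplexed TBS run is `samples x amplicons`
#' pooled on one flow cell; in practice a MiSeq run stays robust up to a
#' loading factor of about 2500. The covered region is
#' `amplicons x mean amplicon length`.
#'
#' @param n_samples,n_amplicons Non-negative counts.
#' @param mean_len Mean amplicon length (bp).
#' @param max_loading Loading ceiling used for the feasibility flag.
#' @return An object of class `tbs_capacity` with fields `n_samples`,
#'   `n_amplicons`, `loading_factor`, `region_bp`, `feasible`.
#' @examples
#' capacity(96, 25, 400)  # loading 2400, ~10 kb covered, feasible
#' @export
capacity <- function(n_samples, n_amplicons, mean_len = 400, max_loading = 2500) {
  stopifnot(n_samples >= 0, n_amplicons >= 0, mean_len >= 0, max_loading >= 0)
  structure(
    list(n_samples = n_samples, n_amplicons = n_amplicons,
         mean_len = mean_len, max_loading = max_loading,
         loading_factor = n_samples * n_amplicons,
         region_bp = n_amplicons * mean_len,
         feasible = n_samples * n_amplicons <= max_loading),
    class = "tbs_capacity")
}

#' @export
print.tbs_capacity <- function(x, ...) {
  cat(sprintf(
    "TBS run capacity: %d sample(s) x %d amplicon(s)\n  loading factor %d (ceiling %d) -> %s\n  covered region %.0f bp (mean amplicon %.0f bp)\n",
    x$n_samples, x$n_amplicons, x$loading_factor, x$max_loading,
    if (x$feasible) "feasible" else "NOT feasible", x$region_bp, x$mean_len))
  invisible(x)
}
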