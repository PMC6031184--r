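#' Simulation settings for bisulfite amplicon reads
#'
#' @param depth Fragments (read pairs) per amplicon.
#' @param conversion Bisulfite conversion efficiency in `[0,1]`: the
#'   probability that an *unmethylated* cytosine is deaminated and reads T.
#'   Conversion failures are drawn i.i.d. per cytosine per fragment.
#' @param base_error Per-base sequencing error rate; an erroneous base is
#'   replaced by one of the three other bases uniformly.
#' @param read_length Read length in bp; paired reads start at both amplicon
#'   ends, so `2 * read_length > amplicon length` produces an overlap.
#' @param paired Emit read pairs (default) or single reads from the 5' end.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @param overlap_lowq Optional Phred score assigned to the second mate's
#'   bases inside the pair overlap (first mate keeps Q37); exercises
#'   quality-aware overlap trimming. `NULL` leaves all bases at Q37.
#' @param artifacts Optional PCR-artifact injection:
#'   `list(positions = data.frame(amplicon, pos), n_reads = <count>)`,
#'   applied by [inject_artifacts()] after regular fragments are drawn.
#' @return An object of class `tbs_simconfig`.
#' @export
sim_config <- function(depth = 2000L, conversion = 0.99, base_error = 0.001,
                       read_length = 250L, paired = TRUE, seed = NULL,
                       overlap_lowq = NULL, artifacts = NULL) {
  stopifnot(depth >= 0, conversion >= 0, conversion <= 1,
            base_error >= 0, base_error <= 1, read_length >= 1)
  structure(list(depth = as.integer(depth), conversion = conversion,
                 base_error = base_error, read_length = as.integer(read_length),
                 paired = isTRUE(paired), seed = seed,
                 overlap_lowq = overlap_lowq, artifacts = artifacts),
            class = "tbs_simconfig")
}

#' Uniform titration methylation profiles
#'
#' Builds one methylation profile per titration level, every reference CpG of
#' the panel set to the same fraction — the in-silico analogue of mixing
#' fully methylated and unmethylated control DNA to nominal levels
#' (classically 0/25/50/75/100%).
#'
#' @param pnl A `tbs_panel`.
#' @param levels Methylation fractions in `[0,1]`.
#' @return A named list of profiles (one per level); each profile is a
#'   data.frame `amplicon`, `pos`, `meth` covering every reference CpG.
#' @examples
#' # pnl <- synthetic_panel(2, seed = 1)
#' # mix_titration(pnl, c(0, .25, .5, .75, 1))
#' @export
mix_titration <- function(pnl, levels) {
  stopifnot(inherits(pnl, "tbs_panel"))
  if (length(levels) && (any(levels < 0) || any(levels > 1)))
    stop("titration levels must lie in [0, 1]")
  ctx <- enumerate_contexts(pnl)
  cpg <- ctx[ctx$is_reference_cpg, c("amplicon", "pos")]
  out <- lapply(levels, function(l) {
    p <- cpg
    p$meth <- l
    rownames(p) <- NULL
    p
  })
  names(out) <- as.character(levels)
  out
}

# map profile (amplicon, pos, meth) onto working-strand CpG offsets
.profile_offsets <- function(pnl, profile) {
  ctx <- enumerate_contexts(pnl)
  cpg <- ctx[ctx$is_reference_cpg, ]
  key <- paste(cpg$amplicon, cpg$pos)
  pkey <- paste(profile$amplicon, profile$pos)
  miss <- setdiff(key, pkey)
  if (length(miss))
    stop("methylation profile missing ", length(miss),
         " reference CpG(s), e.g. ", miss[1])
  cpg$meth <- profile$meth[match(key, pkey)]
  cpg
}

#' Simulate one bisulfite-sequenced sample over a panel
#'
#' Draws `depth` independent amplicon fragments per amplicon. Per fragment,
#' each reference-CpG cytosine is methylated with its profile probability;
#' methylated cytosines always read C, while unmethylated CpG cytosines and
#' every non-CpG cytosine convert to T with probability `conversion`
#' (remaining C models incomplete bisulfite conversion). Uniform base-call
#' errors are then applied. Paired reads of `read_length` bp cover the
#' fragment from both ends and are emitted as SAM-style records already
#' aligned to the assayed-strand amplicon reference with proper coordinates
#' and mate flags.
#'
#' @param pnl A `tbs_panel`.
#' @param profile Methylation profile data.frame (`amplicon`, `pos`, `meth`
#'   fractions in `[0,1]`) covering every reference CpG; see
#'   [mix_titration()].
#' @param config A [sim_config()].
#' @param sample Sample identifier stamped on reads and truth rows.
#' @return An object of class `tbs_sim`: list with `records` (aligned reads,
#'   SAM columns), `truth` (per-site true methylation, conversion efficiency
#'   and artifact flags) and `config`.
#' @export
simulate_sample <- function(pnl, profile, config = sim_config(),
                            sample = "sample1") {
  stopifnot(inherits(pnl, "tbs_panel"), inherits(config, "tbs_simconfig"))
  if (any(profile$meth < 0) || any(profile$meth > 1))
    stop("profile methylation fractions must lie in [0, 1]")
  if (!is.null(config$seed)) set.seed(config$seed)
  cpg <- .profile_offsets(pnl, profile)
  recs <- list(); truth <- list()
  for (amp in pnl) {
    res <- .sim_amplicon(amp, cpg[cpg$amplicon == amp$name, ], config, sample)
    recs[[amp$name]] <- res$records
    truth[[amp$name]] <- res$truth
  }
  sim <- structure(
    list(records = .rbind_records(recs), truth = do.call(rbind, truth),
         config = config, sample = sample,
         seqinfo = .panel_seqinfo(pnl)),
    class = "tbs_sim")
  rownames(sim$truth) <- NULL
  if (!is.null(config$artifacts))
    sim <- inject_artifacts(sim, pnl, config$artifacts$positions,
                            config$artifacts$n_reads)
  sim
}

.panel_seqinfo <- function(pnl) {
  data.frame(name = vapply(pnl, `[[`, character(1), "name"),
             length = vapply(pnl, function(a) nchar(a$ref_seq), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

.rbind_records <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(.empty_records())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

.empty_records <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), stringsAsFactors = FALSE)
}

.sim_amplicon <- function(amp, cpg, config, sample) {
  ws <- working_seq(amp)
  b <- strsplit(ws, "")[[1]]
  L <- length(b)
  D <- config$depth
  truth <- if (nrow(cpg)) {
    data.frame(sample = sample, amplicon = amp$name, pos = cpg$pos,
               offset = cpg$offset, context = "CpG", true_meth = cpg$meth,
               conversion = config$conversion, artifact = FALSE,
               stringsAsFactors = FALSE)
  } else NULL
  if (D == 0L) return(list(records = NULL, truth = truth))

  M <- matrix(b, nrow = D, ncol = L, byrow = TRUE)
  cpg_off <- cpg$offset
  if (length(cpg_off)) {
    k <- length(cpg_off)
    meth <- matrix(stats::rbinom(D * k, 1L, rep(cpg$meth, each = D)), D, k)
    conv <- matrix(stats::rbinom(D * k, 1L, config$conversion), D, k)
    M[, cpg_off] <- ifelse(meth == 1L, "C", ifelse(conv == 1L, "T", "C"))
  }
  other_c <- setdiff(which(b == "C"), cpg_off)
  if (length(other_c)) {
    k <- length(other_c)
    conv <- matrix(stats::rbinom(D * k, 1L, config$conversion), D, k)
    M[, other_c] <- ifelse(conv == 1L, "T", "C")
  }
  if (config$base_error > 0) {
    n_err <- stats::rbinom(1L, D * L, config$base_error)
    if (n_err > 0) {
      idx <- sample.int(D * L, n_err)
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3,
                    dimnames = list(NULL, c("A","C","G","T")))
      pick <- sample.int(3L, n_err, replace = TRUE)
      M[idx] <- alt[cbind(pick, match(M[idx], colnames(alt)))]
    }
  }
  frag <- do.call(paste0, asplit(M, 2))
  qn <- sprintf("%s:%s:%06d", sample, amp$name, seq_len(D))
  list(records = .fragment_records(frag, qn, amp$name, L, config),
       truth = truth)
}

# paired (or single) SAM records for full-length amplicon fragments
.fragment_records <- function(frag, qname, rname, L, config) {
  rl <- min(config$read_length, L)
  D <- length(frag)
  q37 <- strrep("F", rl)
  if (!config$paired) {
    return(data.frame(
      qname = qname, flag = 0L, rname = rname, pos = 1L, mapq = 42L,
      cigar = paste0(rl, "M"), rnext = "*", pnext = 0L, tlen = 0L,
      seq = substr(frag, 1L, rl), qual = q37, stringsAsFactors = FALSE))
  }
  s2 <- L - rl + 1L
  qual2 <- q37
  if (!is.null(config$overlap_lowq) && s2 <= rl) {
    ov_len <- rl - s2 + 1L
    qual2 <- paste0(strrep(rawToChar(as.raw(config$overlap_lowq + 33L)), ov_len),
                    strrep("F", rl - ov_len))
  }
  r1 <- data.frame(
    qname = qname, flag = 99L, rname = rname, pos = 1L, mapq = 42L,
    cigar = paste0(rl, "M"), rnext = "=", pnext = s2, tlen = L,
    seq = substr(frag, 1L, rl), qual = q37, stringsAsFactors = FALSE)
  r2 <- data.frame(
    qname = qname, flag = 147L, rname = rname, pos = s2, mapq = 42L,
    cigar = paste0(rl, "M"), rnext = "=", pnext = 1L, tlen = -L,
    seq = substr(frag, s2, L), qual = qual2, stringsAsFactors = FALSE)
  out <- rbind(r1, r2)
  out[as.vector(rbind(seq_len(D), seq_len(D) + D)), ]
}

#' Inject PCR-artifact reads presenting a spurious CpG
#'
#' Target PCR occasionally introduces errors that create CpG dinucleotides
#' absent from the reference. Such artifact reads show an unconverted C
#' followed by G at a position where the reference carries a non-CpG
#' cytosine, so the spurious site surfaces at very low coverage and extreme
#' (~0 or ~100%) methylation. This injector appends, per requested position,
#' `n_reads` fully converted full-length fragments differing from the
#' reference only by the artifact dinucleotide.
#'
#' @param sim A `tbs_sim` from [simulate_sample()].
#' @param pnl The panel the sample was simulated from.
#' @param positions data.frame (`amplicon`, `pos`) of non-CpG cytosine
#'   positions (1-based genomic) to corrupt; a reference CpG is an error.
#' @param n_reads Artifact fragments added per position.
#' @param seed Optional RNG seed (artifact construction is deterministic;
#'   kept for interface symmetry).
#' @return The `tbs_sim` with appended records and artifact-flagged truth
#'   rows.
#' @export
inject_artifacts <- function(sim, pnl, positions, n_reads, seed = NULL) {
  stopifnot(inherits(sim, "tbs_sim"), inherits(pnl, "tbs_panel"))
  if (!is.null(seed)) set.seed(seed)
  if (n_reads < 0) stop("n_reads must be non-negative")
  if (is.null(positions) || nrow(positions) == 0L || n_reads == 0L)
    return(sim)
  ctx <- enumerate_contexts(pnl)
  for (i in seq_len(nrow(positions))) {
    ampname <- positions$amplicon[i]
    pos <- positions$pos[i]
    amp <- pnl[[ampname]]
    if (is.null(amp)) stop("unknown amplicon '", ampname, "'")
    site <- ctx[ctx$amplicon == ampname & ctx$pos == pos, ]
    if (nrow(site) && any(site$is_reference_cpg))
      stop("position ", pos, " on '", ampname,
           "' is a reference CpG; artifacts must target non-CpG cytosines")
    ws <- working_seq(amp)
    off <- which(vapply(seq_len(nchar(ws)), function(o) genomic_pos(amp, o),
                        integer(1)) == pos)
    if (!length(off) || substr(ws, off, off) != "C")
      stop("position ", pos, " on '", ampname,
           "' is not a cytosine on the assayed strand")
    frag <- convert_reference(ws, "unmethylated")
    substr(frag, off, off) <- "C"
    if (off < nchar(ws)) substr(frag, off + 1L, off + 1L) <- "G"
    qn <- sprintf("%s:%s:art%d:%06d", sim$sample, ampname, pos,
                  seq_len(n_reads))
    rec <- .fragment_records(rep(frag, n_reads), qn, ampname, nchar(ws),
                             sim$config)
    sim$records <- rbind(sim$records, rec)
    sim$truth <- rbind(sim$truth, data.frame(
      sample = sim$sample, amplicon = ampname, pos = pos, offset = off,
      context = "CpG", true_meth = NA_real_,
      conversion = sim$config$conversion, artifact = TRUE,
      stringsAsFactors = FALSE))
  }
  rownames(sim$records) <- rownames(sim$truth) <- NULL
  sim
}

#' @export
print.tbs_sim <- function(x, ...) {
  cat(sprintf(
    "TBS simulated sample '%s': %d aligned read(s) over %d amplicon(s)\n",
    x$sample, nrow(x$records), nrow(x$seqinfo)))
  cat(sprintf(
    "  depth %d, conversion %.3f, base error %.2g, read length %d, %s\n",
    x$config$depth, x$config$conversion, x$config$base_error,
    x$config$read_length, if (x$config$paired) "paired" else "single-end"))
  n_art <- sum(x$truth$artifact)
  if (n_art) cat("  injected artifact site(s):", n_art, "\n")
  invisible(x)
}
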