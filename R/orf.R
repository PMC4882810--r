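# Open-reading-frame discovery and SNP coding-effect classification.
#
# ORFs are scanned in all three frames on both strands. An ORF runs from a
# start codon (ATG; or the contig edge, in which case it is 5'-partial) to
# a stop codon (TAA/TAG/TGA; or the edge, 3'-partial). Codons containing N
# never match start/stop and translate to X. aa_length excludes the stop.

.STOPS <- c("TAA", "TAG", "TGA")

# translate a vector of DNA codons with the standard code; N/other -> "X"
translate_codon <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# scan one strand orientation of a sequence; coords relative to that strand
.scan_strand <- function(s) {
  n <- nchar(s)
  acc <- vector("list", 3)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L  # 1-based nt
    codons <- substring(s, starts, starts + 2L)
    stop_idx <- which(codons %in% .STOPS)
    # segments between stops (each stop closes its segment)
    a <- c(1L, stop_idx + 1L)
    b <- c(stop_idx, n_codons)
    has_stop <- c(rep(TRUE, length(stop_idx)), FALSE)
    keep <- a <= b
    a <- a[keep]; b <- b[keep]; has_stop <- has_stop[keep]
    if (length(a) == 0) next
    # start codon: segment at the 5' edge starts there (partial unless it
    # opens with ATG); interior segments need the first ATG before their stop
    atg_idx <- which(codons == "ATG")
    j <- findInterval(a - 0.5, atg_idx) + 1L
    first_atg <- ifelse(j <= length(atg_idx), atg_idx[pmin(j, length(atg_idx))],
                        NA_integer_)
    start_codon <- ifelse(a == 1L, 1L, first_atg)
    valid <- a == 1L | (!is.na(first_atg) & first_atg <= b)
    partial5 <- a == 1L & codons[1] != "ATG"
    aa_len <- (b - start_codon + 1L) - as.integer(has_stop)
    valid <- valid & !is.na(aa_len) & aa_len >= 1L
    if (!any(valid)) next
    acc[[frame + 1]] <- data.frame(
      start = frame + (start_codon[valid] - 1L) * 3L,       # 0-based
      end = frame + b[valid] * 3L,                          # half-open
      frame = frame, partial5 = partial5[valid],
      partial3 = !has_stop[valid], aa_length = aa_len[valid]
    )
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0) return(NULL)
  do.call(rbind, acc)
}

#' Find open reading frames in a transcript
#'
#' Scans all three frames on both strands and returns maximal ORFs sorted
#' by amino-acid length (descending). Edge-to-edge candidates with neither
#' a start nor a stop codon (partial at both ends) are collapsed to the
#' single longest frame per strand, since the frame carries no signal.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param transcript_id Optional id attached to the result.
#' @param revcomp Optional precomputed reverse complement of `seq` (batch
#'   callers avoid one Biostrings round trip per transcript).
#' @return data.frame: transcript_id, start, end (0-based half-open,
#'   forward-strand coords; `end` includes the stop codon when present),
#'   strand, frame, partial5, partial3, aa_length. Empty for an empty
#'   sequence.
#' @export
find_orfs <- function(seq, transcript_id = NA_character_, revcomp = NULL) {
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      partial5 = logical(), partial3 = logical(),
                      aa_length = integer(), stringsAsFactors = FALSE)
  if (is.na(seq) || nchar(seq) == 0) return(empty)
  seq <- toupper(seq)
  n <- nchar(seq)

  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else (revcomp %||% .revcomp(seq))
    orfs <- .scan_strand(s)
    if (is.null(orfs)) next
    # collapse signal-free edge-to-edge ORFs to the best frame on this strand
    free <- orfs$partial5 & orfs$partial3
    if (sum(free) > 1) {
      keep_free <- which(free)[order(-orfs$aa_length[free],
                                     orfs$frame[free])][1]
      orfs <- orfs[!free | seq_len(nrow(orfs)) == keep_free, , drop = FALSE]
    }
    if (strand == "-") {
      fstart <- n - orfs$end
      fend <- n - orfs$start
      orfs$start <- fstart
      orfs$end <- fend
    }
    orfs$strand <- strand
    res[[length(res) + 1]] <- orfs
  }
  if (length(res) == 0) return(empty)
  orfs <- do.call(rbind, res)
  orfs$transcript_id <- transcript_id
  orfs <- orfs[order(-orfs$aa_length, orfs$partial5 | orfs$partial3,
                     orfs$strand != "+", orfs$start), ]
  rownames(orfs) <- NULL
  orfs[, c("transcript_id", "start", "end", "strand", "frame",
           "partial5", "partial3", "aa_length")]
}

#' Retain the single longest sufficiently long ORF per transcript
#'
#' Keeps, per transcript, the longest ORF with aa_length strictly greater
#' than `min_aa`. Ties break as: complete over partial, then plus strand,
#' then leftmost start. Transcripts with no qualifying ORF are dropped
#' (non-coding).
#'
#' @param orfs data.frame as returned by [find_orfs()] (possibly several
#'   transcripts row-bound).
#' @param min_aa Strict lower bound on amino-acid length (default 100).
#' @return One row per retained transcript.
#' @export
filter_orfs <- function(orfs, min_aa = 100) {
  ok <- orfs[orfs$aa_length > min_aa, , drop = FALSE]
  if (nrow(ok) == 0) return(ok)
  ord <- order(ok$transcript_id, -ok$aa_length, ok$partial5 | ok$partial3,
               ok$strand != "+", ok$start)
  ok <- ok[ord, , drop = FALSE]
  out <- ok[!duplicated(ok$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find and filter ORFs for a set of transcripts
#'
#' @param seqs Named character vector of transcript sequences.
#' @param min_aa Passed to [filter_orfs()].
#' @return data.frame of retained ORFs, one row per coding transcript.
#' @export
find_coding_orfs <- function(seqs, min_aa = 100) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(toupper(seqs)))))
  all <- do.call(rbind, lapply(seq_along(seqs), function(i)
    find_orfs(seqs[[i]], names(seqs)[i], revcomp = rc[[i]])))
  filter_orfs(all, min_aa = min_aa)
}

#' Classify the coding effect of a single-nucleotide substitution
#'
#' A site outside the retained ORF is noncoding. Inside, the affected codon
#' is read in the ORF's frame and strand, the substitution applied, and both
#' codons translated with the standard genetic code; the effect is
#' synonymous when the amino acid (stop included as a state) is unchanged.
#' Codons containing N are untranslatable (X): the effect is reported as
#' noncoding (indeterminate) and excluded from amino-acid-change counts.
#'
#' @param seq Transcript sequence (forward strand).
#' @param orf One row from [filter_orfs()] for this transcript.
#' @param pos 0-based position of the substitution on the forward strand.
#' @param ref,alt Forward-strand alleles; `seq[pos]` must equal `ref`.
#' @return list(effect, codon_ref, codon_alt, aa_ref, aa_alt); effect is
#'   one of "synonymous", "nonsynonymous", "noncoding".
#' @export
classify_variant_effect <- function(seq, orf, pos, ref, alt) {
  seq <- toupper(seq)
  if (pos < 0 || pos >= nchar(seq)) stop("pos out of bounds")
  if (substring(seq, pos + 1, pos + 1) != toupper(ref)) {
    stop("reference allele mismatch at pos ", pos)
  }
  if (toupper(ref) == toupper(alt)) stop("alt must differ from ref")
  ncd <- list(effect = "noncoding", codon_ref = NA_character_,
              codon_alt = NA_character_, aa_ref = NA_character_,
              aa_alt = NA_character_)
  if (is.null(orf) || pos < orf$start || pos >= orf$end) return(ncd)

  if (orf$strand == "+") {
    off <- pos - orf$start
    cstart <- orf$start + (off %/% 3) * 3
    codon_ref <- substring(seq, cstart + 1, cstart + 3)
    within <- off %% 3
    ref_c <- toupper(ref); alt_c <- toupper(alt)
  } else {
    cds <- .revcomp(substring(seq, orf$start + 1, orf$end))
    off <- (orf$end - 1) - pos
    cstart <- (off %/% 3) * 3
    codon_ref <- substring(cds, cstart + 1, cstart + 3)
    within <- off %% 3
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ref_c <- comp[[toupper(ref)]]; alt_c <- comp[[toupper(alt)]]
  }
  codon_alt <- codon_ref
  substring(codon_alt, within + 1, within + 1) <- alt_c
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  if (aa_ref == "X" || aa_alt == "X") {
    out <- ncd
    out$codon_ref <- codon_ref; out$codon_alt <- codon_alt
    out$aa_ref <- aa_ref; out$aa_alt <- aa_alt
    return(out)
  }
  list(effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
       codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Annotate every site of a variant table with its coding effect
#'
#' @param variants A [variant_table()].
#' @param orfs Retained ORFs from [find_coding_orfs()].
#' @param seqs Named transcript sequences.
#' @return Character vector of effects ("synonymous", "nonsynonymous",
#'   "noncoding"), one per site; sites on transcripts with no retained ORF
#'   are noncoding.
#' @export
annotate_variant_effects <- function(variants, orfs, seqs) {
  sites <- variants$sites
  n <- nrow(sites)
  if (n == 0) return(character(0))
  orf_ix <- match(sites$contig, orfs$transcript_id)
  effect <- rep("noncoding", n)

  # bulk path: sites inside a plus-strand ORF, handled with vectorized
  # substring arithmetic; the minus-strand / missing-ORF minority goes
  # through the scalar classifier
  start <- orfs$start[orf_ix]
  end <- orfs$end[orf_ix]
  plus <- !is.na(orf_ix) & orfs$strand[orf_ix] == "+" &
    sites$pos >= start & sites$pos < end
  if (any(plus)) {
    seqv <- unname(seqs[sites$contig[plus]])
    pos <- sites$pos[plus]
    if (!all(substring(seqv, pos + 1, pos + 1) == toupper(sites$ref[plus]))) {
      stop("reference allele mismatch")
    }
    off <- pos - start[plus]
    cstart <- start[plus] + (off %/% 3) * 3
    within <- off %% 3
    codon_ref <- substring(seqv, cstart + 1, cstart + 3)
    codon_alt <- paste0(substring(codon_ref, 1, within),
                        toupper(sites$alt[plus]),
                        substring(codon_ref, within + 2, 3))
    aa_ref <- translate_codon(codon_ref)
    aa_alt <- translate_codon(codon_alt)
    effect[plus] <- ifelse(aa_ref == "X" | aa_alt == "X", "noncoding",
                           ifelse(aa_ref == aa_alt, "synonymous",
                                  "nonsynonymous"))
  }
  minus <- !is.na(orf_ix) & orfs$strand[orf_ix] == "-"
  for (i in which(minus)) {
    effect[i] <- classify_variant_effect(seqs[[sites$contig[i]]],
                                         orfs[orf_ix[i], ], sites$pos[i],
                                         sites$ref[i], sites$alt[i])$effect
  }
  effect
}
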