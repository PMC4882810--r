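# Hemoglobin read accounting: flag dominant transcripts by expression share,
# deplete their reads, subsample to a fixed budget, and tabulate per-species
# totals. Blood libraries are dominated by a couple of hemoglobin subunit
# transcripts; the pipeline identifies them by pooled read share (~20%)
# rather than by homology.

#' Convert a count matrix to a long read-assignment table
#'
#' @param counts genes x samples matrix of read-pair counts.
#' @return data.frame with transcript_id, sample_id, read_pair_count.
#' @export
counts_to_assignment <- function(counts) {
  data.frame(
    transcript_id = rep(rownames(counts), ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    read_pair_count = as.vector(counts),
    stringsAsFactors = FALSE
  )
}

#' Flag transcripts holding a large share of the pooled library
#'
#' A transcript is flagged when its pooled (all-sample) read share is at
#' least `threshold`. The comparison is inclusive: share >= threshold.
#'
#' @param assign Read-assignment table (transcript_id, sample_id,
#'   read_pair_count).
#' @param threshold Fraction in (0, 1]; default 0.20.
#' @return Character vector of flagged transcript ids.
#' @export
flag_high_share_transcripts <- function(assign, threshold = 0.20) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  total <- sum(assign$read_pair_count)
  if (total <= 0) stop("total read count must be positive")
  per_tx <- tapply(assign$read_pair_count, assign$transcript_id, sum)
  names(per_tx)[per_tx / total >= threshold]
}

#' Remove all reads assigned to flagged transcripts
#'
#' @param assign Read-assignment table.
#' @param flagged Transcript ids to remove.
#' @return list(remaining = assignment table with flagged rows dropped,
#'   removed_count = total read pairs removed). Read pairs are conserved:
#'   removed_count + sum(remaining) equals the input total.
#' @export
deplete <- function(assign, flagged) {
  unknown <- setdiff(flagged, unique(assign$transcript_id))
  if (length(unknown) > 0) {
    warning("flagged ids not present in assignment: ",
            paste(unknown, collapse = ", "))
  }
  drop <- assign$transcript_id %in% flagged
  list(remaining = assign[!drop, , drop = FALSE],
       removed_count = sum(assign$read_pair_count[drop]))
}

#' Randomly subsample read pairs to a fixed budget
#'
#' Draws `target_pairs` reads without replacement from the pooled library —
#' a multivariate hypergeometric draw across (transcript, sample) cells —
#' so each cell's expected value is target * cell / total.
#'
#' @param assign Read-assignment table.
#' @param target_pairs Total read pairs to keep; must not exceed the
#'   available total.
#' @param seed Integer seed; the draw is seed-deterministic.
#' @return Assignment table with the same rows and subsampled counts.
#' @export
subsample <- function(assign, target_pairs, seed) {
  total <- sum(assign$read_pair_count)
  if (target_pairs > total) stop("target_pairs exceeds available reads")
  n <- assign$read_pair_count
  out <- numeric(length(n))
  withr::with_seed(seed, {
    remaining <- total
    k <- target_pairs
    for (i in seq_along(n)) {
      if (k == 0) break
      x <- stats::rhyper(1, n[i], remaining - n[i], k)
      out[i] <- x
      k <- k - x
      remaining <- remaining - n[i]
    }
  })
  assign$read_pair_count <- out
  assign
}

# round half away from zero, matching how percentages are usually printed
.round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read-accounting report (per-species totals and hemoglobin share)
#'
#' @param assign Read-assignment table.
#' @param flagged Hemoglobin transcript ids.
#' @param sheet Sample sheet providing `sample` and `species`.
#' @return list with per-species table (total, hemoglobin, post_depletion),
#'   overall totals and `hb_percent` (rounded to the nearest integer, ties
#'   away from zero).
#' @export
accounting_report <- function(assign, flagged, sheet) {
  missing <- setdiff(unique(assign$sample_id), sheet$sample)
  if (length(missing) > 0) {
    stop("samples missing from sheet: ", paste(missing, collapse = ", "))
  }
  species <- sheet$species[match(assign$sample_id, sheet$sample)]
  is_hb <- assign$transcript_id %in% flagged
  tot <- tapply(assign$read_pair_count, species, sum)
  hb <- tapply(assign$read_pair_count * is_hb, species, sum)
  per_species <- data.frame(
    species = names(tot),
    total_pairs = as.numeric(tot),
    hemoglobin_pairs = as.numeric(hb),
    post_depletion_pairs = as.numeric(tot - hb),
    stringsAsFactors = FALSE
  )
  total <- sum(per_species$total_pairs)
  hb_total <- sum(per_species$hemoglobin_pairs)
  list(
    per_species = per_species,
    total_pairs = total,
    hemoglobin_pairs = hb_total,
    post_depletion_pairs = total - hb_total,
    hb_percent = .round_away(100 * hb_total / total)
  )
}
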