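# SNP marker filtering and classification.
#
# The filtering cohort mirrors RNA-seq marker discovery against a single
# reference assembly: a hard per-bird coverage floor, a per-contig variant
# density cap (guards against paralog collapse), a within-species rule
# (some bird looks reference, some bird looks heterozygous or alt), and a
# species-diagnostic rule (alt near-fixed in one species, near-absent in
# the other). All frequencies are per-individual alt-read fractions.

#' Threshold set for SNP classification
#'
#' @param min_depth Minimum reads covering the site in every bird
#'   (inclusive; default 50).
#' @param max_density Maximum variants per bp of contig for within-species
#'   markers (strict; default 1/200).
#' @param low_freq A within-species marker needs at least one individual
#'   strictly below this alt frequency (expected reference genotype;
#'   default 0.05).
#' @param high_freq ... and at least one strictly above this (expected het
#'   or hom-alt genotype; default 0.35).
#' @param diag_high Species-diagnostic: every bird of the carrier species
#'   strictly above this (default 0.80).
#' @param diag_low ... and every bird of the other species strictly below
#'   this (default 0.05).
#' @return list of class `snp_thresholds`.
#' @export
snp_thresholds <- function(min_depth = 50, max_density = 1 / 200,
                           low_freq = 0.05, high_freq = 0.35,
                           diag_high = 0.80, diag_low = 0.05) {
  stopifnot(min_depth >= 1, max_density > 0,
            low_freq >= 0, low_freq < high_freq, high_freq <= 1,
            diag_low >= 0, diag_low < diag_high, diag_high <= 1)
  structure(list(min_depth = min_depth, max_density = max_density,
                 low_freq = low_freq, high_freq = high_freq,
                 diag_high = diag_high, diag_low = diag_low),
            class = "snp_thresholds")
}

#' Per-sample alt-allele frequency at a site
#'
#' @param depth,alt_depth Read counts; `alt_depth <= depth`. Vectorized.
#' @return alt_depth / depth; NA (missing) where depth is 0.
#' @export
site_frequency <- function(depth, alt_depth) {
  if (any(alt_depth > depth)) stop("alt_depth exceeds depth")
  ifelse(depth == 0, NA_real_, alt_depth / depth)
}

#' Coverage filter: every bird covered to at least min_depth reads
#'
#' @param depths Per-individual depths at one site.
#' @param thr A [snp_thresholds()].
#' @return TRUE iff all depths >= thr$min_depth (inclusive).
#' @export
coverage_filter <- function(depths, thr) {
  all(depths >= thr$min_depth)
}

#' Density filter: contig variant density strictly below the cap
#'
#' @param contig_len Contig length in bp (> 0).
#' @param n_variants Variants observed on the contig (pre-coverage-filter).
#' @param thr A [snp_thresholds()].
#' @return TRUE iff n_variants / contig_len < thr$max_density (strict).
#' @export
density_filter <- function(contig_len, n_variants, thr) {
  if (any(contig_len <= 0)) stop("contig_len must be positive")
  n_variants / contig_len < thr$max_density
}

#' Within-species marker rule
#'
#' At least one individual strictly below `low_freq` (reference-like) and
#' at least one strictly above `high_freq` (het/hom-alt-like).
#'
#' @param freqs Per-individual frequencies for one species; NAs (no
#'   coverage) are ignored, but at least two defined values are required.
#' @param thr A [snp_thresholds()].
#' @export
within_species_marker <- function(freqs, thr) {
  f <- freqs[!is.na(freqs)]
  if (length(f) < 2) return(FALSE)
  min(f) < thr$low_freq && max(f) > thr$high_freq
}

#' Species-diagnostic marker rule
#'
#' Diagnostic for species A when every A individual is strictly above
#' `diag_high` and every B individual strictly below `diag_low` (per-bird
#' mode, the default), or when the pooled-read frequencies satisfy the same
#' bounds (`mode = "pooled"`). Symmetric for B.
#'
#' @param freqs_a,freqs_b Per-individual frequencies by species (per-bird
#'   mode) — any NA (uncovered bird) disqualifies the site.
#' @param thr A [snp_thresholds()].
#' @param mode "per_bird" or "pooled".
#' @param pooled_a,pooled_b (pooled mode) length-2 numeric c(alt, depth)
#'   per species.
#' @return "A", "B", or NA_character_.
#' @export
species_diagnostic <- function(freqs_a, freqs_b, thr, mode = "per_bird",
                               pooled_a = NULL, pooled_b = NULL) {
  mode <- match.arg(mode, c("per_bird", "pooled"))
  if (mode == "pooled") {
    fa <- site_frequency(pooled_a[2], pooled_a[1])
    fb <- site_frequency(pooled_b[2], pooled_b[1])
    if (is.na(fa) || is.na(fb)) return(NA_character_)
    if (fa > thr$diag_high && fb < thr$diag_low) return("A")
    if (fb > thr$diag_high && fa < thr$diag_low) return("B")
    return(NA_character_)
  }
  if (anyNA(freqs_a) || anyNA(freqs_b) ||
      length(freqs_a) == 0 || length(freqs_b) == 0) {
    return(NA_character_)
  }
  if (all(freqs_a > thr$diag_high) && all(freqs_b < thr$diag_low)) return("A")
  if (all(freqs_b > thr$diag_high) && all(freqs_a < thr$diag_low)) return("B")
  NA_character_
}

#' Classify every site of a variant table
#'
#' Applies the coverage, density, within-species and species-diagnostic
#' rules. The coverage cohort is all samples; the density cap applies to
#' within-species markers only; diagnostic calls require the coverage
#' filter but not the density cap.
#'
#' @param variants A [variant_table()].
#' @param sheet Sample sheet with `sample` and `species` (two species).
#' @param thr A [snp_thresholds()].
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param effects Optional per-site effect vector from
#'   [annotate_variant_effects()].
#' @param diag_mode Passed to [species_diagnostic()].
#' @return data.frame, one row per site: contig, pos, coverage_pass,
#'   density_pass, within_<species> flags, diagnostic (species label or
#'   NA), effect.
#' @export
classify_sites <- function(variants, sheet, thr, contig_lengths,
                           effects = NULL, diag_mode = "per_bird") {
  sp <- sort(unique(sheet$species))
  stopifnot(length(sp) == 2)
  diag_mode <- match.arg(diag_mode, c("per_bird", "pooled"))
  samp <- colnames(variants$dp)
  species_of <- sheet$species[match(samp, sheet$sample)]
  ia <- which(species_of == sp[1])
  ib <- which(species_of == sp[2])

  n <- nrow(variants$sites)
  freq <- site_frequency(variants$dp, variants$ad)
  coverage_pass <- rowSums(variants$dp >= thr$min_depth) == ncol(variants$dp)

  n_per_contig <- table(variants$sites$contig)
  lens <- contig_lengths[variants$sites$contig]
  density_pass <- density_filter(
    as.numeric(lens),
    as.numeric(n_per_contig[variants$sites$contig]), thr
  )

  # vectorized equivalents of species_diagnostic / within_species_marker;
  # coverage-passing sites have no missing frequencies (depth >= min_depth)
  fa <- freq[, ia, drop = FALSE]
  fb <- freq[, ib, drop = FALSE]
  if (diag_mode == "per_bird") {
    a_fixed <- rowSums(fa > thr$diag_high) == length(ia)
    a_absent <- rowSums(fa < thr$diag_low) == length(ia)
    b_fixed <- rowSums(fb > thr$diag_high) == length(ib)
    b_absent <- rowSums(fb < thr$diag_low) == length(ib)
  } else {
    pa <- rowSums(variants$ad[, ia, drop = FALSE]) /
      rowSums(variants$dp[, ia, drop = FALSE])
    pb <- rowSums(variants$ad[, ib, drop = FALSE]) /
      rowSums(variants$dp[, ib, drop = FALSE])
    a_fixed <- pa > thr$diag_high; a_absent <- pa < thr$diag_low
    b_fixed <- pb > thr$diag_high; b_absent <- pb < thr$diag_low
  }
  diagnostic <- rep(NA_character_, n)
  diagnostic[coverage_pass & a_fixed & b_absent] <- sp[1]
  diagnostic[coverage_pass & b_fixed & a_absent] <- sp[2]

  row_rng <- function(f) {
    list(min = do.call(pmin, c(as.data.frame(f), na.rm = TRUE)),
         max = do.call(pmax, c(as.data.frame(f), na.rm = TRUE)))
  }
  ra <- row_rng(fa); rb <- row_rng(fb)
  eligible <- coverage_pass & density_pass & is.na(diagnostic)
  within_a <- eligible & ra$min < thr$low_freq & ra$max > thr$high_freq
  within_b <- eligible & rb$min < thr$low_freq & rb$max > thr$high_freq
  within_a[is.na(within_a)] <- FALSE
  within_b[is.na(within_b)] <- FALSE

  out <- data.frame(
    contig = variants$sites$contig, pos = variants$sites$pos,
    coverage_pass = coverage_pass, density_pass = as.logical(density_pass),
    within_a = within_a, within_b = within_b, diagnostic = diagnostic,
    effect = if (is.null(effects)) NA_character_ else effects,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "within_a"] <- paste0("within_", sp[1])
  names(out)[names(out) == "within_b"] <- paste0("within_", sp[2])
  attr(out, "species") <- sp
  out
}

#' Summarize site classifications into marker-table counts
#'
#' One row per category — all coverage-passing SNPs seen in each species,
#' species-diagnostic SNPs, and within-species markers per species — with
#' the number predicted to change an amino acid alongside.
#'
#' @param cls Output of [classify_sites()].
#' @param variants,sheet Optional; when both are given, the per-species
#'   "all SNPs" rows (any alt read in that species, coverage-passing) are
#'   included.
#' @return data.frame: category, n, n_aa_changing.
#' @export
summarize_snp_classes <- function(cls, variants = NULL, sheet = NULL) {
  sp <- attr(cls, "species")
  aa <- !is.na(cls$effect) & cls$effect == "nonsynonymous"
  rows <- list()
  if (!is.null(variants) && !is.null(sheet)) {
    for (s in sp) {
      idx <- which(sheet$species[match(colnames(variants$ad),
                                       sheet$sample)] == s)
      seen <- rowSums(variants$ad[, idx, drop = FALSE]) > 0 &
        cls$coverage_pass
      rows[[paste0("all_", s)]] <- c(sum(seen), sum(seen & aa))
    }
  }
  diag <- !is.na(cls$diagnostic)
  rows[["diagnostic"]] <- c(sum(diag), sum(diag & aa))
  for (s in sp) {
    w <- cls[[paste0("within_", s)]]
    rows[[paste0("within_", s)]] <- c(sum(w), sum(w & aa))
  }
  data.frame(category = names(rows),
             n = vapply(rows, `[`, numeric(1), 1),
             n_aa_changing = vapply(rows, `[`, numeric(1), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
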