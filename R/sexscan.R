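# Z-chromosome scan: synteny ordering, per-gene male:female expression
# ratios and per-sex heterozygous SNP densities, a ten-gene moving average,
# non-PAR region calling, and a least-squares changepoint estimate of the
# PAR boundary. In a ZW system without dosage compensation, non-PAR Z genes
# run at ~2x in males (log2 M:F ~ 1) and females are hemizygous there, so
# female heterozygous SNP density collapses; PAR genes show neither signal.

#' Order genes along a chromosome by synteny position
#'
#' @param genes Character vector of gene ids to place.
#' @param map Synteny map with gene_id, chrom, position.
#' @param chrom Target chromosome (default "Z").
#' @return list(genes = ordered ids on `chrom`, excluded = ids without a
#'   mapping on `chrom`). Ties in position keep stable input order.
#' @export
order_by_synteny <- function(genes, map, chrom = "Z") {
  dup <- map$gene_id[duplicated(map$gene_id)]
  conflicting <- unique(map$gene_id[map$gene_id %in% dup])
  if (length(conflicting) > 0) {
    conf <- vapply(conflicting, function(g) {
      sub <- map[map$gene_id == g, ]
      nrow(unique(sub[, c("chrom", "position")])) > 1
    }, logical(1))
    if (any(conf)) {
      stop("conflicting positions for: ",
           paste(conflicting[conf], collapse = ", "))
    }
  }
  ix <- match(genes, map$gene_id)
  on_chrom <- !is.na(ix) & map$chrom[ix] == chrom
  ordered <- genes[on_chrom][order(map$position[ix[on_chrom]])]
  list(genes = ordered, excluded = genes[!on_chrom])
}

#' Per-gene log2 male:female expression ratio
#'
#' @param norm Normalized genes x samples matrix.
#' @param sheet Sample sheet with `sample` and `sex` ("M"/"F"); both sexes
#'   required.
#' @return Named numeric: log2((mean over males + 0.5) /
#'   (mean over females + 0.5)).
#' @export
mf_ratio <- function(norm, sheet) {
  sex <- sheet$sex[match(colnames(norm), sheet$sample)]
  if (!all(c("M", "F") %in% sex)) stop("both sexes required")
  m <- rowMeans(norm[, sex == "M", drop = FALSE])
  f <- rowMeans(norm[, sex == "F", drop = FALSE])
  log2((m + 0.5) / (f + 0.5))
}

#' Per-gene, per-sex heterozygous SNP density
#'
#' A sample is heterozygous at a site when its alt frequency falls in
#' `[het_lo, het_hi]` with depth >= `min_depth`. Density is heterozygous
#' sample-site events per kb of transcript per individual, averaged within
#' sex.
#'
#' @param variants A [variant_table()].
#' @param gene_lengths Named vector of transcript lengths (bp, > 0).
#' @param sheet Sample sheet with `sample` and `sex`.
#' @param het_lo,het_hi Heterozygous allele-frequency band (default 0.2,
#'   0.8, inclusive).
#' @param min_depth Minimum depth for a callable sample-site (default 50).
#' @return data.frame: gene, density_m, density_f (per kb per individual).
#'   Genes absent from the variant table get zero density.
#' @export
sex_snp_density <- function(variants, gene_lengths, sheet,
                            het_lo = 0.2, het_hi = 0.8, min_depth = 50) {
  if (any(gene_lengths <= 0)) stop("zero-length gene span")
  sex <- sheet$sex[match(colnames(variants$dp), sheet$sample)]
  freq <- site_frequency(variants$dp, variants$ad)
  het <- !is.na(freq) & freq >= het_lo & freq <= het_hi &
    variants$dp >= min_depth
  genes <- names(gene_lengths)
  n_m <- sum(sex == "M")
  n_f <- sum(sex == "F")
  het_m <- rowSums(het[, sex == "M", drop = FALSE])
  het_f <- rowSums(het[, sex == "F", drop = FALSE])
  per_gene_m <- tapply(het_m, factor(variants$sites$contig, levels = genes),
                       sum, default = 0)
  per_gene_f <- tapply(het_f, factor(variants$sites$contig, levels = genes),
                       sum, default = 0)
  kb <- gene_lengths / 1000
  data.frame(gene = genes,
             density_m = as.numeric(per_gene_m) / (n_m * kb),
             density_f = as.numeric(per_gene_f) / (n_f * kb),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Centered moving average with truncation at the ends
#'
#' Window of up to `window` genes centered on each position (offsets
#' -floor(w/2) ... ceiling(w/2)-1, e.g. -5...+4 for window 10), truncated
#' at the series ends; output length equals input length.
#'
#' @param x Numeric series (chromosome-ordered values).
#' @param window Window size >= 1 (default 10).
#' @return Smoothed numeric vector.
#' @export
moving_average <- function(x, window = 10) {
  if (length(x) == 0) stop("empty series")
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  lo <- pmax(1, seq_len(n) - floor(window / 2))
  hi <- pmin(n, seq_len(n) + ceiling(window / 2) - 1)
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Assemble per-gene sex statistics along the Z order
#'
#' @param genes Synteny-ordered gene ids (from [order_by_synteny()]).
#' @param log2_mf Named per-gene log2 M:F ratios (from [mf_ratio()]).
#' @param densities Output of [sex_snp_density()].
#' @param window Moving-average window (default 10).
#' @param eps Guard added to the female density before the ratio.
#' @return data.frame: gene, log2_mf, density_m, density_f, ma_log2_mf,
#'   ma_density_m, ma_density_f, ma_density_ratio.
#' @export
gene_sex_stats <- function(genes, log2_mf, densities, window = 10,
                           eps = 1e-9) {
  d <- densities[match(genes, densities$gene), ]
  out <- data.frame(
    gene = genes,
    log2_mf = as.numeric(log2_mf[genes]),
    density_m = d$density_m,
    density_f = d$density_f,
    stringsAsFactors = FALSE
  )
  out$ma_log2_mf <- moving_average(out$log2_mf, window)
  out$ma_density_m <- moving_average(out$density_m, window)
  out$ma_density_f <- moving_average(out$density_f, window)
  out$ma_density_ratio <- out$ma_density_m / (out$ma_density_f + eps)
  out
}

#' Call PAR-like and non-PAR-like regions along the ordered genes
#'
#' A gene is non-PAR-flagged when its smoothed log2 M:F exceeds `tau_expr`
#' and its smoothed male:female SNP-density ratio exceeds `tau_dens`. Runs
#' of at least `min_run` flagged genes become non-PAR-like regions; the
#' remainder is PAR-like. Regions partition the ordered genes.
#'
#' @param stats Output of [gene_sex_stats()] (chromosome-ordered).
#' @param tau_expr Expression threshold on smoothed log2 M:F (default 0.5,
#'   the midpoint of the expected log2 ~ 0 and ~ 1 modes).
#' @param tau_dens Threshold on the smoothed male/female density ratio
#'   (default 1.5).
#' @param min_run Minimum run length for a non-PAR-like region (default 5).
#' @return data.frame: label, start_index, end_index (0-based half-open on
#'   the gene order), n_genes; plus per-gene `nonpar_flag` as an attribute.
#' @export
call_nonpar_regions <- function(stats, tau_expr = 0.5, tau_dens = 1.5,
                                min_run = 5) {
  flag <- stats$ma_log2_mf > tau_expr & stats$ma_density_ratio > tau_dens
  r <- rle(flag)
  # demote short non-PAR runs, then merge
  r$values[r$values & r$lengths < min_run] <- FALSE
  flag2 <- inverse.rle(r)
  r2 <- rle(flag2)
  end <- cumsum(r2$lengths)
  start <- c(0L, utils::head(end, -1))
  out <- data.frame(
    label = ifelse(r2$values, "nonPAR-like", "PAR-like"),
    start_index = start, end_index = end, n_genes = r2$lengths,
    stringsAsFactors = FALSE
  )
  attr(out, "nonpar_flag") <- flag2
  out
}

#' Least-squares single-changepoint fit of the PAR boundary
#'
#' Exhaustive search for the boundary k minimizing the residual sum of
#' squares of fitting one mean to genes [0, k) and another to [k, n);
#' ties resolve to the smallest k.
#'
#' @param log2_mf Chromosome-ordered per-gene log2 M:F values (length >= 2).
#' @return list(boundary = k, sse = residual sum of squares).
#' @export
fit_par_boundary <- function(log2_mf) {
  x <- log2_mf
  n <- length(x)
  if (n < 2) stop("need >= 2 genes")
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- numeric(n + 1)
  for (k in 0:n) {
    s1 <- if (k > 0) cs[k] else 0
    q1 <- if (k > 0) cs2[k] else 0
    s2 <- cs[n] - s1
    q2 <- cs2[n] - q1
    sse[k + 1] <- (q1 - if (k > 0) s1^2 / k else 0) +
      (q2 - if (k < n) s2^2 / (n - k) else 0)
  }
  k <- which.min(sse) - 1L  # which.min takes the first minimum: smallest k
  list(boundary = k, sse = sse[k + 1])
}

#' Two-mode summary of the log2 M:F distribution
#'
#' @param log2_mf Per-gene values.
#' @param cut Split point (default 0.5).
#' @return list(n_low, n_high, mean_low, mean_high); a mean is NA when its
#'   mode is empty.
#' @export
bimodality_summary <- function(log2_mf, cut = 0.5) {
  lo <- log2_mf[log2_mf <= cut]
  hi <- log2_mf[log2_mf > cut]
  list(n_low = length(lo), n_high = length(hi),
       mean_low = if (length(lo)) mean(lo) else NA_real_,
       mean_high = if (length(hi)) mean(hi) else NA_real_)
}
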