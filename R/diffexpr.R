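# Count-based differential expression: quantile normalization, moment
# dispersion estimation with shrinkage, and a negative-binomial
# likelihood-ratio test of equal group means. Species calls additionally
# require a fold-change floor; sex calls do not (a two-fold male bias is
# itself the signal of interest on the Z chromosome).

#' Quantile-normalize a count matrix
#'
#' Forces every column to share the same value multiset: the row-wise mean
#' of the sorted columns. Ties within a column receive the mean of the
#' reference values their ranks span, so the result does not depend on the
#' input ordering of tied entries.
#'
#' @param counts genes x samples numeric matrix, non-negative.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(counts)
  }
  ref <- rowMeans(apply(counts, 2, sort))
  out <- apply(counts, 2, function(x) {
    v <- ref[rank(x, ties.method = "first")]
    stats::ave(v, x, FUN = mean)
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Method-of-moments NB dispersion with shrinkage to the common value
#'
#' Per gene, alpha-hat = max(0, (s2 - m) / m^2) from within-group residual
#' variance (Var = mu + alpha mu^2), then shrunk toward the median
#' dispersion with weight w = n0 / (n0 + df), df = n - K. All-zero genes
#' get dispersion 0 and are flagged in the "zero_gene" attribute.
#'
#' @param counts genes x samples matrix (raw or normalized).
#' @param groups Factor-like of length ncol(counts); at least two samples
#'   per group.
#' @param n0 Shrinkage prior weight (default 10).
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, groups, n0 = 10) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  n <- ncol(counts)
  k <- nlevels(groups)
  ss <- 0
  mbar <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    m <- rowMeans(counts[, idx, drop = FALSE])
    ss <- ss + rowSums((counts[, idx, drop = FALSE] - m)^2)
    mbar <- mbar + m * length(idx)
  }
  mbar <- mbar / n
  s2 <- ss / (n - k)
  alpha_hat <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)
  common <- stats::median(alpha_hat[mbar > 0])
  if (!is.finite(common)) common <- 0
  w <- n0 / (n0 + (n - k))
  alpha <- w * common + (1 - w) * alpha_hat
  alpha[mbar == 0] <- 0
  attr(alpha, "zero_gene") <- mbar == 0
  alpha
}

# continuous NB log-likelihood (gamma-function extension, valid for real
# x >= 0, as quantile-normalized counts are non-integer); alpha -> 0 limit
# is the Poisson log-likelihood
.nb_loglik <- function(x, mu, alpha) {
  mu <- pmax(mu, 1e-8)
  pois <- x * log(mu) - mu - lgamma(x + 1)
  if (length(alpha) == 1) alpha <- rep(alpha, length(x))
  r <- 1 / pmax(alpha, 1e-12)
  nb <- lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * log(r / (r + mu)) + x * log(mu / (r + mu))
  out <- ifelse(alpha < 1e-8, pois, nb)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Negative-binomial likelihood-ratio test of equal group means
#'
#' Per gene, compares a one-mean to a two-mean NB model with the gene's
#' (shrunk) dispersion held fixed; with fixed dispersion the NB mean MLE is
#' the sample mean, so the fit is closed-form. The statistic is referred to
#' chi-squared with 1 df; p-values are BH-adjusted across genes. Fold
#' changes are group A over group B with pseudocount 0.5.
#'
#' @param norm Normalized genes x samples matrix.
#' @param group_a,group_b Column names (or indices) of the two groups.
#' @param level Significance level on the adjusted p (default 0.05).
#' @param dispersion Optional per-gene dispersion; estimated from the two
#'   groups when NULL.
#' @param n0 Shrinkage weight for [estimate_dispersion()].
#' @return data.frame: gene, log2_fold_change, dispersion, p_value,
#'   adjusted_p, significant, direction ("A", "B" or "ns").
#' @export
de_test <- function(norm, group_a, group_b, level = 0.05,
                    dispersion = NULL, n0 = 10) {
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stop("both groups must be non-empty")
  if (all(a == 0) && all(b == 0)) stop("degenerate all-zero matrix")
  x <- cbind(a, b)
  grp <- rep(c("A", "B"), c(ncol(a), ncol(b)))
  if (is.null(dispersion)) dispersion <- estimate_dispersion(x, grp, n0 = n0)

  ma <- rowMeans(a)
  mb <- rowMeans(b)
  m0 <- rowMeans(x)
  ll <- function(mat, mu) {
    rowSums(.nb_loglik(mat, matrix(mu, nrow(mat), ncol(mat)),
                       rep(dispersion, ncol(mat))))
  }
  stat <- pmax(0, 2 * (ll(a, ma) + ll(b, mb) - ll(x, m0)))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  lfc <- log2((ma + 0.5) / (mb + 0.5))
  data.frame(
    gene = rownames(norm) %||% seq_len(nrow(norm)),
    log2_fold_change = lfc,
    dispersion = as.numeric(dispersion),
    p_value = p,
    adjusted_p = padj,
    significant = padj < level,
    direction = ifelse(padj < level, ifelse(lfc > 0, "A", "B"), "ns"),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Species differential-expression call with a fold-change floor
#'
#' A gene is called when it is significant and its absolute fold change is
#' at least `min_fold` (inclusive, i.e. |log2FC| >= log2(min_fold)).
#'
#' @param results Output of [de_test()].
#' @param min_fold Fold-change floor (default 2).
#' @return Factor-like character vector: "up_in_A", "up_in_B" or "ns".
#' @export
classify_species_de <- function(results, min_fold = 2.0) {
  pass <- results$significant &
    abs(results$log2_fold_change) >= log2(min_fold)
  ifelse(pass, ifelse(results$log2_fold_change > 0, "up_in_A", "up_in_B"),
         "ns")
}

#' Sex differential-expression call (no fold threshold)
#'
#' Significance alone decides the call; the two-fold subset is reported in
#' parallel since a two-fold male bias marks non-PAR Z-linkage. Group A is
#' taken as males.
#'
#' @param results Output of [de_test()] with groups = (males, females).
#' @return data.frame: gene, call ("male_biased", "female_biased", "ns"),
#'   twofold (logical: |log2FC| >= 1).
#' @export
classify_sex_de <- function(results) {
  call <- ifelse(results$significant,
                 ifelse(results$log2_fold_change > 0, "male_biased",
                        "female_biased"),
                 "ns")
  data.frame(gene = results$gene, call = call,
             twofold = abs(results$log2_fold_change) >= 1,
             stringsAsFactors = FALSE)
}
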