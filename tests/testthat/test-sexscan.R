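test_that("synteny ordering sorts by position and reports unmapped genes", {
  map <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chrom = c("Z", "Z", "Z", "A"),
                    position = c(30, 10, 20, 5), stringsAsFactors = FALSE)
  out <- order_by_synteny(c("a", "b", "c", "d", "e"), map)
  expect_equal(out$genes, c("b", "c", "a"))
  expect_setequal(out$excluded, c("d", "e"))
  # tie positions keep stable input order
  map$position <- c(10, 10, 20, 5)
  expect_equal(order_by_synteny(c("a", "b", "c"), map)$genes,
               c("a", "b", "c"))
  # conflicting duplicate positions are an error
  bad <- rbind(map, data.frame(gene_id = "a", chrom = "Z", position = 99))
  expect_error(order_by_synteny("a", bad), "conflicting")
})

test_that("log2 M:F ratio behaves at its fixed points", {
  sheet <- data.frame(sample = c("m1", "m2", "f1", "f2"),
                      sex = c("M", "M", "F", "F"))
  norm <- matrix(c(10, 10, 10, 10,
                   2000, 2000, 1000, 1000,
                   0, 0, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("eq", "dbl", "zero"), sheet$sample))
  r <- mf_ratio(norm, sheet)
  expect_equal(unname(r["eq"]), 0)
  expect_lt(abs(r[["dbl"]] - 1), 0.01)
  expect_equal(unname(r["zero"]), 0)
  expect_error(mf_ratio(norm[, 1:2], sheet[1:2, ]), "both sexes")
})

test_that("SNP density counts heterozygous events per kb per individual", {
  sheet <- data.frame(sample = c("m1", "f1"), sex = c("M", "F"))
  lens <- c(g1 = 1000, g2 = 2000)
  v <- variant_table(
    data.frame(contig = c("g1", "g1"), pos = c(10L, 20L), ref = "A",
               alt = "G", stringsAsFactors = FALSE),
    matrix(100L, 2, 2, dimnames = list(NULL, sheet$sample)),
    matrix(c(50L, 0L, 50L, 0L), 2, 2, byrow = TRUE,
           dimnames = list(NULL, sheet$sample))
  )
  d <- sex_snp_density(v, lens, sheet)
  expect_equal(d$density_m[d$gene == "g1"], 2)   # 2 het events / 1 kb / 1 ind
  expect_equal(d$density_f[d$gene == "g1"], 0)
  expect_equal(d$density_m[d$gene == "g2"], 0)   # no variants -> 0
  # doubling transcript length halves density
  d2 <- sex_snp_density(v, c(g1 = 2000, g2 = 2000), sheet)
  expect_equal(d2$density_m[d2$gene == "g1"],
               d$density_m[d$gene == "g1"] / 2)
  expect_error(sex_snp_density(v, c(g1 = 0, g2 = 1), sheet), "zero-length")
})

test_that("female heterozygous density vanishes at non-PAR genes", {
  cfg <- small_cfg(seed = 33, mean_depth = 1000)
  map <- build_gene_map(cfg); sheet <- make_sample_sheet(cfg)
  e <- simulate_expression(cfg, map, sheet)
  v <- simulate_variants(cfg, map, sheet, e$counts)
  lens <- stats::setNames(map$length, map$gene_id)
  nonpar <- map$gene_id[map$chrom == "Z" & !map$par]
  d <- sex_snp_density(v$variants, lens[nonpar], sheet)
  expect_equal(sum(d$density_f), 0)
  expect_gt(sum(d$density_m), 0)
})

test_that("moving average matches a brute-force loop", {
  expect_equal(moving_average(rep(3.5, 20)), rep(3.5, 20))
  expect_equal(moving_average(c(4, 1, 7), window = 1), c(4, 1, 7))
  expect_error(moving_average(numeric(0)), "empty")
  brute <- function(x, w) {
    vapply(seq_along(x), function(i) {
      lo <- max(1, i - floor(w / 2))
      hi <- min(length(x), i + ceiling(w / 2) - 1)
      mean(x[lo:hi])
    }, numeric(1))
  }
  withr::with_seed(12, {
    for (w in c(1, 2, 3, 10, 25)) {
      x <- stats::rnorm(40)
      expect_equal(moving_average(x, w), brute(x, w), info = paste("w =", w))
    }
  })
})

test_that("smoothed values stay within their window's range", {
  withr::with_seed(13, {
    x <- stats::rnorm(60)
    ma <- moving_average(x, 10)
    for (i in seq_along(x)) {
      lo <- max(1, i - 5); hi <- min(60, i + 4)
      expect_gte(ma[i], min(x[lo:hi]) - 1e-12)
      expect_lte(ma[i], max(x[lo:hi]) + 1e-12)
    }
  })
})

test_that("region calling partitions the gene order", {
  mk_stats <- function(lmf, dens_ratio) {
    data.frame(gene = paste0("g", seq_along(lmf)), ma_log2_mf = lmf,
               ma_density_ratio = dens_ratio)
  }
  flat <- mk_stats(rep(0, 30), rep(1, 30))
  r <- call_nonpar_regions(flat)
  expect_equal(nrow(r), 1)
  expect_equal(r$label, "PAR-like")
  expect_equal(r$n_genes, 30)
  stepped <- mk_stats(c(rep(0, 20), rep(1, 10)), c(rep(1, 20), rep(3, 10)))
  r2 <- call_nonpar_regions(stepped)
  expect_equal(r2$label, c("PAR-like", "nonPAR-like"))
  expect_equal(r2$start_index, c(0, 20))
  expect_equal(r2$end_index, c(20, 30))
  expect_equal(sum(r2$n_genes), 30)
  # an infinite expression threshold suppresses all non-PAR calls
  r3 <- call_nonpar_regions(stepped, tau_expr = Inf)
  expect_true(all(r3$label == "PAR-like"))
  # runs shorter than min_run are demoted
  short <- mk_stats(c(rep(0, 10), rep(1, 3), rep(0, 10)),
                    c(rep(1, 10), rep(3, 3), rep(1, 10)))
  expect_true(all(call_nonpar_regions(short)$label == "PAR-like"))
})

test_that("the changepoint fit finds a clean step and breaks ties low", {
  expect_equal(fit_par_boundary(c(rep(0, 10), rep(1, 10)))$boundary, 10)
  expect_equal(fit_par_boundary(rep(2, 15))$boundary, 0)
  expect_error(fit_par_boundary(1), ">= 2")
  # brute-force SSE oracle on random series
  brute <- function(x) {
    n <- length(x)
    sse <- vapply(0:n, function(k) {
      a <- x[seq_len(k)]; b <- x[setdiff(seq_len(n), seq_len(k))]
      (if (k > 0) sum((a - mean(a))^2) else 0) +
        (if (k < n) sum((b - mean(b))^2) else 0)
    }, numeric(1))
    which.min(sse) - 1L
  }
  withr::with_seed(14, {
    for (i in 1:10) {
      x <- stats::rnorm(30) + rep(c(0, 1.5), c(12, 18))
      expect_equal(fit_par_boundary(x)$boundary, brute(x))
    }
  })
})

test_that("sex-label swap negates ratios and mirrors densities", {
  cfg <- small_cfg(seed = 15)
  ds <- simulate_dataset(cfg)
  norm <- quantile_normalize(ds$counts)
  swapped <- ds$sheet
  swapped$sex <- ifelse(ds$sheet$sex == "M", "F", "M")
  expect_equal(mf_ratio(norm, swapped), -mf_ratio(norm, ds$sheet))
  lens <- stats::setNames(ds$map$length, ds$map$gene_id)
  d1 <- sex_snp_density(ds$variants, lens, ds$sheet)
  d2 <- sex_snp_density(ds$variants, lens, swapped)
  expect_equal(d2$density_m, d1$density_f)
  expect_equal(d2$density_f, d1$density_m)
})

test_that("bimodality summary splits at the cut", {
  b <- bimodality_summary(rep(0, 12))
  expect_equal(b$n_low, 12)
  expect_equal(b$n_high, 0)
  expect_equal(b$mean_low, 0)
  expect_true(is.na(b$mean_high))
  b2 <- bimodality_summary(c(-0.1, 0.1, 0.9, 1.1), cut = 0.5)
  expect_equal(b2$n_high, 2)
  expect_equal(b2$mean_high, 1)
})

test_that("called non-PAR regions recover the true non-PAR genes", {
  hit <- fa <- numeric(20)
  for (s in 1:20) {
    cfg <- small_cfg(seed = 600 + s, n_autosomal_genes = 300,
                     n_z_genes = 300, mean_depth = 500)
    ds <- simulate_dataset(cfg)
    norm <- quantile_normalize(ds$counts)
    lmf <- mf_ratio(norm, ds$sheet)
    zg <- order_by_synteny(rownames(norm), ds$map)$genes
    lens <- stats::setNames(ds$map$length, ds$map$gene_id)
    dens <- sex_snp_density(ds$variants, lens[zg], ds$sheet)
    stats_z <- gene_sex_stats(zg, lmf, dens)
    flag <- attr(call_nonpar_regions(stats_z), "nonpar_flag")
    truth_nonpar <- !ds$map$par[match(zg, ds$map$gene_id)]
    hit[s] <- mean(flag[truth_nonpar])
    fa[s] <- mean(flag[!truth_nonpar])
  }
  expect_gte(mean(hit), 0.9)   # coverage of true non-PAR genes
  expect_lte(mean(fa), 0.1)    # intrusion into the PAR
})

test_that("boundary recovery error does not grow with sequencing depth", {
  err_at <- function(depth) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(n_autosomal_genes = 1200, mean_depth = depth,
                        seed = 800 + s)
      map <- build_gene_map(cfg); sheet <- make_sample_sheet(cfg)
      e <- simulate_expression(cfg, map, sheet)
      lmf <- mf_ratio(quantile_normalize(e$counts), sheet)
      zg <- order_by_synteny(names(lmf), map)$genes
      abs(fit_par_boundary(lmf[zg])$boundary - e$truth$par_boundary_index)
    }, numeric(1)))
  }
  # with 8 birds per sex, recovery is already near-exact at moderate depth
  # (the log2 step of 1.0 dwarfs count noise), so the decrease is visible
  # only from the starved-coverage regime upward
  errs <- vapply(c(1, 100, 2000), err_at, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
  expect_lte(errs[3], 3)
})
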