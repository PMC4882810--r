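# Synthetic ZW blood-transcriptome generator.
#
# Emulates the statistical structure the downstream stages assume: two
# species with unequal diversity, eight birds per species at equal sex
# ratio, hemoglobin-dominated libraries, negative-binomial counts, a
# Z-syntenic gene set split into PAR (equal sex expression and SNP density)
# and non-PAR (two-fold male expression, female hemizygosity), and
# species-diagnostic plus within-species SNPs with binomial allele depths.
# Positions are 0-based half-open internally; 1-based only in VCF/BED on disk.

#' Configuration for the synthetic ZW dataset generator
#'
#' Defaults encode the study design the pipeline targets: 300 genes mapped
#' to the Z chromosome with roughly two thirds of them inside the
#' pseudoautosomal region (PAR), eight birds per species at equal sex ratio,
#' a two-fold male expression excess for non-PAR Z genes (no dosage
#' compensation), and hemoglobin transcripts absorbing ~20% of each blood
#' library.
#'
#' @param n_autosomal_genes Number of autosomal genes (default 5700, so
#'   the 300 Z genes are ~5% of the transcriptome, as in a typical avian
#'   gene set; a Z-heavy universe would distort quantile normalization).
#' @param n_z_genes Number of Z-linked genes (default 300).
#' @param par_fraction Fraction of Z genes inside the PAR (default 2/3);
#'   the first `floor(par_fraction * n_z_genes)` Z genes in position order
#'   are PAR.
#' @param n_per_species Birds per species, must be even (equal sex ratio).
#' @param mean_depth Expected reads per gene per sample.
#' @param dispersion_shape Gamma shape for the per-gene NB dispersion.
#' @param dispersion_mean Mean of the per-gene NB dispersion alpha
#'   (Var = mu + alpha * mu^2).
#' @param sex_effect_nonpar Male/female expression ratio outside the PAR
#'   (default 2).
#' @param hemoglobin_fraction Share of each library drawn from the flagged
#'   hemoglobin transcripts (default 0.20).
#' @param diag_snp_rate Species-diagnostic SNPs per kb of transcript.
#' @param within_snp_rate Named numeric of within-species polymorphic SNPs
#'   per kb, one entry per species; unequal defaults mirror a bottlenecked
#'   versus a diverse population.
#' @param species_lfc_sd SD of log2 fold changes for true species-DE genes.
#' @param de_gene_fraction Fraction of genes carrying a true species effect.
#' @param seed Integer seed; fixes every downstream draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_genes = 5700,
                       n_z_genes = 300,
                       par_fraction = 2 / 3,
                       n_per_species = 8,
                       mean_depth = 500,
                       dispersion_shape = 2,
                       dispersion_mean = 0.1,
                       sex_effect_nonpar = 2.0,
                       hemoglobin_fraction = 0.20,
                       diag_snp_rate = 0.5,
                       within_snp_rate = c(A = 0.5, B = 1.0),
                       species_lfc_sd = 1.0,
                       de_gene_fraction = 0.1,
                       seed = 1L) {
  stopifnot(
    n_autosomal_genes >= 0, n_z_genes >= 0,
    par_fraction >= 0, par_fraction <= 1,
    hemoglobin_fraction >= 0, hemoglobin_fraction < 1,
    de_gene_fraction >= 0, de_gene_fraction <= 1,
    sex_effect_nonpar > 0, mean_depth > 0,
    dispersion_shape > 0, dispersion_mean >= 0,
    diag_snp_rate >= 0, all(within_snp_rate >= 0),
    length(within_snp_rate) == 2
  )
  if (n_per_species %% 2 != 0 || n_per_species < 2) {
    stop("n_per_species must be even and >= 2 (equal sex ratio)")
  }
  if (n_z_genes == 0 && par_fraction > 0) {
    stop("par_fraction > 0 requires n_z_genes > 0")
  }
  if (is.null(names(within_snp_rate))) names(within_snp_rate) <- c("A", "B")
  cfg <- list(
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_z_genes = as.integer(n_z_genes),
    par_fraction = par_fraction,
    n_per_species = as.integer(n_per_species),
    mean_depth = mean_depth,
    dispersion_shape = dispersion_shape,
    dispersion_mean = dispersion_mean,
    sex_effect_nonpar = sex_effect_nonpar,
    hemoglobin_fraction = hemoglobin_fraction,
    diag_snp_rate = diag_snp_rate,
    within_snp_rate = within_snp_rate,
    species_lfc_sd = species_lfc_sd,
    de_gene_fraction = de_gene_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Sample sheet for a two-species, equal-sex-ratio cohort
#'
#' @param cfg A [sim_config()].
#' @return data.frame with columns sample, species, sex, age_class, location.
#' @export
make_sample_sheet <- function(cfg) {
  sp <- names(cfg$within_snp_rate)
  half <- cfg$n_per_species / 2
  sheet <- do.call(rbind, lapply(sp, function(s) {
    data.frame(
      sample = sprintf("%s_%s%d", s, rep(c("M", "F"), each = half),
                       rep(seq_len(half), 2)),
      species = s,
      sex = rep(c("M", "F"), each = half),
      age_class = "adult",
      location = paste0("site_", s),
      stringsAsFactors = FALSE
    )
  }))
  rownames(sheet) <- NULL
  sheet
}

#' Build the synthetic gene map
#'
#' Genes are placed on an autosome ("A") and the Z chromosome ("Z") at
#' strictly increasing positions. The first `floor(par_fraction * n_z_genes)`
#' Z genes in position order are flagged PAR. Transcript lengths are
#' log-normal with median ~2 kb, matching typical ORF-bearing blood
#' transcripts. Two autosomal genes are designated hemoglobin subunits.
#'
#' @param cfg A [sim_config()].
#' @return data.frame: gene_id, chrom, position, length, par (NA on
#'   autosomes), hemoglobin.
#' @export
build_gene_map <- function(cfg) {
  withr::with_seed(cfg$seed, {
    n_a <- cfg$n_autosomal_genes
    n_z <- cfg$n_z_genes
    len <- pmax(600L, as.integer(round(stats::rlnorm(n_a + n_z,
                                                     meanlog = log(2000),
                                                     sdlog = 0.35))))
    gene_id <- c(sprintf("gA%04d", seq_len(n_a)), sprintf("gZ%04d", seq_len(n_z)))
    chrom <- c(rep("A", n_a), rep("Z", n_z))
    # strictly increasing starts per chromosome with a fixed intergenic gap
    pos <- c(
      if (n_a > 0) cumsum(c(0L, utils::head(len[chrom == "A"], -1) + 1000L)),
      if (n_z > 0) cumsum(c(0L, utils::head(len[chrom == "Z"], -1) + 1000L))
    )
    n_par <- if (n_z > 0) floor(cfg$par_fraction * n_z) else 0L
    par <- rep(NA, n_a + n_z)
    par[chrom == "Z"] <- seq_len(n_z) <= n_par
    hemoglobin <- rep(FALSE, n_a + n_z)
    if (n_a >= 2) hemoglobin[sample(which(chrom == "A"), 2)] <- TRUE
    data.frame(gene_id = gene_id, chrom = chrom, position = as.integer(pos),
               length = len, par = par, hemoglobin = hemoglobin,
               stringsAsFactors = FALSE)
  })
}

#' Number of PAR genes implied by a gene map
#' @param map Output of [build_gene_map()].
#' @return Integer ordinal of the last PAR gene in Z position order.
#' @export
par_boundary_index <- function(map) {
  sum(map$par[map$chrom == "Z"], na.rm = TRUE)
}

# Random codon soup with no in-frame stop, used to fill planted ORFs.
.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Simulate transcript sequences
#'
#' Each transcript carries one long planted ORF (ATG, stop, no internal
#' stop) flanked by short untranslated ends, so the ORF finder and the
#' SNP-effect classifier have realistic substrate.
#'
#' @param cfg A [sim_config()].
#' @param map Output of [build_gene_map()].
#' @return Named character vector of DNA sequences.
#' @export
sim_transcripts <- function(cfg, map) {
  sense <- .sense_codons()
  bases <- c("A", "C", "G", "T")
  withr::with_seed(cfg$seed + 10L, {
    seqs <- vapply(map$length, function(len) {
      utr5 <- max(10L, round(0.05 * len))
      utr3_min <- max(10L, round(0.05 * len))
      n_codons <- (len - utr5 - utr3_min - 6L) %/% 3L
      orf <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                                 collapse = ""), "TAA")
      pad <- len - utr5 - nchar(orf)
      paste0(paste(sample(bases, utr5, replace = TRUE), collapse = ""),
             orf,
             paste(sample(bases, pad, replace = TRUE), collapse = ""))
    }, character(1))
    names(seqs) <- map$gene_id
    seqs
  })
}

#' Simulate the expression count matrix
#'
#' Counts are negative binomial with per-gene dispersion alpha ~
#' Gamma(shape, mean = dispersion_mean), Var = mu + alpha mu^2. Non-PAR Z
#' genes have male mean = `sex_effect_nonpar` times the female mean; PAR and
#' autosomal genes have equal sex means. A `de_gene_fraction` of non-
#' hemoglobin genes carries a species log2 fold change ~ N(0, species_lfc_sd).
#' Hemoglobin transcripts jointly absorb `hemoglobin_fraction` of every
#' sample's expected library.
#'
#' @param cfg A [sim_config()].
#' @param map Output of [build_gene_map()].
#' @param sheet Output of [make_sample_sheet()]; must contain both sexes in
#'   both species.
#' @return list(counts = genes x samples integer matrix, truth = list with
#'   de_genes, hemoglobin_ids, par_boundary_index).
#' @export
simulate_expression <- function(cfg, map, sheet) {
  if (nrow(sheet) == 0) stop("empty sample sheet")
  if (!all(c("M", "F") %in% sheet$sex)) stop("sample sheet must contain both sexes")
  n_genes <- nrow(map)
  n_samp <- nrow(sheet)
  sp <- names(cfg$within_snp_rate)
  withr::with_seed(cfg$seed + 1L, {
    w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    hb <- which(map$hemoglobin)
    nonhb <- setdiff(seq_len(n_genes), hb)
    n_de <- floor(cfg$de_gene_fraction * length(nonhb))
    de_idx <- sort(sample(nonhb, n_de))
    de_lfc <- stats::rnorm(n_de, 0, cfg$species_lfc_sd)

    mu <- matrix(w, n_genes, n_samp)
    # species effect applied to the second species
    is_b <- sheet$species == sp[2]
    mu[de_idx, is_b] <- mu[de_idx, is_b] * 2^de_lfc
    # male excess at non-PAR Z genes (no dosage compensation)
    nonpar <- which(map$chrom == "Z" & !map$par)
    is_m <- sheet$sex == "M"
    mu[nonpar, is_m] <- mu[nonpar, is_m] * cfg$sex_effect_nonpar
    # hemoglobin absorbs a fixed share of each sample's expected library
    if (length(hb) > 0 && cfg$hemoglobin_fraction > 0) {
      hb_split <- seq(0.45, 0.55, length.out = length(hb))
      hb_split <- hb_split / sum(hb_split)
      hb_tot <- cfg$hemoglobin_fraction / (1 - cfg$hemoglobin_fraction) *
        colSums(mu[nonhb, , drop = FALSE])
      mu[hb, ] <- outer(hb_split, hb_tot)
    }
    # scale so the grand mean count per gene per sample is mean_depth
    mu <- mu * (cfg$mean_depth * n_genes * n_samp / sum(mu))

    alpha <- stats::rgamma(n_genes, shape = cfg$dispersion_shape,
                           scale = cfg$dispersion_mean / cfg$dispersion_shape)
    counts <- matrix(
      stats::rnbinom(n_genes * n_samp, mu = mu,
                     size = rep(1 / pmax(alpha, 1e-8), n_samp)),
      n_genes, n_samp,
      dimnames = list(map$gene_id, sheet$sample)
    )
    storage.mode(counts) <- "integer"
    truth <- list(
      de_genes = data.frame(gene_id = map$gene_id[de_idx], log2fc = de_lfc,
                            stringsAsFactors = FALSE),
      hemoglobin_ids = map$gene_id[hb],
      par_boundary_index = par_boundary_index(map),
      dispersion = alpha
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate per-sample variant observations
#'
#' Plants species-diagnostic sites (alt allele fixed in one species, absent
#' in the other) and within-species polymorphic sites (Hardy-Weinberg
#' genotypes from a per-site allele frequency). Females at non-PAR Z sites
#' are hemizygous: their genotype is a single allele and can never be
#' heterozygous. Per-sample site depth equals that gene's count (uniform
#' coverage); alt depth ~ Binomial(depth, dosage in {0, 1/2, 1}).
#'
#' @param cfg A [sim_config()].
#' @param map Output of [build_gene_map()].
#' @param sheet Sample sheet used for `counts`.
#' @param counts Count matrix from [simulate_expression()].
#' @param seqs Optional transcript sequences (for ref/alt alleles); generated
#'   from `cfg` when missing.
#' @return list(variants = variant_table, truth = list(diagnostic_sites,
#'   within_species_sites, genotype_dosage)).
#' @export
simulate_variants <- function(cfg, map, sheet, counts, seqs = NULL) {
  if (is.null(seqs)) seqs <- sim_transcripts(cfg, map)
  n_samp <- nrow(sheet)
  sp <- names(cfg$within_snp_rate)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(cfg$seed + 2L, {
    kb <- map$length / 1000
    n_diag <- stats::rpois(nrow(map), cfg$diag_snp_rate * kb)
    n_wa <- stats::rpois(nrow(map), cfg$within_snp_rate[1] * kb)
    n_wb <- stats::rpois(nrow(map), cfg$within_snp_rate[2] * kb)

    site_list <- vector("list", nrow(map))
    for (g in seq_len(nrow(map))) {
      tot <- n_diag[g] + n_wa[g] + n_wb[g]
      if (tot == 0) next
      pos <- sort(sample.int(map$length[g], tot) - 1L)  # 0-based, unique
      cat_g <- sample(rep(c("diagnostic", "within_A", "within_B"),
                          c(n_diag[g], n_wa[g], n_wb[g])))
      site_list[[g]] <- data.frame(gene = g, pos = pos, category = cat_g,
                                   stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_list)
    if (is.null(sites)) {
      sites <- data.frame(gene = integer(), pos = integer(),
                          category = character(), stringsAsFactors = FALSE)
    }
    n_sites <- nrow(sites)
    ref <- substring(seqs[map$gene_id[sites$gene]], sites$pos + 1L, sites$pos + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)

    # genotype dosage: expected alt fraction per sample in {0, .5, 1}
    dosage <- matrix(0, n_sites, n_samp,
                     dimnames = list(NULL, sheet$sample))
    hemi_gene <- map$chrom == "Z" & !is.na(map$par) & !map$par
    is_f <- sheet$sex == "F"
    for (i in seq_len(n_sites)) {
      g <- sites$gene[i]
      hemi <- hemi_gene[g]
      if (sites$category[i] == "diagnostic") {
        dosage[i, sheet$species == sp[2]] <- 1
      } else {
        s <- if (sites$category[i] == "within_A") sp[1] else sp[2]
        idx <- which(sheet$species == s)
        p <- stats::runif(1, 0.1, 0.5)
        for (j in idx) {
          if (hemi && is_f[j]) {
            dosage[i, j] <- stats::rbinom(1, 1, p)        # hemizygous: 0 or 1
          } else {
            dosage[i, j] <- stats::rbinom(1, 2, p) / 2     # diploid HW
          }
        }
      }
    }

    dp <- counts[sites$gene, , drop = FALSE]
    storage.mode(dp) <- "integer"
    ad <- matrix(stats::rbinom(length(dp), as.vector(dp), as.vector(dosage)),
                 n_sites, n_samp)
    dimnames(dp) <- dimnames(ad) <- list(NULL, sheet$sample)

    contig <- map$gene_id[sites$gene]
    variants <- variant_table(
      sites = data.frame(contig = contig, pos = sites$pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
      dp = dp, ad = ad
    )
    key <- data.frame(contig = contig, pos = sites$pos, stringsAsFactors = FALSE)
    truth <- list(
      diagnostic_sites = key[sites$category == "diagnostic", ],
      within_species_sites = list(
        key[sites$category == "within_A", ],
        key[sites$category == "within_B", ]
      ),
      genotype_dosage = dosage
    )
    names(truth$within_species_sites) <- sp
    list(variants = variants, truth = truth)
  })
}

#' Per-site, per-sample allele observations
#'
#' @param sites data.frame with contig, pos (0-based), ref, alt.
#' @param dp,ad Integer matrices (sites x samples) of total and alt-allele
#'   read depth.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, dp, ad) {
  stopifnot(nrow(sites) == nrow(dp), nrow(sites) == nrow(ad),
            all(dim(dp) == dim(ad)), all(ad <= dp), all(dp >= 0))
  structure(list(sites = sites, dp = dp, ad = ad), class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$dp)))
  invisible(x)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [build_gene_map()], [make_sample_sheet()],
#' [sim_transcripts()], [simulate_expression()] and [simulate_variants()],
#' merging their ground truth.
#'
#' @param cfg A [sim_config()].
#' @return list(map, sheet, seqs, counts, variants, truth).
#' @export
simulate_dataset <- function(cfg) {
  map <- build_gene_map(cfg)
  sheet <- make_sample_sheet(cfg)
  seqs <- sim_transcripts(cfg, map)
  expr <- simulate_expression(cfg, map, sheet)
  var <- simulate_variants(cfg, map, sheet, expr$counts, seqs)
  list(map = map, sheet = sheet, seqs = seqs, counts = expr$counts,
       variants = var$variants,
       truth = c(expr$truth, var$truth, list(seed = cfg$seed)))
}
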