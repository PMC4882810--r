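# On-disk bundle: transcripts.fasta, counts.tsv, variants.vcf, genemap.bed,
# samples.tsv, truth.json. Internal coordinates are 0-based half-open;
# VCF POS and BED are written in their native dialects (1-based / 0-based).

#' Write a VCF 4.2 file with per-sample DP and AD
#'
#' @param variants A [variant_table()].
#' @param path Output file.
#' @param effects Optional character vector (one per site) of effect codes
#'   (SYN/NSY/NCD) written into INFO as EFF=.
#' @export
write_vcf <- function(variants, path, effects = NULL) {
  samples <- colnames(variants$dp)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=zwscan",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Predicted coding effect: SYN, NSY or NCD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- nrow(variants$sites)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  info <- if (is.null(effects)) rep(".", n) else paste0("EFF=", effects)
  gt <- matrix(paste0(variants$dp, ":", variants$dp - variants$ad, ",",
                      variants$ad),
               nrow = n)
  body <- paste(
    variants$sites$contig, variants$sites$pos + 1L, ".",
    variants$sites$ref, variants$sites$alt, ".", "PASS", info, "DP:AD",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF with DP and AD FORMAT fields into a variant_table
#'
#' @param path VCF file.
#' @return A [variant_table()]; positions converted to 0-based.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  n_body <- sum(!startsWith(lines, "#"))
  if (n_body == 0) {
    hdr <- lines[startsWith(lines, "#CHROM")]
    samples <- utils::tail(strsplit(hdr, "\t")[[1]], -9)
    empty <- matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(variant_table(
      sites = data.frame(contig = character(), pos = integer(),
                         ref = character(), alt = character(),
                         stringsAsFactors = FALSE),
      dp = empty, ad = empty
    ))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad_alt <- vcfR::extract.gt(v, element = "AD")
  ad_alt <- apply(ad_alt, 2, function(x)
    as.integer(vapply(strsplit(x, ","), `[`, character(1), 2)))
  storage.mode(dp) <- "integer"
  dp <- matrix(dp, nrow = nrow(v@fix), dimnames = list(NULL, colnames(v@gt)[-1]))
  ad_alt <- matrix(ad_alt, nrow = nrow(v@fix),
                   dimnames = list(NULL, colnames(v@gt)[-1]))
  variant_table(
    sites = data.frame(contig = unname(v@fix[, "CHROM"]),
                       pos = as.integer(v@fix[, "POS"]) - 1L,
                       ref = unname(v@fix[, "REF"]),
                       alt = unname(v@fix[, "ALT"]),
                       stringsAsFactors = FALSE),
    dp = dp, ad = ad_alt
  )
}

#' Write the full synthetic bundle to a directory
#'
#' Writes transcripts.fasta, counts.tsv, variants.vcf, genemap.bed,
#' samples.tsv and truth.json. A round-trip through [read_dataset()]
#' reproduces all tables exactly.
#'
#' @param dir Output directory (created if missing).
#' @param map,counts,variants,sheet,truth,seqs Pieces from
#'   [simulate_dataset()] (or equivalent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, map, counts, variants, sheet, truth, seqs) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, file.path(dir, "transcripts.fasta"))

  cdf <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_vcf(variants, file.path(dir, "variants.vcf"))

  bed <- data.frame(chrom = map$chrom, start = map$position,
                    end = map$position + map$length, name = map$gene_id,
                    score = ifelse(is.na(map$par), 0L, as.integer(map$par)),
                    strand = "+")
  utils::write.table(bed, file.path(dir, "genemap.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tr <- truth
  tr$genotype_dosage <- NULL  # matrix truth kept in-memory only
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Bundle directory.
#' @return list(map, sheet, seqs, counts, variants, truth).
#' @export
read_dataset <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta"))
  seqs <- as.character(fa)

  cdf <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  storage.mode(counts) <- "integer"

  variants <- read_vcf(file.path(dir, "variants.vcf"))

  bed <- utils::read.table(file.path(dir, "genemap.bed"), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  map <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                    position = as.integer(bed$start),
                    length = as.integer(bed$end - bed$start),
                    par = ifelse(bed$chrom == "Z", bed$score == 1L, NA),
                    stringsAsFactors = FALSE)

  sheet <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)

  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL

  list(map = map, sheet = sheet, seqs = seqs, counts = counts,
       variants = variants, truth = truth)
}
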