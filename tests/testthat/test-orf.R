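test_that("a complete start-to-stop ORF is found with the right length", {
  seq <- paste0("ATG", strrep("GGA", 100), "TAA")  # 303 coding nt + stop
  orfs <- find_orfs(seq, "tx")
  complete <- orfs[!orfs$partial5 & !orfs$partial3, ]
  expect_equal(nrow(complete), 1)
  expect_equal(complete$aa_length, 101)
  expect_equal(complete$start, 0)
  expect_equal(complete$end, 306)
  expect_equal(complete$strand, "+")
})

test_that("a signal-free sequence yields one edge-to-edge ORF per strand", {
  orfs <- find_orfs(strrep("C", 99))
  expect_equal(nrow(orfs), 2)
  expect_true(all(orfs$partial5 & orfs$partial3))
  expect_setequal(orfs$strand, c("+", "-"))
  expect_equal(orfs$aa_length, c(33, 33))
})

test_that("empty sequences give an empty ORF table", {
  expect_equal(nrow(find_orfs("")), 0)
})

test_that("reverse-complementing a sequence mirrors the best ORF", {
  withr::with_seed(21, {
    for (i in 1:20) {
      seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      o1 <- find_orfs(seq)
      o2 <- find_orfs(rc)
      expect_equal(max(o1$aa_length), max(o2$aa_length))
      # per-strand best lengths swap under reverse complement
      best <- function(o, s) max(c(0, o$aa_length[o$strand == s]))
      expect_equal(best(o1, "+"), best(o2, "-"))
      expect_equal(best(o1, "-"), best(o2, "+"))
    }
  })
})

test_that("the >100 aa filter is strict and keeps the longest ORF", {
  orfs <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t3"),
    start = c(0, 0, 0, 500), end = c(303, 306, 453, 863),
    strand = "+", frame = 0, partial5 = FALSE, partial3 = FALSE,
    aa_length = c(100, 101, 150, 120), stringsAsFactors = FALSE
  )
  kept <- filter_orfs(orfs)
  expect_false("t1" %in% kept$transcript_id)     # exactly 100 aa: rejected
  expect_true("t2" %in% kept$transcript_id)      # 101 aa: retained
  expect_equal(kept$aa_length[kept$transcript_id == "t3"], 150)
})

test_that("ORF ties break complete over partial, then plus strand", {
  orfs <- data.frame(
    transcript_id = "t", start = c(0, 10), end = c(453, 463),
    strand = c("-", "+"), frame = 0,
    partial5 = c(FALSE, TRUE), partial3 = FALSE,
    aa_length = c(150, 150), stringsAsFactors = FALSE
  )
  expect_false(filter_orfs(orfs)$partial5)
  orfs$partial5 <- FALSE
  expect_equal(filter_orfs(orfs)$strand, "+")
})

test_that("codon-level effects follow the standard genetic code", {
  #  AAAA ATG GAA TAA CC : ORF [4, 13), GAA (Glu) at positions 7-9
  seq <- "AAAAATGGAATAACC"
  orf <- data.frame(start = 4, end = 13, strand = "+", frame = 1,
                    partial5 = FALSE, partial3 = FALSE, aa_length = 2)
  syn <- classify_variant_effect(seq, orf, 9, "A", "G")   # GAA -> GAG
  expect_equal(syn$effect, "synonymous")
  expect_equal(c(syn$aa_ref, syn$aa_alt), c("E", "E"))
  nsy <- classify_variant_effect(seq, orf, 7, "G", "A")   # GAA -> AAA
  expect_equal(nsy$effect, "nonsynonymous")
  expect_equal(c(nsy$aa_ref, nsy$aa_alt), c("E", "K"))
  expect_equal(classify_variant_effect(seq, orf, 2, "A", "G")$effect,
               "noncoding")                                # 5' UTR
  expect_error(classify_variant_effect(seq, orf, 9, "C", "G"), "mismatch")
  expect_error(classify_variant_effect(seq, orf, 9, "A", "A"), "differ")
})

test_that("minus-strand effects equal plus-strand effects after revcomp", {
  seq <- "AAAAATGGAATAACC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  orf_plus <- data.frame(start = 4, end = 13, strand = "+", frame = 1,
                         partial5 = FALSE, partial3 = FALSE, aa_length = 2)
  orf_minus <- data.frame(start = nchar(seq) - 13, end = nchar(seq) - 4,
                          strand = "-", frame = 0,
                          partial5 = FALSE, partial3 = FALSE, aa_length = 2)
  for (case in list(c(9, "A", "G"), c(7, "G", "A"), c(8, "A", "T"))) {
    pos <- as.integer(case[1])
    plus <- classify_variant_effect(seq, orf_plus, pos, case[2], case[3])
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    minus <- classify_variant_effect(rc, orf_minus, nchar(seq) - 1 - pos,
                                     comp[[case[2]]], comp[[case[3]]])
    expect_equal(minus$effect, plus$effect)
    expect_equal(minus$aa_ref, plus$aa_ref)
    expect_equal(minus$aa_alt, plus$aa_alt)
  }
})

test_that("effect calls agree with direct translation on random codons", {
  bases <- c("A", "C", "G", "T")
  orf <- data.frame(start = 0, end = 9, strand = "+", frame = 0,
                    partial5 = FALSE, partial3 = FALSE, aa_length = 2)
  withr::with_seed(31, {
    for (i in 1:500) {
      codon <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      k <- sample(0:2, 1)
      ref <- substring(codon, k + 1, k + 1)
      alt <- sample(setdiff(bases, ref), 1)
      seq <- paste0("ATG", codon, "TAA")
      got <- classify_variant_effect(seq, orf, 3 + k, ref, alt)
      mutated <- codon
      substring(mutated, k + 1, k + 1) <- alt
      aa1 <- as.character(Biostrings::translate(
        Biostrings::DNAString(codon), no.init.codon = TRUE))
      aa2 <- as.character(Biostrings::translate(
        Biostrings::DNAString(mutated), no.init.codon = TRUE))
      expect_equal(got$effect,
                   if (aa1 == aa2) "synonymous" else "nonsynonymous")
    }
  })
})

test_that("codons containing N are indeterminate and excluded", {
  seq <- "ATGGNATAA"
  orf <- data.frame(start = 0, end = 9, strand = "+", frame = 0,
                    partial5 = FALSE, partial3 = FALSE, aa_length = 2)
  got <- classify_variant_effect(seq, orf, 3, "G", "C")
  expect_equal(got$effect, "noncoding")
  expect_equal(got$aa_ref, "X")
})

test_that("simulated transcripts all carry a retained ORF", {
  cfg <- small_cfg(seed = 2, n_autosomal_genes = 10, n_z_genes = 10)
  map <- build_gene_map(cfg)
  seqs <- sim_transcripts(cfg, map)
  orfs <- find_coding_orfs(seqs)
  expect_equal(sort(orfs$transcript_id), sort(map$gene_id))
  expect_true(all(orfs$aa_length > 100))
})

test_that("bulk effect annotation matches the per-site classifier", {
  cfg <- small_cfg(seed = 44, n_autosomal_genes = 20, n_z_genes = 10)
  ds <- simulate_dataset(cfg)
  orfs <- find_coding_orfs(ds$seqs)
  # force one retained ORF onto the minus strand to exercise that path
  flip <- which(orfs$transcript_id == orfs$transcript_id[1])
  orfs$strand[flip] <- "-"
  bulk <- annotate_variant_effects(ds$variants, orfs, ds$seqs)
  orf_ix <- match(ds$variants$sites$contig, orfs$transcript_id)
  scalar <- vapply(seq_len(nrow(ds$variants$sites)), function(i) {
    orf <- if (is.na(orf_ix[i])) NULL else orfs[orf_ix[i], ]
    classify_variant_effect(ds$seqs[[ds$variants$sites$contig[i]]], orf,
                            ds$variants$sites$pos[i],
                            ds$variants$sites$ref[i],
                            ds$variants$sites$alt[i])$effect
  }, character(1))
  expect_equal(bulk, scalar)
})
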