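test_that("cds_to_codon maps coding positions to codons exactly", {
  expect_equal(cds_to_codon(695), data.frame(codon_index = 232L, offset = 2L))
  expect_equal(cds_to_codon(1), data.frame(codon_index = 1L, offset = 1L))
  expect_equal(cds_to_codon(3505)$codon_index, 1169L)
  expect_error(cds_to_codon(0), ">= 1")

  # round trip over the first 3000 coding positions
  pos <- 1:3000
  m <- cds_to_codon(pos)
  expect_equal((m$codon_index - 1L) * 3L + m$offset, pos)
})

test_that("genomic_to_cds handles introns and both strands", {
  tx <- toy_tx_plus()                      # exon1 1001-1009, exon2 2001-2009
  expect_equal(genomic_to_cds(tx, 1001L), 1L)
  expect_equal(genomic_to_cds(tx, 2001L), 10L)   # first base of exon 2
  expect_true(is.na(genomic_to_cds(tx, 1500L)))  # intron

  mtx <- toy_tx_minus()
  n <- nchar(mtx$cds_sequence)
  expect_equal(genomic_to_cds(mtx, 2009L), 1L)   # last genomic base = CDS 1
  expect_equal(genomic_to_cds(mtx, 1001L), n)
  # inverse mapping agrees everywhere
  for (tx2 in list(tx, mtx)) {
    for (cp in seq_len(nchar(tx2$cds_sequence))) {
      expect_equal(genomic_to_cds(tx2, cds_to_genomic(tx2, cp)), cp)
    }
  }
})

test_that("a codon-232 GGN to GTN change is called p.Gly232Val with HGVS names", {
  # 233-codon toy coding sequence with codon 232 = GGG; position 695 is
  # its middle base
  cds <- paste0("ATG", strrep("GCT", 230), "GGG", "TAA")
  tx <- transcript_model("LMNA_TOY", "TX_LMNA_TOY", "1", "+",
                         exon_starts = 5000L, exon_ends = 5000L + 699L - 1L,
                         cds_start = 5000L, cds_end = 5000L + 699L - 1L,
                         cds_sequence = cds)
  s <- site_genotypes("1", 5000L + 694L, "G", "T", c(A = 1))
  cons <- classify_variant(list(tx), s)
  expect_equal(cons$category, "nonsynonymous SNV")
  expect_equal(cons$hgvs_c, "c.695G>T")
  expect_equal(cons$hgvs_c_legacy, "c.G695T")
  expect_equal(cons$hgvs_p, "p.Gly232Val")
  expect_equal(cons$codon_index, 232L)
})

test_that("SNV classes cover synonymous, stopgain and reference mismatch", {
  # CDS: ATG GGA TAC TAA ; positions 1..12 at genomic 1001..1012
  tx <- transcript_model("T3", "TX_T3", "5", "+", 1001L, 1012L,
                         1001L, 1012L, "ATGGGATACTAA")
  syn <- classify_variant(list(tx),
                          site_genotypes("5", 1006L, "A", "G", c(A = 1)))
  expect_equal(syn$category, "synonymous SNV")   # GGA -> GGG, both Gly
  expect_equal(syn$hgvs_p, "p.Gly2=")

  sg <- classify_variant(list(tx),
                         site_genotypes("5", 1009L, "C", "A", c(A = 1)))
  expect_equal(sg$category, "stopgain")          # codon 3 TAC -> TAA
  expect_error(
    classify_variant(list(tx),
                     site_genotypes("5", 1006L, "C", "G", c(A = 1))),
    class = "reference_mismatch")
})

test_that("indel framing, splice window, UTR and intergenic calls", {
  tx <- toy_tx_plus()
  del2 <- site_genotypes("5", 1003L, "GGG", "G", c(A = 1))
  expect_equal(classify_variant(list(tx), del2)$category, "frameshift indel")
  ins2 <- site_genotypes("5", 1003L, "G", "GAA", c(A = 1))
  expect_equal(classify_variant(list(tx), ins2)$category, "frameshift indel")
  ins_inframe <- site_genotypes("5", 1003L, "G", "GAAA", c(A = 1))
  expect_equal(classify_variant(list(tx), ins_inframe)$category,
               "nonframeshift indel")

  donor <- site_genotypes("5", 1011L, "A", "G", c(A = 1))  # intron +2
  expect_equal(classify_variant(list(tx), donor)$category, "splicing")
  deep <- site_genotypes("5", 1500L, "A", "G", c(A = 1))
  expect_equal(classify_variant(list(tx), deep)$category, "intronic")
  # widened window captures deeper intronic positions
  expect_equal(classify_variant(list(tx), deep,
                                splice_window = 600L)$category, "splicing")

  away <- site_genotypes("5", 99L, "A", "G", c(A = 1))
  expect_equal(classify_variant(list(tx), away)$category, "intergenic")
  other_chrom <- site_genotypes("8", 1005L, "A", "G", c(A = 1))
  expect_equal(classify_variant(list(tx), other_chrom)$category, "intergenic")

  # UTR: CDS restricted to exon 1 leaves exon 2 untranslated
  utr_tx <- transcript_model("U", "TX_U", "5", "+",
                             exon_starts = c(1001L, 2001L),
                             exon_ends = c(1009L, 2009L),
                             cds_start = 1001L, cds_end = 1009L,
                             cds_sequence = "ATGGGGTAA")
  utr <- site_genotypes("5", 2005L, "A", "G", c(A = 1))
  expect_equal(classify_variant(list(utr_tx), utr)$category, "UTR")
})

test_that("strand symmetry: minus-strand call equals the plus-strand construction", {
  withr::local_seed(11)
  cds <- paste0("ATG",
                paste(sample(c("GCT", "GAA", "TGG", "CAT", "AAA", "GGG"),
                             20, replace = TRUE), collapse = ""), "TAA")
  ptx <- toy_tx_plus(cds)
  mtx <- toy_tx_minus(cds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(cds)
  for (cp in sample(seq_len(n), 25)) {
    ref_coding <- substr(cds, cp, cp)
    for (alt_coding in setdiff(c("A", "C", "G", "T"), ref_coding)) {
      gp_p <- cds_to_genomic(ptx, cp)
      gp_m <- cds_to_genomic(mtx, cp)
      res_p <- classify_variant(list(ptx),
        site_genotypes("5", gp_p, ref_coding, alt_coding, c(A = 1)))
      res_m <- classify_variant(list(mtx),
        site_genotypes("5", gp_m, comp[[ref_coding]], comp[[alt_coding]],
                       c(A = 1)))
      expect_equal(res_m$category, res_p$category)
      expect_equal(res_m$hgvs_p, res_p$hgvs_p)
      expect_equal(res_m$hgvs_c, res_p$hgvs_c)
    }
  }
})

test_that("every nonsynonymous call changes the translated protein, synonymous never does", {
  withr::local_seed(13)
  cds <- paste0("ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                            c("TAA", "TAG", "TGA")),
                                    30, replace = TRUE), collapse = ""),
                "TAA")
  tx <- toy_tx_plus(cds)
  translate_str <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  for (rep in 1:60) {
    cp <- sample.int(nchar(cds), 1)
    ref <- substr(cds, cp, cp)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    res <- classify_variant(list(tx),
      site_genotypes("5", cds_to_genomic(tx, cp), ref, alt, c(A = 1)))
    mutant <- cds
    substr(mutant, cp, cp) <- alt
    same_protein <- identical(translate_str(cds), translate_str(mutant))
    if (res$category == "synonymous SNV") {
      expect_true(same_protein)
    } else if (res$category == "nonsynonymous SNV") {
      expect_false(same_protein)
    }
  }
})

test_that("multiple overlapping transcripts report the most severe consequence", {
  tx <- toy_tx_plus()   # coding at 1001-1009
  utr_tx <- transcript_model("U", "TX_U", "5", "+",
                             exon_starts = 901L, exon_ends = 1100L,
                             cds_start = 901L, cds_end = 903L,
                             cds_sequence = "ATG")
  s <- site_genotypes("5", 1007L, "A", "G", c(A = 1))  # codon 3 AAA -> GAA
  res <- classify_variant(list(utr_tx, tx), s)
  expect_equal(res$category, "nonsynonymous SNV")
  expect_equal(length(res$per_transcript), 2L)
})

test_that("transcript TSV+FASTA and BED12 loaders rebuild equivalent models", {
  ds <- simulate_family_dataset(simulation_config(seed = 5, n_background = 0,
                                                  n_genes = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  txs <- read_transcripts(file.path(dir, "tx.tsv"), file.path(dir, "cds.fa"))
  expect_length(txs, length(ds$transcripts))
  orig <- ds$transcripts[[3]]
  back <- txs[[3]]
  expect_equal(back$exon_starts, orig$exon_starts)
  expect_equal(back$cds_sequence, orig$cds_sequence)
  expect_equal(back$strand, orig$strand)

  # BED12 route on a hand-written record equivalent to toy_tx_plus()
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fa")
  tx <- toy_tx_plus()
  writeLines(paste(c("5", 1000, 2009, paste0("TOY1|", tx$transcript_id), 0,
                     "+", 1000, 2009, 0, 2, "9,9,", "0,1000,"),
                   collapse = "\t"), bed)
  writeLines(c(paste0(">", tx$transcript_id), tx$cds_sequence), fa)
  b12 <- read_transcripts_bed12(bed, fa)[[1]]
  expect_equal(b12$exon_starts, tx$exon_starts)
  expect_equal(b12$exon_ends, tx$exon_ends)
  expect_equal(b12$cds_start, tx$cds_start)
  expect_equal(b12$gene, "TOY1")
})
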