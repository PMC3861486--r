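# bare annotation records for cascade tests (already annotated)
mk_records <- function(n, func = "exonic", exonic_func = "nonsynonymous SNV",
                       type = "SNV", conserved = TRUE, segdup = FALSE,
                       dbsnp_id = NA_character_, maf_1000g = NA_real_,
                       maf_esp = NA_real_) {
  data.frame(chrom = rep("1", n), pos = seq_len(n), ref = "A", alt = "G",
             gene = sprintf("G%03d", seq_len(n)), func = func,
             exonic_func = exonic_func, type = type, conserved = conserved,
             segdup = segdup, dbsnp_id = dbsnp_id, maf_1000g = maf_1000g,
             maf_esp = maf_esp, stringsAsFactors = FALSE)
}

test_that("multi-allelic prefilter retains exactly the biallelic records", {
  sites <- c(
    lapply(1:7, function(i) site_genotypes("1", i, "A", "G", c(S = 1))),
    lapply(8:10, function(i) {
      site_genotypes("1", i, "A", c("G", "T"), c(S = 1))
    })
  )
  res <- prefilter_multiallelic(sites)
  expect_length(res$sites, 7)
  expect_equal(res$n_dropped, 3)
  expect_true(all(vapply(res$sites, function(s) length(s$alt) == 1,
                         logical(1))))
})

test_that("each cascade step drops exactly its predicate's failures", {
  pass <- mk_records(1)
  res <- run_cascade(pass)
  expect_equal(nrow(res$survivors), 1)
  expect_equal(res$report$snvs, rep(1, 7))

  common <- mk_records(1, maf_1000g = 0.20)
  res2 <- run_cascade(common)
  expect_equal(nrow(res2$survivors), 0)
  expect_equal(res2$report$snvs[res2$report$step == "maf_below_threshold"], 0)
  expect_equal(res2$report$snvs[res2$report$step == "not_dbsnp"], 1)

  # boundary: af exactly at the threshold is dropped (strict <)
  at <- run_cascade(mk_records(1, maf_1000g = 0.05))
  expect_equal(nrow(at$survivors), 0)
  below <- run_cascade(mk_records(1, maf_1000g = 0.049))
  expect_equal(nrow(below$survivors), 1)

  # synonymous exclusion applies to SNVs only
  syn_snv <- mk_records(1, exonic_func = "synonymous SNV")
  expect_equal(nrow(run_cascade(syn_snv)$survivors), 0)
  indel <- mk_records(1, exonic_func = "nonframeshift indel", type = "indel")
  expect_equal(nrow(run_cascade(indel)$survivors), 1)
})

test_that("a planted survivor set is recovered exactly, with faithful accounting", {
  withr::local_seed(99)
  # 500 records; 12 planted to pass every predicate, the rest each fail
  # at least one randomly chosen step
  n <- 500
  rec <- mk_records(n)
  planted <- sample.int(n, 12)
  bg <- setdiff(seq_len(n), planted)
  fail_step <- sample(1:6, length(bg), replace = TRUE)
  rec$func[bg[fail_step == 1]] <- "intronic"
  rec$exonic_func[bg[fail_step == 2]] <- "synonymous SNV"
  rec$conserved[bg[fail_step == 3]] <- FALSE
  rec$segdup[bg[fail_step == 4]] <- TRUE
  rec$dbsnp_id[bg[fail_step == 5]] <- "rs1"
  rec$maf_1000g[bg[fail_step == 6]] <- 0.3

  res <- run_cascade(rec)
  expect_setequal(res$survivors$gene, rec$gene[planted])
  # counts non-increasing, first row equals input
  expect_equal(res$report$snvs[1], n)
  expect_true(all(diff(res$report$snvs) <= 0))
  expect_true(all(diff(res$report$indels) <= 0))
  # survivors satisfy the conjunction of all predicates, checked directly
  s <- res$survivors
  expect_true(all(s$func %in% c("exonic", "splicing") &
                    s$exonic_func != "synonymous SNV" & s$conserved &
                    !s$segdup & is.na(s$dbsnp_id) &
                    (is.na(s$maf_1000g) | s$maf_1000g < 0.05)))
})

test_that("step order does not change the survivor set (predicates independent)", {
  withr::local_seed(123)
  n <- 200
  rec <- mk_records(n,
                    func = sample(c("exonic", "intronic", "splicing"), n, TRUE),
                    exonic_func = sample(c("nonsynonymous SNV",
                                           "synonymous SNV"), n, TRUE),
                    conserved = sample(c(TRUE, FALSE), n, TRUE),
                    segdup = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
                    dbsnp_id = sample(c(NA, "rs9"), n, TRUE),
                    maf_1000g = sample(c(NA, 0.01, 0.3), n, TRUE))
  res <- run_cascade(rec)
  # independent conjunction evaluation on the input
  keep <- rec$func %in% c("exonic", "splicing") &
    !(rec$type == "SNV" & rec$exonic_func == "synonymous SNV") &
    rec$conserved & !rec$segdup & is.na(rec$dbsnp_id) &
    (is.na(rec$maf_1000g) | rec$maf_1000g < 0.05)
  expect_setequal(res$survivors$gene, rec$gene[keep])
})

test_that("interval overlap agrees with a per-base brute-force scan", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # 0-based half-open: [10,15) -> 1-based 11..15 ; [30,31) -> base 31
  writeLines(c("1\t10\t15", "1\t30\t31", "2\t0\t5"), bed)
  gr <- pedexome:::read_bed_granges(bed)
  covered <- list(`1` = c(11:15, 31), `2` = 1:5)
  rec <- data.frame(chrom = rep(c("1", "2"), each = 40),
                    pos = rep(1:40, 2), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  got <- pedexome:::overlaps_intervals(rec, gr)
  want <- mapply(function(ch, p) p %in% covered[[ch]], rec$chrom, rec$pos)
  expect_equal(got, unname(want))

  # a 3-base deletion span overlaps an interval its start misses
  rec2 <- data.frame(chrom = "1", pos = 9, ref = "AAA", alt = "A",
                     stringsAsFactors = FALSE)
  expect_true(pedexome:::overlaps_intervals(rec2, gr))
})

test_that("novelty filter removes any variant with a frequency entry in either panel", {
  withr::local_seed(4)
  surv <- mk_records(52)
  known <- sample.int(52, 33)
  half <- known[1:16]
  surv$maf_1000g[half] <- 0.01           # rare but known: still removed
  surv$maf_esp[setdiff(known, half)] <- 0.002
  res <- novelty_filter(surv)
  expect_equal(res$n_known, 33)
  expect_equal(nrow(res$candidates), 19)
  expect_true(all(is.na(res$candidates$maf_1000g) &
                    is.na(res$candidates$maf_esp)))
})

test_that("missing resource files raise a configuration error", {
  expect_error(read_resources("nope.bed", "nope2.bed", "no.tsv", "no.tsv",
                              "no.tsv"),
               "missing resource")
})
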