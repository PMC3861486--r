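ped <- study_pedigree()

test_that("study quintet genotypes are AD-consistent via the unsequenced father", {
  s <- site_genotypes("1", 156104651, "G", "T",
                      quintet_calls(0, 1, 1, 1, 0))
  expect_true(site_matches_model(s, ped, "AD"))
  # same observations cannot be AR: affected members are not hom-alt
  expect_false(site_matches_model(s, ped, "AR"))

  asn <- enumerate_assignments(s, ped, "AD")
  expect_gt(nrow(asn), 0)
  expect_true(all(asn[, "I-2"] >= 1))      # father forced to carry
  expect_true(all(asn[, "I-1"] == 0))      # unaffected uncle cannot carry
})

test_that("affected members without the risk allele refute the model", {
  s <- site_genotypes("2", 500, "A", "G", quintet_calls(0, 0, 0, 0, 0))
  expect_false(site_matches_model(s, ped, "AD"))
  expect_equal(nrow(enumerate_assignments(s, ped, "AD")), 0)
})

test_that("missing parent genotype is equivalent to union over all parent genotypes", {
  trio <- trio_pedigree()
  # father's call missing, mother het, affected child hom-alt under AR
  s <- site_genotypes("3", 1000, "C", "T",
                      seq_call(F = NA, M = 1, C = 2))
  expect_true(site_matches_model(s, trio, "AR"))

  # brute force over the three possible father genotypes
  by_hand <- vapply(0:2, function(fg) {
    site_matches_model(
      site_genotypes("3", 1000, "C", "T", seq_call(F = fg, M = 1, C = 2)),
      trio, "AR")
  }, logical(1))
  expect_equal(site_matches_model(s, trio, "AR"), any(by_hand))
  expect_equal(by_hand, c(FALSE, TRUE, FALSE))  # only a carrier father works
})

test_that("a member constrained only by affection enumerates exactly the risk genotypes", {
  duo <- pedigree(id = c("P", "Q"), sex = c("male", "female"),
                  affection = c("affected", "unknown"),
                  sequenced = c(FALSE, TRUE))
  s <- site_genotypes("4", 10, "G", "A", seq_call(Q = NA))
  asn <- enumerate_assignments(s, duo, "AD")
  expect_setequal(asn[, "P"], 1:2)
  expect_setequal(unique(asn[, "Q"]), 0:2)
})

test_that("Mendelian impossibility yields an empty enumeration", {
  trio <- trio_pedigree()
  s <- site_genotypes("5", 77, "T", "C", seq_call(F = 0, M = 0, C = 2))
  expect_equal(nrow(enumerate_assignments(s, trio, "AR")), 0)
  expect_false(site_matches_model(s, trio, "AR"))
})

test_that("XLR consistency with an affected female forces her father hemizygous alt", {
  xped <- pedigree(id = c("F", "M", "D"),
                   sex = c("male", "female", "female"),
                   affection = c("affected", "unaffected", "affected"),
                   father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"))
  s <- site_genotypes("X", 500, "G", "A", seq_call(M = 1, D = 2))
  asn <- enumerate_assignments(s, xped, "XLR")
  expect_gt(nrow(asn), 0)
  expect_true(all(asn[, "F"] == 1))
})

test_that("matcher agrees with the brute-force oracle on randomized observations", {
  withr::local_seed(42)
  peds <- list(trio_pedigree(), quartet_pedigree(), sixer_pedigree())
  for (p in peds) {
    seq_ids <- p$id[p$sequenced]
    for (model in c("AD", "AR", "XLD", "XLR")) {
      chrom <- if (model %in% c("AD", "AR")) "7" else "X"
      valid <- bf_valid_assignments(p, model)
      for (rep in 1:25) {
        calls <- vapply(seq_ids, function(m) {
          dom <- c(bf_domain(p$sex[match(m, p$id)], model), NA)
          dom[sample.int(length(dom), 1)]
        }, numeric(1))
        s <- site_genotypes(chrom, 1000 + rep, "A", "T",
                            stats::setNames(calls, seq_ids))
        expect_identical(site_matches_model(s, p, model),
                         bf_matches(valid, calls),
                         info = sprintf("model %s rep %d", model, rep))
      }
    }
  }
})

test_that("setting an observed call to missing never flips consistency to FALSE", {
  withr::local_seed(7)
  seq_ids <- ped$id[ped$sequenced]
  n_checked <- 0L
  for (model in c("AD", "AR")) {
    # observations projected from valid full assignments are consistent by
    # construction; masking any one call must preserve that
    valid <- bf_valid_assignments(ped, model)
    for (r in seq_len(min(nrow(valid), 15))) {
      calls <- valid[r, seq_ids]
      s <- site_genotypes("9", r, "G", "C", calls)
      expect_true(site_matches_model(s, ped, model))
      for (drop in seq_ids) {
        calls2 <- calls
        calls2[drop] <- NA
        s2 <- site_genotypes("9", r, "G", "C", calls2)
        expect_true(site_matches_model(s2, ped, model))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 0)
})

test_that("scope, key and capacity errors are raised", {
  s_x <- site_genotypes("X", 5, "A", "T", quintet_calls(0, 1, 1, 1, 0))
  expect_error(site_matches_model(s_x, ped, "AD"), "scope")
  s_1 <- site_genotypes("1", 5, "A", "T", quintet_calls(0, 1, 1, 1, 0))
  expect_error(site_matches_model(s_1, ped, "XLR"), "scope")

  s_bad <- site_genotypes("1", 5, "A", "T", c(NOBODY = 1))
  expect_error(site_matches_model(s_bad, ped, "AD"), "absent")
  s_unseq <- site_genotypes("1", 5, "A", "T", c(`I-2` = 1))
  expect_error(site_matches_model(s_unseq, ped, "AD"), "unsequenced")

  s_multi <- site_genotypes("1", 5, "A", c("T", "G"),
                            quintet_calls(0, 1, 1, 1, 0))
  expect_error(site_matches_model(s_multi, ped, "AD"), "biallelic")

  big <- pedigree(id = as.character(1:16), sex = "male",
                  affection = "unknown")
  s16 <- site_genotypes("1", 5, "A", "T", c(`1` = 0))
  expect_error(enumerate_assignments(s16, big, "AD"), "bound")
})

test_that("filter_by_inheritance buckets sites and drops Y/MT unconditionally", {
  ad_only <- site_genotypes("1", 156104651, "G", "T",
                            quintet_calls(0, 1, 1, 1, 0))
  # affected sibs hom-alt is impossible with a genotyped hom-ref mother
  impossible <- site_genotypes("2", 100, "A", "G",
                               quintet_calls(0, 2, 2, 2, 0))
  y_site <- site_genotypes("Y", 50, "A", "G",
                           c(`II-2` = 1, `II-3` = 1, `III-1` = 0))
  mt_site <- site_genotypes("MT", 60, "A", "G", quintet_calls(1, 1, 1, 1, 1))
  res <- filter_by_inheritance(list(ad_only, impossible, y_site, mt_site),
                               ped)

  expect_setequal(res$models, c("AD", "AR", "XLR"))
  expect_equal(res$dropped_chrom, 2)
  ad_pos <- vapply(res$buckets$AD, function(s) s$pos, integer(1))
  expect_equal(ad_pos, 156104651L)
  expect_length(res$buckets$AR, 0)
  expect_equal(res$counts$AD[["snvs"]], 1)

  empty <- filter_by_inheritance(list(), ped)
  expect_equal(lengths(empty$buckets),
               c(AD = 0L, AR = 0L, XLR = 0L))
})

test_that("a hom-alt affected singleton fits both AD and AR buckets", {
  solo <- pedigree(id = "P", sex = "female", affection = "affected")
  dual <- site_genotypes("2", 100, "A", "G", c(P = 2))
  res <- filter_by_inheritance(list(dual), solo, models = c("AD", "AR"))
  expect_length(res$buckets$AD, 1)
  expect_length(res$buckets$AR, 1)
})
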