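#' Packaged 19-candidate prediction-profile fixture
#'
#' The categorical predictor calls for the 19 family-specific candidate
#' variants of the studied conduction-disease family (one gene per row;
#' the SACM1L row is the intronic splice-site variant for which the
#' missense predictors produce no call). Column order: PhyloP, SIFT,
#' PolyPhen-2, LRT, MutationTaster, GERP++, SIFT 2013; values use the
#' alphabets of [prediction_profile()] with `NA` for "not applicable".
#'
#' Exactly one row — LMNA, the c.695G>T (p.Gly232Val) lamin A/C variant —
#' is damaging across all seven predictors.
#'
#' @return data.frame with columns `gene` plus the seven predictor columns.
#' @export
table4_fixture <- function() {
  rows <- list(
    c("SLC39A1", "C", "D", "P", "D", "D", "C", "T"),
    c("LMNA",    "C", "D", "D", "D", "D", "C", "D"),
    c("SACM1L",  NA,  NA,  NA,  NA,  NA,  "C", NA),
    c("ADH4",    "N", "D", "D", "N", "D", "C", "D"),
    c("MFSD8",   "N", "T", "P", "N", "D", "N", "T"),
    c("DLK2",    "C", "D", "D", "D", "N", "C", "T"),
    c("MDN1",    "C", "T", "B", "D", "N", "C", "T"),
    c("ODZ4",    NA,  NA,  NA,  NA,  NA,  "C", "B"),
    c("ANGPTL5", "C", "T", "D", "D", "D", "C", "T"),
    c("L2HGDH",  "C", "T", "P", "D", "D", "C", "T"),
    c("ZNF646",  "C", "T", "D", NA,  NA,  "C", "T"),
    c("LONP2",   "C", "T", "D", "D", "D", "C", "T"),
    c("MMP2",    "C", "T", "P", "D", "D", "C", "T"),
    c("ZFHX3",   "C", NA,  "P", "D", "D", "C", "T"),
    c("MVD",     "C", "D", "B", "D", "D", "C", "T"),
    c("KCNH6",   "C", "T", "D", "D", "D", "C", "T"),
    c("USF2",    "C", "T", "B", "N", "N", "C", "T"),
    c("MYH7B",   "C", NA,  NA,  "N", "N", "C", "T"),
    c("ARHGAP40", NA, NA,  NA,  NA,  NA,  "C", "T")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("gene", PREDICTOR_COLS)
  df
}

#' Packaged Sanger-validation fixture for the seven screened candidates
#'
#' Validation facts for the candidates taken to direct sequencing: the
#' four novel family-specific variants (LMNA chr1:156104651 G/T, MMP2
#' chr16:55519584 G/A, ZFHX3 chr16:72830334 G/A, ANGPTL5
#' chr11:101773401 C/T) with their extended-family genotypes and control
#' screens; the MYH7B variant (chr20:33588956 G/A) found in 2 of 100
#' controls; and the two sequencing-refuted calls (KCNH6, SACM1L). The
#' LMNA variant was additionally absent from 252 further controls, so its
#' panel size is 352. ZFHX3 and MMP2 are carried by the
#' unknown-phenotype grandson III-1; LMNA and ANGPTL5 are not.
#'
#' @return named list of [validation_record()] keyed by gene.
#' @export
table5_fixture <- function() {
  fam <- function(II2, II3, II4, I1, I3, III1) {
    c(`II-2` = II2, `II-3` = II3, `II-4` = II4,
      `I-1` = I1, `I-3` = I3, `III-1` = III1)
  }
  list(
    LMNA = validation_record("LMNA", fam(1, 1, 1, 0, 0, 0),
                             control_carrier_count = 0, control_n = 352),
    MMP2 = validation_record("MMP2", fam(1, 1, 1, 0, 0, 1),
                             control_carrier_count = 0, control_n = 100),
    ZFHX3 = validation_record("ZFHX3", fam(1, 1, 1, 0, 0, 1),
                              control_carrier_count = 0, control_n = 100),
    ANGPTL5 = validation_record("ANGPTL5", fam(1, 1, 1, 0, 0, 0),
                                control_carrier_count = 0, control_n = 100),
    MYH7B = validation_record("MYH7B",
                              control_carrier_count = 2, control_n = 100),
    KCNH6 = validation_record("KCNH6", validated = FALSE),
    SACM1L = validation_record("SACM1L", validated = FALSE)
  )
}

#' Genes previously linked to cardiovascular disease among the candidates
#'
#' The manually curated disease-gene subset of the 19 candidates used by
#' the ranking stage.
#'
#' @return character vector.
#' @export
cardiac_disease_genes <- function() {
  c("LMNA", "ZFHX3", "MMP2", "ANGPTL5", "MYH7B", "KCNH6")
}
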