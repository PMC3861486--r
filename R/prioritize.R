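#' Categorical prediction profile of one variant
#'
#' Seven categorical deleteriousness/conservation predictor calls:
#' PhyloP and GERP++ use C (conserved) / N (not conserved); SIFT and its
#' 2013 release D (deleterious) / T (tolerated) (SIFT 2013 may also emit
#' B, benign); PolyPhen-2 D (probably damaging) / P (possibly damaging) /
#' B (benign); LRT D / N (neutral); MutationTaster D / N (polymorphism).
#' `NA` marks a predictor that produced no call.
#'
#' @param phylop,sift,polyphen,lrt,mutation_taster,gerp,sift2013 single
#'   characters from the respective alphabets, or `NA`.
#' @return named character vector of class `prediction_profile`.
#' @export
prediction_profile <- function(phylop = NA, sift = NA, polyphen = NA,
                               lrt = NA, mutation_taster = NA, gerp = NA,
                               sift2013 = NA) {
  p <- c(phylop = as.character(phylop), sift = as.character(sift),
         polyphen = as.character(polyphen), lrt = as.character(lrt),
         mutation_taster = as.character(mutation_taster),
         gerp = as.character(gerp), sift2013 = as.character(sift2013))
  p[p %in% c("N/A", "NA", ".", "")] <- NA_character_
  alphabets <- list(phylop = c("C", "N"), sift = c("D", "T"),
                    polyphen = c("D", "P", "B"), lrt = c("D", "N"),
                    mutation_taster = c("D", "N"), gerp = c("C", "N"),
                    sift2013 = c("D", "T", "B"))
  for (nm in names(alphabets)) {
    if (!is.na(p[[nm]]) && !p[[nm]] %in% alphabets[[nm]]) {
      stop(nm, " value '", p[[nm]], "' outside alphabet {",
           paste(alphabets[[nm]], collapse = ","), ",NA}", call. = FALSE)
    }
  }
  class(p) <- "prediction_profile"
  p
}

#' Strict consensus deleteriousness call
#'
#' A variant is consensus-deleterious only when every one of the seven
#' predictors made a call and every call is damaging: C for PhyloP and
#' GERP++, D for SIFT, PolyPhen-2, LRT, MutationTaster and SIFT 2013.
#' "Possibly damaging" (P), tolerated (T), benign (B), neutral (N) and
#' missing calls all break the consensus. With `lenient = TRUE`,
#' PolyPhen-2 P also counts as damaging (the strict rule is the default
#' and is what isolates a single candidate on the packaged 19-row
#' fixture).
#'
#' @param profile a [prediction_profile()] (or coercible named vector).
#' @param lenient accept PolyPhen-2 "P" as damaging.
#' @return logical.
#' @export
#' @examples
#' consensus_deleterious(prediction_profile("C","D","D","D","D","C","D"))
consensus_deleterious <- function(profile, lenient = FALSE) {
  p <- unclass(profile)[PREDICTOR_COLS]
  if (anyNA(p)) return(FALSE)
  damaging <- list(phylop = "C", sift = "D",
                   polyphen = if (lenient) c("D", "P") else "D",
                   lrt = "D", mutation_taster = "D", gerp = "C",
                   sift2013 = "D")
  all(vapply(PREDICTOR_COLS, function(nm) p[[nm]] %in% damaging[[nm]],
             logical(1)))
}

#' Sanger validation facts for one candidate variant
#'
#' @param key site key string `chrom:pos:ref:alt` (or a gene label when
#'   keys are gene-level).
#' @param family_genotypes named alt-count vector over the Sanger-typed
#'   extended family (may include unsequenced members).
#' @param control_carrier_count carriers among screened healthy controls.
#' @param control_n number of controls screened (data-driven; the screen
#'   used at least 100).
#' @param validated `FALSE` marks a sequencing-refuted call (calling
#'   error).
#' @return object of class `validation_record`.
#' @export
validation_record <- function(key, family_genotypes = NULL,
                              control_carrier_count = NA_integer_,
                              control_n = NA_integer_, validated = TRUE) {
  if (!is.na(control_carrier_count) && !is.na(control_n) &&
      (control_carrier_count < 0 || control_carrier_count > control_n)) {
    stop("carriers must lie in [0, control_n]", call. = FALSE)
  }
  structure(list(key = key, family_genotypes = family_genotypes,
                 control_carrier_count = as.integer(control_carrier_count),
                 control_n = as.integer(control_n),
                 validated = isTRUE(validated)),
            class = "validation_record")
}

#' Control-panel screen
#'
#' A validated variant carried by any of the screened healthy controls is
#' classed a polymorphism; one absent from every control is
#' family-specific. Calling errors (`validated = FALSE`) must be excluded
#' upstream.
#'
#' @param record a [validation_record()] with `validated = TRUE`.
#' @return `"polymorphism"` or `"family_specific"`.
#' @export
control_screen <- function(record) {
  if (!record$validated) {
    stop("control_screen requires a validated record; calling errors are ",
         "excluded upstream", call. = FALSE)
  }
  if (is.na(record$control_carrier_count)) {
    stop("control carrier count unknown", call. = FALSE)
  }
  if (record$control_carrier_count >= 1L) "polymorphism" else "family_specific"
}

#' Family cosegregation check
#'
#' Under a dominant carrier reading, the variant cosegregates when every
#' affected member carries it and no unaffected member does. Carriers of
#' unknown affection are listed as uninformative rather than violations.
#'
#' @param record a [validation_record()] whose `family_genotypes` cover at
#'   least one affected and one unaffected member.
#' @param ped a [pedigree()].
#' @return list with `status` (`"cosegregates"` or `"violated"`) and
#'   `uninformative_carriers`.
#' @export
cosegregation_check <- function(record, ped) {
  g <- record$family_genotypes
  if (is.null(g) || !length(g)) {
    stop("no family genotypes in validation record", call. = FALSE)
  }
  ids <- names(g)
  aff <- ped$affection[match(ids, ped$id)]
  if (anyNA(aff)) {
    stop("genotyped members absent from pedigree: ",
         paste(ids[is.na(aff)], collapse = ", "), call. = FALSE)
  }
  informative <- aff %in% c("affected", "unaffected") & !is.na(g)
  if (!any(aff[informative] == "affected") ||
      !any(aff[informative] == "unaffected")) {
    stop("cosegregation indeterminate: need at least one informative ",
         "affected and one informative unaffected member", call. = FALSE)
  }
  carrier <- !is.na(g) & g >= 1L
  violated <- any(aff == "affected" & !is.na(g) & !carrier) ||
    any(aff == "unaffected" & carrier)
  list(status = if (violated) "violated" else "cosegregates",
       uninformative_carriers = ids[aff == "unknown" & carrier])
}

#' Rank candidate variants by converging evidence
#'
#' Candidates refuted by Sanger validation (calling errors) are removed.
#' The rest are ordered deterministically by: strict consensus
#' deleteriousness, then family specificity (absent from all controls),
#' then cosegregation with the phenotype, then membership in a
#' user-supplied disease-gene list, with an alphabetical gene-name
#' tie-break. Predicates that cannot be evaluated (no validation record,
#' indeterminate cosegregation) count as not satisfied.
#'
#' @param candidates data.frame with at least `gene` plus the seven
#'   predictor columns (as produced by [annotate_records()] /
#'   [novelty_filter()], or the packaged fixture).
#' @param validations named list of [validation_record()] keyed by gene
#'   (or site key matching `candidates$gene`).
#' @param ped a [pedigree()] for cosegregation.
#' @param disease_genes character vector of genes previously linked to the
#'   phenotype.
#' @param lenient passed to [consensus_deleterious()].
#' @return data.frame ordered best-first with logical predicate columns
#'   `consensus`, `family_specific`, `cosegregates`, `disease_gene`,
#'   `rank`, and `n_calling_errors` as an attribute.
#' @export
rank_candidates <- function(candidates, validations = list(), ped = NULL,
                            disease_genes = character(0), lenient = FALSE) {
  if (!nrow(candidates)) {
    out <- cbind(candidates,
                 data.frame(consensus = logical(0),
                            family_specific = logical(0),
                            cosegregates = logical(0),
                            disease_gene = logical(0),
                            rank = integer(0)))
    attr(out, "n_calling_errors") <- 0L
    return(out)
  }
  key_of <- function(i) {
    g <- candidates$gene[i]
    if (!is.null(validations[[g]])) g
    else if (all(c("chrom", "pos", "ref", "alt") %in% names(candidates))) {
      site_key(candidates[i, ])
    } else g
  }
  n <- nrow(candidates)
  have_pred <- all(PREDICTOR_COLS %in% names(candidates))
  consensus <- logical(n); fam_spec <- logical(n); coseg <- logical(n)
  calling_error <- logical(n)
  for (i in seq_len(n)) {
    consensus[i] <- if (have_pred) {
      prof <- do.call(prediction_profile,
                      as.list(candidates[i, PREDICTOR_COLS]))
      consensus_deleterious(prof, lenient = lenient)
    } else {
      FALSE
    }
    v <- validations[[key_of(i)]]
    if (!is.null(v)) {
      if (!v$validated) {
        calling_error[i] <- TRUE
        next
      }
      fam_spec[i] <- !is.na(v$control_carrier_count) &&
        identical(control_screen(v), "family_specific")
      if (!is.null(ped) && !is.null(v$family_genotypes)) {
        res <- tryCatch(cosegregation_check(v, ped), error = function(e) NULL)
        coseg[i] <- !is.null(res) && res$status == "cosegregates"
      }
    }
  }
  out <- candidates[!calling_error, , drop = FALSE]
  consensus <- consensus[!calling_error]
  fam_spec <- fam_spec[!calling_error]
  coseg <- coseg[!calling_error]
  out$consensus <- consensus
  out$family_specific <- fam_spec
  out$cosegregates <- coseg
  out$disease_gene <- out$gene %in% disease_genes
  o <- order(-out$consensus, -out$family_specific, -out$cosegregates,
             -out$disease_gene, out$gene)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_calling_errors") <- sum(calling_error)
  out
}

#' Read prediction profiles from a TSV
#'
#' Header `chrom, pos, ref, alt` (or `gene`) plus the seven predictor
#' columns; `N/A`, `NA`, `.` and empty strings are treated as missing.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("N/A", "NA", ".", ""))
  if ("chrom" %in% names(tab)) tab$chrom <- norm_chrom(tab$chrom)
  tab
}
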