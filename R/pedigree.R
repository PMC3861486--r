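#' Construct a pedigree
#'
#' A pedigree is the family structure against which inheritance-model
#' consistency of variant sites is tested: members with sex, affection
#' status, parent links, and a flag marking which members were sequenced.
#'
#' @param id character vector of unique member identifiers.
#' @param sex character, `"male"` or `"female"` (or PED codes 1/2).
#' @param affection character, `"affected"`, `"unaffected"` or `"unknown"`
#'   (or PED codes 2/1/0).
#' @param father_id,mother_id character vectors of parent identifiers;
#'   `NA` for founders or unrecorded parents.
#' @param sequenced logical, whether the member's genotypes are observed in
#'   the variant calls.
#'
#' @details Invariants enforced at construction: ids unique; a named father
#' is male and a named mother female; the parent graph is acyclic; at least
#' one member is sequenced. A member may have one recorded parent and one
#' unrecorded parent (e.g. a child whose spouse parent was never enrolled);
#' the unrecorded side contributes an unconstrained gamete during
#' consistency testing.
#'
#' @return An object of class `pedigree`: a data.frame with one row per
#'   member.
#' @seealso [applicable_models()], [site_matches_model()], [read_ped()]
#' @export
#' @examples
#' ped <- pedigree(
#'   id = c("F", "M", "C"),
#'   sex = c("male", "female", "male"),
#'   affection = c("unaffected", "unaffected", "affected"),
#'   father_id = c(NA, NA, "F"),
#'   mother_id = c(NA, NA, "M"),
#'   sequenced = c(TRUE, TRUE, TRUE)
#' )
pedigree <- function(id, sex, affection, father_id = NA, mother_id = NA,
                     sequenced = TRUE) {
  n <- length(id)
  sex <- norm_sex(rep_len(sex, n))
  affection <- norm_affection(rep_len(affection, n))
  father_id <- as.character(rep_len(father_id, n))
  mother_id <- as.character(rep_len(mother_id, n))
  father_id[father_id %in% c("0", "", ".")] <- NA_character_
  mother_id[mother_id %in% c("0", "", ".")] <- NA_character_
  ped <- data.frame(
    id = as.character(id), sex = sex, affection = affection,
    father_id = father_id, mother_id = mother_id,
    sequenced = as.logical(rep_len(sequenced, n)),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

norm_sex <- function(x) {
  x <- as.character(x)
  x[x == "1"] <- "male"
  x[x == "2"] <- "female"
  if (!all(x %in% c("male", "female"))) {
    stop("sex must be 'male'/'female' (or PED codes 1/2)", call. = FALSE)
  }
  x
}

norm_affection <- function(x) {
  x <- as.character(x)
  x[x == "1"] <- "unaffected"
  x[x == "2"] <- "affected"
  x[x %in% c("0", "-9")] <- "unknown"
  if (!all(x %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be 'affected'/'unaffected'/'unknown' (or 2/1/0)",
         call. = FALSE)
  }
  x
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("pedigree ids must be unique", call. = FALSE)
  }
  for (col in c("father_id", "mother_id")) {
    known <- !is.na(ped[[col]])
    bad <- known & !(ped[[col]] %in% ped$id)
    if (any(bad)) {
      stop("unknown ", col, ": ", paste(ped[[col]][bad], collapse = ", "),
           call. = FALSE)
    }
  }
  fa <- ped$father_id[!is.na(ped$father_id)]
  if (any(ped$sex[match(fa, ped$id)] != "male")) {
    stop("a named father must be male", call. = FALSE)
  }
  mo <- ped$mother_id[!is.na(ped$mother_id)]
  if (any(ped$sex[match(mo, ped$id)] != "female")) {
    stop("a named mother must be female", call. = FALSE)
  }
  if (is.null(topo_order(ped))) {
    stop("pedigree parent graph is cyclic (a member is its own ancestor)",
         call. = FALSE)
  }
  if (!any(ped$sequenced)) {
    stop("pedigree must contain at least one sequenced member", call. = FALSE)
  }
  invisible(ped)
}

# Topological order of members (parents before children); NULL if cyclic.
topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- character(0)
  remaining <- ped$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(m) {
      i <- match(m, ped$id)
      ok_f <- is.na(ped$father_id[i]) || ped$father_id[i] %in% placed
      ok_m <- is.na(ped$mother_id[i]) || ped$mother_id[i] %in% placed
      ok_f && ok_m
    }, logical(1))
    if (!any(ready)) return(NULL)
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "members (",
      sum(x$sequenced), "sequenced,",
      sum(x$affection == "affected"), "affected )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' The studied conduction-disease family
#'
#' The seven-member, two-generation-plus-grandson pedigree used throughout
#' the package as default fixture and simulation template: an affected
#' father (I-2, deceased, not sequenced), his unaffected brother (I-1), the
#' unaffected mother (I-3), three affected siblings (II-2, II-3 male;
#' II-4 female) and a grandson (III-1) of uncertain phenotype. Five members
#' were exome sequenced: I-3, II-2, II-3, II-4 and III-1.
#'
#' @return A [pedigree()] object with 7 members.
#' @export
study_pedigree <- function() {
  pedigree(
    id        = c("I-1", "I-2", "I-3", "II-2", "II-3", "II-4", "III-1"),
    sex       = c("male", "male", "female", "male", "male", "female", "male"),
    affection = c("unaffected", "affected", "unaffected",
                  "affected", "affected", "affected", "unknown"),
    father_id = c(NA, NA, NA, "I-2", "I-2", "I-2", "II-2"),
    mother_id = c(NA, NA, NA, "I-3", "I-3", "I-3", NA),
    sequenced = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Read a pedigree from a PED file
#'
#' Standard 6-column whitespace-delimited PED (family, id, father, mother,
#' sex 1=male/2=female, phenotype 1=unaffected/2=affected/0=unknown). An
#' optional 7th column `sequenced` (0/1) is honoured; otherwise sequenced
#' status can be supplied via `sequenced_ids`, defaulting to all members.
#'
#' @param path PED file path.
#' @param sequenced_ids optional character vector of sequenced member ids.
#' @return A [pedigree()] object (first family in the file).
#' @export
read_ped <- function(path, sequenced_ids = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file must have >= 6 columns", call. = FALSE)
  fam <- tab[tab[[1]] == tab[[1]][1], , drop = FALSE]
  seq_flag <- if (ncol(fam) >= 7) {
    fam[[7]] %in% c("1", "TRUE", "yes")
  } else if (!is.null(sequenced_ids)) {
    fam[[2]] %in% sequenced_ids
  } else {
    rep(TRUE, nrow(fam))
  }
  pedigree(
    id = fam[[2]], sex = fam[[5]], affection = fam[[6]],
    father_id = fam[[3]], mother_id = fam[[4]], sequenced = seq_flag
  )
}

#' Write a pedigree to a PED file
#'
#' Emits the 6 standard columns plus a 7th `sequenced` 0/1 column.
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @param family family identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  out <- data.frame(
    family = family,
    id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    phenotype = c(unaffected = 1L, affected = 2L, unknown = 0L)[ped$affection],
    sequenced = as.integer(ped$sequenced)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Determine which inheritance models the pedigree structure allows
#'
#' Applies the structural exclusion rules used when screening a family for
#' a fully penetrant monogenic trait:
#' \itemize{
#'   \item Y-linked inheritance is excluded as soon as any affected member
#'     is female (females carry no Y).
#'   \item Mitochondrial inheritance is excluded when some affected member
#'     has an unaffected mother while its father is affected: mitochondria
#'     are transmitted almost exclusively through the mother, so a paternal
#'     disease origin rules the model out.
#'   \item X-linked dominant inheritance is excluded by male-to-male
#'     transmission (an affected father with an affected son): a father
#'     never passes his X to a son.
#'   \item Autosomal dominant (AD) and recessive (AR) are always retained;
#'     X-linked recessive (XLR) is retained by default, per-site genotype
#'     consistency being left to [site_matches_model()].
#' }
#'
#' @param ped a [pedigree()].
#' @return A list with `models` (character subset of AD, AR, XLD, XLR) and
#'   `excluded` (subset of Y, MT, XLD with the exclusion reason as names).
#' @export
#' @examples
#' applicable_models(study_pedigree())
applicable_models <- function(ped) {
  validate_pedigree(ped)
  excluded <- character(0)
  affected <- ped$id[ped$affection == "affected"]

  if (any(ped$sex[match(affected, ped$id)] == "female")) {
    excluded <- c(excluded, Y = "affected female present")
  }

  # paternal disease origin: affected child, unaffected mother, affected father
  for (m in affected) {
    i <- match(m, ped$id)
    mo <- ped$mother_id[i]
    fa <- ped$father_id[i]
    if (!is.na(mo) && !is.na(fa) &&
        ped$affection[match(mo, ped$id)] == "unaffected" &&
        ped$affection[match(fa, ped$id)] == "affected") {
      excluded <- c(excluded, MT = "paternal disease origin")
      break
    }
  }

  # male-to-male transmission among affecteds
  male_aff <- affected[ped$sex[match(affected, ped$id)] == "male"]
  for (m in male_aff) {
    sons <- ped$id[!is.na(ped$father_id) & ped$father_id == m &
                     ped$sex == "male" & ped$affection == "affected"]
    if (length(sons)) {
      excluded <- c(excluded, XLD = "male-to-male transmission")
      break
    }
  }

  models <- c("AD", "AR", "XLD", "XLR")
  if ("XLD" %in% names(excluded)) models <- setdiff(models, "XLD")
  list(models = models, excluded = excluded)
}

#' Chromosome scope of an inheritance model
#'
#' @param model one of `"AD"`, `"AR"`, `"XLD"`, `"XLR"`.
#' @return `"autosome"` or `"X"`.
#' @export
model_scope <- function(model) {
  model <- match.arg(model, c("AD", "AR", "XLD", "XLR"))
  if (model %in% c("AD", "AR")) "autosome" else "X"
}

# Normalize chromosome names: strip "chr" prefix, uppercase X/Y/MT.
norm_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[toupper(x) %in% c("X", "Y")] <- toupper(x[toupper(x) %in% c("X", "Y")])
  x[toupper(x) %in% c("M", "MT")] <- "MT"
  x
}

chrom_class <- function(chrom) {
  x <- norm_chrom(chrom)
  ifelse(x == "X", "X",
         ifelse(x == "Y", "Y",
                ifelse(x == "MT", "MT", "autosome")))
}
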