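#' Genotype calls at one variant site across sequenced family members
#'
#' A `site_genotypes` object holds one locus (chrom, 1-based pos, ref and
#' alt alleles) and the observed genotype calls of the sequenced pedigree
#' members, coded as alt-allele counts: 0, 1 or 2 on diploid chromosomes,
#' 0 or 1 hemizygous for males on X, and `NA` for a missing call (`./.`).
#'
#' @param chrom chromosome name (with or without `chr` prefix; `M`/`MT`
#'   both accepted for mitochondria).
#' @param pos 1-based position.
#' @param ref,alt allele strings; `alt` of length > 1 marks a multi-allelic
#'   record, which downstream model matching refuses (see
#'   [prefilter_multiallelic()]).
#' @param calls named integer vector of alt-allele counts keyed by member id.
#' @return An object of class `site_genotypes`.
#' @export
#' @examples
#' site_genotypes("1", 156104651, "G", "T",
#'                c(`I-3` = 0, `II-2` = 1, `II-3` = 1, `II-4` = 1,
#'                  `III-1` = 0))
site_genotypes <- function(chrom, pos, ref, alt, calls) {
  stopifnot(length(chrom) == 1, length(pos) == 1, length(ref) == 1)
  calls <- stats::setNames(as.integer(calls), names(calls))
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    stop("calls must be a named vector keyed by member id", call. = FALSE)
  }
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) stop("alt-allele counts must be 0, 1, 2 or NA", call. = FALSE)
  structure(
    list(chrom = norm_chrom(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt), calls = calls),
    class = "site_genotypes"
  )
}

#' @export
print.site_genotypes <- function(x, ...) {
  cat(sprintf("Site %s:%d %s>%s | %s\n", x$chrom, x$pos, x$ref,
              paste(x$alt, collapse = ","),
              paste(names(x$calls), x$calls, sep = "=", collapse = " ")))
  invisible(x)
}

is_biallelic <- function(site) length(site$alt) == 1L

#' Read variant sites and genotypes from a VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) with `VariantAnnotation` and
#' returns one [site_genotypes()] per record. GT is read unphased; any
#' missing allele (`./.` or `.`) yields a missing call. Sample columns are
#' restricted to the sequenced members of `ped` when given; samples absent
#' from the pedigree raise an error.
#'
#' Male genotypes on X are re-coded hemizygous: any call carrying the alt
#' allele becomes 1 (a heterozygous-coded male X call is treated as an alt
#' hemizygote; true heterozygosity is impossible outside pseudo-autosomal
#' regions, which are treated as X here).
#'
#' @param path VCF path.
#' @param ped optional [pedigree()] used to check/restrict sample columns.
#' @return list of `site_genotypes` (multi-allelic records included; filter
#'   with [prefilter_multiallelic()]).
#' @export
read_vcf_sites <- function(path, ped = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  samples <- colnames(gt)
  if (!is.null(ped)) {
    seq_ids <- ped$id[ped$sequenced]
    missing_ped <- setdiff(samples, ped$id)
    if (length(missing_ped)) {
      stop("VCF samples not in pedigree: ",
           paste(missing_ped, collapse = ", "), call. = FALSE)
    }
    gt <- gt[, intersect(samples, seq_ids), drop = FALSE]
    samples <- colnames(gt)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- lapply(rr$ALT, as.character)
  male_ids <- if (is.null(ped)) character(0) else ped$id[ped$sex == "male"]

  lapply(seq_along(pos), function(i) {
    counts <- parse_gt(gt[i, ])
    site_chrom <- norm_chrom(chrom[i])
    if (site_chrom %in% c("X", "Y")) {
      is_male <- names(counts) %in% male_ids
      counts[is_male & !is.na(counts) & counts > 0L] <- 1L
    }
    site_genotypes(site_chrom, pos[i], ref[i], alt_list[[i]], counts)
  })
}

# "0/1", "0|1", "1", "./.", "." -> alt-allele count (NA if any allele missing)
parse_gt <- function(gt_strings) {
  vapply(strsplit(gsub("\\|", "/", gt_strings), "/", fixed = TRUE),
         function(alleles) {
           if (any(alleles == ".")) return(NA_integer_)
           sum(alleles != "0")
         }, integer(1)) |>
    stats::setNames(names(gt_strings))
}

#' Write sites and genotypes to a minimal multi-sample VCF
#'
#' Emits a VCFv4.2 file with GT-only FORMAT. Autosomal calls are written
#' diploid (`0/0`, `0/1`, `1/1`), male X/Y calls hemizygous (`0`, `1`), and
#' missing calls `./.`.
#'
#' @param sites list of [site_genotypes()] (all with the same call names,
#'   in the same order).
#' @param path output path.
#' @param ped optional pedigree for male hemizygous coding on X/Y.
#' @return `path`, invisibly.
#' @export
write_vcf_sites <- function(sites, path, ped = NULL) {
  samples <- if (length(sites)) {
    names(sites[[1]]$calls)
  } else if (!is.null(ped)) {
    ped$id[ped$sequenced]
  } else {
    character(0)
  }
  male_ids <- if (is.null(ped)) character(0) else ped$id[ped$sex == "male"]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedexome",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  ), con)
  if (!length(sites)) return(invisible(path))
  ord <- order(vapply(sites, function(s) chrom_sort_key(s$chrom), numeric(1)),
               vapply(sites, function(s) s$pos, integer(1)))
  lines <- vapply(sites[ord], function(s) {
    hemi <- s$chrom %in% c("X", "Y") & samples %in% male_ids
    gt <- vapply(seq_along(samples), function(j) {
      g <- s$calls[[samples[j]]]
      if (is.na(g)) return("./.")
      if (hemi[j]) as.character(min(g, 1L))
      else c("0/0", "0/1", "1/1")[g + 1L]
    }, character(1))
    paste(c(s$chrom, s$pos, ".", s$ref, paste(s$alt, collapse = ","),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

chrom_sort_key <- function(chrom) {
  x <- norm_chrom(chrom)
  suppressWarnings(k <- as.numeric(x))
  if (!is.na(k)) k else switch(x, X = 23, Y = 24, MT = 25, 26)
}
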