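#' Drop multi-allelic records
#'
#' Loci with more than one alternate allele are removed before any model
#' matching: downstream consistency testing and annotation assume strictly
#' biallelic sites (one ref + one alt). The number dropped is reported.
#'
#' @param sites list of [site_genotypes()].
#' @return list with `sites` (biallelic only) and `n_dropped`.
#' @export
prefilter_multiallelic <- function(sites) {
  keep <- vapply(sites, is_biallelic, logical(1))
  list(sites = sites[keep], n_dropped = sum(!keep))
}

#' Build annotation records for a set of sites
#'
#' Joins consequence calls with the annotation resources: conservation and
#' segmental-duplication interval overlap (BED, 0-based half-open on disk,
#' overlap meaning at least one shared base with the variant's reference
#' span), dbSNP membership and population allele frequencies keyed by
#' (chrom, pos, ref, alt), and categorical prediction profiles.
#'
#' @param sites list of biallelic [site_genotypes()].
#' @param transcripts list of [transcript_model()].
#' @param resources a list as returned by [read_resources()]: elements
#'   `conserved` (GRanges), `segdup` (GRanges), `dbsnp`, `freq_1000g`,
#'   `freq_esp` (data.frames keyed chrom,pos,ref,alt with `af` for the
#'   frequency tables), `predictions` (data.frame with the seven
#'   categorical predictor columns).
#' @param splice_window passed to [classify_variant()].
#' @return data.frame (one row per site that classified cleanly) with the
#'   site key, gene, `func` (region class), `exonic_func`, HGVS fields,
#'   `conserved`, `segdup`, `dbsnp_id`, `maf_1000g`, `maf_esp`, `type`
#'   (SNV/indel) and prediction columns; reference-mismatch sites are
#'   skipped with a warning and counted in attribute `n_ref_mismatch`.
#' @export
annotate_records <- function(sites, transcripts, resources,
                             splice_window = 2L) {
  rows <- list()
  n_bad <- 0L
  for (s in sites) {
    cons <- tryCatch(classify_variant(transcripts, s, splice_window),
                     reference_mismatch = function(e) e)
    if (inherits(cons, "reference_mismatch")) {
      warning(conditionMessage(cons), call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    func <- switch(cons$category,
                   "intergenic" = "intergenic",
                   "intronic" = "intronic",
                   "UTR" = "UTR",
                   "splicing" = "splicing",
                   "exonic")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      gene = if (is.na(cons$gene)) NA_character_ else cons$gene,
      func = func,
      exonic_func = if (func == "exonic") cons$category else NA_character_,
      hgvs_c = cons$hgvs_c, hgvs_p = cons$hgvs_p,
      type = if (is_snv(s)) "SNV" else "indel",
      stringsAsFactors = FALSE
    )
  }
  rec <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), func = character(0),
    exonic_func = character(0), hgvs_c = character(0),
    hgvs_p = character(0), type = character(0), stringsAsFactors = FALSE)

  rec$conserved <- overlaps_intervals(rec, resources$conserved)
  rec$segdup <- overlaps_intervals(rec, resources$segdup)
  rec$dbsnp_id <- lookup_key_column(rec, resources$dbsnp, "id")
  rec$maf_1000g <- lookup_key_column(rec, resources$freq_1000g, "af")
  rec$maf_esp <- lookup_key_column(rec, resources$freq_esp, "af")
  if (!is.null(resources$predictions)) {
    rec <- merge_predictions(rec, resources$predictions)
  }
  attr(rec, "n_ref_mismatch") <- n_bad
  rec
}

# overlap of the variant's reference span with a GRanges (>=1 shared base)
overlaps_intervals <- function(rec, gr) {
  if (!nrow(rec)) return(logical(0))
  if (is.null(gr) || !length(gr)) return(rep(FALSE, nrow(rec)))
  q <- GenomicRanges::GRanges(
    rec$chrom,
    IRanges::IRanges(rec$pos, rec$pos + pmax(nchar(rec$ref) - 1L, 0L))
  )
  # differing seqlevel universes between query and resource are expected
  suppressWarnings(IRanges::overlapsAny(q, gr, ignore.strand = TRUE))
}

site_key <- function(df) {
  paste(norm_chrom(df$chrom), df$pos, df$ref, df$alt, sep = ":")
}

lookup_key_column <- function(rec, table, column) {
  if (!nrow(rec)) {
    return(if (column == "af") numeric(0) else character(0))
  }
  empty <- if (column == "af") NA_real_ else NA_character_
  if (is.null(table) || !nrow(table)) return(rep(empty, nrow(rec)))
  m <- match(site_key(rec), site_key(table))
  out <- table[[column]][m]
  if (column == "af") as.numeric(out) else as.character(out)
}

PREDICTOR_COLS <- c("phylop", "sift", "polyphen", "lrt",
                    "mutation_taster", "gerp", "sift2013")

merge_predictions <- function(rec, pred) {
  m <- match(site_key(rec), site_key(pred))
  for (col in PREDICTOR_COLS) {
    rec[[col]] <- if (col %in% names(pred)) {
      as.character(pred[[col]][m])
    } else {
      NA_character_
    }
  }
  rec
}

#' Run the staged annotation filter cascade
#'
#' Applies, in order: (1) keep variants whose region class is exonic or
#' splicing; (2) drop synonymous SNVs (indels are not touched by this
#' step); (3) keep variants in conserved regions; (4) drop variants in
#' segmental duplications; (5) drop dbSNP members; (6) drop variants whose
#' population allele frequency is at or above `maf_threshold` (variants
#' with no frequency entry are retained — absence of evidence of
#' commonness). Counts of surviving SNVs and indels are recorded after
#' every step.
#'
#' @param records annotation data.frame from [annotate_records()].
#' @param maf_threshold drop when `maf_1000g >= maf_threshold`
#'   (default 0.05, the rare-variant ceiling).
#' @return list with `survivors` (data.frame) and `report` (a
#'   `cascade_report` data.frame: step, snvs, indels; counts are
#'   non-increasing and the first row is the input size).
#' @export
run_cascade <- function(records, maf_threshold = 0.05) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1)
  steps <- list(
    exonic_or_splicing = function(r) r$func %in% c("exonic", "splicing"),
    drop_synonymous = function(r) {
      !(r$type == "SNV" & !is.na(r$exonic_func) &
          r$exonic_func == "synonymous SNV")
    },
    conserved = function(r) r$conserved,
    not_segdup = function(r) !r$segdup,
    not_dbsnp = function(r) is.na(r$dbsnp_id),
    maf_below_threshold = function(r) {
      is.na(r$maf_1000g) | r$maf_1000g < maf_threshold
    }
  )
  report <- data.frame(step = "input",
                       snvs = sum(records$type == "SNV"),
                       indels = sum(records$type == "indel"),
                       stringsAsFactors = FALSE)
  cur <- records
  for (nm in names(steps)) {
    keep <- steps[[nm]](cur)
    cur <- cur[keep, , drop = FALSE]
    report <- rbind(report, data.frame(
      step = nm, snvs = sum(cur$type == "SNV"),
      indels = sum(cur$type == "indel"), stringsAsFactors = FALSE))
  }
  class(report) <- c("cascade_report", "data.frame")
  list(survivors = cur, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Filter cascade accounting (retained after each step):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Novelty filter: drop variants known to either population panel
#'
#' Stricter than the cascade's frequency step: a survivor with \emph{any}
#' reported frequency entry in either the 1000 Genomes or the ESP exome
#' table — regardless of magnitude — is considered a known variant and
#' removed. The remainder are the novel candidate variants.
#'
#' @param survivors data.frame from [run_cascade()] (columns `maf_1000g`,
#'   `maf_esp` already joined).
#' @return list with `candidates` and `n_known`.
#' @export
novelty_filter <- function(survivors) {
  known <- !is.na(survivors$maf_1000g) | !is.na(survivors$maf_esp)
  list(candidates = survivors[!known, , drop = FALSE],
       n_known = sum(known))
}

#' Read cascade annotation resources from disk
#'
#' @param conserved_bed,segdup_bed BED interval files (0-based half-open;
#'   converted to 1-based inclusive GRanges on import).
#' @param dbsnp_tsv TSV with header `chrom, pos, ref, alt, id`.
#' @param freq_1000g_tsv,freq_esp_tsv TSVs with header
#'   `chrom, pos, ref, alt, af`.
#' @param predictions_tsv optional TSV with header `chrom, pos, ref, alt`
#'   plus the seven categorical predictor columns
#'   (`phylop, sift, polyphen, lrt, mutation_taster, gerp, sift2013`).
#' @return list of resources for [annotate_records()]. Missing mandatory
#'   files raise a configuration error.
#' @export
read_resources <- function(conserved_bed, segdup_bed, dbsnp_tsv,
                           freq_1000g_tsv, freq_esp_tsv,
                           predictions_tsv = NULL) {
  paths <- c(conserved_bed, segdup_bed, dbsnp_tsv, freq_1000g_tsv,
             freq_esp_tsv)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("missing resource file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  list(
    conserved = read_bed_granges(conserved_bed),
    segdup = read_bed_granges(segdup_bed),
    dbsnp = read_key_table(dbsnp_tsv),
    freq_1000g = read_key_table(freq_1000g_tsv),
    freq_esp = read_key_table(freq_esp_tsv),
    predictions = if (!is.null(predictions_tsv) &&
                      file.exists(predictions_tsv)) {
      read_key_table(predictions_tsv)
    }
  )
}

read_bed_granges <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::GRanges(norm_chrom(GenomicRanges::seqnames(gr)),
                         IRanges::ranges(gr))
}

read_key_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) return(tab)
  tab$chrom <- norm_chrom(tab$chrom)
  tab
}
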