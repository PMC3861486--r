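#' Pipeline configuration
#'
#' Bundles input paths and tuning parameters for [run_pipeline()]. All
#' referenced paths must exist at run time. A JSON file with the same
#' field names can be loaded with [read_pipeline_config()]; explicit
#' arguments override file values.
#'
#' @param vcf,ped,tx_tsv,cds_fasta,conserved_bed,segdup_bed,dbsnp_tsv,freq_1000g_tsv,freq_esp_tsv
#'   input file paths.
#' @param predictions_tsv,validations_tsv optional inputs.
#' @param maf_threshold cascade frequency ceiling in `[0,1]`.
#' @param splice_window splicing-call window in bases.
#' @param models `"auto"` or explicit model vector.
#' @param disease_genes character vector (or path to a one-gene-per-line
#'   file) of genes previously linked to the phenotype.
#' @param lenient lenient consensus (PolyPhen-2 P damaging).
#' @param out_dir optional directory for TSV/JSON reports.
#' @param verbose log per-step accounting with `message()`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, ped, tx_tsv, cds_fasta, conserved_bed,
                            segdup_bed, dbsnp_tsv, freq_1000g_tsv,
                            freq_esp_tsv, predictions_tsv = NULL,
                            validations_tsv = NULL, maf_threshold = 0.05,
                            splice_window = 2L, models = "auto",
                            disease_genes = character(0), lenient = FALSE,
                            out_dir = NULL, verbose = FALSE) {
  if (maf_threshold < 0 || maf_threshold > 1) {
    stop("maf_threshold must lie in [0,1]", call. = FALSE)
  }
  cfg <- list(vcf = vcf, ped = ped, tx_tsv = tx_tsv, cds_fasta = cds_fasta,
              conserved_bed = conserved_bed, segdup_bed = segdup_bed,
              dbsnp_tsv = dbsnp_tsv, freq_1000g_tsv = freq_1000g_tsv,
              freq_esp_tsv = freq_esp_tsv,
              predictions_tsv = predictions_tsv,
              validations_tsv = validations_tsv,
              maf_threshold = maf_threshold,
              splice_window = as.integer(splice_window), models = models,
              disease_genes = disease_genes, lenient = lenient,
              out_dir = out_dir, verbose = verbose)
  required <- c("vcf", "ped", "tx_tsv", "cds_fasta", "conserved_bed",
                "segdup_bed", "dbsnp_tsv", "freq_1000g_tsv", "freq_esp_tsv")
  absent <- required[!vapply(required, function(f) file.exists(cfg[[f]]),
                             logical(1))]
  if (length(absent)) {
    stop("missing input file(s): ",
         paste(unlist(cfg[absent]), collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror [pipeline_config()]
#'   arguments; relative paths are resolved against the JSON file's
#'   directory.
#' @param ... overrides passed on to [pipeline_config()].
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  pathfields <- c("vcf", "ped", "tx_tsv", "cds_fasta", "conserved_bed",
                  "segdup_bed", "dbsnp_tsv", "freq_1000g_tsv",
                  "freq_esp_tsv", "predictions_tsv", "validations_tsv")
  for (f in intersect(pathfields, names(vals))) {
    if (!is.null(vals[[f]]) && !grepl("^/", vals[[f]])) {
      vals[[f]] <- file.path(base, vals[[f]])
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full candidate-variant discovery pipeline
#'
#' Executes, with per-step accounting: multi-allelic pre-filter;
#' inheritance-model filtering of sites against the applicable models;
#' consequence annotation of the union of model-consistent sites; the
#' staged annotation cascade (per model, mirroring the step-by-model
#' accounting of the original workflow); the novelty filter against both
#' population panels; and consensus/validation-based ranking.
#'
#' @param config a [pipeline_config()], or `NULL` when `dataset` is given.
#' @param dataset optionally, an in-memory `family_dataset` from
#'   [simulate_family_dataset()]; file inputs are then ignored and the
#'   dataset's resources and validations are used (parameters such as
#'   `maf_threshold` may still be passed via `...`).
#' @param ... overrides of `maf_threshold`, `splice_window`, `models`,
#'   `disease_genes`, `lenient`, `verbose` when running from a dataset.
#' @return list of class `pipeline_result`: `report` (ranked candidates),
#'   `candidates`, `cascade_reports` (per model), `survivors`,
#'   `inheritance` (per-model counts, dropped-chromosome count),
#'   `accounting` (named step counts reconciling every stage) and
#'   `models`.
#' @export
run_pipeline <- function(config = NULL, dataset = NULL, ...) {
  opts <- list(maf_threshold = 0.05, splice_window = 2L, models = "auto",
               disease_genes = character(0), lenient = FALSE,
               verbose = FALSE)
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "family_dataset"))
    opts <- utils::modifyList(opts, list(...))
    sites <- dataset$sites
    ped <- dataset$ped
    transcripts <- dataset$transcripts
    resources <- dataset$resources
    validations <- dataset$validations
  } else {
    stopifnot(inherits(config, "pipeline_config"))
    opts <- utils::modifyList(
      opts, config[intersect(names(opts), names(config))])
    opts <- utils::modifyList(opts, list(...))
    ped <- read_ped(config$ped)
    sites <- read_vcf_sites(config$vcf, ped)
    transcripts <- read_transcripts(config$tx_tsv, config$cds_fasta)
    resources <- read_resources(config$conserved_bed, config$segdup_bed,
                                config$dbsnp_tsv, config$freq_1000g_tsv,
                                config$freq_esp_tsv,
                                config$predictions_tsv)
    validations <- if (!is.null(config$validations_tsv) &&
                       file.exists(config$validations_tsv)) {
      read_validations(config$validations_tsv)
    } else {
      list()
    }
  }
  say <- function(...) if (isTRUE(opts$verbose)) message(sprintf(...))

  n_input <- length(sites)
  pre <- prefilter_multiallelic(sites)
  say("input sites: %d (%d multi-allelic dropped)", n_input, pre$n_dropped)

  inh <- filter_by_inheritance(pre$sites, ped, opts$models)
  for (m in inh$models) {
    say("model %s: %d SNVs, %d indels consistent", m,
        inh$counts[[m]][["snvs"]], inh$counts[[m]][["indels"]])
  }

  # union of per-model survivors, keyed to avoid double annotation
  all_sites <- unlist(unname(inh$buckets), recursive = FALSE)
  keys <- vapply(all_sites, function(s) {
    paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
  }, character(1))
  union_sites <- all_sites[!duplicated(keys)]
  union_keys <- keys[!duplicated(keys)]

  records <- annotate_records(union_sites, transcripts, resources,
                              opts$splice_window)
  say("annotated %d model-consistent sites (%d reference mismatches skipped)",
      nrow(records), attr(records, "n_ref_mismatch"))

  cascade_reports <- list()
  survivor_list <- list()
  for (m in inh$models) {
    bkeys <- vapply(inh$buckets[[m]], function(s) {
      paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
    }, character(1))
    rec_m <- records[site_key(records) %in% bkeys, , drop = FALSE]
    res_m <- run_cascade(rec_m, opts$maf_threshold)
    cascade_reports[[m]] <- res_m$report
    survivor_list[[m]] <- res_m$survivors
  }
  survivors <- do.call(rbind, survivor_list)
  if (is.null(survivors)) survivors <- run_cascade(records[0, ],
                                                   opts$maf_threshold)$survivors
  survivors <- survivors[!duplicated(site_key(survivors)), , drop = FALSE]
  say("cascade survivors (all models): %d", nrow(survivors))

  nov <- novelty_filter(survivors)
  say("novelty filter: %d known removed, %d candidates",
      nov$n_known, nrow(nov$candidates))

  report <- rank_candidates(nov$candidates, validations, ped,
                            opts$disease_genes, opts$lenient)
  say("ranked %d candidates (%d calling errors removed)", nrow(report),
      attr(report, "n_calling_errors"))

  accounting <- c(
    input = n_input, multiallelic_dropped = pre$n_dropped,
    excluded_chrom_dropped = inh$dropped_chrom,
    model_consistent_union = length(union_sites),
    annotated = nrow(records),
    ref_mismatch_skipped = attr(records, "n_ref_mismatch"),
    cascade_survivors = nrow(survivors),
    known_removed = nov$n_known, candidates = nrow(nov$candidates),
    calling_errors_removed = attr(report, "n_calling_errors"),
    ranked = nrow(report))

  result <- structure(
    list(report = report, candidates = nov$candidates,
         cascade_reports = cascade_reports, survivors = survivors,
         inheritance = list(counts = inh$counts,
                            dropped_chrom = inh$dropped_chrom),
         accounting = accounting, models = inh$models),
    class = "pipeline_result")

  out_dir <- if (!is.null(config)) config$out_dir
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pedexome pipeline result\n")
  cat("  models:", paste(x$models, collapse = ", "), "\n")
  cat("  accounting:\n")
  for (nm in names(x$accounting)) {
    cat(sprintf("    %-24s %d\n", nm, x$accounting[[nm]]))
  }
  if (nrow(x$report)) {
    cat("  top candidates:\n")
    top <- utils::head(x$report[, c("rank", "gene", "consensus",
                                    "family_specific", "cosegregates",
                                    "disease_gene")], 5)
    print.data.frame(top, row.names = FALSE)
  } else {
    cat("  no candidates\n")
  }
  invisible(x)
}

#' Write pipeline reports to a directory (TSV + JSON)
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$report, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  casc <- do.call(rbind, lapply(names(result$cascade_reports), function(m) {
    data.frame(model = m, result$cascade_reports[[m]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(casc)) {
    utils::write.table(casc, file.path(dir, "cascade_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(accounting = as.list(result$accounting),
         models = result$models,
         inheritance_counts = lapply(result$inheritance$counts, as.list),
         candidates = result$report),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  invisible(dir)
}

#' Explain where the planted variant was lost (or that it won)
#'
#' Miss attribution for simulated runs: walks the pipeline stages and
#' reports the first one at which the planted variant disappeared,
#' together with any injected genotyping errors or masks touching it.
#'
#' @param result a `pipeline_result` from a run over a simulated dataset.
#' @param dataset the `family_dataset` that produced it.
#' @return list with `recovered` (planted ranked first), `rank`
#'   (`NA` if absent from the report), `lost_at` (`NA` when ranked),
#'   `planted_flips` and `planted_masked` (truth-table rows for the
#'   planted site).
#' @export
explain_planted <- function(result, dataset) {
  pl <- dataset$truth$planted
  key <- paste(pl$chrom, pl$pos, pl$ref, pl$alt, sep = ":")
  in_report <- nrow(result$report) > 0 &&
    key %in% site_key(result$report)
  rank <- if (in_report) {
    result$report$rank[site_key(result$report) == key]
  } else {
    NA_integer_
  }
  lost_at <- NA_character_
  if (!in_report) {
    site_keys <- vapply(dataset$sites, function(s) {
      paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
    }, character(1))
    site <- dataset$sites[[match(key, site_keys)]]
    consistent <- any(vapply(intersect(pl$model, result$models),
                             function(m) {
                               site_matches_model(site, dataset$ped, m)
                             }, logical(1)))
    lost_at <- if (!consistent) {
      "inheritance"
    } else if (!(nrow(result$survivors) &&
                 key %in% site_key(result$survivors))) {
      "cascade"
    } else if (!(nrow(result$candidates) &&
                 key %in% site_key(result$candidates))) {
      "novelty"
    } else {
      "validation"
    }
  }
  tf <- dataset$truth$flips
  tm <- dataset$truth$masked
  sel <- function(df) {
    if (is.null(df)) return(NULL)
    df[df$chrom == pl$chrom & df$pos == pl$pos, , drop = FALSE]
  }
  list(recovered = isTRUE(rank == 1L), rank = rank, lost_at = lost_at,
       planted_flips = sel(tf), planted_masked = sel(tm))
}
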