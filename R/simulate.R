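#' Configuration for the synthetic family-exome generator
#'
#' Defaults emulate the post-calling data behind the studied family: the
#' seven-member pedigree with five sequenced members, a single planted
#' autosomal-dominant causal variant (heterozygous in the affecteds,
#' absent from the unaffecteds and the grandson), a pool of neutral
#' background variants at rare-skewed population frequencies, a small
#' number of sequencing-refuted false-positive calls, and annotation
#' resources emitted consistently with the generated truth.
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param ped pedigree to simulate over (default [study_pedigree()]).
#' @param model inheritance model of the planted causal variant.
#' @param n_background number of neutral background variants.
#' @param maf_beta shape parameters of the Beta minor-allele-frequency
#'   prior for background variants (default `c(0.2, 2)`, rare-skewed).
#' @param genotype_error_rate per-call probability of a symmetric
#'   single-genotype miscall.
#' @param missing_rate per-call probability of a missing call (coverage
#'   gap).
#' @param fractions annotation attribute mixture for background variants:
#'   `exonic` (in a coding exon), `indel` (among exonic, insertion rather
#'   than SNV), `synonymous` (among exonic SNVs), `conserved`, `segdup`,
#'   `dbsnp`, `known_1000g`, `known_esp`. Defaults reflect a typical
#'   exome call set after inheritance-agnostic calling: roughly half the
#'   calls exonic, an even synonymous/nonsynonymous split, most sites
#'   already catalogued in dbSNP and the population panels.
#' @param n_false_positive pedigree-consistent injected calls marked
#'   `validated = FALSE` in the truth table (calling-error analogues).
#' @param n_genes toy transcript models to scatter over chromosomes
#'   1-22 and X.
#' @param damaging_prob per-predictor probability that a background
#'   variant's categorical prediction is damaging.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              ped = study_pedigree(),
                              model = "AD",
                              n_background = 1000,
                              maf_beta = c(0.2, 2),
                              genotype_error_rate = 0,
                              missing_rate = 0.01,
                              fractions = list(),
                              n_false_positive = 2,
                              n_genes = 40,
                              damaging_prob = 0.3) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  defaults <- list(exonic = 0.45, indel = 0.08, synonymous = 0.5,
                   conserved = 0.30, segdup = 0.05, dbsnp = 0.90,
                   known_1000g = 0.80, known_esp = 0.60)
  fr <- utils::modifyList(defaults, fractions)
  bad <- names(fr)[vapply(fr, function(x) x < 0 || x > 1, logical(1))]
  if (length(bad)) {
    stop("fractions outside [0,1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_background >= 0, genotype_error_rate >= 0,
            genotype_error_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  structure(list(seed = as.integer(seed), ped = ped,
                 model = match.arg(model, c("AD", "AR", "XLD", "XLR")),
                 n_background = as.integer(n_background),
                 maf_beta = maf_beta,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, fractions = fr,
                 n_false_positive = as.integer(n_false_positive),
                 n_genes = as.integer(n_genes),
                 damaging_prob = damaging_prob),
            class = "simulation_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  sense <- setdiff(names(GENCODE), STOP_CODONS)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# Build toy transcript models: ~n_genes genes over chr1..22,X, three coding
# exons each, alternating strand. The first gene carries a 233-codon CDS
# with codon 232 = GGG on the configured planted chromosome.
build_gene_models <- function(config) {
  chroms <- c(as.character(1:22), "X")
  planted_chrom <- if (model_scope(config$model) == "X") "X" else "1"
  n <- max(config$n_genes, 5L)
  txs <- vector("list", n)
  slot_on_chrom <- integer(length(chroms))
  names(slot_on_chrom) <- chroms
  for (i in seq_len(n)) {
    if (i == 1L) {
      chrom <- planted_chrom
      n_codons <- 233L
      cds <- random_cds(n_codons)
      substr(cds, 694, 696) <- "GGG"   # codon 232: Gly, mutable to Val
      strand <- "+"
    } else {
      chrom <- chroms[((i - 2L) %% length(chroms)) + 1L]
      n_codons <- sample(120:400, 1)
      cds <- random_cds(n_codons)
      strand <- if (i %% 2L == 0L) "-" else "+"
    }
    slot_on_chrom[chrom] <- slot_on_chrom[chrom] + 1L
    len <- 3L * n_codons
    # split CDS into 3 exons, introns 500-2000 bp
    b1 <- resample(seq(30L, len - 60L, by = 3L))
    b2 <- resample(seq(b1 + 30L, len - 30L, by = 3L))
    widths <- c(b1, b2 - b1, len - b2)
    introns <- sample(500:2000, 2, replace = TRUE)
    gstart <- 100000L + (slot_on_chrom[chrom] - 1L) * 1000000L
    starts <- gstart + c(0L, widths[1] + introns[1],
                         widths[1] + introns[1] + widths[2] + introns[2])
    ends <- starts + widths - 1L
    gene <- sprintf("GENE%02d", i)
    txs[[i]] <- transcript_model(
      gene = gene, transcript_id = paste0("TX_", gene), chrom = chrom,
      strand = strand, exon_starts = starts, exon_ends = ends,
      cds_start = starts[1], cds_end = ends[3],
      cds_sequence = cds      # coding orientation regardless of strand
    )
  }
  txs
}

# sample() misreads a length-1 integer vector as 1:n; avoid that
resample <- function(x, size = 1) x[sample.int(length(x), size)]

# Precomputed traversal structure for fast repeated genotype draws.
ped_draw_plan <- function(ped) {
  ids <- topo_order(ped)
  list(ids = ids,
       fa = match(ped$father_id[match(ids, ped$id)], ids),
       mo = match(ped$mother_id[match(ids, ped$id)], ids),
       male = ped$sex[match(ids, ped$id)] == "male",
       out = match(ped$id, ids))
}

# Unconditional Hardy-Weinberg + Mendelian draw of alt counts for every
# pedigree member at one locus, vectorized over k independent replicate
# loci. X loci: male genotypes hemizygous {0,1}; daughters receive the
# paternal hemizygous allele plus one maternal gamete, sons one maternal
# gamete only.
draw_family_genotypes_batch <- function(plan, maf, on_x = FALSE, k = 1L) {
  n <- length(plan$ids)
  g <- matrix(0L, nrow = k, ncol = n, dimnames = list(NULL, plan$ids))
  gamete_from <- function(gv) {
    # diploid parent genotype vector -> transmitted allele vector
    ifelse(gv == 1L, stats::rbinom(k, 1L, 0.5), as.integer(gv == 2L))
  }
  hw_allele <- function() stats::rbinom(k, 1L, maf)
  for (j in seq_len(n)) {
    fa <- plan$fa[j]; mo <- plan$mo[j]
    m_gam <- if (is.na(mo)) hw_allele() else gamete_from(g[, mo])
    g[, j] <- if (on_x && plan$male[j]) {
      m_gam
    } else if (on_x) {
      fx <- if (is.na(fa)) hw_allele() else g[, fa]   # hemizygous father
      fx + m_gam
    } else {
      f_gam <- if (is.na(fa)) hw_allele() else gamete_from(g[, fa])
      f_gam + m_gam
    }
  }
  g[, plan$out, drop = FALSE]
}

# single unconditional draw, named by pedigree member
draw_family_genotypes <- function(ped, maf, on_x = FALSE) {
  g <- draw_family_genotypes_batch(ped_draw_plan(ped), maf, on_x, 1L)[1L, ]
  stats::setNames(as.integer(g), ped$id)
}

# deterministic planted genotype assignment: first enumerated satisfying
# assignment under the model with no observations
planted_assignment <- function(ped, model, chrom) {
  probe <- site_genotypes(chrom, 1L, "G", "T",
                          stats::setNames(NA_integer_,
                                          ped$id[ped$sequenced][1]))
  asn <- enumerate_assignments(probe, ped, model)
  if (!nrow(asn)) {
    stop("planted-variant constraints unsatisfiable for this pedigree ",
         "under model ", model, call. = FALSE)
  }
  asn[1, ]
}

#' Simulate a complete family-exome dataset with a planted causal variant
#'
#' Generates, from one seeded RNG stream: toy transcript models with real
#' codon content; a planted causal variant (coding position 695 of the
#' first gene, codon 232 Gly\eqn{\to}Val) whose genotypes follow the
#' configured inheritance model and the pedigree's affection pattern;
#' neutral background variants with founder genotypes drawn from
#' Hardy-Weinberg at a Beta-distributed MAF and offspring by Mendelian
#' gamete sampling; injected pedigree-consistent false-positive calls
#' (marked `validated = FALSE` in the truth table); symmetric genotyping
#' miscalls and missing-call masking; and annotation resources (conserved
#' and segmental-duplication intervals, dbSNP and population frequency
#' tables, categorical prediction profiles) consistent with the truth
#' attributes. Conservation/segdup truth flags are recomputed from the
#' emitted intervals so resource and truth can never disagree.
#'
#' @param config a [simulation_config()].
#' @return list of class `family_dataset`: `sites` (list of
#'   [site_genotypes()]), `ped`, `transcripts`, `resources` (in-memory,
#'   see [annotate_records()]), `validations` (named list of
#'   [validation_record()] covering the planted variant and the injected
#'   false positives), `truth` (planted key/gene/model, per-variant
#'   attribute table, error flips, masked calls, false-positive keys) and
#'   `config`.
#' @export
simulate_family_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  ped <- config$ped
  plan <- ped_draw_plan(ped)
  fr <- config$fractions
  txs <- build_gene_models(config)
  tx_by_gene <- stats::setNames(txs, vapply(txs, `[[`, "", "gene"))
  seq_ids <- ped$id[ped$sequenced]

  planted_tx <- txs[[1]]
  planted_cds <- 695L
  planted_gpos <- cds_to_genomic(planted_tx, planted_cds)
  planted_full <- planted_assignment(ped, config$model, planted_tx$chrom)
  planted_truth_calls <- planted_full[seq_ids]

  variants <- list()   # per-variant attribute rows (plain lists, cheap)
  calls <- list()      # true (pre-error) calls per variant, sequenced only
  add_variant <- function(chrom, pos, ref, alt, gene, true_calls, source,
                          conserved, segdup, dbsnp, af_1000g, af_esp, maf) {
    variants[[length(variants) + 1L]] <<- list(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      gene = if (is.null(gene)) NA_character_ else gene,
      source = source, conserved = conserved, segdup = segdup,
      dbsnp = dbsnp, af_1000g = af_1000g, af_esp = af_esp, maf = maf)
    calls[[length(calls) + 1L]] <<- true_calls
  }
  collect_variants <- function(rows) {
    col <- function(nm, fn) fn(unlist(lapply(rows, `[[`, nm)))
    data.frame(
      chrom = col("chrom", as.character), pos = col("pos", as.integer),
      ref = col("ref", as.character), alt = col("alt", as.character),
      gene = col("gene", as.character), source = col("source", as.character),
      conserved = col("conserved", as.logical),
      segdup = col("segdup", as.logical), dbsnp = col("dbsnp", as.logical),
      af_1000g = col("af_1000g", as.numeric),
      af_esp = col("af_esp", as.numeric), maf = col("maf", as.numeric),
      stringsAsFactors = FALSE)
  }

  add_variant(planted_tx$chrom, planted_gpos, "G", "T", planted_tx$gene,
              planted_truth_calls, "planted", conserved = TRUE,
              segdup = FALSE, dbsnp = FALSE, af_1000g = NA_real_,
              af_esp = NA_real_, maf = NA_real_)

  # -- background variants ---------------------------------------------
  used_pos <- new.env()
  mark_used <- function(chrom, pos) {
    assign(paste(chrom, pos), TRUE, used_pos)
  }
  is_used <- function(chrom, pos) {
    exists(paste(chrom, pos), used_pos)
  }
  mark_used(planted_tx$chrom, planted_gpos)

  pick_exonic <- function(want_syn, want_indel) {
    for (attempt in 1:40) {
      tx <- txs[[sample(seq_along(txs), 1)]]
      len <- nchar(tx$cds_sequence)
      cpos <- sample(seq_len(len), 1)
      gpos <- cds_to_genomic(tx, cpos)
      if (is_used(tx$chrom, gpos)) next
      ref_c <- substr(tx$cds_sequence, cpos, cpos)
      if (want_indel) {
        ins <- paste(sample(c("A", "C", "G", "T"),
                            sample(c(1, 2, 3), 1), replace = TRUE),
                     collapse = "")
        ref_g <- if (tx$strand == "+") ref_c else revcomp(ref_c)
        return(list(tx = tx, gpos = gpos, ref = ref_g,
                    alt = paste0(ref_g, ins)))
      }
      cod <- cds_to_codon(cpos)
      codon_start <- (cod$codon_index - 1L) * 3L + 1L
      ref_codon <- substr(tx$cds_sequence, codon_start, codon_start + 2L)
      for (alt_c in setdiff(c("A", "C", "G", "T"), ref_c)) {
        alt_codon <- ref_codon
        substr(alt_codon, cod$offset, cod$offset) <- alt_c
        syn <- translate_codon(ref_codon) == translate_codon(alt_codon)
        if (syn == want_syn) {
          ref_g <- if (tx$strand == "+") ref_c else revcomp(ref_c)
          alt_g <- if (tx$strand == "+") alt_c else revcomp(alt_c)
          return(list(tx = tx, gpos = gpos, ref = ref_g, alt = alt_g))
        }
      }
    }
    NULL
  }

  pick_noncoding <- function() {
    for (attempt in 1:40) {
      if (stats::runif(1) < 0.7) {          # intronic (may fall in splice window)
        tx <- txs[[sample(seq_along(txs), 1)]]
        k <- sample(1:2, 1)
        lo <- tx$exon_ends[k] + 1L
        hi <- tx$exon_starts[k + 1L] - 1L
        gpos <- sample(lo:hi, 1)
        chrom <- tx$chrom
      } else {                              # intergenic
        chrom <- sample(c(as.character(1:22), "X"), 1)
        gpos <- sample(5000000:9000000, 1)
      }
      if (!is_used(chrom, gpos)) {
        ref <- sample(c("A", "C", "G", "T"), 1)
        return(list(chrom = chrom, gpos = gpos, ref = ref,
                    alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1)))
      }
    }
    NULL
  }

  rs_counter <- 0L
  for (j in seq_len(config$n_background)) {
    maf <- stats::rbeta(1, config$maf_beta[1], config$maf_beta[2])
    maf <- min(max(maf, 0.001), 0.5)
    exonic <- stats::runif(1) < fr$exonic
    if (exonic) {
      want_indel <- stats::runif(1) < fr$indel
      picked <- pick_exonic(want_syn = stats::runif(1) < fr$synonymous,
                            want_indel = want_indel)
      if (is.null(picked)) next
      chrom <- picked$tx$chrom; gpos <- picked$gpos
      gene <- picked$tx$gene
    } else {
      picked <- pick_noncoding()
      if (is.null(picked)) next
      chrom <- picked$chrom; gpos <- picked$gpos
      gene <- NA_character_
    }
    on_x <- chrom_class(chrom) == "X"
    # rejection-sample a draw segregating in the sequenced members (sites
    # monomorphic in the family are never emitted by joint calling)
    gm <- draw_family_genotypes_batch(plan, maf, on_x, k = 100L)
    hit <- which(rowSums(gm[, seq_ids, drop = FALSE] > 0L) > 0L)
    if (!length(hit)) next               # monomorphic in the family; uncalled
    true_calls <- stats::setNames(as.integer(gm[hit[1L], seq_ids]), seq_ids)
    mark_used(chrom, gpos)
    dbsnp <- stats::runif(1) < fr$dbsnp
    known_1g <- stats::runif(1) < fr$known_1000g
    known_esp <- stats::runif(1) < fr$known_esp
    add_variant(chrom, gpos, picked$ref, picked$alt, gene, true_calls,
                source = "background",
                conserved = stats::runif(1) < fr$conserved,
                segdup = stats::runif(1) < fr$segdup,
                dbsnp = dbsnp,
                af_1000g = if (known_1g) maf else NA_real_,
                af_esp = if (known_esp) maf else NA_real_,
                maf = maf)
  }

  # -- injected false-positive calls: pedigree-consistent, cascade-proof,
  #    refuted by validation ------------------------------------------
  fp_genes <- character(0)
  if (config$n_false_positive > 0L) {
    for (k in seq_len(config$n_false_positive)) {
      picked <- NULL
      for (attempt in 1:40) {
        p <- pick_exonic(want_syn = FALSE, want_indel = FALSE)
        if (!is.null(p) && p$tx$gene != planted_tx$gene &&
            chrom_class(p$tx$chrom) == model_scope(config$model)) {
          picked <- p; break
        }
      }
      if (is.null(picked)) next
      mark_used(picked$tx$chrom, picked$gpos)
      fp_genes <- c(fp_genes, picked$tx$gene)
      add_variant(picked$tx$chrom, picked$gpos, picked$ref, picked$alt,
                  picked$tx$gene, planted_truth_calls, source = "false_positive",
                  conserved = TRUE, segdup = FALSE, dbsnp = FALSE,
                  af_1000g = NA_real_, af_esp = NA_real_, maf = NA_real_)
    }
  }

  truth_tab <- collect_variants(variants)
  n_var <- nrow(truth_tab)

  # -- genotyping error and missingness (symmetric miscall, then mask) --
  obs <- do.call(rbind, calls)                     # n_var x sequenced
  colnames(obs) <- seq_ids
  on_x_row <- chrom_class(truth_tab$chrom) == "X"
  male_col <- ped$sex[match(seq_ids, ped$id)] == "male"
  flips_df <- NULL
  masked_df <- NULL
  if (config$genotype_error_rate > 0) {
    hit <- which(matrix(stats::runif(length(obs)) <
                          config$genotype_error_rate, nrow = n_var),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      from <- obs[hit]
      to <- vapply(seq_len(nrow(hit)), function(r) {
        i <- hit[r, 1]; j <- hit[r, 2]
        dom <- genotype_domain(if (male_col[j]) "male" else "female",
                               on_x_row[i])
        resample(setdiff(dom, obs[i, j]))
      }, integer(1))
      obs[hit] <- to
      flips_df <- data.frame(chrom = truth_tab$chrom[hit[, 1]],
                             pos = truth_tab$pos[hit[, 1]],
                             member = seq_ids[hit[, 2]],
                             from = from, to = to, stringsAsFactors = FALSE)
    }
  }
  if (config$missing_rate > 0) {
    miss <- which(matrix(stats::runif(length(obs)) < config$missing_rate,
                         nrow = n_var), arr.ind = TRUE)
    if (nrow(miss)) {
      obs[miss] <- NA_integer_
      masked_df <- data.frame(chrom = truth_tab$chrom[miss[, 1]],
                              pos = truth_tab$pos[miss[, 1]],
                              member = seq_ids[miss[, 2]],
                              stringsAsFactors = FALSE)
    }
  }

  sites <- lapply(seq_len(n_var), function(i) {
    site_genotypes(truth_tab$chrom[i], truth_tab$pos[i], truth_tab$ref[i],
                   truth_tab$alt[i], obs[i, ])
  })

  # -- resources consistent with truth ---------------------------------
  mk_intervals <- function(flag) {
    idx <- which(flag)
    if (!length(idx)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      truth_tab$chrom[idx],
      IRanges::IRanges(pmax(truth_tab$pos[idx] - 5L, 1L),
                       truth_tab$pos[idx] + 5L)))
  }
  # the planted variant's truth contract (passes every cascade predicate)
  # forbids segdup intervals near it: a flagged neighbour within the
  # interval half-width would otherwise cover the planted base
  near_planted <- truth_tab$chrom == planted_tx$chrom &
    abs(truth_tab$pos - planted_gpos) <= 10L
  truth_tab$segdup[near_planted] <- FALSE
  conserved_gr <- mk_intervals(truth_tab$conserved)
  segdup_gr <- mk_intervals(truth_tab$segdup)
  # recompute flags from the emitted intervals (collision-proof truth)
  truth_tab$conserved <- overlaps_intervals(truth_tab, conserved_gr)
  truth_tab$segdup <- overlaps_intervals(truth_tab, segdup_gr)

  dbsnp_tab <- truth_tab[truth_tab$dbsnp,
                         c("chrom", "pos", "ref", "alt"), drop = FALSE]
  if (nrow(dbsnp_tab)) {
    dbsnp_tab$id <- sprintf("rs%07d", seq_len(nrow(dbsnp_tab)))
  } else {
    dbsnp_tab$id <- character(0)
  }
  freq_tab <- function(col) {
    keep <- !is.na(truth_tab[[col]])
    out <- truth_tab[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    out$af <- truth_tab[[col]][keep]
    out
  }

  # -- categorical prediction profiles ---------------------------------
  pred_rows <- list()
  rand_profile <- function() {
    p <- config$damaging_prob
    pick <- function(damaging, other) {
      r <- stats::runif(1)
      if (r < 0.1) NA_character_
      else if (r < 0.1 + 0.9 * p) damaging
      else sample(other, 1)
    }
    c(phylop = pick("C", "N"), sift = pick("D", "T"),
      polyphen = pick("D", c("P", "B")), lrt = pick("D", "N"),
      mutation_taster = pick("D", "N"), gerp = pick("C", "N"),
      sift2013 = pick("D", c("T", "B")))
  }
  for (i in seq_len(n_var)) {
    if (is.na(truth_tab$gene[i])) next
    prof <- if (truth_tab$source[i] == "planted") {
      c(phylop = "C", sift = "D", polyphen = "D", lrt = "D",
        mutation_taster = "D", gerp = "C", sift2013 = "D")
    } else {
      rand_profile()
    }
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      chrom = truth_tab$chrom[i], pos = truth_tab$pos[i],
      ref = truth_tab$ref[i], alt = truth_tab$alt[i],
      t(prof), stringsAsFactors = FALSE)
  }
  predictions <- if (length(pred_rows)) do.call(rbind, pred_rows) else NULL

  resources <- list(conserved = conserved_gr, segdup = segdup_gr,
                    dbsnp = dbsnp_tab, freq_1000g = freq_tab("af_1000g"),
                    freq_esp = freq_tab("af_esp"),
                    predictions = predictions)

  # -- validation records: planted variant confirmed and family-specific,
  #    injected calls refuted -----------------------------------------
  validations <- stats::setNames(
    c(list(validation_record(planted_tx$gene,
                             family_genotypes = planted_full,
                             control_carrier_count = 0, control_n = 100)),
      lapply(fp_genes, function(g) validation_record(g, validated = FALSE))),
    c(planted_tx$gene, fp_genes))

  truth <- list(
    planted = list(chrom = planted_tx$chrom, pos = planted_gpos,
                   ref = "G", alt = "T", gene = planted_tx$gene,
                   cds_pos = planted_cds, model = config$model,
                   full_assignment = as.list(planted_full)),
    variants = truth_tab,
    flips = flips_df,
    masked = masked_df,
    false_positive_genes = fp_genes
  )

  structure(list(sites = sites, ped = ped, transcripts = txs,
                 resources = resources, validations = validations,
                 truth = truth, config = config),
            class = "family_dataset")
}

#' @export
print.family_dataset <- function(x, ...) {
  cat("Synthetic family exome dataset:", length(x$sites), "sites,",
      length(x$transcripts), "transcripts, planted",
      x$truth$planted$gene, "variant at",
      paste0(x$truth$planted$chrom, ":", x$truth$planted$pos),
      "under", x$truth$planted$model, "\n")
  invisible(x)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `study.vcf`, `family.ped`, `tx.tsv`, `cds.fa`, `conserved.bed`,
#' `segdup.bed`, `freq_1000g.tsv`, `freq_esp.tsv`, `dbsnp.tsv`,
#' `predictions.tsv`, `validations.tsv` and `truth.json`. Identical seeds
#' produce byte-identical outputs.
#'
#' @param ds a `family_dataset` from [simulate_family_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_vcf_sites(ds$sites, p("study.vcf"), ds$ped)
  write_ped(ds$ped, p("family.ped"))

  tx_tab <- do.call(rbind, lapply(ds$transcripts, function(tx) {
    data.frame(gene = tx$gene, transcript_id = tx$transcript_id,
               chrom = tx$chrom, strand = tx$strand,
               exon_starts = paste(tx$exon_starts, collapse = ","),
               exon_ends = paste(tx$exon_ends, collapse = ","),
               cds_start = tx$cds_start, cds_end = tx$cds_end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tx_tab, p("tx.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- unlist(lapply(ds$transcripts, function(tx) {
    c(paste0(">", tx$transcript_id), tx$cds_sequence)
  }))
  writeLines(fa, p("cds.fa"))

  write_bed <- function(gr, path) {
    if (!length(gr)) {
      file.create(path)
      return(invisible())
    }
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    utils::write.table(df[order(vapply(df$chrom, chrom_sort_key, numeric(1)),
                                df$start), ],
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(ds$resources$conserved, p("conserved.bed"))
  write_bed(ds$resources$segdup, p("segdup.bed"))

  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wt(ds$resources$dbsnp, "dbsnp.tsv")
  wt(ds$resources$freq_1000g, "freq_1000g.tsv")
  wt(ds$resources$freq_esp, "freq_esp.tsv")
  if (!is.null(ds$resources$predictions)) {
    wt(ds$resources$predictions, "predictions.tsv")
  }

  val_tab <- do.call(rbind, lapply(names(ds$validations), function(g) {
    v <- ds$validations[[g]]
    data.frame(key = g,
               family_genotypes = if (is.null(v$family_genotypes)) "" else
                 paste(names(v$family_genotypes), v$family_genotypes,
                       sep = "=", collapse = ";"),
               control_carrier_count = v$control_carrier_count,
               control_n = v$control_n, validated = v$validated,
               stringsAsFactors = FALSE)
  }))
  wt(val_tab, "validations.tsv")

  jsonlite::write_json(ds$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  files <- c("study.vcf", "family.ped", "tx.tsv", "cds.fa",
             "conserved.bed", "segdup.bed", "freq_1000g.tsv",
             "freq_esp.tsv", "dbsnp.tsv", "predictions.tsv",
             "validations.tsv", "truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Read a validations TSV back into validation records
#'
#' @param path TSV written by [write_dataset()] (columns `key`,
#'   `family_genotypes` as `member=count;...`, `control_carrier_count`,
#'   `control_n`, `validated`).
#' @return named list of [validation_record()].
#' @export
read_validations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    fg <- NULL
    if (nzchar(tab$family_genotypes[i]) && !is.na(tab$family_genotypes[i])) {
      parts <- strsplit(strsplit(tab$family_genotypes[i], ";")[[1]], "=")
      fg <- stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                            vapply(parts, `[`, "", 1))
    }
    validation_record(tab$key[i], fg, tab$control_carrier_count[i],
                      tab$control_n[i], isTRUE(tab$validated[i]))
  })
  stats::setNames(out, tab$key)
}
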