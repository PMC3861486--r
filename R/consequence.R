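#' Transcript model for consequence calling
#'
#' Holds the exon structure, CDS bounds and spliced coding sequence of one
#' transcript. Coordinates are genomic, 1-based inclusive; `cds_sequence`
#' is given in coding orientation (already reverse-complemented for minus
#' strand transcripts) and its length must equal the spliced CDS length.
#' A CDS length not divisible by 3 is allowed (partial transcript) but
#' flagged with a warning.
#'
#' @param gene gene symbol.
#' @param transcript_id transcript identifier (FASTA key).
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of exon bounds, 1-based
#'   inclusive, sorted, non-overlapping.
#' @param cds_start,cds_end genomic bounds of the coding region.
#' @param cds_sequence spliced coding nucleotide sequence.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript_id, chrom, strand,
                             exon_starts, exon_ends, cds_start, cds_end,
                             cds_sequence) {
  strand <- match.arg(strand, c("+", "-"))
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends)) {
    stop("exon_starts/exon_ends length mismatch", call. = FALSE)
  }
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  if (any(exon_ends < exon_starts)) stop("exon end < start", call. = FALSE)
  if (any(utils::head(exon_ends, -1) >= utils::tail(exon_starts, -1))) {
    stop("exons overlap", call. = FALSE)
  }
  tx <- structure(
    list(gene = gene, transcript_id = transcript_id,
         chrom = norm_chrom(chrom), strand = strand,
         exon_starts = exon_starts, exon_ends = exon_ends,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         cds_sequence = toupper(as.character(cds_sequence))),
    class = "transcript_model"
  )
  cds <- cds_intervals(tx)
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len != nchar(tx$cds_sequence)) {
    stop("cds_sequence length (", nchar(tx$cds_sequence),
         ") != spliced CDS length (", cds_len, ") for ", transcript_id,
         call. = FALSE)
  }
  if (cds_len %% 3L != 0L) {
    warning("CDS length of ", transcript_id,
            " not divisible by 3; partial transcript", call. = FALSE)
  }
  tx
}

# genomic CDS pieces: exons intersected with [cds_start, cds_end]
cds_intervals <- function(tx) {
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Map a coding nucleotide position to its codon
#'
#' For a 1-based coding (CDS) position, returns the 1-based codon index and
#' the position within the codon, so the residue number of a protein change
#' equals the codon index (e.g. coding position 695 falls in codon 232 at
#' codon position 2).
#'
#' @param cds_pos 1-based coding nucleotide position(s).
#' @return data.frame with columns `codon_index` and `offset` (1, 2 or 3).
#' @export
#' @examples
#' cds_to_codon(695)   # codon 232, offset 2
cds_to_codon <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L)) {
    stop("cds_pos must be >= 1", call. = FALSE)
  }
  data.frame(codon_index = (cds_pos - 1L) %/% 3L + 1L,
             offset = (cds_pos - 1L) %% 3L + 1L)
}

#' Map a genomic position to a coding (CDS) position
#'
#' Accounts for introns and strand: on the minus strand the last genomic
#' CDS base is coding position 1.
#'
#' @param tx a [transcript_model()].
#' @param gpos genomic position (1-based) on the transcript's chromosome.
#' @return 1-based coding position, or `NA` if `gpos` is not coding.
#' @export
genomic_to_cds <- function(tx, gpos) {
  cds <- cds_intervals(tx)
  if (!nrow(cds)) return(NA_integer_)
  hit <- which(gpos >= cds$start & gpos <= cds$end)
  if (!length(hit)) return(NA_integer_)
  widths <- cds$end - cds$start + 1L
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  plus_pos <- before + (gpos - cds$start[hit]) + 1L
  if (tx$strand == "+") plus_pos else sum(widths) - plus_pos + 1L
}

#' Map a coding (CDS) position to its genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @param tx a [transcript_model()].
#' @param cds_pos 1-based coding position.
#' @return genomic position (1-based).
#' @export
cds_to_genomic <- function(tx, cds_pos) {
  cds <- cds_intervals(tx)
  widths <- cds$end - cds$start + 1L
  total <- sum(widths)
  if (cds_pos < 1L || cds_pos > total) {
    stop("cds_pos out of range for ", tx$transcript_id, call. = FALSE)
  }
  plus_pos <- if (tx$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(widths)
  piece <- which(plus_pos <= cum)[1]
  before <- if (piece > 1L) cum[piece - 1L] else 0L
  cds$start[piece] + (plus_pos - before) - 1L
}

# region of gpos relative to one transcript
tx_region <- function(tx, gpos, splice_window = 2L) {
  span_s <- min(tx$exon_starts); span_e <- max(tx$exon_ends)
  if (gpos < span_s || gpos > span_e) return("intergenic")
  in_exon <- any(gpos >= tx$exon_starts & gpos <= tx$exon_ends)
  if (in_exon) {
    if (gpos >= tx$cds_start && gpos <= tx$cds_end) return("cds")
    return("UTR")
  }
  # intronic: distance to flanking exon boundaries
  d_left <- gpos - tx$exon_ends[tx$exon_ends < gpos]
  d_right <- tx$exon_starts[tx$exon_starts > gpos] - gpos
  d <- min(c(d_left, d_right))
  if (splice_window > 0L && d <= splice_window) "splicing" else "intronic"
}

SEVERITY <- c("frameshift indel" = 1, "stopgain" = 2, "stoploss" = 3,
              "splicing" = 4, "nonsynonymous SNV" = 5,
              "nonframeshift indel" = 6, "synonymous SNV" = 7,
              "UTR" = 8, "intronic" = 9, "intergenic" = 10)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

# standard genetic code, cached at install time (repeated `::` lookups of
# Biostrings::GENETIC_CODE dominate tight simulation loops otherwise)
GENCODE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- GENCODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  if (nchar(comp) == 1L) return(comp)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Classify a variant's consequence against a set of transcript models
#'
#' For each overlapping transcript the site's region is resolved (coding,
#' UTR, splicing within `splice_window` bases of an exon/intron boundary,
#' intronic, intergenic). Coding SNVs are classified by translating the
#' reference and alternate codons with the standard genetic code
#' (synonymous/nonsynonymous SNV, stopgain, stoploss) and named in HGVS
#' c./p. notation; coding indels are frameshift when the allele length
#' difference is not a multiple of 3, nonframeshift otherwise. When several
#' transcripts overlap, the most severe consequence is reported and the
#' per-transcript calls are retained.
#'
#' @param transcripts list of [transcript_model()] (may include
#'   non-overlapping ones; an empty or non-overlapping set yields
#'   `intergenic`).
#' @param site a biallelic [site_genotypes()].
#' @param splice_window intronic distance (bases) from an exon boundary
#'   called `splicing`; default 2 (the canonical splice dinucleotide).
#' @return A list of class `consequence`: `category`, `gene`,
#'   `transcript_id`, `hgvs_c` (standard, e.g. `c.695G>T`), `hgvs_c_legacy`
#'   (e.g. `c.G695T`), `hgvs_p` (e.g. `p.Gly232Val`, `NA` outside coding
#'   sequence), `cds_pos`, `codon_index`, and `per_transcript` detail.
#'   A reference allele disagreeing with the transcript sequence raises a
#'   `reference_mismatch` error.
#' @export
classify_variant <- function(transcripts, site, splice_window = 2L) {
  stopifnot(splice_window >= 0L)
  if (!is_biallelic(site)) stop("site must be biallelic", call. = FALSE)
  onchrom <- Filter(function(tx) tx$chrom == site$chrom, transcripts)
  per_tx <- lapply(onchrom, classify_one_tx, site = site,
                   splice_window = splice_window)
  per_tx <- Filter(Negate(is.null), per_tx)
  if (!length(per_tx)) {
    return(structure(list(category = "intergenic", gene = NA_character_,
                          transcript_id = NA_character_, hgvs_c = NA,
                          hgvs_c_legacy = NA, hgvs_p = NA,
                          cds_pos = NA_integer_, codon_index = NA_integer_,
                          per_transcript = list()),
                     class = "consequence"))
  }
  sev <- vapply(per_tx, function(x) SEVERITY[[x$category]], numeric(1))
  best <- per_tx[[which.min(sev)]]
  best$per_transcript <- per_tx
  structure(best, class = "consequence")
}

# NULL when the transcript does not cover the site at all
classify_one_tx <- function(tx, site, splice_window) {
  gpos <- site$pos
  region <- tx_region(tx, gpos, splice_window)
  if (region == "intergenic") return(NULL)
  res <- list(category = region, gene = tx$gene,
              transcript_id = tx$transcript_id,
              hgvs_c = NA_character_, hgvs_c_legacy = NA_character_,
              hgvs_p = NA_character_, cds_pos = NA_integer_,
              codon_index = NA_integer_)
  if (region != "cds") return(res)

  ref <- site$ref; alt <- site$alt
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    cds_pos <- genomic_to_cds(tx, gpos)
    cod <- cds_to_codon(cds_pos)
    ref_c <- if (tx$strand == "+") ref else revcomp(ref)
    alt_c <- if (tx$strand == "+") alt else revcomp(alt)
    seq_base <- substr(tx$cds_sequence, cds_pos, cds_pos)
    if (seq_base != toupper(ref_c)) {
      stop(structure(class = c("reference_mismatch", "error", "condition"),
                     list(message = sprintf(
                       "reference mismatch at %s:%d (%s): VCF ref %s vs transcript %s",
                       site$chrom, gpos, tx$transcript_id, ref, seq_base),
                       call = NULL)))
    }
    codon_start <- (cod$codon_index - 1L) * 3L + 1L
    ref_codon <- substr(tx$cds_sequence, codon_start, codon_start + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, cod$offset, cod$offset) <- toupper(alt_c)
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    category <- if (aa_ref == aa_alt) "synonymous SNV"
      else if (aa_alt == "*") "stopgain"
      else if (aa_ref == "*") "stoploss"
      else "nonsynonymous SNV"
    res$category <- category
    res$cds_pos <- cds_pos
    res$codon_index <- cod$codon_index
    res$hgvs_c <- sprintf("c.%d%s>%s", cds_pos, ref_c, alt_c)
    res$hgvs_c_legacy <- sprintf("c.%s%d%s", ref_c, cds_pos, alt_c)
    res$hgvs_p <- if (aa_ref == aa_alt) {
      sprintf("p.%s%d=", AA3[[aa_ref]], cod$codon_index)
    } else {
      sprintf("p.%s%d%s", AA3[[aa_ref]], cod$codon_index, AA3[[aa_alt]])
    }
  } else {
    diff <- abs(nchar(ref) - nchar(alt))
    res$category <- if (diff %% 3L != 0L) "frameshift indel"
      else "nonframeshift indel"
    res$cds_pos <- genomic_to_cds(tx, gpos)
    if (!is.na(res$cds_pos)) {
      res$hgvs_c <- sprintf("c.%d%s>%s", res$cds_pos, ref, alt)
      res$hgvs_c_legacy <- res$hgvs_c
    }
  }
  res
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("%s | %s %s %s %s\n", x$category,
              ifelse(is.na(x$gene), "-", x$gene),
              ifelse(is.na(x$hgvs_c), "", x$hgvs_c),
              ifelse(is.na(x$hgvs_p), "", x$hgvs_p),
              ifelse(is.na(x$transcript_id), "", paste0("[", x$transcript_id, "]"))))
  invisible(x)
}

#' Read transcript models from a TSV + CDS FASTA
#'
#' The TSV has header columns `gene`, `transcript_id`, `chrom`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated, 1-based inclusive),
#' `cds_start`, `cds_end`. The FASTA holds the spliced coding sequence of
#' each transcript keyed by `transcript_id`.
#'
#' @param tsv_path transcript table path.
#' @param fasta_path CDS FASTA path.
#' @return list of [transcript_model()].
#' @export
read_transcripts <- function(tsv_path, fasta_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  lapply(seq_len(nrow(tab)), function(i) {
    tid <- tab$transcript_id[i]
    if (!tid %in% names(seqs)) {
      stop("no CDS sequence for transcript ", tid, call. = FALSE)
    }
    transcript_model(
      gene = tab$gene[i], transcript_id = tid, chrom = tab$chrom[i],
      strand = tab$strand[i],
      exon_starts = as.integer(strsplit(tab$exon_starts[i], ",")[[1]]),
      exon_ends = as.integer(strsplit(tab$exon_ends[i], ",")[[1]]),
      cds_start = as.integer(tab$cds_start[i]),
      cds_end = as.integer(tab$cds_end[i]),
      cds_sequence = as.character(seqs[[tid]])
    )
  })
}

#' Read transcript models from a 12-column BED + CDS FASTA
#'
#' BED12 blocks give the exons (0-based half-open, converted to 1-based
#' inclusive here), thickStart/thickEnd the CDS bounds, and the `name`
#' field is matched against FASTA keys of form `transcript_id` or
#' `gene|transcript_id`.
#'
#' @param bed_path BED12 path.
#' @param fasta_path CDS FASTA path.
#' @return list of [transcript_model()].
#' @export
read_transcripts_bed12 <- function(bed_path, fasta_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  lapply(seq_along(gr), function(i) {
    x <- gr[i]
    name <- x$name
    parts <- strsplit(name, "|", fixed = TRUE)[[1]]
    gene <- parts[1]
    tid <- parts[length(parts)]
    blocks <- x$blocks[[1]]  # relative IRanges, already 1-based
    starts <- GenomicRanges::start(x) + IRanges::start(blocks) - 1L
    ends <- GenomicRanges::start(x) + IRanges::end(blocks) - 1L
    thick <- x$thick
    if (!tid %in% names(seqs)) {
      stop("no CDS sequence for transcript ", tid, call. = FALSE)
    }
    transcript_model(
      gene = gene, transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(x)),
      strand = as.character(GenomicRanges::strand(x)),
      exon_starts = starts, exon_ends = ends,
      cds_start = IRanges::start(thick), cds_end = IRanges::end(thick),
      cds_sequence = as.character(seqs[[tid]])
    )
  })
}
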