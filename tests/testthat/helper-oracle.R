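# Brute-force oracle for inheritance-model consistency, written
# independently of the package's depth-first matcher: enumerate the full
# genotype grid, keep assignments satisfying phenotype and Mendelian
# transmission, and answer observation queries by projection.

bf_domain <- function(sex, model) {
  if (model %in% c("XLD", "XLR") && sex == "male") 0:1 else 0:2
}

bf_is_risk <- function(g, model, sex) {
  if (model == "AD") return(g >= 1)
  if (model == "AR") return(g == 2)
  if (model == "XLD") return(if (sex == "male") g == 1 else g >= 1)
  if (sex == "male") g == 1 else g == 2            # XLR
}

bf_gam <- function(g) if (g == 0) 0 else if (g == 2) 1 else c(0, 1)

bf_child_ok <- function(cg, fg, mg, child_sex, model) {
  on_x <- model %in% c("XLD", "XLR")
  mo_gam <- if (is.na(mg)) c(0, 1) else bf_gam(mg)
  if (on_x) {
    if (child_sex == "male") return(cg %in% mo_gam)
    fa_allele <- if (is.na(fg)) c(0, 1) else fg
    for (a in fa_allele) for (b in mo_gam) if (a + b == cg) return(TRUE)
    return(FALSE)
  }
  fa_gam <- if (is.na(fg)) c(0, 1) else bf_gam(fg)
  for (a in fa_gam) for (b in mo_gam) if (a + b == cg) return(TRUE)
  FALSE
}

# matrix of every full assignment satisfying phenotype + transmission
bf_valid_assignments <- function(ped, model) {
  grid <- as.matrix(expand.grid(lapply(seq_len(nrow(ped)), function(i) {
    bf_domain(ped$sex[i], model)
  })))
  colnames(grid) <- ped$id
  ok <- vapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    for (i in seq_len(nrow(ped))) {
      aff <- ped$affection[i]
      if (aff != "unknown") {
        risk <- bf_is_risk(g[[i]], model, ped$sex[i])
        if ((aff == "affected") != risk) return(FALSE)
      }
      fa <- ped$father_id[i]; mo <- ped$mother_id[i]
      if (!is.na(fa) || !is.na(mo)) {
        fg <- if (is.na(fa)) NA else g[[match(fa, ped$id)]]
        mg <- if (is.na(mo)) NA else g[[match(mo, ped$id)]]
        if (!bf_child_ok(g[[i]], fg, mg, ped$sex[i], model)) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  grid[ok, , drop = FALSE]
}

# does any valid assignment agree with the observed (non-missing) calls?
bf_matches <- function(valid, calls) {
  if (!nrow(valid)) return(FALSE)
  obs <- calls[!is.na(calls)]
  if (!length(obs)) return(TRUE)
  any(apply(valid[, names(obs), drop = FALSE], 1,
            function(row) all(row == obs)))
}

# every observed genotype vector over the given member domains
bf_all_observations <- function(ped, members, model) {
  doms <- lapply(members, function(m) {
    bf_domain(ped$sex[match(m, ped$id)], model)
  })
  grid <- as.matrix(expand.grid(doms))
  colnames(grid) <- members
  grid
}

# --- shared toy pedigrees (all <= 7 members) -------------------------------

trio_pedigree <- function(affection_child = "affected") {
  pedigree(id = c("F", "M", "C"),
           sex = c("male", "female", "male"),
           affection = c("unaffected", "unaffected", affection_child),
           father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"))
}

quartet_pedigree <- function() {
  pedigree(id = c("F", "M", "S1", "D1"),
           sex = c("male", "female", "male", "female"),
           affection = c("affected", "unaffected", "affected", "unknown"),
           father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"))
}

sixer_pedigree <- function() {
  # two generations, one married-in spouse, an unknown-phenotype grandchild
  pedigree(id = c("GF", "GM", "A1", "SP", "A2", "G1"),
           sex = c("male", "female", "female", "male", "male", "female"),
           affection = c("unaffected", "affected", "affected", "unaffected",
                         "unaffected", "unknown"),
           father_id = c(NA, NA, "GF", NA, "GF", "SP"),
           mother_id = c(NA, NA, "GM", NA, "GM", "A1"))
}

# --- toy transcripts -------------------------------------------------------

# two-exon plus-strand transcript, CDS = whole transcript
toy_tx_plus <- function(cds = NULL, gene = "TOY1") {
  if (is.null(cds)) cds <- paste0("ATG", "GGGAAACCCTTT", "TAA")  # 18 nt
  n <- nchar(cds)
  w1 <- 9L
  transcript_model(gene, paste0("TX_", gene), "5", "+",
                   exon_starts = c(1001L, 2001L),
                   exon_ends = c(1000L + w1, 2001L + (n - w1) - 1L),
                   cds_start = 1001L, cds_end = 2001L + (n - w1) - 1L,
                   cds_sequence = cds)
}

# equivalent minus-strand construction of the same coding sequence
toy_tx_minus <- function(cds = NULL, gene = "TOY2") {
  if (is.null(cds)) cds <- paste0("ATG", "GGGAAACCCTTT", "TAA")
  n <- nchar(cds)
  w1 <- 9L   # genomic-leftmost exon carries the CDS *end*
  transcript_model(gene, paste0("TX_", gene), "5", "-",
                   exon_starts = c(1001L, 2001L),
                   exon_ends = c(1000L + w1, 2001L + (n - w1) - 1L),
                   cds_start = 1001L, cds_end = 2001L + (n - w1) - 1L,
                   cds_sequence = cds)
}

seq_call <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}

quintet_calls <- function(I3, II2, II3, II4, III1) {
  c(`I-3` = I3, `II-2` = II2, `II-3` = II3, `II-4` = II4, `III-1` = III1)
}
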