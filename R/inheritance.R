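#' Inheritance-model consistency of a variant site
#'
#' Tests whether the observed genotype calls at a biallelic site can be
#' extended to a full genotype assignment over every pedigree member
#' (sequenced or not) that satisfies, simultaneously:
#' \enumerate{
#'   \item \emph{observation}: the assignment equals the observed call for
#'     every sequenced member with a non-missing call (missing calls are
#'     wildcards — exome coverage gaps);
#'   \item \emph{Mendelian transmission}: every non-founder's genotype is
#'     producible from its parents' gametes (an unrecorded parent
#'     contributes an unconstrained gamete);
#'   \item \emph{full penetrance}: affected members carry the model's risk
#'     genotype and unaffected members do not; members of unknown affection
#'     are unconstrained.
#' }
#' Risk genotypes: AD at least one alt allele; AR homozygous alt; XLD alt
#' hemizygote (males) or at least one alt (females); XLR alt hemizygote
#' (males) or homozygous alt (females). Male X genotypes are hemizygous
#' \{0, 1\}; de-novo mutation, phenocopies and reduced penetrance are not
#' modelled.
#'
#' @param site a biallelic [site_genotypes()].
#' @param ped a [pedigree()].
#' @param model `"AD"`, `"AR"`, `"XLD"` or `"XLR"`; the site's chromosome
#'   must lie in the model's scope (autosome for AD/AR, X for XLD/XLR).
#' @return `TRUE` iff at least one satisfying full assignment exists.
#' @seealso [enumerate_assignments()] (the exhaustive oracle),
#'   [filter_by_inheritance()]
#' @export
#' @examples
#' ped <- study_pedigree()
#' s <- site_genotypes("1", 156104651, "G", "T",
#'                     c(`I-3` = 0, `II-2` = 1, `II-3` = 1, `II-4` = 1,
#'                       `III-1` = 0))
#' site_matches_model(s, ped, "AD")  # TRUE: I-2 assignable as het carrier
site_matches_model <- function(site, ped, model) {
  assignment_search(site, ped, model, find_all = FALSE)$exists
}

#' Enumerate all satisfying full genotype assignments
#'
#' Exhaustively lists every full genotype assignment consistent with the
#' observed calls, Mendelian transmission and full penetrance under the
#' given model (see [site_matches_model()] for the constraint system).
#' Serves as the oracle for the early-exit matcher:
#' `site_matches_model(...)` equals `nrow(enumerate_assignments(...)) > 0`.
#'
#' @inheritParams site_matches_model
#' @param max_members exhaustive-search capacity bound; pedigrees larger
#'   than this raise an error (default 15).
#' @return Integer matrix, one row per satisfying assignment, one column
#'   per pedigree member (alt-allele counts; male X columns hemizygous).
#' @export
enumerate_assignments <- function(site, ped, model, max_members = 15) {
  if (nrow(ped) > max_members) {
    stop("pedigree exceeds exhaustive-search bound (", max_members,
         " members)", call. = FALSE)
  }
  assignment_search(site, ped, model, find_all = TRUE)$assignments
}

# Precomputed, validated traversal context reused across many sites.
ped_search_ctx <- function(ped) {
  validate_pedigree(ped)
  order_ids <- topo_order(ped)
  idx <- match(order_ids, ped$id)
  list(ped = ped, order_ids = order_ids, idx = idx,
       sex = ped$sex[idx], affection = ped$affection[idx],
       fa_pos = match(ped$father_id[idx], order_ids),
       mo_pos = match(ped$mother_id[idx], order_ids),
       founder = is.na(ped$father_id[idx]) & is.na(ped$mother_id[idx]),
       sequenced = ped$sequenced)
}

# Shared depth-first search over member genotypes in topological order.
assignment_search <- function(site, ped, model, find_all, ctx = NULL) {
  model <- match.arg(model, c("AD", "AR", "XLD", "XLR"))
  if (is.null(ctx)) ctx <- ped_search_ctx(ped)
  if (!is_biallelic(site)) {
    stop("site is not biallelic; apply prefilter_multiallelic() first",
         call. = FALSE)
  }
  cls <- chrom_class(site$chrom)
  scope <- model_scope(model)
  if (!identical(cls, scope)) {
    stop("site on chromosome ", site$chrom, " is outside the ", model,
         " model scope (", scope, ")", call. = FALSE)
  }
  ped <- ctx$ped
  unknown <- setdiff(names(site$calls), ped$id)
  if (length(unknown)) {
    stop("calls reference members absent from the pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  not_seq <- intersect(names(site$calls), ped$id[!ped$sequenced])
  if (length(not_seq)) {
    stop("calls present for unsequenced members: ",
         paste(not_seq, collapse = ", "), call. = FALSE)
  }

  order_ids <- ctx$order_ids
  n <- length(order_ids)
  idx <- ctx$idx
  sex <- ctx$sex
  fa_pos <- ctx$fa_pos    # NA when unrecorded
  mo_pos <- ctx$mo_pos
  on_x <- scope == "X"

  # per-member candidate genotypes: domain ∩ phenotype ∩ observation
  candidates <- vector("list", n)
  for (k in seq_len(n)) {
    dom <- genotype_domain(sex[k], on_x)
    aff <- ctx$affection[k]
    if (aff != "unknown") {
      risk <- risk_genotype(dom, model, sex[k])
      dom <- if (aff == "affected") dom[risk] else dom[!risk]
    }
    obs <- if (order_ids[k] %in% names(site$calls)) {
      site$calls[[order_ids[k]]]
    } else {
      NA_integer_
    }
    if (!is.na(obs)) {
      if (on_x && sex[k] == "male") obs <- min(obs, 1L)
      dom <- intersect(dom, obs)
    }
    if (!length(dom)) {
      return(list(exists = FALSE,
                  assignments = empty_assignment_matrix(ped$id)))
    }
    candidates[[k]] <- dom
  }

  found <- list()
  exists <- FALSE
  g <- integer(n)
  recurse <- function(k) {
    if (exists && !find_all) return()
    if (k > n) {
      exists <<- TRUE
      if (find_all) found[[length(found) + 1L]] <<- g
      return()
    }
    for (cand in candidates[[k]]) {
      fg <- if (is.na(fa_pos[k])) NA_integer_ else g[fa_pos[k]]
      mg <- if (is.na(mo_pos[k])) NA_integer_ else g[mo_pos[k]]
      if (ctx$founder[k] ||
          transmission_ok(cand, fg, mg, sex[k], on_x)) {
        g[k] <<- cand
        recurse(k + 1L)
        if (exists && !find_all) return()
      }
    }
  }
  recurse(1L)

  asn <- if (find_all && length(found)) {
    m <- do.call(rbind, found)
    colnames(m) <- order_ids
    m[, ped$id, drop = FALSE]
  } else {
    empty_assignment_matrix(ped$id)
  }
  list(exists = exists, assignments = asn)
}

empty_assignment_matrix <- function(ids) {
  matrix(integer(0), nrow = 0, ncol = length(ids),
         dimnames = list(NULL, ids))
}

genotype_domain <- function(sex, on_x) {
  if (on_x && sex == "male") 0:1 else 0:2
}

# logical vector over genotype values: is g a risk genotype under model?
risk_genotype <- function(g, model, sex) {
  switch(model,
    AD = g >= 1L,
    AR = g == 2L,
    XLD = if (sex == "male") g == 1L else g >= 1L,
    XLR = if (sex == "male") g == 1L else g == 2L
  )
}

# gametes a diploid genotype can transmit
gametes <- function(g) switch(as.character(g), `0` = 0L, `1` = 0:1, `2` = 1L)

# Can child genotype `cg` arise from parents `fg`/`mg` (NA = unrecorded,
# unconstrained gamete)? X transmission: sons take one maternal gamete;
# daughters take the paternal hemizygous allele plus one maternal gamete.
transmission_ok <- function(cg, fg, mg, child_sex, on_x) {
  m_gam <- if (is.na(mg)) 0:1 else gametes(mg)
  if (on_x) {
    if (child_sex == "male") return(cg %in% m_gam)
    f_allele <- if (is.na(fg)) 0:1 else fg
    return(any(outer(f_allele, m_gam, `+`) == cg))
  }
  f_gam <- if (is.na(fg)) 0:1 else gametes(fg)
  any(outer(f_gam, m_gam, `+`) == cg)
}

#' Partition sites by the inheritance models they are consistent with
#'
#' Applies [site_matches_model()] across a list of sites and every
#' applicable model. Sites on Y or MT are dropped unconditionally when
#' those scopes are excluded for the pedigree (and are never testable by
#' the four nuclear models regardless); autosomal sites are tested against
#' AD/AR, X sites against the retained X-linked models. A fast
#' per-member phenotype screen rejects most sites before the assignment
#' search runs.
#'
#' @param sites list of biallelic [site_genotypes()] (run
#'   [prefilter_multiallelic()] first).
#' @param ped a [pedigree()].
#' @param models `"auto"` (use [applicable_models()]) or an explicit
#'   character vector drawn from AD, AR, XLD, XLR.
#' @return A list with `buckets` (model -> list of retained sites),
#'   `counts` (model -> retained SNV/indel counts), `dropped_chrom`
#'   (number of sites dropped for excluded chromosome scope) and
#'   `models` used.
#' @export
filter_by_inheritance <- function(sites, ped, models = "auto") {
  if (identical(models, "auto")) {
    models <- applicable_models(ped)$models
  } else {
    models <- match.arg(models, c("AD", "AR", "XLD", "XLR"),
                        several.ok = TRUE)
  }
  buckets <- stats::setNames(vector("list", length(models)), models)
  for (m in models) buckets[[m]] <- list()
  dropped <- 0L
  if (length(sites)) {
    ctx <- ped_search_ctx(ped)
    cls <- vapply(sites, function(s) chrom_class(s$chrom), character(1))
    dropped <- sum(cls %in% c("Y", "MT"))
    for (m in models) {
      scope <- model_scope(m)
      in_scope <- which(cls == scope)
      keep <- in_scope[vapply(in_scope, function(i) {
        assignment_search(sites[[i]], ped, m, find_all = FALSE,
                          ctx = ctx)$exists
      }, logical(1))]
      buckets[[m]] <- sites[keep]
    }
  }
  counts <- lapply(buckets, function(b) {
    snv <- vapply(b, is_snv, logical(1))
    c(snvs = sum(snv), indels = sum(!snv))
  })
  list(buckets = buckets, counts = counts, dropped_chrom = dropped,
       models = models)
}

is_snv <- function(site) {
  nchar(site$ref) == 1L && all(nchar(site$alt) == 1L)
}
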