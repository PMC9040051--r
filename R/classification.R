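# Gene classification into cytonuclear functional tiers: propagation of a
# reference (model-species) annotation through orthogroups, combined with
# de novo targeting-predictor votes.

#' Classify genes into cytonuclear functional tiers
#'
#' A gene is *interacting* (and inherits the full tier chain and fine
#' category of the reference gene(s)) if its orthogroup contains a
#' reference gene whose product interacts with the mitochondrial or
#' plastid genomes or gene products.  Otherwise it is *organelle-targeted*
#' if at least one targeting predictor votes for that organelle **and**
#' at least 50% of the reference genes in its orthogroup are targeted to
#' the mitochondria or plastids (dual-targeted reference genes counted
#' once).  Otherwise it is non-organelle-targeted (NOT).  Genes with dual
#' targeting evidence belong to both organelle chains.  Genes absent from
#' all inputs are classified NOT with a warning flag.
#'
#' @param orthogroups Data frame: `orthogroup_id`, `gene_id`, `species`
#'   (reference genes carry the species value `"reference"`).
#' @param reference Data frame: `ref_gene_id` plus logical tier columns
#'   `mito_targeted`, `mito_interacting`, `mtec`, `plastid_targeted`,
#'   `plastid_interacting`, `ptec`, and a `category` string.
#' @param votes Data frame: `gene_id`, `mito_votes`, `plastid_votes`
#'   (counts of predictors, 0-4).
#' @param genes Optional character vector of genes to classify (default:
#'   all non-reference genes in `orthogroups`).
#' @return Data frame with the tier flags, `NOT` flag, `category`, `tier`
#'   (a single most-specific label) and `warn` flag per gene.
#' @export
classify_genes <- function(orthogroups, reference, votes, genes = NULL) {
  flags <- c("mito_targeted", "mito_interacting", "mtec",
             "plastid_targeted", "plastid_interacting", "ptec")
  is_ref <- orthogroups$species == "reference"
  if (is.null(genes))
    genes <- unique(orthogroups$gene_id[!is_ref])
  og_of <- split(orthogroups$orthogroup_id, orthogroups$gene_id)
  refs_in_og <- split(orthogroups$gene_id[is_ref],
                      orthogroups$orthogroup_id[is_ref])
  ridx <- function(ids) match(ids, reference$ref_gene_id)
  out <- lapply(genes, function(g) {
    row <- stats::setNames(as.list(rep(FALSE, length(flags))), flags)
    warn <- FALSE
    ogs <- og_of[[g]]
    refs <- unique(unlist(refs_in_og[ogs], use.names = FALSE))
    refs <- refs[!is.na(ridx(refs))]
    category <- ""
    v <- votes[match(g, votes$gene_id), , drop = FALSE]
    in_votes <- nrow(v) == 1L && !is.na(v$gene_id[1])
    if (length(refs) == 0L && (is.null(ogs) || length(ogs) == 0L) &&
        !in_votes) {
      warn <- TRUE
    } else if (length(refs) > 0L) {
      rr <- reference[ridx(refs), , drop = FALSE]
      inter <- rr$mito_interacting | rr$plastid_interacting
      if (any(inter)) {
        # inherit the union of the interacting reference genes' chains
        ri <- rr[inter, , drop = FALSE]
        for (f in flags) row[[f]] <- any(ri[[f]])
        cats <- unique(ri$category[nzchar(ri$category)])
        category <- paste(cats, collapse = ";")
      } else {
        frac_targeted <- mean(rr$mito_targeted | rr$plastid_targeted)
        if (frac_targeted >= 0.5 && in_votes) {
          if (v$mito_votes[1] >= 1L) row$mito_targeted <- TRUE
          if (v$plastid_votes[1] >= 1L) row$plastid_targeted <- TRUE
        }
      }
    }
    is_not <- !any(unlist(row))
    data.frame(gene_id = g, as.data.frame(row), NOT = is_not,
               category = category, warn = warn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$tier <- .primary_tier(out)
  out
}

# most specific single label, mito chain taking precedence at equal depth
.primary_tier <- function(df) {
  ifelse(df$mtec, "mtec",
  ifelse(df$ptec, "ptec",
  ifelse(df$mito_interacting, "mito_interacting",
  ifelse(df$plastid_interacting, "plastid_interacting",
  ifelse(df$mito_targeted, "mito_targeted",
  ifelse(df$plastid_targeted, "plastid_targeted", "NOT"))))))
}

#' Propagate per-species gene classifications to quintets
#'
#' Each quintet is labeled by the classification of its member from the
#' configured reference species (by default the maternal diploid model;
#' designs whose maternal diploid lacks a usable annotation use the
#' paternal diploid instead).  Quintets whose reference member is
#' unclassified are labeled NOT with a warning flag.
#'
#' @param quintets A `quintet_table`.
#' @param classification Output of [classify_genes()] for the reference
#'   species' genes.
#' @param reference_role `"diploid_maternal"` or `"diploid_paternal"`.
#' @return Data frame `gene_id`, `tier`, tier flags, `warn`.
#' @export
propagate_to_quintets <- function(quintets, classification,
                                  reference_role = c("diploid_maternal",
                                                     "diploid_paternal")) {
  reference_role <- match.arg(reference_role)
  member <- quintets[[reference_role]]
  idx <- match(member, classification$gene_id)
  flags <- c("mito_targeted", "mito_interacting", "mtec",
             "plastid_targeted", "plastid_interacting", "ptec")
  out <- data.frame(gene_id = quintets$gene_id, stringsAsFactors = FALSE)
  for (f in flags) out[[f]] <- ifelse(is.na(idx), FALSE,
                                      classification[[f]][idx])
  out$NOT <- !Reduce(`|`, out[flags])
  out$tier <- ifelse(is.na(idx), "NOT", classification$tier[idx])
  out$category <- ifelse(is.na(idx), "", classification$category[idx])
  out$warn <- is.na(idx)
  if (any(out$warn))
    warning(sum(out$warn), " quintet(s) have an unclassified ",
            reference_role, " member; labeled NOT")
  out
}
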