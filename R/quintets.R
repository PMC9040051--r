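# Orthologous-quintet inference: support collapsing, species-complete
# subtree extraction, lineage-duplicate trimming, merging of phylogenetic
# and syntenic quintet sets, and species-tree concordance checks.

# numeric support value per internal node (NA where absent/non-numeric)
.node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  length(sup) <- tree$Nnode
  sup
}

#' Collapse low-support splits into polytomies
#'
#' Removes every internal split whose bootstrap support is at or below
#' `threshold`, reattaching its children to its parent.  Missing support
#' values are never collapsed (only splits with measured low support are).
#' The tip set is unchanged and the operation is idempotent.
#'
#' @param tree A `phylo` with support values as internal node labels.
#' @param threshold Integer; splits with support <= threshold collapse.
#' @return A `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 50L) {
  sup <- .node_support(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_ids <- ntip + seq_len(tree$Nnode)
  drop <- node_ids[!is.na(sup) & sup <= threshold & node_ids != root]
  if (length(drop) == 0L) return(tree)
  .drop_internal_nodes(tree, drop)
}

# remove internal (non-root) nodes, attaching their children to the parent
.drop_internal_nodes <- function(tree, drop) {
  edge <- tree$edge
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  final_parent <- function(n) {
    while (n %in% drop) n <- parent_of[n]
    n
  }
  keep_edge <- !(edge[, 2] %in% drop)
  new_edge <- edge[keep_edge, , drop = FALSE]
  new_edge[, 1] <- vapply(new_edge[, 1], final_parent, integer(1))
  lens <- if (!is.null(tree$edge.length)) tree$edge.length[keep_edge]
  ntip <- length(tree$tip.label)
  old_nodes <- sort(unique(new_edge[, 1]))
  new_ids <- stats::setNames(ntip + seq_along(old_nodes), old_nodes)
  map_id <- function(v) ifelse(v <= ntip, v, new_ids[as.character(v)])
  out <- list(edge = cbind(map_id(new_edge[, 1]), map_id(new_edge[, 2])),
              tip.label = tree$tip.label,
              Nnode = length(old_nodes))
  if (!is.null(lens)) out$edge.length <- lens
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[old_nodes - ntip]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

# tip indices below each node (tips map to themselves)
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    below[[po[k, 1]]] <- c(below[[po[k, 1]]], below[[po[k, 2]]])
  }
  below
}

#' Extract minimally inclusive species-complete subtrees
#'
#' Returns every clade of a (rooted) gene tree that contains at least one
#' tip from each of the four species of the design and none of whose
#' descendant clades also does -- the monophyletic, minimally inclusive,
#' species-complete subtrees from which single-copy quintets are built.
#' The returned subtrees are disjoint in tips; an empty list is returned
#' when no clade qualifies.
#'
#' @param tree A `phylo`.
#' @param map A [species_map()].
#' @return List of `phylo` subtrees.
#' @export
extract_species_complete_subtrees <- function(tree, map) {
  ntip <- length(tree$tip.label)
  roles <- resolve_roles(tree, map)
  sp <- roles$role[match(tree$tip.label, roles$id)]
  below <- .tips_below(tree)
  need <- c("outgroup", "diploid_maternal", "diploid_paternal", "polyploid")
  complete <- vapply(seq_len(ntip + tree$Nnode), function(n) {
    all(need %in% sp[below[[n]]])
  }, logical(1))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  has_complete_desc <- function(n) {
    for (k in kids[[as.character(n)]] %||% integer(0)) {
      if (complete[k] || has_complete_desc(k)) return(TRUE)
    }
    FALSE
  }
  nodes <- which(complete)
  minimal <- nodes[!vapply(nodes, has_complete_desc, logical(1))]
  lapply(minimal, function(n) {
    if (n <= ntip) stop("internal error: tip cannot be species-complete")
    if (n == ntip + 1L) tree else ape::extract.clade(tree, n)
  })
}

#' Trim lineage-specific duplicates from a subtree
#'
#' Within each maximal clade whose tips all belong to one species (one
#' subgenome, for the polyploid), keeps the tip with the longest ungapped
#' sequence; ties are broken by a seeded uniform draw, so reruns with the
#' same seed retain the same tip.
#'
#' @param subtree A `phylo`.
#' @param lengths Named numeric: ungapped sequence length per tip id.
#' @param map A [species_map()].
#' @param seed Integer seed for tie-breaking.
#' @return The reduced `phylo`.
#' @export
trim_lineage_duplicates <- function(subtree, lengths, map, seed = 1L) {
  roles <- resolve_roles(subtree, map)
  grp <- ifelse(roles$role == "polyploid",
                paste0("polyploid:", roles$subgenome), roles$role)
  names(grp) <- roles$id
  ntip <- length(subtree$tip.label)
  below <- .tips_below(subtree)
  tipgrp <- grp[subtree$tip.label]
  node_grp <- vapply(seq_len(ntip + subtree$Nnode), function(n) {
    g <- unique(tipgrp[below[[n]]])
    if (length(g) == 1L) g else NA_character_
  }, character(1))
  parent_of <- integer(ntip + subtree$Nnode)
  parent_of[subtree$edge[, 2]] <- subtree$edge[, 1]
  # maximal single-group nodes: single-group whose parent is not
  maximal <- which(!is.na(node_grp) &
                     (parent_of == 0L | is.na(node_grp[pmax(parent_of, 1L)])))
  drop <- character(0)
  picks <- .with_seed(seed, {
    for (n in maximal) {
      tips <- subtree$tip.label[below[[n]]]
      if (length(tips) < 2L) next
      len <- lengths[tips]
      if (anyNA(len)) stop("missing sequence length for: ",
                           paste(tips[is.na(len)], collapse = ", "))
      best <- tips[len == max(len)]
      keep <- if (length(best) == 1L) best else
        best[sample.int(length(best), 1L)]
      drop <- c(drop, setdiff(tips, keep))
    }
    drop
  })
  if (length(picks) == 0L) return(subtree)
  ape::drop.tip(subtree, picks)
}

#' Check quintet gene-tree concordance with the species topology
#'
#' Roots the five-tip gene tree on the outgroup and asks whether both
#' species-tree cherries -- (polyploid_paternal, diploid_paternal) and
#' (polyploid_maternal, diploid_maternal) -- are present as resolved
#' splits.  The verdict is `"concordant"` when both are present,
#' `"discordant"` when any resolved split conflicts with them, and
#' `"unresolved"` when polytomies prevent both verdicts.
#'
#' @param tree A `phylo` with exactly the five quintet tips.
#' @param map A [species_map()] (or `NULL` when tips are role names).
#' @return One of `"concordant"`, `"discordant"`, `"unresolved"`.
#' @export
check_topology_concordance <- function(tree, map = NULL) {
  if (length(tree$tip.label) != 5L)
    stop("concordance check requires exactly 5 tips, got ",
         length(tree$tip.label))
  role <- if (is.null(map)) {
    if (!setequal(tree$tip.label, quintet_roles()))
      stop("tips are not role names; supply a species_map")
    stats::setNames(tree$tip.label, tree$tip.label)
  } else {
    rr <- resolve_roles(tree, map)
    if (anyDuplicated(rr$quintet_role) || any(rr$quintet_role == "polyploid"))
      stop("tips must resolve to the five distinct quintet roles")
    stats::setNames(rr$quintet_role, rr$id)
  }
  utree <- ape::unroot(tree)
  ntip <- 5L
  below <- .tips_below(utree)
  internal <- setdiff(unique(utree$edge[, 2]), seq_len(ntip))
  splits <- lapply(internal, function(n) sort(below[[n]]))
  # as unordered bipartitions over roles
  tipsets <- lapply(splits, function(s) {
    a <- sort(unname(role[utree$tip.label[s]]))
    b <- sort(setdiff(unname(role[utree$tip.label]), a))
    if (length(a) > length(b) ||
        (length(a) == length(b) && paste(a, collapse = ",") >
         paste(b, collapse = ","))) list(b, a) else list(a, b)
  })
  want <- list(sort(c("polyploid_paternal", "diploid_paternal")),
               sort(c("polyploid_maternal", "diploid_maternal")))
  seen <- vapply(tipsets, function(ts) {
    paste(ts[[1]], collapse = ",")
  }, character(1))
  seen <- seen[vapply(tipsets, function(ts) length(ts[[1]]) == 2L,
                      logical(1))]
  wanted <- vapply(want, paste, "", collapse = ",")
  if (length(seen) > 0 && any(!seen %in% wanted)) return("discordant")
  if (all(wanted %in% seen)) return("concordant")
  "unresolved"
}

#' Filter quintets by tree-wide synonymous divergence
#'
#' Poorly aligned quintets show inflated synonymous tree length; quintets
#' whose tree-wide dS exceeds the per-dataset cutoff are dropped.  The
#' boundary is kept (a maximum cutoff is read as inclusive).
#'
#' @param rates A `branch_rates` fit (or anything with `$tree_dS`).
#' @param cutoff Per-dataset maximum tree-wide dS.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_by_tree_ds <- function(rates, cutoff) {
  isTRUE(rates$tree_dS <= cutoff)
}

# ---- quintet tables and merging --------------------------------------------

#' Construct a quintet table
#'
#' @param gene_id Character vector of stable identifiers.
#' @param members Data frame (or matrix) with one column per quintet role.
#' @param source `"phylogenetic"`, `"syntenic"` or `"both"`.
#' @return Data frame of class `quintet_table`.
#' @export
quintet_table <- function(gene_id, members, source = "phylogenetic") {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (!setequal(colnames(members), quintet_roles()))
    stop("members must have one column per quintet role")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in quintet set")
  out <- cbind(data.frame(gene_id = as.character(gene_id),
                          stringsAsFactors = FALSE),
               members[, quintet_roles()])
  out$source <- source
  class(out) <- c("quintet_table", "data.frame")
  out
}

.member_key <- function(q) {
  apply(q[, quintet_roles(), drop = FALSE], 1L,
        function(r) paste(sort(r), collapse = "|"))
}

#' Merge phylogenetic and syntenic quintet sets
#'
#' The intersection contains quintets whose unordered five-member sets are
#' identical in both inputs (reported once).  The union adds, on top of the
#' intersection, quintets from either input that share no member with any
#' quintet of the other input.  Quintets that overlap with, but are not
#' identical to, a quintet of the other input are conflicts and are
#' excluded from both outputs.
#'
#' @param phylo,syntenic `quintet_table`s.
#' @return List with `union`, `intersection`, `conflicts` quintet tables.
#' @export
merge_quintet_sets <- function(phylo, syntenic) {
  if (anyDuplicated(phylo$gene_id)) stop("duplicate gene_id in phylo set")
  if (anyDuplicated(syntenic$gene_id))
    stop("duplicate gene_id in syntenic set")
  kp <- .member_key(phylo)
  ks <- .member_key(syntenic)
  # member id -> quintet indices of the other set
  idx_of <- function(q) {
    m <- unlist(q[, quintet_roles()], use.names = FALSE)
    split(rep(seq_len(nrow(q)), 5L), m)
  }
  map_s <- idx_of(syntenic)
  map_p <- idx_of(phylo)
  hits <- function(q, map) lapply(seq_len(nrow(q)), function(i) {
    unique(unlist(map[as.character(unlist(q[i, quintet_roles()]))],
                  use.names = FALSE))
  })
  hit_p <- hits(phylo, map_s)     # syntenic quintets sharing a member
  hit_s <- hits(syntenic, map_p)
  in_both_p <- vapply(seq_len(nrow(phylo)), function(i)
    any(ks[hit_p[[i]]] == kp[i]), logical(1))
  in_both_s <- vapply(seq_len(nrow(syntenic)), function(i)
    any(kp[hit_s[[i]]] == ks[i]), logical(1))
  conflict_p <- vapply(seq_len(nrow(phylo)), function(i)
    any(ks[hit_p[[i]]] != kp[i]), logical(1))
  conflict_s <- vapply(seq_len(nrow(syntenic)), function(i)
    any(kp[hit_s[[i]]] != ks[i]), logical(1))
  inter <- phylo[in_both_p & !conflict_p, , drop = FALSE]
  if (nrow(inter)) inter$source <- "both"
  uni <- rbind(inter,
               phylo[!in_both_p & !conflict_p, , drop = FALSE],
               syntenic[!in_both_s & !conflict_s, , drop = FALSE])
  confl <- rbind(phylo[conflict_p, , drop = FALSE],
                 syntenic[conflict_s, , drop = FALSE])
  lapply(list(union = uni, intersection = inter, conflicts = confl),
         function(x) { rownames(x) <- NULL; x })
}
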