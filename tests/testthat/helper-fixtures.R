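# Shared fixtures: tiny alignments, role maps, and simulated datasets
# used across the test files.  Everything is generated in code.

roles5 <- quintet_roles()

read_gene_tree_text <- function(txt) ape::read.tree(text = txt)

# a tiny valid codon alignment with ids = role names
tiny_alignment <- function(codons = c("ATGGCT", "ATGGCT", "ATGGCA",
                                      "ATGGCA", "ATGTCT")) {
  codon_alignment(stats::setNames(codons, roles5))
}

default_species_map <- function() {
  species_map(outgroup = "Out", diploid_maternal = "Dmat",
              diploid_paternal = "Dpat", polyploid = "Poly",
              maternal_tags = "A", paternal_tags = "B")
}

# quintet table with synthetic member ids (one row per gene)
toy_quintet_table <- function(gene_ids, source = "phylogenetic") {
  members <- do.call(rbind, lapply(gene_ids, function(g) {
    stats::setNames(as.data.frame(as.list(paste0(g, "_", 1:5)),
                                  stringsAsFactors = FALSE), roles5)
  }))
  quintet_table(gene_ids, members, source)
}

# a simulated dataset of n_cat + n_not genes with given branch omegas,
# concatenated into category and NOT alignments
simulated_category_dataset <- function(seed, n_cat, n_not, n_codons,
                                       omega_cat = 0.2, omega_not = 0.2) {
  om_cat <- rep(omega_cat, 7)
  cat_alns <- simulate_quintet_genes(
    quintet_sim_params(omega_by_branch = om_cat, n_codons = n_codons,
                       seed = seed),
    n_cat, prefix = "cat")
  not_alns <- simulate_quintet_genes(
    quintet_sim_params(omega_by_branch = rep(omega_not, 7),
                       n_codons = n_codons, seed = seed + 10000L),
    n_not, prefix = "not")
  alns <- c(cat_alns, not_alns)
  tiers <- stats::setNames(c(rep("organelle", n_cat), rep("NOT", n_not)),
                           names(alns))
  q <- toy_quintet_table(names(alns))
  concatenate_by_category(q, alns, tiers)
}

# dataset where the organelle category has branch-specific subgenome omegas
biased_category_dataset <- function(seed, n_cat, n_not, n_codons,
                                    omega_pat, omega_mat,
                                    omega_background = 0.2) {
  om <- rep(omega_background, 7)
  om[1] <- omega_pat   # polyploid_paternal
  om[3] <- omega_mat   # polyploid_maternal
  cat_alns <- simulate_quintet_genes(
    quintet_sim_params(omega_by_branch = om, n_codons = n_codons,
                       seed = seed),
    n_cat, prefix = "cat")
  not_alns <- simulate_quintet_genes(
    quintet_sim_params(omega_by_branch = rep(omega_background, 7),
                       n_codons = n_codons, seed = seed + 10000L),
    n_not, prefix = "not")
  alns <- c(cat_alns, not_alns)
  tiers <- stats::setNames(c(rep("organelle", n_cat), rep("NOT", n_not)),
                           names(alns))
  q <- toy_quintet_table(names(alns))
  concatenate_by_category(q, alns, tiers)
}

# normalized-ratio test on one dataset: category gene bootstrap normalized
# by the NOT point ratio; returns the normalized result
normalized_category_test <- function(conc, B, seed,
                                     category = "organelle") {
  rc <- gene_bootstrap_omega_ratio(conc[[category]], B = B,
                                   optimizer_replicates = 1, seed = seed,
                                   category = category)
  rn_fit <- fit_branch_model(conc$NOT)
  not_ratio <- structure(
    list(ratio = rn_fit$branches$omega[1] / rn_fit$branches$omega[3]),
    class = "omega_ratio_result")
  normalize_ratio(rc, not_ratio)
}

# random bifurcating tree over synthetic species tips (for subtree tests)
random_species_tree <- function(ntip, map, seed_offset = 0) {
  specs <- c("Out_", "Dmat_", "Dpat_", "Poly_A", "Poly_B")
  labs <- paste0(sample(specs, ntip, replace = TRUE),
                 sprintf("x%03d", seq_len(ntip)))
  tr <- ape::rtree(ntip, tip.label = labs)
  tr$node.label <- NULL
  tr
}

# brute-force oracle: all minimally inclusive species-complete clades
brute_force_complete_subtrees <- function(tree, map) {
  ntip <- length(tree$tip.label)
  roles <- resolve_roles(tree, map)
  sp <- roles$role[match(tree$tip.label, roles$id)]
  need <- c("outgroup", "diploid_maternal", "diploid_paternal",
            "polyploid")
  # tip sets below each internal node by repeated edge scanning
  tipset <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- integer(0)
    for (k in kids) {
      if (k <= ntip) out <- c(out, k) else out <- c(out, tipset(k))
    }
    out
  }
  nodes <- ntip + seq_len(tree$Nnode)
  sets <- lapply(nodes, tipset)
  complete <- vapply(sets, function(s) all(need %in% sp[s]), logical(1))
  minimal <- vapply(seq_along(nodes), function(i) {
    if (!complete[i]) return(FALSE)
    for (j in seq_along(nodes)) {
      if (j != i && complete[j] &&
          all(sets[[j]] %in% sets[[i]]) &&
          length(sets[[j]]) < length(sets[[i]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  lapply(which(minimal), function(i) sort(tree$tip.label[sets[[i]]]))
}

# direct hypergeometric enumeration of the two-sided Fisher p-value
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# direct enumeration of the two-sided exact binomial p-value (null 0.5)
binom_p_enum <- function(x, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  p0 <- stats::dbinom(x, n, 0.5)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
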