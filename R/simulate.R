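# Synthetic-data generators: every input the pipeline consumes can be
# produced here with the statistical structure the analysis assumes, so the
# downstream stages are fully testable without any external download.

#' Parameters for quintet alignment simulation
#'
#' The generating process is the same MG94xHKY codon model the likelihood
#' engine fits: the fixed species topology
#' `((polyploid_paternal, diploid_paternal), (polyploid_maternal,
#' diploid_maternal), outgroup)` with per-branch expected substitutions per
#' codon (`branch_lengths`), per-branch dN/dS (`omega_by_branch`), a shared
#' transition/transversion ratio `kappa`, and F3x4-family stationary codon
#' frequencies.  Defaults mimic a typical allotetraploid quintet: short
#' terminal and ancestral ingroup branches, a longer outgroup branch, mild
#' purifying selection (omega 0.2), kappa 2, and slightly AT-rich plant
#' coding-sequence base composition.
#'
#' @param branch_lengths Numeric(7), expected substitutions/codon for
#'   branches in engine order (polyploid_paternal, diploid_paternal,
#'   polyploid_maternal, diploid_maternal, outgroup, paternal_ancestral,
#'   maternal_ancestral).
#' @param kappa Transition/transversion ratio.
#' @param omega_by_branch Numeric(7) dN/dS per branch (recycled if length 1).
#' @param codon_freqs Optional 61-vector of sense codon frequencies
#'   (projected onto the F3x4 family, see [codon_model_spec()]).
#' @param pi3x4 Optional 3 x 4 positional nucleotide frequency matrix.
#' @param n_codons Alignment length in codons.
#' @param seed Integer seed.
#' @return Object of class `quintet_sim_params`.
#' @export
quintet_sim_params <- function(branch_lengths = c(0.05, 0.05, 0.05, 0.05,
                                                  0.30, 0.02, 0.02),
                               kappa = 2, omega_by_branch = 0.2,
                               codon_freqs = NULL, pi3x4 = NULL,
                               n_codons = 400L, seed = 1L) {
  omega_by_branch <- rep_len(omega_by_branch, 7L)
  stopifnot(length(branch_lengths) == 7L, all(branch_lengths >= 0),
            all(omega_by_branch >= 0), kappa > 0, n_codons >= 0)
  if (is.null(pi3x4) && is.null(codon_freqs))
    pi3x4 <- matrix(rep(c(0.28, 0.20, 0.23, 0.29), each = 3), 3, 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  spec <- codon_model_spec(kappa = kappa, codon_freqs = codon_freqs,
                           pi3x4 = pi3x4)
  structure(list(branch_lengths = branch_lengths, kappa = kappa,
                 omega_by_branch = omega_by_branch,
                 codon_freqs = spec$codon_freqs, pi3x4 = spec$pi3x4,
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "quintet_sim_params")
}

#' Simulate a quintet codon alignment
#'
#' Draws root codons from the stationary distribution and evolves them
#' along each branch with the exact transition probabilities
#' `exp(Q t)` of the branch-specific MG94xHKY generator.  Returns the
#' realized alignment, the generating tree (branch lengths in expected
#' substitutions per codon), and the true per-branch rates in the same
#' dN/dS convention the ML fit reports, so simulated truth and fitted
#' estimates are directly comparable.
#'
#' @param params A [quintet_sim_params()].
#' @return List with `alignment` (a `codon_alignment` whose ids are the
#'   role names), `tree` (`phylo`), `true_rates` (a `branch_rates`-style
#'   per-branch table of t, dN, dS, omega), and `internal_states` (the
#'   realized ancestral sequences at the three internal nodes, useful for
#'   validating reconstruction).
#' @export
simulate_quintet_alignment <- function(params) {
  stopifnot(inherits(params, "quintet_sim_params"))
  if (params$n_codons == 0L) stop("zero-length alignment requested")
  tab <- .codon_tables()
  bf <- .bf_matrix(params$pi3x4)
  pi61 <- as.numeric(params$codon_freqs)
  n <- params$n_codons
  P <- lapply(1:7, function(b) codon_pmatrix_cpp(
    params$kappa, params$omega_by_branch[b], params$branch_lengths[b],
    pi61, bf, tab$cls))
  .with_seed(params$seed, {
    root <- sample.int(61L, n, replace = TRUE, prob = pi61)
    evolve <- function(parent, Pb) {
      child <- integer(n)
      for (s in unique(parent)) {
        idx <- which(parent == s)
        child[idx] <- sample.int(61L, length(idx), replace = TRUE,
                                 prob = Pb[s, ])
      }
      child
    }
    n1 <- evolve(root, P[[6]])
    n2 <- evolve(root, P[[7]])
    tips <- list(
      polyploid_paternal = evolve(n1, P[[1]]),
      diploid_paternal   = evolve(n1, P[[2]]),
      polyploid_maternal = evolve(n2, P[[3]]),
      diploid_maternal   = evolve(n2, P[[4]]),
      outgroup           = evolve(root, P[[5]]))
    seqs <- vapply(tips, function(st) paste(tab$codons[st], collapse = ""),
                   character(1))
    aln <- codon_alignment(seqs, validate = FALSE)
    internal <- vapply(list(paternal_ancestral = n1,
                            maternal_ancestral = n2, root = root),
                       function(st) paste(tab$codons[st], collapse = ""),
                       character(1))
    flows <- .flow_rates(pi61, bf)
    dn <- ds <- numeric(7)
    for (b in 1:7) {
      dd <- .branch_dnds(params$branch_lengths[b],
                         params$omega_by_branch[b], params$kappa, flows)
      dn[b] <- dd$dN; ds[b] <- dd$dS
    }
    true_rates <- data.frame(branch = .branch_labels,
                             t = params$branch_lengths, dN = dn, dS = ds,
                             omega = params$omega_by_branch,
                             stringsAsFactors = FALSE)
    tr <- .quintet_phylo(params$branch_lengths)
    list(alignment = aln, tree = tr, true_rates = true_rates,
         internal_states = internal)
  })
}

#' Simulate a set of independent quintet genes under shared parameters
#'
#' Draws `n_genes` independent codon alignments from the same generating
#' process (one long simulation sliced into genes, which is equivalent for
#' i.i.d. codon sites and avoids recomputing the transition matrices per
#' gene).
#'
#' @param params A [quintet_sim_params()]; its `n_codons` is the length of
#'   every gene.
#' @param n_genes Number of genes.
#' @param prefix Gene identifier prefix.
#' @return Named list of `codon_alignment`s (ids are the role names).
#' @export
simulate_quintet_genes <- function(params, n_genes, prefix = "g") {
  long <- params
  long$n_codons <- params$n_codons * as.integer(n_genes)
  sim <- simulate_quintet_alignment(long)
  width <- params$n_codons * 3L
  out <- lapply(seq_len(n_genes), function(g) {
    from <- (g - 1L) * width + 1L
    seqs <- vapply(sim$alignment$seqs, substr, "", from, from + width - 1L)
    codon_alignment(seqs, validate = FALSE)
  })
  stats::setNames(out, sprintf("%s%04d", prefix, seq_len(n_genes)))
}

# rooted quintet phylo with the engine's branch lengths
.quintet_phylo <- function(t, tips = quintet_roles()) {
  txt <- sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g,%s:%g);",
                 tips[1], t[1], tips[2], t[2], t[6],
                 tips[3], t[3], tips[4], t[4], t[7],
                 tips[5], t[5])
  ape::read.tree(text = txt)
}

# ---- gene tree sets --------------------------------------------------------

#' Simulate a set of gene trees for quintet inference
#'
#' Each gene tree starts from the species topology with one tip per role.
#' With probability `discordance_rate` one diploid tip is swapped with the
#' opposite-subgenome polyploid tip (emulating gene conversion or
#' homoeologous exchange); with probability `duplication_rate` a random tip
#' is duplicated into a paralog cherry (so every affected tree has >= 6
#' tips); with probability `low_support_rate` a randomly chosen internal
#' split receives a low bootstrap support value (<= 50), all other splits
#' receiving high support (81-100).
#'
#' Tip labels follow the default species-map identifier rule:
#' `Out_`, `Dmat_`, `Dpat_` prefixes for the single-copy genomes and
#' `Poly_A`/`Poly_B` chromosome-coded subgenomes for the polyploid.
#'
#' @param n_genes Number of trees.
#' @param discordance_rate,duplication_rate,low_support_rate Probabilities
#'   in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `trees` (list of `phylo`), `truth` (data frame:
#'   gene_id, discordant, duplicated, low_support) and `species_map`.
#' @export
simulate_gene_tree_set <- function(n_genes, discordance_rate = 0.1,
                                   duplication_rate = 0.1,
                                   low_support_rate = 0.1, seed = 1L) {
  stopifnot(discordance_rate >= 0, discordance_rate <= 1,
            duplication_rate >= 0, duplication_rate <= 1,
            low_support_rate >= 0, low_support_rate <= 1)
  map <- species_map(outgroup = "Out", diploid_maternal = "Dmat",
                     diploid_paternal = "Dpat", polyploid = "Poly",
                     maternal_tags = "A", paternal_tags = "B")
  .with_seed(seed, {
    trees <- vector("list", n_genes)
    disc <- stats::runif(n_genes) < discordance_rate
    dup <- stats::runif(n_genes) < duplication_rate
    low <- stats::runif(n_genes) < low_support_rate
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%04d", g)
      lab <- c(polyploid_paternal = paste0("Poly_B01", gid),
               diploid_paternal   = paste0("Dpat_", gid),
               polyploid_maternal = paste0("Poly_A01", gid),
               diploid_maternal   = paste0("Dmat_", gid),
               outgroup           = paste0("Out_", gid))
      if (disc[g]) {
        # swap one diploid with the opposite-subgenome polyploid tip
        if (stats::runif(1) < 0.5)
          lab[c("diploid_paternal", "polyploid_maternal")] <-
            lab[c("polyploid_maternal", "diploid_paternal")]
        else
          lab[c("diploid_maternal", "polyploid_paternal")] <-
            lab[c("polyploid_paternal", "diploid_maternal")]
      }
      bl <- stats::runif(7, 0.02, 0.3)
      parts <- stats::setNames(sprintf("%s:%g",
        lab[c("polyploid_paternal", "diploid_paternal",
              "polyploid_maternal", "diploid_maternal", "outgroup")],
        bl[1:5]), c("polyploid_paternal", "diploid_paternal",
                    "polyploid_maternal", "diploid_maternal", "outgroup"))
      if (dup[g]) {
        victim <- sample(names(parts), 1L)
        parts[victim] <- sprintf("(%s:0.01,%sp:0.01):%g", lab[victim],
                                 lab[victim], bl[match(victim, names(parts))])
      }
      txt <- sprintf("((%s,%s):%g,(%s,%s):%g,%s);",
                     parts["polyploid_paternal"], parts["diploid_paternal"],
                     bl[6],
                     parts["polyploid_maternal"], parts["diploid_maternal"],
                     bl[7], parts["outgroup"])
      tr <- ape::read.tree(text = txt)
      nn <- tr$Nnode
      sup <- sample(81:100, nn, replace = TRUE)
      if (low[g] && nn > 1L) sup[sample(2:nn, 1L)] <- sample(0:50, 1L)
      sup[1L] <- NA  # root has no support
      tr$node.label <- ifelse(is.na(sup), "", as.character(sup))
      trees[[g]] <- tr
    }
    list(trees = trees,
         truth = data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                            discordant = disc, duplicated = dup,
                            low_support = low, stringsAsFactors = FALSE),
         species_map = map)
  })
}

# ---- gene content ----------------------------------------------------------

#' Parameters for subgenome gene-content simulation
#'
#' @param n_genes Integer (or named integer vector per category): ancestral
#'   gene count.
#' @param loss_prob Per-subgenome homoeolog loss probability: numeric(2)
#'   `c(paternal, maternal)`, or a 2-column matrix with one row per
#'   category.
#' @param seed Integer seed.
#' @return Object of class `content_sim_params`.
#' @export
content_sim_params <- function(n_genes = 10000L,
                               loss_prob = c(paternal = 0.2,
                                             maternal = 0.2),
                               seed = 1L) {
  if (is.null(names(n_genes))) names(n_genes) <- paste0(
    "category", seq_along(n_genes))
  lp <- if (is.matrix(loss_prob)) loss_prob else
    matrix(loss_prob, nrow = length(n_genes), ncol = 2, byrow = TRUE)
  colnames(lp) <- c("paternal", "maternal")
  rownames(lp) <- names(n_genes)
  stopifnot(all(lp >= 0), all(lp <= 1))
  structure(list(n_genes = n_genes, loss_prob = lp,
                 seed = as.integer(seed)),
            class = "content_sim_params")
}

#' Simulate subgenome gene-content tables
#'
#' Each ancestral gene independently retains or loses its paternal and
#' maternal homoeolog with the per-subgenome loss probabilities, emulating
#' (possibly biased) fractionation after allopolyploidy.
#'
#' @param params A [content_sim_params()].
#' @return Data frame with one row per category: `n_pat`, `n_mat` (genes
#'   present on each subgenome), `n_both` (retained duplicates), `n_single`
#'   (exactly one copy retained), `n_dip_pat`, `n_dip_mat` (diploid model
#'   counts, equal to the ancestral count).
#' @export
simulate_gene_content <- function(params) {
  stopifnot(inherits(params, "content_sim_params"))
  .with_seed(params$seed, {
    out <- lapply(seq_along(params$n_genes), function(k) {
      n <- params$n_genes[[k]]
      keep_p <- stats::runif(n) >= params$loss_prob[k, "paternal"]
      keep_m <- stats::runif(n) >= params$loss_prob[k, "maternal"]
      data.frame(category = names(params$n_genes)[k],
                 n_pat = sum(keep_p), n_mat = sum(keep_m),
                 n_both = sum(keep_p & keep_m),
                 n_single = sum(xor(keep_p, keep_m)),
                 n_dip_pat = n, n_dip_mat = n,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# ---- classification tables -------------------------------------------------

.CLASS_TIERS <- c("NOT",
                  "mito_targeted", "mito_interacting", "mtec",
                  "plastid_targeted", "plastid_interacting", "ptec")

#' Simulate classification input tables
#'
#' Generates the three tables the classifier consumes -- orthogroup
#' membership, a reference (model-species) annotation with interaction
#' tiers, and a targeting-predictor vote table -- jointly consistent, so
#' that with `predictor_error_rate = 0` the classification rule recovers
#' every gene's true tier exactly.
#'
#' @param n_genes Number of focal genes.
#' @param tier_proportions Named numeric over
#'   `c("NOT","mito_targeted","mito_interacting","mtec","plastid_targeted",
#'   "plastid_interacting","ptec")`; must sum to 1.
#' @param dual_target_rate Probability that an organelle gene carries both
#'   organelle chains.
#' @param predictor_error_rate Probability that the predictor votes for a
#'   gene are flipped (targeted genes lose all votes; NOT genes gain one).
#' @param seed Integer seed.
#' @return List with `orthogroups`, `reference`, `votes` (data frames) and
#'   `truth` (gene_id, tier, dual).
#' @export
simulate_classification_tables <- function(n_genes,
                                           tier_proportions = c(
                                             NOT = 0.80,
                                             mito_targeted = 0.06,
                                             mito_interacting = 0.025,
                                             mtec = 0.01,
                                             plastid_targeted = 0.07,
                                             plastid_interacting = 0.025,
                                             ptec = 0.01),
                                           dual_target_rate = 0.05,
                                           predictor_error_rate = 0,
                                           seed = 1L) {
  stopifnot(abs(sum(tier_proportions) - 1) < 1e-9,
            all(names(tier_proportions) %in% .CLASS_TIERS))
  .with_seed(seed, {
    tier <- sample(names(tier_proportions), n_genes, replace = TRUE,
                   prob = tier_proportions)
    dual <- tier != "NOT" & stats::runif(n_genes) < dual_target_rate
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    og_id <- sprintf("OG%05d", seq_len(n_genes))
    categories <- c(mito_interacting = "mito RNA processing",
                    mtec = "OXPHOS complex",
                    plastid_interacting = "plastid transcription",
                    ptec = "chlororibosome")
    mito_side <- tier %in% c("mito_targeted", "mito_interacting", "mtec")
    plastid_side <- tier %in% c("plastid_targeted", "plastid_interacting",
                                "ptec")
    interacting <- tier %in% c("mito_interacting", "mtec",
                               "plastid_interacting", "ptec")
    organelle <- tier != "NOT"
    flags <- data.frame(
      mito_targeted = mito_side | (dual & organelle),
      mito_interacting = interacting & mito_side,
      mtec = tier == "mtec",
      plastid_targeted = plastid_side | (dual & organelle),
      plastid_interacting = interacting & plastid_side,
      ptec = tier == "ptec")
    rg <- paste0("AT", sprintf("%05d", seq_len(n_genes)))
    reference <- cbind(data.frame(ref_gene_id = rg,
                                  stringsAsFactors = FALSE),
                       flags,
                       data.frame(category = ifelse(
                         interacting, unname(categories[tier]), ""),
                         stringsAsFactors = FALSE))
    orthogroups <- data.frame(
      orthogroup_id = rep(og_id, each = 2L),
      gene_id = as.vector(rbind(gene_id, rg)),
      species = rep(c("focal", "reference"), n_genes),
      stringsAsFactors = FALSE)
    flip <- predictor_error_rate > 0 &
      stats::runif(n_genes) < predictor_error_rate
    vote_mito <- xor(flags$mito_targeted, flip & !flags$mito_targeted) &
      !(flip & flags$mito_targeted)
    vote_plastid <- xor(flags$plastid_targeted,
                        flip & !flags$plastid_targeted) &
      !(flip & flags$plastid_targeted)
    votes <- data.frame(
      gene_id = gene_id,
      mito_votes = as.integer(vote_mito) *
        sample(1:4, n_genes, replace = TRUE),
      plastid_votes = as.integer(vote_plastid) *
        sample(1:4, n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    truth <- cbind(data.frame(gene_id = gene_id, tier = tier, dual = dual,
                              stringsAsFactors = FALSE), flags)
    list(orthogroups = orthogroups, reference = reference, votes = votes,
         truth = truth)
  })
}
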