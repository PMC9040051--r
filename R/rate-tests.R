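# Concatenated and gene-level comparisons of paternal vs maternal
# subgenome evolutionary rates: gene-block and codon bootstraps of the
# omega_PAT/omega_MAT ratio, background (NOT) normalization, two-tailed
# bootstrap p-values, sign tests, divergence binning, and
# polyploid-vs-diploid branch contrasts.

#' Concatenate quintet alignments by functional category
#'
#' Appends the per-gene codon alignments of each category in stable
#' (sorted) gene_id order and records per-gene block boundaries for the
#' gene-level block bootstrap.
#'
#' @param quintets A `quintet_table` (or data frame with `gene_id`).
#' @param alignments Named list of `codon_alignment`s (names = gene_id),
#'   each with the five role-named sequences.
#' @param classification Data frame with `gene_id` and `tier` columns (as
#'   from [propagate_to_quintets()]), or a named character vector of tiers.
#' @return Named list of `codon_alignment`s, one per category, each with
#'   attributes `gene_ids` and `boundaries` (cumulative codon counts).
#' @export
concatenate_by_category <- function(quintets, alignments, classification) {
  if (is.character(classification))
    classification <- data.frame(gene_id = names(classification),
                                 tier = unname(classification),
                                 stringsAsFactors = FALSE)
  genes <- sort(intersect(quintets$gene_id, names(alignments)))
  tiers <- classification$tier[match(genes, classification$gene_id)]
  out <- list()
  for (tier in unique(tiers[!is.na(tiers)])) {
    gs <- genes[!is.na(tiers) & tiers == tier]
    out[[tier]] <- .concat_genes(alignments[gs])
  }
  out
}

.concat_genes <- function(alns) {
  roles <- quintet_roles()
  for (g in names(alns)) {
    if (!setequal(alns[[g]]$ids, roles))
      stop("gene ", g, " lacks one of the five quintet roles")
  }
  seqs <- vapply(roles, function(r) {
    paste(vapply(alns, function(a) unname(a$seqs[r]), character(1)),
          collapse = "")
  }, character(1))
  conc <- codon_alignment(seqs, validate = FALSE)
  attr(conc, "gene_ids") <- names(alns)
  attr(conc, "boundaries") <- cumsum(vapply(alns, function(a)
    a$length %/% 3L, integer(1)))
  conc
}

# ---- shared bootstrap machinery --------------------------------------------

# Pattern bookkeeping for a concatenation: global pattern table plus a
# (pattern x gene) count matrix so a gene-block resample is a reweighting.
.concat_engine_data <- function(concat, spec) {
  states <- .alignment_states(concat)
  cp <- .compress_patterns(states)
  bounds <- attr(concat, "boundaries")
  if (is.null(bounds)) bounds <- ncol(states)
  gene_of_site <- rep(seq_along(bounds),
                      times = diff(c(0L, bounds)))
  counts <- matrix(0, nrow = ncol(cp$patterns), ncol = length(bounds))
  tt <- table(cp$site_pattern, gene_of_site)
  counts[cbind(as.integer(rownames(tt))[row(tt)],
               as.integer(colnames(tt))[col(tt)])] <- as.numeric(tt)
  list(patterns = cp$patterns, weights = cp$weights, counts = counts,
       n_genes = length(bounds), n_codons = ncol(states), spec = spec)
}

# median per-branch parameter vector over optimizer replicate fits
# (lower median for even counts, for determinism)
.lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

.replicate_fit <- function(ed, eng, weights, optimizer_replicates, init,
                           seed, control, hessian = NULL) {
  eng_set_weights(eng, weights)
  one_fit <- function(start) {
    if (is.null(hessian)) {
      fit_branch_patterns(ed$patterns, weights, ed$spec, init = start,
                          control = control, engine = eng)
    } else {
      nr <- .newton_refit(eng, start, hessian, fallback_control = control)
      .branch_rates_from_par(nr$par, ed$spec, lnL = -nr$value,
                             npatterns = ncol(ed$patterns))
    }
  }
  fits <- vector("list", optimizer_replicates)
  fits[[1]] <- one_fit(init)
  if (optimizer_replicates > 1) {
    jit <- .with_seed(seed, lapply(seq_len(optimizer_replicates - 1),
                                   function(i)
                                     stats::rnorm(15, 0, 0.2)))
    for (k in seq_len(optimizer_replicates - 1)) {
      st <- pmin(pmax(init + jit[[k]], .LOG_BOUNDS$lower),
                 .LOG_BOUNDS$upper)
      fits[[k + 1]] <- one_fit(st)
    }
  }
  # per-branch lower-medians of omega and dN/dS across replicate runs
  om <- vapply(fits, function(f) f$branches$omega, numeric(7))
  dn <- vapply(fits, function(f) f$branches$dN, numeric(7))
  ds <- vapply(fits, function(f) f$branches$dS, numeric(7))
  if (optimizer_replicates == 1) {
    om <- matrix(om, nrow = 7); dn <- matrix(dn, nrow = 7)
    ds <- matrix(ds, nrow = 7)
  }
  list(omega = apply(om, 1, .lower_median),
       dN = apply(dn, 1, .lower_median),
       dS = apply(ds, 1, .lower_median),
       lnL = fits[[1]]$lnL, logpar = fits[[1]]$logpar)
}

.omega_ratio_result <- function(point, boot_omega, excluded, B, category,
                                reference = 1) {
  ipat <- match("polyploid_paternal", .branch_labels)
  imat <- match("polyploid_maternal", .branch_labels)
  omega_pat <- point$omega[ipat]
  omega_mat <- point$omega[imat]
  ratio <- omega_pat / omega_mat
  dist <- boot_omega[, ipat] / boot_omega[, imat]
  dist <- dist[is.finite(dist)]
  ci <- unname(stats::quantile(dist, c(0.025, 0.975), na.rm = TRUE,
                               type = 7))
  structure(list(category = category, omega_pat = omega_pat,
                 omega_mat = omega_mat, ratio = ratio,
                 normalized_ratio = NA_real_,
                 bootstrap_distribution = dist,
                 boot_omega = boot_omega,
                 ci95 = ci,
                 p_two_tailed = two_tailed_p(dist, reference),
                 B = B, excluded_replicates = excluded,
                 point = point),
            class = "omega_ratio_result")
}

#' @export
print.omega_ratio_result <- function(x, ...) {
  cat(sprintf(
    "omega ratio [%s]: omega_pat = %.4g, omega_mat = %.4g, ratio = %.4g\n",
    x$category %||% "?", x$omega_pat, x$omega_mat, x$ratio))
  if (!is.na(x$normalized_ratio))
    cat(sprintf("normalized ratio = %.4g\n", x$normalized_ratio))
  cat(sprintf("bootstrap B = %d (excluded %d), 95%% CI [%.4g, %.4g], two-tailed p = %.4g\n",
              x$B, x$excluded_replicates, x$ci95[1], x$ci95[2],
              x$p_two_tailed))
  invisible(x)
}

#' Gene-block bootstrap of the paternal/maternal omega ratio
#'
#' Fits the free-ratio model to a category concatenation, then resamples
#' whole gene blocks with replacement B times; each bootstrap replicate is
#' refitted (`optimizer_replicates` optimizer runs, per-branch lower
#' medians taken) and contributes one omega_PAT/omega_MAT ratio to the
#' bootstrap distribution.  Replicates with an undefined ratio (synonymous
#' branch length numerically zero) are flagged and excluded, with the
#' count reported.
#'
#' @param concat A concatenated `codon_alignment` from
#'   [concatenate_by_category()] (>= 2 gene blocks).
#' @param B Bootstrap replicates.
#' @param optimizer_replicates Optimizer runs per fit (medians are used).
#' @param seed Integer seed; the whole bootstrap is reproducible from it.
#' @param spec Optional [codon_model_spec()] (default: F3x4 from the
#'   concatenation).
#' @param category Label carried into the result.
#' @param control Optimizer control for the replicate refits.
#' @return An `omega_ratio_result`.
#' @export
gene_bootstrap_omega_ratio <- function(concat, B = 1000L,
                                       optimizer_replicates = 5L,
                                       seed = 1L, spec = NULL,
                                       category = NULL,
                                       control = list()) {
  gene_ids <- attr(concat, "gene_ids")
  if (is.null(gene_ids) || length(gene_ids) < 2L)
    stop("gene bootstrap needs a concatenation with >= 2 gene blocks")
  if (is.null(spec))
    spec <- codon_model_spec(pi3x4 = attr(compute_f3x4(concat), "pi3x4"))
  ed <- .concat_engine_data(concat, spec)
  eng <- .new_engine(ed$patterns, ed$weights, spec)
  control <- utils::modifyList(list(maxit = 200, factr = 1e8, h = 1e-5),
                               control)
  point <- .replicate_fit(ed, eng, ed$weights, optimizer_replicates,
                          init = .default_start(spec),
                          seed = seed, control = control)
  boot_control <- utils::modifyList(control, list(maxit = 60))
  eng_set_weights(eng, ed$weights)
  eng_loglik(eng, point$logpar)
  hess <- .engine_hessian(eng, point$logpar)
  draws <- .with_seed(seed + 1L, {
    lapply(seq_len(B), function(b)
      tabulate(sample.int(ed$n_genes, ed$n_genes, replace = TRUE),
               nbins = ed$n_genes))
  })
  boot_omega <- matrix(NA_real_, B, 7,
                       dimnames = list(NULL, .branch_labels))
  for (b in seq_len(B)) {
    wb <- as.numeric(ed$counts %*% draws[[b]])
    rb <- .replicate_fit(ed, eng, wb, optimizer_replicates,
                         init = point$logpar, seed = seed + 1L + b,
                         control = boot_control, hessian = hess)
    boot_omega[b, ] <- rb$omega
  }
  ipat <- match("polyploid_paternal", .branch_labels)
  imat <- match("polyploid_maternal", .branch_labels)
  bad <- !is.finite(boot_omega[, ipat] / boot_omega[, imat])
  .omega_ratio_result(point, boot_omega, excluded = sum(bad), B = B,
                      category = category)
}

#' Codon-level bootstrap of the paternal/maternal omega ratio
#'
#' As [gene_bootstrap_omega_ratio()] but resampling codon columns with
#' replacement -- the appropriate resampling unit for small categories
#' where a single gene would make the gene-block bootstrap degenerate.
#'
#' @inheritParams gene_bootstrap_omega_ratio
#' @return An `omega_ratio_result`.
#' @export
codon_bootstrap <- function(concat, B = 1000L, optimizer_replicates = 5L,
                            seed = 1L, spec = NULL, category = NULL,
                            control = list()) {
  n_codons <- concat$length %/% 3L
  if (n_codons < 30L) stop("codon bootstrap needs >= 30 codons")
  if (is.null(spec))
    spec <- codon_model_spec(pi3x4 = attr(compute_f3x4(concat), "pi3x4"))
  ed <- .concat_engine_data(concat, spec)
  eng <- .new_engine(ed$patterns, ed$weights, spec)
  control <- utils::modifyList(list(maxit = 200, factr = 1e8, h = 1e-5),
                               control)
  point <- .replicate_fit(ed, eng, ed$weights, optimizer_replicates,
                          init = .default_start(spec),
                          seed = seed, control = control)
  boot_control <- utils::modifyList(control, list(maxit = 60))
  eng_set_weights(eng, ed$weights)
  eng_loglik(eng, point$logpar)
  hess <- .engine_hessian(eng, point$logpar)
  # resampling codon columns == multinomial reweighting of site patterns
  prob <- ed$weights / sum(ed$weights)
  draws <- .with_seed(seed + 1L, {
    lapply(seq_len(B), function(b)
      as.numeric(stats::rmultinom(1L, ed$n_codons, prob)))
  })
  boot_omega <- matrix(NA_real_, B, 7,
                       dimnames = list(NULL, .branch_labels))
  for (b in seq_len(B)) {
    rb <- .replicate_fit(ed, eng, draws[[b]], optimizer_replicates,
                         init = point$logpar, seed = seed + 1L + b,
                         control = boot_control, hessian = hess)
    boot_omega[b, ] <- rb$omega
  }
  ipat <- match("polyploid_paternal", .branch_labels)
  imat <- match("polyploid_maternal", .branch_labels)
  bad <- !is.finite(boot_omega[, ipat] / boot_omega[, imat])
  .omega_ratio_result(point, boot_omega, excluded = sum(bad), B = B,
                      category = category)
}

#' Normalize a category omega ratio by the background (NOT) ratio
#'
#' Divides a category's point ratio and each of its bootstrap replicate
#' ratios by the point omega_PAT/omega_MAT ratio of the genes not targeted
#' to either organelle, re-deriving the percentile CI and the two-tailed
#' bootstrap p-value against 1.
#'
#' @param category_result,not_result `omega_ratio_result`s computed on the
#'   same dataset.
#' @return An `omega_ratio_result` with `normalized_ratio` and a
#'   normalized bootstrap distribution.
#' @export
normalize_ratio <- function(category_result, not_result) {
  ref <- not_result$ratio
  if (!is.finite(ref) || ref <= 0)
    stop("background (NOT) omega ratio is undefined")
  out <- category_result
  out$normalized_ratio <- category_result$ratio / ref
  out$bootstrap_distribution <- category_result$bootstrap_distribution / ref
  out$ci95 <- unname(stats::quantile(out$bootstrap_distribution,
                                     c(0.025, 0.975), na.rm = TRUE))
  out$p_two_tailed <- two_tailed_p(out$bootstrap_distribution, 1)
  out
}

#' Two-tailed bootstrap p-value
#'
#' `p = 2 * min(Pr(dist <= reference), Pr(dist >= reference))`, capped at
#' 1.  With B replicates the resolution is 2/B: a reference outside the
#' whole distribution yields p = 0, to be reported as "< 2/B".
#'
#' @param dist Numeric bootstrap distribution (>= 20 replicates).
#' @param reference Reference value.
#' @return The p-value.
#' @export
two_tailed_p <- function(dist, reference) {
  dist <- dist[is.finite(dist)]
  if (length(dist) == 0L) stop("empty bootstrap distribution")
  if (length(dist) < 20L)
    warning("fewer than 20 bootstrap replicates; p-value is unreliable")
  p <- 2 * min(mean(dist <= reference), mean(dist >= reference))
  min(p, 1)
}

#' Gene-level sign test of subgenome rate differences
#'
#' For each quintet, asks whether the paternal or the maternal polyploid
#' terminal branch has the higher omega (or dN).  Ties and genes with
#' undefined values are excluded; the two-sided exact binomial test with
#' null 0.5 is applied to the non-tied counts.
#'
#' @param rates_list List of `branch_rates` fits (one per gene).
#' @param comparison `"omega"` or `"dN"`.
#' @return Object of class `sign_test_result`: counts, proportions
#'   `p_pat`/`p_mat`, and the exact binomial p-value (`NA` with an
#'   `undefined` marker when no gene is informative).
#' @export
gene_level_sign_test <- function(rates_list, comparison = c("omega", "dN")) {
  comparison <- match.arg(comparison)
  ipat <- match("polyploid_paternal", .branch_labels)
  imat <- match("polyploid_maternal", .branch_labels)
  vals <- vapply(rates_list, function(r) {
    v <- r$branches[[if (comparison == "omega") "omega" else "dN"]]
    c(v[ipat], v[imat])
  }, numeric(2))
  ok <- is.finite(vals[1, ]) & is.finite(vals[2, ])
  pat_higher <- sum(vals[1, ok] > vals[2, ok])
  mat_higher <- sum(vals[2, ok] > vals[1, ok])
  ties <- sum(ok) - pat_higher - mat_higher
  n_all <- length(rates_list)
  n <- pat_higher + mat_higher
  structure(list(
    n_pat_higher = pat_higher, n_mat_higher = mat_higher,
    n_ties = ties + sum(!ok),
    p_pat = if (n_all > 0) pat_higher / n_all else NA_real_,
    p_mat = if (n_all > 0) mat_higher / n_all else NA_real_,
    p_binomial = if (n == 0L) NA_real_ else
      stats::binom.test(pat_higher, n, 0.5)$p.value,
    undefined = n == 0L), class = "sign_test_result")
}

#' Split genes into high and low divergence bins
#'
#' Bins genes by the amino acid divergence between the two diploid models
#' (per-gene diploid-diploid dN): genes at or below the (lower) median go
#' to the low bin, genes above it to the high bin; with an odd count the
#' median gene is in the low bin.  If all values are equal the high bin is
#' empty (with a warning).
#'
#' @param dn Named numeric vector of per-gene diploid-diploid dN.
#' @return Named character vector (`"low"`/`"high"`).
#' @export
divergence_binning <- function(dn) {
  if (length(dn) < 2L) stop("need >= 2 genes to bin")
  med <- .lower_median(dn)
  bin <- ifelse(dn <= med, "low", "high")
  if (all(bin == "low"))
    warning("all divergence values equal; high bin is empty")
  stats::setNames(bin, names(dn))
}

#' Polyploid versus diploid branch omega ratios
#'
#' From the per-replicate branch omegas of a bootstrap result, forms for
#' each subgenome the ratio of the polyploid terminal branch omega to its
#' sister diploid branch omega, with a percentile 95% CI; the contrast is
#' significant when the CI excludes 1.
#'
#' @param result An `omega_ratio_result` (its `boot_omega` matrix is used).
#' @return Data frame with one row per subgenome: point ratio, CI bounds,
#'   `significant`, and `undefined` flag (diploid omega numerically zero).
#' @export
polyploid_vs_diploid_ratio <- function(result) {
  bo <- result$boot_omega
  pairs <- list(paternal = c("polyploid_paternal", "diploid_paternal"),
                maternal = c("polyploid_maternal", "diploid_maternal"))
  out <- lapply(names(pairs), function(sg) {
    ip <- match(pairs[[sg]][1], .branch_labels)
    id <- match(pairs[[sg]][2], .branch_labels)
    pt <- result$point$omega[ip] / result$point$omega[id]
    undef <- !is.finite(pt)
    dist <- bo[, ip] / bo[, id]
    dist <- dist[is.finite(dist)]
    ci <- if (length(dist) >= 20L)
      unname(stats::quantile(dist, c(0.025, 0.975))) else c(NA_real_, NA_real_)
    data.frame(subgenome = sg, ratio = pt, ci_lower = ci[1],
               ci_upper = ci[2],
               significant = is.finite(ci[1]) && (ci[1] > 1 || ci[2] < 1),
               undefined = undef, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
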