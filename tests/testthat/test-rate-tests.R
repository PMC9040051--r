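test_that("concatenation appends blocks in stable order with boundaries", {
  a1 <- simulate_quintet_genes(quintet_sim_params(n_codons = 300, seed = 1),
                               1, prefix = "ga")[[1]]
  a2 <- simulate_quintet_genes(quintet_sim_params(n_codons = 150, seed = 2),
                               1, prefix = "gb")[[1]]
  alns <- list(gb = a2, ga = a1)    # deliberately unsorted
  q <- toy_quintet_table(c("ga", "gb"))
  tiers <- c(ga = "x", gb = "x")
  conc <- concatenate_by_category(q, alns, tiers)$x
  expect_equal(conc$length, (300 + 150) * 3)
  expect_equal(unname(attr(conc, "boundaries")), c(300, 450))
  expect_equal(attr(conc, "gene_ids"), c("ga", "gb"))   # sorted
  # permuting the input order changes nothing
  conc2 <- concatenate_by_category(q, alns[c(2, 1)], tiers)$x
  expect_identical(conc$seqs, conc2$seqs)
  # single gene: concatenation equals that gene
  conc1 <- concatenate_by_category(toy_quintet_table("ga"),
                                   alns["ga"], c(ga = "x"))$x
  expect_identical(unname(conc1$seqs), unname(a1$seqs[quintet_roles()]))
  # a missing role is an error naming the gene
  bad <- a1; bad$ids[1] <- "someone_else"
  names(bad$seqs)[1] <- "someone_else"
  expect_error(
    concatenate_by_category(q, list(ga = bad, gb = a2), tiers), "ga")
})

test_that("two-tailed bootstrap p-values follow the percentile rule", {
  expect_equal(two_tailed_p(1:101, 51), 1)         # reference at the median
  expect_equal(two_tailed_p(1:200 / 100, 5), 0)    # above all replicates
  expect_equal(two_tailed_p(1:200 / 100, 0.001), 0)  # below all: < 2/B
  # symmetric distribution with the reference at its 2.5th percentile
  d <- seq(-1, 1, length.out = 999)
  ref <- stats::quantile(d, 0.025)
  expect_equal(two_tailed_p(d, ref), 0.05, tolerance = 0.01)
  expect_error(two_tailed_p(numeric(0), 1), "empty")
  expect_warning(two_tailed_p(1:10, 5), "20")
})

test_that("sign tests count subgenome winners with exact binomial p", {
  mk_rates <- function(om_pat, om_mat) {
    br <- data.frame(branch = c("polyploid_paternal", "diploid_paternal",
                                "polyploid_maternal", "diploid_maternal",
                                "outgroup", "paternal_ancestral",
                                "maternal_ancestral"),
                     t = 0.1, dN = 0.01, dS = 0.05,
                     omega = c(om_pat, 0.2, om_mat, 0.2, 0.2, 0.2, 0.2),
                     flag = "ok", stringsAsFactors = FALSE)
    br$dN[1] <- om_pat; br$dN[3] <- om_mat
    list(branches = br)
  }
  # (5, 5): p = 1
  r55 <- gene_level_sign_test(c(replicate(5, mk_rates(2, 1), simplify = FALSE),
                                replicate(5, mk_rates(1, 2), simplify = FALSE)))
  expect_equal(r55$n_pat_higher, 5)
  expect_equal(r55$p_binomial, 1)
  # (60, 40): exact two-sided binomial at n = 100, enumerated directly
  r64 <- gene_level_sign_test(c(replicate(60, mk_rates(2, 1), simplify = FALSE),
                                replicate(40, mk_rates(1, 2), simplify = FALSE)))
  expect_equal(r64$p_binomial, binom_p_enum(60, 100), tolerance = 1e-12)
  # all ties: undefined marker
  rt <- gene_level_sign_test(replicate(4, mk_rates(1, 1), simplify = FALSE))
  expect_true(rt$undefined)
  expect_true(is.na(rt$p_binomial))
  expect_equal(rt$n_ties, 4)
  # dN comparison uses the dN column
  rdn <- gene_level_sign_test(replicate(3, mk_rates(2, 1), simplify = FALSE),
                              comparison = "dN")
  expect_equal(rdn$n_pat_higher, 3)
  # invariant: proportions sum to at most 1
  expect_lte(r55$p_pat + r55$p_mat, 1)
})

test_that("divergence binning splits at the lower median", {
  d10 <- stats::setNames(seq(0.01, 0.10, by = 0.01), paste0("g", 1:10))
  b10 <- divergence_binning(d10)
  expect_equal(sum(b10 == "low"), 5)
  expect_equal(sum(b10 == "high"), 5)
  d11 <- stats::setNames(seq(0.01, 0.11, by = 0.01), paste0("g", 1:11))
  b11 <- divergence_binning(d11)
  expect_equal(sum(b11 == "low"), 6)   # median gene goes low
  expect_equal(sum(b11 == "high"), 5)
  expect_warning(beq <- divergence_binning(c(a = 1, b = 1, c = 1)), "equal")
  expect_true(all(beq == "low"))
})

test_that("normalization divides by the background point ratio", {
  mk_res <- function(ratio, dist) {
    structure(list(ratio = ratio, bootstrap_distribution = dist,
                   normalized_ratio = NA_real_),
              class = "omega_ratio_result")
  }
  r <- normalize_ratio(mk_res(1.2, rep(c(0.9, 1.2, 1.5), 10)),
                       mk_res(1.2, NULL))
  expect_equal(r$normalized_ratio, 1)
  r2 <- normalize_ratio(mk_res(0.6, rep(c(0.5, 0.6, 0.7) * 2, 10)),
                        mk_res(1.2, NULL))
  expect_equal(r2$normalized_ratio, 0.5)
  expect_equal(r2$bootstrap_distribution, rep(c(0.5, 0.6, 0.7) * 2, 10) / 1.2)
  # normalize_ratio(x, x) has unit normalized ratio for any valid x
  x <- mk_res(0.83, seq(0.5, 1.2, length.out = 40))
  expect_equal(normalize_ratio(x, x)$normalized_ratio, 1)
  expect_error(normalize_ratio(x, mk_res(NA_real_, NULL)), "undefined")
})

test_that("gene bootstrap is reproducible and degenerate on identical blocks", {
  gene <- simulate_quintet_genes(
    quintet_sim_params(n_codons = 120, seed = 51), 1)[[1]]
  alns <- stats::setNames(rep(list(gene), 4), paste0("g", 1:4))
  q <- toy_quintet_table(names(alns))
  conc <- concatenate_by_category(
    q, alns, stats::setNames(rep("x", 4), names(alns)))$x
  res <- gene_bootstrap_omega_ratio(conc, B = 30, optimizer_replicates = 1,
                                    seed = 3)
  # identical gene blocks: every resample is the same alignment
  expect_lt(diff(range(res$bootstrap_distribution)), 0.02)
  expect_equal(stats::median(res$bootstrap_distribution), res$ratio,
               tolerance = 0.02)
  # bit-for-bit reproducibility from the seed
  res2 <- gene_bootstrap_omega_ratio(conc, B = 30, optimizer_replicates = 1,
                                     seed = 3)
  expect_identical(res$bootstrap_distribution, res2$bootstrap_distribution)
  expect_error(gene_bootstrap_omega_ratio(gene, B = 10), "2 gene blocks")
})

test_that("codon bootstrap handles one-gene categories reproducibly", {
  gene <- simulate_quintet_genes(
    quintet_sim_params(n_codons = 200, seed = 52), 1)[[1]]
  alns <- list(g1 = gene)
  conc <- concatenate_by_category(toy_quintet_table("g1"), alns,
                                  c(g1 = "x"))$x
  res <- codon_bootstrap(conc, B = 25, optimizer_replicates = 1, seed = 9)
  expect_equal(res$B, 25)
  expect_gt(length(res$bootstrap_distribution), 0)
  res2 <- codon_bootstrap(conc, B = 25, optimizer_replicates = 1, seed = 9)
  expect_identical(res$bootstrap_distribution, res2$bootstrap_distribution)
  expect_error(codon_bootstrap(
    codon_alignment(stats::setNames(rep("ATGGCT", 5), quintet_roles())),
    B = 5), "30 codons")
})

test_that("polyploid vs diploid contrasts flag only real differences", {
  # equal omegas: CI covers 1; inflated polyploid branch omega: CI excludes 1
  conc_eq <- simulated_category_dataset(61, n_cat = 12, n_not = 1,
                                        n_codons = 400)$organelle
  r_eq <- gene_bootstrap_omega_ratio(conc_eq, B = 60,
                                     optimizer_replicates = 1, seed = 5)
  pv_eq <- polyploid_vs_diploid_ratio(r_eq)
  expect_equal(nrow(pv_eq), 2)
  expect_false(any(pv_eq$undefined))
  conc_bias <- biased_category_dataset(62, n_cat = 25, n_not = 1,
                                       n_codons = 600,
                                       omega_pat = 0.8, omega_mat = 0.2)
  r_bias <- gene_bootstrap_omega_ratio(conc_bias$organelle, B = 60,
                                       optimizer_replicates = 1, seed = 6)
  pv_bias <- polyploid_vs_diploid_ratio(r_bias)
  pat <- pv_bias[pv_bias$subgenome == "paternal", ]
  expect_gt(pat$ratio, 1)
  expect_true(pat$significant)
})
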