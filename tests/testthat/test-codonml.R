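test_that("F3x4 frequencies match hand-computed position products", {
  # 2 sequences x 3 codons: position-specific nucleotide counts by hand
  aln <- codon_alignment(c(a = "ATGGCTAAA", b = "ATGGCAAAG"),
                         validate = FALSE)
  f <- compute_f3x4(aln)
  p3 <- attr(f, "pi3x4")
  # position 1 nucleotides: A,G,A | A,G,A -> A 4/6, G 2/6
  expect_equal(unname(p3[1, ]), c(4, 0, 2, 0) / 6)
  # position 2: T,C,A | T,C,A -> A 2/6, C 2/6, T 2/6
  expect_equal(unname(p3[2, ]), c(2, 2, 0, 2) / 6)
  # position 3: G,T,A | G,A,G -> A 2/6, G 3/6, T 1/6
  expect_equal(unname(p3[3, ]), c(2, 0, 3, 1) / 6)
  # codon frequency = product of positions, renormalized over sense codons
  tab <- sense_codons()
  raw <- p3[cbind(1, match(substr(tab$codon, 1, 1), c("A","C","G","T")))] *
    p3[cbind(2, match(substr(tab$codon, 2, 2), c("A","C","G","T")))] *
    p3[cbind(3, match(substr(tab$codon, 3, 3), c("A","C","G","T")))]
  expect_equal(as.numeric(f), raw / sum(raw), tolerance = 1e-12)
})

test_that("degenerate compositions produce degenerate frequency vectors", {
  aln <- codon_alignment(c(a = "AAAAAA", b = "AAAAAA"), validate = FALSE)
  f <- compute_f3x4(aln)
  expect_equal(unname(f[names(f) == "AAA"]), 1)
  # uniform nucleotide composition -> near-uniform sense codon frequencies
  spec <- codon_model_spec()   # uniform positional frequencies
  expect_equal(max(spec$codon_freqs), min(spec$codon_freqs))
  expect_equal(sum(spec$codon_freqs), 1, tolerance = 1e-12)
})

test_that("engine likelihood matches brute-force summation over ancestors", {
  p <- quintet_sim_params(n_codons = 12, seed = 31)
  sim <- simulate_quintet_alignment(p)
  tab <- cytonuclear:::.codon_tables()
  bf <- cytonuclear:::.bf_matrix(p$pi3x4)
  pi61 <- as.numeric(p$codon_freqs)
  P <- lapply(1:7, function(b) codon_pmatrix_cpp(
    p$kappa, p$omega_by_branch[b], p$branch_lengths[b], pi61, bf, tab$cls))
  states <- cytonuclear:::.alignment_states(sim$alignment)
  cp <- cytonuclear:::.compress_patterns(states)
  eng <- cytonuclear:::.new_engine(cp$patterns, cp$weights,
                                   codon_model_spec(pi3x4 = p$pi3x4))
  lpar <- c(log(p$branch_lengths), log(p$omega_by_branch), log(p$kappa))
  sl <- cytonuclear:::eng_site_loglik(eng, lpar)
  # independent oracle: direct summation over the three ancestral states
  brute_site <- function(x) {
    tot <- 0
    for (r in 1:61) {
      pr <- pi61[r] * (if (x[5] < 62) P[[5]][r, x[5]] else 1)
      va <- P[[6]][r, ] ; vb <- P[[7]][r, ]
      sa <- sum(va * (if (x[1] < 62) P[[1]][, x[1]] else 1) *
                  (if (x[2] < 62) P[[2]][, x[2]] else 1))
      sb <- sum(vb * (if (x[3] < 62) P[[3]][, x[3]] else 1) *
                  (if (x[4] < 62) P[[4]][, x[4]] else 1))
      tot <- tot + pr * sa * sb
    }
    log(tot)
  }
  oracle <- vapply(seq_len(ncol(cp$patterns)), function(j)
    brute_site(cp$patterns[, j] + 1L), numeric(1))
  expect_equal(sl, oracle, tolerance = 1e-10)
})

test_that("analytic gradient agrees with finite differences", {
  p <- quintet_sim_params(n_codons = 150, seed = 8)
  sim <- simulate_quintet_alignment(p)
  cp <- cytonuclear:::.compress_patterns(
    cytonuclear:::.alignment_states(sim$alignment))
  spec <- codon_model_spec(pi3x4 = p$pi3x4)
  eng <- cytonuclear:::.new_engine(cp$patterns, cp$weights, spec)
  set.seed(2)
  lpar <- c(log(p$branch_lengths), log(p$omega_by_branch), log(p$kappa)) +
    rnorm(15, 0, 0.3)
  ga <- cytonuclear:::eng_grad(eng, lpar)
  gn <- cytonuclear:::eng_grad_fd(eng, lpar, 1e-6)
  expect_equal(ga, gn, tolerance = 1e-3)
})

test_that("likelihood is invariant to tip input order", {
  p <- quintet_sim_params(n_codons = 200, seed = 5)
  sim <- simulate_quintet_alignment(p)
  fit1 <- fit_branch_model(sim$alignment, control = list(maxit = 150))
  perm <- sample(5)
  aln2 <- codon_alignment(sim$alignment$seqs[perm], validate = FALSE)
  fit2 <- fit_branch_model(aln2, control = list(maxit = 150))
  expect_lt(abs(fit1$lnL - fit2$lnL), 1e-4)
})

test_that("adding a constant-site block shifts lnL by its site lnL", {
  p <- quintet_sim_params(n_codons = 100, seed = 13)
  sim <- simulate_quintet_alignment(p)
  aln <- sim$alignment
  k <- 25L
  aln2 <- codon_alignment(vapply(aln$seqs, function(s)
    paste0(s, strrep("ATG", k)), character(1)), validate = FALSE)
  spec <- codon_model_spec(pi3x4 = p$pi3x4)
  lpar <- c(log(p$branch_lengths), log(p$omega_by_branch), log(p$kappa))
  lnl_of <- function(a) {
    cp <- cytonuclear:::.compress_patterns(
      cytonuclear:::.alignment_states(a))
    eng <- cytonuclear:::.new_engine(cp$patterns, cp$weights, spec)
    list(total = cytonuclear:::eng_loglik(eng, lpar),
         site = cytonuclear:::eng_site_loglik(eng, lpar),
         cp = cp)
  }
  l1 <- lnl_of(aln)
  l2 <- lnl_of(aln2)
  # per-site lnL of the invariant ATG pattern under the same parameters
  atg_state <- cytonuclear:::.codon_states(rep("ATG", 5))
  cp_atg <- list(patterns = matrix(atg_state, ncol = 1), weights = 1)
  eng_atg <- cytonuclear:::.new_engine(cp_atg$patterns, cp_atg$weights, spec)
  atg_lnl <- cytonuclear:::eng_loglik(eng_atg, lpar)
  expect_equal(l2$total, l1$total + k * atg_lnl, tolerance = 1e-6)
})

test_that("identical sequences give zero branch lengths and root-only lnL", {
  seqs <- stats::setNames(rep("ATGGCTAAACCTGGA", 5), quintet_roles())
  aln <- codon_alignment(seqs)
  fit <- fit_branch_model(aln)
  expect_true(all(fit$branches$t == 0))
  expect_true(all(is.na(fit$branches$omega)))
  expect_true(all(fit$branches$flag == "undefined"))
  # lnL equals the log-probability of the root distribution
  f <- compute_f3x4(aln)
  spec <- codon_model_spec(pi3x4 = attr(f, "pi3x4"))
  codons <- substring(seqs[[1]], seq(1, 15, 3), seq(3, 15, 3))
  expect_equal(fit$lnL, sum(log(spec$codon_freqs[codons])),
               tolerance = 1e-9)
})

test_that("NG86 counting behaves on the contract examples", {
  s <- strrep("ATGGCTAAACCTGGATCA", 50)   # 300 codons
  r <- count_pairwise_dnds(s, s)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  # one nonsynonymous difference (GCT -> GTT, Ala -> Val)
  s2 <- sub("ATGGCTAAA", "ATGGTTAAA", s)
  r2 <- count_pairwise_dnds(s, s2)
  expect_gt(r2$dN, 0)
  expect_equal(r2$dS, 0)
  expect_equal(r2$Nd, 1)
  # saturation marker
  a <- strrep("GCA", 30); b <- strrep("CGT", 30)
  r3 <- count_pairwise_dnds(a, b)
  expect_true(any(r3$saturated) || (!is.na(r3$dN) && !is.na(r3$dS)))
})

test_that("ML and NG86 counting agree at low divergence", {
  # oracle cross-check: tree dN and dS vs pairwise counting on a cherry
  set.seed(11)
  devs <- replicate(8, {
    seed <- sample.int(1e6, 1)
    p <- quintet_sim_params(branch_lengths = rep(0.025, 7),
                            n_codons = 1500, seed = seed)
    sim <- simulate_quintet_alignment(p)
    fit <- fit_branch_model(sim$alignment, control = list(maxit = 150))
    ng <- count_pairwise_dnds(
      sim$alignment$seqs[["polyploid_paternal"]],
      sim$alignment$seqs[["diploid_paternal"]])
    i <- match(c("polyploid_paternal", "diploid_paternal"),
               fit$branches$branch)
    ml_dn <- sum(fit$branches$dN[i])
    ml_ds <- sum(fit$branches$dS[i])
    c(dn = abs(ml_dn - ng$dN) / max(ng$dN, 1e-4),
      ds = abs(ml_ds - ng$dS) / max(ng$dS, 1e-4))
  })
  expect_lt(median(devs["dn", ]), 0.25)
  expect_lt(median(devs["ds", ]), 0.25)
})

test_that("omega recovery holds across a grid of rates and divergences", {
  grid <- expand.grid(omega = c(0.1, 0.5, 1.0), t = c(0.05, 0.3))
  for (g in seq_len(nrow(grid))) {
    om_true <- grid$omega[g]
    p <- quintet_sim_params(branch_lengths = rep(grid$t[g], 7),
                            omega_by_branch = om_true, n_codons = 2000,
                            seed = 3000 + g)
    alns <- simulate_quintet_genes(p, 5)
    om_hat <- unlist(lapply(alns, function(a)
      fit_branch_model(a, control = list(maxit = 200))$branches$omega))
    expect_lt(abs(stats::median(om_hat, na.rm = TRUE) / om_true - 1), 0.25,
              label = sprintf("omega=%g t=%g", om_true, grid$t[g]))
  }
})

test_that("a neutral-free branch fits omega near zero", {
  p <- quintet_sim_params(omega_by_branch = c(0, .2, .2, .2, .2, .2, .2),
                          n_codons = 5000, seed = 19)
  sim <- simulate_quintet_alignment(p)
  fit <- fit_branch_model(sim$alignment)
  om_ppat <- fit$branches$omega[fit$branches$branch == "polyploid_paternal"]
  expect_lt(om_ppat, 0.02)
})

test_that("tree-wide dS grows monotonically with divergence time", {
  ds <- vapply(c(0.05, 0.1, 0.2, 0.4), function(tt) {
    sim <- simulate_quintet_alignment(
      quintet_sim_params(branch_lengths = rep(tt, 7), n_codons = 1000,
                         seed = 29))
    fit_branch_model(sim$alignment, control = list(maxit = 200))$tree_dS
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("ancestral reconstruction recovers invariant and majority states", {
  p <- quintet_sim_params(n_codons = 400, seed = 21)
  sim <- simulate_quintet_alignment(p)
  fit <- fit_branch_model(sim$alignment)
  anc <- reconstruct_ancestral(sim$alignment, fit)
  states <- cytonuclear:::.alignment_states(sim$alignment)
  codons <- sense_codons()$codon
  invariant <- which(apply(states, 2, function(x)
    length(unique(x)) == 1L & all(x < 61L)))
  expect_gt(length(invariant), 50)
  for (nd in colnames(anc$codon)) {
    expect_equal(anc$codon[invariant, nd], codons[states[1, invariant] + 1L])
    expect_true(all(anc$posterior[invariant, nd] >= 0.99))
  }
  # posteriors are probabilities
  expect_true(all(anc$posterior >= 0 & anc$posterior <= 1))
  # single-tip variant at short branches: ancestors carry the majority codon
  variant <- which(apply(states, 2, function(x) {
    ux <- table(x[x < 61L])
    length(ux) == 2L && min(ux) == 1L && max(ux) == 4L
  }))
  if (length(variant) > 0) {
    maj <- vapply(variant, function(j) {
      tb <- table(states[, j])
      as.integer(names(tb)[which.max(tb)])
    }, integer(1))
    agree <- mean(anc$codon[variant, "root"] == codons[maj + 1L])
    expect_gt(agree, 0.9)
  }
})

test_that("reconstruction matches the simulator's realized ancestors", {
  p <- quintet_sim_params(n_codons = 600, seed = 77)
  sim <- simulate_quintet_alignment(p)
  fit <- fit_branch_model(sim$alignment)
  anc <- reconstruct_ancestral(sim$alignment, fit)
  for (nd in c("paternal_ancestral", "maternal_ancestral", "root")) {
    truth <- substring(sim$internal_states[[nd]],
                       seq(1, 3 * 600, 3), seq(3, 3 * 600, 3))
    expect_gt(mean(anc$codon[, nd] == truth), 0.95)
  }
})
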