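#' @useDynLib cytonuclear, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Quintet role labels
#'
#' The five sequence roles of an orthologous quintet, in the fixed order used
#' by the likelihood engine and simulator.
#'
#' @return Character vector of the five role labels.
#' @export
quintet_roles <- function() {
  c("polyploid_paternal", "diploid_paternal",
    "polyploid_maternal", "diploid_maternal", "outgroup")
}

.branch_labels <- c("polyploid_paternal", "diploid_paternal",
                    "polyploid_maternal", "diploid_maternal", "outgroup",
                    "paternal_ancestral", "maternal_ancestral")

#' Codon substitution model specification
#'
#' Describes the MG94xHKY codon model used throughout: an HKY mutation
#' process at the nucleotide level (transition/transversion ratio `kappa`,
#' position-specific F3x4 equilibrium frequencies) with a per-branch
#' nonsynonymous/synonymous rate ratio `omega`.  `kappa` and `omega` here
#' are the optimizer's initial values; the free-ratio fit estimates one
#' omega per branch.
#'
#' Frequencies may be given either as a 3 x 4 matrix of position-specific
#' nucleotide frequencies (`pi3x4`, rows = codon positions, columns =
#' A, C, G, T) or as a 61-vector of sense-codon frequencies (`codon_freqs`),
#' which is projected onto the F3x4 family via its positional marginals.
#' The stationary distribution of the resulting chain is the renormalized
#' positional product over sense codons, stored in `$codon_freqs`.
#'
#' @param kappa Initial transition/transversion ratio (> 0).
#' @param omega Initial dN/dS ratio (> 0).
#' @param codon_freqs Optional numeric vector of 61 sense-codon frequencies.
#' @param pi3x4 Optional 3 x 4 matrix of positional nucleotide frequencies.
#' @return An object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(kappa = 2, omega = 0.4, codon_freqs = NULL,
                             pi3x4 = NULL) {
  stopifnot(kappa > 0, omega >= 0)
  if (is.null(pi3x4)) {
    if (is.null(codon_freqs)) {
      pi3x4 <- matrix(0.25, 3, 4, dimnames = list(NULL, .NUC))
    } else {
      stopifnot(length(codon_freqs) == 61)
      if (abs(sum(codon_freqs) - 1) > 1e-9)
        stop("codon_freqs must sum to 1 (within 1e-9)")
      if (any(codon_freqs < 0)) stop("codon_freqs must be non-negative")
      tab <- .codon_tables()
      pi3x4 <- t(vapply(1:3, function(p) {
        m <- vapply(.NUC, function(nu) {
          sum(codon_freqs[tab$splits[, p] == nu])
        }, numeric(1))
        m / sum(m)
      }, numeric(4)))
      colnames(pi3x4) <- .NUC
    }
  } else {
    pi3x4 <- as.matrix(pi3x4)
    stopifnot(nrow(pi3x4) == 3, ncol(pi3x4) == 4)
    pi3x4 <- pi3x4 / rowSums(pi3x4)
    colnames(pi3x4) <- .NUC
  }
  pi61 <- .f3x4_from_positions(pi3x4)
  bf <- .bf_matrix(pi3x4)
  structure(list(kappa = kappa, omega = omega, pi3x4 = pi3x4,
                 codon_freqs = stats::setNames(pi61, .codon_tables()$codons),
                 bf = bf, flows = .flow_rates(pi61, bf)),
            class = "codon_model_spec")
}

#' F3x4 codon frequencies from an alignment
#'
#' Computes position-specific nucleotide frequencies from the observed
#' in-frame codons (characters other than A/C/G/T are skipped per position)
#' and returns their product renormalized over the 61 sense codons -- the
#' standard F3x4 frequency model.
#'
#' @param alignment A `codon_alignment`.
#' @return Named numeric vector of 61 codon frequencies with attribute
#'   `pi3x4` (the 3 x 4 positional frequency matrix).
#' @export
compute_f3x4 <- function(alignment) {
  seqs <- alignment$seqs
  if (alignment$length < 3L) stop("alignment has no codons")
  chars <- strsplit(seqs, "")
  pos <- rep_len(1:3, alignment$length)
  counts <- matrix(0, 3, 4, dimnames = list(NULL, .NUC))
  for (s in chars) {
    for (p in 1:3) {
      tb <- table(factor(s[pos == p], levels = .NUC))
      counts[p, ] <- counts[p, ] + as.numeric(tb)
    }
  }
  if (any(rowSums(counts) == 0))
    stop("no ungapped nucleotides at some codon position")
  pi3x4 <- counts / rowSums(counts)
  out <- stats::setNames(.f3x4_from_positions(pi3x4), .codon_tables()$codons)
  attr(out, "pi3x4") <- pi3x4
  out
}

# ---- engine plumbing -------------------------------------------------------

# 5 x L codon-state matrix (engine tip order) from a codon_alignment.
# `roles` maps sequence id -> role; NULL means ids are the role names.
.alignment_states <- function(alignment, roles = NULL) {
  ids <- alignment$ids
  if (is.null(roles)) {
    if (!setequal(ids, quintet_roles()))
      stop("alignment ids are not the five quintet roles; supply `roles`")
    roles <- stats::setNames(ids, ids)
  }
  role_of <- roles[ids]
  if (anyNA(role_of) || !setequal(role_of, quintet_roles()))
    stop("`roles` must assign each of the five quintet roles exactly once")
  ord <- match(quintet_roles(), role_of)
  mat <- .split_codons(alignment$seqs[ord])
  matrix(.codon_states(mat), nrow = 5L)
}

# Compress site columns into unique patterns; returns patterns (5 x npat),
# weights, and site -> pattern index map.
.compress_patterns <- function(states) {
  key <- paste(states[1, ], states[2, ], states[3, ], states[4, ],
               states[5, ], sep = ",")
  f <- factor(key, levels = unique(key))
  idx <- as.integer(f)
  first <- which(!duplicated(idx))
  list(patterns = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(first))),
       site_pattern = idx)
}

.new_engine <- function(patterns, weights, spec) {
  tab <- .codon_tables()
  bf <- spec$bf %||% .bf_matrix(spec$pi3x4)
  pi61 <- as.numeric(spec$codon_freqs)
  pi61 <- pmax(pi61, 1e-10)
  pi61 <- pi61 / sum(pi61)
  eng_create(patterns, weights, pi61, bf, tab$cls)
}

.LOG_BOUNDS <- list(
  lower = c(rep(log(1e-8), 7), rep(log(1e-6), 7), log(0.05)),
  upper = c(rep(log(20), 7), rep(log(50), 7), log(100)))

# One L-BFGS-B run from a given start (log-parameter scale).
.optimize_engine <- function(eng, start, maxit = 300, factr = 1e8,
                             h = NULL) {
  res <- stats::optim(
    start,
    fn = function(p) -eng_loglik(eng, p),
    gr = function(p) -eng_grad(eng, p),
    method = "L-BFGS-B",
    lower = .LOG_BOUNDS$lower, upper = .LOG_BOUNDS$upper,
    control = list(maxit = maxit, factr = factr))
  if (!is.finite(res$value))
    stop("codon likelihood optimization produced a non-finite value ",
         "(lnL = ", -res$value, ", convergence = ", res$convergence, ")")
  res
}

# Negative-lnL Hessian at `par` by forward differences of the analytic
# gradient, eigenvalue-floored to be safely positive definite.  Used to
# precondition the warm Newton refits of the bootstrap machinery.
.engine_hessian <- function(eng, par, h = 1e-5) {
  g0 <- eng_grad(eng, par)
  H <- matrix(0, 15, 15)
  for (j in 1:15) {
    pj <- par
    pj[j] <- par[j] + h
    eng_loglik(eng, pj)
    H[, j] <- -(eng_grad(eng, pj) - g0) / h
  }
  eng_loglik(eng, par)           # restore committed state
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  floor_val <- max(ev$values) * 1e-6 + 1e-8
  vals <- pmax(ev$values, floor_val)
  ev$vectors %*% (t(ev$vectors) * vals)
}

# Warm Newton ascent with a fixed preconditioner; falls back to the
# quasi-Newton path when it fails to reach the gradient tolerance.
.newton_refit <- function(eng, init, H, max_steps = 12, gtol = 2e-2,
                          fallback_control = list()) {
  lower <- .LOG_BOUNDS$lower
  upper <- .LOG_BOUNDS$upper
  th <- init
  f <- eng_loglik(eng, th)
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    g <- eng_grad(eng, th)
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    step <- solve(H, g)
    improved <- FALSE
    for (k in 0:4) {
      cand <- pmin(pmax(th + step, lower), upper)
      fc <- eng_loglik(eng, cand)
      if (is.finite(fc) && fc >= f - 1e-9) {
        th <- cand; f <- fc; improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  if (!converged) {
    res <- .optimize_engine(eng, th,
                            maxit = fallback_control$maxit %||% 100,
                            factr = fallback_control$factr %||% 1e8)
    return(list(par = res$par, value = res$value))
  }
  eng_loglik(eng, th)
  list(par = th, value = -f)
}

.default_start <- function(spec) {
  c(log(c(0.1, 0.1, 0.1, 0.1, 0.2, 0.05, 0.05)),
    rep(log(spec$omega), 7), log(spec$kappa))
}

# run a block with a private, seeded RNG stream (leaves caller's RNG intact)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- free-ratio branch-model fit -------------------------------------------

#' Fit the free-ratio branch codon model to a quintet alignment
#'
#' Maximizes the MG94xHKY likelihood on the fixed quintet topology
#' `((polyploid_paternal, diploid_paternal), (polyploid_maternal,
#' diploid_maternal), outgroup)` over seven branch lengths, seven
#' branch-specific omega values, and kappa, by box-constrained quasi-Newton
#' search on log-transformed parameters (Felsenstein pruning over the
#' 61-codon state space).  Branch dN and dS are recovered from the fitted
#' generator by partitioning substitution flow into nonsynonymous and
#' synonymous components, so `omega = dN/dS` on every branch with
#' synonymous signal.
#'
#' @param alignment A `codon_alignment` containing the five quintet
#'   sequences.
#' @param tree Optional `phylo`; only its tip set is checked -- the fitted
#'   topology is the fixed species topology encoded by the roles.
#' @param spec A [codon_model_spec()]; default uses F3x4 frequencies
#'   computed from the alignment with the standard initial values
#'   kappa = 2, omega = 0.4.
#' @param n_starts Number of optimizer starts (first from the standard
#'   initial values, the rest jittered).
#' @param seed Integer seed for the start jitter (and tie-breaking).
#' @param roles Named character vector mapping sequence id -> role; `NULL`
#'   when ids are the role names themselves.
#' @param init Optional warm-start parameter vector (as returned in
#'   `$logpar` of a previous fit).
#' @param control List: `maxit`, `factr`, `h` passed to the optimizer.
#' @return An object of class `branch_rates`: per-branch table of
#'   `t` (expected substitutions/codon), `dN`, `dS`, `omega` and flags,
#'   tree-wide sums, `kappa`, and the maximized log-likelihood `lnL`.
#' @export
fit_branch_model <- function(alignment, tree = NULL, spec = NULL,
                             n_starts = 1, seed = NULL, roles = NULL,
                             init = NULL, control = list()) {
  states <- .alignment_states(alignment, roles)
  if (!is.null(tree)) {
    ids <- if (is.null(roles)) quintet_roles() else names(roles)
    if (!setequal(tree$tip.label, ids))
      stop("tree tips do not match alignment sequence ids")
  }
  if (ncol(states) == 0L) stop("alignment has no codons")
  if (is.null(spec)) {
    spec <- codon_model_spec(pi3x4 = attr(compute_f3x4(alignment), "pi3x4"))
  }
  cp <- .compress_patterns(states)
  fit_branch_patterns(cp$patterns, cp$weights, spec, n_starts = n_starts,
                      seed = seed, init = init, control = control)
}

# Pattern-level fitting entry point shared by the bootstrap machinery.
fit_branch_patterns <- function(patterns, weights, spec, n_starts = 1,
                                seed = NULL, init = NULL, control = list(),
                                engine = NULL) {
  maxit <- control$maxit %||% 300
  factr <- control$factr %||% 1e8
  h <- control$h %||% 1e-4
  eng <- engine %||% .new_engine(patterns, weights, spec)
  # degenerate case: no variable, co-observed pattern
  if (.all_constant(patterns)) {
    return(.constant_fit(patterns, weights, spec))
  }
  starts <- list(init %||% .default_start(spec))
  if (n_starts > 1) {
    jit <- .with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i)
        c(stats::runif(7, -0.5, 0.5), stats::runif(7, -0.7, 0.7),
          stats::runif(1, -0.3, 0.3)))
    })
    base <- starts[[1]]
    for (j in jit) starts <- c(starts, list(pmin(pmax(
      base + j, .LOG_BOUNDS$lower), .LOG_BOUNDS$upper)))
  }
  best <- NULL
  for (s in starts) {
    res <- .optimize_engine(eng, s, maxit = maxit, factr = factr, h = h)
    if (is.null(best) || res$value < best$value - 1e-6) best <- res
  }
  .branch_rates_from_par(best$par, spec, lnL = -best$value,
                         npatterns = ncol(patterns),
                         convergence = best$convergence)
}

.all_constant <- function(patterns) {
  all(apply(patterns, 2, function(col) {
    obs <- unique(col[col != 61L])
    length(obs) <= 1L
  }))
}

.constant_fit <- function(patterns, weights, spec) {
  pi61 <- as.numeric(spec$codon_freqs)
  lnL <- sum(vapply(seq_len(ncol(patterns)), function(j) {
    obs <- unique(patterns[, j][patterns[, j] != 61L])
    if (length(obs) == 0L) 0 else weights[j] * log(pi61[obs + 1L])
  }, numeric(1)))
  br <- data.frame(branch = .branch_labels, t = 0, dN = 0, dS = 0,
                   omega = NA_real_, flag = "undefined",
                   stringsAsFactors = FALSE)
  structure(list(branches = br, tree_dN = 0, tree_dS = 0, lnL = lnL,
                 kappa = spec$kappa, npatterns = ncol(patterns),
                 convergence = 0L,
                 logpar = c(rep(log(1e-8), 7), rep(log(spec$omega), 7),
                            log(spec$kappa)),
                 spec = spec),
            class = "branch_rates")
}

.branch_rates_from_par <- function(logpar, spec, lnL, npatterns,
                                   convergence = 0L) {
  t <- exp(logpar[1:7])
  om <- exp(logpar[8:14])
  kappa <- exp(logpar[15])
  flows <- spec$flows %||% .flow_rates(as.numeric(spec$codon_freqs),
                                       .bf_matrix(spec$pi3x4))
  dn <- ds <- numeric(7)
  for (b in 1:7) {
    dd <- .branch_dnds(t[b], om[b], kappa, flows)
    dn[b] <- dd$dN
    ds[b] <- dd$dS
  }
  flag <- rep("ok", 7)
  omega_out <- om
  undef <- ds < 1e-8
  omega_out[undef] <- NA_real_
  flag[undef] <- "undefined"
  flag[!undef & om >= 50 * (1 - 1e-6)] <- "at_cap"
  br <- data.frame(branch = .branch_labels, t = t, dN = dn, dS = ds,
                   omega = omega_out, flag = flag, stringsAsFactors = FALSE)
  structure(list(branches = br, tree_dN = sum(dn), tree_dS = sum(ds),
                 lnL = lnL, kappa = kappa, npatterns = npatterns,
                 convergence = convergence, logpar = logpar, spec = spec),
            class = "branch_rates")
}

#' @export
print.branch_rates <- function(x, ...) {
  cat("Free-ratio MG94xHKY fit (5-taxon quintet)\n")
  cat(sprintf("lnL = %.4f  kappa = %.3f  tree dN = %.4f  tree dS = %.4f\n",
              x$lnL, x$kappa, x$tree_dN, x$tree_dS))
  print(x$branches, digits = 4)
  invisible(x)
}

# convenience accessor used by the rate tests
.branch_omega <- function(rates, label) {
  rates$branches$omega[match(label, rates$branches$branch)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ancestral reconstruction ----------------------------------------------

#' Marginal ancestral codon reconstruction
#'
#' Computes, under a fitted free-ratio model, the marginal posterior
#' distribution of codon states at the three internal nodes of the quintet
#' (the paternal ancestral node, the maternal ancestral node, and the
#' outgroup attachment node) for every site, and reports the
#' maximum-posterior state (ties broken toward the lexicographically
#' smallest codon).
#'
#' @param alignment The `codon_alignment` that was fitted.
#' @param fit A `branch_rates` fit from [fit_branch_model()].
#' @param roles Optional id -> role map (as in [fit_branch_model()]).
#' @return An object of class `ancestral_states`: list with matrices
#'   `codon`, `aa`, `posterior` (sites x 3 nodes).
#' @export
reconstruct_ancestral <- function(alignment, fit, roles = NULL) {
  states <- .alignment_states(alignment, roles)
  cp <- .compress_patterns(states)
  eng <- .new_engine(cp$patterns, cp$weights, fit$spec)
  post <- eng_posterior(eng, fit$logpar)
  tab <- .codon_tables()
  nodes <- c("paternal_ancestral", "maternal_ancestral", "root")
  nsite <- length(cp$site_pattern)
  codon <- aa <- matrix(NA_character_, nsite, 3,
                        dimnames = list(NULL, nodes))
  pp <- matrix(NA_real_, nsite, 3, dimnames = list(NULL, nodes))
  for (k in 1:3) {
    pm <- post[[k]]
    best <- apply(pm, 2, which.max)   # first max = lexicographically least
    prob <- pm[cbind(best, seq_len(ncol(pm)))]
    codon[, k] <- tab$codons[best][cp$site_pattern]
    aa[, k] <- unname(tab$aa[best][cp$site_pattern])
    pp[, k] <- prob[cp$site_pattern]
  }
  structure(list(codon = codon, aa = aa, posterior = pp),
            class = "ancestral_states")
}

# ---- NG86-style counting (independent oracle for the ML engine) ------------

#' Pairwise dN and dS by NG86-style counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' equal-length in-frame sequences, averaging differences over all equal
#' shortest mutational pathways (pathways through stop codons are
#' excluded), and applies the Jukes-Cantor multiple-hit correction.
#' Codons containing gaps or ambiguity in either sequence are skipped.
#'
#' @param seqA,seqB Character strings (aligned, equal length, in frame).
#' @return List with `dN`, `dS`, the raw counts (`N`, `S`, `Nd`, `Sd`), and
#'   saturation flags (`dN`/`dS` are `NA` when the corrected distance is
#'   undefined, i.e. the proportion reaches 3/4).
#' @export
count_pairwise_dnds <- function(seqA, seqB) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences must be equal length")
  if (nchar(seqA) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  tab <- .codon_tables()
  ca <- .split_codons(c(seqA, seqB))
  ia <- .codon_states(ca[1, ]) + 1L
  ib <- .codon_states(ca[2, ]) + 1L
  keep <- ia <= 61L & ib <= 61L
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0L) stop("no comparable codons")
  st <- .ng86_site_counts()
  S <- (sum(st[ia]) + sum(st[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- Nd <- 0
  for (k in seq_along(ia)) {
    if (ia[k] == ib[k]) next
    d <- .ng86_path_diffs(ia[k], ib[k], tab)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(dN = jc(pN), dS = jc(pS), N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = c(dN = pN >= 0.75, dS = pS >= 0.75))
}

# synonymous site count per codon (fractions over sense-codon targets)
.ng86_site_counts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tab <- .codon_tables()
    s <- numeric(61)
    for (i in 1:61) {
      tot <- 0
      for (p in 1:3) {
        nb <- which(tab$pos[i, ] == p)
        if (length(nb) == 0) next
        tot <- tot + sum(tab$cls[i, nb] <= 2L) / length(nb)
      }
      s[i] <- tot
    }
    cache <<- s
    s
  }
})

# average (Sd, Nd) over all shortest pathways between two codons
.ng86_path_diffs <- function(i, j, tab) {
  pos <- which(tab$splits[i, ] != tab$splits[j, ])
  paths <- if (length(pos) == 1L) list(pos) else .permutations(pos)
  acc <- c(0, 0); nvalid <- 0L
  codons <- tab$codons
  for (path in paths) {
    cur <- tab$splits[i, ]
    sd <- nd <- 0
    ok <- TRUE
    for (p in path) {
      nxt <- cur
      nxt[p] <- tab$splits[j, p]
      c1 <- match(paste(cur, collapse = ""), codons)
      c2 <- match(paste(nxt, collapse = ""), codons)
      if (is.na(c2)) { ok <- FALSE; break }   # pathway through a stop
      if (tab$aa[c1] == tab$aa[c2]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(sd, nd); nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) {
    # all pathways blocked by stops: count all changes as nonsynonymous
    return(c(0, length(pos)))
  }
  acc / nvalid
}

.permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in .permutations(x[-k])) out <- c(out, list(c(x[k], rest)))
  }
  out
}
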