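# Genetic-code bookkeeping for the 61-sense-codon state space.
#
# All likelihood, counting and simulation code indexes codons 0..60 in
# lexicographic order (AAA, AAC, ..., TTT minus the three stops of the
# universal code).  The integer 61 is the missing-data state: any codon
# containing '-' or 'N' is treated as fully ambiguous.

.NUC <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.codon_env <- new.env(parent = emptyenv())

# Build (once) the static codon tables shared by the whole package.
.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  all64 <- as.vector(t(outer(
    as.vector(t(outer(.NUC, .NUC, paste0))), .NUC, paste0)))
  codons <- setdiff(all64, .STOPS)            # 61, lexicographic
  aa <- vapply(codons, function(cd) {
    seqinr_free_translate(cd)
  }, character(1))
  n <- length(codons)
  splits <- do.call(rbind, strsplit(codons, ""))
  # neighbor classification: 0 none, 1 syn tv, 2 syn ts, 3 nonsyn tv, 4 nonsyn ts
  cls <- matrix(0L, n, n)
  pos <- matrix(0L, n, n)   # changed position 1..3 (0 if not neighbor)
  tgt <- matrix(0L, n, n)   # target nucleotide 1..4 at changed position
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(splits[i, ] != splits[j, ])
      if (length(d) != 1L) next
      ts <- is_ts(splits[i, d], splits[j, d])
      syn <- aa[i] == aa[j]
      cls[i, j] <- 1L + as.integer(ts) + 2L * as.integer(!syn)
      pos[i, j] <- d
      tgt[i, j] <- match(splits[j, d], .NUC)
    }
  }
  tab <- list(codons = codons, aa = aa, splits = splits,
              cls = cls, pos = pos, tgt = tgt)
  .codon_env$tab <- tab
  tab
}

# Minimal universal-code translation (avoids a Biostrings round trip for
# single codons at table-build time).
seqinr_free_translate <- local({
  code <- NULL
  function(codon) {
    if (is.null(code)) {
      b1 <- rep(.NUC, each = 16)
      b2 <- rep(rep(.NUC, each = 4), 4)
      b3 <- rep(.NUC, 16)
      aas <- strsplit(paste0(
        "KNKNTTTTRSRSIIMI",
        "QHQHPPPPRRRRLLLL",
        "EDEDAAAAGGGGVVVV",
        "*Y*YSSSS*CWCLFLF"), "")[[1]]
      ord <- paste0(b1, b2, b3)
      # the string above is laid out per first base A,C,G,T blocks
      code <<- stats::setNames(aas, ord)
    }
    unname(code[codon])
  }
})

#' Sense codons and their translations
#'
#' Returns the 61 sense codons of the universal genetic code in the
#' lexicographic order used internally by all model machinery, together with
#' their single-letter amino acid translations.
#'
#' @return A data frame with columns `codon` and `aa`.
#' @export
#' @examples
#' head(sense_codons())
sense_codons <- function() {
  tab <- .codon_tables()
  data.frame(codon = tab$codons, aa = unname(tab$aa))
}

# Position-frequency factor matrix for the MG94 generator: BF[i, j] is the
# F3x4 frequency of the target nucleotide at the changed position for
# single-nucleotide neighbours, 0 elsewhere.  `pi3x4` is a 3 x 4 matrix of
# position-specific nucleotide frequencies (rows = codon positions).
.bf_matrix <- function(pi3x4) {
  tab <- .codon_tables()
  bf <- matrix(0, 61, 61)
  nz <- which(tab$cls > 0L)
  bf[nz] <- pi3x4[cbind(tab$pos[nz], tab$tgt[nz])]
  bf
}

# Stationary codon frequencies implied by position-specific nucleotide
# frequencies: product over positions, renormalized over sense codons.
.f3x4_from_positions <- function(pi3x4) {
  tab <- .codon_tables()
  p <- pi3x4[cbind(1L, match(tab$splits[, 1], .NUC))] *
    pi3x4[cbind(2L, match(tab$splits[, 2], .NUC))] *
    pi3x4[cbind(3L, match(tab$splits[, 3], .NUC))]
  p / sum(p)
}

# Stationary flow rates of the four generator components (synonymous
# transversions/transitions, nonsynonymous transversions/transitions)
# for a frequency model: FS0(kappa) = rA + kappa rB and
# FN0(kappa) = rC + kappa rD are the synonymous and nonsynonymous flows
# with the omega factor left out; r(omega) = FS0 + omega FN0 is the mean
# rate that normalizes the generator to substitutions per codon.
.flow_rates <- function(pi61, bf) {
  tab <- .codon_tables()
  flow <- pi61 * bf              # pi_i * q_ij factor (kappa, omega excluded)
  list(rA = sum(flow[tab$cls == 1L]), rB = sum(flow[tab$cls == 2L]),
       rC = sum(flow[tab$cls == 3L]), rD = sum(flow[tab$cls == 4L]))
}

.flow_constants <- function(kappa, flows) {
  list(FS0 = flows$rA + kappa * flows$rB,
       FN0 = flows$rC + kappa * flows$rD)
}

# codeml-convention per-branch dN and dS from the fitted generator:
# dS = t * rhoS / (3 fS), dN = t * rhoN / (3 fN), where rho are realized
# flow proportions at the branch omega and f are site fractions at
# omega = 1; both reduce to the closed forms below.
.branch_dnds <- function(t, omega, kappa, flows) {
  fl <- .flow_constants(kappa, flows)
  r <- fl$FS0 + omega * fl$FN0
  tot <- fl$FS0 + fl$FN0
  list(dS = t * tot / (3 * r), dN = t * omega * tot / (3 * r))
}

# Map aligned codon strings to engine states 0..60 (61 = missing).
# `mat` is a character matrix of codons (rows = sequences).
.codon_states <- function(codon_chr) {
  tab <- .codon_tables()
  idx <- match(codon_chr, tab$codons)
  idx[is.na(idx)] <- 62L
  idx - 1L
}

# Split aligned sequences (equal length, multiple of 3) into codon strings.
.split_codons <- function(seqs) {
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L, len %% 3L == 0L)
  n <- len %/% 3L
  t(vapply(seqs, function(s) {
    substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
  }, character(n)))
}
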