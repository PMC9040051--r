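# Derived amino acid changes on terminal branches at otherwise conserved
# sites, classified as radical or conservative by an exchange matrix.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read an amino acid exchange matrix
#'
#' A 20 x 20 tab-separated table with single-letter amino acid header row
#' and column, symmetric, scores in \[0, 1\] (the diagonal is ignored).
#' Higher scores mark biochemically more dissimilar replacements.
#'
#' @param path TSV file.
#' @param name Provenance label stored on the matrix.
#' @return An object of class `exchange_matrix`.
#' @export
read_exchange_matrix <- function(path, name = basename(path)) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  exchange_matrix(m, name = name)
}

#' Construct an exchange matrix
#'
#' @param scores Numeric 20 x 20 matrix with amino acid dimnames.
#' @param name Provenance label.
#' @return An `exchange_matrix`.
#' @export
exchange_matrix <- function(scores, name = "custom") {
  scores <- as.matrix(scores)
  if (!identical(dim(scores), c(20L, 20L)))
    stop("exchange matrix must be 20 x 20")
  if (!setequal(rownames(scores), .AA20) ||
      !setequal(colnames(scores), .AA20))
    stop("exchange matrix must be indexed by the 20 standard amino acids")
  scores <- scores[.AA20, .AA20]
  off <- scores[row(scores) != col(scores)]
  if (any(off < 0 | off > 1)) stop("scores must lie in [0, 1]")
  if (max(abs(scores - t(scores))) > 1e-9)
    stop("exchange matrix must be symmetric")
  structure(list(scores = scores, name = name), class = "exchange_matrix")
}

#' Default property-based exchange matrix
#'
#' A binary radical/conservative partition built from amino acid
#' physicochemical classes (charge and polarity): replacements within a
#' class score 0 (conservative), replacements across classes score 1
#' (radical).  Shipped for testing and as a fallback; analyses of real
#' data should load the exchange matrix of record via
#' [read_exchange_matrix()].
#'
#' @return An `exchange_matrix` named `"polarity-charge-binary"`.
#' @export
default_exchange_matrix <- function() {
  classes <- list(
    positive = c("H", "K", "R"),
    negative = c("D", "E"),
    polar = c("C", "N", "Q", "S", "T", "Y"),
    nonpolar = c("A", "F", "G", "I", "L", "M", "P", "V", "W"))
  cls <- character(0)
  for (k in names(classes)) cls[classes[[k]]] <- k
  s <- outer(cls[.AA20], cls[.AA20], function(a, b) as.numeric(a != b))
  dimnames(s) <- list(.AA20, .AA20)
  exchange_matrix(s, name = "polarity-charge-binary")
}

#' Classify an amino acid replacement as radical or conservative
#'
#' Radical iff the exchange-matrix score of the unordered pair is strictly
#' greater than the threshold.
#'
#' @param from_aa,to_aa Single-letter amino acids (vectors recycle).
#' @param matrix An `exchange_matrix`.
#' @param threshold Score threshold (strict inequality).
#' @return Character vector `"radical"`/`"conservative"`.
#' @export
classify_radical <- function(from_aa, to_aa, matrix, threshold = 0.5) {
  stopifnot(inherits(matrix, "exchange_matrix"))
  bad <- !(from_aa %in% .AA20) | !(to_aa %in% .AA20)
  if (any(bad))
    stop("nonstandard residue(s): ",
         paste(unique(c(from_aa[bad], to_aa[bad])), collapse = ", "))
  sc <- matrix$scores[cbind(from_aa, to_aa)]
  ifelse(sc > threshold, "radical", "conservative")
}

#' Find derived autapomorphies at conserved sites
#'
#' A site contributes to a terminal branch's autapomorphy count iff
#' (a) the focal tip's amino acid differs from the amino acid of its
#' reconstructed parent node, (b) the other four tips share one identical
#' amino acid, (c) the parent state equals that shared amino acid (the
#' change is derived, not ancestral), and (d) no sequence has a gap or
#' ambiguous codon at the site.  If an exchange matrix is supplied the
#' radical subset is also counted.
#'
#' @param alignment The fitted `codon_alignment`.
#' @param ancestral An `ancestral_states` from [reconstruct_ancestral()].
#' @param branch Focal terminal branch: one of the five role names.
#' @param roles Optional id -> role map.
#' @param matrix Optional `exchange_matrix` for radical classification.
#' @param threshold Radical score threshold (strict).
#' @return List: `total`, `radical` (NA without a matrix), and a `sites`
#'   data frame (site, from_aa, to_aa, class).
#' @export
find_autapomorphies <- function(alignment, ancestral, branch,
                                roles = NULL, matrix = NULL,
                                threshold = 0.5) {
  if (!branch %in% quintet_roles())
    stop("branch must be a terminal branch (one of the five roles)")
  parent_node <- switch(branch,
                        polyploid_paternal = "paternal_ancestral",
                        diploid_paternal = "paternal_ancestral",
                        polyploid_maternal = "maternal_ancestral",
                        diploid_maternal = "maternal_ancestral",
                        outgroup = "root")
  states <- .alignment_states(alignment, roles)   # engine tip order
  tip_order <- c("polyploid_paternal", "diploid_paternal",
                 "polyploid_maternal", "diploid_maternal", "outgroup")
  tab <- .codon_tables()
  aa_of <- function(v) ifelse(v == 61L, NA_character_,
                              unname(tab$aa[v + 1L]))
  aa_tips <- apply(states, 1, aa_of)              # nsite x 5
  focal_i <- match(branch, tip_order)
  nsite <- nrow(aa_tips)
  parent_aa <- ancestral$aa[, parent_node]
  keep <- rep(TRUE, nsite)
  # (d) no gaps/ambiguity anywhere at the site
  keep <- keep & !apply(is.na(aa_tips), 1, any)
  others <- aa_tips[, -focal_i, drop = FALSE]
  shared <- apply(others, 1, function(r)
    if (length(unique(r)) == 1L) r[1] else NA_character_)
  keep <- keep & !is.na(shared)                   # (b)
  keep <- keep & aa_tips[, focal_i] != parent_aa  # (a)
  keep <- keep & parent_aa == shared              # (c)
  idx <- which(keep)
  sites <- data.frame(site = idx,
                      from_aa = parent_aa[idx],
                      to_aa = aa_tips[idx, focal_i],
                      stringsAsFactors = FALSE)
  radical <- NA_integer_
  sites$class <- rep(NA_character_, nrow(sites))
  if (!is.null(matrix) && nrow(sites) > 0) {
    sites$class <- classify_radical(sites$from_aa, sites$to_aa, matrix,
                                    threshold)
    radical <- sum(sites$class == "radical")
  } else if (!is.null(matrix)) {
    radical <- 0L
  }
  list(branch = branch, total = nrow(sites), radical = radical,
       sites = sites)
}

#' Fisher test of subgenome autapomorphy bias against background
#'
#' Tests a 2 x 2 table of (paternal, maternal) autapomorphy counts in a
#' functional category against the counts in the non-organelle-targeted
#' background, by a two-sided Fisher exact test with the conditional
#' maximum likelihood odds ratio.
#'
#' @param category_counts,not_counts Numeric length-2 vectors
#'   `c(paternal, maternal)`.
#' @return List with `odds_ratio`, `p`, `table`, and `undefined` (TRUE
#'   when a margin is zero, in which case the test statistics are NA).
#' @export
bias_fisher_test <- function(category_counts, not_counts) {
  tabm <- rbind(category = as.numeric(category_counts),
                NOT = as.numeric(not_counts))
  colnames(tabm) <- c("paternal", "maternal")
  if (any(rowSums(tabm) == 0) || any(colSums(tabm) == 0))
    return(list(odds_ratio = NA_real_, p = NA_real_, table = tabm,
                undefined = TRUE))
  ft <- stats::fisher.test(tabm)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tabm,
       undefined = FALSE)
}
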