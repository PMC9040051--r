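# Readers/writers for the formats the pipeline touches: FASTA codon
# alignments, newick gene trees, the species-role map, key=value run
# configuration, and stderr stage logging.

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned, upper-case nucleotide
#'   sequences (equal lengths, multiple of 3).
#' @param validate Check invariants (alphabet, frame, internal stops).
#' @return An object of class `codon_alignment` with fields `ids`, `seqs`
#'   and `length` (alignment columns).
#' @export
codon_alignment <- function(seqs, validate = TRUE) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names")
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  len <- lens[[1]]
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not a multiple of 3 (frame error)")
  if (validate) {
    bad <- grepl("[^ACGTN-]", seqs)
    if (any(bad))
      stop("disallowed characters (alphabet is A,C,G,T,N,-) in: ",
           paste(ids[bad], collapse = ", "))
    seqs <- .strip_terminal_stops(seqs)
    .check_internal_stops(seqs, ids)
  }
  structure(list(ids = ids, seqs = seqs, length = len),
            class = "codon_alignment")
}

# terminal stop codons become missing data; internal stops are errors
.strip_terminal_stops <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    last <- substr(s, n - 2L, n)
    if (last %in% .STOPS) s <- paste0(substr(s, 1L, n - 3L), "---")
    s
  }, character(1))
}

.check_internal_stops <- function(seqs, ids) {
  for (k in seq_along(seqs)) {
    cods <- substring(seqs[[k]], seq(1L, nchar(seqs[[k]]), 3L),
                      seq(3L, nchar(seqs[[k]]), 3L))
    if (any(cods %in% .STOPS))
      stop("internal stop codon in sequence ", ids[k])
  }
  invisible(NULL)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$ids), "sequences x", x$length,
      "columns (", x$length / 3, "codons )\n")
  invisible(x)
}

#' Read a codon-aware FASTA alignment
#'
#' Sequences are upper-cased and input order is preserved.  The alignment
#' must be flush (equal lengths) and in frame (length a multiple of 3);
#' terminal stop codons are converted to missing data and internal stop
#' codons are an error, matching the conventions of codon substitution
#' models that exclude stop states.
#'
#' @param path FASTA file.
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)))
}

#' Write a codon alignment to FASTA
#'
#' @param alignment A `codon_alignment`.
#' @param path Output file.
#' @export
write_codon_fasta <- function(alignment, path) {
  out <- character(2L * length(alignment$ids))
  out[c(TRUE, FALSE)] <- paste0(">", alignment$ids)
  out[c(FALSE, TRUE)] <- unname(alignment$seqs)
  writeLines(out, path)
  invisible(path)
}

#' Read a gene tree from newick
#'
#' Internal node labels are interpreted as integer bootstrap support
#' values in \[0, 100\] where present; branch lengths are optional.
#'
#' @param path Newick file (single tree).
#' @return A `phylo` object (ape).
#' @export
read_gene_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in ", path)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support values outside [0, 100] in ", path)
  tr
}

#' Write a gene tree to newick
#'
#' @param tree A `phylo`.
#' @param path Output file.
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- species-role map ------------------------------------------------------

#' Species-role map
#'
#' Associates the four species of a polyploid study design (outgroup,
#' maternal diploid model, paternal diploid model, allopolyploid) with
#' species tags, together with the rule that extracts the species tag --
#' and, for polyploid sequences, the subgenome -- from a sequence
#' identifier.
#'
#' The default `id_rule` reads the species tag as the identifier prefix
#' before the first underscore, and the polyploid subgenome from the first
#' character after that underscore, looked up in `maternal_tags` /
#' `paternal_tags` (chromosome-derived subgenome naming, e.g.
#' `Ghir_A01G001` with maternal tag `"A"`).
#'
#' @param outgroup,diploid_maternal,diploid_paternal,polyploid Species tags
#'   (distinct, non-empty).
#' @param maternal_tags,paternal_tags Characters naming the maternal and
#'   paternal subgenome codes inside polyploid identifiers.
#' @param id_rule Optional custom rule: function(id) returning a list with
#'   `species` and (optionally) `subgenome` (`"maternal"`, `"paternal"` or
#'   `NA`).
#' @return An object of class `species_map`.
#' @export
species_map <- function(outgroup, diploid_maternal, diploid_paternal,
                        polyploid, maternal_tags = "A",
                        paternal_tags = c("B", "D"), id_rule = NULL) {
  tags <- c(outgroup = outgroup, diploid_maternal = diploid_maternal,
            diploid_paternal = diploid_paternal, polyploid = polyploid)
  if (any(!nzchar(tags)) || anyDuplicated(tags))
    stop("species tags must be four distinct non-empty strings")
  structure(list(roles = tags, maternal_tags = maternal_tags,
                 paternal_tags = paternal_tags, id_rule = id_rule),
            class = "species_map")
}

.default_id_rule <- function(id, map) {
  sp <- sub("_.*$", "", id)
  sub_tag <- sub("^[^_]*_(.).*$", "\\1", id)
  subg <- if (sp == map$roles[["polyploid"]]) {
    if (sub_tag %in% map$maternal_tags) "maternal"
    else if (sub_tag %in% map$paternal_tags) "paternal"
    else NA_character_
  } else NA_character_
  list(species = sp, subgenome = subg)
}

#' Resolve sequence identifiers to quintet roles
#'
#' Applies a species map's identifier rule to every sequence id of a tree,
#' alignment, or character vector.  Polyploid identifiers additionally
#' receive a subgenome label when the id encodes one.
#'
#' @param x A `phylo`, `codon_alignment`, or character vector of ids.
#' @param map A [species_map()].
#' @return Data frame with columns `id`, `species`, `role`, `subgenome`;
#'   `role` is one of outgroup/diploid_maternal/diploid_paternal/polyploid,
#'   refined to `polyploid_maternal` / `polyploid_paternal` in column
#'   `quintet_role` when the subgenome is known.
#' @export
resolve_roles <- function(x, map) {
  ids <- if (inherits(x, "phylo")) x$tip.label
  else if (inherits(x, "codon_alignment")) x$ids
  else as.character(x)
  rule <- map$id_rule %||% function(id) .default_id_rule(id, map)
  out <- lapply(ids, function(id) {
    r <- rule(id)
    role <- names(map$roles)[match(r$species, map$roles)]
    if (is.na(role))
      stop("cannot resolve sequence id to a role: ", id)
    q <- role
    if (role == "polyploid" && !is.na(r$subgenome %||% NA))
      q <- paste0("polyploid_", r$subgenome)
    data.frame(id = id, species = r$species, role = role,
               subgenome = r$subgenome %||% NA_character_,
               quintet_role = q, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- run configuration -----------------------------------------------------

#' Run configuration
#'
#' Bundles the tunable pipeline constants: RNG seed, the per-dataset
#' tree-wide dS cutoff, bootstrap replicate count, optimizer replicate
#' count, bootstrap-support collapse threshold, and the radical-substitution
#' score threshold.
#'
#' @param seed Integer RNG seed.
#' @param ds_cutoff Maximum tree-wide synonymous branch length retained by
#'   the alignment-quality filter (inclusive).
#' @param bootstrap_reps Bootstrap replicates for the rate tests.
#' @param optimizer_replicates Optimizer runs per (bootstrap) fit; medians
#'   of the replicate estimates are used.
#' @param support_collapse_threshold Splits with bootstrap support at or
#'   below this value are collapsed to polytomies.
#' @param cri_threshold Exchange-matrix score above which an amino acid
#'   replacement is called radical (strict inequality).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, ds_cutoff = 2, bootstrap_reps = 1000L,
                       optimizer_replicates = 5L,
                       support_collapse_threshold = 50L,
                       cri_threshold = 0.5) {
  cfg <- list(seed = as.integer(seed), ds_cutoff = ds_cutoff,
              bootstrap_reps = as.integer(bootstrap_reps),
              optimizer_replicates = as.integer(optimizer_replicates),
              support_collapse_threshold = as.integer(support_collapse_threshold),
              cri_threshold = cri_threshold)
  if (any(vapply(cfg, function(v) !is.finite(v) || v <= 0, logical(1)) &
          names(cfg) != "cri_threshold"))
    stop("all configuration values must be positive")
  if (cfg$cri_threshold < 0 || cfg$cri_threshold > 1)
    stop("cri_threshold must lie in [0, 1]")
  structure(cfg, class = "run_config")
}

#' Read a key=value run configuration file
#'
#' Unknown keys are an error; missing keys take the [run_config()]
#' defaults.  Lines starting with `#` and blank lines are ignored.
#'
#' @param path Plain-text config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed key=value line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- names(formals(run_config))
  if (any(!keys %in% known))
    stop("unknown configuration keys: ",
         paste(setdiff(keys, known), collapse = ", "))
  args <- stats::setNames(as.list(as.numeric(vals)), keys)
  do.call(run_config, args)
}

# per-stage record counting on stderr
log_stage <- function(stage, read = NA, retained = NA, excluded = NA) {
  message(sprintf("[%s] read=%s retained=%s excluded=%s",
                  stage, read, retained, excluded))
  invisible(NULL)
}
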