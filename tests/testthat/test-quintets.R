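test_that("support collapsing removes splits at or below the threshold", {
  t1 <- read_gene_tree_text("((A,B)95,(C,D)40,E);")
  c1 <- collapse_low_support(t1, 50)
  expect_equal(c1$Nnode, 2L)             # the 40 split is gone
  expect_setequal(c1$tip.label, t1$tip.label)
  # boundary: support exactly equal to the threshold collapses
  t2 <- read_gene_tree_text("((A,B)50,(C,D)51,E);")
  c2 <- collapse_low_support(t2, 50)
  expect_equal(c2$Nnode, 2L)
  # all supports high: unchanged
  t3 <- read_gene_tree_text("((A,B)100,(C,D)100,E);")
  expect_equal(collapse_low_support(t3, 50)$Nnode, t3$Nnode)
  # missing support values are never collapsed
  t4 <- read_gene_tree_text("((A,B),(C,D)100,E);")
  expect_equal(collapse_low_support(t4, 50)$Nnode, t4$Nnode)
  # idempotent fixed point: a fully collapsed tree stays a star
  t5 <- read_gene_tree_text("((A,B)10,(C,D)20,E);")
  star <- collapse_low_support(t5, 50)
  expect_equal(star$Nnode, 1L)
  expect_identical(ape::write.tree(collapse_low_support(star, 50)),
                   ape::write.tree(star))
})

test_that("species-complete subtree extraction matches brute force", {
  map <- default_species_map()
  set.seed(101)
  n_checked <- 0
  for (rep in 1:200) {
    tr <- random_species_tree(sample(5:12, 1), map)
    got <- extract_species_complete_subtrees(tr, map)
    got_sets <- lapply(got, function(s) sort(s$tip.label))
    want_sets <- brute_force_complete_subtrees(tr, map)
    expect_setequal(got_sets, want_sets)
    # subtrees are disjoint in tips
    all_tips <- unlist(got_sets)
    expect_equal(anyDuplicated(all_tips), 0L)
    n_checked <- n_checked + length(want_sets)
  }
  expect_gt(n_checked, 50)   # the sample actually exercised the extractor
})

test_that("two sibling species-complete clades are both returned", {
  map <- default_species_map()
  clade <- "(((Poly_A%d,Dmat_%d),(Poly_B%d,Dpat_%d)),Out_%d)"
  txt <- paste0("(", sprintf(clade, 1, 1, 1, 1, 1), ",",
                sprintf(clade, 2, 2, 2, 2, 2), ");")
  tr <- read_gene_tree_text(txt)
  subs <- extract_species_complete_subtrees(tr, map)
  expect_length(subs, 2L)
  expect_setequal(vapply(subs, function(s) length(s$tip.label), integer(1)),
                  c(5L, 5L))
  # a tree lacking any outgroup tip yields an empty result
  tr2 <- read_gene_tree_text("((Poly_A1,Dmat_1),(Poly_B1,Dpat_1));")
  expect_length(extract_species_complete_subtrees(tr2, map), 0L)
})

test_that("duplicate trimming keeps the longest sequence, ties seeded", {
  map <- default_species_map()
  tr <- read_gene_tree_text(
    "(((Poly_A1,(Dmat_a,Dmat_b)),(Poly_B1,Dpat_1)),Out_1);")
  lens <- c(Poly_A1 = 400, Dmat_a = 300, Dmat_b = 450, Poly_B1 = 400,
            Dpat_1 = 400, Out_1 = 400)
  out <- trim_lineage_duplicates(tr, lens, map, seed = 1)
  expect_true("Dmat_b" %in% out$tip.label)    # longest retained
  expect_false("Dmat_a" %in% out$tip.label)
  # equal lengths: choice is random but reproducible under the seed
  lens2 <- lens; lens2["Dmat_b"] <- 300
  o1 <- trim_lineage_duplicates(tr, lens2, map, seed = 7)
  o2 <- trim_lineage_duplicates(tr, lens2, map, seed = 7)
  expect_identical(o1$tip.label, o2$tip.label)
  # no duplicates: unchanged
  tr3 <- read_gene_tree_text("(((Poly_A1,Dmat_1),(Poly_B1,Dpat_1)),Out_1);")
  expect_identical(sort(trim_lineage_duplicates(tr3, lens, map)$tip.label),
                   sort(tr3$tip.label))
  # polyploid subgenomes are separate lineages: both copies kept
  tr4 <- read_gene_tree_text(
    "(((Poly_A1,Dmat_1),((Poly_B1,Poly_B2),Dpat_1)),Out_1);")
  lens4 <- c(Poly_A1 = 1, Dmat_1 = 1, Poly_B1 = 500, Poly_B2 = 100,
             Dpat_1 = 1, Out_1 = 1)
  o4 <- trim_lineage_duplicates(tr4, lens4, map, seed = 1)
  expect_setequal(o4$tip.label,
                  c("Poly_A1", "Dmat_1", "Poly_B1", "Dpat_1", "Out_1"))
})

test_that("quintet merging partitions into union/intersection/conflicts", {
  mk <- function(gene_ids, member_lists, source) {
    members <- do.call(rbind, lapply(member_lists, function(m)
      stats::setNames(as.data.frame(as.list(m), stringsAsFactors = FALSE),
                      quintet_roles())))
    quintet_table(gene_ids, members, source)
  }
  m5 <- function(tag) paste0(tag, "_", 1:5)
  phylo <- mk(c("p1", "p2", "p3"),
              list(m5("a"), m5("b"), m5("c")), "phylogenetic")
  # s1 identical to p1; s2 shares 4 of 5 members with p3; s4 disjoint
  syn_c <- m5("c"); syn_c[5] <- "other"
  syn <- mk(c("s1", "s2", "s4"),
            list(m5("a"), syn_c, m5("d")), "syntenic")
  res <- merge_quintet_sets(phylo, syn)
  # identical quintet appears once, in both union and intersection
  expect_equal(res$intersection$gene_id, "p1")
  expect_equal(sum(res$union$gene_id %in% c("p1", "s1")), 1L)
  # disjoint quintets from either side go to the union only
  expect_true(all(c("p2", "s4") %in% res$union$gene_id))
  # overlapping non-identical quintets are conflicts, excluded from union
  expect_setequal(res$conflicts$gene_id, c("p3", "s2"))
  expect_false(any(c("p3", "s2") %in% res$union$gene_id))
  # partitions disjoint; union contains the intersection
  expect_true(all(res$intersection$gene_id %in% res$union$gene_id))
  expect_length(intersect(res$union$gene_id, res$conflicts$gene_id), 0L)
  # duplicate gene ids are rejected
  expect_error(merge_quintet_sets(rbind(phylo, phylo[1, ]), syn),
               "duplicate")
})

test_that("topology concordance gives the three verdicts", {
  conc <- read_gene_tree_text(paste0(
    "(((polyploid_paternal,diploid_paternal),",
    "(polyploid_maternal,diploid_maternal)),outgroup);"))
  expect_equal(check_topology_concordance(conc), "concordant")
  disc <- read_gene_tree_text(paste0(
    "(((polyploid_paternal,diploid_maternal),",
    "(polyploid_maternal,diploid_paternal)),outgroup);"))
  expect_equal(check_topology_concordance(disc), "discordant")
  star <- read_gene_tree_text(paste0(
    "(polyploid_paternal,diploid_paternal,polyploid_maternal,",
    "diploid_maternal,outgroup);"))
  expect_equal(check_topology_concordance(star), "unresolved")
  # one resolved species cherry, rest polytomy: still unresolved
  half <- read_gene_tree_text(paste0(
    "((polyploid_paternal,diploid_paternal),polyploid_maternal,",
    "diploid_maternal,outgroup);"))
  expect_equal(check_topology_concordance(half), "unresolved")
  expect_error(check_topology_concordance(
    read_gene_tree_text("((A,B),C);")), "5 tips")
})

test_that("the dS filter drops above the cutoff and keeps at equality", {
  expect_false(filter_by_tree_ds(list(tree_dS = 5.0), 2.0))
  expect_true(filter_by_tree_ds(list(tree_dS = 2.0), 2.0))
  expect_true(filter_by_tree_ds(list(tree_dS = 0.3), 2.0))
})

test_that("quintet pipeline retains the concordant fraction", {
  d <- 0.25
  gs <- simulate_gene_tree_set(300, discordance_rate = d,
                               duplication_rate = 0.1,
                               low_support_rate = 0.1, seed = 23)
  map <- gs$species_map
  kept <- 0L; total <- 0L
  for (g in seq_along(gs$trees)) {
    tr <- collapse_low_support(gs$trees[[g]], 50)
    subs <- extract_species_complete_subtrees(tr, map)
    if (length(subs) != 1L) next
    lens <- stats::setNames(rep(300, length(subs[[1]]$tip.label)),
                            subs[[1]]$tip.label)
    sub <- trim_lineage_duplicates(subs[[1]], lens, map, seed = g)
    if (length(sub$tip.label) != 5L) next
    verdict <- check_topology_concordance(sub, map)
    if (verdict == "unresolved") next   # excluded, like discordant, downstream
    total <- total + 1L
    if (verdict == "concordant") kept <- kept + 1L
  }
  expect_gt(total, 200)
  ci <- stats::binom.test(kept, total, 1 - d, conf.level = 0.99)$p.value
  expect_gt(ci, 0.01)   # concordant fraction consistent with 1 - d
})
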