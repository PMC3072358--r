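chain_dag <- function() {
  # root -> a -> b -> c -> d, plus a shortcut putting e at two depths
  go_dag(data.frame(
    child_id  = c("a", "b", "c", "d", "e", "e", "f"),
    parent_id = c("root", "a", "b", "c", "d", "a", "e")))
}

test_that("term levels are shortest child-to-parent paths to the root", {
  dag <- chain_dag()
  lv <- term_levels(dag)
  expect_identical(unname(lv["root"]), 1L)
  expect_identical(unname(lv["d"]), 5L)
  # e reaches the root via paths of length 5 and 2: shortest wins
  expect_identical(unname(lv["e"]), 3L)
  expect_identical(sort(select_terms(dag, 5)), c("d"))
  # two roots
  expect_error(go_dag(data.frame(child_id = c("a", "b"),
                                 parent_id = c("root1", "root2"))),
               "exactly one root")
  # rooted graph with a cycle off the spine
  expect_error(go_dag(data.frame(child_id  = c("a", "b", "c", "b"),
                                 parent_id = c("root", "a", "b", "c"))),
               "cycle")
})

test_that("annotations propagate to every ancestor before testing", {
  dag <- chain_dag()
  ann <- data.frame(gene_id = "g1", term_id = "d")
  prop <- propagate_annotations(ann, dag)
  expect_setequal(prop$term_id[prop$gene_id == "g1"],
                  c("d", "c", "b", "a", "root"))
  expect_error(propagate_annotations(
    data.frame(gene_id = "g1", term_id = "zzz"), dag), "unknown term")
})

test_that("Fisher p equals the hypergeometric-enumeration oracle", {
  # perfectly separated 2x2 table [[10,0],[0,10]]
  p_oracle <- oracle_fisher_p(10, 0, 0, 10)
  ft <- fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  expect_equal(ft, p_oracle, tolerance = 1e-9)
  # random tables
  set.seed(13)
  for (r in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(fisher.test(tb)$p.value,
                 oracle_fisher_p(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-7)
  }
})

test_that("enrichment over level 5-6 terms finds a planted skew", {
  # two-level-deep tree with level-5/6 terms via a linear spine
  links <- data.frame(
    child_id  = c("l2", "l3", "l4", "t5a", "t5b", "t6a", "t6b"),
    parent_id = c("root", "l2", "l3", "l4", "l4", "t5a", "t5b"))
  dag <- go_dag(links)
  set_a <- sprintf("a%02d", 1:30)
  set_b <- sprintf("b%02d", 1:30)
  ann <- rbind(
    data.frame(gene_id = set_a[1:20], term_id = "t6a"),   # skewed into A
    data.frame(gene_id = set_b[1:4], term_id = "t6a"),
    data.frame(gene_id = set_a[1:10], term_id = "t6b"),
    data.frame(gene_id = set_b[1:10], term_id = "t6b"))
  res <- fisher_enrichment(set_a, set_b, ann, dag)
  expect_true(all(res$level %in% 5:6))
  expect_true(all(res$bh_q >= res$fisher_p))
  top <- res[res$term_id == "t6a", ]
  expect_identical(top$direction, "set_a")
  expect_identical(top$a_in, 20L)
  # t5a inherits t6a's genes by propagation
  expect_identical(res$a_in[res$term_id == "t5a"], 20L)
  # equal proportions give p = 1
  eq <- fisher_enrichment(set_a, set_b,
                          rbind(data.frame(gene_id = set_a[1:10], term_id = "t6b"),
                                data.frame(gene_id = set_b[1:10], term_id = "t6b")),
                          dag)
  expect_equal(eq$fisher_p[eq$term_id == "t6b"], 1, tolerance = 1e-9)
  expect_error(fisher_enrichment(set_a, c(set_b, set_a[1]), ann, dag),
               "disjoint")
  expect_error(fisher_enrichment(character(0), set_b, ann, dag), "non-empty")
})

test_that("BH q-values match the closed-form step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(17)
  for (r in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
  }
  expect_error(bh_adjust(c(0.1, 1.4)), "0,1")
})

test_that("tissue selectivity uses a strict fraction bound and unions datasets", {
  mk <- function(genes, counts, n_tissues) {
    mat <- t(vapply(counts, function(k)
      as.integer(seq_len(n_tissues) <= k), integer(n_tissues)))
    df <- data.frame(gene_id = genes, mat)
    names(df) <- c("gene_id", sprintf("t%02d", seq_len(n_tissues)))
    df
  }
  d36 <- mk(c("g1", "g2", "g3"), c(8, 9, 20), 36)
  expect_setequal(tissue_selective(d36), "g1")   # 9/36 = 0.25 is not < 0.25
  d73 <- mk(c("g2", "g4"), c(17, 30), 73)
  expect_setequal(tissue_selective(list(d36, d73)), c("g1", "g2"))
  # monotone: removing an expressed call never removes a gene from the set
  set.seed(23)
  base <- mk(sprintf("g%02d", 1:20), sample(1:36, 20, replace = TRUE), 36)
  sel0 <- tissue_selective(base)
  fewer <- base
  cols <- setdiff(names(fewer), "gene_id")
  for (g in seq_len(nrow(fewer))) {
    on <- which(fewer[g, cols] == 1)
    if (length(on) > 1) fewer[g, cols[on[1]]] <- 0
  }
  expect_true(all(sel0 %in% tissue_selective(fewer)))
  expect_error(tissue_selective(data.frame(gene_id = "g1")), "no tissue")
})

test_that("ohnolog reconciliation discards singleton false positives", {
  prov <- data.frame(gene_id = c("d1", "d2", "s1", "u1"),
                     origin_index = 0L, origin_label = NA, conservation = 0L,
                     duplicability = c("duplicated", "duplicated",
                                       "singleton", "unassigned"),
                     flags = "")
  rec <- suppressMessages(
    ohnolog_reconcile(c("d1", "d2", "s1", "ghost"), prov))
  expect_setequal(rec$kept, c("d1", "d2"))
  expect_identical(rec$n_discarded, 1L)
  expect_identical(rec$n_unmatched, 1L)
  # kept + discarded + unmatched = input size (u1 not listed)
  expect_identical(length(rec$kept) + rec$n_discarded + rec$n_unmatched, 4L)
})

test_that("dosage overlap fractions, bin merging, and degenerate cases", {
  prov <- data.frame(
    gene_id = sprintf("h%02d", 1:40),
    origin_index = rep(c(0L, 2L, 3L, 6L), 10),
    origin_label = NA, conservation = 0L,
    duplicability = rep(c("duplicated", "singleton"), each = 20),
    flags = "")
  hubs <- prov$gene_id
  da <- data.frame(gene_id = prov$gene_id,
                   ohnolog = prov$duplicability == "duplicated",
                   mirna_target = FALSE, tissue_selective = FALSE)
  dv <- dosage_overlap(hubs, prov, da)
  allrow <- dv$fractions[dv$fractions$bin == "all" &
                         dv$fractions$annotation == "any", ]
  expect_identical(allrow$frac_duplicated, 1)
  expect_identical(allrow$frac_singleton, 0)
  expect_lt(allrow$fisher_p, 1e-9)
  # opisthokont-origin hubs are counted under the eukaryotes bin,
  # group-specific under mammals
  expect_false("opisthokonts" %in% dv$fractions$bin)
  euk <- dv$fractions[dv$fractions$bin == "eukaryotes" &
                      dv$fractions$annotation == "any", ]
  expect_identical(euk$n_duplicated + euk$n_singleton,
                   sum(prov$origin_index == 2L))
  expect_identical(sum(c("LUCA", "eukaryotes", "metazoans", "mammals") %in%
                       dv$fractions$bin), 4L)
  # numerators across disjoint bins sum to the overall numerator
  per_bin <- dv$fractions[dv$fractions$bin != "all" &
                          dv$fractions$annotation == "any", ]
  expect_identical(sum(per_bin$n_dup_annotated), allrow$n_dup_annotated)
  expect_true(all(dv$fractions$frac_duplicated >= 0 &
                  dv$fractions$frac_duplicated <= 1, na.rm = TRUE))
})

test_that("subset origin profile flags a planted skew and rejects empties", {
  set.seed(29)
  prov <- data.frame(gene_id = sprintf("g%04d", 1:800),
                     origin_index = sample(0:6, 800, replace = TRUE,
                                           prob = c(4, 2, 1, 2, 2, 1, 1)),
                     origin_label = NA, conservation = 0L,
                     duplicability = "singleton", flags = "")
  # subset skewed toward metazoans
  met <- prov$gene_id[prov$origin_index == 3L]
  other <- prov$gene_id[prov$origin_index != 3L]
  subset <- c(sample(met, 60), sample(other, 20))
  prof <- subset_origin_profile(subset, prov$gene_id, prov)
  expect_lt(prof$fisher_p[prof$origin_index == 3L], 0.001)
  expect_gt(prof$pct_subset[prof$origin_index == 3L],
            prof$pct_rest[prof$origin_index == 3L])
  # identical mix: nothing significant
  mix <- sample(prov$gene_id, 100)
  prof2 <- subset_origin_profile(mix, prov$gene_id, prov)
  expect_gt(min(prof2$fisher_p), 0.001)
  expect_error(subset_origin_profile(character(0), prov$gene_id, prov),
               "empty")
  expect_error(subset_origin_profile("zzz", prov$gene_id, prov), "contained")
})

test_that("cross-network singleton-hub conservation counts orthologs", {
  mk_prov <- function(genes, origin, dup) data.frame(
    gene_id = genes, origin_index = origin, origin_label = NA,
    conservation = 0L, duplicability = dup, flags = "")
  a <- list(hubs = c("a1", "a2"),
            provenance = mk_prov(c("a1", "a2", "a3"), c(0L, 1L, 0L),
                                 c("singleton", "singleton", "singleton")),
            network_genes = c("a1", "a2", "a3"))
  b <- list(hubs = c("b1"),
            provenance = mk_prov(c("b1", "b2"), c(0L, 0L),
                                 c("singleton", "duplicated")),
            network_genes = c("b1", "b2"))
  links <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  res <- cross_network_hub_conservation(list(spA = a, spB = b), links)
  rA <- res[res$species == "spA", ]
  # a1 -> b1 (singleton hub elsewhere): conserved; a2 -> b2 (duplicated): not
  expect_identical(rA$n_with_linked, 2L)
  expect_identical(rA$n_conserved, 1L)
  expect_equal(rA$fraction, 50)
  expect_error(cross_network_hub_conservation(list(spA = a), links),
               "2 species")
})
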