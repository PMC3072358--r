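ladder <- toy_ladder()

test_that("presence profile maps cluster members onto ladder nodes", {
  cl <- toy_clusters(
    list("c1", "maNOG", "human", "g1"), list("c1", "maNOG", "mouse", "m_g1"),
    list("c2", "veNOG", "human", "g1"), list("c2", "veNOG", "zebrafish", "z_g1"))
  pv <- presence_profile("g1", cl, ladder)
  expect_identical(unclass(pv)[1:7],
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_false(attr(pv, "nonself_group"))
  expect_identical(assign_origin(pv, ladder), 4L)  # vertebrates
})

test_that("a gene with only same-species paralogs is group-specific", {
  cl <- toy_clusters(list("k1", "KOG", "human", "g1"),
                     list("k1", "KOG", "human", "g2"))
  pv <- presence_profile("g1", cl, ladder)
  expect_identical(which(unclass(pv)), 7L)   # present only at index 6
  expect_true(attr(pv, "nonself_group"))
  expect_identical(assign_origin(pv, ladder), 6L)
})

test_that("a gene with no non-self ortholog anywhere is untraceable", {
  cl <- toy_clusters(list("k1", "KOG", "human", "g1"))
  pv <- presence_profile("g1", cl, ladder)
  expect_true(pv[7])                        # self-membership
  expect_false(attr(pv, "nonself_group"))
  expect_true(is.na(assign_origin(pv, ladder)))
  expect_error(compute_conservation(pv, NA_integer_), "untraceable")
})

test_that("presence errors for genes absent from every cluster", {
  cl <- toy_clusters(list("c1", "KOG", "human", "g1"))
  expect_error(presence_profile("nope", cl, ladder), "absent from all")
})

test_that("off-lineage presence projects through the lineage mask", {
  # E. coli focal: a COG containing a metazoan ortholog is LUCA evidence
  sp <- data.frame(
    species_id = c("bsub", "yeast", "fly", "human", "ecoli"),
    node_label = c("LUCA", "eukaryotes", "metazoans", "mammals",
                   "group_specific"),
    stringsAsFactors = FALSE)
  lad <- build_ladder(sp, "ecoli", on_lineage = c(TRUE, rep(FALSE, 5), TRUE))
  cl <- toy_clusters(list("cog1", "COG", "ecoli", "b001"),
                     list("cog1", "COG", "fly", "fly_x"))
  pv <- presence_profile("b001", cl, lad)
  expect_true(pv[4])                        # metazoan member present
  expect_identical(assign_origin(pv, lad), 0L)
})

test_that("conservation counts missing intermediate nodes", {
  mk <- function(present) structure(present, gene_id = "g",
                                    nonself_group = TRUE,
                                    class = "presence_vector")
  # LUCA origin, present only at LUCA and the group node: the documented max
  pv <- mk(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(compute_conservation(pv, 0L), 5L)
  # metazoan origin, absent at vertebrates and mammals
  pv2 <- mk(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(compute_conservation(pv2, 3L), 2L)
  # mammal origin: no intermediate nodes exist at all
  pv3 <- mk(c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(compute_conservation(pv3, 5L), 0L)
  # conservation <= 5 - origin over every profile
  for (o in 0:5) {
    for (r in 1:20) {
      pres <- c(rep(FALSE, o), TRUE,
                runif(5 - o) < 0.5, TRUE)[1:7]
      pres[o + 1] <- TRUE; pres[7] <- TRUE
      expect_lte(compute_conservation(mk(pres), o), 5L - o)
    }
  }
})

test_that("origin assignment is monotone in added ancient presences", {
  mk <- function(present) structure(present, gene_id = "g",
                                    nonself_group = FALSE,
                                    class = "presence_vector")
  for (r in 1:50) {
    pres <- c(runif(6) < 0.4, TRUE)
    if (!any(pres[1:6])) pres[sample.int(6, 1)] <- TRUE
    o1 <- assign_origin(mk(pres), ladder)
    k <- sample.int(6, 1)
    pres2 <- pres; pres2[k] <- TRUE
    o2 <- assign_origin(mk(pres2), ladder)
    expect_lte(o2, o1)    # adding presence never makes origin more recent
  }
})

test_that("duplicability reflects focal paralog count at the reference level", {
  cl <- toy_clusters(
    list("k1", "KOG", "human", "g1"), list("k1", "KOG", "human", "g2"),
    list("k1", "KOG", "mouse", "m1"),
    list("k2", "KOG", "human", "g3"),
    list("c9", "meNOG", "human", "g4"), list("c9", "meNOG", "fly", "f1"))
  expect_identical(assign_duplicability("g1", cl, "KOG", "human"), "duplicated")
  expect_identical(assign_duplicability("g2", cl, "KOG", "human"), "duplicated")
  expect_identical(assign_duplicability("g3", cl, "KOG", "human"), "singleton")
  expect_identical(assign_duplicability("g4", cl, "KOG", "human"), "unassigned")
})

test_that("same-level multi-membership is rejected as malformed", {
  expect_error(toy_clusters(
    list("k1", "KOG", "human", "g1"),
    list("k2", "KOG", "human", "g1")), "more than one cluster")
})

test_that("annotate_genes flags exclusions and satisfies count identities", {
  cl <- toy_clusters(
    list("c1", "veNOG", "human", "g1"), list("c1", "veNOG", "zebrafish", "z1"),
    list("k1", "KOG", "human", "g1"), list("k1", "KOG", "human", "g2"),
    list("c2", "meNOG", "human", "g2"), list("c2", "meNOG", "fly", "f1"),
    list("c3", "COG", "human", "g3"), list("c3", "COG", "ecoli", "e1"),
    list("k9", "KOG", "human", "g4"))
  genes <- c("g1", "g2", "g3", "g4", "lost1", "lost2", "lost3")
  expect_message(
    prov <- annotate_genes(genes, cl, ladder, "KOG"),
    "excluded downstream")
  expect_identical(nrow(prov), 7L)
  expect_identical(prov$origin_index[prov$gene_id == "g1"], 4L)
  expect_identical(prov$duplicability[prov$gene_id == "g1"], "duplicated")
  expect_identical(prov$duplicability[prov$gene_id == "g3"], "unassigned")
  # g4 sits alone in a KOG: traceability lost, duplicability defined
  expect_match(prov$flags[prov$gene_id == "g4"], "untraceable")
  expect_identical(prov$duplicability[prov$gene_id == "g4"], "singleton")
  # cluster-less genes carry both flags
  expect_identical(prov$flags[prov$gene_id == "lost1"],
                   "untraceable,unassigned")
  excl <- attr(prov, "exclusions")
  expect_identical(unname(excl["clusterless"]), 3L)
  # |genes| = |traceable| + |untraceable|
  n_untrace <- sum(grepl("untraceable", prov$flags))
  expect_identical(sum(!is.na(prov$origin_index)) + n_untrace, length(genes))
  # |in reference level| = |singleton| + |duplicated|
  expect_identical(sum(prov$duplicability %in% c("singleton", "duplicated")),
                   length(genes) - sum(grepl("unassigned", prov$flags)))
})

test_that("annotate_genes on an empty list returns an empty table", {
  cl <- toy_clusters(list("c1", "KOG", "human", "g1"))
  prov <- annotate_genes(character(0), cl, ladder, "KOG", quiet = TRUE)
  expect_identical(nrow(prov), 0L)
})
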