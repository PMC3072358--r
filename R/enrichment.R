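#' Build a GO-style directed acyclic graph
#'
#' Accepts a child-to-parent link table, validates acyclicity and single-root
#' reachability, and computes per-term levels as 1 + the length of the
#' shortest child-to-parent path to the root (root = level 1). The shortest
#' path is used because a DAG gives each term many depths.
#'
#' @param links data.frame with columns `child_id`, `parent_id`.
#' @return object of class `go_dag`: list with `terms`, `parents` (list of
#'   parent ids per term), `children`, `root`, `level` (named integer).
#' @export
go_dag <- function(links) {
  stopifnot(is.data.frame(links), all(c("child_id", "parent_id") %in% names(links)))
  child <- as.character(links$child_id)
  parent <- as.character(links$parent_id)
  terms <- sort(unique(c(child, parent)))
  parents <- split(parent, factor(child, levels = terms))
  children <- split(child, factor(parent, levels = terms))

  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop("DAG must have exactly one root, found ", length(roots))
  root <- roots

  # BFS from the root along child links: shortest-path levels
  level <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  level[root] <- 1L
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(level[nxt])]
    if (length(nxt)) level[nxt] <- level[frontier[1L]] + 1L
    frontier <- nxt
  }
  if (anyNA(level))
    stop("orphan term(s) unreachable from the root: ",
         paste(utils::head(terms[is.na(level)], 5L), collapse = ", "))

  # cycle check: child->parent links must strictly decrease ... a DAG rooted
  # BFS already guarantees reachability; detect cycles by topological count
  deg_in <- lengths(parents)
  order_seen <- 0L
  q <- root
  deg_left <- stats::setNames(deg_in, terms)
  while (length(q)) {
    t <- q[1L]; q <- q[-1L]
    order_seen <- order_seen + 1L
    for (c in children[[t]]) {
      deg_left[c] <- deg_left[c] - 1L
      if (deg_left[c] == 0L) q <- c(q, c)
    }
  }
  if (order_seen != length(terms)) stop("cycle detected in the DAG")

  structure(list(terms = terms, parents = parents, children = children,
                 root = root, level = level),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG: ", length(x$terms), " terms, root ", x$root,
      ", max level ", max(x$level), "\n", sep = "")
  invisible(x)
}

#' Per-term levels and level selection
#'
#' @param dag a [go_dag()] object.
#' @return named integer vector of levels (root = 1).
#' @export
term_levels <- function(dag) dag$level

#' @param dag a [go_dag()] object.
#' @param levels integer levels to keep (default 5 and 6).
#' @return character vector of term ids at the requested levels.
#' @rdname term_levels
#' @export
select_terms <- function(dag, levels = c(5L, 6L)) {
  names(dag$level)[dag$level %in% levels]
}

#' Read a GO DAG link table (child_id, parent_id)
#' @param path file path.
#' @return a [go_dag()] object.
#' @export
read_go_dag <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  go_dag(df)
}

#' Read a gene-to-term annotation table (gene_id, term_id)
#' @param path file path.
#' @return data.frame `gene_id`, `term_id`.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotations file must have columns gene_id, term_id")
  df
}

# memoised ancestor closure (term itself included)
ancestor_sets <- function(dag) {
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag$parents[[t]]
    res <- t
    for (p in ps) res <- c(res, anc(p))
    res <- unique(res)
    memo[[t]] <- res
    res
  }
  for (t in dag$terms) anc(t)
  memo
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to all its ancestors.
#'
#' @param annotations data.frame `gene_id`, `term_id`.
#' @param dag a [go_dag()] object.
#' @return data.frame `gene_id`, `term_id` with the closure applied.
#' @export
propagate_annotations <- function(annotations, dag) {
  memo <- ancestor_sets(dag)
  per_term <- split(annotations$gene_id, annotations$term_id)
  out_g <- list(); out_t <- list()
  # invert: for each annotated term, its genes flow up to every ancestor
  up <- new.env(parent = emptyenv())
  for (t in names(per_term)) {
    if (!t %in% dag$terms) stop("annotation to unknown term: ", t)
    for (a in memo[[t]]) {
      up[[a]] <- c(up[[a]], per_term[[t]])
    }
  }
  terms <- ls(up)
  res <- do.call(rbind, lapply(terms, function(t)
    data.frame(gene_id = unique(up[[t]]), term_id = t,
               stringsAsFactors = FALSE)))
  res[order(res$term_id, res$gene_id), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over a vector of p-values.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return numeric vector of q-values (order-preserving, never below p,
#'   clipped at 1).
#' @export
bh_adjust <- function(p) {
  # tolerate floating-point overshoot from exact tests (p = 1 + eps)
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pmin(pmax(p, 0), 1), method = "BH")
}

#' Fisher enrichment of two gene sets over level-restricted terms
#'
#' Annotations are first propagated to ancestors (true-path rule), then terms
#' at the requested levels are tested with a two-sided Fisher exact test on
#' the 2x2 table (in set A vs in set B) x (annotated vs not). P-values are
#' BH-adjusted over the tested terms; direction is taken from the odds ratio
#' (`"set_a"` when the term is relatively enriched in set A).
#'
#' @param set_a,set_b disjoint character vectors of gene ids.
#' @param annotations data.frame `gene_id`, `term_id` (direct annotations).
#' @param dag a [go_dag()] object.
#' @param levels term levels to test (default 5 and 6, tested jointly).
#' @param categories optional data.frame `term_id`, `category` rollup map.
#' @return data.frame: `term_id`, `level`, `a_in`, `a_out`, `b_in`, `b_out`,
#'   `fisher_p`, `bh_q`, `direction`, `category` (`NA` when no map given).
#' @export
fisher_enrichment <- function(set_a, set_b, annotations, dag,
                              levels = c(5L, 6L), categories = NULL) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both gene sets must be non-empty")
  if (length(intersect(set_a, set_b)))
    stop("gene sets must be disjoint")
  prop <- propagate_annotations(annotations, dag)
  terms <- select_terms(dag, levels)
  per_term <- split(prop$gene_id, factor(prop$term_id, levels = terms))

  rows <- lapply(terms, function(t) {
    genes <- per_term[[t]]
    a_in <- sum(set_a %in% genes); b_in <- sum(set_b %in% genes)
    a_out <- length(set_a) - a_in; b_out <- length(set_b) - b_in
    if (a_in + b_in == 0L) return(NULL)   # term annotates neither set
    ft <- stats::fisher.test(matrix(c(a_in, a_out, b_in, b_out), nrow = 2L))
    data.frame(term_id = t, level = dag$level[[t]],
               a_in = a_in, a_out = a_out, b_in = b_in, b_out = b_out,
               fisher_p = ft$p.value,
               direction = if (a_in / length(set_a) > b_in / length(set_b))
                 "set_a" else if (a_in / length(set_a) < b_in / length(set_b))
                   "set_b" else "none",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no tested term annotates either set")
  res$bh_q <- bh_adjust(res$fisher_p)
  res$category <- if (!is.null(categories))
    categories$category[match(res$term_id, categories$term_id)]
  else NA_character_
  res <- res[order(res$bh_q, res$fisher_p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tissue-selective genes from binary expression calls
#'
#' A gene is tissue-selective in a dataset when it is expressed in strictly
#' fewer than `frac` of the dataset's tissues; the final set is the union
#' over datasets.
#'
#' @param expression_calls a data.frame (or list of data.frames, one per
#'   dataset) with `gene_id` followed by one 0/1 column per tissue.
#' @param frac strict fraction bound (default 0.25).
#' @return character vector of tissue-selective gene ids.
#' @export
tissue_selective <- function(expression_calls, frac = 0.25) {
  if (is.data.frame(expression_calls))
    expression_calls <- list(expression_calls)
  out <- character(0)
  for (d in expression_calls) {
    stopifnot("gene_id" %in% names(d))
    mat <- as.matrix(d[setdiff(names(d), "gene_id")])
    if (ncol(mat) == 0L) stop("expression dataset has no tissue columns")
    storage.mode(mat) <- "numeric"
    sel <- rowSums(mat > 0) / ncol(mat) < frac
    out <- union(out, as.character(d$gene_id[sel]))
  }
  out
}

#' Reconcile an ohnolog list against duplicability calls
#'
#' Ohnologs arose by whole-genome duplication, so a listed gene whose
#' reference cluster shows no retained paralog (a singleton) is treated as a
#' likely false positive and discarded. Genes absent from the provenance
#' table are dropped separately.
#'
#' @param ohnolog_list character vector of gene ids.
#' @param provenance output of [annotate_genes()].
#' @return list `kept` (character), `n_discarded` (singleton ohnologs),
#'   `n_unmatched` (absent from provenance).
#' @export
ohnolog_reconcile <- function(ohnolog_list, provenance) {
  ohnolog_list <- unique(as.character(ohnolog_list))
  dup <- provenance$duplicability[match(ohnolog_list, provenance$gene_id)]
  unmatched <- is.na(dup)
  kept <- ohnolog_list[!unmatched & dup == "duplicated"]
  n_disc <- sum(!unmatched & dup == "singleton")
  if (sum(unmatched))
    message("ohnolog_reconcile: ", sum(unmatched),
            " listed genes absent from provenance, dropped")
  list(kept = kept, n_discarded = n_disc, n_unmatched = sum(unmatched))
}

# default bin merge: opisthokonts -> eukaryotes, primates/group -> mammals
default_origin_bins <- function() {
  c("0" = "LUCA", "1" = "eukaryotes", "2" = "eukaryotes",
    "3" = "metazoans", "4" = "vertebrates", "5" = "mammals", "6" = "mammals")
}

#' Dosage-regulation overlap of duplicated versus singleton hubs
#'
#' Compares the fractions of duplicated and singleton hubs that are ohnologs,
#' miRNA targets, tissue-selective, or any of the three -- overall and per
#' origin bin (sparse bins are merged: opisthokonts with eukaryotes,
#' group-specific/primates with mammals). Each duplicated-vs-singleton
#' comparison gets a two-sided Fisher exact p; within duplicated hubs, each
#' bin is additionally tested against all older bins (recent-versus-older).
#'
#' @param hubs character vector of hub gene ids ([call_hubs()]`$hubs`).
#' @param provenance output of [annotate_genes()].
#' @param dosage_annotation data.frame `gene_id`, logical/0-1 columns
#'   `ohnolog`, `mirna_target`, `tissue_selective`.
#' @param origin_bins named character vector mapping origin index (as
#'   character "0".."6") to bin label; default merges sparse bins.
#' @return list `fractions` (data.frame: `bin`, `annotation`,
#'   `n_duplicated`, `n_dup_annotated`, `frac_duplicated`, `n_singleton`,
#'   `n_sing_annotated`, `frac_singleton`, `fisher_p`) and
#'   `recent_vs_older` (data.frame of within-duplicated bin contrasts).
#' @export
dosage_overlap <- function(hubs, provenance, dosage_annotation,
                           origin_bins = default_origin_bins()) {
  keep <- provenance$flags == "" &
    provenance$duplicability %in% c("duplicated", "singleton")
  prov <- provenance[keep & provenance$gene_id %in% hubs, , drop = FALSE]
  if (nrow(prov) == 0L) stop("no hubs with provenance data")
  da <- dosage_annotation
  for (cl in c("ohnolog", "mirna_target", "tissue_selective"))
    da[[cl]] <- as.logical(da[[cl]])
  i <- match(prov$gene_id, da$gene_id)
  ann <- data.frame(
    ohnolog = ifelse(is.na(i), FALSE, da$ohnolog[i]),
    mirna_target = ifelse(is.na(i), FALSE, da$mirna_target[i]),
    tissue_selective = ifelse(is.na(i), FALSE, da$tissue_selective[i]))
  ann$any <- ann$ohnolog | ann$mirna_target | ann$tissue_selective
  bin <- unname(origin_bins[as.character(prov$origin_index)])
  is_dup <- prov$duplicability == "duplicated"

  bin_order <- unique(origin_bins)                       # ancient -> recent
  bins_present <- bin_order[bin_order %in% bin]
  all_bins <- c("all", bins_present)

  frac_rows <- list()
  for (b in all_bins) {
    sel <- if (b == "all") rep(TRUE, nrow(prov)) else bin == b
    nd <- sum(sel & is_dup); ns <- sum(sel & !is_dup)
    if (nd == 0L && ns == 0L) next
    for (a in c("any", "ohnolog", "mirna_target", "tissue_selective")) {
      kd <- sum(sel & is_dup & ann[[a]])
      ks <- sum(sel & !is_dup & ann[[a]])
      p <- if (nd > 0L && ns > 0L)
        stats::fisher.test(matrix(c(kd, nd - kd, ks, ns - ks), 2L))$p.value
      else NA_real_
      frac_rows[[length(frac_rows) + 1L]] <- data.frame(
        bin = b, annotation = a,
        n_duplicated = nd, n_dup_annotated = kd,
        frac_duplicated = if (nd > 0L) kd / nd else NA_real_,
        n_singleton = ns, n_sing_annotated = ks,
        frac_singleton = if (ns > 0L) ks / ns else NA_real_,
        fisher_p = p, stringsAsFactors = FALSE)
    }
  }

  # within duplicated hubs: each bin vs all older bins
  rec_rows <- list()
  if (length(bins_present) > 1L) {
    for (bi in seq_along(bins_present)[-1L]) {
      b <- bins_present[bi]
      older <- bin %in% bins_present[seq_len(bi - 1L)]
      for (a in c("any", "ohnolog", "mirna_target", "tissue_selective")) {
        k1 <- sum(is_dup & bin == b & ann[[a]])
        n1 <- sum(is_dup & bin == b)
        k0 <- sum(is_dup & older & ann[[a]])
        n0 <- sum(is_dup & older)
        if (n1 == 0L || n0 == 0L) next
        p <- stats::fisher.test(matrix(c(k1, n1 - k1, k0, n0 - k0), 2L))$p.value
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          bin = b, annotation = a, n_bin = n1, frac_bin = k1 / n1,
          n_older = n0, frac_older = k0 / n0, fisher_p = p,
          stringsAsFactors = FALSE)
      }
    }
  }

  list(fractions = do.call(rbind, frac_rows),
       recent_vs_older = if (length(rec_rows)) do.call(rbind, rec_rows)
                         else NULL)
}

#' Origin profile of a gene subset versus its universe
#'
#' For each of the seven ladder nodes, compares the fraction of subset genes
#' originating there against the complement (universe minus subset) with a
#' two-sided Fisher exact test.
#'
#' @param subset character vector of gene ids (must be within `universe`).
#' @param universe character vector of gene ids.
#' @param provenance output of [annotate_genes()].
#' @return data.frame: `origin_index`, `origin_label`, `n_subset`,
#'   `pct_subset`, `n_rest`, `pct_rest`, `fisher_p`.
#' @export
subset_origin_profile <- function(subset, universe, provenance) {
  subset <- unique(as.character(subset))
  universe <- unique(as.character(universe))
  if (length(subset) == 0L) stop("subset is empty")
  if (!all(subset %in% universe)) stop("subset must be contained in universe")
  prov <- provenance[!is.na(provenance$origin_index) &
                     provenance$gene_id %in% universe, , drop = FALSE]
  in_sub <- prov$gene_id %in% subset
  n_sub <- sum(in_sub); n_rest <- sum(!in_sub)
  rows <- lapply(0:6, function(k) {
    at_k <- prov$origin_index == k
    a <- sum(at_k & in_sub); b <- sum(at_k & !in_sub)
    p <- stats::fisher.test(matrix(c(a, n_sub - a, b, n_rest - b), 2L))$p.value
    data.frame(origin_index = k, origin_label = LADDER_NODES[k + 1L],
               n_subset = a, pct_subset = 100 * a / n_sub,
               n_rest = b, pct_rest = 100 * b / n_rest,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-network conservation of early singleton hubs
#'
#' For each species, among singleton hubs that originated early in evolution
#' (LUCA or eukaryotes) and have at least one ortholog with network data in
#' another species, computes the fraction whose orthologs include a singleton
#' hub of another network.
#'
#' @param per_species named list; each element a list with `hubs` (character),
#'   `provenance` ([annotate_genes()] output), `network_genes` (character:
#'   genes with network data).
#' @param ortholog_links data.frame `gene_a`, `gene_b` of cross-species
#'   ortholog pairs (gene ids globally unique across species).
#' @return data.frame: `species`, `n_early_singleton_hubs`, `n_with_linked`,
#'   `n_conserved`, `fraction` (percent).
#' @export
cross_network_hub_conservation <- function(per_species, ortholog_links) {
  if (length(per_species) < 2L) stop("need hub calls for at least 2 species")
  if (nrow(ortholog_links) == 0L) stop("no cross-species ortholog links")
  links <- rbind(
    data.frame(a = as.character(ortholog_links$gene_a),
               b = as.character(ortholog_links$gene_b)),
    data.frame(a = as.character(ortholog_links$gene_b),
               b = as.character(ortholog_links$gene_a)))
  link_map <- split(links$b, links$a)

  rows <- lapply(names(per_species), function(sp) {
    x <- per_species[[sp]]
    prov <- x$provenance
    early_sing <- prov$gene_id[!is.na(prov$origin_index) &
                               prov$origin_index %in% c(0L, 1L) &
                               prov$duplicability == "singleton"]
    focal_hubs <- intersect(x$hubs, early_sing)
    other <- per_species[setdiff(names(per_species), sp)]
    other_net <- unlist(lapply(other, `[[`, "network_genes"), use.names = FALSE)
    other_sing_hubs <- unlist(lapply(other, function(o) {
      intersect(o$hubs,
                o$provenance$gene_id[o$provenance$duplicability == "singleton"])
    }), use.names = FALSE)
    with_linked <- 0L; conserved <- 0L
    for (g in focal_hubs) {
      orth <- link_map[[g]]
      if (is.null(orth) || !any(orth %in% other_net)) next
      with_linked <- with_linked + 1L
      if (any(orth %in% other_sing_hubs)) conserved <- conserved + 1L
    }
    data.frame(species = sp, n_early_singleton_hubs = length(focal_hubs),
               n_with_linked = with_linked, n_conserved = conserved,
               fraction = if (with_linked > 0L) 100 * conserved / with_linked
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a one-gene-per-line list file
#' @param path file path (`#` comments and blank lines skipped).
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a binary expression-call table (gene_id + one 0/1 column per tissue)
#' @param path file path.
#' @return data.frame.
#' @export
read_expression_calls <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression file must have gene_id")
  df
}
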