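#' Simulation configuration with planted ground truth
#'
#' Bundles every knob of the synthetic-input generators. Defaults emulate a
#' human-like focal species: roughly 60% of genes of ancient origin (LUCA +
#' early eukaryotes) and about a quarter originating with vertebrates or
#' later, a duplicated fraction rising toward recent origins (about 65%
#' overall), 3 primates and 5 additional mammals among the ladder species,
#' interaction evidence mixing single-gene studies (< 100 interactions each)
#' with a few large screenings, and two expression atlases of 36 and 73
#' tissues.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_genes number of focal-species genes.
#' @param focal_species focal species identifier.
#' @param origin_dist probability over the 7 ladder nodes (ancient first).
#' @param conservation_loss_prob per-intermediate-node ortholog-loss
#'   probability.
#' @param duplicated_fraction length-7 vector: planted duplicated fraction
#'   per origin node.
#' @param untraceable_fraction,unassigned_fraction planted exclusion rates.
#' @param species_per_node non-focal species count per node.
#' @param network_fraction fraction of clean genes carried into the network.
#' @param mean_degree target mean degree of the interaction network.
#' @param age_degree_coupling strength of the ancient-genes-attract-more
#'   fitness term (0 = none).
#' @param hub_boost strength of the within-stratum duplicability contrast
#'   (human-like mode; 0 = off): duplicated genes of metazoan/vertebrate
#'   origin gain attachment fitness at the expense of same-age singletons,
#'   and LUCA/eukaryote-origin singletons gain at the expense of same-age
#'   duplicates, mean-preserving within each stratum (the fitness ratio
#'   between the favoured and disfavoured class is `1 + hub_boost`).
#' @param ancient_singleton_boost analogous contrast strength in favour of
#'   singletons at LUCA/eukaryote origins (the conserved singleton-hub core);
#'   milder by default than the recent-duplicated boost.
#' @param frac_high_throughput fraction of edges supported by high-throughput
#'   screenings (rest get a single-gene record).
#' @param p_second_ht probability a high-throughput edge is confirmed by a
#'   second screening.
#' @param p_sg_extra_ht probability a single-gene edge also appears in a
#'   screening.
#' @param n_ht_experiments number of high-throughput screenings.
#' @param sg_exp_max_edges max interactions per single-gene study (< scale
#'   threshold).
#' @param orthology_decoy_rate,self_loop_rate rates of planted dirty records
#'   exercising the integration filters.
#' @param scale_threshold evidence-scale threshold (strict <; default 100).
#' @param go_depth,go_branching GO tree shape (root = level 1).
#' @param n_categories functional categories over level-5/6 terms.
#' @param go_skew planted category enrichment factor between recent-duplicated
#'   and ancient-singleton gene pools.
#' @param annots_per_gene mean direct annotations per gene.
#' @param enrichment_factor dosage-annotation enrichment among recent
#'   duplicated hub-intent genes.
#' @param base_rates baseline ohnolog/miRNA-target/tissue-selective rates.
#' @param ohnolog_fp_rate fraction of the emitted ohnolog list drawn from
#'   singletons (planted false positives).
#' @param tissue_counts tissues per expression dataset.
#' @param tissue_frac strict tissue-selectivity fraction bound.
#' @param expression_coverage fraction of genes present in expression data.
#' @param noise_drop_prob probability of dropping a non-self cluster member
#'   (0 = noise-free, exact recovery guaranteed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       focal_species = "hsap",
                       origin_dist = c(0.40, 0.17, 0.05, 0.12, 0.18, 0.075, 0.005),
                       conservation_loss_prob = 0.1,
                       duplicated_fraction = c(0.55, 0.55, 0.60, 0.78, 0.80, 0.70, 0.60),
                       untraceable_fraction = 0.006,
                       unassigned_fraction = 0.003,
                       species_per_node = c(3L, 2L, 1L, 2L, 2L, 5L, 2L),
                       network_fraction = 0.6,
                       mean_degree = 8,
                       age_degree_coupling = 2.5,
                       hub_boost = 4,
                       ancient_singleton_boost = 1,
                       frac_high_throughput = 0.7,
                       p_second_ht = 0.4,
                       p_sg_extra_ht = 0.3,
                       n_ht_experiments = 4L,
                       sg_exp_max_edges = 30L,
                       orthology_decoy_rate = 0.02,
                       self_loop_rate = 0.005,
                       scale_threshold = 100L,
                       go_depth = 6L,
                       go_branching = 3L,
                       n_categories = 12L,
                       go_skew = 5,
                       annots_per_gene = 3,
                       enrichment_factor = 3,
                       base_rates = c(ohnolog = 0.31, mirna_target = 0.05,
                                      tissue_selective = 0.25),
                       ohnolog_fp_rate = 0.065,
                       tissue_counts = c(36L, 73L),
                       tissue_frac = 0.25,
                       expression_coverage = 0.8,
                       noise_drop_prob = 0) {
  cfg <- as.list(environment())
  stopifnot(length(origin_dist) == 7L, abs(sum(origin_dist) - 1) < 1e-8,
            all(origin_dist >= 0),
            length(duplicated_fraction) == 7L,
            all(duplicated_fraction >= 0 & duplicated_fraction <= 1),
            conservation_loss_prob >= 0, conservation_loss_prob <= 1,
            length(species_per_node) == 7L, all(species_per_node >= 1L),
            frac_high_throughput >= 0, frac_high_throughput <= 1,
            go_depth >= 6L, n_genes >= 1L,
            noise_drop_prob >= 0, noise_drop_prob <= 1)
  structure(cfg, class = "sim_config")
}

# inclusiveness level label for each origin node's widest cluster
SIM_LEVELS <- c("COG", "euNOG", "opiNOG", "meNOG", "veNOG", "maNOG", "prNOG")
SIM_REFERENCE_LEVEL <- "KOG"

sim_species_table <- function(config) {
  tags <- c("luca", "euk", "opi", "met", "ver", "mam", "grp")
  rows <- list()
  for (k in 0:6) {
    n <- config$species_per_node[k + 1L]
    rows[[k + 1L]] <- data.frame(
      species_id = paste0("sp_", tags[k + 1L], "_", seq_len(n)),
      node_label = LADDER_NODES[k + 1L], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rbind(out, data.frame(species_id = config$focal_species,
                        node_label = "group_specific",
                        stringsAsFactors = FALSE))
}

#' Generate provenance inputs with planted ground truth
#'
#' Emits `species_nodes.tsv` and `clusters.tsv` such that running the
#' provenance pipeline on them recovers the planted origin, conservation,
#' and duplicability of every gene exactly (in noise-free mode). Each gene
#' receives a private most-inclusive cluster holding one ortholog species per
#' planted-present node, plus a reference-level (KOG) cluster that holds a
#' shadow paralog when the gene is planted duplicated. Untraceable genes
#' appear only in a KOG with themselves; unassigned genes lack a KOG.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param plan optional data.frame `gene_id`, `origin` (0--6 or `NA` for
#'   untraceable), `conservation` (`NA` when untraceable), `duplicability`
#'   overriding random generation; infeasible plans (conservation >
#'   max(0, 5 - origin)) raise an error.
#' @return invisible list: `files` (paths), `manifest` (data.frame of planted
#'   values per gene).
#' @export
simulate_provenance_inputs <- function(config, outdir, plan = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 11L)

  if (is.null(plan)) {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    origin <- sample(0:6, n, replace = TRUE, prob = config$origin_dist)
    conservation <- integer(n)
    for (i in seq_len(n)) {
      inter <- if (origin[i] < 5L) (origin[i] + 1L):5L else integer(0)
      conservation[i] <- sum(stats::runif(length(inter)) <
                               config$conservation_loss_prob)
    }
    duplicability <- ifelse(
      stats::runif(n) < config$duplicated_fraction[origin + 1L],
      "duplicated", "singleton")
    untrace <- stats::runif(n) < config$untraceable_fraction
    unassigned <- !untrace & stats::runif(n) < config$unassigned_fraction
    origin[untrace] <- NA_integer_
    conservation[untrace] <- NA_integer_
    duplicability[untrace] <- "singleton"
    duplicability[unassigned] <- "unassigned"
    plan <- data.frame(gene_id = gene_id, origin = origin,
                       conservation = conservation,
                       duplicability = duplicability,
                       stringsAsFactors = FALSE)
  } else {
    plan <- as.data.frame(plan, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "origin", "conservation", "duplicability")
                  %in% names(plan)))
    bad <- !is.na(plan$origin) &
      plan$conservation > pmax(0L, 5L - plan$origin)
    if (any(bad, na.rm = TRUE))
      stop("infeasible plan: conservation exceeds 5 - origin for gene(s) ",
           paste(plan$gene_id[which(bad)], collapse = ", "))
    if (any(is.na(plan$origin) & !is.na(plan$conservation)))
      stop("infeasible plan: conservation defined for untraceable gene")
  }

  species <- sim_species_table(config)
  sp_by_node <- split(species$species_id, species$node_label)
  focal <- config$focal_species

  rows <- vector("list", nrow(plan) * 3L)
  ri <- 0L
  add <- function(cluster, level, sp, gene) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(cluster_id = cluster, level = level,
                              species_id = sp, gene_id = gene,
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(plan))) {
    g <- plan$gene_id[i]
    o <- plan$origin[i]
    dup <- plan$duplicability[i]
    if (is.na(o)) {                      # untraceable: alone in its KOG
      add(paste0("K_", g), SIM_REFERENCE_LEVEL, focal, g)
      next
    }
    # widest cluster: self + one ortholog per planted-present node
    cl <- paste0("C_", g)
    lvl <- SIM_LEVELS[o + 1L]
    add(cl, lvl, focal, g)
    inter <- if (o < 5L) (o + 1L):5L else integer(0)
    lost <- if (length(inter))
      inter[sample.int(length(inter),
                       size = min(plan$conservation[i], length(inter)))]
    else integer(0)
    present_nodes <- c(o, setdiff(inter, lost))
    for (k in present_nodes) {
      if (k == 6L) next
      sp_k <- sample(sp_by_node[[LADDER_NODES[k + 1L]]], 1L)
      add(cl, lvl, sp_k, paste0(sp_k, "_", g))
    }
    if (o == 6L) {                       # group-specific non-self ortholog
      grp <- setdiff(sp_by_node[["group_specific"]], focal)
      sp_k <- sample(grp, 1L)
      add(cl, lvl, sp_k, paste0(sp_k, "_", g))
    }
    if (dup != "unassigned") {
      kog <- paste0("K_", g)
      add(kog, SIM_REFERENCE_LEVEL, focal, g)
      if (dup == "duplicated")
        add(kog, SIM_REFERENCE_LEVEL, focal, paste0(g, "_par"))
    }
  }
  clusters <- do.call(rbind, rows[seq_len(ri)])

  if (config$noise_drop_prob > 0) {
    self_row <- clusters$species_id == focal &
      clusters$gene_id %in% plan$gene_id
    drop <- !self_row & stats::runif(nrow(clusters)) < config$noise_drop_prob
    clusters <- clusters[!drop, , drop = FALSE]
  }

  f_species <- file.path(outdir, "species_nodes.tsv")
  f_clusters <- file.path(outdir, "clusters.tsv")
  f_genes <- file.path(outdir, "gene_list.txt")
  writeLines(plan$gene_id, f_genes)
  write_tsv_commented(species, f_species,
                      list(generator = "simulate_provenance_inputs",
                           seed = config$seed))
  write_tsv_commented(clusters, f_clusters,
                      list(generator = "simulate_provenance_inputs",
                           seed = config$seed,
                           focal_species = focal,
                           reference_level = SIM_REFERENCE_LEVEL))
  invisible(list(files = c(species_nodes = f_species, clusters = f_clusters,
                           gene_list = f_genes),
                 manifest = plan))
}

#' Generate interaction evidence with a planted age-degree coupling
#'
#' Grows a network over a random subset of the clean planted genes by
#' preferential attachment with multiplicative fitness: ancient genes attract
#' more edges with strength `age_degree_coupling`, and (human-like mode,
#' `hub_boost > 0`) recent duplicated genes receive an extra attachment boost
#' reproducing the recent-duplicated-hub pattern. Every edge is assigned
#' evidence records whose experiment sizes respect the planted scale classes
#' (single-gene studies stay strictly below the scale threshold); a few
#' orthology-inferred records and self-loops are planted to exercise the
#' integration filters.
#'
#' @param config a [sim_config()].
#' @param prov_manifest manifest from [simulate_provenance_inputs()].
#' @param outdir output directory.
#' @return invisible list: `files`, `manifest` (list with `edges`,
#'   `experiment_class`, `hub_intent`, `network_genes`, decoy counts).
#' @export
simulate_network_inputs <- function(config, prov_manifest, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 23L)

  clean <- prov_manifest[!is.na(prov_manifest$origin) &
                         prov_manifest$duplicability != "unassigned", ,
                         drop = FALSE]
  n_net <- max(3L, round(config$network_fraction * nrow(clean)))
  net <- clean[sample.int(nrow(clean), n_net), , drop = FALSE]
  net <- net[sample.int(nrow(net)), , drop = FALSE]   # random insertion order

  # between-stratum gradient: ancient genes attract more edges
  ancientness <- (6 - net$origin) / 6
  fitness <- exp(config$age_degree_coupling * ancientness)
  # within-stratum duplicability contrast (human-like mode): duplicated up /
  # singleton down at metazoan+vertebrate origins, reversed at LUCA+eukaryote
  # origins; mean-preserving per stratum so the age gradient is untouched
  recent_dup <- net$origin %in% c(3L, 4L) & net$duplicability == "duplicated"
  if (config$hub_boost > 0 || config$ancient_singleton_boost > 0) {
    contrast <- rep(1, nrow(net))
    is_dup <- net$duplicability == "duplicated"
    recent <- net$origin %in% c(3L, 4L)
    ancient <- net$origin %in% c(0L, 1L)
    q_rec <- sqrt(1 + config$hub_boost)
    q_anc <- sqrt(1 + config$ancient_singleton_boost)
    contrast[recent & is_dup] <- q_rec
    contrast[recent & !is_dup] <- 1 / q_rec
    contrast[ancient & !is_dup] <- q_anc
    contrast[ancient & is_dup] <- 1 / q_anc
    for (o in unique(net$origin)) {
      sel <- net$origin == o
      contrast[sel] <- contrast[sel] / mean(contrast[sel])
    }
    fitness <- fitness * contrast
  }

  # growth with preferential attachment; both the number of edges a node
  # initiates and its attractiveness as a target scale with its fitness
  lambda <- max(0, config$mean_degree / 2 - 1)
  m_i <- 1L + stats::rpois(n_net, lambda * fitness / mean(fitness))
  deg <- integer(n_net)
  ea <- integer(0); eb <- integer(0)
  for (t in 2:n_net) {
    k <- min(m_i[t], t - 1L)
    w <- (deg[seq_len(t - 1L)] + 1) * fitness[seq_len(t - 1L)]
    tgt <- sample.int(t - 1L, k, prob = w)
    ea <- c(ea, rep.int(t, k)); eb <- c(eb, tgt)
    deg[t] <- deg[t] + k
    deg[tgt] <- deg[tgt] + 1L
  }
  edges <- data.frame(gene_a = net$gene_id[ea], gene_b = net$gene_id[eb],
                      stringsAsFactors = FALSE)
  n_edges <- nrow(edges)

  # evidence assignment: planted scale classes
  is_sg <- stats::runif(n_edges) >= config$frac_high_throughput
  sources <- c("biogrid", "intact", "mint", "dip", "hprd")
  ev <- list()
  sg_edges <- which(is_sg)
  if (length(sg_edges)) {
    sizes <- pmin(config$sg_exp_max_edges, config$scale_threshold - 1L)
    n_sg_exp <- ceiling(length(sg_edges) / sizes)
    exp_of <- rep(seq_len(n_sg_exp), each = sizes)[seq_along(sg_edges)]
    ev[[length(ev) + 1L]] <- data.frame(
      edge = sg_edges,
      experiment_id = sprintf("PMID_SG%04d", exp_of),
      source_db = sample(sources, length(sg_edges), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ht_ids <- sprintf("PMID_HT%02d", seq_len(config$n_ht_experiments))
  ht_edges <- which(!is_sg)
  extra_ht <- sg_edges[stats::runif(length(sg_edges)) < config$p_sg_extra_ht]
  ht_all <- c(ht_edges, extra_ht)
  if (length(ht_all)) {
    first <- sample(ht_ids, length(ht_all), replace = TRUE)
    ev[[length(ev) + 1L]] <- data.frame(
      edge = ht_all, experiment_id = first,
      source_db = sample(sources, length(ht_all), replace = TRUE),
      stringsAsFactors = FALSE)
    second <- ht_edges[stats::runif(length(ht_edges)) < config$p_second_ht]
    if (length(second) && config$n_ht_experiments >= 2L) {
      f <- first[match(second, ht_all)]
      s <- vapply(f, function(x) sample(setdiff(ht_ids, x), 1L), character(1))
      ev[[length(ev) + 1L]] <- data.frame(
        edge = second, experiment_id = s,
        source_db = sample(sources, length(second), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev)

  # planted experiment classes must be consistent with the < threshold rule:
  # merge any underfilled intended-HT screening into the fullest one
  cnt <- table(ev$experiment_id[!duplicated(paste(ev$edge, ev$experiment_id))])
  ht_cnt <- cnt[names(cnt) %in% ht_ids]
  if (length(ht_cnt) > 1L) {
    low <- names(ht_cnt)[ht_cnt < config$scale_threshold]
    if (length(low) && length(low) < length(ht_cnt)) {
      big <- names(ht_cnt)[which.max(ht_cnt)]
      ev$experiment_id[ev$experiment_id %in% low] <- big
      ev <- ev[!duplicated(paste(ev$edge, ev$experiment_id)), , drop = FALSE]
    }
  }
  cnt <- table(ev$experiment_id[!duplicated(paste(ev$edge, ev$experiment_id))])
  experiment_class <- ifelse(cnt < config$scale_threshold,
                             "single_gene", "high_throughput")

  records <- data.frame(gene_a = edges$gene_a[ev$edge],
                        gene_b = edges$gene_b[ev$edge],
                        source_db = ev$source_db,
                        experiment_id = ev$experiment_id,
                        provenance_class = "direct",
                        stringsAsFactors = FALSE)

  # planted dirty records: dropped by integrate_evidence()
  n_decoy <- round(config$orthology_decoy_rate * n_edges)
  if (n_decoy > 0L) {
    ia <- sample.int(n_net, n_decoy, replace = TRUE)
    ib <- sample.int(n_net, n_decoy, replace = TRUE)
    records <- rbind(records, data.frame(
      gene_a = net$gene_id[ia], gene_b = net$gene_id[ib],
      source_db = "orthology_transfer", experiment_id = "PMID_ORTH",
      provenance_class = "orthology_inferred", stringsAsFactors = FALSE))
  }
  n_self <- round(config$self_loop_rate * n_edges)
  if (n_self > 0L) {
    ii <- sample.int(n_net, n_self, replace = TRUE)
    records <- rbind(records, data.frame(
      gene_a = net$gene_id[ii], gene_b = net$gene_id[ii],
      source_db = sample(sources, n_self, replace = TRUE),
      experiment_id = "PMID_SELF", provenance_class = "direct",
      stringsAsFactors = FALSE))
  }
  records <- records[sample.int(nrow(records)), , drop = FALSE]

  f_int <- file.path(outdir, "interactions.tsv")
  write_tsv_commented(records, f_int,
                      list(generator = "simulate_network_inputs",
                           seed = config$seed,
                           age_degree_coupling = config$age_degree_coupling,
                           hub_boost = config$hub_boost))
  manifest <- list(edges = edges,
                   experiment_class = as.list(experiment_class),
                   hub_intent = net$gene_id[recent_dup],
                   network_genes = sort(net$gene_id),
                   n_orthology_decoys = n_decoy, n_self_loops = n_self)
  invisible(list(files = c(interactions = f_int), manifest = manifest))
}

#' Generate GO, expression, and gene-list inputs with planted skews
#'
#' Builds a GO tree of the configured depth and branching (plus a sprinkling
#' of second parents, making it a proper DAG without changing shortest-path
#' levels), assigns level-5/6 terms to functional categories, annotates genes
#' with a planted category skew between the recent-duplicated-hub-intent pool
#' (category `cat01`) and the ancient-singleton pool (category `cat02`), and
#' emits ohnolog / miRNA-target / tissue-selective gene lists enriched among
#' recent duplicated hub-intent genes by `enrichment_factor`, together with
#' binary expression-call matrices realising the tissue-selective set.
#'
#' @param config a [sim_config()].
#' @param prov_manifest manifest from [simulate_provenance_inputs()].
#' @param net_manifest manifest from [simulate_network_inputs()].
#' @param outdir output directory.
#' @return invisible list: `files`, `manifest` (planted pools, category skew,
#'   lists, tissue-selective set).
#' @export
simulate_annotation_inputs <- function(config, prov_manifest, net_manifest,
                                       outdir) {
  stopifnot(inherits(config, "sim_config"))
  if (config$go_depth < 6L) stop("go_depth < 6: levels 5-6 would be empty")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 37L)

  # GO tree: ids assigned breadth-first, root level 1
  b <- config$go_branching
  n_per_level <- b^(0:(config$go_depth - 1L))
  total <- sum(n_per_level)
  ids <- sprintf("GO:%07d", seq_len(total))
  level_of <- rep(seq_len(config$go_depth), n_per_level)
  links <- list()
  offset <- cumsum(c(0L, n_per_level))
  for (L in 2:config$go_depth) {
    child_idx <- offset[L] + seq_len(n_per_level[L])
    parent_idx <- offset[L - 1L] + ((seq_len(n_per_level[L]) - 1L) %/% b) + 1L
    links[[L]] <- data.frame(child_id = ids[child_idx],
                             parent_id = ids[parent_idx],
                             stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)
  # extra parents (same level - 1) keep shortest-path levels intact
  deep <- which(level_of >= 3L)
  extra <- deep[stats::runif(length(deep)) < 0.05]
  if (length(extra)) {
    ep <- vapply(extra, function(i) {
      cand <- which(level_of == level_of[i] - 1L)
      sample(cand, 1L)
    }, integer(1))
    links <- rbind(links, data.frame(child_id = ids[extra],
                                     parent_id = ids[ep],
                                     stringsAsFactors = FALSE))
    links <- links[!duplicated(paste(links$child_id, links$parent_id)), ,
                   drop = FALSE]
  }

  # categories are subtree-coherent (as real functional categories are):
  # level-5 terms draw a category, their level-6 children inherit it, so
  # true-path propagation never mixes categories between the two levels
  idx5 <- which(level_of == 5L)
  idx6 <- which(level_of == 6L)
  if (length(idx5) < config$n_categories)
    stop("too few level-5 terms to cover every category")
  cat5 <- sample.int(config$n_categories, length(idx5), replace = TRUE)
  cat5[sample.int(length(idx5), config$n_categories)] <-
    seq_len(config$n_categories)   # every category has >= 1 level-5 subtree
  parent_of6 <- offset[5L] + ((seq_len(n_per_level[6L]) - 1L) %/% b) + 1L
  cat6 <- cat5[match(parent_of6, idx5)]
  categories <- data.frame(
    term_id = ids[c(idx5, idx6)],
    category = sprintf("cat%02d", c(cat5, cat6)),
    stringsAsFactors = FALSE)
  terms_by_cat <- split(categories$term_id, categories$category)

  # gene pools
  genes <- prov_manifest$gene_id
  pool_recent <- net_manifest$hub_intent
  pool_ancient <- prov_manifest$gene_id[
    !is.na(prov_manifest$origin) & prov_manifest$origin %in% c(0L, 1L) &
      prov_manifest$duplicability == "singleton"]
  cats <- sprintf("cat%02d", seq_len(config$n_categories))

  ann_rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    k <- 1L + stats::rpois(1L, config$annots_per_gene - 1)
    w <- rep(1, config$n_categories)
    if (g %in% pool_recent) w[1L] <- config$go_skew
    if (g %in% pool_ancient) w[2L] <- config$go_skew
    cat_i <- sample(cats, k, replace = TRUE, prob = w)
    term_i <- vapply(cat_i, function(cc) sample(terms_by_cat[[cc]], 1L),
                     character(1))
    ann_rows[[i]] <- data.frame(gene_id = g, term_id = unique(term_i),
                                stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann_rows)

  # dosage-regulation gene lists
  boosted <- genes %in% pool_recent
  rate <- function(base) pmin(0.95, ifelse(boosted,
                                           base * config$enrichment_factor,
                                           base))
  is_dup <- prov_manifest$duplicability == "duplicated"
  p_ohno <- rate(config$base_rates[["ohnolog"]])
  ohnolog <- genes[is_dup & stats::runif(length(genes)) < p_ohno]
  singles <- genes[prov_manifest$duplicability == "singleton"]
  n_fp <- round(config$ohnolog_fp_rate * length(ohnolog))
  ohno_fp <- if (n_fp > 0L && length(singles))
    sample(singles, min(n_fp, length(singles))) else character(0)
  ohnolog_list <- sort(c(ohnolog, ohno_fp))

  mirna <- genes[stats::runif(length(genes)) <
                   rate(config$base_rates[["mirna_target"]])]
  tissue_sel <- genes[stats::runif(length(genes)) <
                        rate(config$base_rates[["tissue_selective"]])]

  # expression calls realising the planted tissue-selective set
  covered <- genes[stats::runif(length(genes)) < config$expression_coverage]
  tissue_sel <- intersect(tissue_sel, covered)
  expr_files <- character(length(config$tissue_counts))
  for (d in seq_along(config$tissue_counts)) {
    T <- config$tissue_counts[d]
    max_sel <- ceiling(config$tissue_frac * T) - 1L
    min_non <- ceiling(config$tissue_frac * T)
    if (min_non / T < config$tissue_frac) min_non <- min_non + 1L
    mat <- matrix(0L, nrow = length(covered), ncol = T)
    for (i in seq_along(covered)) {
      cnt <- if (covered[i] %in% tissue_sel) sample.int(max_sel, 1L)
             else sample(min_non:T, 1L)
      mat[i, sample.int(T, cnt)] <- 1L
    }
    df <- data.frame(gene_id = covered, mat, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", sprintf("tissue_%02d", seq_len(T)))
    expr_files[d] <- file.path(outdir, sprintf("expression_calls_%d.tsv", d))
    write_tsv_commented(df, expr_files[d],
                        list(generator = "simulate_annotation_inputs",
                             seed = config$seed, dataset = d, tissues = T))
  }

  f_dag <- file.path(outdir, "go_dag.tsv")
  f_ann <- file.path(outdir, "go_annotations.tsv")
  f_cat <- file.path(outdir, "categories.tsv")
  f_ohno <- file.path(outdir, "ohnologs.txt")
  f_mirna <- file.path(outdir, "mirna_targets.txt")
  write_tsv_commented(links, f_dag, list(generator = "simulate_annotation_inputs",
                                         seed = config$seed))
  write_tsv_commented(annotations, f_ann, list(seed = config$seed))
  write_tsv_commented(categories, f_cat, list(seed = config$seed))
  writeLines(ohnolog_list, f_ohno)
  writeLines(sort(mirna), f_mirna)

  manifest <- list(skew_category_recent = "cat01",
                   skew_category_ancient = "cat02",
                   pool_recent = sort(pool_recent),
                   pool_ancient = sort(pool_ancient),
                   ohnolog_list = ohnolog_list,
                   ohnolog_false_positives = sort(ohno_fp),
                   mirna_targets = sort(mirna),
                   tissue_selective = sort(tissue_sel),
                   expression_genes = sort(covered))
  invisible(list(files = c(go_dag = f_dag, go_annotations = f_ann,
                           categories = f_cat, ohnologs = f_ohno,
                           mirna_targets = f_mirna,
                           expression = expr_files),
                 manifest = manifest))
}

#' Generate every pipeline input and write a manifest
#'
#' Runs the three generators in sequence and writes `manifest.json` with the
#' planted ground truth. Byte-identical outputs for identical config + seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @return invisible list with `files` and the three manifests
#'   (`provenance`, `network`, `annotation`).
#' @export
simulate_all <- function(config, outdir) {
  prov <- simulate_provenance_inputs(config, outdir)
  net <- simulate_network_inputs(config, prov$manifest, outdir)
  ann <- simulate_annotation_inputs(config, prov$manifest, net$manifest,
                                    outdir)
  manifest <- list(
    config = unclass(config),
    provenance = prov$manifest,
    network = list(hub_intent = net$manifest$hub_intent,
                   network_genes = net$manifest$network_genes,
                   experiment_class = net$manifest$experiment_class,
                   n_orthology_decoys = net$manifest$n_orthology_decoys,
                   n_self_loops = net$manifest$n_self_loops),
    annotation = ann$manifest)
  f_manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(list(files = c(prov$files, net$files, ann$files,
                           manifest = f_manifest),
                 provenance = prov$manifest,
                 network = net$manifest,
                 annotation = ann$manifest))
}
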