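#' Assemble a validated run configuration
#'
#' @param species_nodes,clusters,interactions paths to the core input tables.
#' @param gene_list optional path to the analysed gene list (one id per
#'   line); defaults to every focal-species gene in the cluster table.
#' @param go_dag,go_annotations,categories,expression,ohnologs,mirna_targets
#'   optional annotation-stage inputs (`expression` may be a vector of
#'   dataset paths); the enrichment/dosage stages are skipped when absent.
#' @param subset optional gene-list path for the subset origin profile.
#' @param focal_species focal species identifier.
#' @param reference_level duplicability reference level (default `"KOG"`).
#' @param outdir output directory.
#' @param hub_fraction,reps,subset_size,seed,alpha,floor,gold,xmin,
#'   tissue_frac,scale_threshold analysis parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(species_nodes, clusters, interactions,
                       gene_list = NULL,
                       go_dag = NULL, go_annotations = NULL,
                       categories = NULL, expression = NULL,
                       ohnologs = NULL, mirna_targets = NULL, subset = NULL,
                       focal_species, reference_level = "KOG",
                       outdir = ".",
                       hub_fraction = 0.25, reps = 10000L,
                       subset_size = 500L, seed = 1L, alpha = 0.05,
                       floor = 1e-3, gold = FALSE, xmin = 10L,
                       tissue_frac = 0.25, scale_threshold = 100L) {
  cfg <- as.list(environment())
  paths <- c(species_nodes, clusters, interactions, gene_list, go_dag,
             go_annotations, categories, expression, ohnologs, mirna_targets,
             subset)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  stopifnot(hub_fraction > 0, hub_fraction < 1, reps >= 1,
            alpha > 0, alpha < 1, floor > 0, tissue_frac > 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file holds the same fields as [run_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_fields <- c("species_nodes", "clusters", "interactions", "gene_list",
                   "go_dag",
                   "go_annotations", "categories", "expression", "ohnologs",
                   "mirna_targets", "subset")
  for (f in intersect(path_fields, names(y))) {
    p <- y[[f]]
    abs <- file.path(base, p)
    y[[f]] <- ifelse(file.exists(p), p, abs)
  }
  do.call(run_config, y)
}

#' Run the full provenance-versus-network analysis
#'
#' Executes, in order: provenance annotation; evidence integration, scale
#' classification, optional gold filtering; node metrics, hub calls, power-law
#' tail fit; origin and conservation stratum comparisons (Wilcoxon +
#' randomization z) with heatmaps; age-matched duplicability comparison; and,
#' when annotation inputs are configured, GO enrichment, dosage-regulation
#' overlap, and the subset origin profile. All stochastic stages derive their
#' seeds from the single configured seed, so a rerun with the same
#' configuration reproduces the statistics outputs byte for byte.
#'
#' @param config a [run_config()] (or a YAML path).
#' @return invisible list of the in-memory results; tables are written under
#'   `config$outdir` with parameter header comments.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  log_lines <- c(sprintf("evonet %s | R %s", "0.1.0",
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  params <- config[c("focal_species", "reference_level", "hub_fraction",
                     "reps", "subset_size", "seed", "alpha", "floor",
                     "gold", "xmin", "scale_threshold")]

  # -- provenance ------------------------------------------------------------
  res <- list()
  stage("provenance", {
    ladder <- build_ladder(read_species_nodes(config$species_nodes),
                           config$focal_species)
    clusters <- read_clusters(config$clusters)
    # analysed gene list: explicit file when given, otherwise every
    # focal-species gene occurring in the cluster table
    focal_genes <- if (!is.null(config$gene_list))
      read_gene_list(config$gene_list)
    else sort(unique(
      clusters$records$gene_id[clusters$records$species_id ==
                               config$focal_species]))
    prov <- annotate_genes(focal_genes, clusters, ladder,
                           config$reference_level, quiet = TRUE)
    excl <- attr(prov, "exclusions")
    log_lines <- c(log_lines,
                    sprintf("provenance: %d genes, %d untraceable, %d unassigned",
                            nrow(prov), excl[["untraceable"]],
                            excl[["unassigned"]]))
    write_provenance(prov, out("provenance.tsv"), params)
    res$ladder <- ladder
    res$provenance <- prov
  })

  # -- network ---------------------------------------------------------------
  stage("network", {
    net <- integrate_evidence(read_interactions(config$interactions))
    net <- classify_experiment_scale(net, config$scale_threshold)
    if (isTRUE(config$gold)) net <- gold_filter(net)
    metrics <- compute_metrics(net)
    hubs <- call_hubs(metrics, config$hub_fraction)
    fit <- tryCatch(fit_power_law(metrics, config$xmin),
                    error = function(e) NULL)
    log_lines <- c(log_lines,
                    sprintf("network: %d proteins, %d interactions, hub threshold %d (%d hubs)%s",
                            nrow(metrics), nrow(net$edges), hubs$threshold,
                            length(hubs$hubs),
                            if (isTRUE(config$gold)) " [gold set]" else ""),
                    if (!is.null(fit))
                      sprintf("power-law tail: gamma %.2f +/- %.2f, KS p %.3f",
                              fit$gamma, fit$gamma_ci, fit$ks_p)
                    else "power-law tail: not fitted (thin tail)")
    write_tsv_commented(summarize_network(net, metrics),
                        out("network_summary.tsv"), params)
    write_node_metrics(metrics, out("node_metrics.tsv"), hubs, params)
    res$interactome <- net
    res$metrics <- metrics
    res$hubs <- hubs
    res$power_law <- fit
  })

  # -- stratified comparisons ------------------------------------------------
  stage("compare", {
    comp <- list()
    heat <- list()
    for (key in c("origin", "conservation")) {
      cc <- compare_strata(res$provenance, res$metrics, key,
                           randomization = TRUE,
                           subset_size = config$subset_size,
                           reps = config$reps,
                           seed = config$seed + match(key, c("origin",
                                                             "conservation")))
      cc$key <- key
      comp[[key]] <- cc
      hp <- build_heatmap(cc, config$alpha, config$floor, use = "p")
      hp$key <- key; hp$source <- "wilcoxon"
      hz <- build_heatmap(cc, config$alpha, config$floor, use = "z")
      hz$key <- key; hz$source <- "randomization"
      heat[[key]] <- rbind(hp, hz)
    }
    dupcmp <- age_matched_duplicability(res$provenance, res$metrics)
    if (!is.null(dupcmp)) {
      hd <- build_heatmap(dupcmp, config$alpha, config$floor, use = "p")
      hd$key <- "duplicability"; hd$source <- "wilcoxon"
      heat$duplicability <- hd
    }
    comparisons <- do.call(rbind, c(comp, list(make.row.names = FALSE)))
    write_tsv_commented(comparisons, out("comparisons.tsv"), params)
    if (!is.null(dupcmp))
      write_tsv_commented(dupcmp, out("duplicability_comparisons.tsv"), params)
    write_tsv_commented(do.call(rbind, c(heat, list(make.row.names = FALSE))),
                        out("heatmap.tsv"), params)
    res$comparisons <- comparisons
    res$duplicability <- dupcmp
    res$heatmap <- heat
  })

  # -- annotation stages (optional) -----------------------------------------
  if (!is.null(config$go_dag) && !is.null(config$go_annotations)) {
    stage("enrich", {
      dag <- read_go_dag(config$go_dag)
      ann <- read_go_annotations(config$go_annotations)
      cats <- if (!is.null(config$categories))
        utils::read.delim(config$categories, comment.char = "#",
                          stringsAsFactors = FALSE) else NULL
      prov <- res$provenance
      clean <- prov[prov$flags == "", , drop = FALSE]
      hubs <- res$hubs$hubs
      ancient <- clean$gene_id[clean$origin_index %in% c(0L, 1L)]
      recent <- clean$gene_id[clean$origin_index %in% c(3L, 4L)]
      sing <- clean$gene_id[clean$duplicability == "singleton"]
      dup <- clean$gene_id[clean$duplicability == "duplicated"]
      # three comparisons; set A is always the recent/duplicated side
      comparisons <- list(
        hubs = list(a = intersect(hubs, intersect(recent, dup)),
                    b = intersect(hubs, intersect(ancient, sing))),
        origin = list(a = recent, b = ancient),
        duplicability = list(a = dup, b = sing))
      enr <- list()
      for (nm in names(comparisons)) {
        cmp <- comparisons[[nm]]
        if (length(cmp$a) == 0L || length(cmp$b) == 0L) {
          log_lines <- c(log_lines,
                         sprintf("enrichment [%s]: skipped (empty set)", nm))
          next
        }
        e <- fisher_enrichment(cmp$a, cmp$b, ann, dag, categories = cats)
        e$comparison <- nm
        enr[[nm]] <- e
        log_lines <- c(log_lines,
                       sprintf("enrichment [%s]: %d terms tested, %d with q < alpha",
                               nm, nrow(e), sum(e$bh_q < config$alpha)))
      }
      if (length(enr)) {
        enr <- do.call(rbind, c(enr, list(make.row.names = FALSE)))
        write_tsv_commented(enr, out("enrichment.tsv"), params)
        res$enrichment <- enr
      }
    })
  }

  if (!is.null(config$ohnologs) || !is.null(config$expression) ||
      !is.null(config$mirna_targets)) {
    stage("dosage", {
      prov <- res$provenance
      ohno <- if (!is.null(config$ohnologs)) {
        rec <- ohnolog_reconcile(read_gene_list(config$ohnologs), prov)
        log_lines <- c(log_lines,
                        sprintf("ohnologs: %d kept, %d singleton false positives discarded, %d unmatched",
                                length(rec$kept), rec$n_discarded,
                                rec$n_unmatched))
        rec$kept
      } else character(0)
      mirna <- if (!is.null(config$mirna_targets))
        read_gene_list(config$mirna_targets) else character(0)
      tsel <- if (!is.null(config$expression))
        tissue_selective(lapply(config$expression, read_expression_calls),
                         config$tissue_frac) else character(0)
      genes <- prov$gene_id
      da <- data.frame(gene_id = genes,
                       ohnolog = genes %in% ohno,
                       mirna_target = genes %in% mirna,
                       tissue_selective = genes %in% tsel,
                       stringsAsFactors = FALSE)
      dv <- dosage_overlap(res$hubs$hubs, prov, da)
      write_tsv_commented(dv$fractions, out("dosage_overlap.tsv"), params)
      if (!is.null(dv$recent_vs_older))
        write_tsv_commented(dv$recent_vs_older,
                            out("dosage_recent_vs_older.tsv"), params)
      res$dosage <- dv
    })
  }

  if (!is.null(config$subset)) {
    stage("origin_profile", {
      subset <- read_gene_list(config$subset)
      prof <- subset_origin_profile(intersect(subset, res$provenance$gene_id),
                                    res$provenance$gene_id, res$provenance)
      write_tsv_commented(prof, out("origin_profile.tsv"), params)
      res$origin_profile <- prof
    })
  }

  writeLines(log_lines, out("run_log.txt"))
  invisible(res)
}
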