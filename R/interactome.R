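#' Integrate interaction evidence into a simple undirected graph
#'
#' Merges one or more evidence tables (columns `gene_a`, `gene_b`,
#' `source_db`, `experiment_id`, `provenance_class`) into a non-redundant
#' simple graph. Orthology-inferred records are discarded (only primary
#' evidence is kept), self-interactions are dropped, duplicate
#' (pair, experiment) records are collapsed, and parallel evidence from
#' different experiments is merged onto a single edge.
#'
#' @param evidence_tables a data.frame or list of data.frames.
#' @return object of class `interactome`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`, lexicographically ordered pairs), `evidence`
#'   (data.frame `edge`, `gene_a`, `gene_b`, `source_db`, `experiment_id`,
#'   `scale_class`), and `log` (dropped-record counts).
#' @export
integrate_evidence <- function(evidence_tables) {
  if (is.data.frame(evidence_tables)) evidence_tables <- list(evidence_tables)
  if (length(evidence_tables) == 0L) stop("no evidence tables supplied")
  req <- c("gene_a", "gene_b", "source_db", "experiment_id", "provenance_class")
  ev <- do.call(rbind, lapply(evidence_tables, function(t) {
    stopifnot(is.data.frame(t), all(req %in% names(t)))
    t <- t[req]
    for (cl in req) t[[cl]] <- as.character(t[[cl]])
    t
  }))
  if (nrow(ev) == 0L) stop("evidence tables are empty")

  n_orth <- sum(ev$provenance_class == "orthology_inferred")
  ev <- ev[ev$provenance_class != "orthology_inferred", , drop = FALSE]
  n_self <- sum(ev$gene_a == ev$gene_b)
  ev <- ev[ev$gene_a != ev$gene_b, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no primary non-self evidence records remain")

  a <- pmin(ev$gene_a, ev$gene_b)
  b <- pmax(ev$gene_a, ev$gene_b)
  ev$gene_a <- a
  ev$gene_b <- b
  ev$edge <- paste(a, b, sep = "\r")

  dup <- duplicated(paste(ev$edge, ev$experiment_id, sep = "\r"))
  n_dup <- sum(dup)
  ev <- ev[!dup, , drop = FALSE]

  edges <- unique(ev[c("edge", "gene_a", "gene_b")])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  ev <- ev[c("edge", "gene_a", "gene_b", "source_db", "experiment_id")]
  ev$scale_class <- NA_character_
  rownames(ev) <- NULL

  structure(
    list(edges = edges, evidence = ev,
         log = c(orthology_inferred = n_orth, self_loops = n_self,
                 duplicate_records = n_dup)),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("Interactome: ", length(interactome_nodes(x)), " proteins, ",
      nrow(x$edges), " interactions, ", nrow(x$evidence),
      " evidence records\n", sep = "")
  if (!all(is.na(x$evidence$scale_class)))
    cat("  evidence scale classes assigned (threshold ",
        attr(x, "scale_threshold"), ")\n", sep = "")
  invisible(x)
}

#' Node (protein) identifiers of an interactome
#' @param interactome an [integrate_evidence()] object.
#' @return character vector of gene identifiers with >= 1 interaction.
#' @export
interactome_nodes <- function(interactome) {
  sort(unique(c(interactome$edges$gene_a, interactome$edges$gene_b)))
}

#' Classify experiments as single-gene or high-throughput
#'
#' An experiment (publication-level identifier) is a single-gene study when it
#' supports strictly fewer than `threshold` distinct interactions in the
#' integrated corpus; otherwise it is a high-throughput screening. Classes are
#' annotated back onto the evidence records.
#'
#' @param interactome an [integrate_evidence()] object.
#' @param threshold strict upper bound for single-gene studies (default 100).
#' @return the interactome with `evidence$scale_class` filled in and an
#'   `experiment_scale` element (named character map experiment -> class).
#' @export
classify_experiment_scale <- function(interactome, threshold = 100L) {
  ev <- interactome$evidence
  per_exp <- vapply(split(ev$edge, ev$experiment_id),
                    function(e) length(unique(e)), integer(1))
  scale <- ifelse(per_exp < threshold, "single_gene", "high_throughput")
  interactome$evidence$scale_class <- unname(scale[ev$experiment_id])
  interactome$experiment_scale <- scale
  attr(interactome, "scale_threshold") <- threshold
  interactome
}

#' Filter an interactome down to its gold set
#'
#' Keeps an interaction only when it is supported by at least one single-gene
#' experiment or by more than one (>= 2 distinct) high-throughput screenings.
#' Proteins left without interactions are removed. The result is a subgraph of
#' the input, and the filter is idempotent.
#'
#' @param interactome an interactome with scale classes assigned
#'   ([classify_experiment_scale()]).
#' @return a filtered `interactome`.
#' @export
gold_filter <- function(interactome) {
  ev <- interactome$evidence
  if (all(is.na(ev$scale_class)))
    stop("call classify_experiment_scale() before gold_filter()")
  keep_edge <- vapply(split(seq_len(nrow(ev)), ev$edge), function(i) {
    cls <- ev$scale_class[i]
    any(cls == "single_gene") ||
      length(unique(ev$experiment_id[i][cls == "high_throughput"])) >= 2L
  }, logical(1))
  kept <- names(keep_edge)[keep_edge]
  interactome$edges <- interactome$edges[interactome$edges$edge %in% kept, ,
                                         drop = FALSE]
  interactome$evidence <- ev[ev$edge %in% kept, , drop = FALSE]
  rownames(interactome$edges) <- rownames(interactome$evidence) <- NULL
  attr(interactome, "gold") <- TRUE
  interactome
}

as_igraph <- function(interactome) {
  igraph::graph_from_data_frame(
    interactome$edges[c("gene_a", "gene_b")], directed = FALSE,
    vertices = interactome_nodes(interactome))
}

#' Degree and betweenness of every protein
#'
#' Degree is the number of distinct interaction partners. Betweenness is the
#' unnormalized shortest-path count with fractional splitting over unordered
#' pairs, computed within connected components (pairs in different components
#' have no connecting path and contribute nothing).
#'
#' @param interactome an [integrate_evidence()] object.
#' @return data.frame `gene_id`, `degree`, `betweenness`.
#' @export
compute_metrics <- function(interactome) {
  g <- as_igraph(interactome)
  data.frame(gene_id = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                      normalized = FALSE)),
             stringsAsFactors = FALSE)
}

#' Call hubs as the top fraction of the degree distribution
#'
#' The degree threshold is the smallest integer `d` such that the number of
#' proteins with degree strictly greater than `d` is at most
#' `fraction * n`; hubs are the proteins above the threshold. With heavy
#' ties the realized fraction can fall below the nominal one (all tied
#' proteins are excluded); if no threshold separates a non-empty top set the
#' hub set is empty and a warning is raised.
#'
#' @param metrics output of [compute_metrics()].
#' @param fraction nominal hub fraction in (0,1); default 0.25 (top 25% most
#'   connected).
#' @return list with `threshold` (integer degree), `hubs` (character vector),
#'   `realized_fraction`.
#' @export
call_hubs <- function(metrics, fraction = 0.25) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0,1)")
  n <- nrow(metrics)
  if (n == 0L) stop("empty network")
  deg <- metrics$degree
  for (d in 0:max(deg)) {
    if (sum(deg > d) <= fraction * n) break
  }
  hubs <- metrics$gene_id[deg > d]
  if (length(hubs) == 0L)
    warning("no degree threshold separates a non-empty top ",
            fraction * 100, "%: hub set is empty")
  list(threshold = d, hubs = hubs, realized_fraction = length(hubs) / n)
}

#' Fit a power law to the degree-distribution tail
#'
#' Interpolates a line on the log-log plot of the empirical degree
#' frequencies, restricted to degrees strictly greater than `xmin`, and tests
#' the goodness of fit with a Kolmogorov-Smirnov comparison of the empirical
#' tail against the fitted discrete law (null hypothesis: the power law
#' fits). Frequencies are logarithmically binned before the least-squares
#' fit, points are weighted by their bin counts (approximate Poisson
#' weighting), and bins with fewer than 3 tail observations are excluded:
#' raw per-degree frequencies put a flat cloud of count-1 points at the far
#' tail that badly biases an unweighted line.
#'
#' @param metrics output of [compute_metrics()].
#' @param xmin lower degree cutoff (default 10; fit uses degrees > xmin).
#' @param nbins number of logarithmic bins over the tail.
#' @return list of class `power_law_fit`: `gamma`, `gamma_ci` (1.96 x standard
#'   error half-width), `ks_p`, `xmin`, `n_tail`.
#' @export
fit_power_law <- function(metrics, xmin = 10L, nbins = 12L) {
  deg <- metrics$degree
  tail_deg <- deg[deg > xmin]
  ks <- sort(unique(tail_deg))
  if (length(ks) < 5L)
    stop("need at least 5 distinct degree values above xmin = ", xmin)

  edges <- exp(seq(log(xmin + 0.5), log(max(tail_deg) + 0.5),
                   length.out = nbins + 1L))
  cnt <- graphics::hist(tail_deg, breaks = edges, plot = FALSE)$counts
  dens <- cnt / diff(edges) / length(deg)
  mid <- sqrt(edges[-1L] * edges[-length(edges)])
  keep <- cnt >= 3L
  if (sum(keep) < 3L) keep <- cnt >= 1L
  fit <- stats::lm(log(dens[keep]) ~ log(mid[keep]), weights = cnt[keep])
  gamma <- -unname(stats::coef(fit)[2L])
  se <- summary(fit)$coefficients[2L, 2L]

  # empirical tail vs fitted discrete power law, asymptotic Kolmogorov p
  pk <- ks^(-gamma)
  pk <- pk / sum(pk)
  cdf_fit <- cumsum(pk)
  ecdf_tail <- cumsum(as.numeric(table(factor(tail_deg, levels = ks)))) /
    length(tail_deg)
  D <- max(abs(ecdf_tail - cdf_fit))
  ks_p <- kolmogorov_p(D, length(tail_deg))

  structure(list(gamma = gamma, gamma_ci = 1.96 * se, ks_p = ks_p,
                 xmin = xmin, n_tail = length(tail_deg)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law tail fit (degree > %d, n = %d): gamma = %.2f +/- %.2f, KS p = %.3f\n",
              x$xmin, x$n_tail, x$gamma, x$gamma_ci, x$ks_p))
  invisible(x)
}

# asymptotic Kolmogorov distribution: P(sqrt(n) D > x) via the alternating series
kolmogorov_p <- function(D, n) {
  x <- sqrt(n) * D
  if (x < 1e-8) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))
  min(max(p, 0), 1)
}

#' Summarize an interactome in the standard layout
#'
#' Reports protein and interaction counts, the split of interactions by
#' evidence class (an interaction counts as single-gene when at least one of
#' its evidence records comes from a single-gene study, high-throughput
#' otherwise), and the median and mean of degree and betweenness.
#'
#' @param interactome an interactome with scale classes assigned.
#' @param metrics output of [compute_metrics()]; computed if missing.
#' @return data.frame with columns `feature`, `value`.
#' @export
summarize_network <- function(interactome, metrics = NULL) {
  if (is.null(metrics)) metrics <- compute_metrics(interactome)
  ev <- interactome$evidence
  n_edges <- nrow(interactome$edges)
  sg_edges <- if (all(is.na(ev$scale_class))) NA_integer_ else {
    length(unique(ev$edge[ev$scale_class == "single_gene"]))
  }
  ht_edges <- n_edges - sg_edges
  data.frame(
    feature = c("proteins", "interactions",
                "high_throughput_interactions", "high_throughput_pct",
                "single_gene_interactions", "single_gene_pct",
                "degree_median", "degree_mean",
                "betweenness_median", "betweenness_mean"),
    value = c(nrow(metrics), n_edges,
              ht_edges, round(100 * ht_edges / n_edges, 1),
              sg_edges, round(100 * sg_edges / n_edges, 1),
              stats::median(metrics$degree), mean(metrics$degree),
              stats::median(metrics$betweenness), mean(metrics$betweenness)),
    stringsAsFactors = FALSE
  )
}

#' Read an interaction evidence table
#'
#' Tab-separated columns `gene_a`, `gene_b`, `source_db`, `experiment_id`,
#' `provenance_class`; one record per evidence item; `#` comments allowed.
#'
#' @param path file path.
#' @return data.frame of evidence records.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("gene_a", "gene_b", "source_db", "experiment_id", "provenance_class")
  if (!all(req %in% names(df)))
    stop("interactions file must have columns ", paste(req, collapse = ", "))
  df
}

#' Write node metrics (with hub calls) to TSV
#'
#' @param metrics output of [compute_metrics()].
#' @param hubs optional output of [call_hubs()].
#' @param path output file path.
#' @param params optional named list echoed as `#` header comments.
#' @export
write_node_metrics <- function(metrics, path, hubs = NULL, params = NULL) {
  out <- metrics
  if (!is.null(hubs)) out$is_hub <- out$gene_id %in% hubs$hubs
  write_tsv_commented(out, path, params)
}
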