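#' Presence profile of a gene across the seven ladder nodes
#'
#' A gene is present at node *k* if any cluster containing the gene has a
#' member species (other than the focal gene itself) assigned to node *k*.
#' Presence at the group-specific node (index 6) is additionally granted by
#' self-membership, so `present[7]` is always `TRUE`; whether a *non-self*
#' group-specific ortholog or paralog exists is kept in the
#' `nonself_group` attribute (it decides group-specific origin).
#'
#' Presence is computed over the union of all clusters containing the gene:
#' cluster nesting makes this equivalent to per-level checks while tolerating
#' missing levels.
#'
#' @param gene_id focal-species gene identifier.
#' @param clusters an [ortholog_clusters()] object.
#' @param ladder a [build_ladder()] object.
#' @return logical vector of length 7 (class `presence_vector`) with
#'   attributes `gene_id` and `nonself_group`.
#' @export
presence_profile <- function(gene_id, clusters, ladder) {
  r <- clusters$records
  focal <- ladder$focal_species
  cl <- unique(r$cluster_id[r$gene_id == gene_id & r$species_id == focal])
  if (length(cl) == 0L)
    stop("gene '", gene_id, "' absent from all clusters")
  mem <- r[r$cluster_id %in% cl, , drop = FALSE]
  self <- mem$species_id == focal & mem$gene_id == gene_id
  mem <- mem[!self, , drop = FALSE]
  nodes <- if (nrow(mem)) species_node(ladder, mem$species_id) else integer(0)
  present <- tabulate(nodes + 1L, nbins = 7L) > 0L
  nonself_group <- present[7L]
  present[7L] <- TRUE
  structure(present, gene_id = gene_id, nonself_group = nonself_group,
            class = "presence_vector")
}

#' Assign the evolutionary origin of a gene
#'
#' Origin is the most ancient ladder node at which an ortholog of the gene can
#' be found. Off-lineage presences are projected through the ladder's lineage
#' mask first (an *E. coli* gene with a metazoan ortholog originated at LUCA).
#' If no ortholog exists below the group-specific node but a non-self
#' group-specific ortholog or paralog does, the origin is group-specific
#' (index 6). If the gene has no non-self ortholog anywhere its origin is
#' untraceable, returned as `NA`.
#'
#' @param pv a [presence_profile()] vector.
#' @param ladder a [build_ladder()] object.
#' @return integer node index 0--6, or `NA_integer_` for untraceable.
#' @export
assign_origin <- function(pv, ladder) {
  stopifnot(inherits(pv, "presence_vector"))
  k <- which(pv[1:6]) - 1L
  if (length(k) > 0L)
    return(min(ladder$lineage_mask[k + 1L]))
  if (isTRUE(attr(pv, "nonself_group"))) return(6L)
  NA_integer_
}

#' Conservation of a gene since its origin
#'
#' Counts the internal nodes strictly between the origin and the
#' group-specific node where no ortholog is found (missing nodes). 0 means
#' maximal conservation; the maximum value, 5, is attained by a LUCA-origin
#' gene with orthologs only in prokaryotes and the group-specific cluster.
#' The group-specific node itself never counts as missing (the focal gene is
#' present there by definition).
#'
#' @param pv a [presence_profile()] vector.
#' @param origin node index as returned by [assign_origin()].
#' @return integer count of missing nodes, in 0..5.
#' @export
compute_conservation <- function(pv, origin) {
  if (is.na(origin))
    stop("conservation is undefined for untraceable origin")
  stopifnot(inherits(pv, "presence_vector"), origin >= 0L, origin <= 6L)
  if (origin >= 5L) return(0L)
  sum(!pv[(origin + 2L):6L])
}

#' Duplicability of a gene at the reference cluster level
#'
#' A gene is duplicated if its reference-level cluster (KOG for eukaryotic
#' focal species, COG for prokaryotic) contains at least one other gene of the
#' focal species (a paralog); singleton if it is the only focal gene there;
#' unassigned if it has no reference-level cluster.
#'
#' @param gene_id focal-species gene identifier.
#' @param clusters an [ortholog_clusters()] object.
#' @param reference_level level label, e.g. `"KOG"` or `"COG"`.
#' @param focal_species focal species identifier.
#' @return one of `"duplicated"`, `"singleton"`, `"unassigned"`.
#' @export
assign_duplicability <- function(gene_id, clusters, reference_level,
                                 focal_species) {
  r <- clusters$records
  ref <- r[r$level == reference_level, , drop = FALSE]
  cl <- unique(ref$cluster_id[ref$gene_id == gene_id &
                              ref$species_id == focal_species])
  if (length(cl) == 0L) return("unassigned")
  if (length(cl) > 1L)
    stop("gene '", gene_id, "' in more than one ", reference_level,
         " cluster (malformed input)")
  n_focal <- length(unique(ref$gene_id[ref$cluster_id == cl &
                                       ref$species_id == focal_species]))
  if (n_focal >= 2L) "duplicated" else "singleton"
}

#' Annotate a gene list with origin, conservation, and duplicability
#'
#' Orchestrates [presence_profile()], [assign_origin()],
#' [compute_conservation()], and [assign_duplicability()] over a gene list.
#' Genes with no non-self ortholog anywhere are flagged `untraceable`
#' (conservation undefined); genes without a reference-level cluster are
#' flagged `unassigned`. Both classes are excluded from downstream statistics;
#' exclusion counts are reported via `message()` and attached as the
#' `exclusions` attribute.
#'
#' @param gene_list character vector of focal-species gene identifiers.
#' @param clusters an [ortholog_clusters()] object.
#' @param ladder a [build_ladder()] object.
#' @param reference_level duplicability reference level label (e.g. `"KOG"`).
#' @param quiet suppress the exclusion-count message.
#' @return data.frame with columns `gene_id`, `origin_index` (0--6 or `NA`),
#'   `origin_label`, `conservation` (`NA` when untraceable), `duplicability`,
#'   `flags` (comma-separated subset of `untraceable`, `unassigned`, empty
#'   when clean).
#' @export
annotate_genes <- function(gene_list, clusters, ladder, reference_level,
                           quiet = FALSE) {
  gene_list <- as.character(gene_list)
  n <- length(gene_list)
  out <- data.frame(gene_id = gene_list,
                    origin_index = rep(NA_integer_, n),
                    origin_label = rep(NA_character_, n),
                    conservation = rep(NA_integer_, n),
                    duplicability = rep("unassigned", n),
                    flags = rep("", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(out, "exclusions") <- c(untraceable = 0L, unassigned = 0L,
                                 clusterless = 0L)
    return(out)
  }

  r <- clusters$records
  focal <- ladder$focal_species
  node <- species_node(ladder, r$species_id)   # errors on unknown species
  cl_levels <- unique(r$cluster_id)
  cid <- match(r$cluster_id, cl_levels)
  ncl <- length(cl_levels)

  # per-cluster member counts at each ladder node
  cnt <- matrix(0L, nrow = ncl, ncol = 7L)
  for (k in 0:6) {
    t <- tabulate(cid[node == k], nbins = ncl)
    cnt[, k + 1L] <- t
  }

  is_focal <- r$species_id == focal
  gene_cl <- split(cid[is_focal], r$gene_id[is_focal])

  # duplicability lookup: focal-gene counts per reference-level cluster
  ref <- r[r$level == reference_level & is_focal, , drop = FALSE]
  ref_sizes <- table(ref$cluster_id)
  ref_cluster_of <- split(ref$cluster_id, ref$gene_id)

  for (i in seq_len(n)) {
    g <- gene_list[i]
    cls <- unique(gene_cl[[g]])
    flags <- character(0)

    if (is.null(cls)) {
      flags <- c("untraceable", "unassigned")
    } else {
      tot <- colSums(cnt[cls, , drop = FALSE])
      tot[7L] <- tot[7L] - length(cls)  # one self row per containing cluster
      present <- tot > 0L
      nonself6 <- present[7L]
      present[7L] <- TRUE
      pv <- structure(present, gene_id = g, nonself_group = nonself6,
                      class = "presence_vector")
      origin <- assign_origin(pv, ladder)
      if (is.na(origin)) {
        flags <- c(flags, "untraceable")
      } else {
        out$origin_index[i] <- origin
        out$origin_label[i] <- ladder$nodes[origin + 1L]
        out$conservation[i] <- compute_conservation(pv, origin)
      }
      refs <- unique(ref_cluster_of[[g]])
      if (is.null(refs)) {
        flags <- c(flags, "unassigned")
      } else if (length(refs) > 1L) {
        stop("gene '", g, "' in more than one ", reference_level, " cluster")
      } else {
        out$duplicability[i] <-
          if (ref_sizes[[refs]] >= 2L) "duplicated" else "singleton"
      }
    }
    out$flags[i] <- paste(flags, collapse = ",")
  }

  excl <- c(untraceable = sum(grepl("untraceable", out$flags)),
            unassigned = sum(grepl("unassigned", out$flags)),
            clusterless = sum(vapply(gene_list,
                                     function(g) is.null(gene_cl[[g]]),
                                     logical(1))))
  attr(out, "exclusions") <- excl
  if (!quiet)
    message(sprintf(
      "annotate_genes: %d genes; excluded downstream: %d untraceable, %d without %s cluster",
      n, excl[["untraceable"]], excl[["unassigned"]], reference_level))
  out
}

#' Write a provenance table to TSV
#'
#' @param provenance output of [annotate_genes()].
#' @param path output file path.
#' @param params optional named list echoed as `#` header comments.
#' @export
write_provenance <- function(provenance, path, params = NULL) {
  write_tsv_commented(provenance, path, params)
}

# shared TSV writer: '#'-commented parameter header, then a header row
write_tsv_commented <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    for (nm in names(params))
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(params[[nm]]), collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
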