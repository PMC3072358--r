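#' Canonical labels of the seven-node species ladder
#'
#' The ladder discretises the focal lineage into seven internal nodes of the
#' tree of life, ordered from the most ancient (LUCA, index 0) to the
#' group-specific transition (index 6, e.g. primates for human, bacteria for
#' *E. coli*).
#'
#' @export
LADDER_NODES <- c("LUCA", "eukaryotes", "opisthokonts", "metazoans",
                  "vertebrates", "mammals", "group_specific")

#' Build a seven-node taxon ladder
#'
#' Maps every species that can occur in an ortholog-cluster table to one of
#' seven internal nodes of the tree of life, and records how off-lineage nodes
#' project onto the focal lineage. Node indices are 0-based: 0 = LUCA, 6 =
#' group-specific.
#'
#' For a eukaryotic focal species all seven nodes lie on the focal lineage and
#' the lineage mask is the identity. For a prokaryotic focal species the
#' eukaryote-tier nodes (1--5) are off-lineage: an ortholog found there is
#' evidence that the gene predates the prokaryote/eukaryote split, so those
#' nodes project to LUCA. In general an off-lineage node projects to the
#' nearest more-ancient on-lineage node (its most recent shared ancestor with
#' the focal lineage).
#'
#' @param species_map data.frame with columns `species_id` and `node_label`
#'   (one of [LADDER_NODES]).
#' @param focal_species species identifier; must map to the group-specific
#'   node (index 6).
#' @param on_lineage logical vector of length 7: does each node lie on the
#'   focal lineage? Nodes 0 and 6 must always be on-lineage.
#' @param nodes character vector of 7 node labels, most ancient first.
#' @return An object of class `taxon_ladder`: list with `focal_species`,
#'   `nodes`, `species_to_node` (named integer, 0-based), `lineage_mask`
#'   (integer length 7, 0-based projections).
#' @export
build_ladder <- function(species_map, focal_species,
                         on_lineage = rep(TRUE, 7L),
                         nodes = LADDER_NODES) {
  stopifnot(is.data.frame(species_map),
            all(c("species_id", "node_label") %in% names(species_map)))
  if (length(nodes) != 7L)
    stop("a taxon ladder has exactly 7 nodes")
  if (length(on_lineage) != 7L || !is.logical(on_lineage))
    stop("`on_lineage` must be a logical vector of length 7")
  if (!on_lineage[1L] || !on_lineage[7L])
    stop("the LUCA and group-specific nodes are always on the focal lineage")

  sp <- as.character(species_map$species_id)
  if (anyDuplicated(sp)) {
    dup <- unique(sp[duplicated(sp)])
    stop("species assigned to more than one node: ", paste(dup, collapse = ", "))
  }
  idx <- match(as.character(species_map$node_label), nodes) - 1L
  if (anyNA(idx))
    stop("unknown node label(s): ",
         paste(unique(species_map$node_label[is.na(idx)]), collapse = ", "))
  species_to_node <- stats::setNames(idx, sp)

  if (!focal_species %in% sp)
    stop("focal species '", focal_species, "' absent from the species map")
  if (species_to_node[[focal_species]] != 6L)
    stop("focal species must map to the group-specific node (index 6)")
  if (!any(idx == 6L))
    stop("missing group-specific node assignment")

  # off-lineage nodes project to the nearest more-ancient on-lineage node
  mask <- integer(7L)
  for (k in 0:6) {
    mask[k + 1L] <- if (on_lineage[k + 1L]) k else {
      anc <- which(on_lineage[seq_len(k)])  # on-lineage nodes with index < k
      max(anc) - 1L
    }
  }

  structure(
    list(focal_species = focal_species, nodes = nodes,
         species_to_node = species_to_node, lineage_mask = mask),
    class = "taxon_ladder"
  )
}

#' @export
print.taxon_ladder <- function(x, ...) {
  cat("Taxon ladder (focal species: ", x$focal_species, ")\n", sep = "")
  for (k in 0:6) {
    n_sp <- sum(x$species_to_node == k)
    cat(sprintf("  [%d] %-15s %3d species%s\n", k, x$nodes[k + 1L], n_sp,
                if (x$lineage_mask[k + 1L] != k)
                  sprintf("  (off-lineage -> %d)", x$lineage_mask[k + 1L]) else ""))
  }
  invisible(x)
}

#' Map species identifiers to ladder node indices
#'
#' @param ladder a [build_ladder()] object.
#' @param species character vector of species identifiers.
#' @return integer vector of 0-based node indices.
#' @export
species_node <- function(ladder, species) {
  idx <- ladder$species_to_node[as.character(species)]
  if (anyNA(idx))
    stop("species not assigned to any ladder node: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  unname(idx)
}

#' Read a species-to-node table
#'
#' Expects tab-separated columns `species_id`, `node_label`; `#` comments and
#' a header row.
#'
#' @param path file path.
#' @return data.frame with the two columns.
#' @export
read_species_nodes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("species_id", "node_label") %in% names(df)))
    stop("species_nodes file must have columns species_id, node_label")
  df
}
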