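#' Ortholog cluster membership set
#'
#' Wraps a long membership table (cluster_id, level, species_id, gene_id) and
#' indexes it by gene. A gene may belong to clusters at several inclusiveness
#' levels (e.g. COG, KOG, maNOG); within one level a gene belongs to at most
#' one cluster.
#'
#' @param records data.frame with columns `cluster_id`, `level`, `species_id`,
#'   `gene_id`.
#' @return object of class `ortholog_clusters`.
#' @export
ortholog_clusters <- function(records) {
  req <- c("cluster_id", "level", "species_id", "gene_id")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  records <- records[req]
  for (cl in req) records[[cl]] <- as.character(records[[cl]])

  key <- paste(records$cluster_id, records$species_id, records$gene_id, sep = "\r")
  if (anyDuplicated(key))
    records <- records[!duplicated(key), , drop = FALSE]

  # one cluster per (gene, species, level): same-level multi-membership is
  # malformed input and would inflate duplicability if merged silently
  glk <- unique(records[c("cluster_id", "level", "species_id", "gene_id")])
  gl <- paste(glk$species_id, glk$gene_id, glk$level, sep = "\r")
  if (anyDuplicated(gl)) {
    bad <- glk$gene_id[duplicated(gl) | duplicated(gl, fromLast = TRUE)]
    stop("gene(s) present in more than one cluster of the same level: ",
         paste(unique(bad), collapse = ", "))
  }

  structure(list(records = records), class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  r <- x$records
  cat("Ortholog cluster set: ", length(unique(r$cluster_id)), " clusters, ",
      length(unique(r$gene_id)), " genes, levels: ",
      paste(sort(unique(r$level)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a cluster membership table
#'
#' Tab-separated columns `cluster_id`, `level`, `species_id`, `gene_id`;
#' `#` comments allowed.
#'
#' @param path file path.
#' @return an [ortholog_clusters()] object.
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  ortholog_clusters(df)
}

clusters_of <- function(clusters, gene_id, species = NULL) {
  r <- clusters$records
  sel <- r$gene_id == gene_id
  if (!is.null(species)) sel <- sel & r$species_id == species
  unique(r$cluster_id[sel])
}
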