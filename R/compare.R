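#' Stratify genes by origin or conservation with metric vectors
#'
#' Groups genes sharing provenance and network data into ordered strata and,
#' for each stratum, defines the two comparison pools as the union of all
#' strata on either side: `younger`/`older` for the origin key (larger origin
#' index = younger), `less_conserved`/`more_conserved` for the conservation
#' key (larger missing-node count = less conserved).
#'
#' @param provenance output of [annotate_genes()]; flagged genes are excluded.
#' @param metrics output of [compute_metrics()]; genes without network data
#'   are excluded.
#' @param key `"origin"` or `"conservation"`.
#' @return list of strata; each element has `stratum` (integer level),
#'   `label`, `genes`, `degree`, `betweenness`, and pools
#'   `pool_recent`/`pool_ancient` style lists keyed by side label.
#' @export
stratify <- function(provenance, metrics, key = c("origin", "conservation")) {
  key <- match.arg(key)
  keep <- provenance$flags == "" & !is.na(provenance$origin_index)
  prov <- provenance[keep, , drop = FALSE]
  m <- merge(prov, metrics, by = "gene_id")
  lev <- if (key == "origin") m$origin_index else m$conservation
  sides <- if (key == "origin") c("younger", "older")
           else c("less_conserved", "more_conserved")

  levels_present <- sort(unique(lev))
  lapply(levels_present, function(s) {
    in_s <- lev == s
    # side 1: strictly larger level = younger / less conserved
    hi <- lev > s
    lo <- lev < s
    pools <- list(
      list(side = sides[1L], degree = m$degree[hi],
           betweenness = m$betweenness[hi], n = sum(hi)),
      list(side = sides[2L], degree = m$degree[lo],
           betweenness = m$betweenness[lo], n = sum(lo))
    )
    names(pools) <- sides
    list(stratum = s,
         label = if (key == "origin") LADDER_NODES[s + 1L] else
           paste0("conservation_", s),
         key = key,
         genes = m$gene_id[in_s],
         degree = m$degree[in_s],
         betweenness = m$betweenness[in_s],
         pools = pools)
  })
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Uses exact enumeration of the rank-sum distribution (all subset
#' assignments, midranks for ties) when the combined sample size is at most
#' 10, and the large-sample normal approximation with continuity correction
#' otherwise. Direction is the side of the focal sample by mean rank.
#'
#' @param focal,pool numeric vectors (both non-empty).
#' @return list `p`, `direction` (`"higher"`, `"lower"`, or `"none"` when the
#'   mean ranks are equal).
#' @export
ranksum_compare <- function(focal, pool) {
  if (length(focal) == 0L || length(pool) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(focal); n2 <- length(pool)
  r <- rank(c(focal, pool))
  w_obs <- sum(r[seq_len(n1)])
  mean_rank_diff <- mean(r[seq_len(n1)]) - mean(r[n1 + seq_len(n2)])

  if (n1 + n2 <= 10L) {
    sets <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    lo <- mean(w_all <= w_obs + 1e-9)
    hi <- mean(w_all >= w_obs - 1e-9)
    p <- min(1, 2 * min(lo, hi))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(focal, pool, exact = FALSE, correct = TRUE)$p.value)
  }
  direction <- if (mean_rank_diff > 0) "higher"
               else if (mean_rank_diff < 0) "lower" else "none"
  list(p = p, direction = direction)
}

#' Randomization z comparison of two metric pools
#'
#' Draws `reps` times a subset of size `n = min(subset_size, n_focal,
#' n_pool)` without replacement from each side, takes the difference of
#' subset means `D = mean(focal subset) - mean(pool subset)`, and reports the
#' two tail fractions `z_low = P(D < 0)` and `z_high = P(D > 0)` with exact
#' ties (`D = 0`) split equally between them, so `z_low + z_high = 1`.
#' Direction is taken from the sign of the median difference. Deterministic
#' given `seed`.
#'
#' @param focal,pool numeric vectors.
#' @param subset_size per-rep subset size cap (default 500).
#' @param reps number of randomizations (default 100000).
#' @param seed integer seed.
#' @return list `z_low`, `z_high`, `direction`, `n` (subset size used),
#'   `reps`, `seed`.
#' @export
randomization_compare <- function(focal, pool, subset_size = 500L,
                                  reps = 100000L, seed = 1L) {
  if (length(focal) == 0L || length(pool) == 0L)
    stop("both samples must be non-empty")
  if (reps < 1L) stop("reps must be >= 1")
  n <- min(subset_size, length(focal), length(pool))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  D <- numeric(reps)
  for (i in seq_len(reps)) {
    D[i] <- mean(focal[sample.int(length(focal), n)]) -
            mean(pool[sample.int(length(pool), n)])
  }
  z_low <- mean(D < 0) + 0.5 * mean(D == 0)
  z_high <- mean(D > 0) + 0.5 * mean(D == 0)
  med <- stats::median(D)
  list(z_low = z_low, z_high = z_high,
       direction = if (med > 0) "higher" else if (med < 0) "lower" else "none",
       n = n, reps = reps, seed = seed)
}

#' Compare network metrics across provenance strata
#'
#' For every stratum from [stratify()] and both metrics (degree,
#' betweenness), compares the stratum against each side pool with the
#' Wilcoxon rank-sum test and, optionally, the subset-resampling
#' randomization z. Strata with fewer than 2 genes on either side yield
#' absent cells (rows are skipped).
#'
#' @param provenance output of [annotate_genes()].
#' @param metrics output of [compute_metrics()].
#' @param key `"origin"` or `"conservation"`.
#' @param randomization also compute the randomization z per cell.
#' @param subset_size,reps,seed randomization parameters; per-cell seeds are
#'   derived deterministically from `seed`.
#' @return data.frame: `stratum`, `label`, `side`, `metric`, `n_focal`,
#'   `n_pool`, `p`, `direction`, and when requested `z_low`, `z_high`,
#'   `z_direction`, `subset_size`, `reps`, `seed`.
#' @export
compare_strata <- function(provenance, metrics,
                           key = c("origin", "conservation"),
                           randomization = FALSE, subset_size = 500L,
                           reps = 10000L, seed = 1L) {
  key <- match.arg(key)
  strata <- stratify(provenance, metrics, key)
  rows <- list()
  cell <- 0L
  for (st in strata) {
    for (metric in c("degree", "betweenness")) {
      focal <- st[[metric]]
      for (side in names(st$pools)) {
        cell <- cell + 1L
        pool <- st$pools[[side]][[metric]]
        if (length(focal) < 2L || length(pool) < 2L) next
        rs <- ranksum_compare(focal, pool)
        row <- data.frame(stratum = st$stratum, label = st$label,
                          side = side, metric = metric,
                          n_focal = length(focal), n_pool = length(pool),
                          p = rs$p, direction = rs$direction,
                          stringsAsFactors = FALSE)
        if (randomization) {
          rz <- randomization_compare(focal, pool, subset_size, reps,
                                      seed = seed + 101L * cell)
          row$z_low <- rz$z_low
          row$z_high <- rz$z_high
          row$z_direction <- rz$direction
          row$subset_size <- rz$n
          row$reps <- reps
          row$seed <- rz$seed
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Age-matched duplicated-versus-singleton comparison
#'
#' Within each origin stratum, compares degree and betweenness of proteins
#' encoded by duplicated genes against singleton genes of the same age with
#' the Wilcoxon rank-sum test. Direction `"higher"` means duplicated genes
#' encode the more connected/central proteins (red in the heatmap),
#' `"lower"` means singletons do (green). Strata where either class has
#' fewer than 2 genes yield absent cells.
#'
#' @param provenance output of [annotate_genes()].
#' @param metrics output of [compute_metrics()].
#' @return data.frame: `stratum`, `label`, `side`
#'   (`"duplicated_vs_singleton"`), `metric`, `n_focal` (duplicated),
#'   `n_pool` (singleton), `p`, `direction`.
#' @export
age_matched_duplicability <- function(provenance, metrics) {
  keep <- provenance$flags == "" & !is.na(provenance$origin_index) &
    provenance$duplicability %in% c("duplicated", "singleton")
  m <- merge(provenance[keep, , drop = FALSE], metrics, by = "gene_id")
  rows <- list()
  for (s in sort(unique(m$origin_index))) {
    in_s <- m$origin_index == s
    dup <- m[in_s & m$duplicability == "duplicated", , drop = FALSE]
    sing <- m[in_s & m$duplicability == "singleton", , drop = FALSE]
    if (nrow(dup) < 2L || nrow(sing) < 2L) next
    for (metric in c("degree", "betweenness")) {
      rs <- ranksum_compare(dup[[metric]], sing[[metric]])
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, label = LADDER_NODES[s + 1L],
        side = "duplicated_vs_singleton", metric = metric,
        n_focal = nrow(dup), n_pool = nrow(sing),
        p = rs$p, direction = rs$direction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Transform comparison results into a heatmap matrix
#'
#' Significant cells (p or z below `alpha`) carry their value clipped from
#' below at `floor` and a color from the direction: red for higher
#' connectivity/centrality of the focal side, green for lower.
#' Non-significant cells are black.
#'
#' @param results data.frame from [compare_strata()] or
#'   [age_matched_duplicability()].
#' @param alpha significance level per cell (default 0.05; no correction
#'   across cells).
#' @param floor lower display bound for significant values (default 1e-3).
#' @param use `"p"` for the Wilcoxon value or `"z"` for the randomization
#'   tail (the tail on the observed-direction side).
#' @return data.frame: `stratum`, `label`, `side`, `metric`, `value`,
#'   `color` (`red`/`green`/`black`).
#' @export
build_heatmap <- function(results, alpha = 0.05, floor = 1e-3,
                          use = c("p", "z")) {
  use <- match.arg(use)
  if (use == "z") {
    # the significance value is the tail fraction opposite the direction
    val <- ifelse(results$z_direction == "higher",
                  results$z_low, results$z_high)
    dirn <- results$z_direction
  } else {
    val <- results$p
    dirn <- results$direction
  }
  sig <- !is.na(val) & val < alpha & dirn != "none"
  data.frame(
    stratum = results$stratum, label = results$label, side = results$side,
    metric = results$metric,
    value = ifelse(sig, pmax(val, floor), val),
    color = ifelse(!sig, "black", ifelse(dirn == "higher", "red", "green")),
    stringsAsFactors = FALSE)
}
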