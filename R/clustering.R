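#' Neighbor counts at a distance cutoff
#'
#' Two models are neighbors when the core RMSD between them is strictly
#' smaller than the cutoff. A model is not its own neighbor.
#'
#' @param dm A `dist_matrix`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Named integer vector of neighbor counts, in matrix id order.
#' @export
neighbor_counts <- function(dm, cutoff) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  adj <- dm$values < cutoff
  diag(adj) <- FALSE
  counts <- as.integer(rowSums(adj))
  names(counts) <- dm$ids
  counts
}

#' Greedy neighbor-count clustering at a fixed cutoff
#'
#' Iteratively picks the unassigned model with the most unassigned
#' neighbors as a medoid; its cluster is the medoid plus its unassigned
#' neighbors; all are removed and the procedure repeats until every model
#' is assigned (models without neighbors end up as singleton clusters).
#' Clusters are ordered by extraction, so the first cluster is the biggest
#' at extraction time. Ties for the medoid are broken by lower energy rank,
#' then lexicographic id; cluster members are listed medoid first, then by
#' ascending distance to the medoid (ties again by rank, then id). With
#' these tie-breaks the result does not depend on the input id order.
#'
#' @param dm A `dist_matrix`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param ranks Optional named integer vector of energy ranks used in
#'   tie-breaking (defaults to 0 for all, i.e. lexicographic ids decide).
#' @return Object of class `clust_result`: list with `cutoff`, `mode`
#'   (`"fixed"` here), and `clusters`, an ordered list of
#'   `list(medoid = id, members = ids)` with members including the medoid.
#' @export
cluster_at <- function(dm, cutoff, ranks = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- length(dm$ids)
  if (n == 0L) stop("empty distance matrix")
  rk <- rep(0L, n)
  names(rk) <- dm$ids
  if (!is.null(ranks)) {
    hit <- intersect(names(ranks), dm$ids)
    rk[hit] <- as.integer(ranks[hit])
  }
  adj <- dm$values < cutoff
  diag(adj) <- FALSE

  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    ui <- which(unassigned)
    cnt <- rowSums(adj[ui, ui, drop = FALSE])
    ord <- order(-cnt, rk[ui], dm$ids[ui])
    med <- ui[ord[1L]]
    nbr <- ui[adj[med, ui]]
    memb <- c(med, nbr[order(dm$values[med, nbr], rk[nbr], dm$ids[nbr])])
    clusters[[length(clusters) + 1L]] <-
      list(medoid = dm$ids[med], members = dm$ids[memb])
    unassigned[memb] <- FALSE
  }
  structure(list(cutoff = cutoff, mode = "fixed", clusters = clusters),
            class = "clust_result")
}

#' @export
print.clust_result <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat("clust_result: ", length(sizes), " clusters at cutoff ",
      x$cutoff, " A (mode ", x$mode, ")\n", sep = "")
  cat("  sizes: ", paste(utils::head(sizes, 10L), collapse = " "),
      if (length(sizes) > 10L) " ...", "\n", sep = "")
  invisible(x)
}

#' Cluster sizes in extraction order
#' @param clusters A `clust_result`.
#' @return Integer vector of member counts.
#' @export
cluster_sizes <- function(clusters) {
  vapply(clusters$clusters, function(cl) length(cl$members), 0L)
}

#' @export
as.data.frame.clust_result <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$clusters), function(k)
    data.frame(cluster = k,
               model_id = x$clusters[[k]]$members,
               medoid = x$clusters[[k]]$members == x$clusters[[k]]$medoid)))
}

#' Iterative cutoff search with the 1-of-6 / half stopping criteria
#'
#' Runs [cluster_at()] on a cutoff grid starting at `start` and increasing
#' by `step`, stopping at the smallest cutoff whose clustering meets the
#' criterion. In `"one_of_six"` mode the search stops when the first
#' (biggest) cluster holds at least 1/6 of all structures; in `"half"` mode
#' when the first three clusters together hold at least half. The integer
#' thresholds are `ceiling(n/6)` and `ceiling(n/2)` — for 500 pooled
#' structures: first cluster over 80, or at least 250 in the top three.
#'
#' @inheritParams cluster_at
#' @param mode `"one_of_six"` or `"half"`.
#' @param start,step Cutoff grid origin and increment in Angstrom
#'   (defaults 0.5 and 0.5).
#' @param max_cutoff Guard against non-termination on pathological
#'   matrices; the search errors past this cutoff, reporting the trajectory
#'   of first-cluster sizes. Default 50.
#' @return A `clust_result` at the terminating cutoff, with `mode` set and
#'   attribute `"trajectory"`, a data frame of the first-cluster size and
#'   criterion value at every cutoff visited.
#' @export
autocluster <- function(dm, mode = c("one_of_six", "half"), start = 0.5,
                        step = 0.5, max_cutoff = 50, ranks = NULL) {
  mode <- match.arg(mode)
  if (start <= 0 || step <= 0) stop("start and step must be > 0")
  n <- length(dm$ids)
  needed <- switch(mode, one_of_six = ceiling(n / 6), half = ceiling(n / 2))
  cutoff <- start
  traj <- list()
  while (cutoff <= max_cutoff + 1e-9) {
    res <- cluster_at(dm, cutoff, ranks = ranks)
    sizes <- cluster_sizes(res)
    achieved <- switch(mode,
                       one_of_six = sizes[1L],
                       half = sum(utils::head(sizes, 3L)))
    traj[[length(traj) + 1L]] <-
      data.frame(cutoff = cutoff, first_cluster = sizes[1L],
                 criterion = achieved)
    if (achieved >= needed) {
      res$mode <- mode
      attr(res, "trajectory") <- do.call(rbind, traj)
      return(res)
    }
    cutoff <- cutoff + step
  }
  tr <- do.call(rbind, traj)
  stop("clustering criterion '", mode, "' (needs ", needed, " of ", n,
       ") not met up to cutoff ", max_cutoff, " A; first-cluster sizes: ",
       paste(sprintf("%.1f:%d", tr$cutoff, tr$first_cluster), collapse = " "))
}

#' Write / read the cluster report
#'
#' One line per cluster:
#' `cluster<k> cutoff=<A> medoid=<id> n=<size> members=<id> <id> ...`
#'
#' @param clusters A `clust_result`.
#' @param path Output path.
#' @export
write_cluster_report <- function(clusters, path) {
  stopifnot(inherits(clusters, "clust_result"))
  lines <- vapply(seq_along(clusters$clusters), function(k) {
    cl <- clusters$clusters[[k]]
    sprintf("cluster%d cutoff=%g medoid=%s n=%d members=%s",
            k, clusters$cutoff, cl$medoid, length(cl$members),
            paste(cl$members, collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty cluster report: ", path)
  cutoff <- as.numeric(sub(".*cutoff=([0-9.eE+-]+).*", "\\1", lines[1L]))
  clusters <- lapply(lines, function(l) {
    medoid <- sub(".*medoid=([^ ]+).*", "\\1", l)
    members <- strsplit(sub(".*members=", "", l), " ", fixed = TRUE)[[1L]]
    list(medoid = medoid, members = members)
  })
  structure(list(cutoff = cutoff, mode = "fixed", clusters = clusters),
            class = "clust_result")
}
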