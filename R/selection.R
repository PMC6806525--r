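#' Select the final model for the target sequence
#'
#' Two published selection rules:
#' * `"cluster_scan"` (default): scan clusters in extraction order and,
#'   within each cluster, members in order; return the first model whose
#'   homolog is the target sequence. If the first cluster holds no target
#'   model the second is processed, and so on.
#' * `"max_neighbors"`: return the target model with the highest neighbor
#'   count at the terminating cutoff (ties broken by lower energy rank,
#'   then id); requires the distance matrix.
#'
#' @param clusters A `clust_result`.
#' @param models The `model_set` that was clustered (supplies each model's
#'   homolog and rank, and the target name).
#' @param rule `"cluster_scan"` or `"max_neighbors"`.
#' @param dm The `dist_matrix` used for clustering; needed for
#'   `"max_neighbors"`.
#' @return Object of class `selection_report`: list with `chosen`
#'   (model id), `cluster_index` (1-based index of the cluster holding the
#'   chosen model), `rule`, and `runner_ups` (the remaining target models
#'   in scan order).
#' @export
select_final <- function(clusters, models,
                         rule = c("cluster_scan", "max_neighbors"),
                         dm = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(clusters, "clust_result"), inherits(models, "model_set"))
  target <- models$target_name
  homolog_of <- vapply(models$models, function(m) m$homolog, "")
  rank_of <- vapply(models$models, function(m) m$rank, 0L)

  scan_order <- unlist(lapply(clusters$clusters, `[[`, "members"),
                       use.names = FALSE)
  target_in_scan <- scan_order[homolog_of[scan_order] == target]
  if (length(target_in_scan) == 0L)
    stop("no model of target '", target, "' in any cluster; ",
         "check the mapping file")

  chosen <- if (rule == "cluster_scan") {
    target_in_scan[1L]
  } else {
    if (is.null(dm))
      stop("rule 'max_neighbors' needs the distance matrix (dm)")
    counts <- neighbor_counts(dm, clusters$cutoff)
    cand <- names(counts)[homolog_of[names(counts)] == target]
    if (length(cand) == 0L)
      stop("no model of target '", target, "' in the distance matrix")
    cand[order(-counts[cand], rank_of[cand], cand)][1L]
  }

  cluster_index <- which(vapply(clusters$clusters,
                                function(cl) chosen %in% cl$members, TRUE))[1L]
  structure(list(chosen = chosen,
                 cluster_index = as.integer(cluster_index),
                 rule = rule,
                 runner_ups = setdiff(target_in_scan, chosen)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report: chosen ", x$chosen, " (cluster ", x$cluster_index,
      ", rule ", x$rule, ")\n", sep = "")
  invisible(x)
}

#' Write a selection report as key=value lines
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  writeLines(c(paste0("chosen=", report$chosen),
               paste0("cluster_index=", report$cluster_index),
               paste0("rule=", report$rule),
               paste0("runner_ups=", paste(report$runner_ups, collapse = " "))),
             path)
  invisible(path)
}
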