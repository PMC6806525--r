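#' Convert a distance matrix into a CLANS cluster-map document
#'
#' CLANS lays out a graph of pseudo-sequences from pairwise attraction
#' values. Here each decoy model becomes a node, models of the same homolog
#' form a color group (the target colored distinctly, in lime), and every
#' pair with core RMSD strictly below `threshold` is connected with
#' attraction `1 - d / threshold` (linear in `(0, 1]`; any strictly
#' decreasing map gives the same graph topology). Documented presets from
#' practice: 6 Angstrom for compact riboswitch cores, 9 for more open
#' ensembles.
#'
#' An experimental reference trace may be appended as an extra node in its
#' own group, connected through its core RMSD to every model.
#'
#' @param dm A `dist_matrix`.
#' @param groups Named character vector mapping every model id to its
#'   homolog.
#' @param threshold Connection threshold in Angstrom (> 0).
#' @param target Name of the target homolog (gets the distinct color).
#' @param reference Optional `core_trace` of the reference structure; its
#'   distances to all models are computed here.
#' @param models Needed when `reference` is given: the `model_set` (or list
#'   of models) whose traces the reference is compared against, via the
#'   supplied `core` map.
#' @param core Optional `core_map`, required with `reference`.
#' @return Object of class `clans_document`: list with `n`, `ids`,
#'   `groups` (list of name/color/members), `connections` (data frame
#'   `i`, `j`, `attraction`, 1-based, `i < j`), and `lengths` (pseudo-
#'   sequence lengths).
#' @export
to_clans <- function(dm, groups, threshold, target = NULL, reference = NULL,
                     models = NULL, core = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (threshold <= 0) stop("threshold must be > 0")
  miss <- setdiff(dm$ids, names(groups))
  if (length(miss))
    stop("models missing from groups: ", paste(utils::head(miss, 5L), collapse = ", "))
  ids <- dm$ids
  vals <- dm$values
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "core_trace"))
    if (is.null(models) || is.null(core))
      stop("appending a reference needs 'models' and 'core'")
    mods <- if (inherits(models, "model_set")) models$models else models
    refd <- vapply(mods[ids], function(m)
      core_rmsd(core_trace(m, core), reference), 0)
    vals <- rbind(cbind(vals, refd), c(refd, 0))
    ids <- c(ids, "reference")
    groups <- c(groups, reference = "reference")
    dimnames(vals) <- list(ids, ids)
  }
  n <- length(ids)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  keep <- vals[ut] < threshold
  connections <- data.frame(i = ut[keep, 1L], j = ut[keep, 2L],
                            attraction = 1 - vals[ut][keep] / threshold)
  connections <- connections[order(connections$i, connections$j), , drop = FALSE]
  rownames(connections) <- NULL

  palette <- c("0;255;0;255",    # lime for the target
               "255;0;0;255", "0;0;255;255", "255;165;0;255",
               "128;0;128;255", "0;206;209;255", "165;42;42;255",
               "255;192;203;255", "128;128;0;255")
  homs <- unique(unname(groups[ids]))
  if (is.null(target)) target <- homs[1L]
  homs <- c(intersect(target, homs), setdiff(homs, target))
  grp <- lapply(seq_along(homs), function(k) {
    col <- if (homs[k] == "reference") "0;0;0;255"
           else palette[(k - 1L) %% length(palette) + 1L]
    list(name = homs[k], color = col,
         members = unname(which(groups[ids] == homs[k])))
  })
  structure(list(n = n, ids = ids, groups = grp, connections = connections,
                 threshold = threshold),
            class = "clans_document")
}

#' @export
print.clans_document <- function(x, ...) {
  cat("clans_document: ", x$n, " nodes, ", nrow(x$connections),
      " connections (< ", x$threshold, " A), ", length(x$groups),
      " groups\n", sep = "")
  invisible(x)
}

#' Write / read a CLANS file
#'
#' Dialect: `sequences=<n>` header, a `<seq>` block of FASTA-like
#' pseudo-entries (poly-N), a `<seqgroups>` block (`name=`, `colors=`,
#' `numbers=` per group) and an `<hsp>` block of `i j:attraction` lines
#' (0-based indices, as CLANS expects). [read_clans()] round-trips the
#' document.
#'
#' @param doc A `clans_document`.
#' @param path Output path.
#' @export
write_clans <- function(doc, path) {
  stopifnot(inherits(doc, "clans_document"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("sequences=", doc$n), con)
  writeLines("<seq>", con)
  for (id in doc$ids) writeLines(c(paste0(">", id), strrep("N", 20L)), con)
  writeLines("</seq>", con)
  writeLines("<seqgroups>", con)
  for (g in doc$groups) {
    writeLines(c(paste0("name=", g$name),
                 paste0("colors=", g$color),
                 paste0("numbers=", paste(g$members - 1L, collapse = ";"))), con)
  }
  writeLines("</seqgroups>", con)
  writeLines("<hsp>", con)
  if (nrow(doc$connections))
    writeLines(sprintf("%d %d:%.6g", doc$connections$i - 1L,
                       doc$connections$j - 1L, doc$connections$attraction), con)
  writeLines("</hsp>", con)
  invisible(path)
}

#' @rdname write_clans
#' @export
read_clans <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("sequences=", "", lines[grepl("^sequences=", lines)][1L]))
  block <- function(tag) {
    i0 <- which(lines == paste0("<", tag, ">"))[1L]
    i1 <- which(lines == paste0("</", tag, ">"))[1L]
    if (is.na(i0) || is.na(i1)) character(0) else lines[(i0 + 1L):(i1 - 1L)]
  }
  seqb <- block("seq")
  ids <- sub("^>", "", seqb[grepl("^>", seqb)])
  gb <- block("seqgroups")
  starts <- which(grepl("^name=", gb))
  groups <- lapply(seq_along(starts), function(k) {
    lo <- starts[k]
    hi <- if (k < length(starts)) starts[k + 1L] - 1L else length(gb)
    chunk <- gb[lo:hi]
    nums <- sub("numbers=", "", chunk[grepl("^numbers=", chunk)][1L])
    list(name = sub("name=", "", chunk[1L]),
         color = sub("colors=", "", chunk[grepl("^colors=", chunk)][1L]),
         members = if (nzchar(nums))
           as.integer(strsplit(nums, ";")[[1L]]) + 1L else integer(0))
  })
  hb <- block("hsp")
  hb <- hb[nzchar(hb)]
  if (length(hb)) {
    parts <- regmatches(hb, regexec("^(\\d+) (\\d+):(.+)$", hb))
    connections <- data.frame(
      i = as.integer(vapply(parts, `[`, "", 2L)) + 1L,
      j = as.integer(vapply(parts, `[`, "", 3L)) + 1L,
      attraction = as.numeric(vapply(parts, `[`, "", 4L)))
  } else {
    connections <- data.frame(i = integer(0), j = integer(0),
                              attraction = numeric(0))
  }
  structure(list(n = n, ids = ids, groups = groups,
                 connections = connections, threshold = NA_real_),
            class = "clans_document")
}
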