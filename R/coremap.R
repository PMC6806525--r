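#' Conserved core of an alignment
#'
#' The conserved core is the ordered set of alignment columns that are
#' ungapped in every selected sequence. Residues at these columns are
#' structurally comparable across homologs of different lengths, which is
#' what makes the core RMSD metric well defined. The returned map carries,
#' for each selected sequence, the 1-based residue index (position in the
#' ungapped sequence) corresponding to each core column.
#'
#' A column is retained when the fraction of selected sequences that are
#' ungapped at it is at least `min_ungapped_fraction`. The default of 1
#' (ungapped in all) is the published behavior; with a lower fraction a
#' sequence may be gapped at a retained column, in which case its residue
#' index for that column is `NA` and the sequence cannot be traced there.
#'
#' @param aln An [rna_alignment].
#' @param selected Character vector of record names to intersect (at least
#'   two); defaults to all records.
#' @param min_ungapped_fraction Fraction in `(0, 1]` of selected sequences
#'   that must be ungapped for a column to enter the core. Default 1.
#' @return An object of class `core_map`: list with `columns` (strictly
#'   increasing 1-based alignment column indices) and `per_seq` (named list
#'   of 1-based residue indices, one per column, per selected sequence).
#' @export
conserved_core <- function(aln, selected = NULL, min_ungapped_fraction = 1) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (is.null(selected)) selected <- aln$names
  missing <- setdiff(selected, aln$names)
  if (length(missing))
    stop("selected sequences not in alignment: ", paste(missing, collapse = ", "))
  if (length(selected) < 2L) stop("need at least 2 selected sequences")
  if (min_ungapped_fraction <= 0 || min_ungapped_fraction > 1)
    stop("min_ungapped_fraction must be in (0, 1]")

  chars <- do.call(rbind, strsplit(unname(aln$seqs[selected]), ""))
  rownames(chars) <- selected
  nongap <- chars != "-"
  frac <- colMeans(nongap)
  columns <- which(frac >= min_ungapped_fraction)
  if (length(columns) == 0L)
    stop("empty conserved core: no alignment column is ungapped in all ",
         "selected sequences; revise the alignment or the selection")

  per_seq <- lapply(selected, function(nm) {
    ng <- nongap[nm, ]
    resno <- cumsum(ng)          # residue index at each column (if ungapped)
    idx <- ifelse(ng[columns], resno[columns], NA_integer_)
    as.integer(idx)
  })
  names(per_seq) <- selected
  structure(list(columns = as.integer(columns), per_seq = per_seq),
            class = "core_map")
}

#' @export
print.core_map <- function(x, ...) {
  cat("core_map: ", length(x$columns), " core columns, ",
      length(x$per_seq), " sequences\n", sep = "")
  cat("  columns: ", paste(utils::head(x$columns, 12L), collapse = " "),
      if (length(x$columns) > 12L) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.core_map <- function(x, ...) {
  data.frame(column = rep(x$columns, times = length(x$per_seq)),
             name = rep(names(x$per_seq), each = length(x$columns)),
             residue = unlist(x$per_seq, use.names = FALSE))
}

#' Write / read a core map as tab-separated text
#'
#' Format: a header row `column<TAB>c1<TAB>c2...` of 1-based alignment column
#' indices, then one row per sequence of residue indices. Round-trips
#' losslessly through [read_core_map()].
#'
#' @param core A `core_map`.
#' @param path Output path.
#' @export
write_core_map <- function(core, path) {
  stopifnot(inherits(core, "core_map"))
  lines <- c(paste(c("column", core$columns), collapse = "\t"),
             vapply(names(core$per_seq), function(nm)
               paste(c(nm, core$per_seq[[nm]]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_core_map
#' @return For `read_core_map`, a `core_map`.
#' @export
read_core_map <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("core map file has no sequence rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (fields[[1L]][1L] != "column") stop("malformed core map header in ", path)
  columns <- as.integer(fields[[1L]][-1L])
  per_seq <- lapply(fields[-1L], function(f) as.integer(f[-1L]))
  names(per_seq) <- vapply(fields[-1L], `[`, "", 1L)
  structure(list(columns = columns, per_seq = per_seq), class = "core_map")
}
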