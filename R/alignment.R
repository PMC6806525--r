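#' RNA multiple sequence alignment
#'
#' Lightweight container for a gapped RNA alignment. Sequences are stored as a
#' named character vector of equal-width gapped strings over `A C G U -`
#' (ambiguity codes such as `N` or `R` are tolerated and pass through).
#' Normalization applied on construction: uppercase, `T -> U`, `. -> -`.
#'
#' @param seqs Named character vector of gapped sequences.
#' @return An object of class `rna_alignment` with elements `names`, `seqs`
#'   (named character vector) and `width` (alignment length in columns).
#' @export
rna_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment has no records")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all alignment records must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate record names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- normalize_seq(seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- names(seqs)[w != w[1L]][1L]
    stop("ragged alignment: record '", bad, "' has width ", nchar(seqs[[bad]]),
         ", expected ", w[1L])
  }
  structure(list(names = names(seqs), seqs = seqs, width = unname(w[1L])),
            class = "rna_alignment")
}

normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("T.", "U-", x)
  x
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("rna_alignment: ", length(x$names), " sequences x ", x$width,
      " columns\n", sep = "")
  show <- utils::head(x$names, 6L)
  for (nm in show) {
    s <- x$seqs[[nm]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-20s %s\n", nm, s))
  }
  if (length(x$names) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.rna_alignment <- function(x, ...) {
  data.frame(name = x$names, seq = unname(x$seqs[x$names]),
             stringsAsFactors = FALSE)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA, Stockholm or Clustal file into an
#' [rna_alignment]. Parsing of the Stockholm and Clustal dialects is
#' delegated to Biostrings; `#=GC`/`#=GF` annotation lines are ignored.
#' Sequences are normalized (uppercase, `T -> U`, `. -> -`).
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"` (guess from the first line / extension),
#'   `"fasta"`, `"stockholm"`, `"clustal"`.
#' @return An [rna_alignment].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (file.size(path) == 0L) stop("alignment file is empty: ", path)
  if (format == "auto") format <- guess_aln_format(path)
  seqs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      if (length(ss) == 0L) stop("no records in ", path)
      out <- as.character(ss)
      # FASTA headers may carry descriptions; keep the first token as name
      names(out) <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1L)
      out
    },
    stockholm = ,
    clustal = {
      ma <- Biostrings::readAAMultipleAlignment(path, format = format)
      as.character(Biostrings::unmasked(ma))
    })
  rna_alignment(seqs)
}

guess_aln_format <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^# STOCKHOLM", first)) return("stockholm")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (grepl("^>", first)) return("fasta")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         sto = , stk = , stockholm = "stockholm",
         aln = , clustal = "clustal",
         "fasta")
}

#' Pairwise sequence identity on aligned rows
#'
#' Identity = matching columns / columns where at least one of the pair is
#' non-gap. A match requires identical unambiguous nucleotides (`A C G U`) in
#' both rows; ambiguity codes always count as mismatches. Gap-gap columns are
#' ignored. Returns 0 when the denominator is empty.
#'
#' @param a,b Gapped sequences of equal length.
#' @return Identity fraction in `[0, 1]`.
#' @export
pair_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  keep <- ca != "-" | cb != "-"
  if (!any(keep)) return(0)
  match <- ca == cb & ca %in% c("A", "C", "G", "U")
  sum(match & keep) / sum(keep)
}

#' Greedy redundancy reduction of an alignment
#'
#' Scans records in order; a record is dropped when its pairwise identity
#' with any already-kept record is at or above the threshold (see
#' [pair_identity] for the identity convention). Kept order is the original
#' record order, which makes the reduction deterministic.
#'
#' @param aln An [rna_alignment].
#' @param identity_threshold Fraction in `(0, 1]`; records at least this
#'   identical to a kept record are dropped. Default 0.9.
#' @return An [rna_alignment] with the kept records.
#' @export
reduce_redundancy <- function(aln, identity_threshold = 0.9) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  kept <- character(0)
  for (nm in aln$names) {
    dup <- FALSE
    for (k in kept) {
      if (pair_identity(aln$seqs[[nm]], aln$seqs[[k]]) >= identity_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, nm)
  }
  rna_alignment(aln$seqs[kept])
}
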