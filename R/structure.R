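#' RNA structure model
#'
#' One decoy or reference conformation. Residues are kept in chain order as
#' read (chains concatenated in file order); residue identity is positional,
#' not the PDB residue number, because decoys from different folding tools
#' renumber inconsistently and the core map indexes by position in the
#' ungapped sequence.
#'
#' @param residues List of residues, each a list with `res_name` (e.g. "A")
#'   and `atoms`, a numeric matrix with one row per atom (rownames = atom
#'   names, 3 columns = x, y, z in Angstrom).
#' @param model_id Identifier, conventionally `<homolog>_<rank>`.
#' @param homolog Alignment sequence name this model belongs to.
#' @param rank Energy rank within its homolog (1 = best).
#' @return An object of class `rna_model`.
#' @export
rna_model <- function(residues, model_id = "model", homolog = NA_character_,
                      rank = NA_integer_) {
  for (k in seq_along(residues)) {
    at <- residues[[k]]$atoms
    if (!is.matrix(at) || ncol(at) != 3L)
      stop("residue ", k, ": atoms must be an n x 3 matrix")
    if (!all(is.finite(at)))
      stop("residue ", k, ": non-finite coordinates")
    if (!"C3'" %in% rownames(at))
      stop("residue ", k, " (", residues[[k]]$res_name, ") lacks a C3' atom")
  }
  structure(list(model_id = model_id, homolog = homolog,
                 rank = as.integer(rank), residues = residues),
            class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  natoms <- sum(vapply(x$residues, function(r) nrow(r$atoms), 0L))
  cat("rna_model '", x$model_id, "': ", length(x$residues), " residues, ",
      natoms, " atoms", sep = "")
  if (!is.na(x$homolog)) cat(" (homolog ", x$homolog, ", rank ", x$rank, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Length of a model = number of residues
#' @param x An `rna_model`.
#' @export
length.rna_model <- function(x) length(x$residues)

#' Read one RNA model from a PDB file
#'
#' Parses ATOM records via bio3d. Conventions: HETATM ligands are skipped;
#' alternate locations keep blank or 'A' only; only the first MODEL of a
#' multi-model file is read; chains are concatenated in file order; atom
#' names are normalized to the prime convention (`C3*` becomes `C3'`).
#' Every residue must carry a C3' atom or the load fails, naming the
#' residue — models with missing core atoms cannot be traced and are
#' rejected at the door rather than mid-pipeline.
#'
#' @param path PDB file path.
#' @inheritParams rna_model
#' @return An [rna_model].
#' @export
read_pdb_model <- function(path, model_id = NULL, homolog = NA_character_,
                           rank = NA_integer_) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$elety <- gsub("*", "'", at$elety, fixed = TRUE)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(chain, at$resno, insert, sep = "|")
  # residue order = first-appearance order (chains in file order)
  key <- factor(key, levels = unique(key))
  idx <- split(seq_len(nrow(at)), key)
  residues <- lapply(seq_along(idx), function(k) {
    rows <- idx[[k]]
    xyz <- cbind(at$x[rows], at$y[rows], at$z[rows])
    rownames(xyz) <- at$elety[rows]
    rn <- trimws(at$resid[rows][1L])
    if (!"C3'" %in% rownames(xyz))
      stop("residue ", k, " (", rn, " ", at$resno[rows][1L], ", chain '",
           trimws(chain[rows][1L]), "') in ", basename(path), " lacks a C3' atom")
    list(res_name = rn, atoms = xyz)
  })
  if (is.null(model_id))
    model_id <- tools::file_path_sans_ext(basename(path))
  rna_model(residues, model_id = model_id, homolog = homolog, rank = rank)
}

#' Write an RNA model as a PDB file
#'
#' Fixed-width ATOM records, one chain "A", residues renumbered 1..n in
#' chain order, coordinates at the standard 3-decimal PDB precision.
#'
#' @param model An [rna_model].
#' @param path Output path.
#' @export
write_pdb_model <- function(model, path) {
  stopifnot(inherits(model, "rna_model"))
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(model$residues)) {
    r <- model$residues[[k]]
    anames <- rownames(r$atoms)
    for (a in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      nm <- anames[a]
      # element-aligned name field: 1-letter elements start in column 14
      namef <- if (nchar(nm) <= 3L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      elem <- substr(gsub("[^A-Za-z].*", "", nm), 1L, 1L)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namef, substr(r$res_name, 1L, 3L), "A", k,
        r$atoms[a, 1L], r$atoms[a, 2L], r$atoms[a, 3L], 1, 0, elem))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Sequence of a model from residue names
#' @param model An [rna_model].
#' @return Single-letter sequence string (first letter of each residue name).
#' @export
model_sequence <- function(model) {
  paste(vapply(model$residues, function(r) substr(r$res_name, 1L, 1L), ""),
        collapse = "")
}

#' Load a ranked, per-homolog decoy collection
#'
#' The mapping file links alignment sequence names to model files: two
#' tab-separated columns `sequence_name<TAB>filename_glob` (glob relative to
#' `models_dir`), or three columns `sequence_name<TAB>filename<TAB>rank` with
#' one line per file and an explicit energy rank. With globs, files sorted
#' lexicographically define rank order 1, 2, ... — decoy exports from
#' folding engines are number-named, so lexicographic order is the energy
#' order. Only the first `per_homolog_limit` models per homolog are kept.
#'
#' @param models_dir Directory holding the PDB decoys.
#' @param mapping Path to the mapping TSV.
#' @param per_homolog_limit Models retained per homolog (energy-best first).
#'   Default 100.
#' @param target Name of the target (reference) sequence; defaults to the
#'   first homolog in the mapping.
#' @return An object of class `model_set`: list with `models` (named list of
#'   [rna_model], grouped by homolog in mapping order, ranked within) and
#'   `target_name`.
#' @export
load_model_set <- function(models_dir, mapping, per_homolog_limit = 100,
                           target = NULL) {
  if (!dir.exists(models_dir)) stop("models directory not found: ", models_dir)
  if (!file.exists(mapping)) stop("mapping file not found: ", mapping)
  if (per_homolog_limit < 1) stop("per_homolog_limit must be >= 1")
  lines <- readLines(mapping)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty mapping file: ", mapping)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 2L)) stop("mapping line without a tab separator: ",
                           lines[ncol < 2L][1L])

  homologs <- vapply(fields, `[`, "", 1L)
  explicit_rank <- all(ncol >= 3L)
  if (!explicit_rank && anyDuplicated(homologs))
    stop("duplicate sequence_name in mapping: ",
         paste(unique(homologs[duplicated(homologs)]), collapse = ", "))

  per_hom <- if (explicit_rank) {
    sp <- split(seq_along(fields), factor(homologs, levels = unique(homologs)))
    lapply(sp, function(rows) {
      files <- vapply(fields[rows], `[`, "", 2L)
      ranks <- as.integer(vapply(fields[rows], `[`, "", 3L))
      files[order(ranks)]
    })
  } else {
    out <- lapply(fields, function(f)
      sort(basename(Sys.glob(file.path(models_dir, f[2L])))))
    names(out) <- homologs
    out
  }

  models <- list()
  for (h in names(per_hom)) {
    files <- per_hom[[h]]
    if (length(files) == 0L)
      stop("homolog '", h, "' has no matching model files in ", models_dir)
    files <- utils::head(files, per_homolog_limit)
    for (i in seq_along(files)) {
      m <- read_pdb_model(file.path(models_dir, files[i]),
                          model_id = tools::file_path_sans_ext(basename(files[i])),
                          homolog = h, rank = i)
      attr(m, "path") <- file.path(models_dir, files[i])
      models[[m$model_id]] <- m
    }
  }
  if (anyDuplicated(names(models)))
    stop("duplicate model ids across homologs: ",
         paste(unique(names(models)[duplicated(names(models))]), collapse = ", "))
  if (is.null(target)) target <- homologs[1L]
  if (!target %in% names(per_hom))
    stop("target '", target, "' is not a homolog in the mapping")
  structure(list(models = models, target_name = target), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  hom <- vapply(x$models, function(m) m$homolog, "")
  cat("model_set: ", length(x$models), " models, ",
      length(unique(hom)), " homologs (target: ", x$target_name, ")\n", sep = "")
  print(table(hom))
  invisible(x)
}

#' @export
length.model_set <- function(x) length(x$models)
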