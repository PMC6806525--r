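#' Residue-residue interaction set
#'
#' Canonical container for base-base interactions: a data frame with
#' columns `i`, `j` (1-based residue indices, `i < j`) and `kind`
#' (`"base_pair"` or `"stacking"`). Pairs are canonicalized (swapped to
#' `i < j`) and de-duplicated; self-pairs are rejected.
#'
#' @param i,j Integer residue indices.
#' @param kind Character vector, recycled, of interaction kinds.
#' @return Object of classes `interaction_set` and `data.frame`.
#' @export
interaction_set <- function(i = integer(0), j = integer(0),
                            kind = character(0)) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) stop("i and j must have equal length")
  kind <- if (length(i)) rep_len(as.character(kind), length(i))
          else character(0)
  if (any(i == j)) stop("self-pairs are not allowed")
  if (any(!kind %in% c("base_pair", "stacking")))
    stop("kind must be 'base_pair' or 'stacking'")
  lo <- pmin(i, j); hi <- pmax(i, j)
  df <- unique(data.frame(i = lo, j = hi, kind = kind,
                          stringsAsFactors = FALSE))
  df <- df[order(df$i, df$j, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_set", "data.frame")
  df
}

iset_keys <- function(x) paste(x$i, x$j, x$kind, sep = "|")

#' Interaction Network Fidelity
#'
#' `INF = sqrt( (TP / (TP + FP)) * (TP / (TP + FN)) )` — the geometric mean
#' of precision and recall over base-base interaction sets, where TP are
#' interactions present in both prediction and reference, FP those only in
#' the prediction and FN those only in the reference. The value is
#' undefined (returned as `NA`, never coerced to 0) when either denominator
#' is zero; the counts are always reported.
#'
#' @param pred,ref `interaction_set` objects over the same residue indexing.
#' @param kind Optional filter: compute over `"base_pair"` or `"stacking"`
#'   interactions only (default: all).
#' @return List with `inf` (fraction or `NA`), `tp`, `fp`, `fn`.
#' @export
inf_score <- function(pred, ref, kind = NULL) {
  stopifnot(inherits(pred, "interaction_set"), inherits(ref, "interaction_set"))
  if (!is.null(kind)) {
    pred <- pred[pred$kind == kind, , drop = FALSE]
    ref <- ref[ref$kind == kind, , drop = FALSE]
  }
  kp <- iset_keys(pred); kr <- iset_keys(ref)
  tp <- sum(kp %in% kr)
  fp <- length(kp) - tp
  fn <- length(kr) - tp
  inf <- if (tp + fp == 0L || tp + fn == 0L) NA_real_
         else sqrt((tp / (tp + fp)) * (tp / (tp + fn)))
  list(inf = inf, tp = tp, fp = fp, fn = fn)
}

#' Parse a dot-bracket secondary structure
#'
#' Matches `()`, `[]` and `{}` bracket layers independently (pseudoknot
#' layers); every matched pair becomes a `base_pair` interaction. Dots and
#' any other characters are unpaired.
#'
#' @param ss Dot-bracket string, or the path of a file whose first
#'   non-empty line is the structure.
#' @return An [interaction_set] of base pairs (1-based indices).
#' @export
parse_dotbracket <- function(ss) {
  if (!grepl("^[][(){}.]*$", ss)) {
    # not a bare structure string: treat as a file path
    if (!file.exists(ss)) stop("not a dot-bracket string and no such file: ", ss)
    lines <- readLines(ss)
    ss <- lines[nzchar(trimws(lines))][1L]
  }
  chars <- strsplit(ss, "")[[1L]]
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  stacks <- list("(" = integer(0), "[" = integer(0), "{" = integer(0))
  ii <- integer(0); jj <- integer(0)
  for (p in seq_along(chars)) {
    ch <- chars[p]
    if (ch %in% names(openers)) {
      stacks[[ch]] <- c(stacks[[ch]], p)
    } else if (ch %in% openers) {
      op <- names(openers)[openers == ch]
      if (length(stacks[[op]]) == 0L)
        stop("unbalanced dot-bracket: unmatched '", ch, "' at position ", p)
      ii <- c(ii, stacks[[op]][length(stacks[[op]])])
      jj <- c(jj, p)
      stacks[[op]] <- stacks[[op]][-length(stacks[[op]])]
    }
  }
  left <- vapply(stacks, length, 0L)
  if (any(left > 0L))
    stop("unbalanced dot-bracket: unmatched '",
         names(left)[left > 0L][1L], "' at position ",
         stacks[[names(left)[left > 0L][1L]]][1L])
  interaction_set(ii, jj, rep("base_pair", length(ii)))
}

#' Minimal geometric interaction detector
#'
#' A deliberately simple stand-in for a full base-pair classifier, used
#' when no annotated interactions are supplied. A `base_pair` is emitted
#' for residue pairs whose C1'-C1' distance falls in `bp_c1_range` and
#' whose closest Watson-Crick-edge donor/acceptor atom distance is below
#' `bp_edge_max`; `stacking` for sequence-nonadjacent pairs with base
#' centroid distance below `stack_dist_max` and base-plane normal angle
#' below `stack_angle_max` degrees. Residues missing the needed base atoms
#' are skipped with a warning. The thresholds are defaults, not a
#' reproduction of any trained classifier.
#'
#' @param model An [rna_model] with standard nucleotide atom names.
#' @param bp_c1_range C1'-C1' distance window for base pairs (Angstrom).
#' @param bp_edge_max Max WC-edge atom distance for base pairs (Angstrom).
#' @param stack_dist_max Max base-centroid distance for stacking (Angstrom).
#' @param stack_angle_max Max angle between base-plane normals (degrees).
#' @return An [interaction_set].
#' @export
detect_interactions <- function(model, bp_c1_range = c(8, 12),
                                bp_edge_max = 3.5, stack_dist_max = 5.5,
                                stack_angle_max = 30) {
  stopifnot(inherits(model, "rna_model"))
  wc_edge <- list(A = c("N1", "N6"), G = c("N1", "N2", "O6"),
                  C = c("N3", "N4", "O2"), U = c("N3", "O2", "O4"))
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  n <- length(model$residues)
  info <- vector("list", n)
  for (k in seq_len(n)) {
    r <- model$residues[[k]]
    at <- r$atoms
    base <- substr(r$res_name, nchar(r$res_name), nchar(r$res_name))
    edge_names <- intersect(wc_edge[[base]], rownames(at))
    ring_names <- intersect(ring, rownames(at))
    if (!"C1'" %in% rownames(at) || length(ring_names) < 3L) {
      warning("residue ", k, " (", r$res_name,
              "): missing base atoms, skipped in interaction detection")
      next
    }
    ringxyz <- at[ring_names, , drop = FALSE]
    centroid <- colMeans(ringxyz)
    normal <- svd(sweep(ringxyz, 2L, centroid))$v[, 3L]
    info[[k]] <- list(c1 = at["C1'", ], edge = at[edge_names, , drop = FALSE],
                      centroid = centroid, normal = normal)
  }
  ii <- integer(0); jj <- integer(0); kk <- character(0)
  for (a in seq_len(n - 1L)) {
    if (is.null(info[[a]])) next
    for (b in (a + 1L):n) {
      if (is.null(info[[b]])) next
      d_c1 <- sqrt(sum((info[[a]]$c1 - info[[b]]$c1)^2))
      if (d_c1 >= bp_c1_range[1L] && d_c1 <= bp_c1_range[2L] &&
          nrow(info[[a]]$edge) && nrow(info[[b]]$edge)) {
        dmin <- min(point_set_dist(info[[a]]$edge, info[[b]]$edge))
        if (dmin < bp_edge_max) {
          ii <- c(ii, a); jj <- c(jj, b); kk <- c(kk, "base_pair")
        }
      }
      if (b - a > 1L) {
        dc <- sqrt(sum((info[[a]]$centroid - info[[b]]$centroid)^2))
        if (dc < stack_dist_max) {
          cosang <- abs(sum(info[[a]]$normal * info[[b]]$normal))
          if (acos(pmin(1, cosang)) * 180 / pi < stack_angle_max) {
            ii <- c(ii, a); jj <- c(jj, b); kk <- c(kk, "stacking")
          }
        }
      }
    }
  }
  interaction_set(ii, jj, kk)
}

point_set_dist <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)),
        Vectorize(function(x, y) sqrt(sum((a[x, ] - b[y, ])^2))))
}

#' Read / write an interaction TSV (`i<TAB>j<TAB>kind`)
#' @param path File path.
#' @return An [interaction_set].
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("i", "j", "kind"),
                          stringsAsFactors = FALSE)
  interaction_set(df$i, df$j, df$kind)
}

#' @rdname read_interactions
#' @param x An [interaction_set].
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(unclass(x), stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Evaluate a predicted model against a reference structure
#'
#' Computes the metric family used to score predictions: all-heavy-atom
#' RMSD (only when the residue counts match — it is a target-vs-reference
#' metric), core RMSD over the conserved core (always defined), and INF.
#' Interaction sets for INF come from dot-bracket strings when provided,
#' otherwise from [detect_interactions()] on each structure. Sub-scores
#' over base pairs only and stacking only are reported alongside the
#' all-interaction INF.
#'
#' @param pred,ref [rna_model] objects (prediction and reference).
#' @param core A `core_map` covering both models' homologs.
#' @param pred_ss,ref_ss Optional dot-bracket strings (or one-line files).
#' @return Object of class `eval_report`: list with `model_id`,
#'   `rmsd_heavy` (or `NA`), `core_rmsd`, `inf_all`, `inf_bp`, `inf_stack`,
#'   `tp`, `fp`, `fn`.
#' @export
evaluate_model <- function(pred, ref, core, pred_ss = NULL, ref_ss = NULL) {
  stopifnot(inherits(pred, "rna_model"), inherits(ref, "rna_model"))
  rh <- if (length(pred$residues) == length(ref$residues))
    rmsd_heavy(pred, ref) else NA_real_
  cr <- core_rmsd(core_trace(pred, core), core_trace(ref, core))
  pset <- if (is.null(pred_ss)) detect_interactions(pred)
          else parse_dotbracket(pred_ss)
  rset <- if (is.null(ref_ss)) detect_interactions(ref)
          else parse_dotbracket(ref_ss)
  all <- inf_score(pset, rset)
  bp <- inf_score(pset, rset, kind = "base_pair")
  st <- inf_score(pset, rset, kind = "stacking")
  structure(list(model_id = pred$model_id, rmsd_heavy = rh, core_rmsd = cr,
                 inf_all = all$inf, inf_bp = bp$inf, inf_stack = st$inf,
                 tp = all$tp, fp = all$fp, fn = all$fn),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report for ", x$model_id, ":\n", sep = "")
  cat(sprintf("  rmsd_heavy = %s A\n",
              ifelse(is.na(x$rmsd_heavy), "NA", sprintf("%.3f", x$rmsd_heavy))))
  cat(sprintf("  core_rmsd  = %.3f A\n", x$core_rmsd))
  cat(sprintf("  inf_all    = %s (tp=%d fp=%d fn=%d)\n",
              ifelse(is.na(x$inf_all), "NA", sprintf("%.3f", x$inf_all)),
              x$tp, x$fp, x$fn))
  invisible(x)
}

#' Write an evaluation report as key=value lines (and optional CSV row)
#' @param report An `eval_report`.
#' @param path Output path.
#' @param format `"keyvalue"` or `"csv"` (one header + one row).
#' @export
write_eval_report <- function(report, path, format = c("keyvalue", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "eval_report"))
  vals <- unclass(report)
  if (format == "keyvalue") {
    writeLines(paste0(names(vals), "=",
                      vapply(vals, function(v) as.character(v)[1L], "")), path)
  } else {
    utils::write.csv(as.data.frame(vals, stringsAsFactors = FALSE), path,
                     row.names = FALSE)
  }
  invisible(path)
}
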