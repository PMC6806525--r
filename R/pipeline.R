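#' Run the full consensus pipeline
#'
#' Wires the stages end to end: read and normalize the alignment
#' (optionally reducing redundancy), load the ranked decoy sets, extract
#' the conserved core over the homologs present in the mapping, compute the
#' all-vs-all C3' core RMSD matrix, search the clustering cutoff
#' iteratively under the chosen stopping criterion, and select the final
#' model for the target sequence. Artifacts are written under `out_dir`:
#'
#' * `core_map.tsv`, `dist_matrix.txt`, `clusters.txt`, `selection.txt`
#' * `final_model.pdb` — a copy of the chosen decoy
#' * `run_config.txt` — the effective configuration, for provenance
#' * `evaluation.txt` — when a reference structure is supplied
#' * `clusters.clans` — when `clans_threshold` is set
#' * `run.log` — stage log including the terminating cutoff and sizes
#'
#' The pipeline is deterministic given its inputs: no stage draws random
#' numbers (only the synthetic generator takes a seed).
#'
#' @param alignment Path to the alignment (FASTA/Stockholm/Clustal).
#' @param models_dir Directory of decoy PDB files.
#' @param mapping Mapping TSV (see [load_model_set()]).
#' @param out_dir Output directory, created if needed.
#' @param target Target sequence name (default: first mapping entry).
#' @param per_homolog_limit Decoys kept per homolog (default 100).
#' @param mode Stopping criterion, `"one_of_six"` or `"half"`.
#' @param rule Selection rule, `"cluster_scan"` or `"max_neighbors"`.
#' @param start,step,max_cutoff Cutoff grid (Angstrom).
#' @param identity_threshold Optional redundancy threshold applied to the
#'   alignment before core extraction (e.g. 0.9); `NULL` skips reduction.
#' @param min_ungapped_fraction Core column rule (default 1: ungapped in
#'   all homologs).
#' @param reference Optional reference PDB path for evaluation.
#' @param ref_ss,pred_ss Optional dot-bracket strings/files for INF.
#' @param clans_threshold Optional CLANS connection threshold (Angstrom).
#' @return Invisibly, a list with `core`, `dm`, `clusters`, `selection`,
#'   `evaluation` (or `NULL`) and the artifact paths.
#' @export
run_pipeline <- function(alignment, models_dir, mapping, out_dir,
                         target = NULL, per_homolog_limit = 100,
                         mode = c("one_of_six", "half"),
                         rule = c("cluster_scan", "max_neighbors"),
                         start = 0.5, step = 0.5, max_cutoff = 50,
                         identity_threshold = NULL,
                         min_ungapped_fraction = 1,
                         reference = NULL, ref_ss = NULL, pred_ss = NULL,
                         clans_threshold = NULL) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  for (p in c(alignment, mapping)) if (!file.exists(p))
    stop("input file not found: ", p)
  if (!dir.exists(models_dir)) stop("models directory not found: ", models_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }

  cfg <- c(alignment = alignment, models_dir = models_dir, mapping = mapping,
           target = if (is.null(target)) "<first mapping entry>" else target,
           per_homolog_limit = per_homolog_limit, mode = mode, rule = rule,
           start = start, step = step, max_cutoff = max_cutoff,
           identity_threshold = if (is.null(identity_threshold)) "none"
                                else identity_threshold,
           min_ungapped_fraction = min_ungapped_fraction)
  writeLines(paste0(names(cfg), "=", cfg), file.path(out_dir, "run_config.txt"))

  say("stage alignment: reading ", alignment)
  aln <- read_alignment(alignment)
  if (!is.null(identity_threshold)) {
    n0 <- length(aln$names)
    aln <- reduce_redundancy(aln, identity_threshold)
    say("stage alignment: redundancy reduction kept ", length(aln$names),
        " of ", n0, " records")
  }

  say("stage models: loading decoys from ", models_dir)
  models <- load_model_set(models_dir, mapping,
                           per_homolog_limit = per_homolog_limit,
                           target = target)
  homs <- unique(vapply(models$models, function(m) m$homolog, ""))
  say("stage models: ", length(models$models), " models over ",
      length(homs), " homologs; target ", models$target_name)

  say("stage core: conserved core over ", length(homs), " sequences")
  core <- conserved_core(aln, selected = homs,
                         min_ungapped_fraction = min_ungapped_fraction)
  write_core_map(core, file.path(out_dir, "core_map.tsv"))
  say("stage core: ", length(core$columns), " core columns")

  say("stage matrix: all-vs-all core RMSD over ", length(models$models),
      " models")
  dm <- all_vs_all(models, core)
  write_dist_matrix(dm, file.path(out_dir, "dist_matrix.txt"))

  say("stage cluster: iterative search, mode ", mode)
  ranks <- vapply(models$models, function(m) m$rank, 0L)
  clusters <- autocluster(dm, mode = mode, start = start, step = step,
                          max_cutoff = max_cutoff, ranks = ranks)
  sizes <- cluster_sizes(clusters)
  say("stage cluster: terminated at cutoff ", clusters$cutoff, " A with ",
      length(sizes), " clusters; sizes ",
      paste(utils::head(sizes, 5L), collapse = " "),
      if (length(sizes) > 5L) " ...")
  write_cluster_report(clusters, file.path(out_dir, "clusters.txt"))

  say("stage select: rule ", rule)
  sel <- select_final(clusters, models, rule = rule, dm = dm)
  write_selection_report(sel, file.path(out_dir, "selection.txt"))
  say("stage select: chose ", sel$chosen, " from cluster ", sel$cluster_index)
  chosen_path <- attr(models$models[[sel$chosen]], "path")
  final_path <- file.path(out_dir, "final_model.pdb")
  if (!is.null(chosen_path) && file.exists(chosen_path)) {
    file.copy(chosen_path, final_path, overwrite = TRUE)
  } else {
    write_pdb_model(models$models[[sel$chosen]], final_path)
  }

  evaluation <- NULL
  if (!is.null(reference)) {
    say("stage eval: comparing ", sel$chosen, " to ", reference)
    ref_model <- read_pdb_model(reference, model_id = "reference",
                                homolog = models$target_name)
    evaluation <- evaluate_model(models$models[[sel$chosen]], ref_model,
                                 core, pred_ss = pred_ss, ref_ss = ref_ss)
    write_eval_report(evaluation, file.path(out_dir, "evaluation.txt"))
    say(sprintf("stage eval: core_rmsd %.3f A, inf_all %s",
                evaluation$core_rmsd,
                ifelse(is.na(evaluation$inf_all), "NA",
                       sprintf("%.3f", evaluation$inf_all))))
  }

  if (!is.null(clans_threshold)) {
    say("stage clans: exporting map at threshold ", clans_threshold, " A")
    groups <- vapply(models$models, function(m) m$homolog, "")
    doc <- to_clans(dm, groups, clans_threshold, target = models$target_name)
    write_clans(doc, file.path(out_dir, "clusters.clans"))
  }

  say("done")
  invisible(list(core = core, dm = dm, clusters = clusters, selection = sel,
                 evaluation = evaluation, out_dir = out_dir,
                 final_model = final_path))
}
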