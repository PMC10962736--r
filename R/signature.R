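# Cross-model signature derivation: direction-consistent shared DEG sets,
# k-of-n dependent-gene intersections, and cross-tissue / cross-species
# overlaps. All gene-set outputs are sorted lexicographically.

#' Stress DEGs shared by every model
#'
#' @param per_model_results Named list (>= 2 models) of [run_contrast()]
#'   tables over a common gene universe.
#' @param require_direction_consistency Require the same direction (up/down)
#'   in every model (default TRUE).
#' @return Sorted character vector of shared DEG gene ids.
#' @export
shared_degs <- function(per_model_results, require_direction_consistency = TRUE) {
  if (length(per_model_results) < 2L) {
    contract_error("shared_degs() needs >= 2 models, got %d", length(per_model_results))
  }
  sets <- lapply(per_model_results, function(r) r$gene_id[r$is_deg])
  shared <- Reduce(intersect, sets)
  if (require_direction_consistency && length(shared)) {
    dirs <- vapply(per_model_results, function(r) {
      r$direction[match(shared, r$gene_id)]
    }, character(length(shared)))
    dirs <- matrix(dirs, nrow = length(shared))
    consistent <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
    shared <- shared[consistent]
  }
  sort(shared)
}

#' Genes dependent in exactly k of n models
#'
#' The n-of-n set is the core signature; sets for `k < n` are "additional"
#' and exclude genes dependent in more than `k` models.
#'
#' @param per_model_dependence Named list of dependence tables from
#'   [classify_dependent()].
#' @param k Number of models (1 <= k <= n).
#' @return Sorted character vector of gene ids dependent in exactly `k`
#'   models.
#' @export
k_of_n_dependent <- function(per_model_dependence, k) {
  n <- length(per_model_dependence)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    validation_error("k must be in 1..%d, got %s", n, format(k))
  }
  dep_sets <- lapply(per_model_dependence, function(r) r$gene_id[r$is_dependent])
  counts <- table(unlist(dep_sets))
  sort(names(counts)[counts == k])
}

#' Overlap of a signature with a dependent set from another tissue
#'
#' @param signature Non-empty character vector of signature gene ids.
#' @param other_tissue_dependent Character vector of dependent gene ids in
#'   the other tissue.
#' @return List with `overlap` (sorted gene ids), `n_overlap`,
#'   `n_signature`, and `fraction_pct` (percent of the signature found,
#'   full precision).
#' @export
tissue_overlap <- function(signature, other_tissue_dependent) {
  if (!length(signature)) contract_error("tissue_overlap() needs a non-empty signature")
  ov <- sort(intersect(signature, other_tissue_dependent))
  list(overlap = ov, n_overlap = length(ov), n_signature = length(signature),
       fraction_pct = 100 * length(ov) / length(signature))
}

#' Signature genes whose human ortholog is upregulated across studies
#'
#' Maps each signature gene through a one-to-one ortholog table and keeps
#' genes whose ortholog's mean linear fold change across the study columns is
#' at least `min_mean_fc` (inclusive). Genes missing from some studies are
#' averaged over the available studies and flagged; unmapped genes are
#' excluded with a warning and counted.
#'
#' @param signature Character vector of (mouse) signature gene ids.
#' @param ortholog_map data.frame with columns `mouse_gene`, `human_gene`,
#'   one-to-one on the signature genes considered.
#' @param study_fc data.frame with column `human_gene` plus one numeric
#'   column per study of linear fold changes; NA = gene not measured in that
#'   study.
#' @param min_mean_fc Mean linear fold-change cutoff (default 2).
#' @param average `"arithmetic"` (default) or `"geometric"` mean of linear
#'   fold changes.
#' @return List with `genes` (sorted passing mouse gene ids), `table`
#'   (per-gene mouse/human ids, mean fold change, `n_studies`,
#'   `partial` flag), and `n_unmapped`.
#' @export
cross_species_overlap <- function(signature, ortholog_map, study_fc,
                                  min_mean_fc = 2,
                                  average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (anyDuplicated(ortholog_map$mouse_gene) || anyDuplicated(ortholog_map$human_gene)) {
    validation_error("ortholog map must be one-to-one")
  }
  human <- ortholog_map$human_gene[match(signature, ortholog_map$mouse_gene)]
  unmapped <- signature[is.na(human)]
  if (length(unmapped)) {
    warning(sprintf("%d signature gene(s) without an ortholog: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 10), collapse = ", ")),
            call. = FALSE)
  }
  mouse <- signature[!is.na(human)]
  human <- human[!is.na(human)]
  study_cols <- setdiff(names(study_fc), "human_gene")
  fc <- as.matrix(study_fc[match(human, study_fc$human_gene), study_cols,
                           drop = FALSE])
  n_studies <- rowSums(!is.na(fc))
  mean_fc <- if (average == "arithmetic") {
    rowMeans(fc, na.rm = TRUE)
  } else {
    exp(rowMeans(log(fc), na.rm = TRUE))
  }
  mean_fc[n_studies == 0] <- NA_real_
  tab <- data.frame(mouse_gene = mouse, human_gene = human,
                    mean_fc = mean_fc, n_studies = n_studies,
                    partial = n_studies > 0 & n_studies < length(study_cols),
                    stringsAsFactors = FALSE)
  pass <- !is.na(tab$mean_fc) & tab$mean_fc >= min_mean_fc
  list(genes = sort(tab$mouse_gene[pass]), table = tab,
       n_unmapped = length(unmapped))
}

#' Per-gene signature membership report across models
#'
#' Combines per-model DEG and dependence calls into one table with per-model
#' flags, model counts, core membership (dependent in all models) and
#' exactly-k partial membership.
#'
#' @param per_model_results Named list of [run_contrast()] tables.
#' @param per_model_dependence Named list of [classify_dependent()] tables
#'   (same model names).
#' @param k Partial-membership count of interest (default `n - 1`).
#' @return data.frame, one row per gene ever called a stress DEG, sorted by
#'   gene id: per-model `deg_<model>` / `dep_<model>` flags,
#'   `n_models_deg`, `n_models_dependent`, `in_core`, `in_partial_k`.
#' @export
signature_report <- function(per_model_results, per_model_dependence,
                             k = length(per_model_results) - 1L) {
  models <- names(per_model_results)
  if (!setequal(models, names(per_model_dependence))) {
    contract_error("model names differ between DEG and dependence tables")
  }
  genes <- sort(unique(unlist(lapply(per_model_results,
                                     function(r) r$gene_id[r$is_deg]))))
  rep <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in models) {
    r <- per_model_results[[m]]
    d <- per_model_dependence[[m]]
    rep[[paste0("deg_", m)]] <- genes %in% r$gene_id[r$is_deg]
    rep[[paste0("dep_", m)]] <- genes %in% d$gene_id[d$is_dependent]
  }
  deg_cols <- paste0("deg_", models)
  dep_cols <- paste0("dep_", models)
  rep$n_models_deg <- rowSums(as.matrix(rep[deg_cols]))
  rep$n_models_dependent <- rowSums(as.matrix(rep[dep_cols]))
  rep$in_core <- rep$n_models_dependent == length(models)
  rep$in_partial_k <- rep$n_models_dependent == k & !rep$in_core
  rep
}

#' Fraction of each model's stress DEGs that are dependent
#'
#' @param per_model_dependence Named list of [classify_dependent()] tables.
#' @return data.frame with `model`, `n_deg`, `n_dependent`, `pct_dependent`.
#' @export
dependent_fraction <- function(per_model_dependence) {
  do.call(rbind, lapply(names(per_model_dependence), function(m) {
    d <- per_model_dependence[[m]]
    n_deg <- sum(d$is_stress_deg)
    n_dep <- sum(d$is_dependent)
    data.frame(model = m, n_deg = n_deg, n_dependent = n_dep,
               pct_dependent = 100 * n_dep / n_deg, stringsAsFactors = FALSE)
  }))
}
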