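# Modifier-dependence classification: a stress DEG is called dependent when
# the knockout contrast (stress,KO vs stress,WT) passes the same
# fold-change/FDR gates with a fold change opposite in direction to the
# stress effect, i.e. knockout reverts the response toward control. Percent
# dependence quantifies the reverted fraction.

#' Percent dependence of a stress effect on the modifier
#'
#' Fraction of a gene's stress-induced change reverted by modifier knockout,
#' as a percent. Two definitions:
#' \describe{
#'   \item{log2 (default)}{`100 * (-lfc_ko) / lfc_stress`. Full reversion on
#'     the log scale gives exactly 100; no reversion gives 0; overshoot
#'     exceeds 100 and co-directional change is negative.}
#'   \item{linear}{fraction of the linear-scale change from control that is
#'     reverted: `100 * (2^ls - 2^(ls + lk)) / (2^ls - 1)` with
#'     `ls = lfc_stress`, `lk = lfc_ko`. Also 100 at full reversion, for
#'     up- and down-regulated genes alike.}
#' }
#'
#' @param lfc_stress Log2 fold change, stress/modifier+ vs control.
#' @param lfc_ko Log2 fold change, stress/modifierKO vs stress/modifier+.
#' @param definition `"log2"` or `"linear"`.
#' @return Percent dependence (vectorised); `NaN` where `lfc_stress` is 0
#'   (undefined dependence).
#' @examples
#' percent_dependence(2, -2)    # 100
#' percent_dependence(2, -1.5)  # 75
#' @export
percent_dependence <- function(lfc_stress, lfc_ko,
                               definition = c("log2", "linear")) {
  definition <- match.arg(definition)
  out <- if (definition == "log2") {
    100 * (-lfc_ko) / lfc_stress
  } else {
    100 * (2^lfc_stress - 2^(lfc_stress + lfc_ko)) / (2^lfc_stress - 1)
  }
  out[lfc_stress == 0] <- NaN
  out
}

#' Classify stress DEGs as modifier-dependent
#'
#' Intersects two contrasts over the same gene universe: stress vs control
#' (in the modifier+ background) and stress/KO vs stress/modifier+. A stress
#' DEG is dependent when the KO contrast is itself a DEG at the same gates
#' and its fold change opposes the stress fold change. One record is emitted
#' per stress DEG; percent dependence is attached for every stress DEG
#' regardless of the dependence call (set `all_genes = TRUE` to keep
#' non-DEGs too).
#'
#' @param stress_results,ko_results Contrast tables from [run_contrast()]
#'   over identical gene universes.
#' @param pct_definition Percent-dependence definition, see
#'   [percent_dependence()].
#' @param model Optional model name recorded in the output.
#' @param all_genes Keep records for non-stress-DEG genes (default FALSE).
#' @return data.frame with columns `gene_id`, `model`, `lfc_stress`,
#'   `lfc_ko`, `q_stress`, `q_ko`, `is_stress_deg`, `is_dependent`,
#'   `pct_dependence`, `pct_definition`.
#' @export
classify_dependent <- function(stress_results, ko_results,
                               pct_definition = c("log2", "linear"),
                               model = NA_character_, all_genes = FALSE) {
  pct_definition <- match.arg(pct_definition)
  if (!setequal(stress_results$gene_id, ko_results$gene_id)) {
    diff <- c(setdiff(stress_results$gene_id, ko_results$gene_id),
              setdiff(ko_results$gene_id, stress_results$gene_id))
    contract_error("gene universes differ between contrasts: %s",
                   paste(utils::head(diff, 10), collapse = ", "))
  }
  ko <- ko_results[match(stress_results$gene_id, ko_results$gene_id), ]
  rec <- data.frame(
    gene_id = stress_results$gene_id,
    model = model,
    lfc_stress = stress_results$log2fc,
    lfc_ko = ko$log2fc,
    q_stress = stress_results$q,
    q_ko = ko$q,
    is_stress_deg = stress_results$is_deg,
    stringsAsFactors = FALSE)
  rec$is_dependent <- rec$is_stress_deg & ko$is_deg &
    sign(rec$lfc_ko) == -sign(rec$lfc_stress) & rec$lfc_stress != 0
  rec$pct_dependence <- percent_dependence(rec$lfc_stress, rec$lfc_ko,
                                           pct_definition)
  rec$pct_definition <- pct_definition
  if (!all_genes) rec <- rec[rec$is_stress_deg, ]
  rownames(rec) <- NULL
  rec
}

#' Shared-DEG set passing a percent-dependence cutoff in every model
#'
#' Alternative dependent-set definition: among DEGs shared by all models,
#' keep the genes whose percent dependence is at least `cutoff` (inclusive)
#' in every model.
#'
#' @param shared_degs Character vector of shared stress-DEG gene ids.
#' @param records_by_model Named list of dependence tables from
#'   [classify_dependent()], one per model.
#' @param cutoff Percent-dependence cutoff (default 50).
#' @return Sorted character vector of gene ids.
#' @export
threshold_dependent_set <- function(shared_degs, records_by_model, cutoff = 50) {
  keep <- rep(TRUE, length(shared_degs))
  for (m in names(records_by_model)) {
    rec <- records_by_model[[m]]
    idx <- match(shared_degs, rec$gene_id)
    if (anyNA(idx)) {
      contract_error("model '%s' lacks dependence records for: %s", m,
                     paste(utils::head(shared_degs[is.na(idx)], 10), collapse = ", "))
    }
    keep <- keep & rec$pct_dependence[idx] >= cutoff
  }
  sort(shared_degs[keep])
}
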