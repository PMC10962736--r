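# Two-group differential expression: pooled-variance t tests, BH FDR, and
# DEG calling at configurable fold-change / FDR thresholds. Expression is
# assumed to be on the log2 scale throughout.

#' Two-tailed pooled-variance t test
#'
#' Classic two-sample t statistic with the pooled variance estimate,
#' `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))`, on
#' `n_a + n_b - 2` degrees of freedom, with a two-tailed p value.
#'
#' When the pooled variance is exactly zero the statistic is degenerate:
#' equal means give `t = 0, p = 1`; unequal means give `p = 0` (infinite
#' statistic) with a warning, since any nonzero difference is then
#' incompatible with the (zero-noise) null.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A list with components `t`, `df`, `p`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
pooled_t_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    validation_error("pooled_t_test() needs >= 2 values per group (got %d and %d)",
                     length(values_a), length(values_b))
  }
  na <- length(values_a); nb <- length(values_b)
  df <- na + nb - 2L
  diff <- mean(values_a) - mean(values_b)
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    if (diff == 0) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; p = 0", call. = FALSE)
    return(list(t = sign(diff) * Inf, df = df, p = 0))
  }
  t <- diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment; the returned vector is in the
#' input order. `{q <= alpha}` is exactly the classic BH rejection set at
#' level `alpha`; tied p values share a q value.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of q values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    validation_error("p values must be numeric in [0, 1] with no NA")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run one two-group contrast over an expression matrix
#'
#' Computes, per gene, the log2 fold change `mean(group_a) - mean(group_b)`,
#' the pooled-variance t statistic and two-tailed p value, BH q values across
#' all genes in the matrix, and a DEG call requiring both
#' `|log2fc| >= log2(fc_threshold)` and `q <= fdr_threshold` (inclusive
#' bounds by default; `strict = TRUE` uses strict inequalities).
#'
#' @param matrix Numeric genes x samples matrix of log2 expression, with
#'   rownames (gene ids, unique) and colnames (sample ids).
#' @param group_a,group_b Character vectors of sample ids (disjoint, each of
#'   length >= 2, all present as matrix columns). `group_a` is the numerator
#'   arm, e.g. stress; `group_b` the reference, e.g. control.
#' @param fc_threshold Linear fold-change threshold (default 2, i.e.
#'   `|log2fc| >= 1`).
#' @param fdr_threshold BH FDR threshold (default 0.05).
#' @param strict Use strict inequalities at both thresholds (default FALSE).
#' @return A data.frame with columns `gene_id`, `log2fc`, `t`, `df`, `p`,
#'   `q`, `is_deg`, `direction` (`"up"`/`"down"`/`"none"`), one row per gene
#'   in matrix row order.
#' @export
run_contrast <- function(matrix, group_a, group_b,
                         fc_threshold = 2, fdr_threshold = 0.05,
                         strict = FALSE) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    validation_error("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) {
    validation_error("duplicate gene ids in expression matrix: %s",
                     paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
                           collapse = ", "))
  }
  missing <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(missing)) {
    contract_error("samples absent from matrix: %s", paste(missing, collapse = ", "))
  }
  if (length(intersect(group_a, group_b))) {
    validation_error("contrast groups overlap: %s",
                     paste(intersect(group_a, group_b), collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    validation_error("each contrast group needs >= 2 samples")
  }
  if (fc_threshold <= 0 || fdr_threshold <= 0) {
    validation_error("thresholds must be positive")
  }

  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  df <- na + nb - 2L
  ma <- rowMeans(a); mb <- rowMeans(b)
  lfc <- ma - mb
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  q <- bh_fdr(p)

  lfc_cut <- log2(fc_threshold)
  pass_fc <- if (strict) abs(lfc) > lfc_cut else abs(lfc) >= lfc_cut
  pass_q <- if (strict) q < fdr_threshold else q <= fdr_threshold
  is_deg <- pass_fc & pass_q
  direction <- ifelse(!is_deg, "none", ifelse(lfc > 0, "up", "down"))

  data.frame(gene_id = rownames(matrix), log2fc = lfc, t = t, df = df,
             p = p, q = q, is_deg = is_deg, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build arm-wise sample groups from a sample sheet
#'
#' Convenience accessor: returns the sample ids of one design arm within one
#' model. Heterozygous modifier samples are handled upstream by how the
#' sample sheet codes `genotype` (e.g. pooling `+/-` with `+/+` as `"wt"`).
#'
#' @param samples Sample-sheet data.frame with columns `sample_id`, `model`,
#'   `arm` (one of `"control"`, `"stress_wt"`, `"stress_ko"`).
#' @param model Model name.
#' @param arm Arm name.
#' @return Character vector of sample ids.
#' @export
arm_samples <- function(samples, model, arm) {
  need <- c("sample_id", "model", "arm")
  if (!all(need %in% names(samples))) {
    validation_error("sample sheet must have columns: %s", paste(need, collapse = ", "))
  }
  samples$sample_id[samples$model == model & samples$arm == arm]
}
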