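# Readers/writers and the pipeline driver. Canonical tabular dialect: TSV,
# UTF-8, '#'-prefixed header comment lines (used to stamp the config hash).

#' Read an expression matrix and sample sheet
#'
#' @param matrix_path Genes x samples TSV; first column `gene_id`, remaining
#'   columns one per sample. Values are assumed log2 scale.
#' @param samples_path Sample-sheet TSV with at least `sample_id`, `model`,
#'   `arm`.
#' @return List with `matrix` (numeric matrix, gene rownames) and `samples`
#'   (data.frame).
#' @export
read_expression <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") {
    validation_error("matrix TSV must start with a 'gene_id' column")
  }
  if (anyDuplicated(tab$gene_id)) {
    validation_error("duplicate gene ids in %s: %s", matrix_path,
                     paste(unique(tab$gene_id[duplicated(tab$gene_id)]),
                           collapse = ", "))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) validation_error("non-numeric expression values in %s", matrix_path)
  rownames(mat) <- tab$gene_id
  samples <- utils::read.delim(samples_path, comment.char = "#",
                               stringsAsFactors = FALSE)
  missing <- setdiff(samples$sample_id, colnames(mat))
  if (length(missing)) {
    validation_error("sample(s) in sheet absent from matrix: %s",
                     paste(missing, collapse = ", "))
  }
  list(matrix = mat, samples = samples)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param fixture List with `matrix` and `samples` (as returned by
#'   [generate_expression_fixture()]).
#' @param matrix_path,samples_path Output paths.
#' @param comment Optional '#'-prefixed header comment line(s).
#' @export
write_expression <- function(fixture, matrix_path, samples_path, comment = NULL) {
  tab <- data.frame(gene_id = rownames(fixture$matrix), fixture$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, matrix_path, comment)
  write_tsv(fixture$samples, samples_path, comment)
  invisible(NULL)
}

#' Write a data.frame as commented TSV
#' @param x data.frame.
#' @param path Output path.
#' @param comment Optional comment line(s), written '#'-prefixed.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read / write 16-bit single-channel TIFF label masks
#'
#' Labels are stored as 16-bit unsigned integers (so at most 65535 labels).
#'
#' @param labels Integer matrix.
#' @param path File path.
#' @return `read_mask()` returns an integer matrix.
#' @export
write_mask <- function(labels, path) {
  if (any(labels < 0) || any(labels > 65535)) {
    validation_error("labels must fit 16-bit unsigned range")
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "integer"
  img
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of the run configuration (see
#'   [run_pipeline()]).
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the expression pipeline end to end
#'
#' Executes differential expression (stress vs control and KO vs stress per
#' model), dependence classification, and signature derivation, writing one
#' TSV per stage plus a JSON summary and a run manifest. Every output file
#' carries the config hash in a header comment; identical config + inputs
#' give identical outputs.
#'
#' @param config Named list: `matrix_path` + `samples_path` (or `fixture`, a
#'   generated fixture list), `outdir`, and optionally `fc_threshold` (2),
#'   `fdr_threshold` (0.05), `dependence_cutoff` (50), `pct_definition`
#'   (`"log2"`), `direction_consistency` (TRUE), `seed` (1).
#' @return Invisible list with per-model contrast tables (`stress`, `ko`),
#'   `dependence`, `shared`, `core`, `report`, `summary`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(fc_threshold = 2, fdr_threshold = 0.05,
                   dependence_cutoff = 50, pct_definition = "log2",
                   direction_consistency = TRUE, seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (config$fc_threshold <= 0 || config$fdr_threshold <= 0 ||
      config$dependence_cutoff <= 0) {
    validation_error("thresholds must be positive")
  }
  if (is.null(config$outdir)) validation_error("config$outdir is required")

  if (!is.null(config$fixture)) {
    mat <- config$fixture$matrix
    samples <- config$fixture$samples
  } else {
    inp <- read_expression(config$matrix_path, config$samples_path)
    mat <- inp$matrix
    samples <- inp$samples
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  # hash the analytic parameters only, so relocating outputs keeps identity
  hash <- config_hash(config[setdiff(names(config), c("fixture", "outdir"))])
  stamp <- paste0("config_hash: ", hash)

  models <- unique(samples$model)
  stress <- list(); ko <- list(); dep <- list()
  for (m in models) {
    stress[[m]] <- run_contrast(mat,
                                arm_samples(samples, m, "stress_wt"),
                                arm_samples(samples, m, "control"),
                                config$fc_threshold, config$fdr_threshold)
    ko[[m]] <- run_contrast(mat,
                            arm_samples(samples, m, "stress_ko"),
                            arm_samples(samples, m, "stress_wt"),
                            config$fc_threshold, config$fdr_threshold)
    dep[[m]] <- classify_dependent(stress[[m]], ko[[m]],
                                   pct_definition = config$pct_definition,
                                   model = m)
    write_tsv(stress[[m]], file.path(config$outdir, paste0("de_stress_", m, ".tsv")), stamp)
    write_tsv(ko[[m]], file.path(config$outdir, paste0("de_ko_", m, ".tsv")), stamp)
    write_tsv(dep[[m]], file.path(config$outdir, paste0("dependence_", m, ".tsv")), stamp)
  }

  out <- list(stress = stress, ko = ko, dependence = dep)
  if (length(models) >= 2L) {
    shared <- shared_degs(stress, config$direction_consistency)
    core <- k_of_n_dependent(dep, length(models))
    report <- signature_report(stress, dep)
    thr <- threshold_dependent_set(shared, dep, config$dependence_cutoff)
    frac <- dependent_fraction(dep)
    summary <- list(n_shared_degs = length(shared), n_core = length(core),
                    n_threshold_set = length(thr),
                    dependent_fraction = frac)
    write_tsv(report, file.path(config$outdir, "signature_report.tsv"), stamp)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out <- c(out, list(shared = shared, core = core, report = report,
                       summary = summary))
  }
  manifest <- list(config_hash = hash,
                   config = config[setdiff(names(config), "fixture")],
                   models = models,
                   package_version = as.character(utils::packageVersion("mtisr")))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  out$manifest_path <- manifest_path
  invisible(out)
}

#' Load the shipped synthetic cross-species fixture
#'
#' A fixed (seed-free) ortholog map and three-study human fold-change table,
#' both synthetic, shipped as TSV under `inst/extdata`.
#'
#' @return List with `ortholog_map` (`mouse_gene`, `human_gene`) and
#'   `study_fc` (`human_gene`, `study1`..`study3`, linear fold changes, NA =
#'   not measured).
#' @export
load_cross_species_fixture <- function() {
  dir <- system.file("extdata", package = "mtisr")
  list(ortholog_map = read_tsv(file.path(dir, "orthologs_synthetic.tsv")),
       study_fc = read_tsv(file.path(dir, "human_study_fc_synthetic.tsv")))
}
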