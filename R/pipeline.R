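#' Configuration for an end-to-end pipeline run
#'
#' Collects the input paths and parameters for [run_pipeline()]. Annotation
#' format is chosen by extension (`.gff`/`.gff3` vs `.bed`). The expression
#' matrix and the validation dataset are optional; omitting them yields a
#' classification-only run.
#'
#' @param annotation Path to the gene annotation (GFF3 or BED6).
#' @param cov_plus,cov_minus Paths to per-strand bedGraph coverage.
#' @param expression Optional path to a log2 expression TSV.
#' @param validate_annotation,validate_cov_plus,validate_cov_minus Optional
#'   second dataset for cross-dataset confirmation of convergent pairs.
#' @param params A [utr_call_params()] list.
#' @param n_perm Permutations per condition for [pair_correlation()].
#' @param seed Integer seed recorded in the manifest and used for the
#'   permutation tests.
#' @param out_dir Output directory (created if absent).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, cov_plus, cov_minus,
                            expression = NULL,
                            validate_annotation = NULL,
                            validate_cov_plus = NULL,
                            validate_cov_minus = NULL,
                            params = utr_call_params(), n_perm = 10000,
                            seed = 1, out_dir = "convpairs_out") {
  structure(list(
    annotation = annotation, cov_plus = cov_plus, cov_minus = cov_minus,
    expression = expression, validate_annotation = validate_annotation,
    validate_cov_plus = validate_cov_plus,
    validate_cov_minus = validate_cov_minus,
    params = params, n_perm = n_perm, seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; UTR-calling
#' parameters sit under a `params:` mapping.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(utr_call_params, y$params %||% list())
  pipeline_config(
    annotation = y$annotation, cov_plus = y$cov_plus, cov_minus = y$cov_minus,
    expression = y$expression,
    validate_annotation = y$validate_annotation,
    validate_cov_plus = y$validate_cov_plus,
    validate_cov_minus = y$validate_cov_minus,
    params = params,
    n_perm = y$n_perm %||% 10000,
    seed = y$seed %||% 1,
    out_dir = y$out_dir %||% "convpairs_out"
  )
}

read_annotation_any <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) read_bed(path)
  else read_gff(path)
}

stage_msg <- function(...) message("[convpairs] ", ...)

#' Run the full analysis pipeline
#'
#' Stages: read annotation and per-strand coverage, call UTRs, classify
#' adjacent pairs, correlate convergent-pair expression per condition (when
#' an expression matrix is configured), and confirm pairs in a second
#' dataset (when one is configured). All stage outputs are written under
#' `out_dir` (`models.tsv`, `pairs.tsv`, `summary.json`,
#' `correlations.tsv`, `validation.tsv`, `validation_summary.json`) together
#' with `manifest.json` recording package version, parameters, seed and
#' input checksums — enough to reproduce the run. Outputs are pure functions
#' of (inputs, parameters, seed). Progress is logged to stderr; results are
#' never written there.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  inputs <- c(config$annotation, config$cov_plus, config$cov_minus,
              config$expression, config$validate_annotation,
              config$validate_cov_plus, config$validate_cov_minus)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    abort(paste0("missing input file(s): ", paste(missing_in, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  stage_msg("reading annotation: ", config$annotation)
  annot <- read_annotation_any(config$annotation)
  stage_msg("reading coverage: ", config$cov_plus, ", ", config$cov_minus)
  cov <- read_strand_coverage(config$cov_plus, config$cov_minus,
                              chrom_lengths = chrom_lengths(annot))

  stage_msg("calling UTRs for ", nrow(annot), " genes")
  t0 <- proc.time()["elapsed"]
  models <- call_utrs(annot, cov, config$params)
  write_models(models, out("models.tsv"))
  stage_msg("UTRs called in ", round(proc.time()["elapsed"] - t0, 1), "s")

  stage_msg("classifying adjacent pairs")
  pairs <- classify_pairs(models)
  write_pairs(pairs, out("pairs.tsv"))
  summary <- summarize_pairs(pairs, annot)
  jsonlite::write_json(as.list(summary), out("summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "convpairs",
    version = as.character(utils::packageVersion("convpairs")),
    seed = config$seed,
    n_perm = config$n_perm,
    params = unclass(config$params),
    inputs = as.list(tools::md5sum(inputs)),
    utr_summary = as.list(utr_call_summary(models)),
    pair_summary = as.list(summary)
  )

  conv <- pairs[pairs$class == "convergent", ]
  if (!is.null(config$expression)) {
    stage_msg("correlating convergent-pair expression per condition")
    expr <- read_expression(config$expression)
    cors <- correlate_all_conditions(conv, expr, n_perm = config$n_perm,
                                     seed = config$seed)
    readr::write_tsv(tidy(cors), out("correlations.tsv"))
    manifest$correlation_summary <- as.list(glance(cors))
  }

  if (!is.null(config$validate_annotation)) {
    stage_msg("confirming convergent pairs in second dataset")
    v_annot <- read_annotation_any(config$validate_annotation)
    v_cov <- read_strand_coverage(config$validate_cov_plus,
                                  config$validate_cov_minus,
                                  chrom_lengths = chrom_lengths(v_annot))
    records <- validate_pairs(conv, v_annot, v_cov, config$params)
    readr::write_tsv(records, out("validation.tsv"))
    vsum <- summarize_validation(records)
    jsonlite::write_json(as.list(vsum), out("validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$validation_summary <- as.list(vsum)
  }

  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg("done; outputs in ", config$out_dir)
  invisible(manifest)
}
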