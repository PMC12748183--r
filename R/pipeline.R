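## Pipeline orchestration: run selected analysis stages on file inputs and
## write delimited reports plus a run manifest, so a whole assessment is one
## reproducible call. Diagnostics go to stderr via message(); data only to
## files.

## internal: deterministic CSV writer (fixed significant digits so repeated
## runs with one seed are byte-identical)
write_report <- function(df, path, digits = 12) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## internal: flat key-value manifest
write_manifest <- function(path, entries) {
  lines <- vapply(names(entries), function(k)
    sprintf("%s: %s", k, paste(entries[[k]], collapse = ",")),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Run the assessment pipeline
#'
#' Executes the requested stages and writes one delimited report per output
#' table under `out_dir`, plus `manifest.txt` recording parameters, seed,
#' package version and input digests. Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic pot experiment with
#'     [generate_experiment()] and write `indicators.csv`.}
#'   \item{aggregate}{compute stability indices from a sieve-fraction CSV
#'     (`sample, mode, <class columns>`; one dry and one wet row per
#'     sample).}
#'   \item{roughness}{chain roughness from a CSV of `sample, L1, L2` rows,
#'     averaged per sample.}
#'   \item{sqi}{full minimum-data-set SQI on the indicator table.}
#'   \item{gra}{grey relational analysis on the indicator table.}
#'   \item{effects}{control-relative effect table on the indicator table.}
#'   \item{reference_effects}{effect tables recomputed from the bundled
#'     published pot-experiment means.}
#' }
#' `"all"` runs simulate then sqi, gra and effects on the simulated table.
#'
#' @param stages character vector of stage names, or `"all"`.
#' @param out_dir output directory (created if needed).
#' @param indicator_table path to an indicator CSV (required by sqi/gra/
#'   effects unless simulate runs first in the same call).
#' @param config list read from [read_indicator_config()] giving `spec` and
#'   `control`; required with an external `indicator_table`.
#' @param sieve_table path to a sieve-fraction CSV (stage aggregate).
#' @param chain_table path to a chain-measurement CSV (stage roughness).
#' @param seed root seed for the simulate stage.
#' @param kaiser_threshold,loading_window,redundancy_r,rho stage parameters,
#'   as in [sqi_pipeline()] and [gra_pipeline()].
#' @param entity_mode GRA entity mode, see [gra_pipeline()].
#' @return invisibly, a named list of the stage result objects.
#' @export
run_pipeline <- function(stages = "all", out_dir,
                         indicator_table = NULL, config = NULL,
                         sieve_table = NULL, chain_table = NULL,
                         seed = 1L,
                         kaiser_threshold = 1.0, loading_window = 0.10,
                         redundancy_r = 0.60, rho = 0.5,
                         entity_mode = "treatment_means") {
  known <- c("simulate", "aggregate", "roughness", "sqi", "gra",
             "effects", "reference_effects")
  if (identical(stages, "all")) {
    stages <- c("simulate", "sqi", "gra", "effects")
  }
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  inputs <- c(indicator_table, sieve_table, chain_table)
  for (p in inputs) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }

  m <- NULL
  design <- experiment_design(c("CK", "DI", "BA", "DB"), control = "CK")

  if ("simulate" %in% stages) {
    message("stage simulate: seed ", seed)
    m <- generate_experiment(seed = seed)
    write_report(as.data.frame(m), file.path(out_dir, "indicators.csv"))
    results$simulate <- m
  }

  need_matrix <- intersect(c("sqi", "gra", "effects"), stages)
  if (length(need_matrix) && is.null(m)) {
    if (is.null(indicator_table) || is.null(config)) {
      stop("stages ", paste(need_matrix, collapse = "/"),
           " need `indicator_table` and `config` (or a simulate stage)",
           call. = FALSE)
    }
    m <- read_indicator_table(indicator_table, config$spec)
    if (!is.null(config$control)) {
      design <- experiment_design(attr(m, "treatments"),
                                  control = config$control,
                                  replicates = attr(m, "replicates"))
    }
  }

  if ("aggregate" %in% stages) {
    if (is.null(sieve_table)) {
      stop("stage aggregate needs `sieve_table`", call. = FALSE)
    }
    message("stage aggregate: ", sieve_table)
    sv <- utils::read.csv(sieve_table, check.names = FALSE)
    class_cols <- setdiff(names(sv), c("sample", "mode"))
    scheme <- sieve_scheme()
    if (length(class_cols) != scheme$n_class) {
      stop("stage aggregate: expected ", scheme$n_class,
           " class columns in ", sieve_table, call. = FALSE)
    }
    samples <- unique(sv$sample)
    out <- do.call(rbind, lapply(samples, function(s) {
      dry <- sv[sv$sample == s & sv$mode == "dry", class_cols]
      wet <- sv[sv$sample == s & sv$mode == "wet", class_cols]
      if (nrow(dry) != 1L || nrow(wet) != 1L) {
        stop("stage aggregate: sample '", s,
             "' needs exactly one dry and one wet row", call. = FALSE)
      }
      si <- stability_indices(
        sieve_composition(as.numeric(dry), scheme, "dry"),
        sieve_composition(as.numeric(wet), scheme, "wet"))
      data.frame(sample = s, mwd = si$mwd, gmd = si$gmd,
                 ws_mwd = si$ws_mwd, ws_gmd = si$ws_gmd,
                 r025_dry = si$r025_dry, r025_wet = si$r025_wet,
                 pad = si$pad)
    }))
    write_report(out, file.path(out_dir, "aggregate_indices.csv"))
    results$aggregate <- out
  }

  if ("roughness" %in% stages) {
    if (is.null(chain_table)) {
      stop("stage roughness needs `chain_table`", call. = FALSE)
    }
    message("stage roughness: ", chain_table)
    ch <- utils::read.csv(chain_table)
    stopifnot(all(c("sample", "L1", "L2") %in% names(ch)))
    out <- do.call(rbind, lapply(unique(ch$sample), function(s) {
      sub <- ch[ch$sample == s, ]
      data.frame(sample = s, n_placements = nrow(sub),
                 cr = mean_chain_roughness(sub$L1, sub$L2))
    }))
    write_report(out, file.path(out_dir, "roughness.csv"))
    results$roughness <- out
  }

  if ("sqi" %in% stages) {
    message("stage sqi")
    res <- sqi_pipeline(m, kaiser_threshold = kaiser_threshold,
                        loading_window = loading_window,
                        redundancy_r = redundancy_r)
    eig <- data.frame(component = seq_along(res$pca$eigenvalues),
                      eigenvalue = res$pca$eigenvalues,
                      proportion = res$pca$proportion,
                      cumulative = res$pca$cumulative)
    write_report(eig, file.path(out_dir, "sqi_eigenvalues.csv"))
    load_df <- data.frame(indicator = rownames(res$pca$loadings),
                          res$pca$loadings, check.names = FALSE)
    write_report(load_df, file.path(out_dir, "sqi_loadings.csv"))
    mds_df <- data.frame(indicator = res$mds,
                         proposed_by = paste0("PC", res$proposed_by),
                         communality = communalities(res$pca,
                                                     res$retained)[res$mds],
                         weight = res$weights)
    write_report(mds_df, file.path(out_dir, "sqi_mds.csv"))
    sqi_df <- data.frame(treatment = as.data.frame(m)$treatment,
                         replicate = as.data.frame(m)$replicate,
                         sqi = res$sqi)
    write_report(sqi_df, file.path(out_dir, "sqi_values.csv"))
    write_report(data.frame(treatment = names(res$treatment_sqi),
                            sqi = as.numeric(res$treatment_sqi)),
                 file.path(out_dir, "sqi_treatments.csv"))
    results$sqi <- res
  }

  if ("gra" %in% stages) {
    message("stage gra: rho ", rho)
    res <- gra_pipeline(m, rho = rho, entity_mode = entity_mode)
    std <- data.frame(entity = rownames(res$sequences$standardized),
                      res$sequences$standardized, check.names = FALSE)
    write_report(std, file.path(out_dir, "gra_standardized.csv"))
    eta <- data.frame(entity = rownames(res$coefficients),
                      res$coefficients, check.names = FALSE)
    write_report(eta, file.path(out_dir, "gra_coefficients.csv"))
    gr <- data.frame(entity = names(res$grades),
                     grade = as.numeric(res$grades),
                     rank = match(names(res$grades), res$ranking))
    write_report(gr, file.path(out_dir, "gra_grades.csv"))
    results$gra <- res
  }

  if ("effects" %in% stages) {
    message("stage effects: control ", design$control)
    out <- effect_table(m, design)
    write_report(out, file.path(out_dir, "effects.csv"))
    results$effects <- out
  }

  if ("reference_effects" %in% stages) {
    message("stage reference_effects")
    for (layer in c("crust", "soil")) {
      write_report(reference_effects(layer),
                   file.path(out_dir,
                             sprintf("reference_effects_%s.csv", layer)))
    }
    results$reference_effects <- list(crust = reference_effects("crust"),
                                      soil = reference_effects("soil"))
  }

  digests <- character(0L)
  present <- inputs[!vapply(inputs, is.null, logical(1L))]
  if (length(present)) {
    digests <- vapply(unlist(present), function(p)
      unname(tools::md5sum(p)), character(1L))
    names(digests) <- unlist(present)
  }
  write_manifest(file.path(out_dir, "manifest.txt"), c(
    list(package = "biocrustr",
         version = as.character(utils::packageVersion("biocrustr")),
         stages = stages, seed = seed,
         kaiser_threshold = kaiser_threshold,
         loading_window = loading_window,
         redundancy_r = redundancy_r, rho = rho,
         entity_mode = entity_mode),
    as.list(digests)
  ))
  invisible(results)
}
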