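#' Declare a measured indicator
#'
#' An indicator is one measured soil, crust or plant variable (e.g. soil
#' organic carbon, aggregate mean weight diameter, crust roughness). Its
#' direction states whether larger values are favourable (`"larger_better"`,
#' the default for nutrients, enzyme activities and structural indices) or
#' smaller values are (`"smaller_better"`, used for pH and the percentage of
#' aggregate destruction). Direction is consumed by the Soil Quality Index
#' scoring functions and by Grey Relational Analysis standardization; it is
#' deliberately kept out of the data table so one table serves both.
#'
#' @param name short unique identifier, e.g. `"SOC"`.
#' @param direction `"larger_better"` or `"smaller_better"`.
#' @param layer which compartment the indicator describes: `"soil"`,
#'   `"crust"` or `"plant"`.
#' @param units free-text units, for reports only.
#' @return an object of class `indicator_spec`.
#' @export
#' @examples
#' indicator_spec("pH", direction = "smaller_better", layer = "soil")
indicator_spec <- function(name,
                           direction = c("larger_better", "smaller_better"),
                           layer = c("soil", "crust", "plant"),
                           units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  direction <- match.arg(direction)
  layer <- match.arg(layer)
  structure(
    list(name = name, direction = direction, layer = layer, units = units),
    class = "indicator_spec"
  )
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat(sprintf("<indicator %s: %s, %s layer%s>\n", x$name, x$direction,
              x$layer, if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

#' Declare the experiment design
#'
#' @param treatments ordered character vector of treatment labels.
#' @param control the label of the control treatment; must appear in
#'   `treatments`.
#' @param replicates replicate count per treatment (equal by design;
#'   unbalanced designs are rejected at validation).
#' @return an object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(c("CK", "DI", "BA", "DB"), control = "CK")
experiment_design <- function(treatments, control = treatments[[1L]],
                              replicates = 3L) {
  stopifnot(is.character(treatments), length(treatments) >= 1L,
            !anyDuplicated(treatments))
  if (!is.character(control) || length(control) != 1L ||
      !(control %in% treatments)) {
    stop("`control` must be exactly one of the treatment labels",
         call. = FALSE)
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  structure(
    list(treatments = treatments, control = control, replicates = replicates),
    class = "experiment_design"
  )
}

## internal: pull names out of a list of indicator_spec
spec_names <- function(spec) vapply(spec, `[[`, character(1L), "name")

## internal: direction lookup vector, names = indicator names
spec_directions <- function(spec) {
  stats::setNames(vapply(spec, `[[`, character(1L), "direction"),
                  spec_names(spec))
}

#' Assemble a treatment x replicate x indicator matrix
#'
#' The central data container: one row per pot (treatment x replicate), one
#' column per indicator, with the indicator metadata attached. Validation
#' enforces a complete balanced design with finite values, because every
#' downstream stage (SQI, GRA, effect tables) assumes it.
#'
#' @param values data.frame with columns `treatment`, `replicate`, then one
#'   numeric column per indicator (in `spec` order).
#' @param spec list of [indicator_spec()] objects describing the indicator
#'   columns.
#' @return an object of class `indicator_matrix`: the validated data.frame
#'   with attributes `spec` (the indicator list), `treatments` and
#'   `replicates`.
#' @export
indicator_matrix <- function(values, spec) {
  stopifnot(is.data.frame(values), is.list(spec), length(spec) >= 1L)
  nm <- spec_names(spec)
  if (anyDuplicated(nm)) stop("indicator names must be unique", call. = FALSE)
  required <- c("treatment", "replicate", nm)
  missing_cols <- setdiff(required, names(values))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  values <- values[, required, drop = FALSE]
  for (col in nm) {
    v <- values[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("missing or non-finite value in column '%s', row %d",
                   col, which(!is.finite(v))[1L]), call. = FALSE)
    }
  }
  treatments <- unique(as.character(values$treatment))
  counts <- table(values$treatment)
  if (length(unique(as.integer(counts))) != 1L) {
    stop("unbalanced design: replicate counts differ across treatments",
         call. = FALSE)
  }
  reps <- as.integer(counts[[1L]])
  values$treatment <- as.character(values$treatment)
  values$replicate <- as.integer(values$replicate)
  structure(values,
            spec = spec,
            treatments = treatments,
            replicates = reps,
            class = c("indicator_matrix", "data.frame"))
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("indicator matrix: %d treatments x %d replicates x %d indicators\n",
              length(attr(x, "treatments")), attr(x, "replicates"),
              length(attr(x, "spec"))))
  print(as.data.frame(x), ...)
  invisible(x)
}

## internal: numeric sample x indicator matrix from an indicator_matrix
indicator_values <- function(m) {
  nm <- spec_names(attr(m, "spec"))
  as.matrix(as.data.frame(m)[, nm, drop = FALSE])
}

#' Read an indicator table from a delimited file
#'
#' Expects the long layout written by [write_indicator_table()]: a header
#' row naming `treatment`, `replicate` and one column per indicator, one row
#' per pot, comma-separated, `"."` decimal. Blank or non-numeric cells are
#' errors (the designs handled here are complete; nothing is imputed).
#'
#' @param path file to read.
#' @param spec list of [indicator_spec()]; declares and orders the expected
#'   indicator columns.
#' @return an [indicator_matrix()].
#' @export
read_indicator_table <- function(path, spec) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  nm <- spec_names(spec)
  missing_cols <- setdiff(c("treatment", "replicate", nm), names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in nm) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error in %s: column '%s', row %d is not numeric",
                   path, col, bad[1L]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$replicate <- as.integer(raw$replicate)
  indicator_matrix(raw, spec)
}

#' Write an indicator table
#'
#' @param m an [indicator_matrix()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indicator configuration file
#'
#' The configuration is a YAML file declaring the indicator metadata kept out
#' of the data tables: a `control` treatment label and an `indicators` list
#' with `name`, `direction`, `layer` and optional `units` per entry.
#'
#' @param path YAML file.
#' @return list with elements `spec` (list of [indicator_spec()]) and
#'   `control` (character or `NULL`).
#' @export
read_indicator_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators)) {
    stop("config error in ", path, ": no `indicators` block", call. = FALSE)
  }
  spec <- lapply(cfg$indicators, function(e) {
    indicator_spec(e$name,
                   direction = if (is.null(e$direction)) "larger_better" else e$direction,
                   layer = if (is.null(e$layer)) "soil" else e$layer,
                   units = if (is.null(e$units)) "" else e$units)
  })
  list(spec = spec, control = cfg$control)
}

#' Per-treatment means and standard deviations
#'
#' Summarises an indicator matrix into the conventional "mean +- sd" table:
#' one row per treatment x indicator with the arithmetic mean over replicates
#' and the sample (n-1) standard deviation. With a single replicate the sd
#' is reported as `NA`, never zero.
#'
#' @param m an [indicator_matrix()].
#' @return data.frame with columns `treatment`, `indicator`, `mean`, `sd`.
#' @export
treatment_means <- function(m) {
  stopifnot(inherits(m, "indicator_matrix"))
  nm <- spec_names(attr(m, "spec"))
  treatments <- attr(m, "treatments")
  df <- as.data.frame(m)
  out <- expand.grid(indicator = nm, treatment = treatments,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("treatment", "indicator")]
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- df[df$treatment == out$treatment[i], out$indicator[i]]
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) > 1L) stats::sd(v) else NA_real_
  }
  out
}
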