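#' Read a solubility dataset from CSV
#'
#' Loads a tabular dataset of supercritical-CO2 measurements with one row per
#' experimental condition: temperature (Kelvin), pressure (bar), the reported
#' drug solubility and the reported CO2 density.  The canonical header is
#' `T_K,P_bar,y,co2_density`; datasets with other column names are mapped via
#' `schema`.
#'
#' All four columns must be numeric and strictly positive (solubility enters
#' relative-error metrics and the gamma model, so zeros are invalid).  Row
#' order of the source file is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector (or named list) mapping the
#'   canonical names `T_K`, `P_bar`, `y`, `co2_density` to the column names
#'   used in the file, e.g. `c(T_K = "temperature", P_bar = "pressure", ...)`.
#' @return A tibble with columns `T_K`, `P_bar`, `y`, `co2_density`.
#' @examples
#' d <- phenytoin_sc_co2()
#' nrow(d)
#' @export
read_solubility_data <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c(.feature_cols, .response_cols)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    missing_keys <- setdiff(canonical, names(schema))
    if (length(missing_keys) > 0) {
      abort(
        paste0("schema must map all of: ", paste(canonical, collapse = ", ")),
        class = "solubag_schema_error"
      )
    }
    missing_cols <- setdiff(unname(schema[canonical]), names(raw))
    if (length(missing_cols) > 0) {
      abort(
        paste0("columns not found in file: ", paste(missing_cols, collapse = ", ")),
        class = "solubag_schema_error"
      )
    }
    raw <- raw[, unname(schema[canonical])]
    names(raw) <- canonical
  } else {
    missing_cols <- setdiff(canonical, names(raw))
    if (length(missing_cols) > 0) {
      abort(
        paste0("missing required columns: ", paste(missing_cols, collapse = ", ")),
        class = "solubag_schema_error"
      )
    }
    raw <- raw[, canonical]
  }
  validate_solubility_data(raw)
}

#' Validate a solubility dataset
#'
#' Checks the schema and positivity invariants of a (T, P, solubility,
#' density) dataset and returns it as a tibble.  Used by [read_solubility_data()]
#' and by every fitting function that accepts a data frame.
#'
#' @param data A data frame with columns `T_K`, `P_bar`, `y`, `co2_density`.
#' @return The validated data as a tibble, row order untouched.
#' @export
validate_solubility_data <- function(data) {
  canonical <- c(.feature_cols, .response_cols)
  missing_cols <- setdiff(canonical, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required columns: ", paste(missing_cols, collapse = ", ")),
      class = "solubag_schema_error"
    )
  }
  data <- tibble::as_tibble(data)
  for (col in canonical) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("column '", col, "' is not numeric"),
        class = "solubag_validation_error"
      )
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      abort(
        paste0(
          "column '", col, "' must be finite and strictly positive; ",
          "first offending row: ", bad[1]
        ),
        class = "solubag_validation_error"
      )
    }
  }
  data
}

#' Write a solubility dataset to CSV
#'
#' Writes the canonical `T_K,P_bar,y,co2_density` dialect.  A written file
#' read back with [read_solubility_data()] reproduces the records exactly to
#' full printed precision.
#'
#' @param data A validated dataset (see [validate_solubility_data()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solubility_data <- function(data, path) {
  data <- validate_solubility_data(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' The phenytoin / supercritical-CO2 reference dataset
#'
#' The packaged 32-point experimental dataset: phenytoin solubility (`y`,
#' reported units) and CO2 density at four temperatures (313, 318, 333,
#' 345 K) and eight pressures (95--250 bar).  Values are stored at full
#' reported precision; rows are grouped by temperature.
#'
#' @return A 32-row tibble with columns `T_K`, `P_bar`, `y`, `co2_density`.
#' @examples
#' phenytoin_sc_co2()
#' @export
phenytoin_sc_co2 <- function() {
  read_solubility_data(
    system.file("extdata", "phenytoin_sc_co2.csv", package = "solubag", mustWork = TRUE)
  )
}

#' Pearson correlation matrix of the four study variables
#'
#' @param data A validated dataset.
#' @return A symmetric 4x4 matrix of Pearson correlations over
#'   `T_K`, `P_bar`, `y`, `co2_density`, with unit diagonal.
#' @examples
#' correlation_matrix(phenytoin_sc_co2())
#' @export
correlation_matrix <- function(data) {
  data <- validate_solubility_data(data)
  if (nrow(data) < 2) {
    abort("at least 2 records are required", class = "solubag_validation_error")
  }
  m <- as.matrix(data[, c(.feature_cols, .response_cols)])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(
      paste0(
        "correlation undefined: zero variance in column(s) ",
        paste(colnames(m)[sds == 0], collapse = ", ")
      ),
      class = "solubag_zero_variance_error"
    )
  }
  cor(m)
}

#' Correlation heatmap of the study variables
#'
#' @param data A validated dataset.
#' @return A ggplot object.
#' @export
plot_correlation <- function(data) {
  cm <- correlation_matrix(data)
  long <- tibble::as_tibble(as.data.frame.table(cm, responseName = "r"))
  names(long) <- c("var1", "var2", "r")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}
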