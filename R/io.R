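delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = ",",
    tsv = "\t",
    txt = "\t",
    stop("unsupported extension '", ext, "': use .csv or .tsv")
  )
}

meta_path_for <- function(path) {
  ext <- tools::file_ext(path)
  sub(paste0("\\.", ext, "$"), paste0("_variables.", ext), path)
}

# Format doubles with 17 significant digits so write -> read round-trips
# exactly; integers are written as integers.
format_exact <- function(x) {
  if (is.integer(x) || all(x == round(x) & abs(x) < 2^31, na.rm = TRUE)) {
    format(as.integer(round(x)), scientific = FALSE, trim = TRUE)
  } else {
    sprintf("%.17g", x)
  }
}

#' Write a population to delimited text
#'
#' Writes the predictor table plus the outcome column(s) to `path` (dialect
#' chosen by extension: `.csv` comma, `.tsv` tab), and the variable metadata
#' (name, kind, prevalence, effect) to a companion file with `_variables`
#' inserted before the extension. Numeric values are written with enough
#' digits that a write/read round trip reproduces the population exactly.
#'
#' @param pop a `plasmode_population`.
#' @param path data file path ending in `.csv` or `.tsv`.
#' @return invisibly, a character vector with the data and metadata paths.
#' @export
write_population <- function(pop, path) {
  validate_population(pop)
  sep <- delim_for(path)
  df <- as.data.frame(pop$predictors, check.names = FALSE)
  df <- as.data.frame(lapply(df, format_exact),
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- colnames(pop$predictors)
  df$y_weak <- pop$y_weak
  if (!is.null(pop$y_strong)) df$y_strong <- pop$y_strong
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)

  meta <- pop$specs
  meta$prevalence <- ifelse(is.na(meta$prevalence), "NA",
                            sprintf("%.17g", meta$prevalence))
  meta$effect <- sprintf("%.17g", meta$effect)
  mpath <- meta_path_for(path)
  utils::write.table(meta, mpath, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(data = path, metadata = mpath))
}

#' Read a population from delimited text
#'
#' Reads a population table written by [write_population()] or assembled by
#' the user. The outcome column(s) are named by the schema arguments; every
#' other column is a predictor. If a companion metadata file (see
#' [write_population()]) exists it supplies the variable kinds; otherwise a
#' column is declared binary when all its observed values are 0/1.
#'
#' Validation failures (missing values, values other than 0/1 in a declared
#' binary column, duplicated names, absent outcome column) raise errors that
#' name the offending column.
#'
#' @param path data file path ending in `.csv` or `.tsv`.
#' @param outcome name of the weak-outcome column (default `"y_weak"`).
#' @param strong_outcome name of the strong-outcome column, if present.
#' @param metadata optional explicit metadata file path.
#' @return a `plasmode_population` (with `seed` and `intercept` set to `NA`:
#'   they describe generation, not the data).
#' @export
read_population <- function(path, outcome = "y_weak",
                            strong_outcome = "y_strong", metadata = NULL) {
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate column names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  if (!outcome %in% names(df)) {
    stop("schema error: outcome column '", outcome, "' not found")
  }
  has_strong <- !is.null(strong_outcome) && strong_outcome %in% names(df)
  pred_names <- setdiff(names(df), c(outcome, strong_outcome))
  if (length(pred_names) == 0) stop("no predictor columns found")

  na_cols <- names(df)[vapply(df, anyNA, logical(1))]
  if (length(na_cols) > 0) {
    bad <- na_cols[1]
    stop("missing values in column '", bad, "' (first at row ",
         which(is.na(df[[bad]]))[1], ")")
  }

  mpath <- metadata %||% meta_path_for(path)
  if (file.exists(mpath)) {
    meta <- utils::read.table(mpath, header = TRUE, sep = sep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    meta <- meta[match(pred_names, meta$name), , drop = FALSE]
    if (anyNA(meta$name)) stop("metadata file does not cover every predictor")
    kinds <- meta$kind
    prevalence <- suppressWarnings(as.numeric(meta$prevalence))
    effect <- if ("effect" %in% names(meta)) meta$effect else rep(0, nrow(meta))
  } else {
    kinds <- vapply(df[pred_names], function(v) {
      if (all(v %in% c(0, 1))) "binary" else "numeric"
    }, character(1))
    prevalence <- ifelse(kinds == "binary",
                         vapply(df[pred_names], mean, numeric(1)), NA_real_)
    effect <- rep(0, length(pred_names))
  }

  for (nm in pred_names[kinds == "binary"]) {
    if (!all(df[[nm]] %in% c(0, 1))) {
      bad_row <- which(!df[[nm]] %in% c(0, 1))[1]
      stop("column '", nm, "' is declared binary but contains value '",
           df[[nm]][bad_row], "' at row ", bad_row)
    }
  }
  for (nm in c(outcome, if (has_strong) strong_outcome)) {
    if (!all(df[[nm]] %in% c(0, 1))) {
      stop("outcome column '", nm, "' must be coded 0/1")
    }
  }

  X <- as.matrix(df[pred_names])
  storage.mode(X) <- "double"
  pop <- structure(
    list(
      predictors = X,
      y_weak = as.integer(df[[outcome]]),
      y_strong = if (has_strong) as.integer(df[[strong_outcome]]) else NULL,
      specs = data.frame(
        name = pred_names, kind = kinds, prevalence = prevalence,
        effect = effect, stringsAsFactors = FALSE
      ),
      intercept = NA_real_,
      seed = NA_integer_
    ),
    class = "plasmode_population"
  )
  validate_population(pop)
  pop
}
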