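#' @keywords internal
demographic_columns <- function() {
  c("animal_id", "date", "year", "month", "site", "sex", "age_class",
    "exam_abnormal", "sample_quality_poor")
}

month_labels <- function() month.name

#' Assemble a validated sample dataset
#'
#' A dataset pairs a long-format sample table (one row per blood sample, one
#' column per analyte) with the analyte panel that describes those columns.
#' Construction validates the invariants the rest of the pipeline relies on:
#' non-empty animal identifiers, parseable dates, finite analyte values, and
#' non-negativity where the panel demands it. Invalid input errors; it never
#' yields a silently usable dataset.
#'
#' @param samples Data frame with the demographic columns (`animal_id`,
#'   `date`, `year`, `month`, `site`, `sex`, `age_class`, `exam_abnormal`,
#'   `sample_quality_poor`) plus one numeric column per panel analyte. `month`
#'   and `year` may be omitted; they are then derived from `date`.
#' @param analytes Analyte panel as returned by [default_analyte_panel()].
#'
#' @return An object of class `cp_dataset`: a list with elements `samples`
#'   (the validated data frame) and `analytes` (the panel).
#' @export
new_dataset <- function(samples, analytes = default_analyte_panel()) {
  stopifnot(is.data.frame(samples), is.data.frame(analytes))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (!"animal_id" %in% names(samples)) stop("samples lack an 'animal_id' column")
  if (!"date" %in% names(samples)) stop("samples lack a 'date' column")
  if (any(is.na(samples$animal_id) | !nzchar(as.character(samples$animal_id)))) {
    bad <- which(is.na(samples$animal_id) | !nzchar(as.character(samples$animal_id)))
    stop("empty animal_id in row(s) ", paste(bad, collapse = ", "))
  }
  samples$animal_id <- as.character(samples$animal_id)

  dates <- as.Date(as.character(samples$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date (expected ISO-8601 YYYY-MM-DD) in row(s) ",
         paste(which(is.na(dates)), collapse = ", "))
  }
  samples$date <- dates

  # month/year are analyzed as factors; derive from date when absent, but an
  # explicit column wins on conflict (with a warning).
  derived_month <- month_labels()[as.integer(format(dates, "%m"))]
  derived_year <- as.integer(format(dates, "%Y"))
  if (!"month" %in% names(samples)) {
    samples$month <- derived_month
  } else {
    m <- samples$month
    if (is.numeric(m)) m <- month_labels()[as.integer(m)]
    m <- as.character(m)
    conflict <- !is.na(m) & m != derived_month
    if (any(conflict)) {
      warning(sum(conflict), " sample(s) have a month column that disagrees ",
              "with the date; keeping the explicit month")
    }
    m[is.na(m)] <- derived_month[is.na(m)]
    samples$month <- m
  }
  if (!"year" %in% names(samples)) {
    samples$year <- derived_year
  } else {
    y <- as.integer(samples$year)
    conflict <- !is.na(y) & y != derived_year
    if (any(conflict)) {
      warning(sum(conflict), " sample(s) have a year column that disagrees ",
              "with the date; keeping the explicit year")
    }
    y[is.na(y)] <- derived_year[is.na(y)]
    samples$year <- y
  }

  for (fl in c("exam_abnormal", "sample_quality_poor")) {
    if (!fl %in% names(samples)) samples[[fl]] <- FALSE
    samples[[fl]] <- as.logical(samples[[fl]])
    samples[[fl]][is.na(samples[[fl]])] <- FALSE
  }
  for (fac in c("site", "sex", "age_class")) {
    if (!fac %in% names(samples)) samples[[fac]] <- NA_character_
    samples[[fac]] <- as.character(samples[[fac]])
  }

  extra <- setdiff(names(samples), c(demographic_columns(), analytes$analyte))
  if (length(extra)) {
    stop("unknown analyte column(s): ", paste(extra, collapse = ", "))
  }

  for (i in seq_len(nrow(analytes))) {
    a <- analytes$analyte[i]
    if (!a %in% names(samples)) {
      samples[[a]] <- NA_real_
      next
    }
    v <- suppressWarnings(as.numeric(samples[[a]]))
    bad_txt <- which(!is.na(samples[[a]]) & is.na(v))
    if (length(bad_txt)) {
      stop("non-numeric value for analyte '", a, "' in row(s) ",
           paste(bad_txt, collapse = ", "))
    }
    if (any(is.infinite(v))) {
      stop("non-finite value for analyte '", a, "' in row(s) ",
           paste(which(is.infinite(v)), collapse = ", "))
    }
    if (isTRUE(analytes$nonnegative[i]) && any(v < 0, na.rm = TRUE)) {
      stop("negative value for nonnegative analyte '", a, "' in row(s) ",
           paste(which(!is.na(v) & v < 0), collapse = ", "))
    }
    samples[[a]] <- v
  }

  samples <- samples[, c(demographic_columns(), analytes$analyte)]
  rownames(samples) <- NULL
  structure(list(samples = samples, analytes = analytes),
            class = "cp_dataset")
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat("<cp_dataset> ", nrow(x$samples), " samples from ",
      length(unique(x$samples$animal_id)), " animals, ",
      nrow(x$analytes), " analytes\n", sep = "")
  invisible(x)
}

#' Read a long-format sample table from CSV
#'
#' Reads a comma-separated, header-first sample table (one row per blood
#' sample), validates it against an analyte panel, and returns a dataset.
#' Empty cells become missing values; row order is preserved.
#'
#' @param path CSV file path.
#' @param analytes Analyte panel; columns of `path` that are neither
#'   demographic nor in this panel are an error.
#' @return A `cp_dataset`; see [new_dataset()].
#' @export
read_samples <- function(path, analytes = default_analyte_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  new_dataset(raw, analytes)
}

#' Extract one analyte's usable values
#'
#' @param data A `cp_dataset`.
#' @param analyte Analyte name.
#' @param drop_na Drop missing values (default `TRUE`).
#' @return Numeric vector, named by `animal_id`.
#' @export
analyte_values <- function(data, analyte, drop_na = TRUE) {
  stopifnot(inherits(data, "cp_dataset"))
  if (!analyte %in% data$analytes$analyte) stop("unknown analyte: ", analyte)
  v <- data$samples[[analyte]]
  names(v) <- data$samples$animal_id
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Write a result table to TSV
#'
#' Writes a collection of homogeneous records as a tab-separated file with a
#' header row. Numeric values keep at least 6 significant digits, so reading
#' the file back reproduces them. An empty collection produces a header-only
#' file; records with differing field sets are an error.
#'
#' @param rows A data frame, or a list of named lists sharing one field set.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    if (!length(rows)) stop("cannot infer a header from an empty list; ",
                            "pass a zero-row data frame instead")
    fields <- lapply(rows, function(r) sort(names(r)))
    if (!all(vapply(fields, identical, logical(1), fields[[1]]))) {
      stop("records have mixed field sets")
    }
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(out[[j]], digits = 10, format = "g"))
    }
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = ""))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#' @param path File path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
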