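#' @title Survey datasets of detection/non-detection histories
#' @description
#' A `survey_dataset` holds one row per host tree: an identifier, a
#' population label, three site covariates (crown diameter in metres,
#' presence of an infected neighbour within 50 m, presence of an adult
#' infection on the focal host) and a detection history over up to
#' `max_occasions` survey occasions. Occasions beyond a population's
#' survey effort are missing (`NA`); every host must have at least one
#' non-missing occasion.
#'
#' @param records data frame with columns `host_id`, `population`,
#'   `size`, `neighbor`, `infection`.
#' @param y integer matrix of detections, one row per host, entries
#'   0 (not detected), 1 (detected) or `NA` (occasion not surveyed).
#' @return An object of class `survey_dataset`: a list with elements
#'   `records`, `y`, `n_sites` and `max_occasions`.
#' @examples
#' rec <- data.frame(host_id = c("h1", "h2"), population = "A",
#'                   size = c(4, 6), neighbor = c(1, 0), infection = c(0, 0))
#' y <- rbind(c(1, 0, NA), c(0, 0, 0))
#' ds <- survey_dataset(rec, y)
#' ds$n_sites
#' @export
survey_dataset <- function(records, y) {
  records <- as.data.frame(records)
  required <- c("host_id", "population", "size", "neighbor", "infection")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (nrow(y) != nrow(records)) {
    stop("validation error: detection matrix and records disagree on the number of hosts",
         call. = FALSE)
  }
  if (anyDuplicated(records$host_id)) {
    stop("validation error: host_id values must be unique", call. = FALSE)
  }
  if (any(!is.na(y) & !(y %in% c(0L, 1L)))) {
    stop("parse error: detection entries must be 0, 1 or missing", call. = FALSE)
  }
  if (any(rowSums(!is.na(y)) == 0)) {
    bad <- which(rowSums(!is.na(y)) == 0)[1]
    stop("validation error: host ", records$host_id[bad],
         " has no surveyed occasion", call. = FALSE)
  }
  if (any(!is.finite(records$size)) || any(records$size <= 0)) {
    stop("validation error: size must be a positive crown diameter in metres",
         call. = FALSE)
  }
  if (!all(records$neighbor %in% c(0, 1)) || !all(records$infection %in% c(0, 1))) {
    stop("validation error: neighbor and infection must be binary (0/1)",
         call. = FALSE)
  }
  rownames(y) <- NULL
  structure(
    list(records = records, y = y,
         n_sites = nrow(records), max_occasions = ncol(y)),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Detection/non-detection survey dataset\n")
  cat("  hosts:      ", x$n_sites, "\n")
  cat("  occasions:  up to", x$max_occasions, "\n")
  eff <- table(rowSums(!is.na(x$y)))
  cat("  effort:     ", paste(sprintf("%s hosts x %s surveys", eff, names(eff)),
                              collapse = ", "), "\n")
  cat("  populations:", paste(unique(x$records$population), collapse = ", "), "\n")
  invisible(x)
}

survey_cols <- function(max_occasions) paste0("survey_", seq_len(max_occasions))

#' Read a detection-history survey table
#'
#' Reads the canonical CSV dialect (UTF-8, header row, one row per host,
#' columns `host_id`, `population`, `size_m`, `neighbor`, `infection`,
#' `survey_1` .. `survey_3`, with `"."` or an empty cell marking an
#' occasion that was not surveyed). An XLSX sheet in the same layout can
#' be ingested through a column-mapping configuration; the XLSX path
#' shells out to Python's openpyxl and is intended for one-off conversion
#' of deposited supplementary spreadsheets.
#'
#' @param path file to read.
#' @param format `"csv"` (canonical) or `"xlsx"`.
#' @param mapping named character vector mapping canonical column names to
#'   the columns found in the file, e.g. `c(size_m = "crown_diameter")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param max_occasions maximum number of survey occasions (default 3).
#' @return A [survey_dataset()].
#' @export
read_survey_data <- function(path, format = c("csv", "xlsx"), mapping = NULL,
                             max_occasions = 3L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "xlsx") {
    path <- xlsx_to_csv(path)
  }
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) {
      stop("schema error: no parseable survey table in ", path, call. = FALSE)
    })
  if (nrow(raw) == 0 || ncol(raw) <= 1) {
    stop("schema error: no parseable survey table in ", path, call. = FALSE)
  }
  canonical <- c("host_id", "population", "size_m", "neighbor", "infection",
                 survey_cols(max_occasions))
  resolve <- function(name) {
    src <- if (!is.null(mapping) && name %in% names(mapping)) mapping[[name]] else name
    if (!src %in% names(raw)) {
      stop("schema error: missing column: ", src, call. = FALSE)
    }
    raw[[src]]
  }
  for (nm in canonical) resolve(nm)  # fail early, naming the column

  n <- nrow(raw)
  y <- matrix(NA_integer_, n, max_occasions)
  for (j in seq_len(max_occasions)) {
    cell <- resolve(survey_cols(max_occasions)[j])
    blank <- cell %in% c("", ".", "NA")
    ok <- blank | cell %in% c("0", "1")
    if (!all(ok)) {
      stop("parse error: non-binary detection value '", cell[!ok][1],
           "' in column ", survey_cols(max_occasions)[j],
           ", row ", which(!ok)[1], call. = FALSE)
    }
    y[!blank, j] <- as.integer(cell[!blank])
  }
  records <- data.frame(
    host_id = resolve("host_id"),
    population = resolve("population"),
    size = as.numeric(resolve("size_m")),
    neighbor = as.integer(resolve("neighbor")),
    infection = as.integer(resolve("infection")),
    stringsAsFactors = FALSE
  )
  survey_dataset(records, y)
}

#' Write a survey dataset to the canonical CSV dialect
#'
#' Missing occasions are written as `"."`; sizes are written with full
#' double precision so that a write/read cycle reproduces the dataset
#' exactly.
#'
#' @param data a [survey_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survey_data <- function(data, path) {
  stopifnot(inherits(data, "survey_dataset"))
  out <- data.frame(
    host_id = data$records$host_id,
    population = data$records$population,
    size_m = sprintf("%.17g", data$records$size),
    neighbor = data$records$neighbor,
    infection = data$records$infection,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(data$max_occasions)) {
    col <- as.character(data$y[, j])
    col[is.na(col)] <- "."
    out[[survey_cols(data$max_occasions)[j]]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Convert one XLSX sheet to CSV via python/openpyxl; returns the temp CSV path.
xlsx_to_csv <- function(path) {
  py <- Sys.which("python")
  if (py == "") {
    stop("xlsx ingestion requires a 'python' executable with openpyxl; ",
         "convert the sheet to the canonical CSV dialect instead", call. = FALSE)
  }
  out <- tempfile(fileext = ".csv")
  code <- paste(
    "import sys, csv, openpyxl",
    "wb = openpyxl.load_workbook(sys.argv[1], read_only=True, data_only=True)",
    "ws = wb[wb.sheetnames[0]]",
    "w = csv.writer(open(sys.argv[2], 'w', newline=''))",
    "for row in ws.iter_rows(values_only=True):",
    "    w.writerow(['' if v is None else v for v in row])",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("failed to convert xlsx: ", path, call. = FALSE)
  out
}

#' Descriptive summary of a survey dataset
#'
#' Computes the covariate and detection summaries a survey report quotes:
#' mean and standard deviation of host crown diameter, counts and
#' fractions of hosts with/without infected neighbours and with adult
#' infections, and the naive occupancy (fraction of hosts with at least
#' one detection, uncorrected for imperfect detection).
#'
#' @param data a [survey_dataset()].
#' @return A list of class `survey_summary`.
#' @export
summarize_dataset <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  if (data$n_sites == 0) stop("validation error: empty dataset", call. = FALSE)
  rec <- data$records
  detected <- rowSums(data$y == 1, na.rm = TRUE) > 0
  structure(list(
    n_sites = data$n_sites,
    mean_size = mean(rec$size),
    sd_size = stats::sd(rec$size),
    n_without_neighbor = sum(rec$neighbor == 0),
    frac_without_neighbor = mean(rec$neighbor == 0),
    n_infected = sum(rec$infection == 1),
    frac_infected = mean(rec$infection == 1),
    n_detected = sum(detected),
    naive_occupancy = mean(detected),
    surveys_per_host = table(rowSums(!is.na(data$y)))
  ), class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("n = %d hosts\n", x$n_sites))
  cat(sprintf("crown diameter: %.2f +/- %.2f m\n", x$mean_size, x$sd_size))
  cat(sprintf("without infected neighbor: %d (%.0f%%)\n",
              x$n_without_neighbor, 100 * x$frac_without_neighbor))
  cat(sprintf("with adult infection: %d (%.0f%%)\n",
              x$n_infected, 100 * x$frac_infected))
  cat(sprintf("naive occupancy (>=1 detection): %.3f\n", x$naive_occupancy))
  invisible(x)
}
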