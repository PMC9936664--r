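#' Default column mapping for Formularity-style reports
#'
#' The report reader resolves the mandatory columns through a named character
#' vector mapping internal field names to column names in the file. The
#' default follows the Formularity report layout; outputs from other
#' formula-assignment tools can be read by supplying a different mapping.
#'
#' @return Named character vector with entries `mass`, `C`, `H`, `O`, `N`,
#'   `S`, `P`, `c13` and `error_ppm`.
#' @export
formularity_dialect <- function() {
  c(
    mass = "Mass", C = "C", H = "H", O = "O", N = "N", S = "S", P = "P",
    c13 = "C13", error_ppm = "Error_ppm"
  )
}

num_or_stop <- function(x, what, file) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "" & tolower(x) != "na")
  if (length(bad)) {
    stop(
      "non-numeric ", what, " in '", file, "' at row ", bad[1],
      " (value '", x[bad[1]], "')",
      call. = FALSE
    )
  }
  out
}

#' Read a molecular-formula report table
#'
#' Reads a Formularity-style CSV report: one row per detected peak with its
#' (neutral monoisotopic or measured) mass, CHNOPS element counts, a carbon-13
#' isotopologue indicator, the formula assignment error in ppm, and one
#' intensity column per sample where 0 means "not detected". A peak is
#' considered to carry a molecular formula when both its C and H counts are
#' positive; rows with zero counts are retained with `has_formula = FALSE`.
#'
#' @param path Path to the report CSV.
#' @param dialect Named character vector mapping internal fields to column
#'   names, see [formularity_dialect()]. Entries `c13` and `error_ppm` are
#'   optional; `mass` and the six element counts are mandatory.
#' @param sample_ids Optional character vector restricting which non-dialect
#'   columns are interpreted as sample intensity columns. By default every
#'   column not claimed by the dialect is taken as a sample.
#' @return A tibble of class `ftms_report`: columns `peak_id`, `mass`, `C`,
#'   `H`, `N`, `O`, `P`, `S`, `has_c13`, `error_ppm`, `has_formula`, followed
#'   by one numeric intensity column per sample. The sample column names are
#'   also stored in the `sample_ids` attribute.
#' @export
read_report <- function(path, dialect = formularity_dialect(), sample_ids = NULL) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  mandatory <- c("mass", "C", "H", "O", "N", "S", "P")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("report is missing mandatory column '", dialect[[field]] %||% field,
           "' (field '", field, "')", call. = FALSE)
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- setdiff(names(raw), unname(dialect))
  } else {
    missing <- setdiff(sample_ids, names(raw))
    if (length(missing)) {
      stop("sample(s) not found as intensity columns in report: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!length(sample_ids)) stop("report contains no intensity columns", call. = FALSE)

  n <- nrow(raw)
  out <- tibble::tibble(
    peak_id = sprintf("peak_%05d", seq_len(n)),
    mass = num_or_stop(raw[[dialect[["mass"]]]], "mass", path)
  )
  for (el in c("C", "H", "N", "O", "P", "S")) {
    v <- num_or_stop(raw[[dialect[[el]]]], paste("element count", el), path)
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative element count in column ", dialect[[el]], call. = FALSE)
    out[[el]] <- as.integer(round(v))
  }
  if (!is.null(dialect["c13"]) && !is.na(dialect["c13"]) && dialect[["c13"]] %in% names(raw)) {
    v <- num_or_stop(raw[[dialect[["c13"]]]], "C13 flag", path)
    out$has_c13 <- !is.na(v) & v != 0
  } else {
    out$has_c13 <- FALSE
  }
  if (!is.null(dialect["error_ppm"]) && !is.na(dialect["error_ppm"]) &&
      dialect[["error_ppm"]] %in% names(raw)) {
    out$error_ppm <- num_or_stop(raw[[dialect[["error_ppm"]]]], "assignment error", path)
  } else {
    out$error_ppm <- NA_real_
  }
  out$has_formula <- out$C > 0L & out$H > 0L
  if (any(is.na(out$mass)) || any(out$mass <= 0)) {
    stop("all peaks must have a positive mass", call. = FALSE)
  }

  n_missing <- 0L
  for (s in sample_ids) {
    v <- num_or_stop(raw[[s]], paste0("intensity ('", s, "')"), path)
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative intensity in sample column '", s, "'", call. = FALSE)
    }
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    out[[s]] <- v
  }
  if (n_missing > 0L) {
    warning(n_missing, " missing intensity cell(s) treated as 0 (not detected)",
            call. = FALSE)
  }

  key <- paste(out$mass, out$C, out$H, out$N, out$O, out$P, out$S)
  if (anyDuplicated(key)) {
    warning("report contains ", sum(duplicated(key)),
            " duplicate mass+formula row(s); all rows kept", call. = FALSE)
  }
  attr(out, "sample_ids") <- sample_ids
  class(out) <- c("ftms_report", class(out))
  out
}

#' Write a report table back to CSV
#'
#' Inverse of [read_report()] for round-tripping: writes the peak table in the
#' Formularity column dialect with full double precision.
#'
#' @param report An `ftms_report` tibble.
#' @param path Output CSV path.
#' @param dialect Column mapping, see [formularity_dialect()].
#' @export
write_report <- function(report, path, dialect = formularity_dialect()) {
  samples <- attr(report, "sample_ids")
  out <- data.frame(
    Mass = format_num(report$mass),
    C = report$C, H = report$H, O = report$O, N = report$N,
    S = report$S, P = report$P,
    C13 = as.integer(report$has_c13),
    Error_ppm = format_num(report$error_ppm),
    check.names = FALSE
  )
  names(out) <- unname(dialect[c("mass", "C", "H", "O", "N", "S", "P", "c13", "error_ppm")])
  for (s in samples) out[[s]] <- format_num(report[[s]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 15 significant digits, no scientific notation surprises on re-read
format_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Read sample metadata
#'
#' @param path Metadata CSV. The first column (or a column named
#'   `SampleID`/`sample_id`) identifies the sample; the grouping columns hold
#'   categorical labels. At most two grouping variables are supported.
#' @param grouping Character vector (length 1 or 2) of grouping column names.
#' @param report Optional `ftms_report`; when given, every metadata sample must
#'   exist as an intensity column of the report.
#' @return Tibble with columns `sample_id` and the grouping columns.
#' @export
read_metadata <- function(path, grouping, report = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  if (length(grouping) < 1L || length(grouping) > 2L) {
    stop("at most 2 grouping variables are supported (got ", length(grouping), ")",
         call. = FALSE)
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("SampleID", "sample_id", "Sample", "SampleID."), names(raw))
  id_col <- if (length(id_col)) id_col[1] else names(raw)[1]
  missing <- setdiff(grouping, names(raw))
  if (length(missing)) {
    stop("grouping column(s) not in metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(raw[[id_col]]))
  for (g in grouping) {
    v <- as.character(raw[[g]])
    if (any(is.na(v) | v == "")) stop("grouping column '", g, "' has empty labels",
                                      call. = FALSE)
    out[[g]] <- v
  }
  if (anyDuplicated(out$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (!is.null(report)) {
    absent <- setdiff(out$sample_id, attr(report, "sample_ids"))
    if (length(absent)) {
      stop("metadata sample(s) absent from report intensity columns: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Read a biochemical transformation key
#'
#' A transformation key is a CSV with columns `name`, `mass_difference` (Da)
#' and `category` (one of `biotic`, `abiotic`, `unclassified`); an optional
#' `formula` column gives the CHNOPS composition of the mass difference. The
#' package ships a curated default key (28 common biochemical mass
#' differences, e.g. CH2 for methylation, H2O for condensation, amino-acid
#' residues) whose masses are computed from IUPAC monoisotopic atomic masses;
#' it is a stand-in for system-specific keys and users are encouraged to
#' supply their own.
#'
#' @param path Path to a key CSV, or `"builtin"` for the shipped default.
#' @return Tibble with columns `name`, `formula` (possibly `NA`),
#'   `mass_difference`, `category`, sorted by increasing mass difference.
#' @export
read_transformation_key <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "biochemical_key.csv", package = "ftmsflow")
  }
  if (!file.exists(path)) stop("transformation key not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("name", "mass_difference", "category")) {
    if (!col %in% names(raw)) {
      stop("transformation key is missing column '", col, "'", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    name = as.character(raw$name),
    formula = if ("formula" %in% names(raw)) as.character(raw$formula) else NA_character_,
    mass_difference = as.numeric(raw$mass_difference),
    category = as.character(raw$category)
  )
  if (anyDuplicated(out$name)) {
    stop("duplicate transformation name(s): ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(out$mass_difference)) || any(out$mass_difference <= 0)) {
    stop("mass_difference must be a positive number for every key entry",
         call. = FALSE)
  }
  bad <- setdiff(unique(out$category), c("biotic", "abiotic", "unclassified"))
  if (length(bad)) {
    stop("unknown transformation category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out[order(out$mass_difference), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
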