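#' Reading and writing descriptor tables and reports
#'
#' Descriptor tables are CSV/TSV with columns `molecule_id`, `site_id`,
#' `medium`, `unit` and any subset of `BDE, IP, PDE, PA, ETE, SETPT,
#' SPLET, BASE, IPH_ref` (blank = absent).  Cells may carry an
#' uncertainty as `a±b` or the ASCII form `a+/-b`; they are parsed as
#' mean and half-range (stored in a `<col>_half` companion column), and
#' audits use the mean.  Parsing never fabricates values: malformed cells
#' become `NA` with a warning, never zero.
#'
#' @name table_io
NULL

.energy_cols <- c("BDE", "IP", "PDE", "PA", "ETE", "SETPT", "SPLET",
                  "BASE", "IPH_ref")

#' Parse an `a±b` uncertainty cell
#' @param x Character vector.
#' @return data.frame with `mean` and `half` (NA when no uncertainty).
#' @export
parse_uncertainty <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "-", ".")] <- NA
  parts <- strsplit(x, "±|\\+/-", perl = FALSE)
  mean <- vapply(parts, function(p) {
    if (length(p) < 1 || is.na(p[1])) return(NA_real_)
    suppressWarnings(as.numeric(p[1]))
  }, 0)
  half <- vapply(parts, function(p) {
    if (length(p) < 2) return(NA_real_)
    suppressWarnings(as.numeric(p[2]))
  }, 0)
  bad <- !is.na(x) & is.na(mean)
  if (any(bad))
    warning("unparseable numeric cell(s): ",
            paste(unique(x[bad]), collapse = ", "),
            " (treated as absent)", call. = FALSE)
  data.frame(mean = mean, half = half)
}

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) && lengths(regmatches(first, gregexpr("\t", first))) > 0)
    "\t" else ","
}

#' Read a descriptor table from CSV/TSV
#'
#' @param path File path.
#' @param delim Field delimiter; sniffed from the first line by default.
#' @return `descriptor_table` with row provenance attributes `source_file`
#'   and column `source_line`.
#' @export
read_descriptor_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% .sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           blank.lines.skip = TRUE, quote = "\"",
                           comment.char = "#")
  if (!nrow(raw)) {
    warning("empty descriptor table: ", path, call. = FALSE)
    out <- as_descriptor_table(data.frame(molecule_id = character(),
                                          site_id = character(),
                                          medium = character(),
                                          unit = character()))
    attr(out, "source_file") <- path
    return(out)
  }
  names(raw) <- sub("^position$", "site_id", tolower(names(raw)))
  canon <- c(.energy_cols, "molecule_id", "site_id", "medium", "unit")
  names(raw) <- vapply(names(raw), function(n) {
    hit <- canon[tolower(canon) == tolower(n)]
    if (length(hit)) hit[1] else n
  }, "")
  mandatory <- c("molecule_id", "medium", "unit")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("descriptor table lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(raw$site_id)) raw$site_id <- ""
  out <- raw[, intersect(c(mandatory[1], "site_id", mandatory[-1]), names(raw))]
  for (col in intersect(.energy_cols, names(raw))) {
    p <- parse_uncertainty(raw[[col]])
    out[[col]] <- p$mean
    if (any(is.finite(p$half))) out[[paste0(col, "_half")]] <- p$half
  }
  out$source_line <- seq_len(nrow(out)) + 1L
  out <- as_descriptor_table(out)
  attr(out, "source_file") <- path
  out
}

#' Read a long-format species-enthalpy table from CSV/TSV
#'
#' Columns: `molecule_id`, `site_id`, `species_role` (AXH, AX_radical,
#' AX_anion, AXH_cation), `energy`, `unit`.
#'
#' @inheritParams read_descriptor_table
#' @return data.frame ready for [compute_descriptor_table()].
#' @export
read_species_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% .sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           strip.white = TRUE, comment.char = "#")
  need <- c("molecule_id", "site_id", "species_role", "energy", "unit")
  missing <- setdiff(need, tolower(names(raw)))
  if (length(missing))
    stop("species table lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  names(raw) <- tolower(names(raw))
  raw$energy <- as.numeric(raw$energy)
  raw[, need]
}

#' Serialize an audit report
#'
#' @param report An `audit_report`.
#' @param format `"json"` (schema-stable: one object per finding with
#'   check id, residual, tolerance, verdict, diagnosis) or `"text"`.
#' @param path Optional output file; when `NULL` the document is returned
#'   as a character string.
#' @return The document, invisibly when written to `path`.
#' @export
write_report <- function(report, format = c("json", "text"), path = NULL) {
  stopifnot(inherits(report, "audit_report"))
  format <- match.arg(format)
  doc <- if (format == "json") {
    jsonlite::toJSON(list(n_rows = report$n_rows,
                          inferred_medium = report$inferred_medium,
                          findings = report$findings),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA,
                     na = "null", pretty = TRUE)
  } else {
    paste(utils::capture.output(print(report)), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(as.character(doc), path)
    return(invisible(as.character(doc)))
  }
  as.character(doc)
}

#' Re-read a JSON audit report
#' @param path JSON file written by [write_report()].
#' @return An `audit_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path)
  f <- as.data.frame(raw$findings, stringsAsFactors = FALSE)
  structure(list(findings = f,
                 inferred_medium = raw$inferred_medium %||% NA_character_,
                 n_rows = raw$n_rows),
            class = "audit_report")
}

#' Path to a packaged example/fixture table
#' @param name File name under `inst/extdata`; empty lists all.
#' @return Full path (or vector of available names).
#' @export
radaudit_example <- function(name = "") {
  if (!nzchar(name))
    return(list.files(system.file("extdata", package = "radaudit")))
  system.file("extdata", name, package = "radaudit", mustWork = TRUE)
}
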