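## FAERS-style "$"-delimited ASCII table I/O.
##
## The quarterly FAERS distribution ships six case-level tables: DEMO
## (demographics/administrative), DRUG (reported medications with role
## codes), REAC (MedDRA-coded reactions), OUTC (outcome codes), INDI
## (indication terms per drug) and THER (therapy dates per drug). Each file
## is a header line followed by "$"-separated records.

.faers_kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "INDI", "THER")

## modern (post-2014) column names; legacy headers are handled through a
## user-supplied col_map, not auto-detected
.faers_schema <- list(
  DEMO = list(required = c("primaryid", "caseid"),
              optional = c("fda_dt", "event_dt", "age", "age_cod", "sex",
                           "occp_cod", "reporter_country")),
  DRUG = list(required = c("primaryid", "drug_seq", "drugname", "role_cod"),
              optional = c("caseid", "prod_ai", "route")),
  REAC = list(required = c("primaryid", "pt"),
              optional = c("caseid")),
  OUTC = list(required = c("primaryid", "outc_cod"),
              optional = c("caseid")),
  INDI = list(required = c("primaryid", "indi_drug_seq", "indi_pt"),
              optional = c("caseid")),
  THER = list(required = c("primaryid", "dsg_drug_seq", "start_dt"),
              optional = c("caseid"))
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Parse FAERS date strings
#'
#' FAERS dates are `YYYYMMDD` digit strings, with truncated `YYYYMM` and
#' `YYYY` variants for partially known dates. The function is total: no
#' input raises.
#'
#' @param raw character vector of raw date fields.
#' @param partial policy for truncated dates: `"absent"` (default) maps them
#'   to `NA`; `"first"` imputes the first day of the period.
#' @return a `Date` vector (`NA` where unparseable).
#' @export
#' @examples
#' parse_faers_date(c("20230115", "202301", "00000000"))
parse_faers_date <- function(raw, partial = c("absent", "first")) {
  partial <- match.arg(partial)
  raw <- trimws(as.character(raw))
  raw[is.na(raw) | !grepl("^[0-9]+$", raw)] <- ""
  out <- rep(as.Date(NA), length(raw))
  n <- nchar(raw)
  full <- n == 8L
  if (partial == "first") {
    i6 <- n == 6L
    i4 <- n == 4L
    raw[i6] <- paste0(raw[i6], "01")
    raw[i4] <- paste0(raw[i4], "0101")
    full <- full | i6 | i4
  }
  out[full] <- as.Date(raw[full], format = "%Y%m%d")
  out
}

## split "$"-delimited lines into a data.table with the given header;
## trailing empty fields (dropped by strsplit/tstrsplit) are NA-padded
split_dollar_lines <- function(lines, ncol) {
  if (!length(lines)) {
    return(as.data.table(matrix(character(0), nrow = 0, ncol = ncol)))
  }
  parts <- data.table::tstrsplit(lines, "$", fixed = TRUE)
  while (length(parts) < ncol) parts <- c(parts, list(rep(NA_character_, length(lines))))
  setDT(parts)
  parts
}

#' Read one FAERS-style ASCII table
#'
#' Parses a "$"-delimited file with a header line into a typed
#' `data.table`. Unknown columns are preserved as-is; lines whose field
#' count differs from the header, or that lack a kind-specific mandatory
#' value (e.g. an empty PT in REAC, an invalid role code in DRUG), are
#' skipped and counted in the `n_skipped` attribute. Invalid bytes are
#' replaced so the parser is total.
#'
#' @param path path to the ASCII file.
#' @param kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`,
#'   `"THER"`.
#' @param col_map optional named character vector mapping file column names
#'   to the standard (post-2014) names, for legacy quarters
#'   (e.g. `c(isr = "primaryid")`).
#' @param date_partial policy for truncated dates, see [parse_faers_date()].
#' @return a `data.table` with standardized columns for the kind plus any
#'   extra file columns; attributes `n_data_lines` and `n_skipped`.
#' @export
read_faers_table <- function(path, kind, col_map = NULL,
                             date_partial = c("absent", "first")) {
  kind <- match.arg(toupper(kind), .faers_kinds)
  date_partial <- match.arg(date_partial)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- iconv(lines, "UTF-8", "UTF-8", sub = "�")
  if (!length(lines)) stop("empty file: ", path)

  header <- tolower(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  header <- trimws(header)
  if (!is.null(col_map)) {
    hit <- match(header, tolower(names(col_map)))
    header[!is.na(hit)] <- tolower(unname(col_map))[hit[!is.na(hit)]]
  }
  schema <- .faers_schema[[kind]]
  missing_req <- setdiff(schema$required, header)
  if (length(missing_req)) {
    stop("schema error: ", kind, " table is missing mandatory column(s): ",
         paste(missing_req, collapse = ", "))
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n_lines <- length(body)
  nf <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  good <- nf == length(header)
  dt <- split_dollar_lines(body[good], length(header))
  setnames(dt, header)
  for (j in seq_along(dt)) {
    v <- trimws(dt[[j]])
    v[!nzchar(v)] <- NA_character_
    set(dt, j = j, value = v)
  }

  keep <- rep(TRUE, nrow(dt))
  if (kind == "DEMO") {
    keep <- !is.na(dt$primaryid) & !is.na(dt$caseid)
  } else if (kind == "DRUG") {
    keep <- !is.na(dt$primaryid) & !is.na(dt$drugname) &
      dt$role_cod %in% .role_codes
  } else if (kind == "REAC") {
    keep <- !is.na(dt$primaryid) & !is.na(dt$pt)
  } else if (kind == "OUTC") {
    keep <- !is.na(dt$primaryid) & dt$outc_cod %in% .outcome_codes
  } else if (kind == "INDI") {
    keep <- !is.na(dt$primaryid) & !is.na(dt$indi_pt)
  } else if (kind == "THER") {
    keep <- !is.na(dt$primaryid)
  }
  dt <- dt[keep]

  ## fill absent optional columns, order standard columns first
  for (col in setdiff(schema$optional, names(dt))) {
    set(dt, j = col, value = NA_character_)
  }
  std <- c(schema$required, schema$optional)
  setcolorder(dt, c(std, setdiff(names(dt), std)))

  ## typed conversions
  if (kind == "DEMO") {
    dt[, fda_dt := parse_faers_date(fda_dt, date_partial)]
    dt[, event_dt := parse_faers_date(event_dt, date_partial)]
    dt[, age := suppressWarnings(as.numeric(age))]
    dt[, age_cod := toupper(age_cod)]
    dt[, sex := toupper(sex)]
    dt[!sex %in% c("F", "M"), sex := "UNK"]
    dt[, occp_cod := toupper(occp_cod)]
  } else if (kind == "DRUG") {
    dt[, drug_seq := suppressWarnings(as.integer(drug_seq))]
  } else if (kind == "INDI") {
    dt[, indi_drug_seq := suppressWarnings(as.integer(indi_drug_seq))]
  } else if (kind == "THER") {
    dt[, dsg_drug_seq := suppressWarnings(as.integer(dsg_drug_seq))]
    dt[, start_dt := parse_faers_date(start_dt, date_partial)]
  }

  n_skipped <- n_lines - nrow(dt)
  if (n_skipped > 0) {
    message(sprintf("read_faers_table(%s): skipped %d malformed line(s) of %d",
                    kind, n_skipped, n_lines))
  }
  setattr(dt, "n_data_lines", n_lines)
  setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Read a full FAERS-style corpus
#'
#' Loads the six quarterly tables into a `faers_corpus` object (a list with
#' elements `demo`, `drug`, `reac`, `outc`, `indi`, `ther`).
#'
#' @param paths either a directory containing files whose names contain the
#'   table kind (e.g. `DEMO.txt`), or a named character vector/list of paths
#'   with names among `DEMO, DRUG, REAC, OUTC, INDI, THER`.
#' @param col_maps optional named list of per-kind column maps.
#' @param date_partial see [parse_faers_date()].
#' @return a `faers_corpus` object.
#' @export
read_faers_corpus <- function(paths, col_maps = NULL,
                              date_partial = c("absent", "first")) {
  date_partial <- match.arg(date_partial)
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    paths <- setNames(
      vapply(.faers_kinds, function(k) {
        hit <- files[grepl(k, basename(files), ignore.case = TRUE)]
        if (!length(hit)) NA_character_ else hit[[1L]]
      }, character(1)),
      .faers_kinds)
  }
  paths <- unlist(paths)
  names(paths) <- toupper(names(paths))
  out <- lapply(.faers_kinds, function(k) {
    if (is.na(paths[k]) || !k %in% names(paths)) {
      stop("no file supplied for table kind ", k)
    }
    read_faers_table(paths[[k]], k, col_map = col_maps[[k]],
                     date_partial = date_partial)
  })
  names(out) <- tolower(.faers_kinds)
  structure(out, class = "faers_corpus")
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("<faers_corpus>\n")
  for (k in names(x)) {
    cat(sprintf("  %-5s %7d records (%d skipped)\n", k, nrow(x[[k]]),
                attr(x[[k]], "n_skipped") %||% 0L))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write result tables as tab-delimited text
#'
#' Writes each table in a named list to `<out_dir>/<name>.tsv` with a header
#' row. Output is deterministic: identical inputs produce byte-identical
#' files.
#'
#' @param tables named list of data.frames/data.tables.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_result_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.table(tables[[nm]]), p, sep = "\t",
                       quote = FALSE, na = "NA", eol = "\n")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a result table written by [write_result_tables()]
#'
#' @param path path to a `.tsv` file.
#' @return a `data.table`.
#' @export
read_result_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}
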