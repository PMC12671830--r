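
# Canonical column sets per FAERS table (modern AERS/FAERS names, lower case).
# Extra columns in a file are preserved as-is; pre-2012 LAERS-era names are
# mapped through the alias table first.
faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

role_codes <- c("PS", "SS", "C", "I")
outcome_codes <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")
age_codes <- c("DEC", "YR", "MON", "WK", "DY", "HR")

#' Default column-name alias table
#'
#' Maps historical (LAERS-era, pre-2012Q4) column names onto the modern
#' FAERS names used throughout the package. Users can extend it for other
#' schema drifts; matching is case-insensitive.
#'
#' @return named character vector: old name -> canonical name.
#' @export
default_column_aliases <- function() {
  c(isr = "primaryid", "case" = "caseid", gndr_cod = "sex",
    i_f_cod = "i_f_code", drug_rec_act = "drug_rec_act",
    lot_nbr = "lot_num", indi_drug_seq = "indi_drug_seq")
}

# read one '$'-delimited file with a header row; returns a data.table of
# character columns plus a log of malformed lines. Encoding: UTF-8 first,
# latin1 fallback (logged).
read_dollar_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  bad_enc <- !validEnc(lines)
  fallback <- any(bad_enc)
  if (fallback) lines[bad_enc] <- iconv(lines[bad_enc], "latin1", "UTF-8")
  if (length(lines) == 0L) {
    return(list(table = data.table::data.table(), malformed = integer(0),
                encoding_fallback = fallback))
  }
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  nf <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "$", fixed = TRUE)
  # rows ending in an empty field drop it during strsplit; pad those
  lens <- lengths(parts)
  short1 <- lens == nf - 1L & endsWith(body, "$")
  parts[short1] <- lapply(parts[short1], function(p) c(p, ""))
  lens[short1] <- nf
  ok <- lens == nf
  malformed <- which(!ok) + 1L  # 1-based line numbers in the file
  mat <- do.call(rbind, parts[ok])
  tab <- if (is.null(mat)) {
    stats::setNames(data.table::as.data.table(
      replicate(nf, character(0), simplify = FALSE)), header)
  } else {
    stats::setNames(data.table::as.data.table(
      lapply(seq_len(nf), function(j) trimws(mat[, j]))), header)
  }
  list(table = tab, malformed = malformed, encoding_fallback = fallback)
}

apply_aliases <- function(tab, aliases) {
  nm <- names(tab)
  hit <- nm %in% names(aliases)
  if (any(hit)) data.table::setnames(tab, nm[hit], unname(aliases[nm[hit]]))
  tab
}

# domain validation per table; invalid rows are removed and logged
validate_rows <- function(tab, table_name) {
  n0 <- nrow(tab)
  drop <- rep(FALSE, n0)
  if (n0 == 0L) return(list(table = tab, n_dropped = 0L, reasons = character(0)))
  reasons <- character(0)
  flag <- function(bad, why) {
    if (any(bad)) reasons <<- c(reasons, sprintf("%s: %d row(s) %s",
                                                 table_name, sum(bad), why))
    drop <<- drop | bad
  }
  if ("primaryid" %in% names(tab)) {
    flag(is.na(tab$primaryid) | !nzchar(tab$primaryid), "missing primaryid")
  }
  if (table_name == "drug" && "role_cod" %in% names(tab)) {
    flag(!(toupper(tab$role_cod) %in% role_codes), "invalid role_cod")
  }
  if (table_name == "outc" && "outc_cod" %in% names(tab)) {
    flag(!(toupper(tab$outc_cod) %in% outcome_codes), "invalid outc_cod")
  }
  if (table_name == "reac" && "pt" %in% names(tab)) {
    flag(is.na(tab$pt) | !nzchar(tab$pt), "empty pt")
  }
  if (table_name == "demo" && "age_cod" %in% names(tab)) {
    bad <- nzchar(tab$age_cod) & !(toupper(tab$age_cod) %in% age_codes)
    flag(bad, "unknown age_cod")
  }
  list(table = tab[!drop], n_dropped = sum(drop), reasons = reasons)
}

#' Read one FAERS quarter
#'
#' Loads the seven '$'-delimited quarterly tables (DEMO, DRUG, REAC, OUTC,
#' THER, INDI, RPSR) plus the deleted-case list for one quarter from a
#' directory. Files are located as \code{<TABLE><yy>Q<q>.txt} (case
#' insensitive); DEMO, DRUG and REAC are required, the rest optional.
#' Malformed lines are skipped and logged with their line numbers; rows
#' violating enumerated domains (e.g. a DRUG \code{role_cod} outside
#' PS/SS/C/I) are dropped and logged. REAC/DRUG rows whose primaryid is
#' absent from DEMO are retained but flagged \code{orphan}; they are removed
#' during curation, not at parse time.
#'
#' @param path directory containing the quarter's files.
#' @param quarter_id label like \code{"2004Q1"}.
#' @param aliases column-name alias map (see [default_column_aliases()]).
#' @return A \code{faers_quarter} object: list with \code{quarter_id},
#'   \code{tables} (named list of data.tables), \code{deleted_caseids}
#'   (character vector) and \code{log} (per-table row counts, malformed
#'   line numbers, validation messages).
#' @export
read_quarter <- function(path, quarter_id, aliases = default_column_aliases()) {
  stopifnot(dir.exists(path), grepl("^[0-9]{4}Q[1-4]$", quarter_id))
  sfx <- quarter_suffix(quarter_id)
  files <- list.files(path, full.names = TRUE)
  find_file <- function(stem) {
    hit <- grep(paste0("^", stem, sfx, "\\.txt$"), basename(files),
                ignore.case = TRUE)
    if (length(hit)) files[hit[1L]] else NA_character_
  }
  tables <- list()
  log <- list(quarter_id = quarter_id, counts = integer(0),
              malformed = list(), messages = character(0))
  for (tb in names(faers_schema)) {
    f <- find_file(tb)
    if (is.na(f)) {
      if (tb %in% c("demo", "drug", "reac")) {
        stop("required FAERS table '", toupper(tb), "' not found for ",
             quarter_id, " in ", path)
      }
      tables[[tb]] <- stats::setNames(data.table::as.data.table(
        replicate(length(faers_schema[[tb]]), character(0),
                  simplify = FALSE)), faers_schema[[tb]])
      next
    }
    raw <- read_dollar_file(f)
    tab <- apply_aliases(raw$table, aliases)
    # ensure canonical columns exist even if the file lacks them
    missing_cols <- setdiff(faers_schema[[tb]], names(tab))
    for (mc in missing_cols) tab[[mc]] <- ""
    val <- validate_rows(tab, tb)
    tables[[tb]] <- val$table
    log$counts[[tb]] <- nrow(val$table)
    if (length(raw$malformed)) log$malformed[[tb]] <- raw$malformed
    if (raw$encoding_fallback) {
      log$messages <- c(log$messages,
                        sprintf("%s: latin1 encoding fallback", basename(f)))
    }
    log$messages <- c(log$messages, val$reasons)
    if (length(raw$malformed)) {
      log$messages <- c(log$messages,
        sprintf("%s: %d malformed line(s) skipped (lines %s)", basename(f),
                length(raw$malformed),
                paste(utils::head(raw$malformed, 10L), collapse = ",")))
    }
  }
  del_file <- find_file("DELETED")
  deleted <- character(0)
  if (!is.na(del_file)) {
    deleted <- trimws(readLines(del_file, warn = FALSE))
    deleted <- unique(deleted[nzchar(deleted)])
  }
  # orphan flagging: non-DEMO rows whose primaryid is absent from DEMO
  demo_ids <- tables$demo$primaryid
  for (tb in setdiff(names(tables), "demo")) {
    if (nrow(tables[[tb]]) && "primaryid" %in% names(tables[[tb]])) {
      tables[[tb]][, orphan := !(primaryid %in% demo_ids)]
      n_orph <- sum(tables[[tb]]$orphan)
      if (n_orph) log$messages <- c(log$messages,
        sprintf("%s: %d orphan row(s) flagged", tb, n_orph))
    } else if ("primaryid" %in% names(tables[[tb]])) {
      tables[[tb]][, orphan := logical(0)]
    }
  }
  structure(list(quarter_id = quarter_id, tables = tables,
                 deleted_caseids = deleted, log = log),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("FAERS quarter", x$quarter_id, "\n")
  for (tb in names(x$tables)) {
    cat(sprintf("  %-5s %6d rows\n", toupper(tb), nrow(x$tables[[tb]])))
  }
  cat("  deleted caseids:", length(x$deleted_caseids), "\n")
  invisible(x)
}

#' Read every quarter in a directory
#'
#' Scans \code{path} for \code{DEMO<yy>Q<q>.txt} files and reads each
#' matching quarter with [read_quarter()]. Two-digit years below 70 are
#' taken as 20xx (FAERS starts in 1997).
#'
#' @inheritParams read_quarter
#' @return list of \code{faers_quarter} objects, ordered by quarter.
#' @export
read_quarters <- function(path, aliases = default_column_aliases()) {
  demos <- list.files(path, pattern = "^DEMO[0-9]{2}Q[1-4]\\.txt$",
                      ignore.case = TRUE)
  if (!length(demos)) stop("no DEMO<yy>Q<q>.txt files found in ", path)
  sfx <- toupper(sub("\\.txt$", "", sub("^DEMO", "", demos, ignore.case = TRUE),
                     ignore.case = TRUE))
  yy <- as.integer(substr(sfx, 1L, 2L))
  qids <- sprintf("%04d%s", ifelse(yy < 70L, 2000L + yy, 1900L + yy),
                  substr(sfx, 3L, 4L))
  qids <- sort(unique(qids))
  lapply(qids, function(q) read_quarter(path, q, aliases))
}

#' Write a quarter bundle in the FAERS ASCII dialect
#'
#' Serialises a \code{faers_quarter} (or a bare list with the same shape)
#' to \code{<TABLE><yy>Q<q>.txt} files, '$'-delimited with one header row,
#' plus \code{DELETED<yy>Q<q>.txt} (one caseid per line, written even when
#' empty). This is the writer used by the synthetic generator and by the
#' ingest round-trip tests.
#'
#' @param bundle a \code{faers_quarter}.
#' @param path output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_quarter <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sfx <- quarter_suffix(bundle$quarter_id)
  written <- character(0)
  for (tb in names(bundle$tables)) {
    tab <- data.table::as.data.table(bundle$tables[[tb]])
    if ("orphan" %in% names(tab)) tab[, orphan := NULL]
    f <- file.path(path, sprintf("%s%s.txt", toupper(tb), sfx))
    hdr <- paste(names(tab), collapse = "$")
    rows <- if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "$")) else character(0)
    writeLines(c(hdr, rows), f, useBytes = TRUE)
    written <- c(written, f)
  }
  f <- file.path(path, sprintf("DELETED%s.txt", sfx))
  writeLines(as.character(bundle$deleted_caseids), f, useBytes = TRUE)
  invisible(c(written, f))
}
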