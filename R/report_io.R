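# Reading and validating DIA-NN style multiplexed precursor reports.

# Columns the diann dialect must provide. The channel column is handled
# separately because DIA-NN minor versions differ in how they encode it.
.diann_required_cols <- c(
  "Run", "Protein.Group", "Precursor.Id", "Modified.Sequence",
  "Precursor.Charge", "Ms1.Translated", "Precursor.Translated",
  "Global.PG.Q.Value", "Channel.Q.Value", "Lib.PG.Q.Value", "Lib.Q.Value",
  "PG.MaxLFQ"
)

# SILAC label decorations stripped from Modified.Sequence when building the
# pairing key, so that light and heavy partners share a key. Covers the
# explicit SILAC-K/R tags and the UniMod accessions for Lys-8 (259) and
# Arg-10 (267).
.label_mod_pattern <- "\\(SILAC-[KR]-[HL]\\)|\\(UniMod:(259|267)\\)"

# Heavy-channel decoration, used only as a fallback when no channel column
# is present in the report.
.heavy_label_pattern <- "\\(SILAC-[KR]-H\\)|\\(UniMod:(259|267)\\)"

#' Read a DIA-NN style multiplexed report
#'
#' Parses a tab-separated `report.tsv` as written by DIA-NN for multiplexed
#' (SILAC) experiments into a tibble of precursor records, one row per
#' precursor x run x channel. Empty cells become `NA` (missing is kept
#' distinct from zero). The isotope channel is taken from a dedicated channel
#' column when present, otherwise inferred from the SILAC label decoration of
#' `Modified.Sequence`. The pairing key `precursor_key` is the label-stripped
#' modified sequence plus charge, so light and heavy partners of the same
#' precursor share a key.
#'
#' @param path Path to a tab-separated report file.
#' @param dialect Report dialect; only `"diann"` is supported.
#' @param channel_col Name of the channel column, if the report has one.
#'   When the column is absent the channel is inferred from the modified
#'   sequence instead.
#' @param heavy_pattern Regular expression on `Modified.Sequence` identifying
#'   heavy-channel rows when no channel column is present.
#'
#' @return A tibble of precursor records with columns `run_id`,
#'   `protein_group`, `precursor_key`, `channel` (`"L"`/`"H"`),
#'   `precursor_charge`, `ms1_translated`, `precursor_translated`,
#'   `global_pg_qvalue`, `channel_qvalue`, `lib_pg_qvalue`, `lib_qvalue`,
#'   `pg_maxlfq`, `is_contaminant` (initialised `FALSE`; see
#'   [flag_contaminants()]).
#' @export
read_diann_report <- function(path, dialect = "diann", channel_col = "Channel",
                              heavy_pattern = .heavy_label_pattern) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("report file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(.diann_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("report is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  num_cols <- c("Precursor.Charge", "Ms1.Translated", "Precursor.Translated",
                "Global.PG.Q.Value", "Channel.Q.Value", "Lib.PG.Q.Value",
                "Lib.Q.Value", "PG.MaxLFQ")
  parsed <- lapply(num_cols, function(col) {
    x <- raw[[col]]
    y <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(y))
    if (length(bad) > 0) {
      # +1 for the header line, so the number matches the file
      abort(paste0("unparseable numeric value in column ", col,
                   " at file line ", bad[1] + 1L, ": '", x[bad[1]], "'"))
    }
    y
  })
  names(parsed) <- num_cols

  if (channel_col %in% names(raw)) {
    ch <- toupper(substr(raw[[channel_col]], 1, 1))
  } else {
    ch <- ifelse(stringr::str_detect(raw[["Modified.Sequence"]], heavy_pattern),
                 "H", "L")
  }
  if (!all(ch %in% c("L", "H"))) {
    abort("channel column contains values other than L/H")
  }

  stripped <- stringr::str_remove_all(raw[["Modified.Sequence"]], .label_mod_pattern)
  records <- tibble::tibble(
    run_id = raw[["Run"]],
    protein_group = raw[["Protein.Group"]],
    precursor_key = paste0(stripped, "/", parsed[["Precursor.Charge"]]),
    channel = ch,
    precursor_charge = as.integer(parsed[["Precursor.Charge"]]),
    ms1_translated = parsed[["Ms1.Translated"]],
    precursor_translated = parsed[["Precursor.Translated"]],
    global_pg_qvalue = parsed[["Global.PG.Q.Value"]],
    channel_qvalue = parsed[["Channel.Q.Value"]],
    lib_pg_qvalue = parsed[["Lib.PG.Q.Value"]],
    lib_qvalue = parsed[["Lib.Q.Value"]],
    pg_maxlfq = parsed[["PG.MaxLFQ"]],
    is_contaminant = FALSE
  )
  validate_records(records)
  records
}

#' Convert an in-memory report tibble to precursor records
#'
#' Same transformation as [read_diann_report()] applied to a data frame that
#' already holds the diann-dialect columns (e.g. the output of
#' [simulate_report()]), without a file round-trip.
#'
#' @inheritParams read_diann_report
#' @param report A data frame with the diann-dialect columns.
#' @return A validated precursor record tibble.
#' @export
records_from_report <- function(report, channel_col = "Channel",
                                heavy_pattern = .heavy_label_pattern) {
  missing_cols <- setdiff(.diann_required_cols, names(report))
  if (length(missing_cols) > 0) {
    abort(paste0("report is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (channel_col %in% names(report)) {
    ch <- toupper(substr(as.character(report[[channel_col]]), 1, 1))
  } else {
    ch <- ifelse(stringr::str_detect(report[["Modified.Sequence"]],
                                     heavy_pattern), "H", "L")
  }
  stripped <- stringr::str_remove_all(report[["Modified.Sequence"]],
                                      .label_mod_pattern)
  num <- function(col) as.numeric(report[[col]])
  records <- tibble::tibble(
    run_id = as.character(report[["Run"]]),
    protein_group = as.character(report[["Protein.Group"]]),
    precursor_key = paste0(stripped, "/", as.integer(num("Precursor.Charge"))),
    channel = ch,
    precursor_charge = as.integer(num("Precursor.Charge")),
    ms1_translated = num("Ms1.Translated"),
    precursor_translated = num("Precursor.Translated"),
    global_pg_qvalue = num("Global.PG.Q.Value"),
    channel_qvalue = num("Channel.Q.Value"),
    lib_pg_qvalue = num("Lib.PG.Q.Value"),
    lib_qvalue = num("Lib.Q.Value"),
    pg_maxlfq = num("PG.MaxLFQ"),
    is_contaminant = FALSE
  )
  validate_records(records)
  records
}

#' Validate a precursor record table
#'
#' Checks the invariants of a precursor record tibble: channels are L/H,
#' charges are >= 1, q-values lie in \[0, 1\], and (run, precursor_key,
#' channel) is unique. Called by [read_diann_report()]; exported so that
#' programmatically built records can be checked too.
#'
#' @param records A precursor record tibble.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records) {
  if (!all(records$channel %in% c("L", "H"))) {
    abort("channel must be 'L' or 'H'")
  }
  if (any(records$precursor_charge < 1, na.rm = TRUE)) {
    abort("precursor_charge must be >= 1")
  }
  for (qc in c("global_pg_qvalue", "channel_qvalue", "lib_pg_qvalue", "lib_qvalue")) {
    q <- records[[qc]]
    if (any(q < 0 | q > 1, na.rm = TRUE)) {
      abort(paste0(qc, " outside [0, 1]"))
    }
  }
  dup <- duplicated(records[c("run_id", "precursor_key", "channel")])
  if (any(dup)) {
    ex <- records[which(dup)[1], ]
    abort(paste0("duplicate (run, precursor, channel) row: ", ex$run_id, " / ",
                 ex$precursor_key, " / ", ex$channel))
  }
  invisible(records)
}

#' Flag contaminant protein groups
#'
#' Marks records whose protein group contains a contaminant accession,
#' either by membership in an explicit accession set or by an accession
#' prefix (e.g. `"Cont_"`). A semicolon-joined protein group is flagged if
#' *any* member matches. No rows are removed; removal happens in filtering.
#'
#' @param records A precursor record tibble.
#' @param contaminant_ids Character vector of contaminant accessions, or `NULL`.
#' @param prefix Accession prefix identifying contaminants, or `NULL`.
#' @return `records` with `is_contaminant` set.
#' @export
flag_contaminants <- function(records, contaminant_ids = NULL, prefix = NULL) {
  if (is.null(contaminant_ids) && is.null(prefix)) {
    return(records)
  }
  members <- stringr::str_split(records$protein_group, stringr::fixed(";"))
  hit <- vapply(members, function(acc) {
    m <- FALSE
    if (!is.null(contaminant_ids)) m <- any(acc %in% contaminant_ids)
    if (!m && !is.null(prefix)) m <- any(startsWith(acc, prefix))
    m
  }, logical(1))
  records$is_contaminant <- records$is_contaminant | hit
  records
}

#' Read a contaminant accession list
#'
#' One accession per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a plain-text accession list.
#' @return Character vector of accessions.
#' @export
read_contaminant_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a result table to TSV
#'
#' All exported tables are plain TSV (UTF-8, '.' decimal separator) and
#' round-trip through [read_quant_table()] without loss.
#'
#' @param x A data frame.
#' @param path Output path; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("output directory does not exist: ", dir))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_quant_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_quant_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"),
                  progress = FALSE)
}
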