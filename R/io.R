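#' Dataset schema
#'
#' The project's CSV schema for measurement tables. Units are embedded in
#' the column names — the model's most dangerous ambiguities are degC vs K
#' and humidity fraction vs percent, and the suffixes make a mismatch a
#' schema error instead of a silent wrong answer. Mandatory columns:
#' `record_id`, `subject_id`, `timepoint_label`, `Tr_K`, `tw_C`, `ts_C`,
#' `He_frac`, `BF_pu`. Each row must additionally carry either a `ppg_file`
#' path (two-column red,ir CSV with the sampling rate in a `# fs=` header
#' comment) or precomputed vitals `HR_bpm` + `SpO2_pct`. `BG_ref_mmolL` is
#' optional (absent at pure predict time).
#'
#' @return Character vector of mandatory column names.
#' @export
dataset_schema <- function() {
  c("record_id", "subject_id", "timepoint_label",
    "Tr_K", "tw_C", "ts_C", "He_frac", "BF_pu")
}

#' Write a cohort or measurement table to the project CSV schema
#'
#' @param cohort A `bg_cohort` (from [generate_cohort()]) or a data.frame
#'   already in schema columns.
#' @param path Output CSV path.
#' @param ppg_dir Directory for per-record PPG sidecar CSVs (created if
#'   needed). Used only when the cohort carries waveforms; the table then
#'   references them through a `ppg_file` column. When `NULL` and waveforms
#'   exist, precomputed `HR_bpm`/`SpO2_pct` columns are written from the
#'   generator's ground truth instead.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path, ppg_dir = NULL) {
  tab <- as.data.frame(cohort)
  waveforms <- attr(cohort, "waveforms")
  if (inherits(cohort, "bg_cohort")) {
    out <- tab[dataset_schema()]
    if (!is.null(waveforms) && !is.null(ppg_dir)) {
      dir.create(ppg_dir, showWarnings = FALSE, recursive = TRUE)
      out$ppg_file <- vapply(seq_along(waveforms), function(i) {
        f <- file.path(ppg_dir, paste0(tab$record_id[i], "_ppg.csv"))
        write_ppg_csv(waveforms[[i]], f)
        f
      }, character(1))
    } else {
      out$HR_bpm <- tab$HR_true_bpm
      out$SpO2_pct <- tab$SpO2_true_pct
    }
    if ("BG_ref_mmolL" %in% names(tab)) out$BG_ref_mmolL <- tab$BG_ref_mmolL
  } else {
    out <- tab
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a PPG waveform as a two-column CSV
#'
#' Plain-text sidecar format: a `# fs=<Hz>` header comment followed by
#' `red,ir` sample columns.
#'
#' @param waveform A [ppg_waveform()].
#' @param path CSV path.
#' @return `write_ppg_csv` returns `path` invisibly; `read_ppg_csv` a
#'   `ppg_waveform`.
#' @export
write_ppg_csv <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", waveform$fs), con)
  utils::write.csv(data.frame(red = waveform$red, ir = waveform$ir),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppg_csv
#' @export
read_ppg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) {
    stop("PPG file missing the '# fs=' header comment: ", path,
         call. = FALSE)
  }
  dat <- utils::read.csv(path, comment.char = "#")
  if (!all(c("red", "ir") %in% names(dat))) {
    stop("PPG file needs columns red, ir: ", path, call. = FALSE)
  }
  ppg_waveform(dat$red, dat$ir, fs = as.numeric(m[2]))
}

#' Read and validate a measurement table
#'
#' Parses the project CSV schema and validates every row against the sensor
#' frame invariants. Rows that fail validation are *reported by row number*,
#' never silently dropped: they are returned in the `"problems"` attribute,
#' and `strict = TRUE` turns any failure into an error.
#'
#' @param path CSV path.
#' @param strict Abort on the first invalid row instead of collecting.
#' @return The validated data.frame with attribute `"problems"` (a
#'   data.frame of `row`, `message` for the rows that failed).
#' @export
read_dataset <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_schema(), names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_vitals <- all(c("HR_bpm", "SpO2_pct") %in% names(tab))
  has_ppg <- "ppg_file" %in% names(tab)
  if (!has_vitals && !has_ppg) {
    stop("schema error: need either a ppg_file column or precomputed ",
         "HR_bpm + SpO2_pct columns", call. = FALSE)
  }
  problems <- data.frame(row = integer(0), message = character(0))
  for (i in seq_len(nrow(tab))) {
    msg <- tryCatch({
      sensor_frame(Tr = tab$Tr_K[i], tw = tab$tw_C[i], ts = tab$ts_C[i],
                   He = tab$He_frac[i], BF = tab$BF_pu[i])
      NA_character_
    }, error = function(e) conditionMessage(e))
    if (!is.na(msg)) {
      if (strict) stop(sprintf("row %d: %s", i, msg), call. = FALSE)
      problems <- rbind(problems,
                        data.frame(row = i, message = msg))
    }
  }
  if (nrow(problems)) {
    warning(sprintf("%d row(s) failed frame validation (see attr(, 'problems'))",
                    nrow(problems)), call. = FALSE)
  }
  attr(tab, "problems") <- problems
  tab
}

#' Extract the model's feature vector from a measurement table
#'
#' Assembles one feature record (H, SpO2, HR, BF) per row: metabolic heat
#' through the energy model always; HR and SpO2 either passed through from
#' precomputed columns, recovered from the cohort's in-memory waveforms, or
#' read from `ppg_file` sidecars and processed through the optical chain.
#' Per-row failures are collected (with row numbers) in the `"failures"`
#' attribute and the pipeline continues on the valid rows; `strict = TRUE`
#' aborts instead. Counts are conserved: rows in = rows out + rows reported.
#'
#' @param table A validated measurement table ([read_dataset()]) or a
#'   `bg_cohort`.
#' @param vitals `"auto"` (waveforms when available, else columns),
#'   `"waveform"`, or `"columns"`.
#' @param coeffs [absorption_coefficients()] for the saturation map.
#' @param constants [energy_constants()] for the heat model.
#' @param strict Abort on the first failing row.
#' @return A data.frame with columns `record_id`, `H`, `SpO2`, `HR`, `BF`
#'   and (when available) `bg_ref`, plus attribute `"failures"`.
#' @export
extract_features <- function(table,
                             vitals = c("auto", "waveform", "columns"),
                             coeffs = absorption_coefficients(),
                             constants = energy_constants(),
                             strict = FALSE) {
  vitals <- match.arg(vitals)
  waveforms <- attr(table, "waveforms")
  tab <- as.data.frame(table)
  n <- nrow(tab)
  if (n == 0L) {
    out <- data.frame(record_id = character(0), H = numeric(0),
                      SpO2 = numeric(0), HR = numeric(0), BF = numeric(0))
    attr(out, "failures") <- data.frame(row = integer(0),
                                        message = character(0))
    return(out)
  }
  has_cols <- all(c("HR_bpm", "SpO2_pct") %in% names(tab))
  use_wave <- switch(vitals,
    auto = !is.null(waveforms) || "ppg_file" %in% names(tab),
    waveform = TRUE,
    columns = FALSE)
  if (use_wave && is.null(waveforms) && !"ppg_file" %in% names(tab)) {
    stop("no waveforms available: neither in-memory nor a ppg_file column",
         call. = FALSE)
  }
  if (!use_wave && !has_cols) {
    stop("vitals = 'columns' requires HR_bpm and SpO2_pct columns",
         call. = FALSE)
  }

  rows <- vector("list", n)
  failures <- data.frame(row = integer(0), message = character(0))
  for (i in seq_len(n)) {
    res <- tryCatch({
      hf <- metabolic_heat(list(Tr = tab$Tr_K[i], tw = tab$tw_C[i],
                                ts = tab$ts_C[i], He = tab$He_frac[i]),
                           constants)
      if (use_wave) {
        wf <- if (!is.null(waveforms)) waveforms[[i]] else {
          read_ppg_csv(tab$ppg_file[i])
        }
        vs <- process_ppg(wf, coeffs)
        hr_i <- vs$HR; spo2_i <- vs$SpO2
      } else {
        hr_i <- tab$HR_bpm[i]; spo2_i <- tab$SpO2_pct[i]
      }
      data.frame(record_id = as.character(tab$record_id[i]),
                 H = hf$H, SpO2 = spo2_i, HR = hr_i, BF = tab$BF_pu[i],
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      if (strict) stop(sprintf("row %d: %s", i, res), call. = FALSE)
      failures <- rbind(failures, data.frame(row = i, message = res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(record_id = character(0), H = numeric(0),
                      SpO2 = numeric(0), HR = numeric(0), BF = numeric(0))
  }
  bg_col <- intersect(c("BG_ref_mmolL"), names(tab))
  if (length(bg_col)) {
    ok <- setdiff(seq_len(n), failures$row)
    out$bg_ref <- tab[[bg_col]][ok]
  }
  if (nrow(failures)) {
    warning(sprintf("%d row(s) failed feature extraction (see attr(, 'failures'))",
                    nrow(failures)), call. = FALSE)
  }
  attr(out, "failures") <- failures
  out
}
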