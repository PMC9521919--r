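#' Derive onset features from raw laboratory values
#'
#' Computes the two biochemical features used in DILI phenotyping from raw
#' activities at injury onset: the R-value, `(ALT/ULN_ALT) / (ALP/ULN_ALP)`,
#' which classifies the injury pattern (>5 hepatocellular, <2 cholestatic,
#' 2-5 mixed), and the AST/ALT (De Ritis) ratio, computed on raw activities.
#'
#' The AST/ALT ratio is conventionally taken on raw activities, not
#' ULN-normalised values; set `ast_alt_uln_normalised = TRUE` to use
#' `(AST/ULN_AST) / (ALT/ULN_ALT)` instead (requires `ast_uln`).
#'
#' @param alt,ast alanine / aspartate transaminase activity at onset (U/L).
#' @param alt_uln,alp_uln upper limits of normal for ALT and ALP (U/L).
#' @param alp alkaline phosphatase activity at onset (U/L).
#' @param ast_uln upper limit of normal for AST; only needed when
#'   `ast_alt_uln_normalised = TRUE`.
#' @param ast_alt_uln_normalised compute the AST/ALT ratio on ULN-normalised
#'   values instead of raw activities. Default `FALSE`.
#' @return A data frame with columns `r_value` and `ast_alt_ratio`, one row
#'   per input case.
#' @examples
#' derive_features(alt = 400, alt_uln = 40, alp = 120, alp_uln = 120, ast = 320)
#' @export
derive_features <- function(alt, alt_uln, alp, alp_uln, ast, ast_uln = NULL,
                            ast_alt_uln_normalised = FALSE) {
  labs <- list(alt = alt, alt_uln = alt_uln, alp = alp, alp_uln = alp_uln,
               ast = ast)
  if (isTRUE(ast_alt_uln_normalised)) {
    if (is.null(ast_uln)) {
      dc_validation_error("`ast_uln` is required when ast_alt_uln_normalised = TRUE")
    }
    labs$ast_uln <- ast_uln
  }
  for (field in names(labs)) {
    v <- labs[[field]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      dc_validation_error(sprintf("lab value `%s` must be positive and finite", field))
    }
  }
  r_value <- (alt / alt_uln) / (alp / alp_uln)
  ast_alt_ratio <- if (isTRUE(ast_alt_uln_normalised)) {
    (ast / ast_uln) / (alt / alt_uln)
  } else {
    ast / alt
  }
  data.frame(r_value = r_value, ast_alt_ratio = ast_alt_ratio)
}

#' Assemble and validate a DILI case table
#'
#' Builds the canonical case table used throughout the package: one row per
#' DILI case with `case_id`, `drug`, `latency_days` (days from drug start to
#' injury onset), `r_value`, and `ast_alt_ratio`. If the input carries raw
#' labs (`alt`, `alt_uln`, `alp`, `alp_uln`, `ast`) instead of the two derived
#' ratios, they are derived via [derive_features()].
#'
#' Records with a missing or invalid feature are rejected, not silently
#' dropped: every case used in phenotype building must have all three
#' features.
#'
#' @param data a data frame with columns `case_id`, `drug`, `latency_days`
#'   and either (`r_value`, `ast_alt_ratio`) or raw labs.
#' @param drug optional drug label; when given, overrides/fills the `drug`
#'   column.
#' @param round_latency round latency to whole days. Default `FALSE`.
#' @return A validated data frame with the five canonical columns.
#' @export
dili_cases <- function(data, drug = NULL, round_latency = FALSE) {
  if (!is.data.frame(data)) dc_validation_error("`data` must be a data frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(drug)) data$drug <- as.character(drug)
  if (is.null(data$case_id)) data$case_id <- paste0("case_", seq_len(nrow(data)))
  if (is.null(data$drug)) dc_validation_error("column `drug` is required (or pass `drug =`)")

  raw_cols <- c("alt", "alt_uln", "alp", "alp_uln", "ast")
  has_ratios <- all(c("r_value", "ast_alt_ratio") %in% names(data))
  has_raw <- all(raw_cols %in% names(data))
  if (!has_ratios && !has_raw) {
    dc_validation_error(
      "need either columns r_value + ast_alt_ratio, or raw labs alt, alt_uln, alp, alp_uln, ast")
  }
  if (!"latency_days" %in% names(data)) {
    dc_validation_error("column `latency_days` is required")
  }
  if (!has_ratios) {
    bad <- which(!vapply(data[raw_cols], is.numeric, logical(1)))
    for (i in seq_len(nrow(data))) {
      row <- data[i, raw_cols]
      if (anyNA(row) || any(!is.finite(unlist(row))) || any(unlist(row) <= 0)) {
        dc_validation_error(sprintf("row %d: raw lab values must be positive and finite", i))
      }
    }
    derived <- derive_features(data$alt, data$alt_uln, data$alp, data$alp_uln, data$ast)
    data$r_value <- derived$r_value
    data$ast_alt_ratio <- derived$ast_alt_ratio
  }
  if (isTRUE(round_latency)) data$latency_days <- round(data$latency_days)

  out <- data[, c("case_id", "drug", "latency_days", "r_value", "ast_alt_ratio")]
  validate_cases(out)
  out
}

# Row-level validation with row numbers in messages (CLI reports these).
validate_cases <- function(cases) {
  for (col in c("latency_days", "r_value", "ast_alt_ratio")) {
    v <- cases[[col]]
    if (!is.numeric(v)) dc_validation_error(sprintf("column `%s` must be numeric", col))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      dc_validation_error(sprintf("row %d: `%s` is missing or non-finite", bad[1], col))
    }
  }
  bad <- which(cases$latency_days <= 0)
  if (length(bad)) dc_validation_error(sprintf("row %d: `latency_days` must be > 0", bad[1]))
  bad <- which(cases$r_value < 0)
  if (length(bad)) dc_validation_error(sprintf("row %d: `r_value` must be >= 0", bad[1]))
  bad <- which(cases$ast_alt_ratio <= 0)
  if (length(bad)) dc_validation_error(sprintf("row %d: `ast_alt_ratio` must be > 0", bad[1]))
  invisible(cases)
}

#' Read and write case tables
#'
#' Case tables are UTF-8 comma-separated text with a header row and "."
#' decimal separator. Columns are `case_id`, `drug`, `latency_days` plus
#' either the derived features (`r_value`, `ast_alt_ratio`) or raw labs
#' (`alt`, `alt_uln`, `alp`, `alp_uln`, `ast`); raw labs are converted on
#' read. Lines starting with `#` are treated as comments (the writer uses
#' them for provenance headers).
#'
#' @param path file path.
#' @param ... passed to [dili_cases()] (e.g. `drug`, `round_latency`).
#' @return `read_dili_cases()`: a validated case table.
#' @export
read_dili_cases <- function(path, ...) {
  if (!file.exists(path)) dc_validation_error(sprintf("case file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                    fileEncoding = "UTF-8"),
    error = function(e) dc_validation_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0) dc_validation_error(sprintf("case file is empty: %s", path))
  dili_cases(df, ...)
}

#' @rdname read_dili_cases
#' @param cases a case table as returned by [dili_cases()].
#' @param header_lines optional character vector written as `#`-prefixed
#'   comment lines before the CSV header.
#' @export
write_dili_cases <- function(cases, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(cases, con, row.names = FALSE)
  invisible(path)
}
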