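# Readers and writers for the standard input files: bibliographic records
# (CSV or JSONL), the journal metrics table (CSV), positive-id lists and
# phrase lists (newline-delimited text).

#' Read bibliographic records from CSV or JSONL
#'
#' Records carry one article per row/line with fields `id`, `title`,
#' `abstract` and `journal_id`. JSONL files hold one JSON object per line;
#' CSV files use the same header. The format is inferred from the file
#' extension unless `format` is given.
#'
#' @param path file path.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @return data frame with character columns `id`, `title`, `abstract`,
#'   `journal_id` (absent fields become `NA`).
#' @export
read_records <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- switch(format,
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(lines, function(l) {
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
      })
      do.call(rbind, lapply(rows, function(r) {
        for (col in c("id", "title", "abstract", "journal_id")) {
          if (is.null(r[[col]])) r[[col]] <- NA_character_
        }
        r[, c("id", "title", "abstract", "journal_id"), drop = FALSE]
      }))
    },
    csv = utils::read.csv(path,
      stringsAsFactors = FALSE, encoding = "UTF-8",
      colClasses = "character"
    ),
    stop(sprintf("unknown record format '%s'", format), call. = FALSE)
  )
  check_columns(df, c("id", "title"), "record file")
  for (col in c("abstract", "journal_id")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  df$abstract[is.na(df$abstract)] <- ""
  df[, c("id", "title", "abstract", "journal_id"), drop = FALSE]
}

#' Write records as JSONL
#'
#' @param records data frame with `id`, `title`, `abstract`, `journal_id`
#'   and optionally `label`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- intersect(c("id", "title", "abstract", "journal_id", "label"), names(records))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, cols, drop = FALSE]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a journal metrics table
#'
#' Expected CSV columns: `journal_id`, `if_2015` .. `if_2021`, `cite_score`,
#' `sjr`, `snip`, `zone`, `h_index`. Empty cells denote missing metrics.
#'
#' @param path CSV file path.
#' @return data frame with `journal_id` as character, metric columns numeric
#'   (`NA` = missing) and `zone` integer in 1..4 or `NA`.
#' @export
read_journal_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(df, "journal_id", "journal table")
  df$journal_id <- as.character(df$journal_id)
  for (col in setdiff(journal_metric_columns(), names(df))) df[[col]] <- NA_real_
  for (col in journal_metric_columns()) df[[col]] <- as.numeric(df[[col]])
  if (is.null(df$zone)) df$zone <- NA_integer_
  df$zone <- as.integer(df$zone)
  bad <- !is.na(df$zone) & !(df$zone %in% 1:4)
  if (any(bad)) {
    stop(sprintf(
      "zone outside 1..4 for journal(s): %s",
      paste(utils::head(df$journal_id[bad], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' Read a newline-delimited id list
#' @param path text file, one id per line.
#' @return character vector (empty lines dropped).
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x)]
}

#' Read a phrase list file
#'
#' One phrase per line, words separated by spaces; all phrases share the
#' given gap bound.
#'
#' @param path text file path.
#' @param max_gap maximum intervening words (default 3).
#' @return list of [key_phrase] objects.
#' @export
read_phrases <- function(path, max_gap = 3L) {
  lines <- read_id_list(path)
  lapply(strsplit(lines, "\\s+"), key_phrase, max_gap = max_gap)
}
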