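# Delimited-text round trips. Numeric columns are written via "%.17g" so a
# written table re-reads to bit-identical doubles.

format_col <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write a table as tab-delimited text at full numeric precision
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_precise <- function(df, path) {
  out <- vapply(df, format_col, character(nrow(df)))
  if (nrow(df) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(df)))
  con <- file(path, "wb") # binary mode: identical bytes across platforms
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a table written by [write_table_precise()]
#' @param path input file.
#' @return data.frame.
#' @export
read_table_precise <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-subject trial data
#'
#' One row per (subject, trial): `subject_id`, `trial`, `choice`,
#' `reward` — the standard trial-level exchange format of the pipeline.
#'
#' @param records list of [behavioral_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, trial = r$trial,
               choice = r$choice, reward = r$reward)
  })
  write_table_precise(do.call(rbind, rows), path)
}

#' Read per-subject trial data
#' @param path file written by [write_trials()].
#' @return named list of [behavioral_record()]s, in file order.
#' @export
read_trials <- function(path) {
  df <- read_table_precise(path)
  need <- c("subject_id", "trial", "choice", "reward")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  recs <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, ]
    sub <- sub[order(sub$trial), ]
    behavioral_record(id, sub$choice, sub$reward)
  })
  stats::setNames(recs, ids)
}
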