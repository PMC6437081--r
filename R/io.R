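#' Write / read tabular results as TSV
#'
#' Plain tab-separated text with a header row; the format used for event
#' tables, ratings, trait scores, trial-scene tables and all statistical
#' outputs.
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_tsv_table` returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a raw recording as delimited text with a JSON sidecar
#'
#' Samples go to `<prefix>_samples.tsv` (one column per channel, microvolts);
#' acquisition metadata (sampling rate, channel labels, participant) goes to
#' `<prefix>.json`.
#'
#' @param recording a `femg_recording`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "femg_recording"))
  utils::write.table(round(recording$samples, 6),
                     paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = recording$sampling_rate,
         channels = recording$channels,
         participant = recording$participant,
         participant_gender = recording$participant_gender,
         n_samples = recording$n_samples,
         units = "uV"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time.
#' @return a `femg_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  samples <- as.matrix(utils::read.delim(paste0(prefix, "_samples.tsv"), sep = "\t"))
  colnames(samples) <- meta$channels
  structure(list(samples = samples,
                 channels = meta$channels,
                 sampling_rate = meta$sampling_rate,
                 participant = meta$participant,
                 participant_gender = meta$participant_gender,
                 responsiveness = NULL,
                 n_samples = nrow(samples)),
            class = "femg_recording")
}
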