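# Plain-text carriers: recordings and hypnograms as TSV, artifact events,
# hourly/gain tables, and a JSON provenance record.

#' Read and write EEG recordings as TSV
#'
#' Two-column TSV (`sample_index`, `value_uV`) with a `# fs=<Hz>`,
#' `# input_range_uV=<uV>`, `# zt0_offset=<h>` comment header.
#'
#' @param rec A [raw_recording()].
#' @param path File path.
#' @return `write_recording_tsv` returns `path` invisibly;
#'   `read_recording_tsv` returns a [raw_recording()].
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", rec$fs),
               sprintf("# input_range_uV=%.10g", rec$input_range_uV),
               sprintf("# zt0_offset=%.10g", rec$zt0_offset),
               "sample_index\tvalue_uV"), con)
  utils::write.table(data.frame(seq_along(rec$samples),
                                signif(rec$samples, 8)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[grepl("^# ", hdr)]
  getv <- function(key, default) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(line)) as.numeric(sub(".*=", "", line[1])) else default
  }
  d <- utils::read.delim(path, comment.char = "#")
  raw_recording(d[[2]], fs = getv("fs", 200),
                input_range_uV = getv("input_range_uV", 2e5),
                zt0_offset = getv("zt0_offset", 0))
}

#' Read and write hypnograms as TSV
#'
#' Two columns `epoch_index<TAB>label` with single-letter labels
#' (`w`, `n`, `r`, `a`) and a `# zt0_offset=<h>` header.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  code <- c(WAKE = "w", NREM = "n", REM = "r", ARTIFACT = "a")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# zt0_offset=%.10g", hyp$zt0_offset),
               sprintf("# epoch_len_s=%.10g", hyp$epoch_len_s)), con)
  utils::write.table(data.frame(seq_len(length(hyp)),
                                code[as.character(hyp$labels)]),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_tsv
#' @export
read_hypnogram_tsv <- function(path) {
  hdr <- readLines(path, n = 5)
  getv <- function(key, default) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(line)) as.numeric(sub(".*=", "", line[1])) else default
  }
  d <- utils::read.delim(path, header = FALSE, comment.char = "#")
  decode <- c(w = "WAKE", n = "NREM", r = "REM", a = "ARTIFACT")
  hypnogram(decode[as.character(d[[2]])],
            epoch_len_s = getv("epoch_len_s", 4),
            zt0_offset = getv("zt0_offset", 0))
}

#' Write artifact events as TSV (start_s, end_s, kind)
#'
#' @param mask An [artifact_mask()].
#' @param path File path.
#' @export
write_artifact_tsv <- function(mask, path) {
  ev <- mask$events
  out <- data.frame(start_s = (ev$start - 1) / mask$fs,
                    end_s = ev$end / mask$fs, kind = ev$kind)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a provenance record as JSON
#'
#' Echoes every configuration parameter and processing step verbatim into a
#' JSON file, so each reported number is traceable to its inputs.
#'
#' @param x A named list (configuration, provenance steps, seeds).
#' @param path Output path.
#' @export
write_provenance_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
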