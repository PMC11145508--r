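#' Multichannel recording container
#'
#' Holds a channels-by-samples amplitude matrix together with its sampling
#' rate, channel labels and a provenance trail of applied processing stages.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#'   A numeric vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Optional unique channel labels (default `ch1`, `ch2`, ...).
#' @param provenance Character vector of stage descriptors.
#' @return An object of class `mc_record`.
#' @export
new_record <- function(samples, fs, labels = NULL, provenance = character()) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples) || length(samples) == 0L) {
    stop_input("samples must be a non-empty numeric matrix (channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_input("fs must be a single positive number (Hz)")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples) || anyDuplicated(labels)) {
    stop_input("labels must be unique and match the number of channels")
  }
  structure(list(samples = samples, fs = as.numeric(fs),
                 labels = as.character(labels),
                 provenance = as.character(provenance)),
            class = "mc_record")
}

#' @export
print.mc_record <- function(x, ...) {
  cat(sprintf("<mc_record> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("    -", p, "\n")
  }
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a multichannel record to delimited text
#'
#' Emits a CSV (`time` column in seconds followed by one column per channel,
#' 17 significant digits so re-reading is lossless at double precision) and a
#' YAML sidecar `<path>.meta.yaml` holding the sampling rate, channel labels,
#' units and provenance. Re-writing an unchanged record is byte-identical.
#'
#' @param record An [new_record()] object.
#' @param path Output CSV path.
#' @param units Amplitude unit label stored in the sidecar (default `"mV"`).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, units = "mV") {
  stopifnot(inherits(record, "mc_record"))
  n <- ncol(record$samples)
  tm <- (seq_len(n) - 1L) / record$fs
  header <- paste(c("time", record$labels), collapse = ",")
  body <- vapply(seq_len(n), function(j) {
    paste(sprintf("%.17g", c(tm[j], record$samples[, j])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  meta <- list(fs = record$fs, labels = as.list(record$labels),
               units = units, provenance = as.list(record$provenance))
  writeLines(yaml::as.yaml(meta), sidecar_path(path))
  invisible(path)
}

#' Read a multichannel record written by [write_record()]
#'
#' The sidecar's sampling rate is authoritative; if the CSV carries a time
#' column whose implied rate disagrees by more than 0.1%, reading fails with
#' both values named.
#'
#' @param path CSV path (sidecar expected at `<path>.meta.yaml`).
#' @return An `mc_record`.
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop_input("missing sidecar ", sc, " (sampling rate unknown)")
  }
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$fs)) stop_input("sidecar ", sc, " does not declare fs")
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L || ncol(df) < 2L) stop_input("empty record in ", path)
  if (names(df)[1] == "time" && nrow(df) >= 2L) {
    fs_inferred <- 1 / stats::median(diff(df$time))
    if (abs(fs_inferred - meta$fs) / meta$fs > 0.001) {
      stop_input("time column implies fs = ", signif(fs_inferred, 6),
                 " Hz but sidecar declares fs = ", meta$fs, " Hz")
    }
  }
  samples <- t(as.matrix(df[, -1, drop = FALSE]))
  labels <- if (!is.null(meta$labels)) unlist(meta$labels) else rownames(samples)
  new_record(unname(samples), meta$fs, labels,
             provenance = unlist(meta$provenance) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
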