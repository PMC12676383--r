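# The EpochSet container: trials x channels x time tensor with labels,
# session ids and sampling metadata, plus its on-disk serialization.

#' Construct an epoch set
#'
#' The universal pipeline currency: a `trials x channels x time` array of EEG
#' (microvolts) with per-trial class labels and session / subject indices.
#'
#' @param data Numeric array `n x n_channels x n_time`.
#' @param labels Integer class labels in `1..Nclasses`, length `n`.
#' @param session_id Integer session index per trial, length `n`.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, length `n_channels`.
#' @param subject_id Integer subject index per trial (default 1).
#' @return An object of class `cvep_epochs`.
#' @export
new_epochs <- function(data, labels, session_id, fs,
                       channel_names = NULL, subject_id = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1]
  labels <- as.integer(labels)
  session_id <- as.integer(session_id)
  if (length(labels) != n) stop("labels length must match trial count")
  if (length(session_id) != n) stop("session_id length must match trial count")
  if (any(labels < 1L)) stop("labels must be positive class indices")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(subject_id)) subject_id <- rep(1L, n)
  structure(list(data = data, labels = labels, session_id = session_id,
                 subject_id = as.integer(subject_id), fs = fs,
                 channel_names = as.character(channel_names)),
            class = "cvep_epochs")
}

#' @export
print.cvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<cvep_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %s | sessions: %s\n",
              paste(sort(unique(x$labels)), collapse = ","),
              paste(sort(unique(x$session_id)), collapse = ",")))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs A `cvep_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial index
#' @param epochs A `cvep_epochs`.
#' @param idx Integer or logical trial index.
#' @return The subsetted `cvep_epochs`.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epochs(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
             epochs$session_id[idx], epochs$fs, epochs$channel_names,
             epochs$subject_id[idx])
}

#' Concatenate epoch sets along the trial axis
#' @param ... `cvep_epochs` objects with matching channel/time geometry.
#' @return A single `cvep_epochs`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "cvep_epochs"))
    xs <- xs[[1]]
  d <- dim(xs[[1]]$data)
  n_all <- sum(vapply(xs, n_trials, 1L))
  out <- array(0, c(n_all, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    stopifnot(all(dim(x$data)[2:3] == d[2:3]), x$fs == xs[[1]]$fs)
    out[at + seq_len(n_trials(x)), , ] <- x$data
    at <- at + n_trials(x)
  }
  new_epochs(out,
             unlist(lapply(xs, `[[`, "labels")),
             unlist(lapply(xs, `[[`, "session_id")),
             xs[[1]]$fs, xs[[1]]$channel_names,
             unlist(lapply(xs, `[[`, "subject_id")))
}

# Canonical epoch container: a single self-describing binary file.
# Layout: 4-byte little-endian integer = JSON header length in bytes,
# followed by the UTF-8 JSON header (field names as in new_epochs), followed
# by the data tensor as float64 little-endian in R array (column-major) order.

#' Write / read the canonical epoch container
#'
#' Lossless round trip of the data tensor, labels, session and subject ids,
#' sampling rate and channel names. The file is self-describing: a JSON
#' metadata block precedes the raw float64 tensor.
#'
#' @param epochs A `cvep_epochs`.
#' @param path Output file path (conventional extension `.cvep`).
#' @return `read_epochs` returns the `cvep_epochs`; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "cvep_epochs"))
  hdr <- jsonlite::toJSON(
    list(format = "cvep-epochs", version = 1L, dim = dim(epochs$data),
         fs = epochs$fs, channel_names = epochs$channel_names,
         labels = epochs$labels, session_id = epochs$session_id,
         subject_id = epochs$subject_id, storage = "float64-le"),
    auto_unbox = FALSE, digits = NA)
  raw_hdr <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(raw_hdr), con, size = 4L, endian = "little")
  writeBin(raw_hdr, con)
  writeBin(as.numeric(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n_hdr <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = n_hdr)))
  for (f in c("dim", "fs", "labels", "session_id", "channel_names"))
    if (is.null(hdr[[f]])) stop("epoch container is missing ", f)
  d <- as.integer(hdr$dim)
  dat <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
  new_epochs(array(dat, d), hdr$labels, hdr$session_id, as.numeric(hdr$fs),
             hdr$channel_names, hdr$subject_id %||% rep(1L, d[1]))
}
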