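# Binary m-sequence stimulation codes: generation, circular shifting,
# code banks and sample-domain expansion.

#' Construct a binary stimulation code
#'
#' @param bits Integer vector of 0s and 1s.
#' @return An object of class `cvep_code` with fields `bits` and `K`.
#' @export
new_code <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L || !all(bits %in% c(0L, 1L)))
    stop("code bits must be a non-empty vector of 0s and 1s")
  structure(list(bits = bits, K = length(bits)), class = "cvep_code")
}

#' @export
print.cvep_code <- function(x, ...) {
  cat(sprintf("<cvep_code> K=%d, ones=%d\n", x$K, sum(x$bits)))
  cat(paste(x$bits, collapse = ""), "\n")
  invisible(x)
}

#' Generate a maximal-length sequence from an LFSR
#'
#' Runs a Fibonacci linear-feedback shift register for one full period
#' \eqn{2^{degree} - 1} and returns the output bits. The feedback taps must
#' correspond to a primitive polynomial; a shorter period is detected and
#' rejected.
#'
#' @param degree Register length (polynomial degree), at least 2.
#' @param taps Integer set of tap positions in `1..degree`. Defaults to a
#'   standard primitive tap set for the degree (e.g. `c(6, 1)`, polynomial
#'   \eqn{x^6 + x + 1}, for degree 6). Non-primitive taps are detected by
#'   their short period and rejected.
#' @param init_state Bit vector of length `degree`, not all zero. Default all
#'   ones.
#' @return A [new_code()] object of length \eqn{2^{degree} - 1}.
#' @examples
#' generate_msequence(6)          # 63 bits, 32 ones
#' @export
generate_msequence <- function(degree, taps = default_taps(degree),
                               init_state = rep(1L, degree)) {
  degree <- as.integer(degree)
  if (degree < 2L) stop("degree must be at least 2")
  taps <- sort(unique(as.integer(taps)))
  if (any(taps < 1L | taps > degree)) stop("taps must lie in 1..degree")
  init_state <- as.integer(init_state)
  if (length(init_state) != degree || !all(init_state %in% c(0L, 1L)))
    stop("init_state must be a bit vector of length `degree`")
  if (all(init_state == 0L)) stop("degenerate LFSR state: all-zero init_state")

  period <- 2L^degree - 1L
  state <- init_state            # state[1] is the output end
  out <- integer(period)
  seen_init <- FALSE
  for (k in seq_len(period)) {
    out[k] <- state[1L]
    fb <- sum(state[taps]) %% 2L
    state <- c(state[-1L], fb)
    if (k < period && all(state == init_state)) seen_init <- TRUE
  }
  if (seen_init || !all(state == init_state))
    stop("taps are not primitive: LFSR period is shorter than 2^degree - 1")
  new_code(out)
}

#' Primitive feedback taps for small LFSR degrees
#'
#' Tap positions refer to the register state `(s_n, ..., s_{n+m-1})`: the
#' feedback bit `s_{n+m}` is the XOR of the tapped positions, so tap `t`
#' contributes the exponent `t - 1` of the characteristic polynomial
#' `x^m + sum_t x^(t-1)`. Every tabulated set includes tap 1 (constant
#' term) and defines a primitive polynomial, verified by the full-period
#' check in [generate_msequence()].
#'
#' @param degree Register length, 2..16.
#' @return Integer vector of tap positions.
#' @export
default_taps <- function(degree) {
  tab <- list(`2` = c(2L, 1L),                 # x^2 + x + 1
              `3` = c(3L, 1L),                 # x^3 + x^2 + 1
              `4` = c(4L, 1L),                 # x^4 + x^3 + 1
              `5` = c(3L, 1L),                 # x^5 + x^2 + 1
              `6` = c(6L, 1L),                 # x^6 + x^5 + 1
              `7` = c(7L, 1L),                 # x^7 + x^6 + 1
              `8` = c(7L, 6L, 5L, 1L),         # x^8 + x^6 + x^5 + x^4 + 1
              `9` = c(5L, 1L),                 # x^9 + x^4 + 1
              `10` = c(4L, 1L),                # x^10 + x^3 + 1
              `11` = c(3L, 1L),                # x^11 + x^2 + 1
              `12` = c(7L, 5L, 2L, 1L),        # x^12 + x^6 + x^4 + x + 1
              `13` = c(5L, 4L, 2L, 1L),        # x^13 + x^4 + x^3 + x + 1
              `14` = c(11L, 7L, 2L, 1L),       # x^14 + x^10 + x^6 + x + 1
              `15` = c(15L, 1L),               # x^15 + x^14 + 1
              `16` = c(13L, 4L, 2L, 1L))       # x^16 + x^12 + x^3 + x + 1
  taps <- tab[[as.character(as.integer(degree))]]
  if (is.null(taps)) stop("no default taps tabulated for degree ", degree)
  taps
}

#' The bundled 63-bit m-sequence stimulation code
#'
#' Returns the fixed 63-bit maximal-length sequence used to drive the 60 Hz
#' on/off flicker (bit 1 = stimulus image, bit 0 = black screen). The fixture
#' is validated at load: length 63, binary, 32 ones.
#'
#' @return A [new_code()] object with `K = 63`.
#' @export
paper_code <- function() {
  path <- system.file("extdata", "msequence63.txt", package = "cvepr")
  s <- if (nzchar(path)) readLines(path, warn = FALSE)[1] else .MSEQ63
  s <- gsub("[^01]", "", s)
  bits <- as.integer(strsplit(s, "")[[1]])
  if (length(bits) != 63L) stop("m-sequence fixture must have exactly 63 bits")
  code <- new_code(bits)
  if (sum(code$bits) != 32L) stop("m-sequence fixture must contain 32 ones")
  code
}

# inline copy so the function also works from a source-loaded session
.MSEQ63 <- "101011001101110110100100111000101111001010001100001000001111110"

#' Circularly shift a code
#'
#' Shift by `s` bits so that content moves to later positions:
#' `output[k] = input[(k - s) mod K]` (0-based). `s` is taken modulo `K`.
#'
#' @param code A `cvep_code`.
#' @param s Shift in bits (any integer).
#' @return The shifted `cvep_code`.
#' @export
circular_shift <- function(code, s) {
  stopifnot(inherits(code, "cvep_code"))
  K <- code$K
  s <- as.integer(s) %% K
  if (s == 0L) return(code)
  idx0 <- (seq_len(K) - 1L - s) %% K   # 0-based source index
  new_code(code$bits[idx0 + 1L])
}

#' Build a code bank from circular shifts
#'
#' One row per stimulus class, row `i` being the base code circularly shifted
#' by `shifts[i]` bits. Default shifts follow the six-class layout
#' 0, 8, 16, 24, 32, 40.
#'
#' @param code Base `cvep_code`.
#' @param shifts Integer vector of shift amounts, distinct modulo `K`.
#' @return A `cvep_codebank`: list with `codes` (Nclasses x K 0/1 matrix),
#'   `shifts` and `n_classes`.
#' @export
build_code_bank <- function(code, shifts = c(0L, 8L, 16L, 24L, 32L, 40L)) {
  stopifnot(inherits(code, "cvep_code"))
  shifts <- as.integer(shifts)
  if (anyDuplicated(shifts %% code$K))
    stop("duplicate shifts (modulo K) in code bank")
  codes <- t(vapply(shifts, function(s) circular_shift(code, s)$bits,
                    integer(code$K)))
  rownames(codes) <- paste0("class", seq_along(shifts))
  structure(list(codes = codes, shifts = shifts, n_classes = length(shifts)),
            class = "cvep_codebank")
}

#' @export
print.cvep_codebank <- function(x, ...) {
  cat(sprintf("<cvep_codebank> %d classes x %d bits, shifts: %s\n",
              x$n_classes, ncol(x$codes), paste(x$shifts, collapse = ", ")))
  invisible(x)
}

#' Expand a code to a sample-domain waveform
#'
#' Zero-order-hold expansion of a bit sequence presented at the screen refresh
#' rate into the EEG sampling grid: sample `t` (0-based) carries bit
#' `floor(t * refresh_hz / fs)`. The waveform length is
#' `round(K * fs / refresh_hz)` samples (63 bits at 60 Hz sampled at 512 Hz
#' gives 538 samples, about 1.05 s).
#'
#' @param code A `cvep_code`.
#' @param refresh_hz Screen refresh rate in Hz (default 60).
#' @param fs EEG sampling rate in Hz (default 512).
#' @return Numeric 0/1 vector of length `Nt`.
#' @export
code_to_waveform <- function(code, refresh_hz = 60, fs = 512) {
  stopifnot(inherits(code, "cvep_code"), refresh_hz > 0, fs > 0)
  nt <- as.integer(round(code$K * fs / refresh_hz))
  t0 <- seq_len(nt) - 1L
  bit_idx <- floor(t0 * refresh_hz / fs)          # 0-based bit index
  as.numeric(code$bits[(bit_idx %% code$K) + 1L])
}

#' Number of samples per code period
#'
#' @inheritParams code_to_waveform
#' @param K Code length in bits.
#' @return Integer sample count `round(K * fs / refresh_hz)`.
#' @export
samples_per_period <- function(K = 63, refresh_hz = 60, fs = 512) {
  as.integer(round(K * fs / refresh_hz))
}

#' Serialize / read codes as plain text and JSON
#'
#' `write_code` writes one 0/1 character per bit; `read_code` reads it back.
#' `write_code_bank` / `read_code_bank` use JSON with `bits` (base code rows)
#' and `shifts`.
#'
#' @param code A `cvep_code`.
#' @param path File path.
#' @return `read_code` returns a `cvep_code`; writers return the path
#'   invisibly.
#' @export
write_code <- function(code, path) {
  stopifnot(inherits(code, "cvep_code"))
  writeLines(paste(code$bits, collapse = ""), path)
  invisible(path)
}

#' @rdname write_code
#' @export
read_code <- function(path) {
  s <- gsub("[^01]", "", readLines(path, warn = FALSE)[1])
  new_code(as.integer(strsplit(s, "")[[1]]))
}

#' @rdname write_code
#' @param bank A `cvep_codebank`.
#' @export
write_code_bank <- function(bank, path) {
  stopifnot(inherits(bank, "cvep_codebank"))
  jsonlite::write_json(
    list(codes = unname(apply(bank$codes, 1, paste, collapse = "")),
         shifts = bank$shifts),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_code
#' @export
read_code_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  codes <- t(vapply(obj$codes,
                    function(s) as.integer(strsplit(s, "")[[1]]),
                    integer(nchar(obj$codes[1]))))
  rownames(codes) <- paste0("class", seq_len(nrow(codes)))
  structure(list(codes = codes, shifts = as.integer(obj$shifts),
                 n_classes = nrow(codes)),
            class = "cvep_codebank")
}

#' Circular cross-correlation of two codes after +/-1 mapping
#'
#' Maps bits to +/-1 and returns the circular cross-correlation
#' `sum_k a[k] * b[(k + lag) mod K]`. For a maximal-length sequence against
#' itself this equals `K` at lag 0 and -1 at all other lags.
#'
#' @param a,b `cvep_code` objects of equal length.
#' @param lag Integer lag (default 0).
#' @return Numeric correlation value.
#' @export
code_crosscorr <- function(a, b, lag = 0L) {
  stopifnot(inherits(a, "cvep_code"), inherits(b, "cvep_code"), a$K == b$K)
  x <- 2 * a$bits - 1
  y <- 2 * b$bits - 1
  idx0 <- (seq_len(a$K) - 1L + as.integer(lag)) %% a$K
  sum(x * y[idx0 + 1L])
}
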