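# Temporal-shift augmentation and test-time decision combination
# (NA / TA / TC / TA&TC), plus class expansion by circular code-shift
# relabeling.

#' Augmentation configuration
#'
#' @param alpha_shift Shift magnitude in samples (0, 1, 2, 4 or 8 in the
#'   reference grid; any nonnegative integer accepted).
#' @param mode `"NA"` (none), `"TA"` (train augmentation: shifted copies at
#'   -alpha and +alpha added to the training set), `"TC"` (test combination:
#'   scores averaged over inputs shifted by -alpha, 0, +alpha) or `"TA_TC"`
#'   (both).
#' @return A `cvep_augconfig` list.
#' @export
augment_config <- function(alpha_shift = 0L,
                           mode = c("NA", "TA", "TC", "TA_TC")) {
  mode <- match.arg(mode)
  stopifnot(alpha_shift >= 0)
  structure(list(alpha_shift = as.integer(alpha_shift), mode = mode),
            class = "cvep_augconfig")
}

#' Circularly shift epochs along the time axis
#'
#' Content moves `s` samples later (wrap-around; the stimulus is periodic
#' with the epoch). Labels, sessions and geometry preserved. `|s|` must be
#' smaller than the epoch length.
#'
#' @param epochs A `cvep_epochs`.
#' @param s Shift in samples (may be negative).
#' @return Shifted `cvep_epochs`.
#' @export
shift_epochs <- function(epochs, s) {
  stopifnot(inherits(epochs, "cvep_epochs"))
  nt <- dim(epochs$data)[3]
  if (abs(s) >= nt) stop("|s| must be smaller than the epoch length")
  s <- as.integer(s) %% nt
  if (s == 0L) return(epochs)
  idx <- ((seq_len(nt) - 1L - s) %% nt) + 1L
  new_epochs(epochs$data[, , idx, drop = FALSE], epochs$labels,
             epochs$session_id, epochs$fs, epochs$channel_names,
             epochs$subject_id)
}

#' Expand a training set with shifted copies
#'
#' Returns the original trials plus copies shifted by `-alpha` and `+alpha`
#' (tripling the trial count when `alpha > 0`); labels and session ids are
#' preserved on the copies. Only meaningful for the TA and TA&TC modes.
#'
#' @param train A `cvep_epochs`.
#' @param cfg An [augment_config()] with mode `"TA"` or `"TA_TC"`.
#' @return Expanded `cvep_epochs` (input left unmodified).
#' @export
expand_train <- function(train, cfg) {
  stopifnot(inherits(cfg, "cvep_augconfig"))
  if (!cfg$mode %in% c("TA", "TA_TC"))
    stop("expand_train applies only to TA / TA_TC modes")
  a <- cfg$alpha_shift
  if (a == 0L) return(train)
  bind_epochs(list(train, shift_epochs(train, -a), shift_epochs(train, a)))
}

#' Combine scores over shifted test inputs
#'
#' Evaluates `score_fn` on the test set shifted by each element of
#' `{-alpha, 0, +alpha}` (the unshifted view included) and returns the
#' element-wise mean score matrix. For probabilistic scorers the label is the
#' argmax of the mean; for distance matrices pass `decision = "min"` so
#' distances are averaged and the argmin taken.
#'
#' @param score_fn Function `cvep_epochs -> trials x classes matrix`.
#' @param test A `cvep_epochs`.
#' @param cfg An [augment_config()] (mode `"TC"` or `"TA_TC"`; `"NA"`/`"TA"`
#'   behave as alpha = 0).
#' @param decision `"max"` (scores) or `"min"` (distances).
#' @return List with `scores` (the combined matrix) and `labels`.
#' @export
combine_test <- function(score_fn, test, cfg, decision = c("max", "min")) {
  decision <- match.arg(decision)
  stopifnot(inherits(cfg, "cvep_augconfig"))
  a <- if (cfg$mode %in% c("TC", "TA_TC")) cfg$alpha_shift else 0L
  shifts <- unique(c(-a, 0L, a))
  S <- NULL
  for (s in shifts) {
    m <- score_fn(shift_epochs(test, s))
    S <- if (is.null(S)) m else S + m
  }
  S <- S / length(shifts)
  labels <- if (decision == "max") argmax_rows(S) else argmin_rows(S)
  list(scores = S, labels = labels)
}

#' Expand single-target trials over all classes by circular relabeling
#'
#' A trial recorded under the class-`i` code, circularly shifted in time by
#' the sample equivalent of `shifts[j] - shifts[i]` bits, is a valid example
#' of class `j`. Applying all shifts turns one block of `n` single-target
#' trials into `n * Nclasses` labeled examples (114 trials -> 684 under the
#' default six-class bank).
#'
#' @param epochs A `cvep_epochs`.
#' @param bank The [build_code_bank()] defining the class shifts.
#' @param refresh_hz Stimulus refresh rate (bits per second; default 60).
#' @return A `cvep_epochs` with `n * Nclasses` trials.
#' @export
expand_classes <- function(epochs, bank, refresh_hz = 60) {
  stopifnot(inherits(epochs, "cvep_epochs"), inherits(bank, "cvep_codebank"))
  samples_per_bit <- epochs$fs / refresh_hz
  out <- vector("list", bank$n_classes)
  for (j in seq_len(bank$n_classes)) {
    delta_bits <- bank$shifts[j] - bank$shifts[epochs$labels]
    s_all <- as.integer(round(delta_bits * samples_per_bit))
    # group trials by identical sample shift to shift in blocks
    parts <- split(seq_len(n_trials(epochs)), s_all)
    pieces <- lapply(names(parts), function(sv) {
      sub <- subset_epochs(epochs, parts[[sv]])
      sub <- shift_epochs(sub, as.integer(sv) %% dim(sub$data)[3])
      sub$labels <- rep(j, n_trials(sub))
      sub
    })
    out[[j]] <- bind_epochs(pieces)
  }
  bind_epochs(out)
}
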