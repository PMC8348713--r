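#' Construct a trial record
#'
#' A trial record holds one subject-trial: the channel-by-time EEG signal
#' (microvolts) plus the four self-assessment ratings. For a full DEAP-style
#' trial at 128 Hz the signal is 32 x 8064 samples: 3 s of pre-stimulus
#' baseline followed by 60 s of stimulus.
#'
#' @param subject_id Integer subject identifier.
#' @param trial_id Integer trial identifier.
#' @param signal Numeric matrix, channels x samples.
#' @param ratings Named numeric vector with entries `valence`, `arousal`,
#'   `dominance`, `liking`, each in \[1, 9\].
#' @param sampling_rate_hz Sampling rate in Hz (default 128).
#' @return A `trial_record` object.
#' @export
trial_record <- function(subject_id, trial_id, signal, ratings,
                         sampling_rate_hz = 128) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("signal must be a numeric channels x samples matrix")
  need <- c("valence", "arousal", "dominance", "liking")
  if (!all(need %in% names(ratings)))
    stopf("ratings must be named with: %s", paste(need, collapse = ", "))
  ratings <- ratings[need]
  if (any(ratings < 1 | ratings > 9))
    stopf("ratings must lie in [1, 9]")
  structure(
    list(subject_id = as.integer(subject_id), trial_id = as.integer(trial_id),
         signal = signal, ratings = ratings,
         sampling_rate_hz = sampling_rate_hz),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %d trial %d: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate_hz))
  cat("  ratings:", paste(sprintf("%s=%.2f", names(x$ratings), x$ratings),
                          collapse = " "), "\n")
  invisible(x)
}

#' Load one subject's trials from a preprocessed-layout file
#'
#' Reads a per-subject container with the DEAP preprocessed layout: a
#' `data` array of 40 trials x 40 channels x 8064 samples and a `labels`
#' matrix of 40 trials x 4 ratings (valence, arousal, dominance, liking).
#' Only the first 32 signal channels (the EEG electrodes) are retained, in
#' the file's native channel order; peripheral channels 33-40 are dropped.
#' The container is an RDS serialization of `list(data = ..., labels = ...)`;
#' [write_subject_file()] produces it, so synthetic and real-layout data share
#' a single ingestion path.
#'
#' @param path Path to a subject file.
#' @return List of 40 [trial_record()] objects.
#' @export
load_deap_subject <- function(path) {
  if (!file.exists(path))
    stopf(paste("data unavailable: %s does not exist;",
                "generate a synthetic subject with generate_dataset() +",
                "write_subject_file() or point data.path at a local copy"),
          path, class = "msceeg_data_unavailable")
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
    stopf("malformed subject file: expected list(data, labels)",
          class = "msceeg_format_error")
  d <- dim(obj$data)
  if (length(d) != 3L)
    stopf("malformed data array: expected 3 dimensions, got %d", length(d),
          class = "msceeg_format_error")
  if (d[1] != 40L)
    stopf("malformed data array: dimension 1 (trials) is %d, expected 40", d[1],
          class = "msceeg_format_error")
  if (d[2] < 32L)
    stopf("malformed data array: dimension 2 (channels) is %d, expected >= 32",
          d[2], class = "msceeg_format_error")
  dl <- dim(obj$labels)
  if (is.null(dl) || dl[1] != 40L || dl[2] != 4L)
    stopf("malformed labels: expected 40 x 4, got %s",
          paste(dl, collapse = " x "), class = "msceeg_format_error")
  subject_id <- obj$subject_id %||% 1L
  fs <- obj$sampling_rate_hz %||% 128
  lapply(seq_len(40L), function(t) {
    sig <- obj$data[t, seq_len(32L), , drop = TRUE]
    trial_record(subject_id, t, sig,
                 setNames(as.numeric(obj$labels[t, ]),
                          c("valence", "arousal", "dominance", "liking")),
                 sampling_rate_hz = fs)
  })
}

#' Binarize a self-assessment rating
#'
#' Splits ratings in \[1, 9\] into `low`/`high` at a threshold (default 5).
#' Ratings exactly equal to the threshold are `low`: `high` iff
#' `rating > threshold`.
#'
#' @param rating Numeric vector of ratings in \[1, 9\].
#' @param threshold Split point (default 5).
#' @return Character vector of `"low"`/`"high"`.
#' @export
#' @examples
#' binarize_rating(c(1, 5, 5.1, 9))
binarize_rating <- function(rating, threshold = 5) {
  if (any(rating < 1 | rating > 9))
    stopf("rating out of range [1, 9]")
  ifelse(rating > threshold, "high", "low")
}

#' Four-class emotion labels
#'
#' The four-class scheme is the cross product of the binary arousal and
#' valence labels, in the order HAHV (high arousal high valence), HALV,
#' LAHV, LALV with class indices 0-3.
#'
#' @param arousal_class,valence_class `"low"` or `"high"` (vectorized).
#' @return Character vector with levels `HAHV`, `HALV`, `LAHV`, `LALV`.
#' @export
#' @examples
#' four_class_label("high", "low")  # "HALV"
four_class_label <- function(arousal_class, valence_class) {
  ok <- function(x) all(x %in% c("low", "high"))
  if (!ok(arousal_class) || !ok(valence_class))
    stopf("classes must be 'low' or 'high'")
  a <- arousal_class == "high"
  v <- valence_class == "high"
  four_class_levels()[1L + (!a) * 2L + (!v)]
}

#' @rdname four_class_label
#' @export
four_class_levels <- function() c("HAHV", "HALV", "LAHV", "LALV")

#' Derive an integer class label for a classification task
#'
#' @param ratings Named ratings vector (needs `arousal` and/or `valence`).
#' @param task One of `"arousal_binary"`, `"valence_binary"`, `"four_class"`.
#' @param threshold Rating split point (default 5).
#' @return 0-based integer class index: binary tasks 0 = low, 1 = high;
#'   four-class 0-3 in [four_class_levels()] order.
#' @export
label_for_task <- function(ratings, task = c("arousal_binary",
                                             "valence_binary", "four_class"),
                           threshold = 5) {
  task <- match.arg(task)
  switch(task,
    arousal_binary = as.integer(binarize_rating(ratings[["arousal"]],
                                                threshold) == "high"),
    valence_binary = as.integer(binarize_rating(ratings[["valence"]],
                                                threshold) == "high"),
    four_class = {
      lab <- four_class_label(binarize_rating(ratings[["arousal"]], threshold),
                              binarize_rating(ratings[["valence"]], threshold))
      match(lab, four_class_levels()) - 1L
    })
}

#' Number of classes for a task
#' @param task Task name as in [label_for_task()].
#' @return 2 or 4.
#' @export
n_classes_for_task <- function(task) {
  if (task == "four_class") 4L else 2L
}
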