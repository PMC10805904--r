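# EEG ingestion (EDF / CSV), cleaning, downsampling, windowing,
# class-ratio rebalancing, and patient-disjoint split management.

#' @noRd
new_recording <- function(data, sampling_rate, channels, patient_id,
                          invalid = NULL) {
  data <- as.matrix(data)
  if (is.null(invalid)) invalid <- rep(FALSE, ncol(data))
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = channels, patient_id = patient_id,
                 invalid = invalid),
            class = "eeg_recording")
}

# minimal reader for 16-bit EDF: 256-byte ASCII header, per-signal header
# blocks, then interleaved int16 data records scaled to physical units
#' @noRd
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                                   # version
  patient <- rd(80)
  rd(80)                                  # recording id
  rd(8); rd(8)                            # start date / time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdn(16)
  rdn(80)                                 # transducer
  rdn(8)                                  # physical dimension
  pmin_ <- as.numeric(rdn(8))
  pmax_ <- as.numeric(rdn(8))
  dmin_ <- as.numeric(rdn(8))
  dmax_ <- as.numeric(rdn(8))
  rdn(80)                                 # prefiltering
  spr <- as.integer(rdn(8))
  rdn(32)                                 # reserved
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      sig[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2,
                               signed = TRUE, endian = "little")
    }
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- lapply(seq_len(ns), function(i) {
    d <- unlist(sig[[i]])
    pmin_[i] + (d - dmin_[i]) * scale[i]
  })
  list(labels = labels, data = data, samples_per_record = spr,
       record_duration = rec_dur, patient = patient)
}

#' Read a continuous EEG recording
#'
#' Reads an EDF file (16-bit, equal-rate EEG signals) or a CSV matrix
#' (one row per channel, first field the channel name, no header) and
#' applies the cleaning rules: channels on the exclusion name list are
#' dropped, duplicate channel names keep only their first occurrence,
#' and samples that are non-finite on any retained channel are flagged
#' invalid so that windowing can exclude them.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param sampling_rate Required for CSV input (Hz).
#' @param patient_id Patient identifier; defaults to the EDF patient
#'   field or the file name.
#' @param exclude_channels Channel names to drop (case-insensitive exact
#'   match); defaults cover the dummy/non-EEG channels of common scalp
#'   corpora.
#' @return An object of class `eeg_recording`: channels x samples matrix
#'   `data`, `sampling_rate`, `channels`, `patient_id`, and a logical
#'   per-sample `invalid` mask.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           sampling_rate = NULL, patient_id = NULL,
                           exclude_channels = c("-", "ECG", "EKG", "VNS")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    e <- read_edf(path)
    rates <- e$samples_per_record / e$record_duration
    keep_rate <- rates == max(rates)
    labels <- e$labels[keep_rate]
    data <- do.call(rbind, e$data[keep_rate])
    rate <- max(rates)
    if (is.null(patient_id)) {
      patient_id <- if (nzchar(e$patient)) e$patient else basename(path)
    }
  } else {
    if (is.null(sampling_rate)) {
      stop("`sampling_rate` is required for CSV input.", call. = FALSE)
    }
    raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(raw[[1]])
    data <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(data) <- "double"
    rate <- sampling_rate
    if (is.null(patient_id)) patient_id <- basename(path)
  }
  keep <- !(toupper(labels) %in% toupper(exclude_channels)) &
    !duplicated(labels)
  if (!any(keep)) stop("no channels left after cleaning.", call. = FALSE)
  data <- data[keep, , drop = FALSE]
  labels <- labels[keep]
  invalid <- unname(apply(data, 2, function(col) any(!is.finite(col))))
  data[!is.finite(data)] <- 0
  new_recording(data, rate, labels, patient_id, invalid)
}

#' Downsample a recording by an integer factor
#'
#' Applies an 8th-order Butterworth low-pass (zero-phase, cutoff at 0.4
#' times the target rate) followed by decimation. The target rate must
#' divide the source rate; equal rates return the recording unchanged
#' (no filtering).
#'
#' @param rec An `eeg_recording`.
#' @param target_rate Target sampling rate (Hz).
#' @return The downsampled `eeg_recording`.
#' @export
downsample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  src <- rec$sampling_rate
  if (target_rate == src) return(rec)
  factor <- src / target_rate
  if (factor != round(factor) || factor < 1) {
    stop("`target_rate` must divide the source rate.", call. = FALSE)
  }
  factor <- as.integer(factor)
  bf <- signal::butter(8, 0.4 * target_rate / (src / 2), type = "low")
  filtered <- t(apply(rec$data, 1, function(ch) {
    signal::filtfilt(bf, ch)
  }))
  idx <- seq(1L, ncol(rec$data), by = factor)
  n_out <- length(idx)
  inv <- vapply(seq_len(n_out), function(k) {
    any(rec$invalid[((k - 1L) * factor + 1L):min(k * factor,
                                                 ncol(rec$data))])
  }, logical(1))
  new_recording(filtered[, idx, drop = FALSE], target_rate, rec$channels,
                rec$patient_id, inv)
}

#' Window a recording into labeled segments
#'
#' Cuts the recording into consecutive non-overlapping windows of
#' `window_seconds` (the trailing partial window is dropped). A window
#' is labeled seizure if its overlap with any annotated seizure interval
#' strictly exceeds `overlap_threshold` of the window length; windows
#' touching invalid samples are excluded.
#'
#' @param rec An `eeg_recording`.
#' @param annotations Tibble/data frame of seizure intervals with
#'   columns `start_s`, `end_s` (half-open, seconds), or `NULL`.
#' @param window_seconds Window length in seconds (>= 1 sample).
#' @param overlap_threshold Fraction of the window that must be covered
#'   (strictly more than) for a seizure label; default 0.5.
#' @return A segments tibble: `segment_id`, `patient_id`, `label`,
#'   `start_s`, `window_seconds`, `sampling_rate`, `synthetic`, `data`
#'   (list of channels x samples matrices).
#' @export
segment_recording <- function(rec, annotations = NULL, window_seconds,
                              overlap_threshold = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"), window_seconds > 0)
  ws <- as.integer(round(window_seconds * rec$sampling_rate))
  n_win <- ncol(rec$data) %/% ws
  if (n_win == 0L) {
    warning("window longer than the recording; no segments produced.",
            call. = FALSE)
    return(empty_segments())
  }
  rows <- vector("list", n_win)
  kept <- 0L
  for (k in seq_len(n_win)) {
    idx <- ((k - 1L) * ws + 1L):(k * ws)
    if (any(rec$invalid[idx])) next
    start_s <- (k - 1L) * window_seconds
    end_s <- k * window_seconds
    lab <- 0L
    if (!is.null(annotations) && nrow(annotations) > 0) {
      ov <- sum(pmax(0, pmin(annotations$end_s, end_s) -
                       pmax(annotations$start_s, start_s)))
      lab <- as.integer(ov > overlap_threshold * window_seconds)
    }
    kept <- kept + 1L
    rows[[kept]] <- tibble::tibble(
      segment_id = sprintf("%s_w%04d", rec$patient_id, k),
      patient_id = rec$patient_id,
      label = lab,
      start_s = start_s,
      window_seconds = window_seconds,
      sampling_rate = rec$sampling_rate,
      synthetic = FALSE,
      data = list(rec$data[, idx, drop = FALSE]))
  }
  if (kept == 0L) return(empty_segments())
  dplyr::bind_rows(rows[seq_len(kept)])
}

#' Rebalance the seizure : non-seizure segment ratio
#'
#' Keeps every seizure segment and uniformly subsamples the non-seizure
#' segments to `ratio` per seizure segment (or all of them, if fewer);
#' no segment is ever duplicated.
#'
#' @param segments Segments tibble.
#' @param ratio Non-seizure segments to keep per seizure segment.
#' @param seed Integer seed for the subsample.
#' @return The rebalanced segments tibble (original row order).
#' @export
rebalance_segments <- function(segments, ratio = 5, seed = 1L) {
  n1 <- sum(segments$label == 1)
  if (n1 == 0) {
    stop("no seizure segments to rebalance against (patients: ",
         paste(unique(segments$patient_id), collapse = ", "), ").",
         call. = FALSE)
  }
  idx0 <- which(segments$label == 0)
  keep_n <- min(length(idx0), ratio * n1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep0 <- sort(sample(idx0, keep_n))
  segments[sort(c(which(segments$label == 1), keep0)), ]
}

#' Build patient-disjoint train / fine-tune / evaluation splits
#'
#' Leave-one-out mode yields one fold per patient, with that patient's
#' segments held out; holdout mode yields a single fold for the given
#' test patients. In both modes the first `finetune_fraction` of each
#' test patient's segments, in temporal order, form an adaptation set
#' that is excluded from evaluation. Train and test patient sets are
#' disjoint by construction and verified.
#'
#' @param segments Segments tibble.
#' @param mode `"leave_one_out"` or `"holdout"`.
#' @param test_patients Patient ids held out (required for holdout).
#' @param finetune_fraction Fraction in \[0, 1).
#' @return A tibble with columns `fold`, `test_patient`, and
#'   list-columns `train`, `finetune`, `eval`.
#' @export
make_splits <- function(segments, mode = c("leave_one_out", "holdout"),
                        test_patients = NULL, finetune_fraction = 0) {
  mode <- match.arg(mode)
  stopifnot(finetune_fraction >= 0, finetune_fraction < 1)
  patients <- sort(unique(segments$patient_id))
  folds <- if (mode == "leave_one_out") {
    lapply(patients, function(p) list(test = p))
  } else {
    if (is.null(test_patients)) {
      stop("`test_patients` is required for holdout splits.", call. = FALSE)
    }
    if (!all(test_patients %in% patients)) {
      stop("unknown test patients.", call. = FALSE)
    }
    list(list(test = test_patients))
  }
  rows <- lapply(seq_along(folds), function(k) {
    test <- folds[[k]]$test
    train <- segments[!(segments$patient_id %in% test), ]
    if (any(train$patient_id %in% test)) {
      stop("patient appears in both train and test sets.", call. = FALSE)
    }
    held <- segments[segments$patient_id %in% test, ]
    ft_rows <- list()
    ev_rows <- list()
    for (p in test) {
      hp <- held[held$patient_id == p, ]
      hp <- hp[order(hp$start_s), ]
      n_ft <- floor(finetune_fraction * nrow(hp))
      ft_rows[[p]] <- if (n_ft > 0) hp[seq_len(n_ft), ] else hp[0, ]
      ev_rows[[p]] <- if (n_ft > 0) hp[-seq_len(n_ft), ] else hp
    }
    tibble::tibble(fold = k,
                   test_patient = paste(test, collapse = "+"),
                   train = list(train),
                   finetune = list(dplyr::bind_rows(ft_rows)),
                   eval = list(dplyr::bind_rows(ev_rows)))
  })
  dplyr::bind_rows(rows)
}
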