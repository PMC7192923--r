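## Binary fast-AM / slow-AM syllable classification on temporal modulation
## spectra, and the sequence-position analysis of fast-AM syllables.

#' TMS feature vector on a fixed grid
#'
#' Averages normalized TMS power into bins centered on a fixed
#' 0-4000 Hz grid (default 10 Hz steps, 401 values) and renormalizes to
#' unit sum, giving a length-invariant, level-invariant feature vector.
#'
#' @param tms A `"tms"` object from [temporal_modulation_spectrum()].
#' @param step_hz Feature grid step, Hz.
#' @param fmax_hz Upper grid edge, Hz.
#' @return Numeric feature vector of length `fmax_hz / step_hz + 1`.
#' @export
tms_feature_vector <- function(tms, step_hz = 10, fmax_hz = 4000) {
  stopifnot(inherits(tms, "tms"))
  bin <- pmin(round(tms$freq_hz / step_hz), fmax_hz / step_hz)
  v <- vapply(0:(fmax_hz / step_hz), function(b) {
    sel <- bin == b
    if (any(sel)) mean(tms$power[sel]) else 0
  }, numeric(1))
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Train the fast-AM / slow-AM support-vector classifier
#'
#' Fits a binary SVM with a radial-basis-function kernel on TMS feature
#' vectors, without feature standardization (box constraint 1). The
#' cross-validation error is computed by seeded, stratified 10-fold
#' cross-validation.
#'
#' @param features Numeric matrix, one row per training syllable.
#' @param labels Factor or character vector with exactly two classes.
#' @param seed Integer seed for the cross-validation folds.
#' @param gamma RBF kernel coefficient (1 / kernel scale squared);
#'   the default kernel scale ~0.32 matches the scale of unit-sum TMS
#'   feature vectors.
#' @param cost Box constraint.
#' @param n_folds Number of cross-validation folds.
#' @return An object of class `"rough_classifier"`: the fitted svm,
#'   `cv_error` (fraction), `levels`, and the training parameters.
#' @export
train_classifier <- function(features, labels, seed = 1L, gamma = 10,
                             cost = 1, n_folds = 10L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required (got ", nlevels(labels), ")")
  fit <- e1071::svm(features, labels, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  errs <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    if (!any(!tr) || length(unique(labels[tr])) < 2L) return(NA_real_)
    m <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
    pred <- stats::predict(m, features[!tr, , drop = FALSE])
    mean(pred != labels[!tr])
  }, numeric(1))
  structure(list(fit = fit, cv_error = mean(errs, na.rm = TRUE),
                 levels = levels(labels), gamma = gamma, cost = cost,
                 n_train = nrow(features)),
            class = "rough_classifier")
}

#' @export
print.rough_classifier <- function(x, ...) {
  cat(sprintf(paste0("<rough_classifier: RBF SVM, %d training syllables ",
                     "(%s), 10-fold CV error %.1f%%>\n"),
              x$n_train, paste(x$levels, collapse = " vs "),
              100 * x$cv_error))
  invisible(x)
}

#' Classify syllables with a trained model
#'
#' @param model A `"rough_classifier"`.
#' @param features Numeric matrix of feature vectors (same length as the
#'   training vectors), one row per syllable.
#' @param positive Label counted in the reported fraction (default the
#'   first training level, conventionally `"fAMV"`).
#' @return A list: `labels` (character), `fraction` of `positive`
#'   labels (NA, flagged, for an empty corpus), `defined`.
#' @export
classify_syllables <- function(model, features,
                               positive = model$levels[1L]) {
  stopifnot(inherits(model, "rough_classifier"))
  features <- as.matrix(features)
  if (nrow(features) == 0L)
    return(list(labels = character(0), fraction = NA_real_,
                defined = FALSE))
  if (ncol(features) != ncol(model$fit$SV))
    stop("feature length (", ncol(features),
         ") does not match the training features (", ncol(model$fit$SV), ")")
  labels <- as.character(stats::predict(model, features))
  list(labels = labels, fraction = mean(labels == positive),
       defined = TRUE)
}

#' @export
predict.rough_classifier <- function(object, newdata, ...) {
  stats::predict(object$fit, as.matrix(newdata), ...)
}

#' Sequence-position analysis of fast-AM syllables
#'
#' The normalized position of syllable i in a length-N sequence is
#' `(i - 1) / (N - 1)` (0.5 for N = 1). The observed distribution of
#' fast-AM positions is compared with an expected distribution pooled
#' from `n_perm` within-sequence label shuffles (which exactly preserve
#' per-sequence label counts) by a two-sample Kolmogorov-Smirnov test.
#' Additionally, each sequence's proportion of fast-AM syllables falling
#' in the first half ([0, 0.5)) is compared against the second half by a
#' paired signed-rank test across sequences.
#'
#' @param labels_by_sequence List of per-sequence label vectors.
#' @param positive The fast-AM label (default `"fAMV"`).
#' @param n_perm Label shuffles per sequence.
#' @param seed Integer seed for the shuffles.
#' @return A list: `observed` and `expected` position samples,
#'   `ks_stat`, `ks_p`, `first_half`/`second_half` per-sequence
#'   proportions, `halves_p`, and `defined` (FALSE when no fast-AM
#'   labels exist anywhere).
#' @export
position_analysis <- function(labels_by_sequence, positive = "fAMV",
                              n_perm = 100L, seed = 1L) {
  stopifnot(is.list(labels_by_sequence), length(labels_by_sequence) > 0)
  norm_pos <- function(n)
    if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0.5
  pos_of <- function(labels)
    norm_pos(length(labels))[labels == positive]
  observed <- unlist(lapply(labels_by_sequence, pos_of))
  if (!length(observed))
    return(list(observed = numeric(0), expected = numeric(0),
                ks_stat = NA_real_, ks_p = NA_real_,
                first_half = numeric(0), second_half = numeric(0),
                halves_p = NA_real_, defined = FALSE))
  expected <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(p)
      unlist(lapply(labels_by_sequence, function(l) pos_of(sample(l))))))
  })
  ks <- suppressWarnings(stats::ks.test(observed, expected))
  halves <- lapply(labels_by_sequence, function(l) {
    p <- pos_of(l)
    if (!length(p)) return(c(NA_real_, NA_real_))
    c(mean(p < 0.5), mean(p >= 0.5))
  })
  fh <- vapply(halves, `[`, numeric(1), 1L)
  sh <- vapply(halves, `[`, numeric(1), 2L)
  ok <- !is.na(fh)
  halves_p <- if (sum(ok) >= 2L && !all(fh[ok] == sh[ok]))
    paired_and_unpaired_tests(fh[ok], sh[ok], paired = TRUE)$p
  else NA_real_
  list(observed = observed, expected = expected,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       first_half = fh[ok], second_half = sh[ok], halves_p = halves_p,
       defined = TRUE)
}
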