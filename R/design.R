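#' Gamma haemodynamic response kernel
#'
#' Samples a gamma-density HRF parameterised by its mean (`lag`) and
#' standard deviation (`sigma`) in seconds — shape `(lag/sigma)^2`, scale
#' `sigma^2/lag` — on a regular grid of step `dt`, normalised to unit sum so
#' convolution preserves the integral of the stimulus boxcar. The default
#' lag 6 s / sigma 3 s kernel (shape 4, scale 1.5, mode at 4.5 s) is the
#' standard single-gamma model of the haemodynamic response.
#'
#' @param lag mean of the response, seconds.
#' @param sigma standard deviation, seconds.
#' @param dt sampling step, seconds.
#' @param span kernel support length, seconds (default 30, which covers the
#'   default kernel to well below 1e-6 of its mass).
#' @return Numeric vector of `span/dt + 1` non-negative weights summing to 1.
#' @export
gamma_hrf <- function(lag = 6, sigma = 3, dt = 0.1, span = 30) {
  if (lag <= 0 || sigma <= 0 || dt <= 0 || span <= 0) {
    abort("`lag`, `sigma`, `dt` and `span` must all be positive.")
  }
  shape <- (lag / sigma)^2
  scale <- sigma^2 / lag
  tt <- seq(0, span, by = dt)
  k <- dgamma(tt, shape = shape, scale = scale)
  k / sum(k)
}

#' Validate an event table
#'
#' Checks the contract for a run's trial events: columns `onset`,
#' `duration`, `word`, `condition`; strictly increasing onsets; no trial
#' extending past the end of the run; each word at most once per run.
#'
#' @param events data frame of events.
#' @param run_length run duration in seconds (optional).
#' @return The events as a tibble, invisibly validated.
#' @export
validate_events <- function(events, run_length = NULL) {
  events <- as_tibble(events)
  req <- c("onset", "duration", "word", "condition")
  missing <- setdiff(req, names(events))
  if (length(missing)) {
    abort(sprintf("Event table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(events) && any(diff(events$onset) <= 0)) {
    abort("Event onsets must be strictly increasing.")
  }
  if (any(events$duration <= 0)) abort("Event durations must be positive.")
  if (anyDuplicated(events$word)) abort("Each word may appear only once per run.")
  if (!is.null(run_length) && nrow(events) &&
      any(events$onset + events$duration > run_length + 1e-9)) {
    abort("Trial extends past the end of the run.")
  }
  events
}

#' Build an LSA design matrix
#'
#' Constructs the least-squares-all single-trial design for one run: each
#' trial gets its own regressor — a boxcar covering the word presentation
#' period (onset, duration) on a fine time grid, convolved with the HRF
#' kernel and sampled at the volume acquisition times `t = i * tr`. An
#' intercept column is always appended, followed by any nuisance columns;
#' both are tracked so their coefficients can be discarded after fitting.
#'
#' @param events event table for the run (see [validate_events()]).
#' @param n_vols number of volumes in the run.
#' @param tr repetition time, seconds.
#' @param hrf HRF kernel sampled at step `dt` (see [gamma_hrf()]).
#' @param dt fine-grid step used for the boxcar convolution, seconds; must
#'   match the step the kernel was sampled at.
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (`n_vols` rows), appended unmodified.
#' @return A `design_matrix` object: list with elements `X` (n_vols x
#'   (trials + 1 + nuisance)), `trial_idx`, `labels` (trial words),
#'   `conditions`, `tr`.
#' @export
build_design_matrix <- function(events, n_vols, tr, hrf = gamma_hrf(dt = dt),
                                dt = 0.1, nuisance = NULL) {
  events <- validate_events(events, run_length = n_vols * tr)
  n_trials <- nrow(events)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vols) abort("`nuisance` must have `n_vols` rows.")
  }
  grid_len <- ceiling(((n_vols - 1L) * tr) / dt) + length(hrf) + 1L
  vol_idx <- round((seq_len(n_vols) - 1L) * tr / dt) + 1L
  p <- length(hrf)
  trial_cols <- matrix(0, n_vols, n_trials)
  for (k in seq_len(n_trials)) {
    box <- numeric(grid_len)
    i0 <- floor(events$onset[k] / dt) + 1L
    i1 <- min(grid_len, ceiling((events$onset[k] + events$duration[k]) / dt))
    box[i0:i1] <- 1
    # causal convolution; front padding keeps the filter's startup NAs out of
    # the sampled range
    yy <- stats::filter(c(numeric(p), box), hrf, method = "convolution", sides = 1)
    trial_cols[, k] <- as.numeric(yy[vol_idx + p])
  }
  if (n_trials && any(colSums(abs(trial_cols)) == 0)) {
    abort("A trial regressor is all zero; check event timing.")
  }
  X <- cbind(trial_cols, intercept = 1)
  labels <- c(events$word, "(intercept)")
  if (!is.null(nuisance)) {
    X <- cbind(X, nuisance)
    labels <- c(labels, sprintf("nuisance%d", seq_len(ncol(nuisance))))
  }
  colnames(X) <- labels
  structure(
    list(X = X, trial_idx = seq_len(n_trials), labels = events$word,
         conditions = events$condition, tr = tr, n_vols = n_vols),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (%d trials + %d other)\n",
              nrow(x$X), ncol(x$X), length(x$trial_idx),
              ncol(x$X) - length(x$trial_idx)))
  invisible(x)
}
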