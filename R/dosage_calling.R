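#' Dosage-caller parameters
#'
#' @param method `"bins"` (deterministic fixed theta bins, the default)
#'   or `"mixture"` (per-marker five-component Gaussian mixture on theta
#'   with means initialized at the dosage expectations 0, 0.25, 0.5,
#'   0.75, 1).
#' @param bin_edges Theta cut points separating scores 0..4; defaults to
#'   the midpoints between the five cluster expectations.
#' @param low_intensity_threshold Cells with total intensity below this
#'   are flagged as deletion-consistent (a hemizygous two-copy region has
#'   expected intensity 0.5 against the euploid 1.0).
#' @param min_confidence Calls with posterior confidence below this
#'   become missing (only binding for the mixture method).
#' @param max_iter,tol Mixture EM controls.
#' @return Named list of parameters.
#' @export
dosage_params <- function(method = c("bins", "mixture"),
                          bin_edges = c(0.125, 0.375, 0.625, 0.875),
                          low_intensity_threshold = 0.7,
                          min_confidence = 0.95,
                          max_iter = 100, tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(length(bin_edges) == 4, !is.unsorted(bin_edges),
            min_confidence >= 0, min_confidence <= 1)
  list(method = method, bin_edges = bin_edges,
       low_intensity_threshold = low_intensity_threshold,
       min_confidence = min_confidence, max_iter = max_iter, tol = tol)
}

# one-marker EM: 5 Gaussian components on theta, means initialized at the
# dosage expectations, common variance; returns score + posterior per cell
.fit_marker_mixture <- function(theta, params) {
  ok <- !is.na(theta)
  x <- theta[ok]
  mu <- c(0, 0.25, 0.5, 0.75, 1)
  sigma <- 0.05
  pi_k <- rep(0.2, 5)
  loglik <- -Inf
  for (it in seq_len(params$max_iter)) {
    dens <- vapply(1:5, function(k)
      pi_k[k] * stats::dnorm(x, mu[k], sigma), numeric(length(x)))
    dens <- matrix(dens, nrow = length(x), ncol = 5)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    post <- dens / rowsum_
    new_loglik <- sum(log(rowsum_))
    nk <- colSums(post)
    pi_k <- nk / length(x)
    upd <- nk > 1e-8
    mu[upd] <- (colSums(post * x) / nk)[upd]
    sigma <- sqrt(sum(post * (outer(x, mu, "-")^2)) / length(x))
    sigma <- max(sigma, 1e-3)
    if (is.finite(loglik) && abs(new_loglik - loglik) < params$tol) break
    loglik <- new_loglik
  }
  # assign by maximum posterior; ties break toward the euploid score 2
  pref <- order(abs(0:4 - 2))  # 2, 1, 3, 0, 4
  score <- apply(post, 1, function(p) {
    top <- which(p >= max(p) - 1e-12) - 1L
    top[order(match(top, pref - 1L))][1L]
  })
  conf <- apply(post, 1, max)
  out_score <- rep(NA_integer_, length(theta))
  out_conf <- rep(NA_real_, length(theta))
  out_score[ok] <- as.integer(score)
  out_conf[ok] <- conf
  list(score = out_score, confidence = out_conf)
}

#' Call tetraploid allele-dosage scores (0-4) from array signals
#'
#' Converts the A-signal fraction theta of each (marker, sample) cell to
#' an integer count of A-subgenome alleles on the tetraploid 0-4 scale.
#' The default fixed-bin caller assigns the score whose theta expectation
#' (0, 0.25, 0.5, 0.75, 1) is nearest; the optional mixture caller fits a
#' five-component Gaussian mixture per marker and uses the maximum
#' posterior, with sub-threshold-confidence calls set to missing. Cells
#' whose total intensity falls below the low-intensity threshold are
#' flagged as deletion-consistent; deletions themselves are *not* called
#' here — arrays genotype deletion regions unreliably, so resolution is
#' deferred to the sequencing module (see [reconcile()]).
#'
#' @param signals A [simulate_array()]-shaped `SignalMatrix` (or any list
#'   with `theta`, `intensity`, `markers`, `samples`).
#' @param params A [dosage_params()] list.
#' @return An object of class `"DosageMatrix"`: list with integer matrix
#'   `score` (NA = missing), logical `low_intensity`, numeric
#'   `confidence`, plus the `markers` and `samples` tables.
#' @export
call_dosage <- function(signals, params = dosage_params()) {
  theta <- signals$theta
  inten <- signals$intensity
  if (is.null(dim(theta)) || ncol(theta) < 1L) stop("at least one sample required")
  if (any(!is.na(theta) & !is.finite(theta)) ||
      any(!is.na(inten) & !is.finite(inten)))
    stop("non-finite signal values")
  if (any(theta < 0 | theta > 1, na.rm = TRUE))
    stop("theta must lie in [0, 1]")

  if (params$method == "bins") {
    score <- matrix(findInterval(theta, params$bin_edges), nrow(theta),
                    ncol(theta), dimnames = dimnames(theta))
    conf <- matrix(ifelse(is.na(theta), NA_real_, 1.0), nrow(theta),
                   ncol(theta), dimnames = dimnames(theta))
    score[is.na(theta)] <- NA_integer_
  } else {
    score <- matrix(NA_integer_, nrow(theta), ncol(theta),
                    dimnames = dimnames(theta))
    conf <- matrix(NA_real_, nrow(theta), ncol(theta),
                   dimnames = dimnames(theta))
    for (i in seq_len(nrow(theta))) {
      if (all(is.na(theta[i, ]))) next
      fit <- .fit_marker_mixture(theta[i, ], params)
      score[i, ] <- fit$score
      conf[i, ] <- fit$confidence
    }
    low_conf <- !is.na(conf) & conf < params$min_confidence
    score[low_conf] <- NA_integer_
  }
  low <- !is.na(inten) & inten < params$low_intensity_threshold
  structure(list(score = score, low_intensity = low, confidence = conf,
                 markers = signals$markers, samples = signals$samples),
            class = "DosageMatrix")
}

#' @export
print.DosageMatrix <- function(x, ...) {
  cat("DosageMatrix:", nrow(x$score), "markers x", ncol(x$score), "samples;",
      sum(is.na(x$score)), "missing cells\n")
  invisible(x)
}

#' Confusion table of called vs true dosage scores
#'
#' Available on synthetic runs where per-cell truth is known; rows are
#' true scores, columns called scores (plus a `missing` column).
#'
#' @param calls A [call_dosage()] result.
#' @param truth Integer matrix of true scores, same shape as
#'   `calls$score`.
#' @return List with `table` (confusion matrix) and `accuracy` (fraction
#'   of non-missing calls equal to truth).
#' @export
score_accuracy <- function(calls, truth) {
  sc <- calls$score
  if (length(sc) == 0) stop("empty dosage matrix")
  if (!all(dim(sc) == dim(truth))) stop("calls and truth shapes differ")
  called <- factor(ifelse(is.na(sc), "missing", as.character(sc)),
                   levels = c(as.character(0:4), "missing"))
  tr <- factor(as.character(truth), levels = as.character(0:4))
  tab <- table(truth = tr, called = called)
  ok <- !is.na(sc)
  acc <- if (any(ok)) mean(sc[ok] == truth[ok]) else NA_real_
  list(table = tab, accuracy = acc)
}
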