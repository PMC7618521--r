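#' Dose-response matrix container
#'
#' @param doses_a,doses_b dose grids including 0 (vehicle).
#' @param inhibition percent-inhibition matrix (rows = `doses_a`, cols =
#'   `doses_b`), values in `[0, 100]` after clipping; or a 3-d array with
#'   replicates in the third dimension (averaged on construction, replicate
#'   slab kept in `replicates`).
#' @param mode scheduling label (metadata only).
#' @param readout_day metadata: day of readout.
#' @return a `dose_matrix` object.
#' @export
dose_matrix <- function(doses_a, doses_b, inhibition,
                        mode = "concomitant", readout_day = 5) {
  if (!any(doses_a == 0) || !any(doses_b == 0))
    stop("dose grids must include 0 (vehicle)", call. = FALSE)
  reps <- NULL
  if (length(dim(inhibition)) == 3) {
    reps <- inhibition
    inhibition <- apply(inhibition, c(1, 2), mean)
  }
  .assert(nrow(inhibition) == length(doses_a) &&
            ncol(inhibition) == length(doses_b),
          "inhibition must be doses_a x doses_b")
  structure(list(doses_a = as.numeric(doses_a),
                 doses_b = as.numeric(doses_b),
                 inhibition = inhibition, replicates = reps,
                 mode = mode, readout_day = readout_day),
            class = "dose_matrix")
}

#' Four-parameter Hill response
#'
#' `bottom + (top - bottom) * d^slope / (d^slope + ec50^slope)`; the
#' response at dose 0 is `bottom`.
#'
#' @param doses nonnegative doses.
#' @param params list with `bottom`, `top`, `ec50`, `slope`.
#' @return responses on the same scale as `bottom`/`top`.
#' @export
hill_response <- function(doses, params) {
  d <- doses^params$slope
  params$bottom + (params$top - params$bottom) *
    d / (d + params$ec50^params$slope)
}

#' Fit a four-parameter logistic (Hill) dose-response curve
#'
#' Bounded least squares (`bottom` in \[-5, 20\], `top` in \[50, 110\],
#' `slope` in \[0.2, 10\], `ec50 > 0`), EC50 initialized at the geometric
#' mean of the nonzero doses. Degenerate (flat) data yield a flagged flat
#' fit; non-convergence falls back to monotone isotonic interpolation,
#' flagged.
#'
#' @param doses doses including 0; at least 4 levels.
#' @param inhibition percent inhibition in `[0, 100]`, same length.
#' @return a `hill_fit` list: `bottom`, `top`, `ec50`, `slope`, `method`
#'   (`"4pl"`, `"flat"` or `"isotonic"`), `flagged`, plus fit internals.
#' @export
fit_hill <- function(doses, inhibition) {
  .assert(length(doses) == length(inhibition), "length mismatch")
  .assert(length(unique(doses)) >= 4, "need >= 4 dose levels")
  .assert(all(inhibition >= -1e-9 & inhibition <= 100 + 1e-9),
          "inhibition must be within [0, 100]")
  if (diff(range(inhibition)) < 1e-6) {
    fit <- list(bottom = mean(inhibition), top = mean(inhibition),
                ec50 = NA_real_, slope = NA_real_,
                method = "flat", flagged = TRUE)
    class(fit) <- "hill_fit"
    return(fit)
  }
  dpos <- doses[doses > 0]
  start <- list(bottom = max(-5, min(20, min(inhibition))),
                top = max(50, min(110, max(inhibition))),
                ec50 = .geomean(dpos), slope = 1)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) * ifelse(d > 0, d^slope /
                                             (d^slope + ec50^slope), 0),
      data = data.frame(d = doses, y = inhibition),
      start = start,
      lower = c(bottom = -5, top = 50, ec50 = min(dpos) * 1e-4,
                slope = 0.2),
      upper = c(bottom = 20, top = 110, ec50 = max(dpos) * 1e4,
                slope = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- as.list(stats::coef(m))
    c(p, list(method = "4pl", flagged = FALSE))
  }, error = function(e) {
    ord <- order(doses)
    iso <- stats::isoreg(seq_along(doses[ord]), inhibition[ord])
    list(bottom = min(iso$yf), top = max(iso$yf), ec50 = NA_real_,
         slope = NA_real_, method = "isotonic", flagged = TRUE,
         iso_doses = doses[ord], iso_fit = iso$yf)
  })
  class(fit) <- "hill_fit"
  fit
}

#' Predict from a Hill fit
#'
#' @param object a `hill_fit`.
#' @param doses doses to predict at.
#' @param ... unused.
#' @return predicted percent inhibition.
#' @export
predict.hill_fit <- function(object, doses, ...) {
  if (object$method == "flat")
    return(rep(object$bottom, length(doses)))
  if (object$method == "isotonic")
    return(stats::approx(object$iso_doses, object$iso_fit, xout = doses,
                         rule = 2)$y)
  hill_response(doses, object)
}

# Constrained 2-parameter logistic used for potency-shifted refits along a
# row/column: y = y0 + (1 - y0) * d^s / (d^s + m^s) on the [0,1] scale,
# i.e. bottom fixed at the partner drug's monotherapy response, top at 1.
.fit_shifted <- function(doses, y, y0, init_ec50, init_slope) {
  dpos <- doses[doses > 0]
  st <- list(m = if (is.finite(init_ec50) && init_ec50 > 0) init_ec50
             else .geomean(dpos),
             s = if (is.finite(init_slope)) max(0.2, min(10, init_slope))
             else 1)
  tryCatch({
    fitm <- minpack.lm::nlsLM(
      y ~ y0 + (1 - y0) * ifelse(d > 0, d^s / (d^s + m^s), 0),
      data = data.frame(d = doses, y = y),
      start = st,
      lower = c(m = min(dpos) * 1e-4, s = 0.2),
      upper = c(m = max(dpos) * 1e4, s = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fitm)
    list(fun = function(d) y0 + (1 - y0) *
           ifelse(d > 0, d^cf[["s"]] / (d^cf[["s"]] + cf[["m"]]^cf[["s"]]), 0),
         ok = TRUE)
  }, error = function(e) {
    list(fun = stats::approxfun(doses, y, rule = 2), ok = FALSE)
  })
}

#' ZIP (zero interaction potency) synergy scoring
#'
#' On the `[0, 1]` inhibition scale the zero-interaction expectation at a
#' combination well is `yA + yB - yA*yB` from the monotherapy Hill fits.
#' The observed potency-shifted response at each combination well is the
#' average of two constrained logistic refits: along the well's row (drug B
#' fixed; curve bottom pinned to drug B's fitted monotherapy response) and
#' along its column. The delta surface is (observed - expected) x 100 over
#' combination wells; `mean_delta` is its mean (the summary ZIP score) and
#' `max_window_delta` the largest mean over 3x3 sub-windows of the
#' combination grid (the whole grid when smaller).
#'
#' @param dm a [dose_matrix()].
#' @return a `synergy_result` list: `delta_surface`, `mean_delta`,
#'   `max_window_delta`, `call`, `hill_fit_A`, `hill_fit_B`, `mode`,
#'   `flagged`.
#' @export
zip_delta <- function(dm) {
  .assert(inherits(dm, "dose_matrix"), "dm must be a dose_matrix")
  da <- dm$doses_a; db <- dm$doses_b
  ia0 <- which(da == 0)[1]; ib0 <- which(db == 0)[1]
  y <- dm$inhibition / 100

  fitA <- fit_hill(da, dm$inhibition[, ib0])
  fitB <- fit_hill(db, dm$inhibition[ia0, ])
  yA <- predict(fitA, da) / 100
  yB <- predict(fitB, db) / 100

  ai <- which(da > 0); bi <- which(db > 0)
  flagged <- fitA$flagged || fitB$flagged
  if (length(ai) == 0 || length(bi) == 0)
    stop("no combination wells", call. = FALSE)

  expected <- outer(yA[ai], yB[bi], function(a, b) a + b - a * b)

  # column refits: response vs dose of A at fixed B
  from_col <- matrix(NA_real_, length(ai), length(bi))
  for (j in seq_along(bi)) {
    f <- .fit_shifted(da, y[, bi[j]], y0 = yB[bi[j]],
                      init_ec50 = fitA$ec50, init_slope = fitA$slope)
    if (!f$ok) flagged <- TRUE
    from_col[, j] <- f$fun(da[ai])
  }
  # row refits: response vs dose of B at fixed A
  from_row <- matrix(NA_real_, length(ai), length(bi))
  for (i in seq_along(ai)) {
    f <- .fit_shifted(db, y[ai[i], ], y0 = yA[ai[i]],
                      init_ec50 = fitB$ec50, init_slope = fitB$slope)
    if (!f$ok) flagged <- TRUE
    from_row[i, ] <- f$fun(db[bi])
  }
  observed <- (from_col + from_row) / 2
  delta <- (observed - expected) * 100
  dimnames(delta) <- list(dose_a = as.character(da[ai]),
                          dose_b = as.character(db[bi]))
  mean_delta <- mean(delta)
  if (nrow(delta) < 2 || ncol(delta) < 2) {
    max_window <- mean_delta
    flagged <- TRUE
  } else {
    wr <- min(3, nrow(delta)); wc <- min(3, ncol(delta))
    wins <- c()
    for (i in seq_len(nrow(delta) - wr + 1))
      for (j in seq_len(ncol(delta) - wc + 1))
        wins <- c(wins, mean(delta[i:(i + wr - 1), j:(j + wc - 1)]))
    max_window <- max(wins)
  }
  structure(list(delta_surface = delta, mean_delta = mean_delta,
                 max_window_delta = max_window,
                 call = classify_synergy(mean_delta),
                 hill_fit_A = fitA, hill_fit_B = fitB,
                 mode = dm$mode, flagged = flagged),
            class = "synergy_result")
}

#' Categorical synergy call from a ZIP score
#'
#' Scores above +10 are called synergistic and below -10 antagonistic;
#' everything in between is additive.
#'
#' @param score summary ZIP score (percentage points).
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
classify_synergy <- function(score) {
  .assert(is.finite(score), "score must be finite")
  if (score > 10) "synergistic"
  else if (score < -10) "antagonistic"
  else "additive"
}

#' Compare synergy across scheduling modes
#'
#' @param results list of `synergy_result` objects (one per scheduling
#'   mode); duplicate mode labels are an error.
#' @return data frame `mode, mean_delta, max_window_delta, call`, ordered by
#'   `mean_delta` descending; ties keep the canonical mode order
#'   (BETi_first, concomitant, p300i_first).
#' @export
compare_modes <- function(results) {
  .assert(length(results) >= 1, "no results")
  modes <- vapply(results, function(r) r$mode, character(1))
  if (anyDuplicated(modes)) stop("duplicate mode labels", call. = FALSE)
  canon <- c("BETi_first", "concomitant", "p300i_first")
  rank_mode <- match(modes, canon)
  rank_mode[is.na(rank_mode)] <- length(canon) + seq_len(sum(is.na(rank_mode)))
  out <- data.frame(mode = modes,
                    mean_delta = vapply(results, function(r) r$mean_delta,
                                        numeric(1)),
                    max_window_delta = vapply(results,
                                              function(r) r$max_window_delta,
                                              numeric(1)),
                    call = vapply(results, function(r) r$call, character(1)),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_delta, rank_mode), , drop = FALSE]
}
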