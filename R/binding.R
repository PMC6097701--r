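#' BindingFit: single-site saturation binding fit
#'
#' Result of [fitSaturation()]: nonlinear least-squares estimates of the
#' single-site model \deqn{B(c) = b_0 + B_{max} \, c^h / (K_d^h + c^h)}
#' with Hill exponent h fixed at 1 by default. `Kd` is the half-maximal
#' concentration: at c = Kd the predicted signal is exactly
#' b0 + Bmax/2 (for h = 1).
#'
#' @slot estimates named numeric (`Bmax`, `Kd`, `b0`).
#' @slot se named numeric standard errors (NA when unavailable).
#' @slot hill numeric Hill exponent used.
#' @slot converged logical optimizer convergence flag.
#' @slot saturable logical: whether the data support saturable binding at
#'   all (FALSE for flat/background-only ligands).
#' @slot data data.frame of (concentration, signal) used.
#' @slot residuals numeric fit residuals.
#' @slot message diagnostic string.
#' @export
setClass("BindingFit",
  representation(estimates = "numeric", se = "numeric", hill = "numeric",
                 converged = "logical", saturable = "logical",
                 data = "data.frame", residuals = "numeric",
                 message = "character"))

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit (single-site, Hill =", object@hill, ")\n")
  est <- object@estimates; se <- object@se
  for (p in names(est))
    cat(sprintf("  %-4s = %.4g (SE %.3g)\n", p, est[[p]], se[[p]]))
  cat("  converged:", object@converged,
      " saturable:", object@saturable, "\n")
  if (nzchar(object@message)) cat(" ", object@message, "\n")
  invisible(object)
})

#' @describeIn fitSaturation extract the half-maximal concentration (Kd, nM)
#' @export
kd <- function(fit) { stopifnot(is(fit, "BindingFit")); fit@estimates[["Kd"]] }

#' @describeIn fitSaturation extract Bmax
#' @export
bmax <- function(fit) { stopifnot(is(fit, "BindingFit")); fit@estimates[["Bmax"]] }

#' @describeIn fitSaturation predicted signal at new concentrations
#' @param concentration numeric concentrations (same units as the data).
#' @export
predictBinding <- function(fit, concentration) {
  stopifnot(is(fit, "BindingFit"))
  e <- fit@estimates; h <- fit@hill
  e[["b0"]] + e[["Bmax"]] * concentration^h / (e[["Kd"]]^h + concentration^h)
}

#' Fit a saturation binding curve to a ligand titration
#'
#' Fits the single-site Langmuir isotherm with additive constant
#' background, \eqn{B(c) = b0 + Bmax\, c/(Kd + c)}, by bounded nonlinear
#' least squares (Levenberg-Marquardt, all parameters constrained >= 0).
#' The design emulated here is a six-point titration
#' (0, 100, 200, 300, 400, 800 nM) of a motif-carrying reporter against
#' receptor-bearing permeabilized microsomes; `Kd` is reported as the
#' half-maximal binding concentration. Initialization: b0 = minimum
#' signal, Bmax = max - min, Kd = concentration nearest the half-range
#' signal. A Hill exponent can be supplied but is fixed, not fitted, to
#' avoid overparameterization on six-concentration designs.
#'
#' Non-convergence or a background-only ligand does not raise an error:
#' the fit is returned flagged with `converged`/`saturable` FALSE and a
#' diagnostic message. A fit is called non-saturable when the optimizer
#' fails, when Bmax is not distinguishable from 0 (Bmax < 2 SE), or when
#' the Kd standard error spans more than an order of magnitude times the
#' estimate.
#'
#' @param data data.frame with columns `concentration` (>= 0; at least 4
#'   distinct values) and `signal`.
#' @param hill fixed Hill exponent (default 1).
#' @param fit a [BindingFit-class] (for the accessors).
#' @return A [BindingFit-class].
#' @examples
#' d <- genBindingData(bmax = 100, kdTrue = 200, b0 = 0, noiseSd = 0, seed = 1)
#' kd(fitSaturation(d))
#' @export
fitSaturation <- function(data, hill = 1) {
  if (!all(c("concentration", "signal") %in% names(data)))
    stop("data must have columns concentration and signal")
  conc <- data$concentration; sig <- data$signal
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations")
  b0_0 <- min(sig)
  bmax_0 <- max(max(sig) - min(sig), 1e-8)
  half <- b0_0 + bmax_0 / 2
  kd_0 <- conc[which.min(abs(sig - half))]
  if (kd_0 <= 0) kd_0 <- stats::median(conc[conc > 0])
  est <- c(Bmax = NA_real_, Kd = NA_real_, b0 = NA_real_)
  se <- est
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ b0 + Bmax * concentration^hill /
        (Kd^hill + concentration^hill),
      data = data.frame(concentration = conc, signal = sig),
      start = list(Bmax = bmax_0, Kd = kd_0, b0 = b0_0),
      lower = c(Bmax = 0, Kd = 1e-9, b0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("BindingFit", estimates = est, se = se, hill = hill,
               converged = FALSE, saturable = FALSE,
               data = data.frame(concentration = conc, signal = sig),
               residuals = rep(NA_real_, length(sig)),
               message = paste("no saturable binding:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  est[] <- cf[c("Bmax", "Kd", "b0")]
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (!is.null(sm)) se[] <- sm[c("Bmax", "Kd", "b0"), "Std. Error"]
  converged <- isTRUE(fit$convInfo$isConv)
  msg <- ""
  saturable <- converged
  if (is.finite(se[["Bmax"]]) && est[["Bmax"]] < 2 * se[["Bmax"]]) {
    saturable <- FALSE
    msg <- "no saturable binding: Bmax indistinguishable from background"
  }
  if (is.finite(se[["Kd"]]) && se[["Kd"]] > 10 * est[["Kd"]]) {
    saturable <- FALSE
    msg <- "no saturable binding: Kd unidentifiable (SE spans orders of magnitude)"
  }
  new("BindingFit", estimates = est, se = se, hill = hill,
      converged = converged, saturable = saturable,
      data = data.frame(concentration = conc, signal = sig),
      residuals = as.numeric(stats::residuals(fit)), message = msg)
}

#' Estimate the plateau onset of a dose-response curve
#'
#' For detergent-permeabilization dose responses: fits a monotone
#' non-decreasing (isotonic) curve to response vs dose and reports the
#' smallest dose whose fitted response reaches within a stated fraction of
#' the fitted upper asymptote. Flat data plateau at the minimum dose; data
#' still rising at the maximum dose are right-censored and flagged.
#' Departures from monotonicity beyond `tolerance` (relative to the fitted
#' range) raise a warning.
#'
#' @param dose numeric doses (>= 4 values).
#' @param response numeric responses, same length.
#' @param fraction plateau criterion: fitted response >=
#'   (1 - fraction) * upper asymptote (default 0.05).
#' @param tolerance relative non-monotonicity warning threshold
#'   (default 0.1).
#' @return list with `plateau_dose`, `censored` (logical), `fitted`
#'   (data.frame dose/fitted).
#' @examples
#' d <- c(0, 10, 20, 30, 40)
#' r <- c(5, 40, 80, 100, 101)
#' doseResponsePlateau(d, r)$plateau_dose
#' @export
doseResponsePlateau <- function(dose, response, fraction = 0.05,
                                tolerance = 0.1) {
  if (length(dose) < 4L) stop("need at least 4 doses")
  if (length(dose) != length(response)) stop("dose/response length mismatch")
  o <- order(dose)
  dose <- dose[o]; response <- response[o]
  ud <- unique(dose)
  ybar <- vapply(ud, function(d) mean(response[dose == d]), numeric(1L))
  wts <- vapply(ud, function(d) sum(dose == d), numeric(1L))
  fit <- .pavNonDecreasing(ybar, wts)
  rng <- diff(range(fit))
  dev <- max(abs(ybar - fit))
  if (rng > 0 && dev > tolerance * rng)
    warning("dose response departs from monotonicity beyond tolerance")
  if (rng == 0) {
    return(list(plateau_dose = ud[1L], censored = FALSE,
                fitted = data.frame(dose = ud, fitted = fit)))
  }
  top <- max(fit)
  reached <- fit >= (1 - fraction) * top
  idx <- which(reached)[1L]
  censored <- idx == length(ud)
  list(plateau_dose = ud[idx], censored = censored,
       fitted = data.frame(dose = ud, fitted = fit))
}

#' Compare single-concentration binding across motifs
#'
#' Summarizes per-motif replicate binding signals (mean, SEM, n), ranks
#' motifs by mean signal, and runs two-sided Welch t-tests of every motif
#' against named reference motifs (by default the strong consensus "APV"
#' and the diacidic nonbinder "EET"), with Holm correction across all
#' pairwise tests. With a single replicate for a motif no test is run.
#'
#' @param data data.frame with columns `motif` and `signal` (one row per
#'   replicate; >= 2 motifs).
#' @param references character vector of reference motifs to test against
#'   (must be present in `data`; missing ones are dropped with a warning).
#' @param alpha significance level applied to Holm-adjusted p-values.
#' @return list with `summary` (ranked data.frame: motif, mean, sem, n,
#'   rank) and `tests` (data.frame: motif, reference, p, p_adj,
#'   significant).
#' @export
compareMotifBinding <- function(data, references = c("APV", "EET"),
                                alpha = 0.05) {
  if (!all(c("motif", "signal") %in% names(data)))
    stop("data must have columns motif and signal")
  motifs <- unique(data$motif)
  if (length(motifs) < 2L) stop("need at least 2 motifs")
  sp <- split(data$signal, data$motif)
  summ <- data.frame(
    motif = names(sp),
    mean = vapply(sp, mean, numeric(1L)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1L)),
    n = lengths(sp), row.names = NULL, stringsAsFactors = FALSE)
  summ <- summ[order(-summ$mean), , drop = FALSE]
  summ$rank <- seq_len(nrow(summ))
  missing_ref <- setdiff(references, names(sp))
  if (length(missing_ref)) {
    warning("reference motif(s) absent: ", paste(missing_ref, collapse = ", "))
    references <- setdiff(references, missing_ref)
  }
  tests <- NULL
  for (ref in references) {
    others <- setdiff(names(sp), ref)
    for (m in others) {
      if (length(sp[[m]]) < 2L || length(sp[[ref]]) < 2L) next
      p <- stats::t.test(sp[[m]], sp[[ref]])$p.value
      tests <- rbind(tests, data.frame(motif = m, reference = ref, p = p,
                                       stringsAsFactors = FALSE))
    }
  }
  if (!is.null(tests)) {
    tests$p_adj <- stats::p.adjust(tests$p, method = "holm")
    tests$significant <- tests$p_adj <= alpha
  }
  list(summary = summ, tests = tests)
}
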