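#' Two-component autophosphorylation model
#'
#' Fraction of maximal T286 phosphorylation at time `t` for enzyme
#' concentration `c_nM`:
#'
#' \deqn{f(t) = 1 - A_1 e^{-r_1 t} - (1 - A_1) e^{-c\,k_2 t}}
#'
#' The first component is concentration-independent (intra-holoenzyme
#' autophosphorylation at rate `r1`); the second scales with enzyme
#' concentration (`c * k2`), the signature of phosphorylation between
#' holoenzymes.  The amplitudes are constrained to sum to one, so the model
#' starts at 0 and saturates at 1.
#'
#' @param t time, minutes (vectorized, `>= 0`).
#' @param A1 amplitude of the concentration-independent component, in `[0, 1]`.
#' @param r1 concentration-independent rate, 1/min (`>= 0`).
#' @param k2 concentration-scaled rate, 1/(nM * min) (`>= 0`).
#' @param c_nM enzyme concentration, nM (`>= 0`).
#' @return numeric vector of phosphorylation fractions in `[0, 1)`.
#' @examples
#' eval_model(0, 0.5, 0.2, 0.005, 10)          # 0
#' eval_model(1, 1, log(2), 0, 0)              # 0.5
#' @export
eval_model <- function(t, A1, r1, k2, c_nM) {
  if (any(t < 0)) abort_validation("t must be >= 0")
  if (length(A1) != 1L || is.na(A1) || A1 < 0 || A1 > 1) {
    abort_validation("A1 must be a single value in [0, 1]")
  }
  if (any(r1 < 0) || any(k2 < 0) || any(c_nM < 0)) {
    abort_validation("r1, k2 and c_nM must be >= 0")
  }
  1 - A1 * exp(-r1 * t) - (1 - A1) * exp(-c_nM * k2 * t)
}

#' Build a time-course table
#'
#' Standard container for phospho time courses: one row per
#' (concentration, time, replicate) with the raw phospho and total signals and
#' a `normalized` fraction column.
#'
#' @param conc_nM,time_min,replicate,phospho,total vectors of equal length.
#' @param normalized optional precomputed normalized fraction; defaults to
#'   `phospho / total` (NA where `total` is 0).
#' @return a `data.frame` of class `timecourse_table`.
#' @export
timecourse_table <- function(conc_nM, time_min, replicate, phospho, total,
                             normalized = NULL) {
  if (any(time_min < 0)) abort_validation("time_min must be >= 0")
  if (any(phospho < 0) || any(total < 0)) abort_validation("signals must be >= 0")
  df <- data.frame(conc_nM = conc_nM, time_min = time_min,
                   replicate = replicate, phospho = phospho, total = total)
  df$normalized <- if (is.null(normalized)) {
    ifelse(df$total > 0, df$phospho / df$total, NA_real_)
  } else {
    normalized
  }
  class(df) <- c("timecourse_table", "data.frame")
  df
}

#' One- or two-exponential estimate of a curve's maximum
#'
#' Fits `y = ymax * (1 - exp(-r * t))` and
#' `y = ymax * (1 - A1 exp(-r1 t) - (1 - A1) exp(-r2 t))` to the raw
#' phospho/total ratios of a single data set and returns the fitted maximum of
#' the model preferred by AICc.  Used to put curves measured in arbitrary
#' units on a common normalized scale before global fitting.
#'
#' @param table a [timecourse_table()] for a single concentration.
#' @return list with `ymax`, `model` ("one" or "two"), and the AICc values.
#' @export
estimate_curve_max <- function(table) {
  ok <- is.finite(table$normalized)
  t <- table$time_min[ok]
  y <- table$normalized[ok]
  if (length(unique(t)) < 3L) abort_validation("need >= 3 timepoints")

  aicc <- function(rss, n, k) n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)

  fit1 <- minpack.lm::nls.lm(
    par = c(log_ymax = log(max(y[t > 0], 0.5)), log_r = log(log(2) / stats::median(t[t > 0]))),
    fn = function(p) y - exp(p[1]) * (1 - exp(-exp(p[2]) * t))
  )
  rss1 <- sum(fit1$fvec^2)

  best2 <- NULL
  for (a1 in c(0.3, 0.7)) {
    f <- minpack.lm::nls.lm(
      par = c(log_ymax = log(max(y[t > 0], 0.5)), qlogis_a1 = stats::qlogis(a1),
              log_r1 = log(1), log_r2 = log(0.05)),
      fn = function(p) {
        A1 <- stats::plogis(p[2])
        y - exp(p[1]) * (1 - A1 * exp(-exp(p[3]) * t) - (1 - A1) * exp(-exp(p[4]) * t))
      }
    )
    if (is.null(best2) || sum(f$fvec^2) < sum(best2$fvec^2)) best2 <- f
  }
  rss2 <- sum(best2$fvec^2)

  n <- length(y)
  a1c <- aicc(rss1, n, 2L)
  a2c <- aicc(rss2, n, 4L)
  if (a2c < a1c) {
    list(ymax = exp(best2$par[[1]]), model = "two", aicc = c(one = a1c, two = a2c))
  } else {
    list(ymax = exp(fit1$par[[1]]), model = "one", aicc = c(one = a1c, two = a2c))
  }
}

#' Normalize a time-course table to a fitted maximum
#'
#' Recomputes the `normalized` column as `(phospho / total) / fit_max`, so
#' curves from different blots share the 0-1 scale of the model.  Rows with
#' zero total signal cannot be normalized; they are dropped and returned in
#' the `excluded` attribute with a reason.
#'
#' @param table a [timecourse_table()].
#' @param fit_max positive scalar, typically `estimate_curve_max(table)$ymax`.
#' @return the table with `normalized` rescaled; excluded rows in
#'   `attr(, "excluded")`.
#' @export
normalize_curve <- function(table, fit_max) {
  if (!is.numeric(fit_max) || length(fit_max) != 1L || fit_max <= 0) {
    abort_validation("fit_max must be a positive scalar")
  }
  bad <- table$total <= 0
  excluded <- table[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "zero total signal"
  out <- table[!bad, , drop = FALSE]
  out$normalized <- (out$phospho / out$total) / fit_max
  attr(out, "excluded") <- excluded
  out
}

# SD-based weights per (concentration, time): 1/SD across replicates, with a
# zero or undefined SD replaced by that curve's median replicate SD
sd_weights <- function(table) {
  key <- interaction(table$conc_nM, table$time_min, drop = TRUE)
  sds <- tapply(table$normalized, key, stats::sd)
  sds[is.na(sds)] <- 0
  ckey <- tapply(table$conc_nM, key, `[`, 1L)
  for (cc in unique(ckey)) {
    idx <- ckey == cc
    med <- stats::median(sds[idx][sds[idx] > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    sds[idx][sds[idx] <= 0] <- med
  }
  1 / sds[as.character(key)]
}

#' Global two-component fit across enzyme concentrations
#'
#' Fits shared parameters (`A1`, `r1`, `k2`) of [eval_model()] to normalized
#' time courses at several enzyme concentrations simultaneously, minimizing
#' the SD-weighted sum of squared residuals.  Each (concentration, time)
#' point is weighted by 1/SD across replicates (zero/undefined SDs replaced
#' by the curve's median SD).  For concentrations listed in `saturating`
#' (typically the highest, where the reaction saturates within the first
#' sample), the curve is modeled with `A1 = 0`, i.e. as a single exponential
#' with rate `c * k2`.
#'
#' The two-exponential surface is multimodal, so the optimizer is restarted
#' from 5 deterministic starts (`A1` in 0.1..0.9, log-spaced rates) and the
#' best weighted residual wins.
#'
#' @param tables a [timecourse_table()] (or list of them, concatenated)
#'   containing all concentrations.
#' @param saturating numeric vector of concentrations to fit with `A1 = 0`.
#' @return object of class `global_fit`: list with `A1`, `r1`, `k2`,
#'   `single_component` (named logical per concentration), `covariance`,
#'   `weighted_rss`, `half_times` (named, minutes), `n_obs`.
#' @export
fit_global <- function(tables, saturating = numeric()) {
  if (is.list(tables) && !is.data.frame(tables)) tables <- do.call(rbind, tables)
  tab <- tables[is.finite(tables$normalized), , drop = FALSE]
  concs <- sort(unique(tab$conc_nM))
  if (length(concs) < 2L) abort_validation("need >= 2 concentrations for a global fit")
  for (cc in concs) {
    if (length(unique(tab$time_min[tab$conc_nM == cc])) < 3L) {
      abort_validation(sprintf("concentration %g nM has < 3 timepoints", cc))
    }
  }
  if (nrow(tab) < 4L) abort_validation("fewer data points than parameters")

  w <- sd_weights(tab)
  sw <- sqrt(w)
  sat <- tab$conc_nM %in% saturating

  # parameters on unconstrained scales: qlogis(A1), log(r1), log(k2)
  resid_fn <- function(p) {
    A1 <- stats::plogis(p[1]); r1 <- exp(p[2]); k2 <- exp(p[3])
    mu <- ifelse(sat,
                 1 - exp(-tab$conc_nM * k2 * tab$time_min),
                 1 - A1 * exp(-r1 * tab$time_min) -
                   (1 - A1) * exp(-tab$conc_nM * k2 * tab$time_min))
    sw * (tab$normalized - mu)
  }

  t_scale <- stats::median(tab$time_min[tab$time_min > 0])
  starts <- list()
  rates1 <- exp(seq(log(0.1 / t_scale), log(10 / t_scale), length.out = 5))
  a1s <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (i in seq_len(5)) {
    starts[[i]] <- c(stats::qlogis(a1s[i]), log(rates1[i]),
                     log(rates1[6 - i] / max(stats::median(tab$conc_nM), 1)))
  }

  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(f) && (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
  }
  if (is.null(best)) {
    stop(errorCondition("global fit failed to converge from any start",
                        class = c("holophos_fit_error", "error")))
  }

  A1 <- stats::plogis(best$par[[1]]); r1 <- exp(best$par[[2]]); k2 <- exp(best$par[[3]])

  # delta-method covariance on the natural scale
  J <- tryCatch({
    vc_t <- solve(best$hessian) * sum(best$fvec^2) / max(best$df, 1L)
    g <- diag(c(A1 * (1 - A1), r1, k2))
    g %*% vc_t %*% t(g)
  }, error = function(e) matrix(NA_real_, 3, 3))
  dimnames(J) <- list(c("A1", "r1", "k2"), c("A1", "r1", "k2"))

  fit <- structure(
    list(A1 = A1, r1 = r1, k2 = k2,
         single_component = stats::setNames(concs %in% saturating, concs),
         covariance = J, weighted_rss = sum(best$fvec^2), n_obs = nrow(tab)),
    class = "global_fit"
  )
  fit$half_times <- stats::setNames(
    vapply(concs, function(cc) half_time(fit, cc), numeric(1)), concs
  )
  fit
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global two-component autophosphorylation fit\n")
  cat(sprintf("  A1 = %.4g   r1 = %.4g /min   k2 = %.4g /(nM min)\n", x$A1, x$r1, x$k2))
  cat(sprintf("  weighted RSS = %.4g on %d observations\n", x$weighted_rss, x$n_obs))
  cat("  half-times (min):\n")
  for (nm in names(x$half_times)) {
    cat(sprintf("    %s nM: %.3g%s\n", nm, x$half_times[[nm]],
                if (x$single_component[[nm]]) "  [single component]" else ""))
  }
  invisible(x)
}

#' Langmuir (saturation) fit of a single time course
#'
#' Least-squares fit of `y(t) = ymax * t / (t_half + t)` to a single
#' phospho time course, the simple saturation form used for
#' autoradiography-style densitometry.  `t_half` is the time at which the
#' signal reaches half of `ymax`.
#'
#' @param table a [timecourse_table()] (single concentration), or a
#'   data.frame with `time_min` and `normalized` columns.
#' @return object of class `langmuir_fit`: list with `ymax`, `t_half`,
#'   `rss`, and a `degenerate` flag set when `t_half` collapses below
#'   1e-6 min (signal effectively constant at `ymax`).
#' @export
fit_langmuir <- function(table) {
  ok <- is.finite(table$normalized)
  t <- table$time_min[ok]
  y <- table$normalized[ok]
  if (length(unique(t)) < 3L) abort_validation("need >= 3 timepoints")

  p0 <- c(ymax = max(y), log_th = log(max(stats::median(t[t > 0]), 1e-3)))
  f <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) y - p[1] * t / (exp(p[2]) + t),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (f$info %in% c(0L, 9L)) {
    stop(errorCondition(paste0("Langmuir fit did not converge: ", f$message),
                        class = c("holophos_fit_error", "error")))
  }
  t_half <- exp(f$par[[2]])
  structure(
    list(ymax = f$par[[1]], t_half = t_half, rss = sum(f$fvec^2),
         degenerate = t_half < 1e-6),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit: ymax = %.4g, t_half = %.4g min%s\n",
              x$ymax, x$t_half, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Half-time of maximal phosphorylation
#'
#' Smallest time at which the fitted model reaches half of its plateau.  For
#' the two-component model the plateau is 1, and the half-time is located by
#' doubling-bracket plus bisection to 1e-6 min (closed form `ln 2 / r1` when
#' `A1 = 1`).  For a Langmuir fit the half-time is the `t_half` parameter by
#' definition.
#'
#' @param params a `global_fit`, a `langmuir_fit`, or a list with `A1`, `r1`,
#'   `k2` fields.
#' @param c_nM enzyme concentration (needed for the two-component model).
#' @return half-time in minutes.
#' @export
half_time <- function(params, c_nM = NULL) UseMethod("half_time")

#' @export
half_time.langmuir_fit <- function(params, c_nM = NULL) params$t_half

#' @export
half_time.global_fit <- function(params, c_nM = NULL) {
  if (is.null(c_nM)) abort_validation("c_nM is required for the two-component model")
  A1 <- if (isTRUE(params$single_component[as.character(c_nM)])) 0 else params$A1
  half_time_two_component(A1, params$r1, params$k2, c_nM)
}

#' @export
half_time.list <- function(params, c_nM = NULL) {
  if (is.null(c_nM)) abort_validation("c_nM is required for the two-component model")
  half_time_two_component(params$A1, params$r1, params$k2, c_nM)
}

#' @rdname half_time
#' @param A1,r1,k2 two-component model parameters (see [eval_model()]).
#' @export
half_time_two_component <- function(A1, r1, k2, c_nM) {
  f <- function(t) eval_model(t, A1, r1, k2, c_nM) - 0.5
  if (A1 == 1) {
    if (r1 <= 0) {
      stop(errorCondition("model never reaches 0.5 (degenerate parameters)",
                          class = c("holophos_domain_error", "error")))
    }
    return(log(2) / r1)
  }
  hi <- 1
  it <- 0L
  while (f(hi) < 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L) {
      stop(errorCondition("model never reaches 0.5 (degenerate parameters)",
                          class = c("holophos_domain_error", "error")))
    }
  }
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
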