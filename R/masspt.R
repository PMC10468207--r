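#' Fit a Gaussian mixture to a particle-mass distribution
#'
#' Decomposes a mass-photometry event list into Gaussian peaks, mirroring the
#' multi-peak fit applied to instrument mass histograms: a smooth density
#' estimate of the windowed masses (Gaussian kernel, Silverman bandwidth) is
#' fitted with a sum of Gaussians by least squares, peaks seeded at local
#' maxima of the density when `n_peaks = "auto"`.  Peak areas are component
#' integrals of the fitted curve, expressed as percent of the total fitted
#' particle population.  Reported component widths are deconvolved for the
#' kernel bandwidth, so they estimate the underlying population SD rather
#' than the smoothed one.
#'
#' @param events numeric vector of particle masses, kDa (a mass event list).
#' @param n_peaks integer number of components, or `"auto"` to seed one
#'   component per local density maximum.
#' @param mass_window length-2 numeric `c(min, max)` kDa; events outside are
#'   ignored.
#' @param min_events minimum number of windowed events required (default 50).
#' @return object of class `mixture_fit`: data.frame `peaks` with columns
#'   `mean` (kDa), `sd` (kDa), `area_pct`, sorted by mean; plus `residual`
#'   (fitted minus density curve), `density` (the KDE), `n_events`.
#' @export
fit_mixture <- function(events, n_peaks = "auto",
                        mass_window = range(events), min_events = 50L) {
  if (length(mass_window) != 2L || mass_window[1] >= mass_window[2]) {
    abort_validation("mass_window must be c(min, max) with min < max")
  }
  x <- events[is.finite(events) & events >= mass_window[1] & events <= mass_window[2]]
  if (length(x) < min_events) {
    abort_validation(sprintf("only %d events in window; >= %d required",
                             length(x), min_events))
  }

  dens <- stats::density(x, bw = "nrd0", n = 1024,
                         from = mass_window[1], to = mass_window[2])
  bw <- dens$bw
  gx <- dens$x
  gy <- dens$y

  # seed components at local maxima of the smoothed density; shoulder
  # wiggles of broad peaks are pruned by a topographic-prominence test (a
  # maximum only counts as a separate peak if it is separated from every
  # taller accepted peak by a valley dropping below half its own height)
  cand <- which(diff(sign(diff(gy))) == -2) + 1L
  cand <- cand[gy[cand] > 0.01 * max(gy)]
  cand <- cand[order(gy[cand], decreasing = TRUE)]
  is_max <- integer(0)
  for (i in cand) {
    separated <- vapply(is_max, function(j) {
      valley <- min(gy[seq(min(i, j), max(i, j))])
      valley < 0.5 * gy[i]
    }, logical(1))
    if (all(separated)) is_max <- c(is_max, i)
  }
  is_max <- sort(is_max)
  if (identical(n_peaks, "auto")) {
    k <- length(is_max)
    if (k == 0L) abort_validation("no density maxima found in window")
    seeds <- is_max
  } else {
    k <- as.integer(n_peaks)
    if (k < 1L) abort_validation("n_peaks must be >= 1")
    seeds <- if (length(is_max) >= k) {
      is_max[order(gy[is_max], decreasing = TRUE)][seq_len(k)]
    } else {
      # not enough maxima: spread the remaining seeds over the window
      c(is_max, round(seq(1, length(gx), length.out = k - length(is_max) + 2L)[-c(1, k - length(is_max) + 2L)]))[seq_len(k)]
    }
  }
  seeds <- sort(seeds)

  # parameters per component: mean, log(sd), log(amplitude)
  p0 <- as.vector(vapply(seeds, function(i) {
    c(gx[i], log(max(bw * 1.5, diff(mass_window) / 200)), log(max(gy[i], 1e-8)))
  }, numeric(3)))

  model_curve <- function(p) {
    yhat <- numeric(length(gx))
    for (j in seq_len(length(p) / 3)) {
      m <- p[3 * j - 2]; s <- exp(p[3 * j - 1]); a <- exp(p[3 * j])
      yhat <- yhat + a * exp(-(gx - m)^2 / (2 * s^2))
    }
    yhat
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = function(p) gy - model_curve(p),
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  if (fit$info %in% c(0L, 9L)) {
    stop(errorCondition(paste0("mixture fit did not converge: ", fit$message),
                        class = c("holophos_fit_error", "error")))
  }

  p <- fit$par
  kfit <- length(p) / 3
  means <- p[3 * seq_len(kfit) - 2]
  sds_smooth <- exp(p[3 * seq_len(kfit) - 1])
  amps <- exp(p[3 * seq_len(kfit)])
  areas <- amps * sds_smooth * sqrt(2 * pi)
  ord <- order(means)
  peaks <- data.frame(
    mean = means[ord],
    # deconvolve the kernel: observed component variance = true + bw^2
    sd = sqrt(pmax(sds_smooth[ord]^2 - bw^2, (0.1 * bw)^2)),
    area_pct = 100 * areas[ord] / sum(areas)
  )
  structure(
    list(peaks = peaks, residual = model_curve(p) - gy,
         density = dens, n_events = length(x), bandwidth = bw),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%d events, %d peaks)\n",
              x$n_events, nrow(x$peaks)))
  p <- x$peaks
  for (i in seq_len(nrow(p))) {
    extra <- if (!is.null(p$n_mer)) sprintf("  %d-mer, %.1f%% of monomers",
                                            p$n_mer[i], p$monomer_pct[i]) else ""
    cat(sprintf("  peak %d: mean %.1f kDa, sd %.1f kDa, area %.1f%%%s\n",
                i - 1L, p$mean[i], p$sd[i], p$area_pct[i], extra))
  }
  invisible(x)
}

#' Assign an oligomeric state to a fitted peak
#'
#' Chooses the candidate subunit count `n` whose expected particle mass
#' `n * (monomer_mass + ligand_count * ligand_mass)` is closest to the peak
#' mean; ties break toward the smaller `n`.  With calmodulin bound (activated
#' conditions), set `ligand_mass = 16.7` and `ligand_count = 1`.
#'
#' @param peak_mean fitted peak mean, kDa.
#' @param monomer_mass subunit mass, kDa (CaMKII-alpha monomer: 55).
#' @param candidates integer vector of candidate subunit counts.
#' @param ligand_mass per-subunit ligand mass, kDa.
#' @param ligand_count 0 or 1 ligand per subunit.
#' @return the assigned `n`, with the absolute mass distance in
#'   `attr(, "distance")` for audit.
#' @examples
#' assign_oligomer(592, 55, c(2, 4, 12, 24))                     # 12
#' assign_oligomer(1442, 55, c(12, 24), ligand_mass = 16.7,
#'                 ligand_count = 1)                             # 24
#' @export
assign_oligomer <- function(peak_mean, monomer_mass, candidates,
                            ligand_mass = 0, ligand_count = 0) {
  if (!length(candidates)) abort_validation("candidates must be non-empty")
  if (monomer_mass <= 0) abort_validation("monomer_mass must be positive")
  candidates <- sort(as.integer(candidates))
  expected <- candidates * (monomer_mass + ligand_count * ligand_mass)
  d <- abs(peak_mean - expected)
  n <- candidates[which.min(d)]  # which.min takes the first = smallest on ties
  structure(n, distance = min(d))
}

#' Convert peak area percentages to monomer-level percentages
#'
#' Peak areas are percentages of particles; particles of different oligomeric
#' states contain different numbers of subunits.  Each area is therefore
#' weighted by its subunit count and renormalized:
#' `monomer_pct_i = 100 * area_i * n_i / sum_j(area_j * n_j)`.
#'
#' For fitted areas 4.7/85.9/9.4 assigned to 2-/12-/24-mers, the
#' monomer-weighted values are 9.4, 1030.8 and 225.6 (total 1265.8), giving
#' monomer percentages of about 0.7, 81.4 and 17.8.
#'
#' @param area_pct numeric vector of peak area percentages (> 0).
#' @param n_mer integer vector of assigned subunit counts (>= 1).
#' @return data.frame with `area_pct`, `n_mer`, `monomer_weight`
#'   (`area_pct * n_mer`), `monomer_pct` (full precision, sums to 100), and
#'   `monomer_pct_1dp` (rounded to the conventional one decimal);
#'   `attr(, "total_monomer_weight")` carries the summed weights.
#' @export
monomer_fractions <- function(area_pct, n_mer) {
  if (!length(area_pct)) abort_validation("empty peak list")
  if (length(area_pct) != length(n_mer)) abort_validation("area_pct and n_mer lengths differ")
  if (any(area_pct <= 0)) abort_validation("area_pct must be > 0")
  if (any(n_mer < 1)) abort_validation("n_mer must be >= 1")
  w <- area_pct * n_mer
  pct <- 100 * w / sum(w)
  structure(
    data.frame(area_pct = area_pct, n_mer = as.integer(n_mer),
               monomer_weight = w, monomer_pct = pct,
               monomer_pct_1dp = round(pct, 1)),
    total_monomer_weight = sum(w)
  )
}

#' Full mass-photometry decomposition
#'
#' Convenience wrapper: [fit_mixture()], then [assign_oligomer()] per peak,
#' then [monomer_fractions()].
#'
#' @inheritParams fit_mixture
#' @inheritParams assign_oligomer
#' @return the `mixture_fit` with `n_mer`, `monomer_weight` and `monomer_pct`
#'   columns added to `peaks`.
#' @export
decompose_masses <- function(events, monomer_mass, candidates,
                             n_peaks = "auto", mass_window = range(events),
                             ligand_mass = 0, ligand_count = 0) {
  fit <- fit_mixture(events, n_peaks = n_peaks, mass_window = mass_window)
  fit$peaks$n_mer <- vapply(fit$peaks$mean, function(m) {
    as.integer(assign_oligomer(m, monomer_mass, candidates,
                               ligand_mass = ligand_mass, ligand_count = ligand_count))
  }, integer(1))
  mf <- monomer_fractions(fit$peaks$area_pct, fit$peaks$n_mer)
  fit$peaks$monomer_weight <- mf$monomer_weight
  fit$peaks$monomer_pct <- mf$monomer_pct
  fit
}
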