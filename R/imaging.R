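#' Top-fraction intensity mask
#'
#' Binary mask keeping the brightest `ceiling(top_fraction * n_pixels)`
#' pixels of an image (nearest-rank selection on intensity).  All pixels tied
#' at the cutoff intensity are kept, so the mask may exceed the nominal count
#' under ties; the cutoff is reported.  The conventional background-removal
#' threshold for sparse single-molecule TIRF fields is the top 1% of signal.
#'
#' @param image 2-D numeric matrix of intensities.
#' @param top_fraction fraction of pixels to keep, in (0, 1].
#' @return logical matrix of the same shape, with attributes `cutoff`
#'   (intensity at the nominal rank) and `n_kept`.
#' @export
threshold_mask <- function(image, top_fraction = 0.01) {
  if (!is.matrix(image)) abort_validation("image must be a matrix")
  if (top_fraction <= 0 || top_fraction > 1) {
    abort_validation("top_fraction must be in (0, 1]")
  }
  v <- as.vector(image)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort_validation("intensities must be finite and >= 0")
  }
  if (max(v) == min(v)) {
    stop(errorCondition("constant image: top-fraction mask is degenerate",
                        class = c("holophos_domain_error", "error")))
  }
  k <- ceiling(top_fraction * length(v))
  cutoff <- sort(v, decreasing = TRUE)[k]
  mask <- image >= cutoff
  structure(mask, cutoff = cutoff, n_kept = sum(mask))
}

#' Pearson colocalization of a two-channel image pair
#'
#' Implements mask-then-correlate colocalization scoring: each channel is
#' thresholded to its top `top_fraction` of pixels ([threshold_mask()]), the
#' mask is applied to the original channel (pixels outside the mask set to
#' zero), and the Pearson correlation of the two masked channels is computed
#' over a support set.  Three support conventions are provided, because they
#' score anti-colocalized signal differently: `"union"` (default) correlates
#' over pixels in either mask, so fully disjoint signal drives r toward -1;
#' `"intersection"` uses only shared mask pixels; `"all"` correlates the two
#' masked images over the full frame (the full-frame convention of common
#' colocalization plugins, under which independent sparse signal gives r
#' near 0).
#'
#' @param channel_1,channel_2 2-D numeric matrices of equal shape.
#' @param top_fraction per-channel mask fraction (default 0.01 = top 1%).
#' @param support `"union"`, `"intersection"` or `"all"`.
#' @param condition,replicate optional labels carried into the result.
#' @return object of class `coloc_result`: list with `pearson_r`,
#'   `n_pixels_used`, `threshold_fraction`, `support`, `cutoffs`,
#'   `condition`, `replicate`.
#' @export
pearson_coloc <- function(channel_1, channel_2, top_fraction = 0.01,
                          support = c("union", "intersection", "all"),
                          condition = NA_character_, replicate = NA) {
  support <- match.arg(support)
  if (!identical(dim(channel_1), dim(channel_2))) {
    abort_validation("channels must have identical shapes")
  }
  m1 <- threshold_mask(channel_1, top_fraction)
  m2 <- threshold_mask(channel_2, top_fraction)
  sup <- switch(support,
                union = m1 | m2,
                intersection = m1 & m2,
                all = matrix(TRUE, nrow(channel_1), ncol(channel_1)))
  if (sum(sup) < 2L) {
    stop(errorCondition("mask support has fewer than 2 pixels",
                        class = c("holophos_domain_error", "error")))
  }
  a <- ifelse(m1, channel_1, 0)[sup]
  b <- ifelse(m2, channel_2, 0)[sup]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop(errorCondition("zero variance in a masked channel: Pearson undefined",
                        class = c("holophos_domain_error", "error")))
  }
  structure(
    list(pearson_r = stats::cor(a, b), n_pixels_used = sum(sup),
         threshold_fraction = top_fraction, support = support,
         cutoffs = c(attr(m1, "cutoff"), attr(m2, "cutoff")),
         condition = condition, replicate = replicate),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Pearson colocalization r = %.3f (%d px, top %.3g%%, %s support)\n",
              x$pearson_r, x$n_pixels_used, 100 * x$threshold_fraction, x$support))
  invisible(x)
}

#' Many-to-one comparison of condition groups against a control
#'
#' Compares each condition's colocalization scores against a designated
#' control with familywise error controlled at `alpha`, using Dunnett
#' many-to-one contrasts on a one-way layout (normal-theory critical values
#' from the multivariate t distribution).
#'
#' @param groups named list of numeric vectors (one per condition), or a
#'   data.frame with `condition` and `value` columns.
#' @param control name of the control condition.
#' @param alpha familywise error rate (default 0.05).
#' @return data.frame with one row per non-control condition: `condition`,
#'   `mean_diff` (condition minus control), `p_adjusted`, `reject`;
#'   `attr(, "alpha")` records the level.
#' @export
compare_to_control <- function(groups, control, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$condition)
  }
  if (!control %in% names(groups)) {
    abort_validation(sprintf("control group '%s' absent", control))
  }
  if (length(groups) < 2L) abort_validation("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    abort_validation("every group needs >= 2 observations")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups), lengths(groups)),
                       levels = c(control, setdiff(names(groups), control)))
  )
  fit <- stats::aov(value ~ condition, data = df)
  cmp <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  s <- summary(cmp)
  out <- data.frame(
    condition = sub(" - .*$", "", names(s$test$coefficients)),
    mean_diff = as.numeric(s$test$coefficients),
    p_adjusted = as.numeric(s$test$pvalues),
    reject = as.numeric(s$test$pvalues) < alpha
  )
  attr(out, "alpha") <- alpha
  attr(out, "control") <- control
  out
}
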