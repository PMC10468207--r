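#' Ground truth for synthetic phospho time courses
#'
#' Defines the study conditions emulated by [gen_timecourse()]: a
#' concentration titration of the enzyme kinase against excess substrate
#' kinase, with T286 phospho-fraction read out in triplicate at seven
#' timepoints.  Defaults mirror the western-blot titration design: enzyme at
#' 0.5/2/10/100 nM, samples at 1, 2, 5, 10, 15, 30 and 60 min, three
#' technical replicates, additive Gaussian noise on the normalized fraction.
#'
#' @param A1 amplitude of the concentration-independent component, `[0, 1]`.
#' @param r1 concentration-independent rate, 1/min (> 0).
#' @param k2 concentration-scaled rate, 1/(nM min) (> 0).
#' @param concentrations enzyme concentrations, nM (positive, sorted).
#' @param timepoints sample times, min (positive, sorted).
#' @param replicates technical replicates per point.
#' @param noise_sd additive Gaussian SD on the normalized fraction (>= 0).
#' @param seed integer seed.
#' @return validated list of class `kinetic_truth`.
#' @export
kinetic_truth <- function(A1 = 0.6, r1 = 0.3, k2 = 0.004,
                          concentrations = c(0.5, 2, 10, 100),
                          timepoints = c(1, 2, 5, 10, 15, 30, 60),
                          replicates = 3L, noise_sd = 0.05, seed = 1L) {
  if (A1 < 0 || A1 > 1) abort_validation("A1 must be in [0, 1]")
  if (r1 <= 0 || k2 <= 0) abort_validation("r1 and k2 must be > 0")
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    abort_validation("concentrations must be strictly positive and sorted")
  }
  if (any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE)) {
    abort_validation("timepoints must be strictly positive and sorted")
  }
  if (replicates < 1L) abort_validation("replicates must be >= 1")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  structure(list(A1 = A1, r1 = r1, k2 = k2, concentrations = concentrations,
                 timepoints = timepoints, replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kinetic_truth")
}

#' Generate a synthetic phospho time-course table
#'
#' One row per (concentration, time, replicate); the normalized fraction is
#' the two-component model value plus additive Gaussian noise, clipped to
#' `[0, 1.5]` (blot ratios can overshoot the fitted plateau but are bounded).
#' Deterministic given the truth's seed; each replicate draws from its own
#' derived noise sub-stream, so the table is invariant to replicate order.
#'
#' @param truth a [kinetic_truth()].
#' @return a [timecourse_table()] (total signal fixed at 1 a.u., phospho
#'   signal equal to the noisy fraction).
#' @export
gen_timecourse <- function(truth) {
  stopifnot(inherits(truth, "kinetic_truth"))
  grid <- expand.grid(time_min = truth$timepoints,
                      conc_nM = truth$concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  per_rep <- lapply(seq_len(truth$replicates), function(r) {
    mu <- eval_model(grid$time_min, truth$A1, truth$r1, truth$k2, grid$conc_nM)
    noisy <- with_seed(substream_seed(truth$seed, r), {
      mu + stats::rnorm(length(mu), sd = truth$noise_sd)
    })
    noisy <- pmin(pmax(noisy, 0), 1.5)
    data.frame(conc_nM = grid$conc_nM, time_min = grid$time_min,
               replicate = r, phospho = noisy, total = 1)
  })
  all <- do.call(rbind, per_rep)
  timecourse_table(all$conc_nM, all$time_min, all$replicate, all$phospho,
                   all$total, normalized = all$phospho)
}

#' Ground truth for synthetic crosslink tables
#'
#' Three scenarios with distinct, discriminating heterotypic signatures:
#'
#' * `"basal"` -- no mixing: heterotypic channels are zero for every pair
#'   (R = 0), as observed before activation.
#' * `"ihp"` -- inter-holoenzyme phosphorylation: heterotypic intensity only
#'   for kinase-kinase residue pairs, with mean R equal to `hetero_ratio`;
#'   zero elsewhere (notably hub-hub).
#' * `"exchange"` -- subunit exchange: heterotypic intensity across all
#'   domain pairs with a flat mean R of `hetero_ratio`.
#'
#' Crosslinked positions are sampled from the lysines of a synthetic
#' CaMKII-alpha-like sequence ([synthetic_camk2a_sequence()]; DSS is
#' amine-reactive), independently and uniformly over lysines, so the
#' unordered domain-pair sampling weights are the products of per-domain
#' lysine fractions (stored for goodness-of-fit checks).  Channel
#' intensities are log-normal around `intensity_scale` with coefficient of
#' variation `noise_cv` (MS intensities are positive and
#' multiplicative-noise dominated).
#'
#' @param name `"basal"`, `"ihp"` or `"exchange"`.
#' @param n_crosslinks unique crosslinked residue pairs (> 0).
#' @param map a [domain_map()].
#' @param hetero_ratio target mean R for heterotypic-capable pairs (>= 0).
#' @param intensity_scale homotypic channel intensity scale, a.u.
#' @param noise_cv coefficient of variation of intensities (>= 0).
#' @param replicates replicate tables generated (same site pairs, fresh
#'   intensities).
#' @param seed integer seed.
#' @param sequence subunit sequence to sample lysines from.
#' @return validated list of class `xl_scenario`.
#' @export
xl_scenario <- function(name = c("basal", "ihp", "exchange"),
                        n_crosslinks = 200L, map = domain_map(),
                        hetero_ratio = 0.25, intensity_scale = 1e6,
                        noise_cv = 0.2, replicates = 2L, seed = 1L,
                        sequence = synthetic_camk2a_sequence()) {
  name <- match.arg(name)
  if (n_crosslinks < 1L) abort_validation("n_crosslinks must be > 0")
  if (hetero_ratio < 0) abort_validation("hetero_ratio must be >= 0")
  if (noise_cv < 0) abort_validation("noise_cv must be >= 0")
  structure(list(name = name, n_crosslinks = as.integer(n_crosslinks),
                 map = map, hetero_ratio = hetero_ratio,
                 intensity_scale = intensity_scale, noise_cv = noise_cv,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 sequence = sequence),
            class = "xl_scenario")
}

# log-normal draws with a given mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic crosslink table
#'
#' @param scn an [xl_scenario()].
#' @return an [xl_table()] with one row per crosslink and replicate, plus
#'   ground-truth columns `truth_heterotypic` (logical) and `truth_R` (the
#'   drawn per-record mixing ratio; 0 where heterotypic channels are absent).
#'   The generator's unordered domain-pair sampling weights are stored in
#'   `attr(, "pair_weights")`.
#' @export
gen_xl_table <- function(scn) {
  stopifnot(inherits(scn, "xl_scenario"))
  lys <- lysine_positions(scn$sequence, scn$map)
  span <- domain_span(scn$map)
  lys <- lys[lys >= span[1] & lys <= span[2]]
  if (length(lys) < 2L) abort_validation("sequence has too few lysines in the covered span")

  # site pairs are a property of the sample, shared across replicates
  sites <- with_seed(substream_seed(scn$seed, 0L), {
    data.frame(pos_a = sample(lys, scn$n_crosslinks, replace = TRUE),
               pos_b = sample(lys, scn$n_crosslinks, replace = TRUE))
  })
  dom_a <- vapply(sites$pos_a, classify_domain, character(1), map = scn$map)
  dom_b <- vapply(sites$pos_b, classify_domain, character(1), map = scn$map)
  pair <- unordered_pair(dom_a, dom_b)
  hetero_capable <- switch(scn$name,
    basal = rep(FALSE, scn$n_crosslinks),
    ihp = pair == "kinase-kinase",
    exchange = rep(TRUE, scn$n_crosslinks)
  )
  peps_a <- vapply(sites$pos_a, function(p) tryptic_peptide_at(scn$sequence, p)$peptide,
                   character(1))
  peps_b <- vapply(sites$pos_b, function(p) tryptic_peptide_at(scn$sequence, p)$peptide,
                   character(1))
  condition <- if (scn$name == "basal") "basal" else "activated"

  reps <- lapply(seq_len(scn$replicates), function(r) {
    with_seed(substream_seed(scn$seed, r), {
      n <- scn$n_crosslinks
      i_ll <- rlnorm_mean_cv(n, scn$intensity_scale, scn$noise_cv)
      i_hh <- rlnorm_mean_cv(n, scn$intensity_scale, scn$noise_cv)
      # draw the record-level mixing ratio, then split it over the two
      # heterotypic channels so (I_LH + I_HL)/(I_LL + I_HH) equals the draw
      r_draw <- ifelse(hetero_capable,
                       rlnorm_mean_cv(n, scn$hetero_ratio, scn$noise_cv), 0)
      het_sum <- r_draw * (i_ll + i_hh)
      frac <- stats::runif(n, 0.3, 0.7)
      tab <- xl_table(peps_a, peps_b, sites$pos_a, sites$pos_b,
                      replicate = r, condition = condition,
                      I_LL = i_ll, I_LH = het_sum * frac,
                      I_HL = het_sum * (1 - frac), I_HH = i_hh)
      tab$truth_heterotypic <- hetero_capable
      tab$truth_R <- r_draw
      tab
    })
  })
  out <- do.call(rbind, reps)
  class(out) <- c("xl_table", "data.frame")

  # expected unordered domain-pair weights from per-domain lysine fractions
  p_dom <- table(factor(vapply(lys, classify_domain, character(1), map = scn$map),
                        levels = domain_names(scn$map))) / length(lys)
  dn <- domain_names(scn$map)
  w <- c()
  for (i in seq_along(dn)) {
    for (j in i:length(dn)) {
      w[unordered_pair(dn[i], dn[j])] <-
        if (i == j) p_dom[[i]]^2 else 2 * p_dom[[i]] * p_dom[[j]]
    }
  }
  attr(out, "pair_weights") <- w
  out
}

#' Ground truth for synthetic particle-mass mixtures
#'
#' @param components data.frame (or matrix) with columns `mean` (kDa), `sd`
#'   (kDa, > 0), `weight` (fractions summing to 1).
#' @param n_events number of particles (>= 0).
#' @param seed integer seed.
#' @return validated list of class `mass_mixture_truth`.
#' @export
mass_mixture_truth <- function(components, n_events = 10000L, seed = 1L) {
  components <- as.data.frame(components)
  if (!all(c("mean", "sd", "weight") %in% names(components))) {
    abort_validation("components needs mean, sd and weight columns")
  }
  if (any(components$sd <= 0)) abort_validation("component sds must be > 0")
  if (abs(sum(components$weight) - 1) > 1e-8) {
    abort_validation("component weights must sum to 1")
  }
  if (n_events < 0L) abort_validation("n_events must be >= 0")
  structure(list(components = components, n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "mass_mixture_truth")
}

#' Generate synthetic mass-photometry events
#'
#' Draws `n_events` particle masses from the stated Gaussian mixture.
#' Deterministic given the seed; the generating component of each event is
#' kept in `attr(, "component")` for label-aware recovery checks.
#'
#' @param truth a [mass_mixture_truth()].
#' @return numeric vector of masses, kDa.
#' @export
gen_mass_events <- function(truth) {
  stopifnot(inherits(truth, "mass_mixture_truth"))
  if (truth$n_events == 0L) {
    return(structure(numeric(0), component = integer(0)))
  }
  with_seed(truth$seed, {
    comp <- sample.int(nrow(truth$components), truth$n_events, replace = TRUE,
                       prob = truth$components$weight)
    masses <- stats::rnorm(truth$n_events,
                           mean = truth$components$mean[comp],
                           sd = truth$components$sd[comp])
    structure(masses, component = comp)
  })
}

#' Ground truth for synthetic two-channel spot images
#'
#' @param image_shape length-2 integer, pixels.
#' @param n_spots spots per channel.
#' @param coloc_fraction fraction of spot centers shared between channels,
#'   `[0, 1]`.
#' @param psf_sigma Gaussian point-spread sigma, pixels (> 0).
#' @param spot_amplitude peak intensity of one spot, a.u.
#' @param background_sd additive Gaussian background SD (>= 0).
#' @param seed integer seed.
#' @return validated list of class `spot_image_truth`.
#' @export
spot_image_truth <- function(image_shape = c(256L, 256L), n_spots = 150L,
                             coloc_fraction = 0.5, psf_sigma = 1.5,
                             spot_amplitude = 100, background_sd = 1,
                             seed = 1L) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    abort_validation("coloc_fraction must be in [0, 1]")
  }
  if (psf_sigma <= 0) abort_validation("psf_sigma must be > 0")
  if (background_sd < 0) abort_validation("background_sd must be >= 0")
  if (n_spots > prod(image_shape) / 16) {
    abort_validation("n_spots exceeds image capacity for resolvable spots")
  }
  structure(list(image_shape = as.integer(image_shape),
                 n_spots = as.integer(n_spots),
                 coloc_fraction = coloc_fraction, psf_sigma = psf_sigma,
                 spot_amplitude = spot_amplitude, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "spot_image_truth")
}

# render Gaussian spots onto a zero matrix
render_spots <- function(shape, centers, sigma, amplitude) {
  img <- matrix(0, shape[1], shape[2])
  if (nrow(centers) == 0L) return(img)
  half <- ceiling(4 * sigma)
  offs <- (-half):half
  kernel <- exp(-outer(offs^2, offs^2, `+`) / (2 * sigma^2))
  for (i in seq_len(nrow(centers))) {
    r0 <- centers$row[i]; c0 <- centers$col[i]
    rr <- (r0 - half):(r0 + half); cc <- (c0 - half):(c0 + half)
    rok <- rr >= 1 & rr <= shape[1]; cok <- cc >= 1 & cc <= shape[2]
    img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] +
      amplitude * kernel[rok, cok, drop = FALSE]
  }
  img
}

#' Generate a synthetic two-channel spot image pair
#'
#' A controllable fraction of spot centers is shared between the two
#' channels; the remainder are placed independently.  Spots are Gaussian
#' point-spread blobs of fixed amplitude; additive Gaussian background noise
#' is clipped at zero (camera offsets removed).  The ground-truth centers
#' are returned for recovery tests.
#'
#' @param truth a [spot_image_truth()].
#' @return list of class `image_pair` with `channel_1`, `channel_2`
#'   (matrices) and `centers_1`, `centers_2` (data.frames with `row`, `col`,
#'   `shared` columns).
#' @export
gen_spot_images <- function(truth) {
  stopifnot(inherits(truth, "spot_image_truth"))
  with_seed(truth$seed, {
    sh <- truth$image_shape
    n_shared <- round(truth$coloc_fraction * truth$n_spots)
    n_own <- truth$n_spots - n_shared
    draw <- function(n) data.frame(row = sample.int(sh[1], n, replace = TRUE),
                                   col = sample.int(sh[2], n, replace = TRUE))
    shared <- draw(n_shared)
    own1 <- draw(n_own)
    own2 <- draw(n_own)
    tag <- function(df, flag) {
      df$shared <- rep(flag, nrow(df))
      df
    }
    centers_1 <- rbind(tag(shared, TRUE), tag(own1, FALSE))
    centers_2 <- rbind(tag(shared, TRUE), tag(own2, FALSE))
    ch1 <- render_spots(sh, centers_1, truth$psf_sigma, truth$spot_amplitude)
    ch2 <- render_spots(sh, centers_2, truth$psf_sigma, truth$spot_amplitude)
    if (truth$background_sd > 0) {
      ch1 <- ch1 + matrix(stats::rnorm(prod(sh), sd = truth$background_sd), sh[1], sh[2])
      ch2 <- ch2 + matrix(stats::rnorm(prod(sh), sd = truth$background_sd), sh[1], sh[2])
    }
    structure(list(channel_1 = pmax(ch1, 0), channel_2 = pmax(ch2, 0),
                   centers_1 = centers_1, centers_2 = centers_2),
              class = "image_pair")
  })
}
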