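test_that("generators are pure functions of their truth objects", {
  kt <- kinetic_truth(seed = 99)
  expect_identical(gen_timecourse(kt), gen_timecourse(kt))

  scn <- xl_scenario("exchange", seed = 99)
  expect_identical(gen_xl_table(scn), gen_xl_table(scn))

  mt <- mass_mixture_truth(data.frame(mean = 592, sd = 30, weight = 1),
                           n_events = 500, seed = 99)
  expect_identical(gen_mass_events(mt), gen_mass_events(mt))

  st <- spot_image_truth(seed = 99)
  p1 <- gen_spot_images(st); p2 <- gen_spot_images(st)
  expect_identical(p1$channel_1, p2$channel_1)
  expect_identical(p1$channel_2, p2$channel_2)

  # generators leave the session RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_timecourse(kt)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero-noise time courses reproduce the kinetic model exactly", {
  kt <- kinetic_truth(A1 = 0.4, r1 = 0.5, k2 = 0.002, noise_sd = 0)
  tc <- gen_timecourse(kt)
  expect_equal(tc$normalized,
               eval_model(tc$time_min, 0.4, 0.5, 0.002, tc$conc_nM))
})

test_that("time-course noise has the stated standard deviation", {
  kt <- kinetic_truth(A1 = 0.5, r1 = 0.2, k2 = 0.005, concentrations = 10,
                      timepoints = 5, replicates = 1000, noise_sd = 0.05,
                      seed = 17)
  tc <- gen_timecourse(kt)
  expect_equal(nrow(tc), 1000)
  expect_lt(abs(sd(tc$normalized) - 0.05), 0.005)
  # values stay within the stated clip range
  expect_true(all(tc$normalized >= 0 & tc$normalized <= 1.5))
})

test_that("truth validation rejects out-of-range parameters", {
  expect_error(kinetic_truth(A1 = 1.5), class = "holophos_validation_error")
  expect_error(kinetic_truth(noise_sd = -1), class = "holophos_validation_error")
  expect_error(kinetic_truth(concentrations = c(10, 2)),
               class = "holophos_validation_error")
  expect_error(xl_scenario("ihp", hetero_ratio = -0.1),
               class = "holophos_validation_error")
  expect_error(xl_scenario("melt"))
  expect_error(mass_mixture_truth(data.frame(mean = 1, sd = 1, weight = 0.5)),
               class = "holophos_validation_error")
  expect_error(spot_image_truth(coloc_fraction = 2),
               class = "holophos_validation_error")
  expect_error(spot_image_truth(n_spots = 1e6),
               class = "holophos_validation_error")
})

test_that("basal crosslink tables carry no heterotypic signal", {
  xl <- gen_xl_table(xl_scenario("basal", n_crosslinks = 100, seed = 5))
  q <- compute_R(xl)
  expect_true(all(q$R == 0))
  expect_false(any(q$is_heterotypic_capable))
})

test_that("IHP tables put the target mixing ratio only on kinase-kinase pairs", {
  xl <- gen_xl_table(xl_scenario("ihp", hetero_ratio = 0.25, n_crosslinks = 200,
                                 seed = 42))
  q <- compute_R(xl)
  kk <- q$domain_pair == "kinase-kinase"
  expect_lt(abs(mean(q$R[kk]) - 0.25), 0.03)
  # all other pairs, hub-hub in particular, have zero heterotypic intensity
  expect_true(all(q$I_LH[!kk] == 0 & q$I_HL[!kk] == 0))
  hh <- q$domain_pair == "hub-hub"
  expect_gt(sum(hh), 0)
  expect_true(all(q$R[hh] == 0))
})

test_that("exchange tables spread heterotypic links per the sampling weights", {
  scn <- xl_scenario("exchange", n_crosslinks = 400, seed = 13)
  xl <- gen_xl_table(scn)
  w <- attr(xl, "pair_weights")
  q <- compute_R(xl)
  one_rep <- q[q$replicate == 1, ]
  expect_true(all(one_rep$is_heterotypic_capable))
  counts <- table(factor(one_rep$domain_pair, levels = names(w)))
  p <- suppressWarnings(stats::chisq.test(as.vector(counts), p = w)$p.value)
  expect_gt(p, 0.01)
  # flat mixing ratio across domain pairs
  s <- summarize_ratios(q)
  expect_true(all(abs(s$mean_R[s$n >= 10] - 0.25) < 0.05))
})

test_that("mass-event generation matches its mixture truth", {
  expect_length(gen_mass_events(mass_mixture_truth(
    data.frame(mean = 592, sd = 30, weight = 1), n_events = 0)), 0)

  ev <- gen_mass_events(mass_mixture_truth(
    data.frame(mean = 660, sd = 30, weight = 1), n_events = 5000, seed = 3))
  expect_lt(abs(mean(ev) - 660), 2)

  truth <- mass_mixture_truth(
    data.frame(mean = c(110, 592, 1320), sd = c(15, 30, 60),
               weight = c(0.05, 0.85, 0.10)), n_events = 10000, seed = 19)
  ev3 <- gen_mass_events(truth)
  # nearest-mean assignment recovers the component fractions
  assign <- apply(abs(outer(as.numeric(ev3), truth$components$mean, "-")), 1,
                  which.min)
  frac <- tabulate(assign, 3) / length(ev3)
  expect_true(all(abs(frac - truth$components$weight) < 0.02))
})

test_that("spot images share the stated fraction of centers between channels", {
  full <- gen_spot_images(spot_image_truth(coloc_fraction = 1, background_sd = 0,
                                           seed = 6))
  expect_identical(full$channel_1, full$channel_2)
  expect_gt(pearson_coloc(full$channel_1, full$channel_2)$pearson_r, 0.9)

  none <- gen_spot_images(spot_image_truth(coloc_fraction = 0, n_spots = 200,
                                           image_shape = c(512L, 512L), seed = 6))
  expect_lt(pearson_coloc(none$channel_1, none$channel_2)$pearson_r, 0.2)
  expect_false(any(none$centers_1$shared))

  half <- gen_spot_images(spot_image_truth(coloc_fraction = 0.5, seed = 6))
  expect_equal(sum(half$centers_1$shared), round(0.5 * 150))
})
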