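test_that("eval_model matches the closed-form two-component expression", {
  # t = 0: both exponentials are 1 and the amplitudes sum to 1
  expect_equal(eval_model(0, 0.3, 0.5, 0.01, 10), 0)
  expect_equal(eval_model(0, 1, 2, 0.1, 100), 0)
  # A1 = 1 collapses to a single exponential with half-life ln2/r1
  expect_equal(eval_model(1, 1, log(2), 0, 0), 0.5)
  # frozen value of 1 - 0.5 e^-0.4 - 0.5 e^-0.1 (independent calculator)
  expect_equal(eval_model(2, 0.5, 0.2, 0.005, 10), 0.21242126796, tolerance = 1e-9)
  expect_error(eval_model(1, 1.2, 0.5, 0.01, 10), class = "holophos_validation_error")
})

test_that("eval_model is nondecreasing in t and bounded in [0, 1)", {
  set.seed(11)
  for (i in 1:20) {
    A1 <- runif(1); r1 <- 10^runif(1, -2, 0.5); k2 <- 10^runif(1, -4, -1)
    c_nM <- sample(c(0.5, 2, 10, 100), 1)
    tt <- seq(0, 200, length.out = 400)
    y <- eval_model(tt, A1, r1, k2, c_nM)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= 0 & y <= 1))
    expect_lt(eval_model(0, A1, r1, k2, c_nM), 1)
  }
})

test_that("normalize_curve rescales ratios and excludes zero-total rows", {
  tab <- timecourse_table(10, c(1, 2, 5), 1, phospho = c(0.4, 0.4, 0.4), total = 1)
  out <- normalize_curve(tab, fit_max = 0.4)
  expect_equal(out$normalized, rep(1, 3))
  out2 <- normalize_curve(tab, fit_max = 0.8)
  expect_equal(out2$normalized, rep(0.5, 3))

  tab$total[2] <- 0
  out3 <- normalize_curve(tab, fit_max = 0.4)
  expect_equal(nrow(out3), 2)
  excl <- attr(out3, "excluded")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "zero total")
})

test_that("preliminary-fit normalization brings the plateau to one", {
  truth <- kinetic_truth(A1 = 0.6, r1 = 0.3, k2 = 0.004, concentrations = 10,
                         timepoints = c(1, 2, 5, 10, 15, 30, 60),
                         noise_sd = 0.02, seed = 7)
  tc <- gen_timecourse(truth)
  # emulate an arbitrary blot gain: signals in a.u., not fractions
  tc$phospho <- tc$phospho * 0.37
  tc$normalized <- tc$phospho / tc$total
  est <- estimate_curve_max(tc)
  norm <- normalize_curve(tc, est$ymax)
  plateau <- mean(norm$normalized[norm$time_min == 60])
  expect_gt(plateau, 0.95)
  expect_lt(plateau, 1.05)
})

test_that("global fit recovers truth exactly from noiseless data", {
  truth <- kinetic_truth(A1 = 0.6, r1 = 0.3, k2 = 0.004,
                         concentrations = c(0.5, 2, 10), noise_sd = 0)
  fit <- fit_global(gen_timecourse(truth))
  expect_equal(fit$A1, 0.6, tolerance = 1e-4)
  expect_equal(fit$r1, 0.3, tolerance = 1e-4)
  expect_equal(fit$k2, 0.004, tolerance = 1e-4)
  # optimum is at least as good as the generating truth
  expect_lt(fit$weighted_rss, 1e-9)
})

test_that("global fit recovers truth within 20% from noisy triplicates", {
  fit <- fit_global(gen_timecourse(kinetic_truth(seed = 3)))
  expect_lt(abs(fit$A1 / 0.6 - 1), 0.2)
  expect_lt(abs(fit$r1 / 0.3 - 1), 0.2)
  expect_lt(abs(fit$k2 / 0.004 - 1), 0.2)
})

test_that("saturating curves reduce to a one-exponential fit with rate c*k2", {
  # both concentrations flagged saturating: the global model is a shared-k2
  # pair of single exponentials
  truth <- kinetic_truth(A1 = 0.001, r1 = 1e-6, k2 = 0.004,
                         concentrations = c(10, 100), noise_sd = 0)
  tc <- gen_timecourse(truth)
  # regenerate exactly single-exponential data (A1 = 0 is outside the truth
  # constructor's open interval checks for rates, so build rows directly)
  tc$normalized <- 1 - exp(-tc$conc_nM * 0.004 * tc$time_min)
  fit <- fit_global(tc, saturating = c(10, 100))
  expect_equal(fit$k2, 0.004, tolerance = 1e-6)
  # and the implied rate at each concentration equals c * k2
  expect_equal(unname(fit$half_times[["10"]]), log(2) / (10 * 0.004), tolerance = 1e-4)
})

test_that("fit results are invariant to row order and replicate relabeling", {
  tc <- gen_timecourse(kinetic_truth(seed = 5))
  fit1 <- fit_global(tc)
  perm <- sample(nrow(tc))
  fit2 <- fit_global(tc[perm, ])
  expect_equal(fit1$A1, fit2$A1, tolerance = 1e-6)
  expect_equal(fit1$k2, fit2$k2, tolerance = 1e-6)

  tc3 <- tc
  tc3$replicate <- match(tc3$replicate, c(2, 3, 1))  # relabel
  fit3 <- fit_global(tc3)
  expect_equal(fit1$r1, fit3$r1, tolerance = 1e-6)

  lf1 <- fit_langmuir(tc[tc$conc_nM == 10, ])
  lf2 <- fit_langmuir(tc[perm, ][tc[perm, ]$conc_nM == 10, ])
  expect_equal(lf1$t_half, lf2$t_half, tolerance = 1e-6)
})

test_that("Langmuir fit identifies exact saturation data and flags degeneracy", {
  t <- c(1, 2, 4, 8, 16)
  tab <- timecourse_table(1, t, 1, phospho = 2 * t / (4 + t), total = 1)
  fit <- fit_langmuir(tab)
  expect_equal(fit$ymax, 2, tolerance = 1e-8)
  expect_equal(fit$t_half, 4, tolerance = 1e-8)
  expect_false(fit$degenerate)
  expect_equal(half_time(fit), fit$t_half)

  # constant signal with a t = 0 anchor: t_half collapses, flagged
  flat <- timecourse_table(1, c(0, 5, 10, 20), 1,
                           phospho = c(0, 1, 1, 1), total = 1)
  ffit <- fit_langmuir(flat)
  expect_true(ffit$degenerate)
})

test_that("Langmuir fit recovers a seeded noisy half-time within 15%", {
  t <- c(1, 2, 5, 10, 15, 30, 60)
  set.seed(21)
  y <- t / (4 + t) + rnorm(length(t) * 3, sd = 0.03)
  tab <- timecourse_table(1, rep(t, 3), rep(1:3, each = length(t)),
                          phospho = pmax(y, 0), total = 1)
  fit <- fit_langmuir(tab)
  expect_lt(abs(fit$t_half / 4 - 1), 0.15)
  expect_lt(abs(fit$ymax - 1), 0.15)
})

test_that("half-time matches closed forms and the dense-grid oracle", {
  expect_equal(half_time_two_component(1, 0.693147, 0, 0), 1.0, tolerance = 1e-5)
  expect_equal(half_time_two_component(1, 1.386294, 0, 0), 0.5, tolerance = 1e-5)
  expect_equal(half_time_two_component(0.5, 0.2, 0.005, 10),
               grid_half_time(0.5, 0.2, 0.005, 10), tolerance = 1e-3)
  expect_error(half_time_two_component(0.3, 0.5, 0, 0),
               class = "holophos_domain_error")
})

test_that("half-time is monotone in r1 and in concentration", {
  r1s <- c(0.1, 0.2, 0.5, 1, 2)
  ht <- vapply(r1s, function(r) half_time_two_component(1, r, 0, 0), numeric(1))
  expect_true(all(diff(ht) < 0))

  cs <- c(0.5, 2, 10, 100)
  ht2 <- vapply(cs, function(cc) half_time_two_component(0.4, 0.3, 0.004, cc),
                numeric(1))
  expect_true(all(diff(ht2) <= 1e-9))
})
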