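test_that("nitrogen counts follow residue elemental composition and are additive", {
  expect_equal(nitrogen_count("GK"), 3)
  expect_equal(nitrogen_count("R"), 4)
  expect_equal(nitrogen_count("AAA"), 3)
  expect_error(nitrogen_count("AXZ"), "X")

  set.seed(4)
  aas <- names(mass_constants()$residue_N)
  for (i in 1:10) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 5, replace = TRUE), collapse = "")
    expect_equal(nitrogen_count(paste0(a, b)),
                 nitrogen_count(a) + nitrogen_count(b))
  }
})

test_that("channel masses obey linker bookkeeping and 15N shift arithmetic", {
  const <- mass_constants()
  m <- channel_masses("GK", "AK")
  # mixed channels sum to the uni-isotopic channels' sum
  expect_equal(m[["M_LH"]] + m[["M_HL"]], m[["M_LL"]] + m[["M_HH"]],
               tolerance = 1e-12)
  # both peptides carry 3 N: full shift is 6 x 0.997035 Da
  expect_equal(m[["M_HH"]] - m[["M_LL"]], 5.98221, tolerance = 1e-8)
  # the crosslinked pair weighs the two peptides plus the DSS linker
  expect_equal(m[["M_LL"]] - peptide_mono_mass("GK") - peptide_mono_mass("AK"),
               138.068, tolerance = 1e-9)
  # strict channel ordering for nitrogen-containing peptides
  set.seed(9)
  aas <- names(const$residue_N)
  for (i in 1:8) {
    mm <- channel_masses(paste(sample(aas, 6, TRUE), collapse = ""),
                         paste(sample(aas, 9, TRUE), collapse = ""))
    expect_true(mm[["M_LL"]] < mm[["M_LH"]] && mm[["M_LL"]] < mm[["M_HL"]])
    expect_true(mm[["M_LH"]] < mm[["M_HH"]] && mm[["M_HL"]] < mm[["M_HH"]])
  }
})

test_that("the mixing ratio R matches hand arithmetic under both denominators", {
  rec0 <- xl_table("GK", "AK", 42, 56, 1, "basal", 100, 0, 0, 150)
  expect_equal(compute_R(rec0)$R, 0)
  expect_equal(compute_R(rec0, "as_printed")$R, 0)

  rec <- xl_table("GK", "AK", 42, 56, 1, "activated", 100, 20, 30, 150)
  expect_equal(compute_R(rec)$R, 50 / 250)
  expect_equal(compute_R(rec, "as_printed")$R, 50 / 120)
})

test_that("R is scale-invariant and label-swap-invariant under homotypic_sum", {
  set.seed(2)
  for (i in 1:10) {
    I <- runif(4, 1, 1000)
    rec <- xl_table("GK", "AK", 42, 56, 1, "activated", I[1], I[2], I[3], I[4])
    scl <- xl_table("GK", "AK", 42, 56, 1, "activated",
                    7.3 * I[1], 7.3 * I[2], 7.3 * I[3], 7.3 * I[4])
    swp <- xl_table("GK", "AK", 42, 56, 1, "activated", I[4], I[3], I[2], I[1])
    expect_equal(compute_R(rec)$R, compute_R(scl)$R, tolerance = 1e-12)
    expect_equal(compute_R(rec)$R, compute_R(swp)$R, tolerance = 1e-12)
  }
  # zero denominator: undefined, flagged, excluded from summaries
  undef <- xl_table("GK", "AK", 42, 56, 1, "activated", 0, 10, 10, 0)
  q <- compute_R(undef)
  expect_false(q$R_defined)
  expect_true(is.na(q$R))
  s <- summarize_ratios(q)
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "n_undefined"), 1)
})

test_that("residue positions classify into the expected subunit domains", {
  dm <- domain_map()
  expect_equal(classify_domain(100, dm), "kinase")
  expect_equal(classify_domain(344, dm), "hub")
  expect_equal(classify_domain(347, dm), "hub")
  expect_equal(classify_domain(290, dm), "regulatory")
  expect_equal(classify_domain(320, dm), "linker")
  expect_error(classify_domain(500, dm), class = "holophos_validation_error")
})

test_that("heterotypic heatmap of an IHP table is confined to kinase-kinase", {
  xl <- gen_xl_table(xl_scenario("ihp", n_crosslinks = 200, seed = 12))
  hm <- build_heatmap(xl, "heterotypic", require_both_replicates = TRUE)
  m <- unclass(hm)[, ]
  expect_gt(m["kinase", "kinase"], 0)
  m["kinase", "kinase"] <- 0
  expect_true(all(m == 0))
})

test_that("empty input yields an all-zero heatmap", {
  empty <- xl_table(character(0), character(0), integer(0), integer(0),
                    integer(0), character(0), numeric(0), numeric(0),
                    numeric(0), numeric(0))
  hm <- build_heatmap(empty, "heterotypic")
  expect_true(all(unclass(hm)[, ] == 0))
  expect_equal(heatmap_total(hm), 0)
})

test_that("replicate intersection drops single-replicate links and conserves counts", {
  base <- xl_table(pep_a = rep("GK", 3), pep_b = rep("AK", 3),
                   pos_a = c(42, 42, 344), pos_b = c(56, 56, 347),
                   replicate = c(1, 2, 1), condition = "activated",
                   I_LL = 100, I_LH = 10, I_HL = 10, I_HH = 100)
  hm <- build_heatmap(base, "heterotypic", require_both_replicates = TRUE)
  # 42-56 present in both replicates; 344-347 only in replicate 1
  expect_equal(heatmap_total(hm), 1)
  expect_equal(unclass(hm)["kinase", "kinase"], 1)
  expect_equal(unclass(hm)["hub", "hub"], 0)

  # without intersection both unique site pairs are counted
  hm2 <- build_heatmap(base, "heterotypic", require_both_replicates = FALSE)
  expect_equal(heatmap_total(hm2), 2)

  # intersection count never exceeds either replicate's own count
  xl <- gen_xl_table(xl_scenario("exchange", n_crosslinks = 120, seed = 8))
  q <- compute_R(xl)
  per_rep <- vapply(unique(xl$replicate), function(r) {
    heatmap_total(build_heatmap(q[q$replicate == r, ], "heterotypic"))
  }, numeric(1))
  hm3 <- build_heatmap(q, "heterotypic", require_both_replicates = TRUE)
  expect_lte(heatmap_total(hm3), min(per_rep))
})

test_that("ratio summaries recover the generator's target mixing ratio", {
  s1 <- summarize_ratios(compute_R(
    xl_table("GK", "AK", 42, 56, 1, "activated", 100, 20, 20, 100)))
  expect_equal(s1$mean_R, 0.2)
  expect_equal(s1$n, 1)
  expect_true(is.na(s1$se_R))

  xl <- gen_xl_table(xl_scenario("ihp", hetero_ratio = 0.25, n_crosslinks = 200,
                                 seed = 31))
  q <- compute_R(xl)
  kk <- summarize_ratios(q[q$is_heterotypic_capable, ])
  expect_equal(kk$group, "kinase-kinase")
  expect_lt(abs(kk$mean_R - 0.25), 2 * kk$se_R + 0.01)
})

test_that("crosslink-to-structure distances are Euclidean, symmetric and rigid", {
  coords <- data.frame(chain = "A", resno = c(42, 56, 344),
                       x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 0))
  rec <- xl_table(c("GK", "GK"), c("AK", "AK"), c(42, 42), c(56, 344),
                  1, "basal", 100, 0, 0, 100)
  m <- map_to_structure(rec, coords, pairing = "intra_subunit", max_dist = 30)
  expect_equal(m$distance, c(5, 0))
  expect_equal(m$satisfied, c(TRUE, TRUE))

  # symmetric in (pos_a, pos_b)
  rec_sw <- xl_table("AK", "GK", 56, 42, 1, "basal", 100, 0, 0, 100)
  m_sw <- map_to_structure(rec_sw, coords, pairing = "intra_subunit")
  expect_equal(m_sw$distance, 5)

  # invariant under rigid-body transformation
  m_rigid <- map_to_structure(rec, rigid_transform(coords), pairing = "intra_subunit")
  expect_equal(m_rigid$distance, m$distance, tolerance = 1e-6)

  # threshold boundary: tighten max_dist below every distance
  m_tight <- map_to_structure(rec[1, ], coords, pairing = "intra_subunit",
                              max_dist = 4.9)
  expect_false(any(m_tight$satisfied))

  # missing residue: flagged unmapped, not dropped
  rec_miss <- xl_table("GK", "AK", 42, 470, 1, "basal", 100, 0, 0, 100)
  m_miss <- map_to_structure(rec_miss, coords)
  expect_equal(nrow(m_miss), 1)
  expect_false(m_miss$mapped)
  expect_true(is.na(m_miss$distance))
})

test_that("inter-subunit pairing takes the minimum over distinct chains", {
  coords <- data.frame(chain = c("A", "A", "B", "B"),
                       resno = c(42, 56, 42, 56),
                       x = c(0, 1, 10, 20), y = 0, z = 0)
  rec <- xl_table("GK", "AK", 42, 56, 1, "basal", 100, 0, 0, 100)
  # intra: |0-1| = 1;  inter minimum: A42-B56 = 20, B42-A56 = 9 -> 9
  expect_equal(map_to_structure(rec, coords, pairing = "intra_subunit")$distance, 1)
  expect_equal(map_to_structure(rec, coords, pairing = "inter_subunit_min")$distance, 9)
  # holoenzyme grouping: chains in the same assembly are excluded
  m <- map_to_structure(rec, coords, pairing = "inter_holoenzyme_min",
                        chain_groups = c(A = 1, B = 2))
  expect_equal(m$distance, 9)
})

test_that("pseudobond export writes one viewer-readable line per mapped link", {
  coords <- data.frame(chain = "A", resno = c(42, 56), x = c(0, 3), y = c(0, 4),
                       z = 0)
  rec <- xl_table("GK", "AK", 42, 56, 1, "basal", 100, 0, 0, 100)
  m <- map_to_structure(rec, coords, pairing = "intra_subunit")
  path <- tempfile(fileext = ".pb")
  n <- write_pseudobonds(m, path)
  expect_equal(n, 1)
  expect_equal(readLines(path), "/A:42@CA /A:56@CA")
})
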