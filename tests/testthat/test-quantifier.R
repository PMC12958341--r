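test_that("mass_from_integral follows the internal-standard relation", {
  expect_equal(mass_from_integral(0, 10, 2, 3, 196, 246, 1), 0)
  # identity case: same integral, protons and molar mass returns m_is
  expect_equal(mass_from_integral(7.3, 7.3, 3, 3, 246.43, 246.43, 1.7), 1.7)
  # linear in i_a
  m1 <- mass_from_integral(1, 5, 2, 3, 196.24, 246.43, 1)
  m2 <- mass_from_integral(2, 5, 2, 3, 196.24, 246.43, 1)
  expect_equal(m2, 2 * m1)
  expect_error(mass_from_integral(1, 0, 2, 3, 196, 246, 1), "internal-standard")
})

test_that("simulated PS mass is recovered within 3% against a weighed TTB", {
  out <- quick_spec(c(PS = 0.30))
  q <- quantify(out$spec, sample_prep())
  got <- q$mass_mg[q$compound == "PS"]
  expect_equal(got, 0.30, tolerance = 0.03)
})

test_that("PG correction subtracts half the PEG G2 integral and floors at zero", {
  expect_equal(as.numeric(correct_pg_integral(1.0, 0.4)), 0.8)
  expect_equal(as.numeric(correct_pg_integral(3.7, 0)), 3.7)
  floored <- correct_pg_integral(0.1, 0.4)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "floored"))
  # conservation whenever no flooring occurs
  set.seed(1)
  for (i in 1:50) {
    pg <- runif(1, 0, 10); peg <- runif(1, 0, pg)
    corr <- correct_pg_integral(pg, peg)
    expect_equal(as.numeric(corr) + 0.5 * peg, pg)
  }
  expect_error(correct_pg_integral(-1, 0), ">= 0")
})

test_that("EG estimation follows es x (pg/ps) and guards ps <= 0", {
  expect_equal(estimate_eg_yield(0, 8.3, 5.8), 0)
  expect_equal(estimate_eg_yield(0.5, 8.3, 5.8), 0.5 * 5.8 / 8.3)
  expect_equal(estimate_eg_yield(0.5, 8.3, 5.8), 0.349, tolerance = 0.002)
  expect_error(estimate_eg_yield(0.5, 0, 5.8), "PS yield")
})

test_that("phenol interference is detected only when phenol is present", {
  rich <- cached_oil("phenol_rich", seed = 3)
  chk <- detect_phenol_interference(rich$spec)
  expect_true(chk$detected)
  expect_gt(chk$snr, 10)
  clean <- cached_oil("propyl_selective", seed = 3)
  expect_false(detect_phenol_interference(clean$spec)$detected)
  zero <- new_spectrum(seq(12, -2, length.out = 8192), rep(0, 8192),
                       sf_mhz = 400)
  expect_false(detect_phenol_interference(zero)$detected)
})

test_that("the aliphatic profile flags the side chains actually present", {
  prop <- cached_oil("propyl_selective", seed = 2)
  prof <- aliphatic_crosscheck(prop$spec)
  expect_false(any(prof$present[prof$window_id == "ethyl_beta"]))
  expect_true(all(prof$present[prof$window_id == "propyl_gamma"]))
  h2 <- cached_oil("h2free_propenyl", seed = 2)
  prof2 <- aliphatic_crosscheck(h2$spec)
  expect_true(all(prof2$present[prof2$side_chain == "alkene"]))
  expect_false(any(prof2$present[prof2$window_id == "propyl_gamma"]))
})

test_that("aliphatic fallback recovers G-type monomers when the G2 route is gated", {
  pdc <- cached_oil("pdc_three_chain", seed = 4)
  q <- quantify(pdc$spec)
  tr <- true_yield_table(pdc$truth)
  pgoh_true <- tr$true_yield[tr$compound == "PGOH"]
  row <- q[q$compound == "PGOH", ]
  expect_equal(row$method, "aliphatic_fallback")
  expect_match(row$flags, "g2_unreliable")
  expect_equal(row$yield_wt_pct, pgoh_true, tolerance = 0.10)
  # direct S quantification and the aliphatic total agree (conservation)
  s_only <- quick_spec(c(PSOH = 0.4))
  qs <- quantify(s_only$spec)
  fb <- quantify_g_from_aliphatic(s_only$spec, qs, sample_prep())
  expect_equal(fb$yield_wt_pct[fb$compound == "PGOH"], 0, tolerance = 0.05 * 10)
  # no G compounds anywhere: fallback G masses are ~0
  expect_lt(sum(fb$mass_mg), 0.05 * 0.4)
})

test_that("full pipeline recovers a noise-free propyl-selective oil within 3%", {
  sim <- cached_oil("propyl_selective", seed = 1, noise_sigma = 0)
  q <- quantify(sim$spec)
  tr <- true_yield_table(sim$truth)
  for (ab in c("PS", "PSOH", "PG", "PGOH")) {
    got <- q$yield_wt_pct[q$compound == ab]
    want <- tr$true_yield[tr$compound == ab]
    expect_equal(got, want, tolerance = 0.03, label = ab)
  }
})

test_that("doubling every concentration doubles every yield within 0.5%", {
  a <- cached_oil("mixed_50_50", seed = 5, noise_sigma = 0)
  b <- simulate_oil("mixed_50_50", seed = 5, noise_sigma = 0, scale = 2)
  qa <- quantify(a$spec)
  qb <- quantify(process_fid(b$fid))
  j <- dplyr::inner_join(
    dplyr::select(tidy(qa), compound, y1 = yield_wt_pct),
    dplyr::select(tidy(qb), compound, y2 = yield_wt_pct),
    by = "compound"
  )
  j <- j[!is.na(j$y1) & !is.na(j$y2) & j$y1 > 0.1, ]
  expect_gt(nrow(j), 5)
  expect_true(all(abs(j$y2 / j$y1 - 2) < 0.005 * 2))
})

test_that("H2-free oil quantifies PES/PEG while PS/PG report near zero", {
  h2 <- cached_oil("h2free_propenyl", seed = 6)
  q <- quantify(h2$spec)
  tr <- true_yield_table(h2$truth)
  for (ab in c("PES", "PEG")) {
    expect_equal(q$yield_wt_pct[q$compound == ab],
                 tr$true_yield[tr$compound == ab], tolerance = 0.10,
                 label = ab)
  }
  expect_lt(q$yield_wt_pct[q$compound == "PS"] +
              q$yield_wt_pct[q$compound == "PG"], 0.5)
})

test_that("yields are invariant to overall spectrum scaling (internal standard)", {
  sim <- cached_oil("mixed_50_50", seed = 7)
  q1 <- quantify(sim$spec)
  scaled <- new_spectrum(sim$spec$ppm, 4.2 * sim$spec$intensity,
                         sf_mhz = sf_mhz(sim$spec),
                         provenance = provenance(sim$spec))
  q2 <- quantify(scaled)
  expect_equal(q2$yield_wt_pct, q1$yield_wt_pct, tolerance = 1e-8)
})

test_that("quantification is invariant to a rigid axis shift plus recalibration", {
  sim <- cached_oil("propyl_selective", seed = 8)
  q1 <- quantify(sim$spec)
  shifted <- new_spectrum(sim$spec$ppm + 0.013, sim$spec$intensity,
                          sf_mhz = sf_mhz(sim$spec),
                          provenance = provenance(sim$spec))
  q2 <- quantify(shifted)
  expect_equal(q2$yield_wt_pct, q1$yield_wt_pct, tolerance = 1e-10)
})

test_that("reported yield never decreases when a compound's true amount increases", {
  concs <- c(0.05, 0.15, 0.3, 0.6)
  got <- vapply(concs, function(cc) {
    out <- quick_spec(c(PS = cc, PSOH = 0.2))
    q <- quantify(out$spec)
    q$yield_wt_pct[q$compound == "PS"]
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("quantify fails without a detectable internal standard and records prep", {
  out <- quick_spec(c(PS = 0.3))
  naked <- simulate_fid(quick_mix(c(PS = 0.3), is_mass_mg = 0))
  expect_error(quantify(process_fid(naked$fid)), "TTB|reference peak")
  q <- quantify(out$spec, sample_prep(aliquot_ml = 0.5, total_liquor_ml = 40,
                                      basis_mass_mg = 500))
  # yield convention: mass x (total/aliquot) / basis
  ps <- q[q$compound == "PS", ]
  expect_equal(ps$yield_wt_pct,
               100 * ps$mass_mg * (40 / 0.5) / 500)
  expect_error(sample_prep(aliquot_ml = 2, total_liquor_ml = 1), "aliquot")
})
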