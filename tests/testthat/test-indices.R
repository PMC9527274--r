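srvot_med <- median_beat("s-RVOT")
lvot_med <- median_beat("LVOT-ASC")
crits <- default_criteria()

test_that("R-S difference index reproduces the group-median arithmetic", {
  expect_equal(rs_difference_index(lvot_med)$value,
               6.95 + 12.55 + 18.5 - 8.1)  # 29.9
  expect_equal(rs_difference_index(srvot_med)$value,
               3.3 + 6.8 + 10.2 - 11.8)    # 8.5
  expect_identical(
    apply_criterion(rs_difference_index(lvot_med), crits$rs_difference),
    "LVOT-ASC")
  expect_identical(
    apply_criterion(rs_difference_index(srvot_med), crits$rs_difference),
    "s-RVOT")
  expect_equal(rs_difference_index(make_beat())$value, 0)
})

test_that("V2S/V3R index handles medians and degeneracies", {
  expect_equal(v2s_v3r_index(srvot_med)$value, 19 / 6.8)
  expect_equal(v2s_v3r_index(lvot_med)$value, 14 / 12.55)
  expect_identical(apply_criterion(v2s_v3r_index(srvot_med), crits$v2s_v3r),
                   "s-RVOT")
  expect_identical(apply_criterion(v2s_v3r_index(lvot_med), crits$v2s_v3r),
                   "LVOT-ASC")
  inf_case <- v2s_v3r_index(make_beat(V2 = c(0, 0, 5)))
  expect_identical(inf_case$value, Inf)
  expect_identical(apply_criterion(inf_case, crits$v2s_v3r), "s-RVOT")
  degen <- v2s_v3r_index(make_beat())
  expect_false(degen$computable)
  expect_identical(apply_criterion(degen, crits$v2s_v3r), "undetermined")
})

test_that("RV1-V3 transition ratio divides PVC by sinus R-wave sums", {
  sinus <- make_beat(V1 = c(0, 1, 6), V2 = c(0, 5, 10), V3 = c(0, 10, 5),
                     beat_type = "sinus")
  pvc_half <- make_beat(V1 = c(0, 2, 6), V2 = c(0, 3, 10), V3 = c(0, 3, 5))
  expect_equal(rv1v3_transition_ratio(pvc_half, sinus)$value, 8 / 16)
  pvc_same <- make_beat(V1 = c(0, 1, 6), V2 = c(0, 5, 10), V3 = c(0, 10, 5))
  expect_equal(rv1v3_transition_ratio(pvc_same, sinus)$value, 1.0)
  pvc_lvot <- make_beat(V1 = c(0, 1.8, 8.1), V2 = c(0, 6.95, 14),
                        V3 = c(0, 12.55, 2.75))
  expect_equal(rv1v3_transition_ratio(pvc_lvot, sinus)$value, 21.3 / 16)
  expect_identical(
    apply_criterion(rv1v3_transition_ratio(pvc_lvot, sinus),
                    crits$rv1v3_transition_ratio), "LVOT-ASC")
  expect_false(rv1v3_transition_ratio(pvc_lvot, NULL)$computable)
  flat_sinus <- make_beat(beat_type = "sinus")
  expect_false(rv1v3_transition_ratio(pvc_lvot, flat_sinus)$computable)
})

test_that("V2 transition ratio compares the V2 R/(R+S) fractions", {
  sinus <- make_beat(V2 = c(0, 5, 10), beat_type = "sinus")
  expect_equal(v2_transition_ratio(make_beat(V2 = c(0, 7, 14)),
                                   sinus)$value, 1.0)
  expect_equal(v2_transition_ratio(make_beat(V2 = c(0, 14, 0)),
                                   sinus)$value, 3.0)
  flat_sinus <- make_beat(beat_type = "sinus")
  expect_false(v2_transition_ratio(make_beat(V2 = c(0, 7, 14)),
                                   flat_sinus)$computable)
  no_r_sinus <- make_beat(V2 = c(0, 0, 10), beat_type = "sinus")
  expect_false(v2_transition_ratio(make_beat(V2 = c(0, 7, 14)),
                                   no_r_sinus)$computable)
})

test_that("(V1S+V2S)-(V1R+V2R) reproduces the group-median arithmetic", {
  expect_equal(s_minus_r_v1v2(srvot_med)$value, 11.8 + 19 - 1.2 - 3.3)
  expect_equal(s_minus_r_v1v2(lvot_med)$value, 8.1 + 14 - 1.8 - 6.95)
  expect_identical(
    apply_criterion(s_minus_r_v1v2(srvot_med), crits$s_minus_r_v1v2),
    "s-RVOT")
  expect_identical(
    apply_criterion(s_minus_r_v1v2(lvot_med), crits$s_minus_r_v1v2),
    "LVOT-ASC")
  expect_equal(s_minus_r_v1v2(make_beat())$value, 0)
})

test_that("transition lead follows the first-R/S>1 rule", {
  expect_identical(transition_lead(srvot_med), "V4")
  expect_identical(transition_lead(lvot_med), "V3")
  expect_identical(transition_lead(make_beat()), "none")
  # exact R/S = 1 does not transition; monophasic R does
  tie <- make_beat(V1 = c(0, 5, 5), V2 = c(0, 0, 8))
  expect_identical(transition_lead(tie), "none")
  mono <- make_beat(V1 = c(0, 5, 5), V4 = c(0, 3, 0))
  expect_identical(transition_lead(mono), "V4")
  # leads with R = S = 0 are skipped, not treated as transition
  skip_lead <- make_beat(V2 = c(0, 1, 5), V5 = c(0, 9, 2))
  expect_identical(transition_lead(skip_lead), "V5")
})

test_that("increasing an R amplitude never delays the transition", {
  set.seed(42)
  rank_of <- function(ld) match(ld, c(PRECORDIAL_LEADS, "none"))
  for (i in 1:50) {
    amps <- lapply(PRECORDIAL_LEADS,
                   function(ld) c(0, round(runif(2, 0, 10), 1)))
    names(amps) <- PRECORDIAL_LEADS
    b0 <- do.call(make_beat, amps)
    ld <- sample(PRECORDIAL_LEADS, 1)
    amps[[ld]][2] <- amps[[ld]][2] + runif(1, 0.1, 5)
    b1 <- do.call(make_beat, amps)
    expect_lte(rank_of(transition_lead(b1)), rank_of(transition_lead(b0)))
  }
})

test_that("index linearity and scale invariance hold", {
  set.seed(11)
  sinus <- make_beat(V1 = c(0, 1, 6), V2 = c(0, 5, 10), V3 = c(0, 10, 5),
                     beat_type = "sinus")
  for (i in 1:20) {
    amps <- lapply(PRECORDIAL_LEADS,
                   function(ld) c(0, round(runif(2, 0.1, 15), 2)))
    names(amps) <- PRECORDIAL_LEADS
    b <- do.call(make_beat, amps)
    cc <- runif(1, 0.5, 4)
    amps_c <- amps
    amps_c$V3[2] <- amps_c$V3[2] + cc
    expect_equal(rs_difference_index(do.call(make_beat, amps_c))$value,
                 rs_difference_index(b)$value + cc)
    amps_s <- amps
    amps_s$V1[3] <- amps_s$V1[3] + cc
    expect_equal(rs_difference_index(do.call(make_beat, amps_s))$value,
                 rs_difference_index(b)$value - cc)
    k <- runif(1, 0.25, 4)
    amps_k <- lapply(amps, function(v) v * k)
    bk <- do.call(make_beat, amps_k)
    expect_equal(rs_difference_index(bk)$value,
                 k * rs_difference_index(b)$value)
    expect_equal(s_minus_r_v1v2(bk)$value, k * s_minus_r_v1v2(b)$value)
    expect_equal(v2s_v3r_index(bk)$value, v2s_v3r_index(b)$value)
    expect_equal(v2_transition_ratio(bk, sinus)$value,
                 v2_transition_ratio(b, sinus)$value)
    expect_identical(transition_lead(bk), transition_lead(b))
  }
})

test_that("criterion boundaries follow the printed inequalities", {
  iv <- function(v) rs_difference_index(
    make_beat(V2 = c(0, v, 0), V3 = c(0, 0, 0), V4 = c(0, 0, 0)))
  expect_identical(apply_criterion(iv(20.9), crits$rs_difference), "s-RVOT")
  expect_identical(apply_criterion(iv(20.91), crits$rs_difference),
                   "LVOT-ASC")
  le <- v2s_v3r_index(make_beat(V2 = c(0, 0, 1.44), V3 = c(0, 1, 0)))
  expect_identical(apply_criterion(le, crits$v2s_v3r), "LVOT-ASC")
  expect_error(apply_criterion(le, crits$rs_difference), "mismatch")
})

test_that("compute_all_indices flags sinus-dependent indices", {
  sinus <- make_beat(V1 = c(0, 1, 6), V2 = c(0, 5, 10), V3 = c(0, 10, 5),
                     beat_type = "sinus")
  with_sinus <- patient_record("a", "s-RVOT", srvot_med, sinus)
  res <- compute_all_indices(with_sinus)
  expect_setequal(names(res), INDEX_NAMES)
  expect_true(all(vapply(res, `[[`, logical(1), "computable")))
  without <- patient_record("b", "s-RVOT", srvot_med)
  res2 <- compute_all_indices(without)
  expect_equal(sum(vapply(res2, `[[`, logical(1), "computable")), 3)
  expect_false(res2$rv1v3_transition_ratio$computable)
  expect_false(res2$v2_transition_ratio$computable)
})

test_that("cohort_indices preserves record order and attaches predictions", {
  coh <- small_cohort(5, 4)
  idx <- cohort_indices(coh)
  expect_equal(idx$patient_id,
               vapply(coh$records, `[[`, character(1), "patient_id"))
  expect_true(all(paste0("pred_", INDEX_NAMES) %in% names(idx)))
  expect_true(all(idx$transition_lead %in% c(PRECORDIAL_LEADS, "none")))
  expect_true(all(idx$pred_rs_difference %in% c("LVOT-ASC", "s-RVOT")))
})
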