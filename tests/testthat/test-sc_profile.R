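test_that("thickness conversion follows mass/(area * density)", {
  expect_equal(thickness_from_mass(0.49, 1, 1), 4.9)
  expect_equal(thickness_from_mass(0, 1, 1), 0)
  expect_equal(thickness_from_mass(2.45, 5, 1), 4.9)
  # density rescales inversely
  expect_equal(thickness_from_mass(0.49, 1, 1.4), 3.5)
  expect_error(thickness_from_mass(1, 0), "> 0")
  expect_error(thickness_from_mass(-1, 1), ">= 0")
})

test_that("group concentration = drug / SC mass, BLQ per policy", {
  sd_ <- make_strip_data(drug = c(100, 50, 25, NA),
                         blq = c(FALSE, FALSE, FALSE, TRUE),
                         sc_mass_mg = c(rep(0.025, 2), rep(0.1, 18)))
  g <- group_concentration(sd_$groups)
  expect_equal(g$conc_ng_mg[1], 100 / 0.05)  # 2000 ng/mg
  expect_equal(g$conc_ng_cm3[1], 2000 * 1000)
  expect_equal(g$conc_ng_mg[4], 0)           # BLQ -> 0 under default
  expect_true(g$censored[4])
  # half-loq policy: mass = loq/2 * V = 32 ng
  g2 <- group_concentration(sd_$groups, blq_policy = "half-loq")
  expect_equal(g2$conc_ng_mg[4] * sd_$groups$sc_mass_total_mg[4], 32)
})

test_that("site_Q sums groups over area with the BLQ policy", {
  sd_ <- make_strip_data(drug = c(200, 50, 25, NA))
  q <- site_Q(sd_$groups)
  expect_equal(q$q_ng_cm2, (200 + 50 + 25) / 5)  # 55 ng/cm^2
  expect_equal(q$censored_fraction, 0.25)

  # doubling the area at fixed masses halves Q
  sd2 <- make_strip_data(drug = c(200, 50, 25, NA), area = 10)
  expect_equal(site_Q(sd2$groups)$q_ng_cm2, 27.5)

  # all BLQ -> 0 with a warning
  sd3 <- make_strip_data(drug = rep(NA_real_, 4), blq = rep(TRUE, 4))
  expect_warning(q3 <- site_Q(sd3$groups), "all groups censored")
  expect_equal(q3$q_ng_cm2, 0)
  expect_equal(q3$censored_fraction, 1)
})

test_that("depth intervals tile the removed thickness; midpoints used", {
  sd_ <- make_strip_data()
  prof <- depth_profile(sd_)
  expect_equal(prof$depth_top_um[1], 0)
  expect_equal(prof$depth_top_um[-1], head(prof$depth_bottom_um, -1))
  expect_equal(max(prof$depth_bottom_um),
               thickness_from_mass(sum(sd_$strips$sc_mass_mg), 5))
  expect_equal(prof$depth_mid_um,
               (prof$depth_top_um + prof$depth_bottom_um) / 2)
  expect_equal(unique(prof$total_thickness_um), 4.9, tolerance = 1e-12)
})

test_that("noise-free synthetic site reproduces the slab averages", {
  p <- default_params()
  prof <- sctape:::sc_sim_profile(p, 4)
  set.seed(8)
  strips <- strip_site(prof, p, stopping_rule(), area = 5)$strips
  grp <- assay_groups(strips, c(2, 6, 6, 6), assay_config(),
                      cv_analytical = 0)
  sd_ <- structure(list(
    strips = data.frame(subject_id = "S01", site_id = "s",
                        strip_index = strips$strip_index,
                        sc_mass_mg = strips$sc_mass_mg, area_cm2 = 5,
                        group_id = grp$group_id[findInterval(
                          strips$strip_index, grp$strip_first)]),
    groups = as_site_groups(grp, site_id = "s")),
    class = "strip_data")
  dp <- depth_profile(sd_)
  for (i in which(!dp$censored)) {
    slab_avg <- sctape:::profile_Q(prof, dp$depth_top_um[i],
                                   dp$depth_bottom_um[i]) /
      ((dp$depth_bottom_um[i] - dp$depth_top_um[i]) * 1e-4)
    expect_lt(abs(dp$conc_ng_cm3[i] - slab_avg) / slab_avg, 0.01)
  }
})

test_that("Q is invariant to regrouping for uncensored data", {
  p <- default_params(partition_scale = 5e6)  # high load: nothing BLQ
  prof <- sctape:::sc_sim_profile(p, 4)
  set.seed(9)
  strips <- strip_site(prof, p, stopping_rule(), area = 5)$strips
  q_of <- function(grouping) {
    grp <- assay_groups(strips, grouping, assay_config(),
                        cv_analytical = 0)
    expect_false(any(grp$blq))
    site_Q(as_site_groups(grp))$q_ng_cm2
  }
  expect_equal(q_of(c(2, 6, 6, 6)), q_of(c(4, 4, 4, 4, 4)))
  expect_equal(q_of(c(2, 6, 6, 6)), q_of(rep(1, 20)))
})
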