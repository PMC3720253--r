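test_that("indexes recompute the published drainage rates from cohort means", {
  hc_sup <- collateral_flows(reference_flow_set("HC", "supine"))
  pt_sup <- collateral_flows(reference_flow_set("CCSVI", "supine"))
  hc_up <- collateral_flows(reference_flow_set("HC", "upright"))

  expect_equal(compute_djvdi(hc_sup$cvo, hc_sup$hbinf), 44.4, tolerance = 0.01)
  expect_equal(compute_ccdi(hc_sup$q_cd, hc_sup$cbf), 33.4, tolerance = 0.01)
  expect_equal(compute_cfi(pt_sup$q_cp, pt_sup$hbinf), 60.5, tolerance = 0.01)
  # upright controls: about 40% of CBF drains through collaterals
  expect_equal(hc_up$cvo, 382.51)
  expect_equal(compute_ccdi(638 - 382.51, 638), 40.0, tolerance = 0.05)
})

test_that("index edge cases follow their definitions", {
  expect_equal(compute_djvdi(0, 900), 0)
  expect_equal(compute_djvdi(900, 900), 100)
  expect_equal(compute_cfi(0, 900), 0)
  expect_equal(compute_cfi(900, 900), 100)
  expect_equal(compute_ccdi(0, 638), 0)
  expect_error(compute_djvdi(100, 0), "hbinf")
})

test_that("cfi complements the normalized outflow exactly", {
  set.seed(31)
  for (i in 1:50) {
    sol <- collateral_flows(random_flows(sprintf("c%02d", i)))
    cfi <- compute_cfi(sol$q_cp, sol$hbinf)
    expect_equal(cfi + 100 * sol$hboutf / sol$hbinf, 100, tolerance = 1e-9)
    # cross-identity: CVO = HBinF * DJVDI/100 = CBF * (1 - CCDI/100)
    djvdi <- compute_djvdi(sol$cvo, sol$hbinf)
    ccdi <- compute_ccdi(sol$q_cd, sol$cbf)
    expect_equal(sol$hbinf * djvdi / 100, sol$cvo, tolerance = 1e-9)
    expect_equal(sol$cbf * (1 - ccdi / 100), sol$cvo, tolerance = 1e-9)
  }
})

test_that("indexes are invariant under rescaling every flow", {
  f <- random_flows("scale")
  g <- f; g$q <- g$q * 3.7
  a <- collateral_flows(f); b <- collateral_flows(g)
  expect_equal(compute_cfi(b$q_cp, b$hbinf), compute_cfi(a$q_cp, a$hbinf),
               tolerance = 1e-9)
  expect_equal(compute_djvdi(b$cvo, b$hbinf), compute_djvdi(a$cvo, a$hbinf),
               tolerance = 1e-9)
  expect_equal(compute_ccdi(b$q_cd, b$cbf), compute_ccdi(a$q_cd, a$cbf),
               tolerance = 1e-9)
})

test_that("dcvo measures the postural outflow shift and is antisymmetric", {
  sup <- collateral_flows(make_flows(posture = "supine"))
  expect_equal(compute_dcvo(sup, sup), 0)
  # supine fraction 1.0, upright fraction 0.9 -> 10 points
  a <- sup; a$hboutf <- a$hbinf
  b <- sup; b$hboutf <- 0.9 * b$hbinf
  expect_equal(compute_dcvo(a, b), 10, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    x <- collateral_flows(random_flows("x"))
    y <- collateral_flows(random_flows("y"))
    expect_equal(compute_dcvo(x, y), -compute_dcvo(y, x), tolerance = 1e-9)
  }
})

test_that("a missing posture leaves dcvo undefined, not zero", {
  sols <- list(supine = collateral_flows(make_flows(posture = "supine")))
  idx <- subject_indexes(sols)
  expect_true(is.na(idx$dcvo))
  expect_false(is.na(idx$cfi))
})

test_that("per-subject and aggregate index paths are both available and labelled", {
  set.seed(51)
  rows <- dplyr::bind_rows(lapply(1:4, function(i)
    dplyr::bind_rows(random_flows(sprintf("s%d", i)),
                     {
                       u <- random_flows(sprintf("s%d", i))
                       u$posture <- "upright"
                       u
                     })))
  co <- cohort_table(rows)
  per <- cohort_indexes(co)
  agg <- aggregate_indexes(co)
  expect_equal(attr(per, "computation_path"), "per_subject")
  expect_equal(attr(agg, "computation_path"), "aggregate")
  expect_equal(nrow(per), 8)  # 4 subjects x 2 postures
  expect_equal(nrow(agg), 2)
  # aggregate path equals per-subject path applied to the mean flows
  mean_cfi_from_means <- agg$cfi[agg$posture == "supine"]
  mf <- rows |> dplyr::filter(posture == "supine") |>
    dplyr::group_by(vessel, side, segment) |>
    dplyr::summarise(q = mean(q), .groups = "drop")
  sol <- collateral_flows(subject_flow_set("m", "HC", "supine", mf$vessel,
                                           mf$side, mf$segment, mf$q))
  expect_equal(mean_cfi_from_means, compute_cfi(sol$q_cp, sol$hbinf),
               tolerance = 1e-9)
})

test_that("upright denominator can fall back to the supine inflow", {
  sup <- make_flows(posture = "supine")
  up <- make_flows(posture = "upright",
                   q = c(CCA_right_none = 500, CCA_left_none = 500))
  sols <- list(supine = collateral_flows(sup),
               upright = collateral_flows(up))
  matched <- subject_indexes(sols, denominator = "matched")
  fallback <- subject_indexes(sols, denominator = "supine")
  up_m <- matched[matched$posture == "upright", ]
  up_f <- fallback[fallback$posture == "upright", ]
  expect_false(up_m$hbinf_used == up_f$hbinf_used)
  expect_equal(up_f$hbinf_used, sols$supine$hbinf)
})
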