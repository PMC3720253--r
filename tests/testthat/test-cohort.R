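test_that("cohort summaries use sample sd and flag single-subject strata", {
  f1 <- make_flows("a"); f2 <- make_flows("b")
  f1$q[f1$site == "IJV_right_J1"] <- 100
  f2$q[f2$site == "IJV_right_J1"] <- 300
  co <- cohort_table(dplyr::bind_rows(f1, f2))
  s <- summarize_cohort(co)
  row <- s[s$site == "IJV_right_J1", ]
  expect_equal(row$n, 2L)
  expect_equal(row$mean_q, 200)
  expect_equal(row$sd_q, sd(c(100, 300)))
  expect_equal(row$sd_q, 141.42, tolerance = 1e-4)

  single <- summarize_cohort(cohort_table(make_flows("solo")))
  expect_true(all(single$single_subject))
  expect_true(all(single$sd_q == 0))
})

test_that("summaries recover generating moments on a seeded synthetic cohort", {
  sim <- generate_cohort(synthetic_phenotype("HC"), 12, seed = 303,
                         posture = "supine")
  co <- cohort_table(compute_flow(sim$measurements))
  s <- summarize_cohort(co)
  # cohort-mean HBinF-scale site: right J3 truth mean from the phenotype
  tr <- sim$truth |> dplyr::group_by(site) |> dplyr::summarise(q = mean(q))
  for (k in c("IJV_right_J3", "VV_left_C45", "CCA_right_none")) {
    est <- s$mean_q[s$site == k]
    truth <- tr$q[tr$site == k]
    se <- s$sd_q[s$site == k] / sqrt(12)
    expect_lt(abs(est - truth), max(3 * se, 0.15 * truth))
  }
})

test_that("mann-whitney handles degeneracy, separation and symmetry", {
  d <- mann_whitney_u(rep(5, 4), rep(5, 6))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)

  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_exact, 0.1)   # 2 / choose(6, 3)
  expect_equal(r$method, "exact")

  set.seed(61)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    ab <- mann_whitney_u(a, b); ba <- mann_whitney_u(b, a)
    expect_equal(ab$u, length(a) * length(b) - ba$u)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when ties are absent", {
  set.seed(71)
  for (i in 1:15) {
    a <- rnorm(6); b <- rnorm(7, mean = runif(1, -1, 1))
    mine <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = TRUE)
    expect_equal(mine$p_exact, ref$p.value, tolerance = 1e-10)
    refa <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_approx, refa$p.value, tolerance = 1e-10)
  }
})

test_that("exact and approximate p agree for untied 10-vs-10 samples", {
  set.seed(81)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10, mean = runif(1, -0.5, 0.5))
    r <- mann_whitney_u(a, b)
    expect_lt(abs(r$p_exact - r$p_approx), 0.02)
  }
})

test_that("comparing a cohort against itself yields p = 1 everywhere", {
  set.seed(91)
  rows <- dplyr::bind_rows(lapply(1:5, function(i)
    random_flows(sprintf("s%d", i))))
  co <- cohort_table(rows)
  cmp <- compare_cohorts(co, co)
  expect_gt(nrow(cmp), 10)
  expect_true(all(cmp$p_value == 1))
  expect_true(all(!cmp$significant))
})

test_that("missing quantities drop subjects with reported n", {
  set.seed(101)
  a <- cohort_table(dplyr::bind_rows(lapply(1:4, function(i)
    random_flows(sprintf("a%d", i)))))
  rows_b <- dplyr::bind_rows(lapply(1:4, function(i)
    random_flows(sprintf("b%d", i))))
  # subject b4 lacks the VV sites entirely: per-site VV comparison loses it
  rows_b <- rows_b[!(rows_b$subject_id == "b4" & rows_b$vessel == "VV"), ]
  b <- cohort_table(rows_b)
  cmp <- compare_cohorts(a, b, quantities = "Q_VV_right_C45")
  expect_equal(cmp$n_b, 3L)
  expect_equal(cmp$n_a, 4L)
})

test_that("reports render deterministically and the CSV re-parses", {
  f1 <- make_flows("a"); f2 <- make_flows("b")
  co <- cohort_table(dplyr::bind_rows(f1, f2))
  s <- summarize_cohort(co)
  cmp <- compare_cohorts(co, co, quantities = c("CFI", "HBinF"))
  dir <- withr::local_tempdir()
  l1 <- render_tables(s, cmp, dir = dir)
  expect_true(file.exists(file.path(dir, "report.txt")))
  back <- readr::read_csv(file.path(dir, "summary.csv"),
                          show_col_types = FALSE)
  expect_equal(dplyr::arrange(back, site)$mean_q,
               dplyr::arrange(s, site)$mean_q)
  # byte-identical re-render
  dir2 <- withr::local_tempdir()
  render_tables(s, cmp, dir = dir2)
  expect_identical(readLines(file.path(dir, "report.txt")),
                   readLines(file.path(dir2, "report.txt")))
  # header-only on empty input
  empty <- render_tables(s[0, ])
  expect_length(empty, 1)
})
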