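# Reference study replication and its structural properties.

test_that("the reference grid carries the four neonates and three courses", {
  grid <- build_reference_grid()
  expect_length(grid$profiles, 4L)
  expect_length(grid$periods, 3L)
  expect_equal(vapply(grid$profiles, `[[`, numeric(1), "gestational_age"),
               c(24, 27, 29, 32))
  expect_equal(vapply(grid$profiles, `[[`, numeric(1), "birth_weight"),
               c(621, 779, 840, 889))
  expect_equal(vapply(grid$profiles, `[[`, numeric(1),
                      "initial_creatinine"),
               c(0.383, 0.462, 0.518, 0.607))
  expect_equal(vapply(grid$periods, `[[`, integer(1), "start_day"),
               c(1L, 15L, 29L))
  expect_equal(grid$horizon, 42)
})

test_that("study tables satisfy the structural invariants", {
  tabs <- run_study(default_calibration())
  t1 <- tabs$table1
  t2 <- tabs$table2_unrounded
  expect_equal(nrow(t1), 12L)
  expect_equal(nrow(t2), 24L)

  # before-values are arm-invariant within each GA x period cell
  for (ga in c(24, 27, 29, 32)) {
    for (p in 1:3) {
      cell <- t2[t2$ga_weeks == ga & t2$period == p, ]
      expect_equal(cell$before_mg_dl[1], cell$before_mg_dl[2])
    }
  }

  # differences shrink along periods for every GA, and with GA in period 1
  for (ga in c(24, 27, 29, 32)) {
    d <- t1$difference_unrounded[t1$ga_weeks == ga][order(
      t1$period[t1$ga_weeks == ga])]
    expect_true(all(diff(d) < 0))
  }
  p1 <- t1$difference_unrounded[t1$period == 1][order(
    t1$ga_weeks[t1$period == 1])]
  expect_true(all(diff(p1) < 0))

  # rounded differences equal round(unrounded, 3)
  expect_equal(t1$difference_mg_dl, round(t1$difference_unrounded, 3))
})

test_that("figure trajectories obey exposure dominance and clearance
           geometry", {
  tabs <- run_study(default_calibration())
  f1 <- tabs$fig1_data
  f2 <- tabs$fig2_data
  windows <- list(`1` = c(0, 3), `2` = c(14, 17), `3` = c(28, 31))
  for (ga in c(24, 32)) {
    ctrl_c <- f1[f1$ga_weeks == ga & f1$arm == "no_ibuprofen", ]
    ctrl_cl <- f2[f2$ga_weeks == ga & f2$arm == "no_ibuprofen", ]
    # unexposed clearance is non-decreasing
    expect_true(all(diff(ctrl_cl$clearance_l_day) >= -1e-12))
    for (p in 1:3) {
      w <- windows[[as.character(p)]]
      ibu_c <- f1[f1$ga_weeks == ga & f1$arm == "ibuprofen" &
                    f1$period == p, ]
      ibu_cl <- f2[f2$ga_weeks == ga & f2$arm == "ibuprofen" &
                     f2$period == p, ]
      post <- ibu_c$time_day >= w[1]
      expect_true(all(ibu_c$concentration_mg_dl[post] >=
                        ctrl_c$concentration_mg_dl[post] - 1e-12))
      pre <- ibu_c$time_day < w[1]
      expect_equal(ibu_c$concentration_mg_dl[pre],
                   ctrl_c$concentration_mg_dl[pre])
      # inside the window the exposed clearance is the unexposed one
      # minus the constant absolute reduction
      inside <- ibu_cl$time_day >= w[1] & ibu_cl$time_day <= w[2]
      expect_equal(ibu_cl$clearance_l_day[inside],
                   ctrl_cl$clearance_l_day[inside] - 0.013536)
      expect_equal(ibu_cl$clearance_l_day[!inside],
                   ctrl_cl$clearance_l_day[!inside])
    }
  }
})

test_that("proportional reduction is -5.08% at birth and shrinks with
           postnatal age", {
  p <- fixture_params()
  expect_equal(proportional_reduction(0, p), -100 * 0.013536 / 0.26625)
  expect_equal(round(proportional_reduction(0, p), 2), -5.08)
  t <- seq(0, 42, by = 1)
  pr <- proportional_reduction(t, p)
  expect_true(all(diff(abs(pr)) < 0))
  p0 <- fixture_params(emax = 0)
  expect_equal(proportional_reduction(c(0, 10, 30), p0),
               rep(-100 * 0.013536 / 0.26625, 3))
})
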