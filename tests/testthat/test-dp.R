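test_that("terminal fitness is linear through the origin", {
  expect_equal(terminal_fitness(0), 0)
  expect_equal(terminal_fitness(50, 50), 1)
  expect_equal(terminal_fitness(25, 50), 0.5)
  expect_error(terminal_fitness(-1), "outside")
})

test_that("terminal column of the DP table is the terminal fitness", {
  pol <- backward_iterate(dsv_config())
  expect_identical(unname(pol$F[, 51]), (0:50) / 50)
})

test_that("frozen-dynamics DP reproduces the closed-form surface", {
  for (m in all_presets()) {
    cfg <- dsv_config(mortality = m, frozen_dynamics = TRUE)
    dp <- phi_surface(backward_iterate(cfg))$matrix
    oracle <- isolated_effects_surface(m, 50)$matrix
    expect_lt(max(abs(dp - oracle)), 1e-12)
  }
})

test_that("fitness stays in [0, 1] and decays with time to reproduction", {
  for (u in c(0, -0.1)) {
    pol <- backward_iterate(dsv_config(u = u))
    expect_true(all(pol$F >= 0 & pol$F <= 1))
    # F(y, t) <= F(y, t + 1): each extra step to survive can only cost
    expect_true(all(diff(t(pol$F)) >= -1e-15))
  }
})

test_that("zero state is an absorbing death state under combined mortality", {
  pol <- backward_iterate(dsv_config())
  expect_equal(unname(pol$F["0", 1:50]), rep(0, 50))
})

test_that("backward iteration is deterministic", {
  a <- backward_iterate(dsv_config(u = -0.1))
  b <- backward_iterate(dsv_config(u = -0.1))
  expect_identical(a$F, b$F)
  expect_identical(a$q_star, b$q_star)
})

test_that("brute-force policy enumeration matches the DP on a small grid", {
  # independent oracle: evaluate every state- and time-dependent policy
  # q(y, t) on a 5-state, 2-step horizon and take the best; the DP value
  # must equal the best achievable policy value at every starting state
  cfg <- dsv_config(y_min = 0L, y_max = 4L, T_steps = 2L,
                    q_levels = 0:1, u = 0,
                    mortality = mortality_model("constant", intercept = 0.1,
                                                y_min = 0L, y_max = 4L))
  pol <- backward_iterate(cfg)
  kernels <- lapply(0:1, function(q)
    unpred_kernel(q, y_min = 0L, y_max = 4L)$matrix)
  phi0 <- (0:4) / 4
  # a policy is a 5 x 2 table of levels; evaluate it by plain forward
  # expectation, stepping the value function with the prescribed kernel row
  policy_value <- function(qtab) {
    v <- phi0
    for (t in 2:1) {
      v <- vapply(1:5, function(i)
        0.9 * sum(kernels[[qtab[i, t] + 1L]][i, ] * v), numeric(1))
    }
    v
  }
  cells <- expand.grid(rep(list(0:1), 10L))
  best <- rep(-Inf, 5)
  for (r in seq_len(nrow(cells))) {
    qtab <- matrix(as.integer(cells[r, ]), 5L, 2L)
    best <- pmax(best, policy_value(qtab))
  }
  expect_equal(unname(pol$F[, 1L]), best, tolerance = 1e-14)
})

test_that("optimal unpredictability is high at state extremes, zero between", {
  pol <- backward_iterate(dsv_config(u = 0))
  pt <- policy_table(pol)
  q50 <- pt$q_star[pt$tau == 50][-1]      # drop the masked y = 0 row
  y <- (0:50)[-1]
  zero_band <- y[q50 == 0]
  expect_gt(length(zero_band), 0)
  # the q* = 0 region is one contiguous interior band
  expect_true(all(diff(zero_band) == 1))
  expect_true(any(q50[y < min(zero_band)] > 0))
  expect_true(any(q50[y > max(zero_band)] > 0))
})

test_that("a negative expectation effect expands the selected region at high states", {
  pol0 <- backward_iterate(dsv_config(u = 0))
  polm <- backward_iterate(dsv_config(u = -0.1))
  upper <- as.character(26:50)
  n0 <- sum(pol0$q_star[upper, 1L] > 0)
  nm <- sum(polm$q_star[upper, 1L] > 0)
  expect_gte(nm, n0)
})

test_that("ties in expected fitness break toward the smallest level", {
  # with zero mortality and a flat terminal fitness every level ties
  cfg <- dsv_config(y_min = 0L, y_max = 10L, T_steps = 3L,
                    mortality = mortality_model("constant", intercept = 0,
                                                y_min = 0L, y_max = 10L),
                    terminal = function(y, y_max) rep(0.5, length(y)))
  pol <- backward_iterate(cfg)
  expect_true(all(pol$q_star == 0L))
})

test_that("adding a candidate level never lowers expected fitness", {
  for (lv in list(0L, 0:1, 0:2)) {
    sub <- backward_iterate(small_config(q_levels = lv))
    full <- backward_iterate(small_config(q_levels = 0:3))
    expect_true(all(full$F - sub$F >= -1e-15))
  }
})

test_that("phi surface re-indexes time as steps to reproduction", {
  pol <- backward_iterate(dsv_config())
  ps <- phi_surface(pol)
  expect_equal(ps$matrix[, "0"], pol$F[, 51], ignore_attr = TRUE)
  expect_equal(ps$matrix[, "50"], pol$F[, 1], ignore_attr = TRUE)
  expect_equal(nrow(ps$phi), 51 * 51)
  expect_true(all(ps$phi$tau + ps$phi$t == 51))
  row <- ps$phi[ps$phi$tau == 3 & ps$phi$y == 20, ]
  expect_equal(row$phi, unname(pol$F["20", 48]))
})

test_that("policy table masks reproduction time and the death state", {
  pt <- policy_table(backward_iterate(dsv_config()))
  expect_false(0 %in% pt$tau)
  expect_true(all(is.na(pt$q_star[pt$y == 0])))
  expect_true(all(!is.na(pt$q_star[pt$y > 0])))
})

test_that("curvature profile classifies second differences", {
  expect_true(all(curvature_profile((0:50) / 50) == "linear"))
  expect_true(all(curvature_profile(0.95^10 * (0:50) / 50) == "linear"))
  expect_true(all(curvature_profile(((0:10) / 10)^2) == "convex"))
  expect_true(all(curvature_profile(sqrt((0:10) / 10)) == "concave"))
  expect_error(curvature_profile(c(1, 2)), "length >= 3")
  # frozen increasing-linear mortality at large tau: curvature of both signs
  phi <- closed_form_phi(mortality_preset("increasing"), 0:50, 50)
  cls <- curvature_profile(phi)
  expect_true("convex" %in% cls && "concave" %in% cls)
})

test_that("full-size default run completes quickly", {
  elapsed <- system.time(backward_iterate(dsv_config()))[["elapsed"]]
  expect_lt(elapsed, 1)
})
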