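test_that("assembly_fractions matches exhaustive enumeration and sums to 1", {
  for (f in seq(0, 1, by = 0.05)) {
    expect_lt(max(abs(assembly_fractions(f) - enum_assembly_fractions(f))),
              1e-12)
    expect_equal(sum(assembly_fractions(f)), 1)
  }
  expect_identical(assembly_fractions(0), c(1, 0, 0, 0, 0))
  expect_identical(assembly_fractions(1), c(0, 0, 0, 0, 1))
  expect_equal(assembly_fractions(0.5),
               c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  expect_error(assembly_fractions(-0.1), "0, 1")
  expect_error(assembly_fractions(1.2), "0, 1")
})

test_that("expected On-Cell signal reproduces enumerated worked examples", {
  p <- assembly_params(f_var = 0.5, t = c(1, 1, 0, 0, 0))
  expect_equal(expected_oncell_signal(p, "WT"), 1.0)
  expect_equal(expected_oncell_signal(p, "var"), 0.25)
  # all-permissive control: 4 * (1 - f_var) tagged WT subunits
  ctrl <- assembly_params(f_var = 0.5, t = rep(1, 5))
  expect_equal(expected_oncell_signal(ctrl, "WT"), 2.0)
  expect_equal(expected_oncell_signal(p, "WT") /
                 expected_oncell_signal(ctrl, "WT"), 0.5)
  # homozygous WT maximum
  wt <- assembly_params(f_var = 0, t = c(1, 0, 0, 0, 0))
  expect_equal(expected_oncell_signal(wt, "WT"), 4.0)
  # background-only condition
  expect_equal(expected_oncell_signal(p, character()), 0)
  expect_error(expected_oncell_signal(p, "HA"), "subset")
})

test_that("signal agrees with the enumeration oracle on random parameters", {
  set.seed(42)
  for (i in 1:50) {
    f <- runif(1)
    t <- runif(5)
    cap <- if (i %% 2) Inf else runif(1, 0.5, 6)
    tau_w <- runif(1)
    tau_v <- runif(1)
    p <- assembly_params(f_var = f, t = t, capacity = cap)
    expect_equal(hergtraffick:::oncell_signal(p, tau_w, tau_v),
                 enum_oncell(f, t, tau_w, tau_v, cap), tolerance = 1e-12)
  }
})

test_that("signal is monotone in every t_k and in drug_boost", {
  set.seed(7)
  for (i in 1:20) {
    f <- runif(1)
    t <- runif(5, 0, 0.8)
    base <- expected_oncell_signal(assembly_params(f_var = f, t = t))
    for (k in 1:5) {
      t2 <- t
      t2[k] <- t2[k] + 0.2
      expect_gte(expected_oncell_signal(assembly_params(f_var = f, t = t2)),
                 base - 1e-15)
    }
    boosted <- apply_drug(assembly_params(f_var = f, t = t, drug_boost = 1.5))
    expect_gte(expected_oncell_signal(boosted), base - 1e-15)
  }
})

test_that("with capacity off and all t_k = 1 the signal is linear in tag share", {
  for (f in c(0, 0.25, 0.5, 0.9)) {
    p <- assembly_params(f_var = f, t = rep(1, 5))
    # tagging only WT: signal = 4 * (1 - f); only variant: 4 * f
    expect_equal(expected_oncell_signal(p, "WT"), 4 * (1 - f))
    expect_equal(expected_oncell_signal(p, "var"), 4 * f)
    expect_equal(expected_oncell_signal(p, c("WT", "var")), 4)
  }
})

test_that("hyperbolic capacity compresses the total surface signal", {
  p_inf <- assembly_params(f_var = 0, t = c(1, 0, 0, 0, 0))
  p_cap <- assembly_params(f_var = 0, t = c(1, 0, 0, 0, 0), capacity = 4)
  expect_equal(expected_oncell_signal(p_inf, "WT"), 4)
  expect_equal(expected_oncell_signal(p_cap, "WT"), 4 * 4 / (4 + 4))
})

test_that("drug boost is clipped at 1 and parameters are validated", {
  p <- apply_drug(assembly_params(f_var = 0, t = c(0.8, 0.2, 0, 0, 0),
                                  drug_boost = 3))
  expect_equal(p$t[1:2], c(1, 0.6))
  expect_error(assembly_params(t = c(1, 1, 0, 0)), "5 trafficking")
  expect_error(assembly_params(t = c(1, 1, 0, 0, 1.2)), "0, 1")
  expect_error(assembly_params(drug_boost = 0), "positive")
  expect_error(assembly_params(f_var = 2), "0, 1")
  expect_error(noise_params(), "seed")
  expect_error(noise_params(seed = 1, cv_expression = -1), ">= 0")
})
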