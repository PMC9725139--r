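test_that("lg3_profile reduces to the autoregulation gain without decoys", {
  # D = 0, Ct = 0 and the grid below Cp: LG_A = LG_B = 1, so LG3 = LG_F
  p <- tcs_params(f = 12, h = 2, Rb = 1, D = 0, K = 1, Cp = 500, Ct = 0)
  grid <- logspace(0.1, 100, 60)
  pr <- lg3_profile(p, grid)
  expect_equal(pr$LG3, lg_F(pr$Rf, 12, 2), tolerance = 1e-12)
  expect_equal(pr$LG_A, rep(1, 60))
  expect_equal(pr$LG_B, rep(1, 60))
})

test_that("without decoys the profile max respects the analytic LG_F bound", {
  p <- tcs_params(f = 5, h = 2, Rb = 1, D = 0, Cp = 50, Ct = 3)
  pr <- lg3_profile(p, logspace(0.01, 100, 200))
  bound <- max_lg_F(5, 2)$value  # 2(sqrt(5)-1)/(sqrt(5)+1) ~ 0.7639
  expect_lte(attr(pr, "max_LG3"), bound + 1e-9)
  expect_lt(bound, 1)
})

test_that("LG3 equals the product of module gains and the composite slope", {
  p <- params_decoy_ref()
  grid <- logspace(0.2, 50, 40)
  pr <- lg3_profile(p, grid)
  expect_equal(pr$LG3, pr$LG_A * pr$LG_B * pr$LG_F, tolerance = 1e-10)
  expect_true(all(pr$Rf <= pr$RP + 1e-12 & pr$RP <= pr$RT + 1e-12))
  fd <- fd_log_gain(function(x) composite_map(x, p)$production, grid)
  expect_equal(pr$LG3, fd, tolerance = 1e-5)
})

test_that("steady states: no feedback gives the single basal fixed point", {
  p <- tcs_params(f = 1, h = 2, Rb = 3.2, D = 1, K = 1, Cp = 10, Ct = 1)
  ss <- steady_states(p)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$RT, 3.2, tolerance = 1e-9)
  expect_identical(ss$stability, "stable")
})

test_that("the reference decoy-competition set is bistable at high Cp", {
  p <- params_decoy_ref(K = 0.5)
  ss <- steady_states(p, Cp = 60)
  expect_equal(nrow(ss), 3)
  expect_identical(ss$stability, c("stable", "unstable", "stable"))
  expect_equal(count_fixed_points(p, Cp = 60), 3)  # independent scan
  # weakening the competition removes bistability at every capacity
  p2 <- params_decoy_ref(K = 2)
  for (cp in c(10, 60, 200)) {
    expect_equal(nrow(steady_states(p2, Cp = cp)), 1)
    expect_equal(count_fixed_points(p2, Cp = cp), 1)
  }
})

test_that("fixed points satisfy the map and stability matches LG3", {
  p <- params_decoy_ref()
  ss <- steady_states(p, Cp = 60)
  expect_lt(max(abs(ss$production - ss$RT) / pmax(1, ss$RT)), 1e-8)
  expect_true(all((ss$stability == "unstable") == (ss$LG3 > 1)))
})

test_that("stability labels agree with perturbed forward integration", {
  set.seed(17)
  cases <- list(params_decoy_ref(), params_decoy_ref(K = 2),
                tcs_params(f = 30, h = 2, Rb = 0.3, D = 0, Cp = 50, Ct = 1))
  n_checked <- 0
  for (p in cases) {
    ss <- steady_states(p)
    for (k in seq_len(nrow(ss))) {
      for (dir in c(-1, 1)) {
        rt0 <- ss$RT[k] * (1 + dir * 0.03)
        tr <- simulate_rt(rt0, p, tau_end = 60, dt = 0.02)
        final <- tail(tr$RT, 1)
        if (ss$stability[k] == "stable") {
          expect_lt(abs(final - ss$RT[k]), 1e-4 * max(1, ss$RT[k]))
        } else {
          expect_gt(abs(final - ss$RT[k]), 0.05 * ss$RT[k])
        }
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 10)
})

test_that("dose_response: monostable sweep has empty interval, monotone output", {
  p <- params_decoy_ref(K = 2)
  dr <- dose_response(p, logspace(2, 100, 12), n_scan = 800)
  expect_null(dr$bistable_interval)
  occ <- dr$states$occupancy[order(dr$states$Cp)]
  expect_true(all(diff(occ) > -1e-9))
})

test_that("dose_response finds the bistable interval and hysteresis", {
  p <- params_decoy_ref(K = 0.5)
  dr <- dose_response(p, logspace(5, 200, 14), n_scan = 800)
  expect_false(is.null(dr$bistable_interval))
  inside <- unique(dr$states$Cp[ave(dr$states$Cp, dr$states$Cp,
                                    FUN = length) == 3])
  expect_gt(length(inside), 0)
  st <- dr$states[dr$states$Cp == inside[1] &
                    dr$states$stability == "stable", ]
  expect_equal(nrow(st), 2)
  expect_gt(abs(diff(st$occupancy)), 0.02)  # branches respond differently
  # counts change only by +/-2 across folds: states per Cp in {1, 3}
  counts <- table(dr$states$Cp)
  expect_true(all(counts %in% c(1, 3)))
  # necessary condition: bistable => max LG3 > 1
  cp_mid <- sqrt(prod(dr$bistable_interval))
  p_mid <- p; p_mid$Cp <- cp_mid
  expect_gt(attr(lg3_profile(p_mid, logspace(0.1, 100, 150)), "max_LG3"), 1)
})

test_that("transcriptional CNF never enlarges the bistable interval", {
  p <- params_decoy_ref(K = 0.5)
  cp_grid <- logspace(5, 200, 12)
  base <- dose_response(p, cp_grid, n_scan = 800)
  len <- function(dr) if (is.null(dr$bistable_interval)) 0
    else diff(dr$bistable_interval)
  for (f_N in c(0.6, 0.2)) {
    nf <- nf_params("transcriptional", f_N = f_N, K_N = 1, h_N = 2)
    cnf <- dose_response(p, cp_grid, nf = nf, n_scan = 800)
    expect_lte(len(cnf), len(base) + 1e-9)
  }
})

test_that("capacity-inhibition CNF composes self-consistently", {
  p <- params_decoy_ref(K = 0.5)
  nf <- nf_params("capacity", K_I = 2, h_I = 2)
  cm <- composite_map(c(1, 5, 20), p, nf = nf)
  # reported Rf satisfies the inner fixed point with the inhibited capacity
  cp_eff <- p$Cp / (1 + (cm$Rf / 2)^2)
  expect_equal(forward_RP(cm$Rf, p$D, p$K, p$l),
               mapply(function(rt, ce) rp_approx(rt, ce, p$Ct),
                      cm$RT, cp_eff),
               tolerance = 1e-9)
  # inhibition lowers phosphorylation relative to the plain map
  plain <- composite_map(c(1, 5, 20), p)
  expect_true(all(cm$RP < plain$RP))
})

test_that("raising decoy amount converts monostable to bistable", {
  cp_grid <- logspace(5, 200, 10)
  n_multi <- function(D) {
    p <- tcs_params(f = 5, h = 2, Rb = 2.5, D = D, K = 0.5, Cp = 60, Ct = 3)
    dr <- dose_response(p, cp_grid, n_scan = 600)
    !is.null(dr$bistable_interval)
  }
  expect_false(n_multi(0))
  expect_true(n_multi(4))
  # more decoys demand higher capacity: the Cp where max LG3 first
  # exceeds 1 increases with D
  cp_needed <- function(D) {
    p <- tcs_params(f = 5, h = 2, Rb = 2.5, D = D, K = 0.5, Cp = 1, Ct = 3)
    grid <- logspace(0.1, 100, 120)
    for (cp in logspace(1, 500, 40)) {
      p$Cp <- cp
      if (attr(lg3_profile(p, grid), "max_LG3") > 1) return(cp)
    }
    Inf
  }
  expect_gt(cp_needed(8), cp_needed(2))
})
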