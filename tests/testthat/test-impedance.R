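noise_free <- kinetic_params(noise_sd = 0)
grid <- seq(0, 48, 0.5)

test_that("normalization anchors the trace at 1 and is idempotent", {
  tr <- simulate_impedance_trace(5, times = grid, kp = kinetic_params(),
                                 seed = 3)
  nm <- preprocess_trace(tr, t_ref = 0)
  expect_equal(nm$cell_index[nm$time_h == 0], 1.0)
  expect_equal(nm$state, "normalized")
  again <- preprocess_trace(nm, t_ref = 0)
  expect_equal(again$cell_index, nm$cell_index)
  expect_error(preprocess_trace(
    impedance_trace(grid, rep(-1, length(grid))), 0), "<= 0")
})

test_that("a baseline replicate subtracted against itself is identically zero", {
  tr <- simulate_impedance_trace(0, times = grid, kp = noise_free)
  out <- preprocess_trace(tr, 0, baseline = tr)
  expect_equal(out$cell_index, rep(0, length(grid)))
  expect_equal(out$state, "baseline_subtracted")
})

test_that("noiseless baseline-subtracted readout equals the pulse model", {
  for (dose in c(0.1, 0.5, 2, 5)) {
    tr <- simulate_impedance_trace(dose, times = grid, kp = noise_free)
    base <- simulate_impedance_trace(0, times = grid, kp = noise_free)
    bs <- preprocess_trace(tr, 0, base)
    expect_equal(trace_response(bs, 20),
                 impedance_amplitude(dose, noise_free) *
                   impedance_pulse(20, noise_free),
                 tolerance = 1e-9)
  }
})

test_that("the 20 h response is strictly increasing in TGF dose (no noise)", {
  doses <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 5)
  resp <- vapply(doses, function(d) {
    tr <- simulate_impedance_trace(d, times = grid, kp = noise_free)
    base <- simulate_impedance_trace(0, times = grid, kp = noise_free)
    trace_response(preprocess_trace(tr, 0, base), 20)
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
  ## zero dose, no compound: flat raw trace at the baseline cell index
  flat <- simulate_impedance_trace(0, times = grid, kp = noise_free)
  expect_equal(flat$cell_index, rep(noise_free$baseline_ci, length(grid)))
})

test_that("a fully efficacious compound at its IC50 halves the amplitude", {
  cpd <- list(true_ic50_nM = 100, efficacy = 1)
  a0 <- impedance_amplitude(5, noise_free)
  a1 <- impedance_amplitude(5, noise_free, cpd, 100)
  expect_equal(a1, a0 / 2)
  tr <- simulate_impedance_trace(5, cpd, 100, times = grid, kp = noise_free)
  tr0 <- simulate_impedance_trace(5, times = grid, kp = noise_free)
  base <- simulate_impedance_trace(0, times = grid, kp = noise_free)
  expect_equal(trace_response(preprocess_trace(tr, 0, base), 20),
               trace_response(preprocess_trace(tr0, 0, base), 20) / 2,
               tolerance = 1e-9)
})

test_that("trace_response interpolates linearly and validates state/range", {
  bs <- impedance_trace(c(0, 10, 20, 30), c(0, 0.2, 0.4, 0.1),
                        state = "baseline_subtracted", t_ref = 0)
  expect_equal(trace_response(bs, 10), 0.2)   # exactly on a sample
  expect_equal(trace_response(bs, 15), 0.3)   # midway between 0.2 and 0.4
  expect_error(trace_response(bs, 40), "outside")
  raw <- impedance_trace(c(0, 10, 20, 30), c(1, 2, 3, 4))
  expect_error(trace_response(raw, 10), "baseline-subtracted")
})

test_that("nadir search returns the earliest minimum in the window", {
  flat <- impedance_trace(grid, rep(0, length(grid)),
                          state = "baseline_subtracted")
  nd <- find_nadir(flat, c(0, 6))
  expect_equal(nd$depth, 0)
  expect_equal(nd$time, 0)
  ## relaxation with nadir time constant 2.5 h lands in the 2-3 h window
  kp <- kinetic_params(noise_sd = 0, relax_depth = 0.4, relax_tau = 2.5)
  cpd <- list(true_ic50_nM = 1, efficacy = 1)
  tr <- simulate_impedance_trace(0, cpd, 1e6, times = seq(0, 48, 0.25),
                                 kp = kp)
  base <- simulate_impedance_trace(0, times = seq(0, 48, 0.25), kp = kp)
  bs <- preprocess_trace(tr, 0, base)
  nd <- find_nadir(bs, c(0, 10))
  expect_gte(nd$time, 2); expect_lte(nd$time, 3)
  expect_lt(nd$depth, 0)
  ## two equal minima: earlier time wins
  two <- impedance_trace(1:5, c(0, -1, 0, -1, 0),
                         state = "baseline_subtracted")
  expect_equal(find_nadir(two, c(1, 5))$time, 2)
})

test_that("tubulin normalization removes the shared cell-count factor", {
  q <- data.frame(well = "A01", area_col1a1 = 10, area_acta = 10,
                  area_tba1a = 10)
  nq <- normalize_to_tubulin(q)
  expect_equal(nq$ratio_col1, 1); expect_equal(nq$ratio_acta, 1)
  bad <- normalize_to_tubulin(
    data.frame(well = "A02", area_col1a1 = 5, area_acta = 5, area_tba1a = 0))
  expect_true(bad$tubulin_flag)
  expect_true(is.na(bad$ratio_acta))

  ## cell-count jitter: ratio CV < raw-area CV
  set.seed(11)
  wells <- lapply(1:60, function(i) {
    n <- round(rlnorm(1, log(20000), 0.3))
    simulate_msms_well(5, n_cells = n, seed = i, well = paste0("W", i))
  })
  q <- normalize_to_tubulin(do.call(rbind, wells))
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(q$ratio_acta), cv(q$area_acta))

  ## TGF-saturated vs control: ~3-fold mean ratio
  sat <- normalize_to_tubulin(do.call(rbind, lapply(1:16, function(i)
    simulate_msms_well(5, seed = 100 + i, well = paste0("S", i)))))
  ctl <- normalize_to_tubulin(do.call(rbind, lapply(1:16, function(i)
    simulate_msms_well(0, seed = 200 + i, well = paste0("C", i)))))
  fold <- mean(sat$ratio_acta) / mean(ctl$ratio_acta)
  expect_gt(fold, 2.6); expect_lt(fold, 3.3)
})
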