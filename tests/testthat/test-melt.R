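logistic_curve <- function(tm, width = 0.4, id = "s1", grid = melt_grid()) {
  tibble::tibble(
    specimen_id = id, temp_C = grid,
    fluorescence = 1 / (1 + exp((grid - tm) / width))
  )
}

test_that("noiseless simulation and peak calling are mutually consistent", {
  ranked <- default_ranked()
  cond <- thermo_conditions()
  th <- ranked$per_haplotype_tm[[1]][1, ]
  cv <- simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond,
    noise_sd_fluor = 0, jitter = 0
  )
  pk <- cv |>
    normalize_curve() |>
    melt_derivative() |>
    melt_peaks()
  expect_lt(abs(pk$peak_tm_C - th$tm_C), 0.05) # one grid step
  # calibration shifts the recovered peak by exactly the offset
  cal <- calibrate_offset(cond, th$tm_C, 77.0)
  cv2 <- simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cal,
    noise_sd_fluor = 0, jitter = 0
  )
  pk2 <- cv2 |>
    normalize_curve() |>
    melt_derivative() |>
    melt_peaks()
  expect_lt(abs(pk2$peak_tm_C - 77.0), 0.05)
})

test_that("zero-amplitude curves classify as failed", {
  ranked <- default_ranked()
  th <- ranked$per_haplotype_tm[[1]][1, ]
  withr::local_seed(5)
  cv <- simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp,
    amplitude = 0
  )
  calls <- classify_curves(cv, c(marginata = 79.4, dolus = 77.0))
  expect_equal(calls$call, "failed")
  expect_true(is.na(calls$peak_tm_C))
})

test_that("simulated peak separation tracks the imposed Tm difference", {
  ranked <- default_ranked()
  cond <- thermo_conditions()
  th <- ranked$per_haplotype_tm[[1]][1, ]
  cond_hi <- calibrate_offset(cond, th$tm_C, 79.4)
  cond_lo <- calibrate_offset(cond, th$tm_C, 77.0)
  withr::local_seed(101)
  seps <- vapply(1:100, function(i) {
    cv <- dplyr::bind_rows(
      simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond_hi,
        specimen_id = "hi", noise_sd_fluor = 0.02, noise_sd_tm = 0.15
      ),
      simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond_lo,
        specimen_id = "lo", noise_sd_fluor = 0.02, noise_sd_tm = 0.15
      )
    )
    pk <- cv |>
      normalize_curve() |>
      melt_derivative(window_pts = 41) |>
      melt_peaks(vertex_halfwidth_C = 1)
    pk$peak_tm_C[pk$specimen_id == "hi"] - pk$peak_tm_C[pk$specimen_id == "lo"]
  }, numeric(1))
  expect_lt(abs(mean(seps) - 2.4), 0.3)
  expect_lt(stats::sd(seps), 0.5)
})

test_that("normalization is idempotent and affine-invariant", {
  grid <- melt_grid()
  f <- ifelse(grid <= 70, 1, ifelse(grid >= 80, 0, (80 - grid) / 10))
  cv <- tibble::tibble(specimen_id = "s1", temp_C = grid, fluorescence = f)
  norm1 <- normalize_curve(cv)
  expect_equal(norm1$fluorescence, f, tolerance = 1e-9)

  scaled <- cv
  scaled$fluorescence <- 10 * cv$fluorescence + 100
  expect_equal(normalize_curve(scaled)$fluorescence, norm1$fluorescence,
    tolerance = 1e-9
  )
})

test_that("normalized simulated curves sit near 1 before and 0 after the melt", {
  ranked <- default_ranked()
  th <- ranked$per_haplotype_tm[[1]][1, ]
  cv <- simulate_melt_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp,
    noise_sd_fluor = 0, jitter = 0
  )
  nc <- normalize_curve(cv)
  expect_equal(mean(nc$fluorescence[nc$temp_C <= 67]), 1, tolerance = 0.02)
  expect_equal(mean(nc$fluorescence[nc$temp_C >= 84]), 0, tolerance = 0.02)
})

test_that("normalization rejects bad windows", {
  cv <- logistic_curve(75)
  expect_error(normalize_curve(cv, pre_window = c(60, 62)),
    class = "hrmelt_input_error"
  )
  expect_error(normalize_curve(cv, pre_window = c(66, 66.1)),
    class = "hrmelt_input_error"
  )
  expect_error(
    normalize_curve(cv, pre_window = c(66, 84), post_window = c(83, 85)),
    class = "hrmelt_input_error"
  )
})

test_that("derivative peak calling is accurate on symmetric transitions", {
  pk <- logistic_curve(78) |>
    melt_derivative() |>
    melt_peaks()
  expect_lt(abs(pk$peak_tm_C - 78), 0.05)
  # unbiased across the usable grid interior
  for (tm in seq(67.5, 82.5, by = 2.5)) {
    pk <- logistic_curve(tm) |>
      melt_derivative() |>
      melt_peaks()
    expect_lt(abs(pk$peak_tm_C - tm), 0.05)
  }
})

test_that("bimodal curves report the dominant peak plus a secondary", {
  grid <- melt_grid()
  f <- 0.65 / (1 + exp((grid - 72) / 0.4)) + 0.35 / (1 + exp((grid - 79) / 0.4))
  cv <- tibble::tibble(specimen_id = "s1", temp_C = grid, fluorescence = f)
  pk <- cv |>
    melt_derivative() |>
    melt_peaks()
  expect_lt(abs(pk$peak_tm_C - 72), 0.1)
  expect_lt(abs(pk$secondary_tm_C - 79), 0.1)
  expect_gt(pk$peak_height, pk$secondary_height)
})

test_that("flat curves are flagged and fail classification", {
  grid <- melt_grid()
  cv <- tibble::tibble(
    specimen_id = "s1", temp_C = grid,
    fluorescence = rep(0.5, length(grid))
  )
  pk <- cv |>
    melt_derivative() |>
    melt_peaks()
  expect_equal(pk$peak_height, 0)
  expect_true(pk$flat)
  calls <- call_species(pk, c(A = 77, B = 79.4))
  expect_equal(calls$call, "failed")
})

test_that("species calls follow the nearest-reference decision rule", {
  refs <- c(dolus = 77.0, marginata = 79.4)
  peaks <- tibble::tibble(
    specimen_id = c("m", "d", "mid", "weak"),
    peak_tm_C = c(79.4, 77.0, 78.2, 79.4),
    peak_height = c(0.5, 0.5, 0.5, 0.01)
  )
  calls <- call_species(peaks, refs)
  expect_equal(
    calls$call,
    c("marginata", "dolus", "ambiguous", "failed")
  )
  expect_true(all(calls$margin_C[1:2] >= 0.5))
  expect_error(call_species(peaks, c(a = 77, b = 78)),
    class = "hrmelt_config_error"
  )
  expect_error(call_species(peaks, c(77, 79.4)),
    class = "hrmelt_input_error"
  )
})

test_that("curve CSV round trip preserves the long format", {
  cv <- logistic_curve(75)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(cv, path)
  expect_equal(as.data.frame(read_curves(path)), as.data.frame(cv))
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x = 1), bad)
  expect_error(read_curves(bad), class = "hrmelt_input_error")
})

test_that("matrix and per-specimen derivative paths agree", {
  withr::local_seed(3)
  grid <- melt_grid()
  cv <- dplyr::bind_rows(
    logistic_curve(75, id = "a"),
    logistic_curve(78, id = "b")
  )
  cv$fluorescence <- cv$fluorescence + rnorm(nrow(cv), 0, 0.01)
  fast <- melt_derivative(cv, window_pts = 21)
  direct <- unlist(lapply(split(cv$fluorescence, cv$specimen_id), function(f) {
    -signal::sgolayfilt(f, p = 3, n = 21, m = 1, ts = 0.05)
  }), use.names = FALSE)
  expect_equal(fast$neg_dF_dT, direct, tolerance = 1e-12)
  # ragged grids fall back to the per-specimen path
  ragged <- dplyr::bind_rows(
    logistic_curve(75, id = "a"),
    logistic_curve(78, id = "b", grid = seq(65, 85, 0.1))
  )
  d <- melt_derivative(ragged, window_pts = 21)
  expect_equal(nrow(d), nrow(ragged))
})
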