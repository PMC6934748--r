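# Melt-curve forward model and interpretation: simulation, baseline
# normalization, Savitzky-Golay derivative, peak calling, species
# assignment, and Table-style throughput reporting inputs.

#' Default melt acquisition grid
#'
#' 65-85 deg C at 0.05 deg C steps, matching a typical real-time
#' instrument's high-resolution melt acquisition (20 acquisitions per
#' degree at a 0.05 deg C/s ramp).
#'
#' @param from,to,by Grid limits and step, deg C.
#' @return Numeric vector of temperatures.
#' @export
melt_grid <- function(from = 65, to = 85, by = 0.05) {
  seq(from, to, by = by)
}

#' Simulate a fluorescence melt curve
#'
#' Forward model of the instrument signal: the two-state duplex fraction
#' theta(T) from [helicity_curve()], shifted by a per-specimen Tm jitter,
#' scaled by `amplitude` and a gently sloping pre-melt (helix) baseline,
#' plus a post-melt baseline and additive Gaussian fluorescence noise:
#'
#' `F(T) = amplitude * theta(T - jitter) * (1 + pre_slope*(T - T0)) +
#'   post_level + post_slope*(T - T0) + N(0, noise_sd_fluor)`
#'
#' Draws come from the R session RNG, so results are reproducible under
#' `set.seed()` (or [withr::with_seed()]).
#'
#' @inheritParams melting_temperature
#' @param specimen_id Identifier written into the output.
#' @param t_grid Acquisition temperatures, deg C.
#' @param amplitude Melt signal amplitude (0 simulates a failed
#'   amplification: baseline and noise only).
#' @param noise_sd_fluor SD of additive fluorescence noise, signal units.
#' @param noise_sd_tm SD of the per-specimen Tm jitter, deg C (ignored if
#'   `jitter` is given).
#' @param jitter Fixed Tm shift, deg C; `NULL` draws `N(0, noise_sd_tm)`.
#' @param pre_slope,post_level,post_slope Baseline parameters.
#' @return A melt-curve tibble: `specimen_id`, `temp_C`, `fluorescence`.
#' @details The two-state bimolecular transition is slightly asymmetric,
#'   so the maximum of -d(theta)/dT sits a fraction of a degree above the
#'   half-dissociation temperature. Instruments report the derivative
#'   peak, so the simulated signal is shifted by that constant
#'   (`.peak_offset()`) to make the noiseless reported peak coincide with
#'   the amplicon's calibrated Tm.
#' @export
simulate_melt_curve <- function(dH_kcal_mol, dS_cal_molK, n_bp,
                                cond = thermo_conditions(),
                                specimen_id = "s1",
                                t_grid = melt_grid(),
                                amplitude = 1,
                                noise_sd_fluor = 0.02,
                                noise_sd_tm = 0.15,
                                jitter = NULL,
                                pre_slope = -0.002,
                                post_level = 0.05,
                                post_slope = -5e-4) {
  if (amplitude < 0) {
    abort_hrmelt("amplitude must be >= 0", "input_error")
  }
  if (is.null(jitter)) jitter <- rnorm(1, 0, noise_sd_tm)
  t0 <- t_grid[1]
  delta <- .peak_offset(dH_kcal_mol, dS_cal_molK, n_bp, cond)
  theta <- .theta_at(
    dH_kcal_mol, dS_cal_molK, n_bp, cond,
    t_grid - jitter + delta
  )
  f <- amplitude * theta * (1 + pre_slope * (t_grid - t0)) +
    post_level + post_slope * (t_grid - t0) +
    rnorm(length(t_grid), 0, noise_sd_fluor)
  tibble(specimen_id = specimen_id, temp_C = t_grid, fluorescence = f)
}

.check_window <- function(w, grid, what) {
  n_in <- sum(grid >= w[1] & grid <= w[2])
  if (w[1] < min(grid) || w[2] > max(grid)) {
    abort_hrmelt(sprintf("%s window outside the temperature grid", what),
      "input_error")
  }
  if (n_in < 5) {
    abort_hrmelt(sprintf("%s window covers fewer than 5 grid points", what),
      "input_error")
  }
}

# Closed-form least-squares line fit; returns c(intercept, slope).
.line_fit <- function(x, y) {
  if (length(unique(x)) < 2) {
    abort_hrmelt("degenerate baseline window: no temperature variance",
      "normalization_error")
  }
  sl <- stats::cov(x, y) / stats::var(x)
  c(mean(y) - sl * mean(x), sl)
}

#' Baseline-normalize melt curves
#'
#' Fits straight lines to the pre-melt and post-melt windows of each
#' specimen's curve and rescales fluorescence to the fraction between them:
#' `(F - lower)/(upper - lower)`, clipped to `[-0.05, 1.05]`. Invariant
#' under affine transformations of the input fluorescence.
#'
#' @param curves Long melt-curve tibble (`specimen_id`, `temp_C`,
#'   `fluorescence`).
#' @param pre_window,post_window Temperature windows (deg C) assumed fully
#'   helical / fully melted.
#' @return Normalized curves in the same long format.
#' @export
normalize_curve <- function(curves, pre_window = c(66, 68),
                            post_window = c(83, 85)) {
  if (pre_window[2] >= post_window[1]) {
    abort_hrmelt("pre and post windows must not overlap", "input_error")
  }
  curves |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      .check_window(pre_window, df$temp_C, "pre-melt")
      .check_window(post_window, df$temp_C, "post-melt")
      pre <- df$temp_C >= pre_window[1] & df$temp_C <= pre_window[2]
      post <- df$temp_C >= post_window[1] & df$temp_C <= post_window[2]
      cu <- .line_fit(df$temp_C[pre], df$fluorescence[pre])
      cl <- .line_fit(df$temp_C[post], df$fluorescence[post])
      upper <- cu[1] + cu[2] * df$temp_C
      lower <- cl[1] + cl[2] * df$temp_C
      span <- upper - lower
      if (median(abs(span)) < 1e-12) {
        abort_hrmelt("upper and lower baselines coincide",
          "normalization_error")
      }
      df$fluorescence <- pmin(pmax((df$fluorescence - lower) / span, -0.05), 1.05)
      df
    }) |>
    ungroup() |>
    select("specimen_id", "temp_C", "fluorescence")
}

#' Negative smoothed derivative of melt curves
#'
#' Savitzky-Golay smoothed first derivative, negated, per specimen: the
#' familiar -dF/dT plot in which each melt transition appears as a peak.
#'
#' @inheritParams normalize_curve
#' @param window_pts Filter window length in grid points (odd, and at
#'   least `poly_order + 2`).
#' @param poly_order Polynomial order of the filter.
#' @return Long tibble: `specimen_id`, `temp_C`, `neg_dF_dT`.
#' @export
melt_derivative <- function(curves, window_pts = 11, poly_order = 3) {
  if (window_pts %% 2 != 1 || window_pts < poly_order + 2) {
    abort_hrmelt("window_pts must be odd and >= poly_order + 2",
      "config_error")
  }
  ids <- unique(curves$specimen_id)
  n_pts <- nrow(curves) / length(ids)
  common_grid <- n_pts == as.integer(n_pts)
  if (common_grid) {
    tm <- matrix(curves$temp_C, nrow = n_pts)
    im <- matrix(curves$specimen_id, nrow = n_pts)
    common_grid <- all(tm == tm[, 1]) &&
      all(im[1, ] == im[n_pts, ]) && !anyDuplicated(im[1, ])
  }
  if (common_grid && n_pts > window_pts) {
    # all specimens share one grid: filter every curve at once, building
    # the Savitzky-Golay projection a single time
    grid <- curves$temp_C[seq_len(n_pts)]
    step <- median(diff(grid))
    fmat <- matrix(curves$fluorescence, nrow = n_pts)
    fs <- signal::sgolay(p = poly_order, n = window_pts, m = 1, ts = step)
    k <- (window_pts - 1) / 2
    mid <- stats::filter(fmat, rev(fs[k + 1, ]), sides = 2)
    top <- fs[1:k, ] %*% fmat[1:window_pts, , drop = FALSE]
    bot <- fs[(k + 2):window_pts, ] %*%
      fmat[(n_pts - window_pts + 1):n_pts, , drop = FALSE]
    d <- rbind(top, mid[(k + 1):(n_pts - k), , drop = FALSE], bot)
    return(tibble(
      specimen_id = curves$specimen_id,
      temp_C = curves$temp_C,
      neg_dF_dT = -as.vector(d)
    ))
  }
  curves |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      step <- median(diff(df$temp_C))
      tibble(
        temp_C = df$temp_C,
        neg_dF_dT = -signal::sgolayfilt(df$fluorescence,
          p = poly_order, n = window_pts, m = 1, ts = step
        )
      )
    }) |>
    ungroup()
}

# Least-squares quadratic vertex over a window around the argmax; falls
# back to the 3-point parabola when the fit is not concave.
.vertex_fit <- function(t, y, i, half_C) {
  w <- which(abs(t - t[i]) <= half_C)
  tc <- t[w] - t[i]
  fit <- stats::lm.fit(cbind(1, tc, tc^2), y[w])
  b <- unname(fit$coefficients)
  if (!is.finite(b[3]) || b[3] >= 0) {
    return(.refine_peak(t, y, i))
  }
  v <- -b[2] / (2 * b[3])
  c(tm = t[i] + v, height = b[1] + b[2] * v + b[3] * v^2)
}

# Parabolic (3-point) interpolation around a grid maximum.
.refine_peak <- function(t, y, i) {
  if (i <= 1 || i >= length(y)) {
    return(c(tm = t[i], height = y[i]))
  }
  d1 <- y[i] - y[i - 1]
  d2 <- y[i] - y[i + 1]
  denom <- d1 + d2
  if (denom <= 0) {
    return(c(tm = t[i], height = y[i]))
  }
  shift <- 0.5 * (d1 - d2) / denom
  step <- t[i + 1] - t[i]
  c(tm = t[i] + shift * step, height = y[i] + 0.25 * (d1 - d2) * shift)
}

#' Call melting peaks from derivative curves
#'
#' The primary peak is the global maximum of -dF/dT with sub-grid
#' refinement by 3-point parabolic interpolation; a band of
#' `edge_exclude_C` at each end of the grid is excluded from the search,
#' since the smoothing filter's one-sided edge fits are unreliable there.
#' The strongest local maximum more than `secondary_min_sep_C` away is
#' recorded as a secondary peak (bimodal curves). A curve whose maximum is
#' not positive is flagged flat with `peak_height = 0`.
#'
#' @param deriv Output of [melt_derivative()].
#' @param secondary_min_sep_C Minimum separation for reporting a secondary
#'   peak, deg C.
#' @param edge_exclude_C Band at each grid end excluded from peak search,
#'   deg C.
#' @param vertex_halfwidth_C When set, the peak position is refined by a
#'   least-squares quadratic fit to the derivative within this half-width
#'   of the argmax instead of the 3-point parabola -- much more robust to
#'   fluorescence noise on broad melt peaks (see the vignette).
#' @return One row per specimen: `peak_tm_C`, `peak_height`,
#'   `secondary_tm_C`, `secondary_height`, `flat`.
#' @export
melt_peaks <- function(deriv, secondary_min_sep_C = 1, edge_exclude_C = 0.5,
                       vertex_halfwidth_C = NULL) {
  deriv |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      y <- df$neg_dF_dT
      t <- df$temp_C
      interior <- t >= min(t) + edge_exclude_C & t <= max(t) - edge_exclude_C
      y_search <- replace(y, !interior, -Inf)
      i <- which.max(y_search)
      if (!is.finite(y[i]) || y[i] <= 0) {
        return(tibble(
          peak_tm_C = NA_real_, peak_height = 0,
          secondary_tm_C = NA_real_, secondary_height = NA_real_,
          flat = TRUE
        ))
      }
      main <- if (is.null(vertex_halfwidth_C)) {
        .refine_peak(t, y, i)
      } else {
        .vertex_fit(t, y, i, vertex_halfwidth_C)
      }
      is_local_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
      cand <- which(is_local_max & interior &
        abs(t - t[i]) > secondary_min_sep_C)
      sec <- c(tm = NA_real_, height = NA_real_)
      if (length(cand) > 0) {
        j <- cand[which.max(y[cand])]
        sec <- .refine_peak(t, y, j)
      }
      tibble(
        peak_tm_C = unname(main["tm"]), peak_height = unname(main["height"]),
        secondary_tm_C = unname(sec["tm"]),
        secondary_height = unname(sec["height"]),
        flat = FALSE
      )
    }) |>
    ungroup()
}

#' Assign species from melting peaks
#'
#' Nearest-reference classification with a rejection region: a specimen is
#' `failed` when its peak is absent or below `min_height`; otherwise it is
#' assigned to the nearest reference species if that distance is within
#' `tau_C` *and* the gap to the next-nearest reference is at least
#' `min_margin_C`; anything else is `ambiguous`. References closer together
#' than `2 * tau_C` make the assay non-diagnostic at these thresholds and
#' raise a config error.
#'
#' @param peaks Output of [melt_peaks()] (or any tibble with
#'   `specimen_id`, `peak_tm_C`, `peak_height`).
#' @param refs Named numeric vector of reference peak temperatures, one
#'   per species (typically measured from known-species calibrator curves
#'   on the same plate).
#' @param tau_C Maximum distance to the nearest reference, deg C.
#' @param min_margin_C Minimum gap between nearest and next reference
#'   distances, deg C.
#' @param min_height Minimum peak height for a successful amplification,
#'   signal units per deg C.
#' @return One row per specimen: `specimen_id`, `call`, `peak_tm_C`,
#'   `margin_C`.
#' @export
call_species <- function(peaks, refs, tau_C = 0.75, min_margin_C = 0.5,
                         min_height = 0.1) {
  if (length(refs) < 2 || is.null(names(refs))) {
    abort_hrmelt("refs must be a named vector with >= 2 species",
      "input_error")
  }
  if (min(dist(refs)) < 2 * tau_C) {
    abort_hrmelt(
      "reference peaks closer than 2*tau_C: assay not diagnostic at these thresholds",
      "config_error"
    )
  }
  p_tm <- ifelse(is.finite(peaks$peak_tm_C), peaks$peak_tm_C, refs[1] + 1e6)
  d <- abs(outer(p_tm, refs, "-")) # specimens x references
  nearest <- max.col(-d, ties.method = "first")
  d_sorted <- t(apply(d, 1, sort))
  margin <- d_sorted[, 2] - d_sorted[, 1]
  call <- ifelse(
    d_sorted[, 1] <= tau_C & margin >= min_margin_C,
    colnames(d)[nearest], "ambiguous"
  )
  failed <- !is.finite(peaks$peak_height) | peaks$peak_height < min_height |
    !is.finite(peaks$peak_tm_C)
  tibble(
    specimen_id = peaks$specimen_id,
    call = ifelse(failed, "failed", call),
    peak_tm_C = ifelse(failed, NA_real_, peaks$peak_tm_C),
    margin_C = ifelse(failed, NA_real_, margin)
  )
}

#' Classify raw melt curves end to end
#'
#' Pipeline wrapper: estimates each specimen's melt amplitude (median
#' fluorescence gap between the pre- and post-melt windows); specimens
#' below `min_amplitude` are called `failed` without normalization (their
#' baselines carry no transition to normalize). The rest are normalized,
#' differentiated and assigned with [call_species()].
#'
#' @inheritParams normalize_curve
#' @inheritParams call_species
#' @inheritParams melt_derivative
#' @param min_amplitude Minimum pre/post fluorescence gap for a usable
#'   amplification, signal units.
#' @param vertex_halfwidth_C Passed to [melt_peaks()]; the default (1 deg
#'   C) uses the noise-robust multi-point vertex fit.
#' @return Calls tibble as from [call_species()].
#' @details Defaults here differ from the building blocks' own defaults:
#'   classification smooths with a ~2 deg C derivative window
#'   (`window_pts = 41` at the 0.05 deg C grid, on the order of the melt
#'   transition width of a short amplicon) and refines the peak by a
#'   quadratic vertex fit, trading a few hundredths of a degree of
#'   common-mode bias for an order-of-magnitude reduction in
#'   peak-position noise.
#' @export
classify_curves <- function(curves, refs, tau_C = 0.75, min_margin_C = 0.5,
                            min_height = 0.1, min_amplitude = 0.2,
                            pre_window = c(66, 68), post_window = c(83, 85),
                            window_pts = 41, poly_order = 3,
                            vertex_halfwidth_C = 1) {
  amp <- curves |>
    group_by(.data$specimen_id) |>
    summarise(
      amplitude = median(.data$fluorescence[
        .data$temp_C >= pre_window[1] & .data$temp_C <= pre_window[2]
      ]) -
        median(.data$fluorescence[
          .data$temp_C >= post_window[1] & .data$temp_C <= post_window[2]
        ]),
      .groups = "drop"
    )
  failed_ids <- amp$specimen_id[amp$amplitude < min_amplitude]
  ok <- curves[!curves$specimen_id %in% failed_ids, ]
  calls_ok <- if (nrow(ok) > 0) {
    ok |>
      normalize_curve(pre_window, post_window) |>
      melt_derivative(window_pts, poly_order) |>
      melt_peaks(vertex_halfwidth_C = vertex_halfwidth_C) |>
      call_species(refs, tau_C, min_margin_C, min_height)
  } else {
    tibble(
      specimen_id = character(), call = character(),
      peak_tm_C = double(), margin_C = double()
    )
  }
  bind_rows(
    calls_ok,
    tibble(
      specimen_id = failed_ids, call = "failed",
      peak_tm_C = NA_real_, margin_C = NA_real_
    )
  ) |>
    arrange(match(.data$specimen_id, unique(curves$specimen_id)))
}

#' Read / write melt curves as long-format CSV
#'
#' Columns: `specimen_id`, `temp_C`, `fluorescence`.
#'
#' @param path CSV path.
#' @param curves Long melt-curve tibble.
#' @return `read_curves()` returns the tibble; `write_curves()` returns
#'   `path` invisibly.
#' @export
read_curves <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("specimen_id", "temp_C", "fluorescence")
  if (!all(need %in% names(out))) {
    abort_hrmelt(
      paste0("curve CSV needs columns: ", paste(need, collapse = ", ")),
      "input_error"
    )
  }
  out
}

#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}
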