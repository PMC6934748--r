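# Nearest-neighbor duplex thermodynamics: unified parameter set
# (SantaLucia 1998), entropy-based monovalent salt correction with Mg++
# folded in as a monovalent equivalent, two-state bimolecular melting.

# Unified NN doublet parameters, dH in kcal/mol, dS in cal/(mol K).
# The ten unique doublets; the other six follow by duplex symmetry
# (a doublet and its reverse complement denote the same stack).
.NN_10 <- list(
  AA = c(-7.9, -22.2),
  AT = c(-7.2, -20.4),
  TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7),
  GT = c(-8.4, -22.4),
  CT = c(-7.8, -21.0),
  GA = c(-8.2, -22.2),
  CG = c(-10.6, -27.2),
  GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9)
)
.NN_INIT_GC <- c(0.1, -2.8) # per G.C terminal base pair
.NN_INIT_AT <- c(2.3, 4.1) # per A.T terminal base pair
.GAS_R <- 1.987 # cal/(mol K)

# 16-doublet expansion used by the implementation.
.nn_table <- local({
  rc2 <- function(d) {
    # reverse complement of a doublet (self-contained: runs at load time)
    chartr("ACGT", "TGCA", paste0(substr(d, 2, 2), substr(d, 1, 1)))
  }
  all16 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
    1, paste,
    collapse = ""
  )
  tab <- matrix(NA_real_, nrow = 16, ncol = 2, dimnames = list(all16, c("dH", "dS")))
  for (d in all16) {
    key <- if (d %in% names(.NN_10)) d else rc2(d)
    tab[d, ] <- .NN_10[[key]]
  }
  tab
})

#' Thermodynamic and instrument conditions
#'
#' Conditions under which duplex melting temperatures are predicted.
#' Divalent magnesium is folded into a monovalent sodium equivalent
#' (`Na_eq = monovalent + 120 * sqrt(free_Mg)` in mM) before the entropy
#' salt correction. `calibration_offset_C` is an additive instrument/dye
#' offset applied to every predicted Tm: saturating-dye Tm elevation and
#' platform effects are absorbed here rather than modelled, since only the
#' *separation* between variants, not the absolute scale, is a
#' thermodynamic prediction.
#'
#' @param monovalent_mM Monovalent cation concentration, mM.
#' @param free_Mg_mM Free magnesium, mM.
#' @param strand_conc_M Total single-strand concentration CT, molar
#'   (non-self-complementary duplex with equal strands assumed, so the Tm
#'   equation uses CT/4).
#' @param calibration_offset_C Additive offset in deg C.
#' @return An object of class `thermo_conditions`.
#' @export
#' @examples
#' thermo_conditions()
thermo_conditions <- function(monovalent_mM = 50, free_Mg_mM = 2,
                              strand_conc_M = 0.25e-6,
                              calibration_offset_C = 0) {
  if (monovalent_mM <= 0 || free_Mg_mM < 0 || strand_conc_M <= 0) {
    abort_hrmelt("concentrations must be positive", "config_error")
  }
  if (!is.finite(calibration_offset_C)) {
    abort_hrmelt("calibration offset must be finite", "config_error")
  }
  structure(
    list(
      monovalent_mM = monovalent_mM,
      free_Mg_mM = free_Mg_mM,
      strand_conc_M = strand_conc_M,
      calibration_offset_C = calibration_offset_C
    ),
    class = "thermo_conditions"
  )
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf(
    "Thermo conditions: %g mM monovalent, %g mM Mg, CT = %g M, offset %+.2f C\n",
    x$monovalent_mM, x$free_Mg_mM, x$strand_conc_M, x$calibration_offset_C
  ))
  invisible(x)
}

#' Read thermodynamic conditions from a YAML config
#'
#' Recognised keys: `monovalent_mM`, `mg_mM`, `strand_conc_M`,
#' `calibration_offset_C`; missing keys fall back to the
#' [thermo_conditions()] defaults.
#'
#' @param path YAML file path.
#' @return A `thermo_conditions` object.
#' @export
read_conditions <- function(path) {
  y <- yaml::read_yaml(path)
  d <- thermo_conditions()
  thermo_conditions(
    monovalent_mM = y$monovalent_mM %||% d$monovalent_mM,
    free_Mg_mM = y$mg_mM %||% d$free_Mg_mM,
    strand_conc_M = y$strand_conc_M %||% d$strand_conc_M,
    calibration_offset_C = y$calibration_offset_C %||% d$calibration_offset_C
  )
}

.na_equivalent_M <- function(cond) {
  (cond$monovalent_mM + 120 * sqrt(cond$free_Mg_mM)) / 1000
}

.salt_corrected_dS <- function(dS, n_bp, cond) {
  # 0.368 cal/(mol K) per internal stack, SantaLucia entropy correction
  dS + 0.368 * (n_bp - 1) * log(.na_equivalent_M(cond))
}

#' Nearest-neighbor enthalpy and entropy of a duplex
#'
#' Sums the ten unified doublet parameters along the sequence plus terminal
#' initiation terms (A.T vs G.C ends). Both dH and dS are negative for any
#' duplex of length >= 2.
#'
#' @param sequence Character vector of A/C/G/T sequences (one strand of the
#'   duplex, 5'->3'); ambiguity codes are rejected -- expand haplotypes
#'   before calling.
#' @return A tibble with columns `sequence`, `n_bp`, `dH_kcal_mol`,
#'   `dS_cal_molK`.
#' @export
#' @examples
#' nn_thermo("CCAGTACTTGCAGTTGCA")
nn_thermo <- function(sequence) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 2)) {
    abort_hrmelt("duplex must be at least 2 bp", "input_error")
  }
  if (any(str_detect(sequence, "[^ACGT]"))) {
    abort_hrmelt(
      "only A/C/G/T allowed; expand ambiguity codes / haplotypes first",
      "input_error"
    )
  }
  res <- purrr::map(sequence, function(s) {
    n <- nchar(s)
    dbl <- substring(s, 1:(n - 1), 2:n)
    ends <- c(str_sub(s, 1, 1), str_sub(s, n, n))
    init <- vapply(ends, function(b) {
      if (b %in% c("G", "C")) .NN_INIT_GC else .NN_INIT_AT
    }, numeric(2))
    c(
      dH = sum(.nn_table[dbl, "dH"]) + sum(init[1, ]),
      dS = sum(.nn_table[dbl, "dS"]) + sum(init[2, ])
    )
  })
  tibble(
    sequence = sequence,
    n_bp = nchar(sequence),
    dH_kcal_mol = purrr::map_dbl(res, "dH"),
    dS_cal_molK = purrr::map_dbl(res, "dS")
  )
}

#' Melting temperature from nearest-neighbor thermodynamics
#'
#' Two-state bimolecular melting of a non-self-complementary duplex with
#' equal strand concentrations:
#' `Tm(K) = dH*1000 / (dS_salt + R * ln(CT/4))`, with the entropy salt
#' correction `dS + 0.368 * (n_bp - 1) * ln[Na_eq]`. The calibration offset
#' in `cond` is added to the returned value.
#'
#' @param dH_kcal_mol,dS_cal_molK Duplex enthalpy/entropy, e.g. from
#'   [nn_thermo()].
#' @param n_bp Duplex length in base pairs (needed for the salt
#'   correction).
#' @param cond A [thermo_conditions()] object.
#' @return Melting temperature(s) in deg C.
#' @export
melting_temperature <- function(dH_kcal_mol, dS_cal_molK, n_bp,
                                cond = thermo_conditions()) {
  if (any(dH_kcal_mol >= 0) || any(dS_cal_molK >= 0)) {
    abort_hrmelt("duplex dH and dS must be negative", "input_error")
  }
  dS_c <- .salt_corrected_dS(dS_cal_molK, n_bp, cond)
  denom <- dS_c + .GAS_R * log(cond$strand_conc_M / 4)
  if (any(abs(denom) < 1e-8)) {
    abort_hrmelt("degenerate thermodynamics: entropy term near zero",
      "numeric_error")
  }
  dH_kcal_mol * 1000 / denom - 273.15 + cond$calibration_offset_C
}

#' Predict amplicon melting temperature from sequence
#'
#' Convenience wrapper around [nn_thermo()] and [melting_temperature()].
#'
#' @inheritParams nn_thermo
#' @inheritParams melting_temperature
#' @return The [nn_thermo()] tibble with a `tm_C` column appended.
#' @export
#' @examples
#' predict_tm(c("CCAGTACTTGCAGTTGCA", "CCAGTACTTGCAGTTGCC"))
predict_tm <- function(sequence, cond = thermo_conditions()) {
  th <- nn_thermo(sequence)
  th$tm_C <- melting_temperature(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond)
  th
}

#' Equilibrium helicity (duplex fraction) across a temperature grid
#'
#' Two-state bimolecular equilibrium at total strand concentration CT: the
#' fraction of strands in duplex solves `K * CT * (1-f)^2 = 2 f` with the
#' association constant `K(T) = exp(-(dH*1000 - T*dS_salt)/(R*T))`. By
#' construction `f(Tm) = 0.5` at the [melting_temperature()] Tm (including
#' the calibration offset, which shifts the curve along the temperature
#' axis), and f is strictly decreasing in T.
#'
#' @inheritParams melting_temperature
#' @param t_grid Ascending temperatures in deg C.
#' @return A tibble with columns `temp_C` and `theta`.
#' @export
helicity_curve <- function(dH_kcal_mol, dS_cal_molK, n_bp,
                           cond = thermo_conditions(),
                           t_grid = melt_grid()) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort_hrmelt("temperature grid must be strictly ascending", "input_error")
  }
  tibble(
    temp_C = t_grid,
    theta = .theta_at(dH_kcal_mol, dS_cal_molK, n_bp, cond, t_grid)
  )
}

# Vectorised duplex fraction; `temps_C` may be a vector or matrix.
.theta_at <- function(dH_kcal_mol, dS_cal_molK, n_bp, cond, temps_C) {
  t_K <- (temps_C - cond$calibration_offset_C) + 273.15
  dS_c <- .salt_corrected_dS(dS_cal_molK, n_bp, cond)
  ln_a <- -(dH_kcal_mol * 1000 - t_K * dS_c) / (.GAS_R * t_K) +
    log(cond$strand_conc_M)
  a <- exp(pmin(ln_a, 500))
  # stable root of a f^2 - (2a+2) f + a = 0; the discriminant
  # (2a+2)^2 - 4a^2 simplifies exactly to 8a + 4, avoiding overflow and
  # cancellation at large association constants
  f <- 2 * a / (2 * a + 2 + sqrt(8 * a + 4))
  f[ln_a > 500] <- 1
  f
}

#' Calibrate the instrument offset against an observed melting peak
#'
#' Stores `observed - predicted` (on top of any existing offset) in the
#' conditions, so that re-predicting the same amplicon under the returned
#' conditions reproduces the observed peak exactly. Being a single additive
#' shift, it leaves every between-variant delta-Tm unchanged.
#'
#' @param cond A [thermo_conditions()] object under which `predicted_tm_C`
#'   was computed.
#' @param predicted_tm_C Predicted Tm of the anchor amplicon, deg C.
#' @param observed_peak_C Observed melting-peak temperature, deg C.
#' @return Updated `thermo_conditions`.
#' @export
calibrate_offset <- function(cond, predicted_tm_C, observed_peak_C) {
  if (!is.finite(predicted_tm_C) || !is.finite(observed_peak_C)) {
    abort_hrmelt("calibration temperatures must be finite", "input_error")
  }
  cond$calibration_offset_C <- cond$calibration_offset_C +
    (observed_peak_C - predicted_tm_C)
  cond
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Offset between the -d(theta)/dT maximum and the thermodynamic Tm
# (theta = 0.5): the bimolecular transition is mildly asymmetric, so the
# derivative peak sits slightly above Tm. Evaluated numerically on a fine
# grid around Tm.
.peak_offset <- function(dH_kcal_mol, dS_cal_molK, n_bp, cond) {
  tm <- melting_temperature(dH_kcal_mol, dS_cal_molK, n_bp, cond)
  grid <- seq(tm - 4, tm + 4, by = 0.005)
  th <- .theta_at(dH_kcal_mol, dS_cal_molK, n_bp, cond, grid)
  d <- -diff(th) / diff(grid)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  mids[which.max(d)] - tm
}
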