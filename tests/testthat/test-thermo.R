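test_that("nearest-neighbor sums match hand-computed doublet totals", {
  # AT: two A.T initiations + the AT/AT stack
  th <- nn_thermo("AT")
  expect_equal(th$dH_kcal_mol, 2.3 * 2 - 7.2)
  expect_equal(th$dS_cal_molK, 4.1 * 2 - 20.4)
  # ACGT: A.T + T.A ends, stacks AC + CG + GT
  th <- nn_thermo("ACGT")
  expect_equal(th$dH_kcal_mol, 2.3 * 2 - 8.4 - 10.6 - 8.4)
  expect_equal(th$dS_cal_molK, 4.1 * 2 - 22.4 - 27.2 - 22.4)
})

test_that("nearest-neighbor sums equal the naive oracle for every short duplex", {
  for (k in 2:6) {
    seqs <- all_kmers(k)
    got <- nn_thermo(seqs)
    want <- t(vapply(seqs, oracle_nn, numeric(2)))
    expect_equal(got$dH_kcal_mol, unname(want[, "dH"]))
    expect_equal(got$dS_cal_molK, unname(want[, "dS"]))
  }
})

test_that("duplex symmetry and stacking monotonicity hold", {
  withr::local_seed(7)
  for (i in 1:25) {
    s <- random_dna_string(sample(5:40, 1))
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(nn_thermo(s)[-1], nn_thermo(rc)[-1], ignore_attr = TRUE)
    longer <- paste0(s, sample(c("A", "C", "G", "T"), 1))
    expect_lt(nn_thermo(longer)$dH_kcal_mol, nn_thermo(s)$dH_kcal_mol)
  }
  expect_error(nn_thermo("A"), class = "hrmelt_input_error")
  expect_error(nn_thermo("ACGR"), class = "hrmelt_input_error")
})

test_that("melting temperatures reproduce an independent implementation", {
  # expected values frozen from biopython MeltingTemp.Tm_NN with the
  # unified parameter table, the (N-1)-stack entropy salt correction,
  # Na 50 mM / Mg 2 mM, and CT/4 = 62.5 nM
  p <- predict_tm(c(
    "ACGTACGTACGTACGTACGT", "ATATATATATATATATATAT",
    "CCAGTACTTGCAGTTGCA", "GGAGATCCAATCTTATATCAAC"
  ))
  expect_equal(p$tm_C, c(62.294290, 33.538195, 59.116873, 55.152105),
    tolerance = 1e-6
  )
})

test_that("Tm responds correctly to concentration, salt, and GC content", {
  th <- nn_thermo("ACGTACGTACGTACGTACGT")
  base <- melting_temperature(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp)
  doubled <- melting_temperature(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp,
    thermo_conditions(strand_conc_M = 0.5e-6)
  )
  expect_gt(doubled, base)
  salty <- melting_temperature(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp,
    thermo_conditions(monovalent_mM = 150)
  )
  expect_gt(salty, base)

  # any single A/T -> G/C replacement raises Tm (random 60-mers)
  withr::local_seed(11)
  for (i in 1:200) {
    s <- random_dna_string(60)
    at_pos <- which(strsplit(s, "")[[1]] %in% c("A", "T"))
    if (length(at_pos) == 0) next
    j <- sample(at_pos, 1)
    s2 <- s
    substr(s2, j, j) <- sample(c("G", "C"), 1)
    expect_gt(predict_tm(s2)$tm_C, predict_tm(s)$tm_C)
  }
  expect_error(
    melting_temperature(1, -100, 20),
    class = "hrmelt_input_error"
  )
})

test_that("species-diagnostic G/C transitions give at least the observed separation", {
  ranked <- default_ranked()
  per_hap <- ranked$per_haplotype_tm[[1]]
  tma <- per_hap$tm_C[per_hap$species == "marginata"]
  tmb <- per_hap$tm_C[per_hap$species == "dolus"]
  expect_gte(min(abs(outer(tma, tmb, "-"))), 1.7)
  expect_true(all(outer(tma, tmb, "-") > 0)) # G/C-rich species melts higher
})

test_that("helicity curves are proper two-state melt profiles", {
  th <- nn_thermo(strrep("ACGTT", 12))
  cond <- thermo_conditions()
  tm <- melting_temperature(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond)
  grid <- seq(tm - 16, tm + 10, by = 0.01)
  hc <- helicity_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond, grid)
  expect_true(all(diff(hc$theta) <= 0))
  mid <- hc$theta > 1e-9 & hc$theta < 1 - 1e-9 # away from saturation
  expect_true(all(diff(hc$theta[mid]) < 0))
  expect_true(all(hc$theta >= 0 & hc$theta <= 1))
  theta_tm <- stats::approx(hc$temp_C, hc$theta, xout = tm)$y
  expect_equal(theta_tm, 0.5, tolerance = 1e-6)
  expect_gt(hc$theta[abs(hc$temp_C - (tm - 15)) < 0.005], 0.99)
  expect_error(
    helicity_curve(th$dH_kcal_mol, th$dS_cal_molK, th$n_bp, cond, c(70, 69)),
    class = "hrmelt_input_error"
  )
})

test_that("the higher-Tm amplicon melts to the right at every helicity level", {
  ranked <- default_ranked()
  per_hap <- ranked$per_haplotype_tm[[1]]
  hi <- per_hap[which.max(per_hap$tm_C), ]
  lo <- per_hap[which.min(per_hap$tm_C), ]
  grid <- melt_grid()
  cond <- thermo_conditions()
  th_hi <- helicity_curve(hi$dH_kcal_mol, hi$dS_cal_molK, hi$n_bp, cond, grid)
  th_lo <- helicity_curve(lo$dH_kcal_mol, lo$dS_cal_molK, lo$n_bp, cond, grid)
  for (level in c(0.9, 0.5, 0.1)) {
    t_hi <- stats::approx(th_hi$theta, th_hi$temp_C, xout = level)$y
    t_lo <- stats::approx(th_lo$theta, th_lo$temp_C, xout = level)$y
    expect_gt(t_hi, t_lo)
  }
})

test_that("offset calibration is an exact fixed point that preserves separations", {
  cond <- thermo_conditions()
  cond2 <- calibrate_offset(cond, predicted_tm_C = 75, observed_peak_C = 77)
  expect_equal(cond2$calibration_offset_C, 2)

  ranked <- default_ranked()
  per_hap <- ranked$per_haplotype_tm[[1]]
  anchor <- per_hap$tm_C[per_hap$species == "dolus"][1]
  cal <- calibrate_offset(cond, anchor, 77.0)
  re <- melting_temperature(
    per_hap$dH_kcal_mol, per_hap$dS_cal_molK, per_hap$n_bp, cal
  )
  expect_equal(re[per_hap$species == "dolus"][1], 77.0)
  # additive shift: every delta-Tm unchanged
  expect_equal(dist(re), dist(per_hap$tm_C), ignore_attr = TRUE)
})

test_that("conditions validate and read from YAML", {
  expect_error(thermo_conditions(monovalent_mM = 0),
    class = "hrmelt_config_error"
  )
  expect_error(thermo_conditions(calibration_offset_C = Inf),
    class = "hrmelt_config_error"
  )
  yml <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("monovalent_mM: 100", "mg_mM: 3", "calibration_offset_C: 1.5"), yml)
  cond <- read_conditions(yml)
  expect_equal(cond$monovalent_mM, 100)
  expect_equal(cond$free_Mg_mM, 3)
  expect_equal(cond$strand_conc_M, 0.25e-6)
  expect_equal(cond$calibration_offset_C, 1.5)
})
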