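test_that("MGF parsing converts RT to minutes and keeps metadata", {
  path <- write_mgf_fixture(tempfile(fileext = ".mgf"))
  recs <- parse_spectra(path, "mgf")
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$analyte_id, "alpha")
  expect_equal(recs[[1]]$class_label, "JWH")
  expect_equal(recs[[1]]$precursor_mz, 377.2)
  expect_equal(recs[[1]]$rt_min, 2)          # 120 s
  expect_equal(nrow(recs[[1]]$peaks), 4L)
  expect_equal(recs[[1]]$peaks[2L, ], c(mz = 144.0444, intensity = 400))
  expect_equal(recs[[2]]$precursor_mz, 250.5)  # intensity after PEPMASS dropped
  expect_equal(recs[[2]]$rt_min, 5.5)
  expect_equal(recs[[2]]$class_label, "")
})

test_that("parser contract violations are reported with context", {
  empty <- tempfile(fileext = ".mgf"); file.create(empty)
  expect_identical(parse_spectra(empty, "mgf"), list())

  nopep <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), nopep)
  expect_error(parse_spectra(nopep, "mgf"), "PEPMASS")

  badpeak <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=100", "oops", "END IONS"),
             badpeak)
  expect_error(parse_spectra(badpeak, "mgf"), "record 1")

  msp_ok <- write_msp_fixture(tempfile(fileext = ".msp"))
  recs <- parse_spectra(msp_ok, "msp")
  expect_equal(recs[[1]]$class_label, "fentanyls")
  expect_equal(recs[[1]]$rt_min, 5.5)

  msp_bad <- write_msp_fixture(tempfile(fileext = ".msp"), num_peaks = 5L)
  expect_error(parse_spectra(msp_bad, "msp"), "Num Peaks")
})

test_that("csv peak lists group rows into one record per analyte", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    analyte_id = c("a", "a", "b"), class = c("JWH", "JWH", ""),
    precursor_mz = c(300, 300, 200), rt_min = c(2, 2, 1),
    fragment_mz = c(150, 120, 90), intensity = c(100, 50, 10)),
    path, row.names = FALSE)
  recs <- parse_spectra(path, "csv_peaks")
  expect_length(recs, 2L)
  expect_equal(nrow(recs[[1]]$peaks), 2L)
  expect_equal(recs[[2]]$class_label, "")
})

test_that("feature extraction follows the ranked-fragment neutral-loss rules", {
  rec <- spectrum_record("x", 377.2, 2,
                         cbind(c(232.1126, 144.0444, 116.0495, 77.0386),
                               c(1000, 400, 90, 50)))
  # base-peak reference: 90/1000 and 50/1000 fall below the 10% threshold
  fv <- extract_features(rec)
  expect_equal(unname(fv[c("frag1_mz", "frag2_mz")]), c(232.1126, 144.0444))
  expect_true(is.na(fv["frag3_mz"]) && is.na(fv["nl3"]))
  expect_equal(unname(fv["nl1"]), 0)
  expect_equal(unname(fv["nl2"]), 232.1126 - 144.0444)
  expect_equal(attr(fv, "missing_mask"),
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))

  # precursor reference changes only the loss values
  fp <- extract_features(rec, nl_reference = "precursor")
  expect_equal(unname(fp["nl1"]), 377.2 - 232.1126)
  expect_equal(unname(fp[c("frag1_mz", "frag2_mz")]),
               unname(fv[c("frag1_mz", "frag2_mz")]))

  # excluding the base peak promotes the next fragments
  fx <- extract_features(rec, include_base_peak = FALSE)
  expect_equal(unname(fx["frag1_mz"]), 144.0444)

  # single peak: the base peak minus itself
  f1 <- extract_features(spectrum_record("y", 100, 1, cbind(80, 10)))
  expect_equal(unname(f1[c("frag1_mz", "nl1")]), c(80, 0))
  expect_true(all(is.na(f1[c("frag2_mz", "frag3_mz", "nl2", "nl3")])))

  expect_error(extract_features(
    spectrum_record("z", 100, 1, matrix(numeric(), 0, 2))), "empty")
  expect_error(extract_features(
    spectrum_record("z", 100, 1, cbind(c(50, 60), c(0, 0)))), "zero")
})

test_that("extraction is invariant to intensity rescaling and monotone in threshold", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    peaks <- cbind(runif(k, 50, 290), runif(k, 1, 1000))
    rec <- spectrum_record("r", 300, 3, peaks)
    rec2 <- spectrum_record("r", 300, 3, cbind(peaks[, 1], peaks[, 2] * 137.5))
    expect_equal(extract_features(rec), extract_features(rec2))
    surv <- sapply(c(0.05, 0.10, 0.25, 0.6, 1.0), function(th)
      sum(!is.na(extract_features(rec, rel_intensity_threshold = th)[3:5])))
    expect_true(all(diff(surv) <= 0))
  }
})

test_that("intensity ties rank by lower m/z for a deterministic matrix", {
  rec <- spectrum_record("t", 400, 1,
                         cbind(c(300.2, 150.1, 250.3), c(500, 500, 500)))
  fv <- extract_features(rec)
  expect_equal(unname(fv[3:5]), c(150.1, 250.3, 300.2))
})

test_that("build_matrix stacks records in order and aggregates failures", {
  path <- write_mgf_fixture(tempfile(fileext = ".mgf"))
  fm <- build_matrix(parse_spectra(path, "mgf"))
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm), c(2L, 8L))
  expect_equal(fm$analyte_id, c("alpha", "beta"))
  expect_equal(colnames(fm$values),
               c("precursor_mz", "rt_min", "frag1_mz", "frag2_mz",
                 "frag3_mz", "nl1", "nl2", "nl3"))

  one <- build_matrix(list(spectrum_record("solo", 100, 1, cbind(80, 10))))
  expect_equal(dim(one), c(1L, 8L))

  bad <- list(spectrum_record("ok", 100, 1, cbind(80, 10)),
              spectrum_record("broken", 100, 1, matrix(numeric(), 0, 2)))
  expect_error(build_matrix(bad), "broken")
})

test_that("feature tables round-trip through CSV losslessly", {
  panel <- generate_panel(default_templates(), 3, seed = 5)
  fm <- build_matrix(panel$records, nl_reference = "precursor")
  path <- tempfile(fileext = ".csv")
  write_feature_table(fm, path)
  back <- read_feature_table(path)
  expect_equal(back$values, fm$values)
  expect_identical(back$missing_mask, fm$missing_mask)
  expect_identical(back$analyte_id, fm$analyte_id)
  expect_identical(back$class_label, fm$class_label)

  # blank cells become missing; junk numerics are rejected by column name
  df <- as.data.frame(fm)
  df$nl3[2] <- NA
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE, na = "")
  expect_true(read_feature_table(p2)$missing_mask[2, "nl3"])
  df$precursor_mz <- as.character(df$precursor_mz)
  df$precursor_mz[1] <- "not-a-number"
  write.csv(df, p2, row.names = FALSE, na = "")
  expect_error(read_feature_table(p2), "precursor_mz")
  expect_error(read_feature_table(tempfile()), "not found")

  df2 <- as.data.frame(fm)[, -3]
  write.csv(df2, p2, row.names = FALSE)
  expect_error(read_feature_table(p2), "precursor_mz")
})

test_that("monoisotopic masses are exact and additive", {
  expect_equal(monoisotopic_mass("C17H14N"), 232.1126, tolerance = 5e-4 / 232)
  expect_equal(monoisotopic_mass("H"), 1.007825, tolerance = 1e-6)
  expect_identical(monoisotopic_mass("C2"), 24)  # carbon-12 definition
  expect_error(monoisotopic_mass("C2Xx3"), "unsupported")
  expect_error(parse_formula("17C"), "malformed")
  # additivity over disjoint formulas
  set.seed(3)
  els <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  for (i in 1:10) {
    pick <- sample(els, 6)
    a <- setNames(sample(1:20, 3), pick[1:3])
    b <- setNames(sample(1:20, 3), pick[4:6])
    expect_equal(monoisotopic_mass(c(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b))
  }
})
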