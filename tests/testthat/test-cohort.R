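test_that("study-eye selection follows birth-year parity with fallback", {
  both_good <- participant_record("p1", 1990)
  expect_equal(select_study_eye(both_good), "right")
  expect_equal(select_study_eye(participant_record("p2", 1991)), "left")
  # parity eye uninterpretable -> switch to the other
  rec <- participant_record("p3", 1990,
                            right_eye = eye_quality(interpretable = FALSE))
  expect_equal(select_study_eye(rec), "left")
  # both eyes below signal threshold -> excluded
  low <- eye_quality(signal_strength = 6)
  expect_equal(select_study_eye(participant_record("p4", 1990,
                                                   right_eye = low,
                                                   left_eye = low)),
               "excluded")
  # any single disqualifier fires: artefacts, segmentation, signal
  bad_art <- eye_quality(artefact_free = FALSE)
  bad_seg <- eye_quality(segmentation_ok = FALSE)
  expect_equal(select_study_eye(participant_record("p5", 1992,
                                                   right_eye = bad_art,
                                                   left_eye = bad_seg)),
               "excluded")
})

test_that("quality filters split the cohort and log every exclusion", {
  bad <- eye_quality(artefact_free = FALSE)
  cohort <- c(
    lapply(1:43, function(i) participant_record(sprintf("ok%02d", i),
                                                1970 + i)),
    lapply(1:2, function(i) participant_record(sprintf("bad%d", i), 1980 + i,
                                               right_eye = bad,
                                               left_eye = bad)))
  res <- apply_quality_filters(cohort)
  expect_equal(nrow(res$included), 43)
  expect_equal(nrow(res$exclusions), 2)
  expect_setequal(res$exclusions$rule_fired, "significant_artefacts")
  expect_equal(nrow(res$included) + nrow(res$exclusions), length(cohort))
  # all-perfect cohort: nobody excluded
  all_ok <- apply_quality_filters(cohort[1:5])
  expect_equal(nrow(all_ok$exclusions), 0)
  expect_equal(nrow(all_ok$included), 5)
})

test_that("assemble_comparisons pairs the designed scans per plexus", {
  meas <- expand.grid(participant_id = sprintf("P%02d", 1:6),
                      scan_index = 1:3, plexus = c("SCP", "DCP"),
                      stringsAsFactors = FALSE)
  meas$fd <- 1.6 + seq_len(nrow(meas)) / 1000
  comps <- assemble_comparisons(meas)
  expect_setequal(names(comps), c("SCP", "DCP"))
  for (plx in names(comps)) {
    rep_tab <- comps[[plx]]$repeatability
    expect_setequal(unique(rep_tab$rater_id), c("scan2", "scan3"))
    expect_equal(nrow(rep_tab), 12)
    rpr_tab <- comps[[plx]]$reproducibility
    expect_setequal(unique(rpr_tab$rater_id), c("scan1", "scan2"))
    # values come from the right plexus and scan
    for (i in seq_len(nrow(rpr_tab))) {
      src <- meas[meas$participant_id == rpr_tab$participant_id[i] &
                    meas$scan_index == as.integer(sub("scan", "",
                                                      rpr_tab$rater_id[i])) &
                    meas$plexus == plx, "fd"]
      expect_equal(rpr_tab$value[i], src)
    }
  }
  # a participant missing scan 3 drops from repeatability only
  meas2 <- meas[!(meas$participant_id == "P01" & meas$scan_index == 3), ]
  comps2 <- assemble_comparisons(meas2)
  expect_false("P01" %in% comps2$SCP$repeatability$participant_id)
  expect_true("P01" %in% comps2$SCP$reproducibility$participant_id)
  expect_true(nrow(attr(comps2, "dropped")) >= 1)
})

test_that("the design constants match the acquisition protocol", {
  d <- study_design()
  expect_equal(d$repeatability_pair, c(2L, 3L))
  expect_equal(d$reproducibility_pair, c(1L, 2L))
  expect_equal(unname(d$observer_of_scan), c(1L, 2L, 2L))
})
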