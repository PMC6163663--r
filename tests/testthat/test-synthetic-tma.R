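test_that("cohort has the matched-pair design and conserves core counts", {
  cfg <- cohort_config(n_pairs = 41, cores_per_patient = 4,
                       image_side = 24, core_diameter = 20, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$images, 41 * 2 * 4)
  expect_equal(as.integer(table(cohort$metadata$group)[c("HR", "LR")]),
               c(164L, 164L))
  # each pair holds exactly one HR and one LR patient, with equal Gleason
  by_pair <- split(cohort$metadata, cohort$metadata$pair_id)
  expect_true(all(vapply(by_pair, function(p) {
    length(unique(p$patient_id[p$group == "HR"])) == 1 &&
      length(unique(p$patient_id[p$group == "LR"])) == 1 &&
      length(unique(p$gleason_sum)) == 1
  }, logical(1))))
  # ground truth is withheld from the inference-facing metadata
  expect_false("true_dab_fraction" %in% names(cohort$metadata))
  expect_true(all(c("core_id", "true_dab_fraction") %in%
                    names(cohort$truth)))
  expect_true(all(cohort$truth$true_dab_fraction >= 0 &
                    cohort$truth$true_dab_fraction <= 1))
})

test_that("generation is deterministic given the config seed", {
  cfg <- cohort_config(n_pairs = 2, cores_per_patient = 2,
                       image_side = 48, core_diameter = 40, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
})

test_that("degenerate DAB fractions hit their boundaries exactly", {
  cfg0 <- cohort_config(n_pairs = 2, cores_per_patient = 2,
                        image_side = 48, core_diameter = 40,
                        dab_fraction_hr = 0, dab_fraction_lr = 0,
                        patient_sd = 0, core_sd = 0, seed = 5)
  co0 <- generate_cohort(cfg0)
  expect_true(all(vapply(co0$images, attr, numeric(1), "n_dab") == 0))

  cfg1 <- cohort_config(n_pairs = 1, cores_per_patient = 2,
                        image_side = 48, core_diameter = 40,
                        dab_fraction_hr = 1, dab_fraction_lr = 1,
                        patient_sd = 0, core_sd = 0, seed = 5)
  co1 <- generate_cohort(cfg1)
  expect_true(all(vapply(co1$images, function(im) {
    attr(im, "n_dab") == attr(im, "n_tissue")
  }, logical(1))))
})

test_that("realised DAB share and disc area match their targets", {
  cfg <- cohort_config(n_pairs = 25, cores_per_patient = 2,
                       image_side = 48, core_diameter = 40,
                       background_sd = 0, tissue_sd = 0, dab_sd = 0,
                       seed = 13)
  cohort <- generate_cohort(cfg)   # 100 cores
  n_tissue <- vapply(cohort$images, attr, numeric(1), "n_tissue")
  n_dab <- vapply(cohort$images, attr, numeric(1), "n_dab")
  p <- cohort$truth$true_dab_fraction
  se3 <- 3 * sqrt(p * (1 - p) / n_tissue)
  expect_true(all(abs(n_dab / n_tissue - p) <= se3 + 1 / n_tissue))
  # disc rasterisation: area within 4d of pi (d/2)^2
  d <- cfg$core_diameter
  expect_true(all(abs(n_tissue - pi * (d / 2)^2) <= 4 * d))
})

test_that("raising the HR fraction never lowers the realised HR share", {
  mean_hr_share <- function(frac) {
    cfg <- cohort_config(n_pairs = 4, cores_per_patient = 2,
                         image_side = 48, core_diameter = 40,
                         dab_fraction_hr = frac, seed = 21)
    cohort <- generate_cohort(cfg)
    hr <- cohort$metadata$core_id[cohort$metadata$group == "HR"]
    mean(vapply(cohort$images[hr], function(im) {
      attr(im, "n_dab") / attr(im, "n_tissue")
    }, numeric(1)))
  }
  expect_gte(mean_hr_share(0.4), mean_hr_share(0.2))
})

test_that("write_dataset writes a complete, losslessly round-tripping tree", {
  cfg <- cohort_config(n_pairs = 2, cores_per_patient = 2,
                       image_side = 32, core_diameter = 28, seed = 9)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_dataset(cohort, dir, overwrite = TRUE)
  expect_length(list.files(dir, pattern = "\\.png$"), 8)
  expect_true(all(file.exists(file.path(dir, c("cores.csv", "truth.csv")))))

  back <- read_cohort(dir)
  expect_identical(lapply(back$images, `[[`, "pixels"),
                   lapply(cohort$images, `[[`, "pixels"))

  # refuses to clobber a non-empty directory
  expect_error(write_dataset(cohort, dir), "not empty")

  # metadata / image count mismatch is rejected
  broken <- cohort
  broken$metadata <- cohort$metadata[-1, ]
  expect_error(write_dataset(broken, withr::local_tempdir(),
                             overwrite = TRUE), "rows")

  # TIFF round trip is equally lossless
  tdir <- withr::local_tempdir()
  write_dataset(cohort, tdir, format = "tiff", overwrite = TRUE)
  im <- read_core_image(file.path(tdir, paste0(cohort$metadata$core_id[1],
                                               ".tif")))
  expect_identical(im$pixels, cohort$images[[1]]$pixels)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(cohort_config(tissue_mean = 255), "tissue_mean")
  expect_error(cohort_config(dab_mean = 200), "dab_mean")
  expect_error(cohort_config(dab_fraction_hr = 1.2), "dab_fraction_hr")
  expect_error(cohort_config(n_pairs = 0), "n_pairs")
  expect_error(cohort_config(core_diameter = 300, image_side = 256),
               "core_diameter")
})

test_that("core rendering demands an explicit seed", {
  cfg <- cohort_config(n_pairs = 1, image_side = 32, core_diameter = 28)
  meta <- list(core_id = "c1", true_dab_fraction = 0.25)
  expect_error(generate_core_image(meta, cfg), "seed")
  im <- generate_core_image(meta, cfg, seed = 4)
  expect_s3_class(im, "core_image")
  expect_true(all(im$pixels >= 0 & im$pixels <= 255))
})
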