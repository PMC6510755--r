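# The synthetic cohort generator: demographic model, scanner profiles,
# phantom structure and determinism.

test_that("demographics and scanner profiles enforce their invariants", {
  expect_error(demographics("male", -3, 70), "age")
  expect_error(demographics("male", 50, 10), "weight")
  expect_error(demographics("other", 50, 70))
  s1 <- scanner_profile("scanner1")
  s2 <- scanner_profile("scanner2")
  expect_equal(s1$n_views, 19)
  expect_equal(s2$n_views, 36)
  expect_equal(s1$volume_matrix, c(168L, 168L))
  expect_equal(s1$voxel_size, c(4.1, 4.1, 2.0))
  expect_equal(s2$voxel_size, c(4.0, 4.0, 4.0))
  expect_true(all(diff(s2$view_angles) > 0))
  expect_error(scanner_profile("s", voxel_size = c(4, 4, 2),
                               volume_matrix = c(64, 64),
                               view_angles = c(10, 5), noise_scale = 0),
               "increasing")
  expect_error(scanner_profile("nonesuch"), "unknown")
})

test_that("phantom generation is deterministic and respects its design", {
  prof <- scanner_profile("scanner1", volume_matrix = c(64L, 64L),
                          noise_scale = 0.05)
  sp <- phantom_spec(demographics("male", 60, 75), prof, seed = 7)
  v1 <- generate_phantom(sp, "A")
  v2 <- generate_phantom(sp, "A")
  expect_identical(v1$intensities, v2$intensities)
  expect_true(all(v1$intensities >= 0))
  expect_true(all(is.finite(v1$intensities)))
})

test_that("pelvic-band mean difference equals the configured amplitude", {
  prof <- scanner_profile("scanner1", noise_scale = 0)
  amp <- 0.08
  ss <- list(pelvis_mean = amp)
  vm <- generate_phantom(phantom_spec(demographics("male", 60, 75), prof,
                                      seed = 3, signal_strengths = ss), "M")
  vf <- generate_phantom(phantom_spec(demographics("female", 60, 75), prof,
                                      seed = 3, signal_strengths = ss), "F")
  nz <- dim(vm$intensities)[3]
  zf <- (seq_len(nz) - 0.5) / nz
  pel <- which(zf >= 0.60 & zf < 0.85)
  dmean <- mean(vm$intensities[, , pel]) - mean(vf$intensities[, , pel])
  expect_equal(dmean, amp, tolerance = 1e-10)
})

test_that("noise-free brain voxels sit at or above the display window top", {
  prof <- scanner_profile("scanner2", noise_scale = 0)
  v <- generate_phantom(phantom_spec(demographics("female", 40, 60), prof,
                                     seed = 1), "B")
  nz <- dim(v$intensities)[3]
  zf <- (seq_len(nz) - 0.5) / nz
  head_band <- v$intensities[, , zf < 0.15]
  brain <- head_band[head_band > 0.8]  # above soft tissue = brain component
  expect_gt(length(brain), 100)
  expect_true(all(brain >= 10))
})

test_that("silhouette width grows monotonically with weight", {
  prof <- scanner_profile("scanner2", noise_scale = 0)
  width_of <- function(w) {
    v <- generate_phantom(phantom_spec(demographics("male", 60, w), prof,
                                       seed = 1), "W")
    sum(apply(v$intensities, 1, max) > 0)
  }
  widths <- vapply(c(45, 60, 75, 95, 120), width_of, 1)
  expect_true(all(diff(widths) >= 0))
  expect_gt(widths[5], widths[1])
})

test_that("the noise-free pelvic band separates the sexes perfectly", {
  prof <- scanner_profile("scanner2", noise_scale = 0)
  cases <- expand.grid(sex = c("male", "female"),
                       age = c(30, 70), weight = c(55, 90),
                       stringsAsFactors = FALSE)
  stat <- vapply(seq_len(nrow(cases)), function(i) {
    v <- generate_phantom(phantom_spec(
      demographics(cases$sex[i], cases$age[i], cases$weight[i]),
      prof, seed = i), "X")
    nz <- dim(v$intensities)[3]
    zf <- (seq_len(nz) - 0.5) / nz
    band <- v$intensities[, , zf >= 0.60 & zf < 0.85]
    c(peak = max(band), mean = mean(band))
  }, c(peak = 1, mean = 1))
  # the planted male component tops the shared bladder uptake: a single
  # threshold on the band peak classifies every case
  expect_gt(min(stat["peak", cases$sex == "male"]),
            max(stat["peak", cases$sex == "female"]))
  # at matched habitus the band mean separates by the designed amplitude
  for (a in c(30, 70)) for (w in c(55, 90)) {
    sel <- cases$age == a & cases$weight == w
    expect_gt(stat["mean", sel & cases$sex == "male"],
              stat["mean", sel & cases$sex == "female"])
  }
})

test_that("sampled demographics match the cohort model", {
  d <- sample_demographics(10000, seed = 1)
  expect_equal(mean(d$sex == "male"), 0.56, tolerance = 0.02)
  expect_lt(abs(mean(d$age) - 61.6), 0.5)
  expect_true(all(d$age >= 2 & d$age <= 92))
  expect_true(all(d$weight >= 20 & d$weight <= 150))
  expect_identical(sample_demographics(5, seed = 9),
                   sample_demographics(5, seed = 9))
  expect_true(all(sample_demographics(50, ratio_male = 1, seed = 2)$sex == "male"))
})

test_that("cohort generation assigns unique ids and the scanner mix", {
  co <- generate_cohort(40, seed = 3)
  expect_equal(nrow(co$meta), 40)
  expect_equal(length(unique(co$meta$patient_id)), 40)
  expect_equal(length(co$patients), 40)
  co2 <- generate_cohort(40, seed = 3)
  expect_identical(co$meta, co2$meta)
  # scanner assignment is multinomial with the requested fractions
  counts <- vapply(1:15, function(s) {
    sum(generate_cohort(60, seed = s)$meta$scanner == "scanner1")
  }, 1)
  expect_equal(mean(counts) / 60, 0.873, tolerance = 0.04)
  expect_error(generate_cohort(0), "n must be >= 1")
  expect_error(generate_cohort(5, scanner_mix = c(scanner1 = 0.5)), "sum to 1")
})

test_that("invalid phantom configuration is rejected", {
  prof <- scanner_profile("scanner2")
  dm <- demographics("male", 60, 70)
  expect_error(phantom_spec(dm, prof, region_layout = list(
    head = c(0, 0.5), chest = c(0.4, 0.6), abdomen = c(0.6, 0.7),
    pelvis = c(0.7, 0.9))), "non-overlapping")
  expect_error(phantom_spec(dm, prof,
                            signal_strengths = list(pelvis_mean = 0)),
               "positive")
  expect_error(phantom_spec(dm, prof,
                            signal_strengths = list(age_slope = -1)),
               "nonnegative")
})

test_that("materialized cohorts carry one volume per patient", {
  co <- generate_cohort(3, scanner_mix = c(scanner2 = 1), seed = 8,
                        materialize = TRUE)
  expect_true(all(vapply(co$patients, function(p) inherits(p$volume, "pet_volume"), TRUE)))
  v <- patient_volume(co, co$meta$patient_id[2])
  expect_identical(v$intensities, co$patients[[2]]$volume$intensities)
})
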