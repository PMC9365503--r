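cfg <- scenario_config()

test_that("scenario configuration resolves all four treatment scenarios", {
  expect_setequal(names(cfg$scenarios),
                  c("imrt_brachy", "imrt_sib", "3dcrt_brachy", "3dcrt_seq"))
  s1 <- scenario_spec("3dcrt_seq", cfg)
  expect_equal(s1$wbi_scheme$total_dose, 50)
  expect_equal(s1$boost_scheme$total_dose, 10)
  s2 <- scenario_spec("imrt_sib", cfg)
  expect_equal(s2$wbi_scheme$n_fractions, 28L)
  expect_equal(s2$wbi_scheme$dose_per_fraction, 1.8)
  expect_error(scenario_spec("nope", cfg), "unknown scenario")
})

test_that("patient generation is deterministic given (seed, patient)", {
  spec <- scenario_spec("imrt_brachy", cfg)
  a <- generate_patient(spec, seed = 42, patient_id = 3)
  b <- generate_patient(spec, seed = 42, patient_id = 3)
  expect_identical(lapply(a$distribution, `[[`, "voxel_doses"),
                   lapply(b$distribution, `[[`, "voxel_doses"))
  c <- generate_patient(spec, seed = 43, patient_id = 3)
  expect_false(identical(a$distribution[[1]]$voxel_doses,
                         c$distribution[[1]]$voxel_doses))
})

test_that("out-of-field organs stay below 20% of the prescription", {
  spec <- scenario_spec("3dcrt_seq", cfg)
  for (p in 1:3) {
    pat <- generate_patient(spec, seed = 7, patient_id = p)
    for (i in which(pat$organ %in% c("lung_contra", "breast_contra"))) {
      d <- pat$distribution[[i]]
      expect_lt(max(d$voxel_doses), 0.2 * d$scheme$total_dose)
    }
  }
})

test_that("cohort generation honours sizes and hashes deterministically", {
  sizes <- c(imrt_brachy = 2, imrt_sib = 2, `3dcrt_brachy` = 1,
             `3dcrt_seq` = 2)
  st <- generate_cohorts(cfg, seed = 5, sizes = sizes)
  counts <- table(unique(st$doses[c("scenario", "patient_id")])$scenario)
  expect_equal(as.integer(counts[names(sizes)]), unname(sizes))
  st2 <- generate_cohorts(cfg, seed = 5, sizes = sizes)
  expect_identical(st$manifest$hash, st2$manifest$hash)
  st3 <- generate_cohorts(cfg, seed = 6, sizes = sizes)
  expect_false(identical(st$manifest$hash, st3$manifest$hash))
})

test_that("default cohort sizes give the 38-patient study layout", {
  sizes <- vapply(names(cfg$scenarios), function(nm) {
    scenario_spec(nm, cfg)$cohort_size
  }, numeric(1))
  expect_equal(sum(sizes), 38)
  expect_equal(unname(sizes["3dcrt_brachy"]), 8)
})

test_that("cohort export writes dose CSVs and a manifest", {
  out <- withr::local_tempdir()
  st <- generate_cohorts(cfg, seed = 2,
                         sizes = c(imrt_brachy = 1, imrt_sib = 1,
                                   `3dcrt_brachy` = 1, `3dcrt_seq` = 1),
                         out_dir = out)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$hash, st$manifest$hash)
  files <- list.files(out, pattern = "\\.csv$")
  expect_equal(length(files), nrow(st$doses))
  back <- read_dose_distribution(file.path(out, files[1]))
  expect_s3_class(back, "dose_distribution")
})

test_that("generated organ means recover the configured targets", {
  # moderate cohort: empirical mean within 3 standard errors of the target
  spec <- scenario_spec("imrt_brachy", cfg)
  n <- 60
  dm <- vapply(seq_len(n), function(p) {
    pat <- generate_patient(spec, seed = 11, patient_id = p)
    rows <- pat$organ == "heart"
    sum(vapply(pat$distribution[rows], function(d) mean(d$voxel_doses),
               numeric(1)))
  }, numeric(1))
  target <- spec$organs$dmean_mean[spec$organs$organ == "heart"]
  sd_t <- spec$organs$dmean_sd[spec$organs$organ == "heart"]
  expect_lt(abs(mean(dm) - target), 3 * sd_t / sqrt(n))
})

test_that("TLD generation recovers configured doses and flags outliers", {
  spec <- scenario_spec("imrt_brachy", cfg)
  # zero noise: background-corrected mean equals the configured full-course dose
  tl0 <- generate_tld_readings(spec, "small", seed = 3, noise_cv = 0)
  sets <- tld_sets_from_table(tl0, attr(tl0, "n_fractions"))
  expect_equal(mean_organ_dose(sets$heart)$mean_dose_gy,
               spec$tld$small$heart[1], tolerance = 1e-9)

  # Monte-Carlo recovery with noise: mean over replicates within 3 SE
  reps <- 200
  vals <- vapply(seq_len(reps), function(i) {
    tl <- generate_tld_readings(spec, "small", seed = 1000 + i)
    s <- tld_sets_from_table(tl, attr(tl, "n_fractions"))
    mean_organ_dose(s$lung_contra)$mean_dose_gy
  }, numeric(1))
  target <- spec$tld$small$lung_contra[1]
  expect_lt(abs(mean(vals) - target), 3 * sd(vals) / sqrt(reps))

  # injected outlier: exactly one reading at least 5x the others
  tlo <- generate_tld_readings(spec, "large", seed = 4, outlier = TRUE)
  r <- sort(tlo$reading_gy[tlo$organ == "lung_ipsi"], decreasing = TRUE)
  expect_gte(r[1], 5 * r[2])
})

test_that("cohorts reproduce the qualitative scenario ordering", {
  # IMRT + SiB has the highest ipsilateral-lung mean dose,
  # 3D-CRT + brachytherapy the lowest; checked on cohorts large enough that
  # sampling noise does not mask the configured scenario separation
  sizes <- c(imrt_brachy = 60, imrt_sib = 60, `3dcrt_brachy` = 60,
             `3dcrt_seq` = 60)
  for (seed in c(101, 202)) {
    st <- generate_cohorts(cfg, seed = seed, sizes = sizes)
    dm <- st$doses |>
      dplyr::filter(.data$organ == "lung_ipsi") |>
      dplyr::group_by(.data$scenario, .data$patient_id) |>
      dplyr::summarise(
        dm = sum(vapply(.data$distribution, function(d) mean(d$voxel_doses),
                        numeric(1))),
        .groups = "drop") |>
      dplyr::group_by(.data$scenario) |>
      dplyr::summarise(m = mean(.data$dm))
    ord <- dm$scenario[order(dm$m)]
    expect_identical(as.character(ord[1]), "3dcrt_brachy")
    expect_identical(as.character(ord[length(ord)]), "imrt_sib")
  }
})
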