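test_that("dataset construction preserves counts and validates invariants", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "release_dataset")
  expect_equal(nrow(ds$samples), 2L)
  expect_equal(nrow(ds$observations), 10L)

  # duplicated time within a sample is rejected and names the sample
  bad_obs <- rbind(ds$observations,
                   data.frame(sample_id = 1, time_h = 4, release_pct = 50))
  expect_error(release_dataset(ds$samples, bad_obs), "sample 1")

  # out-of-range carrier features are rejected
  s <- tiny_samples(1); s$monomer_ratio <- 1.5
  expect_error(release_dataset(s, tiny_obs(1, 1:3, c(10, 20, 30))),
               "monomer_ratio")
  expect_error(release_dataset(tiny_samples(1),
                               tiny_obs(1, c(1, 2, 3), c(10, 20, 150))),
               "release")
})

test_that("csv and json round-trips reproduce the dataset exactly", {
  gen <- generate_dataset(generator_config(n_samples = 5, seed = 42))
  ds <- gen$dataset
  stem <- file.path(withr::local_tempdir(), "ds")
  write_release_dataset(ds, stem, format = "csv")
  back <- read_release_dataset(stem, format = "csv")
  expect_equal(back$samples, ds$samples)
  expect_equal(back$observations, ds$observations)

  fj <- file.path(withr::local_tempdir(), "ds.json")
  write_release_dataset(ds, fj, format = "json")
  backj <- read_release_dataset(fj, format = "json")
  expect_equal(backj$samples, ds$samples)
  expect_equal(backj$observations, ds$observations)

  expect_error(read_release_dataset(file.path(tempdir(), "nope"), "csv"),
               "not found")
})

test_that("mean imputation fills every missing feature and is idempotent", {
  s <- tiny_samples(3)
  s$pdi <- c(0.1, NA, 0.3)
  s$polymer_mw <- c(10, NA, 30)
  obs <- do.call(rbind, lapply(1:3, function(i)
    tiny_obs(i, c(1, 2, 4), c(10, 20, 40))))
  ds <- release_dataset(s, obs)

  imp <- impute_missing(ds)
  expect_equal(imp$samples$pdi[2], 0.2)
  expect_equal(imp$samples$polymer_mw[2], 20)
  expect_identical(impute_missing(imp)$samples, imp$samples)

  # two missing out of four: both get the mean of the observed pair, and
  # the column mean is unchanged by imputation
  s4 <- tiny_samples(4)
  s4$zeta_potential <- c(1, 2, NA, NA)
  ds4 <- release_dataset(s4, do.call(rbind, lapply(1:4, function(i)
    tiny_obs(i, c(1, 2, 4), c(10, 20, 40)))))
  imp4 <- impute_missing(ds4)
  expect_equal(imp4$samples$zeta_potential[3:4], c(1.5, 1.5))
  expect_equal(mean(imp4$samples$zeta_potential), 1.5)

  s$pdi <- NA_real_
  ds_all_na <- release_dataset(s, obs)
  expect_error(impute_missing(ds_all_na), "pdi")
})

test_that("feature rows pool one row per observation in canonical order", {
  rows <- tiny_rows(n_samples = 2, n_points = 5)
  expect_equal(nrow(rows), 10L)
  expect_identical(names(rows), c("sample_id", feature_names(), "release_pct"))
  expect_equal(length(feature_names()), 21L)

  # last feature is always the observation time
  ds <- tiny_dataset()
  expect_error(to_feature_rows(ds), "descriptors|missing features")

  # uneven point counts: 5 + 7 points -> 12 rows
  s <- tiny_samples(2)
  for (d in descriptor_features()) s[[d]] <- 1
  obs <- rbind(tiny_obs(1, 1:5, seq(10, 50, 10)),
               tiny_obs(2, 1:7, seq(10, 70, 10)))
  rows2 <- to_feature_rows(release_dataset(s, obs))
  expect_equal(nrow(rows2), 12L)
  expect_equal(rows2$time_h, obs$time_h)
})

test_that("row count over a dataset shaped like the literature table equals the point-number sum", {
  point_numbers <- c(33, 37, 33, 35, 35, 35, 35, 35, 35, 35, 35, 35, 35,
                     35, 35, 35, 8, 8, 11, 21, 11, 15, 10, 8, 16, 6, 10,
                     8, 7, 13, 12, 25, 10, 6, 7, 18, 8, 10, 20)
  s <- tiny_samples(39)
  for (d in descriptor_features()) s[[d]] <- 1
  obs <- do.call(rbind, lapply(seq_len(39), function(i) {
    t <- seq_len(point_numbers[i])
    tiny_obs(i, t, pmin(t * 2, 100))
  }))
  rows <- to_feature_rows(release_dataset(s, obs))
  expect_equal(nrow(rows), sum(point_numbers))
  expect_equal(sum(point_numbers), 826L)
})

test_that("z-score scaler round-trips and handles constant columns", {
  rows <- tiny_rows()
  sc <- fit_scaler(rows)
  expect_true(all(sc$scale > 0))
  # constant columns (e.g. pdi) transform to exactly 0
  scaled <- scale_rows(sc, rows)
  expect_true(all(scaled$pdi == 0))
  back <- unscale_rows(sc, scaled)
  for (f in feature_names()) {
    expect_equal(back[[f]], rows[[f]], tolerance = 1e-12)
  }
  # two-point column: center is the midpoint
  r2 <- rows[1:2, ]; r2$polymer_mw <- c(0, 10)
  sc2 <- fit_scaler(r2)
  expect_equal(unname(sc2$center["polymer_mw"]), 5)
  expect_error(fit_scaler(rows[0, ]), ".")
})

test_that("pooled split partitions rows reproducibly at the requested fraction", {
  rows <- tiny_rows(n_samples = 4, n_points = 25)   # 100 rows
  sp <- split_rows(rows, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  key <- function(d) sort(paste(d$sample_id, d$time_h))
  expect_equal(sort(c(key(sp$train), key(sp$test))), key(rows))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)

  sp2 <- split_rows(rows, 0.8, seed = 3)
  expect_identical(sp$train, sp2$train)
  expect_error(split_rows(rows[1, , drop = FALSE], 0.8, 1), "2 rows")
  expect_error(split_rows(rows, 1.2, 1), "train_fraction")
})

test_that("every well-sampled curve contributes points to the train split across seeds", {
  rows <- tiny_rows(n_samples = 5, n_points = 8)
  for (seed in 1:10) {
    sp <- split_rows(rows, 0.8, seed = seed)
    expect_setequal(unique(sp$train$sample_id), 1:5)
    # partition invariant under the same sweep
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rows))
  }
})
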