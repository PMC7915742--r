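withr::local_options(list(petrepeat.warn_bins = FALSE))

test_that("NIfTI round trip preserves values and geometry", {
  img <- pet_image(array(stats::rnorm(6 * 5 * 4), c(6, 5, 4)),
                   spacing = c(2, 2.5, 3), origin = c(-10, 0, 5),
                   units = "SUV")
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_nifti(img, path)
    back <- read_nifti(path)
    expect_equal(back$values, img$values)
    expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
    expect_equal(back$origin, img$origin, tolerance = 1e-6)
    expect_identical(back$units, "SUV")
  }
  # the written file is readable by an independent NIfTI implementation
  # (nibabel) when available; here we at least check the magic bytes
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(img, path)
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 348)
  close(con)
  expect_identical(readBin(hdr[1:4], "integer", size = 4), 348L)
  expect_identical(rawToChar(hdr[345:347]), "n+1")
})

test_that("mask export uses the image geometry", {
  img <- pet_image(array(1, c(10, 10, 10)), spacing = 2)
  voi <- sphere_mask(img, c(9, 9, 9), 8)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_mask(voi, img, path)
  back <- read_nifti(path)
  expect_identical(back$values > 0.5, voi$mask)
  expect_identical(back$units, "tumor_sphere")
})

test_that("pipeline config round-trips through JSON losslessly", {
  cfg <- pipeline_config(
    cohort = cohort_spec(n_per_group = c(wildtype = 3L, mutant = 2L),
                         shape = c(32, 32, 32), seed = 9L),
    sphere_diameters = c(10, 16), min_n = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
})

tiny_config <- function(seed = 31L) {
  pipeline_config(
    cohort = cohort_spec(
      n_per_group = c(wildtype = 2L, mutant = 2L),
      volume_mean_ml = c(wildtype = 6, mutant = 3),
      volume_cv = 0.2,
      shape = c(32, 32, 32), exposure = 400, seed = seed),
    sphere_diameters = c(10, 16), min_n = 4L)
}

test_that("the end-to-end pipeline runs, writes outputs, and is bitwise reproducible", {
  out1 <- withr::local_tempdir()
  res <- suppressWarnings(run_pipeline(tiny_config(), out_dir = out1,
                                       quiet = TRUE))
  # manifest records the full feature-column count
  expect_identical(res$run_manifest$n_feature_columns, 1302L)
  expect_identical(nrow(res$manifest), 4L)
  expect_setequal(unique(res$features$voi_label),
                  c("background_sphere", "tumor_contour", "d10", "d16"))
  expect_identical(ncol(res$features), 3L + 1302L)
  for (f in c("cohort_manifest.csv", "features.csv", "icc_tumor_contour.csv",
              "run_manifest.json", "config.json")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  # every stage output is regenerated identically from the same seed
  out2 <- withr::local_tempdir()
  suppressWarnings(run_pipeline(tiny_config(), out_dir = out2, quiet = TRUE))
  expect_identical(unname(tools::md5sum(file.path(out1, "features.csv"))),
                   unname(tools::md5sum(file.path(out2, "features.csv"))))
  expect_identical(
    unname(tools::md5sum(file.path(out1, "icc_tumor_contour.csv"))),
    unname(tools::md5sum(file.path(out2, "icc_tumor_contour.csv"))))
})

test_that("the CLI drives simulate and icc stages through files", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "cfg.json")
  write_config(tiny_config(), cfg_path)
  sim_dir <- file.path(out, "sim")
  suppressWarnings(petrepeat_cli(c("simulate", "--config", cfg_path,
                                   "--out", sim_dir)))
  man <- utils::read.csv(file.path(sim_dir, "cohort_manifest.csv"))
  expect_identical(nrow(man), 4L)
  expect_true(all(file.exists(man$test_path)))
  img <- read_nifti(man$test_path[1])
  expect_identical(dim(img$values), c(32L, 32L, 32L))
  expect_error(petrepeat_cli("nonsense"), "unknown subcommand")
})
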