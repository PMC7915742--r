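#' Pipeline configuration
#'
#' Aggregates every stage's parameters into one serializable object:
#' cohort simulation, segmentation (ratio threshold, background sphere,
#' tumor sphere diameter series), discretization, filters, ICC and
#' clustering. Round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param cohort A [cohort_spec()] (or a list of its arguments).
#' @param tbr_threshold Tumor-to-brain ratio cutoff, default 1.6.
#' @param background_diameter Background sphere diameter mm, default 30.
#' @param sphere_diameters Tumor sphere series mm,
#'   default `c(10, 16, 20, 24, 30, 35, 40)`.
#' @param bin_width Discretization bin width, default 0.15.
#' @param log_sigmas LoG scales mm, default `1:5`.
#' @param wavelet_kernel Wavelet family, default `"coif1"`.
#' @param alpha ICC CI error rate, default 0.05.
#' @param min_n Minimum subjects per feature for ICC reporting, default 5.
#' @param n_clusters Clusters at the dendrogram cut, default 2.
#' @param cluster_condition Which half's features to cluster on, default
#'   `"test"`.
#' @param cluster_voi VOI whose features are clustered, default
#'   `"tumor_contour"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            tbr_threshold = 1.6,
                            background_diameter = 30,
                            sphere_diameters = c(10, 16, 20, 24, 30, 35, 40),
                            bin_width = 0.15,
                            log_sigmas = 1:5,
                            wavelet_kernel = "coif1",
                            alpha = 0.05,
                            min_n = 5L,
                            n_clusters = 2L,
                            cluster_condition = c("test", "retest"),
                            cluster_voi = "tumor_contour") {
  if (!inherits(cohort, "cohort_spec")) cohort <- do.call(cohort_spec, cohort)
  structure(list(
    cohort = cohort, tbr_threshold = tbr_threshold,
    background_diameter = background_diameter,
    sphere_diameters = as.numeric(sphere_diameters),
    bin_width = bin_width, log_sigmas = as.numeric(log_sigmas),
    wavelet_kernel = wavelet_kernel, alpha = alpha, min_n = as.integer(min_n),
    n_clusters = as.integer(n_clusters),
    cluster_condition = match.arg(cluster_condition),
    cluster_voi = cluster_voi
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  # jsonlite drops the names of named atomic vectors; store them as objects
  for (nm in c("n_per_group", "volume_mean_ml", "tbr_contrast",
               "texture_amplitude")) {
    x$cohort[[nm]] <- as.list(x$cohort[[nm]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- x$cohort
  cohort <- cohort_spec(
    n_per_group = stats::setNames(as.integer(ch$n_per_group),
                                  names(ch$n_per_group)),
    volume_mean_ml = unlist(ch$volume_mean_ml),
    volume_cv = ch$volume_cv,
    tbr_contrast = unlist(ch$tbr_contrast),
    texture_amplitude = unlist(ch$texture_amplitude),
    texture_scale = ch$texture_scale,
    shape = ch$shape, spacing = ch$spacing, psf_fwhm = ch$psf_fwhm,
    exposure = ch$exposure, background_uptake = ch$background_uptake,
    seed = ch$seed
  )
  pipeline_config(
    cohort = cohort, tbr_threshold = x$tbr_threshold,
    background_diameter = x$background_diameter,
    sphere_diameters = x$sphere_diameters, bin_width = x$bin_width,
    log_sigmas = x$log_sigmas, wavelet_kernel = x$wavelet_kernel,
    alpha = x$alpha, min_n = x$min_n, n_clusters = x$n_clusters,
    cluster_condition = x$cluster_condition, cluster_voi = x$cluster_voi
  )
}

# Mean of the two halves reproduces the full-count reconstruction exactly
# (the halves sum to the original counts) - the analog of the conventionally
# reconstructed summed image on which VOIs are defined once and transferred.
reference_image <- function(pair) {
  pet_image((pair$test$values + pair$retest$values) / 2,
            spacing = pair$test$spacing, origin = pair$test$origin,
            units = pair$test$units)
}

#' Segment all VOIs for one subject
#'
#' Defines, on the reference (summed-equivalent) image: the mirrored
#' background sphere, the ratio-threshold tumor contour, and the tumor
#' sphere diameter series centered on the uptake maximum. Masks are computed
#' once and reused on both halves.
#'
#' @param pair A [trt_pair()].
#' @param tumor_center Tumor center in mm (for mirroring the background
#'   sphere).
#' @param config A [pipeline_config()].
#' @return Named list of `voi_mask`s: `background_sphere`, `tumor_contour`,
#'   `d<diam>` per series diameter.
#' @export
segment_subject <- function(pair, tumor_center, config = pipeline_config()) {
  ref <- reference_image(pair)
  bg <- background_sphere(ref, tumor_center,
                          diameter = config$background_diameter)
  tumor <- auto_contour_tbr(ref, bg, threshold = config$tbr_threshold)
  spheres <- tumor_sphere_series(ref, tumor,
                                 diameters = config$sphere_diameters)
  c(list(background_sphere = bg, tumor_contour = tumor), spheres)
}

#' Extract the feature bank for one subject over all VOIs
#'
#' Filters each half once (14 variants) and reuses the variants across VOIs.
#'
#' @param pair A [trt_pair()].
#' @param vois Named list of `voi_mask`s from [segment_subject()].
#' @param config A [pipeline_config()].
#' @return Data frame in tidy layout: subject_id, condition, voi_label
#'   columns followed by the 1,302 feature columns.
#' @export
extract_subject <- function(pair, vois, config = pipeline_config()) {
  vt <- image_variants(pair$test, log_sigmas = config$log_sigmas,
                       wavelet_kernel = config$wavelet_kernel)
  vr <- image_variants(pair$retest, log_sigmas = config$log_sigmas,
                       wavelet_kernel = config$wavelet_kernel)
  rows <- lapply(names(vois), function(vn) {
    fb <- extract_all(pair, vois[[vn]], bin_width = config$bin_width,
                      variants_test = vt, variants_retest = vr)
    rbind(
      data.frame(subject_id = pair$subject_id, condition = "test",
                 voi_label = vn, t(fb$test), check.names = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(subject_id = pair$subject_id, condition = "retest",
                 voi_label = vn, t(fb$retest), check.names = FALSE,
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}

# subjects x features matrix for one voi/condition from the tidy table
feature_matrix <- function(features, voi, condition) {
  sub <- features[features$voi_label == voi &
                    features$condition == condition, ]
  m <- as.matrix(sub[, -(1:3), drop = FALSE])
  rownames(m) <- sub$subject_id
  m
}

#' Run the full synthetic repeatability pipeline
#'
#' simulate -> segment -> filter -> extract -> ICC -> cluster, writing all
#' stage outputs (CSV/JSON) under `out_dir`. Deterministic given the
#' config's master seed: re-running reproduces all outputs bitwise.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `features` (tidy data frame), `icc` (named
#'   list of per-VOI ICC tables), `summaries`, `cluster`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  say("simulating cohort (%d subjects)...", sum(config$cohort$n_per_group))
  cohort <- simulate_cohort(config$cohort)
  manifest <- attr(cohort, "manifest")

  features <- NULL
  for (s in cohort) {
    say("subject %s: segment + extract", s$subject_id)
    vois <- segment_subject(s$pair, s$tumor_center, config)
    features <- rbind(features,
                      extract_subject(s$pair, vois, config))
  }

  voi_labels <- unique(features$voi_label)
  icc_list <- list()
  summaries <- list()
  for (v in voi_labels) {
    tab <- icc_table(feature_matrix(features, v, "test"),
                     feature_matrix(features, v, "retest"),
                     alpha = config$alpha, min_n = config$min_n)
    icc_list[[v]] <- tab
    summaries[[v]] <- list(family = repeatability_summary(tab, "family"),
                           variant = repeatability_summary(tab, "variant"))
  }
  say("ICC tables computed for %d VOIs", length(voi_labels))

  cl <- NULL
  cl_voi <- config$cluster_voi
  if (cl_voi %in% voi_labels) {
    tab <- icc_list[[cl_voi]]
    rep_feats <- tab$feature[tab$label == "repeatable" & tab$status == "ok"]
    if (length(rep_feats) >= 2L) {
      fm <- feature_matrix(features, cl_voi, config$cluster_condition)
      z <- suppressWarnings(zscore_features(fm[, rep_feats, drop = FALSE]))
      wc <- ward_cluster(z, n_clusters = config$n_clusters)
      geno <- manifest$genotype[match(rownames(fm), manifest$subject_id)]
      cl <- list(
        n_repeatable = length(rep_feats),
        assignments = wc$assignments,
        heights = wc$heights,
        composition = genotype_composition(wc$assignments, geno),
        purity = cluster_purity(wc$assignments, geno)
      )
      say("clustered on %d repeatable features; purity %.1f%%",
          length(rep_feats), 100 * cl$purity)
    } else {
      say("fewer than 2 repeatable features in %s; skipping clustering",
          cl_voi)
    }
  }

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("petrepeat")),
    seed = config$cohort$seed,
    n_subjects = sum(config$cohort$n_per_group),
    n_feature_columns = length(feature_manifest(full = TRUE)),
    voi_labels = voi_labels,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    for (v in voi_labels) {
      utils::write.csv(icc_list[[v]],
                       file.path(out_dir, sprintf("icc_%s.csv", v)),
                       row.names = FALSE)
    }
    if (!is.null(cl)) {
      utils::write.csv(
        data.frame(subject_id = names(cl$assignments),
                   cluster = unname(cl$assignments)),
        file.path(out_dir, "cluster_assignments.csv"), row.names = FALSE)
      jsonlite::write_json(cl$composition,
                           file.path(out_dir, "cluster_composition.json"),
                           dataframe = "rows", auto_unbox = TRUE)
    }
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.json"))
  }

  invisible(list(features = features, icc = icc_list, summaries = summaries,
                 cluster = cl, manifest = manifest,
                 run_manifest = run_manifest))
}
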