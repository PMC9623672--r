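#' Pipeline run configuration
#'
#' One configuration object for the whole convert - extract - screen
#' workflow. Defaults equal the study settings: 0.1 degC bin width,
#' symmetric GLCM, all wavelet sub-bands, expression thresholds P < 0.01
#' and |d| > 1.2, 10-pixel feature-map windows.
#'
#' @param pairs data.frame with one row per teat and columns `id`,
#'   `pre_image`, `pre_mask`, `post_image`, `post_mask` (images as PNG/JPG
#'   plus colorbar, or as DICOM temperature maps).
#' @param outdir output directory (created if missing).
#' @param t_min,t_max,colormap colorbar of the colorized images (ignored
#'   for DICOM inputs).
#' @param bin_width,wavelet extraction settings.
#' @param p_thresh,d_thresh expression-screen thresholds.
#' @param map_window feature-map window side, pixels.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(pairs, outdir, t_min = 5, t_max = 40,
                       colormap = "iron", bin_width = 0.1, wavelet = TRUE,
                       p_thresh = 0.01, d_thresh = 1.2, map_window = 10L,
                       seed = 1L) {
  pairs <- as.data.frame(pairs)
  need <- c("id", "pre_image", "pre_mask", "post_image", "post_mask")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  structure(list(pairs = pairs, outdir = outdir, t_min = t_min,
                 t_max = t_max, colormap = colormap, bin_width = bin_width,
                 wavelet = wavelet, p_thresh = p_thresh, d_thresh = d_thresh,
                 map_window = as.integer(map_window), seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' The serialize - parse - serialize round trip is the identity.
#'
#' @param config a [run_config()]; `path` a JSON file path.
#' @return `read_run_config`: a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::fromJSON(path)
  do.call(run_config, j)
}

load_temperature_input <- function(path, lut, who) {
  if (!file.exists(path))
    stop("missing input for ", who, ": ", path)
  if (tolower(tools::file_ext(path)) == "dcm") read_dicom(path)
  else convert_to_temperature(read_thermogram(path), lut)
}

#' Run the full delta-radiomics pipeline
#'
#' For every paired record: loads the pre and post images (colorized PNG/JPG
#' converted through the configured colorbar, or DICOM temperature maps
#' used as-is) and masks, extracts the feature vectors, then screens all
#' features for expression. Writes `features_pre.csv`, `features_post.csv`,
#' `delta.csv`, `summary.json` and a `manifest.json` with input/output
#' checksums sufficient to verify a bit-identical re-run.
#'
#' @param config a [run_config()] or path to its JSON serialization.
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  lut <- build_lut(colorbar_spec(config$t_min, config$t_max, config$colormap))
  settings <- extraction_settings(bin_width = config$bin_width,
                                  wavelet = config$wavelet)
  pairs <- config$pairs
  rows_pre <- list(); rows_post <- list()
  for (k in seq_len(nrow(pairs))) {
    id <- pairs$id[k]
    for (cond in c("pre", "post")) {
      img_path <- pairs[[paste0(cond, "_image")]][k]
      mask_path <- pairs[[paste0(cond, "_mask")]][k]
      tmap <- load_temperature_input(img_path, lut,
                                     paste0(id, " (", cond, "-milking)"))
      if (!file.exists(mask_path))
        stop("missing mask for ", id, " (", cond, "-milking): ", mask_path)
      mask <- read_mask_png(mask_path)
      fv <- extract_all(tmap, mask, settings)
      if (cond == "pre") rows_pre[[id]] <- fv else rows_post[[id]] <- fv
    }
  }
  pre <- do.call(rbind, rows_pre); rownames(pre) <- names(rows_pre)
  post <- do.call(rbind, rows_post); rownames(post) <- names(rows_post)
  screen <- expression_screen(pre, post, p_thresh = config$p_thresh,
                              d_thresh = config$d_thresh)

  paths <- file.path(config$outdir,
                     c("features_pre.csv", "features_post.csv", "delta.csv",
                       "summary.json"))
  write_feature_csv(pre, paths[1])
  write_feature_csv(post, paths[2])
  utils::write.csv(screen, paths[3], row.names = FALSE)
  jsonlite::write_json(list(n_teats = nrow(pre),
                            n_features = ncol(pre),
                            counts = expression_counts(screen),
                            p_thresh = config$p_thresh,
                            d_thresh = config$d_thresh),
                       paths[4], auto_unbox = TRUE, digits = NA)

  input_files <- unlist(pairs[, c("pre_image", "pre_mask", "post_image",
                                  "post_mask")], use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("teatherm")),
    seed = config$seed,
    settings = list(t_min = config$t_min, t_max = config$t_max,
                    colormap = config$colormap, bin_width = config$bin_width,
                    wavelet = config$wavelet, p_thresh = config$p_thresh,
                    d_thresh = config$d_thresh),
    inputs = as.list(tools::md5sum(input_files)),
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a phantom cohort to disk as pipeline inputs
#'
#' Materializes a [generate_cohort()] result as the file layout
#' [run_pipeline()] consumes: per teat and condition a colorized PNG (with
#' JSON sidecar), a mask PNG, and a ground-truth DICOM; plus a `pairs.csv`
#' manifest.
#'
#' @param cohort a rendered [generate_cohort()] result.
#' @param outdir output directory.
#' @return the pairs data.frame, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$teats, function(teat) {
    paths <- character(4); names(paths) <- c("pre_image", "pre_mask",
                                             "post_image", "post_mask")
    for (cond in c("pre", "post")) {
      gen <- teat[[cond]]
      if (is.null(gen$image)) stop("cohort was generated with render = FALSE")
      base <- file.path(outdir, paste0(teat$id, "_", cond))
      write_thermogram_png(gen$image, paste0(base, ".png"))
      jsonlite::write_json(list(t_min = gen$spec$t_min,
                                t_max = gen$spec$t_max,
                                colormap = gen$spec$colormap),
                           paste0(base, ".png.json"), auto_unbox = TRUE)
      write_mask_png(gen$masks[[1]], paste0(base, "_mask.png"))
      write_dicom(gen$tmap, paste0(base, ".dcm"))
      paths[paste0(cond, "_image")] <- paste0(base, ".png")
      paths[paste0(cond, "_mask")] <- paste0(base, "_mask.png")
    }
    data.frame(id = teat$id, t(paths))
  })
  pairs <- do.call(rbind, rows)
  utils::write.csv(pairs, file.path(outdir, "pairs.csv"), row.names = FALSE)
  invisible(pairs)
}
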