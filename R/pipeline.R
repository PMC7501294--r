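# End-to-end orchestration: configuration, per-sample segmentation and
# quantification, band fitting on controls, both classifiers, spatial
# enrichment and the long-format export.

#' Classify deficiency for several channels at once
#'
#' Fits one control band per target channel on the control fibres, applies
#' [classify_2dmito()] to every fibre, computes theta, and runs the
#' theta/KDE classifier per patient sample against the pooled control
#' thetas. Control fibres carry 2Dmito calls (useful for coverage checks)
#' but no KDE call.
#'
#' @param fibres Fibre table with `fibre`, `sample`, logical `control`,
#'   the reference column and every channel column.
#' @param channels Target channel names.
#' @param reference Mitochondrial-mass channel, default `"VDAC1"`.
#' @param level Band and percentile-gate level.
#' @param scale `"log"` or `"linear"`.
#'
#' @return An object of class `deficiency_calls`: list with `calls` (long
#'   tibble: `sample`, `control`, `fibre`, `channel`, `value`,
#'   `reference`, `theta`, `call_2dmito`, `call_kde`) and `bands` (named
#'   list of [regression_band()]s).
#' @export
classify_deficiency <- function(fibres, channels, reference = "VDAC1",
                                level = 0.95, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  need <- c("fibre", "sample", "control", reference, channels)
  if (!all(need %in% names(fibres))) {
    abort(paste("fibres table lacks columns:",
                paste(setdiff(need, names(fibres)), collapse = ", ")))
  }
  controls <- dplyr::filter(fibres, .data$control)
  if (nrow(controls) < 3) abort("need at least 3 control fibres to fit bands")
  bands <- lapply(channels, function(ch) {
    fit_control_band(controls, ch, reference, level, scale)
  })
  names(bands) <- channels

  long <- purrr::map_dfr(channels, function(ch) {
    cl <- classify_2dmito(fibres, bands[[ch]])
    tibble(sample = fibres$sample, control = fibres$control,
           fibre = fibres$fibre, channel = ch,
           value = fibres[[ch]], reference = fibres[[reference]],
           theta = theta(cl$.y, cl$.x), call_2dmito = cl$call,
           call_kde = NA)
  })

  for (ch in channels) {
    ctrl_th <- long$theta[long$channel == ch & long$control]
    for (smp in unique(long$sample[!long$control])) {
      sel <- which(long$channel == ch & long$sample == smp & !long$control)
      if (length(sel) >= 2 && sum(is.finite(ctrl_th)) >= 2) {
        kd <- classify_theta_kde(long$theta[sel], ctrl_th, level = level)
        long$call_kde[sel] <- kd$affected
      }
    }
  }
  structure(list(calls = long, bands = bands, reference = reference,
                 level = level, scale = scale),
            class = "deficiency_calls")
}

#' @export
print.deficiency_calls <- function(x, ...) {
  cat(sprintf("<deficiency_calls> %d fibre x channel rows, %d channels, level %.2f (%s scale)\n",
              nrow(x$calls), length(x$bands), x$level, x$scale))
  invisible(x)
}

#' @method glance deficiency_calls
#' @export
glance.deficiency_calls <- function(x, ...) {
  purrr::map_dfr(x$bands, glance)
}

#' Export per-fibre calls as a long-format CSV
#'
#' One row per fibre and channel with the linear-scale value, reference
#' value, theta and both calls — the layout consumed by interactive
#' fibre-level viewers. Reading the file back reproduces the calls
#' exactly.
#'
#' @param calls A [classify_deficiency()] result (or its `calls` tibble).
#' @param path Optional CSV path; when given the table is written there.
#'
#' @return The long tibble, invisibly when `path` is given.
#' @export
export_long <- function(calls, path = NULL) {
  long <- if (inherits(calls, "deficiency_calls")) calls$calls else as_tibble(calls)
  if (!is.null(path)) {
    readr::write_csv(long, path)
    return(invisible(long))
  }
  long
}

#' Assemble a pipeline run configuration
#'
#' @param samples List of per-sample entries, each a list with `id`,
#'   logical `control`, and `paths` (named character vector,
#'   channel -> TIFF path).
#' @param membrane_channel Channel used for segmentation.
#' @param reference Mitochondrial-mass channel; must be present in every
#'   sample.
#' @param channels Target channels to classify; default: all channels
#'   except the membrane, reference and `DNA`.
#' @param scale,level As in [classify_deficiency()].
#' @param filter A [morphology_filter()].
#' @param multiplier Neighbourhood threshold multiplier.
#' @param deficiency_channel Channel whose `below` calls define the
#'   deficient flag for spatial testing; default the first target channel.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Output directory.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples, out_dir, membrane_channel = "Dystrophin",
                       reference = "VDAC1", channels = NULL,
                       scale = "log", level = 0.95,
                       filter = morphology_filter(), multiplier = 5,
                       deficiency_channel = NULL, seed = 1L) {
  if (length(samples) == 0) abort("no samples configured")
  for (s in samples) {
    if (!all(c(membrane_channel, reference) %in% names(s$paths))) {
      abort(sprintf("sample %s lacks the %s or %s channel",
                    s$id, membrane_channel, reference))
    }
  }
  structure(list(samples = samples, out_dir = out_dir,
                 membrane_channel = membrane_channel, reference = reference,
                 channels = channels, scale = scale, level = level,
                 filter = filter, multiplier = multiplier,
                 deficiency_channel = deficiency_channel, seed = seed),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors [run_config()]: a `samples` array (objects with `id`,
#' `control`, `channels` mapping channel names to TIFF paths, relative to
#' the JSON file) plus any scalar option.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path)
  base <- dirname(path)
  samples <- lapply(j$samples, function(s) {
    paths <- unlist(s$channels)
    rel <- !grepl("^/", paths)
    paths[rel] <- file.path(base, paths[rel])
    list(id = s$id, control = isTRUE(s$control), paths = paths)
  })
  filt <- do.call(morphology_filter, j$filter %||% list())
  run_config(samples = samples,
             out_dir = j$out_dir %||% file.path(base, "out"),
             membrane_channel = j$membrane_channel %||% "Dystrophin",
             reference = j$reference %||% "VDAC1",
             channels = unlist(j$target_channels),
             scale = j$scale %||% "log",
             level = j$level %||% 0.95,
             filter = filt,
             multiplier = j$multiplier %||% 5,
             deficiency_channel = j$deficiency_channel,
             seed = j$seed %||% 1L)
}

#' Run the full analysis pipeline
#'
#' Per sample: read the TIFF stack, segment on the membrane channel,
#' filter regions by morphology and extract features. Then fit control
#' bands, classify every fibre with both methods, test spatial enrichment
#' of deficient fibres per patient sample, and write all artefacts to the
#' output directory: `fibres.csv` (per-fibre features), `calls.csv`
#' (long-format calls), `bands.json`, `enrichment.json`, per-patient
#' fibre maps (`<id>_fibre_map.csv`: centroid, effective radius, theta,
#' deficient and neighbour flags, enough to redraw the spatial deficiency
#' map), per-sample label maps (`<id>_labels.tiff`) and `run_log.txt`.
#' Reruns with the same
#' configuration are reproducible.
#'
#' @param config A [run_config()] or a path to its JSON form.
#'
#' @return Invisibly, a list with `fibres`, `calls`
#'   (`deficiency_calls`), `enrichment` (named list per patient sample)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  per_sample <- lapply(config$samples, function(s) {
    stack <- read_image_stack(s$paths)
    labs <- segment_fibres(stack[[config$membrane_channel]])
    labs <- filter_regions(labs, config$filter)
    tiff::writeTIFF(labs / max(max(labs), 1),
                    file.path(config$out_dir, paste0(s$id, "_labels.tiff")),
                    bits.per.sample = 16L)
    feats <- extract_features(labs, stack)
    dplyr::mutate(feats, sample = s$id, control = s$control,
                  .before = 1)
  })
  fibres <- dplyr::bind_rows(per_sample)
  if (nrow(fibres) == 0) abort("no fibres survived segmentation and filtering")
  readr::write_csv(fibres, file.path(config$out_dir, "fibres.csv"))

  channels <- config$channels %||%
    setdiff(names(config$samples[[1]]$paths),
            c(config$membrane_channel, config$reference, "DNA"))
  if (length(channels) == 0) abort("no target channels to classify")
  calls <- classify_deficiency(fibres, channels, config$reference,
                               config$level, config$scale)
  export_long(calls, file.path(config$out_dir, "calls.csv"))
  jsonlite::write_json(
    lapply(calls$bands, function(b) unclass(b)),
    file.path(config$out_dir, "bands.json"), auto_unbox = TRUE, digits = NA)

  def_ch <- config$deficiency_channel %||% channels[1]
  enrichment <- list()
  for (s in config$samples) {
    if (s$control) next
    fs <- dplyr::filter(fibres, .data$sample == s$id)
    if (nrow(fs) < 2) next
    cl <- dplyr::filter(calls$calls, .data$sample == s$id,
                        .data$channel == def_ch)
    deficient <- cl$call_2dmito[match(fs$fibre, cl$fibre)] == "below"
    g <- build_neighbour_graph(fs, config$multiplier)
    enr <- neighbourhood_enrichment(g, deficient)
    enrichment[[s$id]] <- enr
    fmap <- tibble(fibre = fs$fibre, x = fs$x, y = fs$y,
                   radius = effective_radius(fs$area),
                   theta = cl$theta[match(fs$fibre, cl$fibre)],
                   deficient = deficient,
                   neighbour = seq_len(nrow(fs)) %in% enr$neighbour_set)
    readr::write_csv(fmap, file.path(config$out_dir,
                                     paste0(s$id, "_fibre_map.csv")))
  }
  jsonlite::write_json(
    lapply(enrichment, function(e) unclass(e)[c("N", "K", "n", "k", "p")]),
    file.path(config$out_dir, "enrichment.json"),
    auto_unbox = TRUE, digits = NA)

  writeLines(c(
    paste0("fibreimc ", as.character(utils::packageVersion("fibreimc"))),
    paste0("R ", R.version.string),
    paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed ", config$seed),
    paste0("membrane_channel ", config$membrane_channel),
    paste0("reference ", config$reference),
    paste0("channels ", paste(channels, collapse = ",")),
    paste0("scale ", config$scale),
    paste0("level ", config$level),
    paste0("multiplier ", config$multiplier),
    paste0("deficiency_channel ", def_ch)),
    file.path(config$out_dir, "run_log.txt"))

  invisible(list(fibres = fibres, calls = calls, enrichment = enrichment,
                 out_dir = config$out_dir))
}

#' Write a synthetic dataset to disk
#'
#' Generates a mosaic from the spec and writes one 16-bit TIFF per
#' channel (`<sample>_<channel>.tiff`), the ground-truth table
#' (`<sample>_truth.csv`) and the spec itself (`<sample>_spec.json`), so
#' the dataset is fully determined by the JSON file.
#'
#' @param spec A [mosaic_spec()].
#' @param dir Output directory.
#' @param sample Sample identifier prefix.
#' @return Invisibly, the generated `imc_mosaic`.
#' @export
write_mosaic_dataset <- function(spec, dir, sample = "synthetic") {
  mos <- generate_mosaic(spec)
  write_image_stack(mos$stack, dir, sample)
  readr::write_csv(mos$truth, file.path(dir, paste0(sample, "_truth.csv")))
  m <- spec$intensity_model
  jsonlite::write_json(
    list(field_size = spec$field_size, n_fibres = spec$n_fibres,
         membrane_width = spec$membrane_width, rng_seed = spec$rng_seed,
         deficient_fraction = spec$deficient_fraction,
         deficiency_factor = spec$deficiency_factor,
         rrf_fraction = spec$rrf_fraction,
         rrf_vdac_factor = spec$rrf_vdac_factor,
         spatial_clustering = spec$spatial_clustering,
         membrane_level = spec$membrane_level,
         background_level = spec$background_level,
         dna_level = spec$dna_level,
         intensity_model = list(
           intercepts = as.list(m$intercepts), slopes = as.list(m$slopes),
           sigmas = as.list(m$sigmas), vdac_logmean = m$vdac_logmean,
           vdac_logsd = m$vdac_logsd, count_noise = m$count_noise,
           affected = m$affected)),
    file.path(dir, paste0(sample, "_spec.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(mos)
}

#' Read a mosaic spec back from its JSON form
#'
#' @param path JSON written by [write_mosaic_dataset()] (or hand-written
#'   in the same shape).
#' @return A [mosaic_spec()].
#' @export
read_mosaic_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (is.null(j$intensity_model)) control_model() else {
    im <- j$intensity_model
    control_model(intercepts = unlist(im$intercepts),
                  slopes = unlist(im$slopes), sigmas = unlist(im$sigmas),
                  vdac_logmean = im$vdac_logmean, vdac_logsd = im$vdac_logsd,
                  count_noise = isTRUE(im$count_noise),
                  affected = unlist(im$affected))
  }
  sc <- j$spatial_clustering
  if (!is.null(sc) && length(sc) == 0) sc <- NULL
  mosaic_spec(field_size = unlist(j$field_size), n_fibres = j$n_fibres,
              membrane_width = j$membrane_width %||% 3,
              rng_seed = j$rng_seed %||% 1L, intensity_model = model,
              deficient_fraction = j$deficient_fraction %||% 0,
              deficiency_factor = j$deficiency_factor %||% 1,
              rrf_fraction = j$rrf_fraction %||% 0,
              rrf_vdac_factor = j$rrf_vdac_factor %||% 3,
              spatial_clustering = sc,
              membrane_level = j$membrane_level %||% 20000,
              background_level = j$background_level %||% 2,
              dna_level = j$dna_level %||% 5000)
}
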