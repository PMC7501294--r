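#' Control-population intensity model
#'
#' Describes, on the natural-log scale, how per-fibre mean channel
#' intensities relate to mitochondrial mass in biochemically normal fibres.
#' Log-VDAC1 is drawn from a normal distribution, and each target channel
#' `c` follows the control log-linear relation
#' `log I_c = alpha_c + beta_c * log V + Normal(0, sigma_c)`.
#' This is the generative counterpart of the control cloud of a
#' target-versus-VDAC1 ("2Dmito") scatterplot, where control fibres form a
#' tight band through the origin region of the log-log plane.
#'
#' Defaults give count-scale intensities comfortably inside the 16-bit
#' range (VDAC1 around 150 counts) and a control theta near 50 degrees.
#'
#' @param intercepts Named numeric vector: per-channel intercept `alpha_c`
#'   (log counts).
#' @param slopes Named numeric vector, same names: slope `beta_c` on
#'   log-VDAC1 (dimensionless).
#' @param sigmas Named numeric vector, same names: residual sd `sigma_c`
#'   (log scale, >= 0).
#' @param vdac_logmean,vdac_logsd Mean and sd of log-VDAC1 (log counts).
#' @param count_noise If `TRUE`, pixel values are Poisson draws around the
#'   per-fibre mean (IMC measures ion counts); if `FALSE`, pixels carry the
#'   rounded mean exactly.
#' @param affected Channels suppressed in deficient fibres; defaults to all
#'   target channels.
#'
#' @return An object of class `control_model`.
#' @examples
#' control_model()
#' @export
control_model <- function(intercepts = c(NDUFB8 = 0.55, MTCO1 = 0.35, SDHA = 0.80),
                          slopes = c(NDUFB8 = 1.0, MTCO1 = 1.0, SDHA = 0.9),
                          sigmas = c(NDUFB8 = 0.15, MTCO1 = 0.15, SDHA = 0.12),
                          vdac_logmean = 5.0,
                          vdac_logsd = 0.35,
                          count_noise = FALSE,
                          affected = names(intercepts)) {
  nms <- names(intercepts)
  if (is.null(nms) || !identical(nms, names(slopes)) ||
      !identical(nms, names(sigmas))) {
    abort("intercepts, slopes and sigmas must share the same channel names")
  }
  if (any(sigmas < 0)) abort("sigmas must be >= 0")
  if (any(!is.finite(slopes)) || any(!is.finite(intercepts))) {
    abort("slopes and intercepts must be finite")
  }
  if (vdac_logsd < 0) abort("vdac_logsd must be >= 0")
  if (!all(affected %in% nms)) abort("affected channels must be model channels")
  structure(list(intercepts = intercepts, slopes = slopes, sigmas = sigmas,
                 vdac_logmean = vdac_logmean, vdac_logsd = vdac_logsd,
                 count_noise = count_noise, affected = affected),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat("<control_model> log I_c = alpha_c + beta_c * log(VDAC1) + N(0, sigma_c)\n")
  print(tibble(channel = names(x$intercepts), alpha = unname(x$intercepts),
               beta = unname(x$slopes), sigma = unname(x$sigmas)))
  cat(sprintf("  log VDAC1 ~ N(%.2f, %.2f); count_noise = %s\n",
              x$vdac_logmean, x$vdac_logsd, x$count_noise))
  invisible(x)
}

#' Sample a synthetic per-fibre intensity table
#'
#' Tabular-only companion of [generate_mosaic()]: draws per-fibre channel
#' means from a [control_model()] without any image geometry, for testing
#' the statistical stages directly. A `deficient_fraction` of fibres has
#' its affected-channel intensities multiplied by `deficiency_factor` on
#' the linear scale, emulating loss of oxidative-phosphorylation protein
#' relative to mitochondrial mass.
#'
#' @param model A [control_model()].
#' @param n Number of fibres (>= 1).
#' @param deficient_fraction Proportion of deficient fibres in `[0, 1]`.
#' @param deficiency_factor Multiplicative suppression in `(0, 1]` applied
#'   to affected channels of deficient fibres.
#' @param seed Integer RNG seed; the same seed and arguments reproduce the
#'   table exactly.
#'
#' @return A tibble with one row per fibre: `fibre`, `VDAC1`, one column
#'   per model channel (linear-scale mean intensities), and a logical
#'   `deficient` truth label.
#' @examples
#' tab <- sample_fibre_table(control_model(), 10, 0.3, 0.2, seed = 1)
#' tab
#' @export
sample_fibre_table <- function(model, n, deficient_fraction = 0,
                               deficiency_factor = 1, seed = 1L) {
  stopifnot(inherits(model, "control_model"))
  if (n < 1) abort("n must be >= 1")
  check_fraction(deficient_fraction, "deficient_fraction")
  check_factor(deficiency_factor)
  withr::with_seed(seed, {
    logv <- rnorm(n, model$vdac_logmean, model$vdac_logsd)
    n_def <- round(deficient_fraction * n)
    deficient <- rep(FALSE, n)
    if (n_def > 0) deficient[sample.int(n, n_def)] <- TRUE
    chans <- lapply(names(model$intercepts), function(ch) {
      y <- exp(model$intercepts[[ch]] + model$slopes[[ch]] * logv +
                 rnorm(n, 0, model$sigmas[[ch]]))
      if (ch %in% model$affected) y[deficient] <- y[deficient] * deficiency_factor
      y
    })
    names(chans) <- names(model$intercepts)
    tibble(fibre = seq_len(n), VDAC1 = exp(logv), !!!chans,
           deficient = deficient)
  })
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1) {
    abort(paste0(what, " must be a proportion in [0, 1]"))
  }
}

check_factor <- function(x) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1) {
    abort("deficiency_factor must lie in (0, 1]")
  }
}

#' Specify a synthetic muscle-section mosaic
#'
#' Bundles the geometry and intensity parameters that fully determine a
#' synthetic pseudo-image dataset (together these and the seed make
#' [generate_mosaic()] bit-reproducible). Fibre cross-sections are cells of
#' a Lloyd-relaxed Voronoi tessellation; cells touching the field border
#' are discarded, leaving convex, roughly isotropic interiors bounded by a
#' bright membrane band in the Dystrophin channel.
#'
#' @param field_size Field dimensions in px as `c(width, height)` (a single
#'   number means a square field). 1 px = 1 um^2.
#' @param n_fibres Number of Voronoi seeds (>= 1); the emitted fibre count
#'   is smaller because border cells are clipped.
#' @param membrane_width Width of the membrane band in px (>= 1).
#' @param rng_seed Integer seed.
#' @param intensity_model A [control_model()].
#' @param deficient_fraction,deficiency_factor As in
#'   [sample_fibre_table()].
#' @param rrf_fraction Proportion of fibres given pathologically elevated
#'   VDAC1 (ragged-red-like fibres).
#' @param rrf_vdac_factor VDAC1 multiplier (> 1) for ragged-red-like
#'   fibres; target channels follow the control relation at the elevated
#'   mass.
#' @param spatial_clustering `NULL` for uniformly random deficiency
#'   labels, or `list(cluster_count = , cluster_radius = )` (radius in px)
#'   to concentrate deficient fibres around randomly chosen cluster
#'   centres.
#' @param membrane_level,background_level,dna_level Dystrophin membrane
#'   intensity, off-membrane background intensity, and nuclear-blob
#'   intensity (16-bit counts).
#'
#' @return An object of class `mosaic_spec`.
#' @examples
#' mosaic_spec(field_size = 300, n_fibres = 20, rng_seed = 7)
#' @export
mosaic_spec <- function(field_size = 600, n_fibres = 50, membrane_width = 3,
                        rng_seed = 1L, intensity_model = control_model(),
                        deficient_fraction = 0, deficiency_factor = 1,
                        rrf_fraction = 0, rrf_vdac_factor = 3,
                        spatial_clustering = NULL,
                        membrane_level = 20000, background_level = 2,
                        dna_level = 5000) {
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  if (n_fibres < 1) abort("n_fibres must be >= 1")
  if (membrane_width < 1) abort("membrane_width must be >= 1")
  stopifnot(inherits(intensity_model, "control_model"))
  check_fraction(deficient_fraction, "deficient_fraction")
  check_factor(deficiency_factor)
  check_fraction(rrf_fraction, "rrf_fraction")
  if (rrf_vdac_factor <= 1) abort("rrf_vdac_factor must be > 1")
  if (!is.null(spatial_clustering)) {
    if (!all(c("cluster_count", "cluster_radius") %in% names(spatial_clustering))) {
      abort("spatial_clustering needs cluster_count and cluster_radius")
    }
  }
  mean_cell <- prod(field_size) / n_fibres
  if (mean_cell < 50) {
    abort("field too small: mean Voronoi cell below a plausible fibre area")
  }
  structure(list(field_size = as.integer(field_size),
                 n_fibres = as.integer(n_fibres),
                 membrane_width = as.numeric(membrane_width),
                 rng_seed = as.integer(rng_seed),
                 intensity_model = intensity_model,
                 deficient_fraction = as.numeric(deficient_fraction),
                 deficiency_factor = as.numeric(deficiency_factor),
                 rrf_fraction = as.numeric(rrf_fraction),
                 rrf_vdac_factor = as.numeric(rrf_vdac_factor),
                 spatial_clustering = spatial_clustering,
                 membrane_level = as.numeric(membrane_level),
                 background_level = as.numeric(background_level),
                 dna_level = as.numeric(dna_level)),
            class = "mosaic_spec")
}

#' @export
print.mosaic_spec <- function(x, ...) {
  cat(sprintf("<mosaic_spec> %d x %d px, %d seeds, membrane %d px, seed %d\n",
              x$field_size[1], x$field_size[2], x$n_fibres,
              x$membrane_width, x$rng_seed))
  cat(sprintf("  deficient %.2f (factor %.2f), rrf %.2f (x%.1f VDAC1)\n",
              x$deficient_fraction, x$deficiency_factor, x$rrf_fraction,
              x$rrf_vdac_factor))
  invisible(x)
}

# Nearest / second-nearest Voronoi assignment over the pixel grid.
# Returns label matrix and the two smallest seed distances per pixel.
voronoi_assign <- function(sx, sy, W, H) {
  d1 <- matrix(Inf, H, W); d2 <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  xs <- 1:W; ys <- 1:H
  for (k in seq_along(sx)) {
    d <- outer((ys - sy[k])^2, (xs - sx[k])^2, "+")
    closer <- d < d1
    d2[closer] <- d1[closer]
    d2[!closer & d < d2] <- d[!closer & d < d2]
    d1[closer] <- d[closer]
    lab[closer] <- k
  }
  list(lab = lab, d1 = sqrt(d1), d2 = sqrt(d2))
}

#' Assign deficiency labels, optionally spatially clustered
#'
#' Labels `round(fraction * n)` fibres deficient. With clustering, cluster
#' centres are drawn uniformly over the bounding box of the centroids and
#' fibres whose centroids fall within `cluster_radius` of a centre are
#' labelled first (in random order); any remainder is assigned uniformly at
#' random among the rest. Clustered labels give the spatial
#' neighbourhood-enrichment test a detectable alternative.
#'
#' @param fibres Data frame with centroid columns `x` and `y` (px).
#' @param fraction Proportion of fibres to label deficient.
#' @param clustering `NULL`, or `list(cluster_count =, cluster_radius =)`.
#' @param seed Integer seed.
#'
#' @return Logical vector, one element per row of `fibres`.
#' @export
assign_deficiency <- function(fibres, fraction, clustering = NULL, seed = 1L) {
  n <- nrow(fibres)
  check_fraction(fraction, "fraction")
  n_def <- round(fraction * n)
  withr::with_seed(seed, {
    deficient <- rep(FALSE, n)
    if (n_def == 0) return(deficient)
    if (is.null(clustering)) {
      deficient[sample.int(n, n_def)] <- TRUE
      return(deficient)
    }
    cx <- runif(clustering$cluster_count, min(fibres$x), max(fibres$x))
    cy <- runif(clustering$cluster_count, min(fibres$y), max(fibres$y))
    dmin <- do.call(pmin, lapply(seq_along(cx), function(j) {
      sqrt((fibres$x - cx[j])^2 + (fibres$y - cy[j])^2)
    }))
    inside <- which(dmin <= clustering$cluster_radius)
    take <- utils::head(sample(inside), n_def)
    deficient[take] <- TRUE
    left <- n_def - length(take)
    if (left > 0) {
      pool <- setdiff(seq_len(n), take)
      deficient[sample(pool, left)] <- TRUE
    }
    deficient
  })
}

#' Generate a synthetic pseudo-image mosaic with ground truth
#'
#' Builds a mosaic of convex fibre cross-sections (Lloyd-relaxed Voronoi
#' cells, border cells discarded) and paints one 16-bit channel image per
#' channel of the intensity model plus a bright membrane band in
#' `Dystrophin` and small peripheral nuclear blobs in `DNA`. Per-fibre
#' channel means follow the control log-linear relation to VDAC1;
#' deficient and ragged-red-like subpopulations are injected according to
#' the spec. The same spec (including its seed) always yields bit-identical
#' output.
#'
#' @param spec A [mosaic_spec()].
#'
#' @return A list of class `imc_mosaic` with elements
#'   * `stack`: the [image_stack()] (model channels + `VDAC1`,
#'     `Dystrophin`, `DNA`);
#'   * `truth`: ground-truth tibble, one row per surviving fibre (`fibre`,
#'     centroid `x`, `y`, `area`, per-channel painted means, `deficient`,
#'     `rrf`);
#'   * `labels`: integer matrix, 0 = membrane/clipped, k = fibre k;
#'   * `membrane`: logical matrix of the noiseless membrane band.
#' @examples
#' mos <- generate_mosaic(mosaic_spec(field_size = 250, n_fibres = 12,
#'                                    rng_seed = 2))
#' nrow(mos$truth)
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  model <- spec$intensity_model
  W <- spec$field_size[1]; H <- spec$field_size[2]
  withr::with_seed(spec$rng_seed, {
    sx <- runif(spec$n_fibres, 1, W)
    sy <- runif(spec$n_fibres, 1, H)
    va <- NULL
    for (it in 1:3) {        # Lloyd relaxation: centroids of current cells
      va <- voronoi_assign(sx, sy, W, H)
      cx <- tapply(rep(1:W, each = H), va$lab, mean)
      cy <- tapply(rep(1:H, W), va$lab, mean)
      keep <- as.integer(names(cx))
      sx[keep] <- cx; sy[keep] <- cy
    }
    va <- voronoi_assign(sx, sy, W, H)
    membrane <- (va$d2 - va$d1) < spec$membrane_width
    border_labs <- unique(c(va$lab[1, ], va$lab[H, ], va$lab[, 1], va$lab[, W]))
    survivors <- setdiff(sort(unique(as.vector(va$lab))), border_labs)
    labels <- matrix(0L, H, W)
    for (i in seq_along(survivors)) {
      labels[va$lab == survivors[i] & !membrane] <- i
    }
    K <- length(survivors)
    if (K == 0) abort("no fibre survived border clipping; enlarge the field")

    cen_x <- tapply(rep(1:W, each = H)[labels > 0], labels[labels > 0], mean)
    cen_y <- tapply(rep(1:H, W)[labels > 0], labels[labels > 0], mean)
    areas <- tabulate(labels[labels > 0], K)

    # per-fibre intensities from the control model + pathology mixtures
    logv <- rnorm(K, model$vdac_logmean, model$vdac_logsd)
    truth <- tibble(fibre = seq_len(K), x = as.numeric(cen_x),
                    y = as.numeric(cen_y), area = areas)
    truth$deficient <- assign_deficiency(
      truth, spec$deficient_fraction, spec$spatial_clustering,
      seed = sample.int(.Machine$integer.max, 1))
    n_rrf <- round(spec$rrf_fraction * K)
    rrf <- rep(FALSE, K)
    if (n_rrf > 0) rrf[sample.int(K, n_rrf)] <- TRUE
    logv[rrf] <- logv[rrf] + log(spec$rrf_vdac_factor)
    truth$rrf <- rrf

    means <- list(VDAC1 = exp(logv))
    for (ch in names(model$intercepts)) {
      y <- exp(model$intercepts[[ch]] + model$slopes[[ch]] * logv +
                 rnorm(K, 0, model$sigmas[[ch]]))
      if (ch %in% model$affected) {
        y[truth$deficient] <- y[truth$deficient] * spec$deficiency_factor
      }
      means[[ch]] <- y
    }

    # paint channels
    stack <- list()
    fibre_px <- split(which(labels > 0), labels[labels > 0])
    paint <- function(mean_per_fibre) {
      img <- matrix(spec$background_level, H, W)
      for (k in seq_len(K)) {
        m <- mean_per_fibre[k]
        v <- if (model$count_noise) rpois(length(fibre_px[[k]]), m) else round(m)
        img[fibre_px[[k]]] <- v
      }
      pmin(pmax(img, 0), 65535)
    }
    for (ch in names(means)) {
      painted <- if (model$count_noise) means[[ch]] else
        pmin(pmax(round(means[[ch]]), 0), 65535)
      truth[[ch]] <- painted
      stack[[ch]] <- paint(means[[ch]])
    }

    dys <- matrix(spec$background_level, H, W)
    dys[membrane] <- spec$membrane_level
    stack$Dystrophin <- dys
    truth$Dystrophin <- rep(spec$background_level, K)

    dna <- matrix(spec$background_level, H, W)
    rim <- (va$d2 - va$d1) < (spec$membrane_width + 3)
    for (k in seq_len(K)) {
      px <- fibre_px[[k]]
      peri <- px[rim[px]]
      if (length(peri) == 0) peri <- px
      centres <- peri[sample.int(length(peri), min(2L, length(peri)))]
      for (p in centres) {
        r0 <- (p - 1) %% H + 1; c0 <- (p - 1) %/% H + 1
        rr <- pmax(1, r0 - 1):pmin(H, r0 + 1)
        cc <- pmax(1, c0 - 1):pmin(W, c0 + 1)
        blob <- as.matrix(expand.grid(rr, cc))
        blob_idx <- blob[, 1] + (blob[, 2] - 1) * H
        blob_idx <- blob_idx[labels[blob_idx] == k]
        dna[blob_idx] <- spec$dna_level
      }
    }
    stack$DNA <- dna
    truth$DNA <- vapply(seq_len(K),
                        function(k) mean(dna[fibre_px[[k]]]), numeric(1))

    structure(list(stack = image_stack(stack), truth = truth,
                   labels = labels, membrane = membrane),
              class = "imc_mosaic")
  })
}

#' @export
print.imc_mosaic <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<imc_mosaic> %d fibres on %d x %d px, %d channels\n",
              nrow(x$truth), d[2], d[1], length(x$stack)))
  invisible(x)
}
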