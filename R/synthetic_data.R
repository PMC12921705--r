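#' Synthetic slide configuration
#'
#' Settings for [simulate_slide()], which paints saturated "stained
#' tissue" blobs on a near-white background so the masking stage can be
#' exercised against a known ground truth: sub-threshold specks that the
#' area filter must remove, and carved holes of configurable area that
#' the hole rule must fill or preserve.
#'
#' @param width,height image size in pixels (>= 256).
#' @param n_blobs number of tissue blobs.
#' @param blob_scale characteristic blob diameter in pixels.
#' @param stain_rgb stain colour (saturated, like an eosin-dominant stain).
#' @param background near-white background RGB.
#' @param speck_count number of small (5x5, area 25 px) isolated specks.
#' @param hole_spec numeric vector of hole areas (px) carved into the
#'   first blob.
#' @param noise_sd per-pixel uniform colour jitter amplitude.
#' @param seed RNG seed; the output is a deterministic function of the
#'   config.
#' @return An object of class `slide_sim_config`.
#' @export
slide_sim_config <- function(width = 768L, height = 768L, n_blobs = 3L,
                             blob_scale = 220L,
                             stain_rgb = c(186, 85, 150),
                             background = c(245, 243, 246),
                             speck_count = 6L, hole_spec = numeric(),
                             noise_sd = 3, seed = 1L) {
  stopifnot(width >= 256, height >= 256, n_blobs >= 0, blob_scale >= 8)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blobs = as.integer(n_blobs), blob_scale = as.integer(blob_scale),
                 stain_rgb = stain_rgb, background = background,
                 speck_count = as.integer(speck_count),
                 hole_spec = as.numeric(hole_spec), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "slide_sim_config")
}

#' Simulate a stained-slide image with ground-truth mask
#'
#' Draws `n_blobs` random discs of saturated stain colour on a near-white
#' background, adds `speck_count` isolated 5x5 specks (below the 100 px
#' component threshold, so a correct masking pipeline removes them) and
#' carves square holes with the areas in `hole_spec` into the first blob.
#' The emitted ground-truth mask is what an ideal pipeline should
#' recover: the blobs, with holes larger than the fill threshold kept as
#' cavities (up to the preservation cap, largest first) and smaller holes
#' filled.
#'
#' @param cfg a [slide_sim_config()].
#' @param params the [mask_params()] the truth should anticipate.
#' @param image_path,truth_path optional PNG output paths.
#' @return List with `image` (a [raster_image()] at x5), `truth` (logical
#'   matrix) and the blob/speck geometry used.
#' @export
simulate_slide <- function(cfg = slide_sim_config(), params = mask_params(),
                           image_path = NULL, truth_path = NULL) {
  with_preserved_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    xg <- matrix(rep(seq_len(w), each = h), h, w)
    yg <- matrix(rep(seq_len(h), w), h, w)
    blob <- matrix(FALSE, h, w)
    discs <- NULL
    for (b in seq_len(cfg$n_blobs)) {
      r <- cfg$blob_scale / 2 * runif(1, 0.7, 1.2)
      cx <- runif(1, r + 8, w - r - 8)
      cy <- runif(1, r + 8, h - r - 8)
      blob <- blob | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
      discs <- rbind(discs, c(cx, cy, r))
    }
    carved <- blob
    holes <- NULL
    if (length(cfg$hole_spec) && !is.null(discs)) {
      cx <- discs[1, 1]; cy <- discs[1, 2]; r <- discs[1, 3]
      ang <- seq(0, 2 * pi, length.out = length(cfg$hole_spec) + 1)[-1]
      for (i in seq_along(cfg$hole_spec)) {
        side <- max(1L, round(sqrt(cfg$hole_spec[i])))
        hx <- round(cx + 0.45 * r * cos(ang[i]) - side / 2)
        hy <- round(cy + 0.45 * r * sin(ang[i]) - side / 2)
        rows <- hy:(hy + side - 1L); cols <- hx:(hx + side - 1L)
        carved[rows, cols] <- FALSE
        holes <- rbind(holes, c(hx, hy, side))
      }
    }
    specks <- matrix(FALSE, h, w)
    placed <- 0
    while (placed < cfg$speck_count) {
      sx <- sample.int(w - 24, 1) + 8
      sy <- sample.int(h - 24, 1) + 8
      rows <- sy:(sy + 4); cols <- sx:(sx + 4)
      # keep specks isolated: clear margin around the blobs
      box <- blob[max(sy - 12, 1):min(sy + 16, h), max(sx - 12, 1):min(sx + 16, w)]
      if (!any(box)) {
        specks[rows, cols] <- TRUE
        placed <- placed + 1
      }
    }
    stained <- carved | specks
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      base <- ifelse(stained, cfg$stain_rgb[ch], cfg$background[ch])
      px[, , ch] <- pmin(255, pmax(0, round(base + runif(h * w, -cfg$noise_sd,
                                                         cfg$noise_sd))))
    }
    img <- raster_image(array(as.integer(px), dim(px)), magnification = 5)
    # ground truth: blobs with small holes filled, big holes kept (capped)
    truth <- blob
    if (!is.null(holes)) {
      areas <- holes[, 3]^2
      big <- which(areas > params$min_hole_px)
      keep <- big[order(-areas[big])][seq_len(min(length(big), params$max_holes))]
      for (i in keep) {
        rows <- holes[i, 2]:(holes[i, 2] + holes[i, 3] - 1L)
        cols <- holes[i, 1]:(holes[i, 1] + holes[i, 3] - 1L)
        truth[rows, cols] <- FALSE
      }
    }
    if (!is.null(image_path)) write_image_png(img, image_path)
    if (!is.null(truth_path)) write_image_png(truth, truth_path)
    list(image = img, truth = truth, discs = discs, holes = holes)
  })
}

#' Synthetic cohort configuration
#'
#' Settings for [simulate_cohort()], which emulates the data model of the
#' survival pipeline: per-slide patch-feature graphs plus overall-survival
#' outcomes following a proportional-hazards law driven by a planted
#' graph-level signal. Each patient has an "aggressive fraction" rho of
#' signal-carrying nodes; their true log-hazard is `beta_true * rho`.
#' Event times are exponential with rate `baseline_rate * exp(eta)` and
#' censoring is independent exponential (`censor_rate`), so the expected
#' event fraction has the closed competing-exponentials form
#' `E[h e^eta / (h e^eta + c)]`. Defaults describe a cohort on the scale
#' the model targets: 80 patients, 1-3 slides each, graphs of a few dozen
#' patches, median survival on the years scale with roughly half the
#' patients censored.
#'
#' @param n_patients cohort size (>= 8).
#' @param slides_per_patient integer range (lo, hi).
#' @param nodes_per_graph integer range (lo, hi).
#' @param feature_dim node feature dimension (512).
#' @param signal_dim_count number of feature dimensions carrying the
#'   planted shift.
#' @param signal_shift mean shift added on signal dimensions of
#'   aggressive nodes.
#' @param aggressive_fraction_range (lo, hi) of the per-patient Uniform
#'   for rho.
#' @param beta_true log-hazard per unit rho.
#' @param baseline_rate baseline event rate (events / month).
#' @param censor_rate censoring rate (events / month).
#' @param time_dist `"exponential"` or `"weibull"` (proportional-hazards
#'   Weibull baseline with shape `weibull_shape`).
#' @param weibull_shape Weibull shape when `time_dist = "weibull"`.
#' @param k neighbours for the patch graphs.
#' @param seed RNG seed; fully determines the cohort.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 80L, slides_per_patient = c(1L, 3L),
                              nodes_per_graph = c(16L, 48L), feature_dim = 512L,
                              signal_dim_count = 16L, signal_shift = 2,
                              aggressive_fraction_range = c(0.05, 0.95),
                              beta_true = 2, baseline_rate = 0.008,
                              censor_rate = 0.012,
                              time_dist = c("exponential", "weibull"),
                              weibull_shape = 1.5, k = 8L, seed = 1L) {
  time_dist <- match.arg(time_dist)
  if (aggressive_fraction_range[2] <= aggressive_fraction_range[1]) {
    gs_error("aggressive_fraction_range must have hi > lo", "configuration_error")
  }
  stopifnot(n_patients >= 8, baseline_rate > 0, censor_rate > 0,
            weibull_shape > 0, signal_dim_count <= feature_dim)
  structure(list(n_patients = as.integer(n_patients),
                 slides_per_patient = as.integer(slides_per_patient),
                 nodes_per_graph = as.integer(nodes_per_graph),
                 feature_dim = as.integer(feature_dim),
                 signal_dim_count = as.integer(signal_dim_count),
                 signal_shift = signal_shift,
                 aggressive_fraction_range = aggressive_fraction_range,
                 beta_true = beta_true, baseline_rate = baseline_rate,
                 censor_rate = censor_rate, time_dist = time_dist,
                 weibull_shape = weibull_shape, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

# observed time + event indicator for given linear predictors (used both
# by simulate_cohort and directly in closed-form rate checks)
simulate_survival_times <- function(eta, cfg) {
  n <- length(eta)
  u <- rexp(n, rate = 1)
  t_event <- switch(cfg$time_dist,
    exponential = u / (cfg$baseline_rate * exp(eta)),
    weibull = (u / exp(eta))^(1 / cfg$weibull_shape) / cfg$baseline_rate)
  t_cens <- rexp(n, rate = cfg$censor_rate)
  data.frame(time_months = pmax(pmin(t_event, t_cens), 1e-6),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a patient cohort of patch graphs with planted survival signal
#'
#' Per patient: an aggressive fraction `rho ~ Uniform(lo, hi)`; per
#' slide: nodes with uniform 2D coordinates and standard Gaussian
#' features, except that a rho-fraction of nodes receives a mean shift on
#' the designated signal dimensions (the signal lives in the feature
#' means, not the coordinates, mirroring how pooling summarises patch
#' morphology). Event and censoring times follow the proportional-hazards
#' law described in [cohort_sim_config()].
#'
#' @param cfg a [cohort_sim_config()].
#' @return List with `graphs` (list of `slide_graph`), `survival`
#'   (per-slide data frame: `patient_id`, `slide_id`, `time_months`,
#'   `event`) and `truth` (per-patient `rho` and `eta`).
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  with_preserved_seed(cfg$seed, {
    np <- cfg$n_patients
    rho <- runif(np, cfg$aggressive_fraction_range[1],
                 cfg$aggressive_fraction_range[2])
    eta <- cfg$beta_true * rho
    outc <- simulate_survival_times(eta, cfg)
    graphs <- list()
    surv <- NULL
    for (p in seq_len(np)) {
      pid <- sprintf("P%03d", p)
      ns <- sample_range(cfg$slides_per_patient[1], cfg$slides_per_patient[2])
      for (s in seq_len(ns)) {
        sid <- sprintf("%s_S%d", pid, s)
        n <- sample_range(cfg$nodes_per_graph[1], cfg$nodes_per_graph[2])
        coords <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
        feats <- matrix(rnorm(n * cfg$feature_dim), n, cfg$feature_dim)
        nsig <- round(rho[p] * n)
        if (nsig > 0) {
          sig_nodes <- sample.int(n, nsig)
          feats[sig_nodes, seq_len(cfg$signal_dim_count)] <-
            feats[sig_nodes, seq_len(cfg$signal_dim_count)] + cfg$signal_shift
        }
        graphs[[length(graphs) + 1]] <-
          build_knn_graph(feats, coords, k = cfg$k, slide_id = sid)
        surv <- rbind(surv, data.frame(patient_id = pid, slide_id = sid,
                                       time_months = outc$time_months[p],
                                       event = outc$event[p],
                                       stringsAsFactors = FALSE))
      }
    }
    list(graphs = graphs, survival = surv,
         truth = data.frame(patient_id = sprintf("P%03d", seq_len(np)),
                            rho = rho, eta = eta,
                            time_months = outc$time_months,
                            event = outc$event, stringsAsFactors = FALSE))
  })
}
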