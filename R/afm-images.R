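#' Flatten an AFM topograph
#'
#' Subtracts the least-squares background plane (order 1) or offset
#' (order 0). The fit uses only pixels below the image median plus one
#' standard deviation, so that tall surface features do not pull the plane up
#' and suppress their own heights.
#'
#' @param topo A `"topograph"` matrix (heights in nm) or plain matrix.
#' @param order 0 (offset) or 1 (plane).
#' @return The flattened topograph (attributes preserved); the background
#'   pixels have mean ~0 afterwards.
#' @examples
#' topo <- simulate_topograph(NULL, c(64, 64), noise_sd = 0.1, tilt = 2,
#'                            seed = 1)
#' sd(as.numeric(flatten(topo))) # ~0.1 (tilt removed)
#' @export
flatten <- function(topo, order = 1) {
  if (!order %in% c(0, 1)) {
    abort("`order` must be 0 or 1.", class = "smforce_error")
  }
  nr <- nrow(topo)
  rr <- as.numeric(row(topo))
  cc <- as.numeric(col(topo))
  fit_plane <- function(z, mask) {
    if (order == 0) return(rep(mean(z[mask]), length(z)))
    co <- coef(lm(z[mask] ~ rr[mask] + cc[mask]))
    co[[1]] + co[[2]] * rr + co[[3]] * cc
  }
  z <- as.numeric(topo)
  ## first pass: exclude features (tall pixels) with a one-sided cut
  mask <- z < median(z) + sd(z)
  z <- z - fit_plane(z, mask)
  ## refinement: the one-sided cut truncates the noise asymmetrically and
  ## biases the fitted offset; re-fit on a symmetric band around the
  ## background level until stable
  for (i in 1:3) {
    m0 <- median(z[mask])
    s0 <- sd(z[mask])
    if (!is.finite(s0) || s0 < 1e-9) break # noise-free background
    band <- abs(z - m0) < 2 * s0
    if (sum(band) < 30) break
    z <- z - fit_plane(z, band)
    z <- z - median(z[band])
  }
  out <- matrix(z, nrow = nr)
  attributes(out) <- attributes(topo)
  out
}

#' Segment surface features above a height threshold
#'
#' Thresholds the flattened image and labels 4-connected components
#' (via [EBImage::bwlabel()]); components smaller than `min_pixels` are
#' discarded as noise.
#'
#' @param topo Flattened `"topograph"`.
#' @param threshold_nm Height threshold; default
#'   `max(3 * background SD, 0.5)` nm, the background SD estimated robustly
#'   from the pixels below `median + 1 SD`.
#' @param min_pixels Minimum component size in pixels.
#' @return Integer label matrix (0 = background, 1..n = features) with
#'   attributes `n_features`, `threshold_nm` and the input's
#'   `pixel_size_nm`.
#' @export
segment_features <- function(topo, threshold_nm = NULL, min_pixels = 4) {
  z <- as.numeric(topo)
  if (is.null(threshold_nm)) {
    bg <- z[z < median(z) + sd(z)]
    threshold_nm <- max(3 * sd(bg), 0.5)
  }
  if (threshold_nm <= 0) {
    abort("`threshold_nm` must be positive.", class = "smforce_error")
  }
  bin <- matrix(as.numeric(unclass(topo) > threshold_nm), nrow = nrow(topo))
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow = nrow(topo))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_pixels)
  relabel <- integer(max(lab, 1))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  structure(lab, n_features = length(keep), threshold_nm = threshold_nm,
            pixel_size_nm = attr(topo, "pixel_size_nm"))
}

#' Measure segmented features
#'
#' Per-feature morphometrics from the label matrix and the flattened
#' heights: area, maximum and mean height, principal-axis length and width
#' (extent of the pixel cloud along its principal axes), aspect ratio, and a
#' crest height (mean of the per-position maxima along the major axis —
#' the natural height readout for a ridge-like feature).
#'
#' The reported maximum height is refined by fitting a local quadratic
#' surface around the apex pixel and reading its peak. Taking the raw pixel
#' maximum over a noisy feature selects for positive noise excursions and
#' overestimates heights by several noise SDs; the quadratic refinement is
#' unbiased on dome-shaped apexes and averages the noise down.
#'
#' @param topo Flattened `"topograph"`.
#' @param labels Label matrix from [segment_features()].
#' @return A tibble, one row per feature: `feature`, `area_nm2`,
#'   `max_height_nm`, `mean_height_nm`, `crest_height_nm`, `length_nm`,
#'   `width_nm`, `aspect_ratio`.
#' @export
measure_features <- function(topo, labels) {
  px <- attr(topo, "pixel_size_nm")
  if (is.null(px)) px <- attr(labels, "pixel_size_nm")
  if (is.null(px)) abort("pixel size unknown.", class = "smforce_error")
  n <- attr(labels, "n_features")
  if (is.null(n)) n <- max(labels)
  if (n == 0) {
    return(tibble::tibble(
      feature = integer(), area_nm2 = numeric(), max_height_nm = numeric(),
      mean_height_nm = numeric(), crest_height_nm = numeric(),
      length_nm = numeric(), width_nm = numeric(), aspect_ratio = numeric()
    ))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  hts <- unclass(topo)[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1

  zmat <- unclass(topo)
  out <- lapply(seq_len(n), function(i) {
    sel <- lab == i
    h <- hts[sel]
    x <- cols[sel] * px
    y <- rows[sel] * px
    npx <- sum(sel)
    apex <- which.max(h)
    refined <- refine_apex_height(zmat, rows[sel][apex], cols[sel][apex])
    if (npx == 1) {
      maj <- min_ext <- px
      crest <- max(h)
    } else {
      xy <- cbind(x - mean(x), y - mean(y))
      ev <- eigen(stats::cov(xy), symmetric = TRUE)
      p1 <- xy %*% ev$vectors[, 1]
      p2 <- xy %*% ev$vectors[, 2]
      maj <- diff(range(p1)) + px
      min_ext <- diff(range(p2)) + px
      ## crest: max height per pixel-wide slab along the major axis
      bins <- floor((p1 - min(p1)) / px)
      crest <- mean(vapply(split(h, bins), max, numeric(1)))
    }
    tibble::tibble(
      feature = i, area_nm2 = npx * px^2,
      max_height_nm = refined, mean_height_nm = mean(h),
      crest_height_nm = crest,
      length_nm = maj, width_nm = min_ext,
      aspect_ratio = maj / min_ext
    )
  })
  dplyr::bind_rows(out)
}

## quadratic-surface apex height: fit z ~ 1 + x + y + x^2 + xy + y^2 on a
## 5x5 window around the apex pixel; return the fitted peak when the fit is
## concave with a nearby stationary point, else the fitted (denoised) value
## at the apex pixel; falls back to the raw apex at image borders
refine_apex_height <- function(zmat, r0, c0, half = 2L) {
  nr <- nrow(zmat)
  nc <- ncol(zmat)
  rs <- max(1L, r0 - half):min(nr, r0 + half)
  cs <- max(1L, c0 - half):min(nc, c0 + half)
  if (length(rs) < 3 || length(cs) < 3) return(zmat[r0, c0])
  zz <- as.numeric(zmat[rs, cs])
  dy <- rep(rs - r0, times = length(cs))
  dx <- rep(cs - c0, each = length(rs))
  X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2)
  co <- tryCatch(qr.coef(qr(X), zz), error = function(e) NULL)
  if (is.null(co) || anyNA(co)) return(zmat[r0, c0])
  H <- matrix(c(2 * co[[4]], co[[5]], co[[5]], 2 * co[[6]]), 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev < 0)) {
    st <- tryCatch(solve(H, -c(co[[2]], co[[3]])), error = function(e) NULL)
    if (!is.null(st) && all(abs(st) <= 1.5)) {
      return(co[[1]] + co[[2]] * st[[1]] + co[[3]] * st[[2]] +
               co[[4]] * st[[1]]^2 + co[[5]] * st[[1]] * st[[2]] +
               co[[6]] * st[[2]]^2)
    }
  }
  co[[1]]
}

#' Default morphology classification thresholds
#'
#' @return Named list: `fibril_aspect`, `fibril_length_nm`,
#'   `amorphous_height_nm`, `amorphous_area_nm2`.
#' @export
morphology_thresholds <- function() {
  list(fibril_aspect = 5, fibril_length_nm = 100,
       amorphous_height_nm = 6, amorphous_area_nm2 = 1e4)
}

#' Classify features as oligomer, fibril or amorphous aggregate
#'
#' Deterministic, total rule: a feature is a *fibril* when it is elongated
#' (aspect ratio and length above threshold); an *amorphous aggregate* when
#' it is tall, compact and large; everything else is an *oligomer*.
#'
#' @param features Tibble from [measure_features()].
#' @param thresholds See [morphology_thresholds()].
#' @return The tibble with a `class` factor column added.
#' @export
classify_features <- function(features,
                              thresholds = morphology_thresholds()) {
  th <- thresholds
  cls <- dplyr::case_when(
    features$aspect_ratio >= th$fibril_aspect &
      features$length_nm >= th$fibril_length_nm ~ "fibril",
    features$max_height_nm >= th$amorphous_height_nm &
      features$aspect_ratio < th$fibril_aspect &
      features$area_nm2 >= th$amorphous_area_nm2 ~ "amorphous",
    TRUE ~ "oligomer"
  )
  features$class <- factor(cls, levels = c("oligomer", "fibril", "amorphous"))
  features
}

#' Run the whole image pipeline on one topograph
#'
#' [flatten()] then [segment_features()], [measure_features()] and
#' [classify_features()].
#'
#' @param topo A `"topograph"`.
#' @param threshold_nm,min_pixels Passed to [segment_features()].
#' @param thresholds Passed to [classify_features()].
#' @return Classified feature tibble.
#' @examples
#' topo <- simulate_topograph(feature_spec("cap", 3.13, radius_nm = 50),
#'                            c(100, 100), seed = 3)
#' analyze_topograph(topo)
#' @export
analyze_topograph <- function(topo, threshold_nm = NULL, min_pixels = 4,
                              thresholds = morphology_thresholds()) {
  flat <- flatten(topo)
  labels <- segment_features(flat, threshold_nm = threshold_nm,
                             min_pixels = min_pixels)
  classify_features(measure_features(flat, labels), thresholds = thresholds)
}

#' Summarise a labelled image series as a time course
#'
#' Counts each morphology class and averages its characteristic height
#' (per-feature maximum for oligomers and amorphous aggregates, crest mean
#' for fibrils) per condition and incubation time.
#'
#' @param features Feature tibble carrying `condition`, `time_h` and `class`
#'   columns (e.g. classified features joined with their image labels).
#' @return A tibble with one row per condition/time:
#'   `condition`, `time_h`, `n_oligomer`, `n_fibril`, `n_amorphous`,
#'   `height_oligomer_nm`, `height_fibril_nm`, `height_amorphous_nm`.
#' @export
timecourse_summary <- function(features) {
  cls_height <- function(df, cl) {
    sel <- df$class == cl
    if (!any(sel)) return(NA_real_)
    if (cl == "fibril") mean(df$crest_height_nm[sel]) else
      mean(df$max_height_nm[sel])
  }
  features |>
    dplyr::group_by(.data$condition, .data$time_h) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        n_oligomer = sum(df$class == "oligomer"),
        n_fibril = sum(df$class == "fibril"),
        n_amorphous = sum(df$class == "amorphous"),
        height_oligomer_nm = cls_height(df, "oligomer"),
        height_fibril_nm = cls_height(df, "fibril"),
        height_amorphous_nm = cls_height(df, "amorphous")
      )
    }) |>
    dplyr::ungroup()
}
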