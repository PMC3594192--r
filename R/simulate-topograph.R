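#' Build a feature specification for a synthetic topograph
#'
#' One row per surface feature. Three geometric primitives cover the
#' aggregate morphologies seen by AFM: `"cap"` (paraboloid cap; oligomer),
#' `"ridge"` (half-cylinder of given length and width; fibril) and `"blob"`
#' (irregular union of overlapping caps; amorphous aggregate).
#'
#' @param type One of `"cap"`, `"ridge"`, `"blob"` (recycled).
#' @param height_nm Apex height of each feature, nm (> 0).
#' @param radius_nm Cap base radius, nm (caps only).
#' @param length_nm,width_nm Ridge axis length and cross-width, nm.
#' @param diameter_nm Approximate blob footprint diameter, nm.
#' @return A tibble with one row per feature.
#' @examples
#' feature_spec("cap", height_nm = 3.13, radius_nm = 50)
#' @export
feature_spec <- function(type, height_nm, radius_nm = NA, length_nm = NA,
                         width_nm = NA, diameter_nm = NA) {
  if (any(height_nm <= 0)) {
    abort("feature heights must be positive.", class = "smforce_error")
  }
  tibble::tibble(
    type = type, height_nm = height_nm, radius_nm = radius_nm,
    length_nm = length_nm, width_nm = width_nm, diameter_nm = diameter_nm
  )
}

#' Feature mixes emulating the aggregation time course
#'
#' Returns a [feature_spec()] describing the dominant species observed at
#' each incubation time with and without copper: oligomeric caps of ~3.13 nm
#' at 1 h; in the control, short ~4.5 nm fibrils appearing at 6 h and long
#' (1-3 um) ~7.2 nm fibrils dominating at 24 h; with copper, large amorphous
#' ~9.3 nm aggregates from 6 h onward and no fibrils.
#'
#' @param condition `"control"` or `"copper"`.
#' @param time_h Incubation time label: 1, 6 or 24.
#' @param seed Optional seed for the per-feature size draws.
#' @return A feature tibble with `condition` and `time_h` columns attached.
#' @export
aggregation_stage_spec <- function(condition = c("control", "copper"),
                                   time_h = 1, seed = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  oligo <- function(n) feature_spec("cap", height_nm = 3.13,
                                    radius_nm = runif(n, 40, 60))
  fibril <- function(n, h, lmin, lmax) {
    feature_spec("ridge", height_nm = h, length_nm = runif(n, lmin, lmax),
                 width_nm = 30)
  }
  blob <- function(n) feature_spec("blob", height_nm = 9.3,
                                   diameter_nm = runif(n, 100, 400))
  spec <- if (condition == "control") {
    switch(as.character(time_h),
      "1" = oligo(20),
      "6" = dplyr::bind_rows(oligo(12), fibril(6, 4.5, 200, 600)),
      "24" = dplyr::bind_rows(fibril(5, 7.2, 1000, 3000), oligo(5)),
      abort("time_h must be 1, 6 or 24.", class = "smforce_error")
    )
  } else {
    switch(as.character(time_h),
      "1" = oligo(20),
      "6" = blob(8),
      "24" = blob(10),
      abort("time_h must be 1, 6 or 24.", class = "smforce_error")
    )
  }
  spec$condition <- condition
  spec$time_h <- time_h
  spec
}

#' Simulate an AFM height image
#'
#' Renders the features of a [feature_spec()] onto a flat background with an
#' optional plane tilt and additive Gaussian pixel noise. Features are placed
#' uniformly at random without overlap (ridges are treated as thick segments;
#' a placement that cannot be realised within the retry budget raises an
#' error). Blobs are unions of several overlapping equal-height caps, giving
#' irregular outlines with a well-defined apex height.
#'
#' @param features A [feature_spec()] tibble; zero rows gives background only.
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size Pixel edge, nm.
#' @param noise_sd Gaussian pixel noise SD, nm.
#' @param tilt Background plane tilt along x, nm per um (0.5 by default,
#'   typical residual sample tilt).
#' @param seed Optional integer seed.
#' @param max_tries Placement retries per feature before giving up.
#' @return A numeric matrix of heights (nm) of class `"topograph"` with
#'   attributes `pixel_size_nm` and `features` (the spec augmented with the
#'   placed centre coordinates, nm).
#' @examples
#' topo <- simulate_topograph(feature_spec("cap", 3.13, radius_nm = 50),
#'                            image_size = c(64, 64), noise_sd = 0, tilt = 0)
#' max(topo) # 3.13 up to pixel sampling
#' @export
simulate_topograph <- function(features = NULL,
                               image_size = c(500, 500),
                               pixel_size = 10,
                               noise_sd = 0.3,
                               tilt = 0.5,
                               seed = NULL,
                               max_tries = 500) {
  if (!is.null(seed)) set.seed(seed)
  nr <- image_size[[1]]
  nc <- image_size[[2]]
  if (pixel_size <= 0) {
    abort("`pixel_size` must be positive.", class = "smforce_error")
  }
  ## pixel-centre coordinates in nm; x along columns, y along rows
  xs <- (seq_len(nc) - 0.5) * pixel_size
  ys <- (seq_len(nr) - 0.5) * pixel_size
  img <- outer(rep(1, nr), xs) * (tilt / 1000) # nm per um -> nm per nm

  placed <- list() # each: list(p1 = c(x,y), p2 = c(x,y), hw = half-width nm)
  centres <- NULL

  if (!is.null(features) && nrow(features) > 0) {
    ## place long ridges first: they are the hardest to fit
    ord <- order(features$type != "ridge",
                 -ifelse(is.na(features$length_nm), 0, features$length_nm))
    features <- features[ord, ]
    cx <- cy <- numeric(nrow(features))
    for (i in seq_len(nrow(features))) {
      ft <- features[i, ]
      geom <- place_feature(ft, placed, xs, ys, max_tries)
      placed[[length(placed) + 1]] <- geom
      cx[[i]] <- (geom$p1[[1]] + geom$p2[[1]]) / 2
      cy[[i]] <- (geom$p1[[2]] + geom$p2[[2]]) / 2
      img <- render_feature(img, ft, geom, xs, ys)
    }
    features$x_nm <- cx
    features$y_nm <- cy
  }

  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)

  structure(img, class = c("topograph", "matrix", "array"),
            pixel_size_nm = pixel_size,
            features = features)
}

## footprint half-extent along / across the feature axis, nm
feature_footprint <- function(ft) {
  switch(ft$type,
    cap = list(half_len = 0, hw = ft$radius_nm),
    ridge = list(half_len = ft$length_nm / 2, hw = ft$width_nm / 2),
    blob = list(half_len = 0, hw = ft$diameter_nm / 2),
    abort(sprintf("unknown feature type '%s'.", ft$type),
          class = "smforce_error")
  )
}

place_feature <- function(ft, placed, xs, ys, max_tries) {
  fp <- feature_footprint(ft)
  margin <- 30 # nm clearance between features
  for (try in seq_len(max_tries)) {
    theta <- runif(1, 0, pi)
    dx <- cos(theta) * fp$half_len
    dy <- sin(theta) * fp$half_len
    lo_x <- fp$hw + abs(dx)
    lo_y <- fp$hw + abs(dy)
    if (max(xs) - lo_x <= lo_x || max(ys) - lo_y <= lo_y) {
      abort("feature does not fit in the image.", class = "smforce_error")
    }
    cx <- runif(1, lo_x, max(xs) - lo_x)
    cy <- runif(1, lo_y, max(ys) - lo_y)
    geom <- list(p1 = c(cx - dx, cy - dy), p2 = c(cx + dx, cy + dy),
                 hw = fp$hw)
    ok <- TRUE
    for (g in placed) {
      if (thick_segment_distance(geom, g) < geom$hw + g$hw + margin) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(geom)
  }
  abort("could not place all features without overlap; reduce feature count or enlarge the image.",
        class = "smforce_error")
}

## minimum distance between two (possibly degenerate) segments, by
## discretising each at <= 20 nm steps and taking exact point-to-segment
## distances both ways
thick_segment_distance <- function(a, b) {
  min(points_to_segment(segment_points(a), b$p1, b$p2),
      points_to_segment(segment_points(b), a$p1, a$p2))
}

segment_points <- function(g, step = 20) {
  len <- sqrt(sum((g$p2 - g$p1)^2))
  n <- max(2, ceiling(len / step) + 1)
  t <- seq(0, 1, length.out = n)
  cbind(g$p1[[1]] + t * (g$p2[[1]] - g$p1[[1]]),
        g$p1[[2]] + t * (g$p2[[2]] - g$p1[[2]]))
}

points_to_segment <- function(pts, p1, p2) {
  v <- p2 - p1
  vv <- sum(v^2)
  if (vv == 0) {
    return(min(sqrt((pts[, 1] - p1[[1]])^2 + (pts[, 2] - p1[[2]])^2)))
  }
  t <- pmin(1, pmax(0, ((pts[, 1] - p1[[1]]) * v[[1]] +
                          (pts[, 2] - p1[[2]]) * v[[2]]) / vv))
  min(sqrt((pts[, 1] - (p1[[1]] + t * v[[1]]))^2 +
             (pts[, 2] - (p1[[2]] + t * v[[2]]))^2))
}

render_feature <- function(img, ft, geom, xs, ys) {
  fp <- feature_footprint(ft)
  reach <- fp$hw
  x_lo <- min(geom$p1[[1]], geom$p2[[1]]) - reach
  x_hi <- max(geom$p1[[1]], geom$p2[[1]]) + reach
  y_lo <- min(geom$p1[[2]], geom$p2[[2]]) - reach
  y_hi <- max(geom$p1[[2]], geom$p2[[2]]) + reach
  ci <- which(xs >= x_lo & xs <= x_hi)
  ri <- which(ys >= y_lo & ys <= y_hi)
  if (!length(ci) || !length(ri)) return(img)
  gx <- outer(rep(1, length(ri)), xs[ci])
  gy <- outer(ys[ri], rep(1, length(ci)))

  h <- ft$height_nm
  z <- switch(ft$type,
    cap = {
      d2 <- (gx - geom$p1[[1]])^2 + (gy - geom$p1[[2]])^2
      pmax(0, h * (1 - d2 / ft$radius_nm^2))
    },
    ridge = {
      d <- dist_to_segment_grid(gx, gy, geom$p1, geom$p2)
      u <- (2 * d / ft$width_nm)^2
      h * sqrt(pmax(0, 1 - u))
    },
    blob = {
      ## union of overlapping equal-height caps scattered inside the footprint
      n_sub <- sample(4:6, 1)
      r0 <- ft$diameter_nm / 2
      zz <- matrix(0, length(ri), length(ci))
      for (s in seq_len(n_sub)) {
        if (s == 1) {
          off <- c(0, 0)
        } else {
          ang <- runif(1, 0, 2 * pi)
          rad <- runif(1, 0, r0 * 0.4)
          off <- c(cos(ang), sin(ang)) * rad
        }
        rs <- runif(1, r0 * 0.45, r0 * 0.6)
        d2 <- (gx - geom$p1[[1]] - off[[1]])^2 +
          (gy - geom$p1[[2]] - off[[2]])^2
        zz <- pmax(zz, h * (1 - d2 / rs^2))
      }
      pmax(0, zz)
    }
  )
  img[ri, ci] <- img[ri, ci] + z
  img
}

dist_to_segment_grid <- function(gx, gy, p1, p2) {
  v <- p2 - p1
  vv <- sum(v^2)
  if (vv == 0) {
    return(sqrt((gx - p1[[1]])^2 + (gy - p1[[2]])^2))
  }
  t <- pmin(1, pmax(0, ((gx - p1[[1]]) * v[[1]] +
                          (gy - p1[[2]]) * v[[2]]) / vv))
  sqrt((gx - (p1[[1]] + t * v[[1]]))^2 + (gy - (p1[[2]] + t * v[[2]]))^2)
}

#' @export
print.topograph <- function(x, ...) {
  px <- attr(x, "pixel_size_nm")
  cat(sprintf("<topograph> %d x %d px (%.1f x %.1f um), pixel %g nm\n",
              nrow(x), ncol(x), nrow(x) * px / 1000, ncol(x) * px / 1000, px))
  cat(sprintf("  height range: %.2f .. %.2f nm\n", min(x), max(x)))
  invisible(x)
}
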