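#' Seed point for lumen segmentation
#'
#' @param row,col Seed coordinates (px, 0-based, row/col).
#' @param source One of `"heuristic"`, `"manual"`, `"propagated"`.
#' @return A `seed_point` list.
#' @export
seed_point <- function(row, col, source = c("manual", "heuristic", "propagated")) {
  structure(list(row = row, col = col, source = match.arg(source)),
            class = "seed_point")
}

#' Heuristic dark-blob seed detection
#'
#' Finds the centroid of the largest connected dark blob whose pixel
#' count lies within the configured bounds. Stands in for a trained
#' vessel detector; a manually supplied coordinate bypasses the
#' heuristic entirely (the clinical fallback of clicking in the vessel).
#'
#' @param image Grayscale matrix.
#' @param manual Optional `c(row, col)` (0-based px); returned unchanged
#'   with `source = "manual"`.
#' @param dark_frac Dark threshold as a fraction of the image median.
#' @param min_px Smallest acceptable blob (px).
#' @param max_frac Largest acceptable blob as a fraction of the frame.
#' @return A [seed_point()].
#' @export
detect_seed <- function(image, manual = NULL, dark_frac = 0.35,
                        min_px = 20, max_frac = 0.25) {
  if (!is.null(manual)) {
    stopifnot(length(manual) == 2L,
              manual[1] >= 0, manual[1] <= nrow(image) - 1,
              manual[2] >= 0, manual[2] <= ncol(image) - 1)
    return(seed_point(manual[1], manual[2], "manual"))
  }
  thr <- dark_frac * stats::median(image)
  dark <- image < thr
  if (!any(dark)) {
    stop("detect_seed: no dark region found; supply a manual seed")
  }
  lab <- .label_components(dark)
  sizes <- tabulate(lab[lab > 0])
  ok <- which(sizes >= min_px & sizes <= max_frac * length(image))
  if (!length(ok)) {
    stop("detect_seed: no dark blob within size bounds; supply a manual seed")
  }
  best <- ok[which.max(sizes[ok])]
  idx <- which(lab == best)
  nr <- nrow(image)
  sp <- seed_point(round(mean((idx - 1) %% nr)),
                   round(mean((idx - 1) %/% nr)), "heuristic")
  # centroid of a non-convex blob could fall outside it; snap if needed
  if (!dark[sp$row + 1, sp$col + 1]) {
    d2 <- ((idx - 1) %% nr - sp$row)^2 + ((idx - 1) %/% nr - sp$col)^2
    i <- idx[which.min(d2)]
    sp <- seed_point((i - 1) %% nr, (i - 1) %/% nr, "heuristic")
  }
  sp
}

# 4-connected component labeling of a logical matrix (vectorized BFS).
.label_components <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  remaining <- which(binary)
  current <- 0L
  while (length(remaining)) {
    current <- current + 1L
    frontier <- remaining[1L]
    lab[frontier] <- current
    while (length(frontier)) {
      frontier <- .grow_step(frontier, binary, lab == 0L, nr, nc)
      lab[frontier] <- current
    }
    remaining <- which(binary & lab == 0L)
  }
  lab
}

# one vectorized 4-neighbour expansion: returns new indices in `open`
# that are TRUE in `binary` and adjacent to `frontier`
.grow_step <- function(frontier, binary, open, nr, nc) {
  r <- (frontier - 1L) %% nr
  up <- frontier[r > 0L] - 1L
  dn <- frontier[r < nr - 1L] + 1L
  lf <- frontier[frontier > nr] - nr
  rt <- frontier[frontier <= nr * (nc - 1L)] + nr
  nb <- unique(c(up, dn, lf, rt))
  nb[binary[nb] & open[nb]]
}

#' Region growing from a seed point
#'
#' Grows the 4-connected region of pixels with intensity at or below the
#' threshold that contains the seed. Guards against leakage: reaching the
#' image border or exceeding `max_px` aborts.
#'
#' @param image Grayscale matrix.
#' @param seed A [seed_point()] or `c(row, col)` (0-based px).
#' @param threshold Inclusion threshold (intensity units); the seed pixel
#'   must not exceed it.
#' @param max_px Leakage guard (px); default 40% of the frame.
#' @return Logical mask matrix.
#' @export
region_grow <- function(image, seed, threshold,
                        max_px = 0.4 * length(image)) {
  if (inherits(seed, "seed_point")) seed <- c(seed$row, seed$col)
  nr <- nrow(image); nc <- ncol(image)
  sr <- round(seed[1]); sc <- round(seed[2])
  stopifnot(sr >= 0, sr <= nr - 1, sc >= 0, sc <= nc - 1)
  if (image[sr + 1, sc + 1] > threshold) {
    stop(sprintf(
      "region_grow: seed intensity %.1f exceeds threshold %.1f",
      image[sr + 1, sc + 1], threshold))
  }
  binary <- image <= threshold
  mask <- matrix(FALSE, nr, nc)
  frontier <- (sc * nr) + sr + 1L
  mask[frontier] <- TRUE
  count <- 1L
  while (length(frontier)) {
    frontier <- .grow_step(frontier, binary, !mask, nr, nc)
    mask[frontier] <- TRUE
    count <- count + length(frontier)
    if (count > max_px) stop("region_grow: region exceeds maximum size (leakage)")
  }
  idx <- which(mask)
  r <- (idx - 1L) %% nr; cc <- (idx - 1L) %/% nr
  if (any(r == 0L | r == nr - 1L | cc == 0L | cc == nc - 1L)) {
    stop("region_grow: region reaches the image border (leakage)")
  }
  mask
}

# bilinear intensity sampler on 0-based (row, col); NA outside the image
.bilinear <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  if (!any(ok)) return(out)
  r <- pmin(r[ok], nr - 1 - 1e-9); c <- pmin(c[ok], nc - 1 - 1e-9)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i00 <- image[cbind(r0 + 1, c0 + 1)]
  i10 <- image[cbind(r0 + 2, c0 + 1)]
  i01 <- image[cbind(r0 + 1, c0 + 2)]
  i11 <- image[cbind(r0 + 2, c0 + 2)]
  out[ok] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
  out
}

# argmax with plateau handling: median index of the maximal set
.argmax_med <- function(x) {
  sel <- which(x >= max(x, na.rm = TRUE) - 1e-9)
  sel[ceiling(length(sel) / 2)]
}

# outward intensity difference I(r + h) - I(r - h) along one ray
.ray_profile <- function(image, cr, cc, theta, radii, h = 1) {
  dr <- sin(theta); dc <- cos(theta)
  outer_i <- .bilinear(image, cr + (radii + h) * dr, cc + (radii + h) * dc)
  inner_i <- .bilinear(image, cr + (radii - h) * dr, cc + (radii - h) * dc)
  outer_i - inner_i
}

#' Radial boundary refinement
#'
#' From the mask centroid, casts `n_rays` equally spaced rays and on each
#' returns the radius maximizing the outward intensity difference within
#' a search window around the region-growing boundary (dark lumen inside,
#' bright wall outside, so the maximum marks the wall). Plateaus of the
#' difference profile resolve to their midpoint.
#'
#' @param image Grayscale matrix.
#' @param mask Logical mask from [region_grow()].
#' @param n_rays Number of rays (default 32).
#' @param window_frac Search half-window as a fraction of the boundary
#'   radius (default 0.25).
#' @param window_min Minimum half-window (px).
#' @param step Radial sampling step (px).
#' @return A list of class `radial_boundary`: `points` (n x 2, row/col px),
#'   `radii`, `angles`, `centroid`, `window` (n x 2 lo/hi), `ray_flagged`
#'   (ray exited the image; mask boundary radius used), `degenerate`.
#' @export
radial_refine <- function(image, mask, n_rays = 32, window_frac = 0.25,
                          window_min = 3, step = 0.25) {
  idx <- which(mask)
  if (!length(idx)) stop("radial_refine: empty mask")
  nr <- nrow(image)
  cr <- mean((idx - 1L) %% nr); cc <- mean((idx - 1L) %/% nr)
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  if (length(idx) < 4L) {
    pts <- cbind(cr + 0 * angles, cc + 0 * angles)
    return(structure(list(points = pts, radii = rep(0, n_rays),
                          angles = angles, centroid = c(cr, cc),
                          window = cbind(rep(0, n_rays), rep(0, n_rays)),
                          ray_flagged = rep(FALSE, n_rays),
                          degenerate = TRUE),
                     class = "radial_boundary"))
  }
  r_lim <- sqrt(nr^2 + ncol(image)^2)
  radii <- numeric(n_rays)
  flagged <- logical(n_rays)
  window <- matrix(0, n_rays, 2)
  for (k in seq_len(n_rays)) {
    th <- angles[k]
    probe <- seq(0, r_lim, by = 0.5)
    pr <- round(cr + probe * sin(th)); pc <- round(cc + probe * cos(th))
    inb <- pr >= 0 & pr <= nr - 1 & pc >= 0 & pc <= ncol(image) - 1
    inside <- rep(FALSE, length(probe))
    inside[inb] <- mask[cbind(pr[inb] + 1, pc[inb] + 1)]
    r0 <- if (any(inside)) probe[max(which(inside))] else 0
    half <- max(window_min, window_frac * r0)
    lo <- max(step, r0 - half); hi <- r0 + half
    window[k, ] <- c(lo, hi)
    rr <- seq(lo, hi, by = step)
    d <- .ray_profile(image, cr, cc, th, rr)
    if (anyNA(d)) {
      radii[k] <- r0
      flagged[k] <- TRUE
    } else {
      radii[k] <- rr[.argmax_med(d)]
    }
  }
  pts <- cbind(cr + radii * sin(angles), cc + radii * cos(angles))
  structure(list(points = pts, radii = radii, angles = angles,
                 centroid = c(cr, cc), window = window,
                 ray_flagged = flagged, degenerate = FALSE),
            class = "radial_boundary")
}

#' Gradient-and-shape boundary optimization
#'
#' Adjusts each refined radius to maximize the outward intensity
#' difference minus a roughness penalty `lambda * (r - m)^2`, where `m`
#' is the mean of the two angular neighbours. Coordinate-ascent sweeps
#' over the rays until no radius changes or `max_sweeps` is reached;
#' radii stay within the radial search window. `lambda = 0` reproduces
#' [radial_refine()] exactly.
#'
#' @param boundary A `radial_boundary` from [radial_refine()].
#' @param image Grayscale matrix.
#' @param lambda Roughness weight (intensity units per px^2).
#' @param max_sweeps Sweep limit.
#' @param step Radial grid step (px).
#' @return The adjusted `radial_boundary` (with `sweeps` attribute).
#' @export
shape_optimize <- function(boundary, image, lambda = 0.5, max_sweeps = 50,
                           step = 0.25) {
  if (boundary$degenerate) return(boundary)
  n <- length(boundary$radii)
  cr <- boundary$centroid[1]; cc <- boundary$centroid[2]
  grids <- vector("list", n)
  profs <- vector("list", n)
  for (k in seq_len(n)) {
    rr <- seq(boundary$window[k, 1], boundary$window[k, 2], by = step)
    grids[[k]] <- rr
    d <- .ray_profile(image, cr, cc, boundary$angles[k], rr)
    d[is.na(d)] <- -Inf
    profs[[k]] <- d
  }
  radii <- boundary$radii
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (k in seq_len(n)) {
      if (boundary$ray_flagged[k]) next
      m <- (radii[if (k == 1L) n else k - 1L] +
              radii[if (k == n) 1L else k + 1L]) / 2
      obj <- profs[[k]] - lambda * (grids[[k]] - m)^2
      new_r <- grids[[k]][.argmax_med(obj)]
      if (abs(new_r - radii[k]) > 1e-12) {
        radii[k] <- new_r
        changed <- TRUE
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }
  boundary$radii <- radii
  boundary$points <- cbind(cr + radii * sin(boundary$angles),
                           cc + radii * cos(boundary$angles))
  attr(boundary, "sweeps") <- sweeps
  boundary
}

#' Periodic cubic-spline contour interpolation
#'
#' Interpolates the ordered boundary points with a periodic cubic spline
#' (componentwise in row and col against the point index) sampled at
#' `n_out` uniformly spaced parameter values. The curve passes through
#' every input point. A self-intersecting spline falls back to linear
#' interpolation with a flag.
#'
#' @param points m x 2 matrix of ordered boundary points (m >= 4), or a
#'   `radial_boundary`.
#' @param n_out Number of output samples (default 2000).
#' @return A list of class `lumen_contour`: `points` (n_out x 2),
#'   `flags` (character; may contain `"deduplicated"`, `"linear_fallback"`).
#' @export
interpolate_contour <- function(points, n_out = 2000) {
  if (inherits(points, "radial_boundary")) points <- points$points
  pts <- as.matrix(points)
  flags <- character(0)
  # drop consecutive duplicates (closed: last vs first too)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  dup <- rowSums((pts - nxt)^2) < 1e-12
  if (any(dup)) {
    pts <- pts[!dup, , drop = FALSE]
    flags <- c(flags, "deduplicated")
  }
  m <- nrow(pts)
  if (m < 4L) stop("interpolate_contour: need at least 4 distinct points")
  s <- 0:m
  s_out <- seq(0, m, length.out = n_out + 1L)[seq_len(n_out)]
  per <- function(v) {
    stats::spline(s, c(v, v[1]), method = "periodic", xout = s_out)$y
  }
  out <- cbind(per(pts[, 1]), per(pts[, 2]))
  if (.self_intersects(out)) {
    lin <- function(v) stats::approx(s, c(v, v[1]), xout = s_out)$y
    out <- cbind(lin(pts[, 1]), lin(pts[, 2]))
    flags <- c(flags, "linear_fallback")
  }
  structure(list(points = out, flags = flags), class = "lumen_contour")
}

# approximate simplicity check on a decimated copy of the closed curve
.self_intersects <- function(pts, max_check = 256L) {
  n <- nrow(pts)
  by <- max(1L, ceiling(n / max_check))
  p <- pts[seq(1L, n, by = by), , drop = FALSE]
  m <- nrow(p)
  if (m < 4L) return(FALSE)
  a <- p
  b <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(m - 2L)) {
    js <- (i + 2L):m
    if (i == 1L) js <- js[js != m]  # closing edge is adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# count of pixel centers (integer 0-based coords) strictly inside the
# closed polygon given as n x 2 (row, col); even-odd scanline fill
.poly_pixel_count <- function(pts, return_mask = FALSE, dim = NULL) {
  y <- pts[, 1]; x <- pts[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  total <- 0
  rows_hit <- list()
  for (ry in seq(ceiling(min(y)), floor(max(y)))) {
    sel <- (y <= ry & y2 > ry) | (y2 <= ry & y > ry)
    if (!any(sel)) next
    xc <- sort(x[sel] + (ry - y[sel]) * (x2[sel] - x[sel]) / (y2[sel] - y[sel]))
    cols <- integer(0)
    for (i in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[i] + 1e-9); hi <- floor(xc[i + 1] - 1e-9)
      if (hi >= lo) {
        total <- total + (hi - lo + 1)
        if (return_mask) cols <- c(cols, lo:hi)
      }
    }
    if (return_mask && length(cols)) rows_hit[[as.character(ry)]] <- cols
  }
  if (!return_mask) return(total)
  mask <- matrix(FALSE, dim[1], dim[2])
  for (ry in names(rows_hit)) {
    cc <- rows_hit[[ry]]
    cc <- cc[cc >= 0 & cc <= dim[2] - 1]
    r <- as.integer(ry)
    if (r >= 0 && r <= dim[1] - 1) mask[r + 1, cc + 1] <- TRUE
  }
  mask
}

#' Cross-sectional area from a mask or contour
#'
#' Area is the interior pixel count times the squared pixel pitch: for a
#' mask, the count of true pixels; for a closed contour, the count of
#' pixel centers inside the polygon (the binary-image counting the
#' clinical pipeline uses, not the continuous polygon area).
#'
#' @param obj Logical/numeric mask matrix, `lumen_contour`, or an n x 2
#'   matrix of closed-polygon vertices (n >= 3).
#' @param pixel_pitch Pixel pitch (mm/px).
#' @return Area (mm^2).
#' @export
compute_area <- function(obj, pixel_pitch) {
  if (inherits(obj, "lumen_contour")) obj <- obj$points
  if (is.matrix(obj) && ncol(obj) == 2 && !is.logical(obj)) {
    if (nrow(obj) < 3L) stop("compute_area: open or degenerate contour")
    return(.poly_pixel_count(obj) * pixel_pitch^2)
  }
  if (is.matrix(obj)) return(sum(obj > 0) * pixel_pitch^2)
  stop("compute_area: unsupported input")
}

# 4-neighbour binary erosion/dilation by one pixel
.erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}
.dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m | up | dn | lf | rt
}

# region-growing threshold rule: seed 3x3 mean plus a fraction of its
# contrast against the background median
.grow_threshold <- function(image, seed, offset_frac = 0.25) {
  sr <- round(seed[1]); sc <- round(seed[2])
  nr <- nrow(image); nc <- ncol(image)
  rows <- pmax(1, sr):pmin(nr, sr + 2)
  cols <- pmax(1, sc):pmin(nc, sc + 2)
  seed_mean <- mean(image[rows, cols])
  bg_med <- stats::median(image)
  seed_mean + offset_frac * (bg_med - seed_mean)
}

#' Segment the lumen in a single frame
#'
#' Runs the staged segmentation: region growing from the seed, then --
#' unless the previous frame's area marks the vessel as near collapse
#' (previous area below `near_collapse_mm2`) -- radial gradient
#' refinement, gradient-and-shape optimization, and the 2000-point
#' periodic spline contour. Area is the interior pixel count times the
#' squared pixel pitch. A seed brighter than the growing threshold marks
#' a fully collapsed lumen (area 0) rather than an error.
#'
#' @param image Grayscale matrix.
#' @param seed A [seed_point()] or `c(row, col)` (0-based px).
#' @param pixel_pitch Pixel pitch (mm/px).
#' @param previous_area Previous frame's area (mm^2) or `NULL` (first
#'   frame: all stages run).
#' @param near_collapse_mm2 Area below which only region growing runs
#'   (default 5).
#' @param config Optional [run_config()]; overrides the stage defaults.
#' @param lambda,n_rays,n_contour_points Stage parameters (see
#'   [shape_optimize()], [radial_refine()], [interpolate_contour()]).
#' @return A list of class `segmentation_result`: `contour` (or `NULL`),
#'   `mask`, `area_mm2`, `band_mm2`, `stages_run`, `threshold`,
#'   `seed_next` (propagated seed for the next frame), `flags`.
#' @export
segment_frame <- function(image, seed, pixel_pitch,
                          previous_area = NULL,
                          near_collapse_mm2 = 5,
                          config = NULL,
                          lambda = 0.5, n_rays = 32,
                          n_contour_points = 2000) {
  if (!is.null(config)) {
    near_collapse_mm2 <- config$near_collapse_threshold
    n_rays <- config$n_rays
    n_contour_points <- config$n_contour_points
  }
  if (inherits(seed, "seed_point")) seed <- c(seed$row, seed$col)
  sr <- round(seed[1]); sc <- round(seed[2])
  nbr <- pmax(1, sr):pmin(nrow(image), sr + 2)
  nbc <- pmax(1, sc):pmin(ncol(image), sc + 2)
  bg_med <- stats::median(image)
  if (mean(image[nbr, nbc]) > 0.6 * bg_med) {
    # lumen fully collapsed: nothing dark at the seed
    return(structure(list(contour = NULL,
                          mask = matrix(FALSE, nrow(image), ncol(image)),
                          area_mm2 = 0, band_mm2 = 0,
                          stages_run = "collapsed", threshold = NA_real_,
                          seed_next = seed_point(seed[1], seed[2], "propagated"),
                          flags = "collapsed"),
                     class = "segmentation_result"))
  }
  thr <- .grow_threshold(image, seed)
  if (image[sr + 1, sc + 1] > thr) {
    # speckle at the exact seed pixel: slide to the darkest 3x3 neighbour
    i <- which.min(image[nbr, nbc])
    seed <- c(nbr[(i - 1) %% length(nbr) + 1] - 1,
              nbc[(i - 1) %/% length(nbr) + 1] - 1)
  }
  mask <- region_grow(image, seed, thr)
  stages <- "region_grow"
  contour <- NULL
  flags <- character(0)
  final_mask <- mask
  full <- is.null(previous_area) || previous_area >= near_collapse_mm2
  if (full) {
    rb <- radial_refine(image, mask, n_rays = n_rays)
    if (rb$degenerate) {
      flags <- c(flags, "degenerate_boundary")
    } else {
      rb <- shape_optimize(rb, image, lambda = lambda)
      contour <- interpolate_contour(rb, n_out = n_contour_points)
      flags <- c(flags, contour$flags)
      final_mask <- .poly_pixel_count(contour$points, return_mask = TRUE,
                                      dim = dim(image))
      stages <- c(stages, "radial", "shape", "interp")
    }
  }
  area <- sum(final_mask) * pixel_pitch^2
  ring <- (final_mask & !.erode4(final_mask)) |
    (.dilate4(final_mask) & !final_mask)
  band <- ring & abs(image - thr) <= 0.1 * thr
  idx <- which(final_mask)
  seed_next <- if (length(idx)) {
    nr <- nrow(image)
    seed_point(round(mean((idx - 1) %% nr)),
               round(mean((idx - 1) %/% nr)), "propagated")
  } else {
    seed_point(seed[1], seed[2], "propagated")
  }
  structure(list(contour = contour, mask = final_mask, area_mm2 = area,
                 band_mm2 = sum(band) * pixel_pitch^2,
                 stages_run = stages, threshold = thr,
                 seed_next = seed_next, flags = flags),
            class = "segmentation_result")
}

#' Segment every frame of a cine sequence
#'
#' Applies [segment_frame()] along the sequence, propagating the seed
#' (current mask centroid) and the previous frame's area, which controls
#' the near-collapse simplification to region growing only.
#'
#' @param cine A `cine_sequence`.
#' @param sync Optional `sync_result`; contributes the per-frame force
#'   column.
#' @param seed Initial [seed_point()] or `c(row, col)`; `NULL` runs
#'   [detect_seed()] on the first frame.
#' @param config Optional [run_config()].
#' @param keep_contours Keep the per-frame contours (memory heavy).
#' @return A data.frame of class `segmentation_table` with columns
#'   `frame, t_s, force_N, area_mm2, band_mm2, stages`; attribute
#'   `contours` when requested.
#' @export
segment_sequence <- function(cine, sync = NULL, seed = NULL,
                             config = NULL, keep_contours = FALSE) {
  n <- length(cine$frames)
  if (is.null(seed)) seed <- detect_seed(cine$frames[[1]])
  force <- if (is.null(sync)) rep(NA_real_, n) else sync$force_N
  area <- band <- numeric(n)
  stages <- character(n)
  contours <- if (keep_contours) vector("list", n) else NULL
  prev_area <- NULL
  for (k in seq_len(n)) {
    res <- tryCatch(
      segment_frame(cine$frames[[k]], seed, cine$pixel_pitch,
                    previous_area = prev_area, config = config),
      error = function(e) stop(sprintf("frame %d: %s", k, conditionMessage(e)),
                               call. = FALSE))
    area[k] <- res$area_mm2
    band[k] <- res$band_mm2
    stages[k] <- paste(res$stages_run, collapse = "+")
    if (keep_contours) contours[[k]] <- res$contour
    # only move the seed while the lumen is visible; a collapsed lumen
    # reopens near where it was last seen
    if (!identical(res$stages_run, "collapsed")) seed <- res$seed_next
    prev_area <- res$area_mm2
  }
  out <- data.frame(frame = seq_len(n), t_s = cine$times, force_N = force,
                    area_mm2 = area, band_mm2 = band, stages = stages)
  if (keep_contours) attr(out, "contours") <- contours
  class(out) <- c("segmentation_table", "data.frame")
  out
}
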