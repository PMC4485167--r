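# Densitometry: pixels -> luminosity -> sampled strip/background means ->
# the optical density ratio ODR = (I_b - I_s) / I_b, the fractional
# darkening of a binding strip against the background (0 = no signal,
# 1 = fully black on white).

#' RGB-to-luminosity weighting model
#'
#' Luminosity is the weighted average grayscale of the R, G, B channels.
#' Defaults are the BT.601 weights 0.299/0.587/0.114.
#'
#' @param weights Numeric length-3 vector `(w_R, w_G, w_B)`; each in
#'   `[0, 1]`, summing to 1.
#' @return Object of class `luminosity_model`.
#' @export
luminosity_model <- function(weights = c(0.299, 0.587, 0.114)) {
  if (length(weights) != 3L || anyNA(weights) ||
      any(weights < 0 | weights > 1) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be 3 values in [0, 1] summing to 1", call. = FALSE)
  structure(list(weights = as.numeric(weights)), class = "luminosity_model")
}

#' Convert pixels to luminosity
#'
#' @param pixel An RGB pixel as a length-3 vector, an `h x w x 3` array, an
#'   `n x 3` matrix of pixels, or a grayscale matrix/vector (returned
#'   unchanged; R = G = B = v maps to v since the weights sum to 1).
#'   Channel values must lie in `[0, 255]`.
#' @param model A [luminosity_model()].
#' @return Luminosity on the same 0-255 scale, with the color dimension
#'   collapsed.
#' @export
#' @examples
#' luminosity(c(255, 0, 0))  # 76.245 with default weights
luminosity <- function(pixel, model = luminosity_model()) {
  stopifnot(inherits(model, "luminosity_model"))
  w <- model$weights
  if (anyNA(pixel) || any(pixel < 0) || any(pixel > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (is.array(pixel) && length(dim(pixel)) == 3L) {
    if (dim(pixel)[3] < 3L) stop("expected 3 color planes", call. = FALSE)
    out <- w[1] * pixel[, , 1] + w[2] * pixel[, , 2] + w[3] * pixel[, , 3]
    attr(out, "dpi") <- attr(pixel, "dpi")
    return(out)
  }
  if (is.matrix(pixel) && ncol(pixel) == 3L)
    return(drop(pixel %*% w))
  if (is.numeric(pixel) && length(pixel) == 3L)
    return(sum(w * pixel))
  pixel  # already grayscale
}

#' Pixel-sampling plan for strip and background regions
#'
#' Mirrors the readout app's sampling: three groups of 4715 pixels per
#' region.  Groups are taken from three equal-height, vertically stacked
#' thirds of the region; within each third a centered block of rows is
#' flattened row-major and center-trimmed to exactly `pixels_per_group`
#' pixels, so groups are disjoint and deterministic.
#'
#' @param groups_per_region Number of disjoint pixel groups per region
#'   (default 3).
#' @param pixels_per_group Pixels in each group (default 4715).
#' @return Object of class `sampling_plan`.
#' @export
sampling_plan <- function(groups_per_region = 3, pixels_per_group = 4715) {
  stopifnot(groups_per_region >= 1, pixels_per_group >= 1)
  structure(list(groups_per_region = as.integer(groups_per_region),
                 pixels_per_group = as.integer(pixels_per_group)),
            class = "sampling_plan")
}

.check_rect <- function(r, img, name) {
  need <- c("x", "y", "width", "height")
  if (!all(need %in% names(r)))
    stop(sprintf("region %s must have fields x, y, width, height", name),
         call. = FALSE)
  x0 <- r[["x"]]; y0 <- r[["y"]]; w <- r[["width"]]; h <- r[["height"]]
  if (x0 < 0 || y0 < 0 || w < 1 || h < 1 ||
      x0 + w > ncol(img) || y0 + h > nrow(img))
    stop(sprintf("region %s (x=%g, y=%g, w=%g, h=%g) falls outside the %d x %d image",
                 name, x0, y0, w, h, ncol(img), nrow(img)), call. = FALSE)
  c(x0 = x0, y0 = y0, w = w, h = h)
}

# pixels of one group: region third 'g' of 'G', center-trimmed to n pixels
.group_pixels <- function(img, rect, g, G, n) {
  h3 <- rect["h"] %/% G
  w <- rect["w"]
  avail <- h3 * w
  if (avail < n)
    stop(sprintf(
      "region too small: group %d needs %d pixels but its %d x %d third holds only %d",
      g, n, h3, w, avail), call. = FALSE)
  rows_needed <- ceiling(n / w)
  r0 <- rect["y0"] + (g - 1L) * h3 + (h3 - rows_needed) %/% 2
  block <- img[(r0 + 1L):(r0 + rows_needed),
               (rect["x0"] + 1L):(rect["x0"] + w), drop = FALSE]
  v <- as.vector(t(block))  # row-major
  start <- (length(v) - n) %/% 2
  v[(start + 1L):(start + n)]
}

#' Sample pixel groups from image regions
#'
#' @param image Grayscale matrix or RGB array (converted to luminosity).
#' @param regions Named list of rectangles, each `c(x, y, width, height)`
#'   with 0-based top-left-origin half-open pixel coordinates.
#' @param plan A [sampling_plan()].
#' @param model Luminosity model used if `image` is RGB.
#' @return A list of class `region_samples` with `groups` (per-group
#'   `region`, `group`, `n_pixels`, `mean`) and `regions` (per-region pooled
#'   `mean` over the union of the groups' pixels and the `sd` across group
#'   means).
#' @export
sample_regions <- function(image, regions, plan = sampling_plan(),
                           model = luminosity_model()) {
  stopifnot(inherits(plan, "sampling_plan"))
  img <- luminosity(image, model)
  if (is.null(names(regions)) || any(names(regions) == ""))
    names(regions) <- paste0("region", seq_along(regions))
  groups <- list(); pooled <- list()
  for (nm in names(regions)) {
    rect <- .check_rect(as.list(regions[[nm]]), img, nm)
    vals <- lapply(seq_len(plan$groups_per_region), function(g)
      .group_pixels(img, rect, g, plan$groups_per_region,
                    plan$pixels_per_group))
    gm <- vapply(vals, mean, numeric(1))
    groups[[nm]] <- data.frame(
      region = nm, group = seq_along(gm),
      n_pixels = vapply(vals, length, integer(1)),
      mean = gm, stringsAsFactors = FALSE)
    pooled[[nm]] <- data.frame(
      region = nm, mean = mean(unlist(vals)),
      sd = stats::sd(gm), stringsAsFactors = FALSE)
  }
  structure(list(groups = do.call(rbind, c(groups, make.row.names = FALSE)),
                 regions = do.call(rbind, c(pooled, make.row.names = FALSE)),
                 plan = plan),
            class = "region_samples")
}

#' The optical density ratio
#'
#' `ODR = (I_b - I_s) / I_b`: 0 when the strip matches the background, 1
#' when the strip is fully black (grayscale 0) on the background.  The
#' ratio is invariant under uniform intensity scaling of both inputs.
#'
#' @param I_b Background luminosity (> 0).
#' @param I_s Binding-site (strip) luminosity (>= 0).  Vectorized.
#' @return The ODR.  An `I_s` exceeding `I_b` (strip lighter than
#'   background, e.g. glare) yields a negative value with a warning and a
#'   `glare` attribute flagging the offending entries rather than clamping,
#'   so QC can detect it.
#' @export
#' @examples
#' odr(255, 0)    # 1
#' odr(200, 150)  # 0.25
odr <- function(I_b, I_s) {
  if (anyNA(I_b) || any(I_b <= 0))
    stop("'I_b' must be strictly positive: ODR is undefined for a black background",
         call. = FALSE)
  if (anyNA(I_s) || any(I_s < 0))
    stop("'I_s' must be non-negative", call. = FALSE)
  out <- (I_b - I_s) / I_b
  glare <- I_s > I_b
  if (any(glare)) {
    warning("strip lighter than background: negative ODR flagged (glare?)",
            call. = FALSE)
    attr(out, "glare") <- glare
  }
  out
}

#' Flat-field (lighting) correction
#'
#' Divides the image by a smooth illumination estimate and rescales so the
#' background's median is preserved.  When no estimate is supplied, one is
#' built from the image itself: column-wise maxima (the background shows
#' through the spaces), a 1-D morphological closing wide enough to bridge
#' the widest bar, and a short running-mean smooth.
#'
#' @param image Grayscale matrix.
#' @param background_estimate Optional: a matrix of the image's dimensions
#'   or a per-column vector, strictly positive.
#' @param window_px Half-width of the dilation window used to locate dark
#'   columns; default `max(25, 8%% of the image width)`, which must exceed
#'   the widest bar.
#' @param smooth_px Full width of the running-mean smoother (odd; default 5).
#' @return The corrected image (same dimensions, clipped to `[0, 255]`).
#' @export
flat_field_correct <- function(image, background_estimate = NULL,
                               window_px = NULL, smooth_px = 5) {
  if (is.null(background_estimate)) {
    if (is.null(window_px)) window_px <- max(25L, ceiling(0.08 * ncol(image)))
    prof <- apply(image, 2, max)
    # columns well below the local upper envelope are bars/strips; the
    # illumination there is interpolated from the flanking background
    envelope <- .closing1d(prof, window_px)
    dark <- prof < 0.9 * envelope
    bg <- prof
    if (any(dark) && !all(dark)) {
      xs <- seq_along(prof)
      bg[dark] <- stats::approx(xs[!dark], prof[!dark], xout = xs[dark],
                                rule = 2)$y
    }
    bg <- .runmean1d(bg, smooth_px)
  } else {
    bg <- background_estimate
    if (is.matrix(bg)) {
      if (!all(dim(bg) == dim(image)))
        stop("'background_estimate' matrix must match the image dimensions",
             call. = FALSE)
    } else if (length(bg) != ncol(image)) {
      stop("'background_estimate' vector must have one value per column",
           call. = FALSE)
    }
    if (any(bg <= 0))
      stop("'background_estimate' must be strictly positive everywhere",
           call. = FALSE)
  }
  scale_to <- stats::median(if (is.matrix(bg)) bg else bg)
  norm <- if (is.matrix(bg)) image / bg else sweep(image, 2, bg, `/`)
  out <- pmin(pmax(norm * scale_to, 0), 255)
  attributes(out) <- attributes(image)
  out
}

# 1-D grayscale closing (dilation then erosion) with half-width r
.closing1d <- function(x, r) {
  n <- length(x)
  roll <- function(v, f) {
    pad <- c(rep(v[1], r), v, rep(v[n], r))
    vapply(seq_len(n), function(i) f(pad[i:(i + 2 * r)]), numeric(1))
  }
  roll(roll(x, max), min)
}

.runmean1d <- function(x, w) {
  if (w < 2) return(x)
  r <- w %/% 2
  n <- length(x)
  pad <- c(rep(x[1], r), x, rep(x[n], r))
  stats::filter(pad, rep(1 / (2 * r + 1), 2 * r + 1))[(r + 1):(r + n)]
}

#' Measure the four binding strips of a rendered assay
#'
#' Samples each strip region and a quiet-zone background region (the same
#' rows), pools luminosities, and reports the ODR per strip.  Strip
#' rectangles come from the image's `strip_rects` attribute when present
#' (i.e. an image produced by [render_assay()]) or are recomputed from the
#' layout.  Regions are inset horizontally to avoid blurred edges.
#'
#' @param image Grayscale image from [render_assay()] (or compatible).
#' @param layout The [assay_layout()] used to render, needed only when the
#'   image lacks a `strip_rects` attribute.
#' @param plan A [sampling_plan()], or `NULL` to auto-size groups to the
#'   region (3 groups filling each inset strip region).
#' @param inset_frac Fraction of each strip's width trimmed from both
#'   vertical edges before sampling (default 0.2).
#' @param model Luminosity model for RGB input.
#' @return A data frame of class `strip_measurements` with columns
#'   `strip_index`, `role`, `I_s`, `I_s_sd`, `I_b`, `odr`.
#' @export
measure_assay <- function(image, layout = NULL, plan = NULL,
                          inset_frac = 0.2, model = luminosity_model()) {
  rects <- attr(image, "strip_rects")
  bgrect <- attr(image, "background_rect")
  if (is.null(rects)) {
    if (is.null(layout))
      stop("image carries no strip geometry; supply the rendering 'layout'",
           call. = FALSE)
    probe <- render_assay(layout = layout,
                          scenario = render_scenario(blur_sigma_mm = 0))
    rects <- attr(probe, "strip_rects")
    bgrect <- attr(probe, "background_rect")
  }
  img <- luminosity(image, model)
  regions <- list()
  for (i in seq_len(nrow(rects))) {
    ins <- floor(rects$width[i] * inset_frac)
    regions[[paste0("strip", rects$strip_index[i])]] <-
      c(x = rects$x[i] + ins, y = rects$y[i],
        width = rects$width[i] - 2 * ins, height = rects$height[i])
  }
  regions$background <- c(x = bgrect$x, y = bgrect$y,
                          width = bgrect$width, height = bgrect$height)
  if (is.null(plan)) {
    cap <- vapply(regions, function(r) (r[["height"]] %/% 3) * r[["width"]],
                  numeric(1))
    plan <- sampling_plan(3, max(1, floor(min(cap))))
  }
  sam <- sample_regions(img, regions, plan, model)
  reg <- sam$regions
  I_b <- reg$mean[reg$region == "background"]
  stripreg <- reg[reg$region != "background", ]
  idx <- as.integer(sub("strip", "", stripreg$region))
  out <- data.frame(
    strip_index = idx,
    role = rects$role[match(idx, rects$strip_index)],
    I_s = stripreg$mean, I_s_sd = stripreg$sd, I_b = I_b,
    odr = suppressWarnings(as.numeric(odr(I_b, stripreg$mean))),
    stringsAsFactors = FALSE)
  out <- out[order(out$strip_index), ]
  rownames(out) <- NULL
  class(out) <- c("strip_measurements", "data.frame")
  out
}
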