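# Synthetic imaging: render Code 39 barcodes and barcode-formatted assays as
# 8-bit grayscale rasters.  Physical geometry follows the assay chip: each
# wide bar of the positive-result character is realized as a 3 mm test line
# and a 2 mm control line separated by a ~0.5 mm white barrier, so the wide
# module equals test + barrier + control (5.5 mm) and the narrow module is
# wide / wide_ratio.

#' Physical layout of a barcode-formatted assay
#'
#' @param positive_char,negative_char The differential character pair.  The
#'   positive-result character must realize its differential elements as
#'   wide bars (default "-"); the negative-result character must turn those
#'   same positions into narrow bars flanked by wide spaces (default "+").
#' @param test_line_mm Width of the test line (first part of each divided
#'   wide bar), default 3 mm.
#' @param control_line_mm Width of the control line, default 2 mm.
#' @param barrier_mm Width of the white barrier separating test and control
#'   lines inside a wide bar, default 0.5 mm.
#' @param strip_height_mm Height of the rendered strip region, default 5 mm.
#' @param dpi Rendering resolution in dots per inch, default 300.
#' @param background_gray Background gray level (default 255, white).
#' @param printed_gray Gray level of printed, non-assay bars (default 0,
#'   black: the printed remainder of the barcode).
#' @param wide_ratio Wide:narrow module ratio (Code 39 permits 2-3; default
#'   3, which maximizes decode margin and matches the 5.5 mm divided wide
#'   bar against a ~1.83 mm narrow module).
#' @param quiet_modules Quiet-zone width on each side, in narrow modules
#'   (default 10).
#' @return An object of class `assay_layout`.  The derived fields
#'   `wide_mm` (= test + barrier + control) and `narrow_mm` (= wide /
#'   `wide_ratio`) define the module grid.
#' @export
assay_layout <- function(positive_char = "-", negative_char = "+",
                         test_line_mm = 3, control_line_mm = 2,
                         barrier_mm = 0.5, strip_height_mm = 5,
                         dpi = 300, background_gray = 255, printed_gray = 0,
                         wide_ratio = 3, quiet_modules = 10) {
  positive_char <- .norm_char(positive_char)
  negative_char <- .norm_char(negative_char)
  stopifnot(test_line_mm > 0, control_line_mm > 0, barrier_mm > 0,
            strip_height_mm > 0, dpi > 0, wide_ratio > 1, quiet_modules >= 0)
  if (background_gray < 1 || background_gray > 255)
    stop("'background_gray' must be in [1, 255]", call. = FALSE)
  if (printed_gray < 0 || printed_gray >= background_gray)
    stop("'printed_gray' must be in [0, background_gray)", call. = FALSE)
  wide_mm <- test_line_mm + barrier_mm + control_line_mm
  layout <- structure(list(
    positive_char = positive_char, negative_char = negative_char,
    test_line_mm = test_line_mm, control_line_mm = control_line_mm,
    barrier_mm = barrier_mm, strip_height_mm = strip_height_mm,
    dpi = dpi, background_gray = background_gray, printed_gray = printed_gray,
    wide_ratio = wide_ratio, quiet_modules = quiet_modules,
    wide_mm = wide_mm, narrow_mm = wide_mm / wide_ratio
  ), class = "assay_layout")
  .pair_channels(layout)  # validates the pair is physically compatible
  layout
}

#' @export
print.assay_layout <- function(x, ...) {
  cat(sprintf(
    "Assay layout: pair (%s positive / %s negative), test %.3g mm + barrier %.3g mm + control %.3g mm\n",
    dQuote(x$positive_char), dQuote(x$negative_char),
    x$test_line_mm, x$barrier_mm, x$control_line_mm))
  cat(sprintf("  modules: narrow %.3f mm, wide %.3f mm (%g:1), %g dpi\n",
              x$narrow_mm, x$wide_mm, x$wide_ratio, x$dpi))
  invisible(x)
}

#' Rendering scenario: strip darkness and optical degradation
#'
#' @param strip_odrs Numeric vector of 4 target ODR values in `[0, 1]`, one
#'   per binding strip (order: test 1, control 1, test 2, control 2).  A
#'   strip's drawn gray is `background_gray * (1 - ODR)`.
#' @param blur_sigma_mm Gaussian optical blur, standard deviation in mm.
#'   Default 0.35 mm: jointly calibrated with the decoder's bar threshold
#'   (0.20) so that the 0.5 mm barrier inside a divided wide bar fills in
#'   only when strip ODR reaches the observed "-" readability floor (0.44)
#'   while a lone control line reads from 0.24 up (see the methods
#'   vignette).
#' @param lighting Lighting model: "none" or "linear_gradient".
#' @param lighting_amplitude Ramp amplitude (fraction, 0-0.5); the image is
#'   multiplied by a left-to-right ramp spanning `[1 - a, 1 + a]`.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian pixel noise in
#'   gray levels (default 0).
#' @param seed Integer seed making the noise field reproducible.
#' @return An object of class `render_scenario`.
#' @export
render_scenario <- function(strip_odrs = c(1, 1, 1, 1), blur_sigma_mm = 0.35,
                            lighting = c("none", "linear_gradient"),
                            lighting_amplitude = 0, noise_sigma = 0,
                            seed = 1L) {
  lighting <- match.arg(lighting)
  if (length(strip_odrs) != 4L || anyNA(strip_odrs))
    stop("'strip_odrs' must be 4 ODR values (test1, control1, test2, control2)",
         call. = FALSE)
  if (any(strip_odrs < 0 | strip_odrs > 1))
    stop("strip ODR values must lie in [0, 1]", call. = FALSE)
  if (lighting_amplitude < 0 || lighting_amplitude > 0.5)
    stop("'lighting_amplitude' must lie in [0, 0.5]", call. = FALSE)
  stopifnot(blur_sigma_mm >= 0, noise_sigma >= 0)
  structure(list(strip_odrs = as.numeric(strip_odrs),
                 blur_sigma_mm = blur_sigma_mm, lighting = lighting,
                 lighting_amplitude = lighting_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "render_scenario")
}

# run expr with a fixed RNG seed, restoring caller RNG state
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}

.px_per_mm <- function(dpi) dpi / 25.4
.round_half_up <- function(x) floor(x + 0.5)

# element sequence (mm) for a full barcode: quiet, chars with gaps, quiet
.barcode_elements <- function(spec, layout) {
  stopifnot(inherits(spec, "barcode_spec"), inherits(layout, "assay_layout"))
  nw <- layout$narrow_mm
  wd <- layout$wide_mm
  rows <- list()
  add <- function(char, index, role, width_class, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      char = char, index = index, role = role, width_class = width_class,
      mm = mm, stringsAsFactors = FALSE)
  }
  add(NA_character_, NA_integer_, "quiet", "quiet", layout$quiet_modules * nw)
  for (i in seq_along(spec$chars)) {
    p <- encode_char(spec$chars[i])
    for (j in 1:9) {
      wc <- p$elements$width_class[j]
      add(spec$chars[i], j, p$elements$role[j], wc, if (wc == "wide") wd else nw)
    }
    if (i < length(spec$chars))
      add(NA_character_, NA_integer_, "gap", "narrow", nw)
  }
  add(NA_character_, NA_integer_, "quiet", "quiet", layout$quiet_modules * nw)
  el <- do.call(rbind, rows)
  # pixel edges: accumulate from the left, rounding half-up per edge so
  # rounding error never drifts
  ppm <- .px_per_mm(layout$dpi)
  edges <- .round_half_up(cumsum(c(0, el$mm)) * ppm)
  el$x0 <- edges[-length(edges)]   # 0-based, half-open [x0, x1)
  el$x1 <- edges[-1]
  el
}

# identify the assay channels of the layout's character pair:
# wide bars of the positive character that are narrow bars in the negative
# character, with the control line aligned to the negative character's bar
.pair_channels <- function(layout) {
  pos <- encode_char(layout$positive_char)
  neg <- encode_char(layout$negative_char)
  dpos <- which(pos$elements$width_class != neg$elements$width_class)
  if (length(dpos) == 0L)
    stop("positive and negative characters have identical patterns",
         call. = FALSE)
  nw <- layout$narrow_mm
  mmw <- function(p) ifelse(p$elements$width_class == "wide", layout$wide_mm, nw)
  pe <- cumsum(c(0, mmw(pos)))  # element mm offsets within the character
  ne <- cumsum(c(0, mmw(neg)))
  chan_idx <- which(pos$elements$role == "bar" &
                    pos$elements$width_class == "wide" &
                    seq_len(9) %in% dpos)
  if (length(chan_idx) != 2L)
    stop(sprintf(
      "pair (%s, %s) is not an assay pair: the positive character must have exactly 2 wide bars among the differential elements",
      dQuote(layout$positive_char), dQuote(layout$negative_char)),
      call. = FALSE)
  chans <- lapply(seq_along(chan_idx), function(k) {
    j <- chan_idx[k]
    L <- pe[j]; R <- pe[j + 1]
    if (neg$elements$role[j] != "bar" || neg$elements$width_class[j] != "narrow")
      stop("negative character must carry a narrow bar at each channel position",
           call. = FALSE)
    nL <- ne[j]; nR <- ne[j + 1]
    # which end of the channel does the negative character's bar touch?
    control_side <- if (abs(nR - R) <= abs(nL - L)) "right" else "left"
    if (control_side == "right") {
      list(element = j, test = c(L, L + layout$test_line_mm),
           barrier = c(L + layout$test_line_mm,
                       L + layout$test_line_mm + layout$barrier_mm),
           control = c(R - layout$control_line_mm, R))
    } else {
      list(element = j, test = c(R - layout$test_line_mm, R),
           barrier = c(L + layout$control_line_mm,
                       L + layout$control_line_mm + layout$barrier_mm),
           control = c(L, L + layout$control_line_mm))
    }
  })
  list(diff_positions = dpos, channels = chans)
}

.check_narrow_px <- function(el, layout) {
  nw_px <- el$x1[el$width_class == "narrow"] - el$x0[el$width_class == "narrow"]
  if (length(nw_px) && min(nw_px) < 2)
    stop(sprintf(
      "dpi %g is too low: the %.3f mm narrow module spans %d px (< 2 px); increase dpi",
      layout$dpi, layout$narrow_mm, min(nw_px)), call. = FALSE)
}

.new_image <- function(layout, width_px) {
  h <- max(1L, .round_half_up(layout$strip_height_mm * .px_per_mm(layout$dpi)))
  img <- matrix(layout$background_gray, nrow = h, ncol = width_px)
  attr(img, "dpi") <- layout$dpi
  img
}

#' Render a plain Code 39 barcode image
#'
#' Bars are drawn at `printed_gray`, spaces and the quiet zones at
#' `background_gray`; element widths follow the layout's module grid
#' (mm converted to pixels at `dpi`, edges rounded half-up cumulatively).
#' No optical degradation is applied.
#'
#' @param spec A `barcode_spec` from [encode_string()], or a payload string.
#' @param layout An [assay_layout()].
#' @return An 8-bit grayscale image matrix (rows = y, columns = x) with
#'   attributes `dpi` and `geometry` (per-element pixel extents).
#' @export
#' @examples
#' img <- render_barcode(encode_string("+"), assay_layout())
render_barcode <- function(spec, layout = assay_layout()) {
  if (is.character(spec)) spec <- encode_string(spec)
  el <- .barcode_elements(spec, layout)
  .check_narrow_px(el, layout)
  img <- .new_image(layout, max(el$x1))
  for (i in which(el$role == "bar"))
    img[, (el$x0[i] + 1L):el$x1[i]] <- layout$printed_gray
  attr(img, "geometry") <- el
  img
}

#' Render a barcode-formatted assay image
#'
#' The barcode is printed as in [render_barcode()] except at the assay slot:
#' the first payload character belonging to the layout's differential pair.
#' There, the shared elements are printed normally while each channel (wide
#' bar of the positive character) is drawn as a test line, a white barrier
#' and a control line, each at gray `background_gray * (1 - ODR)` from the
#' scenario's `strip_odrs`.  Gaussian blur, the lighting gradient and seeded
#' pixel noise are then applied in that order and the result is clipped to
#' `[0, 255]` and quantized to 8 bits.
#'
#' @param spec A `barcode_spec` (or payload string) containing at least one
#'   character of the layout's pair; defaults to the positive character
#'   alone.  Either pair character selects the same printed skeleton - the
#'   rendered appearance is governed entirely by the strip ODRs.
#' @param layout An [assay_layout()].
#' @param scenario A [render_scenario()].
#' @return 8-bit grayscale image matrix with attributes `dpi`, `geometry`,
#'   `strip_rects` (pixel rectangles of the four binding strips, 0-based
#'   half-open `x`, `y`, `width`, `height`) and `background_rect` (a
#'   quiet-zone rectangle at the same rows).
#' @export
#' @examples
#' img <- render_assay(scenario = render_scenario(strip_odrs = c(0, 1, 0, 1)))
render_assay <- function(spec = NULL, layout = assay_layout(),
                         scenario = render_scenario()) {
  stopifnot(inherits(layout, "assay_layout"),
            inherits(scenario, "render_scenario"))
  if (is.null(spec)) spec <- encode_string(layout$positive_char)
  if (is.character(spec)) spec <- encode_string(spec)
  pair <- c(layout$positive_char, layout$negative_char)
  payload_chars <- spec$chars[-c(1L, length(spec$chars))]
  slot_in_payload <- which(payload_chars %in% pair)
  if (length(slot_in_payload) == 0L)
    stop(sprintf("payload %s contains neither pair character (%s, %s)",
                 dQuote(spec$payload), dQuote(pair[1]), dQuote(pair[2])),
         call. = FALSE)
  slot <- slot_in_payload[1] + 1L  # index into spec$chars
  # the printed skeleton always uses the positive character's element widths
  chars <- spec$chars
  chars[slot] <- layout$positive_char
  skeleton <- spec
  skeleton$chars <- chars
  el <- .barcode_elements(skeleton, layout)
  .check_narrow_px(el, layout)
  img <- .new_image(layout, max(el$x1))
  ppm <- .px_per_mm(layout$dpi)

  ch <- .pair_channels(layout)
  # locate the slot's rows in the element table by counting character starts
  char_row_start <- which(el$index == 1L)
  slot_start_row <- char_row_start[slot]
  slot_el_rows <- slot_start_row:(slot_start_row + 8L)
  slot_mm0 <- sum(el$mm[seq_len(slot_start_row - 1L)])
  chan_elements <- vapply(ch$channels, function(x) x$element, integer(1))

  bar_rows <- which(el$role == "bar")
  skip <- slot_el_rows[chan_elements]     # channel bars drawn as strips
  for (i in setdiff(bar_rows, skip))
    img[, (el$x0[i] + 1L):el$x1[i]] <- layout$printed_gray

  px <- function(mm) .round_half_up((slot_mm0 + mm) * ppm)
  strip_rects <- list()
  for (k in seq_along(ch$channels)) {
    chan <- ch$channels[[k]]
    for (role in c("test", "control")) {
      iv <- chan[[role]]
      x0 <- px(iv[1]); x1 <- px(iv[2])
      idx <- if (role == "test") 2L * k - 1L else 2L * k
      odr <- scenario$strip_odrs[idx]
      img[, (x0 + 1L):x1] <- layout$background_gray * (1 - odr)
      strip_rects[[length(strip_rects) + 1L]] <- data.frame(
        strip_index = idx, role = role, channel = k,
        x = x0, y = 0L, width = x1 - x0, height = nrow(img))
    }
  }
  strip_rects <- do.call(rbind, strip_rects)
  strip_rects <- strip_rects[order(strip_rects$strip_index), ]
  rownames(strip_rects) <- NULL

  dpi <- layout$dpi
  if (scenario$blur_sigma_mm > 0)
    img <- .gaussian_blur(img, scenario$blur_sigma_mm * ppm)
  if (scenario$lighting != "none")
    img <- apply_lighting(img, scenario$lighting, scenario$lighting_amplitude)
  if (scenario$noise_sigma > 0)
    img <- .with_seed(scenario$seed,
                      img + matrix(stats::rnorm(length(img), 0,
                                                scenario$noise_sigma),
                                   nrow(img)))
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "dpi") <- dpi
  attr(img, "geometry") <- el
  attr(img, "strip_rects") <- strip_rects
  # background reference region inside the leading quiet zone
  q0 <- .round_half_up(2 * layout$narrow_mm * ppm)
  q1 <- .round_half_up((layout$quiet_modules - 2) * layout$narrow_mm * ppm)
  attr(img, "background_rect") <- data.frame(
    x = q0, y = 0L, width = max(1L, q1 - q0), height = nrow(img))
  img
}

# separable Gaussian blur with edge replication
.gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3.5 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv_cols <- function(m) {
    pad <- cbind(m[, rep(1L, r), drop = FALSE], m,
                 m[, rep(ncol(m), r), drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[, j:(j + ncol(m) - 1L), drop = FALSE]
    out
  }
  img2 <- conv_cols(img)
  if (nrow(img2) > 1) img2 <- t(conv_cols(t(img2)))
  img2
}

#' Apply a lighting gradient to an image
#'
#' Models uneven illumination (glare / preferential lighting from one side):
#' pixel intensities are multiplied by a left-to-right linear ramp spanning
#' `[1 - amplitude, 1 + amplitude]`, then clipped to `[0, 255]`.
#'
#' @param image Grayscale image matrix.
#' @param model "none" (identity) or "linear_gradient".
#' @param amplitude Ramp amplitude in `[0, 0.5]`.
#' @return The lit image.
#' @export
apply_lighting <- function(image, model = c("linear_gradient", "none"),
                           amplitude = 0.2) {
  model <- match.arg(model)
  if (amplitude < 0 || amplitude > 0.5)
    stop("'amplitude' must lie in [0, 0.5]", call. = FALSE)
  if (model == "none" || amplitude == 0) return(image)
  ramp <- seq(1 - amplitude, 1 + amplitude, length.out = ncol(image))
  out <- sweep(image, 2, ramp, `*`)
  out <- pmin(pmax(out, 0), 255)
  attributes(out) <- attributes(image)
  out
}
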