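# Scanline decoding of Code 39 barcodes from raster images: column-wise
# profile over a central band, ODR-thresholded binarization against a local
# background estimate, run-length measurement, wide/narrow classification,
# and table lookup with orientation handling via the "*" start/stop framing.

#' Decoder configuration
#'
#' @param bar_threshold_odr Minimum ODR of a column (against the estimated
#'   local background) for it to count as dark.  Default 0.20; jointly
#'   calibrated with the renderer's default blur so the readability floors
#'   of the barcode-formatted assay land at 0.24 for "+" and 0.44 for "-"
#'   on a 0.04 ODR grid (see the methods vignette).
#' @param ratio_cut Wide/narrow boundary as a multiple of the estimated
#'   narrow run width (default 2.0; must lie in (1, 3)).
#' @param band_fraction Fraction of the image height averaged into the scan
#'   profile (central band; default 0.2).
#' @param require_quiet_zones If `TRUE` (default) decoding fails with
#'   status `quiet_zone_violation` unless light margins of at least 7
#'   narrow modules flank the symbol.
#' @param background_quantile Quantile of the profile used as the local
#'   background estimate (default 0.95, robust to glare).
#' @param min_bar_fraction Dark runs shorter than this fraction of the
#'   median dark-run width are discarded as speckle (default 0.4); narrow
#'   bars always outnumber wide ones in Code 39, so the median dark run is
#'   a narrow bar.
#' @return Object of class `decode_config`.
#' @export
decode_config <- function(bar_threshold_odr = 0.20, ratio_cut = 2.0,
                          band_fraction = 0.2, require_quiet_zones = TRUE,
                          background_quantile = 0.95,
                          min_bar_fraction = 0.4) {
  if (bar_threshold_odr <= 0 || bar_threshold_odr >= 1)
    stop("'bar_threshold_odr' must lie in (0, 1)", call. = FALSE)
  if (ratio_cut <= 1 || ratio_cut >= 3)
    stop("'ratio_cut' must lie in (1, 3)", call. = FALSE)
  stopifnot(band_fraction > 0, band_fraction <= 1,
            background_quantile > 0, background_quantile <= 1,
            min_bar_fraction >= 0, min_bar_fraction < 1)
  structure(list(bar_threshold_odr = bar_threshold_odr,
                 ratio_cut = ratio_cut, band_fraction = band_fraction,
                 require_quiet_zones = isTRUE(require_quiet_zones),
                 background_quantile = background_quantile,
                 min_bar_fraction = min_bar_fraction),
            class = "decode_config")
}

#' Extract a scanline profile from an image
#'
#' @param image Grayscale matrix or RGB array (converted to luminosity).
#' @param config A [decode_config()]; `band_fraction` selects the central
#'   band of rows whose column-wise mean forms the profile.
#' @return Object of class `scan_profile`: `values` (length = image width)
#'   and `band_rows`.
#' @export
extract_scanline <- function(image, config = decode_config()) {
  img <- luminosity(image)
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop("empty image", call. = FALSE)
  h <- nrow(img)
  nb <- max(1L, round(h * config$band_fraction))
  r0 <- max(1L, (h - nb) %/% 2 + 1L)
  rows <- r0:min(h, r0 + nb - 1L)
  structure(list(values = colMeans(img[rows, , drop = FALSE]),
                 band_rows = range(rows)),
            class = "scan_profile")
}

#' Binarize a scan profile into alternating runs
#'
#' The local background is estimated as an upper quantile of the profile; a
#' column is dark iff its ODR against that background reaches
#' `bar_threshold_odr`.  Maximal runs are measured and leading/trailing
#' light runs trimmed (their lengths are kept as attributes for the
#' quiet-zone check).
#'
#' @param profile A [extract_scanline()] result (or numeric vector).
#' @param config A [decode_config()].
#' @return A data frame with columns `dark` and `length`, attributes
#'   `background`, `leading_light`, `trailing_light`; zero rows (with
#'   attribute `status = "no_bars"`) if no column is dark.
#' @export
binarize_runs <- function(profile, config = decode_config()) {
  v <- if (inherits(profile, "scan_profile")) profile$values else as.numeric(profile)
  if (length(v) == 0L) stop("empty profile", call. = FALSE)
  bg <- as.numeric(stats::quantile(v, config$background_quantile))
  if (bg <= 0) bg <- 1
  dark <- (bg - v) / bg >= config$bar_threshold_odr
  r <- rle(dark)
  runs <- data.frame(dark = r$values, length = r$lengths)
  lead <- if (nrow(runs) && !runs$dark[1]) runs$length[1] else 0L
  trail <- if (nrow(runs) && !runs$dark[nrow(runs)]) runs$length[nrow(runs)] else 0L
  runs <- runs[cumsum(runs$dark) > 0 & rev(cumsum(rev(runs$dark))) > 0, ,
               drop = FALSE]
  rownames(runs) <- NULL
  attr(runs, "background") <- bg
  attr(runs, "leading_light") <- lead
  attr(runs, "trailing_light") <- trail
  if (!nrow(runs)) attr(runs, "status") <- "no_bars"
  runs
}

# per-polarity narrow-width estimate: median of the cluster of runs within
# ratio_cut of the smallest run (ties broken toward narrow)
.narrow_estimate <- function(lens, ratio_cut) {
  stats::median(lens[lens <= ratio_cut * min(lens)])
}

.lookup_pattern <- function(pat) {
  hit <- names(.code39_table)[match(pat, .code39_table)]
  if (length(hit) == 0L) NA_character_ else hit
}

# one decoding attempt over an ordered run table
.attempt_decode <- function(runs, config) {
  lens <- runs$length
  dark <- runs$dark
  # speckle rejection: drop implausibly thin dark runs, merging neighbours
  if (any(dark)) {
    med <- stats::median(lens[dark])
    while (TRUE) {
      bad <- which(dark & lens < config$min_bar_fraction * med)
      if (!length(bad)) break
      i <- bad[1]
      lo <- max(1L, i - 1L); hi <- min(length(lens), i + 1L)
      merged <- sum(lens[lo:hi])
      keep <- setdiff(seq_along(lens), c(i, setdiff(lo:hi, i)))
      ins <- min(lo, i)
      lens <- append(lens[keep], merged, after = ins - 1L)
      dark <- append(dark[keep], FALSE, after = ins - 1L)
    }
    # re-trim any light runs exposed at the ends
    while (length(dark) && !dark[1]) { dark <- dark[-1]; lens <- lens[-1] }
    while (length(dark) && !dark[length(dark)]) {
      dark <- dark[-length(dark)]; lens <- lens[-length(lens)]
    }
  }
  n <- length(lens)
  if (n < 9L || n %% 10L != 9L)
    return(list(status = "unknown_pattern"))
  ne_dark <- .narrow_estimate(lens[dark], config$ratio_cut)
  ne_light <- if (any(!dark)) .narrow_estimate(lens[!dark], config$ratio_cut)
              else ne_dark
  ne <- ifelse(dark, ne_dark, ne_light)
  wide <- lens > config$ratio_cut * ne
  k <- (n + 1L) %/% 10L
  chars <- character(k); margins <- numeric(k)
  for (i in seq_len(k)) {
    idx <- (10L * (i - 1L) + 1L):(10L * (i - 1L) + 9L)
    pat <- paste(ifelse(wide[idx], "W", "N"), collapse = "")
    chars[i] <- .lookup_pattern(pat)
    margins[i] <- min(abs(lens[idx] - config$ratio_cut * ne[idx]) / ne[idx])
  }
  list(status = "ok", chars = chars, margins = margins,
       ne_light = ne_light)
}

#' Classify runs and decode to characters
#'
#' Estimates narrow run width per polarity (dark runs widen and light runs
#' shrink under blur, so they are clustered separately), classifies each
#' run wide iff it exceeds `ratio_cut` times the narrow estimate, groups
#' 9-element characters split on inter-character gaps, and maps patterns to
#' characters.  If the first character is not the start/stop symbol "*" the
#' reversed run sequence is tried and the orientation reported as
#' `reversed`.
#'
#' @param runs Output of [binarize_runs()].
#' @param config A [decode_config()].
#' @return Object of class `decode_result`: `payload`, `orientation`,
#'   `per_char_margin`, `status` (`ok`, `no_start_stop`, `unknown_pattern`
#'   or `quiet_zone_violation`) and the framed `raw` read.
#' @export
classify_and_decode <- function(runs, config = decode_config()) {
  fail <- function(status) structure(
    list(payload = NA_character_, orientation = NA_character_,
         per_char_margin = numeric(0), status = status, raw = NA_character_),
    class = "decode_result")
  if (!nrow(runs)) return(fail("no_start_stop"))
  fwd <- .attempt_decode(runs, config)
  rev_runs <- runs[rev(seq_len(nrow(runs))), , drop = FALSE]
  bwd <- .attempt_decode(rev_runs, config)
  pick <- NULL; orientation <- NA_character_
  ok_frame <- function(a) {
    a$status == "ok" && !anyNA(a$chars) && length(a$chars) >= 3L &&
      a$chars[1] == "*" && a$chars[length(a$chars)] == "*" &&
      !any(a$chars[-c(1L, length(a$chars))] == "*")
  }
  if (ok_frame(fwd)) { pick <- fwd; orientation <- "forward" }
  else if (ok_frame(bwd)) { pick <- bwd; orientation <- "reversed" }
  if (is.null(pick)) {
    has_star <- function(a) a$status == "ok" && !is.na(a$chars[1]) &&
      a$chars[1] == "*"
    status <- if (has_star(fwd) || has_star(bwd)) "unknown_pattern"
              else if (fwd$status == "ok" || bwd$status == "ok") "no_start_stop"
              else "unknown_pattern"
    return(fail(status))
  }
  if (config$require_quiet_zones) {
    need <- 7 * pick$ne_light
    if (attr(runs, "leading_light") < need ||
        attr(runs, "trailing_light") < need)
      return(fail("quiet_zone_violation"))
  }
  k <- length(pick$chars)
  structure(list(
    payload = paste(pick$chars[-c(1L, k)], collapse = ""),
    orientation = orientation,
    per_char_margin = pick$margins[-c(1L, k)],
    status = "ok",
    raw = paste(pick$chars, collapse = "")
  ), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("Decoded payload %s (%s read)\n", dQuote(x$payload),
                x$orientation))
  else cat(sprintf("Decode failed: %s\n", x$status))
  invisible(x)
}

#' Decode a Code 39 barcode image
#'
#' Composition of [extract_scanline()], [binarize_runs()] and
#' [classify_and_decode()].
#'
#' @param image Grayscale matrix or RGB array.
#' @param config A [decode_config()].
#' @return A `decode_result`.
#' @export
#' @examples
#' decode_image(render_barcode(encode_string("A+")))$payload
decode_image <- function(image, config = decode_config()) {
  profile <- extract_scanline(image, config)
  runs <- binarize_runs(profile, config)
  classify_and_decode(runs, config)
}

#' Minimum readable strip ODR for an assay character
#'
#' Renders the barcode-formatted assay at each grid ODR with a
#' deterministic (noise-free) scenario and reports the smallest grid value
#' from which decoding the expected character succeeds monotonically (every
#' larger grid value must also decode).
#'
#' For the negative character ("+") the test strips are blank and the
#' control strips carry the grid ODR; for the positive character ("-") all
#' four strips carry it, so readability additionally requires the blurred
#' 0.5 mm barrier to fill in and merge each divided wide bar - which is why
#' the "-" floor sits higher than the "+" floor.
#'
#' @param character One of the layout's pair characters.
#' @param layout An [assay_layout()].
#' @param scenario Scenario template; its `strip_odrs` and `noise_sigma`
#'   are overridden (noise-free, strips set per grid point).
#' @param odr_grid Ascending grid of ODR values in `[0, 1]` (default step
#'   0.04, matching the printed readability series).
#' @param config A [decode_config()].
#' @return The minimum readable ODR (NA if the character is never read on
#'   the grid), with attribute `grid` (a data frame of per-grid-point
#'   decode outcomes).
#' @export
min_readable_odr <- function(character, layout = assay_layout(),
                             scenario = render_scenario(),
                             odr_grid = seq(0.04, 1, by = 0.04),
                             config = decode_config()) {
  character <- .norm_char(character)
  if (is.unsorted(odr_grid) || any(odr_grid < 0 | odr_grid > 1))
    stop("'odr_grid' must be ascending within [0, 1]", call. = FALSE)
  pair <- c(layout$positive_char, layout$negative_char)
  if (!character %in% pair)
    stop(sprintf("character %s is not part of the layout's pair (%s, %s)",
                 dQuote(character), dQuote(pair[1]), dQuote(pair[2])),
         call. = FALSE)
  positive <- character == layout$positive_char
  read_at <- vapply(odr_grid, function(g) {
    sc <- scenario
    sc$strip_odrs <- if (positive) rep(g, 4) else c(0, g, 0, g)
    sc$noise_sigma <- 0
    img <- render_assay(layout = layout, scenario = sc)
    res <- decode_image(img, config)
    res$status == "ok" && identical(res$payload, character)
  }, logical(1))
  grid <- data.frame(odr = odr_grid, readable = read_at)
  # longest all-readable suffix of the grid
  ok_from <- rev(cumprod(rev(read_at))) > 0
  out <- if (any(ok_from)) odr_grid[which(ok_from)[1]] else NA_real_
  attr(out, "grid") <- grid
  out
}
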