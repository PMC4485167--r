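# Assay semantics: qualitative calls from strip ODRs, the expected decoded
# character, dose-response calibration (four-parameter logistic) with
# inverse prediction, and multiplexed barcode design/parsing.
#
# Polarity convention: a *positive* test (analyte present) darkens test and
# control lines so the divided wide bars read whole and the scanner sees the
# positive-result character ("-"); a valid *negative* test darkens only the
# control lines, so "+" is read.  A control line without signal voids the
# test regardless of the test lines.

#' Qualitative call from strip measurements
#'
#' Strips 1 and 3 are test lines, strips 2 and 4 control lines.  All
#' controls must carry signal for the test to be valid; test-line signal
#' then decides positive vs negative.
#'
#' @param strips A `strip_measurements` data frame from [measure_assay()],
#'   or a numeric vector of 4 ODR values in strip order.
#' @param signal_threshold_odr Minimum ODR counting as signal.  Default
#'   0.10: above reported blank-level ODRs (0.04-0.07) and below the
#'   decoder's readability floor, so quantification reaches below what the
#'   barcode scan itself can read.
#' @param analyte Label attached to the call.
#' @return Object of class `qual_call`: `analyte`, `result`
#'   (positive/negative/invalid) and the per-strip ODR `evidence`.
#' @export
#' @examples
#' qualitative_call(c(0.02, 0.5, 0.03, 0.5))$result  # "negative"
qualitative_call <- function(strips, signal_threshold_odr = 0.10,
                             analyte = "analyte") {
  odrs <- if (inherits(strips, "strip_measurements")) {
    strips$odr[order(strips$strip_index)]
  } else as.numeric(strips)
  if (length(odrs) != 4L || anyNA(odrs))
    stop("expected 4 strip ODR values (test1, control1, test2, control2)",
         call. = FALSE)
  sig <- odrs >= signal_threshold_odr
  controls <- sig[c(2, 4)]
  tests <- sig[c(1, 3)]
  result <- if (!all(controls)) "invalid"
            else if (all(tests)) "positive"
            else "negative"
  structure(list(analyte = analyte, result = result,
                 evidence = list(odrs = odrs,
                                 threshold = signal_threshold_odr)),
            class = "qual_call")
}

#' @export
print.qual_call <- function(x, ...) {
  cat(sprintf("%s: %s (strip ODRs %s, threshold %.2f)\n", x$analyte,
              toupper(x$result),
              paste(sprintf("%.3f", x$evidence$odrs), collapse = ", "),
              x$evidence$threshold))
  invisible(x)
}

#' Character a qualitative call should decode as
#'
#' @param call A `qual_call` (must be positive or negative; an invalid test
#'   is void and has no character).
#' @param pair Character pair `c(positive, negative)`; default the base
#'   "-"/"+" pair.  For the "F"/"$" pair, "F" is taken as positive (its
#'   differential elements are the wide bars), by analogy with "-".
#' @return The single expected character.
#' @export
expected_character <- function(call, pair = c("-", "+")) {
  stopifnot(inherits(call, "qual_call"))
  pair <- .norm_char(pair)
  if (call$result == "invalid")
    stop("an invalid test is void: no character is expected", call. = FALSE)
  if (call$result == "positive") pair[1] else pair[2]
}

.fourpl <- function(conc, lower, upper, midpoint, slope) {
  ifelse(conc <= 0, lower,
         lower + (upper - lower) / (1 + (midpoint / conc)^slope))
}

#' Fit a dose-response calibration curve
#'
#' Least-squares fit of a monotone four-parameter logistic
#' `ODR(c) = lower + (upper - lower) / (1 + (midpoint / c)^slope)`
#' (the standard sandwich-immunoassay model: ODR rises with concentration
#' and saturates at the upper asymptote).  A 3-parameter Langmuir isotherm
#' (slope fixed at 1) is available as the alternative.
#'
#' @param points Data frame with columns `concentration` and `odr` (an
#'   optional `sd` column is carried through); at least 5 points spanning a
#'   monotone increasing range.
#' @param model "logistic4" (default) or "langmuir3".
#' @param span_frac Fraction of the fitted dynamic range excluded at each
#'   asymptote when reporting the quantifiable `valid_range` (default
#'   0.05).
#' @return Object of class `calibration_curve`: fitted `params` (`lower`,
#'   `upper`, `midpoint`, `slope`), `residual_scale` (RMSE in ODR units),
#'   `valid_range` (concentration interval), `odr_span`, `model`, `data`.
#' @export
fit_calibration <- function(points, model = c("logistic4", "langmuir3"),
                            span_frac = 0.05) {
  model <- match.arg(model)
  if (!is.data.frame(points) ||
      !all(c("concentration", "odr") %in% names(points)))
    stop("'points' needs columns 'concentration' and 'odr'", call. = FALSE)
  pts <- points[order(points$concentration), , drop = FALSE]
  x <- pts$concentration; y <- pts$odr
  if (length(x) < 5L)
    stop("at least 5 calibration points are required", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (diff(range(y)) < 0.02)
    stop("degenerate calibration data: no dynamic range in ODR", call. = FALSE)
  if (stats::cor(x, y, method = "spearman") < 0.5)
    stop("calibration data are not monotone increasing in concentration",
         call. = FALSE)
  # heuristic start values
  lo0 <- max(0, min(y)); up0 <- min(1, max(y))
  half <- (lo0 + up0) / 2
  mid0 <- stats::approx(y, x, xout = half, ties = mean)$y
  if (is.na(mid0) || mid0 <= 0) mid0 <- stats::median(x[x > 0])
  sse <- function(p) {
    lower <- p[1]; upper <- p[2]; midpoint <- exp(p[3])
    slope <- if (model == "langmuir3") 1 else exp(p[4])
    sum((y - .fourpl(x, lower, upper, midpoint, slope))^2)
  }
  p0 <- c(lo0, up0, log(mid0), if (model == "logistic4") log(1.5))
  lb <- c(0, lo0, log(mid0) - 8, if (model == "logistic4") log(0.2))
  ub <- c(min(y) + 1e-9 + 0.2, 1, log(mid0) + 8,
          if (model == "logistic4") log(10))
  fit <- stats::optim(p0, sse, method = "L-BFGS-B", lower = lb, upper = ub,
                      control = list(maxit = 500, factr = 1e4))
  p <- fit$par
  params <- list(lower = p[1], upper = p[2], midpoint = exp(p[3]),
                 slope = if (model == "langmuir3") 1 else exp(p[4]))
  if (params$upper <= params$lower)
    stop("degenerate fit: upper asymptote does not exceed lower", call. = FALSE)
  resid <- y - .fourpl(x, params$lower, params$upper, params$midpoint,
                       params$slope)
  span <- params$upper - params$lower
  inv <- function(odr) params$midpoint /
    ((params$upper - params$lower) / (odr - params$lower) - 1)^(1 / params$slope)
  vr <- c(inv(params$lower + span_frac * span),
          inv(params$upper - span_frac * span))
  structure(list(params = params,
                 residual_scale = sqrt(mean(resid^2)),
                 valid_range = vr,
                 odr_span = c(params$lower + span_frac * span,
                              params$upper - span_frac * span),
                 model = model, span_frac = span_frac, data = pts),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s calibration: lower %.3f, upper %.3f, midpoint %.3g, slope %.3g\n",
              x$model, p$lower, p$upper, p$midpoint, p$slope))
  cat(sprintf("  residual scale %.4f ODR; quantifiable range %.3g - %.3g\n",
              x$residual_scale, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Predict ODR from concentration
#'
#' @param object A `calibration_curve`.
#' @param concentration Concentrations (>= 0).
#' @param ... Unused.
#' @return Predicted ODR values.
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  p <- object$params
  .fourpl(concentration, p$lower, p$upper, p$midpoint, p$slope)
}

#' Plot a calibration curve and its points
#'
#' @param x A `calibration_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.calibration_curve <- function(x, ...) {
  d <- x$data
  xmax <- max(d$concentration) * 1.1
  cc <- seq(0, xmax, length.out = 200)
  graphics::plot(d$concentration, d$odr, xlab = "concentration",
                 ylab = "ODR", ylim = c(0, max(1, d$odr)), ...)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$valid_range, lty = 3)
  invisible(x)
}

#' Estimate concentration from a measured ODR
#'
#' Inverts the fitted monotone curve.  ODRs outside the quantifiable ODR
#' span are flagged (`below_range` / `saturated`) instead of extrapolated;
#' an interval is propagated from the fit's residual scale.
#'
#' @param odr_value Measured ODR value(s).
#' @param curve A [fit_calibration()] result.
#' @return Data frame with columns `odr`, `concentration`, `lower`,
#'   `upper` (interval from inverting `odr +- residual_scale`) and `flag`
#'   (`ok`, `below_range`, `saturated`).
#' @export
estimate_concentration <- function(odr_value, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  p <- curve$params
  inv <- function(o) {
    bad <- o <= p$lower | o >= p$upper
    out <- rep(NA_real_, length(o))
    ok <- !bad
    out[ok] <- p$midpoint /
      ((p$upper - p$lower) / (o[ok] - p$lower) - 1)^(1 / p$slope)
    out
  }
  flag <- ifelse(odr_value < curve$odr_span[1], "below_range",
          ifelse(odr_value > curve$odr_span[2], "saturated", "ok"))
  conc <- inv(odr_value)
  conc[flag != "ok"] <- NA_real_
  lower <- inv(odr_value - curve$residual_scale)
  lower[!is.na(flag) & flag == "ok" &
          odr_value - curve$residual_scale <= p$lower] <- 0
  upper <- inv(odr_value + curve$residual_scale)
  upper[!is.na(flag) & flag == "ok" &
          odr_value + curve$residual_scale >= p$upper] <- Inf
  lower[flag != "ok"] <- NA_real_
  upper[flag != "ok"] <- NA_real_
  data.frame(odr = odr_value, concentration = conc,
             lower = lower, upper = upper, flag = flag,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic calibration data set
#'
#' Generates (concentration, ODR) points from a known four-parameter
#' logistic truth with seeded Gaussian noise.  Defaults state the world of
#' a silver-enhanced sandwich hCG assay: lower asymptote 0.04 (blank-level
#' ODR), upper 0.55 (saturation band 0.50-0.60), midpoint 7.5 mIU/mL (so
#' the curve saturates near 15 mIU/mL), Hill slope 2.
#'
#' @param concentrations Concentration grid (default 0-25 mIU/mL, 8 points).
#' @param truth Named list of the true parameters.
#' @param noise_sd Gaussian ODR noise standard deviation (default 0.02).
#' @param seed RNG seed.
#' @return Data frame with `concentration` and `odr`, attribute `truth`.
#' @export
simulate_calibration <- function(concentrations = c(0, 1, 2, 5, 10, 15, 20, 25),
                                 truth = list(lower = 0.04, upper = 0.55,
                                              midpoint = 7.5, slope = 2),
                                 noise_sd = 0.02, seed = 1L) {
  y <- .fourpl(concentrations, truth$lower, truth$upper, truth$midpoint,
               truth$slope)
  y <- .with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  out <- data.frame(concentration = concentrations,
                    odr = pmin(1, pmax(0, y)))
  attr(out, "truth") <- truth
  out
}

.base_pairs <- list(c(positive = "-", negative = "+"),
                    c(positive = "F", negative = "$"))

#' Design a multiplexed barcode scheme
#'
#' Two modes.  `character_alphabet`: each analyte is assigned a
#' differential character pair, alternating ("-","+") and ("F","$"), so a
#' 2-analyte double negative realizes the combined barcode "+$".
#' `paired_label`: each analyte contributes a printed designator letter
#' followed by its result character from the base ("-","+") pair, e.g.
#' "A+B-" (A negative, B positive).
#'
#' @param analytes Character vector of analyte labels (>= 1).
#' @param mode "character_alphabet" or "paired_label".
#' @return Object of class `multiplex_scheme` with `mode`, `analytes`,
#'   `char_pairs` and `strip_map` (per-analyte binding-strip indices in the
#'   composed assay).
#' @export
design_multiplex <- function(analytes,
                             mode = c("character_alphabet", "paired_label")) {
  mode <- match.arg(mode)
  analytes <- as.character(analytes)
  if (length(analytes) < 1L) stop("at least one analyte", call. = FALSE)
  n <- length(analytes)
  pairs <- lapply(seq_len(n), function(i) .base_pairs[[(i - 1L) %% 2L + 1L]])
  names(pairs) <- analytes
  designators <- NULL
  if (mode == "paired_label") {
    designators <- toupper(substr(analytes, 1, 1))
    if (anyDuplicated(designators) || !all(grepl("^[A-Z0-9]$", designators)))
      designators <- c(LETTERS, as.character(0:9))[seq_len(n)]
    pairs <- rep(list(.base_pairs[[1]]), n)
    names(pairs) <- analytes
  }
  strip_map <- lapply(seq_len(n), function(i) (4L * (i - 1L) + 1L):(4L * i))
  names(strip_map) <- analytes
  structure(list(mode = mode, analytes = analytes, char_pairs = pairs,
                 designators = designators, strip_map = strip_map),
            class = "multiplex_scheme")
}

#' Realize a multiplex scheme as a barcode payload
#'
#' @param scheme A [design_multiplex()] scheme.
#' @param results Character vector of per-analyte results ("positive" /
#'   "negative"), recycled names optional.
#' @return The payload string (no start/stop framing).
#' @export
realize_multiplex <- function(scheme, results) {
  stopifnot(inherits(scheme, "multiplex_scheme"))
  results <- match.arg(as.character(results), c("positive", "negative"),
                       several.ok = TRUE)
  if (length(results) != length(scheme$analytes))
    stop("one result per analyte is required", call. = FALSE)
  res_char <- vapply(seq_along(results), function(i)
    unname(scheme$char_pairs[[i]][[results[i]]]), character(1))
  if (scheme$mode == "paired_label")
    paste0(scheme$designators, res_char, collapse = "")
  else paste(res_char, collapse = "")
}

#' Parse a decoded multiplex payload into per-analyte calls
#'
#' @param payload Decoded payload string.
#' @param scheme The [design_multiplex()] scheme it must conform to.
#' @return Data frame with `analyte` and `result`; an error names the
#'   position of the first violation if the payload does not conform.
#' @export
#' @examples
#' sch <- design_multiplex(c("hCG", "TSH"))
#' parse_multiplex("+$", sch)  # both negative
parse_multiplex <- function(payload, scheme) {
  stopifnot(inherits(scheme, "multiplex_scheme"))
  chars <- .norm_char(strsplit(payload, "")[[1]])
  n <- length(scheme$analytes)
  per <- if (scheme$mode == "paired_label") 2L else 1L
  if (length(chars) != per * n)
    stop(sprintf("payload %s has %d characters; scheme expects %d",
                 dQuote(payload), length(chars), per * n), call. = FALSE)
  results <- character(n)
  for (i in seq_len(n)) {
    pair <- scheme$char_pairs[[i]]
    if (scheme$mode == "paired_label") {
      d <- chars[2L * i - 1L]; rc <- chars[2L * i]
      if (d != scheme$designators[i])
        stop(sprintf("position %d: designator %s does not match expected %s",
                     2L * i - 1L, dQuote(d), dQuote(scheme$designators[i])),
             call. = FALSE)
    } else rc <- chars[i]
    pos_at <- if (scheme$mode == "paired_label") 2L * i else i
    if (rc == pair[["positive"]]) results[i] <- "positive"
    else if (rc == pair[["negative"]]) results[i] <- "negative"
    else stop(sprintf("position %d: character %s is neither %s nor %s",
                      pos_at, dQuote(rc), dQuote(pair[["positive"]]),
                      dQuote(pair[["negative"]])), call. = FALSE)
  }
  data.frame(analyte = scheme$analytes, result = results,
             stringsAsFactors = FALSE)
}
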