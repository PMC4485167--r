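test_that("scanline extraction averages the central band", {
  img <- matrix(255, 20, 40)
  prof <- extract_scanline(img)
  expect_length(prof$values, 40)
  expect_equal(unique(prof$values), 255)
  # band averaging reduces noise variance relative to a single row
  set.seed(11)
  noisy <- matrix(rnorm(100 * 200, 128, 20), 100, 200)
  banded <- extract_scanline(noisy, decode_config(band_fraction = 0.2))
  expect_lt(var(banded$values), var(noisy[50, ]))
  expect_error(extract_scanline(matrix(numeric(0), 0, 0)), "empty")
})

test_that("binarization reproduces rendered module widths exactly", {
  img <- render_barcode(encode_string("+"), assay_layout())
  runs <- binarize_runs(extract_scanline(img))
  geom <- attr(img, "geometry")
  bars <- geom[geom$role == "bar", ]
  expect_equal(runs$length[runs$dark], bars$x1 - bars$x0)
  expect_true(runs$dark[1] && runs$dark[nrow(runs)])
})

test_that("strips below the bar threshold vanish into light runs", {
  sc <- function(g) render_scenario(strip_odrs = c(0, g, 0, g),
                                    blur_sigma_mm = 0)
  n_dark <- function(g) {
    runs <- binarize_runs(extract_scanline(render_assay(scenario = sc(g))))
    sum(runs$dark)
  }
  expect_equal(n_dark(0.6), n_dark(1.0))      # controls present
  expect_equal(n_dark(0.1), n_dark(1.0) - 2)  # both controls dropped
})

test_that("decode is invariant to uniform intensity scaling", {
  img <- render_barcode(encode_string("A-1"), assay_layout())
  base <- binarize_runs(extract_scanline(img))
  for (k in c(0.3, 0.5, 1)) {
    scaled <- img * k
    runs <- binarize_runs(extract_scanline(scaled))
    expect_equal(runs$length, base$length, info = paste("k =", k))
    res <- decode_image(scaled)
    expect_equal(res$payload, "A-1", info = paste("k =", k))
  }
})

test_that("classification decodes framed run sequences in both directions", {
  runs <- runs_from_chars(c("*", "+", "*"))
  res <- classify_and_decode(runs)
  expect_equal(res$payload, "+")
  expect_equal(res$orientation, "forward")
  expect_equal(res$status, "ok")
  expect_length(res$per_char_margin, 1)
  rev_runs <- runs[rev(seq_len(nrow(runs))), ]
  attr(rev_runs, "leading_light") <- 200; attr(rev_runs, "trailing_light") <- 200
  res2 <- classify_and_decode(rev_runs)
  expect_equal(res2$payload, "+")
  expect_equal(res2$orientation, "reversed")
  res3 <- classify_and_decode(runs_from_chars(c("*", "+", "$", "*")))
  expect_equal(res3$payload, "+$")
})

test_that("decode statuses distinguish the failure modes", {
  # no start/stop framing
  res <- classify_and_decode(runs_from_chars(c("A", "B", "C")))
  expect_equal(res$status, "no_start_stop")
  expect_true(is.na(res$payload))
  # a 9-element group that is no Code 39 character
  res <- classify_and_decode(
    runs_from_chars(c("*", "X", "*"),
                    patterns = c("NWNNWNWNN", "NNNNNNNNN", "NWNNWNWNN")))
  expect_equal(res$status, "unknown_pattern")
  # missing quiet zone
  runs <- runs_from_chars(c("*", "+", "*"), lead = 5L)
  expect_equal(classify_and_decode(runs)$status, "quiet_zone_violation")
  expect_equal(classify_and_decode(runs,
    decode_config(require_quiet_zones = FALSE))$status, "ok")
  # an all-white image has no bars at all
  res <- decode_image(matrix(255, 30, 200))
  expect_equal(res$status, "no_start_stop")
})

test_that("mirrored images decode to the same payload, orientation reversed", {
  for (payload in c("+", "-", "P", "A+B-", "1F$")) {
    img <- render_barcode(encode_string(payload), assay_layout())
    fwd <- decode_image(img)
    mir <- decode_image(img[, rev(seq_len(ncol(img)))])
    expect_equal(fwd$payload, payload)
    expect_equal(fwd$orientation, "forward")
    expect_equal(mir$payload, payload, info = payload)
    expect_equal(mir$orientation, "reversed", info = payload)
  }
})

test_that("an assay at ODR 0.10 is unreadable for either character", {
  lay <- assay_layout()
  pos <- render_assay(layout = lay,
                      scenario = render_scenario(strip_odrs = rep(0.10, 4)))
  neg <- render_assay(layout = lay,
                      scenario = render_scenario(strip_odrs = c(0, 0.10, 0, 0.10)))
  expect_false(identical(decode_image(pos)$payload, "-"))
  expect_false(identical(decode_image(neg)$payload, "+"))
})

test_that("min_readable_odr reports a trivial floor at full contrast", {
  out <- min_readable_odr("+", odr_grid = 1)
  expect_equal(as.numeric(out), 1)
  out <- min_readable_odr("-", odr_grid = c(0.04, 0.08))
  expect_true(is.na(out))          # never readable that low
  expect_equal(nrow(attr(out, "grid")), 2)
  expect_error(min_readable_odr("Z"), "pair")
  expect_error(min_readable_odr("+", odr_grid = c(0.5, 0.2)), "ascending")
})

test_that("decoder configuration is validated", {
  expect_error(decode_config(bar_threshold_odr = 1.2), "bar_threshold_odr")
  expect_error(decode_config(ratio_cut = 3.5), "ratio_cut")
})
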