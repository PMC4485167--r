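test_that("qualitative calls follow the control-validity logic", {
  expect_equal(qualitative_call(c(0.5, 0.5, 0.5, 0.5))$result, "positive")
  expect_equal(qualitative_call(c(0.02, 0.5, 0.03, 0.5))$result, "negative")
  expect_equal(qualitative_call(c(0.5, 0.02, 0.5, 0.5))$result, "invalid")
  # one weak test line is not a positive
  expect_equal(qualitative_call(c(0.5, 0.5, 0.03, 0.5))$result, "negative")
  expect_error(qualitative_call(c(0.5, 0.5)), "4 strip")
  # measurement data frames are accepted directly
  img <- render_assay(scenario = render_scenario(strip_odrs = c(0, 1, 0, 1)))
  expect_equal(qualitative_call(measure_assay(img))$result, "negative")
})

test_that("expected characters mirror the decoded barcode", {
  pos <- qualitative_call(c(0.5, 0.5, 0.5, 0.5))
  neg <- qualitative_call(c(0.02, 0.5, 0.03, 0.5))
  expect_equal(expected_character(pos), "-")
  expect_equal(expected_character(neg), "+")
  expect_equal(expected_character(pos, c("F", "$")), "F")
  expect_equal(expected_character(neg, c("F", "$")), "$")
  inv <- qualitative_call(c(0.5, 0.02, 0.5, 0.5))
  expect_error(expected_character(inv), "void")
})

test_that("measured call and decoded character agree above the floor", {
  for (g in c(0.5, 0.8, 1)) {
    for (kind in c("positive", "negative")) {
      odrs <- if (kind == "positive") rep(g, 4) else c(0, g, 0, g)
      img <- render_assay(scenario = render_scenario(strip_odrs = odrs))
      call <- qualitative_call(measure_assay(img))
      expect_equal(call$result, kind)
      expect_equal(decode_image(img)$payload, expected_character(call),
                   info = sprintf("%s at ODR %.2f", kind, g))
    }
  }
})

test_that("the 4PL fitter recovers noiseless parameters", {
  truth <- list(lower = 0.04, upper = 0.55, midpoint = 7.5, slope = 2)
  pts <- simulate_calibration(noise_sd = 0)
  fit <- fit_calibration(pts)
  for (p in names(truth))
    expect_equal(fit$params[[p]], truth[[p]], tolerance = 1e-4,
                 info = p)
  expect_lt(fit$residual_scale, 1e-5)
})

test_that("the fitter recovers the midpoint from noisy data within 15%", {
  pts <- simulate_calibration(noise_sd = 0.02, seed = 101)
  fit <- fit_calibration(pts)
  expect_lt(abs(fit$params$midpoint - 7.5) / 7.5, 0.15)
})

test_that("degenerate calibration data are rejected", {
  flat <- data.frame(concentration = c(0, 1, 2, 5, 10),
                     odr = rep(0.3, 5))
  expect_error(fit_calibration(flat), "dynamic range")
  dec <- data.frame(concentration = c(0, 1, 2, 5, 10),
                    odr = c(0.5, 0.4, 0.3, 0.2, 0.1))
  expect_error(fit_calibration(dec), "monotone")
  expect_error(fit_calibration(data.frame(concentration = 1:3,
                                          odr = c(0.1, 0.2, 0.3))),
               "at least 5")
})

test_that("inverse prediction round-trips across the valid range", {
  fit <- fit_calibration(simulate_calibration(noise_sd = 0))
  cc <- seq(fit$valid_range[1], fit$valid_range[2], length.out = 20)
  est <- estimate_concentration(predict(fit, cc), fit)
  expect_equal(est$concentration, cc, tolerance = 1e-6)
  expect_true(all(est$flag == "ok"))
  expect_true(all(est$lower <= cc & cc <= est$upper))
})

test_that("out-of-span ODRs are flagged instead of extrapolated", {
  fit <- fit_calibration(simulate_calibration(noise_sd = 0))
  est <- estimate_concentration(c(0.01, 0.549), fit)
  expect_equal(est$flag, c("below_range", "saturated"))
  expect_true(all(is.na(est$concentration)))
  # the midpoint ODR inverts to the midpoint concentration
  mid_odr <- with(fit$params, (lower + upper) / 2)
  expect_equal(estimate_concentration(mid_odr, fit)$concentration,
               fit$params$midpoint, tolerance = 1e-6)
})

test_that("multiplex design assigns alternating pairs and strip indices", {
  sch <- design_multiplex(c("hCG", "TSH"))
  expect_equal(sch$char_pairs[[1]][["positive"]], "-")
  expect_equal(sch$char_pairs[[2]][["positive"]], "F")
  expect_equal(sch$strip_map$TSH, 5:8)
  expect_equal(realize_multiplex(sch, c("negative", "negative")), "+$")
  one <- design_multiplex("hCG")
  expect_equal(realize_multiplex(one, "positive"), "-")
  expect_equal(parse_multiplex("-", one)$result, "positive")
})

test_that("paired-label mode emits designator/result pairs", {
  sch <- design_multiplex(c("alpha", "beta"), mode = "paired_label")
  expect_equal(sch$designators, c("A", "B"))
  expect_equal(realize_multiplex(sch, c("negative", "positive")), "A+B-")
  got <- parse_multiplex("A+B-", sch)
  expect_equal(got$result, c("negative", "positive"))
  expect_error(parse_multiplex("A+C-", sch), "position 3")
  expect_error(parse_multiplex("A+", sch), "characters")
})

test_that("multiplex parse inverts design for every result vector, n <= 4", {
  for (n in 1:4) {
    analytes <- paste0("analyte", seq_len(n))
    schemes <- list(design_multiplex(analytes, "character_alphabet"),
                    design_multiplex(analytes, "paired_label"))
    combos <- expand.grid(rep(list(c("positive", "negative")), n),
                          stringsAsFactors = FALSE)
    for (sch in schemes) {
      for (i in seq_len(nrow(combos))) {
        results <- unlist(combos[i, ], use.names = FALSE)
        payload <- realize_multiplex(sch, results)
        expect_equal(parse_multiplex(payload, sch)$result, results,
                     info = sprintf("n=%d mode=%s payload=%s", n, sch$mode,
                                    payload))
      }
    }
  }
})

test_that("paired-label payloads survive the render/decode loop", {
  sch <- design_multiplex(c("alpha", "beta"), mode = "paired_label")
  payload <- realize_multiplex(sch, c("negative", "positive"))
  img <- render_barcode(encode_string(payload), assay_layout())
  expect_equal(decode_image(img)$payload, payload)
})
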