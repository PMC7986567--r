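timeline8 <- its_series(numeric(8), start = c(2020, 1), frequency = 12)

test_that("step, pulse and ramp indicators follow their definitions", {
  expect_equal(as.numeric(step_indicator("2020-05", timeline8)),
               c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(as.numeric(step_indicator("2020-01", timeline8)), rep(1, 8))
  expect_equal(as.numeric(pulse_indicator("2020-05", timeline8)),
               c(0, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(sum(as.numeric(pulse_indicator("2020-03", timeline8))), 1)
  expect_equal(as.numeric(ramp_indicator("2020-05", timeline8)),
               c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_warning(out <- step_indicator("2021-06", timeline8), "after the end")
  expect_equal(as.numeric(out), rep(0, 8))
})

test_that("quetiapine-style timeline: onset 2014-01 on a 2011-2014 series", {
  tl <- its_series(numeric(48), start = c(2011, 1), frequency = 12)
  st <- as.numeric(step_indicator("2014-01", tl))
  expect_equal(st, c(rep(0, 36), rep(1, 12)))
  rp <- ramp_indicator("2014-01", tl)
  expect_equal(as.numeric(rp)[48], 12)   # 12 post-onset months by 2014-12
})

test_that("indicator identities hold over random onsets", {
  tl <- its_series(numeric(40), start = c(2015, 1), frequency = 12)
  labs <- period_labels(tl)
  for (pos in c(1L, 7L, 19L, 39L)) {
    p <- as.numeric(pulse_indicator(labs[pos], tl))
    s0 <- as.numeric(step_indicator(labs[pos], tl))
    s1 <- if (pos < 40L) as.numeric(step_indicator(labs[pos + 1L], tl))
      else numeric(40)
    expect_equal(p, s0 - s1)
    expect_equal(as.numeric(ramp_indicator(labs[pos], tl)), cumsum(s0))
  }
})

test_that("transfer filter reproduces the canonical decay patterns", {
  pulse <- its_series(c(0, 0, 1, 0, 0, 0, 0), frequency = 1)
  out <- apply_transfer(pulse, omega = 10, delta = 0.5)
  expect_equal(as.numeric(out), c(0, 0, 10, 5, 2.5, 1.25, 0.625))

  step <- its_series(c(0, rep(1, 9)), frequency = 1)
  out2 <- as.numeric(apply_transfer(step, omega = 1, delta = 0.5))
  expect_equal(out2[2:5], c(1, 1.5, 1.75, 1.875))
  expect_lt(abs(out2[10] - 2), 0.01)    # approaches omega0 / (1 - delta)

  ramp <- its_series(c(0, 0, 1:5), frequency = 1)
  expect_equal(as.numeric(apply_transfer(ramp, omega = 3)),
               c(0, 0, 3, 6, 9, 12, 15))

  expect_error(apply_transfer(pulse, omega = 1, delta = 1.2), "unstable")
  expect_error(apply_transfer(pulse, omega = 1, delta = 1), "unstable")
})

test_that("closed-form responses match the tabulated forms", {
  expect_equal(theoretical_response("step", omega0 = -3285, k = 0:11),
               rep(-3285, 12))
  expect_equal(theoretical_response("pulse", omega0 = 8, delta1 = 0.25,
                                    k = 2, r = 1), 0.5)
  expect_equal(theoretical_response("ramp", omega0 = -1397, k = 0:2),
               c(-1397, -2794, -4191))
  expect_equal(theoretical_response("step", omega0 = 2, delta1 = 0.5,
                                    k = 0:2, r = 1), c(2, 3, 3.5))
  expect_error(theoretical_response("ramp", omega0 = 1, delta1 = 0.5,
                                    k = 1, r = 1), "unsupported")
  expect_error(theoretical_response("pulse", omega0 = 1, k = -1), "non-negative")
  expect_error(theoretical_response("pulse", omega0 = 1, delta1 = 1.1,
                                    k = 1, r = 1), "unstable")
})

test_that("recursive filter equals closed forms at every horizon", {
  n <- 60L
  tl <- its_series(numeric(n), start = c(2015, 1), frequency = 12)
  onset <- period_labels(tl)[6]
  set.seed(42)
  for (rep_i in 1:8) {
    w0 <- runif(1, -10, 10)
    d1 <- runif(1, -0.95, 0.95)
    for (shape in c("step", "pulse", "ramp")) {
      ind <- intervention_indicator(intervention(shape, onset), tl)
      for (r in 0:1) {
        if (shape == "ramp" && r == 1) next
        filt <- as.numeric(apply_transfer(ind, omega = w0,
                                          delta = if (r) d1 else numeric(0)))
        ks <- 0:50
        closed <- theoretical_response(shape, omega0 = w0,
                                       delta1 = if (r) d1 else NULL,
                                       k = ks, r = r)
        expect_equal(filt[6 + ks], closed, tolerance = 1e-10)
      }
    }
  }
})

test_that("delay shifts the response exactly, r = 0 is pure scaling", {
  tl <- its_series(numeric(30), start = c(2015, 1), frequency = 12)
  base <- intervention("step", onset = "2016-01")
  lag2 <- intervention("step", onset = "2016-01", delay = 2)
  a <- as.numeric(apply_transfer(intervention_indicator(base, tl),
                                 omega = 4, delta = 0.6))
  b <- as.numeric(apply_transfer(intervention_indicator(lag2, tl),
                                 omega = 4, delta = 0.6))
  expect_equal(b[-(1:2)], a[seq_len(28)])
  expect_equal(b[1:2], c(0, 0))

  x <- its_series(rnorm(25), frequency = 1)
  expect_equal(as.numeric(apply_transfer(x, omega = -2.5)),
               -2.5 * as.numeric(x))
})

test_that("intervention specs validate and read from YAML/JSON config", {
  expect_error(intervention("step", "2014-01", delay = -1), "non-negative")
  expect_warning(intervention("step", "2014-01", h = 1), "experimental")
  expect_warning(intervention("pulse", "2014-01", r = 2), "experimental")

  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("interventions:",
               "  - {shape: step, onset: 2014-01, label: policy_step}",
               "  - {shape: ramp, onset: 2014-01, delay: 1}"), ypath)
  specs <- read_intervention_config(ypath)
  expect_length(specs, 2)
  expect_identical(specs[[1]]$label, "policy_step")
  expect_identical(specs[[2]]$delay, 1L)

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"interventions": [{"shape": "pulse", "onset": "2015-03", "r": 1}]}',
             jpath)
  sp <- read_intervention_config(jpath)
  expect_identical(sp[[1]]$shape, "pulse")
  expect_identical(sp[[1]]$r, 1L)

  writeLines("interventions: []", ypath)
  expect_error(read_intervention_config(ypath), "no intervention entries")
})
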