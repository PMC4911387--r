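test_that("response metrics reproduce the clinical definitions on a toy trace", {
  tap <- tibble::tibble(time = c(0, 30, 60, 90, 120),
                        value = 100 * c(1, 1.2, 1.3, 1.2, 1.1))
  m <- response_metrics(tap, baseline = 100, window = 240)
  expect_equal(m$latency, 30)
  expect_equal(m$offset, 120)
  expect_equal(m$duration, 90)
  expect_equal(m$classification, "wearing-off")
  expect_equal(classify_group(m), 2L)

  flat <- tibble::tibble(time = seq(0, 240, 30), value = rep(70, 9))
  m0 <- response_metrics(flat, baseline = 70)
  expect_false(m0$responded)
  expect_equal(m0$classification, "no-response")
  expect_true(is.na(classify_group(m0)))

  tt <- seq(0, 240, 30)
  up <- tibble::tibble(time = tt, value = ifelse(tt >= 60, 150, 100))
  m1 <- response_metrics(up, baseline = 100)
  expect_equal(m1$classification, "stable")
  expect_equal(m1$latency, 60)
  expect_true(is.na(m1$duration))
  expect_equal(classify_group(m1), 1L)
})

test_that("no drug effect leaves tapping flat at the basal frequency", {
  rec <- ld_patient_records()[["g1s2"]]
  rec$effect$Dmax <- 0
  sim <- simulate_patient(rec, sample_times = seq(0, 240, 30),
                          curve = curve_fixture(), protocol = default_prot())
  expect_lt(diff(range(sim$taps_per_min)), 1e-9)
  expect_true(all(sim$D == rec$effect$D0))
})

test_that("printed patient replays discriminate the two response groups", {
  curve <- curve_fixture()
  recs <- ld_patient_records()
  cls <- purrr::map_chr(recs, function(r) {
    sim <- simulate_patient(r, seq(0, 240, by = 15), curve = curve,
                            protocol = default_prot())
    base <- frequency_lookup(curve, r$effect$D0)
    response_metrics(sim, baseline = base)$classification
  })
  # group 1 subjects 1-2 are stable; all group 2 subjects wear off
  expect_equal(unname(cls[c("g1s1", "g1s2")]), c("stable", "stable"))
  expect_equal(unname(cls[c("g2s1", "g2s2", "g2s3")]),
               rep("wearing-off", 3))
  # subject 3 of group 1 sits at the boundary between the groups; its
  # classification is reported, not asserted
  expect_true(cls[["g1s3"]] %in% c("stable", "wearing-off"))
})

test_that("response duration shrinks with steeper Hill law and faster removal", {
  curve <- curve_fixture()
  base_rec <- ld_patient_records()[["g2s3"]]
  dur_of <- function(N = NULL, ke3 = NULL) {
    r <- base_rec
    if (!is.null(N)) r$effect$N <- N
    if (!is.null(ke3)) r$effect$ke3_over_V3 <- ke3
    sim <- simulate_patient(r, seq(0, 240, by = 5), curve = curve,
                            protocol = default_prot())
    base <- frequency_lookup(curve, r$effect$D0)
    m <- response_metrics(sim, baseline = base)
    if (is.na(m$duration)) Inf else m$duration
  }
  dN <- c(dur_of(N = 2), dur_of(N = 5), dur_of(N = 8))
  expect_true(all(diff(dN) <= 0))
  expect_lt(dN[3], dN[1])
  dk <- c(dur_of(ke3 = 0.015), dur_of(ke3 = 0.025), dur_of(ke3 = 0.035))
  expect_true(all(diff(dk) <= 0))
  expect_lt(dk[3], dk[1])
})

test_that("curve mode agrees with direct per-sample simulation", {
  rec <- ld_patient_records()[["g2s1"]]
  tt <- seq(0, 240, by = 60)
  a <- simulate_patient(rec, tt, mode = "curve", curve = curve_fixture(),
                        protocol = default_prot())
  b <- simulate_patient(rec, tt, mode = "direct", protocol = default_prot())
  grid_step <- max(abs(diff(curve_fixture()$taps_per_min)))
  expect_lt(max(abs(a$taps_per_min - b$taps_per_min)), grid_step + 1)
  expect_equal(a$D, b$D)
})

test_that("patient record validation", {
  pk <- pk_params(1, 1, 0.5)
  eff <- effect_params(0.02, 0, 0.28, 0.3, 0.1, 2)
  expect_error(patient_record("x", 3, pk, eff), "group")
  rec <- patient_record("x", 1, pk, eff)
  expect_s3_class(rec, "patient_record")
  expect_error(response_metrics(tibble::tibble(time = 0:3, value = 1:4),
                                baseline = 0), "positive")
})
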