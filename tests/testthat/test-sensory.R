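test_that("contact cells burst once per onset, detach cells at offsets", {
  set.seed(1)
  kin <- make_kin(contact_from = 200, contact_to = 400)
  bank <- tg_bank()
  ct <- encode_contact(kin, bank)
  dt <- encode_detach(kin, bank)
  expect_spike_df(ct)
  expect_equal(nrow(ct), 20)             # one burst of 20 single spikes
  expect_true(all(ct$time >= 200 & ct$time <= 201))
  expect_equal(nrow(dt), 20)
  expect_true(all(dt$time >= 401 & dt$time <= 402))
  # no contact -> silence
  quiet <- make_kin()
  expect_equal(nrow(encode_contact(quiet, bank)), 0)
  expect_equal(nrow(encode_detach(quiet, bank)), 0)
  # two separate contacts -> two onset bursts
  kin2 <- make_kin(duration = 1000)
  kin2$in_contact <- (kin2$time_ms >= 100 & kin2$time_ms <= 200) |
    (kin2$time_ms >= 600 & kin2$time_ms <= 700)
  expect_equal(nrow(encode_contact(kin2, bank)), 40)
  # contact truncated by end of stream -> no detach burst
  kin3 <- make_kin(contact_from = 900, contact_to = 1000)
  expect_equal(nrow(encode_detach(kin3, bank)), 0)
})

test_that("pressure cells fire tonically during contact at the set rate", {
  set.seed(2)
  bank <- tg_bank(pressure_rate = 27)
  kin <- make_kin(contact_from = 1, contact_to = 1000)
  sp <- encode_pressure(kin, bank)
  # Poisson oracle: expected count 20 * r * D within 3 sigma
  expected <- 20 * 27 * 1
  expect_lt(abs(nrow(sp) - expected), 3 * sqrt(expected))
  expect_true(all(sp$time >= 0 & sp$time <= 1000))
  expect_equal(nrow(encode_pressure(make_kin(), bank)), 0)
  # first pressure spike not before contact onset
  kin2 <- make_kin(contact_from = 500, contact_to = 1000)
  sp2 <- encode_pressure(kin2, bank)
  expect_gte(min(sp2$time), 499)
})

test_that("high-threshold cells are a labeled line for proximal contact", {
  bank <- tg_bank()
  near <- make_kin(contact_from = 1, contact_to = 500, distance = 1)
  far <- make_kin(contact_from = 1, contact_to = 500, distance = 10)
  at2 <- make_kin(contact_from = 1, contact_to = 500, distance = 2)
  sp <- encode_high_threshold(near, bank)
  expect_gt(nrow(sp), 0)
  # fixed rate: per-cell count ~ rate * duration
  expect_equal(nrow(sp) / 20, bank$ht_rate * 0.5, tolerance = 0.1)
  expect_equal(nrow(encode_high_threshold(far, bank)), 0)
  expect_equal(nrow(encode_high_threshold(at2, bank)), 0) # strict <
})

test_that("whisking cells are Gaussian-tuned labeled lines for angle", {
  bank <- tg_bank()
  # clamp at cell 7's preferred angle: that cell wins
  set.seed(3)
  kin <- make_kin(duration = 5000, angle = bank$preferred_angle[7])
  sp <- encode_whisking(kin, bank)
  counts <- tabulate(sp$cell, nbins = 20)
  expect_equal(which.max(counts), 7)
  # far from every preferred angle: near-silence
  set.seed(4)
  far <- make_kin(duration = 5000, angle = bank$preferred_angle[20] +
                    6 * bank$tuning_width)
  expect_lt(nrow(encode_whisking(far, bank)), 5)
  # sweep activates cells in preferred-angle order
  set.seed(5)
  sweep <- make_kin(duration = 2000,
                    angle = seq(-5, 30, length.out = 2000))
  ssp <- encode_whisking(sweep, bank)
  first_t <- vapply(split(ssp$time, ssp$cell), min, 0)
  expect_gt(cor(as.integer(names(first_t)), first_t, method = "spearman"),
            0.9)
})

test_that("phase decoder is a pure pressure-gated copy of whisking lines", {
  set.seed(6)
  bank <- tg_bank()
  kin <- make_kin(duration = 2000, angle = 10,
                  contact_from = 500, contact_to = 1000)
  wsp <- encode_whisking(kin, bank)
  psp <- encode_pressure(kin, bank)
  ph <- phase_decode(wsp, psp, window = 10)
  # subset property: every phase spike is a whisking spike (same cell/time)
  key <- paste(ph$cell, ph$time)
  expect_true(all(key %in% paste(wsp$cell, wsp$time)))
  # gating: only within the pressure-active window (+ gating window)
  expect_true(all(ph$time >= 500 & ph$time <= 1011))
  # pressure silent -> all phase cells silent
  quiet <- phase_decode(wsp, psp[0, ], window = 10)
  expect_equal(nrow(quiet), 0)
})

test_that("full TG bank census is 100 cells per whisker in 5 classes", {
  sys <- build_whisker_system(seed = 1)
  for (w in c("L0", "L1", "R0", "R1")) {
    sizes <- vapply(c("contact", "detach", "pressure", "high_threshold",
                      "whisking"),
                    function(cl) sys$tg[[paste(w, cl, sep = ".")]]$size, 0L)
    expect_equal(unname(sizes), rep(20L, 5))
  }
  expect_equal(sys$tn_contact$size, 4L)
  expect_equal(sum(vapply(sys$tn_phase, function(p) p$size, 0L)), 80L)
})

test_that("TN contact relay responds to onset bursts and is silent otherwise", {
  sys <- build_whisker_system(seed = 1)
  net <- sys$net
  reset_network(net)
  # full onset burst on L0 contact cells -> >= 1 TN contact spike
  inject_spikes(net, sys$tg$L0.contact, 1:20, rep(100, 20))
  net_run(net, 200)
  sp <- get_spikes(net)
  tn <- spikes_of(sp, sys$tn_contact)
  expect_gte(nrow(tn), 1)
  expect_equal(unique(tn$cell), 1) # only L0's relay neuron
  reset_network(net)
  net_run(net, 200)
  expect_equal(nrow(spikes_of(get_spikes(net), sys$tn_contact)), 0)
})
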