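test_that("protocol bookkeeping: balanced sessions, reproducible schedules", {
  p <- make_protocol(27, 10, "control", seed = 1)
  expect_equal(nrow(p$trials), 270)
  expect_equal(length(unique(p$trials$session)), 27)
  per <- table(p$trials$session, p$trials$type)
  expect_true(all(per[, "GO"] == 5))
  expect_true(all(per[, "NOGO"] == 5))
  p2 <- make_protocol(27, 10, "control", seed = 1)
  expect_identical(p$trials, p2$trials)
  p3 <- make_protocol(27, 10, "control", seed = 2)
  expect_false(identical(p$trials$type, p3$trials$type))
  expect_error(make_protocol(10, 7), "even")
})

test_that("trial configuration places the bar by trial type", {
  cfg <- default_config()
  go <- trial_config("GO", cfg)
  nogo <- trial_config("NOGO", cfg)
  expect_equal(go$bar$side, "left")
  expect_equal(nogo$bar$side, "right")
  expect_equal(go$duration, 2000)
  expect_equal(go$bar$stop, 1000)
  expect_error(trial_config("MAYBE", cfg))
})

test_that("default construction census matches both wiring tables exactly", {
  sys <- build_whisker_system(seed = 3)
  cen <- construction_census(sys)
  syn <- cen$synapses
  expect_equal(sum(syn[grep("^CPG->FN_pro", names(syn))]), 80)
  expect_equal(sum(syn[grep("^CPG->FN_ret", names(syn))]), 40)
  expect_equal(unname(syn["TG_contact->TN_contact"]), 80)
  expect_equal(sum(syn[grep("^TN_contact->FN_pro", names(syn))]), 80)
  expect_equal(sum(syn[grep("^TN_contact->FN_ret", names(syn))]), 80)
  expect_equal(unname(syn["TG_pressure->MF"]), 80)
  expect_equal(unname(syn["TN_phase->MF"]), 80)
  expect_equal(unname(syn["MF->GrC"]), 8000)
  expect_equal(unname(syn["GrC->PC"]), 115200)
  expect_equal(unname(syn["IO->PC"]), 72)
  expect_equal(unname(syn["MF->DCN"]), 3600)
  expect_equal(unname(syn["PC->DCN"]), 72)
  pops <- cen$populations
  tg <- pops[grep("^TG_", names(pops))]
  expect_equal(length(tg), 20)
  expect_true(all(tg == 20))
  expect_equal(sum(tg), 400) # 100 TG cells per whisker
  expect_equal(unname(pops["TN_contact"]), 4L)
  expect_equal(sum(pops[grep("^TN_phase", names(pops))]), 80L)
  expect_equal(unname(pops["CPG"]), 1L)
  expect_equal(sum(pops[grep("^FN_pro", names(pops))]), 80L)
  expect_equal(sum(pops[grep("^FN_ret", names(pops))]), 40L)
})

test_that("identical seeds give identical wiring and spike rasters", {
  run <- function() {
    sys <- build_whisker_system(seed = 5)
    res <- run_trial(sys, trial_config("GO", default_config()),
                     trial_seed = 9, record = "spikes")
    res$spikes
  }
  expect_identical(run(), run())
})

test_that("config files and manifests round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("cpg_rate: 5.0", "genotype: l7pp2b"), path)
  cfg <- load_config(path)
  expect_equal(cfg$cpg_rate, 5)
  expect_equal(cfg$genotype, "l7pp2b")
  expect_equal(cfg$trial_duration, 2000) # untouched defaults survive
  p2 <- tempfile(fileext = ".yaml")
  write_manifest(default_config(), p2)
  back <- yaml::read_yaml(p2)
  expect_equal(back$bar$angular_position, 15)
})

test_that("a naive system responds in both GO and NOGO trials", {
  cfg <- default_config()
  sys <- build_whisker_system(cfg, seed = 2)
  whiskersim:::eng_plasticity_enabled(sys$net$ptr, FALSE) # probe, no learning
  go <- run_trial(sys, trial_config("GO", cfg), trial_seed = 41)
  nogo <- run_trial(sys, trial_config("NOGO", cfg), trial_seed = 42)
  expect_true(go$responded)      # naive hit
  expect_true(go$rewarded)
  expect_true(nogo$responded)    # naive false alarm
  expect_false(nogo$rewarded)
  # catch trial: no bar, no contact-driven input, no response
  tc <- trial_config("GO", cfg)
  tc$bar <- bar_stimulus("none")
  catch <- run_trial(sys, tc, trial_seed = 43, record = "spikes")
  expect_false(catch$responded)
  for (w in c("L0", "L1", "R0", "R1"))
    expect_equal(nrow(spikes_of(catch$spikes, sys$tg[[paste0(w, ".contact")]])),
                 0)
})

test_that("session metrics summarize responses with reward consistency", {
  cfg <- default_config(trial_duration = 2000)
  m <- run_experiment(make_protocol(1, 4, "control", seed = 6), cfg,
                      outdir = td <- tempfile())
  expect_s3_class(m, "session_metrics")
  expect_true(all(m$hit_rate >= 0 & m$hit_rate <= 100))
  tr <- attr(m, "trials")
  expect_true(all(!tr$rewarded[tr$type == "NOGO"]))
  expect_true(all(tr$rewarded == (tr$type == "GO" & tr$responded)))
  expect_true(file.exists(file.path(td, "metrics.csv")))
  expect_true(file.exists(file.path(td, "manifest.yaml")))
  expect_true(file.exists(file.path(td, "pf_pc_weights.csv")))
})
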