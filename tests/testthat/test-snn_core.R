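test_that("population construction validates sizes and assigns fresh gids", {
  net <- network()
  a <- build_population(net, "TG_pressure_L0", 20)
  b <- build_population(net, "CPG", 1)
  expect_equal(a$size, 20L)
  expect_equal(b$size, 1L)
  expect_equal(gids(a), 0:19)
  expect_equal(gids(b), 20L)
  expect_error(build_population(net, "X", 0), "size")
  expect_error(neuron_params(tau_m = -1), "tau_m")
  expect_error(neuron_params(v_thresh = -80, v_reset = -70), "threshold|reset")
})

test_that("connection rules produce the documented synapse counts", {
  net <- network()
  cpg <- build_population(net, "CPG", 1)
  fn <- build_population(net, "FN", 80)
  grc <- build_population(net, "GrC", 2000)
  pc <- build_population(net, "PC", 72)
  expect_equal(connect(net, cpg, fn, "one_to_all", "excitatory")$n_synapses,
               80)
  pfpc <- connect(net, grc, pc, "fixed_convergence", "excitatory",
                  convergence = 1600, seed = 3)
  expect_equal(pfpc$n_synapses, 115200)
  # distinct presynaptic partners per target
  per_post <- split(pfpc$edges$pre, pfpc$edges$post)
  expect_true(all(vapply(per_post, function(p) !anyDuplicated(p), TRUE)))
  # 2000 into convergence 100 is valid sampling without replacement
  expect_error(connect(net, grc, pc, "fixed_convergence", "excitatory",
                       convergence = 100, seed = 4), NA)
  expect_error(connect(net, cpg, fn, "fixed_convergence", "excitatory",
                       convergence = 2), "convergence")
  expect_warning(connect(net, grc, pc, "fixed_convergence", "excitatory",
                         convergence = 0), "convergence 0")
})

test_that("connectivity is reproducible under a fixed seed", {
  build <- function() {
    net <- network()
    a <- build_population(net, "A", 50)
    b <- build_population(net, "B", 10)
    connect(net, a, b, "fixed_convergence", "excitatory",
            convergence = 7, seed = 42)$edges
  }
  expect_identical(build(), build())
})

test_that("LIF fixed point: zero input at rest stays at rest, no spikes", {
  net <- network()
  p <- build_population(net, "P", 5)
  net_finalize(net)
  net_run(net, 100)
  expect_equal(nrow(get_spikes(net)), 0)
  expect_equal(whiskersim:::eng_get_V(net$ptr, gids(p)),
               rep(p$params$v_rest, 5))
})

test_that("tonic LIF rate matches the closed-form f-I relation within 2%", {
  for (bias in c(20, 30, 45)) {
    net <- network()
    p <- build_population(net, "P", 1, bias_mv = bias)
    net_finalize(net)
    net_run(net, 10000)
    sim <- nrow(get_spikes(net)) / 10
    pp <- p$params
    analytic <- 1000 / (pp$t_ref + pp$tau_m *
                          log(bias / (bias - (pp$v_thresh - pp$v_rest))))
    expect_lt(abs(sim - analytic) / analytic, 0.02)
  }
})

test_that("no neuron fires twice within its refractory period", {
  net <- network()
  p <- build_population(net, "P", 10, bias_mv = 60) # hard-driven
  net_finalize(net)
  net_run(net, 2000)
  sp <- get_spikes(net)
  for (g in unique(sp$gid)) {
    isi <- diff(sort(sp$time[sp$gid == g]))
    expect_true(all(isi > p$params$t_ref))
  }
})

test_that("a 3-neuron network matches the brute-force reference stepper", {
  params <- neuron_params()
  net <- network()
  gen <- build_population(net, "gen", 1, neuron_params(t_ref = 0),
                          generator = TRUE)
  p <- build_population(net, "lif", 2, params, bias_mv = 12)
  id1 <- whiskersim:::eng_add_projection(net$ptr, c(0L, 0L), c(1L, 2L),
                                         c(9, 4.5), 1.0, FALSE, FALSE)
  id2 <- whiskersim:::eng_add_projection(net$ptr, 1L, 2L, 8.0, 2.5,
                                         FALSE, FALSE)
  net_finalize(net)
  inj_times <- c(5, 6, 7, 30, 100, 100.5, 101)
  inject_spikes(net, gen, 1L, inj_times)
  edges <- data.frame(pre = c(0, 0, 1), post = c(1, 2, 2),
                      w = c(9, 4.5, 8), delay_steps = c(10, 10, 25))
  ref <- ref_lif_run(3, params, c(0, 12, 12), edges,
                     data.frame(gid = 0, step = round(inj_times / 0.1)),
                     n_steps = 2000)
  # step the engine 1 ms at a time, comparing membrane state
  for (t in seq(1, 200, by = 1)) {
    net_run(net, t)
  }
  sim <- get_spikes(net)
  expect_equal(sim$time, ref$spikes$time)
  expect_equal(sim$gid, ref$spikes$gid)
  expect_equal(whiskersim:::eng_get_V(net$ptr, 0:2), ref$V,
               tolerance = 1e-12)
})

test_that("population rate is spikes per bin normalized by size, in Hz", {
  pop <- structure(list(name = "TG", size = 20, first_gid = 0L),
                   class = "population")
  one <- data.frame(gid = 3L, time = 4)
  expect_equal(instantaneous_rate(one, pop, 10)$rate, 5)
  none <- data.frame(gid = integer(0), time = numeric(0))
  expect_equal(instantaneous_rate(none, pop, 10, t_stop = 10)$rate, 0)
  full <- data.frame(gid = 0:19, time = rep(7, 20))
  expect_equal(instantaneous_rate(full, pop, 10)$rate, 100)
  expect_error(instantaneous_rate(one, pop, bin_width = 0), "bin_width")
  # rate quantization: multiples of 1000 / (size * bin_width)
  set.seed(1)
  r <- data.frame(gid = sample(0:19, 57, replace = TRUE),
                  time = runif(57, 0, 200))
  tr <- instantaneous_rate(r, pop, 10, t_stop = 200)
  q <- 1000 / (20 * 10)
  expect_equal(tr$rate %% q, rep(0, nrow(tr)))
})

test_that("spike rasters round-trip bit-exactly through the text format", {
  pops <- list(structure(list(name = "A", size = 3, first_gid = 0L),
                         class = "population"),
               structure(list(name = "B", size = 2, first_gid = 3L),
                         class = "population"))
  sp <- data.frame(gid = c(0L, 2L, 3L, 4L),
                   time = c(0.1, 17.3, 17.3, 1999.9))
  path <- tempfile()
  write_raster(sp, pops, path)
  back <- read_raster(path)
  expect_identical(back$spikes$gid, sp$gid)
  expect_identical(back$spikes$time, sp$time)
  expect_equal(back$popmap$name, c("A", "B"))
  expect_equal(back$popmap$first_gid, c(0, 3))
  # rate trace CSV
  tr <- instantaneous_rate(sp, pops[[1]], 10, t_stop = 2000)
  p2 <- tempfile(fileext = ".csv")
  write_rate_trace(tr, p2)
  back2 <- read.csv(p2)
  expect_equal(back2$rate_hz, tr$rate)
})
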