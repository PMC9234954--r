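test_that("eligibility kernel is a normalized single lobe peaked at t0", {
  p <- plasticity_params()
  z <- seq(0, p$integration_window, by = 0.1)
  k <- pfpc_kernel(z, p)
  expect_true(all(k >= 0))
  expect_equal(max(k), 1)
  expect_equal(z[which.max(k)], p$t0) # argmax exactly at 100 ms
  # negligible outside the main lobe
  expect_true(all(k[z > p$t0 + p$lobe_width] < 0.01))
  expect_true(all(k[z < p$t0 - p$lobe_width] < 0.01))
  # holds for other widths too
  p2 <- plasticity_params(lobe_width = 50)
  z2 <- seq(0, 300, by = 0.1)
  k2 <- pfpc_kernel(z2, p2)
  expect_equal(z2[which.max(k2)], 100)
  expect_equal(max(k2), 1)
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(plasticity_params(ltp_step = -1), "ltp_step")
  expect_error(plasticity_params(ltd_scale = 0.1), "ltd_scale")
  expect_error(plasticity_params(weight_min = 2, weight_max = 1), "weight")
  expect_error(plasticity_params(t0 = 400), "t0")
})

test_that("genotypes differ only in the LTP constant (10x reduction)", {
  expect_equal(apply_genotype(plasticity_params(), "control")$ltp_step, 0.01)
  expect_equal(apply_genotype(plasticity_params(), "l7pp2b")$ltp_step, 0.001)
  expect_equal(apply_genotype(plasticity_params(), "l7pp2b")$ltd_scale, -0.03)
  expect_error(apply_genotype(plasticity_params(), "mutantX"), "genotype")
})

test_that("LTP adds exactly the fixed step to PFs active at the PC spike", {
  p <- plasticity_params()
  w <- c(0.5, 0.5, 0.5)
  hist <- list(c(998), c(800), numeric(0)) # only PF 1 active within 5 ms
  w2 <- on_pc_spike(1000, numeric(0), hist, w, p)
  expect_equal(w2, c(0.51, 0.5, 0.5))
  # knock-out step
  pko <- apply_genotype(p, "l7pp2b")
  expect_equal(on_pc_spike(1000, numeric(0), hist, w, pko),
               c(0.501, 0.5, 0.5))
  # no PC spike in an interval -> no update path is ever invoked (event rule);
  # an update at a spike leaves untouched synapses untouched
  expect_equal(w2[2:3], w[2:3])
})

test_that("single-PF depression is maximal at the kernel peak lag", {
  p <- plasticity_params()
  lags <- seq(0, 300, by = 1)
  dep <- vapply(lags, function(L) {
    w <- on_pc_spike(1000, io_spike_times = 1000,
                     pf_history = list(1000 - L), weights = 0.5, params = p)
    0.5 - w
  }, 0)
  expect_equal(lags[which.max(dep)], p$t0)
  expect_true(all(dep >= 0))
})

test_that("event-driven updates match the dense-time brute-force reference", {
  p <- plasticity_params(weight_max = 2)
  set.seed(11)
  pf_trains <- list(sort(runif(40, 0, 2000)), sort(runif(25, 0, 2000)),
                    sort(runif(10, 0, 2000)))
  pf_trains <- lapply(pf_trains, function(x) round(x, 1))
  pc_times <- round(sort(runif(60, 0, 2000)), 1)
  io_times <- c(500, 500.1, 1200)
  w0 <- c(0.5, 0.5, 0.5)
  dense <- ref_plasticity_dense(pc_times, io_times, pf_trains, w0, p)
  # event-driven path: apply the rule spike by spike with causal histories
  w <- w0
  for (t in pc_times) {
    hist <- lapply(pf_trains, function(x) x[x <= t])
    w <- on_pc_spike(t, io_times[io_times <= t], hist, w, p)
  }
  expect_equal(w, dense, tolerance = 1e-12)
})

test_that("engine plasticity equals the replayed R rule on a toy circuit", {
  p <- plasticity_params(weight_max = 2)
  net <- network()
  gen <- neuron_params(t_ref = 0)
  pf <- build_population(net, "PF", 3, gen, generator = TRUE)
  pc <- build_population(net, "PC", 1, bias_mv = bias_for_rate(90))
  io <- build_population(net, "IO", 1, gen, generator = TRUE)
  w0 <- c(0.4, 0.6, 0.8)
  pid <- whiskersim:::eng_add_projection(net$ptr, 0:2, rep(3L, 3), w0, 1,
                                         FALSE, TRUE)
  whiskersim:::eng_add_projection(net$ptr, 4L, 3L, 0, 1, TRUE, FALSE)
  net_finalize(net)
  whiskersim:::eng_set_io_map(net$ptr, 4L, 3L)
  whiskersim:::eng_set_plasticity(net$ptr, p$ltp_step, p$ltd_scale,
                                  p$weight_min, p$weight_max,
                                  kernel_lut(p, 0.1), p$coincidence_window,
                                  TRUE)
  set.seed(12)
  pf_trains <- lapply(1:3, function(i) round(sort(runif(60, 0, 3000)), 1))
  io_times <- c(800, 2000, 2000.2)
  for (i in 1:3) inject_spikes(net, pf, i, pf_trains[[i]])
  inject_spikes(net, io, 1, io_times)
  net_run(net, 3000)
  sp <- get_spikes(net)
  pc_times <- sort(sp$time[sp$gid == 3])
  expect_gt(length(pc_times), 100) # tonic PC activity drives the rule
  w_engine <- whiskersim:::eng_weights(net$ptr, pid)
  w <- w0
  for (t in pc_times) {
    hist <- lapply(pf_trains, function(x) x[x <= t])
    w <- on_pc_spike(t, io_times[io_times <= t], hist, w, p)
  }
  expect_equal(w_engine, w, tolerance = 1e-12)
})

test_that("weight bounds are never violated and monotonicity holds", {
  p <- plasticity_params(weight_min = 0, weight_max = 1)
  # IO silenced -> non-decreasing trajectories
  set.seed(13)
  w <- rep(0.99, 3)
  trains <- lapply(1:3, function(i) sort(runif(200, 0, 1000)))
  traj <- list()
  for (t in sort(runif(100, 0, 1000))) {
    hist <- lapply(trains, function(x) x[x <= t])
    w_new <- on_pc_spike(t, numeric(0), hist, w, p)
    expect_true(all(w_new >= w - 1e-15))
    expect_true(all(w_new <= 1 & w_new >= 0))
    w <- w_new
  }
  expect_equal(w, rep(1, 3)) # clipped at the upper bound
  # LTP = 0 and IO firing at every PC spike -> non-increasing, floored at 0
  p0 <- plasticity_params(ltp_step = 0, weight_min = 0, weight_max = 1)
  w <- rep(0.05, 3)
  for (t in seq(100, 2000, by = 20)) {
    hist <- lapply(trains, function(x) x[x <= t])
    w_new <- on_pc_spike(t, io_spike_times = t, hist, w, p0)
    expect_true(all(w_new <= w + 1e-15))
    expect_true(all(w_new >= 0))
    w <- w_new
  }
  expect_equal(w, rep(0, 3))
})

test_that("depression is selective for PFs that precede the IO signal by t0", {
  p <- plasticity_params()
  # PF 1 reproducibly fires t0 before each IO/PC coincidence; PF 2 fires at
  # unrelated times
  io_times <- c(500, 1000, 1500)
  pf1 <- io_times - p$t0
  set.seed(14)
  pf2 <- sort(runif(length(pf1), 0, 2000))
  w <- c(0.9, 0.9)
  for (t in io_times) {
    hist <- list(pf1[pf1 <= t], pf2[pf2 <= t])
    w <- on_pc_spike(t, io_times[io_times <= t], hist, w, p)
  }
  expect_lt(w[1], w[2])
})
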