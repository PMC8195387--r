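test_that("membrane rests at the leak reversal without input", {
  np <- neuron_params()
  st <- list(V = np$E_L, g_exc = 0, g_inh = 0, refractory_remaining = 0)
  for (k in 1:100) st <- step_membrane(st, np)$state
  expect_equal(st$V, -60)
})

test_that("threshold crossing resets and silences for the refractory time", {
  np <- neuron_params()
  st <- list(V = np$V_th - 0.01, g_exc = 0, g_inh = 0,
             refractory_remaining = 0)
  out <- step_membrane(st, np, dt = 0.1, I_e = 500)
  expect_true(out$spiked)
  expect_equal(out$state$V, -60)
  # stays at reset for the full 5 ms despite strong drive
  st <- out$state
  for (k in 1:49) {
    out <- step_membrane(st, np, dt = 0.1, I_e = 500)
    expect_false(out$spiked)
    expect_equal(out$state$V, -60)
    st <- out$state
  }
})

test_that("synaptic conductances decay exponentially", {
  np <- neuron_params()
  st <- list(V = np$E_L, g_exc = 0.5, g_inh = 1, refractory_remaining = 0)
  for (k in 1:50) st <- step_membrane(st, np, dt = 0.1)$state
  expect_equal(st$g_exc, 0.5 / exp(1), tolerance = 1e-10)
  expect_equal(st$g_inh, 1 * exp(-5 / 10), tolerance = 1e-10)
})

test_that("the symmetric inhibitory STDP rule has its stated fixed point", {
  # pre-synaptic spike with the target trace at alpha: no change
  expect_equal(istdp_update(2, "pre", x_post = 0.12), 2)
  # post-synaptic spike: potentiation by eta * gbar * x_pre
  expect_equal(istdp_update(0, "post", x_pre = 1, eta = 0.05, gbar = 1),
               0.05)
  # depression is clipped at zero
  expect_equal(istdp_update(0.001, "pre", x_post = 0), 0)
  expect_gte(istdp_update(0.5, "pre", x_post = 0), 0)
})

test_that("Poisson drive respects rate, step size and disconnection", {
  set.seed(2)
  expect_false(any(poisson_drive(1000, rate = 0)))
  expect_false(any(poisson_drive(1000, rate = 50,
                                 connected = FALSE)))
  # 1000 neurons x 10 Hz x 0.1 s: count within 3 SD of 1000
  n_ev <- sum(replicate(100, sum(poisson_drive(1000, rate = 10, dt = 1))))
  expect_lt(abs(n_ev - 1000), 3 * sqrt(1000))
})

test_that("the engine honours the refractory contract and records calcium", {
  # two strongly driven neurons, no synapses
  lay <- manual_layout(c(0, 150), c(0, 0), c("E", "E"), c(300, 300))
  cfg <- default_config()
  net <- build_network(lay, empty_synapses(), cfg)
  net$ext_on[] <- FALSE
  net$Ie[] <- 400 # well above rheobase
  set.seed(1)
  res <- simulate_interval(net, 2000, istdp = FALSE)
  sp <- res$spikes
  expect_gt(nrow(sp), 100)
  for (i in 1:2) {
    isi <- diff(sp$t_ms[sp$id == i])
    expect_true(all(isi >= 5 - 1e-9))
  }
  # calcium consistent with the emitted spike count and the (still
  # transient) charging of the 50 s trace over a 2 s run
  rate_hz <- res$spike_count[1] / 2
  expect_equal(res$net$state$ca[1],
               0.1 * rate_hz * 50 * (1 - exp(-2 / 50)), tolerance = 0.05)
})

test_that("engine conductance kicks and decay match closed form", {
  # one neuron receiving a single synapse from a driven source
  lay <- manual_layout(c(0, 150), c(0, 0), c("E", "E"), c(300, 300))
  cfg <- default_config()
  net <- build_network(lay, make_synapses(1, 2, "EE", 0.5), cfg)
  net$ext_on[] <- FALSE
  net$Ie[1] <- 400
  net$state$V[2] <- -60
  set.seed(1)
  res <- simulate_interval(net, 50, istdp = FALSE)
  # target accumulated conductance: every source spike deposits 0.5 nS
  expect_gt(res$net$state$ge[2], 0)
  # with the source silenced the conductance decays with tau_exc
  net2 <- res$net
  net2$Ie[1] <- 0
  net2$state$V[1] <- -60
  g0 <- net2$state$ge[2]
  res2 <- simulate_interval(net2, 5, istdp = FALSE)
  expect_equal(res2$net$state$ge[2], g0 / exp(1), tolerance = 1e-6)
})

test_that("iSTDP in the engine balances a small overexcited circuit", {
  # excitatory neurons driven hard; one inhibitory neuron wired to all of
  # them with plastic IE synapses growing from zero reduces their rate
  set.seed(4)
  n_e <- 20
  lay <- manual_layout(c(seq(0, by = 150, length.out = n_e), 100),
                       rep(0, n_e + 1), c(rep("E", n_e), "I"),
                       c(150 * (n_e + 1), 300))
  syn <- dplyr::bind_rows(
    make_synapses(rep(n_e + 1, n_e), 1:n_e, "IE", 0),
    make_synapses(1:n_e, rep(n_e + 1, n_e), "EI", 2))
  cfg <- default_config(istdp_accel = 10)
  net <- build_network(lay, syn, cfg)
  net$ext_on[] <- FALSE
  net$Ie[1:n_e] <- 180
  net$Ie[n_e + 1] <- 120
  r0 <- NULL
  rates <- numeric(20)
  for (k in 1:20) {
    res <- simulate_interval(net, 1000, istdp = TRUE,
                             record_spikes = FALSE)
    net <- res$net
    rates[k] <- mean(res$spike_count[1:n_e])
  }
  expect_gt(mean(net$syn$g[net$syn$class == "IE"]), 0)
  # trend: later excitatory rates clearly below the initial ones
  expect_lt(mean(rates[16:20]), 0.7 * mean(rates[1:3]))
})

test_that("neuron parameter invariants are enforced", {
  expect_error(neuron_params(E_inh = -50))
  expect_error(neuron_params(V_th = -70))
  expect_error(neuron_params(tau_exc = 0))
})
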