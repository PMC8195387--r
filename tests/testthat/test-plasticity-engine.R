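test_that("formation probability follows the Gaussian kernel", {
  expect_equal(formation_probability(0, 0.8, 8), 0.8)
  expect_equal(formation_probability(8 * 150, 0.8, 8), 0.8 / exp(1))
  expect_lt(formation_probability(1e6, 0.8, 8), 1e-100)
  expect_equal(formation_probability(0, 0.3, 24), 0.3)
  d <- seq(0, 5000, by = 100)
  p <- formation_probability(d, 0.8, 8)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 0.8))
})

test_that("deletion probability decays with conductance", {
  expect_equal(deletion_probability(0, 1), 1)
  expect_equal(deletion_probability(2, 1), exp(-1))
  g <- seq(0, 3, by = 0.1)
  expect_true(all(diff(deletion_probability(g, 0.7)) < 0))
})

test_that("a free pre/post pair at distance zero forms exactly one synapse", {
  lay <- manual_layout(c(0, 0), c(0, 0), c("E", "E"), c(300, 300))
  cfg <- default_config(synapse = list(p_hat_E = 1))
  net <- build_network(lay, empty_synapses(), cfg)
  net$psi <- c(1, 1)
  net$ie_mean <- 1; net$g_th <- 1
  net$curves <- make_regime_curves(net$psi, lay$pop, cfg)
  net$state$z <- matrix(c(1, 0,  0, 1,  0, 0), 2, 3)
  set.seed(1)
  upd <- structural_update(net)
  expect_identical(nrow(upd$net$syn), 1L)
  expect_identical(upd$net$syn$pre, 1L)
  expect_identical(upd$net$syn$post, 2L)
  expect_identical(as.character(upd$net$syn$class), "EE")
  zc <- neuroregrow:::connected_counts(upd$net)
  expect_identical(zc[1, 1], 1L) # source axonal element now bound
  expect_identical(zc[2, 2], 1L) # target post-excitatory element bound
})

test_that("a structural update with no free elements and no losses is a no-op", {
  lay <- manual_layout(c(0, 300, 600), c(0, 0, 0), c("E", "E", "I"),
                       c(900, 900))
  syn <- make_synapses(c(1, 3), c(2, 1), c("EE", "IE"), c(0.5, 1))
  cfg <- default_config()
  net <- build_network(lay, syn, cfg)
  net$psi <- rep(1, 3); net$ie_mean <- 1; net$g_th <- 1
  net$curves <- make_regime_curves(net$psi, lay$pop, cfg)
  net$state$z <- neuroregrow:::connected_counts(net) * 1.0
  set.seed(2)
  upd <- structural_update(net)
  expect_identical(syn_keys(upd$net$syn), syn_keys(net$syn))
  expect_true(all(upd$log[1, 2:9] == 0))
})

test_that("formation respects both sides' free supplies", {
  # one source with 3 free axonal elements, five co-located targets with
  # one free post element each and p_hat = 1: exactly 3 synapses form
  lay <- manual_layout(rep(0, 6), rep(0, 6), rep("E", 6), c(300, 300))
  cfg <- default_config(synapse = list(p_hat_E = 1))
  net <- build_network(lay, empty_synapses(), cfg)
  net$psi <- rep(1, 6); net$ie_mean <- 1; net$g_th <- 1
  net$curves <- make_regime_curves(net$psi, lay$pop, cfg)
  z <- matrix(0, 6, 3)
  z[1, 1] <- 3
  z[2:6, 2] <- 1
  net$state$z <- z
  set.seed(3)
  upd <- structural_update(net)
  expect_identical(nrow(upd$net$syn), 3L)
  expect_true(all(upd$net$syn$pre == 1))
  expect_identical(anyDuplicated(upd$net$syn$post), 0L)
})

test_that("acceptance frequency of new partners follows the kernel", {
  # candidates at graded distances from a single source; repeated
  # independent updates estimate the per-candidate formation probability
  set.seed(9)
  n_c <- 60
  d_true <- seq(100, 3000, length.out = n_c)
  lay <- manual_layout(c(0, d_true), rep(0, n_c + 1),
                       rep("E", n_c + 1), c(8000, 8000))
  cfg <- default_config()
  base <- build_network(lay, empty_synapses(), cfg)
  base$psi <- rep(1, n_c + 1); base$ie_mean <- 1; base$g_th <- 1
  base$curves <- make_regime_curves(base$psi, lay$pop, cfg)
  z <- matrix(0, n_c + 1, 3)
  z[1, 1] <- n_c # ample axonal supply
  z[2:(n_c + 1), 2] <- 1
  reps <- 60
  hits <- numeric(n_c)
  for (r in seq_len(reps)) {
    net <- base
    net$state$z <- z
    upd <- structural_update(net)
    hits[upd$net$syn$post - 1L] <- hits[upd$net$syn$post - 1L] + 1
  }
  p_emp <- hits / reps
  p_kernel <- formation_probability(d_true, 0.8, 8)
  # empirical acceptance tracks the kernel over a 20-fold range
  expect_gt(stats::cor(p_emp, p_kernel), 0.9)
  expect_equal(mean(p_emp[1:10]), mean(p_kernel[1:10]), tolerance = 0.15)
  expect_lt(mean(p_emp[51:60]), 0.2)
})

test_that("weight-dependent deletion spares immune synapses", {
  # an inhibitory neuron must shed axonal elements; only candidates below
  # the immunity threshold may be deleted
  lay <- manual_layout(c(0, 0, 0, 0, 0), rep(0, 5),
                       c("I", "E", "E", "E", "E"), c(300, 300))
  g_vals <- c(0.1, 0.2, 2.5, 3.0) # threshold 1: two immune
  syn <- make_synapses(rep(1, 4), 2:5, rep("IE", 4), g_vals)
  cfg <- default_config()
  net <- build_network(lay, syn, cfg)
  net$psi <- rep(1, 5); net$ie_mean <- 1; net$g_th <- 1
  net$curves <- make_regime_curves(net$psi, lay$pop, cfg)
  z <- neuroregrow:::connected_counts(net) * 1.0
  z[1, 1] <- 0 # demand loss of all four axonal elements
  net$state$z <- z
  set.seed(4)
  upd <- structural_update(net)
  kept <- upd$net$syn
  expect_true(all(kept$g >= 1))
  expect_identical(nrow(kept), 2L)

  # post-synaptic inhibitory losses behave the same on the target side
  net2 <- build_network(lay, syn, cfg)
  net2$psi <- rep(1, 5); net2$ie_mean <- 1; net2$g_th <- 1
  net2$curves <- make_regime_curves(net2$psi, lay$pop, cfg)
  z2 <- neuroregrow:::connected_counts(net2) * 1.0
  z2[2:5, 3] <- 0
  net2$state$z <- z2
  set.seed(5)
  upd2 <- structural_update(net2)
  expect_true(all(upd2$net$syn$g >= 1))
})

test_that("uniform deletion removes the demanded number of excitatory synapses", {
  lay <- manual_layout(rep(0, 5), rep(0, 5), rep("E", 5), c(300, 300))
  syn <- make_synapses(rep(1, 4), 2:5, rep("EE", 4),
                       c(0.4, 0.5, 0.6, 0.7))
  cfg <- default_config()
  net <- build_network(lay, syn, cfg)
  net$psi <- rep(1, 5); net$ie_mean <- 1; net$g_th <- 1
  net$curves <- make_regime_curves(net$psi, lay$pop, cfg)
  z <- neuroregrow:::connected_counts(net) * 1.0
  z[1, 1] <- 2 # lose two axonal elements
  net$state$z <- z
  set.seed(6)
  upd <- structural_update(net)
  expect_identical(nrow(upd$net$syn), 2L)
  expect_identical(sum(upd$log[, c("deleted_EE")]), 2L)
})

test_that("conservation holds through random growth and shrinkage", {
  set.seed(10)
  fx <- make_fixture(scale = 0.05, seed = 2)
  cfg <- fx$cfg
  net <- build_network(fx$layout, fx$syn, cfg)
  net$psi <- runif(500, 0.5, 1.5)
  net$ie_mean <- 0.5; net$g_th <- 0.5
  net$curves <- make_regime_curves(net$psi, fx$layout$pop, cfg)
  net$state$z <- neuroregrow:::connected_counts(net) +
    matrix(sample(c(-3, 0, 2, 5), 500 * 3, replace = TRUE), 500, 3)
  net$state$z[net$state$z < 0] <- 0
  for (k in 1:4) {
    upd <- structural_update(net)
    net <- upd$net
    zc <- neuroregrow:::connected_counts(net)
    syn <- net$syn
    expect_identical(sum(zc[, 1]), nrow(syn))
    expect_identical(sum(zc[, 2]),
                     sum(syn$class %in% c("EE", "EI")))
    expect_identical(sum(zc[, 3]),
                     sum(syn$class %in% c("IE", "II")))
    expect_true(all(net$state$z >= 0))
  }
})

test_that("zero growth leaves the connectome invariant", {
  fx <- make_fixture(scale = 0.05, seed = 3)
  cfg <- default_config(regime = "G0", growth = list(
    E = list(post_exc = list(nu = 0), post_inh = list(nu = 0)),
    I = list(post_exc = list(nu = 0), post_inh = list(nu = 0))))
  net <- build_network(fx$layout, fx$syn, cfg)
  net$psi <- rep(1, 500); net$ie_mean <- 0.5; net$g_th <- 0.5
  net$curves <- make_regime_curves(net$psi, fx$layout$pop, cfg,
                                   regime = "G0")
  expect_true(all(net$curves$nu == 0))
  net$state$z <- neuroregrow:::connected_counts(net) * 1.0
  keys0 <- sort(syn_keys(net$syn))
  set.seed(11)
  for (k in 1:3) {
    net <- structural_update(net)$net
  }
  expect_identical(sort(syn_keys(net$syn)), keys0)
})
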