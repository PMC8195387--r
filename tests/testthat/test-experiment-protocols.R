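curve_rate <- function(curves, i, pool, ca) {
  k <- match(pool, c("axonal", "post_exc", "post_inh"))
  if (curves$gconst[i, k]) return(curves$nu[i, k])
  curves$nu[i, k] *
    (2 * exp(-((ca - curves$xi[i, k]) / curves$zeta[i, k])^2) -
       curves$om[i, k])
}

test_that("regime curves implement the axonal sign patterns", {
  cfg <- default_config()
  psi <- c(10, 10)
  pop <- c("E", "I")
  g2 <- make_regime_curves(psi, pop, cfg, regime = "G2")
  # excitatory axons sprout above psi, up to 1.75 psi
  expect_gt(curve_rate(g2, 1, "axonal", 12), 0)
  expect_lt(curve_rate(g2, 1, "axonal", 9), 0)
  expect_gt(curve_rate(g2, 1, "axonal", 17), 0)
  expect_lt(curve_rate(g2, 1, "axonal", 18), 0)
  # inhibitory axons sprout below psi
  expect_gt(curve_rate(g2, 2, "axonal", 7), 0)
  expect_lt(curve_rate(g2, 2, "axonal", 12), 0)

  g0 <- make_regime_curves(psi, pop, cfg, regime = "G0")
  for (ca in c(1, 5, 10, 20)) {
    expect_identical(curve_rate(g0, 1, "axonal", ca), 0)
    expect_identical(curve_rate(g0, 2, "axonal", ca), 0)
  }

  g0p <- make_regime_curves(psi, pop, cfg, regime = "G0p")
  expect_identical(curve_rate(g0p, 1, "axonal", 1),
                   curve_rate(g0p, 1, "axonal", 100))
  expect_gt(curve_rate(g0p, 1, "axonal", 1), 0)

  g5 <- make_regime_curves(psi, pop, cfg, regime = "G5")
  expect_gt(curve_rate(g5, 1, "axonal", 9), 0)
  expect_gt(curve_rate(g5, 2, "axonal", 9), 0)

  g3 <- make_regime_curves(psi, pop, cfg, regime = "G3")
  expect_lt(curve_rate(g3, 1, "axonal", 12), 0)
  expect_gt(curve_rate(g3, 2, "axonal", 12), 0)

  g4 <- make_regime_curves(psi, pop, cfg, regime = "G4")
  expect_gt(curve_rate(g4, 1, "axonal", 10), 0)
  expect_gt(curve_rate(g4, 2, "axonal", 10), 0)

  expect_error(make_regime_curves(psi, pop, cfg, regime = "G9"))
})

test_that("reference post-synaptic curves pin their fixed points at psi", {
  cfg <- default_config()
  psi <- c(8, 12)
  cur <- make_regime_curves(psi, c("E", "I"), cfg)
  for (i in 1:2) {
    # zero turnover exactly at psi for both dendritic pools
    expect_lt(abs(curve_rate(cur, i, "post_exc", psi[i])), 1e-9)
    expect_lt(abs(curve_rate(cur, i, "post_inh", psi[i])), 1e-9)
    # excitatory dendritic elements sprout below psi, inhibitory above
    expect_gt(curve_rate(cur, i, "post_exc", 0.9 * psi[i]), 0)
    expect_lt(curve_rate(cur, i, "post_exc", 1.2 * psi[i]), 0)
    expect_lt(curve_rate(cur, i, "post_inh", 0.9 * psi[i]), 0)
    expect_gt(curve_rate(cur, i, "post_inh", 1.2 * psi[i]), 0)
  }
  # the post-synaptic battery switches the placement
  alt <- make_regime_curves(psi, c("E", "I"), cfg,
                            post_regime = list(post_exc = "eta_psi",
                                               post_inh = "eps_psi"))
  expect_gt(curve_rate(alt, 1, "post_exc", 1.2 * psi[1]), 0)
  expect_lt(curve_rate(alt, 1, "post_inh", 1.2 * psi[1]), 0)
})

test_that("deafferentation removes external drive only inside the LPZ", {
  fx <- make_fixture(scale = 0.05, seed = 4)
  net <- build_network(fx$layout, fx$syn, fx$cfg)
  net2 <- deafferent(net)
  lpz <- net$layout$region %in% c("LPZ_C", "LPZ_B")
  expect_true(all(!net2$ext_on[lpz]))
  expect_true(all(net2$ext_on[!lpz]))
  expect_true(all(is.infinite(net2$state$next_ext[lpz])))
  expect_error(deafferent(net2), "already")
  # recurrent synapses untouched
  expect_identical(net2$syn, net$syn)
  # engine delivers no external events to deafferented neurons
  set.seed(1)
  res <- simulate_interval(net2, 500, istdp = FALSE)
  expect_true(all(is.infinite(res$net$state$next_ext[lpz])))
})

test_that("single-neuron homeostasis: 4:1 initialisation and counteraction", {
  sn <- run_single_neuron_experiment(t_base_s = 120, t_grow_s = 60,
                                     t_settle_s = 30, period_s = 300,
                                     n_cycles = 1, seed = 2)
  expect_equal(sn$ratio_after_init, 4, tolerance = 1e-9)
  expect_gt(sn$psi, 0)
  # element counts respond to the activity deviation by counteracting it
  expect_lt(sn$cor_ca_dgnet, 0)
  # time series bookkeeping
  expect_true(all(c("baseline", "grow_in", "settle", "sinusoid") %in%
                    sn$ts$stage))
  expect_true(all(sn$ts$z_post_e >= 0 & sn$ts$z_post_i >= 0))
  expect_identical(glance(sn)$ratio_after_init, sn$ratio_after_init)
})

test_that("balance phase records psi, IE mean and the immunity threshold", {
  # miniature network, short schedule: checks plumbing, not the AI state
  fx <- make_fixture(scale = 0.05, seed = 5,
                     overrides = desk_overrides(t1_s = 8, t2_s = 10,
                                                t_end_s = 12))
  net <- build_network(fx$layout, fx$syn, fx$cfg)
  bal <- suppressWarnings(run_balance_phase(net, ai_window_s = 4))
  expect_identical(length(bal$psi), 500L)
  expect_true(all(bal$psi > 0))
  expect_gt(bal$ie_mean, 0)
  expect_identical(bal$g_th, bal$ie_mean)
  expect_identical(bal$net$state$t, 10000)
  expect_false(is.null(bal$net$curves))
  expect_true(all(bal$net$state$z >= 0))
  expect_s3_class(bal$rates, "tbl_df")
  expect_true(nrow(bal$syn_count) > 0)
})

test_that("runs with identical seeds reproduce and streams are isolated", {
  fx1 <- make_fixture(scale = 0.05, seed = 6)
  fx2 <- make_fixture(scale = 0.05, seed = 6)
  expect_identical(fx1$layout, fx2$layout)
  expect_identical(fx1$syn, fx2$syn)
  # changing only the sampling seed leaves placement and wiring unchanged
  fx3 <- make_fixture(scale = 0.05, seed = 6,
                      seeds = list(sampling = 999))
  expect_identical(fx1$layout, fx3$layout)
  expect_identical(fx1$syn, fx3$syn)
  # a different wiring seed changes synapses but not placement
  fx4 <- make_fixture(scale = 0.05, seed = 6, seeds = list(wiring = 999))
  expect_identical(fx1$layout, fx4$layout)
  expect_false(identical(fx1$syn, fx4$syn))
})
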