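test_that("spatial profile and field constructors validate their invariants", {
  expect_error(spatial_profile(c(0, 0.5, 0.4), c(1, 1, 1)), "increasing")
  expect_error(spatial_profile(c(0, 0.5, 1), c(1, -1, 1)), "non-negative")
  expect_error(spatial_profile(c(0, 0.5), c(1, 1, 1)))
  x <- seq(0, 1, length.out = 11)
  f <- spatial_field(x, list(A = rep(1, 11)))
  expect_error(spatial_field(x, list(A = rep(1, 5))))
  p <- field_profile(f, "A")
  expect_s3_class(p, "spatial_profile")
  expect_error(field_profile(f, "B"))
})

test_that("profile and field CSV round-trips preserve data", {
  x <- seq(0, 1, length.out = 21)
  p <- spatial_profile(x, exp(-x), sd = rep(0.05, 21))
  fp <- tempfile(fileext = ".csv")
  write_profile_csv(p, fp)
  p2 <- read_profile_csv(fp)
  expect_equal(p2$positions, p$positions)
  expect_equal(p2$values, p$values)
  expect_equal(p2$sd, p$sd)
  f <- spatial_field(x, list(A = exp(-x), B = x), sd = list(B = rep(0.1, 21)))
  ff <- tempfile(fileext = ".csv")
  write_field_csv(f, ff)
  f2 <- read_field_csv(ff)
  expect_equal(f2$values$A, f$values$A)
  expect_equal(f2$sd$B, f$sd$B)
})

test_that("flanking repressor profiles produce a single interior spike (one-site)", {
  net <- compile_reactions(spike_graph(), "one_site")
  inputs <- spike_inputs()
  lin <- linear_steady_state(net, inputs)
  C <- lin$values$C
  expect_equal(interior_maxima(C), 1)
  peak <- which.max(C)
  x <- inputs$positions
  expect_gt(x[peak], 0.3); expect_lt(x[peak], 0.7)
  # peak clearly dominates the repressed boundaries
  expect_gt(max(C), 1.5 * C[1])
  # matches long-time integration to high accuracy
  sim <- simulate_field(net, inputs, t_final = 500)
  expect_lt(max(abs(sim$values$C - C) / pmax(C, 1e-12)), 1e-8)
})

test_that("the per-site variant of the spike scenario also yields one interior maximum", {
  net <- compile_reactions(
    spike_graph(), "per_site",
    rate_defaults = list(kp_C_a1_r01 = 0.02, kp_C_a1_r10 = 0.02,
                         kp_C_a1_r11 = 0.01))
  inputs <- spike_inputs()
  sim <- simulate_field(net, inputs, t_final = 500)
  expect_equal(interior_maxima(sim$values$C), 1)
  x <- inputs$positions
  peak <- which.max(sim$values$C)
  expect_gt(x[peak], 0.3); expect_lt(x[peak], 0.7)
})

test_that("spatially flat inputs give spatially flat outputs", {
  net <- compile_reactions(spike_graph(), "one_site")
  x <- seq(0, 1, length.out = 20)
  inputs <- spatial_field(x, list(A = rep(1, 20), R1 = rep(0.5, 20),
                                  R2 = rep(0.2, 20)))
  sim <- simulate_field(net, inputs, t_final = 50)
  for (sp in names(sim$values))
    expect_lt(diff(range(sim$values[[sp]])), 1e-8 * max(sim$values[[sp]], 1e-12))
})

test_that("positions are independent: permuting inputs permutes outputs", {
  net <- compile_reactions(spike_graph(), "one_site")
  inputs <- spike_inputs(21)
  sim <- simulate_field(net, inputs, t_final = 30)
  # reversed-input run (grid must stay increasing, so reverse the values)
  rev_inputs <- spatial_field(inputs$positions,
                              lapply(inputs$values, rev))
  sim_rev <- simulate_field(net, rev_inputs, t_final = 30)
  for (sp in names(sim$values))
    expect_equal(sim_rev$values[[sp]], rev(sim$values[[sp]]), tolerance = 1e-9)
})

test_that("repression is monotone: doubling repressors never raises the steady state", {
  net <- compile_reactions(spike_graph(), "one_site")
  inputs <- spike_inputs(41)
  base <- linear_steady_state(net, inputs)
  doubled <- spatial_field(inputs$positions, list(
    A = inputs$values$A, R1 = 2 * inputs$values$R1, R2 = 2 * inputs$values$R2))
  up <- linear_steady_state(net, doubled)
  expect_true(all(up$values$C <= base$values$C + 1e-12))
  # activation is monotone the other way
  more_act <- spatial_field(inputs$positions, list(
    A = 2 * inputs$values$A, R1 = inputs$values$R1, R2 = inputs$values$R2))
  up_a <- linear_steady_state(net, more_act)
  expect_true(all(up_a$values$C >= base$values$C - 1e-12))
})

test_that("zero repressors reduce the steady state to the unregulated activated level, flat when A is flat", {
  net <- compile_reactions(spike_graph(), "one_site")
  x <- seq(0, 1, length.out = 15)
  inputs <- spatial_field(x, list(A = rep(1, 15), R1 = rep(0, 15),
                                  R2 = rep(0, 15)))
  ss <- linear_steady_state(net, inputs)
  expect_lt(diff(range(ss$values$C)), 1e-10)
  # closed form for one activator at one site: C* = (kp/kd) * total * kb A/(kb A + ku)
  p <- net$parameters
  expected <- p[["kp_C_A"]] / p[["kd_C"]] *
    (p[["kb_C_A"]] * 1 / (p[["kb_C_A"]] * 1 + p[["ku_C_A"]]))
  expect_equal(ss$values$C[1], unname(expected), tolerance = 1e-10)
})

test_that("gene totals are conserved at every position of a spatial run", {
  net <- compile_reactions(spike_graph(), "one_site", gene_totals = c(C = 1.7))
  inputs <- spike_inputs(31)
  sim <- simulate_field(net, inputs, t_final = 40)
  tot <- sim$values$C_free + sim$values$C_A + sim$values$C_R1 + sim$values$C_R2
  expect_lt(max(abs(tot - 1.7)) / 1.7, 1e-6)
})

test_that("linear_steady_state rejects nonlinear systems", {
  # self-activation: protein binds its own operon -> state-state product
  g <- double_graph(activations = list(c("A", "A")))
  net <- compile_reactions(g, "per_site")
  x <- seq(0, 1, length.out = 5)
  inputs <- spatial_field(x, setNames(list(), character(0)))
  expect_error(linear_steady_state(net, inputs), "nonlinear")
})

test_that("interior_maxima counts peaks with plateau merging", {
  expect_equal(interior_maxima(c(0, 1, 0)), 1)
  expect_equal(interior_maxima(c(0, 1, 1, 0)), 1)          # plateau
  expect_equal(interior_maxima(c(0, 1, 0, 2, 0)), 2)
  expect_equal(interior_maxima(c(2, 1, 0)), 0)             # boundary max
  expect_equal(interior_maxima(c(0, 1)), 0)
})
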