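test_that("integration matches the closed-form solution of the reduced production mechanism", {
  kp <- 2; kd <- 0.3; G0 <- 1.5; P0 <- 0.4
  g <- double_graph(annotations = list(P = list(initial = P0)))
  net <- compile_reactions(g, "per_site",
                           rate_defaults = list(production = kp, degradation = kd),
                           gene_totals = c(P = G0))
  sys <- build_odes(net)
  times <- seq(0, 25, length.out = 120)
  out <- integrate_odes(sys, times = times)
  expect_lt(max(abs(out[, "P"] -
                      reduced_mechanism_solution(times, kp, kd, G0, P0))), 1e-6)
  # steady state proportional to the gene total
  totals <- seq(0.2, 2, length.out = 10)
  ss <- vapply(totals, function(G) {
    neti <- compile_reactions(g, "per_site",
                              rate_defaults = list(production = kp,
                                                   degradation = kd),
                              gene_totals = c(P = G))
    o <- integrate_odes(build_odes(neti), times = c(0, 200))
    o[nrow(o), "P"]
  }, 0)
  expect_equal(ss, kp * totals / kd, tolerance = 1e-6)
})

test_that("zero initial condition with no basal production stays at zero", {
  sys <- self_activation_system(total = 1, reduce = FALSE)
  out <- integrate_odes(sys, init = c(A_a0 = 0, A_a1 = 0, A = 0),
                        times = c(0, 5, 10))
  expect_true(all(abs(out[, -1]) < 1e-12))
})

test_that("self-activation trajectories preserve the operon total", {
  sys <- self_activation_system(kb = 2, ku = 0.5, kp = 1.5, kd = 0.2,
                                total = 0.8, reduce = FALSE)
  out <- integrate_odes(sys, init = c(A_a0 = 0.8, A_a1 = 0, A = 0.3),
                        times = seq(0, 50, 0.5))
  tot <- out[, "A_a0"] + out[, "A_a1"]
  expect_lt(max(abs(tot - 0.8)) / 0.8, 1e-6)
})

test_that("the reduced self-activation model has exactly two steady states, one at zero protein", {
  # generic positive parameters above threshold
  sys <- self_activation_system(kb = 1.3, ku = 0.7, kp = 2.1, kd = 0.25,
                                total = 1)
  ss <- find_steady_states(sys)
  expect_length(ss, 2)
  prot <- vapply(ss, function(s) s$coordinates[["A"]], 0)
  expect_equal(min(prot), 0)
  expect_gt(max(prot), 0)
  # hand-derived nontrivial coordinates: A* = kp C / kd - ku / kb
  expect_equal(max(prot), 2.1 * 1 / 0.25 - 0.7 / 1.3, tolerance = 1e-6)
  stab <- vapply(ss, `[[`, "", "stability")
  expect_setequal(stab, c("stable", "unstable"))
  # the zero-protein branch is the unstable one above threshold
  expect_equal(stab[which.min(prot)], "unstable")
})

test_that("a pure decay system has a unique stable steady state at the origin", {
  g <- double_graph(repressions = list(c("R", "Y")))
  net <- compile_reactions(g, "per_site")
  net$reactions <- Filter(function(r) r$rate_name == "kd_Y", net$reactions)
  net$species <- "Y"; net$constant_species <- character(0); net$initial <- c(Y = 1)
  ss <- find_steady_states(build_odes(net))
  expect_length(ss, 1)
  expect_equal(unname(ss[[1]]$coordinates), 0)
  expect_equal(ss[[1]]$stability, "stable")
})

test_that("steady states of random one-gene networks are genuine attractor candidates", {
  for (seed in c(4, 9)) {
    set.seed(seed)
    net <- compile_reactions(
      double_graph(activations = list(c("U", "G1"), c("G1", "G1"))),
      sample(c("per_site", "one_site"), 1),
      rate_defaults = list(binding = runif(1, 0.5, 2),
                           degradation = runif(1, 0.1, 0.4)))
    sys <- build_odes(net)
    red <- reduce_by_conservation(sys)
    ss <- find_steady_states(red)
    expect_gt(length(ss), 0)
    for (s in ss) expect_lt(max(abs(red$rhs(s$coordinates))), 1e-8)
    # forward integration from perturbed points lands on a stable listed state
    stable <- Filter(function(s) s$stability == "stable", ss)
    expect_gt(length(stable), 0)
    for (k in 1:5) {
      x0 <- abs(stable[[1]]$coordinates + rnorm(length(red$state_species), 0, 0.05))
      out <- integrate_odes(red, init = x0, times = c(0, 500))
      endpoint <- out[nrow(out), red$state_species]
      d <- vapply(ss, function(s) max(abs(endpoint - s$coordinates)), 0)
      expect_lt(min(d), 1e-4)
    }
  }
})

test_that("threshold scan locates the transcritical point at the derived critical total", {
  kb <- 1.4; ku <- 0.6; kp <- 1.1; kd <- 0.35
  C_star <- self_activation_C_star(kb, ku, kp, kd)
  scan <- threshold_scan(
    function(C) self_activation_system(kb, ku, kp, kd, total = C),
    range = c(C_star / 10, C_star * 5), n_grid = 15, protein = "A")
  expect_false(is.na(scan$C_star))
  expect_lt(abs(scan$C_star - C_star) / C_star, 1e-4)

  # stability exchange on both branches across C*
  below <- self_activation_system(kb, ku, kp, kd, total = C_star * 0.8)
  above <- self_activation_system(kb, ku, kp, kd, total = C_star * 1.25)
  ss_b <- find_steady_states(below)
  ss_a <- find_steady_states(above)
  prot_b <- vapply(ss_b, function(s) s$coordinates[["A"]], 0)
  prot_a <- vapply(ss_a, function(s) s$coordinates[["A"]], 0)
  # below: trivial branch stable (and the only non-negative state)
  expect_equal(Filter(function(s) abs(s$coordinates[["A"]]) < 1e-10,
                      ss_b)[[1]]$stability, "stable")
  # above: trivial unstable, positive branch stable
  triv_a <- Filter(function(s) abs(s$coordinates[["A"]]) < 1e-10, ss_a)[[1]]
  pos_a <- Filter(function(s) s$coordinates[["A"]] > 1e-8, ss_a)[[1]]
  expect_equal(triv_a$stability, "unstable")
  expect_equal(pos_a$stability, "stable")
  # branches coincide continuously at C*: positive branch protein -> 0
  near <- self_activation_system(kb, ku, kp, kd, total = C_star * 1.001)
  ss_n <- find_steady_states(near)
  pos_n <- max(vapply(ss_n, function(s) s$coordinates[["A"]], 0))
  expect_lt(pos_n, 0.01 * kp * C_star / kd)
  # stable protein level is non-decreasing in C over the scan
  tab <- scan_stable_protein(scan)
  expect_true(all(diff(tab$protein) > -1e-9))
})

test_that("the critical total vanishes as degradation goes to zero", {
  kb <- 1; ku <- 1; kp <- 1
  for (kd in c(1e-2, 1e-4)) {
    scan <- threshold_scan(
      function(C) self_activation_system(kb, ku, kp, kd, total = C),
      range = c(self_activation_C_star(kb, ku, kp, kd) / 10, 1),
      n_grid = 9, protein = "A")
    expect_lt(scan$C_star, 2 * kd)   # C* = kd here; -> 0 with kd
  }
})
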