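test_that("the reduced production mechanism yields linear production and degradation", {
  # G -kp-> G + P ; P -kd-> 0, built from an unregulated gene
  g <- double_graph(annotations = list(P = list()))
  net <- compile_reactions(g, "per_site",
                           rate_defaults = list(production = 2, degradation = 0.3),
                           gene_totals = c(P = 1.5))
  sys <- build_odes(net)
  expect_setequal(sys$state_species, c("P_free", "P"))
  # gene is catalytic: its rhs is identically zero
  x <- c(P_free = 1.5, P = 0.7)
  dx <- sys$rhs(x)
  expect_equal(unname(dx["P_free"]), 0)
  expect_equal(unname(dx["P"]), 2 * 1.5 - 0.3 * 0.7)
})

test_that("rhs equals the independent flux-accumulator oracle on random networks", {
  for (seed in 1:15) {
    net <- random_network(seed)
    sys <- build_odes(net)
    for (rep in 1:3) {
      x <- random_state(net, seed * 100 + rep)
      ora <- oracle_rhs(net, x)
      # constant species take the oracle state's value inside the package too
      sys2 <- build_odes(net, constant_values = x[net$constant_species])
      got <- sys2$rhs(x[sys$state_species])
      expect_equal(got, ora[sys$state_species], tolerance = 1e-12)
    }
  }
})

test_that("the analytic Jacobian matches a finite-difference of the rhs", {
  net <- random_network(3)
  sys <- build_odes(net)
  x <- abs(random_state(net, 42))[sys$state_species] + 0.1
  J <- sys$jac(x)
  h <- 1e-7
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fd <- (sys$rhs(xp) - sys$rhs(xm)) / (2 * h)
    expect_equal(unname(J[, i]), unname(fd), tolerance = 1e-5)
  }
})

test_that("empty reaction networks give a zero vector field", {
  net <- structure(list(species = c("X", "Y"), reactions = list(),
                        parameters = numeric(0), constant_species = character(0),
                        initial = c(X = 1, Y = 2), genes = list(),
                        semantics = "per_site", graph = NULL),
                   class = "reaction_network")
  sys <- build_odes(net)
  expect_equal(sys$rhs(c(X = 3, Y = 4)), c(X = 0, Y = 0))
  expect_length(conservation_laws(sys), 2)  # everything conserved
})

test_that("operon-total conservation laws come out exactly", {
  # two-regulator gene, per-site: the four operon states sum to the total
  net <- compile_reactions(two_regulator_graph(), "per_site",
                           gene_totals = c(B = 2.5))
  laws <- conservation_laws(net)
  expect_length(laws, 1)
  w <- laws[[1]]$coefficients
  expect_equal(unname(w[c("B_a0_r0", "B_a0_r1", "B_a1_r0", "B_a1_r1")]),
               rep(1, 4))
  expect_equal(unname(w["B"]), 0)
  expect_equal(laws[[1]]$constant, 2.5)
  # one-site variant: free + two bound states
  net1 <- compile_reactions(two_regulator_graph(), "one_site")
  laws1 <- conservation_laws(net1)
  expect_length(laws1, 1)
  expect_equal(unname(laws1[[1]]$coefficients[c("B_free", "B_A", "B_R")]),
               rep(1, 3))
  # self-activation: operon total is conserved despite protein feedback
  sa <- self_activation_system(reduce = FALSE)
  lsa <- conservation_laws(sa)
  expect_length(lsa, 1)
  expect_equal(unname(lsa[[1]]$coefficients[c("A_a0", "A_a1")]), c(1, 1))
  expect_equal(unname(lsa[[1]]$coefficients["A"]), 0)
})

test_that("a pure-decay system has no conservation law", {
  g <- double_graph(repressions = list(c("R", "Y")))
  net <- compile_reactions(g, "per_site")
  # keep only the degradation reaction: full-rank stoichiometry
  net$reactions <- Filter(function(r) r$rate_name == "kd_Y", net$reactions)
  net$species <- "Y"; net$constant_species <- character(0)
  net$initial <- c(Y = 1)
  expect_length(conservation_laws(build_odes(net)), 0)
})

test_that("null vectors annihilate the stoichiometric matrix exactly; count matches an SVD rank oracle", {
  for (seed in 1:20) {
    net <- random_network(seed + 50)
    sys <- build_odes(net)
    laws <- conservation_laws(sys)
    for (l in laws) {
      prod <- as.vector(l$coefficients %*% sys$stoich)
      expect_identical(max(abs(prod)), 0)        # exact, not approximate
      expect_true(all(l$coefficients == round(l$coefficients)))
      nz <- l$coefficients[l$coefficients != 0]
      expect_gt(nz[1], 0)                         # canonical sign
    }
    # dimension check against an independent numeric rank computation
    sv <- svd(sys$stoich)$d
    num_rank <- sum(sv > max(dim(sys$stoich)) * max(sv, 0) * 1e-12)
    expect_equal(length(laws), nrow(sys$stoich) - num_rank)
  }
})

test_that("conserved quantities drift below 1e-6 along trajectories", {
  for (seed in c(2, 7, 11)) {
    net <- random_network(seed)
    sys <- build_odes(net)
    laws <- conservation_laws(sys)
    if (!length(laws)) next
    out <- integrate_odes(sys, times = seq(0, 30, length.out = 60))
    for (l in laws) {
      q <- as.vector(out[, names(l$coefficients), drop = FALSE] %*%
                       l$coefficients)
      if (abs(q[1]) < 1e-12) expect_lt(max(abs(q - q[1])), 1e-9)
      else expect_lt(max(abs(q - q[1])) / abs(q[1]), 1e-6)
    }
  }
})

test_that("reduction by conservation laws preserves trajectories", {
  sysf <- self_activation_system(kb = 2, ku = 1, kp = 3, kd = 0.2,
                                 total = 1, reduce = FALSE)
  laws <- conservation_laws(sysf)
  red <- reduce_by_conservation(sysf, laws, eliminate = "A_a0")
  expect_setequal(red$state_species, c("A_a1", "A"))
  init_full <- c(A_a0 = 0.6, A_a1 = 0.4, A = 1)
  lawc <- laws
  lawc[[1]]$constant <- 1
  red <- reduce_by_conservation(sysf, lawc, eliminate = "A_a0")
  tf <- integrate_odes(sysf, init = init_full, times = seq(0, 20, 0.5))
  tr <- integrate_odes(red, init = init_full[c("A_a1", "A")],
                       times = seq(0, 20, 0.5))
  expect_equal(tf[, "A"], tr[, "A"], tolerance = 1e-6)
  expect_equal(tf[, "A_a1"], tr[, "A_a1"], tolerance = 1e-6)
  # lifting reconstructs the eliminated species
  lifted <- red$lift(c(A_a1 = 0.4, A = 1))
  expect_equal(unname(lifted["A_a0"]), 0.6)
  # zero-coefficient elimination is rejected
  expect_error(reduce_by_conservation(sysf, lawc, eliminate = "A"),
               "zero coefficient")
})

test_that("a law with constant zero pins the eliminated species at zero", {
  sysf <- self_activation_system(total = 1, reduce = FALSE)
  laws <- conservation_laws(sysf)
  laws[[1]]$constant <- 0
  red <- reduce_by_conservation(sysf, laws, eliminate = "A_a0")
  tr <- integrate_odes(red, init = c(A_a1 = 0, A = 0), times = c(0, 5, 10))
  lifted <- t(apply(tr[, c("A_a1", "A")], 1, function(z) red$lift(z)))
  expect_true(all(abs(lifted[, "A_a0"]) < 1e-12))
})

test_that("equation pretty-printer writes the two-regulator rate equations", {
  sys <- build_odes(compile_reactions(two_regulator_graph(), "per_site"))
  eqs <- ode_equations(sys)
  names(eqs) <- sys$state_species
  expect_match(eqs["B"], "kp_B_a1_r0\\*B_a1_r0")
  expect_match(eqs["B"], "kp_B_a1_r1\\*B_a1_r1")
  expect_match(eqs["B"], "- kd_B\\*B")
  expect_match(eqs["B_a0_r0"], "- kb_B_A\\*B_a0_r0\\*A")
  expect_match(eqs["B_a0_r0"], "ku_B_A\\*B_a1_r0")
})

test_that("integer kernel handles standard cases exactly", {
  # kernel of [1 1 -1] is 2-dimensional
  K <- integer_kernel(matrix(c(1, 1, -1), nrow = 1))
  expect_equal(ncol(K), 2)
  expect_true(all(matrix(c(1, 1, -1), nrow = 1) %*% K == 0))
  # full-rank: trivial kernel
  expect_equal(ncol(integer_kernel(diag(3))), 0)
  # rational pivots are cleared to coprime integers
  A <- matrix(c(2, 0, 3, 1), 2, 2, byrow = TRUE)
  expect_equal(ncol(integer_kernel(A)), 0)
  A2 <- matrix(c(2, 4, 3, 6), 2, 2, byrow = TRUE)
  K2 <- integer_kernel(A2)
  expect_equal(abs(as.vector(K2)), c(2, 1))
})
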