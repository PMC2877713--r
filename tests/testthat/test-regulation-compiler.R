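test_that("operon state enumeration matches the two semantics", {
  # one activator + one repressor: 4 combinatorial states vs 3 competitive
  s4 <- enumerate_operon_states("B", "A", "R", "per_site")
  expect_equal(nrow(s4), 4)
  expect_equal(s4$name, c("B_a0_r0", "B_a0_r1", "B_a1_r0", "B_a1_r1"))
  s3 <- enumerate_operon_states("B", "A", "R", "one_site")
  expect_equal(s3$name, c("B_free", "B_A", "B_R"))
  # at most one site occupied under one_site
  occ <- mapply(function(a, r) sum(as.integer(strsplit(a, ",")[[1]])) +
                  sum(as.integer(strsplit(r, ",")[[1]])), s3$amask, s3$rmask)
  expect_true(all(occ <= 1))
  # 1 activator + 2 repressors: 8 states (brute-force count 2^3)
  s8 <- enumerate_operon_states("KNI", "BCD", c("HB", "TLL"), "per_site")
  expect_equal(nrow(s8), 2^3)
  expect_equal(anyDuplicated(s8$name), 0)
  # no regulators: single free state under both semantics
  expect_equal(enumerate_operon_states("X", character(0), character(0),
                                       "per_site")$name, "X_free")
  expect_equal(enumerate_operon_states("X", character(0), character(0),
                                       "one_site")$name, "X_free")
})

test_that("per-site compilation of the two-regulator gene has the canonical structure", {
  net <- compile_reactions(two_regulator_graph(), "per_site")
  # 4 operon states + protein B as state species; A, R constant
  expect_setequal(net$constant_species, c("A", "R"))
  expect_equal(length(net$species), 7)
  txt <- vapply(net$reactions, format_reaction, "")
  # A binds/unbinds its site in both repressor contexts, R likewise
  expect_true("A + B_a0_r0 -kb_B_A-> B_a1_r0" %in% txt)
  expect_true("A + B_a0_r1 -kb_B_A-> B_a1_r1" %in% txt)
  expect_true("B_a1_r0 -ku_B_A-> A + B_a0_r0" %in% txt)
  expect_true("B_a0_r0 + R -kb_B_R-> B_a0_r1" %in% txt)
  expect_true("B_a1_r1 -ku_B_R-> B_a1_r0 + R" %in% txt)
  # production from every activator-bound state, each with its own rate
  expect_true("B_a1_r0 -kp_B_a1_r0-> B + B_a1_r0" %in% txt)
  expect_true("B_a1_r1 -kp_B_a1_r1-> B + B_a1_r1" %in% txt)
  # no production from activator-free states
  expect_false(any(grepl("^B_a0", txt) & grepl("-kp", txt)))
  # degradation of the protein only
  expect_true("B -kd_B-> 0" %in% txt)
  expect_equal(sum(grepl("-kd", txt)), 1)
  expect_equal(length(net$reactions), 11)
})

test_that("one-site compilation gives competitive binding and single production", {
  net <- compile_reactions(two_regulator_graph(), "one_site")
  txt <- vapply(net$reactions, format_reaction, "")
  expect_setequal(txt, c(
    "A + B_free -kb_B_A-> B_A", "B_A -ku_B_A-> A + B_free",
    "B_free + R -kb_B_R-> B_R", "B_R -ku_B_R-> B_free + R",
    "B_A -kp_B_A-> B + B_A", "B -kd_B-> 0"))
})

test_that("unregulated genes produce basally and degrade", {
  g <- double_graph(annotations = list(X = list()))
  net <- compile_reactions(g, "per_site")
  txt <- vapply(net$reactions, format_reaction, "")
  expect_setequal(txt, c("X_free -kp_X_basal-> X + X_free", "X -kd_X-> 0"))
  # repressed-only gene: basal production from the repressor-free state
  g2 <- double_graph(repressions = list(c("R", "Y")))
  net2 <- compile_reactions(g2, "per_site")
  txt2 <- vapply(net2$reactions, format_reaction, "")
  expect_true("Y_r0 -kp_Y_basal-> Y + Y_r0" %in% txt2)
  expect_false(any(grepl("Y_r1 -kp", txt2)))
})

test_that("all reactions are at most bimolecular and operon states are catalytic in production", {
  for (seed in 1:12) {
    net <- random_network(seed)
    for (r in net$reactions) {
      expect_lte(sum(r$reactants), 2)
      if (grepl("^kp_", r$rate_name)) {
        # catalyst: state appears with equal stoichiometry on both sides
        st <- names(r$reactants)[1]
        expect_equal(r$reactants[[st]], r$products[[st]])
      }
    }
  }
})

test_that("compilation is deterministic: same graph gives identical parameter sequences", {
  a <- compile_reactions(gapgene_graph(), "per_site")
  b <- compile_reactions(gapgene_graph(), "per_site")
  expect_identical(names(a$parameters), names(b$parameters))
  expect_identical(vapply(a$reactions, format_reaction, ""),
                   vapply(b$reactions, format_reaction, ""))
})

test_that("rate defaults and specific overrides are applied", {
  net <- compile_reactions(two_regulator_graph(), "per_site",
                           rate_defaults = list(degradation = 0.5,
                                                kp_B_a1_r1 = 0.01))
  expect_equal(unname(net$parameters["kd_B"]), 0.5)
  expect_equal(unname(net$parameters["kp_B_a1_r1"]), 0.01)
  expect_equal(unname(net$parameters["kp_B_a1_r0"]), 1)
  expect_error(compile_reactions(two_regulator_graph(), "per_site",
                                 rate_defaults = list(kd_B = 0)), "positive")
  net2 <- set_parameters(net, c(kb_B_A = 3))
  expect_equal(unname(net2$parameters["kb_B_A"]), 3)
  expect_error(set_parameters(net, c(nope = 1)), "unknown")
})
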