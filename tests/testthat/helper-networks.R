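# Shared fixtures: canonical networks, an independent pure-R mass-action
# oracle, closed forms derived by hand for the reference mechanisms.

# A activates B, R represses B (the canonical two-regulator gene)
two_regulator_graph <- function() {
  double_graph(activations = list(c("A", "B")),
               repressions = list(c("R", "B")))
}

# the gap-gene wiring: BCD -> HB, BCD -> KNI, HB -| KNI, KNI -| HB, TLL -| KNI
# (mRNA nodes included, annotation-only)
fig_gapgene_graph <- function() gapgene_graph()

# activator A, repressors R1/R2 on one protein C (spatial spike scenario)
spike_graph <- function() {
  double_graph(activations = list(c("A", "C")),
               repressions = list(c("R1", "C"), c("R2", "C")))
}

# flanking repressor bumps + flat activator on [0,1]
spike_inputs <- function(n = 101) {
  x <- seq(0, 1, length.out = n)
  spatial_field(x, list(
    A = rep(1, n),
    R1 = eval_profile_spec(list(family = "gaussian_bump", amplitude = 5,
                                center = 0.1, width = 0.18), x),
    R2 = eval_profile_spec(list(family = "gaussian_bump", amplitude = 5,
                                center = 0.9, width = 0.18), x)))
}

# independent mass-action oracle: accumulate per-reaction fluxes in plain R,
# never touching the package's compiled rhs path
oracle_rhs <- function(network, x) {
  const <- network$constant_species
  dx <- setNames(numeric(length(network$species)), network$species)
  for (r in network$reactions) {
    flux <- r$rate_value
    for (sp in names(r$reactants)) flux <- flux * x[[sp]]^r$reactants[[sp]]
    for (sp in names(r$reactants)) dx[sp] <- dx[sp] - r$reactants[[sp]] * flux
    for (sp in names(r$products)) dx[sp] <- dx[sp] + r$products[[sp]] * flux
  }
  dx[const] <- 0
  dx
}

# closed-form protein trajectory of the reduced production mechanism
# G -kp-> G + P, P -kd-> 0:  P(t) = (kp G0 / kd)(1 - e^{-kd t}) + P0 e^{-kd t}
reduced_mechanism_solution <- function(t, kp, kd, G0, P0 = 0) {
  kp * G0 / kd * (1 - exp(-kd * t)) + P0 * exp(-kd * t)
}

# hand-derived critical gene total of the self-activation model: the trivial
# branch's Jacobian [[-ku, kb C], [ku + kp, -kb C - kd]] has determinant
# ku kd - kb kp C, which vanishes at
self_activation_C_star <- function(kb, ku, kp, kd) ku * kd / (kb * kp)

# random small compiled network for property tests
random_network <- function(seed, semantics = NULL) {
  set.seed(seed)
  n_genes <- sample(1:2, 1)
  n_inputs <- sample(0:2, 1)
  genes <- paste0("G", seq_len(n_genes))
  inputs <- if (n_inputs) paste0("U", seq_len(n_inputs)) else character(0)
  sources <- c(genes, inputs)
  acts <- list(); reps <- list()
  for (g in genes) {
    for (s in sources) {
      u <- runif(1)
      if (u < 0.35) acts[[length(acts) + 1]] <- c(s, g)
      else if (u < 0.6) reps[[length(reps) + 1]] <- c(s, g)
    }
  }
  ann <- setNames(lapply(genes, function(g) list(initial = runif(1, 0, 0.5))),
                  genes)
  g <- double_graph(vertices = c(genes, inputs), activations = acts,
                    repressions = reps, annotations = ann)
  if (is.null(semantics))
    semantics <- sample(c("per_site", "one_site"), 1)
  rd <- list(binding = runif(1, 0.5, 2), unbinding = runif(1, 0.5, 2),
             production = runif(1, 0.5, 2), degradation = runif(1, 0.05, 0.5))
  compile_reactions(g, semantics, rate_defaults = rd,
                    gene_totals = setNames(runif(n_genes, 0.5, 2), genes))
}

# random strictly positive state for oracle comparisons
random_state <- function(network, seed) {
  set.seed(seed)
  setNames(runif(length(network$species), 0, 2), network$species)
}
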