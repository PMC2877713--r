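# Compile a double graph into a mass-action reaction network under the
# operon model: binding sites become explicit binding/unbinding reactions,
# activator-bound operon states transcribe catalytically, proteins degrade.

.state_name <- function(gene, amask, rmask) {
  parts <- character(0)
  if (length(amask)) parts <- c(parts, paste0("a", paste(amask, collapse = "")))
  if (length(rmask)) parts <- c(parts, paste0("r", paste(rmask, collapse = "")))
  if (!length(parts)) return(paste0(gene, "_free"))
  paste(c(gene, parts), collapse = "_")
}

#' Enumerate the operon states of a gene
#'
#' Under `per_site` semantics every regulator has its own binding site and all
#' `2^(a+r)` occupancy masks are enumerated in lexicographic order (rightmost
#' bit fastest; activator bits precede repressor bits). Under `one_site`
#' semantics all regulators compete for a single site, giving the free state
#' plus one singly-bound state per regulator (`a + r + 1` states).
#'
#' @param gene gene name.
#' @param activators,repressors regulator names in canonical (edge) order.
#' @param semantics `"per_site"` or `"one_site"`.
#' @return data frame with columns `name`, `amask`, `rmask` (masks are
#'   comma-separated bit strings; under `one_site` at most one bit is set).
#' @examples
#' enumerate_operon_states("B", "A", "R", "per_site")   # 4 states
#' enumerate_operon_states("B", "A", "R", "one_site")   # 3 states
#' @export
enumerate_operon_states <- function(gene, activators, repressors,
                                    semantics = c("per_site", "one_site")) {
  semantics <- match.arg(semantics)
  na <- length(activators); nr <- length(repressors)
  states <- list()
  if (semantics == "per_site") {
    n <- na + nr
    for (i in seq_len(2^n) - 1L) {
      bits <- as.integer(intToBits(i))[seq_len(max(n, 1))]
      if (n == 0) bits <- integer(0) else bits <- rev(bits[seq_len(n)])
      amask <- if (na) bits[seq_len(na)] else integer(0)
      rmask <- if (nr) bits[na + seq_len(nr)] else integer(0)
      states[[length(states) + 1L]] <-
        list(name = .state_name(gene, amask, rmask), amask = amask, rmask = rmask)
      if (n == 0) break
    }
  } else {
    zero_a <- integer(na); zero_r <- integer(nr)
    states[[1]] <- list(name = if (na + nr > 0) paste0(gene, "_free")
                               else .state_name(gene, zero_a, zero_r),
                        amask = zero_a, rmask = zero_r)
    for (i in seq_len(na)) {
      m <- zero_a; m[i] <- 1L
      states[[length(states) + 1L]] <-
        list(name = paste0(gene, "_", activators[i]), amask = m, rmask = zero_r)
    }
    for (i in seq_len(nr)) {
      m <- zero_r; m[i] <- 1L
      states[[length(states) + 1L]] <-
        list(name = paste0(gene, "_", repressors[i]), amask = zero_a, rmask = m)
    }
  }
  data.frame(
    name = vapply(states, `[[`, "", "name"),
    amask = vapply(states, function(s) paste(s$amask, collapse = ","), ""),
    rmask = vapply(states, function(s) paste(s$rmask, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

.mask_bits <- function(s) if (nzchar(s)) as.integer(strsplit(s, ",")[[1]]) else integer(0)

.reaction <- function(reactants, products, rate_name, rate_value) {
  total <- sum(reactants)
  if (total > 2) stop("reaction '", rate_name, "' is more than bimolecular")
  list(reactants = reactants, products = products,
       rate_name = rate_name, rate_value = rate_value)
}

.named_count <- function(x) {
  if (length(x) == 0) return(setNames(integer(0), character(0)))
  tab <- table(x)
  setNames(as.integer(tab), names(tab))
}

#' Compile a double graph into a mass-action reaction network
#'
#' For every gene vertex (a vertex with incoming regulation edges, or an
#' isolated vertex) the compiler emits, per binding site (`per_site`) or for
#' the shared site (`one_site`), a reversible binding/unbinding reaction pair
#' between the free regulator protein and the operon state; a catalytic
#' transcription reaction `state -> state + protein` for every operon state
#' with at least one activator bound, each with its own production rate; and a
#' degradation reaction for the protein. Genes with no incoming activation
#' edges produce at a basal rate from their repressor-free state. Genes never
#' degrade (they are catalytic), so each gene's operon-state total is an exact
#' conservation law; regulators bound to DNA do not degrade while bound.
#' Vertices that only regulate (no incoming kinetic edge) are constant inputs
#' held fixed by the ODE stage. mRNA-annotated vertices and their translation
#' edges are excluded from the kinetics (their effect is folded into initial
#' conditions).
#'
#' Parameter names are deterministic: `kb_<gene>_<regulator>` /
#' `ku_<gene>_<regulator>` for binding/unbinding, `kp_<gene>_<state-tag>`
#' (`per_site`) or `kp_<gene>_<activator>` / `kp_<gene>_basal` (`one_site`)
#' for production, `kd_<protein>` for degradation.
#'
#' @param graph a `double_graph`.
#' @param semantics `"per_site"` (one binding site per regulator) or
#'   `"one_site"` (single competitive site).
#' @param rate_defaults optional named numeric/list. Keys `binding`,
#'   `unbinding`, `production`, `degradation` override the class defaults
#'   (1, 1, 1, 0.1, arbitrary units); any other key must be an exact generated
#'   parameter name and overrides that single rate.
#' @param gene_totals optional named numeric of total operon concentration per
#'   gene (default 1 for every gene); stored as the free-state initial value.
#' @return an object of class `reaction_network` with fields `species`,
#'   `reactions`, `parameters`, `constant_species`, `initial`, `genes`,
#'   `semantics`.
#' @examples
#' g <- double_graph(activations = list(c("A", "B")),
#'                   repressions = list(c("R", "B")))
#' net <- compile_reactions(g, "per_site")
#' print(net)
#' @export
compile_reactions <- function(graph, semantics = c("per_site", "one_site"),
                              rate_defaults = NULL, gene_totals = NULL) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(graph, "double_graph"))
  validate_double_graph(graph)

  defaults <- list(binding = 1, unbinding = 1, production = 1, degradation = 0.1)
  specific <- list()
  for (nm in names(rate_defaults)) {
    if (nm %in% names(defaults)) defaults[[nm]] <- as.numeric(rate_defaults[[nm]])
    else specific[[nm]] <- as.numeric(rate_defaults[[nm]])
  }

  roles <- vertex_roles(graph)
  genes <- names(roles)[roles == "gene"]
  inputs <- names(roles)[roles == "input"]

  reactions <- list()
  params <- numeric(0)
  add_param <- function(name, value) {
    if (name %in% names(params)) stop("duplicate parameter name: ", name)
    if (!is.null(specific[[name]])) value <- specific[[name]]
    if (value <= 0) stop("rate '", name, "' must be positive")
    params[[name]] <<- value
    name
  }
  add_reaction <- function(reactants, products, rate_name) {
    reactions[[length(reactions) + 1L]] <<-
      .reaction(.named_count(reactants), .named_count(products),
                rate_name, params[[rate_name]])
  }

  gene_info <- list()
  species <- character(0)

  for (g in genes) {
    regs <- regulators_of(graph, g, drop_mrna = TRUE)
    acts <- regs$activators; reps <- regs$repressors
    states <- enumerate_operon_states(g, acts, reps, semantics)
    gene_info[[g]] <- list(activators = acts, repressors = reps, states = states)
    species <- c(species, states$name)

    sites <- c(acts, reps)
    site_role <- c(rep("a", length(acts)), rep("r", length(reps)))

    # binding/unbinding, one reversible pair of rate names per gene+site
    for (si in seq_along(sites)) {
      reg <- sites[si]
      kb <- add_param(paste0("kb_", g, "_", reg), defaults$binding)
      ku <- add_param(paste0("ku_", g, "_", reg), defaults$unbinding)
      for (k in seq_len(nrow(states))) {
        am <- .mask_bits(states$amask[k]); rm <- .mask_bits(states$rmask[k])
        if (semantics == "one_site" && sum(am) + sum(rm) > 0) next  # only free state binds
        bit <- if (site_role[si] == "a") am[si] else rm[si - length(acts)]
        if (bit != 0) next
        am2 <- am; rm2 <- rm
        if (site_role[si] == "a") am2[si] <- 1L else rm2[si - length(acts)] <- 1L
        bound <- states$name[states$amask == paste(am2, collapse = ",") &
                             states$rmask == paste(rm2, collapse = ",")]
        add_reaction(c(reg, states$name[k]), bound, kb)
        add_reaction(bound, c(reg, states$name[k]), ku)
      }
    }

    # transcription: every activator-bound state produces with its own rate;
    # genes without activators produce basally from the repressor-free state
    for (k in seq_len(nrow(states))) {
      am <- .mask_bits(states$amask[k]); rm <- .mask_bits(states$rmask[k])
      fires <- if (length(acts) > 0) sum(am) >= 1 else sum(rm) == 0
      if (!fires) next
      tag <- if (length(acts) == 0) "basal"
             else sub(paste0("^", g, "_"), "", states$name[k])
      kp <- add_param(paste0("kp_", g, "_", tag), defaults$production)
      add_reaction(states$name[k], c(states$name[k], g), kp)
    }

    # protein degradation (free protein only; genes are catalytic)
    kd <- add_param(paste0("kd_", g), defaults$degradation)
    add_reaction(g, character(0), kd)
  }

  species <- c(species, genes, inputs)

  # initial concentrations: free operon state carries the gene total,
  # proteins start at their annotated initial (default 0), constant inputs at
  # their annotated initial (default 1)
  initial <- setNames(numeric(length(species)), species)
  ann <- graph$annotations
  for (g in genes) {
    tot <- if (!is.null(gene_totals) && g %in% names(gene_totals))
      gene_totals[[g]] else 1
    free <- gene_info[[g]]$states$name[1]
    initial[free] <- tot
    if (!is.na(ann[g, "initial"])) initial[g] <- ann[g, "initial"]
  }
  for (v in inputs)
    initial[v] <- if (!is.na(ann[v, "initial"])) ann[v, "initial"] else 1

  structure(list(species = species, reactions = reactions,
                 parameters = params, constant_species = inputs,
                 initial = initial, genes = gene_info,
                 semantics = semantics, graph = graph),
            class = "reaction_network")
}

#' Replace rate values in a compiled network
#'
#' @param network a `reaction_network`.
#' @param values named numeric of parameter values (subset of the network's
#'   parameter names; all positive).
#' @return the network with updated parameters.
#' @export
set_parameters <- function(network, values) {
  stopifnot(inherits(network, "reaction_network"))
  unknown <- setdiff(names(values), names(network$parameters))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  if (any(values <= 0)) stop("rate values must be positive")
  network$parameters[names(values)] <- values
  network$reactions <- lapply(network$reactions, function(r) {
    r$rate_value <- network$parameters[[r$rate_name]]
    r
  })
  network
}

.side_string <- function(side) {
  if (length(side) == 0 || sum(side) == 0) return("0")
  paste(ifelse(side > 1, paste0(side, " ", names(side)), names(side)),
        collapse = " + ")
}

#' One-line human-readable form of a reaction
#' @param r a reaction (element of `network$reactions`).
#' @return character scalar like `"A + B_a0_r0 -kb_B_A-> B_a1_r0"`.
#' @export
format_reaction <- function(r) {
  sprintf("%s -%s-> %s", .side_string(r$reactants), r$rate_name,
          .side_string(r$products))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction network (%s): %d species (%d constant), %d reactions, %d parameters\n",
              x$semantics, length(x$species), length(x$constant_species),
              length(x$reactions), length(x$parameters)))
  for (r in x$reactions) cat(" ", format_reaction(r), "\n")
  invisible(x)
}
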