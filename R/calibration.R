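# Calibration of model parameters to spatial profiles: chi-square objective
# plus a generational genetic algorithm on log10-transformed parameters.

#' Chi-square agreement between a predicted and an observed profile
#'
#' `chi2 = sum over masked points of ((pred - obs) / sd)^2`; the reduced
#' (penalized) chi-square divides by `n_masked - n_params` when that is
#' positive, and is `NA` (flagged) otherwise.
#'
#' @param predicted,observed `spatial_profile`s on the same grid; `observed`
#'   must carry positive `sd` on the masked points.
#' @param mask optional logical vector (or x-range `c(lo, hi)`) selecting the
#'   points entering the objective; default all.
#' @param n_params number of fitted parameters, for the reduced statistic.
#' @return list with `chi2`, `reduced`, `n` (masked point count).
#' @export
chi_square <- function(predicted, observed, mask = NULL, n_params = 0) {
  stopifnot(inherits(predicted, "spatial_profile"),
            inherits(observed, "spatial_profile"))
  if (length(predicted$positions) != length(observed$positions) ||
      max(abs(predicted$positions - observed$positions)) > 1e-12)
    stop("profiles are not on a shared grid")
  if (is.null(observed$sd)) stop("observed profile has no sd")
  m <- .resolve_mask(mask, observed$positions)
  if (!any(m)) stop("mask selects no points")
  sd <- observed$sd[m]
  if (any(sd <= 0)) stop("sd must be positive on masked points")
  chi2 <- sum(((predicted$values[m] - observed$values[m]) / sd)^2)
  n <- sum(m)
  reduced <- if (n - n_params > 0) chi2 / (n - n_params) else NA_real_
  list(chi2 = chi2, reduced = reduced, n = n)
}

.resolve_mask <- function(mask, positions) {
  if (is.null(mask)) return(rep(TRUE, length(positions)))
  if (is.logical(mask)) { stopifnot(length(mask) == length(positions)); return(mask) }
  if (is.numeric(mask) && length(mask) == 2)
    return(positions >= mask[1] & positions <= mask[2])
  stop("mask must be NULL, a logical vector, or an x-range c(lo, hi)")
}

#' Define a fit problem
#'
#' @param simulate function `params -> spatial_field` predicting the fitted
#'   species on the data grid (`params` is a named numeric on the linear
#'   scale).
#' @param data `spatial_field` with `sd` for every fitted species.
#' @param bounds 2-row matrix (`lower`, `upper`) with one named column per
#'   fitted parameter; finite and positive (the GA works in log10 space
#'   between them).
#' @param masks named list (species -> mask as in [chi_square()]); species
#'   absent from `data` are ignored, and each mask must keep at least one
#'   point.
#' @param species character vector of fitted species (default: all species in
#'   `data`).
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(simulate, data, bounds, masks = list(),
                        species = names(data$values)) {
  stopifnot(is.function(simulate), inherits(data, "spatial_field"),
            is.matrix(bounds), nrow(bounds) == 2,
            !is.null(colnames(bounds)))
  if (any(!is.finite(bounds)) || any(bounds <= 0))
    stop("bounds must be finite and positive")
  if (any(bounds[2, ] <= bounds[1, ])) stop("upper bounds must exceed lower")
  for (sp in species) {
    if (is.null(data$sd[[sp]])) stop("data for '", sp, "' has no sd")
    m <- .resolve_mask(masks[[sp]], data$positions)
    if (!any(m)) stop("mask for '", sp, "' selects no points")
  }
  structure(list(simulate = simulate, data = data, bounds = bounds,
                 masks = masks, species = species),
            class = "fit_problem")
}

#' Objective value of a parameter vector
#'
#' Sum of the per-species chi-squares on the masked points; integration or
#' simulation failures score `Inf`.
#'
#' @param problem a `fit_problem`.
#' @param params named numeric on the linear scale.
#' @return non-negative numeric (possibly `Inf`).
#' @export
fit_objective <- function(problem, params) {
  pred <- tryCatch(problem$simulate(params), error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  total <- 0
  for (sp in problem$species) {
    cs <- tryCatch(
      chi_square(field_profile(pred, sp), field_profile(problem$data, sp),
                 mask = problem$masks[[sp]]),
      error = function(e) NULL)
    if (is.null(cs) || !is.finite(cs$chi2)) return(Inf)
    total <- total + cs$chi2
  }
  total
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 200, 500 generations, tournament size 3, crossover
#' rate 0.7 (uniform/blend in log10 space), per-gene mutation rate 0.25 with
#' Gaussian sigma 0.3 (log10 units), 2 elites. `stall_generations` stops the
#' run early once the best objective has not improved for that many
#' generations (`Inf` disables).
#'
#' @param pop_size,generations,tournament,elites positive integers.
#' @param crossover_rate,mutation_rate rates in `[0, 1]`.
#' @param crossover_alpha BLX-alpha blend width: children are sampled
#'   uniformly in the per-gene parent interval extended by this fraction of
#'   its length on both sides.
#' @param mutation_sigma Gaussian mutation scale in log10 units.
#' @param mutation_decay geometric per-generation decay of the mutation scale
#'   (1 = constant; values slightly below 1 anneal the search from coarse to
#'   fine).
#' @param stall_generations early-stop patience.
#' @param seed RNG seed (the whole run is deterministic given the seed).
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, generations = 500, tournament = 3,
                      crossover_rate = 0.7, crossover_alpha = 0.5,
                      mutation_rate = 0.25,
                      mutation_sigma = 0.3, mutation_decay = 1, elites = 2,
                      stall_generations = Inf, seed = 1L) {
  stopifnot(pop_size > 1, generations >= 1, tournament >= 1, elites >= 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, mutation_sigma > 0,
            mutation_decay > 0, mutation_decay <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 crossover_rate = crossover_rate,
                 crossover_alpha = crossover_alpha,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 mutation_decay = mutation_decay,
                 elites = as.integer(elites),
                 stall_generations = stall_generations,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Minimize a fit objective with a genetic algorithm
#'
#' Generational GA on log10-transformed parameters within the bounds:
#' tournament selection, blend (arithmetic) crossover, Gaussian mutation with
#' reflection at the bounds, elitism. Individuals whose simulation fails
#' score `+Inf`; if the entire initial population is invalid the run aborts
#' with a diagnostic. Deterministic under the config seed. The best-so-far
#' objective is non-increasing by construction (elitism), and the result is
#' never worse than the best member of the initial population.
#'
#' @param problem a `fit_problem`.
#' @param config a `ga_config`.
#' @param verbose print per-generation progress to stderr.
#' @return object of class `fit_result`: `parameters` (best-ever, linear
#'   scale), `objective`, `per_species` (chi2 and reduced chi2 per fitted
#'   species at the optimum), `trace` (data frame of best/mean objective per
#'   generation), `evaluations`.
#' @export
ga_minimize <- function(problem, config = ga_config(), verbose = FALSE) {
  stopifnot(inherits(problem, "fit_problem"), inherits(config, "ga_config"))
  lb <- log10(problem$bounds[1, ]); ub <- log10(problem$bounds[2, ])
  pnames <- colnames(problem$bounds)
  D <- length(pnames)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  evals <- 0L
  score <- function(z) {
    evals <<- evals + 1L
    fit_objective(problem, setNames(10^z, pnames))
  }
  clampz <- function(z) {
    # reflect at bounds, then clamp (reflection preserves diversity at edges)
    z <- ifelse(z < lb, 2 * lb - z, z)
    z <- ifelse(z > ub, 2 * ub - z, z)
    pmin(pmax(z, lb), ub)
  }

  # Latin-hypercube initial population for even coverage of the log box
  lh <- lhs::randomLHS(config$pop_size, D)
  pop <- sweep(sweep(lh, 2, ub - lb, `*`), 2, lb, `+`)
  fitness <- apply(pop, 1, score)
  if (all(!is.finite(fitness)))
    stop("all individuals of the initial population are invalid ",
         "(simulation failed everywhere); check bounds and model")

  best_i <- which.min(fitness)
  best_z <- pop[best_i, ]; best_f <- fitness[best_i]
  trace <- data.frame(generation = 0L, best = best_f,
                      mean = mean(fitness[is.finite(fitness)]))
  stall <- 0L
  sigma <- config$mutation_sigma
  for (gen in seq_len(config$generations)) {
    if (gen > 1) sigma <- sigma * config$mutation_decay
    ord <- order(fitness)
    newpop <- matrix(0, config$pop_size, D)
    nelite <- min(config$elites, config$pop_size)
    if (nelite > 0) newpop[seq_len(nelite), ] <- pop[ord[seq_len(nelite)], , drop = FALSE]
    tournament <- function() {
      cand <- sample.int(config$pop_size, config$tournament, replace = TRUE)
      cand[which.min(fitness[cand])]
    }
    for (i in seq(nelite + 1, config$pop_size)) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      child <- if (runif(1) < config$crossover_rate) {
        # BLX-alpha blend: sample around and beyond the parent interval,
        # which lets the population track narrow curved valleys
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        d <- hi - lo
        runif(D, lo - config$crossover_alpha * d,
              hi + config$crossover_alpha * d)
      } else p1
      mut <- runif(D) < config$mutation_rate
      if (any(mut))
        child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma)
      newpop[i, ] <- clampz(child)
    }
    pop <- newpop
    fitness <- apply(pop, 1, score)
    gb <- which.min(fitness)
    if (fitness[gb] < best_f) {
      best_f <- fitness[gb]; best_z <- pop[gb, ]; stall <- 0L
    } else stall <- stall + 1L
    trace <- rbind(trace, data.frame(generation = gen, best = best_f,
                                     mean = mean(fitness[is.finite(fitness)])))
    if (verbose)
      message(sprintf("gen %d: best %.4g mean %.4g", gen, best_f,
                      mean(fitness[is.finite(fitness)])))
    if (stall >= config$stall_generations) break
  }

  best_params <- setNames(10^best_z, pnames)
  pred <- tryCatch(problem$simulate(best_params), error = function(e) NULL)
  per_species <- list()
  if (!is.null(pred)) for (sp in problem$species) {
    per_species[[sp]] <- chi_square(field_profile(pred, sp),
                                    field_profile(problem$data, sp),
                                    mask = problem$masks[[sp]],
                                    n_params = D)
  }
  structure(list(parameters = best_params, objective = best_f,
                 per_species = per_species, trace = trace,
                 evaluations = evals, config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit result: objective %.6g after %d evaluations (%d generations)\n",
              x$objective, x$evaluations, max(x$trace$generation)))
  for (sp in names(x$per_species)) {
    cs <- x$per_species[[sp]]
    cat(sprintf("  %s: chi2 = %.4g, reduced = %s (n = %d)\n", sp, cs$chi2,
                if (is.na(cs$reduced)) "undefined" else sprintf("%.4g", cs$reduced),
                cs$n))
  }
  invisible(x)
}
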