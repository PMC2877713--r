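# The Drosophila gap-gene cross-regulation model: BCD activates hb and kni
# transcription, HB and KNI mutually repress, TLL represses kni. BCD and TLL
# are constant spatial inputs; maternal hb/bcd mRNAs are annotation-only
# nodes whose effect is folded into the initial protein profiles. Compiled
# with one binding site per regulator, this gives 4 hb-operon states, 8
# kni-operon states and the two proteins: 14 state equations per position.

#' The gap-gene regulatory double graph
#'
#' Vertices: mRNAs `bcd`, `hb` (annotation-only, excluded from kinetics),
#' proteins/genes `BCD`, `HB`, `KNI`, `TLL`. Activations: `bcd -> BCD`,
#' `hb -> HB` (translation, annotation edges), `BCD -> HB`, `BCD -> KNI`.
#' Repressions: `HB -| KNI`, `KNI -| HB`, `TLL -| KNI`.
#'
#' @param include_mrna include the maternal mRNA nodes (default `TRUE`; they
#'   are flagged `is_mrna` so the compiler skips them either way).
#' @return a `double_graph`.
#' @export
gapgene_graph <- function(include_mrna = TRUE) {
  acts <- list(c("BCD", "HB"), c("BCD", "KNI"))
  ann <- list(BCD = list(constant_input = TRUE),
              TLL = list(constant_input = TRUE))
  if (include_mrna) {
    acts <- c(list(c("bcd", "BCD"), c("hb", "HB")), acts)
    ann$bcd <- list(is_mrna = TRUE)
    ann$hb <- list(is_mrna = TRUE)
  }
  double_graph(
    activations = acts,
    repressions = list(c("HB", "KNI"), c("KNI", "HB"), c("TLL", "KNI")),
    annotations = ann)
}

#' Build the 14-equation gap-gene model
#'
#' Compiles the gap-gene graph with per-regulator binding sites: the hb gene
#' carries one activator site (BCD) and one repressor site (KNI), so 4 operon
#' states; the kni gene carries one activator site (BCD) and two repressor
#' sites (HB, TLL), so 8 operon states. With the HB and KNI proteins the
#' state dimension is 14; BCD and TLL are constant inputs. Each gene total is
#' an exact conservation law (2 laws).
#'
#' @param parameters optional named numeric of rate values (names as
#'   generated by [compile_reactions()]; see
#'   [gapgene_default_parameters()]).
#' @param gene_totals named numeric `c(HB = ., KNI = .)` total operon
#'   concentration per gene (spatially uniform; default 1 each).
#' @return object of class `gapgene_model`: the compiled `network`, the
#'   `ode_system`, `parameters` and `gene_totals`.
#' @export
build_gapgene_model <- function(parameters = NULL,
                                gene_totals = c(HB = 1, KNI = 1)) {
  net <- compile_reactions(gapgene_graph(), "per_site",
                           gene_totals = gene_totals)
  if (!is.null(parameters)) net <- set_parameters(net, parameters)
  sys <- build_odes(net)
  if (length(sys$state_species) != 14)
    stop("internal consistency error: expected 14 state variables, got ",
         length(sys$state_species))
  laws <- conservation_laws(sys)
  if (length(laws) != 2)
    stop("internal consistency error: expected 2 conservation laws, got ",
         length(laws))
  structure(list(network = net, odes = sys,
                 parameters = net$parameters, gene_totals = gene_totals),
            class = "gapgene_model")
}

#' @export
print.gapgene_model <- function(x, ...) {
  cat("gap-gene cross-regulation model:",
      length(x$odes$state_species), "state variables,",
      length(x$parameters), "rate parameters\n")
  cat("  state:", paste(x$odes$state_species, collapse = ", "), "\n")
  cat("  constant inputs:", paste(x$odes$constant_species, collapse = ", "), "\n")
  invisible(x)
}

#' Names and default values of the gap-gene rate parameters
#'
#' @return named numeric vector of the compiled parameter defaults.
#' @export
gapgene_default_parameters <- function() {
  compile_reactions(gapgene_graph(), "per_site")$parameters
}

#' Predict HB/KNI spatial profiles at a finite time
#'
#' Per-position integration of the 14-equation system from pre-transcription
#' initial conditions (all gene copies in the free operon state at the gene
#' total, KNI = 0, HB = the maternal HB profile) to time `T`. The result is
#' deliberately an out-of-equilibrium pattern: `T` is a model parameter, not
#' a relaxation time.
#'
#' @param model a `gapgene_model`.
#' @param inputs `spatial_field` with profiles `BCD`, `TLL` (constant
#'   regulators) and optionally `HB_maternal` (initial HB; default 0).
#' @param T integration time (> 0; arbitrary units).
#' @param ... passed to [simulate_field()].
#' @return `spatial_field` with all 14 state species; extract `HB`/`KNI`
#'   with [field_profile()].
#' @export
predict_profiles <- function(model, inputs, T, ...) {
  stopifnot(inherits(model, "gapgene_model"), T >= 0)
  init <- NULL
  if ("HB_maternal" %in% names(inputs$values))
    init <- spatial_field(inputs$positions,
                          list(HB = inputs$values[["HB_maternal"]]))
  reg <- spatial_field(inputs$positions,
                       list(BCD = inputs$values[["BCD"]],
                            TLL = inputs$values[["TLL"]]))
  if (T == 0) {
    sp <- model$odes$state_species
    y0 <- setNames(as.list(rep(0, length(sp))), sp)
    vals <- lapply(sp, function(s) rep(model$odes$initial[[s]],
                                       length(inputs$positions)))
    names(vals) <- sp
    for (g in names(model$gene_totals)) {
      free <- model$network$genes[[g]]$states$name[1]
      vals[[free]] <- rep(model$gene_totals[[g]], length(inputs$positions))
    }
    if (!is.null(init)) vals$HB <- init$values$HB
    return(spatial_field(inputs$positions, vals))
  }
  simulate_field(model$odes, reg, t_final = T, initial = init,
                 gene_totals = model$gene_totals, ...)
}
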