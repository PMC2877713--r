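# Synthetic anterior-posterior profiles emulating quantified segmentation
# gradients: an exponential anterior-high BCD gradient, a sigmoidal maternal
# HB domain, a posterior TLL bump, plus an additive Gaussian noise model with
# concentration-dependent sd. These stand in for database profiles so the
# whole pipeline is testable offline; files derived from them are synthetic.

.profile_families <- list(
  exponential = function(x, p) p$amplitude * exp(-x / p$decay),
  sigmoid = function(x, p) p$amplitude / (1 + exp((x - p$center) / p$width)),
  gaussian_bump = function(x, p) p$amplitude * exp(-((x - p$center) / p$width)^2 / 2)
)

#' Evaluate a parametric profile family
#'
#' Families: `exponential` (`amplitude`, `decay`), `sigmoid` (`amplitude`,
#' `center`, `width`; anterior-high), `gaussian_bump` (`amplitude`, `center`,
#' `width`), and `sum` (element `parts`: list of specs added together). All
#' shape parameters are dimensionless on `x` in `[0, 1]`; amplitudes are in
#' arbitrary concentration units and must be non-negative, widths positive.
#'
#' @param spec list with `family` and the family's shape parameters.
#' @param x positions.
#' @return numeric vector of non-negative values.
#' @export
eval_profile_spec <- function(spec, x) {
  fam <- spec$family
  if (identical(fam, "sum"))
    return(Reduce(`+`, lapply(spec$parts, eval_profile_spec, x = x)))
  f <- .profile_families[[fam]]
  if (is.null(f)) stop("unknown profile family: ", fam)
  if (is.null(spec$amplitude) || spec$amplitude < 0)
    stop("profile amplitude must be non-negative")
  if (!is.null(spec$width) && spec$width <= 0) stop("width must be positive")
  if (!is.null(spec$decay) && spec$decay <= 0) stop("decay must be positive")
  f(x, spec)
}

#' Default input-profile specifications
#'
#' BCD: exponential decay from the anterior pole (decay length 0.2 of embryo
#' length). Maternal HB: anterior-high sigmoid with mid-point 0.45 and
#' steepness width 0.05. TLL: posterior Gaussian bump centred at 0.85 with
#' width 0.05, plus a small anterior bump. Amplitudes 1 (arbitrary units).
#'
#' @return named list of profile specs for `BCD`, `HB_maternal`, `TLL`.
#' @export
default_input_specs <- function() {
  list(
    BCD = list(family = "exponential", amplitude = 1, decay = 0.2),
    HB_maternal = list(family = "sigmoid", amplitude = 1, center = 0.45,
                       width = 0.05),
    TLL = list(family = "sum", parts = list(
      list(family = "gaussian_bump", amplitude = 1, center = 0.85, width = 0.05),
      list(family = "gaussian_bump", amplitude = 0.15, center = 0.02,
           width = 0.03)))
  )
}

.apply_noise <- function(values, noise, n) {
  sd <- noise[["a"]] + noise[["b"]] * values
  list(values = pmax(values + rnorm(n, 0, sd), 0), sd = sd)
}

#' Generate synthetic regulator input profiles
#'
#' Evaluates the input specs on the grid and optionally adds Gaussian noise
#' with sd `a + b * value` (clipped at zero). Deterministic under `seed`:
#' the same seed reproduces bit-identical fields; different seeds share the
#' same noise-free means.
#'
#' @param grid positions (default 100 points on `[0, 1]`).
#' @param specs profile specs (default [default_input_specs()]).
#' @param noise `NULL` for noise-free, or `c(a = ., b = .)`.
#' @param seed RNG seed used when `noise` is given.
#' @return `spatial_field` with `BCD`, `HB_maternal`, `TLL` (and sd when
#'   noisy).
#' @export
generate_inputs <- function(grid = seq(0, 1, length.out = 100),
                            specs = default_input_specs(), noise = NULL,
                            seed = 1L) {
  vals <- lapply(specs, eval_profile_spec, x = grid)
  sds <- list()
  if (!is.null(noise)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    for (nm in names(vals)) {
      z <- .apply_noise(vals[[nm]], noise, length(grid))
      vals[[nm]] <- z$values
      sds[[nm]] <- z$sd
    }
  }
  spatial_field(grid, vals, sd = sds)
}

#' Ground-truth parameters for the synthetic gap-gene study
#'
#' A documented parameter set under which the model reproduces the
#' qualitative gap-gene pattern on the default inputs: an anterior HB domain
#' and a single posterior KNI stripe, with no transport. The rates sit in a
#' moderate-binding regime (dissociation constants of order the mid-embryo
#' input levels) so operon occupancies respond smoothly to the gradients;
#' HB/TLL repression of kni carves the stripe, and production from
#' repressor-bound states is weak.
#'
#' @return named numeric parameter vector (rates, arbitrary units) with
#'   attributes `gene_totals` and `T` (integration time).
#' @export
gapgene_truth_parameters <- function() {
  p <- gapgene_default_parameters()
  p[] <- 1
  # moderate-binding regime: occupancies respond smoothly to the gradients
  # (dissociation constants of order the mid-embryo input levels), which
  # keeps the study well conditioned for calibration
  p["kb_HB_BCD"] <- 5;  p["ku_HB_BCD"] <- 1
  p["kb_HB_KNI"] <- 8;  p["ku_HB_KNI"] <- 1
  p["kb_KNI_BCD"] <- 5; p["ku_KNI_BCD"] <- 1
  p["kb_KNI_HB"]  <- 8; p["ku_KNI_HB"] <- 1
  p["kb_KNI_TLL"] <- 8; p["ku_KNI_TLL"] <- 1
  # production fires from activator-bound states; repressor-bound states
  # transcribe only residually
  p["kp_HB_a1_r0"] <- 2;    p["kp_HB_a1_r1"] <- 0.05
  p["kp_KNI_a1_r00"] <- 2;  p["kp_KNI_a1_r01"] <- 0.05
  p["kp_KNI_a1_r10"] <- 0.05; p["kp_KNI_a1_r11"] <- 0.02
  p["kd_HB"] <- 0.1; p["kd_KNI"] <- 0.1
  attr(p, "gene_totals") <- c(HB = 1, KNI = 1)
  attr(p, "T") <- 6
  p
}

#' Generate a synthetic calibration data set
#'
#' Runs the gap-gene model at known parameters on the given inputs, adds
#' Gaussian noise with sd `a + b * value` to the HB and KNI outputs (clipped
#' at zero, sd recorded), and keeps the noise-free prediction as the truth
#' record for recovery tests.
#'
#' @param model a `gapgene_model` (built at the truth parameters).
#' @param inputs `spatial_field` of `BCD`, `TLL`, `HB_maternal`.
#' @param T integration time.
#' @param noise `c(a = ., b = .)` noise model (use `c(a = 0, b = 0)` for
#'   noise-free data).
#' @param seed RNG seed.
#' @return list with `observed` (`spatial_field` of HB, KNI with sd) and
#'   `truth` (list: `parameters`, `gene_totals`, `T`, `prediction`).
#' @export
generate_ground_truth <- function(model, inputs, T,
                                  noise = c(a = 0.02, b = 0.05), seed = 1L) {
  pred <- predict_profiles(model, inputs, T)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  vals <- list(); sds <- list()
  for (sp in c("HB", "KNI")) {
    z <- .apply_noise(pred$values[[sp]], noise, length(inputs$positions))
    vals[[sp]] <- z$values
    sds[[sp]] <- pmax(z$sd, 1e-8)
  }
  list(observed = spatial_field(inputs$positions, vals, sd = sds),
       truth = list(parameters = model$parameters,
                    gene_totals = model$gene_totals, T = T,
                    prediction = pred))
}
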