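#' Model variants
#'
#' The model space is built from a core drift-diffusion model by optionally
#' adding trial-to-trial drift-rate variability (feature V), linearly
#' collapsing decision thresholds (feature D), and by choosing how confidence
#' is read out from the accumulator: a direct readout of its final state, a
#' calibrated Bayesian readout (feature C), or a miscalibrated Bayesian
#' readout with a free time-penalty parameter (feature M).  The twelve
#' combinations are named `0`, `V`, `D`, `VD`, `C`, `DC`, `VC`, `VDC`, `M`,
#' `VM`, `DM`, `VDM`.  Variants `C` and `DC` duplicate the predictions of `0`
#' and `D` (a calibrated observer with no drift variability applies no time
#' penalty) and are retained only for random-effects model comparison.
#'
#' @param name Model name, e.g. `"M"`, `"VDM"`, `"0"`.
#' @return An object of class `ddm_spec` with fields `name`,
#'   `drift_variability`, `collapsing_bound` and `readout` (one of
#'   `"accumulator"`, `"bayes_calibrated"`, `"bayes_miscalibrated"`).
#' @export
#' @examples
#' model_spec("M")
#' model_spec("VD")$collapsing_bound
model_spec <- function(name) {
  name <- as.character(name)
  if (!name %in% ddm_model_names(include_duplicates = TRUE))
    stop("unknown model name: ", name)
  feats <- strsplit(gsub("0", "", name), "")[[1]]
  readout <- if ("M" %in% feats) "bayes_miscalibrated"
  else if ("C" %in% feats) "bayes_calibrated"
  else "accumulator"
  structure(list(name = name,
                 drift_variability = "V" %in% feats,
                 collapsing_bound = "D" %in% feats,
                 readout = readout),
            class = "ddm_spec")
}

#' Names of the model variants
#'
#' @param include_duplicates Include `C` and `DC`, which duplicate the
#'   predictions of `0` and `D` and are used only in random-effects
#'   comparison.
#' @return Character vector of model names.
#' @export
ddm_model_names <- function(include_duplicates = FALSE) {
  ten <- c("0", "V", "D", "VD", "VC", "VDC", "M", "VM", "DM", "VDM")
  if (include_duplicates) c(ten, "C", "DC") else ten
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat("DDM variant ", x$name, ": ",
      if (x$drift_variability) "drift-rate variability; " else "",
      if (x$collapsing_bound) "collapsing thresholds; " else "",
      x$readout, " readout\n", sep = "")
  invisible(x)
}

#' Parameter names of a model variant
#'
#' All variants share the eight core parameters (`sigma_acc`, `sigma_m`, `a`,
#' `I`, `lambda`, `d1`, `d2`, `d3`); V adds `sigma_phi`, D adds `b`, and the
#' miscalibrated readout adds `Gamma`, for 8--11 parameters in total.
#'
#' @param spec A `ddm_spec`.
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  nm <- c("sigma_acc", "sigma_m", "a", "I", "lambda", "d1", "d2", "d3")
  if (spec$drift_variability) nm <- c(nm, "sigma_phi")
  if (spec$collapsing_bound) nm <- c(nm, "b")
  if (spec$readout == "bayes_miscalibrated") nm <- c(nm, "Gamma")
  nm
}

#' Construct and validate a parameter set
#'
#' @param spec A `ddm_spec`.
#' @param sigma_acc Accumulator noise SD, dot.s per sqrt(second); > 0.
#' @param sigma_m Metacognitive noise SD in readout units; >= 0.
#' @param a Decision threshold height, dot.s; > 0.
#' @param I Duration of sensory and motor processing pipelines, seconds; >= 0.
#' @param lambda Confidence lapse probability in \[0, 1\].
#' @param d Numeric vector of three strictly increasing confidence-bin
#'   bounds, in readout units, or `NULL` when bounds are to be calibrated
#'   from simulated readouts (see [simulate_dataset()]).
#' @param sigma_phi Drift-rate scaling SD (required iff the variant has V).
#' @param b Threshold slope per second, >= 0 (required iff the variant has D).
#' @param Gamma Unconstrained miscalibration parameter, mapped to
#'   `gamma = plogis(Gamma)` (required iff the readout is miscalibrated).
#' @return An object of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(model_spec("M"), sigma_acc = 190, sigma_m = 30, a = 280,
#'            I = 0.3, lambda = 0.05, d = c(60, 110, 170), Gamma = 1.4)
ddm_params <- function(spec, sigma_acc, sigma_m, a, I, lambda, d = NULL,
                       sigma_phi = NULL, b = NULL, Gamma = NULL) {
  stopifnot(inherits(spec, "ddm_spec"))
  if (sigma_acc <= 0) stop("sigma_acc must be > 0")
  if (sigma_m < 0) stop("sigma_m must be >= 0")
  if (a <= 0) stop("a must be > 0")
  if (I < 0) stop("I must be >= 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is.null(d)) {
    if (length(d) != 3 || any(diff(d) <= 0))
      stop("d must be three strictly increasing bounds")
  }
  if (spec$drift_variability) {
    if (is.null(sigma_phi) || sigma_phi < 0)
      stop("variant ", spec$name, " requires sigma_phi >= 0")
  } else sigma_phi <- NULL
  if (spec$collapsing_bound) {
    if (is.null(b) || b < 0) stop("variant ", spec$name, " requires b >= 0")
  } else b <- NULL
  if (spec$readout == "bayes_miscalibrated") {
    if (is.null(Gamma)) stop("variant ", spec$name, " requires Gamma")
  } else Gamma <- NULL
  structure(list(sigma_acc = sigma_acc, sigma_m = sigma_m, a = a, I = I,
                 lambda = lambda, d = d, sigma_phi = sigma_phi, b = b,
                 Gamma = Gamma, spec = spec),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Parameters for variant", x$spec$name, "\n")
  v <- unlist(x[c("sigma_acc", "sigma_m", "a", "I", "lambda")])
  print(signif(v, 4))
  if (!is.null(x$d)) cat("d:", paste(signif(x$d, 4), collapse = " < "), "\n")
  for (nm in c("sigma_phi", "b", "Gamma"))
    if (!is.null(x[[nm]])) cat(nm, "=", signif(x[[nm]], 4), "\n")
  invisible(x)
}

# Flat named vector of the fitted parameters, ordered as param_names(spec).
params_to_vector <- function(params) {
  spec <- params$spec
  v <- c(params$sigma_acc, params$sigma_m, params$a, params$I, params$lambda,
         params$d)
  if (spec$drift_variability) v <- c(v, params$sigma_phi)
  if (spec$collapsing_bound) v <- c(v, params$b)
  if (spec$readout == "bayes_miscalibrated") v <- c(v, params$Gamma)
  setNames(v, param_names(spec))
}

params_from_vector <- function(v, spec) {
  v <- setNames(as.numeric(v), param_names(spec))
  ddm_params(spec, sigma_acc = v[["sigma_acc"]], sigma_m = v[["sigma_m"]],
             a = v[["a"]], I = v[["I"]], lambda = v[["lambda"]],
             d = unname(v[c("d1", "d2", "d3")]),
             sigma_phi = if (spec$drift_variability) v[["sigma_phi"]],
             b = if (spec$collapsing_bound) v[["b"]],
             Gamma = if (spec$readout == "bayes_miscalibrated") v[["Gamma"]])
}

# Internal 11-slot layout consumed by the compiled likelihood:
# sigma_acc, sigma_m, a, I, lambda, d1, d2, d3, sigma_phi, b, gamma.
params_to_cpar <- function(params, stats = NULL) {
  if (is.null(params$d)) stop("parameter set has no confidence-bin bounds d")
  c(params$sigma_acc, params$sigma_m, params$a, params$I, params$lambda,
    params$d,
    if (is.null(params$sigma_phi)) 0 else params$sigma_phi,
    if (is.null(params$b)) 0 else params$b,
    resolve_gamma(params, params$spec, stats))
}
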