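#' Construct a linear birth-weight model
#'
#' A linear estimator `intercept + sum(coef * predictor)` with named
#' coefficients, output in grams.
#'
#' @param name Model label.
#' @param intercept Intercept in grams.
#' @param coefficients Named numeric vector: grams per predictor unit.
#' @param units Optional named character vector of predictor unit labels.
#' @return A `linear_model` object.
#' @seealso [fbw_models()] for the two published Ethiopian-population
#'   models, [evaluate_linear_model()].
#' @export
linear_model <- function(name, intercept, coefficients = numeric(0),
                         units = NULL) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("'coefficients' must be named")
  if (anyDuplicated(names(coefficients)))
    stop("predictor names must be unique")
  if (!all(is.finite(c(intercept, coefficients))))
    stop("coefficients must be finite")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, units = units),
            class = "linear_model")
}

#' The two published Ethiopian-population birth-weight models
#'
#' Returns the two multiple-linear-regression estimators of fetal birth
#' weight developed on an Ethiopian cohort:
#'
#' * `model1_physician` — physician-measured biometry:
#'   `EFW = 2294.857 + 81.018 AC - 42.132 GA + 13.970 E`
#' * `model2_image` — image-algorithm biometry (the final model):
#'   `EFW = -780.532 + 7.269 AC - 5.031 BPD + 16.781 FL + 102.989 GA`
#'
#' AC, BPD and FL are in centimetres, GA (gestational age) in completed
#' weeks, E an integer ethnicity code, output in grams.  The centimetre/week
#' unit assignment is the only one giving term-congruent magnitudes (33 cm of
#' AC contributes about 240 g in the image model; millimetres would exceed
#' 6000 g at term).
#'
#' @return Named list of two [linear_model()] objects.
#' @examples
#' m <- fbw_models()
#' evaluate_linear_model(m$model2_image,
#'                       c(ac_cm = 33, bpd_cm = 9, fl_cm = 7, ga_weeks = 38))
#' @export
fbw_models <- function() {
  list(
    model1_physician = linear_model(
      "model1_physician", 2294.857,
      c(ac_cm = 81.018, ga_weeks = -42.132, ethnicity = 13.970),
      units = c(ac_cm = "cm", ga_weeks = "weeks", ethnicity = "code")),
    model2_image = linear_model(
      "model2_image", -780.532,
      c(ac_cm = 7.269, bpd_cm = -5.031, fl_cm = 16.781, ga_weeks = 102.989),
      units = c(ac_cm = "cm", bpd_cm = "cm", fl_cm = "cm",
                ga_weeks = "weeks")))
}

#' Evaluate a linear model on a set of predictor values
#'
#' @param model A [linear_model()].
#' @param predictors Named numeric vector or list mapping predictor names to
#'   values; every model term must be present (extras are ignored).
#' @return Estimated weight in grams.
#' @export
evaluate_linear_model <- function(model, predictors) {
  stopifnot(inherits(model, "linear_model"))
  predictors <- unlist(predictors)
  need <- names(model$coefficients)
  missing <- setdiff(need, names(predictors))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  model$intercept + sum(model$coefficients * predictors[need])
}

#' A subject record for birth-weight estimation
#'
#' @param id Subject identifier.
#' @param ga_weeks Gestational age in completed weeks (the study population
#'   spans 30--42 weeks; values outside are allowed but unusual).
#' @param ethnicity_code Integer code per the configured codebook (default
#'   codebook: Oromo = 1, Amhara = 2, SNNPR = 3, other = 4).
#' @param biometry A [biometry_set()] (millimetres).
#' @param actual_bw_g Actual birth weight in grams, if known.
#' @param sex Optional label.
#' @return A `subject_record` list.
#' @export
subject_record <- function(id, ga_weeks, ethnicity_code = NA_integer_,
                           biometry = biometry_set(),
                           actual_bw_g = NA_real_, sex = NA_character_) {
  stopifnot(ga_weeks > 0)
  if (!is.na(actual_bw_g) && actual_bw_g <= 0)
    stop("'actual_bw_g' must be positive when present")
  structure(list(id = id, ga_weeks = ga_weeks,
                 ethnicity_code = ethnicity_code, biometry = biometry,
                 actual_bw_g = actual_bw_g, sex = sex),
            class = "subject_record")
}

#' Estimate fetal birth weight for a subject
#'
#' Applies one of the two published models (see [fbw_models()]) to a
#' [subject_record()].  Biometry stored in millimetres is converted to the
#' models' centimetre scale automatically.  Estimates outside the plausible
#' 500--6000 g range are flagged, not rejected.
#'
#' @param record A [subject_record()].
#' @param model_id `"model1_physician"` or `"model2_image"`.
#' @return List with `efw_g` (grams) and `implausible` (logical flag).
#' @export
estimate_fbw <- function(record,
                         model_id = c("model2_image", "model1_physician")) {
  stopifnot(inherits(record, "subject_record"))
  model_id <- match.arg(model_id)
  model <- fbw_models()[[model_id]]
  b <- record$biometry
  preds <- c(ac_cm = unname(b$ac_mm) / 10, bpd_cm = unname(b$bpd_mm) / 10,
             fl_cm = unname(b$fl_mm) / 10, ga_weeks = record$ga_weeks,
             ethnicity = as.numeric(record$ethnicity_code))
  need <- names(model$coefficients)
  bad <- need[is.na(preds[need])]
  if (length(bad))
    stop("missing required field(s) for ", model_id, ": ",
         paste(bad, collapse = ", "))
  efw <- evaluate_linear_model(model, preds)
  list(efw_g = efw, implausible = efw < 500 || efw > 6000)
}

#' Classify a birth weight into the standard categories
#'
#' Categories: below 1000 g extremely low; 1000 to below 1500 g very low;
#' 1500 to 2500 g low; strictly between 2500 and 4000 g normal; 4000 g and
#' above macrosomia.  "Normal" is an open interval, so the 2500 g and
#' 4000 g boundaries belong to the adjacent non-normal classes.  Weights of
#' 4500 g and above additionally carry a `severe_macrosomia` flag.
#'
#' @param grams Birth weight in grams (> 0); vectorised.
#' @return A data.frame with columns `grams`, `category` (factor with
#'   levels extremely_low, very_low, low, normal, macrosomia) and
#'   `severe_macrosomia` (logical).
#' @examples
#' classify_weight(c(900, 3380.21, 4200))
#' @export
classify_weight <- function(grams) {
  if (any(grams <= 0)) stop("weight must be positive")
  category <- cut(grams,
                  breaks = c(0, 1000, 1500, 2500, 4000, Inf),
                  labels = c("extremely_low", "very_low", "low", "normal",
                             "macrosomia"),
                  right = FALSE)
  # the low/normal boundary: exactly 2500 g is "low" (normal is open)
  category[grams == 2500] <- "low"
  data.frame(grams = grams, category = category,
             severe_macrosomia = grams >= 4500)
}
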