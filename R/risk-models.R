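# Published clinical risk models for nodule malignancy. Coefficients are
# not hard-coded: they live in cited, human-readable JSON constants files
# under inst/models/ so provenance is auditable and values replaceable.

#' Load a packaged risk-model specification
#'
#' @param name `"mayo"` or `"brock_parsimonious"`, or a path to a JSON
#'   model file following the same schema.
#' @return object of class `risk_model_spec`.
#' @export
load_risk_model <- function(name) {
  path <- if (file.exists(name)) name
          else system.file("models", paste0(name, ".json"),
                           package = "qctlung")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown risk model: ", name)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(is.numeric(spec$intercept), length(spec$terms) >= 1L)
  for (tm in spec$terms)
    if (!is.finite(tm$coefficient)) stop("non-finite coefficient in ", name)
  structure(spec, class = "risk_model_spec")
}

term_value <- function(tm, records) {
  v <- records[[tm$covariate]]
  if (is.null(v)) stop("missing required covariate: ", tm$covariate)
  switch(tm$transform,
         identity = as.numeric(v),
         center = as.numeric(v) - tm$center,
         indicator = as.numeric(as.character(v) == tm$level),
         # screening-model size term: (diameter/10 cm)^(-1/2), centred
         brock_size = (as.numeric(v) / 10)^(-0.5) - tm$offset,
         stop("unknown transform: ", tm$transform))
}

#' Linear predictor and probability of a risk-model specification
#'
#' @param records data.frame of subject records (cohort schema).
#' @param spec a [load_risk_model()] specification.
#' @param policy `"strict"` errors on missing covariate values, `"na"`
#'   propagates NA probabilities.
#' @return numeric vector of malignancy probabilities in (0, 1).
#' @export
risk_model_probability <- function(records, spec, policy = c("strict", "na")) {
  policy <- match.arg(policy)
  stopifnot(inherits(spec, "risk_model_spec"))
  eta <- rep(spec$intercept, nrow(records))
  for (tm in spec$terms) {
    x <- term_value(tm, records)
    if (policy == "strict" && any(is.na(x)))
      stop("missing values in required covariate '", tm$covariate,
           "' under strict policy")
    eta <- eta + tm$coefficient * x
  }
  plogis(eta)
}

#' Mayo Clinic model probability of malignancy
#'
#' Incidental-nodule model over age, ever-smoking, prior extrathoracic
#' cancer, nodule diameter, spiculation and upper-lobe location.
#'
#' @inheritParams risk_model_probability
#' @param spec model constants, default the packaged cited file.
#' @export
mayo_probability <- function(records, spec = load_risk_model("mayo"),
                             policy = "strict") {
  risk_model_probability(records, spec, policy)
}

#' Parsimonious Brock model probability of malignancy
#'
#' Screening-nodule model over sex, nodule size, upper-lobe location,
#' nodule type, nodule count and spiculation; the covariate list is driven
#' by the packaged constants file.
#'
#' @inheritParams mayo_probability
#' @export
brock_probability <- function(records,
                              spec = load_risk_model("brock_parsimonious"),
                              policy = "strict") {
  risk_model_probability(records, spec, policy)
}
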