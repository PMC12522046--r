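# Condition text synthesis. Agents go above the arrow; solvent, temperature,
# time and yield go below it; out-of-role texts (pH, atmosphere, R-group
# legends) are rendered but carry no role token downstream.

#' Condition sampling specification
#'
#' Vocabularies and presence probabilities for the condition text placed
#' around each reaction arrow. Format strings realize numeric roles: `{v}` is
#' replaced by a sampled value (formats without `{v}`, e.g. `"rt"`, are used
#' verbatim).
#'
#' @param agent_vocab,solvent_vocab Name vocabularies (non-empty). Defaults
#'   are common reagent/solvent names; none of them parses as SMILES, so by
#'   default the assembled reaction SMILES keeps the agent field of its
#'   source reaction.
#' @param temperature_formats,time_formats Format strings for the numeric
#'   roles.
#' @param temperature_values,time_values Value pools substituted for `{v}`.
#' @param yield_range Inclusive integer percent range for yields.
#' @param yield_format Format string for yields.
#' @param p_role_present Named probabilities (agent, solvent, temperature,
#'   time, yield) that a role appears at an arrow.
#' @param p_other Probability of one out-of-role text.
#' @param other_texts Pool of out-of-role texts.
#' @param p_second_agent Probability of a second agent given one is present.
#' @return An object of class `rxn_condition_spec`.
#' @export
condition_spec <- function(
    agent_vocab = c("H2", "Pd/C", "Et3N", "NaOH", "TsOH", "DBU", "NaBH4",
                    "LiAlH4", "AcOH", "MsCl", "PBr3", "DMP"),
    solvent_vocab = c("THF", "DMF", "DMSO", "MeOH", "EtOH", "toluene", "DCM",
                      "Et2O", "MeCN", "dioxane"),
    temperature_formats = c("{v} °C", "{v}°C", "rt", "reflux"),
    time_formats = c("{v} h", "{v} min", "overnight"),
    temperature_values = c(-78, -40, 0, 25, 40, 60, 80, 100, 120, 160),
    time_values = c(1, 2, 3, 4, 6, 8, 12, 16, 24, 48),
    yield_range = c(35, 99),
    yield_format = "{v}%",
    p_role_present = c(agent = 0.85, solvent = 0.7, temperature = 0.6,
                       time = 0.5, yield = 0.5),
    p_other = 0.08,
    other_texts = c("pH 10–11", "N2 atmosphere", "2 steps",
                    "R = Me, Et", "sealed tube"),
    p_second_agent = 0.25) {
  spec <- structure(
    list(agent_vocab = agent_vocab, solvent_vocab = solvent_vocab,
         temperature_formats = temperature_formats,
         time_formats = time_formats,
         temperature_values = temperature_values, time_values = time_values,
         yield_range = as.numeric(yield_range), yield_format = yield_format,
         p_role_present = p_role_present, p_other = p_other,
         other_texts = other_texts, p_second_agent = p_second_agent),
    class = "rxn_condition_spec")
  validate_condition_spec(spec)
  spec
}

validate_condition_spec <- function(spec) {
  stopifnot(inherits(spec, "rxn_condition_spec"))
  probs <- c(spec$p_role_present, spec$p_other, spec$p_second_agent)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  need <- names(spec$p_role_present)[spec$p_role_present > 0]
  if ("agent" %in% need && !length(spec$agent_vocab))
    stop("agent role has p > 0 but agent_vocab is empty")
  if ("solvent" %in% need && !length(spec$solvent_vocab))
    stop("solvent role has p > 0 but solvent_vocab is empty")
  if ("temperature" %in% need && !length(spec$temperature_formats))
    stop("temperature role has p > 0 but temperature_formats is empty")
  if ("time" %in% need && !length(spec$time_formats))
    stop("time role has p > 0 but time_formats is empty")
  if (diff(spec$yield_range) < 0) stop("yield_range must be min <= max")
  invisible(spec)
}

.realize_format <- function(fmt, values, rng_unused = NULL) {
  if (grepl("{v}", fmt, fixed = TRUE)) {
    v <- if (length(values) == 1) values else sample(values, 1)
    sub("{v}", format(v, trim = TRUE), fmt, fixed = TRUE)
  } else fmt
}

#' Sample condition items for one arrow
#'
#' Draws zero or more [condition_item()]s per role according to
#' `p_role_present`; numeric roles realize one of their format patterns.
#' Boxes are assigned later, at layout time.
#'
#' @param rng An [rng_stream()].
#' @param spec An [condition_spec()].
#' @return List of `rxn_condition_item` (possibly empty).
#' @export
sample_conditions <- function(rng, spec = condition_spec()) {
  validate_condition_spec(spec)
  p <- spec$p_role_present
  with_rng(rng, {
    items <- list()
    add <- function(text, role)
      items[[length(items) + 1]] <<- condition_item(text, role)
    if (stats::runif(1) < (p[["agent"]] %||% 0)) {
      n_ag <- 1 + (stats::runif(1) < spec$p_second_agent)
      for (a in sample(spec$agent_vocab, min(n_ag, length(spec$agent_vocab))))
        add(a, "agent")
    }
    if (stats::runif(1) < (p[["solvent"]] %||% 0))
      add(sample(spec$solvent_vocab, 1), "solvent")
    if (stats::runif(1) < (p[["temperature"]] %||% 0))
      add(.realize_format(sample(spec$temperature_formats, 1),
                          spec$temperature_values), "temperature")
    if (stats::runif(1) < (p[["time"]] %||% 0))
      add(.realize_format(sample(spec$time_formats, 1), spec$time_values),
          "time")
    if (stats::runif(1) < (p[["yield"]] %||% 0)) {
      v <- if (diff(spec$yield_range) == 0) spec$yield_range[1]
      else sample(seq(spec$yield_range[1], spec$yield_range[2]), 1)
      add(sub("{v}", format(v), spec$yield_format, fixed = TRUE), "yield")
    }
    if (stats::runif(1) < spec$p_other && length(spec$other_texts))
      add(sample(spec$other_texts, 1), "other")
    items
  })
}
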