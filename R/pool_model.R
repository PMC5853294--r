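#' Piecewise-constant input-activity profile
#'
#' Time-varying multiplier `a(t)` in \[0, 1\] applied to uptake edges from the
#' external pool. The default digitizes the collapse of photosynthetic CO2
#' assimilation under nitrogen deprivation: full activity before N removal
#' (t < 0), 50% during the first day, 10% during the second, 5% thereafter.
#'
#' @param breaks Strictly increasing break times in days. `values[1]` applies
#'   for `t < breaks[1]`, `values[i + 1]` for `breaks[i] <= t < breaks[i + 1]`.
#' @param values Activity levels, length `length(breaks) + 1`, each in
#'   \[0, 1\].
#' @return An object of class `piecewise_activity`.
#' @export
piecewise_activity <- function(breaks = c(0, 1, 2),
                               values = c(1, 0.5, 0.1, 0.05)) {
  if (length(values) != length(breaks) + 1L) {
    stop_config("values must have length(breaks) + 1 entries")
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop_config("breaks must be strictly increasing")
  }
  if (any(values < 0 | values > 1)) {
    stop_config("activity values must lie in [0, 1]")
  }
  structure(list(breaks = breaks, values = values),
            class = "piecewise_activity")
}

#' Constant input-activity profile
#'
#' @param value Activity level in \[0, 1\] (default 1); used for tracers whose
#'   uptake does not follow photosynthesis, e.g. fatty-acid labeling.
#' @return A `piecewise_activity` with no breaks.
#' @export
constant_activity <- function(value = 1) {
  structure(list(breaks = numeric(0), values = value),
            class = "piecewise_activity")
}

activity_at <- function(act, t) {
  if (length(act$breaks) == 0L) return(rep(act$values, length(t)))
  act$values[findInterval(t, act$breaks) + 1L]
}

#' First-order compartmental pool model
#'
#' A linear pool model with an external clamped tracer pool, first-order
#' transfer edges among internal pools, a time-dependent multiplier on uptake
#' from the external pool, and an onset lag gating all edges into the TAG
#' pool (storage-lipid synthesis starts 12-24 h after nitrogen removal; the
#' default gate is 0.75 d).
#'
#' @param pools Character vector of internal pool names (unique).
#' @param edges Data frame with columns `source`, `sink`, `rate` (per day,
#'   >= 0). Sources may include `external_pool`; sinks must be internal
#'   pools. No self-edges.
#' @param external_pool Name of the clamped external tracer pool.
#' @param external_value Label level at which the external pool is clamped
#'   while the label is on (its units set the simulation's amount scale).
#' @param input_activity A [piecewise_activity()] profile multiplying rates
#'   of edges leaving `external_pool`.
#' @param tag_onset_lag Days after time 0 before edges into `tag_pool`
#'   activate (default 0.75).
#' @param tag_pool Name of the lag-gated sink pool (default `"TAG"`).
#' @return An object of class `pool_model`.
#' @examples
#' m <- pool_model(
#'   pools = c("A", "B"),
#'   edges = data.frame(source = c("ext", "A"), sink = c("A", "B"),
#'                      rate = c(1, 0.5)),
#'   external_pool = "ext", tag_onset_lag = 0, tag_pool = "B"
#' )
#' @export
pool_model <- function(pools, edges,
                       external_pool = "external_DIC",
                       external_value = 1,
                       input_activity = piecewise_activity(),
                       tag_onset_lag = 0.75,
                       tag_pool = "TAG") {
  if (anyDuplicated(pools)) stop_config("pool names must be unique")
  if (external_pool %in% pools) {
    stop_config("external pool '%s' must not be an internal pool", external_pool)
  }
  req <- c("source", "sink", "rate")
  if (!is.data.frame(edges) || !all(req %in% names(edges))) {
    stop_config("edges must be a data frame with columns source, sink, rate")
  }
  edges <- edges[, req]
  if (any(!is.finite(edges$rate)) || any(edges$rate < 0)) {
    stop_config("edge rates must be finite and >= 0")
  }
  if (any(edges$source == edges$sink)) stop_config("self-edges are not allowed")
  ok_src <- edges$source %in% c(pools, external_pool)
  ok_snk <- edges$sink %in% pools
  if (!all(ok_src)) {
    stop_config("unknown edge source(s): %s",
                paste(unique(edges$source[!ok_src]), collapse = ", "))
  }
  if (!all(ok_snk)) {
    stop_config("edge sinks must be internal pools; offending: %s",
                paste(unique(edges$sink[!ok_snk]), collapse = ", "))
  }
  if (!inherits(input_activity, "piecewise_activity")) {
    stop_config("input_activity must be a piecewise_activity object")
  }
  if (tag_onset_lag < 0) stop_config("tag_onset_lag must be >= 0")
  structure(
    list(pools = pools, edges = edges, external_pool = external_pool,
         external_value = external_value, input_activity = input_activity,
         tag_onset_lag = tag_onset_lag, tag_pool = tag_pool),
    class = "pool_model"
  )
}

#' @export
print.pool_model <- function(x, ...) {
  cat(sprintf("Pool model: %d internal pools (%s), external '%s'\n",
              length(x$pools), paste(x$pools, collapse = ", "),
              x$external_pool))
  cat(sprintf("  TAG-onset lag: %g d (gates edges into '%s')\n",
              x$tag_onset_lag, x$tag_pool))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Update edge rates of a pool model
#'
#' @param model A [pool_model()].
#' @param rates Named numeric vector, names formatted `"source->sink"`.
#' @return The model with the matching edge rates replaced.
#' @export
set_edge_rates <- function(model, rates) {
  keys <- paste0(model$edges$source, "->", model$edges$sink)
  miss <- setdiff(names(rates), keys)
  if (length(miss)) stop_config("no such edge(s): %s", paste(miss, collapse = ", "))
  model$edges$rate[match(names(rates), keys)] <- unname(rates)
  if (any(model$edges$rate < 0)) stop_config("edge rates must be >= 0")
  model
}

#' Labeling protocol for a pulse-chase experiment
#'
#' @param tracer `"bicarbonate"` or `"palmitic_acid"`.
#' @param label_start,label_end Days delimiting the labeling window
#'   (`label_start < label_end`). The external pool is clamped to full label
#'   inside the window and to zero afterwards (instantaneous washout).
#' @param chase_end Last day of the experiment (`>= label_end`).
#' @param specific_activity Tracer specific activity (dpm per umol), carried
#'   for downstream count conversion. Default 1.
#' @param washout Logical; washout is modeled as instantaneous (the only
#'   supported mode; residual label after washing is ignored).
#' @return An object of class `labeling_protocol`.
#' @export
labeling_protocol <- function(tracer = c("bicarbonate", "palmitic_acid"),
                              label_start, label_end, chase_end,
                              specific_activity = 1, washout = TRUE) {
  tracer <- match.arg(tracer)
  if (!(label_start < label_end && label_end <= chase_end)) {
    stop_config("need label_start < label_end <= chase_end (got %g, %g, %g)",
                label_start, label_end, chase_end)
  }
  if (specific_activity <= 0) stop_config("specific_activity must be > 0")
  if (!isTRUE(washout)) stop_config("only instantaneous washout is supported")
  structure(
    list(tracer = tracer, label_start = label_start, label_end = label_end,
         chase_end = chase_end, specific_activity = specific_activity,
         washout = TRUE),
    class = "labeling_protocol"
  )
}

#' @export
print.labeling_protocol <- function(x, ...) {
  cat(sprintf("Labeling protocol: %s, label [%g, %g) d, chase to day %g\n",
              x$tracer, x$label_start, x$label_end, x$chase_end))
  invisible(x)
}
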