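# Pulse-chase flux accounting: interval transfer series, conversion
# efficiencies, per-day pathway contributions, and the daily TAG budget
# (three pathway columns against an independently measured total).

#' Build an interval transfer series directly from totals
#'
#' @param source_decrease,sink_increase Non-negative per-interval amounts
#'   (same length), in nmol C or pmol tracer per 10^6 cells.
#' @param interval_start,interval_end Optional interval boundaries (days).
#' @return An object of class `transfer_series`.
#' @export
transfer_series <- function(source_decrease, sink_increase,
                            interval_start = seq_along(source_decrease) - 1,
                            interval_end = seq_along(source_decrease)) {
  if (length(source_decrease) != length(sink_increase)) {
    stop_input("source_decrease and sink_increase must have equal length")
  }
  if (any(source_decrease < 0) || any(sink_increase < 0)) {
    stop_input("transfer amounts must be >= 0 (clamp upstream)")
  }
  structure(data.frame(interval_start = interval_start,
                       interval_end = interval_end,
                       source_decrease = source_decrease,
                       sink_increase = sink_increase),
            class = c("transfer_series", "data.frame"))
}

#' Interval transfers from a pooled source into a sink pool
#'
#' Averages replicates, sums the label over `source_pools` (e.g. starch plus
#' the water-soluble fraction, so that soluble-to-starch interconversion
#' during the chase cancels out), and takes first differences over
#' consecutive sampling days. Source decreases and sink increases are clamped
#' at zero; the unclamped differences are kept in `attr(, "unclamped")`.
#'
#' @param tc A `timecourse` (or compatible data frame).
#' @param source_pools Character vector of source pool names.
#' @param sink_pool Single sink pool name.
#' @return A [transfer_series()] with one row per sampling interval.
#' @export
pooled_source_series <- function(tc, source_pools, sink_pool) {
  pm <- pool_means(tc, pools = unique(c(source_pools, sink_pool)))
  if (length(pm$days) < 2L) stop_input("need at least two sampling days")
  src <- rowSums(pm$means[, source_pools, drop = FALSE])
  snk <- pm$means[, sink_pool]
  d_src <- -diff(src)
  d_snk <- diff(snk)
  ts <- transfer_series(source_decrease = pmax(0, d_src),
                        sink_increase = pmax(0, d_snk),
                        interval_start = utils::head(pm$days, -1L),
                        interval_end = utils::tail(pm$days, -1L))
  attr(ts, "unclamped") <- data.frame(interval_start = utils::head(pm$days, -1L),
                                      interval_end = utils::tail(pm$days, -1L),
                                      source_decrease = d_src,
                                      sink_increase = d_snk)
  ts
}

#' Source-to-sink conversion efficiency
#'
#' Total sink increase divided by total source decrease over the chase. A
#' value above 1 indicates label influx from outside the pooled source and
#' triggers a warning.
#'
#' @param ts A [transfer_series()].
#' @return Dimensionless efficiency in `[0, Inf)`.
#' @examples
#' conversion_efficiency(transfer_series(300, 180))  # 0.60
#' conversion_efficiency(transfer_series(12, 9))     # 0.75
#' @export
conversion_efficiency <- function(ts) {
  stopifnot(inherits(ts, "transfer_series"))
  src <- sum(ts$source_decrease)
  snk <- sum(ts$sink_increase)
  if (src <= 0) {
    stop_undefined("total source decrease is zero; efficiency undefined")
  }
  if (snk == 0) return(0)
  eff <- snk / src
  if (eff > 1) {
    warning(sprintf(paste0("efficiency %.3f exceeds 1: sink gained more label",
                           " than the pooled source lost"), eff))
  }
  eff
}

pulse_label_end <- function(tc) {
  prot <- attr(tc, "protocol")
  if (!is.null(prot)) prot$label_end else min(tc$day)
}

# Shared walker over a list of daily-pulse time courses: calls f(p, days,
# means) for each pulse with the replicate-mean series of `pool`.
daily_pulse_apply <- function(pulse_tcs, pool, f) {
  for (tc in pulse_tcs) {
    if (!pool %in% unique(tc$pool)) {
      stop_input("pool '%s' missing from pulse experiment '%s'",
                 pool, tc$experiment[1])
    }
    pm <- pool_means(tc, pools = pool)
    f(pulse_label_end(tc), pm$days, pm$means[, pool])
  }
  invisible(NULL)
}

#' Daily TAG production from starch, from daily-pulse chases
#'
#' For each 24-h tracer pulse ending on day `p`, the TAG label appearing
#' after the end of labeling is attributed to the chase day on which it
#' appears; the day-`d` output sums those appearances over all pulses.
#' Negative day-to-day changes are clamped at zero. The day-1 entry is zero
#' by construction: conversion of material made before the first pulse is
#' not measured by this design.
#'
#' @param pulse_tcs List of `timecourse` objects, one per pulse day, each
#'   covering its label-end day through `max(days)`.
#' @param days Output days (default 1:8).
#' @param tag_pool TAG pool name.
#' @return Named numeric vector of per-day contributions (same units as the
#'   input values).
#' @export
starch_to_tag_daily <- function(pulse_tcs, days = 1:8, tag_pool = "TAG") {
  out <- stats::setNames(numeric(length(days)), days)
  daily_pulse_apply(pulse_tcs, tag_pool, function(p, ds, tag) {
    if (length(ds) < 2L) return(invisible(NULL))
    gains <- pmax(0, diff(tag))
    gain_day <- ds[-1L]
    keep <- gain_day %in% days & gain_day > p
    out[as.character(gain_day[keep])] <<-
      out[as.character(gain_day[keep])] + gains[keep]
  })
  out[1L] <- 0
  out
}

#' Daily direct de novo TAG synthesis
#'
#' The TAG label present at the end of each 24-h pulse: tracer incorporated
#' into TAG within the labeling day itself.
#'
#' @inheritParams starch_to_tag_daily
#' @return Named numeric vector over `days`.
#' @export
de_novo_direct_daily <- function(pulse_tcs, days = 1:8, tag_pool = "TAG") {
  out <- stats::setNames(rep(NA_real_, length(days)), days)
  daily_pulse_apply(pulse_tcs, tag_pool, function(p, ds, tag) {
    i <- match(p, ds)
    if (is.na(i)) stop_input("pulse ending day %g has no label-end sample", p)
    if (p %in% days) out[as.character(p)] <<- tag[i]
  })
  if (anyNA(out)) {
    stop_input("no pulse covers day(s): %s",
               paste(days[is.na(out)], collapse = ", "))
  }
  out
}

#' Daily de novo polar-lipid synthesis
#'
#' Polar-lipid label at the end of each 24-h pulse (the PL analogue of
#' [de_novo_direct_daily()]); feeds the via-PL convolution.
#'
#' @inheritParams starch_to_tag_daily
#' @param pl_pool Polar-lipid pool name.
#' @return Named numeric vector over `days`.
#' @export
pl_daily_synthesis <- function(pulse_tcs, days = 1:8, pl_pool = "polar_lipid") {
  out <- stats::setNames(rep(NA_real_, length(days)), days)
  daily_pulse_apply(pulse_tcs, pl_pool, function(p, ds, pl) {
    i <- match(p, ds)
    if (is.na(i)) stop_input("pulse ending day %g has no label-end sample", p)
    if (p %in% days) out[as.character(p)] <<- pl[i]
  })
  if (anyNA(out)) {
    stop_input("no pulse covers day(s): %s",
               paste(days[is.na(out)], collapse = ", "))
  }
  out
}

#' Per-day PL-to-TAG transfer fractions
#'
#' From a chase after labeling the polar lipids: the fraction of the PL label
#' present at the end of labeling that appears in TAG during each subsequent
#' day. Fractions are indexed by lag (days since the end of labeling); the
#' cumulative sum is capped at 1.
#'
#' @param tc A `timecourse` with PL and TAG pools over the chase.
#' @param pl_pool,tag_pool Pool names.
#' @return An object of class `transfer_fraction_series`: a data frame with
#'   columns `lag` and `fraction`, cumulative fraction in
#'   `attr(, "cumulative")`.
#' @export
pl_transfer_fractions <- function(tc, pl_pool = "polar_lipid",
                                  tag_pool = "TAG") {
  p <- pulse_label_end(tc)
  pm <- pool_means(tc, pools = c(pl_pool, tag_pool))
  i0 <- match(p, pm$days)
  if (is.na(i0)) stop_input("no sample at the end of labeling (day %g)", p)
  p0 <- pm$means[i0, pl_pool]
  if (p0 <= 0) stop_undefined("PL label at the end of labeling is zero")
  after <- pm$days > p
  if (!any(after)) stop_input("no chase samples after the end of labeling")
  tag <- pm$means[, tag_pool]
  gains <- pmax(0, diff(tag[pm$days >= p]))
  lags <- pm$days[after] - p
  frac <- gains / p0
  # cap the running total at 1
  cum <- cumsum(frac)
  over <- cum > 1
  if (any(over)) {
    frac <- diff(c(0, pmin(cum, 1)))
  }
  structure(data.frame(lag = lags, fraction = frac),
            class = c("transfer_fraction_series", "data.frame"),
            cumulative = sum(frac))
}

#' Daily de novo TAG synthesis routed through newly made PLs
#'
#' Convolves daily de novo PL synthesis with the per-day PL-to-TAG transfer
#' fractions: the day-`d` value is the sum over synthesis days `s < d` of
#' `pl_synth[s] * fraction(d - s)`. The day-1 value is zero (transfers begin
#' the day after synthesis).
#'
#' @param pl_synth Per-day PL synthesis (numeric vector over `days`).
#' @param fractions A [pl_transfer_fractions()] result, or a numeric vector
#'   of fractions indexed by lag in days.
#' @param days Output days (default 1:8).
#' @return Named numeric vector over `days`.
#' @export
de_novo_via_pl_daily <- function(pl_synth, fractions, days = 1:8) {
  if (length(pl_synth) != length(days)) {
    stop_input("pl_synth must have one value per output day (%d vs %d)",
               length(pl_synth), length(days))
  }
  if (inherits(fractions, "transfer_fraction_series")) {
    f <- stats::setNames(fractions$fraction, fractions$lag)
  } else {
    f <- stats::setNames(as.numeric(fractions), seq_along(fractions))
  }
  if (any(f < 0 | f > 1)) stop_input("fractions must lie in [0, 1]")
  if (sum(f) > 1 + 1e-9) {
    stop_input("cumulative transfer fraction exceeds 1 (%.3f)", sum(f))
  }
  out <- stats::setNames(numeric(length(days)), days)
  for (di in seq_along(days)) {
    for (si in seq_len(di - 1L)) {
      lag <- as.character(days[di] - days[si])
      if (!is.na(f[lag])) out[di] <- out[di] + pl_synth[si] * f[lag]
    }
  }
  out
}

#' Assemble the daily TAG pathway budget
#'
#' Combines the three per-day pathway series (from starch, de novo direct,
#' de novo via PLs) into a daily budget table, with the calculated total as
#' their exact row sum and the independently measured total alongside.
#'
#' @param from_starch,de_novo_direct,de_novo_via_pl,total_measured Numeric
#'   vectors over `days`, all non-negative, same units.
#' @param days Days covered (default 1:8).
#' @return An object of class `pathway_partition`: a data frame with one row
#'   per day plus attributes `totals` (column sums) and `discrepancy`
#'   (measured minus calculated, per day).
#' @export
assemble_partition <- function(from_starch, de_novo_direct, de_novo_via_pl,
                               total_measured, days = 1:8) {
  series <- list(from_starch = from_starch, de_novo_direct = de_novo_direct,
                 de_novo_via_pl = de_novo_via_pl,
                 total_measured = total_measured)
  for (nm in names(series)) {
    s <- series[[nm]]
    if (length(s) != length(days)) {
      stop_input("%s must have %d values (got %d)", nm, length(days), length(s))
    }
    if (any(!is.finite(s)) || any(s < 0)) {
      stop_input("%s must be finite and >= 0", nm)
    }
  }
  calc <- from_starch + de_novo_direct + de_novo_via_pl
  df <- data.frame(day = days,
                   from_starch = as.numeric(from_starch),
                   de_novo_direct = as.numeric(de_novo_direct),
                   de_novo_via_pl = as.numeric(de_novo_via_pl),
                   total_calculated = as.numeric(calc),
                   total_measured = as.numeric(total_measured))
  structure(df, class = c("pathway_partition", "data.frame"),
            totals = colSums(df[, -1L]),
            discrepancy = as.numeric(total_measured) - as.numeric(calc))
}

#' @export
print.pathway_partition <- function(x, ...) {
  cat(render_partition_report(x), sep = "\n")
  invisible(x)
}

#' Pathway shares of calculated TAG production
#'
#' @param p A [assemble_partition()] result.
#' @return Named vector of the three pathway fractions (summing to 1).
#' @examples
#' # printed 8-day totals: starch share ~0.66 ("about two-thirds from starch")
#' @export
pathway_fractions <- function(p) {
  stopifnot(inherits(p, "pathway_partition"))
  tot <- attr(p, "totals")
  paths <- tot[c("from_starch", "de_novo_direct", "de_novo_via_pl")]
  if (sum(paths) <= 0) stop_undefined("total calculated production is zero")
  paths / sum(paths)
}

#' Bound the TAG carbon originating from pre-formed polar lipids
#'
#' Scales the tracer transfer observed in a pre-labeling chase (membrane PLs
#' labeled with a fatty-acid tracer before nitrogen removal) to cellular
#' carbon under explicit assumptions: isotope dilution by the native
#' intracellular fatty-acid pool and the number of carbons per tracer
#' molecule. Also evaluates the homogeneous-labeling extrapolation (transfer
#' fraction times the total PL carbon pool) against a cap such as the
#' observed total PL decrease; exceeding the cap flags the homogeneous
#' assumption as inconsistent.
#'
#' @param prelabel_tc A `timecourse` from the pre-labeling chase (PL and TAG
#'   pools, pmol tracer per 10^6 cells).
#' @param added_pla_conc,internal_pla_conc Added tracer and estimated native
#'   intracellular fatty-acid concentrations (uM). The dilution factor is
#'   `(added + internal) / added`.
#' @param carbons_per_pla Carbon atoms per tracer molecule (16 for palmitic
#'   acid).
#' @param total_pl_carbon Total PL carbon pool (nmol C per 10^6 cells) used
#'   by the homogeneous-labeling extrapolation.
#' @param pl_decrease_cap Observed total PL carbon decrease (nmol C per 10^6
#'   cells) used as the consistency cap.
#' @param pl_pool,tag_pool Pool names.
#' @return A list of class `preformed_pl_estimate` with the dilution-scaled
#'   carbon estimate (`estimate_nmol_c`), the chase conversion fraction, the
#'   homogeneous-labeling extrapolation, the consistency flag, and notes.
#' @export
preformed_pl_estimate <- function(prelabel_tc,
                                  added_pla_conc = 0.5,
                                  internal_pla_conc = 1,
                                  carbons_per_pla = 16,
                                  total_pl_carbon = 169,
                                  pl_decrease_cap = 55,
                                  pl_pool = "polar_lipid",
                                  tag_pool = "TAG") {
  for (nm in c("added_pla_conc", "internal_pla_conc", "carbons_per_pla",
               "total_pl_carbon", "pl_decrease_cap")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_config("assumption '%s' must be a single finite number >= 0", nm)
    }
  }
  if (added_pla_conc <= 0) stop_config("added_pla_conc must be > 0")
  ts <- pooled_source_series(prelabel_tc, pl_pool, tag_pool)
  tag_gain_pmol <- sum(ts$sink_increase)
  fraction <- if (sum(ts$source_decrease) > 0) {
    conversion_efficiency(ts)
  } else 0
  dilution <- (added_pla_conc + internal_pla_conc) / added_pla_conc
  estimate <- tag_gain_pmol * dilution * carbons_per_pla / 1000
  homogeneous <- fraction * total_pl_carbon
  consistent <- homogeneous <= pl_decrease_cap
  notes <- c(
    sprintf("tracer transfer into TAG: %.3g pmol per 1e6 cells", tag_gain_pmol),
    sprintf("isotope-dilution factor: %.3g (added %g uM, internal %g uM)",
            dilution, added_pla_conc, internal_pla_conc),
    sprintf("dilution-scaled estimate: %.3g nmol C per 1e6 cells", estimate),
    sprintf(paste0("homogeneous-labeling extrapolation: %.3g nmol C vs cap ",
                   "%.3g nmol C -> %s"),
            homogeneous, pl_decrease_cap,
            if (consistent) "consistent" else
              "inconsistent (only a turning-over PL subpool can be labeled)")
  )
  structure(list(estimate_nmol_c = estimate,
                 conversion_fraction = fraction,
                 tag_gain_pmol = tag_gain_pmol,
                 dilution_factor = dilution,
                 homogeneous_estimate_nmol_c = homogeneous,
                 consistent = consistent,
                 notes = notes),
            class = "preformed_pl_estimate")
}

#' @export
print.preformed_pl_estimate <- function(x, ...) {
  cat("Pre-formed PL contribution to TAG\n")
  cat(paste0("  ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Relative de novo lipid synthesis between conditions
#'
#' Per-lipid-class ratio of tracer incorporation in a deprived culture to a
#' replete control, plus the implied suppression (`1 - ratio`).
#'
#' @param control_tc,deprived_tc `timecourse` objects (or data frames) whose
#'   pools are lipid classes, measured under identical labeling.
#' @param lipid_classes Character vector of classes to compare (may be
#'   empty).
#' @return Data frame with columns `lipid_class`, `ratio`, `suppression`.
#' @export
relative_de_novo <- function(control_tc, deprived_tc, lipid_classes) {
  if (length(lipid_classes) == 0L) {
    return(data.frame(lipid_class = character(0), ratio = numeric(0),
                      suppression = numeric(0)))
  }
  ctl <- pool_means(control_tc, pools = lipid_classes)
  dep <- pool_means(deprived_tc, pools = lipid_classes)
  ctl_v <- colMeans(ctl$means)
  dep_v <- colMeans(dep$means)
  if (any(ctl_v <= 0)) {
    stop_undefined("control incorporation is zero for: %s",
                   paste(lipid_classes[ctl_v <= 0], collapse = ", "))
  }
  ratio <- dep_v / ctl_v
  data.frame(lipid_class = lipid_classes, ratio = as.numeric(ratio),
             suppression = 1 - as.numeric(ratio), row.names = NULL)
}

#' Run the full daily partition on a synthetic pulse-chase dataset
#'
#' Chains the complete accounting on the output of
#' [generate_paperlike_dataset()]: daily measured totals from the
#' total-labeling design, the starch pathway from the daily bicarbonate
#' pulses, direct de novo from TAG at each pulse's label end, and the via-PL
#' pathway from daily PL synthesis convolved with the PL-to-TAG transfer
#' fractions of the day-1 fatty-acid chase.
#'
#' @param ds A dataset from [generate_paperlike_dataset()].
#' @param days Days to cover (default 1:8).
#' @return A [assemble_partition()] result.
#' @export
partition_paperlike <- function(ds, days = 1:8) {
  pm <- pool_means(ds$total_labeling, pools = "TAG")
  need <- c(min(days) - 1L, days)
  if (!all(need %in% pm$days)) {
    stop_input("total-labeling design must sample days %s",
               paste(need, collapse = ", "))
  }
  tag <- pm$means[match(need, pm$days), "TAG"]
  measured <- pmax(0, diff(tag))
  from_starch <- starch_to_tag_daily(ds$daily_bicarb_pulses, days = days)
  direct <- de_novo_direct_daily(ds$daily_bicarb_pulses, days = days)
  pl_synth <- pl_daily_synthesis(ds$daily_bicarb_pulses, days = days)
  fractions <- pl_transfer_fractions(ds$day1_pla_chase)
  via_pl <- de_novo_via_pl_daily(pl_synth, fractions, days = days)
  assemble_partition(from_starch, direct, via_pl, measured, days = days)
}
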