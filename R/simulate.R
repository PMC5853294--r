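# Numerical core: piecewise-constant linear ODE systems driven by a clamped
# external pool. On every constant piece the dynamics are
#   dx/dt = A x + u,
# with A assembled from first-order edges among internal pools and u from
# uptake edges leaving the external pool (scaled by the input activity and
# zeroed after washout). Integration uses deSolve::lsoda at tight tolerances;
# tests cross-check each piece against a matrix-exponential solution.

rate_matrix <- function(model, tag_active = TRUE) {
  n <- length(model$pools)
  A <- matrix(0, n, n, dimnames = list(model$pools, model$pools))
  e <- model$edges
  internal <- e$source != model$external_pool
  for (i in which(internal)) {
    r <- e$rate[i]
    if (!tag_active && e$sink[i] == model$tag_pool) r <- 0
    A[e$sink[i], e$source[i]] <- A[e$sink[i], e$source[i]] + r
    A[e$source[i], e$source[i]] <- A[e$source[i], e$source[i]] - r
  }
  A
}

forcing_vector <- function(model, activity, label_on, tag_active = TRUE) {
  u <- stats::setNames(numeric(length(model$pools)), model$pools)
  if (!label_on) return(u)
  e <- model$edges
  for (i in which(e$source == model$external_pool)) {
    r <- e$rate[i]
    if (!tag_active && e$sink[i] == model$tag_pool) r <- 0
    u[e$sink[i]] <- u[e$sink[i]] + r * activity * model$external_value
  }
  u
}

integrate_constant <- function(A, u, x0, times) {
  if (length(times) < 2L) {
    return(matrix(x0, nrow = length(times), ncol = length(x0), byrow = TRUE,
                  dimnames = list(NULL, names(x0))))
  }
  rhs <- function(t, y, parms) list(parms$A %*% y + parms$u)
  out <- deSolve::lsoda(y = x0, times = times, func = rhs,
                        parms = list(A = A, u = u),
                        rtol = 1e-10, atol = 1e-12)
  res <- out[, -1L, drop = FALSE]
  colnames(res) <- names(x0)
  res
}

#' Solve a first-order linear pool system
#'
#' Integrates `dx/dt = A x + forcing` from `x0` at `times[1]` to every time in
#' `times`. `A` holds first-order rates: `A[j, i]` is the rate from pool `i`
#' into pool `j` and diagonal entries carry the outflow bookkeeping, so
#' off-diagonals are non-negative and internal columns sum to <= 0.
#'
#' @param A Square rate matrix (per day).
#' @param x0 Initial label vector, one entry per pool.
#' @param times Increasing time points; `times[1]` is the initial time.
#' @param forcing Optional constant inflow vector (same length as `x0`).
#' @return Matrix of trajectories, `length(times)` rows by pool columns.
#' @export
solve_linear_system <- function(A, x0, times, forcing = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_input("A must be a square matrix")
  }
  if (length(x0) != nrow(A)) stop_input("x0 length must match dim(A)")
  if (is.null(forcing)) forcing <- numeric(length(x0))
  if (length(forcing) != length(x0)) stop_input("forcing length must match x0")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_input("times must be strictly increasing")
  }
  x0 <- stats::setNames(as.numeric(x0),
                        if (is.null(names(x0))) rownames(A) else names(x0))
  integrate_constant(A, as.numeric(forcing), x0, times)
}

# Breakpoints at which the (A, u) pair can change: activity breaks, the TAG
# onset gate, and washout at label_end.
system_breakpoints <- function(model, protocol) {
  b <- c(model$input_activity$breaks, model$tag_onset_lag,
         protocol$label_start, protocol$label_end, protocol$chase_end)
  b <- sort(unique(b))
  b[b >= protocol$label_start & b <= protocol$chase_end]
}

# Noise-free trajectories of all internal pools at `times` (plus cumulative
# label flux along every edge into the gated TAG pool when track_fluxes).
simulate_noise_free <- function(model, protocol, times, track_fluxes = FALSE) {
  brk <- system_breakpoints(model, protocol)
  pts <- sort(unique(c(times, brk)))
  x <- stats::setNames(numeric(length(model$pools)), model$pools)
  tag_edges <- which(model$edges$sink == model$tag_pool)
  fl <- stats::setNames(numeric(length(tag_edges)),
                        if (length(tag_edges)) {
                          paste0(model$edges$source[tag_edges], "->",
                                 model$edges$sink[tag_edges])
                        } else character(0))
  traj <- matrix(NA_real_, length(pts), length(x),
                 dimnames = list(NULL, names(x)))
  fluxes <- matrix(NA_real_, length(pts), length(fl),
                   dimnames = list(NULL, names(fl)))
  at_start <- pts == pts[1L]
  traj[at_start, ] <- rep(x, each = sum(at_start))
  fluxes[at_start, ] <- rep(fl, each = sum(at_start))
  pieces <- cbind(utils::head(brk, -1L), utils::tail(brk, -1L))
  for (k in seq_len(nrow(pieces))) {
    t0 <- pieces[k, 1L]; t1 <- pieces[k, 2L]
    mid <- (t0 + t1) / 2
    tag_active <- mid >= model$tag_onset_lag
    A <- rate_matrix(model, tag_active)
    u <- forcing_vector(model,
                        activity = activity_at(model$input_activity, mid),
                        label_on = mid >= protocol$label_start &&
                          mid < protocol$label_end,
                        tag_active = tag_active)
    inside <- pts[pts > t0 & pts <= t1]
    seg_times <- unique(c(t0, inside, t1))
    if (track_fluxes && length(fl)) {
      yy <- c(x, fl)
      rhs <- function(t, y, parms) {
        xx <- y[seq_along(x)]
        dx <- parms$A %*% xx + parms$u
        df <- vapply(tag_edges, function(i) {
          src <- model$edges$source[i]
          r <- if (parms$tag_active) model$edges$rate[i] else 0
          if (src == model$external_pool) {
            if (parms$label_on) {
              r * parms$activity * model$external_value
            } else 0
          } else r * xx[src]
        }, numeric(1))
        list(c(as.numeric(dx), df))
      }
      out <- deSolve::lsoda(yy, seg_times, rhs,
                            parms = list(A = A, u = u, tag_active = tag_active,
                                         label_on = mid >= protocol$label_start &&
                                           mid < protocol$label_end,
                                         activity = activity_at(model$input_activity, mid)),
                            rtol = 1e-10, atol = 1e-12)
      res <- out[, -1L, drop = FALSE]
      x <- stats::setNames(res[nrow(res), seq_along(x)], names(x))
      fl <- stats::setNames(res[nrow(res), length(x) + seq_along(fl)], names(fl))
      if (length(inside)) {
        rows <- match(inside, pts)
        seg_rows <- match(inside, seg_times)
        traj[rows, ] <- res[seg_rows, seq_along(x), drop = FALSE]
        fluxes[rows, ] <- res[seg_rows, length(x) + seq_along(fl), drop = FALSE]
      }
    } else {
      res <- integrate_constant(A, u, x, seg_times)
      x <- stats::setNames(res[nrow(res), ], names(x))
      if (length(inside)) {
        rows <- match(inside, pts)
        traj[rows, ] <- res[match(inside, seg_times), , drop = FALSE]
        fluxes[rows, ] <- rep(fl, each = length(rows))
      }
    }
  }
  keep <- match(times, pts)
  list(times = times,
       pools = traj[keep, , drop = FALSE],
       fluxes = fluxes[keep, , drop = FALSE])
}

tracer_units <- function(tracer) {
  switch(tracer,
         bicarbonate = "nmol_C_per_1e6_cells",
         palmitic_acid = "pmol_PlA_per_1e6_cells",
         stop_config("unknown tracer '%s'", tracer))
}

#' Simulate a pulse-chase labeling experiment
#'
#' Integrates the pool model under a labeling protocol (external pool clamped
#' to full label during the labeling window, zero afterwards) and draws
#' replicate measurements by perturbing the noise-free value multiplicatively
#' with Gaussian noise of coefficient of variation `noise_cv`, truncated at
#' zero. Identical arguments and seed give bit-identical output.
#'
#' @param model A [pool_model()].
#' @param protocol A [labeling_protocol()].
#' @param grid Sampling days, within `[label_start, chase_end]`.
#' @param noise_cv Replicate coefficient of variation (>= 0; default 0.10).
#' @param n_replicates Replicates per (pool, day) (default 3).
#' @param seed Integer seed for the noise draws.
#' @param pools Pools to report (default all internal pools).
#' @param derived_pools Optional named list of pool sums to report in
#'   addition, e.g. `list(total_lipid = c("polar_lipid", "TAG"))`; derived
#'   pools receive their own measurement noise.
#' @param experiment Experiment identifier stored in the output.
#' @param track_fluxes Also accumulate label flux along each edge into the
#'   TAG pool (kept in `attr(, "fluxes")`; used for diagnostics).
#' @return A `timecourse` data frame with columns `experiment`, `tracer`,
#'   `pool`, `day`, `replicate`, `value`, `units`; the noise-free trajectory,
#'   model, and protocol are kept as attributes.
#' @export
simulate_pulse_chase <- function(model, protocol, grid,
                                 noise_cv = 0.10, n_replicates = 3,
                                 seed = 1, pools = model$pools,
                                 derived_pools = NULL,
                                 experiment = "sim",
                                 track_fluxes = FALSE) {
  stopifnot(inherits(model, "pool_model"), inherits(protocol, "labeling_protocol"))
  if (any(grid < protocol$label_start) || any(grid > protocol$chase_end)) {
    stop_input("sampling grid must lie within [label_start, chase_end]")
  }
  grid <- sort(unique(grid))
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  if (n_replicates < 1) stop_input("n_replicates must be >= 1")
  bad <- setdiff(pools, model$pools)
  if (length(bad)) stop_input("unknown pool(s): %s", paste(bad, collapse = ", "))

  sim <- simulate_noise_free(model, protocol, times = grid,
                             track_fluxes = track_fluxes)
  nf <- sim$pools[, pools, drop = FALSE]
  if (!is.null(derived_pools)) {
    for (nm in names(derived_pools)) {
      members <- derived_pools[[nm]]
      bad <- setdiff(members, model$pools)
      if (length(bad)) stop_input("derived pool '%s' uses unknown pools", nm)
      nf <- cbind(nf, rowSums(sim$pools[, members, drop = FALSE]))
      colnames(nf)[ncol(nf)] <- nm
    }
  }

  set.seed(seed)
  all_pools <- colnames(nf)
  rows <- expand.grid(replicate = seq_len(n_replicates), day = grid,
                      pool = all_pools, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  base <- nf[cbind(match(rows$day, grid), match(rows$pool, all_pools))]
  if (noise_cv > 0) {
    value <- pmax(0, base * (1 + stats::rnorm(nrow(rows), 0, noise_cv)))
  } else {
    value <- base
  }
  df <- data.frame(experiment = experiment, tracer = protocol$tracer,
                   pool = rows$pool, day = rows$day,
                   replicate = rows$replicate, value = value,
                   units = tracer_units(protocol$tracer),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pool, df$day, df$replicate), ]
  rownames(df) <- NULL
  new_timecourse(df, protocol = protocol, model = model,
                 noise_free = cbind(day = grid, nf),
                 fluxes = if (track_fluxes) cbind(day = grid, sim$fluxes))
}

new_timecourse <- function(df, protocol = NULL, model = NULL,
                           noise_free = NULL, fluxes = NULL) {
  structure(df, class = c("timecourse", "data.frame"),
            protocol = protocol, model = model,
            noise_free = noise_free, fluxes = fluxes)
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Pulse-chase time course '%s' (%s): %d pools, %d days, %d replicates\n",
              x$experiment[1], x$tracer[1], length(unique(x$pool)),
              length(unique(x$day)), length(unique(x$replicate))))
  NextMethod()
}

# Replicate means on the (pool x day) grid, as a days-by-pools matrix.
pool_means <- function(tc, pools = NULL) {
  stopifnot(is.data.frame(tc))
  if (is.null(pools)) pools <- unique(tc$pool)
  miss <- setdiff(pools, unique(tc$pool))
  if (length(miss)) stop_input("pool(s) not in time course: %s",
                               paste(miss, collapse = ", "))
  days <- sort(unique(tc$day))
  m <- matrix(NA_real_, length(days), length(pools),
              dimnames = list(NULL, pools))
  for (p in pools) {
    sub <- tc[tc$pool == p, ]
    agg <- tapply(sub$value, sub$day, mean)
    m[match(as.numeric(names(agg)), days), p] <- agg
  }
  if (anyNA(m)) stop_input("missing (pool, day) combinations in time course")
  list(days = days, means = m)
}
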