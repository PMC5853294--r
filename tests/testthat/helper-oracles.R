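# Independent oracles and tiny fixture builders used across the suite.

# Matrix-exponential solution of dx/dt = A x + u via the augmented-matrix
# trick; independent of the package's ODE integration path.
expm_solution <- function(A, x0, t, u = NULL) {
  n <- nrow(A)
  if (is.null(u)) u <- numeric(n)
  M <- rbind(cbind(A, u), 0)
  as.numeric(Matrix::expm(M * t) %*% c(x0, 1))[seq_len(n)]
}

# Bateman closed form for ext -> A -> B with A decaying at k1 into B, B
# decaying at k2 (no input), starting from (a0, b0).
bateman_two_pool <- function(a0, b0, k1, k2, t) {
  a <- a0 * exp(-k1 * t)
  b <- if (abs(k1 - k2) > 1e-12) {
    b0 * exp(-k2 * t) + a0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  } else {
    b0 * exp(-k2 * t) + a0 * k1 * t * exp(-k1 * t)
  }
  cbind(A = a, B = b)
}

# Hand-built time course: `values` is a named list pool -> numeric vector
# over `days`; replicates get identical values unless noise_sd > 0.
make_tc <- function(values, days, n_replicates = 1, tracer = "bicarbonate",
                    experiment = "toy", label_end = NULL) {
  rows <- do.call(rbind, lapply(names(values), function(p) {
    stopifnot(length(values[[p]]) == length(days))
    expand.grid(pool = p, day = days, replicate = seq_len(n_replicates),
                stringsAsFactors = FALSE)
  }))
  rows$value <- mapply(function(p, d) values[[p]][match(d, days)],
                       rows$pool, rows$day)
  df <- data.frame(experiment = experiment, tracer = tracer,
                   pool = rows$pool, day = rows$day,
                   replicate = rows$replicate, value = rows$value,
                   units = if (tracer == "bicarbonate") {
                     "nmol_C_per_1e6_cells"
                   } else "pmol_PlA_per_1e6_cells",
                   stringsAsFactors = FALSE)
  tc <- tagflux:::new_timecourse(df)
  if (!is.null(label_end)) {
    attr(tc, "protocol") <- labeling_protocol(tracer, label_end - 1,
                                              label_end, max(days))
  }
  tc
}

# A minimal two-internal-pool chain: external -> S (k_up) -> T (k_out), with
# the TAG gate disabled unless asked for.
chain_model <- function(k_up = 2, k_out = 0.7, lag = 0, tag_pool = "none") {
  pool_model(pools = c("S", "T"),
             edges = data.frame(source = c("ext", "S"),
                                sink = c("S", "T"),
                                rate = c(k_up, k_out)),
             external_pool = "ext", external_value = 1,
             input_activity = constant_activity(1),
             tag_onset_lag = lag, tag_pool = tag_pool)
}

# Reference daily pathway table shipped with the package.
read_reference_table <- function() {
  path <- system.file("extdata", "daily_tag_pathways.tsv", package = "tagflux")
  utils::read.delim(path, comment.char = "#")
}
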