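## Seeded evaluation that never clobbers the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Deterministic per-batch seed stream, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 100003) %% 2147483647)
}

#' Kinetics configuration for the fed-batch fermentation simulator
#'
#' Describes one simulated cultivation: total duration, sampling grid, the
#' hours at which the process switches phase (cell proliferation, fed-batch
#' transition, protein induction), per-phase specific growth rates, product
#' yield during induction, the methanol feed rate, and measurement noise.
#'
#' @param duration_h total run length in hours.
#' @param sample_interval_h off-line sampling interval in hours; the number
#'   of samples per batch is `duration_h / sample_interval_h + 1`.
#' @param phase_boundaries_h strictly increasing hours, inside
#'   `(0, duration_h)`, at which the process changes phase.  The default two
#'   boundaries give three phases of equal length.
#' @param growth_rate_per_phase specific biomass growth/approach rate (1/h),
#'   one per phase.
#' @param initial_biomass starting biomass concentration (ug/mL).
#' @param biomass_capacity carrying capacity of the logistic fed-batch rise
#'   (ug/mL).
#' @param product_yield specific product formation rate during induction
#'   (U/mL per ug/mL biomass per hour).
#' @param methanol_feed_rate methanol feed rate during induction (g/L/h).
#' @param noise_sd_aux measurement noise SD per auxiliary channel (recycled
#'   to `n_aux_features`); all entries must be >= 0.
#' @param noise_sd_target assay noise SD per target variable (length 3:
#'   biomass, inulinase, methanol).
#' @param n_aux_features number of auxiliary channels (default 9).
#' @param seed integer seed; all randomness in a campaign derives from it.
#' @return an object of class `ferm_kinetics` (a validated list).
#' @seealso [simulate_batch()], [simulate_campaign()]
#' @export
kinetics_config <- function(duration_h = 240,
                            sample_interval_h = 4,
                            phase_boundaries_h = c(80, 160),
                            growth_rate_per_phase = c(0.010, 0.060, 0.010),
                            initial_biomass = 5,
                            biomass_capacity = 150,
                            product_yield = 2.5e-4,
                            methanol_feed_rate = 0.35,
                            noise_sd_aux = c(0.10, 0.02, 1.5, 0.03, 0.015,
                                             5, 0.05, 0.03, 0.01),
                            noise_sd_target = c(1.0, 0.03, 0.12),
                            n_aux_features = 9,
                            seed = 42L) {
  bad <- function(field, why) {
    stop(sprintf("invalid kinetics config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(duration_h) || length(duration_h) != 1 || duration_h <= 0)
    bad("duration_h", "must be a positive scalar")
  if (!is.numeric(sample_interval_h) || sample_interval_h <= 0)
    bad("sample_interval_h", "must be a positive scalar")
  if (abs(duration_h / sample_interval_h -
          round(duration_h / sample_interval_h)) > 1e-9)
    bad("sample_interval_h", "must divide duration_h")
  if (any(diff(phase_boundaries_h) <= 0))
    bad("phase_boundaries_h", "must be strictly increasing")
  if (any(phase_boundaries_h <= 0) || any(phase_boundaries_h >= duration_h))
    bad("phase_boundaries_h", "must lie strictly inside (0, duration_h)")
  n_phase <- length(phase_boundaries_h) + 1
  if (length(growth_rate_per_phase) != n_phase)
    bad("growth_rate_per_phase", "must have one rate per phase")
  if (any(!is.finite(growth_rate_per_phase)))
    bad("growth_rate_per_phase", "must be finite")
  if (!is.finite(product_yield) || !is.finite(methanol_feed_rate))
    bad("product_yield", "and methanol_feed_rate must be finite")
  if (initial_biomass <= 0) bad("initial_biomass", "must be > 0")
  if (biomass_capacity <= initial_biomass)
    bad("biomass_capacity", "must exceed initial_biomass")
  if (any(noise_sd_aux < 0)) bad("noise_sd_aux", "must be >= 0")
  if (length(noise_sd_target) != 3 || any(noise_sd_target < 0))
    bad("noise_sd_target", "must be 3 SDs >= 0")
  if (n_aux_features < 1) bad("n_aux_features", "must be >= 1")
  structure(list(
    duration_h = duration_h,
    sample_interval_h = sample_interval_h,
    phase_boundaries_h = phase_boundaries_h,
    growth_rate_per_phase = growth_rate_per_phase,
    initial_biomass = initial_biomass,
    biomass_capacity = biomass_capacity,
    product_yield = product_yield,
    methanol_feed_rate = methanol_feed_rate,
    noise_sd_aux = rep_len(noise_sd_aux, n_aux_features),
    noise_sd_target = noise_sd_target,
    n_aux_features = as.integer(n_aux_features),
    seed = as.integer(seed)
  ), class = "ferm_kinetics")
}

#' Batch-to-batch heterogeneity configuration
#'
#' Multiplicative deviations of one batch from the nominal kinetics:
#' a scale on the inoculum (initial biomass), a scale on the methanol feed
#' rate, and a relative jitter SD applied to the per-phase growth rates.
#' The magnitudes used for target batches follow the reported regime of a
#' 10 % lower inoculum and 5 % higher methanol feed.
#'
#' @param initial_biomass_scale multiplicative factor on initial biomass.
#' @param feed_rate_scale multiplicative factor on the methanol feed rate.
#' @param kinetic_jitter_sd relative SD of lognormal-style jitter on the
#'   per-phase growth rates (0 disables jitter).
#' @return an object of class `ferm_heterogeneity`.
#' @export
heterogeneity_config <- function(initial_biomass_scale = 1,
                                 feed_rate_scale = 1,
                                 kinetic_jitter_sd = 0) {
  if (initial_biomass_scale <= 0 || feed_rate_scale <= 0)
    stop("invalid heterogeneity config: scales must be > 0", call. = FALSE)
  if (kinetic_jitter_sd < 0)
    stop("invalid heterogeneity config: field 'kinetic_jitter_sd' must be >= 0",
         call. = FALSE)
  structure(list(initial_biomass_scale = initial_biomass_scale,
                 feed_rate_scale = feed_rate_scale,
                 kinetic_jitter_sd = kinetic_jitter_sd),
            class = "ferm_heterogeneity")
}

## Phase index (1-based) of each time point given the boundary hours.
phase_of <- function(time_h, boundaries) {
  findInterval(time_h, boundaries, left.open = TRUE) + 1L
}

## Noiseless piecewise process model.  Phase 1: slow exponential growth on
## glycerol batch medium; phase 2: logistic fed-batch rise; phase 3: biomass
## plateau, product formation proportional to biomass, methanol balance of
## feed minus consumption with a 24-h feed-cycle oscillation.
ferm_trajectory <- function(cfg, het, mu) {
  t <- seq(0, cfg$duration_h, by = cfg$sample_interval_h)
  b <- cfg$phase_boundaries_h
  n_phase <- length(b) + 1
  t1 <- b[1]
  t2 <- b[length(b)]
  X0 <- cfg$initial_biomass * het$initial_biomass_scale
  Xmax <- cfg$biomass_capacity

  X <- numeric(length(t))
  ph <- phase_of(t, b)
  ## phase 1: exponential
  X[ph == 1L] <- X0 * exp(mu[1] * t[ph == 1L])
  X_t1 <- X0 * exp(mu[1] * t1)
  ## middle phase(s): logistic toward capacity
  A <- Xmax / X_t1 - 1
  mid <- ph > 1L & ph < n_phase
  X[mid] <- Xmax / (1 + A * exp(-mu[2] * (t[mid] - t1)))
  X_t2 <- Xmax / (1 + A * exp(-mu[2] * (t2 - t1)))
  ## last phase: exponential approach to capacity (plateau)
  last <- ph == n_phase
  X[last] <- Xmax - (Xmax - X_t2) * exp(-mu[n_phase] * (t[last] - t2))

  ## product accumulates only during induction: dP/dt = qp * X
  P <- numeric(length(t))
  if (any(last)) {
    idx <- which(last)
    dt <- cfg$sample_interval_h
    acc <- 0
    prevX <- X_t2
    for (i in idx) {
      acc <- acc + cfg$product_yield * 0.5 * (prevX + X[i]) * dt
      P[i] <- acc
      prevX <- X[i]
    }
  }

  ## methanol: feed (scaled) minus first-order consumption -> saturating
  ## level with a 24-h oscillation from the feed schedule
  k_cons <- 0.044                      # 1/h methanol consumption constant
  feed <- cfg$methanol_feed_rate * het$feed_rate_scale
  M <- numeric(length(t))
  tau <- (t[last] - t2)
  M[last] <- feed / k_cons * (1 - exp(-k_cons * tau)) +
    0.6 * sin(2 * pi * tau / 24) * (1 - exp(-tau / 8))

  ## instantaneous growth rate for the base-addition channel
  dX <- c(0, diff(X)) / cfg$sample_interval_h

  list(t = t, phase = ph, X = X, P = P, M = M, dX = dX,
       feed = feed, t1 = t1, t2 = t2)
}

## Nine engineered auxiliary channels: setpoint-controlled environmental
## variables with distinct per-phase signatures plus smooth within-phase
## dynamics.  Extra channels beyond 9 are harmonic time encodings.
ferm_aux <- function(cfg, tr) {
  t <- tr$t; ph <- tr$phase
  b <- c(0, cfg$phase_boundaries_h, cfg$duration_h)
  ## time-in-phase in [0, 1)
  u <- (t - b[ph]) / (b[ph + 1] - b[ph])
  pick <- function(v) v[pmin(ph, length(v))]

  temp <- pick(c(30, 30, 28)) + 0.15 * sin(2 * pi * t / 48)
  pH <- pick(c(5.0, 5.3, 6.0)) + 0.08 * u
  do_pct <- pick(c(80, 30, 35)) + 5 * exp(-5 * u) -
    3 * sin(2 * pi * (t - tr$t2) / 24) * (ph == max(ph))
  gly_feed <- ifelse(ph == 2L, 0.5 + 0.4 * u, 0)
  meoh_feed <- ifelse(ph == max(ph),
                      tr$feed * (1 + 0.15 * sin(2 * pi * (t - tr$t2) / 24)),
                      0)
  agitation <- pick(c(500, 800, 700))
  base_add <- 2 * tr$dX
  airflow <- pick(c(1.0, 1.5, 2.0))

  base9 <- cbind(temp, pH, do_pct, gly_feed, meoh_feed,
                 agitation, base_add, airflow, u)
  p <- cfg$n_aux_features
  if (p <= 9) {
    A <- base9[, seq_len(p), drop = FALSE]
  } else {
    extra <- sapply(seq_len(p - 9), function(j)
      sin(2 * pi * (j + 1) * t / cfg$duration_h))
    A <- cbind(base9, extra)
  }
  colnames(A) <- paste0("aux_", seq_len(p))
  A
}

#' Simulate one fed-batch fermentation batch
#'
#' Generates a single batch of multi-phase fermentation data on a regular
#' sampling grid: auxiliary (easy-to-measure) process channels and the three
#' soft-sensor targets — biomass (ug/mL), inulinase activity (U/mL) and
#' methanol concentration (g/L) — plus the ground-truth phase label of every
#' sample.  Measurement noise is additive Gaussian, truncated at zero for
#' non-negative quantities.  The result is bit-reproducible for a fixed
#' seed, and with all noise SDs zero and unit heterogeneity the output is
#' independent of the seed.
#'
#' @param cfg a [kinetics_config()].
#' @param het a [heterogeneity_config()].
#' @param batch_id character id stored with the batch.
#' @param seed optional integer overriding `cfg$seed` for this batch.
#' @return an object of class `ferm_batch`: list with `batch_id`, `time_h`,
#'   `X_aux` (samples x features), `Y_target` (samples x 3, columns
#'   `biomass`, `inulinase`, `methanol`) and integer `phase_label`.
#' @examples
#' b <- simulate_batch(kinetics_config(), heterogeneity_config(), "b1")
#' nrow(b$X_aux)  # 61 samples at 4-h spacing over 240 h
#' @export
simulate_batch <- function(cfg, het = heterogeneity_config(),
                           batch_id = "batch", seed = cfg$seed) {
  stopifnot(inherits(cfg, "ferm_kinetics"), inherits(het, "ferm_heterogeneity"))
  with_seed(seed, {
    n_phase <- length(cfg$phase_boundaries_h) + 1
    jit <- exp(stats::rnorm(n_phase, 0, 1) * het$kinetic_jitter_sd)
    mu <- cfg$growth_rate_per_phase * jit
    tr <- ferm_trajectory(cfg, het, mu)
    A <- ferm_aux(cfg, tr)
    n <- length(tr$t)
    noiseA <- matrix(stats::rnorm(n * ncol(A)), n) *
      rep(cfg$noise_sd_aux, each = n)
    Y <- cbind(biomass = tr$X, inulinase = tr$P, methanol = tr$M)
    noiseY <- matrix(stats::rnorm(n * 3), n) *
      rep(cfg$noise_sd_target, each = n)
    Y <- pmax(Y + noiseY, 0)          # concentrations cannot be negative
    structure(list(batch_id = batch_id,
                   time_h = tr$t,
                   X_aux = A + noiseA,
                   Y_target = Y,
                   phase_label = tr$phase),
              class = "ferm_batch")
  })
}

#' Simulate a campaign of fermentation batches
#'
#' Runs [simulate_batch()] once per batch with per-batch seeds derived
#' deterministically from `cfg$seed`, so a campaign is fully reproducible
#' from one integer.
#'
#' @param cfg a [kinetics_config()].
#' @param n_batches number of batches.
#' @param het_list list of [heterogeneity_config()] of length `n_batches`,
#'   or a single config recycled to all batches.
#' @return list of `ferm_batch` objects named `batch_1 ... batch_n`.
#' @examples
#' camp <- simulate_campaign(kinetics_config(), 3)
#' length(camp)
#' @export
simulate_campaign <- function(cfg, n_batches,
                              het_list = heterogeneity_config()) {
  if (inherits(het_list, "ferm_heterogeneity"))
    het_list <- rep(list(het_list), n_batches)
  if (length(het_list) != n_batches)
    stop("het_list must have one entry per batch", call. = FALSE)
  out <- vector("list", n_batches)
  for (k in seq_len(n_batches)) {
    out[[k]] <- simulate_batch(cfg, het_list[[k]],
                               batch_id = paste0("batch_", k),
                               seed = derive_seed(cfg$seed, k))
  }
  names(out) <- paste0("batch_", seq_len(n_batches))
  out
}

#' Default three-batch source + heterogeneous target campaign
#'
#' Convenience wrapper reproducing the standard study conditions: source
#' batches with mild batch-to-batch kinetic jitter and a target batch with
#' a 10 % lower inoculum and 5 % higher methanol feed rate.
#'
#' @param cfg a [kinetics_config()].
#' @param n_source number of source batches (default 2) in addition to the
#'   target batch.
#' @return list with elements `source` (list of batches) and `target`
#'   (one batch).
#' @export
default_campaign <- function(cfg = kinetics_config(), n_source = 2) {
  src_het <- heterogeneity_config(kinetic_jitter_sd = 0.02)
  tgt_het <- heterogeneity_config(initial_biomass_scale = 0.90,
                                  feed_rate_scale = 1.05,
                                  kinetic_jitter_sd = 0.02)
  batches <- simulate_campaign(cfg, n_source + 1,
                               c(rep(list(src_het), n_source), list(tgt_het)))
  list(source = batches[seq_len(n_source)],
       target = batches[[n_source + 1]])
}

#' Write / read one-batch CSV files
#'
#' The on-disk format is one CSV per batch with header
#' `time_h, aux_1..aux_p, biomass, inulinase, methanol, phase`; the `phase`
#' column is optional on read.
#'
#' @param batch a `ferm_batch`.
#' @param path file path.
#' @return `write_batch_csv` returns `path` invisibly; `read_batch_csv`
#'   returns a `ferm_batch`.
#' @export
write_batch_csv <- function(batch, path) {
  df <- data.frame(time_h = batch$time_h,
                   batch$X_aux,
                   batch$Y_target,
                   phase = batch$phase_label,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_batch_csv
#' @param batch_id id to assign to the batch read from `path` (defaults to
#'   the file name without extension).
#' @export
read_batch_csv <- function(path, batch_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  aux_cols <- grep("^aux_", names(df), value = TRUE)
  need <- c("time_h", "biomass", "inulinase", "methanol")
  if (!all(need %in% names(df)))
    stop("batch CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(
    batch_id = batch_id %||% sub("\\.[^.]*$", "", basename(path)),
    time_h = df$time_h,
    X_aux = as.matrix(df[aux_cols]),
    Y_target = as.matrix(df[c("biomass", "inulinase", "methanol")]),
    phase_label = if ("phase" %in% names(df)) as.integer(df$phase) else NULL
  ), class = "ferm_batch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ferm_batch <- function(x, ...) {
  cat(sprintf("<ferm_batch '%s': %d samples, %d aux features, %d phases>\n",
              x$batch_id, length(x$time_h), ncol(x$X_aux),
              if (is.null(x$phase_label)) NA_integer_
              else length(unique(x$phase_label))))
  invisible(x)
}
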