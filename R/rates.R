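# From raw batch time courses to per-phase specific rates.
#
# Biomass grows exponentially within a phase (X = exp(a + mu t)); the specific
# rate of a metabolite is the predicted concentration change over the phase
# divided by the biomass-time integral. Both come from ordinary least squares:
# mu from ln X ~ t, and q from C ~ z where z(t) is the integral of the fitted
# biomass from the phase start (a regression that is linear in its parameters
# and whose slope is q * 1, since dC/dt = q X). Endpoint predictions chain:
# the start value of phase k is the predicted final value of phase k - 1.

#' OD600 to dry cell weight
#'
#' Linear calibration X (gDCW/L) = 0.8105 * OD600 + 0.0104.
#'
#' @param od600 optical density at 600 nm (>= 0).
#' @return biomass in gDCW/L.
#' @export
od_to_dcw <- function(od600) {
  if (any(od600 < 0)) stop("od600 must be non-negative")
  0.8105 * od600 + 0.0104
}

#' Inverse of [od_to_dcw()]
#' @param dcw biomass in gDCW/L (>= 0.0104).
#' @return OD600.
#' @export
dcw_to_od <- function(dcw) {
  if (any(dcw < 0.0104)) stop("dcw below the calibration intercept")
  (dcw - 0.0104) / 0.8105
}

#' Registry of measured metabolites
#'
#' The nine substrates and five products whose specific rates constrain the
#' model, with their molar masses (g/mol, free-acid forms) and exchange
#' reaction ids in the packaged reduced network.
#' @return a data.frame with columns `name`, `exchange_id`, `molar_mass`.
#' @export
measured_metabolites <- function() {
  data.frame(
    name = c("glucose", "fructose", "citrate", "malate", "cysteine", "serine",
             "threonine", "valine", "phenylalanine",
             "mannitol", "erythritol", "l_lactate", "d_lactate", "acetate"),
    exchange_id = c("EX_glc", "EX_fru", "EX_cit", "EX_mal", "EX_cys", "EX_ser",
                    "EX_thr", "EX_val", "EX_phe",
                    "EX_mnl", "EX_eol", "EX_llac", "EX_dlac", "EX_ac"),
    molar_mass = c(180.16, 180.16, 192.12, 134.09, 121.16, 105.09,
                   119.12, 117.15, 165.19,
                   182.17, 122.12, 90.08, 90.08, 60.05),
    role = c(rep("substrate", 9), rep("product", 5)),
    stringsAsFactors = FALSE)
}

#' Convert g/L to mmol/L using the packaged molar masses
#' @param g_per_l concentration in g/L.
#' @param name metabolite name as in [measured_metabolites()].
#' @return concentration in mmol/L.
#' @export
gl_to_mmol <- function(g_per_l, name) {
  reg <- measured_metabolites()
  i <- match(name, reg$name)
  if (any(is.na(i))) stop("no molar mass for: ",
                          paste(name[is.na(i)], collapse = ", "))
  1000 * g_per_l / reg$molar_mass[i]
}

#' Construct a batch time course
#'
#' @param times sampling times in hours, strictly increasing.
#' @param concentrations named list of numeric series (mmol/L), one per
#'   metabolite, each the same length as `times`.
#' @param od600 optional OD600 series; biomass is derived via [od_to_dcw()]
#'   when `biomass` is not given.
#' @param biomass optional gDCW/L series.
#' @param ethanol_level ethanol content of the medium, % v/v (metadata).
#' @return a `timecourse` object.
#' @export
timecourse <- function(times, concentrations, od600 = NULL, biomass = NULL,
                       ethanol_level = 0) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  if (is.null(biomass)) {
    if (is.null(od600)) stop("need od600 or biomass")
    biomass <- od_to_dcw(od600)
  }
  if (is.null(od600)) od600 <- dcw_to_od(pmax(biomass, 0.0104))
  stopifnot(length(biomass) == length(times))
  if (any(biomass <= 0)) stop("biomass must be positive after inoculation")
  for (nm in names(concentrations)) {
    if (length(concentrations[[nm]]) != length(times))
      stop("series '", nm, "' length differs from times")
    if (any(concentrations[[nm]] < -1e-9))
      stop("negative concentrations in '", nm, "'")
    concentrations[[nm]] <- pmax(concentrations[[nm]], 0)
  }
  structure(list(ethanol_level = ethanol_level, times = times, od600 = od600,
                 biomass = biomass, concentrations = concentrations),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> ethanol %g%% v/v, %d samples over %g-%g h, %d metabolites\n",
              x$ethanol_level, length(x$times), min(x$times), max(x$times),
              length(x$concentrations)))
  invisible(x)
}

#' Default growth-phase boundaries (hours)
#' @return numeric vector of cut points `c(0, 48, 104, 168, 264)` delimiting
#'   phases I-IV.
#' @export
default_phase_boundaries <- function() c(0, 48, 104, 168, 264)

#' Segment a time course into growth phases
#'
#' @param tc a [timecourse()].
#' @param boundaries increasing cut points (n+1 values for n phases); default
#'   the packaged 0/48/104/168/264 h. Phases are half-open `[start, end)`,
#'   the last phase closed; phases beyond the observed time range are dropped.
#' @return data.frame with `phase_id`, `t_start`, `t_end` (class
#'   `phase_definition`).
#' @export
segment_phases <- function(tc, boundaries = default_phase_boundaries()) {
  if (any(diff(boundaries) <= 0))
    stop("phase boundaries must be strictly increasing (no gaps or overlaps)")
  if (min(tc$times) < boundaries[1])
    stop("samples before the first phase boundary")
  ph <- data.frame(phase_id = seq_len(length(boundaries) - 1),
                   t_start = boundaries[-length(boundaries)],
                   t_end = boundaries[-1])
  ph <- ph[ph$t_start < max(tc$times), , drop = FALSE]
  rownames(ph) <- NULL
  class(ph) <- c("phase_definition", "data.frame")
  ph
}

phase_window <- function(tc, phase) {
  # boundary samples inform the fits of both adjacent phases
  which(tc$times >= phase$t_start - 1e-9 & tc$times <= phase$t_end + 1e-9)
}

biomass_integral <- function(a, mu, t0, t) {
  # integral of exp(a + mu s) ds from t0 to t (exact; linear limit as mu -> 0)
  if (abs(mu) < 1e-12) exp(a) * (t - t0)
  else (exp(a + mu * t) - exp(a + mu * t0)) / mu
}

#' Estimate per-phase specific rates
#'
#' Fits `ln X ~ t` for the specific growth rate and, per metabolite,
#' `C ~ z(t)` with `z` the fitted biomass-time integral from the phase start;
#' the slope of that regression is the specific rate q (mmol/gDCW/h, negative
#' = consumption) and its value at the phase end is the endpoint prediction.
#'
#' @param tc a [timecourse()].
#' @param phase one row of [segment_phases()] output (or a list with
#'   `phase_id`, `t_start`, `t_end`).
#' @param start_values named vector of concentrations at the phase start:
#'   for phase I the initial measured concentrations (default: the first
#'   sample), for later phases the previous phase's `endpoint_predictions`.
#' @return a `rate_set`: list with `phase_id`, `mu` (1/h), `q` (named,
#'   mmol/gDCW/h), `endpoint_predictions`, `start_values`, `fit_diagnostics`
#'   (r squared and residual SD per metabolite), `biomass_fit` (`a`, `mu`),
#'   `integral_X` (gDCW h / L over the phase).
#' @export
estimate_phase_rates <- function(tc, phase, start_values = NULL) {
  idx <- phase_window(tc, phase)
  if (length(idx) < 3)
    stop("phase ", phase$phase_id, " has fewer than 3 samples")
  t <- tc$times[idx]
  X <- tc$biomass[idx]
  if (any(X <= 0)) stop("non-positive biomass inside phase ", phase$phase_id)
  bf <- stats::lm.fit(cbind(1, t), log(X))
  a <- bf$coefficients[1]; mu <- bf$coefficients[2]
  z <- vapply(t, function(tt) biomass_integral(a, mu, phase$t_start, tt),
              numeric(1))
  z_end <- biomass_integral(a, mu, phase$t_start, phase$t_end)
  if (is.null(start_values)) {
    start_values <- vapply(tc$concentrations, function(cc) cc[idx[1]],
                           numeric(1))
  }
  q <- c(); endp <- c(); r2 <- c(); rsd <- c()
  for (nm in names(tc$concentrations)) {
    y <- tc$concentrations[[nm]][idx]
    fit <- stats::lm.fit(cbind(1, z), y)
    slope <- fit$coefficients[2]
    pred_end <- fit$coefficients[1] + slope * z_end
    c0 <- if (nm %in% names(start_values)) start_values[[nm]]
          else fit$coefficients[1]
    q[nm] <- (pred_end - c0) / z_end
    endp[nm] <- pred_end
    ss_tot <- sum((y - mean(y))^2)
    r2[nm] <- if (ss_tot < 1e-12) 1 else 1 - sum(fit$residuals^2) / ss_tot
    rsd[nm] <- sqrt(sum(fit$residuals^2) / max(1, length(y) - 2))
  }
  structure(list(phase_id = phase$phase_id, mu = unname(mu), q = q,
                 endpoint_predictions = endp, start_values = start_values,
                 fit_diagnostics = data.frame(metabolite = names(r2),
                                              r_squared = unname(r2),
                                              residual_sd = unname(rsd),
                                              stringsAsFactors = FALSE),
                 biomass_fit = c(a = unname(a), mu = unname(mu)),
                 integral_X = z_end),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> phase %d: mu = %.4g 1/h, %d metabolite rates\n",
              x$phase_id, x$mu, length(x$q)))
  invisible(x)
}

#' Estimate rates for all phases of a time course
#'
#' Runs [estimate_phase_rates()] phase by phase, chaining each phase's start
#' values to the previous phase's endpoint predictions. The stationary phase
#' (IV) is segmented but excluded from downstream modeling.
#'
#' @param tc a [timecourse()].
#' @param phases output of [segment_phases()]; default segmentation of `tc`.
#' @param n_model_phases how many leading phases feed the models (default 3).
#' @return list of `rate_set`, one per modeled phase.
#' @export
estimate_all_phase_rates <- function(tc, phases = segment_phases(tc),
                                     n_model_phases = 3) {
  keep <- phases[phases$phase_id <= n_model_phases, , drop = FALSE]
  out <- list()
  start_values <- NULL
  for (i in seq_len(nrow(keep))) {
    rs <- estimate_phase_rates(tc, keep[i, ], start_values)
    out[[i]] <- rs
    start_values <- rs$endpoint_predictions
  }
  out
}

#' Build a per-phase constraint set from estimated rates
#'
#' Maps metabolite names to exchange reaction ids via
#' [measured_metabolites()] and packages the rates (and the fitted mu) as a
#' [constraint_set()].
#'
#' @param rs a `rate_set`.
#' @param tolerance relative slack around each fixed value.
#' @param fix_biomass include the fitted mu as a fixed biomass flux.
#' @return a [constraint_set()].
#' @export
rates_to_constraints <- function(rs, tolerance = 0, fix_biomass = TRUE) {
  reg <- measured_metabolites()
  known <- intersect(names(rs$q), reg$name)
  ff <- setNames(rs$q[known], reg$exchange_id[match(known, reg$name)])
  constraint_set(rs$phase_id, ff,
                 biomass = if (fix_biomass) rs$mu else NULL,
                 tolerance = tolerance)
}

# --- long-format TSV I/O ------------------------------------------------------

#' Read a time course from long-format TSV
#'
#' Expected columns: `time_h`, `variable`, `value`, and optionally
#' `ethanol_pct` and `replicate`. `variable` is `"od600"` or a metabolite name
#' (mmol/L); replicates are averaged per (time, variable).
#'
#' @param path TSV file.
#' @return a [timecourse()].
#' @export
read_timecourse <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_h", "variable", "value")
  if (!all(need %in% names(d)))
    stop("time-course TSV needs columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(value ~ time_h + variable, data = d, FUN = mean)
  times <- sort(unique(agg$time_h))
  grab <- function(v) {
    sub <- agg[agg$variable == v, ]
    sub$value[match(times, sub$time_h)]
  }
  vars <- setdiff(unique(agg$variable), "od600")
  conc <- setNames(lapply(vars, grab), vars)
  eth <- if ("ethanol_pct" %in% names(d)) d$ethanol_pct[1] else 0
  timecourse(times, conc, od600 = grab("od600"), ethanol_level = eth)
}

#' Write a time course as long-format TSV
#' @param tc a [timecourse()].
#' @param path output file.
#' @param replicate replicate label stored in the file.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, replicate = 1) {
  rows <- data.frame(time_h = tc$times, variable = "od600", value = tc$od600,
                     ethanol_pct = tc$ethanol_level, replicate = replicate)
  for (nm in names(tc$concentrations))
    rows <- rbind(rows, data.frame(time_h = tc$times, variable = nm,
                                   value = tc$concentrations[[nm]],
                                   ethanol_pct = tc$ethanol_level,
                                   replicate = replicate))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
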