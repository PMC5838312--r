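# Linear-programming layer: FBA, FVA, linear-combination FVA, NGAM estimation
# and its sensitivity analysis. All solves go through the package's dense
# bounded-variable simplex (src/simplex.cpp); single-threaded and fully
# deterministic, so repeated runs give bit-identical fluxes.

FEAS_RESIDUAL <- 1e-6

lp_run <- function(S, c_obj, lb, ub, maximize = TRUE) {
  .cpp_simplex(S, rep(0, nrow(S)), c_obj, lb, ub, maximize)
}

net_lp_parts <- function(net) {
  list(S = stoichiometric_matrix(net),
       lb = lower_bounds(net), ub = upper_bounds(net),
       ids = reaction_ids(net))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through one reaction subject to the
#' steady-state constraint `S v = 0` and the flux bounds.
#'
#' @param net a `metabolic_network`.
#' @param objective_id reaction to optimize; defaults to the network objective.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_distribution`: list with `fluxes` (named vector),
#'   `objective_id`, `objective_value`, `solver_status`. When the problem is
#'   infeasible or unbounded, `fluxes` is `NULL` and only the status is set.
#' @export
solve_fba <- function(net, objective_id = net$objective_id,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- net_lp_parts(net)
  if (!objective_id %in% p$ids) stop("unknown objective reaction: ", objective_id)
  cv <- as.numeric(p$ids == objective_id)
  r <- lp_run(p$S, cv, p$lb, p$ub, maximize = sense == "max")
  if (r$status != "optimal")
    return(structure(list(fluxes = NULL, objective_id = objective_id,
                          objective_value = NA_real_,
                          solver_status = r$status),
                     class = "flux_distribution"))
  v <- setNames(as.numeric(r$x), p$ids)
  resid <- max(abs(p$S %*% v))
  if (resid > FEAS_RESIDUAL)
    stop(sprintf("solver returned S.v residual %.2e > %.0e", resid, FEAS_RESIDUAL))
  structure(list(fluxes = v, objective_id = objective_id,
                 objective_value = r$objective, solver_status = "optimal"),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> %s: objective %s = %s\n", x$solver_status,
              x$objective_id,
              if (is.na(x$objective_value)) "NA" else
                format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum attainable flux under the network's
#' constraints. The main objective is NOT fixed at its optimum (experimental
#' data, not the objective, carry the constraints here).
#'
#' @param net a `metabolic_network`.
#' @param reaction_ids reactions to scan; defaults to all.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
solve_fva <- function(net, reaction_ids = NULL) {
  p <- net_lp_parts(net)
  if (is.null(reaction_ids)) reaction_ids <- p$ids
  bad <- setdiff(reaction_ids, p$ids)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  res <- t(vapply(reaction_ids, function(id) {
    cv <- as.numeric(p$ids == id)
    lo <- lp_run(p$S, cv, p$lb, p$ub, maximize = FALSE)
    hi <- lp_run(p$S, cv, p$lb, p$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA failed for ", id, " (status ", lo$status, "/", hi$status, ")")
    c(lo$objective, hi$objective)
  }, numeric(2)))
  data.frame(reaction_id = reaction_ids, min = res[, 1], max = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' FVA of a linear combination of fluxes
#'
#' Optimizes `sum(coefficients * v[reaction_ids])` in both senses under all
#' network constraints — used for cofactor-production sums.
#'
#' @param net a `metabolic_network`.
#' @param reaction_ids reactions entering the sum.
#' @param coefficients numeric weights, same length (default all 1).
#' @return list with `min`, `max`, and `unique` (`TRUE` when the span is below
#'   1e-6, i.e. the quantity is determined despite alternate optima).
#' @export
fva_linear_combination <- function(net, reaction_ids,
                                   coefficients = rep(1, length(reaction_ids))) {
  stopifnot(length(reaction_ids) == length(coefficients))
  p <- net_lp_parts(net)
  bad <- setdiff(reaction_ids, p$ids)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  cv <- numeric(length(p$ids))
  cv[match(reaction_ids, p$ids)] <- coefficients
  lo <- lp_run(p$S, cv, p$lb, p$ub, maximize = FALSE)
  hi <- lp_run(p$S, cv, p$lb, p$ub, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("linear-combination FVA failed (status ", lo$status, "/", hi$status, ")")
  list(min = lo$objective, max = hi$objective,
       unique = (hi$objective - lo$objective) <= 1e-6)
}

# --- experimental constraint sets --------------------------------------------

#' Per-phase experimental constraint set
#'
#' Holds the measured specific rates that get fixed in the model for one
#' growth phase: the substrate uptakes and product formation rates (keyed by
#' exchange-reaction id, signed: uptake negative), optionally the biomass flux
#' and an NGAM flux, and the relative slack applied around each "fixed" value.
#'
#' @param phase_id integer 1-3.
#' @param fixed_fluxes named numeric vector, reaction id -> value
#'   (mmol/gDCW/h).
#' @param biomass biomass flux in 1/h, or `NULL`.
#' @param ngam NGAM flux, or `NULL` (left free / to be estimated).
#' @param tolerance relative slack: each value v is bounded to
#'   `v -/+ |v| * tolerance` (exact fixing when 0, the default).
#' @return a `phase_constraints` object.
#' @export
constraint_set <- function(phase_id, fixed_fluxes, biomass = NULL, ngam = NULL,
                           tolerance = 0) {
  stopifnot(is.numeric(fixed_fluxes), !is.null(names(fixed_fluxes)),
            tolerance >= 0)
  structure(list(phase_id = as.integer(phase_id),
                 fixed_fluxes = fixed_fluxes,
                 biomass = biomass, ngam = ngam,
                 tolerance = tolerance),
            class = "phase_constraints")
}

fix_with_tolerance <- function(net, id, value, tol) {
  slack <- abs(value) * tol
  set_bounds(net, id, lower = value - slack, upper = value + slack)
}

#' Apply a constraint set to a network
#'
#' @param net a `metabolic_network`.
#' @param cs a [constraint_set()].
#' @param biomass_id,ngam_id reaction ids for biomass and NGAM.
#' @return the constrained network.
#' @export
apply_constraint_set <- function(net, cs, biomass_id = "BIOMASS",
                                 ngam_id = "ATPM") {
  stopifnot(inherits(cs, "phase_constraints"))
  missing_ids <- setdiff(names(cs$fixed_fluxes), names(net$reactions))
  if (length(missing_ids))
    stop("constraint references unknown reaction(s): ",
         paste(missing_ids, collapse = ", "))
  for (id in names(cs$fixed_fluxes))
    net <- fix_with_tolerance(net, id, cs$fixed_fluxes[[id]], cs$tolerance)
  if (!is.null(cs$biomass))
    net <- fix_with_tolerance(net, biomass_id, cs$biomass, cs$tolerance)
  if (!is.null(cs$ngam))
    net <- fix_with_tolerance(net, ngam_id, cs$ngam, cs$tolerance)
  net
}

# --- NGAM --------------------------------------------------------------------

#' Estimate non-growth-associated maintenance ATP
#'
#' Scans the NGAM flux over a grid (default 0 to 4 mmol/gDCW/h), fixes it,
#' maximizes biomass under the experimental constraints, and returns the grid
#' point with the smallest relative biomass prediction error
#' `|mu_pred - mu_exp| / mu_exp`. Ties break to the smallest NGAM.
#'
#' @param net a `metabolic_network`.
#' @param constraints a [constraint_set()] (its `ngam` slot is ignored).
#' @param mu_experimental measured specific growth rate (1/h).
#' @param grid_step grid resolution (default 0.01).
#' @param grid_max upper end of the scan (default 4).
#' @param biomass_id,ngam_id reaction ids.
#' @return an `ngam_result`: list with `ngam`, `biomass_error` (relative, %),
#'   `scan` (data.frame ngam/predicted_mu/error), `grid`.
#' @export
estimate_ngam <- function(net, constraints, mu_experimental,
                          grid_step = 0.01, grid_max = 4,
                          biomass_id = "BIOMASS", ngam_id = "ATPM") {
  stopifnot(mu_experimental > 0, grid_step > 0)
  cs <- constraints
  cs$biomass <- NULL   # biomass is the scanned objective, never fixed here
  cs$ngam <- NULL
  cnet <- apply_constraint_set(net, cs, biomass_id, ngam_id)
  p <- net_lp_parts(cnet)
  cv <- as.numeric(p$ids == biomass_id)
  k <- match(ngam_id, p$ids)
  if (is.na(k)) stop("NGAM reaction '", ngam_id, "' not in network")
  grid <- seq(0, grid_max, by = grid_step)
  mu_pred <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    lb <- p$lb; ub <- p$ub
    lb[k] <- grid[i]; ub[k] <- grid[i]
    r <- lp_run(p$S, cv, lb, ub, maximize = TRUE)
    if (r$status == "optimal") mu_pred[i] <- r$objective
  }
  if (all(is.na(mu_pred)))
    stop("all NGAM grid points infeasible; check the constraint set ",
         "(phase ", constraints$phase_id, ")")
  err <- abs(mu_pred - mu_experimental) / mu_experimental
  # parsimony tie-break: smallest NGAM whose error is within numerical noise
  # of the minimum
  best <- which(err <= min(err, na.rm = TRUE) + 1e-9)[1]
  structure(list(ngam = grid[best],
                 biomass_error = 100 * err[best],
                 scan = data.frame(ngam = grid, predicted_mu = mu_pred,
                                   error = err),
                 grid = list(lo = 0, hi = grid_max, step = grid_step)),
            class = "ngam_result")
}

#' @export
print.ngam_result <- function(x, ...) {
  cat(sprintf("<ngam_result> NGAM = %g mmol/gDCW/h (biomass error %.4g%%)\n",
              x$ngam, x$biomass_error))
  invisible(x)
}

#' NGAM sensitivity to the experimental constraints
#'
#' Re-estimates NGAM after varying each constrained rate independently by
#' +/- `perturbation` (default 1%), and reports the relative NGAM change.
#'
#' @inheritParams estimate_ngam
#' @param perturbation relative perturbation (default 0.01 = 1%).
#' @return a `sensitivity_report`: data.frame per rate with the re-estimated
#'   NGAM under each perturbation and `relative_change` (%, worst of the two
#'   directions); attribute `baseline` carries the unperturbed result and
#'   `max_change` the headline sensitivity.
#' @export
ngam_sensitivity <- function(net, constraints, mu_experimental,
                             perturbation = 0.01, grid_step = 0.01,
                             grid_max = 4, biomass_id = "BIOMASS",
                             ngam_id = "ATPM") {
  base <- estimate_ngam(net, constraints, mu_experimental, grid_step, grid_max,
                        biomass_id, ngam_id)
  rates <- names(constraints$fixed_fluxes)
  rows <- lapply(rates, function(id) {
    out <- vapply(c(1 + perturbation, 1 - perturbation), function(f) {
      cs <- constraints
      cs$fixed_fluxes[[id]] <- cs$fixed_fluxes[[id]] * f
      r <- tryCatch(estimate_ngam(net, cs, mu_experimental, grid_step,
                                  grid_max, biomass_id, ngam_id),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$ngam
    }, numeric(1))
    denom <- if (base$ngam > 0) base$ngam else grid_step
    rc <- if (all(is.na(out))) NA_real_
          else 100 * max(abs(out - base$ngam), na.rm = TRUE) / denom
    data.frame(rate_id = id, ngam_plus = out[1], ngam_minus = out[2],
               relative_change = rc, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  structure(rep, baseline = base,
            max_change = suppressWarnings(max(rep$relative_change, na.rm = TRUE)),
            class = c("sensitivity_report", "data.frame"))
}
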