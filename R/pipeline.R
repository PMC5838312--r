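# Orchestration: time courses -> per-phase rates -> extended model ->
# accumulation FVA -> split phase models -> NGAM -> per-phase FBA ->
# energetics -> (optionally) EFM table, sensitivity and flux-space sampling.

#' Fix accumulation boundary reactions at their span midpoints
#'
#' The extended-model FVA gives a span per carry-over flux; phase-level
#' estimation uses the midpoint as the package's determinate convention (see
#' the methods vignette). A small symmetric band can be kept around the
#' midpoint to absorb numerical over-determination.
#'
#' @param net a phase model from [split_into_phase_models()].
#' @param bounds an `accumulation_bounds`.
#' @param phase_id which phase `net` is.
#' @param band half-width kept around the midpoint (default 0 = fixed).
#' @return the constrained network.
#' @export
fix_accumulation_midpoints <- function(net, bounds, phase_id, band = 0) {
  mid <- (bounds$min + bounds$max) / 2
  for (i in which(bounds$from_phase == phase_id)) {
    id <- paste0("ACCD_", bounds$compound[i])
    net <- set_bounds(net, id, max(0, mid[i] - band), mid[i] + band)
  }
  for (i in which(bounds$to_phase == phase_id)) {
    id <- paste0("ACCS_", bounds$compound[i])
    net <- set_bounds(net, id, max(0, mid[i] - band), mid[i] + band)
  }
  net
}

estimate_ngam_banded <- function(net, bounds, phase_id, cs, mu_exp,
                                 grid_step = 0.01, grid_max = 4,
                                 bands = c(0, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3)) {
  for (b in bands) {
    nb <- fix_accumulation_midpoints(net, bounds, phase_id, band = b)
    r <- tryCatch(estimate_ngam(nb, cs, mu_exp, grid_step = grid_step,
                                grid_max = grid_max),
                  error = function(e) NULL)
    if (!is.null(r)) return(list(result = r, network = nb, band = b))
  }
  stop("NGAM estimation infeasible for phase ", phase_id,
       " at every accumulation band")
}

#' Run the full analysis pipeline
#'
#' Executes, per culture: rate estimation, extended-model construction and
#' constraint application, accumulation FVA, phase splitting, NGAM
#' estimation (accumulation at span midpoints), per-phase FBA with NGAM and
#' biomass fixed, and ATP/redox/proton accounting. Optionally adds the NGAM
#' sensitivity analysis, the EFM substrate-product table and flux-space
#' sampling per phase.
#'
#' @param timecourses list of [timecourse()] objects (one per ethanol level).
#' @param base the base network (default: packaged reduced model).
#' @param tolerance relative slack on the fixed experimental rates.
#' @param grid_step NGAM scan resolution (mmol/gDCW/h).
#' @param sensitivity run [ngam_sensitivity()] per phase (slow; default
#'   FALSE).
#' @param efm tabulate the substrate-product EFM counts (default TRUE).
#' @param sampling_n retained flux samples per phase (0 = skip sampling).
#' @param thinning,seed sampling parameters.
#' @param outdir if non-NULL, writes TSV/JSON artifacts there.
#' @return a `run_report` list: per culture, per phase: `rates`,
#'   `constraints`, `accumulation_bounds`, `ngam`, `flux`,
#'   `flux_per_mu` (fluxes normalized by specific growth rate), `energetics`,
#'   `redox`, `protons`, optional `sensitivity` and `flexibility`; plus
#'   `efm_table` and `provenance`.
#' @export
run_pipeline <- function(timecourses, base = load_reduced_oeni_model(),
                         tolerance = 0, grid_step = 0.01,
                         sensitivity = FALSE, efm = TRUE, sampling_n = 0,
                         thinning = 500, seed = 1, outdir = NULL) {
  if (inherits(timecourses, "timecourse")) timecourses <- list(timecourses)
  cultures <- list()
  for (tc in timecourses) {
    stopifnot(inherits(tc, "timecourse"))
    rs <- estimate_all_phase_rates(tc)
    css <- lapply(rs, rates_to_constraints, tolerance = tolerance)
    ext <- apply_experimental_constraints(build_extended_model(base, 3), css)
    ab <- fva_accumulation(ext)
    nets <- split_into_phase_models(ext, ab)
    phases <- list()
    for (k in seq_along(nets)) {
      ngb <- estimate_ngam_banded(nets[[k]], ab, k, css[[k]], rs[[k]]$mu,
                                  grid_step = grid_step)
      ng <- ngb$result
      # final FBA: experimental biomass and the estimated NGAM fixed
      # (tiny relative slack escalated as needed: the phase system is close
      # to fully determined, so exact equality can be numerically empty)
      flux <- NULL
      for (tol_fix in unique(pmax(tolerance, c(1e-4, 1e-3, 1e-2)))) {
        cs_fix <- css[[k]]
        cs_fix$ngam <- ng$ngam
        cs_fix$tolerance <- tol_fix
        fnet <- apply_constraint_set(ngb$network, cs_fix)
        flux <- solve_fba(fnet, "BIOMASS", "max")
        if (flux$solver_status == "optimal") break
      }
      if (flux$solver_status != "optimal")
        stop("phase ", k, " FBA infeasible after fixing NGAM")
      ph <- list(rates = rs[[k]], constraints = css[[k]],
                 ngam = ng, flux = flux,
                 flux_per_mu = flux$fluxes / rs[[k]]$mu,
                 energetics = atp_accounting(flux, fnet),
                 redox = redox_accounting(flux, fnet),
                 protons = proton_accounting(flux, fnet))
      if (sensitivity)
        ph$sensitivity <- ngam_sensitivity(ngb$network, css[[k]], rs[[k]]$mu,
                                           grid_step = grid_step)
      if (sampling_n > 0) {
        ss <- sample_flux_space(fnet, n_samples = sampling_n,
                                thinning = thinning, seed = seed)
        ph$flexibility <- flexibility_stats(
          ss, reactions_by_subsystem(fnet, "phosphoketolase"))
      }
      phases[[k]] <- ph
    }
    cultures[[length(cultures) + 1]] <-
      list(ethanol_level = tc$ethanol_level, phases = phases,
           accumulation_bounds = ab)
  }
  report <- list(cultures = cultures,
                 efm_table = if (efm) substrate_product_table(base) else NULL,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("oenoflux")),
                   tolerance = tolerance, grid_step = grid_step,
                   sampling = list(n = sampling_n, thinning = thinning,
                                   seed = seed),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  class(report) <- "run_report"
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d culture(s)\n", length(x$cultures)))
  for (cu in x$cultures) {
    cat(sprintf("  ethanol %g%%: NGAM = %s mmol/gDCW/h; F0F1 ATP share = %s\n",
                cu$ethanol_level,
                paste(vapply(cu$phases, function(p) sprintf("%.2f", p$ngam$ngam),
                             character(1)), collapse = "/"),
                paste(vapply(cu$phases, function(p)
                  sprintf("%.0f%%", 100 * p$energetics$fraction_f0f1),
                  character(1)), collapse = "/")))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summ <- list()
  for (cu in report$cultures) {
    key <- paste0("ethanol_", cu$ethanol_level)
    summ[[key]] <- list(
      ngam = lapply(cu$phases, function(p)
        list(value = p$ngam$ngam, biomass_error_pct = p$ngam$biomass_error)),
      mu = lapply(cu$phases, function(p) p$rates$mu),
      fraction_f0f1 = lapply(cu$phases, function(p) p$energetics$fraction_f0f1),
      q = lapply(cu$phases, function(p) as.list(p$rates$q)))
    ab <- cu$accumulation_bounds
    write.table(ab, file.path(outdir, paste0(key, "_accumulation.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    for (k in seq_along(cu$phases)) {
      f <- cu$phases[[k]]$flux$fluxes
      write.table(data.frame(reaction_id = names(f), flux = unname(f),
                             flux_per_mu = unname(cu$phases[[k]]$flux_per_mu)),
                  file.path(outdir, sprintf("%s_phase%d_flux.tsv", key, k)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(list(summary = summ, provenance = report$provenance),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$efm_table))
    write.table(cbind(substrate = rownames(report$efm_table),
                      as.data.frame(report$efm_table)),
                file.path(outdir, "efm_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(outdir)
}
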