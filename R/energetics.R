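# ATP, NAD(P)H and proton bookkeeping over a solved flux distribution.
#
# Route membership comes from role tags in the model (atp_producer_pkp,
# atp_producer_f0f1, nadh_producer, nadph_producer, proton_extruder, ...),
# never from hard-coded reaction names; every report is cross-checked against
# an independent stoichiometric audit of the cofactor species themselves.

cofactor_species <- function() {
  list(atp = "atp", nadh = "nadh", nadph = "nadph", proton_c = "h_c",
       proton_e = "h_e")
}

# production/consumption of one metabolite across all reactions, from
# stoichiometry alone (the independent audit)
species_turnover <- function(flux, net, met) {
  prod <- 0; cons <- 0
  for (r in net$reactions) {
    coef <- unname(r$stoichiometry[met])
    if (is.na(coef)) next
    rate <- coef * flux$fluxes[[r$id]]
    if (rate > 0) prod <- prod + rate else cons <- cons - rate
  }
  c(production = prod, consumption = cons)
}

role_flux_sum <- function(flux, net, tag, met) {
  ids <- reactions_by_role(net, tag)
  if (!length(ids))
    stop("network carries no '", tag, "' role tags; annotate the model first")
  per <- vapply(ids, function(id) {
    coef <- net$reactions[[id]]$stoichiometry[met]
    if (is.na(coef)) 0 else max(coef * flux$fluxes[[id]], 0)
  }, numeric(1))
  per
}

#' Audit cofactor conservation of a flux distribution
#'
#' Computes, from stoichiometry alone, production and consumption of ATP,
#' NADH, NADPH and cytosolic protons; at steady state each pair must match.
#'
#' @param flux a `flux_distribution`.
#' @param net the network it was solved on.
#' @param tol imbalance tolerance (default 1e-6).
#' @return data.frame with `species`, `production`, `consumption`,
#'   `imbalance`; attribute `balanced` is `TRUE` when all imbalances are
#'   within `tol`.
#' @export
audit_conservation <- function(flux, net, tol = 1e-6) {
  sp <- c("atp", "nadh", "nadph", "h_c")
  rows <- lapply(sp, function(m) {
    t <- species_turnover(flux, net, m)
    data.frame(species = m, production = t[["production"]],
               consumption = t[["consumption"]],
               imbalance = t[["production"]] - t[["consumption"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "balanced") <- all(abs(out$imbalance) <= tol)
  out
}

#' ATP route accounting
#'
#' Splits ATP production between the F0F1-ATPase and the three
#' substrate-level kinases of the phosphoketolase pathway (acetate kinase,
#' pyruvate kinase, 3-phosphoglycerate kinase), and itemizes consumers.
#'
#' @param flux a `flux_distribution`.
#' @param net the network it was solved on (role tags required).
#' @return an `energetics_report`: list with `r_atp_f0f1`, `r_atp_pkp`,
#'   `r_atp_total`, `fraction_f0f1`, `ngam_flux`, `producers` and `consumers`
#'   breakdowns.
#' @export
atp_accounting <- function(flux, net) {
  stopifnot(inherits(flux, "flux_distribution"), !is.null(flux$fluxes))
  pkp <- role_flux_sum(flux, net, "atp_producer_pkp", "atp")
  f0f1 <- role_flux_sum(flux, net, "atp_producer_f0f1", "atp")
  r_pkp <- sum(pkp); r_f0f1 <- sum(f0f1)
  total <- r_pkp + r_f0f1
  # consumers itemized from stoichiometry
  cons <- c()
  for (r in net$reactions) {
    coef <- r$stoichiometry["atp"]
    if (is.na(coef)) next
    rate <- coef * flux$fluxes[[r$id]]
    if (rate < -1e-12) cons[r$id] <- -rate
  }
  audit <- audit_conservation(flux, net)
  atp_prod_audit <- audit$production[audit$species == "atp"]
  if (abs(atp_prod_audit - total) > 1e-6)
    warning("role-tagged ATP producers disagree with the stoichiometric audit (",
            format(total), " vs ", format(atp_prod_audit), ")")
  ngam_ids <- reactions_by_subsystem(net, "NGAM")
  structure(list(r_atp_f0f1 = r_f0f1, r_atp_pkp = r_pkp, r_atp_total = total,
                 fraction_f0f1 = if (total > 0) r_f0f1 / total else NA_real_,
                 ngam_flux = if (length(ngam_ids))
                   sum(unlist(flux$fluxes[ngam_ids])) else NA_real_,
                 producers = c(f0f1, pkp), consumers = cons,
                 audit = audit),
            class = "energetics_report")
}

#' @export
print.energetics_report <- function(x, ...) {
  cat(sprintf("<energetics_report> ATP: F0F1 %.4g + PKP %.4g = %.4g (F0F1 share %.1f%%)\n",
              x$r_atp_f0f1, x$r_atp_pkp, x$r_atp_total, 100 * x$fraction_f0f1))
  invisible(x)
}

#' NADH/NADPH accounting
#'
#' Per-enzyme production of NADH and NADPH over the role-tagged producer
#' sets, plus the share of NAD(P)+ regeneration attributable to mannitol and
#' erythritol formation (computed from stoichiometry: reoxidation flux of
#' reactions producing those polyols divided by total reoxidation).
#'
#' @inheritParams atp_accounting
#' @return a `redox_report`: list with `nadh_production`, `nadph_production`
#'   (named per reaction), `totals`, `regeneration_share`, `audit`.
#' @export
redox_accounting <- function(flux, net) {
  stopifnot(inherits(flux, "flux_distribution"), !is.null(flux$fluxes))
  nadh <- role_flux_sum(flux, net, "nadh_producer", "nadh")
  nadph <- role_flux_sum(flux, net, "nadph_producer", "nadph")
  # reoxidation by polyol formation vs total reoxidation
  polyol_reox <- 0; total_reox <- 0
  for (r in net$reactions) {
    v <- flux$fluxes[[r$id]]
    used <- 0
    for (m in c("nadh", "nadph")) {
      coef <- r$stoichiometry[m]
      if (!is.na(coef)) {
        rate <- coef * v
        if (rate < 0) used <- used - rate
      }
    }
    if (used > 0) {
      total_reox <- total_reox + used
      prod_mets <- names(r$stoichiometry)[r$stoichiometry * sign(v) > 0]
      if (any(prod_mets %in% c("mnl_c", "mnl1p", "ery4p", "eol_c")))
        polyol_reox <- polyol_reox + used
    }
  }
  audit <- audit_conservation(flux, net)
  structure(list(nadh_production = nadh, nadph_production = nadph,
                 totals = c(nadh = sum(nadh), nadph = sum(nadph),
                            nadph_plus_nadh = sum(nadh) + sum(nadph)),
                 regeneration_share = if (total_reox > 0)
                   unname(polyol_reox / total_reox) else NA_real_,
                 audit = audit),
            class = "redox_report")
}

#' @export
print.redox_report <- function(x, ...) {
  cat(sprintf("<redox_report> NADH %.4g, NADPH %.4g; polyol share of NAD(P)+ regeneration %.1f%%\n",
              x$totals[["nadh"]], x$totals[["nadph"]],
              100 * x$regeneration_share))
  invisible(x)
}

#' Proton balance accounting
#'
#' Itemizes membrane proton movement and cytosolic consumption relative to
#' the F0F1-ATPase influx: the fraction re-extruded by the malolactic
#' reaction plus lactate/H+ symport, and the fraction consumed by diacetyl
#' formation (both decarboxylation steps).
#'
#' @inheritParams atp_accounting
#' @return a `proton_report`: list with `protons_in_f0f1`,
#'   `protons_out_mlf_lactate`, `protons_consumed_diacetyl`,
#'   `fraction_mlf_lactate`, `fraction_diacetyl`, `extruders` (per-reaction),
#'   `audit`.
#' @export
proton_accounting <- function(flux, net) {
  stopifnot(inherits(flux, "flux_distribution"), !is.null(flux$fluxes))
  if (!any(c("h_c", "h_e") %in% net$metabolites$id))
    stop("network lacks explicit proton species")
  h_in_f0f1 <- 0
  for (id in reactions_by_role(net, "atp_producer_f0f1")) {
    coef <- net$reactions[[id]]$stoichiometry["h_e"]
    if (!is.na(coef)) {
      v <- flux$fluxes[[id]]
      moved <- unname(-coef * v)  # protons taken from outside when synthesizing
      if (moved > 0) h_in_f0f1 <- h_in_f0f1 + moved
    }
  }
  # MLF decarboxylation consumes one cytosolic proton per turnover
  mlf_h <- 0
  for (id in reactions_by_subsystem(net, "MLF")) {
    coef <- net$reactions[[id]]$stoichiometry["h_c"]
    if (!is.na(coef) && coef < 0)
      mlf_h <- mlf_h + max(unname(-coef * flux$fluxes[[id]]), 0)
  }
  extr <- c()
  for (id in reactions_by_role(net, "proton_extruder")) {
    coef <- net$reactions[[id]]$stoichiometry["h_e"]
    if (!is.na(coef)) extr[id] <- max(coef * flux$fluxes[[id]], 0)
  }
  # lactate/H+ symport = extruders touching L-lactate
  lac_ext <- 0
  for (id in names(extr)) {
    if (any(grepl("^llac", names(net$reactions[[id]]$stoichiometry))))
      lac_ext <- lac_ext + extr[[id]]
  }
  diact_h <- 0
  for (r in net$reactions) {
    coef <- r$stoichiometry["h_c"]
    if (is.na(coef) || coef >= 0) next
    prods <- names(r$stoichiometry)[r$stoichiometry > 0]
    if (any(prods %in% c("alac", "diact_c")))
      diact_h <- diact_h + max(unname(-coef * flux$fluxes[[r$id]]), 0)
  }
  out_mlf_lac <- mlf_h + lac_ext
  aud <- audit_conservation(flux, net)
  h_cons <- aud$consumption[aud$species == "h_c"]
  structure(list(protons_in_f0f1 = h_in_f0f1,
                 protons_out_mlf_lactate = out_mlf_lac,
                 protons_consumed_diacetyl = diact_h,
                 # fractions on the translocated-proton basis (as reported in
                 # the malolactic literature) ...
                 fraction_mlf_lactate = if (h_in_f0f1 > 0)
                   out_mlf_lac / h_in_f0f1 else NA_real_,
                 fraction_diacetyl = if (h_in_f0f1 > 0)
                   diact_h / h_in_f0f1 else NA_real_,
                 # ... and shares of total cytosolic proton consumption,
                 # which sum to one over all consuming routes
                 consumption_shares = if (h_cons > 0)
                   c(mlf_lactate = out_mlf_lac / h_cons,
                     diacetyl = diact_h / h_cons) else
                   c(mlf_lactate = NA_real_, diacetyl = NA_real_),
                 extruders = extr,
                 audit = aud),
            class = "proton_report")
}

#' @export
print.proton_report <- function(x, ...) {
  cat(sprintf("<proton_report> F0F1 influx %.4g; MLF+lactate share %.1f%%, diacetyl share %.1f%%\n",
              x$protons_in_f0f1, 100 * x$fraction_mlf_lactate,
              100 * x$fraction_diacetyl))
  invisible(x)
}
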