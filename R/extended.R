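# The extended multi-phase stoichiometric system: three copies of the base
# network stacked block-diagonally, coupled by irreversible accumulation
# reactions that carry a compound from the cytosol of one phase to the cytosol
# of the next (e.g. mannitol_p1 -> mannitol_p2). Steady state S v = 0 holds
# for the whole stacked system, so material accumulated in one phase is
# consumed in the next instead of violating the per-phase balance.

#' Default accumulation compounds
#'
#' The six compounds observed to accumulate intracellularly between growth
#' phases I->II and II->III: mannitol, malate, cysteine, threonine,
#' phenylalanine, valine.
#' @return named character vector, compound name -> cytosolic metabolite id in
#'   the packaged reduced network.
#' @export
accumulation_compounds <- function() {
  c(mannitol = "mnl_c", malate = "mal_c", cysteine = "cys_c",
    threonine = "thr_c", phenylalanine = "phe_c", valine = "val_c")
}

phase_suffix <- function(id, k) paste0(id, "_p", k)

#' Build the extended multi-phase model
#'
#' @param base a `metabolic_network`.
#' @param n_phases number of stacked phases (default 3).
#' @param compounds named character vector, compound name -> cytosolic
#'   metabolite id in `base`; defaults to [accumulation_compounds()] filtered
#'   to metabolites present in `base`.
#' @return an `extended_model`: list with `base`, `n_phases`, `compounds`,
#'   `network` (the stacked `metabolic_network`, whose stoichiometric matrix
#'   is the block matrix of size `n_phases * n` x `n_phases * m +
#'   (n_phases - 1) * length(compounds)`), and `accumulation` (data.frame of
#'   the coupling reactions).
#' @export
build_extended_model <- function(base, n_phases = 3,
                                 compounds = accumulation_compounds()) {
  stopifnot(n_phases >= 1)
  missing_c <- setdiff(unname(compounds), base$metabolites$id)
  if (length(missing_c))
    stop("accumulation compound metabolite(s) absent from base network: ",
         paste(missing_c, collapse = ", "))
  mets <- do.call(rbind, lapply(seq_len(n_phases), function(k) {
    m <- base$metabolites
    m$id <- phase_suffix(m$id, k)
    m$phase_tag <- k
    m
  }))
  rxns <- list()
  for (k in seq_len(n_phases)) {
    for (r in base$reactions) {
      rk <- r
      rk$id <- phase_suffix(r$id, k)
      names(rk$stoichiometry) <- phase_suffix(names(r$stoichiometry), k)
      rxns[[rk$id]] <- rk
    }
  }
  acc <- NULL
  if (n_phases > 1 && length(compounds)) {
    acc <- do.call(rbind, lapply(seq_len(n_phases - 1), function(k) {
      data.frame(compound = names(compounds),
                 metabolite = unname(compounds),
                 from_phase = k, to_phase = k + 1,
                 reaction_id = sprintf("ACC_%s_%dto%d", names(compounds),
                                       k, k + 1),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(acc))) {
      st <- setNames(c(-1, 1),
                     c(phase_suffix(acc$metabolite[i], acc$from_phase[i]),
                       phase_suffix(acc$metabolite[i], acc$to_phase[i])))
      rxns[[acc$reaction_id[i]]] <-
        reaction(acc$reaction_id[i], st, lower_bound = 0,
                 upper_bound = DEFAULT_BOUND, subsystem = "accumulation",
                 role_tags = "accumulation",
                 name = sprintf("%s carry-over phase %d -> %d",
                                acc$compound[i], acc$from_phase[i],
                                acc$to_phase[i]))
    }
  }
  network <- metabolic_network(mets, rxns,
                               objective_id = phase_suffix(base$objective_id, 1),
                               name = paste0(base$name, "_extended"))
  structure(list(base = base, n_phases = n_phases, compounds = compounds,
                 network = network, accumulation = acc),
            class = "extended_model")
}

#' @export
print.extended_model <- function(x, ...) {
  cat(sprintf("<extended_model> %d phases, %d accumulation reactions, Z is %d x %d\n",
              x$n_phases, if (is.null(x$accumulation)) 0 else nrow(x$accumulation),
              nrow(x$network$metabolites), length(x$network$reactions)))
  invisible(x)
}

#' Apply per-phase experimental constraints to an extended model
#'
#' Each [constraint_set()]'s fixed fluxes (exchange rates, biomass, NGAM) are
#' mapped onto the phase-tagged copies of the named reactions and bounded to
#' `value * (1 -/+ tolerance)`.
#'
#' @param ext an `extended_model`.
#' @param constraint_sets list of [constraint_set()], one per phase (matched
#'   by their `phase_id`).
#' @param biomass_id,ngam_id base-network reaction ids.
#' @return the `extended_model` with a constrained `network`.
#' @export
apply_experimental_constraints <- function(ext, constraint_sets,
                                           biomass_id = "BIOMASS",
                                           ngam_id = "ATPM") {
  stopifnot(inherits(ext, "extended_model"))
  net <- ext$network
  for (cs in constraint_sets) {
    stopifnot(inherits(cs, "phase_constraints"))
    k <- cs$phase_id
    if (k < 1 || k > ext$n_phases)
      stop("constraint set phase_id ", k, " outside 1..", ext$n_phases)
    ids <- names(cs$fixed_fluxes)
    missing_ids <- setdiff(ids, names(ext$base$reactions))
    if (length(missing_ids))
      stop("constraint references unknown reaction(s): ",
           paste(missing_ids, collapse = ", "))
    for (id in ids)
      net <- fix_with_tolerance(net, phase_suffix(id, k),
                                cs$fixed_fluxes[[id]], cs$tolerance)
    if (!is.null(cs$biomass))
      net <- fix_with_tolerance(net, phase_suffix(biomass_id, k),
                                cs$biomass, cs$tolerance)
    if (!is.null(cs$ngam))
      net <- fix_with_tolerance(net, phase_suffix(ngam_id, k),
                                cs$ngam, cs$tolerance)
  }
  ext$network <- net
  ext$constrained <- TRUE
  ext
}

#' Best-effort infeasibility diagnosis
#'
#' When a constrained extended model is infeasible, reports which single
#' constrained reactions restore feasibility if their bounds are relaxed to
#' the defaults — an (approximate) irreducible conflict listing.
#'
#' @param ext a constrained `extended_model`.
#' @param constrained_ids reaction ids (in the extended network) to probe;
#'   default: all reactions whose bounds differ from the base defaults.
#' @return character vector of reaction ids whose relaxation restores
#'   feasibility (empty when the model is feasible).
#' @export
diagnose_infeasibility <- function(ext, constrained_ids = NULL) {
  net <- ext$network
  p <- net_lp_parts(net)
  r <- lp_run(p$S, numeric(length(p$ids)), p$lb, p$ub)
  if (r$status == "optimal") return(character())
  if (is.null(constrained_ids)) {
    base_ids <- names(ext$base$reactions)
    constrained_ids <- unlist(lapply(seq_len(ext$n_phases), function(k) {
      ids <- phase_suffix(base_ids, k)
      keep <- vapply(seq_along(ids), function(i) {
        rb <- ext$base$reactions[[base_ids[i]]]
        re <- net$reactions[[ids[i]]]
        rb$lower_bound != re$lower_bound || rb$upper_bound != re$upper_bound
      }, logical(1))
      ids[keep]
    }))
  }
  hits <- character()
  for (id in constrained_ids) {
    k <- match(id, p$ids)
    lb <- p$lb; ub <- p$ub
    lb[k] <- -DEFAULT_BOUND; ub[k] <- DEFAULT_BOUND
    r <- lp_run(p$S, numeric(length(p$ids)), lb, ub)
    if (r$status == "optimal") hits <- c(hits, id)
  }
  hits
}

#' FVA spans of the accumulation reactions
#'
#' Minimizes and maximizes each inter-phase accumulation flux in the
#' constrained extended model.
#'
#' @param ext a constrained `extended_model`.
#' @return data.frame `compound`, `from_phase`, `to_phase`, `reaction_id`,
#'   `min`, `max` (class `accumulation_bounds`).
#' @export
fva_accumulation <- function(ext) {
  stopifnot(inherits(ext, "extended_model"))
  if (is.null(ext$accumulation)) stop("extended model has no accumulation reactions")
  fva <- tryCatch(solve_fva(ext$network, ext$accumulation$reaction_id),
                  error = function(e)
                    stop("accumulation FVA failed (infeasible model?): ",
                         conditionMessage(e),
                         if (length(h <- diagnose_infeasibility(ext)))
                           paste0("; relaxing any of [",
                                  paste(h, collapse = ", "),
                                  "] restores feasibility") else ""))
  out <- cbind(ext$accumulation, fva[match(ext$accumulation$reaction_id,
                                           fva$reaction_id), c("min", "max")])
  rownames(out) <- NULL
  class(out) <- c("accumulation_bounds", "data.frame")
  out
}

#' Split an extended model into per-phase networks
#'
#' Phase k receives a sink reaction per compound for material accumulated in
#' phase k-1 (inflow) and a demand reaction per compound for material
#' accumulated for phase k+1 (outflow); both bounded by the FVA spans of the
#' corresponding accumulation reactions. All other structure is the base
#' network.
#'
#' @param ext an `extended_model`.
#' @param bounds an `accumulation_bounds` from [fva_accumulation()].
#' @return list of `n_phases` `metabolic_network`s.
#' @export
split_into_phase_models <- function(ext, bounds) {
  stopifnot(inherits(ext, "extended_model"), is.data.frame(bounds))
  lapply(seq_len(ext$n_phases), function(k) {
    net <- ext$base
    net$name <- sprintf("%s_phase%d", ext$base$name, k)
    # demand: outflow to storage used by phase k+1
    out_rows <- bounds[bounds$from_phase == k, , drop = FALSE]
    for (i in seq_len(nrow(out_rows))) {
      id <- paste0("ACCD_", out_rows$compound[i])
      net$reactions[[id]] <-
        reaction(id, setNames(-1, out_rows$metabolite[i]),
                 lower_bound = max(0, out_rows$min[i]),
                 upper_bound = max(0, out_rows$max[i]),
                 subsystem = "accumulation",
                 role_tags = c("demand", "accumulation"),
                 name = sprintf("%s accumulation demand (phase %d -> %d)",
                                out_rows$compound[i], k, k + 1))
    }
    # sink: inflow of material accumulated during phase k-1
    in_rows <- bounds[bounds$to_phase == k, , drop = FALSE]
    for (i in seq_len(nrow(in_rows))) {
      id <- paste0("ACCS_", in_rows$compound[i])
      net$reactions[[id]] <-
        reaction(id, setNames(1, in_rows$metabolite[i]),
                 lower_bound = max(0, in_rows$min[i]),
                 upper_bound = max(0, in_rows$max[i]),
                 subsystem = "accumulation",
                 role_tags = c("sink", "accumulation"),
                 name = sprintf("%s accumulation sink (phase %d -> %d)",
                                in_rows$compound[i], k - 1, k))
    }
    net
  })
}
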