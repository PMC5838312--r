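#' @useDynLib oenoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median sd setNames var
#' @importFrom utils read.delim write.table
NULL

DEFAULT_BOUND <- 1000

#' Create a metabolite
#'
#' Metabolites are rows of the network's species table. `phase_tag` is only
#' used inside extended multi-phase models, where each base metabolite exists
#' once per growth phase.
#'
#' @param id unique short token.
#' @param name free-text name.
#' @param compartment compartment token; `"c"` cytosol, `"e"` extracellular.
#' @param formula optional elemental formula (e.g. `"C6H12O6"`).
#' @param phase_tag optional integer 1-3; `NA` in base networks.
#' @return a one-row `data.frame`.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       phase_tag = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), phase_tag = as.integer(phase_tag),
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' @param id unique short token.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol/gDCW/h (the biomass
#'   reaction carries 1/h). If omitted, defaults are `[0, 1000]` for
#'   irreversible and `[-1000, 1000]` for reversible reactions.
#' @param reversible used only to pick default bounds.
#' @param subsystem subsystem token (e.g. `"phosphoketolase"`, `"MLF"`).
#' @param role_tags character vector of role tokens (e.g.
#'   `"atp_producer_pkp"`, `"proton_extruder"`).
#' @param name free-text name.
#' @return a `list` of class `oeno_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = NULL, upper_bound = NULL,
                     reversible = FALSE, subsystem = "", role_tags = character(),
                     name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- unlist(stoichiometry)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named numeric vector")
  if (is.null(lower_bound)) lower_bound <- if (reversible) -DEFAULT_BOUND else 0
  if (is.null(upper_bound)) upper_bound <- DEFAULT_BOUND
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 subsystem = subsystem,
                 role_tags = as.character(role_tags)),
            class = "oeno_reaction")
}

#' Assemble a constraint-based metabolic network
#'
#' @param metabolites a `data.frame` built by stacking [metabolite()] rows.
#' @param reactions a list of [reaction()] objects.
#' @param objective_id id of the objective reaction (typically biomass).
#' @param name free-text model name.
#' @param check validate on construction (default `TRUE`).
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, objective_id,
                              name = "network", check = TRUE) {
  if (is.null(names(reactions)) || !all(nzchar(names(reactions))))
    names(reactions) <- vapply(reactions, function(r) r$id, character(1))
  net <- structure(list(name = name,
                        metabolites = metabolites,
                        reactions = reactions,
                        objective_id = objective_id),
                   class = "metabolic_network")
  if (check) {
    f <- validate_network(net)
    errs <- f$message[f$level == "error"]
    if (length(errs)) stop("invalid network: ", paste(errs, collapse = "; "))
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s: %d metabolites, %d reactions, objective '%s'\n",
              x$name, nrow(x$metabolites), length(x$reactions), x$objective_id))
  invisible(x)
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique ids, resolvable stoichiometry,
#' ordered bounds, existing objective, single-metabolite exchange reactions.
#' Findings are returned, never raised.
#'
#' @param net a `metabolic_network`.
#' @return a `data.frame` with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when all invariants hold.
#' @export
validate_network <- function(net) {
  lev <- character(); msg <- character()
  add <- function(l, m) { lev <<- c(lev, l); msg <<- c(msg, m) }
  mids <- net$metabolites$id
  if (anyDuplicated(mids))
    add("error", paste0("duplicate metabolite id: ",
                        paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  rids <- vapply(net$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    add("error", paste0("duplicate reaction id: ",
                        paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in net$reactions) {
    bad <- setdiff(names(r$stoichiometry), mids)
    if (length(bad))
      add("error", sprintf("reaction %s references undeclared metabolite(s): %s",
                           r$id, paste(bad, collapse = ", ")))
    if (r$lower_bound > r$upper_bound)
      add("error", sprintf("reaction %s has lower_bound > upper_bound", r$id))
    if (identical(r$subsystem, "exchange") && length(r$stoichiometry) != 1L)
      add("error", sprintf("exchange reaction %s touches %d metabolites",
                           r$id, length(r$stoichiometry)))
  }
  if (!is.null(net$objective_id) && !(net$objective_id %in% rids))
    add("error", sprintf("objective_id '%s' not a reaction", net$objective_id))
  used <- unique(unlist(lapply(net$reactions, function(r) names(r$stoichiometry))))
  orphan <- setdiff(mids, used)
  if (length(orphan))
    add("warning", paste0("orphan metabolite(s): ", paste(orphan, collapse = ", ")))
  data.frame(level = lev, message = msg, stringsAsFactors = FALSE)
}

#' Stoichiometric matrix
#'
#' @param net a `metabolic_network`.
#' @return a dense numeric matrix, metabolites in rows (in declaration order)
#'   and reactions in columns; entry (i, j) is the coefficient of metabolite i
#'   in reaction j.
#' @export
stoichiometric_matrix <- function(net) {
  mids <- net$metabolites$id
  rids <- vapply(net$reactions, function(r) r$id, character(1))
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

# --- small accessors used throughout ----------------------------------------

reaction_ids <- function(net) vapply(net$reactions, function(r) r$id, character(1))

lower_bounds <- function(net) vapply(net$reactions, function(r) r$lower_bound, numeric(1))

upper_bounds <- function(net) vapply(net$reactions, function(r) r$upper_bound, numeric(1))

#' Reactions carrying a given role tag
#' @param net a `metabolic_network`.
#' @param tag role token, e.g. `"atp_producer_pkp"`.
#' @return character vector of reaction ids.
#' @export
reactions_by_role <- function(net, tag) {
  ids <- reaction_ids(net)
  ids[vapply(net$reactions, function(r) tag %in% r$role_tags, logical(1))]
}

#' Reactions in a given subsystem
#' @param net a `metabolic_network`.
#' @param subsystem subsystem token, e.g. `"MLF"`.
#' @return character vector of reaction ids.
#' @export
reactions_by_subsystem <- function(net, subsystem) {
  ids <- reaction_ids(net)
  ids[vapply(net$reactions, function(r) identical(r$subsystem, subsystem),
             logical(1))]
}

#' Set flux bounds on a reaction
#' @param net a `metabolic_network`.
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified network.
#' @export
set_bounds <- function(net, id, lower = NULL, upper = NULL) {
  if (!id %in% names(net$reactions)) stop("unknown reaction id: ", id)
  if (!is.null(lower)) net$reactions[[id]]$lower_bound <- as.numeric(lower)
  if (!is.null(upper)) net$reactions[[id]]$upper_bound <- as.numeric(upper)
  net
}

exchange_ids <- function(net) reactions_by_subsystem(net, "exchange")
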