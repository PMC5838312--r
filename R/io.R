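# Network I/O: canonical JSON, a 3-file TSV layout, and SBML Level 3 + fbc.
#
# JSON is the package's canonical format because SBML has no portable slot for
# role tags; the SBML writer stores them (and subsystems / phase tags) in a
# package annotation namespace so that round trips are lossless.

OENO_XMLNS <- "https://oenoflux.invalid/ns"

#' Read a constraint-based network from file
#'
#' @param path file path. For `format = "tsv"` this is the common prefix of
#'   the three files `<path>_metabolites.tsv`, `<path>_reactions.tsv` and
#'   `<path>_stoichiometry.tsv`.
#' @param format one of `"json"`, `"tsv"`, `"sbml"`; default guessed from the
#'   file extension.
#' @return a validated [metabolic_network()].
#' @export
read_network <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", xml = "sbml", sbml = "sbml", "tsv")
  }
  net <- switch(format,
                json = read_network_json(path),
                tsv  = read_network_tsv(path),
                sbml = read_network_sbml(path))
  f <- validate_network(net)
  errs <- f$message[f$level == "error"]
  if (length(errs))
    stop("validation error in '", path, "': ", paste(errs, collapse = "; "))
  net
}

#' Write a constraint-based network to file
#'
#' Round-trip property: `read_network(write_network(net, p, f), f)` is
#' structurally identical to `net` for every supported format.
#'
#' @param net a `metabolic_network`.
#' @param path output path (prefix for `"tsv"`).
#' @param format one of `"json"`, `"tsv"`, `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "tsv", "sbml")) {
  format <- match.arg(format)
  switch(format,
         json = write_network_json(net, path),
         tsv  = write_network_tsv(net, path),
         sbml = write_network_sbml(net, path))
  invisible(path)
}

# --- JSON --------------------------------------------------------------------

read_network_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("JSON parse failure in '", path, "': ",
                                         conditionMessage(e)))
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    metabolite(m$id,
               name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_,
               phase_tag = m$phase_tag %||% NA_integer_)
  }))
  rxns <- lapply(x$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    rev <- isTRUE(r$reversible)
    reaction(r$id, st,
             lower_bound = r$lower_bound %||% NULL,
             upper_bound = r$upper_bound %||% NULL,
             reversible = rev,
             subsystem = r$subsystem %||% "",
             role_tags = unlist(r$role_tags) %||% character(),
             name = r$name %||% r$id)
  })
  metabolic_network(mets, rxns, objective_id = x$objective_id,
                    name = x$name %||% "network", check = FALSE)
}

write_network_json <- function(net, path) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$phase_tag)) out$phase_tag <- m$phase_tag
    out
  })
  rxns <- lapply(net$reactions, function(r) {
    list(id = r$id, name = r$name,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem, role_tags = as.list(r$role_tags))
  })
  jsonlite::write_json(list(name = net$name, objective_id = net$objective_id,
                            metabolites = mets, reactions = unname(rxns)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- TSV (3-file layout) -----------------------------------------------------

read_network_tsv <- function(prefix) {
  fm <- paste0(prefix, "_metabolites.tsv")
  fr <- paste0(prefix, "_reactions.tsv")
  fs <- paste0(prefix, "_stoichiometry.tsv")
  for (f in c(fm, fr, fs))
    if (!file.exists(f)) stop("TSV layout incomplete, missing: ", f)
  m <- read.delim(fm, stringsAsFactors = FALSE)
  r <- read.delim(fr, stringsAsFactors = FALSE)
  s <- read.delim(fs, stringsAsFactors = FALSE)
  mets <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    metabolite(m$id[i], name = m$name[i], compartment = m$compartment[i],
               formula = if ("formula" %in% names(m)) m$formula[i] else NA,
               phase_tag = if ("phase_tag" %in% names(m)) m$phase_tag[i] else NA)))
  rxns <- lapply(seq_len(nrow(r)), function(i) {
    tri <- s[s$reaction_id == r$id[i], , drop = FALSE]
    st <- setNames(tri$coefficient, tri$metabolite_id)
    tags <- if (is.na(r$role_tags[i]) || !nzchar(r$role_tags[i])) character()
            else strsplit(r$role_tags[i], ";", fixed = TRUE)[[1]]
    reaction(r$id[i], st, lower_bound = r$lower_bound[i],
             upper_bound = r$upper_bound[i], subsystem = r$subsystem[i],
             role_tags = tags, name = r$name[i])
  })
  obj <- r$id[which(r$objective)[1]]
  metabolic_network(mets, rxns, objective_id = obj,
                    name = attr_or(m, "network_name", "network"), check = FALSE)
}

attr_or <- function(x, a, d) d

write_network_tsv <- function(net, prefix) {
  m <- net$metabolites
  write.table(m, paste0(prefix, "_metabolites.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  r <- data.frame(
    id = reaction_ids(net),
    name = vapply(net$reactions, function(x) x$name, character(1)),
    lower_bound = lower_bounds(net),
    upper_bound = upper_bounds(net),
    subsystem = vapply(net$reactions, function(x) x$subsystem, character(1)),
    role_tags = vapply(net$reactions,
                       function(x) paste(x$role_tags, collapse = ";"),
                       character(1)),
    objective = reaction_ids(net) == net$objective_id,
    stringsAsFactors = FALSE)
  write.table(r, paste0(prefix, "_reactions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  tri <- do.call(rbind, lapply(net$reactions, function(x)
    data.frame(reaction_id = x$id, metabolite_id = names(x$stoichiometry),
               coefficient = unname(x$stoichiometry), stringsAsFactors = FALSE)))
  write.table(tri, paste0(prefix, "_stoichiometry.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

# --- SBML Level 3 (+ fbc-style flux bounds) ----------------------------------

read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(species, function(sp) {
    metabolite(xml2::xml_attr(sp, "id"),
               name = xml2::xml_attr(sp, "name") %na% xml2::xml_attr(sp, "id"),
               compartment = xml2::xml_attr(sp, "compartment") %na% "c",
               formula = xml2::xml_attr(sp, "chemicalFormula") %na%
                         oeno_anno(sp, "formula", ns),
               phase_tag = as.integer(oeno_anno(sp, "phaseTag", ns)))
  }))
  rnodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    reac <- xml2::xml_find_all(rn, ".//s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, ".//s:listOfProducts/s:speciesReference", ns)
    st <- c(setNames(-sref_stoich(reac), xml2::xml_attr(reac, "species")),
            setNames(sref_stoich(prod), xml2::xml_attr(prod, "species")))
    st <- tapply(st, names(st), sum)  # merge duplicate species refs
    st <- setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
          else if (rev) -DEFAULT_BOUND else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else DEFAULT_BOUND
    tags <- oeno_anno(rn, "roleTags", ns)
    reaction(id, st, lower_bound = lb, upper_bound = ub,
             subsystem = oeno_anno(rn, "subsystem", ns) %na% "",
             role_tags = if (is.na(tags) || !nzchar(tags)) character()
                         else strsplit(tags, ";", fixed = TRUE)[[1]],
             name = xml2::xml_attr(rn, "name") %na% id)
  })
  obj <- oeno_anno(model, "objective", ns)
  if (is.na(obj)) {
    fo <- xml2::xml_find_first(
      model, ".//*[local-name()='fluxObjective']")
    obj <- if (!inherits(fo, "xml_missing")) xml2::xml_attr(fo, "reaction")
           else NA_character_
  }
  metabolic_network(mets, rxns, objective_id = obj,
                    name = xml2::xml_attr(model, "name") %na% "network",
                    check = FALSE)
}

`%na%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

sref_stoich <- function(nodes) {
  s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
  s[is.na(s)] <- 1
  s
}

oeno_anno <- function(node, key, ns) {
  hit <- xml2::xml_find_first(
    node, sprintf("./*[local-name()='annotation']/*[local-name()='%s']", key))
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

write_network_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, useBytes = TRUE)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  w('<model id="%s" name="%s">', gsub("[^A-Za-z0-9_]", "_", net$name), esc(net$name))
  w('<annotation><objective xmlns="%s">%s</objective></annotation>',
    OENO_XMLNS, net$objective_id)
  comps <- unique(net$metabolites$compartment)
  w('<listOfCompartments>')
  for (cp in comps) w('<compartment id="%s" constant="true"/>', cp)
  w('</listOfCompartments>')
  w('<listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    anno <- character()
    if (!is.na(m$formula))
      anno <- c(anno, sprintf('<formula xmlns="%s">%s</formula>', OENO_XMLNS, m$formula))
    if (!is.na(m$phase_tag))
      anno <- c(anno, sprintf('<phaseTag xmlns="%s">%d</phaseTag>', OENO_XMLNS, m$phase_tag))
    w('<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">%s</species>',
      m$id, esc(m$name), m$compartment,
      if (length(anno)) paste0("<annotation>", paste(anno, collapse = ""), "</annotation>") else "")
  }
  w('</listOfSpecies>')
  w('<listOfParameters>')
  for (r in net$reactions) {
    w('<parameter id="lb_%s" value="%.17g" constant="true"/>', r$id, r$lower_bound)
    w('<parameter id="ub_%s" value="%.17g" constant="true"/>', r$id, r$upper_bound)
  }
  w('</listOfParameters>')
  w('<listOfReactions>')
  for (r in net$reactions) {
    w('<reaction id="%s" name="%s" reversible="%s" fast="false" lowerFluxBound="lb_%s" upperFluxBound="ub_%s">',
      r$id, esc(r$name), if (r$lower_bound < 0) "true" else "false", r$id, r$id)
    anno <- sprintf('<subsystem xmlns="%s">%s</subsystem><roleTags xmlns="%s">%s</roleTags>',
                    OENO_XMLNS, r$subsystem, OENO_XMLNS,
                    paste(r$role_tags, collapse = ";"))
    w('<annotation>%s</annotation>', anno)
    st <- r$stoichiometry
    sub <- st[st < 0]; pro <- st[st > 0]
    if (length(sub)) {
      w('<listOfReactants>')
      for (k in seq_along(sub))
        w('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
          names(sub)[k], -sub[[k]])
      w('</listOfReactants>')
    }
    if (length(pro)) {
      w('<listOfProducts>')
      for (k in seq_along(pro))
        w('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
          names(pro)[k], pro[[k]])
      w('</listOfProducts>')
    }
    w('</reaction>')
  }
  w('</listOfReactions>')
  w('</model>')
  w('</sbml>')
}
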