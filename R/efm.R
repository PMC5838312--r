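# Elementary flux mode enumeration.
#
# Reversible reactions are split into forward/backward parts so the flux cone
# is pointed; extreme rays of {x >= 0, S x = 0} are computed by the double
# description method (constraints processed one at a time, adjacency via the
# standard combinatorial zero-set test); rays are mapped back, futile
# split-cycles removed, duplicates of reversible modes merged, and each mode
# normalized so its smallest nonzero |coefficient| is 1. All rank/zero
# decisions are epsilon-guarded at 1e-9.

EFM_EPS <- 1e-9

prune_network <- function(net, drop_fixed_zero = TRUE) {
  # iteratively drop reactions that touch dead-end metabolites, and
  # (optionally) reactions pinned to zero by their bounds
  repeat {
    S <- stoichiometric_matrix(net)
    lb <- lower_bounds(net); ub <- upper_bounds(net)
    keep <- rep(TRUE, ncol(S))
    if (drop_fixed_zero) keep <- !(lb == 0 & ub == 0)
    # dead-end metabolites: no producer or no consumer among kept reactions
    Sk <- S[, keep, drop = FALSE]
    lbk <- lb[keep]; ubk <- ub[keep]
    dead <- rep(FALSE, nrow(S))
    for (i in seq_len(nrow(S))) {
      row <- Sk[i, ]
      can_prod <- any(row > 0 & ubk > 0) || any(row < 0 & lbk < 0)
      can_cons <- any(row < 0 & ubk > 0) || any(row > 0 & lbk < 0)
      dead[i] <- !(can_prod && can_cons)
    }
    kills <- keep & apply(S[dead, , drop = FALSE] != 0, 2, any)
    if (!any(kills) && all(keep)) break
    drop_ids <- colnames(S)[!keep | kills]
    if (!length(drop_ids)) break
    net$reactions[drop_ids] <- NULL
    used <- unique(unlist(lapply(net$reactions,
                                 function(r) names(r$stoichiometry))))
    net$metabolites <- net$metabolites[net$metabolites$id %in% used, ,
                                       drop = FALSE]
    if (!length(net$reactions)) break
  }
  net
}

# double description: extreme rays of {x >= 0 : A x = 0}
dd_extreme_rays <- function(A, max_rays = 2e5) {
  m <- ncol(A)
  rays <- diag(m)            # columns are rays
  for (i in seq_len(nrow(A))) {
    val <- as.numeric(A[i, ] %*% rays)
    scale <- pmax(apply(abs(rays), 2, max), 1)
    val[abs(val) <= EFM_EPS * scale] <- 0
    zero <- which(val == 0)
    pos <- which(val > 0)
    neg <- which(val < 0)
    if (!length(pos) || !length(neg)) {
      rays <- rays[, zero, drop = FALSE]
      if (!ncol(rays)) return(matrix(0, m, 0))
      next
    }
    # zero-pattern matrix for the adjacency test
    Z <- rays == 0
    keep <- rays[, zero, drop = FALSE]
    new_rays <- list()
    for (p in pos) for (n in neg) {
      zp <- Z[, p] & Z[, n]
      # adjacency: no third ray whose zero set contains the common zeros
      others <- setdiff(c(pos, neg, zero), c(p, n))
      adjacent <- TRUE
      if (length(others)) {
        cand <- others[colSums(!Z[zp, others, drop = FALSE]) == 0]
        adjacent <- length(cand) == 0
      }
      if (adjacent) {
        r <- val[p] * rays[, n] - val[n] * rays[, p]
        mx <- max(abs(r))
        if (mx > EFM_EPS) {
          r[abs(r) <= EFM_EPS * mx] <- 0
          new_rays[[length(new_rays) + 1]] <- r / mx
        }
      }
    }
    rays <- cbind(keep, do.call(cbind, new_rays))
    if (is.null(dim(rays)) || !ncol(rays)) return(matrix(0, m, 0))
    if (ncol(rays) > max_rays)
      stop("double description exceeded ", max_rays,
           " intermediate rays; reduce the network first")
  }
  rays
}

#' Enumerate elementary flux modes
#'
#' Complete, duplicate-free enumeration of the elementary modes of a network:
#' flux vectors with `S v = 0`, irreversible reactions non-negative, and
#' support-minimal. Coefficients are normalized so the smallest nonzero
#' |coefficient| equals 1; modes are ordered lexicographically by support.
#'
#' @param net a `metabolic_network`. Reactions fixed to zero by their bounds
#'   are pruned first, together with dead-end metabolites.
#' @param max_reactions combinatorial guard on the (pruned, split) column
#'   count; raise deliberately for larger models.
#' @return list of modes, each a list with `coefficients` (named numeric over
#'   the full reaction set of the pruned network) and `support` (character).
#' @export
enumerate_efms <- function(net, max_reactions = 80) {
  net <- prune_network(net)
  if (!length(net$reactions)) return(list())
  S <- stoichiometric_matrix(net)
  lb <- lower_bounds(net); ub <- upper_bounds(net)
  rev <- lb < 0
  ids <- colnames(S)
  Ssplit <- cbind(S, -S[, rev, drop = FALSE])
  split_ids <- c(ids, paste0(ids[rev], "__rev"))
  if (ncol(Ssplit) > max_reactions)
    stop("network has ", ncol(Ssplit), " split reactions (> ", max_reactions,
         "); reduce it or raise max_reactions")
  rays <- dd_extreme_rays(Ssplit)
  if (!ncol(rays)) return(list())
  modes <- list()
  seen <- character()
  nrev <- sum(rev)
  for (j in seq_len(ncol(rays))) {
    x <- rays[, j]
    v <- x[seq_along(ids)]
    if (nrev) {
      xr <- x[(length(ids) + 1):(length(ids) + nrev)]
      v[rev] <- v[rev] - xr
    }
    v[abs(v) <= EFM_EPS * max(abs(x))] <- 0
    if (all(v == 0)) next   # futile two-cycle from the split
    # canonical orientation for fully reversible modes
    if (all(lb[v != 0] < 0) && v[which(v != 0)[1]] < 0) v <- -v
    v <- v / min(abs(v[v != 0]))
    key <- paste(which(v != 0), signif(v[v != 0], 9), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    modes[[length(modes) + 1]] <-
      list(coefficients = setNames(v, ids),
           support = ids[v != 0])
  }
  # enforce pairwise support minimality (guards numeric edge cases)
  supp <- lapply(modes, function(m) m$support)
  keep <- rep(TRUE, length(modes))
  for (a in seq_along(modes)) for (b in seq_along(modes)) {
    if (a != b && keep[a] && keep[b] &&
        all(supp[[b]] %in% supp[[a]]) && length(supp[[b]]) < length(supp[[a]]))
      keep[a] <- FALSE
  }
  modes <- modes[keep]
  ord <- order(vapply(modes, function(m)
    paste(sprintf("%03d", match(m$support, ids)), collapse = ","), character(1)))
  modes[ord]
}

#' Default substrate and product sets for the substrate-product table
#' @return named character vectors (display name -> exchange reaction id).
#' @export
efm_table_dimensions <- function() {
  list(substrates = c("D-fructose" = "EX_fru", "D-glucose" = "EX_glc",
                      "Citrate" = "EX_cit", "L-malate" = "EX_mal",
                      "L-cysteine" = "EX_cys", "L-serine" = "EX_ser",
                      "L-threonine" = "EX_thr"),
       products = c("D-mannitol" = "EX_mnl", "D-lactate" = "EX_dlac",
                    "L-lactate" = "EX_llac", "Diacetyl" = "EX_diact",
                    "Ethanol" = "EX_etoh", "Acetate" = "EX_ac",
                    "Erythritol" = "EX_eol"))
}

#' Substrate-product relationships by elementary flux modes
#'
#' For each substrate taken as the sole organic substrate (all other
#' substrate uptakes closed; mineral/small-species exchanges stay open), the
#' elementary modes are enumerated and the number of modes carrying flux to
#' each product's exchange is tabulated.
#'
#' @param net a `metabolic_network`.
#' @param substrates,products named character vectors mapping display names
#'   to exchange reaction ids; default the packaged table layout.
#' @param max_reactions passed to [enumerate_efms()].
#' @return integer matrix (substrates x products) of mode counts, with the
#'   per-substrate total mode count as attribute `n_modes`.
#' @export
substrate_product_table <- function(net,
                                    substrates = efm_table_dimensions()$substrates,
                                    products = efm_table_dimensions()$products,
                                    max_reactions = 80) {
  all_ids <- reaction_ids(net)
  missing_ex <- setdiff(c(substrates, products), all_ids)
  if (length(missing_ex))
    stop("missing exchange reaction(s): ", paste(missing_ex, collapse = ", "))
  counts <- matrix(0L, length(substrates), length(products),
                   dimnames = list(names(substrates), names(products)))
  nm <- integer(length(substrates))
  uptake_ids <- intersect(exchange_ids(net),
                          all_ids[lower_bounds(net) < 0])
  keep_open <- c("EX_h", "EX_h2o", "EX_co2", "EX_pi")   # minerals/small species
  for (si in seq_along(substrates)) {
    n2 <- net
    for (id in setdiff(uptake_ids, c(substrates[si], keep_open)))
      n2 <- set_bounds(n2, id, lower = 0)
    modes <- enumerate_efms(n2, max_reactions = max_reactions)
    nm[si] <- length(modes)
    for (m in modes) {
      for (pj in seq_along(products)) {
        coef <- m$coefficients[products[pj]]
        if (!is.na(coef) && abs(coef) > EFM_EPS)
          counts[si, pj] <- counts[si, pj] + 1L
      }
    }
  }
  attr(counts, "n_modes") <- setNames(nm, names(substrates))
  counts
}
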