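# Independent oracles and shared fixtures.
#
# The oracles here never call the package's solver/enumerator internals: the
# LP oracle enumerates basic solutions (vertices) directly, and the EFM
# oracle enumerates support subsets with a rank test.

# ---- fixture cache: expensive synthetic worlds are generated once ----------

.fixtures <- new.env(parent = emptyenv())

get_base_model <- function() {
  if (is.null(.fixtures$base)) .fixtures$base <- load_reduced_oeni_model()
  .fixtures$base
}

# full noiseless world + pipeline chain for one ethanol level
get_world <- function(eth) {
  key <- paste0("world_", eth)
  if (is.null(.fixtures[[key]])) {
    base <- get_base_model()
    sim <- simulate_culture(ethanol_level = eth, noise_cv = 0)
    rs <- estimate_all_phase_rates(sim$timecourse)
    css <- lapply(rs, rates_to_constraints, tolerance = 0)
    ext <- apply_experimental_constraints(build_extended_model(base, 3), css)
    ab <- fva_accumulation(ext)
    nets <- split_into_phase_models(ext, ab)
    .fixtures[[key]] <- list(sim = sim, rates = rs, css = css, ext = ext,
                             bounds = ab, nets = nets)
  }
  .fixtures[[key]]
}

get_world_ngam <- function(eth) {
  key <- paste0("ngam_", eth)
  if (is.null(.fixtures[[key]])) {
    w <- get_world(eth)
    .fixtures[[key]] <- lapply(1:3, function(k)
      oenoflux:::estimate_ngam_banded(w$nets[[k]], w$bounds, k, w$css[[k]],
                                      w$rates[[k]]$mu,
                                      bands = c(0, 1e-6, 3e-6, 1e-5, 3e-5,
                                                1e-4, 3e-4, 1e-3)))
  }
  .fixtures[[key]]
}

get_efm_table <- function() {
  if (is.null(.fixtures$efm_table))
    .fixtures$efm_table <- substrate_product_table(get_base_model())
  .fixtures$efm_table
}

# ---- tiny network builders --------------------------------------------------

toy_chain <- function(cap = 5) {
  mets <- rbind(metabolite("Ae", "A", "e"), metabolite("A"), metabolite("B"),
                metabolite("Be", "B", "e"))
  metabolic_network(mets, list(
    reaction("EX_A", c(Ae = -1), lower_bound = -cap, upper_bound = 0,
             subsystem = "exchange"),
    reaction("T1", c(Ae = -1, A = 1)),
    reaction("R1", c(A = -1, B = 1)),
    reaction("T2", c(B = -1, Be = 1)),
    reaction("EX_B", c(Be = -1), subsystem = "exchange")),
    objective_id = "EX_B")
}

# a 2-D box polytope: two independent produce/consume pairs in [0, w]
box_network <- function(w = 1) {
  mets <- rbind(metabolite("M1"), metabolite("M2"))
  metabolic_network(mets, list(
    reaction("P1", c(M1 = 1), lower_bound = 0, upper_bound = w),
    reaction("C1", c(M1 = -1), lower_bound = 0, upper_bound = w),
    reaction("P2", c(M2 = 1), lower_bound = 0, upper_bound = w),
    reaction("C2", c(M2 = -1), lower_bound = 0, upper_bound = w)),
    objective_id = "P1")
}

# random small network for oracle comparisons (seeded by caller)
random_toy_network <- function(n_met = 3, n_rxn = 6, p_rev = 0.3) {
  mets <- do.call(rbind, lapply(seq_len(n_met), function(i)
    metabolite(paste0("M", i))))
  rxns <- list()
  for (j in seq_len(n_rxn)) {
    k <- sample(1:2, 1)
    touched <- sample(n_met, min(k + 1, n_met))
    st <- setNames(sample(c(-2, -1, 1, 2), length(touched), replace = TRUE),
                   paste0("M", touched))
    # ~1/3 of reactions are boundary (single metabolite)
    if (stats::runif(1) < 0.35) st <- st[1]
    rxns[[j]] <- reaction(paste0("R", j), st,
                          reversible = stats::runif(1) < p_rev,
                          subsystem = if (length(st) == 1) "exchange" else "")
  }
  metabolic_network(mets, rxns, objective_id = "R1", check = FALSE)
}

# ---- LP vertex oracle -------------------------------------------------------

# brute-force optimum of max c'v s.t. S v = 0, lb <= v <= ub by enumerating
# candidate basic solutions: choose which variables sit at which bound, solve
# the equality system for the rest. Exponential; use only for m <= ~7.
oracle_lp_max <- function(S, lb, ub, cv) {
  m <- ncol(S)
  n <- qr(S)$rank
  free_counts <- n
  best <- -Inf
  idx <- seq_len(m)
  combs <- utils::combn(m, min(free_counts, m), simplify = FALSE)
  for (free in combs) {
    fixed <- setdiff(idx, free)
    # each fixed var at lb or ub
    grids <- expand.grid(rep(list(c(1, 2)), length(fixed)))
    if (!length(fixed)) grids <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grids))) {
      v <- numeric(m)
      if (length(fixed)) {
        ch <- as.numeric(grids[g, ])
        v[fixed] <- ifelse(ch == 1, lb[fixed], ub[fixed])
      }
      rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
      A <- S[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(A, rhs, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - rhs)) > 1e-8) next
      v[free] <- sol
      if (all(v >= lb - 1e-8 & v <= ub + 1e-8))
        best <- max(best, sum(cv * v))
    }
  }
  best
}

# ---- EFM subset oracle ------------------------------------------------------

# all elementary modes of a network by support enumeration + rank test
oracle_efms <- function(net) {
  S <- stoichiometric_matrix(net)
  lb <- vapply(net$reactions, function(r) r$lower_bound, numeric(1))
  m <- ncol(S)
  modes <- list()
  supports <- character()
  for (size in 1:m) {
    for (T in utils::combn(m, size, simplify = FALSE)) {
      ST <- S[, T, drop = FALSE]
      ns <- tryCatch(MASS_null(ST), error = function(e) NULL)
      if (is.null(ns) || ncol(ns) != 1) next
      v <- ns[, 1]
      if (any(abs(v) < 1e-9 * max(abs(v)))) next   # support not full
      full <- numeric(m); full[T] <- v
      # sign feasibility: irreversible components must be >= 0 (try both signs)
      ok <- function(x) all(x[lb >= 0] >= -1e-9)
      w <- if (ok(full)) full else if (ok(-full)) -full else NULL
      if (is.null(w)) next
      # elementarity: rank(S_T) == |T| - 1 (guaranteed by 1-D nullspace)
      key <- paste(T, collapse = ",")
      # skip supersets of an existing support
      if (any(vapply(modes, function(mm)
        all(which(mm != 0) %in% T) && sum(mm != 0) < size, logical(1)))) next
      modes[[length(modes) + 1]] <- w / min(abs(w[w != 0]))
      supports <- c(supports, key)
    }
  }
  modes
}

# nullspace via QR (avoids depending on MASS)
MASS_null <- function(M) {
  qrM <- qr(t(M))
  rank <- qrM$rank
  m <- ncol(M)
  if (rank >= m) return(matrix(0, m, 0))
  qr.Q(qrM, complete = TRUE)[, (rank + 1):m, drop = FALSE]
}

# carbon count from a formula string
carbon_count <- function(formula) {
  if (is.na(formula)) return(NA_real_)
  hit <- regmatches(formula, regexec("C([0-9]*)([A-Z]|$)", formula))[[1]]
  if (!length(hit) || hit[1] == "") return(0)
  if (hit[2] == "") 1 else as.numeric(hit[2])
}

# mode canonicalization shared by the EFM tests
norm_mode <- function(v) {
  v <- v / min(abs(v[abs(v) > 1e-9]))
  i <- which(abs(v) > 1e-9)
  paste(i, signif(v[i], 6), collapse = ";")
}

canon_orient <- function(v, lb) {
  nz <- which(abs(v) > 1e-9)
  if (all(lb[nz] < 0) && v[nz[1]] < 0) -v else v
}

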