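# Fundamental Pathways: extreme-ray enumeration of the flux cone after
# currency-metabolite removal, with exact integer arithmetic, per-pathway
# imbalance in the original network, ATP-production potential via cheapest
# energy-carrier conversion, and Pareto classification of energy pathways.

#' Default currency metabolites and energy carriers
#'
#' Base names matched across all compartments. Users override per model;
#' ubiquitous cofactors differ between reconstructions.
#' @export
default_currency_metabolites <- function() {
  c("atp", "adp", "amp", "pi", "ppi", "nad", "nadh", "nadp", "nadph",
    "h", "h2o", "coa", "co2")
}

#' @rdname default_currency_metabolites
#' @export
default_energy_carriers <- function() {
  c("nadh", "nadph", "q8h2", "fadh2")
}

# reduced <-> oxidized partners used when a carrier is injected for
# conversion-yield measurement
carrier_partner <- function(carrier) {
  map <- c(nadh = "nad", nadph = "nadp", q8h2 = "q8", fadh2 = "fad",
           atp = "adp")
  unname(map[tolower(carrier)])
}

#' Remove currency metabolites from a model
#'
#' Deletes the named metabolites (matched by base name across all
#' compartments) from every reaction; reactions emptied by the removal are
#' dropped. Retained reactions that become pure sinks or sources
#' (only products or only substrates left) are recorded as warnings - they
#' do not invalidate the decomposition but introduce implicit exchanges.
#'
#' @param model a [metabolic_model()].
#' @param currency_ids character vector of metabolite base names (without
#'   compartment suffix), case-insensitive.
#' @return a `reduced_model`: list with the reduced `model`,
#'   `removed_metabolites`, `removed_reactions` and a `warnings` tibble.
#' @export
reduce_model <- function(model, currency_ids = default_currency_metabolites()) {
  base <- purrr::map2_chr(model$metabolites$id, model$metabolites$compartment,
                          met_base_name)
  hit <- base %in% tolower(currency_ids)
  unmatched <- setdiff(tolower(currency_ids), base)
  warnings <- tibble(kind = character(0), id = character(0))
  if (length(unmatched) > 0) {
    warn(paste0("Currency metabolite(s) not present in the model: ",
                paste(unmatched, collapse = ", ")))
    warnings <- dplyr::bind_rows(warnings,
      tibble(kind = "absent_currency", id = unmatched))
  }
  removed_mets <- model$metabolites$id[hit]

  keep_rows <- !hit
  S_red <- model$S[keep_rows, , drop = FALSE]
  nnz <- Matrix::colSums(S_red != 0)
  removed_rxns <- model$reactions$id[nnz == 0 & Matrix::colSums(model$S != 0) > 0]
  keep_cols <- !(model$reactions$id %in% removed_rxns)

  # consideration: retained reactions must not become sinks or sources
  for (j in which(keep_cols)) {
    col_old <- model$S[, j]
    col_new <- S_red[, j]
    had_both <- any(col_old < 0) && any(col_old > 0)
    has_both <- any(col_new < 0) && any(col_new > 0)
    if (had_both && !has_both && any(col_new != 0)) {
      warnings <- dplyr::bind_rows(warnings,
        tibble(kind = if (any(col_new > 0)) "became_source" else "became_sink",
               id = model$reactions$id[[j]]))
    }
  }
  if (any(warnings$kind %in% c("became_sink", "became_source"))) {
    warn("Some retained reactions became sinks or sources after currency removal.")
  }

  mets <- model$metabolites[keep_rows, ]
  rxns <- model$reactions[keep_cols, ]
  stoich <- list()
  for (id in rxns$id) {
    stoich[[id]] <- named_column(S_red, id)
  }
  obj_id <- if (!is.null(model$objective_id) && model$objective_id %in% rxns$id)
    model$objective_id else NULL
  if (is.null(obj_id)) rxns$objective_coefficient <- 0
  reduced <- metabolic_model(mets, rxns, stoich, objective_id = obj_id,
                             big_bound = model$big_bound,
                             require_objective = FALSE)

  structure(list(model = reduced,
                 original = model,
                 removed_metabolites = removed_mets,
                 removed_reactions = removed_rxns,
                 warnings = warnings),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model> removed ", length(x$removed_metabolites),
      " metabolites, ", length(x$removed_reactions), " reactions; ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  invisible(x)
}

# Split every reaction that can run backwards into one-directional columns
# (no cost terms). Returns integer matrix A (rows = metabolites), column ids,
# and the original-reaction/direction map.
split_for_enumeration <- function(model) {
  ids <- character(0); from <- character(0); dir <- integer(0)
  cols <- list()
  for (k in seq_len(nrow(model$reactions))) {
    id <- model$reactions$id[[k]]
    st <- model$S[, id]
    lb <- model$reactions$lower_bound[[k]]
    ub <- model$reactions$upper_bound[[k]]
    if (ub > 0) {
      ids <- c(ids, if (lb < 0) paste0(id, "__f") else id)
      from <- c(from, id); dir <- c(dir, 1L)
      cols[[length(cols) + 1]] <- st
    }
    if (lb < 0) {
      ids <- c(ids, paste0(id, "__b"))
      from <- c(from, id); dir <- c(dir, -1L)
      cols[[length(cols) + 1]] <- -st
    }
  }
  A <- do.call(cbind, cols)
  rownames(A) <- model$metabolites$id
  colnames(A) <- ids
  # exact integer rows (row scaling leaves the cone unchanged)
  A <- t(apply(A, 1, integerize))
  dimnames(A) <- list(model$metabolites$id, ids)
  list(A = A, ids = ids, from = from, dir = dir)
}

#' Enumerate the extreme rays of the reduced flux cone
#'
#' Double-description enumeration of the pointed cone
#' `{v >= 0 : S_reduced v = 0}` on the split (all-irreversible) network, in
#' exact integer arithmetic. Rows are inserted by increasing support size;
#' adjacency is decided by the combinatorial support test. Trivial
#' forward-backward two-cycles of a single split reaction are removed (unless
#' `drop_two_cycles = FALSE`) and each ray is scaled to smallest integer
#' coefficients.
#'
#' @param reduced a `reduced_model` (or a plain [metabolic_model()]).
#' @param max_cols refuse networks with more split columns than this
#'   (enumeration is exponential).
#' @param drop_two_cycles remove the trivial fwd/bwd two-cycles.
#' @return a `fundamental_pathways` tibble: `pathway`, `flux_split`
#'   (list-column of named integer-valued vectors on split columns),
#'   `flux_net` (list of named net fluxes on original reactions),
#'   `is_internal_loop`.
#' @export
enumerate_pathways <- function(reduced, max_cols = 80, drop_two_cycles = TRUE) {
  model <- if (inherits(reduced, "reduced_model")) reduced$model else reduced
  sp <- split_for_enumeration(model)
  A <- sp$A
  n <- ncol(A)
  if (n > max_cols) {
    abort(paste0("Network has ", n, " split columns (> ", max_cols,
                 "); extreme-ray enumeration is exponential. ",
                 "Raise max_cols to force."))
  }

  rays <- dd_rays(A)

  if (drop_two_cycles && ncol(rays) > 0) {
    keep <- rep(TRUE, ncol(rays))
    for (j in seq_len(ncol(rays))) {
      supp <- which(rays[, j] != 0)
      if (length(supp) == 2 &&
          sp$from[supp[1]] == sp$from[supp[2]] &&
          sp$dir[supp[1]] == -sp$dir[supp[2]]) {
        keep[j] <- FALSE
      }
    }
    rays <- rays[, keep, drop = FALSE]
  }

  exch <- model$reactions$id[model$reactions$is_exchange]
  n_rays <- ncol(rays)
  flux_split <- vector("list", n_rays)
  flux_net <- vector("list", n_rays)
  loops <- logical(n_rays)
  for (j in seq_len(n_rays)) {
    v <- rays[, j]
    flux_split[[j]] <- setNames(v, sp$ids)
    net <- tapply(v * sp$dir, sp$from, sum)
    net <- setNames(as.numeric(net), names(net))[unique(sp$from)]
    flux_net[[j]] <- net
    loops[j] <- all(net[names(net) %in% exch] == 0)
  }
  out <- tibble(pathway = seq_len(n_rays),
                flux_split = flux_split,
                flux_net = flux_net,
                is_internal_loop = loops)
  class(out) <- c("fundamental_pathways", class(out))
  attr(out, "model") <- model
  attr(out, "split") <- sp
  out
}

# Core double-description iteration. A: integer matrix. Returns a matrix
# whose columns are the extreme rays (smallest-integer scaling).
dd_rays <- function(A) {
  n <- ncol(A)
  R <- diag(n)                          # rays as columns
  row_order <- order(rowSums(A != 0))
  for (i in row_order) {
    a <- A[i, ]
    s <- as.numeric(a %*% R)
    zero <- which(near_zero(s)); pos <- which(s > 0); neg <- which(s < 0)
    new_cols <- list()
    if (length(pos) > 0 && length(neg) > 0) {
      supp <- R != 0
      for (p in pos) {
        for (q in neg) {
          u <- supp[, p] | supp[, q]
          others <- setdiff(seq_len(ncol(R)), c(p, q))
          adjacent <- TRUE
          for (r in others) {
            if (all(supp[, r] <= u)) { adjacent <- FALSE; break }
          }
          if (!adjacent) next
          v <- s[p] * R[, q] - s[q] * R[, p]
          check_int_magnitude(v)
          v <- v / gcd_vec(v)
          new_cols[[length(new_cols) + 1]] <- v
        }
      }
    }
    R <- cbind(R[, zero, drop = FALSE],
               if (length(new_cols) > 0) do.call(cbind, new_cols))
    if (is.null(R) || ncol(R) == 0) return(matrix(0, nrow = n, ncol = 0))
  }
  # canonical scaling + dedup (identical support and proportional values
  # collapse to the same integer vector after gcd reduction)
  R <- apply(R, 2, function(v) v / gcd_vec(v))
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  R <- R[, !duplicated(t(R)), drop = FALSE]
  R
}

#' Annotate a pathway set with its imbalance in the original model
#'
#' For each pathway, the imbalance is the exact product of the ORIGINAL
#' stoichiometric matrix with the pathway's net flux vector: zero on every
#' metabolite retained (balanced) in the reduced model, generally non-zero on
#' removed currency metabolites. Net production is positive.
#'
#' @param pathways a `fundamental_pathways` tibble.
#' @param full the original [metabolic_model()].
#' @return the tibble with an `imbalance` list-column (named numeric, only
#'   non-zero entries).
#' @export
annotate_imbalance <- function(pathways, full) {
  S <- as.matrix(full$S)
  pathways$imbalance <- purrr::map(pathways$flux_net, function(net) {
    unknown <- setdiff(names(net), colnames(S))
    if (length(unknown) > 0) {
      abort(paste0("Pathway references unknown reaction(s): ",
                   paste(unknown, collapse = ", ")))
    }
    v <- setNames(numeric(ncol(S)), colnames(S))
    v[names(net)] <- net
    imb <- as.numeric(S %*% v)
    names(imb) <- rownames(S)
    imb[imb != 0]
  })
  attr(pathways, "full_model") <- full
  pathways
}

#' Cheapest conversion of an energy carrier into ATP
#'
#' On the full cost-augmented model with all uptakes closed, injects one unit
#' of the reduced carrier (regenerating its oxidized partner), maximizes the
#' ATP drain flux to obtain the yield, then minimizes the cost-sink flux at
#' that yield. ATP itself converts with yield 1 at zero cost.
#'
#' @param aug a `cost_augmented_model`.
#' @param carrier_id carrier base name (`"nadh"`, `"q8h2"`, ... or `"atp"`).
#' @param medium optional medium; all uptake bounds are closed regardless.
#' @param atp_drain_id id of the ATP-hydrolysis drain reaction measuring the
#'   yield.
#' @return list `(yield, cost)` per unit carrier; `(0, 0)` with a warning if
#'   the carrier cannot be converted.
#' @export
carrier_conversion <- function(aug, carrier_id, medium = NULL,
                               atp_drain_id = "ATPM") {
  carrier_id <- tolower(carrier_id)
  if (carrier_id == "atp") return(list(yield = 1, cost = 0))

  model <- apply_medium(aug$model, medium)
  # close every uptake: nothing enters; the carrier injection is the only input
  model$reactions$lower_bound[model$reactions$is_exchange &
                                model$reactions$lower_bound < 0] <- 0

  if (!atp_drain_id %in% model$reactions$id) {
    abort(paste0("ATP drain reaction not in model: ", atp_drain_id))
  }
  base <- purrr::map2_chr(model$metabolites$id, model$metabolites$compartment,
                          met_base_name)
  red_ids <- model$metabolites$id[base == carrier_id]
  ox_base <- carrier_partner(carrier_id)
  ox_ids <- if (!is.na(ox_base)) model$metabolites$id[base == ox_base] else character(0)
  if (length(red_ids) == 0) {
    warn(paste0("Carrier not in model: ", carrier_id))
    return(list(yield = 0, cost = 0))
  }

  st <- setNames(1, red_ids[[1]])
  if (length(ox_ids) > 0) st[ox_ids[[1]]] <- -1
  inj_id <- "CARRIER_INJECT__tmp"
  rxns <- dplyr::bind_rows(model$reactions,
    tibble(id = inj_id, name = inj_id, lower_bound = 1, upper_bound = 1,
           enzyme_associated = FALSE, objective_coefficient = 0,
           reversible = FALSE, is_exchange = FALSE))
  stoich <- stoich_as_list(model)
  stoich[[inj_id]] <- st
  m2 <- metabolic_model(model$metabolites, rxns, stoich,
                        objective_id = model$objective_id,
                        big_bound = model$big_bound,
                        require_objective = FALSE)

  S <- as.matrix(m2$S)
  lb <- m2$reactions$lower_bound; ub <- m2$reactions$upper_bound
  ids <- m2$reactions$id
  drain_obj <- as.numeric(ids == atp_drain_id)
  res <- lp_solve(drain_obj, S, lb, ub, maximize = TRUE)
  if (res$status != "optimal" || res$objective <= 1e-9) {
    warn(paste0("Carrier '", carrier_id, "' cannot be converted into ATP here."))
    return(list(yield = 0, cost = 0))
  }
  yield <- res$objective

  i_drain <- match(atp_drain_id, ids)
  lb[i_drain] <- yield; ub[i_drain] <- yield
  cost_obj <- as.numeric(ids == aug$cost_sink_id)
  res2 <- lp_solve(cost_obj, S, lb, ub, maximize = FALSE)
  cost <- if (res2$status == "optimal") res2$objective else NA_real_
  list(yield = yield, cost = cost)
}

#' Recover a full-model balanced flux vector from a fundamental pathway
#'
#' A fundamental pathway balances every retained metabolite but leaves a
#' currency imbalance in the original model. This adds flux through the
#' REMOVED reactions (the balancing loops: ATP hydrolysis, proton transport,
#' their exchanges) to cancel that imbalance, minimizing the total added
#' flux. The returned vector is balanced in the original network.
#'
#' @param pathways an annotated `fundamental_pathways` tibble.
#' @param reduced the `reduced_model` the pathways came from.
#' @param k pathway index (row of `pathways`).
#' @return named flux vector over all original reactions, or `NULL` (with a
#'   warning) when the removed reactions cannot balance the pathway.
#' @export
recover_pathway <- function(pathways, reduced, k = 1) {
  full <- reduced$original
  net <- pathways$flux_net[[k]]
  v <- setNames(numeric(nrow(full$reactions)), full$reactions$id)
  v[names(net)] <- net

  removed <- reduced$removed_reactions
  if (length(removed) == 0) return(v)
  S <- as.matrix(full$S)
  rhs <- as.numeric(-S %*% v)

  # columns: removed reactions, reversible ones split so the objective
  # (total added flux) is a plain sum
  cols <- list(); ids <- character(0); sgn <- numeric(0); ubs <- numeric(0)
  for (id in removed) {
    i <- match(id, full$reactions$id)
    if (full$reactions$upper_bound[[i]] > 0) {
      cols[[length(cols) + 1]] <- S[, id]
      ids <- c(ids, id); sgn <- c(sgn, 1)
      ubs <- c(ubs, full$reactions$upper_bound[[i]])
    }
    if (full$reactions$lower_bound[[i]] < 0) {
      cols[[length(cols) + 1]] <- -S[, id]
      ids <- c(ids, id); sgn <- c(sgn, -1)
      ubs <- c(ubs, -full$reactions$lower_bound[[i]])
    }
  }
  A <- do.call(cbind, cols)
  # lp over [x; slack for rhs rows]? rhs must be met exactly: A x = rhs
  # shift into lp_solve form by appending a fixed column carrying rhs
  Ax <- cbind(A, -rhs)
  lb <- c(rep(0, ncol(A)), 1)
  ub <- c(ubs, 1)
  res <- lp_solve(c(rep(1, ncol(A)), 0), Ax, lb, ub, maximize = FALSE)
  if (res$status != "optimal") {
    warn("Removed reactions cannot rebalance this pathway.")
    return(NULL)
  }
  x <- res$fluxes[seq_len(ncol(A))]
  for (j in seq_along(ids)) v[ids[j]] <- v[ids[j]] + sgn[j] * x[j]
  v
}

#' ATP-production potential and total cost per pathway
#'
#' Each pathway is normalized per mmol glucose (glucose-uptake flux scaled to
#' 1 when non-zero, otherwise per pathway unit). The ATP potential is the ATP
#' imbalance plus, for every energy carrier, its imbalance credited at the
#' carrier's ATP yield (symmetric: a consumed carrier debits the potential).
#' The total cost is the pathway's own enzyme cost (cost coefficients applied
#' to the split direction fluxes) plus the conversion cost of the carriers it
#' over-produces. `cost_per_atp` is `total_cost / atp_potential`, `Inf` when
#' the potential is non-positive.
#'
#' @param pathways an imbalance-annotated `fundamental_pathways` tibble.
#' @param conversions named list of `(yield, cost)` per carrier base name
#'   (from [carrier_conversion()]).
#' @param coeffs `cost_coefficients` for the original model.
#' @param carriers carrier base names to credit.
#' @param glucose_exchange_id id of the glucose exchange reaction (uptake is
#'   its negative flux), or `NULL` to skip glucose normalization.
#' @return the tibble with `atp_potential`, `total_cost`, `cost_per_atp` and
#'   a `glc_normalized` flag.
#' @export
atp_potential <- function(pathways, conversions, coeffs,
                          carriers = default_energy_carriers(),
                          glucose_exchange_id = NULL) {
  full <- attr(pathways, "full_model")
  if (is.null(full) || !"imbalance" %in% names(pathways)) {
    abort("Run annotate_imbalance() before atp_potential().")
  }
  base_of <- function(met_ids) {
    idx <- match(met_ids, full$metabolites$id)
    purrr::map2_chr(met_ids, full$metabolites$compartment[idx], met_base_name)
  }
  missing <- setdiff(tolower(carriers), names(conversions))
  if (length(missing) > 0) {
    abort(paste0("No conversion entry for carrier(s): ",
                 paste(missing, collapse = ", ")))
  }
  cf <- setNames(coeffs$cost_forward, coeffs$reaction_id)
  cb <- setNames(coeffs$cost_backward, coeffs$reaction_id)

  n <- nrow(pathways)
  atp <- numeric(n); cost <- numeric(n); scaled <- logical(n)
  for (k in seq_len(n)) {
    net <- pathways$flux_net[[k]]
    imb <- pathways$imbalance[[k]]
    scale <- 1
    if (!is.null(glucose_exchange_id) && glucose_exchange_id %in% names(net) &&
        net[[glucose_exchange_id]] < 0) {
      scale <- 1 / abs(net[[glucose_exchange_id]])
      scaled[k] <- TRUE
    }
    net <- net * scale; imb <- imb * scale

    imb_base <- setNames(as.numeric(imb), base_of(names(imb)))
    pot <- sum(imb_base[names(imb_base) == "atp"])
    cc <- 0
    for (cr in tolower(carriers)) {
      x <- sum(imb_base[names(imb_base) == cr])
      if (x == 0) next
      pot <- pot + x * conversions[[cr]]$yield
      if (x > 0) cc <- cc + x * conversions[[cr]]$cost
    }
    # own enzyme cost from the direction fluxes
    own <- 0
    for (r in names(net)) {
      v <- net[[r]]
      if (v > 0 && !is.na(cf[r])) own <- own + v * cf[r]
      if (v < 0 && !is.na(cb[r])) own <- own + (-v) * cb[r]
    }
    atp[k] <- pot
    cost[k] <- own + cc
  }
  pathways$atp_potential <- atp
  pathways$total_cost <- cost
  pathways$cost_per_atp <- ifelse(atp > 0, cost / atp, Inf)
  pathways$glc_normalized <- scaled
  pathways
}

#' Classify pathways as optimal / near-optimal on the energy Pareto front
#'
#' Optimal pathways (OP) are non-dominated in (maximize ATP potential per
#' glucose, minimize cost per ATP); near-optimal pathways (NOP) reach the
#' frontier when their coordinates are relaxed by `margin`; the rest are
#' `"other"`. Internal loops and pathways with non-positive ATP potential are
#' excluded from the frontier and classified `"other"`.
#'
#' @param pathways a `fundamental_pathways` tibble with `atp_potential` and
#'   `cost_per_atp`.
#' @param margin relative dominance margin for NOP (default 0.10).
#' @return the tibble with a `classification` column.
#' @export
pareto_classify <- function(pathways, margin = 0.10) {
  n <- nrow(pathways)
  cls <- rep("other", n)
  if (n == 0) {
    pathways$classification <- character(0)
    return(pathways)
  }
  eligible <- !pathways$is_internal_loop & pathways$atp_potential > 0 &
    is.finite(pathways$cost_per_atp)
  dominates <- function(a_atp, a_cpa, b_atp, b_cpa) {
    (a_atp >= b_atp && a_cpa <= b_cpa) && (a_atp > b_atp || a_cpa < b_cpa)
  }
  idx <- which(eligible)
  for (i in idx) {
    dom <- any(purrr::map_lgl(setdiff(idx, i), function(j) {
      dominates(pathways$atp_potential[[j]], pathways$cost_per_atp[[j]],
                pathways$atp_potential[[i]], pathways$cost_per_atp[[i]])
    }))
    if (!dom) cls[i] <- "OP"
  }
  ops <- which(cls == "OP")
  for (i in setdiff(idx, ops)) {
    relaxed_atp <- pathways$atp_potential[[i]] * (1 + margin)
    relaxed_cpa <- pathways$cost_per_atp[[i]] * (1 - margin)
    dom <- any(purrr::map_lgl(ops, function(j) {
      dominates(pathways$atp_potential[[j]], pathways$cost_per_atp[[j]],
                relaxed_atp, relaxed_cpa)
    }))
    if (!dom) cls[i] <- "NOP"
  }
  pathways$classification <- cls
  pathways
}

#' Full fundamental-pathway analysis in one call
#'
#' Chains [reduce_model()], [enumerate_pathways()], [annotate_imbalance()],
#' [carrier_conversion()] for each requested carrier, [atp_potential()] and
#' [pareto_classify()].
#'
#' @param model a [metabolic_model()].
#' @param costs a `cost_table`; `NULL` gives uniform costs.
#' @param currency_ids currency metabolite base names.
#' @param carriers energy-carrier base names.
#' @param cost_type cost type for the pathway cost (see
#'   [build_cost_coefficients()]).
#' @param medium optional medium for the conversion LPs.
#' @param glucose_exchange_id glucose exchange id for per-glucose
#'   normalization, or `NULL`.
#' @param atp_drain_id ATP drain used to measure conversion yields.
#' @param max_cols enumeration size guard.
#' @return a classified `fundamental_pathways` tibble.
#' @export
fundamental_pathways <- function(model, costs = NULL,
                                 currency_ids = default_currency_metabolites(),
                                 carriers = default_energy_carriers(),
                                 cost_type = "combined", medium = NULL,
                                 glucose_exchange_id = NULL,
                                 atp_drain_id = "ATPM", max_cols = 80) {
  if (is.null(costs)) {
    costs <- cost_table(model$reactions$id, rep(NA_real_, nrow(model$reactions)),
                        rep(0, nrow(model$reactions)),
                        model$reactions$enzyme_associated)
    costs$mw_kda[costs$enzyme_associated] <- 1
    cost_type <- "uniform"
  }
  coeffs <- build_cost_coefficients(model, costs, cost_type = cost_type)
  reduced <- reduce_model(model, currency_ids)
  paths <- enumerate_pathways(reduced, max_cols = max_cols)
  paths <- annotate_imbalance(paths, model)

  aug <- augment_model(model, coeffs)
  conversions <- list()
  for (cr in tolower(carriers)) {
    conversions[[cr]] <- suppressWarnings(
      carrier_conversion(aug, cr, medium = medium, atp_drain_id = atp_drain_id))
  }
  paths <- atp_potential(paths, conversions, coeffs, carriers = carriers,
                         glucose_exchange_id = glucose_exchange_id)
  pareto_classify(paths)
}

#' @exportS3Method generics::tidy
tidy.fundamental_pathways <- function(x, ...) {
  out <- tibble(
    pathway = x$pathway,
    n_reactions = purrr::map_int(x$flux_net, ~ sum(.x != 0)),
    is_internal_loop = x$is_internal_loop
  )
  for (col in c("atp_potential", "total_cost", "cost_per_atp", "classification")) {
    if (col %in% names(x)) out[[col]] <- x[[col]]
  }
  out
}

#' Write pathway tables to TSV
#'
#' Main table: one row per pathway with `reaction:flux` and `met:imbalance`
#' pair strings plus the annotation columns. A second scatter table
#' (`<path>_scatter.tsv`) holds the ATP-potential versus cost-per-ATP
#' coordinates of non-loop pathways.
#'
#' @param pathways a `fundamental_pathways` tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pathway_report <- function(pathways, path) {
  fmt_pairs <- function(v) paste(paste0(names(v), ":", v), collapse = ";")
  out <- tibble(
    pathway = pathways$pathway,
    reactions = purrr::map_chr(pathways$flux_net, ~ fmt_pairs(.x[.x != 0])),
    imbalance = if ("imbalance" %in% names(pathways))
      purrr::map_chr(pathways$imbalance, fmt_pairs) else "",
    atp_potential = pathways$atp_potential %||% NA_real_,
    total_cost = pathways$total_cost %||% NA_real_,
    cost_per_atp = pathways$cost_per_atp %||% NA_real_,
    classification = pathways$classification %||% "",
    is_internal_loop = pathways$is_internal_loop
  )
  readr::write_tsv(out, path)
  if ("atp_potential" %in% names(pathways)) {
    sc <- out[!out$is_internal_loop & is.finite(out$cost_per_atp), ]
    readr::write_tsv(sc[, c("pathway", "atp_potential", "cost_per_atp",
                            "classification")],
                     sub("\\.tsv$", "_scatter.tsv", path))
  }
  invisible(path)
}
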