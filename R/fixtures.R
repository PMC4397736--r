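# Deterministic toy models and cost tables. These encode the study's worked
# networks: a glucose-to-lactate glycolysis with ATP-hydrolysis / proton
# transport balancing loops, a two-pathway overflow model, a small
# electron-transport-chain model for carrier conversion, and an
# internal-loop network. All are emitted as in-memory objects and can be
# written to JSON/TSV files to exercise the I/O and CLI paths end to end.

#' Glycolysis-to-lactate fixture with balancing loops
#'
#' Encodes standard glycolysis from extracellular glucose (PTS uptake) down
#' to D-lactate secretion: net conversion of 1 glucose to 2 lactate producing
#' 2 ATP. Alongside the core route the model carries the balancing set - ATP
#' maintenance hydrolysis (`ATPM`), reversible ATP synthase (`ATPS4r`), a
#' reversible proton transporter (`Ht`) and a proton exchange - so that the
#' full network admits several extreme pathways that share the same core
#' reactions, while currency-metabolite removal collapses them to a single
#' fundamental pathway with ATP/ADP/Pi/H2O imbalances.
#'
#' The objective is `ATPM` (ATP drain), so FBA maximizes energy production:
#' optimum 2 ATP per glucose.
#'
#' @param glc_bound maximum glucose uptake (mmol/gDW/h).
#' @return list with elements `model` ([metabolic_model()]), `costs`
#'   (`cost_table`) and `medium` (tibble).
#' @export
make_glycolysis_fixture <- function(glc_bound = 10) {
  mets <- tibble(
    id = c("glc_D_e", "g6p_c", "f6p_c", "fdp_c", "dhap_c", "g3p_c",
           "x13dpg_c", "x3pg_c", "x2pg_c", "pep_c", "pyr_c", "lac_D_c",
           "lac_D_e", "atp_c", "adp_c", "pi_c", "h_c", "h2o_c",
           "nad_c", "nadh_c", "h_e"),
    name = c("D-glucose", "glucose 6-phosphate", "fructose 6-phosphate",
             "fructose 1,6-bisphosphate", "DHAP", "glyceraldehyde 3-phosphate",
             "1,3-bisphospho-D-glycerate", "3-phospho-D-glycerate",
             "2-phospho-D-glycerate", "PEP", "pyruvate", "D-lactate",
             "D-lactate", "ATP", "ADP", "phosphate", "H+", "H2O",
             "NAD+", "NADH", "H+"),
    compartment = c("e", rep("c", 11), "e", rep("c", 7), "e")
  )

  stoich <- list(
    EX_glc = c(glc_D_e = -1),
    EX_lac = c(lac_D_e = -1),
    EX_h = c(h_e = -1),
    GLCpts = c(glc_D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
    PGI = c(g6p_c = -1, f6p_c = 1),
    PFK = c(atp_c = -1, f6p_c = -1, adp_c = 1, fdp_c = 1, h_c = 1),
    FBA = c(fdp_c = -1, dhap_c = 1, g3p_c = 1),
    TPI = c(dhap_c = -1, g3p_c = 1),
    GAPD = c(g3p_c = -1, nad_c = -1, pi_c = -1, x13dpg_c = 1, h_c = 1, nadh_c = 1),
    PGK = c(x13dpg_c = -1, adp_c = -1, x3pg_c = 1, atp_c = 1),
    PGM = c(x3pg_c = -1, x2pg_c = 1),
    ENO = c(x2pg_c = -1, h2o_c = 1, pep_c = 1),
    PYK = c(adp_c = -1, h_c = -1, pep_c = -1, atp_c = 1, pyr_c = 1),
    LDH_D = c(pyr_c = -1, nadh_c = -1, h_c = -1, lac_D_c = 1, nad_c = 1),
    D_LACt2 = c(lac_D_c = -1, h_c = -1, lac_D_e = 1, h_e = 1),
    ATPM = c(atp_c = -1, h2o_c = -1, adp_c = 1, h_c = 1, pi_c = 1),
    ATPS4r = c(adp_c = -1, pi_c = -1, h_e = -4, atp_c = 1, h2o_c = 1, h_c = 3),
    Ht = c(h_e = -1, h_c = 1)
  )

  # D_LACt2 is a proton symport (outward proton export rides on lactate);
  # Ht is an inward-only leak - a free outward pump next to ATPS4r would be
  # a perpetual-motion proton cycle and unbound the ATP optimum
  rev_ids <- c("PGI", "FBA", "TPI", "GAPD", "PGK", "PGM", "ENO", "D_LACt2",
               "ATPS4r")
  enz_ids <- c("GLCpts", "PGI", "PFK", "FBA", "TPI", "GAPD", "PGK", "PGM",
               "ENO", "PYK", "LDH_D", "ATPS4r")
  ids <- names(stoich)
  rxns <- tibble(
    id = ids,
    lower_bound = dplyr::case_when(
      ids == "EX_glc" ~ -glc_bound,
      ids %in% rev_ids ~ -1000,
      TRUE ~ 0
    ),
    upper_bound = dplyr::if_else(ids == "EX_glc", 0, 1000),
    enzyme_associated = ids %in% enz_ids,
    objective_coefficient = as.numeric(ids == "ATPM")
  )
  model <- metabolic_model(mets, rxns, stoich, objective_id = "ATPM")

  # molecular weights (kDa) and standard Gibbs energies (kcal/mol) of the
  # usual magnitude for these enzymes; exchanges/transport/maintenance are
  # non-enzymatic (zero cost)
  costs <- cost_table(
    reaction_id = ids,
    mw_kda = c(NA, NA, NA, 170, 61.5, 140, 78, 54, 146, 85, 57, 93, 51, 115,
               NA, NA, 530, NA),
    dG0_kcal_mol = c(0, 0, 0, -4.0, 0.6, -3.4, 5.3, 1.8, 1.5, -4.5, 1.0, -1.0,
                     -5.9, -6.0, 0, 0, -3.0, 0),
    enzyme_associated = ids %in% enz_ids
  )
  medium <- tibble(exchange_id = c("EX_glc", "EX_lac", "EX_h"),
                   uptake_bound = c(glc_bound, 0, 0),
                   secretion_allowed = c(0, 1, 1))
  list(model = model, costs = costs, medium = medium)
}

#' Two-pathway overflow fixture
#'
#' Two parallel routes from glucose to biomass: a high-yield, enzymatically
#' expensive route and a low-yield, cheap route. Glucose-limited FBA forces
#' the high-yield route at fraction 1; below the switch fraction
#' `f* = yield_lo / yield_hi` the cost-minimal solution runs entirely through
#' the cheap route - the enzyme-cost / energy-yield tradeoff behind overflow
#' metabolism.
#'
#' @param yield_hi,yield_lo biomass yield per glucose of the two routes
#'   (`yield_hi > yield_lo > 0`).
#' @param cost_hi,cost_lo enzyme MW (= cost per unit flux, dG0 = 0) of the
#'   two routes; a switch exists when `cost_hi/yield_hi > cost_lo/yield_lo`.
#' @param glc_bound glucose uptake bound.
#' @return list with `model`, `costs`, `medium` and the derived switch
#'   fraction `f_star`.
#' @export
make_overflow_fixture <- function(yield_hi = 2, yield_lo = 1,
                                  cost_hi = 10, cost_lo = 3, glc_bound = 10) {
  stopifnot(yield_hi > yield_lo, yield_lo > 0)
  if (cost_hi / yield_hi <= cost_lo / yield_lo) {
    warn("No cost/yield switch: the high-yield route is also cheaper per biomass.")
  }
  mets <- tibble(
    id = c("glc_e", "glc_c", "bm_c"),
    name = c("glucose", "glucose", "biomass precursor"),
    compartment = c("e", "c", "c")
  )
  stoich <- list(
    EX_glc = c(glc_e = -1),
    GLCt = c(glc_e = -1, glc_c = 1),
    PATH_HI = setNames(c(-1, yield_hi), c("glc_c", "bm_c")),
    PATH_LO = setNames(c(-1, yield_lo), c("glc_c", "bm_c")),
    BIOMASS = c(bm_c = -1)
  )
  ids <- names(stoich)
  rxns <- tibble(
    id = ids,
    lower_bound = dplyr::if_else(ids == "EX_glc", -glc_bound, 0),
    upper_bound = dplyr::if_else(ids == "EX_glc", 0, 1000),
    enzyme_associated = ids %in% c("PATH_HI", "PATH_LO"),
    objective_coefficient = as.numeric(ids == "BIOMASS")
  )
  model <- metabolic_model(mets, rxns, stoich, objective_id = "BIOMASS")
  costs <- cost_table(
    reaction_id = ids,
    mw_kda = c(NA, NA, cost_hi, cost_lo, NA),
    dG0_kcal_mol = rep(0, 5),
    enzyme_associated = ids %in% c("PATH_HI", "PATH_LO")
  )
  medium <- tibble(exchange_id = "EX_glc", uptake_bound = glc_bound,
                   secretion_allowed = 0)
  list(model = model, costs = costs, medium = medium,
       f_star = yield_lo / yield_hi)
}

#' Internal-loop fixture
#'
#' A linear substrate-to-product chain plus a three-reaction internal cycle
#' with no exchange flux (a thermodynamically infeasible "type III" cycle).
#' Pathway enumeration flags the cycle `is_internal_loop = TRUE`; cost-minimal
#' solutions carry zero flux around it because any loop flux only adds cost.
#'
#' @param seed integer; permutes reaction order (the network is otherwise
#'   fixed, so the same seed gives a bit-identical model).
#' @return list with `model`, `costs`, `medium`.
#' @export
make_loop_fixture <- function(seed = 1) {
  mets <- tibble(
    id = c("s_e", "s_c", "p_c", "p_e", "a_c", "b_c", "c_c"),
    name = c("substrate", "substrate", "product", "product", "A", "B", "C"),
    compartment = c("e", "c", "c", "e", "c", "c", "c")
  )
  stoich <- list(
    EX_s = c(s_e = -1),
    St = c(s_e = -1, s_c = 1),
    CONV = c(s_c = -1, p_c = 1),
    Pt = c(p_c = -1, p_e = 1),
    EX_p = c(p_e = -1),
    L1 = c(a_c = -1, b_c = 1),
    L2 = c(b_c = -1, c_c = 1),
    L3 = c(c_c = -1, a_c = 1)
  )
  ids <- names(stoich)
  ord <- withr_seed_sample(seed, seq_along(ids))
  stoich <- stoich[ord]
  ids <- names(stoich)
  rxns <- tibble(
    id = ids,
    lower_bound = dplyr::if_else(ids == "EX_s", -10, 0),
    upper_bound = dplyr::if_else(ids == "EX_s", 0, 1000),
    enzyme_associated = ids %in% c("CONV", "L1", "L2", "L3"),
    objective_coefficient = as.numeric(ids == "EX_p")
  )
  model <- metabolic_model(mets, rxns, stoich, objective_id = "EX_p")
  costs <- cost_table(
    reaction_id = ids,
    mw_kda = ifelse(ids %in% c("CONV", "L1", "L2", "L3"), 50, NA),
    dG0_kcal_mol = rep(0, length(ids)),
    enzyme_associated = ids %in% c("CONV", "L1", "L2", "L3")
  )
  medium <- tibble(exchange_id = c("EX_s", "EX_p"), uptake_bound = c(10, 0),
                   secretion_allowed = c(0, 1))
  list(model = model, costs = costs, medium = medium)
}

# draw a permutation under a local seed without touching the global RNG stream
withr_seed_sample <- function(seed, x) {
  withr::with_seed(seed, sample(x))
}

#' Minimal electron-transport-chain fixture
#'
#' One NADH dehydrogenase pumps 4 protons per NADH; ATP synthase makes one
#' ATP per 2 pumped protons; an ATP drain (`ATPM`) measures the yield: 2 ATP
#' per NADH. Used to exercise energy-carrier conversion.
#'
#' @return list with `model`, `costs`, `medium`.
#' @export
make_etc_fixture <- function() {
  mets <- tibble(
    id = c("nadh_c", "nad_c", "h_e", "atp_c", "adp_c", "pi_c", "h2o_c"),
    name = c("NADH", "NAD+", "H+ (periplasm)", "ATP", "ADP", "phosphate", "H2O"),
    compartment = c(rep("c", 2), "e", rep("c", 4))
  )
  stoich <- list(
    NDH = c(nadh_c = -1, nad_c = 1, h_e = 4),
    ATPS = c(adp_c = -1, pi_c = -1, h_e = -2, atp_c = 1, h2o_c = 1),
    ATPM = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1)
  )
  ids <- names(stoich)
  rxns <- tibble(
    id = ids,
    lower_bound = 0,
    upper_bound = 1000,
    enzyme_associated = ids %in% c("NDH", "ATPS"),
    objective_coefficient = as.numeric(ids == "ATPM")
  )
  model <- metabolic_model(mets, rxns, stoich, objective_id = "ATPM")
  costs <- cost_table(
    reaction_id = ids,
    mw_kda = c(550, 530, NA),
    dG0_kcal_mol = c(-18, 8, -7),
    enzyme_associated = ids %in% c("NDH", "ATPS")
  )
  list(model = model, costs = costs, medium = NULL)
}

#' Random small toy model for solver cross-checks
#'
#' Builds a feasible two-route network from substrate to product with
#' seed-determined integer yields, reversibility pattern, enzyme molecular
#' weights and Gibbs energies. Same seed, same model.
#'
#' @param seed integer seed.
#' @return list with `model`, `costs`, `medium`.
#' @export
make_random_toy_model <- function(seed = 1) {
  withr::local_seed(seed)

  y1 <- sample(1:3, 1); y2 <- sample(1:3, 1)
  via_mid <- sample(c(TRUE, FALSE), 1)   # route 2 through an intermediate?
  rev2 <- sample(c(TRUE, FALSE), 1)

  mets <- tibble(
    id = c("s_e", "s_c", "m_c", "p_c", "p_e"),
    name = c("substrate", "substrate", "intermediate", "product", "product"),
    compartment = c("e", "c", "c", "c", "e")
  )
  stoich <- list(
    EX_s = c(s_e = -1),
    St = c(s_e = -1, s_c = 1),
    R1 = setNames(c(-1, y1), c("s_c", "p_c")),
    Pt = c(p_c = -1, p_e = 1),
    EX_p = c(p_e = -1)
  )
  if (via_mid) {
    stoich$R2a <- c(s_c = -1, m_c = 1)
    stoich$R2b <- setNames(c(-1, y2), c("m_c", "p_c"))
  } else {
    stoich$R2 <- setNames(c(-1, y2), c("s_c", "p_c"))
  }
  ids <- names(stoich)
  enz <- setdiff(ids, c("EX_s", "EX_p", "St", "Pt"))
  rev_pick <- if (rev2 && via_mid) "R2a" else character(0)
  rxns <- tibble(
    id = ids,
    lower_bound = dplyr::case_when(
      ids == "EX_s" ~ -10,
      ids %in% rev_pick ~ -1000,
      TRUE ~ 0
    ),
    upper_bound = dplyr::if_else(ids == "EX_s", 0, 1000),
    enzyme_associated = ids %in% enz,
    objective_coefficient = as.numeric(ids == "EX_p")
  )
  model <- metabolic_model(mets, rxns, stoich, objective_id = "EX_p")
  costs <- cost_table(
    reaction_id = ids,
    mw_kda = ifelse(ids %in% enz, sample(10:200, length(ids), replace = TRUE), NA),
    dG0_kcal_mol = ifelse(ids %in% enz, round(runif(length(ids), -6, 6), 1), 0),
    enzyme_associated = ids %in% enz
  )
  medium <- tibble(exchange_id = "EX_s", uptake_bound = 10, secretion_allowed = 0)
  list(model = model, costs = costs, medium = medium)
}

#' Write a fixture to files
#'
#' Emits `model.json`, `costs.tsv` and (when present) `medium.tsv` into a
#' directory so the CLI and file-based workflows can be exercised end to end.
#'
#' @param fixture a fixture list (`model`, `costs`, `medium`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_model(fixture$model, file.path(dir, "model.json"), format = "json")
  write_cost_table(fixture$costs, file.path(dir, "costs.tsv"))
  if (!is.null(fixture$medium)) {
    write_medium(fixture$medium, file.path(dir, "medium.tsv"))
  }
  invisible(dir)
}
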