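# Currency removal, extreme-ray enumeration (against an exhaustive oracle),
# imbalance annotation, carrier conversion, ATP potential and Pareto classes.

test_that("currency removal empties pure-currency reactions and keeps the rest", {
  fx <- make_glycolysis_fixture()
  red <- reduce_model(fx$model, c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"))
  expect_setequal(red$removed_reactions, c("EX_h", "ATPM", "ATPS4r", "Ht"))
  # no removed metabolite appears in any retained reaction
  expect_length(intersect(red$removed_metabolites, red$model$metabolites$id), 0)
  expect_false(any(red$warnings$kind %in% c("became_sink", "became_source")))
  # retained reaction changed in place: PFK lost its currency partners
  expect_equal(names(corsofba:::reaction_stoich(red$model, "PFK")),
               c("f6p_c", "fdp_c"))
})

test_that("removing an absent metabolite warns and is a no-op", {
  fx <- make_overflow_fixture()
  expect_warning(red <- reduce_model(fx$model, c("atp")), "not present")
  expect_length(red$removed_metabolites, 0)
  expect_equal(nrow(red$model$reactions), nrow(fx$model$reactions))
})

test_that("reactions that become sources or sinks are flagged, not dropped", {
  mets <- tibble::tibble(id = c("a_c", "b_c", "c_c"), name = c("a", "b", "c"),
                         compartment = "c")
  stoich <- list(R1 = c(a_c = -1, b_c = -1, c_c = 1), EX_c = c(c_c = -1),
                 EX_a = c(a_c = -1), EX_b = c(b_c = -1))
  rxns <- tibble::tibble(id = names(stoich), lower_bound = c(0, 0, -10, -10),
                         upper_bound = c(1000, 1000, 0, 0),
                         enzyme_associated = c(TRUE, FALSE, FALSE, FALSE),
                         objective_coefficient = c(0, 1, 0, 0))
  model <- metabolic_model(mets, rxns, stoich, objective_id = "EX_c")

  # removing one substrate leaves a two-sided reaction: no warning
  red1 <- reduce_model(model, "b")
  expect_false(any(red1$warnings$kind == "became_source"))
  expect_equal(names(corsofba:::reaction_stoich(red1$model, "R1")),
               c("a_c", "c_c"))

  # removing both substrates leaves R1 a pure source of c
  expect_warning(red2 <- reduce_model(model, c("a", "b")), "source")
  expect_true(any(red2$warnings$kind == "became_source" &
                    red2$warnings$id == "R1"))
  expect_true("R1" %in% red2$model$reactions$id)  # flagged, not dropped
})

test_that("enumeration finds the expected rays on hand-checkable networks", {
  # single chain: exactly one pathway
  mets <- tibble::tibble(id = c("a_c", "b_c"), name = c("a", "b"),
                         compartment = "c")
  stoich <- list(EX_a = c(a_c = -1), R = c(a_c = -1, b_c = 1),
                 EX_b = c(b_c = -1))
  rxns <- tibble::tibble(id = names(stoich), lower_bound = c(-10, 0, 0),
                         upper_bound = c(0, 1000, 1000),
                         enzyme_associated = FALSE,
                         objective_coefficient = 0)
  chain <- metabolic_model(mets, rxns, stoich, require_objective = FALSE)
  p <- enumerate_pathways(chain)
  expect_equal(nrow(p), 1)
  expect_false(p$is_internal_loop[[1]])

  # diamond: two routes a -> b
  stoich2 <- list(EX_a = c(a_c = -1), R1 = c(a_c = -1, b_c = 1),
                  R2 = c(a_c = -1, b_c = 1), EX_b = c(b_c = -1))
  rxns2 <- tibble::tibble(id = names(stoich2), lower_bound = c(-10, 0, 0, 0),
                          upper_bound = c(0, 1000, 1000, 1000),
                          enzyme_associated = FALSE, objective_coefficient = 0)
  diamond <- metabolic_model(mets, rxns2, stoich2, require_objective = FALSE)
  p2 <- enumerate_pathways(diamond)
  expect_equal(nrow(p2), 2)

  # size guard
  expect_error(enumerate_pathways(diamond, max_cols = 3), "exponential")
})

test_that("enumeration equals the exhaustive support-minimal oracle on random cones", {
  n_nonempty <- 0
  for (seed in 1:24) {
    A <- random_cone_matrix(seed)
    model <- cone_model_from_matrix(A)
    rays_pkg <- enumerate_pathways(model, drop_two_cycles = FALSE)
    oracle <- support_minimal_rays(A)
    expect_equal(nrow(rays_pkg), length(oracle),
                 label = paste("ray count, seed", seed))
    if (length(oracle) == 0) next
    n_nonempty <- n_nonempty + 1
    norm_pkg <- lapply(rays_pkg$flux_split, function(v) {
      u <- as.numeric(v)
      u / max(u)
    })
    for (f in oracle) {
      hits <- vapply(norm_pkg, function(u) max(abs(u - f$ray)) < 1e-7, logical(1))
      expect_equal(sum(hits), 1,
                   label = paste("oracle ray matched once, seed", seed))
    }
    # exactness: S v = 0 exactly in integer arithmetic
    for (v in rays_pkg$flux_split) {
      expect_identical(max(abs(A %*% as.numeric(v))), 0)
      expect_identical(as.numeric(v), round(as.numeric(v)))
    }
  }
  expect_gte(n_nonempty, 10)
})

test_that("any feasible reduced flux is a nonnegative combination of the rays", {
  fx <- make_loop_fixture()
  red <- reduce_model(fx$model, character(0))
  rays <- enumerate_pathways(red, drop_two_cycles = FALSE)
  sp <- corsofba:::split_for_enumeration(red$model)
  A <- sp$A
  # random feasible points: optimize random objectives over the split cone
  for (seed in 1:5) {
    cc <- withr::with_seed(seed, stats::runif(ncol(A), -1, 1))
    v <- corsofba:::lp_solve(cc, A, rep(0, ncol(A)), rep(10, ncol(A)),
                             maximize = TRUE)$fluxes
    R <- do.call(cbind, lapply(rays$flux_split, as.numeric))
    # feasibility LP: R lambda = v, lambda >= 0  (solved as S x = 0 via
    # appending -v as a fixed column)
    res <- corsofba:::lp_solve(rep(0, ncol(R) + 1), cbind(R, -v),
                               c(rep(0, ncol(R)), 1),
                               c(rep(1000, ncol(R)), 1))
    expect_equal(res$status, "optimal", label = paste("decomposition seed", seed))
  }
})

test_that("imbalance annotation reproduces hand-computed products", {
  fx <- make_glycolysis_fixture()
  red <- reduce_model(fx$model, c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"))
  paths <- annotate_imbalance(enumerate_pathways(red), fx$model)
  expect_equal(nrow(paths), 1)
  imb <- paths$imbalance[[1]]
  scale <- abs(paths$flux_net[[1]][["EX_glc"]])
  expect_equal(unname(imb["atp_c"] / scale), 2)    # +2 ATP per glucose
  expect_equal(unname(imb["adp_c"] / scale), -2)
  expect_equal(unname(imb["pi_c"] / scale), -2)
  expect_equal(unname(imb["h2o_c"] / scale), 2)
  # no retained metabolite appears in the imbalance
  expect_length(intersect(names(imb), red$model$metabolites$id), 0)

  # a pathway balanced in the original model has an empty imbalance
  lf <- make_loop_fixture()
  redl <- reduce_model(lf$model, character(0))
  pl <- annotate_imbalance(enumerate_pathways(redl), lf$model)
  through <- which(!pl$is_internal_loop)
  expect_length(pl$imbalance[[through]], 0)

  expect_error(
    annotate_imbalance(
      within(paths, flux_net <- list(c(NOPE = 1))), fx$model),
    "unknown")
})

test_that("carrier conversion measures ATP yield and minimal cost", {
  ec <- make_etc_fixture()
  aug <- augment_model(ec$model,
                       build_cost_coefficients(ec$model, ec$costs, "combined"))
  conv <- carrier_conversion(aug, "nadh", atp_drain_id = "ATPM")
  expect_equal(conv$yield, 2)      # 4 pumped protons, 2 per ATP
  expect_gt(conv$cost, 0)

  expect_equal(carrier_conversion(aug, "atp"), list(yield = 1, cost = 0))

  # carrier disconnected from ATP production: zero yield plus a warning
  fx <- make_loop_fixture()
  augl <- augment_model(fx$model,
                        build_cost_coefficients(fx$model, fx$costs, "mw"))
  expect_warning(conv0 <- carrier_conversion(augl, "nadh", atp_drain_id = "CONV"),
                 "nadh")
  expect_equal(conv0, list(yield = 0, cost = 0))
})

test_that("ATP potential credits carriers at their conversion yield", {
  fx <- make_glycolysis_fixture()
  red <- reduce_model(fx$model, c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"))
  paths <- annotate_imbalance(enumerate_pathways(red), fx$model)
  coeffs <- build_cost_coefficients(fx$model, fx$costs, "combined")

  # no carriers: potential equals the ATP imbalance per glucose
  p0 <- atp_potential(paths, conversions = list(), coeffs,
                      carriers = character(0), glucose_exchange_id = "EX_glc")
  expect_equal(p0$atp_potential, 2)
  expect_true(p0$glc_normalized)
  expect_gt(p0$total_cost, 0)
  expect_equal(p0$cost_per_atp, p0$total_cost / 2)

  # synthetic imbalance {ATP +2, NADH +2} with yield 2 -> potential 6,
  # conversion cost added for the over-produced carrier
  fake <- paths
  fake$imbalance <- list(c(atp_c = 2, nadh_c = 2))
  p1 <- atp_potential(fake, conversions = list(nadh = list(yield = 2, cost = 5)),
                      coeffs, carriers = "nadh", glucose_exchange_id = NULL)
  own <- p0$total_cost * abs(paths$flux_net[[1]][["EX_glc"]])  # un-normalized own cost
  expect_equal(p1$atp_potential, 2 + 2 * 2)
  expect_equal(p1$total_cost, own + 2 * 5)

  # consumed carrier debits the potential but adds no conversion cost
  fake$imbalance <- list(c(atp_c = 2, nadh_c = -1))
  p2 <- atp_potential(fake, conversions = list(nadh = list(yield = 2, cost = 5)),
                      coeffs, carriers = "nadh", glucose_exchange_id = NULL)
  expect_equal(p2$atp_potential, 2 - 2)
  expect_equal(p2$total_cost, own)
  expect_equal(p2$cost_per_atp, Inf)   # non-positive potential

  expect_error(atp_potential(paths, conversions = list(), coeffs,
                             carriers = "nadh"),
               "conversion")
})

test_that("Pareto classification separates OP, NOP and dominated pathways", {
  skeleton <- function(atp, cpa) {
    out <- tibble::tibble(
      pathway = seq_along(atp),
      flux_split = replicate(length(atp), c(r = 1), simplify = FALSE),
      flux_net = replicate(length(atp), c(r = 1), simplify = FALSE),
      is_internal_loop = FALSE,
      atp_potential = atp, total_cost = atp * cpa, cost_per_atp = cpa)
    class(out) <- c("fundamental_pathways", class(out))
    out
  }
  # one pathway dominates on both axes
  c1 <- pareto_classify(skeleton(atp = c(10, 5), cpa = c(1, 2)))
  expect_equal(c1$classification, c("OP", "other"))
  # each best on one axis: both optimal
  c2 <- pareto_classify(skeleton(atp = c(10, 5), cpa = c(2, 1)))
  expect_equal(c2$classification, c("OP", "OP"))
  # near-frontier pathway inside the 10% margin
  c3 <- pareto_classify(skeleton(atp = c(10, 9.5), cpa = c(1, 1.02)))
  expect_equal(c3$classification, c("OP", "NOP"))
  # far-dominated pathway stays "other"
  c4 <- pareto_classify(skeleton(atp = c(10, 2), cpa = c(1, 3)))
  expect_equal(c4$classification, c("OP", "other"))
  # empty input passes through
  expect_equal(nrow(pareto_classify(skeleton(numeric(0), numeric(0)))), 0)
})

test_that("adding the removed loops back rebalances the fundamental pathway", {
  fx <- make_glycolysis_fixture()
  red <- reduce_model(fx$model, c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"))
  paths <- annotate_imbalance(enumerate_pathways(red), fx$model)
  v <- recover_pathway(paths, red, k = 1)
  expect_false(is.null(v))
  S <- as.matrix(fx$model$S)
  expect_lt(max(abs(S %*% v[colnames(S)])), 1e-9)
  # the completion used the ATP-hydrolysis loop and the proton exchange
  scale <- abs(v[["EX_glc"]])
  expect_equal(unname(v[["ATPM"]] / scale), 2)
  expect_equal(unname(v[["EX_h"]] / scale), 2)
})

test_that("the one-call decomposition classifies the glycolysis route", {
  fx <- make_glycolysis_fixture()
  paths <- fundamental_pathways(
    fx$model, fx$costs,
    currency_ids = c("atp", "adp", "pi", "h", "h2o", "nad", "nadh"),
    carriers = character(0), cost_type = "combined",
    medium = fx$medium, glucose_exchange_id = "EX_glc")
  expect_equal(nrow(paths), 1)
  expect_equal(paths$atp_potential, 2)
  expect_equal(paths$classification, "OP")
  td <- generics::tidy(paths)
  expect_named(td, c("pathway", "n_reactions", "is_internal_loop",
                     "atp_potential", "total_cost", "cost_per_atp",
                     "classification"))
})
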