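# The two-step optimization: FBA maximum, cost-minimal solve at a fixed
# fraction, sweeps and normalizations, cross-checked against exhaustive
# vertex enumeration and SciPy HiGHS.

chain_model <- function(uptake = 10) {
  mets <- tibble::tibble(id = c("a_e", "a_c"), name = c("A", "A"),
                         compartment = c("e", "c"))
  stoich <- list(EX_A = c(a_e = -1), At = c(a_e = -1, a_c = 1),
                 BIOMASS = c(a_c = -1))
  rxns <- tibble::tibble(id = names(stoich),
                         lower_bound = c(-uptake, 0, 0),
                         upper_bound = c(0, 1000, 1000),
                         enzyme_associated = c(FALSE, TRUE, FALSE),
                         objective_coefficient = c(0, 0, 1))
  model <- metabolic_model(mets, rxns, stoich, objective_id = "BIOMASS")
  costs <- cost_table(names(stoich), c(NA, 50, NA), c(0, 0, 0),
                      c(FALSE, TRUE, FALSE))
  list(model = model, costs = costs)
}

test_that("FBA maximum matches hand-derived optima on toy networks", {
  cm <- chain_model(10)
  aug <- augment_model(cm$model, build_cost_coefficients(cm$model, cm$costs, "mw"))
  expect_equal(maximize_objective(aug)$optimum, 10)  # yield 1, uptake 10

  cm0 <- chain_model(0)
  aug0 <- augment_model(cm0$model, build_cost_coefficients(cm0$model, cm0$costs, "mw"))
  expect_equal(maximize_objective(aug0)$optimum, 0)

  fx <- make_overflow_fixture()   # yields 2 and 1, glucose 10 -> optimum 20
  augo <- augment_model(fx$model, build_cost_coefficients(fx$model, fx$costs, "mw"))
  expect_equal(maximize_objective(augo, fx$medium)$optimum, 20)
})

test_that("infeasibility is reported as a status, not an error", {
  cm <- chain_model(10)
  m <- cm$model
  m$reactions$lower_bound[m$reactions$id == "BIOMASS"] <- 50  # demands > supply
  aug <- augment_model(m, build_cost_coefficients(m, cm$costs, "mw"))
  res <- maximize_objective(aug)
  expect_equal(res$status, "infeasible")
  sol <- solve_corso(aug, fraction = 0.9)
  expect_equal(sol$status, "infeasible")
})

test_that("overflow fixture: forced high-yield at f = 1, cheap route below f*", {
  fx <- make_overflow_fixture()   # f* = 0.5
  aug <- augment_model(fx$model, build_cost_coefficients(fx$model, fx$costs, "mw"))

  sol1 <- solve_corso(aug, fx$medium, fraction = 1)
  v1 <- setNames(sol1$net_fluxes$flux, sol1$net_fluxes$reaction_id)
  expect_equal(unname(v1["PATH_LO"]), 0)
  expect_equal(unname(v1["PATH_HI"]), 10)

  sol_lo <- solve_corso(aug, fx$medium, fraction = 0.45)  # below the switch
  v_lo <- setNames(sol_lo$net_fluxes$flux, sol_lo$net_fluxes$reaction_id)
  expect_equal(unname(v_lo["PATH_HI"]), 0)
  expect_equal(unname(v_lo["PATH_LO"]), 9)  # 0.45 * 20 biomass via yield 1
})

test_that("uniform costs on a single pathway scale fluxes with the fraction", {
  cm <- chain_model(10)
  costs_u <- cost_table(cm$costs$reaction_id, cm$costs$mw_kda,
                        cm$costs$dG0_kcal_mol, cm$costs$enzyme_associated)
  aug <- augment_model(cm$model,
                       build_cost_coefficients(cm$model, costs_u, "uniform"))
  sol1 <- solve_corso(aug, fraction = 1)
  for (f in c(0.5, 0.8)) {
    solf <- solve_corso(aug, fraction = f)
    expect_equal(solf$net_fluxes$flux, f * sol1$net_fluxes$flux,
                 tolerance = 1e-9)
  }
})

test_that("sweeps return one solution per fraction with non-decreasing cost", {
  fx <- make_overflow_fixture()
  aug <- augment_model(fx$model, build_cost_coefficients(fx$model, fx$costs, "mw"))

  sw <- sweep_corso(aug, fx$medium, fractions = c(0.5, 0.75, 1))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$total_cost) >= -1e-9))

  single <- sweep_corso(aug, fx$medium, fractions = 1)
  direct <- solve_corso(aug, fx$medium, fraction = 1)
  expect_equal(single$solution[[1]]$net_fluxes, direct$net_fluxes)

  expect_error(sweep_corso(aug, fx$medium, fractions = c(0, 0.5)), "fractions")
})

test_that("normalizations divide by the requested denominator", {
  fx <- make_glycolysis_fixture()
  aug <- augment_model(fx$model,
                       build_cost_coefficients(fx$model, fx$costs, "combined"))
  sol <- solve_corso(aug, fx$medium, fraction = 1)

  nf <- normalize_fluxes(sol, "glc_g6p", glc_g6p_id = "GLCpts")
  expect_equal(nf$normalized[nf$reaction_id == "EX_lac"], 2)   # 2 lactate/glucose
  expect_equal(nf$normalized[nf$reaction_id == "GLCpts"], 1)

  cm <- chain_model(10)
  augc <- augment_model(cm$model, build_cost_coefficients(cm$model, cm$costs, "mw"))
  solc <- solve_corso(augc, fraction = 1)
  nfc <- normalize_fluxes(solc, "total_enzyme_flux")
  expect_equal(nfc$normalized[nfc$reaction_id == "At"], 1)  # only enzyme reaction

  expect_error(normalize_fluxes(sol, "glc_g6p", glc_g6p_id = "Ht"),
               "denominator")   # Ht carries no flux at the cost optimum
})

test_that("solve_corso matches exhaustive vertex enumeration on random toys", {
  n_checked <- 0
  for (seed in 1:24) {
    fx <- make_random_toy_model(seed)
    aug <- augment_model(fx$model,
                         build_cost_coefficients(fx$model, fx$costs, "combined"))
    m <- apply_medium(aug$model, fx$medium)
    S <- as.matrix(m$S)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    iobj <- match(aug$model$objective_id, m$reactions$id)
    isink <- match(aug$cost_sink_id, m$reactions$id)
    # cap the sink bound so the oracle box stays tight
    ub[isink] <- min(ub[isink], 1e5)

    opt <- brute_force_lp(as.numeric(seq_along(lb) == iobj), S, lb, ub,
                          maximize = TRUE)
    fba <- maximize_objective(aug, fx$medium)
    expect_equal(fba$optimum, opt$objective, tolerance = 1e-6)
    if (opt$objective <= 1e-9) next

    for (f in c(0.6, 1)) {
      lb2 <- lb; ub2 <- ub
      lb2[iobj] <- f * opt$objective
      ub2[iobj] <- f * opt$objective
      oracle <- brute_force_lp(as.numeric(seq_along(lb) == isink), S, lb2, ub2,
                               maximize = FALSE)
      sol <- solve_corso(aug, fx$medium, fraction = f)
      expect_equal(sol$total_cost, oracle$objective, tolerance = 1e-6,
                   label = paste0("seed ", seed, ", f = ", f))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 40)
})

test_that("solve_corso agrees with SciPy HiGHS on the fixture models", {
  for (fx in list(make_glycolysis_fixture(), make_overflow_fixture())) {
    aug <- augment_model(fx$model,
                         build_cost_coefficients(fx$model, fx$costs, "combined"))
    m <- apply_medium(aug$model, fx$medium)
    S <- as.matrix(m$S)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    iobj <- match(aug$model$objective_id, m$reactions$id)
    isink <- match(aug$cost_sink_id, m$reactions$id)

    ref_max <- scipy_lp(as.numeric(seq_along(lb) == iobj), S, lb, ub,
                        maximize = TRUE)
    fba <- maximize_objective(aug, fx$medium)
    expect_equal(fba$optimum, ref_max$objective, tolerance = 1e-6)

    lb[iobj] <- 0.8 * fba$optimum
    ub[iobj] <- 0.8 * fba$optimum
    ref_cost <- scipy_lp(as.numeric(seq_along(lb) == isink), S, lb, ub)
    sol <- solve_corso(aug, fx$medium, fraction = 0.8)
    expect_equal(sol$total_cost, ref_cost$objective, tolerance = 1e-6)
  }
})

test_that("every returned solution satisfies the original steady state", {
  for (fx in list(make_glycolysis_fixture(), make_overflow_fixture(),
                  make_loop_fixture())) {
    aug <- augment_model(fx$model,
                         build_cost_coefficients(fx$model, fx$costs, "combined"))
    S <- as.matrix(fx$model$S)
    sw <- sweep_corso(aug, fx$medium, fractions = seq(0.5, 1, by = 0.1))
    for (sol in sw$solution) {
      v <- setNames(sol$net_fluxes$flux, sol$net_fluxes$reaction_id)
      expect_lt(max(abs(S %*% v[colnames(S)])), 1e-6)
    }
  }
})

test_that("tidiers expose fluxes and summaries as tibbles", {
  fx <- make_overflow_fixture()
  aug <- augment_model(fx$model, build_cost_coefficients(fx$model, fx$costs, "mw"))
  sol <- solve_corso(aug, fx$medium, fraction = 0.8)
  td <- generics::tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("reaction_id", "flux", "enzyme_associated"))
  gl <- generics::glance(sol)
  expect_equal(gl$fraction, 0.8)
  expect_equal(gl$status, "optimal")

  sw <- sweep_corso(aug, fx$medium, fractions = c(0.6, 1))
  tds <- generics::tidy(sw)
  expect_equal(sort(unique(tds$fraction)), c(0.6, 1))
  expect_equal(generics::glance(sw)$n_optimal, 2)
})
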