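# Readers and writers for constraint-based models (BiGG-style JSON, SBML L3
# with FBC), reaction cost tables, medium specifications and flux reports.

#' Read a constraint-based model from file
#'
#' Supports the BiGG-style JSON dialect (`"metabolites"` / `"reactions"` with
#' per-reaction stoichiometry maps, `lower_bound` / `upper_bound`,
#' `objective_coefficient`) and SBML Level 3 with the FBC package. Exchange
#' reactions are detected structurally (columns touching exactly one
#' metabolite); `enzyme_associated` is seeded from gene-association presence
#' and may later be overridden by a cost table.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; the default guesses from the extension.
#' @param big_bound finite stand-in for arbitrarily large bounds.
#' @param require_objective error when the file declares no objective.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       big_bound = 1000, require_objective = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  model <- switch(format,
    json = read_model_json(path, big_bound),
    sbml = read_model_sbml(path, big_bound)
  )
  validate_model(model, require_objective = require_objective)
}

read_model_json <- function(path, big_bound) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    abort("JSON model: missing 'metabolites' or 'reactions' element.")
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    if (is.null(m$id)) abort("JSON model: metabolite without an 'id'.")
    tibble(id = m$id, name = m$name %||% m$id,
           compartment = as.character(m$compartment %||% "c"))
  })
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    if (is.null(r$id)) abort("JSON model: reaction without an 'id'.")
    tibble(
      id = r$id, name = r$name %||% r$id,
      lower_bound = as.numeric(r$lower_bound %||% 0),
      upper_bound = as.numeric(r$upper_bound %||% big_bound),
      enzyme_associated = nzchar(r$gene_reaction_rule %||% ""),
      objective_coefficient = as.numeric(r$objective_coefficient %||% 0)
    )
  })
  stoich <- purrr::map(doc$reactions, function(r) {
    st <- r$metabolites
    if (is.null(st) || length(st) == 0) return(setNames(numeric(0), character(0)))
    setNames(as.numeric(unlist(st)), names(st))
  })
  names(stoich) <- rxns$id
  metabolic_model(mets, rxns, stoich, big_bound = big_bound)
}

xml_local <- function(node, name) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
}

read_model_sbml <- function(path, big_bound) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("SBML parse failure: ", conditionMessage(e))))

  params <- xml_local(doc, "parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  species <- xml_local(doc, "species")
  if (length(species) == 0) abort("SBML parse failure: no species elements.")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  mets <- tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"), xml2::xml_attr(species, "id")),
    compartment = xml2::xml_attr(species, "compartment")
  )[!boundary, ]
  boundary_ids <- xml2::xml_attr(species, "id")[boundary]

  # active FBC objective
  objective_id <- NULL
  fo <- xml_local(doc, "fluxObjective")
  if (length(fo) > 0) {
    refs <- xml2::xml_attr(fo, "reaction")
    if (length(refs) > 0) objective_id <- refs[[1]]
  }

  rnodes <- xml_local(doc, "reaction")
  # only direct children named reaction (avoid fluxObjective matches)
  rnodes <- rnodes[xml2::xml_name(rnodes) == "reaction"]
  if (length(rnodes) == 0) abort("SBML parse failure: no reaction elements.")

  ids <- character(0); lbs <- numeric(0); ubs <- numeric(0)
  enz <- logical(0); nms <- character(0); stoich <- list()
  for (rn in rnodes) {
    id <- xml2::xml_attr(rn, "id")
    attrs <- xml2::xml_attrs(rn)
    lb_ref <- attrs[grepl("lowerFluxBound$", names(attrs))]
    ub_ref <- attrs[grepl("upperFluxBound$", names(attrs))]
    rev <- xml2::xml_attr(rn, "reversible") %in% c("true", "1")
    lb <- if (length(lb_ref) == 1 && lb_ref %in% names(pvals)) pvals[[lb_ref]] else
      if (rev) -big_bound else 0
    ub <- if (length(ub_ref) == 1 && ub_ref %in% names(pvals)) pvals[[ub_ref]] else big_bound

    st <- setNames(numeric(0), character(0))
    for (side in c("listOfReactants", "listOfProducts")) {
      side_nodes <- xml_local(rn, side)
      if (length(side_nodes) == 0) next
      refs <- xml_local(side_nodes[[1]], "speciesReference")
      for (sr in refs) {
        sp <- xml2::xml_attr(sr, "species")
        coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
        if (is.na(coef)) coef <- 1
        if (sp %in% boundary_ids) next
        sgn <- if (side == "listOfReactants") -1 else 1
        cur <- if (sp %in% names(st)) st[[sp]] else 0
        st[sp] <- cur + sgn * coef
      }
    }

    gpa <- xml_local(rn, "geneProductAssociation")
    ids <- c(ids, id); lbs <- c(lbs, lb); ubs <- c(ubs, ub)
    enz <- c(enz, length(gpa) > 0)
    nms <- c(nms, xml2::xml_attr(rn, "name") %||% id)
    stoich[[id]] <- st
  }
  bad <- ids[lbs > ubs]
  if (length(bad) > 0) {
    abort(paste0("SBML model: lower bound exceeds upper bound for reaction(s): ",
                 paste(bad, collapse = ", ")))
  }
  rxns <- tibble(id = ids, name = nms, lower_bound = lbs, upper_bound = ubs,
                 enzyme_associated = enz,
                 objective_coefficient = as.numeric(ids %in% (objective_id %||% "")))
  metabolic_model(mets, rxns, stoich, objective_id = objective_id,
                  big_bound = big_bound)
}

#' Write a model to BiGG-style JSON or SBML L3 + FBC
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  rxns <- model$reactions
  doc <- list(
    id = "model",
    version = "1",
    compartments = as.list(setNames(
      unique(model$metabolites$compartment), unique(model$metabolites$compartment))),
    metabolites = purrr::pmap(model$metabolites[, c("id", "name", "compartment")],
      function(id, name, compartment) {
        list(id = id, name = name, compartment = compartment, charge = 0, formula = "")
      }),
    reactions = purrr::map(seq_len(nrow(rxns)), function(k) {
      st <- reaction_stoich(model, rxns$id[[k]])
      list(
        id = rxns$id[[k]], name = rxns$name[[k]],
        metabolites = as.list(st),
        lower_bound = rxns$lower_bound[[k]], upper_bound = rxns$upper_bound[[k]],
        gene_reaction_rule = if (rxns$enzyme_associated[[k]]) paste0("g_", rxns$id[[k]]) else "",
        objective_coefficient =
          if (identical(rxns$id[[k]], model$objective_id)) 1
          else rxns$objective_coefficient[[k]]
      )
    }),
    genes = purrr::map(rxns$id[rxns$enzyme_associated], function(id) {
      list(id = paste0("g_", id), name = paste0("g_", id))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  rxns <- model$reactions
  mets <- model$metabolites
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    paste0('      <compartment id="', unique(mets$compartment),
           '" constant="true"/>'),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    paste0('      <species id="', mets$id, '" name="', xml_escape(mets$name),
           '" compartment="', mets$compartment,
           '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'),
    '    </listOfSpecies>',
    '    <listOfParameters>'
  )
  for (k in seq_len(nrow(rxns))) {
    lines <- c(lines,
      paste0('      <parameter id="lb_', rxns$id[[k]], '" value="',
             rxns$lower_bound[[k]], '" constant="true"/>'),
      paste0('      <parameter id="ub_', rxns$id[[k]], '" value="',
             rxns$upper_bound[[k]], '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (k in seq_len(nrow(rxns))) {
    id <- rxns$id[[k]]
    st <- reaction_stoich(model, id)
    subs <- st[st < 0]; prods <- st[st > 0]
    lines <- c(lines, paste0(
      '      <reaction id="', id, '" name="', xml_escape(rxns$name[[k]]),
      '" reversible="', tolower(rxns$lower_bound[[k]] < 0),
      '" fast="false" fbc:lowerFluxBound="lb_', id,
      '" fbc:upperFluxBound="ub_', id, '">'))
    if (length(subs) > 0) {
      lines <- c(lines, '        <listOfReactants>',
        paste0('          <speciesReference species="', names(subs),
               '" stoichiometry="', -unname(subs), '" constant="true"/>'),
        '        </listOfReactants>')
    }
    if (length(prods) > 0) {
      lines <- c(lines, '        <listOfProducts>',
        paste0('          <speciesReference species="', names(prods),
               '" stoichiometry="', unname(prods), '" constant="true"/>'),
        '        </listOfProducts>')
    }
    if (rxns$enzyme_associated[[k]]) {
      lines <- c(lines,
        '        <fbc:geneProductAssociation>',
        paste0('          <fbc:geneProductRef fbc:geneProduct="g_', id, '"/>'),
        '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.null(model$objective_id)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      paste0('          <fbc:fluxObjective fbc:reaction="', model$objective_id,
             '" fbc:coefficient="1"/>'),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  enz_ids <- rxns$id[rxns$enzyme_associated]
  if (length(enz_ids) > 0) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
      paste0('      <fbc:geneProduct fbc:id="g_', enz_ids,
             '" fbc:label="g_', enz_ids, '"/>'),
      '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

#' Load a reaction cost table
#'
#' Tab-separated with header exactly `reaction_id`, `mw_kda`, `dG0_kcal_mol`,
#' `enzyme`. Missing molecular weights are flagged for median imputation
#' ([impute_missing_weights()]); a missing standard Gibbs energy is treated as
#' 0 kcal/mol (thermodynamic penalty factor 1).
#'
#' @param path TSV path.
#' @return a `cost_table` tibble with columns `reaction_id`, `mw_kda`,
#'   `dG0_kcal_mol`, `enzyme_associated`, `mw_imputed`.
#' @export
load_cost_table <- function(path) {
  expected <- c("reaction_id", "mw_kda", "dG0_kcal_mol", "enzyme")
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    abort(paste0("Cost table header must be exactly: ",
                 paste(expected, collapse = ", ")))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    reaction_id = readr::col_character(),
    mw_kda = readr::col_double(),
    dG0_kcal_mol = readr::col_double(),
    enzyme = readr::col_double()
  ))
  cost_table(tab$reaction_id, tab$mw_kda, tab$dG0_kcal_mol, tab$enzyme == 1)
}

#' Construct a cost table in code
#'
#' @param reaction_id character reaction ids.
#' @param mw_kda enzyme molecular weight in kDa (`NA` = to be imputed).
#' @param dG0_kcal_mol standard Gibbs free energy of reaction, kcal/mol
#'   (`NA` treated as 0: no thermodynamic penalty).
#' @param enzyme_associated logical; non-enzymatic reactions cost zero.
#' @return a `cost_table` tibble.
#' @export
cost_table <- function(reaction_id, mw_kda, dG0_kcal_mol, enzyme_associated) {
  if (anyDuplicated(reaction_id)) {
    abort(paste0("Duplicate reaction id(s) in cost table: ",
                 paste(unique(reaction_id[duplicated(reaction_id)]), collapse = ", ")))
  }
  if (any(!is.na(mw_kda) & mw_kda < 0)) abort("Negative molecular weight in cost table.")
  out <- tibble(
    reaction_id = reaction_id,
    mw_kda = as.numeric(mw_kda),
    dG0_kcal_mol = ifelse(is.na(dG0_kcal_mol), 0, as.numeric(dG0_kcal_mol)),
    enzyme_associated = enzyme_associated,
    mw_imputed = enzyme_associated & is.na(mw_kda)
  )
  class(out) <- c("cost_table", class(out))
  out
}

#' Write a cost table to TSV
#' @param costs a `cost_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(costs, path) {
  readr::write_tsv(tibble(
    reaction_id = costs$reaction_id,
    mw_kda = costs$mw_kda,
    dG0_kcal_mol = costs$dG0_kcal_mol,
    enzyme = as.integer(costs$enzyme_associated)
  ), path)
  invisible(path)
}

#' Read / write a medium specification
#'
#' TSV with header `exchange_id`, `uptake_bound`, `secretion_allowed` (0/1).
#'
#' @param path TSV path.
#' @return tibble with those columns.
#' @export
read_medium <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    exchange_id = readr::col_character(),
    uptake_bound = readr::col_double(),
    secretion_allowed = readr::col_double()
  ))
}

#' @rdname read_medium
#' @param medium medium tibble.
#' @export
write_medium <- function(medium, path) {
  readr::write_tsv(medium, path)
  invisible(path)
}

#' Write a flux report for a sweep of sub-optimal solutions
#'
#' Rows are original reactions, one raw-flux column per fraction (ascending),
#' plus matching normalized columns when a normalization is requested.
#'
#' @param solutions list of `corso_solution` objects (or a `corso_sweep`).
#' @param path output TSV path.
#' @param normalize `"none"`, `"glc_g6p"` or `"total_enzyme_flux"`.
#' @param glc_g6p_id reaction id of the glucose -> G6P step (for `"glc_g6p"`).
#' @return `path`, invisibly.
#' @export
write_flux_report <- function(solutions, path, normalize = "none",
                              glc_g6p_id = NULL) {
  if (inherits(solutions, "corso_sweep")) solutions <- solutions$solution
  if (length(solutions) == 0) {
    warn("write_flux_report(): empty solution list; writing header only.")
    readr::write_tsv(tibble(reaction_id = character(0)), path)
    return(invisible(path))
  }
  ord <- order(purrr::map_dbl(solutions, "fraction"))
  solutions <- solutions[ord]
  out <- tibble(reaction_id = solutions[[1]]$net_fluxes$reaction_id)
  for (sol in solutions) {
    lab <- format(sol$fraction, trim = TRUE)
    out[[paste0("flux_", lab)]] <- sol$net_fluxes$flux
    if (normalize != "none") {
      out[[paste0("norm_", lab)]] <-
        normalize_fluxes(sol, mode = normalize, glc_g6p_id = glc_g6p_id)$normalized
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back a flux report written by [write_flux_report()]
#' @param path TSV path.
#' @return tibble with `reaction_id` and one column per fraction.
#' @export
read_flux_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    reaction_id = readr::col_character(), .default = readr::col_double()
  ))
}
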