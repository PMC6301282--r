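# Deterministic toy metabolic network and synthetic two-group expression
# matrices. The toy mirrors the engineered producer's topology at miniature
# scale: a glycolysis-like trunk from sugar uptake, a rhamnose branch
# activating glucose-1-phosphate to a dTDP-sugar donor, de-novo fatty-acid
# synthesis feeding an RhlA-like dimerisation to HAA, an RhlB-like
# condensation to mono-rhamnolipid, export, and a biomass drain. Pseudo
# carbon-skeleton formulas (C counts, with carrier moieties as single
# pseudo-elements Q/R/D) make every native reaction pass the elemental
# balance check by construction.

toy_met <- function(id, name, compartment, formula, charge = 0) {
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = charge, stringsAsFactors = FALSE)
}

toy_rxn <- function(id, name, equation, lb = NA, ub = DEFAULT_UB,
                    gpr = NA_character_, subsystem = NA_character_) {
  data.frame(id = id, name = name, equation = equation,
             lower_bound = lb, upper_bound = ub, gpr = gpr,
             subsystem = subsystem, stringsAsFactors = FALSE)
}

#' Deterministic toy metabolic model of a rhamnolipid producer
#'
#' Stoichiometry is scaled so that at a glucose uptake of 10 mmol/gDW/h the
#' maximum mono-rhamnolipid export is exactly 10/6: each rhamnolipid
#' consumes one glucose-6-phosphate through the rhamnose branch and five
#' through glycolysis plus fatty-acid synthesis (1 g6p -> 2 acetyl units,
#' 5 acetyl + ACP -> 1 hydroxyacyl-ACP, 2 hydroxyacyl -> 1 HAA).
#' All carbon-source exchanges default to zero uptake; use [set_medium()].
#'
#' @param with_loop add an isolated 3-reaction reversible cycle (a
#'   thermodynamically infeasible internal loop; geometric FBA centres its
#'   fluxes to zero).
#' @param with_fa_source add a hydroxy-fatty-acid source feeding the
#'   acyl-CoA pool (uptake, CoA activation, and a PhaC-like dimerisation).
#' @param extra_sources add fructose and glycerol source pathways.
#' @param parallel_transport duplicate the glucose and rhamnolipid
#'   transporters (GLCt1/GLCt2, RLt1/RLt2), creating symmetric degenerate
#'   optima that exercise the geometric centring.
#' @param vmax_override optional named numeric vector of upper-bound
#'   overrides, e.g. `c(GLCt1 = 4)`.
#' @return a `metabolic_model` with objective `EX_rl` (mono-rhamnolipid
#'   export).
#' @export
toy_model <- function(with_loop = FALSE, with_fa_source = TRUE,
                      extra_sources = TRUE, parallel_transport = TRUE,
                      vmax_override = NULL) {
  mets <- rbind(
    toy_met("glc_e", "glucose", "e", "C6"),
    toy_met("glc_c", "glucose", "c", "C6"),
    toy_met("g6p_c", "glucose 6-phosphate", "c", "C6"),
    toy_met("g1p_c", "glucose 1-phosphate", "c", "C6"),
    toy_met("dtdpddm_c", "dTDP-4-dehydro-6-deoxy-L-mannose", "c", "C6D"),
    toy_met("dtdp_c", "dTDP", "c", "D"),
    toy_met("accoa_c", "acetyl-CoA", "c", "C3"),
    toy_met("acp_c", "acyl carrier protein", "c", "Q"),
    toy_met("hdacp_c", "(3R)-3-hydroxydecanoyl-ACP", "c", "C10Q"),
    toy_met("coa_c", "coenzyme A", "c", "R"),
    toy_met("haa_c", "3-hydroxydecanoyl-3-hydroxydecanoate", "c", "C20"),
    toy_met("rhl_c", "mono-rhamnolipid", "c", "C26"),
    toy_met("rhl_e", "mono-rhamnolipid", "e", "C26"),
    toy_met("bio_c", "biomass", "c", "C9"),
    toy_met("bio_e", "biomass", "e", "C9"),
    toy_met("h_e", "proton", "e", "H", 1),
    toy_met("h_c", "proton", "c", "H", 1),
    toy_met("h2o_e", "water", "e", "H2O"),
    toy_met("h2o_c", "water", "c", "H2O"),
    toy_met("co2_c", "carbon unit (CO2)", "c", "C"),
    toy_met("co2_e", "carbon unit (CO2)", "e", "C"))
  rxns <- rbind(
    toy_rxn("EX_glc", "glucose exchange", "glc_e -->", 0,
            subsystem = "exchange"),
    toy_rxn("GLCt1", "glucose transporter 1", "glc_e --> glc_c", 0,
            gpr = "glcT1", subsystem = "transport"),
    toy_rxn("HEX", "hexokinase", "glc_c --> g6p_c", 0,
            gpr = "hex", subsystem = "glycolysis"),
    toy_rxn("PGM", "phosphoglucomutase", "g6p_c --> g1p_c", 0,
            gpr = "pgm", subsystem = "rhamnose pathway"),
    toy_rxn("RMLA", "dTDP-sugar synthesis (lumped RmlA-RmlC)",
            "g1p_c + dtdp_c --> dtdpddm_c", 0,
            gpr = "rmlA", subsystem = "rhamnose pathway"),
    toy_rxn("EMP", "lower glycolysis + PDH (lumped)",
            "g6p_c --> 2 accoa_c", 0,
            gpr = "gap", subsystem = "glycolysis"),
    toy_rxn("FAS", "fatty acid synthesis (lumped FabB-FabG)",
            "5 accoa_c + acp_c --> hdacp_c + 5 co2_c", 0,
            gpr = "fabG", subsystem = "fatty acid biosynthesis"),
    toy_rxn("HAAS", "HAA synthase (RhlA-like)",
            "2 hdacp_c --> haa_c + 2 acp_c", 0,
            gpr = "rhlA", subsystem = "rhamnolipid biosynthesis"),
    toy_rxn("RLS", "rhamnosyltransferase B (RhlB-like)",
            "dtdpddm_c + haa_c --> rhl_c + dtdp_c", 0,
            gpr = "rhlB", subsystem = "rhamnolipid biosynthesis"),
    toy_rxn("RLt1", "rhamnolipid transporter 1", "rhl_c --> rhl_e", 0,
            gpr = "rhlT1", subsystem = "transport"),
    toy_rxn("EX_rl", "rhamnolipid exchange", "rhl_e -->", 0,
            subsystem = "exchange"),
    toy_rxn("BIOM", "biomass synthesis", "g6p_c + accoa_c --> bio_c", 0,
            subsystem = "biomass"),
    toy_rxn("BIOMt", "biomass export", "bio_c --> bio_e", 0,
            subsystem = "transport"),
    toy_rxn("EX_bio", "biomass exchange", "bio_e -->", 0,
            subsystem = "exchange"),
    toy_rxn("Ht", "proton transport", "h_e <=> h_c", DEFAULT_LB,
            subsystem = "transport"),
    toy_rxn("EX_h", "proton exchange", "h_e <=>", DEFAULT_LB,
            subsystem = "exchange"),
    toy_rxn("H2Ot", "water transport", "h2o_e <=> h2o_c", DEFAULT_LB,
            subsystem = "transport"),
    toy_rxn("EX_h2o", "water exchange", "h2o_e <=>", DEFAULT_LB,
            subsystem = "exchange"),
    toy_rxn("CO2t", "CO2 transport", "co2_c --> co2_e", 0,
            subsystem = "transport"),
    toy_rxn("EX_co2", "CO2 exchange", "co2_e -->", 0,
            subsystem = "exchange"),
    toy_rxn("SK_coa", "coenzyme A sink", "coa_c <=>", DEFAULT_LB,
            subsystem = "sink"))
  if (parallel_transport)
    rxns <- rbind(rxns,
      toy_rxn("GLCt2", "glucose transporter 2", "glc_e --> glc_c", 0,
              subsystem = "transport"),
      toy_rxn("RLt2", "rhamnolipid transporter 2", "rhl_c --> rhl_e", 0,
              subsystem = "transport"))
  if (extra_sources) {
    mets <- rbind(mets,
      toy_met("fru_e", "fructose", "e", "C6"),
      toy_met("fru_c", "fructose", "c", "C6"),
      toy_met("glyc_e", "glycerol", "e", "C3"),
      toy_met("glyc_c", "glycerol", "c", "C3"))
    rxns <- rbind(rxns,
      toy_rxn("EX_fru", "fructose exchange", "fru_e -->", 0,
              subsystem = "exchange"),
      toy_rxn("FRUt", "fructose transporter", "fru_e --> fru_c", 0,
              gpr = "fruT", subsystem = "transport"),
      toy_rxn("FRK", "fructokinase", "fru_c --> g6p_c", 0,
              gpr = "fruK", subsystem = "glycolysis"),
      toy_rxn("EX_glyc", "glycerol exchange", "glyc_e -->", 0,
              subsystem = "exchange"),
      toy_rxn("GLYCt", "glycerol transporter", "glyc_e --> glyc_c", 0,
              gpr = "glpF", subsystem = "transport"),
      toy_rxn("GLYCK", "glycerol assimilation (lumped)",
              "2 glyc_c --> g6p_c", 0,
              gpr = "glpK", subsystem = "glycolysis"))
  }
  if (with_fa_source) {
    mets <- rbind(mets,
      toy_met("fa_e", "3-hydroxydecanoate", "e", "C10"),
      toy_met("fa_c", "3-hydroxydecanoate", "c", "C10"),
      toy_met("hdcoa_c", "(S)-3-hydroxydecanoyl-CoA", "c", "C10R"))
    rxns <- rbind(rxns,
      toy_rxn("EX_fa", "fatty acid exchange", "fa_e -->", 0,
              subsystem = "exchange"),
      toy_rxn("FAt", "fatty acid transporter", "fa_e --> fa_c", 0,
              gpr = "fadL", subsystem = "transport"),
      toy_rxn("FACT", "acyl-CoA synthetase", "fa_c + coa_c --> hdcoa_c", 0,
              gpr = "fadD", subsystem = "fatty acid degradation"),
      toy_rxn("FAA", "HAA synthase, CoA route (PhaC-like)",
              "2 hdcoa_c --> haa_c + 2 coa_c", 0,
              gpr = "phaC", subsystem = "fatty acid degradation"))
  }
  if (with_loop) {
    mets <- rbind(mets,
      toy_met("la_c", "loop metabolite A", "c", "C"),
      toy_met("lb_c", "loop metabolite B", "c", "C"),
      toy_met("lc_c", "loop metabolite C", "c", "C"))
    rxns <- rbind(rxns,
      toy_rxn("LOOP1", "loop step 1", "la_c <=> lb_c", DEFAULT_LB,
              subsystem = "loop"),
      toy_rxn("LOOP2", "loop step 2", "lb_c <=> lc_c", DEFAULT_LB,
              subsystem = "loop"),
      toy_rxn("LOOP3", "loop step 3", "lc_c <=> la_c", DEFAULT_LB,
              subsystem = "loop"))
  }
  sto <- list()
  for (i in seq_len(nrow(rxns)))
    sto[[rxns$id[i]]] <- parse_equation(rxns$equation[i])$stoichiometry
  rxns$lower_bound[is.na(rxns$lower_bound)] <- 0
  if (!is.null(vmax_override)) {
    idx <- match(names(vmax_override), rxns$id)
    if (anyNA(idx))
      stop("vmax_override names unknown reaction '",
           names(vmax_override)[is.na(idx)][1], "'", call. = FALSE)
    rxns$upper_bound[idx] <- unname(vmax_override)
  }
  model <- metabolic_model("toy_rhamnolipid",
                           mets,
                           rxns[setdiff(names(rxns), "equation")],
                           sto,
                           objective = c(EX_rl = 1))
  model
}

#' Toy pathway sets for flux attribution
#'
#' Named reaction-id sets matching the toy model's two precursor routes:
#' the rhamnose pathway (sugar activation) and the de-novo fatty-acid
#' pathway; when the fatty-acid source is present, its degradation route is
#' included as a third set.
#'
#' @param model a [toy_model()].
#' @return named list of character vectors.
#' @export
toy_pathway_sets <- function(model) {
  sets <- list(
    rhamnose_pathway = c("PGM", "RMLA"),
    fatty_acid_pathway = c("EMP", "FAS", "HAAS"))
  if ("FAA" %in% model$reactions$id)
    sets$fa_degradation_pathway <- c("FAt", "FACT", "FAA")
  lapply(sets, function(s) intersect(s, model$reactions$id))
}

#' Synthetic two-group expression matrix wired to the toy model
#'
#' Emulates a wild-type versus transposon-mutant design: expression levels
#' theta are log-normal, centred at 1 on the log scale with standard
#' deviation `sigma` in both groups; `planted` genes get an additional
#' `+delta` log-scale shift in the second group only. Planted genes must be
#' wired to model reactions through GPR rules; each wired reaction's upper
#' bound is capped at 80% of its flux in the unconstrained geometric-FBA
#' solution, so that the expression-scaled bound binds and group differences
#' become visible in the flux distribution.
#'
#' @param n_per_group samples per group (default 40).
#' @param genes total number of genes (default 200); the model's own genes
#'   come first, synthetic null genes fill the remainder.
#' @param planted character vector of planted gene ids (must be model
#'   genes); default `c("glcT1", "rhlT1")`, the genes of the capped glucose
#'   and rhamnolipid transporters.
#' @param delta log-scale group shift (default `log(2)`).
#' @param sigma log-scale noise standard deviation (default 0.25).
#' @param seed integer seed; all randomness flows from it.
#' @param model host model (default [toy_model()]).
#' @param medium medium under which binding caps are calibrated (default
#'   glucose at 10 mmol/gDW/h).
#' @return list with `expression` (an [expression_matrix()]), `truth`
#'   (planted genes, effect, wiring, seed) and `model` (the capped,
#'   medium-configured model to feed [batch_condition_fba()]).
#' @export
synth_expression <- function(n_per_group = 40, genes = 200,
                             planted = c("glcT1", "rhlT1"),
                             delta = log(2), sigma = 0.25, seed = 1,
                             model = toy_model(),
                             medium = c(glucose = 10)) {
  model_gene_ids <- model_genes(model)
  n_fill <- genes - length(model_gene_ids)
  if (n_fill < 0)
    stop("`genes` smaller than the number of model genes", call. = FALSE)
  gene_ids <- c(model_gene_ids, sprintf("syn_gene_%03d", seq_len(n_fill)))
  missing <- setdiff(planted, gene_ids)
  if (length(missing))
    stop("planted gene '", missing[1], "' not in gene list", call. = FALSE)
  wired <- lapply(planted, function(g) {
    hit <- vapply(model$reactions$gpr, function(x)
      !is.na(x) && g %in% gpr_genes(x), TRUE)
    model$reactions$id[hit]
  })
  names(wired) <- planted
  if (!any(lengths(wired) > 0))
    stop("planted genes appear in no GPR rule", call. = FALSE)

  model <- set_medium(model, medium)
  sol <- geometric_fba(model)
  cap_rxns <- unique(unlist(wired))
  caps <- 0.8 * abs(sol$fluxes[cap_rxns])
  caps <- caps[caps > 1e-9]
  i <- match(names(caps), model$reactions$id)
  model$reactions$upper_bound[i] <- unname(caps)

  nsamp <- 2L * n_per_group
  sample_ids <- c(sprintf("wt_%02d", seq_len(n_per_group)),
                  sprintf("tn5_%02d", seq_len(n_per_group)))
  groups <- setNames(rep(c("wild_type", "tn5_mutant"), each = n_per_group),
                     sample_ids)
  with_seed(seed, {
    logtheta <- matrix(rnorm(genes * nsamp, 0, sigma), genes, nsamp,
                       dimnames = list(gene_ids, sample_ids))
  })
  logtheta[planted, groups == "tn5_mutant"] <-
    logtheta[planted, groups == "tn5_mutant"] + delta
  expr <- expression_matrix(exp(logtheta), groups)
  truth <- list(planted = planted, delta = delta, sigma = sigma,
                wiring = wired, caps = caps, seed = seed)
  list(expression = expr, truth = truth, model = model)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
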