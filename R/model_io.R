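# Model serialisation: COBRA-style JSON, two-file tabular TSV, and a minimal
# SBML Level 3 (FBC-style) subset. All three round-trip S, bounds, objective
# and GPR strings exactly.

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("sbml", "json", "tabular")))
  if (dir.exists(path) || !grepl("\\.[A-Za-z]+$", path)) return("tabular")
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         xml = "sbml", sbml = "sbml", json = "json",
         stop("cannot infer model format from '", path,
              "'; pass format=", call. = FALSE))
}

#' Read a metabolic model
#'
#' @param path file (SBML/JSON) or directory (tabular: `metabolites.tsv` +
#'   `reactions.tsv`).
#' @param format one of `"sbml"`, `"json"`, `"tabular"`; inferred from the
#'   path when omitted.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "tabular") {
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  } else if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  switch(format,
         json = read_model_json(path),
         tabular = read_model_tabular(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' @param model a `metabolic_model`.
#' @param path target file (SBML/JSON) or directory (tabular).
#' @inheritParams read_model
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- infer_format(path, format)
  switch(format,
         json = write_model_json(model, path),
         tabular = write_model_tabular(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# --- JSON (COBRApy dialect) ---------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "",
               formula = m$formula %||% NA_character_,
               charge = if (is.null(m$charge)) NA_real_ else as.numeric(m$charge),
               stringsAsFactors = FALSE)))
  sto <- list(); obj <- numeric()
  rx <- do.call(rbind, lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (!length(s)) stop("reaction '", r$id, "' has malformed stoichiometry",
                         call. = FALSE)
    sto[[r$id]] <<- s
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      obj[r$id] <<- r$objective_coefficient
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               gpr = if (is.null(r$gene_reaction_rule) ||
                         !nzchar(r$gene_reaction_rule)) NA_character_
                     else r$gene_reaction_rule,
               subsystem = r$subsystem %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  metabolic_model(doc$id %||% "model", mets, rx, sto, obj)
}

write_model_json <- function(model, path) {
  genes <- model_genes(model)
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      sto <- model$stoichiometry[[i]]
      list(id = r$id, name = r$name,
           metabolites = as.list(sto),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = if (is.na(r$gpr)) "" else r$gpr,
           subsystem = if (is.na(r$subsystem)) "" else r$subsystem,
           objective_coefficient =
             if (r$id %in% names(model$objective))
               unname(model$objective[r$id]) else 0)
    }),
    genes = lapply(genes, function(g) list(id = g, name = g)),
    compartments = as.list(setNames(
      unique(model$metabolites$compartment),
      unique(model$metabolites$compartment))),
    version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All gene ids appearing in a model's GPR rules
#' @param model a `metabolic_model`.
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  g <- unlist(lapply(model$reactions$gpr, function(x)
    if (is.na(x)) character() else gpr_genes(x)))
  sort(unique(g))
}

# --- tabular (two TSV files) --------------------------------------------------

read_model_tabular <- function(path) {
  mf <- file.path(path, "metabolites.tsv")
  rf <- file.path(path, "reactions.tsv")
  for (f in c(mf, rf)) if (!file.exists(f))
    stop("no such file: ", f, call. = FALSE)
  mets <- read.delim(mf, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  rx <- read.delim(rf, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sto <- list()
  for (i in seq_len(nrow(rx))) {
    parsed <- tryCatch(parse_equation(rx$equation[i]),
                       error = function(e)
                         stop("reaction '", rx$id[i], "': ",
                              conditionMessage(e), call. = FALSE))
    sto[[rx$id[i]]] <- parsed$stoichiometry
  }
  obj <- numeric()
  if (!is.null(rx$objective)) {
    keep <- !is.na(rx$objective) & rx$objective != 0
    obj <- setNames(rx$objective[keep], rx$id[keep])
  }
  mets$compartment <- as.character(mets$compartment)
  metabolic_model(attr(mets, "model_id") %||% basename(path), mets,
                  rx[setdiff(names(rx), c("equation", "objective"))], sto, obj)
}

write_model_tabular <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(model$metabolites, file.path(path, "metabolites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rx <- model$reactions
  rx$equation <- vapply(seq_len(nrow(rx)), function(i)
    format_equation(model$stoichiometry[[i]], rx$lower_bound[i] < 0), "")
  rx$objective <- ifelse(rx$id %in% names(model$objective),
                         model$objective[rx$id], 0)
  rx$is_exchange <- NULL
  write.table(rx, file.path(path, "reactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# --- SBML L3 / FBC-style subset ----------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">', model$id),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    attrs <- sprintf('id="%s" name="%s" compartment="%s"',
                     m$id, m$name, m$compartment)
    if (!is.na(m$formula))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge))
      attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    lines <- c(lines, sprintf(
      '<species %s hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      attrs))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines,
               sprintf('<parameter id="%s_lb" value="%.17g" constant="true"/>',
                       r$id, r$lower_bound),
               sprintf('<parameter id="%s_ub" value="%.17g" constant="true"/>',
                       r$id, r$upper_bound))
  }
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sto <- model$stoichiometry[[i]]
    lines <- c(lines, sprintf(
      '<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">',
      r$id, r$name, tolower(r$lower_bound < 0), r$id, r$id))
    notes <- character()
    if (!is.na(r$gpr))
      notes <- c(notes, sprintf("<p>GENE_ASSOCIATION: %s</p>", r$gpr))
    if (!is.na(r$subsystem))
      notes <- c(notes, sprintf("<p>SUBSYSTEM: %s</p>", r$subsystem))
    if (length(notes))
      lines <- c(lines,
                 '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
                 notes, "</body></notes>")
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    if (length(reac)) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         names(reac), -unname(reac)),
                 "</listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         names(prod), unname(prod)),
                 "</listOfProducts>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>",
             '<fbc:listOfObjectives fbc:activeObjective="obj">',
             '<fbc:objective fbc:id="obj" fbc:type="maximize">',
             "<fbc:listOfFluxObjectives>")
  for (rid in names(model$objective)) {
    lines <- c(lines, sprintf(
      '<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%.17g"/>',
      rid, unname(model$objective[rid])))
  }
  lines <- c(lines, "</fbc:listOfFluxObjectives>", "</fbc:objective>",
             "</fbc:listOfObjectives>", "</model>", "</sbml>")
  writeLines(lines, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS, x = "http://www.w3.org/1999/xhtml")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  attr_or <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = as.numeric(xml2::xml_attr(sp, "charge")),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  sto <- list(); rows <- list()
  for (nd in rxn_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    sr <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    pr <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    s <- c(setNames(-as.numeric(xml2::xml_attr(sr, "stoichiometry")),
                    xml2::xml_attr(sr, "species")),
           setNames(as.numeric(xml2::xml_attr(pr, "stoichiometry")),
                    xml2::xml_attr(pr, "species")))
    if (!length(s))
      stop("reaction '", rid, "' has malformed stoichiometry", call. = FALSE)
    agg <- tapply(s, names(s), sum)[unique(names(s))]
    sto[[rid]] <- setNames(as.numeric(agg), names(agg))
    lbref <- xml2::xml_attr(nd, "lowerFluxBound")
    ubref <- xml2::xml_attr(nd, "upperFluxBound")
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    lb <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
          else if (rev) DEFAULT_LB else 0
    ub <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]]
          else DEFAULT_UB
    notes <- xml2::xml_text(xml2::xml_find_all(nd, ".//s:notes//x:p", ns))
    gpr <- sub("^GENE_ASSOCIATION: *", "",
               grep("^GENE_ASSOCIATION:", notes, value = TRUE)[1])
    subsys <- sub("^SUBSYSTEM: *", "",
                  grep("^SUBSYSTEM:", notes, value = TRUE)[1])
    rows[[rid]] <- data.frame(
      id = rid, name = attr_or(nd, "name", rid),
      lower_bound = lb, upper_bound = ub,
      gpr = if (length(gpr) && !is.na(gpr)) gpr else NA_character_,
      subsystem = if (length(subsys) && !is.na(subsys)) subsys
                  else NA_character_,
      stringsAsFactors = FALSE)
  }
  fo <- xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns)
  obj <- setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                  xml2::xml_attr(fo, "reaction"))
  metabolic_model(attr_or(mdl, "id", "model"), mets, do.call(rbind, rows),
                  sto, obj)
}

# --- medium and objective configuration --------------------------------------

#' Define a growth medium
#'
#' @param uptakes named numeric vector, carbon source -> uptake rate in
#'   mmol/gDW/h (non-negative).
#' @param closed_sources character vector of sources whose uptake is forced
#'   to zero.
#' @return a `medium_spec`.
#' @export
medium_spec <- function(uptakes = numeric(), closed_sources = character()) {
  if (any(uptakes < 0)) stop("uptake rates must be >= 0", call. = FALSE)
  structure(list(uptakes = uptakes, closed_sources = closed_sources),
            class = "medium_spec")
}

#' Read a medium from a two-column TSV (`source<TAB>rate`)
#' @param path TSV file path.
#' @return a [medium_spec()].
#' @export
read_medium <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("source", "rate"))
  medium_spec(setNames(as.numeric(tab$rate), tab$source))
}

find_exchange <- function(model, source) {
  rids <- model$reactions$id
  ex <- which(model$reactions$is_exchange)
  if (source %in% rids[ex]) return(source)
  cand <- paste0("EX_", source)
  if (cand %in% rids[ex]) return(cand)
  # match on the exchanged metabolite's id or name
  for (i in ex) {
    met <- names(model$stoichiometry[[i]])
    row <- model$metabolites[model$metabolites$id == met, ]
    if (tolower(source) %in% tolower(c(met, sub("_[a-z]$", "", met),
                                       row$name)))
      return(rids[i])
  }
  stop("unknown carbon source '", source,
       "': no matching exchange reaction", call. = FALSE)
}

#' Apply a medium to a model
#'
#' Uptake is the negative flux of an exchange reaction, so a source supplied
#' at rate r has its exchange lower bound set to -r; closed sources get a
#' lower bound of 0. Exchanges not named in the medium are untouched.
#' Idempotent: applying the same medium twice equals applying it once.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()] or named numeric vector of uptake rates.
#' @return the configured model.
#' @export
set_medium <- function(model, medium) {
  if (!inherits(medium, "medium_spec")) medium <- medium_spec(medium)
  for (src in names(medium$uptakes)) {
    rid <- find_exchange(model, src)
    i <- match(rid, model$reactions$id)
    model$reactions$lower_bound[i] <- -medium$uptakes[[src]]
  }
  for (src in medium$closed_sources) {
    rid <- find_exchange(model, src)
    i <- match(rid, model$reactions$id)
    model$reactions$lower_bound[i] <- 0
  }
  model
}

#' Set a single-reaction maximisation objective
#'
#' @param model a `metabolic_model`.
#' @param reaction_id the reaction to maximise; the objective vector c
#'   becomes its indicator.
#' @return the configured model.
#' @export
set_objective <- function(model, reaction_id) {
  if (!reaction_id %in% model$reactions$id)
    stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  model$objective <- setNames(1, reaction_id)
  model
}
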