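#' Subsystem vocabulary of the hepatocyte network
#'
#' The closed set of subsystem labels used to annotate reactions. The core
#' labels cover every pathway the flux-phenotype analysis interrogates;
#' auxiliary labels (pentose phosphate pathway, TCA cycle, transport, ATP
#' maintenance) annotate the supporting reactions a working network needs.
#'
#' @return character vector of allowed labels.
#' @export
subsystem_labels <- function() {
  c("fatty-acid oxidation", "NNT", "GSR", "GPX/PRDX",
    "GSH de novo synthesis", "serine-glycine/one-carbon",
    "gluconeogenesis", "glycogenolysis", "ketogenesis",
    "oxidative phosphorylation", "VLDL assembly", "protein synthesis",
    "urea output", "exchange",
    "pentose phosphate pathway", "TCA cycle", "transport", "ATP maintenance")
}

## parse one side of an equation string: "2 pep[c] + nadh[c]"
.parse_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(list(met = character(0), coef = numeric(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  coef <- numeric(length(terms)); met <- character(length(terms))
  for (k in seq_along(terms)) {
    m <- regmatches(terms[k],
                    regexec("^([0-9.]+\\s+)?([A-Za-z0-9_:-]+)\\[([a-z])\\]$", terms[k]))[[1]]
    if (length(m) == 0)
      stop("cannot parse equation term '", terms[k], "'")
    coef[k] <- if (nzchar(trimws(m[2]))) as.numeric(m[2]) else 1
    met[k] <- paste0(m[3], "_", m[4])
  }
  list(met = met, coef = coef)
}

.parse_equation <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  lhs <- .parse_side(sides[1]); rhs <- .parse_side(sides[2])
  list(met = c(lhs$met, rhs$met),
       coef = c(-lhs$coef, rhs$coef),
       reversible = rev)
}

.format_equation <- function(network, j) {
  s <- network$S[, j]
  nz <- which(s != 0)
  fmt <- function(idx) {
    if (!length(idx)) return("")
    ids <- rownames(network$S)[idx]
    comp <- sub(".*_([a-z])$", "\\1", ids)
    bare <- sub("_[a-z]$", "", ids)
    co <- abs(s[idx])
    paste(ifelse(co == 1, "", paste0(co, " ")),
          bare, "[", comp, "]", sep = "", collapse = " + ")
  }
  arrow <- if (network$reactions$reversible[j]) "<->" else "->"
  paste(fmt(nz[s[nz] < 0]), arrow, fmt(nz[s[nz] > 0]))
}

#' Build a metabolic network from reaction equations
#'
#' Constructs a \code{metabolic_network} from a reaction table with equation
#' strings in the form \code{"2 pep[c] + 2 nadh[c] -> g6p[c] + 2 nad[c]"}
#' (\code{"<->"} marks reversible reactions; an empty side marks a boundary
#' reaction, e.g. \code{"-> fa[c]"} for an uptake).
#'
#' @param reactions data.frame with columns \code{id}, \code{equation},
#'   \code{lower}, \code{upper}, \code{subsystem}.
#' @param carbons named numeric vector: carbon atoms per metabolite id
#'   (bare id without compartment suffix); defaults to 0 for carriers.
#' @param objective id of the objective reaction.
#' @return object of class \code{metabolic_network}: list with elements
#'   \code{metabolites}, \code{reactions}, \code{S} (sparse stoichiometric
#'   matrix, metabolites x reactions) and \code{objective}.
#' @export
network_from_reactions <- function(reactions, carbons = numeric(0),
                                   objective = NULL) {
  stopifnot(all(c("id", "equation", "lower", "upper", "subsystem") %in%
                  names(reactions)))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  parsed <- lapply(reactions$equation, .parse_equation)
  mets <- sort(unique(unlist(lapply(parsed, `[[`, "met"))))
  S <- Matrix::Matrix(0, length(mets), nrow(reactions), sparse = TRUE,
                      dimnames = list(mets, reactions$id))
  for (j in seq_along(parsed)) {
    p <- parsed[[j]]
    agg <- tapply(p$coef, p$met, sum)
    S[names(agg), j] <- as.numeric(agg)
  }
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  nterms <- vapply(parsed, function(p) length(p$met), integer(1))
  onesided <- vapply(parsed, function(p)
    length(p$coef) > 0 && (all(p$coef > 0) || all(p$coef < 0)), logical(1))
  boundary <- onesided & nterms == 1L
  bnd_met <- ifelse(boundary,
                    sub("_[a-z]$", "", vapply(parsed, function(p)
                      if (length(p$met)) p$met[1] else NA_character_,
                      character(1))),
                    NA_character_)
  bnd_dir <- ifelse(boundary,
                    ifelse(vapply(parsed, function(p)
                      length(p$coef) && p$coef[1] > 0, logical(1)),
                      "uptake", "secretion"),
                    NA_character_)
  bad <- setdiff(unique(reactions$subsystem), subsystem_labels())
  if (length(bad))
    stop("unknown subsystem label(s): ", paste(bad, collapse = ", "))

  bare <- sub("_[a-z]$", "", mets)
  carb <- ifelse(bare %in% names(carbons), carbons[bare], 0)
  network <- list(
    metabolites = data.frame(id = mets, name = bare,
                             compartment = sub(".*_([a-z])$", "\\1", mets),
                             carbons = as.numeric(carb),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = reactions$id,
                           lower = as.numeric(reactions$lower),
                           upper = as.numeric(reactions$upper),
                           reversible = reversible,
                           subsystem = reactions$subsystem,
                           boundary = boundary,
                           bnd_metabolite = bnd_met,
                           bnd_direction = bnd_dir,
                           stringsAsFactors = FALSE),
    S = S,
    objective = objective
  )
  class(network) <- "metabolic_network"
  if (!is.null(objective) && !objective %in% reactions$id)
    stop("objective reaction '", objective, "' not in network")
  network
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites (",
      sum(x$reactions$boundary), "boundary )\n")
  cat("objective:", if (is.null(x$objective)) "<none>" else x$objective, "\n")
  invisible(x)
}

#' Read or write a metabolic network
#'
#' Two dialects are supported. \code{"table"} is a TSV with one reaction per
#' row (\code{id}, \code{equation}, \code{lower}, \code{upper},
#' \code{subsystem}) preceded by header lines \code{#! met id carbons} for
#' carbon bookkeeping and \code{#! objective id}. \code{"sbml"} is SBML Level
#' 3 with flux bounds as parameters referenced through fbc attributes;
#' subsystem and carbon annotations travel in notes elements. Round-trips in
#' either dialect reproduce stoichiometry, bounds, annotations and objective.
#'
#' @param path file path.
#' @param dialect \code{"sbml"} or \code{"table"}; \code{load_network} infers
#'   it from the file extension when omitted.
#' @param network a \code{metabolic_network} (for writing).
#' @return \code{load_network} returns a \code{metabolic_network}.
#' @export
load_network <- function(path, dialect = c("auto", "sbml", "table")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "table"
  if (!file.exists(path)) stop("network file not found: ", path)
  if (dialect == "table") .load_network_table(path) else .load_network_sbml(path)
}

#' @rdname load_network
#' @export
write_network <- function(network, path, dialect = c("auto", "sbml", "table")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "table"
  if (dialect == "table") .write_network_table(network, path)
  else .write_network_sbml(network, path)
  invisible(path)
}

.write_network_table <- function(network, path) {
  con <- file(path, "w"); on.exit(close(con))
  bare <- unique(network$metabolites[, c("name", "carbons")])
  for (i in seq_len(nrow(bare)))
    writeLines(sprintf("#! met %s %s", bare$name[i],
                       format(bare$carbons[i], digits = 12)), con)
  if (!is.null(network$objective))
    writeLines(paste("#! objective", network$objective), con)
  eqs <- vapply(seq_len(nrow(network$reactions)),
                function(j) .format_equation(network, j), character(1))
  df <- data.frame(id = network$reactions$id, equation = eqs,
                   lower = network$reactions$lower,
                   upper = network$reactions$upper,
                   subsystem = network$reactions$subsystem)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.load_network_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("id", "equation", "lower", "upper", "subsystem")
  if (!all(need %in% names(df)))
    stop("network table at ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  carbons <- numeric(0); objective <- NULL
  for (ln in meta) {
    parts <- strsplit(trimws(sub("^#!\\s*", "", ln)), "\\s+")[[1]]
    if (parts[1] == "met") {
      carbons[parts[2]] <- as.numeric(parts[3])
    } else if (parts[1] == "objective") {
      objective <- parts[2]
    }
  }
  network_from_reactions(df, carbons = carbons, objective = objective)
}

.write_network_sbml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "steatoflux_model",
                               "fbc:strict" = "true")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(network$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (j in seq_len(nrow(network$reactions))) {
    rid <- network$reactions$id[j]
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", rid),
                        value = format(network$reactions$lower[j], digits = 15),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", rid),
                        value = format(network$reactions$upper[j], digits = 15),
                        constant = "true")
  }
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites))) {
    sp <- xml2::xml_add_child(
      sps, "species", id = paste0("M_", network$metabolites$id[i]),
      name = network$metabolites$name[i],
      compartment = network$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    notes <- xml2::xml_add_child(sp, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
                        paste0("carbons: ",
                               format(network$metabolites$carbons[i],
                                      digits = 12)))
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(network$reactions))) {
    rid <- network$reactions$id[j]
    rx <- xml2::xml_add_child(
      rxns, "reaction", id = paste0("R_", rid),
      reversible = tolower(as.character(network$reactions$reversible[j])),
      fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rid),
      "fbc:upperFluxBound" = paste0("ub_", rid))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("subsystem: ",
                                          network$reactions$subsystem[j]))
    s <- network$S[, j]
    nz <- which(s != 0)
    if (any(s[nz] < 0)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in nz[s[nz] < 0])
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", rownames(network$S)[i]),
                            stoichiometry = format(abs(s[i]), digits = 15),
                            constant = "true")
    }
    if (any(s[nz] > 0)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in nz[s[nz] > 0])
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", rownames(network$S)[i]),
                            stoichiometry = format(s[i], digits = 15),
                            constant = "true")
    }
  }
  if (!is.null(network$objective)) {
    objs <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", network$objective),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}

.load_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  xp <- function(node, q) xml2::xml_find_all(node, q)
  attr1 <- xml2::xml_attr

  par_nodes <- xp(doc, ".//*[local-name()='parameter']")
  pvals <- stats::setNames(as.numeric(attr1(par_nodes, "value")),
                           attr1(par_nodes, "id"))

  sp_nodes <- xp(doc, ".//*[local-name()='species']")
  sp_ids <- sub("^M_", "", attr1(sp_nodes, "id"))
  carb_txt <- vapply(sp_nodes, function(nd) {
    p <- xp(nd, ".//*[local-name()='p']")
    txt <- xml2::xml_text(p)
    hit <- grep("^carbons:", txt, value = TRUE)
    if (length(hit)) sub("^carbons:\\s*", "", hit[1]) else "0"
  }, character(1))
  carbons <- stats::setNames(as.numeric(carb_txt),
                             sub("_[a-z]$", "", sp_ids))

  rx_nodes <- xp(doc, ".//*[local-name()='reaction']")
  rows <- lapply(rx_nodes, function(nd) {
    rid <- sub("^R_", "", attr1(nd, "id"))
    rev <- identical(attr1(nd, "reversible"), "true")
    term <- function(q, sign) {
      refs <- xp(nd, q)
      if (!length(refs)) return(character(0))
      sp <- sub("^M_", "", attr1(refs, "species"))
      if (!all(sp %in% sp_ids))
        stop("reaction ", rid, " references undeclared species: ",
             paste(setdiff(sp, sp_ids), collapse = ", "))
      st <- as.numeric(attr1(refs, "stoichiometry"))
      comp <- sub(".*_([a-z])$", "\\1", sp)
      bare <- sub("_[a-z]$", "", sp)
      paste0(ifelse(st == 1, "", paste0(format(st, digits = 15), " ")),
             bare, "[", comp, "]")
    }
    lhs <- term(".//*[local-name()='listOfReactants']/*", -1)
    rhs <- term(".//*[local-name()='listOfProducts']/*", 1)
    arrow <- if (rev) "<->" else "->"
    eq <- paste(paste(lhs, collapse = " + "), arrow,
                paste(rhs, collapse = " + "))
    p <- xml2::xml_text(xp(nd, ".//*[local-name()='p']"))
    subsys <- sub("^subsystem:\\s*", "",
                  grep("^subsystem:", p, value = TRUE)[1])
    data.frame(id = rid, equation = trimws(eq),
               lower = pvals[[paste0("lb_", rid)]],
               upper = pvals[[paste0("ub_", rid)]],
               subsystem = subsys, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  obj_nodes <- xp(doc, ".//*[local-name()='fluxObjective']")
  objective <- if (length(obj_nodes))
    sub("^R_", "", xml2::xml_attr(obj_nodes[[1]], "reaction")) else NULL
  network_from_reactions(df, carbons = carbons, objective = objective)
}

#' Validate a network against a set of exchange bounds
#'
#' Report-only diagnostic: lists bound entries with no matching boundary
#' reaction, orphan metabolites (touched by no reaction), and (optionally,
#' via flux-variability analysis under the applied bounds) blocked reactions
#' whose flux range is zero.
#'
#' @param network a \code{metabolic_network}.
#' @param bounds an \code{exchange_bounds} table, or \code{NULL} to validate
#'   structure only.
#' @param check_blocked run the flux-variability blocked-reaction scan
#'   (one LP pair per reaction).
#' @return list with \code{unmatched} (data.frame of unmatched bound rows),
#'   \code{orphan_metabolites}, \code{blocked} (reaction ids, or \code{NA}
#'   when the scan was skipped or the model infeasible) and \code{feasible}.
#' @export
validate_network <- function(network, bounds = NULL, check_blocked = FALSE) {
  touched <- rownames(network$S)[Matrix::rowSums(abs(network$S)) > 0]
  orphans <- setdiff(network$metabolites$id, touched)
  unmatched <- NULL; blocked <- NA; feasible <- NA
  if (!is.null(bounds)) {
    key_net <- paste(network$reactions$bnd_metabolite,
                     network$reactions$bnd_direction)
    key_b <- paste(bounds$metabolite, bounds$direction)
    unmatched <- as.data.frame(bounds)[!(key_b %in% key_net), , drop = FALSE]
    if (nrow(unmatched) == 0 && check_blocked) {
      nb <- apply_bounds(network, bounds)
      lu <- .lp_form(nb)
      feas <- solve_lp(rep(0, ncol(lu$A)), lu$A, lb = lu$lb, ub = lu$ub)
      feasible <- feas$status == "optimal"
      if (feasible) {
        rng <- vapply(seq_len(ncol(lu$A)), function(j) {
          obj <- rep(0, ncol(lu$A)); obj[j] <- 1
          lo <- solve_lp(obj, lu$A, lb = lu$lb, ub = lu$ub)$objval
          hi <- solve_lp(obj, lu$A, lb = lu$lb, ub = lu$ub, maximize = TRUE)$objval
          c(lo, hi)
        }, numeric(2))
        blocked <- network$reactions$id[abs(rng[1, ]) < 1e-9 &
                                          abs(rng[2, ]) < 1e-9]
      }
    }
  }
  list(unmatched = unmatched, orphan_metabolites = orphans,
       blocked = blocked, feasible = feasible)
}
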