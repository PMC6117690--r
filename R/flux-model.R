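# Stoichiometric model container and readers/writers (simple TSV reaction
# dialect and SBML Level 3 with fbc bounds), plus the packaged toy networks
# used to exercise the flux-correlation analysis at desk scale.

#' Construct a metabolic model
#'
#' Builds the internal model representation from a reaction table and a
#' stoichiometry list. Usually called via [load_model()] or
#' [build_toy_network()] rather than directly.
#'
#' @param reactions Data frame with columns `rxn_id`, `subsystem`, `lb`,
#'   `ub`.
#' @param stoich Named list (by `rxn_id`) of named numeric vectors
#'   (metabolite id -> coefficient; negative = consumed).
#' @param target_reaction Id of the designated target reaction (e.g. the
#'   fucoxanthin-production step).
#' @param metabolites Optional data frame `id`, `compartment`; inferred from
#'   the stoichiometry when omitted (compartment = suffix after the last
#'   `_`).
#' @return Object of class `metabolic_model` with elements `metabolites`,
#'   `reactions`, `S` (dense metabolite x reaction matrix with dimnames) and
#'   `target_reaction`.
#' @export
metabolic_model <- function(reactions, stoich, target_reaction,
                            metabolites = NULL) {
  stopifnot(is.data.frame(reactions),
            all(c("rxn_id", "subsystem", "lb", "ub") %in% names(reactions)))
  if (anyDuplicated(reactions$rxn_id)) {
    stop("duplicated reaction ids", call. = FALSE)
  }
  if (!setequal(names(stoich), reactions$rxn_id)) {
    stop("stoichiometry list and reaction table disagree on reaction ids",
         call. = FALSE)
  }
  if (any(reactions$lb > reactions$ub)) {
    bad <- reactions$rxn_id[reactions$lb > reactions$ub]
    stop("lb > ub for reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  if (is.null(metabolites)) {
    comp <- sub("^.*_", "", met_ids)
    comp[comp == met_ids] <- "c"
    metabolites <- data.frame(id = met_ids, compartment = comp,
                              stringsAsFactors = FALSE)
  } else {
    undeclared <- setdiff(met_ids, metabolites$id)
    if (length(undeclared)) {
      stop("stoichiometry references undeclared metabolite(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }
  S <- matrix(0, nrow = nrow(metabolites), ncol = nrow(reactions),
              dimnames = list(metabolites$id, reactions$rxn_id))
  for (r in reactions$rxn_id) {
    sto <- stoich[[r]]
    if (length(sto)) S[names(sto), r] <- sto
  }
  if (!target_reaction %in% reactions$rxn_id) {
    stop("target reaction '", target_reaction, "' not in the model",
         call. = FALSE)
  }
  structure(list(metabolites = metabolites, reactions = reactions, S = S,
                 target_reaction = target_reaction),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", ncol(x$S), "reactions,", nrow(x$S),
      "metabolites,", length(unique(x$metabolites$compartment)),
      "compartment(s)\n")
  cat("  target reaction:", x$target_reaction, "\n")
  cat("  subsystems:",
      paste(sort(unique(x$reactions$subsystem)), collapse = "; "), "\n")
  invisible(x)
}

parse_equation_side <- function(side, row_label) {
  side <- trimws(side)
  if (side == "") return(numeric(0))
  terms <- trimws(strsplit(side, "\\+")[[1]])
  out <- numeric(0)
  for (tm in terms) {
    parts <- strsplit(tm, "\\s+")[[1]]
    if (length(parts) == 1) {
      coef <- 1; met <- parts[1]
    } else if (length(parts) == 2) {
      coef <- suppressWarnings(as.numeric(parts[1])); met <- parts[2]
    } else {
      stop("malformed equation term '", tm, "' in ", row_label,
           call. = FALSE)
    }
    if (is.na(coef) || coef <= 0 || met == "") {
      stop("malformed equation term '", tm, "' in ", row_label,
           call. = FALSE)
    }
    out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
  }
  out
}

parse_reaction_equation <- function(eq, row_label) {
  if (!grepl("->", eq, fixed = TRUE)) {
    stop("equation lacks '->' in ", row_label, call. = FALSE)
  }
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("multiple '->' in ", row_label, call. = FALSE)
  if (length(sides) == 1) sides <- c(sides, "")
  lhs <- parse_equation_side(sides[1], row_label)
  rhs <- parse_equation_side(sides[2], row_label)
  sto <- numeric(0)
  for (m in names(lhs)) sto[m] <- -lhs[[m]]
  for (m in names(rhs)) sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) +
    rhs[[m]]
  sto[sto != 0]
}

#' Load a metabolic model from TSV or SBML
#'
#' The TSV dialect has one reaction per row with columns
#' `rxn_id  subsystem  lb  ub  equation`, equations written like
#' `1 ga3p_c + 1 pyr_c -> 1 dxp_p` (coefficients optional, an empty side
#' denotes exchange with the environment). SBML input must be Level 3 with
#' `fbc` flux bounds; the reaction subsystem is read from the COBRA-style
#' `SUBSYSTEM:` line in the reaction notes.
#'
#' @param path Path to the model file.
#' @param format `"TSV"` or `"SBML"`; guessed from the file extension when
#'   omitted.
#' @param target_reaction Target reaction id; defaults to `"FUCO_SYN"`.
#' @return A [metabolic_model()]. A message reports reactions that cannot
#'   carry flux because both bounds are zero.
#' @export
load_model <- function(path, format = c("auto", "TSV", "SBML"),
                       target_reaction = "FUCO_SYN") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "SBML" else "TSV"
  }
  model <- switch(format,
                  TSV = load_model_tsv(path, target_reaction),
                  SBML = load_model_sbml(path, target_reaction))
  fixed_zero <- model$reactions$rxn_id[model$reactions$lb == 0 &
                                         model$reactions$ub == 0]
  if (length(fixed_zero)) {
    message("reaction(s) with zero bounds (blocked by construction): ",
            paste(fixed_zero, collapse = ", "))
  }
  model
}

load_model_tsv <- function(path, target_reaction) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("rxn_id", "subsystem", "lb", "ub", "equation")
  if (!all(req %in% names(tab))) {
    stop("model TSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  stoich <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) {
      parse_reaction_equation(tab$equation[i],
                              sprintf("row %d (%s)", i, tab$rxn_id[i]))
    }), tab$rxn_id)
  metabolic_model(tab[, c("rxn_id", "subsystem", "lb", "ub")], stoich,
                  target_reaction)
}

#' Write a metabolic model to the TSV reaction dialect
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  fmt_side <- function(sto, sign) {
    part <- sto[sign * sto > 0]
    if (!length(part)) return("")
    paste(sprintf("%g %s", abs(part), names(part)), collapse = " + ")
  }
  eqs <- vapply(model$reactions$rxn_id, function(r) {
    sto <- model$S[, r]
    sto <- sto[sto != 0]
    paste(fmt_side(sto, -1), "->", fmt_side(sto, 1))
  }, character(1))
  tab <- cbind(model$reactions, equation = trimws(eqs))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

load_model_sbml <- function(path, target_reaction) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(species) == 0) stop("SBML file declares no species",
                                 call. = FALSE)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0) stop("SBML file declares no reactions",
                                   call. = FALSE)
  get_bound <- function(node, attrname) {
    ref <- xml2::xml_attr(node, attrname, ns = ns)
    if (is.na(ref) || !ref %in% names(pvals)) {
      stop("reaction ", xml2::xml_attr(node, "id"),
           " lacks a resolvable fbc bound '", attrname, "'", call. = FALSE)
    }
    pvals[[ref]]
  }
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  subsystems <- vapply(rxn_nodes, function(node) {
    notes <- xml2::xml_find_all(node, ".//s:notes//*", ns)
    txt <- xml2::xml_text(notes)
    hit <- grep("^\\s*SUBSYSTEM:", txt, value = TRUE)
    if (length(hit)) trimws(sub("^\\s*SUBSYSTEM:\\s*", "", hit[1]))
    else "unassigned"
  }, character(1))
  stoich <- stats::setNames(lapply(rxn_nodes, function(node) {
    get_refs <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (!length(refs)) return(numeric(0))
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      stats::setNames(sign * sto, xml2::xml_attr(refs, "species"))
    }
    reac <- get_refs(".//s:listOfReactants/s:speciesReference", -1)
    prod <- get_refs(".//s:listOfProducts/s:speciesReference", +1)
    sto <- numeric(0)
    for (m in names(reac)) sto[m] <- reac[[m]]
    for (m in names(prod)) sto[m] <- (if (m %in% names(sto)) sto[[m]]
                                      else 0) + prod[[m]]
    sto[sto != 0]
  }), rxn_ids)
  reactions <- data.frame(
    rxn_id = rxn_ids, subsystem = subsystems,
    lb = vapply(rxn_nodes, get_bound, numeric(1), "fbc:lowerFluxBound"),
    ub = vapply(rxn_nodes, get_bound, numeric(1), "fbc:upperFluxBound"),
    stringsAsFactors = FALSE)
  metabolic_model(reactions, stoich, target_reaction, metabolites = mets)
}

#' Write a metabolic model as SBML Level 3 (fbc)
#'
#' Emits a minimal, standards-shaped SBML Level 3 Version 1 document with
#' `fbc` flux-bound parameters and the reaction subsystem stored as a
#' COBRA-style `SUBSYSTEM:` line in each reaction's notes; round-trips
#' through [load_model()].
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="toy_model" fbc:strict="true">',
    '    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment)) {
    lines <- c(lines, sprintf(
      '      <compartment id="%s" constant="true"/>', esc(cp)))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"/>'),
      esc(model$metabolites$id[i]), esc(model$metabolites$compartment[i])))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (i in seq_len(nrow(model$reactions))) {
    lines <- c(lines,
      sprintf('      <parameter id="lb_%s" value="%.17g" constant="true"/>',
              esc(model$reactions$rxn_id[i]), model$reactions$lb[i]),
      sprintf('      <parameter id="ub_%s" value="%.17g" constant="true"/>',
              esc(model$reactions$rxn_id[i]), model$reactions$ub[i]))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions$rxn_id[i]
    sto <- model$S[, r]
    sto <- sto[sto != 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
      esc(r), tolower(model$reactions$lb[i] < 0), esc(r), esc(r)),
      "        <notes>",
      '          <body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf("            <p>SUBSYSTEM: %s</p>",
              esc(model$reactions$subsystem[i])),
      "          </body>", "        </notes>")
    reac <- sto[sto < 0]
    prod <- sto[sto > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%.17g" constant="true"/>'),
                esc(names(reac)), abs(reac)),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%.17g" constant="true"/>'),
                esc(names(prod)), prod),
        "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Packaged toy metabolic network
#'
#' A small precursor-sharing network mirroring how carotenoid, chlorophyll
#' and lipid biosynthesis compete in a diatom chloroplast: glyceraldehyde
#' 3-phosphate (GA3P) and pyruvate feed the methylerythritol-phosphate
#' route (DXP synthase) to geranylgeranyl pyrophosphate (GGPP); GGPP is
#' consumed both by the fucoxanthin branch (phytoene synthase, then
#' fucoxanthin synthesis — the target reaction `FUCO_SYN`) and by the
#' chlorophyll branch (geranylgeranyl reductase to phytyl-PP, condensed
#' with chlorophyllide by chlorophyll synthase); pyruvate alternatively
#' enters lipid metabolism via pyruvate dehydrogenase and fatty-acid
#' elongation. A two-reaction nucleotide-salvage pair is stoichiometrically
#' disconnected from everything else, as an internal negative control for
#' the correlation analysis.
#'
#' @return A [metabolic_model()] with 16 reactions across cytosol (`_c`) and
#'   plastid (`_p`) compartments, target `FUCO_SYN`.
#' @export
build_toy_network <- function() {
  rx <- function(id, subsystem, lb, ub, eq) {
    list(id = id, subsystem = subsystem, lb = lb, ub = ub, eq = eq)
  }
  defs <- list(
    rx("EX_GA3P", "exchange", 0, 10, "-> ga3p_c"),
    rx("EX_PYR", "exchange", 0, 10, "-> pyr_c"),
    rx("DXS", "carotenoid biosynthesis", 0, 1000,
       "1 ga3p_c + 1 pyr_c -> 1 dxp_p"),
    rx("GGPPS", "carotenoid biosynthesis", 0, 1000, "1 dxp_p -> 1 ggpp_p"),
    rx("PSY", "carotenoid biosynthesis", 0, 1000,
       "1 ggpp_p -> 1 phytoene_p"),
    rx("FUCO_SYN", "carotenoid biosynthesis", 0, 1000,
       "1 phytoene_p -> 1 fuco_p"),
    rx("DM_FUCO", "exchange", 0, 1000, "1 fuco_p ->"),
    rx("GGDR", "porphyrin and chlorophyll metabolism", 0, 1000,
       "1 ggpp_p -> 1 phypp_p"),
    rx("CHLIDE_SYN", "porphyrin and chlorophyll metabolism", 0, 1000,
       "1 ga3p_c -> 1 chlide_p"),
    rx("CHLG", "porphyrin and chlorophyll metabolism", 0, 1000,
       "1 phypp_p + 1 chlide_p -> 1 chla_p"),
    rx("DM_CHLA", "exchange", 0, 1000, "1 chla_p ->"),
    rx("PDH", "lipid metabolism", 0, 1000, "1 pyr_c -> 1 accoa_c"),
    rx("FAS", "fatty acid elongation", 0, 1000, "1 accoa_c -> 1 fa_c"),
    rx("DM_FA", "exchange", 0, 1000, "1 fa_c ->"),
    rx("EX_URA", "nucleotide metabolism", 0, 5, "-> ura_c"),
    rx("DM_URA", "nucleotide metabolism", 0, 5, "1 ura_c ->"))
  reactions <- data.frame(
    rxn_id = vapply(defs, `[[`, character(1), "id"),
    subsystem = vapply(defs, `[[`, character(1), "subsystem"),
    lb = vapply(defs, `[[`, numeric(1), "lb"),
    ub = vapply(defs, `[[`, numeric(1), "ub"),
    stringsAsFactors = FALSE)
  stoich <- stats::setNames(
    lapply(defs, function(d) parse_reaction_equation(d$eq, d$id)),
    reactions$rxn_id)
  metabolic_model(reactions, stoich, "FUCO_SYN")
}

#' Two branches competing for a fixed precursor supply
#'
#' A minimal competition motif: a precursor enters at a fixed rate
#' (`supply`, both bounds equal) and is split between branch A (the target)
#' and branch B. Because the split fractions sum to one, the two branch
#' fluxes are exactly anticorrelated over the feasible set — the canonical
#' shape of a rival pathway draining a shared precursor pool.
#'
#' @param supply Fixed precursor uptake rate (lb = ub = `supply`).
#' @return A [metabolic_model()] with 5 reactions, target `BRANCH_A`.
#' @export
build_competition_network <- function(supply = 1) {
  stopifnot(supply > 0)
  reactions <- data.frame(
    rxn_id = c("SRC", "BRANCH_A", "BRANCH_B", "DM_A", "DM_B"),
    subsystem = c("exchange", "branch A", "branch B", "exchange",
                  "exchange"),
    lb = c(supply, 0, 0, 0, 0),
    ub = c(supply, supply, supply, supply, supply),
    stringsAsFactors = FALSE)
  stoich <- list(
    SRC = c(p_c = 1),
    BRANCH_A = c(p_c = -1, a_c = 1),
    BRANCH_B = c(p_c = -1, b_c = 1),
    DM_A = c(a_c = -1),
    DM_B = c(b_c = -1))
  metabolic_model(reactions, stoich, "BRANCH_A")
}
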