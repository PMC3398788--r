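#' @include AllGenerics.R
NULL

# ---- MathML <-> R expression conversion ------------------------------------

.mathmlOps <- c(plus = "+", minus = "-", times = "*", divide = "/",
                power = "^")

# Parse a MathML node (namespace-stripped) into an R expression.
parseMathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed MathML: expected one root child")
    return(parseMathml(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      # mantissa and exponent are separate text nodes around <sep/>
      parts <- trimws(xml2::xml_text(xml2::xml_find_all(node, "./text()")))
      parts <- parts[nzchar(parts)]
      return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], parseMathml)
    if (!op %in% names(.mathmlOps))
      stop("unsupported MathML operator: <", op, ">")
    sym <- as.name(.mathmlOps[[op]])
    if (length(args) == 1L) {
      if (op != "minus")
        stop("unary <", op, "> is not supported")
      return(call("-", args[[1L]]))
    }
    expr <- args[[1L]]
    for (i in seq_along(args)[-1L]) expr <- call(as.character(sym), expr,
                                                 args[[i]])
    return(expr)
  }
  if (nm == "csymbol")
    stop("unsupported MathML construct: <csymbol> (",
         trimws(xml2::xml_text(node)), ")")
  stop("unsupported MathML construct: <", nm, ">")
}

# Serialise an R expression to MathML (as a character string, no namespace).
exprToMathml <- function(e) {
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.numeric(e)) {
    if (e == round(e) && abs(e) < 1e15 && e == as.integer(e))
      return(paste0("<cn type=\"integer\"> ", format(e), " </cn>"))
    return(paste0("<cn> ", formatC(e, digits = 17, format = "g"), " </cn>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(exprToMathml(e[[2L]]))
    tag <- names(.mathmlOps)[match(op, .mathmlOps)]
    if (is.na(tag)) stop("cannot serialise operator '", op, "' to MathML")
    args <- vapply(as.list(e)[-1L], exprToMathml, "")
    return(paste0("<apply> <", tag, "/> ", paste(args, collapse = " "),
                  " </apply>"))
  }
  stop("cannot serialise expression of class ", class(e)[1L])
}

# Substitute names in an expression according to a named list of
# replacements (old name -> new expression / name / value).
substituteNames <- function(e, subs) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- substituteNames(e[[i]], subs)
    return(e)
  }
  e
}

# ---- SBML import -----------------------------------------------------------

#' Import a kinetic model from SBML
#'
#' Reads the supported SBML subset: a single compartment, species with
#' initial concentrations, global parameters, initial assignments over
#' parameters, and reactions carrying explicit kinetic laws built from the
#' arithmetic MathML operators (plus, minus, times, divide, power). Local
#' kinetic-law parameters are promoted to global parameters prefixed with
#' the reaction id. Boundary-condition and constant species become
#' parameters (they are not state variables). Unsupported constructs --
#' events, rules of any kind, constraints, function definitions, multiple
#' compartments, reactions without kinetic laws -- are rejected with an
#' error naming the construct, never silently dropped.
#'
#' @param path path to an SBML Level 2 or Level 3 file.
#' @return a \linkS4class{KineticModel}.
#' @seealso \code{\link{writeSBML}} for the round-trip export.
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_find_first(doc, "/sbml")
  if (inherits(root, "xml_missing")) stop("not an SBML document: ", path)
  level <- xml2::xml_attr(root, "level")
  if (!level %in% c("2", "3"))
    stop("unsupported SBML level: ", level)
  model <- xml2::xml_find_first(doc, "/sbml/model")
  if (inherits(model, "xml_missing")) stop("SBML file has no <model>")

  unsupported <- c(listOfEvents = "events", listOfRules = "rules",
                   listOfConstraints = "constraints",
                   listOfFunctionDefinitions = "function definitions")
  for (tag in names(unsupported)) {
    node <- xml2::xml_find_first(model, paste0("./", tag))
    if (!inherits(node, "xml_missing") && length(xml2::xml_children(node)))
      stop("unsupported SBML construct: ", unsupported[[tag]])
  }

  comps <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  if (length(comps) > 1L)
    stop("unsupported SBML construct: multiple compartments")
  if (length(comps) == 1L) {
    size <- xml2::xml_attr(comps[[1L]], "size")
    if (!is.na(size) && abs(as.numeric(size) - 1) > 1e-12)
      stop("unsupported SBML construct: compartment size != 1 ",
           "(amount/concentration conversion is out of scope)")
  }

  spNodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(spNodes)) stop("SBML model declares no species")
  spId <- xml2::xml_attr(spNodes, "id")
  spInit <- as.numeric(xml2::xml_attr(spNodes, "initialConcentration"))
  spInitAmt <- as.numeric(xml2::xml_attr(spNodes, "initialAmount"))
  spInit[is.na(spInit)] <- spInitAmt[is.na(spInit)]
  spInit[is.na(spInit)] <- 0
  isBoundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(spNodes, "constant") %in% "true"

  parNodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parms <- as.numeric(xml2::xml_attr(parNodes, "value"))
  names(parms) <- xml2::xml_attr(parNodes, "id")
  parms[is.na(parms)] <- 0
  # boundary species enter the parameter registry, not the state vector
  if (any(isBoundary)) {
    bparms <- spInit[isBoundary]
    names(bparms) <- spId[isBoundary]
    parms <- c(parms, bparms)
  }
  stateId <- spId[!isBoundary]

  initialExprs <- list()
  iaNodes <- xml2::xml_find_all(model,
                                "./listOfInitialAssignments/initialAssignment")
  for (ia in iaNodes) {
    sym <- xml2::xml_attr(ia, "symbol")
    math <- xml2::xml_find_first(ia, "./math")
    if (inherits(math, "xml_missing"))
      stop("initialAssignment for '", sym, "' lacks <math>")
    if (!sym %in% stateId)
      stop("unsupported SBML construct: initialAssignment to non-species '",
           sym, "'")
    initialExprs[[sym]] <- parseMathml(math)
  }

  rxNodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- list()
  for (rx in rxNodes) {
    rid <- xml2::xml_attr(rx, "id")
    getRefs <- function(xpath) {
      refs <- xml2::xml_find_all(rx, xpath)
      if (!length(refs)) return(numeric())
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      names(st) <- xml2::xml_attr(refs, "species")
      # boundary species are fixed pools: they contribute no state change
      st[!names(st) %in% stateId] <- NULL
      st
    }
    reactants <- getRefs("./listOfReactants/speciesReference")
    products <- getRefs("./listOfProducts/speciesReference")
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", rid, "' lacks a kinetic law")
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      stop("kinetic law of reaction '", rid, "' lacks <math>")
    rate <- parseMathml(math)
    localNodes <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter|./listOfParameters/parameter")
    if (length(localNodes)) {
      lid <- xml2::xml_attr(localNodes, "id")
      lval <- as.numeric(xml2::xml_attr(localNodes, "value"))
      gid <- paste(rid, lid, sep = "_")
      subs <- lapply(gid, as.name)
      names(subs) <- lid
      rate <- substituteNames(rate, subs)
      names(lval) <- gid
      parms <- c(parms, lval)
    }
    reactions[[length(reactions) + 1L]] <-
      list(id = rid, reactants = reactants, products = products, rate = rate)
  }

  KineticModel(name = xml2::xml_attr(model, "id"),
               species = data.frame(name = stateId,
                                    initial = spInit[!isBoundary]),
               parameters = parms, reactions = reactions,
               initialExprs = initialExprs)
}

# ---- SBML export -----------------------------------------------------------

#' Export a kinetic model to SBML Level 3 Version 1
#'
#' Writes the model's species (with initial concentrations), parameters,
#' initial assignments and reactions (with kinetic-law MathML) so the model
#' can be consumed by third-party SBML tools. Species appearing in a rate
#' law without being consumed or produced are declared as reaction
#' modifiers. Amounts are nM, time is minutes; the single compartment has
#' unit size.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param path output file path.
#' @return invisibly, the path.
#' @examples
#' path <- tempfile(fileext = ".xml")
#' writeSBML(makeReducedErbbModel(), path)
#' m2 <- readSBML(path)
#' @export
writeSBML <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp <- model@species
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\">"),
    paste0("  <model id=\"", esc(model@name), "\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"cell\" size=\"1\" spatialDimensions=",
           "\"3\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(sp)))
    lines <- c(lines, paste0(
      "      <species id=\"", sp$name[i], "\" compartment=\"cell\" ",
      "initialConcentration=\"", formatC(sp$initial[i], digits = 17,
                                         format = "g"),
      "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
      "constant=\"false\"/>"))
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (nm in names(model@parameters))
    lines <- c(lines, paste0(
      "      <parameter id=\"", nm, "\" value=\"",
      formatC(model@parameters[[nm]], digits = 17, format = "g"),
      "\" constant=\"true\"/>"))
  lines <- c(lines, "    </listOfParameters>")
  if (length(model@initialExprs)) {
    lines <- c(lines, "    <listOfInitialAssignments>")
    for (nm in names(model@initialExprs))
      lines <- c(lines, paste0(
        "      <initialAssignment symbol=\"", nm, "\">",
        "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
        exprToMathml(model@initialExprs[[nm]]),
        "</math></initialAssignment>"))
    lines <- c(lines, "    </listOfInitialAssignments>")
  }
  lines <- c(lines, "    <listOfReactions>")
  for (rx in model@reactions) {
    lines <- c(lines, paste0("      <reaction id=\"", rx$id,
                             "\" reversible=\"true\">"))
    writeRefs <- function(refs, tag, refTag) {
      if (!length(refs)) return(character())
      c(paste0("        <", tag, ">"),
        vapply(seq_along(refs), function(i) paste0(
          "          <", refTag, " species=\"", names(refs)[i],
          "\" stoichiometry=\"", formatC(refs[[i]], format = "g"),
          "\" constant=\"true\"/>"), ""),
        paste0("        </", tag, ">"))
    }
    lines <- c(lines,
               writeRefs(rx$reactants, "listOfReactants", "speciesReference"),
               writeRefs(rx$products, "listOfProducts", "speciesReference"))
    modifiers <- setdiff(intersect(all.vars(rx$rate), sp$name),
                         c(names(rx$reactants), names(rx$products)))
    if (length(modifiers))
      lines <- c(lines, "        <listOfModifiers>",
                 vapply(modifiers, function(msp) paste0(
                   "          <modifierSpeciesReference species=\"", msp,
                   "\"/>"), ""),
                 "        </listOfModifiers>")
    lines <- c(lines, paste0(
      "        <kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/",
      "MathML\">", exprToMathml(rx$rate), "</math></kineticLaw>"),
      "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
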