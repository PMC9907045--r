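## SBML input/output.  Reads Levels 1-3; bounds are taken from the fbc
## package (Level 3), from the COBRA kinetic-law parameter convention
## (LOWER_BOUND/UPPER_BOUND, Level 2), or defaulted from the
## `reversible` flag: (-1000, 1000) for reversible reactions, (0, 1000)
## for irreversible ones.  Writes Level 3 Version 1 with fbc version 2.
## No R SBML binding is part of this package's dependency footprint, so
## reading is done with xml2 over the (small) subset of SBML this tool
## needs: species, reactions, stoichiometry, bounds, objective,
## boundaryCondition.

DEFAULT_BOUND <- 1000

## attribute lookup that tolerates presence/absence of a namespace
## prefix (documents are parsed with namespaces stripped, which leaves
## prefixed attribute names like "fbc:lowerFluxBound" intact)
xattr <- function(node, names) {
  for (nm in names) {
    v <- xml2::xml_attr(node, nm)
    if (!is.na(v)) return(v)
  }
  NA_character_
}

#' Read a constraint-based model from SBML
#'
#' Supports SBML Levels 1, 2 and 3.  Flux bounds are read from the fbc
#' extension when present (Level 3), from COBRA-style kinetic-law
#' parameters named `LOWER_BOUND`/`UPPER_BOUND` (Level 2), and default
#' to (-1000, 1000) for reactions flagged `reversible` and (0, 1000)
#' otherwise.  The growth objective is taken from the active fbc
#' objective if present, from `objective` if supplied, and is otherwise
#' left unset (computations that need it will then error).  Metabolites
#' with `boundaryCondition="true"` are flagged as boundary.
#'
#' @param path path to an SBML file.
#' @param objective optional reaction id overriding the fbc objective.
#' @return a `cbm` model.
#' @export
read_sbml <- function(path, objective = NULL) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sbml <- xml2::xml_find_first(doc, "/sbml")
  if (inherits(sbml, "xml_missing"))
    stop("SBML parse failure: no <sbml> root element")
  mdl <- xml2::xml_find_first(doc, "/sbml/model")
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure: no <model> element")
  level <- suppressWarnings(as.integer(xml2::xml_attr(sbml, "level")))
  if (is.na(level)) level <- 3L

  sp_nodes <- xml2::xml_find_all(mdl, "listOfSpecies/species")
  sp_id <- vapply(sp_nodes, function(s) {
    id <- xattr(s, c("id", "name"))   # Level 1 has only "name"
    if (is.na(id)) stop("SBML species without id") else id
  }, character(1))
  sp_boundary <- vapply(sp_nodes, function(s)
    identical(tolower(xattr(s, "boundaryCondition")), "true"), logical(1))

  ## global parameters (fbc bound references)
  par_nodes <- xml2::xml_find_all(mdl, "listOfParameters/parameter")
  par_val <- stats::setNames(
    vapply(par_nodes, function(p)
      suppressWarnings(as.numeric(xattr(p, "value"))), numeric(1)),
    vapply(par_nodes, function(p) xattr(p, c("id", "name")), character(1)))

  rx_nodes <- xml2::xml_find_all(mdl, "listOfReactions/reaction")
  n <- length(rx_nodes)
  rx_id <- character(n); lb <- numeric(n); ub <- numeric(n)
  tri_i <- integer(); tri_j <- integer(); tri_x <- numeric()
  sp_index <- stats::setNames(seq_along(sp_id), sp_id)
  for (j in seq_len(n)) {
    rx <- rx_nodes[[j]]
    rx_id[j] <- xattr(rx, c("id", "name"))
    rev_attr <- xattr(rx, "reversible")
    reversible <- is.na(rev_attr) || identical(tolower(rev_attr), "true")
    b <- c(if (reversible) -DEFAULT_BOUND else 0, DEFAULT_BOUND)
    ## Level 3 fbc bound references
    lref <- xattr(rx, c("fbc:lowerFluxBound", "lowerFluxBound"))
    uref <- xattr(rx, c("fbc:upperFluxBound", "upperFluxBound"))
    if (!is.na(lref) && lref %in% names(par_val)) b[1] <- par_val[[lref]]
    if (!is.na(uref) && uref %in% names(par_val)) b[2] <- par_val[[uref]]
    ## Level 2 kinetic-law parameter convention
    kl <- xml2::xml_find_all(rx, "kineticLaw/listOfParameters/parameter")
    for (p in kl) {
      pid <- xattr(p, c("id", "name"))
      pv <- suppressWarnings(as.numeric(xattr(p, "value")))
      if (!is.na(pv)) {
        if (identical(pid, "LOWER_BOUND")) b[1] <- pv
        if (identical(pid, "UPPER_BOUND")) b[2] <- pv
      }
    }
    lb[j] <- b[1]; ub[j] <- b[2]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in xml2::xml_find_all(rx, paste0(side, "/speciesReference"))) {
        sid <- xattr(sr, c("species", "name"))
        st <- suppressWarnings(as.numeric(xattr(sr, "stoichiometry")))
        if (is.na(st)) st <- 1
        if (!sid %in% names(sp_index))
          stop("speciesReference to unknown species: ", sid)
        tri_i <- c(tri_i, sp_index[[sid]])
        tri_j <- c(tri_j, j)
        tri_x <- c(tri_x, sgn * st)
      }
    }
  }
  if (anyDuplicated(rx_id)) stop("duplicate reaction ids in SBML")
  S <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                            dims = c(length(sp_id), n),
                            dimnames = list(sp_id, rx_id))

  obj <- NA_character_
  if (!is.null(objective)) {
    obj <- objective
  } else {
    ## active fbc objective (fbc elements keep their namespace even
    ## after stripping, so match on local-name)
    lo <- xml2::xml_find_first(mdl, "*[local-name()='listOfObjectives']")
    if (!inherits(lo, "xml_missing")) {
      active <- xattr(lo, c("fbc:activeObjective", "activeObjective"))
      objs <- xml2::xml_find_all(lo, "*[local-name()='objective']")
      pick <- objs
      if (!is.na(active) && length(objs)) {
        ids <- vapply(objs, function(o) xattr(o, c("fbc:id", "id")),
                      character(1))
        if (active %in% ids) pick <- objs[ids == active]
      }
      if (length(pick)) {
        fo <- xml2::xml_find_all(
          pick[[1]], ".//*[local-name()='fluxObjective']")
        coef <- vapply(fo, function(f) {
          v <- suppressWarnings(as.numeric(
            xattr(f, c("fbc:coefficient", "coefficient"))))
          if (is.na(v)) 1 else v
        }, numeric(1))
        rids <- vapply(fo, function(f)
          xattr(f, c("fbc:reaction", "reaction")), character(1))
        nz <- which(abs(coef) > 0)
        if (length(nz) > 1)
          stop("multiple reactions with nonzero objective coefficient; ",
               "pass `objective` to select the growth reaction")
        if (length(nz) == 1) obj <- rids[nz]
      }
    }
  }
  cbm(S, lb, ub, reactions = rx_id, metabolites = sp_id,
      objective = obj, boundary = sp_id[sp_boundary])
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.15g", x)

#' Write a constraint-based model as SBML Level 3 + fbc
#'
#' Serializes the model (including any FVA-updated bounds) as SBML
#' Level 3 Version 1 with the fbc version 2 extension: one global
#' parameter per distinct bound value, fbc bound references on each
#' reaction, and the growth objective as the active fbc objective.
#' The output round-trips through [read_sbml()].
#'
#' @param model a `cbm` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "cbm"))
  vals <- sort(unique(c(model$lower, model$upper)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(vals)), num_attr(vals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', "gemvuln_model"),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_along(model$metabolites)) {
    m <- model$metabolites[i]
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="c" constant="false" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="%s"/>'),
      xml_escape(m),
      if (m %in% model$boundary) "true" else "false"))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(vals))
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pid[[k]], num_attr(vals[k])))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  tri <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[j]
    lo <- model$lower[j]; hi <- model$upper[j]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(r), if (lo < 0) "true" else "false",
      pid[[num_attr(lo)]], pid[[num_attr(hi)]]))
    rows <- which(tri$j == j)
    for (side in c(-1, 1)) {
      sel <- rows[sign(tri$x[rows]) == side]
      if (!length(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf('        <%s>', tag))
      for (k in sel)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(model$metabolites[tri$i[k]]), num_attr(abs(tri$x[k]))))
      lines <- c(lines, sprintf('        </%s>', tag))
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.na(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                     'fbc:coefficient="1"/>'), xml_escape(model$objective)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
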