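# In-memory HistoML document. A document is an environment (reference
# semantics) so builder calls can both register the individual and hand it
# back, mirroring how OWL editors treat a working ontology.
#
# Each individual is a list:
#   iri    full IRI
#   class  schema local class name
#   links  data.frame(property, target)   object links
#   values named list: datatype property -> character/numeric vector

#' Slide metadata
#'
#' @param height,width slide dimensions in pixels (> 0).
#' @param magnification objective magnification (e.g. 40 for 40x).
#' @param microns_per_pixel optional physical resolution in micrometres per
#'   pixel (> 0 when given).
#' @return a `histoml_metadata` list.
#' @export
slide_metadata <- function(height, width, magnification,
                           microns_per_pixel = NULL) {
  if (!is.numeric(height) || length(height) != 1L || height <= 0 ||
      height != round(height)) {
    stop("invalid slide metadata: height must be a positive integer")
  }
  if (!is.numeric(width) || length(width) != 1L || width <= 0 ||
      width != round(width)) {
    stop("invalid slide metadata: width must be a positive integer")
  }
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      magnification <= 0) {
    stop("invalid slide metadata: magnification must be positive")
  }
  if (!is.null(microns_per_pixel) &&
      (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)) {
    stop("invalid slide metadata: microns_per_pixel must be positive")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 magnification = as.numeric(magnification),
                 microns_per_pixel = microns_per_pixel),
            class = "histoml_metadata")
}

#' Create an empty HistoML document
#'
#' Binds a document to a schema and records the slide metadata as a
#' `WholeSlideImage` individual. Individual IRIs are minted deterministically
#' as `{base_iri}{slide_id}/{Class}_{counter}` so that serializations are
#' stable and diffable.
#'
#' @param metadata a [slide_metadata()] object.
#' @param schema a `histoml_schema`; defaults to [build_schema()].
#' @param base_iri base IRI for individuals (must end in `/` or `#`).
#' @param slide_id identifier segment for this slide.
#' @return a `histoml_document` (environment; modified in place by the
#'   builder functions).
#' @export
#' @examples
#' doc <- new_document(slide_metadata(1000, 1000, 40))
#' n_individuals(doc)
new_document <- function(metadata, schema = build_schema(),
                         base_iri = "https://histoml.example/wsi/",
                         slide_id = "slide1") {
  if (!inherits(metadata, "histoml_metadata")) {
    metadata <- do.call(slide_metadata, as.list(metadata))
  }
  if (!grepl("[/#]$", base_iri)) base_iri <- paste0(base_iri, "/")
  doc <- new.env(parent = emptyenv())
  doc$schema <- schema
  doc$base_iri <- base_iri
  doc$slide_id <- slide_id
  doc$individuals <- list()
  doc$counters <- list()
  doc$xref_index <- character(0)  # curie -> individual iri
  class(doc) <- "histoml_document"
  slide <- new_individual(doc, "WholeSlideImage")
  slide <- set_value(doc, slide, "height", metadata$height)
  slide <- set_value(doc, slide, "width", metadata$width)
  slide <- set_value(doc, slide, "magnification", metadata$magnification)
  if (!is.null(metadata$microns_per_pixel)) {
    set_value(doc, slide, "micronsPerPixel", metadata$microns_per_pixel)
  }
  doc
}

#' @export
print.histoml_document <- function(x, ...) {
  md <- document_metadata(x)
  cat("HistoML document <", x$base_iri, x$slide_id, ">\n", sep = "")
  cat("  slide: ", md$width, "x", md$height, " px @ ", md$magnification,
      "x\n", sep = "")
  cat("  individuals:", length(x$individuals), "\n")
  invisible(x)
}

#' Number of individuals in a document
#' @param doc a `histoml_document`.
#' @return integer count (including the `WholeSlideImage` metadata
#'   individual).
#' @export
n_individuals <- function(doc) length(doc$individuals)

#' Retrieve an individual by IRI
#' @param doc a `histoml_document`.
#' @param iri full individual IRI.
#' @return the individual record (list), or error if absent.
#' @export
get_individual <- function(doc, iri) {
  ind <- doc$individuals[[iri]]
  if (is.null(ind)) stop("no such individual in document: ", iri)
  ind
}

#' IRIs of all individuals, optionally filtered by class closure
#' @param doc a `histoml_document`.
#' @param class_name optional class local name; when given, only individuals
#'   whose class is in its subclass closure are returned.
#' @return character vector of IRIs, sorted.
#' @export
individual_iris <- function(doc, class_name = NULL) {
  iris <- names(doc$individuals)
  if (!is.null(class_name)) {
    keep <- subclass_closure(doc$schema, class_name)
    cls <- vapply(doc$individuals, `[[`, character(1), "class")
    iris <- iris[cls %in% keep]
  }
  sort(iris)
}

#' Slide metadata of a document
#' @param doc a `histoml_document`.
#' @return a [slide_metadata()] object read back from the document's
#'   `WholeSlideImage` individual.
#' @export
document_metadata <- function(doc) {
  iri <- individual_iris(doc, "WholeSlideImage")
  if (length(iri) != 1L) stop("document must contain exactly one ",
                              "WholeSlideImage individual")
  ind <- get_individual(doc, iri[[1]])
  slide_metadata(ind$values$height, ind$values$width,
                 ind$values$magnification,
                 ind$values$micronsPerPixel)
}

# ---- low-level builders ----------------------------------------------------

new_individual <- function(doc, class_name, iri = NULL) {
  assert_declared_class(doc$schema, class_name)
  if (is.null(iri)) {
    n <- (doc$counters[[class_name]] %||% 0L) + 1L
    doc$counters[[class_name]] <- n
    iri <- paste0(doc$base_iri, doc$slide_id, "/", class_name, "_", n)
  }
  if (!is.null(doc$individuals[[iri]])) {
    stop("individual IRI already present in document: ", iri)
  }
  ind <- list(iri = iri, class = class_name,
              links = data.frame(property = character(),
                                 target = character(),
                                 stringsAsFactors = FALSE),
              values = list())
  doc$individuals[[iri]] <- ind
  ind
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_link <- function(doc, from_iri, property, to_iri) {
  op <- doc$schema$object_properties
  if (!property %in% op$property) {
    stop("object property not declared in schema: ", property)
  }
  ind <- get_individual(doc, from_iri)
  ind$links <- rbind(ind$links,
                     data.frame(property = property, target = to_iri,
                                stringsAsFactors = FALSE))
  doc$individuals[[from_iri]] <- ind
  invisible(ind)
}

set_value <- function(doc, ind, property, value) {
  dp <- doc$schema$datatype_properties
  if (!property %in% dp$property) {
    stop("datatype property not declared in schema: ", property)
  }
  iri <- if (is.character(ind) && length(ind) == 1L) ind else ind$iri
  rec <- get_individual(doc, iri)
  rec$values[[property]] <- c(rec$values[[property]], value)
  doc$individuals[[iri]] <- rec
  invisible(rec)
}

# Individuals whose class is within the closure of `class_name`.
is_of_class <- function(doc, iri, class_name) {
  get_individual(doc, iri)$class %in% subclass_closure(doc$schema, class_name)
}

iri_of <- function(x) if (is.list(x)) x$iri else x

# ---- public builder API ----------------------------------------------------

#' Add a physical entity to a document
#'
#' Creates an individual of a `PhysicalEntity` subclass, optionally linked to
#' a generic [add_entity_reference()] via `entityReference` (so many concrete
#' forms can share one generic description), and carrying `segmentation`
#' identifiers that tie the individual to its pixels in the slide.
#'
#' @param doc a `histoml_document`.
#' @param class_name class local name inside the `PhysicalEntity` closure.
#' @param entity_reference optional `EntityReference` individual (or IRI).
#' @param segmentation_ids character vector of segmentation identifiers.
#' @param name optional human-readable name stored under `name`.
#' @return the new individual.
#' @export
add_physical_entity <- function(doc, class_name, entity_reference = NULL,
                                segmentation_ids = character(0),
                                name = NULL) {
  class_name <- schema_local(doc$schema, class_name)
  if (!class_name %in% subclass_closure(doc$schema, "PhysicalEntity")) {
    stop("class '", class_name, "' is not a PhysicalEntity subclass")
  }
  ind <- new_individual(doc, class_name)
  if (!is.null(entity_reference)) {
    ref_iri <- iri_of(entity_reference)
    if (!is_of_class(doc, ref_iri, "EntityReference")) {
      stop("entity_reference must be an EntityReference individual")
    }
    add_link(doc, ind$iri, "entityReference", ref_iri)
  }
  for (sid in segmentation_ids) set_value(doc, ind$iri, "segmentation", sid)
  if (!is.null(name)) set_value(doc, ind$iri, "name", name)
  get_individual(doc, ind$iri)
}

#' Add a generic entity reference
#'
#' An `EntityReference` holds the description common to many concrete forms
#' of the same kind of entity; concrete `PhysicalEntity` individuals link to
#' it via `entityReference` without duplicating the shared information.
#'
#' @param doc a `histoml_document`.
#' @param name human-readable name of the generic entity.
#' @param xrefs character vector of CURIE cross-references.
#' @return the new individual.
#' @export
add_entity_reference <- function(doc, name, xrefs = character(0)) {
  ind <- new_individual(doc, "EntityReference")
  set_value(doc, ind$iri, "name", name)
  for (x in xrefs) link_xref(doc, ind$iri, x)
  get_individual(doc, ind$iri)
}

#' Quantification node
#'
#' A measured value attached to an entity attribute: parameter name, value,
#' unit, and optionally the defining formula and a link to the source
#' material proposing the measurement.
#'
#' @param parameter_name measurement name (e.g. `"area"`, `"circularity"`).
#' @param value finite numeric value.
#' @param unit unit string or CURIE (e.g. `"um^2"`, a UO CURIE, or
#'   `"dimensionless"`).
#' @param formula optional formula string.
#' @param source optional URL of the proposing source.
#' @return a `histoml_quantification` list.
#' @export
quantification <- function(parameter_name, value, unit, formula = NULL,
                           source = NULL) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("quantification value must be a single finite number")
  }
  if (missing(unit) || is.null(unit) || !nzchar(unit)) {
    stop("quantification unit must be given (use \"dimensionless\" for ",
         "dimensionless parameters)")
  }
  structure(list(parameter_name = parameter_name, value = as.numeric(value),
                 unit = unit, formula = formula, source = source),
            class = "histoml_quantification")
}

# CURIE shape check: PREFIX:LOCALID
is_curie <- function(x) grepl("^[A-Za-z][A-Za-z0-9]*:[^[:space:]]+$", x)

# One Xref individual per distinct CURIE per document.
link_xref <- function(doc, from_iri, curie) {
  if (!is_curie(curie)) {
    stop("malformed CURIE (expected PREFIX:LOCALID): ", curie)
  }
  xiri <- doc$xref_index[curie]
  if (is.na(xiri)) {
    x <- new_individual(doc, "Xref")
    set_value(doc, x$iri, "xrefId", curie)
    doc$xref_index[curie] <- x$iri
    xiri <- x$iri
  }
  add_link(doc, from_iri, "hasXref", unname(xiri))
  invisible(unname(xiri))
}

#' Attach an attribute (with cross-references and quantifications) to an
#' entity
#'
#' Creates an `EntityAttribute` linked from the entity via `hasAttribute`.
#' The attribute pins down *what* is being described through opaque CURIE
#' cross-references into the controlled vocabulary, and *how much* through
#' [quantification()] nodes linked via `hasQuantification`. An attribute
#' with neither xref nor quantification is permitted (purely named
#' attributes occur in practice) but triggers a validation warning.
#'
#' @param doc a `histoml_document`.
#' @param entity a `PhysicalEntity` individual (or IRI).
#' @param attribute_name human-readable attribute name (e.g. `"large"`).
#' @param xrefs character vector of CURIEs.
#' @param quantifications list of [quantification()] objects.
#' @return the new `EntityAttribute` individual.
#' @export
attach_attribute <- function(doc, entity, attribute_name,
                             xrefs = character(0),
                             quantifications = list()) {
  ent_iri <- iri_of(entity)
  if (!is_of_class(doc, ent_iri, "PhysicalEntity")) {
    stop("attributes can only be attached to PhysicalEntity individuals")
  }
  # validate inputs before touching the document, so a failed call leaves
  # no partially-built attribute behind
  for (x in xrefs) {
    if (!is_curie(x)) stop("malformed CURIE (expected PREFIX:LOCALID): ", x)
  }
  for (q in quantifications) {
    if (!inherits(q, "histoml_quantification")) {
      stop("quantifications must be built with quantification()")
    }
  }
  attr_ind <- new_individual(doc, "EntityAttribute")
  set_value(doc, attr_ind$iri, "name", attribute_name)
  add_link(doc, ent_iri, "hasAttribute", attr_ind$iri)
  for (x in xrefs) link_xref(doc, attr_ind$iri, x)
  for (q in quantifications) {
    if (!inherits(q, "histoml_quantification")) {
      stop("quantifications must be built with quantification()")
    }
    qi <- new_individual(doc, "Quantification")
    set_value(doc, qi$iri, "parameterName", q$parameter_name)
    set_value(doc, qi$iri, "value", q$value)
    set_value(doc, qi$iri, "unit", q$unit)
    if (!is.null(q$formula)) set_value(doc, qi$iri, "formula", q$formula)
    if (!is.null(q$source)) set_value(doc, qi$iri, "source", q$source)
    add_link(doc, attr_ind$iri, "hasQuantification", qi$iri)
  }
  get_individual(doc, attr_ind$iri)
}

# Containment edges over hasComponent and its child properties.
containment_properties <- function(schema) {
  c("hasComponent", subproperties_of(schema, "hasComponent"))
}

containment_edges <- function(doc) {
  props <- containment_properties(doc$schema)
  from <- character(0); to <- character(0)
  for (ind in doc$individuals) {
    keep <- ind$links$property %in% props
    if (any(keep)) {
      from <- c(from, rep(ind$iri, sum(keep)))
      to <- c(to, ind$links$target[keep])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

reachable_from <- function(edges, start) {
  out <- character(0)
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, out)
    out <- c(out, frontier)
  }
  out
}

#' Link a component into a containing physical entity
#'
#' Adds a containment edge (`hasComponent` or one of its child properties
#' `hasCell`, `hasCellularComponent`, `hasAnatomicalEntity`) between two
#' physical entities. The containment graph must stay acyclic.
#'
#' @param doc a `histoml_document`.
#' @param parent,child `PhysicalEntity` individuals (or IRIs).
#' @param property containment property name.
#' @return invisibly, the updated parent individual.
#' @export
link_component <- function(doc, parent, child,
                           property = c("hasComponent", "hasCell",
                                        "hasCellularComponent",
                                        "hasAnatomicalEntity")) {
  property <- match.arg(property)
  p_iri <- iri_of(parent); c_iri <- iri_of(child)
  for (iri in c(p_iri, c_iri)) {
    if (!is_of_class(doc, iri, "PhysicalEntity")) {
      stop("containment links connect PhysicalEntity individuals; not: ", iri)
    }
  }
  # range check for the specific child property
  rng <- doc$schema$object_properties$range[
    doc$schema$object_properties$property == property]
  if (!is.na(rng) && !is_of_class(doc, c_iri, rng)) {
    stop("property '", property, "' requires a ", rng, " target; ",
         c_iri, " is a ", get_individual(doc, c_iri)$class)
  }
  if (p_iri == c_iri ||
      p_iri %in% reachable_from(containment_edges(doc), c_iri)) {
    stop("containment cycle: ", c_iri, " already contains ", p_iri)
  }
  add_link(doc, p_iri, property, c_iri)
  invisible(get_individual(doc, p_iri))
}

#' Record a product or reserve of a cell
#'
#' Granular cytoplasmic materials (mucin, glycogen, ...) are represented as
#' `Substance` individuals linked from their cell via `hasProduct` or
#' `hasReserve`.
#'
#' @param doc a `histoml_document`.
#' @param cell a `Cell` individual (or IRI).
#' @param substance a `Substance` individual (or IRI).
#' @param relation `"hasProduct"` or `"hasReserve"`.
#' @return invisibly, the updated cell individual.
#' @export
add_product_or_reserve <- function(doc, cell, substance,
                                   relation = c("hasProduct", "hasReserve")) {
  relation <- match.arg(relation)
  cell_iri <- iri_of(cell); sub_iri <- iri_of(substance)
  if (!is_of_class(doc, cell_iri, "Cell")) {
    stop("products and reserves belong to Cell individuals; not: ",
         get_individual(doc, cell_iri)$class)
  }
  if (!is_of_class(doc, sub_iri, "Substance")) {
    stop("products and reserves must be Substance individuals; not: ",
         get_individual(doc, sub_iri)$class)
  }
  add_link(doc, cell_iri, relation, sub_iri)
  invisible(get_individual(doc, cell_iri))
}

#' Specify a movement relationship
#'
#' Describes a tumor behaviour frozen in the slide: the type of movement
#' (e.g. an extension/invasion CURIE), the moving object, and the subject the
#' movement is towards.
#'
#' @param movement_type string or CURIE naming the movement.
#' @param moving_object `PhysicalEntity` individual (or IRI) that moves.
#' @param target `PhysicalEntity` individual (or IRI) moved towards.
#' @return a `histoml_relationship_spec` list.
#' @export
relationship_spec <- function(movement_type, moving_object, target) {
  structure(list(movement_type = movement_type,
                 moving_object = iri_of(moving_object),
                 target = iri_of(target)),
            class = "histoml_relationship_spec")
}

#' Add a phenotype to a document
#'
#' Creates an individual of one of the three `Phenotype` subclasses and links
#' it to each component via `present_Entity`. Movement relationships are
#' materialized as `Relationship` individuals carrying `movementType`,
#' `movingObject` and `towards`.
#'
#' @param doc a `histoml_document`.
#' @param subclass one of `"Cellular_Appearances"`, `"Product_or_Reserve"`,
#'   `"Architectural_Pattern"`.
#' @param components non-empty list of `PhysicalEntity` individuals (or
#'   IRIs).
#' @param relationships list of [relationship_spec()] objects.
#' @param name optional phenotype name.
#' @param xrefs character vector of CURIEs.
#' @return the new phenotype individual.
#' @export
add_phenotype <- function(doc, subclass = c("Cellular_Appearances",
                                            "Product_or_Reserve",
                                            "Architectural_Pattern"),
                          components, relationships = list(),
                          name = NULL, xrefs = character(0)) {
  subclass <- match.arg(subclass)
  if (missing(components) || length(components) == 0L) {
    stop("a phenotype must have at least one component entity")
  }
  comp_iris <- vapply(components, iri_of, character(1))
  for (iri in comp_iris) {
    if (!is_of_class(doc, iri, "PhysicalEntity")) {
      stop("phenotype components must be PhysicalEntity individuals; not: ",
           iri)
    }
  }
  for (rs in relationships) {
    if (!inherits(rs, "histoml_relationship_spec")) {
      stop("relationships must be built with relationship_spec()")
    }
    for (iri in c(rs$moving_object, rs$target)) {
      if (!is_of_class(doc, iri, "PhysicalEntity")) {
        stop("relationship subject/object must be PhysicalEntity ",
             "individuals; not: ", iri)
      }
    }
  }
  for (x in xrefs) {
    if (!is_curie(x)) stop("malformed CURIE (expected PREFIX:LOCALID): ", x)
  }
  ph <- new_individual(doc, subclass)
  if (!is.null(name)) set_value(doc, ph$iri, "name", name)
  for (iri in comp_iris) add_link(doc, ph$iri, "present_Entity", iri)
  for (x in xrefs) link_xref(doc, ph$iri, x)
  for (rs in relationships) {
    rel <- new_individual(doc, "Relationship")
    set_value(doc, rel$iri, "movementType", rs$movement_type)
    add_link(doc, rel$iri, "movingObject", rs$moving_object)
    add_link(doc, rel$iri, "towards", rs$target)
    add_link(doc, ph$iri, "hasRelationship", rel$iri)
  }
  get_individual(doc, ph$iri)
}

# ---- validation ------------------------------------------------------------

empty_report <- function() {
  data.frame(severity = character(), rule = character(), iri = character(),
             message = character(), stringsAsFactors = FALSE)
}

report_row <- function(severity, rule, iri, message) {
  data.frame(severity = severity, rule = rule, iri = iri, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a document against its schema
#'
#' Checks every individual and link: declared classes and properties,
#' domain/range compatibility (with subclass closure), dangling target IRIs,
#' containment acyclicity, CURIE well-formedness, phenotypes having at least
#' one `present_Entity` component, and (as warnings) attributes with neither
#' xref nor quantification.
#'
#' @param doc a `histoml_document`.
#' @return a data frame report with columns `severity` (`"error"` or
#'   `"warning"`), `rule`, `iri`, `message`. A document is valid iff the
#'   report has no `"error"` rows; [document_is_valid()] treats warnings as
#'   acceptable.
#' @export
validate_document <- function(doc) {
  schema <- doc$schema
  rep <- empty_report()
  op <- schema$object_properties
  dp <- schema$datatype_properties
  closure_cache <- list()
  closure <- function(cl) {
    if (is.null(closure_cache[[cl]])) {
      closure_cache[[cl]] <<- subclass_closure(schema, cl)
    }
    closure_cache[[cl]]
  }
  for (ind in doc$individuals) {
    if (!ind$class %in% schema$classes) {
      rep <- rbind(rep, report_row("error", "undeclared-class", ind$iri,
                                   paste0("class '", ind$class,
                                          "' is not in the schema")))
      next
    }
    for (i in seq_len(nrow(ind$links))) {
      prop <- ind$links$property[i]; tgt <- ind$links$target[i]
      row <- which(op$property == prop)
      if (!length(row)) {
        rep <- rbind(rep, report_row("error", "undeclared-property", ind$iri,
                                     paste0("object property '", prop,
                                            "' is not in the schema")))
        next
      }
      dom <- op$domain[row]; rng <- op$range[row]
      if (!is.na(dom) && !ind$class %in% closure(dom)) {
        rep <- rbind(rep, report_row(
          "error", "domain-violation", ind$iri,
          paste0("'", prop, "' requires a ", dom, " subject but ", ind$iri,
                 " is a ", ind$class)))
      }
      tgt_ind <- doc$individuals[[tgt]]
      if (is.null(tgt_ind)) {
        rep <- rbind(rep, report_row("error", "dangling-iri", ind$iri,
                                     paste0("'", prop, "' points at missing ",
                                            "individual ", tgt)))
      } else if (!is.na(rng) && !tgt_ind$class %in% closure(rng)) {
        rep <- rbind(rep, report_row(
          "error", "range-violation", ind$iri,
          paste0("'", prop, "' requires a ", rng, " target but ", tgt,
                 " is a ", tgt_ind$class)))
      }
    }
    for (prop in names(ind$values)) {
      row <- which(dp$property == prop)
      if (!length(row)) {
        rep <- rbind(rep, report_row("error", "undeclared-property", ind$iri,
                                     paste0("datatype property '", prop,
                                            "' is not in the schema")))
        next
      }
      dom <- dp$domain[row]
      if (!is.na(dom) && !ind$class %in% closure(dom)) {
        rep <- rbind(rep, report_row(
          "error", "domain-violation", ind$iri,
          paste0("'", prop, "' requires a ", dom, " subject but ", ind$iri,
                 " is a ", ind$class)))
      }
      if (prop == "xrefId") {
        for (v in ind$values[[prop]]) {
          if (!is_curie(v)) {
            rep <- rbind(rep, report_row("error", "malformed-curie", ind$iri,
                                         paste0("malformed CURIE: ", v)))
          }
        }
      }
    }
    # phenotype completeness
    if (ind$class %in% closure("Phenotype")) {
      if (!"present_Entity" %in% ind$links$property) {
        rep <- rbind(rep, report_row(
          "error", "phenotype-without-component", ind$iri,
          "phenotype has no present_Entity component"))
      }
    }
    # empty attributes are allowed but flagged
    if (ind$class == "EntityAttribute") {
      if (!any(ind$links$property %in% c("hasXref", "hasQuantification"))) {
        rep <- rbind(rep, report_row(
          "warning", "empty-attribute", ind$iri,
          "attribute has neither cross-reference nor quantification"))
      }
    }
  }
  # containment acyclicity
  edges <- containment_edges(doc)
  if (nrow(edges)) {
    ok <- tryCatch({
      assert_acyclic(edges$from, edges$to, "containment graph")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      rep <- rbind(rep, report_row("error", "containment-cycle", NA_character_,
                                   "containment graph contains a cycle"))
    }
  }
  rownames(rep) <- NULL
  rep
}

#' Is a document valid?
#' @param doc a `histoml_document`.
#' @return `TRUE` iff [validate_document()] reports no errors (warnings are
#'   tolerated).
#' @export
document_is_valid <- function(doc) {
  rep <- validate_document(doc)
  !any(rep$severity == "error")
}
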