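# Well-known vocabulary IRIs used throughout the serializers.
RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

RDF_TYPE       <- paste0(RDF_NS, "type")
RDFS_SUBCLASS  <- paste0(RDFS_NS, "subClassOf")
RDFS_SUBPROP   <- paste0(RDFS_NS, "subPropertyOf")
RDFS_DOMAIN    <- paste0(RDFS_NS, "domain")
RDFS_RANGE     <- paste0(RDFS_NS, "range")
OWL_CLASS      <- paste0(OWL_NS, "Class")
OWL_OBJPROP    <- paste0(OWL_NS, "ObjectProperty")
OWL_DATAPROP   <- paste0(OWL_NS, "DatatypeProperty")
OWL_ONTOLOGY   <- paste0(OWL_NS, "Ontology")

#' Default HistoML namespace
#'
#' Base IRI under which the schema's classes and properties live. All schema
#' terms are identified by local names relative to this namespace.
#' @export
HISTOML_NS <- "https://histoml.example/histoml#"

# Registry of CURIE prefixes for the reference vocabularies that xref values
# may point into. Xrefs stay opaque strings; the registry exists only so
# serializations can declare the prefixes.
#' Prefix registry for cross-reference CURIEs
#'
#' Maps the controlled-vocabulary prefixes used in `hasXref` values (NCIt,
#' CMPO, FMA, GO, PATO, UO) to canonical IRI bases. Values are never resolved
#' or fetched; the registry is used only when declaring prefixes in
#' serializations.
#' @export
XREF_PREFIXES <- c(
  NCIt = "http://purl.obolibrary.org/obo/NCIT_",
  CMPO = "http://www.ebi.ac.uk/cmpo/CMPO_",
  FMA  = "http://purl.obolibrary.org/obo/FMA_",
  GO   = "http://purl.obolibrary.org/obo/GO_",
  PATO = "http://purl.obolibrary.org/obo/PATO_",
  UO   = "http://purl.obolibrary.org/obo/UO_"
)

#' Build the HistoML Level 1 schema
#'
#' Constructs the complete Level 1 class and property hierarchy as a
#' [histoml_schema] object. The schema has exactly three root classes --
#' `Entity`, `Utility` and `Data`. `Entity` holds the microscopically
#' observable world: `PhysicalEntity` (cells, cellular components,
#' substances, tissues and anatomical structures, cross-classified into
#' `NormalEntity` and `Tumor`) and `Phenotype` with its three subclasses
#' `Cellular_Appearances`, `Product_or_Reserve` and `Architectural_Pattern`.
#' `Utility` holds the annotation machinery (`EntityReference`,
#' `EntityAttribute`, `Quantification`, `Relationship`, `Xref`) and `Data`
#' holds slide metadata (`WholeSlideImage`).
#'
#' The subclass graph permits multiple parents (e.g. `NeoplasticCell` is both
#' a `Cell` and a `Tumor`); the structural invariant is acyclicity, not
#' tree-ness.
#'
#' @param namespace base IRI for schema terms; terms are `namespace` +
#'   local name.
#' @return an object of class `histoml_schema`.
#' @export
#' @examples
#' s <- build_schema()
#' schema_roots(s)
#' subclass_closure(s, "Phenotype")
build_schema <- function(namespace = HISTOML_NS) {
  sub <- function(child, parent) data.frame(child = child, parent = parent,
                                            stringsAsFactors = FALSE)
  subclass_of <- rbind(
    sub("PhysicalEntity", "Entity"),
    sub("Phenotype", "Entity"),
    # PhysicalEntity groupings: cells, cellular components, substances,
    # tissues and other anatomical structures, plus the normal/tumor axis.
    sub("Cell", "PhysicalEntity"),
    sub("CellularComponent", "PhysicalEntity"),
    sub("Substance", "PhysicalEntity"),
    sub("Tissue", "PhysicalEntity"),
    sub("AnatomicalStructure", "PhysicalEntity"),
    sub("NormalEntity", "PhysicalEntity"),
    sub("Tumor", "PhysicalEntity"),
    # concrete cell types (multi-parent across the normal/tumor axis)
    sub("NeoplasticCell", "Cell"),
    sub("NeoplasticCell", "Tumor"),
    sub("Lymphocyte", "Cell"),
    sub("Lymphocyte", "NormalEntity"),
    sub("Erythrocyte", "Cell"),
    sub("Erythrocyte", "NormalEntity"),
    sub("Endothelium", "Cell"),
    sub("Endothelium", "NormalEntity"),
    # cellular components
    sub("Nucleus", "CellularComponent"),
    sub("Nucleolus", "CellularComponent"),
    sub("CytoplasmicInclusion", "CellularComponent"),
    # granular cytoplasmic inclusions / products and reserves
    sub("Mucin", "Substance"),
    sub("Glycogen", "Substance"),
    # tissues and anatomical structures
    sub("Stroma", "Tissue"),
    sub("Parenchyma", "Tissue"),
    sub("NeoplasticArea", "Tissue"),
    sub("NeoplasticArea", "Tumor"),
    sub("Capillary", "AnatomicalStructure"),
    sub("RenalSinus", "AnatomicalStructure"),
    # phenotype levels
    sub("Cellular_Appearances", "Phenotype"),
    sub("Product_or_Reserve", "Phenotype"),
    sub("Architectural_Pattern", "Phenotype"),
    # utilities
    sub("EntityReference", "Utility"),
    sub("EntityAttribute", "Utility"),
    sub("Quantification", "Utility"),
    sub("Relationship", "Utility"),
    sub("Xref", "Utility"),
    # data / metadata
    sub("WholeSlideImage", "Data")
  )
  classes <- sort(unique(c("Entity", "Utility", "Data",
                           subclass_of$child, subclass_of$parent)))

  op <- function(property, domain, range, parent = NA_character_) {
    data.frame(property = property, domain = domain, range = range,
               parent = parent, stringsAsFactors = FALSE)
  }
  object_properties <- rbind(
    # the four main PhysicalEntity properties
    op("entityReference", "PhysicalEntity", "EntityReference"),
    op("hasAttribute", "PhysicalEntity", "EntityAttribute"),
    op("hasProduct", "PhysicalEntity", "Substance"),
    op("hasComponent", "PhysicalEntity", "PhysicalEntity"),
    # reserves belong to cells
    op("hasReserve", "Cell", "Substance"),
    # the three containment child properties
    op("hasCell", "PhysicalEntity", "Cell", "hasComponent"),
    op("hasCellularComponent", "PhysicalEntity", "CellularComponent",
       "hasComponent"),
    op("hasAnatomicalEntity", "PhysicalEntity", "AnatomicalStructure",
       "hasComponent"),
    # phenotype machinery
    op("present_Entity", "Phenotype", "PhysicalEntity"),
    op("hasRelationship", "Phenotype", "Relationship"),
    op("movingObject", "Relationship", "PhysicalEntity"),
    op("towards", "Relationship", "PhysicalEntity"),
    # annotation
    op("hasXref", NA_character_, "Xref"),
    op("hasQuantification", "EntityAttribute", "Quantification")
  )

  dp <- function(property, domain, type) {
    data.frame(property = property, domain = domain, type = type,
               stringsAsFactors = FALSE)
  }
  datatype_properties <- rbind(
    dp("segmentation", "PhysicalEntity", "string"),
    dp("name", NA_character_, "string"),
    dp("movementType", "Relationship", "string"),
    dp("parameterName", "Quantification", "string"),
    dp("value", "Quantification", "decimal"),
    dp("unit", "Quantification", "string"),
    dp("formula", "Quantification", "string"),
    dp("source", "Quantification", "string"),
    dp("xrefId", "Xref", "string"),
    dp("height", "WholeSlideImage", "integer"),
    dp("width", "WholeSlideImage", "integer"),
    dp("magnification", "WholeSlideImage", "decimal"),
    dp("micronsPerPixel", "WholeSlideImage", "decimal")
  )

  new_schema(namespace, classes, subclass_of, object_properties,
             datatype_properties)
}

#' Construct and validate a schema definition
#'
#' Low-level constructor enforcing the structural invariants: the subclass
#' graph is acyclic and rooted at exactly `Entity`, `Utility` and `Data`;
#' every property domain/range names a declared class (or a literal type).
#'
#' @param namespace base IRI string.
#' @param classes character vector of class local names.
#' @param subclass_of data frame with columns `child`, `parent`.
#' @param object_properties data frame with columns `property`, `domain`,
#'   `range`, `parent` (`NA` domain means unrestricted).
#' @param datatype_properties data frame with columns `property`, `domain`,
#'   `type` (one of `"string"`, `"integer"`, `"decimal"`).
#' @return a `histoml_schema` object.
#' @export
new_schema <- function(namespace, classes, subclass_of, object_properties,
                       datatype_properties) {
  classes <- sort(unique(classes))
  bad <- setdiff(c(subclass_of$child, subclass_of$parent), classes)
  if (length(bad)) {
    stop("subclass axiom mentions undeclared class(es): ",
         paste(bad, collapse = ", "))
  }
  roots <- sort(setdiff(classes, subclass_of$child))
  if (!identical(roots, sort(c("Data", "Entity", "Utility")))) {
    stop("schema must be rooted at exactly {Entity, Utility, Data}; roots ",
         "found: ", paste(roots, collapse = ", "))
  }
  assert_acyclic(subclass_of$child, subclass_of$parent, "subclass graph")
  for (d in stats::na.omit(c(object_properties$domain,
                             object_properties$range,
                             datatype_properties$domain))) {
    if (!d %in% classes) stop("property domain/range names undeclared class: ", d)
  }
  if (!all(datatype_properties$type %in% c("string", "integer", "decimal"))) {
    stop("datatype property type must be string, integer or decimal")
  }
  bad_parent <- setdiff(stats::na.omit(object_properties$parent),
                        object_properties$property)
  if (length(bad_parent)) {
    stop("sub-property parent not declared: ", paste(bad_parent, collapse = ", "))
  }
  ord <- order(subclass_of$child, subclass_of$parent)
  subclass_of <- subclass_of[ord, , drop = FALSE]
  rownames(subclass_of) <- NULL
  object_properties <- object_properties[order(object_properties$property), ,
                                         drop = FALSE]
  rownames(object_properties) <- NULL
  datatype_properties <-
    datatype_properties[order(datatype_properties$property), , drop = FALSE]
  rownames(datatype_properties) <- NULL
  structure(list(namespace = namespace, classes = classes,
                 subclass_of = subclass_of,
                 object_properties = object_properties,
                 datatype_properties = datatype_properties),
            class = "histoml_schema")
}

# Kahn's algorithm; errors if the edge set (from -> to) has a cycle.
assert_acyclic <- function(from, to, what) {
  nodes <- unique(c(from, to))
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  indeg <- table(factor(edges$to, levels = nodes))
  queue <- nodes[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges$to[edges$from == n]
    edges <- edges[edges$from != n, , drop = FALSE]
    for (m in out) {
      if (!m %in% edges$to) queue <- c(queue, m)
    }
  }
  if (seen < length(nodes)) stop(what, " contains a cycle")
  invisible(TRUE)
}

#' @export
print.histoml_schema <- function(x, ...) {
  cat("HistoML Level 1 schema <", x$namespace, ">\n", sep = "")
  cat("  classes:            ", length(x$classes), "\n")
  cat("  subclass axioms:    ", nrow(x$subclass_of), "\n")
  cat("  object properties:  ", nrow(x$object_properties), "\n")
  cat("  datatype properties:", nrow(x$datatype_properties), "\n")
  invisible(x)
}

#' Root classes of a schema
#'
#' @param schema a `histoml_schema`.
#' @return character vector of classes with no parent.
#' @export
schema_roots <- function(schema) {
  sort(setdiff(schema$classes, schema$subclass_of$child))
}

#' Direct subclasses of a class
#'
#' @param schema a `histoml_schema`.
#' @param class_name class local name or full IRI.
#' @return character vector of direct children.
#' @export
direct_subclasses <- function(schema, class_name) {
  class_name <- schema_local(schema, class_name)
  assert_declared_class(schema, class_name)
  sort(schema$subclass_of$child[schema$subclass_of$parent == class_name])
}

#' Subclass closure
#'
#' Returns a class together with all of its descendants under the subclass
#' relation (explicit graph traversal; no OWL reasoning).
#'
#' @param schema a `histoml_schema`.
#' @param class_name class local name or full IRI.
#' @return character vector of local names, sorted.
#' @export
subclass_closure <- function(schema, class_name) {
  class_name <- schema_local(schema, class_name)
  assert_declared_class(schema, class_name)
  out <- class_name
  frontier <- class_name
  while (length(frontier)) {
    kids <- schema$subclass_of$child[schema$subclass_of$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  sort(unique(out))
}

#' Main (top-level) object properties with a given domain
#'
#' Object properties that are not sub-properties and whose declared domain is
#' `class_name`. For `PhysicalEntity` these are its four main properties:
#' `entityReference`, `hasAttribute`, `hasProduct` and `hasComponent`.
#'
#' @param schema a `histoml_schema`.
#' @param class_name domain class local name or IRI.
#' @return character vector of property names, sorted.
#' @export
main_object_properties <- function(schema, class_name) {
  class_name <- schema_local(schema, class_name)
  assert_declared_class(schema, class_name)
  p <- schema$object_properties
  sort(p$property[is.na(p$parent) & !is.na(p$domain) & p$domain == class_name])
}

#' Sub-properties of an object property
#'
#' @param schema a `histoml_schema`.
#' @param property property local name.
#' @return character vector of direct sub-properties, sorted.
#' @export
subproperties_of <- function(schema, property) {
  p <- schema$object_properties
  if (!property %in% p$property) stop("unknown object property: ", property)
  sort(p$property[!is.na(p$parent) & p$parent == property])
}

# ---- IRI helpers -----------------------------------------------------------

schema_iri <- function(schema, local) paste0(schema$namespace, local)

# Accept either a bare local name or a full IRI within the schema namespace.
schema_local <- function(schema, name) {
  ns <- schema$namespace
  ifelse(startsWith(name, ns), substring(name, nchar(ns) + 1L), name)
}

assert_declared_class <- function(schema, class_name) {
  if (!class_name %in% schema$classes) {
    stop("class not declared in schema: ", class_name)
  }
  invisible(TRUE)
}

# ---- schema <-> triples ----------------------------------------------------

schema_to_triples <- function(schema) {
  ns <- schema$namespace
  t <- triple_frame()
  t <- add_triple(t, sub("#$|/$", "", ns), RDF_TYPE, OWL_ONTOLOGY)
  for (cl in schema$classes) {
    t <- add_triple(t, paste0(ns, cl), RDF_TYPE, OWL_CLASS)
  }
  sc <- schema$subclass_of
  for (i in seq_len(nrow(sc))) {
    t <- add_triple(t, paste0(ns, sc$child[i]), RDFS_SUBCLASS,
                    paste0(ns, sc$parent[i]))
  }
  op <- schema$object_properties
  for (i in seq_len(nrow(op))) {
    p <- paste0(ns, op$property[i])
    t <- add_triple(t, p, RDF_TYPE, OWL_OBJPROP)
    if (!is.na(op$domain[i])) t <- add_triple(t, p, RDFS_DOMAIN,
                                              paste0(ns, op$domain[i]))
    if (!is.na(op$range[i])) t <- add_triple(t, p, RDFS_RANGE,
                                             paste0(ns, op$range[i]))
    if (!is.na(op$parent[i])) t <- add_triple(t, p, RDFS_SUBPROP,
                                              paste0(ns, op$parent[i]))
  }
  dp <- schema$datatype_properties
  for (i in seq_len(nrow(dp))) {
    p <- paste0(ns, dp$property[i])
    t <- add_triple(t, p, RDF_TYPE, OWL_DATAPROP)
    if (!is.na(dp$domain[i])) t <- add_triple(t, p, RDFS_DOMAIN,
                                              paste0(ns, dp$domain[i]))
    t <- add_triple(t, p, RDFS_RANGE, paste0(XSD_NS, dp$type[i]))
  }
  t
}

triples_to_schema <- function(triples, namespace) {
  strip <- function(x) sub(paste0("^", namespace), "", x)
  is_local <- function(x) startsWith(x, namespace)
  tp <- triples[triples$p == RDF_TYPE, , drop = FALSE]
  classes <- strip(tp$s[tp$o == OWL_CLASS & is_local(tp$s)])
  sc <- triples[triples$p == RDFS_SUBCLASS, , drop = FALSE]
  subclass_of <- data.frame(child = strip(sc$s), parent = strip(sc$o),
                            stringsAsFactors = FALSE)
  dom <- triples[triples$p == RDFS_DOMAIN, , drop = FALSE]
  rng <- triples[triples$p == RDFS_RANGE, , drop = FALSE]
  par <- triples[triples$p == RDFS_SUBPROP, , drop = FALSE]
  lookup <- function(df, s) {
    v <- df$o[df$s == s]
    if (length(v)) v[[1]] else NA_character_
  }
  op_iris <- tp$s[tp$o == OWL_OBJPROP]
  object_properties <- do.call(rbind, lapply(op_iris, function(p) {
    d <- lookup(dom, p); r <- lookup(rng, p); pa <- lookup(par, p)
    data.frame(property = strip(p),
               domain = if (is.na(d)) d else strip(d),
               range = if (is.na(r)) r else strip(r),
               parent = if (is.na(pa)) pa else strip(pa),
               stringsAsFactors = FALSE)
  }))
  dp_iris <- tp$s[tp$o == OWL_DATAPROP]
  datatype_properties <- do.call(rbind, lapply(dp_iris, function(p) {
    d <- lookup(dom, p); r <- lookup(rng, p)
    data.frame(property = strip(p),
               domain = if (is.na(d)) d else strip(d),
               type = sub(paste0("^", XSD_NS), "", r),
               stringsAsFactors = FALSE)
  }))
  new_schema(namespace, classes, subclass_of, object_properties,
             datatype_properties)
}

#' Export a schema as an OWL file
#'
#' Writes the schema's class and property axioms as OWL (`owl:Class`,
#' `rdfs:subClassOf`, `owl:ObjectProperty`/`owl:DatatypeProperty` with
#' `rdfs:domain`/`rdfs:range`/`rdfs:subPropertyOf`) in Turtle or RDF/XML.
#' `import_schema()` reverses the operation; export followed by import is the
#' identity.
#'
#' @param schema a `histoml_schema`.
#' @param path output file path.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @return `path`, invisibly.
#' @export
export_schema <- function(schema, path, dialect = c("turtle", "rdfxml")) {
  dialect <- match.arg(dialect)
  triples <- schema_to_triples(schema)
  prefixes <- c(histo = schema$namespace, rdf = RDF_NS, rdfs = RDFS_NS,
                owl = OWL_NS, xsd = XSD_NS)
  write_triples(triples, path, dialect, prefixes)
  invisible(path)
}

#' Import a schema from an OWL file
#'
#' @param path file written by [export_schema()] (Turtle or RDF/XML;
#'   auto-detected from content).
#' @param namespace base IRI of the schema terms.
#' @return a `histoml_schema`.
#' @export
import_schema <- function(path, namespace = HISTOML_NS) {
  triples_to_schema(read_triples(path), namespace)
}

#' Compare two schema definitions
#'
#' @param a,b `histoml_schema` objects.
#' @return `TRUE` iff namespaces, class sets and all axiom tables agree.
#' @export
schemas_equal <- function(a, b) {
  isTRUE(all.equal(a$namespace, b$namespace)) &&
    identical(a$classes, b$classes) &&
    identical(a$subclass_of, b$subclass_of) &&
    identical(a$object_properties, b$object_properties) &&
    identical(a$datatype_properties, b$datatype_properties)
}
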