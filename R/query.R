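# Canned queries over HistoML documents. Each is phrased as SPARQL against
# the document's triples; subclass inference is performed by expanding class
# IRIs to their subclass closure at query-build time (VALUES block), so no
# reasoner is involved and results are deterministic.

histo_prefix_header <- function(doc) {
  paste0("PREFIX histo: <", doc$schema$namespace, ">\n")
}

values_block <- function(var, iris) {
  paste0("VALUES ?", var, " { ",
         paste0("<", iris, ">", collapse = " "), " }")
}

#' Component entities of a phenotype
#'
#' Returns the physical entities a phenotype presents via `present_Entity`;
#' with `include_contained = TRUE` the containment closure (`hasComponent`
#' and its child properties) of those entities is included as well.
#'
#' @param doc a `histoml_document`.
#' @param phenotype_iri IRI of a `Phenotype` individual.
#' @param include_contained also descend through containment links.
#' @return character vector of individual IRIs, sorted.
#' @export
components_of_phenotype <- function(doc, phenotype_iri,
                                    include_contained = FALSE) {
  phenotype_iri <- iri_of(phenotype_iri)
  if (!is_of_class(doc, phenotype_iri, "Phenotype")) {
    stop("not a Phenotype individual: ", phenotype_iri)
  }
  res <- run_sparql(doc, paste0(
    histo_prefix_header(doc),
    "SELECT ?c WHERE { <", phenotype_iri, "> histo:present_Entity ?c }"))
  out <- res$c
  if (include_contained && length(out)) {
    out <- union(out, contained_entities(doc, out))
  }
  sort(unique(out))
}

# Containment transitive closure below `iris`, computed by iterated
# single-step SPARQL queries over hasComponent and its sub-properties.
contained_entities <- function(doc, iris) {
  props <- containment_properties(doc$schema)
  ns <- doc$schema$namespace
  seen <- character(0)
  frontier <- iris
  while (length(frontier)) {
    step <- character(0)
    for (prop in props) {
      res <- run_sparql(doc, paste0(
        histo_prefix_header(doc),
        "SELECT ?child WHERE { ?parent histo:", prop, " ?child . ",
        values_block("parent", frontier), " }"))
      step <- union(step, res$child)
    }
    frontier <- setdiff(step, seen)
    seen <- union(seen, frontier)
  }
  sort(seen)
}

#' Entities of a class inside a container
#'
#' Retrieves the individuals of `class_name` (or any of its subclasses) that
#' lie in the containment transitive closure of `container_iri` -- e.g. the
#' lymphocytes within a stromal component.
#'
#' @param doc a `histoml_document`.
#' @param container_iri IRI of a `PhysicalEntity` individual.
#' @param class_name class local name (subclass closure is applied).
#' @return character vector of individual IRIs, sorted.
#' @export
entities_within <- function(doc, container_iri, class_name) {
  container_iri <- iri_of(container_iri)
  if (!is_of_class(doc, container_iri, "PhysicalEntity")) {
    stop("container must be a PhysicalEntity individual: ", container_iri)
  }
  class_name <- schema_local(doc$schema, class_name)
  classes <- subclass_closure(doc$schema, class_name)  # errors if undeclared
  inside <- contained_entities(doc, container_iri)
  if (!length(inside)) return(character(0))
  ns <- doc$schema$namespace
  res <- run_sparql(doc, paste0(
    histo_prefix_header(doc),
    "SELECT ?e WHERE { ?e a ?cls . ",
    values_block("e", inside), " ",
    values_block("cls", paste0(ns, classes)), " }"))
  sort(unique(res$e))
}

#' Segmentation identifiers of individuals
#'
#' @param doc a `histoml_document`.
#' @param iris character vector of individual IRIs.
#' @return named list mapping each IRI to its (possibly empty) character
#'   vector of `segmentation` data values.
#' @export
segmentations_of <- function(doc, iris) {
  iris <- vapply(iris, iri_of, character(1), USE.NAMES = FALSE)
  out <- stats::setNames(vector("list", length(iris)), iris)
  if (length(iris)) {
    res <- run_sparql(doc, paste0(
      histo_prefix_header(doc),
      "SELECT ?e ?sid WHERE { ?e histo:segmentation ?sid . ",
      values_block("e", iris), " }"))
    for (iri in iris) {
      out[[iri]] <- sort(res$sid[res$e == iri])
    }
  }
  out
}
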