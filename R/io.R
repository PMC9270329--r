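# OWL serialization of documents. Every individual gets one rdf:type triple,
# one triple per object link and one per data value; numeric literals are
# typed (xsd:integer for counts, xsd:decimal for measured values), strings
# are plain literals. Output ordering is canonical, so serialization is
# deterministic and files diff cleanly.

#' Serialization configuration
#'
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @param embed_schema whether the schema axioms are written alongside the
#'   individuals.
#' @param prefix_map named character vector mapping CURIE prefixes to IRI
#'   bases, merged over the defaults (histo/rdf/xsd plus [XREF_PREFIXES]).
#' @return a `histoml_serialization_config` list.
#' @export
serialization_config <- function(dialect = c("turtle", "rdfxml"),
                                 embed_schema = FALSE,
                                 prefix_map = character(0)) {
  dialect <- match.arg(dialect)
  structure(list(dialect = dialect, embed_schema = isTRUE(embed_schema),
                 prefix_map = prefix_map),
            class = "histoml_serialization_config")
}

document_prefixes <- function(doc, config) {
  base <- c(histo = doc$schema$namespace, rdf = RDF_NS, xsd = XSD_NS)
  if (isTRUE(config$embed_schema)) {
    base <- c(base, rdfs = RDFS_NS, owl = OWL_NS)
  }
  extra <- config$prefix_map
  for (p in names(extra)) base[[p]] <- extra[[p]]
  base
}

xsd_lexical <- function(value, type) {
  switch(type,
         string = list(lex = as.character(value), dt = NA_character_),
         integer = list(lex = format_integer(value),
                        dt = paste0(XSD_NS, "integer")),
         decimal = list(lex = format_decimal(value),
                        dt = paste0(XSD_NS, "decimal")),
         stop("unknown literal type: ", type))
}

document_to_triples <- function(doc) {
  schema <- doc$schema
  ns <- schema$namespace
  dp <- schema$datatype_properties
  t <- list()
  k <- 0L
  push <- function(s, p, o, lit = FALSE, dt = NA_character_) {
    k <<- k + 1L
    t[[k]] <<- list(s = s, p = p, o = o, lit = lit, dt = dt)
  }
  for (ind in doc$individuals) {
    push(ind$iri, RDF_TYPE, paste0(ns, ind$class))
    for (i in seq_len(nrow(ind$links))) {
      push(ind$iri, paste0(ns, ind$links$property[i]), ind$links$target[i])
    }
    for (prop in names(ind$values)) {
      type <- dp$type[dp$property == prop]
      if (!length(type)) type <- "string"
      for (v in ind$values[[prop]]) {
        lx <- xsd_lexical(v, type)
        push(ind$iri, paste0(ns, prop), lx$lex, lit = TRUE, dt = lx$dt)
      }
    }
  }
  if (!k) return(triple_frame())
  data.frame(
    s = vapply(t, `[[`, character(1), "s"),
    p = vapply(t, `[[`, character(1), "p"),
    o = vapply(t, `[[`, character(1), "o"),
    lit = vapply(t, `[[`, logical(1), "lit"),
    dt = vapply(t, `[[`, character(1), "dt"),
    stringsAsFactors = FALSE)
}

#' Write a document as OWL
#'
#' Refuses to write documents with validation errors. The file contains one
#' triple per individual type, object link and data value; with
#' `embed_schema = TRUE` the schema axioms are appended so the file is
#' self-contained.
#'
#' @param doc a `histoml_document`.
#' @param path output path.
#' @param config a [serialization_config()]; alternatively pass `dialect`
#'   directly.
#' @param dialect shorthand used when `config` is missing.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path, config = NULL,
                           dialect = c("turtle", "rdfxml")) {
  if (is.null(config)) config <- serialization_config(match.arg(dialect))
  rep <- validate_document(doc)
  if (any(rep$severity == "error")) {
    stop("refusing to write invalid document; first violation: ",
         rep$message[rep$severity == "error"][[1]])
  }
  triples <- document_to_triples(doc)
  if (isTRUE(config$embed_schema)) {
    triples <- rbind(triples, schema_to_triples(doc$schema))
  }
  write_triples(triples, path, config$dialect,
                document_prefixes(doc, config))
  invisible(path)
}

#' Read a document from an OWL file
#'
#' Rebuilds a `histoml_document` from a file written by [write_document()]
#' (either dialect, auto-detected). Individuals of classes or with properties
#' not declared in the schema are not silently dropped: they are collected
#' into an `unknown_report` attribute (a data frame like the one from
#' [validate_document()]) and their triples are carried into the document so
#' validation can point at them.
#'
#' @param path input path.
#' @param schema the schema to bind the document to.
#' @return a `histoml_document`; inspect `attr(doc, "unknown_report")` for
#'   unknown classes/properties.
#' @export
read_document <- function(path, schema = build_schema()) {
  triples <- read_triples(path)
  triples_to_document(triples, schema)
}

triples_to_document <- function(triples, schema) {
  ns <- schema$namespace
  unknown <- empty_report()
  # ignore any embedded schema axioms
  schema_subjects <- triples$s[triples$p == RDF_TYPE &
                                 triples$o %in% c(OWL_CLASS, OWL_OBJPROP,
                                                  OWL_DATAPROP, OWL_ONTOLOGY)]
  triples <- triples[!triples$s %in% schema_subjects &
                       !triples$p %in% c(RDFS_SUBCLASS, RDFS_SUBPROP,
                                         RDFS_DOMAIN, RDFS_RANGE), ,
                     drop = FALSE]
  type_rows <- triples[triples$p == RDF_TYPE, , drop = FALSE]
  subjects <- unique(triples$s)
  doc <- new.env(parent = emptyenv())
  doc$schema <- schema
  doc$individuals <- list()
  doc$counters <- list()
  doc$xref_index <- character(0)
  class(doc) <- "histoml_document"
  dp <- schema$datatype_properties
  for (s in subjects) {
    cls_iri <- type_rows$o[type_rows$s == s]
    if (!length(cls_iri)) {
      unknown <- rbind(unknown, report_row("error", "untyped-individual", s,
                                           "individual has no rdf:type"))
      next
    }
    cls <- schema_local(schema, cls_iri[[1]])
    if (!cls %in% schema$classes) {
      unknown <- rbind(unknown, report_row(
        "error", "unknown-class", s,
        paste0("individual of undeclared class ", cls_iri[[1]])))
    }
    rows <- triples[triples$s == s & triples$p != RDF_TYPE, , drop = FALSE]
    links <- data.frame(property = character(), target = character(),
                        stringsAsFactors = FALSE)
    values <- list()
    for (i in seq_len(nrow(rows))) {
      prop <- schema_local(schema, rows$p[i])
      if (rows$lit[i]) {
        type <- dp$type[dp$property == prop]
        if (!length(type)) {
          unknown <- rbind(unknown, report_row(
            "error", "unknown-property", s,
            paste0("undeclared datatype property ", rows$p[i])))
          type <- "string"
        }
        v <- if (type == "integer") as.integer(rows$o[i])
             else if (type == "decimal") as.numeric(rows$o[i])
             else rows$o[i]
        values[[prop]] <- c(values[[prop]], v)
      } else {
        if (!prop %in% schema$object_properties$property) {
          unknown <- rbind(unknown, report_row(
            "error", "unknown-property", s,
            paste0("undeclared object property ", rows$p[i])))
        }
        links <- rbind(links, data.frame(property = prop, target = rows$o[i],
                                         stringsAsFactors = FALSE))
      }
    }
    doc$individuals[[s]] <- list(iri = s, class = cls, links = links,
                                 values = values)
  }
  # restore deterministic IRI counters and the xref index so further
  # building continues the numbering
  for (ind in doc$individuals) {
    m <- regmatches(ind$iri, regexec("/([A-Za-z_]+)_([0-9]+)$", ind$iri))[[1]]
    if (length(m) == 3L) {
      cl <- m[[2]]; n <- as.integer(m[[3]])
      doc$counters[[cl]] <- max(doc$counters[[cl]] %||% 0L, n)
    }
    if (ind$class == "Xref" && !is.null(ind$values$xrefId)) {
      doc$xref_index[ind$values$xrefId[[1]]] <- ind$iri
    }
  }
  # base iri / slide id from the WholeSlideImage individual when present
  slide <- names(doc$individuals)[vapply(doc$individuals, `[[`, character(1),
                                         "class") == "WholeSlideImage"]
  if (length(slide)) {
    m <- regmatches(slide[[1]],
                    regexec("^(.*[/#])([^/#]+)/WholeSlideImage_[0-9]+$",
                            slide[[1]]))[[1]]
    if (length(m) == 3L) {
      doc$base_iri <- m[[2]]
      doc$slide_id <- m[[3]]
    }
  }
  if (is.null(doc$base_iri)) {
    doc$base_iri <- "https://histoml.example/wsi/"
    doc$slide_id <- "slide1"
  }
  if (nrow(unknown)) attr(doc, "unknown_report") <- unknown
  doc
}

#' Compare two documents as RDF graphs
#'
#' Two documents are equal iff their triple sets (types, object links, data
#' values, metadata) are identical. All nodes are named (no blank nodes), so
#' this is plain set comparison of canonical triples.
#'
#' @param a,b `histoml_document` objects.
#' @return `TRUE` or `FALSE`.
#' @export
documents_equal <- function(a, b) {
  triples_equal(document_to_triples(a), document_to_triples(b))
}
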