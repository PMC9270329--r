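# Randomized valid documents built through the public builder API, plus
# pure graph-traversal oracles used to cross-check the SPARQL-backed
# queries and the validator.

random_document <- function(seed, max_individuals = 50L) {
  set.seed(seed)
  doc <- new_document(slide_metadata(sample(500:5000, 1), sample(500:5000, 1),
                                     sample(c(10, 20, 40), 1)),
                      slide_id = paste0("rand", seed))
  n_tissues <- sample(1:4, 1)
  tissues <- lapply(seq_len(n_tissues), function(i) {
    add_physical_entity(doc, sample(c("Stroma", "Parenchyma", "Tissue"), 1),
                        segmentation_ids = paste0("seg:t", seed, "_", i),
                        name = paste0("tissue_", i))
  })
  # tissue-to-tissue containment only from earlier to later index: acyclic
  if (n_tissues >= 2) {
    for (i in seq_len(n_tissues - 1L)) {
      later <- (i + 1L):n_tissues
      j <- later[sample.int(length(later), 1L)]
      if (stats::runif(1) < 0.6) {
        link_component(doc, tissues[[i]], tissues[[j]], "hasComponent")
      }
    }
  }
  ref <- NULL
  if (stats::runif(1) < 0.7) ref <- add_entity_reference(doc, "generic cell",
                                                         xrefs = "NCIt:C12508")
  n_cells <- sample(0:12, 1)
  cells <- lapply(seq_len(n_cells), function(i) {
    cl <- sample(c("Lymphocyte", "NeoplasticCell", "Erythrocyte",
                   "Endothelium"), 1)
    ce <- add_physical_entity(
      doc, cl,
      entity_reference = if (!is.null(ref) && stats::runif(1) < 0.5) ref,
      segmentation_ids = if (stats::runif(1) < 0.8) paste0("seg:c", i)
                         else character(0))
    link_component(doc, tissues[[sample(n_tissues, 1)]], ce, "hasCell")
    ce
  })
  if (n_cells > 0 && stats::runif(1) < 0.5) {
    sub <- add_physical_entity(doc, "Mucin", name = "mucin")
    add_product_or_reserve(doc, cells[[sample(n_cells, 1)]], sub,
                           sample(c("hasProduct", "hasReserve"), 1))
  }
  for (k in seq_len(sample(0:3, 1))) {
    ent <- if (n_cells && stats::runif(1) < 0.5) cells[[sample(n_cells, 1)]]
           else tissues[[sample(n_tissues, 1)]]
    attach_attribute(doc, ent, paste0("attr_", k),
                     xrefs = if (stats::runif(1) < 0.5) "PATO:0000001"
                             else character(0),
                     quantifications = if (stats::runif(1) < 0.7) list(
                       quantification("area", stats::runif(1, 10, 1e4), "px"))
                     else list())
  }
  comps <- tissues
  rels <- list()
  if (n_cells >= 2 && stats::runif(1) < 0.3) {
    rels <- list(relationship_spec("NCIt:C20625", cells[[1]], cells[[2]]))
  }
  add_phenotype(doc, sample(c("Architectural_Pattern", "Cellular_Appearances",
                              "Product_or_Reserve"), 1),
                components = comps, relationships = rels,
                name = "random phenotype")
  stopifnot(n_individuals(doc) <= max_individuals)
  doc
}

# edge-scan traversal oracles ------------------------------------------------

doc_edges <- function(doc, properties) {
  from <- character(0); prop <- character(0); to <- character(0)
  for (iri in individual_iris(doc)) {
    ind <- get_individual(doc, iri)
    for (i in seq_len(nrow(ind$links))) {
      if (ind$links$property[i] %in% properties) {
        from <- c(from, iri); prop <- c(prop, ind$links$property[i])
        to <- c(to, ind$links$target[i])
      }
    }
  }
  data.frame(from = from, property = prop, to = to, stringsAsFactors = FALSE)
}

oracle_reachable <- function(edges, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

oracle_components_of_phenotype <- function(doc, ph_iri,
                                           include_contained = FALSE) {
  direct <- sort(doc_edges(doc, "present_Entity") |>
                   (\(e) e$to[e$from == ph_iri])())
  if (!include_contained) return(direct)
  cont <- doc_edges(doc, c("hasComponent", "hasCell", "hasCellularComponent",
                           "hasAnatomicalEntity"))
  sort(union(direct, oracle_reachable(cont, direct)))
}

oracle_entities_within <- function(doc, container, class_name) {
  cont <- doc_edges(doc, c("hasComponent", "hasCell", "hasCellularComponent",
                           "hasAnatomicalEntity"))
  inside <- oracle_reachable(cont, container)
  keep <- subclass_closure(doc$schema, class_name)
  sort(inside[vapply(inside, function(i) {
    get_individual(doc, i)$class %in% keep
  }, logical(1))])
}

oracle_segmentations <- function(doc, iris) {
  out <- stats::setNames(vector("list", length(iris)), iris)
  for (iri in iris) {
    v <- get_individual(doc, iri)$values$segmentation
    out[[iri]] <- sort(if (is.null(v)) character(0) else v)
  }
  out
}

# naive triple-by-triple validator: checks the same rules as
# validate_document with plain loops and recursion
oracle_validation_errors <- function(doc) {
  schema <- doc$schema
  descendants <- function(cl) {
    out <- cl
    repeat {
      kids <- schema$subclass_of$child[schema$subclass_of$parent %in% out]
      new <- setdiff(kids, out)
      if (!length(new)) break
      out <- c(out, new)
    }
    out
  }
  n_err <- 0L
  for (iri in names(doc$individuals)) {
    ind <- doc$individuals[[iri]]
    if (!ind$class %in% schema$classes) {
      n_err <- n_err + 1L
      next
    }
    if (nrow(ind$links)) {
      for (i in seq_len(nrow(ind$links))) {
        p <- ind$links$property[i]
        trg <- ind$links$target[i]
        row <- schema$object_properties[
          schema$object_properties$property == p, ]
        if (nrow(row) == 0L) { n_err <- n_err + 1L; next }
        if (!is.na(row$domain) && !ind$class %in% descendants(row$domain)) {
          n_err <- n_err + 1L
        }
        ti <- doc$individuals[[trg]]
        if (is.null(ti)) n_err <- n_err + 1L
        else if (!is.na(row$range) && !ti$class %in% descendants(row$range)) {
          n_err <- n_err + 1L
        }
      }
    }
    for (p in names(ind$values)) {
      row <- schema$datatype_properties[
        schema$datatype_properties$property == p, ]
      if (nrow(row) == 0L) { n_err <- n_err + 1L; next }
      if (!is.na(row$domain) && !ind$class %in% descendants(row$domain)) {
        n_err <- n_err + 1L
      }
      if (p == "xrefId") {
        for (v in ind$values[[p]]) {
          if (!grepl("^[A-Za-z][A-Za-z0-9]*:[^[:space:]]+$", v)) {
            n_err <- n_err + 1L
          }
        }
      }
    }
    if (ind$class %in% descendants("Phenotype") &&
        !"present_Entity" %in% ind$links$property) {
      n_err <- n_err + 1L
    }
  }
  n_err
}
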