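# Minimal RDF triple machinery.
#
# Triples live in a data frame with columns:
#   s  subject IRI
#   p  predicate IRI
#   o  object: IRI, or literal lexical form
#   lit  TRUE when o is a literal
#   dt   datatype IRI for typed literals, NA for plain strings / IRIs
#
# Blank nodes are deliberately unsupported: every node is named, which makes
# document equality plain set comparison and keeps SPARQL results stable.

triple_frame <- function() {
  data.frame(s = character(), p = character(), o = character(),
             lit = logical(), dt = character(), stringsAsFactors = FALSE)
}

add_triple <- function(t, s, p, o, lit = FALSE, dt = NA_character_) {
  rbind(t, data.frame(s = s, p = p, o = o, lit = lit, dt = dt,
                      stringsAsFactors = FALSE))
}

# Canonical one-string form of each triple, used for equality and sorting.
triple_keys <- function(t) {
  obj <- ifelse(t$lit,
                paste0("\"", t$o, "\"",
                       ifelse(is.na(t$dt), "", paste0("^^<", t$dt, ">"))),
                paste0("<", t$o, ">"))
  paste0("<", t$s, "> <", t$p, "> ", obj)
}

sort_triples <- function(t) {
  # rdf:type first within a subject so serializations read naturally
  ord <- order(t$s, t$p != RDF_TYPE, t$p, t$lit, t$o, method = "radix")
  t <- t[ord, , drop = FALSE]
  rownames(t) <- NULL
  t
}

triples_equal <- function(a, b) {
  setequal(triple_keys(a), triple_keys(b))
}

# Canonical lexical forms for numeric literals: integers for counts,
# plain (non-scientific) decimals for measured values.
format_integer <- function(x) formatC(as.integer(x), format = "d")
format_decimal <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}

escape_turtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_turtle <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- ""
    j <- 1L
    n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- paste0(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- res
  }
  out
}

# ---- Turtle ----------------------------------------------------------------

# Compact an IRI to pfx:local when a registered prefix matches and the local
# part is a safe prefixed name; otherwise <iri>.
turtle_term_iri <- function(iri, prefixes) {
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    if (startsWith(iri, base)) {
      local <- substring(iri, nchar(base) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

write_turtle <- function(triples, path, prefixes) {
  triples <- sort_triples(triples)
  header <- vapply(names(prefixes), function(p) {
    paste0("@prefix ", p, ": <", prefixes[[p]], "> .")
  }, character(1))
  obj <- character(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    if (triples$lit[i]) {
      o <- paste0("\"", escape_turtle(triples$o[i]), "\"")
      if (!is.na(triples$dt[i])) {
        o <- paste0(o, "^^", turtle_term_iri(triples$dt[i], prefixes))
      }
      obj[i] <- o
    } else {
      obj[i] <- turtle_term_iri(triples$o[i], prefixes)
    }
  }
  pred <- ifelse(triples$p == RDF_TYPE, "a",
                 vapply(triples$p, turtle_term_iri, character(1),
                        prefixes = prefixes))
  subj <- vapply(triples$s, turtle_term_iri, character(1),
                 prefixes = prefixes)
  lines <- c(header, "", paste(subj, pred, obj, "."))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Tokenizer for the Turtle subset the writer emits (plus ';'/',' statement
# continuation, comments and bare numeric literals, for leniency).
tokenize_turtle <- function(text) {
  pats <- c(
    ws      = "^[ \t\r\n]+",
    comment = "^#[^\n]*",
    iriref  = "^<[^<>\"{}|^`\\\\ ]*>",
    string  = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    dcaret  = "^\\^\\^",
    prefix  = "^@prefix\\b",
    base    = "^@base\\b",
    lang    = "^@[A-Za-z][A-Za-z0-9-]*",
    pname   = "^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_]?[A-Za-z0-9_-]*",
    number  = "^[+-]?[0-9]+(?:\\.[0-9]+)?",
    kw_a    = "^a(?![A-Za-z0-9_:-])",
    punct   = "^[.;,]"
  )
  pos <- 1L
  n <- nchar(text)
  types <- character(0)
  vals <- character(0)
  offs <- integer(0)
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m) && nchar(m)) {
        if (!ty %in% c("ws", "comment")) {
          types <- c(types, ty); vals <- c(vals, m); offs <- c(offs, pos)
        }
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("Turtle parse error at character ", pos, ": unexpected '",
           substr(text, pos, pos + 20L), "'")
    }
  }
  list(types = types, vals = vals, offs = offs)
}

parse_turtle <- function(text) {
  tk <- tokenize_turtle(text)
  i <- 1L
  ntok <- length(tk$types)
  prefixes <- character(0)
  triples <- list()
  peek <- function() if (i <= ntok) tk$types[[i]] else "eof"
  fail <- function(msg) {
    off <- if (i <= ntok) tk$offs[[i]] else nchar(text)
    stop("Turtle parse error at character ", off, ": ", msg)
  }
  take <- function(ty = NULL, val = NULL) {
    if (i > ntok) fail("unexpected end of input")
    if (!is.null(ty) && tk$types[[i]] != ty) {
      fail(paste0("expected ", ty, ", got '", tk$vals[[i]], "'"))
    }
    if (!is.null(val) && tk$vals[[i]] != val) {
      fail(paste0("expected '", val, "'"))
    }
    v <- tk$vals[[i]]
    i <<- i + 1L
    v
  }
  resolve_pname <- function(v) {
    colon <- regexpr(":", v, fixed = TRUE)
    pfx <- substr(v, 1L, colon - 1L)
    local <- substring(v, colon + 1L)
    if (!pfx %in% names(prefixes)) fail(paste0("undeclared prefix '", pfx, ":'"))
    paste0(prefixes[[pfx]], local)
  }
  # returns list(value, lit, dt)
  term <- function() {
    ty <- peek()
    if (ty == "iriref") {
      v <- take()
      list(value = substr(v, 2L, nchar(v) - 1L), lit = FALSE, dt = NA_character_)
    } else if (ty == "pname") {
      list(value = resolve_pname(take()), lit = FALSE, dt = NA_character_)
    } else if (ty == "kw_a") {
      take()
      list(value = RDF_TYPE, lit = FALSE, dt = NA_character_)
    } else if (ty == "string") {
      v <- take()
      str <- unescape_turtle(substr(v, 2L, nchar(v) - 1L))
      dt <- NA_character_
      if (peek() == "dcaret") {
        take()
        dtty <- peek()
        if (dtty == "iriref") {
          dv <- take(); dt <- substr(dv, 2L, nchar(dv) - 1L)
        } else if (dtty == "pname") {
          dt <- resolve_pname(take())
        } else fail("expected datatype IRI after ^^")
      } else if (peek() == "lang") {
        take()  # language tags accepted, stored as plain
      }
      list(value = str, lit = TRUE, dt = dt)
    } else if (ty == "number") {
      v <- take()
      dt <- if (grepl("\\.", v)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      list(value = v, lit = TRUE, dt = dt)
    } else {
      fail(paste0("expected RDF term, got ",
                  if (i <= ntok) paste0("'", tk$vals[[i]], "'") else "end"))
    }
  }
  while (i <= ntok) {
    if (peek() == "prefix") {
      take()
      pn <- take("pname")
      pfx <- sub(":$", "", pn)
      if (!grepl(":$", pn)) fail("malformed @prefix declaration")
      iri <- take("iriref")
      prefixes[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
      take("punct", ".")
      next
    }
    subj <- term()
    if (subj$lit) fail("literal cannot be a subject")
    repeat {
      pred <- term()
      if (pred$lit) fail("literal cannot be a predicate")
      repeat {
        obj <- term()
        triples[[length(triples) + 1L]] <-
          list(s = subj$value, p = pred$value, o = obj$value,
               lit = obj$lit, dt = obj$dt)
        if (peek() == "punct" && tk$vals[[i]] == ",") take() else break
      }
      if (peek() == "punct" && tk$vals[[i]] == ";") {
        take()
        # tolerate trailing ';' before '.'
        if (peek() == "punct" && tk$vals[[i]] == ".") break
      } else break
    }
    take("punct", ".")
  }
  if (length(triples) == 0L) return(triple_frame())
  out <- data.frame(
    s = vapply(triples, `[[`, character(1), "s"),
    p = vapply(triples, `[[`, character(1), "p"),
    o = vapply(triples, `[[`, character(1), "o"),
    lit = vapply(triples, `[[`, logical(1), "lit"),
    dt = vapply(triples, `[[`, character(1), "dt"),
    stringsAsFactors = FALSE)
  out
}

# ---- RDF/XML ---------------------------------------------------------------

# Split an IRI into (namespace, local) at the last '#' or '/'.
split_iri <- function(iri) {
  m <- regexpr("[#/][^#/]*$", iri)
  if (m < 0) stop("cannot split IRI into namespace and local name: ", iri)
  list(ns = substr(iri, 1L, m), local = substring(iri, m + 1L))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}
xml_escape_attr <- function(x) {
  x <- xml_escape(x)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

write_rdfxml <- function(triples, path, prefixes) {
  triples <- sort_triples(triples)
  # namespace table: well-known prefixes first, then any others that appear
  # as predicate namespaces
  nss <- c(rdf = RDF_NS, prefixes[!names(prefixes) %in% "rdf"])
  pred_ns <- vapply(unique(triples$p),
                    function(p) split_iri(p)$ns, character(1))
  extra <- setdiff(unique(pred_ns), unname(nss))
  if (length(extra)) {
    names(extra) <- paste0("ns", seq_along(extra))
    nss <- c(nss, extra)
  }
  pfx_of <- function(ns) names(nss)[match(ns, nss)]
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<rdf:RDF",
                    paste0(vapply(names(nss), function(p) {
                      paste0(" xmlns:", p, "=\"", nss[[p]], "\"")
                    }, character(1)), collapse = ""),
                    ">"))
  for (s in unique(triples$s)) {
    rows <- triples[triples$s == s, , drop = FALSE]
    lines <- c(lines, paste0("  <rdf:Description rdf:about=\"",
                             xml_escape_attr(s), "\">"))
    for (i in seq_len(nrow(rows))) {
      pp <- split_iri(rows$p[i])
      qn <- paste0(pfx_of(pp$ns), ":", pp$local)
      if (rows$lit[i]) {
        dtattr <- if (!is.na(rows$dt[i])) {
          paste0(" rdf:datatype=\"", xml_escape_attr(rows$dt[i]), "\"")
        } else ""
        lines <- c(lines, paste0("    <", qn, dtattr, ">",
                                 xml_escape(rows$o[i]), "</", qn, ">"))
      } else {
        lines <- c(lines, paste0("    <", qn, " rdf:resource=\"",
                                 xml_escape_attr(rows$o[i]), "\"/>"))
      }
    }
    lines <- c(lines, "  </rdf:Description>")
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_rdfxml <- function(text_or_path, is_path = TRUE) {
  x <- if (is_path) xml2::read_xml(text_or_path) else
    xml2::read_xml(charToRaw(text_or_path))
  nsmap <- xml2::xml_ns(x)
  resolve_qname <- function(node) {
    qn <- xml2::xml_name(node, ns = nsmap)
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) paste0(nsmap[[parts[[1]]]], parts[[2]])
    else stop("RDF/XML element without namespace: ", qn)
  }
  rows <- list()
  for (node in xml2::xml_children(x)) {
    subj <- xml2::xml_attr(node, "about")
    if (is.na(subj)) stop("RDF/XML node without rdf:about (blank nodes ",
                          "are not supported)")
    node_iri <- resolve_qname(node)
    if (node_iri != paste0(RDF_NS, "Description")) {
      rows[[length(rows) + 1L]] <- list(s = subj, p = RDF_TYPE, o = node_iri,
                                        lit = FALSE, dt = NA_character_)
    }
    for (pe in xml2::xml_children(node)) {
      pred <- resolve_qname(pe)
      res <- xml2::xml_attr(pe, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- list(s = subj, p = pred, o = res,
                                          lit = FALSE, dt = NA_character_)
      } else {
        dt <- xml2::xml_attr(pe, "datatype")
        rows[[length(rows) + 1L]] <- list(s = subj, p = pred,
                                          o = xml2::xml_text(pe),
                                          lit = TRUE, dt = dt)
      }
    }
  }
  if (!length(rows)) return(triple_frame())
  data.frame(
    s = vapply(rows, `[[`, character(1), "s"),
    p = vapply(rows, `[[`, character(1), "p"),
    o = vapply(rows, `[[`, character(1), "o"),
    lit = vapply(rows, `[[`, logical(1), "lit"),
    dt = vapply(rows, `[[`, character(1), "dt"),
    stringsAsFactors = FALSE)
}

# ---- dispatch --------------------------------------------------------------

write_triples <- function(triples, path, dialect, prefixes) {
  switch(dialect,
         turtle = write_turtle(triples, path, prefixes),
         rdfxml = write_rdfxml(triples, path, prefixes),
         stop("unknown dialect: ", dialect))
}

read_triples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  if (grepl("^\\s*(<\\?xml|<rdf:RDF)", txt)) parse_rdfxml(path)
  else parse_turtle(txt)
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rdf", "owl", "xml")) "rdfxml" else "turtle"
}
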