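# SPARQL SELECT evaluator over a document's triples.
#
# Supported grammar (a practical subset sufficient for basic graph
# patterns over named-node documents):
#
#   PREFIX pfx: <iri>           (repeatable)
#   SELECT [DISTINCT] ?v ... | *
#   WHERE { pattern ( . pattern )* }
#
# where a pattern is either a triple pattern (terms: ?var, <iri>,
# pfx:local, "literal"(^^dt)?, the keyword a) possibly using ';'/','
# continuation, or VALUES ?var { term ... } binding a variable to a fixed
# set. Solutions are computed by successive joins over the basic graph
# pattern; results are returned in deterministic lexicographic order.

sparql_tokenize <- function(text) {
  pats <- c(
    ws      = "^[ \t\r\n]+",
    comment = "^#[^\n]*",
    iriref  = "^<[^<>\"{}|^`\\\\ ]*>",
    string  = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    dcaret  = "^\\^\\^",
    var     = "^\\?[A-Za-z_][A-Za-z0-9_]*",
    keyword = "^(?i:PREFIX|SELECT|DISTINCT|WHERE|VALUES)\\b",
    pname   = "^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_]?[A-Za-z0-9_-]*",
    number  = "^[+-]?[0-9]+(?:\\.[0-9]+)?",
    kw_a    = "^a(?![A-Za-z0-9_:-])",
    punct   = "^[{}.;,*]"
  )
  pos <- 1L; n <- nchar(text)
  types <- character(0); vals <- character(0); offs <- integer(0)
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
      stop("SPARQL syntax error at character ", pos, ": unexpected '",
           substr(text, pos, pos + 20L), "'")
    }
  }
  list(types = types, vals = vals, offs = offs)
}

# Parse into list(variables (or "*"), distinct, patterns).
# A triple pattern is list(kind="triple", s, p, o) where each term is
# list(type = "var"|"iri"|"lit", value, dt); a VALUES block is
# list(kind="values", var, terms).
sparql_parse <- function(text) {
  tk <- sparql_tokenize(text)
  i <- 1L; ntok <- length(tk$types)
  prefixes <- character(0)
  fail <- function(msg) {
    off <- if (i <= ntok) tk$offs[[i]] else nchar(text)
    stop("SPARQL syntax error at character ", off, ": ", msg)
  }
  peek_type <- function() if (i <= ntok) tk$types[[i]] else "eof"
  peek_val <- function() if (i <= ntok) tk$vals[[i]] else ""
  advance <- function() { v <- tk$vals[[i]]; i <<- i + 1L; v }
  expect_kw <- function(kw) {
    if (peek_type() != "keyword" || toupper(peek_val()) != kw) {
      fail(paste0("expected ", kw))
    }
    advance()
  }
  expect_punct <- function(p) {
    if (peek_type() != "punct" || peek_val() != p) {
      fail(paste0("expected '", p, "'"))
    }
    advance()
  }
  resolve_pname <- function(v) {
    colon <- regexpr(":", v, fixed = TRUE)
    pfx <- substr(v, 1L, colon - 1L)
    if (!pfx %in% names(prefixes)) {
      fail(paste0("undeclared prefix '", pfx, ":'"))
    }
    paste0(prefixes[[pfx]], substring(v, colon + 1L))
  }
  term <- function(allow_var = TRUE) {
    ty <- peek_type()
    if (ty == "var") {
      if (!allow_var) fail("variable not allowed here")
      list(type = "var", value = substring(advance(), 2L), dt = NA_character_)
    } else if (ty == "iriref") {
      v <- advance()
      list(type = "iri", value = substr(v, 2L, nchar(v) - 1L),
           dt = NA_character_)
    } else if (ty == "pname") {
      list(type = "iri", value = resolve_pname(advance()), dt = NA_character_)
    } else if (ty == "kw_a") {
      advance()
      list(type = "iri", value = RDF_TYPE, dt = NA_character_)
    } else if (ty == "string") {
      v <- advance()
      str <- unescape_turtle(substr(v, 2L, nchar(v) - 1L))
      dt <- NA_character_
      if (peek_type() == "dcaret") {
        advance()
        if (peek_type() == "iriref") {
          dv <- advance(); dt <- substr(dv, 2L, nchar(dv) - 1L)
        } else if (peek_type() == "pname") {
          dt <- resolve_pname(advance())
        } else fail("expected datatype after ^^")
      }
      list(type = "lit", value = str, dt = dt)
    } else if (ty == "number") {
      v <- advance()
      dt <- if (grepl("\\.", v)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      list(type = "lit", value = v, dt = dt)
    } else {
      fail(paste0("expected term, got '", peek_val(), "'"))
    }
  }
  while (peek_type() == "keyword" && toupper(peek_val()) == "PREFIX") {
    advance()
    pn <- if (peek_type() == "pname") advance() else fail("expected prefix name")
    if (!grepl(":$", pn)) fail("malformed PREFIX declaration")
    if (peek_type() != "iriref") fail("expected IRI in PREFIX declaration")
    iri <- advance()
    prefixes[[sub(":$", "", pn)]] <- substr(iri, 2L, nchar(iri) - 1L)
  }
  expect_kw("SELECT")
  distinct <- FALSE
  if (peek_type() == "keyword" && toupper(peek_val()) == "DISTINCT") {
    advance(); distinct <- TRUE
  }
  variables <- character(0)
  star <- FALSE
  if (peek_type() == "punct" && peek_val() == "*") {
    advance(); star <- TRUE
  } else {
    while (peek_type() == "var") variables <- c(variables,
                                                substring(advance(), 2L))
    if (!length(variables)) fail("SELECT needs variables or *")
  }
  expect_kw("WHERE")
  expect_punct("{")
  patterns <- list()
  repeat {
    if (peek_type() == "punct" && peek_val() == "}") { advance(); break }
    if (peek_type() == "keyword" && toupper(peek_val()) == "VALUES") {
      advance()
      v <- term(allow_var = TRUE)
      if (v$type != "var") fail("VALUES requires a variable")
      expect_punct("{")
      terms <- list()
      while (!(peek_type() == "punct" && peek_val() == "}")) {
        terms[[length(terms) + 1L]] <- term(allow_var = FALSE)
        if (peek_type() == "eof") fail("unterminated VALUES block")
      }
      advance()
      patterns[[length(patterns) + 1L]] <-
        list(kind = "values", var = v$value, terms = terms)
    } else {
      s <- term()
      repeat {
        p <- term()
        repeat {
          o <- term()
          patterns[[length(patterns) + 1L]] <-
            list(kind = "triple", s = s, p = p, o = o)
          if (peek_type() == "punct" && peek_val() == ",") advance() else break
        }
        if (peek_type() == "punct" && peek_val() == ";") {
          advance()
          if (peek_type() == "punct" && peek_val() %in% c(".", "}")) break
        } else break
      }
    }
    if (peek_type() == "punct" && peek_val() == ".") advance()
  }
  if (i <= ntok) fail("unexpected input after query")
  list(variables = if (star) NULL else variables, distinct = distinct,
       patterns = patterns)
}

# encode a term for joining: IRIs as <iri>, literals as "lex"^^<dt>
encode_node <- function(value, lit, dt) {
  ifelse(lit,
         paste0("\"", value, "\"",
                ifelse(is.na(dt), "", paste0("^^<", dt, ">"))),
         paste0("<", value, ">"))
}

encode_term <- function(tm) {
  encode_node(tm$value, tm$type == "lit", tm$dt)
}

# decode one encoded node (strip <>, or quotes plus datatype suffix)
decode_one <- function(x) {
  if (startsWith(x, "<")) return(substr(x, 2L, nchar(x) - 1L))
  x <- sub("\\^\\^<[^>]*>$", "", x)
  substr(x, 2L, nchar(x) - 1L)
}

#' Run a SPARQL SELECT query over a document
#'
#' Evaluates the query against the document's RDF triples (identical to the
#' graph [write_document()] serializes). Results are ordered
#' lexicographically over the projected columns so repeated runs and
#' cross-engine comparisons are stable.
#'
#' @param doc a `histoml_document`.
#' @param query_text SPARQL SELECT string (see package vignette for the
#'   supported subset).
#' @return a data frame of bindings, one column per projected variable;
#'   IRIs are plain strings, literals their lexical forms. Unbound cells are
#'   `NA`. Class `histoml_query_result`.
#' @export
run_sparql <- function(doc, query_text) {
  q <- sparql_parse(query_text)
  triples <- document_to_triples(doc)
  store <- data.frame(
    s = paste0("<", triples$s, ">"),
    p = paste0("<", triples$p, ">"),
    o = encode_node(triples$o, triples$lit, triples$dt),
    stringsAsFactors = FALSE)
  sol <- data.frame(row.names = 1L)  # one empty solution
  for (pat in q$patterns) {
    if (pat$kind == "values") {
      vals <- vapply(pat$terms, encode_term, character(1))
      tbl <- stats::setNames(data.frame(vals, stringsAsFactors = FALSE),
                             pat$var)
      sol <- join_solutions(sol, tbl)
    } else {
      sol <- join_pattern(sol, pat, store)
    }
    if (!nrow(sol)) break
  }
  vars <- q$variables %||% sort(names(sol))
  out <- data.frame(matrix(NA_character_, nrow = nrow(sol),
                           ncol = length(vars)),
                    stringsAsFactors = FALSE)
  names(out) <- vars
  for (v in vars) {
    if (v %in% names(sol)) {
      out[[v]] <- vapply(sol[[v]], decode_one, character(1),
                         USE.NAMES = FALSE)
    }
  }
  if (q$distinct) out <- unique(out)
  if (nrow(out)) {
    out <- out[do.call(order, c(unname(as.list(out)),
                                list(method = "radix"))), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("histoml_query_result", "data.frame")
  out
}

join_solutions <- function(sol, tbl) {
  if (ncol(sol) == 0L) {
    return(if (nrow(sol)) tbl else tbl[0, , drop = FALSE])
  }
  common <- intersect(names(sol), names(tbl))
  if (!length(common)) {
    if (!nrow(sol) || !nrow(tbl)) {
      out <- cbind(sol[0, , drop = FALSE], tbl[0, , drop = FALSE])
      return(out)
    }
    merge(sol, tbl, by = NULL)  # cross product
  } else {
    merge(sol, tbl, by = common)
  }
}

join_pattern <- function(sol, pat, store) {
  terms <- list(s = pat$s, p = pat$p, o = pat$o)
  cand <- store
  for (pos in names(terms)) {
    tm <- terms[[pos]]
    if (tm$type != "var") {
      cand <- cand[cand[[pos]] == encode_term(tm), , drop = FALSE]
    }
  }
  # columns: one per distinct variable; a variable repeated within the
  # pattern constrains rows to equal values
  vars <- character(0)
  for (pos in names(terms)) {
    if (terms[[pos]]$type == "var") vars[pos] <- terms[[pos]]$value
  }
  if (length(vars) >= 2) {
    dup <- duplicated(vars)
    for (pos in names(vars)[dup]) {
      first_pos <- names(vars)[match(vars[[pos]], vars)]
      cand <- cand[cand[[pos]] == cand[[first_pos]], , drop = FALSE]
    }
  }
  keep <- !duplicated(vars)
  tbl <- stats::setNames(
    as.data.frame(cand[names(vars)[keep]], stringsAsFactors = FALSE),
    vars[keep])
  tbl <- unique(tbl)
  if (ncol(tbl) == 0L) {
    # fully ground pattern: acts as an existence filter
    if (nrow(cand)) return(sol) else return(sol[0, , drop = FALSE])
  }
  join_solutions(sol, tbl)
}
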