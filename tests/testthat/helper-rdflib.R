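# Independent second-engine oracles backed by the Python rdflib library
# (invoked through the python interpreter on PATH). Used only to cross-check
# the package's own serializers and SPARQL evaluator.

# Run one SPARQL SELECT with rdflib over a Turtle file; returns a data frame
# with the projected variables (IRIs as plain strings, literals as lexical
# forms), sorted like histoml's run_sparql.
rdflib_select <- function(ttl_path, query) {
  qfile <- tempfile(fileext = ".rq")
  writeLines(query, qfile)
  out <- tempfile(fileext = ".tsv")
  script <- sprintf('
import rdflib, csv, sys
g = rdflib.Graph(); g.parse(%s, format="turtle")
q = open(%s).read()
res = g.query(q)
with open(%s, "w", newline="") as fh:
    w = csv.writer(fh, delimiter="\\t")
    w.writerow([str(v) for v in res.vars])
    for row in res:
        w.writerow(["" if v is None else str(v) for v in row])
', deparse(ttl_path), deparse(qfile), deparse(out))
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0L) stop("rdflib oracle failed")
  df <- utils::read.delim(out, colClasses = "character",
                          check.names = FALSE)
  if (nrow(df)) {
    df <- df[do.call(order, c(unname(as.list(df)), list(method = "radix"))), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# batch graph-isomorphism check: files is a data frame with columns a, b;
# returns logical vector
rdflib_isomorphic <- function(pairs) {
  listing <- tempfile()
  utils::write.table(pairs, listing, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  out <- tempfile()
  script <- sprintf('
import rdflib
from rdflib.compare import isomorphic
def load(p):
    g = rdflib.Graph()
    g.parse(p, format="xml" if p.endswith((".rdf", ".owl", ".xml")) else "turtle")
    return g
res = []
for line in open(%s):
    a, b = line.rstrip("\\n").split("\\t")
    res.append("TRUE" if isomorphic(load(a), load(b)) else "FALSE")
open(%s, "w").write("\\n".join(res) + "\\n")
', deparse(listing), deparse(out))
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0L) stop("rdflib isomorphism oracle failed")
  as.logical(readLines(out))
}
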