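---
title: "Representing and quantifying histopathological features with histoml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and quantifying histopathological features with histoml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoml)
```

## The problem

Whole-slide images (WSIs) carry information at many scales: single cells
and their subcellular components, the substances cells produce, tissues,
anatomical structures, and mesoscopic arrangements such as alveolar nests
or a tumor pushing into the renal sinus. In practice this information is
scattered across label lists, ad hoc taxonomies, free-text descriptions and
feature tables, none of which can express the relationships between
features (containment, shared identity, movement) in a machine-readable
way. HistoML Level 1 addresses this by representing WSI semantics as OWL
individuals of a small, carefully structured ontology, so that documents
can be exchanged, validated, queried with SPARQL and linked to the pixels
they describe.

This package implements that representation language end to end in R: the
schema, a validated document model, deterministic OWL serialization, a
SPARQL query layer, segmentation-linked morphometry, and synthetic fixture
generators that provide exactly known ground truth.

## The schema

`build_schema()` constructs the Level 1 class hierarchy. Three classes root
everything:

* **Entity** — what is observed: `PhysicalEntity` (cells, cellular
  components, substances, tissues, anatomical structures, cross-classified
  into `NormalEntity` and `Tumor`) and `Phenotype` with its three levels,
  `Cellular_Appearances`, `Product_or_Reserve` and `Architectural_Pattern`.
* **Utility** — the annotation machinery: `EntityReference` (a generic
  description shared by many concrete forms), `EntityAttribute`,
  `Quantification`, `Relationship` and `Xref`.
* **Data** — slide metadata (`WholeSlideImage`: height, width,
  magnification, optionally microns per pixel).

The subclass graph allows multiple parents (a `NeoplasticCell` is both a
`Cell` and part of `Tumor`); the enforced structural invariant is
acyclicity plus exactly these three roots. Subclass "inference" is explicit
graph traversal (`subclass_closure()`), never a description-logic
reasoner: results are deterministic and the package has no reasoning
dependency.

`PhysicalEntity` carries four main object properties: `entityReference`,
`hasAttribute`, `hasProduct` and `hasComponent`, the last with three child
properties `hasCell`, `hasCellularComponent` and `hasAnatomicalEntity`.
`hasReserve` is declared with domain `Cell`, reflecting that products and
reserves are materials of cells; the builder enforces cell → substance for
both directions of that pair. A phenotype reaches its component entities
through `present_Entity`, and movement behaviours (e.g. tumor extension)
are `Relationship` individuals. The ontology names only informational
roles for relationships and quantifications, so this package fixes
property names: `movementType`, `movingObject`, `towards` on
`Relationship`, and `parameterName`, `value`, `unit`, `formula`, `source`
on `Quantification`, linked from attributes via `hasQuantification`.
Cross-references into controlled vocabularies (NCIt, CMPO, FMA, GO, PATO,
UO) are opaque CURIE strings stored on `Xref` individuals; they are never
resolved against live ontologies, and only their `PREFIX:LOCALID` shape is
validated.

```{r}
s <- build_schema()
schema_roots(s)
direct_subclasses(s, "Phenotype")
main_object_properties(s, "PhysicalEntity")
```

## Documents and validation

A `histoml_document` is a mutable container (an R environment) bound to a
schema. Builder functions (`add_physical_entity()`, `attach_attribute()`,
`link_component()`, `add_phenotype()`, ...) mint deterministic IRIs of the
form `{base_iri}{slide_id}/{Class}_{counter}`, so serializations are
stable and diffable. Each builder validates its inputs before touching the
document; as a consequence, documents produced through the API always pass
`validate_document()` without errors (a property the test suite checks on
randomized builder sequences). The validator reports, rather than throws:
domain/range violations, dangling IRIs, containment cycles, malformed
CURIEs and phenotypes without components are errors; an attribute with
neither cross-reference nor quantification is only a warning, because
purely named attributes (e.g. "eosinophilic") are legitimate.

## Serialization

Documents and the schema serialize to Turtle and RDF/XML. Design choices
that matter for testability:

* **No blank nodes.** Every node is named, so document equality is plain
  set comparison of triples and SPARQL results never depend on node
  identity heuristics.
* **Deterministic output.** Triples are sorted (subject, then `rdf:type`
  first, then predicate and object); numeric literals have fixed lexical
  forms (`xsd:integer` for counts, non-scientific `xsd:decimal` for
  measurements). Writing the same document twice yields byte-identical
  files.
* **Nothing is dropped on read.** Individuals of unknown classes or with
  unknown properties are carried into the document and reported in an
  `unknown_report` attribute.

The readers accept the subset of each syntax the writers emit (plus
comments, `;`/`,` continuations and bare numbers in Turtle for leniency).
The test suite cross-checks both serializers against an independent RDF
engine: triple counts, graph isomorphism, and SPARQL results must agree.

## Queries

`run_sparql()` evaluates a practical subset of SPARQL SELECT — `PREFIX`,
`SELECT [DISTINCT]`, basic graph patterns with `;`/`,` elaboration, and
`VALUES` blocks — by successive joins over the document's triples. Two
choices keep results reproducible: subclass closure is expanded into
`VALUES` blocks at query-build time (again, no reasoner), and rows are
sorted lexicographically because SPARQL itself leaves order undefined.
Canned queries (`components_of_phenotype()`, `entities_within()`,
`segmentations_of()`) are phrased as SPARQL and property-tested against
pure edge-scan oracles on randomized documents.

## Morphometry

Four region parameters objectify cellular characteristics, computed on
label masks:

* **area** — pixel count, times `microns_per_pixel`² for µm².
* **circularity** — `4πA/P²`. The digital perimeter `P` comes from Moore
  boundary tracing with Kulpa's chain-code weights (0.948 per straight
  move, 1.340 per diagonal move), which keeps a rasterized disk within
  about 1% of `2πr` and hence circularity ≈ 1. Values slightly above 1
  can occur; the estimate is meaningful for regions of more than a few
  dozen pixels. Disconnected regions are refused — the caller must split
  them.
* **eccentricity** — `sqrt(1 − λ₂/λ₁)` from the eigenvalues of the pixel
  covariance matrix (the ellipse-of-equal-second-moments definition);
  0 for a disk, exactly 1 for a degenerate collinear region (returned, not
  an error).
* **image entropy** — Shannon entropy, base 2, of the 256-bin intensity
  histogram over the region: 0 bits for a constant region, 1 bit for a
  50/50 two-level region, → 8 bits for uniform noise.

`quantify_entity()` attaches these as `Quantification` nodes under an
attribute named after each parameter.

### Masks

A label mask is one integer plane (0 = background) plus an `id_map` from
segmentation id strings to label values. An id may own *several* labels,
and different ids may share labels. This convention solves a real
representational problem: a stromal region that contains lymphocytes
covers their pixels too, but one integer plane can give each pixel only
one label. Mapping `seg:stroma` to the stroma fill label *plus* the
lymphocyte labels makes the stroma's region the union — its area includes
the cells it hosts — while each lymphocyte keeps its own exact region.
On disk, masks are PNGs with the 16-bit label packed into the red (high
byte) and green (low byte) channels, next to a sidecar JSON carrying the
`id_map` and resolution. Coordinates are row-major, origin top-left.

### Stromal TILs

`stromal_tils()` computes the fraction of the stromal area covered by
infiltrating lymphocytes. Membership is semantic, not geometric: the
lymphocyte set is the result of the containment query
(`entities_within(stroma, "Lymphocyte")`), then areas come from the
segmentations. The fixtures guarantee that lymphocyte regions are pixel
subsets of their stroma; for data where that is not guaranteed,
`clip_to_stroma = TRUE` intersects lymphocyte pixels with the stromal
region before counting.

## Synthetic fixtures

Because the slides behind the canonical exemplars are not available as
analyzable data, the package generates its own study material with exactly
known ground truth, via the public builder API so every bundle's document
is schema-valid by construction:

* `make_tils_fixture(stroma_area_px, til_fraction, n_lymphocytes, seed)` —
  a parenchyma block plus a stromal region of *exactly* `stroma_area_px`
  pixels. Lymphocytes are laid down by seeded region growing: each starts
  at a random free stromal pixel and annexes the free 4-neighbour closest
  to its seed until its exact pixel budget is met. At sparse densities
  this produces quasi-disks; at dense ones, space-filling cells — so the
  generator covers the whole fraction range up to 1.0 with the true
  fraction equal to `round(f·A)/A`. Defaults (10 000 px stroma, fraction
  0.3, 25 lymphocytes) reflect a plausible immune-infiltrated breast-
  cancer region at the package's test scale.
* `make_rhabdoid_fixture(n_cells, size_range_px, eccentricity_range,
  seed)` — large elliptical cells, each with an off-centre, boundary-
  modulated ("irregular") nucleus containing a bright nucleolus spot. The
  four characteristic attributes (large / irregularly-shaped / eccentric /
  prominent) carry quantifications *measured from the bundle's own mask*,
  so document values and mask recomputation agree by construction.
  Defaults (4 cells of 1500–3000 px², nucleus eccentricity 0.5–0.8) give
  nuclei that are visibly irregular and eccentric while keeping each
  region large enough for the perimeter estimator to be meaningful.
* `make_alveolar_fixture(n_nests, seed)` — nests whose parenchyma core
  (full of neoplastic cells) is ringed by a capillary containing
  erythrocytes and endothelia, nested at containment depth ≥ 3.
* `build_extension_exemplar()` — a mask-free document with one
  `Relationship` recording a tumor's extension towards the renal sinus.

Images are flat tints with seeded Gaussian noise. They deliberately do
**not** emulate H&E stain statistics, nuclear chromatin texture, staining
artifacts or scanner variation; passing tests on these fixtures therefore
demonstrates correctness of representation, serialization, querying and
measurement — not segmentation performance or robustness on real stains.
Every manifest quantity is recomputable from the emitted mask by brute
force, and the suite asserts this closure.

## Numerical and scale choices

* All randomness flows through one seed per generator call; identical
  parameters and seed give bit-identical bundles.
* Entropy uses 256 bins and base 2 throughout; circularity's perimeter
  weights are fixed constants, documented above.
* Randomized-document suites use 200 documents of ≤ 50 individuals for the
  round-trip and query-equivalence properties, and random blobs on ≤ 64×64
  masks for the morphometry-vs-oracle property — sizes at which the
  properties are already discriminating while the whole suite stays quick
  to run.
* Ties in SPARQL result ordering cannot occur (rows are full duplicates
  only under `DISTINCT`, which removes them); ties in region growing are
  broken by pixel index, keeping generators deterministic.

## Known limitations

* The published ontology is larger than the class list implemented here;
  this package mandates the classes and properties named in the Level 1
  description and the exemplars, plus the concrete cell/tissue classes the
  fixtures need. The papillary-thyroid exemplar is not reconstructible
  from the available material and is omitted.
* The SPARQL subset has no `FILTER`, `OPTIONAL`, property paths or
  aggregation; the containment closure in canned queries is computed by
  iterated single-step queries instead of property paths.
* WSI container formats (SVS/NDPI pyramids) are out of scope; the package
  consumes tiles and masks.
* `segmentation` values are plain strings resolved through the sidecar
  `id_map`, not IRIs.
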