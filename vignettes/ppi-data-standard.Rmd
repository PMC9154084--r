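---
title: "Standardized plant-pollinator interaction data: model, serializations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized plant-pollinator interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitools)
```

## The problem and the model

Most published plant-pollinator data are species-level adjacency matrices:
which plant taxa interact with which animal taxa, sometimes with a visit
count. What is actually observed in the field is richer — an individual
animal doing something to an individual plant at a place and time, with
measurable context (what resource it collected, how long the visit lasted,
what color the flower was, how many pollen grains moved). Species-level
networks can always be derived from such records by aggregation; the reverse
is impossible. `ppitools` therefore models the *individual-level interaction
record* as its unit of data and treats networks as a derived product.

The model rests on Darwin Core (DwC) classes:

* **Event** — one interaction: an action at a location during some time.
  Carries `eventID`, date, coordinates, locality, protocol.
* **Occurrence** — one participating organism (one plant, one animal per
  record in the typical case), linked to its event by `eventID`. Carries
  `scientificName` at whatever rank is determinable; functional-group
  annotations belong in the remarks terms.
* **ResourceRelationship** — the type and direction of the interaction:
  subject (`resourceID`), object (`relatedResourceID`), type
  (`relationshipOfResource` as text and/or `relationshipOfResourceID` as a
  Relations Ontology IRI) and source (`relationshipAccordingTo`).
* **MeasurementOrFact** — everything else, typed by terms of the bundled
  plant-pollinator vocabulary, attached either to the event (interaction
  outcomes: resource collected, pollen moved) or to one occurrence (organism
  traits: flower color, caste).

None of the DwC terms are individually mandatory, but a record is only
*reusable* if a minimal core is present. `validate_dataset()` enforces
exactly that contract: every occurrence needs a `scientificName`, every
event an `eventID`, every relationship a resolvable subject and object, a
type and a source. Violations are errors; everything else the package
checks — controlled-vocabulary membership, measurement types unknown to the
registry, events with no relationship — is a warning, because the
vocabulary's value recommendations are explicitly non-normative.

## The vocabulary registry

The bundled registry holds 48 `Property` terms in six informal categories
(Animal, Plant, Flower, Interaction, Reproductive Success, Nectar Dynamics),
each with the normative elements of a TDWG term definition: name, IRI under
`http://rs.rebipp.org.br/ppi/terms/`, definition, modification date, and —
where a closed value list is recommended — a controlled vocabulary with `;`
separators, e.g. `flowerOpeningType` with
`cleistogamous; chasmogamous; both`.

A note on provenance: only a handful of the published term definitions are
reproduced verbatim in the primary literature (among them
`flowerOpeningType`, `flowerColor`, `floralAttractants`, `caste`,
`resourceCollected`, `nectarCollectingBodyPart`,
`numberOfRemovedPollenGrains`); the full roster lives in an external
repository. The bundled file is therefore named
`ppi-terms-synthetic.csv`: those published terms appear under their
published names and IRIs, and the remaining entries are a plausible
reconstruction written for this package (standard pollination-biology
descriptors with units and controlled vocabularies a field ecologist would
recognize). Replace it with the official list via
`load_registry()`/`--registry` when fidelity to the published vocabulary
matters; every function takes a registry argument.

Two namespace details were genuinely open and decided here: the term
namespace includes the `/terms/` path segment (the form used by the term
template itself; diagram captions elsewhere abbreviate it without the
segment), and controlled-vocabulary matching is case-sensitive by default
(`case_sensitive = FALSE` is available) because CV tokens are lowercase
controlled values, not free text.

## Serializations

Three schemas serialize the same model; `read_*`/`write_*` pairs are
inverses on canonicalized datasets, which is the property the test suite
leans on hardest.

**Darwin Core Archive** (`write_dwca()`/`read_dwca()`): the sampling-event
star schema. The Event table is the core; Occurrence,
ExtendedMeasurementOrFact (eMoF) and ResourceRelationship extensions repeat
the `eventID` as their core id. The eMoF extension is classic
MeasurementOrFact plus `occurrenceID` (to point a measurement at one
participant, circumventing the star schema's single-key limit — empty means
"about the interaction itself") and exactly three new ID terms —
`measurementTypeID`, `measurementValueID`, `measurementUnitID` — intended to
carry vocabulary IRIs; `write_dwca()` fills `measurementTypeID` from the
registry when the human-readable type names a registry term. Column meaning
on read comes from the `meta.xml` term IRIs, never from position. Because no
zip tool is guaranteed at run time, the package writes the archive container
itself (deflate streams, CRC-32 computed in R, timestamps fixed at the DOS
epoch so identical datasets are byte-identical); reading goes through
`utils::unzip`, an independent code path.

**XML** (`write_ppi_xml()`/`read_ppi_xml()`): flat, namespaced record
elements under one root. One-to-many links need no star schema: each
measurement appears exactly once as a `MeasurementOrFact` element and the
owning Event or Occurrence element repeats its `measurementID` as a
reference child. The concrete layout (flat elements + ID references rather
than nesting) is this package's documented dialect; the normative content is
the class elements and the `measurementID` referencing. Documents carrying
DOCTYPE/entity declarations are rejected outright (external-entity safety).
A reference to a measurement that has no element is not a read failure; it
surfaces as a `DANGLING_REFERENCE` finding on validation.

**RDF** (`to_triples()`/`from_triples()`, Turtle and N-Triples via
`serialize_graph()`/`parse_graph()`): occurrences and events become typed
nodes minted under a base IRI (`<base>occurrence/<id>` etc. — minted IRIs
rather than blank nodes keep round trips exact and isomorphism checks
trivial); each occurrence links to its event with `dsw:atEvent`; the
interaction itself is a single triple — subject occurrence, Relations
Ontology predicate, object occurrence; measurements hang off their owner via
`dcterms:relation`, with `dwciri:measurementType` when the type is a
vocabulary IRI and literal `dwc:measurementType` otherwise, and values
either as `xsd:string` literals or, for controlled-vocabulary IRIs, as
literals typed `xsd:anyURI` (implemented as specified, though a literal
holding a URI is admittedly in tension with making the value a true object
link; a semantically cleaner object-property mode was considered and
deliberately not made default).

The RDF mapping is knowingly lossy in one respect: the ResourceRelationship
record is *not* reified (its RDF representation is an open debate in the
standard's community), so the relationship's own identifier and
`relationshipAccordingTo` do not survive. `from_triples()` re-mints
relationship identifiers deterministically, recovers the human-readable type
through the shipped RO predicate table, and leaves the attribution empty —
honestly incomplete — unless the caller supplies `according_to`. Round-trip
equality through RDF is therefore asserted with
`ppi_equal(ignore = "relationshipAccordingTo")`, and the CLI refuses an
RDF-to-anything conversion without either `--according-to` or
`--allow-lossy`. Since nothing installed in R speaks RDF, the triple store
and both parsers are part of the package; the Turtle writer emits a prefix
prologue and one statement per line, and the parser reads exactly that
dialect — valid Turtle for any conformant consumer, not a general Turtle
parser.

The RO predicate table (`ro_predicates()`,
`extdata/ro-predicates.csv`) maps labels like "pollinates" and
"visits flowers of" to Relations Ontology IRIs. The exact term IRIs are not
printed in the primary literature; the table ships editable and is the
single place to correct them.

## Networks

`aggregate_to_network()` counts relationship records per (plant taxon,
animal taxon) pair into an adjacency matrix; taxa are keyed by verbatim
`scientificName` (no rank collapsing — any determinable rank is a valid
label) and sorted in C-locale lexicographic order for determinism. Roles
come from the `organismRole` column by default, or a user predicate.

`network_to_dataset()` documents each nonzero cell as one event with two
fresh occurrences (an archive extension row belongs to exactly one core
event, so nodes shared across edges cannot be single occurrences — a
deliberate divergence from the most literal reading of "each node is an
occurrence") and one relationship, subject = animal by default to match
predicates that read animal-acts-on-plant. Weights are an open point in the
record model: the default *compact* mode stores the cell value as one
event-level `"interaction frequency"` measurement (a label defined by this
package, not a vocabulary term — the vocabulary names no count term), which
`aggregate_to_network()` honours, so the matrix is preserved exactly;
*expanded* mode instead emits weight-many replicate events, after which the
relationship count equals the matrix total.

One structural caveat: a taxon whose row or column is all zeros produces no
records at all, so no round trip can recover it; the identity
`aggregate(expand(M)) = M` holds on the submatrix of taxa with at least one
interaction, and the tests state it that way.

## The synthetic fixture generator

`generate_dataset(fixture_profile(...))` emulates a field campaign of
individual-level records: plant and animal pools with deterministic
synthetic binomials ("Plantus sp01" — no real taxon implied),
`ceiling(connectance * n_plants * n_animals)` distinct edges,
`records_per_edge` events per edge with a date in 2021, coordinates in a
small neotropical-looking box, one relationship per event with an
RO-mapped type, and, at `measurement_rate`, one measurement per event drawn
from the registry (event-level terms from the Interaction/Reproductive
Success/Nectar Dynamics categories; occurrence-level from Plant/Flower or
Animal), with values sampled from the term's controlled vocabulary when it
has one. A single seeded stream with fixed draw order makes identical
profiles byte-identical after canonicalization, which the byte-level
round-trip tests rely on.

What it does *not* emulate — and hence what green tests do not show about
real data: realistic degree distributions or nestedness, taxonomic
heterogeneity and misspellings, multi-relationship events, sparse/partial
fields, or legacy `associatedTaxa` packing (that parser is tested on
constructed strings instead). Default sizes (3 plants x 4 animals,
connectance 0.5) keep one dataset around 6 events; the property suites run
100 profiles with pools up to 5x5, connectance 0.2-1 and measurement rates
0-1, sizes chosen so the full suite completes in about a minute and a half
on one core while still crossing every code path.

## Validation semantics worth knowing

* Findings are sorted by (record kind, record id, code) so reports are
  stable under record reordering.
* Blanking an identifier in a flat file removes it everywhere it occurs, so
  the validator reports such a defect once, on the owning record
  (`MISSING_EVENT_ID`), and the dangling-reference check skips empty
  reference fields — except a relationship's subject/object, which the
  minimal contract requires, so emptiness there *is* `DANGLING_REFERENCE`.
  This yields exactly one error per single fault, which the fault-injection
  suite checks exhaustively.
* A measurement with neither type nor type IRI is flagged as the warning
  `UNKNOWN_MEASUREMENT_TYPE` rather than a new error code.
* `canonicalize()` (trim, sort by identifiers, drop all-empty extra columns)
  defines dataset equality; `ppi_equal()` applies it to both sides without
  requiring validity, so equality is well defined even for reconstructions
  from lossy serializations.

## Limitations

Beyond the RDF lossiness and network-zero-row caveats above: no taxonomic
backbone reconciliation (names are verbatim keys), no EML authoring beyond a
title/provenance stub, no network metrics (nestedness, modularity — use a
dedicated network package on the exported matrix), and the bundled registry
is a reconstruction as described. The XML and Turtle dialects are documented
subsets chosen for losslessness, not general-purpose parsers for those
formats.
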