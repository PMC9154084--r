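# ppitools

Tools for standardized plant–pollinator interaction data.

Animal pollination underpins the reproduction of most flowering plants, yet
interaction data are scattered across bespoke spreadsheets and summarized
species-level matrices that cannot be merged or re-analyzed. `ppitools`
implements a working data standard for such data on top of Darwin Core, for
pollination ecologists digitizing field records, data managers publishing to
biodiversity networks, and synthesists aggregating networks across studies.

## The model

One interaction is a **`dwc:Event`** `E` (action at a place and time). Its two
participants are **`dwc:Occurrence`** records `o_p` (plant) and `o_a`
(animal) linked to `E` by `eventID`. Type, direction and source of the
interaction live in a **`dwc:ResourceRelationship`**:

```
resourceID = o_a   relatedResourceID = o_p
relationshipOfResource(ID) = "visits flowers of" (obo:RO_0002623)
relationshipAccordingTo = <person | publication | reference>
```

Everything else — traits and outcomes — is a **MeasurementOrFact** attached
to `E` (interaction level) or to one occurrence, typed by a controlled
vocabulary of 48 `rdf:Property` terms in six categories (Animal, Plant,
Flower, Interaction, Reproductive Success, Nectar Dynamics), e.g.
`ppi:flowerOpeningType` with admissible values
`{cleistogamous, chasmogamous, both}`.

A species-level bipartite network is the aggregation
`W[p, a] = #{relationships with plant taxon p and animal taxon a}`, never
the other way around.

The package provides: the queryable term registry (`load_registry()`,
`get_term()`, `validate_controlled_value()`, `export_term_list()`); the
dataset container with a minimal-record validity contract
(`ppi_dataset()`, `validate_dataset()`, `canonicalize()`); lossless
serializers for Darwin Core Archives (`write_dwca()`/`read_dwca()`,
sampling-event star schema with eMoF and ResourceRelationship extensions),
XML (`write_ppi_xml()`/`read_ppi_xml()`) and RDF following Darwin-SW
(`to_triples()`, `write_rdf()`, `read_rdf()`); network conversion
(`aggregate_to_network()`, `network_to_dataset()`); a deterministic fixture
generator (`generate_dataset()`); legacy `associatedTaxa` parsing; and a
CLI (`ppi_cli()`, wrapper in `inst/cli/ppi-tools`).

## Worked example

```r
library(ppitools)

d <- generate_dataset(fixture_profile(n_plants = 3, n_animals = 4,
                                      connectance = 0.5, seed = 42))
summary(d)
#> Interaction dataset: 6 events, 12 occurrences (3 plant taxa, 4 animal taxa),
#>   2 measurements, 6 relationships
#> <ppi_validation_report> VALID (0 error(s), 0 warning(s))
```

Six events because `ceiling(0.5 * 3 * 4) = 6` distinct plant–animal edges
are realized; each carries one plant and one animal occurrence and one
relationship, and about half the events (rate 0.5) carry a measurement.
Aggregating to the species-level network:

```r
aggregate_to_network(d)
#> <ppi_network> 3 plant(s) x 4 animal(s), weighted, 6 interaction(s)
#>              Animalus sp01 Animalus sp02 Animalus sp03 Animalus sp04
#> Plantus sp01             1             1             0             0
#> Plantus sp02             1             1             0             0
#> Plantus sp03             0             0             1             1
```

Each cell counts interaction events between the two taxa; the 6 ones are
exactly the realized edges. Controlled vocabularies validate values:

```r
term <- get_term(ppi_default_registry(), "flowerOpeningType")
validate_controlled_value(term, "chasmogamous")$accepted  #> TRUE
validate_controlled_value(term, "open")$accepted          #> FALSE
```

Serialize anywhere, losslessly:

```r
write_dwca(d, "interactions.zip")          # DwC-A: meta.xml + 4 tables
ppi_equal(d, read_dwca("interactions.zip"))  #> TRUE
write_rdf(d, "turtle", file = "interactions.ttl")
```

Or from a shell (exit codes: 0 valid, 1 validation errors, 2 usage):

```sh
ppi-tools generate --out interactions.zip --seed 42
ppi-tools validate interactions.zip
ppi-tools convert interactions.zip interactions.ttl
ppi-tools network interactions.zip --to-matrix matrix.csv
```

The bundled registry file is named `ppi-terms-synthetic.csv` because part of
its roster is a reconstruction (see the vignette); swap in an official term
list with `--registry`/`load_registry()` at any time.

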