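---
title: "Versioned records and structured annotations: the collann data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Versioned records and structured annotations: the collann data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collann)
```

## The problem

Natural-history collections publish specimen and occurrence records as XML
documents (rich ABCD records or simpler Darwin Core ones) through networks of
data portals. Researchers who study those specimens — above all taxonomists
revising determinations — have always annotated the *physical* sheets;
online, that pathway is broken: provider records change silently over time,
portals cannot attach structured corrections to individual data elements, and
there is no channel that routes a correction back to the collection's
curator.

`collann` implements the repository side of a digital annotation workflow for
such records:

* **versioned archiving** of the exact XML document a user annotated, so an
  annotation can never be orphaned by a provider-side edit;
* **structured annotations** that address individual elements by XPath
  selector and state the corrective the annotator expects (add, remove,
  update), a proposed value and/or a comment;
* a **curatorial layer**: collection curators annotate published annotations
  with per-element decisions;
* **batch annotations** linking the same correction applied to many records;
* a faithful **W3C Open Annotation RDF serialization** of all three shapes;
* **filter-based query and subscription matching** with an inspectable
  notification outbox; and
* **curator-role access control** kept in sync with record imports.

## Persistent identifiers

A specimen is conventionally referenced by its *triple identifier* —
institution code, collection code and catalogue number. The triple names the
physical object, not the metadata describing it, so `collann` extends it for
record documents with (i) a version, stored as milliseconds since
1970-01-01T00:00:00 UTC, and (ii) the namespace prefix of the data format
(`abcd2.06b`, `dwc`, extensible via `register_format()`):

```{r}
id <- compose_record_id(
  triple_id("BGBM", "Herbarium Berolinense", "B 18 0014862"),
  instant_to_version(as.POSIXct("2013-09-17 08:36:05.371", tz = "UTC")),
  "abcd2.06b"
)
id
```

Annotation ids have three components (authority, system instance, creation
instant in epoch milliseconds) and no version or format part — an annotation
is created exactly once.

Encoding writes spaces as `+`. The escape rule for literal `+`, `:` and `%`
inside a component (percent-encoding) is this package's own choice; it keeps
the 3/5-part grammar unambiguous, and `parse∘format` is the identity for
arbitrary component strings (property-tested). All timestamps are UTC;
formatting splits whole seconds from the millisecond remainder rather than
relying on fractional-second formatting, which truncates floating-point
representations and can silently lose a millisecond.

## Order-insensitive similarity

Two record documents are *similar* — treated as the same revision — when
they contain the same elements and attributes, including values, regardless
of order. `canonicalize_document()` realises this as a multiset with one
entry per element node:

* the **name path** from root to element, namespace-expanded
  (`{uri}local`), with sibling positions dropped;
* the **attribute set**, sorted by expanded name, `xmlns` declarations
  excluded;
* the element's **direct text**, whitespace-stripped and internally
  collapsed; comments and processing instructions are ignored.

Similarity is equality of those multisets, hence a true equivalence
relation. The deliberate consequences:

* serializer differences — indentation, attribute order, namespace-prefix
  spelling, sibling order — never create a new revision;
* moving a subtree among like-named siblings is still "similar", because
  element identity is the positionless name path (content defines the
  document, not layout);
* a **multiset** (not set) is compared, so two identical repeated elements
  differ from one;
* any single character changed in any text or attribute value breaks
  similarity (mutation-tested).

Canonical entries are sorted with radix order, which is locale-independent,
so canonical forms are portable across environments.

## The versioned repository

`import_record()` compares the incoming document against the *current*
revision of its (triple, format) chain:

| situation | outcome |
|---|---|
| no revision archived | `first`: new current revision |
| similar current revision | `reused`: archived revision returned, nothing changes |
| dissimilar current revision | `new_revision`: old one demoted to *historic*, import becomes current |

Historic revisions remain archived (bit-exact raw bytes) and queryable, but
can no longer be annotated — only the most recent revision can. Demotion is
scoped to one (triple, format) chain: the same specimen served in another
format keeps its own chain. If two imports of one chain fall into the same
millisecond, or a clock regression would produce a non-increasing version,
the version is bumped to the next free millisecond: identifiers must stay
unique and ordered, and wall-clock fidelity of the version is secondary to
that. A reused import deliberately refreshes nothing — not even a timestamp
— so re-retrieval of an unchanged record is a true no-op.

Annotation ids are bumped the same way on collision when drafts are saved.

## Element selectors

Selectors are XPath expressions, carried in RDF as fragment selectors
conforming to the XPointer framework. Generated selectors use a small
dialect — absolute child steps with 1-based positional predicates — and the
predicate is always emitted (even `[1]`), so records with repeated elements
(multiple identifications are common) stay unambiguous. Both predicate
styles are accepted on input. For elements in a default namespace the steps
are written as `*[local-name()=...]` so they resolve without a prefix map;
prefixed documents carry their prefix map with the selector.

A selector of `"/"` (after whitespace trimming) addresses the whole record
and encodes a general comment. Selectors bind to one specific revision:
sibling reordering in a *different* revision may retarget a positional
selector, which is exactly why annotations reference the archived revision,
never the live record. Selector "healing" across revisions is out of scope.

## Annotations, curation, batches

A regular annotation carries provenance (motivation, creation instant,
agent), the record revision id, and a non-empty list of annotated elements;
each element has a selector, an expectation (`Add`, `Remove`, `Update`), and
a proposed value and/or comment. `Remove` must not carry a value. The four
motivations (Determination, Gathering, NomenclaturalType, ScientificName)
come with selector-path templates (`template_elements()`) shipped as
configuration, not code, so a new schema extends without code changes.
Multi-element annotations are unrestricted — correcting a latitude usually
means correcting the longitude too.

Validation against the revision requires `Update`/`Remove` selectors to
resolve to at least one node; `Add` selectors need not resolve, but their
parent path must, so the proposed element has a plausible attachment point.

Curatorial annotations target a *published* annotation and cover each of its
elements exactly once with a decision: `Accepted`, `Rejected`, `Undecided`
or `Update` — the last meaning "element already updated for another
reason". The decision named `Update` collides with the expectation named
`Update`; the collision is part of the established vocabulary and is
preserved, not renamed. `Undecided` is a legal terminal state of a published
curatorial annotation: published objects are immutable, so a later change of
mind is a *new* curatorial annotation (several may coexist per annotation).

Batch annotations link ≥ 2 members that are content-identical apart from
their target (all regular → `Batch`, all curatorial → `CuratorialBatch`).
The batch has no elements of its own; it records member ids in order.
Creating a batch publishes nothing by itself.

## Open Annotation serialization

Each annotation maps to an RDF graph with a provenance part
(`oa:motivatedBy`, `oa:annotatedAt`, `oa:annotatedBy` with the agent's name
and institution — never the e-mail address, which is not public), and per
annotated element one specific target (`oa:hasSource` = record URI,
`oa:hasSelector` = FragmentSelector, `oa:hasState` with `oa:when` = version
instant and `oa:cachedSource` = archived-revision URI) paired with one
specific body (expectation class as `rdf:type`, proposed value as
`rdf:value`, comment as `dcterms:description`).

Open Annotation's open-world reading of multiple bodies and targets is
"every body applies to every target" — not what a multi-element annotation
means. The pairing is therefore carried by an explicit `oa:hasScope` soft
link from each body to its target, and reconstruction relies on those links
*alone*: a graph whose scope links are removed is rejected as malformed
rather than guessed at (tested). The scope relation is a bijection between
bodies and targets.

Design choices worth recording:

* **Fragment URIs instead of blank nodes** for bodies, targets, states and
  selectors (`…#body-1`, `…#target-1`, …). Curatorial annotations must
  reference the annotated element's body *in another graph* via
  `oa:hasScope`; blank nodes are not referenceable across documents.
  Fragment URIs make every node addressable while keeping graphs
  self-contained.
* **Expectation classes as body `rdf:type`**, minted in the application
  namespace, matching the element-mapping table of the underlying model.
* **`oa:cachedSource` points at the archived revision's URI**; since the
  5-part id encodes the format, this single link also carries the record
  document format.
* Motivation classes subclass `oa:editing` (regular), `oa:replying`
  (curatorial) and `oa:linking` (batch); decision options subclass
  `decision:Option`. `oa_vocabulary_graph()` emits these axioms;
  `oa_terms()` lists every mapped property exactly once.
* A curatorial comment is written as `dcterms:description`; the variant that
  attaches it via the body's `oa:hasSource` is accepted on input only.
* The `oa`, `dcterms`, `rdf`, `rdfs`, `xsd`, `foaf` namespaces are standard;
  the application and decision namespaces default to stable `example.org`
  URIs and are configurable (`set_namespaces()`), as is the base URI under
  which annotation and record resources are minted.
* Batch graphs have **no body** and one `oa:hasTarget` per member.

Because no R RDF library is available to this package, the triple container,
the Turtle writer and subset parser, and the RDF/XML writer and reader are
implemented here. The writers emit a deliberately regular dialect (prefixed
vocabulary terms, full URIs for resources, grouped subjects); the parsers
accept that dialect plus common variants (`a`, object lists, blank-node
labels, typed node elements). Statement row order is preserved, which the
annotation round-trip uses to retain element and member order — RDF graph
*comparison* (`graph_isomorphic()`) is order-insensitive and matches blank
nodes by signature refinement. Round-trips through both syntaxes are
verified against an independent RDF library in the test suite.

## Query, subscriptions, notifications

Eleven filter types are implemented (species, genus, family, collector name
and number, country, institution/collection/catalogue codes, identified-by,
annotator). The filter → element-path mapping is configuration; the defaults
cover both the ABCD-like dialect (e.g. country →
`…/Gathering/Country/Name`) and simple Darwin Core (`country`). "Family"
matches the higher-taxon name element by local name — the synthetic records
only emit family-rank higher taxa, so a rank predicate would add nothing
here; a schema with mixed ranks would configure a stricter path. Matching is
case-insensitive substring by default, switchable to exact; criteria combine
conjunctively; drafts are never searchable.

Subscriptions come in three topics: own annotated records (created
automatically on an agent's first publication), curated collections
(created automatically with the curator role) and filter-based. Notification
fan-out on publication collects: prior annotators of the same record,
curators of the record's collection, matching filter subscribers, and — only
where no curator is registered — fallback contacts taken from the record's
e-mail elements and/or addresses supplied at publication. One message per
recipient per event; the acting agent is never notified of their own
publication. Delivery is an inspectable outbox (`outbox_tbl()`,
`drain_outbox()`); mail transport is out of scope. Filter matching reuses
the query engine, so query and notification semantics cannot drift; the
test suite additionally checks the fan-out against an independently coded
brute-force evaluation of all subscriptions.

## Access control

Agents are trusted identities in a local profile store —
authentication, sessions and transport security are outside the model.
Authorization is permission-based, grouped into roles: a curator role is
keyed by (institution, collection) and acts as a collection-scoped wildcard,
while per-record permissions are materialized at import time for audit.
That import-time synchronization means a curator is authorized on every
current and future record of their collection without re-assignment —
property-tested over random import histories. Reading published annotations
never requires authorization; drafts are readable only by their owner.
Curation targets annotations (not revisions), so annotations that ended up
on historic revisions can still be curated.

## The synthetic generator

`generate_dataset()` produces desk-scale records in a documented
ABCD-2.06-like subset (`DataSets/DataSet/Units/Unit` with identifier,
identification, higher-taxon, gathering and contact elements) or a flat
simple-Darwin-Core dialect. Every record carries a unique triple, an element
for each filter type and each template path, and a contact e-mail for the
fallback-notification rule. A single integer seed drives all randomness;
the same specification yields a byte-identical corpus.
`permute_document()` shuffles sibling and attribute order and re-flows
whitespace (always similar to its input); `mutate_document()` appends a
marker to exactly one text value (always dissimilar).

What the generator deliberately does **not** emulate: schema-valid ABCD 2.06
(no XSD validation is performed anywhere), mixed element content, CDATA and
entity edge cases, multiple units per document, repeated identifications,
or free-text fields with markup. Passing the property suites therefore
demonstrates the versioning, similarity and serialization *logic*, not
robustness against every real-world provider document; the parser-level
behaviour for exotic XML follows libxml2's defaults.

## Problem sizes and numeric choices

The property suites run at the scale the checks are stated at: 1000
generated documents for the similarity properties, 500-step random import
scripts for the versioning state machine, 500 random annotations for the
Open Annotation round trip, randomized multi-agent scenario matrices for
notification fan-out, and 70–80-step import histories for the authorization
property. The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities at moderately reduced sizes (300 documents, 200 imports,
150 round trips, 25 events) — rates are size-stable, and every run
recomputes them from scratch under the seed passed on the command line.

Other numeric conventions: epoch-millisecond values are held as doubles
(exact far beyond any plausible date; R integers are 32-bit), version and id
collisions bump by +1 ms, and all deterministic orderings (canonical keys,
listing and query output) use radix sort for locale independence.

## Known limitations

* Single-writer, in-process store; `store_save()`/`store_open()` persist to
  a directory of plain files (raw XML per revision, Turtle per annotation)
  but there is no concurrent-access protocol.
* No HTTP services or SPARQL endpoint; the JSON metadata payloads and
  Turtle/RDF-XML exports are produced as values/files instead.
* Attribute- and text-node selectors are not generated (element selectors
  only), and selectors are not healed across revisions.
* The Turtle parser covers the dialect this package and common tools emit,
  not the full grammar (no collections, no multi-line literals, no relative
  IRI resolution).
* The later (2016/2017) Web Annotation vocabulary revisions are not
  targeted; the serialization follows the earlier Open Annotation model
  deliberately.
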