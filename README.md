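# collann

Versioned archiving and structured annotation of biodiversity collection
records.

## The problem

Billions of preserved specimens are documented by XML records (ABCD, Darwin
Core) served through biodiversity data portals. Researchers — taxonomists
above all — have always annotated the physical sheets: a revised
determination, a corrected locality, a type-status note. Online, that
pathway breaks: provider records change silently, portals offer at best
free-text feedback, and nothing routes a structured correction back to the
collection's curator. An annotation that points at a live record can be
orphaned the day the provider edits it.

`collann` implements the repository side of a digital annotation workflow
for schema-based records, for data curators and infrastructure developers in
collection informatics:

* **Persistent versioned identifiers.** A record revision is named by
  `institution:collection:catalogueNumber:version:format` — the community's
  *triple identifier* extended with the import instant in epoch milliseconds
  and the data-format namespace prefix, e.g.
  `BGBM:Herbarium+Berolinense:B+18+0014862:1379406965371:abcd2.06b`.
  Annotation ids are `authority:system:creationMs`.
* **Order-insensitive similarity.** Two documents are the same revision iff
  they contain the same elements and attributes (including values)
  regardless of order — formally, equality of the multiset
  {(name path, attribute set, normalized text)} over all element nodes.
  Re-serialized or reordered documents re-use the archived revision; any
  value change demotes it to *historic* (no longer annotatable) and archives
  a new current revision, raw bytes bit-exact.
* **Structured annotations.** Elements are addressed by XPath selectors
  (`/` = whole-record comment); each annotated element carries an
  expectation (`Add` | `Remove` | `Update`), a proposed value and/or a
  comment. Curatorial annotations record per-element decisions
  (`Accepted` | `Rejected` | `Undecided` | `Update`) on published
  annotations; batch annotations link identical annotations across records.
* **W3C Open Annotation serialization.** Each annotation renders to RDF
  (Turtle or RDF/XML) with specific body/target pairs soft-linked by
  `oa:hasScope`, fragment selectors conforming to XPointer, and
  `oa:hasState`/`oa:cachedSource` pinning the archived revision; graphs
  parse back losslessly.
* **Query, subscriptions, outbox, access control.** Eleven filter types
  (species … annotator) drive both queries and subscription matching;
  publication events fan out to prior annotators, collection curators,
  filter subscribers and — where no curator exists — fallback contacts from
  the record metadata. Curator roles are collection-scoped and synchronized
  automatically at import time.

## Worked example

```r
library(collann)
set_id_authority("BGBM")
st <- annostore(authority = "BGBM")

docs <- generate_dataset(2, seed = 42)       # synthetic ABCD-like records
d <- docs[[1]]

import_record(st, d, now = as.POSIXct("2013-09-17 08:36:05.371", tz = "UTC"))
#> <import_outcome> first -> BGBM:Herbarium+Berolinense:B+42+0000001:1379406965371:abcd2.06b

import_record(st, permute_document(d, 1), now = Sys.time())$kind
#> [1] "reused"

out3 <- import_record(st, mutate_document(d, 3),
                      now = as.POSIXct("2014-01-01", tz = "UTC"))
out3
#> <import_outcome> new_revision -> BGBM:Herbarium+Berolinense:B+42+0000001:1388534400000:abcd2.06b
#>   demoted: BGBM:Herbarium+Berolinense:B+42+0000001:1379406965371:abcd2.06b
```

The first import archives the document and mints its id from the import
instant (1379406965371 ms = 2013-09-17T08:36:05.371Z). A shuffled,
re-indented copy is *similar* and changes nothing. A copy with one changed
value becomes the new current revision; the old one is flagged historic and
can no longer be annotated.

```r
carl <- agent("Carl Curator", "BGBM", "carl@example.org")
assign_curator_role(st, carl, d$triple$institution, d$triple$collection)

ada <- agent("Ada Botanist", "BGBM", "ada@example.org")
sel <- build_element_xpath(d, xml2::xml_find_first(
  d$xml, "//*[local-name()='FullScientificNameString']"))
a <- build_annotation("Determination", ada, out3$revision$id,
  list(annotated_element(sel, "Update", value = "Cremastosperma brevipes",
                         comment = "matches the 2006 revision")),
  now = as.POSIXct("2014-02-02 10:00:00", tz = "UTC"))
id <- save_draft(st, a, ada)
publish_annotation(st, id, ada)

outbox_tbl(st)[, 1:3]
#> # A tibble: 1 × 3
#>   recipient    reason              annotation
#>   <chr>        <chr>               <chr>
#> 1 carl-curator curated_collections BGBM:collann:1391335200000

str(annotation_metadata_json(st, id))
#> List of 4
#>  $ uri      : chr "http://example.org/collann/annotation/BGBM:collann:1391335200000"
#>  $ annotator: chr "Ada Botanist"
#>  $ type     : chr "Determination"
#>  $ date     : chr "2014-02-02T10:00:00.000Z"
```

Publication makes the annotation immutable and public (name and institution
visible, e-mail never), and queues one notification per recipient — here the
collection's curator. `render_graph(to_oa(a), "turtle")` serializes the
annotation to Open Annotation RDF; `query_annotations(st, c(Country =
"Peru"))` finds annotations by record content. A command-line front end over
the same functions, with a file-backed store, ships as
`inst/cli/collann.R` (try `Rscript inst/cli/collann.R demo --store demo`).

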