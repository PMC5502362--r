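# The versioned repository.
#
# An in-process store of record revisions and annotations.  Imports compare
# the incoming document against the *current* revision of its
# (triple, format) chain: a similar document re-uses the archived revision,
# a dissimilar one demotes it to "historic" and becomes the new current
# revision.  Only current revisions can be annotated.  Annotations live in a
# draft state visible only to their owner until published; published
# annotations are immutable public objects.  The store also keeps agents,
# curator roles, materialized permissions, subscriptions, the notification
# outbox and the publication event log, so the curatorial workflow runs
# end-to-end in one object.  `store_save()`/`store_open()` persist it as a
# directory of plain files (raw XML per revision, Turtle per annotation).

#' Create an annotation repository store
#'
#' @param authority Organisation code used when minting annotation ids in
#'   this store.
#' @param system System instance name for minted ids.
#' @param base_uri Base URI for annotation and record resources.
#' @return An object of class `annostore` (environment-backed; functions that
#'   take a store mutate it in place).
#' @examples
#' st <- annostore()
#' @export
annostore <- function(authority = "DEMO", system = "collann",
                      base_uri = default_base_uri()) {
  st <- new.env(parent = emptyenv())
  st$records <- list()       # encoded record id -> revision entry
  st$chains <- list()        # chain key -> encoded ids in version order
  st$annotations <- list()   # encoded annotation id -> list(obj, state, owner, ...)
  st$agents <- list()
  st$roles <- list()
  st$permissions <- tibble(action = character(), record = character(),
                           institution = character(), collection = character())
  st$subscriptions <- list()
  st$outbox <- list()
  st$events <- list()
  st$authority <- authority
  st$system <- system
  st$base_uri <- base_uri
  st$filter_map <- default_filter_map()
  class(st) <- "annostore"
  st
}

#' @export
print.annostore <- function(x, ...) {
  n_pub <- sum(map_chr(x$annotations, "state") == "published")
  cat("<annostore> ", length(x$records), " revision(s) in ", length(x$chains),
      " chain(s); ", length(x$annotations), " annotation(s) (", n_pub,
      " published); ", length(x$agents), " agent(s)\n", sep = "")
  invisible(x)
}

chain_key <- function(triple, format_prefix) {
  paste(format_triple_id(triple), escape_component(format_prefix), sep = ":")
}

# -- record import ------------------------------------------------------------

#' Import a record document into the repository
#'
#' The document is compared for similarity against the current revision
#' archived for the same triple identifier and document format. Three
#' outcomes are possible: `"first"` (no revision archived yet), `"reused"`
#' (a similar current revision exists; nothing changes, the archived
#' revision is returned) and `"new_revision"` (a dissimilar current revision
#' exists; it is demoted to historic — it cannot be annotated any more — and
#' the import becomes the new current revision). Raw bytes are archived
#' bit-exact. Curator permissions for new revisions are synchronized
#' automatically (see [sync_permissions_on_import()]).
#'
#' If the import instant does not exceed the newest archived version of the
#' chain (same-millisecond import or clock regression), the version is
#' bumped to the next free millisecond so ids stay unique and ordered.
#'
#' @param store An [annostore()].
#' @param doc A [parse_record_xml()] document.
#' @param now Import instant (`POSIXct` or epoch milliseconds).
#' @return An object of class `import_outcome`: list with `kind`, `revision`
#'   and (for `new_revision`) `demoted`.
#' @export
import_record <- function(store, doc, now = Sys.time()) {
  stopifnot(inherits(store, "annostore"), inherits(doc, "record_document"))
  ms <- as_ms(now)
  key <- chain_key(doc$triple, doc$format_prefix)
  chain <- store$chains[[key]]
  canon <- canonicalize_document(doc)

  if (!is.null(chain) && length(chain) > 0) {
    newest <- store$records[[chain[length(chain)]]]
    if (ms <= newest$id$version_ms) ms <- newest$id$version_ms + 1
    if (identical(canon$keys, newest$canonical_keys)) {
      outcome <- new_outcome("reused", revision_view(newest), NULL)
      sync_permissions_on_import(store, outcome)
      return(outcome)
    }
    # dissimilar: demote the current revision
    store$records[[newest$id$encoded]]$status <- "historic"
    demoted <- revision_view(store$records[[newest$id$encoded]])
    entry <- new_revision_entry(doc, ms, canon)
    store$records[[entry$id$encoded]] <- entry
    store$chains[[key]] <- c(chain, entry$id$encoded)
    outcome <- new_outcome("new_revision", revision_view(entry), demoted)
  } else {
    entry <- new_revision_entry(doc, ms, canon)
    store$records[[entry$id$encoded]] <- entry
    store$chains[[key]] <- entry$id$encoded
    outcome <- new_outcome("first", revision_view(entry), NULL)
  }
  sync_permissions_on_import(store, outcome)
  outcome
}

new_revision_entry <- function(doc, ms, canon) {
  list(
    id = record_id(doc$triple, ms, doc$format_prefix),
    document = doc,
    status = "current",
    imported_at = ms,
    canonical_keys = canon$keys
  )
}

revision_view <- function(entry) {
  structure(
    list(id = entry$id, document = entry$document, status = entry$status,
         imported_at = entry$imported_at),
    class = "record_revision"
  )
}

#' @export
print.record_revision <- function(x, ...) {
  cat("<record_revision> ", x$id$encoded, " [", x$status, "]\n", sep = "")
  invisible(x)
}

new_outcome <- function(kind, revision, demoted) {
  structure(list(kind = kind, revision = revision, demoted = demoted),
            class = "import_outcome")
}

#' @export
print.import_outcome <- function(x, ...) {
  cat("<import_outcome> ", x$kind, " -> ", x$revision$id$encoded, "\n", sep = "")
  if (!is.null(x$demoted)) cat("  demoted: ", x$demoted$id$encoded, "\n", sep = "")
  invisible(x)
}

#' Retrieve an archived record revision
#'
#' @param store An [annostore()].
#' @param id A [record_id()] or encoded 5-part id string.
#' @return A `record_revision` with the bit-exact archived bytes in
#'   `$document$raw`.
#' @export
get_revision <- function(store, id) {
  enc <- encode_any_id(id, "record_id")
  entry <- store$records[[enc]]
  if (is.null(entry)) ca_abort("not-found", sprintf("No revision '%s' archived.", enc))
  revision_view(entry)
}

encode_any_id <- function(id, class_wanted) {
  if (is.character(id)) id <- parse_persistent_id(id)
  if (!inherits(id, class_wanted)) {
    ca_abort("malformed-id", sprintf("Expected a %s.", class_wanted))
  }
  id$encoded
}

#' List the current revision of every record chain
#'
#' @param store An [annostore()].
#' @return Character vector of encoded ids, one per (triple, format) chain,
#'   sorted for deterministic output.
#' @export
list_current_records <- function(store) {
  ids <- map_chr(store$chains, function(chain) chain[length(chain)])
  current <- unname(ids[map_chr(ids, function(i) store$records[[i]]$status) == "current"])
  sort(current, method = "radix")
}

# -- annotation lifecycle -----------------------------------------------------

#' Save an annotation draft
#'
#' Drafts are stored in the owner's private store: they are invisible to
#' everyone else and never returned by queries. Regular annotations must
#' target a *current* revision — historic revisions cannot be annotated any
#' more. Curatorial annotations must target a published annotation.
#'
#' @param store An [annostore()].
#' @param a A `ca_annotation`, `ca_curatorial` or `ca_batch` object.
#' @param owner The owning [agent()] (registered on first use) or a
#'   registered agent id.
#' @return The (possibly uniqueness-bumped) [annotation_id()] under
#'   which the draft is stored.
#' @export
save_draft <- function(store, a, owner) {
  stopifnot(inherits(store, "annostore"))
  owner_id <- resolve_agent(store, owner)
  if (inherits(a, "ca_annotation")) {
    enc <- a$record$encoded
    entry <- store$records[[enc]]
    if (is.null(entry)) {
      ca_abort("unknown-revision", sprintf("Record revision '%s' is not archived.", enc))
    }
    if (entry$status != "current") {
      ca_abort("historic-revision",
               "Historic revisions cannot be annotated any more; only the most recent one can.")
    }
  } else if (inherits(a, "ca_curatorial")) {
    tgt <- store$annotations[[a$target_annotation$encoded]]
    if (is.null(tgt) || tgt$state != "published") {
      ca_abort("target-not-published", "Curatorial annotations target published annotations.")
    }
  } else if (inherits(a, "ca_batch")) {
    for (m in a$members) {
      if (is.null(store$annotations[[m$encoded]])) {
        ca_abort("unknown-revision", sprintf("Batch member '%s' is not stored.", m$encoded))
      }
    }
  } else {
    ca_abort("malformed-id", "Not an annotation object.")
  }
  # ids are minted from the creation instant; bump to the next free
  # millisecond on collision so every stored annotation has a unique id
  while (!is.null(store$annotations[[a$id$encoded]])) {
    a$id <- annotation_id(a$id$authority, a$id$system, a$id$object_id + 1)
  }
  store$annotations[[a$id$encoded]] <- list(obj = a, state = "draft", owner = owner_id)
  a$id
}

#' Publish an annotation
#'
#' Publication moves the draft into the public store, where it is immutable
#' and searchable; the annotator's name and institution become public
#' metadata. Publishing a curatorial annotation requires curatorial rights
#' on the target record's collection. A publication event is recorded and
#' notification messages are fanned out to the outbox (see
#' [events_for_publication()]).
#'
#' @param store An [annostore()].
#' @param id The draft's [annotation_id()] (or encoded string).
#' @param actor The publishing agent (or agent id); must own the draft.
#' @param extra_contacts E-mail addresses to notify if no curator is
#'   registered for the record's collection.
#' @param now Publication instant.
#' @return The `publication_event`, invisibly usable for fan-out inspection.
#' @export
publish_annotation <- function(store, id, actor, extra_contacts = character(),
                               now = Sys.time()) {
  enc <- encode_any_id(id, "annotation_id")
  entry <- store$annotations[[enc]]
  if (is.null(entry)) ca_abort("not-found", sprintf("No annotation '%s'.", enc))
  if (entry$state == "published") {
    ca_abort("already-published", sprintf("Annotation '%s' is already published.", enc))
  }
  actor_id <- resolve_agent(store, actor)
  if (!identical(entry$owner, actor_id)) {
    ca_abort("not-owner", "Only the owner of a draft can publish it.")
  }
  a <- entry$obj
  if (inherits(a, "ca_curatorial")) {
    tgt <- store$annotations[[a$target_annotation$encoded]]$obj
    if (!authorize(store, actor_id, "curate_record", tgt$record)) {
      ca_abort("unauthorized-curation",
               "Publishing a curatorial annotation requires curatorial rights on the record's collection.")
    }
  }
  ms <- as_ms(now)
  store$annotations[[enc]]$state <- "published"
  store$annotations[[enc]]$published_at <- ms

  ev <- structure(
    list(
      annotation_id = a$id,
      kind = annotation_kind(a),
      actor = actor_id,
      agent_name = annotation_agent(a)$name,
      triples = annotation_triples(store, a),
      published_at = ms,
      extra_contacts = extra_contacts
    ),
    class = "publication_event"
  )
  store$events[[length(store$events) + 1L]] <- ev

  # first publication automatically subscribes the annotator to their records
  add_subscription(store, actor_id, "own_annotated_records")

  msgs <- events_for_publication(store, ev)
  store$outbox <- c(store$outbox, msgs)
  ev
}

annotation_kind <- function(a) {
  if (inherits(a, "ca_annotation")) "regular"
  else if (inherits(a, "ca_curatorial")) "curatorial"
  else "batch"
}

annotation_agent <- function(a) {
  if (inherits(a, "ca_annotation")) a$annotator
  else if (inherits(a, "ca_curatorial")) a$curator
  else a$creator
}

# the record triples an annotation (transitively) refers to
annotation_triples <- function(store, a) {
  if (inherits(a, "ca_annotation")) {
    list(a$record$triple)
  } else if (inherits(a, "ca_curatorial")) {
    tgt <- store$annotations[[a$target_annotation$encoded]]
    if (is.null(tgt)) list() else annotation_triples(store, tgt$obj)
  } else {
    out <- list()
    for (m in a$members) {
      entry <- store$annotations[[m$encoded]]
      if (!is.null(entry)) out <- c(out, annotation_triples(store, entry$obj))
    }
    unique(out)
  }
}

#' @export
print.publication_event <- function(x, ...) {
  cat("<publication_event> ", x$annotation_id$encoded, " (", x$kind, ") by ",
      x$actor, "\n", sep = "")
  invisible(x)
}

get_annotation_entry <- function(store, id) {
  enc <- encode_any_id(id, "annotation_id")
  entry <- store$annotations[[enc]]
  if (is.null(entry)) ca_abort("not-found", sprintf("No annotation '%s'.", enc))
  entry
}

#' Read an annotation object from the store
#'
#' Published annotations are public; drafts are only readable by their
#' owner (`reader`).
#'
#' @param store An [annostore()].
#' @param id Annotation id.
#' @param reader Agent (id) requesting access; needed for drafts.
#' @return The stored annotation object.
#' @export
get_annotation <- function(store, id, reader = NULL) {
  entry <- get_annotation_entry(store, id)
  if (entry$state != "published") {
    reader_id <- if (is.null(reader)) NULL else resolve_agent(store, reader)
    if (is.null(reader_id) || !identical(entry$owner, reader_id)) {
      ca_abort("draft-not-public", "Unpublished annotations are only visible to their owner.")
    }
  }
  entry$obj
}

# -- filter engine ------------------------------------------------------------

FILTER_TYPES <- c("Species", "Genus", "Family", "Collector name",
                  "Collector's number", "Country", "Institution code",
                  "Collection code", "Catalogue number", "Identified by",
                  "Annotator")

default_filter_map <- function() {
  list(
    "Species" = c("FullScientificNameString", "scientificName"),
    "Genus" = c("GenusOrMonomial", "genus"),
    "Family" = c("HigherTaxonName", "family"),
    "Collector name" = c("GatheringAgent", "recordedBy"),
    "Collector's number" = c("CollectorsFieldNumber", "fieldNumber"),
    "Country" = c("Country/Name", "country"),
    "Institution code" = c("SourceInstitutionID", "institutionCode"),
    "Collection code" = c("SourceID", "collectionCode"),
    "Catalogue number" = c("UnitID", "catalogNumber"),
    "Identified by" = c("IdentifiedBy", "identifiedBy"),
    "Annotator" = "provenance"
  )
}

#' Configure the filter-type to element-path mapping
#'
#' @param map Named list: filter type -> character vector of element path
#'   suffixes (local names joined by `/`). The `Annotator` entry is special
#'   and matches annotation provenance instead of record content.
#' @export
set_filter_map <- function(store, map) {
  stopifnot(inherits(store, "annostore"))
  store$filter_map <- map
  invisible(NULL)
}

validate_criteria <- function(store, criteria) {
  if (length(criteria) == 0) return(invisible(criteria))
  if (is.null(names(criteria)) || any(!nzchar(names(criteria)))) {
    ca_abort("unknown-filter-type", "Filter criteria must be a named collection.")
  }
  bad <- setdiff(names(criteria), FILTER_TYPES)
  if (length(bad)) {
    ca_abort("unknown-filter-type", sprintf(
      "Unknown filter type(s): %s.", paste(bad, collapse = ", ")
    ))
  }
  invisible(criteria)
}

# does one record canonical form match one criterion?
canon_matches <- function(store, keys_tbl, filter, value, exact = FALSE) {
  suffixes <- store$filter_map[[filter]]
  # namespace-expanded segments reduce to local names for matching
  paths <- gsub("\\{[^}]*\\}", "", keys_tbl$path)
  hit <- rep(FALSE, length(paths))
  for (sfx in suffixes) {
    hit <- hit | endsWith(paths, paste0("/", sfx))
  }
  texts <- keys_tbl$text[hit]
  texts <- texts[nzchar(texts)]
  if (length(texts) == 0) return(FALSE)
  if (exact) {
    any(tolower(texts) == tolower(value))
  } else {
    any(grepl(tolower(value), tolower(texts), fixed = TRUE))
  }
}

# conjunctive criteria match for one published annotation entry
annotation_matches <- function(store, entry, criteria, exact = FALSE) {
  a <- entry$obj
  for (f in names(criteria)) {
    v <- criteria[[f]]
    if (f == "Annotator") {
      nm <- annotation_agent(a)$name
      ok <- if (exact) tolower(nm) == tolower(v) else
        grepl(tolower(v), tolower(nm), fixed = TRUE)
      if (!ok) return(FALSE)
      next
    }
    # record-content criteria: resolve the annotation's record revision(s)
    recs <- annotation_record_entries(store, a)
    if (length(recs) == 0) return(FALSE)
    ok <- FALSE
    for (r in recs) {
      canon <- canonicalize_document(r$document)
      if (canon_matches(store, canon$elements, f, v, exact)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

annotation_record_entries <- function(store, a) {
  if (inherits(a, "ca_annotation")) {
    entry <- store$records[[a$record$encoded]]
    if (is.null(entry)) list() else list(entry)
  } else if (inherits(a, "ca_curatorial")) {
    tgt <- store$annotations[[a$target_annotation$encoded]]
    if (is.null(tgt)) list() else annotation_record_entries(store, tgt$obj)
  } else {
    out <- list()
    for (m in a$members) {
      e <- store$annotations[[m$encoded]]
      if (!is.null(e)) out <- c(out, annotation_record_entries(store, e$obj))
    }
    out
  }
}

#' Query published annotations by filter criteria
#'
#' All criteria must match (conjunction). Record-content criteria are
#' matched against the element values of the annotation's record revision;
#' `Annotator` matches the annotating agent's name. Matching is
#' case-insensitive substring by default. Drafts are never returned.
#'
#' @param store An [annostore()].
#' @param criteria Named character vector / list, names drawn from the
#'   implemented filter types (`Species`, `Genus`, `Family`,
#'   `"Collector name"`, `"Collector's number"`, `Country`,
#'   `"Institution code"`, `"Collection code"`, `"Catalogue number"`,
#'   `"Identified by"`, `Annotator`). Empty criteria match everything.
#' @param exact Use exact (case-insensitive) matching instead of substring.
#' @return Sorted character vector of encoded annotation ids.
#' @export
query_annotations <- function(store, criteria = list(), exact = FALSE) {
  stopifnot(inherits(store, "annostore"))
  validate_criteria(store, criteria)
  hits <- character()
  for (enc in names(store$annotations)) {
    entry <- store$annotations[[enc]]
    if (entry$state != "published") next
    if (annotation_matches(store, entry, criteria, exact)) hits <- c(hits, enc)
  }
  sort(hits, method = "radix")
}

#' List published annotations referring to a record
#'
#' With a [triple_id()], annotations on *all* revisions of the triple are
#' returned (the version history of annotations on historic revisions is
#' included); with a [record_id()], only annotations bound to that
#' exact revision.
#'
#' @param store An [annostore()].
#' @param record A `triple_id`, `record_id`, or encoded id string.
#' @return Sorted character vector of encoded annotation ids.
#' @export
annotations_for_record <- function(store, record) {
  stopifnot(inherits(store, "annostore"))
  if (is.character(record)) record <- parse_persistent_id(record)
  hits <- character()
  for (enc in names(store$annotations)) {
    entry <- store$annotations[[enc]]
    if (entry$state != "published") next
    a <- entry$obj
    rec_ids <- annotation_record_ids(store, a)
    ok <- if (inherits(record, "triple_id")) {
      any(map_lgl(rec_ids, function(r) identical(unclass(r$triple), unclass(record))))
    } else {
      any(map_chr(rec_ids, "encoded") == record$encoded)
    }
    if (ok) hits <- c(hits, enc)
  }
  sort(hits, method = "radix")
}

annotation_record_ids <- function(store, a) {
  if (inherits(a, "ca_annotation")) {
    list(a$record)
  } else if (inherits(a, "ca_curatorial")) {
    tgt <- store$annotations[[a$target_annotation$encoded]]
    if (is.null(tgt)) list() else annotation_record_ids(store, tgt$obj)
  } else {
    out <- list()
    for (m in a$members) {
      e <- store$annotations[[m$encoded]]
      if (!is.null(e)) out <- c(out, annotation_record_ids(store, e$obj))
    }
    out
  }
}

#' Public metadata of a published annotation, as a JSON-ready list
#'
#' Returns the resolvable URI, the annotator's name, the annotation type and
#' the annotation date (ISO-8601). The annotator's e-mail address is not
#' public and never included.
#'
#' @param store An [annostore()].
#' @param id Annotation id.
#' @return A named list; serialize with
#'   `jsonlite::toJSON(x, auto_unbox = TRUE)`.
#' @export
annotation_metadata_json <- function(store, id) {
  entry <- get_annotation_entry(store, id)
  if (entry$state != "published") {
    ca_abort("draft-not-public", "Draft metadata is not public.")
  }
  a <- entry$obj
  type <- switch(annotation_kind(a),
    regular = a$motivation,
    curatorial = "Curatorial",
    batch = a$motivation
  )
  list(
    uri = annotation_uri(a$id, store$base_uri),
    annotator = annotation_agent(a)$name,
    type = type,
    date = format_instant(a$created_at)
  )
}
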