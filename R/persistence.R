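# File-backed persistence for the repository store.
#
# The store serializes to a directory of plain files: one raw XML file per
# archived revision under a directory hierarchy derived from the persistent
# identifier (institution/collection/unit/version.format.xml), one Turtle
# file per annotation, and JSON tables for agents, roles, permissions,
# subscriptions, outbox and events.  `store_open()` reconstructs the store;
# annotation objects are rebuilt from their Open Annotation graphs, so the
# on-disk format is the public exchange format, not a private dump.

path_segment <- function(x) gsub("/", "%2F", x, fixed = TRUE)

revision_path <- function(id) {
  parts <- strsplit(id$encoded, ":", fixed = TRUE)[[1]]
  file.path("records", path_segment(parts[1]), path_segment(parts[2]),
            path_segment(parts[3]), paste0(parts[4], ".", path_segment(parts[5]), ".xml"))
}

annotation_path <- function(enc) {
  file.path("annotations", paste0(gsub(":", "_", enc, fixed = TRUE), ".ttl"))
}

#' Save a store to a directory
#'
#' @param store An [annostore()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
store_save <- function(store, dir) {
  stopifnot(inherits(store, "annostore"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # raw record bytes, bit-exact
  rec_meta <- list()
  for (enc in names(store$records)) {
    entry <- store$records[[enc]]
    rel <- revision_path(entry$id)
    abs <- file.path(dir, rel)
    dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
    writeLines(entry$document$raw, abs, sep = "", useBytes = TRUE)
    rec_meta[[length(rec_meta) + 1L]] <- list(
      id = enc, status = entry$status, imported_at = entry$imported_at,
      format = entry$document$format_prefix,
      triple = unclass(entry$id$triple), path = rel
    )
  }
  ann_meta <- list()
  for (enc in names(store$annotations)) {
    entry <- store$annotations[[enc]]
    rel <- annotation_path(enc)
    abs <- file.path(dir, rel)
    dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
    writeLines(render_graph(to_oa(entry$obj, store$base_uri), "turtle"), abs, sep = "")
    ann_meta[[length(ann_meta) + 1L]] <- list(
      id = enc, state = entry$state, owner = entry$owner,
      published_at = entry$published_at %||% NULL, path = rel
    )
  }
  state <- list(
    authority = store$authority, system = store$system, base_uri = store$base_uri,
    records = rec_meta,
    annotations = ann_meta,
    agents = lapply(unname(store$agents), unclass),
    roles = unname(store$roles),
    permissions = store$permissions,
    subscriptions = store$subscriptions,
    outbox = store$outbox,
    events = lapply(store$events, function(ev) list(
      annotation_id = ev$annotation_id$encoded, kind = ev$kind, actor = ev$actor,
      agent_name = ev$agent_name,
      triples = lapply(ev$triples, unclass),
      published_at = ev$published_at,
      extra_contacts = as.list(ev$extra_contacts)
    )),
    filter_map = store$filter_map
  )
  jsonlite::write_json(state, file.path(dir, "state.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' Open a store from a directory
#'
#' @param dir A directory written by [store_save()].
#' @return An [annostore()].
#' @export
store_open <- function(dir) {
  state_path <- file.path(dir, "state.json")
  if (!file.exists(state_path)) {
    ca_abort("not-found", sprintf("'%s' is not a saved store (no state.json).", dir))
  }
  state <- jsonlite::read_json(state_path, simplifyVector = FALSE)
  st <- annostore(authority = state$authority, system = state$system,
                  base_uri = state$base_uri)
  st$filter_map <- lapply(state$filter_map, function(x) unlist(x, use.names = FALSE))
  for (ag in state$agents) {
    register_agent(st, agent(ag$name, ag$institution, ag$email, id = ag$id))
  }
  for (r in state$roles) {
    r$members <- unlist(r$members, use.names = FALSE) %||% character()
    st$roles[[role_key(r$institution, r$collection)]] <- r
  }
  if (length(state$permissions)) {
    st$permissions <- bind_rows(lapply(state$permissions, as_tibble))
  }
  st$subscriptions <- lapply(state$subscriptions, function(s) {
    s$criteria <- if (is.null(s$criteria)) NULL else lapply(s$criteria, as.character)
    s
  })
  st$outbox <- state$outbox
  for (rm_ in state$records) {
    raw <- readChar(file.path(dir, rm_$path), file.size(file.path(dir, rm_$path)),
                    useBytes = TRUE)
    triple <- triple_id(rm_$triple$institution, rm_$triple$collection, rm_$triple$unit)
    doc <- parse_record_xml(raw, rm_$format, triple = triple)
    id <- parse_persistent_id(rm_$id)
    st$records[[rm_$id]] <- list(
      id = id, document = doc, status = rm_$status,
      imported_at = as.numeric(rm_$imported_at),
      canonical_keys = canonicalize_document(doc)$keys
    )
    key <- chain_key(triple, rm_$format)
    st$chains[[key]] <- c(st$chains[[key]], rm_$id)
  }
  # chains in version order
  st$chains <- lapply(st$chains, function(chain) {
    chain[order(vapply(chain, function(e) st$records[[e]]$id$version_ms, numeric(1)))]
  })
  for (am in state$annotations) {
    ttl <- readChar(file.path(dir, am$path), file.size(file.path(dir, am$path)),
                    useBytes = TRUE)
    obj <- oa_to_annotation(parse_graph(ttl, "turtle"))
    entry <- list(obj = obj, state = am$state, owner = am$owner)
    if (!is.null(am$published_at)) entry$published_at <- as.numeric(am$published_at)
    st$annotations[[am$id]] <- entry
  }
  st$events <- lapply(state$events, function(ev) {
    structure(
      list(
        annotation_id = parse_persistent_id(ev$annotation_id),
        kind = ev$kind, actor = ev$actor, agent_name = ev$agent_name,
        triples = lapply(ev$triples, function(t) {
          triple_id(t$institution, t$collection, t$unit)
        }),
        published_at = as.numeric(ev$published_at),
        extra_contacts = unlist(ev$extra_contacts, use.names = FALSE) %||% character()
      ),
      class = "publication_event"
    )
  })
  st
}
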