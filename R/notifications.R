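# Subscriptions and notification fan-out.
#
# Agents subscribe to publication events on three topics: records they have
# previously annotated (created automatically on their first publication),
# records within collections they curate (created automatically when the
# curator role is assigned), and annotations matching a set of filter
# criteria.  Delivery is an inspectable outbox rather than a mail transport;
# the filter matching reuses the repository query engine so query and
# notification semantics cannot drift.

SUBSCRIPTION_TOPICS <- c("own_annotated_records", "curated_collections", "filter_based")

#' Add a subscription
#'
#' @param store An [annostore()].
#' @param subscriber A registered [agent()] or agent id.
#' @param topic One of `"own_annotated_records"`, `"curated_collections"`,
#'   `"filter_based"`.
#' @param criteria Filter criteria (named, filter types as in
#'   [query_annotations()]); required for and only meaningful with
#'   `"filter_based"`.
#' @return The subscription id (idempotent: re-adding an identical
#'   subscription returns the existing id).
#' @export
add_subscription <- function(store, subscriber, topic, criteria = NULL) {
  stopifnot(inherits(store, "annostore"))
  sub_id <- resolve_agent(store, subscriber)
  if (!topic %in% SUBSCRIPTION_TOPICS) {
    ca_abort("invalid-criteria", sprintf(
      "Unknown topic '%s'; use one of %s.", topic,
      paste(SUBSCRIPTION_TOPICS, collapse = ", ")
    ))
  }
  if (topic == "filter_based") {
    if (is.null(criteria) || length(criteria) == 0) {
      ca_abort("invalid-criteria", "A filter-based subscription needs criteria.")
    }
    validate_criteria(store, criteria)
  } else if (!is.null(criteria)) {
    ca_abort("invalid-criteria", "Only filter-based subscriptions carry criteria.")
  }
  for (s in store$subscriptions) {
    if (identical(s$subscriber, sub_id) && identical(s$topic, topic) &&
        identical(s$criteria, criteria)) {
      return(s$id)
    }
  }
  id <- paste0("sub-", length(store$subscriptions) + 1L)
  store$subscriptions[[length(store$subscriptions) + 1L]] <-
    list(id = id, subscriber = sub_id, topic = topic, criteria = criteria)
  id
}

#' Subscriptions as a tibble
#' @param store An [annostore()].
#' @return A tibble with columns `id`, `subscriber`, `topic`, `criteria`.
#' @export
subscriptions_tbl <- function(store) {
  tibble(
    id = map_chr(store$subscriptions, "id"),
    subscriber = map_chr(store$subscriptions, "subscriber"),
    topic = map_chr(store$subscriptions, "topic"),
    criteria = map(store$subscriptions, "criteria")
  )
}

#' Does a publication event match filter criteria?
#'
#' Same conjunctive semantics as [query_annotations()]: record-content
#' criteria are matched against the published annotation's record revision,
#' `Annotator` against the annotation's provenance.
#'
#' @param store An [annostore()].
#' @param criteria Named filter criteria.
#' @param ev A `publication_event`.
#' @return `TRUE` or `FALSE`.
#' @export
match_filter_criteria <- function(store, criteria, ev) {
  stopifnot(inherits(ev, "publication_event"))
  validate_criteria(store, criteria)
  entry <- store$annotations[[ev$annotation_id$encoded]]
  if (is.null(entry)) return(FALSE)
  annotation_matches(store, entry, criteria)
}

#' Compute the notification fan-out for a publication event
#'
#' Recipients are: (a) agents who previously annotated the same record
#' (through their automatic own-records subscription), (b) registered
#' curators of the record's collection, (c) filter-based subscribers whose
#' criteria match, and (d) — only when no curator is registered for the
#' collection — fallback contacts taken from the record metadata's e-mail
#' elements and/or addresses the annotator supplied at publication.
#' Recipients are deduplicated: one message per recipient per event, and the
#' acting agent is never notified about their own publication.
#'
#' @param store An [annostore()].
#' @param ev A `publication_event` (as returned by [publish_annotation()]).
#' @return List of outbox messages: `recipient`, `reason`, `annotation`,
#'   `published_at`.
#' @export
events_for_publication <- function(store, ev) {
  stopifnot(inherits(store, "annostore"), inherits(ev, "publication_event"))
  recipients <- character()
  reasons <- character()
  add <- function(who, why) {
    keep <- !(who %in% recipients) & who != ev$actor
    recipients <<- c(recipients, who[keep])
    reasons <<- c(reasons, rep(why, sum(keep)))
  }

  # (a) prior annotators of the same record(s), via their automatic topic
  own_subs <- unique(map_chr(
    keep(store$subscriptions, function(s) s$topic == "own_annotated_records"),
    "subscriber"
  ))
  prior <- prior_annotators(store, ev)
  add(intersect(prior, own_subs), "own_annotated_records")

  # (b) curators registered for the record's collection(s)
  curators <- character()
  uncurated <- list()
  for (tr in ev$triples) {
    members <- collection_curators(store, tr$institution, tr$collection)
    if (length(members) == 0) {
      uncurated[[length(uncurated) + 1L]] <- tr
    } else {
      curators <- c(curators, members)
    }
  }
  add(unique(curators), "curated_collections")

  # (c) filter-based subscribers with matching criteria
  for (s in store$subscriptions) {
    if (s$topic != "filter_based") next
    if (match_filter_criteria(store, s$criteria, ev)) add(s$subscriber, "filter_based")
  }

  # (d) fallback contacts where no curator is registered
  if (length(uncurated) > 0) {
    contacts <- unique(c(record_contacts(store, ev, uncurated), ev$extra_contacts))
    add(contacts, "fallback_contact")
  }

  purrr::map2(recipients, reasons, function(r, why) {
    list(recipient = r, reason = why,
         annotation = ev$annotation_id$encoded, published_at = ev$published_at)
  })
}

prior_annotators <- function(store, ev) {
  triple_keys <- map_chr(ev$triples, format_triple_id)
  out <- character()
  for (enc in names(store$annotations)) {
    if (enc == ev$annotation_id$encoded) next
    entry <- store$annotations[[enc]]
    if (entry$state != "published") next
    if (!inherits(entry$obj, "ca_annotation")) next
    if (format_triple_id(entry$obj$record$triple) %in% triple_keys) {
      out <- c(out, entry$owner)
    }
  }
  unique(out)
}

# e-mail elements found in the metadata of the event's (uncurated) records
record_contacts <- function(store, ev, triples) {
  out <- character()
  keys <- map_chr(triples, format_triple_id)
  entry <- store$annotations[[ev$annotation_id$encoded]]
  if (is.null(entry)) return(out)
  for (r in annotation_record_entries(store, entry$obj)) {
    if (!format_triple_id(r$document$triple) %in% keys) next
    canon <- canonicalize_document(r$document)
    paths <- gsub("\\{[^}]*\\}", "", canon$elements$path)
    hits <- endsWith(paths, "/Email") | endsWith(paths, "/EmailAddress")
    out <- c(out, canon$elements$text[hits & nzchar(canon$elements$text)])
  }
  unique(out)
}

#' Inspect or drain the notification outbox
#'
#' @param store An [annostore()].
#' @return `outbox_tbl()` returns a tibble (`recipient`, `reason`,
#'   `annotation`, `published_at`); `drain_outbox()` returns it and empties
#'   the outbox.
#' @export
outbox_tbl <- function(store) {
  tibble(
    recipient = map_chr(store$outbox, "recipient"),
    reason = map_chr(store$outbox, "reason"),
    annotation = map_chr(store$outbox, "annotation"),
    published_at = vapply(store$outbox, function(m) m$published_at, numeric(1))
  )
}

#' @rdname outbox_tbl
#' @export
drain_outbox <- function(store) {
  out <- outbox_tbl(store)
  store$outbox <- list()
  out
}
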