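# Permission- and role-based authorization.
#
# Authorization is built on permissions, grouped by role definitions —
# typically curator rights for a given collection.  Curator roles are
# collection-scoped wildcards: a curator of (institution, collection) may
# curate every current and future record of that collection.  Whenever an
# import creates a new record revision, a per-record permission is
# materialized and attached to the collection's role automatically, so role
# definitions never go stale.  Agents are trusted identities in a local
# profile store; transport-level authentication is out of scope.

#' Register an agent
#'
#' Registration is required before creating annotations; reading published
#' annotations never requires it.
#'
#' @param store An [annostore()].
#' @param ag An [agent()].
#' @return The agent id, invisibly.
#' @export
register_agent <- function(store, ag) {
  stopifnot(inherits(store, "annostore"), inherits(ag, "ca_agent"))
  store$agents[[ag$id]] <- ag
  invisible(ag$id)
}

resolve_agent <- function(store, who) {
  if (inherits(who, "ca_agent")) {
    if (is.null(store$agents[[who$id]])) register_agent(store, who)
    return(who$id)
  }
  stopifnot(is.character(who), length(who) == 1)
  if (is.null(store$agents[[who]])) {
    ca_abort("unknown-agent", sprintf("Agent '%s' is not registered.", who))
  }
  who
}

role_key <- function(institution, collection) {
  paste("curator", institution, collection, sep = "\x1f")
}

collection_curators <- function(store, institution, collection) {
  role <- store$roles[[role_key(institution, collection)]]
  if (is.null(role)) character() else role$members
}

#' Assign the curator role for a collection
#'
#' The agent gains the right to curate — i.e. to publish curatorial
#' annotations on — all current and future records of the collection, and is
#' automatically subscribed to publication events on it. Assignment is
#' idempotent.
#'
#' @param store An [annostore()].
#' @param ag A registered [agent()] or agent id.
#' @param institution,collection The collection the role covers.
#' @return The updated role (name, institution, collection, members),
#'   invisibly.
#' @export
assign_curator_role <- function(store, ag, institution, collection) {
  agent_id <- resolve_agent(store, ag)
  key <- role_key(institution, collection)
  role <- store$roles[[key]] %||% list(
    name = sprintf("curator:%s/%s", institution, collection),
    institution = institution, collection = collection,
    members = character()
  )
  role$members <- union(role$members, agent_id)
  store$roles[[key]] <- role
  add_subscription(store, agent_id, "curated_collections")
  invisible(role)
}

#' Synchronize curator permissions after an import
#'
#' For `first` and `new_revision` outcomes, a curate permission for the new
#' revision is materialized and (through the collection-scoped role) becomes
#' effective for the collection's curators without re-assignment; `reused`
#' imports change nothing. [import_record()] calls this automatically; the
#' function is idempotent.
#'
#' @param store An [annostore()].
#' @param outcome An `import_outcome` from [import_record()].
#' @return Tibble of permission rows materialized for this outcome.
#' @export
sync_permissions_on_import <- function(store, outcome) {
  stopifnot(inherits(store, "annostore"), inherits(outcome, "import_outcome"))
  if (outcome$kind == "reused") {
    return(store$permissions[0, ])
  }
  id <- outcome$revision$id
  if (id$encoded %in% store$permissions$record) {
    return(store$permissions[store$permissions$record == id$encoded, ])
  }
  row <- tibble(
    action = "curate_record",
    record = id$encoded,
    institution = id$triple$institution,
    collection = id$triple$collection
  )
  store$permissions <- bind_rows(store$permissions, row)
  row
}

#' Authorization check
#'
#' * `curate_record`: `scope` is a record id (or `triple_id`); true when the
#'   agent is a member of the curator role of the record's collection or
#'   holds a matching direct permission.
#' * `publish_annotation`: `scope` is an annotation id; true when the agent
#'   owns the draft.
#' * `read_draft`: `scope` is an annotation id; drafts are readable only by
#'   their owner, published annotations by anyone.
#'
#' Unregistered agents are never authorized to write.
#'
#' @param store An [annostore()].
#' @param ag An [agent()], agent id, or unknown identity string.
#' @param action One of `"curate_record"`, `"publish_annotation"`,
#'   `"read_draft"`.
#' @param scope See description.
#' @return `TRUE` or `FALSE` (never an error for unknown agents).
#' @export
authorize <- function(store, ag, action, scope) {
  stopifnot(inherits(store, "annostore"))
  agent_id <- if (inherits(ag, "ca_agent")) ag$id else ag
  registered <- !is.null(store$agents[[agent_id]])

  if (action == "curate_record") {
    if (!registered) return(FALSE)
    if (inherits(scope, "triple_id")) {
      triple <- scope
    } else {
      if (is.character(scope)) scope <- parse_persistent_id(scope)
      if (!inherits(scope, "record_id")) return(FALSE)
      triple <- scope$triple
    }
    return(agent_id %in% collection_curators(store, triple$institution, triple$collection))
  }

  if (action %in% c("publish_annotation", "read_draft")) {
    entry <- tryCatch(get_annotation_entry(store, scope), error = function(e) NULL)
    if (is.null(entry)) return(FALSE)
    if (action == "read_draft" && entry$state == "published") return(TRUE)
    if (!registered) return(FALSE)
    return(identical(entry$owner, agent_id))
  }

  FALSE
}

#' Materialized permissions as a tibble
#' @param store An [annostore()].
#' @return The permission audit table (`action`, `record`, `institution`,
#'   `collection`).
#' @export
permissions_tbl <- function(store) store$permissions
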