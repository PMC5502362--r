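# Annotation objects: regular, curatorial and batch.
#
# A regular annotation bundles provenance (who, when, why) with a reference
# to one specific record revision and a non-empty list of annotated
# elements.  Each annotated element carries an XPath selector, an
# *expectation* — the corrective the annotator asks of the collection
# curator (Add, Remove, Update) — and a proposed value and/or a free-text
# comment.  Curatorial annotations are annotations *of* published
# annotations: one decision (Accepted, Rejected, Undecided, Update) per
# annotated element of the target.  Batch annotations link identical
# annotations applied to different records; they have no elements of their
# own, only the ordered member references.

MOTIVATIONS <- c("Determination", "Gathering", "NomenclaturalType", "ScientificName")
EXPECTATIONS <- c("Add", "Remove", "Update")
DECISIONS <- c("Accepted", "Rejected", "Undecided", "Update")
BATCH_MOTIVATIONS <- c("Batch", "CuratorialBatch")

#' Construct an annotating agent
#'
#' Name and institutional affiliation become part of the public annotation
#' record on publication (mirroring the practice of signed annotation labels
#' on physical specimens); the e-mail address is kept private and used only
#' for notification delivery.
#'
#' @param name Full name of the agent.
#' @param institution Institutional affiliation.
#' @param email E-mail address (never exposed in public metadata).
#' @param id Stable agent key; defaults to a slug derived from the name.
#' @return An object of class `ca_agent`.
#' @examples
#' agent("Ada Botanist", "BGBM", "ada@example.org")
#' @export
agent <- function(name, institution, email, id = NULL) {
  for (x in list(name, institution, email)) {
    if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
      ca_abort("invalid-agent", "Agent name, institution and email are required.")
    }
  }
  id <- id %||% tolower(gsub("[^A-Za-z0-9]+", "-", name))
  structure(
    list(name = name, institution = institution, email = email, id = id),
    class = "ca_agent"
  )
}

#' @export
print.ca_agent <- function(x, ...) {
  cat("<agent> ", x$name, " (", x$institution, ") id=", x$id, "\n", sep = "")
  invisible(x)
}

#' Construct an annotated element
#'
#' @param selector An [element_selector()] or XPath string; `"/"` makes this a
#'   general comment on the whole record.
#' @param expectation One of `"Add"`, `"Remove"`, `"Update"`.
#' @param value Proposed new value (not allowed for `"Remove"`).
#' @param comment Free-text comment. At least one of `value`/`comment` must be
#'   given.
#' @return An object of class `annotated_element`.
#' @export
annotated_element <- function(selector, expectation, value = NULL, comment = NULL) {
  if (is.character(selector)) selector <- element_selector(selector)
  stopifnot(inherits(selector, "element_selector"))
  if (!is.character(expectation) || length(expectation) != 1 ||
      !expectation %in% EXPECTATIONS) {
    ca_abort("invalid-expectation-payload", sprintf(
      "Expectation must be one of %s.", paste(EXPECTATIONS, collapse = ", ")
    ))
  }
  value <- scalar_or_null(value)
  comment <- scalar_or_null(comment)
  if (is.null(value) && is.null(comment)) {
    ca_abort("invalid-expectation-payload",
             "An annotated element needs a value and/or a comment.")
  }
  if (expectation == "Remove" && !is.null(value)) {
    ca_abort("invalid-expectation-payload",
             "A 'Remove' expectation must not carry an annotated value.")
  }
  structure(
    list(selector = selector, expectation = expectation,
         value = value, comment = comment),
    class = "annotated_element"
  )
}

scalar_or_null <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NULL)
  stopifnot(is.character(x), length(x) == 1)
  x
}

#' @export
print.annotated_element <- function(x, ...) {
  cat("<annotated_element> [", x$expectation, "] ", x$selector$expression, "\n", sep = "")
  if (!is.null(x$value)) cat("  value:   ", x$value, "\n", sep = "")
  if (!is.null(x$comment)) cat("  comment: ", x$comment, "\n", sep = "")
  invisible(x)
}

#' Build a regular annotation
#'
#' @param motivation Annotation type: `"Determination"`, `"Gathering"`,
#'   `"NomenclaturalType"` or `"ScientificName"`.
#' @param annotator An [agent()].
#' @param record A [record_id()] (or encoded 5-part id string) naming
#'   the annotated record revision.
#' @param elements List of [annotated_element()]s; must be non-empty (a
#'   root-selector element encodes a general comment).
#' @param now Creation instant (`POSIXct` or epoch milliseconds); the
#'   annotation id is minted from it.
#' @param authority,system Id components for the minted annotation id.
#' @return An object of class `ca_annotation`.
#' @export
build_annotation <- function(motivation, annotator, record, elements, now = Sys.time(),
                             authority = default_authority(), system = default_system()) {
  if (!motivation %in% MOTIVATIONS) {
    ca_abort("unknown-motivation", sprintf(
      "Motivation must be one of %s.", paste(MOTIVATIONS, collapse = ", ")
    ))
  }
  stopifnot(inherits(annotator, "ca_agent"))
  if (is.character(record)) record <- parse_persistent_id(record)
  stopifnot(inherits(record, "record_id"))
  if (!is.list(elements) || length(elements) == 0) {
    ca_abort("empty-elements", "An annotation needs at least one annotated element.")
  }
  elements <- lapply(elements, function(e) {
    if (!inherits(e, "annotated_element")) {
      ca_abort("invalid-expectation-payload", "elements must be annotated_element objects.")
    }
    e
  })
  ms <- as_ms(now)
  structure(
    list(
      id = annotation_id(authority, system, ms),
      motivation = motivation,
      created_at = ms,
      annotator = annotator,
      record = record,
      elements = elements
    ),
    class = "ca_annotation"
  )
}

as_ms <- function(now) {
  if (inherits(now, "POSIXct")) instant_to_version(now) else check_version_ms(now)
}

default_authority <- function() the$authority %||% "DEMO"
default_system <- function() the$system %||% "collann"

#' Configure the minting authority and system for annotation ids
#'
#' @param authority Organisation code.
#' @param system System instance name.
#' @export
set_id_authority <- function(authority = "DEMO", system = "collann") {
  the$authority <- authority
  the$system <- system
  invisible(NULL)
}

#' @export
print.ca_annotation <- function(x, ...) {
  cat("<annotation> ", x$id$encoded, "\n  motivation: ", x$motivation,
      "\n  record:     ", x$record$encoded,
      "\n  annotator:  ", x$annotator$name,
      "\n  elements:   ", length(x$elements), "\n", sep = "")
  invisible(x)
}

#' Validate an annotation against the referenced record document
#'
#' Update and Remove selectors must resolve to at least one node of the
#' revision they annotate; Add selectors need not resolve, but their parent
#' path must, so the new element has a plausible place in the document. The
#' root selector `"/"` is always valid.
#'
#' @param a A [build_annotation()] result.
#' @param doc The [parse_record_xml()] document of the annotated revision.
#' @return A tibble with one row per element: `element` (index),
#'   `expectation`, `selector`, `ok`, `problem` (`NA`, `"selector-unresolvable"`
#'   or `"add-parent-missing"`).
#' @export
validate_annotation <- function(a, doc) {
  stopifnot(inherits(a, "ca_annotation"), inherits(doc, "record_document"))
  rows <- imap(a$elements, function(e, i) {
    ok <- TRUE
    problem <- NA_character_
    if (!is_general_comment(e$selector)) {
      n_hit <- nrow(resolve_selector(doc, e$selector))
      if (e$expectation %in% c("Update", "Remove")) {
        if (n_hit < 1) {
          ok <- FALSE
          problem <- "selector-unresolvable"
        }
      } else { # Add: parent path must resolve
        if (n_hit < 1) {
          parent <- sub("/[^/]+$", "", e$selector$expression)
          if (!nzchar(parent)) parent <- "/"
          n_parent <- nrow(resolve_selector(
            doc, element_selector(parent, e$selector$prefix_map)
          ))
          if (n_parent < 1) {
            ok <- FALSE
            problem <- "add-parent-missing"
          }
        }
      }
    }
    tibble(element = i, expectation = e$expectation,
           selector = e$selector$expression, ok = ok, problem = problem)
  })
  bind_rows(rows)
}

# -- annotation type templates ------------------------------------------------

default_templates <- function() {
  list(
    Determination = tibble(
      field = c("full scientific name", "identified by", "identification date",
                "reference URI"),
      path = c(
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString",
        "Identifications/Identification/IdentifiedBy",
        "Identifications/Identification/Date",
        "Identifications/Identification/ReferenceURI"
      )
    ),
    Gathering = tibble(
      field = c("collector", "collector's field number", "locality", "country",
                "latitude", "longitude", "altitude", "date"),
      path = c(
        "Gathering/GatheringAgent",
        "Gathering/CollectorsFieldNumber",
        "Gathering/LocalityText",
        "Gathering/Country/Name",
        "Gathering/LatitudeDecimal",
        "Gathering/LongitudeDecimal",
        "Gathering/Altitude",
        "Gathering/DateTime"
      )
    ),
    NomenclaturalType = tibble(
      field = c("type status", "full scientific name", "typified by", "reference URI"),
      path = c(
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/TypeStatus",
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString",
        "Identifications/Identification/TypifiedBy",
        "Identifications/Identification/ReferenceURI"
      )
    ),
    ScientificName = tibble(
      field = c("full scientific name", "genus", "first epithet",
                "infraspecific epithet", "author", "higher taxon name"),
      path = c(
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString",
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/NameAtomised/GenusOrMonomial",
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/NameAtomised/FirstEpithet",
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/NameAtomised/InfraspecificEpithet",
        "Identifications/Identification/Result/TaxonIdentified/ScientificName/NameAtomised/AuthorTeam",
        "Identifications/Identification/Result/TaxonIdentified/HigherTaxa/HigherTaxonName"
      )
    )
  )
}

#' Selector-path templates for an annotation type
#'
#' Each annotation type (motivation) comes with a configured set of element
#' paths that user interfaces would present as entry fields — e.g. a
#' determination involves the full scientific name, the identifier's name and
#' the identification date. Templates are configuration data, so new schemas
#' extend without code changes; paths are relative to the record's unit
#' element in the ABCD-like dialect.
#'
#' @param motivation One of the basic annotation types.
#' @return A tibble with columns `field` and `path`.
#' @examples
#' template_elements("Gathering")
#' @export
template_elements <- function(motivation) {
  templates <- the$templates %||% default_templates()
  if (!motivation %in% names(templates)) {
    ca_abort("unknown-motivation", sprintf("No templates for motivation '%s'.", motivation))
  }
  templates[[motivation]]
}

#' @rdname template_elements
#' @param templates Named list of tibbles (`field`, `path`) replacing the
#'   configured template table.
#' @export
set_templates <- function(templates) {
  the$templates <- templates
  invisible(NULL)
}

# -- curatorial annotations ---------------------------------------------------

#' Build a curatorial annotation
#'
#' A curatorial annotation records the collection curator's per-element
#' decisions on a *published* regular annotation — each annotated element is
#' covered exactly once with one of `"Accepted"`, `"Rejected"`, `"Undecided"`
#' or `"Update"` (the element was already updated for another reason),
#' optionally justified by a comment. Its motivation is fixed to
#' `"Curatorial"`.
#'
#' @param curator An [agent()].
#' @param target The published [build_annotation()] object being curated.
#' @param decisions A data frame with columns `element` (1-based index into
#'   the target's elements), `decision`, and optionally `comment`.
#' @param now Creation instant.
#' @param target_published Assert that the target is published. When
#'   constructing through a repository this is checked against store state.
#' @param authority,system Id components for the minted id.
#' @return An object of class `ca_curatorial`.
#' @export
build_curatorial <- function(curator, target, decisions, now = Sys.time(),
                             target_published = FALSE,
                             authority = default_authority(), system = default_system()) {
  stopifnot(inherits(curator, "ca_agent"), inherits(target, "ca_annotation"))
  if (!isTRUE(target_published)) {
    ca_abort("target-not-published", "Only published annotations can be curated.")
  }
  decisions <- as_tibble(decisions)
  if (!all(c("element", "decision") %in% names(decisions))) {
    ca_abort("uncovered-element", "decisions needs columns 'element' and 'decision'.")
  }
  if (!"comment" %in% names(decisions)) decisions$comment <- NA_character_
  n <- length(target$elements)
  if (!setequal(decisions$element, seq_len(n)) || nrow(decisions) != n) {
    ca_abort("uncovered-element", sprintf(
      "Decisions must cover each of the %d annotated element(s) exactly once.", n
    ))
  }
  bad <- setdiff(unique(decisions$decision), DECISIONS)
  if (length(bad)) {
    ca_abort("unknown-decision", sprintf(
      "Unknown decision(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(DECISIONS, collapse = ", ")
    ))
  }
  decisions <- decisions[order(decisions$element), c("element", "decision", "comment")]
  ms <- as_ms(now)
  structure(
    list(
      id = annotation_id(authority, system, ms),
      motivation = "Curatorial",
      created_at = ms,
      curator = curator,
      target_annotation = target$id,
      curated = decisions
    ),
    class = "ca_curatorial"
  )
}

#' @export
print.ca_curatorial <- function(x, ...) {
  cat("<curatorial_annotation> ", x$id$encoded,
      "\n  target:  ", x$target_annotation$encoded,
      "\n  curator: ", x$curator$name, "\n", sep = "")
  print(x$curated)
  invisible(x)
}

# -- batch annotations --------------------------------------------------------

#' Build a batch annotation
#'
#' Links together annotations whose content is identical apart from the
#' record (or annotation) they target — e.g. the same determination
#' correction applied to several duplicates of one gathering. All members
#' must be regular annotations (motivation `"Batch"`) or all curatorial
#' (`"CuratorialBatch"`). The batch itself carries no annotated elements;
#' it records the member ids in order.
#'
#' @param creator An [agent()].
#' @param members List of at least two member annotation objects.
#' @param now Creation instant.
#' @param authority,system Id components for the minted id.
#' @return An object of class `ca_batch`.
#' @export
build_batch <- function(creator, members, now = Sys.time(),
                        authority = default_authority(), system = default_system()) {
  stopifnot(inherits(creator, "ca_agent"))
  if (!is.list(members) || length(members) < 2) {
    ca_abort("too-few-members", "A batch needs at least two member annotations.")
  }
  regular <- map_lgl(members, inherits, "ca_annotation")
  curatorial <- map_lgl(members, inherits, "ca_curatorial")
  if (all(regular)) {
    motivation <- "Batch"
    essences <- map(members, regular_content_essence)
  } else if (all(curatorial)) {
    motivation <- "CuratorialBatch"
    essences <- map(members, curatorial_content_essence)
  } else {
    ca_abort("heterogeneous-members",
             "Batch members must be all regular or all curatorial annotations.")
  }
  for (i in seq_along(essences)[-1]) {
    if (!identical(essences[[i]], essences[[1]])) {
      ca_abort("content-mismatch", sprintf(
        "Member %d differs from member 1 in annotated content; batch members must be identical apart from their target.", i
      ))
    }
  }
  ms <- as_ms(now)
  structure(
    list(
      id = annotation_id(authority, system, ms),
      motivation = motivation,
      created_at = ms,
      creator = creator,
      members = map(members, "id")
    ),
    class = "ca_batch"
  )
}

# the content that must agree across batch members: everything except target
regular_content_essence <- function(a) {
  list(
    motivation = a$motivation,
    elements = map(a$elements, function(e) {
      list(selector = e$selector$expression, expectation = e$expectation,
           value = e$value, comment = e$comment)
    })
  )
}

curatorial_content_essence <- function(c) {
  list(decision = c$curated$decision, comment = c$curated$comment)
}

#' @export
print.ca_batch <- function(x, ...) {
  cat("<batch_annotation> ", x$id$encoded, " [", x$motivation, "]\n  members:\n", sep = "")
  for (m in x$members) cat("    ", m$encoded, "\n", sep = "")
  invisible(x)
}
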