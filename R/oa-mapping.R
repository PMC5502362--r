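# Open Annotation serialization.
#
# Annotations serialize to the W3C Open Annotation RDF model: a provenance
# part (motivation, creation instant, agent), and per annotated element one
# specific target (source record, fragment selector, state with version
# instant and archived-revision cache) paired with one specific body
# (expectation class, proposed value, comment).  Because OA's open-world
# reading of multiple bodies and targets is "every body applies to every
# target", the pairing is carried by an explicit oa:hasScope soft link from
# each body to its target; reconstruction relies on those links alone.
#
# Motivation classes subclass oa:editing (regular types), oa:replying
# (curatorial) and oa:linking (batch).  Specific bodies, targets, states and
# selectors are minted as fragment URIs of the annotation resource so that
# curatorial annotations can reference an annotated element's body across
# documents.

annotation_uri <- function(id, base = default_base_uri()) {
  paste0(base, "annotation/", id$encoded)
}

record_uri <- function(triple, base = default_base_uri()) {
  paste0(base, "record/", format_triple_id(triple))
}

revision_uri <- function(record_id, base = default_base_uri()) {
  paste0(base, "record/", record_id$encoded)
}

XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"

# triple-row accumulator
new_acc <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}
emit <- function(acc, s, p, o, o_type = "uri", dt = NA_character_) {
  acc$rows[[length(acc$rows) + 1L]] <- list(s = s, p = p, o = o, o_type = o_type, dt = dt)
}
emit_lit <- function(acc, s, p, o, dt = NA_character_) emit(acc, s, p, o, "literal", dt)
acc_graph <- function(acc, base) {
  oa_graph(bind_rows(lapply(acc$rows, as_tibble)), base_uri = base)
}

agent_triples <- function(acc, agent_uri, ag) {
  emit(acc, agent_uri, term("rdf", "type"), term("foaf", "Person"))
  emit_lit(acc, agent_uri, term("foaf", "name"), ag$name)
  emit_lit(acc, agent_uri, term("annot", "institution"), ag$institution)
}

#' Serialize a regular annotation to an Open Annotation graph
#'
#' @param a A [build_annotation()] object.
#' @param base_uri Base URI for minted resources.
#' @return An [oa_graph()]. Render it with [render_graph()].
#' @export
annotation_to_oa <- function(a, base_uri = default_base_uri()) {
  stopifnot(inherits(a, "ca_annotation"))
  acc <- new_acc()
  ann <- annotation_uri(a$id, base_uri)
  agent_uri <- paste0(ann, "#annotator")
  n <- length(a$elements)
  body_uri <- paste0(ann, "#body-", seq_len(n))
  target_uri <- paste0(ann, "#target-", seq_len(n))

  emit(acc, ann, term("rdf", "type"), term("oa", "Annotation"))
  emit(acc, ann, term("oa", "motivatedBy"), term("annot", a$motivation))
  emit_lit(acc, ann, term("oa", "annotatedAt"), format_instant(a$created_at), XSD_DATETIME)
  emit(acc, ann, term("oa", "annotatedBy"), agent_uri)
  for (i in seq_len(n)) {
    emit(acc, ann, term("oa", "hasBody"), body_uri[i])
    emit(acc, ann, term("oa", "hasTarget"), target_uri[i])
  }
  agent_triples(acc, agent_uri, a$annotator)

  rec_uri <- record_uri(a$record$triple, base_uri)
  rev_uri <- revision_uri(a$record, base_uri)
  for (i in seq_len(n)) {
    e <- a$elements[[i]]
    # specific body: expectation class, proposed value, comment, scope link
    emit(acc, body_uri[i], term("rdf", "type"), term("annot", e$expectation))
    if (!is.null(e$value)) emit_lit(acc, body_uri[i], term("rdf", "value"), e$value)
    if (!is.null(e$comment)) {
      emit_lit(acc, body_uri[i], term("dcterms", "description"), e$comment)
    }
    emit(acc, body_uri[i], term("oa", "hasScope"), target_uri[i])
    # specific target: source record, selector (unless general comment), state
    emit(acc, target_uri[i], term("rdf", "type"), term("oa", "SpecificResource"))
    emit(acc, target_uri[i], term("oa", "hasSource"), rec_uri)
    if (!is_general_comment(e$selector)) {
      sel_uri <- paste0(ann, "#selector-", i)
      emit(acc, target_uri[i], term("oa", "hasSelector"), sel_uri)
      emit(acc, sel_uri, term("rdf", "type"), term("oa", "FragmentSelector"))
      emit_lit(acc, sel_uri, term("rdf", "value"), e$selector$expression)
      emit(acc, sel_uri, term("dcterms", "conformsTo"), XPTR_CONFORMS_TO)
    }
    state_uri <- paste0(ann, "#state-", i)
    emit(acc, target_uri[i], term("oa", "hasState"), state_uri)
    emit_lit(acc, state_uri, term("oa", "when"),
             format_instant(a$record$version_ms), XSD_DATETIME)
    emit(acc, state_uri, term("oa", "cachedSource"), rev_uri)
  }
  acc_graph(acc, base_uri)
}

#' Serialize a curatorial annotation to an Open Annotation graph
#'
#' The curatorial annotation's target is the annotation it comments upon;
#' each curated element becomes a body holding the curator's decision
#' (`decision:hasResult`) and optional comment, scope-linked to the
#' corresponding annotated element's body of the target annotation.
#'
#' @param c A [build_curatorial()] object.
#' @param target_graph_uri URI of the annotated annotation; defaults to the
#'   URI minted from its id.
#' @param base_uri Base URI for minted resources.
#' @return An [oa_graph()].
#' @export
curatorial_to_oa <- function(c, target_graph_uri = NULL, base_uri = default_base_uri()) {
  stopifnot(inherits(c, "ca_curatorial"))
  acc <- new_acc()
  ann <- annotation_uri(c$id, base_uri)
  agent_uri <- paste0(ann, "#annotator")
  target_ann <- target_graph_uri %||% annotation_uri(c$target_annotation, base_uri)
  n <- nrow(c$curated)
  body_uri <- paste0(ann, "#body-", seq_len(n))

  emit(acc, ann, term("rdf", "type"), term("oa", "Annotation"))
  emit(acc, ann, term("oa", "motivatedBy"), term("annot", "Curatorial"))
  emit_lit(acc, ann, term("oa", "annotatedAt"), format_instant(c$created_at), XSD_DATETIME)
  emit(acc, ann, term("oa", "annotatedBy"), agent_uri)
  emit(acc, ann, term("oa", "hasTarget"), target_ann)
  for (i in seq_len(n)) emit(acc, ann, term("oa", "hasBody"), body_uri[i])
  agent_triples(acc, agent_uri, c$curator)

  for (i in seq_len(n)) {
    row <- c$curated[i, ]
    emit(acc, body_uri[i], term("decision", "hasResult"),
         term("annot", tolower(row$decision)))
    if (!is.na(row$comment)) {
      emit_lit(acc, body_uri[i], term("dcterms", "description"), row$comment)
    }
    # soft link to the annotated element's body in the target annotation
    emit(acc, body_uri[i], term("oa", "hasScope"),
         paste0(target_ann, "#body-", row$element))
  }
  acc_graph(acc, base_uri)
}

#' Serialize a batch annotation to an Open Annotation graph
#'
#' Batch annotations have no body; they reference the enveloped annotations
#' through one `oa:hasTarget` statement per member, in member order.
#'
#' @param b A [build_batch()] object.
#' @param base_uri Base URI for minted resources.
#' @return An [oa_graph()].
#' @export
batch_to_oa <- function(b, base_uri = default_base_uri()) {
  stopifnot(inherits(b, "ca_batch"))
  acc <- new_acc()
  ann <- annotation_uri(b$id, base_uri)
  agent_uri <- paste0(ann, "#annotator")
  motiv <- if (b$motivation == "Batch") "BatchAnnotation" else "BatchCuratorialAnnotation"
  emit(acc, ann, term("rdf", "type"), term("oa", "Annotation"))
  emit(acc, ann, term("oa", "motivatedBy"), term("annot", motiv))
  emit_lit(acc, ann, term("oa", "annotatedAt"), format_instant(b$created_at), XSD_DATETIME)
  emit(acc, ann, term("oa", "annotatedBy"), agent_uri)
  for (m in b$members) {
    emit(acc, ann, term("oa", "hasTarget"), annotation_uri(m, base_uri))
  }
  agent_triples(acc, agent_uri, b$creator)
  acc_graph(acc, base_uri)
}

# -- reconstruction -----------------------------------------------------------

g_objects <- function(tr, s, p) tr$o[tr$s == s & tr$p == p]
g_first <- function(tr, s, p) {
  v <- g_objects(tr, s, p)
  if (length(v) == 0) NA_character_ else v[[1]]
}

id_from_uri <- function(uri, kind = c("annotation", "record")) {
  kind <- match.arg(kind)
  marker <- paste0("/", kind, "/")
  pos <- regexpr(marker, uri, fixed = TRUE)
  if (pos == -1) {
    ca_abort("malformed-graph", sprintf("URI <%s> does not name a %s resource.", uri, kind))
  }
  parse_persistent_id(substring(uri, pos + attr(pos, "match.length")))
}

strip_ns <- function(uri, prefix) {
  base <- ca_namespaces()[[prefix]]
  if (!startsWith(uri, base)) return(NA_character_)
  substring(uri, nchar(base) + 1)
}

reconstruct_agent <- function(tr, agent_uri) {
  if (is.na(agent_uri)) ca_abort("malformed-graph", "Annotation lacks oa:annotatedBy.")
  name <- g_first(tr, agent_uri, term("foaf", "name"))
  inst <- g_first(tr, agent_uri, term("annot", "institution"))
  if (is.na(name) || is.na(inst)) {
    ca_abort("malformed-graph", "Agent node lacks name or institution.")
  }
  # the e-mail address is never serialized (it is not public); reimported
  # agents carry a placeholder address
  agent(name, inst, "unknown@invalid")
}

#' Reconstruct an annotation object from an Open Annotation graph
#'
#' Inverse of [annotation_to_oa()], [curatorial_to_oa()] and [batch_to_oa()].
#' The motivation class decides which object is built. Element (and batch
#' member) order follows statement order; bodies are paired with their
#' targets strictly through `oa:hasScope` links — a body without a scope link
#' is unrecoverable and raises `malformed-graph`.
#'
#' @param g An [oa_graph()] (e.g. from [parse_graph()]).
#' @return A `ca_annotation`, `ca_curatorial` or `ca_batch` object.
#' @export
oa_to_annotation <- function(g) {
  stopifnot(inherits(g, "oa_graph"))
  tr <- g$triples
  ann <- tr$s[tr$p == term("rdf", "type") & tr$o == term("oa", "Annotation")]
  if (length(ann) != 1) {
    ca_abort("malformed-graph", sprintf(
      "Expected exactly one oa:Annotation node, found %d.", length(ann)
    ))
  }
  motiv_uri <- g_first(tr, ann, term("oa", "motivatedBy"))
  if (is.na(motiv_uri)) ca_abort("malformed-graph", "Annotation lacks oa:motivatedBy.")
  motiv <- strip_ns(motiv_uri, "annot")
  if (is.na(motiv) ||
      !motiv %in% c(MOTIVATIONS, "Curatorial", "BatchAnnotation", "BatchCuratorialAnnotation")) {
    ca_abort("unknown-motivation", sprintf(
      "Motivation <%s> is not a recognized application motivation class.", motiv_uri
    ))
  }
  id <- id_from_uri(ann, "annotation")
  created_at <- parse_instant_ms(g_first(tr, ann, term("oa", "annotatedAt")))
  ag <- reconstruct_agent(tr, g_first(tr, ann, term("oa", "annotatedBy")))
  targets <- g_objects(tr, ann, term("oa", "hasTarget"))
  if (length(targets) == 0) ca_abort("malformed-graph", "Annotation has no oa:hasTarget.")
  bodies <- g_objects(tr, ann, term("oa", "hasBody"))

  if (motiv %in% c("BatchAnnotation", "BatchCuratorialAnnotation")) {
    if (length(bodies) > 0) {
      ca_abort("malformed-graph", "A batch annotation must not carry bodies.")
    }
    members <- lapply(targets, id_from_uri, kind = "annotation")
    return(structure(
      list(id = id,
           motivation = if (motiv == "BatchAnnotation") "Batch" else "CuratorialBatch",
           created_at = created_at, creator = ag, members = members),
      class = "ca_batch"
    ))
  }

  if (motiv == "Curatorial") {
    target_id <- id_from_uri(targets[[1]], "annotation")
    rows <- lapply(bodies, function(b) {
      scope <- g_first(tr, b, term("oa", "hasScope"))
      if (is.na(scope)) {
        ca_abort("malformed-graph",
                 "Curated body lacks its oa:hasScope link; the element reference is unrecoverable.")
      }
      elem <- suppressWarnings(as.integer(sub(".*#body-", "", scope)))
      if (is.na(elem)) {
        ca_abort("dangling-element-ref", sprintf(
          "Scope <%s> does not reference an annotated element body.", scope
        ))
      }
      dec_uri <- g_first(tr, b, term("decision", "hasResult"))
      dec <- decision_from_uri(dec_uri)
      comment <- g_first(tr, b, term("dcterms", "description"))
      if (is.na(comment)) {
        # legacy variant: decision comment attached via the body's oa:hasSource
        alt <- tr$o[tr$s == b & tr$p == term("oa", "hasSource") & tr$o_type == "literal"]
        if (length(alt)) comment <- alt[[1]]
      }
      tibble(element = elem, decision = dec, comment = comment)
    })
    curated <- bind_rows(rows)
    return(structure(
      list(id = id, motivation = "Curatorial", created_at = created_at,
           curator = ag, target_annotation = target_id,
           curated = curated[order(curated$element), ]),
      class = "ca_curatorial"
    ))
  }

  # regular annotation: pair bodies with targets via oa:hasScope only
  if (length(bodies) == 0) ca_abort("malformed-graph", "Annotation has no oa:hasBody.")
  record_id <- NULL
  elements <- lapply(bodies, function(b) {
    scope <- g_first(tr, b, term("oa", "hasScope"))
    if (is.na(scope) || !scope %in% targets) {
      ca_abort("malformed-graph",
               "Body lacks an oa:hasScope link to a target; the annotated element is unrecoverable.")
    }
    expectation <- NA_character_
    for (ty in g_objects(tr, b, term("rdf", "type"))) {
      cand <- strip_ns(ty, "annot")
      if (!is.na(cand) && cand %in% EXPECTATIONS) expectation <- cand
    }
    if (is.na(expectation)) {
      ca_abort("malformed-graph", "Body has no expectation class (rdf:type).")
    }
    value <- g_first(tr, b, term("rdf", "value"))
    comment <- g_first(tr, b, term("dcterms", "description"))
    sel_uri <- g_first(tr, scope, term("oa", "hasSelector"))
    sel <- if (is.na(sel_uri)) "/" else g_first(tr, sel_uri, term("rdf", "value"))
    state <- g_first(tr, scope, term("oa", "hasState"))
    if (!is.na(state)) {
      cached <- g_first(tr, state, term("oa", "cachedSource"))
      if (!is.na(cached)) record_id <<- id_from_uri(cached, "record")
    }
    annotated_element(sel, expectation,
                      value = if (is.na(value)) NULL else value,
                      comment = if (is.na(comment)) NULL else comment)
  })
  if (is.null(record_id)) {
    ca_abort("malformed-graph", "No target state carries an oa:cachedSource revision URI.")
  }
  structure(
    list(id = id, motivation = motiv, created_at = created_at, annotator = ag,
         record = record_id, elements = elements),
    class = "ca_annotation"
  )
}

decision_from_uri <- function(uri) {
  if (is.na(uri)) ca_abort("malformed-graph", "Curated body lacks decision:hasResult.")
  local <- strip_ns(uri, "annot")
  if (is.na(local)) {
    ca_abort("unknown-decision", sprintf("<%s> is not a known decision option.", uri))
  }
  hit <- DECISIONS[tolower(DECISIONS) == tolower(local)]
  if (length(hit) != 1) {
    ca_abort("unknown-decision", sprintf("<%s> is not a known decision option.", uri))
  }
  hit
}

#' Serialize any annotation object
#'
#' Dispatches to [annotation_to_oa()], [curatorial_to_oa()] or
#' [batch_to_oa()].
#'
#' @param x An annotation object.
#' @param base_uri Base URI for minted resources.
#' @return An [oa_graph()].
#' @export
to_oa <- function(x, base_uri = default_base_uri()) {
  if (inherits(x, "ca_annotation")) return(annotation_to_oa(x, base_uri))
  if (inherits(x, "ca_curatorial")) return(curatorial_to_oa(x, base_uri = base_uri))
  if (inherits(x, "ca_batch")) return(batch_to_oa(x, base_uri))
  ca_abort("malformed-graph", "Not an annotation object.")
}

# -- vocabulary ---------------------------------------------------------------

#' The Open Annotation vocabulary used by the package
#'
#' `oa_terms()` lists every mapped property exactly once; `oa_vocabulary_graph()`
#' returns the class axioms: the regular motivation classes subclass
#' `oa:editing`, the curatorial motivation subclasses `oa:replying`, the
#' batch motivations subclass `oa:linking`, and the decision options
#' subclass `decision:Option`.
#'
#' @return A tibble (`term`, `uri`), or an [oa_graph()] of axioms.
#' @export
oa_terms <- function() {
  tibble(
    term = c("oa:hasTarget", "oa:hasBody", "oa:hasScope", "oa:hasSelector",
             "oa:hasSource", "oa:hasState", "oa:cachedSource", "oa:when",
             "oa:motivatedBy", "oa:annotatedAt", "oa:annotatedBy",
             "rdf:value", "rdf:type", "dcterms:description", "decision:hasResult"),
    uri = c(term("oa", "hasTarget"), term("oa", "hasBody"), term("oa", "hasScope"),
            term("oa", "hasSelector"), term("oa", "hasSource"), term("oa", "hasState"),
            term("oa", "cachedSource"), term("oa", "when"), term("oa", "motivatedBy"),
            term("oa", "annotatedAt"), term("oa", "annotatedBy"),
            term("rdf", "value"), term("rdf", "type"),
            term("dcterms", "description"), term("decision", "hasResult"))
  )
}

#' @rdname oa_terms
#' @export
oa_vocabulary_graph <- function() {
  acc <- new_acc()
  sub <- term("rdfs", "subClassOf")
  for (m in MOTIVATIONS) emit(acc, term("annot", m), sub, term("oa", "editing"))
  emit(acc, term("annot", "Curatorial"), sub, term("oa", "replying"))
  emit(acc, term("annot", "BatchAnnotation"), sub, term("oa", "linking"))
  emit(acc, term("annot", "BatchCuratorialAnnotation"), sub, term("oa", "linking"))
  for (d in tolower(DECISIONS)) {
    emit(acc, term("annot", d), sub, term("decision", "Option"))
  }
  acc_graph(acc, default_base_uri())
}

# -- content fingerprints (for round-trip comparison) -------------------------

#' Content fingerprint of an annotation object
#'
#' A plain-list summary of everything the OA serialization carries:
#' identifier, motivation, creation instant, agent name and institution,
#' record reference and per-element content. Two objects with equal
#' fingerprints serialize to isomorphic graphs; private fields (the agent's
#' e-mail) and selector prefix maps are excluded because they are never
#' serialized.
#'
#' @param x An annotation object.
#' @return A plain list suitable for `identical()` comparison.
#' @export
annotation_essence <- function(x) {
  if (inherits(x, "ca_annotation")) {
    list(
      kind = "regular", id = x$id$encoded, motivation = x$motivation,
      created_at = x$created_at,
      agent = c(x$annotator$name, x$annotator$institution),
      record = x$record$encoded,
      elements = map(x$elements, function(e) {
        list(selector = e$selector$expression, expectation = e$expectation,
             value = e$value, comment = e$comment)
      })
    )
  } else if (inherits(x, "ca_curatorial")) {
    list(
      kind = "curatorial", id = x$id$encoded, created_at = x$created_at,
      agent = c(x$curator$name, x$curator$institution),
      target = x$target_annotation$encoded,
      curated = list(element = as.integer(x$curated$element),
                     decision = x$curated$decision,
                     comment = x$curated$comment)
    )
  } else if (inherits(x, "ca_batch")) {
    list(
      kind = "batch", id = x$id$encoded, motivation = x$motivation,
      created_at = x$created_at,
      agent = c(x$creator$name, x$creator$institution),
      members = map_chr(x$members, "encoded")
    )
  } else {
    ca_abort("malformed-graph", "Not an annotation object.")
  }
}
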