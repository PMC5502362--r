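# A minimal RDF triple container with Turtle and RDF/XML round-trips.
#
# The graphs this package emits are small (tens of triples per annotation)
# and fully URI-named — specific bodies, targets and states are minted as
# fragment URIs of the annotation resource, so no blank-node machinery is
# needed for its own output.  The Turtle parser accepts the dialect the
# writer produces plus common variants (prefixed names, 'a', object lists,
# blank-node labels); the RDF/XML reader accepts rdf:Description documents
# and typed node elements.  Statement *row order* is preserved by writer and
# parsers, which the annotation round-trip uses to retain element and member
# order; graph comparison itself is order-insensitive.

#' Construct an RDF graph
#'
#' @param triples A data frame with columns `s`, `p`, `o`, `o_type`
#'   (`"uri"`, `"bnode"` or `"literal"`) and `dt` (datatype URI or `NA`).
#' @param base_uri Base URI recorded with the graph.
#' @return An object of class `oa_graph`.
#' @export
oa_graph <- function(triples = NULL, base_uri = default_base_uri()) {
  if (is.null(triples)) {
    triples <- tibble(s = character(), p = character(), o = character(),
                      o_type = character(), dt = character())
  }
  triples <- as_tibble(triples)
  stopifnot(all(c("s", "p", "o", "o_type") %in% names(triples)))
  if (!"dt" %in% names(triples)) triples$dt <- NA_character_
  stopifnot(all(triples$o_type %in% c("uri", "bnode", "literal")))
  structure(list(triples = triples, base_uri = base_uri), class = "oa_graph")
}

#' @export
print.oa_graph <- function(x, ...) {
  cat("<oa_graph> ", nrow(x$triples), " triple(s), base <", x$base_uri, ">\n", sep = "")
  print(x$triples, ...)
  invisible(x)
}

#' Number of triples in a graph
#' @param g An [oa_graph()].
#' @return Integer count.
#' @export
graph_size <- function(g) nrow(g$triples)

# -- namespaces ---------------------------------------------------------------

default_namespaces <- function() {
  c(
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd = "http://www.w3.org/2001/XMLSchema#",
    oa = "http://www.w3.org/ns/oa#",
    dcterms = "http://purl.org/dc/terms/",
    foaf = "http://xmlns.com/foaf/0.1/",
    annot = "http://example.org/ns/annot#",
    decision = "http://example.org/ns/decision#"
  )
}

#' Namespace configuration
#'
#' The `oa`, `dcterms`, `rdf`, `rdfs`, `xsd` and `foaf` namespaces are the
#' standard ones; the application namespaces (`annot` for motivation and
#' expectation classes, `decision` for the decision-ontology terms) have
#' stable defaults and may be reconfigured.
#'
#' @param annot,decision Replacement namespace URIs.
#' @param base_uri Base URI under which annotation and record resources are
#'   minted.
#' @return `ca_namespaces()` returns the named character vector of prefixes.
#' @export
ca_namespaces <- function() {
  ns <- default_namespaces()
  if (!is.null(the$annot_ns)) ns[["annot"]] <- the$annot_ns
  if (!is.null(the$decision_ns)) ns[["decision"]] <- the$decision_ns
  ns
}

#' @rdname ca_namespaces
#' @export
set_namespaces <- function(annot = NULL, decision = NULL, base_uri = NULL) {
  if (!is.null(annot)) the$annot_ns <- annot
  if (!is.null(decision)) the$decision_ns <- decision
  if (!is.null(base_uri)) the$base_uri <- base_uri
  invisible(NULL)
}

default_base_uri <- function() the$base_uri %||% "http://example.org/collann/"

term <- function(prefix, local) paste0(ca_namespaces()[[prefix]], local)

# -- serialization ------------------------------------------------------------

#' Serialize a graph
#'
#' @param g An [oa_graph()].
#' @param syntax `"turtle"` or `"rdf-xml"`.
#' @return A single string; parse it back with [parse_graph()].
#' @export
render_graph <- function(g, syntax = c("turtle", "rdf-xml")) {
  stopifnot(inherits(g, "oa_graph"))
  if (!is.character(syntax) || !syntax[1] %in% c("turtle", "rdf-xml")) {
    ca_abort("unknown-syntax", sprintf(
      "Unsupported syntax '%s'; use 'turtle' or 'rdf-xml'.", syntax[1]
    ))
  }
  switch(syntax[1], turtle = render_turtle(g), `rdf-xml` = render_rdfxml(g))
}

#' Parse a serialized graph
#'
#' @param text Document text produced by [render_graph()] (or a compatible
#'   subset of Turtle / RDF/XML).
#' @param syntax `"turtle"` or `"rdf-xml"`.
#' @return An [oa_graph()].
#' @export
parse_graph <- function(text, syntax = c("turtle", "rdf-xml")) {
  if (!is.character(syntax) || !syntax[1] %in% c("turtle", "rdf-xml")) {
    ca_abort("unknown-syntax", sprintf(
      "Unsupported syntax '%s'; use 'turtle' or 'rdf-xml'.", syntax[1]
    ))
  }
  switch(syntax[1], turtle = parse_turtle(text), `rdf-xml` = parse_rdfxml(text))
}

# abbreviate a URI with a known prefix when the local part is PN_LOCAL-safe
abbrev_uri <- function(uri, ns) {
  for (p in names(ns)) {
    base <- ns[[p]]
    if (startsWith(uri, base)) {
      local <- substring(uri, nchar(base) + 1)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", uri, ">")
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- ""
    j <- 1
    n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1, j + 1)
        res <- paste0(res, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t", "\"" = "\"", "\\" = "\\", nxt
        ))
        j <- j + 2
      } else {
        res <- paste0(res, ch)
        j <- j + 1
      }
    }
    out[[i]] <- res
  }
  out
}

# blank nodes are stored in the s/o columns with a literal "_:" prefix, so
# subject blank-ness survives the tabular representation
is_bnode_ref <- function(x) startsWith(x, "_:")

turtle_object <- function(o, o_type, dt, ns) {
  if (o_type == "uri") return(abbrev_uri(o, ns))
  if (o_type == "bnode") return(o)
  lit <- paste0("\"", escape_literal(o), "\"")
  if (!is.na(dt)) lit <- paste0(lit, "^^", abbrev_uri(dt, ns))
  lit
}

render_turtle <- function(g) {
  ns <- ca_namespaces()
  tr <- g$triples
  lines <- c(
    sprintf("@prefix %s: <%s> .", names(ns), unname(ns)),
    ""
  )
  if (nrow(tr) > 0) {
    # group *consecutive* triples sharing a subject; preserves row order
    grp <- cumsum(c(TRUE, tr$s[-1] != tr$s[-nrow(tr)]))
    for (gi in unique(grp)) {
      rows <- which(grp == gi)
      subj <- if (is_bnode_ref(tr$s[rows[1]])) tr$s[rows[1]] else abbrev_uri(tr$s[rows[1]], ns)
      body <- vapply(rows, function(i) {
        pred <- if (tr$p[i] == term("rdf", "type")) "a" else abbrev_uri(tr$p[i], ns)
        paste0("    ", pred, " ", turtle_object(tr$o[i], tr$o_type[i], tr$dt[i], ns))
      }, character(1))
      lines <- c(lines, paste0(subj, "\n", paste(body, collapse = " ;\n"), " ."), "")
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# -- turtle parsing -----------------------------------------------------------

turtle_tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  patterns <- list(
    c("WS", "^(\\s+|#[^\n]*)"),
    c("PREFIX", "^@prefix\\b"),
    c("IRI", "^<[^<>\"{}|^`\\\\\\s]*>"),
    c("STRING", "^\"(?:[^\"\\\\]|\\\\.)*\""),
    c("DTMARK", "^\\^\\^"),
    c("LANG", "^@[A-Za-z][A-Za-z0-9-]*"),
    c("BNODE", "^_:[A-Za-z0-9_.-]+"),
    c("PNAME", "^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%+-]*"),
    c("A", "^a(?![A-Za-z0-9_:-])"),
    c("SEMI", "^;"),
    c("COMMA", "^,"),
    c("DOT", "^\\.")
  )
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (pat in patterns) {
      m <- regexpr(pat[2], rest, perl = TRUE)
      if (m != -1L) {
        len <- attr(m, "match.length")
        if (pat[1] != "WS") {
          tokens[[length(tokens) + 1L]] <- c(type = pat[1],
                                             value = substr(rest, 1, len))
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      ca_abort("malformed-graph", sprintf(
        "Cannot tokenize Turtle at position %d: '%s...'", pos, substr(rest, 1, 20)
      ))
    }
  }
  tokens
}

parse_turtle <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- turtle_tokenize(text)
  prefixes <- character()
  i <- 1L
  s_v <- character(); p_v <- character(); o_v <- character()
  t_v <- character(); d_v <- character()
  peek <- function() if (i <= length(tokens)) tokens[[i]][["type"]] else "EOF"
  take <- function(type = NULL) {
    if (i > length(tokens)) ca_abort("malformed-graph", "Unexpected end of Turtle input.")
    tok <- tokens[[i]]
    if (!is.null(type) && !tok[["type"]] %in% type) {
      ca_abort("malformed-graph", sprintf(
        "Expected %s but found %s ('%s').", paste(type, collapse = "/"),
        tok[["type"]], tok[["value"]]
      ))
    }
    i <<- i + 1L
    tok
  }
  expand_pname <- function(v) {
    colon <- regexpr(":", v, fixed = TRUE)
    pfx <- substr(v, 1, colon - 1)
    local <- substring(v, colon + 1)
    if (!pfx %in% names(prefixes)) {
      ca_abort("malformed-graph", sprintf("Undeclared prefix '%s'.", pfx))
    }
    paste0(prefixes[[pfx]], local)
  }
  read_resource <- function(tok) {
    switch(tok[["type"]],
      IRI = list(v = substr(tok[["value"]], 2, nchar(tok[["value"]]) - 1), t = "uri"),
      PNAME = list(v = expand_pname(tok[["value"]]), t = "uri"),
      BNODE = list(v = tok[["value"]], t = "bnode"),
      ca_abort("malformed-graph", sprintf("Expected a resource, found %s.", tok[["type"]]))
    )
  }
  read_object <- function() {
    tok <- take()
    if (tok[["type"]] == "STRING") {
      v <- unescape_literal(substr(tok[["value"]], 2, nchar(tok[["value"]]) - 1))
      dt <- NA_character_
      if (peek() == "DTMARK") {
        take("DTMARK")
        dt <- read_resource(take(c("IRI", "PNAME")))$v
      } else if (peek() == "LANG") {
        take("LANG") # language tags accepted, not retained separately
      }
      list(v = v, t = "literal", dt = dt)
    } else {
      r <- read_resource(tok)
      list(v = r$v, t = r$t, dt = NA_character_)
    }
  }
  while (peek() != "EOF") {
    if (peek() == "PREFIX") {
      take("PREFIX")
      pn <- take("PNAME")[["value"]]
      pfx <- sub(":$", "", pn)
      iri <- take("IRI")[["value"]]
      prefixes[[pfx]] <- substr(iri, 2, nchar(iri) - 1)
      take("DOT")
      next
    }
    subj <- read_resource(take(c("IRI", "PNAME", "BNODE")))
    repeat {
      ptok <- take(c("IRI", "PNAME", "A"))
      pred <- if (ptok[["type"]] == "A") term("rdf", "type") else read_resource(ptok)$v
      repeat {
        obj <- read_object()
        s_v <- c(s_v, subj$v); p_v <- c(p_v, pred)
        o_v <- c(o_v, obj$v); t_v <- c(t_v, obj$t); d_v <- c(d_v, obj$dt)
        if (peek() == "COMMA") take("COMMA") else break
      }
      if (peek() == "SEMI") {
        take("SEMI")
        if (peek() %in% c("DOT")) { take("DOT"); break } # trailing ';' before '.'
      } else {
        take("DOT")
        break
      }
    }
  }
  oa_graph(tibble(s = s_v, p = p_v, o = o_v, o_type = t_v, dt = d_v))
}

# -- rdf/xml ------------------------------------------------------------------

xml_escape <- function(x, attr = FALSE) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  if (attr) x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# predicates must serialize as QNames in RDF/XML
qname_for <- function(uri, ns) {
  for (p in names(ns)) {
    base <- ns[[p]]
    if (startsWith(uri, base)) {
      local <- substring(uri, nchar(base) + 1)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(c(prefix = p, local = local))
      }
    }
  }
  ca_abort("unmapped-term", sprintf(
    "Predicate <%s> has no registered namespace; cannot form an RDF/XML QName.", uri
  ))
}

render_rdfxml <- function(g) {
  ns <- ca_namespaces()
  tr <- g$triples
  decls <- paste0(sprintf(" xmlns:%s=\"%s\"", names(ns), xml_escape(unname(ns), attr = TRUE)),
                  collapse = "")
  body <- character()
  if (nrow(tr) > 0) {
    grp <- cumsum(c(TRUE, tr$s[-1] != tr$s[-nrow(tr)]))
    for (gi in unique(grp)) {
      rows <- which(grp == gi)
      subj <- tr$s[rows[1]]
      subj_attr <- if (is_bnode_ref(subj)) {
        sprintf(" rdf:nodeID=\"%s\"", xml_escape(substring(subj, 3), attr = TRUE))
      } else {
        sprintf(" rdf:about=\"%s\"", xml_escape(subj, attr = TRUE))
      }
      props <- vapply(rows, function(ii) {
        q <- qname_for(tr$p[ii], ns)
        tag <- paste0(q[["prefix"]], ":", q[["local"]])
        if (tr$o_type[ii] == "uri") {
          sprintf("    <%s rdf:resource=\"%s\"/>", tag, xml_escape(tr$o[ii], attr = TRUE))
        } else if (tr$o_type[ii] == "bnode") {
          sprintf("    <%s rdf:nodeID=\"%s\"/>", tag,
                  xml_escape(substring(tr$o[ii], 3), attr = TRUE))
        } else if (!is.na(tr$dt[ii])) {
          sprintf("    <%s rdf:datatype=\"%s\">%s</%s>", tag,
                  xml_escape(tr$dt[ii], attr = TRUE), xml_escape(tr$o[ii]), tag)
        } else {
          sprintf("    <%s>%s</%s>", tag, xml_escape(tr$o[ii]), tag)
        }
      }, character(1))
      body <- c(body, sprintf("  <rdf:Description%s>", subj_attr), props,
                "  </rdf:Description>")
    }
  }
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<rdf:RDF", decls, ">\n",
    paste(body, collapse = "\n"),
    "\n</rdf:RDF>\n"
  )
}

parse_rdfxml <- function(text) {
  x <- tryCatch(xml2::read_xml(text),
                error = function(e) ca_abort("malformed-graph",
                                             paste0("Not well-formed RDF/XML: ", conditionMessage(e))))
  rdf_ns <- default_namespaces()[["rdf"]]
  root_uri <- node_ns_uri(xml2::xml_root(x))
  if (!identical(root_uri, rdf_ns) || xml2::xml_name(xml2::xml_root(x)) != "RDF") {
    ca_abort("malformed-graph", "Root element is not rdf:RDF.")
  }
  s_v <- character(); p_v <- character(); o_v <- character()
  t_v <- character(); d_v <- character()
  push <- function(s, p, o, t, d = NA_character_) {
    s_v <<- c(s_v, s); p_v <<- c(p_v, p); o_v <<- c(o_v, o)
    t_v <<- c(t_v, t); d_v <<- c(d_v, d)
  }
  rdf_attr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0("rdf:", name))
    if (is.na(v)) xml2::xml_attr(node, name) else v
  }
  for (desc in xml2::xml_children(xml2::xml_root(x))) {
    about <- rdf_attr(desc, "about")
    node_id <- rdf_attr(desc, "nodeID")
    if (!is.na(about)) {
      subj <- about
    } else if (!is.na(node_id)) {
      subj <- paste0("_:", node_id)
    } else {
      ca_abort("malformed-graph", "Description without rdf:about or rdf:nodeID.")
    }
    # typed node element: the element name is an rdf:type assertion
    d_uri <- node_ns_uri(desc)
    d_local <- xml2::xml_name(desc)
    if (!(identical(d_uri, rdf_ns) && d_local == "Description")) {
      push(subj, term("rdf", "type"), paste0(d_uri, d_local), "uri")
    }
    for (prop in xml2::xml_children(desc)) {
      pred <- paste0(node_ns_uri(prop), xml2::xml_name(prop))
      res <- rdf_attr(prop, "resource")
      nid <- rdf_attr(prop, "nodeID")
      dt <- rdf_attr(prop, "datatype")
      if (!is.na(res)) {
        push(subj, pred, res, "uri")
      } else if (!is.na(nid)) {
        push(subj, pred, paste0("_:", nid), "bnode")
      } else {
        push(subj, pred, xml2::xml_text(prop), "literal", dt)
      }
    }
  }
  oa_graph(tibble(s = s_v, p = p_v, o = o_v, o_type = t_v, dt = d_v))
}

# -- comparison ---------------------------------------------------------------

canonical_triples <- function(g) {
  tr <- g$triples
  if (nrow(tr) == 0) return(character())
  labels <- canonical_bnode_labels(tr)
  relabel <- function(v, is_bn) {
    out <- v
    out[is_bn] <- paste0("_:", labels[v[is_bn]])
    out
  }
  slab <- relabel(tr$s, is_bnode_ref(tr$s))
  olab <- relabel(tr$o, tr$o_type == "bnode")
  sort(paste(slab, tr$p, olab, tr$o_type == "literal",
             ifelse(is.na(tr$dt), "", tr$dt), sep = "\x1f"),
       method = "radix")
}

# deterministic labels for blank nodes via iterative signature refinement
canonical_bnode_labels <- function(tr) {
  bn <- unique(c(tr$o[tr$o_type == "bnode"], tr$s[is_bnode_ref(tr$s)]))
  if (length(bn) == 0) return(stats::setNames(character(), character()))
  sig <- stats::setNames(rep("b", length(bn)), bn)
  for (iter in 1:3) {
    newsig <- vapply(bn, function(b) {
      out_rows <- tr$s == b
      in_rows <- tr$o == b & tr$o_type == "bnode"
      out_sig <- sort(paste0("O", tr$p[out_rows], ">",
                             ifelse(tr$o_type[out_rows] == "bnode",
                                    sig[tr$o[out_rows]], tr$o[out_rows])))
      in_sig <- sort(paste0("I", tr$p[in_rows], "<",
                            ifelse(tr$s[in_rows] %in% bn, sig[tr$s[in_rows]], tr$s[in_rows])))
      paste(c(sig[[b]], out_sig, in_sig), collapse = "|")
    }, character(1))
    sig <- newsig
  }
  ord <- order(sig, method = "radix")
  stats::setNames(paste0("c", seq_along(bn)), bn[ord])[bn]
}

#' Are two graphs isomorphic?
#'
#' Order-insensitive comparison of the triple sets; blank nodes (only
#' possible in parsed third-party input) are matched by deterministic
#' signature refinement.
#'
#' @param a,b [oa_graph()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_isomorphic <- function(a, b) {
  identical(canonical_triples(a), canonical_triples(b))
}
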