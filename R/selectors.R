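# XPath element selectors.
#
# Annotated elements are addressed by XPath expressions, carried in Open
# Annotation graphs as FragmentSelector values conforming to the XPointer
# framework.  Generated selectors use a deliberately small XPath dialect —
# child steps with 1-based positional predicates, always emitted (even `[1]`)
# so repeated elements such as multiple identifications stay unambiguous.
# The bare expression "/" addresses the whole record and encodes a general
# comment.

XPTR_CONFORMS_TO <- "http://www.w3.org/TR/xptr-framework/"

#' Construct an element selector
#'
#' @param expression An XPath expression; `"/"` denotes the whole record.
#' @param prefix_map Named character vector mapping namespace prefixes used in
#'   the expression to namespace URIs.
#' @return An object of class `element_selector`.
#' @examples
#' element_selector("/DataSets[1]/DataSet[1]/Units[1]/Unit[1]")
#' @export
element_selector <- function(expression, prefix_map = character()) {
  if (!is.character(expression) || length(expression) != 1 || is.na(expression) ||
      !nzchar(trimws(expression))) {
    ca_abort("invalid-xpath", "Selector expression must be a non-empty string.")
  }
  structure(
    list(
      expression = trimws(expression),
      conforms_to = XPTR_CONFORMS_TO,
      prefix_map = prefix_map
    ),
    class = "element_selector"
  )
}

#' @export
print.element_selector <- function(x, ...) {
  cat("<element_selector> ", x$expression, "\n", sep = "")
  invisible(x)
}

#' @export
format.element_selector <- function(x, ...) x$expression

#' Build the canonical XPath of a node within its document
#'
#' Returns an absolute path of child steps with 1-based positional predicates
#' among same-named siblings. Resolving the selector in the same document
#' yields exactly the given node. For elements in a default (unprefixed)
#' namespace the steps use `*[local-name()=...]` so the expression resolves
#' without a prefix map.
#'
#' @param doc A [parse_record_xml()] document.
#' @param node An `xml2` element node belonging to `doc`.
#' @return An [element_selector()].
#' @export
build_element_xpath <- function(doc, node) {
  stopifnot(inherits(doc, "record_document"))
  if (!inherits(node, "xml_node")) ca_abort("node-not-in-doc", "node must be an xml_node.")
  if (!same_document(node, doc$xml)) {
    ca_abort("node-not-in-doc", "node does not belong to the given document.")
  }
  steps <- character()
  cur <- node
  repeat {
    if (xml2::xml_type(cur) != "element") ca_abort("node-not-in-doc", "node is not an element.")
    steps <- c(selector_step(cur), steps)
    parent <- xml2::xml_parent(cur)
    if (inherits(parent, "xml_missing") || xml2::xml_type(parent) != "element") break
    cur <- parent
  }
  element_selector(paste0("/", paste(steps, collapse = "/")),
                   prefix_map = doc_prefix_map(doc$xml))
}

same_document <- function(node, doc) {
  # identity of the owning document (external pointer comparison)
  dn <- tryCatch(node$doc, error = function(e) NULL)
  dd <- tryCatch(doc$doc, error = function(e) NULL)
  !is.null(dn) && !is.null(dd) && identical(dn, dd)
}

selector_step <- function(node) {
  name <- xml2::xml_name(node)
  uri <- node_ns_uri(node)
  # 1-based position among same-named siblings (same expanded name)
  pos <- 1L
  prev <- xml2::xml_find_all(node, "preceding-sibling::*")
  for (sib in prev) {
    if (identical(xml2::xml_name(sib), name) && identical(node_ns_uri(sib), uri)) {
      pos <- pos + 1L
    }
  }
  if (nzchar(uri)) {
    sprintf("*[local-name()='%s'][%d]", name, pos)
  } else {
    sprintf("%s[%d]", name, pos)
  }
}

doc_prefix_map <- function(x) {
  ns <- unclass(xml2::xml_ns(x))
  if (length(ns) == 0) return(character())
  stats::setNames(as.character(ns), names(ns))
}

#' Resolve a selector against a record document
#'
#' @param doc A [parse_record_xml()] document.
#' @param sel An [element_selector()] or bare XPath string.
#' @return A tibble with one row per matched node in document order, columns
#'   `text` (normalized text value) and `node` (list column of `xml_node`
#'   handles). The selector `"/"` matches the document root.
#' @export
resolve_selector <- function(doc, sel) {
  stopifnot(inherits(doc, "record_document"))
  if (is.character(sel)) sel <- element_selector(sel)
  stopifnot(inherits(sel, "element_selector"))
  if (is_general_comment(sel)) {
    nodes <- list(xml2::xml_root(doc$xml))
  } else {
    ns <- sel$prefix_map
    bad <- function(cond) {
      ca_abort("invalid-xpath",
               paste0("Cannot evaluate XPath: ", conditionMessage(cond)))
    }
    # xml2 reports an unparseable expression as a warning with an empty result
    hits <- tryCatch(
      if (length(ns)) {
        xml2::xml_find_all(doc$xml, sel$expression, ns = ns)
      } else {
        xml2::xml_find_all(doc$xml, sel$expression)
      },
      error = bad, warning = bad
    )
    nodes <- lapply(hits, identity)
  }
  tibble(
    text = map_chr(nodes, function(n) normalize_text(xml2::xml_text(n))),
    node = nodes
  )
}

#' Does a selector express a general comment?
#'
#' A selector addressing the document's root element (`"/"`, after trimming
#' surrounding whitespace) annotates the record as a whole rather than a
#' specific element.
#'
#' @param sel An [element_selector()] or string.
#' @return `TRUE` or `FALSE`.
#' @export
is_general_comment <- function(sel) {
  expr <- if (inherits(sel, "element_selector")) sel$expression else sel
  identical(trimws(expr), "/")
}
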