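# XML record documents and the order-insensitive canonical form.
#
# Two record documents count as the *same revision* ("similar") when they
# contain the same elements and attributes, including values, regardless of
# order.  The canonical form realises this: one entry per element node,
# identified by its root-to-element name path (positions dropped, names
# expanded by namespace URI), its attribute set, and its whitespace-normalized
# direct text.  Similarity is multiset equality of these entries, so
# serializer formatting, sibling order, attribute order and namespace-prefix
# spelling never create a new revision, while any value change does.

#' Parse an XML record document
#'
#' Reads a specimen/occurrence record in an ABCD-2.06-like or simple Darwin
#' Core XML dialect and extracts its triple identifier from the dialect's
#' identifier elements (`SourceInstitutionID`/`SourceID`/`UnitID` or
#' `institutionCode`/`collectionCode`/`catalogNumber`). The exact input bytes
#' are preserved for bit-exact archiving.
#'
#' @param raw The document, as a single string or a raw vector.
#' @param format_prefix Registered data-format prefix (see
#'   [registered_formats()]).
#' @param triple Optional [triple_id()] override when the document carries no
#'   identifier elements.
#' @return An object of class `record_document` with fields `raw`, `xml`,
#'   `root_name`, `triple` and `format_prefix`.
#' @export
parse_record_xml <- function(raw, format_prefix, triple = NULL) {
  if (is.raw(raw)) raw <- rawToChar(raw)
  if (!is.character(raw) || length(raw) != 1) {
    ca_abort("not-xml", "raw must be a single string or raw vector.")
  }
  if (!format_prefix %in% registered_formats()) {
    ca_abort("unknown-format", sprintf("Format prefix '%s' is not registered.", format_prefix))
  }
  x <- tryCatch(
    xml2::read_xml(raw, options = c("NOBLANKS" = 0L)),
    error = function(e) ca_abort("not-xml", paste0("Input is not well-formed XML: ", conditionMessage(e)))
  )
  if (is.null(triple)) {
    triple <- extract_triple(x)
    if (is.null(triple)) {
      ca_abort("missing-triple-id",
               "Document has no identifier elements and no triple override was supplied.")
    }
  } else {
    stopifnot(inherits(triple, "triple_id"))
  }
  structure(
    list(
      raw = raw,
      xml = x,
      root_name = expanded_root_name(x),
      triple = triple,
      format_prefix = format_prefix
    ),
    class = "record_document"
  )
}

#' @export
print.record_document <- function(x, ...) {
  cat("<record_document> ", format_triple_id(x$triple), " [", x$format_prefix, "], root <",
      x$root_name, ">\n", sep = "")
  invisible(x)
}

# first non-empty text of elements with any of the given local names
find_local <- function(x, locals) {
  for (nm in locals) {
    hit <- xml2::xml_find_first(x, sprintf("//*[local-name()='%s']", nm))
    if (!inherits(hit, "xml_missing")) {
      txt <- normalize_text(xml2::xml_text(hit))
      if (nzchar(txt)) return(txt)
    }
  }
  NULL
}

extract_triple <- function(x) {
  inst <- find_local(x, c("SourceInstitutionID", "institutionCode"))
  coll <- find_local(x, c("SourceID", "collectionCode"))
  unit <- find_local(x, c("UnitID", "catalogNumber"))
  if (is.null(inst) || is.null(coll) || is.null(unit)) return(NULL)
  triple_id(inst, coll, unit)
}

expanded_root_name <- function(x) {
  root <- xml2::xml_root(x)
  expand_name(xml2::xml_name(root), node_ns_uri(root))
}

node_ns_uri <- function(node) {
  uri <- xml2::xml_find_chr(node, "string(namespace-uri(.))")
  if (is.na(uri)) "" else uri
}

expand_name <- function(local, uri) {
  if (nzchar(uri)) paste0("{", uri, "}", local) else local
}

# strip + collapse runs of whitespace; idempotent
normalize_text <- function(x) {
  gsub("\\s+", " ", trimws(paste(x, collapse = "")))
}

#' Canonicalize a record document
#'
#' Produces the order-insensitive canonical form: one entry per element node
#' with its root-to-element name path (namespace-expanded, positions
#' dropped), its attribute set (sorted, `xmlns` declarations excluded) and
#' its normalized direct text (comments and processing instructions are
#' ignored). The canonical form is what [are_similar()] compares.
#'
#' @param doc A [parse_record_xml()] document, or anything `xml2::read_xml()`
#'   accepts.
#' @return An object of class `canonical_form`: a list with `elements`
#'   (a tibble with columns `path`, `attrs`, `text`) and `keys` (the sorted
#'   multiset of canonical entry strings).
#' @export
canonicalize_document <- function(doc) {
  x <- if (inherits(doc, "record_document")) doc$xml else xml2::read_xml(doc)
  has_ns <- length(unclass(xml2::xml_ns(x))) > 0 &&
    !identical(names(unclass(xml2::xml_ns(x))), character(0))
  rows <- list()
  walk <- function(node, parent_path) {
    local <- xml2::xml_name(node)
    nm <- if (has_ns) expand_name(local, node_ns_uri(node)) else local
    path <- paste0(parent_path, "/", nm)
    atts <- xml2::xml_attrs(node)
    if (length(atts)) {
      atts <- atts[!grepl("^xmlns(:|$)", names(atts))]
    }
    attr_str <- if (length(atts)) {
      paste(sort(paste0(names(atts), "=", atts), method = "radix"), collapse = "\x1e")
    } else ""
    contents <- xml2::xml_contents(node)
    types <- xml2::xml_type(contents)
    txt <- normalize_text(xml2::xml_text(contents[types %in% c("text", "cdata")], trim = FALSE))
    rows[[length(rows) + 1L]] <<- c(path = path, attrs = attr_str, text = txt)
    for (child in contents[types == "element"]) walk(child, path)
    invisible(NULL)
  }
  walk(xml2::xml_root(x), "")
  elements <- tibble(
    path = map_chr(rows, "path"),
    attrs = map_chr(rows, "attrs"),
    text = map_chr(rows, "text")
  )
  # radix sort: locale-independent ordering, so canonical forms are portable
  keys <- sort(paste(elements$path, elements$attrs, elements$text, sep = "\x1f"),
               method = "radix")
  structure(list(elements = elements, keys = keys), class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("<canonical_form> ", nrow(x$elements), " element(s)\n", sep = "")
  print(x$elements, ...)
  invisible(x)
}

#' Are two record documents similar?
#'
#' Two documents are similar when they contain the same elements and
#' attributes (including values) regardless of order — i.e. their canonical
#' multisets are equal. Similarity is the equivalence relation that decides
#' whether an import is a re-retrieval of an archived revision or a genuinely
#' new revision.
#'
#' @param a,b [parse_record_xml()] documents (or [canonicalize_document()]
#'   results).
#' @return `TRUE` or `FALSE`.
#' @export
are_similar <- function(a, b) {
  ka <- if (inherits(a, "canonical_form")) a$keys else canonicalize_document(a)$keys
  kb <- if (inherits(b, "canonical_form")) b$keys else canonicalize_document(b)$keys
  identical(ka, kb)
}
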