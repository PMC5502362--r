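# Persistent identifiers for records and annotations.
#
# A specimen is referenced by its "triple identifier": institution code,
# collection code and catalogue number.  A record *revision* extends the
# triple with a version (milliseconds since the Unix epoch, UTC) and the
# namespace prefix of the data format the document was delivered in, giving a
# 5-component id.  Annotation ids have 3 components (authority, system,
# creation instant) and carry no version or format part, because an
# annotation is created exactly once.

#' Construct a triple identifier
#'
#' The triple identifier designates a specimen by (i) the institution holding
#' it, (ii) the collection within that institution, and (iii) the catalogue
#' number of the individual unit. It is the community's conventional (if
#' imperfect) globally unique reference to a collection object.
#'
#' @param institution Institution code, e.g. `"BGBM"`.
#' @param collection Collection code, e.g. `"Herbarium Berolinense"`.
#' @param unit Catalogue number of the unit, e.g. `"B 18 0014862"`.
#' @return An object of class `triple_id`.
#' @examples
#' triple_id("BGBM", "Herbarium Berolinense", "B 18 0014862")
#' @export
triple_id <- function(institution, collection, unit) {
  for (x in list(institution, collection, unit)) {
    if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
      ca_abort("malformed-id", "All three triple-id components must be non-empty strings.")
    }
  }
  structure(
    list(institution = institution, collection = collection, unit = unit),
    class = "triple_id"
  )
}

#' @export
print.triple_id <- function(x, ...) {
  cat("<triple_id> ", format_triple_id(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.triple_id <- function(x, ...) format_triple_id(x)

# ':' separates components, space is written as '+'; literal '+', ':' and '%'
# inside a component are percent-encoded so the n-part grammar stays
# unambiguous.
escape_component <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("+", "%2B", x, fixed = TRUE)
  x <- gsub(":", "%3A", x, fixed = TRUE)
  gsub(" ", "+", x, fixed = TRUE)
}

unescape_component <- function(x) {
  x <- gsub("+", " ", x, fixed = TRUE)
  x <- gsub("%3A", ":", x, fixed = TRUE, ignore.case = FALSE)
  x <- gsub("%2B", "+", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Encode a triple identifier as text
#'
#' Spaces become `'+'`; literal `'+'`, `':'` and `'%'` are percent-encoded.
#'
#' @param triple A [triple_id()].
#' @return A single string with exactly two `':'` separators.
#' @examples
#' format_triple_id(triple_id("BGBM", "Herbarium Berolinense", "B 18 0014862"))
#' @export
format_triple_id <- function(triple) {
  stopifnot(inherits(triple, "triple_id"))
  paste(
    escape_component(triple$institution),
    escape_component(triple$collection),
    escape_component(triple$unit),
    sep = ":"
  )
}

#' Parse an encoded triple identifier
#'
#' @param encoded A string with exactly three `':'`-separated components.
#' @return A [triple_id()].
#' @examples
#' parse_triple_id("BGBM:Herbarium+Berolinense:B+18+0014862")
#' @export
parse_triple_id <- function(encoded) {
  parts <- split_id(encoded)
  if (length(parts) != 3) {
    ca_abort("malformed-id", sprintf(
      "A triple id must have exactly 3 ':'-separated components, got %d.", length(parts)
    ))
  }
  do.call(triple_id, as.list(unescape_component(parts)))
}

split_id <- function(encoded) {
  if (!is.character(encoded) || length(encoded) != 1 || is.na(encoded)) {
    ca_abort("malformed-id", "An encoded id must be a single string.")
  }
  parts <- strsplit(encoded, ":", fixed = TRUE)[[1]]
  if (length(parts) == 0 || any(!nzchar(parts))) {
    ca_abort("malformed-id", "Encoded id has an empty component.")
  }
  parts
}

# -- registered data formats --------------------------------------------------

default_formats <- c("abcd2.06b", "dwc")

#' Registered record-document formats
#'
#' Record revisions carry the namespace prefix of the XML data standard they
#' were delivered in, so that element selectors resolve against the right
#' schema. The registry ships with `"abcd2.06b"` (an ABCD 2.06-like dialect)
#' and `"dwc"` (simple Darwin Core) and can be extended at run time.
#'
#' @param prefix A new namespace prefix to register.
#' @return `registered_formats()` returns the character vector of prefixes.
#' @examples
#' registered_formats()
#' register_format("abcd2.1")
#' @export
registered_formats <- function() {
  the$formats %||% default_formats
}

#' @rdname registered_formats
#' @export
register_format <- function(prefix) {
  stopifnot(is.character(prefix), length(prefix) == 1, nzchar(prefix))
  the$formats <- union(registered_formats(), prefix)
  invisible(the$formats)
}

# -- record ids ---------------------------------------------------------------

#' Compose a versioned record identifier
#'
#' Extends a triple identifier with the import instant (milliseconds since
#' 1970-01-01T00:00:00 UTC) and the registered namespace prefix of the data
#' format, yielding a 5-component id that names one specific revision of a
#' record document.
#'
#' @param triple A [triple_id()].
#' @param version_ms Non-negative integer-valued number of epoch milliseconds.
#' @param format_prefix A prefix present in [registered_formats()].
#' @return The encoded 5-component id string.
#' @examples
#' compose_record_id(
#'   triple_id("BGBM", "Herbarium Berolinense", "B 18 0014862"),
#'   1379406965371, "abcd2.06b"
#' )
#' @export
compose_record_id <- function(triple, version_ms, format_prefix) {
  stopifnot(inherits(triple, "triple_id"))
  version_ms <- check_version_ms(version_ms)
  if (!format_prefix %in% registered_formats()) {
    ca_abort("unknown-format", sprintf(
      "Format prefix '%s' is not registered (see registered_formats()).", format_prefix
    ))
  }
  paste(format_triple_id(triple), format_ms(version_ms), escape_component(format_prefix), sep = ":")
}

check_version_ms <- function(version_ms) {
  if (!is.numeric(version_ms) || length(version_ms) != 1 || is.na(version_ms) ||
      version_ms < 0 || version_ms != trunc(version_ms)) {
    ca_abort("malformed-id", "version_ms must be a single non-negative integer-valued number.")
  }
  as.numeric(version_ms)
}

# epoch-ms values exceed 32-bit integers; keep them as doubles (exact below 2^53)
format_ms <- function(ms) format(ms, scientific = FALSE, trim = TRUE)

#' Record revision identifier
#'
#' @param triple A [triple_id()].
#' @param version_ms Epoch milliseconds of the import instant.
#' @param format_prefix Registered data-format prefix.
#' @return An object of class `record_id`.
#' @export
record_id <- function(triple, version_ms, format_prefix) {
  encoded <- compose_record_id(triple, version_ms, format_prefix) # validates
  structure(
    list(
      triple = triple, version_ms = as.numeric(version_ms),
      format_prefix = format_prefix, encoded = encoded
    ),
    class = "record_id"
  )
}

#' @export
print.record_id <- function(x, ...) {
  cat("<record_id> ", x$encoded, "\n", sep = "")
  invisible(x)
}

#' @export
format.record_id <- function(x, ...) x$encoded

#' Annotation identifier
#'
#' Annotations are identified by authority, system and their creation instant
#' in epoch milliseconds; they carry no version or format component because
#' an annotation is created exactly once.
#'
#' @param authority Organisation code minting the id.
#' @param system Name of the annotation system instance.
#' @param object_id Creation instant, milliseconds since the Unix epoch.
#' @return An object of class `annotation_id`.
#' @examples
#' annotation_id("BGBM", "collann", 1379006965559)
#' @export
annotation_id <- function(authority, system, object_id) {
  for (x in list(authority, system)) {
    if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
      ca_abort("malformed-id", "authority and system must be non-empty strings.")
    }
  }
  object_id <- check_version_ms(object_id)
  structure(
    list(
      authority = authority, system = system, object_id = object_id,
      encoded = paste(escape_component(authority), escape_component(system),
                      format_ms(object_id), sep = ":")
    ),
    class = "annotation_id"
  )
}

#' @export
print.annotation_id <- function(x, ...) {
  cat("<annotation_id> ", x$encoded, "\n", sep = "")
  invisible(x)
}

#' @export
format.annotation_id <- function(x, ...) x$encoded

#' Parse an encoded identifier (record or annotation form)
#'
#' A 5-component id decodes to a [record_id()]; a 3-component id to an
#' [annotation_id()]. Any other arity is malformed.
#'
#' @param encoded Encoded id string.
#' @return A `record_id` or `annotation_id`.
#' @examples
#' parse_persistent_id("BGBM:collann:1379006965559")
#' parse_persistent_id("BGBM:Herbarium+Berolinense:B+18+0014862:1379406965371:abcd2.06b")
#' @export
parse_persistent_id <- function(encoded) {
  parts <- split_id(encoded)
  if (length(parts) == 3) {
    ms <- parse_ms(parts[3])
    return(annotation_id(unescape_component(parts[1]), unescape_component(parts[2]), ms))
  }
  if (length(parts) == 5) {
    ms <- parse_ms(parts[4])
    triple <- do.call(triple_id, as.list(unescape_component(parts[1:3])))
    fmt <- unescape_component(parts[5])
    return(record_id(triple, ms, fmt))
  }
  ca_abort("malformed-id", sprintf(
    "An encoded id must have 3 or 5 components, got %d.", length(parts)
  ))
}

parse_ms <- function(x) {
  if (!grepl("^[0-9]+$", x)) {
    ca_abort("non-numeric-version", sprintf("Version component '%s' is not a number.", x))
  }
  as.numeric(x)
}

# -- version <-> instant ------------------------------------------------------

#' Convert between version milliseconds and UTC instants
#'
#' Versions are stored as milliseconds since 1970-01-01T00:00:00 UTC.
#' `version_to_instant()` returns a `POSIXct` in UTC; `instant_to_version()`
#' is its inverse at millisecond precision.
#'
#' @param version_ms Non-negative epoch milliseconds.
#' @param instant A `POSIXct` (any timezone; converted to UTC).
#' @return A UTC `POSIXct`, or a numeric millisecond count.
#' @examples
#' version_to_instant(1379406965371)
#' instant_to_version(as.POSIXct("2013-09-17 08:36:05.371", tz = "UTC"))
#' @export
version_to_instant <- function(version_ms) {
  version_ms <- check_version_ms(version_ms)
  .POSIXct(version_ms / 1000, tz = "UTC")
}

#' @rdname version_to_instant
#' @export
instant_to_version <- function(instant) {
  stopifnot(inherits(instant, "POSIXct"))
  round(as.numeric(instant) * 1000)
}

#' Render an instant or millisecond version as an ISO-8601 UTC timestamp
#'
#' @param x A `POSIXct` or a numeric epoch-millisecond count.
#' @return A string like `"2013-09-17T08:36:05.371Z"`.
#' @export
format_instant <- function(x) {
  if (inherits(x, "POSIXct")) x <- instant_to_version(x)
  x <- check_version_ms(x)
  # format whole seconds and milliseconds separately: %OS3 truncates the
  # floating-point representation and can drop a millisecond
  secs <- x %/% 1000
  frac <- x %% 1000
  paste0(format(.POSIXct(secs, tz = "UTC"), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         sprintf(".%03dZ", frac))
}

parse_instant_ms <- function(x) {
  m <- regmatches(x, regexec(
    "^([0-9]{4}-[0-9]{2}-[0-9]{2})T([0-9]{2}:[0-9]{2}:[0-9]{2})(\\.([0-9]+))?Z?$", x
  ))[[1]]
  if (length(m) == 0) ca_abort("malformed-id", sprintf("Cannot parse instant '%s'.", x))
  t <- as.POSIXct(paste(m[2], m[3]), format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (is.na(t)) ca_abort("malformed-id", sprintf("Cannot parse instant '%s'.", x))
  frac <- if (nzchar(m[5])) as.numeric(substr(paste0(m[5], "000"), 1, 3)) else 0
  round(as.numeric(t)) * 1000 + frac
}

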