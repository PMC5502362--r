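# Deterministic synthetic record generator and mutation operators.
#
# Generates desk-scale specimen records in a documented ABCD-2.06-like
# subset (DataSets/DataSet/Units/Unit) or a simple Darwin Core dialect.
# Every generated document carries a unique triple identifier and an element
# for each implemented filter type and each annotation-template path, so
# query, notification and annotation workflows can be exercised without any
# external accession.  `permute_document()` reorders siblings and
# attributes and re-flows whitespace without changing the canonical form;
# `mutate_document()` changes exactly one value, which always produces a
# dissimilar document.  All randomness is driven by a single seed.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Vocabulary pools for the synthetic generator
#'
#' @return A list of character pools (institutions, collections, genera,
#'   epithets, families, people, countries).
#' @export
fixture_vocab <- function() {
  list(
    institutions = c("BGBM", "K", "NY", "P", "M", "US"),
    collections = c("Herbarium Berolinense", "General Herbarium",
                    "Algae Collection", "Lichen Herbarium"),
    genera = c("Cremastosperma", "Guatteria", "Solanum", "Carex", "Festuca",
               "Hieracium", "Navicula", "Usnea"),
    epithets = c("brevipes", "poiteaui", "montanum", "vulgaris", "alpina",
                 "gracilis", "elegans", "minor"),
    families = c("Annonaceae", "Solanaceae", "Cyperaceae", "Poaceae",
                 "Asteraceae", "Naviculaceae", "Parmeliaceae"),
    people = c("A. Humboldt", "M. Sessé", "J. Macbride", "E. Chiovenda",
               "O. Schmidt", "L. Díaz", "R. Brown", "K. Koch"),
    countries = c("Peru", "Germany", "Brazil", "Italy", "Kenya", "Georgia",
                  "Mexico", "Norway")
  )
}

rpick <- function(pool) pool[[sample.int(length(pool), 1)]]

#' Generate a deterministic corpus of synthetic records
#'
#' @param n_records Number of records (each with a unique triple id).
#' @param seed Integer seed; the same `(n_records, seed, dialect)` always
#'   yields a byte-identical corpus.
#' @param dialect `"abcd_like"` or `"dwc_like"`.
#' @param vocab Vocabulary pools, see [fixture_vocab()].
#' @return List of [parse_record_xml()] documents.
#' @examples
#' docs <- generate_dataset(3, seed = 1)
#' @export
generate_dataset <- function(n_records, seed = 1L, dialect = c("abcd_like", "dwc_like"),
                             vocab = fixture_vocab()) {
  stopifnot(n_records >= 1)
  dialect <- match.arg(dialect)
  with_seed(seed, {
    lapply(seq_len(n_records), function(i) {
      f <- fixture_fields(i, seed, vocab)
      xmltxt <- if (dialect == "abcd_like") abcd_like_xml(f) else dwc_like_xml(f)
      parse_record_xml(xmltxt, if (dialect == "abcd_like") "abcd2.06b" else "dwc")
    })
  })
}

fixture_fields <- function(i, seed, vocab) {
  genus <- rpick(vocab$genera)
  epithet <- rpick(vocab$epithets)
  list(
    institution = rpick(vocab$institutions),
    collection = rpick(vocab$collections),
    # unit ids carry the seed and index so corpora never collide
    unit = sprintf("B %02d %07d", seed %% 100, i),
    genus = genus,
    epithet = epithet,
    fullname = paste(genus, epithet),
    author = rpick(vocab$people),
    family = rpick(vocab$families),
    collector = rpick(vocab$people),
    fieldnumber = as.character(sample.int(9999, 1)),
    country = rpick(vocab$countries),
    locality = paste("near", rpick(vocab$countries)),
    identifiedby = rpick(vocab$people),
    iddate = sprintf("19%02d-%02d-%02d", sample.int(99, 1), sample.int(12, 1),
                     sample.int(28, 1)),
    gatherdate = sprintf("18%02d-%02d-%02d", sample.int(99, 1), sample.int(12, 1),
                         sample.int(28, 1)),
    lat = sprintf("%.4f", stats::runif(1, -60, 70)),
    lon = sprintf("%.4f", stats::runif(1, -150, 150)),
    alt = as.character(sample.int(4500, 1)),
    typestatus = rpick(c("holotype", "isotype", "not a type")),
    email = sprintf("curator%d@%s.example.org", sample.int(9, 1),
                    tolower(rpick(vocab$institutions)))
  )
}

xml_txt_escape <- function(x) xml_escape(x)

abcd_like_xml <- function(f) {
  e <- lapply(f, xml_txt_escape)
  paste0(
    "<DataSets><DataSet><Units><Unit>",
    "<SourceInstitutionID>", e$institution, "</SourceInstitutionID>",
    "<SourceID>", e$collection, "</SourceID>",
    "<UnitID>", e$unit, "</UnitID>",
    "<SourceContact><Email>", e$email, "</Email></SourceContact>",
    "<Identifications><Identification>",
    "<Result><TaxonIdentified>",
    "<ScientificName>",
    "<FullScientificNameString>", e$fullname, "</FullScientificNameString>",
    "<TypeStatus>", e$typestatus, "</TypeStatus>",
    "<NameAtomised>",
    "<GenusOrMonomial>", e$genus, "</GenusOrMonomial>",
    "<FirstEpithet>", e$epithet, "</FirstEpithet>",
    "<InfraspecificEpithet>none</InfraspecificEpithet>",
    "<AuthorTeam>", e$author, "</AuthorTeam>",
    "</NameAtomised>",
    "</ScientificName>",
    "<HigherTaxa><HigherTaxon>",
    "<HigherTaxonName rank=\"familia\">", e$family, "</HigherTaxonName>",
    "</HigherTaxon></HigherTaxa>",
    "</TaxonIdentified></Result>",
    "<IdentifiedBy>", e$identifiedby, "</IdentifiedBy>",
    "<TypifiedBy>", e$identifiedby, "</TypifiedBy>",
    "<Date>", e$iddate, "</Date>",
    "<ReferenceURI>http://example.org/ref/", e$fieldnumber, "</ReferenceURI>",
    "</Identification></Identifications>",
    "<Gathering>",
    "<GatheringAgent>", e$collector, "</GatheringAgent>",
    "<CollectorsFieldNumber>", e$fieldnumber, "</CollectorsFieldNumber>",
    "<LocalityText>", e$locality, "</LocalityText>",
    "<Country><Name>", e$country, "</Name></Country>",
    "<DateTime>", e$gatherdate, "</DateTime>",
    "<LatitudeDecimal>", e$lat, "</LatitudeDecimal>",
    "<LongitudeDecimal>", e$lon, "</LongitudeDecimal>",
    "<Altitude>", e$alt, "</Altitude>",
    "</Gathering>",
    "</Unit></Units></DataSet></DataSets>"
  )
}

dwc_like_xml <- function(f) {
  e <- lapply(f, xml_txt_escape)
  paste0(
    "<SimpleDarwinRecordSet><SimpleDarwinRecord>",
    "<institutionCode>", e$institution, "</institutionCode>",
    "<collectionCode>", e$collection, "</collectionCode>",
    "<catalogNumber>", e$unit, "</catalogNumber>",
    "<scientificName>", e$fullname, "</scientificName>",
    "<genus>", e$genus, "</genus>",
    "<family>", e$family, "</family>",
    "<recordedBy>", e$collector, "</recordedBy>",
    "<fieldNumber>", e$fieldnumber, "</fieldNumber>",
    "<country>", e$country, "</country>",
    "<identifiedBy>", e$identifiedby, "</identifiedBy>",
    "<eventDate>", e$gatherdate, "</eventDate>",
    "<decimalLatitude>", e$lat, "</decimalLatitude>",
    "<decimalLongitude>", e$lon, "</decimalLongitude>",
    "</SimpleDarwinRecord></SimpleDarwinRecordSet>"
  )
}

#' Shuffle a document without changing its content
#'
#' Randomly permutes sibling order and attribute order and re-flows
#' whitespace; the result is always similar to the input
#' ([are_similar()] returns `TRUE`).
#'
#' @param doc A [parse_record_xml()] document.
#' @param seed Integer seed (same seed, same output).
#' @return A new `record_document`.
#' @export
permute_document <- function(doc, seed = 1L) {
  stopifnot(inherits(doc, "record_document"))
  x <- xml2::read_xml(doc$raw)
  txt <- with_seed(seed, serialize_shuffled(xml2::xml_root(x), 0L))
  parse_record_xml(txt, doc$format_prefix, triple = doc$triple)
}

serialize_shuffled <- function(node, depth) {
  name <- xml2::xml_name(node)
  atts <- xml2::xml_attrs(node)
  if (length(atts) > 1) atts <- atts[sample.int(length(atts))]
  att_str <- if (length(atts)) {
    paste0(" ", paste0(names(atts), "=\"", xml_escape(unname(atts), attr = TRUE), "\"",
                       collapse = " "))
  } else ""
  contents <- xml2::xml_contents(node)
  types <- xml2::xml_type(contents)
  kids <- contents[types == "element"]
  own_text <- normalize_text(xml2::xml_text(contents[types %in% c("text", "cdata")],
                                            trim = FALSE))
  indent <- strrep(" ", depth * sample.int(3, 1))
  if (length(kids) == 0) {
    return(paste0(indent, "<", name, att_str, ">", xml_escape(own_text),
                  "</", name, ">"))
  }
  kids <- kids[sample.int(length(kids))]
  inner <- vapply(kids, serialize_shuffled, character(1), depth = depth + 1L)
  paste0(indent, "<", name, att_str, ">\n",
         paste(inner, collapse = "\n"),
         "\n", indent, "</", name, ">")
}

#' Alter exactly one value of a document
#'
#' Changes a single randomly chosen text value (appending a marker
#' character), producing a document dissimilar to the input — the smallest
#' change that forces a new revision on import.
#'
#' @param doc A [parse_record_xml()] document.
#' @param seed Integer seed.
#' @return A new `record_document`.
#' @export
mutate_document <- function(doc, seed = 1L) {
  stopifnot(inherits(doc, "record_document"))
  x <- xml2::read_xml(doc$raw)
  leaves <- xml2::xml_find_all(x, "//*[not(*)]")
  leaves <- leaves[nzchar(trimws(xml2::xml_text(leaves)))]
  if (length(leaves) == 0) {
    ca_abort("not-xml", "Document has no text value to mutate.")
  }
  with_seed(seed, {
    pick <- leaves[[sample.int(length(leaves), 1)]]
    xml2::xml_text(pick) <- paste0(xml2::xml_text(pick), "*")
  })
  parse_record_xml(as.character(x), doc$format_prefix, triple = doc$triple)
}
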