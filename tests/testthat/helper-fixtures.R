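# Shared helpers: independent oracles and fixture builders.

# Independent escaping oracle: character-by-character, written without
# reference to the package's gsub chain.
esc_oracle <- function(x) {
  chars <- strsplit(x, "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch == " ") return("+")
    if (ch %in% c("%", "+", ":")) return(sprintf("%%%02X", utf8ToInt(ch)))
    ch
  }, character(1))
  paste(out, collapse = "")
}

# random component strings including the characters that need escaping
rand_component <- function(n = 1) {
  alphabet <- c(letters, LETTERS, 0:9, " ", "+", ":", "%", ".", "-")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = "")
  }, character(1))
}

demo_agent <- function(name = "Ada Botanist", inst = "BGBM",
                       email = "ada@example.org") {
  agent(name, inst, email)
}

# a store pre-loaded with a fixture corpus; returns store, docs, outcomes
seeded_store <- function(n = 3, seed = 1, dialect = "abcd_like") {
  docs <- generate_dataset(n, seed = seed, dialect = dialect)
  st <- annostore()
  outcomes <- lapply(seq_along(docs), function(i) {
    import_record(st, docs[[i]], now = 1e12 + i * 1000)
  })
  list(store = st, docs = docs, outcomes = outcomes)
}

# first node with the given local name
node_by_local <- function(doc, local) {
  xml2::xml_find_first(doc$xml, sprintf("//*[local-name()='%s']", local))
}

# normalized text of the first element with the given local name
text_by_local <- function(doc, local) {
  trimws(xml2::xml_text(node_by_local(doc, local)))
}

# a valid random annotation on an imported revision
rand_annotation <- function(doc, rev_id, now, annotator = demo_agent(),
                            k = NULL) {
  leaves <- xml2::xml_find_all(doc$xml, "//*[not(*)]")
  leaves <- leaves[nzchar(trimws(xml2::xml_text(leaves)))]
  k <- k %||% sample(1:3, 1)
  idx <- sample(seq_along(leaves), min(k, length(leaves)))
  elements <- lapply(idx, function(i) {
    sel <- build_element_xpath(doc, leaves[[i]])
    expectation <- sample(c("Add", "Remove", "Update"), 1)
    if (expectation == "Remove") {
      annotated_element(sel, "Remove", comment = paste("remove", i))
    } else {
      annotated_element(sel, expectation,
                        value = paste0("value-", i),
                        comment = if (runif(1) < 0.5) paste("note", i) else NULL)
    }
  })
  if (runif(1) < 0.3) {
    elements <- c(elements, list(annotated_element("/", "Add", comment = "general")))
  }
  build_annotation(sample(c("Determination", "Gathering", "NomenclaturalType",
                            "ScientificName"), 1),
                   annotator, rev_id, elements, now = now)
}

# Independent brute-force fan-out oracle: re-evaluates every subscription,
# the curator roles and the fallback rule directly against store contents.
brute_force_recipients <- function(st, ev) {
  subs <- subscriptions_tbl(st)
  entry_of <- function(enc) st$annotations[[enc]]
  ev_entry <- entry_of(ev$annotation_id$encoded)
  triple_keys <- vapply(ev$triples, format_triple_id, character(1))

  # record text values by filter type, read straight from the raw XML
  filter_texts <- function(doc, filter) {
    locals <- list(
      "Species" = c("FullScientificNameString", "scientificName"),
      "Genus" = c("GenusOrMonomial", "genus"),
      "Family" = c("HigherTaxonName", "family"),
      "Collector name" = c("GatheringAgent", "recordedBy"),
      "Collector's number" = c("CollectorsFieldNumber", "fieldNumber"),
      "Country" = c("Name", "country"),
      "Institution code" = c("SourceInstitutionID", "institutionCode"),
      "Collection code" = c("SourceID", "collectionCode"),
      "Catalogue number" = c("UnitID", "catalogNumber"),
      "Identified by" = c("IdentifiedBy", "identifiedBy")
    )[[filter]]
    unlist(lapply(locals, function(l) {
      xml2::xml_text(xml2::xml_find_all(doc$xml,
        sprintf("//*[local-name()='%s']", l)))
    }))
  }
  # documents referenced by the published annotation
  ann_docs <- local({
    a <- ev_entry$obj
    recs <- list()
    collect <- function(a) {
      if (inherits(a, "ca_annotation")) {
        e <- st$records[[a$record$encoded]]
        if (!is.null(e)) recs[[length(recs) + 1L]] <<- e$document
      } else if (inherits(a, "ca_curatorial")) {
        t <- entry_of(a$target_annotation$encoded)
        if (!is.null(t)) collect(t$obj)
      } else {
        for (m in a$members) {
          e <- entry_of(m$encoded)
          if (!is.null(e)) collect(e$obj)
        }
      }
    }
    collect(a)
    recs
  })
  ann_agent_name <- ev$agent_name
  matches <- function(criteria) {
    for (f in names(criteria)) {
      v <- tolower(criteria[[f]])
      if (f == "Annotator") {
        if (!grepl(v, tolower(ann_agent_name), fixed = TRUE)) return(FALSE)
        next
      }
      ok <- FALSE
      for (d in ann_docs) {
        texts <- tolower(trimws(filter_texts(d, f)))
        if (any(grepl(v, texts, fixed = TRUE))) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }

  recipients <- character()
  # (a) prior annotators holding the automatic topic
  for (i in seq_len(nrow(subs))) {
    if (subs$topic[i] != "own_annotated_records") next
    who <- subs$subscriber[i]
    prior <- FALSE
    for (enc in names(st$annotations)) {
      e <- st$annotations[[enc]]
      if (enc != ev$annotation_id$encoded && e$state == "published" &&
          inherits(e$obj, "ca_annotation") && identical(e$owner, who) &&
          format_triple_id(e$obj$record$triple) %in% triple_keys) {
        prior <- TRUE
      }
    }
    if (prior) recipients <- c(recipients, who)
  }
  # (b) curators; track collections without one
  uncurated <- character()
  for (tr in ev$triples) {
    members <- character()
    for (r in st$roles) {
      if (r$institution == tr$institution && r$collection == tr$collection) {
        members <- r$members
      }
    }
    if (length(members) == 0) uncurated <- c(uncurated, format_triple_id(tr))
    recipients <- c(recipients, members)
  }
  # (c) filter-based
  for (i in seq_len(nrow(subs))) {
    if (subs$topic[i] != "filter_based") next
    if (matches(subs$criteria[[i]])) recipients <- c(recipients, subs$subscriber[i])
  }
  # (d) fallback contacts
  if (length(uncurated) > 0) {
    mails <- character()
    for (d in ann_docs) {
      if (!format_triple_id(d$triple) %in% uncurated) next
      mails <- c(mails, xml2::xml_text(xml2::xml_find_all(
        d$xml, "//*[local-name()='Email' or local-name()='EmailAddress']"
      )))
    }
    recipients <- c(recipients, trimws(mails), ev$extra_contacts)
  }
  sort(unique(setdiff(recipients, ev$actor)))
}
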