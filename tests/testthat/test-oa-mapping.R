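oa <- function(local) paste0("http://www.w3.org/ns/oa#", local)
ans <- function(local) paste0(ca_namespaces()[["annot"]], local)

simple_annotation <- function(now = 1500, elements = NULL) {
  elements <- elements %||% list(
    annotated_element("/u[1]/name[1]", "Update", value = "Guatteria poiteaui")
  )
  build_annotation("Determination", demo_agent(),
                   record_id(triple_id("BGBM", "Herbarium Berolinense",
                                               "B 18 0014862"),
                                     1379406965371, "abcd2.06b"),
                   elements, now = now)
}

test_that("regular annotations map onto provenance, body and target parts", {
  a <- simple_annotation()
  g <- annotation_to_oa(a)
  tr <- g$triples

  ann <- tr$s[tr$p == oa("motivatedBy")]
  expect_equal(tr$o[tr$p == oa("motivatedBy")], ans("Determination"))
  expect_equal(tr$o[tr$p == oa("annotatedAt")], format_instant(1500))

  # the proposed value lives in the body's rdf:value
  body <- tr$o[tr$s == ann & tr$p == oa("hasBody")]
  expect_length(body, 1)
  expect_equal(tr$o[tr$s == body & tr$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#value"],
               "Guatteria poiteaui")
  expect_equal(tr$o[tr$s == body & tr$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"],
               ans("Update"))

  # the target cites source, selector and state with version and cache
  target <- tr$o[tr$s == ann & tr$p == oa("hasTarget")]
  expect_equal(tr$o[tr$s == body & tr$p == oa("hasScope")], target)
  sel <- tr$o[tr$s == target & tr$p == oa("hasSelector")]
  expect_equal(tr$o[tr$s == sel & tr$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#value"],
               "/u[1]/name[1]")
  state <- tr$o[tr$s == target & tr$p == oa("hasState")]
  expect_equal(tr$o[tr$s == state & tr$p == oa("when")],
               format_instant(1379406965371))
  expect_match(tr$o[tr$s == state & tr$p == oa("cachedSource")],
               "1379406965371:abcd2.06b$")
})

test_that("general comments have a description body and no selector node", {
  a <- simple_annotation(elements = list(
    annotated_element("/", "Add", comment = "whole-record remark")
  ))
  tr <- annotation_to_oa(a)$triples
  expect_equal(tr$o[tr$p == "http://purl.org/dc/terms/description"],
               "whole-record remark")
  expect_length(tr$o[tr$p == oa("hasSelector")], 0)
})

test_that("multi-element annotations are scope-linked bijectively", {
  a <- simple_annotation(elements = list(
    annotated_element("/u[1]/lat[1]", "Update", value = "4.2"),
    annotated_element("/u[1]/lon[1]", "Update", value = "-71.9")
  ))
  tr <- annotation_to_oa(a)$triples
  bodies <- tr$o[tr$p == oa("hasBody")]
  targets <- tr$o[tr$p == oa("hasTarget")]
  scopes <- tr[tr$p == oa("hasScope"), ]
  expect_length(bodies, 2)
  expect_length(targets, 2)
  # one scope link per element, forming a bijection with no cross links
  expect_equal(nrow(scopes), 2)
  expect_setequal(scopes$s, bodies)
  expect_setequal(scopes$o, targets)
  expect_equal(anyDuplicated(scopes$o), 0)
})

test_that("curatorial graphs target the annotation and carry decision bodies", {
  a <- simple_annotation(elements = list(
    annotated_element("/u[1]/a[1]", "Update", value = "x"),
    annotated_element("/u[1]/b[1]", "Remove", comment = "drop")
  ))
  carl <- demo_agent("Carl Curator", "BGBM", "c@example.org")
  ca <- build_curatorial(carl, a,
                         data.frame(element = 1:2,
                                    decision = c("Accepted", "Rejected"),
                                    comment = c(NA, "cannot confirm")),
                         now = 2500, target_published = TRUE)
  tr <- curatorial_to_oa(ca)$triples
  expect_equal(tr$o[tr$p == oa("motivatedBy")], ans("Curatorial"))
  # target is the annotated annotation's URI
  target_ann_uri <- annotation_to_oa(a)$triples$s[1]
  expect_equal(tr$o[tr$p == oa("hasTarget")], target_ann_uri)
  results <- tr$o[tr$p == paste0(ca_namespaces()[["decision"]], "hasResult")]
  expect_setequal(results, c(ans("accepted"), ans("rejected")))
  expect_equal(tr$o[tr$p == "http://purl.org/dc/terms/description"],
               "cannot confirm")
  # scope links reference the annotated elements' bodies
  scopes <- tr$o[tr$p == oa("hasScope")]
  expect_setequal(sub(".*#", "", scopes), c("body-1", "body-2"))
})

test_that("batch graphs have no body and one target per member", {
  ada <- demo_agent()
  mk <- function(ms, unit) {
    build_annotation("Determination", ada,
                     record_id(triple_id("BGBM", "Coll", unit), 1e12, "abcd2.06b"),
                     list(annotated_element("/a[1]", "Update", value = "same")),
                     now = ms)
  }
  b <- build_batch(ada, list(mk(1, "U1"), mk(2, "U2"), mk(3, "U3")), now = 100)
  tr <- batch_to_oa(b)$triples
  expect_length(tr$o[tr$p == oa("hasBody")], 0)
  expect_length(tr$o[tr$p == oa("hasTarget")], 3)
  expect_equal(tr$o[tr$p == oa("motivatedBy")], ans("BatchAnnotation"))

  carl <- demo_agent("Carl Curator", "BGBM", "c@example.org")
  cur <- lapply(list(mk(4, "U1"), mk(5, "U2")), function(m) {
    build_curatorial(carl, m, data.frame(element = 1, decision = "Accepted"),
                     now = 200 + m$id$object_id, target_published = TRUE)
  })
  cb <- build_batch(carl, cur, now = 300)
  expect_equal(batch_to_oa(cb)$triples$o[batch_to_oa(cb)$triples$p == oa("motivatedBy")],
               ans("BatchCuratorialAnnotation"))

  # round trip preserves member order
  b2 <- oa_to_annotation(parse_graph(render_graph(batch_to_oa(b), "turtle"), "turtle"))
  expect_equal(vapply(b2$members, function(m) m$encoded, character(1)),
               vapply(b$members, function(m) m$encoded, character(1)))
})

test_that("serializations re-parse isomorphically in both syntaxes", {
  a <- simple_annotation(elements = list(
    annotated_element("/u[1]/a[1]", "Update", value = "tricky \"quotes\" & <tags>",
                      comment = "line\nbreak and unicode: Ä é ß"),
    annotated_element("/", "Add", comment = "general")
  ))
  g <- annotation_to_oa(a)
  for (syntax in c("turtle", "rdf-xml")) {
    txt <- render_graph(g, syntax)
    g2 <- parse_graph(txt, syntax)
    expect_true(graph_isomorphic(g, g2), label = paste(syntax, "re-parse isomorphic"))
  }
  expect_error(render_graph(g, "n-quads"), class = "collann_error_unknown_syntax")
  expect_false(graph_isomorphic(g, oa_vocabulary_graph()))
})

test_that("reconstruction inverts serialization and requires scope links", {
  set.seed(99)
  docs <- generate_dataset(4, seed = 40)
  for (i in 1:8) {
    doc <- docs[[(i - 1) %% 4 + 1]]
    rid <- record_id(doc$triple, 1e12 + i, doc$format_prefix)
    a <- rand_annotation(doc, rid, now = 2e12 + i)
    g <- annotation_to_oa(a)
    a2 <- oa_to_annotation(parse_graph(render_graph(g, "turtle"), "turtle"))
    expect_identical(annotation_essence(a2), annotation_essence(a))
    # and to_oa of the reconstruction matches the original graph
    expect_true(graph_isomorphic(annotation_to_oa(a2), g))
  }

  a <- simple_annotation()
  g <- annotation_to_oa(a)
  # dropping the scope soft links makes elements unrecoverable
  broken <- oa_graph(g$triples[g$triples$p != oa("hasScope"), ])
  expect_error(oa_to_annotation(broken), class = "collann_error_malformed_graph")
  # dropping all targets is malformed
  no_target <- oa_graph(g$triples[g$triples$p != oa("hasTarget"), ])
  expect_error(oa_to_annotation(no_target), class = "collann_error_malformed_graph")
  # a bare standard motivation without an application subclass is rejected
  tr <- g$triples
  tr$o[tr$p == oa("motivatedBy")] <- oa("editing")
  expect_error(oa_to_annotation(oa_graph(tr)),
               class = "collann_error_unknown_motivation")
})

test_that("the vocabulary covers every mapped property and subclass axiom", {
  terms <- oa_terms()
  expect_equal(anyDuplicated(terms$term), 0)
  expect_equal(anyDuplicated(terms$uri), 0)
  needed <- c("oa:hasTarget", "oa:hasBody", "oa:hasScope", "oa:hasSelector",
              "oa:hasSource", "oa:hasState", "oa:cachedSource", "oa:when",
              "oa:motivatedBy", "oa:annotatedAt", "oa:annotatedBy",
              "rdf:value", "rdf:type", "dcterms:description", "decision:hasResult")
  expect_setequal(terms$term, needed)

  v <- oa_vocabulary_graph()$triples
  sub <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  expect_true(all(v$p == sub))
  for (m in c("Determination", "Gathering", "NomenclaturalType", "ScientificName")) {
    expect_true(any(v$s == ans(m) & v$o == oa("editing")))
  }
  expect_true(any(v$s == ans("Curatorial") & v$o == oa("replying")))
  expect_true(any(v$s == ans("BatchAnnotation") & v$o == oa("linking")))
  expect_true(any(v$s == ans("BatchCuratorialAnnotation") & v$o == oa("linking")))
  for (d in c("accepted", "rejected", "undecided", "update")) {
    expect_true(any(v$s == ans(d) &
                      v$o == paste0(ca_namespaces()[["decision"]], "Option")))
  }
})

test_that("an independent RDF library reads both serializations as the same graph", {
  py <- Sys.which("python")
  a <- simple_annotation(elements = list(
    annotated_element("/u[1]/a[1]", "Update", value = "x & \"y\"", comment = "c"),
    annotated_element("/", "Add", comment = "general")
  ))
  g <- annotation_to_oa(a)
  ttl <- tempfile(fileext = ".ttl")
  rdf <- tempfile(fileext = ".rdf")
  writeLines(render_graph(g, "turtle"), ttl)
  writeLines(render_graph(g, "rdf-xml"), rdf)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import rdflib",
    "from rdflib.compare import to_isomorphic",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='turtle')",
    "g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='xml')",
    "assert len(g1) == len(g2)",
    "assert to_isomorphic(g1) == to_isomorphic(g2)",
    "print(len(g1))"
  ), script)
  out <- suppressWarnings(system2(py, c(script, ttl, rdf), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0
  expect_equal(status, 0)
  expect_equal(as.integer(out[length(out)]), graph_size(g))
})
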