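rev_id_fixture <- function(ms = 1e12) {
  record_id(triple_id("BGBM", "Herbarium Berolinense", "B 18 0014862"),
                    ms, "abcd2.06b")
}

test_that("regular annotations enforce element payload rules", {
  ada <- demo_agent()
  rid <- rev_id_fixture()
  a <- build_annotation("Determination", ada, rid, list(
    annotated_element("/u[1]/name[1]", "Update", value = "Guatteria poiteaui")
  ), now = 1500)
  expect_s3_class(a, "ca_annotation")
  expect_equal(a$id$object_id, 1500)
  expect_equal(a$motivation, "Determination")

  expect_error(build_annotation("Determination", ada, rid, list(), now = 1),
               class = "collann_error_empty_elements")
  expect_error(build_annotation("Sighting", ada, rid, list(
    annotated_element("/", "Add", comment = "x")
  ), now = 1), class = "collann_error_unknown_motivation")
  expect_error(annotated_element("/a[1]", "Remove", value = "not allowed"),
               class = "collann_error_invalid_expectation_payload")
  expect_error(annotated_element("/a[1]", "Update"),
               class = "collann_error_invalid_expectation_payload")
  expect_error(annotated_element("/a[1]", "Erase", value = "x"),
               class = "collann_error_invalid_expectation_payload")
})

test_that("validation resolves selectors against the annotated revision", {
  doc <- generate_dataset(1, seed = 21)[[1]]
  rid <- record_id(doc$triple, 1e12, doc$format_prefix)
  country <- build_element_xpath(doc, node_by_local(doc, "Name"))
  ada <- demo_agent()

  ok <- build_annotation("Gathering", ada, rid, list(
    annotated_element(country, "Update", value = "Chile"),
    annotated_element("/", "Add", comment = "general comment")
  ), now = 1)
  rep <- validate_annotation(ok, doc)
  expect_true(all(rep$ok))

  bad <- build_annotation("Gathering", ada, rid, list(
    annotated_element("/DataSets[1]/Nothing[1]", "Remove", comment = "x")
  ), now = 2)
  rep2 <- validate_annotation(bad, doc)
  expect_false(rep2$ok[1])
  expect_equal(rep2$problem[1], "selector-unresolvable")

  # Add below an existing parent is plausible even though the node is absent
  add_ok <- build_annotation("Gathering", ada, rid, list(
    annotated_element(paste0(sub("/[^/]+$", "", country$expression), "/NewElement[1]"),
                      "Add", value = "proposed")
  ), now = 3)
  expect_true(all(validate_annotation(add_ok, doc)$ok))

  # Add below a missing parent is flagged
  add_bad <- build_annotation("Gathering", ada, rid, list(
    annotated_element("/DataSets[1]/Missing[1]/NewElement[1]", "Add", value = "v")
  ), now = 4)
  expect_equal(validate_annotation(add_bad, doc)$problem[1], "add-parent-missing")
})

test_that("annotation-type templates list the configured element paths", {
  g <- template_elements("Gathering")
  expect_true(all(c("field", "path") %in% names(g)))
  expect_true(any(grepl("GatheringAgent", g$path)))
  expect_true(any(grepl("Country/Name", g$path)))
  expect_true(any(grepl("Latitude", g$path)))
  expect_true(any(grepl("Longitude", g$path)))
  expect_true(any(grepl("DateTime", g$path)))

  s <- template_elements("ScientificName")
  expect_true(any(grepl("GenusOrMonomial", s$path)))
  expect_true(any(grepl("FirstEpithet", s$path)))

  expect_error(template_elements("Foo"), class = "collann_error_unknown_motivation")

  # every template path of every motivation points at a generated element
  doc <- generate_dataset(1, seed = 8)[[1]]
  for (m in c("Determination", "Gathering", "NomenclaturalType", "ScientificName")) {
    for (p in template_elements(m)$path) {
      leaf <- sub(".*/", "", p)
      expect_false(inherits(node_by_local(doc, leaf), "xml_missing"),
                   label = sprintf("template path %s (leaf %s) present", p, leaf))
    }
  }
})

test_that("curatorial annotations cover every element with a known decision", {
  ada <- demo_agent()
  carl <- demo_agent("Carl Curator", "BGBM", "carl@example.org")
  target <- build_annotation("Determination", ada, rev_id_fixture(), list(
    annotated_element("/a[1]", "Update", value = "x"),
    annotated_element("/b[1]", "Remove", comment = "drop")
  ), now = 10)

  ca <- build_curatorial(carl, target,
                         data.frame(element = 1:2,
                                    decision = c("Accepted", "Rejected"),
                                    comment = c("fine", NA)),
                         now = 20, target_published = TRUE)
  expect_s3_class(ca, "ca_curatorial")
  expect_equal(ca$motivation, "Curatorial")
  expect_equal(nrow(ca$curated), length(target$elements))

  expect_error(
    build_curatorial(carl, target, data.frame(element = 1, decision = "Accepted"),
                     now = 21, target_published = TRUE),
    class = "collann_error_uncovered_element"
  )
  expect_error(
    build_curatorial(carl, target,
                     data.frame(element = 1:2, decision = c("Maybe", "Accepted")),
                     now = 22, target_published = TRUE),
    class = "collann_error_unknown_decision"
  )
  expect_error(
    build_curatorial(carl, target, data.frame(element = 1:2, decision = "Accepted"),
                     now = 23, target_published = FALSE),
    class = "collann_error_target_not_published"
  )
  # the decision named "Update" (already updated for another reason) is legal
  upd <- build_curatorial(carl, target,
                          data.frame(element = 1:2, decision = "Update"),
                          now = 24, target_published = TRUE)
  expect_equal(unique(upd$curated$decision), "Update")
})

test_that("batches link identical annotations and preserve member order", {
  ada <- demo_agent()
  mk <- function(ms, unit) {
    build_annotation("Determination", ada,
                     record_id(triple_id("BGBM", "Coll", unit), 1e12, "abcd2.06b"),
                     list(annotated_element("/a[1]", "Update", value = "same")),
                     now = ms)
  }
  members <- list(mk(1, "U1"), mk(2, "U2"), mk(3, "U3"))
  b <- build_batch(ada, members, now = 100)
  expect_equal(b$motivation, "Batch")
  expect_equal(vapply(b$members, function(m) m$encoded, character(1)),
               vapply(members, function(m) m$id$encoded, character(1)))

  differing <- list(mk(1, "U1"), build_annotation("Determination", ada,
    record_id(triple_id("BGBM", "Coll", "U2"), 1e12, "abcd2.06b"),
    list(annotated_element("/a[1]", "Update", value = "DIFFERENT")), now = 2))
  expect_error(build_batch(ada, differing, now = 101),
               class = "collann_error_content_mismatch")
  expect_error(build_batch(ada, members[1], now = 102),
               class = "collann_error_too_few_members")

  carl <- demo_agent("Carl Curator", "BGBM", "carl@example.org")
  cur <- lapply(members, function(m) {
    build_curatorial(carl, m, data.frame(element = 1, decision = "Accepted"),
                     now = 200 + m$id$object_id, target_published = TRUE)
  })
  cb <- build_batch(carl, cur, now = 300)
  expect_equal(cb$motivation, "CuratorialBatch")
  expect_error(build_batch(ada, c(members[1], cur[1]), now = 301),
               class = "collann_error_heterogeneous_members")
})
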