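test_that("imports archive, reuse or demote according to similarity", {
  docs <- generate_dataset(2, seed = 31)
  st <- annostore()
  d <- docs[[1]]

  o1 <- import_record(st, d, now = 1e12)
  expect_equal(o1$kind, "first")
  expect_equal(o1$revision$status, "current")

  # a sibling-permuted copy is similar: reused, same persistent id
  o2 <- import_record(st, permute_document(d, 5), now = 1e12 + 1000)
  expect_equal(o2$kind, "reused")
  expect_equal(o2$revision$id$encoded, o1$revision$id$encoded)

  # one changed value: new revision, prior one demoted to historic
  o3 <- import_record(st, mutate_document(d, 5), now = 1e12 + 2000)
  expect_equal(o3$kind, "new_revision")
  expect_equal(o3$demoted$id$encoded, o1$revision$id$encoded)
  expect_equal(get_revision(st, o1$revision$id)$status, "historic")
  expect_equal(get_revision(st, o3$revision$id)$status, "current")

  # one current id per chain; a second triple adds a second chain
  expect_equal(list_current_records(st), o3$revision$id$encoded)
  import_record(st, docs[[2]], now = 1e12 + 3000)
  expect_length(list_current_records(st), 2)

  expect_error(get_revision(st, "A:B:C:1:dwc"), class = "collann_error_not_found")
})

test_that("archived raw bytes are bit-exact and version collisions bump", {
  d <- generate_dataset(1, seed = 32)[[1]]
  st <- annostore()
  o <- import_record(st, d, now = 1e12)
  expect_identical(get_revision(st, o$revision$id)$document$raw, d$raw)

  # same-millisecond (and clock-regressed) imports get the next free version
  o2 <- import_record(st, mutate_document(d, 1), now = 1e12)
  expect_equal(o2$revision$id$version_ms, 1e12 + 1)
  o3 <- import_record(st, mutate_document(d, 2), now = 1e12 - 5000)
  expect_equal(o3$revision$id$version_ms, 1e12 + 2)
})

test_that("drafts target current revisions only and publication is guarded", {
  s <- seeded_store(n = 2, seed = 33)
  st <- s$store
  ada <- demo_agent()
  rev <- s$outcomes[[1]]$revision

  a <- rand_annotation(s$docs[[1]], rev$id, now = 2e12, annotator = ada)
  id <- save_draft(st, a, ada)
  expect_s3_class(id, "annotation_id")
  expect_equal(id$system, "collann")

  # draft on an unknown record
  ghost <- build_annotation("Determination", ada,
    record_id(triple_id("X", "Y", "Z"), 1, "dwc"),
    list(annotated_element("/", "Add", comment = "x")), now = 3e12)
  expect_error(save_draft(st, ghost, ada), class = "collann_error_unknown_revision")

  # demote revision 1, then try to annotate it
  import_record(st, mutate_document(s$docs[[1]], 9), now = 3e12)
  late <- build_annotation("Determination", ada, rev$id,
    list(annotated_element("/", "Add", comment = "too late")), now = 4e12)
  expect_error(save_draft(st, late, ada), class = "collann_error_historic_revision")

  # publication: owner only, once only
  eve <- demo_agent("Eve Other", "K", "eve@example.org")
  register_agent(st, eve)
  expect_error(publish_annotation(st, id, eve), class = "collann_error_not_owner")
  ev <- publish_annotation(st, id, ada, now = 5e12)
  expect_s3_class(ev, "publication_event")
  expect_error(publish_annotation(st, id, ada), class = "collann_error_already_published")

  # curatorial publication needs curatorial rights on the collection
  carl <- demo_agent("Carl Curator", "BGBM", "carl@example.org")
  register_agent(st, carl)
  ca <- build_curatorial(carl, get_annotation(st, id),
                         data.frame(element = seq_along(a$elements), decision = "Accepted"),
                         now = 6e12, target_published = TRUE)
  cid <- save_draft(st, ca, carl)
  expect_error(publish_annotation(st, cid, carl),
               class = "collann_error_unauthorized_curation")
  assign_curator_role(st, carl, rev$id$triple$institution, rev$id$triple$collection)
  expect_s3_class(publish_annotation(st, cid, carl, now = 7e12), "publication_event")
})

test_that("published annotations are immutable and drafts stay private", {
  s <- seeded_store(n = 1, seed = 34)
  st <- s$store
  ada <- demo_agent()
  a <- rand_annotation(s$docs[[1]], s$outcomes[[1]]$revision$id, now = 2e12,
                       annotator = ada)
  id <- save_draft(st, a, ada)

  # drafts: owner reads, strangers do not, queries never return them
  expect_s3_class(get_annotation(st, id, reader = ada), "ca_annotation")
  expect_error(get_annotation(st, id), class = "collann_error_draft_not_public")
  expect_length(query_annotations(st), 0)
  expect_error(annotation_metadata_json(st, id),
               class = "collann_error_draft_not_public")

  publish_annotation(st, id, ada, now = 3e12)
  before <- render_graph(to_oa(get_annotation(st, id)), "turtle")
  # re-reads return identical serialized content
  after <- render_graph(to_oa(get_annotation(st, id)), "turtle")
  expect_identical(before, after)
})

test_that("query matches the brute-force scan on a fixture corpus", {
  s <- seeded_store(n = 6, seed = 35)
  st <- s$store
  ada <- demo_agent()
  set.seed(35)
  ids <- lapply(1:6, function(i) {
    a <- rand_annotation(s$docs[[i]], s$outcomes[[i]]$revision$id,
                         now = 2e12 + i * 1000, annotator = ada)
    id <- save_draft(st, a, ada)
    publish_annotation(st, id, ada, now = 3e12 + i * 1000)
    id$encoded
  })

  # linear-scan oracle over raw XML
  brute <- function(filter_local, value) {
    hit <- vapply(1:6, function(i) {
      texts <- xml2::xml_text(xml2::xml_find_all(
        s$docs[[i]]$xml, sprintf("//*[local-name()='%s']", filter_local)))
      any(grepl(tolower(value), tolower(texts), fixed = TRUE))
    }, logical(1))
    sort(unlist(ids[hit]))
  }
  countries <- vapply(s$docs, function(d) text_by_local(d, "Name"), character(1))
  for (cty in unique(countries)) {
    expect_equal(query_annotations(st, c(Country = cty)), brute("Name", cty))
  }
  fams <- vapply(s$docs, function(d) text_by_local(d, "HigherTaxonName"), character(1))
  expect_equal(query_annotations(st, c(Family = fams[1])),
               brute("HigherTaxonName", fams[1]))
  # conjunction
  expect_equal(
    query_annotations(st, c(Country = countries[1], Family = fams[1])),
    intersect(brute("Name", countries[1]), brute("HigherTaxonName", fams[1]))
  )
  expect_equal(query_annotations(st), sort(unlist(ids)))
  expect_length(query_annotations(st, c(Annotator = "Nobody")), 0)
  expect_error(query_annotations(st, c(Color = "blue")),
               class = "collann_error_unknown_filter_type")
})

test_that("record-scoped annotation listings follow revisions and triples", {
  s <- seeded_store(n = 1, seed = 36)
  st <- s$store
  ada <- demo_agent()
  rev1 <- s$outcomes[[1]]$revision
  a1 <- rand_annotation(s$docs[[1]], rev1$id, now = 2e12, annotator = ada)
  id1 <- save_draft(st, a1, ada)
  publish_annotation(st, id1, ada, now = 2.1e12)

  o2 <- import_record(st, mutate_document(s$docs[[1]], 3), now = 3e12)
  a2 <- rand_annotation(s$docs[[1]], o2$revision$id, now = 4e12, annotator = ada)
  id2 <- save_draft(st, a2, ada)
  publish_annotation(st, id2, ada, now = 4.1e12)

  # by triple: history includes the annotation on the historic revision
  by_triple <- annotations_for_record(st, s$docs[[1]]$triple)
  expect_setequal(by_triple, c(id1$encoded, id2$encoded))
  # by revision id: scoped to that revision only
  expect_equal(annotations_for_record(st, o2$revision$id), id2$encoded)
  expect_equal(annotations_for_record(st, rev1$id), id1$encoded)
  expect_length(annotations_for_record(st, triple_id("N", "O", "PE")), 0)
})

test_that("public metadata lists uri, annotator, type and date but no e-mail", {
  s <- seeded_store(n = 1, seed = 37)
  st <- s$store
  ada <- demo_agent()
  a <- build_annotation("Determination", ada, s$outcomes[[1]]$revision$id,
                        list(annotated_element("/", "Add", comment = "note")),
                        now = 2e12)
  id <- save_draft(st, a, ada)
  publish_annotation(st, id, ada, now = 3e12)
  meta <- annotation_metadata_json(st, id)
  expect_named(meta, c("uri", "annotator", "type", "date"))
  expect_equal(meta$type, "Determination")
  expect_equal(meta$annotator, "Ada Botanist")
  expect_match(meta$date, "^2033-") # 2e12 ms is in 2033
  expect_false(any(grepl("@", unlist(meta), fixed = TRUE)))

  carl <- demo_agent("Carl Curator", "BGBM", "c@example.org")
  assign_curator_role(st, carl, a$record$triple$institution, a$record$triple$collection)
  ca <- build_curatorial(carl, get_annotation(st, id),
                         data.frame(element = 1, decision = "Accepted"),
                         now = 4e12, target_published = TRUE)
  cid <- save_draft(st, ca, carl)
  publish_annotation(st, cid, carl, now = 5e12)
  expect_equal(annotation_metadata_json(st, cid)$type, "Curatorial")
})
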