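test_that("subscription payload rules are enforced and adds are idempotent", {
  st <- annostore()
  ada <- demo_agent()
  register_agent(st, ada)
  id1 <- add_subscription(st, ada, "filter_based", c(Country = "Peru"))
  id2 <- add_subscription(st, ada, "filter_based", c(Country = "Peru"))
  expect_equal(id1, id2)
  expect_equal(nrow(subscriptions_tbl(st)), 1)

  expect_error(add_subscription(st, ada, "filter_based"),
               class = "collann_error_invalid_criteria")
  expect_error(add_subscription(st, ada, "filter_based", c(Color = "blue")),
               class = "collann_error_unknown_filter_type")
  expect_error(add_subscription(st, ada, "everything"),
               class = "collann_error_invalid_criteria")
  expect_error(add_subscription(st, ada, "own_annotated_records", c(Country = "Peru")),
               class = "collann_error_invalid_criteria")
})

test_that("publishing auto-creates the annotator's own-records subscription", {
  s <- seeded_store(n = 1, seed = 51)
  ada <- demo_agent()
  a <- rand_annotation(s$docs[[1]], s$outcomes[[1]]$revision$id, now = 2e12,
                       annotator = ada)
  id <- save_draft(s$store, a, ada)
  expect_equal(nrow(subscriptions_tbl(s$store)), 0) # draft saves change nothing
  expect_length(s$store$outbox, 0)
  publish_annotation(s$store, id, ada, now = 3e12)
  subs <- subscriptions_tbl(s$store)
  expect_true(any(subs$subscriber == ada$id & subs$topic == "own_annotated_records"))
})

test_that("curators, subscribers and fallback contacts receive one message each", {
  s <- seeded_store(n = 2, seed = 52)
  st <- s$store
  ada <- demo_agent()
  carl <- demo_agent("Carl Curator", "BGBM", "carl@example.org")
  trip1 <- s$docs[[1]]$triple
  assign_curator_role(st, carl, trip1$institution, trip1$collection)

  country1 <- text_by_local(s$docs[[1]], "Name")
  fran <- demo_agent("Fran Follower", "NY", "fran@example.org")
  register_agent(st, fran)
  add_subscription(st, fran, "filter_based", c(Country = country1))

  a1 <- rand_annotation(s$docs[[1]], s$outcomes[[1]]$revision$id, now = 2e12,
                        annotator = ada)
  ev1 <- publish_annotation(st, save_draft(st, a1, ada), ada, now = 3e12)
  ob <- outbox_tbl(st)
  # curator notified for their collection, filter subscriber for the country
  expect_true(any(ob$recipient == carl$id & ob$reason == "curated_collections"))
  expect_true(any(ob$recipient == fran$id & ob$reason == "filter_based"))
  # one message per recipient per event
  expect_equal(anyDuplicated(paste(ob$recipient, ob$annotation)), 0)

  # second record: no curator -> fallback to the record metadata contact
  a2 <- rand_annotation(s$docs[[2]], s$outcomes[[2]]$revision$id, now = 4e12,
                        annotator = ada)
  publish_annotation(st, save_draft(st, a2, ada), ada,
                     extra_contacts = "extra@example.org", now = 5e12)
  ob2 <- outbox_tbl(st)
  mail <- text_by_local(s$docs[[2]], "Email")
  expect_true(any(ob2$recipient == mail & ob2$reason == "fallback_contact"))
  expect_true(any(ob2$recipient == "extra@example.org"))

  # curatorial publication notifies the original annotator
  ca <- build_curatorial(carl, get_annotation(st, a1$id),
                         data.frame(element = seq_along(a1$elements),
                                    decision = "Accepted"),
                         now = 6e12, target_published = TRUE)
  publish_annotation(st, save_draft(st, ca, carl), carl, now = 7e12)
  ob3 <- outbox_tbl(st)
  expect_true(any(ob3$recipient == ada$id & ob3$reason == "own_annotated_records"))

  # drain empties the outbox
  drained <- drain_outbox(st)
  expect_gt(nrow(drained), 0)
  expect_equal(nrow(outbox_tbl(st)), 0)
})

test_that("an agent matching several topics still gets exactly one message", {
  s <- seeded_store(n = 1, seed = 53)
  st <- s$store
  ada <- demo_agent()
  bob <- demo_agent("Bob Both", "K", "bob@example.org")
  register_agent(st, bob)
  # bob is a prior annotator AND a matching filter subscriber
  a0 <- rand_annotation(s$docs[[1]], s$outcomes[[1]]$revision$id, now = 2e12,
                        annotator = bob)
  publish_annotation(st, save_draft(st, a0, bob), bob, now = 2.5e12)
  add_subscription(st, bob, "filter_based",
                   c(Country = text_by_local(s$docs[[1]], "Name")))

  a1 <- rand_annotation(s$docs[[1]], s$outcomes[[1]]$revision$id, now = 3e12,
                        annotator = ada)
  ev <- publish_annotation(st, save_draft(st, a1, ada), ada, now = 4e12)
  msgs <- outbox_tbl(st)
  msgs <- msgs[msgs$annotation == a1$id$encoded, ]
  expect_equal(sum(msgs$recipient == bob$id), 1)
})

test_that("fan-out equals the brute-force subscription evaluation", {
  set.seed(54)
  s <- seeded_store(n = 5, seed = 54)
  st <- s$store
  agents <- lapply(1:6, function(i) {
    demo_agent(paste("Agent", i), sample(c("BGBM", "K", "NY"), 1),
               sprintf("agent%d@example.org", i))
  })
  for (ag in agents) register_agent(st, ag)
  # random curator assignments
  for (i in 1:3) {
    tr <- s$docs[[sample(5, 1)]]$triple
    assign_curator_role(st, sample(agents, 1)[[1]], tr$institution, tr$collection)
  }
  # random filter subscriptions
  pools <- list(
    c(Country = text_by_local(s$docs[[1]], "Name")),
    c(Family = text_by_local(s$docs[[2]], "HigherTaxonName")),
    c(Annotator = "Agent"),
    c(Country = "Atlantis")
  )
  for (i in 1:5) {
    add_subscription(st, sample(agents, 1)[[1]], "filter_based",
                     pools[[sample(length(pools), 1)]])
  }
  # publish a series of annotations and check each fan-out against the oracle
  for (i in 1:8) {
    who <- sample(agents, 1)[[1]]
    di <- sample(5, 1)
    a <- rand_annotation(s$docs[[di]], s$outcomes[[di]]$revision$id,
                         now = 2e12 + i * 1e6, annotator = who)
    id <- save_draft(st, a, who)
    ev <- publish_annotation(st, id, who, now = 3e12 + i * 1e6)
    got <- events_for_publication(st, ev)
    expect_equal(sort(unique(vapply(got, function(m) m$recipient, character(1)))),
                 brute_force_recipients(st, ev),
                 label = sprintf("fan-out for event %d", i))
  }
  expect_true(match_filter_criteria(st, list(), s$store$events[[1]]))
})
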