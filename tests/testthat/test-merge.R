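test_that("only_in conversion prohibits exactly outside the named
           clade", {
  g <- load_ontology(tiny_obo())
  t <- tiny_taxonomy()
  ax <- data.frame(go_id = "GO:0000002", relation = "only_in",
                   taxon_id = 3L)   # Eukaryota-like only
  rec <- convert_only_in(ax, t)
  cs <- constraint_set(rec, meta = list())
  cs$records$source <- "goc"
  # bacteria-like species: prohibited
  expect_true("GO:0000002" %in% expand_constraints(cs, g, t, 7L))
  # human-like species under the clade: not prohibited
  expect_false("GO:0000002" %in% expand_constraints(cs, g, t, 6L))
  # iff-test over every fixture taxon
  for (x in t$taxids) {
    expect_identical("GO:0000002" %in% expand_constraints(cs, g, t, x),
                     !is_in_subtree(t, x, 3L))
  }
  # only_in on the taxonomy root prohibits nowhere
  rec_root <- convert_only_in(
    data.frame(go_id = "GO:0000002", relation = "only_in",
               taxon_id = 1L), t)
  expect_identical(nrow(rec_root), 0L)
  # unknown taxon errors, naming the axiom
  expect_error(convert_only_in(
    data.frame(go_id = "GO:0000002", relation = "only_in",
               taxon_id = 424242L), t), "GO:0000002")
})

test_that("only_in conversion iff holds exhaustively on random trees", {
  for (seed in c(5L, 17L)) {
    b <- make_fixture_bundle(fixture_spec(seed = seed, n_lines = 10L),
                             tempfile())
    g <- b$g; t <- b$t
    targets <- sample(t$taxids, 4L)
    for (T_node in targets) {
      rec <- convert_only_in(
        data.frame(go_id = "GO:0000101", relation = "only_in",
                   taxon_id = T_node), t)
      if (nrow(rec) == 0L) {
        expect_identical(T_node, t$root)
        next
      }
      rec$source <- "goc"
      cs <- constraint_set(rec)
      closure <- c("GO:0000101", go_descendants(g, "GO:0000101"))
      for (x in t$taxids) {
        banned <- expand_constraints(cs, g, t, x)
        if (is_in_subtree(t, x, T_node)) {
          expect_length(intersect(banned, closure), 0L)
        } else {
          expect_true(all(closure %in% banned))
        }
      }
    }
  }
})

test_that("priority is manual > consortium > automatic and matches the
           sequential-overwrite oracle", {
  g <- load_ontology(tiny_obo())
  t <- tiny_taxonomy()
  # auto never_in(B) for Fungi-like vs consortium only_in(B, Eukaryota):
  # consortium wins, B allowed inside Eukaryota (and so inside Fungi)
  auto <- crec(4L, "GO:0000002", reference_node = 4L)
  goc_ax <- data.frame(go_id = "GO:0000002", relation = "only_in",
                       taxon_id = 3L)
  cs <- merge_constraints(auto, goc_ax, NULL, t, g)
  expect_false("GO:0000002" %in% expand_constraints(cs, g, t, 5L))
  expect_true("GO:0000002" %in% expand_constraints(cs, g, t, 7L))
  expect_true(nrow(cs$conflicts) >= 1L)
  expect_identical(cs$conflicts$overridden_source[1L], "automatic")

  # consortium never_in vs manual allow: manual wins inside its subtree
  goc_ni <- data.frame(go_id = "GO:0000002", relation = "never_in",
                       taxon_id = 3L)
  man <- data.frame(taxon_id = 4L, go_id = "GO:0000002",
                    directive = "allow", stringsAsFactors = FALSE)
  cs2 <- merge_constraints(constraint_set()$records, goc_ni, man, t, g)
  expect_false("GO:0000002" %in% expand_constraints(cs2, g, t, 5L))
  # ... but the consortium prohibition still holds outside the hole
  expect_true("GO:0000002" %in% expand_constraints(cs2, g, t, 6L))

  # no overlaps -> union of inputs, no conflicts
  cs3 <- merge_constraints(crec(2L, "GO:0000010"),
                           data.frame(go_id = "GO:0000011",
                                      relation = "never_in",
                                      taxon_id = 3L), NULL, t, g)
  expect_identical(nrow(cs3$records), 2L)
  expect_identical(nrow(cs3$conflicts), 0L)

  # randomized overlap suites vs the three-pass overwrite oracle
  set.seed(77)
  b <- make_fixture_bundle(fixture_spec(seed = 12L, n_lines = 10L),
                           tempfile())
  terms <- b$g$ids[!b$g$obsolete]
  for (rep_i in 1:8) {
    auto_r <- crec(sample(b$t$taxids, 2L), sample(terms, 2L),
                   source = "automatic")
    goc_r <- data.frame(go_id = sample(terms, 2L),
                        relation = sample(c("never_in", "only_in"), 2L,
                                          replace = TRUE),
                        taxon_id = sample(b$t$taxids, 2L))
    man_r <- data.frame(taxon_id = sample(b$t$taxids, 2L),
                        go_id = sample(terms, 2L),
                        directive = sample(c("never_in", "allow"), 2L,
                                           replace = TRUE),
                        stringsAsFactors = FALSE)
    csr <- suppressWarnings(
      merge_constraints(auto_r, goc_r, man_r, b$t, b$g))
    for (x in b$t$taxids) {
      expect_identical(expand_constraints(csr, b$g, b$t, x),
                       oracle_expand(csr, b$g, b$t, x))
    }
  }
})

test_that("merging is a fixed point, order-insensitive, and rejects
           contradictory manual directives", {
  g <- load_ontology(tiny_obo())
  t <- tiny_taxonomy()
  auto <- crec(4L, "GO:0000002", reference_node = 4L)
  goc <- data.frame(go_id = "GO:0000003", relation = "never_in",
                    taxon_id = 2L)
  man <- data.frame(taxon_id = 4L, go_id = "GO:0000002",
                    directive = "allow", stringsAsFactors = FALSE)
  cs <- merge_constraints(auto, goc, man, t, g)
  # re-merging the merged records with empty higher tiers changes nothing
  cs_again <- merge_constraints(cs$records, NULL, NULL, t, g)
  for (x in t$taxids) {
    expect_identical(expand_constraints(cs_again, g, t, x),
                     expand_constraints(cs, g, t, x))
  }
  # input record order inside a tier does not matter
  cs_rev <- merge_constraints(auto[rev(seq_len(nrow(auto))), ],
                              goc, man, t, g)
  for (x in t$taxids) {
    expect_identical(expand_constraints(cs_rev, g, t, x),
                     expand_constraints(cs, g, t, x))
  }
  expect_error(
    merge_constraints(auto, NULL,
                      data.frame(taxon_id = c(4L, 4L),
                                 go_id = "GO:0000002",
                                 directive = c("allow", "never_in")),
                      t, g),
    "contradictory")
  # consortium-internal never_in/only_in collision warns, never_in wins
  goc_clash <- data.frame(go_id = "GO:0000002",
                          relation = c("never_in", "only_in"),
                          taxon_id = c(3L, 3L))
  expect_warning(csx <- merge_constraints(constraint_set()$records,
                                          goc_clash, NULL, t, g),
                 "collision")
  expect_true("GO:0000002" %in% expand_constraints(csx, g, t, 5L))
})

test_that("manual-constraint files parse taxids, names, comments, and
           reject bad syntax", {
  t <- tiny_taxonomy()
  path <- tempfile()
  writeLines(c("# manual overrides",
               "5 GO:0009534 never_in",
               "",
               "Fungi GO:0000002 allow   # by name",
               "666 GO:0000003 only_in"), path)
  man <- read_manual_constraints(path, t)
  expect_identical(man$taxon_id, c(5L, 4L, 562L))
  expect_identical(man$directive, c("never_in", "allow", "only_in"))
  writeLines("5 GO:0000002 frobnicate", path)
  expect_error(read_manual_constraints(path, t), "unknown directive")
  writeLines("Atlantis GO:0000002 never_in", path)
  expect_error(read_manual_constraints(path, t), "line 1")
  writeLines("5 GO:12 never_in", path)
  expect_error(read_manual_constraints(path, t), "malformed GO id")
})

test_that("the annotation audit flags prohibited terms, their
           descendants, and nothing allowed", {
  # chloroplast-like scenario: a plant-restricted term annotated in a
  # trypanosome-like lineage must be flagged
  extra <- c("",
             "[Term]", "id: GO:0009534", "name: chloroplast_thylakoid",
             "namespace: cellular_component", "is_a: GO:0000011",
             "relationship: only_in_taxon NCBITaxon:4")
  g <- load_ontology(tiny_obo(extra = extra))
  t <- tiny_taxonomy()   # 4 = the plant-stand-in clade here
  cs <- merge_constraints(constraint_set()$records,
                          extract_goc_axioms(g), NULL, t, g)
  gaf <- write_gaf_fixture(c(
    gaf_text_line("Q38AK2", "GO:0009534", 7, evidence = "IBA"), # violation
    gaf_text_line("OK1", "GO:0009534", 5, evidence = "IBA"),    # inside clade
    gaf_text_line("OK2", "GO:0000001", 7),                      # allowed term
    gaf_text_line("NOTL", "GO:0009534", 7,
                  qualifier = "NOT|located_in")))               # NOT: skipped
  v <- cmd_audit(gaf, cs, g, t)
  expect_identical(v$object_id, "Q38AK2")
  expect_identical(v$violated_constraint_go, "GO:0009534")
  expect_identical(v$relation, "only_in")
  expect_identical(v$source, "goc")

  # violation via a GO-descendant of the constrained term
  g2 <- load_ontology(tiny_obo())
  cs2 <- merge_constraints(crec(2L, "GO:0000002", reference_node = 2L),
                           NULL, NULL, t, g2)
  gaf2 <- write_gaf_fixture(
    gaf_text_line("PD", "GO:0000005", 7))  # descendant of GO:0000002
  v2 <- cmd_audit(gaf2, cs2, g2, t)
  expect_identical(v2$go_id, "GO:0000005")
  expect_identical(v2$violated_constraint_go, "GO:0000002")
  expect_identical(v2$source, "automatic")
})
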