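test_that("species aggregation takes the per-term maximum and lifts
           scores onto ancestors", {
  g <- load_ontology(tiny_obo())
  preds <- data.frame(protein = c("p1", "p2", "p2"),
                      go_id = c("GO:0000003", "GO:0000003",
                                "GO:0000002"),
                      score = c(0.7, 0.9, 0.4))
  sp <- aggregate_species(preds, 5L, g)
  expect_identical(unname(sp$scores[["GO:0000003"]]), 0.9)
  # unscored parent inherits at least the child's score after closure
  expect_true(sp$scores[["GO:0000002"]] >= 0.9)
  expect_true(sp$scores[["GO:0000001"]] >= 0.9)
  # roots are dropped from the score set
  expect_false(ROOT_BP %in% names(sp$scores))
  # empty input
  sp0 <- aggregate_species(preds[0, ], 5L, g)
  expect_length(sp0$scores, 0L)
  expect_error(aggregate_species(transform(preds, score = score + 1),
                                 5L, g), "input error")
  # per-threshold set closure equality oracle: at any tau the predicted
  # set is ancestor-closed
  for (tau in c(0.3, 0.5, 0.8)) {
    P <- names(sp$scores)[sp$scores >= tau]
    closed <- setdiff(unique(unlist(lapply(P, function(x)
      c(x, oracle_ancestors(g, x))))), c(ROOT_BP, ROOT_MF, ROOT_CC))
    expect_setequal(P, closed)
  }
})

test_that("constraint filtering removes exactly the prohibited set and
           is idempotent", {
  g <- load_ontology(tiny_obo())
  t <- tiny_taxonomy()
  sp <- aggregate_species(
    data.frame(protein = "p", go_id = c("GO:0000003", "GO:0000010"),
               score = c(0.8, 0.6)), 5L, g)
  cs <- constraint_set(crec(3L, "GO:0000002", reference_node = 3L))
  f1 <- apply_constraint_filter(sp, cs, g, t)
  expect_false(any(c("GO:0000002", "GO:0000003") %in% names(f1$scores)))
  expect_true("GO:0000010" %in% names(f1$scores))
  # no applicable constraints: identity
  sp7 <- aggregate_species(
    data.frame(protein = "p", go_id = "GO:0000010", score = 0.5), 7L, g)
  expect_identical(apply_constraint_filter(sp7, cs, g, t)$scores,
                   sp7$scores)
  # idempotence
  f2 <- apply_constraint_filter(f1, cs, g, t)
  expect_identical(f2$scores, f1$scores)
})

test_that("information content follows the smoothed base-2 formula and
           is monotone down the graph", {
  g <- load_ontology(tiny_obo())
  # fixture counts: root 99, term 24 -> ic = -log2(25/100) = 2 bits
  rec <- ann_df(c(rep("GO:0000002", 24L), rep("GO:0000001", 75L)))
  ft <- compute_frequencies(rec, g)
  expect_identical(unname(ft$cumulative[ROOT_BP]), 99L)
  ic <- information_content(ft, g)
  expect_equal(unname(unclass(ic)["GO:0000002"]), 2)
  expect_identical(unname(unclass(ic)[ROOT_BP]), 0)
  # monotone: child ic >= parent ic
  for (id in names(unclass(ic))) {
    for (ch in g$children[[id]]) {
      expect_true(unclass(ic)[[ch]] >= unclass(ic)[[id]])
    }
  }
  expect_error(information_content(
    structure(list(cumulative = integer()), class = "frequency_table"),
    g), "empty")
})

test_that("metric curves reproduce the forced examples", {
  g <- load_ontology(tiny_obo())
  ic <- information_content(
    compute_frequencies(ann_df(rep(c("GO:0000002", "GO:0000003"),
                                   c(10L, 5L))), g), g)
  # perfect prediction: P = T at some threshold
  sp <- structure(list(taxon_id = 5L,
                       scores = c("GO:0000001" = 0.9,
                                  "GO:0000002" = 0.9,
                                  "GO:0000003" = 0.9)),
                  class = "species_prediction")
  truth <- c("GO:0000001", "GO:0000002", "GO:0000003")
  mc <- metric_curve(sp, truth, ic, g)
  expect_identical(mc$fmax, 1)
  expect_identical(mc$smin, 0)
  # disjoint prediction: Fmax = 0
  mc0 <- metric_curve(
    structure(list(taxon_id = 5L, scores = c("GO:0000010" = 0.9)),
              class = "species_prediction"),
    truth = "GO:0000011", ic = ic, g = g)
  expect_identical(mc0$fmax, 0)
  # P = {a, b}, T = {a, c}: precision = recall = F = 1/2
  mch <- metric_curve(
    structure(list(taxon_id = 5L,
                   scores = c("GO:0000002" = 0.8, "GO:0000010" = 0.8)),
              class = "species_prediction"),
    truth = c("GO:0000002", "GO:0000011"), ic = ic, g = g)
  expect_identical(mch$fmax, 0.5)
  expect_identical(mch$curve$precision, 0.5)
  expect_identical(mch$curve$recall, 0.5)
  # empty ground truth is an error
  expect_error(metric_curve(sp, character(), ic, g), "ground truth")
})

test_that("uniform information content makes wFmax equal Fmax, and the
           curve matches the naive per-threshold oracle", {
  g <- load_ontology(tiny_obo())
  live <- g$ids[!g$obsolete]
  unif <- structure(stats::setNames(rep(1, length(live)), live),
                    class = "ic_table")
  real_ic <- information_content(
    compute_frequencies(ann_df(rep(c("GO:0000003", "GO:0000005"),
                                   c(7L, 3L))), g), g)
  set.seed(123)
  terms <- setdiff(live, c(ROOT_BP, ROOT_MF, ROOT_CC))
  for (i in 1:50) {
    k <- sample(2:5, 1L)
    scores <- stats::setNames(round(stats::runif(k), 2), sample(terms, k))
    scores <- scores[!duplicated(names(scores))]
    truth <- sample(terms, sample(2:4, 1L))
    sp <- structure(list(taxon_id = 5L, scores = scores),
                    class = "species_prediction")
    mu <- metric_curve(sp, truth, unif, g)
    expect_equal(mu$wfmax, mu$fmax, tolerance = 1e-12)
    mr <- metric_curve(sp, truth, real_ic, g)
    want <- oracle_metrics(scores, truth, real_ic)
    expect_equal(mr$fmax, want$fmax, tolerance = 1e-12)
    expect_equal(mr$wfmax, want$wfmax, tolerance = 1e-12)
    expect_equal(mr$smin, want$smin, tolerance = 1e-12)
  }
})

test_that("curve monotonicity: recall and mi non-decreasing, ru
           non-increasing as the threshold drops", {
  g <- load_ontology(tiny_obo())
  ic <- information_content(
    compute_frequencies(ann_df(rep("GO:0000003", 10L)), g), g)
  live <- setdiff(g$ids[!g$obsolete], c(ROOT_BP, ROOT_MF, ROOT_CC))
  set.seed(9)
  for (i in 1:40) {
    scores <- stats::setNames(stats::runif(5), sample(live, 5L))
    sp <- structure(list(taxon_id = 5L, scores = scores),
                    class = "species_prediction")
    mc <- metric_curve(sp, sample(live, 3L), ic, g)
    cv <- mc$curve
    expect_true(all(diff(cv$recall) >= -1e-12))
    expect_true(all(diff(cv$ru) <= 1e-12))
    expect_true(all(diff(cv$mi) >= -1e-12))
  }
})

test_that("the benchmark table improves under a filter that removes
           only planted false positives", {
  g <- load_ontology(tiny_obo())
  t <- tiny_taxonomy()
  corpus <- ann_df(rep(c("GO:0000003", "GO:0000010", "GO:0000011"),
                       each = 10L))
  ic <- information_content(compute_frequencies(corpus, g), g)
  truth <- list("5" = c("GO:0000001", "GO:0000002", "GO:0000003",
                        "GO:0000010", "GO:0000011"))
  # predictions: all truth terms at 0.9 plus higher-scored false
  # positives in the prohibited branch (GO:0000004 and its descendant),
  # so no threshold can separate them without the filter
  preds <- data.frame(
    protein = "p",
    go_id = c("GO:0000003", "GO:0000010", "GO:0000011", "GO:0000004",
              "GO:0000005"),
    score = c(0.9, 0.9, 0.9, 0.95, 0.95))
  cs <- constraint_set(crec(3L, "GO:0000004", reference_node = 3L))
  res <- evaluate_benchmark(list("5" = preds), truth,
                            list(ft = cs), g, t, ic)
  for (ns in unique(res$namespace)) {
    f_unf <- res$fmax[res$namespace == ns & res$filter == "unfilt"]
    f_flt <- res$fmax[res$namespace == ns & res$filter == "ft"]
    expect_true(f_flt >= f_unf)
  }
  # BP: the false positives lived there, improvement is strict
  expect_gt(res$fmax[res$namespace == "biological_process" &
                       res$filter == "ft"],
            res$fmax[res$namespace == "biological_process" &
                       res$filter == "unfilt"])
  # identical prediction and truth: all Fmax = 1
  perfect <- data.frame(protein = "p",
                        go_id = truth[["5"]], score = 1)
  res_p <- evaluate_benchmark(list("5" = perfect), truth, list(), g, t,
                              ic)
  expect_true(all(res_p$fmax == 1))
  # empty constraint set: filtered equals unfiltered
  res_e <- evaluate_benchmark(list("5" = preds), truth,
                              list(none = constraint_set()), g, t, ic)
  wide <- split(res_e, res_e$filter)
  expect_identical(wide$none$fmax, wide$unfilt$fmax)
  # species missing from truth: skipped with warning
  expect_warning(evaluate_benchmark(list("7" = preds), truth, list(),
                                    g, t, ic), "absent")
})
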