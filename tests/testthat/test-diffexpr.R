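test_that("opposite-direction duplicates are excluded from both groups", {
  df <- data.frame(id = c("P1", "P2", "P3", "P3"),
                   direction = c("up", "down", "up", "down"))
  ds <- load_dataset(df, name = "toy")
  expect_equal(ds$up, "P1")
  expect_equal(ds$down, "P2")
  expect_equal(unname(attr(ds, "log")["opposite_excluded"]), 1)
})

test_that("ID updates are applied before cleaning", {
  df <- data.frame(id = c("Q9X000", "P2"), direction = c("up", "down"))
  upd <- data.frame(old = "Q9X000", new = "P99999")
  ds <- load_dataset(df, id_updates = upd)
  expect_equal(ds$up, "P99999")
  expect_equal(unname(attr(ds, "log")["updated"]), 1)
})

test_that("within-group duplicates collapse and signed ratios give direction", {
  df <- data.frame(id = c("P1", "P1", "P2"), direction = c("up", "up", "down"))
  ds <- load_dataset(df)
  expect_equal(ds$up, "P1")
  expect_equal(unname(attr(ds, "log")["deduplicated"]), 1)
  df2 <- data.frame(id = c("A", "B"), log2_ratio = c(1.5, -0.7))
  ds2 <- load_dataset(df2)
  expect_equal(ds2$up, "A")
  expect_equal(ds2$down, "B")
})

test_that("malformed inputs are rejected with row information", {
  expect_error(load_dataset(data.frame(id = "P1", direction = "sideways")),
               "malformed direction.*row 1")
  expect_error(load_dataset(data.frame(id = c("P1", "P1"),
                                       direction = c("up", "down"))),
               "empty expression group")
})

test_that("Wilcoxon p-values agree with exact enumeration", {
  expect_equal(wilcoxon_p(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(enumerate_wilcoxon_p(c(1, 2), c(3, 4)), 1 / 3)
  set.seed(201)
  for (i in 1:10) {
    x <- sample(seq(0, 1, by = 1e-4), 6)
    y <- sample(seq(2, 3, by = 1e-4), 5)  # disjoint -> tie-free
    expect_equal(wilcoxon_p(x, y), enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-10)
    xy <- c(x, y)
    x2 <- xy[1:5]; y2 <- xy[6:11]
    expect_equal(wilcoxon_p(x2, y2), enumerate_wilcoxon_p(x2, y2),
                 tolerance = 1e-10)
  }
})

test_that("degenerate Wilcoxon inputs give p = 1", {
  expect_equal(wilcoxon_p(c(5, 5, 5), c(5, 5)), 1)
  x <- c(1.2, 3.4, 2.2)
  expect_equal(wilcoxon_p(x, x), 1)
})

test_that("exact and midrank-normal Wilcoxon agree for moderate samples", {
  set.seed(202)
  for (i in 1:10) {
    x <- stats::rnorm(18); y <- stats::rnorm(22, mean = 0.3)
    p_exact <- wilcoxon_p(x, y)  # tie-free, sizes <= 25 -> exact path
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("CLES matches pair enumeration, with half credit for ties", {
  expect_equal(cles(c(0.1, 0.3), c(0.0, 0.2)), 75)
  expect_equal(cles(1, 1), 50)
  expect_equal(cles(c(5, 6), c(1, 2)), 100)
  set.seed(203)
  for (i in 1:10) {
    x <- sample(1:6, 7, TRUE); y <- sample(1:6, 5, TRUE)  # ties likely
    expect_equal(cles(x, y), enumerate_cles(x, y))
    expect_equal(cles(x, y) + cles(y, x), 100)
    expect_gte(cles(x, y), 0); expect_lte(cles(x, y), 100)
  }
})

# a fully hand-computed 2v2 comparison used in several blocks below
hand_metrics <- data.frame(
  id = c("U1", "U2", "D1", "D2"),
  Zc = c(0.30, 0.10, -0.10, -0.20),
  nH2O = c(-0.70, -0.90, -0.75, -0.85))
hand_ds <- expression_dataset(up = c("U1", "U2"), down = c("D1", "D2"),
                              name = "hand")

test_that("a 2v2 toy reproduces the hand-computed comparison exactly", {
  cmp <- compare_groups(hand_ds, hand_metrics)
  z <- cmp$metrics$Zc
  expect_equal(z$mean_up, 0.20); expect_equal(z$mean_down, -0.15)
  expect_equal(z$delta, 0.35)
  expect_equal(z$cles, 100)        # both ups exceed both downs
  expect_equal(z$p, 1 / 3)         # exact 2v2 two-sided minimum
  h <- cmp$metrics$nH2O
  expect_equal(h$mean_up, -0.80); expect_equal(h$mean_down, -0.80)
  expect_equal(h$delta, 0, tolerance = 1e-12)
  expect_equal(h$cles, 50)         # -0.70 and -0.90 straddle both downs
  expect_equal(h$p, 1)             # perfectly interleaved ranks
})

test_that("identical group compositions give null statistics", {
  met <- data.frame(id = c("A1", "A2", "B1", "B2"),
                    Zc = c(0.1, 0.2, 0.1, 0.2),
                    nH2O = c(-0.7, -0.8, -0.7, -0.8))
  ds <- expression_dataset(up = c("A1", "A2"), down = c("B1", "B2"))
  cmp <- compare_groups(ds, met)
  expect_equal(cmp$metrics$Zc$delta, 0, tolerance = 1e-12)
  expect_equal(cmp$metrics$Zc$cles, 50)
  expect_equal(cmp$metrics$Zc$p, 1)
})

test_that("isoform-suffixed IDs fall back to the parent accession", {
  ds <- expression_dataset(up = c("U1-2"), down = c("D1", "MISSING"))
  cmp <- compare_groups(ds, hand_metrics)
  expect_equal(cmp$n_up, 1)
  expect_equal(cmp$n_down, 1)
  expect_equal(unname(cmp$dropped["down"]), 1)
  expect_equal(cmp$metrics$Zc$mean_up, 0.30)  # U1-2 resolved via parent U1
})

test_that("fully unresolvable groups raise an error listing the IDs", {
  ds <- expression_dataset(up = "NOPE", down = "D1")
  expect_error(compare_groups(ds, hand_metrics), "NOPE")
})

test_that("comparison is invariant to input row order", {
  perm <- hand_metrics[c(3, 1, 4, 2), ]
  cmp1 <- compare_groups(hand_ds, hand_metrics)
  cmp2 <- compare_groups(hand_ds, perm)
  expect_equal(cmp1$metrics, cmp2$metrics)
})

test_that("classification flags follow the thresholds", {
  mk <- function(dZ, pZ, cZ, dH = 0.001, pH = 0.8, cH = 51) {
    structure(list(name = "x", metrics = list(
      Zc = list(metric = "Zc", mean_up = dZ, mean_down = 0, delta = dZ,
                p = pZ, cles = cZ),
      nH2O = list(metric = "nH2O", mean_up = dH, mean_down = 0, delta = dH,
                  p = pH, cles = cH)),
      n_up = 10, n_down = 10, dropped = c(up = 0, down = 0)),
      class = "group_comparison")
  }
  c1 <- classify_comparison(mk(0.005, 0.2, 55))
  z1 <- c1[c1$metric == "Zc", ]
  expect_false(z1$large); expect_false(z1$significant); expect_false(z1$strong)
  c2 <- classify_comparison(mk(0.02, 0.01, 65))
  z2 <- c2[c2$metric == "Zc", ]
  expect_true(z2$large && z2$significant && z2$strong)
  # grouping predicate: focal metric beyond threshold, other metric quiet
  expect_true(z2$qualifies_up)
  c3 <- classify_comparison(mk(0.02, 0.01, 65, dH = 0.02, pH = 0.30, cH = 52))
  expect_true(c3[c3$metric == "Zc", "qualifies_up"])   # other metric quiet
  c4 <- classify_comparison(mk(0.02, 0.01, 65, dH = 0.02, pH = 0.01, cH = 52))
  expect_false(c4[c4$metric == "Zc", "qualifies_up"])  # other metric significant
  c5 <- classify_comparison(mk(-0.02, 0.01, 35))
  expect_true(c5[c5$metric == "Zc", "qualifies_down"])
})

test_that("threshold constructor rejects asymmetric CLES bounds", {
  expect_error(classification_thresholds(cles_bounds = c(45, 60)), "symmetric")
  expect_error(classification_thresholds(delta = -1), "positive")
})

test_that("the long-form summary has one row per dataset per metric", {
  ds2 <- expression_dataset(up = "U1", down = "D2", name = "second")
  ds3 <- expression_dataset(up = c("U2", "U1"), down = "D1", name = "third")
  s <- summarize_datasets(list(hand_ds, ds2, ds3), hand_metrics)
  expect_equal(nrow(s), 6)
  expect_equal(s$dataset, rep(c("hand", "second", "third"), each = 2))
  expect_equal(s$metric, rep(c("Zc", "nH2O"), times = 3))
  # determinism
  s2 <- summarize_datasets(list(hand_ds, ds2, ds3), hand_metrics)
  expect_identical(s, s2)
})

test_that("failing datasets are reported and the rest summarized", {
  bad <- expression_dataset(up = "NOPE", down = "D1", name = "bad")
  expect_warning(s <- summarize_datasets(list(hand_ds, bad), hand_metrics),
                 "bad")
  expect_equal(unique(s$dataset), "hand")
})
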