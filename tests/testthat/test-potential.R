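test_that("WRD reproduces hand-worked rank arithmetic", {
  a <- c(A = 2, B = 3, C = 1)
  expect_equal(wrd_at_point(a, up_ids = c("A", "B"), down_ids = "C"), 2)
  a2 <- c(A = 3, B = 1, C = 2)
  expect_equal(wrd_at_point(a2, up_ids = c("A", "B"), down_ids = "C"), 0)
  # identical multisets of equal size: perfectly balanced
  a3 <- c(u1 = 1, u2 = 2, d1 = 1, d2 = 2)
  expect_equal(wrd_at_point(a3, c("u1", "u2"), c("d1", "d2")), 0)
})

test_that("WRD is antisymmetric and bounded, equality only at separation", {
  set.seed(301)
  for (i in 1:100) {
    n_up <- sample(1:8, 1); n_down <- sample(1:8, 1)
    a <- stats::rnorm(n_up + n_down)
    names(a) <- paste0("p", seq_along(a))
    up <- names(a)[seq_len(n_up)]; down <- names(a)[-seq_len(n_up)]
    w <- wrd_at_point(a, up, down)
    expect_equal(wrd_at_point(a, down, up), -w, tolerance = 1e-12)
    expect_lte(abs(w), n_up * n_down + 1e-9)
    expect_equal(w, brute_wrd(a[up], a[down]), tolerance = 1e-12)
    separated <- min(a[up]) > max(a[down]) || max(a[up]) < min(a[down])
    expect_equal(abs(abs(w) - n_up * n_down) < 1e-9, separated)
  }
})

test_that("WRD is invariant under strictly monotone transforms", {
  set.seed(302)
  a <- stats::rnorm(12); names(a) <- paste0("p", 1:12)
  up <- names(a)[1:5]; down <- names(a)[6:12]
  w <- wrd_at_point(a, up, down)
  expect_equal(wrd_at_point(exp(a), up, down), w)
  expect_equal(wrd_at_point(2 * a + 17, up, down), w)
  expect_equal(wrd_at_point(atan(a), up, down), w)
})

test_that("group errors are raised for malformed inputs", {
  a <- c(x = 1, y = 2)
  expect_error(wrd_at_point(a, character(0), "y"), "non-empty")
  expect_error(wrd_at_point(a, "x", "x"), "overlap")
  expect_error(wrd_at_point(unname(a), "x", "y"), "named")
})

test_that("identical up and down compositions give an identically zero field", {
  seqs <- list(u1 = "AAGG", u2 = "QQWS", d1 = "AAGG", d2 = "QQWS")
  tab <- toy_aatable(seqs)
  ds <- expression_dataset(up = c("u1", "u2"), down = c("d1", "d2"))
  d <- potential_diagram(ds, tab, grid = grid_spec(n = 9))
  expect_equal(max(abs(d$wrd)), 0)
  # zero plateau: equipotential position is the plateau midpoint
  pos <- zero_contour_positions(d, "x")
  expect_true(pos$crossing)
  expect_equal(pos$position, -66)
})

test_that("diagram nodes equal scalar WRD of scalar affinities (oracle)", {
  ex <- generate_synthetic_experiment(
    synthetic_preset("hypoxia", seed = 5, n_up = 5, n_down = 5))
  grid <- grid_spec(logfO2 = c(-70, -62), logaH2O = c(-2, 0), n = c(4, 3))
  d <- potential_diagram(ex$dataset, ex$aatable, grid = grid)
  for (j in c(1, 4)) for (k in c(1, 3)) {
    a <- vapply(seq_len(nrow(ex$aatable)), function(i) {
      comp <- aa_composition(setNames(as.numeric(ex$aatable[i, 4:23]),
                                      names(ex$aatable)[4:23]))
      affinity_per_residue(comp, thermo_conditions(logfO2 = grid$x[j],
                                                   logaH2O = grid$y[k]))$astar
    }, numeric(1))
    names(a) <- ex$aatable$id
    expect_equal(d$wrd[j, k],
                 wrd_at_point(a, ex$dataset$up, ex$dataset$down),
                 tolerance = 1e-9)
  }
  expect_lte(max(abs(d$wrd)), 25)
})

test_that("complete nO2 separation makes WRD monotone along log fO2", {
  # up-expressed: oxygen-rich residues (high nO2); down: reduced residues
  seqs <- list(u1 = strrep("D", 30), u2 = strrep("N", 25),
               d1 = strrep("L", 30), d2 = strrep("I", 25))
  tab <- toy_aatable(seqs)
  ds <- expression_dataset(up = c("u1", "u2"), down = c("d1", "d2"))
  d <- potential_diagram(ds, tab, grid = grid_spec(n = c(17, 5)))
  for (k in seq_along(d$y))
    expect_true(all(diff(d$wrd[, k]) >= -1e-12))
})

test_that("zero contours are extracted with linear interpolation", {
  x <- seq(-72, -60, by = 1); y <- seq(-4, 2, by = 1)
  # analytic vertical contour at x = -66
  W1 <- outer(x + 66, rep(1, length(y)))
  p1 <- zero_contour_positions(fake_diagram(x, y, W1), "x")
  expect_true(p1$crossing)
  expect_equal(p1$position, -66, tolerance = 1e-9)
  # single-sign field: no crossing, not an error
  p2 <- zero_contour_positions(fake_diagram(x, y, W1 * 0 + 1), "x")
  expect_false(p2$crossing)
  expect_true(is.na(p2$position))
  # stepped field -2 / +2 between columns -67 and -66: midpoint -66.5
  W3 <- matrix(rep(ifelse(x <= -67, -2, 2), length(y)), nrow = length(x))
  p3 <- zero_contour_positions(fake_diagram(x, y, W3), "x")
  expect_equal(p3$position, -66.5, tolerance = 1e-9)
})

test_that("merging averages fields and summarizes member positions", {
  x <- seq(-72, -60, by = 1); y <- seq(-4, 2, by = 1)
  mk <- function(at) fake_diagram(x, y, outer(x + at, rep(1, length(y))),
                                  name = paste0("d", at))
  d66 <- mk(66); d67 <- mk(67); d68 <- mk(68)
  # merging one diagram is the identity on the field
  m1 <- merge_diagrams(list(d66))
  expect_equal(m1$mean_wrd, d66$wrd)
  # a diagram and its negation cancel
  dneg <- fake_diagram(x, y, -d66$wrd)
  m0 <- merge_diagrams(list(d66, dneg))
  expect_equal(max(abs(m0$mean_wrd)), 0)
  # member positions -66, -67, -68: median -67, quartiles by type-7 rule
  m3 <- merge_diagrams(list(d66, d67, d68), axis = "x")
  expect_equal(sort(m3$positions), c(-68, -67, -66), tolerance = 1e-9)
  expect_equal(m3$median, -67, tolerance = 1e-9)
  expect_equal(m3$q1, -67.5, tolerance = 1e-9)
  expect_equal(m3$q3, -66.5, tolerance = 1e-9)
  # k identical members reproduce the single field
  mk3 <- merge_diagrams(list(d66, d66, d66))
  expect_equal(mk3$mean_wrd, d66$wrd)
})

test_that("merging rejects mismatched grids", {
  x <- seq(-72, -60, by = 1); y <- seq(-4, 2, by = 1)
  d1 <- fake_diagram(x, y, outer(x + 66, rep(1, length(y))))
  d2 <- fake_diagram(x + 1, y, outer(x + 66, rep(1, length(y))))
  expect_error(merge_diagrams(list(d1, d2)), "different grids")
})

test_that("dataset grouping equals a brute-force filter of the predicate", {
  specs <- list(
    synthetic_preset("hypoxia", seed = 401, n_up = 40, n_down = 40),
    synthetic_preset("hypoxia", seed = 402, n_up = 40, n_down = 40),
    synthetic_preset("cancer", seed = 403, n_up = 40, n_down = 40),
    synthetic_preset("hyperosmotic", seed = 404, n_up = 40, n_down = 40),
    synthetic_preset("null", seed = 405, n_up = 40, n_down = 40))
  exps <- lapply(specs, generate_synthetic_experiment)
  for (i in seq_along(exps))
    exps[[i]]$dataset$name <- paste0("ds", i)
  aatable <- do.call(rbind, lapply(seq_along(exps), function(i) {
    t <- exps[[i]]$aatable
    t$id <- paste0("ds", i, "_", t$id)
    t
  }))
  datasets <- lapply(seq_along(exps), function(i) {
    d <- exps[[i]]$dataset
    expression_dataset(paste0("ds", i, "_", d$up), paste0("ds", i, "_", d$down),
                       name = d$name)
  })
  grp <- group_and_summarize(datasets, aatable, grid = grid_spec(n = 17))
  # brute-force filter from the classification table
  metrics <- compute_metrics(aatable)
  expected_members <- function(metric, dir) {
    keep <- vapply(datasets, function(ds) {
      cc <- classify_comparison(compare_groups(ds, metrics))
      row <- cc[cc$metric == metric, ]
      if (dir > 0) row$qualifies_up else row$qualifies_down
    }, logical(1))
    vapply(datasets[keep], `[[`, character(1), "name")
  }
  expect_setequal(grp$zc_down$members, expected_members("Zc", -1))
  expect_setequal(grp$h2o_down$members, expected_members("nH2O", -1))
  expect_setequal(grp$zc_up$members, expected_members("Zc", 1))
  # hypoxia-like sets land in zc_down; the merged diagram covers exactly them
  if (length(grp$zc_down$members) > 0)
    expect_equal(sort(grp$zc_down$diagram$members),
                 sort(grp$zc_down$members))
})

test_that("diagrams serialize to text plus JSON metadata", {
  ex <- generate_synthetic_experiment(
    synthetic_preset("hypoxia", seed = 7, n_up = 4, n_down = 4))
  d <- potential_diagram(ex$dataset, ex$aatable, grid = grid_spec(n = 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_diagram(d, path)
  W <- as.matrix(utils::read.table(path))
  expect_equal(unname(W), unname(d$wrd), tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$x, d$x)
  expect_equal(meta$n_up, 4)
})
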