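# Loading up/down expression datasets and the group-comparison statistics:
# group means of ZC and water demand, Wilcoxon tests, common language effect
# sizes, and the classification flags used to group datasets.

#' Construct an expression dataset
#'
#' @param up,down Character vectors of protein IDs for the up- and
#'   down-expressed groups. No ID may occur in both.
#' @param name Dataset name.
#' @param description Free-text description.
#' @return Object of class `expression_dataset` with `n1 = |down|` and
#'   `n2 = |up|`.
#' @export
expression_dataset <- function(up, down, name = "dataset", description = "") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) < 1 || length(down) < 1)
    stop("each expression group needs at least one protein")
  both <- intersect(up, down)
  if (length(both))
    stop("IDs in both groups after cleaning: ", paste(both, collapse = ", "))
  structure(list(name = name, description = description,
                 up = up, down = down,
                 n1 = length(down), n2 = length(up)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset", shQuote(x$name), ": n1 (down) =", x$n1,
      ", n2 (up) =", x$n2, "\n")
  invisible(x)
}

#' Load and clean an up/down expression dataset
#'
#' Accepts a data frame (or delimited file path) with an `id` column and
#' either a `direction` column (`up`/`down`) or a signed `log2_ratio` column.
#' Cleaning applies, in order: the ID-updates mapping (old ID to current
#' primary ID), removal of IDs listed with opposite expression directions
#' (excluded from both groups), and deduplication within groups. All removals
#' are counted in the `log` attribute.
#'
#' @param source Data frame or file path.
#' @param id_updates Optional mapping: data frame with columns `old, new`.
#' @param name,description Dataset metadata.
#' @return An `expression_dataset` with attribute `log` (named counts of
#'   `updated`, `opposite_excluded`, `deduplicated`).
#' @export
load_dataset <- function(source, id_updates = NULL, name = "dataset",
                         description = "") {
  df <- if (is.character(source)) {
    first <- readLines(source, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(source, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  } else as.data.frame(source)
  if (!"id" %in% names(df)) stop("dataset table needs an `id` column")
  if ("direction" %in% names(df)) {
    dir <- tolower(as.character(df$direction))
    bad <- which(!dir %in% c("up", "down"))
    if (length(bad))
      stop("malformed direction value in row ", bad[1], ": ",
           shQuote(df$direction[bad[1]]))
  } else if ("log2_ratio" %in% names(df)) {
    r <- as.numeric(df$log2_ratio)
    bad <- which(!is.finite(r) | r == 0)
    if (length(bad)) stop("malformed log2_ratio in row ", bad[1])
    dir <- ifelse(r > 0, "up", "down")
  } else stop("dataset table needs a `direction` or `log2_ratio` column")
  ids <- as.character(df$id)
  n_updated <- 0L
  if (!is.null(id_updates)) {
    if (!all(c("old", "new") %in% names(id_updates)))
      stop("id_updates needs columns `old` and `new`")
    hit <- match(ids, id_updates$old)
    n_updated <- sum(!is.na(hit))
    ids[!is.na(hit)] <- id_updates$new[hit[!is.na(hit)]]
  }
  up <- unique(ids[dir == "up"]); down <- unique(ids[dir == "down"])
  opposite <- intersect(up, down)
  n_dedup <- (sum(dir == "up") - length(up)) +
    (sum(dir == "down") - length(down))
  up <- setdiff(up, opposite); down <- setdiff(down, opposite)
  if (length(up) < 1 || length(down) < 1)
    stop("empty expression group after cleaning in dataset ", shQuote(name))
  ds <- expression_dataset(up, down, name = name, description = description)
  attr(ds, "log") <- c(updated = n_updated,
                       opposite_excluded = length(opposite),
                       deduplicated = n_dedup)
  ds
}

# ---- statistics -----------------------------------------------------------

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 25 observations and there
#' are no ties; otherwise the midrank normal approximation with continuity
#' correction. Two identical constant samples give p = 1.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_p <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (max(c(x, y)) == min(c(x, y))) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 25 && length(y) <= 25
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Common language effect size
#'
#' The probability, expressed as a percentage, that a randomly drawn value of
#' `x` exceeds a randomly drawn value of `y`; tied pairs receive half credit,
#' which preserves `cles(x, y) + cles(y, x) = 100`.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return Percentage in \[0, 100\].
#' @export
cles <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  d <- outer(x, y, "-")
  100 * (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

#' Compare up- and down-expressed groups on compositional metrics
#'
#' Joins the dataset's ID lists to a per-protein metrics table (see
#' [compute_metrics()]) and computes, for each metric, the group means, the
#' mean difference (up minus down), the two-sided Wilcoxon p-value, and the
#' common language effect size. IDs that fail the metrics lookup are first
#' retried with any isoform suffix (`-n`) removed, then dropped and counted.
#'
#' @param dataset An `expression_dataset`.
#' @param metrics Data frame with an `id` column and the metric columns.
#' @param metric_cols Metric column names (default `Zc` and `nH2O`).
#' @return Object of class `group_comparison`: per-metric statistics plus
#'   dropped-ID counts.
#' @export
compare_groups <- function(dataset, metrics, metric_cols = c("Zc", "nH2O")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  missing_cols <- setdiff(c("id", metric_cols), names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks column(s): ", paste(missing_cols, collapse = ", "))
  resolve <- function(ids) {
    i <- match(ids, metrics$id)
    miss <- is.na(i)
    if (any(miss)) {  # isoform fallback: strip -suffix, look up parent
      parent <- sub("-[0-9]+$", "", ids[miss])
      i[miss] <- match(parent, metrics$id)
    }
    i
  }
  iu <- resolve(dataset$up); idn <- resolve(dataset$down)
  dropped <- c(up = sum(is.na(iu)), down = sum(is.na(idn)))
  if (all(is.na(iu)))
    stop("no up-expressed IDs resolvable to compositions: ",
         paste(utils::head(dataset$up[is.na(iu)], 5), collapse = ", "))
  if (all(is.na(idn)))
    stop("no down-expressed IDs resolvable to compositions: ",
         paste(utils::head(dataset$down[is.na(idn)], 5), collapse = ", "))
  iu <- iu[!is.na(iu)]; idn <- idn[!is.na(idn)]
  per_metric <- lapply(metric_cols, function(mc) {
    xu <- metrics[[mc]][iu]; xd <- metrics[[mc]][idn]
    list(metric = mc,
         mean_up = mean(xu), mean_down = mean(xd),
         delta = mean(xu) - mean(xd),
         p = wilcoxon_p(xu, xd),
         cles = cles(xu, xd))
  })
  names(per_metric) <- metric_cols
  structure(list(name = dataset$name, metrics = per_metric,
                 n_up = length(iu), n_down = length(idn), dropped = dropped),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("Group comparison", shQuote(x$name), ": n_down =", x$n_down,
      ", n_up =", x$n_up, "\n")
  for (m in x$metrics) {
    cat(sprintf("  %-6s mean(down) = %.*g, mean(up) = %.*g, delta = %+.*g, p = %.3g, CLES = %.1f%%\n",
                m$metric, digits, m$mean_down, digits, m$mean_up,
                digits, m$delta, m$p, m$cles))
  }
  if (sum(x$dropped) > 0)
    cat("  dropped IDs: up", x$dropped[["up"]], ", down", x$dropped[["down"]], "\n")
  invisible(x)
}

#' Classification thresholds for compositional differences
#'
#' @param delta Mean-difference magnitude defining a "large" difference
#'   (default 0.01, the half-width of the neutral gray box).
#' @param p Significance threshold for the Wilcoxon test (default 0.05).
#' @param cles_bounds CLES percentages outside of which an effect is "strong"
#'   (default 40/60; must be symmetric about 50).
#' @return Object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(delta = 0.01, p = 0.05,
                                      cles_bounds = c(40, 60)) {
  if (delta <= 0 || p <= 0) stop("thresholds must be positive")
  if (abs(mean(cles_bounds) - 50) > 1e-9)
    stop("CLES bounds must be symmetric about 50")
  structure(list(delta = delta, p = p, cles_bounds = sort(cles_bounds)),
            class = "classification_thresholds")
}

#' Classify a group comparison
#'
#' For each metric, flags whether the mean difference is large
#' (`|delta| > delta` threshold), significant (Wilcoxon `p <` threshold), and
#' strong (CLES outside the bounds), plus the direction of change. Also
#' evaluates the diagram-grouping predicate for each metric pair: the focal
#' metric's signed mean difference exceeds the threshold while the other
#' metric is neither significant nor strong.
#'
#' @param result A `group_comparison`.
#' @param thresholds A `classification_thresholds`.
#' @return Data frame with one row per metric: `metric, delta, p, cles,
#'   large, significant, strong, direction, qualifies_up, qualifies_down`
#'   (the last two are the grouping predicate for positive and negative
#'   focal differences).
#' @export
classify_comparison <- function(result,
                                thresholds = classification_thresholds()) {
  stopifnot(inherits(result, "group_comparison"))
  mets <- result$metrics
  quiet <- vapply(mets, function(m) {
    m$p >= thresholds$p &&
      m$cles > thresholds$cles_bounds[1] && m$cles < thresholds$cles_bounds[2]
  }, logical(1))
  rows <- lapply(seq_along(mets), function(i) {
    m <- mets[[i]]
    others_quiet <- all(quiet[-i])
    data.frame(metric = m$metric, delta = m$delta, p = m$p, cles = m$cles,
               large = abs(m$delta) > thresholds$delta,
               significant = m$p < thresholds$p,
               strong = m$cles <= thresholds$cles_bounds[1] |
                 m$cles >= thresholds$cles_bounds[2],
               direction = sign(m$delta),
               qualifies_up = m$delta > thresholds$delta && others_quiet,
               qualifies_down = m$delta < -thresholds$delta && others_quiet,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize many datasets against one metrics table
#'
#' Produces the long-form summary (one row per dataset per metric) with group
#' sizes, means, mean differences, Wilcoxon p-values and CLES. Datasets that
#' fail are reported via warning and omitted; ordering is deterministic
#' (input order, then metric order).
#'
#' @param datasets List of `expression_dataset` objects.
#' @param metrics Per-protein metrics table.
#' @param metric_cols Metric column names.
#' @return Data frame with columns `dataset, metric, n_down, n_up,
#'   mean_down, mean_up, delta, p, cles`.
#' @export
summarize_datasets <- function(datasets, metrics,
                               metric_cols = c("Zc", "nH2O")) {
  rows <- list()
  for (ds in datasets) {
    cmp <- tryCatch(compare_groups(ds, metrics, metric_cols),
                    error = function(e) {
                      warning("dataset ", shQuote(ds$name), " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(cmp)) next
    for (m in cmp$metrics) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = cmp$name, metric = m$metric,
        n_down = cmp$n_down, n_up = cmp$n_up,
        mean_down = m$mean_down, mean_up = m$mean_up,
        delta = m$delta, p = m$p, cles = m$cles,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no dataset could be summarized")
  do.call(rbind, rows)
}
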