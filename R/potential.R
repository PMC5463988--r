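# Weighted rank-difference (WRD) potential diagrams over log fO2 x log aH2O,
# equipotential (zero-WRD) contour extraction, and diagram merging.

#' Weighted rank difference of affinity between two groups
#'
#' Affinities of all proteins are ranked together (ascending, midranks for
#' ties); the rank sums of the up- and down-expressed groups are weighted by
#' the opposite group's relative size:
#' `WRD = 2 * ((n_down/n) * sum(r_up) - (n_up/n) * sum(r_down))`.
#' The statistic is antisymmetric under swapping the groups and bounded by
#' `n_up * n_down` in absolute value, with equality exactly at complete
#' separation of the two groups in rank. Because it depends only on ranks, it
#' is invariant under any strictly increasing transform of the affinities.
#'
#' @param affinities Named numeric vector of per-protein affinities.
#' @param up_ids,down_ids Protein IDs of the two groups; together they must
#'   cover each protein exactly once.
#' @return The WRD (a real number).
#' @export
wrd_at_point <- function(affinities, up_ids, down_ids) {
  if (length(up_ids) < 1 || length(down_ids) < 1)
    stop("both groups must be non-empty")
  if (length(intersect(up_ids, down_ids)))
    stop("groups overlap")
  ids <- names(affinities)
  if (is.null(ids) || !all(c(up_ids, down_ids) %in% ids))
    stop("affinities must be named and cover both groups")
  a <- affinities[c(up_ids, down_ids)]
  r <- rank(a)  # midranks for ties
  n_up <- length(up_ids); n_down <- length(down_ids); n <- n_up + n_down
  r_up <- sum(r[seq_len(n_up)]); r_down <- sum(r) - r_up
  2 * ((n_down / n) * r_up - (n_up / n) * r_down)
}

# fast path used on grids: affinity matrix with up rows first
.wrd_field <- function(A, n_up, n_down) {
  n <- n_up + n_down
  apply(A, c(2, 3), function(a) {
    r <- rank(a)
    r_up <- sum(r[seq_len(n_up)])
    2 * ((n_down / n) * r_up - (n_up / n) * (sum(r) - r_up))
  })
}

#' Potential diagram for one expression dataset
#'
#' Evaluates the per-residue affinities of the dataset's up- and
#' down-expressed proteins over the grid and reduces them at each node to the
#' weighted rank difference. Positive values mean greater relative potential
#' for formation of the up-expressed group.
#'
#' @param dataset An `expression_dataset`.
#' @param aatable Composition table covering the dataset's proteins
#'   (unresolvable IDs are dropped with a count).
#' @param grid A `grid_spec`.
#' @param conditions A `thermo_conditions`.
#' @param basis,table,ionization,terminal Passed to [affinity_grid()].
#' @return Object of class `potential_diagram`: `x`, `y`, `wrd` (nx-by-ny
#'   matrix), `name`, `n_up`, `n_down`.
#' @export
potential_diagram <- function(dataset, aatable, grid = grid_spec(),
                              conditions = thermo_conditions(),
                              basis = basis_set("QEC+"),
                              table = default_thermo_table(),
                              ionization = ionization_model(enabled = FALSE),
                              terminal = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  up <- intersect(dataset$up, aatable$id)
  down <- intersect(dataset$down, aatable$id)
  if (length(up) < 1) stop("no up-expressed protein has a composition")
  if (length(down) < 1) stop("no down-expressed protein has a composition")
  sub <- aatable[match(c(up, down), aatable$id), , drop = FALSE]
  ag <- affinity_grid(sub, grid, conditions, basis, table, ionization,
                      terminal)
  W <- .wrd_field(ag$A, length(up), length(down))
  structure(list(x = ag$x, y = ag$y, wrd = W, name = dataset$name,
                 n_up = length(up), n_down = length(down),
                 dropped = c(up = dataset$n2 - length(up),
                             down = dataset$n1 - length(down))),
            class = "potential_diagram")
}

#' @export
print.potential_diagram <- function(x, ...) {
  cat("Potential diagram", shQuote(x$name), ":",
      length(x$x), "x", length(x$y), "grid, n_up =", x$n_up,
      ", n_down =", x$n_down, "\n")
  cat("  WRD range:", format(range(x$wrd), digits = 5), "\n")
  invisible(x)
}

#' Equipotential (zero-WRD) contour and its scalar position
#'
#' Extracts the zero-level contour of the WRD field by marching squares with
#' linear interpolation. The scalar position is the mean coordinate of the
#' contour vertices along the chosen axis. A field that never changes sign
#' yields a "no crossing" result (not an error) unless it is identically zero
#' on a plateau, in which case the plateau midpoint is reported.
#'
#' @param diagram A `potential_diagram` or `merged_diagram`.
#' @param axis `"x"` (log fO2, used for oxidation-driven groups) or `"y"`
#'   (log aH2O, for hydration-driven groups).
#' @return List with `crossing` (logical), `position` (scalar or NA), and
#'   `contours` (list of data frames with columns `x`, `y`).
#' @export
zero_contour_positions <- function(diagram, axis = c("x", "y")) {
  axis <- match.arg(axis)
  W <- if (inherits(diagram, "merged_diagram")) diagram$mean_wrd else diagram$wrd
  x <- diagram$x; y <- diagram$y
  verts <- .zero_vertices(x, y, W)
  if (nrow(verts) == 0)
    return(list(crossing = FALSE, position = NA_real_, contours = list()))
  pos <- mean(if (axis == "x") verts$x else verts$y)
  # polylines for plotting/serialization (contourLines nudges levels that
  # coincide with node values, so the scalar position comes from the exact
  # vertices above, not from these)
  cl <- if (min(W) < 0 && max(W) > 0)
    grDevices::contourLines(x = x, y = y, z = W, levels = 0) else list()
  contours <- lapply(cl, function(cc) data.frame(x = cc$x, y = cc$y))
  list(crossing = TRUE, position = pos, contours = contours)
}

# exact marching-squares vertex set of the zero level: nodes where the field
# is exactly zero, plus linear-interpolation crossings on grid edges with a
# strict sign change. An identically zero plateau contributes its nodes, so
# its mean coordinate is the plateau midpoint.
.zero_vertices <- function(x, y, W) {
  nx <- length(x); ny <- length(y)
  vx <- numeric(0); vy <- numeric(0)
  zero <- W == 0
  if (any(zero)) {
    idx <- which(zero, arr.ind = TRUE)
    vx <- c(vx, x[idx[, 1]]); vy <- c(vy, y[idx[, 2]])
  }
  # edges along x (between rows i, i+1 at fixed column j)
  a <- W[-nx, , drop = FALSE]; b <- W[-1, , drop = FALSE]
  cross <- a * b < 0
  if (any(cross)) {
    idx <- which(cross, arr.ind = TRUE)
    t <- a[cross] / (a[cross] - b[cross])
    vx <- c(vx, x[idx[, 1]] + t * (x[idx[, 1] + 1] - x[idx[, 1]]))
    vy <- c(vy, y[idx[, 2]])
  }
  # edges along y (between columns j, j+1 at fixed row i)
  a <- W[, -ny, drop = FALSE]; b <- W[, -1, drop = FALSE]
  cross <- a * b < 0
  if (any(cross)) {
    idx <- which(cross, arr.ind = TRUE)
    t <- a[cross] / (a[cross] - b[cross])
    vx <- c(vx, x[idx[, 1]])
    vy <- c(vy, y[idx[, 2]] + t * (y[idx[, 2] + 1] - y[idx[, 2]]))
  }
  data.frame(x = vx, y = vy)
}

#' Merge potential diagrams by node-wise averaging
#'
#' Combines diagrams computed on identical grids by taking the arithmetic
#' mean of the WRD at every node. Each member's equipotential position along
#' the chosen axis is recorded, and their median and quartiles (linear
#' interpolation convention, [stats::quantile()] type 7) summarize the group.
#'
#' @param diagrams List of `potential_diagram` objects on one grid.
#' @param axis Axis for the member equipotential positions.
#' @return Object of class `merged_diagram` with `x`, `y`, `mean_wrd`,
#'   `members`, `positions`, `median`, `q1`, `q3`, `axis`.
#' @export
merge_diagrams <- function(diagrams, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(length(diagrams) >= 1)
  d1 <- diagrams[[1]]
  for (d in diagrams) {
    if (!isTRUE(all.equal(d$x, d1$x)) || !isTRUE(all.equal(d$y, d1$y)))
      stop("diagrams are on different grids and cannot be merged")
  }
  M <- Reduce(`+`, lapply(diagrams, `[[`, "wrd")) / length(diagrams)
  pos <- unname(vapply(diagrams, function(d)
    zero_contour_positions(d, axis)$position, numeric(1)))
  qs <- stats::quantile(pos, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  structure(list(x = d1$x, y = d1$y, mean_wrd = M,
                 members = unname(vapply(diagrams, `[[`, character(1), "name")),
                 positions = pos, q1 = qs[1], median = qs[2], q3 = qs[3],
                 axis = axis),
            class = "merged_diagram")
}

#' @export
print.merged_diagram <- function(x, ...) {
  cat("Merged potential diagram of", length(x$members), "datasets\n")
  cat("  member equipotential positions along", x$axis, ": median",
      format(x$median, digits = 5), "(Q1", format(x$q1, digits = 5),
      ", Q3", format(x$q3, digits = 5), ")\n")
  invisible(x)
}

#' Group datasets by compositional class and merge their diagrams
#'
#' Applies the classification predicate to each dataset's comparison result
#' and builds one merged potential diagram per qualifying group. The four
#' standard groups mirror the compositional classes: positive or negative
#' mean difference of the focal metric beyond the threshold with the other
#' metric neither significant nor strong.
#'
#' @param datasets List of `expression_dataset` objects.
#' @param aatable Composition table.
#' @param groups Named list of group definitions, each
#'   `list(metric =, direction = +1 or -1, axis = "x" or "y")`. Default: the
#'   four standard groups (`zc_up`, `zc_down` on the log fO2 axis; `h2o_up`,
#'   `h2o_down` on the log aH2O axis).
#' @param grid,conditions,basis,table,ionization,terminal Passed through to
#'   [potential_diagram()].
#' @param thresholds A `classification_thresholds`.
#' @param metric_cols Metric columns used for classification.
#' @return Named list; each element has `members` (dataset names) and
#'   `diagram` (a `merged_diagram`, or NULL for an empty group).
#' @export
group_and_summarize <- function(datasets, aatable,
                                groups = list(
                                  zc_up = list(metric = "Zc", direction = 1, axis = "x"),
                                  zc_down = list(metric = "Zc", direction = -1, axis = "x"),
                                  h2o_up = list(metric = "nH2O", direction = 1, axis = "y"),
                                  h2o_down = list(metric = "nH2O", direction = -1, axis = "y")),
                                grid = grid_spec(),
                                conditions = thermo_conditions(),
                                basis = basis_set("QEC+"),
                                table = default_thermo_table(),
                                ionization = ionization_model(enabled = FALSE),
                                terminal = TRUE,
                                thresholds = classification_thresholds(),
                                metric_cols = c("Zc", "nH2O")) {
  metrics <- compute_metrics(aatable)
  cls <- lapply(datasets, function(ds)
    classify_comparison(compare_groups(ds, metrics, metric_cols), thresholds))
  names(cls) <- vapply(datasets, `[[`, character(1), "name")
  out <- list()
  diagrams_cache <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    member_idx <- which(vapply(cls, function(cc) {
      row <- cc[cc$metric == g$metric, ]
      if (g$direction > 0) row$qualifies_up else row$qualifies_down
    }, logical(1)))
    if (!length(member_idx)) {
      out[[gname]] <- list(members = character(0), diagram = NULL)
      next
    }
    dl <- lapply(member_idx, function(i) {
      nm <- datasets[[i]]$name
      if (is.null(diagrams_cache[[nm]]))
        diagrams_cache[[nm]] <<- potential_diagram(
          datasets[[i]], aatable, grid, conditions, basis, table,
          ionization, terminal)
      diagrams_cache[[nm]]
    })
    out[[gname]] <- list(members = names(cls)[member_idx],
                         diagram = merge_diagrams(dl, axis = g$axis))
  }
  out
}

# ---- plotting and serialization ------------------------------------------

.plot_wrd_field <- function(x, y, W, main, contour_pos = NULL, axis = "x") {
  lim <- max(abs(W))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(255)
  graphics::image(x, y, W, col = pal, zlim = c(-lim, lim),
                  xlab = expression(log * italic(f)[O[2]]),
                  ylab = expression(log * italic(a)[H[2] * O]),
                  main = main)
  graphics::contour(x, y, W, levels = 0, add = TRUE, col = "white",
                    lwd = 2, drawlabels = FALSE)
  if (!is.null(contour_pos) && is.finite(contour_pos$median)) {
    abfun <- if (axis == "x") function(v, ...) graphics::abline(v = v, ...)
             else function(v, ...) graphics::abline(h = v, ...)
    abfun(contour_pos$median, lwd = 2)
    abfun(c(contour_pos$q1, contour_pos$q3), lty = 2)
  }
  invisible(NULL)
}

#' Plot a potential diagram
#'
#' Red/blue diverging fill for positive/negative WRD with the equipotential
#' line in white.
#'
#' @param x A `potential_diagram`.
#' @param ... Unused.
#' @export
plot.potential_diagram <- function(x, ...) {
  .plot_wrd_field(x$x, x$y, x$wrd, x$name)
}

#' Plot a merged potential diagram
#'
#' Adds the median (solid) and quartile (dashed) lines of the member
#' equipotential positions.
#'
#' @param x A `merged_diagram`.
#' @param ... Unused.
#' @export
plot.merged_diagram <- function(x, ...) {
  .plot_wrd_field(x$x, x$y, x$mean_wrd,
                  sprintf("merged (%d datasets)", length(x$members)),
                  contour_pos = x, axis = x$axis)
}

#' Write a potential diagram as plain text plus JSON metadata
#'
#' The field is a whitespace-delimited matrix (rows = log fO2 nodes); axes,
#' dataset name and group sizes go to `<path>.json`.
#'
#' @param diagram A `potential_diagram` or `merged_diagram`.
#' @param path Output path for the matrix file.
#' @export
write_diagram <- function(diagram, path) {
  W <- if (inherits(diagram, "merged_diagram")) diagram$mean_wrd else diagram$wrd
  utils::write.table(W, path, row.names = FALSE, col.names = FALSE)
  meta <- list(x = diagram$x, y = diagram$y)
  if (inherits(diagram, "merged_diagram")) {
    meta$members <- diagram$members
    meta$positions <- diagram$positions
  } else {
    meta$name <- diagram$name
    meta$n_up <- diagram$n_up
    meta$n_down <- diagram$n_down
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
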