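# Configuration, manifests, and machine-readable logs.

#' Read a dataset manifest
#'
#' YAML file listing datasets, each with `name`, `description`, `file`
#' (dataset table path, resolved relative to the manifest), and optional
#' `source`, `organism`, `labels`. Names must be unique and files must exist.
#'
#' @param path Manifest path.
#' @return List of manifest entries.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  entries <- if (!is.null(man$datasets)) man$datasets else man
  nms <- vapply(entries, function(e) e$name %||% "", character(1))
  if (any(!nzchar(nms))) stop("every manifest entry needs a name")
  if (anyDuplicated(nms)) stop("duplicate dataset names in manifest")
  for (i in seq_along(entries)) {
    f <- entries[[i]]$file
    if (is.null(f)) stop("manifest entry ", shQuote(nms[i]), " has no file")
    if (!file.exists(f)) {
      rel <- file.path(dirname(path), f)
      if (!file.exists(rel))
        stop("dataset file not found: ", f)
      entries[[i]]$file <- rel
    }
  }
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load every dataset listed in a manifest
#'
#' @param manifest Path to a manifest or list from [read_manifest()].
#' @param id_updates Optional ID-updates mapping passed to [load_dataset()].
#' @return Named list of `expression_dataset` objects.
#' @export
load_manifest_datasets <- function(manifest, id_updates = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- lapply(manifest, function(e)
    load_dataset(e$file, id_updates = id_updates, name = e$name,
                 description = e$description %||% ""))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Read thermodynamic conditions and grid from a YAML config
#'
#' Recognized keys: `logfO2`, `logaH2O`, `pH`, `loga_cys`, `loga_glu`,
#' `loga_gln`, `loga_residue`, `grid` (with `logfO2`, `logaH2O` ranges and
#' `points` per axis). Missing keys fall back to the package defaults.
#'
#' @param path Config path.
#' @return List with `conditions` (a `thermo_conditions`) and `grid` (a
#'   `grid_spec`).
#' @export
read_conditions_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cond <- thermo_conditions(
    logfO2 = cfg$logfO2 %||% -66,
    logaH2O = cfg$logaH2O %||% 0,
    pH = cfg$pH %||% 7,
    loga_basis = c(Cys = cfg$loga_cys %||% -3.6,
                   Glu = cfg$loga_glu %||% -4.5,
                   Gln = cfg$loga_gln %||% -3.2),
    loga_residue = cfg$loga_residue %||% 0)
  g <- cfg$grid
  grid <- if (is.null(g)) grid_spec() else
    grid_spec(logfO2 = unlist(g$logfO2) %||% c(-72, -60),
              logaH2O = unlist(g$logaH2O) %||% c(-4, 2),
              n = unlist(g$points) %||% 129)
  list(conditions = cond, grid = grid)
}

#' Append a machine-readable log record
#'
#' Writes one JSON object per line so data-cleaning events (dropped IDs,
#' nonstandard residues, opposite-direction exclusions) stay auditable.
#'
#' @param record Named list.
#' @param path Log file path (created if needed).
#' @export
write_json_log <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
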