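# Node-removal fragility analysis: recompute the topology panel after
# deleting each designated hub from the baseline network and report deltas
# in communication efficiency (diameter, path length) and cohesion
# (clustering, density).

#' Remove one node (and its incident edges)
#'
#' @param net igraph network
#' @param gene vertex name to remove
#' @return a new igraph; the input is unmodified
#' @export
remove_node <- function(net, gene) {
  if (!gene %in% igraph::V(net)$name) np_stop("gene '%s' is not in the network", gene)
  igraph::delete_vertices(net, gene)
}

#' Hub-removal fragility analysis
#'
#' Each hub is removed independently from the original network (removals
#' are not cumulative: every column of the report is a single-deletion
#' panel) and the full topology panel recomputed under identical
#' conventions. Deltas are reported per metric as removal minus baseline.
#'
#' @param net igraph network
#' @param hubs character vector of hub symbols, all present, no duplicates
#' @return a `fragility_report`: list with `baseline` (metric panel),
#'   `removals` (named list of panels), `deltas` (named list of per-metric
#'   differences)
#' @export
fragility_analysis <- function(net, hubs) {
  if (length(hubs) == 0L) np_stop("no hubs supplied")
  if (anyDuplicated(hubs)) np_stop("duplicate hub in removal list: %s",
                                   paste(unique(hubs[duplicated(hubs)]), collapse = ", "))
  missing <- setdiff(hubs, igraph::V(net)$name)
  if (length(missing) > 0L) np_stop("hubs not in network: %s", paste(missing, collapse = ", "))
  baseline <- metric_panel(net)
  removals <- lapply(hubs, function(h) metric_panel(remove_node(net, h)))
  names(removals) <- hubs
  metrics <- setdiff(names(baseline), "n_components")
  deltas <- lapply(removals, function(p) {
    d <- setNames(vapply(metrics, function(m) {
      as.numeric(p[[m]]) - as.numeric(baseline[[m]])
    }, numeric(1)), metrics)
    as.list(d)
  })
  structure(list(baseline = baseline, removals = removals, deltas = deltas,
                 hubs = hubs), class = "fragility_report")
}

#' @export
print.fragility_report <- function(x, ...) {
  cat("<fragility_report>\n")
  print(fragility_table(x))
  invisible(x)
}

#' Fragility report as a metrics-by-removal table
#'
#' One row per panel metric, columns `original` then one per removed hub —
#' the layout of published robustness tables.
#'
#' @param report a `fragility_report`
#' @param digits rounding (default 3); `NULL` for full precision
#' @return data.frame
#' @export
fragility_table <- function(report, digits = 3L) {
  metrics <- setdiff(names(report$baseline), "n_components")
  cols <- c(list(original = vapply(metrics, function(m)
    as.numeric(report$baseline[[m]]), numeric(1))),
    lapply(report$removals, function(p) vapply(metrics, function(m)
      as.numeric(p[[m]]), numeric(1))))
  df <- data.frame(metric = metrics, cols, check.names = FALSE)
  if (!is.null(digits)) df[-1] <- lapply(df[-1], round, digits = digits)
  rownames(df) <- NULL
  names(df) <- c("metric", "original", paste0("no_", report$hubs))
  df
}

#' Write a fragility report (TSV matrix + JSON deltas)
#'
#' @param report a `fragility_report`
#' @param tsv_path output TSV in Table-2 layout
#' @param json_path optional JSON with full-precision panels and deltas
#' @return `tsv_path`, invisibly
#' @export
write_fragility <- function(report, tsv_path, json_path = NULL) {
  write_tsv(fragility_table(report), tsv_path)
  if (!is.null(json_path)) {
    write_json(list(baseline = unclass(report$baseline),
                    removals = lapply(report$removals, unclass),
                    deltas = report$deltas), json_path)
  }
  invisible(tsv_path)
}
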