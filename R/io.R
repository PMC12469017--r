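# File formats: TSV edge lists with a mandatory `u<TAB>v<TAB>w` header for
# graphs, JSON for hazard tables, trajectories and reports. Infinite
# capacities serialize as the string "inf".

#' Read a weighted edge list
#'
#' Parses a TSV file with a mandatory 3-column header (`u`, `v`, `w`:
#' endpoints and capacity/rate). Malformed lines are reported with their
#' line numbers; negative weights are rejected.
#'
#' @param path file path.
#' @return data frame with columns `from`, `to`, `cap`.
#' @seealso [read_linking()], [read_rate_model()]
#' @export
read_edge_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty edge-list file", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 3L) {
    stop("edge list must have a 3-column tab-separated header (u, v, w)",
         call. = FALSE)
  }
  body <- lines[-1L]
  body_no <- which(nzchar(trimws(body))) + 1L
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge line(s) (expected 3 tab-separated fields): %s",
                 paste(body_no[bad], collapse = ", ")), call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(w))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric capacity on line(s): %s",
                 paste(body_no[bad], collapse = ", ")), call. = FALSE)
  }
  bad <- which(w < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative capacity on line(s): %s",
                 paste(body_no[bad], collapse = ", ")), call. = FALSE)
  }
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L),
             cap = w)
}

#' Read a linking model or SI rate model from a TSV edge list
#'
#' @param path TSV edge list, see [read_edge_tsv()].
#' @param directed orient edges as written (`TRUE`) or treat the file as an
#'   undirected graph.
#' @return `read_linking`: an `sf_linking`; `read_rate_model`: an
#'   `sf_rate_model`.
#' @export
read_linking <- function(path, directed = TRUE) {
  edges <- read_edge_tsv(path)
  nodes <- sf_natural_order(unique(c(edges$from, edges$to)))
  if (directed) digraph_linking(edges, nodes = nodes)
  else undirected_linking(edges, nodes = nodes)
}

#' @rdname read_linking
#' @export
read_rate_model <- function(path, directed = FALSE) {
  edges <- read_edge_tsv(path)
  names(edges)[names(edges) == "cap"] <- "rate"
  graph_rate_model(edges, directed = directed,
                   nodes = sf_natural_order(unique(c(edges$from, edges$to))))
}

# deterministic ground order for labels coming from files: numeric when all
# labels parse as numbers, otherwise C-locale alphabetical
sf_natural_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels, method = "radix")
}

#' Write a graph model as a canonical TSV edge list
#'
#' Arcs/edges are written in ground order with the `u<TAB>v<TAB>w` header,
#' so `write_edge_tsv(read_linking(f))` is an identity on canonicalized
#' edge lists.
#'
#' @param model an `sf_linking` or `sf_graph_rate_model`.
#' @param path output path.
#' @export
write_edge_tsv <- function(model, path) {
  df <- if (inherits(model, "sf_undirected_linking")) model$edges
        else if (inherits(model, "sf_digraph_linking")) model$arcs
        else if (inherits(model, "sf_graph_rate_model")) {
          e <- model$edges
          if (!model$directed) {
            # keep one representative per undirected pair
            keep <- match(e$from, model$nodes) < match(e$to, model$nodes)
            e <- e[keep, , drop = FALSE]
          }
          names(e)[names(e) == "rate"] <- "cap"
          e
        } else stop("unsupported model type", call. = FALSE)
  writeLines(c("u\tv\tw",
               sprintf("%s\t%s\t%s", df$from, df$to,
                       format(df$cap, scientific = FALSE, trim = TRUE))),
             path)
  invisible(path)
}

#' Read a table rate model from JSON
#'
#' Expects `{"nodes": [...], "hazard": [{"u": ..., "B": [...], "rate": ...}]}`.
#'
#' @param path JSON file path.
#' @return an `sf_table_rate_model`.
#' @export
read_table_rate_model <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- vapply(obj$nodes, as.character, "")
  hazard <- lapply(obj$hazard, function(h)
    list(u = as.character(h$u),
         B = vapply(h$B, as.character, character(1L)),
         rate = as.numeric(h$rate)))
  table_rate_model(nodes, hazard)
}

# recursively map Inf -> "inf" for JSON output; data frames become row lists
sf_json_sanitize <- function(x) {
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
  }
  if (is.list(x)) return(lapply(x, sf_json_sanitize))
  if (is.numeric(x) && length(x) == 1L && is.infinite(x) && x > 0) return("inf")
  x
}

#' Write a result or report as JSON
#'
#' Generic JSON export for capacity/selection results and experiment
#' reports. Positive infinity serializes as the string `"inf"`.
#'
#' @param x a list, data frame, `sf_capacity` or `sf_selection`.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "sf_capacity")) {
    x <- list(kind = x$kind, sources = as.list(x$S), sinks = as.list(x$A),
              value = x$value, oracle_calls = x$oracle_calls)
  } else if (inherits(x, "sf_selection")) {
    sel <- if (is.list(x$selected)) lapply(x$selected, as.list)
           else as.list(x$selected)
    x <- list(method = x$method, kind = x$kind, sinks = as.list(x$sinks),
              selected = sel, rate = x$rate, oracle_calls = x$oracle_calls)
  }
  jsonlite::write_json(sf_json_sanitize(x), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
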