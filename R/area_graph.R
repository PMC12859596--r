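#' Area adjacency graphs
#'
#' An `area_graph` records which small areas are neighbours. It is the only
#' geographical information the model consumes: the intrinsic CAR (ICAR)
#' spatial prior is built from the graph's adjacency structure, so lattice
#' stand-ins are interchangeable with real administrative geographies of the
#' same topology.
#'
#' @param n_areas Number of areas (positive integer).
#' @param edges Two-column integer matrix of unordered area pairs (1-based
#'   indices). Self-loops and duplicate edges are rejected.
#'
#' @return An object of class `area_graph`: a list with elements `n_areas`,
#'   `edges` (two-column matrix with `edges[, 1] < edges[, 2]`, sorted), and
#'   `component` (integer vector of connected-component labels per area).
#' @export
area_graph <- function(n_areas, edges) {
  n_areas <- as.integer(n_areas)
  if (length(n_areas) != 1L || is.na(n_areas) || n_areas < 1L) {
    stop("`n_areas` must be a positive integer", call. = FALSE)
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_areas)) {
      stop("edge indices must lie in [1, n_areas]", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = n_areas, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- as.integer(igraph::components(g)$membership)
  structure(
    list(n_areas = n_areas, edges = edges, component = comp),
    class = "area_graph"
  )
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", x$n_areas, "areas,", nrow(x$edges), "edges,",
      max(x$component), "connected component(s)\n")
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Builds a regular `n_rows` x `n_cols` grid in which each cell is adjacent to
#' its horizontal and vertical neighbours. Used as a configurable stand-in for
#' real small-area adjacency (e.g. census geographies), which the spatial
#' model only sees through its adjacency structure.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @return An [area_graph()] with `n_rows * n_cols` areas (row-major order)
#'   and `n_rows * (n_cols - 1) + n_cols * (n_rows - 1)` edges.
#' @examples
#' g <- make_lattice_graph(3, 3)
#' g$n_areas  # 9
#' nrow(g$edges)  # 12
#' @export
make_lattice_graph <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || is.na(n_rows) || n_rows < 1L ||
      length(n_cols) != 1L || is.na(n_cols) || n_cols < 1L) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  idx <- function(r, c) (r - 1L) * n_cols + c
  e <- list()
  if (n_cols > 1L) {
    r <- rep(seq_len(n_rows), each = n_cols - 1L)
    c <- rep(seq_len(n_cols - 1L), times = n_rows)
    e[[1L]] <- cbind(idx(r, c), idx(r, c + 1L))
  }
  if (n_rows > 1L) {
    r <- rep(seq_len(n_rows - 1L), each = n_cols)
    c <- rep(seq_len(n_cols), times = n_rows - 1L)
    e[[2L]] <- cbind(idx(r, c), idx(r + 1L, c))
  }
  area_graph(n_rows * n_cols, do.call(rbind, e))
}

#' Node degrees of an area graph
#' @param graph An [area_graph()].
#' @return Integer vector of neighbour counts per area.
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n_areas)
}

#' Neighbour lists of an area graph
#' @param graph An [area_graph()].
#' @return List of integer vectors; element `i` holds the neighbours of area `i`.
#' @export
graph_neighbours <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  nb <- vector("list", graph$n_areas)
  for (i in seq_len(graph$n_areas)) nb[[i]] <- integer()
  if (nrow(graph$edges) > 0L) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Write an area graph as a plain-text edge list
#'
#' Format: a header line `n_areas <N>` followed by one `i j` pair per line
#' (1-based indices, whitespace-separated).
#'
#' @param graph An [area_graph()].
#' @param path Output file path.
#' @export
write_area_graph <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("n_areas", graph$n_areas), con)
  if (nrow(graph$edges) > 0L) {
    writeLines(paste(graph$edges[, 1L], graph$edges[, 2L]), con)
  }
  invisible(path)
}

#' Read an area graph written by [write_area_graph()]
#' @param path Edge-list file path.
#' @return An [area_graph()].
#' @export
read_area_graph <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^n_areas\\s+\\d+$", lines[1L])) {
    stop("graph file must start with a 'n_areas <N>' header line", call. = FALSE)
  }
  n <- as.integer(sub("^n_areas\\s+", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(area_graph(n, NULL))
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2L)) stop("each edge line must contain two indices", call. = FALSE)
  edges <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  area_graph(n, edges)
}
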