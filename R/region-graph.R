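#' Areal adjacency graph for CAR-type priors
#'
#' A `region_graph` holds an ordered set of region labels, a symmetric binary
#' adjacency matrix `W` (zero diagonal) and the neighbour counts
#' `D = rowSums(W)`. It is the backbone of every spatial prior in the package
#' (ICAR, MCAR) and of Moran's I.
#'
#' @param region_ids character vector of unique region labels (order fixes the
#'   index `i` used everywhere else).
#' @param edges two-column matrix or data.frame of region labels, one row per
#'   undirected edge. Duplicate edges are collapsed; self-loops are an error.
#' @return An object of class `region_graph`: a list with elements
#'   `region_ids`, `W` (N x N binary symmetric matrix), `D` (neighbour
#'   counts) and `n_regions`.
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' g$D
#' @export
region_graph <- function(region_ids, edges) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) {
    stop("duplicate region labels: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  n <- length(region_ids)
  W <- matrix(0L, n, n, dimnames = list(region_ids, region_ids))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have exactly two columns")
    for (r in seq_len(nrow(edges))) {
      a <- as.character(edges[r, 1L]); b <- as.character(edges[r, 2L])
      if (a == b) stop("self-loop edge '", a, " ", b, "' is not allowed")
      if (!a %in% region_ids || !b %in% region_ids) {
        stop("edge references unknown region: ", a, " ", b)
      }
      W[a, b] <- 1L
      W[b, a] <- 1L
    }
  }
  structure(
    list(region_ids = region_ids, W = W, D = rowSums(W), n_regions = n),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("<region_graph> ", x$n_regions, " regions, ",
      sum(x$W) / 2L, " edges\n", sep = "")
  invisible(x)
}

#' Read an adjacency edge list from a text file
#'
#' The file format is one undirected edge per line, two whitespace-separated
#' region labels. The graph's region set is the union of all labels seen, in
#' order of first appearance; duplicate edges collapse to one.
#'
#' @param path path to the edge-list file.
#' @return A [region_graph()].
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("adjacency file has no edges: ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad)) {
    stop("line ", bad[1L], " does not have exactly two tokens: '",
         lines[bad[1L]], "'")
  }
  loop <- which(vapply(toks, function(t) t[1L] == t[2L], TRUE))
  if (length(loop)) {
    stop("self-loop at line ", loop[1L], ": '", lines[loop[1L]], "'")
  }
  edges <- do.call(rbind, toks)
  ids <- unique(as.vector(t(edges)))
  region_graph(ids, edges)
}

#' Write a graph as an edge list
#'
#' Inverse of [read_adjacency()]: one `regionA regionB` line per undirected
#' edge, each edge listed once.
#'
#' @param graph a [region_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "region_graph"))
  idx <- which(upper.tri(graph$W) & graph$W == 1L, arr.ind = TRUE)
  lines <- paste(graph$region_ids[idx[, 1L]], graph$region_ids[idx[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Seven-province study graph
#'
#' Preset adjacency for the seven provinces covered in every wave of the
#' China Health and Nutrition Survey from 1991 onwards: Jiangsu, Shandong,
#' Henan, Hubei, Hunan, Guangxi and Guizhou. Contiguity is restricted to the
#' study provinces themselves (administrative neighbours outside the study
#' are dropped): Shandong-Jiangsu, Shandong-Henan, Henan-Hubei, Hubei-Hunan,
#' Hunan-Guangxi, Hunan-Guizhou and Guangxi-Guizhou.
#'
#' @return A [region_graph()] with 7 regions and 7 edges.
#' @export
study7_graph <- function() {
  region_graph(
    c("Jiangsu", "Shandong", "Henan", "Hubei", "Hunan", "Guangxi", "Guizhou"),
    rbind(
      c("Shandong", "Jiangsu"),
      c("Shandong", "Henan"),
      c("Henan", "Hubei"),
      c("Hubei", "Hunan"),
      c("Hunan", "Guangxi"),
      c("Hunan", "Guizhou"),
      c("Guangxi", "Guizhou")
    )
  )
}

#' Export a graph as a GeoBUGS-style adjacency block
#'
#' Returns the three vectors used by BUGS-era areal tooling: `num` (number
#' of neighbours per region, in region order), `adj` (concatenated neighbour
#' indices) and `sumNumNeigh` (total length of `adj`).
#'
#' @param graph a [region_graph()].
#' @return list with `num`, `adj`, `sumNumNeigh`.
#' @export
as_geobugs <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  adj <- unlist(lapply(seq_len(graph$n_regions),
                       function(i) which(graph$W[i, ] == 1L)),
                use.names = FALSE)
  list(num = unname(graph$D), adj = as.integer(adj),
       sumNumNeigh = length(adj))
}

#' Neighbour index list
#'
#' @param graph a [region_graph()].
#' @return list of integer vectors, element `i` holding the neighbours of
#'   region `i`.
#' @keywords internal
neighbor_list <- function(graph) {
  lapply(seq_len(graph$n_regions), function(i) which(graph$W[i, ] == 1L))
}

#' Check that a graph is usable under an intrinsic CAR prior
#'
#' CAR/ICAR priors require every region to have at least one neighbour, and
#' the intrinsic variants used here additionally assume a connected graph.
#'
#' @param graph a [region_graph()].
#' @param require_connected also require a single connected component.
#' @return `graph`, invisibly; errors otherwise.
#' @export
validate_car_graph <- function(graph, require_connected = TRUE) {
  stopifnot(inherits(graph, "region_graph"))
  iso <- which(graph$D == 0L)
  if (length(iso)) {
    stop("isolated region(s) not allowed under a CAR prior: ",
         paste(graph$region_ids[iso], collapse = ", "))
  }
  if (require_connected && graph$n_regions > 1L) {
    seen <- rep(FALSE, graph$n_regions)
    stack <- 1L
    seen[1L] <- TRUE
    nb <- neighbor_list(graph)
    while (length(stack)) {
      i <- stack[[1L]]; stack <- stack[-1L]
      new <- nb[[i]][!seen[nb[[i]]]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    if (!all(seen)) {
      stop("graph is not connected; intrinsic CAR prior requires one component")
    }
  }
  invisible(graph)
}
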