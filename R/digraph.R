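#' Simple directed graph
#'
#' A labelled digraph without self-loops, stored as a two-column matrix of
#' 0-based `(tail, head)` pairs.
#'
#' @param n_vertices Positive integer.
#' @param edges Two-column matrix (or empty) of 0-based vertex pairs; no
#'   self-pairs, no duplicates.
#' @return An object of class `digraph`.
#' @export
digraph <- function(n_vertices, edges = matrix(integer(0), ncol = 2)) {
  stopifnot(length(n_vertices) == 1L, n_vertices >= 1)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 0) || any(edges >= n_vertices)) {
      stop("edge endpoints must lie in [0, n_vertices)")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(edges[, 1] * n_vertices + edges[, 2])) {
      stop("duplicate edges are not allowed")
    }
  }
  colnames(edges) <- c("tail", "head")
  structure(list(n_vertices = as.integer(n_vertices), edges = edges),
            class = "digraph")
}

# Row-major arc ordering: arcs (i, j), i != j, enumerated i-major. These
# index maps are what both canonicalization and enumeration are built on.
.arc_table <- function(n) {
  tails <- rep(0:(n - 1), each = n)
  heads <- rep(0:(n - 1), times = n)
  keep <- tails != heads
  cbind(tail = tails[keep], head = heads[keep])
}

.arc_index <- function(tail, head, n) {
  # 1-based index of arc (tail, head) in .arc_table order
  tail * (n - 1) + head - (head > tail) + 1L
}

# For each of the n! vertex permutations, the induced permutation of the
# n(n-1) arc indices. Rows: permutations, columns: source arc index.
.perm_arc_maps <- function(n) {
  arcs <- .arc_table(n)
  perms <- pracma::perms(seq_len(n))  # n! x n, 1-based images
  maps <- matrix(0L, nrow = nrow(perms), ncol = nrow(arcs))
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ] - 1L
    maps[k, ] <- .arc_index(p[arcs[, "tail"] + 1L], p[arcs[, "head"] + 1L], n)
  }
  maps
}

# Numeric canonical code: minimum over all vertex permutations of the
# arc-set code sum(2^(n_arcs - arc_index)); ordering of arcs is row-major,
# so smaller code == lexicographically smaller adjacency bit string.
.canonical_code <- function(g, maps = NULL) {
  n <- g$n_vertices
  if (nrow(g$edges) == 0L) return(0)
  if (is.null(maps)) maps <- .perm_arc_maps(n)
  n_arcs <- ncol(maps)
  idx <- .arc_index(g$edges[, 1], g$edges[, 2], n)
  w <- 2^(n_arcs - seq_len(n_arcs))
  min(apply(maps[, idx, drop = FALSE], 1, function(m) sum(w[m])))
}

.code_to_digraph <- function(code, n) {
  n_arcs <- n * (n - 1)
  bits <- as.integer(intToBits(code))[seq_len(n_arcs)]
  # intToBits is little-endian over 2^0..; our weights are 2^(n_arcs - k)
  present <- which(rev(bits) == 1L)
  digraph(n, .arc_table(n)[present, , drop = FALSE])
}

#' Canonical form of a digraph
#'
#' The lexicographically minimal row-major adjacency bit string over all
#' vertex permutations. Two digraphs with equal vertex counts are
#' isomorphic iff their canonical labels are equal.
#'
#' @param g A [digraph()].
#' @return A character bit string of length `n_vertices^2` (class
#'   `canonical_form`), with zero diagonal positions.
#' @export
canonical_form <- function(g) {
  stopifnot(inherits(g, "digraph"))
  n <- g$n_vertices
  code <- .canonical_code(g)
  canon <- .code_to_digraph(code, n)
  A <- to_adjacency_raw(canon)
  structure(paste(as.integer(t(A)), collapse = ""), class = "canonical_form")
}

#' Enumerate nonisomorphic digraphs
#'
#' Iterates all `choose(n(n-1), m)` edge subsets of the given size, maps
#' each to its canonical code, and keeps the first representative (in
#' lexicographic edge-set order) of every isomorphism class. Intended for
#' small circuits (`n <= 6`); the 5-vertex, 10-edge case covered by the
#' receiver-circuit sweep has 184,756 subsets collapsing to 1,665 classes.
#'
#' With `drop_isolated = TRUE` classes containing a vertex of total degree
#' zero are removed: a five-vertex circuit with an unused vertex is really
#' a four-vertex circuit, and the canonical receiver-circuit set (5
#' vertices, 10 edges) counts 1,665 classes under this convention versus
#' 1,670 without it (exactly five classes pack all 10 arcs among 4
#' vertices).
#'
#' @param n_vertices Number of vertices.
#' @param n_edges Number of directed edges, in `[0, n_vertices*(n_vertices-1)]`.
#' @param drop_isolated Drop classes containing an isolated (degree-zero)
#'   vertex (default `FALSE`).
#' @return List of [digraph()] objects, one per isomorphism class, in
#'   first-encountered order.
#' @export
enumerate_digraphs <- function(n_vertices, n_edges, drop_isolated = FALSE) {
  n <- n_vertices
  n_arcs <- n * (n - 1)
  if (n_edges < 0 || n_edges > n_arcs) {
    stop("n_edges must lie in [0, n_vertices*(n_vertices-1)]")
  }
  if (n_edges == 0L) return(list(digraph(n)))
  arcs <- .arc_table(n)
  subs <- utils::combn(n_arcs, n_edges)      # n_edges x n_subsets
  maps <- .perm_arc_maps(n)
  w <- 2^(n_arcs - seq_len(n_arcs))
  code_min <- rep(Inf, ncol(subs))
  for (k in seq_len(nrow(maps))) {
    mapped <- matrix(w[maps[k, ][subs]], nrow = n_edges)
    code_min <- pmin(code_min, .colSums(mapped, n_edges, ncol(subs)))
  }
  keep <- which(!duplicated(code_min))
  graphs <- lapply(keep, function(j) digraph(n, arcs[subs[, j], , drop = FALSE]))
  if (drop_isolated) {
    used <- vapply(graphs, function(g) {
      length(unique(as.vector(g$edges))) == n
    }, logical(1))
    graphs <- graphs[used]
  }
  graphs
}

#' Receiver-circuit topology set
#'
#' The canonical study set: all nonisomorphic 5-vertex, 10-edge digraphs
#' in which every vertex participates (no isolated vertices) - 1,665
#' classes.
#'
#' @return List of [digraph()] objects.
#' @export
receiver_circuit_topologies <- function() {
  enumerate_digraphs(5, 10, drop_isolated = TRUE)
}

#' Complete (all-to-all) digraph
#'
#' @param n_vertices Number of vertices (>= 1).
#' @return A [digraph()] containing every ordered pair of distinct
#'   vertices.
#' @export
complete_digraph <- function(n_vertices) {
  stopifnot(n_vertices >= 1)
  digraph(n_vertices, .arc_table(n_vertices))
}

to_adjacency_raw <- function(g) {
  # Plain tail->head incidence: M[tail+1, head+1] = 1. Used for labels.
  n <- g$n_vertices
  A <- matrix(0L, n, n)
  if (nrow(g$edges) > 0) A[g$edges[, 1:2, drop = FALSE] + 1L] <- 1L
  A
}

#' Coupling adjacency matrix of a digraph
#'
#' Returns the input-oriented matrix used by the circuit model: an edge
#' `tail -> head` sets `A[head, tail] = 1`, so row `i` lists the inputs of
#' oscillator `i` (the row convention of the coupling sum
#' `sum_j A_ij sin(theta_j - theta_i)`).
#'
#' @param g A [digraph()].
#' @return `n x n` binary matrix with zero diagonal.
#' @export
to_adjacency <- function(g) {
  stopifnot(inherits(g, "digraph"))
  t(to_adjacency_raw(g))
}

#' Read / write edge-list files
#'
#' Plain-text format: one `tail head` pair per line, 0-based. Multiple
#' graphs in one file are separated by lines starting with `#`.
#'
#' @param graphs List of [digraph()] objects.
#' @param path File path.
#' @param n_vertices Vertex count shared by all graphs in the file.
#' @return `read_edge_lists` returns a list of [digraph()] objects.
#' @export
write_edge_lists <- function(graphs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    writeLines(sprintf("# graph %d n=%d", i, g$n_vertices), con)
    if (nrow(g$edges) > 0) {
      writeLines(paste(g$edges[, 1], g$edges[, 2]), con)
    }
  }
  invisible(path)
}

#' @rdname write_edge_lists
#' @export
read_edge_lists <- function(path, n_vertices = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  graphs <- list()
  cur <- NULL
  cur_n <- n_vertices
  flush_graph <- function() {
    if (is.null(cur) && is.null(cur_n)) return()
    e <- if (is.null(cur)) matrix(integer(0), ncol = 2) else do.call(rbind, cur)
    nv <- if (!is.null(cur_n)) cur_n else max(e) + 1L
    graphs[[length(graphs) + 1L]] <<- digraph(nv, e)
  }
  started <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (started) flush_graph()
      started <- TRUE
      cur <- NULL
      m <- regmatches(ln, regexpr("n=\\d+", ln))
      cur_n <- if (length(m)) as.integer(sub("n=", "", m)) else n_vertices
    } else {
      started <- TRUE
      cur[[length(cur) + 1L]] <- as.integer(strsplit(ln, "\\s+")[[1]][1:2])
    }
  }
  if (started) flush_graph()
  graphs
}

#' @export
print.digraph <- function(x, ...) {
  cat(sprintf("<digraph> %d vertices, %d edges\n", x$n_vertices,
              nrow(x$edges)))
  invisible(x)
}
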