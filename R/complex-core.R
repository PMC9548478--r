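# Core operations on simplicial representations: skeletons, full
# subcomplexes, adjacency, and clique (flag) completion of a 1-skeleton.

#' k-skeleton of a complex
#'
#' All simplices of dimension at most `k`, with labels restricted to the
#' surviving vertices.
#'
#' @param K An `srep`.
#' @param k Nonnegative integer.
#' @return An `srep`.
#' @export
skeleton <- function(K, k) {
  if (!is_count(k) || k < 0) stop_screp("bad-argument", "k must be a nonnegative integer")
  keep <- lengths(K$simplices) <= k + 1L
  simplices <- K$simplices[keep]
  vkeys <- unique(unlist(simplices, use.names = FALSE))
  new_srep(K$vertices[vkeys %||% character(0)], simplices,
           labels = K$labels[vkeys %||% character(0)], universe = attr(K, "universe"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full subcomplex on a vertex set
#'
#' Exactly the simplices of `K` whose vertices all lie in `W`. Restricting to
#' the empty set yields the void complex.
#'
#' @param K An `srep`.
#' @param W Vector or list of vertex references, all in `Vert(K)`.
#' @return An `srep`.
#' @export
full_subcomplex <- function(K, W) {
  keys <- if (length(W) == 0L) character(0) else
    vapply(if (is.list(W)) W else as.list(W), vertex_key, character(1), K = K)
  keys <- unique(keys)
  keep <- vapply(K$simplices, function(s) all(s %in% keys), logical(1))
  new_srep(K$vertices[keys], K$simplices[keep],
           labels = K$labels[keys], universe = attr(K, "universe"))
}

#' Vertices adjacent to a vertex
#'
#' All vertices sharing a simplex with `u`, excluding `u` itself.
#'
#' @param K An `srep`.
#' @param u A vertex reference in `Vert(K)`.
#' @return Character vector of canonical vertex keys (possibly empty).
#' @export
adjacent_vertices <- function(K, u) {
  key <- vertex_key(u, K)
  nb <- unlist(K$simplices[vapply(K$simplices, function(s) key %in% s, logical(1))],
               use.names = FALSE)
  csort(setdiff(unique(nb), key))
}

#' Clique completion (flag complex) of a 1-dimensional complex
#'
#' Model files often specify only components and their pairwise
#' interconnections; higher-dimensional simplices are then obtained by
#' filling every clique of the underlying graph. This computes the flag
#' complex: a vertex set spans a simplex exactly when all its pairs are
#' edges.
#'
#' @param K1 An `srep` of dimension at most 1.
#' @return An `srep`, the flag complex of the 1-skeleton.
#' @export
clique_completion <- function(K1) {
  if (complex_dimension(K1) > 1) {
    stop_screp("not-a-1-skeleton", "clique completion expects a 1-skeleton (dimension <= 1)")
  }
  vkeys <- csort(names(K1$vertices))
  edges <- K1$simplices[lengths(K1$simplices) == 2L]
  adj <- new.env(parent = emptyenv())
  for (e in edges) {
    assign(paste(e, collapse = "|"), TRUE, envir = adj)
  }
  is_edge <- function(a, b) {
    exists(paste(csort(c(a, b)), collapse = "|"), envir = adj)
  }
  # grow cliques incrementally: extend each k-clique by a vertex of larger
  # index adjacent to all members (indices in the canonical vertex order)
  n <- length(vkeys)
  cliques <- lapply(seq_len(n), identity)
  out <- cliques
  repeat {
    nxt <- list()
    for (cl in cliques) {
      top <- cl[length(cl)]
      for (j in seq_len(n)[-seq_len(top)]) {
        if (all(vapply(vkeys[cl], is_edge, logical(1), b = vkeys[j]))) {
          nxt[[length(nxt) + 1L]] <- c(cl, j)
        }
      }
    }
    if (length(nxt) == 0L) break
    out <- c(out, nxt)
    cliques <- nxt
  }
  out <- lapply(out, function(idx) vkeys[idx])
  new_srep(K1$vertices, out, labels = K1$labels, universe = attr(K1, "universe"))
}
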