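# Worked-example fixtures and synthetic generators: random complexes and
# planted exchangeable pairs, so every pipeline stage is testable without
# external model files.

#' Packaged worked-example complexes
#'
#' Small complexes used throughout the documentation and tests:
#' `unit_edge` (the 1-simplex on vertices 1, 2 — also the reference complex
#' of the G-representation examples), `triangle` (the full 2-simplex on
#' 1, 2, 3), `square_cycle` (the 4-cycle 1-2-3-4-1), and `path_n` (the path
#' on `n` vertices).
#'
#' @param name One of `"unit_edge"`, `"triangle"`, `"square_cycle"`,
#'   `"path_n"`.
#' @param n Number of vertices for `"path_n"` (default 3).
#' @return An `srep`.
#' @examples
#' fixture("triangle")       # 7 simplices
#' fixture("path_n", n = 3)  # 5 simplices
#' @export
fixture <- function(name, n = 3L) {
  known <- c("unit_edge", "triangle", "square_cycle", "path_n")
  if (!(is.character(name) && length(name) == 1L && name %in% known)) {
    stop_screp("unknown-fixture", "unknown fixture; available: %s",
               paste(known, collapse = ", "))
  }
  switch(name,
    unit_edge = close_under_faces(list(c(1, 2))),
    triangle = close_under_faces(list(c(1, 2, 3))),
    square_cycle = close_under_faces(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))),
    path_n = {
      if (!is_count(n) || n < 1) stop_screp("bad-argument", "n must be a positive integer")
      if (n == 1L) close_under_faces(list(1))
      else close_under_faces(lapply(seq_len(n - 1L), function(i) c(i, i + 1L)))
    }
  )
}

#' Random simplicial representation
#'
#' An Erdos-Renyi graph on `n_vertices` singleton vertices with independent
#' edge probability `edge_density`, optionally completed to its flag
#' complex. Reproducible under `seed`; models in this domain are specified
#' graph-first (components and pairwise interconnections) with higher
#' simplices formed as cliques, which this generator emulates.
#'
#' @param n_vertices Integer in 1..12.
#' @param edge_density Edge probability in `[0, 1]`.
#' @param clique_complete Form the flag complex (default `FALSE`).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return An `srep`.
#' @export
random_complex <- function(n_vertices, edge_density, clique_complete = FALSE,
                           seed = NULL) {
  if (!is_count(n_vertices) || n_vertices < 1 || n_vertices > 12) {
    stop_screp("bad-argument", "n_vertices must be an integer in 1..12")
  }
  if (!is.numeric(edge_density) || edge_density < 0 || edge_density > 1) {
    stop_screp("bad-argument", "edge_density must be in [0, 1]")
  }
  gen <- function() {
    maximal <- lapply(seq_len(n_vertices), identity)
    if (n_vertices >= 2L) {
      for (i in seq_len(n_vertices - 1L)) {
        for (j in (i + 1L):n_vertices) {
          if (stats::runif(1) < edge_density) {
            maximal[[length(maximal) + 1L]] <- c(i, j)
          }
        }
      }
    }
    K <- close_under_faces(maximal)
    if (clique_complete) clique_completion(K) else K
  }
  if (is.null(seed)) gen()
  else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    gen()
  }
}

#' Plant an exchangeable partner for a vertex
#'
#' Duplicates the closed star of `v`: a fresh vertex `v'` receives a copy of
#' every simplex through `v` (with `v` replaced by `v'`), which is the
#' minimal construction guaranteeing the nonadjacent-identification
#' preconditions for `(v, v')`. With `mode = "adjacent"` every simplex
#' through `v` additionally spawns its extension by `v'`, so the pair
#' co-faces everywhere and satisfies the adjacent-identification
#' preconditions. The planted pair is exchangeable in the output, and
#' quotienting by it recovers a complex isomorphic to `K`.
#'
#' @param K An `srep`.
#' @param v A vertex reference in `Vert(K)`.
#' @param mode `"adjacent"` or `"nonadjacent"`.
#' @param new_id Fresh positive integer (or identifier) for the partner.
#' @return An `srep`.
#' @export
plant_exchangeable <- function(K, v, mode = c("nonadjacent", "adjacent"), new_id) {
  mode <- match.arg(mode)
  kv <- vertex_key(v, K)
  nid <- norm_vid(new_id)
  nkey <- vid_key(nid)
  if (nkey %in% names(K$vertices)) {
    stop_screp("vertex-collision", "new_id %s collides with an existing vertex", nkey)
  }
  vertices <- K$vertices
  vertices[[nkey]] <- nid
  labels <- K$labels
  labels[[nkey]] <- vid_flatten(nid)
  simplices <- K$simplices
  for (s in K$simplices) {
    if (kv %in% s) {
      simplices[[length(simplices) + 1L]] <- c(setdiff(s, kv), nkey)
      if (mode == "adjacent") {
        simplices[[length(simplices) + 1L]] <- c(s, nkey)
      }
    }
  }
  new_srep(vertices, simplices, labels = labels, universe = attr(K, "universe"))
}
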