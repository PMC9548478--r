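# Orbits, orbit spaces, projection maps, fundamental domains, and the
# iterated reduction of a representation to its final orbit space.

# Normalize a generators argument: a list of permutations (named character
# vectors) and/or transposition pairs (length-2 vectors of vertex refs).
#' @keywords internal
as_generators <- function(K, generators) {
  lapply(generators, function(g) {
    if (is.character(g) && !is.null(names(g))) g
    else vertex_permutation(K, list(g))
  })
}

#' Vertex orbits of a group action
#'
#' The partition of `Vert(K)` into orbits of the permutation group generated
#' by `generators` (the connected components of the union of generator
#' cycles).
#'
#' @param K An `srep`.
#' @param generators List of permutations (named character vectors as from
#'   [vertex_permutation()]) and/or transpositions given as length-2 vectors
#'   of vertex references. Each must act simplicially on `K`.
#' @return List of character vectors (disjoint sorted blocks covering
#'   `Vert(K)`), sorted canonically.
#' @export
vertex_orbits <- function(K, generators) {
  gens <- as_generators(K, generators)
  for (g in gens) {
    if (!is_simplicial_automorphism(K, g)) {
      stop_screp("action-not-simplicial", "generator is not a simplicial automorphism of K")
    }
  }
  vkeys <- csort(names(K$vertices))
  parent <- stats::setNames(seq_along(vkeys), vkeys)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (g in gens) {
    for (v in vkeys) {
      a <- find(match(v, vkeys))
      b <- find(match(unname(g[[v]]), vkeys))
      if (a != b) parent[[a]] <- b
    }
  }
  roots <- vapply(seq_along(vkeys), find, numeric(1))
  blocks <- split(vkeys, roots)
  blocks <- lapply(blocks, csort)
  names(blocks) <- NULL
  blocks[order(vapply(blocks, `[`, character(1), 1L), method = "radix")]
}

# Build the quotient complex from an orbit partition. The orbit vertex is
# identified by the set of its members' identifiers (a singleton set
# collapses to its member, so trivial orbits keep their vertex unchanged).
#' @keywords internal
quotient_by_orbits <- function(K, blocks) {
  vmap <- character(0)
  vertices <- list()
  labels <- list()
  for (b in blocks) {
    vs <- norm_vid(lapply(b, function(v) K$vertices[[v]]))
    key <- vid_key(vs)
    vertices[[key]] <- vs
    labels[[key]] <- sort(unique(unlist(lapply(b, function(v) vertex_label(K, v)))))
    vmap[b] <- key
  }
  simplices <- lapply(K$simplices, function(s) unique(unname(vmap[s])))
  Q <- new_srep(vertices, simplices, labels = labels, universe = attr(K, "universe"))
  list(complex = Q, vertex_map = vmap)
}

#' Orbit space (quotient) of a complex under a group action
#'
#' The quotient `K/G`: vertices are the `G`-orbits of `Vert(K)`, and the
#' simplices are the images of the simplices of `K` under the orbit
#' projection. An orbit vertex is labelled by the nested set of the member
#' identifiers, and carries the union of the member component labels as its
#' flattened label.
#'
#' @inheritParams vertex_orbits
#' @return A list with `complex` (an `srep`) and `vertex_map` (named
#'   character vector `Vert(K) -> Vert(K/G)`, the projection map on
#'   vertices).
#' @examples
#' K <- close_under_faces(list(c(1, 2, 3)))
#' orbit_space(K, list(c(1, 2)))$complex      # an edge: {{1},{2}} -- {3}
#' orbit_space(K, list(c(1, 2, 3)))$complex   # by the 3-cycle: one vertex
#' @export
orbit_space <- function(K, generators) {
  blocks <- vertex_orbits(K, generators)
  quotient_by_orbits(K, blocks)
}

# Single quotient step by a set of exchangeable pairs.
#' @keywords internal
quotient_by_pairs <- function(K, pairs) {
  pairs <- lapply(pairs, function(p) {
    c(vertex_key(p[[1]], K), vertex_key(p[[2]], K))
  })
  for (p in pairs) {
    if (!are_exchangeable(K, p[1], p[2])) {
      stop_screp("not-exchangeable", "pair (%s, %s) is not exchangeable", p[1], p[2])
    }
  }
  orbit_space(K, pairs)
}

#' Fundamental domain of an exchange action
#'
#' A full subcomplex meeting each vertex orbit exactly once; for actions by
#' exchangeable vertices it is isomorphic to the orbit space, whatever
#' representatives are chosen.
#'
#' @param K An `srep`.
#' @param pairs List of exchangeable pairs (length-2 vectors of vertex
#'   references) generating the action.
#' @param representative_rule `"min"` (default) or `"max"`: which member of
#'   each orbit, in canonical key order, represents it; or a function
#'   taking a character vector of keys and returning one of them.
#' @return An `srep`.
#' @export
fundamental_domain <- function(K, pairs, representative_rule = "min") {
  pairs <- lapply(pairs, function(p) c(vertex_key(p[[1]], K), vertex_key(p[[2]], K)))
  for (p in pairs) {
    if (!are_exchangeable(K, p[1], p[2])) {
      stop_screp("not-exchangeable", "pair (%s, %s) is not exchangeable", p[1], p[2])
    }
  }
  blocks <- vertex_orbits(K, pairs)
  pick <- if (is.function(representative_rule)) representative_rule
  else switch(representative_rule,
              min = function(b) b[1L],
              max = function(b) b[length(b)],
              stop_screp("bad-argument", "unknown representative rule"))
  reps <- vapply(blocks, function(b) pick(csort(b)), character(1))
  full_subcomplex(K, reps)
}

#' Project a transposition to the orbit space
#'
#' Given an exchange action on `K` and a further exchangeable pair `t` of
#' `K` (not necessarily in the action), the corresponding transposition on
#' `K/G` exchanges the two orbit vertices containing the endpoints of `t`;
#' it degenerates to the identity exactly when both endpoints lie in one
#' orbit.
#'
#' @param K An `srep`.
#' @param pairs The exchange action, as for [fundamental_domain()].
#' @param t A length-2 vector of vertex references, exchangeable in `K`.
#' @return A list with `identity` (logical) and, when not the identity,
#'   `pair` (the two orbit-vertex keys) plus the quotient `complex`.
#' @export
project_transposition <- function(K, pairs, t) {
  tu <- vertex_key(t[[1]], K)
  tv <- vertex_key(t[[2]], K)
  if (!are_exchangeable(K, tu, tv)) {
    stop_screp("not-exchangeable", "t = (%s, %s) is not exchangeable in K", tu, tv)
  }
  q <- quotient_by_pairs(K, pairs)
  a <- unname(q$vertex_map[[tu]])
  b <- unname(q$vertex_map[[tv]])
  if (a == b) return(list(identity = TRUE, complex = q$complex))
  list(identity = FALSE, pair = csort(c(a, b)), complex = q$complex)
}

#' Reduce a representation to its final orbit space
#'
#' Repeatedly finds all exchangeable pairs, quotients by the group they
#' generate (all identifications of a stage applied simultaneously), and
#' stops when no exchangeable pairs remain. The returned trace records every
#' stage: its transpositions, projection map, and resulting complex.
#'
#' @param K An `srep`.
#' @param admissible Optional predicate `function(K, u, v)` returning whether
#'   the identification of vertices `u, v` (keys) is admissible; only
#'   admissible exchangeable pairs are applied. Default: all.
#' @return An object of class `reduction_trace`: a list with `stages` (each
#'   a list with `pairs`, `vertex_map`, `complex`) and `final` (an `srep`
#'   with no admissible exchangeable pairs).
#' @examples
#' K <- close_under_faces(list(c(1, 2, 3)))
#' final_orbit_space(K)$final  # a single vertex {{1},{2},{3}}
#' @export
final_orbit_space <- function(K, admissible = NULL) {
  stages <- list()
  cur <- K
  n0 <- length(K$vertices)
  repeat {
    pairs <- exchangeable_pairs(cur)
    if (!is.null(admissible)) {
      pairs <- Filter(function(p) isTRUE(admissible(cur, p[1], p[2])), pairs)
    }
    if (length(pairs) == 0L) break
    q <- quotient_by_pairs(cur, pairs)
    stages[[length(stages) + 1L]] <- list(pairs = pairs,
                                          vertex_map = q$vertex_map,
                                          complex = q$complex)
    cur <- q$complex
    stopifnot(length(stages) <= n0)  # vertex count strictly decreases
  }
  structure(list(stages = stages, final = cur), class = "reduction_trace")
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf("Reduction trace: %d stage(s)\n", length(x$stages)))
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf("  stage %d: %d transposition(s): %s\n", i, length(st$pairs),
                paste(vapply(st$pairs, function(p) paste0("(", p[1], " ", p[2], ")"),
                             character(1)), collapse = " ")))
  }
  cat("Final orbit space:\n")
  print(x$final)
  invisible(x)
}
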