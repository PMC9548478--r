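# Vertex permutations, simplicial automorphisms, exchangeable pairs, and the
# regularity condition that exchange actions deliberately violate.

#' Build a vertex permutation from cycles
#'
#' Permutations are bijections of `Vert(K)` represented as named character
#' vectors mapping each vertex key to its image key. Composition is right to
#' left (see [compose_permutations()]).
#'
#' @param K An `srep`.
#' @param cycles A list of cycles; each cycle is a vector of vertex
#'   references, e.g. `list(c(1, 2))` for the transposition (1 2) or
#'   `list(c(1, 2, 3))` for a 3-cycle. Unlisted vertices are fixed.
#' @return Named character vector on all of `Vert(K)`.
#' @examples
#' K <- close_under_faces(list(c(1, 2, 3)))
#' vertex_permutation(K, list(c(1, 2)))
#' @export
vertex_permutation <- function(K, cycles) {
  vkeys <- csort(names(K$vertices))
  p <- stats::setNames(vkeys, vkeys)
  for (cyc in cycles) {
    keys <- vapply(if (is.list(cyc)) cyc else as.list(cyc), vertex_key,
                   character(1), K = K)
    if (anyDuplicated(keys)) stop_screp("bad-permutation", "cycle repeats a vertex")
    if (length(keys) > 1L) {
      p[keys] <- keys[c(seq_along(keys)[-1L], 1L)]
    }
  }
  p
}

#' Compose two vertex permutations (right to left)
#'
#' `compose_permutations(p, q)` is the permutation "first q, then p".
#'
#' @param p,q Named character vectors as from [vertex_permutation()].
#' @return Named character vector.
#' @export
compose_permutations <- function(p, q) {
  stats::setNames(unname(p[unname(q[names(q)])]), names(q))
}

#' @keywords internal
check_permutation <- function(K, p) {
  vkeys <- names(K$vertices)
  if (length(p) != length(vkeys) || !setequal(names(p), vkeys) ||
      !setequal(unname(p), vkeys) || anyDuplicated(unname(p))) {
    stop_screp("bad-permutation", "permutation is not a bijection on Vert(K)")
  }
  invisible(TRUE)
}

#' Cycle form of a vertex permutation
#'
#' @param p Named character vector permutation.
#' @return List of character vectors, the nontrivial cycles.
#' @export
cycle_form <- function(p) {
  seen <- character(0)
  cycles <- list()
  for (v in csort(names(p))) {
    if (v %in% seen) next
    cyc <- v
    w <- unname(p[[v]])
    while (w != v) {
      cyc <- c(cyc, w)
      w <- unname(p[[w]])
    }
    seen <- c(seen, cyc)
    if (length(cyc) > 1L) cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Apply a vertex permutation to a complex
#'
#' Every simplex is mapped element-wise; the result need not equal `K`.
#'
#' @param K An `srep`.
#' @param p A permutation of `Vert(K)`.
#' @return An `srep` on the same vertex set.
#' @export
apply_vertex_permutation <- function(K, p) {
  check_permutation(K, p)
  simplices <- lapply(K$simplices, function(s) unname(p[s]))
  new_srep(K$vertices, simplices, labels = K$labels, universe = attr(K, "universe"))
}

#' Is a permutation a simplicial automorphism?
#'
#' `TRUE` iff the element-wise image of the simplex family equals the family.
#'
#' @param K An `srep`.
#' @param p A permutation of `Vert(K)`.
#' @return Logical.
#' @export
is_simplicial_automorphism <- function(K, p) {
  check_permutation(K, p)
  img <- vapply(K$simplices, function(s) paste(csort(unname(p[s])), collapse = "|"),
                character(1))
  setequal(img, srep_skeys(K))
}

#' Are two vertices exchangeable?
#'
#' Two vertices are exchangeable when the transposition swapping them and
#' fixing every other vertex is a simplicial automorphism. Exchangeable
#' vertices sit in symmetric positions of the complex and are the candidates
#' for conceptual identification.
#'
#' @param K An `srep`.
#' @param u,v Distinct vertex references in `Vert(K)`.
#' @return Logical.
#' @examples
#' K <- close_under_faces(list(c(1, 2, 3)))
#' are_exchangeable(K, 1, 2)  # TRUE: a simplex is fully symmetric
#' @export
are_exchangeable <- function(K, u, v) {
  ku <- vertex_key(u, K)
  kv <- vertex_key(v, K)
  if (ku == kv) stop_screp("bad-argument", "u and v must be distinct")
  for (s in K$simplices) {
    iu <- ku %in% s
    iv <- kv %in% s
    if (iu == iv) next  # fixed setwise by the swap
    img <- if (iu) c(setdiff(s, ku), kv) else c(setdiff(s, kv), ku)
    if (!(paste(csort(img), collapse = "|") %in% srep_skeys(K))) return(FALSE)
  }
  TRUE
}

#' All exchangeable vertex pairs of a complex
#'
#' Tests every unordered vertex pair, after an optional degree prefilter:
#' exchangeable vertices necessarily have the same number of adjacencies, so
#' pairs with different degree can be skipped without changing the result.
#'
#' @param K An `srep`.
#' @param prefilter Use the degree prefilter (default `TRUE`; the result is
#'   identical either way, only the cost differs).
#' @return A list of character vectors of length 2 (sorted vertex keys),
#'   sorted canonically.
#' @export
exchangeable_pairs <- function(K, prefilter = TRUE) {
  vkeys <- csort(names(K$vertices))
  n <- length(vkeys)
  if (n < 2L) return(list())
  deg <- vapply(vkeys, function(v) length(adjacent_vertices(K, v)), integer(1))
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (prefilter && deg[[i]] != deg[[j]]) next
      if (are_exchangeable(K, vkeys[i], vkeys[j])) {
        out[[length(out) + 1L]] <- c(vkeys[i], vkeys[j])
      }
    }
  }
  out
}

# Enumerate the permutation group generated by `generators` (named character
# vectors). Breadth-first closure under composition; errors beyond `budget`
# elements.
#' @keywords internal
enumerate_group <- function(K, generators, budget = 10000L) {
  vkeys <- csort(names(K$vertices))
  idp <- stats::setNames(vkeys, vkeys)
  elems <- list(idp)
  keys <- paste(idp[vkeys], collapse = "|")
  frontier <- list(idp)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (g in frontier) {
      for (h in generators) {
        gh <- compose_permutations(h, g)
        k <- paste(gh[vkeys], collapse = "|")
        if (!(k %in% keys)) {
          keys <- c(keys, k)
          elems[[length(elems) + 1L]] <- gh
          nxt[[length(nxt) + 1L]] <- gh
          if (length(elems) > budget) {
            stop_screp("enumeration-budget", "regularity check exceeds enumeration budget")
          }
        }
      }
    }
    frontier <- nxt
  }
  elems
}

#' Is a group action regular (Condition A)?
#'
#' A simplicial action is regular when, for any group elements
#' `g_1, ..., g_m` and any simplex `{v_1, ..., v_m}` whose pointwise image
#' `{g_1 v_1, ..., g_m v_m}` is also a simplex, a single group element `g`
#' realises the same pointwise assignment. Exchange actions of interest here
#' are deliberately nonregular: they permute the vertices within a simplex.
#' Checked by brute force over the enumerated group; intended for
#' worked-example scale.
#'
#' @param K An `srep`.
#' @param generators List of permutations (named character vectors), each a
#'   simplicial automorphism of `K`.
#' @param budget Maximum group size / tuple count before erroring.
#' @return Logical.
#' @export
is_regular_action <- function(K, generators, budget = 10000L) {
  for (g in generators) {
    if (!is_simplicial_automorphism(K, g)) {
      stop_screp("action-not-simplicial", "generator is not a simplicial automorphism")
    }
  }
  G <- enumerate_group(K, generators, budget = budget)
  nG <- length(G)
  skeys <- srep_skeys(K)
  for (s in K$simplices) {
    m <- length(s)
    if (nG^m > budget * 10) {
      stop_screp("enumeration-budget", "regularity check exceeds enumeration budget")
    }
    tuple <- rep(1L, m)
    repeat {
      img <- vapply(seq_len(m), function(i) unname(G[[tuple[i]]][[s[i]]]), character(1))
      if (paste(csort(unique(img)), collapse = "|") %in% skeys) {
        ok <- FALSE
        for (g in G) {
          if (all(vapply(seq_len(m), function(i) unname(g[[s[i]]]) == img[i], logical(1)))) {
            ok <- TRUE
            break
          }
        }
        if (!ok) return(FALSE)
      }
      # next tuple in G^m
      pos <- 1L
      while (pos <= m) {
        tuple[pos] <- tuple[pos] + 1L
        if (tuple[pos] <= nG) break
        tuple[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > m) break
    }
  }
  TRUE
}
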