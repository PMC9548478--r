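# Independent oracles used to cross-check the package. These operate on a
# bitmask representation of complexes over a ground set [n] (a simplex is an
# integer mask; a complex is a sorted vector of masks) and never call the
# pruned/optimized code paths they are used to verify.

mask_bits <- function(m, n) which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)

# All nonzero submasks of each mask (face closure by enumeration).
oracle_close <- function(maximal) {
  out <- integer(0)
  for (m in maximal) {
    sub <- m
    repeat {
      out <- c(out, sub)
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, m)
    }
  }
  sort(unique(out[out != 0L]))
}

# Every simplicial complex over vertex ground set [n]: the face closures of
# all antichains of nonempty subsets of [n] (the void complex included).
all_complexes <- function(n) {
  masks <- seq_len(2L^n - 1L)
  nm <- length(masks)
  comparable <- outer(masks, masks, function(a, b) {
    bitwAnd(a, b) == a | bitwAnd(a, b) == b
  })
  res <- list(integer(0))
  dfs <- function(start, chosen) {
    if (start > nm) return(invisible())
    for (i in start:nm) {
      if (length(chosen) == 0L || all(!comparable[chosen, i])) {
        res[[length(res) + 1L]] <<- oracle_close(masks[c(chosen, i)])
        dfs(i + 1L, c(chosen, i))
      }
    }
  }
  if (nm >= 1L) dfs(1L, integer(0))
  res
}

# Swap vertices i and j (1-based bit positions) in every mask; TRUE iff the
# family is unchanged.
oracle_exchangeable <- function(cx, i, j) {
  bi <- bitwShiftL(1L, i - 1L)
  bj <- bitwShiftL(1L, j - 1L)
  swapped <- vapply(cx, function(m) {
    hi <- bitwAnd(m, bi) != 0L
    hj <- bitwAnd(m, bj) != 0L
    if (hi == hj) m
    else if (hi) bitwOr(bitwAnd(m, bitwNot(bi)), bj)
    else bitwOr(bitwAnd(m, bitwNot(bj)), bi)
  }, integer(1))
  identical(sort(unique(swapped)), cx)
}

# Build an srep from a mask complex (vertices are the bits that occur).
mask_to_srep <- function(cx, n) {
  if (length(cx) == 0L) return(close_under_faces(list()))
  close_under_faces(lapply(cx, mask_bits, n = n))
}

# All permutations of 1..n, as a list of integer vectors.
all_perms <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      q <- integer(n)
      q[i] <- n
      q[-i] <- p
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

# Brute-force isomorphism oracle: try every vertex bijection and compare the
# image family directly. labelled = TRUE additionally requires equal
# flattened labels of matched vertices.
oracle_isomorphic <- function(K, L, labelled = FALSE) {
  vk <- sort(as.character(names(K$vertices)), method = "radix")
  vl <- sort(as.character(names(L$vertices)), method = "radix")
  if (length(vk) != length(vl)) return(FALSE)
  if (length(K$simplices) != length(L$simplices)) return(FALSE)
  if (length(vk) == 0L) return(TRUE)
  lkeys <- vapply(L$simplices, paste, character(1), collapse = "|")
  for (p in all_perms(length(vk))) {
    map <- stats::setNames(vl[p], vk)
    if (labelled &&
        !all(vapply(vk, function(v) {
          identical(vertex_label(K, v), vertex_label(L, unname(map[[v]])))
        }, logical(1)))) {
      next
    }
    img <- vapply(K$simplices, function(s) {
      paste(sort(unname(map[s]), method = "radix"), collapse = "|")
    }, character(1))
    if (setequal(img, lkeys)) return(TRUE)
  }
  FALSE
}

# Brute-force search for label-constrained isomorphisms between two (small)
# complexes: all bijections, filtered by the shared-component rule, checked
# by direct image comparison. Returns the number found.
oracle_iso_count <- function(Khat, Lhat, enforce = TRUE) {
  vk <- sort(as.character(names(Khat$vertices)), method = "radix")
  vl <- sort(as.character(names(Lhat$vertices)), method = "radix")
  if (length(vk) != length(vl)) return(0L)
  if (length(vk) == 0L) return(1L)
  lkeys <- vapply(Lhat$simplices, paste, character(1), collapse = "|")
  cnt <- 0L
  for (p in all_perms(length(vk))) {
    map <- stats::setNames(vl[p], vk)
    if (enforce) {
      ok <- all(vapply(vk, function(v) {
        lab <- vertex_label(Khat, v)
        sharers <- vl[vapply(vl, function(w) {
          length(intersect(lab, vertex_label(Lhat, w))) > 0L
        }, logical(1))]
        length(sharers) == 0L || unname(map[[v]]) %in% sharers
      }, logical(1)))
      if (!ok) next
    }
    if (length(Khat$simplices) != length(Lhat$simplices)) next
    img <- vapply(Khat$simplices, function(s) {
      paste(sort(unname(map[s]), method = "radix"), collapse = "|")
    }, character(1))
    if (setequal(img, lkeys)) cnt <- cnt + 1L
  }
  cnt
}

# A deterministic stream of random test complexes.
rand_srep <- function(n, density = 0.5, clique = FALSE) {
  random_complex(n, density, clique_complete = clique)
}

# All nonempty subsets of a character vector (oracle-side enumeration).
nonempty_subsets_chr <- function(x) {
  n <- length(x)
  if (n == 0L) return(list())
  lapply(seq_len(2L^n - 1L), function(m) {
    x[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  })
}
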