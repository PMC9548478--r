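# The G-representation of a model: the elementary abelian 2-group of all
# subsets of a complex's simplices under symmetric difference. The group has
# 2^|K| elements and is never materialized; elements are sparse simplex sets
# constructed on demand.

# Canonical serialization of a complex, used to check that two elements
# refer to the same complex.
#' @keywords internal
srep_ref <- function(K) paste(srep_skeys(K), collapse = ";")

#' Construct an element of the G-representation
#'
#' An element is a finite (possibly empty) set of simplices of a reference
#' complex `K`; the empty set is the group identity.
#'
#' @param K An `srep`.
#' @param simplices List of simplices, each a vector of vertex references
#'   (or a character vector of vertex keys). `list()` gives the identity.
#' @return An object of class `g_element`.
#' @examples
#' K <- close_under_faces(list(c(1, 2)))
#' g_element(K, list(1, c(1, 2)))   # the set {{1},{1,2}}
#' @export
g_element <- function(K, simplices = list()) {
  keys <- vapply(simplices, function(s) {
    ks <- vapply(if (is.list(s)) s else as.list(s), vertex_key, character(1), K = K)
    paste(csort(unique(ks)), collapse = "|")
  }, character(1))
  bad <- setdiff(keys, srep_skeys(K))
  if (length(bad) > 0L) {
    stop_screp("not-a-simplex", "%s is not a simplex of K", bad[1L])
  }
  structure(list(simplices = csort(unique(keys))),
            ref = srep_ref(K), complex = K, class = "g_element")
}

#' @export
print.g_element <- function(x, ...) {
  if (length(x$simplices) == 0L) cat("G-element: identity (empty set)\n")
  else cat("G-element:", paste(x$simplices, collapse = "  "), "\n")
  invisible(x)
}

#' @keywords internal
check_same_ref <- function(a, b) {
  if (!identical(attr(a, "ref"), attr(b, "ref"))) {
    stop_screp("mismatched-complex", "elements refer to different complexes")
  }
}

#' Group operation: symmetric difference
#'
#' @param a,b `g_element`s over the same complex.
#' @return A `g_element`.
#' @export
g_product <- function(a, b) {
  check_same_ref(a, b)
  keys <- c(setdiff(a$simplices, b$simplices), setdiff(b$simplices, a$simplices))
  structure(list(simplices = csort(keys)),
            ref = attr(a, "ref"), complex = attr(a, "complex"), class = "g_element")
}

#' Order of a group element
#'
#' Every nonidentity element is self-inverse under symmetric difference, so
#' the order is 1 for the identity and 2 otherwise.
#'
#' @param a A `g_element`.
#' @return Integer, 1 or 2.
#' @export
g_order <- function(a) if (length(a$simplices) == 0L) 1L else 2L

#' Classify a nonidentity group element
#'
#' Elements are of three types: a single simplex; a subset closed under
#' taking faces (a simplicial subcomplex); or a bare set of simplices. A
#' singleton containing one vertex is both a simplex and a subcomplex; the
#' primary type returned is `"simplex"` with attribute `also_subcomplex`.
#'
#' @param a A nonidentity `g_element`.
#' @return One of `"simplex"`, `"subcomplex"`, `"simplex-set"`, with logical
#'   attribute `also_subcomplex`.
#' @export
classify_element <- function(a) {
  if (length(a$simplices) == 0L) {
    stop_screp("identity-element", "the identity has no classification")
  }
  members <- strsplit(a$simplices, "|", fixed = TRUE)
  closed <- all(vapply(members, function(s) {
    all(vapply(nonempty_subsets(s), function(sub) {
      paste(sub, collapse = "|") %in% a$simplices
    }, logical(1)))
  }, logical(1)))
  if (length(a$simplices) == 1L) {
    structure("simplex", also_subcomplex = closed)
  } else if (closed) {
    structure("subcomplex", also_subcomplex = TRUE)
  } else {
    structure("simplex-set", also_subcomplex = FALSE)
  }
}

#' Minimal generating set of the G-representation
#'
#' The singletons of all simplices of `K` form a minimal generating set;
#' its cardinality `|K|` is shared by every minimal generating set
#' (Burnside basis).
#'
#' @param K A nonvoid `srep`.
#' @return List of `g_element`s, one per simplex, in canonical order.
#' @export
minimal_generators <- function(K) {
  if (length(K$simplices) == 0L) {
    stop_screp("void-complex", "the void complex has no generators")
  }
  lapply(srep_skeys(K), function(sk) {
    structure(list(simplices = sk), ref = srep_ref(K), complex = K,
              class = "g_element")
  })
}

#' Map a set of G-representation vertices to the simplex they span
#'
#' The vertices of the G-representation are the singleton sets of the
#' 0-simplices; a set of them maps to the simplex of `K` spanned by the
#' corresponding vertices, when that simplex exists.
#'
#' @param K An `srep`.
#' @param S List of vertex references (or of singleton `g_element`s).
#' @return Character vector of vertex keys: the spanned simplex.
#' @export
rho <- function(K, S) {
  keys <- vapply(S, function(v) {
    if (inherits(v, "g_element")) {
      if (length(v$simplices) != 1L || grepl("|", v$simplices, fixed = TRUE)) {
        stop_screp("not-a-vertex", "rho expects vertices of the G-representation")
      }
      v$simplices
    } else {
      vertex_key(v, K)
    }
  }, character(1))
  keys <- csort(unique(keys))
  if (!(paste(keys, collapse = "|") %in% srep_skeys(K))) {
    stop_screp("not-a-simplex", "the vertices {%s} do not span a simplex of K",
               paste(keys, collapse = ", "))
  }
  keys
}

#' Distance between two models as G-representations
#'
#' The cardinality of the symmetric difference of the two simplex families,
#' with simplices compared by their component labels so that representations
#' over one universe are comparable regardless of internal vertex naming.
#'
#' @param K,L Two `srep`s over one component universe.
#' @return Nonnegative integer.
#' @export
g_distance <- function(K, L) {
  label_form <- function(X) {
    vapply(X$simplices, function(s) {
      paste(csort(vapply(s, function(v) {
        paste(vertex_label(X, v), collapse = ",")
      }, character(1))), collapse = "|")
    }, character(1))
  }
  a <- label_form(K)
  b <- label_form(L)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Identification as a G-representation homomorphism
#'
#' For a pair `(u, v)` satisfying the adjacent (Operation 1) or nonadjacent
#' (Operation 2) identification preconditions, the induced map on
#' G-representations is the canonical projection that deletes from any
#' element every simplex containing the removed vertex (by default `v`, the
#' second). The codomain is the G-representation of the subcomplex of
#' `v`-free simplices.
#'
#' @param K An `srep`.
#' @param u,v The identified pair.
#' @param kind `"adjacent"` or `"nonadjacent"`; checked against the pair.
#' @param remove Which vertex's simplices are deleted: `"second"` (default)
#'   or `"first"`.
#' @return A function mapping `g_element`s over `K` to `g_element`s over the
#'   projected complex (available as attribute `codomain`).
#' @export
phi_identify <- function(K, u, v, kind = c("adjacent", "nonadjacent"),
                         remove = c("second", "first")) {
  kind <- match.arg(kind)
  remove <- match.arg(remove)
  chk <- check_identification(K, u, v)
  if (chk$kind != kind) {
    stop_screp(if (kind == "adjacent") "not-adjacent" else "use-operation-1",
               "pair is %s, not %s", chk$kind, kind)
  }
  if (!chk$ok) stop_screp(chk$clause, "identification precondition fails for (%s, %s)",
                          chk$u, chk$v)
  drop_key <- if (remove == "second") chk$v else chk$u
  keep <- vapply(K$simplices, function(s) !(drop_key %in% s), logical(1))
  codomain <- new_srep(K$vertices[setdiff(names(K$vertices), drop_key)],
                       K$simplices[keep],
                       labels = K$labels[setdiff(names(K$labels), drop_key)],
                       universe = attr(K, "universe"))
  ref_in <- srep_ref(K)
  f <- function(a) {
    if (!identical(attr(a, "ref"), ref_in)) {
      stop_screp("mismatched-complex", "element is not over the domain complex")
    }
    keys <- a$simplices[!vapply(strsplit(a$simplices, "|", fixed = TRUE),
                                function(s) drop_key %in% s, logical(1))]
    structure(list(simplices = keys), ref = srep_ref(codomain),
              complex = codomain, class = "g_element")
  }
  attr(f, "codomain") <- codomain
  f
}

#' Vertex substitution as a G-representation isomorphism
#'
#' The bijective relabelling of `u` to `c` induces an isomorphism of
#' G-representations mapping each element simplex-wise.
#'
#' @inheritParams vertex_substitution
#' @return A function on `g_element`s, with attribute `codomain`.
#' @export
phi_substitute <- function(K, u, c) {
  L <- vertex_substitution(K, u, c)
  ku <- vertex_key(u, K)
  ckey <- vid_key(norm_vid(c))
  ref_in <- srep_ref(K)
  f <- function(a) {
    if (!identical(attr(a, "ref"), ref_in)) {
      stop_screp("mismatched-complex", "element is not over the domain complex")
    }
    keys <- vapply(strsplit(a$simplices, "|", fixed = TRUE), function(s) {
      s[s == ku] <- ckey
      paste(csort(s), collapse = "|")
    }, character(1))
    structure(list(simplices = csort(keys)), ref = srep_ref(L),
              complex = L, class = "g_element")
  }
  attr(f, "codomain") <- L
  f
}
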