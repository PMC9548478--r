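# The admissible partial operations on simplicial representations:
# adjacent-vertex identification, nonadjacent-vertex identification, and
# vertex substitution. Vertex split and inclusion are their inverses and are
# exercised implicitly through recorded traces.

# Precondition check for the identification operations. For a pair (u, v):
#   adjacent case:   (i) V(u)\{v} = V(v)\{u};
#   nonadjacent:     (i) V(u) = V(v);
#   both: (ii) for any nonempty W inside the common (deleted) neighbourhood,
#         W + {u} spans a simplex iff W + {v} does.
# Clause (ii) is checked over the subsets W that actually occur as
# simplex-minus-{u,v} supports, which is equivalent: a simplex witness is
# required on both sides, so non-support subsets hold vacuously.
#' @keywords internal
check_identification <- function(K, u, v) {
  ku <- vertex_key(u, K)
  kv <- vertex_key(v, K)
  if (ku == kv) stop_screp("bad-argument", "u and v must be distinct")
  nu <- adjacent_vertices(K, ku)
  nv <- adjacent_vertices(K, kv)
  adjacent <- kv %in% nu
  kind <- if (adjacent) "adjacent" else "nonadjacent"
  if (adjacent) {
    if (!setequal(setdiff(nu, kv), setdiff(nv, ku))) {
      return(list(kind = kind, ok = FALSE, clause = "shared-deleted-neighbourhood"))
    }
  } else {
    if (!setequal(nu, nv)) {
      return(list(kind = kind, ok = FALSE, clause = "equal-neighbourhood"))
    }
  }
  skeys <- srep_skeys(K)
  coface_ok <- function(a, b) {
    # every simplex W+{a} with b not in W must have the partner W+{b}
    for (s in K$simplices) {
      if (a %in% s && !(b %in% s)) {
        W <- setdiff(s, a)
        if (length(W) == 0L) next
        if (!(paste(csort(c(W, b)), collapse = "|") %in% skeys)) return(FALSE)
      }
    }
    TRUE
  }
  if (!coface_ok(ku, kv) || !coface_ok(kv, ku)) {
    return(list(kind = kind, ok = FALSE, clause = "co-face"))
  }
  list(kind = kind, ok = TRUE, clause = NULL, u = ku, v = kv)
}

#' @keywords internal
do_identification <- function(K, ku, kv, merged_label = NULL) {
  if (is.null(merged_label)) {
    cid <- norm_vid(list(K$vertices[[ku]], K$vertices[[kv]]))
  } else {
    cid <- norm_vid(merged_label)
  }
  ckey <- vid_key(cid)
  if (ckey %in% setdiff(names(K$vertices), c(ku, kv))) {
    stop_screp("vertex-collision", "merged identifier %s collides with an existing vertex", ckey)
  }
  vertices <- K$vertices[setdiff(names(K$vertices), c(ku, kv))]
  vertices[[ckey]] <- cid
  labels <- K$labels[setdiff(names(K$labels), c(ku, kv))]
  labels[[ckey]] <- sort(unique(c(vertex_label(K, ku), vertex_label(K, kv))))
  vmap <- stats::setNames(names(K$vertices), names(K$vertices))
  vmap[c(ku, kv)] <- ckey
  simplices <- lapply(K$simplices, function(s) unique(unname(vmap[s])))
  new_srep(vertices, simplices, labels = labels, universe = attr(K, "universe"))
}

#' Operation 1: adjacent-vertex identification
#'
#' Merges two adjacent vertices whose positions in the complex are
#' symmetric: they must share the same deleted neighbourhood, and every
#' co-face over that neighbourhood must exist for one exactly when it exists
#' for the other. The merged vertex carries the nested set of the two
#' identifiers (overridable) and the union of their component labels. The
#' result equals the orbit space of `K` under the transposition `(u v)`.
#'
#' @param K An `srep`.
#' @param u,v Adjacent vertex references.
#' @param merged_label Optional identifier for the merged vertex (an integer
#'   set or nested identifier).
#' @return An `srep`.
#' @export
adjacent_vertex_identification <- function(K, u, v, merged_label = NULL) {
  chk <- check_identification(K, u, v)
  if (chk$kind != "adjacent") {
    stop_screp("not-adjacent", "vertices are not adjacent; use nonadjacent_vertex_identification")
  }
  if (!chk$ok) stop_screp(chk$clause, "adjacent-vertex identification precondition fails")
  do_identification(K, chk$u, chk$v, merged_label)
}

#' Operation 2: nonadjacent-vertex identification
#'
#' As [adjacent_vertex_identification()], for a nonadjacent pair: the two
#' vertices must have equal neighbourhoods and matching co-faces.
#'
#' @inheritParams adjacent_vertex_identification
#' @export
nonadjacent_vertex_identification <- function(K, u, v, merged_label = NULL) {
  chk <- check_identification(K, u, v)
  if (chk$kind != "nonadjacent") {
    stop_screp("use-operation-1", "vertices are adjacent; use adjacent_vertex_identification")
  }
  if (!chk$ok) stop_screp(chk$clause, "nonadjacent-vertex identification precondition fails")
  do_identification(K, chk$u, chk$v, merged_label)
}

#' Operation 5: vertex substitution
#'
#' Bijectively relabels one vertex: `u` is replaced by the identifier `c`,
#' every other vertex and the simplex structure are unchanged. Substituting
#' back recovers the original complex.
#'
#' @param K An `srep`.
#' @param u A vertex reference in `Vert(K)`.
#' @param c The replacement identifier (integer, integer set, or nested
#'   identifier); must not collide with another existing vertex.
#' @param label Optional integer component set for the new vertex; defaults
#'   to the integers in `c`.
#' @return An `srep`.
#' @export
vertex_substitution <- function(K, u, c, label = NULL) {
  ku <- vertex_key(u, K)
  cid <- norm_vid(c)
  ckey <- vid_key(cid)
  if (ckey %in% setdiff(names(K$vertices), ku)) {
    stop_screp("vertex-collision", "replacement %s collides with an existing vertex", ckey)
  }
  if (ckey == ku) return(K)
  vertices <- K$vertices[setdiff(names(K$vertices), ku)]
  vertices[[ckey]] <- cid
  labels <- K$labels[setdiff(names(K$labels), ku)]
  labels[[ckey]] <- if (is.null(label)) vid_flatten(cid) else sort(unique(as.integer(label)))
  vmap <- stats::setNames(names(K$vertices), names(K$vertices))
  vmap[[ku]] <- ckey
  simplices <- lapply(K$simplices, function(s) unname(vmap[s]))
  new_srep(vertices, simplices, labels = labels, universe = attr(K, "universe"))
}
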