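# Simplicial representations: labelled abstract simplicial complexes.
#
# A vertex identifier is a finite nonempty set of positive integers, possibly
# nested: an original model component is the singleton {c}, and a vertex
# produced by a quotient is the set of the identifiers it merged. Internally
# an identifier is either an integer vector (a flat set) or a list of
# identifiers (a nested set); identity is decided through a canonical string
# key such as "{1}" or "{{1},{2}}". A set with a single member collapses to
# that member, matching the convention that a vertex v and the set {v} are
# interchangeable.

# ---- vertex identifier structures -------------------------------------------

#' @keywords internal
norm_vid <- function(x) {
  if (is.numeric(x)) {
    v <- unique(as.integer(x))
    if (length(v) == 0L) stop_screp("empty-vertex-id", "vertex identifier must be nonempty")
    if (any(is.na(v)) || any(v < 1L)) {
      stop_screp("bad-vertex-id", "vertex identifiers contain only positive integers")
    }
    return(sort(v))
  }
  if (is.list(x)) {
    kids <- lapply(x, norm_vid)
    keys <- vapply(kids, vid_key, character(1))
    kids <- kids[!duplicated(keys)]
    if (length(kids) == 0L) stop_screp("empty-vertex-id", "vertex identifier must be nonempty")
    if (length(kids) == 1L) return(kids[[1L]])  # {v} collapses to v
    kids[order(vapply(kids, vid_key, character(1)), method = "radix")]
  } else {
    stop_screp("bad-vertex-id", "a vertex identifier is an integer vector or a list of identifiers")
  }
}

#' @keywords internal
vid_key <- function(x) {
  if (is.numeric(x)) {
    paste0("{", paste(sort(as.integer(x)), collapse = ","), "}")
  } else {
    paste0("{", paste(csort(vapply(x, vid_key, character(1))), collapse = ","), "}")
  }
}

# Union of all integers contained in an identifier (the flattened label view).
#' @keywords internal
vid_flatten <- function(x) sort(unique(as.integer(unlist(x, use.names = FALSE))))

# ---- component universe -----------------------------------------------------

#' Component universe
#'
#' The set of all model components under consideration, together with the
#' ordering bijection between component names and positive integers. Every
#' representation compared against another is labelled from one shared
#' universe.
#'
#' @param components Named character vector or named list: names are the
#'   positive-integer codes (as strings) and values the component names, or a
#'   plain character vector which is numbered `1..n` in order.
#' @return An object of class `component_universe`: a named character vector
#'   mapping integer codes to component names.
#' @examples
#' component_universe(c("Morphogen 1", "Diffusion 1"))
#' @export
component_universe <- function(components) {
  if (is.list(components)) components <- unlist(components)
  if (is.null(names(components)) || all(names(components) == "")) {
    names(components) <- as.character(seq_along(components))
  }
  ids <- suppressWarnings(as.integer(names(components)))
  if (any(is.na(ids)) || any(ids < 1L) || anyDuplicated(ids)) {
    stop_screp("bad-universe", "component codes must be distinct positive integers")
  }
  vals <- as.character(components)
  if (anyDuplicated(vals) || any(!nzchar(vals))) {
    stop_screp("bad-universe", "component names must be distinct nonempty strings")
  }
  structure(stats::setNames(vals, as.character(ids)), class = "component_universe")
}

#' @export
print.component_universe <- function(x, ...) {
  cat("Component universe with", length(x), "components\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, x[[k]]))
  invisible(x)
}

# ---- the srep class ---------------------------------------------------------

# Low-level constructor. `vertices` is a named list key -> identifier
# structure, `simplices` a list of character vectors of vertex keys,
# `labels` a named list key -> integer vector. No closure is performed;
# callers are expected to hand in a face-closed family (validate() reports
# violations otherwise).
#' @keywords internal
new_srep <- function(vertices, simplices, labels = NULL, universe = NULL) {
  vkeys <- names(vertices)
  simplices <- lapply(simplices, function(s) csort(unique(s)))
  skeys <- vapply(simplices, paste, character(1), collapse = "|")
  keep <- !duplicated(skeys)
  simplices <- simplices[keep]
  skeys <- skeys[keep]
  ord <- order(lengths(simplices), skeys, method = "radix")
  simplices <- simplices[ord]
  skeys <- skeys[ord]
  if (is.null(labels)) {
    labels <- lapply(vertices, vid_flatten)
  } else {
    labels <- lapply(labels, function(l) sort(unique(as.integer(l))))
  }
  structure(
    list(vertices = vertices, simplices = simplices, labels = labels),
    skeys = skeys, universe = universe, class = "srep"
  )
}

#' @keywords internal
srep_skeys <- function(K) attr(K, "skeys", exact = TRUE)

# Resolve a user-supplied vertex reference (integer, integer set, canonical
# key string, or nested list identifier) to a canonical key.
#' @keywords internal
vertex_key <- function(v, K = NULL, require = TRUE) {
  key <- if (is.character(v) && length(v) == 1L) v else vid_key(norm_vid(v))
  if (!is.null(K) && require && !(key %in% names(K$vertices))) {
    stop_screp("unknown-vertex", "vertex %s is not in the complex", key)
  }
  key
}

#' Construct a simplicial representation from its maximal simplices
#'
#' Builds the labelled simplicial complex containing exactly the listed
#' vertex sets and all their nonempty subsets, so the face-closure axiom
#' holds by construction. An empty list yields the void complex.
#'
#' @param maximal List of simplices; each simplex is a vector of vertex
#'   references (positive integers for original components, or canonical
#'   key strings / nested identifiers for quotient vertices).
#' @param labels Optional named list mapping vertex keys to integer component
#'   sets; defaults to the integers contained in each vertex identifier.
#' @param universe Optional [component_universe()] attached to the result.
#' @return An object of class `srep`.
#' @examples
#' close_under_faces(list(c(1, 2, 3)))       # the full triangle, 7 simplices
#' close_under_faces(list(c(1, 2), c(2, 3))) # a path, 5 simplices
#' close_under_faces(list())                 # the void complex
#' @export
close_under_faces <- function(maximal, labels = NULL, universe = NULL) {
  verts <- list()
  key_sets <- vector("list", length(maximal))
  for (i in seq_along(maximal)) {
    s <- maximal[[i]]
    if (length(s) == 0L) stop_screp("empty-simplex", "simplices must be nonempty vertex sets")
    ids <- if (is.numeric(s)) lapply(as.integer(s), identity) else if (is.list(s)) s else as.list(s)
    keys <- character(length(ids))
    for (j in seq_along(ids)) {
      if (is.character(ids[[j]])) {
        keys[j] <- ids[[j]]
        if (is.null(verts[[keys[j]]])) {
          stop_screp("unknown-vertex", "vertex key %s used before its identifier is known", keys[j])
        }
      } else {
        vs <- norm_vid(ids[[j]])
        keys[j] <- vid_key(vs)
        verts[[keys[j]]] <- vs
      }
    }
    key_sets[[i]] <- unique(keys)
  }
  simplices <- list()
  seen <- character(0)
  for (ks in key_sets) {
    for (sub in nonempty_subsets(csort(ks))) {
      sk <- paste(sub, collapse = "|")
      if (!(sk %in% seen)) {
        seen <- c(seen, sk)
        simplices[[length(simplices) + 1L]] <- sub
      }
    }
  }
  new_srep(verts, simplices, labels = labels, universe = universe)
}

#' @export
print.srep <- function(x, ...) {
  d <- complex_dimension(x)
  cat(sprintf("Simplicial representation: %d vertices, %d simplices, dimension %s\n",
              length(x$vertices), length(x$simplices),
              if (is.infinite(d)) "-Inf (void)" else d))
  if (length(x$simplices) > 0L) {
    shown <- utils::head(srep_skeys(x), 25L)
    cat("  ", paste(shown, collapse = "  "), "\n", sep = "")
    if (length(x$simplices) > 25L) cat("  ...\n")
  }
  invisible(x)
}

# Structural equality: same vertex keys, same simplex family, same labels.
#' @keywords internal
srep_equal <- function(K, L) {
  identical(csort(names(K$vertices)), csort(names(L$vertices))) &&
    identical(srep_skeys(K), srep_skeys(L)) &&
    identical(K$labels[csort(names(K$labels))], L$labels[csort(names(L$labels))])
}

#' Flattened component label of a vertex
#'
#' The set of model-component integers carried by a vertex: for an original
#' vertex its single component, for a quotient vertex the union over every
#' identifier merged into it.
#'
#' @param K An `srep`.
#' @param v A vertex reference.
#' @return Sorted integer vector.
#' @export
vertex_label <- function(K, v) {
  key <- vertex_key(v, K)
  lbl <- K$labels[[key]]
  if (is.null(lbl)) vid_flatten(K$vertices[[key]]) else lbl
}

#' Validate a simplicial representation
#'
#' Checks the simplicial-complex axioms: every nonempty subset of a simplex
#' is a simplex (face closure), every vertex appears as a 0-simplex, no
#' simplex uses an unknown vertex, and every vertex carries a label. The void
#' complex is valid.
#'
#' @param K An `srep`.
#' @return A list with `ok` (logical) and `violations`, a data frame with
#'   columns `rule` and `detail`; `ok` is `TRUE` iff `violations` is empty.
#' @export
validate_srep <- function(K) {
  rules <- character(0); details <- character(0)
  skeys <- srep_skeys(K)
  vkeys <- names(K$vertices)
  for (i in seq_along(K$simplices)) {
    s <- K$simplices[[i]]
    bad <- setdiff(s, vkeys)
    if (length(bad) > 0L) {
      rules <- c(rules, "unknown-vertex")
      details <- c(details, paste0(skeys[i], " uses ", paste(bad, collapse = ",")))
    }
    if (length(s) > 1L) {
      for (sub in nonempty_subsets(s)) {
        if (length(sub) < length(s) && !(paste(sub, collapse = "|") %in% skeys)) {
          rules <- c(rules, "face-closure")
          details <- c(details, paste0(skeys[i], " missing face ", paste(sub, collapse = "|")))
        }
      }
    }
  }
  zero <- vapply(K$simplices, length, integer(1)) == 1L
  present <- unlist(K$simplices[zero], use.names = FALSE)
  for (v in setdiff(vkeys, present)) {
    rules <- c(rules, "orphan-vertex")
    details <- c(details, v)
  }
  for (v in vkeys) {
    if (is.null(K$labels[[v]]) || length(K$labels[[v]]) == 0L) {
      rules <- c(rules, "unlabelled-vertex")
      details <- c(details, v)
    }
  }
  viol <- data.frame(rule = rules, detail = details, stringsAsFactors = FALSE)
  list(ok = nrow(viol) == 0L, violations = viol)
}

#' Dimension of a simplicial representation
#'
#' The maximum simplex cardinality minus one. The void complex has the
#' assigned dimension `-Inf`.
#'
#' @param K An `srep`.
#' @return Integer dimension, or `-Inf` for the void complex.
#' @export
complex_dimension <- function(K) {
  if (length(K$simplices) == 0L) return(-Inf)
  max(lengths(K$simplices)) - 1L
}
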