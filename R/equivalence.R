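# Deciding model equivalence: label-constrained isomorphism search between
# final orbit spaces, restricted reductions, and partitioning a model
# collection into equivalence classes.

#' Label consistency between two reduced complexes
#'
#' A vertex label in one final orbit space should not share model components
#' with two distinct vertices of the other: that indicates a conceptual
#' inconsistency in at least one of the representations. Returns one
#' diagnostic per offending vertex (checked in both directions).
#'
#' @param Khat,Lhat Two `srep`s carrying flattened component labels.
#' @return Data frame with columns `side`, `vertex`, `overlaps`.
#' @export
label_consistency_check <- function(Khat, Lhat) {
  one_way <- function(A, B, side) {
    rows <- list()
    for (v in csort(names(A$vertices))) {
      lab <- vertex_label(A, v)
      hits <- Filter(function(w) length(intersect(lab, vertex_label(B, w))) > 0L,
                     csort(names(B$vertices)))
      if (length(hits) >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, vertex = v, overlaps = paste(hits, collapse = " "),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }
  rows <- c(one_way(Khat, Lhat, "K"), one_way(Lhat, Khat, "L"))
  if (length(rows) == 0L) {
    data.frame(side = character(0), vertex = character(0), overlaps = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}

# Per-vertex structural signature used to prune the bijection search:
# degree (number of edge adjacencies) and maximal co-face dimension.
#' @keywords internal
vertex_signature <- function(K) {
  vkeys <- csort(names(K$vertices))
  sig <- lapply(vkeys, function(v) {
    deg <- length(adjacent_vertices(K, v))
    maxco <- max(vapply(K$simplices,
                        function(s) if (v %in% s) length(s) else 0L, integer(1))) - 1L
    c(deg = deg, maxco = maxco)
  })
  stats::setNames(sig, vkeys)
}

#' Candidate vertex bijections between two complexes
#'
#' All bijections `Vert(Khat) -> Vert(Lhat)` compatible with per-vertex
#' degree, per-vertex maximal co-face dimension, and (optionally) the forced
#' matching of vertices that share a model component. Returns an empty list
#' when the vertex counts differ.
#'
#' @param Khat,Lhat Two `srep`s.
#' @param enforce_shared_components When `TRUE` (default), a vertex whose
#'   flattened label shares a component with some vertices of the other
#'   complex may only be mapped to those vertices.
#' @return List of named character vectors (each a bijection by vertex key),
#'   in deterministic order.
#' @export
candidate_vertex_bijections <- function(Khat, Lhat, enforce_shared_components = TRUE) {
  kk <- csort(names(Khat$vertices))
  ll <- csort(names(Lhat$vertices))
  if (length(kk) != length(ll)) return(list())
  if (length(kk) == 0L) return(list(stats::setNames(character(0), character(0))))
  sigK <- vertex_signature(Khat)
  sigL <- vertex_signature(Lhat)
  allowed <- lapply(kk, function(v) {
    cand <- ll[vapply(ll, function(w) identical(sigK[[v]], sigL[[w]]), logical(1))]
    if (enforce_shared_components) {
      share <- ll[vapply(ll, function(w) {
        length(intersect(vertex_label(Khat, v), vertex_label(Lhat, w))) > 0L
      }, logical(1))]
      if (length(share) > 0L) cand <- intersect(cand, share)
    }
    cand
  })
  out <- list()
  assign_next <- function(i, used, map) {
    if (i > length(kk)) {
      out[[length(out) + 1L]] <<- stats::setNames(map, kk)
      return(invisible())
    }
    for (w in setdiff(allowed[[i]], used)) {
      assign_next(i + 1L, c(used, w), c(map, w))
    }
  }
  assign_next(1L, character(0), character(0))
  out
}

#' Does a vertex bijection extend to a simplicial isomorphism?
#'
#' `TRUE` iff the element-wise image of the simplex family of `Khat` equals
#' the simplex family of `Lhat`.
#'
#' @param Khat,Lhat Two `srep`s.
#' @param vertex_map Named character vector, a bijection
#'   `Vert(Khat) -> Vert(Lhat)`.
#' @return Logical.
#' @export
is_isomorphism <- function(Khat, Lhat, vertex_map) {
  if (length(Khat$simplices) != length(Lhat$simplices)) return(FALSE)
  if (!setequal(names(vertex_map), names(Khat$vertices)) ||
      !setequal(unname(vertex_map), names(Lhat$vertices)) ||
      anyDuplicated(unname(vertex_map))) {
    return(FALSE)
  }
  img <- vapply(Khat$simplices,
                function(s) paste(csort(unname(vertex_map[s])), collapse = "|"),
                character(1))
  setequal(img, srep_skeys(Lhat))
}

#' All label-constrained isomorphisms between two complexes
#'
#' @inheritParams candidate_vertex_bijections
#' @return List of vertex bijections that extend to simplicial isomorphisms.
#' @export
find_isomorphisms <- function(Khat, Lhat, enforce_shared_components = TRUE) {
  Filter(function(m) is_isomorphism(Khat, Lhat, m),
         candidate_vertex_bijections(Khat, Lhat, enforce_shared_components))
}

#' Decide whether two simplicial representations are equivalent
#'
#' Reduces both representations to their final orbit spaces, searches for
#' label-constrained simplicial isomorphisms between them, and, when one
#' exists, emits the explicit sequence of partial operations (the per-stage
#' identifications on each side followed by the closing vertex
#' substitutions) realising the equivalence.
#'
#' Whether the matched component sets are conceptually meaningful is a
#' domain judgement outside the software: the verdict carries
#' `component_pairings` for human review, and `assume_meaningful` controls
#' the reported verdict.
#'
#' @param K,L Two `srep`s over one component universe.
#' @param enforce_shared_components Passed to
#'   [candidate_vertex_bijections()].
#' @param assume_meaningful When `TRUE` (default) an isomorphism is taken as
#'   establishing equivalence; when `FALSE`, `equivalent` is reported `NA`
#'   whenever isomorphisms exist, pending conceptual sign-off.
#' @return A list of class `equivalence_verdict`: `equivalent`,
#'   `isomorphisms`, `component_pairings` (per isomorphism, the matched
#'   flattened label sets), `operations` (the audit sequence for the first
#'   isomorphism), `consistency` (diagnostics from
#'   [label_consistency_check()]), `trace_K`, `trace_L`.
#' @export
decide_equivalence <- function(K, L, enforce_shared_components = TRUE,
                               assume_meaningful = TRUE) {
  trK <- final_orbit_space(K)
  trL <- final_orbit_space(L)
  Khat <- trK$final
  Lhat <- trL$final
  isos <- find_isomorphisms(Khat, Lhat, enforce_shared_components)
  pairings <- lapply(isos, function(m) {
    lapply(csort(names(m)), function(v) {
      list(K = vertex_label(Khat, v), L = vertex_label(Lhat, unname(m[[v]])))
    })
  })
  ops <- NULL
  if (length(isos) > 0L) {
    ops <- equivalence_operations(trK, trL, isos[[1L]])
  }
  equivalent <- length(isos) > 0L
  if (equivalent && !assume_meaningful) equivalent <- NA
  structure(list(
    equivalent = equivalent,
    isomorphisms = isos,
    component_pairings = pairings,
    operations = ops,
    consistency = label_consistency_check(Khat, Lhat),
    trace_K = trK, trace_L = trL
  ), class = "equivalence_verdict")
}

# Audit sequence realising the equivalence: each stage's identifications on
# both sides, then vertex substitutions (via fresh temporaries to avoid
# collisions) transforming the final complex of K into the final complex of
# L under the chosen isomorphism.
#' @keywords internal
equivalence_operations <- function(trK, trL, iso) {
  ops <- list()
  for (side in c("K", "L")) {
    tr <- if (side == "K") trK else trL
    for (i in seq_along(tr$stages)) {
      for (p in tr$stages[[i]]$pairs) {
        ops[[length(ops) + 1L]] <- list(op = "identify", side = side, stage = i,
                                        u = p[1], v = p[2])
      }
    }
  }
  Khat <- trK$final
  src <- csort(names(iso))
  tgt <- unname(iso[src])
  moved <- src != tgt
  src <- src[moved]
  tgt <- tgt[moved]
  if (length(src) > 0L) {
    used <- vid_flatten(c(lapply(Khat$vertices, vid_flatten),
                          lapply(trL$final$vertices, vid_flatten)))
    fresh <- setdiff(seq_len(max(used, 0L) + length(src)), used)[seq_along(src)]
    for (i in seq_along(src)) {
      ops[[length(ops) + 1L]] <- list(op = "substitute", side = "K",
                                      from = src[i], to = vid_key(fresh[i]))
    }
    for (i in seq_along(src)) {
      ops[[length(ops) + 1L]] <- list(op = "substitute", side = "K",
                                      from = vid_key(fresh[i]), to = tgt[i])
    }
  }
  ops
}

#' Replay the substitution part of an equivalence audit sequence
#'
#' Applies the recorded vertex substitutions to the final orbit space of `K`
#' and returns the transformed complex, which must equal the final orbit
#' space of `L` exactly when the verdict is sound.
#'
#' @param verdict An `equivalence_verdict` with `equivalent = TRUE`.
#' @return An `srep`.
#' @export
replay_operations <- function(verdict) {
  if (!isTRUE(verdict$equivalent)) {
    stop_screp("not-equivalent", "verdict has no operation sequence to replay")
  }
  cur <- verdict$trace_K$final
  Lhat <- verdict$trace_L$final
  for (op in verdict$operations) {
    if (op$op != "substitute") next
    target_id <- if (op$to %in% names(Lhat$vertices)) Lhat$vertices[[op$to]] else NULL
    cur <- if (is.null(target_id)) {
      # temporary identifier: parse from its key (always a flat integer set)
      vertex_substitution(cur, op$from,
                          as.integer(strsplit(gsub("[{}]", "", op$to), ",")[[1]]))
    } else {
      vertex_substitution(cur, op$from, target_id,
                          label = Lhat$labels[[op$to]])
    }
  }
  cur
}

#' @export
print.equivalence_verdict <- function(x, ...) {
  cat("Equivalence verdict:",
      if (isTRUE(x$equivalent)) "EQUIVALENT"
      else if (is.na(x$equivalent)) "isomorphic (conceptual sign-off pending)"
      else "not equivalent", "\n")
  cat(sprintf("  reduction: %d stage(s) for K, %d for L; %d isomorphism(s)\n",
              length(x$trace_K$stages), length(x$trace_L$stages),
              length(x$isomorphisms)))
  if (nrow(x$consistency) > 0L) {
    cat("  label inconsistencies detected:\n")
    print(x$consistency)
  }
  if (length(x$component_pairings) > 0L) {
    cat("  component pairings (first isomorphism):\n")
    for (p in x$component_pairings[[1L]]) {
      cat(sprintf("    {%s} ~ {%s}\n", paste(p$K, collapse = ","),
                  paste(p$L, collapse = ",")))
    }
  }
  invisible(x)
}

#' Final orbit space under restricted identifications
#'
#' The same fixpoint iteration as [final_orbit_space()], but an exchangeable
#' pair is identified only when every cross pair of model components merged
#' by it is in `allowed_pairs`. Supplying all pairs reproduces
#' [final_orbit_space()]; supplying none returns `K` unchanged.
#'
#' @param K An `srep`.
#' @param allowed_pairs List of unordered pairs of component integers (each
#'   a length-2 numeric vector).
#' @return A `reduction_trace`.
#' @export
restricted_final_orbit_space <- function(K, allowed_pairs) {
  allowed <- vapply(allowed_pairs, function(p) paste(sort(as.integer(p)), collapse = "-"),
                    character(1))
  admissible <- function(Kc, u, v) {
    a <- vertex_label(Kc, u)
    b <- vertex_label(Kc, v)
    for (x in a) for (y in b) {
      if (x != y && !(paste(sort(c(x, y)), collapse = "-") %in% allowed)) return(FALSE)
    }
    TRUE
  }
  final_orbit_space(K, admissible = admissible)
}

#' Partition a collection of representations into equivalence classes
#'
#' Computes pairwise verdicts, asserts that they are transitive (a violation
#' signals an implementation bug, since model equivalence is an equivalence
#' relation), and returns the classes.
#'
#' @param reps Named list of `srep`s over one component universe.
#' @param enforce_shared_components Passed to [decide_equivalence()].
#' @return List of character vectors (names of `reps`), each one class.
#' @export
partition_by_equivalence <- function(reps, enforce_shared_components = TRUE) {
  n <- length(reps)
  if (n == 0L) return(list())
  if (is.null(names(reps))) names(reps) <- paste0("model", seq_len(n))
  eq <- diag(TRUE, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- decide_equivalence(reps[[i]], reps[[j]], enforce_shared_components)
      eq[i, j] <- eq[j, i] <- isTRUE(v$equivalent)
    }
  }
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (eq[a, b] && eq[b, cc] && !eq[a, cc]) {
      stop_screp("transitivity-violation",
                 "pairwise verdicts are not transitive (%d ~ %d ~ %d)", a, b, cc)
    }
  }
  classes <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cls <- which(eq[i, ])
    assigned[cls] <- TRUE
    classes[[length(classes) + 1L]] <- names(reps)[cls]
  }
  classes
}
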