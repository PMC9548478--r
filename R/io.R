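# JSON interchange format for simplicial representations.
#
# {"components": {"1": "Morphogen 1", ...},        optional
#  "vertices":   [1, 2, [3, 4], [[1],[2]], ...],   optional; inferred
#  "simplices":  [[1], [2], [1,2], ...],
#  "maximal_only": false,
#  "clique_complete": false}
#
# Inside a simplex array, a bare integer n is the singleton vertex {n} and a
# nested array is a (possibly nested) quotient-vertex identifier. When
# "maximal_only" is true the listed simplices are closed under faces on
# reading; when "clique_complete" is true the file may carry only the
# 1-skeleton and the flag complex is formed. The writer emits a canonical
# ordering so that the same complex always serializes byte-identically.

#' @keywords internal
json_to_vid <- function(x) {
  if (is.numeric(x)) return(norm_vid(x))
  if (is.list(x)) {
    if (all(vapply(x, is.numeric, logical(1))) &&
        all(vapply(x, length, integer(1)) == 1L)) {
      return(norm_vid(unlist(x)))
    }
    return(norm_vid(lapply(x, json_to_vid)))
  }
  stop_screp("bad-json", "cannot parse vertex identifier from JSON")
}

#' @keywords internal
vid_to_json <- function(x) {
  if (is.numeric(x)) return(as.list(as.integer(x)))
  lapply(x, vid_to_json)
}

#' Read a simplicial representation from a JSON file
#'
#' @param path File path (or a JSON string).
#' @return An `srep`, with any component universe attached.
#' @export
read_srep <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$simplices)) stop_screp("bad-json", "file has no \"simplices\" field")
  universe <- NULL
  if (!is.null(doc$components) && length(doc$components) > 0L) {
    universe <- component_universe(unlist(doc$components))
  }
  maximal <- lapply(doc$simplices, function(s) {
    if (length(s) == 0L) stop_screp("empty-simplex", "simplices must be nonempty")
    lapply(s, json_to_vid)
  })
  extra <- lapply(doc$vertices %||% list(), function(v) list(json_to_vid(v)))
  K <- close_under_faces(c(maximal, extra), universe = universe)
  if (isTRUE(doc$clique_complete)) {
    K <- clique_completion(K)
  } else if (!isTRUE(doc$maximal_only) && !isTRUE(doc$clique_complete)) {
    # file claims to list the full family; closure must not have added faces
    listed <- vapply(maximal, function(s) {
      paste(csort(vapply(s, function(v) vid_key(v), character(1))), collapse = "|")
    }, character(1))
    missing <- setdiff(srep_skeys(K), listed)
    if (length(missing) > 0L) {
      stop_screp("face-closure", "file is not face-closed (missing %s); set maximal_only",
                 paste(utils::head(missing, 3L), collapse = ", "))
    }
  }
  K
}

#' Write a simplicial representation to a JSON file
#'
#' Emits the full simplex family in canonical order (by dimension, then by
#' lexicographic vertex key), so equal complexes produce byte-identical
#' files.
#'
#' @param K An `srep`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_srep <- function(K, path) {
  doc <- list()
  uni <- attr(K, "universe")
  if (!is.null(uni)) doc$components <- as.list(unclass(uni))
  vkeys <- csort(names(K$vertices))
  doc$vertices <- lapply(vkeys, function(k) vid_to_json(K$vertices[[k]]))
  doc$simplices <- lapply(K$simplices, function(s) {
    lapply(s, function(k) {
      v <- K$vertices[[k]]
      if (is.numeric(v) && length(v) == 1L) as.integer(v) else vid_to_json(v)
    })
  })
  doc$maximal_only <- FALSE
  doc$clique_complete <- FALSE
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(txt, path)
  invisible(path)
}
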