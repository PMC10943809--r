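#' Neuron skeletons
#'
#' A skeleton is a node tree in SWC convention: each node has an integer id, a
#' structure type code, a 3D position (um, in an alignment space), a radius
#' (um) and a parent id (`-1` for roots). `skeleton()` validates the node
#' table: ids must be unique, every parent must exist (or be -1), and the
#' parent graph must be acyclic.
#'
#' @param nodes A data frame with columns `node_id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent_id`.
#' @param space The [alignment_space()] the coordinates live in.
#' @return An object of class `skeleton` with fields `nodes` (tibble) and
#'   `space`.
#' @export
skeleton <- function(nodes, space) {
  stopifnot(is_alignment_space(space))
  cols <- c("node_id", "type", "x", "y", "z", "radius", "parent_id")
  nodes <- as_tibble(nodes)
  if (!all(cols %in% names(nodes))) abort("skeleton nodes need columns node_id, type, x, y, z, radius, parent_id")
  nodes <- nodes[cols]
  if (nrow(nodes) == 0L) abort("skeleton must have at least one node")
  if (anyDuplicated(nodes$node_id)) abort("skeleton node_ids must be unique")
  bad <- !(nodes$parent_id == -1L | nodes$parent_id %in% nodes$node_id)
  if (any(bad))
    abort(sprintf("dangling parent_id(s): node %s refers to absent parent %s",
                  paste(nodes$node_id[bad], collapse = ","),
                  paste(nodes$parent_id[bad], collapse = ",")))
  # acyclicity: follow parents from every node; depth is bounded by n
  parent_of <- setNames(nodes$parent_id, as.character(nodes$node_id))
  n <- nrow(nodes)
  for (start in nodes$node_id) {
    cur <- start; steps <- 0L
    while (cur != -1L) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) abort("skeleton parent graph contains a cycle")
    }
  }
  structure(list(nodes = nodes, space = space), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, %d root(s), space %s\n",
              nrow(x$nodes), sum(x$nodes$parent_id == -1L), x$space$name))
  invisible(x)
}

#' Read a neuron skeleton from an SWC file
#'
#' Accepts the common SWC dialect: 7 whitespace-delimited columns
#' (id, type, x, y, z, radius, parent), `#` comment lines and blank lines.
#' Coordinates are taken as micrometres in `space`.
#'
#' @param path Path to an SWC file.
#' @param space The [alignment_space()] of the coordinates.
#' @return A [skeleton()].
#' @export
read_swc <- function(path, space) {
  if (!file.exists(path)) abort(sprintf("SWC file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) abort(sprintf("SWC file has no data lines: %s", path))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad) > 0L)
    abort(sprintf("malformed SWC line %d in %s: expected 7 fields, got %d",
                  keep[bad[1]], path, lengths(parts)[bad[1]]))
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    row <- which(apply(is.na(m), 1L, any))[1]
    abort(sprintf("malformed SWC line %d in %s: non-numeric field", keep[row], path))
  }
  nodes <- tibble(
    node_id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7]))
  skeleton(nodes, space)
}

#' Write a skeleton to an SWC file
#'
#' Writes standard 7-column SWC with single-space separators and a one-line
#' header comment. Round-trips exactly with [read_swc()].
#'
#' @param skel A [skeleton()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton"))
  if (nrow(skel$nodes) == 0L) abort("refusing to write an empty skeleton")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC skeleton in space %s (um)", skel$space$name), con)
  with(skel$nodes, writeLines(sprintf(
    "%d %d %.17g %.17g %.17g %.17g %d", node_id, type, x, y, z, radius, parent_id), con))
  invisible(path)
}
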