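#' Read an SWC reconstruction
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comment lines
#' tolerated. In this package's depth convention the y column holds the
#' depth from the pia in micrometers, increasing downward (coronal-slice
#' reconstructions are effectively two-dimensional; z is carried but
#' ignored by the feature code). Type codes: 1 soma, 3 basal dendrite,
#' 4 apical dendrite.
#'
#' @param path file path.
#' @return a `morphology_tree`: list with `nodes` (data frame), `soma`
#'   (named vector `x`, `depth`) and `label` (NA unless set by a
#'   generator).
#' @export
read_swc <- function(path) {
  nodes <- read.table(path, comment.char = "#", col.names = c(
    "id", "type", "x", "y", "z", "radius", "parent"
  ))
  morphology_tree(nodes)
}

#' Write an SWC reconstruction
#'
#' @param tree a `morphology_tree`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_swc <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC: id type x y z radius parent (y = depth from pia, um)", con)
  write.table(format(tree$nodes, trim = TRUE, digits = 8), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a morphology tree from an SWC node table
#'
#' Validates the tree structure: exactly one root (parent -1), every parent
#' id present, no cycles, depths (y) nonnegative.
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`; `y` is depth from pia (um).
#' @param label optional ground-truth class label (`"BT"`/`"ST"`).
#' @return an object of class `morphology_tree`.
#' @export
morphology_tree <- function(nodes, label = NA_character_) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (!all(nodes$parent %in% c(-1, nodes$id))) stop("missing parent ids")
  if (any(nodes$y < 0)) stop("depths must be nonnegative")
  # cycle check: walking up from any node must reach the root
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- 0L
    cur <- id
    while (cur != -1) {
      cur <- parent_of[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > nrow(nodes)) stop("cycle detected at node ", id)
    }
  }
  soma_nodes <- nodes[nodes$type == 1, ]
  if (nrow(soma_nodes) == 0) stop("no soma node (type 1)")
  structure(
    list(nodes = nodes,
         soma = c(x = mean(soma_nodes$x), depth = mean(soma_nodes$y)),
         label = label),
    class = "morphology_tree"
  )
}

# children lookup: list mapping id -> integer vector of child ids
tree_children <- function(nodes) {
  split(nodes$id, factor(nodes$parent, levels = nodes$id))
}

# all descendant ids of `start_id`, inclusive
tree_descendants <- function(nodes, start_id) {
  ch <- tree_children(nodes)
  out <- integer(0)
  stack <- start_id
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, cur)
    kids <- ch[[as.character(cur)]]
    if (length(kids)) stack <- c(stack, kids)
  }
  out
}
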