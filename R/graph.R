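#' Build the breakpoint graph of an observed breakpoint set
#'
#' The chromosome is partitioned at the sorted unique breakpoint positions
#' into `n` segments.  The graph has `2n` nodes -- one per segment end,
#' labelled (position, terminus) -- a *segment edge* joining the head and
#' tail of every segment, and a *breakpoint edge* per observed breakpoint
#' joining its two end labels.  Every node carries exactly one segment edge
#' and at most one breakpoint edge; a breakpoint set violating the latter
#' (two junctions sharing an end label, or a fold-back junction pairing a
#' label with itself) is rejected with a conflict error naming the node.
#'
#' @param bp An [breakpoints()] table.
#' @param L Chromosome length (must exceed all breakpoint positions).
#' @return An object of class `sv_bpgraph`: the graph `partition`, the
#'   breakpoint `edges` (two-column matrix of node codes), per-node
#'   breakpoint partners, and the node count.
#' @examples
#' tbl1 <- breakpoints(c(10, 30, 20, 60, 70), c("tail", "tail", "head", "head", "head"),
#'                     c(40, 50, 70, 80, 90), c("head", "tail", "tail", "tail", "head"))
#' g <- build_graph(tbl1, L = 100)
#' g
#' @export
build_graph <- function(bp, L = attr(bp, "L")) {
  stopifnot(inherits(bp, "sv_breakpoints"))
  partition <- partition_from_breakpoints(bp, L)
  n <- partition$n
  edges <- if (nrow(bp)) breakpoint_codes(bp, partition) else
    matrix(integer(), ncol = 2L)
  use <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = 2L * n)
  if (any(use > 1L)) {
    v <- which(use > 1L)[1] - 1L
    stop(sprintf(
      "node (%s,%s) carries more than one breakpoint edge",
      format(code_position(v, partition), scientific = FALSE),
      substr(code_terminus(v), 1, 1)))
  }
  partner <- rep(NA_integer_, 2L * n)
  if (nrow(edges)) {
    partner[edges[, 1] + 1L] <- edges[, 2]
    partner[edges[, 2] + 1L] <- edges[, 1]
  }
  structure(list(partition = partition, n = n, edges = edges,
                 bp_partner = partner),
            class = "sv_bpgraph")
}

#' @export
print.sv_bpgraph <- function(x, ...) {
  cat(sprintf(
    "<sv_bpgraph> %d nodes, %d segment edges, %d breakpoint edges\n",
    2L * x$n, x$n, nrow(x$edges)))
  invisible(x)
}

node_label <- function(code, partition) {
  paste0(format(code_position(code, partition), scientific = FALSE), ":",
         substr(code_terminus(code), 1, 1))
}

#' Classify the connected components of a breakpoint graph
#'
#' Since every node has one segment edge and at most one breakpoint edge,
#' each component is one of: a *path* alternating segment and breakpoint
#' edges with two free termini (a stretch of the derivative chromosome); an
#' *isolated segment* -- two nodes, one segment edge, no breakpoint edges --
#' read as a deleted segment; or a *cycle*, which represents duplicated
#' material.
#'
#' @param graph An [build_graph()] object.
#' @return List of components, each a list with `kind` (`"path"`,
#'   `"isolated_segment"` or `"cycle"`), `nodes` (codes in traversal order),
#'   `segments` (reference segment ids touched) and, for paths, `termini`.
#' @export
classify_components <- function(graph) {
  stopifnot(inherits(graph, "sv_bpgraph"))
  n2 <- 2L * graph$n
  partner <- graph$bp_partner
  visited <- logical(n2)
  comps <- list()

  walk <- function(v0) {
    ## alternate segment edge, breakpoint edge starting at free terminus v0
    nodes <- integer()
    v <- v0
    repeat {
      nodes <- c(nodes, v)
      visited[v + 1L] <<- TRUE
      s <- bitwXor(v, 1L)           # segment-edge partner
      nodes <- c(nodes, s)
      visited[s + 1L] <<- TRUE
      nxt <- partner[s + 1L]
      if (is.na(nxt) || visited[nxt + 1L]) return(nodes)
      v <- nxt
    }
  }

  ## paths start at nodes without a breakpoint edge
  for (v in which(is.na(partner)) - 1L) {
    if (visited[v + 1L]) next
    nodes <- walk(v)
    kind <- if (length(nodes) == 2L) "isolated_segment" else "path"
    comps[[length(comps) + 1L]] <- list(
      kind = kind, nodes = nodes,
      segments = sort(unique(code_segment(nodes))),
      termini = c(nodes[1], nodes[length(nodes)]))
  }
  ## everything left is in cycles
  for (v in which(!visited) - 1L) {
    if (visited[v + 1L]) next
    nodes <- walk(v)
    comps[[length(comps) + 1L]] <- list(
      kind = "cycle", nodes = nodes,
      segments = sort(unique(code_segment(nodes))), termini = NULL)
  }
  comps
}

#' Chain partial paths into one start-to-end traversal
#'
#' When the observed breakpoint set is incomplete the graph decomposes into
#' several path components.  Chaining starts from the component containing
#' the chromosome start node `(1, h)`, repeatedly joins a randomly selected
#' remaining breakpoint-bearing path by adding a new breakpoint edge between
#' free termini, and finishes with the component containing the end node
#' `(L, t)`.  Added edges are new (unobserved) breakpoints and are reported.
#' Cycle components are not consumed -- they are returned for duplication
#' handling -- and isolated segments other than the start/end components are
#' left out as deletions.
#'
#' @param graph An [build_graph()] object.
#' @param seed Integer seed for the random join order.
#' @return An object of class `sv_chain`: `nodes` (the full path, node
#'   codes), `added` (two-column matrix of added breakpoint edges),
#'   `added_breakpoints` (as an [breakpoints()] table), and the component
#'   classification in `components`.
#' @export
chain_paths <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "sv_bpgraph"))
  comps <- classify_components(graph)
  start_node <- 0L
  end_node <- 2L * graph$n - 1L
  if (!is.na(graph$bp_partner[start_node + 1L]) ||
      !is.na(graph$bp_partner[end_node + 1L]))
    stop(paste("a breakpoint uses a chromosome-end label; the derivative",
               "does not retain both reference telomeres, which single-path",
               "chaining requires"))
  i_start <- which(vapply(comps, function(cp) start_node %in% cp$nodes, TRUE))
  i_end <- which(vapply(comps, function(cp) end_node %in% cp$nodes, TRUE))
  stopifnot(length(i_start) == 1L, length(i_end) == 1L)
  pool <- setdiff(which(vapply(comps, function(cp) cp$kind == "path", TRUE)),
                  c(i_start, i_end))

  orient_from <- function(nodes, first) if (nodes[1] == first) nodes else rev(nodes)

  ## if the start and end nodes already share one component, remaining path
  ## components cannot be spliced into the walk; they represent extra copies
  ## (like cycles) and are returned unconsumed for duplication handling
  leftover <- integer()
  if (i_start == i_end && length(pool) > 0L) {
    leftover <- pool
    pool <- integer()
  }

  with_seed(seed, {
    chain <- orient_from(comps[[i_start]]$nodes, start_node)
    added <- matrix(integer(), ncol = 2L)
    while (length(pool) > 0L) {
      j <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
      pool <- pool[pool != j]
      nodes <- comps[[j]]$nodes
      enter <- if (stats::runif(1) < 0.5) nodes[1] else nodes[length(nodes)]
      added <- rbind(added, c(chain[length(chain)], enter))
      chain <- c(chain, orient_from(nodes, enter))
    }
    if (i_end != i_start) {
      nodes <- comps[[i_end]]$nodes
      ## the end component is entered at its non-end terminus
      tail_nodes <- rev(orient_from(nodes, end_node))  # ends at end_node
      added <- rbind(added, c(chain[length(chain)], tail_nodes[1]))
      chain <- c(chain, tail_nodes)
    }
    stopifnot(chain[length(chain)] == end_node)
    added_bp <- if (nrow(added))
      codes_to_breakpoints(added[, 1], added[, 2], graph$partition) else
      breakpoints(numeric(), character(), numeric(), character())
    structure(list(nodes = chain, added = added,
                   added_breakpoints = added_bp, components = comps,
                   leftover = leftover, graph = graph),
              class = "sv_chain")
  })
}

#' @export
print.sv_chain <- function(x, ...) {
  cat(sprintf("<sv_chain> %d-node path, %d added breakpoint edge%s\n",
              length(x$nodes), nrow(x$added),
              if (nrow(x$added) == 1L) "" else "s"))
  invisible(x)
}

#' Read a chained path out as a signed permutation
#'
#' Traverses the full start-to-end path: entering a segment edge at the
#' segment's head yields `+id`, at its tail `-id`.  The result is the
#' derivative chromosome implied by the path, as signed graph-segment ids.
#'
#' @param chain An [chain_paths()] result (or any alternating node sequence
#'   beginning at `(1, h)` and ending at `(L, t)`).
#' @return Integer vector of signed segment ids.
#' @examples
#' tbl1 <- breakpoints(c(10, 30, 20, 60, 70), c("tail", "tail", "head", "head", "head"),
#'                     c(40, 50, 70, 80, 90), c("head", "tail", "tail", "tail", "head"))
#' path_to_signed_permutation(chain_paths(build_graph(tbl1, L = 100)))
#' @export
path_to_signed_permutation <- function(chain) {
  nodes <- if (inherits(chain, "sv_chain")) chain$nodes else chain
  if (length(nodes) %% 2L != 0L)
    stop("path does not alternate segment and breakpoint edges")
  enter <- nodes[seq(1L, length(nodes), by = 2L)]
  leave <- nodes[seq(2L, length(nodes), by = 2L)]
  if (any(bitwXor(enter, 1L) != leave))
    stop("path does not alternate segment and breakpoint edges")
  ifelse(enter %% 2L == 0L, code_segment(enter), -code_segment(enter))
}

#' Convert a breakpoint graph to an igraph object
#'
#' Nodes are named `"position:h"` / `"position:t"`; edges carry a `type`
#' attribute (`"segment"` or `"breakpoint"`), plus any `added` chaining
#' edges when a chain is supplied.
#'
#' @param graph An [build_graph()] object.
#' @param chain Optional [chain_paths()] result whose added edges are
#'   included with `type = "added"`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph, chain = NULL) {
  stopifnot(inherits(graph, "sv_bpgraph"))
  part <- graph$partition
  labels <- node_label(0:(2L * graph$n - 1L), part)
  seg_edges <- cbind(seq(0L, 2L * graph$n - 2L, by = 2L),
                     seq(1L, 2L * graph$n - 1L, by = 2L))
  el <- rbind(seg_edges, graph$edges)
  type <- c(rep("segment", nrow(seg_edges)),
            rep("breakpoint", nrow(graph$edges)))
  if (!is.null(chain) && nrow(chain$added)) {
    el <- rbind(el, chain$added)
    type <- c(type, rep("added", nrow(chain$added)))
  }
  g <- igraph::graph_from_edgelist(
    cbind(labels[el[, 1] + 1L], labels[el[, 2] + 1L]), directed = FALSE)
  igraph::E(g)$type <- type
  g
}

#' Export a breakpoint graph to DOT or JSON
#'
#' @param graph An [build_graph()] object.
#' @param path Output file path.
#' @param format `"dot"` (via igraph) or `"json"` (nodes plus typed edges).
#' @param chain Optional [chain_paths()] result to include added edges.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("dot", "json"),
                         chain = NULL) {
  format <- match.arg(format)
  if (format == "dot") {
    igraph::write_graph(as_igraph(graph, chain), path, format = "dot")
  } else {
    part <- graph$partition
    nodes <- node_label(0:(2L * graph$n - 1L), part)
    seg_edges <- cbind(seq(0L, 2L * graph$n - 2L, by = 2L),
                       seq(1L, 2L * graph$n - 1L, by = 2L))
    obj <- list(
      nodes = nodes,
      edges = c(
        lapply(seq_len(nrow(seg_edges)), function(i)
          list(from = nodes[seg_edges[i, 1] + 1L],
               to = nodes[seg_edges[i, 2] + 1L], type = "segment")),
        lapply(seq_len(nrow(graph$edges)), function(i)
          list(from = nodes[graph$edges[i, 1] + 1L],
               to = nodes[graph$edges[i, 2] + 1L], type = "breakpoint")),
        if (!is.null(chain) && nrow(chain$added))
          lapply(seq_len(nrow(chain$added)), function(i)
            list(from = nodes[chain$added[i, 1] + 1L],
                 to = nodes[chain$added[i, 2] + 1L], type = "added"))
      )
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
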