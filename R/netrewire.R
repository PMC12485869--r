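#' Construct a condition network
#'
#' A signed, directed interaction network for one ligand condition, stored
#' as unique (source, relation, target) edge triples, as emitted by causal
#' network inference in SIF form.
#'
#' @param edges data.frame with columns `source`, `relation`, `target`.
#' @param condition condition label.
#' @return object of class `condition_network`.
#' @export
condition_network <- function(edges, condition = NA_character_) {
  stopifnot(is.data.frame(edges),
            all(c("source", "relation", "target") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      relation = as.character(edges$relation),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  key <- paste(edges$source, edges$relation, edges$target, sep = "\t")
  if (anyDuplicated(key)) stop("duplicate edge triples in condition_network")
  structure(list(condition = condition, edges = edges,
                 nodes = sort(unique(c(edges$source, edges$target)))),
            class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("<condition_network> '%s': %d nodes, %d edges\n",
              x$condition, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a SIF edge list
#'
#' Parses whitespace/tab-delimited `source relation target` lines. Blank and
#' '#'-comment lines are skipped; duplicate triples are collapsed with a log
#' entry; a line without exactly three tokens is an error naming the line.
#'
#' @param path file path.
#' @param condition condition label attached to the network.
#' @return a [condition_network()]; attribute `"log"` records collapsed
#'   duplicates.
#' @export
read_sif <- function(path, condition = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed SIF line %d (expected 3 tokens, got %d): '%s'",
                 keep[bad[1L]], lengths(toks)[bad[1L]], lines[keep[bad[1L]]]))
  }
  m <- do.call(rbind, toks)
  edges <- data.frame(source = m[, 1], relation = m[, 2], target = m[, 3],
                      stringsAsFactors = FALSE)
  key <- paste(edges$source, edges$relation, edges$target, sep = "\t")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    message(n_dup, " duplicate edge line(s) collapsed in ", path)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  net <- condition_network(edges, condition = condition)
  attr(net, "log") <- list(n_lines = length(keep), n_duplicates_collapsed = n_dup)
  net
}

#' Write a condition network as a SIF edge list
#' @param network a [condition_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "condition_network"))
  writeLines(paste(network$edges$source, network$edges$relation,
                   network$edges$target, sep = "\t"), path)
  invisible(path)
}

# incident edge triples of a node, as strings (orientation and relation
# are part of edge identity: flipping a relation costs 2 edits)
.incident_set <- function(net, node) {
  e <- net$edges
  hit <- e$source == node | e$target == node
  paste(e$source[hit], e$relation[hit], e$target[hit], sep = "\t")
}

#' Per-node rewiring score between two condition networks
#'
#' The rewiring score of a node is the number of incident edges that would
#' need to be added or removed to turn its connectivity in one network into
#' its connectivity in the other: the size of the symmetric difference of
#' its incident-edge sets (edge identity includes relation label and
#' orientation). Also returns the union degree and the normalized score
#' raw/union (0 when the union is empty).
#'
#' @param net_a,net_b [condition_network()]s.
#' @param node node symbol; must be present in at least one network.
#' @return list: `node`, `raw_rewiring`, `degree_union`,
#'   `normalized_rewiring`.
#' @export
rewiring_score <- function(net_a, net_b, node) {
  stopifnot(inherits(net_a, "condition_network"),
            inherits(net_b, "condition_network"))
  if (!(node %in% net_a$nodes) && !(node %in% net_b$nodes)) {
    stop("node '", node, "' absent from both networks")
  }
  sa <- .incident_set(net_a, node)
  sb <- .incident_set(net_b, node)
  raw <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  uni <- length(union(sa, sb))
  list(node = node, raw_rewiring = raw, degree_union = uni,
       normalized_rewiring = if (uni == 0L) 0 else raw / uni)
}

#' Integrate multi-assay molecular features
#'
#' Resolves transcript/protein duplicates in favor of the proteomic record,
#' then keeps only features whose log-fold change passes the threshold
#' (`lfc >= 1` by default, on the signed LFC as provided; set
#' `use_absolute = TRUE` to threshold |LFC| and retain strong
#' downregulation).
#'
#' @param features data.frame with `node`, `assay` (`"transcript"` or
#'   `"protein"`), `lfc`, and optionally `condition`.
#' @param lfc_threshold minimum LFC (default 1).
#' @param use_absolute threshold `abs(lfc)` instead of signed `lfc`.
#' @return filtered data.frame, one row per retained node.
#' @export
integrate_features <- function(features, lfc_threshold = 1,
                               use_absolute = FALSE) {
  stopifnot(all(c("node", "assay", "lfc") %in% names(features)))
  if (nrow(features) == 0L) return(features)
  if (!all(features$assay %in% c("transcript", "protein"))) {
    stop("assay must be 'transcript' or 'protein'")
  }
  if (any(!is.finite(features$lfc))) stop("non-finite lfc")
  cond <- if ("condition" %in% names(features)) features$condition
          else rep("", nrow(features))
  key <- paste(features$node, features$assay, cond, sep = "\r")
  if (anyDuplicated(key)) {
    d <- features[duplicated(key), , drop = FALSE][1L, ]
    stop("conflicting duplicate records within one assay for node '",
         d$node, "'")
  }
  # proteomic precedence: order protein first, keep the first per node
  ord <- order(features$node, cond, features$assay != "protein")
  features <- features[ord, , drop = FALSE]
  keep_key <- paste(features$node, cond[ord], sep = "\r")
  features <- features[!duplicated(keep_key), , drop = FALSE]
  pass <- if (use_absolute) abs(features$lfc) >= lfc_threshold
          else features$lfc >= lfc_threshold
  out <- features[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LFC-weighted rewiring ranking over all nodes
#'
#' Scores every node of either network with [rewiring_score()], then weights
#' the raw rewiring count by the node's log-fold change under the treated
#' condition: `weighted_score = raw_rewiring * max(lfc, 0)` by default,
#' prioritizing nodes both highly rewired and upregulated. Alternative
#' weightings: `"signed"` (`raw * lfc`) and `"normalized"`
#' (`normalized_rewiring * max(lfc, 0)`). Nodes without an LFC record get
#' LFC 0 (logged). Ties break by raw rewiring, then node name.
#'
#' @param net_a,net_b [condition_network()]s.
#' @param features data.frame with `node`, `lfc` (e.g. the OSM-condition
#'   output of [integrate_features()]).
#' @param weighting `"positive"`, `"signed"` or `"normalized"`.
#' @return data.frame sorted by `weighted_score` descending: `node`,
#'   `raw_rewiring`, `degree_union`, `normalized_rewiring`, `lfc`,
#'   `weighted_score`, `rank`; attribute `"log"` lists nodes with no LFC.
#' @export
weighted_rewiring <- function(net_a, net_b, features,
                              weighting = c("positive", "signed", "normalized")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("node", "lfc") %in% names(features)))
  nodes <- sort(union(net_a$nodes, net_b$nodes))
  scores <- lapply(nodes, function(nd) {
    as.data.frame(rewiring_score(net_a, net_b, nd), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, scores)
  lfc <- features$lfc[match(tab$node, features$node)]
  no_lfc <- tab$node[is.na(lfc)]
  lfc[is.na(lfc)] <- 0
  tab$lfc <- lfc
  tab$weighted_score <- switch(weighting,
    positive = tab$raw_rewiring * pmax(lfc, 0),
    signed = tab$raw_rewiring * lfc,
    normalized = tab$normalized_rewiring * pmax(lfc, 0))
  ord <- order(-tab$weighted_score, -tab$raw_rewiring, tab$node)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "log") <- list(nodes_without_lfc = no_lfc, weighting = weighting)
  tab
}

#' Nominate the top-ranked candidate regulators
#'
#' Returns the first `n` nodes of a ranked rewiring table under its
#' deterministic (score, raw rewiring, name) ordering; defaults to the
#' 14-node shortlist size used for experimental validation.
#'
#' @param ranked output of [weighted_rewiring()].
#' @param n number of nodes (default 14).
#' @return character vector of node symbols.
#' @export
nominate_top_nodes <- function(ranked, n = 14L) {
  stopifnot(is.data.frame(ranked), "node" %in% names(ranked), n >= 1)
  if (n > nrow(ranked)) {
    warning("requested ", n, " nodes but table has ", nrow(ranked),
            "; returning all")
    n <- nrow(ranked)
  }
  ranked$node[seq_len(n)]
}
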