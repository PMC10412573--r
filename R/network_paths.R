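# Directed signalling networks and Yen's K-shortest loopless paths, used
# to connect biomarker genes to drug targets.

#' Construct a signalling network from an edge list
#'
#' Self-loops are dropped (with a warning) and duplicate edges collapsed
#' keeping the minimum weight. Edges without a weight column default to
#' weight 1 (hop-count metric).
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `weight`.
#' @returns A tibble edge list of class `signaling_network`.
#' @export
as_signaling_network <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = min(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  structure(edges, class = c("signaling_network", class(tibble())))
}

#' Read a signalling network edge list from TSV
#'
#' @param path TSV with `from` and `to` (optionally `weight`) columns.
#' @returns A `signaling_network` (see [as_signaling_network()]).
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("network TSV needs 'from' and 'to' columns")
  }
  bad <- which(is.na(edges$from) | is.na(edges$to))
  if (length(bad) > 0) {
    abort(sprintf("malformed network row at line %d", bad[1] + 1L))
  }
  as_signaling_network(edges)
}

network_nodes <- function(network) sort(unique(c(network$from, network$to)))

# adjacency list: for each node, a tibble of (to, weight) sorted by node
# name, so traversal order is deterministic
adjacency_list <- function(network) {
  split(network[c("to", "weight")], network$from)
}

# lexicographic comparison of node sequences; TRUE if a < b
lex_lt <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# best (min total weight, then lexicographically smallest) simple path via
# branch-and-bound DFS; blocked edges given as "from->to" keys
best_path <- function(adj, source, target, blocked_edges = character(0),
                      blocked_nodes = character(0)) {
  best <- NULL
  best_w <- Inf
  walk <- function(node, path, w) {
    if (node == target) {
      if (w < best_w || (w == best_w && lex_lt(path, best))) {
        best <<- path
        best_w <<- w
      }
      return(invisible())
    }
    nbrs <- adj[[node]]
    if (is.null(nbrs)) return(invisible())
    for (k in seq_len(nrow(nbrs))) {
      nxt <- nbrs$to[k]
      ew <- nbrs$weight[k]
      if (nxt %in% path || nxt %in% blocked_nodes) next
      if (paste0(node, "->", nxt) %in% blocked_edges) next
      if (w + ew > best_w) next
      walk(nxt, c(path, nxt), w + ew)
    }
    invisible()
  }
  if (source %in% blocked_nodes) return(NULL)
  walk(source, source, 0)
  if (is.null(best)) NULL else list(nodes = best, weight = best_w)
}

#' K-shortest loopless directed paths (Yen's algorithm)
#'
#' Returns up to `K` simple paths from `source` to `target` in
#' non-decreasing total weight (hop count for unweighted networks), with
#' deterministic lexicographic tie-breaking of equal-weight paths.
#'
#' @param network a `signaling_network`.
#' @param source,target node names (must be present in the network).
#' @param K maximum number of paths (default 10).
#' @returns Tibble with `rank`, `nodes` (list-column of node sequences),
#'   `weight` and `hops`; zero rows when no path exists. `source ==
#'   target` yields the single zero-length path.
#' @export
yen_k_shortest <- function(network, source, target, K = 10) {
  nodes <- network_nodes(network)
  if (!source %in% nodes || !target %in% nodes) {
    abort("source and target must be nodes of the network")
  }
  empty <- tibble(rank = integer(0), nodes = list(), weight = numeric(0),
                  hops = integer(0))
  path_tbl <- function(paths) {
    if (length(paths) == 0) return(empty)
    tibble(rank = seq_along(paths),
           nodes = lapply(paths, `[[`, "nodes"),
           weight = vapply(paths, `[[`, numeric(1), "weight"),
           hops = vapply(paths, function(p) length(p$nodes) - 1L,
                         integer(1)))
  }
  if (source == target) {
    return(path_tbl(list(list(nodes = source, weight = 0))))
  }
  adj <- adjacency_list(network)
  first <- best_path(adj, source, target)
  if (is.null(first)) return(empty)
  A <- list(first)
  B <- list()
  path_key <- function(p) paste(p$nodes, collapse = "\r")
  seen <- path_key(first)
  while (length(A) < K) {
    prev <- A[[length(A)]]$nodes
    for (si in seq_len(length(prev) - 1)) {
      spur <- prev[si]
      root <- prev[seq_len(si)]
      blocked_edges <- character(0)
      for (p in A) {
        pn <- p$nodes
        if (length(pn) > si && identical(pn[seq_len(si)], root)) {
          blocked_edges <- c(blocked_edges,
                             paste0(pn[si], "->", pn[si + 1]))
        }
      }
      blocked_nodes <- root[-length(root)]
      sp <- best_path(adj, spur, target, blocked_edges, blocked_nodes)
      if (is.null(sp)) next
      root_w <- 0
      if (si > 1) {
        for (e in seq_len(si - 1)) {
          nb <- adj[[prev[e]]]
          root_w <- root_w + nb$weight[match(prev[e + 1], nb$to)]
        }
      }
      cand <- list(nodes = c(root[-length(root)], sp$nodes),
                   weight = root_w + sp$weight)
      key <- path_key(cand)
      if (!key %in% seen) {
        B[[length(B) + 1]] <- cand
        seen <- c(seen, key)
      }
    }
    if (length(B) == 0) break
    ws <- vapply(B, `[[`, numeric(1), "weight")
    best_i <- which(ws == min(ws))
    if (length(best_i) > 1) {
      pick <- best_i[1]
      for (i in best_i[-1]) {
        if (lex_lt(B[[i]]$nodes, B[[pick]]$nodes)) pick <- i
      }
      best_i <- pick
    }
    A[[length(A) + 1]] <- B[[best_i]]
    B <- B[-best_i]
  }
  path_tbl(A)
}

#' Connect a biomarker gene to drug targets on the network
#'
#' Searches forward paths from the biomarker gene to each drug target; if
#' no forward path exists for a target, paths from the target back to the
#' gene are used instead (reverse direction). The biomarker is flagged
#' network-supported when any path is found for any target.
#'
#' @param network a `signaling_network`.
#' @param biomarker_gene source gene symbol.
#' @param drug_targets character vector of target symbols.
#' @param K paths per target (default 10).
#' @returns Object of class `network_evidence`: list with `per_target`
#'   (tibble: `target`, `direction`, `n_paths`, `shortest_hops`, `paths`
#'   list-column), `supported`, `reason`, and `subnetwork` (edge tibble of
#'   all traversed edges).
#' @export
connect_biomarker_to_targets <- function(network, biomarker_gene,
                                         drug_targets, K = 10) {
  nodes <- network_nodes(network)
  per_target <- list()
  if (!biomarker_gene %in% nodes) {
    return(structure(
      list(per_target = tibble(target = drug_targets, direction = NA_character_,
                               n_paths = 0L, shortest_hops = NA_integer_,
                               paths = replicate(length(drug_targets),
                                                 list(), simplify = FALSE)),
           supported = FALSE, reason = "node_missing",
           subnetwork = network[0, ]),
      class = "network_evidence"))
  }
  for (tg in drug_targets) {
    if (!tg %in% nodes) {
      per_target[[tg]] <- tibble(target = tg, direction = NA_character_,
                                 n_paths = 0L, shortest_hops = NA_integer_,
                                 paths = list(list()))
      next
    }
    fwd <- yen_k_shortest(network, biomarker_gene, tg, K = K)
    if (nrow(fwd) > 0) {
      per_target[[tg]] <- tibble(target = tg, direction = "forward",
                                 n_paths = nrow(fwd),
                                 shortest_hops = min(fwd$hops),
                                 paths = list(fwd$nodes))
    } else {
      rev <- yen_k_shortest(network, tg, biomarker_gene, K = K)
      if (nrow(rev) > 0) {
        per_target[[tg]] <- tibble(target = tg, direction = "reverse",
                                   n_paths = nrow(rev),
                                   shortest_hops = min(rev$hops),
                                   paths = list(rev$nodes))
      } else {
        per_target[[tg]] <- tibble(target = tg, direction = NA_character_,
                                   n_paths = 0L,
                                   shortest_hops = NA_integer_,
                                   paths = list(list()))
      }
    }
  }
  per_target <- dplyr::bind_rows(per_target)
  traversed <- unique(unlist(lapply(per_target$paths, unlist)))
  sub <- network[network$from %in% traversed & network$to %in% traversed, ,
                 drop = FALSE]
  supported <- any(per_target$n_paths > 0)
  structure(list(per_target = per_target, supported = supported,
                 reason = if (supported) "path_found" else "no_path",
                 subnetwork = sub),
            class = "network_evidence")
}

#' @export
print.network_evidence <- function(x, ...) {
  cat(sprintf("<network_evidence> supported: %s (%s)\n",
              x$supported, x$reason))
  invisible(x)
}

#' Write a network evidence report
#'
#' Writes a JSON report of the per-target paths plus a SIF-style TSV of
#' the traversed subnetwork. Output is deterministic.
#'
#' @param evidence a `network_evidence` object.
#' @param json_path output JSON path.
#' @param sif_path output TSV path (`from`, `interaction`, `to`).
#' @returns Invisibly, a list with both paths.
#' @export
write_network_report <- function(evidence, json_path, sif_path) {
  report <- list(
    supported = evidence$supported,
    reason = evidence$reason,
    targets = lapply(seq_len(nrow(evidence$per_target)), function(i) {
      list(target = evidence$per_target$target[i],
           direction = evidence$per_target$direction[i],
           n_paths = evidence$per_target$n_paths[i],
           shortest_hops = evidence$per_target$shortest_hops[i],
           paths = lapply(evidence$per_target$paths[[i]], as.character))
    }))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  sif <- tibble(from = evidence$subnetwork$from, interaction = "directed",
                to = evidence$subnetwork$to)
  readr::write_tsv(sif, sif_path, progress = FALSE)
  invisible(list(json = json_path, sif = sif_path))
}
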