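# Core regulatory circuitry construction: TF->TF motif-support graph,
# the strict autoregulation rule, exhaustive enumeration of fully
# interconnected circuitries and occurrence-frequency scoring.

#' Build the TF->TF regulatory graph from motif-hit counts
#'
#' Nodes are the SE-associated TFs; the directed edge a -> b exists iff the
#' count of TF a's motif in TF b's extended super-enhancer regions is at
#' least `edge_min`. Self-pairs carry the autoregulation evidence.
#'
#' @param hit_counts Data.frame with `source_tf`, `target_tf`, `count`
#'   (see [count_hits()]); missing pairs count 0.
#' @param tfs Character vector of SE-associated TFs (the node set).
#' @param edge_min Minimum count for an edge.
#' @return An object of class `"regulatory_graph"`: list with `tfs`,
#'   `counts` (square matrix, rows = source) and `edge_min`.
#' @export
build_graph <- function(hit_counts, tfs, edge_min = 1L) {
  tfs <- sort(unique(as.character(tfs)))
  counts <- matrix(0L, nrow = length(tfs), ncol = length(tfs),
                   dimnames = list(tfs, tfs))
  if (nrow(hit_counts)) {
    keep <- hit_counts$source_tf %in% tfs & hit_counts$target_tf %in% tfs
    hc <- hit_counts[keep, , drop = FALSE]
    counts[cbind(hc$source_tf, hc$target_tf)] <- as.integer(hc$count)
  }
  structure(list(tfs = tfs, counts = counts, edge_min = as.integer(edge_min)),
            class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  n_edge <- sum(x$counts >= x$edge_min) - sum(diag(x$counts) >= x$edge_min)
  cat(sprintf("Regulatory graph: %d TFs, %d directed edges (edge_min %d)\n",
              length(x$tfs), n_edge, x$edge_min))
  invisible(x)
}

#' Autoregulated TFs of a regulatory graph
#'
#' A TF is autoregulated when its own-motif hit count in its extended
#' super-enhancer regions is strictly greater than `self_threshold`
#' ("more than two binding motifs" with the default of 2).
#'
#' @param graph A `"regulatory_graph"`.
#' @param self_threshold Strict lower bound on the self count.
#' @return Sorted character vector of autoregulated TF symbols.
#' @export
autoregulated_tfs <- function(graph, self_threshold = 2) {
  graph$tfs[diag(graph$counts) > self_threshold]
}

empty_circuitries <- function() {
  data.frame(members = I(list()), key = character(0), size = integer(0),
             is_maximal = logical(0))
}

#' Enumerate all fully interconnected circuitries
#'
#' A circuitry is a set of autoregulated TFs in which every ordered pair is
#' a graph edge (full interconnection). ALL such subsets within the size
#' bounds are emitted — the downward-closed universe over which occurrence
#' frequencies are counted — with maximal ones flagged. Enumeration runs as
#' clique search on the symmetrised graph (undirected edge iff both
#' directions present) and equals brute-force power-set filtering.
#'
#' @param graph A `"regulatory_graph"`.
#' @param min_size Smallest circuitry size (>= 2).
#' @param max_size Largest size, or `NULL` for unbounded.
#' @param self_threshold Passed to [autoregulated_tfs()].
#' @param node_limit Without `max_size`, more autoregulated nodes than this
#'   is an error (the universe grows exponentially).
#' @return A data.frame with columns `members` (list of sorted symbol
#'   vectors), `key` (comma-joined members), `size`, `is_maximal`.
#' @export
enumerate_circuitries <- function(graph, min_size = 2L, max_size = NULL,
                                  self_threshold = 2, node_limit = 25L) {
  stopifnot(min_size >= 2)
  auto <- autoregulated_tfs(graph, self_threshold)
  if (length(auto) < min_size) return(empty_circuitries())
  if (length(auto) > node_limit && is.null(max_size)) {
    stop(sprintf(paste0("%d autoregulated TFs: the circuitry universe is ",
                        "exponential; set max_size"), length(auto)),
         call. = FALSE)
  }
  cm <- graph$counts[auto, auto, drop = FALSE]
  und <- cm >= graph$edge_min & t(cm) >= graph$edge_min
  diag(und) <- FALSE
  ig <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  cl <- igraph::cliques(ig, min = min_size,
                        max = if (is.null(max_size)) 0 else max_size)
  if (!length(cl)) return(empty_circuitries())
  members <- lapply(cl, function(v) sort(auto[as.integer(v)]))
  key <- vapply(members, paste, character(1), collapse = ",")
  mx <- igraph::max_cliques(ig, min = min_size)
  mx_key <- vapply(mx, function(v) paste(sort(auto[as.integer(v)]),
                                         collapse = ","), character(1))
  size <- lengths(members)
  ord <- order(size, key)
  data.frame(members = I(members[ord]), key = key[ord],
             size = as.integer(size[ord]),
             is_maximal = key[ord] %in% mx_key)
}

#' Score circuitries by occurrence frequency
#'
#' Over the enumerated universe, `occ(t)` is the number of circuitries
#' containing TF `t`; a circuitry's score is the sum of its members'
#' occurrences divided by its size. Ranking is by score descending, ties
#' by size descending, then by member order alphabetically. With
#' `maximal_only = TRUE` both counting and scoring are restricted to
#' maximal circuitries.
#'
#' @param circuitries Data.frame from [enumerate_circuitries()].
#' @param maximal_only Count occurrences over maximal circuitries only.
#' @return The (possibly restricted) data.frame with `score` and `rank`
#'   columns, ordered by rank; TF occurrences are attached as the
#'   `"occurrence"` attribute.
#' @export
score_circuitries <- function(circuitries, maximal_only = FALSE) {
  if (maximal_only) {
    circuitries <- circuitries[circuitries$is_maximal, , drop = FALSE]
  }
  if (!nrow(circuitries)) {
    out <- circuitries
    out$score <- numeric(0)
    out$rank <- integer(0)
    attr(out, "occurrence") <- integer(0)
    return(out)
  }
  occ <- table(unlist(circuitries$members))
  score <- vapply(circuitries$members,
                  function(m) sum(occ[m]) / length(m), numeric(1))
  ord <- order(-score, -circuitries$size, circuitries$key)
  out <- circuitries[ord, , drop = FALSE]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  occ_v <- as.integer(occ)
  names(occ_v) <- names(occ)
  attr(out, "occurrence") <- occ_v
  out
}

#' Top-ranked circuitry members
#' @param scored Scored circuitries from [score_circuitries()].
#' @param maximal_only Return the best-ranked maximal circuitry instead of
#'   the overall best.
#' @return Character vector of member symbols (empty if none).
#' @export
top_circuitry <- function(scored, maximal_only = FALSE) {
  if (maximal_only) scored <- scored[scored$is_maximal, , drop = FALSE]
  if (!nrow(scored)) return(character(0))
  scored$members[[1]]
}

#' Write circuitry and edge reports
#'
#' `circuitries.tsv` lists the ranked circuitries (members comma-joined,
#' size, score, maximal flag); `edges.tsv` lists every ordered TF pair with
#' a positive count and whether it passes `edge_min`. Deterministic for
#' identical inputs. Optionally draws the top circuitry as a graph.
#'
#' @param graph A `"regulatory_graph"`.
#' @param scored Scored circuitries from [score_circuitries()].
#' @param dir Output directory (created if needed).
#' @param plot_top Also write `top_circuitry.pdf`.
#' @return Invisibly, the paths written.
#' @export
report_crc <- function(graph, scored, dir, plot_top = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "circuitries.tsv")
  cdf <- data.frame(rank = scored$rank, members = scored$key,
                    size = scored$size,
                    score = if (nrow(scored)) fmt_num(scored$score, 6)
                            else character(0),
                    is_maximal = scored$is_maximal)
  utils::write.table(cdf, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  epath <- file.path(dir, "edges.tsv")
  idx <- which(graph$counts > 0, arr.ind = TRUE)
  edf <- data.frame(source_tf = rownames(graph$counts)[idx[, 1]],
                    target_tf = colnames(graph$counts)[idx[, 2]],
                    count = graph$counts[idx],
                    is_edge = graph$counts[idx] >= graph$edge_min)
  edf <- edf[order(edf$source_tf, edf$target_tf), , drop = FALSE]
  utils::write.table(edf, epath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(cpath, epath)
  if (plot_top && nrow(scored)) {
    ppath <- file.path(dir, "top_circuitry.pdf")
    top <- top_circuitry(scored)
    sub <- graph$counts[top, top, drop = FALSE] >= graph$edge_min
    diag(sub) <- FALSE
    ig <- igraph::graph_from_adjacency_matrix(sub, mode = "directed")
    grDevices::pdf(ppath, width = 5, height = 5)
    igraph::plot.igraph(ig, vertex.size = 30, edge.arrow.size = 0.4,
                        vertex.color = "lightsteelblue")
    grDevices::dev.off()
    paths <- c(paths, ppath)
  }
  invisible(paths)
}
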