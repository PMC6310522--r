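# Word-adjacency-augmented parse graphs and shortest dependency paths.
#
# The parse graph is undirected: dependency edges have weight 1 and an
# artificial edge is added between every pair of linearly adjacent tokens
# with a configurable (heavier) weight, default 5. The adjacency edges
# guarantee connectivity even when the parser emits several components, and
# the weighting makes the search prefer genuine dependency edges.

#' Build the undirected weighted parse graph for one sentence
#'
#' @param n_tokens Number of tokens in the sentence.
#' @param heads Integer vector, \code{heads[t]} = dependency head of token t
#'   (0 for the root attachment, which emits no edge).
#' @param deplabels Dependency labels parallel to \code{heads}.
#' @param adjacency_weight Positive weight of word-adjacency edges
#'   (default 5; dependency edges always have weight 1).
#' @return A \code{cprex_graph}: node count plus an edge table with columns
#'   u, v, label, kind (dependency/adjacency), weight, head, dep.
#' @export
build_parse_graph <- function(n_tokens, heads, deplabels,
                              adjacency_weight = 5) {
  stopifnot(n_tokens >= 1, adjacency_weight > 0,
            length(heads) == length(deplabels))
  if (length(heads) > 0 &&
      (any(heads < 0) || any(heads > n_tokens) ||
       any(seq_along(heads) > n_tokens))) {
    stop("dependency edge references token outside 1..", n_tokens)
  }
  dep <- which(heads > 0)
  edges <- data.frame(
    u = heads[dep], v = dep, label = deplabels[dep],
    kind = rep("dependency", length(dep)),
    weight = rep(1, length(dep)),
    head = heads[dep], dep = dep,
    stringsAsFactors = FALSE
  )
  if (n_tokens > 1) {
    adj <- data.frame(
      u = seq_len(n_tokens - 1L), v = 2:n_tokens,
      label = "ADJ", kind = "adjacency",
      weight = adjacency_weight,
      head = NA_integer_, dep = NA_integer_,
      stringsAsFactors = FALSE
    )
    edges <- rbind(edges, adj)
  }
  structure(list(n = n_tokens, edges = edges), class = "cprex_graph")
}

#' Select the syntactic head token of an entity span
#'
#' The head is the unique token in the span whose dependency head lies
#' outside the span (or is the root). If no or several such tokens exist,
#' the last token of the span is used.
#'
#' @param tok_first,tok_last Inclusive token index range of the entity.
#' @param heads Sentence head vector (0 = root).
#' @return Token index of the entity head.
#' @export
select_entity_head <- function(tok_first, tok_last, heads) {
  span <- tok_first:tok_last
  outside <- span[heads[span] == 0 | !(heads[span] %in% span)]
  if (length(outside) == 1) outside else tok_last
}

# comparator: path a better than b under (weight, edge count, lexicographic
# token sequence)?
path_better <- function(wa, na, pa, wb, nb, pb) {
  if (wa != wb) return(wa < wb)
  if (na != nb) return(na < nb)
  l <- min(length(pa), length(pb))
  for (i in seq_len(l)) {
    if (pa[i] != pb[i]) return(pa[i] < pb[i])
  }
  length(pa) < length(pb)
}

#' Shortest dependency path between two tokens
#'
#' Dijkstra search over the undirected weighted parse graph with
#' deterministic tie-breaking: among equal-weight paths the one with fewer
#' edges wins, then the lexicographically smallest token-index sequence.
#' The path is always reported from the chemical head to the gene head,
#' regardless of surface order. When both entities share a head token the
#' result is the degenerate single-node path.
#'
#' @param graph A \code{cprex_graph}.
#' @param from,to Token indices (chemical head, gene head).
#' @return List with \code{token_path}, \code{total_weight} and
#'   \code{edge_rows} (row indices into \code{graph$edges} of the traversed
#'   edges, picking the cheaper edge where dependency and adjacency edges
#'   are parallel).
#' @export
sdp_search <- function(graph, from, to) {
  n <- graph$n
  stopifnot(from >= 1, from <= n, to >= 1, to <= n)
  if (from == to) {
    return(list(token_path = from, total_weight = 0, edge_rows = integer()))
  }
  # adjacency lists
  nbr <- vector("list", n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    nbr[[e$u[r]]] <- rbind(nbr[[e$u[r]]], c(e$v[r], e$weight[r], r))
    nbr[[e$v[r]]] <- rbind(nbr[[e$v[r]]], c(e$u[r], e$weight[r], r))
  }
  dist <- rep(Inf, n)
  nedge <- rep(Inf, n)
  paths <- vector("list", n)
  done <- rep(FALSE, n)
  dist[from] <- 0; nedge[from] <- 0; paths[[from]] <- from
  repeat {
    u <- 0L
    for (v in which(!done & is.finite(dist))) {
      if (u == 0L || path_better(dist[v], nedge[v], paths[[v]],
                                 dist[u], nedge[u], paths[[u]])) u <- v
    }
    if (u == 0L) break
    done[u] <- TRUE
    if (u == to) break
    if (!is.null(nbr[[u]])) {
      for (r in seq_len(nrow(nbr[[u]]))) {
        v <- nbr[[u]][r, 1]; w <- nbr[[u]][r, 2]
        if (done[v]) next
        cand_w <- dist[u] + w
        cand_n <- nedge[u] + 1
        cand_p <- c(paths[[u]], v)
        if (path_better(cand_w, cand_n, cand_p, dist[v], nedge[v],
                        if (is.null(paths[[v]])) integer() else paths[[v]])) {
          dist[v] <- cand_w; nedge[v] <- cand_n; paths[[v]] <- cand_p
        }
      }
    }
  }
  if (!is.finite(dist[to])) stop("no path between tokens ", from, " and ", to)
  tp <- paths[[to]]
  # recover traversed edges: for each consecutive pair the minimum-weight
  # edge, preferring dependency over adjacency on ties
  rows <- integer(length(tp) - 1L)
  for (i in seq_len(length(tp) - 1L)) {
    a <- tp[i]; b <- tp[i + 1L]
    cand <- which((e$u == a & e$v == b) | (e$u == b & e$v == a))
    cand <- cand[order(e$weight[cand], e$kind[cand] != "dependency")]
    rows[i] <- cand[1]
  }
  list(token_path = tp, total_weight = dist[to], edge_rows = rows)
}

#' Extract the word/POS/dependency-type sequences along a path
#'
#' Dependency labels carry a traversal-direction marker: \code{↑} when
#' the edge is traversed dependent-to-head, \code{↓} head-to-dependent.
#' Word-adjacency edges contribute the reserved label \code{ADJ}.
#'
#' @param graph A \code{cprex_graph}.
#' @param path Result of \code{\link{sdp_search}}.
#' @param tokens Sentence token table (columns surface, pos).
#' @param directed Attach direction markers to dependency labels
#'   (default TRUE).
#' @return List with \code{words}, \code{pos_tags} (length n) and
#'   \code{dt_labels} (length n - 1).
#' @export
extract_sequences <- function(graph, path, tokens, directed = TRUE) {
  tp <- path$token_path
  dt <- character(length(tp) - 1L)
  e <- graph$edges
  for (i in seq_along(dt)) {
    r <- path$edge_rows[i]
    if (e$kind[r] == "adjacency") {
      dt[i] <- "ADJ"
    } else {
      lab <- e$label[r]
      if (directed) {
        a <- tp[i]; b <- tp[i + 1L]
        # traversed a -> b; up if a is the dependent
        lab <- paste0(lab, if (a == e$dep[r]) "↑" else "↓")
      }
      dt[i] <- lab
    }
  }
  list(words = tokens$surface[tp], pos_tags = tokens$pos[tp], dt_labels = dt)
}

#' Shortest dependency path for a candidate entity pair
#'
#' Convenience wrapper: builds the parse graph for the pair's sentence,
#' selects the two entity heads, runs the search chemical-to-gene and
#' extracts the feature sequences.
#'
#' @param sentence A sentence from a parsed corpus document.
#' @param chem,gene Rows of the document entity table (chemical and gene).
#' @param adjacency_weight Word-adjacency edge weight (default 5).
#' @param directed Direction markers on dependency labels (default TRUE).
#' @return A \code{cprex_sdp}: token_path, words, pos_tags, dt_labels,
#'   total_weight.
#' @export
pair_sdp <- function(sentence, chem, gene, adjacency_weight = 5,
                     directed = TRUE) {
  n <- nrow(sentence$tokens)
  g <- build_parse_graph(n, sentence$heads, sentence$deplabels,
                         adjacency_weight)
  ch <- select_entity_head(chem$tok_first, chem$tok_last, sentence$heads)
  gh <- select_entity_head(gene$tok_first, gene$tok_last, sentence$heads)
  p <- sdp_search(g, ch, gh)
  seqs <- extract_sequences(g, p, sentence$tokens, directed = directed)
  structure(c(list(token_path = p$token_path,
                   total_weight = p$total_weight), seqs),
            class = "cprex_sdp")
}
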