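#' Gene set with normalized symbols
#'
#' @param name set name.
#' @param members character vector of gene symbols; uppercased and
#'   deduplicated.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- unique(toupper(trimws(as.character(members))))
  members <- members[!is.na(members) & members != ""]
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", x$name, length(x$members)))
  invisible(x)
}

#' Intersect two gene sets with Venn percentage
#'
#' @param a,b nonempty `gene_set` objects (or character vectors).
#' @return list with `overlap` (sorted symbols), `n_overlap`, and
#'   `percent_of_union` (`100 |a intersect b| / |a union b|`).
#' @examples
#' intersect_sets(gene_set("drug", c("EGFR", "STAT3", "TP53")),
#'                gene_set("disease", c("STAT3", "TP53", "MTOR")))
#' @export
intersect_sets <- function(a, b) {
  if (!inherits(a, "gene_set")) a <- gene_set("a", a)
  if (!inherits(b, "gene_set")) b <- gene_set("b", b)
  if (length(a$members) == 0L || length(b$members) == 0L)
    stopf("both gene sets must be nonempty")
  ov <- sort(intersect(a$members, b$members))
  un <- union(a$members, b$members)
  list(overlap = ov, n_overlap = length(ov),
       percent_of_union = 100 * length(ov) / length(un))
}

#' Scored undirected gene interaction network
#'
#' Self-loops are dropped; duplicate unordered edges are collapsed to the
#' highest score. Scores must lie in `[0, 1]` (e.g. STRING combined
#' scores rescaled to probabilities).
#'
#' @param edges data frame with columns `gene1`, `gene2`, `score`.
#' @return object of class `gene_network` with elements `nodes` and
#'   `edges`.
#' @export
gene_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("gene1", "gene2", "score") %in% names(edges)))
    stopf("edges need columns gene1, gene2, score")
  edges$gene1 <- toupper(trimws(edges$gene1))
  edges$gene2 <- toupper(trimws(edges$gene2))
  edges$score <- as.numeric(edges$score)
  if (any(is.na(edges$score) | edges$score < 0 | edges$score > 1))
    stopf("edge scores must lie in [0, 1]")
  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]
  lo <- pmin(edges$gene1, edges$gene2)
  hi <- pmax(edges$gene1, edges$gene2)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -edges$score)
  edges <- data.frame(gene1 = lo[ord], gene2 = hi[ord],
                      score = edges$score[ord])
  edges <- edges[!duplicated(paste(edges$gene1, edges$gene2,
                                   sep = "\r")), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$gene1, edges$gene2))),
                 edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Filter network edges by confidence score
#'
#' Keeps edges with `score >= min_score` (inclusive, matching the usual
#' "high-confidence cutoff 0.7" convention); isolated nodes are dropped
#' unless `drop_isolated = FALSE`.
#'
#' @param network a `gene_network`.
#' @param min_score cutoff in `[0, 1]`.
#' @param drop_isolated drop nodes left without edges.
#' @return a filtered `gene_network`.
#' @export
filter_edges <- function(network, min_score, drop_isolated = TRUE) {
  stopifnot(inherits(network, "gene_network"))
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      is.na(min_score) || min_score < 0 || min_score > 1)
    stopf("min_score must be a single value in [0, 1]")
  keep <- network$edges$score >= min_score
  edges <- network$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (drop_isolated) {
    sort(unique(c(edges$gene1, edges$gene2)))
  } else {
    network$nodes
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' Betweenness centrality of network nodes
#'
#' Unweighted shortest-path betweenness (Brandes accumulation via igraph),
#' normalized by `(n-1)(n-2)/2` for undirected graphs. Unreachable pairs
#' in disconnected components contribute zero.
#'
#' @param network a `gene_network`.
#' @param normalized divide by the number of node pairs excluding the
#'   focal node.
#' @return named numeric vector over `network$nodes`.
#' @export
betweenness_centrality <- function(network, normalized = TRUE) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0L) stopf("network has no nodes")
  g <- igraph::graph_from_data_frame(
    network$edges[c("gene1", "gene2")], directed = FALSE,
    vertices = network$nodes)
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA,
                            normalized = normalized)
  bc[network$nodes]
}

#' Rank hub genes by centrality
#'
#' Descending by centrality, ties broken alphabetically. Asking for more
#' hubs than there are nodes returns all nodes with a warning.
#'
#' @param centrality named numeric vector (e.g. from
#'   [betweenness_centrality()]).
#' @param k number of hubs.
#' @return character vector of the top-`k` gene symbols.
#' @export
rank_hubs <- function(centrality, k) {
  k <- check_count(k, "k", min = 1L)
  if (k > length(centrality)) {
    warning(sprintf("k = %d exceeds node count %d; returning all nodes",
                    k, length(centrality)))
    k <- length(centrality)
  }
  ord <- order(-centrality, names(centrality))
  names(centrality)[ord][seq_len(k)]
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the query over-represents the
#' set within the universe: `p = P(X >= overlap)` for `X` hypergeometric
#' with population `|universe|`, successes `|set intersect universe|` and
#' draws `|query|`. Annotation sets are intersected with the universe
#' before testing; sets with zero overlap report `p = 1`. Benjamini-
#' Hochberg adjustment is applied across all tested sets.
#'
#' @param query a `gene_set` (or character vector), must be a subset of
#'   `universe`.
#' @param universe a `gene_set` (or character vector) of assayable genes.
#' @param annotation_sets list of `gene_set`s (e.g. from [read_gmt()]).
#' @return data frame with columns `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `p_adj`, ordered by `p`.
#' @export
ora <- function(query, universe, annotation_sets) {
  if (!inherits(query, "gene_set")) query <- gene_set("query", query)
  if (!inherits(universe, "gene_set"))
    universe <- gene_set("universe", universe)
  bad <- setdiff(query$members, universe$members)
  if (length(bad))
    stopf("query genes absent from universe: %s",
          paste(head(bad, 10), collapse = ", "))
  nU <- length(universe$members)
  nQ <- length(query$members)
  rows <- lapply(annotation_sets, function(s) {
    if (!inherits(s, "gene_set")) s <- gene_set("set", s)
    m <- intersect(s$members, universe$members)
    ov <- length(intersect(m, query$members))
    p <- if (ov == 0) 1 else
      stats::phyper(ov - 1, length(m), nU - length(m), nQ,
                    lower.tail = FALSE)
    data.frame(set = s$name, overlap = ov, set_size = length(m),
               query_size = nQ, universe_size = nU, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold filter for scored gene tables
#'
#' Generic dual-threshold target selection: keep symbols whose score
#' meets the cutoff (used upstream of [intersect_sets()] for predicted
#' target or disease-relevance tables).
#'
#' @param scored data frame with columns `symbol` and `score`.
#' @param min_score cutoff.
#' @param inclusive use `>=` (default) rather than `>`.
#' @return a `gene_set` of the retained symbols.
#' @export
threshold_filter <- function(scored, min_score, inclusive = TRUE) {
  scored <- as.data.frame(scored)
  if (!all(c("symbol", "score") %in% names(scored)))
    stopf("scored table needs columns `symbol` and `score`")
  s <- as.numeric(scored$score)
  keep <- if (inclusive) s >= min_score else s > min_score
  gene_set("filtered", scored$symbol[keep & !is.na(keep)])
}

# Plain-text readers --------------------------------------------------------

#' Read a one-symbol-per-line gene list
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  gene_set(name, readLines(path, warn = FALSE))
}

#' Read GMT-format annotation sets
#'
#' Tab-separated lines: set name, description, then member symbols.
#'
#' @param path file path.
#' @return list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("malformed GMT line (need name, description, members): '%s'",
            substr(ln, 1, 60))
    gene_set(f[1], f[-(1:2)])
  })
}

#' Read a scored edge list (TSV: gene1, gene2, score)
#' @param path file path.
#' @return a `gene_network`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path, sep = "\t")
  names(df)[1:3] <- c("gene1", "gene2", "score")
  gene_network(df)
}
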