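#' Construct a role-typed undirected graph
#'
#' A simple undirected graph whose nodes carry a role tag (`compound`,
#' `target` or `pathway`). Self-loops are rejected; duplicate edges collapse;
#' edge endpoints must exist among the nodes.
#'
#' @param nodes Data frame with columns `id` and `role`.
#' @param edges Data frame with columns `from` and `to` (node ids).
#' @return An object of class `typed_graph`: a list with tibbles `nodes`
#'   and `edges` (edges stored with endpoints in sorted order).
#' @export
typed_graph <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "role") %in% names(nodes)))
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  nodes <- dplyr::distinct(nodes, .data$id, .data$role)
  if (anyDuplicated(nodes$id)) {
    stop("node id(s) assigned more than one role", call. = FALSE)
  }
  if (!all(nodes$role %in% c("compound", "target", "pathway"))) {
    stop("roles must be compound, target or pathway", call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not in node set: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- dplyr::distinct(tibble::tibble(from = a, to = b)) |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(nodes = dplyr::arrange(nodes, .data$id), edges = edges),
            class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  counts <- table(x$nodes$role)
  cat("<typed_graph> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

graph_adjacency <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(g$edges) > 0) {
    fi <- match(g$edges$from, ids)
    ti <- match(g$edges$to, ids)
    adj <- split(c(ti, fi), factor(c(fi, ti), levels = seq_len(n)))
    adj <- lapply(adj, as.integer)
  }
  names(adj) <- ids
  adj
}

#' Node degrees
#' @param g A `typed_graph`.
#' @return Named integer vector over all nodes (zeros included).
#' @export
graph_degree <- function(g) {
  deg <- stats::setNames(integer(nrow(g$nodes)), g$nodes$id)
  if (nrow(g$edges) > 0) {
    t <- table(c(g$edges$from, g$edges$to))
    deg[names(t)] <- as.integer(t)
  }
  deg
}

#' Normalized betweenness centrality (Brandes' algorithm)
#'
#' Unweighted shortest-path betweenness, endpoints excluded, computed by
#' Brandes' dependency accumulation. Values are normalized by
#' `2 / ((n - 1)(n - 2))` with `n` the node count of the whole graph, so a
#' star center scores exactly 1. Disconnected graphs are handled per
#' component but normalized against the whole graph (the convention used by
#' common network-visualization software). Graphs with fewer than three
#' nodes score 0 everywhere.
#'
#' @param g A `typed_graph`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  bc <- stats::setNames(numeric(n), ids)
  if (n < 3 || nrow(g$edges) == 0) return(bc)
  adj <- graph_adjacency(g)
  raw <- numeric(n)
  for (s in seq_len(n)) {
    # single-source shortest-path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n); head <- 1L; tail <- 1L
    order_visited[1L] <- s
    while (head <= tail) {
      v <- order_visited[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          order_visited[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    if (tail >= 2L) {
      for (i in seq.int(tail, 2L)) {
        w <- order_visited[i]
        coef <- (1 + delta[w]) / sigma[w]
        for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      }
    }
    delta[s] <- 0
    raw <- raw + delta
  }
  # each unordered pair counted twice in the undirected accumulation
  bc[] <- raw / 2 * 2 / ((n - 1) * (n - 2))
  bc
}

#' Degree and betweenness table
#'
#' @param g A `typed_graph`.
#' @return Tibble with `id`, `role`, `degree`, `betweenness`.
#' @export
centrality <- function(g) {
  tibble::tibble(
    id = g$nodes$id, role = g$nodes$role,
    degree = unname(graph_degree(g)),
    betweenness = unname(betweenness_centrality(g))
  )
}

#' @export
tidy.typed_graph <- function(x, ...) centrality(x)

#' Whole-graph and per-role summary
#'
#' Mean degree is `2 E / N`. For bipartite compound-target graphs the
#' compound-role mean degree equals `E / n_compounds` because every edge is
#' incident to exactly one compound.
#'
#' @param g A `typed_graph`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `mean_degree`, per-role
#'   node counts (`n_compound`, `n_target`, `n_pathway`) and per-role mean
#'   degrees.
#' @export
summarize_network <- function(g) {
  n <- nrow(g$nodes); e <- nrow(g$edges)
  deg <- graph_degree(g)
  role_of <- stats::setNames(g$nodes$role, g$nodes$id)
  role_stats <- function(role) {
    ids <- g$nodes$id[g$nodes$role == role]
    list(n = length(ids),
         mean_degree = if (length(ids) > 0) mean(deg[ids]) else 0)
  }
  comp <- role_stats("compound"); targ <- role_stats("target"); path <- role_stats("pathway")
  tibble::tibble(
    n_nodes = n, n_edges = e,
    mean_degree = if (n > 0) 2 * e / n else 0,
    n_compound = comp$n, n_target = targ$n, n_pathway = path$n,
    mean_degree_compound = comp$mean_degree,
    mean_degree_target = targ$mean_degree,
    mean_degree_pathway = path$mean_degree
  )
}

#' @export
glance.typed_graph <- function(x, ...) summarize_network(x)

#' Build the bipartite compound-target network
#'
#' Links compounds to their predicted targets, restricted to the therapeutic
#' target set; compounds and targets left without any edge are omitted (so
#' the node count can be smaller than the input compound count).
#'
#' @param per_compound Data frame with columns `compound_id` and `gene`
#'   (e.g. `screen_predictions()$per_compound`).
#' @param therapeutic Character vector: the therapeutic target set.
#' @return A bipartite `typed_graph` with roles `compound` and `target`.
#' @export
build_compound_target_network <- function(per_compound, therapeutic) {
  per_compound <- tibble::as_tibble(per_compound)
  stopifnot(all(c("compound_id", "gene") %in% names(per_compound)))
  links <- per_compound |>
    dplyr::mutate(gene = toupper(trimws(.data$gene))) |>
    dplyr::filter(.data$gene %in% canonical_genes(therapeutic)) |>
    dplyr::distinct(.data$compound_id, .data$gene)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(links$compound_id), role = "compound"),
    tibble::tibble(id = unique(links$gene), role = "target")
  )
  typed_graph(nodes, tibble::tibble(from = links$compound_id, to = links$gene))
}

#' Screen main ingredients by network topology
#'
#' Computes degree and betweenness means over compound nodes only and keeps
#' compounds exceeding both means (strictly by default, matching a
#' "greater than the mean" screen).
#'
#' @param g A bipartite compound-target `typed_graph`.
#' @param strict If `TRUE` (default) both comparisons are strict `>`;
#'   otherwise `>=`.
#' @return A list of class `phytonet_ingredients`: `ingredients` (character
#'   vector), `mean_degree`, `mean_betweenness`, and `table` (per-compound
#'   centrality tibble with a `selected` flag).
#' @export
screen_main_ingredients <- function(g, strict = TRUE) {
  cent <- centrality(g) |> dplyr::filter(.data$role == "compound")
  if (nrow(cent) == 0) stop("graph has no compound nodes", call. = FALSE)
  mu_d <- mean(cent$degree)
  mu_b <- mean(cent$betweenness)
  cmp <- if (strict) `>` else `>=`
  cent <- cent |>
    dplyr::mutate(selected = cmp(.data$degree, mu_d) & cmp(.data$betweenness, mu_b)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  structure(list(
    ingredients = sort(cent$id[cent$selected]),
    mean_degree = mu_d, mean_betweenness = mu_b, table = cent
  ), class = "phytonet_ingredients")
}

#' @export
print.phytonet_ingredients <- function(x, ...) {
  cat("<main-ingredient screen> mean degree ", format(x$mean_degree),
      ", mean betweenness ", format(x$mean_betweenness), "\n", sep = "")
  cat("selected:", paste(x$ingredients, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.phytonet_ingredients <- function(x, ...) x$table

#' @export
glance.phytonet_ingredients <- function(x, ...) {
  tibble::tibble(n_compounds = nrow(x$table), n_selected = length(x$ingredients),
                 mean_degree = x$mean_degree, mean_betweenness = x$mean_betweenness)
}

#' Build the protein-protein interaction network
#'
#' Keeps edges whose combined score meets the threshold (inclusive) between
#' genes of the given set, then removes "free" genes — nodes left without
#' any edge.
#'
#' @param ppi Data frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (scores in `[0, 1]`).
#' @param genes Character vector restricting the node universe (typically
#'   the therapeutic target set).
#' @param threshold Minimum combined score, default 0.9.
#' @return A `typed_graph` with all nodes in role `target`.
#' @export
build_ppi_network <- function(ppi, genes, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  ppi <- tibble::as_tibble(ppi)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(ppi))) {
    stop("PPI table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(ppi$combined_score) | ppi$combined_score < 0 |
                 ppi$combined_score > 1 | ppi$gene_a == ppi$gene_b |
                 is.na(ppi$gene_a) | is.na(ppi$gene_b))
  if (length(bad) > 0) {
    stop("malformed PPI row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  genes <- canonical_genes(genes)
  kept <- ppi |>
    dplyr::mutate(gene_a = toupper(trimws(.data$gene_a)),
                  gene_b = toupper(trimws(.data$gene_b))) |>
    dplyr::filter(.data$combined_score >= threshold,
                  .data$gene_a %in% genes, .data$gene_b %in% genes)
  nodes <- tibble::tibble(id = unique(c(kept$gene_a, kept$gene_b)), role = "target")
  typed_graph(nodes, tibble::tibble(from = kept$gene_a, to = kept$gene_b))
}

#' Rank hub genes by degree
#'
#' Nodes sorted by degree descending with alphabetical tie-break; the first
#' `k` are the hubs. If nodes beyond position `k` tie with the k-th degree,
#' they are reported separately rather than silently dropped.
#'
#' @param g A `typed_graph` (typically the PPI network).
#' @param k Number of hubs, default 10.
#' @return A list of class `phytonet_hubs`: `hubs` (tibble `gene`, `degree`)
#'   and `tie_overflow` (tibble, possibly empty).
#' @export
hub_genes <- function(g, k = 10) {
  stopifnot(k >= 1)
  deg <- graph_degree(g)
  tab <- tibble::tibble(gene = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  k <- min(k, nrow(tab))
  hubs <- tab[seq_len(k), ]
  overflow <- tab[-seq_len(k), , drop = FALSE]
  overflow <- overflow[overflow$degree == hubs$degree[k], , drop = FALSE]
  structure(list(hubs = hubs, tie_overflow = overflow), class = "phytonet_hubs")
}

#' @export
print.phytonet_hubs <- function(x, ...) {
  cat("<hub genes>\n"); print(x$hubs)
  if (nrow(x$tie_overflow) > 0) {
    cat("tied at the cut:", paste(x$tie_overflow$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.phytonet_hubs <- function(x, ...) x$hubs

#' Build the compound-target-pathway network
#'
#' Combines the compound-target graph with target-pathway membership for a
#' selected set of pathways. Targets not annotated to any selected pathway
#' are dropped, and compounds losing all edges are dropped with them.
#'
#' @param g A bipartite compound-target `typed_graph`.
#' @param pathway_membership Data frame with columns `pathway`, `gene`.
#' @param top_pathways Character vector of pathway ids to include; must be a
#'   subset of `pathway_membership$pathway`.
#' @return A `typed_graph` with roles `compound`, `target`, `pathway`.
#' @export
build_ctp_network <- function(g, pathway_membership, top_pathways) {
  pathway_membership <- tibble::as_tibble(pathway_membership)
  stopifnot(all(c("pathway", "gene") %in% names(pathway_membership)))
  if (!all(top_pathways %in% pathway_membership$pathway)) {
    stop("top_pathways contains pathways absent from the membership table",
         call. = FALSE)
  }
  if (length(top_pathways) == 0) {
    return(typed_graph(tibble::tibble(id = character(), role = character()),
                       tibble::tibble(from = character(), to = character())))
  }
  membership <- pathway_membership |>
    dplyr::filter(.data$pathway %in% top_pathways) |>
    dplyr::mutate(gene = toupper(trimws(.data$gene))) |>
    dplyr::distinct(.data$pathway, .data$gene)
  targets_in_graph <- g$nodes$id[g$nodes$role == "target"]
  kept_targets <- intersect(targets_in_graph, membership$gene)
  ct_edges <- g$edges |>
    dplyr::filter(.data$from %in% kept_targets | .data$to %in% kept_targets)
  tp_edges <- membership |>
    dplyr::filter(.data$gene %in% kept_targets) |>
    dplyr::transmute(from = .data$gene, to = .data$pathway)
  kept_compounds <- intersect(
    g$nodes$id[g$nodes$role == "compound"],
    c(ct_edges$from, ct_edges$to)
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = kept_compounds, role = "compound"),
    tibble::tibble(id = kept_targets, role = "target"),
    tibble::tibble(id = top_pathways, role = "pathway")
  )
  typed_graph(nodes, dplyr::bind_rows(ct_edges, tp_edges))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a typed graph as GraphML
#'
#' Node roles are preserved in a `role` attribute.
#' @param g A `typed_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"role\" for=\"node\" attr.name=\"role\" attr.type=\"string\"/>",
    "  <graph edgedefault=\"undirected\">",
    sprintf("    <node id=\"%s\"><data key=\"role\">%s</data></node>",
            xml_escape(g$nodes$id), xml_escape(g$nodes$role)),
    if (nrow(g$edges) > 0) {
      sprintf("    <edge source=\"%s\" target=\"%s\"/>",
              xml_escape(g$edges$from), xml_escape(g$edges$to))
    },
    "  </graph>",
    "</graphml>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a typed graph as SIF
#'
#' One `nodeA relation nodeB` line per edge; the relation is derived from
#' the endpoint roles (e.g. `compound-target`). Isolated nodes are written
#' as single-column lines.
#' @param g A `typed_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  role_of <- stats::setNames(g$nodes$role, g$nodes$id)
  rel <- paste(role_of[g$edges$from], role_of[g$edges$to], sep = "-")
  lines <- sprintf("%s\t%s\t%s", g$edges$from, rel, g$edges$to)
  isolated <- setdiff(g$nodes$id, c(g$edges$from, g$edges$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}
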