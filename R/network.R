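#' Call differentially expressed genes
#'
#' Per-gene Welch two-sample test on log2 expression between two conditions,
#' with an optional variance-shrinkage step that pools each gene's variance
#' toward the mean variance across genes. Genes are flagged by the rule
#' `p_adj < 0.05` (Benjamini-Hochberg) and fold change strictly greater than
#' 2 (`|log2FC| > 1`).
#'
#' @param expr Genes x samples numeric matrix of log2 expression (rownames =
#'   gene ids), or the list returned by [gen_expression_matrix()].
#' @param conditions Character vector assigning each column to a condition
#'   (ignored when `expr` carries its own).
#' @param contrast Length-2 character vector `c(treatment, control)`; log2FC
#'   is treatment minus control.
#' @param shrink Variance-shrinkage weight in `[0, 1]`: each gene's variance
#'   becomes `(1 - shrink) * s2_gene + shrink * mean(s2)`. Default 0 (plain
#'   Welch test).
#' @param p_threshold Adjusted-p cutoff of the DE rule (default 0.05).
#' @param lfc_threshold log2 fold-change cutoff, strict (default 1).
#' @return A tibble: `gene_id`, `log2fc`, `t`, `p`, `p_adj`, `de`.
#' @export
call_de <- function(expr, conditions = NULL, contrast, shrink = 0,
                    p_threshold = 0.05, lfc_threshold = 1) {
  if (is.list(expr) && !is.matrix(expr)) {
    conditions <- conditions %||% expr$conditions
    expr <- expr$expr
  }
  if (is.null(conditions)) stop_input("`conditions` is required")
  if (length(contrast) != 2 || !all(contrast %in% conditions))
    stop_input("`contrast` must name two conditions present in the data")
  ia <- which(conditions == contrast[1])
  ib <- which(conditions == contrast[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop_input("each contrasted condition needs at least 2 replicates")

  xa <- expr[, ia, drop = FALSE]
  xb <- expr[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (shrink > 0) {
    va <- (1 - shrink) * va + shrink * mean(va)
    vb <- (1 - shrink) * vb + shrink * mean(vb)
  }
  lfc <- ma - mb
  se2 <- va / na + vb / nb
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate zero-variance genes: exact difference decides
  zero <- se2 == 0
  p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
  tstat[zero] <- ifelse(lfc[zero] == 0, 0, Inf * sign(lfc[zero]))
  p_adj <- bh_fdr(p)
  tibble(
    gene_id = rownames(expr) %||% sprintf("g%05d", seq_len(nrow(expr))),
    log2fc = unname(lfc), t = unname(tstat), p = unname(p),
    p_adj = unname(p_adj),
    de = unname(p_adj < p_threshold & abs(lfc) > lfc_threshold)
  )
}

#' Build a rank-correlation co-expression network
#'
#' Edges connect gene pairs whose Spearman correlation across samples has
#' absolute value at least `min_similarity`. This correlation network stands
#' behind the pipeline's network-construction step; it is a deliberately
#' simple, self-contained similarity graph, not a composite multi-evidence
#' network.
#'
#' @param expr Genes x samples log2 matrix, or [gen_expression_matrix()]
#'   output.
#' @param genes Optional subset of gene ids (e.g. the DE genes).
#' @param min_similarity Absolute-correlation edge threshold (default 0.7).
#' @return A list of class `coexpr_graph`: `graph` (an igraph object with
#'   edge attribute `weight` holding the signed correlation) and `edges`
#'   (tibble `from`, `to`, `weight`).
#' @export
build_network <- function(expr, genes = NULL, min_similarity = 0.7) {
  if (is.list(expr) && !is.matrix(expr)) expr <- expr$expr
  if (ncol(expr) < 3) stop_input("need at least 3 samples to correlate")
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), ,
                                    drop = FALSE]
  rho <- stats::cor(t(expr), method = "spearman")
  diag(rho) <- 0
  idx <- which(abs(rho) >= min_similarity & upper.tri(rho), arr.ind = TRUE)
  edges <- tibble(
    from = rownames(rho)[idx[, 1]],
    to = rownames(rho)[idx[, 2]],
    weight = rho[idx]
  ) |> arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(rownames(rho))))
  structure(list(graph = g, edges = edges, min_similarity = min_similarity),
            class = "coexpr_graph")
}

#' @export
print.coexpr_graph <- function(x, ...) {
  cat(sprintf("<coexpr_graph> %d genes, %d edges (|rho| >= %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$min_similarity))
  invisible(x)
}

as_igraph <- function(g) {
  if (inherits(g, "coexpr_graph")) return(g$graph)
  if (inherits(g, "igraph")) return(g)
  if (is.data.frame(g))
    return(igraph::graph_from_data_frame(g, directed = FALSE))
  stop_input("expected a coexpr_graph, igraph object, or edge data frame")
}

#' MCODE vertex weights
#'
#' Each vertex is weighted by the density of the highest k-core (k >= 2) of
#' its closed neighbourhood times that core's number:
#' `weight(v) = k_max * density(core)`. A complete graph K5 therefore weighs
#' every vertex `4 * 1 = 4`, while vertices whose neighbourhood holds no
#' multiply-connected core at all -- isolated vertices, pendant vertices, the
#' leaves and centre of a star -- weigh 0. Weights are deterministic and
#' independent of edge-list order.
#'
#' @param g A `coexpr_graph`, igraph object, or edge data frame.
#' @return A named numeric vector of weights (names = vertex ids).
#' @export
mcode_weights <- function(g) {
  g <- as_igraph(g)
  n <- igraph::vcount(g)
  w <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0) return(w)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (v in seq_len(n)) {
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 2) next
    core_g <- igraph::induced_subgraph(sub, which(core == kmax))
    m <- igraph::vcount(core_g)
    dens <- if (m < 2) 0 else
      2 * igraph::ecount(core_g) / (m * (m - 1))
    w[v] <- kmax * dens
  }
  w
}

#' MCODE-style complex detection
#'
#' Complexes are grown greedily from unassigned seed vertices in descending
#' weight order (ties by vertex id). A neighbour joins the growing complex
#' when its weight is at least `(1 - node_score_cutoff)` times the seed
#' weight **and** it is connected to at least half of the current members
#' (minimum 2; a single edge suffices only while the complex is one vertex).
#' The attachment condition keeps every complex a dense 2-core as it grows,
#' so single-edge bridges and sparse spurious links between dense regions
#' are never crossed. Candidates are re-examined until no more qualify,
#' which makes the result independent of edge-list order.
#'
#' Each complex is post-processed as soon as it is found. Haircut iteratively
#' removes members with fewer than two within-complex edges before the
#' complex claims its vertices, so a pruned vertex stays available to later
#' complexes. Fluff then adds still-unassigned neighbours whose
#' closed-neighbourhood density exceeds `fluff_density` and that connect to
#' at least a quarter of the complex (minimum 2 edges) -- fluffed vertices
#' may appear in several complexes and stay unassigned -- after which haircut
#' runs once more so a fluffed-in pendant is still pruned. Complexes with fewer
#' than two final members are dropped. Complexes are reported in descending
#' score (`density * size`).
#'
#' @param g A `coexpr_graph`, igraph object, or edge data frame.
#' @param node_score_cutoff Allowed fractional weight drop from the seed
#'   (default 0.2).
#' @param haircut,fluff Enable the respective post-processing step
#'   (defaults TRUE, matching the reported settings).
#' @param fluff_density Closed-neighbourhood density threshold for fluff
#'   (default 0.5).
#' @return A list of class `mcode_result` with `complexes` (a list of member
#'   id vectors), `seeds`, `scores` (density x size), `weights` (the vertex
#'   weights) and `membership` (tibble `gene_id`, `complex`, `fluffed`).
#' @export
mcode_complexes <- function(g, node_score_cutoff = 0.2, haircut = TRUE,
                            fluff = TRUE, fluff_density = 0.5) {
  g <- as_igraph(g)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  w <- mcode_weights(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)

  order_seed <- order(-w, ids)
  assigned <- logical(n)
  complexes <- list(); seeds <- character(0); fluff_sets <- list()
  glob_dens <- if (fluff) closed_neighbourhood_density(g) else NULL

  for (s in order_seed) {
    if (assigned[s] || w[s] <= 0) next
    thr <- (1 - node_score_cutoff) * w[s]
    members <- s
    repeat {
      cand <- setdiff(unique(unlist(adj[members])), members)
      cand <- cand[!assigned[cand] & w[cand] >= thr]
      if (length(cand) == 0) break
      need <- min(length(members), max(2L, as.integer(ceiling(length(members) / 2))))
      links <- vapply(cand, function(v) sum(adj[[v]] %in% members),
                      integer(1))
      ok <- cand[links >= need]
      if (length(ok) == 0) break
      members <- c(members, ok[order(ids[ok])])
    }
    if (haircut) members <- haircut_members(members, adj)
    if (length(members) < 2) next
    assigned[members] <- TRUE
    fl <- integer(0)
    if (fluff) {
      nb <- setdiff(unique(unlist(adj[members])), members)
      fl_need <- max(2L, as.integer(ceiling(length(members) / 4)))
      fl_links <- vapply(nb, function(v) sum(adj[[v]] %in% members),
                         integer(1))
      fl <- nb[!assigned[nb] & glob_dens[nb] > fluff_density &
                 fl_links >= fl_need]
      members <- c(members, fl)
      # fluffed-in pendants are still pruned; core members stay multiply
      # connected so only fluff vertices can fall
      if (haircut) members <- haircut_members(members, adj)
    }
    if (length(members) < 2) next
    complexes[[length(complexes) + 1]] <- members
    seeds <- c(seeds, ids[s])
    fluff_sets[[length(fluff_sets) + 1]] <- intersect(fl, members)
  }

  sizes <- lengths(complexes)
  dens <- vapply(seq_along(complexes), function(k) {
    sub <- igraph::induced_subgraph(g, complexes[[k]])
    m <- sizes[k]
    if (m < 2) 0 else 2 * igraph::ecount(sub) / (m * (m - 1))
  }, double(1))
  scores <- dens * sizes
  ord <- order(-scores,
               vapply(complexes, function(m) min(ids[m]), character(1)))

  complexes <- complexes[ord]; seeds <- seeds[ord]
  scores <- scores[ord]; fluff_sets <- fluff_sets[ord]
  member_ids <- map(seq_along(complexes), function(k)
    sort(ids[complexes[[k]]]))
  membership <- if (length(complexes)) {
    bind_rows(map(seq_along(complexes), function(k) {
      tibble(gene_id = sort(ids[complexes[[k]]]), complex = k) |>
        mutate(fluffed = .data$gene_id %in% ids[fluff_sets[[k]]])
    }))
  } else {
    tibble(gene_id = character(), complex = integer(), fluffed = logical())
  }
  structure(list(complexes = member_ids, seeds = seeds, scores = scores,
                 weights = w, membership = membership),
            class = "mcode_result")
}

haircut_members <- function(members, adj) {
  repeat {
    if (length(members) == 0) return(members)
    deg <- vapply(members, function(v) sum(adj[[v]] %in% members), integer(1))
    drop <- deg < 2
    if (!any(drop)) return(members)
    members <- members[!drop]
  }
}

closed_neighbourhood_density <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  vapply(seq_len(n), function(v) {
    nb <- c(v, as.integer(adj[[v]]))
    m <- length(nb)
    if (m < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    2 * igraph::ecount(sub) / (m * (m - 1))
  }, double(1))
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("<mcode_result> %d complex(es)\n", length(x$complexes)))
  for (k in seq_along(x$complexes)) {
    cat(sprintf("  %d: %d members, seed %s, score %.2f\n", k,
                length(x$complexes[[k]]), x$seeds[k], x$scores[k]))
  }
  invisible(x)
}

#' @export
tidy.mcode_result <- function(x, ...) x$membership

#' @export
glance.mcode_result <- function(x, ...) {
  tibble(n_complexes = length(x$complexes),
         n_assigned = sum(!x$membership$fluffed),
         largest = if (length(x$complexes)) max(lengths(x$complexes)) else 0L,
         top_score = if (length(x$scores)) max(x$scores) else NA_real_)
}

#' Select the complex containing an anchor gene
#'
#' @param complexes An `mcode_result`.
#' @param anchor Gene id of interest.
#' @return Character vector of the complex's members (including the anchor),
#'   or an empty vector with a warning when the anchor is unclustered.
#' @export
select_anchor_cluster <- function(complexes, anchor) {
  hit <- which(map_lgl(complexes$complexes, function(m) anchor %in% m))
  if (length(hit) == 0) {
    warn(sprintf("anchor gene '%s' is not in any complex", anchor))
    return(character(0))
  }
  complexes$complexes[[hit[1]]]
}

#' @importFrom purrr map_lgl
NULL
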