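# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration / naive looping, sharing no code with the package
# paths they check.

BASES <- c("A", "C", "G", "T")

# naive per-offset scanner: returns data.frame(offset, strand, score)
naive_scan <- function(seq, lo, threshold) {
  L <- nrow(lo)
  v <- match(strsplit(toupper(seq), "")[[1]], BASES)
  n <- length(v)
  out <- list()
  if (n >= L) {
    for (o in 0:(n - L)) {
      w <- v[(o + 1):(o + L)]
      if (any(is.na(w))) next
      sc <- sum(lo[cbind(seq_len(L), w)])
      if (sc >= threshold)
        out[[length(out) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = sc)
      w2 <- rev(5 - w)   # reverse complement in code space
      sc2 <- sum(lo[cbind(seq_len(L), w2)])
      if (sc2 >= threshold)
        out[[length(out) + 1]] <- data.frame(offset = o, strand = "-",
                                             score = sc2)
    }
  }
  if (length(out) == 0)
    return(data.frame(offset = integer(), strand = character(),
                      score = double()))
  d <- do.call(rbind, out)
  d[order(d$offset, d$strand), ]
}

# exact one-sided Fisher p by full enumeration of tables with fixed margins
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, double(1))
  sum(probs[(lo:hi) >= a])
}

# exact binomial upper tail by term summation on the log scale
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_enum_oracle <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  r <- rank(c(xa, xb))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force MCODE vertex weights: for each vertex, enumerate all subsets of
# its closed neighbourhood, find the highest k (k >= 2) such that some subset
# has minimum induced degree >= k, take the union of all such subsets
# (the k-core), and score k * density.
brute_mcode_weights <- function(adj_list, ids) {
  n <- length(adj_list)
  vapply(seq_len(n), function(v) {
    nb <- sort(unique(c(v, adj_list[[v]])))
    m <- length(nb)
    if (m < 2) return(0)
    best_k <- 0; best_core <- integer(0)
    for (k in seq_len(m - 1)) {
      core_members <- integer(0)
      for (mask in 1:(2^m - 1)) {
        sub <- nb[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
        if (length(sub) < k + 1) next
        degs <- vapply(sub, function(u) sum(adj_list[[u]] %in% sub),
                       integer(1))
        if (all(degs >= k)) core_members <- union(core_members, sub)
      }
      if (length(core_members) > 0 && k >= 2) {
        best_k <- k; best_core <- core_members
      }
    }
    if (best_k < 2) return(0)
    e <- sum(vapply(best_core, function(u)
      sum(adj_list[[u]] %in% best_core), integer(1))) / 2
    s <- length(best_core)
    best_k * (2 * e / (s * (s - 1)))
  }, double(1))
}

adj_from_igraph <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

random_graph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n) < p, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  idx <- which(m, arr.ind = TRUE)
  ids <- sprintf("v%02d", seq_len(n))
  igraph::graph_from_data_frame(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids))
}

barbell_graph <- function() {
  el <- rbind(t(utils::combn(paste0("a", 1:5), 2)),
              t(utils::combn(paste0("b", 1:5), 2)),
              c("a1", "b1"))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# near-deterministic consensus matrix: column probabilities ~1 for the
# consensus base, so planted sites equal the consensus string
toy_pwm_consensus <- function(word, id = "TOY", strength = 1e6) {
  v <- match(strsplit(word, "")[[1]], BASES)
  counts <- matrix(0, nrow = length(v), ncol = 4)
  counts[cbind(seq_along(v), v)] <- strength
  pwm(counts, id = id)
}

# insert gaps into an ungapped sequence at given 1-based column positions
gapify <- function(seq, gap_cols) {
  chars <- strsplit(seq, "")[[1]]
  total <- length(chars) + length(gap_cols)
  out <- character(total)
  out[gap_cols] <- "-"
  out[setdiff(seq_len(total), gap_cols)] <- chars
  paste(out, collapse = "")
}
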