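#' One-sided Fisher exact test for promoter hit counts
#'
#' Tests whether target promoters carry at least one binding site more often
#' than reference promoters, with the 2x2 table `(a, b; c, d)` = (targets
#' with a site, targets without, references with, references without). The
#' p-value is the hypergeometric tail probability of observing `a` or more
#' hit-bearing target promoters given the margins.
#'
#' @param a,b,c,d Non-negative counts.
#' @return A list with `p` (one-sided, enrichment direction) and `odds_ratio`
#'   (Haldane-Anscombe +0.5 corrected when any cell is zero).
#' @export
#' @examples
#' fisher_promoter_test(10, 0, 0, 10)
fisher_promoter_test <- function(a, b, c, d) {
  for (x in list(a, b, c, d))
    if (x < 0 || x != round(x)) stop_input("counts must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0)
    stop_input("both promoter sets must be non-empty")
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p = p, odds_ratio = or)
}

#' One-sided binomial test for site frequency
#'
#' The null per-bp site rate is estimated from the reference set
#' (`lambda = s_r / B_r`); the p-value is `P(X >= s_t)` for
#' `X ~ Binomial(B_t, lambda)`. When the reference set has no sites, the rate
#' is floored at `1 / (2 * B_r)` so the test stays finite and conservative.
#'
#' @param s_t Collapsed site count in the target set.
#' @param B_t Target set length in bp (single strand).
#' @param s_r Collapsed site count in the reference set.
#' @param B_r Reference set length in bp.
#' @return A list with `p`, `lambda` (null rate per bp), and the observed
#'   frequencies per 1000 bp (`rate_target_kb`, `rate_reference_kb`).
#' @export
binomial_site_test <- function(s_t, B_t, s_r, B_r) {
  if (B_t <= 0 || B_r <= 0) stop_input("set lengths must be positive")
  lambda <- if (s_r == 0) 1 / (2 * B_r) else s_r / B_r
  p <- stats::pbinom(s_t - 1, B_t, lambda, lower.tail = FALSE)
  list(p = p, lambda = lambda,
       rate_target_kb = 1000 * s_t / B_t,
       rate_reference_kb = 1000 * s_r / B_r)
}

#' Confidence-interval-adjusted fold enrichment
#'
#' The odds ratio of the 2x2 promoter table, corrected downward to the lower
#' bound of its Wald confidence interval on the log scale, with
#' Haldane-Anscombe +0.5 added to every cell:
#' `afe = exp(ln(OR+) - z * sqrt(sum(1/(cell + 0.5))))`.
#' Values above 1 mean the enrichment direction survives the correction.
#'
#' @inheritParams fisher_promoter_test
#' @param confidence Two-sided confidence level for the interval
#'   (default 0.99, giving `z = 2.5758`).
#' @return The adjusted fold enrichment (non-negative scalar); vectorised over
#'   the counts.
#' @export
#' @examples
#' adjusted_fold_enrichment(80, 20, 10, 90)
adjusted_fold_enrichment <- function(a, b, c, d, confidence = 0.99) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c + 0.5) + 1 / (d + 0.5))
  pmax(exp(log(or) - z * se), 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (wraps [stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Maximum adjusted fold enrichment over score thresholds
#'
#' For one PWM and one target/reference promoter pair: calibrates the score
#' threshold grid on the reference set (all thresholds whose reference site
#' frequency respects `cap`), computes the adjusted fold enrichment of the
#' promoter 2x2 table at every grid threshold, and returns the maximum, with
#' the Fisher and binomial tests evaluated at the maximising threshold. Ties
#' resolve to the higher (stricter) threshold.
#'
#' @param pwm A [pwm()] object.
#' @param targets,references Promoter tibbles or named character vectors.
#' @param cap Maximum reference site frequency per bp (default `1/2000`).
#' @param confidence Confidence level for [adjusted_fold_enrichment()].
#' @return One-row tibble: `matrix_id`, `threshold`, counts `a`,`b`,`c`,`d`,
#'   `sites_kb_target`, `sites_kb_reference`, `fisher_p`, `odds_ratio`,
#'   `binom_p`, `afe`, `capped`.
#' @export
sweep_max_afe <- function(pwm, targets, references, cap = 1 / 2000,
                          confidence = 0.99) {
  prof <- scan_profile(pwm, references, cap)
  sweep_with_profile(pwm, prof, targets, confidence)
}

sweep_with_profile <- function(pwm, prof, targets, confidence = 0.99) {
  L <- length(pwm)
  t_cap <- prof$threshold
  ref_ids <- prof$enc$ids
  R <- length(ref_ids)
  B_r <- prof$total_bp

  enc_t <- encode_set(targets)
  Tn <- length(enc_t$ids)
  B_t <- enc_t$total_bp
  rest <- cpp_scan(enc_t$codes, pwm_log_odds(pwm), enc_t$starts, enc_t$lens,
                   t_cap, 0L)

  grid <- unique(prof$tail_scores[prof$tail_scores >= t_cap])  # descending
  if (length(grid) == 0) grid <- t_cap

  t_pmax <- rest$pmax
  r_pmax <- prof$pmax
  a_vec <- vapply(grid, function(t) sum(t_pmax >= t), double(1))
  c_vec <- vapply(grid, function(t) sum(r_pmax >= t), double(1))
  afe_vec <- adjusted_fold_enrichment(a_vec, Tn - a_vec, c_vec, R - c_vec,
                                      confidence)
  best <- which.max(afe_vec)              # first max = strictest threshold
  t_star <- grid[best]
  a <- a_vec[best]; b <- Tn - a; cc <- c_vec[best]; d <- R - cc

  ref_keep <- prof$tail_scores >= t_star
  ref_hits <- hits_from_cpp(
    list(pos = prof$tail_pos[ref_keep], strand = prof$tail_strand[ref_keep],
         score = prof$tail_scores[ref_keep]),
    ref_ids, prof$enc$starts, pwm$id)
  tgt_keep <- rest$score >= t_star
  tgt_hits <- hits_from_cpp(
    list(pos = rest$pos[tgt_keep], strand = rest$strand[tgt_keep],
         score = rest$score[tgt_keep]),
    enc_t$ids, enc_t$starts, pwm$id)

  s_r <- nrow(collapse_hits(ref_hits, L))
  s_t <- nrow(collapse_hits(tgt_hits, L))

  fish <- fisher_promoter_test(a, b, cc, d)
  bino <- binomial_site_test(s_t, B_t, s_r, B_r)

  tibble(
    matrix_id = pwm$id,
    threshold = t_star,
    a = a, b = b, c = cc, d = d,
    sites_kb_target = bino$rate_target_kb,
    sites_kb_reference = bino$rate_reference_kb,
    fisher_p = fish$p,
    odds_ratio = fish$odds_ratio,
    binom_p = bino$p,
    afe = afe_vec[best],
    capped = prof$capped
  )
}

#' TFBS enrichment report across gene clusters and matrices
#'
#' The main enrichment entry point: for every (matrix, cluster) pair, runs
#' [sweep_max_afe()] of the cluster's promoters against the reference set,
#' then adjusts the binomial p-values per cluster across matrices
#' (Benjamini-Hochberg) and flags significance by the decision rule
#' `afe > 1 & fdr < 0.05`.
#'
#' @param clusters A two-column data frame (`gene_id`, `cluster`) or a named
#'   list of gene id vectors.
#' @param matrices A list of [pwm()] objects (e.g. from [read_transfac()]).
#' @param promoters Promoter tibble covering every clustered gene.
#' @param references Reference promoter tibble (the background sample).
#' @param cap Maximum reference site frequency per bp (default `1/2000`).
#' @param confidence Confidence level for the adjusted fold enrichment.
#' @param fdr_threshold FDR cutoff of the significance rule (default 0.05).
#' @return A tibble of class `tfbs_enrichment`, one row per (matrix, cluster),
#'   with the [sweep_max_afe()] columns plus `cluster`, `fdr` and
#'   `significant`.
#' @export
enrich_report <- function(clusters, matrices, promoters, references,
                          cap = 1 / 2000, confidence = 0.99,
                          fdr_threshold = 0.05) {
  clusters <- as_cluster_table(clusters)
  if (inherits(matrices, "pwm")) matrices <- list(matrices)
  prom_seqs <- promoter_seqs(promoters)
  missing <- setdiff(clusters$gene_id, names(prom_seqs))
  if (length(missing) > 0)
    stop_input(sprintf("no promoter for cluster gene(s): %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  cluster_ids <- unique(clusters$cluster)

  references <- encode_set(references)
  enc_clusters <- map(cluster_ids, function(cl) {
    encode_set(prom_seqs[clusters$gene_id[clusters$cluster == cl]])
  })
  rows <- map(matrices, function(m) {
    prof <- scan_profile(m, references, cap)
    map2(cluster_ids, enc_clusters, function(cl, enc) {
      sweep_with_profile(m, prof, enc, confidence) |>
        mutate(cluster = as.character(cl), .after = "matrix_id")
    }) |> bind_rows()
  }) |> bind_rows()

  if (nrow(rows) > 0) {
    rows <- rows |>
      group_by(.data$cluster) |>
      mutate(fdr = bh_fdr(.data$binom_p)) |>
      ungroup() |>
      mutate(significant = .data$afe > 1 & .data$fdr < fdr_threshold)
  } else {
    rows$cluster <- character(0)
    rows$fdr <- double(0)
    rows$significant <- logical(0)
  }
  structure(rows, class = c("tfbs_enrichment", class(tibble())),
            fdr_threshold = fdr_threshold, confidence = confidence, cap = cap)
}

as_cluster_table <- function(clusters) {
  if (is.list(clusters) && !is.data.frame(clusters)) {
    tibble(gene_id = unlist(clusters, use.names = FALSE),
           cluster = rep(names(clusters), lengths(clusters)))
  } else {
    out <- as_tibble(clusters)
    names(out)[1:2] <- c("gene_id", "cluster")
    out
  }
}

#' @export
tidy.tfbs_enrichment <- function(x, ...) {
  as_tibble(unclass2_tbl(x))
}

#' @export
glance.tfbs_enrichment <- function(x, ...) {
  tibble(
    n_matrices = length(unique(x$matrix_id)),
    n_clusters = length(unique(x$cluster)),
    n_significant = sum(x$significant),
    fdr_threshold = attr(x, "fdr_threshold"),
    confidence = attr(x, "confidence")
  )
}

unclass2_tbl <- function(x) {
  class(x) <- class(tibble())
  x
}

#' Wide matrix-by-cluster view of an enrichment report
#'
#' @param x A `tfbs_enrichment` report.
#' @param value Which column to spread (default `"afe"`).
#' @return A tibble with one row per matrix and one column per cluster.
#' @export
enrichment_matrix <- function(x, value = "afe") {
  tidy(x) |>
    select("matrix_id", "cluster", all_of(value)) |>
    tidyr::pivot_wider(names_from = "cluster", values_from = all_of(value))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of adjusted fold enrichment per matrix and cluster
#'
#' Tiles show AFE; significant entries (AFE > 1 and FDR below the report's
#' threshold) are outlined.
#'
#' @param object A `tfbs_enrichment` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfbs_enrichment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$matrix_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$afe)) +
    ggplot2::geom_tile(data = d[d$significant, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "gene cluster", y = NULL, fill = "AFE") +
    ggplot2::theme_minimal()
}
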