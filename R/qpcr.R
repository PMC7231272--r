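#' Relative expression by the 2^dCt method
#'
#' For each sample the reference Ct is the arithmetic mean of the three
#' reference genes' Cts (equivalently the geometric mean of their
#' expressions), and the relative expression of gene *g* is
#' `2^(ref_ct - ct_g)`. Adding a constant to every Ct of a sample leaves the
#' result unchanged, and a reference gene that agrees exactly with the
#' others has relative expression exactly 1.
#'
#' @param ct Ct tibble with columns `gene_id`, `sample_id`, `group`,
#'   `replicate`, `ct` (e.g. from [gen_ct_table()]).
#' @param targets Gene ids to report (default: all non-reference genes).
#' @param references Character vector of reference gene ids (typically 3).
#' @return A tibble `gene_id`, `sample_id`, `group`, `replicate`,
#'   `rel_expr`, with attribute `normalisation = "mean of reference Cts"`.
#' @export
relative_expression <- function(ct, targets = NULL, references) {
  ct <- as_tibble(ct)
  req <- c("gene_id", "sample_id", "group", "replicate", "ct")
  if (!all(req %in% names(ct)))
    stop_input("`ct` needs columns gene_id, sample_id, group, replicate, ct")
  if (any(!is.finite(ct$ct)))
    stop_input("Ct values must be finite")
  targets <- targets %||% setdiff(unique(ct$gene_id), references)

  refs <- ct |>
    filter(.data$gene_id %in% references) |>
    group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$ct), n_refs = dplyr::n(), .groups = "drop")
  bad <- refs$sample_id[refs$n_refs < length(references)]
  missing_samples <- setdiff(unique(ct$sample_id), refs$sample_id)
  bad <- union(bad, missing_samples)
  if (length(bad) > 0)
    stop_input(sprintf("sample(s) missing reference measurements: %s",
                       paste(utils::head(bad, 5), collapse = ", ")))

  out <- ct |>
    filter(.data$gene_id %in% c(targets, references)) |>
    inner_join(refs[, c("sample_id", "ref_ct")], by = "sample_id") |>
    mutate(rel_expr = 2^(.data$ref_ct - .data$ct)) |>
    select("gene_id", "sample_id", "group", "replicate", "rel_expr")
  attr(out, "normalisation") <- "mean of reference Cts"
  out
}

#' Mann-Whitney comparison of relative expression between two groups
#'
#' Two-sided Mann-Whitney U test on the biological-replicate values of one
#' gene. For group sizes up to 8 the null distribution is enumerated exactly
#' over all assignments of the pooled values; larger groups use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param rel Relative-expression tibble from [relative_expression()] (or any
#'   tibble with `gene_id`, `group`, `rel_expr`).
#' @param gene Gene id to compare.
#' @param group_a,group_b Group labels.
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: `gene_id`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `U` (for `group_a`), `p`, `method` (`"exact"`/`"normal"`),
#'   `significant`.
#' @export
compare_groups <- function(rel, gene, group_a, group_b, alpha = 0.01) {
  xa <- rel$rel_expr[rel$gene_id == gene & rel$group == group_a]
  xb <- rel$rel_expr[rel$gene_id == gene & rel$group == group_b]
  if (length(xa) < 3 || length(xb) < 3)
    stop_input("need at least 3 replicates per group")
  mw <- mann_whitney(xa, xb)
  tibble(gene_id = gene, group_a = group_a, group_b = group_b,
         n_a = length(xa), n_b = length(xb), U = mw$U, p = mw$p,
         method = mw$method, significant = mw$p < alpha)
}

# Two-sided Mann-Whitney U; exact by enumeration for small groups.
mann_whitney <- function(xa, xb, exact_max = 8) {
  na <- length(xa); nb <- length(xb)
  pooled <- c(xa, xb)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    combos <- utils::combn(na + nb, na)
    Us <- apply(combos, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    list(U = U, p = p, method = "exact")
  } else {
    N <- na + nb
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) return(list(U = U, p = 1, method = "normal"))
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    list(U = U, p = min(1, p), method = "normal")
  }
}
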