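#' Scan promoters with a PWM on both strands
#'
#' Every window whose log2-odds score (see [pwm_log_odds()]) reaches
#' `threshold` is reported, on both strands. Minus-strand windows are scored
#' on the reverse complement and reported at the offset of the window's
#' leftmost base on the forward sequence. Windows containing `N` are skipped.
#' Overlapping hits are all reported; use [collapse_hits()] for
#' non-overlapping site counts.
#'
#' @param promoters A promoter tibble (as returned by
#'   [extract_promoters()] or [gen_background_promoters()]) with columns
#'   `gene_id` and `seq`, or a named character vector of sequences.
#' @param pwm A [pwm()] object.
#' @param threshold Score threshold in bits (finite).
#' @return A tibble of hits with columns `promoter_id`, `matrix_id`, `offset`
#'   (0-based), `strand` (`"+"`/`"-"`) and `score` (bits), sorted by promoter,
#'   offset, strand. Promoters shorter than the motif yield no rows.
#' @export
scan_pwm <- function(promoters, pwm, threshold) {
  enc <- encode_set(promoters)
  if (!is.finite(threshold)) stop_input("`threshold` must be finite")
  res <- cpp_scan(enc$codes, pwm_log_odds(pwm), enc$starts, enc$lens,
                  threshold, 0L)
  hits_from_cpp(res, enc$ids, enc$starts, pwm$id) |>
    arrange(match(.data$promoter_id, enc$ids), .data$offset, .data$strand)
}

promoter_seqs <- function(promoters) {
  if (is.character(promoters)) {
    seqs <- toupper(promoters)
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  } else {
    if (!all(c("gene_id", "seq") %in% names(promoters)))
      stop_input("promoter table needs `gene_id` and `seq` columns")
    seqs <- toupper(promoters$seq)
    names(seqs) <- promoters$gene_id
  }
  seqs
}

hits_from_cpp <- function(res, ids, starts, matrix_id) {
  if (length(res$pos) == 0) {
    return(tibble(promoter_id = character(), matrix_id = character(),
                  offset = integer(), strand = character(), score = double()))
  }
  idx <- findInterval(res$pos, starts)
  tibble(
    promoter_id = ids[idx],
    matrix_id = matrix_id,
    offset = res$pos - starts[idx],
    strand = c("+", "-")[res$strand + 1L],
    score = res$score
  )
}

#' Greedy non-overlap collapsing of motif hits
#'
#' Within each (promoter, strand), hits are kept in descending score order,
#' discarding any hit that overlaps an already-kept one. This is the site set
#' used for site-frequency statistics, so a single strong site never counts
#' once per overlapping window.
#'
#' @param hits A hit tibble from [scan_pwm()].
#' @param motif_length Motif length in bp (window width of the hits).
#' @return The collapsed hit tibble, same columns as `hits`.
#' @export
collapse_hits <- function(hits, motif_length) {
  if (nrow(hits) == 0) return(hits)
  grp <- paste(hits$promoter_id, hits$strand)
  keep_idx <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(ii) {
    ii <- ii[order(-hits$score[ii], hits$offset[ii])]
    off <- hits$offset[ii]
    kept <- integer(0)
    keep <- logical(length(ii))
    for (j in seq_along(ii)) {
      if (!any(abs(kept - off[j]) < motif_length)) {
        keep[j] <- TRUE
        kept <- c(kept, off[j])
      }
    }
    ii[keep]
  }), use.names = FALSE)
  out <- hits[sort(keep_idx), ]
  out[order(out$promoter_id, out$offset, out$strand), ]
}

#' Calibrate a PWM score threshold to a maximum site frequency
#'
#' Finds the smallest threshold, over the grid of window scores observed on a
#' calibration promoter set, whose total hit count per scanned bp does not
#' exceed `max_frequency` (default one site per 2000 bp). Both strands are
#' scanned; frequency is hits on either strand divided by the single-strand
#' length of the set.
#'
#' @param pwm A [pwm()] object.
#' @param calibration_set Promoter tibble or named character vector of
#'   sequences (typically the reference promoter set).
#' @param max_frequency Maximum allowed sites per bp (default `1/2000`).
#' @return A one-row tibble of class `threshold_calibration`: `matrix_id`,
#'   `threshold` (bits), `achieved_frequency` (sites/bp), `target_cap`,
#'   `n_hits`, `total_bp`, `capped` (TRUE when even the maximum observed
#'   score exceeds the cap, with a warning).
#' @export
calibrate_threshold <- function(pwm, calibration_set, max_frequency = 1 / 2000) {
  prof <- scan_profile(pwm, calibration_set, max_frequency)
  tibble(
    matrix_id = pwm$id,
    threshold = prof$threshold,
    achieved_frequency = prof$achieved_frequency,
    target_cap = max_frequency,
    n_hits = prof$n_hits,
    total_bp = prof$total_bp,
    capped = prof$capped
  ) |> structure(class = c("threshold_calibration", "tbl_df", "tbl", "data.frame"))
}

# Single scan of a promoter set retaining everything threshold selection and
# the enrichment sweep need: per-promoter max window scores and the top tail
# of window scores (score, offset, strand) down to the calibration cutoff.
scan_profile <- function(pwm, promoters, max_frequency) {
  enc <- encode_set(promoters)
  L <- length(pwm)
  total_bp <- enc$total_bp
  m_allowed <- floor(total_bp * max_frequency)
  if (!is.finite(max_frequency)) m_allowed <- .Machine$integer.max
  # extra slack so ties at the cut are counted exactly
  k <- min(as.double(m_allowed) + 64, 2 * sum(pmax(enc$lens - L + 1, 0)))
  res <- cpp_scan(enc$codes, pwm_log_odds(pwm), enc$starts, enc$lens,
                  0, as.integer(k))
  scores <- res$score                     # sorted descending
  n_windows <- res$n_windows

  if (n_windows == 0) {
    warn(sprintf("matrix %s: no scannable windows in calibration set", pwm$id))
    return(list(threshold = pwm_score_range(pwm)[["max"]],
                achieved_frequency = 0, n_hits = 0, total_bp = total_bp,
                capped = TRUE, enc = enc, pmax = res$pmax,
                tail_scores = numeric(0), tail_pos = integer(0),
                tail_strand = integer(0)))
  }

  capped <- FALSE
  if (m_allowed >= n_windows) {
    threshold <- scores[length(scores)]   # everything fits under the cap
  } else {
    u <- unique(scores)                   # descending
    cnt <- tabulate(match(scores, u))
    ccnt <- cumsum(cnt)
    ok <- which(ccnt <= m_allowed)
    if (length(ok) == 0) {
      threshold <- u[1]
      capped <- ccnt[1] > m_allowed
      if (capped)
        warn(sprintf(
          "matrix %s: even the maximum score (%.3f bits) exceeds the frequency cap",
          pwm$id, threshold))
    } else {
      threshold <- u[max(ok)]
    }
  }
  n_hits <- sum(scores >= threshold)
  list(threshold = threshold, achieved_frequency = n_hits / total_bp,
       n_hits = n_hits, total_bp = total_bp, capped = capped,
       enc = enc, pmax = res$pmax,
       tail_scores = scores, tail_pos = res$pos, tail_strand = res$strand)
}
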