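#' Build a position weight matrix object
#'
#' A `pwm` bundles the position-specific base counts of a transcription-factor
#' binding motif with the pseudocount and background model used to turn the
#' counts into log2-odds scores.
#'
#' @param counts Numeric matrix, L rows (motif positions) by 4 columns in the
#'   order A, C, G, T; non-negative counts or frequencies.
#' @param id Matrix identifier (e.g. `"I$KAY_01"`).
#' @param tf Transcription-factor name; defaults to the id.
#' @param pseudocount Total pseudocount distributed over the column in
#'   proportion to the background (default 1).
#' @param background Background base probabilities (A, C, G, T); must be
#'   strictly positive and sum to 1. Default uniform.
#' @return An object of class `pwm`.
#' @export
#' @examples
#' m <- pwm(matrix(c(9, 0, 0, 1,
#'                   0, 10, 0, 0), nrow = 2, byrow = TRUE), id = "TOY_01")
#' pwm_consensus(m)
pwm <- function(counts, id, tf = id, pseudocount = 1,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4)
    stop_input("`counts` must have 4 columns (A, C, G, T)")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_input("`counts` must be finite and non-negative")
  if (any(rowSums(counts) == 0))
    stop_input(sprintf("matrix %s has an all-zero column", id))
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop_input("`background` must be 4 strictly positive probabilities summing to 1")
  colnames(counts) <- DNA_BASES
  structure(
    list(id = as.character(id), tf = as.character(tf), counts = counts,
         pseudocount = pseudocount, background = as.numeric(background)),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d, consensus %s\n",
              x$id, x$tf, nrow(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' @export
length.pwm <- function(x) nrow(x$counts)

#' Consensus sequence of a PWM (highest-count base per position)
#' @param x A [pwm()] object.
#' @return A single character string.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 1, which.max)], collapse = "")
}

#' Per-position base probabilities of a PWM
#'
#' Columns are regularised with the pseudocount distributed according to the
#' background, then normalised to sum to 1.
#'
#' @inheritParams pwm_consensus
#' @return L x 4 matrix of probabilities.
#' @export
pwm_probabilities <- function(x) {
  reg <- sweep(x$counts, 2, x$pseudocount * x$background, `+`)
  reg / rowSums(reg)
}

#' Log2-odds score matrix of a PWM
#'
#' Scores are `log2(p(base | position) / background(base))` with the
#' pseudocount-regularised probabilities of [pwm_probabilities()]. The score
#' of a sequence window is the sum over positions, in bits.
#'
#' @inheritParams pwm_consensus
#' @return L x 4 matrix of scores in bits (columns A, C, G, T).
#' @export
pwm_log_odds <- function(x) {
  p <- pwm_probabilities(x)
  log2(sweep(p, 2, x$background, `/`))
}

#' Attainable score range of a PWM
#' @inheritParams pwm_consensus
#' @return Named numeric vector with elements `min` and `max`, in bits.
#' @export
pwm_score_range <- function(x) {
  lo <- pwm_log_odds(x)
  c(min = sum(apply(lo, 1, min)), max = sum(apply(lo, 1, max)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PWM into a long tibble
#' @param x A [pwm()] object.
#' @param ... Unused.
#' @return A tibble with columns `matrix_id`, `position`, `base`, `count`,
#'   `probability`, `score` (bits).
#' @export
tidy.pwm <- function(x, ...) {
  p <- pwm_probabilities(x)
  s <- pwm_log_odds(x)
  tibble(
    matrix_id = x$id,
    position = rep(seq_len(nrow(x$counts)), times = 4),
    base = rep(DNA_BASES, each = nrow(x$counts)),
    count = as.vector(x$counts),
    probability = as.vector(p),
    score = as.vector(s)
  ) |> arrange(.data$position, .data$base)
}

#' Parse TRANSFAC-format matrix files
#'
#' Reads the TRANSFAC flat-file dialect: blocks introduced by `AC`/`ID` lines,
#' a `P0` (or `PO`) header naming the base columns, numbered count rows with
#' an optional trailing consensus letter, and `//` terminators. Both the
#' classic database layout and minimal matrix-only files are accepted.
#'
#' @param path Path to a TRANSFAC-format file, or a character vector of lines.
#' @return A named list of [pwm()] objects (names are the matrix ids).
#' @export
read_transfac <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  pwms <- list()
  id <- NULL; tf <- NULL; rows <- list(); row_lines <- integer()
  in_matrix <- FALSE

  flush_block <- function() {
    if (length(rows) == 0) return()
    counts <- do.call(rbind, rows)
    this_id <- id %||% sprintf("MATRIX_%03d", length(pwms) + 1)
    pwms[[this_id]] <<- pwm(counts, id = this_id, tf = tf %||% this_id)
    id <<- NULL; tf <<- NULL; rows <<- list(); in_matrix <<- FALSE
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" ) next
    tag <- toupper(substr(ln, 1, 2))
    rest <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "//") { flush_block(); next }
    if (tag == "AC") { if (in_matrix) flush_block(); id <- id %||% rest; next }
    if (tag == "ID") { if (in_matrix && length(rows)) flush_block(); id <- rest; next }
    if (tag == "NA") { tf <- rest; next }
    if (tag %in% c("P0", "PO")) { in_matrix <- TRUE; next }
    if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (length(f) < 5 || any(is.na(vals)))
        abort(sprintf("malformed TRANSFAC count row at line %d: '%s'", i, ln),
              class = "promotif_parse_error")
      rows[[length(rows) + 1]] <- vals
      next
    }
  }
  flush_block()
  if (length(pwms) == 0)
    abort("no matrix blocks found", class = "promotif_parse_error")
  pwms
}

#' Write PWMs in TRANSFAC format
#'
#' @param pwms A [pwm()] object or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    writeLines(c(sprintf("AC  %s", m$id),
                 "XX",
                 sprintf("ID  %s", m$id),
                 sprintf("NA  %s", m$tf),
                 "P0      A      C      G      T"), con)
    for (i in seq_len(nrow(m$counts))) {
      writeLines(sprintf("%02d %6.2f %6.2f %6.2f %6.2f %s",
                         i, m$counts[i, 1], m$counts[i, 2], m$counts[i, 3],
                         m$counts[i, 4], DNA_BASES[which.max(m$counts[i, ])]),
                 con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
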