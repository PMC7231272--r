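#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap
#' @importFrom Rcpp sourceCpp
#' @useDynLib promotif, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

# byte -> base code lookup: A,C,G,T -> 0..3 (upper or lower case), else -1
.base_code <- local({
  tb <- rep(-1L, 256L)
  tb[utf8ToInt("A") + 1L] <- 0L; tb[utf8ToInt("a") + 1L] <- 0L
  tb[utf8ToInt("C") + 1L] <- 1L; tb[utf8ToInt("c") + 1L] <- 1L
  tb[utf8ToInt("G") + 1L] <- 2L; tb[utf8ToInt("g") + 1L] <- 2L
  tb[utf8ToInt("T") + 1L] <- 3L; tb[utf8ToInt("t") + 1L] <- 3L
  tb
})

encode_seq <- function(x) {
  .base_code[utf8ToInt(x) + 1L]
}

decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- codes >= 0L
  out[ok] <- DNA_BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Keeps `N` as `N`. Used internally for strand-aware promoter extraction and
#' minus-strand motif planting.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# One root seed, one derived stream per operation tag, so any generator can be
# re-run on its own and still match a full pipeline run.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 9349) %% 2147483563) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Pre-encoded promoter set: one concatenated base-code vector plus per-
# promoter offsets, so repeated scans with different matrices skip the
# string-to-code conversion. The C scan loop is bounded per promoter, so no
# spacer is needed between sequences.
encode_set <- function(promoters) {
  if (inherits(promoters, "promotif_encoded")) return(promoters)
  seqs <- promoter_seqs(promoters)
  lens <- nchar(seqs)
  structure(
    list(ids = names(seqs),
         codes = encode_seq(paste(seqs, collapse = "")),
         starts = as.integer(c(0L, cumsum(lens[-length(lens)]))),
         lens = as.integer(lens),
         total_bp = sum(lens)),
    class = "promotif_encoded")
}

stop_input <- function(msg) abort(msg, class = "promotif_input_error")
stop_config <- function(msg) abort(msg, class = "promotif_config_error")

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(sprintf("`%s` must be a single probability in [0, 1]", name))
  invisible(x)
}

check_composition <- function(comp) {
  if (length(comp) != 4 || any(comp < 0) || abs(sum(comp) - 1) > 1e-9)
    stop_config(
      "`composition` must be 4 non-negative probabilities over A,C,G,T summing to 1")
  invisible(comp)
}
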