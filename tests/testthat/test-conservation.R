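test_that("alignment reading builds correct gap maps", {
  blk <- read_alignment(c(s1 = "AC-GT", s2 = "ACAGT"))
  expect_equal(blk$width, 5)
  expect_equal(blk$maps$s1, c(1, 2, 4, 5))
  expect_equal(blk$maps$s2, 1:5)
  expect_equal(ungapped_seq(blk, "s1"), "ACGT")
  # identity maps for gapless alignments
  blk2 <- read_alignment(c(a = "ACGT", b = "TTTT"))
  expect_equal(blk2$maps$a, 1:4)
  expect_error(read_alignment(c(a = "ACGT", b = "ACG")),
               class = "promotif_parse_error")
  expect_error(read_alignment(c(a = "ACGT")), class = "promotif_input_error")
})

test_that("aligned FASTA and Clustal files are parsed equivalently", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">sp1", "ACGT-ACGT", ">sp2", "ACGTTAC-T"), fa)
  blk <- read_alignment(fa)
  expect_equal(blk$species, c("sp1", "sp2"))
  expect_equal(blk$width, 9)
  expect_equal(ungapped_seq(blk, "sp1"), "ACGTACGT")

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "sp1   ACGT-ACGT", "sp2   ACGTTAC-T"), cl)
  blk2 <- read_alignment(cl)
  expect_equal(blk2$aligned, blk$aligned)
})

test_that("hit coordinates map through gaps and back", {
  # motif at ungapped 2..5 of s1; a gap at column 4 pushes columns right
  blk <- read_alignment(c(s1 = "ACG-TACGT", s2 = "ACGTTACGT"))
  hits <- tibble::tibble(promoter_id = "s1", matrix_id = "m", offset = 2L,
                         strand = "+", score = 1)
  mapped <- map_hits_to_columns(hits, blk, "s1", motif_length = 4)
  expect_equal(mapped$col_start, 3)
  expect_equal(mapped$col_end, 7)
  # a gap in the OTHER species leaves this species' mapping unchanged
  blk2 <- read_alignment(c(s1 = "ACGTACGT-", s2 = "ACGTTACGT"))
  mapped2 <- map_hits_to_columns(hits, blk2, "s1", motif_length = 4)
  expect_equal(mapped2$col_start, 3)
  expect_equal(mapped2$col_end, 6)
  expect_error(map_hits_to_columns(
    tibble::tibble(offset = 7L), blk, "s1", motif_length = 4),
    class = "promotif_input_error")
})

test_that("randomised gap insertion round-trips motif coordinates", {
  set.seed(11)
  for (i in 1:20) {
    ungapped <- random_seq(60, seed = 500 + i)
    n_gaps <- sample(0:15, 1)
    gap_cols <- sort(sample(seq_len(60 + n_gaps), n_gaps))
    gapped <- gapify(ungapped, gap_cols)
    blk <- read_alignment(c(x = gapped, y = strrep("A", 60 + n_gaps)))
    off <- sample(0:(60 - 8), 1)
    hits <- tibble::tibble(promoter_id = "x", matrix_id = "m",
                           offset = off, strand = "+", score = 0)
    mapped <- map_hits_to_columns(hits, blk, "x", motif_length = 8)
    # degapping the spanned columns recovers the motif subsequence
    span <- substr(gapped, mapped$col_start, mapped$col_end)
    expect_equal(gsub("-", "", span), substr(ungapped, off + 1, off + 8))
  }
})

test_that("conservation reports match a scripted gain/loss truth table", {
  species <- paste0("sp", 1:7)
  pwms <- list(toy_pwm_consensus("GATTACAGGC", id = "M_ALL"),
               toy_pwm_consensus("CCGGTTAACG", id = "M_TRIO"))
  script <- tidyr::expand_grid(matrix_id = c("M_ALL", "M_TRIO"),
                               species = species)
  script$present <- script$matrix_id == "M_ALL" |
    script$species %in% c("sp1", "sp2", "sp3")
  orth <- gen_ortholog_promoters(species, pwms, script, seed = 21)
  blk <- read_alignment(orth$sequences)
  thr <- vapply(pwms, function(m) 0.9 * pwm_score_range(m)[["max"]],
                double(1))
  names(thr) <- c("M_ALL", "M_TRIO")
  rep <- conservation_matrix(blk, pwms, thr)

  truth_wide <- tidyr::pivot_wider(orth$truth[, c("matrix_id", "species",
                                                  "present")],
                                   names_from = "matrix_id",
                                   values_from = "present")
  got <- rep$presence
  expect_equal(got$species, species)
  expect_equal(got$M_ALL, truth_wide$M_ALL)
  expect_equal(got$M_TRIO, truth_wide$M_TRIO)
  cons <- rep$conserved
  expect_true(cons$positionally_conserved[cons$matrix_id == "M_ALL"])
  expect_equal(cons$n_present[cons$matrix_id == "M_ALL"], 7)
  expect_equal(cons$n_present[cons$matrix_id == "M_TRIO"], 3)
  # every merged window overlaps at least one hit of its matrix
  for (i in seq_len(nrow(rep$windows))) {
    w <- rep$windows[i, ]
    h <- rep$hits[rep$hits$matrix_id == w$matrix_id, ]
    expect_true(any(h$col_start <= w$col_end & h$col_end >= w$col_start))
  }
})

test_that("an absent motif yields an all-absent row and no windows", {
  species <- c("s1", "s2", "s3")
  pwms <- list(toy_pwm_consensus("GGGGCCCCAA", id = "MX"))
  script <- tibble::tibble(matrix_id = "MX", species = species,
                           present = FALSE)
  orth <- gen_ortholog_promoters(species, pwms, script, seed = 22)
  rep <- conservation_matrix(read_alignment(orth$sequences), pwms,
                             c(MX = 0.9 * pwm_score_range(pwms[[1]])[["max"]]))
  expect_false(any(rep$presence$MX))
  expect_equal(nrow(rep$windows), 0)
  expect_false(rep$conserved$positionally_conserved)
})

test_that("raising the merge tolerance never shrinks window species sets", {
  species <- paste0("sp", 1:5)
  pwms <- list(toy_pwm_consensus("GATTACAGGC", id = "MA"))
  script <- tibble::tibble(matrix_id = "MA", species = species,
                           present = TRUE)
  orth <- gen_ortholog_promoters(species, pwms, script,
                                 substitution_rate = 0.15, seed = 23)
  blk <- read_alignment(orth$sequences)
  thr <- c(MA = 0.9 * pwm_score_range(pwms[[1]])[["max"]])
  for (tol in list(c(0, 10), c(10, 50))) {
    lo <- conservation_matrix(blk, pwms, thr, window_merge_tolerance = tol[1])
    hi <- conservation_matrix(blk, pwms, thr, window_merge_tolerance = tol[2])
    max_lo <- max(c(0, lo$windows$n_species))
    max_hi <- max(c(0, hi$windows$n_species))
    expect_gte(max_hi, max_lo)
  }
})
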