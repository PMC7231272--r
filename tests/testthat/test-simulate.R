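test_that("background promoters follow the requested composition exactly", {
  p <- gen_background_promoters(1, 10, composition = c(1, 0, 0, 0), seed = 1)
  expect_equal(p$seq, "AAAAAAAAAA")

  big <- gen_background_promoters(200, 500, seed = 2)
  tab <- table(strsplit(paste(big$seq, collapse = ""), ""))
  freqs <- as.numeric(tab[BASES]) / sum(tab)
  expect_true(all(abs(freqs - 0.25) < 0.01))

  expect_identical(gen_background_promoters(10, 50, seed = 7),
                   gen_background_promoters(10, 50, seed = 7))
  expect_false(identical(gen_background_promoters(10, 50, seed = 7)$seq,
                         gen_background_promoters(10, 50, seed = 8)$seq))
  expect_error(gen_background_promoters(5, 10, composition = c(1, 1, 0, 0)),
               class = "promotif_config_error")
})

test_that("motif planting writes every logged site verbatim", {
  m <- toy_pwm_consensus("GATTACA")
  p <- gen_background_promoters(50, 200, seed = 3)
  out <- plant_motifs(p, m, plant_probability = 1, sites_per_promoter = 2,
                      seed = 4)
  expect_equal(nrow(out$log), 100)
  cons <- pwm_consensus(m)
  for (i in seq_len(nrow(out$log))) {
    row <- out$log[i, ]
    s <- out$promoters$seq[out$promoters$gene_id == row$promoter_id]
    written <- substr(s, row$offset + 1, row$offset + nchar(cons))
    expect_equal(written,
                 if (row$strand == "+") cons else revcomp(cons))
  }
  # sites within a promoter never overlap
  by_prom <- split(out$log$offset, out$log$promoter_id)
  for (off in by_prom)
    if (length(off) > 1)
      expect_gte(min(abs(diff(sort(off)))), nchar(cons))
})

test_that("plant probability 0 leaves promoters untouched", {
  p <- gen_background_promoters(10, 100, seed = 5)
  out <- plant_motifs(p, random_pwm(8, seed = 6), 0, seed = 7)
  expect_identical(out$promoters$seq, p$seq)
  expect_equal(nrow(out$log), 0)
})

test_that("strand assignment is balanced at the configured probability", {
  m <- toy_pwm_consensus("ACGTACGT")
  p <- gen_background_promoters(1000, 60, seed = 8)
  out <- plant_motifs(p, m, 1, 1, strand_probability = 0.5, seed = 9)
  frac <- mean(out$log$strand == "+")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("noiseless block effects produce exact fold changes", {
  sim <- gen_expression_matrix(
    30, 8, rep(c("ctrl", "stress"), each = 4),
    modules = list(list(genes = 1:10, condition = "stress", effect = 2)),
    noise_sd = 0, seed = 10)
  lfc <- rowMeans(sim$expr[, 5:8]) - rowMeans(sim$expr[, 1:4])
  expect_equal(unname(lfc[1:10]), rep(2, 10))
  expect_equal(unname(lfc[11:30]), rep(0, 20))
})

test_that("module genes correlate more within than between blocks", {
  sim <- gen_expression_matrix(
    100, 12, rep(c("ctrl", "stress"), each = 6),
    modules = list(list(genes = 1:30, condition = "stress", effect = 2)),
    noise_sd = 0.3, seed = 11)
  r <- stats::cor(t(sim$expr))
  within <- mean(r[1:30, 1:30][upper.tri(diag(30))])
  between <- mean(r[1:30, 31:100])
  expect_gt(within, between)
  expect_gt(within, 0.8)
  expect_error(gen_expression_matrix(
    50, 4, rep(c("a", "b"), 2),
    modules = list(list(genes = 1:10, condition = "a", effect = 1),
                   list(genes = 5:15, condition = "b", effect = 1))),
    class = "promotif_config_error")
})

test_that("latent module factors hit the requested correlation", {
  sim <- gen_expression_matrix(
    40, 50, rep("c", 50),
    modules = list(list(genes = 1:20, condition = "c", effect = 0)),
    noise_sd = 0.5, module_cor = 0.8, seed = 12)
  r <- stats::cor(t(sim$expr[1:20, ]))
  expect_equal(mean(r[upper.tri(r)]), 0.8, tolerance = 0.08)
})

test_that("ortholog promoters follow the gain/loss script", {
  species <- paste0("sp", 1:7)
  pwms <- list(toy_pwm_consensus("GATTACAG", id = "MA"),
               toy_pwm_consensus("CCGGTTAA", id = "MB"))
  script <- tidyr::expand_grid(matrix_id = c("MA", "MB"), species = species)
  script$present <- script$matrix_id == "MA" |
    script$species %in% c("sp1", "sp2", "sp3")
  orth <- gen_ortholog_promoters(species, pwms, script,
                                 substitution_rate = 0.05, seed = 13)
  expect_equal(orth$sequences$species, species)
  for (i in seq_len(nrow(orth$truth))) {
    row <- orth$truth[i, ]
    s <- orth$sequences$seq[orth$sequences$species == row$species]
    word <- pwm_consensus(pwms[[match(row$matrix_id, c("MA", "MB"))]])
    found <- substr(s, row$offset + 1, row$offset + nchar(word)) == word
    if (row$present) expect_true(found)
  }
})

test_that("zero substitution rate keeps scaffolds identical outside motifs", {
  species <- c("s1", "s2", "s3")
  pwms <- list(toy_pwm_consensus("GATTACAG", id = "MA"))
  script <- tibble::tibble(matrix_id = "MA", species = species,
                           present = c(TRUE, FALSE, FALSE))
  orth <- gen_ortholog_promoters(species, pwms, script,
                                 substitution_rate = 0, seed = 14)
  expect_equal(orth$sequences$seq[2], orth$sequences$seq[3])
  o <- orth$truth$offset[1]
  s1 <- orth$sequences$seq[1]; s2 <- orth$sequences$seq[2]
  expect_equal(substr(s1, o + 9, nchar(s1)), substr(s2, o + 9, nchar(s2)))
  expect_equal(substr(s1, 1, o), substr(s2, 1, o))
})

test_that("Ct tables encode fold changes as exact cycle shifts", {
  fc <- matrix(c(1, 4), 1, 2, dimnames = list("tg", c("ctrl", "stress")))
  ct <- gen_ct_table("tg", c("r1", "r2", "r3"), c("ctrl", "stress"),
                     fold_changes = fc, ct_noise_sd = 0, n_replicates = 4,
                     seed = 15)
  m <- tapply(ct$ct, list(ct$gene_id, ct$group), mean)
  expect_equal(m["tg", "ctrl"] - m["tg", "stress"], 2)  # log2(4)
  expect_equal(unname(m["r1", ]), unname(m["r2", ]))
  bad_fc <- matrix(c(2, 2), 1, 2, dimnames = list("r1", c("ctrl", "stress")))
  expect_error(gen_ct_table("tg", c("r1", "r2", "r3"), c("ctrl", "stress"),
                            fold_changes = bad_fc),
               class = "promotif_config_error")
})
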