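#' Generate background promoter sequences
#'
#' Sequences are drawn i.i.d. base-by-base from a background composition,
#' emulating a reference promoter sample with no planted signal.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp.
#' @param composition Probabilities over A, C, G, T (must sum to 1); default
#'   uniform.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param prefix Gene id prefix (ids are `<prefix>_00001`, ...).
#' @return A promoter tibble with columns `gene_id` and `seq`.
#' @export
#' @examples
#' gen_background_promoters(3, 20, seed = 1)
gen_background_promoters <- function(n, length, composition = rep(0.25, 4),
                                     seed = 1, prefix = "bg") {
  if (length <= 0) stop_config("`length` must be positive")
  check_composition(composition)
  with_seed(derive_seed(seed, "background_promoters"), {
    big <- paste(sample(DNA_BASES, n * length, replace = TRUE,
                        prob = composition), collapse = "")
    seqs <- substring(big, (seq_len(n) - 1) * length + 1, seq_len(n) * length)
  })
  tibble(gene_id = sprintf("%s_%05d", prefix, seq_len(n)), seq = seqs)
}

#' Plant motif instances into promoters
#'
#' Each promoter is selected with probability `plant_probability`; selected
#' promoters receive `sites_per_promoter` sites written in place at
#' non-overlapping uniform-random offsets. Each site is sampled column-wise
#' from the PWM's probability matrix; with probability `1 - strand_probability`
#' the site is written as its reverse complement (a minus-strand site). The
#' returned plant log is exhaustive: every planted site appears exactly once,
#' with its 0-based offset and strand.
#'
#' @param promoters Promoter tibble (columns `gene_id`, `seq`).
#' @param pwm A [pwm()] object supplying the site model.
#' @param plant_probability Probability that a promoter receives sites.
#' @param sites_per_promoter Number of sites per selected promoter (a single
#'   integer, or a vector of probabilities over counts 1, 2, ...).
#' @param strand_probability Probability of a forward-strand placement
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list with `promoters` (the modified tibble) and `log`, a tibble
#'   of (`promoter_id`, `matrix_id`, `offset`, `strand`, `site`).
#' @export
plant_motifs <- function(promoters, pwm, plant_probability,
                         sites_per_promoter = 1, strand_probability = 0.5,
                         seed = 1) {
  check_probability(plant_probability, "plant_probability")
  check_probability(strand_probability, "strand_probability")
  L <- length(pwm)
  if (any(nchar(promoters$seq) < L))
    stop_config("motif longer than some promoters")
  probs <- pwm_probabilities(pwm)

  with_seed(derive_seed(seed, "plant_motifs"), {
    chosen <- stats::runif(nrow(promoters)) < plant_probability
    log_rows <- list()
    seqs <- promoters$seq
    for (i in which(chosen)) {
      plen <- nchar(seqs[i])
      n_sites <- if (length(sites_per_promoter) == 1) {
        as.integer(sites_per_promoter)
      } else {
        sample.int(length(sites_per_promoter), 1, prob = sites_per_promoter)
      }
      if (n_sites == 0) next
      offsets <- integer(0)
      attempts <- 0
      while (length(offsets) < n_sites) {
        attempts <- attempts + 1
        if (attempts > 1000)
          stop_config(sprintf(
            "could not place %d non-overlapping sites in promoter %s",
            n_sites, promoters$gene_id[i]))
        cand <- sample.int(plen - L + 1, 1) - 1L   # 0-based
        if (!any(abs(offsets - cand) < L)) offsets <- c(offsets, cand)
      }
      for (o in offsets) {
        site <- paste(DNA_BASES[apply(probs, 1, function(p)
          sample.int(4, 1, prob = p))], collapse = "")
        fwd <- stats::runif(1) < strand_probability
        written <- if (fwd) site else revcomp(site)
        substr(seqs[i], o + 1, o + L) <- written
        log_rows[[length(log_rows) + 1]] <- tibble(
          promoter_id = promoters$gene_id[i], matrix_id = pwm$id,
          offset = as.integer(o), strand = if (fwd) "+" else "-",
          site = site)
      }
    }
  })
  plant_log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(promoter_id = character(), matrix_id = character(),
           offset = integer(), strand = character(), site = character())
  out <- promoters
  out$seq <- seqs
  list(promoters = out, log = plant_log)
}

#' Generate a log2 expression matrix with planted co-expression modules
#'
#' Entries are `baseline + block effect + N(0, noise_sd)`. A module is a gene
#' block with a condition-specific effect: its genes are shifted by `effect`
#' log2 units in all samples of the named condition, which makes them
#' positively correlated across samples whenever conditions vary.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param conditions Character vector of length `n_samples` assigning each
#'   sample to a condition.
#' @param modules List of modules, each a list with elements `genes` (integer
#'   indices or gene ids), `condition` (a condition name), and `effect`
#'   (log2 shift). Gene blocks must be disjoint.
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param module_cor Target within-module correlation induced by a shared
#'   per-sample latent factor (0 disables the factor; condition effects add
#'   further correlation on top). A module can override via its own `cor`
#'   element.
#' @param baseline Baseline log2 expression (default 7).
#' @param seed Integer seed.
#' @return A list with `expr` (genes x samples numeric matrix, dimnames set),
#'   `conditions` (named by sample), and `truth` (tibble of gene, module).
#' @export
gen_expression_matrix <- function(n_genes, n_samples, conditions, modules =
                                    list(), noise_sd = 0.5, module_cor = 0,
                                  baseline = 7, seed = 1) {
  if (length(conditions) != n_samples)
    stop_config("`conditions` must have one entry per sample")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  module_genes <- map(modules, function(m) {
    g <- m$genes
    if (is.character(g)) match(g, gene_ids) else as.integer(g)
  })
  if (length(module_genes) > 1 &&
      anyDuplicated(unlist(module_genes)))
    stop_config("module gene blocks must be disjoint")
  for (m in modules)
    if (!m$condition %in% conditions)
      stop_config(sprintf("condition '%s' not present in samples", m$condition))

  with_seed(derive_seed(seed, "expression_matrix"), {
    expr <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                   nrow = n_genes) + baseline
    for (k in seq_along(modules)) {
      r <- modules[[k]]$cor %||% module_cor
      check_probability(r, "module_cor")
      if (r >= 1) stop_config("`module_cor` must be < 1")
      if (r > 0 && noise_sd > 0) {
        # shared factor with loading c: pairwise r = c^2 / (c^2 + noise_sd^2)
        loading <- noise_sd * sqrt(r / (1 - r))
        f <- stats::rnorm(n_samples)
        expr[module_genes[[k]], ] <- expr[module_genes[[k]], ] +
          rep(loading * f, each = length(module_genes[[k]]))
      }
    }
  })
  for (k in seq_along(modules)) {
    cols <- which(conditions == modules[[k]]$condition)
    expr[module_genes[[k]], cols] <- expr[module_genes[[k]], cols] +
      modules[[k]]$effect
  }
  dimnames(expr) <- list(gene_ids, sample_ids)
  names(conditions) <- sample_ids
  truth <- tibble(
    gene_id = gene_ids[unlist(module_genes) %||% integer(0)],
    module = rep(seq_along(modules), lengths(module_genes)))
  list(expr = expr, conditions = conditions, truth = truth)
}

#' Generate ortholog promoter sets with scripted motif gain and loss
#'
#' All species share one ancestral scaffold sequence, independently mutated
#' per species at a per-base substitution rate; motifs are then written at a
#' shared (homologous) position in every species the script marks present.
#' Because only substitutions are applied, the sequences are naturally
#' aligned (gapless, equal length) and can be fed directly to
#' [conservation_matrix()].
#'
#' @param species Ordered character vector of species names.
#' @param pwms Named list of [pwm()] objects, one per scripted motif.
#' @param script Data frame with columns `matrix_id`, `species`, `present`
#'   (logical). Matrices absent from the script are treated as absent.
#' @param scaffold_length Scaffold length in bp (default 1000, matching a
#'   -881..+119 conserved promoter window).
#' @param substitution_rate Per-base substitution probability per species
#'   (default 0.05).
#' @param positions Optional named integer vector of 0-based motif offsets;
#'   defaults to evenly spaced positions.
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble `species`, `seq` in input order)
#'   and `truth` (the normalised script tibble with planted offsets).
#' @export
gen_ortholog_promoters <- function(species, pwms, script,
                                   scaffold_length = 1000,
                                   substitution_rate = 0.05,
                                   positions = NULL, seed = 1) {
  script <- as_tibble(script)
  names(pwms) <- map_chr(pwms, "id")
  if (!all(c("matrix_id", "species", "present") %in% names(script)))
    stop_config("`script` needs columns matrix_id, species, present")
  if (!all(script$species %in% species))
    stop_config("script names species not in `species`")
  if (!all(script$matrix_id %in% names(pwms)))
    stop_config("script names matrices not in `pwms`")
  check_probability(substitution_rate, "substitution_rate")

  matrix_ids <- unique(script$matrix_id)
  Ls <- map_int(pwms[matrix_ids], length)
  if (is.null(positions)) {
    gap <- scaffold_length %/% (length(matrix_ids) + 1)
    positions <- seq_along(matrix_ids) * gap
    names(positions) <- matrix_ids
  }
  if (any(positions + Ls[names(positions)] > scaffold_length))
    stop_config("motif positions run past the scaffold")

  with_seed(derive_seed(seed, "ortholog_promoters"), {
    scaffold <- paste(sample(DNA_BASES, scaffold_length, replace = TRUE),
                      collapse = "")
    seqs <- vapply(species, function(sp) {
      s <- strsplit(scaffold, "")[[1]]
      mut <- stats::runif(scaffold_length) < substitution_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    # consensus site per matrix, identical across species => homologous
    sites <- vapply(pwms[matrix_ids], pwm_consensus, character(1))
  })
  for (mid in matrix_ids) {
    rows <- script[script$matrix_id == mid & script$present, ]
    for (sp in rows$species) {
      o <- positions[[mid]]
      substr(seqs[sp], o + 1, o + nchar(sites[[mid]])) <- sites[[mid]]
    }
  }
  truth <- script |>
    mutate(offset = as.integer(positions[.data$matrix_id])) |>
    arrange(match(.data$species, species), .data$matrix_id)
  list(sequences = tibble(species = species, seq = unname(seqs[species])),
       truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Ct values follow `base_ct - log2(relative expression) + N(0, ct_noise_sd)`
#' so a fold change of 4 in a group shifts Ct down by exactly 2 cycles.
#' Reference genes must have fold change 1 in every group.
#'
#' @param genes Character vector of target gene ids.
#' @param references Character vector of reference gene ids.
#' @param groups Character vector of group labels.
#' @param fold_changes Matrix or data frame of true fold changes, genes
#'   (rows, named) by groups (columns, named); missing genes/groups default
#'   to 1.
#' @param ct_noise_sd Replicate noise in cycles (default 0.2).
#' @param n_replicates Biological replicates per group (default 6).
#' @param base_ct Baseline Ct in cycles (default 22).
#' @param seed Integer seed.
#' @return A Ct tibble: `gene_id`, `sample_id`, `group`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(genes, references, groups, fold_changes = NULL,
                         ct_noise_sd = 0.2, n_replicates = 6, base_ct = 22,
                         seed = 1) {
  all_genes <- union(genes, references)
  fc <- matrix(1, nrow = length(all_genes), ncol = length(groups),
               dimnames = list(all_genes, groups))
  if (!is.null(fold_changes)) {
    fold_changes <- as.matrix(fold_changes)
    if (any(rownames(fold_changes) %in% references))
      if (any(fold_changes[intersect(rownames(fold_changes), references), ] != 1))
        stop_config("reference genes must have fold change 1 in all groups")
    fc[rownames(fold_changes), colnames(fold_changes)] <- fold_changes
  }
  if (any(fc <= 0)) stop_config("fold changes must be positive")

  grid <- tidyr::expand_grid(group = groups,
                             replicate = seq_len(n_replicates),
                             gene_id = all_genes)
  with_seed(derive_seed(seed, "ct_table"), {
    noise <- stats::rnorm(nrow(grid), 0, ct_noise_sd)
  })
  grid |>
    mutate(
      sample_id = sprintf("%s_r%d", .data$group, .data$replicate),
      ct = base_ct - log2(fc[cbind(.data$gene_id, .data$group)]) + noise
    ) |>
    select("gene_id", "sample_id", "group", "replicate", "ct")
}

#' Generate a random, well-peaked PWM for simulations
#'
#' Each column concentrates most of its count mass on one random base, giving
#' an informative motif whose consensus is recoverable by scanning.
#'
#' @param length Motif length (default 8).
#' @param id Matrix id.
#' @param sharpness Fraction of counts on the dominant base (default 0.85).
#' @param total Column count total (default 20).
#' @param seed Integer seed.
#' @return A [pwm()] object.
#' @export
random_pwm <- function(length = 8, id = "SIM_01", sharpness = 0.85,
                       total = 20, seed = 1) {
  with_seed(derive_seed(seed, paste0("random_pwm_", id)), {
    dom <- sample.int(4, length, replace = TRUE)
    counts <- matrix(total * (1 - sharpness) / 3, nrow = length, ncol = 4)
    counts[cbind(seq_len(length), dom)] <- total * sharpness
  })
  pwm(counts, id = id)
}
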