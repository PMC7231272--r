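#' Read a multiple alignment of ortholog promoters
#'
#' Accepts aligned FASTA or Clustal files, a named character vector of
#' equal-length gapped sequences, or the `sequences` tibble produced by
#' [gen_ortholog_promoters()]. Builds, per species, the map from ungapped
#' positions to alignment columns.
#'
#' @param x File path, named character vector, or tibble with `species` and
#'   `seq` columns.
#' @param format `"fasta"` or `"clustal"`; guessed from the file when
#'   omitted.
#' @return A list of class `alignment_block`: `species` (in input order),
#'   `aligned` (named gapped sequences), `maps` (per species, integer vector
#'   mapping ungapped position 1..n to 1-based alignment column) and `width`.
#' @export
read_alignment <- function(x, format = NULL) {
  if (is.data.frame(x)) {
    aligned <- stats::setNames(toupper(x$seq), x$species)
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    format <- format %||%
      (if (grepl("^CLUSTAL", readLines(x, n = 1), ignore.case = TRUE))
        "clustal" else "fasta")
    if (format == "clustal") {
      ss <- parse_clustal(readLines(x))
    } else {
      ss <- as.character(Biostrings::readBStringSet(x))
    }
    aligned <- toupper(ss)
    names(aligned) <- sub("\\s.*$", "", names(aligned))
  } else if (is.character(x) && !is.null(names(x))) {
    aligned <- toupper(x)
  } else {
    stop_input("`x` must be an alignment file, named sequences, or a tibble")
  }
  if (length(aligned) < 2)
    stop_input("an alignment needs at least 2 sequences")
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1)
    abort(sprintf("ragged alignment: widths %s",
                  paste(unique(widths), collapse = ", ")),
          class = "promotif_parse_error")
  maps <- lapply(aligned, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
  })
  structure(list(species = names(aligned), aligned = aligned, maps = maps,
                 width = unname(widths[1])),
            class = "alignment_block")
}

# Minimal Clustal parser: header line, then blocks of "<name> <chunk>"
# rows; conservation rows (only *:. and spaces) and blank lines are skipped.
parse_clustal <- function(lines) {
  body <- lines[-1]
  body <- body[trimws(body) != ""]
  body <- body[!grepl("^[\\s*:.]+$", body, perl = TRUE)]
  out <- list()
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2) next
    out[[f[1]]] <- paste0(out[[f[1]]] %||% "", f[2])
  }
  if (length(out) == 0)
    abort("no sequences found in Clustal file", class = "promotif_parse_error")
  unlist(out)
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d species, %d columns\n",
              length(x$species), x$width))
  invisible(x)
}

#' Ungapped sequence of one species in an alignment
#' @param block An `alignment_block`.
#' @param species Species id.
#' @return The degapped sequence (character scalar).
#' @export
ungapped_seq <- function(block, species) {
  gsub("-", "", block$aligned[[species]], fixed = TRUE)
}

#' Map motif hits from ungapped promoter coordinates to alignment columns
#'
#' Each hit occupying ungapped positions `offset .. offset + L - 1` (0-based)
#' of one species' promoter maps to the inclusive column interval
#' `[column(first base), column(last base)]`; gaps inside the motif in other
#' rows simply widen the interval.
#'
#' @param hits Hit tibble from [scan_pwm()] with `offset` and `score`
#'   columns, plus a `width` attribute or `motif_length` argument.
#' @param block An `alignment_block`.
#' @param species Species whose ungapped coordinates the hits use.
#' @param motif_length Motif length in bp.
#' @return The hits with added 1-based `col_start` and `col_end` columns.
#' @export
map_hits_to_columns <- function(hits, block, species, motif_length) {
  map <- block$maps[[species]]
  if (is.null(map)) stop_input(sprintf("species '%s' not in alignment", species))
  if (nrow(hits) > 0 && any(hits$offset + motif_length > length(map)))
    stop_input("hit runs past the species' ungapped length")
  hits$col_start <- map[hits$offset + 1L]
  hits$col_end <- map[hits$offset + motif_length]
  hits
}

#' Cross-species motif presence and positional conservation
#'
#' Scans every species' ungapped promoter with each PWM at its threshold,
#' maps the hits into alignment columns, and merges hit windows across
#' species when their column intervals overlap or lie within
#' `window_merge_tolerance` columns. A motif is positionally conserved when a
#' single merged window contains hits from every species that has the motif
#' at all.
#'
#' @param block An `alignment_block` (see [read_alignment()]).
#' @param pwms List of [pwm()] objects.
#' @param thresholds Named numeric vector of per-matrix score thresholds
#'   (bits); typically each matrix's calibrated threshold. A single unnamed
#'   value is recycled.
#' @param window_merge_tolerance Maximum column gap between merged windows
#'   (default 10).
#' @param tree Optional `ape::phylo` tree; when given, report rows follow the
#'   tree's tip order.
#' @return A list of class `conservation_report`: `presence` (tibble species
#'   x matrix, logical), `windows` (tibble `matrix_id`, `window`,
#'   `col_start`, `col_end`, `species`, `n_species`), `conserved` (tibble
#'   `matrix_id`, `n_present`, `positionally_conserved`), and `hits` (all
#'   mapped hits).
#' @export
conservation_matrix <- function(block, pwms, thresholds,
                                window_merge_tolerance = 10, tree = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  ids <- map_chr(pwms, "id")
  names(pwms) <- ids
  if (is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length.out = length(ids)), ids)
  }
  if (!all(ids %in% names(thresholds)))
    stop_input("`thresholds` must cover every matrix id")

  species <- block$species
  if (!is.null(tree)) {
    tips <- intersect(tree$tip.label, species)
    species <- c(tips, setdiff(species, tips))
  }

  all_hits <- map(ids, function(mid) {
    m <- pwms[[mid]]
    map(species, function(sp) {
      seqs <- stats::setNames(ungapped_seq(block, sp), sp)
      h <- scan_pwm(seqs, m, thresholds[[mid]])
      if (nrow(h) == 0) return(NULL)
      h <- map_hits_to_columns(h, block, sp, length(m))
      h$species <- sp
      h
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(all_hits) == 0)
    all_hits <- tibble(promoter_id = character(), matrix_id = character(),
                       offset = integer(), strand = character(),
                       score = double(), col_start = integer(),
                       col_end = integer(), species = character())

  presence <- tidyr::expand_grid(species = species, matrix_id = ids) |>
    left_join(
      all_hits |> count(.data$species, .data$matrix_id, name = "n_hits"),
      by = c("species", "matrix_id")) |>
    mutate(present = !is.na(.data$n_hits)) |>
    select("species", "matrix_id", "present") |>
    tidyr::pivot_wider(names_from = "matrix_id", values_from = "present")

  windows <- map(ids, function(mid) {
    h <- all_hits[all_hits$matrix_id == mid, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    merge_windows(h, window_merge_tolerance) |> mutate(matrix_id = mid)
  }) |> bind_rows()
  if (nrow(windows) == 0)
    windows <- tibble(matrix_id = character(), window = integer(),
                      col_start = integer(), col_end = integer(),
                      species = list(), n_species = integer())

  conserved <- map(ids, function(mid) {
    pres_sp <- all_hits$species[all_hits$matrix_id == mid]
    pres_sp <- unique(pres_sp)
    wins <- windows[windows$matrix_id == mid, , drop = FALSE]
    cons <- length(pres_sp) > 0 &&
      any(map_lgl(wins$species, function(s) all(pres_sp %in% s)))
    tibble(matrix_id = mid, n_present = length(pres_sp),
           positionally_conserved = cons)
  }) |> bind_rows()

  structure(list(presence = presence, windows = windows, conserved = conserved,
                 hits = all_hits, tolerance = window_merge_tolerance),
            class = "conservation_report")
}

merge_windows <- function(hits, tolerance) {
  h <- hits[order(hits$col_start, hits$col_end), , drop = FALSE]
  win_id <- integer(nrow(h))
  cur <- 1L; cur_end <- h$col_end[1]
  win_id[1] <- 1L
  if (nrow(h) > 1) {
    for (i in 2:nrow(h)) {
      if (h$col_start[i] <= cur_end + tolerance) {
        cur_end <- max(cur_end, h$col_end[i])
      } else {
        cur <- cur + 1L
        cur_end <- h$col_end[i]
      }
      win_id[i] <- cur
    }
  }
  h$window <- win_id
  h |>
    group_by(.data$window) |>
    summarise(col_start = min(.data$col_start), col_end = max(.data$col_end),
              species = list(sort(unique(.data$species))),
              n_species = length(unique(.data$species)), .groups = "drop")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %d species x %d matrices, %d merged window(s)\n",
              nrow(x$presence), nrow(x$conserved), nrow(x$windows)))
  print(x$conserved)
  invisible(x)
}

#' @export
tidy.conservation_report <- function(x, ...) {
  x$presence |>
    tidyr::pivot_longer(-"species", names_to = "matrix_id",
                        values_to = "present")
}

#' @export
glance.conservation_report <- function(x, ...) {
  tibble(n_species = nrow(x$presence),
         n_matrices = nrow(x$conserved),
         n_conserved = sum(x$conserved$positionally_conserved),
         merge_tolerance = x$tolerance)
}

#' Presence/absence tile plot of motifs across species
#'
#' @param object A `conservation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_report <- function(object, ...) {
  d <- tidy(object)
  d$species <- factor(d$species, levels = rev(object$presence$species))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$matrix_id, y = .data$species,
                                  fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkgreen",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "motif present") +
    ggplot2::theme_minimal()
}
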