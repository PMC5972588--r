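#' Canonicalize unordered gene pairs
#'
#' Pairs of genes are unordered; every operation in the package works on the
#' canonical form with `gene_a <= gene_b` lexicographically. Self-pairs are
#' dropped.
#'
#' @param pairs tibble with `gene_a`, `gene_b` (other columns kept).
#' @return Tibble with canonical, deduplicated pairs.
#' @export
canonicalize_pairs <- function(pairs) {
  pairs |>
    dplyr::mutate(
      .lo = pmin(.data$gene_a, .data$gene_b),
      .hi = pmax(.data$gene_a, .data$gene_b),
      gene_a = .data$.lo, gene_b = .data$.hi
    ) |>
    dplyr::select(-".lo", -".hi") |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a complex catalogue TSV
#'
#' Long format: one row per membership, columns `complex_id` and `gene_id`
#' (tab-separated, `#` comments allowed).
#' @param path file path or character vector of lines.
#' @return Tibble (`complex_id`, `gene_id`).
#' @export
read_complexes <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  tibble::tibble(
    complex_id = vapply(parts, `[`, character(1), 1),
    gene_id = vapply(parts, `[`, character(1), 2)
  ) |> dplyr::distinct()
}

#' Read a CYC2008-format complex catalogue
#'
#' The CYC2008 v2.0 distribution is a tab-separated table whose first column
#' is the ORF systematic name and whose `Complex` column names the complex;
#' rows belonging to one complex repeat the complex name. A header row is
#' expected.
#'
#' @param path file path.
#' @param orf_col,complex_col column names in the header.
#' @return Tibble (`complex_id`, `gene_id`).
#' @export
read_cyc2008 <- function(path, orf_col = "ORF", complex_col = "Complex") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(orf_col, complex_col) %in% names(df))) {
    stop("expected columns ", orf_col, " and ", complex_col,
         " in CYC2008 table; found: ", paste(names(df), collapse = ", "))
  }
  tibble::tibble(
    complex_id = as.character(df[[complex_col]]),
    gene_id = as.character(df[[orf_col]])
  ) |>
    dplyr::filter(!is.na(.data$complex_id), nzchar(.data$complex_id)) |>
    dplyr::distinct()
}

#' Summarise complex sizes
#' @param complexes tibble (`complex_id`, `gene_id`).
#' @return One-row tibble with `n_complexes`, `min_size`, `max_size`,
#'   `median_size`, `n_size2` and `n_multi_complex_genes` (genes in more
#'   than one complex).
#' @export
complex_summary <- function(complexes) {
  sizes <- complexes |> dplyr::count(.data$complex_id, name = "size")
  tibble::tibble(
    n_complexes = nrow(sizes),
    n_genes = dplyr::n_distinct(complexes$gene_id),
    min_size = min(sizes$size),
    max_size = max(sizes$size),
    median_size = stats::median(sizes$size),
    n_size2 = sum(sizes$size == 2),
    n_multi_complex_genes = complexes |>
      dplyr::distinct(.data$complex_id, .data$gene_id) |>
      dplyr::count(.data$gene_id) |>
      dplyr::filter(.data$n > 1) |> nrow()
  )
}

#' Matrix expansion of a complex catalogue
#'
#' Every unordered pair of members of the same complex becomes a positive
#' co-complex interaction; pairs arising from several overlapping complexes
#' are deduplicated with all contributing complex ids kept as provenance.
#' Complexes with fewer than two members are skipped with a warning.
#'
#' @param complexes tibble (`complex_id`, `gene_id`).
#' @return Interaction tibble (`gene_a`, `gene_b`, `label = "positive"`,
#'   `complexes` = ;-separated contributing complex ids).
#' @export
matrix_expand <- function(complexes) {
  complexes <- dplyr::distinct(complexes, .data$complex_id, .data$gene_id)
  sizes <- complexes |> dplyr::count(.data$complex_id)
  small <- sizes$complex_id[sizes$n < 2]
  if (length(small) > 0) {
    warning(length(small), " complex(es) with <2 members skipped: ",
            paste(utils::head(small, 3), collapse = ", "))
    complexes <- complexes[!complexes$complex_id %in% small, ]
  }
  if (nrow(complexes) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          label = character(), complexes = character()))
  }
  by_cx <- split(complexes$gene_id, complexes$complex_id)
  pairs <- purrr::imap_dfr(by_cx, function(members, cx) {
    members <- sort(members)
    idx <- utils::combn(length(members), 2)
    tibble::tibble(gene_a = members[idx[1, ]], gene_b = members[idx[2, ]],
                   complex_id = cx)
  })
  pairs |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      complexes = paste(sort(unique(.data$complex_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = "positive") |>
    dplyr::select("gene_a", "gene_b", "label", "complexes") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Spoke expansion of a complex catalogue
#'
#' The conservative alternative to matrix expansion: only bait-prey pairs
#' are emitted (bait versus every other member).
#'
#' @param complexes tibble (`complex_id`, `gene_id`).
#' @param baits named character vector or tibble (`complex_id`, `gene_id`)
#'   naming one bait per complex; a bait not belonging to its complex is an
#'   error.
#' @return Interaction tibble as in [matrix_expand()].
#' @export
spoke_expand <- function(complexes, baits) {
  if (is.data.frame(baits)) {
    baits <- stats::setNames(baits$gene_id, baits$complex_id)
  }
  complexes <- dplyr::distinct(complexes, .data$complex_id, .data$gene_id)
  by_cx <- split(complexes$gene_id, complexes$complex_id)
  pairs <- purrr::imap_dfr(by_cx, function(members, cx) {
    bait <- baits[[cx]]
    if (is.null(bait) || is.na(bait)) return(NULL)
    if (!bait %in% members) {
      stop("bait ", bait, " is not a member of complex ", cx)
    }
    prey <- setdiff(members, bait)
    if (length(prey) == 0) return(NULL)
    tibble::tibble(gene_a = bait, gene_b = prey, complex_id = cx)
  })
  if (nrow(pairs) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          label = character(), complexes = character()))
  }
  canonicalize_pairs(pairs) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      complexes = paste(sort(unique(.data$complex_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = "positive") |>
    dplyr::select("gene_a", "gene_b", "label", "complexes") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Read a homolog map
#' @param path two-column TSV (source gene, target gene), many-to-many.
#' @return Tibble (`source_gene`, `target_gene`).
#' @export
read_homolog_map <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  tibble::tibble(
    source_gene = vapply(parts, `[`, character(1), 1),
    target_gene = vapply(parts, `[`, character(1), 2)
  ) |> dplyr::distinct()
}

#' Transfer interactions by homology
#'
#' For each pair (a, b), emits every canonical pair (a', b') with a' a
#' homolog of a and b' a homolog of b (interologs). Pairs with an unmapped
#' member are dropped; transfers that collapse to a self-pair are dropped.
#' Provenance keeps the source pair.
#'
#' @param pairs interaction tibble (`gene_a`, `gene_b`, ...).
#' @param homolog_map tibble (`source_gene`, `target_gene`).
#' @return Interaction tibble in the target id space with a `source_pair`
#'   provenance column; attribute `transfer_report` counts dropped pairs.
#' @export
transfer_by_homology <- function(pairs, homolog_map) {
  hm <- dplyr::distinct(homolog_map, .data$source_gene, .data$target_gene)
  mapped_a <- dplyr::inner_join(
    pairs, hm, by = c(gene_a = "source_gene"),
    relationship = "many-to-many"
  ) |> dplyr::rename(target_a = "target_gene")
  mapped <- dplyr::inner_join(
    mapped_a, hm, by = c(gene_b = "source_gene"),
    relationship = "many-to-many"
  ) |> dplyr::rename(target_b = "target_gene")
  n_unmapped <- nrow(dplyr::anti_join(
    pairs,
    dplyr::distinct(mapped, .data$gene_a, .data$gene_b),
    by = c("gene_a", "gene_b")
  ))
  out <- mapped |>
    dplyr::mutate(source_pair = paste(.data$gene_a, .data$gene_b, sep = "|"),
                  gene_a = .data$target_a, gene_b = .data$target_b) |>
    dplyr::select(-"target_a", -"target_b")
  n_self <- sum(out$gene_a == out$gene_b)
  out <- canonicalize_pairs(out) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  attr(out, "transfer_report") <- list(
    n_source = nrow(pairs), n_unmapped = n_unmapped,
    n_self_dropped = n_self, n_transferred = nrow(out)
  )
  out
}

#' Sample negative gene pairs
#'
#' Draws exactly `n` distinct canonical pairs uniformly without replacement
#' from all unordered pairs over `universe`, excluding self-pairs and every
#' pair in `exclude` (the positive set plus any known interactions). This
#' keeps the level of annotation identical between the classes, since both
#' are drawn from the same gene universe. Reproducible under `seed`.
#'
#' @param n number of negatives.
#' @param universe character vector of gene ids.
#' @param exclude interaction tibble or NULL; its pairs are never sampled.
#' @param seed integer seed.
#' @param weights optional named per-gene sampling weights. The default
#'   (`NULL`) samples pairs uniformly. Supplying each gene's degree in the
#'   positive set gives degree-matched negatives: matrix expansion makes
#'   genes of large complexes appear in many positive pairs, and under
#'   uniform negatives that imbalance alone predicts the label, so any
#'   gene-identifying annotation leaks class information. Degree matching
#'   removes that confound.
#' @return Interaction tibble with `label = "negative"` and a `sampled`
#'   provenance column carrying the seed.
#' @export
sample_negatives <- function(n, universe, exclude = NULL, seed = 1L,
                             weights = NULL) {
  universe <- sort(unique(universe))
  if (!is.null(weights)) {
    weights <- as.numeric(weights[universe])
    weights[is.na(weights)] <- 0
    if (sum(weights > 0) < 2) stop("weights leave fewer than two genes")
  }
  n_genes <- length(universe)
  total <- n_genes * (n_genes - 1) / 2
  excl_keys <- if (is.null(exclude) || nrow(exclude) == 0) character(0) else {
    unique(pair_key(exclude$gene_a, exclude$gene_b))
  }
  # only exclusions whose both members are in the universe shrink the pool
  in_univ <- if (length(excl_keys) > 0) {
    both <- strsplit(excl_keys, "\r", fixed = TRUE)
    vapply(both, function(p) all(p %in% universe), logical(1))
  } else {
    logical(0)
  }
  avail <- total - sum(in_univ)
  if (n > avail) {
    stop("cannot sample ", n, " negatives: only ", avail,
         " admissible pairs over ", n_genes, " genes")
  }
  withr::with_seed(seed, {
    chosen <- character(0)
    got <- tibble::tibble(gene_a = character(), gene_b = character())
    while (nrow(got) < n) {
      k <- max(16L, ceiling((n - nrow(got)) * 1.6))
      a <- sample(universe, k, replace = TRUE, prob = weights)
      b <- sample(universe, k, replace = TRUE, prob = weights)
      cand <- tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b)) |>
        dplyr::filter(.data$gene_a != .data$gene_b) |>
        dplyr::distinct()
      keys <- pair_key(cand$gene_a, cand$gene_b)
      cand <- cand[!keys %in% c(excl_keys, chosen), ]
      if (nrow(cand) > 0) {
        take <- utils::head(cand, n - nrow(got))
        chosen <- c(chosen, pair_key(take$gene_a, take$gene_b))
        got <- dplyr::bind_rows(got, take)
      }
    }
    got |>
      dplyr::mutate(label = "negative", sampled = paste0("seed:", seed)) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  })
}

#' Exclude pairs touching a gene blocklist
#'
#' Drops every pair with at least one member in `blocklist` (e.g. histone
#' and cytoplasmic-ribosomal genes, which would otherwise dominate a
#' complex-derived positive set).
#'
#' @param pairs interaction tibble.
#' @param blocklist character vector of gene ids.
#' @return Filtered tibble; attribute `n_dropped` records the count.
#' @export
exclude_gene_families <- function(pairs, blocklist) {
  keep <- !(pairs$gene_a %in% blocklist | pairs$gene_b %in% blocklist)
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(pairs) > 0) {
    warning("blocklist removed every pair")
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Subsample an interaction set
#' @param pairs interaction tibble.
#' @param k sample size (without replacement).
#' @param seed integer seed.
#' @return Tibble of `k` pairs, canonical order.
#' @export
subsample_pairs <- function(pairs, k, seed = 1L) {
  if (k > nrow(pairs)) {
    stop("cannot subsample ", k, " from ", nrow(pairs), " pairs")
  }
  withr::with_seed(seed, {
    idx <- sample(nrow(pairs), k)
  })
  pairs[sort(idx), , drop = FALSE]
}
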