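#' Expand a source selection
#'
#' Named combinations: `"GO"` is the union of the three GO branches,
#' `"GO-IP"` all four sources. Features always keep their base-source tag;
#' combining sources only widens which features a model sees, it never mixes
#' terms from different sources inside one feature.
#'
#' @param sources character vector of base sources (`GO-BP`, `GO-CC`,
#'   `GO-MF`, `IP`) and/or the combinations `GO`, `GO-IP`.
#' @return Character vector of base sources.
#' @export
expand_sources <- function(sources) {
  out <- unlist(lapply(sources, function(s) {
    switch(s, "GO" = GO_SOURCES, "GO-IP" = ALL_SOURCES, s)
  }))
  bad <- setdiff(out, ALL_SOURCES)
  if (length(bad) > 0) stop("unknown source(s): ", paste(bad, collapse = ", "))
  unique(out)
}

#' Pair features of annotated gene pairs
#'
#' A pair feature is the unordered pair of one term from each protein,
#' within a single annotation source: for genes g1, g2 with term sets T1,
#' T2 in a source, the features are `{(source, min(t1,t2), max(t1,t2))}`
#' over the cross product T1 x T2. Because the protein pair is unordered
#' the term pair is canonicalized too, which makes the representation
#' symmetric in the two genes. A pair with a missing annotation on either
#' side of a source contributes no features for that source.
#'
#' @param pairs interaction tibble (`gene_a`, `gene_b`).
#' @param cat an [annotation_catalogue].
#' @param sources source selection, see [expand_sources()].
#' @return Tibble (`pair_id`, `gene_a`, `gene_b`, `source`, `term_lo`,
#'   `term_hi`), one row per distinct feature per pair.
#' @export
pair_features <- function(pairs, cat, sources = "GO-IP") {
  sources <- expand_sources(sources)
  pairs <- tibble::as_tibble(pairs[, c("gene_a", "gene_b")])
  pairs$pair_id <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  ann <- cat |>
    dplyr::filter(.data$source %in% sources) |>
    dplyr::distinct(.data$gene_id, .data$source, .data$term_id)
  ta <- dplyr::inner_join(pairs, ann, by = c(gene_a = "gene_id"),
                          relationship = "many-to-many") |>
    dplyr::rename(term_a = "term_id")
  both <- dplyr::inner_join(
    ta, ann, by = c(gene_b = "gene_id", "source"),
    relationship = "many-to-many"
  ) |>
    dplyr::rename(term_b = "term_id")
  both |>
    dplyr::transmute(
      .data$pair_id, .data$gene_a, .data$gene_b, .data$source,
      term_lo = pmin(.data$term_a, .data$term_b),
      term_hi = pmax(.data$term_a, .data$term_b)
    ) |>
    dplyr::distinct()
}

#' Build (or reuse) a pair-feature space
#'
#' The feature space is a frozen, deterministically ordered index of the
#' distinct `(source, term_lo, term_hi)` triples seen in training data.
#' Feature ids are assigned by sorting on (source, term_lo, term_hi), so
#' rebuilding from identical input gives identical ids.
#'
#' @param features tibble from [pair_features()].
#' @return Tibble (`feature_id`, `source`, `term_lo`, `term_hi`) of class
#'   `pair_feature_space`, frozen.
#' @export
build_feature_space <- function(features) {
  sp <- features |>
    dplyr::distinct(.data$source, .data$term_lo, .data$term_hi) |>
    dplyr::arrange(.data$source, .data$term_lo, .data$term_hi) |>
    dplyr::mutate(feature_id = dplyr::row_number()) |>
    dplyr::select("feature_id", "source", "term_lo", "term_hi")
  attr(sp, "frozen") <- TRUE
  class(sp) <- c("pair_feature_space", class(sp))
  sp
}

space_key <- function(sp) paste(sp$source, sp$term_lo, sp$term_hi, sep = "\r")

#' Build a sparse binary pair-by-feature matrix
#'
#' Rows are canonical pairs (in input order), columns the features of a
#' [pair_feature_space]. When `space` is `NULL` a new space is built from
#' the supplied pairs and frozen; when a frozen space is given (prediction
#' time), features absent from it are silently dropped, so a pair made only
#' of unseen term combinations yields an all-zero row (flagged in the
#' `zero_rows` attribute).
#'
#' @param pairs interaction tibble (`gene_a`, `gene_b`, optionally `label`).
#' @param cat an [annotation_catalogue].
#' @param sources source selection.
#' @param space an existing `pair_feature_space` or `NULL`.
#' @param features optional precomputed [pair_features()] tibble for these
#'   pairs (an optimisation for repeated splits); must cover `sources`.
#' @return List of class `pair_feature_matrix`: `x` (dgCMatrix), `space`,
#'   `pairs`, `labels` (factor positive/negative or NULL).
#' @export
build_feature_matrix <- function(pairs, cat = NULL, sources = "GO-IP",
                                 space = NULL, features = NULL) {
  sources <- expand_sources(sources)
  pairs <- tibble::as_tibble(pairs)
  pair_ids <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  if (is.null(features)) {
    if (is.null(cat)) stop("either cat or features must be supplied")
    features <- pair_features(pairs, cat, sources)
  } else {
    features <- features |>
      dplyr::filter(.data$source %in% sources,
                    .data$pair_id %in% pair_ids)
  }
  if (is.null(space)) space <- build_feature_space(features)
  fid <- match(space_key(features), space_key(space))
  features <- features[!is.na(fid), , drop = FALSE]
  fid <- fid[!is.na(fid)]
  row <- match(features$pair_id, pair_ids)
  x <- Matrix::sparseMatrix(
    i = row, j = fid, x = 1,
    dims = c(length(pair_ids), nrow(space)),
    dimnames = list(pair_ids, NULL)
  )
  x@x[] <- 1  # collapse duplicates to binary
  labels <- if ("label" %in% names(pairs)) {
    factor(pairs$label, levels = c("negative", "positive"))
  } else {
    NULL
  }
  structure(
    list(x = x, space = space, pairs = pairs, labels = labels,
         sources = sources),
    class = "pair_feature_matrix",
    zero_rows = pair_ids[Matrix::rowSums(x) == 0]
  )
}

#' @export
print.pair_feature_matrix <- function(x, ...) {
  cat("<pair_feature_matrix> ", nrow(x$x), " pairs x ", ncol(x$x),
      " features (", length(x$x@x), " nonzero), sources: ",
      paste(x$sources, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a feature matrix as MatrixMarket plus sidecars
#'
#' Writes `matrix.mtx`, `rows.tsv` (pair ids and labels) and
#' `features.tsv` (the feature space).
#' @param fm a `pair_feature_matrix`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(fm$x, mtx)
  rows <- tibble::tibble(
    pair_id = rownames(fm$x),
    label = if (is.null(fm$labels)) NA_character_ else as.character(fm$labels)
  )
  readr::write_tsv(rows, file.path(dir, "rows.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(fm$space), file.path(dir, "features.tsv"),
                   progress = FALSE)
  invisible(file.path(dir, c("matrix.mtx", "rows.tsv", "features.tsv")))
}
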