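#' Annotation catalogues
#'
#' A catalogue is a long tibble with one row per (gene, source, term)
#' assignment, where `source` is one of `GO-BP`, `GO-CC`, `GO-MF`, `IP`.
#' The `mode` attribute records whether term sets are as asserted
#' (`term_only`) or closed over ancestors (`all_parents`).
#'
#' @name annotation_catalogue
NULL

EXCLUDED_EVIDENCE <- c("NAS", "ND", "IEA", "NR")
GO_SOURCES <- c("GO-BP", "GO-CC", "GO-MF")
ALL_SOURCES <- c(GO_SOURCES, "IP")

new_catalogue <- function(df, mode) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene_id", "source", "term_id") %in% names(df)))
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  attr(df, "mode") <- mode
  class(df) <- c("annotation_catalogue", class(df))
  df
}

#' @export
print.annotation_catalogue <- function(x, ...) {
  cat("<annotation_catalogue> mode=", catalogue_mode(x), ", ",
      dplyr::n_distinct(x$gene_id), " genes, ", nrow(x),
      " assignments\n", sep = "")
  NextMethod()
}

#' Annotation mode of a catalogue
#' @param cat an annotation catalogue.
#' @return `"term_only"` or `"all_parents"`.
#' @export
catalogue_mode <- function(cat) attr(cat, "mode") %||% "term_only"

#' Read a GAF 2.x gene association file
#'
#' Loads GO annotations, applying the evidence and qualifier filter: rows
#' with evidence code NAS, ND, IEA or NR, or a qualifier containing `NOT`,
#' are dropped. The aspect column routes each term to `GO-BP` / `GO-CC` /
#' `GO-MF`. Annotations to obsolete terms are remapped through `replaced_by`
#' when available, otherwise dropped with a warning; unknown GO ids are
#' skipped with a warning. Terms asserted under several retained evidence
#' codes are deduplicated to one row with the codes collapsed.
#'
#' @param path GAF file path or character vector of GAF lines.
#' @param graph the GO `ontology_graph` terms must resolve against.
#' @param excluded_evidence evidence codes to drop.
#' @return An [annotation_catalogue] in `term_only` mode.
#' @export
read_gaf <- function(path, graph, excluded_evidence = EXCLUDED_EVIDENCE) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0) {
    return(new_catalogue(tibble::tibble(
      gene_id = character(), source = character(), term_id = character(),
      evidence = character()
    ), "term_only"))
  }
  parts <- stringr::str_split(lines, "\t")
  ok <- vapply(parts, length, integer(1)) >= 9
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " malformed GAF row(s) at line(s) ",
            paste(utils::head(which(!ok), 5), collapse = ", "))
    parts <- parts[ok]
  }
  df <- tibble::tibble(
    gene_id   = vapply(parts, `[`, character(1), 3),
    qualifier = vapply(parts, `[`, character(1), 4),
    term_id   = vapply(parts, `[`, character(1), 5),
    evidence  = vapply(parts, `[`, character(1), 7),
    aspect    = vapply(parts, `[`, character(1), 9)
  )
  df <- df |>
    dplyr::filter(!.data$evidence %in% excluded_evidence) |>
    dplyr::filter(!purrr::map_lgl(
      stringr::str_split(.data$qualifier, "\\|"),
      function(q) any(toupper(q) == "NOT")
    ))
  df$term_id <- resolve_term_ids(graph, df$term_id)
  # obsolete remap
  if (nrow(graph$obsolete) > 0) {
    m <- match(df$term_id, graph$obsolete$term_id)
    hit <- !is.na(m)
    if (any(hit)) {
      repl <- graph$obsolete$replaced_by[m[hit]]
      ok_repl <- !is.na(repl)
      if (any(!ok_repl)) {
        warning(sum(!ok_repl),
                " annotation(s) to obsolete terms without replaced_by dropped")
      }
      df$term_id[hit] <- ifelse(ok_repl, repl, NA_character_)
      df <- df[!is.na(df$term_id), ]
    }
  }
  unknown <- !df$term_id %in% graph$terms$term_id
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " annotation(s) to unknown GO id(s): ",
            paste(utils::head(unique(df$term_id[unknown]), 3), collapse = ", "))
    df <- df[!unknown, ]
  }
  aspect_map <- c(P = "GO-BP", C = "GO-CC", "F" = "GO-MF")
  df$source <- aspect_map[df$aspect]
  df <- df[!is.na(df$source), ]
  df <- df |>
    dplyr::group_by(.data$gene_id, .data$source, .data$term_id) |>
    dplyr::summarise(
      evidence = paste(sort(unique(.data$evidence)), collapse = ","),
      .groups = "drop"
    )
  new_catalogue(df, "term_only")
}

#' Read per-gene InterPro assignments
#'
#' Two-column TSV (gene id, IPR id); duplicate rows are deduplicated and
#' there is no evidence filtering (InterPro assignments carry none). IPR ids
#' absent from the hierarchy are kept as root-level orphans with a warning.
#'
#' @param path file path or character vector of TSV lines.
#' @param graph optional InterPro `ontology_graph` for id validation.
#' @return An [annotation_catalogue] fragment with source `IP`.
#' @export
read_interpro_annotations <- function(path, graph = NULL) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(new_catalogue(tibble::tibble(
      gene_id = character(), source = character(), term_id = character(),
      evidence = character()
    ), "term_only"))
  }
  parts <- stringr::str_split(lines, "\t")
  df <- tibble::tibble(
    gene_id = vapply(parts, `[`, character(1), 1),
    term_id = vapply(parts, `[`, character(1), 2)
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(source = "IP", evidence = NA_character_)
  if (!is.null(graph)) {
    orphan <- setdiff(unique(df$term_id), graph$terms$term_id)
    if (length(orphan) > 0) {
      warning(length(orphan), " InterPro id(s) absent from hierarchy kept ",
              "as root-level orphans: ",
              paste(utils::head(orphan, 3), collapse = ", "))
    }
  }
  new_catalogue(df[, c("gene_id", "source", "term_id", "evidence")],
                "term_only")
}

#' Combine catalogue fragments
#'
#' Row-binds catalogues of the same mode (e.g. the GO catalogue from
#' [read_gaf()] and the InterPro fragment from
#' [read_interpro_annotations()]).
#' @param ... annotation catalogues in the same mode.
#' @return A single [annotation_catalogue].
#' @export
bind_catalogues <- function(...) {
  cats <- list(...)
  modes <- unique(vapply(cats, catalogue_mode, character(1)))
  if (length(modes) > 1) stop("cannot bind catalogues of different modes")
  new_catalogue(dplyr::distinct(dplyr::bind_rows(lapply(cats, tibble::as_tibble))),
                modes)
}

#' Close a catalogue over term ancestors
#'
#' Replaces each gene's term set, per source, by its ancestor closure
#' (including the asserted terms themselves), flipping the catalogue to
#' `all_parents` mode. GO sources are closed against the GO graph over
#' `is_a` and `part_of`; `IP` against the InterPro forest. Closure never
#' leaves a term's namespace. Genes with no retained annotation stay absent
#' (they are not given a bare root). Evidence-code filtering has already
#' happened at load time, so an ancestor is present exactly when at least
#' one retained descendant contributed it; the contributing evidence codes
#' are propagated to the ancestor row.
#'
#' @param cat a `term_only` [annotation_catalogue].
#' @param go_graph GO `ontology_graph` (used for GO-BP/GO-CC/GO-MF rows).
#' @param ip_graph InterPro `ontology_graph` (used for IP rows); orphan IPR
#'   ids absent from the hierarchy close to themselves.
#' @param relations relation types traversed for GO closure.
#' @return An [annotation_catalogue] in `all_parents` mode.
#' @export
close_catalogue <- function(cat, go_graph = NULL, ip_graph = NULL,
                            relations = c("is_a", "part_of")) {
  if (catalogue_mode(cat) != "term_only") {
    stop("catalogue is already in all_parents mode")
  }
  pieces <- list()
  go_rows <- cat[cat$source %in% GO_SOURCES, , drop = FALSE]
  if (nrow(go_rows) > 0) {
    if (is.null(go_graph)) stop("GO rows present but no go_graph supplied")
    anc <- closure_table(go_graph, relations)
    pieces$go <- expand_closure(go_rows, anc)
  }
  ip_rows <- cat[cat$source == "IP", , drop = FALSE]
  if (nrow(ip_rows) > 0) {
    anc <- if (is.null(ip_graph)) list() else {
      closure_table(ip_graph, unique(ip_graph$edges$relation))
    }
    pieces$ip <- expand_closure(ip_rows, anc)
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(cat)[0, ]
  }
  new_catalogue(out, "all_parents")
}

expand_closure <- function(rows, anc) {
  rows$.anc <- purrr::map(rows$term_id, function(t) {
    a <- anc[[t]]
    if (is.null(a)) t else c(t, a)  # orphan term closes to itself
  })
  rows |>
    tidyr::unnest_longer(".anc") |>
    dplyr::group_by(.data$gene_id, .data$source, term_id = .data$.anc) |>
    dplyr::summarise(
      evidence = paste(sort(unique(stats::na.omit(.data$evidence))),
                       collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(evidence = dplyr::na_if(.data$evidence, ""))
}

#' Annotation coverage of an interaction set
#'
#' Fraction of pairs, per label class, where both members have at least one
#' term in at least one common source — i.e. the pair generates at least one
#' pair-feature. An empty class is reported as `NA` (not applicable).
#'
#' @param cat an [annotation_catalogue].
#' @param pairs interaction tibble with `gene_a`, `gene_b`, `label`.
#' @param sources annotation sources considered.
#' @return Tibble with `label`, `n_pairs`, `n_covered`, `coverage`.
#' @export
annotation_coverage <- function(cat, pairs, sources = ALL_SOURCES) {
  gs <- cat |>
    dplyr::filter(.data$source %in% sources) |>
    dplyr::distinct(.data$gene_id, .data$source)
  covered <- function(a, b) {
    sa <- gs$source[gs$gene_id == a]
    sb <- gs$source[gs$gene_id == b]
    length(intersect(sa, sb)) > 0
  }
  pairs |>
    dplyr::mutate(.cov = purrr::map2_lgl(.data$gene_a, .data$gene_b, covered)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_covered = sum(.data$.cov),
      coverage = ifelse(dplyr::n() > 0, sum(.data$.cov) / dplyr::n(), NA_real_),
      .groups = "drop"
    )
}
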