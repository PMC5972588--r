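#' Ontology graphs
#'
#' An `ontology_graph` holds a directed acyclic graph of annotation terms:
#' GO terms connected by `is_a` / `part_of` edges (child to parent), or
#' InterPro entries connected by `interpro_parent` edges. It is the substrate
#' for ancestor closure ("all parents") of gene annotations.
#'
#' @param terms tibble with columns `term_id`, `name`, `namespace`,
#'   `is_obsolete`.
#' @param edges tibble with columns `child`, `parent`, `relation`.
#' @param alt_ids tibble mapping `alt_id` to canonical `term_id`.
#' @param obsolete tibble of obsolete terms (`term_id`, `name`,
#'   `replaced_by`).
#' @return An object of class `ontology_graph`.
#' @keywords internal
new_ontology_graph <- function(terms, edges, alt_ids = NULL, obsolete = NULL) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
    if (length(missing) > 0) {
      stop("ontology edge endpoint(s) not present as terms: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term_id in ontology: ",
         terms$term_id[duplicated(terms$term_id)][1])
  }
  check_acyclic(edges)
  structure(
    list(
      terms = terms,
      edges = edges,
      alt_ids = if (is.null(alt_ids)) {
        tibble::tibble(alt_id = character(), term_id = character())
      } else {
        tibble::as_tibble(alt_ids)
      },
      obsolete = if (is.null(obsolete)) {
        tibble::tibble(term_id = character(), name = character(),
                       replaced_by = character())
      } else {
        tibble::as_tibble(obsolete)
      },
      closure_cache = new.env(parent = emptyenv())
    ),
    class = "ontology_graph"
  )
}

check_acyclic <- function(edges) {
  if (nrow(edges) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::ends(g, cyc[[1]])[1, 1]
    stop("cycle detected in ontology involving term ", member)
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " edges (", paste(unique(x$edges$relation), collapse = ", "), "), ",
      length(ontology_roots(x)), " root(s), ",
      nrow(x$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

#' Root terms of an ontology graph
#'
#' Terms with no outgoing parent edge, per namespace.
#' @param graph an `ontology_graph`.
#' @return Character vector of root term ids.
#' @export
ontology_roots <- function(graph) {
  setdiff(graph$terms$term_id, unique(graph$edges$child))
}

#' Parse an OBO ontology file
#'
#' Reads OBO 1.2/1.4 stanza text into an [ontology graph][new_ontology_graph].
#' `is_a:` and `relationship: part_of` lines become child-to-parent edges;
#' `alt_id:` lines populate an alias table; obsolete terms are excluded from
#' the live graph but retained (with any `replaced_by` target) in an obsolete
#' index so annotations can be remapped. `part_of` edges that would cross GO
#' namespaces are dropped with a warning: the three GO branches are analysed
#' separately, so closure must never leave a term's namespace.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return An `ontology_graph`.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' g <- read_obo(obo)
#' ontology_roots(g)
#' @export
read_obo <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- sub("\\s*!.*$", "", lines)  # trailing comments
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) {
    return(new_ontology_graph(
      tibble::tibble(term_id = character(), name = character(),
                     namespace = character(), is_obsolete = logical()),
      tibble::tibble(child = character(), parent = character(),
                     relation = character())
    ))
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  stanzas <- lapply(seq_along(stanza_starts), function(i) {
    lines[bounds[i]:(bounds[i + 1] - 1L)]
  })
  stanzas <- stanzas[vapply(stanzas, function(s) s[1] == "[Term]", logical(1))]

  field <- function(s, key) {
    hit <- grep(paste0("^", key, ":\\s*"), s, value = TRUE)
    stringr::str_trim(sub(paste0("^", key, ":\\s*"), "", hit))
  }
  recs <- purrr::map(stanzas, function(s) {
    id <- field(s, "id")[1]
    rel <- field(s, "relationship")
    part_of <- sub("^part_of\\s+", "", grep("^part_of\\s", rel, value = TRUE))
    list(
      term_id = id,
      name = if (length(field(s, "name")) > 0) field(s, "name")[1] else id,
      namespace = if (length(field(s, "namespace")) > 0) {
        field(s, "namespace")[1]
      } else {
        NA_character_
      },
      is_obsolete = any(field(s, "is_obsolete") == "true"),
      is_a = field(s, "is_a"),
      part_of = part_of,
      alt_id = field(s, "alt_id"),
      replaced_by = if (length(field(s, "replaced_by")) > 0) {
        field(s, "replaced_by")[1]
      } else {
        NA_character_
      }
    )
  })

  terms <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(term_id = r$term_id, name = r$name,
                   namespace = r$namespace, is_obsolete = r$is_obsolete)
  })
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term stanza for ",
         terms$term_id[duplicated(terms$term_id)][1])
  }
  obsolete <- terms[terms$is_obsolete, ]
  obsolete$replaced_by <- vapply(
    recs[terms$is_obsolete], function(r) r$replaced_by, character(1)
  )
  live <- terms[!terms$is_obsolete, ]

  ns_of <- stats::setNames(live$namespace, live$term_id)
  edges <- purrr::map_dfr(recs, function(r) {
    if (r$is_obsolete) return(NULL)
    dplyr::bind_rows(
      tibble::tibble(child = r$term_id, parent = r$is_a, relation = "is_a"),
      tibble::tibble(child = r$term_id, parent = r$part_of,
                     relation = "part_of")
    )
  })
  if (nrow(edges) > 0) {
    unknown <- setdiff(edges$parent, live$term_id)
    if (length(unknown) > 0) {
      stop("unknown parent id(s) in OBO: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    cross <- edges$relation == "part_of" &
      ns_of[edges$child] != ns_of[edges$parent]
    if (any(cross)) {
      warning(sum(cross), " part_of edge(s) crossing GO namespaces dropped")
      edges <- edges[!cross, ]
    }
  }
  alt <- purrr::map_dfr(recs, function(r) {
    if (length(r$alt_id) == 0) return(NULL)
    tibble::tibble(alt_id = r$alt_id, term_id = r$term_id)
  })
  new_ontology_graph(live, edges, alt_ids = alt,
                     obsolete = obsolete[, c("term_id", "name", "replaced_by")])
}

#' Parse an InterPro hierarchy
#'
#' Accepts either the dash-indented ParentChildTreeFile dialect
#' (`IPR000001::name::`, children indented with leading `--`) or a plain
#' two-column child/parent TSV. InterPro is a forest: an entry with two
#' distinct parents is rejected.
#'
#' @param path path or character vector of lines.
#' @param format `"auto"`, `"tree"` or `"tsv"`.
#' @param max_depth maximum allowed depth (root = depth 1); the InterPro
#'   hierarchy is shallow (8 levels observed in practice).
#' @return An `ontology_graph` with relation `interpro_parent` and namespace
#'   `interpro`.
#' @export
read_interpro_hierarchy <- function(path, format = c("auto", "tree", "tsv"),
                                    max_depth = 12) {
  format <- match.arg(format)
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    return(new_ontology_graph(
      tibble::tibble(term_id = character(), name = character(),
                     namespace = character(), is_obsolete = logical()),
      tibble::tibble(child = character(), parent = character(),
                     relation = character())
    ))
  }
  if (format == "auto") {
    format <- if (any(grepl("::", lines, fixed = TRUE))) "tree" else "tsv"
  }
  if (format == "tree") {
    depth <- nchar(sub("^((--)*).*$", "\\1", lines)) / 2L + 1L
    body <- sub("^(--)*", "", lines)
    parts <- stringr::str_split(body, "::")
    ids <- vapply(parts, `[`, character(1), 1)
    nms <- vapply(parts, function(p) {
      if (length(p) >= 2 && nzchar(p[2])) p[2] else p[1]
    }, character(1))
    parent <- rep(NA_character_, length(ids))
    stack <- character(0)
    for (i in seq_along(ids)) {
      d <- depth[i]
      if (d > length(stack) + 1L) {
        stop("malformed InterPro tree indentation at entry ", ids[i])
      }
      if (d > 1L) parent[i] <- stack[d - 1L]
      stack <- c(stack[seq_len(d - 1L)], ids[i])
    }
    df <- tibble::tibble(term_id = ids, name = nms, parent = parent)
  } else {
    parts <- stringr::str_split(lines, "\t")
    df <- tibble::tibble(
      term_id = vapply(parts, `[`, character(1), 1),
      name = vapply(parts, `[`, character(1), 1),
      parent = vapply(parts, function(p) {
        if (length(p) >= 2 && nzchar(p[2])) p[2] else NA_character_
      }, character(1))
    )
  }
  # a repeated entry is fine only if every occurrence names the same parent
  par_by_id <- split(df$parent, df$term_id)
  multi <- names(par_by_id)[vapply(par_by_id, function(p) {
    length(unique(p[!is.na(p)])) > 1
  }, logical(1))]
  if (length(multi) > 0) {
    stop("InterPro entry with multiple parents (forest violated): ", multi[1])
  }
  df <- dplyr::distinct(df, .data$term_id, .keep_all = TRUE)
  terms <- tibble::tibble(term_id = df$term_id, name = df$name,
                          namespace = "interpro", is_obsolete = FALSE)
  edges <- df |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::transmute(child = .data$term_id, parent = .data$parent,
                     relation = "interpro_parent")
  orphans <- setdiff(edges$parent, terms$term_id)
  if (length(orphans) > 0) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term_id = orphans, name = orphans, namespace = "interpro",
      is_obsolete = FALSE
    ))
  }
  g <- new_ontology_graph(terms, edges)
  depths <- term_depths(g)
  if (max(depths) > max_depth) {
    stop("InterPro hierarchy depth ", max(depths), " exceeds max_depth ",
         max_depth)
  }
  g
}

term_depths <- function(graph) {
  anc <- closure_table(graph, unique(graph$edges$relation))
  n_anc <- vapply(graph$terms$term_id, function(id) length(anc[[id]]),
                  integer(1))
  n_anc + 1L
}

# Full ancestor closure (excluding self) for every term, memoised per
# relation subset. Propagation in topological order: a term's ancestors are
# its parents plus the parents' ancestors.
closure_table <- function(graph, relations) {
  key <- paste0("rel:", paste(sort(relations), collapse = "|"))
  cache <- graph$closure_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  ids <- graph$terms$term_id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(anc)) anc[[i]] <- character(0)
  ed <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (nrow(ed) > 0) {
    g <- igraph::graph_from_data_frame(
      ed[, c("child", "parent")], directed = TRUE,
      vertices = data.frame(name = ids)
    )
    ord <- igraph::topo_sort(g, mode = "in")$name  # parents before children
    parents <- split(ed$parent, ed$child)
    for (id in ord) {
      p <- parents[[id]]
      if (is.null(p)) next
      anc[[id]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
    }
  }
  cache[[key]] <- anc
  anc
}

#' Ancestor closure of ontology terms
#'
#' Transitive closure over the selected relationship types. With
#' `include_self = TRUE` (the default used throughout the all-parents
#' annotation mode) the query terms themselves are part of the closure, so a
#' leaf-level annotation still pairs at its own level as well as at every
#' ancestral level up to the namespace root.
#'
#' @param graph an `ontology_graph`.
#' @param term_ids character vector of term ids (alt_ids are resolved).
#' @param relations which edge types to traverse; defaults to every relation
#'   present in the graph (for GO that is `is_a` and `part_of`).
#' @param include_self whether each queried term is included in its own
#'   closure.
#' @return Character vector: the union of closures of `term_ids`.
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: r", "namespace: biological_process",
#'          "[Term]", "id: GO:2", "name: x", "namespace: biological_process",
#'          "is_a: GO:1",
#'          "[Term]", "id: GO:3", "name: y", "namespace: biological_process",
#'          "is_a: GO:2")
#' g <- read_obo(obo)
#' term_ancestors(g, "GO:3")                        # GO:3, GO:2, GO:1
#' term_ancestors(g, "GO:3", include_self = FALSE)  # GO:2, GO:1
#' @export
term_ancestors <- function(graph, term_ids,
                           relations = unique(graph$edges$relation),
                           include_self = TRUE) {
  term_ids <- resolve_term_ids(graph, term_ids)
  unknown <- setdiff(term_ids, graph$terms$term_id)
  if (length(unknown) > 0) {
    stop("unknown term id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  anc <- closure_table(graph, relations)
  out <- unlist(anc[term_ids], use.names = FALSE)
  if (include_self) out <- c(term_ids, out)
  unique(out)
}

# Map alt_ids to canonical ids; leave unknown ids untouched (callers decide).
resolve_term_ids <- function(graph, term_ids) {
  if (nrow(graph$alt_ids) == 0) return(term_ids)
  m <- match(term_ids, graph$alt_ids$alt_id)
  hit <- !is.na(m)
  term_ids[hit] <- graph$alt_ids$term_id[m[hit]]
  term_ids
}
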