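#' Configuration for the synthetic input generator
#'
#' The generator emulates every input the pipeline consumes — a GO-style
#' OBO ontology (three namespaces), an InterPro forest, GAF annotations
#' with realistic evidence codes, per-gene InterPro assignments, a complex
#' catalogue with a CYC2008-like size profile (many 2-member complexes and
#' a long tail), a homolog map and labelled pairs — with a planted
#' co-complex signal of controllable strength.
#'
#' The signal model mimics how co-complex membership shows up in real
#' annotation: complexes belong to functional modules, and one "module term"
#' per (module, source) recurs across every complex of that module (the way
#' terms like "ribosome" or "proteasome complex" annotate members of many
#' related complexes). Each complex is assigned to one of `n_modules`
#' modules independently per source; with probability `signal` a positive
#' pair has its complex's module term assigned to both members in that
#' source, so the pair feature (term, term) marks co-membership while still
#' generalizing across complexes. Negative pairs pick up the same feature
#' only when both genes happen to sit in same-module complexes, giving a
#' natural false-signal floor of roughly 1/`n_modules` per source. With
#' `signal = 0` annotations carry no class information. `background`
#' optionally contaminates sampled negatives with an explicit shared
#' planted term on top of that floor.
#'
#' @param seed master seed; the bundle is byte-reproducible given the
#'   config.
#' @param complex_sizes integer vector of complex sizes (all >= 2).
#' @param n_extra_genes genes outside any complex (annotated, never in
#'   positive pairs).
#' @param n_terms named vector: background ontology size per namespace.
#' @param part_of_frac fraction of GO edges emitted as `part_of`.
#' @param complex_name_frac fraction of cellular-component terms whose name
#'   contains the word "complex" (for the term-frequency audit).
#' @param ann_geom_p geometric parameter for the per-gene, per-source count
#'   of background annotations (truncated at `ann_cap`); sparse annotation
#'   as in real catalogues.
#' @param ann_cap cap on background annotations per gene per source.
#' @param annotation_rate probability a gene is annotated at all in a
#'   source.
#' @param n_modules number of functional modules per source; each module
#'   owns a block of planted terms per source.
#' @param module_term_count terms per (module, source) block: complex
#'   members share a coherent annotation profile (e.g. the complex's
#'   localization, process and function terms), not a single tag.
#' @param signal,background planted-signal rates in \[0, 1\].
#' @param iea_frac fraction of GAF rows duplicated as electronic (IEA)
#'   annotations of other terms, which the evidence filter must drop.
#' @param not_frac fraction of GAF rows emitted with a NOT qualifier.
#' @param n_positive,n_negative final class sizes (positives are
#'   subsampled from the matrix expansion; negatives sampled by the real
#'   dataset module).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             complex_sizes = c(rep(2, 25), rep(3, 15),
                                               rep(4, 8), rep(5, 5),
                                               rep(6, 3), rep(8, 2),
                                               10, 14, 16),
                             n_extra_genes = 14,
                             n_terms = c(bp = 60, cc = 40, mf = 40,
                                         ip = 60),
                             part_of_frac = 0.2,
                             complex_name_frac = 0.15,
                             ann_geom_p = 0.5, ann_cap = 4,
                             annotation_rate = 0.9,
                             n_modules = 20, module_term_count = 3,
                             signal = 0.9, background = 0,
                             iea_frac = 0.15, not_frac = 0.03,
                             n_positive = 500, n_negative = 500) {
  stopifnot(all(complex_sizes >= 2), signal >= 0, signal <= 1,
            background >= 0, background <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Named synthetic presets
#'
#' `"tiny"` is a seconds-scale bundle for smoke tests; `"paper-shaped"`
#' mirrors the study conditions used throughout the package's benchmark
#' (1,000 labelled pairs, four sources, signal 0.9).
#' @param name preset name.
#' @param seed master seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("paper-shaped", "tiny"), seed = 1L,
                             ...) {
  name <- match.arg(name)
  defaults <- if (name == "tiny") {
    list(
      complex_sizes = c(2, 2, 3, 3, 4, 5),
      n_extra_genes = 4,
      n_terms = c(bp = 30, cc = 25, mf = 25, ip = 30),
      n_positive = 20, n_negative = 20
    )
  } else {
    list()
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, c(list(seed = seed), args))
}

#' Build a complex catalogue with a prescribed size profile
#'
#' @param sizes integer vector of complex sizes.
#' @param overlap_rate fraction of memberships replaced by genes already
#'   used in another complex (0 = disjoint complexes).
#' @param seed seed.
#' @param gene_prefix prefix for generated gene ids.
#' @return Tibble (`complex_id`, `gene_id`).
#' @export
plant_complexes <- function(sizes, overlap_rate = 0, seed = 1L,
                            gene_prefix = "g") {
  withr::with_seed(seed, {
    total <- sum(sizes)
    genes <- sprintf("%s%04d", gene_prefix, seq_len(total))
    out <- purrr::map_dfr(seq_along(sizes), function(i) {
      start <- if (i == 1) 0 else sum(sizes[seq_len(i - 1)])
      tibble::tibble(complex_id = sprintf("cx%03d", i),
                     gene_id = genes[start + seq_len(sizes[i])])
    })
    if (overlap_rate > 0) {
      swap <- which(stats::runif(nrow(out)) < overlap_rate)
      for (j in swap) {
        donor <- sample(setdiff(out$gene_id, out$gene_id[out$complex_id ==
                                                           out$complex_id[j]]), 1)
        out$gene_id[j] <- donor
      }
      out <- dplyr::distinct(out)
    }
    out
  })
}

go_ns_long <- c(bp = "biological_process", cc = "cellular_component",
                mf = "molecular_function")

# random rooted DAG-ish tree per namespace; term 1 is the root
make_go_namespace <- function(ns, n, part_of_frac, complex_name_frac) {
  pre <- match(ns, names(go_ns_long))
  ids <- sprintf("GO:%d%06d", pre, seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1), integer(1)))
  relation <- c(NA, ifelse(stats::runif(n - 1) < part_of_frac,
                           "part_of", "is_a"))
  name <- sprintf("synthetic %s term %d", go_ns_long[[ns]], seq_len(n))
  if (ns == "cc" && complex_name_frac > 0) {
    k <- max(1L, round(complex_name_frac * n))
    idx <- sample(2:n, min(k, n - 1))
    name[idx] <- sprintf("synthetic protein complex %d", idx)
  }
  name[1] <- paste("synthetic", go_ns_long[[ns]], "root")
  tibble::tibble(term_id = ids, name = name,
                 namespace = go_ns_long[[ns]],
                 parent = ifelse(is.na(parent), NA, ids[parent]),
                 relation = relation)
}

make_interpro_forest <- function(n, max_depth = 8) {
  ids <- sprintf("IPR%06d", seq_len(n))
  n_roots <- max(1L, round(0.3 * n))
  parent <- rep(NA_character_, n)
  depth <- rep(1L, n)
  for (i in seq_len(n)[-seq_len(n_roots)]) {
    cand <- which(depth[seq_len(i - 1)] < max_depth)
    p <- sample(cand, 1)
    parent[i] <- ids[p]
    depth[i] <- depth[p] + 1L
  }
  tibble::tibble(term_id = ids, name = paste("synthetic domain", seq_len(n)),
                 parent = parent, depth = depth)
}

render_obo <- function(go) {
  header <- c("format-version: 1.2", "ontology: synthetic-go", "")
  stanzas <- purrr::pmap(go, function(term_id, name, namespace, parent,
                                      relation) {
    s <- c("[Term]", paste0("id: ", term_id), paste0("name: ", name),
           paste0("namespace: ", namespace))
    if (!is.na(parent)) {
      s <- c(s, if (relation == "is_a") {
        paste0("is_a: ", parent, " ! parent")
      } else {
        paste0("relationship: part_of ", parent, " ! parent")
      })
    }
    c(s, "")
  })
  c(header, unlist(stanzas))
}

render_interpro_tree <- function(ip) {
  # dash-indented ParentChildTreeFile dialect, depth-first per root
  lines <- character(0)
  children <- split(ip$term_id, ip$parent)
  emit <- function(id, depth) {
    lines <<- c(lines, paste0(
      strrep("--", depth),
      id, "::", ip$name[match(id, ip$term_id)], "::"
    ))
    for (ch in children[[id]]) emit(ch, depth + 1L)
  }
  for (r in ip$term_id[is.na(ip$parent)]) emit(r, 0L)
  lines
}

render_gaf <- function(ann) {
  # ann: gene_id, term_id, evidence, qualifier, aspect
  header <- "!gaf-version: 2.1"
  rows <- sprintf(
    "SYN\t%s\t%s\t%s\t%s\tSYN_REF:0000001\t%s\t\t%s\t%s\tprotein\ttaxon:0000\t20180101\tSYN\t\t\t",
    ann$gene_id, ann$gene_id, ann$qualifier, ann$term_id, ann$evidence,
    ann$aspect, ann$gene_id
  )
  c(header, rows)
}

#' Generate a synthetic input bundle
#'
#' Produces, fully seeded and byte-reproducible, every file the pipeline
#' reads plus the ground-truth labelled pairs. Positive pairs come from
#' matrix expansion of the generated complex catalogue and negatives from
#' [sample_negatives()] against those positives, so the generator exercises
#' the production dataset code rather than bypassing it.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_bundle` with character-vector file
#'   images (`obo`, `interpro_tree`, `gaf`, `interpro_annotations`,
#'   `complexes_tsv`, `homologs_tsv`, `pairs_tsv`) and parsed pieces
#'   (`complexes`, `pairs`, `planted_terms`).
#' @export
generate_bundle <- function(config = synthetic_config()) {
  cfg <- config
  complexes <- plant_complexes(cfg$complex_sizes, seed = cfg$seed)
  withr::with_seed(cfg$seed + 1L, {
    complex_genes <- sort(unique(complexes$gene_id))
    extra <- if (cfg$n_extra_genes > 0) {
      sprintf("x%04d", seq_len(cfg$n_extra_genes))
    } else {
      character(0)
    }
    genes <- c(complex_genes, extra)

    go <- purrr::map_dfr(c("bp", "cc", "mf"), function(ns) {
      make_go_namespace(ns, cfg$n_terms[[ns]], cfg$part_of_frac,
                        cfg$complex_name_frac)
    })
    ip <- make_interpro_forest(cfg$n_terms[["ip"]])

    # background term pools snapshot the base ontologies: module terms are
    # planted only through the signal path, never as background noise
    pools <- list(
      "GO-BP" = go$term_id[go$namespace == "biological_process"],
      "GO-CC" = go$term_id[go$namespace == "cellular_component"],
      "GO-MF" = go$term_id[go$namespace == "molecular_function"],
      "IP" = ip$term_id
    )

    # planted module terms: each complex joins one of n_modules functional
    # modules per source (independent partitions across sources); the
    # module's term recurs across all of its complexes
    cxs <- sort(unique(complexes$complex_id))
    n_mod <- min(cfg$n_modules, length(cxs))
    mtc <- cfg$module_term_count
    planted <- purrr::map_dfr(c("bp", "cc", "mf", "ip"), function(src) {
      n0 <- cfg$n_terms[[src]]
      module <- sample(n_mod, length(cxs), replace = TRUE)
      n_new <- n_mod * mtc
      if (src == "ip") {
        mod_terms <- matrix(sprintf("IPR%06d", n0 + seq_len(n_new)),
                            nrow = n_mod, byrow = TRUE)
        mod_parent <- matrix(sample(ip$term_id[ip$depth < 8], n_new,
                                    replace = TRUE),
                             nrow = n_mod, byrow = TRUE)
        src_name <- "IP"
      } else {
        pre <- match(src, names(go_ns_long))
        ns_terms <- go$term_id[go$namespace == go_ns_long[[src]]]
        mod_terms <- matrix(sprintf("GO:%d%06d", pre, n0 + seq_len(n_new)),
                            nrow = n_mod, byrow = TRUE)
        mod_parent <- matrix(sample(ns_terms, n_new, replace = TRUE),
                             nrow = n_mod, byrow = TRUE)
        src_name <- c(bp = "GO-BP", cc = "GO-CC", mf = "GO-MF")[[src]]
      }
      term_block <- as.vector(t(mod_terms)[, module])
      parent_block <- as.vector(t(mod_parent)[, module])
      tibble::tibble(
        source = src_name,
        complex_id = rep(cxs, each = mtc),
        module = rep(module, each = mtc),
        term_id = term_block,
        parent = parent_block
      )
    })
    go_planted <- planted |>
      dplyr::filter(.data$source != "IP") |>
      dplyr::distinct(.data$source, .data$term_id, .data$parent) |>
      dplyr::mutate(
        name = paste("synthetic module term", dplyr::row_number()),
        namespace = go_ns_long[match(tolower(substr(.data$source, 4, 5)),
                                     names(go_ns_long))],
        relation = "is_a"
      ) |>
      dplyr::select("term_id", "name", "namespace", "parent", "relation")
    go <- dplyr::bind_rows(go, go_planted)
    ip_planted <- planted |>
      dplyr::filter(.data$source == "IP") |>
      dplyr::distinct(.data$term_id, .data$parent)
    ip <- dplyr::bind_rows(ip, tibble::tibble(
      term_id = ip_planted$term_id,
      name = paste("synthetic module domain", seq_len(nrow(ip_planted))),
      parent = ip_planted$parent,
      depth = ip$depth[match(ip_planted$parent, ip$term_id)] + 1L
    ))

    # background annotations
    retained_ev <- c("IDA", "IPI", "IMP", "IGI", "ISS", "TAS", "IC")
    ann <- purrr::map_dfr(names(pools), function(src) {
      purrr::map_dfr(genes, function(g) {
        if (stats::runif(1) > cfg$annotation_rate) return(NULL)
        n_ann <- 1 + min(stats::rgeom(1, cfg$ann_geom_p), cfg$ann_cap)
        tibble::tibble(gene_id = g, source = src,
                       term_id = sample(pools[[src]], n_ann))
      })
    })

    # positive pairs via the production expansion, then subsample
    positives <- matrix_expand(complexes)
    if (cfg$n_positive < nrow(positives)) {
      positives <- subsample_pairs(positives, cfg$n_positive,
                                   seed = cfg$seed + 2L)
    }

    # plant the co-complex signal at pair level
    planted_rows <- purrr::pmap_dfr(
      positives[, c("gene_a", "gene_b", "complexes")],
      function(gene_a, gene_b, complexes) {
        cx <- strsplit(complexes, ";", fixed = TRUE)[[1]][1]
        hit <- planted[planted$complex_id == cx, ]
        # the signal switches per source: a signalled pair inherits the
        # whole module profile of that source, not isolated terms
        srcs <- unique(hit$source)
        on_src <- srcs[stats::runif(length(srcs)) < cfg$signal]
        hit <- hit[hit$source %in% on_src, ]
        if (nrow(hit) == 0) return(NULL)
        tibble::tibble(
          gene_id = rep(c(gene_a, gene_b), each = nrow(hit)),
          source = rep(hit$source, 2),
          term_id = rep(hit$term_id, 2)
        )
      }
    )
    ann <- dplyr::distinct(dplyr::bind_rows(ann, planted_rows))

    # negatives via the production sampler, degree-matched to the positive
    # set: matrix expansion gives large-complex genes many positive pairs,
    # and uniform negatives would let gene identity alone predict the
    # label (see sample_negatives); matching the per-gene degree keeps the
    # null benchmark honest
    pos_degree <- table(c(positives$gene_a, positives$gene_b))
    negatives <- sample_negatives(cfg$n_negative, names(pos_degree),
                                  exclude = matrix_expand(complexes),
                                  seed = cfg$seed + 3L,
                                  weights = pos_degree)
    if (cfg$background > 0) {
      contam <- which(stats::runif(nrow(negatives)) < cfg$background)
      contam_rows <- purrr::map_dfr(contam, function(i) {
        hit <- planted[sample(nrow(planted), 1), ]
        tibble::tibble(
          gene_id = c(negatives$gene_a[i], negatives$gene_b[i]),
          source = hit$source, term_id = hit$term_id
        )
      })
      ann <- dplyr::distinct(dplyr::bind_rows(ann, contam_rows))
    }

    pairs <- dplyr::bind_rows(
      positives[, c("gene_a", "gene_b", "label")],
      negatives[, c("gene_a", "gene_b", "label")]
    )

    # GAF rows: retained evidence for real annotations, plus decoy IEA and
    # NOT-qualified rows that the filter must remove
    go_ann <- ann[ann$source != "IP", ]
    aspect_of <- c("GO-BP" = "P", "GO-CC" = "C", "GO-MF" = "F")
    gaf <- tibble::tibble(
      gene_id = go_ann$gene_id, term_id = go_ann$term_id,
      evidence = sample(retained_ev, nrow(go_ann), replace = TRUE),
      qualifier = "", aspect = aspect_of[go_ann$source]
    )
    n_iea <- round(cfg$iea_frac * nrow(gaf))
    if (n_iea > 0) {
      src_pick <- sample(names(aspect_of), n_iea, replace = TRUE)
      gaf <- dplyr::bind_rows(gaf, tibble::tibble(
        gene_id = sample(genes, n_iea, replace = TRUE),
        term_id = vapply(src_pick, function(s) sample(pools[[s]], 1),
                         character(1)),
        evidence = sample(c("IEA", "NAS", "ND", "NR"), n_iea,
                          replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
        qualifier = "", aspect = aspect_of[src_pick]
      ))
    }
    n_not <- round(cfg$not_frac * nrow(gaf))
    if (n_not > 0) {
      src_pick <- sample(names(aspect_of), n_not, replace = TRUE)
      gaf <- dplyr::bind_rows(gaf, tibble::tibble(
        gene_id = sample(genes, n_not, replace = TRUE),
        term_id = vapply(src_pick, function(s) sample(pools[[s]], 1),
                         character(1)),
        evidence = "IDA", qualifier = "NOT", aspect = aspect_of[src_pick]
      ))
    }
    gaf <- gaf[order(gaf$gene_id, gaf$aspect, gaf$term_id, gaf$evidence), ]

    ip_ann <- ann[ann$source == "IP", c("gene_id", "term_id")]
    ip_ann <- ip_ann[order(ip_ann$gene_id, ip_ann$term_id), ]

    homologs <- tibble::tibble(source_gene = genes, target_gene = genes)

    structure(
      list(
        obo = render_obo(go),
        interpro_tree = render_interpro_tree(ip),
        gaf = render_gaf(gaf),
        interpro_annotations = paste(ip_ann$gene_id, ip_ann$term_id,
                                     sep = "\t"),
        complexes_tsv = paste(complexes$complex_id, complexes$gene_id,
                              sep = "\t"),
        homologs_tsv = paste(homologs$source_gene, homologs$target_gene,
                             sep = "\t"),
        pairs_tsv = paste(pairs$gene_a, pairs$gene_b, pairs$label,
                          sep = "\t"),
        complexes = complexes, pairs = pairs, planted_terms = planted,
        config = cfg
      ),
      class = "synthetic_bundle"
    )
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", sum(x$pairs$label == "positive"), " positive / ",
      sum(x$pairs$label == "negative"), " negative pairs, ",
      dplyr::n_distinct(x$complexes$complex_id), " complexes, signal ",
      x$config$signal, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to disk
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory.
#' @return Invisibly, the named file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    obo = "ontology.obo", interpro_tree = "interpro_hierarchy.txt",
    gaf = "annotations.gaf", interpro_annotations = "interpro.tsv",
    complexes_tsv = "complexes.tsv", homologs_tsv = "homologs.tsv",
    pairs_tsv = "pairs.tsv"
  )
  for (nm in names(paths)) {
    writeLines(bundle[[nm]], file.path(dir, paths[[nm]]))
  }
  invisible(stats::setNames(file.path(dir, paths), names(paths)))
}

#' Parse a bundle through the production readers
#'
#' Round-trips the generated file images through [read_obo()],
#' [read_interpro_hierarchy()], [read_gaf()], [read_interpro_annotations()]
#' and [read_complexes()], returning the loaded objects — the same path an
#' external user takes with real files.
#'
#' @param bundle a `synthetic_bundle`.
#' @param close_annotations close the catalogue over ancestors
#'   (all-parents mode).
#' @return List: `go_graph`, `ip_graph`, `catalogue`, `complexes`, `pairs`.
#' @export
load_bundle <- function(bundle, close_annotations = TRUE) {
  go_graph <- read_obo(bundle$obo)
  ip_graph <- read_interpro_hierarchy(bundle$interpro_tree)
  cat_go <- read_gaf(bundle$gaf, go_graph)
  cat_ip <- read_interpro_annotations(bundle$interpro_annotations, ip_graph)
  cat <- bind_catalogues(cat_go, cat_ip)
  if (close_annotations) {
    cat <- close_catalogue(cat, go_graph, ip_graph)
  }
  list(go_graph = go_graph, ip_graph = ip_graph, catalogue = cat,
       complexes = read_complexes(bundle$complexes_tsv),
       pairs = bundle$pairs)
}
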