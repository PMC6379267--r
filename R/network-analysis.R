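#' Read a gene annotation table
#'
#' Native format: TSV with columns `gene`, `chrom`, `start`, `end`,
#' `biotype` (`protein_coding` or `regulatory_other`), coordinates 1-based
#' inclusive. BED input (0-based half-open, columns chrom/start/end/name and
#' optionally biotype in column 5) is converted on load.
#'
#' @param path File path.
#' @param format `"tsv"` (native, default) or `"bed"`.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`, `biotype`.
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene", "chrom", "start", "end", "biotype")
    if (!all(need %in% names(tab))) {
      abort(sprintf("Annotation TSV needs columns: %s.", paste(need, collapse = ", ")))
    }
    tab <- tab[need]
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    if (ncol(tab) < 4L) abort("BED file needs at least 4 columns.")
    tab <- tibble(gene = tab[[4L]], chrom = tab[[1L]],
                  start = tab[[2L]] + 1L, end = tab[[3L]],
                  biotype = if (ncol(tab) >= 5L) tab[[5L]] else "protein_coding")
  }
  if (any(tab$start > tab$end)) abort("Annotation intervals with start > end.")
  tab
}

#' Read a one-gene-per-line category list
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

marker_category <- function(genes, biotypes, craniofacial, growth) {
  if (length(genes) == 0L) return("Regulatory")
  if (any(genes %in% craniofacial)) return("Craniofacial")
  if (any(genes %in% growth)) return("Growth")
  if (any(biotypes == "protein_coding")) return("Other")
  "Regulatory"
}

#' Attach candidate genes and a functional category to markers
#'
#' A gene is a candidate for a marker when its interval lies within `window`
#' base pairs of the marker position (distance 0 if the marker falls inside
#' the interval). Each marker gets one category with priority Craniofacial >
#' Growth > Other > Regulatory: craniofacial if any candidate is on the
#' craniofacial list, else growth, else `Other` for any other protein-coding
#' candidate, else `Regulatory` (covering regulatory-only neighbourhoods and
#' empty ones).
#'
#' @param markers Tibble with columns `marker`, `chrom`, `pos` (e.g. a
#'   dosage map, possibly filtered to significant markers).
#' @param annotation Annotation tibble from [read_annotation()].
#' @param craniofacial,growth Character vectors of reference gene ids.
#' @param window Candidate window in bp (default 200000).
#' @return Tibble with `marker`, `chrom`, `pos`, `genes` (list-column),
#'   `n_genes`, `category`, `unknown_chrom`.
#' @export
annotate_markers <- function(markers, annotation, craniofacial = character(),
                             growth = character(), window = 200000) {
  window <- check_number(window, "window", 0)
  purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    chrom <- markers$chrom[i]
    pos <- markers$pos[i]
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    unknown <- !chrom %in% annotation$chrom
    if (unknown) {
      hit_genes <- character()
      hit_biotypes <- character()
    } else {
      dist <- pmax(ann$start - pos, pos - ann$end, 0)
      hit <- dist <= window
      hit_genes <- ann$gene[hit]
      hit_biotypes <- ann$biotype[hit]
    }
    cat_label <- marker_category(hit_genes, hit_biotypes, craniofacial, growth)
    tibble(marker = markers$marker[i], chrom = chrom, pos = pos,
           genes = list(sort(unique(hit_genes))),
           n_genes = length(unique(hit_genes)),
           category = cat_label,
           unknown_chrom = unknown)
  })
}

#' Merge markers sharing an identical candidate-gene list into regions
#'
#' Markers on the same chromosome whose candidate gene sets are equal
#' collapse into one genomic region spanning the member markers. The merge
#' is order-invariant.
#'
#' @param annotations Tibble from [annotate_markers()].
#' @return Tibble with `region`, `chrom`, `start`, `end`, `markers`
#'   (list-column), `genes` (list-column), `category`.
#' @export
merge_markers <- function(annotations) {
  key <- vapply(seq_len(nrow(annotations)), function(i) {
    paste(annotations$chrom[i],
          paste(annotations$genes[[i]], collapse = ";"), sep = "|")
  }, character(1))
  ann <- dplyr::mutate(annotations, .key = key)
  grouped <- dplyr::group_by(ann, .data$.key)
  out <- dplyr::summarise(
    grouped,
    chrom = dplyr::first(.data$chrom),
    start = min(.data$pos),
    end = max(.data$pos),
    markers = list(sort(.data$marker)),
    genes = list(.data$genes[[1L]]),
    category = dplyr::first(.data$category),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$region <- sprintf("R%03d", seq_len(nrow(out)))
  dplyr::select(out, "region", "chrom", "start", "end", "markers", "genes",
                "category")
}

#' Build the epistatic interaction network at the region level
#'
#' Maps each significant marker pair to its merged regions; marker pairs
#' collapsing onto one region pair become a single undirected edge with the
#' multiplicity stored as `weight`; pairs falling inside a single region are
#' dropped (no self-loops) and counted.
#'
#' @param interactions An `interaction_table` (or tibble with `marker_j`,
#'   `marker_k`, and optionally `significant`).
#' @param regions Region tibble from [merge_markers()].
#' @return An igraph graph with vertex attributes `category`, `genes`
#'   (semicolon-joined) and a `dropped_self` graph attribute.
#' @export
build_interaction_graph <- function(interactions, regions) {
  ia <- as_tibble(interactions)
  if ("significant" %in% names(ia)) ia <- ia[which(ia$significant), ]
  marker2region <- tibble(
    marker = unlist(regions$markers),
    region = rep(regions$region, lengths(regions$markers))
  )
  lookup <- setNames(marker2region$region, marker2region$marker)
  rj <- lookup[ia$marker_j]
  rk <- lookup[ia$marker_k]
  if (anyNA(rj) || anyNA(rk)) abort("Some interacting markers are not annotated in `regions`.")
  self <- rj == rk
  dropped <- sum(self)
  edges <- tibble(a = pmin(rj[!self], rk[!self]), b = pmax(rj[!self], rk[!self]))
  edges <- dplyr::summarise(dplyr::group_by(edges, .data$a, .data$b),
                            weight = dplyr::n(), .groups = "drop")
  used <- sort(unique(c(edges$a, edges$b)))
  verts <- regions[match(used, regions$region), ]
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = tibble(name = verts$region, category = verts$category,
                      genes = vapply(verts$genes, paste, character(1),
                                     collapse = ";"))
  )
  g <- igraph::set_graph_attr(g, "dropped_self", dropped)
  g
}

#' Centrality measures of the epistatic network
#'
#' Kleinberg hub scores (principal eigenvector of `A A'`, normalized to max
#' 1), betweenness centrality (unnormalized shortest-path counts with even
#' splitting over ties) and Bonacich power centrality with exponent `beta`.
#' The default `beta` sits just below the reciprocal spectral radius of the
#' adjacency matrix, where the Bonacich series converges.
#'
#' @param graph igraph graph from [build_interaction_graph()].
#' @param power_beta Bonacich exponent; default `0.9 / (1 + lambda_1)`.
#' @return Tibble with `node`, `category` (if present), `hub_score`,
#'   `betweenness`, `power`.
#' @export
centralities <- function(graph, power_beta = NULL) {
  if (igraph::vcount(graph) == 0L) abort("Empty graph.")
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  lambda1 <- max(abs(eigen(adj, symmetric = TRUE, only.values = TRUE)$values))
  if (is.null(power_beta)) power_beta <- 0.9 / (1 + lambda1)
  hub <- igraph::hits_scores(graph, scale = TRUE)$hub
  btw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  pow <- igraph::power_centrality(graph, exponent = power_beta)
  cat_attr <- igraph::vertex_attr(graph, "category")
  tibble(node = igraph::V(graph)$name,
         category = cat_attr %||% NA_character_,
         hub_score = as.numeric(hub),
         betweenness = as.numeric(btw),
         power = as.numeric(pow))
}

#' Fisher enrichment of candidate genes in a reference list
#'
#' One-sided Fisher exact test of over-representation on the 2x2 table
#' candidate x in-reference-list; the reference list is intersected with the
#' universe first.
#'
#' @param candidate_genes Character vector, a subset of `universe`.
#' @param reference_list Character vector of reference gene ids.
#' @param universe All genes considered (default: union handled by caller,
#'   typically every gene in the annotation).
#' @return List with `odds_ratio`, `p`, `table`.
#' @export
enrichment_test <- function(candidate_genes, reference_list, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("Empty gene universe.")
  candidate_genes <- unique(candidate_genes)
  if (!all(candidate_genes %in% universe)) {
    abort("Candidate genes must be a subset of the universe.")
  }
  ref <- intersect(reference_list, universe)
  in_cand <- universe %in% candidate_genes
  in_ref <- universe %in% ref
  tab <- table(candidate = factor(in_cand, c(TRUE, FALSE)),
               reference = factor(in_ref, c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Homogeneity of marker-category proportions
#'
#' Pearson chi-square test (no continuity correction, df = 3) comparing two
#' vectors of counts over the four categories (Craniofacial, Growth, Other,
#' Regulatory) — e.g. before and after merging markers into regions.
#'
#' @param counts_a,counts_b Numeric vectors of 4 category counts.
#' @return List with `chi2`, `df`, `p`.
#' @export
category_homogeneity_test <- function(counts_a, counts_b) {
  if (length(counts_a) != 4L || length(counts_b) != 4L) {
    abort("Each count vector must have 4 categories.")
  }
  tab <- rbind(counts_a, counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("Zero expected cell count; pool sparse categories before testing.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Export a network and its centralities
#' @param graph igraph graph.
#' @param edge_path,graphml_path,centrality_path Output paths (skipped when
#'   `NULL`).
#' @param power_beta Passed to [centralities()].
#' @return Invisibly, the centrality tibble.
#' @export
write_network <- function(graph, edge_path = NULL, graphml_path = NULL,
                          centrality_path = NULL, power_beta = NULL) {
  if (!is.null(edge_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    readr::write_tsv(as_tibble(el), edge_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  cent <- centralities(graph, power_beta = power_beta)
  if (!is.null(centrality_path)) readr::write_tsv(cent, centrality_path)
  invisible(cent)
}
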