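## Haplotype networks: pairwise minimum mutation steps between haplotype
## CDS sequences, and a minimum spanning network (Kruskal growth with
## retention of equal-weight alternative edges).

#' Pairwise mutation-step distances between haplotype sequences
#'
#' The distance between two equal-length sequences is the number of
#' differing positions, except that a run of contiguous gap positions
#' counts as a single mutation step (one indel event). Sequences of
#' unequal length are first aligned pairwise (global, end-gapped)
#' so that an indel haplotype aligns against the others.
#'
#' @param seqs Named character vector of sequences over `A,C,G,T,-`.
#' @param gap_mode `"run"` (default: a gap run = 1 step) or `"position"`
#'   (each gap position = 1 step).
#' @return A symmetric integer matrix with zero diagonal.
#' @export
#' @examples
#' mutation_distance_matrix(c(h1 = "AAA", h2 = "AAT"))
mutation_distance_matrix <- function(seqs, gap_mode = c("run", "position")) {
  gap_mode <- match.arg(gap_mode)
  if (length(seqs) == 0) stop_gchap("empty sequence set")
  if (is.null(names(seqs))) names(seqs) <- paste0("Hap", seq_along(seqs))
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d[i, j] <- d[j, i] <- pair_steps(seqs[[i]], seqs[[j]], gap_mode)
    }
  }
  d
}

## mutation steps between two sequences, aligning first if lengths differ
pair_steps <- function(a, b, gap_mode) {
  if (nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("-", "", a)),
      Biostrings::DNAString(gsub("-", "", b)),
      type = "global", gapOpening = 10, gapExtension = 0.5)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  diff <- va != vb
  gap <- (va == "-") | (vb == "-")
  steps <- sum(diff & !gap)
  gd <- diff & gap
  if (any(gd)) {
    if (gap_mode == "position") {
      steps <- steps + sum(gd)
    } else {
      runs <- rle(gd)
      steps <- steps + sum(runs$values)  # each TRUE run = one indel event
    }
  }
  as.integer(steps)
}

#' Minimum spanning network over a distance matrix
#'
#' Kruskal-style growth in ascending distance with tie retention: an edge
#' is kept whenever its endpoints are in different components of the
#' graph formed by all strictly smaller (minus `epsilon`) retained edges
#' — so every edge whose weight equals the weight that first connects its
#' two components is retained, not just one arbitrary choice. The result
#' contains at least one minimum spanning tree; with `epsilon = 0` and
#' all pairwise distances distinct it is exactly the MST.
#'
#' @param d Symmetric numeric matrix with zero diagonal (no `NA`).
#' @param epsilon Additionally retain edges within `epsilon` of the
#'   connecting weight (default 0).
#' @return Tibble of retained edges: `hap_a`, `hap_b`, `steps`.
#' @export
minimum_spanning_network <- function(d, epsilon = 0) {
  if (any(is.na(d))) stop_gchap("distance matrix contains NA")
  if (!isSymmetric(unname(d))) stop_gchap("distance matrix must be symmetric")
  n <- nrow(d)
  nms <- rownames(d) %||% paste0("Hap", seq_len(n))
  if (n == 1) {
    return(tibble::tibble(hap_a = character(), hap_b = character(),
                          steps = numeric()))
  }
  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                          w = d[idx])
  edges <- dplyr::arrange(edges, .data$w)
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    w <- edges$w[k]
    ## components induced by retained edges strictly below w - epsilon
    parent <- dsu_new(n)
    sm <- which(keep & edges$w < w - epsilon - 1e-12)
    for (m in sm) parent <- dsu_union(parent, edges$i[m], edges$j[m])
    keep[k] <- dsu_find(parent, edges$i[k]) != dsu_find(parent, edges$j[k])
  }
  out <- edges[keep, , drop = FALSE]
  tibble::tibble(hap_a = nms[out$i], hap_b = nms[out$j], steps = out$w)
}

#' Build the haplotype network of one gene
#'
#' Combines the haplotype sequences, panel-wide frequencies and
#' per-population carrier counts of one gene into a minimum spanning
#' network whose nodes are haplotypes (sized by frequency, with
#' population composition for pie rendering) and whose edges carry
#' mutation steps.
#'
#' @param gchaps A `gchap_set` from [call_gchaps()].
#' @param panel Variety panel tibble.
#' @param gene Gene id.
#' @param epsilon Tie-retention slack passed to
#'   [minimum_spanning_network()].
#' @param gap_mode Passed to [mutation_distance_matrix()].
#' @return An object of class `hap_network`: list with `gene_id`, `nodes`
#'   (tibble: `hap_id`, `n`, `freq`, one `pop_*` count column per
#'   population), `edges` (tibble: `hap_a`, `hap_b`, `steps`) and
#'   `distance` (the full matrix).
#' @export
build_hap_network <- function(gchaps, panel, gene, epsilon = 0,
                              gap_mode = "run") {
  haps <- dplyr::filter(gchaps$haplotypes, .data$gene_id == !!gene)
  if (nrow(haps) == 0) stop_gchap(paste0("gene ", gene, " not in gchap set"))
  asg <- dplyr::filter(gchaps$assignments, .data$gene_id == !!gene)
  seqs <- stats::setNames(haps$hap_seq, haps$hap_id)
  d <- mutation_distance_matrix(seqs, gap_mode = gap_mode)
  edges <- minimum_spanning_network(d, epsilon = epsilon)
  comp <- dplyr::count(dplyr::inner_join(asg, panel, by = "variety_id"),
                       .data$hap_id, .data$population)
  comp <- tidyr::pivot_wider(comp, names_from = "population",
                             values_from = "n", values_fill = 0L,
                             names_prefix = "pop_")
  nodes <- dplyr::left_join(
    dplyr::select(haps, "hap_id", n = "n_carriers", "freq"),
    comp, by = "hap_id")
  nodes <- dplyr::mutate(nodes, dplyr::across(dplyr::starts_with("pop_"),
                                              function(v) tidyr::replace_na(v, 0L)))
  structure(list(gene_id = gene, nodes = nodes, edges = edges,
                 distance = d, distance_definition = paste0(
                   "mutation steps (gap ", gap_mode, ")")),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", x$gene_id, ": ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges (", x$distance_definition, ")\n", sep = "")
  invisible(x)
}

## igraph view of a hap_network (used for export and checks)
as_igraph_hap_network <- function(net) {
  g <- igraph::graph_from_data_frame(
    dplyr::rename(net$edges, from = "hap_a", to = "hap_b", weight = "steps"),
    directed = FALSE,
    vertices = as.data.frame(dplyr::rename(net$nodes, name = "hap_id")))
  g
}

#' Export a haplotype network
#'
#' Writes GraphML (node attributes include frequency and per-population
#' counts for pie rendering) and/or an edge-list TSV.
#'
#' @param net A `hap_network`.
#' @param path Output path (extension added per format).
#' @param format `"graphml"`, `"tsv"`, or `"both"` (default).
#' @return Character vector of files written, invisibly.
#' @export
export_network <- function(net, path, format = c("both", "graphml", "tsv")) {
  format <- match.arg(format)
  written <- character()
  base <- sub("\\.(graphml|tsv)$", "", path)
  if (format %in% c("both", "graphml")) {
    f <- paste0(base, ".graphml")
    igraph::write_graph(as_igraph_hap_network(net), f, format = "graphml")
    written <- c(written, f)
  }
  if (format %in% c("both", "tsv")) {
    f <- paste0(base, ".tsv")
    write_gchap_tsv(net$edges, f)
    written <- c(written, f)
  }
  invisible(written)
}

#' @method autoplot hap_network
#' @describeIn build_hap_network `autoplot()` draws the network with node
#'   area proportional to frequency.
#' @param object A `hap_network`.
#' @param ... Unused.
#' @export
autoplot.hap_network <- function(object, ...) {
  g <- as_igraph_hap_network(object)
  set.seed(1)  # layout only
  lay <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  edges <- dplyr::left_join(
    object$edges,
    dplyr::select(nodes, hap_a = "hap_id", xa = "x", ya = "y"), by = "hap_a")
  edges <- dplyr::left_join(
    edges,
    dplyr::select(nodes, hap_b = "hap_id", xb = "x", yb = "y"), by = "hap_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey50") +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes((.data$xa + .data$xb) / 2,
                                    (.data$ya + .data$yb) / 2,
                                    label = .data$steps), size = 3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$freq),
                        colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$hap_id),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 15) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("gcHap network: ", object$gene_id),
                  size = "frequency")
}
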