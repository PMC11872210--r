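#' Bin raw SSR fragment sizes into allele classes
#'
#' Capillary-electrophoresis fragment sizes scatter around the true allele
#' length; sizes within \code{bin_width} of each other (single-linkage on
#' the sorted sizes) are collapsed to one allele, represented by the most
#' frequent size in the bin rounded to the nearest integer (ties broken by
#' the rounded mean of the tied sizes). Known artefact alleles can be
#' removed via \code{exclusions}.
#'
#' @param samples SSR table as produced by [generate_ssr()] /
#'   [read_ssr_csv()]: metadata columns plus one slash-separated size
#'   column per locus; sizes may be fractional.
#' @param bin_width maximal size gap (bp) joined into one bin; >= 1.
#' @param exclusions data.frame with columns \code{locus} and \code{size}:
#'   binned alleles to drop from every sample.
#' @return the SSR table with integer, binned allele sets.
#' @export
#' @examples
#' x <- data.frame(sample_id = c("s1", "s2"), cytotype = "hybrid",
#'                 origin = NA, MS02 = c("249.6", "250.2"))
#' bin_alleles(x)$MS02  # both collapse to "250"
bin_alleles <- function(samples, bin_width = 1, exclusions = NULL) {
  stopifnot(bin_width >= 1)
  loci <- ssr_locus_columns(samples)
  for (lc in loci) {
    sets <- ssr_allele_sets(samples, lc)
    all_sizes <- unlist(sets)
    if (any(all_sizes < 0)) stop("negative fragment sizes at locus ", lc)
    if (!length(all_sizes)) next
    freq <- table(all_sizes)
    uniq <- sort(as.numeric(names(freq)))
    # single-linkage chains: break where the gap exceeds bin_width
    grp <- cumsum(c(1, diff(uniq) > bin_width))
    rep_of <- numeric(length(uniq))
    for (g in unique(grp)) {
      members <- uniq[grp == g]
      counts <- as.numeric(freq[as.character(members)])
      modal <- members[counts == max(counts)]
      rep_of[grp == g] <- round(mean(modal))
    }
    map <- stats::setNames(rep_of, as.character(uniq))
    excl <- if (!is.null(exclusions))
      exclusions$size[exclusions$locus == lc] else numeric(0)
    samples[[lc]] <- vapply(sets, function(s) {
      binned <- unique(as.numeric(map[as.character(s)]))
      format_alleles(setdiff(binned, excl))
    }, character(1))
  }
  samples
}

# One canonical string per sample over all loci, e.g.
# "MS02=268;MS07=257/273;..." -- the multilocus genotype identity.
multilocus_key <- function(samples) {
  loci <- sort(ssr_locus_columns(samples))
  keys <- lapply(loci, function(lc)
    vapply(ssr_allele_sets(samples, lc), format_alleles, character(1)))
  do.call(paste, c(Map(function(lc, k) paste0(lc, "=", k), loci, keys),
                   sep = ";"))
}

#' Call multilocus genotypes and their frequencies
#'
#' Samples with identical allele sets at every locus share a genotype.
#' Genotypes are labelled A, B, C, ... in descending frequency (count ties
#' broken lexicographically by the serialized allele content, so labels do
#' not depend on sample order), and relative frequencies are reported
#' overall and per cytotype as count/stratum-size x 100, rounded half-up
#' to one decimal.
#'
#' @param samples SSR table with binned alleles; at least one sample.
#' @return object of class \code{genotype_table}: \code{labels} (named by
#'   sample_id), \code{table} (per-genotype counts and frequencies),
#'   \code{n} stratum sizes, \code{n_genotypes}, \code{n_alleles} (distinct
#'   alleles in the population) and \code{n_modal_alleles} (allele
#'   complement size of genotype A).
#' @export
call_multilocus_genotypes <- function(samples) {
  if (!nrow(samples)) stop("need at least one sample")
  key <- multilocus_key(samples)
  counts <- table(key)
  ord <- order(-as.numeric(counts), names(counts))
  genos <- names(counts)[ord]
  labels_all <- make_genotype_labels(length(genos))
  lab_of <- stats::setNames(labels_all, genos)
  sample_lab <- stats::setNames(as.character(lab_of[key]), samples$sample_id)

  strata <- c("hybrid", "allopolyploid")
  n_str <- vapply(strata, function(s) sum(samples$cytotype == s), numeric(1))
  n_tot <- nrow(samples)
  tab <- data.frame(label = labels_all,
                    genotype = genos,
                    n = as.numeric(counts[genos]),
                    stringsAsFactors = FALSE)
  for (s in strata) {
    ns <- vapply(genos, function(g)
      sum(key == g & samples$cytotype == s), numeric(1))
    tab[[paste0("n_", s)]] <- ns
    tab[[paste0("freq_", s)]] <-
      if (n_str[[s]] > 0) round_half_up(100 * ns / n_str[[s]], 1) else NA_real_
  }
  tab$freq_total <- round_half_up(100 * tab$n / n_tot, 1)

  modal_alleles <- sum(lengths(lapply(ssr_locus_columns(samples), function(lc)
    parse_alleles(samples[[lc]][which(key == genos[1])[1]]))))
  all_alleles <- sum(vapply(ssr_locus_columns(samples), function(lc)
    length(unique(unlist(ssr_allele_sets(samples, lc)))), numeric(1)))

  structure(list(labels = sample_lab, table = tab,
                 n = c(total = n_tot, hybrid = n_str[["hybrid"]],
                       allopolyploid = n_str[["allopolyploid"]]),
                 n_genotypes = length(genos),
                 n_alleles = all_alleles,
                 n_modal_alleles = modal_alleles),
            class = "genotype_table")
}

# A, B, ..., Z, AA, AB, ... labels in frequency order
make_genotype_labels <- function(n) {
  lab <- LETTERS
  while (length(lab) < n)
    lab <- c(lab, as.vector(t(outer(LETTERS, LETTERS, paste0))))
  lab[seq_len(n)]
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Multilocus genotypes: %d genotypes in %d samples (%d hybrid, %d allopolyploid)\n",
              x$n_genotypes, x$n["total"], x$n["hybrid"], x$n["allopolyploid"]))
  cat(sprintf("Distinct alleles: %d (modal genotype A carries %d)\n",
              x$n_alleles, x$n_modal_alleles))
  print(x$table[, c("label", "n", "freq_hybrid", "freq_allopolyploid",
                    "freq_total")], row.names = FALSE, ...)
  invisible(x)
}

#' Per-locus genotype-class frequency table
#'
#' For one locus, tabulates the distinct allele-set classes and their
#' carrier frequencies per cytotype and overall (count / stratum size x
#' 100, rounded half-up to one decimal) -- the arithmetic of the published
#' per-marker frequency table.
#'
#' @param samples SSR table with binned alleles.
#' @param locus locus (column) name.
#' @return data.frame with one row per allele-set class: \code{locus},
#'   \code{genotype} (slash-separated sizes), per-stratum counts and
#'   frequencies, sorted by descending total count.
#' @export
frequency_table <- function(samples, locus) {
  if (!(locus %in% ssr_locus_columns(samples)))
    stop("unknown locus: ", locus)
  cls <- vapply(ssr_allele_sets(samples, locus), format_alleles, character(1))
  keep <- nzchar(cls)  # empty set = failed amplification, not a class
  classes <- sort(unique(cls[keep]))
  n_h <- sum(samples$cytotype == "hybrid")
  n_a <- sum(samples$cytotype == "allopolyploid")
  n_t <- nrow(samples)
  out <- data.frame(locus = locus, genotype = classes, stringsAsFactors = FALSE)
  out$n_hybrid <- vapply(classes, function(g)
    sum(cls == g & samples$cytotype == "hybrid"), numeric(1))
  out$n_allopolyploid <- vapply(classes, function(g)
    sum(cls == g & samples$cytotype == "allopolyploid"), numeric(1))
  out$n_total <- out$n_hybrid + out$n_allopolyploid
  out$freq_hybrid <- if (n_h) round_half_up(100 * out$n_hybrid / n_h, 1) else NA_real_
  out$freq_allopolyploid <- if (n_a) round_half_up(100 * out$n_allopolyploid / n_a, 1) else NA_real_
  out$freq_total <- round_half_up(100 * out$n_total / n_t, 1)
  out <- out[order(-out$n_total, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allelic dissimilarity matrix
#'
#' Pairwise dissimilarity between samples as the number of alleles present
#' in exactly one of the two samples (size of the symmetric difference),
#' summed over loci -- the presence/absence treatment appropriate for
#' dominant polyploid SSR data. A locus with a failed amplification (empty
#' set) in either sample is treated as missing there and contributes 0.
#'
#' @param samples SSR table with binned alleles.
#' @return symmetric numeric matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
dissimilarity_matrix <- function(samples) {
  n <- nrow(samples)
  loci <- ssr_locus_columns(samples)
  sets <- lapply(loci, function(lc) ssr_allele_sets(samples, lc))
  d <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  for (lsets in sets) {
    for (i in seq_len(n - 1)) {
      a <- lsets[[i]]
      if (!length(a)) next
      for (j in (i + 1):n) {
        b <- lsets[[j]]
        if (!length(b)) next
        dd <- length(setdiff(a, b)) + length(setdiff(b, a))
        d[i, j] <- d[i, j] + dd
      }
    }
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

#' Minimum spanning network over genotype dissimilarities
#'
#' Builds a minimum spanning tree (Kruskal) on the complete weighted graph
#' given by \code{d} and retains, in addition, every non-tree edge whose
#' weight equals the maximum edge weight on the tree path between its
#' endpoints -- i.e. every tied alternative that could replace a tree edge
#' without increasing the total weight. The result visualises clonal
#' lineages: nodes are multilocus genotypes, edge weights allele
#' differences.
#'
#' @param d symmetric non-negative dissimilarity matrix, zero diagonal,
#'   no NaN/NA.
#' @param node_counts optional named vector of per-node sample counts
#'   (stored on the nodes for plotting/export).
#' @return object of class \code{msn}: \code{nodes} (name, count),
#'   \code{edges} (all node pairs with \code{weight}, \code{in_mst},
#'   \code{in_msn}) and \code{mst_weight}.
#' @export
minimum_spanning_network <- function(d, node_counts = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(!is.finite(d))) stop("d contains non-finite weights")
  if (any(abs(d - t(d)) > 1e-12)) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  if (any(d < 0)) stop("d must be non-negative")
  n <- nrow(d)
  nm <- rownames(d)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(from = nm[pairs[, 1]], to = nm[pairs[, 2]],
                      weight = d[pairs], i = pairs[, 1], j = pairs[, 2],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$weight, edges$i, edges$j), , drop = FALSE]

  # Kruskal with union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  in_mst <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) { parent[ri] <- rj; in_mst[e] <- TRUE }
  }
  edges$in_mst <- in_mst

  # adjacency of the tree for path queries
  adj <- vector("list", n)
  for (e in which(in_mst)) {
    adj[[edges$i[e]]] <- rbind(adj[[edges$i[e]]], c(edges$j[e], edges$weight[e]))
    adj[[edges$j[e]]] <- rbind(adj[[edges$j[e]]], c(edges$i[e], edges$weight[e]))
  }
  # max edge weight on the unique tree path between a and b (DFS)
  path_max <- function(a, b) {
    stack <- list(c(a, -Inf)); seen <- logical(n); seen[a] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- cur[1]; mx <- cur[2]
      if (v == b) return(mx)
      nb <- adj[[v]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (!seen[w]) { seen[w] <- TRUE
          stack[[length(stack) + 1]] <- c(w, max(mx, nb[r, 2])) }
      }
    }
    stop("tree path not found")  # cannot happen on a spanning tree
  }
  edges$in_msn <- edges$in_mst
  for (e in which(!in_mst))
    if (edges$weight[e] == path_max(edges$i[e], edges$j[e]))
      edges$in_msn[e] <- TRUE

  nodes <- data.frame(name = nm, stringsAsFactors = FALSE)
  nodes$count <- if (is.null(node_counts)) NA_real_ else
    as.numeric(node_counts[nm])
  structure(list(nodes = nodes,
                 edges = edges[, c("from", "to", "weight", "in_mst", "in_msn")],
                 mst_weight = sum(edges$weight[edges$in_mst])),
            class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat(sprintf("Minimum spanning network: %d nodes, %d MSN edges (%d tree + %d tied), total tree weight %g\n",
              nrow(x$nodes), sum(x$edges$in_msn), sum(x$edges$in_mst),
              sum(x$edges$in_msn) - sum(x$edges$in_mst), x$mst_weight))
  print(x$edges[x$edges$in_msn, ], row.names = FALSE, ...)
  invisible(x)
}

#' Export a minimum spanning network
#'
#' \code{write_msn_graphml()} writes the MSN subgraph (retained edges only,
#' with \code{weight} and \code{in_mst} edge attributes and node sample
#' counts) as GraphML; \code{write_msn_edges()} writes the full edge list
#' with the \code{in_msn} flag as CSV.
#'
#' @param msn an object from [minimum_spanning_network()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_msn_graphml <- function(msn, path) {
  keep <- msn$edges[msn$edges$in_msn, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep[, c("from", "to", "weight", "in_mst")],
                                     directed = FALSE, vertices = msn$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_msn_graphml
#' @export
write_msn_edges <- function(msn, path) {
  utils::write.csv(msn$edges, path, row.names = FALSE)
  invisible(path)
}

#' One representative sample per called genotype
#'
#' Convenience for building genotype-level dissimilarities and networks:
#' returns the SSR table reduced to the first sample of each genotype
#' label, with sample ids replaced by the labels.
#'
#' @param samples SSR table with binned alleles.
#' @param genotypes matching [call_multilocus_genotypes()] result.
#' @return SSR table with one row per genotype, ordered by label.
#' @export
genotype_representatives <- function(samples, genotypes) {
  lab <- genotypes$labels[samples$sample_id]
  first <- !duplicated(lab)
  rep_tab <- samples[first, , drop = FALSE]
  rep_tab$sample_id <- lab[first]
  rep_tab <- rep_tab[order(match(rep_tab$sample_id, genotypes$table$label)), ,
                     drop = FALSE]
  rownames(rep_tab) <- NULL
  rep_tab
}
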