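#' Remove nonspecific terms from an annotation table before closure
#'
#' Exclusions are applied to the raw (pre-closure) annotations: only the
#' listed terms themselves are removed, never ancestors reached through
#' other terms. Probands left with no terms are recorded in the
#' `empty_probands` attribute and trigger a named error downstream when a
#' similarity matrix is requested.
#'
#' @param annotations Annotation tibble (`proband_id`, `term_id`).
#' @param exclude Character vector of term ids or exact term names.
#' @param graph An [load_obo()] ontology, used to resolve names to ids.
#' @return The filtered annotation tibble with attribute `empty_probands`.
#' @export
apply_exclusions <- function(annotations, exclude, graph) {
  check_annotation_table(annotations)
  stopifnot(inherits(graph, "onto_graph"))
  if (length(exclude) == 0) {
    attr(annotations, "empty_probands") <- character(0)
    return(annotations)
  }
  by_name <- names(graph$name)[match(exclude, graph$name)]
  resolved <- ifelse(!is.na(by_name), by_name,
                     ifelse(exclude %in% names(graph$alt),
                            unname(graph$alt[exclude]), exclude))
  bad <- resolved[!resolved %in% graph$terms]
  if (length(bad)) {
    lc_abort(paste0("Exclusion term(s) not resolvable by id or exact name: ",
                    paste(bad, collapse = ", ")), "error_config")
  }
  before <- unique(annotations$proband_id)
  out <- dplyr::filter(annotations, !.data$term_id %in% resolved)
  empty <- setdiff(before, unique(out$proband_id))
  if (length(empty)) {
    rlang::warn(paste0("Proband(s) left with no terms after exclusion: ",
                       paste(empty, collapse = ", ")))
  }
  attr(out, "empty_probands") <- empty
  out
}

#' Pairwise proband phenotypic similarity matrix
#'
#' Entry (i, j) is the symmetric best-match-average Lin similarity
#' ([set_similarity()]) between the closed term sets of probands i and j.
#'
#' @param annotations Annotation tibble (`proband_id`, `term_id`); closure is
#'   applied internally (idempotent if already closed).
#' @param ic An [compute_ic()] table.
#' @param graph An [load_obo()] ontology.
#' @return A symmetric numeric matrix with unit diagonal, dimnames set to
#'   the sorted proband ids.
#' @export
build_similarity_matrix <- function(annotations, ic, graph) {
  check_annotation_table(annotations)
  empty <- attr(annotations, "empty_probands") %||% character(0)
  if (length(empty)) {
    lc_abort(paste0("Similarity undefined for proband(s) with empty term sets: ",
                    paste(empty, collapse = ", ")), "error_empty_proband")
  }
  closed <- cohort_closure(annotations, graph)
  sets <- split(closed$term_id, closed$proband_id)
  ids <- sort(names(sets))
  lc_assert(length(ids) >= 2, "At least two probands are required.")
  m <- lin_matrix(unique(closed$term_id), ic, graph)
  n <- length(ids)
  S <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub <- m[sets[[ids[i]]], sets[[ids[j]]], drop = FALSE]
    s <- (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
    S[i, j] <- S[j, i] <- s
  }
  S
}

check_square_matrix <- function(M, what) {
  lc_assert(is.matrix(M) && nrow(M) == ncol(M) && !is.null(rownames(M)),
            paste0(what, " must be a square matrix with dimnames."))
  lc_assert(isTRUE(all.equal(M, t(M), tolerance = 1e-8)),
            paste0(what, " must be symmetric."), "error_precondition")
  invisible(M)
}

#' Convert a similarity matrix to a distance matrix
#'
#' `D = 1 - S` with the diagonal forced to zero; valid because similarities
#' lie in `[0, 1]` with unit self-similarity.
#'
#' @param S Similarity matrix from [build_similarity_matrix()].
#' @return Distance matrix of the same shape.
#' @export
similarity_to_distance <- function(S) {
  check_square_matrix(S, "Similarity matrix")
  D <- 1 - S
  diag(D) <- 0
  D
}

#' Ward hierarchical clustering of a proband distance matrix
#'
#' Agglomerates with the Ward criterion in its squared-distance
#' (Lance-Williams, "ward.D2") form. Probands are sorted into canonical
#' (lexicographic) order before linkage so that results do not depend on
#' input order even in the presence of tied merges.
#'
#' @param D Distance matrix from [similarity_to_distance()].
#' @return An object of class `hclust` with `n - 1` merges.
#' @export
ward_cluster <- function(D) {
  check_square_matrix(D, "Distance matrix")
  lc_assert(all(D >= -1e-12), "Distances must be non-negative.", "error_precondition")
  lc_assert(nrow(D) >= 2, "At least two probands are required.")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

# Pooled within-cluster dispersion W_k = sum_r (1/(2 n_r)) sum_{i,j in C_r} d_ij^2
within_dispersion <- function(D, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    sum(D[idx, idx, drop = FALSE]^2) / (2 * length(idx))
  }, numeric(1)))
}

#' Gap statistic curve for choosing the number of clusters
#'
#' For k = 1..`kmax`, computes the pooled within-cluster dispersion
#' `W_k` of the Ward cut at k and compares `log W_k` with its expectation
#' under a null reference. Because the input is a bare distance matrix, the
#' reference is built by classical multidimensional scaling of `D` to the
#' leading components covering at least 95% of the positive eigen-mass
#' (capped at 10 dimensions), then sampling points uniformly within the
#' per-dimension bounding box. `Gap(k) = mean_b log W*_kb - log W_k`, and
#' `se(k) = sd_b(log W*) * sqrt(1 + 1/B)`.
#'
#' @param D Distance matrix.
#' @param kmax Largest cluster count considered (must be `< n`).
#' @param B Number of reference data sets (at least 10).
#' @param seed Mandatory RNG seed; the curve is reproducible given the seed.
#' @return A `gap_curve`: tibble with columns `k`, `logW`, `ElogW`, `gap`,
#'   `se`, and attributes `B` and `seed`.
#' @export
gap_statistic <- function(D, kmax = 15, B = 100, seed) {
  check_square_matrix(D, "Distance matrix")
  n <- nrow(D)
  if (kmax >= n) lc_abort("`kmax` must be smaller than the number of probands.", "error_input")
  lc_assert(kmax >= 2, "`kmax` must be at least 2.")
  lc_assert(B >= 10, "`B` must be at least 10.")
  if (missing(seed)) lc_abort("`seed` is required for the gap statistic.", "error_input")

  hc <- ward_cluster(D)
  cuts <- stats::cutree(hc, k = seq_len(kmax))
  logW <- vapply(seq_len(kmax), function(k) {
    labels <- cuts[, k]
    log(max(within_dispersion(D[names(labels), names(labels)], labels),
            .Machine$double.eps))
  }, numeric(1))

  # reference coordinates from classical MDS; fewer positive eigenvalues than
  # asked for is expected and handled below
  mds <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(n - 1, 10), eig = TRUE)
  )
  eig <- mds$eig[mds$eig > 1e-12]
  if (length(eig) == 0) {
    ndim <- 1
    X <- matrix(0, n, 1)
  } else {
    frac <- cumsum(eig) / sum(eig)
    ndim <- min(which(frac >= 0.95), 10, ncol(mds$points))
    X <- mds$points[, seq_len(ndim), drop = FALSE]
  }
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)

  logWstar <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      Xb <- vapply(seq_along(lo), function(d) stats::runif(n, lo[d], hi[d]),
                   numeric(n))
      Db <- as.matrix(stats::dist(Xb))
      hcb <- stats::hclust(stats::as.dist(Db), method = "ward.D2")
      cutsb <- stats::cutree(hcb, k = seq_len(kmax))
      vapply(seq_len(kmax), function(k) {
        log(max(within_dispersion(Db, cutsb[, k]), .Machine$double.eps))
      }, numeric(1))
    }, numeric(kmax))
  })
  ElogW <- rowMeans(logWstar)
  sdk <- sqrt(rowMeans((logWstar - ElogW)^2))

  out <- tibble::tibble(
    k = seq_len(kmax),
    logW = logW,
    ElogW = ElogW,
    gap = ElogW - logW,
    se = sdk * sqrt(1 + 1 / B)
  )
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("gap_curve", class(out))
  out
}

#' Select the number of clusters from a gap curve
#'
#' The default rule locates the point at which the slope of the gap curve
#' decreases the most: the k in `[2, kmax - 1]` minimising the second
#' difference `Gap(k+1) - 2 Gap(k) + Gap(k-1)`. The classical one-standard-
#' error rule (smallest k with `Gap(k) >= Gap(k+1) - se(k+1)`) is available
#' as an alternative, and an explicit override always wins.
#'
#' @param curve A [gap_statistic()] curve.
#' @param method `"second_diff"` (default) or `"one_se"`.
#' @param k_override Optional integer forcing the returned k.
#' @return An integer cluster count.
#' @export
select_k <- function(curve, method = c("second_diff", "one_se"), k_override = NULL) {
  if (!is.null(k_override)) return(as.integer(k_override))
  method <- match.arg(method)
  lc_assert(inherits(curve, "gap_curve"), "`curve` must be a gap_curve.")
  kmax <- nrow(curve)
  lc_assert(kmax >= 3, "Gap curve needs kmax >= 3 to select k.")
  gap <- curve$gap
  if (method == "one_se") {
    for (k in seq_len(kmax - 1)) {
      if (gap[k] >= gap[k + 1] - curve$se[k + 1]) return(k)
    }
    return(kmax)
  }
  ks <- 2:(kmax - 1)
  d2 <- gap[ks + 1] - 2 * gap[ks] + gap[ks - 1]
  if (diff(range(d2)) < 1e-12) {
    rlang::warn("Gap curve has no elbow (all second differences equal); choosing the smallest k.")
    return(ks[1])
  }
  ks[which.min(d2)]
}

#' Cut a dendrogram into k clusters
#'
#' @param hc An `hclust` tree from [ward_cluster()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `cluster_assignment`: tibble (`proband_id`, `cluster`) with
#'   attributes `leaf_order` (dendrogram leaf order, used to order heatmaps)
#'   and `dendrogram` (the `hclust` object).
#' @export
cut_clusters <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k < 1 || k > n) lc_abort("`k` must lie in [1, n].", "error_input")
  labels <- stats::cutree(hc, k = k)
  out <- tibble::tibble(proband_id = names(labels), cluster = unname(labels))
  attr(out, "leaf_order") <- hc$labels[hc$order]
  attr(out, "dendrogram") <- hc
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Per-cluster phenotype term frequencies
#'
#' Fraction of each cluster's probands annotated (post-closure or raw,
#' whatever is passed) with each term; used to build phenotype-grid
#' summaries.
#'
#' @param assignment A [cut_clusters()] assignment covering every proband in
#'   `annotations`.
#' @param annotations Annotation tibble (`proband_id`, `term_id`).
#' @return Tibble (`cluster`, `term_id`, `n`, `frequency`) completed with
#'   zero rows for cluster/term pairs never observed.
#' @export
cluster_term_frequencies <- function(assignment, annotations) {
  check_annotation_table(annotations)
  missing <- setdiff(unique(annotations$proband_id), assignment$proband_id)
  lc_assert(length(missing) == 0,
            paste0("Unassigned proband(s): ", paste(missing, collapse = ", ")))
  sizes <- dplyr::count(assignment, .data$cluster, name = "size")
  annotations %>%
    dplyr::distinct(.data$proband_id, .data$term_id) %>%
    dplyr::inner_join(assignment, by = "proband_id") %>%
    dplyr::count(.data$cluster, .data$term_id) %>%
    tidyr::complete(.data$cluster, .data$term_id, fill = list(n = 0L)) %>%
    dplyr::inner_join(sizes, by = "cluster") %>%
    dplyr::mutate(frequency = .data$n / .data$size) %>%
    dplyr::select("cluster", "term_id", "n", "frequency")
}

#' Largest number of a proband subset sharing one cluster
#'
#' @param assignment A [cut_clusters()] assignment.
#' @param ids Proband ids of interest (e.g. the biallelic probands).
#' @return Integer: the maximum, over clusters, of the number of `ids`
#'   assigned to that cluster (0 for an empty subset).
#' @export
cocluster_count <- function(assignment, ids) {
  if (length(ids) == 0) return(0L)
  unknown <- setdiff(ids, assignment$proband_id)
  if (length(unknown)) {
    lc_abort(paste0("Unknown proband id(s): ", paste(unknown, collapse = ", ")),
             "error_lookup")
  }
  sub <- assignment$cluster[assignment$proband_id %in% ids]
  max(table(sub))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights, so the tree can be drawn by
#' any phylogenetics viewer.
#'
#' @param hc An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Full phenotype-similarity clustering pipeline
#'
#' Convenience wrapper running exclusion filtering, ancestor closure, IC
#' computation, similarity and distance matrices, the gap-statistic curve,
#' Ward clustering and the cluster cut.
#'
#' @param annotations Raw annotation tibble (`proband_id`, `term_id`).
#' @param graph An [load_obo()] ontology.
#' @param exclude Terms (ids or exact names) removed before closure.
#' @param k Cluster count; `NULL` selects via [select_k()] on the gap curve.
#' @param kmax,B Gap-statistic parameters (see [gap_statistic()]).
#' @param seed RNG seed for the gap reference distribution.
#' @return A `phenoclust_fit` list: `similarity`, `distance`, `dendrogram`,
#'   `gap`, `k`, `assignment`, `ic`, `term_frequencies`.
#' @examples
#' g <- load_obo(write_mini_ontology(tempfile(fileext = ".obo")))
#' fit <- phenocluster(proband_annotations(), g,
#'                     exclude = exclusion_terms(), k = 5, B = 20, seed = 1)
#' cocluster_count(fit$assignment, biallelic_probands())
#' @export
phenocluster <- function(annotations, graph, exclude = character(),
                         k = NULL, kmax = 15, B = 100, seed = 1) {
  ann <- apply_exclusions(annotations, exclude, graph)
  empty <- attr(ann, "empty_probands")
  if (length(empty)) {
    lc_abort(paste0("Proband(s) with empty post-exclusion term sets: ",
                    paste(empty, collapse = ", ")), "error_empty_proband")
  }
  closed <- cohort_closure(ann, graph)
  ic <- compute_ic(closed, graph)
  S <- build_similarity_matrix(closed, ic, graph)
  D <- similarity_to_distance(S)
  hc <- ward_cluster(D)
  gap <- gap_statistic(D, kmax = min(kmax, nrow(D) - 1), B = B, seed = seed)
  k_used <- if (is.null(k)) select_k(gap) else as.integer(k)
  assignment <- cut_clusters(hc, k_used)
  structure(
    list(similarity = S, distance = D, dendrogram = hc, gap = gap,
         k = k_used, assignment = assignment, ic = ic,
         term_frequencies = cluster_term_frequencies(assignment, closed)),
    class = "phenoclust_fit"
  )
}

#' @export
print.phenoclust_fit <- function(x, ...) {
  cat("<phenoclust_fit> ", nrow(x$assignment), " probands in ", x$k,
      " clusters\n", sep = "")
  print(dplyr::count(x$assignment, .data$cluster))
  invisible(x)
}
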