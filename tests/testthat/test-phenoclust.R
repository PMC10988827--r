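mini_fit_inputs <- function() {
  g <- mini_ontology()
  ann <- apply_exclusions(proband_annotations(), exclusion_terms(), g)
  closed <- cohort_closure(ann, g)
  list(g = g, closed = closed, ic = compute_ic(closed, g))
}

test_that("exclusions remove only the listed terms, resolve names, flag empties", {
  g <- mini_ontology()
  ann <- tibble::tibble(
    proband_id = c("x", "x", "y"),
    term_id = c("CP:0000041", "CP:0000005", "CP:0000043")
  )
  out <- apply_exclusions(ann, "atrial septal defect", g)
  expect_identical(out$term_id, c("CP:0000005", "CP:0000043"))
  # identity when the exclusion list is empty
  expect_identical(apply_exclusions(ann, character(0), g)$term_id, ann$term_id)
  # a proband stripped of every term is flagged and later errors by name
  expect_warning(
    out2 <- apply_exclusions(ann, c("CP:0000041", "CP:0000005", "CP:0000043"), g),
    "x"
  )
  expect_setequal(attr(out2, "empty_probands"), c("x", "y"))
  ic <- compute_ic(cohort_closure(ann, g), g)
  expect_error(build_similarity_matrix(out2, ic, g),
               class = "latcohort_error_empty_proband")
  expect_error(apply_exclusions(ann, "no such term", g),
               class = "latcohort_error_config")
})

test_that("similarity matrix is symmetric with unit diagonal and matches per-pair scores", {
  inp <- mini_fit_inputs()
  S <- build_similarity_matrix(inp$closed, inp$ic, inp$g)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 & S <= 1))
  sets <- split(inp$closed$term_id, inp$closed$proband_id)
  for (pair in list(c("CVG0005", "LAT0080"), c("LAT1763", "CVG0006"))) {
    expect_equal(S[pair[1], pair[2]],
                 set_similarity(sets[[pair[1]]], sets[[pair[2]]],
                                inp$ic, inp$g))
  }
  # identical term sets give off-diagonal 1 (the biallelic block)
  expect_equal(S["LAT1763", "LAT0108"], 1)
  expect_error(
    build_similarity_matrix(dplyr::filter(inp$closed, proband_id == "CVG0005"),
                            inp$ic, inp$g),
    class = "latcohort_error_input"
  )
})

test_that("distance transform flips similarity monotonically with zero diagonal", {
  inp <- mini_fit_inputs()
  S <- build_similarity_matrix(inp$closed, inp$ic, inp$g)
  D <- similarity_to_distance(S)
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_equal(D[lower.tri(D)], 1 - S[lower.tri(S)])
})

test_that("Ward clustering separates two tight blobs and ignores input order", {
  # 4 + 4 points: within-blob distances ~0.1, across ~1
  ids <- sprintf("q%02d", 1:8)
  D <- matrix(1, 8, 8, dimnames = list(ids, ids))
  D[1:4, 1:4] <- 0.1; D[5:8, 5:8] <- 0.1
  diag(D) <- 0
  hc <- ward_cluster(D)
  # first 6 merges stay within blobs: both blobs complete before any
  # cross-blob merge
  lab <- cut_clusters(hc, 2)
  expect_equal(length(unique(lab$cluster[lab$proband_id %in% ids[1:4]])), 1)
  expect_equal(length(unique(lab$cluster[lab$proband_id %in% ids[5:8]])), 1)
  expect_true(all(hc$height[1:6] < hc$height[7]))
  # permuting the matrix leaves cut labels unchanged up to relabeling
  perm <- sample(8)
  hc2 <- ward_cluster(D[perm, perm])
  lab2 <- cut_clusters(hc2, 2)
  joined <- dplyr::inner_join(lab, lab2, by = "proband_id")
  expect_equal(dplyr::n_distinct(paste(joined$cluster.x, joined$cluster.y)), 2)
  # 2 points merge once at their distance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc3 <- ward_cluster(D2)
  expect_equal(nrow(hc3$merge), 1)
  expect_equal(hc3$height, 0.4)
  asym <- D2; asym[1, 2] <- 0.9
  expect_error(ward_cluster(asym), class = "latcohort_error_precondition")
})

test_that("gap curve is finite, reproducible under a seed, and flat for one blob", {
  ids <- sprintf("r%02d", 1:12)
  set.seed(3)
  X <- matrix(rnorm(24, sd = 0.05), 12)
  D <- as.matrix(dist(X)); dimnames(D) <- list(ids, ids)
  c1 <- gap_statistic(D, kmax = 6, B = 20, seed = 9)
  c2 <- gap_statistic(D, kmax = 6, B = 20, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(is.finite(unlist(c1[c("logW", "ElogW", "gap", "se")]))))
  # a single tight cluster: no pronounced gap increase after k = 1
  expect_lt(max(c1$gap) - c1$gap[1], 3 * max(c1$se))
  expect_error(gap_statistic(D, kmax = 12, B = 20, seed = 1),
               class = "latcohort_error_input")
})

test_that("gap curve elbow sits at the true group count for well-separated groups", {
  set.seed(6)
  centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(16, sd = 0.3), 8), 2, centers[i, ], "+")
  }))
  rownames(X) <- sprintf("b%02d", 1:32)
  D <- as.matrix(dist(X))
  curve <- gap_statistic(D, kmax = 10, B = 30, seed = 9)
  expect_equal(select_k(curve), 4)
})

test_that("select_k finds a constructed elbow, warns on flat curves, honours overrides", {
  elbow <- tibble::tibble(
    k = 1:8,
    logW = 0, ElogW = 0,
    gap = c(0, 1, 2, 3, 3.1, 3.2, 3.3, 3.4),  # slope collapses after k = 4
    se = 0.1
  )
  class(elbow) <- c("gap_curve", class(elbow))
  expect_equal(select_k(elbow), 4)
  flat <- dplyr::mutate(elbow, gap = as.numeric(k))
  class(flat) <- c("gap_curve", class(flat))
  expect_warning(k <- select_k(flat), "smallest")
  expect_equal(k, 2)
  expect_equal(select_k(elbow, k_override = 5), 5)
})

test_that("cluster cuts cover the degenerate k values and recover blob truth", {
  ids <- sprintf("q%02d", 1:8)
  D <- matrix(1, 8, 8, dimnames = list(ids, ids))
  D[1:4, 1:4] <- 0.1; D[5:8, 5:8] <- 0.1; diag(D) <- 0
  hc <- ward_cluster(D)
  expect_equal(unique(cut_clusters(hc, 1)$cluster), 1L)
  expect_equal(sort(cut_clusters(hc, 8)$cluster), 1:8)
  expect_error(cut_clusters(hc, 9), class = "latcohort_error_input")
  lab <- cut_clusters(hc, 2)
  expect_equal(dplyr::n_distinct(lab$cluster), 2)
  expect_identical(sort(attr(lab, "leaf_order")), sort(ids))
})

test_that("cluster term frequencies use cluster size as denominator", {
  assignment <- tibble::tibble(proband_id = c("a", "b", "c", "d"),
                               cluster = c(1L, 1L, 1L, 2L))
  ann <- tibble::tibble(
    proband_id = c("a", "b", "c", "a", "b", "d"),
    term_id = c("t1", "t1", "t1", "t2", "t2", "t3")
  )
  tf <- cluster_term_frequencies(assignment, ann)
  f <- function(cl, t) tf$frequency[tf$cluster == cl & tf$term_id == t]
  expect_equal(f(1, "t1"), 1)
  expect_equal(f(2, "t1"), 0)
  expect_equal(f(1, "t2"), 2 / 3)
  expect_equal(f(2, "t3"), 1)
})

test_that("cocluster count takes the best cluster overlap and validates ids", {
  assignment <- tibble::tibble(proband_id = sprintf("p%d", 1:6),
                               cluster = c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(cocluster_count(assignment, c("p1", "p2", "p3")), 3)
  expect_equal(cocluster_count(assignment, c("p1", "p4")), 1)
  expect_equal(cocluster_count(assignment, character(0)), 0L)
  expect_error(cocluster_count(assignment, "nope"),
               class = "latcohort_error_lookup")
})

test_that("full pipeline is deterministic and exports a leaf-ordered Newick tree", {
  g <- mini_ontology()
  ann <- proband_annotations()
  f1 <- phenocluster(ann, g, exclude = exclusion_terms(), k = 5, B = 15, seed = 4)
  f2 <- phenocluster(ann, g, exclude = exclusion_terms(), k = 5, B = 15, seed = 4)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$gap, f2$gap)
  nwk <- dendrogram_newick(f1$dendrogram)
  expect_match(nwk, "^\\(.*\\);$")
  expect_setequal(attr(f1$assignment, "leaf_order"), rownames(f1$similarity))
  expect_s3_class(autoplot(f1$gap), "ggplot")
  expect_s3_class(autoplot(f1), "ggplot")
})
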