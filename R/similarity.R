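#' Information content of ontology terms from cohort annotation frequencies
#'
#' The information content (IC) of a term is the negative natural log of its
#' annotation frequency in the corpus: `IC(t) = -ln(n_t / N)` where `n_t`
#' counts probands whose closed term set contains `t` and `N` is the number
#' of probands. Terms never annotated receive a floored count of 1 so that
#' their IC stays finite and similarity remains defined for arbitrary query
#' terms. The default corpus is the analysis cohort itself; an external
#' term-frequency table may be supplied instead.
#'
#' @param annotations Closed annotation tibble (`proband_id`, `term_id`); see
#'   [cohort_closure()]. Sets must be closed under the ancestor relation, or
#'   a precondition error is raised.
#' @param graph An [load_obo()] ontology.
#' @param term_counts Optional external corpus: tibble with columns `term_id`
#'   and `count`. When given, `annotations` may be `NULL` and `n` must be
#'   supplied.
#' @param n Corpus size when `term_counts` is used.
#' @return An `ic_table`: tibble with columns `term_id`, `count`, `ic`
#'   (nats), one row per ontology term, with attribute `n` (corpus size).
#' @examples
#' g <- load_obo(write_mini_ontology(tempfile(fileext = ".obo")))
#' ann <- cohort_closure(proband_annotations(), g)
#' ic <- compute_ic(ann, g)
#' @export
compute_ic <- function(annotations, graph, term_counts = NULL, n = NULL) {
  stopifnot(inherits(graph, "onto_graph"))
  if (is.null(term_counts)) {
    check_annotation_table(annotations)
    lc_assert(nrow(annotations) > 0, "Empty annotation table.")
    closed <- cohort_closure(annotations, graph)
    if (!identical(
      dplyr::arrange(dplyr::distinct(annotations), .data$proband_id, .data$term_id),
      dplyr::arrange(closed, .data$proband_id, .data$term_id)
    )) {
      lc_abort("Annotation sets must be closed under the ancestor relation; run cohort_closure() first.",
               "error_precondition")
    }
    n <- dplyr::n_distinct(annotations$proband_id)
    counts <- annotations %>%
      dplyr::distinct(.data$proband_id, .data$term_id) %>%
      dplyr::count(.data$term_id, name = "count")
  } else {
    lc_assert(!is.null(n) && n >= 1, "`n` (corpus size) required with `term_counts`.")
    counts <- tibble::tibble(term_id = resolve_terms(term_counts$term_id, graph),
                             count = as.integer(term_counts$count))
  }
  out <- tibble::tibble(term_id = graph$terms) %>%
    dplyr::left_join(counts, by = "term_id") %>%
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      ic = -log(pmax(.data$count, 1L) / n)
    )
  attr(out, "n") <- n
  class(out) <- c("ic_table", class(out))
  out
}

ic_lookup <- function(ic, terms) {
  idx <- match(terms, ic$term_id)
  lc_assert(!anyNA(idx),
            paste0("Term(s) absent from IC table: ",
                   paste(terms[is.na(idx)], collapse = ", ")), "error_lookup")
  ic$ic[idx]
}

#' Lin similarity between two ontology terms
#'
#' `Lin(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` where MICA is the
#' most-informative common ancestor. Identity returns 1 even when both ICs
#' are 0; distinct terms whose only common ancestors carry zero IC score 0.
#'
#' @param t1,t2 Term ids.
#' @param ic An [compute_ic()] table.
#' @param graph An [load_obo()] ontology.
#' @return A similarity in `[0, 1]`.
#' @export
lin_similarity <- function(t1, t2, ic, graph) {
  t1 <- resolve_terms(t1, graph); t2 <- resolve_terms(t2, graph)
  if (identical(t1, t2)) return(1)
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  ic_mica <- if (length(common)) max(ic_lookup(ic, common)) else 0
  denom <- sum(ic_lookup(ic, c(t1, t2)))
  if (denom <= 0 || ic_mica <= 0) return(0)
  min(1, 2 * ic_mica / denom)
}

# Pairwise Lin similarity matrix over a fixed term universe.
lin_matrix <- function(terms, ic, graph) {
  terms <- resolve_terms(terms, graph)
  k <- length(terms)
  m <- matrix(0, k, k, dimnames = list(terms, terms))
  icv <- ic_lookup(ic, terms)
  for (i in seq_len(k)) {
    m[i, i] <- 1
    if (i < k) for (j in (i + 1):k) {
      common <- intersect(graph$ancestors[[terms[i]]], graph$ancestors[[terms[j]]])
      ic_mica <- if (length(common)) max(ic_lookup(ic, common)) else 0
      denom <- icv[i] + icv[j]
      s <- if (denom <= 0 || ic_mica <= 0) 0 else min(1, 2 * ic_mica / denom)
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}

#' Symmetric best-match-average similarity between two term sets
#'
#' The symmetric Lin set score: for each term in one set take its best Lin
#' match in the other set, average within each direction, and average the
#' two directions:
#' `sym(a,b) = (mean_x max_y Lin(x,y) + mean_y max_x Lin(x,y)) / 2`.
#'
#' @param a,b Non-empty character vectors of term ids.
#' @inheritParams lin_similarity
#' @return A similarity in `[0, 1]`; `sym(a, a) = 1` and the score is
#'   symmetric in its arguments.
#' @export
set_similarity <- function(a, b, ic, graph) {
  lc_assert(length(a) > 0 && length(b) > 0,
            "Both term sets must be non-empty.")
  a <- unique(resolve_terms(a, graph))
  b <- unique(resolve_terms(b, graph))
  m <- lin_matrix(union(a, b), ic, graph)
  sub <- m[a, b, drop = FALSE]
  (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
}
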