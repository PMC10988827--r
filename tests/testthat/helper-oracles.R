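# Shared fixtures and independent brute-force oracles.

# 7-term toy DAG: root -> A -> {B, C}; root -> D -> {E, F}
write_toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:root", "name: root", "",
    "[Term]", "id: T:A", "name: branch a", "is_a: T:root", "",
    "[Term]", "id: T:B", "name: leaf b", "is_a: T:A", "",
    "[Term]", "id: T:C", "name: leaf c", "is_a: T:A", "",
    "[Term]", "id: T:D", "name: branch d", "is_a: T:root", "",
    "[Term]", "id: T:E", "name: leaf e", "is_a: T:D", "",
    "[Term]", "id: T:F", "name: leaf f", "is_a: T:D", ""
  ), path)
  path
}

toy_graph <- function() load_obo(write_toy_obo())

# toy cohort of 4 probands over the toy DAG (raw, pre-closure)
toy_annotations <- function() {
  tibble::tibble(
    proband_id = c("p1", "p2", "p3", "p4"),
    term_id = c("T:B", "T:C", "T:E", "T:F")
  )
}

# Independent ancestor walk (not the packaged precomputed lists).
oracle_ancestors <- function(term, parents) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
  }
  seen
}

# Brute-force symmetric best-match-average set similarity: recomputes IC from
# raw counts and Lin by enumerating every term pair and every common ancestor.
oracle_set_similarity <- function(a, b, closed_sets, graph) {
  n <- length(closed_sets)
  count <- function(t) sum(vapply(closed_sets, function(s) t %in% s, logical(1)))
  ic <- function(t) -log(max(count(t), 1) / n)
  lin <- function(t1, t2) {
    if (t1 == t2) return(1)
    common <- intersect(oracle_ancestors(t1, graph$parents),
                        oracle_ancestors(t2, graph$parents))
    icm <- if (length(common)) max(vapply(common, ic, numeric(1))) else 0
    denom <- ic(t1) + ic(t2)
    if (denom <= 0 || icm <= 0) 0 else 2 * icm / denom
  }
  best <- function(x, ys) max(vapply(ys, function(y) lin(x, y), numeric(1)))
  (mean(vapply(a, best, numeric(1), ys = b)) +
      mean(vapply(b, best, numeric(1), ys = a))) / 2
}

# Exact two-sided Fisher p by enumerating the hypergeometric support with
# choose() arithmetic (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exhaustive phase classification over an explicit clone-state list.
oracle_phase <- function(states) {
  # states: list of c(locus1, locus2)
  has <- function(l1, l2) any(vapply(states, function(s)
    s[1] == l1 && s[2] == l2, logical(1)))
  if (has("mut", "wt") && has("wt", "mut") && !has("mut", "mut")) return("trans")
  if (has("mut", "mut") && !has("mut", "wt") && !has("wt", "mut")) return("cis")
  "ambiguous"
}

# Random rooted DAG with <= n_terms terms for property tests.
random_dag_graph <- function(n_terms) {
  ids <- c("R:0", sprintf("R:%d", seq_len(n_terms - 1)))
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: R:0", "name: root", "")
  for (i in seq_len(n_terms - 1)) {
    # parents drawn among earlier terms guarantees acyclicity
    k <- sample(1:min(2, i), 1)
    parents <- sample(ids[seq_len(i)], k)
    lines <- c(lines, "[Term]", paste0("id: ", ids[i + 1]),
               paste0("name: term ", i),
               paste0("is_a: ", parents), "")
  }
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  load_obo(path)
}

random_cohort_sets <- function(graph, n_probands) {
  terms <- setdiff(graph$terms, graph$root)
  sets <- lapply(seq_len(n_probands), function(i) {
    raw <- sample(terms, sample(1:3, 1))
    annotation_closure(raw, graph)
  })
  names(sets) <- sprintf("p%d", seq_len(n_probands))
  sets
}

sets_to_annotations <- function(sets) {
  tibble::tibble(proband_id = rep(names(sets), lengths(sets)),
                 term_id = unlist(sets, use.names = FALSE))
}
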