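#' Load a phenotype ontology from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas honouring the `id`, `name`, `is_a`, `alt_id` and
#' `is_obsolete` tags. Obsolete terms are dropped, alternate ids are resolved
#' to their primary ids, and when the file contains several roots they are
#' joined under a synthetic virtual root so that every term reaches a single
#' root. The result is validated to be a directed acyclic graph.
#'
#' @param path Path to an OBO 1.2 flat file.
#' @return An object of class `onto_graph`: a list with elements `terms`
#'   (character vector of primary term ids), `name` (named character, id to
#'   label), `parents` (named list of `is_a` parent ids), `children` (named
#'   list), `ancestors` (named list of all ancestors, self included), `root`
#'   (the root id) and `alt` (named character mapping alternate ids to
#'   primary ids).
#' @examples
#' obo <- write_mini_ontology(tempfile(fileext = ".obo"))
#' g <- load_obo(obo)
#' g$root
#' @export
load_obo <- function(path) {
  lc_assert(file.exists(path), paste0("OBO file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  lc_assert(length(starts) > 0, "OBO file contains no stanzas.", "error_input")
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"
  lc_assert(any(keep), "OBO file contains no [Term] stanzas.", "error_input")

  tag_values <- function(block, tag) {
    hits <- grep(paste0("^", tag, ":"), block, value = TRUE)
    vals <- sub(paste0("^", tag, ":\\s*"), "", hits)
    vals <- sub("\\s*!.*$", "", vals)   # strip trailing comments
    trimws(vals)
  }

  ids <- character(0); names_ <- character(0)
  parents <- list(); alt <- character(0); obsolete <- character(0)
  for (i in which(keep)) {
    block <- lines[starts[i]:ends[i]]
    id <- tag_values(block, "id")
    if (length(id) == 0) next
    id <- id[[1]]
    if (tolower(tag_values(block, "is_obsolete")[1] %||% "") %in% "true") {
      obsolete <- c(obsolete, id)
      next
    }
    nm <- tag_values(block, "name")
    isa <- sub("\\s.*$", "", tag_values(block, "is_a"))
    a <- tag_values(block, "alt_id")
    ids <- c(ids, id)
    names_[id] <- if (length(nm)) nm[[1]] else id
    parents[[id]] <- isa
    if (length(a)) alt[a] <- id
  }
  lc_assert(length(ids) > 0, "OBO file defines no non-obsolete terms.", "error_input")
  lc_assert(!anyDuplicated(ids), "Duplicate term ids in OBO file.", "error_input")

  # resolve parent references through alt ids; drop edges to obsolete/unknown
  parents <- lapply(parents, function(p) {
    p <- ifelse(p %in% names(alt), unname(alt[p]), p)
    unique(p[p %in% ids])
  })
  names(parents) <- ids

  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0) {
    # every term has a parent: the graph must contain a cycle
    lc_abort(paste0("Cycle detected in ontology (no root reachable); e.g. term ",
                    ids[[1]]), "error_structural")
  }
  if (length(roots) > 1) {
    vroot <- "VIRTUAL:ROOT"
    ids <- c(vroot, ids)
    names_[vroot] <- "virtual root"
    parents[[vroot]] <- character(0)
    for (r in roots) parents[[r]] <- vroot
    root <- vroot
  } else {
    root <- roots
  }

  # Kahn topological sort root-down; leftovers indicate a cycle
  indeg <- vapply(parents[ids], length, 1L)
  order <- character(0)
  queue <- ids[indeg == 0L]
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  remaining <- indeg
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    bad <- setdiff(ids, order)
    lc_abort(paste0("Cycle detected in ontology involving term ", bad[[1]]),
             "error_structural")
  }

  # ancestors (self included) in topological order
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  for (v in order) {
    anc <- v
    for (p in parents[[v]]) anc <- c(anc, ancestors[[p]])
    ancestors[[v]] <- unique(anc)
  }

  structure(
    list(terms = ids, name = names_, parents = parents, children = children,
         ancestors = ancestors, root = root, alt = alt,
         obsolete = obsolete),
    class = "onto_graph"
  )
}

#' @export
print.onto_graph <- function(x, ...) {
  cat("<onto_graph> ", length(x$terms), " terms, root: ", x$root,
      " (", x$name[[x$root]], ")\n", sep = "")
  invisible(x)
}

# Resolve term ids through the alternate-id map; error on unknown ids.
resolve_terms <- function(terms, graph) {
  terms <- ifelse(terms %in% names(graph$alt), unname(graph$alt[terms]), terms)
  unknown <- setdiff(terms, graph$terms)
  if (length(unknown)) {
    lc_abort(paste0("Unknown term id(s): ", paste(unknown, collapse = ", ")),
             "error_lookup")
  }
  terms
}

#' Ancestor closure of a set of terms
#'
#' Returns the input terms together with all of their `is_a` ancestors up to
#' the root. The operation is idempotent and maps the empty set to itself.
#'
#' @param terms Character vector of term ids (alternate ids are resolved).
#' @param graph An [load_obo()] ontology.
#' @return Sorted character vector of term ids closed under the ancestor
#'   relation.
#' @export
annotation_closure <- function(terms, graph) {
  stopifnot(inherits(graph, "onto_graph"))
  if (length(terms) == 0) return(character(0))
  terms <- resolve_terms(terms, graph)
  sort(unique(unlist(graph$ancestors[terms], use.names = FALSE)))
}

#' Ancestor closure of a cohort annotation table
#'
#' @param annotations Tibble with columns `proband_id` and `term_id`, one row
#'   per proband/term pair.
#' @param graph An [load_obo()] ontology.
#' @return A tibble with the same columns, each proband's term set closed
#'   under the ancestor relation.
#' @export
cohort_closure <- function(annotations, graph) {
  check_annotation_table(annotations)
  annotations %>%
    dplyr::group_by(.data$proband_id) %>%
    dplyr::reframe(term_id = annotation_closure(.data$term_id, graph)) %>%
    dplyr::ungroup()
}

check_annotation_table <- function(annotations) {
  lc_assert(is.data.frame(annotations) &&
              all(c("proband_id", "term_id") %in% names(annotations)),
            "`annotations` must have columns `proband_id` and `term_id`.")
  invisible(annotations)
}

#' Read a proband annotation table
#'
#' Two-column TSV (`proband_id`, `term_id`), one row per pair.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `proband_id` and `term_id`.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE) %>%
    check_annotation_table()
}
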