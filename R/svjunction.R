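#' RPKM normalisation of an exon read-count matrix
#'
#' `RPKM = reads * 1e9 / (exon length * total mapped reads)`.
#'
#' @param counts Integer matrix, exons in rows (rownames = exon ids),
#'   samples in columns.
#' @param exons Tibble describing the rows: `exon_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `gene`. Lengths derive from `end - start`.
#' @param totals Per-sample total mapped reads; defaults to the column
#'   sums.
#' @return An `rpkm_matrix`: list with `values` (numeric matrix) and
#'   `exons` (the interval table).
#' @export
rpkm <- function(counts, exons, totals = colSums(counts)) {
  lc_assert(is.matrix(counts) && !is.null(rownames(counts)),
            "`counts` must be a matrix with exon rownames.")
  lc_assert(all(c("exon_id", "chrom", "start", "end") %in% names(exons)),
            "`exons` needs exon_id, chrom, start, end.")
  lc_assert(!anyDuplicated(exons$exon_id), "Duplicate exon ids.")
  lc_assert(setequal(rownames(counts), exons$exon_id),
            "`counts` rows and `exons` must describe the same exons.")
  exons <- exons[match(rownames(counts), exons$exon_id), ]
  len <- exons$end - exons$start
  lc_assert(all(len > 0), "Exon lengths must be positive.")
  if (any(totals <= 0)) lc_abort("Zero total mapped reads for a sample.", "error_input")
  values <- sweep(counts * 1e9 / len, 2, totals, "/")
  structure(list(values = values, exons = tibble::as_tibble(exons)),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat("<rpkm_matrix> ", nrow(x$values), " exons x ", ncol(x$values),
      " samples\n", sep = "")
  invisible(x)
}

#' Screen one sample for exonic deletions by cohort-median RPKM ratio
#'
#' For each exon the sample's RPKM is divided by the median RPKM of the
#' other samples; maximal runs of consecutive exons (same chromosome, in
#' genomic order) whose ratio falls inside the heterozygous window are
#' reported as het deletion calls, and runs below the homozygous ceiling as
#' hom calls. This is a deliberately simple cohort-median ratio screen with
#' configurable thresholds.
#'
#' @param m An [rpkm()] matrix built from at least 8 samples.
#' @param sample Sample (column) name to screen.
#' @param het_window Ratio window called heterozygous (default `[0.3, 0.7]`).
#' @param hom_max Ratio at or below which a run is called homozygous
#'   (default 0.1).
#' @param min_consecutive Minimum run length to report (default 1).
#' @return Tibble of calls: `sample`, `chrom`, `start`, `end`, `size`,
#'   `zygosity`, `n_exons`, `exons` (list of supporting exon ids),
#'   `mean_ratio`.
#' @export
screen_deletions <- function(m, sample, het_window = c(0.3, 0.7),
                             hom_max = 0.1, min_consecutive = 1) {
  stopifnot(inherits(m, "rpkm_matrix"))
  lc_assert(ncol(m$values) >= 8,
            "At least 8 samples are needed for a stable cohort median.",
            "error_precondition")
  lc_assert(sample %in% colnames(m$values), "Unknown sample.", "error_lookup")
  others <- m$values[, setdiff(colnames(m$values), sample), drop = FALSE]
  med <- apply(others, 1, stats::median)
  ratio <- m$values[, sample] / med
  skip <- med == 0
  if (any(skip)) {
    rlang::warn(paste0("Exon(s) with zero cohort median skipped: ",
                       paste(rownames(m$values)[skip], collapse = ", ")))
  }
  state <- dplyr::case_when(
    skip ~ "skip",
    ratio <= hom_max ~ "hom",
    ratio >= het_window[1] & ratio <= het_window[2] ~ "het",
    TRUE ~ "normal"
  )
  exons <- m$exons[match(rownames(m$values), m$exons$exon_id), ]
  ord <- order(exons$chrom, exons$start)
  state <- state[ord]; ratio <- ratio[ord]; exons <- exons[ord, ]
  # runs must stay on one chromosome
  run_key <- paste(exons$chrom, state)
  r <- rle(run_key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  calls <- purrr::map_dfr(seq_along(r$lengths), function(i) {
    st <- state[starts[i]]
    if (!st %in% c("het", "hom") || r$lengths[i] < min_consecutive) {
      return(NULL)
    }
    idx <- starts[i]:ends[i]
    tibble::tibble(
      sample = sample,
      chrom = exons$chrom[idx[1]],
      start = min(exons$start[idx]),
      end = max(exons$end[idx]),
      zygosity = st,
      n_exons = length(idx),
      exons = list(exons$exon_id[idx]),
      mean_ratio = mean(ratio[idx])
    )
  })
  if (nrow(calls) == 0) return(calls)
  dplyr::mutate(calls, size = .data$end - .data$start, .after = "end")
}

#' Deletion size from its two printed genomic coordinates
#'
#' Size is the absolute coordinate difference, so the call is
#' order-invariant.
#'
#' @param coord1,coord2 Positive genomic positions (1-based, inclusive, as
#'   printed in clinical reports).
#' @return Integer size in bp.
#' @examples
#' deletion_size(72204016, 72157996)  # 46020
#' @export
deletion_size <- function(coord1, coord2) {
  lc_assert(all(coord1 > 0) && all(coord2 > 0), "Coordinates must be positive.")
  as.integer(abs(coord1 - coord2))
}

#' Orientation-normalised deletion span
#'
#' @inheritParams deletion_size
#' @return Tibble with `start` (the smaller coordinate), `end` and `size`.
#' @export
deletion_span <- function(coord1, coord2) {
  tibble::tibble(start = pmin(coord1, coord2), end = pmax(coord1, coord2),
                 size = deletion_size(coord1, coord2))
}

#' Resolve a deletion breakpoint junction against its two reference flanks
#'
#' Finds the longest prefix of the junction read exactly matching the
#' proximal reference and the longest suffix exactly matching the distal
#' reference. If prefix and suffix overlap within the read, the overlap is
#' junction microhomology (the breakpoint can slide anywhere across the
#' shared tract, so breakpoints are reported as intervals whose width
#' equals the microhomology length); if a gap remains, the gap is inserted
#' sequence; when they meet exactly the junction is blunt. Matching is
#' exact, reflecting high-quality Sanger-derived junction sequences.
#'
#' @param junction Junction read sequence (character or `DNAString`), at
#'   least 20 nt.
#' @param prox_ref,dist_ref Reference flank sequences; each must contain a
#'   unique exact match for its side of the junction.
#' @param seed_len Minimum anchor length on each side (default 12 nt).
#' @return A `junction_resolution`: list with `prox_interval` and
#'   `dist_interval` (1-based positions in the respective references,
#'   `c(lo, hi)` bounding the ambiguous breakpoint), `microhomology`,
#'   `inserted`, `exact`, `prefix_len`, `suffix_start` (read coordinates).
#' @export
resolve_junction <- function(junction, prox_ref, dist_ref, seed_len = 12) {
  junction <- toupper(as.character(junction))
  prox_ref <- toupper(as.character(prox_ref))
  dist_ref <- toupper(as.character(dist_ref))
  lc_assert(nchar(junction) >= 20, "Junction read must be at least 20 nt.")

  find_side <- function(read_sub, ref, side) {
    # longest prefix (side = "prox") or suffix (side = "dist") of the read
    # occurring exactly in ref
    L <- nchar(read_sub); R <- nchar(ref)
    seed <- if (side == "prox") substr(read_sub, 1, seed_len) else
      substr(read_sub, L - seed_len + 1, L)
    if (gregexpr(seed, ref, fixed = TRUE)[[1]][1] == -1) {
      lc_abort(paste0("No exact match of at least ", seed_len,
                      " nt on the ", side, " side."), "error_unresolvable")
    }
    best <- seed_len
    while (best < min(L, R)) {
      cand <- if (side == "prox") substr(read_sub, 1, best + 1) else
        substr(read_sub, L - best, L)
      if (gregexpr(cand, ref, fixed = TRUE)[[1]][1] == -1) break
      best <- best + 1
    }
    frag <- if (side == "prox") substr(read_sub, 1, best) else
      substr(read_sub, L - best + 1, L)
    pos <- gregexpr(frag, ref, fixed = TRUE)[[1]]
    if (length(pos) > 1) {
      lc_abort(paste0("Ambiguous ", side, " placement: equally long matches at positions ",
                      paste(pos, collapse = ", ")), "error_ambiguous")
    }
    list(len = best, ref_start = pos[1])
  }

  prox <- find_side(junction, prox_ref, "prox")
  dist <- find_side(junction, dist_ref, "dist")

  L <- nchar(junction)
  prefix_end <- prox$len                 # read coordinate of last prefix base
  suffix_start <- L - dist$len + 1       # read coordinate of first suffix base
  overlap <- prefix_end - suffix_start + 1
  if (overlap > 0) {
    mh <- substr(junction, suffix_start, prefix_end)
    inserted <- ""
  } else if (overlap < 0) {
    mh <- ""
    inserted <- substr(junction, prefix_end + 1, suffix_start - 1)
  } else {
    mh <- ""; inserted <- ""
  }
  m <- nchar(mh)
  prox_end <- prox$ref_start + prox$len - 1
  dist_start <- dist$ref_start
  structure(
    list(
      prox_interval = as.integer(c(prox_end - m, prox_end)),
      dist_interval = as.integer(c(dist_start, dist_start + m)),
      microhomology = mh,
      inserted = inserted,
      exact = overlap == 0,
      prefix_len = prox$len,
      suffix_start = suffix_start
    ),
    class = "junction_resolution"
  )
}

#' @export
print.junction_resolution <- function(x, ...) {
  cat("<junction_resolution> ")
  if (nzchar(x$microhomology)) {
    cat("microhomology '", x$microhomology, "' (", nchar(x$microhomology),
        " nt)\n", sep = "")
  } else if (nzchar(x$inserted)) {
    cat("inserted '", x$inserted, "'\n", sep = "")
  } else {
    cat("blunt junction\n")
  }
  invisible(x)
}

#' Classify a deletion as a candidate Alu-Alu mediated rearrangement
#'
#' A deletion is an AAMR candidate when both breakpoints fall within Alu
#' repeat annotations lying on the same strand (directly oriented); it is
#' additionally flagged chimeric when junction microhomology is present
#' with both breakpoints intra-Alu, the signature of a chimeric Alu formed
#' by the recombination.
#'
#' @param prox_pos,dist_pos Genomic breakpoint positions (1-based; the
#'   midpoint of the reported interval is a reasonable choice).
#' @param repeats Repeat annotation tibble: `start`, `end` (0-based
#'   half-open, BED convention), `family`, `strand`, optional `chrom`.
#' @param microhomology Junction microhomology sequence (may be empty).
#' @return Tibble row: `aamr_candidate`, `family_proximal`,
#'   `family_distal`, `chimeric`.
#' @export
classify_aamr <- function(prox_pos, dist_pos, repeats, microhomology = "") {
  hit <- function(pos) {
    if (is.null(repeats) || nrow(repeats) == 0) return(NULL)
    i <- which(repeats$start < pos & pos <= repeats$end)
    if (length(i) == 0) NULL else repeats[i[1], ]
  }
  hp <- hit(prox_pos); hd <- hit(dist_pos)
  is_alu <- function(h) !is.null(h) && startsWith(h$family, "Alu")
  candidate <- is_alu(hp) && is_alu(hd) && hp$strand == hd$strand
  tibble::tibble(
    aamr_candidate = candidate,
    family_proximal = if (!is.null(hp)) hp$family else NA_character_,
    family_distal = if (!is.null(hd)) hd$family else NA_character_,
    chimeric = candidate && nzchar(microhomology)
  )
}

#' Read repeat annotations from a BED file
#'
#' BED6 with the repeat family in the name column: chrom, start, end,
#' family, score, strand.
#'
#' @param path Path to the BED file.
#' @return Tibble (`chrom`, `start`, `end`, `family`, `strand`).
#' @export
read_repeats_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "family",
                                      "score", "strand"),
                  show_col_types = FALSE, progress = FALSE) %>%
    dplyr::select("chrom", "start", "end", "family", "strand")
}

#' Read exon intervals from a BED file
#'
#' BED with chrom, start, end, exon_id and optionally gene.
#'
#' @param path Path to the BED file.
#' @return Tibble (`chrom`, `start`, `end`, `exon_id`, `gene`).
#' @export
read_exons_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ncol <- length(strsplit(first, "\t")[[1]])
  nm <- c("chrom", "start", "end", "exon_id", "gene")[seq_len(min(ncol, 5))]
  readr::read_tsv(path, col_names = nm, show_col_types = FALSE, progress = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
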