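# Seeded generators producing every input the pipeline consumes, with
# ground-truth bundles. All generators are pure functions of their
# arguments and the seed.

#' Generate a synthetic phenotype cohort from lesion archetypes
#'
#' Each proband is drawn from one of the lesion archetypes
#' ([lesion_archetypes()] by default): its archetype term set with
#' independent per-term dropout, plus (with probability `spurious`) one
#' spurious term drawn uniformly from the rest of the ontology. A proband
#' always keeps at least one archetype term.
#'
#' @param n Number of probands.
#' @param archetypes Archetype table (`archetype`, `term_id`).
#' @param mix Named proportions over archetypes (default uniform); must sum
#'   to 1.
#' @param dropout Per-term dropout probability in `[0, 1]`.
#' @param spurious Probability of adding one spurious term.
#' @param graph Ontology used to draw spurious terms ([mini_ontology()] by
#'   default).
#' @param seed RNG seed.
#' @return List with `annotations` (tibble `proband_id`, `term_id`) and
#'   `truth` (tibble `proband_id`, `archetype`).
#' @export
gen_phenotype_cohort <- function(n = 33, archetypes = lesion_archetypes(),
                                 mix = NULL, dropout = 0.15, spurious = 0.1,
                                 graph = mini_ontology(), seed) {
  arch_ids <- unique(archetypes$archetype)
  if (is.null(mix)) {
    mix <- stats::setNames(rep(1 / length(arch_ids), length(arch_ids)), arch_ids)
  }
  unknown <- setdiff(names(mix), arch_ids)
  if (length(unknown)) {
    lc_abort(paste0("Unknown archetype id(s): ", paste(unknown, collapse = ", ")),
             "error_config")
  }
  lc_assert(abs(sum(mix) - 1) < 1e-8, "Archetype proportions must sum to 1.")
  lc_assert(dropout >= 0 && dropout <= 1 && spurious >= 0 && spurious <= 1,
            "Probabilities must lie in [0, 1].")
  sets <- split(archetypes$term_id, archetypes$archetype)
  arch_ids <- names(mix)   # mix may use a subset of the archetypes
  # deterministic largest-remainder apportionment of archetype counts
  raw <- mix[arch_ids] * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(arch_ids, counts)
  candidates <- setdiff(graph$terms, c(graph$root, exclusion_terms()))
  with_seed(seed, {
    ann <- purrr::map_dfr(seq_len(n), function(i) {
      terms <- sets[[labels[i]]]
      keep <- stats::runif(length(terms)) >= dropout
      if (!any(keep)) keep[sample.int(length(terms), 1)] <- TRUE
      terms <- terms[keep]
      if (stats::runif(1) < spurious) {
        terms <- unique(c(terms, sample(candidates, 1)))
      }
      tibble::tibble(proband_id = sprintf("S%03d", i), term_id = terms)
    })
    list(annotations = ann,
         truth = tibble::tibble(proband_id = sprintf("S%03d", seq_len(n)),
                                archetype = labels))
  })
}

#' Generate a synthetic case-control genotype cohort and trio set
#'
#' Cases carry a variant allele at frequency `rho * q` where `q` is the
#' control allele frequency (`control_ac / control_an`); per-case allele
#' counts are binomial, after which a designated fraction of carriers is
#' made homozygous. Also generates `n_trios` parent-proband trios with
#' known maternal / paternal / de novo origins, including one
#' compound-heterozygous trio with a matching clone-observation set in
#' trans.
#'
#' @param n_cases Number of cases.
#' @param control_ac,control_an Control variant / total allele counts.
#' @param rho Case enrichment factor (case allele frequency = `rho * q`);
#'   `rho * q` must not exceed 1.
#' @param frac_biallelic Fraction of carriers made homozygous.
#' @param n_trios Number of trios to generate.
#' @param seed RNG seed.
#' @return List with `cases` (tibble `case_id`, `zygosity`), `trios`
#'   (tibble `trio_id`, `proband`, `mother`, `father`, `origin_truth`,
#'   `biallelic_truth`), `clones` (tibble for the compound-het trio) and
#'   `truth` (list with `rho`, `q`, carrier counts).
#' @export
gen_genotype_cohort <- function(n_cases = 111, control_ac = 76,
                                control_an = 34592, rho = 26,
                                frac_biallelic = 0.2, n_trios = 12, seed) {
  q <- control_ac / control_an
  p <- rho * q
  if (p > 1) lc_abort("Infeasible case allele frequency: rho * q > 1.", "error_input")
  lc_assert(frac_biallelic >= 0 && frac_biallelic <= 1,
            "`frac_biallelic` must lie in [0, 1].")
  with_seed(seed, {
    alleles <- stats::rbinom(n_cases, 2, p)
    zyg <- dplyr::case_when(alleles == 0 ~ "ref", alleles == 1 ~ "het",
                            TRUE ~ "hom")
    # make the designated fraction of carriers homozygous while conserving
    # the total allele count: two het carriers collapse into one hom + one ref
    carriers <- which(zyg != "ref")
    target_hom <- round(frac_biallelic * length(carriers))
    hom_now <- sum(zyg == "hom")
    while (hom_now < target_hom && sum(zyg == "het") >= 2) {
      pair <- which(zyg == "het")[1:2]
      zyg[pair[1]] <- "hom"; zyg[pair[2]] <- "ref"
      hom_now <- hom_now + 1
    }
    while (hom_now > target_hom) {
      i <- which(zyg == "hom")[1]
      j <- which(zyg == "ref")[1]
      zyg[i] <- "het"; zyg[j] <- "het"
      hom_now <- hom_now - 1
    }
    cases <- tibble::tibble(case_id = sprintf("C%03d", seq_len(n_cases)),
                            zygosity = zyg)

    origins <- c("maternal", "paternal", "de_novo")
    trio_origin <- sample(origins, n_trios, replace = TRUE,
                          prob = c(0.45, 0.45, 0.1))
    trios <- tibble::tibble(
      trio_id = sprintf("T%02d", seq_len(n_trios)),
      origin_truth = trio_origin,
      proband = "het",
      mother = dplyr::if_else(trio_origin == "maternal", "het", "ref"),
      father = dplyr::if_else(trio_origin == "paternal", "het", "ref"),
      biallelic_truth = "none"
    )
    # last trio becomes a compound heterozygote (trans): maternal missense
    # plus a paternally-derived second allele, with clone evidence
    trios$biallelic_truth[n_trios] <- "compound_het_trans"
    trios$origin_truth[n_trios] <- "maternal"
    trios$mother[n_trios] <- "het"
    trios$father[n_trios] <- "ref"
    clones <- tibble::tibble(
      clone_id = sprintf("clone%02d", 1:12),
      locus1 = rep(c("mut", "wt"), each = 6),
      locus2 = rep(c("wt", "mut"), each = 6)
    )
    list(cases = cases, trios = trios, clones = clones,
         truth = list(rho = rho, q = q,
                      n_carriers = sum(cases$zygosity != "ref"),
                      n_hom = sum(cases$zygosity == "hom")))
  })
}

#' Write a trio cohort as a multi-sample VCF and PED file
#'
#' Each trio contributes three samples genotyped at one biallelic site
#' (plus a second site for the compound-heterozygous trio). Files are plain
#' text (uncompressed VCF 4.2, whitespace PED).
#'
#' @param trios Trio tibble from [gen_genotype_cohort()].
#' @param dir Output directory.
#' @return List with paths `vcf` and `ped`.
#' @export
write_trio_vcf <- function(trios, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- c(t(outer(trios$trio_id, c("_P", "_M", "_F"), paste0)))
  gt_code <- c(ref = "0/0", het = "0/1", hom = "1/1")
  site1 <- c("10", "72195155", ".", "C", "T")
  site2 <- c("10", "72195210", ".", "CAGGCCGCCCGGGAGCCCGCCCCG", "TTGACTTCC")
  row_for <- function(site, gts) {
    paste(c(site, ".", "PASS", ".", "GT",
            unname(gt_code[gts])), collapse = "\t")
  }
  gts1 <- c(rbind(trios$proband, trios$mother, trios$father))
  comp <- trios$biallelic_truth == "compound_het_trans"
  gts2 <- rep("ref", length(gts1))
  if (any(comp)) {
    # second allele is paternally inherited in the compound-het trio
    for (i in which(comp)) {
      gts2[(i - 1) * 3 + 1] <- "het"   # proband
      gts2[(i - 1) * 3 + 3] <- "het"   # father
    }
  }
  vcf_path <- file.path(dir, "trios.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    row_for(site1, gts1),
    row_for(site2, gts2)
  ), vcf_path)
  ped_path <- file.path(dir, "trios.ped")
  ped <- purrr::map_chr(seq_len(nrow(trios)), function(i) {
    id <- trios$trio_id[i]
    paste(c(paste(id, paste0(id, "_P"), paste0(id, "_F"), paste0(id, "_M"), 1, 2),
            paste(id, paste0(id, "_M"), 0, 0, 2, 1),
            paste(id, paste0(id, "_F"), 0, 0, 1, 1)), collapse = "\n")
  })
  writeLines(ped, ped_path)
  list(vcf = vcf_path, ped = ped_path)
}

#' Default exon map for the read-depth deletion screen
#'
#' Thirty exons across three convergently numbered genes on one chromosome,
#' with realistic spacing and lengths.
#'
#' @return Exon tibble (`exon_id`, `chrom`, `start`, `end`, `gene`).
#' @export
default_exon_map <- function() {
  genes <- c(rep("GENE1", 10), rep("GENE2", 12), rep("GENE3", 8))
  n <- length(genes)
  start <- 72150000 + cumsum(rep(2000, n)) - 2000
  len <- rep(c(150, 220, 180, 120, 260), length.out = n)
  tibble::tibble(
    exon_id = sprintf("%s_ex%02d", genes,
                      unlist(lapply(rle(genes)$lengths, seq_len))),
    chrom = "10", start = start, end = start + len, gene = genes
  )
}

#' Generate a synthetic exon read-count cohort with embedded deletions
#'
#' Counts follow a negative binomial around exon-specific means
#' (overdispersed exome depth); deleted exons are scaled by 0.5 for
#' heterozygous and 0 for homozygous deletions in the designated samples.
#' With `dispersion = 0` counts equal their means exactly (useful to check
#' the scaling limit).
#'
#' @param n_samples Number of samples (at least 8).
#' @param exons Exon map (see [default_exon_map()]).
#' @param deletions Tibble (`sample`, `exon_id`, `zygosity`) marking deleted
#'   exons; sample names are `SMP01`, `SMP02`, ...
#' @param dispersion Extra-Poisson dispersion: counts follow a negative
#'   binomial with variance `mu * (1 + dispersion)`, so 0.1 means 10%
#'   variance inflation over Poisson depth noise.
#' @param base_mean Mean read count scale.
#' @param seed RNG seed.
#' @return List with `counts` (matrix exons x samples), `exons`, and
#'   `truth` (the deletion table with genomic coordinates).
#' @export
gen_rpkm_cohort <- function(n_samples = 20, exons = default_exon_map(),
                            deletions = NULL, dispersion = 0.1,
                            base_mean = 500, seed) {
  lc_assert(n_samples >= 8, "At least 8 samples are required.")
  if (!is.null(deletions)) {
    bad <- setdiff(deletions$exon_id, exons$exon_id)
    if (length(bad)) {
      lc_abort(paste0("Deletion references unknown exon(s): ",
                      paste(bad, collapse = ", ")), "error_config")
    }
  }
  samples <- sprintf("SMP%02d", seq_len(n_samples))
  with_seed(seed, {
    exon_mean <- base_mean * stats::rlnorm(nrow(exons), 0, 0.4)
    factor <- matrix(1, nrow(exons), n_samples,
                     dimnames = list(exons$exon_id, samples))
    if (!is.null(deletions)) {
      for (i in seq_len(nrow(deletions))) {
        factor[deletions$exon_id[i], deletions$sample[i]] <-
          if (deletions$zygosity[i] == "hom") 0 else 0.5
      }
    }
    mu <- exon_mean * factor
    counts <- if (dispersion > 0) {
      # variance = mu (1 + dispersion)  =>  size = mu / dispersion
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = pmax(mu, 1e-8) / dispersion),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    } else {
      round(mu)
    }
    truth <- if (is.null(deletions)) {
      tibble::tibble(sample = character(), exon_id = character(),
                     zygosity = character())
    } else {
      dplyr::left_join(deletions, exons, by = "exon_id")
    }
    list(counts = counts, exons = exons, truth = truth)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic deletion breakpoint-junction case
#'
#' Builds proximal and distal reference flanks, a junction read carrying an
#' engineered microhomology (or templated insertion, mutually exclusive), a
#' repeat-annotation table placing an Alu pair across the breakpoints, and
#' the ground truth needed to verify junction resolution exactly.
#'
#' @param del_size Deletion size in bp (separates the two flank segments on
#'   the genome).
#' @param mh_len Engineered microhomology length (0 for none).
#' @param insertion Inserted sequence at the junction (requires
#'   `mh_len = 0`).
#' @param repeat_pair Repeat family names placed over the proximal and
#'   distal breakpoints.
#' @param strands Strands of the two repeats (`"+"`/`"-"`); direct
#'   orientation means equal strands.
#' @param flank Length of each reference flank (nt).
#' @param seed RNG seed.
#' @return List with `prox_ref`, `dist_ref`, `junction` (character
#'   sequences), `repeats` (tibble in genomic coordinates), `offsets`
#'   (genomic start of each flank) and `truth` (breakpoint intervals in
#'   flank-local coordinates, microhomology, insertion).
#' @export
gen_junction_case <- function(del_size = 46020, mh_len = 5, insertion = "",
                              repeat_pair = c("AluSx1", "AluSq2"),
                              strands = c("+", "+"), flank = 150, seed) {
  lc_assert(mh_len == 0 || !nzchar(insertion),
            "Microhomology and insertion are mutually exclusive.")
  lc_assert(mh_len >= 0 && mh_len < flank / 3,
            "Microhomology too long for the flank length.", "error_input")
  with_seed(seed, {
    repeat {
      prox <- strsplit(random_dna(flank), "")[[1]]
      dist <- strsplit(random_dna(flank), "")[[1]]
      p_end <- round(flank * 2 / 3)    # last retained proximal base
      d_start <- round(flank / 3)      # first retained distal base
      if (mh_len > 0) {
        # share the tract: distal start copies the proximal continuation
        dist[d_start:(d_start + mh_len - 1)] <- prox[(p_end + 1):(p_end + mh_len)]
        # block accidental extension on both sides
        if (dist[d_start + mh_len] == prox[p_end + mh_len + 1]) {
          dist[d_start + mh_len] <- setdiff(c("A", "C", "G", "T"),
                                            prox[p_end + mh_len + 1])[1]
        }
        if (d_start > 1 && dist[d_start - 1] == prox[p_end]) {
          dist[d_start - 1] <- setdiff(c("A", "C", "G", "T"), prox[p_end])[1]
        }
        ins <- ""
      } else {
        ins <- toupper(insertion)
        if (dist[d_start] == prox[p_end + 1]) {
          dist[d_start] <- setdiff(c("A", "C", "G", "T"), prox[p_end + 1])[1]
        }
        if (nzchar(ins)) {
          first <- substr(ins, 1, 1); last <- substr(ins, nchar(ins), nchar(ins))
          if (first == prox[p_end + 1]) next
          if (last == dist[d_start - 1]) next
        }
        if (d_start > 1 && dist[d_start - 1] == prox[p_end]) {
          dist[d_start - 1] <- setdiff(c("A", "C", "G", "T"), prox[p_end])[1]
        }
      }
      prox_ref <- paste(prox, collapse = "")
      dist_ref <- paste(dist, collapse = "")
      read_prox <- substr(prox_ref, 1, p_end)
      read_dist <- substr(dist_ref, d_start, flank)
      junction <- paste0(read_prox, ins, read_dist)
      res <- tryCatch(resolve_junction(junction, prox_ref, dist_ref),
                      error = function(e) NULL)
      if (is.null(res)) next   # ambiguous by chance; redraw
      break
    }
    prox_offset <- 1000L
    dist_offset <- prox_offset + flank + as.integer(del_size)
    repeats <- tibble::tibble(
      chrom = "10",
      start = c(prox_offset + p_end - 40, dist_offset + d_start - 10) - 1L,
      end = c(prox_offset + p_end + 20, dist_offset + d_start + 50),
      family = repeat_pair,
      strand = strands
    )
    list(
      prox_ref = prox_ref, dist_ref = dist_ref, junction = junction,
      repeats = repeats,
      offsets = c(prox = prox_offset, dist = dist_offset),
      truth = list(
        prox_interval = as.integer(c(p_end, p_end + mh_len)),
        dist_interval = as.integer(c(d_start, d_start + mh_len)),
        microhomology = if (mh_len > 0)
          substr(prox_ref, p_end + 1, p_end + mh_len) else "",
        inserted = ins,
        del_size = del_size
      )
    )
  })
}
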