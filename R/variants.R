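#' Read a minimal VCF plus an annotation TSV into genotype records
#'
#' Reads a VCF 4.2 file (CHROM, POS, ID, REF, ALT plus per-sample GT and,
#' when present, AD fields) and joins a variant annotation table keyed by
#' chrom, pos, ref, alt. Annotation columns are the per-database minor
#' allele frequencies (`maf_tgp`, `maf_aric`, `maf_gnomad`, `maf_inhouse`),
#' `cadd`, `revel` and `gene`.
#'
#' @param vcf_path Path to an uncompressed VCF file.
#' @param ann_path Optional path to the annotation TSV.
#' @return Tibble with one row per sample x variant: `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gt` (`"ref"`, `"het"`, `"hom"` or `NA`),
#'   `v_reads`, `t_reads`, plus the annotation columns (NA when
#'   unannotated).
#' @export
read_genotypes <- function(vcf_path, ann_path = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf)) %>%
    dplyr::transmute(chrom = .data$CHROM, pos = as.integer(.data$POS),
                     ref = .data$REF, alt = .data$ALT)
  lc_assert(all(fix$pos >= 1) && !any(fix$ref == fix$alt, na.rm = TRUE),
            "Malformed VCF records (pos < 1 or ref == alt).")
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  classify_gt <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/")
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_character_)
      n_alt <- sum(a != "0")
      if (n_alt == 0) "ref" else if (n_alt == length(a)) "hom" else "het"
    }, character(1))
  }
  ad_raw <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
  records <- purrr::map_dfr(colnames(gt_raw), function(s) {
    out <- fix
    out$sample_id <- s
    out$gt <- unname(classify_gt(gt_raw[, s]))
    if (!is.null(ad_raw)) {
      parts <- strsplit(unname(ad_raw[, s]), ",")
      out$v_reads <- vapply(parts, function(p)
        if (length(p) >= 2) suppressWarnings(as.integer(p[[2]])) else NA_integer_,
        integer(1))
      out$t_reads <- vapply(parts, function(p) {
        v <- suppressWarnings(as.integer(p))
        if (all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
      }, integer(1))
    } else {
      out$v_reads <- NA_integer_
      out$t_reads <- NA_integer_
    }
    out
  }) %>%
    dplyr::select("sample_id", dplyr::everything())

  if (!is.null(ann_path)) {
    ann <- read_variant_annotation(ann_path)
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    orphan <- setdiff(key(ann), key(fix))
    if (length(orphan)) {
      rlang::warn(paste0("Annotation rows for variants absent from the VCF ignored: ",
                         paste(orphan, collapse = ", ")))
      ann <- ann[!key(ann) %in% orphan, ]
    }
    records <- dplyr::left_join(records, ann,
                                by = c("chrom", "pos", "ref", "alt"))
  }
  records
}

#' Read a variant annotation TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `maf_tgp`, `maf_aric`,
#' `maf_gnomad`, `maf_inhouse`, `cadd`, `revel`. Duplicate
#' chrom/pos/ref/alt keys are an input error.
#'
#' @param path Path to the TSV.
#' @return A tibble keyed by chrom, pos, ref, alt.
#' @export
read_variant_annotation <- function(path) {
  ann <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE) %>%
    dplyr::mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos))
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  if (anyDuplicated(key)) {
    lc_abort(paste0("Annotation key collision: ",
                    paste(unique(key[duplicated(key)]), collapse = ", ")),
             "error_input")
  }
  ann
}

#' Read a PED pedigree file
#'
#' Whitespace-delimited PED dialect: family, individual, father, mother,
#' sex, affected status. `0` parent codes become `NA`.
#'
#' @param path Path to the PED file.
#' @return Tibble (`family`, `individual`, `father`, `mother`, `sex`,
#'   `affected`).
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "affected"))
  tibble::as_tibble(ped) %>%
    dplyr::mutate(father = dplyr::na_if(as.character(.data$father), "0"),
                  mother = dplyr::na_if(as.character(.data$mother), "0"),
                  individual = as.character(.data$individual),
                  family = as.character(.data$family))
}

#' Rare, predicted-damaging variant prioritisation
#'
#' Retains records whose gene is on the analysis gene list, whose maximum
#' minor allele frequency across the available population databases is
#' strictly below `maf_max`, and whose CADD-phred score is strictly above
#' `cadd_min`. Missing frequencies ("not found") count as 0; a missing CADD
#' score fails the CADD criterion. Pre-specified variants on the `rescue`
#' list (keys `"chrom:pos:ref:alt"`) bypass the filter, mirroring the
#' inclusion of established alleles whose database statistics would
#' otherwise exclude them; every decision is logged.
#'
#' @param records Genotype/variant tibble carrying `gene`, the `maf_*`
#'   columns and `cadd` (see [read_genotypes()]).
#' @param genes Character vector of gene symbols defining the panel.
#' @param maf_max Strict upper bound on the maximum database MAF
#'   (default 1e-4, i.e. < 0.01%).
#' @param cadd_min Strict lower bound on CADD-phred (default 15).
#' @param rescue Character vector of variant keys that bypass the filter.
#' @return The retained rows, with attribute `filter_log`: a tibble with one
#'   row per input record recording `retained` and the failing criterion.
#' @export
filter_rare_damaging <- function(records, genes, maf_max = 1e-4, cadd_min = 15,
                                 rescue = character()) {
  lc_assert(length(genes) > 0, "Gene list must be non-empty.", "error_config")
  lc_assert(maf_max > 0 && cadd_min > 0, "Thresholds must be positive.")
  maf_cols <- intersect(c("maf_tgp", "maf_aric", "maf_gnomad", "maf_inhouse"),
                        names(records))
  max_maf <- if (length(maf_cols)) {
    m <- as.matrix(records[maf_cols])
    m[is.na(m)] <- 0
    apply(m, 1, max)
  } else {
    rep(0, nrow(records))
  }
  key <- paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
  cadd <- if ("cadd" %in% names(records)) records$cadd else rep(NA_real_, nrow(records))
  reason <- dplyr::case_when(
    key %in% rescue ~ "rescued",
    !(records$gene %in% genes) ~ "gene_not_on_panel",
    max_maf >= maf_max ~ "frequency",
    is.na(cadd) | cadd <= cadd_min ~ "cadd",
    TRUE ~ "pass"
  )
  log <- tibble::tibble(key = key, gene = records$gene, max_maf = max_maf,
                        cadd = cadd, reason = reason,
                        retained = reason %in% c("pass", "rescued"))
  out <- records[log$retained, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Label the parental origin of a proband variant
#'
#' Vectorised over genotype codes (`"ref"`, `"het"`, `"hom"`, `NA`).
#' With both parents observed: a variant present in exactly one parent is
#' labelled with that parent; absent from both parents it is `de_novo`;
#' present in both it cannot be resolved to a single origin and is
#' `unknown`. Any missing parental genotype yields `unknown`. A reference
#' proband genotype is an input error (there is no variant to trace).
#'
#' @param proband,mother,father Genotype code vectors of equal length.
#' @return Character vector with values `maternal`, `paternal`, `de_novo`
#'   or `unknown`.
#' @export
assign_inheritance <- function(proband, mother = NA_character_,
                               father = NA_character_) {
  n <- length(proband)
  mother <- rep_len(mother, n); father <- rep_len(father, n)
  if (any(proband == "ref", na.rm = TRUE) || anyNA(proband)) {
    lc_abort("Proband genotype must carry the variant (het or hom).", "error_input")
  }
  carries <- function(g) !is.na(g) & g %in% c("het", "hom")
  observed <- function(g) !is.na(g)
  dplyr::case_when(
    observed(mother) & observed(father) & carries(mother) & !carries(father) ~ "maternal",
    observed(mother) & observed(father) & carries(father) & !carries(mother) ~ "paternal",
    observed(mother) & observed(father) & !carries(mother) & !carries(father) ~ "de_novo",
    TRUE ~ "unknown"
  )
}

#' Label inheritance for every proband variant in a trio cohort
#'
#' Joins genotype records with a pedigree, looks up each parent's genotype
#' at each variant the proband carries, and applies
#' [assign_inheritance()].
#'
#' @param genotypes Records from [read_genotypes()] for all trio members.
#' @param ped Pedigree from [read_ped()].
#' @return Tibble (`proband_id`, `chrom`, `pos`, `ref`, `alt`, `gt`,
#'   `origin`).
#' @export
label_inheritance <- function(genotypes, ped) {
  probands <- ped %>%
    dplyr::filter(!is.na(.data$father) | !is.na(.data$mother))
  gt_of <- function(sample, chrom, pos, ref, alt) {
    if (is.na(sample)) return(NA_character_)
    hit <- genotypes$gt[genotypes$sample_id == sample &
                          genotypes$chrom == chrom & genotypes$pos == pos &
                          genotypes$ref == ref & genotypes$alt == alt]
    if (length(hit) == 0) NA_character_ else hit[[1]]
  }
  genotypes %>%
    dplyr::filter(.data$sample_id %in% probands$individual,
                  .data$gt %in% c("het", "hom")) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      origin = {
        par <- probands[probands$individual == .data$sample_id, ]
        assign_inheritance(
          .data$gt,
          gt_of(par$mother[[1]], .data$chrom, .data$pos, .data$ref, .data$alt),
          gt_of(par$father[[1]], .data$chrom, .data$pos, .data$ref, .data$alt)
        )
      }
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(proband_id = "sample_id", "chrom", "pos", "ref", "alt",
                  "gt", "origin")
}

#' Phase two heterozygous variants from clone sequencing observations
#'
#' Each clone captures one physical allele and reports the state (`"wt"` or
#' `"mut"`) at both loci. Two variants are in trans when clones carrying
#' exactly one of the two variants are each observed and no clone carries
#' both; they are in cis when a double-mutant clone exists and no
#' single-mutant clone contradicts it; anything else is ambiguous.
#'
#' @param obs Tibble with columns `locus1` and `locus2` (one row per clone,
#'   values `"wt"`/`"mut"`).
#' @return `"trans"`, `"cis"` or `"ambiguous"`.
#' @export
phase_from_clones <- function(obs) {
  lc_assert(is.data.frame(obs) && all(c("locus1", "locus2") %in% names(obs)),
            "`obs` must have columns `locus1` and `locus2`.")
  if (nrow(obs) < 2) {
    lc_abort("At least two clones are required to phase.", "error_insufficient_evidence")
  }
  lc_assert(all(unlist(obs[c("locus1", "locus2")]) %in% c("wt", "mut")),
            "Clone states must be 'wt' or 'mut'.")
  m1 <- obs$locus1 == "mut" & obs$locus2 == "wt"
  m2 <- obs$locus1 == "wt" & obs$locus2 == "mut"
  mm <- obs$locus1 == "mut" & obs$locus2 == "mut"
  if (any(m1) && any(m2) && !any(mm)) return("trans")
  if (any(mm) && !any(m1) && !any(m2)) return("cis")
  "ambiguous"
}

#' Classify the biallelic status of a proband's variants at one gene
#'
#' A homozygous call is `homozygous`. Two heterozygous variants whose
#' parental origins differ (one maternal, one paternal), or whose clone
#' phase is trans, form a `compound_het_trans`; a shared origin or cis phase
#' gives `cis`; two heterozygotes with no phasing evidence are reported as
#' an `unphased_pair`, never silently promoted. A single heterozygote is
#' `none`.
#'
#' @param zygosity Character vector of zygosity codes (`"het"`/`"hom"`) for
#'   the proband's variants at the gene.
#' @param origins Optional parental origins aligned with `zygosity`
#'   (`"maternal"`, `"paternal"`, `"de_novo"`, `"unknown"`).
#' @param clone_phase Optional result of [phase_from_clones()].
#' @return One of `"none"`, `"homozygous"`, `"compound_het_trans"`,
#'   `"cis"`, `"unphased_pair"`.
#' @export
detect_biallelic <- function(zygosity, origins = NULL, clone_phase = NULL) {
  lc_assert(all(zygosity %in% c("het", "hom")),
            "`zygosity` values must be 'het' or 'hom'.")
  if (any(zygosity == "hom")) return("homozygous")
  if (sum(zygosity == "het") < 2) return("none")
  if (!is.null(clone_phase)) {
    if (clone_phase == "trans") return("compound_het_trans")
    if (clone_phase == "cis") return("cis")
  }
  if (!is.null(origins)) {
    known <- origins[origins %in% c("maternal", "paternal")]
    if (length(unique(known)) == 2) return("compound_het_trans")
    if (length(known) >= 2 && length(unique(known)) == 1) return("cis")
  }
  "unphased_pair"
}

#' Cohort yield by lesion category
#'
#' Counts, per lesion category, the probands carrying a qualifying variant,
#' with the percentage rounded to one decimal. Categories may overlap (a
#' proband can contribute to several rows); probands with no lesion label
#' still count toward the overall row. Empty categories report `NA`.
#'
#' @param cohort Long tibble with columns `proband_id`, `lesion` (may be
#'   `NA`; repeated rows allowed for overlapping categories) and `carrier`
#'   (logical, constant within proband).
#' @param categories Optional character vector fixing the set and order of
#'   reported lesion rows; categories absent from the cohort report `NA`.
#' @param include_overall Add an `(all)` row over distinct probands.
#' @return Tibble (`lesion`, `total`, `carriers`, `percent`, `proportion`).
#' @export
cohort_yield_table <- function(cohort, categories = NULL, include_overall = TRUE) {
  lc_assert(all(c("proband_id", "lesion", "carrier") %in% names(cohort)),
            "`cohort` needs columns proband_id, lesion, carrier.")
  per_proband <- cohort %>%
    dplyr::distinct(.data$proband_id, .data$carrier)
  lc_assert(!anyDuplicated(per_proband$proband_id),
            "`carrier` must be constant within proband.")
  yield_row <- function(d, label) {
    total <- dplyr::n_distinct(d$proband_id)
    carriers <- dplyr::n_distinct(d$proband_id[d$carrier])
    tibble::tibble(
      lesion = label, total = total, carriers = carriers,
      percent = if (total == 0) NA_real_ else round(100 * carriers / total, 1),
      proportion = if (total == 0) NA_real_ else carriers / total
    )
  }
  cats <- categories %||% sort(unique(cohort$lesion[!is.na(cohort$lesion)]))
  rows <- purrr::map_dfr(cats, function(lb) {
    yield_row(dplyr::filter(cohort, .data$lesion %in% lb), lb)
  })
  if (include_overall) {
    overall <- cohort %>%
      dplyr::distinct(.data$proband_id, .data$carrier) %>%
      dplyr::mutate(proband_id = .data$proband_id) %>%
      yield_row("(all)")
    rows <- dplyr::bind_rows(overall, rows)
  }
  rows
}
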