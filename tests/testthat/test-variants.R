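write_toy_vcf <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("10", "72192697", ".", "G", "A", ".", "PASS", ".", "GT:AD",
            "0/1:102,106", "0/0:95,0"), collapse = "\t"),
    paste(c("10", "72195155", ".", "C", "T", ".", "PASS", ".", "GT:AD",
            "1/1:1,142", "0/1:60,58"), collapse = "\t"),
    paste(c("10", "72195326", ".", "C", "T", ".", "PASS", ".", "GT:AD",
            "./.:.", "0/1:43,43"), collapse = "\t")
  ), vcf)
  ann <- file.path(dir, "ann.tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "10", pos = c(72192697L, 72195155L, 72195326L),
    ref = c("G", "C", "C"), alt = c("A", "T", "T"),
    gene = "NODAL",
    maf_tgp = NA_real_, maf_aric = NA_real_,
    maf_gnomad = c(4.06e-6, 3e-4, 4e-4),
    maf_inhouse = NA_real_,
    cadd = c(31, 33, 11.7), revel = c(0.51, 0.79, 0.45)
  ), ann)
  list(vcf = vcf, ann = ann)
}

test_that("VCF + annotation join yields typed genotype records", {
  p <- write_toy_vcf()
  rec <- read_genotypes(p$vcf, p$ann)
  expect_equal(nrow(rec), 6)  # 3 variants x 2 samples
  r <- function(s, pos) rec[rec$sample_id == s & rec$pos == pos, ]
  expect_equal(r("S1", 72192697)$gt, "het")
  expect_equal(r("S1", 72195155)$gt, "hom")
  expect_true(is.na(r("S1", 72195326)$gt))
  expect_equal(r("S1", 72192697)$v_reads, 106L)
  expect_equal(r("S1", 72192697)$t_reads, 208L)
  expect_equal(unique(rec$gene), "NODAL")
})

test_that("annotation rows for absent variants warn; duplicate keys error", {
  p <- write_toy_vcf()
  ann <- readr::read_tsv(p$ann, show_col_types = FALSE)
  extra <- dplyr::mutate(ann[1, ], pos = 1L)
  readr::write_tsv(dplyr::bind_rows(ann, extra), p$ann)
  expect_warning(read_genotypes(p$vcf, p$ann), "ignored")
  readr::write_tsv(dplyr::bind_rows(ann, ann[1, ]), p$ann)
  expect_error(read_genotypes(p$vcf, p$ann), class = "latcohort_error_input")
})

test_that("rare-damaging filter applies panel, frequency and CADD rules with logging", {
  records <- tibble::tibble(
    chrom = "10", pos = 1:5 * 10L, ref = "A", alt = "T",
    gene = c("NODAL", "NODAL", "NODAL", "OTHER", "NODAL"),
    maf_gnomad = c(4.06e-6, 0.02, 0, 0, 3e-4),
    maf_tgp = NA_real_,
    cadd = c(31, 30, 14.9, 30, 33)
  )
  out <- filter_rare_damaging(records, genes = "NODAL")
  log <- attr(out, "filter_log")
  expect_equal(log$reason, c("pass", "frequency", "cadd",
                             "gene_not_on_panel", "frequency"))
  expect_equal(out$pos, 10L)
  # CADD boundary is strict: exactly 15 fails
  records$cadd[3] <- 15
  out2 <- filter_rare_damaging(records, genes = "NODAL")
  expect_equal(attr(out2, "filter_log")$reason[3], "cadd")
  # rescue list bypasses the filter for pre-specified known alleles
  out3 <- filter_rare_damaging(records, genes = "NODAL",
                               rescue = "10:50:A:T")
  expect_true("rescued" %in% attr(out3, "filter_log")$reason)
  expect_setequal(out3$pos, c(10L, 50L))
  expect_error(filter_rare_damaging(records, genes = character(0)),
               class = "latcohort_error_config")
})

test_that("rare-damaging filter is idempotent and order-independent", {
  records <- tibble::tibble(
    chrom = "10", pos = 1:6 * 7L, ref = "G", alt = "C",
    gene = "NODAL",
    maf_gnomad = c(0, 1e-5, 2e-4, 0, NA, 5e-5),
    cadd = c(20, 14, 30, 25, 16, NA)
  )
  strip <- function(x) { attr(x, "filter_log") <- NULL; tibble::as_tibble(x) }
  once <- filter_rare_damaging(records, "NODAL")
  twice <- filter_rare_damaging(once, "NODAL")
  expect_identical(strip(once), strip(twice))
  shuffled <- filter_rare_damaging(records[sample(6), ], "NODAL")
  expect_identical(dplyr::arrange(strip(once), pos),
                   dplyr::arrange(strip(shuffled), pos))
})

test_that("inheritance labels follow trio genotype logic", {
  expect_equal(assign_inheritance("het", mother = "ref", father = "het"), "paternal")
  expect_equal(assign_inheritance("het", mother = "het", father = "ref"), "maternal")
  expect_equal(assign_inheritance("het", mother = "ref", father = "ref"), "de_novo")
  expect_equal(assign_inheritance("het", mother = "het", father = "het"), "unknown")
  expect_equal(assign_inheritance("het", mother = "het", father = NA), "unknown")
  expect_equal(assign_inheritance("hom", mother = "het", father = "het"), "unknown")
  expect_error(assign_inheritance("ref", "het", "het"),
               class = "latcohort_error_input")
})

test_that("clone phasing matches the exhaustive case oracle on all patterns up to 4 clones", {
  states <- list(c("wt", "wt"), c("mut", "wt"), c("wt", "mut"), c("mut", "mut"))
  for (n in 2:4) {
    combos <- do.call(expand.grid, rep(list(1:4), n))
    for (i in seq_len(nrow(combos))) {
      picked <- states[as.integer(combos[i, ])]
      obs <- tibble::tibble(
        clone_id = sprintf("c%d", seq_len(n)),
        locus1 = vapply(picked, `[`, "", 1),
        locus2 = vapply(picked, `[`, "", 2)
      )
      expect_identical(phase_from_clones(obs), oracle_phase(picked))
    }
  }
  expect_error(phase_from_clones(tibble::tibble(locus1 = "mut", locus2 = "wt")),
               class = "latcohort_error_insufficient_evidence")
})

test_that("clone phasing recognises the canonical trans and cis patterns", {
  trans_obs <- tibble::tibble(
    clone_id = sprintf("c%d", 1:12),
    locus1 = rep(c("mut", "wt"), each = 6),
    locus2 = rep(c("wt", "mut"), each = 6)
  )
  expect_identical(phase_from_clones(trans_obs), "trans")
  cis_obs <- tibble::tibble(clone_id = c("c1", "c2"),
                            locus1 = c("mut", "wt"), locus2 = c("mut", "wt"))
  expect_identical(phase_from_clones(cis_obs), "cis")
  amb <- tibble::tibble(clone_id = c("c1", "c2"),
                        locus1 = c("mut", "mut"), locus2 = c("wt", "mut"))
  expect_identical(phase_from_clones(amb), "ambiguous")
})

test_that("biallelic detection distinguishes hom, trans, cis and unphased pairs", {
  expect_equal(detect_biallelic("hom"), "homozygous")
  expect_equal(detect_biallelic(c("het", "het"),
                                origins = c("maternal", "paternal")),
               "compound_het_trans")
  expect_equal(detect_biallelic(c("het", "het"), clone_phase = "trans"),
               "compound_het_trans")
  expect_equal(detect_biallelic(c("het", "het"),
                                origins = c("maternal", "maternal")), "cis")
  expect_equal(detect_biallelic(c("het", "het"), clone_phase = "cis"), "cis")
  expect_equal(detect_biallelic(c("het", "het")), "unphased_pair")
  expect_equal(detect_biallelic("het"), "none")
})

test_that("generated noiseless trios are labelled in full agreement with truth", {
  gg <- gen_genotype_cohort(n_trios = 12, seed = 31)
  paths <- write_trio_vcf(gg$trios, tempfile())
  labels <- label_inheritance(read_genotypes(paths$vcf), read_ped(paths$ped))
  primary <- dplyr::filter(labels, pos == 72195155) %>%
    dplyr::mutate(trio_id = sub("_P$", "", proband_id))
  joined <- dplyr::inner_join(primary, gg$trios, by = "trio_id")
  expect_equal(nrow(joined), nrow(gg$trios))
  expect_identical(joined$origin, joined$origin_truth)
  # compound-het trio: second site is paternal, clones phase trans
  comp <- gg$trios$trio_id[gg$trios$biallelic_truth == "compound_het_trans"]
  second <- dplyr::filter(labels, pos == 72195210,
                          proband_id == paste0(comp, "_P"))
  expect_equal(second$origin, "paternal")
  expect_equal(
    detect_biallelic(c("het", "het"),
                     origins = c("maternal", second$origin),
                     clone_phase = phase_from_clones(gg$clones)),
    "compound_het_trans"
  )
})

test_that("cohort yield table reproduces published per-lesion frequencies", {
  yt <- cohort_yield_table(cohort_lesion_rows(laterality_cohort()))
  row <- function(l) yt[yt$lesion == l, ]
  expect_equal(row("(all)")$percent, 6.5)
  expect_equal(row("CCTGA")$percent, 15.4)
  expect_equal(row("Any L-looping")$percent, 13.6)
  expect_equal(row("Right atrial isomerism/Asplenia")$percent, 10.3)
  expect_equal(row("DORV with malposed GA")$percent, 0)
  expect_equal(row("Simple DTGA")$percent, 6.1)
  # empty category reports NA
  yt2 <- cohort_yield_table(cohort_lesion_rows(laterality_cohort()),
                            categories = c("CCTGA", "Never seen"),
                            include_overall = FALSE)
  expect_true(is.na(yt2$percent[yt2$lesion == "Never seen"]))
})
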