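test_that("RPKM applies the reads-per-kilobase-per-million formula exactly", {
  exons <- tibble::tibble(exon_id = c("e1", "e2"), chrom = "1",
                          start = c(0L, 5000L), end = c(1000L, 5500L),
                          gene = "G")
  counts <- matrix(c(100L, 0L, 50L, 10L), 2,
                   dimnames = list(c("e1", "e2"), c("s1", "s2")))
  m <- rpkm(counts, exons, totals = c(s1 = 1e7, s2 = 1e7))
  expect_equal(m$values["e1", "s1"], 10)       # 100 reads / 1 kb / 10 M
  expect_equal(m$values["e2", "s1"], 0)
  # doubling the library size halves RPKM
  m2 <- rpkm(counts, exons, totals = c(s1 = 2e7, s2 = 2e7))
  expect_equal(m2$values, m$values / 2)
  expect_error(rpkm(counts, exons, totals = c(s1 = 0, s2 = 1e7)),
               class = "latcohort_error_input")
})

test_that("deletion screen finds embedded het runs and stays silent on clean cohorts", {
  dels <- tibble::tibble(sample = "SMP03",
                         exon_id = c("GENE2_ex02", "GENE2_ex03"),
                         zygosity = "het")
  rc <- gen_rpkm_cohort(n_samples = 20, deletions = dels, seed = 5)
  m <- rpkm(rc$counts, rc$exons)
  calls <- screen_deletions(m, "SMP03")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$zygosity, "het")
  expect_setequal(calls$exons[[1]], dels$exon_id)
  expect_equal(calls$start, min(rc$truth$start))
  expect_equal(calls$end, max(rc$truth$end))
  # all-normal sample in the same cohort yields nothing
  expect_equal(nrow(screen_deletions(m, "SMP07")), 0)
  expect_error(screen_deletions(m, "nope"), class = "latcohort_error_lookup")
})

test_that("single-exon deletions are called at min_consecutive = 1", {
  dels <- tibble::tibble(sample = "SMP02", exon_id = "GENE1_ex03",
                         zygosity = "het")
  rc <- gen_rpkm_cohort(n_samples = 12, deletions = dels, seed = 8)
  calls <- screen_deletions(rpkm(rc$counts, rc$exons), "SMP02")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_exons, 1)
  expect_equal(calls$exons[[1]], "GENE1_ex03")
})

test_that("homozygous deletions are separated from het calls by the ratio windows", {
  dels <- tibble::tibble(sample = "SMP04",
                         exon_id = c("GENE3_ex02", "GENE3_ex03"),
                         zygosity = "hom")
  rc <- gen_rpkm_cohort(n_samples = 16, deletions = dels, seed = 12)
  calls <- screen_deletions(rpkm(rc$counts, rc$exons), "SMP04")
  expect_equal(calls$zygosity, "hom")
  expect_setequal(calls$exons[[1]], dels$exon_id)
})

test_that("screen sensitivity is 1 for two-exon deletions and exon FPR stays below 1%", {
  hits <- 0; fp <- 0; exons_total <- 0
  for (s in 1:15) {
    dels <- tibble::tibble(sample = "SMP05",
                           exon_id = c("GENE2_ex04", "GENE2_ex05"),
                           zygosity = "het")
    rc <- gen_rpkm_cohort(n_samples = 15, deletions = dels, seed = 300 + s)
    m <- rpkm(rc$counts, rc$exons)
    calls <- screen_deletions(m, "SMP05")
    found <- nrow(calls) > 0 &&
      any(vapply(calls$exons, function(e) all(dels$exon_id %in% e), logical(1)))
    hits <- hits + found
    clean <- screen_deletions(m, "SMP09")
    fp <- fp + if (nrow(clean)) sum(clean$n_exons) else 0
    exons_total <- exons_total + nrow(rc$counts)
  }
  expect_equal(hits, 15)
  expect_lte(fp / exons_total, 0.01)
})

test_that("deletion size is the absolute coordinate difference, order-invariant", {
  expect_equal(deletion_size(72204016, 72157996), 46020L)
  expect_equal(deletion_size(72157996, 72204016), 46020L)
  expect_equal(deletion_size(5, 5), 0L)
  span <- deletion_span(72204016, 72157996)
  expect_equal(span$start, 72157996)
  expect_equal(span$end, 72204016)
  expect_equal(span$size, 46020L)
})

test_that("junction resolution recovers engineered microhomology exactly", {
  jc <- gen_junction_case(mh_len = 5, seed = 3)
  res <- resolve_junction(jc$junction, jc$prox_ref, jc$dist_ref)
  expect_equal(nchar(res$microhomology), 5)
  expect_equal(res$microhomology, jc$truth$microhomology)
  expect_equal(res$inserted, "")
  expect_equal(res$prox_interval, jc$truth$prox_interval)
  expect_equal(res$dist_interval, jc$truth$dist_interval)
  expect_equal(diff(res$prox_interval), diff(res$dist_interval))
})

test_that("blunt junctions and templated insertions are classified correctly", {
  jb <- gen_junction_case(mh_len = 0, insertion = "", seed = 10)
  rb <- resolve_junction(jb$junction, jb$prox_ref, jb$dist_ref)
  expect_true(rb$exact)
  expect_equal(rb$microhomology, "")
  expect_equal(rb$inserted, "")
  ji <- gen_junction_case(mh_len = 0, insertion = "ACT", seed = 11)
  ri <- resolve_junction(ji$junction, ji$prox_ref, ji$dist_ref)
  expect_equal(ri$inserted, "ACT")
  expect_equal(ri$microhomology, "")
  expect_false(ri$exact)
})

test_that("junction resolution errors on unmatchable or ambiguous flanks", {
  jc <- gen_junction_case(mh_len = 2, seed = 14)
  expect_error(resolve_junction(jc$junction, strrep("A", 150), jc$dist_ref),
               class = "latcohort_error_unresolvable")
  expect_error(resolve_junction(jc$junction,
                                paste0(jc$prox_ref, jc$prox_ref),
                                jc$dist_ref),
               class = "latcohort_error_ambiguous")
  expect_error(resolve_junction("ACGTACGTACGT", jc$prox_ref, jc$dist_ref))
})

test_that("AAMR classification needs directly oriented Alu pairs at both breakpoints", {
  jc <- gen_junction_case(mh_len = 5, seed = 3)
  prox_pos <- jc$offsets[["prox"]] + jc$truth$prox_interval[1]
  dist_pos <- jc$offsets[["dist"]] + jc$truth$dist_interval[1]
  cls <- classify_aamr(prox_pos, dist_pos, jc$repeats, "GATTC")
  expect_true(cls$aamr_candidate)
  expect_equal(cls$family_proximal, "AluSx1")
  expect_equal(cls$family_distal, "AluSq2")
  expect_true(cls$chimeric)
  # opposite strands: inverted orientation, not AAMR
  ji <- gen_junction_case(mh_len = 5, strands = c("+", "-"), seed = 4)
  cls2 <- classify_aamr(ji$offsets[["prox"]] + ji$truth$prox_interval[1],
                        ji$offsets[["dist"]] + ji$truth$dist_interval[1],
                        ji$repeats, "AA")
  expect_false(cls2$aamr_candidate)
  # breakpoint outside any repeat
  cls3 <- classify_aamr(1, dist_pos, jc$repeats, "AA")
  expect_false(cls3$aamr_candidate)
  expect_true(is.na(cls3$family_proximal))
  # microhomology absent: candidate but not chimeric
  cls4 <- classify_aamr(prox_pos, dist_pos, jc$repeats, "")
  expect_true(cls4$aamr_candidate)
  expect_false(cls4$chimeric)
})

test_that("FASTA and BED round-trips preserve generated junction inputs", {
  jc <- gen_junction_case(mh_len = 4, seed = 6)
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "refs.fa")
  write_fasta(c(prox = jc$prox_ref, dist = jc$dist_ref, junction = jc$junction), fa)
  seqs <- read_fasta(fa)
  expect_equal(unname(seqs["prox"]), jc$prox_ref)
  expect_equal(unname(seqs["junction"]), jc$junction)
  bed <- file.path(dir, "repeats.bed")
  readr::write_tsv(dplyr::mutate(jc$repeats, score = 0L, .after = "family"),
                   bed, col_names = FALSE)
  reps <- read_repeats_bed(bed)
  expect_equal(reps$family, jc$repeats$family)
  expect_equal(reps$start, jc$repeats$start)
})
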