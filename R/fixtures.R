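# Packaged miniature cardiac-phenotype ontology and reconstructed cohort
# fixtures. Per-proband term sets are a synthetic reconstruction from
# published summary-level lesion and segmental-anatomy information, not the
# study's original annotation data.

mini_ontology_terms <- function() {
  tibble::tribble(
    ~id, ~name, ~parents,
    "CP:0000001", "cardiovascular and laterality phenotype", "",
    "CP:0000002", "abnormal left-right patterning", "CP:0000001",
    "CP:0000003", "situs inversus totalis", "CP:0000002",
    "CP:0000004", "heterotaxy", "CP:0000002",
    "CP:0000005", "right atrial isomerism", "CP:0000004",
    "CP:0000006", "left atrial isomerism", "CP:0000004",
    "CP:0000007", "asplenia", "CP:0000002",
    "CP:0000008", "dextrocardia", "CP:0000002",
    "CP:0000010", "abnormal ventricular looping", "CP:0000001",
    "CP:0000011", "L-looped ventricles", "CP:0000010",
    "CP:0000012", "D-looped ventricles", "CP:0000010",
    "CP:0000015", "abnormal great artery position", "CP:0000001",
    "CP:0000016", "transposition of the great arteries", "CP:0000015",
    "CP:0000017", "dextro-transposition of the great arteries", "CP:0000016",
    "CP:0000018", "levo-transposition of the great arteries", "CP:0000016",
    "CP:0000019", "malposition of the great arteries", "CP:0000015",
    "CP:0000020", "D-malposition of the great arteries", "CP:0000019",
    "CP:0000021", "L-malposition of the great arteries", "CP:0000019",
    "CP:0000022", "congenitally corrected transposition of the great arteries",
      "CP:0000018|CP:0000026",
    "CP:0000025", "abnormal atrioventricular connection", "CP:0000001",
    "CP:0000026", "discordant atrioventricular connection", "CP:0000025",
    "CP:0000027", "double inlet left ventricle", "CP:0000025",
    "CP:0000028", "tricuspid atresia", "CP:0000025",
    "CP:0000029", "mitral atresia", "CP:0000025",
    "CP:0000030", "straddling atrioventricular valve", "CP:0000025",
    "CP:0000031", "common atrioventricular canal", "CP:0000025",
    "CP:0000032", "abnormal ventriculoarterial connection", "CP:0000001",
    "CP:0000033", "double outlet right ventricle", "CP:0000032",
    "CP:0000035", "right ventricular outflow tract obstruction", "CP:0000001",
    "CP:0000036", "pulmonary stenosis", "CP:0000035",
    "CP:0000037", "pulmonary atresia", "CP:0000035",
    "CP:0000040", "septal defect", "CP:0000001",
    "CP:0000041", "atrial septal defect", "CP:0000040",
    "CP:0000042", "secundum atrial septal defect", "CP:0000041",
    "CP:0000043", "ventricular septal defect", "CP:0000040",
    "CP:0000045", "single ventricle", "CP:0000001",
    "CP:0000047", "abnormal aortic arch", "CP:0000001",
    "CP:0000048", "coarctation of the aorta", "CP:0000047",
    "CP:0000049", "hypoplastic aortic arch", "CP:0000047",
    "CP:0000050", "subaortic stenosis", "CP:0000001"
  )
}

#' Write the packaged miniature cardiac-phenotype ontology
#'
#' A fixed ~40-term DAG standing in for the full human phenotype ontology in
#' tests and examples. It carries the vocabulary of laterality congenital
#' heart disease: left-right patterning (situs inversus, heterotaxy, atrial
#' isomerism, asplenia), ventricular looping, great-artery position and
#' transposition/malposition, atrioventricular and ventriculoarterial
#' connections, outflow obstruction, septal defects, single ventricle and
#' aortic arch anomalies. The four nonspecific terms used as the default
#' exclusion list ([exclusion_terms()]) are included. Content is fixed (not
#' randomised) for reproducibility; the file also carries one alternate id
#' (`CP:0000099` for heterotaxy) and one obsolete stanza to exercise
#' parsers.
#'
#' @param path Output path for the OBO file.
#' @return `path`, invisibly usable with [load_obo()].
#' @export
write_mini_ontology <- function(path) {
  tt <- mini_ontology_terms()
  lines <- c("format-version: 1.2",
             "ontology: mini-cardiac-phenotype", "")
  for (i in seq_len(nrow(tt))) {
    lines <- c(lines, "[Term]",
               paste0("id: ", tt$id[i]),
               paste0("name: ", tt$name[i]))
    if (tt$id[i] == "CP:0000004") lines <- c(lines, "alt_id: CP:0000099")
    ps <- strsplit(tt$parents[i], "|", fixed = TRUE)[[1]]
    ps <- ps[nzchar(ps)]
    for (p in ps) {
      lines <- c(lines, paste0("is_a: ", p, " ! ",
                               tt$name[tt$id == p]))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "[Term]", "id: CP:0000060",
             "name: obsolete cardiac anomaly", "is_obsolete: true", "")
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged miniature cardiac-phenotype ontology
#'
#' @return An `onto_graph` (see [load_obo()]).
#' @export
mini_ontology <- function() {
  path <- tempfile(fileext = ".obo")
  on.exit(unlink(path))
  load_obo(write_mini_ontology(path))
}

#' Default exclusion list of nonspecific terms
#'
#' Atrial septal defect, ventricular septal defect, single ventricle and
#' secundum atrial septal defect: lesions too nonspecific to rare
#' laterality disease to carry signal in the primary similarity analysis.
#'
#' @return Character vector of term ids in the mini ontology.
#' @export
exclusion_terms <- function() {
  c("CP:0000041", "CP:0000043", "CP:0000045", "CP:0000042")
}

#' Reconstructed proband phenotype annotations (synthetic fixture)
#'
#' Term sets for the 33 cohort probands, reconstructed from summary-level
#' lesion and segmental-anatomy information using the mini ontology. The
#' four biallelic probands ([biallelic_probands()]) share the consistent
#' heterotaxy / right atrial isomerism / asplenia phenotype with abnormal
#' atrioventricular connection, D-malposed great arteries and pulmonary
#' atresia. This is an approximate stand-in for the study's per-proband
#' annotation supplement, which is not reproduced here.
#'
#' @return Annotation tibble (`proband_id`, `term_id`).
#' @export
proband_annotations <- function() {
  sets <- list(
    CVG0005 = c("CP:0000011", "CP:0000022", "CP:0000037", "CP:0000043"),
    LAT0080 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000029",
                "CP:0000033", "CP:0000020", "CP:0000036", "CP:0000043"),
    LAT0022 = c("CP:0000011", "CP:0000022", "CP:0000043"),
    LAT0045 = c("CP:0000003", "CP:0000011", "CP:0000022"),
    LAT1696 = c("CP:0000011", "CP:0000022", "CP:0000036"),
    LAT0123 = c("CP:0000003", "CP:0000011", "CP:0000027", "CP:0000021"),
    LAT1246 = c("CP:0000011", "CP:0000022", "CP:0000008"),
    LAT0191 = c("CP:0000011", "CP:0000027", "CP:0000021", "CP:0000045"),
    LAT1763 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000026", "CP:0000037", "CP:0000041"),
    CVG0006 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000026", "CP:0000037", "CP:0000043"),
    LAT0108 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000026", "CP:0000037"),
    LAT0265 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000026", "CP:0000037", "CP:0000041"),
    CVG0001 = c("CP:0000011", "CP:0000022", "CP:0000036"),
    LAT0040 = c("CP:0000003", "CP:0000012", "CP:0000017"),
    LAT0201 = c("CP:0000011", "CP:0000021", "CP:0000008"),
    LAT0248 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000028", "CP:0000036"),
    LAT0658 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000033", "CP:0000036"),
    LAT0830 = c("CP:0000011", "CP:0000020", "CP:0000008"),
    LAT0858 = c("CP:0000012", "CP:0000017", "CP:0000043"),
    LAT1016 = c("CP:0000012", "CP:0000017"),
    LAT0909 = c("CP:0000012", "CP:0000017", "CP:0000041"),
    LAT1028 = c("CP:0000012", "CP:0000028", "CP:0000021"),
    LAT1391 = c("CP:0000012", "CP:0000017", "CP:0000043"),
    LAT1617 = c("CP:0000011", "CP:0000022"),
    LAT1769 = c("CP:0000011", "CP:0000027", "CP:0000021"),
    LAT0165 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000033", "CP:0000029", "CP:0000036"),
    CVG0003 = c("CP:0000012", "CP:0000033", "CP:0000021", "CP:0000036"),
    LAT0368 = c("CP:0000011", "CP:0000022", "CP:0000043"),
    LAT0457 = c("CP:0000011", "CP:0000022", "CP:0000036"),
    LAT1724 = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                "CP:0000020", "CP:0000029"),
    LAT0048 = c("CP:0000012", "CP:0000017"),
    LAT1415 = c("CP:0000012", "CP:0000028", "CP:0000030", "CP:0000033",
                "CP:0000020", "CP:0000048"),
    CVG0007 = c("CP:0000012", "CP:0000033", "CP:0000020", "CP:0000050",
                "CP:0000049", "CP:0000048")
  )
  tibble::tibble(
    proband_id = rep(names(sets), lengths(sets)),
    term_id = unlist(sets, use.names = FALSE)
  )
}

#' Probands carrying biallelic variation
#'
#' The three homozygous probands and the compound-heterozygous (trans)
#' proband.
#'
#' @return Character vector of proband ids.
#' @export
biallelic_probands <- function() {
  c("CVG0006", "LAT0108", "LAT0265", "LAT1763")
}

#' Phenotype archetype table for the synthetic cohort generator
#'
#' Five lesion archetypes transcribed from the cohort's lesion and
#' segmental-anatomy strata; each maps to a term combination in the mini
#' ontology. The heterotaxy / right atrial isomerism archetype mirrors the
#' consistent biallelic phenotype.
#'
#' @return Tibble (`archetype`, `term_id`).
#' @export
lesion_archetypes <- function() {
  sets <- list(
    simple_dtga = c("CP:0000012", "CP:0000017"),
    dorv_dmga = c("CP:0000012", "CP:0000033", "CP:0000020", "CP:0000030",
                  "CP:0000048"),
    cctga = c("CP:0000011", "CP:0000022", "CP:0000037", "CP:0000008"),
    dilv_l = c("CP:0000011", "CP:0000027", "CP:0000021"),
    heterotaxy_rai = c("CP:0000004", "CP:0000005", "CP:0000007", "CP:0000012",
                       "CP:0000020", "CP:0000026", "CP:0000037")
  )
  tibble::tibble(
    archetype = rep(names(sets), lengths(sets)),
    term_id = unlist(sets, use.names = FALSE)
  )
}

#' Reconstructed laterality cohort for yield calculations (synthetic)
#'
#' Builds a 321-proband cohort whose lesion-category totals, variant-carrier
#' counts, and ancestry-subgroup margins reproduce the published cohort
#' summary: 21/321 carriers overall; per-lesion totals and carriers for
#' simple DTGA (49/3), DORV with malposed great arteries (26/0), CCTGA
#' (26/4), DILV D-looped (11/1), DILV L-looped (22/3), other L-looping
#' (18/2), situs inversus (15/1) and right atrial isomerism/asplenia
#' (68/7); 111 Hispanic probands of whom 10 carry the recurrent missense
#' allele (2 homozygous), all 10 within the 64 Hispanic probands whose
#' lesions are the classically associated categories.
#'
#' @return Tibble with one row per proband: `proband_id`, `category`,
#'   `hispanic`, `carrier`, `zygosity` (`NA` for non-carriers),
#'   `nodal_lesion` (lesion in the associated-category subgroup).
#' @export
laterality_cohort <- function() {
  strata <- tibble::tribble(
    ~category, ~total, ~carriers, ~hisp_carriers, ~hisp_noncarriers, ~assoc,
    "simple_dtga",     49L, 3L, 2L, 18L, TRUE,
    "dorv_malposed",   26L, 0L, 0L,  8L, FALSE,
    "cctga",           26L, 4L, 1L,  5L, TRUE,
    "dilv_d",          11L, 1L, 0L,  3L, TRUE,
    "dilv_l",          22L, 3L, 1L,  5L, TRUE,
    "other_l_looping", 18L, 2L, 0L,  4L, TRUE,
    "situs_inversus",  15L, 1L, 0L,  4L, FALSE,
    "heterotaxy_rai",  68L, 7L, 6L, 19L, TRUE,
    "unclassified",    86L, 0L, 0L, 35L, FALSE
  )
  rows <- purrr::pmap_dfr(strata, function(category, total, carriers,
                                         hisp_carriers, hisp_noncarriers, assoc) {
    carrier <- c(rep(TRUE, carriers), rep(FALSE, total - carriers))
    hispanic <- rep(FALSE, total)
    if (hisp_carriers > 0) hispanic[seq_len(hisp_carriers)] <- TRUE
    if (hisp_noncarriers > 0) {
      hispanic[carriers + seq_len(hisp_noncarriers)] <- TRUE
    }
    tibble::tibble(category = category, carrier = carrier,
                   hispanic = hispanic, nodal_lesion = assoc)
  })
  # the two homozygous Hispanic carriers sit in the isomerism group
  rows <- rows %>%
    dplyr::mutate(proband_id = sprintf("P%03d", dplyr::row_number()),
                  zygosity = dplyr::if_else(.data$carrier, "het", NA_character_))
  hom_idx <- which(rows$category == "heterotaxy_rai" & rows$carrier &
                     rows$hispanic)[1:2]
  rows$zygosity[hom_idx] <- "hom"
  dplyr::select(rows, "proband_id", "category", "hispanic", "carrier",
                "zygosity", "nodal_lesion")
}

#' Expand a cohort into overlapping lesion rows for yield tabulation
#'
#' Maps primary categories to the published lesion strata, including the
#' overlapping aggregates "DILV, All" (D- plus L-looped DILV) and "Any
#' L-looping" (CCTGA, L-looped DILV and other L-looping lesions).
#'
#' @param cohort A [laterality_cohort()]-shaped tibble.
#' @return Long tibble (`proband_id`, `lesion`, `carrier`) for
#'   [cohort_yield_table()].
#' @export
cohort_lesion_rows <- function(cohort) {
  label <- c(simple_dtga = "Simple DTGA",
             dorv_malposed = "DORV with malposed GA",
             cctga = "CCTGA",
             dilv_d = "DILV, D-looped",
             dilv_l = "DILV, L-looped",
             other_l_looping = "Other L-looping lesion",
             situs_inversus = "Situs inversus with CHD",
             heterotaxy_rai = "Right atrial isomerism/Asplenia",
             unclassified = NA_character_)
  base <- cohort %>%
    dplyr::transmute(.data$proband_id, lesion = label[.data$category],
                     .data$carrier)
  dilv_all <- cohort %>%
    dplyr::filter(.data$category %in% c("dilv_d", "dilv_l")) %>%
    dplyr::transmute(.data$proband_id, lesion = "DILV, All", .data$carrier)
  any_l <- cohort %>%
    dplyr::filter(.data$category %in% c("cctga", "dilv_l", "other_l_looping")) %>%
    dplyr::transmute(.data$proband_id, lesion = "Any L-looping", .data$carrier)
  dplyr::bind_rows(base, dilv_all, any_l)
}
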