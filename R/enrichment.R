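#' Build an allele-based 2x2 case-control contingency table
#'
#' Counts variant versus reference alleles: each heterozygous case
#' contributes one variant allele, each homozygous case two, out of
#' `2 * n_cases` case alleles; control counts come from a population
#' database (variant allele count out of total alleles).
#'
#' @param case_zygosity Character vector of zygosity codes (`"het"`/`"hom"`)
#'   for the carrier cases (non-carriers are implied by `n_cases`).
#' @param n_cases Total number of cases.
#' @param control_ac Control variant allele count.
#' @param control_an Control total allele count.
#' @return An `allele_table`: named list with non-negative integer cells
#'   `a` (case variant alleles), `b` (case reference alleles), `c` (control
#'   variant alleles), `d` (control reference alleles).
#' @examples
#' # 10 carriers of whom 2 homozygous among 111 cases; 76/34,592 control alleles
#' build_allele_table(c(rep("het", 8), rep("hom", 2)), 111, 76, 34592)
#' @export
build_allele_table <- function(case_zygosity, n_cases, control_ac, control_an) {
  lc_assert(all(case_zygosity %in% c("het", "hom")),
            "`case_zygosity` values must be 'het' or 'hom'.")
  lc_assert(control_an >= control_ac && control_ac >= 0,
            "Control total alleles must be at least the variant allele count.")
  a <- sum(ifelse(case_zygosity == "hom", 2L, 1L))
  b <- 2L * as.integer(n_cases) - a
  c_ <- as.integer(control_ac)
  d <- as.integer(control_an) - c_
  if (b < 0 || d < 0) lc_abort("Derived cell count is negative.", "error_input")
  allele_table(a, b, c_, d)
}

#' Construct a 2x2 contingency table of allele counts
#'
#' @param a,b Case variant / reference allele counts.
#' @param c,d Control variant / reference allele counts.
#' @return An `allele_table` list.
#' @export
allele_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  lc_assert(all(cells >= 0) && all(cells == round(cells)),
            "Cells must be non-negative integers.")
  lc_assert(a + b > 0 && c + d > 0, "Each arm must have at least one allele.")
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  m <- matrix(unlist(x), 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("variant", "reference")))
  print(m)
  invisible(x)
}

#' Odds ratio with Wald 95% confidence interval
#'
#' `OR = ad / bc`. When any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied before both the estimate and the
#' interval. The interval is
#' `exp(ln OR +/- 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))` on the
#' (possibly corrected) cells.
#'
#' @param t An [allele_table()].
#' @return An `enrichment_result`: list with `or`, `ci_low`, `ci_high`,
#'   `se_log`, `p` (NA until [fisher_exact()] is folded in via
#'   [enrich()]), `correction_applied` and the input `table`.
#' @export
odds_ratio_wald <- function(t) {
  stopifnot(inherits(t, "allele_table"))
  z <- 1.959964
  cells <- unlist(t)
  correction <- any(cells == 0)
  if (correction) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  structure(
    list(or = unname(or),
         ci_low = unname(exp(log(or) - z * se)),
         ci_high = unname(exp(log(or) + z * se)),
         se_log = unname(se),
         p = NA_real_,
         correction_applied = correction,
         table = t),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("OR = %.1f (95%% CI %.1f-%.1f)", x$or, x$ci_low, x$ci_high))
  if (!is.na(x$p)) cat(sprintf(", Fisher p = %.3g", x$p))
  if (x$correction_applied) cat("  [Haldane-Anscombe corrected]")
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 allele table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's (with the
#' customary relative guard of 1 + 1e-7 against floating-point ties).
#' Always uses the uncorrected counts.
#'
#' @param t An [allele_table()].
#' @return A p-value in `(0, 1]`.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "allele_table"))
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  m <- a + b          # case alleles
  n <- c_ + d         # control alleles
  k <- a + c_         # variant alleles
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Allele-based case-control enrichment analysis
#'
#' Builds the allele table, computes the Wald odds ratio and confidence
#' interval, and attaches the Fisher exact p-value. The allele-based table
#' is the headline statistic; set `mode = "carrier"` for the clearly
#' labelled carrier-based variant (one count per carrier regardless of
#' zygosity, out of `n_cases` individuals per arm unit).
#'
#' @inheritParams build_allele_table
#' @param mode `"allele"` (default) or `"carrier"`.
#' @return An `enrichment_result` with `p` filled in and a `mode` element.
#' @examples
#' enrich(c(rep("het", 8), rep("hom", 2)), 111, 76, 34592)
#' @export
enrich <- function(case_zygosity, n_cases, control_ac, control_an,
                   mode = c("allele", "carrier")) {
  mode <- match.arg(mode)
  t <- if (mode == "allele") {
    build_allele_table(case_zygosity, n_cases, control_ac, control_an)
  } else {
    carriers <- length(case_zygosity)
    allele_table(carriers, n_cases - carriers, control_ac, control_an - control_ac)
  }
  res <- odds_ratio_wald(t)
  res$p <- fisher_exact(t)
  res$mode <- mode
  res
}

#' Expected variant alleles in a cohort at a given population frequency
#'
#' Under the control allele frequency `q`, a cohort of `n` diploid
#' individuals is expected to harbour `2 n q` variant alleles; used to
#' quantify how many carriers chance alone would produce.
#'
#' @param q Allele frequency in `[0, 1]`.
#' @param n_individuals Cohort size.
#' @return Expected number of variant alleles.
#' @examples
#' expected_variant_alleles(76 / 34592, 111)  # about 0.49
#' @export
expected_variant_alleles <- function(q, n_individuals) {
  lc_assert(q >= 0 && q <= 1 && n_individuals >= 0,
            "`q` must lie in [0, 1] and `n_individuals` must be non-negative.")
  2 * n_individuals * q
}
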