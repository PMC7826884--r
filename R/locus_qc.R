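# Marker quality control: Hardy-Weinberg exact testing, null-allele frequency
# estimation, and linkage-disequilibrium screening, with the locus filter used
# before any relatedness estimation.

# log conditional probability of a genotype table given its allele counts
# (Levene): P = n! 2^h prod(a_i!) / ((2n)! prod(n_ij!)). Only terms that vary
# across tables with fixed allele counts are needed for comparisons, but the
# full value is returned for the exhaustive-enumeration oracle.
log_table_prob <- function(genotype_counts, allele_counts) {
  n <- sum(genotype_counts)
  h <- sum(genotype_counts[!homozygous_key(names(genotype_counts))])
  lfactorial(n) + h * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(genotype_counts))
}

homozygous_key <- function(keys) {
  parts <- strsplit(keys, "/", fixed = TRUE)
  vapply(parts, function(p) p[1] == p[2], logical(1))
}

genotype_keys <- function(a1, a2) paste(a1, a2, sep = "/")

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium at one locus
#'
#' The exact test conditions on the observed allele counts: the 2n observed
#' alleles are shuffled into n diploid genotypes `n_mc` times, and the p-value
#' is the proportion of shuffles whose conditional genotype-table probability
#' (multivariate hypergeometric, Levene) is no larger than the observed
#' table's, with the add-one correction `(1 + #{P_sim <= P_obs}) / (n_mc + 1)`.
#'
#' @param G a [genotype_matrix()].
#' @param locus locus id.
#' @param n_mc number of Monte-Carlo shuffles (>= 1000).
#' @param seed integer seed for the shuffles.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(G, locus, n_mc = 10000, seed = 1L) {
  a1 <- G$a1[, locus]; a2 <- G$a2[, locus]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  alleles <- c(a1, a2)
  if (length(unique(alleles)) < 2L) {
    warning("monomorphic locus '", locus, "': HWE p defined as 1")
    return(1.0)
  }
  if (n < 5L) stop("fewer than 5 typed genotypes at locus ", locus)
  if (n_mc < 1000L) stop("n_mc must be >= 1000")
  # integer encoding: genotype (i <= j) -> (i-1)*k + j; the only parts of the
  # Levene log-probability that vary with the table (allele counts fixed) are
  # h*log(2) - sum(log(n_ij!))
  f <- factor(alleles)
  k <- nlevels(f)
  ai <- as.integer(f)
  i1 <- ai[seq_len(n)]; i2 <- ai[n + seq_len(n)]
  lf <- lfactorial(0:n)
  het_code <- as.vector(outer(seq_len(k), seq_len(k), `!=`))  # symmetric, so
  # column-major layout equals the (i-1)*k+j row-major genotype coding
  lp_var <- function(x1, x2) {
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    cnt <- tabulate((lo - 1L) * k + hi, nbins = k * k)
    nz <- cnt > 0L
    sum(cnt[nz & het_code]) * log(2) - sum(lf[cnt[nz] + 1L])
  }
  lp_obs <- lp_var(i1, i2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- 1e-9
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample.int(2L * n)
    s1 <- ai[perm[seq_len(n)]]
    s2 <- ai[perm[n + seq_len(n)]]
    if (lp_var(s1, s2) <= lp_obs + eps) hits <- hits + 1L
  }
  (1 + hits) / (n_mc + 1)
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Null-allele frequency estimates from heterozygosity
#'
#' Two closed-form moment estimators of the frequency of a non-amplifying
#' (null) allele from the observed heterozygote deficit: Chakraborty's
#' `r_C = (He - Ho) / (He + Ho)` and Brookfield's first estimator
#' `r_B = (He - Ho) / (1 + He)`. Negative values (heterozygote excess) are
#' reported as-is.
#'
#' @param Ho,He observed and expected heterozygosity in `[0, 1]`.
#' @return named numeric vector `c(r_C, r_B)`; if `He + Ho == 0` the
#'   Chakraborty estimator is undefined and reported as 0 with a warning.
#' @export
null_allele_estimates <- function(Ho, He) {
  stopifnot(Ho >= 0, Ho <= 1, He >= 0, He <= 1)
  if (He + Ho == 0) {
    warning("He + Ho = 0: Chakraborty estimator undefined, reported as 0")
    r_c <- 0
  } else {
    r_c <- (He - Ho) / (He + Ho)
  }
  c(r_C = r_c, r_B = (He - Ho) / (1 + He))
}

#' Genotypic linkage-disequilibrium permutation test for a locus pair
#'
#' Computes the log-likelihood-ratio statistic `G = 2 * sum(O * ln(O/E))` on
#' the two-locus genotype contingency table over individuals typed at both
#' loci, and builds the null by permuting one locus's genotypes across
#' individuals. `p = (1 + #{G_perm >= G_obs}) / (n_perm + 1)`.
#'
#' @param G a [genotype_matrix()].
#' @param locusA,locusB locus ids.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
ld_permutation_test <- function(G, locusA, locusB, n_perm = 2000, seed = 1L) {
  typed <- !is.na(G$a1[, locusA]) & !is.na(G$a1[, locusB])
  if (sum(typed) < 5L) {
    stop("fewer than 5 individuals typed at both ", locusA, " and ", locusB)
  }
  ga <- genotype_keys(G$a1[typed, locusA], G$a2[typed, locusA])
  gb <- genotype_keys(G$a1[typed, locusB], G$a2[typed, locusB])
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    warning("fewer than 2 distinct genotypes at ", locusA, " or ", locusB,
            ": LD p defined as 1")
    return(1.0)
  }
  fa <- factor(ga); fb <- factor(gb)
  ra <- nlevels(fa); rb <- nlevels(fb)
  ia <- as.integer(fa); ib <- as.integer(fb)
  # margins are permutation-invariant, so expected counts are fixed;
  # e is laid out to match the (a-1)*rb + b cell coding below
  e <- as.vector(outer(tabulate(ib, rb), tabulate(ia, ra))) / length(ia)
  g_from_counts <- function(cnt) {
    nz <- cnt > 0L
    2 * sum(cnt[nz] * log(cnt[nz] / e[nz]))
  }
  code <- function(a, b) (a - 1L) * rb + b
  g_obs <- g_from_counts(tabulate(code(ia, ib), ra * rb))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    cnt <- tabulate(code(ia, ib[sample.int(length(ib))]), ra * rb)
    if (g_from_counts(cnt) >= g_obs - 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

g_statistic <- function(tab) {
  o <- as.numeric(tab)
  e <- as.numeric(outer(rowSums(tab), colSums(tab))) / sum(tab)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Full marker quality-control report
#'
#' Runs the HWE exact test and null-allele estimators per locus and the LD
#' permutation test per locus pair, then applies [filter_loci()].
#'
#' @param G a [genotype_matrix()] (typically adults only).
#' @param alpha significance level for HWE and LD flags.
#' @param null_threshold null-allele frequency above which a locus is flagged
#'   (flag only, never auto-dropped).
#' @param n_mc Monte-Carlo shuffles for the HWE test.
#' @param n_perm permutations for each LD test.
#' @param seed integer seed.
#' @param bonferroni if `TRUE`, Bonferroni-correct alpha across loci (HWE) and
#'   pairs (LD); default applies raw alpha.
#' @return class `locus_qc_report`: list with `loci` (data.frame: locus, Ho,
#'   He, p_hwe, r_C, r_B, hwe_fail, null_fail), `pairs` (data.frame: locusA,
#'   locusB, p_ld, ld_fail), `retained` (character), and the thresholds used.
#' @export
locus_qc <- function(G, alpha = 0.05, null_threshold = 0.20,
                     n_mc = 10000, n_perm = 2000, seed = 1L,
                     bonferroni = FALSE) {
  freqs <- allele_frequencies(G)
  het <- locus_heterozygosity(G, freqs)
  n_loci <- length(G$loci)
  alpha_hwe <- if (bonferroni) alpha / n_loci else alpha
  p_hwe <- vapply(seq_along(G$loci), function(i) {
    suppressWarnings(hwe_exact_test(G, G$loci[i], n_mc = n_mc, seed = seed + i))
  }, numeric(1))
  nulls <- t(vapply(seq_len(nrow(het)), function(i) {
    suppressWarnings(null_allele_estimates(het$Ho[i], het$He[i]))
  }, numeric(2)))
  loci_df <- data.frame(
    locus = het$locus, Ho = het$Ho, He = het$He, p_hwe = p_hwe,
    r_C = nulls[, "r_C"], r_B = nulls[, "r_B"],
    hwe_fail = p_hwe < alpha_hwe,
    null_fail = pmax(nulls[, "r_C"], nulls[, "r_B"]) >= null_threshold,
    stringsAsFactors = FALSE
  )
  prs <- if (n_loci >= 2) t(utils::combn(G$loci, 2)) else
    matrix(character(), 0, 2)
  alpha_ld <- if (bonferroni && nrow(prs)) alpha / nrow(prs) else alpha
  p_ld <- vapply(seq_len(nrow(prs)), function(i) {
    suppressWarnings(ld_permutation_test(G, prs[i, 1], prs[i, 2],
                                         n_perm = n_perm, seed = seed + 1000L + i))
  }, numeric(1))
  pairs_df <- data.frame(locusA = prs[, 1], locusB = prs[, 2], p_ld = p_ld,
                         ld_fail = p_ld < alpha_ld, stringsAsFactors = FALSE)
  report <- structure(
    list(loci = loci_df, pairs = pairs_df, retained = character(),
         alpha = alpha, alpha_hwe = alpha_hwe, alpha_ld = alpha_ld,
         null_threshold = null_threshold, seed = seed),
    class = "locus_qc_report")
  report$retained <- filter_loci(G, report, alpha = alpha,
                                 null_threshold = null_threshold)
  report
}

#' @export
print.locus_qc_report <- function(x, ...) {
  cat(sprintf("locus_qc_report: %d loci, %d retained (alpha = %g, null threshold = %g)\n",
              nrow(x$loci), length(x$retained), x$alpha, x$null_threshold))
  print(x$loci, digits = 3)
  dropped <- setdiff(x$loci$locus, x$retained)
  if (length(dropped)) cat("dropped:", paste(dropped, collapse = ", "), "\n")
  flagged <- x$loci$locus[x$loci$null_fail]
  if (length(flagged)) {
    cat("null-allele flag (reported, not dropped):",
        paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply the exclusion rules to a QC report
#'
#' Drops loci whose HWE p-value falls below `alpha`; then resolves significant
#' LD pairs greedily, repeatedly dropping the locus involved in the most
#' significant pairs (ties broken lexicographically) until no significant pair
#' remains among retained loci. Loci with `max(r_C, r_B) >= null_threshold`
#' are flagged in the report but never auto-dropped.
#'
#' @param G a [genotype_matrix()].
#' @param report a [locus_qc()] report covering `G`'s loci.
#' @param alpha significance level.
#' @param null_threshold flag threshold for null-allele frequency.
#' @return character vector of retained locus ids.
#' @export
filter_loci <- function(G, report, alpha = 0.05, null_threshold = 0.20) {
  loci <- report$loci
  alpha_hwe <- if (!is.null(report$alpha_hwe)) report$alpha_hwe else alpha
  alpha_ld <- if (!is.null(report$alpha_ld)) report$alpha_ld else alpha
  retained <- loci$locus[loci$p_hwe >= alpha_hwe]
  pairs <- report$pairs
  repeat {
    act <- pairs$locusA %in% retained & pairs$locusB %in% retained &
      pairs$p_ld < alpha_ld
    if (!any(act)) break
    counts <- table(c(pairs$locusA[act], pairs$locusB[act]))
    worst <- sort(names(counts)[counts == max(counts)])[1]
    retained <- setdiff(retained, worst)
  }
  if (!length(retained)) stop("no locus survives quality control")
  sort(retained)
}

#' Write a QC report as TSV (per-locus table) and JSON
#'
#' @param report a [locus_qc()] report.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_qc_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$loci, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(loci = report$loci, pairs = report$pairs,
           retained = report$retained, alpha = report$alpha,
           null_threshold = report$null_threshold, seed = report$seed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
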