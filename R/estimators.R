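# Moment estimators of pairwise relatedness and individual inbreeding
# (Ritland 1996) and Amos-style standardized multilocus heterozygosity.
#
# Per locus with n_l alleles and reference frequencies p_i:
#   relatedness  r_l = (2/(n_l - 1)) * (sum_i P_xi * P_yi / p_i - 1)
#   inbreeding   F_l = (1/(n_l - 1)) * (sum_i d_i / p_i - 1)
# where P_xi in {0, 1/2, 1} is x's dosage of allele i and d_i indicates
# homozygosity for allele i. Multilocus values are weighted means with
# information weights w_l = n_l - 1.

# dosage list for one individual at one locus: named c(allele = dosage)
.dosage <- function(a1, a2) {
  if (a1 == a2) stats::setNames(1, a1) else stats::setNames(c(0.5, 0.5), c(a1, a2))
}

.check_freqs <- function(d, p, locus) {
  miss <- setdiff(names(d), names(p))
  if (length(miss)) {
    stop("allele(s) ", paste(miss, collapse = ","), " at locus ", locus,
         " have no reference frequency; frequencies must derive from a sample",
         " containing both individuals")
  }
}

#' Ritland pairwise relatedness for one dyad
#'
#' Moment estimator of the relatedness coefficient between two diploid
#' individuals given reference allele frequencies. Per-locus estimates are
#' combined with information weights `n_l - 1`; loci missing in either
#' individual are excluded. The estimator is unbiased (expectation 0 for
#' unrelated, 0.25 for half sibs, 0.5 for full sibs and parent-offspring) but
#' individual values can fall outside `[-1, 1]`.
#'
#' @param gx,gy genotypes: named lists with `a1`, `a2` character vectors named
#'   by locus, or single rows of a [genotype_matrix()] extracted with
#'   [genotype_row()].
#' @param freqs an [allele_frequencies()] table containing every observed
#'   allele (with all `p_i > 0`).
#' @return list with `r` (numeric) and `n_loci_used`.
#' @export
ritland_r <- function(gx, gy, freqs) {
  loci <- intersect(names(gx$a1)[!is.na(gx$a1)], names(gy$a1)[!is.na(gy$a1)])
  loci <- intersect(loci, names(freqs))
  if (!length(loci)) stop("no locus typed in both individuals")
  num <- 0; den <- 0
  for (l in loci) {
    p <- freqs[[l]]$freqs
    nl <- length(p)
    if (nl < 2L) next  # monomorphic locus carries no information (weight 0)
    dx <- .dosage(gx$a1[[l]], gx$a2[[l]])
    dy <- .dosage(gy$a1[[l]], gy$a2[[l]])
    .check_freqs(dx, p, l); .check_freqs(dy, p, l)
    shared <- intersect(names(dx), names(dy))
    s <- if (length(shared)) sum(dx[shared] * dy[shared] / p[shared]) else 0
    r_l <- (2 / (nl - 1)) * (s - 1)
    w <- nl - 1
    num <- num + w * r_l
    den <- den + w
  }
  if (den == 0) stop("no polymorphic locus typed in both individuals")
  list(r = num / den, n_loci_used = length(loci))
}

#' Ritland individual inbreeding coefficient
#'
#' Moment estimator of F for one diploid individual: per locus
#' `F_l = (sum_i d_i / p_i - 1) / (n_l - 1)` with `d_i` the indicator of
#' homozygosity for allele i, combined across loci with weights `n_l - 1`.
#' A heterozygote at a 2-allele locus scores -1, a homozygote for an allele at
#' frequency 0.5 scores +1; the expectation over a population with inbreeding
#' coefficient F is F.
#'
#' @param g genotype (as in [ritland_r()]).
#' @param freqs an [allele_frequencies()] table.
#' @return list with `F` and `n_loci_used`.
#' @export
ritland_f <- function(g, freqs) {
  loci <- intersect(names(g$a1)[!is.na(g$a1)], names(freqs))
  if (!length(loci)) stop("no typed locus")
  num <- 0; den <- 0
  for (l in loci) {
    p <- freqs[[l]]$freqs
    nl <- length(p)
    if (nl < 2L) next
    d <- .dosage(g$a1[[l]], g$a2[[l]])
    .check_freqs(d, p, l)
    s <- if (g$a1[[l]] == g$a2[[l]]) 1 / p[[g$a1[[l]]]] else 0
    f_l <- (s - 1) / (nl - 1)
    w <- nl - 1
    num <- num + w * f_l
    den <- den + w
  }
  if (den == 0) stop("no polymorphic typed locus")
  list(F = num / den, n_loci_used = length(loci))
}

#' Standardized multilocus heterozygosity
#'
#' An individual's proportion of heterozygous typed loci divided by the mean
#' population observed heterozygosity of exactly those loci. An individual
#' typed at loci of population-average heterozygosity scores about 1;
#' standardization removes the bias introduced when individuals are typed at
#' different locus subsets.
#'
#' @param g genotype (as in [ritland_r()]).
#' @param population_locus_Ho named numeric vector of population observed
#'   heterozygosity per locus (e.g. the `Ho` column of
#'   [locus_heterozygosity()]).
#' @return list with `Hs` (>= 0) and `n_loci_typed`.
#' @export
standardized_heterozygosity <- function(g, population_locus_Ho) {
  loci <- names(g$a1)[!is.na(g$a1)]
  if (!length(loci)) stop("no typed locus")
  missing_ho <- setdiff(loci, names(population_locus_Ho))
  if (length(missing_ho)) {
    stop("no population Ho for locus/loci: ", paste(missing_ho, collapse = ", "))
  }
  mean_ho <- mean(population_locus_Ho[loci])
  if (mean_ho == 0) stop("mean population Ho of the typed loci is 0")
  prop_het <- mean(g$a1[loci] != g$a2[loci])
  list(Hs = prop_het / mean_ho, n_loci_typed = length(loci))
}

#' Extract one individual's genotype from a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param id individual id.
#' @return list with named vectors `a1`, `a2` (names = loci).
#' @export
genotype_row <- function(G, id) {
  list(a1 = stats::setNames(G$a1[id, ], G$loci),
       a2 = stats::setNames(G$a2[id, ], G$loci))
}

#' Pairwise Ritland relatedness matrix
#'
#' Vectorized computation of the Ritland relatedness estimate for every
#' (row id, column id) combination. Missing calls are handled per dyad: a
#' locus enters a dyad's weighted mean only when typed in both members.
#'
#' @param G a [genotype_matrix()] containing all ids.
#' @param freqs reference [allele_frequencies()].
#' @param ids_row,ids_col character vectors of ids (default: all).
#' @return numeric matrix `length(ids_row)` x `length(ids_col)`.
#' @export
relatedness_matrix <- function(G, freqs, ids_row = G$ids, ids_col = G$ids) {
  ids <- union(ids_row, ids_col)
  num <- matrix(0, length(ids_row), length(ids_col),
                dimnames = list(ids_row, ids_col))
  den <- num
  for (l in G$loci) {
    p <- freqs[[l]]$freqs
    nl <- length(p)
    if (nl < 2L) next
    # dosage matrix D: individuals x alleles, rows of untyped ids are NA
    a1 <- G$a1[ids, l]; a2 <- G$a2[ids, l]
    typed <- !is.na(a1)
    bad <- setdiff(unique(c(a1[typed], a2[typed])), names(p))
    if (length(bad)) {
      stop("allele(s) ", paste(bad, collapse = ","), " at locus ", l,
           " have no reference frequency")
    }
    D <- matrix(0, length(ids), nl, dimnames = list(ids, names(p)))
    idx <- which(typed)
    D[cbind(idx, match(a1[typed], names(p)))] <-
      D[cbind(idx, match(a1[typed], names(p)))] + 0.5
    D[cbind(idx, match(a2[typed], names(p)))] <-
      D[cbind(idx, match(a2[typed], names(p)))] + 0.5
    S <- (D[ids_row, , drop = FALSE] %*% (t(D[ids_col, , drop = FALSE]) / p))
    r_l <- (2 / (nl - 1)) * (S - 1)
    ok <- outer(typed[match(ids_row, ids)], typed[match(ids_col, ids)], `&`)
    w <- nl - 1
    num[ok] <- num[ok] + w * r_l[ok]
    den[ok] <- den[ok] + w
  }
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1, ]
    stop("no shared polymorphic typed locus for dyad ",
         ids_row[bad[1]], " x ", ids_col[bad[2]])
  }
  num / den
}

#' Ritland relatedness for paired dyads (vectorized)
#'
#' Computes the Ritland estimate for dyad i = (row i of `gx`, row i of `gy`)
#' for all i at once; the workhorse behind large simulation checks.
#'
#' @param gx,gy [genotype_matrix()]s with equal row counts and identical loci.
#' @param freqs reference [allele_frequencies()].
#' @return numeric vector of length `nrow`.
#' @export
relatedness_dyads <- function(gx, gy, freqs) {
  stopifnot(identical(gx$loci, gy$loci), length(gx$ids) == length(gy$ids))
  n <- length(gx$ids)
  num <- numeric(n); den <- numeric(n)
  for (l in gx$loci) {
    p <- freqs[[l]]$freqs
    nl <- length(p)
    if (nl < 2L) next
    Dx <- .dosage_matrix(gx$a1[, l], gx$a2[, l], names(p), l)
    Dy <- .dosage_matrix(gy$a1[, l], gy$a2[, l], names(p), l)
    typed <- !is.na(gx$a1[, l]) & !is.na(gy$a1[, l])
    S <- rowSums(Dx * sweep(Dy, 2, p, `/`))
    num[typed] <- num[typed] + 2 * (S[typed] - 1)
    den[typed] <- den[typed] + (nl - 1)
  }
  if (any(den == 0)) stop("dyad(s) without a shared polymorphic typed locus")
  num / den
}

# dosage matrix (n x alleles) for one locus; untyped rows are all-zero
.dosage_matrix <- function(a1, a2, allele_labels, locus) {
  typed <- !is.na(a1)
  bad <- setdiff(unique(c(a1[typed], a2[typed])), allele_labels)
  if (length(bad)) {
    stop("allele(s) ", paste(bad, collapse = ","), " at locus ", locus,
         " have no reference frequency")
  }
  D <- matrix(0, length(a1), length(allele_labels),
              dimnames = list(NULL, allele_labels))
  idx <- which(typed)
  D[cbind(idx, match(a1[typed], allele_labels))] <-
    D[cbind(idx, match(a1[typed], allele_labels))] + 0.5
  D[cbind(idx, match(a2[typed], allele_labels))] <-
    D[cbind(idx, match(a2[typed], allele_labels))] + 0.5
  D
}

#' Ritland inbreeding coefficients for all individuals (vectorized)
#'
#' @param G a [genotype_matrix()].
#' @param freqs reference [allele_frequencies()].
#' @return named numeric vector of F, one per individual.
#' @export
inbreeding_coefficients <- function(G, freqs) {
  n <- length(G$ids)
  num <- numeric(n); den <- numeric(n)
  for (l in G$loci) {
    p <- freqs[[l]]$freqs
    nl <- length(p)
    if (nl < 2L) next
    a1 <- G$a1[, l]; a2 <- G$a2[, l]
    typed <- !is.na(a1)
    bad <- setdiff(unique(c(a1[typed], a2[typed])), names(p))
    if (length(bad)) {
      stop("allele(s) ", paste(bad, collapse = ","), " at locus ", l,
           " have no reference frequency")
    }
    s <- numeric(n)
    hom <- typed & a1 == a2
    s[hom] <- 1 / p[a1[hom]]
    num[typed] <- num[typed] + (s[typed] - 1)
    den[typed] <- den[typed] + (nl - 1)
  }
  if (any(den == 0)) stop("individual(s) without a polymorphic typed locus")
  stats::setNames(num / den, G$ids)
}

#' Standardized heterozygosity for all individuals (vectorized)
#'
#' @param G a [genotype_matrix()].
#' @param population_locus_Ho named numeric vector of per-locus population Ho.
#' @return named numeric vector of Hs.
#' @export
standardized_heterozygosities <- function(G, population_locus_Ho) {
  ho <- population_locus_Ho[G$loci]
  if (anyNA(ho)) stop("population Ho missing for some loci")
  typed <- !is.na(G$a1)
  het <- typed & (G$a1 != G$a2)
  n_typed <- rowSums(typed)
  mean_ho <- as.vector(typed %*% ho) / n_typed
  if (any(mean_ho == 0)) stop("mean population Ho of typed loci is 0")
  stats::setNames((rowSums(het) / n_typed) / mean_ho, G$ids)
}

#' Genetic scores for a breeding population
#'
#' Applies the three estimators with the reference sets used in the analysis:
#' pairwise relatedness uses allele frequencies from paired adults only, while
#' individual F and Hs use frequencies and population Ho from all genotyped
#' birds (adults and offspring).
#'
#' @param G a [genotype_matrix()] of all genotyped birds.
#' @param pairs data.frame with columns `female_id`, `male_id` and optionally
#'   `year`; all ids must be present in `G`.
#' @param adult_ids ids forming the adult reference set for relatedness
#'   (default: all ids appearing in `pairs`).
#' @return list with `dyads` (data.frame: female_id, male_id, year, r,
#'   n_loci_used) and `individuals` (data.frame: individual_id, F, Hs,
#'   n_loci_typed), plus `meta` recording estimator and reference sets.
#' @export
score_population <- function(G, pairs,
                             adult_ids = unique(c(pairs$female_id, pairs$male_id))) {
  unknown <- setdiff(c(pairs$female_id, pairs$male_id), G$ids)
  if (length(unknown)) {
    stop("pairs reference unknown individuals: ", paste(unknown, collapse = ", "))
  }
  G_adults <- G[adult_ids, ]
  freqs_adults <- allele_frequencies(G_adults)
  freqs_all <- allele_frequencies(G)
  ho_all <- stats::setNames(locus_heterozygosity(G, freqs_all)$Ho, G$loci)

  rmat <- relatedness_matrix(G, freqs_adults,
                             ids_row = unique(pairs$female_id),
                             ids_col = unique(pairs$male_id))
  shared <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(!is.na(G$a1[pairs$female_id[i], ]) & !is.na(G$a1[pairs$male_id[i], ]))
  }, numeric(1))
  dyads <- data.frame(
    female_id = pairs$female_id, male_id = pairs$male_id,
    year = if ("year" %in% names(pairs)) pairs$year else NA,
    r = rmat[cbind(pairs$female_id, pairs$male_id)],
    n_loci_used = shared, stringsAsFactors = FALSE)

  individuals <- data.frame(
    individual_id = G$ids,
    F = unname(inbreeding_coefficients(G, freqs_all)),
    Hs = unname(standardized_heterozygosities(G, ho_all)),
    n_loci_typed = rowSums(!is.na(G$a1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(dyads = dyads, individuals = individuals,
       meta = list(estimator = "Ritland (1996) moment estimator",
                   r_reference = "paired adults",
                   f_hs_reference = "all genotyped birds",
                   loci = G$loci))
}

#' Write population scores as TSV with a metadata header
#'
#' @param scores output of [score_population()].
#' @param dyad_path,individual_path output paths.
#' @return invisibly, `scores`.
#' @export
write_scores <- function(scores, dyad_path, individual_path) {
  hdr <- sprintf("# estimator: %s | r reference: %s | F/Hs reference: %s | loci: %s",
                 scores$meta$estimator, scores$meta$r_reference,
                 scores$meta$f_hs_reference,
                 paste(scores$meta$loci, collapse = ","))
  for (spec in list(list(scores$dyads, dyad_path),
                    list(scores$individuals, individual_path))) {
    con <- file(spec[[2]], "w")
    writeLines(hdr, con)
    utils::write.table(spec[[1]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(scores)
}
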