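# Synthetic populations with the statistical structure the analysis assumes:
# Dirichlet allele frequencies, HWE founders, Mendelian gene-dropping,
# trait-dependent double-breeding labels from a logistic model, and the two
# observation artefacts of microsatellite data (missing calls and segregating
# null alleles that mask heterozygotes as homozygotes).

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is designed for: 8
#' polymorphic microsatellite loci, three breeding years with 29/23/21 pairs,
#' a ~30% double-breeding incidence, and double-breeding odds increasing with
#' male breast-stripe width and standardized heterozygosity and decreasing
#' with pair relatedness. Trait means/SDs are calibrated to published great
#' tit summaries (stripe ~ N(9.9, 1.8) mm, tarsus ~ N(21.5, 1.3) mm,
#' repertoire ~ N(3.7, 1.1) rounded to integers >= 1, first-egg date ~
#' N(19.5, 5.5) days with April 1 = day 1, first broods of ~11.7 and second
#' broods of ~8.0 nestlings).
#'
#' @param seed mandatory integer seed.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param dirichlet_concentration concentration of the Dirichlet prior on
#'   allele frequencies (1 = uniform on the simplex).
#' @param years named integer vector of pairs per breeding year.
#' @param target_db_fraction target double-breeding incidence; the logistic
#'   intercept is centred so the population mean probability matches it.
#' @param beta named numeric vector `c(stripe=, Hs=, r=)` of logistic effect
#'   sizes on double breeding (logit scale per unit of each covariate).
#' @param beta0 logistic intercept; `NA` (default) centres it from
#'   `target_db_fraction` at the realized covariate means.
#' @param traits list of `c(mean, sd)` pairs for `stripe`, `tarsus`,
#'   `repertoire`, `first_egg`, `female_tarsus`.
#' @param brood1_size,brood2_size `c(mean, sd)` of first/second brood
#'   offspring counts (rounded, floor 1).
#' @param missing_rate per-call missing-data probability.
#' @param null_allele_rate frequency of a segregating null (non-amplifying)
#'   allele per locus; heterozygote visible/null is observed as a visible
#'   homozygote, null/null as missing.
#' @param founder_f founder inbreeding coefficient (probability the two
#'   alleles of a founder are identical by descent).
#' @return class `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_loci = 8L,
                       alleles_per_locus = 6L,
                       dirichlet_concentration = 1.0,
                       years = c("2014" = 29L, "2015" = 23L, "2016" = 21L),
                       target_db_fraction = 0.30,
                       beta = c(stripe = 1.4, Hs = 9, r = -28),
                       beta0 = NA_real_,
                       traits = list(stripe = c(9.9, 1.8),
                                     tarsus = c(21.5, 1.3),
                                     repertoire = c(3.7, 1.1),
                                     first_egg = c(19.5, 5.5),
                                     female_tarsus = c(21.3, 1.0)),
                       brood1_size = c(11.7, 1.6),
                       brood2_size = c(8.0, 1.5),
                       missing_rate = 0.02,
                       null_allele_rate = 0,
                       founder_f = 0) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_loci >= 1, alleles_per_locus >= 2, all(years >= 1),
            target_db_fraction > 0, target_db_fraction < 1,
            missing_rate >= 0, missing_rate < 1,
            null_allele_rate >= 0, null_allele_rate < 0.5,
            founder_f >= 0, founder_f <= 1)
  if (!all(c("stripe", "Hs", "r") %in% names(beta))) {
    stop("beta must name stripe, Hs and r effects")
  }
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 dirichlet_concentration = dirichlet_concentration,
                 years = years, target_db_fraction = target_db_fraction,
                 beta = beta, beta0 = beta0, traits = traits,
                 brood1_size = brood1_size, brood2_size = brood2_size,
                 missing_rate = missing_rate,
                 null_allele_rate = null_allele_rate,
                 founder_f = founder_f),
            class = "sim_config")
}

NULL_ALLELE <- "99"

# Dirichlet allele frequencies per locus; visible alleles "01", "02", ...;
# a null allele NULL_ALLELE at the configured frequency is appended.
.sim_freqs <- function(config) {
  k <- config$alleles_per_locus
  labs <- sprintf("%02d", seq_len(k))
  lapply(seq_len(config$n_loci), function(l) {
    g <- stats::rgamma(k, shape = config$dirichlet_concentration)
    p <- g / sum(g)
    if (config$null_allele_rate > 0) {
      p <- c(p * (1 - config$null_allele_rate), config$null_allele_rate)
      names(p) <- c(labs, NULL_ALLELE)
    } else {
      names(p) <- labs
    }
    p
  })
}

# n HWE genotypes at one locus; founder_f induces identity by descent
.sim_locus_genotypes <- function(n, p, founder_f = 0) {
  labs <- names(p)
  a1 <- labs[sample.int(length(p), n, replace = TRUE, prob = p)]
  a2 <- labs[sample.int(length(p), n, replace = TRUE, prob = p)]
  if (founder_f > 0) {
    ibd <- stats::runif(n) < founder_f
    a2[ibd] <- a1[ibd]
  }
  cbind(a1, a2)
}

#' Simulate unrelated founders under Hardy-Weinberg equilibrium
#'
#' @param config a [sim_config()].
#' @param n number of founders.
#' @param ids optional ids (default `IND_1..n`).
#' @return list with `G` (a fully typed, truth-level [genotype_matrix()];
#'   observation artefacts are not applied here), `freqs` (the generating
#'   per-locus frequency vectors) and `loci`.
#' @export
simulate_founders <- function(config, n, ids = sprintf("IND_%d", seq_len(n))) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  freqs <- .sim_freqs(config)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  a1 <- matrix(NA_character_, n, config$n_loci, dimnames = list(ids, loci))
  a2 <- a1
  for (l in seq_len(config$n_loci)) {
    g <- .sim_locus_genotypes(n, freqs[[l]], config$founder_f)
    a1[, l] <- g[, 1]; a2[, l] <- g[, 2]
  }
  names(freqs) <- loci
  list(G = genotype_matrix(ids, loci, a1, a2), freqs = freqs, loci = loci)
}

# one Mendelian pick per row from two parental allele columns
.mendel_pick <- function(p1, p2) {
  take1 <- stats::runif(length(p1)) < 0.5
  ifelse(take1, p1, p2)
}

#' Simulate dyads of known relationship by gene dropping
#'
#' Generates `n` dyads per call by Mendelian transmission from shared
#' ancestors: `unrelated` (expected kinship r = 0), `half_sib` (0.25),
#' `full_sib` (0.5), `parent_offspring` (0.5). Used as the simulation oracle
#' for the relatedness estimators.
#'
#' @param config a [sim_config()].
#' @param relationship one of `"unrelated"`, `"half_sib"`, `"full_sib"`,
#'   `"parent_offspring"`.
#' @param n number of dyads.
#' @return list with `gx`, `gy` (truth-level [genotype_matrix()]s, row i of
#'   each = dyad i), `freqs`, `expected_r`.
#' @export
simulate_dyads <- function(config, relationship, n) {
  relationship <- match.arg(relationship,
                            c("unrelated", "half_sib", "full_sib",
                              "parent_offspring"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  freqs <- .sim_freqs(config)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  names(freqs) <- loci
  ids_x <- sprintf("X_%d", seq_len(n)); ids_y <- sprintf("Y_%d", seq_len(n))
  x1 <- matrix(NA_character_, n, length(loci), dimnames = list(ids_x, loci))
  x2 <- x1
  y1 <- matrix(NA_character_, n, length(loci), dimnames = list(ids_y, loci))
  y2 <- y1
  for (l in seq_along(loci)) {
    p <- freqs[[l]]
    draw <- function() .sim_locus_genotypes(n, p)
    if (relationship == "unrelated") {
      gx <- draw(); gy <- draw()
    } else if (relationship == "parent_offspring") {
      gx <- draw()  # parent
      mate <- draw()
      gy <- cbind(.mendel_pick(gx[, 1], gx[, 2]),
                  .mendel_pick(mate[, 1], mate[, 2]))
    } else if (relationship == "full_sib") {
      pa <- draw(); pb <- draw()
      gx <- cbind(.mendel_pick(pa[, 1], pa[, 2]), .mendel_pick(pb[, 1], pb[, 2]))
      gy <- cbind(.mendel_pick(pa[, 1], pa[, 2]), .mendel_pick(pb[, 1], pb[, 2]))
    } else {  # half_sib: one shared parent
      shared <- draw(); pa <- draw(); pb <- draw()
      gx <- cbind(.mendel_pick(shared[, 1], shared[, 2]),
                  .mendel_pick(pa[, 1], pa[, 2]))
      gy <- cbind(.mendel_pick(shared[, 1], shared[, 2]),
                  .mendel_pick(pb[, 1], pb[, 2]))
    }
    x1[, l] <- gx[, 1]; x2[, l] <- gx[, 2]
    y1[, l] <- gy[, 1]; y2[, l] <- gy[, 2]
  }
  list(gx = genotype_matrix(ids_x, loci, x1, x2),
       gy = genotype_matrix(ids_y, loci, y1, y2),
       freqs = freqs,
       expected_r = switch(relationship, unrelated = 0, half_sib = 0.25,
                           full_sib = 0.5, parent_offspring = 0.5))
}

# observation model: null-allele masking then missing calls
.observe <- function(a1, a2, missing_rate) {
  both_null <- a1 == NULL_ALLELE & a2 == NULL_ALLELE
  one_null_1 <- a1 == NULL_ALLELE & !both_null
  one_null_2 <- a2 == NULL_ALLELE & !both_null
  a1[one_null_1] <- a2[one_null_1]  # false homozygote for the visible allele
  a2[one_null_2] <- a1[one_null_2]
  a1[both_null] <- NA_character_
  a2[both_null] <- NA_character_
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(a1)) < missing_rate, nrow = nrow(a1))
    a1[drop] <- NA_character_
    a2[drop] <- NA_character_
  }
  # every individual keeps >= 1 typed locus: restore the first masked-by-
  # missingness locus where an individual lost all calls
  gone <- rowSums(!is.na(a1)) == 0
  list(a1 = a1, a2 = a2, all_missing = gone)
}

#' Simulate a full breeding population
#'
#' Builds, per year, the configured number of socially monogamous pairs from
#' unrelated HWE founders; draws male traits; computes each pair's true
#' relatedness and each male's standardized heterozygosity from the true
#' genotypes and generating frequencies; assigns double-breeding labels from
#' the logistic model `P(double) = plogis(beta0 + b_s*stripe + b_h*Hs +
#' b_r*r)`; generates Mendelian first-brood (and, for double breeders,
#' second-brood) offspring; and finally applies the observation model
#' (null-allele masking, missing calls) to produce the analysis-ready
#' genotype matrix.
#'
#' @param config a [sim_config()].
#' @return class `synthetic_dataset`: list with `genotypes` (observed
#'   [genotype_matrix()], adults + offspring), `genotypes_true`, `records`
#'   (breeding-record data.frame: year, female_id, male_id, double,
#'   first_egg, stripe, tarsus, repertoire, female_tarsus, offspring_first,
#'   offspring_total), `pedigree` (offspring_id, mother, father, brood),
#'   `truth` (generating parameters, true r/Hs/F inputs, achieved fraction),
#'   and `config`.
#' @export
simulate_breeding_population <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  freqs <- .sim_freqs(config)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  names(freqs) <- loci
  years <- names(config$years)

  fem_ids <- unlist(lapply(years, function(y) {
    sprintf("F%s_%02d", y, seq_len(config$years[[y]]))
  }))
  male_ids <- unlist(lapply(years, function(y) {
    sprintf("M%s_%02d", y, seq_len(config$years[[y]]))
  }))
  year_of_pair <- rep(years, times = config$years)
  n_pairs <- length(fem_ids)
  adults <- c(fem_ids, male_ids)

  a1 <- matrix(NA_character_, length(adults), length(loci),
               dimnames = list(adults, loci))
  a2 <- a1
  for (l in seq_along(loci)) {
    g <- .sim_locus_genotypes(length(adults), freqs[[l]], config$founder_f)
    a1[, l] <- g[, 1]; a2[, l] <- g[, 2]
  }

  # traits
  rn <- function(par, n) stats::rnorm(n, par[1], par[2])
  stripe <- rn(config$traits$stripe, n_pairs)
  tarsus <- rn(config$traits$tarsus, n_pairs)
  repertoire <- pmax(1, round(rn(config$traits$repertoire, n_pairs)))
  female_tarsus <- rn(config$traits$female_tarsus, n_pairs)
  first_egg <- pmax(1, round(rn(config$traits$first_egg, n_pairs)))

  # true genetic covariates from true genotypes + generating frequencies
  freq_table <- lapply(freqs, function(p) {
    list(freqs = p, n_alleles = length(p), n_typed = NA_integer_)
  })
  class(freq_table) <- "allele_frequency_table"
  G_true_adults <- genotype_matrix(adults, loci, a1, a2)
  r_true <- relatedness_matrix(G_true_adults, freq_table,
                               ids_row = fem_ids,
                               ids_col = male_ids)[cbind(fem_ids, male_ids)]
  ho_true <- stats::setNames(locus_heterozygosity(G_true_adults,
                                                  allele_frequencies(G_true_adults))$Ho,
                             loci)
  male_het <- rowMeans(a1[male_ids, , drop = FALSE] != a2[male_ids, , drop = FALSE])
  hs_true <- male_het / mean(ho_true)

  # double-breeding labels from the logistic model
  b <- config$beta
  lin_slope <- b[["stripe"]] * stripe + b[["Hs"]] * hs_true + b[["r"]] * r_true
  beta0 <- config$beta0
  if (is.na(beta0)) {
    # centre the intercept so the realized mean double-breeding probability
    # equals the target incidence (Jensen correction over the covariate
    # distribution, solved numerically)
    beta0 <- stats::uniroot(function(b0) {
      mean(stats::plogis(b0 + lin_slope)) - config$target_db_fraction
    }, lower = -50 - max(lin_slope), upper = 50 - min(lin_slope))$root
  }
  p_db <- stats::plogis(beta0 + lin_slope)
  double <- as.integer(stats::runif(n_pairs) < p_db)
  achieved <- mean(double)
  # flag infeasible targets, not binomial sampling noise: the label draw
  # alone has SD sqrt(t(1-t)/n) even when the intercept is centred exactly
  t_db <- config$target_db_fraction
  tol <- max(0.15, 4 * sqrt(t_db * (1 - t_db) / n_pairs))
  if (abs(achieved - t_db) > tol) {
    warning(sprintf("achieved double-breeding fraction %.3f far from target %.3f",
                    achieved, t_db))
  }

  # Mendelian offspring
  brood_n1 <- pmax(1, round(rn(config$brood1_size, n_pairs)))
  brood_n2 <- ifelse(double == 1, pmax(1, round(rn(config$brood2_size, n_pairs))), 0)
  ped <- list(); off1 <- list(); off2 <- list()
  for (i in seq_len(n_pairs)) {
    n_off <- brood_n1[i] + brood_n2[i]
    oid <- sprintf("O_%s_%02d", male_ids[i], seq_len(n_off))
    brood <- rep(c(1L, 2L), times = c(brood_n1[i], brood_n2[i]))
    o1 <- matrix(NA_character_, n_off, length(loci), dimnames = list(oid, loci))
    o2 <- o1
    for (l in seq_along(loci)) {
      o1[, l] <- .mendel_pick(rep(a1[fem_ids[i], l], n_off),
                              rep(a2[fem_ids[i], l], n_off))
      o2[, l] <- .mendel_pick(rep(a1[male_ids[i], l], n_off),
                              rep(a2[male_ids[i], l], n_off))
    }
    ped[[i]] <- data.frame(offspring_id = oid, mother = fem_ids[i],
                           father = male_ids[i], brood = brood,
                           stringsAsFactors = FALSE)
    off1[[i]] <- o1; off2[[i]] <- o2
  }
  pedigree <- do.call(rbind, ped)
  O1 <- do.call(rbind, off1); O2 <- do.call(rbind, off2)

  all_ids <- c(adults, pedigree$offspring_id)
  A1 <- rbind(a1, O1); A2 <- rbind(a2, O2)
  roles <- c(rep("adult_female", n_pairs), rep("adult_male", n_pairs),
             rep("offspring", nrow(pedigree)))
  G_true <- genotype_matrix(all_ids, loci, A1, A2, groups = roles)

  obs <- .observe(A1, A2, config$missing_rate)
  if (any(obs$all_missing)) {
    # restore the first locus from truth for fully-masked individuals (a bird
    # with no typed locus would not be in a genotype dataset at all)
    idx <- which(obs$all_missing)
    obs$a1[idx, 1] <- A1[idx, 1]
    obs$a2[idx, 1] <- A2[idx, 1]
    still_null <- obs$a1[idx, 1] == NULL_ALLELE | obs$a2[idx, 1] == NULL_ALLELE
    obs$a1[idx[still_null], 1] <- "01"
    obs$a2[idx[still_null], 1] <- "01"
  }
  G_obs <- genotype_matrix(all_ids, loci, obs$a1, obs$a2, groups = roles)

  records <- data.frame(
    year = year_of_pair, female_id = fem_ids, male_id = male_ids,
    double = double, first_egg = first_egg, stripe = stripe, tarsus = tarsus,
    repertoire = repertoire, female_tarsus = female_tarsus,
    offspring_first = brood_n1,
    offspring_total = brood_n1 + brood_n2,
    stringsAsFactors = FALSE)

  structure(list(
    genotypes = G_obs, genotypes_true = G_true, records = records,
    pedigree = pedigree,
    truth = list(beta0 = beta0, beta = b, p_db = p_db, r_true = r_true,
                 hs_true = hs_true, freqs = freqs,
                 achieved_db_fraction = achieved),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d pairs over %d years, %d genotyped birds, %.1f%% double breeding\n",
              nrow(x$records), length(unique(x$records$year)),
              length(x$genotypes$ids), 100 * x$truth$achieved_db_fraction))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the observed genotypes as GenePop and long-form CSV, the breeding
#' records as CSV, and the generating truth as JSON.
#'
#' @param dataset a [simulate_breeding_population()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(genepop = file.path(dir, "genotypes.gen"),
         csv = file.path(dir, "genotypes.csv"),
         records = file.path(dir, "breeding_records.csv"),
         truth = file.path(dir, "truth.json"))
  write_genepop(dataset$genotypes, f[["genepop"]], title = "synthetic population")
  write_genotypes_csv(dataset$genotypes, f[["csv"]])
  utils::write.csv(dataset$records, f[["records"]], row.names = FALSE)
  jsonlite::write_json(
    list(beta0 = dataset$truth$beta0, beta = as.list(dataset$truth$beta),
         achieved_db_fraction = dataset$truth$achieved_db_fraction,
         seed = dataset$config$seed,
         r_true = dataset$truth$r_true, hs_true = dataset$truth$hs_true),
    f[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(f)
}
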