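test_that("Ritland r matches hand computation from the per-locus formula", {
  ft <- freq_table(list(L1 = c(A = 0.5, B = 0.5)))
  gx <- list(a1 = c(L1 = "A"), a2 = c(L1 = "A"))
  gy <- list(a1 = c(L1 = "B"), a2 = c(L1 = "B"))
  # identical homozygotes: (2/1) * (1*1/0.5 - 1) = 2
  expect_equal(ritland_r(gx, gx, ft)$r, 2.0)
  # opposite homozygotes: sum term 0 -> (2/1) * (0 - 1) = -2
  expect_equal(ritland_r(gx, gy, ft)$r, -2.0)

  # a 3-allele locus against the independent per-locus oracle
  p3 <- c(A = 0.2, B = 0.3, C = 0.5)
  ft3 <- freq_table(list(L1 = p3))
  ga <- list(a1 = c(L1 = "A"), a2 = c(L1 = "B"))
  gb <- list(a1 = c(L1 = "B"), a2 = c(L1 = "C"))
  expect_equal(ritland_r(ga, gb, ft3)$r,
               ritland_r_locus_oracle(c("A", "B"), c("B", "C"), p3),
               tolerance = 1e-12)
})

test_that("multilocus r weights loci by allele count minus one", {
  ft <- freq_table(list(L1 = c(A = 0.5, B = 0.5),
                        L2 = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)))
  gx <- list(a1 = c(L1 = "A", L2 = "A"), a2 = c(L1 = "A", L2 = "B"))
  gy <- list(a1 = c(L1 = "A", L2 = "A"), a2 = c(L1 = "B", L2 = "C"))
  r1 <- ritland_r_locus_oracle(c("A", "A"), c("A", "B"), ft$L1$freqs)
  r2 <- ritland_r_locus_oracle(c("A", "B"), c("A", "C"), ft$L2$freqs)
  expect_equal(ritland_r(gx, gy, ft)$r, (1 * r1 + 3 * r2) / 4,
               tolerance = 1e-12)
  # loci missing in either member are excluded
  gx_miss <- list(a1 = c(L1 = "A", L2 = NA), a2 = c(L1 = "A", L2 = NA))
  expect_equal(ritland_r(gx_miss, gy, ft)$r, r1, tolerance = 1e-12)
  expect_error(ritland_r(list(a1 = c(L1 = NA), a2 = c(L1 = NA)), gy, ft),
               "typed")
})

test_that("Ritland r is unbiased for unrelated, half-sib and full-sib dyads", {
  for (case in list(list(rel = "unrelated", r = 0),
                    list(rel = "half_sib", r = 0.25),
                    list(rel = "full_sib", r = 0.5),
                    list(rel = "parent_offspring", r = 0.5))) {
    n <- 10000
    d <- simulate_dyads(sim_config(seed = 207), case$rel, n)
    ft <- freq_table(d$freqs)
    r <- relatedness_dyads(d$gx, d$gy, ft)
    mc_se <- stats::sd(r) / sqrt(n)
    expect_lt(abs(mean(r) - case$r), 3 * mc_se)
  }
})

test_that("vectorized dyad relatedness agrees with the scalar estimator", {
  d <- simulate_dyads(sim_config(seed = 31), "full_sib", 25)
  ft <- freq_table(d$freqs)
  rv <- relatedness_dyads(d$gx, d$gy, ft)
  rs <- vapply(seq_len(25), function(i) {
    ritland_r(genotype_row(d$gx, d$gx$ids[i]),
              genotype_row(d$gy, d$gy$ids[i]), ft)$r
  }, numeric(1))
  expect_equal(rv, rs, tolerance = 1e-12)
  # and with the all-pairs matrix
  G <- genotype_matrix(c(d$gx$ids, d$gy$ids), d$gx$loci,
                       rbind(d$gx$a1, d$gy$a1), rbind(d$gx$a2, d$gy$a2))
  rm <- relatedness_matrix(G, ft, ids_row = d$gx$ids, ids_col = d$gy$ids)
  expect_equal(unname(diag(rm)), unname(rv), tolerance = 1e-12)
})

test_that("r is invariant under allele relabeling and locus reordering", {
  d <- simulate_dyads(sim_config(seed = 13), "half_sib", 30)
  ft <- freq_table(d$freqs)
  r0 <- relatedness_dyads(d$gx, d$gy, ft)

  relabel <- function(x) chartr("0123456", "0654321", x)  # 01<->06, 02<->05 ...
  rl <- function(G) genotype_matrix(G$ids, G$loci, relabel(G$a1), relabel(G$a2))
  ft_rl <- freq_table(lapply(d$freqs, function(p) {
    stats::setNames(p, relabel(names(p)))
  }))
  expect_equal(relatedness_dyads(rl(d$gx), rl(d$gy), ft_rl), r0,
               tolerance = 1e-12)

  perm <- rev(d$gx$loci)
  expect_equal(relatedness_dyads(d$gx[, perm], d$gy[, perm], ft[perm]), r0,
               tolerance = 1e-12)
})

test_that("Ritland F matches hand values and recovers simulated inbreeding", {
  ft <- freq_table(list(L1 = c(A = 0.5, B = 0.5)))
  het <- list(a1 = c(L1 = "A"), a2 = c(L1 = "B"))
  hom <- list(a1 = c(L1 = "A"), a2 = c(L1 = "A"))
  expect_equal(ritland_f(het, ft)$F, -1.0)
  expect_equal(ritland_f(hom, ft)$F, 1.0)

  for (f_true in c(0, 0.25, 0.5)) {
    fs <- simulate_founders(sim_config(seed = 900 + round(100 * f_true),
                                       founder_f = f_true), n = 4000)
    ft_true <- freq_table(fs$freqs)
    f_hat <- inbreeding_coefficients(fs$G, ft_true)
    mc_se <- stats::sd(f_hat) / sqrt(length(f_hat))
    expect_lt(abs(mean(f_hat) - f_true), 3 * mc_se)
  }
})

test_that("vectorized F agrees with the scalar estimator", {
  fs <- simulate_founders(sim_config(seed = 5, founder_f = 0.3), n = 20)
  ft <- freq_table(fs$freqs)
  fv <- inbreeding_coefficients(fs$G, ft)
  fscalar <- vapply(fs$G$ids, function(id) {
    ritland_f(genotype_row(fs$G, id), ft)$F
  }, numeric(1))
  expect_equal(fv, fscalar, tolerance = 1e-12)
})

test_that("standardized heterozygosity follows its defining ratio", {
  ho <- stats::setNames(rep(0.8, 8), sprintf("L%d", 1:8))
  g_all_het <- list(a1 = stats::setNames(rep("A", 8), names(ho)),
                    a2 = stats::setNames(rep("B", 8), names(ho)))
  expect_equal(standardized_heterozygosity(g_all_het, ho)$Hs, 1.25)

  ho5 <- stats::setNames(rep(0.5, 8), names(ho))
  g_half <- list(a1 = stats::setNames(rep(c("A", "A"), 4), names(ho)),
                 a2 = stats::setNames(rep(c("B", "A"), 4), names(ho)))
  expect_equal(standardized_heterozygosity(g_half, ho5)$Hs, 1.0)

  g_hom <- list(a1 = stats::setNames(rep("A", 8), names(ho)),
                a2 = stats::setNames(rep("A", 8), names(ho)))
  expect_equal(standardized_heterozygosity(g_hom, ho)$Hs, 0)
  expect_error(standardized_heterozygosity(g_hom, ho * 0), "Ho")

  # only the typed loci's population Ho enters the denominator
  g_part <- list(a1 = stats::setNames(c("A", NA, rep("A", 6)), names(ho)),
                 a2 = stats::setNames(c("B", NA, rep("A", 6)), names(ho)))
  ho_mix <- stats::setNames(c(0.9, 0.1, rep(0.6, 6)), names(ho))
  expect_equal(standardized_heterozygosity(g_part, ho_mix)$Hs,
               (1 / 7) / mean(ho_mix[-2]), tolerance = 1e-12)
})

test_that("population-average individuals score Hs near 1", {
  fs <- simulate_founders(sim_config(seed = 64), n = 800)
  ho <- stats::setNames(locus_heterozygosity(fs$G)$Ho, fs$G$loci)
  hs <- standardized_heterozygosities(fs$G, ho)
  expect_equal(mean(hs), 1, tolerance = 0.02)
})

test_that("score_population composes the estimators with the right references", {
  cfg <- test_config(seed = 21)
  ds <- simulate_breeding_population(cfg)
  adults <- unique(c(ds$records$female_id, ds$records$male_id))
  sc <- score_population(ds$genotypes, ds$records[, c("female_id", "male_id", "year")],
                         adult_ids = adults)
  expect_equal(nrow(sc$dyads), nrow(ds$records))
  expect_equal(nrow(sc$individuals), length(ds$genotypes$ids))

  # r consistent with calling ritland_r directly under adult frequencies
  fa <- allele_frequencies(ds$genotypes[adults, ])
  i <- 5
  direct <- ritland_r(genotype_row(ds$genotypes, sc$dyads$female_id[i]),
                      genotype_row(ds$genotypes, sc$dyads$male_id[i]), fa)
  expect_equal(sc$dyads$r[i], direct$r, tolerance = 1e-12)

  # F/Hs computed against the all-birds reference
  f_all <- allele_frequencies(ds$genotypes)
  id <- ds$pedigree$offspring_id[1]
  expect_equal(sc$individuals$F[match(id, sc$individuals$individual_id)],
               ritland_f(genotype_row(ds$genotypes, id), f_all)$F,
               tolerance = 1e-12)
  expect_error(score_population(ds$genotypes,
                                data.frame(female_id = "nope", male_id = adults[1])),
               "unknown")
})

test_that("pedigree group means of r match expectations in one population", {
  # unrelated founder pairs ~0; parent-offspring dyads ~0.5, estimated with
  # frequencies from the same population
  cfg <- test_config(seed = 88)
  ds <- simulate_breeding_population(cfg)
  G <- ds$genotypes_true
  ft <- freq_table(ds$truth$freqs)
  ped <- ds$pedigree[!duplicated(ds$pedigree$mother), ]  # one per family:
  # sibling dyads share parents, so within-family r estimates are correlated
  r_po <- relatedness_matrix(G, ft, ids_row = ped$offspring_id,
                             ids_col = unique(ped$mother))[
    cbind(ped$offspring_id, ped$mother)]
  expect_lt(abs(mean(r_po) - 0.5), 3 * stats::sd(r_po) / sqrt(length(r_po)) + 0.02)
})
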