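# shared fixtures and small independent oracles

# wrap a list of named frequency vectors as an allele_frequency_table
freq_table <- function(freqs, n_typed = NA_integer_) {
  out <- lapply(freqs, function(p) {
    list(freqs = p[order(names(p))], n_alleles = length(p), n_typed = n_typed)
  })
  structure(out, class = "allele_frequency_table")
}

# genotype_matrix from a compact string spec: list(id = c("A/B", "C/C", NA))
make_G <- function(calls, loci = NULL, groups = NULL) {
  ids <- names(calls)
  n_loci <- length(calls[[1]])
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(n_loci))
  a1 <- matrix(NA_character_, length(ids), n_loci, dimnames = list(ids, loci))
  a2 <- a1
  for (i in seq_along(ids)) {
    for (l in seq_len(n_loci)) {
      g <- calls[[i]][l]
      if (!is.na(g)) {
        al <- strsplit(g, "/", fixed = TRUE)[[1]]
        a1[i, l] <- al[1]; a2[i, l] <- al[2]
      }
    }
  }
  genotype_matrix(ids, loci, a1, a2, groups = groups)
}

# exhaustive HWE exact p for a biallelic locus: enumerate every genotype table
# compatible with the observed allele counts via its heterozygote count and
# accumulate Levene probabilities no larger than the observed table's
hwe_exact_enum_biallelic <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  ca <- 2 * n_aa + n_ab  # copies of allele a
  levene_log <- function(h) {
    naa <- (ca - h) / 2
    nbb <- n - naa - h
    lfactorial(n) + h * log(2) + lfactorial(ca) + lfactorial(2 * n - ca) -
      lfactorial(2 * n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }
  hs <- seq(ca %% 2, min(ca, 2 * n - ca), by = 2)
  lp <- vapply(hs, levene_log, numeric(1))
  lp_obs <- levene_log(n_ab)
  sum(exp(lp[lp <= lp_obs + 1e-9]))
}

# G statistic of a contingency table, by the textbook formula
g_stat_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
}

# Ritland r for one dyad at one locus, directly from the definition
ritland_r_locus_oracle <- function(gx, gy, p) {
  dose <- function(g) {
    d <- stats::setNames(rep(0, length(p)), names(p))
    d[g[1]] <- d[g[1]] + 0.5
    d[g[2]] <- d[g[2]] + 0.5
    d
  }
  nl <- length(p)
  (2 / (nl - 1)) * (sum(dose(gx) * dose(gy) / p) - 1)
}

# default small simulation config for fast tests
test_config <- function(seed, ...) {
  sim_config(seed = seed, brood1_size = c(3, 1), brood2_size = c(2, 1), ...)
}
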