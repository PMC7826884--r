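# End-to-end orchestration: QC -> genetic scores -> group summaries ->
# randomization tests -> hypothesis comparison and all-subsets selection ->
# offspring genetic-quality contrast, with every output written to disk and
# every seed recorded.

#' Group summaries in the style of a descriptive statistics table
#'
#' Mean, standard error (`sd/sqrt(n)`) and n per (variable, group) cell.
#'
#' @param data data.frame of one row per unit.
#' @param variables character vector of numeric column names to summarize.
#' @param group name of the grouping column.
#' @return data.frame with columns `variable`, `group`, `mean`, `se`, `n`
#'   (empty groups get `n = 0` and `NA` elsewhere; singleton groups get
#'   `se = NA`).
#' @export
summarize_groups <- function(data, variables, group) {
  levels_g <- unique(data[[group]])
  rows <- list()
  for (v in variables) {
    for (g in levels_g) {
      x <- data[[v]][data[[group]] == g]
      x <- x[!is.na(x)]
      n <- length(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = as.character(g),
        mean = if (n) mean(x) else NA_real_,
        se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# relatedness lookup matrices (rows = a year's double-breeding females,
# columns = that year's male pool) for dyad_null()
.build_r_lookup <- function(records, rmat, exclude_observed_mate = FALSE) {
  out <- list()
  for (y in unique(records$year)) {
    rec <- records[records$year == y, ]
    db <- rec[rec$double == 1, ]
    if (!nrow(db)) next
    pool <- rec$male_id
    if (exclude_observed_mate) pool <- setdiff(pool, db$male_id)
    out[[as.character(y)]] <- rmat[db$female_id, pool, drop = FALSE]
  }
  out
}

#' Run the full mate-choice analysis pipeline
#'
#' Stages: (1) locus QC on adult genotypes and locus filtering; (2) genetic
#' scoring (pairwise relatedness from paired adults, F and Hs from all birds);
#' (3) descriptive group summaries (double- vs single-breeding, by sex); (4)
#' year-stratified randomization tests of mean pair relatedness, male Hs and
#' male stripe width; (5) the three-hypothesis AIC comparison and all-subsets
#' AICc selection with coefficient tables for the global and best models; (6)
#' offspring F/Hs contrast between double- and single-breeding pairs
#' (rank-sum tests); (7) a run log with seeds and timings. Any stage failure
#' halts with the stage name.
#'
#' @param genotypes a [genotype_matrix()] of all genotyped birds (adults and
#'   offspring); adult ids must match the breeding records.
#' @param records breeding-record data.frame with columns `year`,
#'   `female_id`, `male_id`, `double` (0/1), `first_egg`, `stripe`, `tarsus`,
#'   `repertoire`, `offspring_first`.
#' @param pedigree optional data.frame (`offspring_id`, `mother`, `father`)
#'   linking offspring to pairs; required for stage 6.
#' @param out_dir output directory; `NULL` skips all file output.
#' @param alpha,null_threshold locus-QC thresholds.
#' @param n_mc,n_perm Monte-Carlo sizes for the HWE and LD tests.
#' @param n_iter randomization iterations.
#' @param tail per-end tail probability for critical values.
#' @param exclude_observed_mate stricter null pool: drop double-breeding
#'   females' own mates from the year pools.
#' @param delta_threshold ΔAICc retention threshold.
#' @param nAGQ GLMM integration setting (see [fit_binomial_glmm()]).
#' @param seed integer seed controlling every stochastic stage.
#' @return class `pipeline_result`: list with `qc`, `scores`, `summaries`,
#'   `randomization` (list of [randomization_test()]s for relatedness, Hs,
#'   stripe), `hypotheses`, `selection`, `coefficients` (global + best),
#'   `offspring_tests`, `model_data`, `log`.
#' @export
run_pipeline <- function(genotypes, records, pedigree = NULL, out_dir = NULL,
                         alpha = 0.05, null_threshold = 0.20,
                         n_mc = 10000, n_perm = 2000,
                         n_iter = 10000, tail = 0.025,
                         exclude_observed_mate = FALSE,
                         delta_threshold = 4, nAGQ = 1L, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(sprintf("broodmate pipeline | R %s | lme4 %s | seed %d | %s",
                         getRversion(), as.character(utils::packageVersion("lme4")),
                         seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-22s %8.2fs", name,
                                       proc.time()[["elapsed"]] - t))
    res
  }

  adults <- unique(c(records$female_id, records$male_id))
  orphans <- setdiff(adults, genotypes$ids)
  if (length(orphans)) {
    stop("breeding records reference ungenotyped birds: ",
         paste(orphans, collapse = ", "))
  }

  # 1. locus QC on adults, then restrict to retained loci
  qc <- stage("locus_qc", locus_qc(genotypes[adults, ], alpha = alpha,
                                   null_threshold = null_threshold,
                                   n_mc = n_mc, n_perm = n_perm, seed = seed))
  G <- genotypes[, qc$retained]

  # 2. genetic scores
  pairs <- records[, c("female_id", "male_id", "year")]
  scores <- stage("score_population", score_population(G, pairs,
                                                       adult_ids = adults))
  ind <- scores$individuals
  model_data <- data.frame(
    records,
    relatedness = scores$dyads$r,
    F = ind$F[match(records$male_id, ind$individual_id)],
    Hs = ind$Hs[match(records$male_id, ind$individual_id)],
    female_F = ind$F[match(records$female_id, ind$individual_id)],
    female_Hs = ind$Hs[match(records$female_id, ind$individual_id)],
    stringsAsFactors = FALSE)

  # 3. descriptive summaries by breeding status
  model_data$status <- ifelse(model_data$double == 1, "double", "single")
  summary_vars <- intersect(c("F", "Hs", "stripe", "tarsus", "repertoire",
                              "relatedness", "female_F", "female_Hs",
                              "female_tarsus", "first_egg", "offspring_first",
                              "offspring_total"), names(model_data))
  summaries <- stage("summaries",
                     summarize_groups(model_data, summary_vars, "status"))

  # 4. randomization tests
  rand <- stage("randomization", {
    rmat <- relatedness_matrix(G[adults, ],
                               allele_frequencies(G[adults, ]),
                               ids_row = unique(records$female_id),
                               ids_col = unique(records$male_id))
    r_lookup <- .build_r_lookup(records, rmat, exclude_observed_mate)
    db <- model_data$double == 1
    res <- list()
    res$relatedness <- randomization_test(
      "mean pair relatedness (double-breeding pairs)",
      observed = mean(model_data$relatedness[db]),
      null_values = dyad_null(r_lookup, n_iter = n_iter, seed = seed),
      tail = tail, n_iter = n_iter, seed = seed)
    for (tr in c("Hs", "stripe")) {
      pools <- split(model_data[[tr]], model_data$year)
      n_db <- vapply(split(db, model_data$year), sum, integer(1))
      res[[tr]] <- randomization_test(
        sprintf("mean male %s (double-breeding males)", tr),
        observed = mean(model_data[[tr]][db]),
        null_values = trait_null(pools, n_db, n_iter = n_iter,
                                 seed = seed + match(tr, c("Hs", "stripe"))),
        tail = tail, n_iter = n_iter, seed = seed)
    }
    res
  })

  # 5. hypothesis comparison + all-subsets selection
  hyp <- stage("compare_hypotheses",
               compare_hypotheses(model_data, nAGQ = nAGQ))
  sel <- stage("all_subsets_selection",
               fit_all_subsets(model_data, "double",
                               predictors = c("F", "Hs", "stripe", "tarsus",
                                              "repertoire", "relatedness"),
                               random = c("male_id", "year"),
                               delta_threshold = delta_threshold, nAGQ = nAGQ))
  best_fixed <- sel$fits[[which.min(vapply(sel$fits, function(f)
    aicc(f$loglik, f$k, f$n), numeric(1)))]]
  coefs <- list(global = coefficient_table(hyp$fits$both),
                best = coefficient_table(best_fixed))

  # 6. offspring genetic quality (double- vs single-breeding pairs)
  offspring_tests <- NULL
  if (!is.null(pedigree)) {
    offspring_tests <- stage("offspring_contrast", {
      status <- model_data$status[match(pedigree$father, model_data$male_id)]
      off <- ind[match(pedigree$offspring_id, ind$individual_id), ]
      keep <- !is.na(status) & !is.na(off$F)
      list(
        F = rank_sum_test(off$F[keep & status == "double"],
                          off$F[keep & status == "single"]),
        Hs = rank_sum_test(off$Hs[keep & status == "double"],
                           off$Hs[keep & status == "single"]),
        summary = summarize_groups(
          data.frame(F = off$F[keep], Hs = off$Hs[keep],
                     status = status[keep], stringsAsFactors = FALSE),
          variables = c("F", "Hs"), group = "status"))
    })
  }

  log_lines <- c(log_lines, sprintf("total %29.2fs", proc.time()[["elapsed"]] - t0))
  result <- structure(list(
    qc = qc, scores = scores, summaries = summaries, randomization = rand,
    hypotheses = hyp, selection = sel$table, coefficients = coefs,
    offspring_tests = offspring_tests, model_data = model_data,
    seed = seed, log = log_lines
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_qc_report(qc, file.path(out_dir, "locus_qc.tsv"),
                    file.path(out_dir, "locus_qc.json"))
    write_scores(scores, file.path(out_dir, "dyad_scores.tsv"),
                 file.path(out_dir, "individual_scores.tsv"))
    utils::write.table(summaries, file.path(out_dir, "group_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(rand)) {
      write_randomization_json(rand[[nm]],
                               file.path(out_dir, sprintf("randomization_%s.json", nm)))
    }
    utils::write.table(hyp$ranking, file.path(out_dir, "hypothesis_aic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sel$table),
                       file.path(out_dir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(coefs$global, file.path(out_dir, "coefficients_global.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(coefs$best, file.path(out_dir, "coefficients_best.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("broodmate pipeline result\n")
  cat(sprintf("  loci retained: %d/%d\n", length(x$qc$retained),
              nrow(x$qc$loci)))
  cat(sprintf("  pairs: %d (%d double-breeding)\n", nrow(x$model_data),
              sum(x$model_data$double)))
  for (nm in names(x$randomization)) {
    r <- x$randomization[[nm]]
    cat(sprintf("  randomization %-12s observed %8.4f vs (%.4f, %.4f): %s\n",
                nm, r$observed, r$critical_lo, r$critical_hi, r$decision))
  }
  cat("  hypothesis AIC ranking:\n")
  print(x$hypotheses$ranking, digits = 5, row.names = FALSE)
  cat(sprintf("  top models (dAICc < %g): %d of %d\n",
              attr(x$selection, "delta_threshold"),
              sum(x$selection$retained), nrow(x$selection)))
  invisible(x)
}
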