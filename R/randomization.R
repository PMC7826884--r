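# Year-stratified dyadic randomization machinery: null distributions for the
# mean relatedness of double-breeding pairs and for mean male trait values,
# two-tailed empirical critical values, decisions and empirical p-values.

#' Null distribution of mean dyad relatedness under random mate assignment
#'
#' Per iteration, within each year independently, every double-breeding female
#' is assigned a male drawn uniformly without replacement from that year's
#' full male pool (sampling without replacement encodes that a male holds one
#' social bond per season); the statistic recorded is the mean relatedness of
#' all assigned dyads pooled over years.
#'
#' @param r_lookup named list (one element per year) of numeric matrices of
#'   relatedness values, rows = that year's double-breeding females, columns =
#'   that year's male pool.
#' @param n_iter number of iterations.
#' @param seed integer seed.
#' @return numeric vector of `n_iter` simulated means.
#' @export
dyad_null <- function(r_lookup, n_iter = 10000, seed = 1L) {
  for (y in names(r_lookup)) {
    m <- r_lookup[[y]]
    if (nrow(m) > ncol(m)) {
      stop("year ", y, ": male pool (", ncol(m),
           ") smaller than double-breeding females (", nrow(m), ")")
    }
    if (anyNA(m)) stop("year ", y, ": missing relatedness values in lookup")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_total <- sum(vapply(r_lookup, nrow, integer(1)))
  sums <- numeric(n_iter)
  for (y in names(r_lookup)) {
    m <- r_lookup[[y]]
    nf <- nrow(m); nm <- ncol(m)
    picks <- vapply(seq_len(n_iter), function(i) sample.int(nm, nf),
                    integer(nf))
    picks <- matrix(picks, nrow = nf)  # nf x n_iter even when nf == 1
    vals <- m[cbind(rep.int(seq_len(nf), n_iter), as.vector(picks))]
    sums <- sums + colSums(matrix(vals, nrow = nf))
  }
  sums / n_total
}

#' Null distribution of a mean male trait under random double-breeder draws
#'
#' Per iteration, draws the observed number of double-breeding males per year
#' without replacement from that year's full male pool and records the pooled
#' mean trait value.
#'
#' @param trait_by_year named list (per year) of numeric vectors: the trait of
#'   every male in that year's pool.
#' @param n_db_by_year named integer vector: double-breeding males per year.
#' @param n_iter number of iterations.
#' @param seed integer seed.
#' @return numeric vector of `n_iter` simulated means.
#' @export
trait_null <- function(trait_by_year, n_db_by_year, n_iter = 10000, seed = 1L) {
  years <- names(trait_by_year)
  n_db_by_year <- n_db_by_year[years]
  for (y in years) {
    if (anyNA(trait_by_year[[y]])) stop("year ", y, ": missing trait values")
    if (n_db_by_year[[y]] > length(trait_by_year[[y]])) {
      stop("year ", y, ": male pool smaller than number of double breeders")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_total <- sum(n_db_by_year)
  sums <- numeric(n_iter)
  for (y in years) {
    v <- trait_by_year[[y]]
    k <- n_db_by_year[[y]]
    if (k == 0L) next
    draws <- vapply(seq_len(n_iter), function(i) sum(v[sample.int(length(v), k)]),
                    numeric(1))
    sums <- sums + draws
  }
  sums / n_total
}

#' Two-tailed empirical critical values of a null distribution
#'
#' @param null_values numeric vector of simulated statistics.
#' @param tail tail probability at each end (default 0.025 gives the 2.5% and
#'   97.5% empirical quantiles, type-7 linear interpolation).
#' @return named numeric vector `c(critical_lo, critical_hi)`.
#' @export
critical_values <- function(null_values, tail = 0.025) {
  stopifnot(length(null_values) > 0, tail > 0, tail < 0.5)
  q <- stats::quantile(null_values, probs = c(tail, 1 - tail), type = 7,
                       names = FALSE)
  c(critical_lo = q[1], critical_hi = q[2])
}

#' Decision rule against two-tailed critical values
#'
#' @param observed observed statistic.
#' @param critical_lo,critical_hi critical values with `critical_lo <=
#'   critical_hi`.
#' @return `"reject_below"`, `"reject_above"` or `"fail_to_reject"`.
#' @export
decide <- function(observed, critical_lo, critical_hi) {
  stopifnot(critical_lo <= critical_hi)
  if (observed < critical_lo) "reject_below"
  else if (observed > critical_hi) "reject_above"
  else "fail_to_reject"
}

#' Two-tailed add-one empirical p-value
#'
#' `p = 2 * min(#{null <= obs} + 1, #{null >= obs} + 1) / (n + 1)`, capped at 1.
#'
#' @param null_values numeric vector of simulated statistics.
#' @param observed observed statistic.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(null_values, observed) {
  stopifnot(length(null_values) > 0)
  n <- length(null_values)
  lo <- sum(null_values <= observed) + 1
  hi <- sum(null_values >= observed) + 1
  min(1, 2 * min(lo, hi) / (n + 1))
}

#' Assemble a full randomization-test result
#'
#' Convenience wrapper combining a null distribution with the observed
#' statistic into critical values, a decision, and an empirical p-value.
#'
#' @param statistic_name label for the statistic tested.
#' @param observed observed mean over the double-breeding set.
#' @param null_values simulated null means (from [dyad_null()] or
#'   [trait_null()]).
#' @param tail per-end tail probability.
#' @param n_iter,seed recorded metadata.
#' @return class `randomization_test`: list with the fields above plus
#'   `critical_lo`, `critical_hi`, `decision`, `empirical_p`.
#' @export
randomization_test <- function(statistic_name, observed, null_values,
                               tail = 0.025, n_iter = length(null_values),
                               seed = NA_integer_) {
  cv <- critical_values(null_values, tail)
  structure(list(
    statistic_name = statistic_name,
    observed = observed,
    null_values = null_values,
    critical_lo = unname(cv[1]), critical_hi = unname(cv[2]),
    decision = decide(observed, cv[1], cv[2]),
    empirical_p = empirical_p(null_values, observed),
    tail = tail, n_iter = n_iter, seed = seed
  ), class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("randomization test: %s\n", x$statistic_name))
  cat(sprintf("  observed %.4f vs critical (%.4f, %.4f) [%d iterations, seed %s]\n",
              x$observed, x$critical_lo, x$critical_hi, x$n_iter,
              as.character(x$seed)))
  cat(sprintf("  decision: %s (two-tailed empirical p = %.4g)\n",
              x$decision, x$empirical_p))
  invisible(x)
}

#' Write a randomization result as JSON (and optionally its null as TSV)
#'
#' @param x a [randomization_test()] result.
#' @param json_path output JSON path.
#' @param null_tsv_path optional TSV path for the full null distribution.
#' @return invisibly, `x`.
#' @export
write_randomization_json <- function(x, json_path, null_tsv_path = NULL) {
  jsonlite::write_json(
    list(statistic = x$statistic_name, observed = x$observed,
         critical_lo = x$critical_lo, critical_hi = x$critical_hi,
         decision = x$decision, empirical_p = x$empirical_p,
         tail = x$tail, n_iter = x$n_iter, seed = x$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_tsv_path)) {
    utils::write.table(data.frame(null_value = x$null_values), null_tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
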