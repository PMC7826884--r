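#' Construct a codominant multilocus genotype matrix
#'
#' The central genotype container: a set of diploid individuals typed at a set
#' of codominant loci (microsatellites). Allele calls are opaque string labels;
#' a call is an unordered pair of alleles, stored canonically with the
#' lexicographically smaller allele first. A missing call blanks both alleles
#' of a locus (`NA`): partial calls are not representable.
#'
#' @param individual_ids character vector of unique individual identifiers.
#' @param locus_ids character vector of unique locus names.
#' @param allele1,allele2 character matrices (`length(individual_ids)` x
#'   `length(locus_ids)`) of allele labels; `NA` in both marks a missing call.
#' @param groups optional character vector of per-individual group labels
#'   (population, sex, role or year tags), recycled `NA` if absent.
#' @return An object of class `genotype_matrix` with elements `ids`, `loci`,
#'   `a1`, `a2`, `groups`.
#' @export
genotype_matrix <- function(individual_ids, locus_ids, allele1, allele2,
                            groups = NULL) {
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  a1 <- matrix(as.character(allele1), nrow = length(individual_ids),
               dimnames = list(individual_ids, locus_ids))
  a2 <- matrix(as.character(allele2), nrow = length(individual_ids),
               dimnames = list(individual_ids, locus_ids))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("missing calls must blank both alleles of a locus")
  # canonical order: smaller allele label first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  typed <- rowSums(!is.na(a1)) > 0
  if (!all(typed)) {
    stop("individuals with no typed locus: ",
         paste(individual_ids[!typed], collapse = ", "))
  }
  if (is.null(groups)) groups <- rep(NA_character_, length(individual_ids))
  groups <- as.character(groups)
  if (length(groups) != length(individual_ids)) {
    stop("groups must have one label per individual")
  }
  names(groups) <- individual_ids
  structure(list(ids = individual_ids, loci = locus_ids,
                 a1 = a1, a2 = a2, groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d missing calls, %.1f%%)\n",
              length(x$ids), length(x$loci), n_missing,
              100 * n_missing / length(x$a1)))
  grp <- table(x$groups, useNA = "ifany")
  if (length(grp) > 1L || !all(is.na(names(grp)))) {
    cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i individual ids (character) or indices; missing keeps all.
#' @param j locus ids (character) or indices; missing keeps all.
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- x$ids
  if (missing(j)) j <- x$loci
  if (!is.character(i)) i <- x$ids[i]
  if (!is.character(j)) j <- x$loci[j]
  genotype_matrix(i, j, x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  groups = x$groups[i])
}

# ---- GenePop I/O -----------------------------------------------------------

#' Read a GenePop file
#'
#' Parses the GenePop 4.x text dialect: a title line, one locus name per line
#' (or a single comma-separated line), then `POP` blocks of individual rows
#' `id , 0101 0102 ...` with 2- or 3-digit allele codes; an all-zero code
#' (`0000`/`000000`) is a missing call. Population blocks become group labels.
#'
#' @param path file path.
#' @return a [genotype_matrix()]; allele codes are kept verbatim as labels and
#'   POP blocks are mapped to `groups` (`"POP_1"`, `"POP_2"`, ...).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 3L) stop("GenePop parse error at line 1: file too short")
  lines <- sub("\r$", "", lines)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("GenePop parse error: no POP line after header (line ",
         if (is.na(first_pop)) length(lines) else first_pop, ")")
  }
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("GenePop parse error: duplicate locus names")

  ids <- character(); groups <- character()
  rows1 <- list(); rows2 <- list()
  pop <- 0L
  code_width <- NA_integer_
  for (k in seq(from = first_pop, to = length(lines))) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") { pop <- pop + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      stop("GenePop parse error at line ", k, ": expected 'id , genotypes'")
    }
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(geno) != length(loci)) {
      stop("GenePop parse error at line ", k, ": ", length(geno),
           " genotypes for ", length(loci), " loci")
    }
    w <- unique(nchar(geno))
    if (length(w) != 1L || !(w %in% c(4L, 6L))) {
      stop("GenePop parse error at line ", k,
           ": allele codes must be uniformly 2- or 3-digit")
    }
    w <- w / 2L
    if (is.na(code_width)) code_width <- w
    if (w != code_width) {
      stop("GenePop parse error at line ", k, ": inconsistent allele-code width")
    }
    a1 <- substr(geno, 1L, w)
    a2 <- substr(geno, w + 1L, 2L * w)
    zero <- strrep("0", w)
    miss <- a1 == zero | a2 == zero
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
    ids <- c(ids, id)
    groups <- c(groups, paste0("POP_", pop))
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
  }
  if (!length(ids)) stop("GenePop parse error: no individuals")
  genotype_matrix(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2),
                  groups = groups)
}

#' Write a genotype matrix as a GenePop file
#'
#' @param G a [genotype_matrix()] whose allele labels are numeric codes of a
#'   common width (2 or 3 digits).
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(G, path, title = "broodmate export") {
  labs <- c(G$a1, G$a2)
  labs <- labs[!is.na(labs)]
  w <- unique(nchar(labs))
  if (length(w) != 1L || !(w %in% c(2L, 3L))) {
    stop("allele labels must be uniform 2- or 3-digit codes for GenePop output")
  }
  zero <- strrep("0", w)
  groups <- G$groups
  if (all(is.na(groups))) groups <- rep("POP_1", length(G$ids))
  out <- c(title, G$loci)
  for (g in unique(groups)) {
    out <- c(out, "POP")
    for (i in which(groups == g)) {
      a1 <- G$a1[i, ]; a2 <- G$a2[i, ]
      a1[is.na(a1)] <- zero; a2[is.na(a2)] <- zero
      out <- c(out, paste0(G$ids[i], " , ", paste0(a1, a2, collapse = " ")))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# ---- long-form CSV dialect -------------------------------------------------

#' Read genotypes from long-form CSV
#'
#' Dialect: columns `id, group, locus, allele1, allele2`; empty allele cells
#' mark a missing call; one row per (individual, locus).
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "group", "locus", "allele1", "allele2")
  if (!all(need %in% names(d))) {
    stop("genotype CSV must have columns: ", paste(need, collapse = ", "))
  }
  d$allele1[!nzchar(d$allele1)] <- NA_character_
  d$allele2[!nzchar(d$allele2)] <- NA_character_
  ids <- unique(d$id)
  loci <- unique(d$locus)
  a1 <- matrix(NA_character_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(d$id, ids), match(d$locus, loci))] <- d$allele1
  a2[cbind(match(d$id, ids), match(d$locus, loci))] <- d$allele2
  groups <- d$group[!duplicated(d$id)]
  genotype_matrix(ids, loci, a1, a2, groups = groups)
}

#' Write genotypes as long-form CSV
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(G, path) {
  d <- data.frame(
    id = rep(G$ids, times = length(G$loci)),
    group = rep(unname(G$groups), times = length(G$loci)),
    locus = rep(G$loci, each = length(G$ids)),
    allele1 = as.vector(G$a1),
    allele2 = as.vector(G$a2),
    stringsAsFactors = FALSE
  )
  d$allele1[is.na(d$allele1)] <- ""
  d$allele2[is.na(d$allele2)] <- ""
  d <- d[order(match(d$id, G$ids), match(d$locus, G$loci)), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- allele frequencies and heterozygosity ---------------------------------

#' Sample allele frequencies per locus
#'
#' Counts both alleles of every typed genotype; missing calls contribute to
#' neither numerator nor denominator (per-locus pairwise deletion).
#'
#' @param G a [genotype_matrix()].
#' @return class `allele_frequency_table`: a list with one element per locus,
#'   each holding `freqs` (named proportions, lexicographic allele order),
#'   `n_alleles`, and `n_typed` (typed genotypes at that locus).
#' @export
allele_frequencies <- function(G) {
  out <- lapply(G$loci, function(l) {
    alleles <- c(G$a1[, l], G$a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) stop("locus with zero typed genotypes: ", l)
    tab <- table(alleles)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)  # table() sorts labels lexicographically
    list(freqs = p, n_alleles = length(p), n_typed = length(alleles) / 2L)
  })
  names(out) <- G$loci
  structure(out, class = "allele_frequency_table")
}

#' Wrap known per-locus frequency vectors as an allele-frequency table
#'
#' Used when reference frequencies are known exactly (e.g. the generating
#' frequencies of a simulation) rather than estimated from a sample.
#'
#' @param freqs named list (by locus) of named numeric vectors of proportions.
#' @return an `allele_frequency_table`.
#' @export
as_allele_frequency_table <- function(freqs) {
  out <- lapply(freqs, function(p) {
    stopifnot(abs(sum(p) - 1) < 1e-9, all(p > 0))
    p <- p[order(names(p))]
    list(freqs = p, n_alleles = length(p), n_typed = NA_integer_)
  })
  structure(out, class = "allele_frequency_table")
}

#' @export
print.allele_frequency_table <- function(x, ...) {
  cat("allele_frequency_table:", length(x), "loci\n")
  for (l in names(x)) {
    cat(sprintf("  %s: %d alleles, n = %d\n", l, x[[l]]$n_alleles, x[[l]]$n_typed))
  }
  invisible(x)
}

#' Observed and expected heterozygosity per locus
#'
#' Ho is the heterozygote proportion among typed genotypes. He is the unbiased
#' gene diversity `(2n/(2n-1)) * (1 - sum(p_i^2))` with `n` typed genotypes —
#' the small-sample correction matters at the study scale (n near 73).
#'
#' @param G a [genotype_matrix()].
#' @param freqs an [allele_frequencies()] table computed from `G`.
#' @return data.frame with columns `locus`, `Ho`, `He`, `n_typed`.
#' @export
locus_heterozygosity <- function(G, freqs = allele_frequencies(G)) {
  rows <- lapply(G$loci, function(l) {
    a1 <- G$a1[, l]; a2 <- G$a2[, l]
    typed <- !is.na(a1)
    n <- sum(typed)
    ho <- if (n) mean(a1[typed] != a2[typed]) else NA_real_
    p <- freqs[[l]]$freqs
    he <- if (n > 0) min(1, (2 * n / (2 * n - 1)) * (1 - sum(p^2))) else NA_real_
    data.frame(locus = l, Ho = ho, He = he, n_typed = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
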