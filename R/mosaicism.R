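#' Read-length count distribution for one allele
#'
#' A named non-negative integer vector: names are CAG repeat lengths (codon
#' units), values are read counts. The constructor validates and sorts.
#'
#' @param counts Named numeric vector, or a two-column data.frame
#'   (`cag_length`, `count`).
#' @param allele_label `"normal"` or `"disease"`.
#' @return An object of class `read_length_dist`.
#' @export
read_length_dist <- function(counts, allele_label = "disease") {
  if (is.data.frame(counts)) {
    v <- counts[[2]]
    names(v) <- counts[[1]]
    counts <- v
  }
  lens <- as.integer(names(counts))
  if (anyNA(lens) || any(lens < 1L)) stop("lengths must be positive integers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0)
    stop(errorCondition("empty read-length distribution",
                        class = c("httex1_empty_input", "error", "condition")))
  o <- order(lens)
  d <- structure(as.numeric(counts[o]), names = lens[o],
                 class = "read_length_dist")
  attr(d, "allele_label") <- allele_label
  d
}

#' @export
print.read_length_dist <- function(x, ...) {
  cat("<read_length_dist> (", attr(x, "allele_label"), "), ",
      sum(x), " reads over lengths ", names(x)[1], "..",
      names(x)[length(x)], "\n", sep = "")
  invisible(x)
}

#' Partition per-read structures into the two alleles of an individual
#'
#' Builds the pure-CAG length histogram, finds the two largest modes at
#' least 3 CAG units apart, and splits at the minimum-count valley between
#' them. The longer-mode cluster is labelled `disease`. When no second mode
#' exists the distribution is returned whole with a single-allele warning.
#'
#' @param per_read_structures List of [allele_structure()] (one per read).
#' @param min_separation Minimum distance between allele modes (default 3).
#' @return A list with `dists` (list of [read_length_dist()]; normal first
#'   when two alleles are found), `structures` (the per-read structures of
#'   each cluster), and `valley` (the split point, `NA` if unimodal).
#' @export
split_alleles <- function(per_read_structures, min_separation = 3L) {
  q1s <- vapply(per_read_structures, function(s) s$q1, integer(1))
  tab <- table(q1s)
  lens <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  m1 <- lens[which.max(cnt)]
  far <- abs(lens - m1) >= min_separation
  if (!any(far)) {
    warning("unimodal read-length distribution: treating as a single allele")
    d <- read_length_dist(tab, allele_label = "disease")
    return(list(dists = list(d), structures = list(per_read_structures),
                valley = NA_integer_))
  }
  m2 <- lens[far][which.max(cnt[far])]
  lo <- min(m1, m2); hi <- max(m1, m2)
  inner <- lens > lo & lens < hi
  valley <- if (any(inner)) {
    cand <- lens[inner]
    cand[which.min(cnt[inner])]
  } else lo  # adjacent modes: split just above the lower mode
  lower <- q1s <= valley
  mk <- function(idx, label) read_length_dist(table(q1s[idx]), label)
  list(dists = list(normal = mk(lower, "normal"),
                    disease = mk(!lower, "disease")),
       structures = list(normal = per_read_structures[lower],
                         disease = per_read_structures[!lower]),
       valley = as.integer(valley))
}

#' Call the progenitor (inherited) allele length
#'
#' The progenitor is the modal read length; ties break toward the larger
#' length because PCR slippage is downward-biased, so the upper of two
#' equally supported lengths is the more plausible template.
#'
#' @param d A [read_length_dist()] (or named count vector).
#' @return Integer CAG length.
#' @export
call_progenitor <- function(d) {
  if (!inherits(d, "read_length_dist")) d <- read_length_dist(d)
  lens <- as.integer(names(d))
  mx <- max(d)
  max(lens[d == mx])
}

#' Ratio of somatic CAG expansions
#'
#' The per-individual mosaicism measure: number of somatic expansion
#' products (reads strictly longer than the progenitor) divided by the
#' number of progenitor allele products (reads at the progenitor length).
#' Contraction reads (shorter than the progenitor; dominated by PCR
#' slippage) are counted and reported but never enter the ratio.
#'
#' @param d A [read_length_dist()] (or named count vector).
#' @param progenitor Progenitor CAG length; defaults to
#'   [call_progenitor()]`(d)`.
#' @param progenitor_window Half-width of the denominator window around the
#'   progenitor (default 0: the progenitor peak only).
#' @param subtract_slippage Optional estimate of the upward-slippage rate
#'   (expansion-like reads per progenitor read expected from PCR artefact
#'   alone, e.g. measured on the short, stable non-disease allele). When
#'   given, `numerator - subtract_slippage * denominator` is used, floored
#'   at 0. Default `NULL`: all reads above the progenitor count as genuine
#'   somatic expansions.
#' @return A list of class `mosaicism_result`: `progenitor_length`,
#'   `expansion_ratio`, `n_progenitor_reads`, `n_expansion_reads`,
#'   `n_contraction_reads`.
#' @export
expansion_ratio <- function(d, progenitor = NULL, progenitor_window = 0L,
                            subtract_slippage = NULL) {
  if (!inherits(d, "read_length_dist")) d <- read_length_dist(d)
  if (is.null(progenitor)) progenitor <- call_progenitor(d)
  lens <- as.integer(names(d))
  denom <- sum(d[abs(lens - progenitor) <= progenitor_window])
  if (denom <= 0)
    stop(errorCondition(
      paste0("no reads at progenitor length ", progenitor),
      class = c("httex1_division_undefined", "error", "condition")))
  n_exp <- sum(d[lens > progenitor + progenitor_window])
  n_con <- sum(d[lens < progenitor - progenitor_window])
  num <- n_exp
  if (!is.null(subtract_slippage))
    num <- max(0, n_exp - subtract_slippage * denom)
  out <- list(progenitor_length = as.integer(progenitor),
              expansion_ratio = num / denom,
              n_progenitor_reads = denom,
              n_expansion_reads = n_exp,
              n_contraction_reads = n_con)
  class(out) <- "mosaicism_result"
  out
}

#' @export
print.mosaicism_result <- function(x, ...) {
  cat("<mosaicism_result> progenitor ", x$progenitor_length,
      " CAG; expansion ratio ", format(x$expansion_ratio, digits = 4),
      " (", x$n_expansion_reads, "/", x$n_progenitor_reads,
      " reads; ", x$n_contraction_reads, " contractions)\n", sep = "")
  invisible(x)
}

#' Tabulate mosaicism for a pre-tabulated count file
#'
#' @param counts Data frame with columns `sample_id`, `allele_label`,
#'   `cag_length`, `count` (the count-TSV interface).
#' @inheritParams expansion_ratio
#' @return Data frame with one row per sample: progenitor length, expansion
#'   ratio and read counts of the disease allele.
#' @export
mosaicism_table <- function(counts, progenitor_window = 0L,
                            subtract_slippage = NULL) {
  need <- c("sample_id", "allele_label", "cag_length", "count")
  if (!all(need %in% names(counts)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  dd <- counts[counts$allele_label == "disease", , drop = FALSE]
  rows <- lapply(split(dd, dd$sample_id), function(g) {
    d <- read_length_dist(data.frame(g$cag_length, g$count))
    r <- expansion_ratio(d, progenitor_window = progenitor_window,
                         subtract_slippage = subtract_slippage)
    data.frame(sample_id = g$sample_id[1],
               progenitor_length = r$progenitor_length,
               expansion_ratio = r$expansion_ratio,
               n_progenitor_reads = r$n_progenitor_reads,
               n_expansion_reads = r$n_expansion_reads,
               n_contraction_reads = r$n_contraction_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
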