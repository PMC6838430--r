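#' Read amplicon reads covering the repeat region
#'
#' Thin wrapper over Biostrings readers. FASTQ qualities are Sanger-scaled;
#' FASTA reads carry no qualities and pass any quality filter.
#'
#' @param path FASTQ or FASTA file.
#' @param format `"fastq"` or `"fasta"`; guessed from the extension when
#'   missing.
#' @return A list with `seq` (character vector of reads) and `mean_qual`
#'   (numeric vector of per-read mean Phred qualities, `NA` for FASTA).
#' @export
read_repeat_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    # Biostrings notes dropped metadata columns on FASTQ import; harmless
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    q <- methods::as(Biostrings::quality(x), "IntegerList")
    list(seq = as.character(x), mean_qual = vapply(q, mean, numeric(1)))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    list(seq = as.character(x), mean_qual = rep(NA_real_, length(x)))
  }
}

#' Genotype a set of amplicon reads at codon granularity
#'
#' Parses each read with [parse_repeat_sequence()]; reads failing the
#' mean-quality filter or the repeat grammar are rejected and counted
#' separately rather than rescued.
#'
#' @param reads Character vector of read sequences, or the list returned by
#'   [read_repeat_reads()].
#' @param flank5,flank3 Optional constant anchors passed to the parser.
#' @param min_qual Minimum mean Phred quality (default 30); reads without
#'   qualities are not filtered.
#' @return A list with `structures` (list of [allele_structure()] for parsed
#'   reads), `n_unparseable`, and `n_low_quality`.
#' @export
genotype_reads <- function(reads, flank5 = NULL, flank3 = NULL,
                           min_qual = 30) {
  if (is.list(reads) && !is.null(reads$seq)) {
    mq <- reads$mean_qual
    reads <- reads$seq
  } else {
    mq <- rep(NA_real_, length(reads))
  }
  keep <- is.na(mq) | mq >= min_qual
  n_low <- sum(!keep)
  out <- vector("list", sum(keep))
  bad <- 0L
  j <- 0L
  for (r in reads[keep]) {
    s <- tryCatch(parse_repeat_sequence(r, flank5, flank3),
                  httex1_parse_error = function(e) NULL,
                  httex1_anchor_error = function(e) NULL)
    if (is.null(s)) bad <- bad + 1L else {
      j <- j + 1L
      out[[j]] <- s
    }
  }
  list(structures = out[seq_len(j)], n_unparseable = bad,
       n_low_quality = n_low)
}

#' Genotype one individual: two alleles from pooled reads
#'
#' Splits reads into the non-disease and disease allele with
#' [split_alleles()], calls each allele's progenitor pure-CAG length, and
#' reports the modal structure of the reads at the progenitor length.
#'
#' @param reads As in [genotype_reads()].
#' @param sample_id Sample label carried into the output.
#' @inheritParams genotype_reads
#' @return A data.frame with one row per allele and the columns
#'   `sample_id, allele_rank, q1, q2, qt, p1, p2, p3, structure_code, hgvs,
#'   qfl, n_reads, n_unparseable`.
#' @export
genotype_sample <- function(reads, sample_id = "sample", flank5 = NULL,
                            flank3 = NULL, min_qual = 30) {
  g <- genotype_reads(reads, flank5, flank3, min_qual)
  if (length(g$structures) == 0L) stop("no parseable reads for ", sample_id)
  split <- split_alleles(g$structures)
  rows <- lapply(seq_along(split$dists), function(i) {
    d <- split$dists[[i]]
    prog <- call_progenitor(d)
    members <- split$structures[[i]]
    at_prog <- members[vapply(members, function(s) s$q1, 1L) == prog]
    codes <- vapply(at_prog, structure_code, character(1))
    rep_s <- at_prog[[match(names(which.max(table(codes))), codes)]]
    data.frame(sample_id = sample_id,
               allele_rank = i,
               q1 = prog,
               q2 = rep_s$q2, qt = prog + rep_s$q2,
               p1 = rep_s$p1, p2 = rep_s$p2, p3 = rep_s$p3,
               structure_code = paste(prog, rep_s$q2, rep_s$p1, rep_s$p2,
                                      rep_s$p3, sep = "-"),
               hgvs = to_hgvs(allele_structure(prog, rep_s$extra_caa,
                                               rep_s$caacag, rep_s$ccgcca,
                                               rep_s$p2, rep_s$p3)),
               qfl = fragment_length_estimate(
                 allele_structure(prog, rep_s$extra_caa, rep_s$caacag,
                                  rep_s$ccgcca, rep_s$p2, rep_s$p3)),
               n_reads = sum(d),
               n_unparseable = g$n_unparseable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
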