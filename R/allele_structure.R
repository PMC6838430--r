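#' Codon-cassette decomposition of one HTT exon-1 repeat allele
#'
#' The glutamine/proline-encoding repeat region of *HTT* exon 1 decomposes as
#' `(CAG)q1 (CAA)extra_caa (CAACAG)caacag (CCGCCA)ccgcca (CCG)p2 (CCT)p3`.
#' Derived quantities follow the field's notation: `q2 = extra_caa +
#' 2*caacag` (additional glutamine codons downstream of the pure CAG tract),
#' `qt = q1 + q2` (total consecutive encoded glutamines), `p1 = 2*ccgcca`,
#' `pt = p1 + p2 + p3` (total encoded prolines).
#'
#' @param q1 Number of pure CAG codons (>= 1).
#' @param extra_caa 0 or 1: a lone CAA codon between the pure CAG tract and
#'   the CAACAG cassettes.
#' @param caacag Number of CAACAG cassettes.
#' @param ccgcca Number of CCGCCA cassettes.
#' @param p2 Number of pure CCG codons.
#' @param p3 Number of CCT codons.
#' @return An object of class `allele_structure`: a list with the six
#'   primary fields plus derived `q2`, `qt`, `p1`, `pt`.
#' @examples
#' allele_structure(q1 = 43, caacag = 1, ccgcca = 1, p2 = 7, p3 = 2)
#' @export
allele_structure <- function(q1, extra_caa = 0L, caacag = 0L, ccgcca = 0L,
                             p2 = 0L, p3 = 0L) {
  fields <- c(q1 = q1, extra_caa = extra_caa, caacag = caacag,
              ccgcca = ccgcca, p2 = p2, p3 = p3)
  if (any(is.na(fields)) || any(fields < 0) || any(fields != round(fields)))
    stop("allele_structure fields must be non-negative integers")
  if (q1 < 1L) stop("q1 must be >= 1 for a parseable allele")
  if (extra_caa > 1L) stop("extra_caa must be 0 or 1")
  s <- list(q1 = as.integer(q1), extra_caa = as.integer(extra_caa),
            caacag = as.integer(caacag), ccgcca = as.integer(ccgcca),
            p2 = as.integer(p2), p3 = as.integer(p3))
  s$q2 <- s$extra_caa + 2L * s$caacag
  s$qt <- s$q1 + s$q2
  s$p1 <- 2L * s$ccgcca
  s$pt <- s$p1 + s$p2 + s$p3
  class(s) <- "allele_structure"
  s
}

#' @export
print.allele_structure <- function(x, ...) {
  cat("<allele_structure> ", structure_code(x),
      "  (qt = ", x$qt, ", pt = ", x$pt, ")\n", sep = "")
  invisible(x)
}

#' @export
format.allele_structure <- function(x, ...) structure_code(x)

#' Compact Q1-Q2-P1-P2-P3 structure code
#'
#' @param s An [allele_structure()].
#' @return A string such as `"17-2-0-6-2"`.
#' @export
structure_code <- function(s) {
  stopifnot(inherits(s, "allele_structure"))
  paste(s$q1, s$q2, s$p1, s$p2, s$p3, sep = "-")
}

#' Parse a Q1-Q2-P1-P2-P3 structure code
#'
#' Inverse of [structure_code()]. An even `q2` maps to `q2/2` CAACAG
#' cassettes; an odd `q2` implies one lone CAA plus `(q2-1)/2` cassettes.
#' `p1` must be even (CCGCCA cassettes).
#'
#' @param code String `"Q1-Q2-P1-P2-P3"`.
#' @export
parse_structure_code <- function(code) {
  parts <- strsplit(code, "-", fixed = TRUE)[[1]]
  if (length(parts) != 5L || anyNA(suppressWarnings(as.integer(parts))))
    stop("malformed structure code: ", code)
  v <- as.integer(parts)
  if (v[3] %% 2L != 0L) stop("p1 must be even (CCGCCA cassettes): ", code)
  allele_structure(q1 = v[1], extra_caa = v[2] %% 2L, caacag = v[2] %/% 2L,
                   ccgcca = v[3] %/% 2L, p2 = v[4], p3 = v[5])
}

#' Serialize an allele structure to its nucleotide sequence
#'
#' Deterministic concatenation in cassette order; the result has length
#' `3 * (qt + pt)` nucleotides.
#'
#' @param s An [allele_structure()].
#' @return A nucleotide string.
#' @export
to_sequence <- function(s) {
  stopifnot(inherits(s, "allele_structure"))
  paste0(strrep("CAG", s$q1), strrep("CAA", s$extra_caa),
         strrep("CAACAG", s$caacag), strrep("CCGCCA", s$ccgcca),
         strrep("CCG", s$p2), strrep("CCT", s$p3))
}

# munch as many copies of `unit` as possible starting at `at` (1-based)
.munch <- function(dna, unit, at) {
  w <- nchar(unit)
  n <- 0L
  while (substr(dna, at, at + w - 1L) == unit) {
    n <- n + 1L
    at <- at + w
  }
  list(n = n, at = at)
}

#' Parse a repeat-region nucleotide sequence into its cassette structure
#'
#' Greedy left-to-right maximal decomposition into `(CAG)+`, an optional
#' single lone CAA, `(CAACAG)*`, `(CCGCCA)*`, `(CCG)*`, `(CCT)*`. The lone
#' CAA is taken only when the following codons do not start a CAACAG
#' cassette, which reproduces the published decomposition of interrupted
#' alleles such as 41-3-2-7-2. Parsing is exact at codon granularity: any
#' residue that does not fit the grammar raises a classed error carrying the
#' 1-based offset of the first offending nucleotide.
#'
#' @param dna Nucleotide string containing the repeat region (A/C/G/T,
#'   case-insensitive).
#' @param flank5,flank3 Optional constant anchor sequences. When given, each
#'   must occur exactly once in `dna` and the region between them is parsed;
#'   when absent the whole string is taken as pre-trimmed repeat region.
#' @return An [allele_structure()].
#' @export
parse_repeat_sequence <- function(dna, flank5 = NULL, flank3 = NULL) {
  dna <- toupper(dna)
  if (!is.null(flank5) || !is.null(flank3)) {
    dna <- .trim_flanks(dna, toupper(flank5), toupper(flank3))
  }
  n <- nchar(dna)
  m <- .munch(dna, "CAG", 1L)
  if (m$n == 0L)
    stop(errorCondition(paste0("no pure CAG tract at offset 1"),
                        offset = 1L,
                        class = c("httex1_parse_error", "error", "condition")))
  q1 <- m$n; at <- m$at
  extra_caa <- 0L
  if (substr(dna, at, at + 2L) == "CAA" &&
      substr(dna, at, at + 5L) != "CAACAG") {
    extra_caa <- 1L
    at <- at + 3L
  }
  m <- .munch(dna, "CAACAG", at); caacag <- m$n; at <- m$at
  m <- .munch(dna, "CCGCCA", at); ccgcca <- m$n; at <- m$at
  m <- .munch(dna, "CCG", at);    p2 <- m$n;     at <- m$at
  m <- .munch(dna, "CCT", at);    p3 <- m$n;     at <- m$at
  if (at != n + 1L)
    stop(errorCondition(
      paste0("unparseable residue '", substr(dna, at, min(n, at + 8L)),
             "' at offset ", at),
      offset = at,
      class = c("httex1_parse_error", "error", "condition")))
  allele_structure(q1, extra_caa, caacag, ccgcca, p2, p3)
}

.trim_flanks <- function(dna, flank5, flank3) {
  start <- 1L
  end <- nchar(dna)
  if (!is.null(flank5) && nzchar(flank5)) {
    hits <- gregexpr(flank5, dna, fixed = TRUE)[[1]]
    if (length(hits) != 1L || hits[1] == -1L)
      stop(errorCondition(paste0("5' anchor found ",
                                 if (hits[1] == -1L) 0L else length(hits),
                                 " times (expected exactly once)"),
                          class = c("httex1_anchor_error", "error", "condition")))
    start <- hits[1] + nchar(flank5)
  }
  if (!is.null(flank3) && nzchar(flank3)) {
    hits <- gregexpr(flank3, dna, fixed = TRUE)[[1]]
    if (length(hits) != 1L || hits[1] == -1L)
      stop(errorCondition(paste0("3' anchor found ",
                                 if (hits[1] == -1L) 0L else length(hits),
                                 " times (expected exactly once)"),
                          class = c("httex1_anchor_error", "error", "condition")))
    end <- hits[1] - 1L
  }
  substr(dna, start, end)
}

#' HGVS-style annotation of an allele structure
#'
#' Serializes to the bracketed-count dialect used for this locus, e.g.
#' `"LRG_763:c.52_153CAG[41]CAACAG[0]CCGCCA[0]CCG[9]CCT[2]"`. Zero-count
#' CAACAG/CCGCCA/CCG/CCT blocks are emitted explicitly; the lone-CAA block
#' appears only when present (`CAA[1]`). The `c.52_153` prefix is carried as
#' an opaque locus label, not a computed coordinate.
#'
#' @param s An [allele_structure()].
#' @return A single annotation string.
#' @export
to_hgvs <- function(s) {
  stopifnot(inherits(s, "allele_structure"))
  paste0("LRG_763:c.52_153",
         "CAG[", s$q1, "]",
         if (s$extra_caa > 0L) paste0("CAA[", s$extra_caa, "]") else "",
         "CAACAG[", s$caacag, "]",
         "CCGCCA[", s$ccgcca, "]",
         "CCG[", s$p2, "]",
         "CCT[", s$p3, "]")
}

#' Parse an HGVS-style repeat annotation
#'
#' Inverse of [to_hgvs()]. Malformed input raises a classed error naming the
#' first bad token.
#'
#' @param text Annotation string as produced by [to_hgvs()].
#' @export
parse_hgvs <- function(text) {
  prefix <- "LRG_763:c.52_153"
  if (!startsWith(text, prefix))
    stop(errorCondition(paste0("bad prefix token: '",
                               substr(text, 1, nchar(prefix)), "'"),
                        class = c("httex1_hgvs_error", "error", "condition")))
  body <- substr(text, nchar(prefix) + 1L, nchar(text))
  toks <- regmatches(body, gregexpr("[ACGT]+\\[[0-9]+\\]", body))[[1]]
  if (paste0(toks, collapse = "") != body) {
    bad <- sub("^([ACGT]+\\[[0-9]+\\])*", "", body)
    stop(errorCondition(paste0("malformed annotation at token: '",
                               substr(bad, 1, 12), "'"),
                        class = c("httex1_hgvs_error", "error", "condition")))
  }
  units <- sub("\\[.*", "", toks)
  counts <- as.integer(sub(".*\\[([0-9]+)\\]", "\\1", toks))
  names(counts) <- units
  expected <- c("CAG", "CAA", "CAACAG", "CCGCCA", "CCG", "CCT")
  if (!all(units %in% expected) || anyDuplicated(units) ||
      !identical(units, expected[expected %in% units]))
    stop(errorCondition(paste0("unexpected block order or unit: '",
                               units[which.max(!(units %in% expected))], "'"),
                        class = c("httex1_hgvs_error", "error", "condition")))
  g <- function(u) if (u %in% units) counts[[u]] else 0L
  allele_structure(q1 = g("CAG"), extra_caa = g("CAA"), caacag = g("CAACAG"),
                   ccgcca = g("CCGCCA"), p2 = g("CCG"), p3 = g("CCT"))
}

#' Fragment-length CAG estimate (QFL) for an allele structure
#'
#' Emulates PCR fragment-length sizing under the typical-structure
#' assumption (Q2 = 2). Atypical alleles are mis-sized: cassette-deletion
#' alleles (Q2 = 0) size two repeats short of the pure CAG number, and
#' cassette-duplication alleles (Q2 = 4) size only one repeat long because
#' the sizing primer mis-primes across the polymorphic region. The Q2 = 3
#' offset (+1) is a declared convention for the interrupted allele.
#'
#' @param s An [allele_structure()].
#' @return Integer QFL estimate: `q1 + c(-2, 0, +1, +1)[match(q2, c(0,2,3,4))]`.
#' @export
fragment_length_estimate <- function(s) {
  stopifnot(inherits(s, "allele_structure"))
  offsets <- c(`0` = -2L, `2` = 0L, `3` = 1L, `4` = 1L)
  key <- as.character(s$q2)
  if (!key %in% names(offsets))
    stop(errorCondition(paste0("no fragment-length model for q2 = ", s$q2),
                        class = c("httex1_unsupported_structure", "error",
                                  "condition")))
  s$q1 + offsets[[key]]
}

#' Pure-CAG inclusion filter
#'
#' Cohort inclusion is defined on the sequence-determined pure CAG count:
#' `40 <= q1 <= 50`, both bounds inclusive. Note this differs from filtering
#' on total glutamines: an allele with qt = 53 and q2 = 4 has q1 = 49 and is
#' included, while qt = 40 with q2 = 2 gives q1 = 38 and is excluded.
#'
#' @param s An [allele_structure()].
#' @return Logical.
#' @export
pure_cag_inclusion <- function(s) {
  stopifnot(inherits(s, "allele_structure"))
  s$q1 >= 40L && s$q1 <= 50L
}
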