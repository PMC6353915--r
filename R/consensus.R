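# Pileup construction on the circular reference and threshold consensus
# calling with heteroplasmy flagging.

#' Build a base pileup over the circular reference
#'
#' Counts A/C/G/T observations per reference position from the stored
#' (reference-forward) fragment sequences. `N` bases contribute to no
#' count; fragments spanning the origin wrap onto positions `L-1` and 0.
#'
#' @param frags Fragment `data.frame`.
#' @param L Reference length in bases.
#' @return An object of class `pileup`: a list with `counts` (4 x `L`
#'   integer matrix, rows A/C/G/T; columns are 0-based positions) and `L`.
#' @export
build_pileup <- function(frags, L) {
  validate_fragments(frags)
  L <- as.integer(L)
  bt <- fragment_base_table(frags, L)
  code <- match(bt$base, c(CHR_A, CHR_C, CHR_G, CHR_T))
  keep <- !is.na(code)
  counts <- matrix(tabulate((bt$refpos[keep]) * 4L + code[keep], nbins = 4L * L),
                   nrow = 4L, dimnames = list(BASES, NULL))
  structure(list(counts = counts, L = L), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cov <- colSums(x$counts)
  cat(sprintf("pileup: L = %d, mean coverage %.1f, %d uncovered position(s)\n",
              x$L, mean(cov), sum(cov == 0)))
  invisible(x)
}

#' Call a threshold consensus from a pileup
#'
#' A position is called with its majority base when coverage is at least
#' `min_cov` AND the majority base is supported by at least `min_support`
#' of the counted fragments (both boundaries inclusive); otherwise it is
#' `N`. Well-covered positions failing only the support threshold are
#' flagged as heteroplasmy candidates: they are reported with their
#' counts but never called into the sequence.
#'
#' @param pileup A [build_pileup()] result.
#' @param min_cov Minimum coverage to call (default 5).
#' @param min_support Minimum majority support to call (default 0.8).
#' @return An object of class `consensus_sequence`: `sequence` (character
#'   scalar over A/C/G/T/N), per-position `status` (`"called"`,
#'   `"low_coverage"`, `"low_support"`), `heteroplasmy` data frame
#'   (0-based `position`, base counts, `coverage`, `support`),
#'   `mean_coverage`, `n_called`, and the thresholds used.
#' @export
call_consensus <- function(pileup, min_cov = 5L, min_support = 0.8) {
  stopifnot(inherits(pileup, "pileup"))
  counts <- pileup$counts
  L <- pileup$L
  cov <- colSums(counts)
  maj <- max.col(t(counts), ties.method = "first")
  majc <- counts[cbind(maj, seq_len(L))]
  support <- ifelse(cov > 0, majc / cov, NA_real_)
  cov_ok <- cov >= min_cov
  sup_ok <- cov > 0 & support >= min_support - 1e-9
  called <- cov_ok & sup_ok
  chars <- ifelse(called, BASES[maj], "N")
  status <- ifelse(called, "called",
                   ifelse(!cov_ok, "low_coverage", "low_support"))
  het_idx <- which(cov_ok & !sup_ok)
  het <- data.frame(position = het_idx - 1L,
                    t(counts[, het_idx, drop = FALSE]),
                    coverage = cov[het_idx],
                    support = support[het_idx], row.names = NULL)
  names(het)[2:5] <- BASES
  structure(list(sequence = paste(chars, collapse = ""),
                 status = status, heteroplasmy = het,
                 mean_coverage = mean(cov), n_called = sum(called),
                 L = L, min_cov = min_cov, min_support = min_support),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("consensus_sequence: %d / %d positions called (min_cov %d, min_support %.0f%%)\n",
              x$n_called, x$L, x$min_cov, 100 * x$min_support))
  cat(sprintf("  mean coverage %.1f; %d heteroplasmy candidate(s)\n",
              x$mean_coverage, nrow(x$heteroplasmy)))
  invisible(x)
}

#' @export
as.character.consensus_sequence <- function(x, ...) x$sequence

#' Override consensus calls in declared regions
#'
#' Applies an explicit per-position patch (e.g. a manually curated
#' homopolymer region): each row sets one position to a declared base.
#' Patched positions get status `"patched"`. No automatic correction is
#' attempted.
#'
#' @param consensus A `consensus_sequence`.
#' @param patch `data.frame` with columns `position` (0-based) and `base`
#'   (single character in A/C/G/T/N).
#' @return The patched `consensus_sequence`.
#' @export
patch_consensus <- function(consensus, patch) {
  stopifnot(inherits(consensus, "consensus_sequence"))
  if (nrow(patch) == 0) return(consensus)
  if (any(patch$position < 0 | patch$position >= consensus$L))
    stop("patch positions out of range")
  if (any(!patch$base %in% c(BASES, "N")))
    stop("patch bases must be A, C, G, T or N")
  s <- strsplit(consensus$sequence, "", fixed = TRUE)[[1]]
  s[patch$position + 1L] <- patch$base
  consensus$sequence <- paste(s, collapse = "")
  consensus$status[patch$position + 1L] <- "patched"
  consensus$n_called <- sum(consensus$status %in% c("called", "patched") &
                              s != "N")
  consensus
}

as_consensus_string <- function(x) {
  if (inherits(x, "consensus_sequence")) return(x$sequence)
  if (inherits(x, "mt_genome")) return(x$sequence)
  if (is.character(x) && length(x) == 1) return(toupper(x))
  stop("expected a consensus_sequence, mt_genome, or a single sequence string")
}

#' Compare two called sequences position by position
#'
#' @param a,b Sequences of equal length (`consensus_sequence`,
#'   `mt_genome` or character scalar).
#' @return List with `mismatches` (data frame of 0-based `position`, `a`,
#'   `b` at positions where both are called and differ), `n_compared`
#'   (positions where both are non-N) and `n_uncomparable` (positions
#'   where either side is N).
#' @export
compare_consensus <- function(a, b) {
  sa <- as_consensus_string(a)
  sb <- as_consensus_string(b)
  if (nchar(sa) != nchar(sb))
    stop("sequences differ in length (", nchar(sa), " vs ", nchar(sb), ")")
  va <- utf8ToInt(sa)
  vb <- utf8ToInt(sb)
  both <- va != CHR_N & vb != CHR_N
  mism <- which(both & va != vb)
  list(mismatches = data.frame(position = mism - 1L,
                               a = intToUtf8(va[mism], multiple = TRUE) %||% character(0),
                               b = intToUtf8(vb[mism], multiple = TRUE) %||% character(0),
                               stringsAsFactors = FALSE),
       n_compared = sum(both),
       n_uncomparable = sum(!both))
}
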