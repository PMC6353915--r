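# Length filtering, PCR-duplicate fusing, and the per-library
# fragment/coverage accounting reported for each sequencing library.

#' Retain fragments of at least a minimum length
#'
#' @param frags Fragment `data.frame`.
#' @param min_len Minimum retained length in bases; the boundary is
#'   inclusive (default 35).
#' @return Filtered fragment `data.frame`, input order preserved.
#' @export
filter_length <- function(frags, min_len = 35L) {
  validate_fragments(frags)
  frags[(frags$end - frags$start) >= min_len, , drop = FALSE]
}

# Majority base per column across equal-length duplicate sequences;
# ties become N.
fuse_sequences <- function(seqs) {
  if (length(unique(seqs)) == 1) return(seqs[[1]])
  m <- matrix(utf8ToInt(paste(seqs, collapse = "")),
              nrow = nchar(seqs[[1]]))
  fused <- apply(m, 1, function(col) {
    col <- col[col != CHR_N]
    if (length(col) == 0) return(CHR_N)
    tab <- table(col)
    top <- tab[tab == max(tab)]
    if (length(top) > 1) CHR_N else as.integer(names(top))
  })
  intToUtf8(fused)
}

#' Fuse fragments with identical alignment coordinates
#'
#' PCR duplicates share start and end coordinates. One fragment is kept
#' per `(library, start, end, strand)` key; where duplicate sequences
#' disagree at a column, the per-column majority base is used and ties
#' become `N`. The operation is idempotent.
#'
#' @param frags Fragment `data.frame`.
#' @return Fragment `data.frame` with unique coordinates per library and
#'   strand.
#' @export
collapse_duplicates <- function(frags) {
  validate_fragments(frags)
  if (nrow(frags) == 0) return(frags)
  key <- paste(frags$library, frags$start, frags$end, frags$strand,
               sep = "\r")
  first <- !duplicated(key)
  out <- frags[first, , drop = FALSE]
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) > 0) {
    groups <- split(frags$sequence, key)[dup_keys]
    fused <- vapply(groups, fuse_sequences, character(1))
    out$sequence[match(dup_keys, key[first])] <- fused
  }
  rownames(out) <- NULL
  out
}

#' Per-library fragment counts and coverage
#'
#' Coverage is the total of fragment lengths divided by the genome length
#' `L` (the expected depth per position on the circle).
#'
#' @param frags Fragment `data.frame` (normally post-collapse).
#' @param L Reference length in bases; must be positive.
#' @return `data.frame` with one row per library plus a pooled `"all"`
#'   row: `library`, `n_fragments`, `mean_length`, `coverage`.
#' @export
summarize_fragments <- function(frags, L) {
  if (!is.numeric(L) || length(L) != 1 || L <= 0)
    stop("L must be a positive number")
  validate_fragments(frags)
  lens <- frags$end - frags$start
  one <- function(lab, lens) {
    data.frame(library = lab, n_fragments = length(lens),
               mean_length = if (length(lens)) mean(lens) else NA_real_,
               coverage = sum(lens) / L, stringsAsFactors = FALSE)
  }
  if (nrow(frags) == 0) return(one("all", integer(0)))
  libs <- sort(unique(frags$library))
  per <- do.call(rbind, lapply(libs, function(lb) one(lb, lens[frags$library == lb])))
  if (length(libs) > 1) per <- rbind(per, one("all", lens))
  rownames(per) <- NULL
  per
}
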