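# Readers and writers for the formats the pipeline consumes: FASTA,
# SAM/BAM alignments, the internal fragment TSV, and `.14c` calibration
# curve tables.

#' Read a FASTA file as a named character vector
#'
#' Sequences are upper-cased on read. Empty files and duplicate record
#' names are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("FASTA file contains no records: ", path)
  out <- toupper(as.character(ss))
  # keep only the first word of each header, as aligners do
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out)))
    stop("duplicate sequence names in FASTA file: ", path)
  out
}

#' Write named sequences to a FASTA file (60-column wrapping)
#'
#' @param seqs Named character vector (or `mt_genome`).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "mt_genome"))
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write / read the internal fragment TSV
#'
#' Columns: `id`, `library`, `start`, `end`, `strand`, `sequence`,
#' `truth_label` (optional; `NA` when unknown). Coordinates are 0-based,
#' half-open, on the circular reference.
#'
#' @param frags Fragment `data.frame`.
#' @param path File path.
#' @return `read_fragments_tsv` returns the fragment `data.frame`.
#' @export
write_fragments_tsv <- function(frags, path) {
  validate_fragments(frags)
  cols <- c("id", "library", "start", "end", "strand", "sequence")
  if ("truth_label" %in% names(frags)) cols <- c(cols, "truth_label")
  utils::write.table(frags[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  frags <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  frags$start <- as.integer(frags$start)
  frags$end <- as.integer(frags$end)
  validate_fragments(frags)
  frags
}

# Split a CIGAR string into (lengths, ops).
parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]", "", ops)),
       op = sub("[0-9]+", "", ops))
}

#' Ingest mapped fragments from SAM/BAM or the internal TSV
#'
#' Replaces the read-mapping step: alignments produced elsewhere are
#' converted to the package's fragment table. SAM 1-based positions become
#' 0-based half-open coordinates; unmapped, secondary and supplementary
#' records are dropped; soft-clipped bases are trimmed from the stored
#' sequence. The fragment model is gapless: records whose CIGAR contains
#' an insertion, deletion or skip are excluded, with the count reported
#' via `message()` and the `n_skipped_indel` attribute.
#'
#' @param path Input file.
#' @param format `"sam"`, `"bam"` or `"tsv"`; default guessed from the
#'   file extension.
#' @param ref_name Optional reference name; alignments to other references
#'   are dropped.
#' @param library Library label to attach (SAM/BAM input only; default the
#'   file name without extension).
#' @return Fragment `data.frame` as in [write_fragments_tsv()].
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "tsv"),
                            ref_name = NULL, library = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") return(read_fragments_tsv(path))
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- rep(TRUE, length(rec$qname))
  if (!is.null(ref_name)) keep <- as.character(rec$rname) == ref_name
  idx <- which(keep)
  n_indel <- 0L
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    cg <- parse_cigar(rec$cigar[i])
    if (any(cg$op %in% c("I", "D", "N"))) {
      n_indel <- n_indel + 1L
      next
    }
    consume_q <- cg$op %in% c("M", "=", "X", "S")
    consume_r <- cg$op %in% c("M", "=", "X")
    qstart <- if (length(cg$op) > 0 && cg$op[1] == "S") cg$len[1] else 0L
    qlen <- sum(cg$len[consume_r])
    rlen <- sum(cg$len[consume_r])
    seqc <- substr(toupper(as.character(rec$seq[i])),
                   qstart + 1L, qstart + qlen)
    out[[k]] <- data.frame(
      id = rec$qname[i],
      library = library %||% tools::file_path_sans_ext(basename(path)),
      start = rec$pos[i] - 1L,
      end = rec$pos[i] - 1L + rlen,
      strand = if (as.character(rec$strand[i]) == "-") "-" else "+",
      sequence = seqc,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  frags <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(id = character(0), library = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), sequence = character(0),
               stringsAsFactors = FALSE)
  if (n_indel > 0)
    message(n_indel, " alignment(s) with indels skipped (gapless fragment model)")
  attr(frags, "n_skipped_indel") <- n_indel
  validate_fragments(frags)
  frags
}

#' Read a radiocarbon calibration curve
#'
#' Parses the `.14c` dialect: comment/header lines starting with `#` are
#' skipped, fields are comma- or whitespace-separated, and the first three
#' numeric columns are calendar age (cal BP), conventional radiocarbon age
#' (BP) and the 1-sigma curve error (years). Rows are sorted by calendar
#' age ascending.
#'
#' @param path Path to the curve file.
#' @return An object of class `calibration_curve`: list with numeric
#'   vectors `cal_bp`, `c14_bp`, `error`.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("calibration curve file has no data rows: ", path)
  fields <- strsplit(lines, "[,[:space:]]+")
  mat <- t(vapply(fields, function(f) {
    f <- f[nzchar(f)]
    if (length(f) < 3) stop("calibration curve row has fewer than 3 fields")
    as.numeric(f[1:3])
  }, numeric(3)))
  if (anyNA(mat)) stop("non-numeric values in calibration curve: ", path)
  ord <- order(mat[, 1])
  mat <- mat[ord, , drop = FALSE]
  if (anyDuplicated(mat[, 1]))
    stop("duplicate calendar ages in calibration curve: ", path)
  calibration_curve(cal_bp = mat[, 1], c14_bp = mat[, 2], error = mat[, 3])
}

#' Construct a calibration curve object
#'
#' @param cal_bp Calendar ages (cal BP), strictly increasing.
#' @param c14_bp Conventional radiocarbon ages at `cal_bp`.
#' @param error 1-sigma curve error (years).
#' @export
calibration_curve <- function(cal_bp, c14_bp, error) {
  if (length(cal_bp) != length(c14_bp) || length(cal_bp) != length(error))
    stop("cal_bp, c14_bp and error must have equal length")
  if (any(diff(cal_bp) <= 0)) stop("cal_bp must be strictly increasing")
  structure(list(cal_bp = as.numeric(cal_bp), c14_bp = as.numeric(c14_bp),
                 error = as.numeric(error)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %d points, %s-%s cal BP\n",
              length(x$cal_bp), format(min(x$cal_bp), big.mark = ","),
              format(max(x$cal_bp), big.mark = ",")))
  invisible(x)
}
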