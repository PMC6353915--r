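# Shared internals: coordinate arithmetic on the circular reference,
# per-base expansion of fragment sets, sequence helpers.
#
# Conventions used throughout the package:
#   * positions are 0-based; intervals are half-open [start, end)
#   * start is always in [0, L); end may exceed L, in which case the
#     fragment wraps around the origin of the circular genome
#   * fragment sequences are stored reference-forward; read orientation
#     (5' -> 3' of the sequenced molecule) is recovered from `strand`

BASES <- c("A", "C", "G", "T")
# utf8 codes: A=65 C=67 G=71 T=84 N=78
CHR_A <- 65L; CHR_C <- 67L; CHR_G <- 71L; CHR_T <- 84L; CHR_N <- 78L

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reference bases under each fragment, reference-forward, via the doubled
# reference (handles fragments spanning the origin).
frag_ref_seq <- function(frags, ref) {
  doubled <- paste0(ref, ref)
  substring(doubled, frags$start + 1L, frags$end)
}

validate_fragments <- function(frags) {
  needed <- c("id", "library", "start", "end", "strand", "sequence")
  miss <- setdiff(needed, names(frags))
  if (length(miss) > 0)
    stop("fragment table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(frags) == 0) return(invisible(frags))
  if (any(frags$end - frags$start != nchar(frags$sequence)))
    stop("fragment end - start must equal sequence length")
  if (any(frags$start < 0))
    stop("fragment start must be >= 0")
  if (!all(frags$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(grepl("[^ACGTN]", frags$sequence)))
    stop("fragment sequences may contain only A, C, G, T, N")
  invisible(frags)
}

# Expand a fragment table to one row per aligned base.  Returns parallel
# vectors: frag (row index), refpos (0-based position on the circle),
# base / refbase (utf8 integer codes), d5 / d3 (distance of the base from
# the fragment's 5' / 3' end in READ orientation), plus (logical strand).
# refbase is NULL unless `ref` is supplied.
fragment_base_table <- function(frags, L, ref = NULL) {
  lens <- frags$end - frags$start
  n <- nrow(frags)
  if (n == 0 || sum(lens) == 0) {
    return(list(frag = integer(0), refpos = integer(0), base = integer(0),
                refbase = NULL, d5 = integer(0), d3 = integer(0),
                plus = logical(0)))
  }
  idx <- rep.int(seq_len(n), lens)
  off <- sequence(lens) - 1L
  refpos <- (frags$start[idx] + off) %% L
  base <- utf8ToInt(paste(frags$sequence, collapse = ""))
  len_i <- lens[idx]
  plus <- frags$strand[idx] == "+"
  d5 <- off
  d5[!plus] <- (len_i - 1L - off)[!plus]
  d3 <- len_i - 1L - d5
  refbase <- NULL
  if (!is.null(ref))
    refbase <- utf8ToInt(paste(frag_ref_seq(frags, ref), collapse = ""))
  list(frag = idx, refpos = refpos, base = base, refbase = refbase,
       d5 = d5, d3 = d3, plus = plus)
}

# Read-orientation C->T events against the reference: on the + strand a
# stored C-site reads T directly; on the - strand the same chemical event
# appears reference-forward as G->A.
ct_masks <- function(bt) {
  site <- (bt$plus & bt$refbase == CHR_C) | (!bt$plus & bt$refbase == CHR_G)
  list(site = site & bt$base != CHR_N,
       ct   = site & ((bt$plus & bt$base == CHR_T) | (!bt$plus & bt$base == CHR_A)))
}

# Wilson score interval for a binomial proportion (no continuity
# correction); matches prop.test(x, n, correct = FALSE)$conf.int.
wilson_ci <- function(x, n, conf = 0.95) {
  if (is.na(n) || n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
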