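# Synthetic ancient-mtDNA data: reference, haplotype panel, and labelled
# fragment mixtures with the damage structure the downstream estimators
# assume (terminal-decaying C->T deamination on endogenous molecules from
# single-stranded libraries; background-only damage on present-day
# contaminants).

#' Generate a random circular mitochondrial reference genome
#'
#' Produces a uniform-random A/C/G/T sequence used as a stand-in for the
#' 16,569-bp human mitochondrial reference coordinate system.
#'
#' @param L Genome length in bases (default 16569, the length of the human
#'   mitochondrial reference). Must be at least 1000.
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return An object of class `mt_genome`: a list with `name`, `sequence`
#'   (upper-case character scalar), `circular` (always `TRUE`) and `length`.
#' @examples
#' ref <- generate_reference(L = 2000, seed = 1)
#' nchar(ref$sequence)
#' @export
generate_reference <- function(L = 16569L, seed = NULL) {
  if (!is.numeric(L) || length(L) != 1 || L < 1000)
    stop("reference length L must be a single number >= 1000")
  L <- as.integer(L)
  seqc <- with_seed(seed, intToUtf8(utf8ToInt("ACGT")[sample.int(4L, L, replace = TRUE)]))
  structure(list(name = "synthetic_mt_ref", sequence = seqc,
                 circular = TRUE, length = L),
            class = "mt_genome")
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("mt_genome '%s': %d bp, circular\n", x$name, x$length))
  invisible(x)
}

#' Plant an endogenous haplotype and a present-day panel on a reference
#'
#' Each panel member receives `panel_div` random substitutions relative to
#' the root. The endogenous haplotype receives exactly `k_private`
#' substitutions at positions untouched by any panel member, so that every
#' private substitution is diagnostic: the endogenous state differs there
#' from the root and from every panel member.
#'
#' @param ref An `mt_genome` (or a character scalar) acting as the root.
#' @param k_private Number of private substitutions on the endogenous
#'   lineage (default 10).
#' @param n_panel Number of present-day panel haplotypes (default 311).
#' @param panel_div Substitutions per panel member relative to the root
#'   (default 20).
#' @param seed Optional integer seed.
#' @return An object of class `haplotype_set`: root and endogenous
#'   sequences, 0-based `private_positions` with their derived
#'   `private_states`, a named character vector `panel`, and provenance.
#' @export
generate_haplotypes <- function(ref, k_private = 10L, n_panel = 311L,
                                panel_div = 20L, seed = NULL) {
  root <- if (inherits(ref, "mt_genome")) ref$sequence else toupper(ref)
  L <- nchar(root)
  if (k_private < 0 || n_panel < 1 || panel_div < 0)
    stop("k_private, panel_div must be >= 0 and n_panel >= 1")
  if (panel_div > L)
    stop("panel_div exceeds available positions")
  root_int <- utf8ToInt(root)
  alt_of <- function(cur) {
    # random base different from the current one
    others <- matrix(c(CHR_C, CHR_G, CHR_T,  CHR_A, CHR_G, CHR_T,  CHR_A, CHR_C, CHR_T,  CHR_A, CHR_C, CHR_G),
                     nrow = 3)
    col <- match(cur, c(CHR_A, CHR_C, CHR_G, CHR_T))
    others[cbind(sample.int(3L, length(cur), replace = TRUE), col)]
  }
  with_seed(seed, {
    panel_positions <- vector("list", n_panel)
    panel <- character(n_panel)
    for (j in seq_len(n_panel)) {
      pos <- sort(sample.int(L, panel_div)) - 1L
      s <- root_int
      if (panel_div > 0) s[pos + 1L] <- alt_of(root_int[pos + 1L])
      panel_positions[[j]] <- pos
      panel[j] <- intToUtf8(s)
    }
    names(panel) <- sprintf("panel_%03d", seq_len(n_panel))
    used <- unique(unlist(panel_positions))
    avail <- setdiff(seq_len(L) - 1L, used)
    if (k_private > length(avail))
      stop("requested private substitutions exceed available positions")
    priv <- sort(sample(avail, k_private))
    endo_int <- root_int
    states <- character(0)
    if (k_private > 0) {
      states <- intToUtf8(alt_of(root_int[priv + 1L]), multiple = TRUE)
      endo_int[priv + 1L] <- utf8ToInt(paste(states, collapse = ""))
    }
    structure(list(root = root, endogenous = intToUtf8(endo_int),
                   private_positions = priv, private_states = states,
                   panel = panel, panel_positions = panel_positions,
                   L = L,
                   params = list(k_private = k_private, n_panel = n_panel,
                                 panel_div = panel_div, seed = seed)),
              class = "haplotype_set")
  })
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: L = %d bp, %d panel members (%d subs each), %d private substitutions\n",
              x$L, length(x$panel), x$params$panel_div,
              length(x$private_positions)))
  invisible(x)
}

#' Terminal-decaying deamination damage model
#'
#' Cytosine deamination in ancient molecules is concentrated at fragment
#' ends. The per-base probability that a read-orientation C is observed as
#' T is `delta_term * exp(-d / lambda_decay) + delta_bg`, where `d` is the
#' distance to the nearer fragment end (both ends are affected when
#' `both_ends = TRUE`, the behaviour of single-stranded libraries).
#' Contaminant (present-day) molecules receive only `delta_bg`.
#'
#' @param delta_term C->T probability at a terminal base (default 0.4).
#' @param lambda_decay Exponential decay length in bases (default 3).
#' @param delta_bg Background internal C->T probability (default 0.01).
#' @param seq_error Per-base uniform miscall probability (default 0.001).
#' @param both_ends Apply terminal elevation at both read ends
#'   (default `TRUE`).
#' @return A list of class `damage_model`.
#' @export
damage_model <- function(delta_term = 0.4, lambda_decay = 3,
                         delta_bg = 0.01, seq_error = 0.001,
                         both_ends = TRUE) {
  probs <- c(delta_term = delta_term, delta_bg = delta_bg,
             seq_error = seq_error)
  if (any(probs < 0 | probs > 1))
    stop("delta_term, delta_bg and seq_error must lie in [0, 1]")
  if (lambda_decay <= 0) stop("lambda_decay must be > 0")
  structure(list(delta_term = delta_term, lambda_decay = lambda_decay,
                 delta_bg = delta_bg, seq_error = seq_error,
                 both_ends = isTRUE(both_ends)),
            class = "damage_model")
}

#' Simulation configuration for a fragment library
#'
#' @param n_fragments Number of molecules to draw (before PCR duplication).
#' @param contamination_fraction Probability a molecule is a present-day
#'   contaminant drawn from the panel (default 0.3).
#' @param length_min,length_mean,length_max Fragment-length model: a
#'   geometric distribution shifted to `length_min` (35 bp, the retention
#'   floor used throughout), with the given mean, truncated at
#'   `length_max`.
#' @param duplicate_rate Probability a molecule is emitted twice with
#'   identical coordinates, emulating PCR duplicates (default 0.1).
#' @param damage A [damage_model()].
#' @param library Library label attached to every fragment.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fragments = 1000L, contamination_fraction = 0.3,
                       length_min = 35L, length_mean = 55, length_max = 150L,
                       duplicate_rate = 0.1, damage = damage_model(),
                       library = "sim", seed = NULL) {
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must lie in [0, 1]")
  if (length_min < 1) stop("length_min must be >= 1")
  if (length_mean <= length_min) stop("length_mean must exceed length_min")
  if (duplicate_rate < 0 || duplicate_rate > 1)
    stop("duplicate_rate must lie in [0, 1]")
  stopifnot(inherits(damage, "damage_model"))
  structure(list(n_fragments = as.integer(n_fragments),
                 contamination_fraction = contamination_fraction,
                 length_min = as.integer(length_min),
                 length_mean = length_mean,
                 length_max = as.integer(length_max),
                 duplicate_rate = duplicate_rate,
                 damage = damage, library = library, seed = seed),
            class = "sim_config")
}

# Shifted, truncated geometric fragment lengths.
sample_lengths <- function(n, cfg) {
  p <- 1 / (cfg$length_mean - cfg$length_min + 1)
  len <- cfg$length_min + stats::rgeom(n, p)
  bad <- which(len > cfg$length_max)
  while (length(bad) > 0) {
    len[bad] <- cfg$length_min + stats::rgeom(length(bad), p)
    bad <- bad[len[bad] > cfg$length_max]
  }
  len
}

# Apply read-orientation C->T deamination and uniform sequencing error to
# a character vector of read-orientation sequences.  `terminal` switches
# the exponential terminal elevation on (endogenous) or off (contaminant).
apply_damage <- function(seqs, dm, terminal) {
  n <- length(seqs)
  if (n == 0) return(seqs)
  lens <- nchar(seqs)
  base <- utf8ToInt(paste(seqs, collapse = ""))
  off <- sequence(lens) - 1L
  len_i <- rep.int(lens, lens)
  term_i <- rep.int(terminal, lens)
  d5 <- off
  d3 <- len_i - 1L - off
  d <- if (dm$both_ends) pmin(d5, d3) else d5
  p <- ifelse(term_i, dm$delta_term * exp(-d / dm$lambda_decay), 0) + dm$delta_bg
  flip <- base == CHR_C & stats::runif(length(base)) < p
  base[flip] <- CHR_T
  out <- substring(intToUtf8(base), cumsum(c(1L, lens[-n])), cumsum(lens))
  out
}

apply_seq_error <- function(seqs, seq_error) {
  if (seq_error <= 0 || length(seqs) == 0) return(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  base <- utf8ToInt(paste(seqs, collapse = ""))
  hit <- which(stats::runif(length(base)) < seq_error & base != CHR_N)
  if (length(hit) > 0) {
    codes <- c(CHR_A, CHR_C, CHR_G, CHR_T)
    cur <- match(base[hit], codes)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    base[hit] <- codes[((cur - 1L + shift) %% 4L) + 1L]
  }
  substring(intToUtf8(base), cumsum(c(1L, lens[-n])), cumsum(lens))
}

#' Simulate an aligned ancient-DNA fragment library
#'
#' Draws a labelled mixture of endogenous and contaminant molecules from a
#' [generate_haplotypes()] set: starts uniform on the circle, lengths from
#' the shifted geometric model, strand uniform. Endogenous molecules get
#' terminal-decaying C->T deamination in read orientation; contaminants get
#' background damage only. A fraction of molecules is re-emitted with
#' identical coordinates (PCR duplicates, independent sequencing error).
#' Sequences are stored reference-forward; the true origin of each
#' fragment is kept in `truth_label`.
#'
#' @param haps A `haplotype_set`.
#' @param cfg A [sim_config()].
#' @return A `data.frame` with columns `id`, `library`, `start`, `end`,
#'   `strand`, `sequence`, `truth_label` (0-based half-open coordinates on
#'   the circular reference; `end` may exceed `L` for fragments spanning
#'   the origin).
#' @export
simulate_fragments <- function(haps, cfg) {
  stopifnot(inherits(haps, "haplotype_set"), inherits(cfg, "sim_config"))
  L <- haps$L
  dm <- cfg$damage
  with_seed(cfg$seed, {
    n <- cfg$n_fragments
    contaminant <- stats::runif(n) < cfg$contamination_fraction
    member <- integer(n)
    member[contaminant] <- sample.int(length(haps$panel),
                                      sum(contaminant), replace = TRUE)
    start <- sample.int(L, n, replace = TRUE) - 1L
    len <- sample_lengths(n, cfg)
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # reference-forward molecule sequences from the doubled source haplotype
    fwd <- character(n)
    endo_doubled <- paste0(haps$endogenous, haps$endogenous)
    ie <- which(!contaminant)
    if (length(ie) > 0)
      fwd[ie] <- substring(endo_doubled, start[ie] + 1L, end[ie])
    for (j in unique(member[contaminant])) {
      jj <- which(member == j)
      dbl <- paste0(haps$panel[j], haps$panel[j])
      fwd[jj] <- substring(dbl, start[jj] + 1L, end[jj])
    }

    # damage acts in read orientation
    read_seq <- fwd
    minus <- strand == "-"
    read_seq[minus] <- revcomp(fwd[minus])
    read_seq <- apply_damage(read_seq, dm, terminal = !contaminant)

    # PCR duplicates share the molecule (and its damage); sequencing error
    # is drawn independently per emitted copy
    dup <- stats::runif(n) < cfg$duplicate_rate
    emit <- rep.int(seq_len(n), 1L + dup)
    copy <- sequence(1L + dup)
    read_emit <- apply_seq_error(read_seq[emit], dm$seq_error)
    stored <- read_emit
    memit <- minus[emit]
    stored[memit] <- revcomp(read_emit[memit])

    data.frame(
      id = sprintf("f%06d%s", emit, ifelse(copy > 1L, "_dup", "")),
      library = cfg$library,
      start = start[emit], end = end[emit], strand = strand[emit],
      sequence = stored,
      truth_label = ifelse(contaminant[emit], "contaminant", "endogenous"),
      stringsAsFactors = FALSE)
  })
}
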